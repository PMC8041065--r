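#' Fit a unit-specific growth curve through observed points
#'
#' Interpolates a positive-valued series (BS population) between observed
#' time points. Two variants mirror the two generations of the interpolation
#' framework:
#'
#' * `"logistic"`: the validated form. With two points the three-parameter
#'   logistic is underdetermined, so a carrying capacity must be supplied
#'   (the caller's default is twice the larger endpoint); with three points
#'   the capacity is solved for exactly. The curve passes through every
#'   supplied point.
#' * `"exponential"`: the early two-point form, `v(t) = v0 * exp(r (t-t0))`
#'   with `r = log(v1/v0)/(t1-t0)`; with more than two points it is applied
#'   piecewise between consecutive points, so it still interpolates exactly.
#'
#' @param points two-column matrix or data.frame of (year, value) pairs,
#'   values strictly positive.
#' @param kind `"logistic"` or `"exponential"`.
#' @param capacity carrying capacity for the 2-point logistic; must exceed
#'   both values.
#' @return a vectorised function of time.
#' @export
fit_growth_curve <- function(points, kind = c("logistic", "exponential"),
                             capacity = NULL) {
  kind <- match.arg(kind)
  pts <- as.matrix(points)
  if (ncol(pts) != 2 || nrow(pts) < 2) {
    stop("`points` must be >= 2 (year, value) pairs", call. = FALSE)
  }
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  tt <- pts[, 1]; vv <- pts[, 2]
  if (anyDuplicated(tt)) stop("duplicate years in `points`", call. = FALSE)
  if (any(vv <= 0)) {
    stop("values must be strictly positive for ", kind, " curves", call. = FALSE)
  }

  if (kind == "exponential") {
    # piecewise two-point exponential; exact at every point
    return(function(t) {
      t <- as.numeric(t)
      seg <- pmin(pmax(findInterval(t, tt), 1L), length(tt) - 1L)
      r <- log(vv[seg + 1L] / vv[seg]) / (tt[seg + 1L] - tt[seg])
      vv[seg] * exp(r * (t - tt[seg]))
    })
  }

  # logistic: v(t) = K / (1 + exp(-(a + b t)))
  if (nrow(pts) == 2) {
    if (is.null(capacity)) {
      stop("a 2-point logistic is underdetermined: supply `capacity` or use ",
           "kind = \"exponential\"", call. = FALSE)
    }
    K <- capacity
    if (K <= max(vv)) stop("`capacity` must exceed both observed values", call. = FALSE)
  } else if (nrow(pts) == 3) {
    K <- .solve_logistic_capacity(tt, vv)
  } else {
    stop("logistic interpolation supports 2 points (with capacity) or 3 points",
         call. = FALSE)
  }
  L <- log(vv / (K - vv))
  b <- (L[2] - L[1]) / (tt[2] - tt[1])
  a <- L[1] - b * tt[1]
  function(t) K / (1 + exp(-(a + b * as.numeric(t))))
}

# Find K > max(v) such that the log-odds log(v/(K-v)) are collinear in t.
.solve_logistic_capacity <- function(tt, vv) {
  g <- function(K) {
    L <- log(vv / (K - vv))
    (L[2] - L[1]) / (tt[2] - tt[1]) - (L[3] - L[2]) / (tt[3] - tt[2])
  }
  lo <- max(vv) * (1 + 1e-9)
  hi <- max(vv) * 1e6
  if (!is.finite(g(lo)) || !is.finite(g(hi)) || g(lo) * g(hi) > 0) {
    stop("no logistic curve passes through the three supplied points",
         call. = FALSE)
  }
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Natural cubic spline interpolation of a unit-level series
#'
#' Natural cubic spline (second derivative zero at both boundary knots),
#' exact at every knot; with two points it degenerates to the linear
#' interpolant. Used for unit-level BS population density between epochs.
#'
#' @param points two-column matrix or data.frame of (year, value) pairs with
#'   strictly increasing years.
#' @return a vectorised function of time.
#' @export
interpolate_density_spline <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2 || nrow(pts) < 2) {
    stop("`points` must be >= 2 (year, value) pairs", call. = FALSE)
  }
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  if (anyDuplicated(pts[, 1])) stop("duplicate years in `points`", call. = FALSE)
  stats::splinefun(pts[, 1], pts[, 2], method = "natural")
}

#' Annual transition-demand weights from an implied BS area series
#'
#' Converts a unit's interpolated series of implied BS area (BS population /
#' BS population density) into normalised per-year weights over the
#' transition years (each year after the first): `w_t` is proportional to
#' `max(0, A_t - A_{t-1})` — an interpolative model cannot remove settlement,
#' so negative increments are clamped. If every increment is non-positive
#' the weights fall back to uniform.
#'
#' @param area numeric vector of implied BS area, one value per year
#'   (length >= 2).
#' @return numeric vector of length `length(area) - 1`, summing to 1.
#' @export
demand_weights <- function(area) {
  if (length(area) < 2) stop("`area` must cover at least 2 years", call. = FALSE)
  inc <- pmax(0, diff(area))
  if (sum(inc) <= 0) {
    return(rep(1 / length(inc), length(inc)))
  }
  inc / sum(inc)
}

#' Largest-remainder apportionment of an integer total over weights
#'
#' Temporally disaggregates an observed period transition count into integer
#' per-year counts: each year gets `floor(total * w)` and the remaining units
#' go to the largest fractional remainders (ties broken by earlier position).
#' The result always sums exactly to `total`.
#'
#' @param total nonnegative integer.
#' @param weights nonnegative weights summing to 1.
#' @return integer vector, same length as `weights`, summing to `total`.
#' @export
disaggregate_transitions <- function(total, weights) {
  if (length(total) != 1 || is.na(total) || total < 0 || total != round(total)) {
    stop("`total` must be a single nonnegative integer", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be nonnegative and sum to 1", call. = FALSE)
  }
  q <- total * weights
  base <- floor(q)
  rem <- q - base
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    idx <- order(-rem, seq_along(rem))[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Demand quantification: per-unit annual transition counts
#'
#' For each unit, interpolates BS population between the observed epochs with
#' a growth curve and BS population density with a natural cubic spline
#' (logistic variant) or interpolates both exponentially (early variant),
#' forms the implied BS area series `A = population / density`, converts its
#' increments to normalised weights, and apportions the unit's observed
#' period transition count to the transition years by largest remainder.
#' Units whose epoch observations cannot support a multiplicative curve
#' (a nonpositive endpoint) fall back to uniform weights.
#'
#' @param epoch_obs data.frame with columns `unit_id`, `year`,
#'   `bs_population`, `bs_pixels` holding the two epoch observations per
#'   unit.
#' @param years consecutive integer years t0..t1.
#' @param transitions named vector: observed period transition count
#'   (pixels) per unit id.
#' @param curve `"logistic"` or `"exponential"`.
#' @param capacity_factor the 2-point logistic capacity as a multiple of the
#'   larger BS population endpoint.
#' @return data.frame with columns `unit_id`, `year`, `n_transitions`, one
#'   row per unit and transition year; per unit the counts sum exactly to
#'   the observed total.
#' @export
bsgmi_demand <- function(epoch_obs, years, transitions,
                         curve = c("logistic", "exponential"),
                         capacity_factor = 2) {
  curve <- match.arg(curve)
  years <- as.integer(years)
  trans_years <- years[-1]
  unit_ids <- sort(unique(epoch_obs$unit_id))
  out <- vector("list", length(unit_ids))
  for (i in seq_along(unit_ids)) {
    u <- unit_ids[i]
    obs <- epoch_obs[epoch_obs$unit_id == u, , drop = FALSE]
    obs <- obs[order(obs$year), , drop = FALSE]
    total <- transitions[[as.character(u)]]
    if (is.null(total) || is.na(total)) total <- 0L
    w <- .unit_demand_weights(obs, years, curve, capacity_factor)
    counts <- disaggregate_transitions(total, w)
    out[[i]] <- data.frame(unit_id = u, year = trans_years,
                           n_transitions = counts)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.unit_demand_weights <- function(obs, years, curve, capacity_factor) {
  pop <- obs$bs_population
  dens <- ifelse(obs$bs_pixels > 0, obs$bs_population / obs$bs_pixels, 0)
  if (any(pop <= 0) || any(dens <= 0)) {
    return(rep(1 / (length(years) - 1), length(years) - 1))
  }
  pop_pts <- cbind(obs$year, pop)
  dens_pts <- cbind(obs$year, dens)
  if (curve == "logistic") {
    cap <- if (nrow(obs) == 2) capacity_factor * max(pop) else NULL
    pop_curve <- fit_growth_curve(pop_pts, "logistic", capacity = cap)
    dens_curve <- interpolate_density_spline(dens_pts)
  } else {
    pop_curve <- fit_growth_curve(pop_pts, "exponential")
    dens_curve <- fit_growth_curve(dens_pts, "exponential")
  }
  area <- pop_curve(years) / dens_curve(years)
  demand_weights(area)
}
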