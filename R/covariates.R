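#' Euclidean distance to the nearest edge of a raster class
#'
#' Continuizes a binary raster by computing, for every pixel outside the
#' class, the Euclidean distance (in pixel units, between pixel centers) to
#' the nearest class pixel. Pixels inside the class have distance 0 (unsigned
#' DTE; the signed-inside variant is deliberately not used — outside the class
#' the ordering information seen by a random forest is identical).
#'
#' Uses the exact two-pass squared Euclidean distance transform of
#' Felzenszwalb & Huttenlocher, so results agree exactly with a brute-force
#' all-pairs computation.
#'
#' @param mask binary matrix (0/1); must contain at least one 1 pixel.
#' @return numeric matrix of distances, 0 exactly on the support of `mask`.
#' @export
distance_to_nearest_edge <- function(mask) {
  .assert_binary(mask)
  if (!any(mask == 1, na.rm = TRUE)) {
    stop("mask has no 1-pixels: distance to nearest edge is undefined ",
         "(unit/country with no settlement)", call. = FALSE)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  big <- (nr * nr + nc * nc + 1) * 4  # exceeds any attainable squared distance
  f <- matrix(big, nr, nc)
  f[mask == 1] <- 0
  for (j in seq_len(nc)) f[, j] <- .edt_1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- .edt_1d(f[i, ])
  sqrt(f)
}

# Exact 1-D squared distance transform (lower envelope of parabolas).
# f: vector of squared distances (0 at sources, a large finite value
# elsewhere); returns min_q' (q - q')^2 + f[q'].
.edt_1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
    while (k > 1L && s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Proportion of class pixels within a Euclidean pixel radius
#'
#' At each pixel, the count of 1-pixels whose center lies within `radius`
#' (Euclidean, center included) divided by the count of all in-grid pixels in
#' that disc; grid edges use the truncated neighbourhood, so values are always
#' a proportion of the pixels actually present.
#'
#' @param mask binary matrix.
#' @param radius positive integer disc radius in pixels.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
proportion_in_radius <- function(mask, radius) {
  .assert_binary(mask)
  if (length(radius) != 1L || radius < 1 || radius != round(radius)) {
    stop("`radius` must be a single positive integer", call. = FALSE)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  m <- mask
  m[is.na(m)] <- 0
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  r <- as.integer(radius)
  for (di in -r:r) {
    r_lo <- max(1L, 1L - di); r_hi <- min(nr, nr - di)
    if (r_lo > r_hi) next
    r_dst <- r_lo:r_hi
    r_src <- r_dst + di
    for (dj in -r:r) {
      if (di * di + dj * dj > r * r) next
      c_lo <- max(1L, 1L - dj); c_hi <- min(nc, nc - dj)
      if (c_lo > c_hi) next
      c_dst <- c_lo:c_hi
      c_src <- c_dst + dj
      num[r_dst, c_dst] <- num[r_dst, c_dst] + m[r_src, c_src]
      den[r_dst, c_dst] <- den[r_dst, c_dst] + 1
    }
  }
  num / den
}

#' Mean of a raster within each subnational unit
#'
#' Arithmetic mean of `grid` over the pixels of each unit; `NA` pixels in
#' either the grid or the unit map (e.g. water) are excluded.
#'
#' @param grid numeric matrix.
#' @param unit_map integer matrix of unit labels, `NA` outside units.
#' @return named numeric vector, one mean per unit label.
#' @export
unit_mean <- function(grid, unit_map) {
  .assert_grid(grid); .assert_grid(unit_map)
  .assert_congruent(grid, unit_map, "grid", "unit_map")
  keep <- !is.na(unit_map) & !is.na(grid)
  units_all <- sort(unique(unit_map[!is.na(unit_map)]))
  if (length(units_all) == 0L) stop("unit_map contains no units", call. = FALSE)
  counts <- table(factor(unit_map[keep], levels = units_all))
  if (any(counts == 0)) {
    stop("unit(s) with zero unmasked pixels: ",
         paste(units_all[counts == 0], collapse = ", "), call. = FALSE)
  }
  out <- tapply(grid[keep], factor(unit_map[keep], levels = units_all), mean)
  stats::setNames(as.numeric(out), as.character(units_all))
}

#' Unit-rescaled lights-at-night difference weights
#'
#' Computes the annual LAN radiance difference `d = lan_curr - lan_prev` and
#' min-max rescales it within each subnational unit so that, per unit, the
#' pixel with the greatest increase in brightness gets weight 1 and the
#' smallest gets 0. A degenerate within-unit range (constant difference) maps
#' to 0.5 everywhere in that unit: an uninformative difference should neither
#' zero out nor saturate the transition probability product. Pixels outside
#' any unit get weight 0.
#'
#' @param lan_curr,lan_prev congruent numeric matrices of LAN radiance.
#' @param unit_map integer matrix of unit labels, `NA` outside units.
#' @return numeric matrix of weights in `[0, 1]`.
#' @export
lan_weight <- function(lan_curr, lan_prev, unit_map) {
  .assert_grid(lan_curr); .assert_grid(lan_prev); .assert_grid(unit_map)
  .assert_congruent(lan_curr, lan_prev, "lan_curr", "lan_prev")
  .assert_congruent(lan_curr, unit_map, "lan_curr", "unit_map")
  d <- lan_curr - lan_prev
  w <- matrix(0, nrow(d), ncol(d))
  for (u in sort(unique(unit_map[!is.na(unit_map)]))) {
    sel <- which(unit_map == u)
    du <- d[sel]
    rng <- range(du)
    if (rng[2] > rng[1]) {
      w[sel] <- (du - rng[1]) / (rng[2] - rng[1])
    } else {
      w[sel] <- 0.5
    }
  }
  w
}

#' Covariate stack for the transition random forest
#'
#' Builds the epoch-t0 predictor layers used to model the probability of a
#' non-BS-to-BS transition: DTE of BS at t0, proportion of BS within 1/5/10/15
#' pixel radii at t0, elevation, slope, and distance to the protected-area
#' analogue.
#'
#' @param bundle a `scenario_bundle`.
#' @param radii integer vector of disc radii for the proportion layers.
#' @return named list of numeric matrices.
#' @export
transition_covariates <- function(bundle, radii = c(1L, 5L, 10L, 15L)) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  bs0 <- bundle$observed_bs_t0
  covs <- list(bs_dte_t0 = distance_to_nearest_edge(bs0))
  for (r in radii) {
    covs[[paste0("bs_prop_r", r)]] <- proportion_in_radius(bs0, r)
  }
  covs$elevation <- bundle$static_covariates$elevation
  covs$slope <- bundle$static_covariates$slope
  covs$protected_dst <- bundle$static_covariates$protected_dst
  covs
}

#' Covariate stack for a year's population model
#'
#' Assembles the per-year predictor layers used in the dasymetric population
#' model: the year-specific BS DTE (from interpolated extents for interim
#' years, observed extents at the epochs), the historical epoch-t0 BS DTE
#' (kept in all years), the DTE of the coarse annual settlement product for
#' that year, the LAN radiance for that year, and the static layers.
#'
#' @param bundle a `scenario_bundle`.
#' @param bs_grid binary matrix of BS extents for the target year.
#' @param year integer year (must be in `bundle$years`).
#' @return named list of numeric matrices.
#' @export
population_covariates <- function(bundle, bs_grid, year) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  yr <- as.character(year)
  if (!yr %in% names(bundle$coarse_annual_bs)) {
    stop("year ", year, " not present in the scenario bundle", call. = FALSE)
  }
  list(
    bs_dte_annual = distance_to_nearest_edge(bs_grid),
    bs_dte_t0     = distance_to_nearest_edge(bundle$observed_bs_t0),
    bs_dte_coarse = distance_to_nearest_edge(bundle$coarse_annual_bs[[yr]]),
    lan           = bundle$lan_series[[yr]],
    elevation     = bundle$static_covariates$elevation,
    slope         = bundle$static_covariates$slope,
    water_dst     = bundle$static_covariates$water_dst,
    road_dst      = bundle$static_covariates$road_dst,
    protected_dst = bundle$static_covariates$protected_dst
  )
}
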