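#' Configuration for a synthetic country scenario
#'
#' Defines a planar pixel grid scenario with `n_units` subnational units,
#' annual time steps from the first year (epoch t0) to the last (epoch t1),
#' and the stochastic mechanisms downstream modules are validated against:
#' settlement growth, lights-at-night radiance, and population density tied
#' to settlement proximity with known coefficients.
#'
#' Defaults describe the reference study condition used throughout the test
#' suite: a 64x64 grid, 4 units, 13 annual steps, 5% of candidate pixels
#' transitioning per year.
#'
#' @param rows,cols grid dimensions (pixels).
#' @param n_units number of contiguous subnational units.
#' @param years consecutive integer years, t0..t1, length >= 3.
#' @param seed master seed; every generator draws from sub-streams derived
#'   from it by fixed offsets.
#' @param growth_rate expected per-year fraction of candidate (non-BS land)
#'   pixels that transition to BS, in `[0, 1]`.
#' @param settlement_effect coefficient linking BS proximity
#'   (`exp(-DTE/proximity_scale)`) to log population density.
#' @param noise_sd standard deviation of iid log-density noise.
#' @param lan_noise_sd standard deviation of LAN radiance noise.
#' @param coarse_factor block size of the coarse annual settlement product
#'   (3 emulates a 300 m product on a 100 m grid).
#' @param water_frac fraction of the grid covered by water.
#' @param proximity_scale e-folding distance (pixels) of the settlement
#'   proximity effect on density.
#' @param static_effects named coefficients of the (z-scored) static
#'   covariates in the log-density model.
#' @param lan_baseline,lan_gain LAN radiance baseline and gain on local BS
#'   density.
#' @param alpha intercept of the log-density model (density 1 per pixel far
#'   from settlement, before static effects).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(rows = 64L, cols = 64L, n_units = 4L,
                            years = 2000:2012, seed = 1L,
                            growth_rate = 0.05, settlement_effect = 3,
                            noise_sd = 0.3, lan_noise_sd = 0.1,
                            coarse_factor = 3L, water_frac = 0.08,
                            proximity_scale = 5,
                            static_effects = c(elevation = -0.4, slope = -0.2,
                                               water_dst = -0.15,
                                               road_dst = -0.4,
                                               protected_dst = 0.1),
                            lan_baseline = 0.1, lan_gain = 1,
                            alpha = 0) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              n_units = as.integer(n_units), years = as.integer(years),
              seed = as.integer(seed), growth_rate = growth_rate,
              settlement_effect = settlement_effect, noise_sd = noise_sd,
              lan_noise_sd = lan_noise_sd,
              coarse_factor = as.integer(coarse_factor),
              water_frac = water_frac, proximity_scale = proximity_scale,
              static_effects = static_effects, lan_baseline = lan_baseline,
              lan_gain = lan_gain, alpha = alpha)
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

#' @rdname scenario_config
#' @param cfg a `scenario_config` to validate.
#' @export
validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$rows < 1 || cfg$cols < 1) stop("grid dimensions must be positive", call. = FALSE)
  if (length(cfg$years) < 3) {
    stop("`years` must span at least 3 years (one interim year between epochs)",
         call. = FALSE)
  }
  if (any(diff(cfg$years) != 1L)) stop("`years` must be consecutive integers", call. = FALSE)
  if (cfg$n_units < 1 || cfg$n_units > cfg$rows * cfg$cols) {
    stop("`n_units` must be between 1 and the pixel count", call. = FALSE)
  }
  if (cfg$growth_rate < 0 || cfg$growth_rate > 1) stop("`growth_rate` must be in [0,1]", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$lan_noise_sd < 0) stop("noise SDs must be nonnegative", call. = FALSE)
  if (cfg$coarse_factor < 1) stop("`coarse_factor` must be a positive integer", call. = FALSE)
  if (cfg$water_frac < 0 || cfg$water_frac >= 1) stop("`water_frac` must be in [0,1)", call. = FALSE)
  cfg
}

#' Generate the static landscape of a scenario
#'
#' Produces the water mask (threshold of a smooth random field), a partition
#' of the land pixels into `n_units` contiguous units (multi-source flood
#' fill from well-separated seeds; isolated land pixels join the unit with
#' the nearest seed), and the static covariates: a smooth elevation field,
#' its gradient-magnitude slope, distance to water, distance to synthetic
#' straight-line roads, and distance to a synthetic protected-area disc.
#' A smooth "development suitability" field is also generated; settlement
#' growth uses it so growth intensity varies across the landscape.
#'
#' @param config a `scenario_config`.
#' @return list with `unit_map` (integer matrix, `NA` on water),
#'   `static_covariates` (named list of matrices), `water_mask` (binary
#'   matrix) and `suitability` (positive matrix).
#' @export
generate_landscape <- function(config) {
  validate_scenario_config(config)
  nr <- config$rows; nc <- config$cols
  .substream(config$seed, .STREAM["landscape"])

  elevation <- .smooth_field(nr, nc)
  wfield <- .smooth_field(nr, nc)
  suit_field <- .smooth_field(nr, nc, half = 4L)
  water_mask <- matrix(0, nr, nc)
  if (config$water_frac > 0 && nr * nc > 1) {
    thr <- stats::quantile(wfield, config$water_frac, type = 7)
    water_mask[wfield <= thr] <- 1
  }
  land <- which(water_mask == 0)
  if (length(land) < config$n_units) {
    stop("configuration error: fewer land pixels than units", call. = FALSE)
  }

  # slope: central-difference gradient magnitude of elevation
  gx <- elevation; gy <- elevation
  gx[, ] <- 0; gy[, ] <- 0
  if (nr > 2) gy[2:(nr - 1), ] <- (elevation[3:nr, ] - elevation[1:(nr - 2), ]) / 2
  if (nc > 2) gx[, 2:(nc - 1)] <- (elevation[, 3:nc] - elevation[, 1:(nc - 2)]) / 2
  slope <- sqrt(gx^2 + gy^2)

  unit_map <- .grow_units(land, config$n_units, nr, nc)
  unit_map[water_mask == 1] <- NA_integer_

  water_dst <- if (any(water_mask == 1)) {
    distance_to_nearest_edge(water_mask)
  } else {
    matrix(nr + nc, nr, nc)
  }
  road_dst <- .road_distance(nr, nc, n_roads = 3L)
  protected_dst <- .disc_distance(nr, nc)

  list(unit_map = unit_map,
       static_covariates = list(elevation = elevation, slope = slope,
                                water_dst = water_dst, road_dst = road_dst,
                                protected_dst = protected_dst),
       water_mask = water_mask,
       suitability = exp(suit_field))
}

# Contiguous partition of the land pixels: sample well-spread seeds, then
# multi-source BFS over the 4-neighbourhood; unreachable land joins the unit
# with the nearest seed (Euclidean).
.grow_units <- function(land, n_units, nr, nc) {
  unit_map <- matrix(NA_integer_, nr, nc)
  seeds <- if (length(land) == n_units) land else {
    # farthest-point style spread: greedy from a random start
    first <- sample(land, 1L)
    sel <- first
    coords <- .pix_coords(land, nr)
    for (k in seq_len(n_units - 1L)) {
      sc <- .pix_coords(sel, nr)
      dmin <- rep(Inf, length(land))
      for (i in seq_len(nrow(sc))) {
        dmin <- pmin(dmin, (coords[, 1] - sc[i, 1])^2 + (coords[, 2] - sc[i, 2])^2)
      }
      sel <- c(sel, land[which.max(dmin)])
    }
    sel
  }
  unit_map[seeds] <- seq_len(n_units)
  frontier <- seeds
  land_set <- matrix(FALSE, nr, nc); land_set[land] <- TRUE
  while (length(frontier) > 0) {
    nxt <- integer(0)
    frontier <- frontier[sample.int(length(frontier))]  # randomised growth order
    for (p in frontier) {
      r <- ((p - 1L) %% nr) + 1L; cc <- ((p - 1L) %/% nr) + 1L
      u <- unit_map[p]
      for (nb in list(c(r - 1L, cc), c(r + 1L, cc), c(r, cc - 1L), c(r, cc + 1L))) {
        if (nb[1] < 1L || nb[1] > nr || nb[2] < 1L || nb[2] > nc) next
        q <- (nb[2] - 1L) * nr + nb[1]
        if (land_set[q] && is.na(unit_map[q])) {
          unit_map[q] <- u
          nxt <- c(nxt, q)
        }
      }
    }
    frontier <- nxt
  }
  orphan <- land[is.na(unit_map[land])]
  if (length(orphan) > 0) {
    oc <- .pix_coords(orphan, nr)
    sc <- .pix_coords(seeds, nr)
    for (i in seq_along(orphan)) {
      d2 <- (sc[, 1] - oc[i, 1])^2 + (sc[, 2] - oc[i, 2])^2
      unit_map[orphan[i]] <- which.min(d2)
    }
  }
  unit_map
}

# distance from each pixel center to the nearest of n random straight lines
.road_distance <- function(nr, nc, n_roads = 3L) {
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  d <- matrix(Inf, nr, nc)
  for (k in seq_len(n_roads)) {
    r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
    th <- stats::runif(1, 0, pi)
    # line through (r0, c0) with direction (cos th, sin th)
    dk <- abs(-sin(th) * (rr - r0) + cos(th) * (cc - c0))
    d <- pmin(d, dk)
  }
  d
}

# distance to a random disc ("protected area"): 0 inside, radial outside
.disc_distance <- function(nr, nc) {
  r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
  rad <- stats::runif(1, min(nr, nc) / 10, min(nr, nc) / 4)
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  d <- sqrt((rr - r0)^2 + (cc - c0)^2) - rad
  d[d < 0] <- 0
  d
}

# noise-free latent log density for a given BS extent
.latent_log_density <- function(bs, landscape, config) {
  dte <- distance_to_nearest_edge(bs)
  lat <- config$alpha + config$settlement_effect *
    exp(-dte / config$proximity_scale)
  for (nm in names(config$static_effects)) {
    z <- landscape$static_covariates[[nm]]
    zs <- stats::sd(z)
    if (zs > 0) z <- (z - mean(z)) / zs else z <- z * 0
    lat <- lat + config$static_effects[[nm]] * z
  }
  lat
}

#' Simulate monotone built-settlement growth with known truth
#'
#' Seeds one compact settlement cluster (radius-2 disc) per unit at the most
#' road-accessible land pixel, then each year draws the number of new
#' transitions as Binomial(candidates, growth_rate) and places them by
#' weighted sampling without replacement, with weights decaying in distance
#' to existing BS and modulated by the landscape's smooth suitability field.
#' The series is monotone by construction: a BS pixel stays BS.
#'
#' Also computes the withheld per-unit BS population series: the noise-free
#' latent pixel density summed over each year's BS extent (the population
#' found spatially coincident with the extents).
#'
#' @param landscape output of [generate_landscape()].
#' @param config a `scenario_config`.
#' @return object of class `scenario_truth`: `true_bs_series` (named list of
#'   binary matrices, one per year), `bs_population_series` (data.frame:
#'   unit_id, year, bs_population, bs_pixels), `density_coefficients`.
#' @export
simulate_settlement_growth <- function(landscape, config) {
  validate_scenario_config(config)
  nr <- config$rows; nc <- config$cols
  .substream(config$seed, .STREAM["growth"])
  land <- landscape$water_mask == 0

  bs <- matrix(0, nr, nc)
  road <- landscape$static_covariates$road_dst
  for (u in seq_len(config$n_units)) {
    in_unit <- which(!is.na(landscape$unit_map) & landscape$unit_map == u)
    ctr <- in_unit[which.min(road[in_unit])]
    r0 <- ((ctr - 1L) %% nr) + 1L; c0 <- ((ctr - 1L) %/% nr) + 1L
    for (dr in -2:2) for (dc in -2:2) {
      if (dr * dr + dc * dc > 4) next
      r <- r0 + dr; cc <- c0 + dc
      if (r >= 1 && r <= nr && cc >= 1 && cc <= nc && land[r, cc]) bs[r, cc] <- 1
    }
  }

  years <- config$years
  series <- stats::setNames(vector("list", length(years)), as.character(years))
  series[[1]] <- bs
  for (t in seq_along(years)[-1]) {
    cand <- which(land & bs == 0)
    if (length(cand) == 0) {
      if (config$growth_rate >= 1) {
        warning("no candidate pixels remain; settlement series is saturated",
                call. = FALSE)
      }
      series[[t]] <- bs
      next
    }
    n_new <- stats::rbinom(1L, length(cand), config$growth_rate)
    if (n_new > 0) {
      dte <- distance_to_nearest_edge(bs)
      w <- exp(-dte[cand] / 3) * landscape$suitability[cand]
      chosen <- cand[sample.int(length(cand), n_new, prob = w)]
      bs[chosen] <- 1
    }
    series[[t]] <- bs
  }

  bs_pop <- do.call(rbind, lapply(seq_along(years), function(t) {
    lat <- .latent_log_density(series[[t]], landscape, config)
    dens <- exp(lat)
    um <- landscape$unit_map
    out <- lapply(seq_len(config$n_units), function(u) {
      sel <- !is.na(um) & um == u & series[[t]] == 1
      data.frame(unit_id = u, year = years[t],
                 bs_population = sum(dens[sel]), bs_pixels = sum(sel))
    })
    do.call(rbind, out)
  }))

  structure(list(true_bs_series = series,
                 bs_population_series = bs_pop,
                 density_coefficients = list(
                   alpha = config$alpha,
                   settlement_effect = config$settlement_effect,
                   proximity_scale = config$proximity_scale,
                   static_effects = config$static_effects,
                   noise_sd = config$noise_sd)),
            class = "scenario_truth")
}

#' Emulate a coarse annual settlement product
#'
#' Degrades a binary extent grid to the resolution of a coarser annual
#' product: majority vote within each `factor` x `factor` block (ties vote
#' 0), then nearest-neighbour upsampling back to the full grid. Edge blocks
#' are truncated when `factor` does not divide the grid dimensions.
#'
#' @param true_bs binary matrix.
#' @param factor positive integer block size.
#' @return binary matrix of the same dimensions.
#' @export
emulate_coarse_annual_extents <- function(true_bs, factor) {
  .assert_binary(true_bs)
  if (factor < 1 || factor != round(factor)) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  if (factor == 1) return(true_bs)
  nr <- nrow(true_bs); nc <- ncol(true_bs)
  out <- matrix(0, nr, nc)
  for (bi in seq(1L, nr, by = factor)) {
    ri <- bi:min(bi + factor - 1L, nr)
    for (bj in seq(1L, nc, by = factor)) {
      cj <- bj:min(bj + factor - 1L, nc)
      blk <- true_bs[ri, cj, drop = FALSE]
      ones <- sum(blk == 1, na.rm = TRUE)
      out[ri, cj] <- as.numeric(ones * 2 > length(blk))  # strict majority; ties -> 0
    }
  }
  out
}

#' Simulate annual lights-at-night radiance
#'
#' Per-year radiance = baseline + gain x local BS density (proportion of BS
#' within a 3-pixel radius of the year's true extents) + Gaussian noise,
#' truncated at zero.
#'
#' @param truth a `scenario_truth`.
#' @param config a `scenario_config`.
#' @return named list of numeric matrices, one per year.
#' @export
simulate_lan <- function(truth, config) {
  stopifnot(inherits(truth, "scenario_truth"))
  .substream(config$seed, .STREAM["lan"])
  nr <- config$rows; nc <- config$cols
  lapply(truth$true_bs_series, function(bs) {
    dens <- proportion_in_radius(bs, 3L)
    noise <- if (config$lan_noise_sd > 0) {
      matrix(stats::rnorm(nr * nc, sd = config$lan_noise_sd), nr, nc)
    } else {
      matrix(0, nr, nc)
    }
    out <- config$lan_baseline + config$lan_gain * dens + noise
    out[out < 0] <- 0
    out
  })
}

#' Simulate annual subnational population counts
#'
#' Pixel-level latent log density is `alpha + settlement_effect *
#' exp(-DTE/proximity_scale) + sum(gamma_k * z_k) + noise` on land (density 0
#' on water); the unit-year count is the sum of pixel densities over the
#' unit, rounded to an integer.
#'
#' @param truth a `scenario_truth`.
#' @param landscape output of [generate_landscape()].
#' @param config a `scenario_config`.
#' @return data.frame with columns `unit_id`, `year`, `population`.
#' @export
simulate_population <- function(truth, landscape, config) {
  stopifnot(inherits(truth, "scenario_truth"))
  .substream(config$seed, .STREAM["population"])
  nr <- config$rows; nc <- config$cols
  um <- landscape$unit_map
  years <- config$years
  out <- vector("list", length(years))
  for (t in seq_along(years)) {
    lat <- .latent_log_density(truth$true_bs_series[[t]], landscape, config)
    if (config$noise_sd > 0) {
      lat <- lat + matrix(stats::rnorm(nr * nc, sd = config$noise_sd), nr, nc)
    }
    dens <- exp(lat)
    dens[landscape$water_mask == 1] <- 0
    sums <- tapply(dens[!is.na(um)], um[!is.na(um)], sum)
    out[[t]] <- data.frame(unit_id = as.integer(names(sums)),
                           year = years[t],
                           population = round(as.numeric(sums)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic country scenario
#'
#' Runs the full generator chain and splits the result into the observable
#' bundle (what the models are allowed to see: epoch extents, coarse annual
#' product, LAN series, static covariates, unit populations, and the
#' population/pixel counts coincident with the epoch extents) and the
#' withheld truth (the annual extent series and generating coefficients),
#' used only for scoring.
#'
#' @param config a `scenario_config`.
#' @return list with elements `bundle` (class `scenario_bundle`) and `truth`
#'   (class `scenario_truth`).
#' @export
simulate_scenario <- function(config = scenario_config()) {
  validate_scenario_config(config)
  landscape <- generate_landscape(config)
  truth <- simulate_settlement_growth(landscape, config)
  lan <- simulate_lan(truth, config)
  population <- simulate_population(truth, landscape, config)
  years <- config$years
  coarse <- lapply(truth$true_bs_series, emulate_coarse_annual_extents,
                   factor = config$coarse_factor)
  epochs <- c(years[1], years[length(years)])
  epoch_obs <- truth$bs_population_series[
    truth$bs_population_series$year %in% epochs, , drop = FALSE]
  rownames(epoch_obs) <- NULL
  bundle <- structure(list(
    unit_map = landscape$unit_map,
    static_covariates = landscape$static_covariates,
    observed_bs_t0 = truth$true_bs_series[[1]],
    observed_bs_t1 = truth$true_bs_series[[length(years)]],
    coarse_annual_bs = coarse,
    lan_series = lan,
    population = population,
    epoch_obs = epoch_obs,
    water_mask = landscape$water_mask,
    years = years,
    config = config
  ), class = "scenario_bundle")
  list(bundle = bundle, truth = truth)
}
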