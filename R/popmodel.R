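#' Build a unit-level training table for a year's population model
#'
#' Aggregates the year's covariate stack to subnational-unit means and pairs
#' them with the response: natural-log population density (unit count
#' divided by the unit's land-pixel count). Units with zero population are
#' excluded from training (recorded in the `"excluded_units"` attribute);
#' they still receive predictions downstream.
#'
#' @param bundle a `scenario_bundle`.
#' @param bs_grid binary matrix of the year's BS extents (interpolated for
#'   interim years, observed at the epochs).
#' @param year integer year.
#' @return data.frame with `unit_id`, `response`, and one column per
#'   covariate.
#' @export
build_training_table <- function(bundle, bs_grid, year) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  covs <- population_covariates(bundle, bs_grid, year)
  um <- bundle$unit_map
  unit_ids <- sort(unique(um[!is.na(um)]))
  land_px <- table(factor(um[!is.na(um)], levels = unit_ids))
  pop <- bundle$population[bundle$population$year == year, , drop = FALSE]
  counts <- stats::setNames(pop$population, as.character(pop$unit_id))[
    as.character(unit_ids)]
  tab <- data.frame(unit_id = unit_ids,
                    response = log(as.numeric(counts) / as.numeric(land_px)))
  for (nm in names(covs)) {
    tab[[nm]] <- as.numeric(unit_mean(covs[[nm]], um)[as.character(unit_ids)])
  }
  keep <- is.finite(tab$response)
  excluded <- tab$unit_id[!keep]
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0) stop("all units have zero population", call. = FALSE)
  rownames(tab) <- NULL
  attr(tab, "excluded_units") <- excluded
  tab
}

# OOB-MSE-guided mtry search: start at floor(p/3), double/halve while the
# improvement exceeds 5%.
.tune_mtry <- function(x, y, n_trees, seed, step_factor = 2, improve = 0.05) {
  p <- ncol(x)
  oob <- function(m) {
    set.seed(as.integer(seed))
    fit <- randomForest::randomForest(x = x, y = y, ntree = as.integer(n_trees),
                                      mtry = m)
    fit$mse[fit$ntree]
  }
  m0 <- max(1L, floor(p / 3))
  best_m <- m0
  best_err <- oob(m0)
  for (dir in c(1, -1)) {
    m <- m0
    err <- best_err
    repeat {
      m_new <- if (dir > 0) as.integer(ceiling(m * step_factor))
               else as.integer(floor(m / step_factor))
      if (m_new < 1L || m_new > p || m_new == m) break
      err_new <- oob(m_new)
      if ((err - err_new) / err <= improve) break
      m <- m_new; err <- err_new
      if (err < best_err) { best_err <- err; best_m <- m }
    }
  }
  best_m
}

# Unscaled permutation importance expressed as percent increase over the
# model's OOB MSE.
.per_inc_mse <- function(fit) {
  raw <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  mse <- fit$mse[fit$ntree]
  out <- 100 * raw / mse
  # a covariate with no usable OOB permutation evidence carries no importance
  out[!is.finite(out)] <- 0
  out
}

#' Iterative covariate elimination for the population forest
#'
#' Repeatedly fits a 500-tree regression random forest (mtry tuned by a
#' seeded OOB search) and removes every covariate whose permutation
#' importance (average percent increase in OOB MSE, `Per.Inc.MSE`) is less
#' than or equal to zero, until no covariate is dropped or only
#' `min_retained` remain (at which point the top `min_retained` are kept).
#'
#' @param table training table from [build_training_table()].
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @param min_retained floor on the number of retained covariates.
#' @param tune_mtry tune mtry by OOB search (`TRUE`) or use the
#'   `floor(p/3)` default.
#' @param keep covariate names exempt from elimination (e.g. the settlement
#'   representations that are always included in production models); they
#'   remain in the model regardless of their importance.
#' @return list with `model` (the final `randomForest` fit), `retained`
#'   (covariate names), `importances` (named Per.Inc.MSE vector), `mtry`.
#' @export
select_covariates <- function(table, n_trees = 500L, seed = 1L,
                              min_retained = 3L, tune_mtry = TRUE,
                              keep = character(0)) {
  covs <- setdiff(names(table), c("unit_id", "response"))
  if (length(covs) < 2) stop("need at least 2 covariates", call. = FALSE)
  if (length(covs) < min_retained) {
    stop("fewer than `min_retained` covariates supplied", call. = FALSE)
  }
  keep <- intersect(keep, covs)
  y <- table$response
  round <- 0L
  repeat {
    round <- round + 1L
    x <- table[, covs, drop = FALSE]
    m <- if (tune_mtry && length(covs) > 1) {
      .tune_mtry(x, y, n_trees, seed)
    } else {
      max(1L, floor(length(covs) / 3))
    }
    # a fresh sub-stream per elimination round: re-tests of surviving
    # covariates are not tied to the first round's forest randomness
    set.seed(as.integer((as.numeric(seed) * 31 + round) %% 2147483629))
    fit <- randomForest::randomForest(x = x, y = y, ntree = as.integer(n_trees),
                                      mtry = m, importance = TRUE)
    imp <- .per_inc_mse(fit)
    drop <- setdiff(names(imp)[imp <= 0], keep)
    if (length(drop) == 0) break
    remaining <- setdiff(covs, drop)
    if (length(remaining) < min_retained) {
      covs <- union(names(sort(imp, decreasing = TRUE))[seq_len(min_retained)],
                    keep)
      x <- table[, covs, drop = FALSE]
      set.seed(as.integer(seed))
      fit <- randomForest::randomForest(x = x, y = y,
                                        ntree = as.integer(n_trees),
                                        mtry = max(1L, floor(length(covs) / 3)),
                                        importance = TRUE)
      imp <- .per_inc_mse(fit)
      m <- fit$mtry
      break
    }
    covs <- remaining
  }
  list(model = fit, retained = covs, importances = imp, mtry = m)
}

#' Predict the pixel-level population density surface
#'
#' Applies the unit-trained forest to pixel-level covariates and
#' back-transforms from the log scale; water pixels get weight 0. The
#' absolute scale is irrelevant — the dasymetric renormalisation only uses
#' these values as unit-relative weights.
#'
#' @param model output of [select_covariates()] (or a `randomForest` fit
#'   plus a `retained` character vector).
#' @param cov_stack named list of covariate matrices (must cover the
#'   retained covariates).
#' @param water_mask binary matrix; 1 = water.
#' @return numeric matrix of nonnegative weights.
#' @export
predict_density_surface <- function(model, cov_stack, water_mask) {
  fit <- model$model
  retained <- model$retained
  missing <- setdiff(retained, names(cov_stack))
  if (length(missing) > 0) {
    stop("covariate stack is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nr <- nrow(water_mask); nc <- ncol(water_mask)
  land_idx <- which(water_mask == 0)
  newdata <- data.frame(row.names = seq_along(land_idx))
  for (nm in retained) newdata[[nm]] <- cov_stack[[nm]][land_idx]
  pred <- stats::predict(fit, newdata)
  out <- matrix(0, nr, nc)
  out[land_idx] <- exp(as.numeric(pred))
  out
}

#' Dasymetric redistribution of unit counts over a weight surface
#'
#' Allocates each unit's population count to its pixels proportionally to
#' the weight surface: `value = count * w / sum(w)` within the unit, so the
#' pixel values in every unit sum back to the unit count exactly. A unit
#' whose weights are all zero falls back to a uniform distribution over its
#' pixels (reported via a message).
#'
#' @param weights nonnegative numeric matrix.
#' @param unit_map integer matrix of unit labels, `NA` outside units.
#' @param counts data.frame with `unit_id`, `population` for one year.
#' @return numeric matrix of pixel-level population.
#' @export
dasymetric_redistribute <- function(weights, unit_map, counts) {
  .assert_grid(weights); .assert_grid(unit_map)
  .assert_congruent(weights, unit_map, "weights", "unit_map")
  out <- matrix(0, nrow(weights), ncol(weights))
  for (i in seq_len(nrow(counts))) {
    u <- counts$unit_id[i]
    cnt <- counts$population[i]
    sel <- which(!is.na(unit_map) & unit_map == u)
    if (length(sel) == 0) {
      if (cnt > 0) stop("populated unit ", u, " has no pixels", call. = FALSE)
      next
    }
    w <- weights[sel]
    s <- sum(w)
    if (s <= 0) {
      if (cnt > 0) {
        message("unit ", u, " has all-zero weights; falling back to uniform")
      }
      out[sel] <- cnt / length(sel)
    } else {
      out[sel] <- cnt * w / s
    }
  }
  out
}

#' Extract per-covariate permutation importances from a fitted model
#'
#' One record per retained covariate: the average percent increase in
#' out-of-bag MSE when that covariate is permuted (`Per.Inc.MSE`), tagged
#' with the country and year of the model.
#'
#' @param model output of [select_covariates()].
#' @param country_id country identifier.
#' @param year model year.
#' @return data.frame with columns `country_id`, `year`, `covariate`,
#'   `per_inc_mse`.
#' @export
extract_importances <- function(model, country_id, year) {
  imp <- model$importances[model$retained]
  data.frame(country_id = country_id, year = year,
             covariate = names(imp), per_inc_mse = as.numeric(imp),
             row.names = NULL)
}

#' Run one year's dasymetric population model
#'
#' Builds the unit training table, runs covariate elimination, predicts the
#' pixel weight surface, and redistributes the year's unit counts.
#'
#' @param bundle a `scenario_bundle`.
#' @param bs_grid the year's BS extents.
#' @param year integer year.
#' @param country_id label recorded on the importance records.
#' @param n_trees,seed,min_retained,tune_mtry,keep forwarded to
#'   [select_covariates()]; by default the three settlement representations
#'   (annual, historical t0, coarse annual) are always included, as in the
#'   production population models.
#' @return list with `surface` (pixel population matrix), `importances`
#'   (data.frame), `retained`, `mtry`, `model`.
#' @export
disaggregate_population <- function(bundle, bs_grid, year, country_id = 1L,
                                    n_trees = 500L, seed = 1L,
                                    min_retained = 3L, tune_mtry = TRUE,
                                    keep = c("bs_dte_annual", "bs_dte_t0",
                                             "bs_dte_coarse")) {
  tab <- build_training_table(bundle, bs_grid, year)
  sel <- select_covariates(tab, n_trees = n_trees, seed = seed,
                           min_retained = min_retained, tune_mtry = tune_mtry,
                           keep = keep)
  covs <- population_covariates(bundle, bs_grid, year)
  wsurf <- predict_density_surface(sel, covs, bundle$water_mask)
  counts <- bundle$population[bundle$population$year == year, , drop = FALSE]
  surface <- dasymetric_redistribute(wsurf, bundle$unit_map, counts)
  list(surface = surface,
       importances = extract_importances(sel, country_id, year),
       retained = sel$retained, mtry = sel$mtry, model = sel)
}
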