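#' Fit the transition-probability random forest
#'
#' Trains a classification random forest on a pixel sample labelled 1 if the
#' pixel transitioned from non-BS to BS between the observed epochs and 0 if
#' it stayed non-BS; the class-vote fraction is used as the period-level
#' transition probability.
#'
#' @param table data.frame with a binary `label` column and numeric covariate
#'   columns (no missing values).
#' @param n_trees number of trees.
#' @param seed integer seed for reproducibility.
#' @return object of class `transition_rf`.
#' @export
fit_transition_rf <- function(table, n_trees = 500L, seed = 1L) {
  if (!"label" %in% names(table)) stop("`table` must have a `label` column", call. = FALSE)
  if (anyNA(table)) stop("`table` must not contain missing values", call. = FALSE)
  if (length(unique(table$label)) < 2) {
    stop("training table is single-class (degenerate unit): both transition ",
         "outcomes must be present", call. = FALSE)
  }
  covs <- setdiff(names(table), "label")
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x = table[, covs, drop = FALSE],
    y = factor(table$label, levels = c(0, 1)),
    ntree = as.integer(n_trees))
  structure(list(fit = fit, covariates = covs), class = "transition_rf")
}

#' @rdname fit_transition_rf
#' @param object a `transition_rf`.
#' @param newdata data.frame of covariates.
#' @param ... unused.
#' @return numeric vector of transition probabilities in `[0, 1]`.
#' @export
predict.transition_rf <- function(object, newdata, ...) {
  missing <- setdiff(object$covariates, names(newdata))
  if (length(missing) > 0) {
    stop("missing covariates: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- stats::predict(object$fit, newdata[, object$covariates, drop = FALSE],
                      type = "prob")
  as.numeric(p[, "1"])
}

#' Year-specific transition probability surface
#'
#' Multiplies the period-level RF transition probabilities by the year's LAN
#' weights on the remaining candidate pixels; everything off the candidate
#' set is 0.
#'
#' @param period_prob numeric matrix of period transition probabilities.
#' @param lan_w numeric matrix of LAN weights in `[0, 1]`.
#' @param candidate_mask logical/binary matrix of pixels still available for
#'   allocation.
#' @return numeric matrix in `[0, 1]`.
#' @export
annual_probability <- function(period_prob, lan_w, candidate_mask) {
  .assert_grid(period_prob); .assert_grid(lan_w)
  .assert_congruent(period_prob, lan_w, "period_prob", "lan_w")
  .assert_congruent(period_prob, candidate_mask, "period_prob", "candidate_mask")
  out <- period_prob * lan_w
  out[!(candidate_mask == 1)] <- 0
  out
}

#' Allocate one year's transition demand within units
#'
#' For each unit, selects the `n_transitions` candidate pixels with the
#' highest annual probability (exact top-k; ties broken by a seeded shuffle
#' so equal-probability candidates are chosen reproducibly but without
#' positional bias). If a unit's demand exceeds its remaining candidates,
#' all candidates are taken and the shortfall is reported for carry-over.
#'
#' @param surface numeric matrix of annual probabilities.
#' @param candidate_mask logical/binary matrix of available pixels.
#' @param unit_map integer matrix of unit labels.
#' @param demand data.frame with columns `unit_id`, `n_transitions` for one
#'   year.
#' @param seed integer seed for tie-breaking.
#' @return list with `selected` (binary matrix of newly transitioned pixels)
#'   and `shortfall` (named vector of unmet demand per unit).
#' @export
allocate_year <- function(surface, candidate_mask, unit_map, demand, seed = 1L) {
  .assert_grid(surface)
  set.seed(as.integer(seed))
  selected <- matrix(0, nrow(surface), ncol(surface))
  shortfall <- stats::setNames(integer(nrow(demand)), as.character(demand$unit_id))
  for (i in seq_len(nrow(demand))) {
    u <- demand$unit_id[i]
    k <- demand$n_transitions[i]
    if (k <= 0) next
    cand <- which(candidate_mask == 1 & !is.na(unit_map) & unit_map == u)
    if (length(cand) == 0) {
      shortfall[i] <- k
      next
    }
    if (k >= length(cand)) {
      selected[cand] <- 1
      shortfall[i] <- k - length(cand)
      next
    }
    p <- surface[cand]
    shuffle <- sample.int(length(cand))
    ord <- order(-p, shuffle)
    selected[cand[ord[seq_len(k)]]] <- 1
  }
  list(selected = selected, shortfall = shortfall)
}

#' Interpolate annual built-settlement extents between two observed epochs
#'
#' Runs the full interpolation: demand quantification (growth curve +
#' density spline + largest-remainder apportionment of each unit's observed
#' period transition count), a transition random forest trained on all
#' transitioned pixels plus an equal-size seeded sample of persistent non-BS
#' pixels, LAN-modulated year-specific probability surfaces, and iterative
#' per-unit top-k allocation. Transitions are only ever allocated to pixels
#' observed to have transitioned over the whole period, so the series starts
#' at the t0 extents, ends bitwise at the t1 extents, and is pixelwise
#' monotone.
#'
#' @param bundle a `scenario_bundle`.
#' @param curve demand interpolation variant, `"logistic"` or
#'   `"exponential"`.
#' @param n_trees trees in the transition forest.
#' @param seed integer seed (forest, training sample, tie-breaks).
#' @return named list of binary matrices, one per year including both
#'   epochs, with attributes `demand` (the per-unit-year transition counts)
#'   and `allocated` (per-year totals actually placed).
#' @export
run_bsgmi <- function(bundle, curve = c("logistic", "exponential"),
                      n_trees = 500L, seed = 1L) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  curve <- match.arg(curve)
  years <- bundle$years
  bs0 <- bundle$observed_bs_t0
  bs1 <- bundle$observed_bs_t1
  if (any(bs0 == 1 & bs1 == 0)) {
    stop("observed t0 extents are not a subset of t1 extents", call. = FALSE)
  }
  um <- bundle$unit_map
  land <- bundle$water_mask == 0
  transitioned <- land & bs0 == 0 & bs1 == 1

  totals <- table(factor(um[transitioned & !is.na(um)],
                         levels = sort(unique(um[!is.na(um)]))))
  totals <- stats::setNames(as.integer(totals), names(totals))
  demand <- bsgmi_demand(bundle$epoch_obs, years, totals, curve = curve)

  covs <- transition_covariates(bundle)
  cand_idx <- which(transitioned)

  series <- stats::setNames(vector("list", length(years)), as.character(years))
  series[[1]] <- bs0
  allocated <- stats::setNames(integer(length(years) - 1), as.character(years[-1]))

  if (length(cand_idx) == 0) {
    for (t in seq_along(years)[-1]) series[[t]] <- bs0
    attr(series, "demand") <- demand
    attr(series, "allocated") <- allocated
    return(series)
  }

  # training sample: all transitioned pixels + equal-size sample of
  # persistent non-BS land pixels
  .substream(seed, .STREAM["rf_transition"])
  persistent <- which(land & bs1 == 0)
  n_neg <- min(length(persistent), length(cand_idx))
  if (n_neg == 0) {
    stop("no persistent non-BS pixels: transition model is single-class",
         call. = FALSE)
  }
  neg_idx <- if (length(persistent) > n_neg) sample(persistent, n_neg) else persistent
  train_idx <- c(cand_idx, neg_idx)
  train <- data.frame(label = rep(c(1, 0), c(length(cand_idx), length(neg_idx))))
  for (nm in names(covs)) train[[nm]] <- covs[[nm]][train_idx]
  rf <- fit_transition_rf(train, n_trees = n_trees, seed = seed)

  period_prob <- matrix(0, nrow(bs0), ncol(bs0))
  cand_df <- data.frame(row.names = seq_along(cand_idx))
  for (nm in names(covs)) cand_df[[nm]] <- covs[[nm]][cand_idx]
  period_prob[cand_idx] <- predict(rf, cand_df)

  candidate_mask <- matrix(0, nrow(bs0), ncol(bs0))
  candidate_mask[cand_idx] <- 1
  bs <- bs0
  carry <- stats::setNames(rep(0L, length(totals)), names(totals))
  for (t in seq_along(years)[-1]) {
    yr <- years[t]
    lw <- lan_weight(bundle$lan_series[[as.character(yr)]],
                     bundle$lan_series[[as.character(years[t - 1])]], um)
    surf <- annual_probability(period_prob, lw, candidate_mask)
    dem_t <- demand[demand$year == yr, c("unit_id", "n_transitions"), drop = FALSE]
    dem_t$n_transitions <- dem_t$n_transitions +
      carry[as.character(dem_t$unit_id)]
    alloc <- allocate_year(surf, candidate_mask, um, dem_t,
                           seed = (as.numeric(seed) * 131 + t) %% 2147483629)
    if (any(alloc$shortfall > 0)) {
      message("allocation shortfall carried over in year ", yr, ": ",
              sum(alloc$shortfall), " transition(s)")
    }
    carry <- stats::setNames(rep(0L, length(totals)), names(totals))
    carry[names(alloc$shortfall)] <- alloc$shortfall
    bs <- pmax(bs, alloc$selected)
    allocated[as.character(yr)] <- sum(alloc$selected)
    candidate_mask[alloc$selected == 1] <- 0
    series[[t]] <- bs
  }
  attr(series, "demand") <- demand
  attr(series, "allocated") <- allocated
  series
}

#' Pixel accuracy of an interpolated extent series against withheld truth
#'
#' Fraction of pixels whose BS/non-BS state matches the true extents, per
#' interim year (epochs agree by construction and are excluded).
#'
#' @param series named list of binary matrices (output of [run_bsgmi()]).
#' @param truth a `scenario_truth`.
#' @return named numeric vector of per-interim-year accuracies in `[0, 1]`.
#' @export
bsgmi_accuracy <- function(series, truth) {
  stopifnot(inherits(truth, "scenario_truth"))
  yrs <- names(series)
  interim <- yrs[-c(1, length(yrs))]
  vapply(interim, function(y) {
    mean(series[[y]] == truth$true_bs_series[[y]])
  }, numeric(1))
}
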