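#' Weighted Importance Rank (WIR) of a model's covariates
#'
#' Ranks a single model's covariates by descending permutation importance
#' (ties get average ranks) and divides the rank by the number of covariates
#' in the model. WIR lies in `(0, 1]`: the least important covariate has WIR
#' exactly 1 and the most important has WIR `1/n` — being rank-based, WIR is
#' comparable across models with different covariate sets and invariant to
#' monotone transforms of the raw importances.
#'
#' @param records data.frame of one model's importance records with columns
#'   `covariate` and `per_inc_mse` (optionally `country_id`, `year`, carried
#'   through).
#' @return the input data.frame with added columns `rank`, `n_covariates`,
#'   `wir`.
#' @export
compute_wir <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no importance records supplied", call. = FALSE)
  }
  if (!all(c("covariate", "per_inc_mse") %in% names(records))) {
    stop("`records` needs columns `covariate` and `per_inc_mse`", call. = FALSE)
  }
  out <- records
  out$rank <- rank(-out$per_inc_mse, ties.method = "average")
  out$n_covariates <- nrow(out)
  out$wir <- out$rank / out$n_covariates
  out
}

#' WIR for a table of importance records spanning many models
#'
#' Applies [compute_wir()] within each (country, year) model.
#'
#' @param records data.frame with columns `country_id`, `year`, `covariate`,
#'   `per_inc_mse`.
#' @return data.frame of WIR records across all models.
#' @export
compute_wir_table <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no importance records supplied", call. = FALSE)
  }
  key <- interaction(records$country_id, records$year, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), compute_wir))
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with `k - 1` degrees of freedom and a
#' chi-square upper-tail p-value.
#'
#' @param values numeric vector.
#' @param groups group labels, same length as `values`; at least two
#'   nonempty groups.
#' @return list with elements `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(values)) == 1) {
    stop("all values identical: Kruskal-Wallis statistic undefined", call. = FALSE)
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Dunn post hoc pairwise comparisons
#'
#' Pairwise z statistics on mean-rank differences with tie correction,
#' Holm-adjusted across all pairs. Runs unconditionally; the
#' `"posthoc_valid"` attribute records whether the Kruskal-Wallis omnibus
#' was significant at `alpha`, matching the convention of only interpreting
#' post hoc tests after a significant omnibus.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param alpha omnibus significance level used for the validity flag.
#' @return data.frame with columns `group1`, `group2`, `z`, `p`, `p_holm`.
#' @export
dunn_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(factor(groups))
  lev <- levels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 1)) stop("every group needs >= 1 observation", call. = FALSE)
  N <- length(values)
  r <- rank(values, ties.method = "average")
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[i] <- if (se > 0) (mean_r[[a]] - mean_r[[b]]) / se else 0
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = z, p = p, p_holm = holm_adjust(p))
  omni <- tryCatch(kruskal_wallis(values, groups),
                   error = function(e) list(p = NA_real_))
  attr(out, "posthoc_valid") <- isTRUE(omni$p < alpha)
  out
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether the median of `diffs` differs from `mu`. Zeros (after the
#' mu shift) are dropped; ties in the absolute values get average ranks. For
#' `n <= exact_limit` the two-sided p-value comes from exact enumeration of
#' the null distribution of the signed-rank statistic (computed by dynamic
#' programming over the tied rank multiset, equivalent to enumerating all
#' 2^n sign assignments); above that, a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param diffs numeric vector of differences.
#' @param mu null median.
#' @param exact_limit largest n for which the exact distribution is used.
#' @return list with `V` (signed-rank statistic), `p` (two-sided), `n`
#'   (nonzero differences used), `exact` (logical).
#' @export
wilcoxon_one_sample <- function(diffs, mu = 0, exact_limit = 25L) {
  d <- diffs - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero: no information", call. = FALSE)
  r <- rank(abs(d), ties.method = "average")
  V <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))  # half-integer ranks made integral
    S <- sum(r2)
    w <- numeric(S + 1)
    w[1] <- 1
    for (a in r2) {
      shifted <- c(numeric(a), w[seq_len(S + 1 - a)])
      w <- w + shifted
    }
    tot <- sum(w)  # 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(w[seq_len(v2 + 1)]) / tot
    p_ge <- sum(w[(v2 + 1):(S + 1)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(V = V, p = p, n = n, exact = TRUE))
  }
  mu_v <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu_v - sign(V - mu_v) * 0.5) / sqrt(sig2)
  list(V = V, p = min(1, 2 * stats::pnorm(-abs(z))), n = n, exact = FALSE)
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorts p-values ascending, multiplies the i-th by `m - i + 1`, enforces
#' monotonicity with a running maximum, caps at 1, and restores the input
#' order. Controls the family-wise error rate.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  ord <- order(pvals)
  adj <- pvals[ord] * (m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Per-model WIR differences for a covariate contrast
#'
#' For every model (country-year) containing both covariates, computes
#' `WIR(first) - WIR(second)`. Positive differences mean the first covariate
#' of the pair was *less* important than the second (higher WIR = lower
#' importance); the sign convention is recorded in the
#' `"sign_convention"` attribute. Models missing either covariate are
#' skipped and counted in the `"skipped_models"` attribute.
#'
#' @param wir data.frame of WIR records (from [compute_wir_table()]).
#' @param contrast character vector of two covariate names,
#'   `c(first, second)`.
#' @param regions optional data.frame with `country_id`, `region` used to
#'   label rows.
#' @return data.frame with `country_id`, `year`, `region`, `diff`.
#' @export
wir_difference_table <- function(wir, contrast, regions = NULL) {
  stopifnot(length(contrast) == 2)
  key <- interaction(wir$country_id, wir$year, drop = TRUE)
  rows <- lapply(split(wir, key), function(m) {
    w1 <- m$wir[m$covariate == contrast[1]]
    w2 <- m$wir[m$covariate == contrast[2]]
    if (length(w1) != 1 || length(w2) != 1) return(NULL)
    data.frame(country_id = m$country_id[1], year = m$year[1],
               diff = w1 - w2)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop("contrast covariates (", paste(contrast, collapse = ", "),
         ") absent from every model", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$region <- if (!is.null(regions)) {
    as.character(regions$region[match(out$country_id, regions$country_id)])
  } else {
    "all"
  }
  rownames(out) <- NULL
  attr(out, "sign_convention") <-
    "positive = first covariate less important than second"
  attr(out, "skipped_models") <- skipped
  attr(out, "contrast") <- contrast
  out
}

#' Test WIR-difference contrasts against a zero median
#'
#' For each contrast and region, a one-sample Wilcoxon signed-rank test of
#' the per-model WIR differences against zero, with Holm correction across
#' all contrast-region combinations.
#'
#' @param wir data.frame of WIR records.
#' @param contrasts list of 2-element character vectors.
#' @param regions optional data.frame with `country_id`, `region`.
#' @param alpha significance level recorded alongside results.
#' @return data.frame with `contrast`, `region`, `n`, `median_diff`, `V`,
#'   `p`, `p_holm`, `significant`.
#' @export
wir_contrast_tests <- function(wir, contrasts, regions = NULL, alpha = 0.05) {
  rows <- list()
  for (ct in contrasts) {
    tab <- wir_difference_table(wir, ct, regions)
    for (reg in sort(unique(tab$region))) {
      d <- tab$diff[tab$region == reg]
      res <- tryCatch(wilcoxon_one_sample(d),
                      error = function(e) list(V = NA_real_, p = NA_real_))
      rows[[length(rows) + 1]] <- data.frame(
        contrast = paste(ct[1], "minus", ct[2]), region = reg,
        n = length(d), median_diff = stats::median(d),
        V = res$V, p = res$p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  ok <- !is.na(out$p)
  out$p_holm[ok] <- holm_adjust(out$p[ok])
  out$significant <- !is.na(out$p_holm) & out$p_holm < alpha
  rownames(out) <- NULL
  out
}

#' Boxplot summary statistics by group
#'
#' Five-number-style summaries matching the usual boxplot convention: median
#' splitting the interquartile range, whiskers at the most extreme data
#' within 1.5 x IQR of the quartiles. Quartiles use linear interpolation of
#' order statistics (type 7) so summaries are bit-reproducible.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return data.frame with `group`, `n`, `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high`.
#' @export
summarize_boxplots <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (length(values) == 0) stop("no values supplied", call. = FALSE)
  out <- lapply(levels(groups), function(g) {
    x <- values[groups == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(group = g, n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               iqr = iqr,
               whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_high = max(x[x <= q[3] + 1.5 * iqr]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
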