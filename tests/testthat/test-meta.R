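test_that("WIR ranks descending importance and assigns 1 to the least important", {
  recs <- data.frame(covariate = c("a", "b", "c", "d"),
                     per_inc_mse = c(5, 2, 1, 0.5))
  w <- compute_wir(recs)
  expect_equal(w$wir, c(0.25, 0.5, 0.75, 1))
  expect_equal(w$wir[which.min(w$per_inc_mse)], 1)
  top10 <- data.frame(covariate = letters[1:10], per_inc_mse = 10:1)
  expect_equal(compute_wir(top10)$wir[1], 0.1)
  # ties share average ranks
  tied <- data.frame(covariate = c("a", "b", "c", "d"),
                     per_inc_mse = c(5, 5, 2, 1))
  expect_equal(compute_wir(tied)$wir[1:2], c(0.375, 0.375))
  expect_error(compute_wir(data.frame()), "no importance")
})

test_that("WIR is invariant under monotone transforms of the importances", {
  set.seed(10)
  for (i in 1:10) {
    recs <- data.frame(covariate = letters[1:7], per_inc_mse = rnorm(7))
    a <- compute_wir(recs)$wir
    recs2 <- recs
    recs2$per_inc_mse <- exp(2 * recs$per_inc_mse + 3)
    expect_equal(compute_wir(recs2)$wir, a)
  }
})

test_that("Kruskal-Wallis matches hand computation and the first-principles oracle", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 12 / 42 * 13.5, tolerance = 1e-9)  # 3.857143
  expect_equal(kw$df, 1)
  kw2 <- kruskal_wallis(c(1, 3, 2, 4), c("a", "a", "b", "b"))
  expect_equal(kw2$H, 0.6, tolerance = 1e-9)
  kw11 <- kruskal_wallis(seq_len(33), rep(1:11, each = 3))
  expect_equal(kw11$df, 10)
  expect_error(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3)), "identical")
  set.seed(11)
  for (i in 1:8) {
    v <- sample(1:5, 8, replace = TRUE)  # small n, with ties
    g <- rep(c("a", "b"), each = 4)
    if (length(unique(v)) == 1) next
    expect_equal(kruskal_wallis(v, g)$H, bf_kw_H(v, g), tolerance = 1e-9)
  }
})

test_that("Dunn post hoc compares mean ranks with Holm-adjusted p-values", {
  d2 <- dunn_posthoc(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(nrow(d2), 1)
  expect_equal(d2$p, d2$p_holm)  # single comparison: Holm is identity
  di <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(di$z, 0)
  expect_equal(di$p, 1)
  set.seed(12)
  d3 <- dunn_posthoc(rnorm(15), rep(c("a", "b", "c"), each = 5))
  expect_equal(nrow(d3), 3)
  ord <- order(d3$p)
  expect_true(all(diff(d3$p_holm[ord]) >= -1e-12))  # step-down monotone
  expect_true(all(d3$p_holm >= d3$p - 1e-12))
})

test_that("one-sample Wilcoxon matches exact enumeration", {
  sym <- wilcoxon_one_sample(c(1, -1, 2, -2))
  expect_equal(sym$p, 1)
  pos <- wilcoxon_one_sample(c(1, 2, 3, 4, 5))
  expect_equal(pos$V, 15)
  expect_equal(pos$p, 0.0625)  # 2 / 2^5
  # shift invariance
  x <- c(0.2, 1.4, -0.7, 2.2, 0.9)
  expect_equal(wilcoxon_one_sample(x, mu = 0.5)$p,
               wilcoxon_one_sample(x - 0.5)$p)
  expect_error(wilcoxon_one_sample(c(0, 0)), "zero")
  set.seed(13)
  for (i in 1:12) {
    n <- sample(3:8, 1)
    d <- round(rnorm(n), 1)
    d[d == 0] <- 0.05
    got <- wilcoxon_one_sample(d)
    expect_true(got$exact)
    expect_equal(got$p, bf_wilcoxon_p(d), tolerance = 1e-12)
  }
  # large-n path: normal approximation close to the exact answer
  set.seed(14)
  d <- rnorm(30) + 0.3
  approx <- wilcoxon_one_sample(d, exact_limit = 25)
  exact <- wilcoxon_one_sample(d, exact_limit = 30)
  expect_false(approx$exact)
  expect_equal(approx$p, exact$p, tolerance = 0.02)
})

test_that("Holm adjustment is the step-down procedure", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  set.seed(15)
  for (i in 1:10) {
    p <- runif(sample(1:8, 1))
    got <- holm_adjust(p)
    expect_equal(got, p.adjust(p, method = "holm"))
    expect_true(all(got <= 1 & got >= p))
  }
})

test_that("WIR difference tables follow the stated sign convention", {
  recs <- rbind(
    data.frame(country_id = 1, year = 2001,
               covariate = c("hist", "annual", "x"),
               per_inc_mse = c(1, 5, 3)),
    data.frame(country_id = 1, year = 2002,
               covariate = c("hist", "annual", "x"),
               per_inc_mse = c(2, 2, 5)),
    data.frame(country_id = 2, year = 2001,
               covariate = c("hist", "x"),  # missing "annual": skipped
               per_inc_mse = c(4, 1)))
  w <- compute_wir_table(recs)
  tab <- wir_difference_table(w, c("hist", "annual"))
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "skipped_models"), 1)
  # model 1/2001: hist rank 3 (wir 1), annual rank 1 (wir 1/3) -> diff +2/3,
  # positive because hist is less important
  expect_equal(tab$diff[tab$year == 2001], 2 / 3, tolerance = 1e-12)
  expect_equal(tab$diff[tab$year == 2002], 0)  # tied WIRs
  expect_match(attr(tab, "sign_convention"), "less important")
  expect_error(wir_difference_table(w, c("nope1", "nope2")), "absent")

  tests <- wir_contrast_tests(w, list(c("hist", "annual")))
  expect_equal(nrow(tests), 1)
  expect_equal(tests$n, 2)
})

test_that("boxplot summaries match the quartile and whisker conventions", {
  s <- summarize_boxplots(c(1, 2, 3, 4, 5), rep("g", 5))
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)
  one <- summarize_boxplots(0.1, "g")
  expect_equal(one$median, 0.1)
  expect_equal(one$iqr, 0)
  set.seed(16)
  x <- rnorm(40)
  g <- rep(c("a", "b"), 20)
  s2 <- summarize_boxplots(x, g)
  for (i in 1:2) {
    xi <- x[g == s2$group[i]]
    expect_gte(s2$whisker_low[i], min(xi))
    expect_lte(s2$whisker_high[i], max(xi))
  }
})
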