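test_that("generators are deterministic in (config, seed) and partition land", {
  cfg <- scenario_config(rows = 32, cols = 32, n_units = 4, years = 2000:2004,
                         seed = 42)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$bundle$observed_bs_t1, b$bundle$observed_bs_t1)
  expect_identical(a$bundle$lan_series, b$bundle$lan_series)
  expect_identical(a$bundle$population, b$bundle$population)
  expect_identical(a$truth$true_bs_series, b$truth$true_bs_series)

  ls <- generate_landscape(cfg)
  land_n <- sum(ls$water_mask == 0)
  counts <- table(ls$unit_map[!is.na(ls$unit_map)])
  expect_length(counts, 4)
  expect_true(all(counts >= 1))
  expect_equal(sum(counts), land_n)

  ls1 <- generate_landscape(scenario_config(rows = 16, cols = 16, n_units = 1,
                                            years = 2000:2002, seed = 5))
  expect_equal(sort(unique(ls1$unit_map[!is.na(ls1$unit_map)])), 1L)
  expect_error(generate_landscape(scenario_config(rows = 4, cols = 4,
                                                  n_units = 16,
                                                  years = 2000:2002,
                                                  water_frac = 0.3)),
               "configuration error")
})

test_that("settlement growth is monotone, anchored at t0, and zero-growth is static", {
  cfg0 <- scenario_config(rows = 24, cols = 24, n_units = 3, years = 2000:2004,
                          seed = 7, growth_rate = 0)
  ls <- generate_landscape(cfg0)
  tr <- simulate_settlement_growth(ls, cfg0)
  for (y in names(tr$true_bs_series)) {
    expect_identical(tr$true_bs_series[[y]], tr$true_bs_series[[1]])
  }

  cfg <- scenario_config(rows = 24, cols = 24, n_units = 3, years = 2000:2006,
                         seed = 7, growth_rate = 0.1)
  ls <- generate_landscape(cfg)
  tr <- simulate_settlement_growth(ls, cfg)
  ser <- tr$true_bs_series
  for (t in 2:length(ser)) {
    expect_true(all(ser[[t]] >= ser[[t - 1]]))
  }
  # water never settled
  expect_true(all(ser[[length(ser)]][ls$water_mask == 1] == 0))
  # BS population series is positive where extents exist and monotone info
  expect_true(all(tr$bs_population_series$bs_population > 0))
})

test_that("per-year transition fraction matches growth_rate over many seeds", {
  rate <- 0.05
  fracs <- numeric(0)
  for (s in 1:100) {
    cfg <- scenario_config(rows = 20, cols = 20, n_units = 2,
                           years = 2000:2002, seed = s, growth_rate = rate,
                           water_frac = 0)
    ls <- generate_landscape(cfg)
    tr <- simulate_settlement_growth(ls, cfg)
    for (t in 2:3) {
      prev <- tr$true_bs_series[[t - 1]]
      curr <- tr$true_bs_series[[t]]
      n_cand <- sum(prev == 0)
      fracs <- c(fracs, sum(curr == 1 & prev == 0) / n_cand)
    }
  }
  se <- sqrt(rate * (1 - rate) / (length(fracs) * 350))
  expect_lt(abs(mean(fracs) - rate), max(5 * se, 0.005))
})

test_that("coarse annual product is a block majority vote with ties voting 0", {
  m <- matrix(1, 4, 4)
  expect_identical(emulate_coarse_annual_extents(m, 2), m)
  m3 <- matrix(0, 3, 3)
  m3[c(1, 2, 4, 5)] <- 1  # 4 of 9: majority fails
  expect_identical(emulate_coarse_annual_extents(m3, 3), matrix(0, 3, 3))
  m3[7] <- 1              # 5 of 9: majority passes
  expect_identical(emulate_coarse_annual_extents(m3, 3), matrix(1, 3, 3))
  # ties (2 of 4) vote 0
  m2 <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_identical(emulate_coarse_annual_extents(m2, 2), matrix(0, 2, 2))
  set.seed(3)
  r <- matrix(rbinom(49, 1, 0.5), 7, 7)  # 7 not divisible by 3: edge blocks truncate
  expect_identical(emulate_coarse_annual_extents(r, 1), r)
  out <- emulate_coarse_annual_extents(r, 3)
  expect_true(all(out %in% c(0, 1)))
  expect_equal(out[7, 7], as.numeric(r[7, 7] == 1))  # 1x1 corner block
})

test_that("LAN tracks settlement density and is seed-reproducible", {
  cfg <- scenario_config(rows = 20, cols = 20, n_units = 2, years = 2000:2003,
                         seed = 9, lan_noise_sd = 0, growth_rate = 0)
  ls <- generate_landscape(cfg)
  tr <- simulate_settlement_growth(ls, cfg)
  # zero noise, no settlement -> constant baseline
  tr0 <- tr
  tr0$true_bs_series <- lapply(tr0$true_bs_series, function(x) x * 0)
  lan0 <- simulate_lan(tr0, cfg)
  expect_true(all(vapply(lan0, function(g) all(g == cfg$lan_baseline),
                         logical(1))))
  # transition year brightens the pixel in expectation
  diffs <- numeric(0)
  for (s in 1:30) {
    cfgs <- scenario_config(rows = 16, cols = 16, n_units = 2,
                            years = 2000:2002, seed = s, growth_rate = 0.1)
    lss <- generate_landscape(cfgs)
    trs <- simulate_settlement_growth(lss, cfgs)
    lans <- simulate_lan(trs, cfgs)
    new_px <- trs$true_bs_series[[2]] == 1 & trs$true_bs_series[[1]] == 0
    if (any(new_px)) {
      diffs <- c(diffs, mean(lans[[2]][new_px] - lans[[1]][new_px]))
    }
  }
  expect_gt(mean(diffs), 0)
  expect_identical(simulate_lan(tr, cfg), simulate_lan(tr, cfg))
})

test_that("population counts respond to settlement and are reproducible", {
  cfg <- scenario_config(rows = 24, cols = 24, n_units = 3, years = 2000:2004,
                         seed = 13)
  ls <- generate_landscape(cfg)
  tr <- simulate_settlement_growth(ls, cfg)
  p1 <- simulate_population(tr, ls, cfg)
  p2 <- simulate_population(tr, ls, cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$population >= 0))
  expect_equal(nrow(p1), 3 * 5)

  # settlement_effect = 0, no noise, no static effects -> density ~ area
  cfg0 <- scenario_config(rows = 24, cols = 24, n_units = 3, years = 2000:2004,
                          seed = 13, settlement_effect = 0, noise_sd = 0,
                          static_effects = c(elevation = 0, slope = 0,
                                             water_dst = 0, road_dst = 0,
                                             protected_dst = 0))
  p0 <- simulate_population(tr, ls, cfg0)
  px <- table(ls$unit_map[!is.na(ls$unit_map)])
  y0 <- p0[p0$year == 2000, ]
  expect_equal(y0$population, as.integer(round(as.numeric(px[as.character(y0$unit_id)]))))

  # growing settlement raises expected counts when the effect is positive
  first <- p1[p1$year == 2000, "population"]
  last <- p1[p1$year == 2004, "population"]
  expect_gt(sum(last), sum(first))
})

test_that("unit settlement share and density are positively rank-correlated", {
  hits <- 0
  n_rep <- 30
  statics <- c(elevation = -0.05, slope = 0, water_dst = 0, road_dst = -0.05,
               protected_dst = 0)
  for (s in 1:n_rep) {
    scn <- tiny_scenario(seed = 400 + s, n_units = 8, years = 2000:2006,
                         growth_rate = 0.08, settlement_effect = 6,
                         noise_sd = 0.05, static_effects = statics)
    b <- scn$bundle
    um <- b$unit_map
    px <- table(um[!is.na(um)])
    yr <- max(b$years)
    bs <- scn$truth$true_bs_series[[as.character(yr)]]
    prop <- tapply(bs[!is.na(um)], um[!is.na(um)], mean)
    cnt <- b$population[b$population$year == yr, ]
    dens <- cnt$population / as.numeric(px[as.character(cnt$unit_id)])
    rho <- cor(as.numeric(prop[as.character(cnt$unit_id)]), dens,
               method = "spearman")
    if (!is.na(rho) && rho > 0) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("bundle invariants hold: epoch nesting, water exclusion, epoch observations", {
  scn <- tiny_scenario(seed = 21, years = 2000:2005)
  b <- scn$bundle
  expect_true(all(b$observed_bs_t0 <= b$observed_bs_t1))
  expect_true(all(b$observed_bs_t1[b$water_mask == 1] == 0))
  expect_identical(b$observed_bs_t0, scn$truth$true_bs_series[["2000"]])
  expect_identical(b$observed_bs_t1, scn$truth$true_bs_series[["2005"]])
  expect_setequal(unique(b$epoch_obs$year), c(2000, 2005))
  expect_equal(nrow(b$epoch_obs), 2 * 4)
})
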