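# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation they check.

# all-pairs Euclidean distance to the nearest 1-pixel
bf_dte <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  ones <- which(mask == 1, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- sqrt(min((ones[, 1] - i)^2 + (ones[, 2] - j)^2))
    }
  }
  out
}

# disc enumeration for proportion-in-radius
bf_prop_radius <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      num <- 0; den <- 0
      for (a in seq_len(nr)) {
        for (b in seq_len(nc)) {
          if ((a - i)^2 + (b - j)^2 <= radius^2) {
            den <- den + 1
            num <- num + mask[a, b]
          }
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
bf_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# tie-corrected Kruskal-Wallis H from first principles
bf_kw_H <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(n_g * (rbar - (N + 1) / 2)^2)
  ties <- table(r)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# exhaustive best-sum top-k subset value
bf_topk_value <- function(probs, k) {
  max(combn(length(probs), k, function(ix) sum(probs[ix])))
}

# all compositions of `total` over k cells; minimal max |c - total*w|
bf_apportion_maxdev <- function(total, w) {
  k <- length(w)
  grid <- expand.grid(rep(list(0:total), k))
  grid <- grid[rowSums(grid) == total, , drop = FALSE]
  devs <- apply(grid, 1, function(cc) max(abs(cc - total * w)))
  min(devs)
}

# compact scenario used where full realism is not needed
tiny_scenario <- function(seed = 1, rows = 24, cols = 24, n_units = 4,
                          years = 2000:2004, ...) {
  simulate_scenario(scenario_config(rows = rows, cols = cols,
                                    n_units = n_units, years = years,
                                    seed = seed, ...))
}
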