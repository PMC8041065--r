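# Internal grid utilities: validation, seeded sub-streams, smooth random fields.
# Grids are plain numeric/logical matrices on a planar lattice with unit pixel
# spacing; row/col indices are the coordinate system (no projections).

.assert_grid <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x)) stop(sprintf("`%s` must be a matrix", name), call. = FALSE)
  invisible(x)
}

.assert_binary <- function(x, name = deparse(substitute(x))) {
  .assert_grid(x, name)
  v <- x[!is.na(x)]
  if (!all(v %in% c(0, 1))) {
    stop(sprintf("`%s` must be a binary (0/1) grid", name), call. = FALSE)
  }
  invisible(x)
}

.assert_congruent <- function(a, b, name_a = "a", name_b = "b") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("grids `%s` and `%s` have different dimensions", name_a, name_b),
         call. = FALSE)
  }
  invisible(NULL)
}

# One master seed; independent sub-streams per operation via fixed offsets so
# that e.g. regenerating the LAN series does not perturb the settlement draw.
.substream <- function(seed, offset) {
  set.seed(as.integer((as.numeric(seed) * 97 + offset) %% 2147483629))
}

.STREAM <- c(landscape = 11, growth = 23, lan = 37, population = 53,
             rf_transition = 67, allocation = 71, rf_population = 83,
             sampling = 89)

# Smooth Gaussian-ish random field: iid normal noise passed through `passes`
# rounds of a (2*half+1)-square moving average with edge truncation, then
# z-scored. Used for elevation, suitability and water surfaces.
.smooth_field <- function(rows, cols, half = 3L, passes = 3L) {
  f <- matrix(stats::rnorm(rows * cols), rows, cols)
  for (p in seq_len(passes)) {
    num <- matrix(0, rows, cols)
    den <- matrix(0, rows, cols)
    for (di in -half:half) {
      r_lo <- max(1L, 1L - di); r_hi <- min(rows, rows - di)
      if (r_lo > r_hi) next
      r_dst <- r_lo:r_hi
      r_src <- r_dst + di
      for (dj in -half:half) {
        c_lo <- max(1L, 1L - dj); c_hi <- min(cols, cols - dj)
        if (c_lo > c_hi) next
        c_dst <- c_lo:c_hi
        c_src <- c_dst + dj
        num[r_dst, c_dst] <- num[r_dst, c_dst] + f[r_src, c_src]
        den[r_dst, c_dst] <- den[r_dst, c_dst] + 1
      }
    }
    f <- num / den
  }
  s <- stats::sd(f)
  if (!is.finite(s) || s == 0) return(f * 0)  # degenerate tiny grids
  (f - mean(f)) / s
}

# row/col index helpers for a matrix laid out column-major
.pix_coords <- function(idx, rows) {
  cbind(row = ((idx - 1L) %% rows) + 1L, col = ((idx - 1L) %/% rows) + 1L)
}
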