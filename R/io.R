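#' Write a grid to an ESRI ASCII raster file
#'
#' Plain-text raster interchange format (`.asc`) readable by GDAL and
#' standard GIS tools; the planar pixel grid is written with cell size 1 and
#' origin at (0, 0). `NA` values are written as the nodata sentinel.
#'
#' @param grid numeric matrix (row 1 = top of the raster).
#' @param path output file path.
#' @param nodata nodata sentinel value.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  .assert_grid(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid)),
    paste("nrows", nrow(grid)),
    "xllcorner 0",
    "yllcorner 0",
    "cellsize 1",
    paste("NODATA_value", nodata)
  ), con)
  g <- grid
  g[is.na(g)] <- nodata
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a grid from an ESRI ASCII raster file
#'
#' @param path file written by [write_asc()] (or any ESRI ASCII grid).
#' @return numeric matrix with `NA` at nodata cells.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6)
  hdr <- lapply(strsplit(lines, "\\s+"), function(x) x)
  vals <- stats::setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                          tolower(vapply(hdr, `[`, "", 1)))
  g <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(g) <- NULL
  stopifnot(nrow(g) == vals[["nrows"]], ncol(g) == vals[["ncols"]])
  g[g == vals[["nodata_value"]]] <- NA
  g
}

#' Write a scenario bundle (and optionally its truth) to a directory
#'
#' Rasters go to `.asc` files, tables to CSV, and the configuration to YAML;
#' the withheld truth, when written, goes under a `truth/` subdirectory so
#' the observable inputs and the scoring data stay separate.
#'
#' @param scenario list with `bundle` and `truth` (from
#'   [simulate_scenario()]).
#' @param dir output directory (created if needed).
#' @param write_truth also write the withheld truth.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir, write_truth = TRUE) {
  bundle <- scenario$bundle
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  um <- bundle$unit_map
  write_asc(ifelse(is.na(um), NA, um), file.path(dir, "unit_map.asc"))
  write_asc(bundle$water_mask, file.path(dir, "water_mask.asc"))
  write_asc(bundle$observed_bs_t0, file.path(dir, "bs_t0.asc"))
  write_asc(bundle$observed_bs_t1, file.path(dir, "bs_t1.asc"))
  for (nm in names(bundle$static_covariates)) {
    write_asc(bundle$static_covariates[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  for (yr in names(bundle$lan_series)) {
    write_asc(bundle$lan_series[[yr]], file.path(dir, paste0("lan_", yr, ".asc")))
    write_asc(bundle$coarse_annual_bs[[yr]],
              file.path(dir, paste0("coarse_bs_", yr, ".asc")))
  }
  utils::write.csv(bundle$population, file.path(dir, "population.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$epoch_obs, file.path(dir, "epoch_obs.csv"),
                   row.names = FALSE)
  cfg <- bundle$config
  cfg_list <- unclass(cfg)
  cfg_list$static_effects <- as.list(cfg_list$static_effects)
  yaml::write_yaml(cfg_list, file.path(dir, "scenario.yaml"))
  if (write_truth && !is.null(scenario$truth)) {
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    for (yr in names(scenario$truth$true_bs_series)) {
      write_asc(scenario$truth$true_bs_series[[yr]],
                file.path(tdir, paste0("bs_", yr, ".asc")))
    }
    utils::write.csv(scenario$truth$bs_population_series,
                     file.path(tdir, "bs_population.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file written by [write_scenario()].
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  scenario_config(rows = cfg$rows, cols = cfg$cols, n_units = cfg$n_units,
                  years = cfg$years, seed = cfg$seed,
                  growth_rate = cfg$growth_rate,
                  settlement_effect = cfg$settlement_effect,
                  noise_sd = cfg$noise_sd, lan_noise_sd = cfg$lan_noise_sd,
                  coarse_factor = cfg$coarse_factor,
                  water_frac = cfg$water_frac,
                  proximity_scale = cfg$proximity_scale,
                  static_effects = unlist(cfg$static_effects),
                  lan_baseline = cfg$lan_baseline, lan_gain = cfg$lan_gain,
                  alpha = cfg$alpha)
}
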