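#' Configuration of a multi-country synthetic experiment
#'
#' Describes an experiment of `n_countries` synthetic countries, each
#' simulated from a shared scenario template with its own seed, modelled
#' annually (one population model object per country-year), and pooled into
#' the WIR meta-analysis.
#'
#' @param n_countries number of countries (>= 1).
#' @param years annual time steps shared by all countries.
#' @param seeds one distinct integer seed per country.
#' @param scenario named list of [scenario_config()] arguments overriding the
#'   template defaults (years/seed are filled per country).
#' @param contrasts list of 2-element covariate-name vectors tested as WIR
#'   differences.
#' @param regions optional character vector of region labels cycled over
#'   countries (default: one global region).
#' @param n_trees trees for both random forests.
#' @param alpha significance level of the meta-analysis.
#' @param country_overrides named list (country id as name) of per-country
#'   scenario argument overrides.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_countries, years = 2000:2012,
                              seeds = seq_len(n_countries),
                              scenario = list(),
                              contrasts = list(
                                c("bs_dte_t0", "bs_dte_annual"),
                                c("bs_dte_coarse", "bs_dte_annual"),
                                c("bs_dte_t0", "bs_dte_coarse")),
                              regions = "global",
                              n_trees = 500L, alpha = 0.05,
                              country_overrides = list()) {
  if (n_countries < 1) stop("`n_countries` must be >= 1", call. = FALSE)
  if (length(seeds) != n_countries) {
    stop("`seeds` must supply one seed per country", call. = FALSE)
  }
  if (anyDuplicated(seeds)) stop("`seeds` must be distinct", call. = FALSE)
  structure(list(n_countries = as.integer(n_countries),
                 years = as.integer(years), seeds = as.integer(seeds),
                 scenario = scenario, contrasts = contrasts,
                 regions = regions, n_trees = as.integer(n_trees),
                 alpha = alpha, country_overrides = country_overrides),
            class = "experiment_config")
}

#' Enumerate the model objects an experiment will produce
#'
#' One population model object is fitted per country and year, so the plan
#' has `n_countries * length(years)` rows; its row count is the experiment's
#' model-object count.
#'
#' @param config an `experiment_config`.
#' @return data.frame with columns `country_id`, `year`, `seed`, `region`.
#' @export
plan_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  region <- rep_len(config$regions, config$n_countries)
  out <- expand.grid(year = config$years,
                     country_id = seq_len(config$n_countries))
  out <- out[, c("country_id", "year")]
  out$seed <- config$seeds[out$country_id]
  out$region <- region[out$country_id]
  rownames(out) <- NULL
  out
}

#' Run a full synthetic experiment
#'
#' For every country: simulate a scenario, interpolate the annual BS extents
#' from the two epochs, and fit one population model per year (epoch years
#' use the observed extents, interim years the interpolated ones). Pools
#' the per-model importance records into WIR, runs the Kruskal-Wallis test
#' of the annual BS covariate's WIR across interim years, the WIR-difference
#' contrasts (one-sample Wilcoxon, Holm-corrected), and boxplot summaries,
#' and writes everything plus a manifest with per-file checksums under
#' `out_dir`. A failure in one country-year is recorded in the manifest and
#' does not abort the rest of the run.
#'
#' @param config an `experiment_config`.
#' @param out_dir output directory.
#' @param write_surfaces write each country-year population surface as an
#'   `.asc` raster.
#' @param quiet suppress progress messages.
#' @return the manifest (also written to `manifest.json`), invisibly.
#' @export
run_experiment <- function(config, out_dir, write_surfaces = TRUE,
                           quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- plan_experiment(config)
  say <- function(...) if (!quiet) message(...)
  importance <- list()
  failures <- list()
  n_models <- 0L
  for (cid in seq_len(config$n_countries)) {
    args <- config$scenario
    ov <- config$country_overrides[[as.character(cid)]]
    if (!is.null(ov)) args[names(ov)] <- ov
    args$years <- config$years
    args$seed <- config$seeds[cid]
    say("country ", cid, ": simulating scenario")
    stage <- sprintf("country %d/simulate", cid)
    res <- tryCatch({
      cfg <- do.call(scenario_config, args)
      scn <- simulate_scenario(cfg)
      stage <- sprintf("country %d/bsgmi", cid)
      series <- run_bsgmi(scn$bundle, n_trees = config$n_trees,
                          seed = config$seeds[cid])
      list(scn = scn, series = series)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        list(stage = stage, error = conditionMessage(res))
      say("country ", cid, " failed at ", stage, ": ", conditionMessage(res))
      next
    }
    for (yr in config$years) {
      stage <- sprintf("country %d/popmodel %d", cid, yr)
      out <- tryCatch({
        disaggregate_population(res$scn$bundle, res$series[[as.character(yr)]],
                                yr, country_id = cid,
                                n_trees = config$n_trees,
                                seed = config$seeds[cid])
      }, error = function(e) e)
      if (inherits(out, "error")) {
        failures[[length(failures) + 1]] <-
          list(stage = stage, error = conditionMessage(out))
        say("  failed at ", stage, ": ", conditionMessage(out))
        next
      }
      n_models <- n_models + 1L
      importance[[length(importance) + 1]] <- out$importances
      if (write_surfaces) {
        write_asc(out$surface,
                  file.path(out_dir, sprintf("population_c%d_%d.asc", cid, yr)))
      }
    }
  }
  if (length(importance) == 0) stop("every country-year failed", call. = FALSE)
  records <- do.call(rbind, importance)
  utils::write.csv(records, file.path(out_dir, "importance_records.csv"),
                   row.names = FALSE)
  wir <- compute_wir_table(records)
  utils::write.csv(wir, file.path(out_dir, "wir_records.csv"),
                   row.names = FALSE)

  region_map <- unique(plan[, c("country_id", "region")])
  interim <- config$years[-c(1, length(config$years))]
  wir_interim <- wir[wir$year %in% interim, , drop = FALSE]

  kw_rows <- NULL
  annual <- wir_interim[wir_interim$covariate == "bs_dte_annual", , drop = FALSE]
  if (nrow(annual) > 0 && length(unique(annual$year)) >= 2) {
    kw <- tryCatch(kruskal_wallis(annual$wir, annual$year),
                   error = function(e) NULL)
    if (!is.null(kw)) {
      kw_rows <- data.frame(test = "bs_dte_annual WIR across interim years",
                            H = kw$H, df = kw$df, p = kw$p)
    }
  }
  if (!is.null(kw_rows)) {
    utils::write.csv(kw_rows, file.path(out_dir, "tests_kruskal_wallis.csv"),
                     row.names = FALSE)
  }
  contrast_tests <- tryCatch(
    wir_contrast_tests(wir_interim, config$contrasts, region_map,
                       alpha = config$alpha),
    error = function(e) NULL)
  if (!is.null(contrast_tests)) {
    utils::write.csv(contrast_tests, file.path(out_dir, "tests_contrasts.csv"),
                     row.names = FALSE)
  }
  box <- summarize_boxplots(wir$wir, paste(wir$covariate, wir$year, sep = "@"))
  utils::write.csv(box, file.path(out_dir, "boxplot_summaries.csv"),
                   row.names = FALSE)

  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("bsgmpop")),
    n_countries = config$n_countries,
    years = config$years,
    seeds = config$seeds,
    planned_models = nrow(plan),
    fitted_models = n_models,
    failures = failures,
    files = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
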