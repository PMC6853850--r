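#' Run configuration for the full pipeline
#'
#' @param sim a [sim_config()] to generate data, or NULL when reading
#'   `survey_csv`.
#' @param survey_csv path to a survey CSV (columns site, lat, lon, method,
#'   year, n_surveyed, n_occupied); ignored when `sim` is given.
#' @param covariates_csv optional covariate CSV (site, year, name, value).
#' @param variable synchrony variable, `"growth"` or `"abundance"`.
#' @param min_overlap minimum shared years per site pair.
#' @param n_perm permutations for the synchrony null models (>= 100 for
#'   reported p-values).
#' @param seed root seed recorded in the manifest.
#' @param wavelet_min_overlap minimum contributing sites per pooled cell.
#' @param period_range wavelet period range in years.
#' @param lag covariate lag frame for the growth model.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, survey_csv = NULL, covariates_csv = NULL,
                       variable = c("growth", "abundance"),
                       min_overlap = 3, n_perm = 5000, seed = 1L,
                       wavelet_min_overlap = 5, period_range = c(2, 8.5),
                       lag = "year_t-1") {
  variable <- match.arg(variable)
  if (is.null(sim) && is.null(survey_csv)) {
    stop("config error: provide either a simulator config or a survey CSV")
  }
  if (n_perm < 100) warning("n_perm < 100: reported p-values are coarse")
  structure(list(sim = sim, survey_csv = survey_csv,
                 covariates_csv = covariates_csv, variable = variable,
                 min_overlap = min_overlap, n_perm = n_perm,
                 seed = as.integer(seed),
                 wavelet_min_overlap = wavelet_min_overlap,
                 period_range = period_range, lag = lag),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> series -> growth model (when covariates exist) ->
#' synchrony correlogram with both null models -> pooled wavelet spectrum
#' with significance mask. All randomness derives from the configured
#' seed, so a rerun with the same configuration writes byte-identical
#' outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory for CSV tables, the JSON summary and
#'   the manifest; NULL to skip writing.
#' @return list with every stage's result (`survey`, `series`, `pairs`,
#'   `correlogram`, `growth_fit`, `spectra`, `pooled`, `mask`, `summary`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  covariates <- NULL
  if (!is.null(config$sim)) {
    simres <- stage("simulate", simulate_survey(config$sim))
    survey <- simres$survey
    covariates <- simres$covariates
  } else {
    survey <- stage("simulate", utils::read.csv(config$survey_csv))
    if (!is.null(config$covariates_csv)) {
      covariates <- utils::read.csv(config$covariates_csv)
    }
  }

  series <- stage("series", {
    need <- c("site", "lat", "lon", "year", "n_surveyed", "n_occupied")
    miss <- setdiff(need, names(survey))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    growth_rate(occupancy_rate(survey))
  })

  growth_fit <- NULL
  if (!is.null(covariates)) {
    growth_fit <- stage("growth", {
      md <- build_model_data(series, covariates, lag = config$lag)
      fit_growth_model(md)
    })
  }

  pairs <- stage("synchrony", pairwise_synchrony(
    series, variable = config$variable, min_overlap = config$min_overlap))
  crg <- stage("synchrony", fit_correlogram(
    pairs, n_perm = config$n_perm, seed = config$seed))

  spectra <- stage("wavelet", site_spectra(
    series, period_range = config$period_range))
  pooled <- stage("wavelet", pool_spectra(
    spectra, min_overlap = config$wavelet_min_overlap))
  mask <- significance_mask(pooled)

  summary <- list(
    seed = config$seed,
    n_sites = length(unique(series$site)),
    n_site_years = nrow(series),
    variable = config$variable,
    n_pairs = nrow(pairs),
    average_synchrony_r = crg$average_r,
    average_synchrony_ci = as.numeric(crg$average_ci),
    mantel_p = crg$mantel_p,
    n_perm = crg$n_perm,
    correlogram_edf = crg$edf,
    correlogram_r2_adj = crg$r2_adj,
    n_spectra = length(spectra),
    n_significant_cells = sum(mask),
    wavelet_min_overlap = config$wavelet_min_overlap
  )

  result <- list(survey = survey, series = series, pairs = pairs,
                 correlogram = crg, growth_fit = growth_fit,
                 spectra = spectra, pooled = pooled, mask = mask,
                 summary = summary, config = config)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write pipeline outputs to a directory
#'
#' Emits the survey echo, the series table, the pair-correlation table,
#' the correlogram grid, the pooled spectrum, a JSON summary and a
#' manifest carrying the seed and a hash of the configuration echo.
#'
#' @param result value of [run_pipeline()].
#' @param out_dir directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(result$survey, p("survey.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$series), p("series.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$pairs), p("pairs.csv"),
                   row.names = FALSE)
  crg <- result$correlogram
  grid_tab <- data.frame(dist_km = crg$grid, fit_r = crg$fit_r,
                         band_no_corr_lower = crg$band_no_correlation[1, ],
                         band_no_corr_upper = crg$band_no_correlation[2, ],
                         band_shuffle_lower = crg$band_distance_shuffle[1, ],
                         band_shuffle_upper = crg$band_distance_shuffle[2, ])
  utils::write.csv(grid_tab, p("correlogram.csv"), row.names = FALSE)
  utils::write.csv(pooled_spectrum_table(result$pooled, result$mask),
                   p("pooled_spectrum.csv"), row.names = FALSE)
  if (!is.null(result$growth_fit)) {
    utils::write.csv(result$growth_fit$coef_table, p("growth_model.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_echo <- jsonlite::serializeJSON(result$config)
  manifest <- list(
    seed = result$config$seed,
    n_perm = result$config$n_perm,
    config_hash = unname(tools::md5sum(
      {f <- p("config_echo.json"); writeLines(cfg_echo, f); f})),
    files = c("survey.csv", "series.csv", "pairs.csv", "correlogram.csv",
              "pooled_spectrum.csv", "summary.json")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list.files(out_dir, full.names = TRUE))
}

#' Coordinates of the long-term monitoring sites
#'
#' Centres of the nine Finnish flying-squirrel monitoring areas
#' (nest-box and pellet surveys) bundled with the package, used for the
#' distance-geometry checks and as a realistic site layout for the
#' simulator.
#'
#' @return data.frame `site`, `lat`, `lon`, `method`, `first_year`,
#'   `last_year`, `mean_occupancy`, `mean_units`.
#' @export
monitoring_sites <- function() {
  utils::read.csv(system.file("extdata", "monitoring_sites.csv",
                              package = "moransync"))
}
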