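#' Record a reproducibility manifest for a run
#'
#' Writes a JSON manifest (command label, parameter bundle path, seed, PSA
#' size, scenario list, timestamp, package version) alongside a run's
#' outputs, sufficient to reproduce the run exactly.
#'
#' @param out_dir output directory (created if needed).
#' @param command label of the driving script or call.
#' @param params_path path of the parameter bundle used (or `NA`).
#' @param seed integer seed.
#' @param n_psa probabilistic run count (or 1).
#' @param scenarios character vector of scenario ids (optional).
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, command, params_path = NA, seed = NA,
                               n_psa = 1, scenarios = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    command = command,
    params_path = params_path,
    seed = seed,
    n_psa = n_psa,
    scenarios = scenarios,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("abdoscreen"))
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export publication-shaped result tables
#'
#' Writes the headline cost-effectiveness summary, the per-disease INMB
#' decomposition and the epidemiological outputs as plain CSV (numeric
#' columns, units in headers, no currency symbols).
#'
#' @param cea an `abdo_cea` result.
#' @param out_dir output directory.
#' @param psa optional `abdo_psa` result; adds 95% credible intervals, the
#'   probability cost-effective, CE-plane points and the CEAC grid.
#' @return character vector of files written, invisibly.
#' @export
export_cea_tables <- function(cea, out_dir, psa = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  summary <- data.frame(
    measure = c("cost_gbp", "life_years", "qalys"),
    current_care = c(cea$arms$cost[1], cea$arms$ly[1], cea$arms$qaly[1]),
    screening = c(cea$arms$cost[2], cea$arms$ly[2], cea$arms$qaly[2]),
    incremental = c(cea$incremental$cost, cea$incremental$ly, cea$incremental$qaly))
  if (!is.null(psa)) {
    summary$incremental_lower95 <- c(psa$ci[1, "inc_cost"], psa$ci[1, "inc_ly"], psa$ci[1, "inc_qaly"])
    summary$incremental_upper95 <- c(psa$ci[2, "inc_cost"], psa$ci[2, "inc_ly"], psa$ci[2, "inc_qaly"])
  }
  w(summary, "summary.csv")
  w(data.frame(measure = c("inmb_gbp", "icer_gbp_per_qaly", "icer_code",
                           "prob_cost_effective", "mean_screen_cost_gbp",
                           "max_justifiable_cost_gbp"),
               value = c(cea$inmb, cea$icer$value, cea$icer$code,
                         if (!is.null(psa)) psa$prob_cost_effective else NA,
                         cea$mean_screen_cost,
                         max_justifiable_cost(cea$mean_screen_cost, cea$inmb))),
    "headline.csv")
  w(cea$decomposition, "inmb_decomposition.csv")
  w(cea$epi, "epi_outputs.csv")
  w(cea$cohort_results, "cohort_results.csv")
  if (!is.null(psa)) {
    w(psa$draws, "ce_plane.csv")
    w(ceac(psa), "ceac.csv")
  }
  invisible(files)
}
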