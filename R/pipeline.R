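#' Configuration for a full two-resolution analysis run
#'
#' @param input a \code{coral_survey}, a [scenario_config()] to simulate
#'   from, or a file path readable by [read_survey()].
#' @param projection passed to [read_survey()] for file input.
#' @param bins a [distance_bins()].
#' @param envelope_sims simulations per L-function envelope (default 99).
#' @param grid a [grid_spec()] or \code{NULL} (grid over the survey region).
#' @param cell cell size used when \code{grid} is \code{NULL}.
#' @param radius filter radius in metres or \code{"auto"} ([h_opt()]).
#' @param n_sims Monte Carlo simulations for the surfaces (default 1000).
#' @param alpha cluster significance level (default 0.05).
#' @param buffer cluster-proximity buffer in metres (default 100).
#' @param seed master seed; per-stage seeds are derived from it by a fixed
#'   counter scheme so stages can be rerun in isolation.
#' @param outdir optional directory to write result files into.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(input = scenario_config(), projection = NULL,
                       bins = distance_bins(), envelope_sims = 99,
                       grid = NULL, cell = 50, radius = "auto",
                       n_sims = 1000, alpha = 0.05, buffer = 100,
                       seed = 1L, outdir = NULL) {
  stopifnot(inherits(bins, "distance_bins"), envelope_sims >= 1,
            n_sims >= 1, alpha > 0, alpha < 1)
  structure(list(input = input, projection = projection, bins = bins,
                 envelope_sims = envelope_sims, grid = grid, cell = cell,
                 radius = radius, n_sims = n_sims, alpha = alpha,
                 buffer = buffer, seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

# deterministic fan-out of the master seed: stage k gets an independent,
# reproducible stream; kept below 2^31
stage_seed <- function(master, k) {
  as.integer((as.numeric(master) + 1000003 * k) %% 2147483647)
}

#' Run the full two-resolution spatial analysis
#'
#' Executes, for both the transect and the colony resolution: the observed
#' L-function with a CSR envelope for the disease, disease-absent and
#' population views (six homogeneous analyses), the disease-minus-population
#' difference
#' function with a random-labeling envelope (two analyses), and the filtered
#' prevalence surface with Monte Carlo significance and cluster extraction
#' (two surfaces). If \code{outdir} is set, tidy tables, ASCII grids, a JSON
#' manifest and the text report are written there; a stage failure aborts
#' with the stage name while earlier outputs remain on disk.
#'
#' @param config a [run_config()].
#' @return an object of class \code{coral_run_report} containing the survey,
#'   its summary, all L-function/difference results, surfaces, cluster sets
#'   and cluster summaries, plus the manifest.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "load"
  out <- tryCatch({
    survey <-
      if (inherits(config$input, "coral_survey")) config$input
      else if (inherits(config$input, "scenario_config"))
        simulate_survey(config$input, seed = stage_seed(config$seed, 0L))
      else read_survey(config$input, projection = config$projection)
    stage <- "summarize"
    surv_summary <- summary(survey)
    stage <- "ripley"
    modes <- c("transect", "colony")
    lcurves <- list()
    skipped <- character()
    for (m in modes) for (v in c("disease", "healthy", "population")) {
      nm <- paste(v, m, sep = "_")
      vw <- survey_view(survey, v, m)
      if (sum(vw$w > 0) < 2L) { skipped <- c(skipped, nm); next }
      lcurves[[nm]] <- lfun(survey, view = v, mode = m, bins = config$bins,
                            n_sims = config$envelope_sims,
                            seed = stage_seed(config$seed, 1L))
    }
    diffs <- list()
    for (m in modes) {
      if (sum(survey_view(survey, "disease", m)$w > 0) < 2L) {
        skipped <- c(skipped, paste0("difference_", m)); next
      }
      diffs[[m]] <- difference_function(survey, mode = m, bins = config$bins,
                                        n_sims = config$envelope_sims,
                                        seed = stage_seed(config$seed, 2L))
    }
    stage <- "filter_map"
    grid <- if (is.null(config$grid)) grid_for_survey(survey, config$cell)
            else config$grid
    surfaces <- list(); clusters <- list(); csum <- list()
    for (m in modes) {
      surf <- filtered_prevalence(survey, grid, radius = config$radius,
                                  mode = m)
      surf <- monte_carlo_significance(surf, survey, n_sims = config$n_sims,
                                       seed = stage_seed(config$seed, 3L))
      surfaces[[m]] <- surf
      clusters[[m]] <- extract_clusters(surf, alpha = config$alpha)
      csum[[m]] <- cluster_summary(clusters[[m]], survey,
                                   buffer = config$buffer)
    }
    stage <- "report"
    manifest <- list(
      seed = config$seed,
      stage_seeds = vapply(0:3, function(k) stage_seed(config$seed, k), 0L),
      n_l_curves = length(lcurves),
      n_difference_curves = length(diffs),
      n_surfaces = length(surfaces),
      n_cluster_sets = length(clusters),
      skipped_analyses = if (length(skipped)) skipped else NULL,
      bins = list(d_max = config$bins$d_max, step = config$bins$step),
      envelope_sims = config$envelope_sims,
      n_sims = config$n_sims, alpha = config$alpha,
      radius = surfaces$transect$radius,
      n_transects = nrow(survey$records),
      checksum = round(sum(survey$records$x) + sum(survey$records$y) +
                         sum(survey$records$n_colonies), 6)
    )
    structure(list(survey = survey, summary = surv_summary,
                   l_functions = lcurves, difference = diffs,
                   surfaces = surfaces, clusters = clusters,
                   cluster_summaries = csum, manifest = manifest,
                   config = config),
              class = "coral_run_report")
  }, error = function(e)
    stop("analysis failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(config$outdir)) export_report(out, config$outdir)
  out
}

export_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$l_functions))
    utils::write.csv(as.data.frame(report$l_functions[[nm]]),
                     file.path(outdir, paste0("lfun_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(report$difference))
    utils::write.csv(as.data.frame(report$difference[[nm]]),
                     file.path(outdir, paste0("difference_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(report$surfaces)) {
    write_ascii_grid(report$surfaces[[nm]],
                     file.path(outdir, paste0("prevalence_", nm, ".asc")),
                     "prevalence")
    write_ascii_grid(report$surfaces[[nm]],
                     file.path(outdir, paste0("pvalue_", nm, ".asc")),
                     "p_value")
  }
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(utils::capture.output(write_report(report)),
             file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' Human-readable run report
#'
#' Prints the cross-resolution comparison: prevalence at both resolutions,
#' the per-bin significance classes of all spatial analyses, and the cluster
#' counts, areas and proximity percentages.
#'
#' @param report a \code{coral_run_report}.
#' @param file connection or filename for [cat()]; default prints to the
#'   console.
#' @return the report, invisibly.
#' @export
write_report <- function(report, file = "") {
  stopifnot(inherits(report, "coral_run_report"))
  out <- character()
  add <- function(...) out <<- c(out, sprintf(...))
  s <- report$summary
  pct <- function(v) formatC(round(v, 2), format = "f", digits = 2)
  add("=== Coral disease spatial analysis ===")
  add("Transects: %d surveyed, %d positive; transect-level prevalence %s%%",
      s$n_transects, s$n_transects_positive, pct(s$prevalence_transect))
  add("Colonies:  %d surveyed, %d diseased; colony-level prevalence %s%%",
      s$n_colonies, s$n_colonies_diseased, pct(s$prevalence_colony))
  if (!is.na(s$mean_depth)) add("Mean transect depth: %.2f m", s$mean_depth)
  add("")
  add("--- L-functions (CSR envelopes, %d sims) ---",
      report$config$envelope_sims)
  for (nm in names(report$l_functions)) {
    tb <- table(report$l_functions[[nm]]$significance_class)
    add("%-22s %s", nm,
        paste(sprintf("%s=%d", names(tb)[tb > 0], tb[tb > 0]), collapse = ", "))
  }
  add("")
  add("--- Difference functions D(d) (random labeling) ---")
  for (nm in names(report$difference)) {
    tb <- table(report$difference[[nm]]$significance_class)
    add("%-22s %s", nm,
        paste(sprintf("%s=%d", names(tb)[tb > 0], tb[tb > 0]), collapse = ", "))
  }
  add("")
  add("--- Filtered prevalence surfaces (%d Monte Carlo sims, alpha %g) ---",
      report$config$n_sims, report$config$alpha)
  for (nm in names(report$clusters)) {
    cs <- report$cluster_summaries[[nm]]
    add("%s level: %d cluster(s), total %.4f km^2", nm, cs$n_clusters,
        cs$total_area_km2)
    if (cs$n_clusters > 0) {
      add("  positive transects: %s%% inside, %s%% within %g m",
          pct(cs$pct_positive_transects_inside),
          pct(cs$pct_positive_transects_within_buffer), cs$buffer)
      add("  diseased colonies:  %s%% inside, %s%% within %g m",
          pct(cs$pct_diseased_colonies_inside),
          pct(cs$pct_diseased_colonies_within_buffer), cs$buffer)
      if (!is.na(cs$mean_depth_inside))
        add("  mean depth inside clusters: %.2f m", cs$mean_depth_inside)
    }
  }
  cat(paste(out, collapse = "\n"), "\n", file = file)
  invisible(report)
}

#' @export
print.coral_run_report <- function(x, ...) {
  write_report(x)
  invisible(x)
}
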