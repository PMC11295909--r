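#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles the per-stage configurations and a master seed. The master
#' seed spawns a deterministic, stage-name-keyed child seed per stage, so
#' changing one stage's parameters never perturbs another stage's
#' randomness.
#'
#' @param panel A [panel_config()] (its `seed` is overridden by the
#'   stage child seed).
#' @param sim A [sim_config()] (likewise).
#' @param stages Character vector of stages to run, a subset of
#'   `c("synth", "descriptives", "census", "ranksum", "regress",
#'   "evolve", "curve", "placebo")`.
#' @param seed Master seed.
#' @param placebo_subsample Placebo sets drawn per scheme (`NULL` = all).
#' @param curve_draws,curve_sample_size Sampling-distribution parameters
#'   for the predicted cooperation curve.
#' @param exclude_rounds_list List of round-exclusion sets for the
#'   exploratory refits (default: none, drop round 2, drop rounds 2-3).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(panel = panel_config(),
                            sim = sim_config(),
                            stages = c("synth", "descriptives", "census",
                                       "ranksum", "regress", "evolve",
                                       "curve", "placebo"),
                            seed = 1,
                            placebo_subsample = 500,
                            curve_draws = 1000,
                            curve_sample_size = 256,
                            exclude_rounds_list = list(integer(0), 2L,
                                                       c(2L, 3L))) {
  structure(list(panel = panel, sim = sim, stages = stages,
                 seed = as.integer(seed),
                 placebo_subsample = placebo_subsample,
                 curve_draws = curve_draws,
                 curve_sample_size = curve_sample_size,
                 exclude_rounds_list = exclude_rounds_list),
            class = "pipeline_config")
}

#' Run the full prime-round cooperation analysis
#'
#' Executes the selected stages in dependency order on a synthetic panel
#' (or one supplied via `panel`): descriptive summaries, the
#' autocorrelation cycle census, the prime-vs-composite rank-sum test,
#' the focal mixed model with round-exclusion refits, the evolutionary
#' simulation with predicted-vs-observed cooperation curves and their
#' interval-overlap report, and the placebo-prime battery with its
#' distance diagnostics.
#'
#' @param config A [pipeline_config()].
#' @param panel Optional pre-built `contribution_panel` (skips the
#'   `synth` stage).
#' @param out_dir Optional directory: stage outputs are written as
#'   CSV/JSON artifacts.
#' @return An `analysis_report` list with one element per executed stage
#'   plus a `provenance` block (seed, stage seeds, package version).
#' @export
run_pipeline <- function(config = pipeline_config(), panel = NULL,
                         out_dir = NULL) {
  stages <- config$stages
  seeds <- lapply(setNames(nm = c("synth", "evolve", "curve", "placebo")),
                  function(s) child_seed(config$seed, s))
  report <- list()

  if (is.null(panel)) {
    pc <- config$panel
    pc$seed <- seeds$synth
    panel <- generate_panel(pc)
  }
  report$panel_dims <- tibble(n_participants = length(unique(panel$participant_id)),
                              n_rounds = max(panel$round),
                              n_records = nrow(panel))

  if ("descriptives" %in% stages) {
    report$descriptives <- panel_descriptives(panel)
  }
  if ("census" %in% stages) {
    report$census <- acf_census(panel)
  }
  if ("ranksum" %in% stages) {
    report$ranksum <- rank_sum_prime_vs_composite(panel)
  }
  if ("regress" %in% stages) {
    pr <- primes_in(1, max(panel$round))
    report$focal_fit <- fit_focal_model(build_design(panel, pr))
    report$exclusion_fits <- lapply(config$exclude_rounds_list, function(ex) {
      if (length(ex) == 0) return(report$focal_fit)
      fit_focal_model(build_design(panel, pr, exclude_rounds = ex))
    })
    names(report$exclusion_fits) <-
      vapply(config$exclude_rounds_list,
             function(ex) if (length(ex) == 0) "none" else
               paste0("excl_", paste(ex, collapse = "_")),
             character(1))
  }
  if ("evolve" %in% stages) {
    sc <- config$sim
    sc$seed <- seeds$evolve
    report$fixation_records <- run_evolution(sc)
  }
  if ("curve" %in% stages && !is.null(report$fixation_records)) {
    sim_curve <- predicted_cooperation_curve(
      report$fixation_records,
      sample_size = config$curve_sample_size,
      n_draws = config$curve_draws,
      n_rounds = max(panel$round),
      seed = seeds$curve
    )
    obs_curve <- empirical_full_cooperation_curve(panel)
    report$curves <- dplyr::bind_rows(sim_curve, obs_curve)
    report$overlap <- overlap_report(sim_curve, obs_curve)
  }
  if ("placebo" %in% stages && !is.null(report$focal_fit)) {
    sets <- dplyr::bind_rows(lapply(standard_schemes(),
                                    enumerate_placebo_sets))
    report$battery <- run_battery(panel, sets,
                                  subsample = config$placebo_subsample,
                                  seed = seeds$placebo)
    report$battery_summary <- summarize_battery(report$battery,
                                                report$focal_fit)
    report$distance_association <-
      distance_coefficient_association(report$battery)
  }

  report$provenance <- list(
    master_seed = config$seed,
    stage_seeds = seeds,
    package_version = as.character(utils::packageVersion("primecoop")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_report(report, panel, out_dir)
  report
}

write_report <- function(report, panel, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_panel(panel, file.path(out_dir, "panel.csv"))
  if (!is.null(report$census)) {
    readr::write_csv(report$census$classification,
                     file.path(out_dir, "acf_classification.csv"))
  }
  if (!is.null(report$fixation_records)) {
    readr::write_csv(report$fixation_records,
                     file.path(out_dir, "fixation_records.csv"))
  }
  if (!is.null(report$curves)) {
    readr::write_csv(report$curves, file.path(out_dir, "curves.csv"))
  }
  if (!is.null(report$battery)) {
    flat <- report$battery
    flat$members <- vapply(flat$members, paste, character(1), collapse = ";")
    readr::write_csv(flat, file.path(out_dir, "placebo_battery.csv"))
  }
  summary <- list(
    provenance = report$provenance,
    panel_dims = report$panel_dims,
    descriptives = report$descriptives,
    census_summary = if (!is.null(report$census)) report$census$summary,
    ranksum = report$ranksum,
    focal_fit = strip_fit(report$focal_fit),
    exclusion_fits = lapply(report$exclusion_fits, strip_fit),
    overlap = report$overlap,
    battery_summary = report$battery_summary,
    distance_association = if (!is.null(report$distance_association)) {
      report$distance_association[c("pearson", "spearman", "defined")]
    }
  )
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

strip_fit <- function(fit) {
  if (is.null(fit)) return(NULL)
  fit$fit <- NULL
  unclass(fit)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  if (!is.null(x$focal_fit)) {
    cat("\nFocal prime-indicator coefficient:\n")
    print(coef_row(x$focal_fit, "indicator"))
  }
  if (!is.null(x$battery_summary)) {
    cat("\nPlacebo battery:\n")
    print(x$battery_summary$overall)
  }
  invisible(x)
}
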