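#' Run a placebo-prime regression battery
#'
#' Re-estimates the focal mixed model once per placebo set, substituting
#' the set's placebo-prime-time-point indicator for the prime indicator.
#' The design's indicator-independent parts (response, peer lag, trend,
#' grouping) are built once and reused; only the indicator column changes
#' between fits, so the battery evaluated at the true prime set is
#' bit-identical to the focal fit. Non-convergence of a single fit is
#' recorded per set, never fatal.
#'
#' @param panel A `contribution_panel`.
#' @param sets Placebo sets from [enumerate_placebo_sets()] (rows can
#'   come from several schemes).
#' @param subsample Number of sets to draw (without replacement, seeded)
#'   or `NULL` for all.
#' @param seed Seed for the subsample draw.
#' @param exclude_rounds,lag_peers,method Passed through to
#'   [build_design()] / [fit_focal_model()].
#' @return A tibble with one row per fitted set: `set_id`, `scheme`,
#'   `members` (list-column), `distance_to_primes`, `estimate`, `se`,
#'   `z`, `p`, `ci_lower`, `ci_upper`, `converged`.
#' @export
run_battery <- function(panel, sets, subsample = NULL, seed = NULL,
                        exclude_rounds = integer(0),
                        lag_peers = "previous_round_groupmates",
                        method = "reml") {
  stopifnot(nrow(sets) > 0)
  if (!is.null(subsample) && subsample < nrow(sets)) {
    keep <- with_seed_if(seed, sort(sample.int(nrow(sets), subsample)))
    sets <- sets[keep, , drop = FALSE]
  }
  base <- build_design(panel, indicator_set = primes_in(1, max(panel$round)),
                       exclude_rounds = exclude_rounds,
                       lag_peers = lag_peers)
  res <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    members <- sets$members[[i]]
    d <- base
    d$indicator <- as.integer(d$round %in% members)
    row <- tryCatch({
      fit <- fit_focal_model(d, method = method)
      cbind(coef_row(fit, "indicator")[, c("estimate", "se", "z", "p",
                                           "ci_lower", "ci_upper")],
            converged = fit$converged)
    }, error = function(e) {
      tibble(estimate = NA_real_, se = NA_real_, z = NA_real_,
             p = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
             converged = FALSE)
    })
    cbind(sets[i, c("set_id", "scheme")],
          tibble(members = list(members),
                 distance_to_primes = sets$distance_to_primes[[i]]),
          row)
  })
  as_tibble(res)
}

#' Summarize a placebo battery against the focal fit
#'
#' Counts how many placebo sets produced (i) an indicator estimate
#' strictly exceeding the focal prime-indicator estimate and (ii) a
#' "positive significant" result: estimate > 0 *and* Wald 95% lower
#' bound > 0. Both are reported overall and per bin scheme.
#'
#' @param battery Output of [run_battery()].
#' @param focal The focal `coop_fit` (prime indicator), which must have
#'   converged.
#' @return List with `overall` (one-row tibble: `n_sets`,
#'   `n_exceeding_focal`, `rate_exceeding_focal`,
#'   `n_positive_significant`, `rate_positive_significant`,
#'   `focal_estimate`) and `per_scheme` (same columns by scheme).
#' @export
summarize_battery <- function(battery, focal) {
  stopifnot(inherits(focal, "coop_fit"))
  if (!focal$converged) stop_config("focal fit did not converge")
  focal_est <- coef_row(focal, "indicator")$estimate
  summarise_part <- function(df) {
    tibble(
      n_sets = nrow(df),
      n_exceeding_focal = sum(df$estimate > focal_est, na.rm = TRUE),
      rate_exceeding_focal = mean(df$estimate > focal_est, na.rm = TRUE),
      n_positive_significant = sum(df$estimate > 0 & df$ci_lower > 0,
                                   na.rm = TRUE),
      rate_positive_significant = mean(df$estimate > 0 & df$ci_lower > 0,
                                       na.rm = TRUE),
      focal_estimate = focal_est
    )
  }
  per_scheme <- battery |>
    dplyr::group_by(scheme = .data$scheme) |>
    dplyr::group_modify(~ summarise_part(.x)) |>
    dplyr::ungroup()
  list(overall = summarise_part(battery), per_scheme = per_scheme)
}

#' Distance-coefficient association across placebo sets
#'
#' Pearson and Spearman correlations between each placebo set's Euclidean
#' distance from the primes and its estimated indicator coefficient,
#' plus the paired table for a scatter plot. Constant inputs leave the
#' correlations undefined (flagged, not an error).
#'
#' @param battery Output of [run_battery()] with at least 3 converged
#'   rows.
#' @return List: `pearson`, `spearman`, `defined` flag, `table` (tibble
#'   `distance_to_primes`, `estimate`, `scheme`).
#' @export
distance_coefficient_association <- function(battery) {
  df <- battery[!is.na(battery$estimate), , drop = FALSE]
  if (nrow(df) < 3L) stop_config("need at least 3 battery results")
  tab <- df[, c("distance_to_primes", "estimate", "scheme")]
  if (sd(df$estimate) == 0 || sd(df$distance_to_primes) == 0) {
    return(list(pearson = NA_real_, spearman = NA_real_,
                defined = FALSE, table = tab))
  }
  list(
    pearson = cor(df$distance_to_primes, df$estimate),
    spearman = cor(df$distance_to_primes, df$estimate, method = "spearman"),
    defined = TRUE,
    table = tab
  )
}
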