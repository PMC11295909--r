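#' Build the regression design table from a panel
#'
#' One row per participant per non-excluded round `t >= 2` (round 1 never
#' enters: the lagged peer mean is undefined there). The response is the
#' effective contribution; covariates are the lagged group-mates' mean
#' (`peer_lag`), the round number as a linear time trend (`round_value`)
#' and a binary `indicator` of membership of `t` in `indicator_set` (the
#' primes, or a placebo set). Excluded rounds are dropped as estimation
#' rows only — their decisions still feed lag construction, so excluding
#' round 2 removes exactly `n_participants` rows.
#'
#' @param panel A `contribution_panel`.
#' @param indicator_set Nonempty set of round numbers scored 1.
#' @param exclude_rounds Rounds (subset of `2..n_rounds`) dropped from
#'   estimation.
#' @param lag_peers Peer-lag convention. `"previous_round_groupmates"`
#'   (default): the mean round-`(t-1)` contribution of the focal
#'   participant's round-`(t-1)` group-mates — what the participant
#'   actually observed as feedback. `"current_round_groupmates"`: the
#'   round-`(t-1)` contributions of the participant's round-`t`
#'   group-mates.
#' @return A tibble: `participant_id`, `matching_group_id`, `round`,
#'   `response`, `peer_lag`, `round_value`, `indicator`.
#' @export
build_design <- function(panel, indicator_set = primes_in(1, max(panel$round)),
                         exclude_rounds = integer(0),
                         lag_peers = c("previous_round_groupmates",
                                       "current_round_groupmates")) {
  lag_peers <- match.arg(lag_peers)
  if (length(indicator_set) == 0L) stop_config("indicator_set must be nonempty")
  n_rounds <- max(panel$round)
  if (length(exclude_rounds) && (any(exclude_rounds < 2) ||
                                 any(exclude_rounds > n_rounds))) {
    stop_config("exclude_rounds must lie in 2..n_rounds")
  }
  gs <- panel |>
    dplyr::group_by(.data$round, .data$round_group_id) |>
    dplyr::mutate(.group_sum = sum(.data$effective_contribution),
                  .group_n = dplyr::n()) |>
    dplyr::ungroup()

  if (lag_peers == "previous_round_groupmates") {
    # peer mean the participant observed after round t-1
    lagged <- gs |>
      dplyr::mutate(
        peer_obs = (.data$.group_sum - .data$effective_contribution) /
          (.data$.group_n - 1),
        round = .data$round + 1L
      ) |>
      dplyr::select("participant_id", "round", peer_lag = "peer_obs")
    design <- gs |>
      dplyr::inner_join(lagged, by = c("participant_id", "round"))
  } else {
    # round-(t-1) decisions of the round-t group-mates
    prev <- gs |>
      dplyr::mutate(round = .data$round + 1L) |>
      dplyr::select("participant_id", "round",
                    prev_contribution = "effective_contribution")
    design <- gs |>
      dplyr::inner_join(prev, by = c("participant_id", "round")) |>
      dplyr::group_by(.data$round, .data$round_group_id) |>
      dplyr::mutate(
        peer_lag = (sum(.data$prev_contribution) - .data$prev_contribution) /
          (dplyr::n() - 1)
      ) |>
      dplyr::ungroup()
  }

  design <- design |>
    dplyr::filter(!(.data$round %in% exclude_rounds)) |>
    dplyr::mutate(
      response = as.numeric(.data$effective_contribution),
      round_value = as.numeric(.data$round),
      indicator = as.integer(.data$round %in% indicator_set)
    ) |>
    dplyr::select("participant_id", "matching_group_id", "round",
                  "response", "peer_lag", "round_value", "indicator") |>
    dplyr::arrange(.data$participant_id, .data$round)
  if (nrow(design) == 0L) stop_config("exclusions leave no estimation rows")
  design
}

#' Fit the focal mixed-effects contribution model
#'
#' Linear mixed model of effective contributions on the lagged
#' group-mates' mean, a linear round trend and the round-set indicator,
#' with random intercepts for the matching group and for the individual
#' (individuals never cross matching groups, so crossed and nested
#' specifications coincide). Estimated with [lme4::lmer()], REML by
#' default; inference is Wald-z (`z = estimate / SE`, two-sided normal p,
#' 95% CI `estimate +/- 1.96 SE`).
#'
#' @param design A design table from [build_design()].
#' @param method `"reml"` (default) or `"ml"`.
#' @param keep_fit Keep the underlying `lmerMod` object in the result.
#' @return A `coop_fit` object: list with `coefficients` (tibble `term`,
#'   `estimate`, `se`, `z`, `p`, `ci_lower`, `ci_upper`), `varcomp`
#'   (tibble `group`, `variance`, `sd`), `n_obs`, `converged`, `method`
#'   and (optionally) `fit`.
#' @export
fit_focal_model <- function(design, method = c("reml", "ml"),
                            keep_fit = FALSE) {
  method <- match.arg(method)
  stopifnot(nrow(design) > 0)
  if (length(unique(design$indicator)) < 2L) {
    stop_config("indicator is constant in the design")
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- withCallingHandlers(
    lme4::lmer(
      response ~ peer_lag + round_value + indicator +
        (1 | matching_group_id) + (1 | participant_id),
      data = design, REML = (method == "reml"), control = ctrl
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  converged <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L &&
    fit@optinfo$conv$opt == 0
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  coefs <- tibble(
    term = c("(Intercept)", "peer_lag", "round_value", "indicator"),
    estimate = unname(est),
    se = unname(se),
    z = unname(z),
    p = unname(2 * pnorm(-abs(z))),
    ci_lower = unname(est - 1.96 * se),
    ci_upper = unname(est + 1.96 * se)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble(
    group = vc$grp,
    variance = vc$vcov,
    sd = vc$sdcor
  )
  structure(list(
    coefficients = coefs,
    varcomp = varcomp,
    n_obs = nrow(design),
    converged = converged,
    method = toupper(method),
    fit = if (keep_fit) fit else NULL
  ), class = "coop_fit")
}

#' @export
print.coop_fit <- function(x, ...) {
  cat("<coop_fit> linear mixed model (", x$method, "), n = ", x$n_obs,
      if (!x$converged) " [did not converge]", "\n", sep = "")
  print(x$coefficients)
  cat("Variance components:\n")
  print(x$varcomp)
  invisible(x)
}

#' @describeIn fit_focal_model Coefficient table in broom convention
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `conf.low`, `conf.high`).
#' @param x A `coop_fit`.
#' @param ... Unused.
#' @method tidy coop_fit
#' @export
tidy.coop_fit <- function(x, ...) {
  dplyr::rename(x$coefficients, std.error = "se", statistic = "z",
                p.value = "p", conf.low = "ci_lower", conf.high = "ci_upper")
}

#' @describeIn fit_focal_model One-row model summary.
#' @method glance coop_fit
#' @export
glance.coop_fit <- function(x, ...) {
  vc <- setNames(x$varcomp$variance, x$varcomp$group)
  tibble(
    nobs = x$n_obs,
    sigma2_matching_group = unname(vc[["matching_group_id"]]),
    sigma2_participant = unname(vc[["participant_id"]]),
    sigma2_residual = unname(vc[["Residual"]]),
    converged = x$converged,
    method = x$method
  )
}

# pull one coefficient row from a coop_fit
coef_row <- function(fit, term) {
  fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
}

#' Rank-sum test of contributions at prime versus non-prime rounds
#'
#' Two-sided Wilcoxon/Mann-Whitney test (tie-corrected) comparing
#' effective contributions made in prime-numbered rounds against all
#' other rounds. Round 1 — neither prime nor composite — joins the
#' non-prime group by default and can be dropped instead. Reports the
#' statistic in both conventions: `W` as the rank sum of the prime group
#' and `U` (the [stats::wilcox.test()] statistic).
#'
#' @param panel A `contribution_panel`.
#' @param include_round_one Keep round-1 decisions in the non-prime group
#'   (default `TRUE`).
#' @param ... Passed to [stats::wilcox.test()] (e.g. `exact`).
#' @return One-row tibble: `W`, `U`, `p`, `n_prime`, `n_other`,
#'   `mean_prime`, `sd_prime`, `mean_other`, `sd_other`.
#' @export
rank_sum_prime_vs_composite <- function(panel, include_round_one = TRUE,
                                        ...) {
  pr <- primes_in(1, max(panel$round))
  dat <- if (include_round_one) panel else panel[panel$round != 1L, ]
  x <- dat$effective_contribution[dat$round %in% pr]
  y <- dat$effective_contribution[!dat$round %in% pr]
  ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided", ...))
  # complete ties leave the tie-corrected variance at zero; there is no
  # evidence against the null, so report p = 1
  if (is.nan(ht$p.value)) ht$p.value <- 1
  n1 <- length(x)
  tibble(
    W = unname(ht$statistic) + n1 * (n1 + 1) / 2,
    U = unname(ht$statistic),
    p = ht$p.value,
    n_prime = n1,
    n_other = length(y),
    mean_prime = mean(x), sd_prime = sd(x),
    mean_other = mean(y), sd_other = sd(y)
  )
}

#' Descriptive summaries of a contribution panel
#'
#' @param panel A `contribution_panel`.
#' @return List of two tibbles: `per_round` (`round`, `mean`, `sd`,
#'   `median`, `share_positive`) and `by_primality` (`group` in
#'   `c("prime", "composite", "round_1")`, `n`, `mean`, `sd`).
#' @export
panel_descriptives <- function(panel) {
  pr <- primes_in(1, max(panel$round))
  per_round <- panel |>
    dplyr::group_by(round = .data$round) |>
    dplyr::summarise(
      mean = mean(.data$effective_contribution),
      sd = sd(.data$effective_contribution),
      median = median(.data$effective_contribution),
      share_positive = mean(.data$effective_contribution > 0),
      .groups = "drop"
    )
  by_primality <- panel |>
    dplyr::mutate(group = dplyr::case_when(
      .data$round %in% pr ~ "prime",
      .data$round == 1L ~ "round_1",
      TRUE ~ "composite"
    )) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$effective_contribution),
      sd = sd(.data$effective_contribution),
      .groups = "drop"
    )
  list(per_round = per_round, by_primality = by_primality)
}
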