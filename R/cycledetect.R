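#' Eligibility of a contribution series for cycle detection
#'
#' A per-participant series enters the autocorrelation census only if it
#' is neither always 0 nor weakly monotonic over time. Weak monotonicity
#' (entirely non-increasing or non-decreasing) also excludes constant
#' series, whose sample ACF is undefined; a nonzero constant series is
#' reported with reason `"constant"` for clarity.
#'
#' @param series Numeric vector of per-round decisions, length `>= 3`.
#' @return List with `eligible` flag and `reason` in
#'   `c("all_zero", "constant", "monotonic", "none")`.
#' @examples
#' is_eligible(c(5, 0, 7, 0, 3))   # eligible
#' is_eligible(rep(0, 27))         # all_zero
#' @export
is_eligible <- function(series) {
  stopifnot(length(series) >= 3)
  if (all(series == 0)) {
    return(list(eligible = FALSE, reason = "all_zero"))
  }
  d <- diff(series)
  if (all(d == 0)) {
    return(list(eligible = FALSE, reason = "constant"))
  }
  if (all(d >= 0) || all(d <= 0)) {
    return(list(eligible = FALSE, reason = "monotonic"))
  }
  list(eligible = TRUE, reason = "none")
}

#' Sample autocorrelation function
#'
#' The standard biased sample ACF:
#' `r_k = sum_{t=1}^{n-k} (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`
#' for `k = 1..max_lag`, computed via [stats::acf()].
#'
#' @param series Numeric series with nonzero variance (callers should
#'   filter with [is_eligible()]).
#' @param max_lag Largest lag, `1 <= max_lag < length(series)`.
#' @return Named numeric vector of `r_1..r_max_lag`.
#' @export
sample_acf <- function(series, max_lag = 13) {
  n <- length(series)
  if (max_lag < 1 || max_lag >= n) stop_config("need 1 <= max_lag < length(series)")
  if (var(series) == 0) stop_config("zero-variance series has no ACF")
  r <- as.numeric(acf(series, lag.max = max_lag, plot = FALSE,
                      demean = TRUE)$acf)[-1]
  setNames(r, seq_len(max_lag))
}

#' Lag of maximum autocorrelation
#'
#' Returns the smallest lag attaining the maximum of the signed ACF
#' values (ties break toward the smaller lag; no positivity requirement
#' by default).
#'
#' @param acf_values Numeric vector of ACF values at lags
#'   `1..length(acf_values)`.
#' @return Integer lag.
#' @export
max_acf_lag <- function(acf_values) {
  stopifnot(length(acf_values) >= 1)
  which.max(acf_values)[[1]]
}

#' Autocorrelation cycle census of a panel
#'
#' For each participant: filter by [is_eligible()], compute the sample
#' ACF of the effective-contribution series, find the
#' maximum-autocorrelation lag, and classify it as prime or not. The
#' summary counts how many of the population's series peak at a
#' prime-valued lag.
#'
#' @param panel A `contribution_panel`.
#' @param max_lag Largest lag searched; default 13 (`floor(27/2)`), since
#'   lags beyond half the series length rest on very few pairs.
#' @param require_positive_acf If `TRUE`, a maximum lag "exists" only
#'   when its ACF value is strictly positive; otherwise (default) the
#'   signed argmax always exists for eligible series.
#' @return List with `summary` (one-row tibble: `n_series`, `n_eligible`,
#'   `n_prime_max_lag`, `share_prime_of_all`, `share_prime_of_eligible`)
#'   and `classification` (per-participant tibble: `participant_id`,
#'   `eligible`, `reason`, `max_lag`, `max_lag_is_prime`).
#' @export
acf_census <- function(panel, max_lag = 13, require_positive_acf = FALSE) {
  series <- panel |>
    dplyr::arrange(.data$participant_id, .data$round) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(x = list(.data$effective_contribution),
                     .groups = "drop")
  cls <- purrr::map2_dfr(series$participant_id, series$x, function(id, x) {
    el <- is_eligible(x)
    if (!el$eligible) {
      return(tibble(participant_id = id, eligible = FALSE,
                    reason = el$reason, max_lag = NA_integer_,
                    max_lag_is_prime = NA))
    }
    r <- sample_acf(x, max_lag = min(max_lag, length(x) - 1L))
    lag <- max_acf_lag(r)
    if (require_positive_acf && r[lag] <= 0) {
      return(tibble(participant_id = id, eligible = TRUE, reason = "none",
                    max_lag = NA_integer_, max_lag_is_prime = NA))
    }
    tibble(participant_id = id, eligible = TRUE, reason = "none",
           max_lag = as.integer(lag), max_lag_is_prime = is_prime(lag))
  })
  n_series <- nrow(cls)
  n_eligible <- sum(cls$eligible)
  n_prime <- sum(cls$max_lag_is_prime, na.rm = TRUE)
  list(
    summary = tibble(
      n_series = n_series,
      n_eligible = n_eligible,
      n_prime_max_lag = n_prime,
      share_prime_of_all = if (n_series > 0) n_prime / n_series else 0,
      share_prime_of_eligible = if (n_eligible > 0) n_prime / n_eligible else 0
    ),
    classification = cls
  )
}
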