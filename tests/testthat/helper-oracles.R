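# independent oracles and small fixture builders, used across test files

# O(n^2) brute-force sample ACF: full-series mean, n-denominator
brute_force_acf <- function(x, max_lag) {
  n <- length(x)
  xb <- mean(x)
  denom <- sum((x - xb)^2)
  vapply(seq_len(max_lag), function(k) {
    num <- 0
    for (t in seq_len(n - k)) {
      num <- num + (x[t] - xb) * (x[t + k] - xb)
    }
    num / denom
  }, numeric(1))
}

# small default-shaped panel for structural tests
small_panel <- function(seed = 1, n = 64, ...) {
  generate_panel(panel_config(n_participants = n, matching_group_size = 16,
                              seed = seed, ...))
}

# overwrite a panel's effective contributions (and decisions) in place
set_contributions <- function(panel, eff, endowment = 20) {
  panel$effective_contribution <- as.integer(eff)
  panel$decision <- ifelse(panel$treatment == "provision",
                           panel$effective_contribution,
                           endowment - panel$effective_contribution)
  panel
}

# hand-built 8-participant, 2-round panel with known group assignments,
# for checking the two peer-lag conventions against hand arithmetic
two_round_panel <- function() {
  ids <- letters[1:8]
  tibble::tibble(
    participant_id = rep(ids, 2),
    matching_group_id = "mg01",
    round_group_id = c(
      # round 1: {a,b,c,d}, {e,f,g,h}
      rep(c("r1g1", "r1g2"), each = 4),
      # round 2: {a,b,e,f}, {c,d,g,h}
      c("r2g1", "r2g1", "r2g2", "r2g2", "r2g1", "r2g1", "r2g2", "r2g2")
    ),
    treatment = "provision",
    round = rep(1:2, each = 8),
    decision = c(1:8, rep(0L, 8)),
    effective_contribution = c(1:8, rep(0L, 8))
  )
}

# prime-set row shaped like an enumerate_placebo_sets() result
prime_set_row <- function(max_round = 27) {
  p <- primes_in(1, max_round)
  tibble::tibble(set_id = 0L, scheme = "primes", members = list(p),
                 distance_to_primes = 0)
}
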