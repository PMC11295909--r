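test_that("the design-row law holds across panels and exclusion sets", {
  p <- small_panel(seed = 1)
  n <- 64
  expect_equal(nrow(build_design(p)), n * 26)
  expect_equal(nrow(build_design(p, exclude_rounds = 2)), n * 25)
  expect_equal(nrow(build_design(p, exclude_rounds = c(2, 3))), n * 24)
  expect_equal(nrow(build_design(p, exclude_rounds = c(5, 11, 20))), n * 23)
  expect_error(build_design(p, indicator_set = integer(0)),
               class = "primecoop_config_error")
  expect_error(build_design(p, exclude_rounds = 1), class = "primecoop_config_error")
  expect_error(build_design(p, exclude_rounds = 2:27), class = "primecoop_config_error")
  d <- build_design(p)
  expect_false(1 %in% d$round)
  expect_setequal(d$round[d$indicator == 1], primes_in(2, 27))
})

test_that("both peer-lag conventions match hand arithmetic", {
  p <- two_round_panel()
  prev <- build_design(p, indicator_set = 2, lag_peers = "previous_round_groupmates")
  # round-1 groups {a,b,c,d} with 1,2,3,4 and {e,f,g,h} with 5,6,7,8
  expect_equal(prev$peer_lag[prev$participant_id == "a"], (2 + 3 + 4) / 3)
  expect_equal(prev$peer_lag[prev$participant_id == "e"], (6 + 7 + 8) / 3)
  cur <- build_design(p, indicator_set = 2, lag_peers = "current_round_groupmates")
  # a's round-2 group-mates are b, e, f; their round-1 decisions 2, 5, 6
  expect_equal(cur$peer_lag[cur$participant_id == "a"], (2 + 5 + 6) / 3)
  expect_equal(cur$peer_lag[cur$participant_id == "c"], (4 + 7 + 8) / 3)
})

test_that("excluded rounds still feed lag construction", {
  p <- small_panel(seed = 2)
  d_all <- build_design(p)
  d_ex <- build_design(p, exclude_rounds = 2)
  # round-3 rows are identical: the lag for t = 3 reads round-2 decisions
  r3a <- d_all[d_all$round == 3, ]
  r3b <- d_ex[d_ex$round == 3, ]
  expect_identical(r3a$peer_lag, r3b$peer_lag)
})

test_that("Wald inference follows the fitted model and is deterministic", {
  p <- small_panel(seed = 3)
  d <- build_design(p)
  f1 <- fit_focal_model(d)
  f2 <- fit_focal_model(d)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_equal(f1$coefficients$ci_lower,
               f1$coefficients$estimate - 1.96 * f1$coefficients$se)
  expect_equal(f1$coefficients$z, f1$coefficients$estimate / f1$coefficients$se)
  expect_equal(f1$n_obs, nrow(d))
  expect_error(fit_focal_model(dplyr::mutate(d, indicator = 1L)),
               class = "primecoop_config_error")
  td <- tidy(f1)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  gl <- glance(f1)
  expect_equal(gl$nobs, nrow(d))
  expect_true(gl$converged)
})

test_that("known fixed effects are recovered from a constructed response", {
  # response generated from the fitted equation itself with iid noise
  truth <- c(5, 0.3, -0.1, 0.5)
  ok <- withr::with_seed(2024, vapply(1:200, function(i) {
    p <- small_panel(seed = 60000 + i, n = 32)
    d <- build_design(p)
    d$response <- truth[1] + truth[2] * d$peer_lag + truth[3] * d$round_value +
      truth[4] * d$indicator + rnorm(nrow(d), 0, 0.5)
    cf <- fit_focal_model(d)$coefficients
    all(abs(cf$estimate - truth) <= 3 * cf$se)
  }, logical(1)))
  expect_gte(mean(ok), 0.95)
})

test_that("the null panel leaves the prime indicator unidentified from noise", {
  # two-sided 95% CI excludes 0 in about 5% of null fits
  hits <- vapply(1:200, function(i) {
    p <- small_panel(seed = 70000 + i)
    cf <- fit_focal_model(build_design(p))$coefficients
    cr <- cf[cf$term == "indicator", ]
    cr$ci_lower > 0 || cr$ci_upper < 0
  }, logical(1))
  rate <- mean(hits)
  expect_lte(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("an injected prime-round effect is recovered by the focal model", {
  res <- vapply(1:60, function(i) {
    p <- generate_panel(panel_config(
      n_participants = 64, matching_group_size = 16, seed = 80000 + i,
      prime_effect_delta = 2, prime_effect_fraction = 0.5
    ))
    cr <- with(fit_focal_model(build_design(p)), coefficients)
    cr <- cr[cr$term == "indicator", ]
    cr$ci_lower <= 1 && 1 <= cr$ci_upper
  }, logical(1))
  expect_gte(mean(res), 0.9 - 3 * sqrt(0.9 * 0.1 / 60))
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  # one participant, rounds 1..6: primes {2,3,5} hold 1,2,3; others 4,5,6
  p <- tibble::tibble(
    participant_id = "p001", matching_group_id = "mg01",
    round_group_id = paste0("g", 1:6), treatment = "provision",
    round = 1:6, decision = c(4L, 1L, 2L, 5L, 3L, 6L),
    effective_contribution = c(4L, 1L, 2L, 5L, 3L, 6L)
  )
  rs <- rank_sum_prime_vs_composite(p)
  expect_equal(rs$p, 0.1)
  expect_equal(rs$U, 0)
  expect_equal(rs$W, 6)  # rank-sum of {1,2,3}
  rs2 <- rank_sum_prime_vs_composite(p, include_round_one = FALSE)
  expect_equal(rs2$n_other, 2)

  tied <- p; tied$effective_contribution <- 5L; tied$decision <- 5L
  expect_equal(rank_sum_prime_vs_composite(tied)$p, 1)

  big <- small_panel(seed = 4)
  shifted <- inject_prime_effect(big, delta = 5, fraction = 1, seed = 1)
  expect_lt(rank_sum_prime_vs_composite(shifted)$p, 0.001)
})

test_that("descriptives summarise rounds and primality groups", {
  p <- small_panel(seed = 5, n = 32)
  zero <- set_contributions(p, 0L)
  dz <- panel_descriptives(zero)
  expect_true(all(dz$per_round$mean == 0))
  expect_true(all(dz$per_round$share_positive == 0))
  const <- set_contributions(p, 7L)
  dc <- panel_descriptives(const)
  expect_true(all(dc$per_round$mean == 7))
  expect_true(all(dc$per_round$sd == 0))
  expect_setequal(dc$by_primality$group, c("prime", "composite", "round_1"))
  expect_equal(sum(dc$by_primality$n), nrow(p))
})
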