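test_that("schedule activity is divisibility with no action at time point 1", {
  expect_true(is_active(3, 9))
  expect_false(is_active(5, 7))
  expect_false(any(is_active(2:27, 1)))
  expect_error(is_active(1, 5), class = "primecoop_config_error")
})

test_that("generation play accumulates prisoner's dilemma payoffs by schedule", {
  cfg4 <- sim_config(max_time_point = 4)
  both_coop <- tibble::tibble(behaviour = "cooperator", period = c(2L, 2L))
  expect_equal(play_generation(both_coop, cfg4), c(6, 6))

  cfg2 <- sim_config(max_time_point = 2)
  mixed <- tibble::tibble(behaviour = c("cooperator", "defector"),
                          period = c(2L, 2L))
  expect_equal(play_generation(mixed, cfg2), c(0, 5))

  lonely <- tibble::tibble(behaviour = "cooperator", period = 2L)
  expect_equal(play_generation(lonely, sim_config()), 0)

  # agent active alone at a time point idles; never-active agent scores 0
  odd <- tibble::tibble(behaviour = c("defector", "defector", "cooperator"),
                        period = c(2L, 2L, 27L))
  pay <- withr::with_seed(1, play_generation(odd, sim_config(max_time_point = 26)))
  expect_equal(pay[3], 0)
  expect_equal(pay[1] + pay[2], 2 * 13 * 1)  # both defect at 13 even time points
})

test_that("pairwise comparison adopts by the Fermi rule", {
  pop <- tibble::tibble(behaviour = c("cooperator", "defector"),
                        period = c(3L, 2L))
  expect_error(pairwise_comparison_step(pop[1, ], 0, 1),
               class = "primecoop_config_error")
  # equal payoffs (or s = 0): adoption probability exactly 1/2
  changed <- withr::with_seed(11, vapply(1:2000, function(i) {
    !identical(pairwise_comparison_step(pop, c(4, 4), 1), pop)
  }, logical(1)))
  expect_lt(abs(mean(changed) - 0.5), 3 * sqrt(0.25 / 2000))
  changed0 <- withr::with_seed(12, vapply(1:2000, function(i) {
    !identical(pairwise_comparison_step(pop, c(9, 1), 0), pop)
  }, logical(1)))
  expect_lt(abs(mean(changed0) - 0.5), 3 * sqrt(0.25 / 2000))
  # strong selection: every adoption copies the higher-payoff genotype
  res <- withr::with_seed(13, lapply(1:200, function(i) {
    pairwise_comparison_step(pop, c(10, 0), 50)
  }))
  changed <- !vapply(res, identical, logical(1), pop)
  expect_true(any(changed))
  for (r in res[changed]) {
    expect_identical(r$behaviour, c("cooperator", "cooperator"))
    expect_identical(r$period, c(3L, 3L))
  }
})

test_that("runs terminate, flag fixation, and are seed-reproducible", {
  homog <- tibble::tibble(behaviour = rep("defector", 10), period = rep(4L, 10))
  one <- run_to_fixation(sim_config(population_size = 10, seed = 1), init = homog)
  expect_identical(one$generations, 0L)
  expect_true(one$fixated)

  cfg <- sim_config(population_size = 12, n_runs = 30, max_time_point = 12,
                    max_period = 12, seed = 5)
  a <- run_evolution(cfg)
  b <- run_evolution(cfg)
  expect_identical(a, b)
  expect_true(all(a$fixated | a$generations == cfg$max_generations))
  expect_true(all(a$period[a$fixated] >= 2))
})

test_that("neutral drift fixes a genotype at its initial frequency", {
  n <- 20; k <- 5
  init <- tibble::tibble(
    behaviour = rep(c("cooperator", "defector"), c(k, n - k)),
    period = rep(c(3L, 2L), c(k, n - k))
  )
  r <- run_evolution(sim_config(population_size = n, selection_intensity = 0,
                                n_runs = 500, seed = 99), init = init)
  expect_true(all(r$fixated))
  phat <- mean(r$behaviour == "cooperator")
  expect_lt(abs(phat - k / n), 3 * sqrt((k / n) * (1 - k / n) / 500))
})

test_that("fixated strategies map onto the stated contribution patterns", {
  s <- simulate_subject("cooperator", 2, 27)
  expect_equal(unname(s[as.character(seq(2, 26, 2))]), rep(20, 13))
  expect_equal(unname(s[as.character(seq(3, 27, 2))]), rep(0, 13))
  expect_true(all(simulate_subject("defector", 5, 27) == 0))
  s23 <- simulate_subject("cooperator", 23, 27)
  expect_equal(sum(s23 > 0), 1)
  expect_equal(unname(s23["23"]), 20)
})

test_that("predicted cooperation curves summarise the sampling distribution", {
  recs <- tibble::tibble(run_id = 1:40, behaviour = "cooperator", period = 2L,
                         generations = 10L, fixated = TRUE)
  cv <- predicted_cooperation_curve(recs, sample_size = 40, n_draws = 200, seed = 1)
  expect_false(1 %in% cv$round)
  even <- cv$round %% 2 == 0
  expect_true(all(cv$point[even] == 1 & cv$lower[even] == 1 & cv$upper[even] == 1))
  expect_true(all(cv$point[!even] == 0 & cv$upper[!even] == 0))

  defs <- tibble::tibble(run_id = 1:40, behaviour = "defector", period = 3L,
                         generations = 10L, fixated = TRUE)
  cvd <- predicted_cooperation_curve(defs, sample_size = 40, n_draws = 50, seed = 1)
  expect_true(all(cvd$point == 0))

  half <- dplyr::bind_rows(recs, defs)
  cvh <- predicted_cooperation_curve(half, sample_size = 256, n_draws = 4000, seed = 2)
  expect_true(all(abs(cvh$point[cvh$round %% 2 == 0] - 0.5) < 0.02))
  expect_true(all(cvh$lower <= cvh$point & cvh$point <= cvh$upper))
  expect_error(predicted_cooperation_curve(recs[recs$fixated == FALSE, ]),
               class = "primecoop_config_error")
})

test_that("the observed curve uses Wilson intervals over rounds 2..n", {
  p <- small_panel(seed = 6, n = 256)
  eff <- ifelse(p$participant_id %in% sprintf("p%03d", 1:64), 20L, 0L)
  p <- set_contributions(p, eff)
  cv <- empirical_full_cooperation_curve(p)
  expect_identical(cv$round, 2:27)
  expect_true(all(cv$point == 0.25))
  oracle <- stats::prop.test(64, 256, correct = FALSE)$conf.int
  expect_equal(cv$lower[1], oracle[1], tolerance = 1e-10)
  expect_equal(cv$upper[1], oracle[2], tolerance = 1e-10)

  all_full <- set_contributions(p, 20L)
  expect_true(all(empirical_full_cooperation_curve(all_full)$point == 1))
  none_full <- set_contributions(p, 3L)
  expect_true(all(empirical_full_cooperation_curve(none_full)$point == 0))
})

test_that("interval overlap uses closed intervals per round", {
  mk <- function(lo, up) tibble::tibble(round = 2:4, point = (lo + up) / 2,
                                        lower = lo, upper = up)
  a <- mk(c(0.1, 0.1, 0.1), c(0.3, 0.3, 0.3))
  expect_equal(overlap_report(a, a)$fraction_overlapping, 1)
  b <- mk(c(0.5, 0.5, 0.5), c(0.7, 0.7, 0.7))
  expect_equal(overlap_report(a, b)$fraction_overlapping, 0)
  touch <- mk(c(0.3, 0.5, 0.5), c(0.9, 0.9, 0.9))
  expect_equal(overlap_report(a, touch)$per_round$overlap, c(TRUE, FALSE, FALSE))
  expect_error(overlap_report(a, touch[1:2, ]), class = "primecoop_config_error")
})
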