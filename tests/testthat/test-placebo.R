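test_that("primality and interval sieves match the number line", {
  expect_false(is_prime(1))
  expect_false(is_prime(27))
  expect_true(all(is_prime(c(2, 3, 5, 7, 11, 13, 17, 19, 23))))
  expect_error(is_prime(0), class = "primecoop_config_error")
  expect_identical(primes_in(1, 27), c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L))
  expect_identical(composites_in(1, 9), c(4L, 6L, 8L, 9L))
  expect_identical(composites_in(19, 27), c(20L, 21L, 22L, 24L, 25L, 26L, 27L))
  expect_length(composites_in(1, 27), 17)
  # unit excluded from both classes
  expect_false(1 %in% composites_in(1, 27))
  expect_false(1 %in% primes_in(1, 27))
})

test_that("standard bin schemes require as many composites as primes per bin", {
  s <- standard_schemes()
  expect_equal(s$one_bin$bins$count, 9L)
  expect_equal(s$two_bins$bins$count, c(6L, 3L))
  expect_equal(s$three_bins$bins$count, c(4L, 3L, 2L))
  expect_equal(s$two_bins$bins$count,
               c(length(primes_in(1, 14)), length(primes_in(15, 27))))
  expect_equal(sum(s$three_bins$bins$count), length(primes_in(1, 27)))
})

test_that("enumeration counts equal products of binomial coefficients", {
  s <- standard_schemes()
  sets <- lapply(s, enumerate_placebo_sets)
  expected <- vapply(s, function(sc) {
    prod(vapply(seq_len(nrow(sc$bins)), function(b) {
      choose(length(composites_in(sc$bins$lo[b], sc$bins$hi[b])),
             sc$bins$count[b])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(vapply(sets, nrow, integer(1)), as.integer(expected),
               ignore_attr = TRUE)
  expect_equal(unname(expected), c(24310, 840, 420))
})

test_that("enumerated sets are valid, distinct and deterministic", {
  sets <- enumerate_placebo_sets(standard_schemes()$three_bins)
  comp <- composites_in(1, 27)
  for (m in sets$members) {
    expect_length(m, 9)
    expect_false(anyDuplicated(m) > 0)
    expect_true(all(m %in% comp))
    expect_equal(sum(m <= 9), 4)
    expect_equal(sum(m >= 10 & m <= 18), 3)
  }
  keys <- vapply(sets$members, paste, character(1), collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(sets, enumerate_placebo_sets(standard_schemes()$three_bins))
})

test_that("binned sets nest inside the one-bin enumeration", {
  sets1 <- enumerate_placebo_sets(standard_schemes()$one_bin)
  keys1 <- vapply(sets1$members, paste, character(1), collapse = ",")
  for (nm in c("two_bins", "three_bins")) {
    setsb <- enumerate_placebo_sets(standard_schemes()[[nm]])
    keysb <- vapply(setsb$members, paste, character(1), collapse = ",")
    expect_true(all(keysb %in% keys1))
  }
})

test_that("Euclidean distance to the primes is order-free and exact", {
  expect_equal(euclidean_distance_to_primes(primes_in(1, 27)), 0)
  ex <- c(4, 6, 8, 9, 10, 12, 14, 15, 16)
  expect_equal(euclidean_distance_to_primes(ex), sqrt(102))
  expect_equal(euclidean_distance_to_primes(rev(ex)),
               euclidean_distance_to_primes(ex))
  expect_equal(euclidean_distance_to_primes(sample(ex)),
               euclidean_distance_to_primes(ex))
  expect_error(euclidean_distance_to_primes(c(4, 6)),
               class = "primecoop_config_error")
})

test_that("the battery at the true prime set reproduces the focal fit", {
  p <- small_panel(seed = 11, n = 32)
  focal <- fit_focal_model(build_design(p))
  bat <- run_battery(p, prime_set_row())
  ind <- focal$coefficients[focal$coefficients$term == "indicator", ]
  expect_identical(bat$estimate, ind$estimate)
  expect_identical(bat$se, ind$se)
  expect_identical(bat$ci_lower, ind$ci_lower)
  expect_identical(bat$ci_upper, ind$ci_upper)
})

test_that("battery summaries count exceedance strictly and significance by CI", {
  p <- small_panel(seed = 12, n = 32)
  focal <- fit_focal_model(build_design(p))
  sets <- utils::head(enumerate_placebo_sets(standard_schemes()$two_bins), 6)
  bat <- run_battery(p, sets)
  expect_equal(nrow(bat), 6)
  s <- summarize_battery(bat, focal)
  expect_lte(s$overall$n_exceeding_focal, s$overall$n_sets)
  expect_equal(s$overall$n_positive_significant,
               sum(bat$estimate > 0 & bat$ci_lower > 0))
  # a battery equal to the focal fit in every entry never exceeds it (strict)
  bat_self <- run_battery(p, prime_set_row())
  s_self <- summarize_battery(bat_self, focal)
  expect_equal(s_self$overall$n_exceeding_focal, 0L)
  # all-negative estimates leave both counts at zero
  bat_neg <- bat
  bat_neg$estimate <- -abs(bat_neg$estimate)
  bat_neg$ci_lower <- bat_neg$estimate - 0.1
  s_neg <- summarize_battery(bat_neg, focal)
  expect_equal(s_neg$overall$n_positive_significant, 0L)
})

test_that("battery subsampling is seeded and reproducible", {
  p <- small_panel(seed = 13, n = 32)
  sets <- enumerate_placebo_sets(standard_schemes()$three_bins)
  b1 <- run_battery(p, sets, subsample = 5, seed = 3)
  b2 <- run_battery(p, sets, subsample = 5, seed = 3)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 5)
})

test_that("distance-coefficient association flags degeneracy and finds signal", {
  tab <- tibble::tibble(
    set_id = 1:4, scheme = "one_bin",
    members = replicate(4, composites_in(1, 27)[1:9], simplify = FALSE),
    distance_to_primes = c(1, 2, 3, 4),
    estimate = c(1, 2, 3, 4), se = 1, z = 1, p = 0.5,
    ci_lower = 0, ci_upper = 2, converged = TRUE
  )
  a <- distance_coefficient_association(tab)
  expect_equal(a$pearson, 1)
  expect_equal(a$spearman, 1)
  flat <- tab; flat$estimate <- rep(2, 4)
  af <- distance_coefficient_association(flat)
  expect_false(af$defined)
  expect_true(is.na(af$pearson))
  expect_error(distance_coefficient_association(tab[1:2, ]),
               class = "primecoop_config_error")
})

test_that("a low-prime contribution boost induces a positive distance association", {
  # elevated contributions at the low primes only: placebo sets close to
  # the primes mark nearby (unboosted) early composites, which the
  # boost-tilted trend overpredicts, depressing their coefficients;
  # far-from-prime sets mark late rounds and escape that, so the
  # distance-coefficient correlation is positive
  p <- small_panel(seed = 14, n = 64)
  low <- p
  sel <- low$round %in% c(2, 3, 5, 7)
  low$effective_contribution[sel] <- as.integer(
    pmin(20, low$effective_contribution[sel] + 4L)
  )
  low$decision <- ifelse(low$treatment == "provision",
                         low$effective_contribution,
                         20L - low$effective_contribution)
  sets <- enumerate_placebo_sets(standard_schemes()$one_bin)
  bat <- run_battery(low, sets, subsample = 40, seed = 5)
  a <- distance_coefficient_association(bat)
  expect_true(a$defined)
  expect_gt(a$pearson, 0)
})
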