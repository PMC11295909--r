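#' Configuration for the behaviour-schedule evolutionary simulation
#'
#' A finite population of agents carries a genotype pairing a behaviour
#' (cooperator or defector) with a cyclical activity schedule of period
#' `T >= 2`; an agent is active at intra-generational time point `t` iff
#' `t mod T = 0` (so no agent acts at time point 1). Active agents are
#' paired uniformly at random each time point to play one-shot prisoner's
#' dilemma games; accumulated payoffs drive a pairwise-comparison (Fermi)
#' imitation process, run until genotype fixation or `max_generations`.
#'
#' @param population_size Number of agents.
#' @param payoffs Named prisoner's dilemma entries `temptation > reward >
#'   punishment > sucker`.
#' @param selection_intensity Fermi slope `s >= 0`; `s = 0` is neutral
#'   drift.
#' @param max_generations Cap on generations per run.
#' @param max_time_point Intra-generational time points per generation
#'   (27 to match the experimental panel).
#' @param max_period Largest schedule period in the genotype space.
#' @param n_runs Independent runs for [run_evolution()].
#' @param events_per_generation Pairwise-comparison updates per
#'   generation (classic process: 1).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(population_size = 100,
                       payoffs = c(temptation = 5, reward = 3,
                                   punishment = 1, sucker = 0),
                       selection_intensity = 1.0,
                       max_generations = 1e5,
                       max_time_point = 27,
                       max_period = 27,
                       n_runs = 1e4,
                       events_per_generation = 1,
                       seed = NULL) {
  need <- c("temptation", "reward", "punishment", "sucker")
  if (!all(need %in% names(payoffs))) {
    stop_config("payoffs must name temptation, reward, punishment, sucker")
  }
  p <- payoffs[need]
  if (!(p["temptation"] > p["reward"] && p["reward"] > p["punishment"] &&
        p["punishment"] > p["sucker"])) {
    stop_config("need temptation > reward > punishment > sucker")
  }
  if (max_period < 2) stop_config("max_period must be >= 2")
  structure(list(
    population_size = as.integer(population_size),
    payoffs = p,
    selection_intensity = selection_intensity,
    max_generations = as.integer(max_generations),
    max_time_point = as.integer(max_time_point),
    max_period = as.integer(max_period),
    n_runs = as.integer(n_runs),
    events_per_generation = as.integer(events_per_generation),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' Schedule activity rule
#'
#' An agent with schedule period `T` is active at time point `t` iff `t`
#' is a multiple of `T`. Since every period is at least 2, no agent is
#' active at time point 1 and the model makes no prediction there.
#'
#' @param period Schedule period(s), `>= 2`.
#' @param time_point Time point(s), `>= 1`.
#' @return Logical vector.
#' @examples
#' is_active(3, 9)    # TRUE
#' is_active(2:27, 1) # all FALSE
#' @export
is_active <- function(period, time_point) {
  if (any(period < 2)) stop_config("period must be >= 2")
  if (any(time_point < 1)) stop_config("time_point must be >= 1")
  time_point %% period == 0
}

#' Play one generation of scheduled prisoner's dilemma games
#'
#' Reference R implementation of the intra-generational game phase: at
#' each time point the agents active under [is_active()] are paired
#' uniformly at random (one idles if the active count is odd) and each
#' pair plays a one-shot prisoner's dilemma with moves fixed by their
#' behaviours. Payoffs accumulate over time points; agents never active
#' keep the baseline 0.
#'
#' @param population Tibble with columns `behaviour`
#'   (`"cooperator"`/`"defector"`) and `period`.
#' @param config A [sim_config()].
#' @return Numeric vector of accumulated payoffs aligned with
#'   `population`.
#' @export
play_generation <- function(population, config = sim_config()) {
  stopifnot(nrow(population) > 0)
  p <- config$payoffs
  n <- nrow(population)
  coop <- population$behaviour == "cooperator"
  pay <- numeric(n)
  for (t in seq_len(config$max_time_point)) {
    act <- which(is_active(population$period, t))
    if (length(act) > 1L) act <- sample(act)
    m <- length(act) - length(act) %% 2L
    for (k in seq_len(m / 2)) {
      a <- act[2L * k - 1L]; b <- act[2L * k]
      if (coop[a] && coop[b]) {
        pay[a] <- pay[a] + p["reward"]; pay[b] <- pay[b] + p["reward"]
      } else if (coop[a]) {
        pay[a] <- pay[a] + p["sucker"]; pay[b] <- pay[b] + p["temptation"]
      } else if (coop[b]) {
        pay[a] <- pay[a] + p["temptation"]; pay[b] <- pay[b] + p["sucker"]
      } else {
        pay[a] <- pay[a] + p["punishment"]; pay[b] <- pay[b] + p["punishment"]
      }
    }
  }
  unname(pay)
}

#' One pairwise-comparison (Fermi) update
#'
#' A uniformly random focal agent adopts a uniformly random distinct
#' model agent's genotype with probability
#' `1 / (1 + exp(-s * (payoff_model - payoff_focal)))`; otherwise the
#' population is unchanged. At `s = 0` the adoption probability is
#' exactly 1/2 regardless of payoffs (neutral imitation).
#'
#' @param population Tibble with `behaviour` and `period` columns.
#' @param payoffs Numeric vector aligned with `population`.
#' @param selection_intensity Fermi slope `s`.
#' @return The (possibly updated) population tibble.
#' @export
pairwise_comparison_step <- function(population, payoffs,
                                     selection_intensity = 1.0) {
  n <- nrow(population)
  if (n < 2L) stop_config("population must have at least 2 agents")
  stopifnot(length(payoffs) == n)
  focal <- sample.int(n, 1L)
  model <- sample.int(n - 1L, 1L)
  if (model >= focal) model <- model + 1L
  pr <- 1 / (1 + exp(-selection_intensity * (payoffs[model] - payoffs[focal])))
  if (runif(1) < pr) {
    population$behaviour[focal] <- population$behaviour[model]
    population$period[focal] <- population$period[model]
  }
  population
}

#' Run the evolutionary simulation to fixation
#'
#' `run_evolution()` executes `config$n_runs` independent runs (compiled
#' engine); each run initialises the population uniformly over the
#' genotype space `{cooperator, defector} x {2..max_period}` (unless
#' `init` overrides it), alternates game play and pairwise-comparison
#' updates, and stops at genotype homogeneity or `max_generations`.
#' `run_to_fixation()` is the single-run variant.
#'
#' @param config A [sim_config()].
#' @param init Optional tibble with `behaviour` and `period` columns of
#'   length `population_size`, used as the initial population of *every*
#'   run (e.g. for neutral-drift checks).
#' @return A tibble of fixation records: `run_id`, `behaviour`, `period`,
#'   `generations`, `fixated`. For runs hitting the generation cap,
#'   `behaviour`/`period` are `NA` and `fixated` is `FALSE`.
#' @examples
#' run_evolution(sim_config(population_size = 10, n_runs = 5,
#'                          max_time_point = 8, max_period = 8, seed = 1))
#' @export
run_evolution <- function(config = sim_config(), init = NULL) {
  ib <- ip <- NULL
  if (!is.null(init)) {
    stopifnot(nrow(init) == config$population_size)
    ib <- as.integer(init$behaviour == "cooperator")
    ip <- as.integer(init$period)
    if (any(ip < 2)) stop_config("init periods must be >= 2")
  }
  res <- with_seed_if(config$seed, cpp_run_batch(
    n_runs = config$n_runs,
    pop_size = config$population_size,
    max_period = config$max_period,
    max_time_point = config$max_time_point,
    temptation = config$payoffs[["temptation"]],
    reward = config$payoffs[["reward"]],
    punishment = config$payoffs[["punishment"]],
    sucker = config$payoffs[["sucker"]],
    s = config$selection_intensity,
    max_generations = config$max_generations,
    events_per_generation = config$events_per_generation,
    init_behaviour = ib, init_period = ip
  ))
  tibble(
    run_id = seq_len(config$n_runs),
    behaviour = ifelse(res$fixated,
                       ifelse(res$behaviour == 1L, "cooperator", "defector"),
                       NA_character_),
    period = ifelse(res$fixated, res$period, NA_integer_),
    generations = res$generations,
    fixated = res$fixated
  )
}

#' @rdname run_evolution
#' @export
run_to_fixation <- function(config = sim_config(), init = NULL) {
  cfg1 <- config
  cfg1$n_runs <- 1L
  run_evolution(cfg1, init = init)
}

#' Simulate a fixated strategy as an experimental subject
#'
#' Maps a behaviour-schedule genotype onto per-round contribution
#' decisions for rounds `2..n_rounds`: a cooperator contributes the full
#' endowment at rounds where its schedule is active and 0 otherwise; a
#' defector contributes 0 everywhere.
#'
#' @param behaviour `"cooperator"` or `"defector"`.
#' @param period Schedule period, `>= 2`.
#' @param n_rounds Last round simulated (`>= 2`).
#' @param endowment Tokens contributed when cooperating.
#' @return Named numeric vector over rounds `2..n_rounds`.
#' @examples
#' simulate_subject("cooperator", 23, 27)  # single spike at round 23
#' @export
simulate_subject <- function(behaviour, period, n_rounds = 27,
                             endowment = 20) {
  stopifnot(n_rounds >= 2)
  rounds <- 2:n_rounds
  contrib <- if (behaviour == "cooperator") {
    endowment * as.numeric(is_active(period, rounds))
  } else {
    rep(0, length(rounds))
  }
  setNames(contrib, rounds)
}

new_cooperation_curve <- function(df, source) {
  df$source <- source
  out <- as_tibble(df)
  class(out) <- c("cooperation_curve", class(out))
  out
}

#' Predicted per-round cooperation curve from fixation records
#'
#' Each draw samples `sample_size` fixated runs (with replacement by
#' default), treats each run's fixated strategy as a subject via
#' [simulate_subject()], and records the proportion of full-contribution
#' plays per round `2..n_rounds`. The curve point is the mean over draws;
#' the bounds are the 2.5th/97.5th percentiles of the sampling
#' distribution.
#'
#' @param records Fixation records from [run_evolution()]; only rows with
#'   `fixated` are used.
#' @param sample_size Runs per draw (256, matching the experimental n).
#' @param n_draws Number of draws.
#' @param n_rounds Rounds simulated per subject.
#' @param replace Sample runs with replacement (default) or without.
#' @param seed Optional seed.
#' @return A `cooperation_curve` tibble: `round`, `point`, `lower`,
#'   `upper`, `n_draws`, `sample_size`, `source = "simulated"`.
#' @export
predicted_cooperation_curve <- function(records, sample_size = 256,
                                        n_draws = 1e4, n_rounds = 27,
                                        replace = TRUE, seed = NULL) {
  rec <- records[records$fixated, , drop = FALSE]
  if (nrow(rec) == 0L) stop_config("no fixated records")
  rounds <- 2:n_rounds
  # collapse to genotype frequencies: at most 2 * max_period profiles
  key <- paste(rec$behaviour, rec$period)
  freq <- table(key)
  geno <- do.call(rbind, strsplit(names(freq), " "))
  G <- t(vapply(seq_len(nrow(geno)),
                function(g) as.numeric(simulate_subject(geno[g, 1],
                                                        as.integer(geno[g, 2]),
                                                        n_rounds, 1)),
                numeric(length(rounds))))
  props <- with_seed_if(seed, {
    if (replace) {
      cnt <- rmultinom(n_draws, sample_size, as.numeric(freq))
      crossprod(cnt, G) / sample_size
    } else {
      if (sample_size > nrow(rec)) {
        stop_config("sample_size exceeds fixated runs when replace = FALSE")
      }
      gi <- match(key, names(freq))
      t(vapply(seq_len(n_draws), function(d) {
        idx <- sample.int(nrow(rec), sample_size)
        colSums(G[gi[idx], , drop = FALSE]) / sample_size
      }, numeric(length(rounds))))
    }
  })
  new_cooperation_curve(tibble(
    round = rounds,
    point = colMeans(props),
    lower = apply(props, 2, quantile, 0.025, names = FALSE),
    upper = apply(props, 2, quantile, 0.975, names = FALSE),
    n_draws = n_draws,
    sample_size = sample_size
  ), source = "simulated")
}

# Wilson score interval for a binomial proportion
wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Observed full-cooperation curve of a panel
#'
#' Per round `2..n_rounds`, the proportion of decisions whose effective
#' contribution equals the endowment, with a Wilson score 95% interval.
#'
#' @param panel A `contribution_panel`.
#' @param endowment Full-cooperation level; defaults to the panel
#'   config's endowment.
#' @return A `cooperation_curve` tibble with `source = "observed"`.
#' @export
empirical_full_cooperation_curve <- function(panel, endowment = NULL) {
  endowment <- endowment %||% panel_config_of(panel)$endowment
  df <- panel |>
    dplyr::filter(.data$round >= 2) |>
    dplyr::group_by(round = .data$round) |>
    dplyr::summarise(
      x = sum(.data$effective_contribution == endowment),
      n = dplyr::n(), .groups = "drop"
    )
  ci <- wilson_interval(df$x, df$n)
  new_cooperation_curve(tibble(
    round = df$round,
    point = df$x / df$n,
    lower = ci[, "lower"],
    upper = ci[, "upper"],
    n_draws = NA_integer_,
    sample_size = df$n
  ), source = "observed")
}

#' Interval-overlap report between two cooperation curves
#'
#' Per round, `TRUE` iff the two curves' 95% intervals intersect as
#' closed intervals (touching endpoints count as overlap), plus the
#' fraction of rounds overlapping.
#'
#' @param simulated,observed `cooperation_curve` tibbles over the same
#'   rounds.
#' @return List with `per_round` (tibble `round`, `overlap`) and
#'   `fraction_overlapping`.
#' @export
overlap_report <- function(simulated, observed) {
  if (!identical(as.integer(simulated$round), as.integer(observed$round))) {
    stop_config("curves must cover identical round ranges")
  }
  ov <- simulated$lower <= observed$upper & observed$lower <= simulated$upper
  list(
    per_round = tibble(round = simulated$round, overlap = ov),
    fraction_overlapping = mean(ov)
  )
}
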