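#' Configuration for the synthetic public-goods-game panel generator
#'
#' Describes a strangers-condition panel: `n_participants` players in
#' matching groups of `matching_group_size`, reshuffled into play groups of
#' `group_size` every round, making integer contribution decisions in
#' `[0, endowment]` over `n_rounds` one-shot rounds. The behavioural mix is
#' a population of archetypes:
#'
#' * `free_rider` — contributes nothing, ever;
#' * `conditional_cooperator` — partial adjustment toward the observed
#'   mean of last round's group-mates, shrunk by a multiplicative decay;
#' * `persistent_contributor` — sporadic contributions at a stable rate
#'   throughout, sustaining the late-round tail of cooperation;
#' * `prime_cycler` — contributes the full endowment at prime-numbered
#'   rounds only (share 0 by default).
#'
#' The default mixture and decline parameters are calibrated so that the
#' grand mean effective contribution starts near 6.5 tokens in round 1,
#' falls to roughly 1 token by round 27, and the per-round median hits 0
#' by round 3.
#'
#' @param n_participants,n_rounds,group_size,matching_group_size Panel
#'   dimensions. `n_participants` must be divisible by
#'   `matching_group_size`, and that by `group_size`.
#' @param multiplier Public-good return factor applied to the group sum.
#' @param endowment Tokens available per round.
#' @param archetype_mix Named proportions over the four archetypes; must
#'   sum to 1 (tolerance 1e-9).
#' @param decline_params List: `initial_mean` and `initial_sd` of the
#'   latent round-1 contribution of non-free-riders (tokens), `decay`
#'   (per-round multiplicative shrink of conditional cooperators) and
#'   `adjust_weight` (weight on last round's group-mates' mean versus own
#'   lagged decision).
#' @param noise_params List: `cc_sd`, round-to-round latent noise of
#'   conditional cooperators; `persist_rate` and `persist_mean`,
#'   `persist_sd`, the contribution probability and latent amount of
#'   persistent contributors.
#' @param prime_effect_delta Tokens added at prime rounds for affected
#'   participants (applied post hoc via [inject_prime_effect()]).
#' @param prime_effect_fraction Proportion of participants affected.
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return A validated `panel_config` list.
#' @seealso [generate_panel()]
#' @export
panel_config <- function(n_participants = 256,
                         n_rounds = 27,
                         group_size = 4,
                         matching_group_size = 16,
                         multiplier = 0.4,
                         endowment = 20,
                         archetype_mix = c(free_rider = 0.40,
                                           conditional_cooperator = 0.45,
                                           persistent_contributor = 0.15,
                                           prime_cycler = 0.00),
                         decline_params = list(initial_mean = 11,
                                               initial_sd = 6,
                                               decay = 0.87,
                                               adjust_weight = 1),
                         noise_params = list(cc_sd = 1.6,
                                             persist_rate = 0.45,
                                             persist_mean = 7,
                                             persist_sd = 3),
                         prime_effect_delta = 0,
                         prime_effect_fraction = 0,
                         seed = NULL) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_rounds = as.integer(n_rounds),
    group_size = as.integer(group_size),
    matching_group_size = as.integer(matching_group_size),
    multiplier = multiplier,
    endowment = as.integer(endowment),
    archetype_mix = archetype_mix,
    decline_params = decline_params,
    noise_params = noise_params,
    prime_effect_delta = prime_effect_delta,
    prime_effect_fraction = prime_effect_fraction,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_panel_config(cfg)
  structure(cfg, class = "panel_config")
}

validate_panel_config <- function(cfg) {
  with(cfg, {
    if (n_participants %% matching_group_size != 0L) {
      stop_config("n_participants must be divisible by matching_group_size")
    }
    if (matching_group_size %% group_size != 0L) {
      stop_config("matching_group_size must be divisible by group_size")
    }
    need <- c("free_rider", "conditional_cooperator",
              "persistent_contributor", "prime_cycler")
    if (!all(need %in% names(archetype_mix))) {
      stop_config("archetype_mix must name all four archetypes")
    }
    if (any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-9) {
      stop_config("archetype_mix proportions must be nonnegative and sum to 1")
    }
    if (multiplier < 0) stop_config("multiplier must be nonnegative")
    if (endowment <= 0) stop_config("endowment must be positive")
    if (prime_effect_delta < 0 || prime_effect_fraction < 0 ||
        prime_effect_fraction > 1) {
      stop_config("invalid prime effect parameters")
    }
  })
  invisible(cfg)
}

#' Randomly partition a matching group into play groups
#'
#' Draws a uniformly random partition of `members` into groups of
#' `group_size` (uniform over partitions into unordered groups), as the
#' strangers condition reshuffles participants every round.
#'
#' @param members Vector of participant identifiers.
#' @param group_size Players per group; must divide `length(members)`.
#' @return Integer vector of group indices (1, 2, ...) aligned with
#'   `members`.
#' @examples
#' withr::with_seed(1, reshuffle_groups(1:8, 4))
#' @export
reshuffle_groups <- function(members, group_size) {
  n <- length(members)
  if (n %% group_size != 0L) {
    stop_config("member count not divisible by group_size")
  }
  idx <- sample.int(n)
  grp <- integer(n)
  grp[idx] <- rep(seq_len(n %/% group_size), each = group_size)
  grp
}

#' Generate a synthetic strangers-condition contribution panel
#'
#' Simulates the panel described by a [panel_config()]: every round each
#' matching group is independently reshuffled into play groups, each
#' participant makes an integer decision, and the common response scale is
#' the *effective contribution* (the contribution itself under the
#' provision framing; endowment minus withdrawal under maintenance).
#' Treatments are assigned 50/50 at the matching-group level and are
#' cosmetic: the effective-contribution process is framing-free.
#'
#' Round 1 decisions of non-free-riders are drawn from the initial-mean
#' distribution; from round 2 on, conditional cooperators adjust toward
#' the observed mean of their previous round's group-mates with
#' multiplicative decay, which reproduces the canonical decline of
#' contributions in repeated one-shot play.
#'
#' If `config$prime_effect_delta > 0` and `config$prime_effect_fraction >
#' 0`, a random fraction of participants add `delta` tokens to their
#' latent decision at every prime-numbered round *during* generation, so
#' group-mates observe the boosted contributions and conditional
#' cooperators react to them — the data-generating process the focal
#' model's prime indicator is meant to recover. For a purely post hoc
#' boost of an existing panel see [inject_prime_effect()].
#'
#' @param config A [panel_config()].
#' @return A `contribution_panel`: a tibble with one row per participant
#'   per round and columns `participant_id`, `matching_group_id`,
#'   `round_group_id`, `treatment`, `round`, `decision`,
#'   `effective_contribution`; the config is kept in attribute `"config"`.
#' @examples
#' p <- generate_panel(panel_config(n_participants = 32,
#'                                  matching_group_size = 16, seed = 1))
#' dplyr::summarise(dplyr::group_by(p, round),
#'                  mean = mean(effective_contribution))
#' @export
generate_panel <- function(config = panel_config()) {
  validate_panel_config(config)
  with_seed_if(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(cfg) {
  n <- cfg$n_participants
  R <- cfg$n_rounds
  E <- cfg$endowment
  mix <- cfg$archetype_mix
  dp <- cfg$decline_params
  np <- cfg$noise_params

  archetype <- sample(names(mix), n, replace = TRUE, prob = mix)
  mg <- rep(seq_len(n %/% cfg$matching_group_size),
            each = cfg$matching_group_size)
  treatment_mg <- rep_len(c("provision", "maintenance"), max(mg))
  treatment <- treatment_mg[mg]
  prime_rounds <- primes_in(1, R)

  eff <- matrix(0L, nrow = n, ncol = R)        # effective contributions
  grp <- matrix(0L, nrow = n, ncol = R)        # within-matching-group group index
  is_fr <- archetype == "free_rider"
  is_cc <- archetype == "conditional_cooperator"
  is_pc <- archetype == "persistent_contributor"
  is_cy <- archetype == "prime_cycler"

  # generation-time prime-round boost: affected participants add delta to
  # their latent decision at prime rounds, so group-mates observe (and
  # conditional cooperators react to) the boosted contributions
  boosted <- rep(FALSE, n)
  if (cfg$prime_effect_delta > 0 && cfg$prime_effect_fraction > 0) {
    n_hit <- round(cfg$prime_effect_fraction * n)
    boosted[sample.int(n, n_hit)] <- TRUE
  }

  peer_mean_prev <- rep(NA_real_, n)
  for (t in seq_len(R)) {
    for (m in seq_len(max(mg))) {
      sel <- which(mg == m)
      grp[sel, t] <- reshuffle_groups(sel, cfg$group_size)
    }
    x <- numeric(n)
    if (t == 1L) {
      ini <- rnorm(n, dp$initial_mean, dp$initial_sd)
      x[is_cc | is_pc] <- ini[is_cc | is_pc]
    } else {
      x[is_cc] <- dp$decay *
        (dp$adjust_weight * peer_mean_prev[is_cc] +
           (1 - dp$adjust_weight) * eff[is_cc, t - 1L]) +
        rnorm(sum(is_cc), 0, np$cc_sd)
      x[is_pc] <- rbinom(sum(is_pc), 1L, np$persist_rate) *
        rnorm(sum(is_pc), np$persist_mean, np$persist_sd)
    }
    if (t %in% prime_rounds) x[is_cy] <- E
    x[is_fr] <- 0
    if (t %in% prime_rounds) x[boosted] <- x[boosted] + cfg$prime_effect_delta
    eff[, t] <- as.integer(clamp(round(x), 0, E))

    # observed group-mates' mean this round, feeding next round's decisions
    key <- paste(mg, grp[, t], sep = ":")
    gsum <- tapply(eff[, t], key, sum)[key]
    peer_mean_prev <- (as.numeric(gsum) - eff[, t]) / (cfg$group_size - 1)
  }

  ids <- sprintf("p%03d", seq_len(n))
  panel <- tibble(
    participant_id = rep(ids, times = R),
    matching_group_id = rep(sprintf("mg%02d", mg), times = R),
    round_group_id = sprintf("mg%02d_r%02d_g%d",
                             rep(mg, times = R),
                             rep(seq_len(R), each = n),
                             as.vector(grp)),
    treatment = rep(treatment, times = R),
    round = rep(seq_len(R), each = n),
    effective_contribution = as.integer(as.vector(eff))
  )
  panel$decision <- ifelse(panel$treatment == "provision",
                           panel$effective_contribution,
                           E - panel$effective_contribution)
  panel <- panel[, c("participant_id", "matching_group_id", "round_group_id",
                     "treatment", "round", "decision",
                     "effective_contribution")]
  new_panel(panel, cfg)
}

new_panel <- function(df, config) {
  out <- as_tibble(df)
  attr(out, "config") <- config
  class(out) <- c("contribution_panel", class(out))
  out
}

#' Retrieve the config attached to a panel
#' @param panel A `contribution_panel`.
#' @return The [panel_config()] used to generate it, or a default-valued
#'   config if none is attached (e.g. a panel read from file).
#' @export
panel_config_of <- function(panel) {
  attr(panel, "config") %||% panel_config()
}

#' Per-round payoffs of a contribution panel
#'
#' Computes each participant's round payoff under their treatment's payoff
#' function. With group members indexed by `j` and effective contributions
#' `c_j`: provision pays `endowment - c_i + multiplier * sum_j c_j`;
#' maintenance pays `w_i + multiplier * sum_j c_j` with withdrawal
#' `w_i = endowment - c_i`. The two framings are monetarily equivalent.
#'
#' @param panel A `contribution_panel`.
#' @param multiplier,endowment Game parameters; default from the panel's
#'   config.
#' @return Tibble `participant_id`, `round`, `payoff`.
#' @export
compute_payoffs <- function(panel, multiplier = NULL, endowment = NULL) {
  cfg <- panel_config_of(panel)
  multiplier <- multiplier %||% cfg$multiplier
  endowment <- endowment %||% cfg$endowment
  panel |>
    dplyr::group_by(.data$round, .data$round_group_id) |>
    dplyr::mutate(group_sum = sum(.data$effective_contribution)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      payoff = ifelse(
        .data$treatment == "provision",
        endowment - .data$decision + multiplier * .data$group_sum,
        .data$decision + multiplier * .data$group_sum
      )
    ) |>
    dplyr::select("participant_id", "round", "payoff")
}

#' Inject a contribution boost at prime-numbered rounds
#'
#' Adds `delta` tokens to the effective contribution of a random fraction
#' of participants at every prime-numbered round, clipping at the
#' endowment (never an error); non-prime rounds and unaffected
#' participants are untouched. Decisions are updated consistently with
#' each row's treatment. Used for parameter-recovery exercises: the
#' expected prime-minus-nonprime mean difference is `delta * fraction`
#' (minus clipping losses).
#'
#' @param panel A `contribution_panel`.
#' @param delta Tokens added at prime rounds (`>= 0`).
#' @param fraction Proportion of participants affected, in `[0, 1]`;
#'   `round(fraction * n)` participants are sampled without replacement.
#' @param seed Optional seed for the participant draw.
#' @return The modified panel (same shape, attributes preserved).
#' @export
inject_prime_effect <- function(panel, delta, fraction, seed = NULL) {
  if (delta < 0) stop_config("delta must be nonnegative")
  if (fraction < 0 || fraction > 1) stop_config("fraction must be in [0, 1]")
  cfg <- panel_config_of(panel)
  if (delta == 0 || fraction == 0) return(panel)
  ids <- unique(panel$participant_id)
  n_hit <- round(fraction * length(ids))
  if (n_hit == 0L) return(panel)
  hit <- with_seed_if(seed, sample(ids, n_hit))
  prime_rounds <- primes_in(1, max(panel$round))
  sel <- panel$participant_id %in% hit & panel$round %in% prime_rounds
  eff <- panel$effective_contribution
  eff[sel] <- as.integer(clamp(eff[sel] + delta, 0, cfg$endowment))
  panel$effective_contribution <- eff
  panel$decision <- ifelse(panel$treatment == "provision",
                           eff, cfg$endowment - eff)
  panel
}
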