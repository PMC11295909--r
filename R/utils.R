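# internal helpers shared across modules

# clip to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run `expr` under `seed` if non-NULL, otherwise in the ambient RNG stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# derive a stage-keyed child seed from a master seed so that one stage's
# randomness is unaffected by another stage's parameters; kept < 2^31
child_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  key <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(master) * 7919 + key) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

stop_config <- function(msg) abort(msg, class = "primecoop_config_error")
stop_validation <- function(msg) abort(msg, class = "primecoop_validation_error")
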