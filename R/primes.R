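#' Primality test
#'
#' Standard primality on positive integers; 1 is neither prime nor
#' composite. Vectorised.
#'
#' @param n Vector of integers, all `>= 1`.
#' @return Logical vector, `TRUE` where `n` is prime.
#' @examples
#' is_prime(1:10)
#' @export
is_prime <- function(n) {
  if (length(n) == 0L) return(logical(0))
  if (any(!is.finite(n)) || any(n < 1) || any(n != floor(n))) {
    stop_config("`n` must contain integers >= 1")
  }
  vapply(as.integer(n), function(k) {
    if (k < 2L) return(FALSE)
    if (k < 4L) return(TRUE)
    if (k %% 2L == 0L) return(FALSE)
    d <- 3L
    while (d * d <= k) {
      if (k %% d == 0L) return(FALSE)
      d <- d + 2L
    }
    TRUE
  }, logical(1))
}

#' Primes and composites in an integer interval
#'
#' `primes_in()` returns the primes in `[lo, hi]`; `composites_in()` the
#' integers that are neither prime nor 1 (the unit is excluded from both
#' classes, so `composites_in(1, 27)` has 17 elements, not 18).
#'
#' @param lo,hi Inclusive integer interval bounds, `1 <= lo <= hi`.
#' @return Ordered integer vector.
#' @examples
#' primes_in(1, 27)     # the nine primes up to 27
#' composites_in(1, 9)  # 4, 6, 8, 9
#' @export
primes_in <- function(lo, hi) {
  check_interval(lo, hi)
  x <- seq.int(lo, hi)
  x[is_prime(x)]
}

#' @rdname primes_in
#' @export
composites_in <- function(lo, hi) {
  check_interval(lo, hi)
  x <- seq.int(lo, hi)
  x[!is_prime(x) & x != 1L]
}

check_interval <- function(lo, hi) {
  if (!is_count(lo) || !is_count(hi) || lo > hi) {
    stop_config("need integer bounds 1 <= lo <= hi")
  }
  invisible(NULL)
}

#' Bin schemes for placebo-prime construction
#'
#' A bin scheme partitions the round interval `[1, max_round]` into
#' inclusive integer bins and requires, per bin, as many composite numbers
#' as there are primes in that bin. The three standard schemes over
#' `[1, 27]` are: one bin (`[1,27]`: 9), two bins (`[1,14]`: 6,
#' `[15,27]`: 3) and three bins (`[1,9]`: 4, `[10,18]`: 3, `[19,27]`: 2).
#'
#' @param name One of `"one_bin"`, `"two_bins"`, `"three_bins"`.
#' @param breaks For [bin_scheme()], an ordered vector of bin lower bounds
#'   starting at 1; the last bin ends at `max_round`.
#' @param max_round Upper end of the interval (default 27).
#' @return A `bin_scheme` object: a list with `name` and a tibble `bins`
#'   holding columns `lo`, `hi`, `count` (required composites per bin,
#'   equal to the prime count in the bin).
#' @examples
#' standard_schemes()
#' @export
bin_scheme <- function(breaks, max_round = 27, name = NULL) {
  stopifnot(is.numeric(breaks), breaks[1] == 1, !is.unsorted(breaks, strictly = TRUE))
  lo <- as.integer(breaks)
  hi <- c(lo[-1] - 1L, as.integer(max_round))
  if (any(hi < lo)) stop_config("empty bin in scheme")
  bins <- tibble(
    lo = lo, hi = hi,
    count = vapply(seq_along(lo), function(b) length(primes_in(lo[b], hi[b])), integer(1))
  )
  n_comp <- vapply(seq_along(lo), function(b) length(composites_in(lo[b], hi[b])), integer(1))
  if (any(bins$count > n_comp)) {
    stop_config("a bin requires more composites than it contains")
  }
  structure(
    list(name = name %||% paste0(length(lo), "_bins"), bins = bins,
         max_round = as.integer(max_round)),
    class = "bin_scheme"
  )
}

#' @rdname bin_scheme
#' @export
standard_schemes <- function() {
  list(
    one_bin    = bin_scheme(1, 27, name = "one_bin"),
    two_bins   = bin_scheme(c(1, 15), 27, name = "two_bins"),
    three_bins = bin_scheme(c(1, 10, 19), 27, name = "three_bins")
  )
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("<bin_scheme>", x$name, "over [1,", x$max_round, "]\n")
  print(x$bins)
  invisible(x)
}

#' Enumerate placebo-prime sets under a bin scheme
#'
#' Exhaustively enumerates every set of composite numbers matching the
#' scheme's per-bin counts (the per-bin counts equal the per-bin prime
#' counts, so every set has as many members as there are primes in the
#' interval — nine over `[1, 27]`). Order is deterministic lexicographic:
#' within-bin combinations in [utils::combn()] order, earlier bins varying
#' slowest.
#'
#' @param scheme A [bin_scheme()].
#' @return A tibble with one row per placebo set: `set_id`, `scheme`,
#'   `members` (list-column of sorted integer vectors) and
#'   `distance_to_primes` (see [euclidean_distance_to_primes()]).
#' @examples
#' nrow(enumerate_placebo_sets(standard_schemes()$three_bins))  # 420
#' @export
enumerate_placebo_sets <- function(scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  per_bin <- lapply(seq_len(nrow(scheme$bins)), function(b) {
    comp <- composites_in(scheme$bins$lo[b], scheme$bins$hi[b])
    k <- scheme$bins$count[b]
    if (k > length(comp)) stop_config("infeasible bin counts")
    cols <- combn(comp, k)
    lapply(seq_len(ncol(cols)), function(j) cols[, j])
  })
  sets <- Reduce(
    function(acc, nxt) {
      out <- vector("list", length(acc) * length(nxt))
      i <- 1L
      for (a in acc) for (b in nxt) { out[[i]] <- c(a, b); i <- i + 1L }
      out
    },
    per_bin[-1],
    per_bin[[1]]
  )
  members <- lapply(sets, function(s) sort(as.integer(s)))
  dist <- vapply(members, euclidean_distance_to_primes, numeric(1),
                 max_round = scheme$max_round)
  tibble(
    set_id = seq_along(members),
    scheme = scheme$name,
    members = members,
    distance_to_primes = dist
  )
}

#' Euclidean distance from a placebo set to the primes
#'
#' Sorts the member set and the primes of `[1, max_round]` ascending and
#' returns the L2 norm of the componentwise difference of the two vectors.
#' The embedding is order-free: any permutation of `members` gives the
#' same distance.
#'
#' @param members Integer vector with as many elements as there are primes
#'   in `[1, max_round]` (nine when `max_round = 27`).
#' @param max_round Interval end defining the reference prime set.
#' @return Nonnegative scalar distance.
#' @examples
#' euclidean_distance_to_primes(c(4, 6, 8, 9, 10, 12, 14, 15, 16))  # sqrt(102)
#' @export
euclidean_distance_to_primes <- function(members, max_round = 27) {
  p <- primes_in(1, max_round)
  if (length(members) != length(p) || anyDuplicated(members)) {
    stop_config(sprintf("`members` must be %d distinct integers", length(p)))
  }
  sqrt(sum((sort(as.double(members)) - as.double(p))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
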