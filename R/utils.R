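# Deterministic substream seeding: every source of randomness in the model is
# derived from one master seed so that a run manifest (seed + parameter digest)
# reproduces any result bit-for-bit. Streams are identified by small integer
# tags; per-individual streams additionally mix in the individual id but NOT
# the scenario arm, so the two arms of a comparison share random numbers.
STREAM_POPULATION <- 1L
STREAM_TRIAL <- 2L
STREAM_DES <- 3L
STREAM_PSA <- 4L

#' Derive a substream seed from a master seed
#'
#' Mixes a master seed with one or more integer tags into a new seed in
#' `[1, 2^31 - 2]`. Used internally to give the population generator, the
#' synthetic trial, each simulated individual and each PSA iteration their own
#' reproducible random-number stream.
#'
#' @param master integer master seed.
#' @param ... integer tags (stream id, individual id, iteration number, ...).
#' @return A single integer seed.
#' @export
mix_seed <- function(master, ...) {
  tags <- c(master, ...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- 104729
  for (k in tags) {
    k <- as.numeric(k) %% m
    s <- (s * 48271 + k + 1) %% m
  }
  as.integer(if (s < 1) s + 1 else s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Present value of a point payment under continuous annual discounting
#'
#' @param x amount.
#' @param t time in years from model entry.
#' @param rate annual discount rate (default 0.035).
#' @return Discounted amount `x * (1 + rate)^(-t)`.
#' @export
discount_point <- function(x, t, rate = 0.035) {
  stopifnot(rate >= 0)
  x * (1 + rate)^(-t)
}

#' Present value of a constant annual flow over an interval
#'
#' Integrates `flow * (1 + rate)^(-t)` over `[t0, t1]`, the continuous-time
#' analogue of annual discounting used throughout the cost and QALY accrual.
#'
#' @param flow amount per year.
#' @param t0,t1 interval bounds in years, `t1 >= t0 >= 0`.
#' @param rate annual discount rate.
#' @return Discounted total for the interval.
#' @export
discount_flow <- function(flow, t0, t1, rate = 0.035) {
  stopifnot(rate >= 0, all(t1 >= t0), all(t0 >= 0))
  if (rate == 0) {
    return(flow * (t1 - t0))
  }
  lr <- log1p(rate)
  flow * ((1 + rate)^(-t0) - (1 + rate)^(-t1)) / lr
}

# Collect-all validation helper: accumulates messages, then throws once.
validator <- function() {
  problems <- character(0)
  list(
    check = function(ok, msg) {
      if (!isTRUE(ok)) problems[[length(problems) + 1L]] <<- msg
      invisible(ok)
    },
    fail_if_any = function(context) {
      if (length(problems)) {
        stop(sprintf(
          "%s: %d problem(s)\n  - %s",
          context, length(problems), paste(problems, collapse = "\n  - ")
        ), call. = FALSE)
      }
      invisible(TRUE)
    },
    problems = function() problems
  )
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
is_nonneg <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)
is_pos <- function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0)

# FNV-1a hash of a string, reported as hex; used for the run-manifest
# parameter digest (no external digest dependency).
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
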