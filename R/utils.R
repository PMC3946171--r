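# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator functions are reproducible
#' without disturbing the caller's random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number.", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# scalar validators ----------------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d.", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_number <- function(x, name, min = -Inf, max = Inf,
                          open_min = FALSE, open_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_min) x > min else x >= min) &&
    (if (open_max) x < max else x <= max)
  if (!ok) {
    stop(sprintf("`%s` must be a single number in %s%s, %s%s.",
                 name, if (open_min) "(" else "[", format(min),
                 format(max), if (open_max) ")" else "]"),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE.", name), call. = FALSE)
  }
  invisible(x)
}

#' Sigmoid function
#'
#' Numerically stable logistic sigmoid \eqn{\sigma(t) = 1 / (1 + e^{-t})}.
#'
#' @param t numeric vector.
#' @return numeric vector of the same length with values in (0, 1).
#' @examples
#' sigmoid(0)     # 0.5
#' sigmoid(c(-Inf, 0, Inf))
#' @export
sigmoid <- function(t) {
  out <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  out[pos] <- 1 / (1 + exp(-t[pos]))
  ez <- exp(t[!pos])
  out[!pos] <- ez / (1 + ez)
  out[is.na(t)] <- NA_real_
  out
}

#' Stable log-sigmoid: log(1/(1+exp(-t)))
#' @noRd
log_sigmoid <- function(t) {
  # -log1p(exp(-t)) for t >= 0, t - log1p(exp(t)) otherwise
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- -log1p(exp(-t[pos]))
  out[!pos] <- t[!pos] - log1p(exp(t[!pos]))
  out
}

# labels are +1 (positive class, EC) / -1 throughout
assert_pm1 <- function(y, name = "y") {
  if (!all(y %in% c(-1, 1))) {
    stop(sprintf("`%s` must contain only -1 and +1.", name), call. = FALSE)
  }
  invisible(as.numeric(y))
}
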