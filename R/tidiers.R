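# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted classifier: one row per coefficient
#'
#' @param x an `al_model`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `selected` (|estimate| above the
#'   zero tolerance).
#' @export
tidy.al_model <- function(x, ...) {
  tibble::tibble(term = names(x$beta),
                 estimate = unname(x$beta),
                 selected = c(TRUE, abs(x$beta[-1L]) > 1e-6))
}

#' @rdname tidy.al_model
#' @return `glance()`: one-row tibble with `lambda`, `n_train`,
#'   `n_features`, `n_selected`, `objective`, `converged`.
#' @export
glance.al_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_train = x$n_train,
                 n_features = length(x$feature_names),
                 n_selected = length(selected_features(x)),
                 objective = x$objective, converged = x$converged)
}

#' Tidy an active-learning state: the information-gain trajectory
#'
#' @param x an `al_state`.
#' @param ... unused.
#' @return tibble with `iteration`, `information_gain`, `n_labeled`.
#' @export
tidy.al_state <- function(x, ...) {
  n_iter <- length(x$gain_history)
  n0 <- nrow(x$labeled) - (n_iter - 1L) * x$config$batch_size
  tibble::tibble(
    iteration = seq_len(n_iter),
    information_gain = x$gain_history,
    n_labeled = c(n0, n0 + seq_len(n_iter - 1L) * x$config$batch_size)
  )
}

#' @rdname tidy.al_state
#' @return `glance()`: one-row tibble with `n_labeled`, `iterations`,
#'   `converged`, `final_gain`.
#' @export
glance.al_state <- function(x, ...) {
  tibble::tibble(n_labeled = nrow(x$labeled),
                 iterations = length(x$gain_history),
                 converged = x$converged,
                 final_gain = utils::tail(x$gain_history, 1L))
}

#' Tidy a benchmark: the long accuracy table / summary curves
#'
#' @param x a `benchmark_result`.
#' @param ... unused.
#' @return `tidy()`: the long per-replicate tibble (`method`, `replicate`,
#'   `n_train`, `accuracy`); `glance()`: final mean accuracy and SEM per
#'   method.
#' @export
tidy.benchmark_result <- function(x, ...) x$curves

#' @rdname tidy.benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) {
  x$summary |>
    dplyr::filter(.data$n_train == max(.data$n_train)) |>
    dplyr::select("method", final_accuracy = "mean_accuracy", "sem")
}
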