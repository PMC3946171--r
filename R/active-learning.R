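# Sequential D-optimal query selection: training examples are chosen to
# maximise the determinant of the (regularised) Fisher information matrix of
# the logistic model, shrinking the volume of the parameter-uncertainty
# ellipsoid fastest.

#' Fisher information matrix of a logistic model
#'
#' For logistic regression the Fisher information over points \eqn{x_i} is
#' \deqn{I(\beta) = \sum_i w_i x_i x_i^\top, \quad
#'   w_i = \sigma(\beta^\top x_i)(1 - \sigma(\beta^\top x_i)),}
#' independent of the labels. A small ridge \eqn{\epsilon D} (with `D` the
#' identity, \eqn{\epsilon} of order 1e-9) keeps the matrix positive definite
#' even before any labels have been collected.
#'
#' @param model an `al_model`.
#' @param X design matrix with leading intercept column (standardized scale);
#'   may have zero rows.
#' @return symmetric positive-definite matrix of size `length(model$beta)`.
#' @export
fisher_information <- function(model, X) {
  p <- length(model$beta)
  X <- as.matrix(X)
  if (nrow(X) > 0L && ncol(X) != p) {
    stop("Design matrix width does not match the model coefficients.",
         call. = FALSE)
  }
  fim <- diag(model$fim_eps, p)
  if (nrow(X) > 0L) {
    s <- sigmoid(drop(X %*% model$beta))
    w <- s * (1 - s)
    fim <- fim + crossprod(X * sqrt(w))
  }
  dimnames(fim) <- list(names(model$beta), names(model$beta))
  fim
}

#' Information gain: log-determinant of the Fisher information
#'
#' The determinant of \eqn{I(\beta)} is the D-optimality criterion; its
#' logarithm is returned for numerical stability (monotone in the
#' determinant).
#'
#' @param fim symmetric positive-definite matrix.
#' @return scalar \eqn{\ln \det(\mathrm{fim})}.
#' @export
information_gain <- function(fim) {
  fim <- as.matrix(fim)
  if (!isSymmetric(unname(fim), tol = 1e-8)) {
    stop("Fisher information matrix is not symmetric.", call. = FALSE)
  }
  ch <- tryCatch(chol(fim), error = function(e) {
    stop("Fisher information matrix is not positive definite: ",
         conditionMessage(e), call. = FALSE)
  })
  2 * sum(log(diag(ch)))
}

#' Configuration of an active-learning run
#'
#' @param n_init_per_class initial labeled examples per class (default 1: the
#'   trainer provides one example of each class to start).
#' @param max_iterations maximum number of query iterations (default 50).
#' @param batch_size cells queried per iteration (default 1; for larger
#'   batches the information matrix is updated with the expected, label-free
#'   contribution of each pick before re-scoring).
#' @param plateau_tol relative information-gain increase below which an
#'   iteration counts towards the plateau.
#' @param plateau_patience consecutive sub-tolerance iterations required to
#'   declare convergence.
#' @param lambda L1 penalty; `NULL` (default) uses the schedule
#'   `0.15 * n_labeled`, rescaling the penalty as labels accrue so it neither
#'   dominates the few-label fits nor vanishes later. At this strength, a
#'   feature must carry signal roughly above the noise level of a null
#'   score statistic to survive, which empirically zeroes uninformative
#'   features while keeping informative ones.
#' @param relax refit the selected support unpenalised after each L1 fit
#'   (relaxed lasso; default `TRUE`), so the sparsity of the penalty does not
#'   shrink the retained coefficients.
#' @param l1_eps,fim_eps smoothing constant of the eps-L1 penalty and ridge
#'   weight of the regularised Fisher information matrix.
#' @param seed integer seed (drives the choice of initial examples when
#'   `init_ids` are not supplied).
#' @return an object of class `al_config`.
#' @export
al_config <- function(n_init_per_class = 1L, max_iterations = 50L,
                      batch_size = 1L, plateau_tol = 1e-3,
                      plateau_patience = 5L, lambda = NULL, relax = TRUE,
                      l1_eps = 1e-6, fim_eps = 1e-9, seed = 1L) {
  assert_count(n_init_per_class, "n_init_per_class", min = 1L)
  assert_count(max_iterations, "max_iterations", min = 0L)
  assert_count(batch_size, "batch_size", min = 1L)
  assert_number(plateau_tol, "plateau_tol", min = 0, open_min = TRUE)
  assert_count(plateau_patience, "plateau_patience", min = 1L)
  if (!is.null(lambda)) assert_number(lambda, "lambda", min = 0)
  structure(
    list(n_init_per_class = as.integer(n_init_per_class),
         max_iterations = as.integer(max_iterations),
         batch_size = as.integer(batch_size),
         plateau_tol = plateau_tol,
         plateau_patience = as.integer(plateau_patience),
         lambda = lambda, relax = relax,
         l1_eps = l1_eps, fim_eps = fim_eps,
         seed = as.integer(seed)),
    class = "al_config"
  )
}

lambda_for <- function(config, n_labeled) {
  if (is.null(config$lambda)) 0.15 * n_labeled else config$lambda
}

new_al_state <- function(model, labeled, fim, gain_history, config,
                         converged = FALSE) {
  structure(
    list(model = model, labeled = labeled, fim = fim,
         gain_history = gain_history, config = config, converged = converged),
    class = "al_state"
  )
}

#' @export
print.al_state <- function(x, ...) {
  cat("<al_state>", nrow(x$labeled), "labeled cells,",
      length(x$gain_history), "iterations,",
      if (x$converged) "converged" else "not converged", "\n")
  if (length(x$gain_history) > 0L) {
    cat("  information gain:",
        format(utils::tail(x$gain_history, 1L), digits = 6), "\n")
  }
  invisible(x)
}

#' Select the next cells to query (D-optimal rule)
#'
#' Scores every unlabeled candidate `x` by the increase in the determinant of
#' the regularised Fisher information were it added:
#' \eqn{\det(I + w(x) x x^\top) = \det(I)\,(1 + w(x)\, x^\top I^{-1} x)}
#' (matrix determinant lemma), so the ranking score is
#' \eqn{w(x)\, x^\top I^{-1} x} with
#' \eqn{w(x) = \sigma(\beta^\top x)(1 - \sigma(\beta^\top x))}.
#' For `batch_size > 1` the selection is greedy: after each pick the
#' information matrix is updated with the picked candidate's expected
#' (label-free) contribution and the remaining pool re-scored. Ties are
#' broken by the smallest `cell_id`.
#'
#' @param state an `al_state`.
#' @param pool feature table with `cell_id` and the model features.
#' @param batch_size number of cells to select.
#' @return ordered vector of selected `cell_id`s.
#' @export
select_query <- function(state, pool, batch_size = state$config$batch_size) {
  candidates <- pool[!pool$cell_id %in% state$labeled$cell_id, , drop = FALSE]
  if (nrow(candidates) == 0L) {
    stop("Query pool is empty: all cells are already labeled.", call. = FALSE)
  }
  batch_size <- min(batch_size, nrow(candidates))
  X <- design_matrix(candidates, state$model$standardization)
  X <- X[, names(state$model$beta), drop = FALSE]
  s <- sigmoid(drop(X %*% state$model$beta))
  w <- s * (1 - s)
  fim <- state$fim
  ids <- candidates$cell_id
  picked <- integer(0)
  available <- rep(TRUE, nrow(X))
  for (b in seq_len(batch_size)) {
    fim_inv <- chol2inv(chol(fim))
    lev <- rowSums((X %*% fim_inv) * X)
    score <- w * lev
    score[!available] <- -Inf
    ord <- order(-score, ids)
    best <- ord[1L]
    picked <- c(picked, ids[best])
    available[best] <- FALSE
    if (b < batch_size) {
      fim <- fim + w[best] * tcrossprod(X[best, ])
    }
  }
  picked
}

#' Incorporate newly labeled cells and refit
#'
#' Appends the new labels, refits the L1-logistic model on all labeled cells
#' (with the configured penalty schedule), recomputes the regularised Fisher
#' information over the labeled set, and appends the resulting information
#' gain (log-determinant) to the gain history.
#'
#' @param state an `al_state`.
#' @param new_labels data frame with columns `cell_id` and `label`
#'   (\{-1, +1\}).
#' @param pool feature table containing the labeled cells.
#' @return the updated `al_state`.
#' @export
update_state <- function(state, new_labels, pool) {
  new_labels <- tibble::as_tibble(new_labels[, c("cell_id", "label")])
  assert_pm1(new_labels$label, "new_labels$label")
  missing_ids <- setdiff(new_labels$cell_id, pool$cell_id)
  if (length(missing_ids) > 0L) {
    stop("Label(s) for cells absent from the pool: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  overlap <- dplyr::inner_join(state$labeled, new_labels, by = "cell_id",
                               suffix = c("", ".new"))
  if (nrow(overlap) > 0L) {
    conflict <- overlap$label != overlap$label.new
    if (any(conflict)) {
      stop("Conflicting relabeling of cell id(s): ",
           paste(overlap$cell_id[conflict], collapse = ", "), call. = FALSE)
    }
    new_labels <- new_labels[!new_labels$cell_id %in% overlap$cell_id, ,
                             drop = FALSE]
  }
  labeled <- dplyr::bind_rows(state$labeled, new_labels)
  config <- state$config

  train <- dplyr::inner_join(labeled,
                             pool[, c("cell_id", names(state$model$standardization$mean))],
                             by = "cell_id")
  X <- design_matrix(train, state$model$standardization)
  model <- fit_logistic(X, train$label,
                        lambda = lambda_for(config, nrow(train)),
                        l1_eps = config$l1_eps, fim_eps = config$fim_eps,
                        relax = isTRUE(config$relax),
                        standardization = state$model$standardization)
  fim <- fisher_information(model, X)
  gain <- information_gain(fim)
  new_al_state(model, labeled, fim, c(state$gain_history, gain), config,
               converged = state$converged)
}

#' Detect an information-gain plateau
#'
#' Convergence is declared when the relative gain increase
#' \eqn{(G_t - G_{t-1}) / \max(|G_{t-1}|, 1)} stays below `plateau_tol` for
#' `plateau_patience` consecutive iterations.
#'
#' @param gain_history numeric vector of log-determinant values, one per
#'   completed iteration.
#' @param plateau_tol relative tolerance.
#' @param plateau_patience required consecutive sub-tolerance steps.
#' @return `TRUE` if the plateau criterion is met.
#' @export
check_convergence <- function(gain_history, plateau_tol = 1e-3,
                              plateau_patience = 5L) {
  if (length(gain_history) == 0L) {
    stop("`gain_history` must be non-empty.", call. = FALSE)
  }
  g <- gain_history
  if (length(g) < plateau_patience || length(g) < 2L) return(FALSE)
  rel <- diff(g) / pmax(abs(g[-length(g)]), 1)
  all(utils::tail(rel, min(plateau_patience, length(rel))) < plateau_tol)
}

#' Run the active-learning loop
#'
#' Seeds the labeled set with `n_init_per_class` examples of each class, then
#' repeats select-query / oracle / refit until the information gain plateaus
#' or `max_iterations` is reached. Given the same pool, seed, initial
#' examples and oracle answers, the run queries the same cells and returns
#' identical coefficients.
#'
#' @param pool feature table with `cell_id` and feature columns (a `label`
#'   column, if present, is ignored for training and may serve the oracle).
#' @param oracle labeling function as returned by [simulated_oracle()].
#' @param config an [al_config()].
#' @param init_ids optional vector of cell ids to use as the initial labeled
#'   examples (must cover both classes per the oracle). When omitted, cells
#'   are scanned in a seed-determined random order and the first
#'   `n_init_per_class` of each class (per the oracle's answers) are kept.
#' @param verbose print per-iteration information gain.
#' @return the final `al_state`.
#' @examples
#' pool <- make_feature_dataset(tabular_spec(n_cells = 200, seed = 5))
#' st <- run_active_learning(pool, simulated_oracle(pool),
#'                           al_config(max_iterations = 10))
#' length(st$gain_history)
#' @export
run_active_learning <- function(pool, oracle, config = al_config(),
                                init_ids = NULL, verbose = FALSE) {
  pool <- tibble::as_tibble(pool)
  if (anyDuplicated(pool$cell_id)) {
    stop("`pool` has duplicate cell ids.", call. = FALSE)
  }
  feats <- feature_names(pool)
  standardization <- pool_standardization(pool, feats)

  if (is.null(init_ids)) {
    scan_order <- with_seed(config$seed, sample(pool$cell_id))
    need <- c(`-1` = config$n_init_per_class, `1` = config$n_init_per_class)
    got <- c(`-1` = 0L, `1` = 0L)
    init <- integer(0)
    for (id in scan_order) {
      lab <- oracle(id)
      key <- as.character(lab)
      if (got[key] < need[key]) {
        got[key] <- got[key] + 1L
        init <- c(init, id)
      }
      if (all(got >= need)) break
    }
    if (!all(got >= need)) {
      stop("Could not find ", config$n_init_per_class,
           " initial example(s) of each class in the pool.", call. = FALSE)
    }
    init_ids <- init
  }
  init_labels <- tibble::tibble(cell_id = init_ids,
                                label = oracle(init_ids))
  if (length(unique(init_labels$label)) < 2L) {
    stop("Initial examples must cover both classes.", call. = FALSE)
  }

  # empty-state model: zero coefficients, ridge-only information matrix
  model0 <- structure(
    list(beta = stats::setNames(rep(0, length(standardization$mean) + 1L),
                                c("(Intercept)", names(standardization$mean))),
         feature_names = names(standardization$mean),
         standardization = standardization,
         lambda = lambda_for(config, 0L),
         l1_eps = config$l1_eps, fim_eps = config$fim_eps,
         objective = NA_real_, converged = NA, n_train = 0L),
    class = "al_model")
  state <- new_al_state(model0,
                        tibble::tibble(cell_id = integer(0), label = numeric(0)),
                        fisher_information(model0, matrix(0, 0, length(model0$beta))),
                        numeric(0), config)
  state <- update_state(state, init_labels, pool)

  iter <- 0L
  while (iter < config$max_iterations &&
         nrow(state$labeled) < nrow(pool)) {
    ids <- select_query(state, pool, config$batch_size)
    labels <- tibble::tibble(cell_id = ids, label = oracle(ids))
    state <- tryCatch(
      update_state(state, labels, pool),
      error = function(e) {
        stop("Active-learning iteration ", iter + 1L, " failed: ",
             conditionMessage(e), call. = FALSE)
      })
    iter <- iter + 1L
    if (verbose) {
      message(sprintf("iteration %d: information gain %.6f", iter,
                      utils::tail(state$gain_history, 1L)))
    }
    if (check_convergence(state$gain_history, config$plateau_tol,
                          config$plateau_patience)) {
      state$converged <- TRUE
      break
    }
  }
  state
}
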