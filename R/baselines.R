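# Comparator pipelines: classical feature selection (PCA, univariate t-test,
# mRMR) feeding a plain logistic regression trained on randomly sampled
# labels, plus the replicated learning-curve benchmark harness.

#' PCA projection onto the leading components
#'
#' Centres the data and returns the top-`k` principal components (eigenvectors
#' of the covariance matrix), ordered by explained variance.
#'
#' @param X numeric matrix (cells x features).
#' @param k number of components, `1 <= k <= ncol(X)`.
#' @return list of class `pca_transform`: `center` (mean vector), `rotation`
#'   (features x k), `sdev` (all singular values / sqrt(n-1)). Use
#'   `predict()` to project new data.
#' @export
pca_select <- function(X, k) {
  X <- as.matrix(X)
  assert_count(k, "k", min = 1L)
  if (k > ncol(X)) {
    stop("`k` must not exceed the number of features.", call. = FALSE)
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(center = fit$center,
                 rotation = fit$rotation[, seq_len(k), drop = FALSE],
                 sdev = fit$sdev),
            class = "pca_transform")
}

#' @export
predict.pca_transform <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2L, object$center, "-") %*% object$rotation
}

#' Univariate feature selection by Welch t-test
#'
#' Runs a two-sample Welch (unequal-variance) t-test of each feature against
#' the class labels and returns the `k` features with the smallest p-values
#' (ties broken by column index).
#'
#' @param X numeric matrix (cells x features).
#' @param y labels in \{-1, +1\}; each class needs >= 2 members.
#' @param k number of features to keep (0 gives an empty selection).
#' @return integer vector of selected column indices, best first.
#' @export
ttest_select <- function(X, y, k) {
  X <- as.matrix(X)
  y <- assert_pm1(y)
  assert_count(k, "k", min = 0L)
  if (k > ncol(X)) {
    stop("`k` must not exceed the number of features.", call. = FALSE)
  }
  if (sum(y == 1) < 2L || sum(y == -1) < 2L) {
    stop("Each class needs at least two members for the t-test.",
         call. = FALSE)
  }
  if (k == 0L) return(integer(0))
  pvals <- vapply(seq_len(ncol(X)), function(j) {
    a <- X[y == 1, j]
    b <- X[y == -1, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }, numeric(1))
  order(pvals, seq_along(pvals))[seq_len(k)]
}

# Mutual information (nats) between two discrete vectors via the plug-in
# estimate on the contingency table.
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

# Three-bin discretization at mu +/- sigma, the common mRMR convention.
discretize3 <- function(x) {
  mu <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(rep(1L, length(x)))
  cut(x, breaks = c(-Inf, mu - s, mu + s, Inf), labels = FALSE)
}

#' Minimum-redundancy maximum-relevance feature selection (MID form)
#'
#' Greedy mutual-information selection: features are discretized into three
#' bins at \eqn{\mu \pm \sigma}; the first pick maximises the mutual
#' information with the class, and each subsequent pick maximises
#' \deqn{MI(f; y) - \frac{1}{|S|} \sum_{s \in S} MI(f; s)}
#' (relevance minus mean redundancy with the already-selected set). Ties are
#' broken by column index.
#'
#' @inheritParams ttest_select
#' @return integer vector of selected column indices, in pick order.
#' @export
mrmr_select <- function(X, y, k) {
  X <- as.matrix(X)
  y <- assert_pm1(y)
  assert_count(k, "k", min = 0L)
  if (k > ncol(X)) {
    stop("`k` must not exceed the number of features.", call. = FALSE)
  }
  if (k == 0L) return(integer(0))
  D <- apply(X, 2L, discretize3)
  relevance <- vapply(seq_len(ncol(D)), function(j) discrete_mi(D[, j], y),
                      numeric(1))
  selected <- integer(0)
  redundancy_sum <- numeric(ncol(D))
  remaining <- seq_len(ncol(D))
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0L) {
      relevance[remaining]
    } else {
      relevance[remaining] - redundancy_sum[remaining] / length(selected)
    }
    pick <- remaining[order(-score, remaining)[1L]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0L && step < k) {
      redundancy_sum[remaining] <- redundancy_sum[remaining] +
        vapply(remaining, function(j) discrete_mi(D[, j], D[, pick]),
               numeric(1))
    }
  }
  selected
}

# Fit an unpenalised logistic model on a labeled subset; returns NULL when
# only one class is present (caller carries the previous model forward).
fit_plain_lr <- function(pool_std, design, labeled_ids, labels) {
  if (length(unique(labels)) < 2L) return(NULL)
  rows <- match(labeled_ids, pool_std$cell_id)
  fit_logistic(design[rows, , drop = FALSE], labels, lambda = 0)
}

#' Random-sampling logistic regression baseline
#'
#' The "standard" comparator: training examples are drawn uniformly at random
#' without replacement (after a class-balanced initial pair supplied by the
#' oracle), an unpenalised logistic regression is refitted after each
#' addition, and accuracy on all remaining cells is recorded.
#'
#' @param pool feature table with `cell_id`, feature columns and a hidden
#'   `label` column used for scoring.
#' @param oracle labeling function (see [simulated_oracle()]).
#' @param budget total number of labels to collect (`<=` pool size).
#' @param seed integer seed for the sampling order.
#' @return list with `model` (final fit), `trace` (tibble `n_train`,
#'   `accuracy`) and `train_ids`.
#' @export
random_sampling_lr <- function(pool, oracle, budget = 50L, seed = 1L) {
  pool <- tibble::as_tibble(pool)
  assert_count(budget, "budget", min = 2L)
  if (budget > nrow(pool)) {
    stop("`budget` exceeds the pool size.", call. = FALSE)
  }
  feats <- feature_names(pool)
  standardization <- pool_standardization(pool, feats)
  design <- design_matrix(pool, standardization)

  with_seed(seed, {
    scan_order <- sample(pool$cell_id)
    # class-balanced initial pair
    init <- integer(0)
    got <- c(`-1` = 0L, `1` = 0L)
    for (id in scan_order) {
      lab <- as.character(oracle(id))
      if (got[lab] == 0L) {
        got[lab] <- 1L
        init <- c(init, id)
      }
      if (all(got == 1L)) break
    }
    if (length(init) < 2L) {
      stop("Pool does not contain both classes.", call. = FALSE)
    }
    rest <- sample(setdiff(pool$cell_id, init))
    train_ids <- c(init, rest[seq_len(budget - length(init))])
  })

  labels <- oracle(train_ids)
  model <- NULL
  trace <- vector("list", budget - 1L)
  for (m in 2:budget) {
    ids <- train_ids[seq_len(m)]
    fit <- fit_plain_lr(pool, design, ids, labels[seq_len(m)])
    if (!is.null(fit)) {
      fit$standardization <- standardization
      model <- fit
    }
    held <- !pool$cell_id %in% ids
    acc <- if (is.null(model) || !any(held)) {
      NA_real_
    } else {
      pred <- ifelse(sigmoid(drop(design[held, , drop = FALSE] %*%
                                    model$beta)) > 0.5, 1, -1)
      mean(pred == pool$label[held])
    }
    trace[[m - 1L]] <- tibble::tibble(n_train = m, accuracy = acc)
  }
  list(model = model, trace = dplyr::bind_rows(trace), train_ids = train_ids)
}

benchmark_methods <- c("al", "random_lr", "pca", "ttest", "mrmr")

# One replicate of one method: returns accuracy at each training-set size
# 2..budget, evaluated on all cells outside the training set at that step.
benchmark_one <- function(pool, method, budget, seed, k_features,
                          preselect_full, al_cfg) {
  oracle <- simulated_oracle(pool)
  feats <- feature_names(pool)
  if (method == "al") {
    # grow step by step so accuracy can be recorded after each addition
    state <- run_active_learning(
      pool, oracle,
      al_config(n_init_per_class = al_cfg$n_init_per_class,
                max_iterations = 0L, l1_eps = al_cfg$l1_eps,
                fim_eps = al_cfg$fim_eps, lambda = al_cfg$lambda,
                seed = seed))
    acc <- numeric(0)
    record <- function(state) {
      held <- !pool$cell_id %in% state$labeled$cell_id
      pred <- predict(state$model, pool[held, , drop = FALSE])
      mean(pred$label == pool$label[held])
    }
    acc <- c(acc, record(state))
    while (nrow(state$labeled) < budget) {
      ids <- select_query(state, pool, 1L)
      state <- update_state(state,
                            tibble::tibble(cell_id = ids, label = oracle(ids)),
                            pool)
      acc <- c(acc, record(state))
    }
    return(acc)
  }

  X_all <- as.matrix(pool[, feats, drop = FALSE])
  # comparator protocol: feature selection on the fully labeled design (or,
  # with preselect_full = FALSE, on a random budget-sized labeled subset),
  # then logistic regression trained on randomly sampled labels
  if (preselect_full) {
    X_sel <- X_all
    y_sel <- pool$label
  } else {
    idx <- with_seed(seed, sample.int(nrow(pool), budget))
    X_sel <- X_all[idx, , drop = FALSE]
    y_sel <- pool$label[idx]
  }
  reduced <- switch(method,
    random_lr = X_all,
    pca = predict(pca_select(X_sel, k_features), X_all),
    ttest = X_all[, ttest_select(X_sel, y_sel, k_features), drop = FALSE],
    mrmr = X_all[, mrmr_select(X_sel, y_sel, k_features), drop = FALSE],
    stop("Unknown benchmark method: ", method, call. = FALSE)
  )
  colnames(reduced) <- paste0("f", seq_len(ncol(reduced)))
  rpool <- dplyr::bind_cols(pool[, c("cell_id", "image_id", "label")],
                            tibble::as_tibble(as.data.frame(reduced)))
  random_sampling_lr(rpool, oracle, budget = budget, seed = seed)$trace$accuracy
}

#' Replicated learning-curve benchmark
#'
#' For each method and replicate, grows the training set one label at a time
#' up to `budget` and records classification accuracy on all cells outside
#' the training set after each addition. Feature-selection comparators (PCA,
#' t-test, mRMR) reduce the design on the fully labeled pool first, then
#' train a plain logistic regression on randomly sampled labels; the
#' active-learning method selects its own training examples.
#'
#' @param dataset labeled feature table (e.g. [make_feature_dataset()]); the
#'   `label` column is the oracle and the scoring ground truth.
#' @param methods subset of `c("al", "random_lr", "pca", "ttest", "mrmr")`.
#' @param n_replicates number of independent replicates (default 25).
#' @param budget total labels per replicate (default 50).
#' @param seeds integer vector of length `n_replicates`; defaults to
#'   `seq_len(n_replicates)`.
#' @param k_features number of features/components kept by the comparators.
#' @param preselect_full if `TRUE` (default) comparators select features on
#'   the fully labeled design; `FALSE` restricts selection to the sampled
#'   budget (alternative protocol).
#' @param al_cfg base [al_config()] supplying penalty/smoothing settings for
#'   the active-learning arm.
#' @return object of class `benchmark_result`: list with `curves` (long
#'   tibble: `method`, `replicate`, `n_train`, `accuracy`), `summary`
#'   (tibble: `method`, `n_train`, `mean_accuracy`, `sem`), `accuracy`
#'   (named list of replicate x step matrices) and `seeds`.
#' @export
benchmark_learning_curves <- function(dataset,
                                      methods = benchmark_methods,
                                      n_replicates = 25L, budget = 50L,
                                      seeds = seq_len(n_replicates),
                                      k_features = 5L,
                                      preselect_full = TRUE,
                                      al_cfg = al_config()) {
  dataset <- tibble::as_tibble(dataset)
  if (is.null(dataset$label)) {
    stop("`dataset` must carry a ground-truth `label` column.", call. = FALSE)
  }
  bad <- setdiff(methods, benchmark_methods)
  if (length(bad) > 0L) {
    stop("Unknown benchmark method(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(seeds) != n_replicates) {
    stop("`seeds` must have length `n_replicates`.", call. = FALSE)
  }
  curves <- list()
  mats <- list()
  for (method in methods) {
    rows <- lapply(seq_len(n_replicates), function(r) {
      acc <- benchmark_one(dataset, method, budget, seeds[r], k_features,
                           preselect_full, al_cfg)
      tibble::tibble(method = method, replicate = r,
                     n_train = seq(2L, budget), accuracy = acc)
    })
    long <- dplyr::bind_rows(rows)
    curves[[method]] <- long
    mats[[method]] <- matrix(long$accuracy, nrow = n_replicates,
                             byrow = TRUE)
  }
  curves <- dplyr::bind_rows(curves)
  summary <- curves |>
    dplyr::group_by(.data$method, .data$n_train) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sem = if (dplyr::n() > 1L) {
        stats::sd(.data$accuracy) / sqrt(dplyr::n())
      } else 0,
      .groups = "drop")
  structure(list(curves = curves, summary = summary, accuracy = mats,
                 seeds = seeds, budget = budget),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>", length(x$accuracy), "methods,",
      nrow(x$accuracy[[1L]]), "replicates, budget", x$budget, "\n")
  final <- dplyr::filter(x$summary, .data$n_train == max(.data$n_train))
  print(final)
  invisible(x)
}

#' Write benchmark curves to CSV (long format) and a JSON summary
#'
#' @param result a `benchmark_result`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_benchmark <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "benchmark_result"))
  if (!is.null(csv_path)) {
    utils::write.csv(result$curves, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(result$summary, json_path, digits = NA)
  }
  invisible(c(csv = csv_path, json = json_path))
}
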