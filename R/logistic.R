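# L1-regularised logistic regression with eps-L1 smoothing: the classifier
# at the heart of the active-learning loop. Labels are coded -1/+1 and the
# design matrix carries a leading column of ones for the intercept.

#' Build the standardized design matrix for a feature table
#'
#' Applies a stored standardization (per-feature mean and scale) and prepends
#' the intercept column of ones.
#'
#' @param data feature table (data frame) containing all model features.
#' @param standardization list with named numeric vectors `mean` and `scale`.
#' @return numeric matrix with `length(mean) + 1` columns; the first column is
#'   all ones.
#' @export
design_matrix <- function(data, standardization) {
  feats <- names(standardization$mean)
  missing_cols <- setdiff(feats, names(data))
  if (length(missing_cols) > 0L) {
    stop("Feature column(s) missing from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[, feats, drop = FALSE])
  if (!is.numeric(X)) stop("Features must be numeric.", call. = FALSE)
  X <- sweep(X, 2L, standardization$mean[feats], "-")
  X <- sweep(X, 2L, standardization$scale[feats], "/")
  cbind(`(Intercept)` = 1, X)
}

#' Compute pool standardization statistics
#'
#' Per-feature mean and standard deviation over the (typically unlabeled)
#' pool. L1 penalties compare coefficient magnitudes across features, so
#' features must be brought to a common scale before fitting. Constant
#' features (zero variance) are dropped with a warning.
#'
#' @param data feature table.
#' @param features feature column names; defaults to [feature_names()].
#' @return list with named vectors `mean` and `scale`.
#' @export
pool_standardization <- function(data, features = feature_names(data)) {
  X <- as.matrix(data[, features, drop = FALSE])
  if (any(!is.finite(X))) {
    stop("Non-finite feature values in pool.", call. = FALSE)
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  constant <- sdev == 0 | !is.finite(sdev)
  if (any(constant)) {
    warning("Dropping constant feature(s): ",
            paste(features[constant], collapse = ", "), call. = FALSE)
    mu <- mu[!constant]
    sdev <- sdev[!constant]
  }
  list(mean = mu, scale = sdev)
}

smoothed_objective <- function(beta, X, y, lambda, l1_eps) {
  margins <- y * drop(X %*% beta)
  nll <- -sum(log_sigmoid(margins))
  pen <- if (lambda > 0) lambda * sum(sqrt(beta[-1L]^2 + l1_eps)) else 0
  nll + pen
}

smoothed_gradient <- function(beta, X, y, lambda, l1_eps) {
  margins <- y * drop(X %*% beta)
  # d/dbeta of -sum log sigma(y X beta) = -X' (y * (1 - sigma(margins)))
  g <- -drop(crossprod(X, y * (1 - sigmoid(margins))))
  if (lambda > 0) {
    pen_g <- lambda * beta / sqrt(beta^2 + l1_eps)
    pen_g[1L] <- 0
    g <- g + pen_g
  }
  g
}

#' Fit an L1-regularised logistic regression (eps-L1 smoothing)
#'
#' Maximises the penalised log-likelihood
#' \deqn{\sum_i \ln \sigma(y_i \beta^\top x_i) - \lambda \|\beta_{-0}\|_1}
#' over labels \eqn{y_i \in \{-1, +1\}}, with the non-differentiable
#' \eqn{|\beta_j|} replaced by the smooth surrogate
#' \eqn{\sqrt{\beta_j^2 + \epsilon_s}} (eps-L1) so a quasi-Newton optimiser
#' applies. The intercept (first coefficient) is never penalised. When
#' `polish = TRUE` (default for `lambda > 0`), coefficients whose magnitude
#' falls below the smoothing resolution `sqrt(l1_eps)` are truncated to exact
#' zero after optimisation: under the smoothed penalty such coefficients are
#' numerically indistinguishable from zero, and truncation restores the exact
#' sparsity that the ideal L1 penalty would produce.
#'
#' @param X numeric design matrix whose first column is all ones (intercept);
#'   remaining columns are standardized features (see [design_matrix()]).
#' @param y labels in \{-1, +1\}; both classes must be present.
#' @param lambda L1 penalty weight (>= 0).
#' @param l1_eps eps-L1 smoothing constant \eqn{\epsilon_s}.
#' @param fim_eps Fisher-information regulariser stored on the model.
#' @param standardization optional standardization carried onto the model (so
#'   [predict.al_model()] can consume raw feature tables); identity if `NULL`.
#' @param polish truncate sub-resolution coefficients to exact zero.
#' @param relax refit the selected support without the penalty (relaxed
#'   lasso): the L1 stage decides which features participate, the unpenalised
#'   stage removes the shrinkage bias from the retained coefficients. Zeroed
#'   coefficients stay exactly zero.
#' @param max_iter,grad_tol optimiser budget and gradient tolerance.
#' @return an object of class `al_model`: named coefficient vector `beta`
#'   (leading intercept), `feature_names`, `standardization`, `lambda`,
#'   `l1_eps`, `fim_eps`, plus optimiser diagnostics.
#' @examples
#' X <- cbind(1, matrix(rnorm(40), 20, 2))
#' colnames(X) <- c("(Intercept)", "f1", "f2")
#' y <- ifelse(X[, 2] > 0, 1, -1)
#' m <- fit_logistic(X, y, lambda = 0.1)
#' selected_features(m)
#' @export
fit_logistic <- function(X, y, lambda = 0, l1_eps = 1e-6, fim_eps = 1e-9,
                         standardization = NULL, polish = lambda > 0,
                         relax = FALSE, max_iter = 500L, grad_tol = 1e-6) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) {
    stop("Design matrix contains non-finite values.", call. = FALSE)
  }
  if (length(y) != nrow(X)) {
    stop("Length of `y` does not match rows of `X`.", call. = FALSE)
  }
  y <- assert_pm1(y)
  if (length(unique(y)) < 2L) {
    stop("Training data must contain both classes.", call. = FALSE)
  }
  if (any(X[, 1L] != 1)) {
    stop("First column of `X` must be the intercept column of ones.",
         call. = FALSE)
  }
  assert_number(lambda, "lambda", min = 0)

  p <- ncol(X)
  beta0 <- numeric(p)
  fn <- function(b) smoothed_objective(b, X, y, lambda, l1_eps)
  gr <- function(b) smoothed_gradient(b, X, y, lambda, l1_eps)
  opt <- stats::optim(beta0, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = grad_tol))
  beta <- opt$par
  if (polish && lambda > 0) {
    small <- abs(beta) < sqrt(l1_eps)
    small[1L] <- FALSE
    beta[small] <- 0
  }
  if (relax && lambda > 0) {
    active <- c(TRUE, beta[-1L] != 0)
    Xa <- X[, active, drop = FALSE]
    fn_a <- function(b) smoothed_objective(b, Xa, y, 0, l1_eps)
    gr_a <- function(b) smoothed_gradient(b, Xa, y, 0, l1_eps)
    opt_a <- stats::optim(beta[active], fn_a, gr_a, method = "BFGS",
                          control = list(maxit = max_iter, reltol = grad_tol))
    beta[active] <- opt_a$par
  }
  feat_names <- colnames(X)[-1L]
  if (is.null(feat_names)) feat_names <- paste0("x", seq_len(p - 1L))
  names(beta) <- c("(Intercept)", feat_names)
  if (is.null(standardization)) {
    standardization <- list(
      mean = stats::setNames(rep(0, p - 1L), feat_names),
      scale = stats::setNames(rep(1, p - 1L), feat_names))
  }
  structure(
    list(beta = beta, feature_names = feat_names,
         standardization = standardization,
         lambda = lambda, l1_eps = l1_eps, fim_eps = fim_eps,
         objective = opt$value, converged = opt$convergence == 0L,
         n_train = nrow(X)),
    class = "al_model"
  )
}

#' @export
print.al_model <- function(x, ...) {
  cat("<al_model> L1-logistic classifier\n")
  cat("  features:", length(x$feature_names),
      "| lambda:", format(x$lambda),
      "| trained on", x$n_train, "cells\n")
  sel <- selected_features(x)
  cat("  non-zero features:", length(sel), "\n")
  if (length(sel) > 0L) {
    cat("  top:", paste(utils::head(sel, 5L), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Log-likelihood of labels under a logistic model
#'
#' \eqn{\sum_i \ln \sigma(y_i \beta^\top x_i)}; always non-positive.
#'
#' @param model an `al_model`.
#' @param X design matrix with leading intercept column (standardized scale).
#' @param y labels in \{-1, +1\}.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(model, X, y) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$beta)) {
    stop("Design matrix width does not match the model coefficients.",
         call. = FALSE)
  }
  if (nrow(X) != length(y)) {
    stop("`X` and `y` have mismatched lengths.", call. = FALSE)
  }
  y <- assert_pm1(y)
  sum(log_sigmoid(y * drop(X %*% model$beta)))
}

#' Predict class probabilities and labels
#'
#' Applies the model's stored standardization to the raw features of
#' `newdata`, computes \eqn{p = \sigma(\beta^\top x)}, and assigns label +1
#' when `p > 0.5` (strict: `p == 0.5` predicts -1).
#'
#' @param object an `al_model`.
#' @param newdata feature table containing all model feature columns.
#' @param ... unused.
#' @return a tibble with columns `cell_id` (if present in `newdata`),
#'   `p` and `label`.
#' @export
predict.al_model <- function(object, newdata, ...) {
  X <- design_matrix(newdata, object$standardization)
  # the standardization names the retained features; the model may hold the
  # same set in a different order
  X <- X[, names(object$beta), drop = FALSE]
  p <- sigmoid(drop(X %*% object$beta))
  out <- tibble::tibble(p = p, label = ifelse(p > 0.5, 1, -1))
  if (!is.null(newdata$cell_id)) {
    out <- dplyr::bind_cols(tibble::tibble(cell_id = newdata$cell_id), out)
  }
  out
}

#' Features retained by the fitted model
#'
#' Feature names whose coefficient magnitude exceeds `zero_tol`, ordered by
#' decreasing \eqn{|\beta_j|}. With an L1 penalty the classifier sets the
#' weights of uninformative features to (exactly, after polishing) zero, so
#' this list is the model's automatic feature selection.
#'
#' @param model an `al_model`.
#' @param zero_tol magnitude below which a coefficient counts as zero.
#' @return character vector of feature names (possibly empty).
#' @export
selected_features <- function(model, zero_tol = 1e-6) {
  b <- model$beta[-1L]
  b <- b[is.finite(b) & abs(b) > zero_tol]
  names(b)[order(-abs(b))]
}

#' Serialize a model to JSON / read it back
#'
#' All numeric fields are written with full precision so the roundtrip is
#' lossless to the printed digits.
#'
#' @param model an `al_model`.
#' @param path file path.
#' @return `read_model()` returns the `al_model`; `write_model()` the path,
#'   invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    beta = as.list(model$beta),
    feature_names = model$feature_names,
    standardization = list(mean = as.list(model$standardization$mean),
                           scale = as.list(model$standardization$scale)),
    lambda = model$lambda, l1_eps = model$l1_eps, fim_eps = model$fim_eps,
    n_train = model$n_train
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(beta = unlist(obj$beta),
         feature_names = obj$feature_names,
         standardization = list(mean = unlist(obj$standardization$mean),
                                scale = unlist(obj$standardization$scale)),
         lambda = obj$lambda, l1_eps = obj$l1_eps, fim_eps = obj$fim_eps,
         objective = NA_real_, converged = NA, n_train = obj$n_train),
    class = "al_model"
  )
}
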