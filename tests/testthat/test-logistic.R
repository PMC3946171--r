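# The eps-L1 logistic classifier: likelihood values, penalty behaviour,
# prediction rules and serialization.

test_that("log-likelihood matches closed-form values", {
  X <- toy_design(matrix(c(-1, 1), 2, 1))
  m0 <- list(beta = c(`(Intercept)` = 0, f1 = 0))
  class(m0) <- "al_model"
  # beta = 0: every cell contributes ln(1/2)
  expect_equal(log_likelihood(m0, X, c(-1, 1)), 2 * log(0.5))
  # single cell with margin y * beta'x = 1: ln sigma(1) = -ln(1 + exp(-1))
  m1 <- list(beta = c(`(Intercept)` = 0, f1 = 1))
  class(m1) <- "al_model"
  expect_equal(log_likelihood(m1, X[2, , drop = FALSE], 1),
               -log(1 + exp(-1)))
  # perfectly classified far-margin points: ~ 0
  mbig <- list(beta = c(`(Intercept)` = 0, f1 = 50))
  class(mbig) <- "al_model"
  expect_gt(log_likelihood(mbig, X, c(-1, 1)), -1e-10)
  expect_lte(log_likelihood(mbig, X, c(-1, 1)), 0)
  expect_error(log_likelihood(m1, X, c(1, -1, 1)), "mismatch")
})

test_that("symmetric two-point data gives positive slope, zero intercept", {
  X <- toy_design(matrix(c(-1, 1), 2, 1))
  m <- fit_logistic(X, c(-1, 1), lambda = 0.01)
  expect_gt(m$beta["f1"], 0)
  expect_lt(abs(m$beta["(Intercept)"]), 1e-4)
})

test_that("a dominant penalty shrinks every non-intercept coefficient", {
  set.seed(42)
  X <- toy_design(matrix(rnorm(200), 50, 4))
  y <- ifelse(X[, 2] + rnorm(50, sd = 0.3) > 0, 1, -1)
  m <- fit_logistic(X, y, lambda = 1e3, polish = FALSE)
  expect_true(all(abs(m$beta[-1]) < 1e-3))
  # with polishing they become exact zeros and selected_features is empty
  mp <- fit_logistic(X, y, lambda = 1e3)
  expect_true(all(mp$beta[-1] == 0))
  expect_length(selected_features(mp), 0)
})

test_that("unpenalized fit separates a separable set perfectly", {
  X <- toy_design(matrix(c(-3, -2, -1, 1, 2, 3), 6, 1))
  y <- c(-1, -1, -1, 1, 1, 1)
  m <- fit_logistic(X, y, lambda = 0)
  p <- sigmoid(drop(X %*% m$beta))
  expect_equal(ifelse(p > 0.5, 1, -1), y)
})

test_that("the smoothed objective at the fit is no worse than at zero", {
  set.seed(7)
  X <- toy_design(matrix(rnorm(300), 60, 5))
  y <- ifelse(X[, 2] - X[, 3] + rnorm(60, sd = 0.5) > 0, 1, -1)
  for (lam in c(0, 0.5, 5)) {
    m <- fit_logistic(X, y, lambda = lam, polish = FALSE)
    obj <- function(b) {
      -sum(log(sigmoid(y * drop(X %*% b)))) +
        lam * sum(sqrt(b[-1]^2 + m$l1_eps))
    }
    expect_lte(obj(m$beta), obj(rep(0, ncol(X))) + 1e-8)
  }
})

test_that("sparsity is monotone between the penalty extremes", {
  set.seed(9)
  X <- toy_design(matrix(rnorm(400), 80, 5))
  y <- ifelse(X[, 2] > 0, 1, -1)
  n_active <- function(lam) {
    sum(abs(fit_logistic(X, y, lambda = lam, polish = FALSE)$beta[-1]) > 1e-3)
  }
  expect_gte(n_active(0), n_active(1e3))
})

test_that("training-input validation catches bad labels and features", {
  X <- toy_design(matrix(rnorm(20), 10, 2))
  expect_error(fit_logistic(X, rep(1, 10)), "both classes")
  expect_error(fit_logistic(X, c(rep(1, 9), 0)), "-1")
  Xbad <- X; Xbad[3, 2] <- NA
  expect_error(fit_logistic(Xbad, rep(c(-1, 1), 5)), "non-finite")
  Xno1 <- X; Xno1[1, 1] <- 0
  expect_error(fit_logistic(Xno1, rep(c(-1, 1), 5)), "intercept")
})

test_that("prediction applies the strict p > 0.5 rule and symmetry", {
  m <- fit_logistic(toy_design(matrix(c(-1, 1), 2, 1)), c(-1, 1),
                    lambda = 0.01)
  zero <- m; zero$beta[] <- 0
  newdata <- tibble::tibble(cell_id = 1:3, f1 = c(-2, 0, 2))
  p0 <- predict(zero, newdata)
  expect_equal(p0$p, rep(0.5, 3))
  expect_equal(p0$label, rep(-1, 3))  # p == 0.5 is negative
  # negating all coefficients (intercept 0) flips every call
  p <- predict(m, newdata)
  neg <- m; neg$beta <- -neg$beta
  expect_equal(predict(neg, newdata)$p, 1 - p$p)
  expect_error(predict(m, tibble::tibble(cell_id = 1, other = 1)), "missing")
})

test_that("selected_features orders by magnitude and honours the tolerance", {
  m <- list(beta = c(`(Intercept)` = 0.2, a = 0.5, b = -2, c = 0),
            feature_names = c("a", "b", "c"))
  class(m) <- "al_model"
  expect_equal(selected_features(m), c("b", "a"))
  expect_equal(selected_features(m, zero_tol = 1), "b")
  expect_length(selected_features(m, zero_tol = Inf), 0)
})

test_that("standardization drops constant features with a warning", {
  tbl <- small_pool(n = 50, seed = 1)
  tbl$flat <- 5
  expect_warning(std <- pool_standardization(tbl), "flat")
  expect_false("flat" %in% names(std$mean))
})

test_that("model JSON roundtrip preserves coefficients exactly", {
  tbl <- small_pool(n = 80, seed = 6)
  std <- pool_standardization(tbl)
  m <- fit_logistic(design_matrix(tbl, std), tbl$label, lambda = 1,
                    standardization = std)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  # lossless to the printed precision (>= 15 significant digits)
  expect_equal(unname(m2$beta), unname(m$beta), tolerance = 1e-14)
  expect_identical(m2$feature_names, m$feature_names)
  expect_equal(unname(m2$standardization$scale),
               unname(m$standardization$scale), tolerance = 1e-14)
  expect_equal(predict(m2, tbl)$p, predict(m, tbl)$p, tolerance = 1e-12)
})

test_that("relaxed refit preserves the L1 support but removes shrinkage", {
  tbl <- make_feature_dataset(tabular_spec(n_cells = 200, n_informative = 2,
                                           n_noise = 10, effect_size = 2,
                                           seed = 13))
  std <- pool_standardization(tbl)
  X <- design_matrix(tbl, std)
  m_l1 <- fit_logistic(X, tbl$label, lambda = 10)
  m_rx <- fit_logistic(X, tbl$label, lambda = 10, relax = TRUE)
  expect_identical(m_rx$beta[-1] == 0, m_l1$beta[-1] == 0)
  active <- m_l1$beta[-1] != 0
  expect_true(all(abs(m_rx$beta[-1][active]) >= abs(m_l1$beta[-1][active]) - 1e-6))
})
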