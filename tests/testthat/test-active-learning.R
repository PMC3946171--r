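# D-optimal query selection: the Fisher information matrix, the determinant
# lemma, plateau detection, and the loop's determinism.

make_model <- function(beta, fim_eps = 1e-9) {
  nm <- c("(Intercept)", paste0("f", seq_len(length(beta) - 1L)))
  structure(list(beta = stats::setNames(beta, nm),
                 feature_names = nm[-1L],
                 standardization = list(
                   mean = stats::setNames(rep(0, length(beta) - 1L), nm[-1L]),
                   scale = stats::setNames(rep(1, length(beta) - 1L), nm[-1L])),
                 lambda = 0, l1_eps = 1e-6, fim_eps = fim_eps),
            class = "al_model")
}

test_that("Fisher information matches the closed form at beta = 0", {
  m <- make_model(c(0, 0))
  X <- matrix(c(1, 2), 1, 2)
  fim <- fisher_information(m, X)
  # w = sigma(0)(1 - sigma(0)) = 0.25
  expect_equal(unname(fim), 0.25 * matrix(c(1, 2, 2, 4), 2) + 1e-9 * diag(2),
               tolerance = 1e-12)
})

test_that("a far-margin cell contributes almost nothing", {
  m <- make_model(c(0, 10))
  X <- matrix(c(1, 10), 1, 2)  # beta'x = 100, w ~ 0
  fim <- fisher_information(m, X)
  expect_lt(max(abs(fim - 1e-9 * diag(2))), 1e-20)
})

test_that("the empty labeled set gives the ridge alone, with finite gain", {
  m <- make_model(c(0, 0, 0))
  fim <- fisher_information(m, matrix(0, 0, 3))
  expect_equal(unname(fim), 1e-9 * diag(3))
  expect_true(is.finite(information_gain(fim)))
  expect_equal(information_gain(fim), 3 * log(1e-9))
})

test_that("information gain is the log-determinant", {
  expect_equal(information_gain(diag(2)), 0)
  expect_equal(information_gain(diag(2, 2)), 2 * log(2))
  # random SPD matrix vs the cofactor-expansion oracle
  set.seed(21)
  A <- matrix(rnorm(25), 5)
  S <- crossprod(A) + diag(5) * 0.1
  expect_equal(information_gain(S), log(cofactor_det(S)), tolerance = 1e-10)
  expect_error(information_gain(matrix(c(1, 2, 2, 1), 2)), "positive definite")
  expect_error(information_gain(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("select_query agrees with brute-force determinant maximisation", {
  # several random pools; compare against det(I + w x x') per candidate
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60; p <- 6
    pool <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * p), n, p)))
    names(pool) <- paste0("f", 1:p)
    pool <- dplyr::mutate(pool, cell_id = dplyr::row_number(), .before = 1)
    beta <- rnorm(p + 1, sd = 0.5)
    m <- make_model(beta)
    fim <- fisher_information(m, cbind(1, as.matrix(pool[, -1]))) +
      diag(p + 1) * 0.01
    state <- structure(list(model = m,
                            labeled = tibble::tibble(cell_id = integer(0)),
                            fim = fim,
                            config = al_config()),
                       class = "al_state")
    picked <- select_query(state, pool, batch_size = 1)
    # brute force: evaluate det(fim + w x x') candidate by candidate
    dets <- vapply(seq_len(n), function(i) {
      x <- c(1, as.numeric(pool[i, -1]))
      s <- sigmoid(sum(beta * x))
      det(fim + s * (1 - s) * tcrossprod(x))
    }, numeric(1))
    expect_equal(picked, pool$cell_id[which.max(dets)])
  }
})

test_that("an orthogonal direction beats a duplicate of a sampled point", {
  # labeled mass along f1; candidates: duplicate of that point vs the same
  # norm along f2. At beta = 0 the scores are w * x' I^{-1} x.
  m <- make_model(c(0, 0, 0))
  xa <- c(1, 2, 0)
  fim <- fisher_information(m, matrix(rep(xa, 10), 10, byrow = TRUE))
  pool <- tibble::tibble(cell_id = 1:2, f1 = c(2, 0), f2 = c(0, 2))
  state <- structure(list(model = m, labeled = tibble::tibble(cell_id = integer(0)),
                          fim = fim, config = al_config()),
                     class = "al_state")
  expect_equal(select_query(state, pool, 1), 2)
  # hand check via the rank-one identity
  fim_inv <- solve(fim)
  score <- function(x) 0.25 * drop(t(x) %*% fim_inv %*% x)
  expect_gt(score(c(1, 0, 2)), score(c(1, 2, 0)))
})

test_that("batch_size equal to the pool returns a permutation of the pool", {
  pool <- small_pool(n = 15, seed = 4)
  m <- make_model(rep(0, length(feature_names(pool)) + 1))
  names(m$beta) <- c("(Intercept)", feature_names(pool))
  m$standardization <- pool_standardization(pool)
  m$feature_names <- feature_names(pool)
  fim <- fisher_information(m, design_matrix(pool, m$standardization))
  state <- structure(list(model = m, labeled = tibble::tibble(cell_id = integer(0)),
                          fim = fim, config = al_config()),
                     class = "al_state")
  picked <- select_query(state, pool, batch_size = nrow(pool))
  expect_setequal(picked, pool$cell_id)
  expect_error(select_query(state, pool[0, ], 1), "empty")
})

test_that("update_state appends gains, rejects conflicts, ignores duplicates", {
  pool <- small_pool(n = 60, seed = 5)
  oracle <- simulated_oracle(pool)
  st <- run_active_learning(pool, oracle, al_config(max_iterations = 0))
  expect_length(st$gain_history, 1)  # the first balanced pair
  st2 <- run_active_learning(pool, oracle, al_config(max_iterations = 10,
                                                     plateau_patience = 50))
  # informative labels raise the log-determinant above the ridge-only floor
  p <- length(st2$model$beta)
  expect_gt(utils::tail(st2$gain_history, 1), p * log(1e-9))
  # conflicting relabel errors; consistent duplicate is a no-op
  id <- st2$labeled$cell_id[1]
  lab <- st2$labeled$label[1]
  expect_error(update_state(st2, tibble::tibble(cell_id = id, label = -lab),
                            pool), "Conflict")
  st3 <- update_state(st2, tibble::tibble(cell_id = id, label = lab), pool)
  expect_equal(nrow(st3$labeled), nrow(st2$labeled))
  expect_error(update_state(st2, tibble::tibble(cell_id = 1e6, label = 1),
                            pool), "absent")
})

test_that("plateau detection follows the relative-increase rule", {
  expect_false(check_convergence(seq(1, 10), 1e-3, 3))        # linear growth
  expect_true(check_convergence(rep(2, 5), 1e-3, 5))          # constant
  expect_false(check_convergence(rep(2, 4), 1e-3, 5))         # too short
  # worked example: increments 1e-4 relative to a base > 1
  expect_true(check_convergence(c(0, 1, 1.0001, 1.0002, 1.0003), 1e-3, 3))
  expect_error(check_convergence(numeric(0)), "non-empty")
})

test_that("the loop is deterministic and respects max_iterations", {
  pool <- small_pool(n = 100, seed = 8)
  oracle <- simulated_oracle(pool)
  cfg <- al_config(max_iterations = 12, seed = 5, plateau_patience = 50)
  a <- run_active_learning(pool, oracle, cfg)
  b <- run_active_learning(pool, oracle, cfg)
  expect_identical(a$labeled, b$labeled)     # same query sequence
  expect_identical(a$model$beta, b$model$beta)
  expect_equal(nrow(a$labeled), 2 + 12)
  z <- run_active_learning(pool, oracle, al_config(max_iterations = 0, seed = 5))
  expect_equal(nrow(z$labeled), 2)           # initial examples only
})

test_that("the loop converges on an information-gain plateau", {
  pool <- small_pool(n = 150, seed = 9)
  oracle <- simulated_oracle(pool)
  st <- run_active_learning(pool, oracle,
                            al_config(max_iterations = 100, plateau_tol = 0.05,
                                      plateau_patience = 3, seed = 1))
  expect_true(st$converged)
  expect_lt(nrow(st$labeled), 102)
})
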