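test_that("a single component collapses to per-equation OLS", {
  set.seed(81)
  m <- nutrition_model()
  sim <- simulate_pls_data(m, 150, nutrition_global_spec(), seed = 81)
  fit <- pls_path(sim$data, m)
  fm <- fimix(fit, m, K = 1, seed = 1)
  expect_equal(unname(fm$mixing_proportions), 1)
  S <- fit$scores
  ll <- 0
  for (j in m$endogenous) {
    P <- m$latents[m$inner[j, ] == 1]
    cf <- qr.solve(S[, P, drop = FALSE], S[, j])
    expect_equal(unname(fm$coefficients[[1]][j, P]), unname(cf),
                 tolerance = 1e-8)
    res <- S[, j] - S[, P, drop = FALSE] %*% cf
    psi <- mean(res^2)
    ll <- ll + sum(dnorm(res, 0, sqrt(psi), log = TRUE))
  }
  expect_equal(fm$log_likelihood, ll, tolerance = 1e-6)
  expect_true(is.na(fm$entropy))
  expect_true(all(abs(rowSums(fm$posteriors) - 1) < 1e-12))
})

test_that("the EM trace is nondecreasing and posteriors stay stochastic", {
  m <- nutrition_model()
  fx <- fixture_suite(83)
  for (nm in c("one_segment", "two_segment_separated",
               "two_segment_overlapping")) {
    fit <- pls_path(fx[[nm]]$data, m)
    for (K in 2:3) {
      fm <- fimix(fit, m, K, seed = 7, n_restarts = 3)
      expect_true(all(diff(fm$em_trace) >= -1e-8))
      expect_true(all(abs(rowSums(fm$posteriors) - 1) < 1e-8))
      expect_true(all(fm$posteriors >= 0 & fm$posteriors <= 1))
      expect_true(all(fm$mixing_proportions > 0))
      expect_equal(sum(fm$mixing_proportions), 1, tolerance = 1e-12)
      expect_true(all(diff(fm$mixing_proportions) <= 1e-12))  # canonical
    }
  }
})

test_that("the parameter count and information criteria are exact", {
  expect_equal(fimix_n_parameters(1, 3), 3)
  expect_equal(fimix_n_parameters(2, 3), 7)
  expect_error(fimix_n_parameters(0, 3), "at least 1")
  expect_error(fimix_n_parameters(2, -1), "non-negative")
  expect_equal(fimix_n_parameters(2, 3, n_equations = 3,
                                  count_variances = TRUE), 13)
  expect_equal(unname(information_criteria(0, 0, 10)), c(0, 0, 0))
  ic <- information_criteria(-100, fimix_n_parameters(2, 3), 216)
  expect_equal(unname(ic["AIC"]), 214)
  expect_equal(unname(ic["BIC"]), 200 + log(216) * 7, tolerance = 1e-10)
  expect_equal(unname(ic["CAIC"]), 200 + (log(216) + 1) * 7,
               tolerance = 1e-10)
  # CAIC - BIC = N identically
  for (N in c(0, 3, 11)) {
    ic <- information_criteria(-55.5, N, 99)
    expect_equal(unname(ic["CAIC"] - ic["BIC"]), N, tolerance = 1e-10)
  }
  expect_error(information_criteria(-1, 2, 0), "at least 1")
})

test_that("normed entropy hits its boundary values and hand example", {
  hard <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(entropy_criterion(hard), 1)
  unif <- matrix(1 / 3, 5, 3)
  expect_equal(entropy_criterion(unif), 0, tolerance = 1e-12)
  p <- matrix(rep(c(0.9, 0.1), each = 4), 4, 2)
  expect_equal(entropy_criterion(p),
               1 - (-0.9 * log(0.9) - 0.1 * log(0.1)) / log(2),
               tolerance = 1e-12)
  expect_true(is.na(entropy_criterion(matrix(1, 4, 1))))
  expect_error(entropy_criterion(rbind(c(0.5, 0.2))), "row-stochastic")
})

test_that("two mixed regressions are recovered from scores", {
  m <- nutrition_model()
  mix <- list(
    segment_spec(0.5, c("X -> Y1" = 0.8, "Y1 -> Y2" = 0.8,
                        "Y2 -> Y3" = 0.8)),
    segment_spec(0.5, c("X -> Y1" = -0.8, "Y1 -> Y2" = -0.8,
                        "Y2 -> Y3" = -0.8)))
  sc <- simulate_mixture_scores(m, n = 400, segments = mix, seed = 85)
  fm <- fimix(sc$scores, m, K = 2, seed = 85, n_restarts = 5)
  expect_gt(ari(fm$assignment, sc$true_labels), 0.9)
  slopes <- sapply(fm$coefficients, function(B)
    B[cbind(c("Y1", "Y2", "Y3"), c("X", "Y1", "Y2"))])
  err <- min(max(abs(slopes - c(0.8, 0.8, 0.8, -0.8, -0.8, -0.8))),
             max(abs(slopes - c(-0.8, -0.8, -0.8, 0.8, 0.8, 0.8))))
  expect_lt(err, 0.1)
})

test_that("relabelling symmetry: criteria are permutation invariant", {
  m <- nutrition_model()
  sim <- simulate_pls_data(m, 216, separated_segments(), seed = 87)
  fit <- pls_path(sim$data, m)
  f1 <- fimix(fit, m, 2, seed = 11, n_restarts = 4)
  f2 <- fimix(fit, m, 2, seed = 23, n_restarts = 4)
  # different restarts, same maximiser: identical criteria
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-3)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-2)
  expect_equal(f1$entropy, f2$entropy, tolerance = 1e-3)
  # canonical order sorts by descending mixing proportion
  expect_true(all(diff(f1$mixing_proportions) <= 1e-12))
})

test_that("component-count selection favours the true mixture order", {
  m <- nutrition_model()
  sim <- simulate_pls_data(m, 216, separated_segments(), seed = 89)
  fit <- pls_path(sim$data, m)
  sel <- fimix_select(fit, m, K_range = 2:3, seed = 89, n_restarts = 4)
  expect_equal(nrow(sel$criteria), 3L)  # K = 1 baseline + 2 candidates
  expect_true(all(is.finite(as.matrix(
    sel$criteria[, c("logLik", "AIC", "BIC", "CAIC")]))))
  expect_equal(sel$recommended_K, 2L)
  # homogeneous data: no crisp segmentation at any K
  sim0 <- simulate_pls_data(m, 216, nutrition_global_spec(), seed = 90)
  fit0 <- pls_path(sim0$data, m)
  sel0 <- fimix_select(fit0, m, K_range = 2:3, seed = 90, n_restarts = 4)
  expect_true(all(sel0$criteria$EN[sel0$criteria$K > 1] < 0.5))
})

test_that("mixing proportions are recovered without material bias", {
  m <- nutrition_model()
  mix <- list(
    segment_spec(0.6, c("X -> Y1" = 0.8, "Y1 -> Y2" = 0.8,
                        "Y2 -> Y3" = 0.8)),
    segment_spec(0.4, c("X -> Y1" = -0.8, "Y1 -> Y2" = -0.8,
                        "Y2 -> Y3" = -0.8)))
  rho <- sapply(1:50, function(r) {
    sc <- simulate_mixture_scores(m, 1000, mix, seed = 1000 + r)
    fm <- fimix(sc$scores, m, 2, seed = r, n_restarts = 2)
    fm$mixing_proportions[1]
  })
  expect_lt(abs(mean(rho) - 0.6), 0.05)
})

test_that("infeasible component counts are rejected", {
  m <- nutrition_model()
  sim <- simulate_pls_data(m, 30, nutrition_global_spec(), seed = 91)
  fit <- pls_path(sim$data, m)
  expect_error(fimix(fit, m, K = 20, seed = 1), "too large")
  expect_error(fimix(fit, m, K = 0, seed = 1), "at least 1")
})
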