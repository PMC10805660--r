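test_that("single-indicator blocks load exactly 1 and scores standardize", {
  sim <- simulate_pls_data(nutrition_model(), n = 216,
                           segments = nutrition_global_spec(), seed = 2)
  fit <- pls_path(sim$data, nutrition_model())
  expect_true(fit$converged)
  expect_lt(fit$n_iterations, 100)
  expect_equal(unname(fit$loadings[["X1.1"]]), 1, tolerance = 1e-12)
  expect_equal(unname(colMeans(fit$scores)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(fit$scores, 2, sd)), rep(1, 4),
               tolerance = 1e-10)
  # communality = loading^2, inner residual identity
  expect_equal(fit$communalities, fit$loadings^2, tolerance = 1e-12)
  for (j in fit$model$endogenous) {
    pred <- as.vector(fit$scores %*% fit$path_coefficients[j, ])
    expect_equal(fit$inner_residuals[, j], fit$scores[, j] - pred,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("path coefficients equal per-equation OLS on the scores", {
  for (seed in 1:3) {
    sim <- simulate_pls_data(nutrition_model(), n = 150,
                             segments = nutrition_global_spec(),
                             seed = seed)
    fit <- pls_path(sim$data, nutrition_model())
    for (j in fit$model$endogenous) {
      P <- fit$model$latents[fit$model$inner[j, ] == 1]
      ols <- qr.solve(fit$scores[, P, drop = FALSE], fit$scores[, j])
      expect_equal(unname(fit$path_coefficients[j, P]), unname(ols),
                   tolerance = 1e-10)
    }
  }
})

test_that("a block of identical indicators collapses to the indicator", {
  set.seed(3)
  x <- rnorm(60)
  y <- 0.6 * x + rnorm(60, sd = 0.8)
  d <- data.frame(a1 = x, a2 = x, a3 = x, b1 = y)
  m <- path_model(list(A = c("a1", "a2", "a3"), B = "b1"), "A -> B")
  fit <- pls_path(d, m)
  w <- fit$weights[c("a1", "a2", "a3")]
  expect_equal(unname(w / w[[1]]), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(fit$loadings[c("a1", "a2", "a3")]), rep(1, 3),
               tolerance = 1e-10)
  expect_equal(unname(fit$scores[, "A"]), unname(scale(x)[, 1]),
               tolerance = 1e-8)
})

test_that("inner weighting schemes follow their definitions", {
  set.seed(5)
  m <- path_model(list(A = "a1", B = "b1", C = "c1"),
                  c("A -> B", "B -> C"))
  S <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  S[, 2] <- 0.5 * S[, 1] + rnorm(100, sd = 0.5)
  S[, 3] <- -0.4 * S[, 2] + rnorm(100, sd = 0.5)
  S <- scale(S)
  C <- cor(S)
  Ec <- inner_weights(S, m, "centroid")
  Ef <- inner_weights(S, m, "factor")
  Ep <- inner_weights(S, m, "path")
  # nonadjacent pairs are zero under all schemes
  for (E in list(Ec, Ef, Ep)) {
    expect_equal(E["A", "C"], 0)
    expect_equal(E["C", "A"], 0)
    expect_equal(diag(E), c(A = 0, B = 0, C = 0))
  }
  expect_equal(Ec["A", "B"], sign(C["A", "B"]))
  expect_equal(Ec["C", "B"], sign(C["C", "B"]))
  expect_equal(Ef["A", "B"], C["A", "B"], tolerance = 1e-12)
  # path scheme: predecessors by regression, successors by correlation
  expect_equal(Ep["B", "A"],
               unname(coef(lm(S[, "B"] ~ S[, "A"]))[2]),
               tolerance = 1e-10)
  expect_equal(Ep["B", "C"], C["B", "C"], tolerance = 1e-12)
})

test_that("Mode A weights are proportional to proxy covariances", {
  set.seed(8)
  z <- rnorm(500)
  x1 <- 0.8 * z + rnorm(500, sd = 0.2)
  x2 <- 0.4 * z + rnorm(500, sd = 0.2)
  Xb <- cbind(a = x1, b = x2)
  w <- outer_weights_mode_a(Xb, z, normalize = FALSE)
  expect_equal(unname(w), unname(as.vector(cov(Xb, z))), tolerance = 1e-12)
  expect_equal(unname(w[["a"]] / w[["b"]]), cov(x1, z) / cov(x2, z),
               tolerance = 1e-12)
  # single indicator: score is the standardized indicator
  w1 <- outer_weights_mode_a(cbind(only = x1), z)
  expect_equal(sd(x1 * w1), 1, tolerance = 1e-12)
  # uncorrelated proxy -> degenerate weights
  expect_error(outer_weights_mode_a(Xb, rep(c(1, -1), 250) * 0), "zero-variance")
  set.seed(9)
  noise <- cbind(n1 = rnorm(6))
  expect_error(outer_weights_mode_a(matrix(0.5 + numeric(12), 6, 2), rnorm(6)),
               "uncorrelated|degenerate")
})

test_that("Mode B weights solve the block normal equations", {
  set.seed(11)
  z <- rnorm(400)
  x1 <- 0.7 * z + rnorm(400, sd = 0.4)
  x2 <- 0.5 * x1 + 0.3 * z + rnorm(400, sd = 0.4)
  Xb <- cbind(a = x1, b = x2)
  w <- outer_weights_mode_b(Xb, z, normalize = FALSE)
  oracle <- solve(cov(Xb), cov(Xb, z))
  expect_equal(unname(w), unname(as.vector(oracle)), tolerance = 1e-10)
  # orthonormal block: Mode B == Mode A
  Q <- qr.Q(qr(matrix(rnorm(400 * 2), 400, 2))) * sqrt(399)
  colnames(Q) <- c("q1", "q2")
  wa <- outer_weights_mode_a(Q, z, normalize = FALSE)
  wb <- outer_weights_mode_b(Q, z, normalize = FALSE)
  expect_equal(unname(wa), unname(wb), tolerance = 0.02)
  # singular block covariance fails
  expect_error(outer_weights_mode_b(cbind(a = x1, b = x1), z), "singular")
})

test_that("location parameters follow the weighted-mean identity", {
  set.seed(13)
  x <- rnorm(100, mean = 9.231, sd = 2)
  y1 <- 5 + 0.5 * x + rnorm(100)
  y2 <- 0.8 * y1 + rnorm(100)
  d <- data.frame(x1 = x, y1 = y1, y2 = y2)
  m <- path_model(list(X = "x1", Y = c("y1", "y2")), "X -> Y")
  fit <- pls_path(d, m)
  lp <- location_parameters(fit)
  # single-indicator latent: mean equals the indicator's sample mean
  expect_equal(unname(lp$means[["X"]]), mean(x), tolerance = 1e-10)
  # general block: weighted indicator means with weights normalised to 1
  wY <- fit$weights[c("y1", "y2")]
  expect_equal(unname(lp$means[["Y"]]),
               sum(wY / sum(wY) * c(mean(y1), mean(y2))),
               tolerance = 1e-10)
  # intercept identity at the means
  expect_equal(unname(lp$intercepts[["Y"]]),
               unname(lp$means[["Y"]] -
                        fit$path_coefficients["Y", "X"] * lp$means[["X"]]),
               tolerance = 1e-10)
  # all-centred data: means and intercepts vanish
  fit0 <- pls_path(scale(d, scale = FALSE), m)
  expect_equal(unname(fit0$means), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(fit0$inner_intercepts), 0, tolerance = 1e-10)
})

test_that("residuals vanish on noiseless data and obey least squares", {
  fx <- fixture_suite(2)
  m <- nutrition_model()
  fit <- pls_path(fx$noiseless_chain$data, m)
  expect_lt(max(abs(fit$outer_residuals)), 1e-10)
  expect_lt(max(abs(fit$inner_residuals)), 1e-10)
  # structural residuals orthogonal to predecessor scores
  fit2 <- pls_path(fx$one_segment$data, m)
  for (j in m$endogenous) {
    P <- m$latents[m$inner[j, ] == 1]
    expect_lt(max(abs(crossprod(fit2$scores[, P, drop = FALSE],
                                fit2$inner_residuals[, j]))), 1e-8)
  }
  # brute-force evaluation on a 5-unit toy
  d <- data.frame(a1 = c(1, 2, 4, 3, 5), a2 = c(2, 1, 3, 5, 4),
                  b1 = c(1, 3, 2, 5, 4), b2 = c(2, 4, 1, 3, 5))
  tm <- toy_model()
  ft <- pls_path(d, tm)
  X <- ft$data_std
  for (l in tm$latents) for (q in tm$blocks[[l]])
    expect_equal(ft$outer_residuals[, q],
                 X[, q] - ft$loadings[[q]] * ft$scores[, l],
                 tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ft$inner_residuals[, "B"],
               ft$scores[, "B"] -
                 ft$path_coefficients["B", "A"] * ft$scores[, "A"],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("flipping a block's indicators flips signs but not fit quality", {
  d <- toy_data(seed = 21)
  m <- toy_model()
  f1 <- pls_path(d, m)
  d2 <- d
  d2$b1 <- -d2$b1
  d2$b2 <- -d2$b2
  f2 <- pls_path(d2, m)
  expect_equal(abs(f1$path_coefficients["B", "A"]),
               abs(f2$path_coefficients["B", "A"]), tolerance = 1e-8)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-8)
  expect_equal(unname(f1$communalities[c("b1", "b2")]),
               unname(f2$communalities[c("b1", "b2")]), tolerance = 1e-8)
  expect_equal(abs(unname(f1$loadings[c("b1", "b2")])),
               abs(unname(f2$loadings[c("b1", "b2")])), tolerance = 1e-8)
  # sign policy: sum of indicator-score correlations is non-negative
  for (f in list(f1, f2)) for (l in m$latents)
    expect_gte(sum(cor(f$data_std[, m$blocks[[l]]], f$scores[, l])), 0)
})

test_that("prediction reproduces training scores and structural fits", {
  d <- toy_data(seed = 31)
  fit <- pls_path(d, toy_model())
  p <- predict(fit)
  expect_equal(unname(p$scores), unname(fit$scores), tolerance = 1e-10)
  pnew <- predict(fit, newdata = d[1:10, ])
  expect_equal(unname(pnew$scores), unname(fit$scores[1:10, ]),
               tolerance = 1e-10)
  expect_equal(unname(fitted(fit) + residuals(fit)),
               unname(fit$scores[, "B", drop = FALSE]), tolerance = 1e-10)
})
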