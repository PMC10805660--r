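test_that("Cronbach's alpha matches its closed form", {
  R0 <- diag(2)
  expect_equal(cronbach_alpha(R0), 0)
  R1 <- matrix(1, 2, 2)
  expect_equal(cronbach_alpha(R1), 1)
  # p = 3, all off-diagonals 0.5: numerator 3, variance 6, times 3/2
  R <- matrix(0.5, 3, 3)
  diag(R) <- 1
  expect_equal(cronbach_alpha(R), 0.75)
  # single indicator: defined as 1 by convention
  expect_equal(cronbach_alpha(matrix(1, 1, 1)), 1)
  # data-matrix input agrees with correlation-matrix input
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  expect_equal(cronbach_alpha(x), cronbach_alpha(cor(x)), tolerance = 1e-12)
})

test_that("AVE and composite reliability match hand evaluation", {
  expect_equal(ave(c(1, 1), c(0, 0)), 1)
  expect_equal(ave(c(0.6, 0.8)), 0.5)
  expect_equal(ave(c(0, 0), c(1, 1)), 0)
  expect_error(ave(numeric(0)), "empty")
  expect_equal(composite_reliability(1, 0), 1)
  expect_equal(composite_reliability(c(0.7, 0.7), c(0.51, 0.51)),
               1.96 / 2.98, tolerance = 1e-12)
  expect_equal(composite_reliability(c(0, 0), c(1, 1)), 0)
})

test_that("VIF equals the reciprocal unexplained variance", {
  set.seed(4)
  X <- qr.Q(qr(matrix(rnorm(300), 100, 3))) * sqrt(99)
  colnames(X) <- c("p1", "p2", "p3")
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-3)
  Z <- matrix(rnorm(300), 100, 3)
  Z[, 3] <- 0.6 * Z[, 1] + 0.4 * Z[, 2] + rnorm(100, sd = 0.5)
  v <- vif(Z)
  oracle <- sapply(1:3, function(j)
    1 / (1 - summary(lm(Z[, j] ~ Z[, -j]))$r.squared))
  expect_equal(unname(v), oracle, tolerance = 1e-8)
  expect_true(all(v >= 1))
  W <- cbind(Z[, 1], Z[, 1], Z[, 2])
  expect_warning(vw <- vif(W), "collinearity")
  expect_true(any(!is.finite(vw)))
  expect_error(vif(Z[, 1, drop = FALSE]), "two predictor")
})

test_that("Q-squared follows the chained-product formula", {
  expect_equal(q_squared(c(0.148, 0.686, 0.078)), 0.753, tolerance = 5e-4)
  expect_equal(q_squared(c(0, 0, 0)), 0)
  expect_equal(q_squared(0.42), 0.42)
  expect_error(q_squared(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(q_squared(-0.1))
  # monotone nondecreasing in each argument
  set.seed(6)
  for (k in 1:20) {
    r2 <- runif(3)
    bumped <- pmin(r2 + c(0.1, 0, 0), 1)
    expect_gte(q_squared(bumped), q_squared(r2))
  }
})

test_that("GoF combines communality and R-squared geometrically", {
  # synthetic fit with known averages: mean communality 0.64, mean R2 0.25
  m <- path_model(list(A = c("a1", "a2"), B = c("b1", "b2")), "A -> B")
  fake <- structure(list(
    model = m,
    communalities = c(a1 = 0.64, a2 = 0.64, b1 = 0.64, b2 = 0.64),
    r_squared = c(B = 0.25)), class = "plspath")
  expect_equal(gof(fake), 0.4, tolerance = 1e-12)
  expect_equal(gof(fake, "pooled"), 0.4, tolerance = 1e-12)
  fake$communalities[] <- 1
  fake$r_squared[] <- 1
  expect_equal(gof(fake), 1)
  fake$r_squared[] <- 0
  expect_equal(gof(fake), 0)
  # average and pooled forms agree whenever blocks share a size
  fx <- fixture_suite(3)
  fit <- pls_path(fx$one_segment$data, nutrition_model())
  g_avg <- gof(fit)
  g_pool <- gof(fit, "pooled")
  expect_true(abs(g_avg - g_pool) < 0.05)  # unequal blocks: close, not equal
  d <- toy_data(seed = 41)
  ft <- pls_path(d, toy_model())
  expect_equal(gof(ft), gof(ft, "pooled"), tolerance = 1e-12)
})

test_that("f-squared matches the two-regression oracle", {
  d <- toy_data(seed = 43)
  fit <- pls_path(d, toy_model())
  r2 <- fit$r_squared[["B"]]
  # single-predictor closed form
  expect_equal(f_squared(fit, "A", "B"), r2 / (1 - r2), tolerance = 1e-10)
  # two-predictor equation against an lm() oracle
  set.seed(44)
  n <- 200
  x <- rnorm(n); z <- rnorm(n)
  y <- 0.5 * x + 0.0 * z + rnorm(n, sd = 0.7)
  dd <- data.frame(x1 = x, x2 = x + rnorm(n, sd = 0.3),
                   z1 = z, z2 = z + rnorm(n, sd = 0.3),
                   y1 = y, y2 = y + rnorm(n, sd = 0.3))
  m2 <- path_model(list(X = c("x1", "x2"), Z = c("z1", "z2"),
                        Y = c("y1", "y2")),
                   c("X -> Y", "Z -> Y"))
  f2 <- pls_path(dd, m2)
  sc <- as.data.frame(f2$scores)
  r_full <- summary(lm(Y ~ X + Z - 1, sc))$r.squared
  r_red <- summary(lm(Y ~ Z - 1, sc))$r.squared
  expect_equal(f_squared(f2, "X", "Y"), (r_full - r_red) / (1 - r_full),
               tolerance = 1e-6)
  # a predictor with (near-)zero coefficient has (near-)zero effect size
  expect_lt(abs(f_squared(f2, "Z", "Y")), 0.03)
  expect_error(f_squared(f2, "Y", "X"), "no structural path")
})

test_that("the evaluation report assembles all indices consistently", {
  fx <- fixture_suite(5)
  fit <- pls_path(fx$one_segment$data, nutrition_model())
  ev <- evaluate(fit)
  expect_s3_class(ev, "pls_evaluation")
  expect_equal(nrow(ev$outer), 10L)
  expect_equal(nrow(ev$blocks), 4L)
  blk <- ev$blocks
  expect_true(all(blk$ave >= 0 & blk$ave <= 1))
  expect_true(all(blk$composite_reliability >= 0 &
                    blk$composite_reliability <= 1))
  # single-indicator block: AVE and composite reliability exactly 1
  expect_equal(blk$ave[blk$latent == "X"], 1)
  expect_equal(blk$composite_reliability[blk$latent == "X"], 1)
  expect_equal(ev$q_squared, q_squared(fit$r_squared), tolerance = 1e-12)
  expect_true(all(fit$r_squared >= 0 & fit$r_squared <= 1))
  expect_gte(ev$q_squared, max(fit$r_squared) - 1e-12)
  # cross-loadings: own-block correlation equals the loading
  for (l in fit$model$latents) for (q in fit$model$blocks[[l]])
    expect_equal(ev$cross_loadings[q, l], unname(fit$loadings[q]),
                 tolerance = 1e-10)
})
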