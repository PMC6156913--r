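test_that("interaction matrix is the elementwise environment-dosage product", {
  expect_equal(build_interaction_matrix(matrix(c(0, 2)), c(1, 2)),
               matrix(c(0, 4)))
  expect_equal(build_interaction_matrix(matrix(1:6, 3, 2), rep(0, 3)),
               matrix(0, 3, 2))
  expect_equal(build_interaction_matrix(matrix(c(2, 2)), c(0, 1)),
               matrix(c(0, 2)))
  expect_error(build_interaction_matrix(matrix(1:4, 2, 2), 1:3),
               "does not match")
})

test_that("intercept-only residualization reduces to mean-centering", {
  r <- residualize(c(1, 2, 3, 4), EG = matrix(rnorm(4)))
  expect_equal(r$y_res, c(-1.5, -0.5, 0.5, 1.5))
})

test_that("residuals match an explicit normal-equations solve", {
  set.seed(21)
  n <- 6
  Z <- matrix(rnorm(n), n, 1)
  G <- matrix(sample(0:2, n, replace = TRUE), n, 1)
  E <- rnorm(n)
  y <- rnorm(n)
  EG <- build_interaction_matrix(G, E)
  r <- residualize(y, EG, Z = Z, G = G, E = E)
  D <- cbind(1, Z, G, E)
  beta <- solve(t(D) %*% D, t(D) %*% y)        # independent oracle
  expect_equal(r$y_res, as.numeric(y - D %*% beta), tolerance = 1e-10)
  bX <- solve(t(D) %*% D, t(D) %*% EG)
  expect_equal(unname(r$X_res), unname(EG - D %*% bX), tolerance = 1e-10)
})

test_that("residuals are orthogonal to every adjustment column", {
  set.seed(22)
  n <- 80
  Z <- cbind(rnorm(n), rbinom(n, 1, 0.4))
  G <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  E <- rnorm(n)
  y <- rnorm(n) + 0.3 * E + 0.2 * Z[, 1]
  r <- residualize(y, build_interaction_matrix(G, E), Z = Z, G = G, E = E)
  D <- cbind(1, Z, G, E)
  expect_lt(max(abs(crossprod(D, r$y_res))), 1e-8)
  expect_lt(max(abs(crossprod(D, r$X_res))), 1e-8)
})

test_that("identity-link residualization is homogeneous in the trait", {
  set.seed(23)
  n <- 30
  G <- matrix(rbinom(n * 2, 2, 0.2), n, 2)
  E <- rnorm(n)
  y <- rnorm(n)
  EG <- build_interaction_matrix(G, E)
  r1 <- residualize(y, EG, G = G, E = E)
  r2 <- residualize(3.7 * y, EG, G = G, E = E)
  expect_equal(r2$y_res, 3.7 * r1$y_res, tolerance = 1e-12)
})

test_that("binary traits use response residuals from the null logistic fit", {
  set.seed(24)
  n <- 200
  Z <- matrix(rnorm(n), n, 1)
  G <- matrix(rbinom(n, 2, 0.3), n, 1)
  E <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 + 0.5 * Z[, 1]))
  r <- residualize(y, build_interaction_matrix(G, E), Z = Z, G = G, E = E,
                   link = "logit")
  fit <- glm(y ~ Z + G + E, family = binomial())   # independent fit
  expect_equal(r$y_res, unname(y - fitted(fit)), tolerance = 1e-6)
  # score equations make response residuals orthogonal to the design
  expect_lt(max(abs(crossprod(cbind(1, Z, G, E), r$y_res))), 1e-6)
  expect_error(residualize(rnorm(n), build_interaction_matrix(G, E),
                           link = "logit"),
               "\\{0,1\\}")
})

test_that("degenerate design columns are pruned and collinearity is an error", {
  X <- cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), d = c(1, 2, 3, 4),
             e = c(0, 1, 0, 1))
  pr <- prune_degenerate(X)
  expect_equal(colnames(pr$X), c("b", "e"))
  expect_match(pr$removed[["a"]], "constant")
  expect_match(pr$removed[["d"]], "duplicate of b")

  full <- cbind(x = c(1, 2, 3, 5), y = c(2, 1, 0, 7))
  expect_identical(prune_degenerate(full)$X, full)

  # a column that is a linear combination (not an exact duplicate) survives
  # duplicate pruning; the QR pivot drops it without changing the residuals
  set.seed(91)
  n <- 10
  Z <- cbind(z1 = rnorm(n))
  Z <- cbind(Z, z2 = 2 * Z[, 1] + 3)
  y <- rnorm(n); EG <- matrix(rnorm(n))
  r <- residualize(y, EG, Z = Z)
  expect_match(r$pruned[["z2"]], "collinear")
  r_ref <- residualize(y, EG, Z = Z[, 1, drop = FALSE])
  expect_equal(r$y_res, r_ref$y_res, tolerance = 1e-12)
})

test_that("monomorphic genotype columns do not break residualization", {
  n <- 12
  G <- cbind(mono = rep(0, n), ok = rbinom(n, 2, 0.4))
  E <- rnorm(n)
  r <- residualize(rnorm(n), build_interaction_matrix(G, E), G = G, E = E)
  expect_true("mono" %in% names(r$pruned))
  expect_equal(r$M, 2)   # interaction columns are never pruned here
})
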