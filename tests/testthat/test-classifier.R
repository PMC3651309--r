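test_that("isotropic log-density matches the normal closed forms", {
  expect_equal(exp(logdensity_original(0, 0, 1)), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(exp(logdensity_original(c(0, 0), c(0, 0), 1)), 1 / (2 * pi),
               tolerance = 1e-12)
  # moving one sigma away in one coordinate multiplies the density by e^-1/2
  at_mode <- logdensity_original(c(1, 2), c(1, 2), 0.5)
  off <- logdensity_original(c(1.5, 2), c(1, 2), 0.5)
  expect_equal(off - at_mode, -0.5, tolerance = 1e-12)
  expect_error(logdensity_original(0, 0, 0), "sigma")
})

test_that("compressed density reduces to the original one when Phi = I", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    y <- rnorm(n); s <- rnorm(n); sigma <- runif(1, 0.2, 3)
    expect_equal(logdensity_compressed(y, diag(n), s, sigma),
                 logdensity_original(y, s, sigma), tolerance = 1e-12)
  }
})

test_that("compressed density has the correct covariance and normalizer", {
  # M = 1, Phi = (1, 1): variance sigma^2 Phi Phi^T = 2
  expect_equal(exp(logdensity_compressed(0, matrix(c(1, 1), 1, 2),
                                         c(0, 0), 1)),
               1 / sqrt(4 * pi), tolerance = 1e-12)
  # at y = Phi s the density equals [(2 pi)^M |sigma^2 Phi Phi^T|]^(-1/2)
  set.seed(17)
  P <- matrix(rnorm(8), 2, 4)
  s <- rnorm(4); sigma <- 0.7
  cov <- sigma^2 * tcrossprod(P)
  expect_equal(logdensity_compressed(as.vector(P %*% s), P, s, sigma),
               -0.5 * (2 * log(2 * pi) + determinant(cov)$modulus[1]),
               tolerance = 1e-10)
  # rank-deficient Phi Phi^T is rescued by the trace ridge (finite density)
  Psing <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE)  # rank 1
  expect_true(is.finite(logdensity_compressed(c(0, 0), Psing, c(0, 0), 1)))
  # an all-zero Phi cannot be conditioned at all
  expect_error(logdensity_compressed(c(0, 0), matrix(0, 2, 3), rep(0, 3), 1),
               class = "mcsd_singular_covariance_error")
})

test_that("two-class Bayes risk quadrature agrees with the closed form", {
  # identical densities: tails sum to one with weight 1/2
  p <- function(y) dnorm(y, 1, 2)
  expect_equal(bayes_risk_two_class(p, p, y0 = 0.3), 0.5, tolerance = 1e-8)

  # unit-variance Gaussians at 0 and 2, boundary 1: risk = pnorm(-1)
  br <- bayes_risk_two_class(function(y) dnorm(y, 0, 1),
                             function(y) dnorm(y, 2, 1), y0 = 1)
  expect_equal(br, pnorm(-1), tolerance = 1e-6)
  expect_equal(bayes_risk_gaussian(0, 2, y0 = 1), pnorm(-1),
               tolerance = 1e-12)

  # y0 -> +Inf pushes the risk to P2
  expect_equal(bayes_risk_gaussian(0, 2, y0 = 50, P1 = 0.3, P2 = 0.7), 0.7,
               tolerance = 1e-9)
  expect_error(bayes_risk_gaussian(0, 2, y0 = 1, P1 = 0.6, P2 = 0.6),
               "sum to 1")
})

test_that("utility estimators behave at the coincident and separated extremes", {
  # identity method: exact Kronecker delta
  mu <- cbind(c(0, 0), c(0, 0))
  model_same <- mcsd_model(diag(2), rbind(mu[1, ], mu[2, ]),
                           sigma = 1, class_names = c("a", "b"))
  expect_equal(unname(estimate_utility(model_same, "identity")), diag(2))

  # coincident compressed means: pairwise Bayes risk is 0.5 off-diagonal
  u_same <- estimate_utility(model_same, "pairwise_br")
  expect_equal(unname(u_same), matrix(c(1, 0.5, 0.5, 1), 2), tolerance = 1e-12)

  # far-separated classes: Monte-Carlo utility approaches the identity
  means <- cbind(rep(0, 3), rep(10, 3), rep(-10, 3))
  model_far <- mcsd_model(diag(3), means, sigma = 1)
  u_mc <- estimate_utility(model_far, "mc_multiclass", n_mc = 10000, seed = 4)
  expect_lt(max(abs(u_mc - diag(3))), 0.01)
  u_br <- estimate_utility(model_far, "pairwise_br")
  expect_lt(max(abs(u_br - diag(3))), 1e-6)

  expect_error(estimate_utility(model_far, "mc_multiclass", n_mc = 10),
               class = "mcsd_config_error")
  expect_error(estimate_utility(model_far, "mc_multiclass"),
               class = "mcsd_config_error")
})

test_that("utility matrices valuing errors above correct decisions are rejected", {
  u <- matrix(c(1, 0, 2, 1), 2)
  expect_error(validate_utility(u), class = "mcsd_config_error")
  expect_warning(validate_utility(u, strict = FALSE), "above")
  expect_silent(validate_utility(diag(2)))
})

test_that("identity utility with equal priors is exactly maximum likelihood", {
  set.seed(23)
  for (i in 1:100) {
    M <- sample(1:3, 1); N <- M + sample(1:3, 1); n <- sample(2:4, 1)
    P <- matrix(rnorm(M * N), M, N)
    model <- mcsd_model(P, matrix(rnorm(N * n), N, n),
                        sigma = runif(1, 0.3, 2))
    y <- rnorm(M)
    ml <- which.max(vapply(seq_len(n), function(k)
      logdensity_compressed(y, P, model$class_means[, k], model$sigma),
      numeric(1)))
    expect_identical(classify_compressed(model, y), ml)
  }
})

test_that("ties are broken toward the lowest class index", {
  means <- cbind(c(1, 1), c(1, 1), c(5, 5))   # classes 1 and 2 identical
  model <- mcsd_model(diag(2), rbind(means[1, ], means[2, ]), sigma = 1)
  expect_identical(classify_compressed(model, c(1, 1)), 1L)
})

test_that("raising a class prior never shrinks its decision region", {
  # 1-D compressed toy model, scanned on a grid
  means <- rbind(c(-1, 0.5, 2))
  grid <- matrix(seq(-4, 5, by = 0.02), nrow = 1)
  for (p2 in c(1 / 3, 0.5, 0.7, 0.9)) {
    rest <- (1 - p2) / 2
    base <- mcsd_model(matrix(1), means, sigma = 1,
                       priors = c(1 / 3, 1 / 3, 1 / 3))
    bumped <- mcsd_model(matrix(1), means, sigma = 1,
                         priors = c(rest, p2, rest))
    reg_base <- classify_compressed(base, grid) == 2L
    reg_bump <- classify_compressed(bumped, grid) == 2L
    expect_true(all(!reg_base | reg_bump),
                label = sprintf("region shrank at P2 = %.2f", p2))
  }
})

test_that("accuracy is the exact fraction correct, reported to one decimal", {
  # 55-sample test arm: 17 + 3 + 17 + 18 per subtype with 1, 2, 2, 0 errors
  truth <- rep(c("pro-neural", "neural", "classical", "mesenchymal"),
               c(17, 3, 17, 18))
  predicted <- truth
  flip <- function(lab, k) {
    idx <- which(truth == lab)[seq_len(k)]
    predicted[idx] <<- "other"
  }
  flip("pro-neural", 1); flip("neural", 2); flip("classical", 2)
  acc <- accuracy(predicted, truth)
  expect_equal(acc, 50 / 55)
  expect_equal(percent_accuracy(acc), 90.9)

  expect_equal(accuracy(letters[1:4], letters[1:4]), 1)
  expect_equal(accuracy(letters[1:4], letters[4:1]), 0)
  expect_error(accuracy(character(0), character(0)), "non-empty")
  expect_error(accuracy(letters[1:3], letters[1:4]), "length mismatch")
})
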