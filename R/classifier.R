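#' Log-density of the isotropic Gaussian observation model
#'
#' The original (uncompressed) observation model: an N-dimensional isotropic
#' Gaussian with class mean `s` and shared standard deviation `sigma`,
#' \deqn{p(\hat y \mid g = \pi_k) = (2\pi\sigma^2)^{-N/2}
#'   \exp(-\|\hat y - s\|^2 / 2\sigma^2).}
#'
#' @param y_hat Length-N observation.
#' @param s Length-N class mean.
#' @param sigma Positive noise standard deviation.
#' @return Log density (scalar).
#' @export
logdensity_original <- function(y_hat, s, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive scalar")
  if (length(y_hat) != length(s))
    stop("y_hat and s must have the same length")
  n <- length(y_hat)
  -0.5 * (n * log(2 * pi * sigma^2) + sum((y_hat - s)^2) / sigma^2)
}

## Cholesky factor of Phi Phi^T, ridge-conditioned only when needed so that
## well-posed cases (e.g. Phi = I) stay exact.
chol_pp <- function(P, ridge = 1e-10, cond_limit = 1e12) {
  PP <- as.matrix(Matrix::tcrossprod(P))
  PP <- (PP + t(PP)) / 2
  cond_of <- function(M) tryCatch(kappa(M, exact = FALSE),
                                  error = function(e) Inf)
  R <- tryCatch(chol(PP), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(R) || cond_of(PP) > cond_limit) {
    PP <- PP + diag(ridge * sum(diag(PP)) / nrow(PP), nrow(PP))
    R <- tryCatch(chol(PP), error = function(e) NULL)
    ridged <- TRUE
    if (is.null(R) || cond_of(PP) > cond_limit)
      mcsd_stop("singular_covariance",
                "Phi Phi^T is singular beyond ridge conditioning")
  }
  structure(R, ridged = ridged)
}

mvn_logdensity <- function(y, mu, R, sigma) {
  ## R: Cholesky (upper) of Phi Phi^T; covariance is sigma^2 * Phi Phi^T.
  M <- length(mu)
  w <- backsolve(R, y - mu, transpose = TRUE)
  logdet_pp <- 2 * sum(log(diag(R)))
  -0.5 * (M * log(2 * pi * sigma^2) + logdet_pp + sum(w^2) / sigma^2)
}

#' Log-density of the compressed Gaussian observation model
#'
#' After compression by `Phi`, the observation model stays Gaussian with
#' mean `Phi s` and covariance `sigma^2 Phi Phi^T`.  The density is an
#' M-dimensional multivariate normal (M = `nrow(Phi)`); it is evaluated via
#' a Cholesky factorization, never an explicit inverse, and a small ridge
#' (`ridge * trace/M` on the diagonal) is applied only if `Phi Phi^T` is
#' ill-conditioned.
#'
#' @param y Length-M compressed observation.
#' @param phi Compress matrix (an `"mcsd_compress"` object or an M x N
#'   matrix).
#' @param s Length-N class mean in the original space.
#' @param sigma Positive noise standard deviation.
#' @param ridge Relative ridge used only when factorization requires it.
#' @return Log density (scalar).
#' @export
logdensity_compressed <- function(y, phi, s, sigma, ridge = 1e-10) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive scalar")
  P <- if (inherits(phi, "mcsd_compress")) phi$phi else phi
  if (length(s) != ncol(P) || length(y) != nrow(P))
    stop("dimension mismatch between y, phi and s")
  mu <- as.vector(P %*% s)
  R <- chol_pp(P, ridge = ridge)
  mvn_logdensity(y, mu, R, sigma)
}

#' Two-class Bayes risk for a one-dimensional decision boundary
#'
#' For a boundary `y0` separating class 1 (decided when `y < y0`) from
#' class 2 (decided when `y > y0`),
#' \deqn{BR = P_2 \int_{-\infty}^{y_0} p_2(y)\,dy
#'          + P_1 \int_{y_0}^{\infty} p_1(y)\,dy.}
#' Densities are integrated numerically; see [bayes_risk_gaussian()] for the
#' Gaussian closed form.
#'
#' @param p1,p2 Density functions of class 1 and class 2.
#' @param y0 Decision boundary.
#' @param P1,P2 Prior probabilities (must sum to 1).
#' @return Bayes risk in \[0, 1\].
#' @export
bayes_risk_two_class <- function(p1, p2, y0, P1 = 0.5, P2 = 0.5) {
  if (abs(P1 + P2 - 1) > 1e-12) stop("priors P1 + P2 must sum to 1")
  lower_tail2 <- stats::integrate(p2, -Inf, y0, rel.tol = 1e-10)$value
  upper_tail1 <- stats::integrate(p1, y0, Inf, rel.tol = 1e-10)$value
  P2 * lower_tail2 + P1 * upper_tail1
}

#' Closed-form two-class Bayes risk for Gaussian densities
#'
#' @param mu1,mu2 Class means (class 2 is the class decided above `y0`).
#' @param sd1,sd2 Class standard deviations.
#' @inheritParams bayes_risk_two_class
#' @return Bayes risk in \[0, 1\].
#' @export
bayes_risk_gaussian <- function(mu1, mu2, y0, sd1 = 1, sd2 = 1,
                                P1 = 0.5, P2 = 0.5) {
  if (abs(P1 + P2 - 1) > 1e-12) stop("priors P1 + P2 must sum to 1")
  P2 * stats::pnorm(y0, mu2, sd2) + P1 * (1 - stats::pnorm(y0, mu1, sd1))
}

#' Validate a utility matrix
#'
#' A valid utility matrix `U[i, j]` (utility of deciding class i when the
#' truth is j) is square with, in every column, the diagonal at least as
#' large as any off-diagonal entry: a correct decision is never worth less
#' than an error.
#'
#' @param u Square numeric matrix.
#' @param n Expected number of classes.
#' @param strict Error (default) or warn on violations.
#' @return `u`, invisibly.
#' @export
validate_utility <- function(u, n = nrow(u), strict = TRUE) {
  bad <- NULL
  if (!is.matrix(u) || nrow(u) != n || ncol(u) != n)
    bad <- sprintf("utility must be a %d x %d matrix", n, n)
  else {
    viol <- vapply(seq_len(n), function(j)
      any(u[-j, j] > u[j, j] + 1e-8), logical(1))
    if (any(viol))
      bad <- sprintf("utility column(s) %s value an error above the correct decision",
                     paste(which(viol), collapse = ", "))
  }
  if (!is.null(bad)) {
    if (strict) mcsd_stop("config", "%s", bad) else warning(bad)
  }
  invisible(u)
}

#' Estimate the utility matrix of the ideal-observer rule
#'
#' Three estimators for `U[i, j]`, the utility of deciding class i when the
#' truth is class j:
#' \describe{
#'   \item{identity}{the Kronecker delta: the ideal detector, reducing the
#'     maximum-expected-utility rule to maximum likelihood (the default);}
#'   \item{pairwise_br}{diagonal 1; off-diagonal the closed-form two-class
#'     Bayes risk between the compressed Gaussians of classes i and j at
#'     equal priors along their discriminant direction
#'     (`pnorm(-Delta_ij / 2)` with `Delta` the Mahalanobis distance) — the
#'     payoff of a confusable error approaches 1/2, that of an impossible
#'     one approaches 0;}
#'   \item{mc_multiclass}{the Monte-Carlo confusion matrix of the
#'     maximum-likelihood rule: `n_mc` draws per class from its compressed
#'     Gaussian are classified and `U[i, j]` is the fraction of class-j
#'     draws landing in decision region i (diagonal = correct fraction).}
#' }
#' For well-separated classes both estimators approach the identity.
#'
#' @param object A fitted [mcsd] model (only its compressed means, noise
#'   scale and compress matrix are used).
#' @param method One of `"identity"`, `"pairwise_br"`, `"mc_multiclass"`.
#' @param n_mc Monte-Carlo draws per class (>= 1000) for `"mc_multiclass"`.
#' @param seed RNG seed, required for `"mc_multiclass"`.
#' @return An n x n utility matrix with class names on both dimensions.
#' @export
estimate_utility <- function(object,
                             method = c("identity", "pairwise_br",
                                        "mc_multiclass"),
                             n_mc = 10000, seed = NULL) {
  method <- match.arg(method)
  n <- length(object$class_names)
  u <- diag(n)
  if (method == "pairwise_br") {
    mu <- object$class_means_compressed
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      w <- backsolve(object$chol, mu[, i] - mu[, j], transpose = TRUE)
      sig2 <- mean(object$sigma[c(min(i, length(object$sigma)),
                                  min(j, length(object$sigma)))]^2)
      delta <- sqrt(sum(w^2) / sig2)
      u[i, j] <- u[j, i] <- stats::pnorm(-delta / 2)
    }
  } else if (method == "mc_multiclass") {
    if (n_mc < 1000) mcsd_stop("config", "mc_multiclass requires n_mc >= 1000")
    if (is.null(seed) || is.na(seed))
      mcsd_stop("config", "mc_multiclass requires an explicit seed")
    mle <- object
    mle$utility <- diag(n)
    u <- with_seed(seed, {
      conf <- matrix(0, n, n)
      for (j in seq_len(n)) {
        y <- simulate_compressed(mle, n_mc, class = j)
        d <- classify_compressed(mle, y)
        conf[, j] <- tabulate(d, nbins = n) / n_mc
      }
      conf
    })
    validate_utility(u, n, strict = FALSE)
  }
  dimnames(u) <- list(decided = object$class_names,
                      truth = object$class_names)
  u
}

## Log expected utility of each candidate class for each column of y (M x k):
## log EU_l = logsumexp_k [ log(U[l,k] P_k) + logdens_k ], in log space for
## numerical stability.
log_expected_utility <- function(object, y) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1L)
  n <- length(object$class_names)
  if (nrow(y) != nrow(object$class_means_compressed))
    stop(sprintf("y has %d rows but the compressed space has dimension %d",
                 nrow(y), nrow(object$class_means_compressed)))
  sig <- if (length(object$sigma) == n) object$sigma else rep(object$sigma, n)
  ld <- vapply(seq_len(n), function(k)
    apply(y, 2L, function(col)
      mvn_logdensity(col, object$class_means_compressed[, k],
                     object$chol, sig[k])),
    numeric(ncol(y)))
  ld <- matrix(ld, nrow = ncol(y))       # k samples x n classes
  lw <- log(object$utility) +
    matrix(log(object$priors), n, n, byrow = TRUE)   # lw[l,k]
  out <- matrix(-Inf, ncol(y), n,
                dimnames = list(colnames(y), object$class_names))
  for (l in seq_len(n)) {
    fin <- is.finite(lw[l, ])
    if (any(fin))
      out[, l] <- apply(ld[, fin, drop = FALSE] +
                          matrix(lw[l, fin], ncol(y), sum(fin), byrow = TRUE),
                        1L, logsumexp)
  }
  out
}

#' Classify compressed observations with the ideal-observer rule
#'
#' Assigns each compressed observation to the class with maximal expected
#' utility, `argmax_l sum_k U[l,k] P_k p(y | g = pi_k)`, evaluated in log
#' space with log-sum-exp stabilization.  Ties are broken by the lowest
#' class index.  With the identity utility and equal priors this is exactly
#' maximum likelihood over the compressed Gaussian densities.
#'
#' @param object A fitted [mcsd] model (or [mcsd_model()] construction).
#' @param y Length-M vector or M x k matrix of compressed observations.
#' @return Integer class indices (length k), named by `y`'s column names.
#' @export
classify_compressed <- function(object, y) {
  eu <- log_expected_utility(object, y)
  apply(eu, 1L, which.max)
}

#' Classification accuracy
#'
#' The ratio between the number of correctly labelled samples and the total
#' number of samples.
#'
#' @param predicted,truth Equal-length label vectors (any type coercible to
#'   character).
#' @return The exact proportion correct in \[0, 1\] (use
#'   [percent_accuracy()] for the one-decimal percentage the summaries
#'   print).
#' @export
accuracy <- function(predicted, truth) {
  if (!length(predicted) || !length(truth))
    stop("predicted and truth must be non-empty")
  if (length(predicted) != length(truth))
    stop(sprintf("length mismatch: %d predicted vs %d truth",
                 length(predicted), length(truth)))
  sum(as.character(predicted) == as.character(truth)) / length(truth)
}

#' Accuracy as a percentage to one decimal
#'
#' @param acc Proportion in \[0, 1\] (e.g. from [accuracy()]).
#' @return The percentage rounded to one decimal place.
#' @export
percent_accuracy <- function(acc) round(100 * as.numeric(acc), 1)
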