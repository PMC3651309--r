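#' Fit a multi-class compressed-sensing detector
#'
#' Runs the full training pipeline on one or several expression blocks
#' measured on the same samples:
#' \enumerate{
#'   \item cascade the blocks into one probes-by-samples matrix
#'     ([cascade()]);
#'   \item min-max normalize every row to \[0, 1\] using training statistics
#'     ([normalize_rows()]);
#'   \item score all probes with five group statistics and select the `m`
#'     most informative ([feature_profile()], [select_features()]);
#'   \item learn the sparse compress matrix `Phi` (m x N) whose rows
#'     reproduce the selected probes by minimum-l1 solutions of
#'     `S^T phi = y` ([solve_compress_matrix()]);
#'   \item estimate per-class compressed means `Phi s_k`, a pooled (or
#'     per-class) noise scale `sigma`, priors and the utility matrix of the
#'     Bayesian ideal observer.
#' }
#' Prediction for new samples (see [predict.mcsd()]) normalizes with the
#' stored row statistics, projects with `Phi`, and picks the class with
#' maximal expected utility under the compressed Gaussian densities.
#'
#' @param x Numeric matrix (probes x samples) or named list of block
#'   matrices sharing the sample set.
#' @param labels Class labels for the samples: a factor/character vector
#'   aligned with the columns, or a named vector keyed by sample id.  Every
#'   class needs at least 2 training samples.
#' @param m Number of informative probes = compressed dimension.  Must not
#'   exceed the number of training samples (each row of `Phi` solves a
#'   c-equation system).  Default `min(50, c - 1, N)`.
#' @param utility `"identity"` (default), `"pairwise_br"`,
#'   `"mc_multiclass"`, or a custom n x n utility matrix (see
#'   [estimate_utility()]).
#' @param sigma_mode `"pooled"` (one shared within-class standard deviation
#'   across selected probes, default) or `"per_class"`.
#' @param priors Class prior probabilities (default equal).
#' @param tol Feasibility tolerance of the l1 solver.
#' @param n_mc,seed Monte-Carlo settings forwarded to [estimate_utility()];
#'   `seed` also makes the whole fit reproducible.
#' @return An object of class `"mcsd"`; see [predict.mcsd()],
#'   [summary.mcsd()], [coef.mcsd()], [simulate.mcsd()], [write_mcsd()].
#' @examples
#' cfg <- synthetic_config(block_sizes = c(a = 40, b = 60),
#'                         per_class_train = 5, per_class_test = 4,
#'                         informative_per_class_per_block = 3,
#'                         effect_size = 4, seed = 1)
#' d <- generate_synthetic(cfg)
#' fit <- mcsd(d$train$blocks, d$train$labels, m = 12)
#' mean(predict(fit, d$test$blocks) == d$test$labels)
#' @export
mcsd <- function(x, labels, m = NULL,
                 utility = "identity",
                 sigma_mode = c("pooled", "per_class"),
                 priors = NULL, tol = 1e-6, n_mc = 10000, seed = NULL) {
  sigma_mode <- match.arg(sigma_mode)
  cl <- match.call()
  with_seed(seed, {
    casc <- if (is.list(x) && !is.matrix(x)) cascade(x) else cascade(list(data = x))
    bm <- block_map(casc)
    if (is.matrix(x)) bm$block <- "data"
    f <- as_labels(labels, colnames(casc))
    counts <- table(f)
    if (any(counts < 2L))
      mcsd_stop("insufficient_samples",
                "class(es) with fewer than 2 training samples: %s",
                paste(names(counts)[counts < 2L], collapse = ", "))
    N <- nrow(casc); cdim <- ncol(casc)
    if (is.null(m)) m <- min(50L, cdim - 1L, N)
    m <- as.integer(m)
    if (m < 1L || m > N)
      mcsd_stop("config", "m must be in [1, %d]", N)
    if (m > cdim)
      mcsd_stop("config",
                "m = %d exceeds the %d training samples; each compress-matrix row solves a %d-equation system, so m <= c is required",
                m, cdim, cdim)

    norm <- normalize_rows(casc)
    s_norm <- norm$train

    profiles <- feature_profile(s_norm, f)
    selected <- select_features(profiles, m)

    y_target <- build_target(s_norm, selected)
    comp <- solve_compress_matrix(s_norm, y_target, tol = tol)

    lv <- levels(f)
    n <- length(lv)
    class_means <- vapply(lv, function(k)
      rowMeans(s_norm[, f == k, drop = FALSE]), numeric(N))
    mu_c <- project(comp, class_means)
    colnames(mu_c) <- lv

    ## Noise scale: pooled within-class sample sd over the selected probes.
    sel_rows <- s_norm[selected, , drop = FALSE]
    ss_k <- vapply(lv, function(k) {
      xi <- sel_rows[, f == k, drop = FALSE]
      c(sum((xi - rowMeans(xi))^2), nrow(xi) * (ncol(xi) - 1L))
    }, numeric(2))
    sigma_floor <- 1e-8                  # keeps separable (zero-noise) fits defined
    sigma <- if (sigma_mode == "pooled") {
      max(sqrt(sum(ss_k[1, ]) / sum(ss_k[2, ])), sigma_floor)
    } else {
      pmax(sqrt(ss_k[1, ] / ss_k[2, ]), sigma_floor)
    }

    if (is.null(priors)) priors <- rep(1 / n, n)
    if (length(priors) != n || any(priors < 0) || abs(sum(priors) - 1) > 1e-8)
      mcsd_stop("config", "priors must be %d non-negative values summing to 1", n)

    obj <- structure(list(
      call = cl,
      class_names = lv,
      priors = stats::setNames(priors, lv),
      m = m, n_probes = N, n_samples = cdim,
      block_map = bm,
      probe_ids = rownames(casc),
      row_stats = norm$stats,
      profile = profiles,
      selected = selected,
      phi = comp$phi,
      solver_report = comp$report,
      tol = tol,
      chol = chol_pp(comp$phi),
      class_means = class_means,
      class_means_compressed = mu_c,
      class_means_selected = class_means[selected, , drop = FALSE],
      sigma = sigma, sigma_mode = sigma_mode,
      utility_method = if (is.matrix(utility)) "custom" else utility,
      n_mc = n_mc, seed = seed,
      mcsd_version = as.character(utils::packageVersion("mcsd"))
    ), class = "mcsd")

    obj$utility <- if (is.matrix(utility)) {
      validate_utility(utility, n)
      dimnames(utility) <- list(decided = lv, truth = lv)
      utility
    } else {
      estimate_utility(obj, method = utility, n_mc = n_mc, seed = seed)
    }

    ## Training performance (on the compressed training data Phi S = Y).
    y_train <- project(comp, s_norm)
    pred_train <- lv[classify_compressed(obj, y_train)]
    obj$training_accuracy <- accuracy(pred_train, as.character(f))
    obj$training_confusion <- table(truth = f,
                                    decided = factor(pred_train, levels = lv))
    obj
  })
}

#' Construct an MCSD model from explicit components
#'
#' Mainly for toy models, diagnostics and simulation studies: builds a
#' classifiable model directly from a compress matrix, full-space class
#' means and a noise scale, bypassing the training pipeline.
#'
#' @param phi M x N compress matrix (matrix, `Matrix`, or
#'   `"mcsd_compress"`).
#' @param class_means N x n matrix of class means in the original space.
#' @param sigma Positive noise scale (scalar, or length n for per-class).
#' @param priors Prior probabilities (default equal).
#' @param utility n x n utility matrix (default identity).
#' @param class_names Class names (default `colnames(class_means)`).
#' @return An object of class `"mcsd"` supporting [classify_compressed()],
#'   [simulate.mcsd()] and [estimate_utility()].
#' @export
mcsd_model <- function(phi, class_means, sigma, priors = NULL,
                       utility = NULL, class_names = NULL) {
  P <- if (inherits(phi, "mcsd_compress")) phi$phi else Matrix::Matrix(phi)
  class_means <- as.matrix(class_means)
  if (nrow(class_means) != ncol(P))
    stop("class_means rows must match ncol(phi)")
  n <- ncol(class_means)
  class_names <- class_names %||% colnames(class_means) %||%
    paste0("class_", seq_len(n))
  if (any(sigma <= 0)) stop("sigma must be positive")
  priors <- priors %||% rep(1 / n, n)
  if (abs(sum(priors) - 1) > 1e-8) mcsd_stop("config", "priors must sum to 1")
  utility <- utility %||% diag(n)
  validate_utility(utility, n)
  structure(list(
    class_names = class_names,
    priors = stats::setNames(priors, class_names),
    m = nrow(P), n_probes = ncol(P), n_samples = NA_integer_,
    phi = P,
    chol = chol_pp(P),
    class_means = class_means,
    class_means_compressed = as.matrix(P %*% class_means),
    sigma = sigma,
    sigma_mode = if (length(sigma) == n) "per_class" else "pooled",
    utility = utility,
    utility_method = "custom"
  ), class = "mcsd")
}

#' Predict subtype labels for new samples
#'
#' New samples are normalized with the training row statistics (values
#' outside the training range are clipped), projected into the compressed
#' space with `Phi`, and classified by maximal expected utility.  A
#' non-compressed reference detector is available which applies the
#' isotropic Gaussian likelihood directly to the (selected or all)
#' normalized probes.
#'
#' @param object A fitted [mcsd] model.
#' @param newdata Probes x samples matrix, or list of block matrices as in
#'   training; probes must match the training probes (same set; a reordered
#'   matrix is realigned).
#' @param type `"class"` (default) for a factor of predicted labels,
#'   `"utility"` for the samples x classes matrix of log expected
#'   utilities, or `"compressed"` for the M x samples projected data.
#' @param detector `"mcsd"` (default) or `"noncompressed"`.
#' @param features For the non-compressed detector: use the `"selected"`
#'   probes (default) or `"all"` probes (only available on models fitted in
#'   the current session, not deserialized ones).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.mcsd <- function(object, newdata,
                         type = c("class", "utility", "compressed"),
                         detector = c("mcsd", "noncompressed"),
                         features = c("selected", "all"), ...) {
  type <- match.arg(type)
  detector <- match.arg(detector)
  features <- match.arg(features)
  x <- if (is.list(newdata) && !is.matrix(newdata)) cascade(newdata) else newdata
  validate_expression_matrix(x)
  if (!identical(rownames(x), object$probe_ids)) {
    if (setequal(rownames(x), object$probe_ids)) {
      x <- x[object$probe_ids, , drop = FALSE]
    } else {
      mcsd_stop("alignment",
                "newdata probes do not match the training probes")
    }
  }
  xn <- apply_row_stats(x, object$row_stats)
  if (detector == "mcsd") {
    yc <- project(object$phi, xn)
    if (type == "compressed") return(yc)
    eu <- log_expected_utility(object, yc)
  } else {
    means <- if (features == "selected") {
      if (is.null(object$class_means_selected))
        mcsd_stop("config", "model lacks selected-probe class means")
      object$class_means_selected
    } else {
      if (is.null(object$class_means))
        mcsd_stop("config",
                  "full-probe class means are not serialized; refit to use features = \"all\"")
      object$class_means
    }
    xs <- if (features == "selected") xn[object$selected, , drop = FALSE] else xn
    if (type == "compressed")
      stop("type = \"compressed\" requires detector = \"mcsd\"")
    n <- length(object$class_names)
    sig <- if (length(object$sigma) == n) object$sigma else rep(object$sigma, n)
    ld <- vapply(seq_len(n), function(k)
      apply(xs, 2L, function(col)
        logdensity_original(col, means[, k], sig[k])), numeric(ncol(xs)))
    ld <- matrix(ld, nrow = ncol(xs))
    lw <- log(object$utility) +
      matrix(log(object$priors), n, n, byrow = TRUE)
    eu <- matrix(-Inf, ncol(xs), n,
                 dimnames = list(colnames(xs), object$class_names))
    for (l in seq_len(n)) {
      fin <- is.finite(lw[l, ])
      if (any(fin))
        eu[, l] <- apply(ld[, fin, drop = FALSE] +
                           matrix(lw[l, fin], ncol(xs), sum(fin), byrow = TRUE),
                         1L, logsumexp)
    }
  }
  if (type == "utility") return(eu)
  factor(object$class_names[apply(eu, 1L, which.max)],
         levels = object$class_names)
}

## Draw n compressed observations from one class's Gaussian.
simulate_compressed <- function(object, n, class) {
  M <- nrow(object$class_means_compressed)
  k <- length(object$class_names)
  sig <- if (length(object$sigma) == k) object$sigma[class] else object$sigma
  z <- matrix(stats::rnorm(M * n), M, n)
  object$class_means_compressed[, class] +
    sig * crossprod(object$chol, z)      # t(R) z has covariance Phi Phi^T
}

#' Simulate compressed observations from a fitted model
#'
#' Draws observations from the model's compressed Gaussian class densities
#' `N(Phi s_k, sigma^2 Phi Phi^T)`, with classes sampled from the priors.
#'
#' @param object A fitted [mcsd] model.
#' @param nsim Number of observations.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list with `y` (M x nsim matrix) and `class` (factor of
#'   generating classes).
#' @export
simulate.mcsd <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    cls <- sample.int(length(object$class_names), nsim, replace = TRUE,
                      prob = object$priors)
    y <- matrix(0, nrow(object$class_means_compressed), nsim)
    for (k in unique(cls))
      y[, cls == k] <- simulate_compressed(object, sum(cls == k), k)
    list(y = y, class = factor(object$class_names[cls],
                               levels = object$class_names))
  })
}

#' @export
coef.mcsd <- function(object, ...) object$phi

#' @export
print.mcsd <- function(x, ...) {
  cat("Multi-class compressed-sensing detector (MCSD)\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  classes (%d): %s\n", length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  if (!is.na(x$n_samples %||% NA))
    cat(sprintf("  training data: %d probes x %d samples", x$n_probes,
                x$n_samples),
        if (!is.null(x$block_map) && nrow(x$block_map) > 1L)
          sprintf(" in %d blocks (%s)", nrow(x$block_map),
                  paste(x$block_map$block, collapse = ", ")) else "",
        "\n", sep = "")
  cat(sprintf("  compressed dimension: %d (Phi %.2f%% non-zero)\n",
              nrow(x$phi), 100 * Matrix::nnzero(x$phi) / prod(dim(x$phi))))
  cat(sprintf("  noise sigma (%s): %s\n", x$sigma_mode,
              paste(signif(x$sigma, 4), collapse = ", ")))
  cat(sprintf("  utility: %s; priors: %s\n", x$utility_method,
              paste(signif(x$priors, 3), collapse = ", ")))
  if (!is.null(x$training_accuracy))
    cat(sprintf("  training accuracy: %.1f%%\n", 100 * x$training_accuracy))
  invisible(x)
}

#' Summarize a fitted MCSD model
#'
#' @param object A fitted [mcsd] model.
#' @param ... Unused.
#' @return An object of class `"summary.mcsd"` with solver diagnostics,
#'   selected-probe listing and the training confusion matrix.
#' @export
summary.mcsd <- function(object, ...) {
  structure(list(model = object,
                 l1_max = if (!is.null(object$solver_report))
                   max(object$solver_report$l1) else NA_real_,
                 residual_max = if (!is.null(object$solver_report))
                   max(object$solver_report$residual) else NA_real_,
                 selected = utils::head(names(object$selected), 10L)),
            class = "summary.mcsd")
}

#' @export
print.summary.mcsd <- function(x, ...) {
  print(x$model)
  cat(sprintf("  l1 solver: max row l1 norm %.6g, max residual %.3g (tol %g)\n",
              x$l1_max, x$residual_max, x$model$tol))
  if (length(x$selected))
    cat("  top selected probes: ", paste(x$selected, collapse = ", "),
        if (x$model$m > length(x$selected)) ", ..." else "", "\n", sep = "")
  if (!is.null(x$model$training_confusion)) {
    cat("  training confusion (truth x decided):\n")
    print(x$model$training_confusion)
  }
  invisible(x)
}

#' Plot compressed class means of a fitted model
#'
#' One line per class across the M compressed coordinates; informative
#' coordinates show the class means fanning apart.
#'
#' @param x A fitted [mcsd] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mcsd <- function(x, ...) {
  mu <- x$class_means_compressed
  graphics::matplot(mu, type = "l", lty = 1, lwd = 2,
                    xlab = "compressed coordinate",
                    ylab = "class mean (normalized units)",
                    main = "Compressed class means", ...)
  graphics::legend("topright", legend = x$class_names, lty = 1, lwd = 2,
                   col = seq_len(ncol(mu)), bty = "n")
  invisible(x)
}
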