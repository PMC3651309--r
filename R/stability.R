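#' Stability of the classifier under repeated balanced splits
#'
#' Repeatedly rearranges the samples into a balanced training arm
#' (`per_class_train` per class) and a test arm made of the remainder, fits
#' the detector on each training arm and scores the matching test arm.  The
#' spread of the per-split accuracies measures how robust the pipeline is to
#' the train/test assignment.
#'
#' @param x Expression matrix or named list of block matrices.
#' @param labels Class labels for the samples (see [mcsd()]).
#' @param n_repeats Number of random splits (default 10).
#' @param per_class_train Training samples per class (default 15).
#' @param seed RNG seed making the whole experiment reproducible.
#' @param ... Further arguments passed to [mcsd()] (e.g. `m`).
#' @return An object of class `"mcsd_stability"`: list with `mean`, `sd`,
#'   `accuracies`, `n_repeats`, `per_class_train`.
#' @export
stability_experiment <- function(x, labels, n_repeats = 10,
                                 per_class_train = 15, seed = NULL, ...) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  casc <- if (is.list(x) && !is.matrix(x)) cascade(x) else x
  f <- as_labels(labels, colnames(casc))
  acc <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(r) {
      sp <- split_balanced(f, per_class_train)
      fit <- mcsd(casc[, sp$train, drop = FALSE], f[sp$train], ...)
      pred <- predict(fit, casc[, sp$test, drop = FALSE])
      accuracy(pred, f[sp$test])
    }, numeric(1))
  })
  structure(list(mean = mean(acc),
                 sd = if (n_repeats > 1) stats::sd(acc) else 0,
                 accuracies = acc,
                 n_repeats = n_repeats,
                 per_class_train = per_class_train),
            class = "mcsd_stability")
}

#' @export
print.mcsd_stability <- function(x, ...) {
  cat(sprintf("Stability over %d balanced splits (%d training samples/class):\n",
              x$n_repeats, x$per_class_train))
  cat(sprintf("  accuracy %.1f%% +/- %.1f%% (per split: %s)\n",
              100 * x$mean, 100 * x$sd,
              paste(sprintf("%.1f", 100 * x$accuracies), collapse = ", ")))
  invisible(x)
}

#' Accuracy as a function of the number of informative features
#'
#' Refits the detector for every feature count in `m_grid` and scores it on
#' a fixed test set — the accuracy-versus-feature-count curve used to choose
#' the compressed dimension.
#'
#' @param x,labels Training data (as in [mcsd()]).
#' @param newdata,newlabels Test data and labels.
#' @param m_grid Integer vector of feature counts to try.
#' @param ... Further arguments passed to [mcsd()].
#' @return A data frame with columns `m` and `accuracy`.
#' @export
sweep_features <- function(x, labels, newdata, newlabels, m_grid, ...) {
  if (!length(m_grid)) stop("m_grid must be non-empty")
  xte <- if (is.list(newdata) && !is.matrix(newdata)) cascade(newdata) else newdata
  truth <- as_labels(newlabels, colnames(xte))
  acc <- vapply(m_grid, function(m) {
    fit <- mcsd(x, labels, m = m, ...)
    accuracy(predict(fit, xte), truth)
  }, numeric(1))
  data.frame(m = as.integer(m_grid), accuracy = acc)
}
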