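#' Per-probe informativeness profile
#'
#' For every probe (row), five group statistics summarise how well the probe
#' separates the classes:
#' \describe{
#'   \item{MeanStd}{mean over classes of the within-class standard deviation
#'     (low for a tight, informative probe);}
#'   \item{StdStd}{standard deviation over classes of those within-class
#'     standard deviations (low = equally tight in every class);}
#'   \item{StdMean}{standard deviation over classes of the class means
#'     (high = class means spread apart);}
#'   \item{MeanCorr}{mean over classes of |Pearson r| between the probe's
#'     values and a one-vs-rest 0/1 class indicator (high = tracks class
#'     membership);}
#'   \item{StdCorr}{standard deviation over classes of those |r| (low =
#'     tracks every class equally well).}
#' }
#' All standard deviations are sample (n-1) standard deviations; a
#' correlation with zero denominator (constant probe or degenerate
#' indicator) is defined as 0.
#'
#' @param x Numeric matrix, probes x samples.
#' @param labels Class labels for the columns of `x` (factor, or character /
#'   named vector); every class needs at least 2 samples.
#' @return Numeric matrix, probes x 5, columns `MeanStd`, `StdStd`,
#'   `StdMean`, `MeanCorr`, `StdCorr`.
#' @seealso [normalize_profile()], [select_features()]
#' @export
feature_profile <- function(x, labels) {
  validate_expression_matrix(x)
  f <- as_labels(labels, colnames(x))
  counts <- table(f)
  if (any(counts < 2L))
    mcsd_stop("insufficient_samples",
              "class(es) with fewer than 2 samples: %s",
              paste(names(counts)[counts < 2L], collapse = ", "))
  lv <- levels(f)
  n <- length(lv)

  cls_mean <- matrix(0, nrow(x), n)
  cls_sd <- matrix(0, nrow(x), n)
  abs_r <- matrix(0, nrow(x), n)
  xc <- x - rowMeans(x)                   # row-centred once for correlations
  xss <- sqrt(rowSums(xc^2))
  for (k in seq_len(n)) {
    xi <- x[, f == lv[k], drop = FALSE]
    cls_mean[, k] <- rowMeans(xi)
    cls_sd[, k] <- row_sd(xi)
    z <- as.numeric(f == lv[k])
    zc <- z - mean(z)
    zss <- sqrt(sum(zc^2))
    den <- xss * zss
    r <- ifelse(den > 0, as.vector(xc %*% zc) / den, 0)
    abs_r[, k] <- abs(r)
  }
  out <- cbind(MeanStd = rowMeans(cls_sd),
               StdStd = row_sd(cls_sd),
               StdMean = row_sd(cls_mean),
               MeanCorr = rowMeans(abs_r),
               StdCorr = row_sd(abs_r))
  rownames(out) <- rownames(x)
  out
}

#' Normalize a feature profile to [0, 1]
#'
#' Each of the five profile components is divided by its maximum across all
#' probes; an all-zero component is left untouched.
#'
#' @param profiles Matrix from [feature_profile()].
#' @return The rescaled profile matrix, every entry in \[0, 1\].
#' @export
normalize_profile <- function(profiles) {
  if (!is.matrix(profiles) || !nrow(profiles))
    mcsd_stop("config", "profiles must be a non-empty matrix")
  mx <- apply(profiles, 2L, max)
  sweep(profiles, 2L, ifelse(mx > 0, mx, 1), "/")
}

#' Rank-sum informativeness score
#'
#' Lower is better: ascending ranks for `MeanStd`, `StdStd`, `StdCorr` (low
#' desired) plus descending ranks for `StdMean`, `MeanCorr` (high desired).
#' Being rank-based, the score is invariant to any common positive rescaling
#' of a component, so it is unchanged by [normalize_profile()].
#'
#' @param profiles Matrix from [feature_profile()] (normalized or not).
#' @return Numeric score per probe.
#' @export
feature_score <- function(profiles) {
  asc <- c("MeanStd", "StdStd", "StdCorr")
  desc <- c("StdMean", "MeanCorr")
  r <- sapply(asc, function(j) rank(profiles[, j], ties.method = "average"))
  r2 <- sapply(desc, function(j) rank(-profiles[, j], ties.method = "average"))
  stats::setNames(rowSums(cbind(r, r2)), rownames(profiles))
}

#' Select the M most informative probes
#'
#' Probes are ordered by the rank-sum score of [feature_score()], ties broken
#' by row index; the best `m` are returned.  Selections are nested: the top
#' `m` probes are always a subset of the top `m + 1`.
#'
#' @param profiles Matrix from [feature_profile()].
#' @param m Number of probes to select, `1 <= m <= nrow(profiles)`.
#' @return Integer vector of row indices (named by probe id when available),
#'   ordered best-first, with the scores attached as attribute `"score"`.
#' @export
select_features <- function(profiles, m) {
  n <- nrow(profiles)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1L || m > n)
    stop(sprintf("m must be in [1, %d], got %s", n, format(m)))
  score <- feature_score(profiles)
  ord <- order(score, seq_len(n))[seq_len(m)]
  out <- stats::setNames(ord, rownames(profiles)[ord])
  attr(out, "score") <- unname(score[ord])
  out
}

#' Tabulate the feature profile with scores and selection flags
#'
#' @param profiles Matrix from [feature_profile()].
#' @param m Number of probes flagged as selected.
#' @return A data frame with probe id, the five (max-normalized) profile
#'   components, the rank-sum score, and a logical `selected` column; rows
#'   in input order.  Suitable for writing as TSV.
#' @export
feature_report <- function(profiles, m) {
  sel <- select_features(profiles, m)
  norm <- normalize_profile(profiles)
  data.frame(probe_id = rownames(profiles) %||% as.character(seq_len(nrow(profiles))),
             norm,
             score = unname(feature_score(profiles)),
             selected = seq_len(nrow(profiles)) %in% sel,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
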