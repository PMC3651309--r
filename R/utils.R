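# Internal helpers shared across the package.

#' @keywords internal
#' @importFrom methods as
#' @importFrom stats pnorm rnorm rlnorm integrate sd setNames
#' @importFrom utils read.table head packageVersion
"_PACKAGE"

## Signalled conditions carry a subclass so callers can distinguish input
## problems (duplicate ids, misaligned probes, ...) from numerical failures.
mcsd_stop <- function(subclass, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("mcsd_", subclass, "_error"),
                                "mcsd_error")))
}

## Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    mcsd_stop("config", "seed must be a single finite number")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Sample (n-1) standard deviation of each row of a matrix.
row_sd <- function(m) {
  if (ncol(m) < 2L) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (ncol(m) - 1L))
}

## Full-precision numeric formatting: 17 significant digits round-trip
## doubles exactly, which the determinism contract relies on.
num_chr <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

as_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      mcsd_stop("sample_mismatch", "no label for sample(s): %s",
                paste(missing, collapse = ", "))
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    mcsd_stop("sample_mismatch",
              "labels (%d) do not match the %d samples and are unnamed",
              length(labels), length(sample_ids))
  }
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(f) < 2L)
    mcsd_stop("config", "at least 2 classes are required, got %d", nlevels(f))
  if (anyNA(f)) mcsd_stop("config", "labels contain missing values")
  f
}
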