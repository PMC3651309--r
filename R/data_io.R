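#' Read an expression matrix from delimited text
#'
#' Reads a probes-by-samples matrix from tab-separated (or otherwise
#' delimited) text.  The first header cell names the probe-identifier column;
#' the remaining header cells are sample identifiers.  Every value cell must
#' parse as a finite number.
#'
#' @param path Path to the text file.
#' @param sep Field delimiter (default tab).
#' @return A numeric matrix with probe identifiers as row names and sample
#'   identifiers as column names.
#' @seealso [write_expression_matrix()], [cascade()]
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) mcsd_stop("parse", "file not found: %s", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    mcsd_stop("parse", "%s: need a probe-id column plus >=1 sample column",
              path)
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    mcsd_stop("duplicate_id", "duplicate sample id(s): %s",
              paste(unique(samples[duplicated(samples)]), collapse = ", "))
  probes <- raw[[1L]]
  if (anyDuplicated(probes))
    mcsd_stop("duplicate_id", "duplicate probe id(s): %s",
              paste(unique(probes[duplicated(probes)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(probes, samples))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    mcsd_stop("parse",
              "%s: non-numeric value %s at probe '%s' (row %d), sample '%s' (column %d)",
              path, dQuote(raw[i, j + 1L]), probes[i], i, samples[j], j)
  }
  vals
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]; values are written with 17
#' significant digits so that a write/read round trip is exact.
#'
#' @param x Numeric matrix with probe row names and sample column names.
#' @param path Output path.
#' @param sep Field delimiter.
#' @param id_column Name used for the probe-identifier header cell.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, sep = "\t",
                                    id_column = "probe_id") {
  validate_expression_matrix(x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c(id_column, colnames(x)), collapse = sep), con)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], num_chr(x[i, ])), collapse = sep), character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a sample-to-class label table
#'
#' Two-column delimited text (`sample_id`, `class_name`) with a header row.
#'
#' @inheritParams read_expression_matrix
#' @return Named character vector mapping sample id to class name.
#' @export
read_labels <- function(path, sep = "\t") {
  if (!file.exists(path)) mcsd_stop("parse", "file not found: %s", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L)
    mcsd_stop("parse", "%s: expected columns sample_id, class_name", path)
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    mcsd_stop("duplicate_id", "duplicate sample id(s) in labels: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(tab[[2L]], ids)
}

validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    mcsd_stop("parse", "expression data must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    mcsd_stop("parse", "expression matrix needs probe row names and sample column names")
  if (anyDuplicated(rownames(x)))
    mcsd_stop("duplicate_id", "duplicate probe ids")
  if (anyDuplicated(colnames(x)))
    mcsd_stop("duplicate_id", "duplicate sample ids")
  if (any(!is.finite(x)))
    mcsd_stop("parse", "expression matrix contains non-finite values")
  invisible(x)
}

#' Stack expression blocks of different data types into one cascaded matrix
#'
#' Per-sample profiles from several data types (e.g. a miRNA block and an
#' mRNA block measured on the same patients) are concatenated feature-wise:
#' block 1 rows first, then block 2, and so on, with every block's columns
#' reordered to a common sample order.
#'
#' @param blocks A named list of probes-by-samples matrices (a single matrix
#'   is treated as one block).
#' @param sample_order Character vector of sample ids defining the output
#'   column order.  Defaults to the samples common to all blocks, in the
#'   order of the first block; samples absent from any block are dropped
#'   with a warning.
#' @return The cascaded matrix with an attached block map (see
#'   [block_map()]); rows of block *b* occupy the contiguous range recorded
#'   there.
#' @export
cascade <- function(blocks, sample_order = NULL) {
  if (is.matrix(blocks)) blocks <- list(blocks)
  if (!is.list(blocks) || !length(blocks))
    mcsd_stop("config", "blocks must be a non-empty list of matrices")
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    names(blocks) <- paste0("block", seq_along(blocks))
  for (b in blocks) validate_expression_matrix(b)
  common <- Reduce(intersect, lapply(blocks, colnames))
  if (is.null(sample_order)) {
    sample_order <- colnames(blocks[[1L]])[colnames(blocks[[1L]]) %in% common]
    n_drop <- sum(vapply(blocks, function(b)
      sum(!colnames(b) %in% common), integer(1)))
    if (n_drop > 0L)
      warning(sprintf("dropping %d sample column(s) absent from some block; using the %d shared samples",
                      n_drop, length(sample_order)))
  } else {
    missing <- setdiff(sample_order, common)
    if (length(missing))
      mcsd_stop("sample_mismatch", "sample(s) missing from some block: %s",
                paste(missing, collapse = ", "))
  }
  if (!length(sample_order))
    mcsd_stop("sample_mismatch", "no samples shared by all blocks")

  aligned <- lapply(blocks, function(b) b[, sample_order, drop = FALSE])
  all_probes <- unlist(lapply(aligned, rownames), use.names = FALSE)
  if (anyDuplicated(all_probes)) {
    warning("probe ids repeat across blocks; prefixing with block names")
    aligned <- lapply(names(aligned), function(nm) {
      b <- aligned[[nm]]
      rownames(b) <- paste(nm, rownames(b), sep = ":")
      b
    })
    names(aligned) <- names(blocks)
  }
  out <- do.call(rbind, aligned)
  n_rows <- vapply(aligned, nrow, integer(1))
  end <- cumsum(n_rows)
  attr(out, "block_map") <- data.frame(block = names(blocks),
                                       start = end - n_rows + 1L,
                                       end = end,
                                       stringsAsFactors = FALSE)
  out
}

#' Block provenance of a cascaded matrix
#'
#' @param x A matrix returned by [cascade()] (or a fitted [mcsd] model).
#' @return A data frame with columns `block`, `start`, `end` (1-based,
#'   inclusive row ranges), or `NULL` if `x` carries no block map.
#' @export
block_map <- function(x) {
  if (inherits(x, "mcsd")) return(x$block_map)
  attr(x, "block_map")
}

#' Extract one block from a cascaded matrix
#'
#' @param x A matrix returned by [cascade()].
#' @param block Block name or index.
#' @return The block's rows, bit-identical to the input block (columns in
#'   the cascaded sample order).
#' @export
slice_block <- function(x, block) {
  bm <- block_map(x)
  if (is.null(bm)) mcsd_stop("config", "x carries no block map")
  i <- if (is.character(block)) match(block, bm$block) else as.integer(block)
  if (is.na(i) || i < 1L || i > nrow(bm))
    mcsd_stop("config", "unknown block: %s", block)
  out <- x[bm$start[i]:bm$end[i], , drop = FALSE]
  attr(out, "block_map") <- NULL
  out
}

#' Min-max normalize matrix rows to [0, 1]
#'
#' Each row is mapped affinely so that the *training* minimum lands at 0 and
#' the training maximum at 1 (step 2 of the classification algorithm).  Test
#' values outside the training range are clipped to \[0, 1\]; rows constant
#' in the reference data map to all zeros.  With `method = "joint"` the
#' min/max are computed on the column-bound train+test matrix instead (a
#' replication mode; the default avoids test-set leakage).
#'
#' @param train Training matrix (probes x samples).
#' @param test Optional test matrix sharing `train`'s probes in the same
#'   order.
#' @param method `"train"` (default) or `"joint"`.
#' @return A list with elements `train`, `test` (or `NULL`), and `stats`, a
#'   data frame of per-row `min`/`max` used for the mapping (store it to
#'   normalize future samples via [apply_row_stats()]).
#' @export
normalize_rows <- function(train, test = NULL,
                           method = c("train", "joint")) {
  method <- match.arg(method)
  validate_expression_matrix(train)
  if (!is.null(test)) {
    validate_expression_matrix(test)
    if (nrow(test) != nrow(train) ||
        !identical(rownames(test), rownames(train)))
      mcsd_stop("alignment", "train and test probe ids differ or are reordered")
  }
  ref <- if (method == "joint" && !is.null(test)) cbind(train, test) else train
  stats <- data.frame(probe_id = rownames(train),
                      min = apply(ref, 1L, min),
                      max = apply(ref, 1L, max),
                      stringsAsFactors = FALSE)
  list(train = apply_row_stats(train, stats, clip = (method == "train")),
       test = if (!is.null(test)) apply_row_stats(test, stats),
       stats = stats)
}

#' Apply stored row min/max statistics to new data
#'
#' @param x Matrix whose rows match `stats$probe_id` in order.
#' @param stats Row statistics from [normalize_rows()].
#' @param clip Clip results into \[0, 1\] (default; values can stray outside
#'   only when `x` was not part of the reference data).
#' @return The normalized matrix.
#' @export
apply_row_stats <- function(x, stats, clip = TRUE) {
  validate_expression_matrix(x)
  if (nrow(x) != nrow(stats) || !identical(rownames(x), stats$probe_id))
    mcsd_stop("alignment", "probe ids do not match the stored row statistics")
  rng <- stats$max - stats$min
  const <- rng == 0
  rng[const] <- 1                      # avoid 0/0; rows zeroed below
  out <- (x - stats$min) / rng
  if (any(const)) out[const, ] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}
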