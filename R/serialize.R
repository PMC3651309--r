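#' Serialize a fitted MCSD model to a directory
#'
#' Writes four plain-text artifacts: `model.json` (scalars, priors, utility
#' matrix, compressed and selected-probe class means, configuration),
#' `phi.tsv` (sparse triplets `row`, `col`, `value` of the compress matrix),
#' `row_stats.tsv` (per-probe normalization min/max) and `selected.tsv`
#' (selection order, row index, probe id, rank-sum score).  All numbers are
#' written with 17 significant digits, so identical fits serialize to
#' byte-identical directories and deserialized models predict identically.
#'
#' @param object A fitted [mcsd] model.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_mcsd()]
#' @export
write_mcsd <- function(object, dir) {
  if (!inherits(object, "mcsd")) stop("object must be a fitted mcsd model")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  meta <- list(
    format = "mcsd-model",
    version = object$mcsd_version %||% "0",
    class_names = object$class_names,
    priors = unname(object$priors),
    m = object$m,
    n_probes = object$n_probes,
    n_samples = object$n_samples,
    sigma = unname(object$sigma),
    sigma_mode = object$sigma_mode,
    tol = object$tol,
    utility_method = object$utility_method,
    utility = unname(as.matrix(object$utility)),
    class_means_compressed = unname(object$class_means_compressed),
    class_means_selected = unname(object$class_means_selected),
    seed = object$seed,
    n_mc = object$n_mc,
    block_map = object$block_map,
    training_accuracy = object$training_accuracy
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  tr <- Matrix::summary(object$phi)       # triplets i, j, x
  ord <- order(tr$i, tr$j)
  writeLines(c("row\tcol\tvalue",
               sprintf("%d\t%d\t%s", tr$i[ord], tr$j[ord],
                       num_chr(tr$x[ord]))),
             file.path(dir, "phi.tsv"))

  rs <- object$row_stats
  writeLines(c("probe_id\tmin\tmax",
               sprintf("%s\t%s\t%s", rs$probe_id, num_chr(rs$min),
                       num_chr(rs$max))),
             file.path(dir, "row_stats.tsv"))

  sc <- attr(object$selected, "score")
  writeLines(c("order\tindex\tprobe_id\tscore",
               sprintf("%d\t%d\t%s\t%s", seq_along(object$selected),
                       as.integer(object$selected),
                       names(object$selected) %||%
                         as.character(object$selected),
                       num_chr(sc %||% rep(NA_real_, length(object$selected))))),
             file.path(dir, "selected.tsv"))
  invisible(dir)
}

#' Load a serialized MCSD model
#'
#' Reconstructs a model written by [write_mcsd()].  Everything needed for
#' prediction round-trips exactly (the 17-digit decimal representation is
#' lossless for doubles); the full-probe class means are not serialized, so
#' `predict(..., detector = "noncompressed", features = "all")` requires a
#' model fitted in the current session.
#'
#' @param dir Directory written by [write_mcsd()].
#' @return An object of class `"mcsd"`.
#' @export
read_mcsd <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path))
    mcsd_stop("parse", "not a model directory (missing model.json): %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "mcsd-model"))
    mcsd_stop("parse", "%s is not an mcsd model file", meta_path)

  tr <- utils::read.table(file.path(dir, "phi.tsv"), sep = "\t",
                          header = TRUE)
  phi <- Matrix::sparseMatrix(i = tr$row, j = tr$col, x = tr$value,
                              dims = c(meta$m, meta$n_probes))
  rs <- utils::read.table(file.path(dir, "row_stats.tsv"), sep = "\t",
                          header = TRUE, colClasses = c("character",
                                                        "numeric", "numeric"))
  sel_tab <- utils::read.table(file.path(dir, "selected.tsv"), sep = "\t",
                               header = TRUE,
                               colClasses = c("integer", "integer",
                                              "character", "numeric"))
  selected <- stats::setNames(sel_tab$index, sel_tab$probe_id)
  attr(selected, "score") <- sel_tab$score

  lv <- meta$class_names
  n <- length(lv)
  u <- matrix(unlist(meta$utility), n, n, byrow = FALSE)
  dimnames(u) <- list(decided = lv, truth = lv)
  mu_c <- matrix(unlist(meta$class_means_compressed), meta$m, n)
  colnames(mu_c) <- lv
  mu_sel <- matrix(unlist(meta$class_means_selected), meta$m, n)
  colnames(mu_sel) <- lv

  structure(list(
    class_names = lv,
    priors = stats::setNames(meta$priors, lv),
    m = meta$m, n_probes = meta$n_probes, n_samples = meta$n_samples,
    block_map = meta$block_map,
    probe_ids = rs$probe_id,
    row_stats = rs,
    selected = selected,
    phi = phi,
    tol = meta$tol,
    chol = chol_pp(phi),
    class_means = NULL,
    class_means_compressed = mu_c,
    class_means_selected = mu_sel,
    sigma = meta$sigma, sigma_mode = meta$sigma_mode,
    utility = u, utility_method = meta$utility_method,
    n_mc = meta$n_mc, seed = meta$seed,
    training_accuracy = meta$training_accuracy,
    mcsd_version = meta$version
  ), class = "mcsd")
}
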