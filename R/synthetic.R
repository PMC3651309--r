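#' Configure the synthetic multi-block expression generator
#'
#' Describes a labelled multi-block dataset with planted class structure:
#' baseline values are i.i.d. Gaussian around 0.5 (mimicking normalized
#' expression), and each class owns a disjoint set of informative probes per
#' block whose mean is shifted by `effect_size * noise_sigma` for that
#' class's samples.  The default shape echoes a two-platform design — a
#' small block and a much larger one measured on the same patients, with a
#' balanced training arm of 15 samples per class.
#'
#' @param n_classes Number of classes (default 4).
#' @param block_sizes Named integer vector of probes per block (default
#'   `c(miRNA = 150, mRNA = 2000)`, emulating the small/large platform
#'   asymmetry).
#' @param per_class_train,per_class_test Samples per class in each arm
#'   (defaults 15 / 14).
#' @param informative_per_class_per_block Planted probes per class per block
#'   (default 10); classes get disjoint sets within a block.
#' @param effect_size Mean shift of planted probes, in units of
#'   `noise_sigma` (default 2).
#' @param noise_sigma Noise standard deviation (default 0.1).
#' @param block_signal_map Logical `n_classes` x `n_blocks` matrix saying in
#'   which blocks a class is separable (default: all).  A class with `FALSE`
#'   in a block gets no planted shift there.
#' @param noise `"gaussian"` (default, matching the classifier's normal
#'   hypothesis) or `"lognormal"` (standardized, for misspecification
#'   robustness checks).
#' @param seed RNG seed (default 1).
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_classes = 4,
                             block_sizes = c(miRNA = 150, mRNA = 2000),
                             per_class_train = 15, per_class_test = 14,
                             informative_per_class_per_block = 10,
                             effect_size = 2, noise_sigma = 0.1,
                             block_signal_map = NULL,
                             noise = c("gaussian", "lognormal"),
                             seed = 1) {
  noise <- match.arg(noise)
  if (is.null(names(block_sizes)) || any(names(block_sizes) == ""))
    names(block_sizes) <- paste0("block", seq_along(block_sizes))
  cfg <- list(n_classes = as.integer(n_classes),
              block_sizes = block_sizes,
              per_class_train = as.integer(per_class_train),
              per_class_test = as.integer(per_class_test),
              informative_per_class_per_block =
                as.integer(informative_per_class_per_block),
              effect_size = effect_size, noise_sigma = noise_sigma,
              block_signal_map = block_signal_map, noise = noise,
              seed = seed)
  chk <- function(ok, msg, ...) if (!ok) mcsd_stop("config", msg, ...)
  chk(cfg$n_classes >= 2, "n_classes must be >= 2")
  chk(length(block_sizes) >= 1 && all(block_sizes >= 1),
      "block_sizes must be positive")
  chk(cfg$per_class_train >= 2 && cfg$per_class_test >= 1,
      "per-class sample counts must be positive (>= 2 for training)")
  chk(cfg$informative_per_class_per_block >= 1,
      "informative_per_class_per_block must be positive")
  chk(effect_size >= 0, "effect_size must be >= 0")
  chk(noise_sigma > 0, "noise_sigma must be > 0")
  chk(all(cfg$n_classes * cfg$informative_per_class_per_block <= block_sizes),
      "each block needs room for %d disjoint planted probes",
      cfg$n_classes * cfg$informative_per_class_per_block)
  if (is.null(cfg$block_signal_map)) {
    cfg$block_signal_map <- matrix(TRUE, cfg$n_classes, length(block_sizes))
  } else {
    cfg$block_signal_map <- as.matrix(cfg$block_signal_map)
    chk(is.logical(cfg$block_signal_map) &&
          all(dim(cfg$block_signal_map) ==
                c(cfg$n_classes, length(block_sizes))),
        "block_signal_map must be a logical n_classes x n_blocks matrix")
  }
  dimnames(cfg$block_signal_map) <- list(paste0("class_", seq_len(cfg$n_classes)),
                                         names(block_sizes))
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic multi-block design: %d classes; blocks %s\n",
              x$n_classes,
              paste(sprintf("%s (%d)", names(x$block_sizes), x$block_sizes),
                    collapse = ", ")))
  cat(sprintf("  %d train + %d test per class; %d planted probes/class/block\n",
              x$per_class_train, x$per_class_test,
              x$informative_per_class_per_block))
  cat(sprintf("  effect size %.3g x sigma, noise sigma %.3g (%s), seed %s\n",
              x$effect_size, x$noise_sigma, x$noise, format(x$seed)))
  invisible(x)
}

#' Generate a labelled synthetic multi-block dataset
#'
#' @param config A [synthetic_config()] object.
#' @return A list with `train` and `test`, each a list of `blocks` (named
#'   list of probes x samples matrices) and `labels` (factor named by sample
#'   id), plus `truth`, a per-block list of per-class planted probe indices,
#'   and the `config`.  Fully reproducible from `config$seed`.
#' @export
generate_synthetic <- function(config) {
  if (!inherits(config, "synthetic_config"))
    mcsd_stop("config", "config must come from synthetic_config()")
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_classes
    ctr <- n * cfg$per_class_train
    cte <- n * cfg$per_class_test
    cls <- paste0("class_", seq_len(n))
    lab_tr <- factor(rep(cls, each = cfg$per_class_train), levels = cls)
    lab_te <- factor(rep(cls, each = cfg$per_class_test), levels = cls)
    ids_tr <- sprintf("tr%03d", seq_len(ctr))
    ids_te <- sprintf("te%03d", seq_len(cte))
    names(lab_tr) <- ids_tr
    names(lab_te) <- ids_te

    truth <- list()
    blocks_tr <- list()
    blocks_te <- list()
    for (b in seq_along(cfg$block_sizes)) {
      nb <- cfg$block_sizes[[b]]
      bname <- names(cfg$block_sizes)[b]
      planted <- split(sample.int(nb, n * cfg$informative_per_class_per_block),
                       rep(seq_len(n), each = cfg$informative_per_class_per_block))
      names(planted) <- cls
      noise_draw <- function(count) {
        if (cfg$noise == "gaussian") stats::rnorm(count, 0, cfg$noise_sigma)
        else {                      # standardized log-normal: mean 0, sd sigma
          raw <- stats::rlnorm(count, 0, 1)
          cfg$noise_sigma * (raw - exp(0.5)) / sqrt((exp(1) - 1) * exp(1))
        }
      }
      mk <- function(labels, ids) {
        m <- matrix(0.5 + noise_draw(nb * length(ids)), nb, length(ids),
                    dimnames = list(sprintf("%s_p%05d", bname, seq_len(nb)),
                                    ids))
        for (k in seq_len(n)) {
          if (!cfg$block_signal_map[k, b]) next
          m[planted[[k]], labels == cls[k]] <-
            m[planted[[k]], labels == cls[k]] +
            cfg$effect_size * cfg$noise_sigma
        }
        m
      }
      blocks_tr[[bname]] <- mk(lab_tr, ids_tr)
      blocks_te[[bname]] <- mk(lab_te, ids_te)
      truth[[bname]] <- planted
    }
    list(train = list(blocks = blocks_tr, labels = lab_tr),
         test = list(blocks = blocks_te, labels = lab_te),
         truth = truth, config = cfg)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes each block of each arm as a TSV expression matrix (the format
#' [read_expression_matrix()] reads), the labels as two-column TSVs, and the
#' planted-probe truth as JSON.
#'
#' @param dataset Output of [generate_synthetic()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (arm in c("train", "test")) {
    d <- dataset[[arm]]
    for (bname in names(d$blocks))
      write_expression_matrix(d$blocks[[bname]],
                              file.path(dir, sprintf("%s_%s.tsv", arm, bname)))
    writeLines(c("sample_id\tclass_name",
                 sprintf("%s\t%s", names(d$labels), as.character(d$labels))),
               file.path(dir, sprintf("%s_labels.tsv", arm)))
  }
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       pretty = TRUE)
  invisible(dir)
}

#' Balanced random train/test split
#'
#' Uniformly samples `per_class` training columns from every class; the
#' remainder is the test set (the bias-reducing balanced design used for
#' model building).
#'
#' @param labels Class labels (factor or character), one per sample.
#' @param per_class Training samples per class; every class must have more
#'   samples than this.
#' @param seed Optional RNG seed.
#' @return A list with integer index vectors `train` and `test` (a disjoint
#'   partition of `seq_along(labels)`).
#' @export
split_balanced <- function(labels, per_class, seed = NULL) {
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  counts <- table(f)
  if (any(counts <= per_class))
    stop(sprintf("class(es) with <= %d samples cannot be split: %s",
                 per_class,
                 paste(names(counts)[counts <= per_class], collapse = ", ")))
  with_seed(seed, {
    train <- sort(unlist(lapply(levels(f), function(k) {
      idx <- which(f == k)
      idx[sample.int(length(idx), per_class)]
    }), use.names = FALSE))
    list(train = train, test = setdiff(seq_along(f), train))
  })
}
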