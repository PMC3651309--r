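# Shared builders for small labelled datasets used across test files.

# Downsized two-block design: fast enough to fit dozens of times.
small_synth <- function(seed, effect_size = 4, ...) {
  generate_synthetic(synthetic_config(
    block_sizes = c(a = 60, b = 120),
    per_class_train = 8, per_class_test = 6,
    informative_per_class_per_block = 5,
    effect_size = effect_size, seed = seed, ...))
}

# Tiny matrix with explicit dimnames.
named_matrix <- function(values, nrow, ncol,
                         probes = sprintf("p%02d", seq_len(nrow)),
                         samples = sprintf("s%02d", seq_len(ncol))) {
  matrix(values, nrow, ncol, dimnames = list(probes, samples))
}

# Noise-free, perfectly separable 3-class dataset: each class has its own
# signature probes; remaining probes carry a deterministic gradient so rows
# are non-constant.
separable_dataset <- function(n_per_class = 3, n_extra = 12) {
  template <- rbind(diag(3) * 2 + 1,
                    matrix(seq_len(3 * n_extra), n_extra, 3))
  x <- template[, rep(1:3, each = n_per_class)]
  # tiny deterministic jitter so no two samples are exactly identical
  x <- x + outer(rep(1e-4, nrow(x)), seq_len(ncol(x)))
  rownames(x) <- sprintf("p%02d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  labels <- factor(rep(paste0("k", 1:3), each = n_per_class))
  names(labels) <- colnames(x)
  list(x = x, labels = labels)
}
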