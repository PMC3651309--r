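test_that("a separable fit classifies its own training data perfectly", {
  d <- separable_dataset()
  fit <- mcsd(d$x, d$labels, m = 3)
  expect_equal(fit$training_accuracy, 1)
  pred <- predict(fit, d$x)
  expect_identical(as.character(pred), as.character(d$labels))
})

test_that("compressed class means are the projection of the class means", {
  d <- small_synth(2)
  fit <- mcsd(d$train$blocks, d$train$labels, m = 12)
  expect_equal(fit$class_means_compressed,
               project(fit$phi, fit$class_means), tolerance = 1e-10)
  # every learned row respects the selector feasibility bound
  expect_true(all(fit$solver_report$l1 <= 1 + fit$tol))
})

test_that("m is capped by the number of training samples", {
  d <- separable_dataset()           # 15 probes x 9 samples
  expect_error(mcsd(d$x, d$labels, m = 12), class = "mcsd_config_error")
  err <- tryCatch(mcsd(d$x, d$labels, m = 12), error = identity)
  expect_match(conditionMessage(err), "exceeds the 9 training samples")
  expect_error(mcsd(d$x, d$labels[1:9][c(1:8, 1)],
                    m = 2), class = "mcsd_sample_mismatch_error")
})

test_that("prediction is per-sample: column permutations permute predictions", {
  d <- small_synth(4)
  fit <- mcsd(d$train$blocks, d$train$labels, m = 12)
  xte <- cascade(d$test$blocks)
  pred <- predict(fit, xte)
  perm <- rev(seq_len(ncol(xte)))
  expect_identical(as.character(predict(fit, xte[, perm])),
                   as.character(pred)[perm])
  # single sample in, single label out
  one <- predict(fit, xte[, 1, drop = FALSE])
  expect_length(one, 1L)
  expect_identical(as.character(one), as.character(pred[1]))
  # reordered probes are realigned; disjoint probes are refused
  shuffled <- xte[sample(nrow(xte)), , drop = FALSE]
  expect_identical(predict(fit, shuffled), pred)
  bad <- xte; rownames(bad)[1] <- "nonexistent_probe"
  expect_error(predict(fit, bad), class = "mcsd_alignment_error")
})

test_that("the non-compressed detector runs on selected or all features", {
  d <- small_synth(5)
  fit <- mcsd(d$train$blocks, d$train$labels, m = 12)
  xte <- cascade(d$test$blocks)
  p_sel <- predict(fit, xte, detector = "noncompressed")
  p_all <- predict(fit, xte, detector = "noncompressed", features = "all")
  expect_s3_class(p_sel, "factor")
  expect_length(p_all, ncol(xte))
  # on strongly separable data all detectors agree with the truth
  expect_gte(accuracy(p_sel, d$test$labels), 0.95)
})

test_that("fits with the same seed serialize byte-identically", {
  d <- small_synth(6)
  fit1 <- mcsd(d$train$blocks, d$train$labels, m = 10,
               utility = "mc_multiclass", n_mc = 1000, seed = 99)
  fit2 <- mcsd(d$train$blocks, d$train$labels, m = 10,
               utility = "mc_multiclass", n_mc = 1000, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_mcsd(fit1, d1); write_mcsd(fit2, d2)
  for (f in c("model.json", "phi.tsv", "row_stats.tsv", "selected.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  xte <- cascade(d$test$blocks)
  expect_identical(predict(fit1, xte), predict(fit2, xte))
})

test_that("serialized models round-trip and predict identically", {
  d <- small_synth(7)
  fit <- mcsd(d$train$blocks, d$train$labels, m = 12, seed = 1)
  dir <- withr::local_tempdir()
  write_mcsd(fit, dir)
  back <- read_mcsd(dir)
  xte <- cascade(d$test$blocks)
  expect_identical(predict(back, xte), predict(fit, xte))
  expect_equal(predict(back, xte, type = "utility"),
               predict(fit, xte, type = "utility"), tolerance = 1e-12)
  expect_equal(back$sigma, fit$sigma)
  expect_equal(unname(back$utility), unname(fit$utility))
  # full-feature means are deliberately not serialized
  expect_error(predict(back, xte, detector = "noncompressed", features = "all"),
               class = "mcsd_config_error")
})

test_that("simulate draws from the fitted compressed densities", {
  d <- small_synth(8)
  fit <- mcsd(d$train$blocks, d$train$labels, m = 10)
  sim <- simulate(fit, nsim = 200, seed = 2)
  expect_equal(dim(sim$y), c(10L, 200L))
  # self-consistency: simulated draws classify back to their classes
  pred <- fit$class_names[classify_compressed(fit, sim$y)]
  expect_gte(accuracy(pred, sim$class), 0.95)
  expect_identical(simulate(fit, 20, seed = 5)$y, simulate(fit, 20, seed = 5)$y)
})

test_that("print, summary, coef and plot expose the fitted components", {
  d <- small_synth(9)
  fit <- mcsd(d$train$blocks, d$train$labels, m = 8)
  expect_output(print(fit), "compressed dimension: 8")
  expect_output(print(summary(fit)), "l1 solver")
  expect_s4_class(coef(fit), "dgCMatrix")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("balanced splits partition the samples reproducibly", {
  labels <- factor(rep(c("a", "b", "c", "d"), times = c(32, 18, 32, 33)))
  sp <- split_balanced(labels, 15, seed = 3)
  expect_length(sp$train, 60L)
  expect_equal(as.vector(table(labels[sp$train])), rep(15L, 4))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(split_balanced(labels, 15, seed = 3), sp)
  expect_error(split_balanced(factor(rep("a", 10)), 15))
  expect_error(split_balanced(labels, 18), "cannot be split")
})

test_that("stability experiment aggregates seeded balanced splits", {
  d <- small_synth(10)
  blocks <- Map(cbind, d$train$blocks, d$test$blocks) # pool both arms

  labels <- c(d$train$labels, d$test$labels)
  names(labels) <- c(names(d$train$labels), names(d$test$labels))
  st <- stability_experiment(blocks, labels, n_repeats = 3,
                             per_class_train = 8, seed = 11, m = 10)
  expect_length(st$accuracies, 3L)
  expect_equal(st$mean, mean(st$accuracies))
  # strongly separable data: every split classifies perfectly
  expect_equal(st$accuracies, rep(1, 3))
  st2 <- stability_experiment(blocks, labels, n_repeats = 3,
                              per_class_train = 8, seed = 11, m = 10)
  expect_identical(st$accuracies, st2$accuracies)
  # a single repeat reduces to one fit/predict
  st1 <- stability_experiment(blocks, labels, n_repeats = 1,
                              per_class_train = 8, seed = 12, m = 10)
  expect_length(st1$accuracies, 1L)
  expect_equal(st1$sd, 0)
  expect_output(print(st), "balanced splits")
})

test_that("feature-count sweep reports accuracy per m", {
  d <- small_synth(12)
  sw <- sweep_features(d$train$blocks, d$train$labels,
                       d$test$blocks, d$test$labels, m_grid = c(8, 16))
  expect_equal(sw$m, c(8L, 16L))
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
  one <- sweep_features(d$train$blocks, d$train$labels,
                        d$test$blocks, d$test$labels, m_grid = 16)
  expect_equal(nrow(one), 1L)
  # strongly separable data: perfect at every m >= the class count
  expect_equal(one$accuracy, 1)
})
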