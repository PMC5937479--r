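test_that("confusion matrices count true-by-predicted sounds", {
  cls <- c("a", "b", "c")
  cm <- confusion(c("a", "a", "b", "c"), c("a", "b", "b", "c"), cls)
  expect_equal(sum(cm), 4)
  expect_equal(cm["a", "b"], 1)
  # perfect predictions: diagonal
  cmp <- confusion(cls, cls, cls)
  expect_equal(unname(diag(cmp)), rep(1L, 3))
  expect_equal(sum(cmp) - sum(diag(cmp)), 0)
  # everything predicted as one class: single nonzero column
  cm1 <- confusion(cls, rep("a", 3), cls)
  expect_equal(unname(colSums(cm1)), c(3, 0, 0))
  expect_error(confusion("a", "z", cls), "outside")
})

test_that("one-vs-rest metrics follow the standard confusion formulas", {
  # TP=40 FN=10 FP=5 TN=45
  cm <- structure(matrix(c(40, 5, 10, 45), 2, 2,
                         dimnames = list(c("pos", "neg"), c("pos", "neg"))),
                  class = "confusion_matrix")
  m <- one_vs_rest_metrics(cm, "pos")
  expect_equal(unname(m["SNS"]), 0.8)
  expect_equal(unname(m["SPC"]), 0.9)
  expect_equal(unname(m["AUC"]), 0.85)
  expect_equal(unname(m["GM"]), sqrt(0.72), tolerance = 1e-12)
  expect_equal(unname(m["ACC"]), 0.85)
  expect_equal(unname(m["PRC"]), 40 / 45)
})

test_that("zero-denominator metrics report 0 with a warning", {
  cm <- confusion(c("a", "a"), c("b", "b"), c("a", "b"))
  expect_warning(m <- one_vs_rest_metrics(cm, "b"), "zero denominator")
  expect_equal(unname(m["SNS"]), 0)
})

test_that("macro averaging is the unweighted mean per metric", {
  m1 <- c(ACC = 0.9, PRC = 0.8, SNS = 0.7, SPC = 0.9, F1 = 0.74,
          GM = 0.79, AUC = 0.8)
  m2 <- m1; m2["AUC"] <- 0.9
  avg <- macro_average(list(m1, m2))
  expect_equal(unname(avg["AUC"]), 0.85)
  expect_equal(macro_average(list(m1, m1)), m1)
})

test_that("GM never exceeds AUC, per class and after averaging", {
  set.seed(1)
  cls <- c("a", "b", "c", "d")
  for (i in 1:25) {
    truth <- sample(cls, 40, replace = TRUE)
    pred <- ifelse(runif(40) < 0.6, truth, sample(cls, 40, replace = TRUE))
    mt <- metrics_table(confusion(truth, pred, cls))
    expect_true(all(mt$per_class[, "GM"] <= mt$per_class[, "AUC"] + 1e-12))
    expect_lte(mt$macro["GM"], mt$macro["AUC"] + 1e-12)
    expect_true(all(mt$per_class >= 0 & mt$per_class <= 1))
  }
})

test_that("instance selection splits non-patterns ~50/50 by class", {
  manifest <- data.frame(file = sprintf("r%02d.wav", 1:44),
                         class = rep(c("a", "b", "c", "d"), each = 11),
                         is_pattern = rep(c(TRUE, rep(FALSE, 10)), 4))
  sp <- split_dataset(manifest, "instance_selection", seed = 3)
  expect_equal(sum(sp$split == "train"), 4)
  expect_equal(sum(sp$split == "validation"), 20)
  expect_equal(sum(sp$split == "test"), 20)
  for (k in c("a", "b", "c", "d"))
    expect_equal(sum(sp$split == "test" & sp$class == k), 5)
  # determinism
  expect_identical(sp, split_dataset(manifest, "instance_selection", seed = 3))
  expect_false(identical(sp$split,
                         split_dataset(manifest, "instance_selection",
                                       seed = 4)$split))
  # a class without patterns is a data error
  bad <- manifest; bad$is_pattern[1] <- FALSE
  expect_error(split_dataset(bad, "instance_selection", seed = 1),
               "no pattern")
})

test_that("cv4 assigns stratified folds", {
  manifest <- data.frame(class = rep(c("a", "b"), each = 8))
  sp <- split_dataset(manifest, "cv4", seed = 1)
  for (k in c("a", "b"))
    expect_equal(as.vector(table(sp$fold[sp$class == k])), rep(2L, 4))
})

test_that("bootstrap CIs are ordered and collapse for degenerate data", {
  cls <- c("a", "b")
  # one sound repeated: every resample identical, zero-width CI
  br <- bootstrap_metrics(rep("a", 10), rep("a", 10), cls,
                          n_boot = 50, seed = 1)
  expect_equal(unname(br$ci["upper", ] - br$ci["lower", ]), rep(0, 7))
  set.seed(2)
  truth <- sample(cls, 40, replace = TRUE)
  pred <- ifelse(runif(40) < 0.7, truth, sample(cls, 40, replace = TRUE))
  br2 <- bootstrap_metrics(truth, pred, cls, n_boot = 200, seed = 3)
  expect_true(all(br2$ci["lower", ] <= br2$ci["upper", ]))
  expect_true(all(br2$point >= br2$ci["lower", ] - 1e-9 |
                    br2$point <= br2$ci["upper", ] + 1e-9))
  expect_equal(nrow(br2$samples), 200)
})

test_that("outperformance probabilities behave under identity and swap", {
  set.seed(4)
  cls <- c("a", "b")
  truth <- sample(cls, 30, replace = TRUE)
  p1 <- ifelse(runif(30) < 0.9, truth, sample(cls, 30, replace = TRUE))
  p2 <- ifelse(runif(30) < 0.55, truth, sample(cls, 30, replace = TRUE))
  # strict ">" reading: a method never outperforms itself
  self <- prob_outperform(truth, p1, p1, cls, n_boot = 100, seed = 5)
  expect_equal(unname(self$o), rep(0, 7))
  fwd <- prob_outperform(truth, p1, p2, cls, n_boot = 300, seed = 6)
  swp <- prob_outperform(truth, p2, p1, cls, n_boot = 300, seed = 6)
  # antisymmetry: swapping methods maps o to the fraction of strictly
  # negative differences (paired resamples, same seed)
  expect_equal(unname(swp$o), unname(colMeans(fwd$delta < 0)))
  expect_equal(swp$delta_mean, -fwd$delta_mean)
  expect_gt(fwd$o["ACC"], 0.5)   # clearly better method wins mostly
})
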