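test_that("a codebook of all distinct training vectors has zero distortion", {
  set.seed(1)
  x <- matrix(rnorm(16 * 3), 16, 3)
  suppressWarnings(cb <- lbg_codebook(x, 16, seed = 1))
  expect_equal(cb$n_codes, 16)
  o <- quantize(x, cb)
  expect_equal(sort(unique(o)), 1:16)
  expect_lt(max(rowSums((x - cb$codes[o, ])^2)), 1e-10)
})

test_that("LBG distortion never increases within a refinement level", {
  set.seed(2)
  x <- matrix(rnorm(500 * 4), 500, 4)
  cb <- lbg_codebook(x, 16, seed = 3)
  # trace restarts (upward jumps) only at level splits; within a run of
  # Lloyd iterations it must not increase
  d <- cb$distortion_trace
  increases <- which(diff(d) > 1e-12)
  # each increase must coincide with a codebook doubling (bounded count)
  expect_lte(length(increases), log2(16))
})

test_that("two separated clouds give centroids near the cloud means", {
  set.seed(4)
  a <- matrix(rnorm(400, 0, 1), 200, 2)
  b <- matrix(rnorm(400, 10, 1), 200, 2)
  cb <- lbg_codebook(rbind(a, b), 2, seed = 5)
  got <- cb$codes[order(cb$codes[, 1]), ]
  se <- 1 / sqrt(200)
  expect_lt(max(abs(got[1, ] - colMeans(a))), 3 * se)
  expect_lt(max(abs(got[2, ] - colMeans(b))), 3 * se)
})

test_that("quantization is nearest-centroid with identity on the codes", {
  set.seed(6)
  x <- matrix(rnorm(64 * 2), 64, 2)
  suppressWarnings(cb <- lbg_codebook(x, 8, seed = 7))
  expect_equal(quantize(cb$codes, cb), 1:8)
  o <- quantize(x, cb)
  expect_length(o, 64)
  expect_error(quantize(matrix(0, 1, 3), cb), "width mismatch")
})

test_that("Baum-Welch keeps the left-right structure and stochastic rows", {
  set.seed(8)
  seqs <- lapply(1:5, function(i) sample(1:6, 30, replace = TRUE))
  hmm <- train_hmm(seqs, n_codes = 6, n_states = 5, seed = 1)
  expect_equal(dim(hmm$T), c(5, 5))
  mask <- anuracall:::.lr_transition_init(5) > 0
  expect_true(all(hmm$T[!mask] == 0))        # structural zeros exact
  expect_equal(rowSums(hmm$T), rep(1, 5), tolerance = 1e-9)
  expect_equal(rowSums(hmm$E), rep(1, 5), tolerance = 1e-9)
  # EM log-likelihood is non-decreasing (tiny slack for emission flooring)
  d <- diff(hmm$loglik_trace)
  expect_true(all(d > -1e-6))
})

test_that("short sequences are skipped with a warning", {
  expect_warning(
    hmm <- train_hmm(list(c(1, 2), sample(1:4, 20, replace = TRUE)),
                     n_codes = 4, n_states = 5, seed = 2),
    "skipped")
  expect_s3_class(hmm, "discrete_hmm")
  expect_error(suppressWarnings(train_hmm(list(c(1, 2)), 4, 5)), "no usable")
})

test_that("forward log-likelihood matches certainty and flooring cases", {
  hmm <- structure(list(T = matrix(1, 1, 1),
                        E = matrix(c(1 - 1e-6, 1e-6), 1, 2),
                        init = 1, n_states = 1, n_codes = 2),
                   class = "discrete_hmm")
  expect_equal(hmm_loglik(c(1, 1, 1), hmm), 3 * log(1 - 1e-6))
  expect_equal(hmm_loglik(2, hmm), log(1e-6))
  expect_error(hmm_loglik(integer(0), hmm), "empty")
  expect_error(hmm_loglik(3, hmm), "alphabet")
})

test_that("the forward algorithm equals brute-force path enumeration", {
  for (case in 1:100) {
    p <- random_lr_hmm(ns = sample(2:3, 1), nc = 4, seed = case)
    n_obs <- sample(2:5, 1)
    o <- sample(1:4, n_obs, replace = TRUE)
    hmm <- structure(list(T = p$tm, E = p$em, init = p$init,
                          n_states = nrow(p$tm), n_codes = 4),
                     class = "discrete_hmm")
    expect_equal(hmm_loglik(o, hmm),
                 hmm_loglik_bruteforce(o, p$tm, p$em, p$init),
                 tolerance = 1e-10)
  }
})

test_that("segment classification takes the highest-likelihood class", {
  set.seed(9)
  # model A emits mostly code 1, model B mostly code 2
  mk <- function(p1) structure(
    list(T = matrix(1, 1, 1), E = matrix(c(p1, 1 - p1), 1, 2), init = 1,
         n_states = 1, n_codes = 2), class = "discrete_hmm")
  hmms <- list(A = mk(0.95), B = mk(0.05))
  correct <- mean(replicate(200, {
    o <- sample(1:2, 20, replace = TRUE, prob = c(0.95, 0.05))
    classify_segment_hmm(o, hmms)$class == "A"
  }))
  expect_gte(correct, 0.95)
  # identical models: first class by tie-break
  expect_equal(classify_segment_hmm(c(1, 2), list(X = mk(0.5), Y = mk(0.5)))$class,
               "X")
})

test_that("segment plans cover full, ROI-mean and sliding modes", {
  expect_equal(segment_plan(100, "full"), list(1:100))
  segs <- segment_plan(100, "roi_mean", roi_mean_frames = 20)
  expect_length(segs, 5)
  expect_equal(segs[[5]], 81:100)
  # trailing partial shorter than half a block is dropped
  segs2 <- segment_plan(105, "roi_mean", roi_mean_frames = 20)
  expect_length(segs2, 5)
  sl <- segment_plan(10, "sliding", w = 1)
  expect_length(sl, 10)
  expect_equal(sl[[3]], 3)
  expect_warning(big <- segment_plan(5, "sliding", w = 9), "larger than clip")
  expect_equal(big, list(1:5))
})

test_that("a constant series fits as pure mean with zero dynamics", {
  x <- matrix(5, 50, 3)
  m <- fit_var(x, 1)
  expect_equal(m$C0, rep(5, 3), tolerance = 1e-6)
  expect_lt(max(abs(m$A[[1]])), 1e-6)
})

test_that("VAR(1) coefficients are recovered from simulated data", {
  set.seed(11)
  d <- 3
  a1 <- matrix(c(0.4, 0.1, 0, -0.2, 0.3, 0.1, 0, 0.05, 0.35), d, d)
  expect_lt(max(abs(eigen(a1)$values)), 0.6)
  sim <- function(s) {
    x <- matrix(0, s, d)
    for (i in 2:s) x[i, ] <- a1 %*% x[i - 1, ] + rnorm(d, sd = 0.5)
    x
  }
  x2000 <- sim(2000)
  m <- fit_var(x2000, 1)
  expect_lt(max(abs(m$A[[1]] - a1)), 0.05)
  # bias shrinks with segment length
  err200 <- max(abs(fit_var(sim(200), 1)$A[[1]] - a1))
  expect_lt(max(abs(m$A[[1]] - a1)), err200 + 0.05)
  # white noise: coefficients near zero
  mw <- fit_var(matrix(rnorm(2000 * d), 2000, d), 1)
  expect_lt(max(abs(mw$A[[1]])), 0.1)
  expect_error(fit_var(matrix(rnorm(12), 4, 3), 1), "too short")
})

test_that("the weighted mean order follows the printed closed forms", {
  # constant AIC over orders 1..10: mean order 5.5
  aic <- matrix(7, 10, 3)
  expect_equal(unname(anuracall:::.weighted_order_means(aic)), rep(5.5, 3))
  # constant negative AIC: positive shift leaves the mean at 5.5
  expect_equal(unname(anuracall:::.weighted_order_means(matrix(-2, 10, 1))),
               5.5)
  # mean orders {3.2, 3.5} round to order 3
  expect_equal(round(mean(c(3.2, 3.5))), 3)
})

test_that("order selection averages per-segment weighted orders", {
  set.seed(12)
  segs <- lapply(1:3, function(i) {
    x <- matrix(0, 120, 2)
    for (t in 2:120) x[t, ] <- 0.5 * x[t - 1, ] + rnorm(2, sd = 0.3)
    x
  })
  sel <- select_var_order(segs, max_order = 5)
  expect_equal(dim(sel$aic), c(5, 3))
  expect_true(all(sel$mean_orders >= 1 & sel$mean_orders <= 5))
  expect_equal(sel$order, as.integer(round(mean(sel$mean_orders))))
  # single segment: order = rounded mean order of that segment
  sel1 <- select_var_order(segs[1], max_order = 5)
  expect_equal(sel1$order, as.integer(round(sel1$mean_orders[1])))
  expect_error(select_var_order(list(matrix(0, 5, 2)), max_order = 10),
               "long enough")
})

test_that("VAR feature vectors flatten row-major to a*D^2 values", {
  set.seed(13)
  x <- matrix(rnorm(600), 120, 5)
  m <- fit_var(x, 3)
  v <- var_feature_vector(m)
  expect_length(v, 75)                     # 3 x 5^2
  # round-trip: reshaping recovers the coefficient matrices
  back <- lapply(1:3, function(k)
    matrix(v[(k - 1) * 25 + 1:25], 5, 5, byrow = TRUE))
  expect_equal(back, m$A)
  m11 <- fit_var(matrix(rnorm(11 * 400), 400, 11), 3)
  expect_length(var_feature_vector(m11), 363)   # 3 x 11^2
})
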