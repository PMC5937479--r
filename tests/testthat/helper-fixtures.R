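# In-code fixtures shared across test files.

tone_clip <- function(freq = 1000, duration = 1, sr = 22050, amp = 0.5,
                      id = "tone") {
  audio_clip(amp * sin(2 * pi * freq * (0:(round(duration * sr) - 1)) / sr),
             sr, source_id = id)
}

noise_clip <- function(duration = 1, sr = 22050, amp = 0.2, seed = 42,
                       id = "noise") {
  set.seed(seed)
  audio_clip(amp * stats::rnorm(round(duration * sr)), sr, source_id = id)
}

# Two well-separated Gaussian classes in `d` dimensions.
toy_patterns <- function(n = 60, d = 3, gap = 6, seed = 1) {
  set.seed(seed)
  x1 <- matrix(stats::rnorm(n * d), n, d)
  x2 <- matrix(stats::rnorm(n * d, mean = gap), n, d)
  pattern_set(rbind(x1, x2), rep(c("a", "b"), each = n))
}

# Tiny synthetic scene for pipeline tests: short recordings, small codebook.
tiny_config <- function(methods, seed = 1, r = 4, w = NULL, ...) {
  experiment_config(methods = methods, r = r, w = w,
                    scene = scene_config(seed = seed, snr_db = 20,
                                         recording_duration = 2,
                                         noise_kind = "band"),
                    n_per_class = 4, pattern_fraction = 0.25,
                    codebook_size = 16, ...)
}

# Independent fine-grid base-2 JS divergence oracle for two Gaussian pdfs.
js_gaussian_oracle <- function(mu1, mu2, sd1 = 1, sd2 = 1, n = 2^14) {
  lo <- min(mu1 - 8 * sd1, mu2 - 8 * sd2)
  hi <- max(mu1 + 8 * sd1, mu2 + 8 * sd2)
  x <- seq(lo, hi, length.out = n)
  f <- stats::dnorm(x, mu1, sd1); g <- stats::dnorm(x, mu2, sd2)
  m <- (f + g) / 2
  term <- function(p) {
    v <- numeric(length(p)); ok <- p > 0
    v[ok] <- p[ok] * log2(p[ok] / m[ok]); v
  }
  h <- x[2] - x[1]
  0.5 * sum((term(f)[-1] + term(f)[-n]) / 2 * h) +
    0.5 * sum((term(g)[-1] + term(g)[-n]) / 2 * h)
}

# Brute-force HMM likelihood by enumerating every state path.
hmm_loglik_bruteforce <- function(o, tm, em, init) {
  ns <- nrow(tm); n <- length(o)
  paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), n)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    p <- init[paths[i, 1]] * em[paths[i, 1], o[1]]
    if (n > 1) for (t in 2:n)
      p <- p * tm[paths[i, t - 1], paths[i, t]] * em[paths[i, t], o[t]]
    total <- total + p
  }
  log(total)
}

# Random left-right HMM parameters for property tests.
random_lr_hmm <- function(ns, nc, seed) {
  set.seed(seed)
  tm <- matrix(0, ns, ns)
  for (a in seq_len(ns - 1)) {
    u <- stats::runif(1, 0.2, 0.8)
    tm[a, a] <- u; tm[a, a + 1] <- 1 - u
  }
  tm[ns, ns] <- 1
  em <- matrix(stats::runif(ns * nc, 0.1, 1), ns, nc)
  em <- em / rowSums(em)
  list(tm = tm, em = em, init = c(1, rep(0, ns - 1)))
}
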