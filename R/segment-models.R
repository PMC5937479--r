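#' Linde-Buzo-Gray vector-quantization codebook
#'
#' Binary-splitting LBG: starting from the global centroid, every centroid
#' is split into a `(1 + eps)` / `(1 - eps)` pair and refined by Lloyd
#' (k-means) iterations until the relative distortion improvement falls
#' below `tol`, doubling the codebook until `n_codes` entries. If fewer
#' training frames than `n_codes` are supplied, the codebook stops at the
#' largest power of two not exceeding the frame count (with a warning).
#'
#' @param X Training frames (rows).
#' @param n_codes Target codebook size (default 256).
#' @param seed Integer seed (used only for empty-cell repair).
#' @param eps Split perturbation (default 0.01).
#' @param tol Relative distortion tolerance per level (default 1e-4).
#' @param max_lloyd Maximum Lloyd iterations per level.
#' @return Object of class `vq_codebook`: `codes` (matrix of centroids),
#'   `distortion_trace` (per-Lloyd-iteration mean squared distortion, for
#'   monotonicity checks).
#' @export
lbg_codebook <- function(X, n_codes = 256, seed = 1, eps = 0.01, tol = 1e-4,
                         max_lloyd = 100) {
  x <- .as_feature_matrix(X)
  if (nrow(x) == 0) stop("lbg_codebook: no training frames")
  if (nrow(x) < n_codes) {
    n_codes <- 2^floor(log2(nrow(x)))
    warning("lbg_codebook: fewer frames than codes; codebook reduced to ",
            n_codes)
  }
  set.seed(seed %% .Machine$integer.max)
  codes <- matrix(colMeans(x), nrow = 1)
  trace <- c()
  while (nrow(codes) < n_codes) {
    delta <- eps * pmax(abs(codes), 1e-3)
    codes <- rbind(codes * 0 + codes + delta, codes - delta)
    prev <- Inf
    for (it in seq_len(max_lloyd)) {
      asg <- .vq_assign(x, codes)
      dist <- mean(asg$d2)
      trace <- c(trace, dist)
      for (j in seq_len(nrow(codes))) {
        rows <- which(asg$code == j)
        if (length(rows)) {
          codes[j, ] <- colMeans(x[rows, , drop = FALSE])
        } else {
          # empty cell: reseed at the farthest point from its centroid
          far <- which.max(asg$d2)
          codes[j, ] <- x[far, ]
        }
      }
      if (is.finite(prev) && prev - dist <= tol * max(prev, 1e-30)) break
      prev <- dist
    }
  }
  structure(list(codes = codes, n_codes = nrow(codes),
                 distortion_trace = trace),
            class = "vq_codebook")
}

.vq_assign <- function(x, codes) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(codes))) -
    2 * x %*% t(codes) + outer(rep(1, nrow(x)), rowSums(codes^2))
  d2[d2 < 0] <- 0
  code <- apply(d2, 1, which.min)
  list(code = code, d2 = d2[cbind(seq_len(nrow(x)), code)])
}

#' Quantize frames against a codebook
#'
#' Nearest-centroid (Euclidean) assignment; ties take the lowest code
#' index. Codes are 1-based.
#'
#' @param X Frame matrix (rows) or single frame vector.
#' @param codebook A `vq_codebook`.
#' @return Integer observation sequence, one code per frame.
#' @export
quantize <- function(X, codebook) {
  stopifnot(inherits(codebook, "vq_codebook"))
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  x <- .as_feature_matrix(X)
  if (ncol(x) != ncol(codebook$codes))
    stop("quantize: feature width mismatch (", ncol(x), " vs ",
         ncol(codebook$codes), ")")
  .vq_assign(x, codebook$codes)$code
}

# Left-right transition template: self-loop + advance-by-one, absorbing
# final state; chain starts in state 1.
.lr_transition_init <- function(n_states) {
  tm <- matrix(0, n_states, n_states)
  for (a in seq_len(n_states - 1)) {
    tm[a, a] <- 0.5
    tm[a, a + 1] <- 0.5
  }
  tm[n_states, n_states] <- 1
  tm
}

#' Train a discrete-observation left-right HMM
#'
#' Baum-Welch (forward-backward EM) on the left-right topology (self-loop
#' plus advance-by-one, start in state 1). Structural zeros of the
#' transition matrix are preserved exactly. Emission probabilities are
#' floored at `emission_floor` and renormalized so that unseen codes never
#' zero out a test likelihood. Sequences shorter than `n_states` are
#' skipped with a warning.
#'
#' @param sequences List of integer code sequences (1-based codes).
#' @param n_codes Codebook size (observation alphabet).
#' @param n_states Number of states (default 5).
#' @param seed Seed for the random emission initialization.
#' @param max_iter,tol EM stopping rule (log-likelihood improvement).
#' @param emission_floor Emission probability floor.
#' @return Object of class `discrete_hmm`: `T` (transitions), `E`
#'   (emissions), `init`, `loglik_trace`.
#' @export
train_hmm <- function(sequences, n_codes, n_states = 5, seed = 1,
                      max_iter = 200, tol = 1e-4, emission_floor = 1e-6) {
  if (!is.list(sequences)) sequences <- list(sequences)
  keep <- vapply(sequences, length, integer(1)) >= n_states
  if (!all(keep))
    warning("train_hmm: ", sum(!keep), " sequence(s) shorter than n_states skipped")
  sequences <- sequences[keep]
  if (length(sequences) == 0) stop("train_hmm: no usable sequences")
  set.seed(seed %% .Machine$integer.max)
  tm <- .lr_transition_init(n_states)
  em <- matrix(stats::runif(n_states * n_codes, 0.5, 1.5), n_states, n_codes)
  em <- em / rowSums(em)
  init <- c(1, rep(0, n_states - 1))
  mask <- tm > 0
  ll_trace <- numeric(0)
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    tm_num <- matrix(0, n_states, n_states)
    em_num <- matrix(0, n_states, n_codes)
    total_ll <- 0
    for (o in sequences) {
      fb <- .hmm_forward_backward(o, tm, em, init)
      total_ll <- total_ll + fb$loglik
      em_num_o <- rowsum(t(fb$gamma), o)          # sums gamma by emitted code
      em_num[, as.integer(rownames(em_num_o))] <-
        em_num[, as.integer(rownames(em_num_o))] + t(em_num_o)
      tm_num <- tm_num + fb$xi_sum
    }
    ll_trace <- c(ll_trace, total_ll)
    tm_new <- tm_num * mask
    rs <- rowSums(tm_new)
    tm_new[rs > 0, ] <- tm_new[rs > 0, , drop = FALSE] / rs[rs > 0]
    tm_new[rs == 0, ] <- tm[rs == 0, , drop = FALSE]  # unvisited state keeps prior row
    em_new <- em_num
    em_new <- em_new + emission_floor
    em_new <- em_new / rowSums(em_new)
    tm <- tm_new; em <- em_new
    if (is.finite(prev_ll) && total_ll - prev_ll < tol &&
        total_ll - prev_ll >= 0) break
    prev_ll <- total_ll
  }
  em <- pmax(em, emission_floor)
  em <- em / rowSums(em)
  structure(list(T = tm, E = em, init = init, n_states = n_states,
                 n_codes = n_codes, loglik_trace = ll_trace),
            class = "discrete_hmm")
}

# Scaled forward-backward for one observation sequence.
.hmm_forward_backward <- function(o, tm, em, init) {
  n <- length(o); ns <- nrow(tm)
  alpha <- matrix(0, ns, n)
  beta <- matrix(0, ns, n)
  scale <- numeric(n)
  b <- em[, o, drop = FALSE]                       # ns x n emission probs
  alpha[, 1] <- init * b[, 1]
  scale[1] <- sum(alpha[, 1])
  if (scale[1] <= 0) scale[1] <- .Machine$double.xmin
  alpha[, 1] <- alpha[, 1] / scale[1]
  if (n > 1) for (t in 2:n) {
    a <- (t(tm) %*% alpha[, t - 1]) * b[, t]
    s <- sum(a)
    if (s <= 0) s <- .Machine$double.xmin
    alpha[, t] <- a / s
    scale[t] <- s
  }
  beta[, n] <- 1
  if (n > 1) for (t in (n - 1):1) {
    beta[, t] <- (tm %*% (b[, t + 1] * beta[, t + 1])) / scale[t + 1]
  }
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2, pmax(colSums(gamma), .Machine$double.xmin), `/`)
  xi_sum <- matrix(0, ns, ns)
  if (n > 1) for (t in seq_len(n - 1)) {
    xi <- (alpha[, t] %o% (b[, t + 1] * beta[, t + 1])) * tm / scale[t + 1]
    xi_sum <- xi_sum + xi
  }
  list(loglik = sum(log(scale)), gamma = gamma, xi_sum = xi_sum)
}

#' Log-likelihood of an observation sequence under an HMM
#'
#' Scaled forward algorithm; finite for any in-alphabet sequence thanks to
#' the emission floor applied at training.
#'
#' @param o Integer code sequence (1-based).
#' @param hmm A `discrete_hmm`.
#' @return `log P(o | hmm)`.
#' @export
hmm_loglik <- function(o, hmm) {
  stopifnot(inherits(hmm, "discrete_hmm"))
  if (length(o) == 0) stop("hmm_loglik: empty observation sequence")
  if (any(o < 1 | o > hmm$n_codes)) stop("hmm_loglik: code outside alphabet")
  .hmm_forward_backward(o, hmm$T, hmm$E, hmm$init)$loglik
}

#' Classify a segment against per-class HMMs
#'
#' @param o Integer code sequence.
#' @param hmms Named list of `discrete_hmm` models (>= 2); names are class
#'   labels.
#' @return List with `class` (argmax log-likelihood; ties take the first
#'   listed class) and `loglik` (named vector).
#' @export
classify_segment_hmm <- function(o, hmms) {
  stopifnot(is.list(hmms), length(hmms) >= 2)
  ll <- vapply(hmms, function(h) hmm_loglik(o, h), numeric(1))
  list(class = names(hmms)[which.max(ll)], loglik = ll)
}

#' Plan segment boundaries over a clip's frames
#'
#' @param n_frames Number of frames in the clip.
#' @param mode `"full"` (one segment), `"roi_mean"` (consecutive blocks of
#'   `roi_mean_frames`; trailing partial kept when at least half a block),
#'   or `"sliding"` (per-frame centred windows of `w` frames, clipped at the
#'   edges).
#' @param roi_mean_frames Mean ROI length in frames (for `"roi_mean"`).
#' @param w Window length in frames (for `"sliding"`).
#' @return List of integer index vectors, one per segment.
#' @export
segment_plan <- function(n_frames, mode = c("full", "roi_mean", "sliding"),
                         roi_mean_frames = NULL, w = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 1)
  if (mode == "full") return(list(seq_len(n_frames)))
  if (mode == "roi_mean") {
    stopifnot(!is.null(roi_mean_frames), roi_mean_frames >= 1)
    l <- round(roi_mean_frames)
    starts <- seq(1, n_frames, by = l)
    segs <- lapply(starts, function(s) s:min(s + l - 1, n_frames))
    last <- segs[[length(segs)]]
    if (length(segs) > 1 && length(last) < l / 2)
      segs <- segs[-length(segs)]
    return(segs)
  }
  stopifnot(!is.null(w), w >= 1)
  if (w > n_frames) {
    warning("segment_plan: window larger than clip; using one full segment")
    return(list(seq_len(n_frames)))
  }
  d <- floor((w - 1) / 2)
  lapply(seq_len(n_frames), function(i)
    max(1, i - d):min(n_frames, i - d + w - 1))
}

#' Fit a VAR(a) model to a feature segment by least squares
#'
#' Stationary pure-AR vector model
#' `x[i] = C0 + sum_k A_k x[i-k] + eps[i]` estimated by least squares
#' (the Gaussian maximum-likelihood solution for the coefficients), with
#' the residual covariance at its ML (1/T) normalization.
#'
#' @param X Segment feature matrix (frames x D).
#' @param a Autoregressive order.
#' @return Object of class `var_model`: `a`, `C0`, `A` (list of D x D
#'   matrices), `sigma`, `loglik`, `aic`, `n_obs`.
#' @export
fit_var <- function(X, a) {
  x <- .as_feature_matrix(X)
  d <- ncol(x); s <- nrow(x)
  # need more effective rows (s - a) than the a*d regressors plus the mean
  if (s <= a * (d + 1) + 1)
    stop("fit_var: segment too short for order ", a, " in ", d,
         " dimensions (need > ", a * (d + 1) + 1, " frames, got ", s, ")")
  t_eff <- s - a
  y <- x[(a + 1):s, , drop = FALSE]
  reg <- matrix(0, t_eff, a * d)
  for (k in seq_len(a))
    reg[, (k - 1) * d + seq_len(d)] <- x[(a + 1 - k):(s - k), , drop = FALSE]
  # centering both sides is exactly equivalent to including an intercept
  ybar <- colMeans(y); rbar <- colMeans(reg)
  yc <- sweep(y, 2, ybar); rc <- sweep(reg, 2, rbar)
  fit <- tryCatch(qr.solve(rc, yc), error = function(e) {
    # rank-deficient regressors (e.g. constant series): ridge fallback,
    # scaled to the regressor magnitude
    g <- crossprod(rc)
    lambda <- 1e-8 * mean(diag(g)) + 1e-12
    solve(g + diag(lambda, ncol(rc)), crossprod(rc, yc))
  })
  fit <- matrix(fit, ncol = d)
  c0 <- as.numeric(ybar - t(fit) %*% rbar)
  a_mats <- lapply(seq_len(a), function(k)
    t(fit[(k - 1) * d + seq_len(d), , drop = FALSE]))
  resid <- yc - rc %*% fit
  sigma <- crossprod(resid) / t_eff
  ld <- determinant(sigma, logarithm = TRUE)
  logdet <- as.numeric(ld$modulus)
  if (ld$sign <= 0 || !is.finite(logdet)) {
    # singular residual covariance (e.g. a feature constant within the
    # segment): regularize at a scale tied to the residual magnitude
    eps <- 1e-9 * mean(diag(sigma)) + 1e-12
    logdet <- as.numeric(determinant(sigma + diag(eps, d), TRUE)$modulus)
  }
  loglik <- -t_eff / 2 * (d * log(2 * pi) + logdet + d)
  k_par <- a * d^2 + d
  structure(list(a = a, C0 = c0, A = a_mats, sigma = sigma,
                 loglik = loglik, aic = 2 * k_par - 2 * loglik,
                 n_obs = t_eff),
            class = "var_model")
}

#' Select the VAR order by weighted-AIC averaging over ROI patterns
#'
#' For every ROI pattern segment, VAR models of order `1..max_order` are
#' fitted and a weighted mean order is formed with the (positive-shifted)
#' AIC values as weights; the selected order is the nearest integer to the
#' mean of the per-segment weighted orders. The raw-AIC weighting is the
#' default; `weighting = "inverse"` uses `1/AIC` weights (which favour
#' better-fitting orders) for sensitivity analysis.
#'
#' @param segments List of segment feature matrices.
#' @param max_order Maximum order considered (default 10).
#' @param weighting `"literal"` (raw AIC weights) or `"inverse"`.
#' @return Object of class `var_order_selection`: `aic` (order x segment
#'   matrix), `mean_orders` (weighted mean order per segment), `order`
#'   (selected integer).
#' @export
select_var_order <- function(segments, max_order = 10,
                             weighting = c("literal", "inverse")) {
  weighting <- match.arg(weighting)
  if (!is.list(segments)) segments <- list(segments)
  usable <- list()
  for (seg in segments) {
    seg <- .as_feature_matrix(seg)
    # enough rows for the top order plus a full-rank residual covariance
    if (nrow(seg) > max_order * (ncol(seg) + 1) + ncol(seg) + 1)
      usable <- c(usable, list(seg))
  }
  if (length(usable) == 0)
    stop("select_var_order: no segment long enough for order ", max_order)
  aic <- sapply(usable, function(seg)
    vapply(seq_len(max_order), function(i) fit_var(seg, i)$aic, numeric(1)))
  aic <- matrix(aic, nrow = max_order)
  mean_orders <- .weighted_order_means(aic, weighting)
  structure(list(aic = aic, mean_orders = mean_orders,
                 order = as.integer(round(mean(mean_orders))),
                 max_order = max_order, weighting = weighting),
            class = "var_order_selection")
}

# AIC-weighted mean order per segment (columns of the order x segment AIC
# table). Weights must be positive: if any AIC is <= 0 the whole table is
# shifted by -min + 1 first.
.weighted_order_means <- function(aic, weighting = c("literal", "inverse")) {
  weighting <- match.arg(weighting)
  aw <- aic
  if (min(aw) <= 0) aw <- aw - min(aw) + 1
  if (weighting == "inverse") aw <- 1 / aw
  orders <- seq_len(nrow(aw))
  colSums(orders * aw) / colSums(aw)
}

#' Flatten VAR coefficient matrices into a feature vector
#'
#' Row-major flattening of `A_1, ..., A_a` in order, giving a vector of
#' length `a * D^2` for downstream frame-style classification.
#'
#' @param model A `var_model`.
#' @return Numeric vector of length `a * D^2`.
#' @export
var_feature_vector <- function(model) {
  stopifnot(inherits(model, "var_model"))
  unlist(lapply(model$A, function(m) as.vector(t(m))), use.names = FALSE)
}
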