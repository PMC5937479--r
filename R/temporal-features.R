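#' Local interquartile-range (LIQR) feature construction
#'
#' For every frame, a window of the `window` closest frames centred on it is
#' taken (for the default even window of 10: 5 frames before, the frame
#' itself and 4 after, truncated at clip edges). For each original feature
#' the IQR of its values over the window becomes a new derived feature, so
#' the output has `2 * D` columns: the original features followed by their
#' IQR counterparts. Pulsatile (croak-like) calls spread feature values
#' frame-to-frame and yield large IQRs; tonal (whistle-like) calls yield
#' small ones.
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param X Numeric matrix (frames x features) or `frame_feature_matrix`.
#' @param window Window size in frames (default 10, i.e. 100 ms).
#' @return Matrix `S x 2D` with IQR columns named `<feature>_iqr`.
#' @export
liqr_features <- function(X, window = 10) {
  x <- .as_feature_matrix(X)
  s <- nrow(x)
  before <- ceiling((window - 1) / 2)
  after <- window - 1 - before
  iqr <- matrix(0, s, ncol(x))
  for (i in seq_len(s)) {
    lo <- max(1L, i - before); hi <- min(s, i + after)
    w <- x[lo:hi, , drop = FALSE]
    q <- apply(w, 2, stats::quantile, probs = c(0.25, 0.75),
               names = FALSE, type = 7)
    iqr[i, ] <- q[2, ] - q[1, ]
  }
  colnames(iqr) <- paste0(.feat_names(x), "_iqr")
  cbind(x, iqr)
}

#' Sliding-window frame stacking (SW)
#'
#' Row `i` of the result is the concatenation
#' `(x[i-d], ..., x[i], ..., x[i+d])` with `w = 2d + 1`; indices beyond the
#' clip edges are replaced by the nearest edge frame, so the output keeps
#' all `S` rows and has width `w * D`.
#'
#' @param X Numeric matrix (frames x features) or `frame_feature_matrix`.
#' @param w Odd window size in frames.
#' @return Matrix `S x (w * D)`; columns named `<feature>_lag<k>` for
#'   `k = -d..d`.
#' @export
sliding_window_stack <- function(X, w) {
  x <- .as_feature_matrix(X)
  if (w < 1 || w %% 2 == 0) stop("sliding_window_stack: w must be odd and >= 1")
  d <- (w - 1) / 2
  s <- nrow(x)
  cols <- lapply(-d:d, function(k) {
    idx <- pmin(pmax(seq_len(s) + k, 1L), s)
    m <- x[idx, , drop = FALSE]
    colnames(m) <- sprintf("%s_lag%+d", .feat_names(x), k)
    m
  })
  do.call(cbind, cols)
}

#' Recurrent sliding-window augmentation (RSW)
#'
#' Extends the stacked window of [sliding_window_stack()] with one-hot
#' encodings of the `d` previous frame decisions: row `i` is
#' `(onehot(theta[i-d]), ..., onehot(theta[i-1]), x[i-d], ..., x[i+d])`.
#' Missing history at the sequence start is encoded as the all-zero one-hot
#' ("unknown"). During training, ground-truth prior labels are supplied
#' (teacher forcing); at inference the classifier feeds back its own
#' decisions in a left-to-right pass (see [rsw_classify_frames()]).
#'
#' @param X Numeric matrix (frames x features) or `frame_feature_matrix`.
#' @param prior_labels Class label per frame (character/factor, length `S`).
#' @param w Odd window size (`w = 2d + 1`).
#' @param classes Class label universe fixing the one-hot column order.
#' @return Matrix `S x (d*A + w*D)`.
#' @export
recurrent_augment <- function(X, prior_labels, w, classes) {
  x <- .as_feature_matrix(X)
  if (w < 1 || w %% 2 == 0) stop("recurrent_augment: w must be odd and >= 1")
  d <- (w - 1) / 2
  s <- nrow(x)
  stopifnot(length(prior_labels) == s)
  sw <- sliding_window_stack(x, w)
  if (d == 0) return(sw)
  a <- length(classes)
  onehot <- matrix(0, s, a, dimnames = list(NULL, classes))
  li <- match(as.character(prior_labels), classes)
  ok <- which(!is.na(li))
  onehot[cbind(ok, li[ok])] <- 1
  hist_cols <- lapply(seq(d, 1), function(k) {   # theta[i-d] .. theta[i-1]
    idx <- seq_len(s) - k
    m <- matrix(0, s, a, dimnames = list(NULL, sprintf("prior%+d_%s", -k, classes)))
    valid <- idx >= 1
    m[valid, ] <- onehot[idx[valid], , drop = FALSE]
    m
  })
  cbind(do.call(cbind, hist_cols), sw)
}

.as_feature_matrix <- function(X) {
  if (inherits(X, "frame_feature_matrix")) X <- X$X
  if (is.data.frame(X)) X <- as.matrix(X)
  stopifnot(is.matrix(X), is.numeric(X))
  X
}

.feat_names <- function(x) {
  if (is.null(colnames(x))) sprintf("f%02d", seq_len(ncol(x))) else colnames(x)
}
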