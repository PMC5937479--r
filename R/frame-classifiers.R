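#' Construct a pattern set
#'
#' Labelled pattern frames: the training data for every frame-level
#' classifier. The class order given (or first-appearance order) fixes all
#' deterministic tie-breaks downstream.
#'
#' @param Pi Numeric matrix, one row per pattern frame.
#' @param labels Class label per row.
#' @param classes Optional explicit class order; defaults to first
#'   appearance. Every listed class must be non-empty.
#' @return Object of class `pattern_set` with fields `Pi`, `labels`,
#'   `classes`, `counts`.
#' @export
pattern_set <- function(Pi, labels, classes = NULL) {
  Pi <- .as_feature_matrix(Pi)
  labels <- as.character(labels)
  stopifnot(nrow(Pi) == length(labels))
  if (is.null(classes)) classes <- unique(labels)
  if (!all(labels %in% classes))
    stop("pattern_set: labels outside the declared class set")
  counts <- vapply(classes, function(k) sum(labels == k), integer(1))
  if (any(counts == 0))
    stop("pattern_set: empty class: ", paste(classes[counts == 0], collapse = ", "))
  structure(list(Pi = Pi, labels = labels, classes = classes, counts = counts),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set: %d frames x %d features, %d classes>\n",
              nrow(x$Pi), ncol(x$Pi), length(x$classes)))
  print(x$counts)
  invisible(x)
}

# z-scoring statistics from training data only; zero-variance columns get
# unit scale so they pass through unchanged.
.fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

.apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, `/`)
}

#' Train the minimum-distance classifier
#'
#' Features are z-scored with training-set statistics (raw mixed-unit
#' features -- Hz next to dB -- would let large-scale features dominate the
#' Euclidean distance), then the per-class, per-feature means are stored.
#'
#' @param patterns A [pattern_set()].
#' @param standardize Set `FALSE` to skip z-scoring.
#' @return Object of class `mindis_model`.
#' @export
train_min_distance <- function(patterns, standardize = TRUE) {
  stopifnot(inherits(patterns, "pattern_set"))
  scaler <- if (standardize) .fit_scaler(patterns$Pi) else
    list(mean = rep(0, ncol(patterns$Pi)), sd = rep(1, ncol(patterns$Pi)))
  z <- .apply_scaler(patterns$Pi, scaler)
  mu <- do.call(rbind, lapply(patterns$classes, function(k)
    colMeans(z[patterns$labels == k, , drop = FALSE])))
  rownames(mu) <- patterns$classes
  structure(list(mu = mu, classes = patterns$classes, scaler = scaler),
            class = "mindis_model")
}

#' Classify frames by minimum distance to the class means
#'
#' Euclidean distance in the standardized feature space; ties break toward
#' the class listed first in the training pattern set.
#'
#' @param x Numeric vector (one frame) or matrix (frames in rows).
#' @param model A `mindis_model`.
#' @return List with `class` (label per frame) and `distances` (frames x
#'   classes matrix).
#' @export
classify_min_distance <- function(x, model) {
  stopifnot(inherits(model, "mindis_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$mu))
    stop("classify_min_distance: feature width mismatch (", ncol(x),
         " vs ", ncol(model$mu), ")")
  z <- .apply_scaler(x, model$scaler)
  # squared distances via the expansion |z - mu|^2 = |z|^2 - 2 z mu' + |mu|^2
  d2 <- outer(rowSums(z^2), rep(1, nrow(model$mu))) -
    2 * z %*% t(model$mu) +
    outer(rep(1, nrow(z)), rowSums(model$mu^2))
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  colnames(d) <- model$classes
  idx <- apply(d, 1, which.min)   # which.min takes the first (lowest index) tie
  list(class = model$classes[idx], distances = d)
}

#' Train the Gaussian maximum-likelihood classifier
#'
#' One full-covariance Gaussian per class with equal priors. Singular or
#' ill-conditioned covariances are ridge-regularized with
#' `lambda = 1e-6 * mean(diag)`.
#'
#' @param patterns A [pattern_set()].
#' @param standardize z-score features with training statistics first.
#' @return Object of class `maxlik_model`.
#' @export
train_max_likelihood <- function(patterns, standardize = TRUE) {
  stopifnot(inherits(patterns, "pattern_set"))
  scaler <- if (standardize) .fit_scaler(patterns$Pi) else
    list(mean = rep(0, ncol(patterns$Pi)), sd = rep(1, ncol(patterns$Pi)))
  z <- .apply_scaler(patterns$Pi, scaler)
  fit_class <- function(k) {
    xk <- z[patterns$labels == k, , drop = FALSE]
    mu <- colMeans(xk)
    sig <- stats::cov(xk)
    sig[!is.finite(sig)] <- 0
    ridge <- 1e-6 * mean(diag(sig))
    if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-6
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    while (is.null(ch)) {
      sig <- sig + diag(ridge, ncol(sig))
      ridge <- ridge * 10
      ch <- tryCatch(chol(sig), error = function(e) NULL)
    }
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))))
  }
  models <- lapply(patterns$classes, fit_class)
  names(models) <- patterns$classes
  structure(list(models = models, classes = patterns$classes, scaler = scaler),
            class = "maxlik_model")
}

#' Classify frames by Gaussian maximum likelihood
#'
#' @param x Frame vector or matrix (frames in rows).
#' @param model A `maxlik_model`.
#' @return List with `class` and `loglik` (frames x classes).
#' @export
classify_max_likelihood <- function(x, model) {
  stopifnot(inherits(model, "maxlik_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  z <- .apply_scaler(x, model$scaler)
  d <- ncol(z)
  ll <- vapply(model$models, function(m) {
    u <- backsolve(m$chol, t(z) - m$mu, transpose = TRUE)
    -0.5 * (d * log(2 * pi) + m$logdet + colSums(u^2))
  }, numeric(nrow(z)))
  ll <- matrix(ll, nrow = nrow(z), dimnames = list(NULL, model$classes))
  idx <- apply(ll, 1, which.max)
  list(class = model$classes[idx], loglik = ll)
}

#' Pluggable frame-classifier backends
#'
#' A common train/predict contract over the classifier roster: native
#' `MinDis` and `MaxLik`, plus `DecTr` (rpart), `kNN` (class::knn), `SVM`
#' (e1071), `LogReg` (nnet::multinom), `Neur` (nnet, 10 hidden units),
#' `Discr` (MASS::lda) and `Bayes` (e1071::naiveBayes), each at its
#' library's defaults.
#'
#' @param name Backend name.
#' @return List with `name`, `train(patterns)` and `predict(model, X)`.
#' @export
classifier_backend <- function(name = c("MinDis", "MaxLik", "DecTr", "kNN",
                                        "SVM", "LogReg", "Neur", "Discr",
                                        "Bayes")) {
  name <- match.arg(name)
  scale_train <- function(patterns) {
    scaler <- .fit_scaler(patterns$Pi)
    list(z = .apply_scaler(patterns$Pi, scaler),
         y = factor(patterns$labels, levels = patterns$classes),
         scaler = scaler, classes = patterns$classes)
  }
  df_of <- function(z) {
    d <- as.data.frame(z)
    names(d) <- sprintf("V%03d", seq_len(ncol(d)))
    d
  }
  backend <- switch(
    name,
    MinDis = list(
      train = function(p) train_min_distance(p),
      predict = function(m, X) classify_min_distance(X, m)$class),
    MaxLik = list(
      train = function(p) train_max_likelihood(p),
      predict = function(m, X) classify_max_likelihood(X, m)$class),
    DecTr = list(
      train = function(p) {
        s <- scale_train(p)
        d <- df_of(s$z); d$.y <- s$y
        list(fit = rpart::rpart(.y ~ ., data = d, method = "class"),
             scaler = s$scaler, classes = s$classes)
      },
      predict = function(m, X) {
        d <- df_of(.apply_scaler(X, m$scaler))
        as.character(predict(m$fit, d, type = "class"))
      }),
    kNN = list(
      train = function(p) {
        s <- scale_train(p)
        list(z = s$z, y = s$y, scaler = s$scaler, classes = s$classes)
      },
      predict = function(m, X) {
        as.character(class::knn(m$z, .apply_scaler(X, m$scaler), m$y, k = 1))
      }),
    SVM = list(
      train = function(p) {
        s <- scale_train(p)
        list(fit = e1071::svm(s$z, s$y, scale = FALSE),
             scaler = s$scaler, classes = s$classes)
      },
      predict = function(m, X)
        as.character(predict(m$fit, .apply_scaler(X, m$scaler)))),
    LogReg = list(
      train = function(p) {
        s <- scale_train(p)
        d <- df_of(s$z); d$.y <- s$y
        list(fit = nnet::multinom(.y ~ ., data = d, trace = FALSE,
                                  MaxNWts = 100000),
             scaler = s$scaler, classes = s$classes)
      },
      predict = function(m, X) {
        d <- df_of(.apply_scaler(X, m$scaler))
        as.character(predict(m$fit, d))
      }),
    Neur = list(
      train = function(p) {
        s <- scale_train(p)
        list(fit = nnet::nnet(s$z, nnet::class.ind(s$y), size = 10,
                              softmax = TRUE, trace = FALSE, maxit = 200,
                              MaxNWts = 100000),
             scaler = s$scaler, classes = s$classes)
      },
      predict = function(m, X) {
        pr <- predict(m$fit, .apply_scaler(X, m$scaler))
        m$classes[apply(pr, 1, which.max)]
      }),
    Discr = list(
      train = function(p) {
        s <- scale_train(p)
        keep <- apply(s$z, 2, stats::sd) > 1e-10
        list(fit = MASS::lda(s$z[, keep, drop = FALSE], s$y),
             keep = keep, scaler = s$scaler, classes = s$classes)
      },
      predict = function(m, X) {
        z <- .apply_scaler(X, m$scaler)[, m$keep, drop = FALSE]
        as.character(predict(m$fit, z)$class)
      }),
    Bayes = list(
      train = function(p) {
        s <- scale_train(p)
        d <- df_of(s$z)
        list(fit = e1071::naiveBayes(d, s$y),
             scaler = s$scaler, classes = s$classes)
      },
      predict = function(m, X) {
        d <- df_of(.apply_scaler(X, m$scaler))
        as.character(predict(m$fit, d))
      })
  )
  c(list(name = name), backend)
}

#' Aggregate frame decisions into one sound label
#'
#' Plurality vote over the non-silence frame labels. If every frame is
#' silence/noise the sound is labelled silence. Ties break toward the class
#' with the most training pattern frames (when `pattern_counts` is given),
#' then toward the class listed first.
#'
#' @param frame_labels Ordered frame class decisions (length >= 1).
#' @param classes Class order used for tie-breaking.
#' @param silence_label Label treated as silence/noise (excluded from the
#'   vote).
#' @param pattern_counts Optional named vector of training frame counts.
#' @return A single class label.
#' @export
vote_sound <- function(frame_labels, classes = unique(frame_labels),
                       silence_label = "silence", pattern_counts = NULL) {
  if (length(frame_labels) == 0) stop("vote_sound: empty label vector")
  lab <- as.character(frame_labels)
  lab <- lab[lab != silence_label]
  if (length(lab) == 0) return(silence_label)
  cls <- setdiff(classes, silence_label)
  votes <- vapply(cls, function(k) sum(lab == k), integer(1))
  top <- which(votes == max(votes))
  if (length(top) > 1 && !is.null(pattern_counts)) {
    pc <- pattern_counts[cls[top]]
    pc[is.na(pc)] <- 0
    top <- top[pc == max(pc)]
  }
  cls[top[1]]
}

#' Left-to-right recurrent sliding-window classification of one sound
#'
#' Classifies frames sequentially: frame `i`'s RSW feature row is rebuilt
#' from the classifier's own decisions on frames `i-d..i-1` before
#' prediction (at the start of the clip, unknown history is the all-zero
#' one-hot).
#'
#' @param X Frame feature matrix of the sound (frames x features).
#' @param model Trained backend model (trained on [recurrent_augment()]ed
#'   patterns with teacher forcing).
#' @param backend The [classifier_backend()] used for training.
#' @param w Odd window size.
#' @param classes One-hot class universe used in training.
#' @return Character vector of frame labels.
#' @export
rsw_classify_frames <- function(X, model, backend, w, classes) {
  x <- .as_feature_matrix(X)
  d <- (w - 1) / 2
  s <- nrow(x)
  sw <- sliding_window_stack(x, w)
  if (d == 0) return(backend$predict(model, sw))
  a <- length(classes)
  out <- character(s)
  hist_width <- d * a
  for (i in seq_len(s)) {
    hist <- numeric(hist_width)
    for (k in seq_len(d)) {           # slot k encodes theta[i - d + k - 1]
      j <- i - d + k - 1
      if (j >= 1) {
        ci <- match(out[j], classes)
        if (!is.na(ci)) hist[(k - 1) * a + ci] <- 1
      }
    }
    row <- c(hist, sw[i, ])
    out[i] <- backend$predict(model, matrix(row, nrow = 1))
  }
  out
}
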