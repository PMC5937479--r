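#' Kernel density estimate on a shared grid
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth, evaluated on the
#' supplied grid and renormalized so that its trapezoid integral is 1. A
#' bandwidth floor of `1e-3` times the grid span keeps constant samples from
#' collapsing to a zero-width delta.
#'
#' @param values Numeric sample vector (length >= 2).
#' @param grid Ordered evaluation abscissae.
#' @return List of class `class_pdf` with `density` and `grid`.
#' @export
estimate_pdf <- function(values, grid) {
  stopifnot(length(values) >= 2, length(grid) >= 8, !is.unsorted(grid))
  span <- grid[length(grid)] - grid[1]
  floor_bw <- 1e-3 * span
  # bw.nrd0 falls back to an arbitrary scale for zero-spread samples; the
  # documented behaviour there is a near-delta at the common value
  bw <- if (stats::sd(values) == 0) floor_bw else
    max(stats::bw.nrd0(values), floor_bw)
  # column-wise kernel sums; chunked so long sample vectors stay in memory
  dens <- numeric(length(grid))
  chunk <- 4096L
  for (i in seq(1, length(values), by = chunk)) {
    v <- values[i:min(i + chunk - 1L, length(values))]
    dens <- dens + rowSums(stats::dnorm(outer(grid, v, `-`), sd = bw))
  }
  dens <- dens / length(values)
  z <- .trapz(grid, dens)
  if (z <= 0) stop("estimate_pdf: degenerate density (zero mass on grid)")
  structure(list(density = dens / z, grid = grid), class = "class_pdf")
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Jensen-Shannon divergence between two densities on a shared grid
#'
#' Base-2 Jensen-Shannon divergence, evaluated by trapezoid quadrature;
#' integrand terms where a density vanishes contribute 0 (the `0 log 0`
#' convention). The result lies in `[0, 1]`.
#'
#' @param f,g `class_pdf` objects sharing the same grid.
#' @return Scalar divergence in `[0, 1]`.
#' @export
js_divergence <- function(f, g) {
  stopifnot(inherits(f, "class_pdf"), inherits(g, "class_pdf"))
  if (length(f$grid) != length(g$grid) || any(f$grid != g$grid))
    stop("js_divergence: densities must share an evaluation grid")
  fd <- f$density; gd <- g$density
  m <- fd + gd
  term <- function(d) {
    v <- numeric(length(d))
    ok <- d > 0 & m > 0
    v[ok] <- d[ok] * log2(2 * d[ok] / m[ok])
    v
  }
  val <- 0.5 * .trapz(f$grid, term(fd)) + 0.5 * .trapz(f$grid, term(gd))
  min(max(val, 0), 1)
}

#' Jensen-Shannon distance
#'
#' The square root of [js_divergence()]; a metric in `[0, 1]`.
#'
#' @inheritParams js_divergence
#' @return Scalar distance in `[0, 1]`.
#' @export
js_distance <- function(f, g) sqrt(js_divergence(f, g))

# Shared evaluation grid for one feature: pooled range widened by 3 pooled
# bandwidths, 512 points.
.feature_grid <- function(values, n_grid = 512) {
  bw <- stats::bw.nrd0(values)
  span <- diff(range(values))
  bw <- max(bw, 1e-3 * max(span, 1e-8))
  seq(min(values) - 3 * bw, max(values) + 3 * bw, length.out = n_grid)
}

#' Class-separability index of one feature
#'
#' The geometric mean of the pairwise Jensen-Shannon distances between the
#' class-conditional densities of the feature: with `A` classes there are
#' `B = A(A-1)/2` unordered pairs and the index is the `B`-th root of the
#' product of their distances. Any coincident pair annihilates the index.
#'
#' @param values Numeric vector of feature values over pattern frames.
#' @param labels Class label per value (>= 2 classes, each with >= 2 values).
#' @param n_grid Number of evaluation-grid points.
#' @return Scalar separability index (>= 0).
#' @export
separability_index <- function(values, labels, n_grid = 512) {
  labels <- as.character(labels)
  classes <- unique(labels)
  a <- length(classes)
  if (a < 2) stop("separability_index: need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2))
    stop("separability_index: every class needs >= 2 pattern frames (got ",
         paste(names(counts)[counts < 2], collapse = ", "), ")")
  grid <- .feature_grid(values, n_grid)
  pdfs <- lapply(classes, function(k) estimate_pdf(values[labels == k], grid))
  dists <- c()
  for (u in seq_len(a - 1)) for (v in (u + 1):a)
    dists <- c(dists, js_distance(pdfs[[u]], pdfs[[v]]))
  if (any(dists == 0)) return(0)
  exp(mean(log(dists)))
}

#' Rank features by class separability
#'
#' Computes the separability index of every feature column over the pattern
#' frames and orders features by descending index; ties break by original
#' column position (lower first).
#'
#' @param patterns A [pattern_set()].
#' @param n_grid Evaluation-grid size per feature.
#' @return Object of class `separability_ranking`: list with `psi` (named
#'   index vector in original column order), `order` (column indices by
#'   descending relevance), `A` (class count) and `B` (pair count).
#' @export
rank_features <- function(patterns, n_grid = 512) {
  stopifnot(inherits(patterns, "pattern_set"))
  x <- patterns$Pi
  psi <- vapply(seq_len(ncol(x)), function(j)
    separability_index(x[, j], patterns$labels, n_grid), numeric(1))
  names(psi) <- colnames(x)
  a <- length(patterns$classes)
  ord <- order(-psi, seq_along(psi))
  structure(list(psi = psi, order = ord, A = a, B = a * (a - 1) / 2),
            class = "separability_ranking")
}

#' @export
print.separability_ranking <- function(x, ...) {
  cat(sprintf("<separability_ranking: %d features, %d classes (%d pairs)>\n",
              length(x$psi), x$A, x$B))
  df <- data.frame(rank = seq_along(x$order),
                   feature = names(x$psi)[x$order],
                   psi = round(x$psi[x$order], 4), row.names = NULL)
  print(utils::head(df, 18))
  invisible(x)
}

#' Select the r most relevant features
#'
#' @param ranking A `separability_ranking`.
#' @param r Number of features to keep.
#' @return Integer vector of the top `r` original column indices.
#' @export
select_top <- function(ranking, r) {
  stopifnot(inherits(ranking, "separability_ranking"))
  if (r < 1 || r > length(ranking$psi))
    stop("select_top: r must be in 1..", length(ranking$psi))
  ranking$order[seq_len(r)]
}
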