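#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run: data source, method(s),
#' feature count `r`, window size `w`, backend classifier, and seeds.
#' Method/parameter compatibility is validated up front: `w` applies only
#' to the SW, RSW and HMM-SW methods and must be odd.
#'
#' @param methods Character vector out of `NTA`, `LIQR`, `SW`, `RSW`,
#'   `HMM-F`, `HMM-ROI`, `HMM-SW`, `VAR`. Several methods share one
#'   dataset, feature extraction, ranking and split (paired evaluation).
#' @param r Number of most-relevant features to keep (1..18).
#' @param w Odd window size in frames (required iff any method uses it).
#' @param backend Underlying frame classifier name (see
#'   [classifier_backend()]).
#' @param specs Call class roster (default [default_call_classes()]).
#' @param scene A [scene_config()] for synthetic data; its seed drives
#'   generation.
#' @param n_per_class Recordings per class.
#' @param pattern_fraction Fraction of each class used as training
#'   patterns.
#' @param liqr_window LIQR window in frames.
#' @param hmm_states HMM state count.
#' @param codebook_size VQ codebook size.
#' @param var_max_order Maximum VAR order scanned by AIC.
#' @param split_seed Seed for the validation/test split (defaults to the
#'   scene seed).
#' @param dataset Optional pre-built `call_dataset` (overrides synthetic
#'   generation, e.g. from [load_dataset()]).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(methods = "NTA", r = 5, w = NULL,
                              backend = "MinDis",
                              specs = default_call_classes(),
                              scene = scene_config(),
                              n_per_class = 6, pattern_fraction = 0.2,
                              liqr_window = 10, hmm_states = 5,
                              codebook_size = 256, var_max_order = 10,
                              split_seed = NULL, dataset = NULL) {
  all_methods <- c("NTA", "LIQR", "SW", "RSW", "HMM-F", "HMM-ROI",
                   "HMM-SW", "VAR")
  if (!all(methods %in% all_methods))
    stop("experiment_config: unknown method(s): ",
         paste(setdiff(methods, all_methods), collapse = ", "))
  windowed <- intersect(methods, c("SW", "RSW", "HMM-SW"))
  if (length(windowed) && (is.null(w) || w < 1 || w %% 2 == 0))
    stop("experiment_config: methods ", paste(windowed, collapse = "/"),
         " need an odd window size w")
  if (!length(windowed) && !is.null(w))
    stop("experiment_config: w given but no configured method uses a window")
  if (r < 1 || r > 18) stop("experiment_config: r must be in 1..18")
  structure(list(methods = methods, r = r, w = w, backend = backend,
                 specs = specs, scene = scene, n_per_class = n_per_class,
                 pattern_fraction = pattern_fraction,
                 liqr_window = liqr_window, hmm_states = hmm_states,
                 codebook_size = codebook_size,
                 var_max_order = var_max_order,
                 split_seed = if (is.null(split_seed)) scene$seed else split_seed,
                 dataset = dataset),
            class = "experiment_config")
}

#' Load a generated dataset from disk
#'
#' Reads the `manifest.csv`, `rois.csv` and WAV files written by
#' [generate_dataset()].
#'
#' @param dir Dataset directory.
#' @return A `call_dataset`.
#' @export
load_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  rois <- utils::read.csv(file.path(dir, "rois.csv"), stringsAsFactors = FALSE)
  recordings <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- sub("\\.wav$", "", manifest$file[i])
    clip <- read_wav(file.path(dir, manifest$file[i]))
    spans <- rois[rois$file == manifest$file[i], c("start_s", "end_s")]
    recordings[[id]] <- list(clip = clip, roi_spans = spans,
                             label = manifest$class[i],
                             is_pattern = isTRUE(manifest$is_pattern[i]))
  }
  structure(list(manifest = manifest, rois = rois, recordings = recordings,
                 scene = NULL, dir = dir),
            class = "call_dataset")
}

# Contiguous runs of frames carrying `target` in a label vector.
.label_runs <- function(labels, target) {
  r <- rle(labels == target)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  Map(function(s, e) s:e, starts[r$values], ends[r$values])
}

# Shared stage: features, per-frame pattern labels, ranking, split.
.prepare_experiment <- function(config) {
  ds <- config$dataset
  if (is.null(ds))
    ds <- generate_dataset(config$specs, config$scene, config$n_per_class,
                           config$pattern_fraction)
  ids <- sub("\\.wav$", "", ds$manifest$file)
  feats <- list()
  for (id in ids) {
    rec <- ds$recordings[[id]]
    feats[[id]] <- extract_features(frame_signal(rec$clip))
  }
  frame_s <- feats[[1]]$frame_s
  call_classes <- unique(ds$manifest$class)
  classes <- c(call_classes, "silence")

  pat_ids <- ids[ds$manifest$is_pattern]
  pat_labels <- list()
  for (id in pat_ids) {
    rec <- ds$recordings[[id]]
    pat_labels[[id]] <- frame_labels_from_rois(rec$roi_spans,
                                               nrow(feats[[id]]$X),
                                               frame_s, rec$label)
  }
  Pi <- do.call(rbind, lapply(pat_ids, function(id) feats[[id]]$X))
  lab <- unlist(pat_labels[pat_ids], use.names = FALSE)
  patterns18 <- pattern_set(Pi, lab, classes = classes)
  ranking <- rank_features(patterns18)
  sel <- select_top(ranking, config$r)

  manifest <- split_dataset(ds$manifest, "instance_selection",
                            seed = config$split_seed)
  list(ds = ds, ids = ids, feats = feats, frame_s = frame_s,
       classes = classes, call_classes = call_classes,
       pat_ids = pat_ids, pat_labels = pat_labels,
       ranking = ranking, sel = sel, manifest = manifest)
}

# Frame-based methods: build the (possibly augmented) pattern matrix, train
# the backend, classify each sound's frames and vote.
.run_frame_method <- function(prep, method, config, eval_ids) {
  sel <- prep$sel
  be <- classifier_backend(config$backend)
  build <- function(id, labels = NULL) {
    x <- prep$feats[[id]]$X[, sel, drop = FALSE]
    switch(method,
           NTA = x,
           LIQR = liqr_features(x, config$liqr_window),
           SW = sliding_window_stack(x, config$w),
           RSW = recurrent_augment(x, labels, config$w, prep$classes))
  }
  tr <- do.call(rbind, lapply(prep$pat_ids, function(id)
    build(id, prep$pat_labels[[id]])))
  tr_lab <- unlist(prep$pat_labels[prep$pat_ids], use.names = FALSE)
  patterns <- pattern_set(tr, tr_lab, classes = prep$classes)
  model <- be$train(patterns)
  preds <- vapply(eval_ids, function(id) {
    frames <- if (method == "RSW")
      rsw_classify_frames(prep$feats[[id]]$X[, sel, drop = FALSE], model, be,
                          config$w, prep$classes)
    else be$predict(model, build(id))
    vote_sound(frames, prep$classes, "silence", patterns$counts)
  }, character(1))
  preds
}

.run_hmm_method <- function(prep, method, config, eval_ids) {
  sel <- prep$sel
  pat_mats <- lapply(prep$pat_ids, function(id)
    prep$feats[[id]]$X[, sel, drop = FALSE])
  scaler <- .fit_scaler(do.call(rbind, pat_mats))
  pooled <- .apply_scaler(do.call(rbind, pat_mats), scaler)
  suppressWarnings(
    cb <- lbg_codebook(pooled, config$codebook_size, seed = config$split_seed))
  roi_lens <- c()
  seqs_by_class <- stats::setNames(
    vector("list", length(prep$call_classes)), prep$call_classes)
  for (i in seq_along(prep$pat_ids)) {
    id <- prep$pat_ids[i]
    cls <- prep$ds$recordings[[id]]$label
    runs <- .label_runs(prep$pat_labels[[id]], cls)
    codes <- quantize(.apply_scaler(pat_mats[[i]], scaler), cb)
    for (run in runs) {
      seqs_by_class[[cls]] <- c(seqs_by_class[[cls]], list(codes[run]))
      roi_lens <- c(roi_lens, length(run))
    }
  }
  hmms <- lapply(seqs_by_class, function(seqs)
    train_hmm(seqs, cb$n_codes, config$hmm_states,
              seed = config$split_seed))
  preds <- vapply(eval_ids, function(id) {
    x <- .apply_scaler(prep$feats[[id]]$X[, sel, drop = FALSE], scaler)
    codes <- quantize(x, cb)
    segs <- switch(method,
                   `HMM-F` = segment_plan(length(codes), "full"),
                   `HMM-ROI` = segment_plan(length(codes), "roi_mean",
                                            roi_mean_frames = mean(roi_lens)),
                   `HMM-SW` = segment_plan(length(codes), "sliding",
                                           w = config$w))
    seg_labels <- vapply(segs, function(ix)
      classify_segment_hmm(codes[ix], hmms)$class, character(1))
    vote_sound(seg_labels, prep$call_classes, "silence")
  }, character(1))
  preds
}

.run_var_method <- function(prep, config, eval_ids) {
  sel <- prep$sel
  d <- length(sel)
  segs <- list(); seg_class <- c()
  for (id in prep$pat_ids) {
    cls <- prep$ds$recordings[[id]]$label
    x <- prep$feats[[id]]$X[, sel, drop = FALSE]
    for (run in .label_runs(prep$pat_labels[[id]], cls)) {
      segs <- c(segs, list(x[run, , drop = FALSE]))
      seg_class <- c(seg_class, cls)
    }
  }
  min_len <- min(vapply(segs, nrow, integer(1)))
  # the shortest segment must keep d+ spare rows beyond the a*d regressors
  # so the residual covariance stays full rank at every scanned order
  a_max <- min(config$var_max_order, floor((min_len - d - 2) / (d + 1)))
  if (a_max < 1)
    stop("VAR: pattern ROI segments too short for any order in ", d,
         " dimensions")
  selection <- select_var_order(segs, a_max)
  a <- max(1L, selection$order)
  keep <- vapply(segs, nrow, integer(1)) > a * (d + 1) + 1
  tr <- t(vapply(segs[keep], function(s)
    var_feature_vector(fit_var(s, a)), numeric(a * d^2)))
  patterns <- pattern_set(tr, seg_class[keep],
                          classes = unique(seg_class))
  be <- classifier_backend(config$backend)
  model <- be$train(patterns)
  preds <- vapply(eval_ids, function(id) {
    x <- prep$feats[[id]]$X[, sel, drop = FALSE]
    v <- var_feature_vector(fit_var(x, a))
    be$predict(model, matrix(v, nrow = 1))
  }, character(1))
  attr(preds, "var_order") <- a
  attr(preds, "order_selection") <- selection
  preds
}

# Metrics restricted to the call classes (silence is a frame-level label
# only; a sound predicted all-silence still counts against its true class).
.evaluate_sounds <- function(true, pred, call_classes) {
  cm <- confusion(true, pred, c(call_classes, "silence"))
  per <- t(vapply(call_classes, function(k)
    suppressWarnings(one_vs_rest_metrics(cm, k)), numeric(7)))
  list(confusion = cm, per_class = per, macro = macro_average(per))
}

#' Run an end-to-end classification experiment
#'
#' Generates (or ingests) the dataset, extracts the 18 descriptors, ranks
#' features on the training patterns, keeps the top `r`, trains every
#' configured method and evaluates sound-level classification on the
#' requested split. All configured methods share the dataset, features,
#' ranking and split, so their predictions are paired.
#'
#' @param config An [experiment_config()].
#' @param eval_split `"test"` (default) or `"validation"`.
#' @return Object of class `experiment_report`: `config`, `ranking`,
#'   `selected` (feature indices), `manifest` (with split assignment) and
#'   `results` -- per method: `predictions` (data frame with `sound`,
#'   `true`, `pred`), `confusion`, `per_class`, `macro`.
#' @export
run_experiment <- function(config, eval_split = c("test", "validation")) {
  stopifnot(inherits(config, "experiment_config"))
  eval_split <- match.arg(eval_split)
  prep <- .prepare_experiment(config)
  eval_rows <- prep$manifest$split == eval_split
  eval_ids <- sub("\\.wav$", "", prep$manifest$file[eval_rows])
  true <- prep$manifest$class[eval_rows]
  results <- list()
  for (method in config$methods) {
    pred <- if (method %in% c("NTA", "LIQR", "SW", "RSW"))
      .run_frame_method(prep, method, config, eval_ids)
    else if (method %in% c("HMM-F", "HMM-ROI", "HMM-SW"))
      .run_hmm_method(prep, method, config, eval_ids)
    else
      .run_var_method(prep, config, eval_ids)
    ev <- .evaluate_sounds(true, as.character(pred), prep$call_classes)
    results[[method]] <- c(
      list(predictions = data.frame(sound = eval_ids, true = true,
                                    pred = as.character(pred),
                                    row.names = NULL)),
      ev,
      if (!is.null(attr(pred, "var_order")))
        list(var_order = attr(pred, "var_order")))
  }
  structure(list(config = config, ranking = prep$ranking,
                 selected = prep$sel, manifest = prep$manifest,
                 eval_split = eval_split, results = results),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report: %s split, r = %d>\n",
              x$eval_split, x$config$r))
  for (m in names(x$results))
    cat(sprintf("  %-8s macro AUC %.4f  ACC %.4f\n", m,
                x$results[[m]]$macro["AUC"], x$results[[m]]$macro["ACC"]))
  invisible(x)
}

#' Joint sweep of feature count and window size
#'
#' Runs the first configured method over the `r x w` grid, scoring each
#' cell by macro AUC on the validation split only (test labels are never
#' touched during selection).
#'
#' @param config Base [experiment_config()].
#' @param r_grid,w_grid Candidate values.
#' @return List with `table` (data frame `r`, `w`, `auc`) and `best`
#'   (`r`, `w` of the best cell; ties take the smaller total width `r*w`).
#' @export
sweep_experiment <- function(config, r_grid, w_grid) {
  stopifnot(length(r_grid) >= 1, length(w_grid) >= 1)
  rows <- list()
  for (r in r_grid) for (w in w_grid) {
    cfg <- config
    cfg$r <- r
    cfg$w <- w
    rep_ <- run_experiment(cfg, eval_split = "validation")
    rows[[length(rows) + 1]] <- data.frame(
      r = r, w = w, auc = rep_$results[[1]]$macro["AUC"], row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  best <- tab[tab$auc == max(tab$auc), , drop = FALSE]
  best <- best[order(best$r * best$w), , drop = FALSE][1, ]
  list(table = tab, best = list(r = best$r, w = best$w, auc = best$auc))
}
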