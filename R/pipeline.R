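#' Split a dataset into train / validation / test
#'
#' Disjoint, exhaustive index sets with sizes `round(n * fraction)`;
#' remainder items from rounding go to training (the largest split). With
#' `stratify = TRUE` the fractions are applied within each label class.
#'
#' @param n number of items, or a vector of item indices.
#' @param fractions numeric `(train, validation, test)` summing to 1.
#' @param labels labels for stratification (required when `stratify`).
#' @param stratify logical.
#' @param seed integer seed for the shuffling.
#' @return A list of integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), labels = NULL,
                          stratify = FALSE, seed = 1L) {
  idx <- if (length(n) == 1L) seq_len(n) else n
  if (any(fractions <= 0)) stop("split_dataset: fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split_dataset: fractions must sum to 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  alloc <- function(ids) {
    ids <- sample(ids)
    m <- length(ids)
    nv <- round(fractions[2] * m)
    nt <- round(fractions[3] * m)
    ntr <- m - nv - nt
    list(train = ids[seq_len(ntr)],
         validation = ids[ntr + seq_len(nv)],
         test = ids[ntr + nv + seq_len(nt)])
  }
  if (stratify) {
    if (is.null(labels)) stop("split_dataset: stratify needs labels")
    parts <- lapply(split(idx, labels[idx]), alloc)
    out <- list(train = unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
                validation = unlist(lapply(parts, `[[`, "validation"),
                                    use.names = FALSE),
                test = unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
  } else {
    out <- alloc(idx)
  }
  if (!length(out$train) || !length(out$validation) || !length(out$test))
    stop("split_dataset: a split would be empty")
  lapply(out, sort)
}

#' Run the full pipeline end to end
#'
#' Executes, in order: synthetic data generation (or directory loading) ->
#' preprocessing -> SK-UNet segmentation (trained on the training split) ->
#' feature extraction -> FOA feature selection (fitness on the validation
#' split) -> hybrid 1D-CNN-GRU training -> evaluation on the held-out test
#' split. Ablation flags replace a stage by its pass-through: ground-truth
#' masks for `use_segmentation = FALSE`, all features for
#' `foa$enabled = FALSE`, a convolution-only head for
#' `classifier$use_gru = FALSE`.
#'
#' Test-split data never enter preprocessing statistics, FOA fitness, or
#' classifier fitting; the returned report carries the index sets so this
#' can be audited.
#'
#' @param config a `pipeline_config` (see [default_config()]); the
#'   `synthetic` block defines the generated dataset.
#' @param dataset optional pre-built dataset (list of `image`/`mask`/`label`
#'   items) overriding synthetic generation.
#' @param use_segmentation logical ablation flag (FALSE: ground-truth
#'   masks).
#' @param verbose print stage log lines.
#' @return A `run_report` list with per-stage seeds, configs, segmentation
#'   metrics, selected feature names, classification metrics per split, and
#'   wall times.
#' @export
run_pipeline <- function(config = default_config(), dataset = NULL,
                         use_segmentation = TRUE, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- as_pipeline_config(config)
  if (!verbose) {
    oq <- options(lesionkit.quiet = TRUE)
    on.exit(options(oq))
  }
  seed <- config$seed
  tic <- function() proc.time()[["elapsed"]]
  times <- list()

  t0 <- tic()
  if (is.null(dataset)) {
    sp <- synth_image_params(size = config$synthetic$size)
    sp$classes <- sp$classes[seq_len(min(config$synthetic$classes,
                                         length(sp$classes)))]
    dataset <- make_image_dataset(config$synthetic$n, sp,
                                  seed = derive_seed(seed, "synth"))
  }
  labels <- vapply(dataset, `[[`, numeric(1), "label")
  times$synth <- tic() - t0
  lk_log("synth", sprintf("%d items, %d classes", length(dataset),
                          length(unique(labels))),
         derive_seed(seed, "synth"))

  split <- split_dataset(length(dataset), with(config$split,
                                               c(train, validation, test)),
                         labels = labels, stratify = config$split$stratify,
                         seed = derive_seed(seed, "split"))

  # preprocessing: per-image, parameter-free across images (no statistics
  # are pooled, so applying it to all images leaks nothing)
  t0 <- tic()
  pcfg <- config$preprocess
  pcfg$resize$height <- dim(strip_raster(dataset[[1]]$image))[1]
  pcfg$resize$width <- dim(strip_raster(dataset[[1]]$image))[2]
  if (isTRUE(pcfg$enabled)) {
    for (i in seq_along(dataset))
      dataset[[i]]$image <- preprocess(dataset[[i]]$image,
                                       list(preprocess = pcfg))
  }
  times$preprocess <- tic() - t0
  lk_log("preprocess", sprintf("done in %.1fs", times$preprocess))

  t0 <- tic()
  seg_metrics <- NULL
  masks <- lapply(dataset, `[[`, "mask")
  if (use_segmentation) {
    seg_seed <- derive_seed(seed, "segment")
    model <- build_sk_unet(config$segmentation, seed = seg_seed)
    model <- train_segmenter(model, dataset[split$train],
                             train = config$segmentation$train,
                             seed = seg_seed)
    pred <- lapply(dataset, function(it) predict_mask(model, it$image))
    mtest <- lapply(split$test, function(i)
      segmentation_metrics(pred[[i]], dataset[[i]]$mask))
    seg_metrics <- list(
      dice = mean(vapply(mtest, `[[`, numeric(1), "dice")),
      iou = mean(vapply(mtest, `[[`, numeric(1), "iou")),
      pixel_accuracy = mean(vapply(mtest, `[[`, numeric(1),
                                   "pixel_accuracy")))
    # fall back to truth where the predicted mask is too degenerate to
    # support feature extraction (needs one pixel with a full 3x3 window)
    masks <- lapply(seq_along(pred), function(i)
      if (mask_usable(pred[[i]])) pred[[i]] else dataset[[i]]$mask)
    lk_log("segment", sprintf("test dice %.3f", seg_metrics$dice), seg_seed)
  } else {
    lk_log("segment", "ablated: using ground-truth masks")
  }
  times$segment <- tic() - t0

  t0 <- tic()
  feats <- t(vapply(seq_along(dataset), function(i)
    extract_features(dataset[[i]]$image, masks[[i]], config),
    extract_features(dataset[[1]]$image, masks[[1]], config)))
  times$features <- tic() - t0
  lk_log("features", sprintf("%d x %d matrix", nrow(feats), ncol(feats)))

  t0 <- tic()
  if (isTRUE(config$foa$enabled)) {
    foa_seed <- derive_seed(seed, "select")
    fcfg <- foa_config(dimensions = ncol(feats),
                       population = config$foa$population,
                       iterations = config$foa$iterations,
                       subset_penalty = config$foa$subset_penalty,
                       threshold = config$foa$threshold,
                       knn_k = config$foa$knn_k,
                       cv_folds = config$foa$cv_folds, seed = foa_seed)
    selection <- select_features(feats[split$train, , drop = FALSE],
                                 labels[split$train], fcfg,
                                 val_table = feats[split$validation, ,
                                                   drop = FALSE],
                                 val_labels = labels[split$validation])
    sel <- selection$selected
    lk_log("select", sprintf("%d / %d features", length(sel), ncol(feats)),
           foa_seed)
  } else {
    selection <- NULL
    sel <- seq_len(ncol(feats))
    lk_log("select", "ablated: all features")
  }
  times$select <- tic() - t0

  t0 <- tic()
  clf_seed <- derive_seed(seed, "classify")
  clf <- build_classifier(length(sel), length(unique(labels)),
                          config$classifier, seed = clf_seed)
  clf <- train_classifier(clf, feats[split$train, sel, drop = FALSE],
                          labels[split$train],
                          train = config$classifier$train, seed = clf_seed)
  times$classify <- tic() - t0

  t0 <- tic()
  reports <- lapply(split, function(ix)
    evaluate_classifier(clf, feats[ix, sel, drop = FALSE], labels[ix]))
  times$evaluate <- tic() - t0
  lk_log("evaluate", sprintf("test accuracy %.3f macro F1 %.3f",
                             reports$test$accuracy, reports$test$f1),
         clf_seed)

  structure(list(
    seed = seed,
    stage_seeds = list(synth = derive_seed(seed, "synth"),
                       split = derive_seed(seed, "split"),
                       segment = derive_seed(seed, "segment"),
                       select = derive_seed(seed, "select"),
                       classify = derive_seed(seed, "classify")),
    config = unclass(config),
    split = split,
    labels = labels,
    ablation = list(segmentation = use_segmentation,
                    foa = isTRUE(config$foa$enabled),
                    gru = isTRUE(config$classifier$use_gru)),
    segmentation = seg_metrics,
    selected_features = colnames(feats)[sel],
    selection_history = selection$history,
    metrics = lapply(reports, report_to_list),
    wall_time = times), class = "run_report")
}

# a mask supports feature extraction if some pixel has its whole 3x3
# neighborhood inside the foreground (LBP interior condition)
mask_usable <- function(mask) {
  m <- strip_raster(mask)
  if (sum(m) < 9) return(FALSE)
  h <- nrow(m); w <- ncol(m)
  if (h < 3 || w < 3) return(FALSE)
  core <- m[2:(h - 1), 2:(w - 1)]
  for (dr in -1:1) for (dc in -1:1)
    core <- core * m[2:(h - 1) + dr, 2:(w - 1) + dc]
  sum(core) > 0
}

report_to_list <- function(r) {
  list(accuracy = r$accuracy, precision = r$precision, recall = r$recall,
       f1 = r$f1, auc = r$auc, confusion = unname(as.matrix(r$confusion)))
}

#' Save a run report as JSON
#'
#' @param report a `run_report`.
#' @param path output `.json` path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  if (!is.null(x$segmentation))
    cat(sprintf("  segmentation: dice %.3f iou %.3f acc %.3f\n",
                x$segmentation$dice, x$segmentation$iou,
                x$segmentation$pixel_accuracy))
  cat(sprintf("  selected features: %d\n", length(x$selected_features)))
  cat(sprintf("  test: accuracy %.3f macro F1 %.3f\n",
              x$metrics$test$accuracy, x$metrics$test$f1))
  invisible(x)
}
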