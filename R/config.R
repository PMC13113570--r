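#' Pipeline configuration
#'
#' A `pipeline_config` is a named list of per-stage sub-configurations
#' (`preprocess`, `segmentation`, `features`, `foa`, `classifier`, `split`,
#' `synthetic`, plus a global `seed`). [default_config()] returns the full
#' default set; [load_config()] reads a YAML or JSON file, fills defaults for
#' absent fields, rejects unknown keys, and validates every numeric bound.
#' Training defaults follow the reference protocol: Adam with learning rate
#' `1e-4`, batch size 32, 30 epochs, and a 70/15/15 train/validation/test
#' split.
#'
#' The single global `seed` fans out to per-stage derived seeds (see
#' [derive_seed()]) so each stage is reproducible independently of stage
#' order.
#'
#' @return A `pipeline_config` list.
#' @export
default_config <- function() {
  cfg <- list(
    seed = 1L,
    preprocess = list(
      enabled = TRUE,
      clahe = list(enabled = TRUE, tile_size = 8L, clip_factor = 2,
                   levels = 256L),
      wiener = list(enabled = TRUE, window = 3L, noise_variance = NULL),
      resize = list(enabled = TRUE, height = 224L, width = 224L)
    ),
    segmentation = list(
      stages = 4L, base_channels = 16L, sk_branches = 3L,
      sk_dilations = c(1L, 2L, 3L), se_reduction = 8L, sk_reduction = 8L,
      classes = 2L, head_channels = 32L,
      train = list(learning_rate = 1e-3, batch_size = 4L, epochs = 30L,
                   dice_loss = FALSE)
    ),
    features = list(
      glcm = list(levels = 8L, distances = 1L, angles = c(0L, 45L, 90L, 135L),
                  symmetric = TRUE, normalized = TRUE, average_angles = TRUE),
      lbp = list(block_size = NULL)
    ),
    foa = list(
      enabled = TRUE, population = 20L, iterations = 50L,
      subset_penalty = 0.01, threshold = 0.5, knn_k = 3L, cv_folds = 3L
    ),
    classifier = list(
      conv_filters = c(32L, 64L), kernel_size = 3L, gru_hidden = 64L,
      dropout = 0, use_gru = TRUE,
      train = list(learning_rate = 1e-4, batch_size = 32L, epochs = 30L)
    ),
    split = list(train = 0.70, validation = 0.15, test = 0.15,
                 stratify = TRUE),
    synthetic = list(n = 60L, size = 64L, classes = 3L)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname default_config
#' @param path path to a `.yaml`/`.yml` or `.json` config file. An empty file
#'   yields all defaults.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext == "json") {
    if (file.size(path) == 0) NULL else jsonlite::read_json(path,
                                                            simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_pipeline_config(user)
}

#' @rdname default_config
#' @param x a (possibly partial) named list of configuration overrides.
#' @export
as_pipeline_config <- function(x = NULL) {
  cfg <- merge_config(default_config(), x, path = "config")
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname default_config
#' @param cfg a `pipeline_config`.
#' @export
save_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  plain <- unclass(cfg)
  if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}

# Recursive default-filling merge; unknown keys are a schema error.
merge_config <- function(def, user, path) {
  if (is.null(user)) return(def)
  if (!is.list(user)) stop("config: '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("config: unknown key(s) under '", path, "': ",
         paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- merge_config(def[[k]], user[[k]], paste0(path, ".", k))
    } else {
      v <- user[[k]]
      if (is.list(v)) v <- unlist(v)
      def[k] <- list(v)  # keeps explicit NULL assignments
    }
  }
  def
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("config: field '", field, "' ", msg)
  }
  pc <- cfg$preprocess$clahe
  chk(pc$tile_size >= 2, "preprocess.clahe.tile_size", "must be >= 2")
  chk(pc$clip_factor >= 0 && pc$clip_factor <= 100,
      "preprocess.clahe.clip_factor", "must be in [0, 100]")
  chk(pc$levels >= 2, "preprocess.clahe.levels", "must be >= 2")
  pw <- cfg$preprocess$wiener
  chk(pw$window >= 3 && pw$window %% 2 == 1, "preprocess.wiener.window",
      "must be odd and >= 3")
  if (!is.null(pw$noise_variance))
    chk(pw$noise_variance >= 0, "preprocess.wiener.noise_variance",
        "must be >= 0")
  pr <- cfg$preprocess$resize
  chk(pr$height >= 1 && pr$width >= 1, "preprocess.resize", "must be positive")
  sg <- cfg$segmentation
  chk(sg$stages >= 2, "segmentation.stages", "must be >= 2")
  chk(sg$sk_branches == 3, "segmentation.sk_branches", "must be 3")
  chk(length(sg$sk_dilations) == 3 && !anyDuplicated(sg$sk_dilations) &&
        all(sg$sk_dilations >= 1), "segmentation.sk_dilations",
      "must be 3 distinct positive integers")
  chk(sg$classes >= 2, "segmentation.classes", "must be >= 2")
  chk(sg$train$batch_size >= 1, "segmentation.train.batch_size",
      "must be >= 1")
  chk(sg$train$learning_rate > 0, "segmentation.train.learning_rate",
      "must be > 0")
  fg <- cfg$features$glcm
  chk(fg$levels >= 2, "features.glcm.levels", "must be >= 2")
  chk(all(fg$angles %in% c(0, 45, 90, 135)), "features.glcm.angles",
      "must be among 0, 45, 90, 135")
  chk(all(fg$distances >= 1), "features.glcm.distances", "must be >= 1")
  fo <- cfg$foa
  chk(fo$population >= 2, "foa.population", "must be >= 2")
  chk(fo$iterations >= 0, "foa.iterations", "must be >= 0")
  chk(fo$subset_penalty >= 0, "foa.subset_penalty", "must be >= 0")
  chk(fo$threshold > 0 && fo$threshold < 1, "foa.threshold",
      "must be in (0, 1)")
  cl <- cfg$classifier
  chk(all(cl$conv_filters >= 1), "classifier.conv_filters", "must be >= 1")
  chk(cl$kernel_size >= 1, "classifier.kernel_size", "must be >= 1")
  chk(cl$gru_hidden >= 1, "classifier.gru_hidden", "must be >= 1")
  chk(cl$dropout >= 0 && cl$dropout < 1, "classifier.dropout",
      "must be in [0, 1)")
  chk(cl$train$batch_size >= 1, "classifier.train.batch_size", "must be >= 1")
  chk(cl$train$learning_rate > 0, "classifier.train.learning_rate",
      "must be > 0")
  chk(cl$train$epochs >= 1, "classifier.train.epochs", "must be >= 1")
  sp <- cfg$split
  chk(sp$train > 0 && sp$validation > 0 && sp$test > 0, "split",
      "fractions must be positive")
  chk(abs(sp$train + sp$validation + sp$test - 1) < 1e-9, "split",
      "fractions must sum to 1")
  invisible(cfg)
}

#' Derive a stage seed from the global seed
#'
#' Deterministic fan-out of one global seed into per-stage seeds, so a stage
#' is reproducible regardless of which other stages ran before it. The result
#' always fits a 32-bit signed integer.
#'
#' @param seed integer global seed.
#' @param stage character stage name (hashed into the derived seed).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Structured stage logging
#'
#' One-line log records with stage name and seed; silenced by
#' `options(lesionkit.quiet = TRUE)`.
#'
#' @param stage stage name.
#' @param msg message text.
#' @param seed optional seed to record.
#' @export
lk_log <- function(stage, msg, seed = NULL) {
  if (isTRUE(getOption("lesionkit.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[lesionkit:%s]%s %s", stage,
                  if (is.null(seed)) "" else sprintf(" (seed=%d)", seed), msg))
}
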