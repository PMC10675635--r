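# End-to-end orchestration: dataset simulation, preparation into aligned
# per-camera sample arrays, training, and evaluation, driven by one YAML
# config and one global seed.

#' Derive a stage seed from the global seed
#'
#' Each pipeline stage draws its randomness from a seed derived
#' deterministically from `(global seed, stage name)`, so stages can be
#' re-run independently without reshuffling the others.
#'
#' @param seed Global integer seed.
#' @param stage Stage name string.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483646 + 1)
}

#' Load a pipeline run configuration
#'
#' Reads a YAML file with optional blocks `seed`, `paths` (`data`, `out`),
#' `scene` (`n_cows`, `sensor`, `noise_sd`, `frames_per_cow`),
#' `preprocess` (per camera: `distance_threshold`, `crop`,
#' `binarize_threshold`, `gradient_cap`), `split` (`test_fraction`, `cap`,
#' `stratify`), `model` (`fusion`, `cameras`) and `train`
#' (`learning_rate`, `epochs`, `batch_size`, `class_weighting`), filling
#' defaults for anything absent.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A normalised config list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    path
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$paths$data <- cfg$paths$data %||% file.path(tempdir(), "bcs_data")
  cfg$paths$out <- cfg$paths$out %||% file.path(tempdir(), "bcs_out")
  sc <- cfg$scene %||% list()
  cfg$scene_config <- scene_config(
    sensor = as.integer(sc$sensor %||% c(424L, 512L)),
    pixel_pitch = sc$pixel_pitch,
    noise_sd = sc$noise_sd %||% 5,
    class_probs = sc$class_probs,
    frames_per_cow = as.integer(sc$frames_per_cow %||% c(3L, 7L))
  )
  cfg$scene$n_cows <- as.integer(sc$n_cows %||% 50L)
  pp <- cfg$preprocess
  cfg$preprocess_config <- if (is.null(pp)) {
    default_preprocess_config(cfg$scene_config$sensor)
  } else {
    stats::setNames(lapply(names(pp), function(cam) {
      camera_preprocess(pp[[cam]]$distance_threshold,
                        as.integer(pp[[cam]]$crop),
                        pp[[cam]]$binarize_threshold,
                        pp[[cam]]$gradient_cap)
    }), match_camera(names(pp)))
  }
  cfg$split$test_fraction <- cfg$split$test_fraction %||% 0.3
  cfg$split$cap <- as.integer(cfg$split$cap %||% 7L)
  cfg$split$stratify <- isTRUE(cfg$split$stratify %||% TRUE)
  tr <- cfg$train %||% list()
  cfg$train_config <- train_config(
    learning_rate = tr$learning_rate %||% 0.001,
    epochs = as.integer(tr$epochs %||% 30L),
    batch_size = as.integer(tr$batch_size %||% 32L),
    class_weighting = tr$class_weighting %||% TRUE,
    seed = stage_seed(cfg$seed, "train")
  )
  cfg$model$fusion <- toupper(cfg$model$fusion %||% "LATE")
  cfg$model$cameras <- match_camera(cfg$model$cameras %||% CAMERA_VIEWS)
  structure(cfg, class = c("run_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

provenance <- function(cfg, stage, extra = list()) {
  c(list(stage = stage, seed = cfg$seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         package_version = as.character(utils::packageVersion("bcsfusion"))),
    extra)
}

#' Pipeline commands
#'
#' Thin orchestration wrappers, one per pipeline stage, each reproducible
#' from `(config, seed)` and writing a provenance record next to its
#' outputs. `cmd_simulate()` renders the synthetic dataset;
#' `cmd_prepare()` runs frame capping, cow-level splitting, test-frame
#' selection, channel construction and phase augmentation and returns the
#' aligned sample arrays; `cmd_train()` trains the configured fusion
#' model; `cmd_evaluate()` scores it over all camera subsets and writes
#' the report.
#'
#' @param cfg A [load_run_config()] result (or path to one).
#' @return `cmd_simulate()`: the manifest. `cmd_prepare()`: the prepared
#'   dataset list. `cmd_train()`: the trained model (also saved under
#'   `paths$out`). `cmd_evaluate()`: the camera-set report.
#' @export
cmd_simulate <- function(cfg) {
  cfg <- as_run_config(cfg)
  index <- generate_dataset(cfg$scene$n_cows, cfg$scene_config,
                            seed = stage_seed(cfg$seed, "simulate"),
                            dir = cfg$paths$data)
  jsonlite::write_json(
    provenance(cfg, "simulate", list(n_cows = cfg$scene$n_cows,
                                     n_frames = nrow(index))),
    file.path(cfg$paths$data, "provenance.json"), auto_unbox = TRUE)
  index
}

as_run_config <- function(cfg) {
  if (inherits(cfg, "run_config")) cfg else load_run_config(cfg)
}

# Build channel stacks for every manifest row, sub-sample into the four
# phase images, and align samples across cameras by (cow, frame rank,
# phase) so that fusion models see paired views.
assemble_samples <- function(index, dir, pp_cfg, cameras = CAMERA_VIEWS) {
  phases <- c("p00", "p01", "p10", "p11")
  per_cam <- list()
  for (cam in cameras) {
    sub <- index[index$camera == cam, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no frames for camera ", cam, call. = FALSE)
    }
    sub <- sub[order(sub$cow_id, sub$frame_ref), , drop = FALSE]
    # rank of the frame within its cow's capture sequence
    rank <- unlist(lapply(split(seq_len(nrow(sub)), sub$cow_id),
                          function(i) {
                            match(sub$frame_ref[i],
                                  sort(unique(sub$frame_ref[i])))
                          }), use.names = FALSE)
    stacks <- list()
    samples <- list()
    uf <- !duplicated(sub$frame_ref)
    for (i in which(uf)) {
      frame <- read_depth_frame(file.path(dir, sub$frame_ref[i]), cam)
      st <- build_channel_stack(frame, pp_cfg[[cam]])
      # Network inputs are conditioned for training (the stack contract is
      # unchanged): the derivative plane (raw mm per pixel) is divided by
      # the gradient cap, and the depth plane is mean-centred over covered
      # pixels and rescaled so surface relief -- not the cow-to-background
      # step or global range shifts from cow position -- carries the
      # channel's dynamic range.
      st[, , 3L] <- st[, , 3L] / pp_cfg[[cam]]$gradient_cap
      d1 <- st[, , 1L]
      cov <- d1 > 0
      if (any(cov)) d1[cov] <- (d1[cov] - mean(d1[cov])) * 8
      st[, , 1L] <- d1
      stacks[[sub$frame_ref[i]]] <- subsample_phases(st)
    }
    key <- character(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      ph <- if ("phase" %in% names(sub)) sub$phase[i] else "p00"
      samples[[i]] <- stacks[[sub$frame_ref[i]]][[ph]]
      key[i] <- paste(sub$cow_id[i], rank[i], ph, sep = "|")
    }
    per_cam[[cam]] <- list(samples = samples, key = key,
                           y = bcs_to_class(sub$bcs),
                           cow_id = sub$cow_id)
  }
  common <- Reduce(intersect, lapply(per_cam, `[[`, "key"))
  common <- sort(common)
  x <- list()
  for (cam in cameras) {
    pc <- per_cam[[cam]]
    sel <- match(common, pc$key)
    d <- dim(pc$samples[[1L]])
    arr <- array(0, c(d[1], d[2], d[3], length(sel)))
    for (j in seq_along(sel)) arr[, , , j] <- pc$samples[[sel[j]]]
    x[[cam]] <- arr
  }
  ref <- per_cam[[cameras[1L]]]
  sel <- match(common, ref$key)
  list(x = x, y = ref$y[sel], cow_id = ref$cow_id[sel], key = common)
}

#' @param index Optional manifest; defaults to the one under `paths$data`.
#' @rdname cmd_simulate
#' @export
cmd_prepare <- function(cfg, index = NULL) {
  cfg <- as_run_config(cfg)
  dir <- cfg$paths$data
  if (is.null(index)) index <- load_manifest(file.path(dir, "manifest.csv"))
  index <- limit_frames_per_cow(index, cap = cfg$split$cap)
  index <- cow_level_split(index, test_fraction = cfg$split$test_fraction,
                           seed = stage_seed(cfg$seed, "split"),
                           stratify = cfg$split$stratify)
  index <- select_test_frames(index, seed = stage_seed(cfg$seed, "testsel"))
  index <- augment_index(index)
  cams <- cfg$model$cameras
  train <- assemble_samples(index[index$split == "TRAIN", , drop = FALSE],
                            dir, cfg$preprocess_config, cams)
  test <- assemble_samples(index[index$split == "TEST", , drop = FALSE],
                           dir, cfg$preprocess_config, cams)
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  save_manifest(index, file.path(cfg$paths$out, "prepared_manifest.csv"))
  jsonlite::write_json(
    provenance(cfg, "prepare",
               list(n_train = length(train$y), n_test = length(test$y))),
    file.path(cfg$paths$out, "prepare_provenance.json"), auto_unbox = TRUE)
  list(train = train, test = test, index = index)
}

# Hold out a fraction of training cows as the validation set.
validation_split <- function(train, fraction = 0.15, seed = 1L) {
  cows <- unique(train$cow_id)
  val_cows <- with_local_seed(seed, {
    sample(cows, max(1L, round(fraction * length(cows))))
  })
  vi <- train$cow_id %in% val_cows
  subset_samples <- function(keep) {
    list(x = lapply(train$x, function(a) a[, , , keep, drop = FALSE]),
         y = train$y[keep], cow_id = train$cow_id[keep])
  }
  list(fit = subset_samples(!vi), val = subset_samples(vi))
}

#' @param prepared A [cmd_prepare()] result (recomputed if NULL).
#' @rdname cmd_simulate
#' @export
cmd_train <- function(cfg, prepared = NULL) {
  cfg <- as_run_config(cfg)
  if (is.null(prepared)) prepared <- cmd_prepare(cfg)
  cams <- cfg$model$cameras
  shapes <- lapply(prepared$train$x[cams], function(a) dim(a)[1:3])
  bconfig <- backbone_config(shapes)
  model <- build_model(cfg$model$fusion, cams, bconfig,
                       seed = stage_seed(cfg$seed, "init"))
  vs <- validation_split(prepared$train,
                         seed = stage_seed(cfg$seed, "valsplit"))
  model <- train_model(model, vs$fit, vs$val, cfg$train_config)
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(cfg$paths$out, "model.rds"))
  jsonlite::write_json(
    provenance(cfg, "train",
               c(list(fusion = cfg$model$fusion, cameras = cams),
                 model_stats(model))),
    file.path(cfg$paths$out, "model_sidecar.json"), auto_unbox = TRUE)
  model
}

#' @param model A trained model (loaded from `paths$out` if NULL).
#' @rdname cmd_simulate
#' @export
cmd_evaluate <- function(cfg, model = NULL, prepared = NULL) {
  cfg <- as_run_config(cfg)
  if (is.null(prepared)) prepared <- cmd_prepare(cfg)
  if (is.null(model)) {
    mp <- file.path(cfg$paths$out, "model.rds")
    if (!file.exists(mp)) {
      stop("no trained model at ", mp, "; run cmd_train first",
           call. = FALSE)
    }
    model <- readRDS(mp)
  }
  pred <- predict(model, prepared$test$x)
  report <- if (model$kind == "LATE" &&
                setequal(model$cameras, CAMERA_VIEWS)) {
    evaluate_camera_sets(pred$member_prob, prepared$test$y)
  } else {
    evaluate_predictions(prepared$test$y, pred$class)
  }
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  write_metrics_json(report, file.path(cfg$paths$out, "metrics.json"))
  grid <- bcs_grid()
  pred_df <- data.frame(cow_id = prepared$test$cow_id,
                        true_bcs = grid[prepared$test$y + 1L],
                        camera_set = paste(model$cameras, collapse = "&"),
                        pred_bcs = grid[pred$class + 1L])
  utils::write.csv(cbind(pred_df, stats::setNames(
    as.data.frame(pred$prob), paste0("p", 0:7))),
    file.path(cfg$paths$out, "predictions.csv"), row.names = FALSE)
  report
}
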