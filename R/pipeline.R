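#' Save / load a dataset on disk
#'
#' Images and masks are written as 8-bit grayscale PNGs, per-record
#' metadata (class, lesion size, split) as one CSV row per record, and a
#' JSON manifest ties the files together.
#'
#' @param dataset list with `train` and `test` record lists, as returned
#'   by [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `read_dataset` returns the restored dataset (without the
#'   generating spec).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  files <- list()
  for (split in c("train", "test")) {
    for (i in seq_along(dataset[[split]])) {
      rec <- dataset[[split]][[i]]
      id <- sprintf("%s_%04d", split, i)
      img_f <- file.path(dir, paste0(id, "_image.png"))
      mask_f <- file.path(dir, paste0(id, "_mask.png"))
      png::writePNG(t(rec$image) / 255, img_f)
      png::writePNG(t(rec$mask) * 1.0, mask_f)
      rows[[length(rows) + 1]] <- data.frame(
        id = id, split = split, label = rec$label,
        size_mm = rec$lesion_size_mm,
        pixel_spacing = rec$pixel_spacing)
      files[[id]] <- list(image = basename(img_f),
                          mask = basename(mask_f))
    }
  }
  labels <- do.call(rbind, rows)
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_train = length(dataset$train),
                            n_test = length(dataset$test),
                            records = files),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  labels <- read.csv(file.path(dir, "labels.csv"),
                     stringsAsFactors = FALSE)
  out <- list(train = list(), test = list())
  for (i in seq_len(nrow(labels))) {
    id <- labels$id[i]
    img <- t(png::readPNG(file.path(dir, paste0(id, "_image.png"))))
    mask <- t(png::readPNG(file.path(dir, paste0(id, "_mask.png"))))
    rec <- structure(list(
      image = matrix(as.integer(round(img * 255)), nrow(img)),
      mask = matrix(as.integer(mask > 0.5), nrow(mask)),
      label = labels$label[i], lesion_size_mm = labels$size_mm[i],
      pixel_spacing = labels$pixel_spacing[i]), class = "usj_record")
    out[[labels$split[i]]] <- c(out[[labels$split[i]]], list(rec))
  }
  out
}

#' Save / load a trained network checkpoint
#'
#' Weights, batch-norm running statistics and the configuration are
#' stored in R's native serialization format.
#'
#' @param net a `usj_network`.
#' @param path checkpoint file path (conventionally `.rds`).
#' @return `load_network` returns the restored `usj_network`.
#' @export
save_network <- function(net, path) {
  freeze <- function(x) {
    if (is.environment(x)) return(list(.bn_stats = TRUE, rm = x$rm,
                                       rv = x$rv))
    if (is.list(x)) return(lapply(x, freeze))
    x
  }
  saveRDS(freeze(unclass(net)), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  thaw <- function(x) {
    if (is.list(x) && isTRUE(x$.bn_stats)) {
      e <- new.env(parent = emptyenv())
      e$rm <- x$rm
      e$rv <- x$rv
      return(e)
    }
    if (is.list(x)) return(lapply(x, thaw))
    x
  }
  net <- thaw(readRDS(path))
  net$config <- structure(net$config, class = "usj_net_config")
  structure(net, class = "usj_network")
}

#' Run the full phantom pipeline: generate, train, evaluate
#'
#' Generates a balanced phantom dataset, precomputes per-image click
#' sequences, trains the requested network variant, evaluates it in the
#' requested test modes, and writes every artifact (dataset metadata,
#' checkpoint, training log, evaluation reports, run manifest) under
#' `out_dir`. Re-running with the same seed reproduces the metrics.
#'
#' @param out_dir output directory.
#' @param n_per_class phantoms per lesion class.
#' @param image_size phantom side in pixels (power-of-two friendly).
#' @param pixel_spacing mm per pixel; the default of 1 mm at 64 px keeps
#'   the clinical size distributions inside the field of view.
#' @param variant network variant to train.
#' @param n_classes 2 or 4.
#' @param iterations training iterations (`NULL` for the profile
#'   default).
#' @param profile `"desk"` or `"paper"` network/training profile.
#' @param split_fraction test fraction per class.
#' @param modes evaluation input modes to run.
#' @param seed global seed propagated to generation, clicks, training
#'   and evaluation.
#' @param write_images also write the phantom PNGs (slower; metadata is
#'   always written).
#' @param spec optional [phantom_spec()] overriding the one implied by
#'   `image_size`/`pixel_spacing`.
#' @return (invisibly) list with the dataset, trained network, training
#'   log and one evaluation report per mode.
#' @export
run_pipeline <- function(out_dir, n_per_class = 50, image_size = 64,
                         pixel_spacing = 1, variant = "joint",
                         n_classes = 4, iterations = NULL,
                         profile = "desk", split_fraction = 0.2,
                         modes = c("two_click", "one_click"), seed = 0,
                         write_images = FALSE, spec = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- spec %||% phantom_spec(image_size = image_size,
                                 pixel_spacing = pixel_spacing)
  message("generating ", 4 * n_per_class, " phantoms ...")
  ds <- generate_dataset(spec, n_per_class, split_fraction, seed)
  if (write_images) write_dataset(ds, file.path(out_dir, "dataset"))
  labels <- do.call(rbind, lapply(c(train = "train", test = "test"),
                                  function(s) data.frame(
    split = s,
    label = vapply(ds[[s]], `[[`, character(1), "label"),
    size_mm = vapply(ds[[s]], `[[`, numeric(1), "lesion_size_mm"))))
  write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
  train_recs <- ds$train
  if (variant != "cls_only") {
    message("simulating click sequences ...")
    # background band is defined at the 256 px reference scale; keep it
    # proportional on smaller canvases so training background clicks sit
    # at the same relative distance as test-time box corners
    band_scale <- image_size / 256
    train_recs <- prepare_training_set(
      train_recs, d_min = max(2, round(5 * band_scale)),
      d_max = max(8, round(40 * band_scale)), rng_seed = seed + 1L)
  }
  net_cfg <- network_config(variant, n_classes = n_classes,
                            profile = profile)
  net <- build_network(net_cfg, rng_seed = seed + 2L)
  tr_cfg <- train_config(profile, variant, iterations = iterations,
                         seed = seed + 3L)
  message("training ", variant, " network (", tr_cfg$iterations,
          " iterations) ...")
  fit <- train_network(net, train_recs, tr_cfg)
  utils::write.csv(as.data.frame(fit$log),
                   file.path(out_dir, "train_log.csv"),
                   row.names = FALSE)
  ckpt <- file.path(out_dir, paste0(variant, ".rds"))
  save_network(fit$network, ckpt)
  reports <- list()
  if (variant == "cls_only") modes <- modes[1]
  for (mode in modes) {
    message("evaluating (", mode, ") ...")
    rep <- evaluate_system(fit$network, ds$test, input_mode = mode,
                           rng_seed = seed + 4L)
    write_eval_report(rep, file.path(out_dir,
                                     paste0("report_", mode, ".json")))
    reports[[mode]] <- rep
  }
  manifest <- list(
    seed = seed, variant = variant, n_classes = n_classes,
    n_per_class = n_per_class, image_size = image_size,
    pixel_spacing = pixel_spacing, iterations = tr_cfg$iterations,
    profile = profile,
    config_hash = sum(utils::head(as.integer(charToRaw(paste(
      seed, variant, n_classes, n_per_class, image_size,
      tr_cfg$iterations, collapse = ":"))), 1000)),
    artifacts = c(list(labels = "labels.csv",
                       train_log = "train_log.csv",
                       checkpoint = basename(ckpt)),
                  setNames(as.list(paste0("report_", modes, ".json")),
                           paste0("report_", modes))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(dataset = ds, network = fit$network, log = fit$log,
                 reports = reports))
}
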