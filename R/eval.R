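#' Count contaminant blobs
#'
#' Number of 8-connected components per class. 8-connectivity is
#' deliberate: thin diagonal contaminants (1-2 px ribbons) would shatter
#' into many components under 4-connectivity.
#'
#' @param pred A \code{\link{prediction_map}} or integer label matrix.
#' @param classes Integer vector of 0-based class indices to count.
#' @return Named integer vector of blob counts per requested class.
#' @export
count_blobs <- function(pred, classes) {
  m <- matrix(as.integer(pred), nrow(pred), ncol(pred))
  out <- vapply(classes, function(cl) max(0L, max(cpp_label8(m == cl))), 0L)
  names(out) <- as.character(classes)
  out
}

#' Confusion matrix and mean IoU
#'
#' Pixel-level 13 x 13 confusion matrix (rows: reference, cols:
#' prediction) and the mean intersection-over-union across the classes
#' present in the reference mask. Pixels labelled 255 are excluded.
#'
#' @param pred A \code{\link{prediction_map}} or integer matrix.
#' @param mask Reference label matrix (255 = unannotated).
#' @return List with \code{confusion}, per-class \code{iou} (NA for absent
#'   classes) and scalar \code{miou}.
#' @export
confusion_and_miou <- function(pred, mask) {
  stopifnot(identical(dim(pred)[1:2], dim(mask)[1:2]))
  p <- as.integer(pred); r <- as.integer(mask)
  keep <- r != 255L
  if (!any(keep)) stop("mask has no labelled pixels")
  p <- p[keep]; r <- r[keep]
  conf <- matrix(0L, 13L, 13L)
  tab <- table(factor(r, levels = 0:12), factor(p, levels = 0:12))
  conf[] <- as.integer(tab)
  present <- sort(unique(r))
  iou <- rep(NA_real_, 13L)
  for (c in present) {
    tp <- conf[c + 1L, c + 1L]
    un <- sum(conf[c + 1L, ]) + sum(conf[, c + 1L]) - tp
    iou[c + 1L] <- if (un > 0) tp / un else NA_real_
  }
  list(confusion = conf, iou = iou, miou = mean(iou[present + 1L], na.rm = TRUE))
}

#' Evaluate post-processing arms on a scene set
#'
#' Runs model prediction once per scene, then applies each requested
#' post-processing arm and aggregates detection statistics at image, blob
#' and pixel granularity:
#' \itemize{
#'   \item a ground-truth contaminant blob counts as detected (TP) if at
#'     least one predicted contaminant pixel of any class overlaps it —
#'     the operational goal is flagging, not per-class identification;
#'   \item a clean image (no contaminant in its mask) counts as a FP image
#'     if any contaminant pixel survives the arm;
#'   \item FP blobs/pixels are predicted contaminant components/pixels not
#'     overlapping any true contaminant blob.
#' }
#'
#' @param samples List of lists with elements \code{cube} (normalized
#'   hypercube) and \code{mask} (label matrix).
#' @param fit A \code{\link{train_vitseg}} fit.
#' @param arms Named list of pipelines (character vectors accepted by
#'   \code{\link{run_postprocessing}}), e.g.
#'   \code{list(raw = character(0), rules_erosion = c("rules", "erosion"))}.
#' @param tax Taxonomy.
#' @return An object of class \code{eval_summary}: per-arm totals plus the
#'   per-image data frame.
#' @export
evaluate_arms <- function(samples, fit,
                          arms = list(raw = character(0),
                                      erosion = "erosion",
                                      rules = "rules",
                                      rules_erosion = c("rules", "erosion")),
                          tax = hsi_taxonomy()) {
  stopifnot(length(samples) >= 1L, inherits(fit, "vitseg_fit"))
  rows <- list(); k <- 0L
  fp_class_px <- matrix(0, length(arms), 13L,
                        dimnames = list(names(arms), class_names(tax)))
  for (si in seq_along(samples)) {
    cube <- samples[[si]]$cube; mask <- samples[[si]]$mask
    pred0 <- predict(fit, cube)
    gt_cont <- matrix(mask %in% tax$contaminant, nrow(mask), ncol(mask))
    gt_lab <- cpp_label8(gt_cont)
    n_gt_blobs <- max(0L, max(gt_lab))
    clean <- n_gt_blobs == 0L
    for (ai in seq_along(arms)) {
      pred <- run_postprocessing(pred0, cube, pipeline = arms[[ai]], tax = tax)
      pc <- matrix(pred %in% tax$contaminant, nrow(pred), ncol(pred))
      detected <- if (n_gt_blobs) sum(vapply(seq_len(n_gt_blobs), function(b)
        any(pc[gt_lab == b]), TRUE)) else 0L
      fp_mask <- pc & !gt_cont
      # blobs entirely off ground truth
      pl <- cpp_label8(pc)
      fp_blobs <- if (max(pl) > 0L) sum(vapply(seq_len(max(pl)), function(b)
        !any(gt_cont[pl == b]), TRUE)) else 0L
      for (cl in tax$contaminant)
        fp_class_px[ai, cl + 1L] <- fp_class_px[ai, cl + 1L] +
          sum(fp_mask & pred == cl)
      k <- k + 1L
      rows[[k]] <- data.frame(
        arm = names(arms)[ai], image = si, clean = clean,
        gt_blobs = n_gt_blobs, tp_blobs = detected,
        tp_pixels = sum(pc & gt_cont),
        fp_image = clean && any(pc),
        fp_blobs = fp_blobs, fp_pixels = sum(fp_mask),
        miou = confusion_and_miou(pred, mask)$miou,
        stringsAsFactors = FALSE)
    }
  }
  per_image <- do.call(rbind, rows)
  totals <- do.call(rbind, lapply(names(arms), function(a) {
    d <- per_image[per_image$arm == a, ]
    data.frame(arm = a,
               tp_blobs = sum(d$tp_blobs), gt_blobs = sum(d$gt_blobs),
               tp_pixels = sum(d$tp_pixels),
               fp_images = sum(d$fp_image), n_clean = sum(d$clean),
               fp_blobs = sum(d$fp_blobs), fp_pixels = sum(d$fp_pixels),
               mean_miou = mean(d$miou), stringsAsFactors = FALSE)
  }))
  structure(list(totals = totals, per_image = per_image,
                 fp_class_pixels = fp_class_px),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("Post-processing arm comparison\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation summary to CSV
#' @param summary An \code{eval_summary}.
#' @param path Output CSV path (per-image rows).
#' @return \code{path}, invisibly.
#' @export
write_eval_csv <- function(summary, path) {
  utils::write.csv(summary$per_image, path, row.names = FALSE)
  invisible(path)
}

#' Inference throughput (smoke metric)
#'
#' Images per second of the full predict path on the given cubes. A
#' hardware-dependent smoke figure, not an accuracy metric.
#'
#' @param fit A \code{vitseg_fit}.
#' @param cubes List of normalized hypercubes.
#' @return Images per second (positive scalar), invisibly; also printed.
#' @export
throughput_report <- function(fit, cubes) {
  stopifnot(length(cubes) >= 1L)
  t0 <- proc.time()[["elapsed"]]
  for (cb in cubes) predict(fit, cb)
  el <- proc.time()[["elapsed"]] - t0
  fps <- length(cubes) / max(el, 1e-9)
  message(sprintf("throughput: %.2f images/s (%d images, %s)", fps,
                  length(cubes), R.version$platform))
  invisible(fps)
}

#' End-to-end synthetic benchmark
#'
#' The package's headline experiment, run entirely on synthetic scenes:
#' render a training set of contaminated scenes, train the tile
#' transformer at desk scale, then measure (a) held-out segmentation mIoU,
#' (b) false positives on clean scenes with hard fat-like PEHD regions for
#' every post-processing arm, and (c) retention of true contaminant blobs
#' that own a 3 x 3 core through the rules + erosion arm.
#'
#' @param n_train_scenes Contaminated scenes rendered for training.
#' @param n_holdout Held-out contaminated scenes for mIoU.
#' @param n_clean Clean scenes for the false-positive arms.
#' @param n_contaminated Contaminated scenes for TP retention.
#' @param scene Scene size c(height, width).
#' @param tiles_per_scene Training tiles kept per scene (contaminant-rich
#'   tiles preferred, plus background context tiles).
#' @param epochs,batch_size,lr,warmup_epochs Training schedule (desk-scale
#'   defaults; the production recipe is 24 epochs at batch 520).
#' @param seed Master seed.
#' @param verbose Print progress.
#' @return List with the trained fit, the per-arm \code{eval_summary} on
#'   clean scenes, and the headline numbers (holdout_miou, fp_images_raw,
#'   fp_images_rules_erosion, tp_blob_retention, ...).
#' @export
run_synthetic_benchmark <- function(n_train_scenes = 200L, n_holdout = 6L,
                                    n_clean = 50L, n_contaminated = 12L,
                                    scene = c(128L, 160L),
                                    tiles_per_scene = 6L,
                                    epochs = 3L, batch_size = 24L, lr = 2e-3,
                                    warmup_epochs = 1L, seed = 1L,
                                    verbose = FALSE) {
  tax <- hsi_taxonomy()
  seed <- as.integer(seed) %% 20000L  # scene sub-seeds stay below 2^31
  lib <- make_spectrum_library(seed = 1L)  # fixed material physics
  grid <- tile_grid()  # disjoint tiles

  say <- function(...) if (verbose) message(sprintf(...))
  scene_tiles <- function(s) {
    cube <- condition_sample(s)
    tl <- extract_tiles(cube, s$mask, grid)
    ncont <- vapply(tl, function(t) sum(t$mask %in% tax$contaminant), 0L)
    keep_cont <- order(ncont, decreasing = TRUE)[seq_len(min(5L, sum(ncont > 0L)))]
    bg <- which(ncont == 0L)
    keep_bg <- bg[seq_len(max(0L, min(tiles_per_scene - length(keep_cont),
                                      length(bg))))]
    tl[c(keep_cont, keep_bg)]
  }

  say("rendering %d training scenes", n_train_scenes)
  train_tiles <- list()
  for (i in seq_len(n_train_scenes)) {
    rec <- random_scene_recipe(seed * 100000L + i, scene[1], scene[2],
                               n_contaminants = 3L)
    train_tiles <- c(train_tiles, scene_tiles(render_scene(rec, lib, tax)))
  }

  say("training on %d tiles", length(train_tiles))
  fit <- train_vitseg(train_tiles,
                      model_config = vitseg_config(),
                      config = train_config(epochs = epochs,
                                            batch_size = batch_size, lr = lr,
                                            warmup_epochs = warmup_epochs,
                                            seed = seed),
                      verbose = verbose)

  say("evaluating %d held-out scenes", n_holdout)
  mious <- vapply(seq_len(n_holdout), function(i) {
    rec <- random_scene_recipe(seed * 100000L + 70000L + i, scene[1], scene[2],
                               n_contaminants = 3L)
    s <- render_scene(rec, lib, tax)
    cube <- condition_sample(s)
    confusion_and_miou(predict(fit, cube), s$mask)$miou
  }, 0)

  say("evaluating %d clean scenes", n_clean)
  clean_samples <- lapply(seq_len(n_clean), function(i) {
    rec <- random_scene_recipe(seed * 100000L + 80000L + i, scene[1], scene[2],
                               n_contaminants = 0L, hard_fat_frac = 0.1)
    s <- render_scene(rec, lib, tax)
    list(cube = condition_sample(s), mask = s$mask)
  })
  clean_eval <- evaluate_arms(clean_samples, fit, tax = tax)

  say("evaluating %d contaminated scenes", n_contaminated)
  cont_samples <- lapply(seq_len(n_contaminated), function(i) {
    rec <- random_scene_recipe(seed * 100000L + 90000L + i, scene[1], scene[2],
                               n_contaminants = 3L)
    s <- render_scene(rec, lib, tax)
    list(cube = condition_sample(s), mask = s$mask)
  })
  # retention restricted to ground-truth blobs that own a 3x3 core: blobs
  # thinner than the structuring element are removed by design
  core_blob_stats <- function(samples, arm) {
    tot <- 0L; det <- 0L
    for (s in samples) {
      gt <- matrix(s$mask %in% tax$contaminant, nrow(s$mask), ncol(s$mask))
      lab <- cpp_label8(gt)
      if (max(lab) == 0L) next
      core <- cpp_erode3x3(gt)
      pred <- run_postprocessing(predict(fit, s$cube), s$cube, pipeline = arm,
                                 tax = tax)
      pc <- matrix(pred %in% tax$contaminant, nrow(pred), ncol(pred))
      for (b in seq_len(max(lab))) {
        if (!any(core[lab == b])) next
        tot <- tot + 1L
        if (any(pc[lab == b])) det <- det + 1L
      }
    }
    c(total = tot, detected = det)
  }
  ret <- core_blob_stats(cont_samples, c("rules", "erosion"))

  tt <- clean_eval$totals
  res <- list(
    fit = fit, clean_eval = clean_eval,
    holdout_miou = mean(mious),
    holdout_miou_per_scene = mious,
    fp_images_raw = tt$fp_images[tt$arm == "raw"],
    fp_pixels_raw = tt$fp_pixels[tt$arm == "raw"],
    fp_images_rules_erosion = tt$fp_images[tt$arm == "rules_erosion"],
    fp_pixels_rules_erosion = tt$fp_pixels[tt$arm == "rules_erosion"],
    n_clean = n_clean,
    core_blobs_total = unname(ret["total"]),
    core_blobs_detected = unname(ret["detected"]),
    tp_blob_retention = unname(ret["detected"] / max(ret["total"], 1L)))
  class(res) <- "hsi_benchmark"
  res
}

#' @export
print.hsi_benchmark <- function(x, ...) {
  cat(sprintf("Synthetic end-to-end benchmark\n"))
  cat(sprintf("  held-out mIoU:             %.4f\n", x$holdout_miou))
  cat(sprintf("  FP images (raw model):     %d / %d clean scenes\n",
              x$fp_images_raw, x$n_clean))
  cat(sprintf("  FP images (rules+erosion): %d / %d clean scenes\n",
              x$fp_images_rules_erosion, x$n_clean))
  cat(sprintf("  TP blob retention:         %d / %d cored blobs (%.1f%%)\n",
              x$core_blobs_detected, x$core_blobs_total,
              100 * x$tp_blob_retention))
  invisible(x)
}
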