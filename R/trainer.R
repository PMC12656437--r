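#' Label-smoothed target distribution
#'
#' q_c = (1 - eps) * [c == t] + eps/K. Smoothing softens the hard one-hot
#' targets, which tempers the penalty for near-boundary disagreements where
#' annotations are least reliable.
#'
#' @param t 0-based true class index.
#' @param eps Smoothing rate in [0, 1).
#' @param K Number of classes.
#' @return Probability vector of length K summing to 1.
#' @export
smoothed_targets <- function(t, eps = 0.3, K = 13L) {
  stopifnot(eps >= 0, eps < 1, t >= 0, t < K)
  q <- rep(eps / K, K)
  q[t + 1L] <- q[t + 1L] + (1 - eps)
  q
}

#' Cost-sensitive smoothed cross-entropy for one pixel
#'
#' The base loss is cross-entropy against the smoothed targets
#' q = smoothed_targets(t); on top of it, a penalty factor W[t, yhat] keyed
#' by the true class and the currently predicted class (yhat = argmax of
#' the logits) scales the loss. The factor is treated as a constant with
#' respect to the gradient — it rescales the pixel's contribution rather
#' than differentiating through the argmax. Misclassifying meat or fat as
#' a contaminant costs extra; misclassifying conveyor belt as a contaminant
#' costs less, since belt alarms are operationally cheap.
#'
#' This R implementation is the reference for the single-precision training
#' path implemented in C++.
#'
#' @param logits Numeric vector of unnormalized class scores.
#' @param t 0-based true class index.
#' @param W Penalty matrix (true class x predicted class), e.g.
#'   \code{\link{default_penalty_matrix}}.
#' @param eps Label-smoothing rate.
#' @return Non-negative scalar loss.
#' @export
pixel_loss <- function(logits, t, W = default_penalty_matrix(), eps = 0.3) {
  if (any(!is.finite(logits))) stop("non-finite logits")
  K <- length(logits)
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  yhat <- which.max(p) - 1L
  q <- smoothed_targets(t, eps, K)
  W[t + 1L, yhat + 1L] * sum(-q * log(p))
}

#' Default misclassification penalty matrix
#'
#' W[t, p] = w_high when true meat/fat is predicted as a contaminant,
#' w_low when true conveyor belt is predicted as a contaminant, and 1
#' otherwise (including the diagonal). The structure encodes the
#' operational asymmetry of false alarms; the numeric defaults are package
#' choices exposed for configuration.
#'
#' @param w_high Penalty for meat/fat -> contaminant; must be >= 1.
#' @param w_low Penalty for conveyor belt -> contaminant; in (0, 1].
#' @param tax Taxonomy defining the class partition.
#' @return 13 x 13 numeric matrix (rows: true class, cols: predicted).
#' @export
default_penalty_matrix <- function(w_high = 2.0, w_low = 0.5,
                                   tax = hsi_taxonomy()) {
  if (!(w_high >= 1 && w_low > 0 && w_low <= 1))
    stop("require w_high >= 1 >= w_low > 0")
  K <- nrow(tax$classes)
  W <- matrix(1, K, K, dimnames = list(true = class_names(tax),
                                       predicted = class_names(tax)))
  cont <- tax$contaminant + 1L
  meat_fat <- class_index(tax, c("meat", "fat")) + 1L
  belt <- class_index(tax, "conveyor_belt") + 1L
  W[meat_fat, cont] <- w_high
  W[belt, cont] <- w_low
  diag(W) <- 1
  W
}

#' Training configuration
#'
#' Defaults follow the production recipe: AdamW (weight decay 2e-4,
#' learning rate 1e-3) for 24 epochs at batch size 520 tiles, a polynomial
#' learning-rate schedule with 3 warm-up epochs, and label smoothing 0.3.
#' Desk-scale experiments use fewer epochs and smaller batches.
#'
#' @param epochs Training epochs.
#' @param batch_size Tiles per optimizer step.
#' @param lr Peak learning rate.
#' @param weight_decay Decoupled weight decay (linear weights only).
#' @param warmup_epochs Linear warm-up length; must be < epochs.
#' @param poly_power Exponent of the polynomial decay (1 = linear).
#' @param label_smoothing Smoothing rate eps.
#' @param seed RNG seed for shuffling.
#' @param penalty Penalty matrix, see \code{\link{default_penalty_matrix}}.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(epochs = 24L, batch_size = 520L, lr = 1e-3,
                         weight_decay = 2e-4, warmup_epochs = 3L,
                         poly_power = 1, label_smoothing = 0.3, seed = 1L,
                         penalty = default_penalty_matrix()) {
  stopifnot(label_smoothing >= 0, label_smoothing < 1,
            warmup_epochs < epochs, all(penalty > 0),
            all(abs(diag(penalty) - 1) < 1e-12))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 warmup_epochs = as.integer(warmup_epochs),
                 poly_power = poly_power, label_smoothing = label_smoothing,
                 seed = as.integer(seed), penalty = penalty),
            class = "train_config")
}

#' Learning rate at a given step
#'
#' Linear warm-up from 0 to the peak rate over \code{warmup_epochs}, then
#' polynomial decay to 0 at the final step:
#' lr * (1 - s/S)^power with s the post-warm-up step.
#'
#' @param step Global optimizer step (0-based; the first update uses
#'   step = 1).
#' @param cfg A \code{\link{train_config}}.
#' @param steps_per_epoch Optimizer steps per epoch.
#' @return Learning rate.
#' @export
lr_at <- function(step, cfg, steps_per_epoch) {
  stopifnot(step >= 0)
  W <- cfg$warmup_epochs * steps_per_epoch
  total <- cfg$epochs * steps_per_epoch
  if (W > 0 && step <= W) return(cfg$lr * step / W)
  s <- step - W
  S <- total - W
  cfg$lr * max(0, 1 - s / S)^cfg$poly_power
}

# stack a list of tiles (from extract_tiles) into the token matrix and
# label vector the C++ kernels consume
.tiles_to_tokens <- function(tiles, cfg) {
  nt <- cfg$n_tokens
  x <- matrix(0, length(tiles) * nt, cfg$embed_dim)
  y <- rep(255L, length(tiles) * nt)
  for (i in seq_along(tiles)) {
    rows <- ((i - 1L) * nt + 1L):(i * nt)
    x[rows, ] <- matrix(tiles[[i]]$data, nt, cfg$embed_dim)
    if (!is.null(tiles[[i]]$mask)) y[rows] <- as.integer(tiles[[i]]$mask)
  }
  list(x = x, y = y)
}

#' Train the tile segmentation model
#'
#' Runs the AdamW recipe with seeded shuffling. Pixels labelled 255
#' (unannotated) stay in the input — they provide spatial context — but are
#' excluded from the loss. When a validation tile set is given, the
#' parameters of the epoch with the best validation mIoU are returned;
#' otherwise the final parameters.
#'
#' @param tiles List of training tiles with masks (see
#'   \code{\link{extract_tiles}}).
#' @param model_config A \code{\link{vitseg_config}}.
#' @param config A \code{\link{train_config}}.
#' @param validation Optional list of validation tiles with masks.
#' @param verbose Print a line per epoch.
#' @return An object of class \code{vitseg_fit}: list with \code{model}
#'   (a \code{vitseg_model} holding the trained parameters), a per-epoch
#'   \code{history} data frame (epoch, loss, acc, lr, and val_miou when a
#'   validation set is given) and the two configs.
#' @export
train_vitseg <- function(tiles, model_config = vitseg_config(),
                         config = train_config(), validation = NULL,
                         verbose = FALSE) {
  stopifnot(length(tiles) >= 1L, inherits(config, "train_config"))
  tk <- .tiles_to_tokens(tiles, model_config)
  labelled <- tk$y[tk$y != 255L]
  if (length(labelled) == 0L) stop("training set has no annotated pixels")
  if (length(unique(labelled)) < 2L)
    stop("training set must contain at least 2 classes")
  model <- vitseg_init(model_config, seed = config$seed)
  zero <- lapply(model$params, function(m) m * 0)
  m <- zero; v <- zero
  n_tiles <- length(tiles)
  bs <- min(config$batch_size, n_tiles)
  steps_per_epoch <- ceiling(n_tiles / bs)
  has_pos <- model_config$positional_embedding == "learned"
  dmask <- .decay_mask(model)
  vtk <- if (!is.null(validation)) .tiles_to_tokens(validation, model_config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  hist <- list()
  best <- list(miou = -Inf, params = NULL)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_tiles) - 1L
    lrs <- vapply(seq_len(steps_per_epoch),
                  function(k) lr_at(step + k, config, steps_per_epoch), 0)
    res <- cpp_vit_epoch(tk$x, tk$y, unname(model$params), unname(m), unname(v),
                         step, lrs, ord, bs, model_config$n_tokens,
                         model_config$n_heads, has_pos, config$penalty,
                         config$label_smoothing, config$weight_decay, dmask)
    model$params <- stats::setNames(res$params, names(model$params))
    m <- res$m; v <- res$v; step <- res$step
    row <- data.frame(epoch = ep, loss = res$loss, acc = res$acc,
                      lr = lrs[length(lrs)])
    if (!is.null(validation)) {
      lg <- cpp_vit_forward(vtk$x, unname(model$params), model_config$n_tokens,
                            model_config$n_heads, has_pos, "single")
      pred <- max.col(lg, ties.method = "first") - 1L
      row$val_miou <- .pixel_miou(pred, vtk$y)
      if (row$val_miou > best$miou)
        best <- list(miou = row$val_miou, params = model$params)
    }
    hist[[ep]] <- row
    if (verbose)
      cat(sprintf("epoch %2d  loss %.4f  acc %.4f%s\n", ep, res$loss, res$acc,
                  if (!is.null(validation))
                    sprintf("  val mIoU %.4f", row$val_miou) else ""))
  }
  if (!is.null(validation) && !is.null(best$params)) model$params <- best$params
  structure(list(model = model, history = do.call(rbind, hist),
                 train_config = config, model_config = model_config),
            class = "vitseg_fit")
}

# mIoU over classes present in the reference labels (255 excluded)
.pixel_miou <- function(pred, ref) {
  keep <- ref != 255L
  pred <- pred[keep]; ref <- ref[keep]
  cls <- sort(unique(ref))
  ious <- vapply(cls, function(c) {
    tp <- sum(pred == c & ref == c)
    un <- sum(pred == c | ref == c)
    if (un == 0) return(NA_real_)
    tp / un
  }, 0)
  mean(ious, na.rm = TRUE)
}

#' @export
print.vitseg_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<vitseg fit> %d epochs, final loss %.4f, final pixel accuracy %.4f\n",
              nrow(h), h$loss[nrow(h)], h$acc[nrow(h)]))
  if (!is.null(h$val_miou))
    cat(sprintf("  best validation mIoU %.4f (epoch %d)\n",
                max(h$val_miou), which.max(h$val_miou)))
  invisible(x)
}

#' @export
summary.vitseg_fit <- function(object, ...) {
  print(object$model)
  print(object)
  invisible(object$history)
}

#' @export
plot.vitseg_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "loss",
                 main = "training loss", ...)
  graphics::plot(h$epoch, h$acc, type = "b", xlab = "epoch",
                 ylab = "pixel accuracy", main = "training accuracy",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Predict a whole-cube segmentation map
#'
#' Cuts the cube into tiles, runs the model on every tile and stitches the
#' per-tile logits back into a full-image prediction map. The default grid
#' is disjoint tiles; pass an overlapping grid to average logits over
#' overlaps.
#'
#' @param object A \code{vitseg_fit}.
#' @param cube A normalized \code{\link{hypercube}}.
#' @param grid A \code{\link{tile_grid}}.
#' @param combine Overlap combination rule, see
#'   \code{\link{stitch_predictions}}.
#' @param ... Unused.
#' @return A \code{\link{prediction_map}}.
#' @export
predict.vitseg_fit <- function(object, cube, grid = tile_grid(),
                               combine = "mean_logits", ...) {
  cfg <- object$model_config
  tiles <- extract_tiles(cube, grid = grid)
  tk <- .tiles_to_tokens(tiles, cfg)
  lg <- cpp_vit_forward(tk$x, unname(object$model$params), cfg$n_tokens,
                        cfg$n_heads, cfg$positional_embedding == "learned",
                        "single")
  nt <- cfg$n_tokens
  tl <- lapply(seq_along(tiles), function(i) {
    rows <- ((i - 1L) * nt + 1L):(i * nt)
    list(origin = tiles[[i]]$origin,
         logits = array(lg[rows, ], c(cfg$tile_h, cfg$tile_w, cfg$n_classes)))
  })
  stitch_predictions(tl, dim(cube$data)[1:2], combine = combine)
}
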