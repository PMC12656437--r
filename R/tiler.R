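#' Tile grid specification
#'
#' Hypercubes are cut into 20 x 16 pixel tiles for the dense segmentation
#' model. Training uses 50% overlap (stride 10 x 8); inference defaults to
#' disjoint tiles (stride = tile size) for speed.
#'
#' @param tile_h,tile_w Tile height and width in pixels.
#' @param stride_h,stride_w Origin strides; must be in 1..tile size.
#' @return An object of class \code{tile_grid}.
#' @export
tile_grid <- function(tile_h = 20L, tile_w = 16L,
                      stride_h = tile_h, stride_w = tile_w) {
  tile_h <- as.integer(tile_h); tile_w <- as.integer(tile_w)
  stride_h <- as.integer(stride_h); stride_w <- as.integer(stride_w)
  if (stride_h < 1L || stride_h > tile_h || stride_w < 1L || stride_w > tile_w)
    stop("strides must lie in 1..tile size")
  structure(list(tile_h = tile_h, tile_w = tile_w,
                 stride_h = stride_h, stride_w = stride_w),
            class = "tile_grid")
}

# 0-based origins along one axis: step by stride, and shift the final
# origin so the last tile ends exactly at the border (no padding).
.tile_origins_1d <- function(extent, tile, stride) {
  if (extent < tile) stop("image extent smaller than one tile")
  o <- seq.int(0L, extent - tile, by = stride)
  if (o[length(o)] != extent - tile) o <- c(o, extent - tile)
  o
}

#' Cut a hypercube into tiles
#'
#' Tiles are placed at origins (i * stride_h, j * stride_w); the final
#' origin along each axis is clamped so the last tile ends exactly at the
#' image border, giving full coverage without padding (padding would
#' fabricate spectra).
#'
#' @param cube A normalized \code{\link{hypercube}}.
#' @param mask Optional label mask matrix matching the cube's spatial shape.
#' @param grid A \code{\link{tile_grid}}.
#' @param drop_unannotated Drop tiles whose mask is entirely 255 (training
#'   mode). Requires \code{mask}.
#' @return A list of tiles; each tile is a list with \code{data}
#'   (tile_h x tile_w x bands), \code{mask} (or NULL) and \code{origin}
#'   (0-based row, col of the top-left pixel).
#' @export
extract_tiles <- function(cube, mask = NULL, grid = tile_grid(),
                          drop_unannotated = FALSE) {
  stopifnot(inherits(cube, "hypercube"), inherits(grid, "tile_grid"))
  if (cube$state != "normalized184")
    stop("extract_tiles expects a normalized184 cube, got ", cube$state)
  d <- dim(cube$data)
  if (!is.null(mask) && !identical(dim(mask), d[1:2]))
    stop("mask shape does not match cube")
  if (drop_unannotated && is.null(mask))
    stop("drop_unannotated requires a mask")
  ro <- .tile_origins_1d(d[1], grid$tile_h, grid$stride_h)
  co <- .tile_origins_1d(d[2], grid$tile_w, grid$stride_w)
  out <- vector("list", length(ro) * length(co))
  k <- 0L
  for (j in co) for (i in ro) {
    rows <- (i + 1L):(i + grid$tile_h)
    cols <- (j + 1L):(j + grid$tile_w)
    tm <- if (is.null(mask)) NULL else mask[rows, cols, drop = FALSE]
    if (drop_unannotated && all(tm == 255L)) next
    k <- k + 1L
    out[[k]] <- list(data = cube$data[rows, cols, , drop = FALSE],
                     mask = tm, origin = c(i, j))
  }
  out[seq_len(k)]
}

#' Stitch per-tile logits into a whole-image prediction map
#'
#' Overlapping tiles are combined per pixel: \code{mean_logits} averages
#' the logits of all covering tiles and then takes the argmax;
#' \code{majority_vote} takes each tile's argmax and the most frequent
#' class wins (ties to the lowest class index). Every pixel must be covered
#' by at least one tile.
#'
#' @param tiles List of lists with \code{origin} (0-based row, col) and
#'   \code{logits} (tile_h x tile_w x n_classes array).
#' @param shape Integer c(height, width) of the output map.
#' @param combine Combination rule for overlapped pixels.
#' @return A \code{\link{prediction_map}} in stage \code{raw_model}.
#' @export
stitch_predictions <- function(tiles, shape,
                               combine = c("mean_logits", "majority_vote")) {
  combine <- match.arg(combine)
  h <- shape[1]; w <- shape[2]
  nc <- dim(tiles[[1]]$logits)[3]
  cover <- matrix(0L, h, w)
  acc <- array(0, c(h, w, nc))
  for (t in tiles) {
    dl <- dim(t$logits)
    rows <- (t$origin[1] + 1L):(t$origin[1] + dl[1])
    cols <- (t$origin[2] + 1L):(t$origin[2] + dl[2])
    if (max(rows) > h || max(cols) > w) stop("tile extends beyond the image")
    cover[rows, cols] <- cover[rows, cols] + 1L
    if (combine == "mean_logits") {
      acc[rows, cols, ] <- acc[rows, cols, ] + t$logits
    } else {
      lab <- .argmax_map(t$logits)
      idx <- cbind(rep(rows, times = length(cols)),
                   rep(cols, each = length(rows)),
                   as.vector(lab) + 1L)
      acc[idx] <- acc[idx] + 1
    }
  }
  if (any(cover == 0L)) {
    bad <- which(cover == 0L, arr.ind = TRUE)
    stop(sprintf("uncovered pixel(s), first at (row %d, col %d), %d total",
                 bad[1, 1], bad[1, 2], nrow(bad)))
  }
  if (combine == "mean_logits") acc <- acc / as.vector(cover)  # recycles over classes
  prediction_map(.argmax_map(acc), stage = "raw_model")
}

# argmax over the 3rd axis, ties -> lowest class index; returns 0-based map
.argmax_map <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' Per-pixel class prediction map
#'
#' An integer matrix of 0-based class indices with a stage flag tracking
#' post-processing progress (\code{raw_model}, \code{rules_applied},
#' \code{eroded}).
#'
#' @param labels Integer matrix of class indices 0..12.
#' @param stage Processing stage.
#' @return An object of class \code{prediction_map} (a classed matrix).
#' @export
prediction_map <- function(labels, stage = c("raw_model", "rules_applied", "eroded")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (any(labels < 0L) || any(labels > 12L))
    stop("prediction classes must lie in 0..12")
  structure(labels, class = "prediction_map", stage = stage)
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("<prediction map, stage %s> %d x %d pixels, %d contaminant pixel(s)\n",
              attr(x, "stage"), nrow(x), ncol(x),
              sum(x >= 3L)))
  invisible(x)
}
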