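#' Segmentation model configuration
#'
#' A lightweight Vision Transformer that densely classifies every pixel of
#' a 20 x 16 tile. Each of the tile's 320 pixels is a token and the token
#' embedding is its raw 184-band spectrum — there is no patch projection,
#' so the embedding length stays 184 throughout. Four pre-norm transformer
#' blocks (8-head self-attention over the 320 tokens, then a two-layer
#' GELU MLP, residual connections around both) are followed by a per-token
#' linear map to the 13 class scores.
#'
#' By default no positional embedding is used: the spectra themselves carry
#' the signal and self-attention then treats the tile as a set, making the
#' model exactly permutation-equivariant in its pixels. A learned
#' 320-position table can be enabled instead.
#'
#' @param n_blocks Number of transformer blocks.
#' @param n_heads Attention heads; must divide \code{embed_dim}.
#' @param embed_dim Token embedding length (the band count).
#' @param mlp_hidden Hidden width of the per-block MLP (ViT convention:
#'   4 x embed).
#' @param n_classes Number of output classes.
#' @param tile_h,tile_w Tile spatial size.
#' @param positional_embedding \code{"none"} or \code{"learned"}.
#' @param dropout Dropout rate; only 0 is supported (the training recipe
#'   does not use dropout).
#' @return An object of class \code{vitseg_config}.
#' @export
vitseg_config <- function(n_blocks = 4L, n_heads = 8L, embed_dim = 184L,
                          mlp_hidden = 4L * embed_dim, n_classes = 13L,
                          tile_h = 20L, tile_w = 16L,
                          positional_embedding = c("none", "learned"),
                          dropout = 0) {
  positional_embedding <- match.arg(positional_embedding)
  if (embed_dim %% n_heads != 0L)
    stop("embed_dim must be divisible by n_heads")
  if (dropout != 0) stop("only dropout = 0 is supported")
  structure(list(n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
                 embed_dim = as.integer(embed_dim),
                 mlp_hidden = as.integer(mlp_hidden),
                 n_classes = as.integer(n_classes),
                 tile_h = as.integer(tile_h), tile_w = as.integer(tile_w),
                 n_tokens = as.integer(tile_h * tile_w),
                 positional_embedding = positional_embedding,
                 dropout = dropout),
            class = "vitseg_config")
}

# truncated normal (+/- 2 sd) used for linear-layer weight init
.trunc_normal <- function(n, sd = 0.02) {
  u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
  stats::qnorm(u) * sd
}

#' Initialize model parameters
#'
#' Linear weights are truncated-normal (sd 0.02), biases zero, layer-norm
#' scales one and shifts zero. Fully determined by the seed.
#'
#' @param config A \code{\link{vitseg_config}}.
#' @param seed Integer RNG seed.
#' @return An object of class \code{vitseg_model}: list with \code{config}
#'   and the named parameter list.
#' @export
vitseg_init <- function(config = vitseg_config(), seed = 1L) {
  stopifnot(inherits(config, "vitseg_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  D <- config$embed_dim; Hd <- config$mlp_hidden; C <- config$n_classes
  w <- function(nr, nc) matrix(.trunc_normal(nr * nc), nr, nc)
  zeros <- function(n) matrix(0, 1, n)
  ones <- function(n) matrix(1, 1, n)
  params <- list()
  if (config$positional_embedding == "learned")
    params$pos <- w(config$n_tokens, D)
  for (b in seq_len(config$n_blocks)) {
    pre <- sprintf("blk%d.", b)
    params[[paste0(pre, "ln1.g")]] <- ones(D)
    params[[paste0(pre, "ln1.b")]] <- zeros(D)
    params[[paste0(pre, "attn.Wqkv")]] <- w(D, 3L * D)
    params[[paste0(pre, "attn.bqkv")]] <- zeros(3L * D)
    params[[paste0(pre, "attn.Wo")]] <- w(D, D)
    params[[paste0(pre, "attn.bo")]] <- zeros(D)
    params[[paste0(pre, "ln2.g")]] <- ones(D)
    params[[paste0(pre, "ln2.b")]] <- zeros(D)
    params[[paste0(pre, "mlp.W1")]] <- w(D, Hd)
    params[[paste0(pre, "mlp.b1")]] <- zeros(Hd)
    params[[paste0(pre, "mlp.W2")]] <- w(Hd, D)
    params[[paste0(pre, "mlp.b2")]] <- zeros(D)
  }
  params[["head.W"]] <- w(D, C)
  params[["head.b"]] <- zeros(C)
  structure(list(config = config, params = params), class = "vitseg_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Total parameter count of a model
#' @param model A \code{vitseg_model}.
#' @return Integer number of scalar parameters.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "vitseg_model"))
  sum(vapply(model$params, length, 0L))
}

#' @export
print.vitseg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<vitseg model> %d blocks, %d heads, embed %d, mlp %d, %d classes; %s positional embedding; %s parameters\n",
              cfg$n_blocks, cfg$n_heads, cfg$embed_dim, cfg$mlp_hidden,
              cfg$n_classes, cfg$positional_embedding,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

# weight-decay mask aligned with the parameter list: decay only the
# 2-D linear weights, not biases, layer norms or positional tables
.decay_mask <- function(model) {
  nm <- names(model$params)
  as.integer(grepl("\\.(Wqkv|Wo|W1|W2)$|^head\\.W$", nm))
}

#' Forward pass
#'
#' Computes per-pixel class logits for a batch of tiles.
#'
#' @param model A \code{vitseg_model}.
#' @param x Either a single tile array (tile_h x tile_w x bands), a batch
#'   array (B x tile_h x tile_w x bands), or a token matrix
#'   ((B * n_tokens) x bands).
#' @param precision \code{"single"} (default) or \code{"double"}.
#' @return Logits in the shape matching the input: token matrix in,
#'   ((B * n_tokens) x n_classes) out; tile array in, tile logits array out.
#' @export
vitseg_forward <- function(model, x, precision = c("single", "double")) {
  stopifnot(inherits(model, "vitseg_model"))
  precision <- match.arg(precision)
  cfg <- model$config
  shape <- NULL
  if (is.matrix(x)) {
    xm <- x
  } else if (length(dim(x)) == 3L) {
    shape <- "tile"
    xm <- .tile_tokens(x, cfg)
  } else if (length(dim(x)) == 4L) {
    shape <- "batch"
    d <- dim(x)
    xm <- do.call(rbind, lapply(seq_len(d[1]), function(b)
      .tile_tokens(array(x[b, , , ], d[2:4]), cfg)))
  } else stop("unsupported input shape")
  if (ncol(xm) != cfg$embed_dim)
    stop(sprintf("expected %d spectral bands, got %d", cfg$embed_dim, ncol(xm)))
  if (nrow(xm) %% cfg$n_tokens != 0L)
    stop(sprintf("token count must be a multiple of %d (a %dx%d tile)",
                 cfg$n_tokens, cfg$tile_h, cfg$tile_w))
  lg <- cpp_vit_forward(xm, unname(model$params), cfg$n_tokens, cfg$n_heads,
                        cfg$positional_embedding == "learned", precision)
  if (is.null(shape)) return(lg)
  if (shape == "tile")
    return(array(lg, c(cfg$tile_h, cfg$tile_w, cfg$n_classes)))
  array(aperm(array(lg, c(cfg$n_tokens, nrow(lg) / cfg$n_tokens, cfg$n_classes)),
              c(2, 1, 3)),
        c(nrow(lg) / cfg$n_tokens, cfg$tile_h, cfg$tile_w, cfg$n_classes))
}

# flatten a tile's spatial grid to tokens (column-major, matching R arrays)
.tile_tokens <- function(tile, cfg) {
  stopifnot(identical(dim(tile)[1:2], c(cfg$tile_h, cfg$tile_w)))
  matrix(tile, cfg$n_tokens, dim(tile)[3])
}

#' Classify one tile
#'
#' Argmax of the 13 per-pixel logits; ties resolve to the lowest class
#' index, which favours the background class meat — deliberate, given the
#' pipeline's false-positive aversion.
#'
#' @param model A \code{vitseg_model}.
#' @param tile Tile array tile_h x tile_w x bands.
#' @return Integer tile_h x tile_w matrix of 0-based class indices.
#' @export
predict_tile <- function(model, tile) {
  lg <- vitseg_forward(model, tile)
  .argmax_map(lg)
}
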