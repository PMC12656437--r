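# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written in the most literal way possible and share
# no code with the package internals they verify.

# random hypercube of a given state
random_cube <- function(h, w, bands = 224L, state = "raw224", seed = 1L,
                        lo = 100, hi = 4000) {
  set.seed(seed)
  wl <- if (bands == 224L) default_wavelength_grid(224L)
        else default_wavelength_grid(224L)[21:204]
  hypercube(array(runif(h * w * bands, lo, hi), c(h, w, bands)),
            wl, state = state, temperature = 25)
}

# per-pixel, per-band re-computation of the flat-field equation
# C = (I - D) * m / (F - D), clamped at zero
oracle_flat_field <- function(cube, pair) {
  d <- dim(cube$data)
  m <- mean(pair$flat - pair$dark)
  out <- array(0, d)
  for (l in seq_len(d[1]))
    for (cc in seq_len(d[2]))
      for (b in seq_len(d[3])) {
        v <- (cube$data[l, cc, b] - pair$dark[cc, b]) * m /
          (pair$flat[cc, b] - pair$dark[cc, b])
        out[l, cc, b] <- max(v, 0)
      }
  out
}

# literal per-pixel interpreter of the three spectral conditions, written
# from their printed form; classes by name to stay independent of index
# conventions
oracle_rules <- function(pred, cube, tax, threshold = 1.04) {
  wl <- cube$wavelengths
  bandof <- function(w) which.min(abs(wl - w))
  I <- function(l, c, w) cube$data[l, c, bandof(w)]
  nm <- class_names(tax)
  out <- matrix(as.integer(pred), nrow(pred), ncol(pred))
  for (l in seq_len(nrow(pred)))
    for (c in seq_len(ncol(pred))) {
      cls <- nm[pred[l, c] + 1L]
      if (cls == "pehd") {
        r1 <- (I(l, c, 1225.5) - I(l, c, 1211.5) > I(l, c, 1026) - I(l, c, 1012)) &&
          (I(l, c, 1407.5) > 1e-8) &&
          (I(l, c, 1411) / I(l, c, 1407.5) < threshold)
        r2 <- I(l, c, 1117) > I(l, c, 1099.5)
        if (r1) out[l, c] <- which(nm == "fat") - 1L
        else if (r2) out[l, c] <- which(nm == "conveyor_belt") - 1L
      } else if (cls == "pa_pp") {
        if (I(l, c, 1225.5) - I(l, c, 1215) < I(l, c, 1232.5) - I(l, c, 1012))
          out[l, c] <- which(nm == "meat") - 1L
      }
    }
  out
}

# structuring-element definition of 3x3 erosion: a pixel survives iff the
# full 3x3 neighbourhood lies inside the mask (outside the image counts as
# background)
oracle_erode3x3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      keep <- TRUE
      for (di in -1:1)
        for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || jj < 1 || ii > nr || jj > nc || !mask[ii, jj])
            keep <- FALSE
        }
      out[i, j] <- keep
    }
  out
}

# flood-fill 8-connected component count
oracle_count_blobs8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      if (!mask[i, j] || seen[i, j]) next
      n <- n + 1L
      stack <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1)
          for (dj in -1:1) {
            ii <- p[1] + di; jj <- p[2] + dj
            if (ii >= 1 && jj >= 1 && ii <= nr && jj <= nc &&
                mask[ii, jj] && !seen[ii, jj]) {
              seen[ii, jj] <- TRUE
              stack[[length(stack) + 1L]] <- c(ii, jj)
            }
          }
      }
    }
  n
}

# brute-force logit accumulation oracle for tile stitching
oracle_stitch_mean <- function(tiles, shape, nc) {
  acc <- array(0, c(shape, nc))
  cnt <- matrix(0, shape[1], shape[2])
  for (t in tiles) {
    d <- dim(t$logits)
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2])) {
        r <- t$origin[1] + i; c <- t$origin[2] + j
        acc[r, c, ] <- acc[r, c, ] + t$logits[i, j, ]
        cnt[r, c] <- cnt[r, c] + 1
      }
  }
  out <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(shape[1]))
    for (j in seq_len(shape[2]))
      out[i, j] <- which.max(acc[i, j, ] / cnt[i, j]) - 1L
  out
}

# brute-force 1-D tile origin enumeration (clamped last origin)
oracle_origins <- function(extent, tile, stride) {
  o <- integer(); p <- 0L
  repeat {
    if (p + tile >= extent) { o <- c(o, extent - tile); break }
    o <- c(o, p); p <- p + stride
  }
  unique(o)
}

# small fully-annotated synthetic tile set for trainer tests with an
# arbitrary (tiny) model geometry
fake_tiles <- function(n, cfg, n_classes_used = 3L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cls <- sample.int(n_classes_used, cfg$n_tokens, replace = TRUE) - 1L
    centers <- outer(seq_len(n_classes_used) / n_classes_used,
                     seq_len(cfg$embed_dim) / cfg$embed_dim, function(a, b)
                       0.5 + 0.4 * sin(6 * a + 3 * b))
    dat <- centers[cls + 1L, ] + matrix(rnorm(cfg$n_tokens * cfg$embed_dim, 0, 0.02),
                                        cfg$n_tokens, cfg$embed_dim)
    dat <- pmin(pmax(dat, 0), 1)
    list(data = array(dat, c(cfg$tile_h, cfg$tile_w, cfg$embed_dim)),
         mask = matrix(cls, cfg$tile_h, cfg$tile_w), origin = c(0L, 0L))
  })
}
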