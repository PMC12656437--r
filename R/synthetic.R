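#' Synthetic material spectrum library
#'
#' Parameterized mean reflectance curves for the 13 material classes, each
#' a smooth baseline plus a few Gaussian bumps/dips (centre nm, width nm,
#' amplitude), over the full 224-band grid. The curves are a designed
#' family, not digitized measurements; only their structure mirrors real
#' NIR signatures:
#' \itemize{
#'   \item the 13 canonical curves are pairwise well separated in spectral
#'     angle (after per-pixel normalization, the representation the model
#'     sees);
#'   \item PEHD carries the discriminative features the post-processing
#'     rules probe: an inflection (dip then rise) around 1205--1230 nm, a
#'     rising flank at 1012--1026 nm, a dip at 1117 nm relative to
#'     1099.5 nm, and a reflectance step above ~1408 nm that pushes its
#'     normalized 1411/1407.5 ratio well above 1.04;
#'   \item a 14th curve, \code{pehd_hard}, models the hard false-positive
#'     mode: fat tissue whose spectrum matches fat everywhere except a
#'     PEHD-like inflection near 1222 nm. Per-pixel, a mixing coefficient
#'     u in [0, u_max] moves it further towards PEHD in every region
#'     except the three rule windows, which stay fat-like — so a
#'     classifier working on the whole spectrum mislabels a controllable
#'     fraction of these pixels as PEHD, while the spectral rules still
#'     recognize them as fat (rule 1) or at worst belt (rule 2).
#' }
#'
#' @param seed Integer seed; perturbs the per-class baseline levels
#'   slightly so distinct libraries can be generated. Rule-critical
#'   features are fixed by design.
#' @param hard_u_max Upper bound of the per-pixel PEHD-mixing coefficient
#'   for \code{pehd_hard} pixels (0 = pure fat + inflection).
#' @param jitter_sd Per-pixel relative amplitude jitter of the bumps.
#' @param albedo_sd Log-sd of the per-pixel albedo scale (removed by
#'   normalization).
#' @param read_noise Additive sensor read noise, raw counts.
#' @return An object of class \code{spectrum_library} with the 14 x 224
#'   matrix of mean curves and the generator parameters.
#' @export
make_spectrum_library <- function(seed = 1L, hard_u_max = 1.0,
                                  jitter_sd = 0.06, albedo_sd = 0.08,
                                  read_noise = 3.0) {
  wl <- default_wavelength_grid(224L)
  t <- (wl - 942) / 781
  g <- function(c, s) exp(-(wl - c)^2 / (2 * s^2))
  sigm <- function(c, s) 1 / (1 + exp(-(wl - c) / s))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # the PEHD inflection: dip near 1205, rise peaking near 1230 — the
  # crossing sits around 1220 nm. Modelled as one component so per-pixel
  # jitter scales dip and rise together. The hard fat-like mode carries a
  # weaker copy: visible, but small against fat's narrow dynamic range.
  infl <- -0.06 * g(1205, 8) + 0.09 * g(1230, 9)
  infl_hard <- infl / 3

  # per class: smooth baseline + named bump/dip components (amplitude
  # folded into the component vector); per-pixel jitter rescales each
  # component independently, which changes spectral shape (a non-affine
  # perturbation that survives normalization)
  defs <- list(
    meat          = list(base = 0.35 - 0.05 * t,
                         comp = cbind(-0.12 * g(1450, 55), -0.04 * g(1190, 35))),
    fat           = list(base = 0.55 + 0.05 * t,
                         comp = cbind(0.05 * g(1150, 40), -0.05 * g(1680, 70))),
    conveyor_belt = list(base = 0.20 + 0.03 * t,
                         comp = cbind(0.05 * g(1350, 90))),
    pa_pp         = list(base = 0.50 + 0 * t,
                         comp = cbind(0.10 * g(1226, 8), 0.08 * g(1005, 15),
                                      0.08 * g(1390, 35))),
    pu            = list(base = 0.45 + 0.05 * t,
                         comp = cbind(0.09 * g(1320, 30), -0.06 * g(1500, 40))),
    metal         = list(base = 0.75 - 0.15 * t,
                         comp = cbind(0.03 * g(1080, 60))),
    pehd          = list(base = 0.52 + 0.02 * t,
                         comp = cbind(infl, 0.12 * g(1042, 16),
                                      -0.06 * g(1117, 12), 0.10 * sigm(1408, 3))),
    teflon        = list(base = 0.82 - 0.02 * t,
                         comp = cbind(-0.08 * g(1550, 40))),
    nitrile       = list(base = 0.40 + 0.10 * t,
                         comp = cbind(0.08 * g(1470, 35), -0.05 * g(1180, 30))),
    wood          = list(base = 0.50 + 0.12 * t,
                         comp = cbind(-0.10 * g(1420, 45), 0.10 * g(1100, 50))),
    paper         = list(base = 0.70 + 0 * t,
                         comp = cbind(-0.06 * g(1480, 45), -0.04 * g(1190, 50))),
    cardboard     = list(base = 0.60 - 0.08 * t,
                         comp = cbind(-0.08 * g(1460, 50), 0.05 * g(1120, 40))),
    white_belt    = list(base = 0.78 + 0 * t,
                         comp = cbind(0.06 * g(1250, 70), -0.04 * g(1600, 60))))
  # small seed-dependent per-class level shift (rule-critical features are
  # fixed design constants)
  for (nm in names(defs)) defs[[nm]]$base <- defs[[nm]]$base + stats::rnorm(1, 0, 0.01)

  # hard fat-like PEHD: fat plus the (weak) inflection...
  defs$pehd_hard <- list(base = defs$fat$base,
                         comp = cbind(defs$fat$comp, infl_hard))
  curves <- t(vapply(defs, function(s) s$base + rowSums(s$comp), numeric(224L)))

  # ...with a per-pixel drift towards PEHD everywhere EXCEPT the three
  # rule windows, which stay fat-like at every mixing level
  smoothbox <- function(a, b, s = 4) sigm(a, s) * (1 - sigm(b, s))
  window_mask <- pmin(1, smoothbox(1000, 1050) + smoothbox(1085, 1130) +
                         smoothbox(1390, 1430))
  hard_dir <- (curves["pehd", ] - curves["pehd_hard", ]) * (1 - window_mask)

  if (any(curves <= 0) || any(curves > 1))
    stop("library curves must lie in (0, 1]")
  structure(list(wavelengths = wl, curves = curves, components = defs,
                 hard_dir = hard_dir,
                 hard_u_max = hard_u_max, jitter_sd = jitter_sd,
                 albedo_sd = albedo_sd, read_noise = read_noise, seed = seed),
            class = "spectrum_library")
}

#' @export
print.spectrum_library <- function(x, ...) {
  cat(sprintf("<spectrum library> %d curves x %d bands, hard-mode u_max %.2f\n",
              nrow(x$curves), ncol(x$curves), x$hard_u_max))
  invisible(x)
}

#' Scene recipe
#'
#' Describes one synthetic conveyor-belt scene: a pork belly (elliptical
#' region split into a fat and a meat zone, either side up), foreign
#' objects on or off the belly, a smooth multiplicative shadow field,
#' per-column fixed-pattern stripe gains, and a sensor temperature that
#' drives global gain and dark-level drift. All stochastic elements are
#' drawn from \code{seed} at render time.
#'
#' @param height,width Scene size in pixels (default 128 x 160, a
#'   desk-scale stand-in for the production 640 x 1000 frames).
#' @param side \code{"fat_up"} or \code{"meat_up"}.
#' @param contaminants Data frame with columns class (name), shape
#'   (\code{"rectangle"}, \code{"ellipse"}, \code{"ribbon"}), h, w (size in
#'   px), row, col (0-based top-left / centre), or NULL for none.
#' @param hard_fat_frac Fraction of the fat area rendered with the
#'   \code{pehd_hard} confuser spectrum (ground truth stays fat).
#' @param shadow_amp Peak attenuation of the shadow field (0 = none).
#' @param temperature Sensor temperature in degrees C (10--55 nominal).
#' @param seed Integer seed for all per-scene randomness.
#' @return An object of class \code{scene_recipe}.
#' @export
scene_recipe <- function(height = 128L, width = 160L,
                         side = c("fat_up", "meat_up"), contaminants = NULL,
                         hard_fat_frac = 0, shadow_amp = 0.25,
                         temperature = 25, seed = 1L) {
  side <- match.arg(side)
  if (!is.null(contaminants)) {
    need <- c("class", "shape", "h", "w", "row", "col")
    if (!all(need %in% names(contaminants)))
      stop("contaminants needs columns ", paste(need, collapse = ", "))
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 side = side, contaminants = contaminants,
                 hard_fat_frac = hard_fat_frac, shadow_amp = shadow_amp,
                 temperature = as.numeric(temperature), seed = as.integer(seed)),
            class = "scene_recipe")
}

#' Draw a randomized scene recipe
#'
#' Samples side, temperature, and a contaminant inventory (class, shape
#' and placement on the belly) for a contaminated or clean scene. Clean
#' scenes carry no contaminants but (by default) include hard fat-like
#' PEHD confuser regions, the empirically dominant false-positive mode.
#'
#' @param seed Integer seed.
#' @param height,width Scene size.
#' @param n_contaminants Number of foreign objects (0 for a clean scene).
#' @param classes Contaminant class names to sample from.
#' @param hard_fat_frac See \code{\link{scene_recipe}}.
#' @param min_size,max_size Object size range in px.
#' @return A \code{\link{scene_recipe}}.
#' @export
random_scene_recipe <- function(seed, height = 128L, width = 160L,
                                n_contaminants = 3L,
                                classes = c("pa_pp", "pu", "metal", "pehd",
                                            "teflon", "nitrile", "wood",
                                            "paper", "cardboard", "white_belt"),
                                hard_fat_frac = 0, min_size = 6L, max_size = 16L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  side <- sample(c("fat_up", "meat_up"), 1)
  temperature <- stats::runif(1, 10, 55)
  cont <- NULL
  if (n_contaminants > 0L) {
    cls <- sample(classes, n_contaminants, replace = TRUE)
    shp <- sample(c("rectangle", "ellipse", "ribbon"), n_contaminants,
                  replace = TRUE, prob = c(0.45, 0.4, 0.15))
    max_size <- min(max_size, height %/% 3L, width %/% 3L)
    min_size <- min(min_size, max_size)
    h <- sample(min_size:max_size, n_contaminants, replace = TRUE)
    w <- sample(min_size:max_size, n_contaminants, replace = TRUE)
    # keep objects inside the central belly area and inside the frame
    pick <- function(lo, hi) vapply(hi, function(x) sample(seq.int(lo, x), 1L), 0L)
    row <- pick(round(height * 0.2), pmin(round(height * 0.8), height - h - 1L))
    col <- pick(round(width * 0.2), pmin(round(width * 0.8), width - w - 1L))
    cont <- data.frame(class = cls, shape = shp, h = h, w = w,
                       row = row, col = col, stringsAsFactors = FALSE)
  }
  scene_recipe(height, width, side = side, contaminants = cont,
               hard_fat_frac = hard_fat_frac, temperature = temperature,
               seed = sample.int(.Machine$integer.max, 1))
}

# temperature response of the sensor model: global gain and dark level
.temp_gain <- function(temperature) 1 + 0.012 * (temperature - 25)
.temp_dark <- function(temperature) 90 + 0.6 * temperature

#' Render a synthetic scene
#'
#' Builds the effective reflectance cube (class spectra + per-pixel jitter
#' + shadow), then pushes it through the sensor forward model
#' \deqn{I = D + g(T) \cdot stripe_c \cdot E_b \cdot R + \epsilon,}
#' with D the dark frame, g(T) the temperature gain, stripe the per-column
#' fixed-pattern gains, E the illumination/sensitivity envelope and
#' epsilon read noise. The matching calibration pair (noise-free frames,
#' as averages of many acquisitions would be) is F = D + g(T) stripe E, so
#' flat-field correction recovers m * R exactly up to read noise, and the
#' full conditioning chain cancels temperature, exposure, stripes and
#' shadows.
#'
#' @param recipe A \code{\link{scene_recipe}}.
#' @param lib A \code{\link{spectrum_library}}.
#' @param tax Taxonomy.
#' @return An object of class \code{synth_sample}: list with \code{raw}
#'   (hypercube, state raw224), \code{reflectance} (noiseless ground-truth
#'   cube including the shadow), \code{mask} (label matrix) and \code{pair}
#'   (a \code{\link{calibration_pair}}).
#' @export
render_scene <- function(recipe, lib, tax = hsi_taxonomy()) {
  stopifnot(inherits(recipe, "scene_recipe"), inherits(lib, "spectrum_library"))
  H <- recipe$height; W <- recipe$width; nb <- 224L
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(recipe$seed)

  geo <- .scene_geometry(recipe, tax)
  mask <- geo$mask
  hard <- geo$hard
  npix <- H * W
  cls <- as.vector(mask)

  # per-pixel reflectance: class mean curve + per-bump jitter, albedo scale
  R <- matrix(0, npix, nb)
  albedo <- exp(stats::rnorm(npix, 0, lib$albedo_sd))
  for (nm in rownames(lib$curves)) {
    if (nm == "pehd_hard") next
    idx <- which(cls == class_index(tax, nm) & !as.vector(hard))
    if (!length(idx)) next
    R[idx, ] <- .sample_class_spectra(lib, nm, length(idx))
  }
  hidx <- which(as.vector(hard))
  if (length(hidx)) R[hidx, ] <- .sample_hard_spectra(lib, length(hidx))
  R <- R * albedo
  R[R < 0.01] <- 0.01

  # smooth multiplicative shadow field
  shadow <- 1 - recipe$shadow_amp * .smooth_field(H, W)
  R <- R * as.vector(shadow)

  # sensor model
  temp <- recipe$temperature
  gT <- .temp_gain(temp)
  stripes <- exp(stats::rnorm(W, 0, 0.05))
  E <- 2000 * (0.5 + 0.5 * exp(-(lib$wavelengths - 1300)^2 / (2 * 300^2)))
  # calibration frames are noise-free, as averages of many acquisitions
  # would be; dark has a per-column fixed pattern on top of the
  # temperature-driven level
  dark <- outer(rep(1, W), .temp_dark(temp) + 3 * sin(lib$wavelengths / 40)) +
    4 * sin(seq_len(W))
  flat <- dark + gT * stripes * outer(rep(1, W), E)

  colidx <- rep(seq_len(W), each = H)
  gain_pix <- gT * stripes[colidx]
  raw <- dark[colidx, ] + (gain_pix * R) * rep(E, each = npix) +
    matrix(stats::rnorm(npix * nb, 0, lib$read_noise), npix, nb)
  raw[raw < 0] <- 0

  structure(list(
    raw = hypercube(array(raw, c(H, W, nb)), lib$wavelengths, state = "raw224",
                    temperature = temp, exposure = "synthetic"),
    reflectance = array(R, c(H, W, nb)),
    mask = mask,
    pair = calibration_pair(dark, flat, temperature = temp)),
    class = "synth_sample")
}

# paint belly, fat/meat zones, hard patches and contaminants; returns the
# label mask plus the hard-pixel indicator
.scene_geometry <- function(recipe, tax) {
  H <- recipe$height; W <- recipe$width
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  belly <- ((rr - H / 2) / (0.42 * H))^2 + ((cc - W / 2) / (0.46 * W))^2 <= 1
  boundary <- H * (0.45 + 0.06 * sin(2 * pi * seq_len(W) / W + stats::runif(1, 0, 2 * pi)))
  upper <- rr < matrix(boundary, H, W, byrow = TRUE)
  fatzone <- if (recipe$side == "fat_up") upper else !upper
  mask <- matrix(class_index(tax, "conveyor_belt"), H, W)
  mask[belly & fatzone] <- class_index(tax, "fat")
  mask[belly & !fatzone] <- class_index(tax, "meat")

  hard <- matrix(FALSE, H, W)
  if (recipe$hard_fat_frac > 0) {
    fat_px <- sum(mask == class_index(tax, "fat"))
    target <- recipe$hard_fat_frac * fat_px
    tries <- 0
    while (sum(hard & mask == class_index(tax, "fat")) < target && tries < 50) {
      tries <- tries + 1
      r0 <- stats::runif(1, 0.15 * H, 0.85 * H)
      c0 <- stats::runif(1, 0.15 * W, 0.85 * W)
      a <- stats::runif(1, 4, 9); b <- stats::runif(1, 4, 9)
      patch <- ((rr - r0) / a)^2 + ((cc - c0) / b)^2 <= 1
      hard <- hard | (patch & mask == class_index(tax, "fat"))
    }
  }

  if (!is.null(recipe$contaminants)) {
    for (i in seq_len(nrow(recipe$contaminants))) {
      ct <- recipe$contaminants[i, ]
      ci <- class_index(tax, ct$class)
      px <- .shape_pixels(ct, H, W)
      if (any(px$row < 1L | px$row > H | px$col < 1L | px$col > W))
        stop("contaminant ", i, " extends outside the image")
      mask[cbind(px$row, px$col)] <- ci
      hard[cbind(px$row, px$col)] <- FALSE
    }
  }
  list(mask = mask, hard = hard)
}

# pixel coordinates of one foreign object
.shape_pixels <- function(ct, H, W) {
  r0 <- ct$row; c0 <- ct$col
  if (ct$shape == "rectangle") {
    px <- expand.grid(row = r0 + seq_len(ct$h) - 1L, col = c0 + seq_len(ct$w) - 1L)
  } else if (ct$shape == "ellipse") {
    a <- ct$h / 2; b <- ct$w / 2
    px <- expand.grid(row = (r0):(r0 + ct$h - 1L), col = (c0):(c0 + ct$w - 1L))
    keep <- ((px$row - r0 - a + 0.5) / a)^2 + ((px$col - c0 - b + 0.5) / b)^2 <= 1
    px <- px[keep, ]
  } else if (ct$shape == "ribbon") {
    # thin wavy ribbon; every scan line it crosses gets >= 2 pixels
    # (physical detection floor: a 1 mm^2 object spans >= 2 px on the line)
    len <- max(ct$h, ct$w, 10L)
    s <- seq(0, 1, length.out = 4L * len)
    rowf <- r0 + s * (ct$h - 1)
    colf <- c0 + (ct$w - 1) / 2 * (1 + sin(2 * pi * 1.5 * s)) / 1
    px <- unique(data.frame(row = round(rowf), col = round(colf)))
    px <- rbind(px, data.frame(row = px$row, col = px$col + 1L))
    px <- unique(px)
  } else stop("unknown shape ", ct$shape)
  px
}

# smooth random field in [0, 1], outer product of smoothed 1-D profiles
.smooth_field <- function(H, W) {
  f1 <- stats::filter(stats::rnorm(H + 40), rep(1 / 21, 21), circular = TRUE)[1:H]
  f2 <- stats::filter(stats::rnorm(W + 40), rep(1 / 21, 21), circular = TRUE)[1:W]
  f <- outer(as.numeric(f1), as.numeric(f2))
  f <- f - min(f)
  if (max(f) > 0) f <- f / max(f)
  f
}

# n jittered spectra of one class: mean curve plus per-pixel, per-bump
# amplitude jitter (a shape change, not a gain/offset, so it survives
# per-pixel normalization)
.sample_class_spectra <- function(lib, nm, n) {
  s <- lib$components[[nm]]
  k <- ncol(s$comp)
  z <- matrix(stats::rnorm(n * k, 0, lib$jitter_sd), n, k)
  matrix(s$base + rowSums(s$comp), n, 224L, byrow = TRUE) + z %*% t(s$comp)
}

# hard fat-like PEHD pixels: (fat + inflection, jittered) + u * towards-pehd
# with u ~ U(0, u_max) per pixel
.sample_hard_spectra <- function(lib, n) {
  u <- stats::runif(n, 0, lib$hard_u_max)
  .sample_class_spectra(lib, "pehd_hard", n) + outer(u, lib$hard_dir)
}

#' @export
print.synth_sample <- function(x, ...) {
  d <- dim(x$raw$data)
  cat(sprintf("<synthetic sample> %d x %d px, T = %.1f degC, %d contaminant px\n",
              d[1], d[2], x$raw$temperature, sum(x$mask >= 3L)))
  invisible(x)
}

#' Generate a synthetic dataset on disk
#'
#' Renders train/test scenes and writes them as ENVI cubes with PNG label
#' masks, per-scene calibration pairs and a manifest CSV (scene id, split,
#' side, temperature, contaminant inventory). Clean scenes contain no
#' contaminant pixels; by default they include hard fat-like PEHD regions.
#'
#' @param dir Output directory.
#' @param n_train,n_contaminated,n_clean Scene counts per split.
#' @param seed Integer seed.
#' @param height,width Scene size.
#' @param lib A \code{\link{spectrum_library}}.
#' @param clean_hard_frac \code{hard_fat_frac} for clean scenes.
#' @return The manifest data frame, invisibly.
#' @export
make_dataset <- function(dir, n_train = 10L, n_contaminated = 5L, n_clean = 5L,
                         seed = 1L, height = 128L, width = 160L,
                         lib = make_spectrum_library(), clean_hard_frac = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tax <- hsi_taxonomy()
  rows <- list()
  render_one <- function(id, split, rec) {
    s <- render_scene(rec, lib, tax)
    stem <- file.path(dir, sprintf("%s_%03d", split, id))
    write_envi(s$raw, paste0(stem, ".hdr"))
    write_mask_png(s$mask, paste0(stem, "_mask.png"))
    write_calibration(s$pair, stem)
    inv <- if (is.null(rec$contaminants)) ""
           else paste(rec$contaminants$class, collapse = ";")
    data.frame(scene = basename(stem), split = split, side = rec$side,
               temperature = rec$temperature, contaminants = inv,
               stringsAsFactors = FALSE)
  }
  k <- 0L
  for (i in seq_len(n_train)) {
    k <- k + 1L
    rows[[k]] <- render_one(i, "train",
      random_scene_recipe(seed * 1000L + i, height, width, n_contaminants = 3L))
  }
  for (i in seq_len(n_contaminated)) {
    k <- k + 1L
    rows[[k]] <- render_one(i, "test",
      random_scene_recipe(seed * 2000L + i, height, width, n_contaminants = 3L))
  }
  for (i in seq_len(n_clean)) {
    k <- k + 1L
    rows[[k]] <- render_one(i, "clean",
      random_scene_recipe(seed * 3000L + i, height, width, n_contaminants = 0L,
                          hard_fat_frac = clean_hard_frac))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Run the full conditioning chain on a raw synthetic sample
#'
#' Convenience wrapper: flat-field correct with the sample's own
#' calibration pair, trim bands, normalize.
#'
#' @param sample A \code{synth_sample}.
#' @param mode Normalization mode.
#' @return A normalized \code{\link{hypercube}}.
#' @export
condition_sample <- function(sample, mode = "minmax") {
  stopifnot(inherits(sample, "synth_sample"))
  normalize_pixelwise(trim_bands(flat_field_correct(sample$raw, sample$pair)),
                      mode = mode)
}
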