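#' Dark/flat calibration pair
#'
#' A dark frame D (shutter closed) and a flat frame F (homogeneous bright
#' target, typically a Teflon tile) acquired at a given sensor temperature.
#' Both are per-(sample column, band) matrices of size width x 224 that are
#' broadcast over scan lines: on a line-scan sensor, fixed-pattern noise is
#' constant along the scan direction and shows up as vertical stripes.
#'
#' @param dark,flat Numeric width x 224 matrices.
#' @param temperature Sensor temperature in degrees Celsius.
#' @return An object of class \code{calibration_pair}.
#' @export
calibration_pair <- function(dark, flat, temperature) {
  stopifnot(is.matrix(dark), is.matrix(flat))
  if (!identical(dim(dark), dim(flat)))
    stop("dark and flat frames must have identical dimensions")
  if (ncol(dark) != 224L) stop("calibration frames must have 224 bands")
  bad <- which(flat - dark <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("flat - dark is not strictly positive at (column %d, band %d)%s",
                 bad[1, 1], bad[1, 2],
                 if (nrow(bad) > 1L) sprintf(" and %d more", nrow(bad) - 1L) else ""))
  structure(list(dark = dark, flat = flat, temperature = as.numeric(temperature)),
            class = "calibration_pair")
}

#' @export
print.calibration_pair <- function(x, ...) {
  cat(sprintf("<calibration pair> %d columns x %d bands, T = %.1f degC\n",
              nrow(x$dark), ncol(x$dark), x$temperature))
  invisible(x)
}

#' Compute the gain field of a calibration pair
#'
#' The corrected flat field F - D has mean m over all (column, band)
#' entries; the gain field G = (F - D)/m records how each photosite
#' deviates from that mean. Correction divides by G, i.e.
#' C = (I - D)/G = (I - D) * m/(F - D).
#'
#' @param pair A \code{\link{calibration_pair}}.
#' @return An object of class \code{gain_field}: list with the width x 224
#'   gain matrix \code{G} and the scalar \code{m}.
#' @examples
#' d <- matrix(0, 4, 224); f <- matrix(2, 4, 224)
#' g <- compute_gain(calibration_pair(d, f, 25))
#' g$m          # 2
#' range(g$G)   # 1 1
#' @export
compute_gain <- function(pair) {
  stopifnot(inherits(pair, "calibration_pair"))
  fd <- pair$flat - pair$dark
  m <- mean(fd)
  structure(list(G = fd / m, m = m), class = "gain_field")
}

#' Flat-field correct a raw hypercube
#'
#' Applies C = (I - D) * m/(F - D) per line, column and band, removing
#' fixed-pattern vertical stripe noise and pixel-to-pixel sensitivity
#' variation. Negative results (possible in dark regions due to read noise)
#' are clamped to 0. Correcting the flat frame itself yields a constant
#' image of value m.
#'
#' @param cube A \code{\link{hypercube}} in state \code{raw224}.
#' @param pair A \code{\link{calibration_pair}} with matching width.
#' @return The corrected \code{hypercube} (state \code{corrected224}).
#' @export
flat_field_correct <- function(cube, pair) {
  stopifnot(inherits(cube, "hypercube"), inherits(pair, "calibration_pair"))
  if (cube$state != "raw224")
    stop("flat_field_correct expects a raw224 cube, got ", cube$state)
  d <- dim(cube$data)
  if (nrow(pair$dark) != d[2])
    stop(sprintf("cube width %d does not match calibration width %d",
                 d[2], nrow(pair$dark)))
  g <- compute_gain(pair)
  # broadcast the (column, band) frames over lines: pixel i (column-major)
  # sits in sensor column (i - 1) %/% lines + 1
  npix <- d[1] * d[2]
  colidx <- rep(seq_len(d[2]), each = d[1])
  out <- (matrix(cube$data, npix, d[3]) - pair$dark[colidx, ]) / g$G[colidx, ]
  out[out < 0] <- 0
  out <- array(out, d)
  hypercube(out, cube$wavelengths, state = "corrected224",
            temperature = cube$temperature, exposure = cube$exposure)
}

#' Trim uninformative spectral bands
#'
#' The first and last 20 of the 224 bands are noisy due to weak signal and
#' are dropped, leaving 184 bands (roughly 1012--1653 nm on the nominal
#' grid).
#'
#' @param cube A corrected 224-band \code{\link{hypercube}}.
#' @return A \code{hypercube} in state \code{trimmed184}.
#' @export
trim_bands <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$state != "corrected224")
    stop("trim_bands expects a corrected224 cube, got ", cube$state)
  keep <- .trim_keep()
  hypercube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
            state = "trimmed184", temperature = cube$temperature,
            exposure = cube$exposure)
}

#' Per-pixel spectral normalization
#'
#' Rescales every pixel's 184-band spectrum s independently of its
#' neighbours:
#' \describe{
#'   \item{minmax (default)}{(s - min s)/(max s - min s); invariant under
#'     per-pixel gain and offset, so exposure changes, temperature-driven
#'     gain drift and multiplicative shadows all cancel. Output attains 0
#'     and 1 in every pixel.}
#'   \item{maxdiv}{(s - min s)/(max s); invariant under gain only.}
#' }
#' Degenerate (constant) spectra, as produced by dead photosites, normalize
#' to the all-zero vector; their count is reported via a warning.
#'
#' @param cube A \code{\link{hypercube}} in state \code{trimmed184}.
#' @param mode Normalization variant, see above.
#' @param eps Denominators below this are treated as degenerate.
#' @return A \code{hypercube} in state \code{normalized184}.
#' @export
normalize_pixelwise <- function(cube, mode = c("minmax", "maxdiv"),
                                eps = 1e-8) {
  stopifnot(inherits(cube, "hypercube"))
  mode <- match.arg(mode)
  if (cube$state != "trimmed184")
    stop("normalize_pixelwise expects a trimmed184 cube, got ", cube$state)
  d <- dim(cube$data)
  npix <- d[1] * d[2]
  m <- matrix(cube$data, npix, d[3])  # pixels x bands
  rng <- cpp_row_range(m)
  mn <- rng[, 1]
  mx <- rng[, 2]
  den <- if (mode == "minmax") mx - mn else mx
  degen <- den < eps
  den[degen] <- 1
  out <- (m - mn) / den
  if (any(degen)) {
    out[degen, ] <- 0
    warning(sum(degen), " degenerate (constant) spectra normalized to zero")
  }
  out[out < 0] <- 0; out[out > 1] <- 1  # guard against rounding
  hypercube(array(out, d), cube$wavelengths, state = "normalized184",
            temperature = cube$temperature, exposure = cube$exposure)
}

.rowMins <- function(m) cpp_row_range(m)[, 1]
.rowMaxs <- function(m) cpp_row_range(m)[, 2]

#' Nearest spectral band lookup
#'
#' Maps a wavelength in nm to the index of the closest band on the cube's
#' grid; used to evaluate spectral rules phrased in nm. Ties resolve to the
#' lower index. Wavelengths farther than half a band spacing outside the
#' grid are an error.
#'
#' @param cube A \code{\link{hypercube}} (any state), or a numeric
#'   wavelength vector.
#' @param wavelength_nm Scalar wavelength in nm.
#' @return 1-based band index.
#' @export
nearest_band <- function(cube, wavelength_nm) {
  wl <- if (inherits(cube, "hypercube")) cube$wavelengths else as.numeric(cube)
  stopifnot(length(wavelength_nm) == 1L, is.finite(wavelength_nm))
  half <- max(diff(wl)) / 2
  if (wavelength_nm < wl[1] - half || wavelength_nm > wl[length(wl)] + half)
    stop(sprintf("wavelength %.1f nm outside grid range %.1f-%.1f nm",
                 wavelength_nm, wl[1], wl[length(wl)]))
  d <- abs(wl - wavelength_nm)
  which(d == min(d))[1]
}

#' Calibration library keyed by sensor temperature
#'
#' Sensor temperature drifts during a production day and shifts both dark
#' current and gain, so dark/flat pairs are acquired at several
#' temperatures and the closest one is selected at correction time.
#'
#' @param pairs List of \code{\link{calibration_pair}} objects with
#'   distinct temperatures.
#' @return An object of class \code{calibration_library}.
#' @export
calibration_library <- function(pairs) {
  stopifnot(length(pairs) >= 1L,
            all(vapply(pairs, inherits, TRUE, "calibration_pair")))
  temps <- vapply(pairs, function(p) p$temperature, 0)
  if (anyDuplicated(temps)) stop("calibration temperatures must be unique")
  structure(list(pairs = pairs[order(temps)], temperatures = sort(temps)),
            class = "calibration_library")
}

#' @describeIn calibration_library Select the pair whose temperature is
#'   closest to the query; ties resolve to the lower temperature.
#' @param lib A \code{calibration_library}.
#' @param temperature Query temperature in degrees Celsius.
#' @export
select_calibration <- function(lib, temperature) {
  stopifnot(inherits(lib, "calibration_library"))
  if (length(lib$pairs) == 0L) stop("empty calibration library")
  d <- abs(lib$temperatures - temperature)
  lib$pairs[[which(d == min(d))[1]]]  # temperatures sorted -> lower wins ties
}
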