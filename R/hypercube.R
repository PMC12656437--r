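#' Hypercube container
#'
#' A hypercube is a 3-D array of non-negative intensities with axis order
#' (line, sample, band): the first axis is the along-belt scan direction,
#' the second the 640-pixel sensor line, the third the spectral axis. A
#' processing-state flag tracks where the cube sits in the conditioning
#' chain:
#' \describe{
#'   \item{raw224}{sensor units, 224 bands (942--1723 nm)}
#'   \item{corrected224}{flat-field corrected, 224 bands}
#'   \item{trimmed184}{20 noisy bands dropped at each end, 184 bands}
#'   \item{normalized184}{per-pixel normalized, every spectrum in [0, 1]}
#' }
#'
#' @param data Numeric array, lines x samples x bands, non-negative.
#' @param wavelengths Strictly increasing per-band wavelengths in nm;
#'   defaults to the nominal sensor grid when the cube has 224 bands.
#' @param state Processing state, see above.
#' @param temperature Sensor temperature in degrees Celsius (metadata).
#' @param exposure Free-text exposure tag (metadata).
#' @return An object of class \code{hypercube}.
#' @export
hypercube <- function(data, wavelengths = NULL,
                      state = c("raw224", "corrected224", "trimmed184", "normalized184"),
                      temperature = NA_real_, exposure = "") {
  state <- match.arg(state)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-D array (lines x samples x bands)")
  nb <- dim(data)[3]
  if (is.null(wavelengths)) {
    if (nb == 224L) wavelengths <- default_wavelength_grid(224L)
    else stop("wavelengths must be supplied for a ", nb, "-band cube")
  }
  if (length(wavelengths) != nb)
    stop("length(wavelengths) must equal the band dimension")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  need <- if (state %in% c("raw224", "corrected224")) 224L else 184L
  if (nb != need)
    stop(sprintf("state '%s' requires %d bands, got %d", state, need, nb))
  if (state == "normalized184") {
    rng <- range(data)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("normalized cube must lie in [0, 1]")
  }
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 state = state, temperature = as.numeric(temperature),
                 exposure = as.character(exposure)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube %s> %d lines x %d samples x %d bands, %.1f-%.1f nm",
              x$state, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.na(x$temperature)) cat(sprintf(", T = %.1f degC", x$temperature))
  cat("\n")
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Nominal sensor wavelength grid
#'
#' The line-scan camera samples 224 bands spanning 942--1723 nm, about
#' 3.5 nm per band. The grid is linear: lambda(i) = 942 + i * (1723 - 942)/223
#' for i = 0..223. Real ENVI headers override this; the nominal grid exists
#' for synthetic cubes.
#'
#' @param n_bands Must be 224.
#' @return Numeric vector of 224 wavelengths in nm.
#' @examples
#' g <- default_wavelength_grid(224)
#' g[1]    # 942
#' g[224]  # 1723
#' g[21]   # ~1012.06, the first band retained after trimming
#' @export
default_wavelength_grid <- function(n_bands = 224L) {
  if (n_bands != 224L)
    stop("the nominal grid is defined for 224 bands only")
  942 + (0:223) * (1723 - 942) / 223
}

# band indices (1-based) kept by trimming: drop first and last 20 of 224
.trim_keep <- function() 21:204
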