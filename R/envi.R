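#' Read an ENVI hypercube
#'
#' Reads an ENVI header/binary pair as produced by line-scan hyperspectral
#' cameras and by \code{\link{write_envi}}. All three interleaves (BIL, BIP,
#' BSQ) and data types 4 (32-bit float) and 12 (unsigned 16-bit) are
#' accepted; the in-memory axis order is always (line, sample, band)
#' regardless of the stored interleave.
#'
#' The header must declare \code{samples}, \code{lines}, \code{bands},
#' \code{interleave}, \code{data type} and a \code{wavelength} list. The
#' custom keys \code{cube state}, \code{sensor temperature} and
#' \code{exposure tag} written by \code{write_envi} are restored when
#' present; otherwise the state is inferred from the band count (224 = raw,
#' 184 = trimmed).
#'
#' @param header_path Path to the \code{.hdr} text header. The binary file
#'   is looked up next to it (same stem, \code{.raw}/\code{.img}/\code{.dat}
#'   or no extension).
#' @return A \code{\link{hypercube}}.
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  hdr <- .parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  if (is.null(hdr$wavelength))
    stop("ENVI header has no wavelength field")
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  if (!nb %in% c(224L, 184L))
    stop("unsupported band count ", nb, " (expected 224 raw or 184 trimmed)")
  wl <- as.numeric(strsplit(gsub("[{}]", "", hdr$wavelength), ",")[[1]])
  if (length(wl) != nb) stop("wavelength list length != bands")
  dtype <- as.integer(hdr$`data type`)
  if (!dtype %in% c(4L, 12L)) stop("unsupported ENVI data type ", dtype)
  inter <- tolower(hdr$interleave)
  if (!inter %in% c("bil", "bip", "bsq")) stop("unsupported interleave ", inter)
  endian <- if (!is.null(hdr$`byte order`) && as.integer(hdr$`byte order`) == 1L)
    "big" else "little"

  data_path <- .envi_data_path(header_path)
  n <- ns * nl * nb
  con <- file(data_path, "rb"); on.exit(close(con))
  v <- if (dtype == 4L)
    readBin(con, "numeric", n = n, size = 4L, endian = endian)
  else
    as.numeric(readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                       endian = endian))
  if (length(v) != n) stop("binary file too short for declared dimensions")

  arr <- switch(inter,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3L, 2L, 1L)))

  state <- hdr$`cube state`
  if (is.null(state)) state <- if (nb == 224L) "raw224" else "trimmed184"
  temp <- if (is.null(hdr$`sensor temperature`)) NA_real_
          else as.numeric(hdr$`sensor temperature`)
  expo <- if (is.null(hdr$`exposure tag`)) ""
          else gsub("[{}]", "", hdr$`exposure tag`)
  hypercube(arr, wl, state = state, temperature = temp, exposure = trimws(expo))
}

#' Write an ENVI hypercube
#'
#' Writes the header/binary pair so that \code{\link{read_envi}} inverts it
#' exactly. Wavelengths are serialized at full precision; the processing
#' state, sensor temperature and exposure tag travel as custom header keys.
#'
#' @param cube A \code{\link{hypercube}}.
#' @param header_path Output \code{.hdr} path; the binary goes to the same
#'   stem with \code{.raw}.
#' @param interleave One of \code{"bil"}, \code{"bip"}, \code{"bsq"}.
#' @param data_type 4 (float32) or 12 (uint16).
#' @return \code{header_path}, invisibly.
#' @export
write_envi <- function(cube, header_path, interleave = c("bil", "bip", "bsq"),
                       data_type = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  .write_envi_array(cube$data, cube$wavelengths, header_path, interleave,
                    as.integer(data_type),
                    extra = c(
                      sprintf("cube state = %s", cube$state),
                      if (!is.na(cube$temperature))
                        sprintf("sensor temperature = %.6g", cube$temperature),
                      if (nzchar(cube$exposure))
                        sprintf("exposure tag = {%s}", cube$exposure)))
  invisible(header_path)
}

.envi_data_path <- function(header_path, must_exist = TRUE) {
  stem <- sub("\\.hdr$", "", header_path)
  if (!must_exist) return(paste0(stem, ".raw"))
  for (ext in c(".raw", ".img", ".dat", "")) {
    p <- paste0(stem, ext)
    if (file.exists(p) && p != header_path) return(p)
  }
  stop("no binary data file found next to ", header_path)
}

.parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || toupper(trimws(lines[1])) != "ENVI")
    stop("malformed ENVI header (line 1): missing ENVI magic")
  out <- list()
  i <- 2L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, ";")) { i <- i + 1L; next }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed ENVI header (line ", i, "): ", ln)
    key <- tolower(trimws(substr(ln, 1L, eq - 1L)))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    # brace-wrapped values may span lines
    if (startsWith(val, "{")) {
      while (!grepl("}", val) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      if (!grepl("}", val))
        stop("malformed ENVI header (line ", i, "): unterminated brace list")
    }
    out[[key]] <- val
    i <- i + 1L
  }
  out
}

.write_envi_array <- function(arr, wavelengths, header_path, interleave,
                              data_type, extra = character()) {
  stopifnot(length(dim(arr)) == 3L)
  d <- dim(arr)  # lines, samples, bands
  stem <- sub("\\.hdr$", "", header_path)
  data_path <- paste0(stem, ".raw")
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           "wavelength units = Nanometers",
           sprintf("wavelength = {%s}",
                   paste(format(wavelengths, digits = 17, trim = TRUE,
                                scientific = FALSE), collapse = ", ")),
           extra)
  writeLines(hdr, header_path)
  v <- as.vector(switch(interleave,
    bsq = aperm(arr, c(2L, 1L, 3L)),
    bil = aperm(arr, c(2L, 3L, 1L)),
    bip = aperm(arr, c(3L, 2L, 1L))))
  con <- file(data_path, "wb"); on.exit(close(con))
  if (data_type == 4L) {
    writeBin(v, con, size = 4L, endian = "little")
  } else if (data_type == 12L) {
    iv <- as.integer(round(v))
    if (any(iv < 0L) || any(iv > 65535L)) stop("values out of uint16 range")
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L  # reinterpret as signed bits
    writeBin(iv, con, size = 2L, endian = "little")
  } else stop("unsupported data type ", data_type)
  invisible(header_path)
}

#' Read and write label masks as indexed PNG
#'
#' Label masks are single-channel 8-bit PNGs whose pixel values are 0-based
#' class indices; 255 marks unannotated pixels.
#'
#' @param path PNG file path.
#' @param mask Integer matrix of class indices (and possibly 255).
#' @return \code{read_mask_png}: an integer matrix. \code{write_mask_png}:
#'   the path, invisibly.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  m
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  v <- as.integer(mask)
  if (any(is.na(v)) || any(v < 0L) || any(v > 255L))
    stop("mask values must be 0..255")
  png::writePNG(matrix(v, nrow(mask), ncol(mask)) / 255, path)
  invisible(path)
}

#' Store and load a dark/flat calibration pair
#'
#' The pair is written as two one-line ENVI cubes (\code{<prefix>_dark.hdr},
#' \code{<prefix>_flat.hdr}) carrying the sensor temperature as a header key.
#'
#' @param pair A \code{\link{calibration_pair}}.
#' @param prefix Path prefix for the two files.
#' @return \code{write_calibration}: \code{prefix}, invisibly.
#'   \code{read_calibration}: a \code{\link{calibration_pair}}.
#' @export
write_calibration <- function(pair, prefix) {
  stopifnot(inherits(pair, "calibration_pair"))
  wl <- default_wavelength_grid(224L)
  ex <- sprintf("sensor temperature = %.6g", pair$temperature)
  .write_envi_array(array(pair$dark, c(1L, dim(pair$dark))), wl,
                    paste0(prefix, "_dark.hdr"), "bil", 4L, extra = ex)
  .write_envi_array(array(pair$flat, c(1L, dim(pair$flat))), wl,
                    paste0(prefix, "_flat.hdr"), "bil", 4L, extra = ex)
  invisible(prefix)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(prefix) {
  rd <- function(p) {
    hdr <- .parse_envi_header(p)
    ns <- as.integer(hdr$samples); nb <- as.integer(hdr$bands)
    con <- file(.envi_data_path(p), "rb"); on.exit(close(con))
    v <- readBin(con, "numeric", n = ns * nb, size = 4L, endian = "little")
    list(m = matrix(v, ns, nb), temp = as.numeric(hdr$`sensor temperature`))
  }
  dk <- rd(paste0(prefix, "_dark.hdr"))
  fl <- rd(paste0(prefix, "_flat.hdr"))
  calibration_pair(dk$m, fl$m, temperature = dk$temp)
}
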