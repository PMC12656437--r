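#' Material class taxonomy
#'
#' The pipeline distinguishes 13 material classes: three background classes
#' (meat, fat and the conveyor belt itself, which never raise an alarm) and
#' ten contaminant classes whose detection is the purpose of the system.
#' Polyamide and polypropylene are merged into a single \code{pa_pp} class
#' because their near-infrared signatures are practically indistinguishable;
#' fragments of white conveyor belt material (\code{white_belt}) are a
#' contaminant class distinct from the background \code{conveyor_belt}.
#'
#' Class indices are stable 0-based integers in the canonical order
#' meat, fat, conveyor_belt, pa_pp, pu, metal, pehd, teflon, nitrile, wood,
#' paper, cardboard, white_belt. Label masks use index 255 for unannotated
#' pixels.
#'
#' @param file Path to a taxonomy YAML file. Defaults to the file shipped
#'   with the package.
#' @return An object of class \code{hsi_taxonomy}: a list with a
#'   \code{classes} data frame (index, name, role, color), the background
#'   and contaminant index sets, and the unannotated sentinel value.
#' @examples
#' tax <- hsi_taxonomy()
#' class_names(tax)
#' is_contaminant(tax, 6)   # pehd -> TRUE
#' @export
hsi_taxonomy <- function(file = system.file("extdata", "taxonomy.yaml",
                                            package = "hsinspect")) {
  raw <- yaml::read_yaml(file)
  cls <- do.call(rbind, lapply(raw$classes, function(x) {
    data.frame(index = as.integer(x$index), name = x$name, role = x$role,
               color = x$color, stringsAsFactors = FALSE)
  }))
  cls <- cls[order(cls$index), ]
  if (nrow(cls) != 13L || !identical(cls$index, 0:12))
    stop("taxonomy must define exactly 13 classes with indices 0..12")
  if (anyDuplicated(cls$name)) stop("duplicate class names in taxonomy")
  bg <- cls$index[cls$role == "background"]
  fg <- cls$index[cls$role == "contaminant"]
  if (length(bg) != 3L || length(fg) != 10L)
    stop("taxonomy must have 3 background and 10 contaminant classes")
  structure(list(classes = cls,
                 background = bg,
                 contaminant = fg,
                 unannotated = as.integer(raw$unannotated %||% 255L)),
            class = "hsi_taxonomy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hsi_taxonomy <- function(x, ...) {
  cat("Material taxonomy: 13 classes",
      sprintf("(%d background, %d contaminant)\n",
              length(x$background), length(x$contaminant)))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Class names in canonical index order
#' @param tax An \code{hsi_taxonomy}.
#' @return Character vector of length 13, position i holds the name of
#'   class index i-1.
#' @export
class_names <- function(tax) tax$classes$name

#' Map class names to 0-based indices
#' @param tax An \code{hsi_taxonomy}.
#' @param name Character vector of class names.
#' @return Integer vector of 0-based class indices.
#' @export
class_index <- function(tax, name) {
  i <- match(name, tax$classes$name)
  if (anyNA(i)) stop("unknown class name: ", paste(name[is.na(i)], collapse = ", "))
  tax$classes$index[i]
}

#' Is a class a contaminant?
#'
#' Background classes (meat, fat, conveyor belt) are negative classes; every
#' other material is a positive detection.
#'
#' @param tax An \code{hsi_taxonomy}.
#' @param class_id Integer vector of 0-based class indices.
#' @return Logical vector, TRUE where the class is a contaminant.
#' @export
is_contaminant <- function(tax, class_id) {
  class_id <- as.integer(class_id)
  if (any(is.na(class_id)) || any(class_id < 0L) || any(class_id > 12L))
    stop("class_id out of range 0..12")
  class_id %in% tax$contaminant
}

#' @rdname is_contaminant
#' @export
background_classes <- function(tax) tax$background

#' @rdname is_contaminant
#' @export
contaminant_classes <- function(tax) tax$contaminant
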