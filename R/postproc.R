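#' Spectral false-positive rules
#'
#' Three pixel-wise conditions separate true from false positives in the
#' two classes whose signatures are closest to the background, PEHD and
#' PA-PP. With I(w) the normalized intensity at the band nearest to
#' wavelength w (nm):
#' \enumerate{
#'   \item predicted PEHD, I(1225.5) - I(1211.5) > I(1026) - I(1012) and
#'     I(1411)/I(1407.5) < 1.04: relabel as fat;
#'   \item predicted PEHD, I(1117) > I(1099.5): relabel as conveyor belt;
#'   \item predicted PA-PP, I(1225.5) - I(1215) < I(1232.5) - I(1012):
#'     relabel as meat.
#' }
#' Rule 3's comparison pairs 1232.5 nm with 1012 nm — the asymmetry is
#' part of the rule's definition. All rules are evaluated against the original
#' prediction (no chaining); rule 1 takes precedence over rule 2 when both
#' fire on a pixel.
#'
#' @param ratio_threshold Threshold of rule 1's band ratio.
#' @param wavelengths Named vector of the ten probe wavelengths in nm;
#'   override to adapt the rules to a different sensor grid.
#' @return An object of class \code{spectral_rule_set}.
#' @export
spectral_rules <- function(ratio_threshold = 1.04,
                           wavelengths = c(w1012 = 1012, w1026 = 1026,
                                           w1099.5 = 1099.5, w1117 = 1117,
                                           w1211.5 = 1211.5, w1215 = 1215,
                                           w1225.5 = 1225.5, w1232.5 = 1232.5,
                                           w1407.5 = 1407.5, w1411 = 1411)) {
  need <- c("w1012", "w1026", "w1099.5", "w1117", "w1211.5", "w1215",
            "w1225.5", "w1232.5", "w1407.5", "w1411")
  if (!all(need %in% names(wavelengths)))
    stop("wavelengths must name all ten rule probes")
  structure(list(ratio_threshold = ratio_threshold, wavelengths = wavelengths),
            class = "spectral_rule_set")
}

#' Apply the spectral rules to a prediction map
#'
#' Per-pixel relabelling as documented in \code{\link{spectral_rules}}.
#' When the rule-1 ratio denominator I(1407.5) is numerically zero the
#' ratio clause counts as false. Rules never touch pixels outside the two
#' trigger classes and never create contaminant pixels, so the contaminant
#' pixel count is non-increasing and a second application is a no-op.
#'
#' @param pred A \code{\link{prediction_map}} in stage \code{raw_model}.
#' @param cube The matching normalized \code{\link{hypercube}} (the
#'   representation the model saw).
#' @param rules A \code{\link{spectral_rule_set}}.
#' @param tax Taxonomy.
#' @param eps Denominator guard for the ratio clause.
#' @return A \code{prediction_map} in stage \code{rules_applied}.
#' @export
apply_spectral_rules <- function(pred, cube, rules = spectral_rules(),
                                 tax = hsi_taxonomy(), eps = 1e-8) {
  stopifnot(inherits(pred, "prediction_map"), inherits(cube, "hypercube"))
  if (cube$state != "normalized184")
    stop("spectral rules are evaluated on the normalized cube")
  if (!identical(dim(pred)[1:2], dim(cube$data)[1:2]))
    stop("prediction and cube shapes differ")
  wl <- rules$wavelengths
  band <- vapply(wl, function(w) nearest_band(cube, w), 0L)
  I <- function(w) as.vector(cube$data[, , band[[paste0("w", w)]]])
  p <- as.integer(pred)
  pehd <- class_index(tax, "pehd"); papp <- class_index(tax, "pa_pp")
  fat <- class_index(tax, "fat"); meat <- class_index(tax, "meat")
  belt <- class_index(tax, "conveyor_belt")

  i1407 <- I("1407.5")
  ratio_ok <- i1407 >= eps & (I("1411") / pmax(i1407, eps)) < rules$ratio_threshold
  r1 <- p == pehd &
    (I("1225.5") - I("1211.5")) > (I("1026") - I("1012")) & ratio_ok
  r2 <- p == pehd & I("1117") > I("1099.5")
  r3 <- p == papp & (I("1225.5") - I("1215")) < (I("1232.5") - I("1012"))

  out <- p
  out[r2] <- belt
  out[r1] <- fat       # rule 1 wins where both fire
  out[r3] <- meat
  structure(matrix(out, nrow(pred), ncol(pred)),
            class = "prediction_map", stage = "rules_applied")
}

#' Morphological erosion with blob reclassification
#'
#' For each contaminant class, the binary mask of that class is eroded
#' with the full 3 x 3 structuring element (pixels outside the image count
#' as background). 8-connected blobs that vanish entirely — anything
#' without a 3 x 3 core, e.g. a 2 x 2 speck or a 1-2 px wide ribbon — are
#' reclassified to the fallback class, as are the rim pixels that erosion
#' strips from surviving blobs: detections shrink to their most confident
#' interiors. Background pixels are never modified. Erosion runs per
#' class, not on the union mask, so adjacent blobs of different classes
#' cannot prop each other up.
#'
#' @param pred A \code{\link{prediction_map}} (stage \code{rules_applied},
#'   or \code{raw_model} for the erosion-only ablation arm).
#' @param tax Taxonomy.
#' @param fallback Class name that removed contaminant pixels receive.
#' @return A \code{prediction_map} in stage \code{eroded}.
#' @export
erode_and_reclassify <- function(pred, tax = hsi_taxonomy(), fallback = "fat") {
  stopifnot(inherits(pred, "prediction_map"))
  fb <- class_index(tax, fallback)
  out <- matrix(as.integer(pred), nrow(pred), ncol(pred))
  for (cl in tax$contaminant) {
    mask <- out == cl
    if (!any(mask)) next
    core <- cpp_erode3x3(mask)
    out[mask & !core] <- fb
  }
  structure(out, class = "prediction_map", stage = "eroded")
}

#' Run the post-processing stack
#'
#' Applies the selected stages in order; the default, spectral rules
#' followed by erosion, is the configuration with the lowest false-positive
#' rate. An empty pipeline is the identity.
#'
#' @param pred A \code{\link{prediction_map}} from the model.
#' @param cube The matching normalized \code{\link{hypercube}} (needed by
#'   the \code{rules} stage).
#' @param pipeline Character vector, ordered subset of
#'   \code{c("rules", "erosion")}.
#' @param rules A \code{\link{spectral_rule_set}}.
#' @param tax Taxonomy.
#' @return A \code{prediction_map}.
#' @export
run_postprocessing <- function(pred, cube = NULL,
                               pipeline = c("rules", "erosion"),
                               rules = spectral_rules(), tax = hsi_taxonomy()) {
  bad <- setdiff(pipeline, c("rules", "erosion"))
  if (length(bad)) stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "))
  for (stage in pipeline) {
    pred <- switch(stage,
      rules = apply_spectral_rules(pred, cube, rules, tax),
      erosion = erode_and_reclassify(pred, tax))
  }
  pred
}
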