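tax <- hsi_taxonomy()
PEHD <- class_index(tax, "pehd"); PAPP <- class_index(tax, "pa_pp")
FAT <- class_index(tax, "fat"); MEAT <- class_index(tax, "meat")
BELT <- class_index(tax, "conveyor_belt")

# build a normalized cube whose pixel (1,1) takes prescribed values at the
# rule wavelengths and a neutral ramp elsewhere
rule_cube <- function(vals, h = 1, w = 1) {
  wl <- default_wavelength_grid()[21:204]
  base <- seq(0.001, 0.999, length.out = 184)
  for (nm in names(vals)) base[which.min(abs(wl - as.numeric(nm)))] <- vals[[nm]]
  hypercube(array(rep(base, each = h * w), c(h, w, 184)), wl,
            state = "normalized184")
}

test_that("crafted spectra flip exactly as the three conditions specify", {
  # rule 1: difference clause and ratio clause both satisfied -> fat
  cb <- rule_cube(list("1225.5" = 0.30, "1211.5" = 0.10, "1026" = 0.20,
                       "1012" = 0.10, "1411" = 0.50, "1407.5" = 0.50,
                       "1117" = 0.10, "1099.5" = 0.20))
  pred <- prediction_map(matrix(PEHD, 1, 1))
  expect_equal(as.integer(apply_spectral_rules(pred, cb, tax = tax)), FAT)
  # same spectrum under a non-trigger class: untouched
  predm <- prediction_map(matrix(MEAT, 1, 1))
  expect_equal(as.integer(apply_spectral_rules(predm, cb, tax = tax)), MEAT)
  # ratio clause fails (1.2 >= 1.04) but 1117 > 1099.5 -> rule 2 -> belt
  cb2 <- rule_cube(list("1225.5" = 0.30, "1211.5" = 0.10, "1026" = 0.20,
                        "1012" = 0.10, "1411" = 0.60, "1407.5" = 0.50,
                        "1117" = 0.30, "1099.5" = 0.20))
  expect_equal(as.integer(apply_spectral_rules(pred, cb2, tax = tax)), BELT)
  # rule 1 takes precedence when both fire
  cb3 <- rule_cube(list("1225.5" = 0.30, "1211.5" = 0.10, "1026" = 0.20,
                        "1012" = 0.10, "1411" = 0.50, "1407.5" = 0.50,
                        "1117" = 0.30, "1099.5" = 0.20))
  expect_equal(as.integer(apply_spectral_rules(pred, cb3, tax = tax)), FAT)
  # neither fires: prediction kept
  cb4 <- rule_cube(list("1225.5" = 0.10, "1211.5" = 0.10, "1026" = 0.30,
                        "1012" = 0.10, "1411" = 0.60, "1407.5" = 0.50,
                        "1117" = 0.10, "1099.5" = 0.20))
  expect_equal(as.integer(apply_spectral_rules(pred, cb4, tax = tax)), PEHD)
  # rule 3 on a PA-PP prediction -> meat
  cb5 <- rule_cube(list("1225.5" = 0.20, "1215" = 0.15, "1232.5" = 0.40,
                        "1012" = 0.10))
  predp <- prediction_map(matrix(PAPP, 1, 1))
  expect_equal(as.integer(apply_spectral_rules(predp, cb5, tax = tax)), MEAT)
  # zero denominator: the ratio clause counts as false
  cb6 <- rule_cube(list("1225.5" = 0.30, "1211.5" = 0.10, "1026" = 0.15,
                        "1012" = 0.10, "1411" = 0.20, "1407.5" = 0,
                        "1117" = 0.10, "1099.5" = 0.20))
  expect_equal(as.integer(apply_spectral_rules(pred, cb6, tax = tax)), PEHD)
})

test_that("rule application matches a literal per-pixel interpreter", {
  set.seed(51)
  h <- 25; w <- 40  # 1000 pixels
  cube <- normalize_pixelwise(
    random_cube(h, w, bands = 184, state = "trimmed184", seed = 51))
  for (trigger in c(PEHD, PAPP)) {
    pred <- prediction_map(matrix(sample(c(trigger, MEAT, FAT, BELT),
                                        h * w, replace = TRUE), h, w))
    got <- apply_spectral_rules(pred, cube, tax = tax)
    want <- oracle_rules(pred, cube, tax)
    expect_equal(unclass(got), want, ignore_attr = TRUE)
  }
})

test_that("rule application is idempotent and never adds contaminants", {
  set.seed(52)
  cube <- normalize_pixelwise(
    random_cube(20, 20, bands = 184, state = "trimmed184", seed = 52))
  pred <- prediction_map(matrix(sample(0:12, 400, replace = TRUE), 20, 20))
  once <- apply_spectral_rules(pred, cube, tax = tax)
  twice <- apply_spectral_rules(prediction_map(unclass(once)), cube, tax = tax)
  expect_equal(unclass(once), unclass(twice))
  expect_lte(sum(unclass(once) %in% tax$contaminant),
             sum(unclass(pred) %in% tax$contaminant))
  # background pixels are fixed points
  bg <- unclass(pred) %in% tax$background
  expect_equal(unclass(once)[bg], unclass(pred)[bg])
})

test_that("erosion geometry: 2x2 vanishes, 3x3 keeps its centre, 4x6 keeps 2x4", {
  base <- matrix(MEAT, 12, 12)
  p22 <- base; p22[2:3, 2:3] <- PEHD
  e22 <- erode_and_reclassify(prediction_map(p22, "rules_applied"), tax)
  expect_equal(sum(e22 == PEHD), 0)
  expect_equal(sum(e22 == FAT), 4)      # reclassified to the fallback
  p33 <- base; p33[4:6, 4:6] <- PEHD
  e33 <- erode_and_reclassify(prediction_map(p33, "rules_applied"), tax)
  expect_equal(sum(e33 == PEHD), 1)
  expect_equal(e33[5, 5], PEHD)
  expect_equal(sum(e33 == FAT), 8)
  p46 <- base; p46[3:6, 3:8] <- PEHD
  e46 <- erode_and_reclassify(prediction_map(p46, "rules_applied"), tax)
  expect_equal(sum(e46 == PEHD), 8)
  expect_true(all(e46[4:5, 4:7] == PEHD))
  # blobs touching the border erode like any other (outside = background)
  pb <- base; pb[1:3, 1:3] <- PEHD
  eb <- erode_and_reclassify(prediction_map(pb, "rules_applied"), tax)
  expect_equal(sum(eb == PEHD), 1)
  expect_equal(eb[2, 2], PEHD)
})

test_that("erosion matches the structuring-element oracle on random masks", {
  set.seed(53)
  for (rep in 1:30) {
    m <- matrix(stats::runif(64 * 64) < stats::runif(1, 0.2, 0.7), 64, 64)
    got <- hsinspect:::cpp_erode3x3(m)
    expect_identical(matrix(as.logical(got), 64, 64), oracle_erode3x3(m))
  }
})

test_that("erosion is per class and never touches background", {
  base <- matrix(BELT, 10, 10)
  # two adjacent 3x3-free blobs of different classes must not support
  # each other
  base[3:4, 3:6] <- PEHD
  base[5:6, 3:6] <- PAPP
  er <- erode_and_reclassify(prediction_map(base, "rules_applied"), tax)
  expect_equal(sum(er == PEHD) + sum(er == PAPP), 0)
  expect_equal(sum(er == BELT), sum(base == BELT))  # background untouched
})

test_that("the pipeline composes stages in order with identity default", {
  set.seed(54)
  cube <- normalize_pixelwise(
    random_cube(15, 15, bands = 184, state = "trimmed184", seed = 54))
  pred <- prediction_map(matrix(sample(0:12, 225, replace = TRUE), 15, 15))
  expect_equal(unclass(run_postprocessing(pred, cube, pipeline = character(0))),
               unclass(pred))
  expect_equal(unclass(run_postprocessing(pred, cube, pipeline = "erosion")),
               unclass(erode_and_reclassify(pred, tax)))
  full <- run_postprocessing(pred, cube)
  expect_equal(attr(full, "stage"), "eroded")
  # monotone contaminant counts through raw -> rules -> rules+erosion
  n0 <- sum(unclass(pred) %in% tax$contaminant)
  n1 <- sum(unclass(run_postprocessing(pred, cube, "rules")) %in% tax$contaminant)
  n2 <- sum(unclass(full) %in% tax$contaminant)
  expect_true(n0 >= n1 && n1 >= n2)
  expect_error(run_postprocessing(pred, cube, pipeline = "blur"), "unknown")
})
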