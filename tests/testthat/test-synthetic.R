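tax <- hsi_taxonomy()

norm_curve <- function(v) {
  v <- v[21:204]
  (v - min(v)) / (max(v) - min(v))
}
angle_deg <- function(a, b)
  acos(min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi

test_that("the spectrum library is deterministic and physically plausible", {
  a <- make_spectrum_library(seed = 3)
  b <- make_spectrum_library(seed = 3)
  expect_identical(a$curves, b$curves)
  c <- make_spectrum_library(seed = 4)
  expect_gt(max(abs(a$curves - c$curves)), 0)
  expect_true(all(a$curves > 0 & a$curves <= 1))
  expect_equal(rownames(a$curves), c(class_names(tax), "pehd_hard"))
})

test_that("classes are separable except the deliberate hard pair", {
  lib <- make_spectrum_library(seed = 1)
  nc <- t(apply(lib$curves, 1, norm_curve))
  ang <- matrix(NA_real_, 14, 14)
  for (i in 1:14) for (j in 1:14)
    if (i < j) ang[i, j] <- angle_deg(nc[i, ], nc[j, ])
  hard_fat <- ang[2, 14]  # fat vs pehd_hard
  # the hard pair is the single closest pair in the whole library
  expect_equal(min(ang, na.rm = TRUE), hard_fat)
  # canonical classes: min pairwise angle clears 3x the mean intra-class
  # spread (sampled with jitter and read-noise at the normalized scale)
  canon <- ang[1:13, 1:13]
  set.seed(61)
  intra <- vapply(rownames(lib$curves)[1:13], function(nm) {
    sp <- hsinspect:::.sample_class_spectra(lib, nm, 100) +
      matrix(rnorm(100 * 224, 0, 0.002), 100, 224)
    mu <- norm_curve(lib$curves[nm, ])
    mean(apply(sp, 1, function(v) angle_deg(norm_curve(v), mu)))
  }, 0)
  expect_gt(min(canon, na.rm = TRUE), 3 * mean(intra))
})

test_that("pehd carries the rule-window features and the hard mode stays fat-like", {
  lib <- make_spectrum_library(seed = 1)
  wl <- lib$wavelengths[21:204]
  q <- function(v, w) v[which.min(abs(wl - w))]
  p <- norm_curve(lib$curves["pehd", ])
  h0 <- norm_curve(lib$curves["pehd_hard", ])
  hu <- norm_curve(lib$curves["pehd_hard", ] + lib$hard_u_max * lib$hard_dir)
  # true PEHD escapes rule 1 through the ratio clause and rule 2 by its dip
  expect_gt(q(p, 1411) / q(p, 1407.5), 1.1)
  expect_lt(q(p, 1117), q(p, 1099.5))
  # the hard mode fires rule 1 (and rule 2 as backup) at both mixing ends
  for (v in list(h0, hu)) {
    expect_gt((q(v, 1225.5) - q(v, 1211.5)) - (q(v, 1026) - q(v, 1012)), 0.1)
    expect_lt(q(v, 1411) / q(v, 1407.5), 1.03)
    expect_gt(q(v, 1117), q(v, 1099.5))
  }
  # pa_pp robustly avoids rule 3
  a <- norm_curve(lib$curves["pa_pp", ])
  expect_gt((q(a, 1225.5) - q(a, 1215)) - (q(a, 1232.5) - q(a, 1012)), 0.3)
})

test_that("a nearest-centroid classifier mislabels hard pixels at a tunable rate", {
  nc_rate <- function(u_max, n = 400) {
    lib <- make_spectrum_library(seed = 1, hard_u_max = u_max)
    set.seed(62)
    sp <- hsinspect:::.sample_hard_spectra(lib, n)
    cent <- t(apply(lib$curves[1:13, ], 1, norm_curve))
    hits <- apply(sp, 1, function(v) {
      vn <- norm_curve(v)
      which.min(apply(cent, 1, function(m) angle_deg(vn, m)))
    })
    mean(rownames(lib$curves)[hits] == "pehd")
  }
  lo <- nc_rate(0.2); hi <- nc_rate(1.0)
  expect_lt(lo, 0.05)          # near-fat mixtures stay fat
  expect_gt(hi, 0.2)           # strong mixtures are (mis)read as PEHD
  expect_gt(hi, lo)
})

test_that("a noise-free scene inverts exactly through the calibration chain", {
  lib0 <- make_spectrum_library(seed = 1, jitter_sd = 0, albedo_sd = 0,
                                read_noise = 0)
  rec <- scene_recipe(height = 32, width = 40, shadow_amp = 0, seed = 2,
                      temperature = 48)
  s <- render_scene(rec, lib0, tax)
  corr <- flat_field_correct(s$raw, s$pair)
  m <- compute_gain(s$pair)$m
  expect_lt(max(abs(corr$data - s$reflectance * m) /
                  pmax(s$reflectance * m, 1e-12)), 1e-6)
})

test_that("noisy scenes still invert to the stored ground-truth reflectance", {
  lib <- make_spectrum_library(seed = 1)
  rec <- scene_recipe(height = 48, width = 60, seed = 5, temperature = 40,
                      contaminants = data.frame(class = "wood",
                                                shape = "rectangle",
                                                h = 8, w = 8, row = 20, col = 30))
  s <- render_scene(rec, lib, tax)
  m <- compute_gain(s$pair)$m
  rel <- abs(flat_field_correct(s$raw, s$pair)$data - s$reflectance * m) /
    (s$reflectance * m)
  expect_lt(median(rel), 0.02)
  expect_lt(unname(quantile(rel, 0.999)), 0.1)
})

test_that("scenes are reproducible and masks only contain placed classes", {
  lib <- make_spectrum_library(seed = 1)
  rec <- scene_recipe(height = 40, width = 50, seed = 7,
                      contaminants = data.frame(class = c("pehd", "metal"),
                                                shape = c("rectangle", "ellipse"),
                                                h = c(6, 8), w = c(6, 8),
                                                row = c(10, 24), col = c(10, 30)))
  s1 <- render_scene(rec, lib, tax)
  s2 <- render_scene(rec, lib, tax)
  expect_identical(s1$raw$data, s2$raw$data)
  expect_identical(s1$mask, s2$mask)
  expect_setequal(unique(as.vector(s1$mask)),
                  class_index(tax, c("meat", "fat", "conveyor_belt",
                                     "pehd", "metal")))
  expect_error(render_scene(scene_recipe(height = 40, width = 50, seed = 7,
    contaminants = data.frame(class = "pehd", shape = "rectangle",
                              h = 30, w = 6, row = 20, col = 10)), lib, tax),
    "outside")
})

test_that("ribbon contaminants span at least two pixels per crossed line", {
  lib <- make_spectrum_library(seed = 1)
  rec <- scene_recipe(height = 60, width = 60, seed = 8,
                      contaminants = data.frame(class = "pehd", shape = "ribbon",
                                                h = 20, w = 10, row = 15, col = 20))
  s <- render_scene(rec, lib, tax)
  rows <- which(apply(s$mask == class_index(tax, "pehd"), 1, any))
  counts <- rowSums(s$mask[rows, , drop = FALSE] == class_index(tax, "pehd"))
  expect_true(all(counts >= 2))
})

test_that("normalized class means converge to the normalized library curves", {
  lib <- make_spectrum_library(seed = 1)
  rec <- scene_recipe(height = 48, width = 60, seed = 9, temperature = 30)
  s <- render_scene(rec, lib, tax)
  cube <- condition_sample(s)
  for (nm in c("meat", "fat", "conveyor_belt")) {
    sel <- s$mask == class_index(tax, nm)
    sm <- apply(cube$data, 3, function(sl) mean(sl[sel]))
    mu <- norm_curve(lib$curves[nm, ])
    expect_lt(mean(abs(sm - mu)), 0.04)
  }
})

test_that("dataset generation writes consistent scenes and a manifest", {
  lib <- make_spectrum_library(seed = 1)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- make_dataset(d1, n_train = 1, n_contaminated = 1, n_clean = 2,
                     seed = 5, height = 32, width = 40, lib = lib)
  m2 <- make_dataset(d2, n_train = 1, n_contaminated = 1, n_clean = 2,
                     seed = 5, height = 32, width = 40, lib = lib)
  expect_equal(nrow(m1), 4L)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  # clean scenes contain only background classes
  for (f in list.files(d1, pattern = "^clean.*mask\\.png$", full.names = TRUE)) {
    msk <- read_mask_png(f)
    expect_true(all(msk %in% tax$background))
  }
  # cubes round-trip and match their mask geometry
  cube <- read_envi(file.path(d1, "train_001.hdr"))
  msk <- read_mask_png(file.path(d1, "train_001_mask.png"))
  expect_equal(dim(cube$data)[1:2], dim(msk))
  pair <- read_calibration(file.path(d1, "train_001"))
  expect_equal(dim(pair$dark), c(40L, 224L))
})
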