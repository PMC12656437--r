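tiny_cfg <- vitseg_config(n_blocks = 2, n_heads = 2, embed_dim = 8,
                          mlp_hidden = 16, n_classes = 4, tile_h = 2, tile_w = 3)

test_that("smoothed targets follow (1 - eps) one-hot + eps/K", {
  expect_equal(smoothed_targets(4, eps = 0), c(rep(0, 4), 1, rep(0, 8)))
  q <- smoothed_targets(2, eps = 0.3, K = 13)
  expect_equal(q[3], 0.7 + 0.3 / 13, tolerance = 1e-12)
  expect_equal(q[1], 0.3 / 13, tolerance = 1e-12)
  expect_equal(q[3], 0.7230769, tolerance = 1e-5)
  expect_equal(q[1], 0.0230769, tolerance = 1e-5)
  for (eps in runif(5)) expect_equal(sum(smoothed_targets(5, eps)), 1)
})

test_that("pixel loss hits its closed forms", {
  W1 <- matrix(1, 13, 13)
  # uniform logits: -sum q log(1/13) = log 13 whatever the smoothing
  expect_equal(pixel_loss(rep(0, 13), 4, W1, eps = 0), log(13))
  expect_equal(pixel_loss(rep(2.5, 13), 4, W1, eps = 0.3), log(13))
  expect_equal(log(13), 2.5649, tolerance = 1e-4)
  # softmax equal to the smoothed target: loss is the entropy of q
  q <- smoothed_targets(6, eps = 0.3, K = 13)
  expect_equal(pixel_loss(log(q), 6, W1, eps = 0.3), -sum(q * log(q)))
  expect_equal(-sum(q * log(q)), 1.2781, tolerance = 1e-4)
  # penalty factor scales exactly linearly
  W2 <- W1; W2[7, ] <- 2  # true class 6, any prediction
  lg <- rnorm(13)
  expect_equal(pixel_loss(lg, 6, W2, eps = 0.3),
               2 * pixel_loss(lg, 6, W1, eps = 0.3))
  expect_error(pixel_loss(c(rep(0, 12), Inf), 1), "non-finite")
})

test_that("eps = 0 and W = 1 reduce the loss to plain cross-entropy", {
  set.seed(41)
  W1 <- matrix(1, 13, 13)
  for (i in 1:20) {
    lg <- rnorm(13, sd = 3)
    t <- sample(0:12, 1)
    ce <- -(lg[t + 1] - max(lg) - log(sum(exp(lg - max(lg)))))
    expect_equal(pixel_loss(lg, t, W1, eps = 0), ce, tolerance = 1e-10)
    # shift invariance
    expect_equal(pixel_loss(lg + 7.3, t, W1, eps = 0.3),
                 pixel_loss(lg, t, W1, eps = 0.3), tolerance = 1e-9)
  }
})

test_that("raising w_high penalizes only meat/fat -> contaminant errors", {
  tax <- hsi_taxonomy()
  lg <- rep(0, 13); lg[class_index(tax, "pehd") + 1] <- 4  # predicts pehd
  lo <- pixel_loss(lg, class_index(tax, "meat"), default_penalty_matrix(2, 0.5))
  hi <- pixel_loss(lg, class_index(tax, "meat"), default_penalty_matrix(3, 0.5))
  expect_equal(hi / lo, 1.5)
  correct <- rep(0, 13); correct[1] <- 4  # predicts meat
  expect_equal(pixel_loss(correct, 0, default_penalty_matrix(2, 0.5)),
               pixel_loss(correct, 0, default_penalty_matrix(9, 0.5)))
})

test_that("the default penalty matrix encodes the cost asymmetry", {
  tax <- hsi_taxonomy()
  W <- default_penalty_matrix(2, 0.5, tax)
  expect_equal(W["meat", "pehd"], 2)
  expect_equal(W["fat", "wood"], 2)
  expect_equal(W["conveyor_belt", "wood"], 0.5)
  expect_equal(unname(diag(W)), rep(1, 13))
  expect_equal(W["meat", "fat"], 1)          # background confusions neutral
  expect_equal(W["pehd", "meat"], 1)         # misses are not up-weighted
  expect_error(default_penalty_matrix(0.5, 0.5), "w_high")
})

test_that("the C++ training loss agrees with the R reference per pixel", {
  set.seed(42)
  m <- vitseg_init(tiny_cfg, seed = 7)
  X <- matrix(runif(6 * 8), 6, 8)
  y <- c(0L, 1L, 2L, 3L, 255L, 1L)
  W <- matrix(runif(16, 0.5, 3), 4, 4); diag(W) <- 1
  res <- hsinspect:::cpp_vit_loss_grad(X, y, unname(m$params), 6L, 2L, FALSE,
                                       W, 0.3)
  lg <- vitseg_forward(m, X, precision = "double")
  ref <- mean(vapply(which(y != 255L), function(i)
    pixel_loss(lg[i, ], y[i], W, eps = 0.3), 0))
  expect_equal(res$loss, ref, tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences", {
  set.seed(43)
  m <- vitseg_init(tiny_cfg, seed = 7)
  X <- matrix(runif(12 * 8), 12, 8)
  y <- c(0L, 1L, 2L, 3L, 255L, 0L, 1L, 1L, 2L, 255L, 3L, 0L)
  W <- matrix(1, 4, 4)
  gr <- hsinspect:::cpp_vit_loss_grad(X, y, unname(m$params), 6L, 2L, FALSE,
                                      W, 0.3)
  h <- 1e-5
  for (pi in seq_along(m$params)) {
    pm <- unname(m$params)
    for (k in sample(length(pm[[pi]]), min(3, length(pm[[pi]])))) {
      pp <- pm; pp[[pi]][k] <- pp[[pi]][k] + h
      lp <- hsinspect:::cpp_vit_loss_grad(X, y, pp, 6L, 2L, FALSE, W, 0.3)$loss
      pn <- pm; pn[[pi]][k] <- pn[[pi]][k] - h
      lm <- hsinspect:::cpp_vit_loss_grad(X, y, pn, 6L, 2L, FALSE, W, 0.3)$loss
      num <- (lp - lm) / (2 * h)
      # absolute comparison: many gradients are legitimately ~0
      expect_lt(abs(gr$grads[[pi]][k] - num), 1e-7 * (1 + abs(num)))
    }
  }
})

test_that("learning rate warms up linearly then decays polynomially to 0", {
  cfg <- train_config(epochs = 24, warmup_epochs = 3, lr = 1e-3)
  spe <- 100
  expect_equal(lr_at(0, cfg, spe), 0)
  expect_equal(lr_at(150, cfg, spe), 1e-3 / 2)
  expect_equal(lr_at(3 * spe, cfg, spe), 1e-3)      # end of warmup: peak
  expect_equal(lr_at(24 * spe, cfg, spe), 0)        # final step: zero
  mid <- lr_at(13.5 * 100, cfg, spe)
  expect_equal(mid, 1e-3 * 0.5)                     # linear decay midpoint
  sq <- train_config(epochs = 24, warmup_epochs = 3, lr = 1e-3, poly_power = 2)
  expect_equal(lr_at(13.5 * 100, sq, spe), 1e-3 * 0.25)
  expect_error(train_config(epochs = 2, warmup_epochs = 3), "warmup")
})

test_that("training is deterministic and can overfit a small tile set", {
  tiles <- fake_tiles(6, tiny_cfg, seed = 44)
  cfg <- train_config(epochs = 60, batch_size = 3, lr = 1e-2,
                      warmup_epochs = 2, seed = 9,
                      penalty = matrix(1, 4, 4))
  f1 <- train_vitseg(tiles, tiny_cfg, cfg)
  f2 <- train_vitseg(tiles, tiny_cfg, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model$params, f2$model$params)
  expect_gt(tail(f1$history$acc, 1), 0.95)
  expect_lt(tail(f1$history$loss, 1), f1$history$loss[1])
})

test_that("unlabelled-only and single-class training sets are rejected", {
  t1 <- fake_tiles(2, tiny_cfg, seed = 45)
  t1[[1]]$mask[] <- 255L; t1[[2]]$mask[] <- 255L
  expect_error(train_vitseg(t1, tiny_cfg, train_config(penalty = matrix(1, 4, 4))),
               "no annotated")
  t2 <- fake_tiles(2, tiny_cfg, seed = 45)
  t2[[1]]$mask[] <- 1L; t2[[2]]$mask[] <- 1L
  expect_error(train_vitseg(t2, tiny_cfg, train_config(penalty = matrix(1, 4, 4))),
               "2 classes")
})

test_that("validation selects the best epoch and 255 pixels stay out of the loss", {
  tiles <- fake_tiles(6, tiny_cfg, seed = 46)
  # half-unannotated masks still train (context kept, loss masked)
  for (i in seq_along(tiles)) tiles[[i]]$mask[1, ] <- 255L
  val <- fake_tiles(2, tiny_cfg, seed = 47)
  cfg <- train_config(epochs = 4, batch_size = 6, lr = 5e-3, warmup_epochs = 1,
                      seed = 10, penalty = matrix(1, 4, 4))
  fit <- train_vitseg(tiles, tiny_cfg, cfg, validation = val)
  expect_true("val_miou" %in% names(fit$history))
  expect_true(all(fit$history$val_miou >= 0 & fit$history$val_miou <= 1))
})
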