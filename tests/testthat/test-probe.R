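test_that("boundary training: count, accuracy profile, symmetry, errors", {
  cfg <- fx_gen_cfg()
  ds <- fx_codes(40, seed = 202)
  lat <- fx_codes_array(ds)
  bds <- train_layer_boundaries(lat, ds$labels, seed = 5)
  expect_length(bds, cfg$L)

  acc <- vapply(bds, `[[`, 0, "cv_accuracy")
  expect_true(all(acc[cfg$groups$middle] >= 0.9))
  expect_true(all(acc[cfg$groups$early] <= 0.65))
  expect_true(all(vapply(bds, function(b)
    b$C_selected >= 0.001 && b$C_selected <= 0.1, TRUE)))

  # label flip negates weights and bias (single layer for speed)
  flip <- ifelse(ds$labels == "milky", "glycerin", "milky")
  b1 <- train_layer_boundaries(lat[, 8, , drop = FALSE], ds$labels, seed = 5)
  b2 <- train_layer_boundaries(lat[, 8, , drop = FALSE], flip, seed = 5)
  expect_equal(b1[[1]]$weights, -b2[[1]]$weights, tolerance = 1e-4)
  expect_equal(b1[[1]]$bias, -b2[[1]]$bias, tolerance = 1e-4)

  expect_error(train_layer_boundaries(lat, rep("milky", nrow(lat)), seed = 1),
               "both material classes")
  mix <- c(1:5, 41:45)   # both classes present, but n < 20
  expect_error(train_layer_boundaries(lat[mix, , , drop = FALSE],
                                      ds$labels[mix], seed = 1), "n >= 20")
})

test_that("probing is layer-local and scale-invariant in CV accuracy", {
  cfg <- fx_gen_cfg()
  ds <- fx_codes(25, seed = 303)
  lat <- fx_codes_array(ds)
  b8 <- train_layer_boundaries(lat[, 8, , drop = FALSE], ds$labels,
                               seed = 2)[[1]]
  b8$layer_index <- 8L
  b8 <- calibrate_boundary(b8, ds$codes)
  code <- ds$codes[[3]]
  zeroed <- code; zeroed[-8, ] <- 0
  expect_identical(predict_translucency(code, b8),
                   predict_translucency(latent_code(unclass(zeroed)), b8))

  sc <- train_layer_boundaries(lat[, 8, , drop = FALSE] * 5, ds$labels,
                               seed = 2)[[1]]
  expect_equal(sc$cv_accuracy,
               train_layer_boundaries(lat[, 8, , drop = FALSE], ds$labels,
                                      seed = 2)[[1]]$cv_accuracy,
               tolerance = 0.05)
})

test_that("normalised-distance predictions: bounds, order, errors", {
  ds <- fx_codes(25, seed = 303)
  lat <- fx_codes_array(ds)
  bd <- train_layer_boundaries(lat[, 8, , drop = FALSE], ds$labels,
                               seed = 2)[[1]]
  bd$layer_index <- 8L
  expect_error(predict_translucency(ds$codes[[1]], bd), "norm_bounds")
  bd <- calibrate_boundary(bd, ds$codes)
  scores <- vapply(ds$codes, predict_translucency, 0, boundary = bd)
  raws <- vapply(ds$codes, lucent:::raw_translucency_distance, 0,
                 boundary = bd)
  expect_equal(scores[which.min(raws)], 0)
  expect_equal(scores[which.max(raws)], 1)
  expect_identical(order(scores), order(raws))   # order-preserving

  # a code placed exactly on the boundary has raw distance 0
  x <- -bd$bias * bd$weights / sum(bd$weights^2)
  on_b <- ds$codes[[1]]; on_b[8, ] <- x
  expect_lt(abs(lucent:::raw_translucency_distance(
    latent_code(unclass(on_b)), bd)), 1e-10)
})

test_that("tuning curve: self-consistency, permutation null, peak location", {
  cfg <- fx_gen_cfg()
  ds <- fx_codes(30, seed = 404)
  lat <- fx_codes_array(ds)
  bds <- train_layer_boundaries(lat, ds$labels, seed = 7)
  bds <- lapply(bds, calibrate_boundary, eval_codes = ds$codes)

  # ratings equal to the layer-9 score give r = 1 at layer 9
  s9 <- vapply(ds$codes, predict_translucency, 0, boundary = bds[[9]])
  tc <- tuning_curve(bds, ds$codes, data.frame(translucency = s9))
  expect_equal(tc$r[tc$layer == 9], 1, tolerance = 1e-12)

  # permuted ratings decorrelate everywhere (averaged over permutations)
  perm_r <- withr::with_seed(11, {
    sapply(1:50, function(i) {
      tcp <- tuning_curve(bds, ds$codes,
                          data.frame(translucency = sample(s9)))
      tcp$r
    })
  })
  expect_lt(max(abs(rowMeans(perm_r))), 0.15)

  # ratings generated from tau put the peak in the middle group
  ratings <- normalize_ratings(simulate_ratings(ds$factors, seed = 5))$ratings
  tcf <- tuning_curve(bds, ds$codes, ratings)
  tr <- tcf[tcf$attribute == "translucency", ]
  expect_true(tr$layer[which.max(tr$r)] %in% cfg$groups$middle)

  # alignment and degenerate input handling
  expect_error(tuning_curve(bds, ds$codes[1:5],
                            data.frame(translucency = s9)), "align")
  tc0 <- tuning_curve(bds, ds$codes,
                      data.frame(flat = rep(0.5, length(ds$codes))))
  expect_true(all(is.na(tc0$r)))
})

test_that("MDS reproduces collinear configurations and pads dimensions", {
  X <- cbind(c(0, 1, 2), c(0, 0, 0))
  emb <- mds_embed(X, 2, seed = 3)
  expect_lt(attr(emb, "stress"), 1e-4)
  d0 <- as.vector(dist(X)); d1 <- as.vector(dist(emb))
  expect_lt(max(abs(d0 - d1) / d0), 0.01)
})

test_that("tsne embeds jointly with the requested shape; errors on bad perplexity", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  })
  emb <- tsne_embed(X, 3, perplexity = 8, max_iter = 60, seed = 2)
  expect_identical(dim(emb), c(40L, 3L))
  # the two well-separated clusters stay separated
  lab <- rep(1:2, each = 20)
  within <- mean(dist(emb[lab == 1, ])) + mean(dist(emb[lab == 2, ]))
  between <- mean(as.matrix(dist(emb))[lab == 1, lab == 2])
  expect_gt(between, within / 2)
  expect_error(tsne_embed(X, 2, perplexity = 45), "perplexity")
})

test_that("pixel_embedding_baseline returns a joint embedding and a curve", {
  cfg <- fx_gen_cfg(resolution = 32)
  ds <- fx_codes(12, seed = 505, cfg = cfg)
  imgs <- lapply(ds$codes, function(cd) decode(cd, cfg)$image)
  ev <- imgs[c(1:5, 20:24)]
  ratings <- data.frame(translucency =
    vapply(ds$factors[c(1:5, 20:24)], function(f) f$tau, 0))
  bl <- pixel_embedding_baseline(imgs, ds$labels, ev, ratings,
                                 method = "mds", embed_dim = 4,
                                 pixel_res = 16, seed = 2)
  expect_identical(dim(bl$embedding), c(length(imgs) + length(ev), 4L))
  expect_true(all(bl$scores >= 0 & bl$scores <= 1))
  expect_identical(nrow(bl$curve), 1L)
  expect_error(pixel_embedding_baseline(imgs, ds$labels, ev, ratings,
                                        method = "tsne", perplexity = 100),
               "perplexity")
})
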