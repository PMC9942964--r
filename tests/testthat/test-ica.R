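test_that("swap-pair count law", {
  expect_identical(nrow(swap_pairs(1:40, 1:80)), 3160L)   # targets included
  expect_identical(nrow(swap_pairs(1:40, 41:120)), 3200L) # disjoint sources
  expect_identical(nrow(swap_pairs(1, 1:2)), 1L)
})

test_that("build_high_translucency_set selects top-rated targets and swaps", {
  cfg <- fx_gen_cfg()
  ds <- fx_codes(8)
  ratings <- withr::with_seed(4, runif(length(ds$codes)))
  hi <- build_high_translucency_set(ds$codes, ratings, cfg, n_targets = 3,
                                    n_extra_sources = 3, render = FALSE)
  expect_identical(hi$target_idx,
                   order(ratings, decreasing = TRUE)[1:3])
  expect_identical(nrow(hi$pairs), 6L * 3L - 3L)
  expect_error(build_high_translucency_set(ds$codes, ratings, cfg,
                                           n_targets = 100), "exceeds")

  hi2 <- build_high_translucency_set(ds$codes, ratings, cfg, n_targets = 2,
                                     n_extra_sources = 1, render = TRUE)
  expect_length(hi2$images, nrow(hi2$pairs))
  # the kept render is the material-scale intermediate (half of 48 px here;
  # 64 px at the canonical 128 px output resolution)
  expect_identical(attr(hi2$images[[1]], "resolution"), 24L)
  # the swapped image equals decoding the source code with target middle rows
  r <- 1
  cd <- ds$codes[[hi2$pairs$source[r]]]
  cd[cfg$groups$middle, ] <- ds$codes[[hi2$pairs$target[r]]][cfg$groups$middle, ]
  expect_identical(hi2$images[[r]],
                   decode(latent_code(unclass(cd)), cfg)$intermediates[[2]]$image)
})

test_that("sample_patches: counts, determinism, verbatim content", {
  imgs <- lapply(1:3, function(i) render_scene(sample_scene(i), 32))
  P <- sample_patches(imgs, resize_to = 64, patch = 8, per_image = 5, seed = 9)
  expect_identical(dim(P), c(15L, 8L * 8L * 3L))
  P2 <- sample_patches(imgs, resize_to = 64, patch = 8, per_image = 5, seed = 9)
  expect_identical(P, P2)
  expect_error(sample_patches(imgs, resize_to = 16, patch = 24), "exceed")

  # a patch's values appear verbatim in the resized source image
  big <- resize_bilinear(unclass(imgs[[1]]), 64)
  pat <- array(P[1, ], c(8, 8, 3))
  hit <- FALSE
  for (oy in 1:(64 - 7)) for (ox in 1:(64 - 7)) {
    if (isTRUE(all.equal(big[oy:(oy + 7), ox:(ox + 7), ], pat,
                         tolerance = 1e-12))) hit <- TRUE
  }
  expect_true(hit)
})

test_that("ICA recovers known sparse sources and yields decorrelated responses", {
  p <- 6; nsrc <- 8; n <- 1600
  withr::with_seed(21, {
    S_true <- matrix(rnorm(nsrc * p * p * 3), nsrc)
    coef <- matrix(rnorm(n * nsrc) * (runif(n * nsrc) < 0.25), n)
  })
  X <- coef %*% S_true
  attr(X, "patch") <- p
  bank <- learn_ica_kernels(X, K = nsrc, seed = 31)
  expect_identical(dim(bank$kernels), as.integer(c(p, p, 3, nsrc)))
  expect_equal(apply(bank$kernels, 4, function(k) sum(k^2)),
               rep(1, nsrc), tolerance = 1e-9)
  expect_true(all(diff(bank$negentropy) <= 1e-12))  # descending order

  rec <- vapply(seq_len(nsrc), function(k) as.vector(bank$kernels[, , , k]),
                numeric(p * p * 3))
  match_r <- apply(abs(cor(rec, t(S_true))), 2, max)
  expect_true(all(match_r >= 0.9))

  # reproducibility and error paths
  bank2 <- learn_ica_kernels(X, K = nsrc, seed = 31)
  expect_identical(bank$kernels, bank2$kernels)
  expect_error(learn_ica_kernels(X[1:50, ], K = nsrc), "10\\*K")
  low <- coef[, 1:2] %*% S_true[1:2, ]
  attr(low, "patch") <- p
  expect_error(learn_ica_kernels(low, K = nsrc), "rank")
})

test_that("whitened ICA source responses are uncorrelated", {
  p <- 5; nsrc <- 6; n <- 1200
  withr::with_seed(5, {
    S_true <- matrix(rnorm(nsrc * p * p * 3), nsrc)
    coef <- matrix(rnorm(n * nsrc)^3, n)   # heavy-tailed activations
  })
  X <- coef %*% S_true
  attr(X, "patch") <- p
  bank <- learn_ica_kernels(X, K = nsrc, seed = 2)
  # project patches on the kernels and check response decorrelation
  Xc <- sweep(X, 2, colMeans(X))
  B <- vapply(seq_len(nsrc), function(k) as.vector(bank$kernels[, , , k]),
              numeric(p * p * 3))
  resp <- Xc %*% B %*% solve(crossprod(B))   # coefficients in the basis
  cc <- cor(resp)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("kernel classification: chromaticity, orientation, angles", {
  p <- 24
  xs <- (1:p - (p + 1) / 2) / p
  X <- matrix(xs, p, p, byrow = TRUE); Y <- matrix(rev(xs), p, p)
  mkbank <- function(ker) {
    ker <- ker / sqrt(sum(ker^2))
    structure(list(kernels = array(ker, c(p, p, 3, 1)), K = 1L, patch = p),
              class = "kernel_bank")
  }
  # gray kernel: achromatic
  g <- exp(-(X^2 + Y^2) / 0.02)
  ann <- classify_kernels(mkbank(array(rep(g, 3), c(p, p, 3))))$annotations
  expect_identical(ann$chromaticity, "achromatic")

  # R = -G Gabor: chromatic, oriented, angle within 10 degrees
  for (ang in c(20, 70, 140)) {
    th <- ang * pi / 180
    gb <- exp(-(X^2 + Y^2) / (2 * 0.18^2)) *
      cos(2 * pi * 3 * (X * cos(th) + Y * sin(th)))
    ker <- array(0, c(p, p, 3)); ker[, , 1] <- gb; ker[, , 2] <- -gb
    ann <- classify_kernels(mkbank(ker))$annotations
    expect_identical(ann$chromaticity, "chromatic")
    expect_identical(ann$orientation, "oriented")
    dd <- abs(ann$angle_deg - (ang + 90) %% 180)
    expect_lt(min(dd, 180 - dd), 10)
  }

  # isotropic center-surround: orientation-free
  cs <- exp(-(X^2 + Y^2) / (2 * 0.1^2)) - 0.5 * exp(-(X^2 + Y^2) / (2 * 0.2^2))
  ann <- classify_kernels(mkbank(array(rep(cs, 3), c(p, p, 3))))$annotations
  expect_identical(ann$orientation, "orientation-free")
})

test_that("filter_image: zero-mean on constants, delta identity, linearity", {
  withr::with_seed(3, {
    img <- array(runif(32 * 32 * 3), c(32, 32, 3))
    img2 <- array(runif(32 * 32 * 3), c(32, 32, 3))
    ker <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  })
  ker0 <- ker - mean(ker)
  flat <- array(0.7, c(32, 32, 3))
  expect_lt(max(abs(filter_image(flat, ker0))), 1e-10)

  delta <- array(0, c(5, 5, 3)); delta[3, 3, 2] <- 1
  expect_equal(filter_image(img, delta), img[, , 2], tolerance = 1e-12)

  lin <- filter_image(0.3 * img + 0.6 * img2, ker)
  expect_equal(lin, 0.3 * filter_image(img, ker) + 0.6 * filter_image(img2, ker),
               tolerance = 1e-10)
  expect_error(filter_image(array(0, c(4, 4, 3)), ker), "smaller")
})

test_that("translucency response contrast: sign, zero, chromatic top kernel", {
  cfg <- fx_gen_cfg()
  hi <- lapply(1:6, function(i) {
    f <- sample_scene(i, "glycerin"); f$tau <- 0.95
    render_scene(f, 48)
  })
  lo <- lapply(1:6, function(i) {
    f <- sample_scene(i, "glycerin"); f$tau <- 0.05
    render_scene(f, 48)
  })
  masks_hi <- lapply(hi, object_mask); masks_lo <- lapply(lo, object_mask)

  # small bank learned from the translucent renders themselves
  P <- sample_patches(hi, resize_to = 96, patch = 8, per_image = 40, seed = 2)
  bank <- classify_kernels(learn_ica_kernels(P, K = 8, seed = 3))

  ct <- translucency_response_contrast(hi, lo, bank, masks_hi, masks_lo)
  expect_identical(nrow(ct), 8L)
  top <- ct$kernel[which.max(ct$contrast)]
  expect_identical(bank$annotations$chromaticity[top], "chromatic")

  # identical sets give zero contrast; swapping the sets flips the sign
  c0 <- translucency_response_contrast(hi, hi, bank, masks_hi, masks_hi)
  expect_true(all(abs(c0$contrast) < 1e-12))
  cs <- translucency_response_contrast(lo, hi, bank, masks_lo, masks_hi)
  expect_equal(cs$contrast, -ct$contrast, tolerance = 1e-9)
})
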