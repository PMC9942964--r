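#' Ordered source-target pairs for the middle-layer swap construction
#'
#' Self-pairs are excluded: with `n_targets` targets also serving among the
#' sources, `n_sources * n_targets - n_overlap` pairs remain (40 targets and
#' 80 sources containing them give 3160).
#'
#' @param target_idx,source_idx integer index vectors (targets may occur in
#'   the sources)
#' @return data frame with columns `source`, `target`
#' @export
swap_pairs <- function(target_idx, source_idx) {
  g <- expand.grid(source = source_idx, target = target_idx)
  g[g$source != g$target, , drop = FALSE]
}

#' Build the high-translucency intermediate-image set by middle-layer swap
#'
#' Targets are the `n_targets` top-rated images by mean translucency rating;
#' sources are the targets plus `n_extra_sources` further images.  For every
#' ordered (source, target) pair with source != target, the source code's
#' middle-group rows are replaced by the target's and the result is decoded,
#' keeping the 64 x 64 material-scale intermediate render.
#'
#' @param codes list of `latent_code`s
#' @param translucency_ratings per-code mean translucency ratings
#' @param cfg `generator_config`
#' @param n_targets number of top-rated targets (default 40)
#' @param n_extra_sources additional non-target sources (default 40)
#' @param render decode images (set FALSE for count-only/lazy use)
#' @return list with `pairs` (data frame), `images` (list of 64 x 64
#'   `stimulus_image`, or NULL), `target_idx`, `source_idx`
#' @export
build_high_translucency_set <- function(codes, translucency_ratings, cfg,
                                        n_targets = 40L,
                                        n_extra_sources = 40L,
                                        render = TRUE) {
  n <- length(codes)
  stopifnot(length(translucency_ratings) == n)
  if (n_targets > n)
    stopf("n_targets (%d) exceeds available images (%d)", n_targets, n)
  if (n_targets + n_extra_sources > n)
    stopf("need %d images, have %d", n_targets + n_extra_sources, n)
  ord <- order(translucency_ratings, decreasing = TRUE)
  target_idx <- ord[seq_len(n_targets)]
  source_idx <- c(target_idx,
                  setdiff(ord, target_idx)[seq_len(n_extra_sources)])
  pairs <- swap_pairs(target_idx, source_idx)
  mids <- cfg$groups$middle
  images <- NULL
  if (render) {
    images <- lapply(seq_len(nrow(pairs)), function(r) {
      cd <- codes[[pairs$source[r]]]
      cd[mids, ] <- codes[[pairs$target[r]]][mids, ]
      dec <- decode(latent_code(unclass(cd)), cfg)
      dec$intermediates[[2]]$image   # 64 x 64 material-scale render
    })
  }
  list(pairs = pairs, images = images,
       target_idx = target_idx, source_idx = source_idx)
}

#' Sample random square patches from a set of images
#'
#' Each image is first resized (bilinear) to `resize_to` per side, then
#' `per_image` patches of `patch x patch` pixels are cut at uniform random
#' valid offsets.
#'
#' @param images list of H x W x 3 arrays
#' @param resize_to working resolution (default 512)
#' @param patch patch side length (default 24); must not exceed `resize_to`
#' @param per_image patches per image (default 10)
#' @param seed integer seed
#' @return matrix `n_patches x (patch * patch * 3)`; attribute `patch`
#'   records the side length
#' @export
sample_patches <- function(images, resize_to = 512L, patch = 24L,
                           per_image = 10L, seed = 1L) {
  if (patch > resize_to)
    stopf("patch (%d) must not exceed resize_to (%d)", patch, resize_to)
  out <- with_seed(seed, {
    res <- lapply(images, function(im) {
      big <- resize_bilinear(unclass(im), resize_to)
      t(vapply(seq_len(per_image), function(j) {
        oy <- sample.int(resize_to - patch + 1L, 1L)
        ox <- sample.int(resize_to - patch + 1L, 1L)
        as.vector(big[oy:(oy + patch - 1L), ox:(ox + patch - 1L), ])
      }, numeric(patch * patch * 3)))
    })
    do.call(rbind, res)
  })
  attr(out, "patch") <- as.integer(patch)
  out
}

# symmetric FastICA (logcosh nonlinearity) on pre-whitened data; deterministic
fastica_core <- function(Z, K, seed, max_iter = 500, tol = 1e-7) {
  W <- with_seed(seed, matrix(rnorm(K * K), K, K))
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  n <- ncol(Z)
  for (it in seq_len(max_iter)) {
    S <- W %*% Z                       # K x n
    G <- tanh(S)
    Gp <- 1 - G^2
    W1 <- G %*% t(Z) / n - diag(rowMeans(Gp)) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Learn ICA basis kernels from image patches
#'
#' Column-centres the patch matrix, whitens with the top-K principal
#' components, runs symmetric fixed-point ICA (logcosh contrast), and
#' returns the mixing-matrix columns as unit-norm p x p x 3 kernels,
#' ordered by descending non-Gaussianity of their source activations, with
#' each kernel's sign fixed so its maximum-magnitude coefficient is
#' positive.
#'
#' @param patches matrix from [sample_patches()] (or any n x (p*p*3) matrix
#'   with a `patch` attribute / `patch` argument)
#' @param K number of basis functions (default 64)
#' @param seed integer seed (initial rotation)
#' @param patch patch side length; defaults to the matrix attribute
#' @return list of class `kernel_bank`: `kernels` (p x p x 3 x K array),
#'   `negentropy` (descending), `patch`, `K`; annotations are added by
#'   [classify_kernels()]
#' @export
learn_ica_kernels <- function(patches, K = 64L, seed = 1L,
                              patch = attr(patches, "patch")) {
  stopifnot(is.matrix(patches))
  n <- nrow(patches); p2 <- ncol(patches)
  if (n < 10L * K)
    stopf("need at least 10*K = %d patches, got %d", 10L * K, n)
  if (is.null(patch)) stopf("patch size unknown; pass `patch`")
  mu <- colMeans(patches)
  Xc <- sweep(patches, 2, mu)
  sv <- svd(Xc, nu = 0, nv = K)
  dK <- sv$d[seq_len(K)]
  if (dK[K] < 1e-10 * dK[1])
    stopf("patch matrix is rank deficient for K = %d components", K)
  # whitened rows: Z = V' X' * sqrt(n)/d
  Z <- t(Xc %*% sv$v) * sqrt(n) / dK            # K x n
  W <- fastica_core(Z, K, seed)
  S <- W %*% Z
  # mixing (basis) functions in the original patch space
  A <- sv$v %*% (t(W) * dK / sqrt(n))           # p2 x K
  # non-Gaussianity score: squared deviation of E[log cosh s] from Gaussian
  g0 <- 0.3745672   # E[log cosh z], z ~ N(0,1)
  ng <- (rowMeans(log(cosh(S))) - g0)^2
  ord <- order(ng, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]; ng <- ng[ord]
  kerns <- array(0, c(patch, patch, 3, K))
  for (k in seq_len(K)) {
    v <- A[, k]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    kerns[, , , k] <- array(v, c(patch, patch, 3))
  }
  structure(list(kernels = kerns, negentropy = ng, patch = as.integer(patch),
                 K = as.integer(K)),
            class = "kernel_bank")
}

#' Annotate kernels as chromatic/achromatic and oriented/orientation-free
#'
#' Chromaticity: fraction of kernel energy in the deviations of each channel
#' from the pixelwise channel mean; above `chroma_threshold` = chromatic.
#' Orientation: anisotropy of the summed per-channel structure tensor;
#' above `aniso_threshold` = oriented, with the dominant angle (degrees,
#' \[0, 180)) reported.
#'
#' @param bank `kernel_bank`
#' @param chroma_threshold default 0.2
#' @param aniso_threshold default 0.4
#' @return the bank with an `annotations` data frame: `kernel`,
#'   `chromaticity`, `orientation`, `angle_deg`, `chroma_energy`,
#'   `anisotropy`
#' @export
classify_kernels <- function(bank, chroma_threshold = 0.2,
                             aniso_threshold = 0.4) {
  stopifnot(inherits(bank, "kernel_bank"))
  rows <- lapply(seq_len(bank$K), function(k) {
    ker <- bank$kernels[, , , k]
    m <- (ker[, , 1] + ker[, , 2] + ker[, , 3]) / 3
    # both energies on the mean-removed kernel: the DC pedestal carries no
    # feature structure and can never be chromatic, so including it in the
    # denominator would bias DC-heavy kernels toward "achromatic"
    ac <- sum((ker - mean(ker))^2)
    chroma_e <- if (ac < 1e-12) 0 else
      sum((ker - array(m, dim(ker)))^2) / ac
    # structure tensor summed over channels
    jxx <- jyy <- jxy <- 0
    for (c_ in 1:3) {
      pl <- ker[, , c_]
      gx <- (cbind(pl[, -1], pl[, ncol(pl)]) - cbind(pl[, 1], pl[, -ncol(pl)])) / 2
      gy <- (rbind(pl[-1, , drop = FALSE], pl[nrow(pl), , drop = FALSE]) -
               rbind(pl[1, , drop = FALSE], pl[-nrow(pl), , drop = FALSE])) / 2
      jxx <- jxx + sum(gx^2); jyy <- jyy + sum(gy^2); jxy <- jxy + sum(gx * gy)
    }
    tr <- jxx + jyy
    aniso <- if (tr < 1e-12) 0 else
      sqrt((jxx - jyy)^2 + 4 * jxy^2) / tr
    # row index increases downward; negate jxy for the y-up image convention
    ang <- (atan2(-2 * jxy, jxx - jyy) / 2) * 180 / pi
    # gradient angle -> stripe orientation is perpendicular
    ang <- (ang + 90) %% 180
    data.frame(kernel = k,
               chromaticity = if (chroma_e > chroma_threshold)
                 "chromatic" else "achromatic",
               orientation = if (aniso > aniso_threshold)
                 "oriented" else "orientation-free",
               angle_deg = if (aniso > aniso_threshold) ang else NA_real_,
               chroma_energy = chroma_e, anisotropy = aniso)
  })
  bank$annotations <- do.call(rbind, rows)
  bank
}

#' Filter an RGB image with a 3-channel kernel
#'
#' Channel-summed cross-correlation (no kernel flip) with reflect padding
#' and 'same' output size.
#'
#' @param image H x W x 3 array (spatial dims >= kernel's)
#' @param kernel p x p x 3 array
#' @return H x W response matrix
#' @export
filter_image <- function(image, kernel) {
  stopifnot(length(dim(image)) == 3L, length(dim(kernel)) == 3L)
  if (nrow(image) < nrow(kernel) || ncol(image) < ncol(kernel))
    stopf("image (%dx%d) smaller than kernel (%dx%d)",
          nrow(image), ncol(image), nrow(kernel), ncol(kernel))
  r <- xcorr2_same(image[, , 1], kernel[, , 1]) +
    xcorr2_same(image[, , 2], kernel[, , 2]) +
    xcorr2_same(image[, , 3], kernel[, , 3])
  r
}

# derive an object mask from an image by deviation from the border color
infer_mask <- function(image) {
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  n <- nrow(lum)
  border <- c(lum[1, ], lum[n, ], lum[, 1], lum[, n])
  dev <- abs(lum - median(border))
  m <- dev > 0.12
  # keep the central connected blob heuristically: drop border-touching noise
  m
}

#' Per-kernel translucency response contrast
#'
#' For every kernel: the mean absolute filter response within an edge band
#' of the object mask, averaged over the translucent set minus the opaque
#' set, standardised by the pooled across-image standard deviation.
#'
#' @param images_translucent,images_opaque nonempty lists of images
#' @param bank `kernel_bank`
#' @param masks_translucent,masks_opaque optional lists of logical masks;
#'   inferred from the images when omitted
#' @param band edge band width in pixels (default 1/8 of image side)
#' @return data frame `kernel`, `contrast`, `mean_translucent`,
#'   `mean_opaque`
#' @export
translucency_response_contrast <- function(images_translucent, images_opaque,
                                           bank,
                                           masks_translucent = NULL,
                                           masks_opaque = NULL,
                                           band = NULL) {
  stopifnot(length(images_translucent) > 0, length(images_opaque) > 0)
  edge_mean <- function(img, mask) {
    if (is.null(mask)) mask <- infer_mask(img)
    n <- nrow(mask)
    b <- band %||% max(3L, round(n / 8))
    d <- dist_transform(mask)
    sel <- d >= 1 & d <= b
    if (!any(sel)) stopf("empty mask edge band")
    vapply(seq_len(bank$K), function(k)
      mean(abs(filter_image(img, bank$kernels[, , , k])[sel])), 0)
  }
  resp_set <- function(images, masks) {
    t(vapply(seq_along(images), function(i)
      edge_mean(images[[i]], if (is.null(masks)) NULL else masks[[i]]),
      numeric(bank$K)))
  }
  Mt <- resp_set(images_translucent, masks_translucent)
  Mo <- resp_set(images_opaque, masks_opaque)
  mt <- colMeans(Mt); mo <- colMeans(Mo)
  colvar0 <- function(M) if (nrow(M) < 2) rep(0, ncol(M)) else apply(M, 2, var)
  v <- (colvar0(Mt) * (nrow(Mt) - 1) + colvar0(Mo) * (nrow(Mo) - 1)) /
    max(1, nrow(Mt) + nrow(Mo) - 2)
  sdp <- sqrt(pmax(v, 1e-300))
  data.frame(kernel = seq_len(bank$K), contrast = (mt - mo) / sdp,
             mean_translucent = mt, mean_opaque = mo)
}
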