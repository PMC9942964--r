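#' Layer groups of the latent code
#'
#' Contiguous latent layers operating at coarse/middle/fine spatial scales.
#' Defaults follow the 18-layer convention: early = layers 1-6 (shape,
#' orientation, lighting direction), middle = layers 7-9 (material:
#' translucency and backlight strength), late = layers 10-18 (body color and
#' fine texture).
#'
#' @param early,middle,late integer index vectors; must be disjoint,
#'   nonempty, and cover `1:L`
#' @return list of class `layer_groups`
#' @export
layer_groups <- function(early = 1:6, middle = 7:9, late = 10:18) {
  all_ <- sort(c(early, middle, late))
  if (anyDuplicated(all_) || length(early) == 0 || length(middle) == 0 ||
      length(late) == 0 || !identical(all_, seq_len(length(all_))))
    stopf("layer groups must be disjoint, nonempty, and cover 1..L")
  structure(list(early = early, middle = middle, late = late),
            class = "layer_groups")
}

# factor names controlled by each group
group_factor_names <- list(
  early = c(paste0("ca", 2:5), paste0("cb", 2:5), "az_c", "az_s"),
  middle = c("tau", "backlight_strength"),
  late = c("color_r", "color_g", "color_b", "texture_strength"))

# hard clamp ranges per factor (saturating; decode never errors)
factor_ranges <- function() {
  lo <- c(rep(-0.25, 8), rep(-1, 2), 0, 0, rep(0.05, 3), 0)
  hi <- c(rep(0.25, 8), rep(1, 2), 1, 1, rep(1, 3), 0.3)
  nm <- unlist(group_factor_names, use.names = FALSE)
  data.frame(factor = nm, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

#' Build an analytic layer-wise generator configuration
#'
#' The generator replaces a trained style-based image synthesis network with
#' an analytic construction: an `L x d` latent code in which each layer
#' group controls its factor subset through a full-row-rank affine map
#' `f_g = scale * A_g w_g + b_g` (`A_g` has orthonormal rows over the
#' concatenated group rows).  Remaining latent directions are nuisance
#' dimensions filled with seeded Gaussian noise, so probes must learn to
#' ignore irrelevant directions.
#'
#' @param L number of layers (default 18)
#' @param d layer width (default 16; the probing/editing math is
#'   dimension-agnostic, larger widths are for stress tests)
#' @param groups a [layer_groups()]
#' @param signal_scale latent-units-per-factor-unit gain; factors map to
#'   latent excursions of about `1/signal_scale`
#' @param nuisance_sd standard deviation of the seeded nuisance dimensions
#' @param seed integer seed fixing the random orthonormal maps
#' @param resolution output resolution of the full render
#' @return list of class `generator_config`
#' @export
generator_config <- function(L = 18L, d = 16L, groups = layer_groups(),
                             signal_scale = 0.25, nuisance_sd = 0.25,
                             seed = 1234L, resolution = 128L) {
  L <- as.integer(L); d <- as.integer(d)
  stopifnot(max(unlist(groups[c("early", "middle", "late")])) == L)
  rng <- factor_ranges()
  maps <- with_seed(seed, {
    lapply(c("early", "middle", "late"), function(g) {
      idx <- groups[[g]]
      nf <- length(group_factor_names[[g]])
      nl <- length(idx)
      if (nf > d) stopf("group '%s': more factors than layer width", g)
      # per-layer random orthonormal frames, each layer carrying an equal
      # 1/n_layers share of every factor: no layer in a group is
      # accidentally starved of signal
      A <- matrix(0, nf, nl * d)
      for (li in seq_len(nl)) {
        Q <- qr.Q(qr(matrix(rnorm(d * nf), d, nf)))[, seq_len(nf),
                                                    drop = FALSE]
        A[, (li - 1L) * d + seq_len(d)] <- t(Q) / sqrt(nl)
      }
      ri <- match(group_factor_names[[g]], rng$factor)
      list(A = A,                          # nf x p, orthonormal rows
           b = (rng$lo[ri] + rng$hi[ri]) / 2,
           lo = rng$lo[ri], hi = rng$hi[ri],
           factors = group_factor_names[[g]], layers = idx)
    })
  })
  names(maps) <- c("early", "middle", "late")
  structure(list(L = L, d = d, groups = groups, maps = maps,
                 signal_scale = signal_scale, nuisance_sd = nuisance_sd,
                 seed = as.integer(seed), resolution = as.integer(resolution)),
            class = "generator_config")
}

#' Construct a latent code object
#' @param layers L x d numeric matrix (row i = layer i's latent vector)
#' @return matrix of class `latent_code`
#' @export
latent_code <- function(layers) {
  stopifnot(is.matrix(layers), all(is.finite(layers)))
  structure(layers, class = c("latent_code", "matrix", "array"))
}

check_code <- function(code, cfg) {
  if (!is.matrix(code) || nrow(code) != cfg$L || ncol(code) != cfg$d)
    stopf("latent code must be %d x %d, got %d x %d",
          cfg$L, cfg$d, NROW(code), NCOL(code))
}

# concatenated rows of a group as one vector
group_vec <- function(code, cfg, g) as.vector(t(code[cfg$groups[[g]], , drop = FALSE]))

#' Read the clamped factor vector out of a latent code
#'
#' @param code `latent_code` matrix
#' @param cfg `generator_config`
#' @return named numeric vector over all factors (clamped to their ranges)
#' @export
decode_factors <- function(code, cfg) {
  check_code(code, cfg)
  out <- c()
  for (g in c("early", "middle", "late")) {
    m <- cfg$maps[[g]]
    f <- cfg$signal_scale * as.vector(m$A %*% group_vec(code, cfg, g)) + m$b
    out <- c(out, setNames(clamp(f, m$lo, m$hi), m$factors))
  }
  out
}

#' Encode scene factors into a latent code
#'
#' Analytic inverse of the generator's factor maps: the factor-relevant
#' latent component is `A_g^T (f_g - b_g) / scale`; the nuisance component
#' is seeded Gaussian noise projected onto the null space of `A_g`, so the
#' factor readout of the result is exact.
#'
#' @param factors `scene_factors` object (all factors within clamp ranges)
#' @param cfg `generator_config`
#' @param rng_seed seed for the nuisance dimensions
#' @return `latent_code`
#' @export
encode_factors <- function(factors, cfg, rng_seed = 0L) {
  fv <- factors_to_vec(factors)
  code <- matrix(0, cfg$L, cfg$d)
  with_seed(rng_seed, {
    for (g in c("early", "middle", "late")) {
      m <- cfg$maps[[g]]
      f <- fv[m$factors]
      bad <- f < m$lo - 1e-9 | f > m$hi + 1e-9
      if (any(bad))
        stopf("factor out of range: %s", paste(m$factors[bad], collapse = ", "))
      p <- length(m$layers) * cfg$d
      w_sig <- as.vector(crossprod(m$A, (f - m$b) / cfg$signal_scale))
      z <- rnorm(p, 0, cfg$nuisance_sd)
      w_nui <- z - as.vector(crossprod(m$A, m$A %*% z))   # null-space part
      code[m$layers, ] <- matrix(w_sig + w_nui, length(m$layers), cfg$d,
                                 byrow = TRUE)
    }
  })
  latent_code(code)
}

#' Decode a latent code into a stimulus image plus intermediate renders
#'
#' Mirrors the progressive synthesis of a style-based generator: factors are
#' read off per layer group (with hard clamping, so decoding is total), and
#' three renders are exposed from coarse to fine -- (i) a 16 x 16 shape-only
#' render driven by the early group, (ii) a 64 x 64 material-scale render
#' (shape + translucency, neutral body color), the scale at which
#' translucency cues are established, and (iii) the full render at the
#' configured output resolution.
#'
#' @param code `latent_code`
#' @param cfg `generator_config`
#' @return list with `image` (full render), `factors` (clamped readout,
#'   named vector), and `intermediates`: list of `(resolution, image)` pairs
#'   ordered coarse to fine, final entry identical to `image`
#' @export
decode <- function(code, cfg) {
  fv <- decode_factors(code, cfg)
  f <- vec_to_factors(fv)
  full <- render_scene(f, cfg$resolution)
  f_shape <- f
  f_shape$tau <- 0; f_shape$body_color <- rep(0.6, 3)
  f_shape$texture_strength <- 0
  f_mat <- f
  f_mat$body_color <- rep(0.6, 3); f_mat$texture_strength <- 0
  # material scale: 64 px at the canonical full resolution (>= 128), half
  # the output below that, keeping the ladder strictly increasing
  mat_res <- max(17L, min(64L, cfg$resolution %/% 2L))
  if (mat_res >= cfg$resolution) mat_res <- cfg$resolution - 1L
  intermediates <- list(
    list(resolution = 16L, image = render_scene(f_shape, 16)),
    list(resolution = mat_res, image = render_scene(f_mat, mat_res)),
    list(resolution = cfg$resolution, image = full))
  list(image = full, factors = fv, intermediates = intermediates)
}

#' Fit a linear (ridge) image encoder mapping pixels to latent codes
#'
#' Stand-in for a learned image-to-latent encoder: ridge regression from
#' downsampled RGB pixels (plus intercept) to the `L x d` latent entries.
#' Uses the dual (kernel) form when pixels outnumber training images.
#'
#' @param pairs list of `list(image =, code =)` entries; all images must
#'   share one resolution
#' @param ridge_strength nonnegative per-sample ridge penalty (the total
#'   penalty scales with n, so duplicating training pairs leaves the fit
#'   unchanged); default 0.002
#' @param feature_res images are downsampled to this side length before
#'   flattening (default 32)
#' @return list of class `image_encoder` with the coefficient matrix, the
#'   training metadata and the mean training reconstruction error
#' @export
fit_image_encoder <- function(pairs, ridge_strength = 0.002,
                              feature_res = 32L) {
  stopifnot(length(pairs) >= 2)
  res <- vapply(pairs, function(p) attr(p$image, "resolution") %||%
                  nrow(p$image), 1L)
  if (length(unique(res)) != 1L)
    stopf("inconsistent image resolutions: %s",
          paste(unique(res), collapse = ", "))
  X <- t(vapply(pairs, function(p)
    as.vector(resize_bilinear(unclass(p$image), feature_res)),
    numeric(3 * feature_res^2)))
  Y <- t(vapply(pairs, function(p) as.vector(p$code),
                numeric(length(pairs[[1]]$code))))
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  lambda <- ridge_strength * n
  if (p > n) {            # dual ridge: coef = X' (XX' + lambda I)^-1 Yc
    K <- tcrossprod(Xc)
    alpha <- solve(K + lambda * diag(n), Yc)
    B <- crossprod(Xc, alpha)
  } else {
    B <- solve(crossprod(Xc) + lambda * diag(p), crossprod(Xc, Yc))
  }
  fit <- Xc %*% B
  err <- sqrt(mean((fit - Yc)^2))
  structure(list(B = B, x_mean = xm, y_mean = ym,
                 feature_res = as.integer(feature_res),
                 train_res = res[1], n = n, ridge_strength = ridge_strength,
                 code_dim = dim(pairs[[1]]$code), train_rmse = err),
            class = "image_encoder")
}

#' Embed an image into the latent space with a fitted encoder
#'
#' @param image `stimulus_image` at the encoder's training resolution
#' @param enc an [fit_image_encoder()] result
#' @return `latent_code`
#' @export
embed_image <- function(image, enc) {
  res <- attr(image, "resolution") %||% nrow(image)
  if (res != enc$train_res)
    stopf("image resolution %d does not match encoder training resolution %d",
          res, enc$train_res)
  x <- as.vector(resize_bilinear(unclass(image), enc$feature_res))
  yhat <- enc$y_mean + as.vector(crossprod(enc$B, x - enc$x_mean))
  latent_code(matrix(yhat, enc$code_dim[1], enc$code_dim[2]))
}
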