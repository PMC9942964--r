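#' Configuration for the synthetic soap-stimulus world
#'
#' The generator of synthetic stimuli emulates the statistical structure of a
#' photo collection of soaps: two material classes (opaque "milky" vs
#' translucent "glycerin") that differ in a scalar translucency factor
#' `tau`, plus nuisance variation in shape, orientation, body color and
#' lighting.  Lighting direction falls into four categories whose default
#' frequencies follow the approximate mix of the emulated photo dataset
#' (backlighting 44%, partial-front 8%, side 40%, diffuse 8%).
#'
#' @param tau_milky_mean,tau_milky_sd mean/sd of the milky-class truncated
#'   Gaussian over `tau` (low-translucency class)
#' @param tau_glycerin_mean,tau_glycerin_sd mean/sd for the glycerin class
#' @param tau_overlap half-width by which the two class supports extend past
#'   the class threshold 0.5.  `0` makes the classes linearly separable in
#'   `tau`; positive values give a positive Bayes error.
#' @param light_probs named probabilities for the four lighting categories
#' @param contour_amp maximum Fourier amplitude of the contour perturbation
#' @return a list of class `scene_config`
#' @export
scene_config <- function(tau_milky_mean = 0.25, tau_milky_sd = 0.12,
                         tau_glycerin_mean = 0.75, tau_glycerin_sd = 0.12,
                         tau_overlap = 0.1,
                         light_probs = c(backlight = 0.44, partial_front = 0.08,
                                         side = 0.40, diffuse = 0.08),
                         contour_amp = 0.18) {
  stopifnot(tau_overlap >= 0, tau_overlap <= 0.5,
            abs(sum(light_probs) - 1) < 1e-8,
            all(names(light_probs) == c("backlight", "partial_front",
                                        "side", "diffuse")))
  structure(list(tau_milky_mean = tau_milky_mean, tau_milky_sd = tau_milky_sd,
                 tau_glycerin_mean = tau_glycerin_mean,
                 tau_glycerin_sd = tau_glycerin_sd,
                 tau_overlap = tau_overlap, light_probs = light_probs,
                 contour_amp = contour_amp),
            class = "scene_config")
}

# truncated-normal draw by inverse-CDF (exact, vectorised)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Sample ground-truth scene factors for one stimulus
#'
#' Draws a shape contour (low-order Fourier amplitudes and phases), an
#' orientation, a translucency level `tau` from the class-conditional
#' distribution, a body color, a lighting category with continuous azimuth
#' jitter, and a backlight strength.
#'
#' @param rng_seed integer seed; the same seed yields identical factors
#' @param material_class optional `"milky"` or `"glycerin"`; sampled
#'   uniformly when omitted
#' @param cfg a [scene_config()]
#' @return a list of class `scene_factors` with fields `contour_amps`,
#'   `contour_phases`, `orientation`, `tau`, `body_color`, `light_azimuth`,
#'   `backlight_strength`, `light_category`, `material_class`
#' @export
sample_scene <- function(rng_seed, material_class = NULL, cfg = scene_config()) {
  if (!is.null(material_class) &&
      !material_class %in% c("milky", "glycerin"))
    stopf("unknown material class '%s'", material_class)
  with_seed(rng_seed, {
    cls <- material_class %||% sample(c("milky", "glycerin"), 1L)
    ov <- cfg$tau_overlap
    tau <- if (cls == "milky")
      rtruncnorm1(1, cfg$tau_milky_mean, cfg$tau_milky_sd, 0, 0.5 + ov)
    else
      rtruncnorm1(1, cfg$tau_glycerin_mean, cfg$tau_glycerin_sd, 0.5 - ov, 1)
    k <- 2:5
    amps <- runif(4, 0, cfg$contour_amp) / k   # higher harmonics weaker
    phases <- runif(4, -pi, pi)
    cat_ <- sample(names(cfg$light_probs), 1L, prob = cfg$light_probs)
    az <- switch(cat_,
      backlight     = pi + rnorm(1, 0, 0.35),
      partial_front = rnorm(1, 0, 0.35),
      side          = sample(c(-1, 1), 1L) * (pi / 2 + rnorm(1, 0, 0.25)),
      diffuse       = runif(1, -pi, pi))
    az <- atan2(sin(az), cos(az))  # wrap to (-pi, pi]
    bl <- switch(cat_,
      backlight     = runif(1, 0.6, 1),
      partial_front = runif(1, 0.1, 0.4),
      side          = runif(1, 0.2, 0.6),
      diffuse       = runif(1, 0, 0.25))
    # body colors: saturated dye-like hues, bounded away from black
    hue <- runif(1, 0, 1); sat <- runif(1, 0.2, 0.85); val <- runif(1, 0.5, 0.95)
    col <- hsv_to_rgb(hue, sat, val)
    structure(list(contour_amps = amps, contour_phases = phases,
                   orientation = runif(1, -pi, pi), tau = tau,
                   body_color = clamp(col, 0.05, 1),
                   light_azimuth = az, backlight_strength = bl,
                   light_category = cat_, material_class = cls),
              class = "scene_factors")
  })
}

hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6); f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(t, p, v), "5" = c(v, p, q))
}

# radial contour function r(theta) for a scene, clamped to keep the shape valid
contour_radius <- function(f, theta) {
  r <- 0.62 * (1 + colSums(f$contour_amps *
                             cos(outer(2:5, theta) +
                                   f$contour_phases)))
  clamp(r, 0.2, 0.92)
}

#' Render a stimulus image from scene factors
#'
#' Deterministic procedural render of a centred soap-like object on a light
#' background.  The opaque component is diffuse shading of the contour's
#' implied relief plus a hard cast shadow.  The translucent component adds
#' the image cues of translucency: a glowing edge falling off with interior
#' depth, a low-spatial-frequency hue/saturation gradient across the body, a
#' softened weakened shadow, and a chromatic caustic opposite the light.
#' The blend weight of the two components grows monotonically with `tau`
#' and `backlight_strength`.  The binary object mask depends on the contour
#' and orientation only, never on `tau` or color.
#'
#' @param factors a `scene_factors` object
#' @param resolution output side length in pixels (>= 16)
#' @return H x W x 3 array in \[0, 1\] of class `stimulus_image`, with
#'   attributes `mask` (logical matrix) and `resolution`
#' @export
render_scene <- function(factors, resolution = 128) {
  stopifnot(inherits(factors, "scene_factors"))
  if (resolution < 16) stopf("resolution must be >= 16, got %d", resolution)
  n <- as.integer(resolution)
  # pixel-center convention so grids align across resolutions
  ax <- (seq_len(n) - 0.5) / n * 2 - 1
  x <- matrix(ax, n, n, byrow = TRUE)   # column -> x
  y <- matrix(rev(ax), n, n)            # row 1 = top (y = +1)
  # rotate into object frame
  co <- cos(-factors$orientation); si <- sin(-factors$orientation)
  xo <- co * x - si * y; yo <- si * x + co * y
  theta <- atan2(yo, xo); rho <- sqrt(xo^2 + yo^2)
  rb <- matrix(contour_radius(factors, as.vector(theta)), n, n)
  mask <- rho <= rb
  d_in <- (rb - rho) / rb                # normalized interior depth, 0 at edge
  d_in[d_in < 0] <- 0

  lx <- cos(factors$light_azimuth); ly <- sin(factors$light_azimuth)

  # ---- opaque component: multiplicative diffuse shading of implied relief
  h <- sqrt(d_in)
  step <- 2 / n
  dhx <- (cbind(h[, -1], h[, n]) - cbind(h[, 1], h[, -n])) / (2 * step)
  dhy <- (rbind(h[1, , drop = FALSE], h[-n, , drop = FALSE]) -
            rbind(h[-1, , drop = FALSE], h[n, , drop = FALSE])) / (2 * step)
  slope <- dhx * lx + dhy * ly
  shading <- clamp(0.45 + 0.55 * clamp(0.55 + 0.45 * tanh(1.5 * slope), 0, 1),
                   0.05, 1)
  bc <- factors$body_color

  # ---- translucency blend weight: monotone in tau and backlight strength.
  # The backlight gain is kept mild (0.75..1) so the material factor remains
  # approximately linearly readable from pixels across lighting conditions.
  wt <- factors$tau * (0.75 + 0.25 * factors$backlight_strength)

  # ---- background with cast shadow (hard when opaque, soft/weak when not);
  # strong backlighting dims the ambient background (a direct image cue for
  # the backlight factor)
  bg0 <- 0.82 - 0.12 * factors$backlight_strength
  sx <- x + 0.16 * lx; sy <- y + 0.16 * ly   # shadow cast opposite the light
  co2 <- cos(-factors$orientation); si2 <- sin(-factors$orientation)
  sxo <- co2 * sx - si2 * sy; syo <- si2 * sx + co2 * sy
  sth <- atan2(syo, sxo); srho <- sqrt(sxo^2 + syo^2)
  srb <- matrix(contour_radius(factors, as.vector(sth)), n, n) * 1.04
  sh_edge <- (srb - srho) / (0.02 + 0.06 * wt)   # sharp -> soft with wt
  shadow <- clamp(sh_edge, 0, 1)
  sh_strength <- 0.45 * (1 - 0.45 * wt)
  bg <- bg0 * (1 - sh_strength * shadow)

  # ---- caustic blob opposite the light (translucent component only)
  cd <- 1.18 * 0.62
  cxc <- -cd * lx; cyc <- -cd * ly
  cau <- exp(-(((x - cxc)^2 + (y - cyc)^2) / (2 * 0.12^2)))
  cau_col <- clamp(bc * 1.6, 0, 1)

  img <- array(0, c(n, n, 3))
  # fine multiplicative surface texture (late/fine factor); same factor on all
  # channels so chromaticity -- and hence glow_statistic -- is unaffected
  ts <- factors$texture_strength %||% 0
  tex <- if (ts > 0)   # kept <= 1 so texture never clips (chromaticity exact)
    1 - ts * 0.25 * (1 + sin(19 * pi * x + 7 * pi * y) *
                       sin(17 * pi * y - 5 * pi * x))
  else 1
  # translucent interior: edge glow + low-frequency chromatic gradient;
  # the glow extends well into the body (an inner glow, not a thin rim)
  glow <- exp(-d_in / 0.25)
  ramp <- clamp(0.5 + 0.5 * (x * lx + y * ly), 0, 1)   # along light axis
  grad_gain <- c(0.22, 0, -0.22)                       # warm-cool chroma shift
  bl <- factors$backlight_strength
  # inner glow is dye-filtered light: saturated body color, not white
  cglow <- (bc / max(bc))^1.5
  for (k in 1:3) {
    opaque_k <- bc[k] * shading
    # translucency cues are edge-localized (glowing edge, inner glow near the
    # silhouette, chroma gradient): the far interior stays close to the
    # opaque brightness so material is a mid-scale feature, not a global
    # pixel-variance direction
    # edge glow: a luminance-neutral chroma boost (dye-filtered light raises
    # saturation near the silhouette) plus a faint luminance lift; the base
    # level 0.71 + 0.06 bl matches the opaque shading mean (~0.74), so
    # translucency is carried by chroma and spatial structure, not by a
    # global luminance offset
    trans_k <- clamp(bc[k] * (0.71 + 0.06 * bl + 0.04 * glow * (0.5 + 0.5 * bl)) *
                       (1 + grad_gain[k] * (ramp - 0.5) * (0.3 + 0.7 * glow)) +
                       0.7 * glow^1.5 * (0.4 + 0.6 * bl) *
                       (cglow[k] - mean(cglow)), 0, 1)
    inside <- ((1 - wt) * opaque_k + wt * trans_k) * tex
    outside <- clamp(bg + wt * 0.55 * cau * cau_col[k], 0, 1)
    img[, , k] <- ifelse(mask, inside, outside)
  }
  structure(clamp(img, 0, 1), class = "stimulus_image",
            mask = mask, resolution = n)
}

#' Object mask of a rendered stimulus
#' @param image a `stimulus_image`
#' @return logical matrix
#' @export
object_mask <- function(image) attr(image, "mask")

#' Mean chromatic-gradient energy in the edge band of an object
#'
#' A scalar proxy for the "glow" cue: the mean squared spatial gradient of
#' the chromaticity coordinates (r, g) = (R, G) / (R + G + B) over an
#' interior band next to the object edge.  Pure multiplicative shading of a
#' constant body color has constant chromaticity, so flat-shaded (fully
#' opaque) interiors score exactly 0.  The definition is isotropic: global
#' 90-degree rotations (with the mask co-rotated) leave it unchanged.
#'
#' @param image H x W x 3 array in \[0,1\]
#' @param mask logical matrix marking the object; defaults to the render mask
#' @param band band width in pixels (default scales with resolution)
#' @return nonnegative scalar
#' @export
glow_statistic <- function(image, mask = object_mask(image), band = NULL) {
  stopifnot(length(dim(image)) == 3L)
  if (is.null(mask) || !any(mask)) stopf("glow_statistic: empty or missing mask")
  n <- nrow(mask)
  band <- band %||% max(3L, round(0.1 * n))
  d <- dist_transform(mask)
  # gradient is only evaluated where all 4-neighbours are inside the mask
  inner <- d >= 2
  sel <- inner & d <= (band + 1)
  if (!any(sel)) stopf("glow_statistic: empty edge band")
  s <- image[, , 1] + image[, , 2] + image[, , 3]
  safe <- s > 1e-12
  r <- ifelse(safe, image[, , 1] / s, 1 / 3)
  g <- ifelse(safe, image[, , 2] / s, 1 / 3)
  gx <- function(m) {
    nn <- ncol(m)
    (cbind(m[, -1], m[, nn]) - cbind(m[, 1], m[, -nn])) / 2
  }
  gy <- function(m) {
    nn <- nrow(m)
    (rbind(m[-1, , drop = FALSE], m[nn, , drop = FALSE]) -
       rbind(m[1, , drop = FALSE], m[-nn, , drop = FALSE])) / 2
  }
  e <- gx(r)^2 + gy(r)^2 + gx(g)^2 + gy(g)^2
  mean(e[sel]) * 1e3    # rescale to a convenient magnitude
}

#' Generate a labelled two-class stimulus dataset
#'
#' Draws `n_per_class` scenes per material class with shapes, colors and
#' lighting varying across instances, and renders each one.
#'
#' @param n_per_class number of stimuli per class (>= 1)
#' @param seed integer seed; renders are byte-identical across reruns
#' @param resolution render resolution
#' @param cfg a [scene_config()]
#' @param render if `FALSE`, skip rendering and return factors only
#' @return list with `factors` (list of `scene_factors`), `images`
#'   (list of `stimulus_image` or NULL), `labels` (character vector)
#' @export
make_dataset <- function(n_per_class, seed, resolution = 128,
                         cfg = scene_config(), render = TRUE) {
  stopifnot(n_per_class >= 1)
  classes <- rep(c("milky", "glycerin"), each = n_per_class)
  seeds <- with_seed(seed, sample.int(2^30, length(classes)))
  factors <- mapply(function(s, cl) sample_scene(s, cl, cfg),
                    seeds, classes, SIMPLIFY = FALSE)
  images <- if (render)
    lapply(factors, render_scene, resolution = resolution) else NULL
  list(factors = factors, images = images, labels = classes)
}

#' Flatten scene factors to a named numeric vector
#'
#' Circular quantities are stored in rectangular form so that the vector
#' lives in a box (affine-map friendly, no wraparound): the contour as
#' cosine/sine Fourier coefficients `ca2..ca5`, `cb2..cb5`, and the
#' orientation and light azimuth as cos/sin pairs.
#'
#' Object orientation is a gauge freedom of the contour (rotating the object
#' is the same image operation as shifting all contour phases), so the
#' stored coefficients are image-frame: orientation is folded into the
#' phases, exactly as an unsupervised generator would entangle them.
#'
#' @param f a `scene_factors` object
#' @return named numeric vector of the continuous factors
#' @export
factors_to_vec <- function(f) {
  a <- f$contour_amps
  ph <- f$contour_phases - (2:5) * f$orientation   # image-frame phases
  c(setNames(a * cos(ph), paste0("ca", 2:5)),
    setNames(-a * sin(ph), paste0("cb", 2:5)),
    az_c = cos(f$light_azimuth), az_s = sin(f$light_azimuth),
    tau = f$tau, backlight_strength = f$backlight_strength,
    setNames(f$body_color, c("color_r", "color_g", "color_b")),
    texture_strength = f$texture_strength %||% 0)
}

#' Reassemble scene factors from a named numeric vector
#' @param v named vector as produced by [factors_to_vec()]
#' @return `scene_factors` object (material class derived from `tau`)
#' @export
vec_to_factors <- function(v) {
  ca <- unname(v[paste0("ca", 2:5)]); cb <- unname(v[paste0("cb", 2:5)])
  structure(list(
    contour_amps = sqrt(ca^2 + cb^2),
    contour_phases = atan2(-cb, ca),
    orientation = 0,   # gauge: folded into the image-frame phases
    tau = unname(v["tau"]),
    body_color = unname(v[c("color_r", "color_g", "color_b")]),
    light_azimuth = atan2(unname(v["az_s"]), unname(v["az_c"])),
    backlight_strength = unname(v["backlight_strength"]),
    texture_strength = unname(v["texture_strength"]),
    light_category = NA_character_,
    material_class = if (unname(v["tau"]) >= 0.5) "glycerin" else "milky"),
    class = "scene_factors")
}
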