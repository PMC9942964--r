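#' Construct a simulated-observer model
#'
#' Encapsulates everything the three psychophysical designs need: monotone
#' link functions from the translucency factor `tau` to the expected rating
#' of each attribute (translucency, see-throughness, glow) on the 7-point
#' scale; per-observer additive bias and noise heterogeneity; a Gaussian
#' signal-detection model (sensitivity `d_prime`, criterion) for the
#' real-versus-generated task; and a softmax choice temperature for the
#' forced-choice attribute-selection task.
#'
#' @param n_observers default 20, the design's sample size
#' @param noise_sd rating noise SD on the 7-point scale
#' @param bias_sd SD of the per-observer additive rating bias
#' @param noise_mult_sd SD (lognormal scale) of per-observer noise scaling
#' @param link_slopes,link_offsets named per-attribute linear link
#'   coefficients: expected rating = 1 + 6 * (offset + slope * tau), clipped
#' @param d_prime,criterion signal-detection parameters (see
#'   [sdt_calibrate()])
#' @param image_sd per-image realism heterogeneity SD (signal-detection)
#' @param temperature softmax temperature for attribute choices (0 = argmax)
#' @param salience perceptual salience weights applied to the standardised
#'   attribute deltas before the softmax: shape changes dominate lighting
#'   changes of comparable physical size (observers overwhelmingly report
#'   shape when both change together)
#' @return list of class `observer_model`
#' @export
observer_model <- function(n_observers = 20L, noise_sd = 0.8, bias_sd = 0.35,
                           noise_mult_sd = 0.2,
                           link_slopes = c(translucency = 0.85,
                                           see_through = 0.75, glow = 0.6),
                           link_offsets = c(translucency = 0.05,
                                            see_through = 0.05, glow = 0.2),
                           d_prime = sdt_calibrate()$d_prime,
                           criterion = sdt_calibrate()$criterion,
                           image_sd = 0.5, temperature = 0.4,
                           salience = c(shape = 1.6, color = 1.0,
                                        material = 1.2, lighting = 0.5)) {
  stopifnot(noise_sd >= 0, all(link_slopes > 0), temperature >= 0,
            all(salience > 0))
  structure(list(n_observers = as.integer(n_observers), noise_sd = noise_sd,
                 bias_sd = bias_sd, noise_mult_sd = noise_mult_sd,
                 link_slopes = link_slopes, link_offsets = link_offsets,
                 d_prime = d_prime, criterion = criterion,
                 image_sd = image_sd, temperature = temperature,
                 salience = salience),
            class = "observer_model")
}

#' Simulate 7-point attribute ratings for a stimulus set
#'
#' Every observer rates every stimulus on the three attributes:
#' `rating = round(clip(link(tau) + observer bias + noise, 1, 7))`.
#' The three attribute links share the common `tau` dependence (plus
#' attribute-specific slope/offset), so attribute ratings are positively
#' correlated across stimuli.
#'
#' @param factors list of `scene_factors` (or named vectors with `tau`)
#' @param model `observer_model`
#' @param seed integer seed
#' @return data frame of class `rating_table`: `observer`, `stimulus`,
#'   `attribute`, `rating` (integers 1..7), complete factorial
#' @export
simulate_ratings <- function(factors, model = observer_model(), seed = 1L) {
  taus <- vapply(factors, function(f)
    if (inherits(f, "scene_factors")) f$tau else unname(f["tau"]), 0)
  n_s <- length(taus); n_o <- model$n_observers
  atts <- names(model$link_slopes)
  with_seed(seed, {
    bias <- rnorm(n_o, 0, model$bias_sd)
    nmult <- exp(rnorm(n_o, 0, model$noise_mult_sd))
    rows <- expand.grid(observer = seq_len(n_o), stimulus = seq_len(n_s),
                        attribute = atts, stringsAsFactors = FALSE)
    mu <- 1 + 6 * (model$link_offsets[rows$attribute] +
                     model$link_slopes[rows$attribute] * taus[rows$stimulus])
    noise <- rnorm(nrow(rows), 0, model$noise_sd) * nmult[rows$observer]
    rows$rating <- as.integer(round(clamp(mu + bias[rows$observer] + noise,
                                          1, 7)))
    class(rows) <- c("rating_table", "data.frame")
    rows
  })
}

#' Closed-form calibration of the signal-detection model
#'
#' Inverts the Gaussian equal-variance SDT error-rate equations for target
#' marginal error rates on generated and real stimuli, accounting for
#' per-image heterogeneity `image_sd`:
#' `P(error | real) = Phi((c - d'/2) / s)` and
#' `P(error | generated) = 1 - Phi((c + d'/2) / s)` with
#' `s = sqrt(1 + image_sd^2)`.
#'
#' @param target_error_generated,target_error_real target error rates in (0,1)
#' @param image_sd per-image heterogeneity (must match the simulation's)
#' @return list with `d_prime` and `criterion`
#' @export
sdt_calibrate <- function(target_error_generated = 0.28,
                          target_error_real = 0.25, image_sd = 0.5) {
  s <- sqrt(1 + image_sd^2)
  a <- qnorm(1 - target_error_generated) * s   # = c + d'/2
  b <- qnorm(target_error_real) * s            # = c - d'/2
  list(d_prime = a - b, criterion = (a + b) / 2)
}

#' Draw standardised per-image realism offsets
#'
#' A seeded Gaussian draw rescaled to exact sample mean 0 and SD
#' `image_sd`, so the finite image sample matches the population moments
#' the closed-form calibration ([sdt_calibrate()]) integrates over.
#'
#' @param n number of images
#' @param image_sd offset standard deviation
#' @param seed integer seed
#' @return numeric vector of length `n`
#' @export
realism_offsets <- function(n, image_sd = 0.5, seed = 1L) {
  x <- with_seed(seed, rnorm(n))
  if (image_sd == 0 || n < 2) return(rep(0, n))
  as.vector(scale(x)) * image_sd
}

#' Simulate the real-versus-generated discrimination experiment
#'
#' Equal-variance Gaussian signal detection: each image carries a fixed
#' realism offset (seeded, SD `image_sd`); on every trial the observer's
#' internal evidence is the class mean (`+d'/2` real, `-d'/2` generated)
#' plus the image offset plus unit noise, answered "real" above the
#' criterion.  Runs `n_repeats` full passes over all images per observer.
#'
#' @param realism_scores numeric vector, one per image: per-image realism
#'   offsets on the evidence axis (typically `rnorm(n, 0, model$image_sd)`)
#' @param is_real logical vector: ground truth per image
#' @param model `observer_model`
#' @param n_repeats passes per observer (default 2)
#' @param seed integer seed
#' @return data frame of class `judgment_table`: `observer`, `image`,
#'   `repeat_`, `is_real`, `judged_real`, `error`
#' @export
simulate_discrimination <- function(realism_scores, is_real,
                                    model = observer_model(),
                                    n_repeats = 2L, seed = 1L) {
  stopifnot(all(is.finite(realism_scores)),
            length(realism_scores) == length(is_real))
  n_img <- length(is_real); n_o <- model$n_observers
  with_seed(seed, {
    rows <- expand.grid(observer = seq_len(n_o), image = seq_len(n_img),
                        repeat_ = seq_len(n_repeats))
    mu <- ifelse(is_real[rows$image], model$d_prime / 2, -model$d_prime / 2) +
      realism_scores[rows$image]
    x <- mu + rnorm(nrow(rows))
    rows$is_real <- is_real[rows$image]
    rows$judged_real <- x > model$criterion
    rows$error <- rows$judged_real != rows$is_real
    class(rows) <- c("judgment_table", "data.frame")
    rows
  })
}

#' Ground-truth factor deltas of a morph sequence's endpoints
#'
#' Measures, on the decoded factor readouts of the first and last frame:
#' shape/orientation change (contour-coefficient distance), body-color
#' change, material change (|delta tau|), and lighting change (azimuth and
#' backlight shift).
#'
#' @param seq `morph_sequence` (codes are used, images not needed)
#' @param cfg `generator_config`
#' @return named numeric vector `c(shape, color, material, lighting)`
#' @export
sequence_deltas <- function(seq, cfg) {
  f0 <- decode_factors(seq$codes[[1]], cfg)
  f1 <- decode_factors(seq$codes[[length(seq$codes)]], cfg)
  sh <- sqrt(sum((f1[c(paste0("ca", 2:5), paste0("cb", 2:5))] -
                    f0[c(paste0("ca", 2:5), paste0("cb", 2:5))])^2))
  co <- sqrt(sum((f1[c("color_r", "color_g", "color_b")] -
                    f0[c("color_r", "color_g", "color_b")])^2))
  ma <- abs(f1["tau"] - f0["tau"])
  li <- 0.5 * sqrt(sum((f1[c("az_c", "az_s")] - f0[c("az_c", "az_s")])^2)) +
    abs(f1["backlight_strength"] - f0["backlight_strength"])
  c(shape = unname(sh), color = unname(co), material = unname(ma),
    lighting = unname(li))
}

#' Simulate forced-choice "most prominent change" responses
#'
#' For each sequence, the four attribute deltas are standardised by their
#' scale over the whole stimulus set, and each observer samples a choice
#' from a softmax over the standardised deltas at the model temperature
#' (temperature 0 picks the argmax deterministically).
#'
#' @param sequences list of `morph_sequence`s with `pair_condition` and
#'   `layer_group` fields (from [build_exp3_stimuli()])
#' @param cfg `generator_config`
#' @param model `observer_model`
#' @param seed integer seed
#' @return data frame of class `choice_table`: `observer`, `sequence`,
#'   `pair_condition`, `layer_group`, `choice` in
#'   shape/orientation, color, material, lighting
#' @export
simulate_exp3_choices <- function(sequences, cfg, model = observer_model(),
                                  seed = 1L) {
  D <- t(vapply(sequences, sequence_deltas, numeric(4), cfg = cfg))
  # standardise each delta type by its root-mean-square over the set
  sc <- sqrt(colMeans(D^2))
  sc[sc < 1e-12] <- 1
  Z <- sweep(D, 2, sc, "/")
  sal <- model$salience %||% c(shape = 1, color = 1, material = 1,
                               lighting = 1)
  Z <- sweep(Z, 2, unname(sal[c("shape", "color", "material", "lighting")]),
             "*")
  choices <- c("shape/orientation", "color", "material", "lighting")
  n_o <- model$n_observers
  with_seed(seed, {
    rows <- vector("list", length(sequences))
    for (s in seq_along(sequences)) {
      z <- Z[s, ]
      pr <- if (all(z < 1e-12)) {
        warning(sprintf("sequence %d: all deltas zero; uniform choice", s))
        rep(0.25, 4)
      } else if (model$temperature == 0) {
        p <- numeric(4); p[which.max(z)] <- 1; p
      } else {
        e <- exp((z - max(z)) / model$temperature)
        e / sum(e)
      }
      ch <- choices[sample.int(4, n_o, replace = TRUE, prob = pr)]
      rows[[s]] <- data.frame(observer = seq_len(n_o), sequence = s,
                              pair_condition = sequences[[s]]$pair_condition,
                              layer_group = sequences[[s]]$layer_group,
                              choice = ch, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("choice_table", "data.frame")
    out
  })
}
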