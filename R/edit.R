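#' Traverse one layer's latent vector along a boundary normal
#'
#' For each step `alpha`, adds `alpha * unit_normal` to the boundary's layer
#' row (positive direction = milky/opaque side); all other rows are left
#' bit-identical.  Each edited code is decoded.
#'
#' @param code `latent_code`
#' @param boundary `boundary_model` whose `layer_index` is valid for `code`
#' @param cfg `generator_config`
#' @param alphas numeric step grid; the default spans -3..3 units of
#'   `step_sd` (one unit defaults to 1 latent SD worth of displacement)
#' @param step_sd scale of one alpha unit in latent units
#' @param decode_images render each step (default TRUE)
#' @return list of class `edit_sequence`: `alphas`, `codes`, `images`,
#'   `factors` (decoded factor readout per step), `layer_index`
#' @export
edit_along_normal <- function(code, boundary, cfg, alphas = -3:3,
                              step_sd = 1, decode_images = TRUE) {
  check_code(code, cfg)
  if (any(!is.finite(alphas))) stopf("alphas must be finite")
  i <- boundary$layer_index
  if (i < 1 || i > nrow(code)) stopf("boundary layer %d invalid for code", i)
  nrm <- boundary$weights / sqrt(sum(boundary$weights^2))
  steps <- lapply(alphas, function(a) {
    cd <- code
    cd[i, ] <- cd[i, ] + a * step_sd * nrm
    cd <- latent_code(unclass(cd))
    if (decode_images) {
      dec <- decode(cd, cfg)
      list(code = cd, image = dec$image, factors = dec$factors)
    } else list(code = cd, image = NULL, factors = decode_factors(cd, cfg))
  })
  structure(list(alphas = alphas,
                 codes = lapply(steps, `[[`, "code"),
                 images = lapply(steps, `[[`, "image"),
                 factors = lapply(steps, `[[`, "factors"),
                 layer_index = i),
            class = "edit_sequence")
}

#' Evaluate the selectivity of a boundary-normal edit
#'
#' Reports, per step: the decoded material (tau) readout, the shape-mask IoU
#' against step 0 (the first alpha), and the mean absolute body-color shift;
#' plus verdicts for material monotonicity (tau nonincreasing along positive
#' alpha, i.e. toward the milky side) and shape/color invariance.
#'
#' @param seq an `edit_sequence` with at least 2 steps and decoded images
#' @param cfg `generator_config`
#' @param tol invariance tolerance on factor readouts
#' @return list with `report` (data frame: alpha, tau_readout, shape_iou,
#'   color_shift), `tau_monotone_nonincreasing`, `shape_invariant`,
#'   `color_invariant`
#' @export
evaluate_edit <- function(seq, cfg, tol = 1e-6) {
  stopifnot(inherits(seq, "edit_sequence"), length(seq$alphas) >= 2)
  has_img <- !is.null(seq$images[[1]])
  m0 <- if (has_img) object_mask(seq$images[[1]]) else NULL
  f0 <- seq$factors[[1]]
  rep_ <- do.call(rbind, lapply(seq_along(seq$alphas), function(j) {
    f <- seq$factors[[j]]
    data.frame(
      alpha = seq$alphas[j],
      tau_readout = unname(f["tau"]),
      shape_iou = if (has_img) mask_iou(m0, object_mask(seq$images[[j]])) else NA_real_,
      color_shift = mean(abs(f[c("color_r", "color_g", "color_b")] -
                               f0[c("color_r", "color_g", "color_b")])))
  }))
  ord <- order(rep_$alpha)
  taus <- rep_$tau_readout[ord]
  list(report = rep_,
       tau_monotone_nonincreasing = all(diff(taus) <= tol),
       shape_invariant = if (has_img) all(rep_$shape_iou == 1) else NA,
       color_invariant = all(rep_$color_shift <= tol))
}
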