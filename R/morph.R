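#' Layer-subset linear interpolation between two latent codes
#'
#' Rows in the layer set `s` become `(1 - lam) * source + lam * target`;
#' all other rows are taken from the source, bit-identical.  `lam = 0`
#' returns the source code exactly; `lam = 1` replaces the rows in `s` with
#' the target's.
#'
#' @param source,target `latent_code` matrices of identical dimension
#' @param s nonempty integer set of layer indices
#' @param lam interpolation step in \[0, 1\]
#' @return `latent_code`
#' @export
morph <- function(source, target, s, lam) {
  if (!identical(dim(source), dim(target)))
    stopf("source and target codes have different dimensions")
  if (length(s) == 0) stopf("layer set s must be nonempty")
  s <- as.integer(s)
  if (any(s < 1 | s > nrow(source))) stopf("layer index out of range")
  if (!is.finite(lam) || lam < 0 || lam > 1)
    stopf("lam must be in [0, 1], got %s", format(lam))
  out <- source
  out[s, ] <- (1 - lam) * source[s, , drop = FALSE] +
    lam * target[s, , drop = FALSE]
  latent_code(unclass(out))
}

#' Default interpolation grid: four equal steps
#' @return numeric vector `c(0, 1/3, 2/3, 1)` (recorded rounded as 0, 0.33,
#'   0.67, 1 in manifests)
#' @export
default_lambdas <- function() c(0, 1 / 3, 2 / 3, 1)

#' Build and decode a morph sequence
#'
#' @param source,target `latent_code`s
#' @param s layer index set to interpolate
#' @param cfg `generator_config`
#' @param lambdas ascending interpolation steps in \[0,1\]
#'   (default [default_lambdas()])
#' @param decode_images if `FALSE`, skip rendering (codes only)
#' @return list of class `morph_sequence` with `codes`, `images`, `lambdas`,
#'   `layer_set`
#' @export
morph_sequence <- function(source, target, s, cfg,
                           lambdas = default_lambdas(),
                           decode_images = TRUE) {
  if (is.unsorted(lambdas)) stopf("lambdas must be ascending")
  codes <- lapply(lambdas, function(l) morph(source, target, s, l))
  images <- if (decode_images)
    lapply(codes, function(cd) decode(cd, cfg)$image) else NULL
  structure(list(codes = codes, images = images, lambdas = lambdas,
                 layer_set = as.integer(s)),
            class = "morph_sequence")
}

#' Build the forced-choice experiment's morph-sequence stimuli
#'
#' Crosses three source-target pair conditions -- opaque-translucent (OT),
#' opaque-opaque (OO), translucent-translucent (TT), assigned from
#' ground-truth class labels -- with the three layer-manipulation methods
#' (early/middle/late group morphing), sampling `n_per_cell` sequences per
#' cell without replacement (default 50, i.e. 450 sequences).
#'
#' @param codes list of `latent_code`s
#' @param labels character vector, `"milky"` (opaque) / `"glycerin"`
#'   (translucent), aligned with `codes`
#' @param cfg `generator_config`
#' @param n_per_cell sequences per (pair condition x layer manipulation) cell
#' @param seed integer seed
#' @param decode_images render each frame (slow); codes are always kept
#' @param replace sample pairs with replacement (fallback for tiny datasets)
#' @return list of `morph_sequence` objects, each with fields `pair_condition`
#'   (`"OT"`, `"OO"`, `"TT"`), `layer_group` (`"early"|"middle"|"late"`),
#'   `source_idx`, `target_idx`
#' @export
build_exp3_stimuli <- function(codes, labels, cfg, n_per_cell = 50L,
                               seed = 1L, decode_images = FALSE,
                               replace = FALSE) {
  stopifnot(length(codes) == length(labels), n_per_cell >= 1)
  op <- which(labels == "milky"); tr <- which(labels == "glycerin")
  if (length(op) == 0 || length(tr) == 0)
    stopf("dataset must contain both material classes")
  pair_pool <- function(cond) {
    switch(cond,
      OT = expand.grid(s = op, t = tr),
      OO = {g <- expand.grid(s = op, t = op); g[g$s != g$t, ]},
      TT = {g <- expand.grid(s = tr, t = tr); g[g$s != g$t, ]})
  }
  out <- list()
  with_seed(seed, {
    for (cond in c("OT", "OO", "TT")) {
      pool <- pair_pool(cond)
      for (g in c("early", "middle", "late")) {
        if (!replace && nrow(pool) < n_per_cell)
          stopf("cell %s x %s: only %d eligible pairs for %d requested",
                cond, g, nrow(pool), n_per_cell)
        pick <- pool[sample.int(nrow(pool), n_per_cell, replace = replace), ,
                     drop = FALSE]
        for (r in seq_len(nrow(pick))) {
          si <- pick$s[r]; ti <- pick$t[r]
          sq <- morph_sequence(codes[[si]], codes[[ti]], cfg$groups[[g]], cfg,
                               decode_images = decode_images)
          sq$pair_condition <- cond
          sq$layer_group <- g
          sq$source_idx <- si; sq$target_idx <- ti
          out[[length(out) + 1L]] <- sq
        }
      }
    }
  })
  out
}
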