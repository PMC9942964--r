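#' Train one linear decision boundary per latent layer
#'
#' For each layer `i`, fits a linear max-margin classifier on that layer's
#' `n x d` latent slice to separate the two material classes, with the
#' regularisation constant `C` chosen by nested cross-validation (stratified
#' 5 outer x 3 inner folds; `C` grid log-spaced in \[0.001, 0.1\], smallest
#' near-tied `C` preferred).  The boundary's sign is oriented so that the
#' milky (opaque) class lies on the positive side of the normal.
#'
#' @param latents `n x L x d` array of layer-wise latent codes
#' @param labels character (`"milky"`/`"glycerin"`) or factor, length `n`
#' @param seed integer seed controlling fold assignment
#' @param C_grid ascending grid of regularisation constants
#' @param k_outer,k_inner outer/inner fold counts
#' @return list of `L` objects of class `boundary_model` with fields
#'   `layer_index`, `weights`, `bias`, `C_selected`, `cv_accuracy`,
#'   `norm_bounds` (unset; see [calibrate_boundary()])
#' @export
train_layer_boundaries <- function(latents, labels, seed = 1L,
                                   C_grid = 10^seq(-3, -1, length.out = 7),
                                   k_outer = 5L, k_inner = 3L) {
  stopifnot(length(dim(latents)) == 3L)
  n <- dim(latents)[1]; L <- dim(latents)[2]
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stopf("both material classes must be present")
  if (n < 20L) stopf("need n >= 20 for nested cross-validation, got %d", n)
  if (!all(labels %in% c("milky", "glycerin")))
    stopf("labels must be 'milky' or 'glycerin'")
  y <- ifelse(labels == "milky", 1, -1)
  out <- vector("list", L)
  for (i in seq_len(L)) {
    X <- latents[, i, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, n)
    res <- with_seed(child_seed(seed, i), {
      fold <- stratified_folds(y, k_outer)
      accs <- numeric(k_outer)
      for (f in seq_len(k_outer)) {
        tr <- fold != f
        Cf <- select_C(X[tr, , drop = FALSE], y[tr], C_grid, k_inner)
        m <- linsvm_fit(X[tr, , drop = FALSE], y[tr], Cf)
        accs[f] <- mean(linsvm_predict(m, X[!tr, , drop = FALSE]) == y[!tr])
      }
      C_fin <- select_C(X, y, C_grid, k_inner)
      m <- linsvm_fit(X, y, C_fin)
      list(m = m, cv = mean(accs), C = C_fin)
    })
    w <- res$m$w; b <- res$m$b
    # orient: milky (y = +1) on the positive side
    if (mean(X[y == 1, , drop = FALSE] %*% w + b) <
        mean(X[y == -1, , drop = FALSE] %*% w + b)) {
      w <- -w; b <- -b
    }
    out[[i]] <- structure(
      list(layer_index = i, weights = w, bias = b, C_selected = res$C,
           cv_accuracy = res$cv, norm_bounds = NULL),
      class = "boundary_model")
  }
  out
}

# signed distance of layer-i latent vectors to the boundary, oriented toward
# the translucent (glycerin) side so that larger = more translucent
raw_translucency_distance <- function(code, boundary) {
  x <- code[boundary$layer_index, ]
  -(sum(boundary$weights * x) + boundary$bias) / sqrt(sum(boundary$weights^2))
}

#' Fix a boundary's normalisation bounds on an evaluation set
#'
#' Records the min/max raw signed distance (translucency-oriented) over the
#' evaluation codes, making [predict_translucency()] a pure function.
#'
#' @param boundary `boundary_model`
#' @param eval_codes list of `latent_code`s
#' @return the boundary with `norm_bounds` set
#' @export
calibrate_boundary <- function(boundary, eval_codes) {
  raw <- vapply(eval_codes, raw_translucency_distance, 0, boundary = boundary)
  boundary$norm_bounds <- range(raw)
  boundary
}

#' Normalised-distance translucency prediction from one layer's boundary
#'
#' The raw signed distance of the code's layer-`i` latent vector from the
#' boundary (oriented toward the translucent side; the boundary normal
#' itself stays milky-positive for editing) is min-max normalised to
#' \[0, 1\] using the bounds fixed by [calibrate_boundary()].  The mapping
#' is order-preserving; values outside the calibration range clip to 0/1.
#'
#' @param code `latent_code`
#' @param boundary calibrated `boundary_model`
#' @return translucency score in \[0, 1\]
#' @export
predict_translucency <- function(code, boundary) {
  if (is.null(boundary$norm_bounds))
    stopf("boundary %d has no norm_bounds; call calibrate_boundary() first",
          boundary$layer_index)
  raw <- raw_translucency_distance(code, boundary)
  b <- boundary$norm_bounds
  if (b[2] <= b[1]) return(0.5)
  clamp((raw - b[1]) / (b[2] - b[1]), 0, 1)
}

#' Layer-wise correlation tuning curve against perceptual ratings
#'
#' Pearson correlation (`r_hc`), two-sided p-value and a 95%-level
#' significance flag between each layer's normalised-distance predictions
#' and each attribute's mean normalised ratings.
#'
#' @param boundaries list of `boundary_model`s (calibrated or not; bounds
#'   are fixed on `eval_codes` when unset)
#' @param eval_codes list of `latent_code`s
#' @param ratings data frame of per-image mean normalised ratings, one
#'   column per attribute, rows aligned with `eval_codes`
#' @return data frame with columns `layer`, `attribute`, `r`, `p`,
#'   `significant` (`NA` r flagged not computed on zero variance)
#' @export
tuning_curve <- function(boundaries, eval_codes, ratings) {
  stopifnot(is.data.frame(ratings), nrow(ratings) >= 10)
  if (length(eval_codes) != nrow(ratings))
    stopf("ratings rows (%d) must align with eval codes (%d)",
          nrow(ratings), length(eval_codes))
  rows <- list()
  for (bd in boundaries) {
    if (is.null(bd$norm_bounds)) bd <- calibrate_boundary(bd, eval_codes)
    score <- vapply(eval_codes, predict_translucency, 0, boundary = bd)
    for (att in names(ratings)) {
      v <- ratings[[att]]
      if (sd(score) < 1e-12 || sd(v) < 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          layer = bd$layer_index, attribute = att, r = NA_real_,
          p = NA_real_, significant = NA)
      } else {
        ct <- cor.test(score, v)
        rows[[length(rows) + 1L]] <- data.frame(
          layer = bd$layer_index, attribute = att, r = unname(ct$estimate),
          p = ct$p.value, significant = ct$p.value < 0.05)
      }
    }
  }
  do.call(rbind, rows)
}

#' Pixel-embedding control: dimensionality reduction + linear probe
#'
#' The control analysis for the latent-space probe: images are flattened to
#' raw RGB pixel vectors at a working resolution, embedded jointly
#' (train + eval) by t-SNE or classical MDS, a linear max-margin classifier
#' is fit on the training rows only, and the same normalised-distance
#' protocol yields per-eval-image translucency scores and their correlation
#' with ratings.
#'
#' @param train_images,eval_images lists of `stimulus_image`
#' @param train_labels `"milky"`/`"glycerin"` labels for the training images
#' @param ratings data frame of mean normalised ratings for the eval images
#' @param method `"tsne"` or `"mds"`
#' @param embed_dim embedding dimensionality (default 16; 512 mirrors the
#'   full-scale protocol but is slow with the exact t-SNE gradient)
#' @param perplexity t-SNE perplexity (one of the protocol's 5/15/25)
#' @param max_iter maximum embedding iterations (default 300)
#' @param pixel_res images are downsampled to this side length (default 64)
#' @param seed integer seed (t-SNE initialisation, folds)
#' @param C_grid regularisation grid for the probe
#' @return list with `scores` (per eval image), `curve` (attribute, r, p,
#'   significant), `embedding` (joint matrix), `method`
#' @export
pixel_embedding_baseline <- function(train_images, train_labels, eval_images,
                                     ratings, method = c("tsne", "mds"),
                                     embed_dim = 16L, perplexity = 15,
                                     max_iter = 300L, pixel_res = 64L,
                                     seed = 1L,
                                     C_grid = 10^seq(-3, -1, length.out = 7)) {
  method <- match.arg(method)
  n_tr <- length(train_images)
  if (method == "tsne" && perplexity >= n_tr)
    stopf("perplexity (%g) must be below the number of training images (%d)",
          perplexity, n_tr)
  feats <- function(imgs) t(vapply(imgs, function(im)
    as.vector(resize_bilinear(unclass(im), pixel_res)),
    numeric(3 * pixel_res^2)))
  X <- rbind(feats(train_images), feats(eval_images))
  emb <- switch(method,
    mds = mds_embed(X, embed_dim, max_iter = max_iter,
                    seed = child_seed(seed, "mds-init")),
    tsne = tsne_embed(X, embed_dim, perplexity, max_iter, seed))
  tr_rows <- seq_len(n_tr)
  y <- ifelse(as.character(train_labels) == "milky", 1, -1)
  Etr <- emb[tr_rows, , drop = FALSE]
  model <- with_seed(child_seed(seed, "baseline-svm"), {
    Cs <- select_C(Etr, y, C_grid, 3L)
    linsvm_fit(Etr, y, Cs)
  })
  w <- model$w; b <- model$b
  if (mean(Etr[y == 1, , drop = FALSE] %*% w + b) <
      mean(Etr[y == -1, , drop = FALSE] %*% w + b)) { w <- -w; b <- -b }
  Eev <- emb[-tr_rows, , drop = FALSE]
  raw <- -(as.vector(Eev %*% w) + b) / sqrt(sum(w^2))
  rng <- range(raw)
  scores <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else rep(0.5, length(raw))
  curve <- do.call(rbind, lapply(names(ratings), function(att) {
    v <- ratings[[att]]
    if (sd(scores) < 1e-12 || sd(v) < 1e-12)
      return(data.frame(attribute = att, r = NA_real_, p = NA_real_,
                        significant = NA))
    ct <- cor.test(scores, v)
    data.frame(attribute = att, r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < 0.05)
  }))
  list(scores = scores, curve = curve, embedding = emb, method = method)
}

#' Metric MDS embedding by stress majorisation (SMACOF)
#'
#' Euclidean-dissimilarity metric MDS fitted by the SMACOF (Guttman
#' transform) iteration from a seeded random initialisation, with the
#' protocol's iteration cap.  This mirrors the standard iterative MDS
#' implementation; it is not the closed-form classical scaling.
#'
#' @param X feature matrix (rows = observations)
#' @param k output dimensionality
#' @param max_iter iteration cap (default 300)
#' @param seed seed for the random initialisation
#' @param tol relative stress-decrease convergence tolerance
#' @return n x k coordinate matrix; attribute `stress` holds the final
#'   normalised stress
#' @export
mds_embed <- function(X, k, max_iter = 300L, seed = 1L, tol = 1e-6) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  scale0 <- sqrt(mean(D^2))
  Y <- with_seed(seed, matrix(rnorm(n * k), n, k)) * scale0 / sqrt(2 * k)
  ssq <- sum(D^2) / 2
  stress_old <- Inf
  for (it in seq_len(max_iter)) {
    DY <- as.matrix(dist(Y))
    stress <- sum((D - DY)^2) / 2
    if (is.finite(stress_old) &&
        (stress_old - stress) < tol * stress_old) break
    stress_old <- stress
    R <- ifelse(DY > 1e-12, -D / DY, 0)
    diag(R) <- 0
    diag(R) <- -rowSums(R)
    Y <- R %*% Y / n     # Guttman transform
  }
  attr(Y, "stress") <- stress_old / ssq
  Y
}

#' Exact-gradient t-SNE embedding
#'
#' Plain (non tree-accelerated) t-SNE so the output dimensionality is
#' unrestricted.  Perplexity calibration by per-point binary search;
#' standard early exaggeration and momentum schedule.
#'
#' @param X feature matrix
#' @param k output dimensionality
#' @param perplexity target perplexity
#' @param max_iter gradient iterations (default 300)
#' @param seed seed for the Gaussian initialisation
#' @return n x k coordinate matrix
#' @export
tsne_embed <- function(X, k, perplexity = 15, max_iter = 300L, seed = 1L) {
  n <- nrow(X)
  if (perplexity >= n) stopf("perplexity must be < n")
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp < 1e-300) { H <- 0 } else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  Y <- with_seed(seed, matrix(rnorm(n * k, 0, 1e-4), n, k))
  G <- matrix(0, n, k)
  gains <- matrix(1, n, k)
  eta <- 100
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    W <- (ex * P - Q) * num
    grad <- 4 * (Y * rowSums(W) - W %*% Y)
    mom <- if (iter <= 20) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
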