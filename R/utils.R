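#' @keywords internal
#' @import stats
#' @import utils
#' @importFrom grDevices rgb col2rgb
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a fixed RNG seed, restoring RNG state afterwards
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed for a pipeline stage
#'
#' One global seed fans out deterministically to per-stage seeds so stages
#' can be re-run in isolation.  Results stay below 2^31 - 1.
#'
#' @param seed integer master seed
#' @param stage stage name (character) or integer stage index
#' @return integer child seed
#' @export
child_seed <- function(seed, stage) {
  if (is.character(stage))
    stage <- sum(utf8ToInt(stage) * (seq_along(utf8ToInt(stage)) %% 97L))
  as.integer((as.double(seed) * 48271 + as.double(stage) * 16807) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' City-block distance transform of a binary mask
#'
#' Distance (in pixels) from every TRUE pixel to the nearest FALSE pixel
#' (image border counts as outside).  Two-pass chamfer scheme, vectorised
#' across rows/columns.
#'
#' @param mask logical matrix
#' @return numeric matrix of distances; 0 outside the mask
#' @export
dist_transform <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  big <- h + w + 2
  d <- matrix(0, h, w)
  d[mask] <- big
  # forward pass
  for (i in seq_len(h)) {
    up <- if (i == 1L) rep(1, w) else d[i - 1L, ] + 1
    row <- pmin(d[i, ], pmin(up, big))
    row[1L] <- min(row[1L], 1)
    for (j in 2:w) row[j] <- min(row[j], row[j - 1L] + 1)
    d[i, ] <- row
  }
  # backward pass
  for (i in rev(seq_len(h))) {
    dn <- if (i == h) rep(1, w) else d[i + 1L, ] + 1
    row <- pmin(d[i, ], dn)
    row[w] <- min(row[w], 1)
    for (j in (w - 1L):1L) row[j] <- min(row[j], row[j + 1L] + 1)
    d[i, ] <- row
  }
  d
}

#' Bilinear resize of a 2-D matrix or H x W x 3 array
#'
#' @param img matrix or 3-d array with values in any range
#' @param out integer output side length (square output)
#' @return resized matrix/array
#' @export
resize_bilinear <- function(img, out) {
  out <- as.integer(out)
  stopifnot(out >= 1)
  rs1 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    # output pixel centers mapped into 1-based source index coordinates
    # (exact identity when out == source size)
    ys <- (seq_len(out) - 0.5) * h / out + 0.5
    xs <- (seq_len(out) - 0.5) * w / out + 0.5
    y0 <- clamp(floor(ys), 1, h); y1 <- clamp(y0 + 1, 1, h)
    x0 <- clamp(floor(xs), 1, w); x1 <- clamp(x0 + 1, 1, w)
    fy <- clamp(ys - y0, 0, 1);   fx <- clamp(xs - x0, 0, 1)
    a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
    c <- m[y1, x0, drop = FALSE]; dd <- m[y1, x1, drop = FALSE]
    wy <- matrix(fy, out, out); wx <- matrix(fx, out, out, byrow = TRUE)
    (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c + wx * dd)
  }
  if (length(dim(img)) == 3L) {
    res <- array(0, c(out, out, dim(img)[3]))
    for (k in seq_len(dim(img)[3])) res[, , k] <- rs1(img[, , k])
    res
  } else rs1(img)
}

# reflect-pad a matrix by (py, px) on each side
pad_reflect <- function(m, py, px) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rev(seq_len(min(py, h))), seq_len(h), h + 1 - seq_len(min(py, h)))
  ci <- c(rev(seq_len(min(px, w))), seq_len(w), w + 1 - seq_len(min(px, w)))
  m[ri, ci, drop = FALSE]
}

#' 2-D cross-correlation with 'same' output and reflect padding (FFT based)
#'
#' @param m numeric matrix (image plane)
#' @param k numeric matrix (kernel), dimensions not exceeding `m`'s
#' @return matrix of `dim(m)` with the channel response
#' @keywords internal
xcorr2_same <- function(m, k) {
  kh <- nrow(k); kw <- ncol(k)
  if (kh > nrow(m) || kw > ncol(m)) stopf("kernel larger than image")
  py <- kh %/% 2; px <- kw %/% 2
  mp <- pad_reflect(m, py, px)
  H <- nrow(mp); W <- ncol(mp)
  kf <- matrix(0, H, W)
  # cross-correlation = circular convolution with the 180-deg rotated kernel;
  # entries conv[y + kh - 1, x + kw - 1] equal sum_k k * mp[y + u - 1, x + v - 1]
  kf[seq_len(kh), seq_len(kw)] <- k[kh:1, kw:1]
  conv <- Re(fft(fft(mp) * fft(kf), inverse = TRUE)) / (H * W)
  conv[(kh - 1L) + seq_len(nrow(m)), (kw - 1L) + seq_len(ncol(m)), drop = FALSE]
}

# simple separable box blur with reflect padding; radius r >= 0
box_blur <- function(m, r) {
  if (r < 1) return(m)
  r <- as.integer(r)
  h <- nrow(m); w <- ncol(m)
  mp <- pad_reflect(m, r, r)
  cs <- apply(mp, 2, cumsum)
  top <- rbind(matrix(0, 1, ncol(cs)), cs)
  v <- (top[(2 * r + 1) + seq_len(h), ] - top[seq_len(h), ]) / (2 * r + 1)
  v <- v[, , drop = FALSE]
  cs2 <- t(apply(v, 1, cumsum))
  left <- cbind(matrix(0, nrow(cs2), 1), cs2)
  out <- (left[, (2 * r + 1) + seq_len(w)] - left[, seq_len(w)]) / (2 * r + 1)
  out
}

#' Intersection-over-union of two logical masks
#' @param a,b logical matrices of identical dimension
#' @return scalar in [0, 1] (1 when both masks are empty)
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
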