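#' Write a stimulus image as PNG
#'
#' @param image H x W x 3 array in \[0,1\]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_stimulus_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the 'png' package is required for PNG export")
  png::writePNG(clamp(unclass(image), 0, 1), path)
  invisible(path)
}

#' Write a morph/edit sequence as a horizontal PNG filmstrip
#' @param images list of equal-sized H x W x 3 arrays
#' @param path output file
#' @return `path`, invisibly
#' @export
write_filmstrip_png <- function(images, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the 'png' package is required for PNG export")
  h <- nrow(images[[1]])
  strip <- do.call(cbind, lapply(images, function(im) {
    m <- clamp(unclass(im), 0, 1)
    matrix(rgb(m[, , 1], m[, , 2], m[, , 3]), h)
  }))
  arr <- array(0, c(h, ncol(strip), 3))
  cv <- t(col2rgb(strip)) / 255
  arr[, , 1] <- matrix(cv[, 1], h); arr[, , 2] <- matrix(cv[, 2], h)
  arr[, , 3] <- matrix(cv[, 3], h)
  png::writePNG(arr, path)
  invisible(path)
}

#' Write a dataset's factors and labels as CSV + JSON manifest
#'
#' @param dataset result of [make_dataset()]
#' @param dir output directory (created if missing)
#' @param write_images also write each stimulus as PNG
#' @return the manifest path, invisibly
#' @export
write_dataset <- function(dataset, dir, write_images = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fac <- do.call(rbind, lapply(seq_along(dataset$factors), function(i) {
    v <- factors_to_vec(dataset$factors[[i]])
    cbind(data.frame(stimulus = i, material_class = dataset$labels[i],
                     light_category = dataset$factors[[i]]$light_category),
          as.data.frame(as.list(v)))
  }))
  utils::write.csv(fac, file.path(dir, "factors.csv"), row.names = FALSE)
  if (write_images && !is.null(dataset$images)) {
    for (i in seq_along(dataset$images))
      write_stimulus_png(dataset$images[[i]],
                         file.path(dir, sprintf("stimulus_%04d.png", i)))
  }
  manifest <- list(n = length(dataset$factors),
                   classes = as.list(table(dataset$labels)),
                   files = list(factors = "factors.csv"))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}

#' Serialise trained boundaries to CSV
#' @param boundaries list of `boundary_model`
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_boundaries <- function(boundaries, path) {
  df <- do.call(rbind, lapply(boundaries, function(b) {
    data.frame(layer = b$layer_index, t(b$weights), bias = b$bias,
               C_selected = b$C_selected, cv_accuracy = b$cv_accuracy,
               norm_lo = (b$norm_bounds %||% c(NA, NA))[1],
               norm_hi = (b$norm_bounds %||% c(NA, NA))[2])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
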