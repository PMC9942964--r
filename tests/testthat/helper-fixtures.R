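# Shared fixtures, built once per test run.  Everything is generated in
# code from fixed seeds; nothing is read from disk.

fx <- new.env()

# small generator configuration used throughout the unit tests
fx_gen_cfg <- function(resolution = 48) {
  key <- paste0("gen", resolution)
  if (is.null(fx[[key]]))
    fx[[key]] <- generator_config(resolution = resolution)
  fx[[key]]
}

# n codes per class with factors and labels (no rendering)
fx_codes <- function(n_per_class = 30, seed = 101, cfg = fx_gen_cfg()) {
  key <- paste0("codes", n_per_class, "_", seed)
  if (is.null(fx[[key]])) {
    classes <- rep(c("milky", "glycerin"), each = n_per_class)
    seeds <- withr::with_seed(seed, sample.int(2^30, length(classes)))
    factors <- mapply(function(s, cl) sample_scene(s, cl),
                      seeds, classes, SIMPLIFY = FALSE)
    codes <- mapply(function(f, s) encode_factors(f, cfg, rng_seed = s),
                    factors, seeds + 7L, SIMPLIFY = FALSE)
    fx[[key]] <- list(codes = codes, factors = factors, labels = classes)
  }
  fx[[key]]
}

fx_codes_array <- function(ds) {
  L <- nrow(ds$codes[[1]]); d <- ncol(ds$codes[[1]])
  arr <- array(0, c(length(ds$codes), L, d))
  for (i in seq_along(ds$codes)) arr[i, , ] <- ds$codes[[i]]
  arr
}

# random latent codes (not factor-consistent; for algebraic identities)
fx_random_code <- function(cfg = fx_gen_cfg(), seed = 1) {
  withr::with_seed(seed, latent_code(matrix(rnorm(cfg$L * cfg$d), cfg$L)))
}
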