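#' Default pipeline configuration
#'
#' Desk-scale defaults for the end-to-end synthetic replication.  Sizes are
#' deliberately smaller than the full-scale protocol (which used 500 images
#' per class for boundary training and 150 evaluation images) so a complete
#' run stays in the minutes range on one CPU; all sizes scale up by config.
#'
#' @param n_train_per_class training stimuli per material class
#' @param n_eval evaluation stimuli (ratings + tuning curve)
#' @param resolution render resolution for full decodes
#' @param n_exp3_per_cell morph sequences per design cell
#' @param ica list: n_targets, n_extra_sources, resize_to, patch, per_image, K
#' @param baseline list: enabled, methods, embed_dim, perplexity, pixel_res
#' @param stages character vector of stages to run
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(n_train_per_class = 150L, n_eval = 100L,
                            resolution = 64L, n_exp3_per_cell = 50L,
                            ica = list(n_targets = 10L, n_extra_sources = 10L,
                                       resize_to = 128L, patch = 12L,
                                       per_image = 10L, K = 16L),
                            baseline = list(enabled = TRUE,
                                            methods = c("tsne", "mds"),
                                            embed_dim = 16L, perplexity = 15,
                                            pixel_res = 32L),
                            stages = c("dataset", "probe", "baselines",
                                       "editing", "exp1", "exp3", "ica")) {
  structure(list(n_train_per_class = as.integer(n_train_per_class),
                 n_eval = as.integer(n_eval),
                 resolution = as.integer(resolution),
                 n_exp3_per_cell = as.integer(n_exp3_per_cell),
                 ica = ica, baseline = baseline, stages = stages),
            class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  req <- c("n_train_per_class", "n_eval", "resolution", "n_exp3_per_cell",
           "ica", "baseline", "stages")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stopf("pipeline config is missing fields: %s", paste(miss, collapse = ", "))
  if (cfg$n_train_per_class < 10 || cfg$n_eval < 10)
    stopf("pipeline config: n_train_per_class and n_eval must be >= 10")
  invisible(TRUE)
}

# build (codes, factors, labels, images?) for n stimuli per class
synth_codes <- function(n_per_class, gen_cfg, seed, render = FALSE,
                        scene_cfg = scene_config()) {
  classes <- rep(c("milky", "glycerin"), each = n_per_class)
  seeds <- with_seed(seed, sample.int(2^30, 2 * n_per_class))
  factors <- mapply(function(s, cl) sample_scene(s, cl, scene_cfg),
                    seeds, classes, SIMPLIFY = FALSE)
  codes <- mapply(function(f, s) encode_factors(f, gen_cfg, rng_seed = s),
                  factors, seeds + 1L, SIMPLIFY = FALSE)
  images <- if (render)
    lapply(codes, function(cd) decode(cd, gen_cfg)$image) else NULL
  list(codes = codes, factors = factors, labels = classes, images = images)
}

codes_to_array <- function(codes) {
  L <- nrow(codes[[1]]); d <- ncol(codes[[1]])
  arr <- array(0, c(length(codes), L, d))
  for (i in seq_along(codes)) arr[i, , ] <- codes[[i]]
  arr
}

#' Run the full synthetic replication pipeline
#'
#' Executes, in order: stimulus/dataset synthesis, layer-wise boundary
#' probing with the rating tuning curve, pixel-embedding baselines,
#' boundary-normal editing selectivity, the discrimination experiment
#' (signal detection), the forced-choice morphing experiment with the
#' multinomial choice model, and ICA kernel discovery.  Every stage derives
#' its own child seed from the master seed, so stages are independently
#' reproducible.
#'
#' @param config `pipeline_config` (or path to a JSON file with its fields)
#' @param seed master integer seed
#' @param gen_cfg `generator_config`
#' @param outdir optional output directory for CSV/JSON artifacts
#' @param observer `observer_model`
#' @return list of class `pipeline_report`
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         gen_cfg = generator_config(resolution = 64),
                         outdir = NULL, observer = observer_model()) {
  if (is.character(config)) {
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg0 <- pipeline_config()
    for (nm in intersect(names(raw), names(cfg0))) {
      if (nm %in% c("ica", "baseline"))
        cfg0[[nm]] <- utils::modifyList(cfg0[[nm]], as.list(raw[[nm]]))
      else cfg0[[nm]] <- raw[[nm]]
    }
    config <- cfg0
  }
  validate_pipeline_config(config)
  report <- list(seed = seed, config = config[setdiff(names(config), "")])
  run_stage <- function(name) name %in% config$stages

  ## ---- dataset ----------------------------------------------------------
  train <- synth_codes(config$n_train_per_class, gen_cfg,
                       child_seed(seed, "train"))
  ev_cls <- synth_codes(ceiling(config$n_eval / 2), gen_cfg,
                        child_seed(seed, "eval"))
  keep <- seq_len(config$n_eval)
  evset <- list(codes = ev_cls$codes[keep], factors = ev_cls$factors[keep],
                labels = ev_cls$labels[keep])
  ratings_tab <- simulate_ratings(evset$factors, observer,
                                  child_seed(seed, "ratings"))
  ratings <- normalize_ratings(ratings_tab)$ratings
  report$dataset <- list(n_train = length(train$codes),
                         n_eval = length(evset$codes))

  ## ---- probing ----------------------------------------------------------
  boundaries <- NULL
  if (run_stage("probe")) {
    lat <- codes_to_array(train$codes)
    boundaries <- train_layer_boundaries(lat, train$labels,
                                         seed = child_seed(seed, "probe"))
    boundaries <- lapply(boundaries, calibrate_boundary,
                         eval_codes = evset$codes)
    curve <- tuning_curve(boundaries, evset$codes, ratings)
    tc <- curve[curve$attribute == "translucency", ]
    report$probe <- list(
      n_boundaries = length(boundaries),
      cv_accuracy = vapply(boundaries, `[[`, 0, "cv_accuracy"),
      tuning_curve = curve,
      argmax_layer = tc$layer[which.max(tc$r)],
      argmax_in_middle = tc$layer[which.max(tc$r)] %in% gen_cfg$groups$middle)
  }

  ## ---- pixel-embedding baselines ----------------------------------------
  if (run_stage("baselines") && isTRUE(config$baseline$enabled)) {
    tr_imgs <- lapply(train$codes, function(cd) decode(cd, gen_cfg)$image)
    ev_imgs <- lapply(evset$codes, function(cd) decode(cd, gen_cfg)$image)
    bl <- lapply(config$baseline$methods, function(mth)
      pixel_embedding_baseline(tr_imgs, train$labels, ev_imgs, ratings,
                               method = mth,
                               embed_dim = config$baseline$embed_dim,
                               perplexity = config$baseline$perplexity,
                               pixel_res = config$baseline$pixel_res,
                               seed = child_seed(seed, paste0("bl-", mth))))
    names(bl) <- config$baseline$methods
    report$baselines <- lapply(bl, function(b)
      list(curve = b$curve,
           r_translucency = b$curve$r[b$curve$attribute == "translucency"]))
    if (!is.null(report$probe)) {
      best_mid <- max(report$probe$tuning_curve$r[
        report$probe$tuning_curve$attribute == "translucency" &
          report$probe$tuning_curve$layer %in% gen_cfg$groups$middle])
      report$baselines_below_middle <- all(vapply(report$baselines,
        function(b) b$r_translucency < best_mid, TRUE))
    }
  }

  ## ---- editing selectivity ----------------------------------------------
  if (run_stage("editing") && !is.null(boundaries)) {
    mid_l <- gen_cfg$groups$middle[ceiling(length(gen_cfg$groups$middle) / 2)]
    late_l <- gen_cfg$groups$late[min(3, length(gen_cfg$groups$late))]
    base_code <- evset$codes[[1]]
    ed_mid <- evaluate_edit(edit_along_normal(base_code, boundaries[[mid_l]],
                                              gen_cfg), gen_cfg)
    ed_late <- evaluate_edit(edit_along_normal(base_code, boundaries[[late_l]],
                                               gen_cfg), gen_cfg)
    report$editing <- list(
      middle_layer = mid_l, late_layer = late_l,
      middle = ed_mid$report, late = ed_late$report,
      middle_tau_monotone = ed_mid$tau_monotone_nonincreasing,
      middle_shape_iou_all1 = all(ed_mid$report$shape_iou == 1),
      late_tau_range = diff(range(ed_late$report$tau_readout)))
  }

  ## ---- Experiment 1: discrimination -------------------------------------
  if (run_stage("exp1")) {
    scores <- c(realism_offsets(config$n_eval, observer$image_sd,
                                child_seed(seed, "exp1-r")),
                realism_offsets(config$n_eval, observer$image_sd,
                                child_seed(seed, "exp1-g")))
    is_real <- rep(c(TRUE, FALSE), each = config$n_eval)
    jud <- simulate_discrimination(scores, is_real, observer, 2L,
                                   child_seed(seed, "exp1"))
    report$exp1 <- discrimination_summary(jud)
  }

  ## ---- Experiment 3: morph sequences + choice model ---------------------
  if (run_stage("exp3")) {
    seqs <- build_exp3_stimuli(train$codes, train$labels, gen_cfg,
                               n_per_cell = config$n_exp3_per_cell,
                               seed = child_seed(seed, "exp3-stim"))
    choices <- simulate_exp3_choices(seqs, gen_cfg, observer,
                                     child_seed(seed, "exp3-choice"))
    hm <- choice_heatmap(choices)
    cm <- fit_choice_model(choices, n_boot = 300L,
                           seed = child_seed(seed, "exp3-boot"))
    modal <- apply(hm$proportions, 1, function(p) colnames(hm$proportions)[which.max(p)])
    report$exp3 <- list(n_sequences = length(seqs), heatmap = hm,
                        model = cm, modal_attribute = modal)
  }

  ## ---- ICA feature discovery --------------------------------------------
  if (run_stage("ica")) {
    ic <- config$ica
    hi <- build_high_translucency_set(evset$codes, ratings$translucency,
                                      gen_cfg, n_targets = ic$n_targets,
                                      n_extra_sources = ic$n_extra_sources)
    patches <- sample_patches(hi$images, resize_to = ic$resize_to,
                              patch = ic$patch, per_image = ic$per_image,
                              seed = child_seed(seed, "ica-patch"))
    bank <- classify_kernels(learn_ica_kernels(patches, K = ic$K,
                                               seed = child_seed(seed, "ica")))
    report$ica <- list(n_pair_images = nrow(hi$pairs), K = bank$K,
                       annotations = bank$annotations)
  }

  ## ---- persist -----------------------------------------------------------
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_to_json(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(report$probe))
      utils::write.csv(report$probe$tuning_curve,
                       file.path(outdir, "tuning_curve.csv"),
                       row.names = FALSE)
  }
  structure(report, class = "pipeline_report")
}

# strip heavy objects to a JSON-serialisable summary
report_to_json <- function(report) {
  out <- list(seed = report$seed, dataset = report$dataset)
  if (!is.null(report$probe))
    out$probe <- list(n_boundaries = report$probe$n_boundaries,
                      argmax_layer = report$probe$argmax_layer,
                      argmax_in_middle = report$probe$argmax_in_middle,
                      cv_accuracy = report$probe$cv_accuracy)
  if (!is.null(report$baselines))
    out$baselines <- lapply(report$baselines, function(b)
      list(r_translucency = b$r_translucency))
  if (!is.null(report$baselines_below_middle))
    out$baselines_below_middle <- report$baselines_below_middle
  if (!is.null(report$editing))
    out$editing <- report$editing[c("middle_layer", "late_layer",
                                    "middle_tau_monotone",
                                    "middle_shape_iou_all1",
                                    "late_tau_range")]
  if (!is.null(report$exp1)) out$exp1 <- list(overall = report$exp1$overall)
  if (!is.null(report$exp3))
    out$exp3 <- list(n_sequences = report$exp3$n_sequences,
                     modal_attribute = report$exp3$modal_attribute)
  if (!is.null(report$ica))
    out$ica <- list(n_pair_images = report$ica$n_pair_images,
                    K = report$ica$K)
  out
}
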