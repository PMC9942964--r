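test_that("ratings: range, determinism, monotone link, attribute correlations", {
  taus <- seq(0.02, 0.98, length.out = 30)
  facs <- lapply(taus, function(t) c(tau = t))
  noiseless <- observer_model(n_observers = 4, noise_sd = 0, bias_sd = 0,
                              noise_mult_sd = 0)
  rt <- simulate_ratings(facs, noiseless, seed = 3)
  expect_true(all(rt$rating %in% 1:7))
  expect_identical(rt, simulate_ratings(facs, noiseless, seed = 3))
  # zero noise: rating order equals tau order for every observer
  for (ob in unique(rt$observer)) {
    sub <- rt[rt$observer == ob & rt$attribute == "translucency", ]
    r_by_s <- sub$rating[order(sub$stimulus)]
    expect_true(all(diff(r_by_s) >= 0))
  }

  # default model on 150 stimuli: all pairwise attribute correlations > 0.5
  facs150 <- lapply(withr::with_seed(8, runif(150)), function(t) c(tau = t))
  rt150 <- simulate_ratings(facs150, observer_model(), seed = 4)
  mean_ratings <- normalize_ratings(rt150)$ratings
  cm <- attribute_correlations(mean_ratings)
  off <- cm$r[upper.tri(cm$r)]
  expect_true(all(off > 0.5))
  expect_true(all(cm$p[upper.tri(cm$p)] < 0.05))
})

test_that("rating-link manipulation raises rating-tau rank correlation", {
  taus <- withr::with_seed(2, runif(80))
  facs <- lapply(taus, function(t) c(tau = t))
  weak <- observer_model(noise_sd = 1.5,
                         link_slopes = c(translucency = 0.3,
                                         see_through = 0.3, glow = 0.3))
  strong <- observer_model(noise_sd = 1.5,
                           link_slopes = c(translucency = 0.6,
                                           see_through = 0.6, glow = 0.6))
  rw <- normalize_ratings(simulate_ratings(facs, weak, seed = 6))$ratings
  rs <- normalize_ratings(simulate_ratings(facs, strong, seed = 6))$ratings
  expect_gt(cor(rs$translucency, taus, method = "spearman"),
            cor(rw$translucency, taus, method = "spearman"))
})

test_that("signal detection: chance and ceiling asymptotes", {
  n_img <- 300
  scores <- withr::with_seed(1, rnorm(n_img, 0, 0.0))
  is_real <- rep(c(TRUE, FALSE), each = n_img / 2)
  guess <- observer_model(d_prime = 0, criterion = 0, image_sd = 0)
  jd <- simulate_discrimination(scores, is_real, guess, n_repeats = 2, seed = 2)
  er <- mean(jd$error)
  se2 <- 2 * sqrt(0.25 / nrow(jd))
  expect_lt(abs(er - 0.5), se2 * 2)

  sharp <- observer_model(d_prime = 10, criterion = 0, image_sd = 0)
  jd2 <- simulate_discrimination(scores, is_real, sharp, n_repeats = 2, seed = 2)
  expect_lt(mean(jd2$error), 0.01)
})

test_that("SDT calibration oracle reproduces the target error rates", {
  cal <- sdt_calibrate(0.28, 0.25, image_sd = 0.5)
  # closed-form check
  s <- sqrt(1 + 0.5^2)
  expect_equal(1 - pnorm((cal$criterion + cal$d_prime / 2) / s), 0.28,
               tolerance = 1e-12)
  expect_equal(pnorm((cal$criterion - cal$d_prime / 2) / s), 0.25,
               tolerance = 1e-12)

  # simulation at the full design size reproduces both within 2 points
  model <- observer_model(d_prime = cal$d_prime, criterion = cal$criterion)
  scores <- c(realism_offsets(150, model$image_sd, seed = 3),
              realism_offsets(150, model$image_sd, seed = 4))
  is_real <- rep(c(TRUE, FALSE), each = 150)
  jd <- simulate_discrimination(scores, is_real, model, n_repeats = 2, seed = 4)
  sm <- discrimination_summary(jd)
  e_gen <- sm$overall$error_rate[sm$overall$condition == "generated"]
  e_real <- sm$overall$error_rate[sm$overall$condition == "real"]
  expect_lt(abs(e_gen - 0.28), 0.02)
  expect_lt(abs(e_real - 0.25), 0.02)
})

test_that("choice simulation: argmax limit, distributional checks, exchangeability", {
  cfg <- fx_gen_cfg()
  ds <- fx_codes(12)
  seqs <- build_exp3_stimuli(ds$codes, ds$labels, cfg, n_per_cell = 4,
                             seed = 2)
  argmax <- observer_model(temperature = 0)
  ch <- simulate_exp3_choices(seqs, cfg, argmax, seed = 5)
  expect_identical(nrow(ch), length(seqs) * argmax$n_observers)
  # temperature 0: early-layer sequences always yield shape/orientation
  early <- ch[ch$layer_group == "early", ]
  expect_true(all(early$choice == "shape/orientation"))

  # default temperature: middle-layer OT sequences choose material modally
  ch2 <- simulate_exp3_choices(seqs, cfg, observer_model(), seed = 6)
  mot <- ch2[ch2$layer_group == "middle" & ch2$pair_condition == "OT", ]
  expect_identical(names(which.max(table(mot$choice))), "material")

  # observer ids are exchangeable labels
  ch3 <- simulate_exp3_choices(seqs, cfg, observer_model(), seed = 6)
  expect_identical(ch2, ch3)
})

test_that("all-zero deltas are flagged and yield uniform choices", {
  cfg <- fx_gen_cfg()
  code <- fx_random_code(cfg, 4)
  sq <- morph_sequence(code, code, 7:9, cfg, decode_images = FALSE)
  sq$pair_condition <- "TT"; sq$layer_group <- "middle"
  expect_warning(simulate_exp3_choices(list(sq), cfg, observer_model(),
                                       seed = 1), "uniform")
})
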