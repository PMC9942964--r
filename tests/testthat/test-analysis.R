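test_that("normalize_ratings: min-max mapping, fallback, affine invariance", {
  tab <- data.frame(observer = 1, stimulus = 1:7, attribute = "translucency",
                    rating = 1:7)
  out <- normalize_ratings(tab)
  expect_equal(out$ratings$translucency, seq(0, 1, length.out = 7))
  expect_equal(out$ratings$translucency[4], 0.5)

  # constant-rating observer maps to 0.5 and is flagged
  tab2 <- rbind(tab, data.frame(observer = 2, stimulus = 1:7,
                                attribute = "translucency", rating = 4))
  out2 <- normalize_ratings(tab2)
  expect_identical(out2$flagged$observer, 2)
  expect_equal(out2$ratings$translucency,
               (seq(0, 1, length.out = 7) + 0.5) / 2)

  # per-observer affine rating transforms do not change the output
  tab3 <- tab; tab3$rating <- tab$rating * 2 + 3
  expect_equal(normalize_ratings(tab3)$ratings, out$ratings)
})

test_that("attribute correlations: duplicates, negation, degenerate input", {
  x <- withr::with_seed(1, runif(20))
  df <- data.frame(a = x, b = x, c = 1 - x)
  cm <- attribute_correlations(df)
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_true(all(diag(cm$r) == 1))
  expect_equal(cm$r, t(cm$r))
  dfz <- data.frame(a = x, z = rep(0.5, 20))
  expect_true(is.na(attribute_correlations(dfz)$r["a", "z"]))
  expect_error(attribute_correlations(df[1:5, ]), "10")
})

test_that("translucency bins use the stated intervals and conserve counts", {
  expect_identical(as.character(bin_by_translucency(0.61)), "high")
  expect_identical(as.character(bin_by_translucency(0.2)), "intermediate")
  expect_identical(as.character(bin_by_translucency(c(0, 0.19999))),
                   c("low", "low"))
  expect_identical(as.character(bin_by_translucency(c(0.6, 1))),
                   c("high", "high"))
  x <- withr::with_seed(2, runif(100))
  expect_identical(sum(table(bin_by_translucency(x))), 100L)
  expect_error(bin_by_translucency(1.2), "\\[0, 1\\]")
})

test_that("discrimination summary: perfect, chance, and shape of output", {
  n <- 40
  jd <- data.frame(observer = rep(1:4, each = n), image = rep(1:n, 4),
                   repeat_ = 1L, is_real = rep(c(TRUE, FALSE), n * 2),
                   judged_real = rep(c(TRUE, FALSE), n * 2))
  jd$error <- jd$judged_real != jd$is_real
  sm <- discrimination_summary(jd)
  expect_true(all(sm$overall$error_rate == 0))
  expect_true(all(sm$misjudgment$pct_observers_misjudging == 0))

  coin <- withr::with_seed(5, {
    jd$judged_real <- sample(c(TRUE, FALSE), nrow(jd), replace = TRUE)
    jd$error <- jd$judged_real != jd$is_real
    jd
  })
  smc <- discrimination_summary(coin)
  se2 <- 2 * sqrt(0.25 / (nrow(coin) / 2))
  expect_true(all(abs(smc$overall$error_rate - 0.5) < 2 * se2))
})

test_that("choice heatmap rows sum to one; argmax worlds concentrate mass", {
  cfg <- fx_gen_cfg()
  ds <- fx_codes(12)
  seqs <- build_exp3_stimuli(ds$codes, ds$labels, cfg, n_per_cell = 3,
                             seed = 2)
  ch <- simulate_exp3_choices(seqs, cfg, observer_model(temperature = 0),
                              seed = 3)
  hm <- choice_heatmap(ch)
  expect_equal(unname(rowSums(hm$proportions)), rep(1, 9), tolerance = 1e-12)
  early_rows <- grep("^early", rownames(hm$proportions))
  expect_true(all(hm$proportions[early_rows, "shape/orientation"] == 1))

  # permuting row order leaves the matrix unchanged
  hm2 <- choice_heatmap(ch[withr::with_seed(1, sample(nrow(ch))), ])
  expect_identical(hm$proportions, hm2$proportions)

  # empty cell errors with the cell name
  expect_error(choice_heatmap(ch[ch$layer_group != "middle" |
                                   ch$pair_condition != "OO", ]),
               "middle x OO")
})

test_that("saturated choice model reproduces empirical cell frequencies", {
  cfg <- fx_gen_cfg()
  ds <- fx_codes(12)
  seqs <- build_exp3_stimuli(ds$codes, ds$labels, cfg, n_per_cell = 4,
                             seed = 7)
  ch <- simulate_exp3_choices(seqs, cfg, observer_model(temperature = 0.8),
                              seed = 8)
  m <- suppressWarnings(fit_choice_model(ch, n_boot = 50, seed = 9))
  emp <- m$counts / rowSums(m$counts)
  fit <- matrix(m$conditional$prob, 9, 4, byrow = TRUE)
  if (!m$separation)
    expect_lt(max(abs(fit - emp)), 1e-5)
  expect_true(all(m$conditional$lower <= m$conditional$prob + 1e-9))
  expect_true(all(m$conditional$upper >= m$conditional$prob - 1e-9))
})

test_that("two-cell log-odds recovery with analytic truth", {
  # balanced design, known probabilities (0.9, 0.1) vs (0.1, 0.9)
  atts <- c("shape/orientation", "material")
  mk <- function(p_shape, layer, n = 400) {
    data.frame(observer = rep(1:20, length.out = n), sequence = NA,
               pair_condition = "OT", layer_group = layer,
               choice = withr::with_seed(nchar(layer) + 1,
                 sample(atts, n, TRUE, c(p_shape, 1 - p_shape))))
  }
  ch <- rbind(mk(0.9, "early"), mk(0.1, "middle"))
  m <- suppressWarnings(fit_choice_model(ch, n_boot = 100, seed = 3))
  sub <- m$conditional[m$conditional$choice == "material" &
                         m$conditional$pair_condition == "OT" &
                         m$conditional$layer_group %in% c("early", "middle"), ]
  lo <- log(sub$prob / (1 - sub$prob))
  expect_equal(abs(diff(lo)), 2 * log(9), tolerance = 0.8)
})
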