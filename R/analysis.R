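#' Per-observer min-max normalisation and across-observer averaging
#'
#' Each observer's ratings of each attribute are min-max mapped to \[0, 1\]
#' (an observer who used the full 1..7 scale maps 1 to 0, 7 to 1, 4 to 0.5);
#' the normalised ratings are then averaged across observers per stimulus.
#' An observer with constant ratings for an attribute is mapped to 0.5
#' everywhere and flagged.
#'
#' @param table a `rating_table` data frame
#' @return list with `ratings` (data frame: one row per stimulus, one column
#'   per attribute) and `flagged` (data frame of constant-rating
#'   observer/attribute combinations)
#' @export
normalize_ratings <- function(table) {
  stopifnot(all(c("observer", "stimulus", "attribute", "rating") %in%
                  names(table)))
  atts <- unique(table$attribute)
  stims <- sort(unique(table$stimulus))
  flagged <- list()
  out <- data.frame(row.names = seq_along(stims))
  for (att in atts) {
    sub <- table[table$attribute == att, ]
    norm <- numeric(nrow(sub))
    for (ob in unique(sub$observer)) {
      sel <- sub$observer == ob
      r <- sub$rating[sel]
      if (max(r) == min(r)) {
        norm[sel] <- 0.5
        flagged[[length(flagged) + 1L]] <-
          data.frame(observer = ob, attribute = att)
      } else {
        norm[sel] <- (r - min(r)) / (max(r) - min(r))
      }
    }
    out[[att]] <- vapply(stims, function(s)
      mean(norm[sub$stimulus == s]), 0)
  }
  list(ratings = out,
       flagged = if (length(flagged)) do.call(rbind, flagged) else
         data.frame(observer = integer(), attribute = character()))
}

#' Pairwise Pearson correlations between attribute ratings
#'
#' @param ratings data frame of per-stimulus mean normalised ratings
#'   (>= 10 rows)
#' @return list with `r` (symmetric correlation matrix, unit diagonal) and
#'   `p` (two-sided p-values, NA on the diagonal); zero-variance attributes
#'   yield NA entries
#' @export
attribute_correlations <- function(ratings) {
  stopifnot(is.data.frame(ratings), nrow(ratings) >= 10)
  k <- ncol(ratings)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(names(ratings), names(ratings))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- ratings[[i]]; y <- ratings[[j]]
    if (sd(x) < 1e-12 || sd(y) < 1e-12) {
      r[i, j] <- r[j, i] <- NA_real_
    } else {
      ct <- cor.test(x, y)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' Bin stimuli by mean normalised translucency rating
#'
#' Bins: low \[0, 0.2), intermediate \[0.2, 0.6), high \[0.6, 1\]
#' (lower-closed convention; the top bin includes 1).
#'
#' @param x numeric ratings in \[0, 1\]
#' @return factor with levels `low`, `intermediate`, `high`
#' @export
bin_by_translucency <- function(x) {
  if (any(x < 0 | x > 1)) stopf("ratings must lie in [0, 1]")
  cut(x, breaks = c(0, 0.2, 0.6, 1 + 1e-12), right = FALSE,
      labels = c("low", "intermediate", "high"))
}

#' Summarise a discrimination experiment
#'
#' @param judgments `judgment_table` from [simulate_discrimination()]
#' @return list with `error_rates` (per condition x repeat, plus overall per
#'   condition) and `misjudgment` (per-image percentage of observers
#'   misjudging it, by condition and repeat)
#' @export
discrimination_summary <- function(judgments) {
  cond <- ifelse(judgments$is_real, "real", "generated")
  er <- aggregate(error ~ cond + repeat_, data =
                    transform(judgments, cond = cond), FUN = mean)
  names(er) <- c("condition", "repeat_", "error_rate")
  overall <- aggregate(error ~ cond, data = transform(judgments, cond = cond),
                       FUN = mean)
  names(overall) <- c("condition", "error_rate")
  mis <- aggregate(error ~ image + repeat_ + cond,
                   data = transform(judgments, cond = cond), FUN = mean)
  names(mis) <- c("image", "repeat_", "condition", "pct_observers_misjudging")
  mis$pct_observers_misjudging <- 100 * mis$pct_observers_misjudging
  list(error_rates = er, overall = overall, misjudgment = mis)
}

#' Choice-proportion heat map for the forced-choice experiment
#'
#' @param choices `choice_table`
#' @return list with `proportions` (9 cells x 4 attributes; every row sums
#'   to 1) and `sd` (same shape; SD of per-observer proportions)
#' @export
choice_heatmap <- function(choices) {
  atts <- c("shape/orientation", "color", "material", "lighting")
  cells <- expand.grid(layer_group = c("early", "middle", "late"),
                       pair_condition = c("OT", "OO", "TT"),
                       stringsAsFactors = FALSE)
  pm <- sdm <- matrix(NA_real_, nrow(cells), length(atts),
                      dimnames = list(paste(cells$layer_group,
                                            cells$pair_condition, sep = ":"),
                                      atts))
  for (r in seq_len(nrow(cells))) {
    sel <- choices$layer_group == cells$layer_group[r] &
      choices$pair_condition == cells$pair_condition[r]
    if (!any(sel))
      stopf("empty cell: %s x %s", cells$layer_group[r],
            cells$pair_condition[r])
    sub <- choices[sel, ]
    pm[r, ] <- vapply(atts, function(a) mean(sub$choice == a), 0)
    per_obs <- t(vapply(unique(sub$observer), function(ob)
      vapply(atts, function(a)
        mean(sub$choice[sub$observer == ob] == a), 0),
      numeric(length(atts))))
    sdm[r, ] <- apply(per_obs, 2, sd)
  }
  list(proportions = pm, sd = sdm, cells = cells)
}

# ---- multinomial logit (softmax regression) on aggregated counts ----------

# build the cell-level design matrix: intercept + layer + pair + interaction
exp3_design <- function(cells) {
  lg <- factor(cells$layer_group, levels = c("early", "middle", "late"))
  pc <- factor(cells$pair_condition, levels = c("OT", "OO", "TT"))
  model.matrix(~ lg * pc)
}

# negative log-likelihood and gradient for counts (cells x K categories)
mnl_nll <- function(beta, Xd, counts, ridge = 0) {
  K <- ncol(counts); P <- ncol(Xd)
  B <- matrix(beta, P, K - 1)            # reference category = column 1
  eta <- cbind(0, Xd %*% B)
  m <- apply(eta, 1, max)
  lse <- m + log(rowSums(exp(eta - m)))
  ll <- sum(counts * eta) - sum(rowSums(counts) * lse)
  -ll + 0.5 * ridge * sum(beta^2)
}

mnl_grad <- function(beta, Xd, counts, ridge = 0) {
  K <- ncol(counts); P <- ncol(Xd)
  B <- matrix(beta, P, K - 1)
  eta <- cbind(0, Xd %*% B)
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  resid <- counts - rowSums(counts) * pr
  -as.vector(crossprod(Xd, resid[, -1, drop = FALSE])) + ridge * beta
}

fit_mnl_counts <- function(Xd, counts, ridge = 0) {
  P <- ncol(Xd); K <- ncol(counts)
  start <- numeric(P * (K - 1))
  fit <- optim(start, mnl_nll, mnl_grad, Xd = Xd, counts = counts,
               ridge = ridge, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  B <- matrix(fit$par, P, K - 1)
  eta <- cbind(0, Xd %*% B)
  pr <- exp(eta - apply(eta, 1, max)); pr <- pr / rowSums(pr)
  list(coef = B, probs = pr, nll = fit$value, convergence = fit$convergence)
}

#' Multinomial-logit model of forced-choice attribute selections
#'
#' Maximum-likelihood softmax regression of the chosen attribute on the
#' layer-manipulation method, the source-target pair type and their
#' interaction (reference category: shape/orientation), with 95% confidence
#' intervals for the conditional choice probabilities per cell obtained by
#' resampling observers with replacement (cluster bootstrap).  Complete
#' separation (unbounded coefficients) is detected and handled by a
#' lightly ridge-penalised refit, with a warning.
#'
#' @param choices `choice_table`
#' @param n_boot bootstrap resamples (default 500)
#' @param seed integer seed for the bootstrap
#' @param ridge penalty used only on separation fallback
#' @return list of class `choice_model`: `coef` (design-parameter x
#'   category-1 matrix), `conditional` (data frame: layer_group,
#'   pair_condition, choice, prob, lower, upper), `separation` flag
#' @export
fit_choice_model <- function(choices, n_boot = 500L, seed = 1L,
                             ridge = 1e-3) {
  atts <- c("shape/orientation", "color", "material", "lighting")
  if (length(unique(choices$choice)) < 2L)
    stopf("need at least 2 observed choice categories")
  cells <- expand.grid(layer_group = c("early", "middle", "late"),
                       pair_condition = c("OT", "OO", "TT"),
                       stringsAsFactors = FALSE)
  Xd <- exp3_design(cells)
  count_mat <- function(ch) {
    t(vapply(seq_len(nrow(cells)), function(r) {
      sel <- ch$layer_group == cells$layer_group[r] &
        ch$pair_condition == cells$pair_condition[r]
      vapply(atts, function(a) sum(ch$choice[sel] == a), 0)
    }, numeric(length(atts))))
  }
  counts <- count_mat(choices)
  fit <- fit_mnl_counts(Xd, counts)
  separation <- any(abs(fit$coef) > 12)
  if (separation) {
    warning("complete separation detected; refitting with a small ridge penalty")
    fit <- fit_mnl_counts(Xd, counts, ridge = ridge)
  }
  obs_ids <- unique(choices$observer)
  counts_by_obs <- lapply(obs_ids, function(ob)
    count_mat(choices[choices$observer == ob, ]))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample.int(length(obs_ids), length(obs_ids), replace = TRUE)
      cb <- Reduce(`+`, counts_by_obs[take])
      fb <- fit_mnl_counts(Xd, cb, ridge = if (any(cb == 0)) ridge else 0)
      as.vector(fb$probs)
    }, numeric(nrow(cells) * length(atts)))
  })
  # t-interval on the bootstrap SE (df = clusters - 1): percentile intervals
  # under-cover noticeably with only ~20 observer clusters
  se <- matrix(apply(boot, 1, sd), nrow(cells))
  tq <- qt(0.975, df = max(1L, length(obs_ids) - 1L))
  lo <- clamp(fit$probs - tq * se, 0, 1)
  hi <- clamp(fit$probs + tq * se, 0, 1)
  conditional <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r)
    data.frame(layer_group = cells$layer_group[r],
               pair_condition = cells$pair_condition[r],
               choice = atts, prob = fit$probs[r, ],
               lower = lo[r, ], upper = hi[r, ],
               row.names = NULL)))
  structure(list(coef = fit$coef, conditional = conditional,
                 separation = separation, counts = counts, cells = cells),
            class = "choice_model")
}
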