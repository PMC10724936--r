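test_that("AUC matches hand-enumerated pair counting", {
  # {pos: 0.9, 0.4; neg: 0.6, 0.1}: 3 concordant pairs of 4
  scores <- c(0.9, 0.4, 0.6, 0.1)
  labels <- c(1, 1, 0, 0)
  expect_equal(auc_score(scores, labels), 3 / 4)
  # separable set
  expect_equal(auc_score(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  # label flip antisymmetry
  expect_equal(auc_score(scores, 1 - labels), 1 - 3 / 4)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC enumeration matches the worked 4-point example", {
  scores <- c(0.9, 0.4, 0.6, 0.1)
  labels <- c(1, 1, 0, 0)
  curve <- roc_points(scores, labels)
  # thresholds: sentinels + midpoints 0.25, 0.5, 0.75
  expect_equal(curve$threshold, c(-Inf, 0.25, 0.5, 0.75, Inf))
  expect_equal(curve$sensitivity, c(1, 1, 0.5, 0.5, 0))
  expect_equal(curve$specificity, c(0, 0.5, 0.5, 1, 1))
  # perfect separation exposes an (Se, Sp) = (1, 1) operating point
  perfect <- roc_points(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_true(any(perfect$sensitivity == 1 & perfect$specificity == 1))
})

test_that("ROC, AUC and cutoff agree with brute-force oracles", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # force some ties
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
    curve <- roc_points(scores, labels)
    for (j in seq_len(nrow(curve))) {
      ss <- oracle_se_sp(scores, labels, curve$threshold[j])
      expect_equal(curve$sensitivity[j], unname(ss["se"]))
      expect_equal(curve$specificity[j], unname(ss["sp"]))
    }
    expect_equal(cutoff_closest_to_01(curve), oracle_cutoff(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  scores <- rnorm(80)
  labels <- sample(0:1, 80, replace = TRUE, prob = c(0.45, 0.55))
  a <- auc_score(scores, labels)
  expect_equal(auc_score(2 * scores + 3, labels), a, tolerance = 1e-12)
  expect_equal(auc_score(exp(scores), labels), a, tolerance = 1e-12)
  expect_equal(auc_score(plogis(scores), labels), a, tolerance = 1e-12)
})

test_that("closest-to-(0,1) cutoff can disagree with the Youden cutoff", {
  # (Se, Sp) pairs where Youden's J and the corner distance pick
  # different points: J prefers (1.0, 0.55), distance prefers (0.7, 0.8)
  scores <- c(rep(1, 7), rep(2, 3), rep(3, 2), rep(4, 9), rep(5, 4))
  labels <- c(rep(0, 7), rep(1, 3), rep(0, 2), rep(1, 9), rep(0, 4))
  curve <- roc_points(scores, labels)
  youden <- curve$threshold[which.max(curve$sensitivity + curve$specificity)]
  chosen <- cutoff_closest_to_01(curve)
  expect_false(youden == chosen)
  expect_equal(chosen, oracle_cutoff(scores, labels))
  d2 <- (1 - curve$sensitivity)^2 + (1 - curve$specificity)^2
  expect_equal(d2[curve$threshold == chosen], min(d2))
  # perfect classifier: distance 0 at the separating threshold
  pc <- roc_points(c(3, 4, 1, 2), c(1, 1, 0, 0))
  t0 <- cutoff_closest_to_01(pc)
  i0 <- which(pc$threshold == t0)
  expect_equal((1 - pc$sensitivity[i0])^2 + (1 - pc$specificity[i0])^2, 0)
})

test_that("balanced threshold minimizes |Se - Sp| with stated tie-breaks", {
  # separable: midpoint of the inner pair, Se = Sp = 1
  expect_equal(balance_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 0.5)
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(1, 1, 0, 0)
  t <- balance_threshold(scores, labels)
  ss <- oracle_se_sp(scores, labels, t)
  expect_equal(unname(ss["se"] - ss["sp"]), 0)
  # all scores equal: only the sentinels exist; smallest wins the tie
  expect_equal(balance_threshold(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), -Inf)
})

test_that("log-odds weights follow the stated closed form", {
  expect_equal(weight_from_accuracy(0.5), 0)
  expect_equal(weight_from_accuracy(0.6735), log(0.6735 / 0.3265),
               tolerance = 1e-12)
  expect_equal(weight_from_accuracy(0.6735), 0.7241, tolerance = 1e-3)
  expect_equal(weight_from_accuracy(1.0), log((1 - 1e-6) / 1e-6))
  expect_equal(weight_from_accuracy(1.0), 13.8155, tolerance = 1e-4)
  expect_lt(weight_from_accuracy(0.3), 0)
})

test_that("M1/M2/M3 vote construction follows each strategy's rule", {
  mk_out <- function(prob, crisp, acc = 0.7) {
    structure(list(lesion_id = seq_along(prob), prob = prob, crisp = crisp,
                   accuracy = acc, feature = "f", algorithm = "logistic",
                   n_folds = 2L),
              class = "model_output")
  }
  labels <- c(1, 1, 0, 0)
  m <- mk_out(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  # single model: M2 votes equal thresholding at its own ROC cutoff
  v2 <- make_votes(list(m), labels, "M2")
  expect_equal(unname(v2$votes[, 1]), as.numeric(m$prob >= v2$cutoffs[1]))
  # identical models: M1 equals M2 (mean cutoff = each cutoff)
  v1 <- make_votes(list(m, m), labels, "M1")
  v2b <- make_votes(list(m, m), labels, "M2")
  expect_equal(v1$votes, v2b$votes)
  # two models with ROC cutoffs 0.4 and 0.6; the probe lesion (row 5)
  # has probability 0.5 in both: M1 (mean cutoff 0.5) -> both vote 1,
  # M2 (own cutoffs) -> votes (1, 0)
  labels5 <- c(1, 1, 0, 0, 1)
  a <- mk_out(c(0.50, 0.45, 0.35, 0.10, 0.5), c(1, 1, 0, 0, 1))
  b <- mk_out(c(0.90, 0.65, 0.55, 0.10, 0.5), c(1, 1, 0, 0, 1))
  va <- make_votes(list(a, b), labels5, "M1")
  expect_equal(va$cutoffs, c(0.4, 0.6))
  expect_equal(va$mean_cutoff, 0.5)
  expect_equal(unname(va$votes[5, ]), c(1, 1))
  vb <- make_votes(list(a, b), labels5, "M2")
  expect_equal(unname(vb$votes[5, ]), c(1, 0))
  # M3 votes are the crisp labels themselves
  v3 <- make_votes(list(a, b), labels5, "M3")
  expect_equal(unname(v3$votes), cbind(a$crisp, b$crisp))
})

test_that("vote aggregation follows the normalized weighted mean", {
  votes <- cbind(c(1, 0), c(1, 0), c(0, 0))
  # unanimous rows keep their label under any weights
  uv <- matrix(1, 2, 3)
  expect_equal(aggregate_votes(uv, "weighted", c(0.55, 0.7, 0.95))$label,
               c(1L, 1L))
  # equal accuracies reduce weighted voting to simple majority
  s <- aggregate_votes(votes, "simple")
  w <- aggregate_votes(votes, "weighted", rep(0.7, 3))
  expect_equal(s$label, w$label)
  expect_equal(w$score, s$score, tolerance = 1e-12)
  # the worked 3-model example: weights overturn the simple majority
  ww <- aggregate_votes(matrix(c(1, 1, 0), 1), "weighted",
                        c(0.55, 0.55, 0.95))
  wgt <- log(0.55 / 0.45)
  W <- log(0.95 / 0.05)
  expect_equal(ww$score, 2 * wgt / (2 * wgt + W), tolerance = 1e-12)
  expect_equal(round(ww$score, 3), 0.12)
  expect_equal(ww$label, 0L)
  expect_equal(aggregate_votes(matrix(c(1, 1, 0), 1), "simple")$label, 1L)
  # tie at exactly 0.5 errs toward the significant class
  expect_equal(aggregate_votes(matrix(c(1, 0), 1), "simple")$label, 1L)
  # all models at or below chance: refuse to weight
  expect_error(aggregate_votes(votes, "weighted", c(0.4, 0.5, 0.45)),
               "simple voting")
})

test_that("weighted label is invariant to the weight scale (log base)", {
  set.seed(12)
  votes <- matrix(sample(0:1, 50 * 5, replace = TRUE), 50)
  acc <- runif(5, 0.55, 0.9)
  lab1 <- aggregate_votes(votes, "weighted", acc)$label
  # natural-log weights scaled by any positive constant (e.g. log10)
  w10 <- log10(acc / (1 - acc))
  score10 <- as.numeric(votes %*% w10) / sum(w10)
  expect_equal(as.integer(score10 >= 0.5), lab1)
})

test_that("top-k sweep has the documented shape and k = 1 behavior", {
  set.seed(41)
  n <- 60
  labels <- sample(0:1, n, replace = TRUE, prob = c(0.45, 0.55))
  outs <- lapply(1:13, function(i) {
    prob <- plogis(2 * (labels - 0.5) + rnorm(n))
    structure(list(lesion_id = 1:n, prob = prob,
                   crisp = as.integer(prob >= 0.5),
                   accuracy = mean((prob >= 0.5) == labels),
                   feature = paste0("f", i), algorithm = "logistic",
                   n_folds = 10L),
              class = "model_output")
  })
  sw <- run_topk_sweep(outs, labels, k_max = 13)
  expect_equal(nrow(sw), 39L)
  expect_equal(as.vector(table(sw$strategy)), rep(13L, 3))
  # every point estimate sits inside its own interval
  expect_true(all(sw$accuracy >= sw$ci_low - 1e-9 &
                    sw$accuracy <= sw$ci_high + 1e-9))
  expect_true(all(sw$auc_crisp >= sw$auc_crisp_low - 1e-9 &
                    sw$auc_crisp <= sw$auc_crisp_high + 1e-9))
  # k = 1 under M2: the ensemble is the single model thresholded at its
  # own ROC cutoff
  one <- sw[sw$strategy == "M2" & sw$k == 1, ]
  cut1 <- cutoff_closest_to_01(roc_points(outs[[1]]$prob, labels))
  acc1 <- 100 * mean((outs[[1]]$prob >= cut1) == labels)
  expect_equal(one$accuracy, acc1)
})
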