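# The worked 8-score example used throughout: 4 positives, 4 negatives.
eight_scores <- c(0.9, 0.7, 0.7, 0.3, 0.8, 0.4, 0.2, 0.1)
eight_labels <- c(1, 1, 1, 1, 0, 0, 0, 0)

test_that("confusion_at counts the worked example and edge thresholds", {
  cm <- confusion_at(eight_scores, eight_labels, 0.5)
  expect_equal(cm[c("TP", "FN", "FP", "TN")], list(TP = 3, FN = 1, FP = 1, TN = 3))
  expect_equal(cm$TPR, 0.75)
  expect_equal(cm$FPR, 0.25)
  expect_equal(cm$PPV, 0.75)
  expect_equal(cm$NPV, 0.75)

  low <- confusion_at(eight_scores, eight_labels, 0)
  expect_equal(c(low$TPR, low$FPR), c(1, 1))
  high <- confusion_at(eight_scores, eight_labels, 2)
  expect_equal(c(high$TPR, high$FPR), c(0, 0))
  expect_true(is.na(high$PPV))

  expect_error(confusion_at(c(1, 2), c(1, 1), 0.5),
               class = "hrss_degenerate_input")
})

test_that("roc_curve endpoints, AUC and monotone sweep behave", {
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)

  curve <- roc_curve(eight_scores, eight_labels)
  expect_equal(curve$auc, 0.75)     # Mann-Whitney with one 0.7/0.8 inversion
  pts <- curve$points
  expect_equal(pts$FPR[1], 0); expect_equal(pts$TPR[1], 0)
  expect_equal(pts$FPR[nrow(pts)], 1); expect_equal(pts$TPR[nrow(pts)], 1)
  expect_true(all(diff(pts$TPR) >= 0))
  expect_true(all(diff(pts$FPR) >= 0))
})

test_that("AUC equals the Mann-Whitney oracle on random score sets", {
  for (seed in 1:60) {
    set <- withr::with_seed(seed, {
      n <- sample(4:50, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), sample(1:3, 1))   # rounding induces ties
      list(scores = scores, labels = labels)
    })
    expect_equal(roc_curve(set$scores, set$labels)$auc,
                 oracle_auc(set$scores, set$labels))
  }
})

test_that("AUC is ~0.5 for shuffled labels and complements under negation", {
  big <- withr::with_seed(11, {
    list(scores = runif(2000), labels = sample(rep(0:1, 1000)))
  })
  expect_lt(abs(roc_curve(big$scores, big$labels)$auc - 0.5), 0.05)

  tiefree <- withr::with_seed(12, {
    list(scores = sample(seq_len(40)) / 41, labels = rep(0:1, 20))
  })
  expect_equal(roc_curve(tiefree$scores, tiefree$labels)$auc +
                 roc_curve(-tiefree$scores, tiefree$labels)$auc, 1)
})

test_that("youden_index maximizes TPR - FPR with smallest-threshold ties", {
  curve <- roc_curve(eight_scores, eight_labels)
  yj <- youden_index(curve)
  expect_equal(yj$youden, 0.5)
  # brute force over the candidate thresholds, same tie rule
  cand <- curve$points$threshold
  ys <- vapply(cand, function(t) {
    cm <- confusion_at(eight_scores, eight_labels, t)
    cm$TPR - cm$FPR
  }, numeric(1))
  expect_equal(yj$threshold, min(cand[ys == max(ys)]))

  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(youden_index(perfect)$youden, 1)

  flat <- withr::with_seed(3, {
    list(scores = runif(500), labels = sample(rep(0:1, 250)))
  })
  expect_lt(youden_index(roc_curve(flat$scores, flat$labels))$youden, 0.15)
})

test_that("f1_at matches the worked example and its edge cases", {
  expect_equal(f1_at(eight_scores, eight_labels, 0.5),
               2 * (0.75 * 0.75) / 1.5)
  expect_equal(f1_at(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5), 1)
  expect_true(is.na(f1_at(eight_scores, eight_labels, 2)))   # TPR = 0, PPV NA
})

test_that("built-in confidence schemes carry the published boundaries", {
  ybp <- confidence_scheme("yeast", "biological_process")
  expect_equal(confidence_bin(0.75, ybp), "H")
  expect_equal(confidence_bin(0.0, ybp), "L")
  hcc <- confidence_scheme("human", "cellular_component")
  expect_equal(confidence_bin(0.5, hcc), "H")
  hbp <- confidence_scheme("human", "biological_process")
  expect_equal(confidence_bin(0.55, hbp), "M_H")
  expect_error(confidence_bin(1.2, ybp), class = "hrss_range_error")
  expect_error(confidence_scheme("mouse", "biological_process"),
               class = "hrss_usage_error")
})

test_that("confidence bins partition [0,1]: every score has exactly one label", {
  schemes <- list(confidence_scheme("yeast", "biological_process"),
                  confidence_scheme("yeast", "cellular_component"),
                  confidence_scheme("human", "biological_process"),
                  confidence_scheme("human", "cellular_component"))
  grid <- c(0, 1, seq(0.0, 1, by = 0.001),
            0.1 - 1e-9, 0.1, 0.2, 0.5, 0.6, 0.7, 1 - 1e-9)
  for (s in schemes) {
    labs <- confidence_bin(grid, s)
    expect_true(all(labs %in% s$labels))
    expect_length(labs, length(grid))
    # boundary semantics: cuts open on the right except the closed top bin
    expect_equal(confidence_bin(s$cuts[1], s), "M_L")
    expect_equal(confidence_bin(s$cuts[1] - 1e-9, s), "L")
    expect_equal(confidence_bin(s$cuts[3], s), "H")
  }
})

test_that("zscore_orthologs reproduces the enumerable 2-pair null", {
  pairs <- data.frame(a = c("h1", "h2"), b = c("m1", "m2"))
  scorer <- function(a, b) {
    as.numeric((a == "h1" && b == "m1") || (a == "h2" && b == "m2"))
  }
  # two bijections: identity (ASV 1) and the swap (ASV 0); null mean 0.5
  rep1 <- zscore_orthologs(pairs, scorer, reps = 400, seed = 5)
  expect_true(all(rep1$asv_random %in% c(0, 1)))
  expect_equal(rep1$asv_observed, 1)
  expect_lt(abs(rep1$null_mean - 0.5), 3 * 0.5 / sqrt(400))
  # bit-identical rerun
  rep2 <- zscore_orthologs(pairs, scorer, reps = 400, seed = 5)
  expect_identical(rep1$asv_random, rep2$asv_random)
  expect_identical(rep1$z, rep2$z)

  expect_error(zscore_orthologs(pairs, function(a, b) 0.7, reps = 50, seed = 1),
               class = "hrss_degenerate_null")
  expect_error(zscore_orthologs(pairs[1, ], scorer, reps = 10, seed = 1),
               class = "hrss_usage_error")
  expect_error(zscore_orthologs(pairs, scorer, reps = 0, seed = 1),
               class = "hrss_usage_error")
})

test_that("pairs with unannotated genes are dropped and counted", {
  w <- toy_world()
  scorer <- function(a, b) sim_ui(w$corpus, a, b, BP)
  pairs <- data.frame(a = c("g1", "g2", "ghost"), b = c("g5", "g8", "g1"))
  rep <- zscore_orthologs(pairs, scorer, reps = 50, seed = 2)
  expect_equal(rep$n_dropped, 1)
  expect_equal(rep$n_pairs, 3)
})

test_that("pearson matches closed-form examples and flags degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson(x, rep(2, 4))))
  expect_error(pearson(1:2, 1:2), class = "hrss_usage_error")
})
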