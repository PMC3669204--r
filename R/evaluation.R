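check_labeled <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_hrss("scores and labels differ in length", "hrss_usage_error")
  }
  if (any(!is.finite(scores))) {
    stop_hrss("scores must be finite", "hrss_usage_error")
  }
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop_hrss("need at least one positive and one negative label",
              "hrss_degenerate_input")
  }
  labels
}

#' Confusion counts and rates at a score threshold
#'
#' Predicts positive where `score >= threshold` (ties predicted positive) and
#' tabulates the confusion matrix against the labels.  `TPR = TP/(TP+FN)`,
#' `FPR = FP/(FP+TN)`, `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`; PPV and NPV
#' are `NA` when their denominator is zero.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Logical (or 0/1) vector; `TRUE` marks a true positive pair.
#' @param threshold Decision threshold.
#' @return Named list with TP, FP, TN, FN, TPR, FPR, PPV, NPV.
#' @export
confusion_at <- function(scores, labels, threshold) {
  labels <- check_labeled(scores, labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       TPR = tp / (tp + fn),
       FPR = fp / (fp + tn),
       PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps thresholds over the descending unique scores plus a sentinel above
#' the maximum (so the curve starts at (0, 0) and ends at (1, 1)) and
#' integrates TPR over FPR with the trapezoidal rule.
#'
#' @inheritParams confusion_at
#' @return A `roc_curve`: `points` (data.frame of threshold, TPR, FPR, PPV,
#'   NPV, TP, FP, TN, FN in threshold-descending order) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_labeled(scores, labels)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- lapply(thresholds, function(t) {
    cm <- confusion_at(scores, labels, t)
    data.frame(threshold = t, TPR = cm$TPR, FPR = cm$FPR,
               PPV = cm$PPV, NPV = cm$NPV,
               TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN)
  })
  pts <- do.call(rbind, pts)
  # trapezoidal rule over (FPR, TPR), FPR ascending as threshold descends
  x <- pts$FPR
  y <- pts$TPR
  auc <- sum((x[-1] - x[-length(x)]) * (y[-1] + y[-length(y)]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Youden-optimal threshold
#'
#' Maximizes the Youden index `Y = Sensitivity + Specificity - 1 =
#' TPR - FPR` over the curve's thresholds; ties break to the smallest
#' threshold.
#'
#' @param curve A `roc_curve`.
#' @return List with `threshold` and `youden`.
#' @export
youden_index <- function(curve) {
  pts <- curve$points
  y <- pts$TPR - pts$FPR
  best <- which(y == max(y))
  i <- best[which.min(pts$threshold[best])]
  list(threshold = pts$threshold[i], youden = y[i])
}

#' F1 measure at a threshold
#'
#' `F = 2 (PPV x TPR) / (PPV + TPR)`; `NA` when the denominator is zero or
#' PPV is undefined.
#'
#' @inheritParams confusion_at
#' @return F1 value or `NA`.
#' @export
f1_at <- function(scores, labels, threshold) {
  cm <- confusion_at(scores, labels, threshold)
  if (is.na(cm$PPV) || cm$PPV + cm$TPR == 0) return(NA_real_)
  2 * (cm$PPV * cm$TPR) / (cm$PPV + cm$TPR)
}

#' F1-optimal threshold
#'
#' Brute-force scan of the F1 measure over the curve's thresholds; ties break
#' to the smallest threshold, undefined F1 values are skipped.
#'
#' @param curve A `roc_curve`.
#' @return List with `threshold` and `f1`.
#' @export
f1_optimal <- function(curve) {
  pts <- curve$points
  f1 <- ifelse(is.na(pts$PPV) | (pts$PPV + pts$TPR) == 0, NA_real_,
               2 * (pts$PPV * pts$TPR) / (pts$PPV + pts$TPR))
  if (all(is.na(f1))) {
    stop_hrss("F1 undefined at every threshold", "hrss_degenerate_input")
  }
  best <- which(f1 == max(f1, na.rm = TRUE))
  i <- best[which.min(pts$threshold[best])]
  list(threshold = pts$threshold[i], f1 = f1[i])
}

# Interval boundaries for the four built-in confidence schemes: cut points
# between L / M_L / M_H / H for HRSS(MAX) scores, per species and namespace.
builtin_scheme_cuts <- list(
  yeast = list(biological_process = c(0.1, 0.2, 0.7),
               cellular_component = c(0.1, 0.2, 0.5)),
  human = list(biological_process = c(0.1, 0.2, 0.6),
               cellular_component = c(0.1, 0.2, 0.5))
)

#' Confidence scheme for similarity scores
#'
#' Four confidence groups for a score in \[0, 1\]: low (L), medium-low
#' (M_L), medium-high (M_H) and high (H).  Bins are left-closed,
#' right-open, except the top bin which is closed.  Built-in schemes carry
#' the published cut points for yeast and human in the biological_process
#' and cellular_component ontologies (all share the 0.1 and 0.2 lower cuts;
#' the high-confidence cut is 0.7 for yeast BP, 0.6 for human BP and 0.5
#' for CC in both species).
#'
#' @param species `"yeast"` or `"human"` for a built-in scheme, or `NULL`
#'   when giving `cuts` directly.
#' @param namespace `"biological_process"` or `"cellular_component"` for a
#'   built-in scheme.
#' @param cuts Three strictly increasing cut points inside (0, 1).
#' @return A `confidence_scheme` with `cuts` and `labels`.
#' @export
confidence_scheme <- function(species = NULL, namespace = NULL, cuts = NULL) {
  if (is.null(cuts)) {
    cuts <- builtin_scheme_cuts[[species]][[namespace]]
    if (is.null(cuts)) {
      stop_hrss(sprintf("no built-in confidence scheme for %s/%s",
                        species %||% "?", namespace %||% "?"), "hrss_usage_error")
    }
  }
  cuts <- as.numeric(cuts)
  if (length(cuts) != 3 || any(diff(cuts) <= 0) || cuts[1] <= 0 || cuts[3] >= 1) {
    stop_hrss("cuts must be 3 strictly increasing values inside (0, 1)",
              "hrss_usage_error")
  }
  structure(
    list(species = species, namespace = namespace, cuts = cuts,
         labels = c("L", "M_L", "M_H", "H")),
    class = "confidence_scheme"
  )
}

#' Format a confidence scheme's intervals
#'
#' @param scheme A `confidence_scheme`.
#' @return Named character vector of interval strings, e.g. `"[0, 0.1)"`.
#' @export
format_scheme <- function(scheme) {
  lo <- c(0, scheme$cuts)
  hi <- c(scheme$cuts, 1)
  close <- c(")", ")", ")", "]")
  fmt1 <- function(v) vapply(v, format, character(1))   # no common-width padding
  stats::setNames(sprintf("[%s, %s%s", fmt1(lo), fmt1(hi), close),
                  scheme$labels)
}

#' @export
print.confidence_scheme <- function(x, ...) {
  cat("<confidence_scheme>",
      if (!is.null(x$species)) sprintf("%s/%s", x$species, x$namespace) else "custom",
      "\n ", paste(sprintf("%s %s", x$labels, format_scheme(x)), collapse = "  "),
      "\n")
  invisible(x)
}

#' Assign a score to a confidence bin
#'
#' @param score Numeric score(s) in \[0, 1\].
#' @param scheme A `confidence_scheme`.
#' @return Character label(s) among L, M_L, M_H, H.
#' @export
confidence_bin <- function(score, scheme) {
  if (any(score < 0 | score > 1)) {
    stop_hrss("score outside [0, 1]", "hrss_range_error")
  }
  idx <- findInterval(score, c(0, scheme$cuts), rightmost.closed = FALSE)
  scheme$labels[idx]
}

#' Permutation Z-score for a set of gene pairs
#'
#' Measures how far the average similarity value (ASV) of an observed pair
#' set — typically one-to-one orthologs — departs from a permutation null.
#' Each replicate permutes the second-column genes by a uniform random
#' bijection (no fixed-point exclusion, so a few true pairs recur by
#' chance), recomputes the ASV, and the Z-score standardizes the observed
#' ASV against the replicate mean and standard deviation.
#'
#' Pairs whose score is undefined (e.g. an unannotated gene) are dropped from
#' the observed ASV and counted in the report; within replicates undefined
#' scores are likewise skipped.
#'
#' @param pairs Data frame or matrix whose first two columns are gene ids.
#' @param scorer Function of two gene ids returning a numeric similarity (or
#'   `NA` / an `hrss_unannotated_gene` error for unscorable pairs).
#' @param reps Number of randomization replicates (the reference analysis
#'   uses 1000).
#' @param seed Integer seed; the report is bit-reproducible given the seed.
#' @return A `zscore_report`: asv_observed, reps, null_mean, null_sd, z,
#'   seed, n_pairs, n_dropped and the replicate ASV vector `asv_random`.
#' @export
zscore_orthologs <- function(pairs, scorer, reps = 1000, seed = 1) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 2) {
    stop_hrss("need at least 2 pairs for a permutation null", "hrss_usage_error")
  }
  if (reps < 1) {
    stop_hrss("reps must be a positive integer", "hrss_usage_error")
  }
  a <- as.character(pairs[[1]])
  b <- as.character(pairs[[2]])
  score_pairing <- function(bs) {
    vals <- mapply(function(x, y) {
      tryCatch(scorer(x, y), hrss_unannotated_gene = function(e) NA_real_)
    }, a, bs)
    vals[is.finite(vals)]
  }
  obs <- score_pairing(b)
  if (!length(obs)) {
    stop_hrss("no observed pair could be scored", "hrss_degenerate_input")
  }
  asv_obs <- mean(obs)
  asv_random <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      mean(score_pairing(b[sample.int(length(b))]))
    }, numeric(1))
  })
  null_sd <- stats::sd(asv_random)
  if (!is.finite(null_sd) || null_sd == 0) {
    stop_hrss("randomization null has zero variance", "hrss_degenerate_null")
  }
  structure(
    list(asv_observed = asv_obs,
         reps = as.integer(reps),
         null_mean = mean(asv_random),
         null_sd = null_sd,
         z = (asv_obs - mean(asv_random)) / null_sd,
         seed = seed,
         n_pairs = nrow(pairs),
         n_dropped = nrow(pairs) - length(obs),
         asv_random = asv_random),
    class = "zscore_report"
  )
}

#' @export
print.zscore_report <- function(x, ...) {
  cat(sprintf(paste0("<zscore_report> ASV_observed = %.4f over %d pairs ",
                     "(%d dropped)\n  null: mean %.4f, sd %.4f over %d reps ",
                     "(seed %s) -> z = %.2f\n"),
              x$asv_observed, x$n_pairs, x$n_dropped, x$null_mean, x$null_sd,
              x$reps, format(x$seed), x$z))
  invisible(x)
}

#' Pearson correlation of two score vectors
#'
#' Product-moment correlation, used to relate semantic-similarity scores to
#' reference similarity vectors (sequence, domain or conservation based).
#' Returns `NA` when either vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_hrss("pearson needs two equal-length vectors of length >= 3",
              "hrss_usage_error")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
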