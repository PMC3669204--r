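new_term_score <- function(a, b, measure, value, components = NULL) {
  structure(
    list(term_a = a, term_b = b, measure = measure,
         value = as.numeric(value), components = components),
    class = "term_pair_score"
  )
}

#' @export
print.term_pair_score <- function(x, ...) {
  cat(sprintf("<term_pair_score> %s(%s, %s) = %.6g\n",
              x$measure, x$term_a, x$term_b, x$value))
  if (!is.null(x$components)) {
    vals <- vapply(x$components, function(v) {
      if (is.numeric(v)) format(v, digits = 6) else as.character(v)
    }, character(1))
    cat("  components:",
        paste(sprintf("%s=%s", names(vals), vals), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Relative specificity similarity (edge-based)
#'
#' Combines three structural components of a term pair: `alpha`, the depth of
#' the most recent common ancestor (its specificity); `beta`, the mean leaf
#' generality of the two terms (how far each sits above its closest leaf);
#' and `gamma`, the summed edge distance of the two terms from the MRCA
#' (their local divergence).  The score is
#' \deqn{RSS = \frac{maxDepth}{maxDepth + \gamma} \times
#'       \frac{\alpha}{\alpha + \beta}}
#' with `maxDepth` the maximum root-to-leaf distance of the namespace, so the
#' value lies in \[0, 1\].  A root-level MRCA (`alpha = 0`) gives 0.
#'
#' @param graph An `ontology_graph`.
#' @param a,b Term ids in the same namespace.
#' @return A `term_pair_score` with `components` alpha, beta, gamma.
#' @export
rss <- function(graph, a, b) {
  a <- resolve_term(graph, a)
  b <- resolve_term(graph, b)
  space <- check_same_namespace(graph, a, b)
  anc <- mrca(graph, a, b)
  alpha <- term_depth(graph, anc)
  beta <- (leaf_generality(graph, a) + leaf_generality(graph, b)) / 2
  gamma <- up_distance_to(graph, a, anc) + up_distance_to(graph, b, anc)
  max_depth <- graph$max_depth[[space]]
  value <- if (alpha == 0) 0 else {
    (max_depth / (max_depth + gamma)) * (alpha / (alpha + beta))
  }
  new_term_score(a, b, "rss", value,
                 list(alpha = alpha, beta = beta, gamma = gamma, mrca = anc))
}

up_distance_to <- function(graph, term, ancestor) {
  if (identical(term, ancestor)) return(0L)
  d <- up_distances(graph, term)
  if (is.na(d[ancestor])) {
    stop_hrss(sprintf("'%s' is not an ancestor of '%s'", ancestor, term),
              "hrss_domain_error")
  }
  as.integer(d[[ancestor]])
}

#' Hybrid relative specificity similarity
#'
#' The information-content analogue of [rss()]: `alpha_ic` is the IC of the
#' most informative common ancestor (MICA), `beta_ic` the mean IC generality
#' of the two terms (their IC gap to the most informative annotated leaf
#' below each), and `gamma` the summed IC distance of the two terms from the
#' MICA.  The score is
#' \deqn{HRSS = \frac{1}{1 + \gamma} \times
#'       \frac{\alpha_{IC}}{\alpha_{IC} + \beta_{IC}}}
#' in \[0, 1\].  When the MICA carries no information (`alpha_ic = 0`, i.e.
#' the terms share only the root) the similarity is 0 by convention.
#'
#' @param ic An `ic_table`.
#' @param graph An `ontology_graph`.
#' @param a,b Term ids in the same namespace, both with defined IC.
#' @return A `term_pair_score` with `components` alpha_ic, beta_ic, gamma.
#' @export
hrss <- function(ic, graph, a, b) {
  a <- resolve_term(graph, a)
  b <- resolve_term(graph, b)
  check_same_namespace(graph, a, b)
  get_ic(ic, a)
  get_ic(ic, b)
  anc <- mica(ic, graph, a, b)
  alpha_ic <- get_ic(ic, anc)
  beta_ic <- (mil_generality(ic, graph, a) + mil_generality(ic, graph, b)) / 2
  gamma <- dist_ic(ic, graph, anc, a) + dist_ic(ic, graph, anc, b)
  value <- if (alpha_ic == 0) 0 else {
    (1 / (1 + gamma)) * (alpha_ic / (alpha_ic + beta_ic))
  }
  new_term_score(a, b, "hrss", value,
                 list(alpha_ic = alpha_ic, beta_ic = beta_ic, gamma = gamma,
                      mica = anc))
}

#' Resnik term similarity
#'
#' The IC of the most informative common ancestor; unnormalized,
#' non-negative.
#'
#' @inheritParams hrss
#' @return A `term_pair_score`.
#' @export
resnik <- function(ic, graph, a, b) {
  a <- resolve_term(graph, a)
  b <- resolve_term(graph, b)
  check_same_namespace(graph, a, b)
  get_ic(ic, a)
  get_ic(ic, b)
  anc <- mica(ic, graph, a, b)
  new_term_score(a, b, "resnik", get_ic(ic, anc), list(mica = anc))
}

#' Lin term similarity
#'
#' `2 IC(MICA) / (IC(a) + IC(b))`, in \[0, 1\]; defined as 0 when both terms
#' have zero IC (the 0/0 case at the root).
#'
#' @inheritParams hrss
#' @return A `term_pair_score`.
#' @export
lin <- function(ic, graph, a, b) {
  a <- resolve_term(graph, a)
  b <- resolve_term(graph, b)
  check_same_namespace(graph, a, b)
  denom <- get_ic(ic, a) + get_ic(ic, b)
  anc <- mica(ic, graph, a, b)
  value <- if (denom == 0) 0 else 2 * get_ic(ic, anc) / denom
  new_term_score(a, b, "lin", value, list(mica = anc))
}

#' Jiang-Conrath term similarity
#'
#' Converts the Jiang-Conrath semantic distance
#' `d = IC(a) + IC(b) - 2 IC(MICA)` into a similarity `1 / (1 + d)` in
#' (0, 1].  The normalization is recorded in the score metadata so an
#' alternative transform can be layered on.
#'
#' @inheritParams hrss
#' @return A `term_pair_score`.
#' @export
jiang <- function(ic, graph, a, b) {
  a <- resolve_term(graph, a)
  b <- resolve_term(graph, b)
  check_same_namespace(graph, a, b)
  anc <- mica(ic, graph, a, b)
  d <- get_ic(ic, a) + get_ic(ic, b) - 2 * get_ic(ic, anc)
  new_term_score(a, b, "jiang", 1 / (1 + d),
                 list(distance = d, mica = anc, normalization = "1/(1+d)"))
}

term_measures <- c("hrss", "rss", "resnik", "lin", "jiang")

# Dispatch a term measure by name.
term_similarity <- function(measure, graph, ic, a, b) {
  switch(measure,
    rss = rss(graph, a, b),
    hrss = hrss(ic, graph, a, b),
    resnik = resnik(ic, graph, a, b),
    lin = lin(ic, graph, a, b),
    jiang = jiang(ic, graph, a, b),
    stop_hrss(sprintf("unknown term measure '%s'", measure), "hrss_usage_error")
  )
}

#' Score a batch of term pairs
#'
#' @param graph An `ontology_graph`.
#' @param ic An `ic_table` (ignored by the edge-based `rss`).
#' @param pairs Data frame or matrix whose first two columns are term ids.
#' @param measure One of `hrss`, `rss`, `resnik`, `lin`, `jiang`.
#' @return Data frame with columns term_a, term_b, measure, value, alpha,
#'   beta, gamma (components `NA` where a measure does not define them).
#' @export
score_term_pairs <- function(graph, ic, pairs, measure = "hrss") {
  if (!measure %in% term_measures) {
    stop_hrss(sprintf("unknown term measure '%s'", measure), "hrss_usage_error")
  }
  pairs <- as.data.frame(pairs)
  n <- nrow(pairs)
  out <- data.frame(term_a = character(n), term_b = character(n),
                    measure = character(n), value = numeric(n),
                    alpha = numeric(n), beta = numeric(n), gamma = numeric(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- term_similarity(measure, graph, ic, pairs[i, 1], pairs[i, 2])
    comp <- s$components %||% list()
    out$term_a[i] <- s$term_a
    out$term_b[i] <- s$term_b
    out$measure[i] <- s$measure
    out$value[i] <- s$value
    out$alpha[i] <- comp$alpha %||% comp$alpha_ic %||% NA_real_
    out$beta[i] <- comp$beta %||% comp$beta_ic %||% NA_real_
    out$gamma[i] <- comp$gamma %||% NA_real_
  }
  out
}
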