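#' MAX aggregation of a term-pair score matrix
#'
#' The maximum semantic similarity over all term pairs of two annotation
#' sets.
#'
#' @param matrix Numeric matrix of term-pair scores (rows: terms of gene P,
#'   columns: terms of gene Q).
#' @return The maximum entry.
#' @export
max_strategy <- function(matrix) {
  if (!length(matrix)) {
    stop_hrss("empty term-pair matrix (unannotated gene)", "hrss_unannotated_gene")
  }
  max(matrix)
}

#' Best-match-average aggregation of a term-pair score matrix
#'
#' For each term of either gene, take its best match on the other side (row
#' and column maxima), then average the pooled best matches: the sum of row
#' and column maxima divided by `nrow + ncol`.
#'
#' @inheritParams max_strategy
#' @return The pooled best-match mean; never exceeds [max_strategy()].
#' @export
bma_strategy <- function(matrix) {
  if (!length(matrix)) {
    stop_hrss("empty term-pair matrix (unannotated gene)", "hrss_unannotated_gene")
  }
  matrix <- as.matrix(matrix)
  mean(c(apply(matrix, 1, max), apply(matrix, 2, max)))
}

#' Term-set union-intersection gene similarity (simUI)
#'
#' Jaccard index of the two genes' propagated (ancestor-closed) annotation
#' sets in a namespace.
#'
#' @param corpus A propagated `annotation_corpus`.
#' @param gene_a,gene_b Gene ids.
#' @param namespace Ontology namespace.
#' @return Value in (0, 1] (the sets always share the namespace root).
#' @export
sim_ui <- function(corpus, gene_a, gene_b, namespace) {
  sa <- propagated_set(corpus, gene_a, namespace)
  sb <- propagated_set(corpus, gene_b, namespace)
  if (is.null(sa)) {
    stop_hrss(sprintf("gene '%s' has no annotations in %s", gene_a, namespace),
              "hrss_unannotated_gene")
  }
  if (is.null(sb)) {
    stop_hrss(sprintf("gene '%s' has no annotations in %s", gene_b, namespace),
              "hrss_unannotated_gene")
  }
  length(intersect(sa, sb)) / length(union(sa, sb))
}

#' IC-weighted term-set gene similarity (simGIC)
#'
#' The sum of term ICs over the intersection of the two genes' propagated
#' annotation sets, divided by the sum over their union; 0 when the union
#' carries no information.
#'
#' @param ic An `ic_table`.
#' @inheritParams sim_ui
#' @return Value in \[0, 1\].
#' @export
sim_gic <- function(ic, corpus, gene_a, gene_b, namespace) {
  sa <- propagated_set(corpus, gene_a, namespace)
  sb <- propagated_set(corpus, gene_b, namespace)
  if (is.null(sa)) {
    stop_hrss(sprintf("gene '%s' has no annotations in %s", gene_a, namespace),
              "hrss_unannotated_gene")
  }
  if (is.null(sb)) {
    stop_hrss(sprintf("gene '%s' has no annotations in %s", gene_b, namespace),
              "hrss_unannotated_gene")
  }
  both <- union(sa, sb)
  missing_ic <- both[!both %in% names(ic$ic)]
  if (length(missing_ic)) {
    stop_hrss(sprintf("term '%s' has no defined IC", missing_ic[1]),
              "hrss_missing_ic")
  }
  denom <- sum(ic$ic[both])
  if (denom == 0) return(0)
  sum(ic$ic[intersect(sa, sb)]) / denom
}

gene_measures <- c("hrss", "rss", "resnik", "lin", "jiang", "simui", "simgic")

# Direct annotations of a gene with root-only terms removed; used as the
# term set for pairwise strategies.
direct_terms <- function(corpus, graph, gene, namespace, propagated = FALSE) {
  pool <- if (propagated) corpus$propagated else corpus$direct
  terms <- pool[[namespace]][[gene]]
  if (is.null(terms)) {
    stop_hrss(sprintf("gene '%s' has no annotations in %s", gene, namespace),
              "hrss_unannotated_gene")
  }
  terms <- setdiff(terms, graph$roots[[namespace]])
  if (!length(terms)) {
    stop_hrss(sprintf("gene '%s' is annotated only to the %s root", gene, namespace),
              "hrss_unannotated_gene")
  }
  terms
}

#' Gene-product functional similarity
#'
#' Scores a pair of gene products in one ontology namespace.  Pairwise term
#' measures (`hrss`, `rss`, `resnik`, `lin`, `jiang`) build the term-pair
#' score matrix over the two genes' term sets and aggregate it with the MAX
#' or BMA strategy; groupwise measures (`simui`, `simgic`) compare the
#' propagated annotation sets directly and take no strategy.
#'
#' Pairwise term sets default to the direct (unpropagated) annotations with
#' root-only annotations removed; set `use_propagated = TRUE` to aggregate
#' over ancestor-closed sets instead.
#'
#' @param corpus A propagated `annotation_corpus`.
#' @param ic An `ic_table` (ignored by `rss` and `simui`).
#' @param graph An `ontology_graph`.
#' @param gene_a,gene_b Gene ids present in the corpus.
#' @param namespace Ontology namespace.
#' @param measure One of `hrss`, `rss`, `resnik`, `lin`, `jiang`, `simui`,
#'   `simgic`.
#' @param strategy `"max"` or `"bma"` for pairwise measures (default
#'   `"max"`); must be omitted (`NULL` or `"groupwise"`) for groupwise
#'   measures.
#' @param use_propagated Use ancestor-closed term sets for pairwise
#'   strategies?
#' @return A `gene_pair_score` with fields gene_a, gene_b, namespace,
#'   measure, strategy and value.
#' @export
gene_similarity <- function(corpus, ic, graph, gene_a, gene_b, namespace,
                            measure = "hrss", strategy = NULL,
                            use_propagated = FALSE) {
  measure <- tolower(measure)
  if (!measure %in% gene_measures) {
    stop_hrss(sprintf("unknown measure '%s'", measure), "hrss_usage_error")
  }
  groupwise <- measure %in% c("simui", "simgic")
  if (groupwise) {
    if (!is.null(strategy) && !identical(strategy, "groupwise")) {
      stop_hrss(sprintf("measure '%s' is groupwise and takes no strategy", measure),
                "hrss_usage_error")
    }
    value <- if (measure == "simui") {
      sim_ui(corpus, gene_a, gene_b, namespace)
    } else {
      sim_gic(ic, corpus, gene_a, gene_b, namespace)
    }
    strategy <- "groupwise"
  } else {
    if (is.null(strategy)) strategy <- "max"
    if (!strategy %in% c("max", "bma")) {
      stop_hrss(sprintf("pairwise measure '%s' needs strategy 'max' or 'bma'",
                        measure), "hrss_usage_error")
    }
    tp <- direct_terms(corpus, graph, gene_a, namespace, use_propagated)
    tq <- direct_terms(corpus, graph, gene_b, namespace, use_propagated)
    m <- matrix(NA_real_, length(tp), length(tq), dimnames = list(tp, tq))
    for (i in seq_along(tp)) {
      for (j in seq_along(tq)) {
        m[i, j] <- term_similarity(measure, graph, ic, tp[i], tq[j])$value
      }
    }
    value <- if (strategy == "max") max_strategy(m) else bma_strategy(m)
  }
  structure(
    list(gene_a = gene_a, gene_b = gene_b, namespace = namespace,
         measure = measure, strategy = strategy, value = value),
    class = "gene_pair_score"
  )
}

#' @export
print.gene_pair_score <- function(x, ...) {
  cat(sprintf("<gene_pair_score> %s(%s) %s ~ %s [%s] = %.6g\n",
              x$measure, x$strategy, x$gene_a, x$gene_b, x$namespace, x$value))
  invisible(x)
}

#' Score a batch of gene pairs
#'
#' Pairs with a gene missing from the corpus (or annotated only to the root)
#' are skipped with a warning giving the skip count, mirroring batch
#' behaviour on real annotation sets.
#'
#' @inheritParams gene_similarity
#' @param pairs Data frame or matrix whose first two columns are gene ids.
#' @return Data frame with columns gene_a, gene_b, namespace, measure,
#'   strategy, value.
#' @export
score_gene_pairs <- function(corpus, ic, graph, pairs, namespace,
                             measure = "hrss", strategy = NULL,
                             use_propagated = FALSE) {
  pairs <- as.data.frame(pairs)
  rows <- vector("list", nrow(pairs))
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    s <- tryCatch(
      gene_similarity(corpus, ic, graph, pairs[i, 1], pairs[i, 2], namespace,
                      measure, strategy, use_propagated),
      hrss_unannotated_gene = function(e) NULL
    )
    if (is.null(s)) {
      skipped <- skipped + 1L
    } else {
      rows[[i]] <- data.frame(gene_a = s$gene_a, gene_b = s$gene_b,
                              namespace = s$namespace, measure = s$measure,
                              strategy = s$strategy, value = s$value,
                              stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) {
    warn_hrss(sprintf("skipped %d gene pair(s) with unannotated genes", skipped),
              "hrss_skipped_pairs")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      namespace = character(0), measure = character(0),
                      strategy = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out
}
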