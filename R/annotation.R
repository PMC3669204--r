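#' Parse a GAF annotation file into an annotation corpus
#'
#' Reads a Gene Association File (GAF 2.x, 17-column TSV, `!` comment lines)
#' and builds the per-namespace gene-to-term assignments used for information
#' content.  Rows whose qualifier contains `NOT` are dropped, as are rows
#' whose evidence code is in `exclude_evidence`.  When a graph is supplied,
#' term ids are resolved through `alt_id` mappings; annotations to unknown or
#' obsolete terms are dropped and counted in a message.
#'
#' @param path Path to a GAF file (gzip transparent).
#' @param exclude_evidence Character vector of evidence codes to drop, e.g.
#'   `"IEA"` to exclude electronically inferred annotations.  Empty (default)
#'   keeps every evidence code.
#' @param namespace Optional filter: keep only one of `biological_process`,
#'   `cellular_component`, `molecular_function`.
#' @param graph Optional `ontology_graph` used to resolve and validate term
#'   ids at parse time.
#' @return An `annotation_corpus`: `direct` maps namespace -> gene -> direct
#'   term ids; `propagated` is filled by [propagate()]; `universe` gives the
#'   per-namespace count of annotated genes; `exclude_evidence` records the
#'   filter applied.
#' @export
parse_gaf <- function(path, exclude_evidence = character(0), namespace = NULL,
                      graph = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop_hrss(sprintf("cannot read GAF file '%s'", path), "hrss_io_error")
  }
  build_annotation_corpus(readLines(path, warn = FALSE), exclude_evidence,
                          namespace, graph)
}

aspect_to_namespace <- c(P = "biological_process",
                         C = "cellular_component",
                         F = "molecular_function")

build_annotation_corpus <- function(lines, exclude_evidence = character(0),
                                    namespace = NULL, graph = NULL) {
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  rows <- which(keep)
  direct <- list()
  n_dropped_terms <- 0L
  for (i in rows) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 15L || length(fields) > 17L) {
      stop_hrss(sprintf("GAF line %d has %d columns (expected 15-17)",
                        i, length(fields)), "hrss_parse_error")
    }
    gene <- fields[2]
    qualifier <- fields[4]
    term <- fields[5]
    evidence <- fields[7]
    aspect <- fields[9]

    if (grepl("NOT", qualifier, fixed = TRUE)) next
    if (evidence %in% exclude_evidence) next
    space <- aspect_to_namespace[[aspect]] %||% NA_character_
    if (is.na(space)) next
    if (!is.null(namespace) && space != namespace) next

    if (!is.null(graph)) {
      term <- resolve_term(graph, term, error = FALSE)
      if (is.na(term) || graph$terms[term, "is_obsolete"]) {
        n_dropped_terms <- n_dropped_terms + 1L
        next
      }
      space <- term_namespace(graph, term)  # trust the ontology over column 9
    }
    if (is.null(direct[[space]])) direct[[space]] <- list()
    direct[[space]][[gene]] <- union(direct[[space]][[gene]], term)
  }
  if (n_dropped_terms > 0L) {
    message(sprintf("parse_gaf: dropped %d annotation(s) to unknown or obsolete terms",
                    n_dropped_terms))
  }
  structure(
    list(direct = direct,
         propagated = NULL,
         universe = vapply(direct, length, integer(1)),
         exclude_evidence = exclude_evidence),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("<annotation_corpus>",
      if (length(x$exclude_evidence)) {
        sprintf("(excluding %s)", paste(x$exclude_evidence, collapse = ","))
      } else "(all evidence)", "\n")
  for (space in names(x$direct)) {
    cat(sprintf("  %s: %d genes%s\n", space, x$universe[[space]],
                if (is.null(x$propagated)) "" else ", propagated"))
  }
  invisible(x)
}

#' Propagate annotations by the true path rule
#'
#' Closes each gene's annotation set under ancestors: a gene annotated to a
#' term is implicitly annotated to every ancestor of that term, up to the
#' namespace root.
#'
#' @param corpus An `annotation_corpus`.
#' @param graph The `ontology_graph` the annotations refer to.
#' @return The corpus with its `propagated` component filled.
#' @export
propagate <- function(corpus, graph) {
  prop <- lapply(corpus$direct, function(genes) {
    lapply(genes, function(terms) {
      unique(unlist(lapply(terms, ancestors, graph = graph,
                           include_self = TRUE), use.names = FALSE))
    })
  })
  corpus$propagated <- prop
  corpus
}

genes_of <- function(corpus, namespace) names(corpus$direct[[namespace]] %||% list())

propagated_set <- function(corpus, gene, namespace) {
  if (is.null(corpus$propagated)) {
    stop_hrss("corpus is not propagated; call propagate() first", "hrss_usage_error")
  }
  corpus$propagated[[namespace]][[gene]]
}

#' Corpus-based information content
#'
#' For each term `c`, `count(c)` is the number of genes annotated (after true
#' path propagation) to `c` or any of its descendants, `p(c) = count(c) /
#' universe` with the universe the number of annotated genes in the term's
#' namespace, and `IC(c) = -log_base p(c)`.  The root of each namespace has
#' `p = 1` and `IC = 0`; terms with zero counts have no defined IC and are
#' absent from the table.
#'
#' @param corpus A propagated `annotation_corpus` (propagated automatically
#'   when needed).
#' @param graph The `ontology_graph`.
#' @param base Logarithm base; natural log by default.  Quotients of ICs are
#'   base-invariant but mixed-base operands are not, so the base is recorded
#'   in the table.
#' @return An `ic_table` with named vectors `count`, `p`, `ic` over term ids,
#'   plus `base` and the per-namespace `universe`.
#' @export
compute_ic <- function(corpus, graph, base = exp(1)) {
  if (is.null(corpus$propagated)) corpus <- propagate(corpus, graph)
  if (!length(corpus$universe) || all(corpus$universe == 0)) {
    stop_hrss("annotation corpus is empty (universe size 0)", "hrss_domain_error")
  }
  count <- integer(0)
  p <- numeric(0)
  for (space in names(corpus$propagated)) {
    universe <- corpus$universe[[space]]
    if (universe == 0L) next
    tally <- table(unlist(corpus$propagated[[space]], use.names = FALSE))
    cnt <- stats::setNames(as.integer(tally), names(tally))
    count <- c(count, cnt)
    p <- c(p, cnt / universe)
  }
  structure(
    list(count = count, p = p, ic = -log(p) / log(base),
         base = base, universe = corpus$universe),
    class = "ic_table"
  )
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("<ic_table> %d terms with defined IC, log base %.4g\n",
              length(x$ic), x$base))
  invisible(x)
}

has_ic <- function(ic, term) term %in% names(ic$ic)

get_ic <- function(ic, term) {
  if (!has_ic(ic, term)) {
    stop_hrss(sprintf("term '%s' has no defined IC (zero annotations in corpus)",
                      term), "hrss_missing_ic")
  }
  ic$ic[[term]]
}

#' Information-content distance from an ancestor to a descendant
#'
#' The difference `IC(v) - IC(u)` for `u` an ancestor of `v` (or `u == v`,
#' giving 0).  Non-negative by the monotonicity of IC along ancestor paths.
#'
#' @param ic An `ic_table`.
#' @param graph The `ontology_graph`.
#' @param u Ancestor term id.
#' @param v Descendant term id.
#' @return Non-negative real.
#' @export
dist_ic <- function(ic, graph, u, v) {
  u <- resolve_term(graph, u)
  v <- resolve_term(graph, v)
  if (!identical(u, v) && !(u %in% ancestors(graph, v))) {
    stop_hrss(sprintf("'%s' is not an ancestor of '%s'", u, v), "hrss_domain_error")
  }
  get_ic(ic, v) - get_ic(ic, u)
}

#' Most informative common ancestor
#'
#' Among the common ancestors of `a` and `b` (terms subsume themselves) with
#' defined IC, the one with maximal IC.  IC ties break to the
#' lexicographically smallest id for determinism.
#'
#' @inheritParams dist_ic
#' @param a,b Term ids in the same namespace.
#' @return A term id.
#' @export
mica <- function(ic, graph, a, b) {
  a <- resolve_term(graph, a)
  b <- resolve_term(graph, b)
  check_same_namespace(graph, a, b)
  common <- intersect(ancestors(graph, a, include_self = TRUE),
                      ancestors(graph, b, include_self = TRUE))
  common <- common[common %in% names(ic$ic)]
  if (!length(common)) {
    stop_hrss(sprintf("no common ancestor of '%s' and '%s' has defined IC", a, b),
              "hrss_missing_ic")
  }
  vals <- ic$ic[common]
  best <- common[vals == max(vals)]
  sort(best)[1]
}

#' Information-content generality of a term
#'
#' The IC distance from a term to its most informative annotated leaf (MIL):
#' the maximum of `IC(leaf) - IC(term)` over descendant leaves with defined
#' IC.  Zero for leaves, and zero for terms with no annotated descendant leaf
#' (they behave as maximally specific).  This is the per-term ingredient of
#' the beta component of HRSS.
#'
#' @inheritParams dist_ic
#' @param term A term id with defined IC.
#' @return Non-negative real.
#' @export
mil_generality <- function(ic, graph, term) {
  term <- resolve_term(graph, term)
  ic_term <- get_ic(ic, term)
  if (!length(graph$children[[term]])) return(0)
  desc <- descendants(graph, term)
  leaves <- desc[lengths(graph$children[desc]) == 0L]
  leaves <- leaves[leaves %in% names(ic$ic)]
  if (!length(leaves)) return(0)
  max(ic$ic[leaves]) - ic_term
}
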