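# Toy world shared across tests: the canonical 6-term DAG and 8-gene corpus
# with base-2 IC, so every hand-derived value is exact.
toy_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      obo <- tempfile(fileext = ".obo")
      gaf <- tempfile(fileext = ".gaf")
      toy_ontology_T(obo)
      toy_corpus_F(gaf)
      graph <- parse_obo(obo)
      corpus <- propagate(parse_gaf(gaf, graph = graph), graph)
      cache <<- list(
        graph = graph,
        corpus = corpus,
        ic = compute_ic(corpus, graph, base = 2)
      )
    }
    cache
  }
})

BP <- "biological_process"

# Exact base-2 ICs of the toy corpus (counts 8,4,6,2,1,3 over universe 8).
toy_ic_values <- c(R = 0, A = 1, B = log2(8 / 6), C = 2, D = 3, E = log2(8 / 3))

write_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

write_gaf <- function(lines) {
  path <- tempfile(fileext = ".gaf")
  writeLines(lines, path)
  path
}

# Minimal OBO text from a parent list (list id -> character vector).
obo_from_parents <- function(parents, namespace = "biological_process") {
  out <- c("format-version: 1.2", "")
  for (id in names(parents)) {
    out <- c(out, "[Term]", paste0("id: ", id), paste0("name: ", id),
             paste0("namespace: ", namespace),
             if (length(parents[[id]])) paste0("is_a: ", parents[[id]]),
             "")
  }
  out
}

# Random single-root DAG with n nodes: node i > 1 draws 1-2 parents among
# nodes 1..(i-1).  Returns a parsed ontology_graph.
random_dag <- function(n, seed) {
  parents <- withr::with_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n))
    p <- stats::setNames(vector("list", n), ids)
    p[[ids[1]]] <- character(0)
    for (i in seq_len(n)[-1]) {
      k <- sample.int(min(2L, i - 1L), 1)
      p[[ids[i]]] <- sample(ids[seq_len(i - 1L)], k)
    }
    p
  })
  parse_obo(write_obo(obo_from_parents(parents)))
}

# Random annotation corpus over a graph: each of n_genes genes gets 1-2
# direct annotations to random non-root terms.  Returns propagated corpus.
random_corpus <- function(graph, n_genes, seed) {
  terms <- setdiff(graph$terms$id, unname(graph$roots))
  rows <- withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    g <- character(0); t <- character(0)
    for (gene in genes) {
      picked <- sample(terms, sample.int(min(2L, length(terms)), 1))
      g <- c(g, rep(gene, length(picked)))
      t <- c(t, picked)
    }
    list(gene = g, term = t)
  })
  lines <- c("!gaf-version: 2.2",
             hrss:::gaf_lines(rows$gene, rows$term, "EXP", "P"))
  propagate(parse_gaf(write_gaf(lines), graph = graph), graph)
}
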