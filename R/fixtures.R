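# Deterministic miniature OBO/GAF generators.  They let every other module
# be exercised without downloading an ontology or annotation release, and
# their numbers are chosen so base-2 information content is exactly
# representable (counts over a universe of 8), making hand-derived oracle
# values exact.

#' Canonical six-term toy ontology
#'
#' A fixed DAG of six terms in one namespace: root R; A and B children of R;
#' C a child of both A and B (multiple inheritance); D a child of C; E a
#' child of B.  Leaves are D and E; the maximum root-to-leaf depth is 3.
#'
#' @param path Optional file to write the OBO text to.
#' @return The OBO 1.2 text as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
toy_ontology_T <- function(path = NULL) {
  stanza <- function(id, name, parents = character(0)) {
    c("[Term]",
      paste0("id: ", id),
      paste0("name: ", name),
      "namespace: biological_process",
      paste0("is_a: ", parents, " ! ", parents),
      "")
  }
  text <- c(
    "format-version: 1.2",
    "ontology: toy",
    "",
    stanza("R", "root"),
    stanza("A", "branch a", "R"),
    stanza("B", "branch b", "R"),
    stanza("C", "joint child", c("A", "B")),
    stanza("D", "deep leaf", "C"),
    stanza("E", "shallow leaf", "B")
  )
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Canonical eight-gene toy annotation corpus
#'
#' Eight genes annotated in the [toy_ontology_T()] DAG: g1 to D, g2 to C, g3
#' and g4 to A, g5-g7 to E, g8 to B.  After true-path propagation the
#' per-term gene counts are R:8, A:4, B:6, C:2, D:1, E:3, so base-2 IC
#' values are the exact logs of 1, 2, 4/3, 4, 8 and 8/3.  Genes g3 and g6
#' carry the IEA evidence code (the rest EXP), so excluding IEA removes
#' exactly two genes.
#'
#' @param path Optional file to write the GAF text to.
#' @return GAF 2.2 text as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
toy_corpus_F <- function(path = NULL) {
  ann <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8"),
    term = c("D", "C", "A", "A", "E", "E", "E", "B"),
    evidence = c("EXP", "EXP", "IEA", "EXP", "EXP", "IEA", "EXP", "EXP"),
    stringsAsFactors = FALSE
  )
  text <- c("!gaf-version: 2.2",
            gaf_lines(ann$gene, ann$term, ann$evidence, "P"))
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

# 17-column GAF rows.
gaf_lines <- function(gene, term, evidence, aspect) {
  vapply(seq_along(gene), function(i) {
    paste(c("TOY", gene[i], gene[i], "", term[i], "TOY:0000001", evidence[i],
            "", aspect, "", "", "protein", "taxon:4932", "20120401", "TOY",
            "", ""), collapse = "\t")
  }, character(1))
}

obo_text <- function(ids, names, parents, namespace = "biological_process") {
  out <- c("format-version: 1.2", "ontology: synthetic-benchmark", "")
  for (i in seq_along(ids)) {
    out <- c(out,
             "[Term]",
             paste0("id: ", ids[i]),
             paste0("name: ", names[i]),
             paste0("namespace: ", namespace),
             if (length(parents[[i]])) paste0("is_a: ", parents[[i]]),
             "")
  }
  out
}

#' Specification for a synthetic benchmark
#'
#' Parameters of [random_benchmark()].  Defaults describe a miniature but
#' non-trivial world: a 30-term, 4-level DAG, 40 genes concentrated on the
#' deepest terms, 50 positive and 50 negative pairs, and a 20% fraction of
#' IEA evidence mirroring the mixed-evidence character of real annotation
#' sets.
#'
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param n_terms Total number of terms including the root.
#' @param max_parents Maximum parents drawn for a term (multiple
#'   inheritance).
#' @param n_genes Number of annotated genes.
#' @param n_pairs Number of positive (and of negative) gene pairs.
#' @param annotations_per_gene Mean direct annotations per gene (each gene
#'   always gets its home leaf; extras are shallow noise terms).
#' @param iea_fraction Fraction of annotation rows given the IEA evidence
#'   code.
#' @param namespace Ontology namespace written into the files.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_terms = 30, max_parents = 2, n_genes = 40,
                         n_pairs = 50, annotations_per_gene = 1.3,
                         iea_fraction = 0.2,
                         namespace = "biological_process") {
  structure(list(seed = seed, n_terms = n_terms, max_parents = max_parents,
                 n_genes = n_genes, n_pairs = n_pairs,
                 annotations_per_gene = annotations_per_gene,
                 iea_fraction = iea_fraction, namespace = namespace),
            class = "fixture_spec")
}

#' Seeded synthetic benchmark: ontology, annotations and labeled pairs
#'
#' Builds a layered random DAG (root, three internal levels, a leaf level),
#' annotates genes to the deep leaves plus occasional shallow noise terms,
#' and derives gold-standard pair sets: positives are gene pairs sharing a
#' deep (high-IC) home term; negatives are sampled from pairs whose home
#' terms lie in different top-level branches, so they share only shallow
#' ancestors.  Positive and negative sets have equal size.  Output is byte
#' identical for identical specs.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, writes `ontology.obo`,
#'   `annotations.gaf`, `positives.tsv`, `negatives.tsv`.
#' @return List with `obo` and `gaf` (character vectors of lines) and
#'   `positives` / `negatives` (two-column data frames of gene ids).
#' @export
random_benchmark <- function(spec = fixture_spec(), dir = NULL) {
  with_seed(spec$seed, generate_benchmark(spec, dir))
}

generate_benchmark <- function(spec, dir) {
  n_terms <- spec$n_terms
  if (n_terms < 10) {
    stop_hrss("need at least 10 terms for a layered benchmark DAG",
              "hrss_generation_error")
  }
  # layer sizes: root + 4 levels; leaves get the remainder
  n_branch <- max(3L, round(n_terms * 0.15))
  n_mid <- max(3L, round(n_terms * 0.2))
  n_deep <- max(3L, round(n_terms * 0.2))
  n_leaf <- n_terms - 1L - n_branch - n_mid - n_deep
  if (n_leaf < 2L) {
    stop_hrss("term budget too small for the layered DAG", "hrss_generation_error")
  }
  ids <- sprintf("S:%04d", seq_len(n_terms))
  root <- ids[1]
  layers <- list(
    root = root,
    branch = ids[1L + seq_len(n_branch)],
    mid = ids[1L + n_branch + seq_len(n_mid)],
    deep = ids[1L + n_branch + n_mid + seq_len(n_deep)],
    leaf = ids[1L + n_branch + n_mid + n_deep + seq_len(n_leaf)]
  )
  # Each non-root term belongs to one top-level branch lineage; parents are
  # drawn within the lineage, so lineages meet only at the root.  That keeps
  # the negative-pair construction sound: genes homed in different lineages
  # share no ancestor below the root.  Lineage assignment is balanced
  # round-robin (then shuffled), so every branch is populated at any size.
  parents <- vector("list", n_terms)
  names(parents) <- ids
  parents[[root]] <- character(0)
  for (t in layers$branch) parents[[t]] <- root
  branch_of <- stats::setNames(layers$branch, layers$branch)
  assign_layer <- function(members, parent_pool_of) {
    lineage <- sample(rep_len(layers$branch, length(members)))
    for (i in seq_along(members)) {
      pool <- parent_pool_of(lineage[i])
      k <- sample.int(min(spec$max_parents, length(pool)), 1)
      parents[[members[i]]] <<- sample(pool, k)
      branch_of[members[i]] <<- lineage[i]
    }
  }
  in_branch <- function(members, b) members[branch_of[members] == b]
  assign_layer(layers$mid, function(b) b)
  assign_layer(layers$deep, function(b) {
    pool <- in_branch(layers$mid, b)
    if (length(pool)) pool else b
  })
  assign_layer(layers$leaf, function(b) {
    pool <- in_branch(layers$deep, b)
    if (length(pool)) pool else b
  })
  obo <- obo_text(ids, paste("synthetic term", seq_len(n_terms)), parents,
                  spec$namespace)
  leaf_branch <- branch_of[layers$leaf]

  genes <- sprintf("gene%03d", seq_len(spec$n_genes))
  # concentrate genes on a bounded set of "cluster" leaves, assigned nearly
  # evenly, so enough same-home pairs exist for any reasonable spec; pick the
  # cluster leaves round-robin across top-level branches so cross-branch
  # (negative) pairs always exist too
  n_clusters <- min(length(layers$leaf), max(2L, ceiling(spec$n_genes / 4)))
  by_branch <- lapply(split(layers$leaf, leaf_branch[layers$leaf]),
                      function(l) if (length(l) > 1) sample(l) else l)
  by_branch <- by_branch[sample(length(by_branch))]
  interleaved <- unlist(by_branch, use.names = FALSE)[
    order(unlist(lapply(by_branch, seq_along), use.names = FALSE))]
  cluster_leaves <- interleaved[seq_len(n_clusters)]
  home <- sample(rep_len(cluster_leaves, spec$n_genes))
  extra_n <- stats::rpois(spec$n_genes, max(0, spec$annotations_per_gene - 1))
  rows_gene <- character(0)
  rows_term <- character(0)
  for (i in seq_along(genes)) {
    terms <- c(home[i],
               if (extra_n[i] > 0) sample(layers$branch, min(extra_n[i], 2)))
    rows_gene <- c(rows_gene, rep(genes[i], length(terms)))
    rows_term <- c(rows_term, terms)
  }
  evidence <- ifelse(stats::runif(length(rows_gene)) < spec$iea_fraction,
                     "IEA", "EXP")
  aspect <- switch(spec$namespace, biological_process = "P",
                   cellular_component = "C", molecular_function = "F")
  gaf <- c("!gaf-version: 2.2", gaf_lines(rows_gene, rows_term, evidence, aspect))

  # positives: pairs sharing a home leaf
  pos_pool <- do.call(rbind, lapply(split(genes, home), function(g) {
    if (length(g) < 2) return(NULL)
    t(utils::combn(sort(g), 2))
  }))
  if (is.null(pos_pool) || nrow(pos_pool) < spec$n_pairs) {
    stop_hrss("cannot form enough positive pairs; increase n_genes or lower n_pairs",
              "hrss_generation_error")
  }
  pos_idx <- sample.int(nrow(pos_pool), spec$n_pairs)
  positives <- data.frame(gene_a = pos_pool[pos_idx, 1],
                          gene_b = pos_pool[pos_idx, 2],
                          stringsAsFactors = FALSE)

  # negatives: home leaves in different top-level branches, excluding the
  # positive pool (the known-interaction set)
  gene_branch <- stats::setNames(leaf_branch[home], genes)
  known <- paste(pos_pool[, 1], pos_pool[, 2])
  all_pairs <- t(utils::combn(sort(genes), 2))
  cross <- gene_branch[all_pairs[, 1]] != gene_branch[all_pairs[, 2]]
  neg_pool <- all_pairs[cross & !(paste(all_pairs[, 1], all_pairs[, 2]) %in% known),
                        , drop = FALSE]
  if (nrow(neg_pool) < spec$n_pairs) {
    stop_hrss("cannot form enough negative pairs; increase n_genes or branches",
              "hrss_generation_error")
  }
  neg_idx <- sample.int(nrow(neg_pool), spec$n_pairs)
  negatives <- data.frame(gene_a = neg_pool[neg_idx, 1],
                          gene_b = neg_pool[neg_idx, 2],
                          stringsAsFactors = FALSE)

  out <- list(obo = obo, gaf = gaf, positives = positives, negatives = negatives)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(obo, file.path(dir, "ontology.obo"))
    writeLines(gaf, file.path(dir, "annotations.gaf"))
    utils::write.table(positives, file.path(dir, "positives.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(negatives, file.path(dir, "negatives.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
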