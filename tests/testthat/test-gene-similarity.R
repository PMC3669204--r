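# Extends the toy world with two extra genes used in the aggregation
# examples: gp annotated {D, C}, gq annotated {E}.  IC still comes from the
# canonical 8-gene corpus so hand values stay exact.
pq_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- toy_world()
      lines <- c("!gaf-version: 2.2",
                 hrss:::gaf_lines(c("gp", "gp", "gq"), c("D", "C", "E"),
                                  "EXP", "P"))
      corp <- propagate(parse_gaf(write_gaf(lines), graph = w$graph), w$graph)
      cache <<- list(graph = w$graph, ic = w$ic, corpus = corp)
    }
    cache
  }
})

test_that("max and bma strategies aggregate the toy 2x1 matrix correctly", {
  w <- pq_world()
  v_de <- hrss(w$ic, w$graph, "D", "E")$value   # 0.218...
  v_ce <- hrss(w$ic, w$graph, "C", "E")$value
  m <- matrix(c(v_de, v_ce), nrow = 2,
              dimnames = list(c("D", "C"), "E"))
  expect_equal(max_strategy(m), max(v_de, v_ce))
  expect_equal(max_strategy(m), v_de)           # D-E dominates on the fixture
  # row maxima v_de, v_ce; column maximum max(v_de, v_ce); pooled over 3
  expect_equal(bma_strategy(m), (v_de + v_ce + max(v_de, v_ce)) / 3)
  expect_error(max_strategy(matrix(numeric(0), 0, 0)),
               class = "hrss_unannotated_gene")
})

test_that("bma never exceeds max and both collapse on singletons", {
  expect_equal(bma_strategy(matrix(0.4)), max_strategy(matrix(0.4)))
  expect_equal(max_strategy(matrix(0, 3, 3)), 0)
  for (seed in 1:25) {
    m <- withr::with_seed(seed, matrix(runif(12), 3, 4))
    expect_lte(bma_strategy(m), max_strategy(m))
    expect_gte(bma_strategy(m), 0)
  }
})

test_that("sim_ui and sim_gic match the set-algebra toy values", {
  w <- toy_world()
  # propagated: g1 -> {D,C,A,B,R}; g5 -> {E,B,R}; intersection {B,R}
  expect_equal(sim_ui(w$corpus, "g1", "g5", BP), 2 / 6)
  expect_equal(sim_ui(w$corpus, "g1", "g1", BP), 1)
  expect_equal(sim_gic(w$ic, w$corpus, "g1", "g5", BP),
               log2(8 / 6) / sum(toy_ic_values))
  expect_equal(sim_gic(w$ic, w$corpus, "g1", "g1", BP), 1)
  expect_error(sim_ui(w$corpus, "ghost", "g1", BP),
               class = "hrss_unannotated_gene")
})

test_that("genes annotated only to the root score 1 under simUI, 0 under simGIC", {
  w <- toy_world()
  lines <- c("!gaf-version: 2.2",
             hrss:::gaf_lines(c("r1", "r2"), c("R", "R"), "EXP", "P"))
  corp <- propagate(parse_gaf(write_gaf(lines), graph = w$graph), w$graph)
  ic <- compute_ic(corp, w$graph, base = 2)
  expect_equal(sim_ui(corp, "r1", "r2", BP), 1)
  expect_equal(sim_gic(ic, corp, "r1", "r2", BP), 0)
  # root-only genes are unusable for pairwise strategies
  expect_error(gene_similarity(corp, ic, w$graph, "r1", "r2", BP, "hrss", "max"),
               class = "hrss_unannotated_gene")
})

test_that("gene_similarity dispatches measures and validates combinations", {
  w <- pq_world()
  s <- gene_similarity(w$corpus, w$ic, w$graph, "gp", "gq", BP, "hrss", "max")
  expect_equal(s$value, hrss(w$ic, w$graph, "D", "E")$value)
  s2 <- gene_similarity(w$corpus, w$ic, w$graph, "gp", "gp", BP, "lin", "bma")
  expect_equal(s2$value, 1)                     # perfect self-match
  s3 <- gene_similarity(w$corpus, w$ic, w$graph, "gp", "gq", BP, "simui")
  expect_equal(s3$value, 2 / 6)
  expect_equal(s3$strategy, "groupwise")
  expect_error(
    gene_similarity(w$corpus, w$ic, w$graph, "gp", "gq", BP, "simui", "bma"),
    class = "hrss_usage_error"
  )
  expect_error(
    gene_similarity(w$corpus, w$ic, w$graph, "gp", "gq", BP, "hrss", "median"),
    class = "hrss_usage_error"
  )
  expect_error(
    gene_similarity(w$corpus, w$ic, w$graph, "gp", "gq", BP, "wang"),
    class = "hrss_usage_error"
  )
})

test_that("gene similarity is symmetric and bounded across measures", {
  bm <- random_benchmark(fixture_spec(seed = 7, n_genes = 20, n_pairs = 10))
  g <- parse_obo(write_obo(bm$obo))
  corp <- propagate(parse_gaf(write_gaf(bm$gaf), graph = g), g)
  ic <- compute_ic(corp, g)
  pairs <- rbind(bm$positives, bm$negatives)[1:10, ]
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    for (m in c("hrss", "rss", "lin", "jiang")) {
      for (strat in c("max", "bma")) {
        v1 <- gene_similarity(corp, ic, g, a, b, BP, m, strat)$value
        v2 <- gene_similarity(corp, ic, g, b, a, BP, m, strat)$value
        expect_equal(v1, v2, info = paste(m, strat))
        expect_gte(v1, 0); expect_lte(v1, 1)
      }
      vmax <- gene_similarity(corp, ic, g, a, b, BP, m, "max")$value
      vbma <- gene_similarity(corp, ic, g, a, b, BP, m, "bma")$value
      expect_lte(vbma, vmax + 1e-12)
    }
    expect_equal(gene_similarity(corp, ic, g, a, b, BP, "simui")$value,
                 gene_similarity(corp, ic, g, b, a, BP, "simui")$value)
    expect_equal(gene_similarity(corp, ic, g, a, b, BP, "simgic")$value,
                 gene_similarity(corp, ic, g, b, a, BP, "simgic")$value)
  }
})

test_that("groupwise measures agree with brute-force Jaccard / IC-sum oracles", {
  for (seed in 1:20) {
    g <- random_dag(sample(8:20, 1), seed = seed)
    corp <- random_corpus(g, n_genes = 6, seed = seed + 900)
    ic <- compute_ic(corp, g)
    genes <- hrss:::genes_of(corp, BP)
    picks <- withr::with_seed(seed, {
      cbind(sample(genes, 3, replace = TRUE), sample(genes, 3, replace = TRUE))
    })
    for (i in seq_len(nrow(picks))) {
      sa <- unique(unlist(lapply(corp$direct[[BP]][[picks[i, 1]]],
                                 oracle_ancestors, graph = g,
                                 include_self = TRUE)))
      sb <- unique(unlist(lapply(corp$direct[[BP]][[picks[i, 2]]],
                                 oracle_ancestors, graph = g,
                                 include_self = TRUE)))
      expect_equal(sim_ui(corp, picks[i, 1], picks[i, 2], BP),
                   length(intersect(sa, sb)) / length(union(sa, sb)))
      denom <- sum(ic$ic[union(sa, sb)])
      expected <- if (denom == 0) 0 else sum(ic$ic[intersect(sa, sb)]) / denom
      expect_equal(sim_gic(ic, corp, picks[i, 1], picks[i, 2], BP), expected)
    }
  }
})

test_that("self-similarity is 1 for the normalized measures on the toy genes", {
  w <- pq_world()
  for (m in c("lin", "jiang", "simui", "simgic")) {
    strat <- if (m %in% c("simui", "simgic")) NULL else "bma"
    expect_equal(
      gene_similarity(w$corpus, w$ic, w$graph, "gq", "gq", BP, m, strat)$value,
      1, info = m
    )
  }
  # hrss self-similarity is 1 when annotations are informative leaves
  expect_equal(
    gene_similarity(w$corpus, w$ic, w$graph, "gq", "gq", BP, "hrss", "max")$value,
    1
  )
})

test_that("score_gene_pairs skips unannotated genes with a warning", {
  w <- pq_world()
  pairs <- data.frame(a = c("gp", "ghost"), b = c("gq", "gp"))
  expect_warning(
    out <- score_gene_pairs(w$corpus, w$ic, w$graph, pairs, BP, "hrss", "max"),
    class = "hrss_skipped_pairs"
  )
  expect_equal(nrow(out), 1)
  expect_equal(out$gene_a, "gp")
})
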