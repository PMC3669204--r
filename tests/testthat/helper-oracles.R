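# Brute-force oracles, written independently of the implementation paths
# they check: naive recursion and exhaustive enumeration only.

# Ancestor set by naive recursive parent enumeration.
oracle_ancestors <- function(graph, term, include_self = FALSE) {
  rec <- function(t) {
    out <- character(0)
    for (p in graph$parents[[t]]) out <- union(out, c(p, rec(p)))
    out
  }
  anc <- rec(term)
  if (include_self) anc <- union(term, anc)
  anc
}

# Shortest upward edge distance from u to ancestor c by naive recursion;
# Inf when c is not an ancestor of u.
oracle_up_dist <- function(graph, u, c) {
  if (identical(u, c)) return(0)
  ps <- graph$parents[[u]]
  if (!length(ps)) return(Inf)
  1 + min(vapply(ps, function(p) oracle_up_dist(graph, p, c), numeric(1)))
}

# Distance between u and v: min over every term of the summed upward
# distances.
oracle_dist <- function(graph, u, v) {
  cands <- graph$terms$id
  best <- Inf
  for (c in cands) {
    d <- oracle_up_dist(graph, u, c) + oracle_up_dist(graph, v, c)
    if (d < best) best <- d
  }
  best
}

oracle_depth <- function(graph, t) {
  root <- graph$roots[[graph$terms[t, "namespace"]]]
  oracle_up_dist(graph, t, root)
}

# MRCA: enumerate common ancestors, take max depth, break ties to the
# lexicographically smallest id.
oracle_mrca <- function(graph, a, b) {
  common <- intersect(oracle_ancestors(graph, a, TRUE),
                      oracle_ancestors(graph, b, TRUE))
  depth <- vapply(common, function(c) oracle_depth(graph, c), numeric(1))
  sort(common[depth == max(depth)])[1]
}

# MICA: common ancestor with defined IC maximizing IC; ties to smallest id.
oracle_mica <- function(ic, graph, a, b) {
  common <- intersect(oracle_ancestors(graph, a, TRUE),
                      oracle_ancestors(graph, b, TRUE))
  common <- common[common %in% names(ic$ic)]
  vals <- ic$ic[common]
  sort(common[vals == max(vals)])[1]
}

# AUC as the Mann-Whitney statistic: fraction of positive-negative score
# comparisons won, ties counting one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# Straight-line transcriptions of the five term measures, built only on the
# oracle primitives above (no calls into the implementation under test).
# `icv` is a named IC vector; `max_depth` the namespace maxDepth.
oracle_term_measures <- function(graph, icv, max_depth, a, b) {
  common_e <- intersect(oracle_ancestors(graph, a, TRUE),
                        oracle_ancestors(graph, b, TRUE))
  depth <- vapply(common_e, function(c) oracle_depth(graph, c), numeric(1))
  anc_e <- sort(common_e[depth == max(depth)])[1]

  leaf_gen <- function(t) {
    leaves <- graph$terms$id[lengths(graph$children[graph$terms$id]) == 0]
    below <- leaves[vapply(leaves, function(l) {
      is.finite(oracle_up_dist(graph, l, t))
    }, logical(1))]
    min(vapply(below, function(l) oracle_up_dist(graph, l, t), numeric(1)))
  }
  alpha <- oracle_depth(graph, anc_e)
  beta <- (leaf_gen(a) + leaf_gen(b)) / 2
  gamma_e <- oracle_up_dist(graph, a, anc_e) + oracle_up_dist(graph, b, anc_e)
  rss_val <- if (alpha == 0) 0 else {
    (max_depth / (max_depth + gamma_e)) * (alpha / (alpha + beta))
  }

  common_ic <- common_e[common_e %in% names(icv)]
  vals <- icv[common_ic]
  anc_ic <- sort(common_ic[vals == max(vals)])[1]
  alpha_ic <- icv[[anc_ic]]
  mil_gen <- function(t) {
    leaves <- graph$terms$id[lengths(graph$children[graph$terms$id]) == 0]
    below <- leaves[vapply(leaves, function(l) {
      is.finite(oracle_up_dist(graph, l, t))
    }, logical(1))]
    below <- setdiff(below[below %in% names(icv)], t)
    if (!length(below)) return(0)
    max(icv[below]) - icv[[t]]
  }
  beta_ic <- (mil_gen(a) + mil_gen(b)) / 2
  gamma_ic <- (icv[[a]] - alpha_ic) + (icv[[b]] - alpha_ic)
  hrss_val <- if (alpha_ic == 0) 0 else {
    (1 / (1 + gamma_ic)) * (alpha_ic / (alpha_ic + beta_ic))
  }

  denom <- icv[[a]] + icv[[b]]
  lin_val <- if (denom == 0) 0 else 2 * alpha_ic / denom
  jiang_val <- 1 / (1 + (icv[[a]] + icv[[b]] - 2 * alpha_ic))

  list(rss = rss_val, hrss = hrss_val, resnik = alpha_ic, lin = lin_val,
       jiang = jiang_val)
}
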