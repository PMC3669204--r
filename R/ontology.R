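#' Parse an OBO flat file into an ontology graph
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas and builds a directed acyclic graph of
#' terms linked by subsumption relations.  Child terms point to more general
#' parent terms; each namespace has a single root (a non-obsolete term with no
#' parents) from which depths are measured in edge counts (root depth 0).
#'
#' Obsolete terms are retained in the term table but carry no edges and are
#' excluded from every traversal.  `alt_id` entries are recorded so that
#' secondary accessions resolve to their canonical term.
#'
#' @param path Path to an OBO flat file.
#' @param relations Character vector of relations to traverse as parent links.
#'   Supported: `"is_a"` and `"part_of"`.  The default follows only `is_a`,
#'   the conservative true-path core; `part_of` can be added when the analysis
#'   calls for it.
#' @return An object of class `ontology_graph` with components `terms` (a
#'   data.frame of id, name, namespace, is_obsolete), `parents` and `children`
#'   (adjacency lists), `alt_ids` (named vector mapping secondary to canonical
#'   ids), `roots`, `depth` (edges from the namespace root) and `max_depth`
#'   (per namespace).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(toy_ontology_T(), obo)
#' g <- parse_obo(obo)
#' g$max_depth
#' @export
parse_obo <- function(path, relations = "is_a") {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop_hrss(sprintf("cannot read OBO file '%s'", path), "hrss_io_error")
  }
  bad <- setdiff(relations, c("is_a", "part_of"))
  if (length(bad)) {
    stop_hrss(sprintf("unsupported relation(s): %s", paste(bad, collapse = ", ")),
              "hrss_usage_error")
  }
  lines <- readLines(path, warn = FALSE)
  build_ontology_graph(lines, relations)
}

# Shared by parse_obo() and the fixture generators (which hold OBO text in
# memory).  `lines` is the file split into lines.
build_ontology_graph <- function(lines, relations = "is_a") {
  lines <- sub("\\s*!.*$", "", lines)           # strip trailing comments
  stanza_starts <- which(lines == "[Term]")
  boundaries <- c(grep("^\\[", lines), length(lines) + 1L)

  ids <- character(0)
  nm <- character(0)
  ns <- character(0)
  obsolete <- logical(0)
  parent_of <- list()     # id -> character vector of parent ids
  alt_map <- character(0) # alt id -> canonical id

  for (s in stanza_starts) {
    end <- min(boundaries[boundaries > s]) - 1L
    block <- lines[s:end]
    kv <- regmatches(block, regexec("^([a-z_]+):\\s*(.*)$", block))
    keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else "", "")
    vals <- vapply(kv, function(m) if (length(m) == 3) trimws(m[3]) else "", "")

    id <- vals[keys == "id"][1]
    if (is.na(id) || !nzchar(id)) next
    is_obs <- any(keys == "is_obsolete" & vals == "true")

    ids <- c(ids, id)
    nm <- c(nm, if (any(keys == "name")) vals[keys == "name"][1] else id)
    ns <- c(ns, if (any(keys == "namespace")) vals[keys == "namespace"][1] else NA_character_)
    obsolete <- c(obsolete, is_obs)

    for (alt in vals[keys == "alt_id"]) alt_map[alt] <- id

    if (!is_obs) {
      pars <- character(0)
      if ("is_a" %in% relations) pars <- c(pars, vals[keys == "is_a"])
      if ("part_of" %in% relations) {
        rel <- vals[keys == "relationship"]
        po <- regmatches(rel, regexec("^part_of\\s+(\\S+)", rel))
        pars <- c(pars, vapply(po[lengths(po) == 2], `[`, "", 2))
      }
      parent_of[[id]] <- unique(pars)
    } else {
      parent_of[[id]] <- character(0)
    }
  }

  if (anyDuplicated(ids)) {
    stop_hrss(sprintf("duplicate term id '%s'", ids[duplicated(ids)][1]),
              "hrss_validation_error")
  }
  terms <- data.frame(id = ids, name = nm, namespace = ns,
                      is_obsolete = obsolete, stringsAsFactors = FALSE)
  rownames(terms) <- ids

  # default namespace: single-namespace files may omit the key
  if (all(is.na(terms$namespace))) terms$namespace <- "biological_process"

  # drop edges to unknown parents (e.g. filtered relations pointing outside)
  parent_of <- lapply(parent_of, function(p) p[p %in% ids])

  children_of <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) children_of[[id]] <- character(0)
  for (id in ids) {
    for (p in parent_of[[id]]) children_of[[p]] <- c(children_of[[p]], id)
  }

  detect_cycle(parent_of)

  g <- structure(
    list(terms = terms, parents = parent_of, children = children_of,
         alt_ids = alt_map, relations = relations),
    class = "ontology_graph"
  )
  g$roots <- find_roots(g)
  g$depth <- compute_depths(g)
  active <- ids[!obsolete]
  g$max_depth <- vapply(split(g$depth[active], terms[active, "namespace"]),
                        max, numeric(1))
  g
}

detect_cycle <- function(parent_of) {
  remaining <- lengths(parent_of)          # unresolved parent counts
  queue <- names(remaining)[remaining == 0L]
  # reverse adjacency: parent -> children
  kids <- stats::setNames(vector("list", length(parent_of)), names(parent_of))
  for (id in names(parent_of)) {
    for (p in parent_of[[id]]) kids[[p]] <- c(kids[[p]], id)
  }
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    seen <- seen + 1L
    for (ch in kids[[v]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(parent_of)) {
    member <- names(remaining)[remaining > 0L][1]
    stop_hrss(sprintf("ontology contains a cycle involving term '%s'", member),
              "hrss_validation_error")
  }
  invisible(NULL)
}

find_roots <- function(graph) {
  t <- graph$terms
  active <- t$id[!t$is_obsolete]
  roots <- character(0)
  for (space in unique(t[active, "namespace"])) {
    in_ns <- active[t[active, "namespace"] == space]
    r <- in_ns[lengths(graph$parents[in_ns]) == 0L]
    if (length(r) != 1L) {
      stop_hrss(sprintf("namespace '%s' has %d roots (expected exactly 1)",
                        space, length(r)), "hrss_validation_error")
    }
    roots[space] <- r
  }
  roots
}

# BFS down from each namespace root: depth = shortest root->term edge count.
compute_depths <- function(graph) {
  t <- graph$terms
  depth <- stats::setNames(rep(NA_real_, nrow(t)), t$id)
  for (space in names(graph$roots)) {
    root <- graph$roots[[space]]
    depth[root] <- 0
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (ch in graph$children[[v]]) {
        if (is.na(depth[ch])) {
          depth[ch] <- depth[v] + 1
          queue <- c(queue, ch)
        }
      }
    }
  }
  active <- t$id[!t$is_obsolete]
  orphan <- active[is.na(depth[active])]
  if (length(orphan)) {
    stop_hrss(sprintf("term '%s' cannot reach its namespace root", orphan[1]),
              "hrss_validation_error")
  }
  depth
}

#' @export
print.ontology_graph <- function(x, ...) {
  t <- x$terms
  cat(sprintf("<ontology_graph> %d terms (%d obsolete), relations: %s\n",
              nrow(t), sum(t$is_obsolete), paste(x$relations, collapse = "+")))
  for (space in names(x$roots)) {
    cat(sprintf("  %s: root %s, maxDepth %d\n", space, x$roots[[space]],
                as.integer(x$max_depth[[space]])))
  }
  invisible(x)
}

# Resolve an accession to its canonical id, following alt_id mappings.
resolve_term <- function(graph, id, error = TRUE) {
  if (id %in% graph$terms$id) return(id)
  if (id %in% names(graph$alt_ids)) return(graph$alt_ids[[id]])
  if (error) stop_hrss(sprintf("unknown term id '%s'", id), "hrss_lookup_error")
  NA_character_
}

term_namespace <- function(graph, id) graph$terms[id, "namespace"]

check_same_namespace <- function(graph, a, b) {
  na <- term_namespace(graph, a)
  nb <- term_namespace(graph, b)
  if (!identical(na, nb)) {
    stop_hrss(sprintf("terms '%s' (%s) and '%s' (%s) are in different namespaces",
                      a, na, b, nb), "hrss_domain_error")
  }
  invisible(na)
}

#' Ancestors of a term
#'
#' Transitive closure over the parent links (the true-path rule: annotation to
#' a term implies annotation to all of its ancestors).
#'
#' @param graph An `ontology_graph`.
#' @param term A term id (alt ids are resolved).
#' @param include_self Include the term itself in the returned set?
#' @return Character vector of term ids.
#' @export
ancestors <- function(graph, term, include_self = FALSE) {
  term <- resolve_term(graph, term)
  out <- character(0)
  queue <- graph$parents[[term]]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (!(v %in% out)) {
      out <- c(out, v)
      queue <- c(queue, graph$parents[[v]])
    }
  }
  if (include_self) out <- c(term, out)
  unique(out)
}

#' Descendants of a term
#'
#' @inheritParams ancestors
#' @return Character vector of term ids.
#' @export
descendants <- function(graph, term, include_self = FALSE) {
  term <- resolve_term(graph, term)
  out <- character(0)
  queue <- graph$children[[term]]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (!(v %in% out)) {
      out <- c(out, v)
      queue <- c(queue, graph$children[[v]])
    }
  }
  if (include_self) out <- c(term, out)
  unique(out)
}

# Shortest edge distances from `term` to each of its ancestors (self included,
# distance 0), following parent links only.  BFS; edges are unweighted.
up_distances <- function(graph, term) {
  d <- stats::setNames(0L, term)
  queue <- term
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (p in graph$parents[[v]]) {
      if (is.na(d[p])) {
        d[p] <- d[[v]] + 1L
        queue <- c(queue, p)
      } else if (d[[v]] + 1L < d[[p]]) {
        d[p] <- d[[v]] + 1L
        queue <- c(queue, p)
      }
    }
  }
  d
}

#' Shortest-path distance between two terms
#'
#' The number of edges along the shortest path connecting the terms through a
#' common ancestor: the minimum over common ancestors `c` of the upward
#' distance from each term to `c`.  Paths run only through ancestors, matching
#' the MRCA-path decomposition used by the RSS measure.  Zero if and only if
#' the two terms are identical; symmetric.
#'
#' @inheritParams ancestors
#' @param u,v Term ids in the same namespace.
#' @return Non-negative integer edge count.
#' @export
term_distance <- function(graph, u, v) {
  u <- resolve_term(graph, u)
  v <- resolve_term(graph, v)
  check_same_namespace(graph, u, v)
  if (identical(u, v)) return(0L)
  du <- up_distances(graph, u)
  dv <- up_distances(graph, v)
  common <- intersect(names(du), names(dv))
  if (!length(common)) {
    stop_hrss(sprintf("no common ancestor connects '%s' and '%s'", u, v),
              "hrss_unreachable")
  }
  as.integer(min(du[common] + dv[common]))
}

#' Most recent common ancestor
#'
#' Among the common ancestors of `a` and `b` (each term counts as its own
#' ancestor, so subsumption returns the subsumer), the one at maximal depth
#' from the namespace root.  Depth ties break to the lexicographically
#' smallest id, for determinism.
#'
#' @inheritParams term_distance
#' @param a,b Term ids in the same namespace.
#' @return A term id.
#' @export
mrca <- function(graph, a, b) {
  a <- resolve_term(graph, a)
  b <- resolve_term(graph, b)
  check_same_namespace(graph, a, b)
  common <- intersect(ancestors(graph, a, include_self = TRUE),
                      ancestors(graph, b, include_self = TRUE))
  if (!length(common)) {
    stop_hrss(sprintf("no common ancestor of '%s' and '%s'", a, b),
              "hrss_unreachable")
  }
  d <- graph$depth[common]
  best <- common[d == max(d)]
  sort(best)[1]
}

#' Leaf generality of a term
#'
#' The minimum edge distance from a term to any leaf descending from it;
#' zero for leaves.  This is the structural generality used as component
#' beta of the RSS measure.
#'
#' @inheritParams ancestors
#' @return Non-negative integer.
#' @export
leaf_generality <- function(graph, term) {
  term <- resolve_term(graph, term)
  if (!length(graph$children[[term]])) return(0L)
  # BFS down; first leaf reached gives the minimum distance
  dist <- stats::setNames(0L, term)
  queue <- term
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (ch in graph$children[[v]]) {
      if (is.na(dist[ch])) {
        dist[ch] <- dist[[v]] + 1L
        if (!length(graph$children[[ch]])) return(as.integer(dist[[ch]]))
        queue <- c(queue, ch)
      }
    }
  }
  0L  # unreachable: a non-leaf always reaches a leaf in a finite DAG
}

#' Depth of a term
#'
#' Shortest edge distance from the namespace root (root depth 0).
#'
#' @inheritParams ancestors
#' @return Non-negative integer.
#' @export
term_depth <- function(graph, term) {
  term <- resolve_term(graph, term)
  as.integer(graph$depth[[term]])
}

# Leaves (non-obsolete, childless terms) of a namespace.
namespace_leaves <- function(graph, namespace) {
  t <- graph$terms
  active <- t$id[!t$is_obsolete & t$namespace == namespace]
  active[lengths(graph$children[active]) == 0L]
}
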