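#' Collapse exactly redundant nodes
#'
#' Any edge whose endpoints carry bit-identical vectors is contracted,
#' the parent (higher abstraction) surviving; chains of identical nodes
#' collapse to their most abstract member.  The alias map records every
#' merged id.  The set of distinct vectors present in the graph is
#' unchanged; only exact duplicates connected by edges disappear.
#'
#' Contraction works on connected components of the identical-vector
#' edge subgraph (all members of such a component share one vector), with
#' the survivor chosen deterministically as the component member latest
#' in topological order.  In the rare case where a whole-component
#' contraction would close a cycle through an intervening node with a
#' different vector (possible only via threshold nodes, which are not
#' OR-monotone), the routine falls back to contracting single edges that
#' are provably safe, and warns if any identical-vector edge must be
#' left in place to preserve acyclicity.
#'
#' @param graph a fully encoded [feature_graph()].
#' @return the collapsed graph.
#' @export
collapse_redundant <- function(graph) {
  if (is.null(graph$vectors) || anyNA(graph$vectors))
    stop("every node needs an assigned vector before collapsing")
  key <- apply(graph$vectors, 1L, paste, collapse = "")
  same <- key[graph$edges$child] == key[graph$edges$parent]
  if (!any(same)) return(graph)

  sub <- graph$edges[same, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(sub, directed = FALSE)
  comp <- igraph::components(ig)
  ord <- match(names(comp$membership), topo_order(graph))
  mapping <- stats::setNames(names(comp$membership), names(comp$membership))
  for (cid in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == cid]
    survivor <- members[which.max(ord[match(members, names(comp$membership))])]
    mapping[members] <- survivor
  }
  collapsed <- apply_contraction(graph, mapping)
  if (!is.null(collapsed)) return(maybe_recurse(collapsed))

  # fall back: contract one provably safe edge at a time
  repeat {
    key <- apply(graph$vectors, 1L, paste, collapse = "")
    same_idx <- which(key[graph$edges$child] == key[graph$edges$parent])
    if (!length(same_idx)) return(graph)
    done <- FALSE
    for (e in same_idx) {
      u <- graph$edges$child[e]; v <- graph$edges$parent[e]
      mapping <- stats::setNames(graph$nodes$node_id, graph$nodes$node_id)
      mapping[u] <- v
      trial <- apply_contraction(graph, mapping)
      if (!is.null(trial)) { graph <- trial; done <- TRUE; break }
    }
    if (!done) {
      warning("identical-vector edge(s) left uncontracted to keep the ",
              "graph acyclic")
      return(graph)
    }
  }
}

# returns NULL when the contraction would create a cycle
apply_contraction <- function(graph, mapping) {
  merged <- names(mapping)[mapping != names(mapping)]
  if (!length(merged)) return(graph)
  map_id <- function(x) ifelse(x %in% names(mapping), unname(mapping[x]), x)
  edges <- data.frame(child = map_id(graph$edges$child),
                      parent = map_id(graph$edges$parent))
  edges <- unique(edges[edges$child != edges$parent, , drop = FALSE])
  keep <- !(graph$nodes$node_id %in% merged)
  nodes <- graph$nodes[keep, , drop = FALSE]
  if (nrow(edges)) {
    ig <- igraph::graph_from_data_frame(
      edges, directed = TRUE, vertices = data.frame(name = nodes$node_id))
    if (!igraph::is_dag(ig)) return(NULL)
  }
  # merge direct-variant mappings into survivors
  lv <- graph$leaf_variants
  for (m in intersect(merged, names(lv))) {
    tgt <- unname(mapping[m])
    lv[[tgt]] <- sort(unique(c(lv[[tgt]], lv[[m]])))
    lv[[m]] <- NULL
  }
  alias <- graph$alias
  if (length(alias)) alias[] <- map_id(unname(alias))
  alias <- c(alias, stats::setNames(unname(mapping[merged]), merged))
  g <- feature_graph(nodes, edges,
                     vectors = graph$vectors[keep, , drop = FALSE],
                     sample_ids = graph$sample_ids,
                     leaf_variants = lv, alias = alias,
                     go_genes = graph$go_genes, go_stats = graph$go_stats)
  g$direct <- if (!is.null(graph$direct)) graph$direct[keep, , drop = FALSE]
  g
}

# component contraction can expose new identical-vector edges (two
# formerly separated duplicates now adjacent); iterate to fixpoint
maybe_recurse <- function(graph) {
  key <- apply(graph$vectors, 1L, paste, collapse = "")
  if (any(key[graph$edges$child] == key[graph$edges$parent]))
    return(collapse_redundant(graph))
  graph
}
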