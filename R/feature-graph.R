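#' Feature knowledge graph
#'
#' A `feature_graph` is a directed acyclic graph whose nodes are candidate
#' feature encodings of genomic variation -- from single variant loci up
#' through exons, UTRs, transcripts, genes, peptide/biological regions and
#' Gene Ontology terms.  Edges point from child to parent, where the parent
#' is the higher level of abstraction: an exon points at its transcript, a
#' transcript at its gene, a gene at the GO leaf terms it is annotated to.
#'
#' Genomic intervals are held internally as 0-based half-open coordinates;
#' conversion from the 1-based inclusive input conventions (GFF3, VCF)
#' happens once, at the parsing boundary.
#'
#' @param nodes data.frame with columns `node_id`, `kind` (one of `snp`,
#'   `exon`, `transcript`, `gene`, `utr`, `peptide`, `bio_region`,
#'   `go_term`), `label`, `chrom`, `start`, `end` (0-based half-open, `NA`
#'   for interval-free nodes) and `combine_rule` (`leaf`, `or` or
#'   `threshold`).
#' @param edges data.frame with columns `child`, `parent` (node ids).
#' @param vectors optional integer matrix of per-sample binary vectors,
#'   one row per node (rownames = node ids), one column per sample.
#' @param sample_ids optional character vector naming the vector columns.
#' @param leaf_variants named list mapping node ids to integer indices of
#'   variant loci contributing directly to that node.
#' @param alias named character vector mapping collapsed node ids to the
#'   id of the surviving node.
#' @param go_genes named list mapping GO leaf term ids to the gene node
#'   ids they are associated with.
#' @param go_stats named list of enrichment-threshold statistics per GO
#'   leaf term (see [go_leaf_threshold()]).
#' @return an object of class `feature_graph`.
#' @export
feature_graph <- function(nodes,
                          edges = data.frame(child = character(),
                                             parent = character()),
                          vectors = NULL,
                          sample_ids = NULL,
                          leaf_variants = list(),
                          alias = character(),
                          go_genes = list(),
                          go_stats = list()) {
  stopifnot(is.data.frame(nodes), all(c("node_id", "kind") %in% names(nodes)))
  nodes$node_id <- as.character(nodes$node_id)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node ids: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  for (col in c("label", "chrom"))
    if (is.null(nodes[[col]])) nodes[[col]] <- rep(NA_character_, nrow(nodes))
  for (col in c("start", "end"))
    if (is.null(nodes[[col]])) nodes[[col]] <- rep(NA_real_, nrow(nodes))
  if (is.null(nodes$combine_rule)) nodes$combine_rule <- rep("or", nrow(nodes))
  bad_kind <- setdiff(unique(nodes$kind), c("snp", "exon", "transcript", "gene",
                                            "utr", "peptide", "bio_region", "go_term"))
  if (length(bad_kind)) stop("unknown node kind: ", paste(bad_kind, collapse = ", "))
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  missing_ep <- setdiff(unique(c(edges$child, edges$parent)), nodes$node_id)
  if (length(missing_ep))
    stop("edge endpoint not in node table: ", paste(missing_ep, collapse = ", "))
  g <- structure(list(nodes = nodes, edges = edges, vectors = vectors,
                      sample_ids = sample_ids, leaf_variants = leaf_variants,
                      alias = alias, go_genes = go_genes, go_stats = go_stats),
                 class = "feature_graph")
  if (!fg_is_acyclic(g)) stop("feature_graph must be acyclic")
  g
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("feature_graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(table(x$nodes$kind))
  if (!is.null(x$vectors))
    cat(sprintf("binary vectors over %d samples\n", ncol(x$vectors)))
  if (length(x$alias))
    cat(sprintf("%d collapsed node aliases\n", length(x$alias)))
  invisible(x)
}

# igraph view of the child -> parent edge set; isolated nodes kept
fg_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges, directed = TRUE,
    vertices = data.frame(name = graph$nodes$node_id))
}

fg_is_acyclic <- function(graph) {
  if (nrow(graph$edges) == 0L) return(TRUE)
  igraph::is_dag(fg_igraph(graph))
}

#' Topological order of a feature graph
#'
#' Returns node ids ordered so that every child precedes every parent
#' (bottom-up over the abstraction hierarchy).
#'
#' @param graph a [feature_graph()].
#' @return character vector of node ids.
#' @export
topo_order <- function(graph) {
  ig <- fg_igraph(graph)
  ord <- igraph::topo_sort(ig, mode = "out")
  names(ord)
}

# children (direct lower-level nodes) of each node: named list
fg_children <- function(graph) {
  split(graph$edges$child, factor(graph$edges$parent, levels = graph$nodes$node_id))
}

fg_parents <- function(graph) {
  split(graph$edges$parent, factor(graph$edges$child, levels = graph$nodes$node_id))
}

#' Ancestors of a node (higher abstractions, following child-to-parent edges)
#'
#' A node counts as its own ancestor, so a gene node is among its own gene
#' ancestors.
#'
#' @param graph a [feature_graph()].
#' @param ids node ids to query.
#' @return named list of character vectors.
#' @export
node_ancestors <- function(graph, ids = graph$nodes$node_id) {
  ig <- fg_igraph(graph)
  out <- lapply(ids, function(id) {
    names(igraph::subcomponent(ig, id, mode = "out"))
  })
  names(out) <- ids
  out
}

#' Descendants of a node (more concrete nodes feeding into it)
#'
#' @inheritParams node_ancestors
#' @return named list of character vectors (each includes the query node).
#' @export
node_descendants <- function(graph, ids = graph$nodes$node_id) {
  ig <- fg_igraph(graph)
  out <- lapply(ids, function(id) {
    names(igraph::subcomponent(ig, id, mode = "in"))
  })
  names(out) <- ids
  out
}

# resolve an id through the alias map (collapsed node -> survivor)
#' Resolve node ids through the collapse alias map
#'
#' After [collapse_redundant()], nodes merged away are recorded in the
#' graph's alias map.  `resolve_alias()` maps any node id (original or
#' surviving) to the id of its surviving representative.
#'
#' @param graph a [feature_graph()].
#' @param ids character vector of node ids.
#' @return character vector of surviving node ids.
#' @export
resolve_alias <- function(graph, ids) {
  out <- as.character(ids)
  if (length(graph$alias)) {
    repeat {
      hit <- out %in% names(graph$alias)
      if (!any(hit)) break
      out[hit] <- unname(graph$alias[out[hit]])
    }
  }
  out
}

#' Cohort of labelled samples
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param labels vector of class labels, same length, binary or categorical.
#' @return an object of class `cohort`.
#' @export
cohort <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(labels) != length(sample_ids))
    stop("labels and sample_ids differ in length")
  structure(list(sample_ids = sample_ids, labels = labels), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d samples, labels: %s\n", length(x$sample_ids),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
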