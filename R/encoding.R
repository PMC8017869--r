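#' Assign leaf binary vectors from variant presence calls
#'
#' For every node with directly mapped variant loci, bit *i* is set when
#' sample *i* carries at least one non-reference allele at any of those
#' loci.  Graph leaves (nodes with no children) without mapped variants
#' get all-zero vectors.  Internal nodes stay unassigned until
#' [propagate_or()] runs.
#'
#' @param graph a [feature_graph()] with `leaf_variants` mappings.
#' @param variants the `variant_set` the mappings index into.
#' @param cohort a [cohort()]; its sample order must match the variant
#'   set's.
#' @return the graph with a vectors matrix (unassigned rows `NA`) and
#'   per-node direct contributions recorded.
#' @export
encode_leaves <- function(graph, variants, cohort) {
  if (!identical(variants$sample_ids, cohort$sample_ids))
    stop("variant stream sample order does not match cohort")
  n <- length(cohort$sample_ids)
  ids <- graph$nodes$node_id
  direct <- matrix(0L, nrow(graph$nodes), n,
                   dimnames = list(ids, cohort$sample_ids))
  for (nd in names(graph$leaf_variants)) {
    idx <- graph$leaf_variants[[nd]]
    if (length(idx))
      direct[nd, ] <- as.integer(
        colSums(variants$presence[idx, , drop = FALSE]) > 0L)
  }
  vectors <- matrix(NA_integer_, nrow(graph$nodes), n,
                    dimnames = list(ids, cohort$sample_ids))
  is_leaf <- !(ids %in% graph$edges$parent)
  vectors[is_leaf, ] <- direct[is_leaf, ]
  graph$vectors <- vectors
  graph$direct <- direct
  graph$sample_ids <- cohort$sample_ids
  graph
}

#' Enrichment-threshold vector for a GO leaf term
#'
#' Given per-sample counts of variants mapping to a term's associated
#' genes, bit *i* is set when `counts[i] >= mu + sigma`, where `mu` and
#' `sigma` are the mean and *population* (divide-by-n) standard deviation
#' of the counts.  When every count is equal the rule saturates
#' (`sigma = 0`, every bit set); saturated vectors carry zero mutual
#' information and are removed by the relevance filter downstream, so no
#' special case is made here.
#'
#' @param counts non-negative integer vector, one entry per sample.
#' @return list with `vector` (integer 0/1) and `stats` (`counts`, `mu`,
#'   `sigma`, `cutoff = mu + sigma`).
#' @export
go_leaf_threshold <- function(counts) {
  stopifnot(all(counts >= 0))
  mu <- mean(counts)
  sigma <- sqrt(mean((counts - mu)^2))
  cutoff <- mu + sigma
  list(vector = as.integer(counts >= cutoff),
       stats = list(counts = as.integer(counts), mu = mu, sigma = sigma,
                    cutoff = cutoff))
}

# per-sample variant counts over the genes associated with each GO
# threshold term; counts each distinct locus in the genes' subtrees once
go_term_counts <- function(graph, variants) {
  if (!length(graph$go_genes)) return(list())
  gene_ids <- unique(unlist(graph$go_genes))
  desc <- node_descendants(graph, gene_ids)
  gene_loci <- lapply(desc, function(nodeset)
    unique(unlist(graph$leaf_variants[intersect(nodeset, names(graph$leaf_variants))])))
  lapply(graph$go_genes, function(gs) {
    idx <- unique(unlist(gene_loci[gs]))
    if (!length(idx)) return(integer(ncol(variants$presence)))
    as.integer(colSums(variants$presence[idx, , drop = FALSE]))
  })
}

#' Compute enrichment thresholds for all GO leaf terms
#'
#' @param graph an encoded [feature_graph()] (after [encode_leaves()]).
#' @param variants the matching `variant_set`.
#' @param cutoffs optional named numeric vector of pre-computed cutoffs
#'   (term -> cutoff), used to apply thresholds learned on a training
#'   cohort to new samples without re-estimating `mu + sigma`.
#' @return the graph with `go_stats` filled and threshold-node vectors
#'   assigned.
#' @export
compute_go_thresholds <- function(graph, variants, cutoffs = NULL) {
  term_counts <- go_term_counts(graph, variants)
  thr_nodes <- graph$nodes$node_id[graph$nodes$combine_rule == "threshold"]
  for (term in thr_nodes) {
    counts <- term_counts[[term]]
    if (is.null(counts)) {
      warning("GO term ", term, " has no associated genes present; ",
              "vector set to all zeros")
      graph$vectors[term, ] <- 0L
      next
    }
    if (is.null(cutoffs)) {
      res <- go_leaf_threshold(counts)
      graph$go_stats[[term]] <- res$stats
      graph$vectors[term, ] <- res$vector
    } else {
      cut <- cutoffs[[term]]
      if (is.null(cut) || is.na(cut))
        stop("no stored cutoff for GO term ", term)
      graph$vectors[term, ] <- as.integer(counts >= cut)
      graph$go_stats[[term]] <- list(counts = as.integer(counts),
                                     mu = NA_real_, sigma = NA_real_,
                                     cutoff = cut)
    }
  }
  graph
}

#' Bottom-up OR-propagation of binary vectors
#'
#' Processes nodes in topological (children before parents) order.  An
#' `or` node's vector is the bitwise OR of its children's vectors and its
#' own direct variant contribution (a structural node may carry variants
#' mapped directly to it).  `threshold` nodes must already have vectors
#' (see [compute_go_thresholds()]); they act as fixed inputs to their
#' ancestors.
#'
#' @param graph an encoded [feature_graph()].
#' @return the graph with every node's vector assigned.
#' @export
propagate_or <- function(graph) {
  if (is.null(graph$vectors)) stop("run encode_leaves() first")
  children <- fg_children(graph)
  for (nd in topo_order(graph)) {
    rule <- graph$nodes$combine_rule[match(nd, graph$nodes$node_id)]
    if (rule == "threshold") {
      if (anyNA(graph$vectors[nd, ]))
        stop("threshold node ", nd, " has no vector; ",
             "run compute_go_thresholds() first")
      next
    }
    if (!anyNA(graph$vectors[nd, ]) && !length(children[[nd]])) next
    ch <- children[[nd]]
    v <- if (!is.null(graph$direct)) graph$direct[nd, ]
         else integer(ncol(graph$vectors))
    if (length(ch)) {
      chv <- graph$vectors[ch, , drop = FALSE]
      if (anyNA(chv)) stop("child vector unassigned below node ", nd)
      v <- as.integer((colSums(chv) + v) > 0L)
    }
    graph$vectors[nd, ] <- v
  }
  graph
}

#' Encode a graph end to end
#'
#' Convenience wrapper: [encode_leaves()], [compute_go_thresholds()],
#' [propagate_or()].
#'
#' @inheritParams encode_leaves
#' @param cutoffs see [compute_go_thresholds()].
#' @return fully encoded graph.
#' @export
assign_vectors <- function(graph, variants, cohort, cutoffs = NULL) {
  graph <- encode_leaves(graph, variants, cohort)
  graph <- compute_go_thresholds(graph, variants, cutoffs = cutoffs)
  propagate_or(graph)
}

#' Identify saturated (all-ones) feature vectors
#'
#' A saturated vector is uninformative: its mutual information with any
#' label vector is exactly zero, so the relevance filter removes it.
#' The flags returned here are informational.
#'
#' @param graph an encoded [feature_graph()].
#' @return character vector of node ids whose vectors are all ones.
#' @export
saturation_flags <- function(graph) {
  if (is.null(graph$vectors)) stop("vectors not assigned")
  rownames(graph$vectors)[rowSums(graph$vectors == 1L) == ncol(graph$vectors)]
}
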