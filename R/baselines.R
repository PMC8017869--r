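#' Greedy hierarchical feature selection (two-step baseline)
#'
#' A two-step greedy selector over the feature hierarchy, used as a
#' comparison baseline.  Step 1 sweeps the graph leaves-to-root and
#' drops a node when it is irrelevant (relevance exactly zero) or
#' redundant with any of its direct ancestors (absolute Pearson
#' correlation at or above `similarity_threshold`).  Step 2 computes,
#' for every root-to-leaf path, the mean relevance of the nodes that
#' survived step 1, and drops any node strictly below the mean on at
#' least one of its paths.
#'
#' Relevance here is mutual information with the label, and similarity
#' is absolute Pearson correlation, matching the measures used by the
#' optimal selector so the comparison isolates the selection strategy.
#'
#' @param graph an encoded [feature_graph()].
#' @param relevance named numeric vector of per-node relevance scores.
#' @param similarity_threshold redundancy cutoff in `[0, 1]`,
#'   default 0.99.
#' @param nodes node ids to consider (default: the names of
#'   `relevance`); selection runs on the induced subgraph.
#' @return character vector of surviving node ids.
#' @export
shsel_select <- function(graph, relevance, similarity_threshold = 0.99,
                         nodes = names(relevance)) {
  stopifnot(similarity_threshold >= 0, similarity_threshold <= 1)
  nodes <- intersect(graph$nodes$node_id, nodes)
  V <- graph$vectors
  edges <- graph$edges[graph$edges$child %in% nodes &
                       graph$edges$parent %in% nodes, , drop = FALSE]
  parents <- split(edges$parent, factor(edges$child, levels = nodes))
  ord <- intersect(topo_order(graph), nodes)  # children before parents

  # step 1: drop irrelevant or ancestor-redundant nodes
  surv <- character()
  for (nd in ord) {
    if (relevance[[nd]] <= 0) next
    redundant <- FALSE
    for (p in parents[[nd]]) {
      r <- suppressWarnings(pearson_binary(V[nd, ], V[p, ]))
      if (abs(r) >= similarity_threshold) { redundant <- TRUE; break }
    }
    if (!redundant) surv <- c(surv, nd)
  }

  # step 2: drop nodes strictly below the mean relevance of survivors
  # along any root-to-leaf path of the considered subgraph
  paths <- enumerate_paths(nodes, edges)
  drop <- character()
  for (pth in paths) {
    on_path <- intersect(pth, surv)
    if (!length(on_path)) next
    mean_rel <- mean(relevance[on_path])
    drop <- c(drop, on_path[relevance[on_path] < mean_rel])
  }
  sort(setdiff(surv, unique(drop)))
}

# all maximal directed paths (leaf -> ... -> root) in the induced
# subgraph; guarded against combinatorial blow-up
enumerate_paths <- function(nodes, edges, max_paths = 1e5) {
  parents <- split(edges$parent, factor(edges$child, levels = nodes))
  leaves <- setdiff(nodes, edges$parent)
  paths <- list()
  walk <- function(nd, acc) {
    if (length(paths) >= max_paths) {
      warning("path enumeration truncated at ", max_paths, " paths")
      return()
    }
    ps <- parents[[nd]]
    if (!length(ps)) { paths[[length(paths) + 1L]] <<- acc; return() }
    for (p in ps) walk(p, c(acc, p))
  }
  for (lf in leaves) walk(lf, lf)
  paths
}

#' Mutual-information threshold baseline
#'
#' Selects every feature whose relevance reaches `t`; the trivial filter
#' baseline that the hierarchical selectors are compared against.
#'
#' @param relevance named numeric vector of per-node relevance.
#' @param t non-negative threshold.
#' @return character vector of selected node ids.
#' @export
threshold_select <- function(relevance, t) {
  stopifnot(t >= 0)
  sort(names(relevance)[relevance >= t])
}

#' Redundancy of a selected feature set
#'
#' Samples up to `m` of the selected features without replacement and
#' reports the mean (and standard error) of the absolute pairwise
#' Pearson correlations among them.
#'
#' @param graph an encoded [feature_graph()].
#' @param selected character vector of at least two selected node ids.
#' @param m maximum number of features to sample, default 1000.
#' @param seed integer seed for the subsample.
#' @return list with `mean_abs_corr`, `se`, `n_features`, `n_pairs`.
#' @export
redundancy_report <- function(graph, selected, m = 1000, seed = 1L) {
  if (length(selected) < 2L) stop("need at least two selected features")
  take <- min(m, length(selected))
  ids <- withr::with_seed(seed, sample(selected, take))
  V <- t(graph$vectors[ids, , drop = FALSE])
  cm <- suppressWarnings(stats::cor(V))
  cm[is.na(cm)] <- 0                      # constant vectors
  vals <- abs(cm[upper.tri(cm)])
  list(mean_abs_corr = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       n_features = take, n_pairs = length(vals))
}
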