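#' Empirical entropy of a label vector (bits)
#'
#' Plug-in estimate over the observed label alphabet, log base 2, with
#' the convention 0·log 0 = 0.  Labels may be binary or categorical.
#'
#' @param L label vector.
#' @return entropy in bits.
#' @export
entropy <- function(L) {
  if (!length(L)) stop("empty label vector")
  p <- table(L) / length(L)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conditional entropy H(L | B) in bits
#'
#' Plug-in estimate: the expectation over the feature alphabet of the
#' entropy of labels within each feature stratum.
#'
#' @param L label vector.
#' @param B feature vector of the same length.
#' @return conditional entropy in bits.
#' @export
conditional_entropy <- function(L, B) {
  if (length(L) != length(B)) stop("length mismatch between L and B")
  n <- length(L)
  strata <- split(L, B)
  sum(vapply(strata, function(Ls) length(Ls) / n * entropy(Ls), numeric(1)))
}

#' Mutual information I(B; L) in bits
#'
#' `H(L) - H(L | B)`; non-negative and bounded by `min(H(B), H(L))`.
#' A constant (e.g. saturated all-ones) feature has exactly zero mutual
#' information with any label.
#'
#' @param B binary feature vector.
#' @param L label vector of the same length.
#' @return mutual information in bits.
#' @export
mutual_information <- function(B, L) {
  mi <- entropy(L) - conditional_entropy(L, B)
  max(mi, 0)  # clip floating-point negatives like -1e-17
}

#' Mutual-information relevance table and pre-filter
#'
#' Scores every node's vector against the cohort labels and retains the
#' nodes whose mutual information is at least `t`.
#'
#' @param graph an encoded [feature_graph()].
#' @param cohort a [cohort()] whose sample order matches the vectors.
#' @param t non-negative threshold in bits.
#' @return list with `retained` (character vector of node ids) and
#'   `relevance` (named numeric vector over all nodes).
#' @export
mi_filter <- function(graph, cohort, t) {
  if (t < 0) stop("mutual-information threshold must be non-negative")
  if (is.null(graph$vectors)) stop("vectors not assigned")
  L <- cohort$labels
  relevance <- apply(graph$vectors, 1L, mutual_information, L = L)
  list(retained = names(relevance)[relevance >= t], relevance = relevance)
}

#' Pearson correlation between two binary feature vectors
#'
#' Standard Pearson correlation on 0/1 values.  A constant vector makes
#' the correlation undefined; it is reported as 0 with a warning, since
#' constant vectors carry no mutual information and are filtered out
#' upstream anyway.
#'
#' @param B_i,B_j binary vectors of equal length.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_binary <- function(B_i, B_j) {
  if (length(B_i) != length(B_j)) stop("length mismatch")
  if (stats::var(B_i) == 0 || stats::var(B_j) == 0) {
    warning("constant vector: correlation undefined, reported as 0")
    return(0)
  }
  stats::cor(B_i, B_j)
}

#' Build the candidate pair set entering the redundancy penalty
#'
#' Only a structured subset of feature pairs is penalized in the
#' selection objective.  A retained pair (i, j) is a candidate when any
#' of three conditions holds on the (collapsed) graph: (1) the two nodes
#' share a common gene-node ancestor (a gene counts as its own
#' ancestor); (2) they have gene ancestors whose genomic intervals
#' overlap; (3) one lies on a directed path to the other.  Candidates
#' are kept only when `|Pearson correlation| >= pair_gate`.
#'
#' @param graph an encoded, typically collapsed, [feature_graph()].
#' @param retained character vector of node ids that passed the MI
#'   filter.
#' @param pair_gate absolute-correlation gate, default 0.3.
#' @return data.frame with columns `i`, `j` (id order, `i < j`), `corr`
#'   and `abs_corr`; class `candidate_pairs`.
#' @export
build_candidate_pairs <- function(graph, retained, pair_gate = 0.3) {
  retained <- sort(intersect(retained, graph$nodes$node_id))
  m <- length(retained)
  empty <- data.frame(i = character(), j = character(),
                      corr = numeric(), abs_corr = numeric())
  class(empty) <- c("candidate_pairs", "data.frame")
  if (m < 2L) return(empty)

  gene_ids <- graph$nodes$node_id[graph$nodes$kind == "gene"]
  anc <- node_ancestors(graph, retained)
  gene_anc <- lapply(anc, intersect, gene_ids)
  # genomic intervals of genes, for the overlapping-genes rule
  gi <- graph$nodes[graph$nodes$node_id %in% gene_ids, , drop = FALSE]
  genes_overlap <- function(a, b) {
    ia <- match(a, gi$node_id); ib <- match(b, gi$node_id)
    any(outer(seq_along(ia), seq_along(ib), function(x, y) {
      gi$chrom[ia[x]] == gi$chrom[ib[y]] &
        gi$start[ia[x]] < gi$end[ib[y]] & gi$end[ia[x]] > gi$start[ib[y]]
    }))
  }
  rows <- list(); nr <- 0L
  V <- graph$vectors
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      i <- retained[a]; j <- retained[b]
      structural <-
        length(intersect(gene_anc[[i]], gene_anc[[j]])) > 0L ||
        (length(gene_anc[[i]]) && length(gene_anc[[j]]) &&
           genes_overlap(gene_anc[[i]], gene_anc[[j]])) ||
        j %in% anc[[i]] || i %in% anc[[j]]  # directed path either way
      if (!structural) next
      r <- suppressWarnings(pearson_binary(V[i, ], V[j, ]))
      if (abs(r) >= pair_gate) {
        nr <- nr + 1L
        rows[[nr]] <- data.frame(i = i, j = j, corr = r, abs_corr = abs(r))
      }
    }
  }
  out <- if (nr) do.call(rbind, rows) else empty
  class(out) <- c("candidate_pairs", "data.frame")
  out
}
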