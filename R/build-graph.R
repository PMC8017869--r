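#' Build the genomic hierarchy from annotation records and variant loci
#'
#' Creates one node per annotation record and one per distinct variant
#' locus, and wires the abstraction edges: exon -> transcript,
#' transcript -> gene, UTR -> transcript (or gene when no transcript
#' parent exists), peptide / biological-region -> every overlapping gene.
#' Each variant locus attaches to its *smallest* containing structural
#' element(s) among exons, UTRs, biological regions and peptides; a
#' variant inside a gene but outside all of its sub-elements attaches to
#' the gene directly; a variant overlapping nothing stays an isolated
#' leaf.  Ancestors receive variant signal later through OR-propagation,
#' so attaching only to minimal containers avoids duplicated leaf
#' contributions.
#'
#' @param annotations data.frame from [read_gff3()].
#' @param variants a `variant_set` from [read_vcf()].
#' @return a [feature_graph()] whose variant (snp) nodes carry
#'   `leaf_variants` indices into `variants$loci`.
#' @export
build_genomic_hierarchy <- function(annotations, variants) {
  ann <- annotations
  loci <- variants$loci
  # distinct variant loci -> snp nodes
  locus_key <- paste(loci$chrom, loci$pos, sep = ":")
  uniq <- !duplicated(locus_key)
  snp_id <- ifelse(!is.na(loci$id) & loci$id != "." & !duplicated(loci$id) & uniq,
                   loci$id,
                   paste0("snp:", loci$chrom, ":", loci$pos + 1L))
  snp_tab <- data.frame(node_id = snp_id[uniq], chrom = loci$chrom[uniq],
                        pos = loci$pos[uniq])
  leaf_variants <- split(seq_along(locus_key),
                         factor(locus_key, levels = locus_key[uniq]))
  names(leaf_variants) <- snp_tab$node_id

  nodes <- data.frame(
    node_id = c(ann$id, snp_tab$node_id),
    kind = c(ann$kind, rep("snp", nrow(snp_tab))),
    label = c(ann$id, snp_tab$node_id),
    chrom = c(ann$chrom, snp_tab$chrom),
    start = c(ann$start, snp_tab$pos),
    end = c(ann$end, snp_tab$pos + 1),
    combine_rule = c(rep("or", nrow(ann)), rep("leaf", nrow(snp_tab))))

  kind_of <- stats::setNames(ann$kind, ann$id)
  edges_c <- character(); edges_p <- character()
  add_edge <- function(child, parent) {
    edges_c <<- c(edges_c, child); edges_p <<- c(edges_p, parent)
  }
  genes <- ann[ann$kind == "gene", , drop = FALSE]
  overlapping_genes <- function(chrom, start, end) {
    genes$id[genes$chrom == chrom & genes$start < end & genes$end > start]
  }
  for (i in seq_len(nrow(ann))) {
    k <- ann$kind[i]
    if (k %in% c("peptide", "bio_region")) {
      for (g in overlapping_genes(ann$chrom[i], ann$start[i], ann$end[i]))
        add_edge(ann$id[i], g)
    } else if (k != "gene") {
      p <- ann$parent_id[i]
      if (!is.na(p) && p %in% ann$id) {
        add_edge(ann$id[i], p)
      } else if (k == "utr") {
        # no declared parent: fall back to containing gene(s)
        for (g in genes$id[genes$chrom == ann$chrom[i] &
                           genes$start <= ann$start[i] &
                           genes$end >= ann$end[i]])
          add_edge(ann$id[i], g)
      }
    }
  }

  # containment-based variant attachment
  containers <- ann[ann$kind %in% c("exon", "utr", "bio_region", "peptide"), ,
                    drop = FALSE]
  struct_edges <- data.frame(child = edges_c, parent = edges_p)
  gene_desc <- gene_descendant_sets(nodes, struct_edges)
  for (s in seq_len(nrow(snp_tab))) {
    chrom <- snp_tab$chrom[s]; pos <- snp_tab$pos[s]
    hit <- containers[containers$chrom == chrom & containers$start <= pos &
                      containers$end > pos, , drop = FALSE]
    chosen <- character()
    if (nrow(hit)) {
      # minimal containers under interval containment; ties all kept
      minimal <- vapply(seq_len(nrow(hit)), function(a) {
        !any(hit$start >= hit$start[a] & hit$end <= hit$end[a] &
             (hit$end - hit$start) < (hit$end[a] - hit$start[a]))
      }, logical(1))
      chosen <- hit$id[minimal]
      for (el in chosen) add_edge(snp_tab$node_id[s], el)
    }
    g_hit <- genes$id[genes$chrom == chrom & genes$start <= pos & genes$end > pos]
    for (g in g_hit) {
      if (!any(chosen %in% gene_desc[[g]]))
        add_edge(snp_tab$node_id[s], g)
    }
  }
  edges <- unique(data.frame(child = edges_c, parent = edges_p))
  feature_graph(nodes, edges, leaf_variants = leaf_variants)
}

# descendant node ids (structural subtree) of each gene, gene included
gene_descendant_sets <- function(nodes, edges) {
  gene_ids <- nodes$node_id[nodes$kind == "gene"]
  if (!length(gene_ids)) return(list())
  ig <- igraph::graph_from_data_frame(
    edges, directed = TRUE, vertices = data.frame(name = nodes$node_id))
  out <- lapply(gene_ids, function(g)
    names(igraph::subcomponent(ig, g, mode = "in")))
  names(out) <- gene_ids
  out
}

#' Graft the Gene Ontology DAGs onto the genomic hierarchy
#'
#' GO term nodes are added with child-term -> parent-term edges, keeping
#' the three namespace roots separate.  A GO *leaf* term (one with no
#' child terms) that is associated with genes present in the graph
#' becomes an abstraction of those genes: an edge is added from each
#' associated gene node to the term, and the term is marked with the
#' `threshold` combine rule so that its binary vector derives from
#' per-sample variant counts over the associated genes rather than a
#' saturating logical OR.  All other GO terms keep the `or` rule.
#' Associations naming genes absent from the graph are skipped with a
#' warning; associations to non-leaf terms are ignored (those terms
#' receive signal through the ontology edges).
#'
#' @param graph the genomic hierarchy from [build_genomic_hierarchy()].
#' @param go_edges data.frame (`child`, `parent`) of is_a relations.
#' @param associations data.frame (`gene_id`, `go_term`).
#' @param go_terms optional data.frame with a `term` column; terms absent
#'   from edges and associations are still added as nodes.
#' @return the combined [feature_graph()].
#' @export
graft_go <- function(graph, go_edges, associations,
                     go_terms = NULL) {
  terms <- unique(c(go_edges$child, go_edges$parent, associations$go_term,
                    if (!is.null(go_terms)) go_terms$term))
  terms <- setdiff(terms, graph$nodes$node_id)
  if (!length(terms)) return(graph)
  leaf_terms <- setdiff(terms, go_edges$parent)  # no child terms
  gene_nodes <- graph$nodes$node_id[graph$nodes$kind == "gene"]

  assoc <- associations[associations$go_term %in% leaf_terms, , drop = FALSE]
  unknown <- setdiff(unique(assoc$gene_id), gene_nodes)
  if (length(unknown)) {
    warning("association(s) to absent gene id(s) skipped: ",
            paste(unknown, collapse = ", "))
    assoc <- assoc[assoc$gene_id %in% gene_nodes, , drop = FALSE]
  }
  go_genes <- split(assoc$gene_id, factor(assoc$go_term, levels = leaf_terms))
  go_genes <- lapply(go_genes, unique)
  go_genes <- go_genes[lengths(go_genes) > 0L]

  term_nodes <- data.frame(
    node_id = terms, kind = "go_term", label = terms,
    chrom = NA_character_, start = NA_real_, end = NA_real_,
    combine_rule = ifelse(terms %in% names(go_genes), "threshold", "or"))
  gene_edges <- data.frame(child = assoc$gene_id, parent = assoc$go_term)
  new_edges <- rbind(graph$edges,
                     go_edges[, c("child", "parent")],
                     unique(gene_edges))
  feature_graph(rbind(graph$nodes, term_nodes), new_edges,
                vectors = NULL, sample_ids = graph$sample_ids,
                leaf_variants = graph$leaf_variants,
                alias = graph$alias, go_genes = go_genes,
                go_stats = graph$go_stats)
}
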