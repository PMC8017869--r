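# Builders for in-code fixtures: tiny graphs, random DAGs, random
# selection problems, and minimal on-disk format files.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_vcf <- function(samples = c("S1", "S2"),
                     rows = list(list(chrom = "chr1", pos = 100, id = "rs1",
                                      gts = c("0/1", "0/0")))) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(rows, function(r)
    paste(c(r$chrom, r$pos, r$id, "A", "T", ".", "PASS", ".", "GT", r$gts),
          collapse = "\t"), character(1))
  write_lines_tmp(c(hdr, body), ".vcf")
}

# structural chain: gene g1 > transcript t1 > exon e1, with given extras
tiny_gff <- function(extra = character()) {
  write_lines_tmp(c(
    "##gff-version 3",
    "chr1\tsim\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\tsim\tmRNA\t1\t900\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsim\texon\t50\t150\t.\t+\t.\tID=e1;Parent=t1",
    extra), ".gff3")
}

tiny_obo <- function(stanzas = list(
    c("id: GO:0000001", "name: A", "namespace: biological_process"),
    c("id: GO:0000002", "name: B", "namespace: biological_process",
      "is_a: GO:0000001 ! A"))) {
  lines <- c("format-version: 1.2", "")
  for (s in stanzas) lines <- c(lines, "[Term]", s, "")
  write_lines_tmp(lines, ".obo")
}

# small feature_graph with assigned vectors, built directly in code
mk_graph <- function(nodes, edges = data.frame(child = character(),
                                               parent = character()),
                     vectors = NULL, ...) {
  nd <- data.frame(node_id = nodes$id, kind = nodes$kind,
                   label = nodes$id,
                   chrom = if (!is.null(nodes$chrom)) nodes$chrom else NA,
                   start = if (!is.null(nodes$start)) nodes$start else NA,
                   end = if (!is.null(nodes$end)) nodes$end else NA,
                   combine_rule = if (!is.null(nodes$rule)) nodes$rule
                                  else "or")
  dots <- list(...)
  if (!is.null(vectors)) {
    vectors <- matrix(as.integer(vectors), nrow = nrow(nd), byrow = TRUE,
                      dimnames = list(nd$node_id, dots$sample_ids))
  }
  do.call(feature_graph, c(list(nd, edges, vectors = vectors), dots))
}

# random DAG feature_graph: gene roots with intervals, snp leaves, OR
# internals; vectors propagated from random leaves
random_or_graph <- function(n_nodes = 12, n_samples = 8, p_edge = 0.35,
                            n_genes = 2) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  kind <- rep("exon", n_nodes)
  gene_pos <- seq(n_nodes, n_nodes - n_genes + 1L)   # topologically last
  kind[gene_pos] <- "gene"
  kind[seq_len(max(1, floor(n_nodes / 3)))] <- "snp"
  starts <- ends <- rep(NA_real_, n_nodes)
  starts[gene_pos] <- sample(0:500, n_genes)
  ends[gene_pos] <- starts[gene_pos] + sample(100:400, n_genes)
  ec <- character(); ep <- character()
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      if (kind[j] == "snp") next           # snps stay leaves
      if (stats::runif(1) < p_edge) { ec <- c(ec, ids[i]); ep <- c(ep, ids[j]) }
    }
  }
  g <- mk_graph(list(id = ids, kind = kind, chrom = "chr1",
                     start = starts, end = ends,
                     rule = ifelse(kind == "snp", "leaf", "or")),
                data.frame(child = ec, parent = ep))
  leaves <- setdiff(ids, ep)
  V <- matrix(NA_integer_, n_nodes, n_samples, dimnames = list(ids, NULL))
  V[leaves, ] <- matrix(stats::rbinom(length(leaves) * n_samples, 1, 0.4),
                        length(leaves))
  g$vectors <- V
  propagate_or(g)
}

random_problem <- function(n_feat = 12, n_pairs = 20,
                           lam = sample(c(0.5, 1, 2), 1),
                           cmax = sample(2:8, 1)) {
  ids <- sprintf("f%02d", seq_len(n_feat))
  mi <- stats::setNames(round(stats::runif(n_feat), 3), ids)
  pairs <- NULL
  if (n_pairs > 0 && n_feat >= 2) {
    all_pairs <- t(utils::combn(ids, 2))
    take <- sample(nrow(all_pairs), min(n_pairs, nrow(all_pairs)))
    corr <- round(stats::runif(length(take), 0.3, 1), 3) *
      sample(c(-1, 1), length(take), replace = TRUE)
    pairs <- data.frame(i = all_pairs[take, 1], j = all_pairs[take, 2],
                        corr = corr, abs_corr = abs(corr))
  }
  selection_problem(mi, pairs, lam = lam, max_features = cmax)
}

# independent brute-force candidate-pair oracle: boolean-matrix
# reachability, explicit gene-interval overlap, all C(m,2) pairs tested
oracle_candidate_pairs <- function(graph, retained, pair_gate = 0.3) {
  ids <- graph$nodes$node_id
  n <- length(ids)
  R <- diag(n) > 0
  dimnames(R) <- list(ids, ids)
  for (k in seq_len(nrow(graph$edges)))
    R[graph$edges$child[k], graph$edges$parent[k]] <- TRUE
  repeat {                                  # transitive closure
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  genes <- ids[graph$nodes$kind == "gene"]
  gstart <- graph$nodes$start[match(genes, ids)]
  gend <- graph$nodes$end[match(genes, ids)]
  gchrom <- graph$nodes$chrom[match(genes, ids)]
  retained <- sort(retained)
  out <- NULL
  for (a in seq_along(retained)) for (b in seq_along(retained)) {
    if (a >= b) next
    i <- retained[a]; j <- retained[b]
    gi <- genes[R[i, genes]]; gj <- genes[R[j, genes]]
    shared <- length(intersect(gi, gj)) > 0
    overlap <- FALSE
    for (x in gi) for (y in gj) {
      xi <- match(x, genes); yi <- match(y, genes)
      if (gchrom[xi] == gchrom[yi] && gstart[xi] < gend[yi] &&
          gend[xi] > gstart[yi]) overlap <- TRUE
    }
    path <- R[i, j] || R[j, i]
    if (!(shared || overlap || path)) next
    vi <- graph$vectors[i, ]; vj <- graph$vectors[j, ]
    r <- if (stats::sd(vi) == 0 || stats::sd(vj) == 0) 0 else stats::cor(vi, vj)
    if (abs(r) >= pair_gate)
      out <- rbind(out, data.frame(i = i, j = j, corr = r))
  }
  out
}
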