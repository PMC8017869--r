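# Hierarchy assembly, GO grafting and node collapsing.

chain_fixture <- function(extra_gff = character(), vcf_rows = NULL) {
  if (is.null(vcf_rows))
    vcf_rows <- list(list(chrom = "chr1", pos = 100, id = "s1",
                          gts = c("0/1", "0/0")))
  ann <- read_gff3(tiny_gff(extra_gff))
  variants <- read_vcf(tiny_vcf(samples = c("S1", "S2"), rows = vcf_rows))
  list(ann = ann, variants = variants)
}

test_that("snp -> exon -> transcript -> gene chain is wired bottom-up", {
  fx <- chain_fixture()
  g <- build_genomic_hierarchy(fx$ann, fx$variants)
  expect_setequal(g$nodes$node_id, c("g1", "t1", "e1", "s1"))
  expect_setequal(paste(g$edges$child, g$edges$parent),
                  c("s1 e1", "e1 t1", "t1 g1"))
})

test_that("variant placement follows containment rules", {
  rows <- list(
    list(chrom = "chr1", pos = 100, id = "sExon", gts = c("0/1", "0/0")),
    list(chrom = "chr1", pos = 500, id = "sIntron", gts = c("0/0", "0/1")),
    list(chrom = "chr2", pos = 77, id = "sNowhere", gts = c("1/1", "0/0")))
  fx <- chain_fixture(vcf_rows = rows)
  g <- build_genomic_hierarchy(fx$ann, fx$variants)
  ed <- paste(g$edges$child, g$edges$parent)
  expect_true("sExon e1" %in% ed)
  expect_false(any(grepl("^sExon g1", ed)))   # ancestors get it via OR
  # inside the gene, outside every sub-element: direct edge to the gene
  expect_true("sIntron g1" %in% ed)
  expect_equal(sum(g$edges$child == "sIntron"), 1L)
  # overlapping nothing: isolated leaf
  expect_false("sNowhere" %in% c(g$edges$child, g$edges$parent))
  expect_true("sNowhere" %in% g$nodes$node_id)
})

test_that("a snp under two overlapping genes joins both subtrees", {
  extra <- c("chr1\tsim\tgene\t80\t400\t.\t+\t.\tID=g2",
             "chr1\tsim\tmRNA\t80\t400\t.\t+\t.\tID=t2;Parent=g2",
             "chr1\tsim\texon\t90\t120\t.\t+\t.\tID=e2;Parent=t2")
  fx <- chain_fixture(extra)
  g <- build_genomic_hierarchy(fx$ann, fx$variants)
  ed <- paste(g$edges$child, g$edges$parent)
  # e2 (inside e1) is the minimal container; g1's subtree is reached by
  # the direct gene fallback since none of its sub-elements is minimal
  expect_true("s1 e2" %in% ed)
  expect_false("s1 e1" %in% ed)
  expect_true("s1 g1" %in% ed)
  desc <- node_descendants(g, c("g1", "g2"))
  expect_true(all(c("s1") %in% desc$g1))
  expect_true(all(c("s1") %in% desc$g2))
})

test_that("peptide and biological regions attach to overlapping genes", {
  extra <- c("chr1\tsim\tbiological_region\t60\t120\t.\t+\t.\tID=br1",
             "chr1\tsim\tbiological_region\t5000\t5100\t.\t+\t.\tID=br2")
  fx <- chain_fixture(extra)
  g <- build_genomic_hierarchy(fx$ann, fx$variants)
  ed <- paste(g$edges$child, g$edges$parent)
  expect_true("br1 g1" %in% ed)
  expect_false("br2" %in% g$edges$child)      # no overlap: stays a root
  # the contained snp now also sits in br1 (a minimal container)
  expect_true("s1 br1" %in% ed)
})

test_that("GO grafting makes leaf terms threshold-parents of their genes", {
  fx <- chain_fixture()
  g <- build_genomic_hierarchy(fx$ann, fx$variants)
  go_edges <- data.frame(child = "GO:0000002", parent = "GO:0000001")
  assoc <- data.frame(gene_id = "g1", go_term = "GO:0000002")
  g2 <- graft_go(g, go_edges, assoc)
  ed <- paste(g2$edges$child, g2$edges$parent)
  expect_true("g1 GO:0000002" %in% ed)
  expect_true("GO:0000002 GO:0000001" %in% ed)
  rule <- setNames(g2$nodes$combine_rule, g2$nodes$node_id)
  expect_equal(rule[["GO:0000002"]], "threshold")  # GO leaf
  expect_equal(rule[["GO:0000001"]], "or")         # internal GO term
  expect_equal(g2$go_genes[["GO:0000002"]], "g1")
})

test_that("associations to absent genes are skipped with a warning", {
  fx <- chain_fixture()
  g <- build_genomic_hierarchy(fx$ann, fx$variants)
  assoc <- data.frame(gene_id = c("g1", "g9"),
                      go_term = c("GO:0000002", "GO:0000002"))
  expect_warning(
    g2 <- graft_go(g, data.frame(child = character(), parent = character()),
                   assoc),
    "g9")
  expect_false("g9" %in% g2$edges$child)
  expect_equal(g2$go_genes[["GO:0000002"]], "g1")
})

test_that("grafting adds no edge between two structural nodes", {
  set.seed(7)
  fx <- chain_fixture()
  g <- build_genomic_hierarchy(fx$ann, fx$variants)
  go_edges <- data.frame(child = c("GO:0000002", "GO:0000003"),
                         parent = c("GO:0000001", "GO:0000001"))
  assoc <- data.frame(gene_id = "g1",
                      go_term = c("GO:0000002", "GO:0000003"))
  g2 <- graft_go(g, go_edges, assoc)
  new_edges <- setdiff(paste(g2$edges$child, g2$edges$parent),
                       paste(g$edges$child, g$edges$parent))
  kinds <- setNames(g2$nodes$kind, g2$nodes$node_id)
  for (e in new_edges) {
    ends <- strsplit(e, " ")[[1]]
    expect_true("go_term" %in% kinds[ends])
  }
})

test_that("every construction step preserves acyclicity", {
  set.seed(11)
  for (trial in 1:20) {
    g <- random_or_graph(n_nodes = sample(5:14, 1))
    expect_silent(topo_order(g))   # topo_sort errors on cyclic graphs
    expect_true(igraph::is_dag(igraph::graph_from_data_frame(
      g$edges, vertices = data.frame(name = g$nodes$node_id))))
  }
})

# ---- collapsing ----

test_that("an out-degree-one chain with identical vectors collapses to one node", {
  g <- mk_graph(list(id = c("s1", "e1", "t1", "g1"),
                     kind = c("snp", "exon", "transcript", "gene")),
                data.frame(child = c("s1", "e1", "t1"),
                           parent = c("e1", "t1", "g1")),
                vectors = rep(c(1, 0, 1, 0), 4))
  cg <- collapse_redundant(g)
  expect_equal(cg$nodes$node_id, "g1")
  expect_equal(nrow(cg$edges), 0L)
  expect_setequal(names(cg$alias), c("s1", "e1", "t1"))
  expect_equal(unname(resolve_alias(cg, c("s1", "e1", "t1"))),
               rep("g1", 3))
})

test_that("differing parent-child vectors are never contracted", {
  g <- mk_graph(list(id = c("a", "b", "p"), kind = c("snp", "snp", "gene")),
                data.frame(child = c("a", "b"), parent = c("p", "p")),
                vectors = c(1, 0, 0, 0,
                            0, 1, 0, 0,
                            1, 1, 0, 0))
  cg <- collapse_redundant(g)
  expect_equal(nrow(cg$nodes), 3L)
  expect_equal(length(cg$alias), 0L)
})

test_that("in a diamond only the identical branch contracts", {
  # top t, branches a and b, bottom u; a == t, b differs
  g <- mk_graph(list(id = c("u", "a", "b", "t"),
                     kind = c("snp", "exon", "exon", "gene")),
                data.frame(child = c("u", "u", "a", "b"),
                           parent = c("a", "b", "t", "t")),
                vectors = c(1, 0, 0, 0,
                            1, 1, 0, 0,     # a == t
                            1, 0, 1, 0,     # b differs
                            1, 1, 0, 0))
  cg <- collapse_redundant(g)
  # hand enumeration: a merges into t; u->a becomes u->t; b->t kept
  expect_setequal(cg$nodes$node_id, c("u", "b", "t"))
  expect_setequal(paste(cg$edges$child, cg$edges$parent),
                  c("u t", "u b", "b t"))
  expect_equal(unname(cg$alias["a"]), "t")
})

test_that("collapse invariants hold on random propagated graphs", {
  set.seed(23)
  for (trial in 1:30) {
    g <- random_or_graph(n_nodes = sample(6:16, 1), n_samples = 5)
    cg <- collapse_redundant(g)
    key <- apply(cg$vectors, 1, paste, collapse = "")
    # no remaining edge joins identical vectors
    if (nrow(cg$edges))
      expect_false(any(key[cg$edges$child] == key[cg$edges$parent]))
    # the set of distinct vectors present is unchanged
    expect_setequal(unique(key),
                    unique(apply(g$vectors, 1, paste, collapse = "")))
    # acyclic afterwards
    expect_silent(topo_order(cg))
  }
})

test_that("collapsing requires fully assigned vectors", {
  g <- mk_graph(list(id = c("a", "b"), kind = c("snp", "gene")),
                data.frame(child = "a", parent = "b"))
  expect_error(collapse_redundant(g), "vector")
})
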