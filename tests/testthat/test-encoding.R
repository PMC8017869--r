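# Leaf encoding, OR-propagation, GO enrichment thresholds, saturation.

test_that("leaf encoding marks carriers of at least one alternate allele", {
  rows <- list(list(chrom = "chr1", pos = 100, id = "s1",
                    gts = c("0/1", "0/0", "1/1")))
  ann <- read_gff3(tiny_gff())
  variants <- read_vcf(tiny_vcf(samples = c("S1", "S2", "S3"), rows = rows))
  coh <- cohort(c("S1", "S2", "S3"), c(1, 0, 1))
  g <- encode_leaves(build_genomic_hierarchy(ann, variants), variants, coh)
  expect_equal(unname(g$vectors["s1", ]), c(1L, 0L, 1L))
})

test_that("an exon's contribution is the union of its variants' carriers", {
  rows <- list(
    list(chrom = "chr1", pos = 60, id = "sA", gts = c("0/1", "0/0", "0/0")),
    list(chrom = "chr1", pos = 70, id = "sB", gts = c("0/0", "0/1", "0/0")))
  ann <- read_gff3(tiny_gff())
  variants <- read_vcf(tiny_vcf(samples = c("S1", "S2", "S3"), rows = rows))
  coh <- cohort(c("S1", "S2", "S3"), c(1, 1, 0))
  g <- build_genomic_hierarchy(ann, variants)
  g <- propagate_or(encode_leaves(g, variants, coh))
  expect_equal(unname(g$vectors["e1", ]), c(1L, 1L, 0L))
})

test_that("sample-order mismatch between variants and cohort errors", {
  ann <- read_gff3(tiny_gff())
  variants <- read_vcf(tiny_vcf())
  coh <- cohort(c("S2", "S1"), c(0, 1))
  g <- build_genomic_hierarchy(ann, variants)
  expect_error(encode_leaves(g, variants, coh), "sample order")
})

test_that("OR-propagation combines children and direct contributions", {
  g <- mk_graph(list(id = c("a", "b", "p"), kind = c("snp", "snp", "exon"),
                     rule = c("leaf", "leaf", "or")),
                data.frame(child = c("a", "b"), parent = c("p", "p")))
  n <- 4L
  g$vectors <- matrix(NA_integer_, 3, n, dimnames = list(c("a", "b", "p"), NULL))
  g$vectors["a", ] <- c(1L, 0L, 0L, 0L)
  g$vectors["b", ] <- c(0L, 1L, 0L, 0L)
  g <- propagate_or(g)
  expect_equal(unname(g$vectors["p", ]), c(1L, 1L, 0L, 0L))
})

test_that("a chain propagates a leaf vector unchanged; childless or-node is zero", {
  g <- mk_graph(list(id = c("x", "y", "z", "lonely"),
                     kind = c("snp", "exon", "gene", "gene")),
                data.frame(child = c("x", "y"), parent = c("y", "z")))
  g$vectors <- matrix(NA_integer_, 4, 4,
                      dimnames = list(c("x", "y", "z", "lonely"), NULL))
  g$vectors["x", ] <- c(1L, 0L, 1L, 0L)
  g$vectors["lonely", ] <- c(0L, 0L, 0L, 0L)
  g <- propagate_or(g)
  expect_equal(unname(g$vectors["y", ]), c(1L, 0L, 1L, 0L))
  expect_equal(unname(g$vectors["z", ]), c(1L, 0L, 1L, 0L))
  expect_equal(unname(g$vectors["lonely", ]), rep(0L, 4))
})

test_that("GO threshold reproduces the mu + sigma rule exactly", {
  res <- go_leaf_threshold(c(1, 1, 1, 10))
  expect_equal(res$stats$mu, 3.25)
  expect_equal(res$stats$sigma, 3.8971143170299740, tolerance = 1e-12)
  expect_equal(res$stats$cutoff, 7.1471143170299740, tolerance = 1e-12)
  expect_equal(res$vector, c(0L, 0L, 0L, 1L))

  # equal counts: sigma = 0, cutoff = mu, everything saturates
  expect_equal(go_leaf_threshold(c(2, 2, 2, 2))$vector, rep(1L, 4))
  # degenerate all-zero counts saturate too (the MI filter removes them)
  expect_equal(go_leaf_threshold(c(0, 0, 0, 0))$vector, rep(1L, 4))
})

test_that("GO term counts pool distinct loci across a gene's subtree", {
  rows <- list(
    list(chrom = "chr1", pos = 60, id = "sA", gts = c("0/1", "0/0", "0/1")),
    list(chrom = "chr1", pos = 70, id = "sB", gts = c("0/1", "0/1", "0/0")),
    list(chrom = "chr1", pos = 500, id = "sIn", gts = c("0/0", "0/1", "0/0")))
  ann <- read_gff3(tiny_gff())
  variants <- read_vcf(tiny_vcf(samples = c("S1", "S2", "S3"), rows = rows))
  coh <- cohort(c("S1", "S2", "S3"), c(1, 1, 0))
  g <- build_genomic_hierarchy(ann, variants)
  g <- graft_go(g, data.frame(child = character(), parent = character()),
                data.frame(gene_id = "g1", go_term = "GO:0000002"))
  g <- assign_vectors(g, variants, coh)
  # counts: S1 carries sA+sB = 2, S2 sB+sIn = 2, S3 sA = 1
  expect_equal(g$go_stats[["GO:0000002"]]$counts, c(2L, 2L, 1L))
  mu <- mean(c(2, 2, 1)); sig <- sqrt(mean((c(2, 2, 1) - mu)^2))
  expect_equal(g$go_stats[["GO:0000002"]]$cutoff, mu + sig)
  expect_equal(unname(g$vectors["GO:0000002", ]),
               as.integer(c(2, 2, 1) >= mu + sig))
})

test_that("conservation: every or-node equals the OR of children and direct", {
  set.seed(31)
  for (trial in 1:100) {
    g <- random_or_graph(n_nodes = sample(5:18, 1),
                         n_samples = sample(3:10, 1))
    children <- split(g$edges$child,
                      factor(g$edges$parent, levels = g$nodes$node_id))
    for (nd in g$nodes$node_id) {
      ch <- children[[nd]]
      if (!length(ch)) next
      expected <- as.integer(colSums(g$vectors[ch, , drop = FALSE]) > 0)
      expect_identical(unname(g$vectors[nd, ]), expected)
    }
  }
})

test_that("support of a child is contained in the support of its or-parent", {
  set.seed(37)
  for (trial in 1:20) {
    g <- random_or_graph(n_nodes = sample(6:14, 1))
    for (k in seq_len(nrow(g$edges))) {
      child <- g$vectors[g$edges$child[k], ]
      parent <- g$vectors[g$edges$parent[k], ]
      expect_true(all(parent[child == 1L] == 1L))
    }
  }
})

test_that("saturated vectors are flagged, propagate upward, and have zero MI", {
  g <- mk_graph(list(id = c("sat", "mid", "top", "other"),
                     kind = c("snp", "exon", "gene", "snp")),
                data.frame(child = c("sat", "mid", "other"),
                           parent = c("mid", "top", "top")))
  g$vectors <- matrix(NA_integer_, 4, 4,
                      dimnames = list(c("sat", "mid", "top", "other"), NULL))
  g$vectors["sat", ] <- rep(1L, 4)
  g$vectors["other", ] <- c(1L, 0L, 0L, 0L)
  g <- propagate_or(g)
  expect_setequal(saturation_flags(g), c("sat", "mid", "top"))
  for (L in list(c(1, 1, 0, 0), c(1, 0, 1, 0), c("a", "b", "b", "a")))
    expect_identical(mutual_information(g$vectors["sat", ], L), 0)

  g$vectors["sat", ] <- c(1L, 1L, 0L, 1L)
  g <- propagate_or(g)
  expect_equal(length(saturation_flags(g)), 0L)
})
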