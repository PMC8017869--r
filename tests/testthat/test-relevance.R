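# Entropy, mutual information, the MI filter, correlations and the
# candidate pair set.

test_that("entropy closed forms", {
  expect_equal(entropy(c(1, 1, 1, 1, 0, 0, 0, 0)), 1.0)
  expect_equal(entropy(rep(1, 6)), 0)
  expect_equal(entropy(c("a", "b", "c", "d")), 2.0)
  expect_error(entropy(c()), "empty")
})

test_that("conditional entropy matches the hand-derived 4-sample case", {
  L <- c(1, 1, 0, 0); B <- c(1, 1, 1, 0)
  expect_equal(conditional_entropy(L, B), 0.6887218755408672,
               tolerance = 1e-12)
  expect_error(conditional_entropy(c(1, 0), c(1, 0, 0)), "length mismatch")
})

test_that("mutual information closed forms", {
  L <- c(1, 1, 0, 0, 1, 1, 0, 0)
  expect_equal(mutual_information(L, L), 1.0)                # identical
  expect_equal(mutual_information(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0)
  expect_equal(mutual_information(c(1, 1, 1, 0), c(1, 1, 0, 0)),
               0.3112781244591328, tolerance = 1e-12)
  # symmetry and the upper bound
  for (trial in 1:20) {
    B <- rbinom(10, 1, 0.5); L <- rbinom(10, 1, 0.5)
    mi <- mutual_information(B, L)
    expect_equal(mi, mutual_information(L, B), tolerance = 1e-12)
    expect_gte(mi, 0)
    expect_lte(mi, min(entropy(B), entropy(L)) + 1e-12)
  }
})

test_that("MI is invariant under jointly permuting samples", {
  set.seed(5)
  for (trial in 1:20) {
    n <- sample(6:20, 1)
    B <- rbinom(n, 1, 0.4); L <- rbinom(n, 1, 0.5)
    perm <- sample(n)
    expect_equal(mutual_information(B, L),
                 mutual_information(B[perm], L[perm]), tolerance = 1e-12)
  }
})

mi_fixture <- function() {
  # three nodes with MI 1.0, ~0.31, 0 against the balanced label
  g <- mk_graph(list(id = c("a", "b", "c"), kind = c("exon", "exon", "exon")),
                vectors = c(1, 1, 0, 0,
                            1, 1, 1, 0,
                            1, 0, 1, 0))
  list(g = g, coh = cohort(paste0("S", 1:4), c(1, 1, 0, 0)))
}

test_that("the MI filter retains exactly the nodes at or above t", {
  fx <- mi_fixture()
  flt <- mi_filter(fx$g, fx$coh, 0.1)
  expect_setequal(flt$retained, c("a", "b"))
  expect_equal(unname(flt$relevance["c"]), 0)

  expect_setequal(mi_filter(fx$g, fx$coh, 0)$retained, c("a", "b", "c"))
  expect_equal(length(mi_filter(fx$g, fx$coh, 1.01)$retained), 0L)
  expect_error(mi_filter(fx$g, fx$coh, -0.1), "non-negative")
})

test_that("retained sets are nested as t increases", {
  set.seed(13)
  g <- random_or_graph(n_nodes = 15, n_samples = 12)
  coh <- cohort(paste0("S", 1:12), rbinom(12, 1, 0.5))
  ts <- sort(runif(6, 0, 1))
  prev <- mi_filter(g, coh, 0)$retained
  for (t in ts) {
    cur <- mi_filter(g, coh, t)$retained
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("Pearson correlation on binary vectors", {
  x <- c(1, 1, 0, 0)
  expect_equal(pearson_binary(x, x), 1.0)
  expect_equal(pearson_binary(x, 1 - x), -1.0)
  expect_equal(pearson_binary(x, c(1, 0, 1, 0)), 0.0)
  expect_warning(r <- pearson_binary(x, c(1, 1, 1, 1)), "constant")
  expect_equal(r, 0)
})

test_that("candidate pairs follow the structural rules and the gate", {
  # gene g with exon e and transcript t; vectors strongly correlated
  g <- mk_graph(list(id = c("e", "t", "g"),
                     kind = c("exon", "transcript", "gene"),
                     chrom = "chr1", start = c(0, 0, 0),
                     end = c(50, 100, 100)),
                data.frame(child = c("e", "t"), parent = c("t", "g")),
                vectors = c(1, 1, 0, 0, 0,
                            1, 1, 1, 0, 0,
                            1, 1, 1, 0, 1))
  pairs <- build_candidate_pairs(g, c("e", "t", "g"), pair_gate = 0.3)
  expect_setequal(paste(pairs$i, pairs$j), c("e g", "e t", "g t"))
  expect_equal(pairs$abs_corr, abs(pairs$corr))

  # a weakly correlated pair on a directed path is gated out
  g2 <- mk_graph(list(id = c("x", "y"), kind = c("go_term", "go_term")),
                 data.frame(child = "x", parent = "y"),
                 vectors = c(1, 0, 0, 1, 1, 0, 1, 0,
                             1, 1, 0, 0, 1, 1, 0, 1))
  p2 <- build_candidate_pairs(g2, c("x", "y"), pair_gate = 0.3)
  expect_equal(nrow(p2), 0L)
  # lowering the gate below |corr| admits it
  r <- abs(pearson_binary(g2$vectors["x", ], g2$vectors["y", ]))
  p3 <- build_candidate_pairs(g2, c("x", "y"), pair_gate = r - 0.01)
  expect_equal(nrow(p3), 1L)
})

test_that("nodes without a shared gene, overlap or path never pair", {
  g <- mk_graph(list(id = c("a", "ga", "b", "gb"),
                     kind = c("exon", "gene", "exon", "gene"),
                     chrom = "chr1",
                     start = c(0, 0, 500, 500), end = c(50, 100, 550, 600)),
                data.frame(child = c("a", "b"), parent = c("ga", "gb")),
                vectors = c(1, 1, 0, 0,
                            1, 1, 0, 0,
                            1, 1, 0, 1,
                            1, 1, 0, 1))
  pairs <- build_candidate_pairs(g, c("a", "b", "ga", "gb"))
  # genes 0-100 and 500-600 do not overlap: only within-gene pairs remain
  expect_false(any((pairs$i %in% c("a", "ga")) & (pairs$j %in% c("b", "gb"))))
})

test_that("candidate pairs equal the brute-force all-pairs oracle", {
  set.seed(19)
  for (trial in 1:100) {
    g <- random_or_graph(n_nodes = sample(8:20, 1),
                         n_samples = sample(6:12, 1),
                         n_genes = sample(2:3, 1))
    retained <- sample(g$nodes$node_id,
                       min(nrow(g$nodes), sample(4:30, 1)))
    got <- suppressWarnings(build_candidate_pairs(g, retained))
    want <- suppressWarnings(oracle_candidate_pairs(g, retained))
    key <- function(df) if (is.null(df) || nrow(df) == 0) character() else
      sprintf("%s|%s|%.10f", df$i, df$j, df$corr)
    expect_setequal(key(got), key(want))
  }
})
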