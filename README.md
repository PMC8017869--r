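# hfselect

Hierarchical feature selection for supervised learning from genomic
variant calls.

## The problem

Learning a phenotype from whole-genome variant calls faces two coupled
problems: millions of raw SNP features invite overfitting, and a per-SNP
binary encoding is often the wrong level of description — the signal may
live at the level of an exon, a transcript, a gene, or a biological
process.  `hfselect` builds a **knowledge graph** of candidate
encodings and then selects among *all levels at once*.

Given a multi-sample VCF, a GFF3 annotation, and (optionally) a GO
ontology with gene associations, the package:

1. builds a DAG whose nodes are candidate features — SNP, exon, UTR,
   transcript, gene, peptide/biological region, GO term — with edges
   pointing from concrete to abstract;
2. assigns each node an *n*-sample binary vector: leaves mark variant
   carriers, internal nodes take the bitwise OR of their children, and
   GO leaf terms use an enrichment threshold (`count >= mu + sigma` of
   per-sample variant counts over the term's genes) to avoid saturation;
3. collapses edges joining bit-identical vectors (exact redundancy);
4. scores relevance as mutual information with the label, in bits, and
   selects a subset by solving, exactly,

   ```
   maximize   sum_i w_i I(B_i; L)  -  lambda * sum_(i,j) z_ij |Corr(B_i, B_j)|
   subject to z_ij >= w_i + w_j - 1,  sum_i w_i <= c,  w_i, z_ij in {0,1}
   ```

   where the penalized pairs are restricted to hierarchically related
   features (shared gene ancestor, overlapping gene ancestors, or a
   directed path) with |Pearson| >= 0.3;
5. evaluates selections with leakage-safe repeated stratified holdouts
   (logistic regression, random forest, or SVM; AUC reported on the
   untouched holdout).

A greedy two-step hierarchical selector and a plain MI-threshold filter
are included as comparison baselines, plus a synthetic fixture generator
with a planted signal so the whole pipeline is testable without any
data download.

## A worked example

```r
library(hfselect)

spec  <- sim_spec(seed = 1)          # 200 samples, 10 genes, planted exon
files <- generate_fixtures(spec)     # writes toy VCF/GFF3/OBO/GAF/labels
fx    <- load_fixtures(files)
print(fx$graph)
#> feature_graph: 272 nodes, 291 edges
#> bio_region       exon       gene    go_term        snp transcript        utr
#>          1         66         11          5        145         22         22

fit <- fit_selector(fx$graph, fx$variants, fx$cohort, selector = "ilp")
fit$selected
#> [1] "g1"       "g1.t1.e1" "rs00002"
fit$result$objective
#> [1] 0.9467632
round(fit$relevance[fit$selected], 4)
#>       g1 g1.t1.e1  rs00002
#>   0.0609   0.8155   0.0703
```

The selector found the planted exon `g1.t1.e1` (0.82 bits of mutual
information with the labels — close to the 1-bit ceiling, the gap being
the 5% label noise) plus two weak satellite features; the objective is
the summed MI minus the correlation penalty of the selected pair set.
An end-to-end run with a 30% holdout:

```r
res <- recovery_harness(spec)
str(res[c("recovered", "n_ilp", "n_shsel", "n_threshold", "auc")])
#> $ recovered  : logi TRUE
#> $ n_ilp      : int 4
#> $ n_shsel    : int 3
#> $ n_threshold: int 5
#> $ auc        : num 0.958
```

A thin command-line wrapper over the same functions lives at
`inst/cli/hfselect.R` (subcommands `simulate`, `build-graph`, `score`,
`select`, `baseline`, `evaluate`, `run-all`).

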