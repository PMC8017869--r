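---
title: "Hierarchical feature selection from variant calls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical feature selection from variant calls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfselect)
```

## The problem

Supervised learning from variant calls suffers doubly: the feature space is
enormous (millions of loci), and a raw per-SNP encoding is often not the
level of organization at which the signal lives.  A damaging event may be
best described as "this exon is perturbed", "this transcript", "this gene",
or "this biological process".  `hfselect` addresses both issues at once by
building a *knowledge graph* of candidate encodings — one binary feature
per SNP, exon, UTR, transcript, gene, peptide/biological region and Gene
Ontology (GO) term — and then selecting a maximally informative,
minimally redundant subset of those features by solving an integer linear
program (ILP) exactly.

## The knowledge graph

Nodes are candidate feature encodings; a directed edge points from child
to parent, the parent being the higher abstraction.  The genomic half of
the graph comes from the annotation: exons and UTRs point at their
transcripts, transcripts at their genes.  Peptide and biological-region
records attach to every gene they overlap.  Each variant locus becomes a
leaf that attaches to its *smallest* containing structural element(s)
among exons, UTRs, biological regions and peptides; a variant inside a
gene but outside all of its sub-elements attaches to the gene directly,
and a variant overlapping nothing stays an isolated leaf.  Attaching only
to minimal containers avoids counting one variant several times along a
chain — ancestors receive the signal through propagation instead.  A
variant contained in two overlapping genes joins both subtrees, since
interval containment is the only attachment criterion.

The three GO namespaces are grafted on top: term-to-term `is_a` edges
keep their child-to-parent orientation, and each GO *leaf* term becomes a
parent of the gene nodes it is associated with.  The direction is chosen
so that information always flows bottom-up — from variants through genes
into the ontology — and every node's vector derives from variant data.
Associations to terms that are not leaves are ignored; those terms
receive signal through the ontology edges.  The graph need not be
connected, and isolated nodes are legitimate features.

## Binary encodings

Every node carries an *n*-sample binary vector.  A sample is a *carrier*
of a variant when its genotype contains at least one non-reference allele
(het or hom-alt); missing genotypes count as absent.  Dosage-aware,
real-valued encodings are out of scope.  Leaf vectors set bit *i* when
sample *i* carries any variant mapped to the node.  Internal vectors are
computed bottom-up as the bitwise OR of the children (plus any variants
mapped directly to the node itself).

GO leaf terms would saturate under OR — a term annotated to many genes
quickly becomes all-ones, and an all-ones vector has exactly zero mutual
information with any label while also saturating every OR-ancestor.  GO
leaves therefore use an enrichment threshold instead: let `counts[i]` be
the number of distinct variant loci in sample *i* that fall anywhere in
the subtrees of the term's associated genes, and let `mu` and `sigma` be
the mean and *population* (divide-by-*n*) standard deviation of those
counts.  Bit *i* is set when `counts[i] >= mu + sigma` — the sample shows
an unusual accumulation of variants in that functional neighbourhood.
The population form of `sigma` is a pinned numerical choice so that tests
can assert the rule exactly.  Two degenerate cases are kept literal
rather than special-cased: equal counts give `sigma = 0` and a saturated
vector, and all-zero counts likewise saturate; both are uninformative and
are removed by the relevance filter downstream, never by a hidden rule in
the encoder.

Edges whose endpoints carry bit-identical vectors are redundant; they are
contracted, the parent (more abstract, more interpretable label)
surviving, iterating to a fixpoint.  Contraction works on whole connected
components of identical-vector edges with the survivor chosen as the
component member latest in topological order, which makes the result
deterministic.  The alias map records every merged node, so downstream
consumers can ask for a node "or whatever it collapsed into".  Collapsing
never changes the set of distinct vectors present in the graph.  A
component contraction that would close a cycle through an intervening
node with a different vector (possible only via threshold nodes, which
are not OR-monotone) falls back to contracting provably safe single
edges, warning if an identical-vector edge must be kept.

## Relevance, redundancy, and the selection program

Relevance is the plug-in mutual information, in bits (log base 2 — the
base is pinned here; it only rescales thresholds), between a node's
vector and the label vector:
`I(B; L) = H(L) - H(L | B)` with `0 log 0 = 0`.  Labels may be
multi-class; features stay binary.  A pre-filter discards every node with
`I < t`.  The threshold `t` (default 0.05 bits) plays the role that
variant-level quality filters play in sequence analysis: it removes
clearly irrelevant features before the expensive pairwise stage.

Redundancy is penalized only over a structured candidate set of pairs:
two retained features form a candidate when they share a common gene
ancestor, when they have gene ancestors whose genomic intervals overlap,
or when one lies on a directed path to the other (this last rule is what
ties the genomic and GO halves together).  Candidate pairs are kept when
`|Pearson correlation| >= 0.3` (the gate is exposed as `pair_gate`).
Correlation of a constant vector is undefined and reported as 0 with a
warning — constant vectors carry zero MI and are filtered anyway.  Pair
construction runs on the collapsed graph, after all encoding, because
collapsing precedes scoring in the pipeline order.

Selection maximizes, over binary indicators `w_i`,

```
sum_i w_i * I(B_i; L)  -  lambda * sum_(i,j) z_ij * |Corr(B_i, B_j)|
s.t.  z_ij >= w_i + w_j - 1,   sum_i w_i <= c,   w_i, z_ij in {0, 1}
```

With non-negative penalties the optimum satisfies `z_ij = w_i * w_j`, so
the program is equivalent to a combinatorial objective over subsets.
`lambda` (default 1) trades relevance against redundancy; `c` caps the
subset size and, when left unbounded, lets the optimizer choose the
count.  No MIP solver package is available as a dependency, and the
program's structure is simple enough to solve exactly by specialized
branch and bound: features are explored in decreasing-MI order with an
admissible bound that ignores penalties among undecided features, and
when `c` is slack the pair graph decomposes into connected components
that are solved independently (isolated features are selected exactly
when their MI is positive).  The solver is validated in the test suite
against an independent subset-enumeration oracle on hundreds of random
instances, with exact objective equality required.

Degenerate optima are resolved deterministically: at an objective tie
(within 1e-9) the smaller subset wins — parsimony is the stated goal —
and among equal sizes the lexicographically smallest sorted id tuple.
The same rule lives in the solver and the oracle.  Alternate optima can
be enumerated by re-solving under no-good cuts until the objective
drops.

## Baselines

Two baselines are built in for comparisons.  The *threshold* baseline
selects every feature passing the MI filter.  The *greedy hierarchical*
baseline is a two-step selector: sweeping leaves-to-root, drop nodes that
are irrelevant (zero relevance) or redundant with a direct ancestor
(`|corr| >= 0.99` by default); then, per root-to-leaf path, drop
surviving nodes strictly below the path's mean relevance.  It is
implemented from its published summary description, with two pinned
interpretations: redundancy is checked against *direct* ancestors only,
and a node is removed when it falls below the mean on *any* of its
paths.  Relevance is MI and similarity is |Pearson| for symmetry with
the optimal selector, so comparisons isolate the selection strategy
rather than the scoring function.

## Leakage-safe evaluation

Model assessment uses repeated stratified splits: per permutation, a
30% holdout is drawn preserving class proportions (largest-remainder
allocation), and *everything* sample-dependent — leaf vectors, GO
`mu + sigma` cutoffs, collapsing, MI, correlations, selection — is
recomputed on the training side only.  Holdout samples are encoded with
the training-side GO cutoffs applied as fixed numbers.  Re-estimating
cutoffs on all samples would be label-free but still cohort-dependent,
so the stricter option is taken.  Classifiers are logistic regression
(no regularization; one-vs-rest macro-averaged AUC via multinomial
regression for multi-class labels), random forest with 100 trees, and an
RBF-kernel SVM, all otherwise at library defaults.  A permutation that
selects zero features records AUC 0.5 with a warning.  The test suite
asserts the leakage contract directly: physically deleting the holdout
samples from every input file leaves the training-side selection
identical.

## The synthetic generator

Because the motivating experiments require controlled-access cohorts,
the package's entire test surface runs on generated fixtures.  The
generator tiles genes (default 10, each 2 transcripts x 3 exons x 2
variants, one 5' UTR per transcript) along one synthetic chromosome with
fixed gaps, adds one gene overlapping the first (to exercise the
overlapping-genes pair rule), a biological region, one intronic variant
per gene, two intergenic variants, and a small GO ontology (4 leaf
terms x 3 genes under one root).  Background carriers are i.i.d. at 10%
per locus.  One exon is *planted*: its first variant's carrier pattern
is forced to a Bernoulli(1/2) vector `v` and its other variants are
masked to subsets of `v`, so the exon's propagated vector equals `v`
exactly; labels are `v` passed through a binary symmetric channel with
flip probability 0.05.  The defaults (n = 200 samples and the values
above) are the package's reference study conditions; the channel noise
model is chosen because MI under it has a closed form, which gives the
tests an independent oracle.

What the generator does *not* emulate: linkage disequilibrium and
population structure (variants are independent), realistic GO topology
(two levels, uniform fan-out), indels/multi-allelic records, and
phased genotypes.  Passing tests therefore demonstrate algorithmic
correctness and the pipeline's statistical contracts, not performance on
real cohorts.

## Problem sizes and known limitations

The packaged simulations are deliberately small — a few hundred nodes
and 200 samples, ten seeds per study — so the whole suite, including
solver-versus-oracle validation at up to 15 features and 40 pairs,
completes in minutes on one core.  The exact solver is intended for the
post-filter problem sizes this package produces (up to a few hundred
correlated features per component); it is not a general-purpose MIP
solver.

One behavioral caveat surfaced by the simulation study itself: the
generator's exact-realization contract forces the planted exon's
secondary variants to be subsets of the planted vector, making them
genuine weak sub-signals (they pass the MI filter on merit) whose
correlation with the exon sits below the 0.3 pair gate.  The optimal
selector rightly keeps them — they strictly improve the objective —
while the greedy baseline's path-mean pruning discards them, so at this
toy scale the optimal selector can select one more feature than the
greedy baseline in a minority of runs, with indistinguishable holdout
AUC.  In redundancy-dominated graphs (the regime the method targets) the
penalty term drives the expected parsimony advantage; at toy scale the
count comparison is sensitive to single borderline features.

## A worked example

```{r example, eval = FALSE}
spec <- sim_spec(seed = 1)
files <- generate_fixtures(spec)
fx <- load_fixtures(files)

fit <- fit_selector(fx$graph, fx$variants, fx$cohort, selector = "ilp")
fit$selected
fit$result$objective

plan <- eval_plan(permutations = 10, seed = 1)
evaluate_selection(fx$graph, fx$variants, fx$cohort, "ilp", plan)
```

The same steps are available from the shell through the thin CLI at
`inst/cli/hfselect.R` (subcommands `simulate`, `build-graph`, `score`,
`select`, `baseline`, `evaluate`, `run-all`).
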