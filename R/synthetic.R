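#' Specification for a synthetic toy cohort
#'
#' Describes a small simulated study: a nested annotation (genes contain
#' transcripts contain exons, with UTRs, one biological region, and an
#' optional overlapping gene pair), variant loci inside exons plus
#' intronic and intergenic loci, i.i.d. background carriers, one planted
#' informative node whose propagated vector defines the labels through a
#' binary symmetric channel, and a tiny GO ontology over the genes.
#'
#' The defaults are the package's reference study conditions: 200
#' samples, 10 genes, a planted exon, 5% label noise, 10% background
#' carrier probability.
#'
#' @param n_samples number of samples.
#' @param n_genes number of non-overlapping genes.
#' @param transcripts_per_gene,exons_per_transcript,snps_per_exon
#'   annotation shape parameters.
#' @param n_go_terms number of GO leaf terms.
#' @param genes_per_go_term genes associated with each GO leaf term.
#' @param planted_exon index (in generation order) of the exon whose
#'   vector is planted as the label signal.
#' @param label_noise per-sample label flip probability (binary
#'   symmetric channel), in `[0, 0.5)`.
#' @param background_maf per-variant background carrier probability.
#' @param overlapping_pair add one extra gene overlapping the first gene
#'   (exercises the overlapping-genes pair rule).
#' @param seed integer seed; identical specs generate byte-identical
#'   files.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_samples = 200L, n_genes = 10L,
                     transcripts_per_gene = 2L, exons_per_transcript = 3L,
                     snps_per_exon = 2L, n_go_terms = 4L,
                     genes_per_go_term = 3L, planted_exon = 1L,
                     label_noise = 0.05, background_maf = 0.1,
                     overlapping_pair = TRUE, seed = 1L) {
  stopifnot(n_samples >= 1, n_genes >= 1, transcripts_per_gene >= 1,
            exons_per_transcript >= 1, snps_per_exon >= 1,
            label_noise >= 0, label_noise < 0.5,
            background_maf > 0, background_maf < 1)
  structure(as.list(environment()), class = "sim_spec")
}

#' Generate toy VCF/GFF3/OBO/GAF/label fixtures with planted signal
#'
#' Lays the genes out on one synthetic chromosome with fixed gaps,
#' draws background carriers i.i.d. at `background_maf`, forces the
#' planted exon's propagated vector to a Bernoulli(1/2) pattern `v`
#' (its first variant carries `v` exactly; its remaining variants are
#' subsets of `v`), and emits labels equal to `v` with each bit flipped
#' with probability `label_noise`.  One intronic variant per gene and
#' two intergenic variants exercise the direct-to-gene and isolated-node
#' attachment rules.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @return list with file paths (`vcf`, `gff3`, `obo`, `gaf`, `labels`)
#'   and `truth` (`planted_node`, `planted_vector`, `labels`).
#' @export
generate_fixtures <- function(spec, dir = tempfile("simfix")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed, generate_fixtures_impl(spec, dir))
}

generate_fixtures_impl <- function(spec, dir) {
  exon_len <- 100L; exon_gap <- 50L; tx_gap <- 100L; gene_gap <- 500L
  chrom <- "chrS"
  genes <- list(); transcripts <- list(); exons <- list(); utrs <- list()
  snp_rows <- list()          # chrom/pos0/id/container id
  cursor <- 1000L
  exon_counter <- 0L
  n_extra <- if (spec$overlapping_pair) 1L else 0L
  for (g in seq_len(spec$n_genes + n_extra)) {
    overlap_gene <- g > spec$n_genes
    gid <- if (overlap_gene) "gOverlap" else paste0("g", g)
    g_start <- if (overlap_gene) genes[[1]]$start + 200L else cursor
    pos <- g_start + 70L        # leading room for the 5' UTR
    tx_list <- character()
    for (t in seq_len(spec$transcripts_per_gene)) {
      tid <- paste0(gid, ".t", t)
      t_start <- pos - 50L
      utr <- list(id = paste0(tid, ".utr"), start = t_start,
                  end = t_start + 30L, parent = tid)
      ex_ids <- character()
      for (e in seq_len(spec$exons_per_transcript)) {
        exon_counter <- exon_counter + 1L
        eid <- paste0(tid, ".e", e)
        ex <- list(id = eid, start = pos, end = pos + exon_len, parent = tid,
                   index = exon_counter)
        exons[[eid]] <- ex
        ex_ids <- c(ex_ids, eid)
        step <- exon_len %/% (spec$snps_per_exon + 1L)
        for (s in seq_len(spec$snps_per_exon))
          snp_rows[[length(snp_rows) + 1L]] <-
            list(pos = pos + s * step, exon = eid)
        pos <- pos + exon_len + exon_gap
      }
      t_end <- pos - exon_gap
      transcripts[[tid]] <- list(id = tid, start = t_start, end = t_end,
                                 parent = gid)
      utrs[[utr$id]] <- utr
      tx_list <- c(tx_list, tid)
      # one intronic locus per first transcript (inside gene, outside exons)
      if (t == 1L && spec$exons_per_transcript > 1L)
        snp_rows[[length(snp_rows) + 1L]] <-
          list(pos = exons[[ex_ids[1]]]$end + 10L, exon = NA_character_)
      pos <- pos + tx_gap
    }
    g_end <- pos - tx_gap + 10L
    genes[[gid]] <- list(id = gid, start = t_start_of(transcripts, tx_list),
                         end = g_end)
    if (!overlap_gene) cursor <- g_end + gene_gap
  }
  # intergenic loci: isolated leaves
  iso_pos <- c(10L, 200L)
  for (p in iso_pos)
    snp_rows[[length(snp_rows) + 1L]] <- list(pos = p, exon = NA_character_)

  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  nv <- length(snp_rows)
  presence <- matrix(stats::rbinom(nv * n, 1L, spec$background_maf), nv, n)

  planted_id <- names(exons)[vapply(exons, `[[`, integer(1), "index") ==
                               spec$planted_exon]
  if (!length(planted_id)) stop("planted exon index matches no exon")
  v <- stats::rbinom(n, 1L, 0.5)
  in_planted <- which(vapply(snp_rows, function(r)
    identical(r$exon, planted_id), logical(1)))
  presence[in_planted[1L], ] <- v
  for (s in in_planted[-1L])
    presence[s, ] <- as.integer(presence[s, ] & v)
  flips <- stats::rbinom(n, 1L, spec$label_noise)
  labels <- as.integer(xor(v, flips))

  # ---- GFF3 ----
  gff_path <- file.path(dir, "annotation.gff3")
  lines <- c("##gff-version 3")
  add <- function(type, start0, end0, attrs)
    sprintf("%s\tsim\t%s\t%d\t%d\t.\t+\t.\t%s",
            chrom, type, start0 + 1L, end0, attrs)
  for (g in genes)
    lines <- c(lines, add("gene", g$start, g$end, paste0("ID=", g$id)))
  for (t in transcripts)
    lines <- c(lines, add("mRNA", t$start, t$end,
                          paste0("ID=", t$id, ";Parent=", t$parent)))
  for (e in exons)
    lines <- c(lines, add("exon", e$start, e$end,
                          paste0("ID=", e$id, ";Parent=", e$parent)))
  for (u in utrs)
    lines <- c(lines, add("five_prime_UTR", u$start, u$end,
                          paste0("ID=", u$id, ";Parent=", u$parent)))
  if (length(genes) >= 2L) {
    g2 <- genes[[2L]]
    lines <- c(lines, add("biological_region", g2$start + 5L, g2$start + 60L,
                          "ID=bio1"))
  }
  writeLines(lines, gff_path)

  # ---- VCF ----
  vcf_path <- file.path(dir, "calls.vcf")
  ord <- order(vapply(snp_rows, `[[`, integer(1), "pos"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(ord), function(k) {
    i <- ord[k]
    gts <- ifelse(presence[i, ] == 1L, "0/1", "0/0")
    paste(c(chrom, snp_rows[[i]]$pos + 1L, sprintf("rs%05d", i), "A", "T",
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), vcf_path)

  # ---- GO: OBO + associations ----
  obo_path <- file.path(dir, "go.obo")
  gaf_path <- file.path(dir, "assoc.tsv")
  leaf_terms <- sprintf("GO:%07d", 1L + seq_len(spec$n_go_terms))
  root <- "GO:0000001"
  obo <- c("format-version: 1.2", "",
           "[Term]", paste0("id: ", root), "name: sim root",
           "namespace: biological_process", "")
  for (tm in leaf_terms)
    obo <- c(obo, "[Term]", paste0("id: ", tm),
             paste0("name: sim term ", tm),
             "namespace: biological_process",
             paste0("is_a: ", root, " ! sim root"), "")
  writeLines(obo, obo_path)
  gene_ids <- paste0("g", seq_len(spec$n_genes))
  assoc <- character()
  for (k in seq_along(leaf_terms)) {
    gs <- gene_ids[((k - 1L + seq_len(spec$genes_per_go_term) - 1L) %%
                      spec$n_genes) + 1L]
    assoc <- c(assoc, paste(gs, leaf_terms[k], sep = "\t"))
  }
  writeLines(assoc, gaf_path)

  # ---- labels ----
  lab_path <- file.path(dir, "labels.tsv")
  writeLines(paste(samples, labels, sep = "\t"), lab_path)

  list(vcf = vcf_path, gff3 = gff_path, obo = obo_path, gaf = gaf_path,
       labels = lab_path,
       truth = list(planted_node = planted_id, planted_vector = v,
                    labels = labels, sample_ids = samples))
}

t_start_of <- function(transcripts, ids) {
  min(vapply(transcripts[ids], `[[`, integer(1), "start"))
}

#' Build the structural knowledge graph from generated fixtures
#'
#' Convenience loader: parses the fixture files and assembles the
#' grafted (but not yet encoded) graph plus variant set and cohort.
#'
#' @param files the list returned by [generate_fixtures()].
#' @return list with `graph`, `variants`, `cohort`.
#' @export
load_fixtures <- function(files) {
  coh <- read_labels(files$labels)
  variants <- read_vcf(files$vcf, coh$sample_ids)
  ann <- read_gff3(files$gff3)
  go <- read_go(files$obo, files$gaf)
  graph <- build_genomic_hierarchy(ann, variants)
  graph <- graft_go(graph, go$edges, go$associations, go_terms = go$terms)
  list(graph = graph, variants = variants, cohort = coh)
}

#' End-to-end planted-signal recovery run
#'
#' Generates fixtures for the given simulation settings, runs the full
#' pipeline with a
#' stratified 70/30 train/holdout split (selection strictly on the
#' training side), and reports whether the planted node -- or the node
#' it collapsed into -- was selected, the selected-set sizes of the
#' optimal selector and both baselines, and the holdout AUC of a
#' logistic-regression classifier on the optimal selection.
#'
#' @param spec a [sim_spec()].
#' @param mi_threshold MI pre-filter in bits (default 0.05).
#' @param pair_gate candidate-pair correlation gate (default 0.3).
#' @param lam redundancy weight (default 1).
#' @param holdout_fraction holdout size (default 0.3).
#' @return list with `recovered`, `selected` ids, `n_ilp`, `n_shsel`,
#'   `n_threshold`, `auc`, `planted_alias`.
#' @export
recovery_harness <- function(spec, mi_threshold = 0.05, pair_gate = 0.3,
                             lam = 1, holdout_fraction = 0.3) {
  files <- generate_fixtures(spec)
  on.exit(unlink(dirname(files$vcf), recursive = TRUE), add = TRUE)
  fx <- load_fixtures(files)
  plan <- eval_plan(holdout_fraction = holdout_fraction, permutations = 1L,
                    seed = spec$seed)
  sp <- split_permutations(fx$cohort, plan)[[1L]]
  tr_var <- subset_samples(fx$variants, sp$train_ids)
  tr_coh <- subset_samples(fx$cohort, sp$train_ids)
  fit <- fit_selector(fx$graph, tr_var, tr_coh, selector = "ilp",
                      mi_threshold = mi_threshold, pair_gate = pair_gate,
                      lam = lam)
  alias <- resolve_alias(fit$collapsed, files$truth$planted_node)
  recovered <- alias %in% fit$selected
  sel_shsel <- shsel_select(fit$collapsed, fit$relevance,
                            nodes = fit$retained)
  n_threshold <- length(fit$retained)
  ho_var <- subset_samples(fx$variants, sp$holdout_ids)
  ho_coh <- subset_samples(fx$cohort, sp$holdout_ids)
  holdout_auc <- function(selected) {
    if (!length(selected)) return(0.5)
    f <- fit; f$selected <- selected
    Xtr <- feature_matrix(f, fx$graph, tr_var, tr_coh)
    Xho <- feature_matrix(f, fx$graph, ho_var, ho_coh)
    classifier_auc(Xtr, tr_coh$labels, Xho, ho_coh$labels,
                   "logistic_regression", seed = spec$seed)
  }
  list(recovered = recovered, selected = fit$selected,
       n_ilp = length(fit$selected), n_shsel = length(sel_shsel),
       n_threshold = n_threshold, auc = holdout_auc(fit$selected),
       auc_shsel = holdout_auc(sel_shsel), planted_alias = alias)
}
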