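#' Read a multi-sample VCF into a variant set
#'
#' Parses variant calls and reduces each genotype to a binary presence
#' call: a sample "carries" a variant when its genotype contains at least
#' one non-reference allele (het or hom-alt); missing genotypes (`./.`)
#' count as absent.  Positions are converted to 0-based coordinates at
#' this boundary.
#'
#' @param path path to a VCF (v4.x) file, plain text.
#' @param cohort_sample_order optional character vector; genotype columns
#'   are reordered to this sample order.  Every requested sample must be
#'   present in the VCF header.
#' @return an object of class `variant_set`: a list with `loci`
#'   (data.frame `chrom`, `pos` 0-based, `id`), `presence` (integer
#'   matrix, variants x samples) and `sample_ids`.
#' @export
read_vcf <- function(path, cohort_sample_order = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  if (is.null(cohort_sample_order)) cohort_sample_order <- samples
  missing <- setdiff(cohort_sample_order, samples)
  if (length(missing))
    stop("unknown sample in VCF header: ", paste(missing, collapse = ", "))
  nvar <- nrow(vcf@fix)
  if (is.null(nvar) || nvar == 0L) {
    return(structure(list(
      loci = data.frame(chrom = character(), pos = integer(),
                        id = character()),
      presence = matrix(0L, 0L, length(cohort_sample_order),
                        dimnames = list(NULL, cohort_sample_order)),
      sample_ids = cohort_sample_order), class = "variant_set"))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nvar, dimnames = list(NULL, samples))
  gt <- gt[, cohort_sample_order, drop = FALSE]
  presence <- matrix(vapply(gt, gt_has_alt, logical(1)), nrow = nvar)
  storage.mode(presence) <- "integer"
  colnames(presence) <- cohort_sample_order
  structure(list(
    loci = data.frame(chrom = as.character(vcf@fix[, "CHROM"]),
                      pos = as.integer(vcf@fix[, "POS"]) - 1L,
                      id = as.character(vcf@fix[, "ID"])),
    presence = presence,
    sample_ids = cohort_sample_order), class = "variant_set")
}

# one genotype string -> TRUE when any called allele is non-reference
gt_has_alt <- function(g) {
  if (is.na(g) || g == "." ) return(FALSE)
  alleles <- strsplit(g, "[/|]")[[1]]
  alleles <- suppressWarnings(as.integer(alleles))
  any(!is.na(alleles) & alleles > 0L)
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d loci x %d samples\n",
              nrow(x$loci), length(x$sample_ids)))
  invisible(x)
}

# GFF3 type strings recognized for each internal node kind; the
# biological_region / peptide mapping is configurable because annotation
# dialects differ in how they spell these concepts.
default_gff_aliases <- function() {
  list(gene = c("gene", "protein_coding_gene", "ncRNA_gene"),
       transcript = c("mRNA", "transcript", "ncRNA", "lnc_RNA"),
       exon = "exon",
       utr = c("five_prime_UTR", "three_prime_UTR"),
       bio_region = "biological_region",
       peptide = c("polypeptide", "peptide", "mature_protein_region"))
}

#' Read genome annotation from GFF3
#'
#' Keeps only the record types that become knowledge-graph nodes (genes,
#' transcripts, exons, UTRs, biological regions, peptides); everything
#' else (chromosome lines, CDS, ...) is skipped.  Parent links are taken
#' from the `Parent=` attribute.  Coordinates are converted from 1-based
#' inclusive to 0-based half-open here.  Strand is parsed but not used by
#' downstream overlap tests.
#'
#' @param path path to a GFF3 file.
#' @param type_aliases named list mapping internal kinds (`gene`,
#'   `transcript`, `exon`, `utr`, `bio_region`, `peptide`) to the GFF3
#'   `type` strings that denote them; see `default_gff_aliases()`.
#' @return data.frame of annotation records with columns `id`, `kind`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `parent_id`.
#' @export
read_gff3 <- function(path, type_aliases = default_gff_aliases()) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  kind_of <- rep(NA_character_, nrow(gff))
  for (k in names(type_aliases))
    kind_of[as.character(gff$type) %in% type_aliases[[k]]] <- k
  keep <- !is.na(kind_of)
  gff <- gff[keep, , drop = FALSE]
  kind_of <- kind_of[keep]
  ids <- if (!is.null(gff$ID)) as.character(gff$ID) else rep(NA_character_, nrow(gff))
  # records without an ID attribute still become nodes; synthesize one
  need <- is.na(ids) | ids == ""
  ids[need] <- sprintf("%s:%s:%d-%d", kind_of[need], gff$seqid[need],
                       gff$start[need], gff$end[need])
  parent <- rep(NA_character_, nrow(gff))
  if (!is.null(gff$Parent)) {
    p <- gff$Parent                        # CharacterList from readGFF
    parent <- vapply(seq_along(p), function(i) {
      v <- as.character(p[[i]])
      if (length(v)) v[[1]] else NA_character_
    }, character(1))
  }
  rec <- data.frame(id = ids, kind = kind_of,
                    chrom = as.character(gff$seqid),
                    start = as.integer(gff$start) - 1L,
                    end = as.integer(gff$end),
                    strand = as.character(gff$strand),
                    parent_id = parent,
                    stringsAsFactors = FALSE)
  if (any(rec$start >= rec$end)) stop("annotation record with start > end")
  orphan <- !is.na(rec$parent_id) & !(rec$parent_id %in% rec$id)
  if (any(orphan)) {
    warning("annotation parent id(s) never defined, kept as orphans: ",
            paste(unique(rec$parent_id[orphan]), collapse = ", "))
    rec$parent_id[orphan] <- NA_character_
  }
  rec
}

#' Read a Gene Ontology DAG (OBO) and gene associations (GAF or TSV)
#'
#' The OBO parser keeps `[Term]` stanzas with their `is_a` relations;
#' obsolete terms are dropped.  Edges are oriented child term -> parent
#' term, and the three namespace roots stay separate.  Associations come
#' either from a GAF 2.x file (columns DB Object Symbol and GO ID used;
#' rows with a `NOT` qualifier dropped) or a two-column TSV
#' (gene_id, go_term).
#'
#' @param obo_path path to an OBO ontology file.
#' @param gaf_path path to a GAF 2.x file or a two-column TSV.
#' @return list with `terms` (data.frame `term`, `name`, `namespace`),
#'   `edges` (data.frame `child`, `parent`) and `associations`
#'   (data.frame `gene_id`, `go_term`).
#' @export
read_go <- function(obo_path, gaf_path) {
  onto <- parse_obo(obo_path)
  assoc <- parse_associations(gaf_path)
  bad <- !grepl("^GO:[0-9]{7}$", assoc$go_term)
  if (any(bad)) {
    warning(sum(bad), " association(s) with malformed GO ids dropped")
    assoc <- assoc[!bad, , drop = FALSE]
  }
  c(onto, list(associations = assoc))
}

parse_obo <- function(path) {
  lines <- readLines(path)
  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) stop("no stanzas found in OBO file")
  terms <- list(); edges_child <- character(); edges_parent <- character()
  bounds <- c(stanza_starts, length(lines) + 1L)
  for (s in seq_along(stanza_starts)) {
    if (lines[stanza_starts[s]] != "[Term]") next
    block <- lines[(stanza_starts[s] + 1L):(bounds[s + 1L] - 1L)]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": "), "", grep(paste0("^", key, ": "), block, value = TRUE))
      if (length(v)) v[[1]] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) next
    isa <- grep("^is_a: ", block, value = TRUE)
    isa <- sub("^is_a: ", "", isa)
    isa <- sub(" !.*$", "", isa)
    isa <- trimws(isa)
    terms[[id]] <- data.frame(term = id, name = get1("name"),
                              namespace = get1("namespace"))
    if (length(isa)) {
      edges_child <- c(edges_child, rep(id, length(isa)))
      edges_parent <- c(edges_parent, isa)
    }
  }
  term_df <- do.call(rbind, terms)
  rownames(term_df) <- NULL
  keep <- edges_parent %in% term_df$term  # drop links to obsolete/absent terms
  edges <- data.frame(child = edges_child[keep], parent = edges_parent[keep])
  if (nrow(edges)) {
    ig <- igraph::graph_from_data_frame(edges, directed = TRUE)
    if (!igraph::is_dag(ig)) stop("cyclic is_a relations: ontology is not a DAG")
  }
  list(terms = term_df, edges = edges)
}

parse_associations <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene_id = character(), go_term = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  if (ncol1 >= 15L) {                      # GAF 2.x
    qualifier <- vapply(fields, `[`, character(1), 4L)
    keep <- !grepl("\\bNOT\\b", qualifier)
    data.frame(gene_id = vapply(fields[keep], `[`, character(1), 3L),
               go_term = vapply(fields[keep], `[`, character(1), 5L))
  } else if (ncol1 >= 2L) {                # two-column TSV
    data.frame(gene_id = vapply(fields, `[`, character(1), 1L),
               go_term = vapply(fields, `[`, character(1), 2L))
  } else stop("association file is neither GAF nor two-column TSV")
}

#' Read per-sample labels
#'
#' @param path two-column TSV: sample_id, label.  A header line reading
#'   `sample_id<TAB>label` is allowed and skipped.
#' @return a [cohort()].
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample_id", "label"),
                          colClasses = "character")
  if (nrow(df) && df$sample_id[1] == "sample_id") df <- df[-1, , drop = FALSE]
  cohort(df$sample_id, df$label)
}
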