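# Plain-text container for a feature_graph: a node table and edge list as
# TSV sections plus one hex-packed bit row per node, in node-table order.
# Section headers carry element counts, which read_graph verifies, so a
# truncated or reordered file fails loudly rather than loading silently.

FMT_MAGIC <- "#HKG\t1"

bits_to_hex <- function(bits) {
  if (anyNA(bits)) return(".")
  n <- length(bits)
  pad <- (4L - n %% 4L) %% 4L
  bits <- c(as.integer(bits), rep(0L, pad))
  m <- matrix(bits, nrow = 4L)
  vals <- as.integer(2L^(3:0) %*% m)
  paste(substring("0123456789abcdef", vals + 1L, vals + 1L), collapse = "")
}

hex_to_bits <- function(h, nbits) {
  if (h == ".") return(rep(NA_integer_, nbits))
  vals <- strtoi(strsplit(h, "")[[1]], base = 16L)
  if (anyNA(vals)) stop("malformed hex vector row")
  bits <- as.integer(t(outer(vals, 2L^(3:0), function(v, p) bitwAnd(v, p) > 0)))
  if (length(bits) < nbits) stop("truncated vector row: expected ", nbits, " bits")
  bits[seq_len(nbits)]
}

na_dot <- function(x) ifelse(is.na(x), ".", as.character(x))
dot_na <- function(x, as = as.character) {
  out <- as(x)
  out[x == "."] <- NA
  out
}

#' Serialize a feature graph to a plain-text store
#'
#' Writes the node table, edge list, alias map, GO association and
#' threshold statistics, and the per-node binary vectors (hex-packed, in
#' node-table order) into a single text file that [read_graph()] restores
#' bit-for-bit.
#'
#' @param graph a [feature_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  w(FMT_MAGIC)
  writeLines(paste(c("#%samples", graph$sample_ids), collapse = "\t"), con)
  nd <- graph$nodes
  w("#%nodes", nrow(nd))
  if (nrow(nd))
    writeLines(paste(nd$node_id, nd$kind, na_dot(nd$label), na_dot(nd$chrom),
                     na_dot(nd$start), na_dot(nd$end), nd$combine_rule,
                     sep = "\t"), con)
  w("#%edges", nrow(graph$edges))
  if (nrow(graph$edges))
    writeLines(paste(graph$edges$child, graph$edges$parent, sep = "\t"), con)
  w("#%alias", length(graph$alias))
  if (length(graph$alias))
    writeLines(paste(names(graph$alias), graph$alias, sep = "\t"), con)
  w("#%gogenes", length(graph$go_genes))
  for (term in names(graph$go_genes))
    writeLines(paste(term, paste(graph$go_genes[[term]], collapse = ","),
                     sep = "\t"), con)
  w("#%gostats", length(graph$go_stats))
  for (term in names(graph$go_stats)) {
    s <- graph$go_stats[[term]]
    writeLines(paste(term, format_num(s$mu), format_num(s$sigma),
                     format_num(s$cutoff),
                     paste(s$counts, collapse = ","), sep = "\t"), con)
  }
  nvec <- if (is.null(graph$vectors)) 0L else nrow(graph$vectors)
  nbit <- if (is.null(graph$vectors)) 0L else ncol(graph$vectors)
  w("#%vectors", nvec, nbit)
  if (nvec)
    writeLines(vapply(seq_len(nvec),
                      function(i) bits_to_hex(graph$vectors[i, ]), character(1)),
               con)
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 17, format = "g")

#' Restore a feature graph written by [write_graph()]
#'
#' @param path path to the store.
#' @return a [feature_graph()].
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[[1]] != FMT_MAGIC)
    stop("not a feature-graph store: ", path)
  pos <- 2L
  expect_section <- function(tag) {
    parts <- strsplit(lines[[pos]], "\t", fixed = TRUE)[[1]]
    if (parts[[1]] != tag) stop("expected section ", tag, " at line ", pos)
    pos <<- pos + 1L
    parts[-1L]
  }
  take <- function(n) {
    if (n == 0L) return(character())
    if (pos + n - 1L > length(lines)) stop("truncated store: ", path)
    out <- lines[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  samples <- expect_section("#%samples")
  n_nodes <- as.integer(expect_section("#%nodes")[[1]])
  node_rows <- strsplit(take(n_nodes), "\t", fixed = TRUE)
  if (n_nodes && any(lengths(node_rows) != 7L))
    stop("node table field-count mismatch")
  col <- function(rows, i) vapply(rows, `[`, character(1), i)
  nodes <- if (n_nodes) data.frame(
    node_id = col(node_rows, 1), kind = col(node_rows, 2),
    label = dot_na(col(node_rows, 3)), chrom = dot_na(col(node_rows, 4)),
    start = as.numeric(dot_na(col(node_rows, 5))),
    end = as.numeric(dot_na(col(node_rows, 6))),
    combine_rule = col(node_rows, 7))
  else data.frame(node_id = character(), kind = character(),
                  label = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  combine_rule = character())
  n_edges <- as.integer(expect_section("#%edges")[[1]])
  edge_rows <- strsplit(take(n_edges), "\t", fixed = TRUE)
  edges <- if (n_edges) data.frame(child = col(edge_rows, 1),
                                   parent = col(edge_rows, 2))
  else data.frame(child = character(), parent = character())
  n_alias <- as.integer(expect_section("#%alias")[[1]])
  alias_rows <- strsplit(take(n_alias), "\t", fixed = TRUE)
  alias <- if (n_alias) stats::setNames(col(alias_rows, 2), col(alias_rows, 1))
  else character()
  n_gg <- as.integer(expect_section("#%gogenes")[[1]])
  gg_rows <- strsplit(take(n_gg), "\t", fixed = TRUE)
  go_genes <- stats::setNames(
    lapply(gg_rows, function(r) strsplit(r[[2]], ",", fixed = TRUE)[[1]]),
    vapply(gg_rows, `[`, character(1), 1))
  n_gs <- as.integer(expect_section("#%gostats")[[1]])
  gs_rows <- strsplit(take(n_gs), "\t", fixed = TRUE)
  go_stats <- stats::setNames(lapply(gs_rows, function(r) {
    list(mu = as.numeric(r[[2]]), sigma = as.numeric(r[[3]]),
         cutoff = as.numeric(r[[4]]),
         counts = as.integer(strsplit(r[[5]], ",", fixed = TRUE)[[1]]))
  }), vapply(gs_rows, `[`, character(1), 1))
  vec_hdr <- expect_section("#%vectors")
  n_vec <- as.integer(vec_hdr[[1]]); n_bit <- as.integer(vec_hdr[[2]])
  vec_rows <- take(n_vec)
  vectors <- NULL
  if (n_vec) {
    if (n_vec != n_nodes) stop("vector row count does not match node table")
    vectors <- t(vapply(vec_rows, hex_to_bits, integer(n_bit), nbits = n_bit))
    dimnames(vectors) <- list(nodes$node_id,
                              if (length(samples)) samples else NULL)
  }
  feature_graph(nodes, edges, vectors = vectors,
                sample_ids = if (length(samples)) samples else NULL,
                alias = alias, go_genes = go_genes, go_stats = go_stats)
}
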