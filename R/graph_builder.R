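# ---------------------------------------------------------------------------
# Meta-cells and per-chromosome gene-gene spatial interaction graphs.
#
# A meta-cell pools a target cell with its k most Hi-C-similar cells of the
# same type (default k = 20) to densify the very sparse per-cell contact
# sets. An edge joins two genes when their regions share at least one contact
# anywhere in the meta-cell; the edge feature vector holds the per-member
# contact counts (target first, then neighbours by descending similarity),
# their mean, and the log10 genomic distance between the gene midpoints.
# ---------------------------------------------------------------------------

#' Cosine similarity between two cells' binned Hi-C contact patterns
#'
#' Each contact is assigned to an unordered (bin(pos1), bin(pos2)) pair at
#' `bin_size` resolution within its chromosome; the per-cell count vectors
#' over all observed (chrom, bin, bin) keys are compared by cosine
#' similarity. The measure is symmetric, equals 1 for a cell against itself,
#' and lies in [0, 1] for non-negative counts. Two cells with no contacts in
#' common score 0; if either cell has no contacts at all the similarity is
#' defined as 0.
#'
#' @param a,b `contact_set` objects mapped to the same genome.
#' @param bin_size bin width in bp (default 1e6).
#' @return a single numeric similarity in [0, 1].
#' @export
cell_similarity <- function(a, b, bin_size = 1e6) {
  stopifnot(bin_size > 0)
  va <- binned_contact_counts(a, bin_size)
  vb <- binned_contact_counts(b, bin_size)
  if (nrow(va) == 0 || nrow(vb) == 0) return(0)
  m <- merge(va, vb, by = "bin_key", all = FALSE)
  num <- if (nrow(m) == 0) 0 else sum(m$n.x * m$n.y)
  if (num == 0) return(0)
  num / (sqrt(sum(va$n^2)) * sqrt(sum(vb$n^2)))
}

binned_contact_counts <- function(x, bin_size) {
  r <- x$records
  if (nrow(r) == 0) {
    return(data.table::data.table(bin_key = character(), n = numeric()))
  }
  b1 <- r$pos1 %/% bin_size
  b2 <- r$pos2 %/% bin_size
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  dt <- data.table::data.table(bin_key = paste(r$chrom, lo, hi, sep = ":"))
  dt[, .(n = as.numeric(.N)), by = "bin_key"]
}

#' Build a meta-cell around a target cell
#'
#' Selects the `k` cells of the target's own cell type whose Hi-C patterns
#' are most similar to the target ([cell_similarity()]), ties broken towards
#' the lexicographically smaller cell id so that selection is deterministic.
#' `k = 0` gives the single-cell ("independent") mode in which no pooling is
#' performed.
#'
#' @param target a `contact_set`.
#' @param population list of `contact_set` of the same cell type as `target`
#'   (the target itself must not be among them).
#' @param k number of neighbours to pool (default 20).
#' @param bin_size similarity bin width in bp.
#' @return a `metacell`: list with `target`, `neighbors` (list, descending
#'   similarity), `similarities`, `member_count` = k + 1.
#' @export
build_metacell <- function(target, population, k = 20, bin_size = 1e6) {
  ids <- vapply(population, function(c) c$cell_id, "")
  if (any(ids == target$cell_id)) {
    stop_fmt("population must not contain the target cell (%s)", target$cell_id)
  }
  types <- vapply(population, function(c) as.character(c$cell_type %||% NA_character_), "")
  if (length(population) > 0 && !all(types == as.character(target$cell_type))) {
    stop_fmt("all population cells must share the target's cell type (%s)",
             target$cell_type)
  }
  if (length(population) < k) {
    stop_fmt("meta-cell needs %d same-type neighbours but only %d are available; lower k or supply more cells",
             k, length(population))
  }
  if (k == 0) {
    return(structure(list(target = target, neighbors = list(),
                          similarities = numeric(), member_count = 1L),
                     class = "metacell"))
  }
  sims <- vapply(population, function(c) cell_similarity(target, c, bin_size), 0)
  ord <- order(-sims, ids)
  sel <- ord[seq_len(k)]
  structure(
    list(target = target, neighbors = population[sel],
         similarities = sims[sel], member_count = as.integer(k + 1)),
    class = "metacell"
  )
}

#' @export
print.metacell <- function(x, ...) {
  cat(sprintf("<metacell> target %s + %d neighbour(s) (%s)\n",
              x$target$cell_id, length(x$neighbors), x$target$cell_type %||% "?"))
  invisible(x)
}

metacell_members <- function(mc) c(list(mc$target), mc$neighbors)

#' Count Hi-C contacts between all gene pairs on a chromosome
#'
#' For every contact, every gene whose region contains `pos1` is paired with
#' every gene whose region contains `pos2` (a position inside several
#' overlapping genes credits all of them); pairs of a gene with itself are
#' skipped and counts accumulate per unordered pair. Positions landing in no
#' gene contribute nothing.
#'
#' @param contacts a `contact_set`.
#' @param genes a `gene_table` (will be restricted to `chrom`).
#' @param chrom chromosome name.
#' @return data.table with columns `i`, `j` (i < j, row indices into the
#'   chrom-restricted gene table) and `count`.
#' @export
pair_contact_counts <- function(contacts, genes, chrom) {
  # subset with precomputed logical vectors: a bare `chrom` inside
  # `[.data.table` would resolve to the column, not the argument
  .gene_rows <- genes[["chrom"]] == chrom
  g <- genes[.gene_rows, ]
  empty <- data.table::data.table(i = integer(), j = integer(), count = numeric())
  if (nrow(g) == 0) return(empty)
  .rec_rows <- contacts$records[["chrom"]] == chrom
  r <- contacts$records[.rec_rows, ]
  if (nrow(r) == 0) return(empty)
  gene_ir <- IRanges::IRanges(start = g$start + 1L, end = g$end)  # 0-based half-open -> 1-based closed
  hit1 <- IRanges::findOverlaps(IRanges::IRanges(r$pos1 + 1L, r$pos1 + 1L), gene_ir)
  hit2 <- IRanges::findOverlaps(IRanges::IRanges(r$pos2 + 1L, r$pos2 + 1L), gene_ir)
  h1 <- data.table::data.table(contact = S4Vectors::queryHits(hit1),
                               gene_a = S4Vectors::subjectHits(hit1))
  h2 <- data.table::data.table(contact = S4Vectors::queryHits(hit2),
                               gene_b = S4Vectors::subjectHits(hit2))
  if (nrow(h1) == 0 || nrow(h2) == 0) return(empty)
  pairs <- merge(h1, h2, by = "contact", allow.cartesian = TRUE)
  pairs <- pairs[gene_a != gene_b]
  if (nrow(pairs) == 0) return(empty)
  pairs[, `:=`(i = pmin(gene_a, gene_b), j = pmax(gene_a, gene_b))]
  out <- pairs[, .(count = as.numeric(.N)), by = .(i, j)]
  data.table::setorder(out, i, j)
  out[]
}

#' Build the per-chromosome gene-gene spatial interaction graph of a cell
#'
#' Nodes are all retained genes on `chrom` (isolated genes included — they
#' still carry an expression target and are handled by the model's residual
#' path). An edge (i, j) exists when the meta-cell members together contribute
#' at least one contact between the two gene regions. The edge feature row is
#' `[count_target, count_neighbor1..count_neighborK, mean of the K+1 counts,
#' log10(genomic midpoint distance)]`, giving 23 features for the default
#' k = 20 and 3 features in single-cell mode (k = 0). Midpoint distances are
#' floored at 10 bp before the log so overlapping genes cannot produce a
#' negative or undefined distance feature.
#'
#' @param metacell a `metacell`.
#' @param genes `gene_table`.
#' @param chrom chromosome to build on.
#' @param node_features numeric matrix (rows = genes of `chrom` in gene-table
#'   order) of projected node features.
#' @param expression_row named numeric vector of normalized targets in [0, 1]
#'   for the genes on `chrom` (names = gene ids).
#' @param member_counts optional precomputed [pair_contact_counts()] tables,
#'   one per meta-cell member (target first); avoids recounting when the same
#'   cell participates in many meta-cells.
#' @return a `gene_graph`: list with `cell_id`, `chrom`, `gene_ids`,
#'   `node_features` (n x p), `edges` (m x 2 integer matrix, i < j),
#'   `edge_features` (m x (k + 3)), `targets` (length n), `n`; or `NULL` with
#'   a warning when the chromosome carries no genes.
#' @export
build_gene_graph <- function(metacell, genes, chrom, node_features, expression_row,
                             member_counts = NULL) {
  .gene_rows <- genes[["chrom"]] == chrom
  g <- genes[.gene_rows, ]
  n <- nrow(g)
  if (n == 0) {
    warn_fmt("no genes on %s; graph skipped", chrom)
    return(NULL)
  }
  stopifnot(nrow(node_features) == n, length(expression_row) == n)
  if (!is.null(names(expression_row))) {
    stopifnot(identical(names(expression_row), g$gene_id))
  }
  stopifnot(all(expression_row >= 0 & expression_row <= 1))
  members <- metacell_members(metacell)
  k1 <- length(members)
  per_member <- member_counts %||%
    lapply(members, pair_contact_counts, genes = g, chrom = chrom)
  stopifnot(length(per_member) == k1)
  all_pairs <- unique(data.table::rbindlist(
    lapply(per_member, function(p) p[, .(i, j)])
  ))
  if (nrow(all_pairs) == 0) {
    edges <- matrix(integer(), ncol = 2)
    efeat <- matrix(numeric(), ncol = k1 + 2)
  } else {
    data.table::setorder(all_pairs, i, j)
    counts <- matrix(0, nrow(all_pairs), k1)
    key <- paste(all_pairs$i, all_pairs$j)
    for (m in seq_len(k1)) {
      p <- per_member[[m]]
      if (nrow(p) > 0) {
        pos <- match(paste(p$i, p$j), key)
        counts[pos, m] <- p$count
      }
    }
    dist <- abs(g$midpoint[all_pairs$i] - g$midpoint[all_pairs$j])
    efeat <- cbind(counts, rowMeans(counts), log10(pmax(dist, 10)))
    edges <- cbind(all_pairs$i, all_pairs$j)
  }
  structure(
    list(cell_id = metacell$target$cell_id, chrom = chrom,
         gene_ids = g$gene_id,
         node_features = unname(as.matrix(node_features)),
         edges = edges, edge_features = unname(efeat),
         targets = unname(expression_row), n = n),
    class = "gene_graph"
  )
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph> cell %s %s: %d genes, %d undirected edges, %d-d edge features\n",
              x$cell_id, x$chrom, x$n, nrow(x$edges), ncol(x$edge_features)))
  invisible(x)
}

n_edges <- function(g) nrow(g$edges)

# ---------------------------------------------------------------------------
# Plain-text graph serialization (one file per cell x chromosome) + manifest
# ---------------------------------------------------------------------------

#' Write a gene graph to a plain-text file
#'
#' The format is line-oriented: `#key value` headers, then one `N` line per
#' node (`gene_id`, target, node features) and one `E` line per undirected
#' edge (`i`, `j`, edge features). Numbers are written with full precision
#' (`%.17g`) so that a write/read round trip is exact and repeated runs are
#' byte-identical.
#'
#' @param graph a `gene_graph`.
#' @param path output path.
#' @export
write_gene_graph <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#cell_id %s", graph$cell_id), con)
  writeLines(sprintf("#chrom %s", graph$chrom), con)
  writeLines(sprintf("#n_nodes %d", graph$n), con)
  writeLines(sprintf("#n_edges %d", nrow(graph$edges)), con)
  writeLines(sprintf("#edge_dim %d", ncol(graph$edge_features)), con)
  num <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  for (i in seq_len(graph$n)) {
    writeLines(paste("N", graph$gene_ids[i], sprintf("%.17g", graph$targets[i]),
                     num(graph$node_features[i, ]), sep = "\t"), con)
  }
  for (e in seq_len(nrow(graph$edges))) {
    writeLines(paste("E", graph$edges[e, 1], graph$edges[e, 2],
                     num(graph$edge_features[e, ]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a gene graph written by [write_gene_graph()]
#' @param path graph file path.
#' @return a `gene_graph`.
#' @export
read_gene_graph <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    ln <- grep(paste0("^#", key, " "), hdr, value = TRUE)[1]
    sub(paste0("^#", key, " "), "", ln)
  }
  n <- as.integer(get_hdr("n_nodes"))
  m <- as.integer(get_hdr("n_edges"))
  ed <- as.integer(get_hdr("edge_dim"))
  nl <- strsplit(grep("^N\t", lines, value = TRUE), "\t", fixed = TRUE)
  el <- strsplit(grep("^E\t", lines, value = TRUE), "\t", fixed = TRUE)
  stopifnot(length(nl) == n, length(el) == m)
  gene_ids <- vapply(nl, `[[`, "", 2)
  targets <- vapply(nl, function(x) as.numeric(x[3]), 0)
  nf <- do.call(rbind, lapply(nl, function(x) as.numeric(x[-(1:3)])))
  if (m > 0) {
    edges <- do.call(rbind, lapply(el, function(x) as.integer(x[2:3])))
    efeat <- do.call(rbind, lapply(el, function(x) as.numeric(x[-(1:3)])))
  } else {
    edges <- matrix(integer(), ncol = 2)
    efeat <- matrix(numeric(), ncol = ed)
  }
  structure(
    list(cell_id = get_hdr("cell_id"), chrom = get_hdr("chrom"),
         gene_ids = gene_ids, node_features = nf, edges = edges,
         edge_features = efeat, targets = targets, n = n),
    class = "gene_graph"
  )
}

#' Write a directory of graphs with an index manifest
#'
#' @param graphs list of `gene_graph`.
#' @param dir output directory (created if needed).
#' @param splits optional character vector (one of train/val/test per graph)
#'   recorded in the manifest.
#' @return the manifest as a data.table (invisibly).
#' @export
write_graph_dataset <- function(graphs, dir, splits = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.table::data.table(
    cell_id = vapply(graphs, function(g) g$cell_id, ""),
    chrom = vapply(graphs, function(g) g$chrom, ""),
    n_nodes = vapply(graphs, function(g) as.integer(g$n), 0L),
    n_edges = vapply(graphs, function(g) as.integer(nrow(g$edges)), 0L),
    split = if (is.null(splits)) NA_character_ else splits
  )
  manifest[, file := sprintf("%s__%s.graph.tsv", cell_id, chrom)]
  for (i in seq_along(graphs)) {
    write_gene_graph(graphs[[i]], file.path(dir, manifest$file[i]))
  }
  data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}

#' Read a graph dataset directory written by [write_graph_dataset()]
#' @param dir dataset directory.
#' @param split optional split name to restrict to.
#' @return list with `graphs` and `manifest`.
#' @export
read_graph_dataset <- function(dir, split = NULL) {
  manifest <- data.table::fread(file.path(dir, "manifest.tsv"), sep = "\t")
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  graphs <- lapply(manifest$file, function(f) read_gene_graph(file.path(dir, f)))
  list(graphs = graphs, manifest = manifest)
}
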