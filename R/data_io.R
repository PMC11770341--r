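#' @import data.table
NULL

# ---------------------------------------------------------------------------
# Internal containers
#
# All genomic coordinates inside the package are 0-based, half-open [start,
# end). GTF (1-based, closed) and pairs positions (1-based) are converted on
# read and back on write. Strand is ignored throughout.
# ---------------------------------------------------------------------------

new_contact_set <- function(cell_id, cell_type, records,
                            n_interchrom = 0L, n_malformed = 0L) {
  stopifnot(is.data.frame(records))
  records <- data.table::as.data.table(records)[, .(chrom, pos1, pos2)]
  structure(
    list(cell_id = cell_id, cell_type = cell_type, records = records,
         n_interchrom = n_interchrom, n_malformed = n_malformed),
    class = "contact_set"
  )
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set> cell %s (%s): %d intrachromosomal contacts on %d chromosome(s)\n",
              x$cell_id, x$cell_type %||% "?", nrow(x$records),
              data.table::uniqueN(x$records$chrom)))
  invisible(x)
}

n_contacts <- function(x) nrow(x$records)

# ---------------------------------------------------------------------------
# 4DN pairs
# ---------------------------------------------------------------------------

#' Read a single-cell Hi-C pairs file
#'
#' Reads 4DN-style `.pairs` text (header lines starting with `#`, a
#' `#columns:` line naming the fields) or a minimal 4-column TSV
#' (`chrom1 pos1 chrom2 pos2`, with or without a header row); the dialect is
#' auto-detected. Only intrachromosomal records are kept — interchromosomal
#' rows are counted and dropped, mirroring the fact that gene-gene spatial
#' graphs are built from within-chromosome contacts only. Positions are
#' 1-based in the file and converted to 0-based internally.
#'
#' Malformed rows (wrong field count, non-numeric or non-positive positions)
#' are dropped; their count is reported in a warning and kept in the
#' `n_malformed` field of the result.
#'
#' @param path path to the pairs file.
#' @param cell_id identifier of the cell the file belongs to.
#' @param cell_type optional cell-type label.
#' @return a `contact_set`: list with `cell_id`, `cell_type`, `records`
#'   (data.table `chrom`, `pos1`, `pos2`, 0-based), `n_interchrom`,
#'   `n_malformed`.
#' @export
read_pairs <- function(path, cell_id, cell_type = NA_character_) {
  if (!file.exists(path)) stop_fmt("pairs file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  comment <- startsWith(lines, "#")
  cols <- NULL
  col_line <- grep("^#\\s*columns:", lines, value = TRUE)
  if (length(col_line) > 0) {
    cols <- strsplit(sub("^#\\s*columns:\\s*", "", col_line[1]), "\\s+")[[1]]
  }
  body <- lines[!comment & nzchar(lines)]
  if (length(body) == 0 && is.null(cols)) {
    warn_fmt("empty pairs file: %s", path)
    return(new_contact_set(cell_id, cell_type,
                           data.table::data.table(chrom = character(),
                                                  pos1 = integer(),
                                                  pos2 = integer())))
  }
  if (is.null(cols)) {
    # minimal dialect; a non-numeric first row is a header
    first <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    if (any(c("chrom1", "pos1") %in% first)) {
      cols <- first
      body <- body[-1]
    } else if (length(first) == 4) {
      cols <- c("chrom1", "pos1", "chrom2", "pos2")
    } else {
      stop_fmt("cannot determine pairs columns in %s: no '#columns:' header and first row has %d fields",
               path, length(first))
    }
  }
  req <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(req %in% cols)) {
    stop_fmt("pairs file %s is missing required column(s): %s",
             path, paste(setdiff(req, cols), collapse = ", "))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf == length(cols)
  idx <- match(req, cols)
  get_col <- function(k) vapply(fields[ok], `[[`, "", idx[k])
  chrom1 <- get_col(1); chrom2 <- get_col(3)
  pos1 <- suppressWarnings(as.numeric(get_col(2)))
  pos2 <- suppressWarnings(as.numeric(get_col(4)))
  valid <- !is.na(pos1) & !is.na(pos2) & pos1 >= 1 & pos2 >= 1
  n_malformed <- sum(!ok) + sum(!valid)
  if (n_malformed > 0) {
    warn_fmt("%d malformed line(s) dropped while reading %s", n_malformed, path)
  }
  chrom1 <- chrom1[valid]; chrom2 <- chrom2[valid]
  pos1 <- pos1[valid]; pos2 <- pos2[valid]
  intra <- chrom1 == chrom2
  n_inter <- sum(!intra)
  rec <- data.table::data.table(
    chrom = chrom1[intra],
    pos1 = as.integer(pos1[intra] - 1L),
    pos2 = as.integer(pos2[intra] - 1L)
  )
  if (nrow(rec) == 0) warn_fmt("no intrachromosomal contacts in %s", path)
  new_contact_set(cell_id, cell_type, rec,
                  n_interchrom = n_inter, n_malformed = as.integer(n_malformed))
}

#' Write a contact set as a 4DN-style pairs file
#'
#' Inverse of [read_pairs()]; internal 0-based positions are written 1-based.
#'
#' @param x a `contact_set`.
#' @param path output path.
#' @export
write_pairs <- function(x, path) {
  hdr <- c("## pairs format v1.0",
           "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2")
  r <- x$records
  if (nrow(r) > 0) {
    rows <- sprintf("r%06d\t%s\t%d\t%s\t%d\t+\t+",
                    seq_len(nrow(r)), r$chrom, r$pos1 + 1L, r$chrom, r$pos2 + 1L)
  } else {
    rows <- character()
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene annotation (GTF)
# ---------------------------------------------------------------------------

#' Read gene-level records from a GTF annotation
#'
#' Keeps `gene` feature rows only. GTF 1-based closed intervals are converted
#' to 0-based half-open; the gene midpoint, used for the genomic-distance edge
#' feature, is `floor((start + end) / 2)` on the converted coordinates.
#'
#' @param path path to a GTF file with gene-level rows.
#' @return a data.table (`gene_id`, `chrom`, `start`, `end`, `midpoint`) in
#'   file order, classed `gene_table`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop_fmt("annotation file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if ("type" %in% names(meta)) {
    keep <- as.character(meta$type) == "gene"
    gr <- gr[keep]
    meta <- S4Vectors::mcols(gr)
  }
  if (length(gr) == 0) stop_fmt("no gene-level rows in %s", path)
  if (!"gene_id" %in% names(meta)) stop_fmt("GTF %s lacks gene_id attributes", path)
  ids <- as.character(meta$gene_id)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop_fmt("duplicate gene_id in %s: %s", path, paste(unique(dup), collapse = ", "))
  }
  out <- data.table::data.table(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.integer(GenomicRanges::start(gr) - 1L),
    end = as.integer(GenomicRanges::end(gr))
  )
  out[, midpoint := as.integer(floor((start + end) / 2))]
  stopifnot(all(out$start < out$end),
            all(out$midpoint >= out$start & out$midpoint < out$end))
  data.table::setattr(out, "class", c("gene_table", class(out)))
  out[]
}

#' Write a gene table as GTF
#' @param genes a `gene_table` as returned by [read_gene_annotation()].
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  lines <- sprintf('%s\tschicexpr\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s";',
                   genes$chrom, genes$start + 1L, genes$end, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Expression matrix + cell types
# ---------------------------------------------------------------------------

#' Read a gene x cell raw count matrix with its cell-type map
#'
#' The expression table is a TSV with gene identifiers in the first column and
#' one column per cell. Cell-type labels live in a separate two-column TSV
#' (`cell_id`, `cell_type`) because train/validation/test splits are made by
#' cell type.
#'
#' @param path expression TSV.
#' @param cell_types_path two-column cell-type TSV.
#' @return an `expression_matrix`: list with `counts` (genes x cells numeric
#'   matrix, dimnames set) and `cell_types` (named character vector, one label
#'   per cell).
#' @export
read_expression <- function(path, cell_types_path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  gene_ids <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, with = FALSE])
  mode(mat) <- "numeric"
  if (anyNA(mat)) stop_fmt("non-numeric expression values in %s", path)
  if (any(mat < 0)) stop_fmt("negative expression count in %s", path)
  rownames(mat) <- gene_ids
  ct <- read_cell_types(cell_types_path)
  missing <- setdiff(colnames(mat), names(ct))
  if (length(missing) > 0) {
    stop_fmt("cells missing from cell-type map: %s", paste(missing, collapse = ", "))
  }
  structure(list(counts = mat, cell_types = ct[colnames(mat)]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells, %d cell type(s), %.1f%% zeros\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_types)),
              100 * mean(x$counts == 0)))
  invisible(x)
}

#' Read a two-column cell-type map (cell_id, cell_type)
#' @param path TSV path; a header row is optional.
#' @return named character vector of cell types.
#' @export
read_cell_types <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = TRUE)
  if (ncol(dt) < 2) stop_fmt("cell-type map %s needs two columns", path)
  if (identical(as.character(dt[1, 1][[1]]), "cell_id")) dt <- dt[-1]
  stats::setNames(as.character(dt[[2]]), as.character(dt[[1]]))
}

#' Write an expression matrix and its cell-type map
#' @param x an `expression_matrix`.
#' @param path expression TSV path.
#' @param cell_types_path cell-type TSV path.
#' @export
write_expression <- function(x, path, cell_types_path = NULL) {
  dt <- data.table::data.table(gene_id = rownames(x$counts))
  dt <- cbind(dt, data.table::as.data.table(x$counts))
  data.table::fwrite(dt, path, sep = "\t")
  if (!is.null(cell_types_path)) {
    write_cell_types(x$cell_types, cell_types_path)
  }
  invisible(path)
}

#' @rdname write_expression
#' @param cell_types named character vector (names = cell ids).
#' @export
write_cell_types <- function(cell_types, cell_types_path) {
  dt <- data.table::data.table(cell_id = names(cell_types),
                               cell_type = unname(cell_types))
  data.table::fwrite(dt, cell_types_path, sep = "\t", col.names = FALSE)
  invisible(cell_types_path)
}

# ---------------------------------------------------------------------------
# Chromatin-state track (BED)
# ---------------------------------------------------------------------------

#' Read a chromatin-state segmentation (BED4)
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged;
#' the 4th column is the state label. Intervals are sorted within each
#' chromosome. Overlapping intervals are allowed with a warning — during
#' featurization the earlier-sorted interval wins on the overlapped region.
#'
#' @param path BED file with a state label in column 4.
#' @return a data.table (`chrom`, `start`, `end`, `state`), classed
#'   `state_track`, sorted by (chrom, start).
#' @export
read_state_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) stop_fmt("empty state track: %s", path)
  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.integer(GenomicRanges::start(gr) - 1L),
    end = as.integer(GenomicRanges::end(gr)),
    state = as.character(S4Vectors::mcols(gr)$name)
  )
  data.table::setorder(out, chrom, start, end)
  has_overlap <- out[, any(start[-1] < head(end, -1)), by = chrom][, any(V1)]
  if (isTRUE(has_overlap)) {
    warn_fmt("overlapping state intervals in %s; first-wins resolution applies", path)
  }
  data.table::setattr(out, "class", c("state_track", class(out)))
  out[]
}

#' Write a chromatin-state track as BED4
#' @param track a `state_track`.
#' @param path output path.
#' @export
write_state_track <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end, track$state)
  writeLines(lines, path)
  invisible(path)
}
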