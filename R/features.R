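# ---------------------------------------------------------------------------
# Node features and expression targets.
#
# Per gene: a 768-d sequence embedding (mean over 1000-bp segments) is
# concatenated with 3 chromatin-state coverage fractions, and the resulting
# gene x 771 matrix is reduced by PCA to the node-feature width (100 by
# default). Raw counts are clipped at a high percentile and min-max scaled to
# [0, 1] to become per-node regression targets.
# ---------------------------------------------------------------------------

#' Embed a gene's nucleotide sequence via a pluggable segment embedder
#'
#' The sequence is cut into consecutive 1000-bp segments (the last may be
#' shorter), each segment is mapped to a fixed-length real vector by
#' `provider`, and the per-segment vectors are averaged element-wise. The
#' provider abstracts a sequence language model; any deterministic function
#' from a nucleotide string to a numeric vector of constant length works.
#'
#' @param sequence nucleotide string (length >= 1).
#' @param provider function(segment) -> numeric vector of fixed length.
#' @param segment_size segment width in bp (default 1000).
#' @return numeric vector: the mean segment embedding.
#' @export
embed_gene <- function(sequence, provider, segment_size = 1000) {
  n <- nchar(sequence)
  stopifnot(n >= 1, segment_size >= 1)
  starts <- seq(1, n, by = segment_size)
  segs <- substring(sequence, starts, pmin(starts + segment_size - 1, n))
  vecs <- lapply(segs, provider)
  len <- length(vecs[[1]])
  if (any(lengths(vecs) != len)) {
    stop_fmt("embedding provider returned vectors of differing length")
  }
  rowMeans(matrix(unlist(vecs), nrow = len))
}

#' A deterministic hash-based segment embedder
#'
#' Returns a provider that maps each distinct segment to a reproducible
#' pseudo-random Gaussian vector keyed by a hash of the segment and `seed`.
#' Useful wherever a fixed, download-free stand-in for a sequence language
#' model is needed (tests, synthetic pipelines).
#'
#' @param seed integer seed.
#' @param dim embedding width (default 768).
#' @return a `function(segment) -> numeric[dim]`.
#' @export
hash_embedding_provider <- function(seed = 1L, dim = 768) {
  force(seed); force(dim)
  function(segment) {
    with_seed(derive_seed(seed, paste0("segment-embed:", segment)), rnorm(dim))
  }
}

#' Chromatin-state coverage fractions of a gene
#'
#' Collapses the state vocabulary into three groups via `grouping` and
#' returns, for one gene, the fraction of its interval covered by each
#' group. Overlapping track intervals are resolved first-wins in (chrom,
#' start) sort order. Components are in [0, 1] and sum to at most 1 (gaps in
#' the segmentation count towards no group).
#'
#' @param gene one-row `gene_table` slice (or list with `chrom`, `start`,
#'   `end`).
#' @param track a `state_track`.
#' @param grouping named character vector mapping each state label to one of
#'   the three group names.
#' @return numeric vector of length 3, named by the (sorted unique) group
#'   names.
#' @export
chromatin_state_features <- function(gene, track, grouping) {
  groups <- sort(unique(unname(grouping)))
  if (length(groups) != 3) {
    stop_fmt("grouping must collapse states into exactly 3 groups, got %d", length(groups))
  }
  out <- stats::setNames(numeric(3), groups)
  tr <- track[track$chrom == gene$chrom, ]
  if (nrow(tr) == 0) {
    warn_fmt("chromosome %s absent from state track; zero state features", gene$chrom)
    return(out)
  }
  unknown <- setdiff(unique(tr$state), names(grouping))
  if (length(unknown) > 0) {
    stop_fmt("state label(s) not covered by grouping: %s", paste(unknown, collapse = ", "))
  }
  glen <- gene$end - gene$start
  covered_to <- gene$start  # first-wins: earlier-sorted interval keeps overlap
  for (r in seq_len(nrow(tr))) {
    s <- max(tr$start[r], gene$start, covered_to)
    e <- min(tr$end[r], gene$end)
    if (e > s) {
      grp <- grouping[[tr$state[r]]]
      out[grp] <- out[grp] + (e - s) / glen
      covered_to <- max(covered_to, e)
    }
  }
  out
}

#' Assemble the gene x 771 raw feature matrix
#'
#' Combines a per-gene embedding table with the 3 chromatin-state coverage
#' fractions of every gene.
#'
#' @param genes `gene_table`.
#' @param embeddings numeric matrix (rownames = gene ids) of sequence
#'   embeddings.
#' @param track `state_track`.
#' @param grouping state -> group map, see [chromatin_state_features()].
#' @return numeric matrix, rows in `genes` order, `ncol(embeddings) + 3`
#'   columns.
#' @export
assemble_node_features <- function(genes, embeddings, track, grouping) {
  missing <- setdiff(genes$gene_id, rownames(embeddings))
  if (length(missing) > 0) {
    stop_fmt("genes missing from embedding table: %s", paste(missing, collapse = ", "))
  }
  emb <- embeddings[genes$gene_id, , drop = FALSE]
  st <- t(vapply(seq_len(nrow(genes)),
                 function(i) chromatin_state_features(genes[i, ], track, grouping),
                 numeric(3)))
  unname(cbind(emb, st))
}

#' Fit a PCA projection of the raw node features
#'
#' Centered (not scaled) PCA; the model keeps the first `n_components`
#' loadings, the centering vector, and the per-component explained-variance
#' ratios. The projection is fit once on the genome-wide gene matrix and
#' reused for every cell, because node features are cell-independent.
#'
#' @param features numeric matrix (genes x raw feature width).
#' @param n_components output dimensionality (default 100).
#' @return a `projection_model`: list with `rotation`, `center`,
#'   `explained_variance_ratio`, `total_variance_captured`.
#' @export
fit_projection <- function(features, n_components = 100) {
  features <- as.matrix(features)
  if (nrow(features) <= n_components) {
    stop_fmt("PCA needs more genes (%d) than components (%d); use fewer components",
             nrow(features), n_components)
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (rank < n_components) {
    stop_fmt("feature matrix has rank %d < %d components; use fewer components",
             rank, n_components)
  }
  ratio <- ev[seq_len(n_components)] / sum(ev)
  structure(
    list(rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
         center = pc$center,
         explained_variance_ratio = ratio,
         total_variance_captured = sum(ratio)),
    class = "projection_model"
  )
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model> %d -> %d dims, %.2f%% of total variance captured\n",
              nrow(x$rotation), ncol(x$rotation), 100 * x$total_variance_captured))
  invisible(x)
}

#' Project raw feature rows through a fitted PCA model
#' @param model a `projection_model`.
#' @param features matrix (or vector) of raw features.
#' @return projected matrix (rows x n_components).
#' @export
project_features <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  sweep(as.matrix(features), 2, model$center) %*% model$rotation
}

#' Clip and min-max normalize a raw expression matrix
#'
#' Genes with no nonzero value anywhere in the dataset are dropped (they
#' carry no signal to model). The clip value is the `clip_percentile`-th
#' percentile (linear-interpolation definition, zeros included) of all
#' retained values; values are clipped to [0, clip_value] and divided by it,
#' mapping the data to [0, 1].
#'
#' @param expr an `expression_matrix` (or bare genes x cells numeric matrix).
#' @param clip_percentile percentile for the clip value (default 98, which on
#'   the data this models corresponds to a raw count of about 3).
#' @return list with `normalized` (genes x cells in [0, 1]), `normalizer`
#'   (`clip_value`, `clip_percentile`), `retained_gene_ids`.
#' @export
normalize_expression <- function(expr, clip_percentile = 98) {
  counts <- if (inherits(expr, "expression_matrix")) expr$counts else as.matrix(expr)
  stopifnot(all(counts >= 0))
  keep <- rowSums(counts > 0) > 0
  if (!any(keep)) stop_fmt("all expression values are zero; nothing to model")
  counts <- counts[keep, , drop = FALSE]
  clip_value <- unname(quantile(as.numeric(counts), clip_percentile / 100, type = 7))
  if (clip_value <= 0) {
    stop_fmt("clip value at the %g-th percentile is 0; raise clip_percentile", clip_percentile)
  }
  normalized <- pmin(counts, clip_value) / clip_value
  list(
    normalized = normalized,
    normalizer = structure(list(clip_value = clip_value,
                                clip_percentile = clip_percentile),
                           class = "expression_normalizer"),
    retained_gene_ids = rownames(counts)
  )
}

#' @export
print.expression_normalizer <- function(x, ...) {
  cat(sprintf("<expression_normalizer> clip at %.4g (%g-th percentile), then /clip\n",
              x$clip_value, x$clip_percentile))
  invisible(x)
}
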