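# ---------------------------------------------------------------------------
# Synthetic dataset generator.
#
# Emulates the structure of simultaneously captured single-cell Hi-C +
# scRNA-seq data: per-cell pairs files, a gene annotation, a chromatin-state
# segmentation, a per-gene embedding table and a zero-inflated gene x cell
# count matrix. Cell types differ in their contact distance-decay exponent
# and in type-specific "hub" gene pairs with elevated contact probability,
# so meta-cell neighbour selection and cell-type clustering are non-trivial.
# The nonzero expression magnitude of a gene increases with the gene's
# contact degree in its cell, planting a learnable edge -> expression
# signal.
# ---------------------------------------------------------------------------

#' Synthetic dataset configuration
#'
#' @param n_cell_types number of cell types (default 3).
#' @param cells_per_type cells per type (default 30).
#' @param n_chromosomes chromosomes (default 2).
#' @param genes_per_chromosome genes per chromosome (default 40).
#' @param contacts_per_cell intrachromosomal contacts per cell (default 800).
#' @param zero_fraction target fraction of exact zeros in the count matrix
#'   (default 0.92, the zero-inflation level typical of this data).
#' @param signal_strength coupling between a gene's per-cell contact degree
#'   and its nonzero expression magnitude (default 2; 0 removes the planted
#'   signal).
#' @param gene_length,gene_gap gene tiling geometry in bp (defaults 10 kb
#'   genes separated by 15 kb gaps, so random distance-decay contacts rarely
#'   span two genes and graph edges are dominated by the planted hubs).
#' @param hub_fraction fraction of same-chromosome gene pairs designated as
#'   hubs for each type (default 0.01; hubs must stay rarer than the
#'   expressed-gene rate for the contact-expression coupling to be visible).
#' @param hub_prob probability that a contact is drawn from a hub pair
#'   (default 0.5).
#' @param decay_exponent_base,decay_exponent_step power-law distance-decay
#'   exponent of type t is `base + step * (t - 1)`.
#' @param embed_dim,embed_rank,embed_noise_sd embedding table geometry: the
#'   per-gene vectors have a rank-`embed_rank` planted structure plus
#'   isotropic noise (defaults chosen so ~100 principal components capture
#'   roughly 90% of the variance).
#' @param seed master seed; every sub-stream is derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cell_types = 3, cells_per_type = 30,
                       n_chromosomes = 2, genes_per_chromosome = 40,
                       contacts_per_cell = 800, zero_fraction = 0.92,
                       signal_strength = 2, gene_length = 10000,
                       gene_gap = 15000, hub_fraction = 0.01, hub_prob = 0.5,
                       decay_exponent_base = 1.8, decay_exponent_step = 0.15,
                       embed_dim = 768, embed_rank = 80, embed_noise_sd = 3.2,
                       seed = 1L) {
  stopifnot(n_cell_types >= 1, cells_per_type >= 1, n_chromosomes >= 1,
            genes_per_chromosome >= 1, contacts_per_cell >= 0,
            zero_fraction >= 0, zero_fraction < 1, signal_strength >= 0)
  arg_names <- names(formals(sim_config))
  structure(mget(arg_names), class = "sim_config")
}

sim_gene_table <- function(cfg) {
  pitch <- cfg$gene_length + cfg$gene_gap
  data.table::rbindlist(lapply(seq_len(cfg$n_chromosomes), function(ch) {
    g <- seq_len(cfg$genes_per_chromosome)
    data.table::data.table(
      gene_id = sprintf("SYNG%02d%03d", ch, g),
      chrom = sprintf("chr%d", ch),
      start = (g - 1L) * pitch,
      end = (g - 1L) * pitch + cfg$gene_length
    )
  }))
}

# gene index of a position under the regular tiling, NA in gaps
sim_gene_at <- function(pos, cfg) {
  pitch <- cfg$gene_length + cfg$gene_gap
  idx <- pos %/% pitch
  ifelse(pos %% pitch < cfg$gene_length & idx < cfg$genes_per_chromosome,
         idx + 1L, NA_integer_)
}

sim_chrom_length <- function(cfg) {
  cfg$genes_per_chromosome * (cfg$gene_length + cfg$gene_gap)
}

#' Generate a deterministic per-gene embedding table
#'
#' Each gene's vector is a fixed linear combination of `rank` shared loading
#' directions plus isotropic Gaussian noise; both the loadings and the
#' per-gene coefficients are derived from `seed` (and the gene id), so the
#' same gene id under the same seed always yields the identical vector,
#' independent of which other genes are present. The low-rank structure
#' makes a ~100-component PCA capture most of the variance.
#'
#' @param gene_ids character vector of unique gene ids.
#' @param dim embedding width (default 768).
#' @param seed integer seed.
#' @param rank planted rank (default 80).
#' @param noise_sd isotropic noise standard deviation (default 3.2).
#' @return numeric matrix (genes x dim), rownames = gene ids.
#' @export
simulate_embeddings <- function(gene_ids, dim = 768, seed = 1L,
                                rank = 80, noise_sd = 3.2) {
  if (anyDuplicated(gene_ids)) {
    stop_fmt("duplicate gene ids: %s",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  loadings <- with_seed(derive_seed(seed, "embed-loadings"),
                        matrix(rnorm(rank * dim), rank, dim))
  out <- t(vapply(gene_ids, function(id) {
    with_seed(derive_seed(seed, paste0("embed-gene:", id)), {
      coeff <- rnorm(rank)
      as.numeric(coeff %*% loadings) + rnorm(dim, sd = noise_sd)
    })
  }, numeric(dim)))
  rownames(out) <- gene_ids
  out
}

#' Read / write an embedding table (TSV keyed by gene_id)
#' @param path TSV path.
#' @return numeric matrix with gene-id rownames.
#' @export
read_embedding_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' @rdname read_embedding_table
#' @param embeddings matrix with gene-id rownames.
#' @export
write_embedding_table <- function(embeddings, path) {
  dt <- data.table::data.table(gene_id = rownames(embeddings))
  dt <- cbind(dt, data.table::as.data.table(embeddings))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Default 3-way grouping of a chromatin-state vocabulary
#' @param states state labels.
#' @return named character vector state -> group ("A"/"B"/"C").
#' @export
default_state_grouping <- function(states = paste0("E", 1:9)) {
  groups <- c("A", "B", "C")[ceiling(seq_along(states) / (length(states) / 3))]
  stats::setNames(groups, states)
}

sim_contacts_for_cell <- function(cfg, type_idx, cell_seed, hubs) {
  L <- sim_chrom_length(cfg)
  expo <- cfg$decay_exponent_base + cfg$decay_exponent_step * (type_idx - 1)
  with_seed(cell_seed, {
    # each cell emphasizes one dominant hub pair (a cell-state-specific
    # contact hub): 95% of its hub contacts land there, concentrating
    # contact degree on the pair's two genes
    dom_ch <- sample.int(cfg$n_chromosomes, 1)
    dom_pair <- if (nrow(hubs[[dom_ch]]) > 0) sample.int(nrow(hubs[[dom_ch]]), 1) else 0L
    chrom_idx <- sample.int(cfg$n_chromosomes, cfg$contacts_per_cell, replace = TRUE)
    is_hub <- runif(cfg$contacts_per_cell) < cfg$hub_prob
    is_dom <- runif(cfg$contacts_per_cell) < 0.95
    pos1 <- integer(cfg$contacts_per_cell)
    pos2 <- integer(cfg$contacts_per_cell)
    pitch <- cfg$gene_length + cfg$gene_gap
    for (i in seq_len(cfg$contacts_per_cell)) {
      if (is_hub[i] && is_dom[i] && dom_pair > 0L) chrom_idx[i] <- dom_ch
      ch <- chrom_idx[i]
      hub_set <- hubs[[ch]]
      if (is_hub[i] && nrow(hub_set) > 0) {
        hp <- if (is_dom[i] && ch == dom_ch && dom_pair > 0L) {
          hub_set[dom_pair, ]
        } else {
          hub_set[sample.int(nrow(hub_set), 1), ]
        }
        pos1[i] <- (hp$i - 1L) * pitch + sample.int(cfg$gene_length, 1) - 1L
        pos2[i] <- (hp$j - 1L) * pitch + sample.int(cfg$gene_length, 1) - 1L
      } else {
        p1 <- sample.int(L, 1) - 1L
        # power-law distance decay
        d <- round(1000 * (1 - runif(1))^(-1 / expo))
        p2 <- if (runif(1) < 0.5) p1 - d else p1 + d
        pos1[i] <- p1
        pos2[i] <- as.integer(min(max(p2, 0), L - 1))
      }
    }
    data.table::data.table(chrom = sprintf("chr%d", chrom_idx),
                           pos1 = pos1, pos2 = pos2)
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Writes, under `dir`: `genes.gtf`, `cell_types.tsv`, `expression.tsv`,
#' `states.bed`, `embeddings.tsv`, one `pairs/<cell>.pairs` file per cell,
#' and `ledger.json` recording every count and generative parameter (used by
#' tests to verify that the readers recover exactly what was written).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @return the ledger (invisibly).
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(file.path(dir, "pairs"), recursive = TRUE, showWarnings = FALSE)
  genes <- sim_gene_table(cfg)
  write_gene_annotation(genes, file.path(dir, "genes.gtf"))

  types <- sprintf("type%d", seq_len(cfg$n_cell_types))
  cells <- data.table::data.table(
    cell_id = unlist(lapply(types, function(t)
      sprintf("%s_c%03d", t, seq_len(cfg$cells_per_type)))),
    cell_type = rep(types, each = cfg$cells_per_type)
  )
  write_cell_types(stats::setNames(cells$cell_type, cells$cell_id),
                   file.path(dir, "cell_types.tsv"))

  # type-specific hub gene pairs, per chromosome
  all_pairs <- t(utils::combn(cfg$genes_per_chromosome, 2))
  n_hub <- max(1, round(cfg$hub_fraction * nrow(all_pairs)))
  hubs_by_type <- lapply(seq_len(cfg$n_cell_types), function(t) {
    lapply(seq_len(cfg$n_chromosomes), function(ch) {
      sel <- with_seed(derive_seed(cfg$seed, sprintf("hubs-t%d-ch%d", t, ch)),
                       sample.int(nrow(all_pairs), n_hub))
      data.table::data.table(i = all_pairs[sel, 1], j = all_pairs[sel, 2])
    })
  })

  # contacts per cell -> pairs files + per-gene contact degree
  n_genes_total <- nrow(genes)
  degree <- matrix(0, n_genes_total, nrow(cells),
                   dimnames = list(genes$gene_id, cells$cell_id))
  contact_counts <- integer(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    t_idx <- match(cells$cell_type[ci], types)
    rec <- sim_contacts_for_cell(
      cfg, t_idx, derive_seed(cfg$seed, paste0("contacts:", cells$cell_id[ci])),
      hubs_by_type[[t_idx]])
    cs <- new_contact_set(cells$cell_id[ci], cells$cell_type[ci], rec)
    write_pairs(cs, file.path(dir, "pairs", paste0(cells$cell_id[ci], ".pairs")))
    contact_counts[ci] <- nrow(rec)
    for (side in c("pos1", "pos2")) {
      gi <- sim_gene_at(rec[[side]], cfg)
      ch <- as.integer(sub("chr", "", rec$chrom))
      ok <- !is.na(gi)
      gidx <- (ch[ok] - 1L) * cfg$genes_per_chromosome + gi[ok]
      tab <- table(gidx)
      degree[as.integer(names(tab)), ci] <- degree[as.integer(names(tab)), ci] + as.integer(tab)
    }
  }

  # Zero-inflated expression: per-entry Bernoulli mask x Gamma magnitude.
  # Both the expression probability and the nonzero magnitude increase with
  # the gene's contact degree in its cell (signal_strength = 0 decouples
  # them). The mask concentrates a signal_strength-dependent share of the
  # expression budget on each cell's top-degree genes: because both ends of
  # a hub pair accumulate the same contacts, they co-rank and co-express,
  # which is what lets the expression signal travel along graph edges. The
  # per-cell mask probabilities average exactly 1 - zero_fraction.
  mean_deg <- max(mean(degree), 1e-9)
  phi <- 1 - exp(-0.45 * cfg$signal_strength)  # share of budget on top genes
  p_top <- 0.9
  expressed_rate <- 1 - cfg$zero_fraction
  p_express <- apply(degree, 2, function(dc) {
    n <- length(dc)
    if (phi <= 0) return(rep(expressed_rate, n))
    n_top <- max(1, round(min(0.9, phi * expressed_rate / p_top) * n))
    top_idx <- order(-dc)[seq_len(n_top)]  # deterministic tie-break by index
    p_rest <- max(0, (expressed_rate * n - p_top * n_top) / (n - n_top))
    p <- rep(p_rest, n)
    p[top_idx] <- p_top
    p
  })
  counts <- with_seed(derive_seed(cfg$seed, "expression"), {
    mask <- matrix(runif(length(degree)) < p_express, nrow(degree))
    mag <- matrix(rgamma(length(degree), shape = 2, scale = 1), nrow(degree)) *
      (1 + cfg$signal_strength * degree / mean_deg)
    m <- ifelse(mask, pmax(1, round(mag)), 0)
    dimnames(m) <- dimnames(degree)
    m
  })
  em <- structure(list(counts = counts,
                       cell_types = stats::setNames(cells$cell_type, cells$cell_id)),
                  class = "expression_matrix")
  write_expression(em, file.path(dir, "expression.tsv"))

  # chromatin-state segmentation: 20-kb windows with random states
  vocab <- paste0("E", 1:9)
  L <- sim_chrom_length(cfg)
  win <- 20000
  starts <- seq(0, L - 1, by = win)
  state_rows <- with_seed(derive_seed(cfg$seed, "states"), {
    data.table::rbindlist(lapply(seq_len(cfg$n_chromosomes), function(ch) {
      data.table::data.table(chrom = sprintf("chr%d", ch), start = starts,
                             end = pmin(starts + win, L),
                             state = sample(vocab, length(starts), replace = TRUE))
    }))
  })
  writeLines(sprintf("%s\t%d\t%d\t%s", state_rows$chrom, state_rows$start,
                     state_rows$end, state_rows$state),
             file.path(dir, "states.bed"))

  emb <- simulate_embeddings(genes$gene_id, dim = cfg$embed_dim,
                             seed = derive_seed(cfg$seed, "embeddings"),
                             rank = cfg$embed_rank, noise_sd = cfg$embed_noise_sd)
  write_embedding_table(emb, file.path(dir, "embeddings.tsv"))

  ledger <- list(
    config = unclass(cfg),
    cell_ids = cells$cell_id,
    cell_types = cells$cell_type,
    n_cells = nrow(cells),
    n_genes = n_genes_total,
    genes_per_chromosome = cfg$genes_per_chromosome,
    contact_counts = stats::setNames(as.list(contact_counts), cells$cell_id),
    n_state_intervals = nrow(state_rows),
    state_vocabulary = vocab,
    expression_dim = dim(counts),
    zero_fraction_realized = mean(counts == 0),
    embedding_dim = ncol(emb)
  )
  jsonlite::write_json(ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ledger)
}

#' Planted well-separated expression profiles for clustering checks
#'
#' Gives each cell type its own mean expression profile with between-type
#' shifts much larger than the within-type noise, so K-means at k = number
#' of types recovers the types exactly.
#'
#' @param n_types number of types (default 3).
#' @param cells_per_type cells per type.
#' @param n_genes genes (columns).
#' @param shift between-type mean shift (default 5).
#' @param noise_sd within-type noise (default 1).
#' @param seed integer seed.
#' @return list: `expr` (cells x genes), `cell_types`.
#' @export
simulate_planted_expression <- function(n_types = 3, cells_per_type = 50,
                                        n_genes = 40, shift = 5, noise_sd = 1,
                                        seed = 1L) {
  with_seed(seed, {
    centers <- matrix(rnorm(n_types * n_genes, sd = shift), n_types, n_genes)
    expr <- do.call(rbind, lapply(seq_len(n_types), function(t) {
      matrix(rnorm(cells_per_type * n_genes, sd = noise_sd),
             cells_per_type, n_genes) +
        matrix(centers[t, ], cells_per_type, n_genes, byrow = TRUE)
    }))
    list(expr = expr,
         cell_types = rep(sprintf("type%d", seq_len(n_types)),
                          each = cells_per_type))
  })
}
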