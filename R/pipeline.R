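# ---------------------------------------------------------------------------
# End-to-end orchestration: dataset directory -> node features -> meta-cells
# -> per-chromosome gene graphs with splits, and evaluation of a trained
# model against the naive baselines.
# ---------------------------------------------------------------------------

#' Load a dataset directory
#'
#' Expects the layout written by [simulate_dataset()]: `genes.gtf`,
#' `cell_types.tsv`, `expression.tsv`, `states.bed`, `embeddings.tsv` and
#' `pairs/<cell>.pairs`.
#'
#' @param dir dataset directory.
#' @return list: `genes`, `expression`, `states`, `embeddings`, `contacts`
#'   (list of `contact_set` keyed by cell id).
#' @export
load_dataset <- function(dir) {
  genes <- read_gene_annotation(file.path(dir, "genes.gtf"))
  expression <- read_expression(file.path(dir, "expression.tsv"),
                                file.path(dir, "cell_types.tsv"))
  states <- read_state_track(file.path(dir, "states.bed"))
  embeddings <- read_embedding_table(file.path(dir, "embeddings.tsv"))
  cells <- colnames(expression$counts)
  contacts <- lapply(cells, function(cid) {
    read_pairs(file.path(dir, "pairs", paste0(cid, ".pairs")), cid,
               expression$cell_types[[cid]])
  })
  names(contacts) <- cells
  list(genes = genes, expression = expression, states = states,
       embeddings = embeddings, contacts = contacts)
}

# top-k neighbour selection shared by build_metacell and the batch builder:
# descending similarity, ties towards the lexicographically smaller cell id
select_top_k <- function(sims, ids, k) order(-sims, ids)[seq_len(k)]

#' Build all meta-cells of one cell type from a shared similarity matrix
#'
#' Equivalent to calling [build_metacell()] once per cell, but computes each
#' pairwise similarity only once.
#'
#' @param cells list of `contact_set`, all of one cell type.
#' @param k neighbours per meta-cell.
#' @param bin_size similarity bin width.
#' @return named list of `metacell` (one per input cell).
#' @export
build_metacells <- function(cells, k = 20, bin_size = 1e6) {
  nc <- length(cells)
  ids <- vapply(cells, function(c) c$cell_id, "")
  if (nc - 1 < k) {
    stop_fmt("meta-cell needs %d same-type neighbours but only %d are available; lower k or supply more cells",
             k, nc - 1)
  }
  simmat <- diag(1, nc)
  if (k > 0 && nc > 1) {
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        simmat[i, j] <- simmat[j, i] <- cell_similarity(cells[[i]], cells[[j]], bin_size)
      }
    }
  }
  out <- lapply(seq_len(nc), function(i) {
    if (k == 0) {
      return(structure(list(target = cells[[i]], neighbors = list(),
                            similarities = numeric(), member_count = 1L),
                       class = "metacell"))
    }
    others <- setdiff(seq_len(nc), i)
    sel <- others[select_top_k(simmat[i, others], ids[others], k)]
    structure(list(target = cells[[i]], neighbors = cells[sel],
                   similarities = simmat[i, sel],
                   member_count = as.integer(k + 1)),
              class = "metacell")
  })
  names(out) <- ids
  out
}

#' Build every per-chromosome gene graph of a dataset
#'
#' Normalizes the expression matrix (dropping never-expressed genes), warns
#' about and drops expressed genes absent from the annotation, assembles and
#' PCA-projects the node features once (they are cell-independent), builds
#' per-type meta-cells, and assembles one graph per cell x chromosome.
#' Train/validation/test splits are assigned by cell type.
#'
#' @param dataset list from [load_dataset()].
#' @param k meta-cell neighbours (default 20; 0 = single-cell mode).
#' @param n_components node-feature width after PCA.
#' @param bin_size similarity bin width in bp.
#' @param state_grouping state -> 3-group map (default
#'   [default_state_grouping()] over the states present).
#' @param splits optional named list of cell-type character vectors
#'   (`train`, `val`, `test`).
#' @param clip_percentile expression clip percentile (default 98).
#' @return list: `graphs`, `manifest`, `projection`, `normalizer`,
#'   `cell_types`, `genes` (retained), `in_edge_dim`.
#' @export
build_graph_dataset <- function(dataset, k = 20, n_components = 100,
                                bin_size = 1e6, state_grouping = NULL,
                                splits = NULL, clip_percentile = 98) {
  norm <- normalize_expression(dataset$expression, clip_percentile)
  retained <- norm$retained_gene_ids
  missing <- setdiff(retained, dataset$genes$gene_id)
  if (length(missing) > 0) {
    warn_fmt("%d expressed gene(s) absent from the annotation were dropped: %s",
             length(missing), paste(head(missing, 5), collapse = ", "))
    retained <- setdiff(retained, missing)
  }
  genes <- dataset$genes[dataset$genes$gene_id %in% retained, ]
  expr <- norm$normalized[genes$gene_id, , drop = FALSE]

  grouping <- state_grouping %||% default_state_grouping(sort(unique(dataset$states$state)))
  raw_feats <- assemble_node_features(genes, dataset$embeddings,
                                      dataset$states, grouping)
  projection <- fit_projection(raw_feats, n_components)
  node_feats <- project_features(projection, raw_feats)

  cell_types <- dataset$expression$cell_types
  chroms <- unique(genes$chrom)
  metacells <- list()
  for (tp in unique(cell_types)) {
    tp_cells <- dataset$contacts[names(cell_types)[cell_types == tp]]
    metacells <- c(metacells, build_metacells(tp_cells, k = k, bin_size = bin_size))
  }

  # pair counts are per (cell, chromosome); compute each once
  counts_cache <- lapply(dataset$contacts, function(cs) {
    stats::setNames(lapply(chroms, function(ch) pair_contact_counts(cs, genes, ch)),
                    chroms)
  })

  split_of <- function(tp) {
    if (is.null(splits)) return(NA_character_)
    for (s in names(splits)) if (tp %in% splits[[s]]) return(s)
    NA_character_
  }
  graphs <- list()
  split_vec <- character()
  for (cid in names(dataset$contacts)) {
    mc <- metacells[[cid]]
    member_ids <- vapply(metacell_members(mc), function(c) c$cell_id, "")
    for (ch in chroms) {
      on_ch <- genes$chrom == ch
      gph <- build_gene_graph(
        mc, genes, ch,
        node_features = node_feats[on_ch, , drop = FALSE],
        expression_row = stats::setNames(expr[genes$gene_id[on_ch], cid],
                                         genes$gene_id[on_ch]),
        member_counts = lapply(member_ids, function(m) counts_cache[[m]][[ch]])
      )
      if (!is.null(gph)) {
        graphs[[length(graphs) + 1]] <- gph
        split_vec <- c(split_vec, split_of(cell_types[[cid]]))
      }
    }
  }
  manifest <- data.table::data.table(
    cell_id = vapply(graphs, function(g) g$cell_id, ""),
    chrom = vapply(graphs, function(g) g$chrom, ""),
    n_nodes = vapply(graphs, function(g) g$n, 0L),
    n_edges = vapply(graphs, function(g) nrow(g$edges), 0L),
    split = split_vec
  )
  list(graphs = graphs, manifest = manifest, projection = projection,
       normalizer = norm$normalizer, cell_types = cell_types, genes = genes,
       in_edge_dim = k + 3)
}

#' Evaluate trained-model and baseline predictions over a set of graphs
#'
#' Runs the trained model (clamped predictions) and both naive predictors on
#' every graph and returns evaluation reports plus the paired per-graph
#' comparison statistics.
#'
#' @param params `model_params`.
#' @param graphs list of `gene_graph`.
#' @param config `model_config`.
#' @return list: `predictions` (data.table with model and baseline columns),
#'   `model`, `naive1`, `naive2` (`eval_report`s), `vs_naive1`, `vs_naive2`
#'   ([compare_models()] results).
#' @export
evaluate_model <- function(params, graphs, config) {
  per_graph <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    data.table::data.table(
      graph = i, cell_id = g$cell_id, chrom = g$chrom, gene_id = g$gene_ids,
      y_true = g$targets,
      y_pred = model_forward(g, params, config, clamp = TRUE),
      naive1 = naive_predict(g, mode = 1),
      naive2 = naive_predict(g, mode = 2)
    )
  })
  preds <- data.table::rbindlist(per_graph)
  list(
    predictions = preds,
    model = eval_report(preds$y_pred, preds$y_true, chrom = preds$chrom),
    naive1 = eval_report(preds$naive1, preds$y_true, chrom = preds$chrom),
    naive2 = eval_report(preds$naive2, preds$y_true, chrom = preds$chrom),
    vs_naive1 = compare_models(abs(preds$y_pred - preds$y_true),
                               abs(preds$naive1 - preds$y_true), preds$graph),
    vs_naive2 = compare_models(abs(preds$y_pred - preds$y_true),
                               abs(preds$naive2 - preds$y_true), preds$graph)
  )
}

#' Serialize an evaluation report to JSON
#' @param report list from [evaluate_model()] or an `eval_report`.
#' @param path output JSON path.
#' @export
write_eval_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "eval_report")) x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  keep <- report[setdiff(names(report), "predictions")]
  jsonlite::write_json(strip(keep), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
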