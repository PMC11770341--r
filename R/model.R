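# ---------------------------------------------------------------------------
# Edge-gated graph transformer.
#
# Each block computes, per attention head, a query/key/value projection of
# the node states and an affine encoding of the edge features. Two attention
# scores are formed over each node's neighbourhood — one from the encoded
# edge alone, one from key + edge — normalized with an exponential
# dot-product softmax, and mixed by a learned sigmoid gate. Messages
# alpha * (value + encoded edge) are aggregated per node, heads are
# concatenated (averaged in the final block), and a gated residual with
# LayerNorm + ReLU counters over-smoothing. Between blocks the edge feature
# is updated to the per-head concatenation of (attention weight, encoded
# edge). A final affine readout maps each node state to one scalar
# prediction.
#
# All of this is implemented directly in base R matrix algebra, together
# with the analytic reverse-mode gradients in model_grad.R.
# ---------------------------------------------------------------------------

#' Model configuration
#'
#' @param n_blocks number of transformer blocks (default 3).
#' @param n_heads attention heads H (default 10).
#' @param head_dim per-head hidden size d (default 16); the node hidden width
#'   between blocks is `n_heads * head_dim`.
#' @param in_node_dim input node-feature width (default 100).
#' @param in_edge_dim input edge-feature width (23 for the default 20-neighbour
#'   meta-cell, 3 in single-cell mode).
#' @param seed seed for parameter initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(n_blocks = 3, n_heads = 10, head_dim = 16,
                         in_node_dim = 100, in_edge_dim = 23, seed = 1L) {
  stopifnot(n_blocks >= 1, n_heads >= 1, head_dim >= 1,
            in_node_dim >= 1, in_edge_dim >= 1)
  structure(list(n_blocks = n_blocks, n_heads = n_heads, head_dim = head_dim,
                 in_node_dim = in_node_dim, in_edge_dim = in_edge_dim,
                 seed = as.integer(seed)),
            class = "model_config")
}

# Per-block dimensions implied by a config: node/edge input widths and the
# aggregated output width (concat blocks: H*d; final mean block: d).
block_dims <- function(config) {
  H <- config$n_heads; d <- config$head_dim
  lapply(seq_len(config$n_blocks), function(o) {
    list(
      node_in = if (o == 1) config$in_node_dim else H * d,
      edge_in = if (o == 1) config$in_edge_dim else H * (1 + d),
      out = if (o == config$n_blocks) d else H * d,
      mode = if (o == config$n_blocks) "mean" else "concat"
    )
  })
}

init_affine <- function(n_out, n_in) {
  bound <- 1 / sqrt(n_in)
  list(W = matrix(runif(n_out * n_in, -bound, bound), n_out, n_in),
       b = runif(n_out, -bound, bound))
}

#' Initialize all trainable parameters of the model
#'
#' Uniform fan-in scaled initialization, fully determined by `config$seed`.
#'
#' @param config a `model_config`.
#' @return nested parameter list (`blocks`, `readout`), classed
#'   `model_params`.
#' @export
init_model_params <- function(config) {
  dims <- block_dims(config)
  H <- config$n_heads; d <- config$head_dim
  with_seed(config$seed, {
    blocks <- lapply(seq_len(config$n_blocks), function(o) {
      dm <- dims[[o]]
      heads <- lapply(seq_len(H), function(h) {
        q <- init_affine(d, dm$node_in)
        k <- init_affine(d, dm$node_in)
        v <- init_affine(d, dm$node_in)
        e <- init_affine(d, dm$edge_in)
        list(Wq = q$W, bq = q$b, Wk = k$W, bk = k$b,
             Wv = v$W, bv = v$b, We = e$W, be = e$b)
      })
      r <- init_affine(dm$out, dm$node_in)
      list(heads = heads,
           Wl = runif(3, -1 / sqrt(3), 1 / sqrt(3)),
           Wr = r$W, br = r$b,
           Wg = runif(3 * dm$out, -1 / sqrt(3 * dm$out), 1 / sqrt(3 * dm$out)))
    })
    ro <- init_affine(1, d)
    structure(list(blocks = blocks,
                   readout = list(w = as.numeric(ro$W), b = ro$b)),
              class = "model_params")
  })
}

# --- grouped softmax helpers (receiver-node neighbourhood normalization) ---

group_stat <- function(s, f, fun) {
  m <- tapply(s, f, fun)
  as.numeric(m[f])
}

# softmax of scores s within groups f, computed in log space with per-group
# max subtraction (the raw exponential dot-products overflow for large
# logits)
group_softmax <- function(s, f) {
  z <- exp(s - group_stat(s, f, max))
  z / group_stat(z, f, sum)
}

# scatter-add rows of x (one per directed edge) into an n-row matrix by
# receiver index
scatter_rows <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

add_bias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

layer_norm_eps <- 1e-5

# --- forward pass -----------------------------------------------------------

# One block. G: n x node_in; E: m_dir x edge_in (directed, both orientations
# present); ei/ej: receiver/sender node index per directed edge; f: receiver
# factor. Returns G_out, E_out (NULL in the final block) and, when cache =
# TRUE, every intermediate the backward pass needs.
forward_block <- function(G, E, ei, ej, f, block, dm, config, cache = FALSE) {
  n <- nrow(G)
  H <- config$n_heads
  d <- config$head_dim
  m_dir <- length(ei)
  heads <- vector("list", H)
  M_list <- vector("list", H)
  for (h in seq_len(H)) {
    p <- block$heads[[h]]
    Q <- add_bias(tcrossprod(G, p$Wq), p$bq)
    K <- add_bias(tcrossprod(G, p$Wk), p$bk)
    V <- add_bias(tcrossprod(G, p$Wv), p$bv)
    if (m_dir > 0) {
      Een <- add_bias(tcrossprod(E, p$We), p$be)
      Qe <- Q[ei, , drop = FALSE]
      s1 <- rowSums(Qe * Een) / sqrt(d)
      s2 <- rowSums(Qe * (K[ej, , drop = FALSE] + Een)) / sqrt(d)
      a1 <- group_softmax(s1, f)
      a2 <- group_softmax(s2, f)
      pre <- block$Wl[1] * a1 + block$Wl[2] * a2 + block$Wl[3] * (a1 - a2)
      rho <- sigmoid(pre)
      alpha <- rho * a1 + (1 - rho) * a2
      Msg <- scatter_rows((V[ej, , drop = FALSE] + Een) * alpha, ei, n)
    } else {
      Een <- matrix(numeric(), 0, d)
      s1 <- s2 <- a1 <- a2 <- rho <- alpha <- numeric()
      Msg <- matrix(0, n, d)
    }
    M_list[[h]] <- Msg
    heads[[h]] <- list(Q = Q, K = K, V = V, Een = Een,
                       a1 = a1, a2 = a2, rho = rho, alpha = alpha)
  }
  ghat <- if (dm$mode == "concat") do.call(cbind, M_list) else Reduce(`+`, M_list) / H
  r <- add_bias(tcrossprod(G, block$Wr), block$br)
  W <- dm$out
  pre_g <- as.numeric(cbind(ghat, r, ghat - r) %*% block$Wg)
  beta <- sigmoid(pre_g)
  u <- (1 - beta) * ghat + beta * r
  mu <- rowMeans(u)
  xc <- u - mu
  sigma <- sqrt(rowMeans(xc^2) + layer_norm_eps)
  xhat <- xc / sigma
  G_out <- pmax(xhat, 0)
  E_out <- NULL
  if (dm$mode == "concat") {
    # updated edge feature: per-head [alpha ; encoded edge], width H * (1 + d)
    E_out <- do.call(cbind, lapply(seq_len(H), function(h) {
      cbind(heads[[h]]$alpha, heads[[h]]$Een)
    }))
    if (m_dir == 0) E_out <- matrix(numeric(), 0, H * (1 + d))
  }
  out <- list(G_out = G_out, E_out = E_out)
  if (cache) {
    out$cache <- list(G = G, E = E, heads = heads, ghat = ghat, r = r,
                      beta = beta, xhat = xhat, sigma = sigma)
  }
  out
}

# Build directed-edge index structures for a graph (each undirected edge is
# materialized in both orientations with identical features).
directed_edges <- function(graph) {
  m <- nrow(graph$edges)
  if (m == 0) {
    return(list(ei = integer(), ej = integer(), f = factor(integer()),
                E = matrix(numeric(), 0, ncol(graph$edge_features))))
  }
  ei <- c(graph$edges[, 1], graph$edges[, 2])
  ej <- c(graph$edges[, 2], graph$edges[, 1])
  list(ei = ei, ej = ej, f = factor(ei, levels = sort(unique(ei))),
       E = rbind(graph$edge_features, graph$edge_features))
}

#' Pack several gene graphs into one batch with disjoint node ranges
#'
#' Because graphs share no edges after packing, a forward pass on the packed
#' batch equals the per-graph forward passes concatenated.
#'
#' @param graphs list of `gene_graph` (same feature widths).
#' @return a `gene_graph`-like batch with an extra `graph_of_node` index and
#'   `graph_ids`.
#' @export
pack_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  offsets <- cumsum(c(0L, vapply(graphs, function(g) g$n, 0L)))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edges
    if (nrow(e) == 0) matrix(integer(), ncol = 2) else e + offsets[i]
  }))
  structure(
    list(cell_id = "batch", chrom = "batch",
         gene_ids = unlist(lapply(graphs, function(g) g$gene_ids)),
         node_features = do.call(rbind, lapply(graphs, function(g) g$node_features)),
         edges = edges,
         edge_features = do.call(rbind, lapply(graphs, function(g) g$edge_features)),
         targets = unlist(lapply(graphs, function(g) g$targets)),
         n = offsets[length(offsets)],
         graph_of_node = rep(seq_along(graphs), vapply(graphs, function(g) g$n, 0L)),
         graph_ids = vapply(graphs, function(g) paste(g$cell_id, g$chrom), "")),
    class = "gene_graph"
  )
}

#' Forward pass of the graph transformer
#'
#' @param graph a `gene_graph` or packed batch ([pack_graphs()]).
#' @param params `model_params`.
#' @param config `model_config`.
#' @param clamp clamp predictions to [0, 1]? Use `TRUE` at inference; keep
#'   `FALSE` during loss computation so gradients stay clean.
#' @param cache keep intermediates for the backward pass?
#' @return numeric prediction vector (one per node); with `cache = TRUE`, a
#'   list `(pred, caches, idx)`.
#' @export
model_forward <- function(graph, params, config, clamp = FALSE, cache = FALSE) {
  dims <- block_dims(config)
  stopifnot(ncol(graph$node_features) == config$in_node_dim,
            ncol(graph$edge_features) == config$in_edge_dim)
  idx <- directed_edges(graph)
  G <- graph$node_features
  E <- idx$E
  caches <- vector("list", config$n_blocks)
  for (o in seq_len(config$n_blocks)) {
    res <- forward_block(G, E, idx$ei, idx$ej, idx$f,
                         params$blocks[[o]], dims[[o]], config, cache = cache)
    if (any(!is.finite(res$G_out))) {
      stop_fmt("non-finite node state after block %d", o)
    }
    G <- res$G_out
    E <- res$E_out
    if (cache) caches[[o]] <- res$cache
  }
  pred <- as.numeric(G %*% params$readout$w) + params$readout$b
  if (clamp) pred <- pmin(pmax(pred, 0), 1)
  if (cache) list(pred = pred, caches = caches, idx = idx, G_final = G) else pred
}

#' Predict expression for one or more graphs (inference mode)
#'
#' Runs the forward pass with predictions clamped to [0, 1].
#'
#' @param params `model_params`.
#' @param graphs a `gene_graph` or list of them.
#' @param config `model_config`.
#' @return for a single graph, a numeric vector; for a list, a data.table
#'   (`cell_id`, `chrom`, `gene_id`, `y_true`, `y_pred`).
#' @export
predict_expression <- function(params, graphs, config) {
  if (inherits(graphs, "gene_graph")) {
    return(model_forward(graphs, params, config, clamp = TRUE))
  }
  data.table::rbindlist(lapply(graphs, function(g) {
    data.table::data.table(cell_id = g$cell_id, chrom = g$chrom,
                           gene_id = g$gene_ids, y_true = g$targets,
                           y_pred = model_forward(g, params, config, clamp = TRUE))
  }))
}

# --- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints carry a format version, the config, the full parameter set,
#' the seed and any training state (epoch, optimizer moments, history).
#'
#' @param path file path (`.rds`).
#' @param params `model_params`.
#' @param config `model_config`.
#' @param training_state optional list from [train_model()].
#' @export
save_checkpoint <- function(path, params, config, training_state = NULL) {
  saveRDS(list(format = "schicexpr-checkpoint-v1", config = config,
               params = params, seed = config$seed,
               training_state = training_state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "schicexpr-checkpoint-v1")) {
    stop_fmt("not a recognized checkpoint: %s", path)
  }
  ck
}
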