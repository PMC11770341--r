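# ---------------------------------------------------------------------------
# Reverse-mode gradients of the graph transformer.
#
# Hand-derived, block by block, mirroring forward_block(); verified against
# central finite differences in the test suite. Gradients flow through the
# per-block edge updates as well (the attention weights of block o feed the
# edge features of block o + 1), so each block's backward returns both the
# node-state and the edge-feature gradients for the block below.
# ---------------------------------------------------------------------------

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) tree_map2(a[[i]], b[[i]], f))
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_add <- function(a, b) tree_map2(a, b, `+`)

# Backward through one block. dG_out: gradient at the block's node output;
# dE_out: gradient at the block's updated edge features (NULL for the final
# block). Returns dG (input node states), dE (input edge features) and the
# parameter gradients.
backward_block <- function(cache, dG_out, dE_out, block, dm, config, ei, ej, f) {
  H <- config$n_heads
  d <- config$head_dim
  W <- dm$out
  G <- cache$G
  E <- cache$E
  n <- nrow(G)
  m_dir <- length(ei)
  sqd <- sqrt(d)

  # ReLU then LayerNorm (no learnable affine)
  dxhat <- dG_out * (cache$xhat > 0)
  du <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) / cache$sigma
  beta <- cache$beta
  ghat <- cache$ghat
  r <- cache$r
  dghat <- du * (1 - beta)
  dr <- du * beta
  dbeta <- rowSums(du * (r - ghat))
  dpre_g <- dbeta * beta * (1 - beta)
  Wg1 <- block$Wg[seq_len(W)]
  Wg2 <- block$Wg[W + seq_len(W)]
  Wg3 <- block$Wg[2 * W + seq_len(W)]
  dghat <- dghat + outer(dpre_g, Wg1 + Wg3)
  dr <- dr + outer(dpre_g, Wg2 - Wg3)
  dWg <- c(as.numeric(crossprod(ghat, dpre_g)),
           as.numeric(crossprod(r, dpre_g)),
           as.numeric(crossprod(ghat - r, dpre_g)))
  dWr <- crossprod(dr, G)
  dbr <- colSums(dr)
  dG <- dr %*% block$Wr

  dWl <- numeric(3)
  dE <- if (m_dir > 0) matrix(0, m_dir, ncol(E)) else matrix(numeric(), 0, ncol(E))
  head_grads <- vector("list", H)
  for (h in seq_len(H)) {
    hc <- cache$heads[[h]]
    p <- block$heads[[h]]
    if (m_dir == 0) {
      head_grads[[h]] <- list(Wq = p$Wq * 0, bq = p$bq * 0, Wk = p$Wk * 0,
                              bk = p$bk * 0, Wv = p$Wv * 0, bv = p$bv * 0,
                              We = p$We * 0, be = p$be * 0)
      next
    }
    dM <- if (dm$mode == "concat") {
      dG_h <- dghat[, (h - 1) * d + seq_len(d), drop = FALSE]
      dG_h
    } else {
      dghat / H
    }
    alpha <- hc$alpha
    a1 <- hc$a1; a2 <- hc$a2; rho <- hc$rho
    Qe <- hc$Q[ei, , drop = FALSE]
    Kj <- hc$K[ej, , drop = FALSE]
    Msg_term <- hc$V[ej, , drop = FALSE] + hc$Een
    dM_e <- dM[ei, , drop = FALSE]
    dalpha <- rowSums(dM_e * Msg_term)
    dMsg_term <- dM_e * alpha
    dEen <- dMsg_term
    dV <- scatter_rows(dMsg_term, ej, n)
    if (!is.null(dE_out)) {
      base <- (h - 1) * (1 + d)
      dalpha <- dalpha + dE_out[, base + 1]
      dEen <- dEen + dE_out[, base + 1 + seq_len(d), drop = FALSE]
    }
    # gated mixing of the two attention scores
    drho <- dalpha * (a1 - a2)
    dpre_l <- drho * rho * (1 - rho)
    da1 <- dalpha * rho + dpre_l * (block$Wl[1] + block$Wl[3])
    da2 <- dalpha * (1 - rho) + dpre_l * (block$Wl[2] - block$Wl[3])
    dWl <- dWl + c(sum(dpre_l * a1), sum(dpre_l * a2), sum(dpre_l * (a1 - a2)))
    # softmax over each receiver's neighbourhood
    ds1 <- a1 * (da1 - group_stat(a1 * da1, f, sum))
    ds2 <- a2 * (da2 - group_stat(a2 * da2, f, sum))
    dQe_acc <- (hc$Een * ds1 + (Kj + hc$Een) * ds2) / sqd
    dEen <- dEen + Qe * (ds1 + ds2) / sqd
    dKe <- Qe * ds2 / sqd
    dQ <- scatter_rows(dQe_acc, ei, n)
    dK <- scatter_rows(dKe, ej, n)
    head_grads[[h]] <- list(
      Wq = crossprod(dQ, G), bq = colSums(dQ),
      Wk = crossprod(dK, G), bk = colSums(dK),
      Wv = crossprod(dV, G), bv = colSums(dV),
      We = crossprod(dEen, E), be = colSums(dEen)
    )
    dG <- dG + dQ %*% p$Wq + dK %*% p$Wk + dV %*% p$Wv
    dE <- dE + dEen %*% p$We
  }
  list(dG = dG, dE = dE,
       grads = list(heads = head_grads, Wl = dWl, Wr = dWr, br = dbr, Wg = dWg))
}

#' Gradients of a scalar loss with respect to all model parameters
#'
#' Takes the cached forward pass of [model_forward()] (`cache = TRUE`) and
#' the gradient of the loss with respect to the per-node predictions, and
#' returns gradients in the same nested layout as the parameters.
#'
#' @param fw list returned by `model_forward(..., cache = TRUE)`.
#' @param dpred numeric vector, dLoss/dprediction per node.
#' @param params `model_params`.
#' @param config `model_config`.
#' @return nested gradient list matching `params`.
#' @export
model_backward <- function(fw, dpred, params, config) {
  dims <- block_dims(config)
  dG <- outer(dpred, params$readout$w)
  dw <- as.numeric(crossprod(fw$G_final, dpred))
  db <- sum(dpred)
  dE <- NULL
  block_grads <- vector("list", config$n_blocks)
  for (o in rev(seq_len(config$n_blocks))) {
    bb <- backward_block(fw$caches[[o]], dG, dE, params$blocks[[o]],
                         dims[[o]], config, fw$idx$ei, fw$idx$ej, fw$idx$f)
    block_grads[[o]] <- bb$grads
    dG <- bb$dG
    dE <- bb$dE
  }
  list(blocks = block_grads, readout = list(w = dw, b = db))
}
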