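# Shared fixtures and independent oracles.

# random connected-ish gene graph with given feature widths
rand_graph <- function(n = 6, m = 7, nf = 5, ef = 4, seed = 1) {
  schicexpr:::with_seed(seed, {
    pairs <- t(combn(n, 2))
    m <- min(m, nrow(pairs))
    sel <- sample(nrow(pairs), m)
    structure(list(
      cell_id = paste0("cell", seed), chrom = "chr1",
      gene_ids = paste0("g", seq_len(n)),
      node_features = matrix(rnorm(n * nf), n, nf),
      edges = pairs[sel, , drop = FALSE],
      edge_features = matrix(rnorm(m * ef), m, ef),
      targets = runif(n), n = as.integer(n)
    ), class = "gene_graph")
  })
}

make_contact_set <- function(cell_id, chrom, pos1, pos2, cell_type = "typeA") {
  schicexpr:::new_contact_set(
    cell_id, cell_type,
    data.table::data.table(chrom = chrom, pos1 = as.integer(pos1),
                           pos2 = as.integer(pos2)))
}

# flatten a nested parameter list to a vector and back (finite differences)
flatten_params <- function(x) {
  if (is.list(x)) unlist(lapply(x, flatten_params), use.names = FALSE) else as.numeric(x)
}

set_flat_params <- function(tmpl, v) {
  i <- 0
  rec <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, rec)
      attributes(out) <- attributes(x)
      out
    } else {
      k <- length(x)
      r <- x
      r[] <- v[i + seq_len(k)]
      i <<- i + k
      r
    }
  }
  rec(tmpl)
}

# ---------------------------------------------------------------------------
# Straight-line re-implementation of the whole graph transformer forward
# pass: explicit loops over nodes, heads and neighbourhoods, naive
# exponential dot-products (no log-space), no sharing with the package
# implementation. Used as the whole-forward oracle.
# ---------------------------------------------------------------------------
oracle_forward <- function(graph, params, cfg) {
  H <- cfg$n_heads; d <- cfg$head_dim
  mu <- nrow(graph$edges)
  ei <- c(graph$edges[, 1], graph$edges[, 2])
  ej <- c(graph$edges[, 2], graph$edges[, 1])
  E <- rbind(graph$edge_features, graph$edge_features)
  if (mu == 0) E <- matrix(numeric(), 0, ncol(graph$edge_features))
  G <- graph$node_features
  n <- graph$n
  for (o in seq_len(cfg$n_blocks)) {
    blk <- params$blocks[[o]]
    last <- o == cfg$n_blocks
    width <- if (last) d else H * d
    alpha_all <- matrix(NA_real_, max(1, length(ei)), H)
    een_all <- vector("list", H)
    ghat <- matrix(0, n, width)
    head_msgs <- array(0, c(n, d, H))
    for (h in seq_len(H)) {
      p <- blk$heads[[h]]
      een <- matrix(0, length(ei), d)
      for (e in seq_along(ei)) een[e, ] <- p$We %*% E[e, ] + p$be
      een_all[[h]] <- een
      for (i in seq_len(n)) {
        nb <- which(ei == i)
        if (length(nb) == 0) next
        q <- p$Wq %*% G[i, ] + p$bq
        s1 <- numeric(length(nb)); s2 <- numeric(length(nb))
        for (t in seq_along(nb)) {
          e <- nb[t]; j <- ej[e]
          k <- p$Wk %*% G[j, ] + p$bk
          s1[t] <- exp(sum(q * een[e, ]) / sqrt(d))
          s2[t] <- exp(sum(q * (k + een[e, ])) / sqrt(d))
        }
        a1 <- s1 / sum(s1)
        a2 <- s2 / sum(s2)
        rho <- 1 / (1 + exp(-(blk$Wl[1] * a1 + blk$Wl[2] * a2 + blk$Wl[3] * (a1 - a2))))
        a <- rho * a1 + (1 - rho) * a2
        msg <- numeric(d)
        for (t in seq_along(nb)) {
          e <- nb[t]; j <- ej[e]
          v <- p$Wv %*% G[j, ] + p$bv
          msg <- msg + a[t] * (as.numeric(v) + een[e, ])
        }
        head_msgs[i, , h] <- msg
        alpha_all[nb, h] <- a
      }
    }
    for (i in seq_len(n)) {
      ghat[i, ] <- if (last) {
        rowMeans(head_msgs[i, , , drop = TRUE])
      } else {
        as.numeric(head_msgs[i, , ])
      }
    }
    Gnew <- matrix(0, n, width)
    for (i in seq_len(n)) {
      r <- as.numeric(blk$Wr %*% G[i, ] + blk$br)
      gi <- ghat[i, ]
      b <- 1 / (1 + exp(-sum(blk$Wg * c(gi, r, gi - r))))
      u <- (1 - b) * gi + b * r
      xh <- (u - mean(u)) / sqrt(mean((u - mean(u))^2) + 1e-5)
      Gnew[i, ] <- pmax(xh, 0)
    }
    G <- Gnew
    if (!last && length(ei) > 0) {
      Enew <- matrix(0, length(ei), H * (1 + d))
      for (e in seq_along(ei)) {
        Enew[e, ] <- unlist(lapply(seq_len(H), function(h) {
          c(alpha_all[e, h], een_all[[h]][e, ])
        }))
      }
      E <- Enew
    }
  }
  as.numeric(G %*% params$readout$w) + params$readout$b
}

# small end-to-end synthetic dataset shared by the slower tests; built once
# per test run
fixture_dataset_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "schicexpr-fixture")
      cfg <- sim_config(n_cell_types = 3, cells_per_type = 12,
                        n_chromosomes = 2, genes_per_chromosome = 25,
                        contacts_per_cell = 400, seed = 202L)
      simulate_dataset(cfg, dir)
    }
    dir
  }
})
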