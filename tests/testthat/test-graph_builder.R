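# brute-force similarity: explicit dense vectors over all (chrom,bin,bin) keys
brute_cosine <- function(a, b, bin_size) {
  keyify <- function(cs) {
    r <- cs$records
    if (nrow(r) == 0) return(table(character()))
    b1 <- r$pos1 %/% bin_size; b2 <- r$pos2 %/% bin_size
    table(paste(r$chrom, pmin(b1, b2), pmax(b1, b2)))
  }
  ta <- keyify(a); tb <- keyify(b)
  keys <- union(names(ta), names(tb))
  va <- as.numeric(ta[keys]); va[is.na(va)] <- 0
  vb <- as.numeric(tb[keys]); vb[is.na(vb)] <- 0
  if (sum(va) == 0 || sum(vb) == 0 || sum(va * vb) == 0) return(0)
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

test_that("cell similarity is cosine on binned contacts with pinned special cases", {
  a <- make_contact_set("a", "chr1", c(0, 10, 2e6), c(5, 15, 2e6 + 9))
  expect_equal(cell_similarity(a, a), 1.0)
  b <- make_contact_set("b", "chr1", 5e6, 5e6 + 1)  # disjoint bins
  expect_equal(cell_similarity(a, b), 0.0)
  # counts (1,2,0) vs (1,0,0) over three bins -> 1/sqrt(5)
  x <- make_contact_set("x", "chr1", c(0, 1e6, 1e6), c(1, 1e6 + 1, 1e6 + 2))
  y <- make_contact_set("y", "chr1", 0, 1)
  expect_equal(cell_similarity(x, y), 1 / sqrt(5))
  expect_equal(cell_similarity(x, y), cell_similarity(y, x))
  # matches brute-force dense cosine on random cells
  for (s in 1:5) {
    cs <- schicexpr:::with_seed(s, lapply(1:2, function(i) {
      p1 <- sample(0:(8e6), 40)
      make_contact_set(paste0("r", i), "chr1", p1, p1 + sample(1e6, 40))
    }))
    expect_equal(cell_similarity(cs[[1]], cs[[2]]), brute_cosine(cs[[1]], cs[[2]], 1e6))
  }
})

test_that("meta-cell selection matches an exhaustive sort with deterministic tie-break", {
  mk <- function(id, pos) make_contact_set(id, "chr1", pos, pos + 10)
  target <- mk("t", c(0, 1e6, 2e6))
  # population of exactly k -> all selected
  pop <- lapply(1:3, function(i) mk(paste0("p", i), i * 1e6))
  mc <- build_metacell(target, pop, k = 3)
  expect_equal(mc$member_count, 4L)
  expect_setequal(vapply(mc$neighbors, function(c) c$cell_id, ""), c("p1", "p2", "p3"))

  # identical similarity -> lexicographically smaller cell id first
  twin1 <- mk("zeta", 0); twin2 <- mk("alpha", 0)
  mc2 <- build_metacell(target, list(twin1, twin2), k = 2)
  expect_equal(vapply(mc2$neighbors, function(c) c$cell_id, ""), c("alpha", "zeta"))

  expect_error(build_metacell(target, pop, k = 10), "lower k")

  # planted similarity gradient: 30 cells sharing j bins with the target
  target2 <- mk("t2", (0:19) * 1e6)
  pop2 <- schicexpr:::with_seed(99, lapply(1:30, function(i) {
    shared <- sample(20, sample(3:18, 1)) - 1
    mk(sprintf("c%02d", i), c(shared * 1e6, (20:24) * 1e6 + i * 7))
  }))
  mc3 <- build_metacell(target2, pop2, k = 20)
  sims <- vapply(pop2, function(c) cell_similarity(target2, c), 0)
  ids <- vapply(pop2, function(c) c$cell_id, "")
  expected <- ids[order(-sims, ids)][1:20]
  expect_equal(vapply(mc3$neighbors, function(c) c$cell_id, ""), expected)
  expect_true(all(diff(mc3$similarities) <= 1e-12))
})

test_that("k = 0 meta-cells hold only the target", {
  t <- make_contact_set("t", "chr1", 0, 10)
  mc <- build_metacell(t, list(), k = 0)
  expect_equal(mc$member_count, 1L)
  expect_length(mc$neighbors, 0)
})

test_that("pair contact counts equal a brute-force double loop, overlapping genes included", {
  genes <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
    start = as.integer(seq(0, 1900, by = 100)),
    end = as.integer(seq(0, 1900, by = 100) + 150))  # neighbours overlap by 50
  genes[, midpoint := as.integer(floor((start + end) / 2))]

  # both ends outside all genes -> empty (gap positions do not exist here, use far pos)
  far <- make_contact_set("f", "chr1", 5000, 6000)
  expect_equal(nrow(pair_contact_counts(far, genes, "chr1")), 0)

  # one contact: pos1 in gene 1, pos2 inside both overlapping genes 2 and 3
  one <- make_contact_set("o", "chr1", 10, 210)
  pc <- pair_contact_counts(one, genes, "chr1")
  expect_equal(as.data.frame(pc), data.frame(i = c(1L, 1L), j = c(2L, 3L), count = c(1, 1)))

  cs <- schicexpr:::with_seed(7, make_contact_set(
    "r", "chr1", sample(0:2200, 200, replace = TRUE), sample(0:2200, 200, replace = TRUE)))
  got <- pair_contact_counts(cs, genes, "chr1")
  # brute force: double loop over contacts x gene pairs
  contains <- function(g, p) p >= genes$start[g] & p < genes$end[g]
  exp_counts <- new.env()
  for (r in seq_len(nrow(cs$records))) {
    g1 <- which(contains(seq_len(20), cs$records$pos1[r]))
    g2 <- which(contains(seq_len(20), cs$records$pos2[r]))
    for (a in g1) for (b in g2) {
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      exp_counts[[key]] <- (exp_counts[[key]] %||% 0) + 1
    }
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  expect_equal(nrow(got), length(ls(exp_counts)))
  for (r in seq_len(nrow(got))) {
    expect_equal(got$count[r], exp_counts[[paste(got$i[r], got$j[r])]])
  }
})

test_that("gene graphs carry the full edge-feature contract", {
  cfg <- sim_config(n_cell_types = 1, cells_per_type = 6, n_chromosomes = 1,
                    genes_per_chromosome = 15, contacts_per_cell = 150, seed = 5L)
  genes <- schicexpr:::sim_gene_table(cfg)
  genes[, midpoint := as.integer(floor((start + end) / 2))]
  cells <- lapply(1:6, function(i) {
    schicexpr:::with_seed(i * 11, {
      L <- schicexpr:::sim_chrom_length(cfg)
      make_contact_set(sprintf("c%d", i), "chr1",
                       sample(0:(L - 1), 150, TRUE), sample(0:(L - 1), 150, TRUE))
    })
  })
  mc <- build_metacell(cells[[1]], cells[-1], k = 5)
  nf <- matrix(rnorm(15 * 4), 15, 4)
  y <- stats::setNames(runif(15), genes$gene_id)
  g <- build_gene_graph(mc, genes, "chr1", nf, y)

  expect_equal(ncol(g$edge_features), 5 + 3)  # k + 3
  expect_gt(nrow(g$edges), 0)
  # mean column equals the mean of the per-member counts at machine precision
  k1 <- 6
  expect_equal(g$edge_features[, k1 + 1], rowMeans(g$edge_features[, 1:k1]))
  expect_false(any(g$edges[, 1] == g$edges[, 2]))
  expect_false(anyDuplicated(paste(g$edges[, 1], g$edges[, 2])) > 0)
  # independent per-member recount of the full edge feature matrix
  members <- schicexpr:::metacell_members(mc)
  for (e in sample(nrow(g$edges), 10)) {
    i <- g$edges[e, 1]; j <- g$edges[e, 2]
    for (m in seq_along(members)) {
      cnt <- 0
      rr <- members[[m]]$records
      for (r in seq_len(nrow(rr))) {
        in1 <- function(gg, p) p >= genes$start[gg] && p < genes$end[gg]
        if ((in1(i, rr$pos1[r]) && in1(j, rr$pos2[r])) ||
            (in1(j, rr$pos1[r]) && in1(i, rr$pos2[r]))) cnt <- cnt + 1
      }
      expect_equal(g$edge_features[e, m], cnt)
    }
    expect_equal(g$edge_features[e, k1 + 2],
                 log10(max(abs(genes$midpoint[i] - genes$midpoint[j]), 10)))
  }
  # targets and nodes
  expect_equal(g$targets, unname(y))
  expect_equal(g$n, 15)
})

test_that("edgeless meta-cells give node-only graphs and distances are floored", {
  genes <- data.table::data.table(gene_id = c("a", "b"), chrom = "chr1",
                                  start = c(0L, 100000L), end = c(2000L, 102000L))
  genes[, midpoint := as.integer(floor((start + end) / 2))]
  empty <- make_contact_set("t", "chr1", 50000L, 50001L)  # hits no gene
  mc <- build_metacell(empty, list(), k = 0)
  g <- build_gene_graph(mc, genes, "chr1", matrix(0, 2, 2), c(a = 0, b = 0))
  expect_equal(g$n, 2)
  expect_equal(nrow(g$edges), 0)

  # midpoints 1000 and 101000 -> log10(100000) = 5
  touching <- make_contact_set("t2", "chr1", 10L, 100010L)
  mc2 <- build_metacell(touching, list(), k = 0)
  g2 <- build_gene_graph(mc2, genes, "chr1", matrix(0, 2, 2), c(a = 0.2, b = 1))
  expect_equal(ncol(g2$edge_features), 3)  # single-cell mode: count, mean, distance
  expect_equal(g2$edge_features[1, ], c(1, 1, 5))

  # overlapping genes: distance floored at 10 bp -> feature 1.0
  genes2 <- data.table::data.table(gene_id = c("a", "b"), chrom = "chr1",
                                   start = c(0L, 1L), end = c(100L, 103L))
  genes2[, midpoint := as.integer(floor((start + end) / 2))]
  c3 <- make_contact_set("t3", "chr1", 0L, 101L)
  g3 <- build_gene_graph(build_metacell(c3, list(), k = 0), genes2, "chr1",
                         matrix(0, 2, 2), c(a = 0, b = 0))
  expect_equal(g3$edge_features[1, 3], 1.0)
})

test_that("graph serialization round-trips exactly and is byte-deterministic", {
  g <- rand_graph(n = 8, m = 11, nf = 6, ef = 5, seed = 3)
  td <- withr::local_tempdir()
  write_gene_graph(g, file.path(td, "g1.tsv"))
  g2 <- read_gene_graph(file.path(td, "g1.tsv"))
  expect_equal(g2$node_features, g$node_features)
  expect_equal(g2$edge_features, g$edge_features)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$targets, g$targets)
  write_gene_graph(g2, file.path(td, "g2.tsv"))
  expect_identical(readLines(file.path(td, "g1.tsv")), readLines(file.path(td, "g2.tsv")))

  man <- write_graph_dataset(list(g), file.path(td, "ds"), splits = "train")
  back <- read_graph_dataset(file.path(td, "ds"), split = "train")
  expect_equal(back$graphs[[1]]$edge_features, g$edge_features)
  expect_equal(man$n_edges, 11L)
})
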