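# ---------------------------------------------------------------------------
# Evaluation: regression + classification metrics on normalized expression,
# naive one-hop baselines, K-means/ARI cell-type clustering, and paired
# per-graph model comparison.
#
# "Accuracy" throughout is the fraction of predictions whose absolute error
# against the normalized ground truth is strictly below 0.1. Classification
# metrics binarize the truth as (value > 0) — expressed vs silent — and use
# the continuous prediction as the score (AP, AUC) or threshold it at 0.1
# for hard labels (F1, MCC).
# ---------------------------------------------------------------------------

#' Regression metrics between predictions and ground truth
#'
#' @param pred,true numeric vectors (length >= 2).
#' @param accuracy_tol absolute-error tolerance for the accuracy metric
#'   (default 0.1; the comparison is strict `<`).
#' @return list: `accuracy`, `pcc`, `scc`, `avg_abs_error`. Correlations are
#'   `NA` (with a warning) when either vector is constant.
#' @export
regression_metrics <- function(pred, true, accuracy_tol = 0.1) {
  stopifnot(length(pred) == length(true), length(pred) >= 2)
  abs_err <- abs(pred - true)
  if (sd(pred) == 0 || sd(true) == 0) {
    warn_fmt("constant vector: correlations undefined, reported as NA")
    pcc <- scc <- NA_real_
  } else {
    pcc <- cor(pred, true, method = "pearson")
    scc <- cor(pred, true, method = "spearman")
  }
  list(accuracy = mean(abs_err < accuracy_tol), pcc = pcc, scc = scc,
       avg_abs_error = mean(abs_err))
}

# average precision over distinct score thresholds:
# AP = sum_k (R_k - R_{k-1}) * P_k, descending-score order
average_precision <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  label <- label[ord]; score <- score[ord]
  n_pos <- sum(label)
  if (n_pos == 0) return(NA_real_)
  tp <- cumsum(label)
  fp <- cumsum(!label)
  last_of_tie <- c(score[-1] != score[-length(score)], TRUE)
  tp <- tp[last_of_tie]; fp <- fp[last_of_tie]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Classification metrics on binarized expression
#'
#' Truth labels are `true > 0`; AP and AUC use the continuous prediction as
#' score, F1 and MCC use hard labels `pred > threshold`. With single-class
#' truth, AP and AUC are `NA` with a warning. MCC is defined as 0 when any
#' marginal of the confusion matrix is empty.
#'
#' @param pred,true numeric vectors.
#' @param threshold hard-label threshold (default 0.1).
#' @return list: `ap`, `f1`, `mcc`, `auc`.
#' @export
classification_metrics <- function(pred, true, threshold = 0.1) {
  stopifnot(length(pred) == length(true))
  label <- true > 0
  if (length(unique(label)) < 2) {
    warn_fmt("single-class truth: AP and AUC undefined, reported as NA")
    ap <- auc <- NA_real_
  } else {
    ap <- average_precision(pred, label)
    auc <- as.numeric(pROC::auc(response = label, predictor = pred,
                                levels = c(FALSE, TRUE), direction = "<",
                                quiet = TRUE))
  }
  hard <- pred > threshold
  tp <- sum(hard & label); fp <- sum(hard & !label)
  fn <- sum(!hard & label); tn <- sum(!hard & !label)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (denom == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  list(ap = ap, f1 = f1, mcc = mcc, auc = auc)
}

#' Full evaluation report
#'
#' Combines [regression_metrics()] and [classification_metrics()] with the
#' spread statistics used for model comparison: the standard deviation of
#' the absolute errors and the normal-approximation 95% confidence interval
#' of the mean absolute error. When `chrom` is given, a per-chromosome
#' absolute-error summary table is attached.
#'
#' @param pred,true numeric vectors.
#' @param chrom optional chromosome label per observation.
#' @param accuracy_tol,threshold see the metric functions.
#' @return an `eval_report` list.
#' @export
eval_report <- function(pred, true, chrom = NULL,
                        accuracy_tol = 0.1, threshold = 0.1) {
  reg <- regression_metrics(pred, true, accuracy_tol)
  cls <- classification_metrics(pred, true, threshold)
  abs_err <- abs(pred - true)
  n <- length(abs_err)
  half <- qnorm(0.975) * sd(abs_err) / sqrt(n)
  rep <- c(reg, cls,
           list(error_sd = sd(abs_err),
                ci_mean_abs_error = c(mean(abs_err) - half, mean(abs_err) + half),
                n = n))
  if (!is.null(chrom)) {
    dt <- data.table::data.table(chrom = chrom, abs_err = abs_err)
    rep$per_chromosome <- dt[, .(
      n = .N, mean_abs_err = mean(abs_err), median_abs_err = stats::median(abs_err),
      q25 = quantile(abs_err, 0.25), q75 = quantile(abs_err, 0.75)
    ), by = chrom]
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n=%d\n",
                     "  accuracy %.3f  AP %.3f  F1 %.3f  PCC %.3f\n",
                     "  MCC %.3f  SCC %.3f  AUC %.3f  avg|err| %.4f\n"),
              x$n, x$accuracy, x$ap, x$f1, x$pcc, x$mcc, x$scc, x$auc,
              x$avg_abs_error))
  invisible(x)
}

#' Naive one-hop baseline predictors
#'
#' Mode 1 predicts each gene's expression as the plain mean of its one-hop
#' neighbours' true expression; mode 2 as the weighted mean with the edge's
#' log10 genomic distance as weight (taken literally — larger distance,
#' larger weight; set `weight_scheme = "inverse_distance"` for 1/distance
#' weights instead). Isolated nodes predict 0.
#'
#' @param graph a `gene_graph` with targets attached.
#' @param mode 1 or 2.
#' @param weight_scheme `"log10_distance"` (default) or
#'   `"inverse_distance"`; mode 2 only.
#' @return numeric prediction vector, one per node.
#' @export
naive_predict <- function(graph, mode = 1, weight_scheme = "log10_distance") {
  weight_scheme <- match.arg(weight_scheme, c("log10_distance", "inverse_distance"))
  pred <- numeric(graph$n)
  m <- nrow(graph$edges)
  if (m == 0) return(pred)
  ei <- c(graph$edges[, 1], graph$edges[, 2])
  ej <- c(graph$edges[, 2], graph$edges[, 1])
  y <- graph$targets
  if (mode == 1) {
    w <- rep(1, 2 * m)
  } else {
    logd <- graph$edge_features[, ncol(graph$edge_features)]
    w <- if (weight_scheme == "log10_distance") rep(logd, 2) else rep(10^(-logd), 2)
  }
  num <- rowsum(w * y[ej], ei)
  den <- rowsum(w, ei)
  pred[as.integer(rownames(num))] <- num / den
  pred
}

#' Cell-type clustering report (ARI-global / ARI-reduced)
#'
#' K-means with k = number of distinct cell types (10 restarts, seeded) on
#' the full cells x genes matrix gives ARI-global against the true labels;
#' a seeded 2-d UMAP embedding followed by K-means on the two coordinates
#' gives ARI-reduced. The embedding is returned for plotting.
#'
#' @param expr cells x genes numeric matrix (typically predicted or true
#'   normalized expression).
#' @param cell_types character/factor label per cell (>= 2 types).
#' @param seed RNG seed for K-means restarts and UMAP.
#' @return a `cluster_report`: list with `ari_global`, `ari_reduced`,
#'   `embedding` (cells x 2), `clusters_global`, `clusters_reduced`, `k`.
#' @export
clustering_report <- function(expr, cell_types, seed = 1L) {
  expr <- as.matrix(expr)
  k <- length(unique(cell_types))
  if (k < 2) stop_fmt("need at least 2 cell types, got %d", k)
  if (nrow(expr) < k) stop_fmt("fewer cells (%d) than clusters (%d)", nrow(expr), k)
  stopifnot(length(cell_types) == nrow(expr))
  km <- with_seed(derive_seed(seed, "kmeans-global"),
                  kmeans(expr, centers = k, nstart = 10, iter.max = 100))
  ari_global <- mclust::adjustedRandIndex(km$cluster, cell_types)
  emb <- with_seed(derive_seed(seed, "umap"), {
    uwot::umap(expr, n_neighbors = min(15, nrow(expr) - 1), n_threads = 1,
               n_sgd_threads = 0)
  })
  km2 <- with_seed(derive_seed(seed, "kmeans-reduced"),
                   kmeans(emb, centers = k, nstart = 10, iter.max = 100))
  structure(
    list(ari_global = ari_global,
         ari_reduced = mclust::adjustedRandIndex(km2$cluster, cell_types),
         embedding = emb, clusters_global = km$cluster,
         clusters_reduced = km2$cluster, k = k),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k=%d  ARI-global %.3f  ARI-reduced %.3f\n",
              x$k, x$ari_global, x$ari_reduced))
  invisible(x)
}

# Two-sided Wilcoxon signed-rank P-value for differences d (zeros already
# dropped). For n <= 25 the exact null distribution is computed by dynamic
# programming over doubled average ranks (so heavily tied differences — the
# norm for paired per-graph errors — still get an exact P); larger n uses
# the normal approximation with tie correction.
signed_rank_p <- function(d, exact_limit = 25) {
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    s <- as.integer(round(2 * r))  # doubled ranks are integers even with ties
    counts <- numeric(sum(s) + 1)  # counts[k+1] = #subsets with doubled sum k
    counts[1] <- 1
    for (si in s) {
      shifted <- c(numeric(si), counts[seq_len(length(counts) - si)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- round(2 * w)
    pl <- sum(probs[seq_len(w2 + 1)])
    pu <- sum(probs[(w2 + 1):length(probs)])
    return(min(1, 2 * min(pl, pu)))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (w - mu) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Paired per-graph comparison of two models' absolute errors
#'
#' For each graph, a two-sided Wilcoxon signed-rank test is run on the
#' paired absolute errors (zero differences dropped; graphs with fewer than
#' `min_pairs` usable pairs are skipped) and the per-graph P-values are
#' averaged. Also reports each model's overall error standard deviation and
#' the normal-approximation 95% CI of its mean absolute error.
#'
#' @param abs_err_a,abs_err_b paired absolute-error vectors.
#' @param graph_idx grouping index (one graph id per observation).
#' @param min_pairs minimum usable pairs per graph (default 5).
#' @return list: `mean_p`, `n_graphs_tested`, `sd_a`, `sd_b`, `ci_a`, `ci_b`.
#'   `mean_p` is `NA` when every graph was skipped (non-comparable models).
#' @export
compare_models <- function(abs_err_a, abs_err_b, graph_idx, min_pairs = 5) {
  stopifnot(length(abs_err_a) == length(abs_err_b),
            length(abs_err_a) == length(graph_idx))
  pvals <- unlist(lapply(split(seq_along(graph_idx), graph_idx), function(ii) {
    d <- abs_err_a[ii] - abs_err_b[ii]
    d <- d[d != 0]
    if (length(d) < min_pairs) return(NULL)
    signed_rank_p(d)
  }))
  ci <- function(e) {
    half <- qnorm(0.975) * sd(e) / sqrt(length(e))
    c(mean(e) - half, mean(e) + half)
  }
  if (length(pvals) == 0) {
    warn_fmt("no graph had %d or more nonzero paired differences; models are non-comparable", min_pairs)
  }
  list(mean_p = if (length(pvals) == 0) NA_real_ else mean(pvals),
       n_graphs_tested = length(pvals),
       sd_a = sd(abs_err_a), sd_b = sd(abs_err_b),
       ci_a = ci(abs_err_a), ci_b = ci(abs_err_b))
}
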