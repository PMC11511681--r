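#' Variation of Information between two partitions
#'
#' Information-theoretic metric between two labelings of the same elements:
#' `VI = H(p1) + H(p2) - 2 I(p1; p2)`, in nats. Zero iff the partitions are
#' identical up to label names.
#'
#' @param p1,p2 label vectors over the same elements (same length and order).
#' @return A non-negative number.
#' @export
variation_of_information <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("partitions must be over the same element set")
  n <- length(p1)
  tab <- table(p1, p2) / n
  px <- rowSums(tab); py <- colSums(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pj <- tab[tab > 0]
  hxy <- -sum(pj * log(pj))
  # VI = 2 H(X,Y) - H(X) - H(Y)
  2 * hxy - ent(px) - ent(py)
}

#' Spearman correlation distance between cells
#'
#' `d = (1 - rho) / 2` with `rho` the Spearman correlation between cells over
#' the given feature set; midranks for ties. Cells with zero variance have
#' undefined correlation; their distances are set to 0.5 (message emitted).
#'
#' @param m ExpressionMatrix (any layer) or a plain cells x features matrix.
#' @param features feature ids or indices to use (default: all).
#' @return symmetric cells x cells distance matrix with zero diagonal,
#'   entries in \[0, 1\].
#' @export
spearman_distance <- function(m, features = NULL) {
  x <- if (inherits(m, "ExpressionMatrix")) m$values else as.matrix(m)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 cells and 2 features")
  rho <- suppressWarnings(cor(t(x), method = "spearman"))
  if (anyNA(rho)) {
    message("constant cell(s): undefined correlations set to distance 0.5")
    rho[is.na(rho)] <- 0
  }
  d <- (1 - rho) / 2
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

# Cut an average-linkage dendrogram with a simplified hybrid rule: a static
# cut at a deepsplit-indexed quantile of the merge heights, followed by
# reassignment of clusters smaller than min_size to the nearest retained
# cluster by average distance. deepsplit 0..4 indexes increasingly aggressive
# cut heights (0.99, 0.95, 0.90, 0.80, 0.70 height quantiles).
hybrid_cut <- function(hc, d, deepsplit, min_size = 10) {
  stopifnot(deepsplit %in% 0:4)
  qs <- c(0.99, 0.95, 0.90, 0.80, 0.70)
  h <- quantile(hc$height, qs[deepsplit + 1], names = FALSE, type = 7)
  labs <- cutree(hc, h = h)
  sizes <- table(labs)
  retained <- as.integer(names(sizes)[sizes >= min_size])
  if (length(retained) == 0) return(rep(1L, length(labs)))
  small <- setdiff(as.integer(names(sizes)), retained)
  if (length(small)) {
    for (s in small) {
      members <- which(labs == s)
      avg <- vapply(retained, function(r)
        mean(d[members, labs == r & !(seq_along(labs) %in% members),
               drop = FALSE]), numeric(1))
      labs[members] <- retained[which.min(avg)]
    }
  }
  as.integer(factor(labs))
}

#' Hierarchical clustering with Variation-of-Information model selection
#'
#' Average-linkage hierarchical clustering on a Spearman correlation distance
#' matrix, cut with the hybrid rule at deepsplit values 0..4. The deepsplit is
#' chosen by a robustness scan: for each deepsplit, the partition on the full
#' feature set is compared (average VI) against partitions recomputed on
#' `n_subsamples` random feature subsamples (a fraction `subsample_fraction`
#' of features each). The chosen deepsplit is the one just before the largest
#' jump ('kick') of the average VI curve: `argmax_d avg_VI(d+1) - avg_VI(d)`,
#' ties resolved towards the smallest deepsplit.
#'
#' @param d cells x cells Spearman distance matrix (see
#'   [spearman_distance()]).
#' @param m ExpressionMatrix used to recompute distances on feature
#'   subsamples.
#' @param features feature set over which `d` was computed.
#' @param deepsplits candidate deepsplit values (default 0:4).
#' @param n_subsamples number of feature subsamples per deepsplit.
#' @param subsample_fraction fraction of features kept per subsample.
#' @param min_size minimum cluster size.
#' @param seed integer seed; each subsample uses its own derived stream.
#' @return list of class `ClusterModelSelection`: `deepsplits`, `partitions`
#'   (one integer vector per deepsplit), `avg_vi`, `chosen_deepsplit`,
#'   `partition` (the chosen one), `min_size`.
#' @export
cluster_with_vi_selection <- function(d, m, features,
                                      deepsplits = 0:4,
                                      n_subsamples = 50,
                                      subsample_fraction = 0.5,
                                      min_size = 10, seed = 0) {
  n <- nrow(d)
  if (n < 2 * min_size) {
    warning("too few cells for model selection; returning a single cluster")
    part <- rep(1L, n)
    out <- list(deepsplits = deepsplits,
                partitions = stats::setNames(rep(list(part),
                                                 length(deepsplits)),
                                             deepsplits),
                avg_vi = rep(NA_real_, length(deepsplits)),
                chosen_deepsplit = min(deepsplits), partition = part,
                min_size = min_size)
    class(out) <- "ClusterModelSelection"
    return(out)
  }
  hc <- hclust(stats::as.dist(d), method = "average")
  full <- lapply(deepsplits, function(ds) hybrid_cut(hc, d, ds, min_size))
  names(full) <- deepsplits

  vi_mat <- matrix(NA_real_, n_subsamples, length(deepsplits))
  for (i in seq_len(n_subsamples)) {
    feats_i <- with_seed(stream_seed(seed, i),
                         sample(features, max(2, floor(length(features) *
                                                        subsample_fraction))))
    d_i <- spearman_distance(m, feats_i)
    hc_i <- hclust(stats::as.dist(d_i), method = "average")
    for (k in seq_along(deepsplits)) {
      part_i <- hybrid_cut(hc_i, d_i, deepsplits[k], min_size)
      vi_mat[i, k] <- variation_of_information(full[[k]], part_i)
    }
  }
  avg_vi <- colMeans(vi_mat)
  if (length(deepsplits) > 1) {
    dvi <- diff(avg_vi)
    kick <- which.max(round(dvi, 12)) # ties -> smallest index
    chosen <- deepsplits[kick]
  } else chosen <- deepsplits[1]
  out <- list(deepsplits = deepsplits, partitions = full, avg_vi = avg_vi,
              chosen_deepsplit = chosen,
              partition = full[[as.character(chosen)]],
              min_size = min_size)
  class(out) <- "ClusterModelSelection"
  out
}

#' @exportS3Method base::print
print.ClusterModelSelection <- function(x, ...) {
  cat("ClusterModelSelection\n")
  for (k in seq_along(x$deepsplits))
    cat(sprintf("  deepsplit %d: %d clusters, avg VI %.4f%s\n",
                x$deepsplits[k],
                length(unique(x$partitions[[k]])), x$avg_vi[k],
                if (x$deepsplits[k] == x$chosen_deepsplit) "  <- chosen" else ""))
  invisible(x)
}

#' Partitioning Around Medoids split on a distance matrix
#'
#' Thin wrapper around [cluster::pam()] on a precomputed (Spearman) distance
#' matrix, used to split a cluster into `k` groups.
#'
#' @param d distance matrix over the cells to split.
#' @param cells optional subset (ids or indices) of cells to split.
#' @param k number of groups.
#' @return integer partition vector over the (subset of) cells.
#' @export
pam_split <- function(d, cells = NULL, k = 2) {
  if (!is.null(cells)) d <- d[cells, cells, drop = FALSE]
  if (k >= nrow(d)) stop("k must be smaller than the number of cells")
  if (k == 1) return(rep(1L, nrow(d)))
  as.integer(cluster::pam(stats::as.dist(d), k = k,
                          diss = TRUE, cluster.only = TRUE))
}

#' kNN-distance outlier detection
#'
#' Scores each cell by its Euclidean distance to its k-th nearest neighbour
#' and flags the top `contamination` fraction as outliers (ties broken by
#' cell index).
#'
#' @param m ExpressionMatrix or plain matrix, cells in rows.
#' @param features feature subset (default all).
#' @param k neighbour rank used as the score.
#' @param contamination fraction of cells to flag.
#' @return logical vector, TRUE for outliers; scores attached as attribute
#'   `"score"`.
#' @export
knn_outliers <- function(m, features = NULL, k = 5, contamination = 0.05) {
  x <- if (inherits(m, "ExpressionMatrix")) m$values else as.matrix(m)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of cells")
  dd <- as.matrix(dist(x))
  score <- apply(dd, 1, function(r) sort(r)[k + 1]) # +1 skips self
  n_flag <- floor(contamination * n)
  flag <- rep(FALSE, n)
  if (n_flag > 0)
    flag[order(score, decreasing = TRUE)[seq_len(n_flag)]] <- TRUE
  attr(flag, "score") <- score
  flag
}

#' Marker genes by pairwise Wilcoxon tests
#'
#' For every ordered pair of clusters, tests each gene with a two-sided
#' Wilcoxon rank-sum test (BH-adjusted across genes within each comparison)
#' and computes the log2 fold change on de-logged mean expression (pseudocount
#' 1e-9). A gene is selected as a marker of cluster `c` when at least one
#' comparison `c` vs `c'` shows log2FC > `lfc_min` and adjusted p <
#' `alpha`; a gene may mark more than one cluster. Within each cluster genes
#' are ranked by the average -log10 adjusted p over all its pairwise
#' comparisons.
#'
#' @param m ExpressionMatrix with a lognorm layer.
#' @param partition cluster label per cell (>= 2 clusters).
#' @param lfc_min log2 fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.1).
#' @return list of class `MarkerTable`: `pairwise` (long data.frame with
#'   cluster, other, gene, log2fc, p_value, adjusted_p) and `ranking`
#'   (data.frame with cluster, gene, rank_score, selected), sorted by
#'   cluster then decreasing rank_score.
#' @export
rank_markers <- function(m, partition, lfc_min = 1, alpha = 0.1) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "lognorm")
  u <- sort(unique(partition))
  if (length(u) < 2) stop("need at least 2 clusters")
  sizes <- table(partition)
  if (any(sizes < 3))
    warning("cluster(s) of size < 3; marker statistics will be unstable")
  x <- m$values
  genes <- feature_ids(m)
  idx <- lapply(u, function(cl) which(partition == cl))
  names(idx) <- u
  mean_de <- vapply(u, function(cl)
    expm1(colMeans(x[idx[[as.character(cl)]], , drop = FALSE])),
    numeric(ncol(x)))

  pw <- list()
  for (a in seq_along(u)) for (b in seq_along(u)) {
    if (a >= b) next
    p <- rank_sum_test(x, idx[[a]], idx[[b]])
    adj <- p.adjust(p, method = "BH")
    lfc <- log2((mean_de[, a] + 1e-9) / (mean_de[, b] + 1e-9))
    pw[[length(pw) + 1]] <- data.frame(
      cluster = u[a], other = u[b], gene = genes, log2fc = lfc,
      p_value = p, adjusted_p = adj, row.names = NULL)
    pw[[length(pw) + 1]] <- data.frame(
      cluster = u[b], other = u[a], gene = genes, log2fc = -lfc,
      p_value = p, adjusted_p = adj, row.names = NULL)
  }
  pairwise <- do.call(rbind, pw)

  ranking <- do.call(rbind, lapply(u, function(cl) {
    sub <- pairwise[pairwise$cluster == cl, ]
    neglog <- -log10(pmax(sub$adjusted_p, 1e-300))
    score <- tapply(neglog, sub$gene, mean)
    sel <- tapply(sub$log2fc > lfc_min & sub$adjusted_p < alpha,
                  sub$gene, any)
    data.frame(cluster = cl, gene = names(score),
               rank_score = as.numeric(score),
               selected = as.logical(sel[names(score)]), row.names = NULL)
  }))
  ranking <- ranking[order(ranking$cluster, -ranking$rank_score), ]
  rownames(ranking) <- NULL
  out <- list(pairwise = pairwise, ranking = ranking,
              lfc_min = lfc_min, alpha = alpha)
  class(out) <- "MarkerTable"
  out
}

#' Top selected markers of one cluster
#'
#' @param mt a [rank_markers()] result.
#' @param cluster cluster label.
#' @param n maximum number of genes.
#' @return character vector of gene ids, best ranked first.
#' @export
top_markers <- function(mt, cluster, n = 50) {
  sub <- mt$ranking[mt$ranking$cluster == cluster & mt$ranking$selected, ]
  utils::head(sub$gene, n)
}
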