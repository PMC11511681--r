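#' k-nearest-neighbour graph on principal components
#'
#' Runs PCA on the (lognorm) expression over the given features and builds a
#' kNN graph on the first `n_pcs` components, using either Euclidean
#' distance (sub-clustering) or Spearman correlation distance (pseudotime).
#'
#' @param m ExpressionMatrix with a lognorm layer.
#' @param features feature set (e.g. HVGs).
#' @param n_pcs number of principal components.
#' @param k number of neighbours (must be < number of cells).
#' @param distance `"euclidean"` or `"spearman"`.
#' @return list of class `knn_graph`: `indices` (n x k neighbour indices),
#'   `distances` (n x k), `scores` (n x n_pcs PC coordinates), `k`,
#'   `distance`, and `dist_matrix` (full cell-cell distances).
#' @export
knn_graph <- function(m, features = NULL, n_pcs = 10, k = 15,
                      distance = c("euclidean", "spearman")) {
  distance <- match.arg(distance)
  x <- if (inherits(m, "ExpressionMatrix")) m$values else as.matrix(m)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of cells")
  n_pcs <- min(n_pcs, ncol(x), n - 1)
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  dd <- if (distance == "euclidean") as.matrix(dist(scores))
        else spearman_distance(scores)
  idx <- t(apply(dd, 1, function(r) order(r)[2:(k + 1)]))
  dmat <- t(vapply(seq_len(n), function(i) dd[i, idx[i, ]], numeric(k)))
  structure(list(indices = idx, distances = dmat, scores = scores,
                 k = k, distance = distance, dist_matrix = dd),
            class = "knn_graph")
}

# Convert a knn_graph to an undirected igraph (union of directed kNN edges).
knn_to_igraph <- function(graph) {
  n <- nrow(graph$indices)
  edges <- cbind(rep(seq_len(n), each = graph$k), as.vector(t(graph$indices)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Community detection on a kNN graph
#'
#' Leiden community detection (modularity objective) at the given resolution.
#'
#' @param graph a [knn_graph()] object or an igraph graph.
#' @param resolution resolution parameter.
#' @param seed integer seed (Leiden refinement is stochastic).
#' @return integer membership vector.
#' @export
community_detect <- function(graph, resolution = 1, seed = 0) {
  g <- if (inherits(graph, "knn_graph")) knn_to_igraph(graph) else graph
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 3)))
  as.integer(memb)
}

#' Count specific marker genes per cluster
#'
#' A gene is specific to cluster `c` when its mean lognorm expression in `c`
#' exceeds `min_mean` and it is significantly upregulated (BH-adjusted
#' Wilcoxon p < `alpha`, positive log2 fold change) in every pairwise
#' comparison of `c` against each other cluster.
#'
#' @param m ExpressionMatrix with a lognorm layer.
#' @param partition cluster label per cell.
#' @param min_mean minimum mean lognorm expression in the home cluster.
#' @param alpha adjusted-p threshold.
#' @return named integer vector of counts per cluster; the specific gene ids
#'   are attached as attribute `"genes"` (a named list). Empty for a single
#'   cluster.
#' @export
count_specific_markers <- function(m, partition, min_mean = 0.01,
                                   alpha = 0.1) {
  u <- sort(unique(partition))
  if (length(u) < 2) {
    out <- integer(0)
    attr(out, "genes") <- list()
    return(out)
  }
  x <- m$values
  idx <- lapply(u, function(cl) which(partition == cl))
  genes <- feature_ids(m)
  means <- vapply(idx, function(ii) colMeans(x[ii, , drop = FALSE]),
                  numeric(ncol(x)))
  ok <- vector("list", length(u))
  for (a in seq_along(u)) ok[[a]] <- rep(TRUE, ncol(x))
  for (a in seq_along(u)) for (b in seq_along(u)) {
    if (a >= b) next
    p <- rank_sum_test(x, idx[[a]], idx[[b]])
    adj <- p.adjust(p, method = "BH")
    up_a <- means[, a] > means[, b]
    sig <- adj < alpha
    ok[[a]] <- ok[[a]] & sig & up_a
    ok[[b]] <- ok[[b]] & sig & !up_a
  }
  res <- integer(length(u))
  glist <- list()
  for (a in seq_along(u)) {
    spec_a <- ok[[a]] & means[, a] > min_mean
    res[a] <- sum(spec_a)
    glist[[as.character(u[a])]] <- genes[spec_a]
  }
  names(res) <- u
  attr(res, "genes") <- glist
  res
}

#' Merge clusters lacking specific-marker support
#'
#' Iteratively merges clusters with at most one specific marker into the
#' Euclidean-nearest remaining cluster (centroids in PC space), recomputing
#' marker counts after each merge, until every cluster has at least two
#' specific markers or a single cluster remains. The cluster count strictly
#' decreases each iteration, so termination is guaranteed.
#'
#' @param m ExpressionMatrix with a lognorm layer.
#' @param partition initial cluster labels.
#' @param scores cells x PCs coordinate matrix for centroid distances.
#' @param min_markers minimum number of specific markers (default 2).
#' @param min_mean,alpha passed to [count_specific_markers()].
#' @return integer partition with consecutive labels; final marker counts
#'   attached as attribute `"marker_counts"`.
#' @export
merge_unsupported <- function(m, partition, scores, min_markers = 2,
                              min_mean = 0.01, alpha = 0.1) {
  part <- as.integer(factor(partition))
  repeat {
    u <- sort(unique(part))
    counts <- count_specific_markers(m, part, min_mean, alpha)
    if (length(u) <= 1 || all(counts >= min_markers)) {
      part <- as.integer(factor(part))
      attr(part, "marker_counts") <-
        if (length(unique(part)) > 1)
          count_specific_markers(m, part, min_mean, alpha)
        else integer(0)
      return(part)
    }
    weak <- u[which.min(counts)]
    cent <- vapply(u, function(cl)
      colMeans(scores[part == cl, , drop = FALSE]), numeric(ncol(scores)))
    others <- setdiff(u, weak)
    dd <- vapply(others, function(cl)
      sqrt(sum((cent[, u == weak] - cent[, u == cl])^2)), numeric(1))
    part[part == weak] <- others[which.min(dd)]
  }
}

#' Sub-clustering over a (k, resolution) grid with robustness selection
#'
#' Evaluates Leiden clustering over a grid of neighbourhood sizes `ks` and
#' resolutions `rs` on the first `n_pcs` PCs of the given HVG set. Each grid
#' point's robustness is the average Variation of Information between its
#' partition and partitions recomputed on `n_subsamples` random half-gene
#' subsamples. Each partition is then post-processed with
#' [merge_unsupported()]. The selected partition is the post-merge partition
#' with more than one cluster that has the lowest average VI (ties towards
#' fewer clusters); when none has more than one cluster, a single cluster is
#' returned.
#'
#' @param m ExpressionMatrix with a lognorm layer.
#' @param features HVG set (typically top 2000).
#' @param ks,rs grid values (defaults: k 15..35 step 5, r 0.1..1 step 0.1).
#' @param n_pcs number of PCs.
#' @param n_subsamples gene subsamples per grid point.
#' @param subsample_fraction fraction of genes per subsample.
#' @param min_markers minimum specific markers per retained cluster.
#' @param seed integer seed.
#' @return list of class `SubclusterGridResult`: `grid` (data.frame k, r,
#'   n_clusters, avg_vi, n_clusters_postmerge), `partitions` and
#'   `postmerge_partitions` (lists), `selected` (partition), `selected_index`.
#' @export
grid_subcluster <- function(m, features, ks = seq(15, 35, by = 5),
                            rs = seq(0.1, 1, by = 0.1), n_pcs = 10,
                            n_subsamples = 50, subsample_fraction = 0.5,
                            min_markers = 2, seed = 0) {
  grid <- expand.grid(k = ks, r = rs)
  n_pt <- nrow(grid)
  parts <- vector("list", n_pt)
  post <- vector("list", n_pt)
  avg_vi <- numeric(n_pt)
  n_clusters <- integer(n_pt)
  n_post <- integer(n_pt)

  graphs <- lapply(ks, function(k) knn_graph(m, features, n_pcs, k))
  names(graphs) <- ks
  sub_graphs <- lapply(seq_len(n_subsamples), function(i) {
    feats_i <- with_seed(stream_seed(seed, i),
                         sample(features,
                                max(2, floor(length(features) *
                                               subsample_fraction))))
    gl <- lapply(ks, function(k) knn_graph(m, feats_i, n_pcs, k))
    names(gl) <- ks
    gl
  })

  for (i in seq_len(n_pt)) {
    k <- grid$k[i]; r <- grid$r[i]
    g <- graphs[[as.character(k)]]
    part <- community_detect(g, r, seed = stream_seed(seed, 9000 + i))
    vis <- vapply(seq_len(n_subsamples), function(s) {
      p_s <- community_detect(sub_graphs[[s]][[as.character(k)]], r,
                              seed = stream_seed(seed, 9000 + i))
      variation_of_information(part, p_s)
    }, numeric(1))
    parts[[i]] <- part
    avg_vi[i] <- mean(vis)
    n_clusters[i] <- length(unique(part))
    post[[i]] <- merge_unsupported(m, part, g$scores, min_markers)
    n_post[i] <- length(unique(post[[i]]))
  }
  grid$n_clusters <- n_clusters
  grid$avg_vi <- avg_vi
  grid$n_clusters_postmerge <- n_post

  multi <- which(n_post > 1)
  if (length(multi)) {
    ord <- multi[order(avg_vi[multi], n_post[multi])]
    sel_idx <- ord[1]
    selected <- post[[sel_idx]]
  } else {
    sel_idx <- NA_integer_
    selected <- rep(1L, nrow(m$values))
  }
  structure(list(grid = grid, partitions = parts,
                 postmerge_partitions = post, selected = selected,
                 selected_index = sel_idx),
            class = "SubclusterGridResult")
}

#' Supervised split on a gene signature
#'
#' Community detection on a kNN graph built from the signature genes only,
#' used to look for weak sub-populations that a full-HVG scan misses (e.g.
#' applying a later-stage subcluster signature to an earlier stage).
#'
#' @param m ExpressionMatrix with a lognorm layer.
#' @param signature_genes non-empty vector of feature ids.
#' @param k neighbours (default 15).
#' @param resolution Leiden resolution.
#' @param seed integer seed.
#' @return integer partition vector.
#' @export
signature_split <- function(m, signature_genes, k = 15, resolution = 1,
                            seed = 0) {
  if (length(signature_genes) == 0) stop("empty signature")
  sig <- intersect(signature_genes, feature_ids(m))
  if (length(sig) == 0) stop("no signature gene present in the features")
  x <- m$values[, sig, drop = FALSE]
  if (all(apply(x, 2, var) < 1e-12)) return(rep(1L, nrow(x)))
  g <- knn_graph(m, sig, n_pcs = min(10, length(sig)), k = k)
  community_detect(g, resolution, seed)
}
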