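#' Diffusion map from a kNN graph
#'
#' Builds a Gaussian affinity with per-cell adaptive bandwidth (distance to
#' the ceiling(k/2)-th neighbour), symmetrises it, applies density
#' normalisation (alpha = 1) to remove sampling-density effects, and
#' eigendecomposes the symmetric conjugate of the row-stochastic transition
#' matrix. Components are ordered by eigenvalue; DC1 is the trivial
#' (stationary) component and DC2 the first informative one. Signs are fixed
#' so the largest-magnitude entry of each component is positive.
#'
#' If the graph is disconnected, only the largest connected component is
#' used (with a warning) and the remaining cells get NA coordinates.
#'
#' @param graph a [knn_graph()] object.
#' @param n_comps number of diffusion components to keep.
#' @return list of class `DiffusionMap`: `transition` (row-stochastic T),
#'   `eigenvalues`, `components` (cells x n_comps, DC1..DCn),
#'   `phi` (orthonormal eigenvectors of the symmetric conjugate),
#'   `stationary` (stationary distribution of T), `cells` (indices used).
#' @export
diffusion_map <- function(graph, n_comps = 15) {
  stopifnot(inherits(graph, "knn_graph"))
  n <- nrow(graph$indices)
  k <- graph$k
  sigma <- graph$distances[, ceiling(k / 2)]
  sigma[sigma <= 0] <- min(sigma[sigma > 0], 1e-12)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- graph$indices[i, ]
    W[i, j] <- exp(-graph$distances[i, ]^2 / (sigma[i] * sigma[j]))
  }
  W <- pmax(W, t(W)) # symmetrise: union of kNN edges
  diag(W) <- 1       # self-affinity (kernel at distance 0)

  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  cells <- seq_len(n)
  if (comp$no > 1) {
    warning("kNN graph is disconnected; using the largest component (",
            max(comp$csize), " of ", n, " cells)")
    cells <- which(comp$membership == which.max(comp$csize))
    W <- W[cells, cells, drop = FALSE]
  }
  q <- rowSums(W)
  W <- W / outer(q, q) # density normalisation, alpha = 1
  d <- rowSums(W)
  Tmat <- W / d
  S <- W / sqrt(outer(d, d))
  eig <- eigen(S, symmetric = TRUE)
  nc <- min(n_comps, length(cells))
  lambda <- eig$values[seq_len(nc)]
  phi <- eig$vectors[, seq_len(nc), drop = FALSE]
  comps <- phi / sqrt(d) # right eigenvectors of T
  for (j in seq_len(nc)) {
    s <- sign(comps[which.max(abs(comps[, j])), j])
    if (s < 0) { comps[, j] <- -comps[, j]; phi[, j] <- -phi[, j] }
  }
  full_comps <- matrix(NA_real_, n, nc)
  full_comps[cells, ] <- comps
  colnames(full_comps) <- paste0("DC", seq_len(nc))
  stationary <- d / sum(d)
  structure(list(transition = Tmat, eigenvalues = lambda,
                 components = full_comps, phi = phi,
                 stationary = stationary, cells = cells),
            class = "DiffusionMap")
}

#' Diffusion pseudotime from a root cell
#'
#' Computes, for every cell, the diffusion-pseudotime distance to the root:
#' the Euclidean distance between rows of the accumulated transition
#' operator `M = (I - (S - phi1 phi1^T))^-1 - I` (equivalently
#' `sum_{i>=2} lambda_i/(1-lambda_i) phi_i phi_i^T` in the eigenbasis of the
#' symmetric conjugate S). The root is either an explicit cell or the cell
#' with the minimum/maximum value of DC2 — the choice is stage-dependent, so
#' it must be stated explicitly.
#'
#' @param dm a [diffusion_map()].
#' @param root explicit root cell index (in the original cell ordering), or
#'   NULL to use `root_dc2`.
#' @param root_dc2 `"min"` or `"max"`: root at the extremum of DC2.
#' @return list of class `PseudotimeResult`: `root`, `dpt` (>= 0 per cell;
#'   0 at the root; NA for cells outside the used component).
#' @export
dpt <- function(dm, root = NULL, root_dc2 = NULL) {
  stopifnot(inherits(dm, "DiffusionMap"))
  if (is.null(root) == is.null(root_dc2))
    stop("specify exactly one of `root` or `root_dc2` ('min'/'max')")
  dc2 <- dm$components[, 2]
  if (!is.null(root_dc2)) {
    root_dc2 <- match.arg(root_dc2, c("min", "max"))
    root <- if (root_dc2 == "min") which.min(dc2) else which.max(dc2)
  }
  if (!(root %in% dm$cells))
    stop("root cell is not in the connected component used by the map")
  lambda <- dm$eigenvalues
  if (sum(lambda > 1 - 1e-10) > 1)
    stop("eigenvalue 1 has multiplicity ", sum(lambda > 1 - 1e-10),
         "; the diffusion operator is reducible")
  w <- lambda[-1] / (1 - lambda[-1])
  phi <- dm$phi[, -1, drop = FALSE]
  root_local <- match(root, dm$cells)
  diffs <- sweep(phi, 2, phi[root_local, ])
  vals <- sqrt(rowSums(sweep(diffs, 2, w, `*`)^2))
  out <- rep(NA_real_, nrow(dm$components))
  out[dm$cells] <- vals
  structure(list(root = root, dpt = out), class = "PseudotimeResult")
}

#' Differential expression along pseudotime by smooth trends
#'
#' Fits each gene's lognorm expression as a cubic regression spline of the
#' pseudotime coordinate (4 effective degrees of freedom) and tests the fit
#' against an intercept-only model with an F-test; p-values are BH-adjusted.
#' Genes detected (value > 0) in fewer than `min_cells` cells are excluded,
#' and constant genes get p = 1.
#'
#' @param m ExpressionMatrix with a lognorm layer.
#' @param pt pseudotime coordinate per cell (a [dpt()] result or numeric).
#' @param min_cells minimum number of expressing cells.
#' @param fdr FDR threshold for the `significant` flag.
#' @param df spline degrees of freedom.
#' @return data.frame of class `TrendDEResult` with `gene`, `p_value`,
#'   `adjusted_p`, `significant`, `slope` (linear trend sign of the fitted
#'   curve); fitted values (genes x cells) attached as attribute `"fitted"`,
#'   excluded genes as attribute `"excluded"`.
#' @export
trend_de <- function(m, pt, min_cells = 10, fdr = 0.01, df = 4) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "lognorm")
  t_ <- if (inherits(pt, "PseudotimeResult")) pt$dpt else pt
  stopifnot(length(t_) == nrow(m$values))
  use <- !is.na(t_)
  x <- m$values[use, , drop = FALSE]
  t_ <- t_[use]
  detected <- colSums(x > 0)
  keep <- detected >= min_cells
  genes <- feature_ids(m)[keep]
  basis <- splines::ns(t_, df = df)
  X <- cbind(1, basis)
  qrX <- qr(X)
  n <- length(t_)
  p_model <- ncol(X)
  fitted <- matrix(NA_real_, length(genes), n,
                   dimnames = list(genes, rownames(x)))
  pvals <- numeric(length(genes))
  slopes <- numeric(length(genes))
  for (gi in seq_along(genes)) {
    y <- x[, genes[gi]]
    if (var(y) < 1e-15) {
      pvals[gi] <- 1; fitted[gi, ] <- mean(y); slopes[gi] <- 0
      next
    }
    fit <- qr.fitted(qrX, y)
    rss1 <- sum((y - fit)^2)
    rss0 <- sum((y - mean(y))^2)
    df1 <- p_model - 1
    df2 <- n - p_model
    Fstat <- ((rss0 - rss1) / df1) / (rss1 / max(df2, 1))
    pvals[gi] <- if (rss1 < 1e-12 * rss0) 0 else
      pf(Fstat, df1, df2, lower.tail = FALSE)
    fitted[gi, ] <- fit
    slopes[gi] <- suppressWarnings(cor(fit, t_))
    if (is.na(slopes[gi])) slopes[gi] <- 0
  }
  adj <- p.adjust(pvals, method = "BH")
  out <- data.frame(gene = genes, p_value = pvals, adjusted_p = adj,
                    significant = adj < fdr, slope = slopes,
                    stringsAsFactors = FALSE)
  class(out) <- c("TrendDEResult", "data.frame")
  attr(out, "fitted") <- fitted
  attr(out, "pseudotime") <- t_
  attr(out, "excluded") <- feature_ids(m)[!keep]
  out
}

#' Group significant trends into high-in-AVE / low-in-AVE
#'
#' Clusters the standardised fitted trends of the significant genes with the
#' VI-guided hierarchical procedure (genes as elements, cells as features),
#' assessing robustness by subsampling cells; each resulting gene cluster is
#' labelled `high_in_AVE` when its mean trend decreases along pseudotime
#' (negative mean slope) and `low_in_AVE` otherwise.
#'
#' @param trends a [trend_de()] result.
#' @param min_group minimum gene-cluster size (default 50).
#' @param subsample_fraction fraction of cells per robustness subsample.
#' @param n_subsamples number of subsamples.
#' @param seed integer seed.
#' @return named character vector over all tested genes with values
#'   `"high_in_AVE"`, `"low_in_AVE"` or `"none"` (non-significant genes);
#'   the gene-cluster partition is attached as attribute `"partition"`.
#' @export
group_trends <- function(trends, min_group = 50, subsample_fraction = 0.7,
                         n_subsamples = 50, seed = 0) {
  stopifnot(inherits(trends, "TrendDEResult"))
  fitted <- attr(trends, "fitted")
  sig <- trends$gene[trends$significant]
  labels <- setNames(rep("none", nrow(trends)), trends$gene)
  if (length(sig) == 0) return(labels)
  z <- fitted[sig, , drop = FALSE]
  z <- t(scale(t(z)))
  z[!is.finite(z)] <- 0
  if (length(sig) < min_group) {
    warning("fewer significant genes than min_group; assigning one group")
    part <- rep(1L, length(sig))
  } else {
    gm <- expression_matrix(z + 0, "lognorm")
    d <- spearman_distance(gm)
    sel <- cluster_with_vi_selection(d, gm, features = feature_ids(gm),
                                     n_subsamples = n_subsamples,
                                     subsample_fraction = subsample_fraction,
                                     min_size = min_group, seed = seed)
    part <- sel$partition
  }
  slopes <- trends$slope[match(sig, trends$gene)]
  for (cl in unique(part)) {
    lab <- if (mean(slopes[part == cl]) < 0) "high_in_AVE" else "low_in_AVE"
    labels[sig[part == cl]] <- lab
  }
  attr(labels, "partition") <- setNames(part, sig)
  labels
}
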