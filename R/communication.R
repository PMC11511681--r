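#' Read a ligand-receptor pair table
#'
#' TSV with columns `lrp_id`, `ligand_genes`, `receptor_genes`; multi-gene
#' complexes are comma-joined within a field.
#'
#' @param path TSV file path.
#' @return list of LRP entries `list(id, ligand, receptor)`.
#' @export
read_lrp_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lrp_id", "ligand_genes", "receptor_genes") %in%
                  colnames(tab)))
  lapply(seq_len(nrow(tab)), function(i)
    list(id = tab$lrp_id[i],
         ligand = strsplit(tab$ligand_genes[i], ",")[[1]],
         receptor = strsplit(tab$receptor_genes[i], ",")[[1]]))
}

#' Per-node expression summaries for communication scoring
#'
#' For each node (cell type) and gene: `phi`, the fraction of the node's
#' cells expressing the gene (set to 0 when below `phi_min`); `cbar`, the
#' mean of the non-zero lognorm values; and `p = cbar / max over nodes of
#' cbar`. Genes detected in fewer than `min_cells` cells overall or with
#' non-zero mean lognorm expression below `min_nonzero_mean` are removed
#' before summarising.
#'
#' @param m ExpressionMatrix with a lognorm layer.
#' @param partition node (cell-type) label per cell.
#' @param genes optional gene subset to consider.
#' @param min_cells overall detection filter (default 10 cells).
#' @param min_nonzero_mean overall non-zero-mean filter (default 1).
#' @param phi_min minimum expressing fraction (default 0.1).
#' @return list of class `NodeExpressionSummary`: `phi`, `p`, `cbar`
#'   (nodes x genes matrices), `nodes`, `genes`.
#' @export
summarize_nodes <- function(m, partition, genes = NULL, min_cells = 10,
                            min_nonzero_mean = 1, phi_min = 0.1) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "lognorm")
  stopifnot(length(partition) == nrow(m$values))
  x <- m$values
  if (!is.null(genes)) x <- x[, intersect(genes, colnames(x)), drop = FALSE]
  nodes <- sort(unique(partition))
  sizes <- table(partition)
  if (any(sizes == 0)) stop("empty node")
  nz <- colSums(x > 0)
  nzmean <- ifelse(nz > 0, colSums(x) / pmax(nz, 1), 0)
  keep <- nz >= min_cells & nzmean >= min_nonzero_mean
  x <- x[, keep, drop = FALSE]
  gn <- colnames(x)
  phi <- matrix(0, length(nodes), length(gn),
                dimnames = list(as.character(nodes), gn))
  cbar <- phi
  for (i in seq_along(nodes)) {
    sub <- x[partition == nodes[i], , drop = FALSE]
    f <- colMeans(sub > 0)
    f[f < phi_min] <- 0
    phi[i, ] <- f
    nzc <- colSums(sub > 0)
    cbar[i, ] <- ifelse(nzc > 0, colSums(sub) / pmax(nzc, 1), 0)
  }
  mx <- apply(cbar, 2, max)
  p <- sweep(cbar, 2, ifelse(mx > 0, mx, 1), `/`)
  structure(list(phi = phi, p = p, cbar = cbar,
                 nodes = as.character(nodes), genes = gn),
            class = "NodeExpressionSummary")
}

# phi / p of a (possibly multi-gene) unit at every node: product over genes.
unit_stat <- function(mat, genes) {
  apply(mat[, genes, drop = FALSE], 1, prod)
}

#' Ligand-receptor communication graphs
#'
#' For each ligand-receptor pair (LRP) alpha, computes the weighted directed
#' adjacency over nodes `w_ij = (phi_i^lig * phi_j^rec) * (p_i^lig *
#' p_j^rec)`; for multi-gene complexes, phi and p are products over member
#' genes. Weights below the `weight_percentile`-th percentile of all weights
#' pooled across all LRPs (zeros included by default) are set to 0, and LRPs
#' whose weight matrix becomes all-zero are removed. LRPs with genes absent
#' from the summary are dropped with a message.
#'
#' @param summary a [summarize_nodes()] result.
#' @param lrps list of LRP entries (see [read_lrp_table()]).
#' @param weight_percentile percentile filter (default 50).
#' @param include_zeros include zero weights when computing the percentile.
#' @return list of class `LRPCommunicationGraph`: `weights` (named list of
#'   node x node matrices), `lrps` (the retained LRP entries), `threshold`,
#'   `dropped` (ids of LRPs with missing genes).
#' @export
lrp_weights <- function(summary, lrps, weight_percentile = 50,
                        include_zeros = TRUE) {
  stopifnot(inherits(summary, "NodeExpressionSummary"))
  nodes <- summary$nodes
  mats <- list(); kept <- list(); dropped <- character(0)
  for (e in lrps) {
    gs <- c(e$ligand, e$receptor)
    if (!all(gs %in% summary$genes)) { dropped <- c(dropped, e$id); next }
    phi_l <- unit_stat(summary$phi, e$ligand)
    phi_r <- unit_stat(summary$phi, e$receptor)
    p_l <- unit_stat(summary$p, e$ligand)
    p_r <- unit_stat(summary$p, e$receptor)
    w <- outer(phi_l * p_l, phi_r * p_r)
    dimnames(w) <- list(nodes, nodes)
    mats[[e$id]] <- w
    kept[[e$id]] <- e
  }
  if (length(dropped))
    message("dropped ", length(dropped), " LRP(s) with missing genes")
  pool <- unlist(mats)
  if (!include_zeros) pool <- pool[pool > 0]
  threshold <- if (length(pool)) quantile(pool, weight_percentile / 100,
                                          names = FALSE) else 0
  for (id in names(mats)) mats[[id]][mats[[id]] < threshold] <- 0
  nonzero <- vapply(mats, function(w) any(w > 0), logical(1))
  structure(list(weights = mats[nonzero], lrps = kept[nonzero],
                 threshold = threshold, dropped = dropped),
            class = "LRPCommunicationGraph")
}

#' Restrict communication graphs to LRPs touching a gene group
#'
#' Keeps the LRPs with at least one ligand or receptor gene in `gene_group`
#' (e.g. the high-in-AVE genes from the pseudotime analysis).
#'
#' @param graphs an [lrp_weights()] result.
#' @param gene_group non-empty vector of gene ids.
#' @return `LRPCommunicationGraph` with the retained subset.
#' @export
restrict_to_gene_group <- function(graphs, gene_group) {
  stopifnot(inherits(graphs, "LRPCommunicationGraph"))
  if (length(gene_group) == 0) {
    graphs$weights <- list(); graphs$lrps <- list()
    return(graphs)
  }
  keep <- vapply(graphs$lrps, function(e)
    any(c(e$ligand, e$receptor) %in% gene_group), logical(1))
  graphs$weights <- graphs$weights[keep]
  graphs$lrps <- graphs$lrps[keep]
  graphs
}

#' Long-format table of communication weights
#'
#' @param graphs an [lrp_weights()] result.
#' @return data.frame with `lrp_id`, `source_node`, `target_node`, `weight`.
#' @export
communication_table <- function(graphs) {
  stopifnot(inherits(graphs, "LRPCommunicationGraph"))
  rows <- lapply(names(graphs$weights), function(id) {
    w <- graphs$weights[[id]]
    df <- expand.grid(source_node = rownames(w), target_node = colnames(w),
                      stringsAsFactors = FALSE)
    df$lrp_id <- id
    df$weight <- as.vector(w)
    df[, c("lrp_id", "source_node", "target_node", "weight")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap significance of PCA loadings on a gene pathway
#'
#' Restricts the expression matrix to pathway genes with mean lognorm
#' expression above `min_mean`, runs a PCA over cells, and assesses each
#' loading of the first `n_pcs` components by bootstrap: cells are resampled
#' with replacement `n_boot` times, the PCA recomputed, each replicate
#' component sign-aligned to the full-sample component (flipped when the dot
#' product of the loading vectors is negative, handling axis reflections),
#' and the loading's p-value taken as the fraction of replicates in which
#' its aligned sign differs from the full-sample sign. A gene is significant
#' when any of its first `n_pcs` loadings has p < `alpha`.
#'
#' @param m ExpressionMatrix with a lognorm layer.
#' @param pathway_genes candidate gene ids.
#' @param min_mean mean-expression filter (default 0.5).
#' @param n_boot bootstrap replicates (default 1000).
#' @param n_pcs components assessed (default 3).
#' @param alpha significance level (default 0.01).
#' @param seed integer seed.
#' @return list of class `BootstrapPCAResult`: `loadings` (genes x n_pcs),
#'   `p_values` (genes x n_pcs), `significant` (gene ids), `genes_used`,
#'   `explained_variance`.
#' @export
pathway_pca_bootstrap <- function(m, pathway_genes, min_mean = 0.5,
                                  n_boot = 1000, n_pcs = 3, alpha = 0.01,
                                  seed = 0) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "lognorm")
  genes <- intersect(pathway_genes, feature_ids(m))
  mu <- colMeans(m$values[, genes, drop = FALSE])
  used <- genes[mu > min_mean]
  if (length(used) < 3)
    stop("fewer than 3 pathway genes pass the expression filter; survivors: ",
         paste(used, collapse = ", "))
  x <- m$values[, used, drop = FALSE]
  n_pcs <- min(n_pcs, length(used))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ref <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(x)
  inv <- matrix(0, length(used), n_pcs,
                dimnames = list(used, colnames(ref)))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      pb <- prcomp(x[idx, , drop = FALSE], center = TRUE, scale. = FALSE)
      rb <- pb$rotation[, seq_len(n_pcs), drop = FALSE]
      for (j in seq_len(n_pcs)) {
        if (sum(rb[, j] * ref[, j]) < 0) rb[, j] <- -rb[, j]
        inv[, j] <- inv[, j] + (rb[, j] * ref[, j] < 0)
      }
    }
  })
  pv <- inv / n_boot
  sig <- used[apply(pv[, seq_len(min(3, n_pcs)), drop = FALSE] < alpha,
                    1, any)]
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = ref, p_values = pv, significant = sig,
                 genes_used = used,
                 explained_variance = ev[seq_len(n_pcs)]),
            class = "BootstrapPCAResult")
}
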