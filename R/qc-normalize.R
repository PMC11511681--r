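#' Quality-control thresholds for single-cell libraries
#'
#' The five retention criteria applied to Smart-seq2-style libraries: number
#' of genes above 10 reads-per-million, log10 total reads, fraction of mapped
#' reads, fraction of mitochondrial reads and fraction of spike-in reads.
#' Defaults are the thresholds used throughout the package.
#'
#' @param min_genes_over_10rpm minimum number of genes with > 10 rpm.
#' @param min_log10_reads minimum log10 of total read count.
#' @param min_mapped_fraction minimum fraction of mapped reads.
#' @param max_mito_fraction maximum fraction of mitochondrial reads.
#' @param max_spikein_fraction maximum fraction of spike-in reads.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes_over_10rpm = 3000,
                          min_log10_reads = 4,
                          min_mapped_fraction = 0.5,
                          max_mito_fraction = 0.1,
                          max_spikein_fraction = 0.3) {
  out <- list(min_genes_over_10rpm = min_genes_over_10rpm,
              min_log10_reads = min_log10_reads,
              min_mapped_fraction = min_mapped_fraction,
              max_mito_fraction = max_mito_fraction,
              max_spikein_fraction = max_spikein_fraction)
  stopifnot(all(vapply(out, is.finite, logical(1))))
  class(out) <- "qc_thresholds"
  out
}

qc_metadata_cols <- c("n_genes_over_10rpm", "log10_total_reads",
                      "mapped_fraction", "mito_fraction", "spikein_fraction")

#' Filter low-quality cells
#'
#' Retains the cells that satisfy all five QC criteria simultaneously and
#' reports, per criterion, how many cells failed it (a cell may fail several).
#'
#' @param m ExpressionMatrix with a counts layer and the five QC metadata
#'   columns (`n_genes_over_10rpm`, `log10_total_reads`, `mapped_fraction`,
#'   `mito_fraction`, `spikein_fraction`).
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `retained` (ExpressionMatrix), `removed` (cell ids),
#'   `pass` (named logical per cell) and `report` (named integer failure
#'   counts per criterion).
#' @export
filter_cells <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "counts")
  meta <- m$cell_metadata
  missing <- setdiff(qc_metadata_cols, colnames(meta))
  if (length(missing))
    stop("missing QC metadata column(s): ", paste(missing, collapse = ", "))
  fail <- cbind(
    n_genes_over_10rpm = meta$n_genes_over_10rpm <= thresholds$min_genes_over_10rpm,
    log10_total_reads  = meta$log10_total_reads <= thresholds$min_log10_reads,
    mapped_fraction    = meta$mapped_fraction <= thresholds$min_mapped_fraction,
    mito_fraction      = meta$mito_fraction >= thresholds$max_mito_fraction,
    spikein_fraction   = meta$spikein_fraction >= thresholds$max_spikein_fraction
  )
  pass <- rowSums(fail) == 0
  names(pass) <- cell_ids(m)
  list(retained = subset_cells(m, cells = which(pass)),
       removed = cell_ids(m)[!pass],
       pass = pass,
       report = colSums(fail))
}

#' Size factors by pooled deconvolution
#'
#' Estimates per-cell size factors by summing counts over sliding pools of
#' cells arranged on a ring ordered by library size, and solving the
#' resulting linear pool-equation system by least squares. Pooling averages
#' out gene-specific zero inflation, making the factors robust to
#' composition bias relative to plain library-size scaling. Factors are
#' rescaled to mean 1.
#'
#' @param counts cells x genes count matrix.
#' @param pool_sizes cells per pool; several sizes keep the linear system
#'   well conditioned (clamped to the cell count).
#' @return numeric vector of positive size factors, mean 1.
#' @export
deconvolution_size_factors <- function(counts, pool_sizes = c(21, 15, 9)) {
  n <- nrow(counts)
  if (n < 2) stop("need at least 2 cells")
  lib <- rowSums(counts)
  if (any(lib == 0)) stop("all-zero cell encountered; run QC filtering first")
  sizes <- unique(pmax(2L, pmin(pool_sizes, n)))
  ord <- order(lib)
  # reference composition profile (sums to 1): counts_j ~ s_j * ref
  ref <- colMeans(counts / lib)
  keep <- ref > 0
  rows <- list(); v <- numeric(0)
  for (w in sizes) {
    for (i in seq_len(n)) {
      pool <- ord[((i - 1 + seq_len(w) - 1) %% n) + 1]
      pooled <- colSums(counts[pool, , drop = FALSE])
      # median-ratio estimate of the pool total sum_{j in pool} s_j
      a <- numeric(n); a[pool] <- 1
      rows[[length(rows) + 1]] <- a
      v <- c(v, median(pooled[keep] / ref[keep]))
    }
  }
  # anchor the overall scale at mean(s) = mean library size
  A <- rbind(do.call(rbind, rows), rep(1, n))
  v <- c(v, n * mean(lib))
  AtA <- crossprod(A) + diag(1e-8 * mean(diag(crossprod(A))), n)
  sf <- solve(AtA, crossprod(A, v))[, 1]
  if (any(sf <= 0)) {
    warning("non-positive deconvolution factor(s); clamped to the ",
            "library-size floor")
    sf <- pmax(sf, 0.1 * lib)
  }
  sf / mean(sf)
}

#' Log-normalize a counts matrix
#'
#' Divides each cell's counts by its size factor and applies a natural-log
#' transform with a pseudocount of 1: `ln(count / size_factor + 1)`.
#' Size factors come either from pooled deconvolution (default) or plain
#' library-size scaling; either way they are rescaled to mean 1.
#'
#' @param m ExpressionMatrix with a counts layer.
#' @param method `"deconvolution"` or `"library"`.
#' @param pool_sizes pool sizes for the deconvolution method.
#' @return ExpressionMatrix with a lognorm layer; size factors are attached
#'   as metadata column `size_factor`.
#' @export
normalize_log <- function(m, method = c("deconvolution", "library"),
                          pool_sizes = c(21, 15, 9)) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "counts")
  method <- match.arg(method)
  lib <- rowSums(m$values)
  if (any(lib == 0))
    stop("all-zero cell(s): ", paste(cell_ids(m)[lib == 0], collapse = ", "),
         " (should have been removed by QC)")
  sf <- switch(method,
               library = lib / mean(lib),
               deconvolution = deconvolution_size_factors(m$values, pool_sizes))
  vals <- log1p(m$values / sf)
  out <- m
  out$values <- vals
  out$layer <- "lognorm"
  out$cell_metadata$size_factor <- sf
  out
}

#' Select highly variable genes by binned dispersion
#'
#' Computes, on the de-logged normalised values, the per-gene mean and
#' dispersion (variance / mean), z-scores the dispersion within 20
#' equal-occupancy mean bins, excludes genes with `log1p(mean) > max_mean`,
#' and returns the top `n_top` feature ids by normalised dispersion.
#'
#' @param m ExpressionMatrix with a lognorm layer.
#' @param n_top number of genes to return.
#' @param max_mean upper bound on log1p of the de-logged mean.
#' @param n_bins number of equal-occupancy mean bins.
#' @return character vector of feature ids, ranked most to least variable.
#' @export
select_hvgs <- function(m, n_top = 3000, max_mean = 10, n_bins = 20) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "lognorm")
  x <- expm1(m$values)
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  keep <- log1p(mu) <= max_mean & mu > 0
  ids <- feature_ids(m)[keep]
  mu_k <- mu[keep]; disp_k <- disp[keep]
  # equal-occupancy bins need enough genes each for a meaningful z-score
  nb <- max(1L, min(n_bins, floor(length(mu_k) / 5)))
  bins <- cut(rank(mu_k, ties.method = "first"), breaks = nb, labels = FALSE)
  z <- disp_k
  for (b in unique(bins)) {
    sel <- bins == b
    # robust centre/scale: a bin may contain several genuine HVGs, which
    # would inflate a mean/sd and mask them
    mb <- median(disp_k[sel])
    sb <- stats::mad(disp_k[sel])
    if (!is.finite(sb) || sb == 0) sb <- sd(disp_k[sel])
    if (!is.finite(sb) || sb == 0) sb <- 1
    z[sel] <- (disp_k[sel] - mb) / sb
  }
  if (n_top > length(ids)) {
    warning("n_top exceeds the number of eligible features; returning all")
    n_top <- length(ids)
  }
  ids[order(z, decreasing = TRUE)][seq_len(n_top)]
}
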