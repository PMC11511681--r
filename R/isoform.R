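#' Isoform-level differential expression between two clusters
#'
#' For each gene with usable isoform diversity, builds a contingency table of
#' the average normalised (TPM-like) expression of each isoform in the two
#' clusters and applies a Pearson chi-squared test (no continuity
#' correction). Genes whose counts are concentrated (> `single_isoform_cutoff`
#' of the total) on a single isoform are removed before testing, as are genes
#' left with fewer than two isoforms; p-values are Benjamini-Hochberg
#' adjusted across the tested genes.
#'
#' Table entries are average expression values and need not be integers; to
#' avoid zero expected counts, entries below `floor` are clipped up to it.
#'
#' @param transcripts ExpressionMatrix of cells x transcripts, normalised
#'   (TPM-like) values.
#' @param gene_map data.frame with columns `transcript_id` and `gene_id`.
#' @param partition cluster label per cell.
#' @param pair length-2 vector of cluster labels to compare.
#' @param single_isoform_cutoff single-isoform concentration above which a
#'   gene is excluded (default 0.8).
#' @param floor lower clip applied to table entries.
#' @return data.frame with one row per tested gene: `gene`, `statistic`,
#'   `df`, `p_value`, `adjusted_p`; the per-gene isoform x cluster tables are
#'   attached as attribute `"tables"`; excluded genes as attribute
#'   `"excluded"`.
#' @export
isoform_de <- function(transcripts, gene_map, partition, pair,
                       single_isoform_cutoff = 0.8, floor = 1e-6) {
  stopifnot(inherits(transcripts, "ExpressionMatrix"))
  stopifnot(all(c("transcript_id", "gene_id") %in% colnames(gene_map)))
  stopifnot(length(pair) == 2)
  stopifnot(length(partition) == nrow(transcripts$values))
  idx1 <- which(partition == pair[1])
  idx2 <- which(partition == pair[2])
  if (!length(idx1) || !length(idx2))
    stop("both clusters in `pair` must be present in `partition`")
  tx_ids <- feature_ids(transcripts)
  gm <- gene_map[gene_map$transcript_id %in% tx_ids, , drop = FALSE]
  genes <- split(gm$transcript_id, gm$gene_id)

  rows <- list(); tables <- list(); excluded <- character(0)
  for (g in names(genes)) {
    txs <- genes[[g]]
    sub <- transcripts$values[c(idx1, idx2), txs, drop = FALSE]
    tot <- colSums(sub)
    if (sum(tot) <= 0 || max(tot) / sum(tot) > single_isoform_cutoff) {
      excluded <- c(excluded, g)
      next
    }
    keep_iso <- tot > 0
    if (sum(keep_iso) < 2) { excluded <- c(excluded, g); next }
    txs <- txs[keep_iso]
    O <- cbind(colMeans(transcripts$values[idx1, txs, drop = FALSE]),
               colMeans(transcripts$values[idx2, txs, drop = FALSE]))
    colnames(O) <- as.character(pair)
    O[O < floor] <- floor
    res <- pearson_chisq(O)
    rows[[g]] <- data.frame(gene = g, statistic = res$statistic,
                            df = res$df, p_value = res$p_value,
                            stringsAsFactors = FALSE)
    tables[[g]] <- O
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), statistic = numeric(0), df = integer(0),
               p_value = numeric(0))
  rownames(out) <- NULL
  out$adjusted_p <- p.adjust(out$p_value, method = "BH")
  attr(out, "tables") <- tables
  attr(out, "excluded") <- excluded
  out
}

# Pearson chi-squared test of independence on a (possibly non-integer)
# contingency table, without continuity correction.
pearson_chisq <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Anterior/posterior expression ratio
#'
#' Ratio of reference-normalised anterior to posterior signal intensities,
#' `(anterior_signal / anterior_ref) / (posterior_signal / posterior_ref)`;
#' 1 indicates balanced expression. References are typically nuclear-stain
#' (DAPI) intensities in the same regions of interest.
#'
#' @param anterior_signal,posterior_signal mean signal intensities.
#' @param anterior_ref,posterior_ref positive reference intensities.
#' @return a single number.
#' @export
ap_ratio <- function(anterior_signal, posterior_signal,
                     anterior_ref, posterior_ref) {
  if (anterior_ref <= 0 || posterior_ref <= 0)
    stop("reference intensities must be positive")
  (anterior_signal / anterior_ref) / (posterior_signal / posterior_ref)
}
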