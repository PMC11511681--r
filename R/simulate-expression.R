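#' Specification for a synthetic single-cell count matrix
#'
#' Describes a negative-binomial, cluster-structured count matrix with
#' optional pseudotime gradient population, planted marker genes, planted
#' ligand-receptor expression patterns, isoform splits and QC-failing cells.
#' Defaults emulate a Smart-seq2-style experiment at desk scale:
#' overdispersed counts (variance `mu + dispersion * mu^2`) with log-normal
#' gene baseline means, and marker genes upregulated in their home cluster
#' by `exp(marker_log_fold_change)`.
#'
#' @param n_cells_per_cluster integer vector of cluster sizes (all > 0).
#' @param n_genes number of genes.
#' @param n_marker_genes_per_cluster planted markers per cluster (disjoint
#'   gene blocks starting at gene 1).
#' @param marker_log_fold_change natural-log fold change of markers in their
#'   home cluster.
#' @param nb_dispersion NB dispersion (`size = 1/nb_dispersion`).
#' @param baseline_mean mean of the log-normal gene baseline means (counts).
#' @param pseudotime_fraction fraction of cells (taken from the start of the
#'   cell ordering) placed on a latent-time gradient in \[0, 1\].
#' @param gradient_gene_sets list with integer vectors `decreasing` and
#'   `increasing` (disjoint): genes whose log-mean varies linearly in latent
#'   time with slope -/+ `marker_log_fold_change`.
#' @param qc_fail_fraction fraction of cells constructed to fail exactly one
#'   QC criterion each (round-robin over the five criteria).
#' @param mito_gene_indices,spikein_gene_indices gene indices treated as
#'   mitochondrial / spike-in for the QC fractions.
#' @param isoform_map named list (names = gene ids or indices as character)
#'   of entries `list(transcripts = ids, proportions = K x n_iso matrix)`
#'   with per-cluster isoform proportions summing to 1.
#' @param lrp_plan list of planted ligand-receptor patterns, each
#'   `list(ligand =, receptor = gene indices, phi_ligand =, phi_receptor =,
#'   magnitude_ligand =, magnitude_receptor = per-cluster vectors)`.
#' @param seed integer seed; fixes the output bit-for-bit.
#' @return An `ExpressionSimSpec` list.
#' @export
expression_sim_spec <- function(n_cells_per_cluster = c(100, 100, 100),
                                n_genes = 2000,
                                n_marker_genes_per_cluster = 20,
                                marker_log_fold_change = 2.0,
                                nb_dispersion = 0.4,
                                baseline_mean = 5,
                                pseudotime_fraction = 0,
                                gradient_gene_sets = list(decreasing = integer(0),
                                                          increasing = integer(0)),
                                qc_fail_fraction = 0,
                                mito_gene_indices = integer(0),
                                spikein_gene_indices = integer(0),
                                isoform_map = NULL,
                                lrp_plan = NULL,
                                seed = 1) {
  if (any(n_cells_per_cluster <= 0) || n_genes <= 0)
    stop("degenerate spec: cluster sizes and n_genes must be positive")
  if (length(intersect(gradient_gene_sets$decreasing,
                       gradient_gene_sets$increasing)))
    stop("gradient gene sets must be disjoint")
  stopifnot(pseudotime_fraction >= 0, pseudotime_fraction <= 1,
            qc_fail_fraction >= 0, qc_fail_fraction < 1)
  if (!is.null(isoform_map))
    for (e in isoform_map)
      if (any(abs(rowSums(e$proportions) - 1) > 1e-8))
        stop("isoform proportions must sum to 1 per cluster")
  out <- as.list(environment())
  class(out) <- "ExpressionSimSpec"
  out
}

#' Simulate a cluster-structured single-cell count matrix
#'
#' Draws negative-binomial counts according to an [expression_sim_spec()],
#' attaches per-cell QC metadata (QC-failing cells violate exactly one
#' criterion each) and returns the ground truth used by parameter-recovery
#' tests.
#'
#' Good cells receive passing values for the metadata columns that are not
#' derivable from the simulated gene panel (`n_genes_over_10rpm`,
#' `log10_total_reads`, `mapped_fraction`); mitochondrial and spike-in
#' fractions are computed from the counts. Cells planted to fail on the
#' mitochondrial or spike-in criterion have the corresponding gene counts
#' inflated so the computed fraction violates the threshold.
#'
#' @param spec an [expression_sim_spec()].
#' @return list with `matrix` (ExpressionMatrix, counts layer, metadata and
#'   true cluster labels attached) and `truth` (cluster labels, marker gene
#'   indices per cluster, latent time, isoform map, planted LRP plan, QC-fail
#'   cells with the violated criterion).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "ExpressionSimSpec"))
  with_seed(spec$seed, simulate_counts_impl(spec))
}

simulate_counts_impl <- function(spec) {
  K <- length(spec$n_cells_per_cluster)
  n <- sum(spec$n_cells_per_cluster)
  G <- spec$n_genes
  clusters <- rep(seq_len(K), spec$n_cells_per_cluster)

  base <- stats::rlnorm(G, meanlog = log(spec$baseline_mean) - 0.5, sdlog = 1)
  markers <- lapply(seq_len(K), function(k) {
    lo <- (k - 1) * spec$n_marker_genes_per_cluster + 1
    hi <- k * spec$n_marker_genes_per_cluster
    if (hi > G) stop("not enough genes for the planted markers")
    lo:hi
  })

  # per-cell latent time for the gradient population
  n_grad <- round(spec$pseudotime_fraction * n)
  latent <- rep(NA_real_, n)
  if (n_grad > 0) latent[seq_len(n_grad)] <- seq(0, 1, length.out = n_grad)

  mu <- matrix(rep(base, each = n), n, G)
  for (k in seq_len(K))
    mu[clusters == k, markers[[k]]] <-
      mu[clusters == k, markers[[k]], drop = FALSE] *
      exp(spec$marker_log_fold_change)
  if (n_grad > 0) {
    gl <- latent[seq_len(n_grad)]
    dec <- spec$gradient_gene_sets$decreasing
    inc <- spec$gradient_gene_sets$increasing
    if (length(dec))
      mu[seq_len(n_grad), dec] <- mu[seq_len(n_grad), dec, drop = FALSE] *
        exp(-spec$marker_log_fold_change * gl)
    if (length(inc))
      mu[seq_len(n_grad), inc] <- mu[seq_len(n_grad), inc, drop = FALSE] *
        exp(spec$marker_log_fold_change * (gl - 1))
  }
  # planted ligand-receptor expression patterns
  if (!is.null(spec$lrp_plan)) {
    for (e in spec$lrp_plan) {
      for (role in c("ligand", "receptor")) {
        gs <- e[[role]]
        phi <- e[[paste0("phi_", role)]]
        mag <- e[[paste0("magnitude_", role)]]
        for (k in seq_len(K)) {
          cells_k <- which(clusters == k)
          mu[cells_k, gs] <- mag[k]
          silent <- cells_k[stats::runif(length(cells_k)) > phi[k]]
          if (length(silent)) mu[silent, gs] <- 0
        }
      }
    }
  }

  counts <- matrix(rnbinom(n * G, mu = as.vector(mu),
                           size = 1 / spec$nb_dispersion), n, G)
  rownames(counts) <- sprintf("cell_%03d", seq_len(n))
  colnames(counts) <- sprintf("gene_%04d", seq_len(G))

  # QC metadata: passing values for good cells
  n_genes_meta <- round(stats::runif(n, 4500, 8000))
  log10_reads <- stats::runif(n, 4.8, 6.2)
  mapped <- stats::runif(n, 0.6, 0.95)

  n_fail <- round(spec$qc_fail_fraction * n)
  fail_cells <- if (n_fail > 0) sample(n, n_fail) else integer(0)
  criteria <- c("n_genes_over_10rpm", "log10_total_reads", "mapped_fraction",
                "mito_fraction", "spikein_fraction")
  fail_criterion <- character(0)
  if (n_fail > 0) {
    fail_criterion <- criteria[((seq_len(n_fail) - 1) %% 5) + 1]
    for (i in seq_len(n_fail)) {
      cell <- fail_cells[i]
      switch(fail_criterion[i],
        n_genes_over_10rpm = { n_genes_meta[cell] <- round(stats::runif(1, 500, 2500)) },
        log10_total_reads = { log10_reads[cell] <- stats::runif(1, 3, 3.9) },
        mapped_fraction = { mapped[cell] <- stats::runif(1, 0.1, 0.45) },
        mito_fraction = {
          if (!length(spec$mito_gene_indices))
            stop("mito QC failures require mito_gene_indices")
          tot <- sum(counts[cell, ])
          counts[cell, spec$mito_gene_indices] <-
            counts[cell, spec$mito_gene_indices] +
            ceiling(0.3 * tot / length(spec$mito_gene_indices))
        },
        spikein_fraction = {
          if (!length(spec$spikein_gene_indices))
            stop("spike-in QC failures require spikein_gene_indices")
          tot <- sum(counts[cell, ])
          counts[cell, spec$spikein_gene_indices] <-
            counts[cell, spec$spikein_gene_indices] +
            ceiling(0.8 * tot / length(spec$spikein_gene_indices))
        })
    }
  }
  tot <- rowSums(counts)
  mito <- if (length(spec$mito_gene_indices))
    rowSums(counts[, spec$mito_gene_indices, drop = FALSE]) / pmax(tot, 1)
  else rep(0.02, n)
  spike <- if (length(spec$spikein_gene_indices))
    rowSums(counts[, spec$spikein_gene_indices, drop = FALSE]) / pmax(tot, 1)
  else rep(0.05, n)

  meta <- data.frame(n_genes_over_10rpm = n_genes_meta,
                     log10_total_reads = log10_reads,
                     mapped_fraction = mapped,
                     mito_fraction = mito,
                     spikein_fraction = spike)
  m <- expression_matrix(counts, "counts", cell_metadata = meta,
                         cluster = clusters)
  truth <- list(seed = spec$seed,
                clusters = clusters,
                markers = markers,
                latent_time = latent,
                baseline_means = base,
                isoform_map = spec$isoform_map,
                lrp_plan = spec$lrp_plan,
                qc_fail_cells = rownames(counts)[fail_cells],
                qc_fail_criterion = fail_criterion)
  list(matrix = m, truth = truth)
}

#' Simulate transcript-level counts by multinomial isoform splitting
#'
#' Splits each cell's gene counts over that gene's transcripts according to
#' the isoform proportions of the cell's cluster, so per-gene transcript sums
#' equal the gene counts exactly. Genes without an isoform-map entry pass
#' through as a single transcript.
#'
#' @param sim a [simulate_counts()] result (or a list with `matrix` carrying
#'   cluster labels and `truth$isoform_map`).
#' @return list with `matrix` (ExpressionMatrix of transcript counts) and
#'   `gene_map` (data.frame transcript_id, gene_id).
#' @export
simulate_transcript_counts <- function(sim) {
  m <- sim$matrix
  iso <- sim$truth$isoform_map
  if (is.null(iso)) stop("spec has no isoform_map")
  counts <- m$values
  clusters <- cluster_labels(m)
  genes <- feature_ids(m)
  seed <- if (!is.null(sim$truth$seed)) sim$truth$seed else 0
  cols <- list(); tx_ids <- character(0); gene_of <- character(0)
  with_seed(stream_seed(seed, 777), {
    for (g in genes) {
      entry <- iso[[g]]
      if (is.null(entry)) {
        cols[[length(cols) + 1]] <- counts[, g]
        tx_ids <- c(tx_ids, paste0(g, ".t1"))
        gene_of <- c(gene_of, g)
        next
      }
      n_iso <- length(entry$transcripts)
      tx <- matrix(0L, nrow(counts), n_iso)
      for (i in seq_len(nrow(counts))) {
        cgc <- counts[i, g]
        if (cgc > 0)
          tx[i, ] <- as.integer(rmultinom(1, cgc,
                                          entry$proportions[clusters[i], ]))
      }
      for (j in seq_len(n_iso)) cols[[length(cols) + 1]] <- tx[, j]
      tx_ids <- c(tx_ids, entry$transcripts)
      gene_of <- c(gene_of, rep(g, n_iso))
    }
  })
  tx_mat <- do.call(cbind, cols)
  rownames(tx_mat) <- cell_ids(m)
  colnames(tx_mat) <- tx_ids
  tm <- expression_matrix(tx_mat, "counts", cell_metadata = m$cell_metadata)
  list(matrix = tm,
       gene_map = data.frame(transcript_id = tx_ids, gene_id = gene_of,
                             stringsAsFactors = FALSE))
}

#' TPM-like normalisation of a transcript count matrix
#'
#' Scales each cell to one million and returns values on the linear (non-log)
#' scale, suitable for [isoform_de()].
#'
#' @param m ExpressionMatrix with a counts layer.
#' @return ExpressionMatrix with TPM values on the linear scale (tagged as
#'   the normalised layer).
#' @export
normalize_tpm <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "counts")
  lib <- rowSums(m$values)
  if (any(lib == 0)) stop("all-zero cell(s) present")
  out <- m
  out$values <- m$values / lib * 1e6
  out$layer <- "lognorm"
  out
}

#' Write a ground-truth record as JSON
#'
#' @param truth list as returned in `simulate_counts()$truth`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
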