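#' Aggregate peptide counts to the protein level
#'
#' Sums the counts of all peptides of the same protein, per sample x run
#' column; run-level values are retained (see [average_runs()]).
#'
#' @param peptides long-format data.frame with columns `peptide`, `protein`,
#'   `sample`, `run`, `count` (and optionally `site`).
#' @return numeric matrix proteins x (sample.run) columns.
#' @export
aggregate_peptides <- function(peptides) {
  req <- c("peptide", "protein", "sample", "run", "count")
  stopifnot(all(req %in% colnames(peptides)), nrow(peptides) > 0)
  col <- interaction(peptides$sample, peptides$run, drop = TRUE, sep = ".")
  tab <- tapply(peptides$count, list(peptides$protein, col), sum)
  tab[is.na(tab)] <- 0
  mat <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  mat[order(rownames(mat)), , drop = FALSE]
}

#' Cyclic-loess normalization of a count matrix
#'
#' Applies pairwise MA-loess (cyclic loess) normalization to log2-transformed
#' values, stopping early when the mean absolute between-pass change drops
#' below `tol`. The number of passes is capped at `max_iter` (default 3):
#' cyclic loess is not a projection, and iterating it much further starts
#' absorbing genuine differential signal rather than technical bias.
#'
#' @param mat proteins x columns matrix of counts (or log2 values when
#'   `log = FALSE`).
#' @param log log2-transform with pseudocount 1 before normalising.
#' @param span loess span.
#' @param tol early-stop tolerance on the mean absolute offset per pass.
#' @param max_iter pass cap.
#' @return normalized matrix on the log2 scale.
#' @export
normalize_loess <- function(mat, log = TRUE, span = 0.7, tol = 1e-6,
                            max_iter = 3) {
  if (ncol(mat) < 2) stop("need at least 2 columns")
  if (any(colSums(abs(mat)) == 0)) stop("column of zeros")
  x <- if (log) log2(mat + 1) else mat
  for (i in seq_len(max_iter)) {
    xn <- limma::normalizeCyclicLoess(x, span = span, iterations = 1,
                                      method = "pairs")
    delta <- mean(abs(xn - x))
    x <- xn
    if (delta < tol) break
  }
  dimnames(x) <- dimnames(mat)
  x
}

#' Average technical runs into sample-level values
#'
#' Arithmetic mean of each sample's run columns; NA runs are dropped from
#' the mean (with a message); a sample with all runs NA is an error.
#'
#' @param mat proteins x (sample.run) matrix.
#' @param run_map named character vector mapping column name -> sample id.
#' @return proteins x samples matrix.
#' @export
average_runs <- function(mat, run_map) {
  stopifnot(all(colnames(mat) %in% names(run_map)))
  samples <- unique(run_map[colnames(mat)])
  out <- vapply(samples, function(s) {
    cols <- colnames(mat)[run_map[colnames(mat)] == s]
    sub <- mat[, cols, drop = FALSE]
    if (anyNA(sub)) {
      if (any(rowSums(!is.na(sub)) == 0))
        stop("sample ", s, " has proteins with all runs NA")
      message("sample ", s, ": NA run values dropped from the average")
    }
    rowMeans(sub, na.rm = TRUE)
  }, numeric(nrow(mat)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(mat))
  dimnames(out) <- list(rownames(mat), samples)
  out
}

#' Differential protein abundance between two groups
#'
#' Moderated two-sample t-test (empirical-Bayes variance shrinkage via
#' limma) on normalized log2 values, BH-corrected; the log2 fold change is
#' the group-mean difference (first group minus second). A protein is
#' flagged differential when |log2FC| > `lfc_min` and adjusted p < `alpha`.
#' Welch's t-test is available as an alternative for designs where variance
#' shrinkage is not wanted.
#'
#' @param mat proteins x samples matrix of normalized log2 values.
#' @param groups factor/vector of length ncol(mat) with exactly two levels;
#'   the first level is the numerator of the fold change.
#' @param lfc_min,alpha DE thresholds (defaults 1 and 0.1).
#' @param method `"moderated"` (limma) or `"welch"`.
#' @return data.frame with `protein`, `log2fc`, `p_value`, `adjusted_p`,
#'   `de` (logical flag).
#' @export
differential_proteins <- function(mat, groups, lfc_min = 1, alpha = 0.1,
                                  method = c("moderated", "welch")) {
  method <- match.arg(method)
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("need >= 2 replicates per group")
  if (method == "moderated") {
    design <- stats::model.matrix(~ 0 + g)
    colnames(design) <- c("a", "b")
    fit <- limma::lmFit(mat, design)
    fit <- limma::contrasts.fit(
      fit, limma::makeContrasts(a - b, levels = design))
    fit <- limma::eBayes(fit)
    lfc <- fit$coefficients[, 1]
    p <- fit$p.value[, 1]
  } else {
    i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
    lfc <- rowMeans(mat[, i1, drop = FALSE]) -
      rowMeans(mat[, i2, drop = FALSE])
    p <- apply(mat, 1, function(r) {
      if (var(r[i1]) + var(r[i2]) == 0) return(1)
      stats::t.test(r[i1], r[i2])$p.value
    })
  }
  p[is.na(p)] <- 1
  adj <- p.adjust(p, method = "BH")
  data.frame(protein = rownames(mat), log2fc = as.numeric(lfc),
             p_value = as.numeric(p), adjusted_p = adj,
             de = abs(lfc) > lfc_min & adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare proteomic and transcriptomic fold changes
#'
#' Inner-joins the two differential tables through a gene-protein mapping
#' and returns the paired log2 fold changes with their Pearson correlation.
#'
#' @param protein_de data.frame with `protein` and `log2fc`.
#' @param rna_de data.frame with `gene` and `log2fc`.
#' @param mapping data.frame with columns `gene` and `protein`.
#' @return list with `table` (gene, protein, log2fc_rna, log2fc_protein),
#'   `r` (Pearson correlation) and `p_value` (two-sided).
#' @export
compare_with_rna <- function(protein_de, rna_de, mapping) {
  stopifnot(all(c("gene", "protein") %in% colnames(mapping)))
  tab <- merge(mapping, rna_de[, c("gene", "log2fc")], by = "gene")
  tab <- merge(tab, protein_de[, c("protein", "log2fc")], by = "protein",
               suffixes = c("_rna", "_protein"))
  if (nrow(tab) < 3) stop("fewer than 3 shared identifiers after mapping")
  ct <- cor.test(tab$log2fc_rna, tab$log2fc_protein, method = "pearson")
  list(table = tab[, c("gene", "protein", "log2fc_rna", "log2fc_protein")],
       r = unname(ct$estimate), p_value = ct$p.value)
}

# Normalise a phospho-site string to RESIDUE+POSITION (e.g. "S23");
# returns NA for malformed strings.
normalize_site <- function(site) {
  s <- toupper(trimws(as.character(site)))
  ok <- grepl("^[A-Z][0-9]+$", s)
  s[!ok] <- NA_character_
  s
}

#' Kinase-substrate bipartite networks from differential phosphoproteins
#'
#' Restricts a kinase-substrate interaction table to substrates that are
#' differentially phosphorylated, requiring the phosphorylation-site
#' annotations to match exactly (case-insensitive residue letter plus
#' position). Two bipartite networks are returned, one per side: substrates
#' up in the embryonic half (positive log2FC) and up in the abembryonic half
#' (negative log2FC). Interaction rows with malformed sites are skipped with
#' a message.
#'
#' @param de_phospho data.frame with `protein`, `site`, `log2fc`, `de`.
#' @param interaction_table data.frame with `kinase`, `substrate`, `site`.
#' @return list of class `KinaseSubstrateNetwork` with `embryonic` and
#'   `abembryonic` edge data.frames (`kinase`, `substrate`, `site`).
#' @export
kinase_substrate_network <- function(de_phospho, interaction_table) {
  stopifnot(all(c("protein", "site", "log2fc", "de") %in%
                  colnames(de_phospho)))
  stopifnot(all(c("kinase", "substrate", "site") %in%
                  colnames(interaction_table)))
  it <- interaction_table
  it$site_norm <- normalize_site(it$site)
  bad <- is.na(it$site_norm)
  if (any(bad))
    message("skipped ", sum(bad), " interaction row(s) with malformed sites")
  it <- it[!bad, , drop = FALSE]
  de <- de_phospho[de_phospho$de, , drop = FALSE]
  de$site_norm <- normalize_site(de$site)
  de <- de[!is.na(de$site_norm), , drop = FALSE]
  side_edges <- function(sub_de) {
    key <- paste(sub_de$protein, sub_de$site_norm)
    hit <- paste(it$substrate, it$site_norm) %in% key
    out <- it[hit, c("kinase", "substrate", "site_norm")]
    colnames(out) <- c("kinase", "substrate", "site")
    rownames(out) <- NULL
    out
  }
  structure(list(
    embryonic = side_edges(de[de$log2fc > 0, , drop = FALSE]),
    abembryonic = side_edges(de[de$log2fc < 0, , drop = FALSE])),
    class = "KinaseSubstrateNetwork")
}

#' Write a kinase-substrate network as edge-list TSV and GraphML
#'
#' @param net a [kinase_substrate_network()] result.
#' @param prefix output path prefix; writes `<prefix>_<side>.tsv` and
#'   `<prefix>_<side>.graphml`.
#' @return invisibly, the prefix.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "KinaseSubstrateNetwork"))
  for (side in c("embryonic", "abembryonic")) {
    edges <- net[[side]]
    utils::write.table(edges, paste0(prefix, "_", side, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(edges)) {
      g <- igraph::graph_from_data_frame(
        data.frame(from = edges$kinase,
                   to = paste0(edges$substrate, "_", edges$site)))
      igraph::V(g)$type <- igraph::V(g)$name %in% edges$kinase
      igraph::write_graph(g, paste0(prefix, "_", side, ".graphml"),
                          format = "graphml")
    }
  }
  invisible(prefix)
}
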