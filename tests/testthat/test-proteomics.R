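make_peptides <- function(n_pep = 40, n_prot = 20, n_samples = 4,
                          n_runs = 3, seed = 1, de_proteins = character(0),
                          de_samples = character(0), fold = 4) {
  set.seed(seed)
  peps <- expand.grid(peptide = sprintf("pep%03d", seq_len(n_pep)),
                      sample = sprintf("s%d", seq_len(n_samples)),
                      run = seq_len(n_runs))
  prot_of <- sprintf("P%03d", rep_len(seq_len(n_prot), n_pep))
  peps$protein <- rep(prot_of, times = n_samples * n_runs)
  base <- rep(rlnorm(n_pep, 5, 0.6), times = n_samples * n_runs)
  shift <- ifelse(peps$protein %in% de_proteins &
                    peps$sample %in% de_samples, fold, 1)
  peps$count <- round(base * shift * rlnorm(nrow(peps), 0, 0.1))
  peps
}

test_that("peptide aggregation sums per protein and conserves totals", {
  peps <- data.frame(peptide = c("a", "b", "c"),
                     protein = c("P1", "P1", "P2"),
                     sample = "s1", run = 1, count = c(100, 50, 7))
  mat <- aggregate_peptides(peps)
  expect_equal(mat["P1", "s1.1"], 150)
  expect_equal(sum(mat), sum(peps$count))
  # row-order invariance
  mat2 <- aggregate_peptides(peps[c(3, 1, 2), ])
  expect_equal(mat2, mat)
})

test_that("cyclic loess removes scale bias without touching clean data", {
  set.seed(2)
  base <- rlnorm(300, 6, 0.8)
  clean <- matrix(rep(base, 4), ncol = 4,
                  dimnames = list(sprintf("P%03d", 1:300), paste0("s", 1:4)))
  nm <- normalize_loess(clean)
  expect_equal(nm, log2(clean + 1), tolerance = 1e-9)
  # one column scaled x2: offset removed within 1%
  biased <- clean
  biased[, 2] <- biased[, 2] * 2
  nb <- normalize_loess(biased)
  offs <- rowMeans(nb[, c(1, 3, 4)]) - nb[, 2]
  expect_lt(mean(abs(offs)), 0.01 * mean(nb))
  # column medians agree after normalization of a monotone bias
  expect_lt(diff(range(apply(nb, 2, median))), 0.02)
  expect_error(normalize_loess(cbind(base, 0)), "zeros")
})

test_that("run averaging handles missing runs and errors on empty samples", {
  mat <- matrix(c(10, 20, 30, 5, NA, 7), 1,
                dimnames = list("P1", c("s1.1", "s1.2", "s1.3",
                                        "s2.1", "s2.2", "s2.3")))
  rm_ <- setNames(rep(c("s1", "s2"), each = 3), colnames(mat))
  expect_message(out <- average_runs(mat, rm_), "NA run")
  expect_equal(out["P1", "s1"], 20)
  expect_equal(out["P1", "s2"], 6)
  single <- matrix(1:2, 1, dimnames = list("P1", c("s1.1", "s2.1")))
  expect_equal(unname(average_runs(single,
                                   setNames(c("s1", "s2"),
                                            colnames(single)))[1, ]),
               c(1, 2))
  allna <- matrix(c(NA, NA, 1, 2), 1,
                  dimnames = list("P1", c("s1.1", "s1.2", "s2.1", "s2.2")))
  expect_error(average_runs(allna, setNames(rep(c("s1", "s2"), each = 2),
                                            colnames(allna))), "all runs NA")
})

test_that("moderated differential test recovers planted shifts", {
  peps <- make_peptides(n_pep = 400, n_prot = 200, seed = 3,
                        de_proteins = sprintf("P%03d", 1:10),
                        de_samples = c("s1", "s2"))
  mat <- aggregate_peptides(peps)
  nm <- normalize_loess(mat)
  run_map <- setNames(sub("[.][0-9]+$", "", colnames(nm)), colnames(nm))
  sm <- average_runs(nm, run_map)
  g <- factor(ifelse(colnames(sm) %in% c("s1", "s2"), "emb", "ab"),
              levels = c("emb", "ab"))
  de <- differential_proteins(sm, g)
  expect_true(all(de$de[de$protein %in% sprintf("P%03d", 1:10)]))
  expect_false(any(de$de[!de$protein %in% sprintf("P%03d", 1:10)]))
  expect_gt(mean(de$log2fc[de$protein %in% sprintf("P%03d", 1:10)]), 1.5)
  # identical group means: log2FC 0, not DE
  flat <- matrix(5, 10, 4, dimnames = list(paste0("Q", 1:10),
                                           paste0("s", 1:4)))
  flat <- flat + matrix(rnorm(40, 0, 0.01), 10)
  def <- differential_proteins(flat, c("a", "a", "b", "b"))
  expect_true(all(abs(def$log2fc) < 0.1))
  expect_false(any(def$de))
})

test_that("planted 2-log2 shifts at sd 0.3 are detected reliably (4v4)", {
  set.seed(4)
  hits <- vapply(1:20, function(i) {
    mat <- matrix(rnorm(200 * 8, 10, 0.3), 200, 8)
    mat[1, 1:4] <- mat[1, 1:4] + 2
    rownames(mat) <- paste0("P", 1:200)
    de <- differential_proteins(mat, rep(c("a", "b"), each = 4))
    de$de[1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("moderated test holds its size on null data", {
  set.seed(5)
  mat <- matrix(rnorm(1000 * 8, 10, 0.5), 1000, 8,
                dimnames = list(paste0("P", 1:1000), NULL))
  de <- differential_proteins(mat, rep(c("a", "b"), each = 4))
  rate <- mean(de$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 0.015)
})

test_that("cross-omics comparison joins identifiers and correlates", {
  prot <- data.frame(protein = paste0("P", 1:50), log2fc = rnorm(50))
  rna <- data.frame(gene = paste0("g", 1:50), log2fc = prot$log2fc)
  mapping <- data.frame(gene = paste0("g", 1:50),
                        protein = paste0("P", 1:50))
  res <- compare_with_rna(prot, rna, mapping)
  expect_equal(res$r, 1)
  rna2 <- rna; rna2$log2fc <- -rna2$log2fc
  expect_equal(compare_with_rna(prot, rna2, mapping)$r, -1)
  # independent fold changes: weak correlation in most runs
  set.seed(6)
  weak <- vapply(1:10, function(i) {
    p2 <- data.frame(protein = paste0("P", 1:100), log2fc = rnorm(100))
    r2 <- data.frame(gene = paste0("g", 1:100), log2fc = rnorm(100))
    m2 <- data.frame(gene = paste0("g", 1:100), protein = paste0("P", 1:100))
    abs(compare_with_rna(p2, r2, m2)$r)
  }, numeric(1))
  expect_gte(mean(weak < 0.3), 0.9)
  expect_error(compare_with_rna(prot[1, , drop = FALSE], rna, mapping),
               "fewer than 3")
})

test_that("kinase-substrate edges require exact site correspondence", {
  de <- data.frame(protein = c("P1", "P2", "P3"),
                   site = c("S23", "T44", "Y10"),
                   log2fc = c(2, -1.5, 1.2), de = c(TRUE, TRUE, FALSE))
  it <- data.frame(kinase = c("K1", "K1", "K2", "K2", "K3"),
                   substrate = c("P1", "P1", "P2", "P3", "P1"),
                   site = c("s23", "S24", "T44", "Y10", "banana"))
  expect_message(net <- kinase_substrate_network(de, it), "malformed")
  # matching site (case-insensitive) kept on the embryonic side
  expect_equal(nrow(net$embryonic), 1)
  expect_equal(net$embryonic$kinase, "K1")
  expect_equal(net$embryonic$site, "S23") # S24 mismatch excluded
  # negative fold change goes to the abembryonic side
  expect_equal(net$abembryonic$substrate, "P2")
  # non-DE substrates never appear
  expect_false("P3" %in% c(net$embryonic$substrate,
                           net$abembryonic$substrate))
  # empty DE list: empty networks
  net0 <- kinase_substrate_network(de[de$de == FALSE, ], it)
  expect_equal(nrow(net0$embryonic) + nrow(net0$abembryonic), 0)
})

test_that("network writers emit edge lists and GraphML", {
  tmp <- withr::local_tempdir()
  de <- data.frame(protein = "P1", site = "S23", log2fc = 2, de = TRUE)
  it <- data.frame(kinase = "K1", substrate = "P1", site = "S23")
  net <- kinase_substrate_network(de, it)
  write_network(net, file.path(tmp, "net"))
  expect_true(file.exists(file.path(tmp, "net_embryonic.tsv")))
  expect_true(file.exists(file.path(tmp, "net_embryonic.graphml")))
  g <- igraph::read_graph(file.path(tmp, "net_embryonic.graphml"),
                          format = "graphml")
  expect_equal(igraph::gsize(g), 1)
})
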