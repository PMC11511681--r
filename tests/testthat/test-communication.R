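# Hand-built NodeExpressionSummary for formula checks.
make_summary <- function(phi, p) {
  structure(list(phi = phi, p = p, cbar = p,
                 nodes = rownames(phi), genes = colnames(phi)),
            class = "NodeExpressionSummary")
}

test_that("node summaries compute phi, non-zero means and p correctly", {
  vals <- matrix(0, 40, 3)
  colnames(vals) <- c("gA", "gB", "gC")
  nodes <- rep(c("n1", "n2"), each = 20)
  vals[nodes == "n1", "gA"] <- 2          # phi 1, cbar 2 in n1
  vals[nodes == "n2", "gA"] <- c(rep(4, 10), rep(0, 10)) # phi .5, cbar 4
  vals[, "gB"] <- 1.5                     # uniform, passes filters
  vals[nodes == "n1", "gC"] <- c(3, rep(0, 19)) # detected in 1 cell only
  m <- expression_matrix(vals, "lognorm")
  s <- summarize_nodes(m, nodes, min_cells = 10, min_nonzero_mean = 1)
  expect_false("gC" %in% s$genes) # detection filter
  expect_equal(s$phi["n1", "gA"], 1)
  expect_equal(s$phi["n2", "gA"], 0.5)
  expect_equal(s$cbar["n1", "gA"], 2)
  expect_equal(s$cbar["n2", "gA"], 4)
  expect_equal(s$p["n1", "gA"], 0.5) # {2,4} -> {0.5, 1}
  expect_equal(s$p["n2", "gA"], 1)
  # low expressing fractions are zeroed
  vals2 <- vals
  vals2[nodes == "n2", "gA"] <- c(rep(30, 1), rep(0, 19)) # phi raw 0.05
  s2 <- summarize_nodes(expression_matrix(vals2, "lognorm"), nodes,
                        min_cells = 10, min_nonzero_mean = 1)
  expect_equal(s2$phi["n2", "gA"], 0)
})

test_that("LRP weights follow the phi/p product formula", {
  phi <- rbind(n1 = c(lig = 0.5, rec = 0.2), n2 = c(lig = 0.1, rec = 0.8))
  p <- rbind(n1 = c(lig = 0.6, rec = 0.3), n2 = c(lig = 0.4, rec = 1.0))
  s <- make_summary(phi, p)
  gr <- lrp_weights(s, list(list(id = "a", ligand = "lig",
                                 receptor = "rec")),
                    weight_percentile = 0)
  # w_12 = (0.5 * 0.8) * (0.6 * 1.0) = 0.24
  expect_equal(gr$weights$a["n1", "n2"], 0.24)
  # full saturation gives weight 1
  s1 <- make_summary(phi * 0 + 1, p * 0 + 1)
  gr1 <- lrp_weights(s1, list(list(id = "a", ligand = "lig",
                                   receptor = "rec")),
                     weight_percentile = 0)
  expect_equal(unname(gr1$weights$a), matrix(1, 2, 2))
})

test_that("complex phi and p are products over member genes", {
  phi <- rbind(n1 = c(l1 = 1, r1 = 0.5, r2 = 0.5),
               n2 = c(l1 = 1, r1 = 0.5, r2 = 0.5))
  p <- phi * 0 + 1
  s <- make_summary(phi, p)
  gr <- lrp_weights(s, list(list(id = "cx", ligand = "l1",
                                 receptor = c("r1", "r2"))),
                    weight_percentile = 0)
  expect_equal(gr$weights$cx["n1", "n2"], 1 * 0.25) # complex phi = 0.25
})

test_that("weights are zero when any constituent phi is zero", {
  phi <- rbind(n1 = c(lig = 0, rec = 1), n2 = c(lig = 1, rec = 1))
  p <- phi * 0 + 1
  s <- make_summary(phi, p)
  gr <- lrp_weights(s, list(list(id = "a", ligand = "lig",
                                 receptor = "rec")),
                    weight_percentile = 0)
  expect_equal(unname(gr$weights$a["n1", ]), c(0, 0))
})

test_that("weights are monotone in each factor", {
  set.seed(2)
  for (rep in 1:50) {
    v <- runif(4) # phi_i, phi_j, p_i, p_j
    base <- (v[1] * v[2]) * (v[3] * v[4])
    for (k in 1:4) {
      v2 <- v; v2[k] <- min(1, v2[k] + runif(1, 0, 1 - v2[k]))
      expect_gte((v2[1] * v2[2]) * (v2[3] * v2[4]), base)
    }
  }
})

test_that("the percentile filter halves the weight mass and drops dead LRPs", {
  set.seed(3)
  phi <- matrix(runif(12, 0.1, 1), 3,
                dimnames = list(paste0("n", 1:3), paste0("g", 1:4)))
  p <- matrix(runif(12), 3, dimnames = dimnames(phi))
  s <- make_summary(phi, p)
  lrps <- list(list(id = "a", ligand = "g1", receptor = "g2"),
               list(id = "b", ligand = "g3", receptor = "g4"))
  gr <- lrp_weights(s, lrps, weight_percentile = 50)
  pre <- c(outer(phi[, "g1"] * p[, "g1"], phi[, "g2"] * p[, "g2"]),
           outer(phi[, "g3"] * p[, "g3"], phi[, "g4"] * p[, "g4"]))
  post <- unlist(gr$weights)
  expect_lte(sum(post > 0), ceiling(length(pre) / 2))
  expect_true(all(post[post > 0] >= quantile(pre, 0.5)))
  # an LRP below the percentile everywhere is removed entirely
  weak <- make_summary(rbind(n1 = c(g1 = 0.1, g2 = 0.1),
                             n2 = c(g1 = 0.1, g2 = 0.1)),
                       rbind(n1 = c(g1 = 1, g2 = 0.01),
                             n2 = c(g1 = 0.01, g2 = 1)))
  # percentile computed within a single weak LRP keeps only the top half
  gr2 <- lrp_weights(weak, list(list(id = "w", ligand = "g1",
                                     receptor = "g2")))
  expect_true(all(vapply(gr2$weights, function(w) any(w > 0), logical(1))))
})

test_that("restriction keeps LRPs touching the gene group", {
  phi <- matrix(0.5, 2, 6,
                dimnames = list(c("n1", "n2"), paste0("g", 1:6)))
  s <- make_summary(phi, phi)
  lrps <- lapply(1:3, function(i)
    list(id = paste0("l", i), ligand = paste0("g", 2 * i - 1),
         receptor = paste0("g", 2 * i)))
  gr <- lrp_weights(s, lrps, weight_percentile = 0)
  expect_length(restrict_to_gene_group(gr, character(0))$weights, 0)
  expect_length(restrict_to_gene_group(gr, paste0("g", 1:6))$weights, 3)
  expect_equal(names(restrict_to_gene_group(gr, "g3")$weights), "l2")
  # missing genes drop the LRP with a message
  expect_message(
    gr2 <- lrp_weights(s, c(lrps, list(list(id = "bad", ligand = "zz",
                                            receptor = "g1"))),
                       weight_percentile = 0), "dropped")
  expect_false("bad" %in% names(gr2$weights))
})

test_that("a planted node-pair LRP carries the top post-filter weight", {
  mk <- function(lig, rec, phi_l, phi_r) list(
    ligand = lig, receptor = rec, phi_ligand = phi_l, phi_receptor = phi_r,
    magnitude_ligand = rep(30, 3), magnitude_receptor = rep(30, 3))
  plan <- c(list(mk(501L, 502L, c(0.9, 0, 0), c(0, 0.9, 0))),
            lapply(0:9, function(i) {
              set.seed(i + 40)
              mk(503L + 2L * i, 504L + 2L * i, runif(3, 0.15, 0.5),
                 runif(3, 0.15, 0.5))
            }))
  sim <- simulate_counts(expression_sim_spec(
    n_cells_per_cluster = c(80, 80, 80), n_genes = 600,
    n_marker_genes_per_cluster = 10, marker_log_fold_change = 1.5,
    lrp_plan = plan, seed = 31))
  ln <- normalize_log(sim$matrix)
  s <- summarize_nodes(ln, cluster_labels(ln))
  lrps <- lapply(seq_along(plan), function(j) list(
    id = if (j == 1) "planted" else paste0("bg", j),
    ligand = gene_id(plan[[j]]$ligand),
    receptor = gene_id(plan[[j]]$receptor)))
  gr <- lrp_weights(s, lrps)
  mx <- vapply(gr$weights, max, numeric(1))
  expect_equal(names(which.max(mx)), "planted")
  w <- gr$weights$planted
  am <- which(w == max(w), arr.ind = TRUE)
  expect_equal(unname(c(rownames(w)[am[1]], colnames(w)[am[2]])),
               c("1", "2"))
})

test_that("bootstrap PCA flags driver genes and not noise", {
  set.seed(5)
  n <- 120
  latent <- rnorm(n)
  vals <- cbind(driver1 = 1.5 + 1.0 * latent + rnorm(n, 0, 0.1),
                driver2 = 1.5 - 1.0 * latent + rnorm(n, 0, 0.1),
                driver3 = 1.5 + 0.8 * latent + rnorm(n, 0, 0.1),
                noise1 = 1.5 + rnorm(n, 0, 1),
                noise2 = 1.5 + rnorm(n, 0, 1))
  m <- expression_matrix(abs(vals), "lognorm")
  res <- pathway_pca_bootstrap(m, colnames(vals), min_mean = 0.5,
                               n_boot = 400, seed = 7)
  expect_lt(res$p_values["driver1", 1], 0.01)
  expect_true("driver1" %in% res$significant)
  # pure-noise loadings invert about half the time somewhere in PC2/PC3
  noise_p <- res$p_values[c("noise1", "noise2"), 2:3]
  expect_true(any(noise_p > 0.2))
  # loadings are unit vectors
  expect_equal(colSums(res$loadings^2), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(pathway_pca_bootstrap(m, c("driver1", "noise1"),
                                     min_mean = 0.5), "fewer than 3")
})

test_that("noise genes invert about half the time on an anchored PC", {
  # one strong driver anchors PC1 (fixing the reflection). True-null noise
  # is orthogonalized against the signal — a raw finite-sample correlation
  # |r| ~ 1/sqrt(n) biases inversions towards 0 — with a small random
  # admixture so reference loadings are nonzero
  set.seed(6)
  n <- 150
  latent <- rnorm(n)
  noise_o <- apply(matrix(rnorm(n * 5), n, 5), 2,
                   function(v) residuals(lm(v ~ latent)))
  noise <- noise_o + 0.05 * matrix(rnorm(n * 5), n, 5)
  vals <- cbind(driver = 5 + 2 * latent, 3 + 0.5 * noise)
  colnames(vals) <- c("driver", paste0("noise", 1:5))
  m <- expression_matrix(vals, "lognorm")
  res <- pathway_pca_bootstrap(m, colnames(vals), min_mean = 0.5,
                               n_boot = 400, seed = 8)
  expect_lt(res$p_values["driver", 1], 0.01)
  noise_inv <- res$p_values[paste0("noise", 1:5), 1]
  expect_lt(abs(mean(noise_inv) - 0.5), 0.1)
})

test_that("communication tables round-trip through the TSV schema", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lrp_id\tligand_genes\treceptor_genes",
               "a\tL1\tR1", "cx\tL1,L2\tR1"), tmp)
  lrps <- read_lrp_table(tmp)
  expect_length(lrps, 2)
  expect_equal(lrps[[2]]$ligand, c("L1", "L2"))
  phi <- matrix(1, 2, 3, dimnames = list(c("n1", "n2"),
                                         c("L1", "L2", "R1")))
  gr <- lrp_weights(make_summary(phi, phi), lrps, weight_percentile = 0)
  tab <- communication_table(gr)
  expect_setequal(colnames(tab),
                  c("lrp_id", "source_node", "target_node", "weight"))
  expect_equal(nrow(tab), 2 * 4)
})
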