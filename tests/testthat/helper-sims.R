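# Shared fixtures, built in code.

gene_id <- function(i) sprintf("gene_%04d", i)

# Three well-separated NB clusters.
sim_three_clusters <- function(n_per = 80, n_genes = 600, seed = 5,
                               lfc = 2) {
  simulate_counts(expression_sim_spec(
    n_cells_per_cluster = rep(n_per, 3), n_genes = n_genes,
    n_marker_genes_per_cluster = 20, marker_log_fold_change = lfc,
    seed = seed))
}

# A single homogeneous NB cloud.
sim_single_cloud <- function(n = 150, n_genes = 600, seed = 7) {
  simulate_counts(expression_sim_spec(
    n_cells_per_cluster = n, n_genes = n_genes,
    n_marker_genes_per_cluster = 0, seed = seed))
}

# 1-D gradient population: 30% of genes on a monotone latent-time program,
# matching the fraction of pseudotime-DE genes seen in real AVE/emVE data.
sim_gradient <- function(n = 300, n_genes = 800, seed = 11) {
  dec <- 101:220; inc <- 221:340
  sim <- simulate_counts(expression_sim_spec(
    n_cells_per_cluster = n, n_genes = n_genes,
    n_marker_genes_per_cluster = 0, pseudotime_fraction = 1,
    gradient_gene_sets = list(decreasing = dec, increasing = inc),
    marker_log_fold_change = 2, seed = seed))
  sim$gradient <- list(decreasing = gene_id(dec), increasing = gene_id(inc))
  sim
}

# Hand-built TrackSet (for analytic strain/saliency checks).
make_trackset <- function(x, y, w_sp = 4, direction = "forward",
                          frame_shape = c(64, 64)) {
  structure(list(x = x, y = y, birth = rep(1L, nrow(x)), w_sp = w_sp,
                 direction = direction, frame_shape = frame_shape,
                 n_initial = nrow(x)),
            class = "TrackSet")
}

# Brute-force Variation of Information from first principles: explicit
# joint distribution and conditional entropies, VI = H(X|Y) + H(Y|X).
vi_bruteforce <- function(p1, p2) {
  n <- length(p1)
  u1 <- unique(p1); u2 <- unique(p2)
  joint <- matrix(0, length(u1), length(u2))
  for (i in seq_along(u1)) for (j in seq_along(u2))
    joint[i, j] <- sum(p1 == u1[i] & p2 == u2[j]) / n
  hx_given_y <- 0; hy_given_x <- 0
  for (i in seq_along(u1)) for (j in seq_along(u2)) {
    pij <- joint[i, j]
    if (pij > 0) {
      hx_given_y <- hx_given_y - pij * log(pij / sum(joint[, j]))
      hy_given_x <- hy_given_x - pij * log(pij / sum(joint[i, ]))
    }
  }
  hx_given_y + hy_given_x
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of group
# assignments (oracle for small, tie-free samples).
wilcox_enumerate <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(x2) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
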