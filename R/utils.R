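#' @importFrom stats pnorm p.adjust quantile median var sd cor prcomp rnorm
#' @importFrom stats rnbinom rmultinom rbinom rpois runif cor.test wilcox.test
#' @importFrom stats pwilcox lm anova pf pchisq setNames aggregate dist hclust
#' @importFrom stats cutree complete.cases na.omit plogis
NULL

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-stream seed from a base seed and a counter, kept within 32-bit
# integer range so set.seed() accepts it on all platforms.
stream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same elements;
#' 1 for identical partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Vectorised two-sample Wilcoxon rank-sum test applied gene-wise.
# x: cells x genes matrix; idx1/idx2: row indices of the two groups.
# Uses the exact null distribution when both groups are small and the gene
# has no ties; otherwise the normal approximation with tie correction and
# continuity correction (two-sided).
rank_sum_test <- function(x, idx1, idx2, exact_max_n = 10) {
  n1 <- length(idx1); n2 <- length(idx2)
  sub <- x[c(idx1, idx2), , drop = FALSE]
  p <- vapply(seq_len(ncol(sub)), function(j) {
    v <- sub[, j]
    r <- rank(v)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    has_ties <- any(ties > 1)
    if (!has_ties && max(n1, n2) <= exact_max_n) {
      p_lo <- pwilcox(u, n1, n2)
      p_hi <- 1 - pwilcox(u - 1, n1, n2)
      return(min(1, 2 * min(p_lo, p_hi)))
    }
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    z <- u - mu
    corr <- sign(z) * 0.5
    min(1, 2 * pnorm(-abs((z - corr) / sqrt(sigma2))))
  }, numeric(1))
  names(p) <- colnames(x)
  p
}

# Gaussian kernel vector (odd length), normalised to sum 1.
gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D correlation of matrix `img` with outer(ky, kx), replicate
# boundary, via EBImage's filter.
sep_filter <- function(img, kx, ky = kx) {
  EBImage::filter2(img, outer(ky, kx), boundary = "replicate")
}

# Gaussian smoothing with the kernel radius capped so the filter fits the
# image (needed at coarse pyramid levels / small maps).
gauss_smooth <- function(img, sigma) {
  radius <- min(ceiling(3 * sigma), floor((min(dim(img)) - 1) / 2))
  if (radius < 1) return(img)
  sep_filter(img, gauss_kernel(sigma, radius))
}

# Bilinear sampling of matrix `img` at (row, col) positions (may be fractional);
# positions outside the matrix are clamped to the border.
bilinear_sample <- function(img, row, col) {
  row <- as.vector(row); col <- as.vector(col)
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1); c0 <- pmin(floor(col), nc - 1)
  if (nr == 1) r0 <- rep(1, length(row))
  if (nc == 1) c0 <- rep(1, length(col))
  fr <- row - r0; fc <- col - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(pmin(r0 + 1, nr), c0)]
  i01 <- img[cbind(r0, pmin(c0 + 1, nc))]
  i11 <- img[cbind(pmin(r0 + 1, nr), pmin(c0 + 1, nc))]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}
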