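# Independent oracles, deliberately written as plain loops/enumeration so
# they share no code path with the package implementation.

# Brute-force DES: one sample at a time, scalar arithmetic only.
des_bruteforce <- function(expr_vec, cn_vec, loss = 1.7, gain = 2.3, k = 1,
                           min_cna_fraction = 0.10, min_neutral = 5) {
  n <- length(cn_vec)
  neutral <- c(); gains <- c(); losses <- c()
  for (i in seq_len(n)) {
    if (is.na(cn_vec[i])) next
    if (cn_vec[i] < loss) losses <- c(losses, i)
    else if (cn_vec[i] > gain) gains <- c(gains, i)
    else neutral <- c(neutral, i)
  }
  cna <- length(gains) + length(losses)
  if (cna <= min_cna_fraction * n || length(neutral) < min_neutral)
    return(NA_real_)
  mu <- mean(expr_vec[neutral]); sdv <- stats::sd(expr_vec[neutral])
  if (sdv == 0) return(NA_real_)
  conc <- 0
  for (i in gains) if (expr_vec[i] > mu + k * sdv) conc <- conc + 1
  for (i in losses) if (expr_vec[i] < mu - k * sdv) conc <- conc + 1
  conc / cna
}

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins (probability-mass criterion, with the standard
# relative tolerance for ties).
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) stats::dhyper(x, r1, r2, c1), numeric(1))
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact conditional Cochran-Armitage p by expand.grid enumeration of row-1
# counts (independent of the package's recursive enumeration).
ca_enum_p <- function(tab, scores = seq_len(ncol(tab))) {
  nk <- colSums(tab); N <- sum(nk); R1 <- sum(tab[1, ])
  cen <- nk * R1 / N
  stat <- function(x1) abs(sum(scores * (x1 - cen)))
  t_obs <- stat(tab[1, ])
  grid <- do.call(expand.grid, lapply(nk, function(m) 0:m))
  grid <- grid[rowSums(grid) == R1, , drop = FALSE]
  logp <- apply(grid, 1, function(x1) sum(lchoose(nk, x1))) - lchoose(N, R1)
  ts <- apply(grid, 1, stat)
  sum(exp(logp[ts >= t_obs - 1e-9]))
}

# Small hand-buildable paired dataset from explicit matrices.
toy_dataset <- function(expr, cn, chrom = NULL) {
  g <- rownames(expr)
  ann <- gene_annotation(data.frame(
    gene = g,
    chrom = if (is.null(chrom)) rep("1", length(g)) else chrom,
    tx_start = seq_along(g) * 1000L,
    tx_end = seq_along(g) * 1000L + 500L))
  suppressMessages(align_paired(omics_matrix(expr, "expression"),
                                omics_matrix(cn, "copy_number"), ann))
}

# Random small cohort for oracle-equivalence loops.
random_small_cohort <- function(n_genes, n_samples) {
  g <- sprintf("G%02d", seq_len(n_genes))
  s <- sprintf("S%02d", seq_len(n_samples))
  cn <- matrix(sample(c(1, 1.5, 2, 2.1, 2.6, 3), n_genes * n_samples,
                      replace = TRUE),
               n_genes, n_samples, dimnames = list(g, s))
  cn[stats::runif(length(cn)) < 0.05] <- NA
  expr <- matrix(stats::rnorm(n_genes * n_samples, 8, 1), n_genes, n_samples,
                 dimnames = list(g, s))
  toy_dataset(expr, cn)
}
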