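test_that("copy-number status bands are inclusive at the thresholds", {
  expect_identical(cna_status(c(1.6, 2.5, 2.0, 2.3, 1.7, NA)),
                   c("loss", "gain", "neutral", "neutral", "neutral",
                     "missing"))
})

test_that("DES matches the hand-computed toy cohort", {
  # 14 neutral samples scaled to neutral mean 10 and sd 1 exactly,
  # 6 gain samples (CN 2.8): expressions > 11 are concordant
  neut <- as.numeric(scale(c(1:7, 1:7))) + 10
  expect_equal(mean(neut), 10)
  expect_equal(sd(neut), 1)
  gain_expr <- c(11.5, 11.2, 10.5, 9.8, 12.0, 10.9)
  ex <- matrix(c(neut, gain_expr), 1, 20,
               dimnames = list("G", sprintf("s%02d", 1:20)))
  cn <- matrix(c(rep(2, 14), rep(2.8, 6)), 1, 20, dimnames = dimnames(ex))
  des <- compute_des(toy_dataset(ex, cn))
  expect_equal(des$neutral_mean, 10)
  expect_equal(des$neutral_sd, 1)
  expect_equal(des$cna_count, 6L)
  expect_equal(des$concordant_count, 3)          # 11.5, 11.2, 12.0
  expect_equal(des$des, 0.5)
  expect_identical(des$category, "high")

  # no CNA expression escapes the band -> DES 0
  ex0 <- matrix(c(neut, rep(10, 6)), 1, 20, dimnames = dimnames(ex))
  expect_equal(compute_des(toy_dataset(ex0, cn))$des, 0)

  # frequency guard: 1 altered sample out of 20 leaves DES undefined
  cn1 <- matrix(c(rep(2, 19), 2.8), 1, 20, dimnames = dimnames(ex))
  d1 <- compute_des(toy_dataset(ex, cn1))
  expect_true(is.na(d1$des))
  expect_identical(d1$undefined_reason, "low_cna_frequency")
})

test_that("losses count concordance downward and both directions combine", {
  neut <- as.numeric(scale(c(1:7, 1:7))) + 10
  ex <- matrix(c(neut, 8.5, 9.5, 11.8, 10.2), 1, 18,
               dimnames = list("G", sprintf("s%02d", 1:18)))
  cn <- matrix(c(rep(2, 14), 1.4, 1.5, 2.9, 3.0), 1, 18,
               dimnames = dimnames(ex))
  des <- compute_des(toy_dataset(ex, cn))
  expect_equal(des$gain_count, 2L)
  expect_equal(des$loss_count, 2L)
  # loss at 8.5 (< 9) and gain at 11.8 (> 11) are concordant
  expect_equal(des$concordant_count, 2)
  expect_equal(des$des, 0.5)
})

test_that("DES category bounds follow low < 0.2 <= medium <= 0.4 < high", {
  expect_identical(categorize_des(c(0.19, 0.20, 0.40, 0.41, 0, 1, NA)),
                   c("low", "medium", "medium", "high", "low", "high",
                     NA_character_))
})

test_that("DES agrees with brute-force enumeration on small cohorts", {
  set.seed(202)
  p <- des_params(min_neutral_samples = 3)
  for (rep in 1:40) {
    n <- sample(6:12, 1)
    pd <- random_small_cohort(n_genes = 8, n_samples = n)
    des <- compute_des(pd, p)
    for (i in seq_len(8)) {
      expected <- des_bruteforce(pd$expression$values[i, ],
                                 pd$copy_number$values[i, ],
                                 min_neutral = 3)
      expect_equal(des$des[i], expected, info = sprintf("rep %d gene %d", rep, i))
    }
  }
})

test_that("DES is invariant to affine expression rescaling and sample order", {
  set.seed(303)
  sim <- simulate_cohort(sim_config(n_samples = 40, n_genes = 150, seed = 31))
  pd <- sim$dataset
  des <- compute_des(pd)

  scaled <- pd
  scaled$expression$values <- pd$expression$values * 3.7 - 12
  expect_equal(compute_des(scaled)$des, des$des)

  perm <- sample(ncol(pd$expression$values))
  shuffled <- suppressMessages(align_paired(
    omics_matrix(pd$expression$values[, perm], "expression"),
    omics_matrix(pd$copy_number$values[, perm], "copy_number"),
    pd$annotation))
  expect_equal(compute_des(shuffled)$des, des$des)

  # more concordant samples can only raise the score at fixed CNA count
  ok <- !is.na(des$des)
  expect_true(all(des$des[ok] >= 0 & des$des[ok] <= 1))
  expect_true(all(des$concordant_count[ok] <= des$cna_count[ok]))
})

test_that("dosage-resistant genes are highly expressed with low DES", {
  genes <- sprintf("g%02d", 1:10)
  samples <- sprintf("s%02d", 1:20)
  # expression medians increase g01 -> g10; g09, g10 are the top quintile
  ex <- matrix(rep(1:10, times = 20), 10, 20,
               dimnames = list(genes, samples))
  ex <- ex + matrix(seq(-0.01, 0.01, length.out = 200), 10, 20)
  cn <- matrix(2, 10, 20, dimnames = dimnames(ex))
  cn[, 1:8] <- 2.8                         # every gene altered in 8/20
  neut <- as.numeric(scale(1:12))
  ex[, 9:20] <- matrix(rep(1:10, 12), 10, 12) + rep(neut, each = 10) * 0.01
  # make g10 concordant in 5/8 gains, g09 in 0/8
  ex["g10", 1:5] <- 10 + 1
  pd <- toy_dataset(ex, cn)
  des <- compute_des(pd)
  expect_true(des$des[des$gene == "g10"] > 0.2)
  expect_true(des$des[des$gene == "g09"] < 0.2)
  res <- identify_dosage_resistant(pd, des)
  expect_identical(res, "g09")

  # when the resistance bound admits no score, nothing is resistant
  p_strict <- des_params(resistant_des_max = 0)
  expect_length(identify_dosage_resistant(pd, des, p_strict), 0L)
})

test_that("expression strata are equal-sized with remainder to lower groups", {
  sim <- simulate_cohort(sim_config(n_samples = 50, n_genes = 320, seed = 77))
  des <- compute_des(sim$dataset)
  tr <- expression_group_trend(sim$dataset, des)
  sizes <- colSums(tr$table)
  nd <- sum(!is.na(des$des))
  expect_equal(sum(sizes), nd)
  expect_true(max(sizes) - min(sizes) <= 1)
  # remainder goes to the lower-expression (first) groups
  expect_true(all(diff(sizes) <= 0))
  expect_true(tr$p_value >= 0 && tr$p_value <= 1)
})

test_that("a planted expression-linked gradient is detected, a flat one is not", {
  # only highly expressed genes are dosage sensitive -> strong trend
  cfg <- sim_config(n_samples = 120, n_genes = 500, seed = 13,
                    frac_sensitive = 0)
  sim <- simulate_cohort(cfg)
  pd <- sim$dataset
  mu <- sim$truth$genes$mu_g
  top <- mu >= quantile(mu, 0.8)
  att <- 2 + sweep(sim$truth$true_cn - 2L, 2, sim$truth$samples$purity, `*`)
  ex <- pd$expression$values
  ex[top, ] <- ex[top, ] + log2(att[top, ] / 2)
  pd2 <- suppressMessages(align_paired(omics_matrix(ex, "expression"),
                                       pd$copy_number, pd$annotation))
  tr <- expression_group_trend(pd2, compute_des(pd2))
  expect_lt(tr$p_value, 1e-6)

  # every scored gene high -> no gradient possible
  des_all_high <- compute_des(pd2)
  des_all_high$des[!is.na(des_all_high$des)] <- 0.9
  tr2 <- expression_group_trend(pd2, des_all_high)
  expect_equal(tr2$p_value, 1)
  expect_equal(tr2$z, 0)
})

test_that("chromosome summary reports category proportions and CNA burden", {
  genes <- c("a", "b", "c", "d", "e")
  des <- structure(data.frame(
    gene = genes, n_samples = 10,
    gain_count = c(1, 3, 2, 0, 0), loss_count = c(0, 0, 1, 2, 0),
    cna_count = c(1, 3, 3, 2, 0), neutral_count = 9,
    neutral_mean = 0, neutral_sd = 1,
    concordant_count = c(1, 1, 1, 1, NA),
    des = c(0.9, 1 / 3, 0.1, 0.1, NA),
    category = c("high", "medium", "low", "low", NA),
    undefined_reason = c(NA, NA, NA, NA, "low_cna_frequency"),
    stringsAsFactors = FALSE), class = c("des_table", "data.frame"))
  ann <- gene_annotation(data.frame(
    gene = genes, chrom = c("1", "1", "1", "1", "2"),
    tx_start = 1:5 * 1000, tx_end = 1:5 * 1000 + 10))
  out <- suppressMessages(chromosome_summary(des, ann))
  c1 <- out[out$chrom == "1", ]
  expect_equal(c1$n_defined, 4L)
  expect_equal(c1$prop_high, 0.25)
  expect_equal(c1$prop_low, 0.5)
  expect_equal(c1$mean_cna_fraction, mean(c(0.1, 0.3, 0.3, 0.2)))
  c2 <- out[out$chrom == "2", ]
  expect_true(is.na(c2$prop_high))
  expect_equal(c2$mean_cna_fraction, 0)
})
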