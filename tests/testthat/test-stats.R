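test_that("BH adjustment is step-up and order-preserving", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- sort(runif(50))
  expect_true(all(diff(bh_adjust(p)) >= 0))
  expect_true(all(bh_adjust(p) >= p))
  # permuting input then un-permuting output is a no-op
  set.seed(1)
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher exact test follows the probability-mass criterion", {
  f <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(f$p_value, 1)
  expect_equal(f$odds_ratio, 1)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3)$p_value, 34 / 70)
  expect_lt(fisher_exact_2x2(744, 3958, 416, 7718)$p_value, 2.2e-16)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margin")
  # Haldane-corrected sample odds ratio when a cell is zero
  expect_equal(fisher_exact_2x2(4, 0, 2, 6)$odds_ratio,
               (4.5 * 6.5) / (0.5 * 2.5))
  expect_equal(fisher_exact_2x2(8, 2, 3, 9)$odds_ratio, (8 * 9) / (2 * 3))
})

test_that("Fisher p equals hypergeometric enumeration on random tables", {
  set.seed(404)
  for (i in 1:200) {
    N <- sample(4:40, 1)
    repeat {
      x <- as.vector(stats::rmultinom(1, N, runif(4, 0.1, 1)))
      if (x[1] + x[2] > 0 && x[3] + x[4] > 0 &&
          x[1] + x[3] > 0 && x[2] + x[4] > 0) break
    }
    expect_equal(fisher_exact_2x2(x[1], x[2], x[3], x[4])$p_value,
                 fisher_enum_p(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-10,
                 info = paste(x, collapse = ","))
  }
})

test_that("two-proportion chi-square reproduces known values", {
  expect_equal(two_proportion_test(2418, 4702, 3999, 8134)$p_value, 0.014,
               tolerance = 0.05)
  expect_equal(two_proportion_test(30, 100, 30, 100)$p_value, 1)
  # closed form: z = 0.20 / sqrt(0.4 * 0.6 * (1/100 + 1/100))
  z <- 0.20 / sqrt(0.4 * 0.6 * 0.02)
  expect_equal(two_proportion_test(30, 100, 50, 100)$p_value,
               2 * pnorm(-z))
  expect_warning(pdeg <- two_proportion_test(0, 5, 0, 7), "degenerate")
  expect_equal(pdeg$p_value, 1)
})

test_that("overlap significance delegates to the 2x2 Fisher test", {
  expect_equal(hypergeometric_overlap(4, 4, 3, 8)$p_value,
               fisher_exact_2x2(3, 1, 1, 3)$p_value)
  expect_lt(hypergeometric_overlap(2958, 611, 306, 12836)$p_value, 2.2e-16)
  # an overlap at its expectation is unremarkable
  expect_gt(hypergeometric_overlap(100, 100, 10, 1000)$p_value, 0.5)
  expect_error(hypergeometric_overlap(4, 4, 5, 100), "exceeds")
  expect_error(hypergeometric_overlap(40, 40, 0, 50), "universe")
})

test_that("Cochran-Armitage statistic behaves under null and trend", {
  flat <- rbind(c(4, 4, 4), c(6, 6, 6))
  ca <- cochran_armitage_trend(flat)
  expect_equal(ca$z, 0)
  expect_equal(ca$p_value, 1)

  # asymptotic z matches the classic chi-square trend test up to the
  # finite-population factor (N-1)/N
  tab <- rbind(c(10, 14, 20, 30), c(40, 35, 30, 22))
  ca2 <- cochran_armitage_trend(tab, exact = FALSE)
  ptt <- stats::prop.trend.test(tab[1, ], colSums(tab), score = 1:4)
  N <- sum(tab)
  expect_equal(ca2$z^2, unname(ptt$statistic) * (N - 1) / N)

  big <- rbind(c(10, 30, 60, 90), c(90, 70, 40, 15))
  expect_lt(cochran_armitage_trend(big)$p_value, 1e-6)
  expect_error(cochran_armitage_trend(rbind(c(0, 0, 0), c(1, 2, 3))),
               "zero row margin")
  expect_error(cochran_armitage_trend(rbind(c(1, 2), c(3, 4))), "K >= 3")
})

test_that("exact Cochran-Armitage p matches independent enumeration", {
  tab <- rbind(c(1, 2, 3), c(3, 2, 1))
  ca <- cochran_armitage_trend(tab)
  expect_identical(ca$method, "exact")
  expect_equal(ca$p_value, ca_enum_p(tab), tolerance = 1e-9)

  set.seed(505)
  for (i in 1:25) {
    K <- sample(3:5, 1)
    nk <- sample(1:7, K, replace = TRUE)
    x1 <- vapply(nk, function(m) sample(0:m, 1), integer(1))
    tab <- rbind(x1, nk - x1)
    if (any(rowSums(tab) == 0)) next
    expect_equal(cochran_armitage_trend(tab, exact = TRUE)$p_value,
                 ca_enum_p(tab), tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
})

test_that("moderated differential expression is sane on toy input", {
  ex <- matrix(rnorm(100 * 12), 100, 12,
               dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:12)))
  ex["g001", ] <- 5                     # identical in both groups
  ex["g002", 7:12] <- ex["g002", 7:12] + 50
  grp <- setNames(rep(c("A", "B"), each = 6), colnames(ex))
  de <- differential_expression(omics_matrix(ex, "expression"), grp)
  expect_equal(de$t[de$gene == "g001"], 0)
  expect_equal(de$p_value[de$gene == "g001"], 1)
  expect_true(de$significant[de$gene == "g002"])
  expect_identical(de$direction[de$gene == "g002"], "down_in_A")
  expect_true(all(de$p_adjusted >= de$p_value))
  expect_identical(de$significant, de$p_adjusted < 0.05)

  bad <- setNames(c("A", rep("B", 11)), colnames(ex))
  expect_error(differential_expression(omics_matrix(ex, "expression"), bad),
               ">= 2 samples")
})

test_that("per-chromosome DE counts and trisomy enrichment are wired", {
  genes <- sprintf("g%02d", 1:20)
  ann <- gene_annotation(data.frame(
    gene = genes, chrom = rep(c("9", "10"), each = 10),
    tx_start = 1:20 * 1000, tx_end = 1:20 * 1000 + 10))
  de <- structure(data.frame(
    gene = genes, mean_A = 1, mean_B = 0, t = 5,
    p_value = 0.001, p_adjusted = 0.01,
    direction = "up_in_A",
    significant = rep(c(TRUE, FALSE), each = 10),
    stringsAsFactors = FALSE), class = c("de_result", "data.frame"))
  out <- de_by_chromosome(de, ann, trisomy_chromosomes = "9")
  expect_equal(out$counts$n_up[out$counts$chrom == "9"], 10L)
  expect_equal(out$counts$n_up[out$counts$chrom == "10"], 0L)
  expect_equal(out$up_enrichment$p_value,
               fisher_exact_2x2(10, 0, 0, 10)$p_value)
  # row order of the input does not matter
  out2 <- de_by_chromosome(de[sample(20), ], ann, trisomy_chromosomes = "9")
  expect_equal(out2$counts, out$counts)

  de$significant <- FALSE
  expect_message(out3 <- de_by_chromosome(de, ann, "9"), "skipped")
  expect_null(out3$up_enrichment)
  expect_equal(sum(out3$counts$n_up), 0L)
})

test_that("expressed-gene flag takes the top half with tie inclusion", {
  m <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3,
              dimnames = list(c("a", "b", "c", "d"), c("s1", "s2", "s3")))
  f <- expressed_gene_flag(omics_matrix(m, "expression"))
  expect_identical(unname(f), c(FALSE, FALSE, TRUE, TRUE))
  m2 <- matrix(7, 4, 3, dimnames = dimnames(m))
  expect_true(all(expressed_gene_flag(omics_matrix(m2, "expression"))))
  # distinct medians split the genes into halves differing by at most one
  set.seed(6)
  m3 <- matrix(rnorm(33 * 4), 33, 4,
               dimnames = list(sprintf("g%02d", 1:33), paste0("s", 1:4)))
  f3 <- expressed_gene_flag(omics_matrix(m3, "expression"))
  expect_lte(abs(sum(f3) - sum(!f3)), 1)
})

test_that("gene-set enrichment ranks a planted set first", {
  universe <- sprintf("g%03d", 1:200)
  query <- universe[1:40]
  sets <- list(planted = universe[1:30],
               unrelated = universe[101:130],
               mixed = universe[c(1:5, 150:174)])
  res <- gene_set_enrichment(query, sets, universe)
  expect_identical(res$set[1], "planted")
  expect_lt(res$p_value[1], 1e-10)
  expect_equal(res$overlap[res$set == "planted"], 30L)
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("tiny p-values print with the conventional floor", {
  expect_identical(format_pvalue(c(1e-20, 0.5)), c("< 2.2e-16", "0.5"))
})
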