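#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, order-preserving with the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p-value under the probability-mass criterion: the sum of
#' hypergeometric probabilities of all tables with the observed margins that
#' are no more probable than the observed one. The reported odds ratio is
#' the sample (cross-product) odds ratio, with a Haldane correction of 0.5
#' per cell when any cell is zero.
#'
#' @param a,b,c,d Non-negative integer counts, row-wise: `(a, b)` / `(c, d)`.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("all-zero table")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("every margin of the table must be positive")
  m <- matrix(x, 2L, 2L, byrow = TRUE)
  p <- stats::fisher.test(m)$p.value
  or <- if (any(x == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Two-proportion test (chi-square homogeneity, no continuity correction)
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `p_value`, `prop1`, `prop2`. Degenerate margins (all
#'   successes or all failures pooled) give p = 1 with a warning.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2, n1 > 0, n2 > 0)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2L, 2L, byrow = TRUE)
  if (any(colSums(tab) == 0)) {
    warning("degenerate margin: both groups all-success or all-failure; p = 1")
    return(list(p_value = 1, prop1 = x1 / n1, prop2 = x2 / n2))
  }
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(p_value = p, prop1 = x1 / n1, prop2 = x2 / n2)
}

#' Significance of an overlap between two gene lists
#'
#' Builds the 2 x 2 table (overlap, query-only, set-only, rest of universe)
#' and applies [fisher_exact_2x2()].
#'
#' @param query_size,set_size Sizes of the two lists.
#' @param overlap Number of shared genes.
#' @param universe Total number of genes considered.
#' @return List with `odds_ratio` and `p_value`.
#' @export
hypergeometric_overlap <- function(query_size, set_size, overlap, universe) {
  if (overlap > min(query_size, set_size))
    stop("overlap exceeds the smaller list")
  rest <- universe - query_size - set_size + overlap
  if (rest < 0) stop("universe smaller than the union of the two lists")
  fisher_exact_2x2(overlap, query_size - overlap, set_size - overlap, rest)
}

#' Cochran-Armitage trend test for a 2 x K table
#'
#' Tests for a monotone trend in the proportion of row-1 counts across
#' ordered columns. The statistic is
#' `T = sum_k s_k * (x_1k - n_k * R1 / N)` with variance conditional on all
#' margins (hypergeometric, including the `N/(N-1)` finite-population
#' factor); `z = T / sqrt(Var)` is referred to a standard normal,
#' two-sided. For small tables (`N <= 30` by default when `exact = NULL`)
#' an exact conditional p-value is computed by enumerating all tables with
#' the observed margins and summing the probability of those with
#' `|T| >= |T_obs|`.
#'
#' @param table 2 x K matrix of non-negative integer counts, K >= 3.
#' @param scores Ordered column scores, default `1:K`.
#' @param exact `TRUE`/`FALSE` to force, `NULL` to enumerate exactly when
#'   the total count is at most 30.
#' @return List with `z`, `p_value`, `method` (`"asymptotic"` or `"exact"`),
#'   and `p_asymptotic`.
#' @export
cochran_armitage_trend <- function(table, scores = NULL, exact = NULL) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 3L)
    stop("need a 2 x K table with K >= 3")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0)) stop("zero row margin")
  K <- ncol(table)
  if (is.null(scores)) scores <- seq_len(K)
  stopifnot(length(scores) == K)
  nk <- colSums(table)
  N <- sum(nk)
  R1 <- sum(table[1L, ])
  R2 <- N - R1
  Tobs <- sum(scores * (table[1L, ] - nk * R1 / N))
  v <- R1 * R2 / (N^2 * (N - 1)) * (N * sum(nk * scores^2) - sum(nk * scores)^2)
  z <- if (v > 0) Tobs / sqrt(v) else 0
  p_asym <- if (v > 0) 2 * stats::pnorm(-abs(z)) else 1
  use_exact <- if (is.null(exact)) N <= 30 else isTRUE(exact)
  if (use_exact) {
    p <- .ca_exact_p(table, scores)
    list(z = z, p_value = p, method = "exact", p_asymptotic = p_asym)
  } else {
    list(z = z, p_value = p_asym, method = "asymptotic", p_asymptotic = p_asym)
  }
}

# exact conditional two-sided p: enumerate all 2xK tables with the observed
# margins; P(table) is multivariate hypergeometric; extremeness by |T|
.ca_exact_p <- function(table, scores) {
  nk <- colSums(table)
  K <- length(nk)
  N <- sum(nk)
  R1 <- sum(table[1L, ])
  cen <- nk * R1 / N
  Tobs <- abs(sum(scores * (table[1L, ] - cen)))
  logdenom <- lchoose(N, R1)
  p <- 0
  rec <- function(k, rem, logp, tpart) {
    if (k > K) {
      if (rem == 0L && abs(tpart) >= Tobs - 1e-9)
        p <<- p + exp(logp - logdenom)
      return(invisible())
    }
    tail_cap <- if (k < K) sum(nk[(k + 1):K]) else 0L
    lo <- max(0L, rem - tail_cap)
    hi <- min(nk[k], rem)
    if (lo > hi) return(invisible())
    for (x in lo:hi)
      rec(k + 1L, rem - x, logp + lchoose(nk[k], x),
          tpart + scores[k] * (x - cen[k]))
    invisible()
  }
  rec(1L, R1, 0, 0)
  min(p, 1)
}

#' Moderated two-group differential expression
#'
#' Per-gene two-sample t test with the pooled variance shrunk toward the
#' across-gene median pooled variance with equal weight
#' (`s2_shrunk = (s2_gene + s2_median) / 2`), which stabilizes small
#' variances the way empirical-Bayes moderation does; the reference degrees
#' of freedom are inflated to `2 * (n1 + n2 - 2)` to account for the
#' information borrowed from the variance ensemble. P-values are BH-adjusted.
#'
#' @param expr An expression [omics_matrix()].
#' @param groups A `ploidy_call_set`, or a factor / character vector with
#'   exactly two levels, named by (or ordered as) the matrix samples.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param shrink_weight Weight of the across-gene median variance (0.5).
#' @return A `de_result` data.frame: `gene`, `mean_A`, `mean_B`, `t`,
#'   `p_value`, `p_adjusted`, `direction` (`"up_in_A"`/`"down_in_A"`),
#'   `significant`. Attribute `groups` records the two levels (A, B).
#' @export
differential_expression <- function(expr, groups, alpha = 0.05,
                                    shrink_weight = 0.5) {
  stopifnot(inherits(expr, "omics_matrix"), expr$role == "expression")
  if (inherits(groups, "ploidy_call_set"))
    groups <- stats::setNames(groups$label, groups$sample)
  g <- as.character(groups)
  if (!is.null(names(groups))) {
    miss <- setdiff(sample_ids(expr), names(groups))
    if (length(miss)) stop("no group label for sample(s): ",
                           paste(miss, collapse = ", "))
    g <- as.character(groups[sample_ids(expr)])
  } else if (length(g) != ncol(expr$values))
    stop("`groups` must be named or match the sample count")
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("exactly two groups required, got: ",
                              paste(lev, collapse = ", "))
  iA <- g == lev[1L]; iB <- g == lev[2L]
  n1 <- sum(iA); n2 <- sum(iB)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  vA <- expr$values[, iA, drop = FALSE]
  vB <- expr$values[, iB, drop = FALSE]
  mA <- rowMeans(vA); mB <- rowMeans(vB)
  s2 <- (rowSums((vA - mA)^2) + rowSums((vB - mB)^2)) / (n1 + n2 - 2)
  s2_shrunk <- (1 - shrink_weight) * s2 + shrink_weight * stats::median(s2)
  se <- sqrt(s2_shrunk * (1 / n1 + 1 / n2))
  d <- mA - mB
  t_stat <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  df <- 2 * (n1 + n2 - 2)
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  padj <- bh_adjust(p)
  out <- data.frame(
    gene = rownames(expr$values),
    mean_A = mA, mean_B = mB, t = t_stat, p_value = p, p_adjusted = padj,
    direction = ifelse(d >= 0, "up_in_A", "down_in_A"),
    significant = padj < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, groups = c(A = lev[1L], B = lev[2L]), alpha = alpha,
            class = c("de_result", "data.frame"))
}

#' Differential expression counts by chromosome, with trisomy enrichment
#'
#' Counts significantly up- and down-regulated genes (group A relative to
#' group B) per chromosome and tests, with Fisher's exact test, whether
#' up-regulated (and, separately, down-regulated) genes are enriched on the
#' trisomy chromosomes.
#'
#' @param de A `de_result`.
#' @param annotation A `gene_annotation` covering the tested genes.
#' @param trisomy_chromosomes Chromosome labels treated as trisomic.
#' @return List: `counts` (data.frame chrom / n_genes / n_up / n_down),
#'   `up_enrichment`, `down_enrichment` (each a [fisher_exact_2x2()] result
#'   plus the table, or `NULL` with a message when there is nothing to
#'   test).
#' @export
de_by_chromosome <- function(de, annotation,
                             trisomy_chromosomes = ploidy_params()$trisomy_chromosomes) {
  annotation <- gene_annotation(annotation)
  chrom <- annotation[de$gene, "chrom"]
  if (anyNA(chrom)) stop("de result contains genes absent from annotation")
  up <- de$significant & de$direction == "up_in_A"
  dn <- de$significant & de$direction == "down_in_A"
  counts <- do.call(rbind, lapply(split(seq_along(chrom), chrom), function(i)
    data.frame(chrom = chrom[i[1L]], n_genes = length(i),
               n_up = sum(up[i]), n_down = sum(dn[i]),
               stringsAsFactors = FALSE)))
  suppressWarnings({
    num <- as.numeric(counts$chrom)
    counts <- counts[order(is.na(num), num, counts$chrom), , drop = FALSE]
  })
  rownames(counts) <- NULL
  on_tri <- chrom %in% trisomy_chromosomes
  enrich <- function(flag) {
    if (!any(flag)) {
      message("no significant genes; enrichment test skipped")
      return(NULL)
    }
    tab <- c(sum(flag & on_tri), sum(!flag & on_tri),
             sum(flag & !on_tri), sum(!flag & !on_tri))
    res <- fisher_exact_2x2(tab[1L], tab[2L], tab[3L], tab[4L])
    res$table <- matrix(tab, 2L, 2L, byrow = TRUE,
                        dimnames = list(c("trisomy", "other"),
                                        c("flagged", "not_flagged")))
    res
  }
  list(counts = counts, up_enrichment = enrich(up), down_enrichment = enrich(dn))
}

#' Flag expressed genes (top half by median expression)
#'
#' A gene is "expressed" when its median expression across samples is at or
#' above the across-gene median of those medians (ties included).
#'
#' @param expr An expression [omics_matrix()] with >= 2 genes.
#' @return Named logical vector, one flag per gene.
#' @export
expressed_gene_flag <- function(expr) {
  stopifnot(inherits(expr, "omics_matrix"), nrow(expr$values) >= 2L)
  med <- apply(expr$values, 1L, stats::median)
  med >= stats::median(med)
}

#' Fisher-exact enrichment of a query gene list in gene sets
#'
#' One 2 x 2 Fisher test per set (overlap with the query versus the rest of
#' the universe), BH-adjusted across sets.
#'
#' @param query Character vector of gene symbols (e.g. dosage-sensitive
#'   genes).
#' @param gene_sets Named list of character vectors (see
#'   [read_gene_sets()]).
#' @param universe Character vector of all eligible gene symbols; query and
#'   sets are intersected with it.
#' @return data.frame: `set`, `set_size`, `overlap`, `odds_ratio`,
#'   `p_value`, `p_adjusted`, sorted by p-value.
#' @export
gene_set_enrichment <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (!length(query)) stop("query has no gene in the universe")
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(s, query))
    if (!length(s))
      return(data.frame(set = nm, set_size = 0L, overlap = 0L,
                        odds_ratio = NA_real_, p_value = 1,
                        stringsAsFactors = FALSE))
    f <- fisher_exact_2x2(ov, length(query) - ov, length(s) - ov,
                          length(universe) - length(query) - length(s) + ov)
    data.frame(set = nm, set_size = length(s), overlap = ov,
               odds_ratio = f$odds_ratio, p_value = f$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out[order(out$p_value, out$set), , drop = FALSE]
}

#' Format a p-value the way small p-values are conventionally reported
#'
#' Values below the double-precision floor 2.2e-16 print as "< 2.2e-16".
#'
#' @param p Numeric vector.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 2.2e-16) "< 2.2e-16" else format(signif(x, 3))
  }, character(1))
}
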