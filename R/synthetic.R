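# Approximate autosome lengths (Mb) and centromere positions (Mb), used
# only to lay out a plausible synthetic genome.
.chrom_lengths_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136,
                       135, 134, 115, 107, 102, 90, 81, 78, 59, 63, 48, 51)
.centromere_mb <- c(125, 93, 91, 50, 48, 61, 60, 45, 49, 40,
                    53, 36, 18, 17, 19, 36, 24, 17, 26, 28, 13, 15)

#' Configuration of the synthetic paired cohort
#'
#' The generator emulates the copy-number architecture of a myeloma-like
#' cohort: a hyperdiploid subtype (HMM) with trisomies of chromosomes 3, 5,
#' 7, 9, 11, 15, 19 and 21, recurrent whole-chromosome/arm events
#' (chromosome 13 loss enriched in the non-hyperdiploid subtype, 1q gain,
#' 8p and 16q loss), tumor purity that attenuates the observed copy number
#' toward 2 (so trisomies peak near 2.6, not 3), and per-gene dosage
#' sensitivity: a sensitive gene's log2 expression tracks
#' `log2(attenuated_CN / 2)`, a resistant gene's ignores copy number.
#'
#' @param n_samples,n_genes Cohort dimensions (defaults 200 x 2000).
#' @param p_hmm Probability that a sample is hyperdiploid (0.5).
#' @param trisomy_chromosomes Chromosomes trisomic in HMM samples.
#' @param events data.frame of recurrent events: `region` (`"chr13"`,
#'   `"chr1q"`, ... — optional `p`/`q` arm suffix), `type` (`"gain"` or
#'   `"loss"`), `p_hmm`, `p_nhmm` (per-subtype event probabilities).
#' @param purity_mean,purity_sd Per-sample tumor purity distribution
#'   (Normal, clamped to `[0.05, 1]`); defaults 0.6 and 0.1.
#' @param cn_noise_sd Measurement noise on observed copy number (0.08).
#' @param frac_sensitive Fraction of genes with dosage sensitivity 1 (0.3).
#' @param mu_mean,mu_sd Baseline log2 expression distribution (8, 2).
#' @param expr_noise_sd Expression noise on the log2 scale (0.5).
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 200, n_genes = 2000, p_hmm = 0.5,
                       trisomy_chromosomes = c("3", "5", "7", "9", "11",
                                               "15", "19", "21"),
                       events = data.frame(
                         region = c("chr13", "chr1q", "chr8p", "chr16q"),
                         type = c("loss", "gain", "loss", "loss"),
                         p_hmm = c(0.1, 0.3, 0.2, 0.2),
                         p_nhmm = c(0.7, 0.5, 0.2, 0.2),
                         stringsAsFactors = FALSE),
                       purity_mean = 0.6, purity_sd = 0.1,
                       cn_noise_sd = 0.08, frac_sensitive = 0.3,
                       mu_mean = 8, mu_sd = 2, expr_noise_sd = 0.5,
                       seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= 22, p_hmm >= 0, p_hmm <= 1,
            all(c(events$p_hmm, events$p_nhmm) >= 0),
            all(c(events$p_hmm, events$p_nhmm) <= 1),
            all(events$type %in% c("gain", "loss")),
            purity_sd >= 0, cn_noise_sd >= 0, expr_noise_sd >= 0,
            frac_sensitive >= 0, frac_sensitive <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# allocate genes to 22 autosomes proportionally to length (largest-remainder
# rounding), evenly spaced midpoints, 20 kb transcripts
.synthetic_annotation <- function(n_genes) {
  len_bp <- .chrom_lengths_mb * 1e6
  raw <- n_genes * len_bp / sum(len_bp)
  n_c <- floor(raw)
  rem <- n_genes - sum(n_c)
  if (rem > 0) {
    o <- order(raw - n_c, decreasing = TRUE)
    n_c[o[seq_len(rem)]] <- n_c[o[seq_len(rem)]] + 1L
  }
  rows <- lapply(1:22, function(ch) {
    n <- n_c[ch]
    if (n == 0L) return(NULL)
    mid <- round(len_bp[ch] * (seq_len(n) - 0.5) / n)
    data.frame(chrom = as.character(ch),
               tx_start = pmax(1, mid - 10000),
               tx_end = mid + 10000, stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  ann <- data.frame(gene = sprintf("SIMG%04d", seq_len(nrow(ann))), ann,
                    stringsAsFactors = FALSE)
  gene_annotation(ann)
}

# genes hit by an event region like "chr13" (whole) or "chr1q" (arm)
.region_genes <- function(ann, region) {
  m <- regmatches(region, regexec("^chr([0-9XY]+)([pq]?)$", region))[[1L]]
  if (length(m) != 3L) stop("cannot parse event region: ", region)
  ch <- m[2L]; arm <- m[3L]
  on_ch <- ann$chrom == ch
  if (arm == "") return(on_ch)
  cen <- .centromere_mb[as.integer(ch)] * 1e6
  mid <- (ann$tx_start + ann$tx_end) / 2
  if (arm == "p") on_ch & mid < cen else on_ch & mid >= cen
}

#' Simulate a paired expression / copy-number cohort with known truth
#'
#' Generative model, with all draws from one seeded stream in a fixed,
#' documented order (subtype, purity, event indicators, gene sensitivity,
#' baseline expression, copy-number noise, expression noise):
#' \enumerate{
#'   \item subtype ~ Bernoulli(`p_hmm`); HMM samples carry true copy number
#'     3 on every trisomy-chromosome gene; each recurrent event fires per
#'     sample with its subtype-specific probability and sets its region to
#'     copy number 1 (loss) or 3 (gain); everything else is 2.
#'   \item observed CN = `2 + purity * (trueCN - 2) + N(0, cn_noise_sd)`,
#'     floored at 0.1 — purity attenuation is what moves the trisomy peak
#'     from 3 to about 2.6 at the default purity 0.6.
#'   \item log2 expression = `mu_g + s_g * log2(cn_att / 2) +
#'     N(0, expr_noise_sd)` with `cn_att = 2 + purity * (trueCN - 2)`, so a
#'     sensitive gene (`s_g = 1`) tracks the attenuated dosage and a
#'     resistant gene (`s_g = 0`) ignores it.
#' }
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a `paired_dataset`) and `truth`: `samples`
#'   (sample, subtype, purity), `genes` (gene, chrom, s_g, mu_g) and
#'   `true_cn` (genes x samples integer matrix in `{1, 2, 3}`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ann <- .synthetic_annotation(config$n_genes)
  G <- nrow(ann); S <- config$n_samples
  samples <- sprintf("S%03d", seq_len(S))

  subtype <- ifelse(stats::rbinom(S, 1L, config$p_hmm) == 1L, "HMM", "NHMM")
  purity <- pmin(1, pmax(0.05, stats::rnorm(S, config$purity_mean,
                                            config$purity_sd)))
  ev <- config$events
  event_on <- matrix(0L, nrow(ev), S)
  for (e in seq_len(nrow(ev))) {
    pr <- ifelse(subtype == "HMM", ev$p_hmm[e], ev$p_nhmm[e])
    event_on[e, ] <- stats::rbinom(S, 1L, pr)
  }
  s_g <- stats::rbinom(G, 1L, config$frac_sensitive)
  mu_g <- stats::rnorm(G, config$mu_mean, config$mu_sd)

  true_cn <- matrix(2L, G, S, dimnames = list(ann$gene, samples))
  on_tri <- ann$chrom %in% as.character(config$trisomy_chromosomes)
  true_cn[on_tri, subtype == "HMM"] <- 3L
  for (e in seq_len(nrow(ev))) {
    in_reg <- .region_genes(ann, ev$region[e])
    hit <- event_on[e, ] == 1L
    if (any(in_reg) && any(hit))
      true_cn[in_reg, hit] <- if (ev$type[e] == "gain") 3L else 1L
  }

  att <- 2 + sweep(true_cn - 2L, 2L, purity, `*`)
  cn_obs <- att + matrix(stats::rnorm(G * S, 0, config$cn_noise_sd), G, S)
  cn_obs <- pmax(cn_obs, 0.1)
  dimnames(cn_obs) <- dimnames(true_cn)
  expr <- mu_g + s_g * log2(att / 2) +
    matrix(stats::rnorm(G * S, 0, config$expr_noise_sd), G, S)
  dimnames(expr) <- dimnames(true_cn)

  dataset <- suppressMessages(
    align_paired(omics_matrix(expr, "expression"),
                 omics_matrix(cn_obs, "copy_number"), ann))
  truth <- list(
    samples = data.frame(sample = samples, subtype = subtype,
                         purity = purity, stringsAsFactors = FALSE),
    genes = data.frame(gene = ann$gene, chrom = ann$chrom, s_g = s_g,
                       mu_g = mu_g, stringsAsFactors = FALSE),
    true_cn = true_cn)
  list(dataset = dataset, truth = truth, config = config)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical or 0/1); both classes must occur.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate DES recovery of planted dosage sensitivity
#'
#' @param des A `des_table` computed on a simulated cohort.
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @return List: `auroc` (DES vs planted sensitivity label, over genes with
#'   defined DES), `n_defined`, `mean_des_sensitive`, `mean_des_resistant`,
#'   and `by_chromosome` (per-chromosome mean DES by sensitivity class).
#' @export
truth_eval <- function(des, truth) {
  m <- merge(des[, c("gene", "des")], truth$genes, by = "gene")
  m <- m[!is.na(m$des), , drop = FALSE]
  if (!nrow(m)) stop("no gene has a defined DES")
  if (length(unique(m$s_g)) < 2L)
    stop("defined-DES genes contain a single sensitivity class")
  by_chr <- stats::aggregate(des ~ chrom + s_g, data = m, FUN = mean)
  list(auroc = auroc(m$des, m$s_g == 1L),
       n_defined = nrow(m),
       mean_des_sensitive = mean(m$des[m$s_g == 1L]),
       mean_des_resistant = mean(m$des[m$s_g == 0L]),
       by_chromosome = by_chr)
}
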