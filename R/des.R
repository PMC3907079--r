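#' Parameters for dosage effect scoring
#'
#' The neutral copy-number band is `[loss_threshold, gain_threshold]`
#' inclusive at both ends; copy numbers strictly below/above it are losses/
#' gains. The defaults 1.7 and 2.3 allow for signal noise and normal-cell
#' contamination around the diploid value 2. A sample is concordant when its
#' expression lies strictly beyond `sd_multiplier` neutral standard
#' deviations from the neutral mean, in the direction of its alteration.
#' DES is left undefined for genes altered in at most `min_cna_fraction` of
#' samples (the score is unreliable on few alterations), with fewer than
#' `min_neutral_samples` copy-neutral samples, or with zero neutral standard
#' deviation.
#'
#' @param loss_threshold Copy number below which a sample is a loss (1.7).
#' @param gain_threshold Copy number above which a sample is a gain (2.3).
#' @param sd_multiplier Width of the concordance band in neutral SDs (1).
#' @param min_cna_fraction Minimum altered fraction of the cohort for a
#'   defined score (0.10, strict: `cna_count > min_cna_fraction * n`).
#' @param min_neutral_samples Minimum copy-neutral samples for a usable
#'   neutral mean/SD (5).
#' @param low_max,high_min Category bounds: DES < `low_max` is low,
#'   `low_max` <= DES <= `high_min` is medium, DES > `high_min` is high.
#' @param resistant_expr_quantile Quantile of per-gene median expression
#'   above which a gene counts as highly expressed (0.80, i.e. top 20%).
#' @param resistant_des_max Dosage-resistant genes are highly expressed
#'   genes with defined DES below this value (0.2).
#' @return A `des_params` list.
#' @export
des_params <- function(loss_threshold = 1.7, gain_threshold = 2.3,
                       sd_multiplier = 1, min_cna_fraction = 0.10,
                       min_neutral_samples = 5, low_max = 0.2, high_min = 0.4,
                       resistant_expr_quantile = 0.80,
                       resistant_des_max = 0.2) {
  stopifnot(loss_threshold > 0, loss_threshold < gain_threshold,
            sd_multiplier > 0, min_cna_fraction >= 0, min_cna_fraction <= 1,
            min_neutral_samples >= 0, low_max <= high_min)
  structure(list(loss_threshold = loss_threshold,
                 gain_threshold = gain_threshold,
                 sd_multiplier = sd_multiplier,
                 min_cna_fraction = min_cna_fraction,
                 min_neutral_samples = min_neutral_samples,
                 low_max = low_max, high_min = high_min,
                 resistant_expr_quantile = resistant_expr_quantile,
                 resistant_des_max = resistant_des_max),
            class = "des_params")
}

#' Classify copy numbers as loss / neutral / gain
#'
#' @param cn Numeric vector of linear copy numbers (`NA` allowed).
#' @param params A [des_params()].
#' @return Character vector in `{"loss","neutral","gain","missing"}`. The
#'   thresholds themselves are neutral (inclusive band).
#' @export
cna_status <- function(cn, params = des_params()) {
  out <- rep("neutral", length(cn))
  out[cn < params$loss_threshold] <- "loss"
  out[cn > params$gain_threshold] <- "gain"
  out[is.na(cn)] <- "missing"
  out
}

#' Compute the per-gene dosage effect score
#'
#' For each gene: samples are split by copy-number status; the copy-neutral
#' samples give the gene's neutral expression mean and standard deviation
#' (n-1 denominator); the concordant count is the number of gain samples
#' with expression strictly above mean + k*sd plus the number of loss
#' samples strictly below mean - k*sd; DES is concordant / altered when the
#' guards in [des_params()] are met, otherwise `NA` with a recorded reason.
#' Genes with both gains and losses contribute both directions.
#'
#' @param dataset A `paired_dataset`.
#' @param params A [des_params()].
#' @return A `des_table` data.frame (one row per gene): `gene`, `n_samples`,
#'   `gain_count`, `loss_count`, `cna_count`, `neutral_count`,
#'   `neutral_mean`, `neutral_sd`, `concordant_count`, `des`, `category`
#'   (low/medium/high or `NA`), `undefined_reason`. The parameters used are
#'   kept in attribute `params` for provenance.
#' @export
compute_des <- function(dataset, params = des_params()) {
  stopifnot(inherits(dataset, "paired_dataset"))
  cn <- dataset$copy_number$values
  ex <- dataset$expression$values
  n <- ncol(cn)
  is_loss <- !is.na(cn) & cn < params$loss_threshold
  is_gain <- !is.na(cn) & cn > params$gain_threshold
  is_neut <- !is.na(cn) & !is_loss & !is_gain

  neutral_count <- rowSums(is_neut)
  gain_count <- rowSums(is_gain)
  loss_count <- rowSums(is_loss)
  cna_count <- gain_count + loss_count

  en <- ex
  en[!is_neut] <- NA_real_
  mu <- rowMeans(en, na.rm = TRUE)
  ss <- rowSums((en - mu)^2, na.rm = TRUE)
  sdv <- ifelse(neutral_count > 1L, sqrt(ss / (neutral_count - 1L)), NA_real_)

  k <- params$sd_multiplier
  conc <- rowSums(is_gain & ex > mu + k * sdv, na.rm = TRUE) +
          rowSums(is_loss & ex < mu - k * sdv, na.rm = TRUE)

  reason <- rep(NA_character_, nrow(cn))
  reason[!is.na(sdv) & sdv == 0] <- "zero_neutral_sd"
  reason[is.na(sdv) | neutral_count < params$min_neutral_samples] <- "too_few_neutral"
  reason[cna_count <= params$min_cna_fraction * n] <- "low_cna_frequency"
  defined <- is.na(reason)

  des <- ifelse(defined, conc / cna_count, NA_real_)
  out <- data.frame(
    gene = rownames(cn), n_samples = n,
    gain_count = gain_count, loss_count = loss_count, cna_count = cna_count,
    neutral_count = neutral_count,
    neutral_mean = ifelse(neutral_count > 0L, mu, NA_real_),
    neutral_sd = sdv,
    concordant_count = ifelse(defined, conc, NA_integer_),
    des = des,
    category = categorize_des(des, params),
    undefined_reason = reason,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, params = params, class = c("des_table", "data.frame"))
}

#' Categorize dosage effect scores
#'
#' Low: DES < 0.2; medium: 0.2 <= DES <= 0.4 (bounds inclusive); high:
#' DES > 0.4 (defaults; see [des_params()]).
#'
#' @param des Numeric vector of scores (`NA` allowed).
#' @param params A [des_params()].
#' @return Character vector `"low"`/`"medium"`/`"high"`, `NA` where
#'   undefined.
#' @export
categorize_des <- function(des, params = des_params()) {
  out <- rep(NA_character_, length(des))
  out[des < params$low_max] <- "low"
  out[des >= params$low_max & des <= params$high_min] <- "medium"
  out[des > params$high_min] <- "high"
  out
}

per_gene_median_expression <- function(dataset) {
  apply(dataset$expression$values, 1L, stats::median)
}

#' Identify dosage-resistant genes
#'
#' Highly expressed genes whose expression nevertheless ignores copy number:
#' per-gene median expression at or above the `resistant_expr_quantile`
#' quantile of all genes' medians, with a defined DES below
#' `resistant_des_max`.
#'
#' @param dataset A `paired_dataset`.
#' @param des A `des_table` from [compute_des()].
#' @param params A [des_params()].
#' @return Character vector of gene symbols.
#' @export
identify_dosage_resistant <- function(dataset, des, params = des_params()) {
  med <- per_gene_median_expression(dataset)
  med <- med[des$gene]
  thr <- stats::quantile(med, params$resistant_expr_quantile, names = FALSE)
  des$gene[med >= thr & !is.na(des$des) & des$des < params$resistant_des_max]
}

#' Dosage sensitivity across expression strata
#'
#' Genes with defined DES are ranked by median expression across samples and
#' split into five groups of (as near as possible) equal size, remainders
#' going to the lower-expression groups; ties at group boundaries are broken
#' by gene symbol so the split is deterministic. The 2 x 5 table of
#' high-DES vs other genes per group is tested for a monotone trend with the
#' Cochran-Armitage statistic (scores 1..5). Degenerate tables (every gene
#' high, or none) carry no gradient and return z = 0, p = 1.
#'
#' @param dataset A `paired_dataset`.
#' @param des A `des_table`.
#' @param n_groups Number of expression strata (default 5).
#' @param params A [des_params()] (for the high-DES bound).
#' @return List: `table` (2 x n_groups counts, rows high/other), `z`,
#'   `p_value`, `group_of` (named group index per gene).
#' @export
expression_group_trend <- function(dataset, des, n_groups = 5,
                                   params = des_params()) {
  keep <- !is.na(des$des)
  if (sum(keep) < n_groups)
    stop("need at least ", n_groups, " genes with defined DES")
  genes <- des$gene[keep]
  med <- per_gene_median_expression(dataset)[genes]
  o <- order(med, genes)           # ascending expression, symbol tie-break
  ng <- length(genes)
  base <- ng %/% n_groups
  sizes <- rep(base, n_groups)
  extra <- ng %% n_groups
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  grp <- integer(ng)
  grp[o] <- rep(seq_len(n_groups), times = sizes)
  high <- des$des[keep] > params$high_min
  tab <- rbind(high = tabulate(grp[high], n_groups),
               other = tabulate(grp[!high], n_groups))
  colnames(tab) <- paste0("G", seq_len(n_groups))
  if (all(high) || !any(high)) {
    z <- 0; p <- 1
  } else {
    ca <- cochran_armitage_trend(tab, scores = seq_len(n_groups))
    z <- ca$z; p <- ca$p_value
  }
  list(table = tab, z = z, p_value = p,
       group_of = stats::setNames(grp, genes))
}

#' Per-chromosome dosage effect and CNA-frequency summary
#'
#' For each chromosome: the proportion of defined-DES genes in each category
#' (low/medium/high), and the mean over all scored genes of the per-gene
#' CNA sample fraction.
#'
#' @param des A `des_table`.
#' @param annotation A `gene_annotation` covering the scored genes.
#' @param dataset Optional `paired_dataset` (unused beyond interface
#'   symmetry; counts come from `des`).
#' @return data.frame: `chrom`, `n_genes`, `n_defined`, `prop_low`,
#'   `prop_medium`, `prop_high` (NA when no gene has defined DES),
#'   `mean_cna_fraction`.
#' @export
chromosome_summary <- function(des, annotation, dataset = NULL) {
  annotation <- gene_annotation(annotation)
  chrom <- annotation[des$gene, "chrom"]
  if (anyNA(chrom)) stop("des table contains genes absent from annotation")
  cna_frac <- des$cna_count / des$n_samples
  out <- do.call(rbind, lapply(split(seq_along(chrom), chrom), function(i) {
    cat_i <- des$category[i]
    nd <- sum(!is.na(cat_i))
    data.frame(
      chrom = chrom[i[1L]], n_genes = length(i), n_defined = nd,
      prop_low = if (nd) sum(cat_i == "low", na.rm = TRUE) / nd else NA_real_,
      prop_medium = if (nd) sum(cat_i == "medium", na.rm = TRUE) / nd else NA_real_,
      prop_high = if (nd) sum(cat_i == "high", na.rm = TRUE) / nd else NA_real_,
      mean_cna_fraction = mean(cna_frac[i]),
      stringsAsFactors = FALSE)
  }))
  suppressWarnings({
    num <- as.numeric(out$chrom)
    out <- out[order(is.na(num), num, out$chrom), , drop = FALSE]
  })
  if (any(out$n_defined == 0L))
    message("chromosome(s) without defined-DES genes: ",
            paste(out$chrom[out$n_defined == 0L], collapse = ", "))
  rownames(out) <- NULL
  out
}
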