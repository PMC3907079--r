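#' Collapse a probe-level matrix to gene level
#'
#' When several probes (or probe sets) measure one gene, the gene's value per
#' sample is the arithmetic mean of its probes. Probes without a mapping are
#' dropped; a probe mapping to more than one gene is an error.
#'
#' @param x Probe-level [omics_matrix()] (duplicate row ids allowed).
#' @param probe_to_gene Two-column data.frame (`probe`, `gene`) or a named
#'   character vector `probe -> gene`.
#' @return Gene-level [omics_matrix()] with unique row ids.
#' @export
collapse_to_genes <- function(x, probe_to_gene) {
  stopifnot(inherits(x, "omics_matrix"))
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene[[2L]]),
                           as.character(probe_to_gene[[1L]]))
  } else map <- probe_to_gene
  dup <- names(map)[duplicated(names(map))]
  if (length(dup)) {
    conflict <- vapply(unique(dup), function(p)
      length(unique(map[names(map) == p])) > 1L, logical(1))
    if (any(conflict))
      stop("probe(s) mapped to multiple genes: ",
           paste(unique(dup)[conflict], collapse = ", "))
    map <- map[!duplicated(names(map))]
  }
  keep <- rownames(x$values) %in% names(map)
  if (!any(keep)) stop("no probe of the matrix is present in the mapping")
  v <- x$values[keep, , drop = FALSE]
  g <- unname(map[rownames(v)])
  sums <- rowsum(v, g)
  cnt <- as.vector(table(g)[rownames(sums)])
  omics_matrix(sums / cnt, x$role)
}

#' Summarize SNP copy numbers to gene level
#'
#' A gene's copy number per sample is the mean over SNPs lying within
#' `window_bp` of its transcription region, i.e. with position in
#' `[tx_start - window_bp, tx_end + window_bp]` (both ends inclusive) on the
#' same chromosome. The window is symmetric and strand is ignored. A SNP in
#' two overlapping genes' windows contributes to both. Genes with no SNP in
#' the window get missing values and are reported in a message.
#'
#' @param snps A `snp_cn_table` (see [read_snp_table()]).
#' @param annotation A `gene_annotation`.
#' @param window_bp Flank around the transcription region, default 5000.
#' @return Gene-level copy-number [omics_matrix()]; result row order follows
#'   `annotation`, independent of SNP row order.
#' @export
snp_to_gene_copynumber <- function(snps, annotation, window_bp = 5000) {
  stopifnot(inherits(snps, "snp_cn_table"), window_bp >= 0)
  annotation <- gene_annotation(annotation)
  genes <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(
      start = pmax(1, annotation$tx_start - window_bp),
      end = annotation$tx_end + window_bp))
  pos <- GenomicRanges::GRanges(
    seqnames = snps$info$chrom,
    ranges = IRanges::IRanges(start = snps$info$pos, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(genes, pos))
  out <- matrix(NA_real_, nrow(annotation), ncol(snps$values),
                dimnames = list(annotation$gene, colnames(snps$values)))
  if (length(hits)) {
    gi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    sums <- rowsum(snps$values[si, , drop = FALSE], gi)
    cnt <- as.vector(table(gi)[rownames(sums)])
    out[as.integer(rownames(sums)), ] <- sums / cnt
  }
  n_empty <- sum(rowSums(!is.na(out)) == 0L)
  if (n_empty == nrow(out))
    warning("no gene has any SNP within its window")
  else if (n_empty > 0L)
    message(n_empty, " gene(s) with no SNP within the ", window_bp,
            " bp window: copy number set to missing")
  omics_matrix(out, "copy_number")
}

#' Align paired expression and copy-number matrices
#'
#' Restricts both matrices to the genes common to expression, copy number and
#' annotation, and to the samples common to both matrices, in a shared order.
#' Counts of dropped genes/samples are reported.
#'
#' @param expression Gene-level expression [omics_matrix()].
#' @param copy_number Gene-level copy-number [omics_matrix()].
#' @param annotation A `gene_annotation`.
#' @return A `paired_dataset`: list with `expression`, `copy_number`
#'   (identical dimnames) and `annotation` (same gene order).
#' @export
align_paired <- function(expression, copy_number, annotation) {
  stopifnot(inherits(expression, "omics_matrix"),
            inherits(copy_number, "omics_matrix"))
  if (expression$role != "expression" || copy_number$role != "copy_number")
    stop("arguments must be an expression and a copy_number matrix, in order")
  annotation <- gene_annotation(annotation)
  genes <- intersect(intersect(gene_ids(expression), gene_ids(copy_number)),
                     annotation$gene)
  if (!length(genes)) stop("no gene is shared by expression, copy number and annotation")
  samples <- intersect(sample_ids(expression), sample_ids(copy_number))
  if (!length(samples)) stop("expression and copy number share no sample id")
  message(sprintf(
    "aligned %d genes x %d samples (dropped %d expression-only, %d CN-only genes; %d/%d unmatched samples)",
    length(genes), length(samples),
    length(setdiff(gene_ids(expression), genes)),
    length(setdiff(gene_ids(copy_number), genes)),
    length(setdiff(sample_ids(expression), samples)),
    length(setdiff(sample_ids(copy_number), samples))))
  structure(list(
    expression = omics_matrix(expression$values[genes, samples, drop = FALSE],
                              "expression"),
    copy_number = omics_matrix(copy_number$values[genes, samples, drop = FALSE],
                               "copy_number"),
    annotation = annotation[genes, , drop = FALSE]),
    class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset: %d genes x %d samples>\n",
              nrow(x$expression$values), ncol(x$expression$values)))
  invisible(x)
}
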