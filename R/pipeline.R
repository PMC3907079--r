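#' Write a DES table to TSV with a provenance header
#'
#' Commented `# key=value` header lines record the parameters used, then a
#' regular TSV body with one row per gene.
#'
#' @param des A `des_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_des_table <- function(des, path) {
  p <- attr(des, "params")
  hdr <- c(sprintf("# descna_version=%s",
                   as.character(utils::packageVersion("descna"))),
           sprintf("# %s=%s", names(unclass(p)),
                   vapply(unclass(p), function(v) paste(v, collapse = ","),
                          character(1))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(des), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a DES table written by [write_des_table()]
#' @param path TSV file with commented header.
#' @return A `des_table` data.frame (parameters not reconstructed).
#' @export
read_des_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  class(out) <- c("des_table", "data.frame")
  out
}

#' Run the full dosage effect pipeline
#'
#' Wires the stages together: load (or simulate) paired matrices, align,
#' call ploidy subtypes, compute DES, differential expression between the
#' subtypes with per-chromosome trisomy enrichment, optional gene-set
#' enrichment of the dosage-sensitive genes, expression-strata trend,
#' chromosome summary, and the two figures. Every output is written under
#' `out_dir` and listed, with md5 checksums and the parameters used, in
#' `manifest.json`.
#'
#' @param expression,copy_number,annotation Paths to the input TSVs, or the
#'   corresponding in-memory objects. All three may be omitted together by
#'   supplying `simulate = TRUE`, in which case a synthetic cohort from
#'   `sim` is analyzed and its truth tables are also written.
#' @param out_dir Output directory (created).
#' @param gene_sets Optional GMT path or named list for enrichment.
#' @param des_par A [des_params()].
#' @param ploidy_par A [ploidy_params()].
#' @param alpha Adjusted-p significance level for differential expression.
#' @param simulate Use the synthetic generator instead of input files.
#' @param sim A [sim_config()] when `simulate = TRUE`.
#' @param plots Write the karyotype and DES-distribution figures (PDF).
#' @return List with every intermediate result plus `manifest`.
#' @export
run_pipeline <- function(expression = NULL, copy_number = NULL,
                         annotation = NULL, out_dir = "descna_out",
                         gene_sets = NULL, des_par = des_params(),
                         ploidy_par = ploidy_params(), alpha = 0.05,
                         simulate = FALSE, sim = sim_config(), plots = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }

  truth <- NULL
  if (simulate) {
    simres <- simulate_cohort(sim)
    dataset <- simres$dataset
    truth <- simres$truth
  } else {
    if (is.null(expression) || is.null(copy_number) || is.null(annotation))
      stop("expression, copy_number and annotation are required unless simulate = TRUE")
    if (is.character(annotation)) {
      if (!file.exists(annotation)) stop("annotation path not found: ", annotation)
      annotation <- read_gene_annotation(annotation)
    }
    if (is.character(expression)) expression <- read_matrix(expression, "expression")
    if (is.character(copy_number)) copy_number <- read_matrix(copy_number, "copy_number")
    dataset <- align_paired(expression, copy_number, annotation)
  }

  calls <- classify_ploidy(dataset, ploidy_par)
  des <- compute_des(dataset, des_par)
  de <- differential_expression(dataset$expression, calls, alpha = alpha)
  de_chr <- de_by_chromosome(de, dataset$annotation,
                             ploidy_par$trisomy_chromosomes)
  trend <- expression_group_trend(dataset, des, params = des_par)
  chrsum <- chromosome_summary(des, dataset$annotation)
  resistant <- identify_dosage_resistant(dataset, des, des_par)
  sensitive <- des$gene[!is.na(des$category) & des$category == "high"]

  w_tsv <- function(obj, path) utils::write.table(
    obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  emit(write_matrix, dataset$expression, "expression.aligned.tsv")
  emit(write_matrix, dataset$copy_number, "copy_number.aligned.tsv")
  emit(write_gene_annotation, dataset$annotation, "annotation.aligned.tsv")
  emit(w_tsv, as.data.frame(calls), "ploidy_calls.tsv")
  emit(write_des_table, des, "des_table.tsv")
  emit(w_tsv, as.data.frame(de), "differential_expression.tsv")
  emit(w_tsv, de_chr$counts, "de_by_chromosome.tsv")
  emit(w_tsv, chrsum, "chromosome_summary.tsv")
  emit(function(x, p) writeLines(x, p), resistant, "dosage_resistant_genes.txt")
  emit(function(x, p) writeLines(x, p), sensitive, "dosage_sensitive_genes.txt")
  if (!is.null(truth)) {
    emit(w_tsv, truth$samples, "truth_samples.tsv")
    emit(w_tsv, truth$genes, "truth_genes.tsv")
  }

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    if (is.character(gene_sets)) gene_sets <- read_gene_sets(gene_sets)
    if (length(sensitive))
      enrichment <- gene_set_enrichment(sensitive, gene_sets, des$gene)
    else message("no dosage-sensitive gene; enrichment skipped")
    if (!is.null(enrichment)) emit(w_tsv, enrichment, "enrichment.tsv")
  }

  if (plots) {
    track <- build_karyotype_track(dataset, des, des_par)
    emit(function(x, p) plot_karyotype(x, p), track, "karyotype.pdf")
    emit(function(x, p) plot_des_distribution(x, p, params = des_par), des,
         "des_distribution.pdf")
  }

  manifest <- list(
    package = "descna",
    version = as.character(utils::packageVersion("descna")),
    created = "(timestamp omitted for reproducibility)",
    parameters = list(des = unclass(des_par), ploidy = unclass(ploidy_par),
                      alpha = alpha,
                      sim = if (simulate) unclass(sim)[
                        setdiff(names(unclass(sim)), "events")] else NULL),
    n_genes = nrow(dataset$expression$values),
    n_samples = ncol(dataset$expression$values),
    n_hmm = sum(calls$label == "HMM"),
    trend_p = trend$p_value,
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(outputs))), basename(outputs)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(dataset = dataset, ploidy = calls, des = des, de = de,
                 de_by_chromosome = de_chr, trend = trend,
                 chromosome_summary = chrsum, resistant = resistant,
                 sensitive = sensitive, enrichment = enrichment,
                 truth = truth, manifest = manifest,
                 manifest_path = manifest_path))
}
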