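#' Construct an omics matrix
#'
#' A light container for a genes x samples real-valued matrix tagged with its
#' role. Copy-number matrices are on the linear scale (diploid = 2) and may
#' contain `NA` where a gene has no supporting measurement; expression
#' matrices must be complete.
#'
#' @param values Numeric matrix with gene symbols as rownames and sample ids
#'   as colnames.
#' @param role Either `"expression"` or `"copy_number"`.
#' @param allow_duplicate_genes Permit duplicated row ids (probe-level input
#'   that has not yet been collapsed to genes). Duplicates are flagged with a
#'   warning, never silently accepted.
#' @return An object of class `omics_matrix`: a list with elements `values`
#'   and `role`.
#' @export
omics_matrix <- function(values, role = c("expression", "copy_number"),
                         allow_duplicate_genes = FALSE) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    if (!allow_duplicate_genes)
      stop("duplicate gene id(s): ", paste(utils::head(dup_g, 5), collapse = ", "))
    warning(length(dup_g), " duplicated row id(s); collapse to genes before analysis")
  }
  if (role == "expression" && anyNA(values))
    stop("expression matrix must not contain missing values")
  if (role == "copy_number") {
    if (any(values <= 0, na.rm = TRUE))
      stop("copy-number values must be > 0 on the linear scale (diploid = 2)")
    med <- stats::median(values, na.rm = TRUE)
    if (is.finite(med) && med < 1)
      stop("overall copy-number median is ", signif(med, 3),
           " (< 1): input looks like log-ratios; supply linear copy numbers",
           " with diploid = 2")
  }
  structure(list(values = values, role = role), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix role=%s: %d genes x %d samples>\n",
              x$role, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# fread wrapper: gzip-transparent, keeps cells as character for validation
.read_tsv_chr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    if (!length(lines)) stop("empty file: ", path)
    dt <- data.table::fread(text = lines, sep = "\t", header = TRUE,
                            colClasses = "character", data.table = FALSE,
                            check.names = FALSE)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", data.table = FALSE,
                            check.names = FALSE)
  }
  if (nrow(dt) == 0L || ncol(dt) < 2L) stop("empty or single-column file: ", path)
  dt
}

#' Read a genes x samples matrix from TSV
#'
#' Expects a header row of sample ids and gene/row ids in the first column.
#' Reading is gzip-transparent. Duplicate gene rows are flagged (probe-level
#' data is collapsed later by [collapse_to_genes()]), duplicate sample ids
#' are an error, and non-numeric cells are reported with their line number.
#'
#' @param path TSV file (optionally gzipped).
#' @inheritParams omics_matrix
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, role = c("expression", "copy_number")) {
  role <- match.arg(role)
  dt <- .read_tsv_chr(path)
  ids <- dt[[1L]]
  vals <- suppressWarnings(
    vapply(dt[-1L], as.numeric, numeric(nrow(dt)), USE.NAMES = TRUE))
  vals <- matrix(vals, nrow = nrow(dt),
                 dimnames = list(ids, colnames(dt)[-1L]))
  chr <- as.matrix(dt[-1L])
  bad <- which(is.na(vals) & !(chr %in% c("", "NA", "na", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at line %d (gene %s, sample %s) in %s",
                 chr[bad[1L, , drop = FALSE]], bad[1L, 1L] + 1L,
                 ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]], path))
  omics_matrix(vals, role, allow_duplicate_genes = TRUE)
}

#' Write an omics matrix to TSV
#'
#' Inverse of [read_matrix()] up to floating-point formatting; round-trips
#' ids and values exactly (full precision output).
#'
#' @param x An [omics_matrix()].
#' @param path Output file; a `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  dt <- data.table::data.table(gene = rownames(x$values))
  for (s in colnames(x$values)) dt[[s]] <- x$values[, s]
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

.normalize_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", trimws(x))

#' Read gene annotation (BED-like TSV)
#'
#' Four columns: gene symbol, chromosome, transcript start, transcript end
#' (1-based, inclusive). Both `"chr13"` and `"13"` chromosome dialects are
#' accepted and normalized to bare labels. Sex chromosomes are kept but
#' excluded from the karyotype plot downstream.
#'
#' @param path TSV with a header row.
#' @return A `gene_annotation` data.frame with columns `gene`, `chrom`,
#'   `tx_start`, `tx_end`.
#' @export
read_gene_annotation <- function(path) {
  dt <- .read_tsv_chr(path)
  if (ncol(dt) < 4L) stop("annotation needs 4 columns: gene, chrom, start, end")
  ann <- data.frame(gene = dt[[1L]],
                    chrom = .normalize_chrom(dt[[2L]]),
                    tx_start = suppressWarnings(as.numeric(dt[[3L]])),
                    tx_end = suppressWarnings(as.numeric(dt[[4L]])),
                    stringsAsFactors = FALSE)
  gene_annotation(ann)
}

#' Validate a gene annotation table
#'
#' @param ann data.frame with columns `gene`, `chrom`, `tx_start`, `tx_end`.
#' @return The validated `gene_annotation` data.frame.
#' @export
gene_annotation <- function(ann) {
  need <- c("gene", "chrom", "tx_start", "tx_end")
  if (!all(need %in% names(ann))) stop("annotation must have columns ",
                                       paste(need, collapse = ", "))
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  ann$chrom <- .normalize_chrom(ann$chrom)
  if (anyNA(ann$tx_start) || anyNA(ann$tx_end) ||
      any(ann$tx_start != round(ann$tx_start)) ||
      any(ann$tx_end != round(ann$tx_end)))
    stop("non-integer transcript coordinate in annotation")
  if (any(ann$tx_start < 1) || any(ann$tx_end < 1))
    stop("coordinates must be positive (1-based)")
  if (any(ann$tx_start > ann$tx_end)) {
    i <- which(ann$tx_start > ann$tx_end)[1L]
    stop("tx_start > tx_end for gene ", ann$gene[i])
  }
  dup <- unique(ann$gene[duplicated(ann$gene)])
  if (length(dup))
    stop("duplicate gene symbol(s) in annotation: ",
         paste(utils::head(dup, 5), collapse = ", "))
  rownames(ann) <- ann$gene
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write gene annotation to TSV
#' @param ann A `gene_annotation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  data.table::fwrite(as.data.frame(ann)[c("gene", "chrom", "tx_start", "tx_end")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a SNP-level copy-number table
#'
#' TSV with columns `snp_id`, `chrom`, `pos` followed by one linear-scale
#' copy-number column per sample.
#'
#' @param path TSV file.
#' @return A `snp_cn_table`: list with `info` (snp_id, chrom, pos) and
#'   `values` (SNPs x samples matrix).
#' @export
read_snp_table <- function(path) {
  dt <- .read_tsv_chr(path)
  if (ncol(dt) < 4L) stop("SNP table needs snp_id, chrom, pos + >= 1 sample")
  info <- data.frame(snp_id = dt[[1L]],
                     chrom = .normalize_chrom(dt[[2L]]),
                     pos = suppressWarnings(as.numeric(dt[[3L]])),
                     stringsAsFactors = FALSE)
  vals <- vapply(dt[-(1:3)], as.numeric, numeric(nrow(dt)))
  vals <- matrix(vals, nrow = nrow(dt),
                 dimnames = list(info$snp_id, colnames(dt)[-(1:3)]))
  snp_cn_table(info, vals)
}

#' Construct a SNP copy-number table
#' @param info data.frame with `snp_id`, `chrom`, `pos` (1-based bp).
#' @param values SNPs x samples numeric matrix, linear scale.
#' @return A validated `snp_cn_table`.
#' @export
snp_cn_table <- function(info, values) {
  if (anyDuplicated(info$snp_id)) stop("duplicate snp_id")
  if (anyNA(info$pos) || any(info$pos < 1)) stop("SNP positions must be positive")
  if (nrow(info) != nrow(values)) stop("info/values row mismatch")
  if (anyDuplicated(colnames(values))) stop("duplicate sample id in SNP table")
  structure(list(info = info, values = values), class = "snp_cn_table")
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member gene symbols. Members are
#' de-duplicated within a set; empty sets and duplicate set names are errors.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields (name, description, members)")
    nm <- f[1L]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    sets[[nm]] <- unique(f[-(1:2)])
  }
  sets
}
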