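#' Build the per-gene karyotype track
#'
#' For every scored gene: gain fraction and loss fraction of samples
#' (relative to cohort size) and its DES, positioned at the midpoint of the
#' transcription region. Genes are ordered by chromosome, then midpoint.
#'
#' @param dataset A `paired_dataset`.
#' @param des A `des_table` from [compute_des()].
#' @param params A [des_params()] (kept for interface symmetry; fractions
#'   come from the counts already in `des`).
#' @return A `karyotype_track` data.frame: `gene`, `chrom`, `mid`,
#'   `gain_fraction`, `loss_fraction`, `des`.
#' @export
build_karyotype_track <- function(dataset, des, params = des_params()) {
  ann <- dataset$annotation[des$gene, , drop = FALSE]
  out <- data.frame(
    gene = des$gene,
    chrom = ann$chrom,
    mid = (ann$tx_start + ann$tx_end) / 2,
    gain_fraction = des$gain_count / des$n_samples,
    loss_fraction = des$loss_count / des$n_samples,
    des = des$des,
    stringsAsFactors = FALSE)
  suppressWarnings(num <- as.numeric(out$chrom))
  out <- out[order(is.na(num), num, out$chrom, out$mid), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("karyotype_track", "data.frame")
  out
}

.autosome_levels <- function(x) {
  lv <- as.character(1:22)
  lv[lv %in% unique(x)]
}

#' Genome-wide karyotype plot of CNA frequency colored by DES
#'
#' One panel per autosome. Per gene, an upward bar shows the fraction of
#' samples with copy-number gain and a downward bar the fraction with loss,
#' at the gene's genomic midpoint; bars are colored by DES on a continuous
#' colorblind-safe (viridis) scale, with undefined-DES genes in gray. A
#' gray reference bar at the start of each chromosome marks 100%. Sex
#' chromosomes are excluded.
#'
#' @param track A `karyotype_track` (see [build_karyotype_track()]).
#' @param out_path Optional output file; extension selects the device
#'   (`.pdf`, `.svg`, `.png`). PDF output suppresses embedded timestamps so
#'   rendering is reproducible.
#' @param width,height,dpi Figure geometry passed to the device.
#' @return The ggplot object, invisibly; writes `out_path` when given.
#' @export
plot_karyotype <- function(track, out_path = NULL, width = 12, height = 8,
                           dpi = 150) {
  stopifnot(inherits(track, "karyotype_track"), nrow(track) > 0)
  d <- track[track$chrom %in% as.character(1:22), , drop = FALSE]
  if (!nrow(d)) stop("track has no autosomal gene")
  d$chrom <- factor(d$chrom, levels = .autosome_levels(d$chrom))
  ref <- data.frame(chrom = factor(levels(d$chrom), levels = levels(d$chrom)),
                    x = -Inf, y0 = 0, y1 = 1)
  p <- ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      data = ref, ggplot2::aes(x = .data$x, xend = .data$x,
                               y = .data$y0, yend = .data$y1),
      linewidth = 2, colour = "gray40") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$mid, xend = .data$mid,
                   y = 0, yend = .data$gain_fraction, colour = .data$des),
      linewidth = 0.3) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$mid, xend = .data$mid,
                   y = 0, yend = -.data$loss_fraction, colour = .data$des),
      linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::facet_wrap(~chrom, scales = "free_x", nrow = 4) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), na.value = "gray70",
                                    name = "DES") +
    ggplot2::scale_y_continuous(limits = c(-1, 1),
                                labels = function(v) paste0(abs(v) * 100, "%")) +
    ggplot2::labs(x = "genomic position", y = "samples with loss | gain",
                  title = "CNA frequency by gene, colored by dosage effect score") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  if (!is.null(out_path)) .save_plot(p, out_path, width, height, dpi)
  invisible(p)
}

#' Histogram of the DES distribution
#'
#' Defined scores only, with the category boundaries marked and the
#' low/medium/high percentages annotated.
#'
#' @param des A `des_table`.
#' @param out_path Optional output file (extension selects the device).
#' @param params A [des_params()] (category bounds).
#' @param binwidth Histogram bin width.
#' @param width,height,dpi Figure geometry.
#' @return The ggplot object, invisibly.
#' @export
plot_des_distribution <- function(des, out_path = NULL, params = des_params(),
                                  binwidth = 0.025, width = 6, height = 4,
                                  dpi = 150) {
  v <- des$des[!is.na(des$des)]
  if (!length(v)) stop("no gene has a defined DES")
  cats <- categorize_des(v, params)
  pct <- 100 * c(low = mean(cats == "low"), medium = mean(cats == "medium"),
                 high = mean(cats == "high"))
  lab <- sprintf("low %.1f%%  |  medium %.1f%%  |  high %.1f%%",
                 pct["low"], pct["medium"], pct["high"])
  p <- ggplot2::ggplot(data.frame(des = v), ggplot2::aes(x = .data$des)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white",
                            linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = c(params$low_max, params$high_min),
                        linetype = "dashed") +
    ggplot2::labs(x = "dosage effect score", y = "genes", subtitle = lab,
                  title = "Distribution of dosage effect scores") +
    ggplot2::coord_cartesian(xlim = c(0, 1.03)) +
    ggplot2::theme_minimal(base_size = 10)
  if (!is.null(out_path)) .save_plot(p, out_path, width, height, dpi)
  invisible(p)
}

.save_plot <- function(p, out_path, width, height, dpi) {
  ext <- tolower(tools::file_ext(out_path))
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  if (ext == "pdf") {
    grDevices::pdf(out_path, width = width, height = height,
                   useDingbats = FALSE)
    on.exit(grDevices::dev.off(), add = TRUE)
    print(p)
  } else if (ext == "svg") {
    grDevices::svg(out_path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    print(p)
  } else if (ext == "png") {
    grDevices::png(out_path, width = width, height = height, units = "in",
                   res = dpi)
    on.exit(grDevices::dev.off(), add = TRUE)
    print(p)
  } else stop("unsupported image extension: .", ext)
  invisible(out_path)
}
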