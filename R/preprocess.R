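# Normalization, cell QC, and highly-variable-gene selection.

#' Log-normalize counts to log2(CPM + 1)
#'
#' Each cell is scaled to one million counts and log2-transformed with a
#' pseudocount of 1, so a value is 0 exactly when the underlying count is 0
#' and per-cell column sums of \code{2^value - 1} equal 1e6.
#'
#' @param counts a \code{\link{count_matrix}} or genes x cells matrix.
#' @return genes x cells numeric matrix with attribute
#'   \code{normalization = "log2cpm"}; cell metadata (if any) is carried in
#'   attribute \code{cell_meta}.
#' @export
normalize_log <- function(counts) {
  meta <- NULL
  if (inherits(counts, "count_matrix")) {
    meta <- counts$cell_meta
    counts <- counts$values
  }
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("cells with zero total counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  out <- log2(sweep(counts, 2, totals, "/") * 1e6 + 1)
  attr(out, "normalization") <- "log2cpm"
  attr(out, "cell_meta") <- meta
  out
}

#' Filter cells by detected genes and total counts
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param min_genes_detected minimum number of genes with a nonzero count.
#' @param min_total minimum total counts per cell.
#' @return a \code{count_matrix} with failing cells removed (original order
#'   preserved); removed cells are reported via \code{message}.
#' @export
qc_filter <- function(counts, min_genes_detected = 500, min_total = 1e4) {
  vals <- counts$values
  ok <- colSums(vals > 0) >= min_genes_detected &
    colSums(vals) >= min_total
  if (!any(ok)) stop("QC removed every cell")
  removed <- colnames(vals)[!ok]
  if (length(removed))
    message("qc_filter removed ", length(removed), " cells: ",
            paste(utils::head(removed, 10), collapse = ", "),
            if (length(removed) > 10) ", ..." else "")
  count_matrix(vals[, ok, drop = FALSE],
               counts$cell_meta[ok, , drop = FALSE])
}

#' Select highly variable genes by binned dispersion
#'
#' Genes are binned into equal-frequency bins of mean expression; the
#' dispersion (variance / mean) is z-standardized within each bin and genes
#' exceeding \code{z_cutoff} inside the mean bounds are selected. This is
#' the classic binned-dispersion criterion used by single-cell toolkits;
#' the number of genes selected depends on the data and the parameters.
#'
#' @param logm log-normalized genes x cells matrix.
#' @param n_bins number of equal-frequency mean bins.
#' @param z_cutoff dispersion z-score threshold.
#' @param mean_bounds length-2 numeric, genes outside are never selected.
#' @return list of class \code{hvg_result}: \code{selected} (gene ids, in
#'   original gene order), \code{table} (per-gene mean, dispersion, bin, z),
#'   and \code{params}.
#' @export
select_hvg <- function(logm, n_bins = 20, z_cutoff = 1,
                       mean_bounds = c(0.1, Inf)) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  mu <- rowMeans(logm)
  v <- apply(logm, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  qs <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = qs, include.lowest = TRUE, labels = FALSE)
  z <- rep(NA_real_, length(mu))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    if (length(idx) < 2) {
      warning("mean bin with < 2 genes; ", length(idx),
              " gene(s) excluded from selection")
      next
    }
    s <- stats::sd(disp[idx])
    z[idx] <- if (s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  ok <- !is.na(z) & z > z_cutoff & mu >= mean_bounds[1] & mu <= mean_bounds[2]
  structure(list(selected = rownames(logm)[ok],
                 table = data.frame(gene_id = rownames(logm), mean = mu,
                                    dispersion = disp, bin = bin, z = z,
                                    selected = ok, row.names = NULL),
                 params = list(n_bins = n_bins, z_cutoff = z_cutoff,
                               mean_bounds = mean_bounds)),
            class = "hvg_result")
}

#' Per-gene z-scaling with clipping
#'
#' Standardizes each gene across cells and clips to \code{[-clip, clip]};
#' the standard transform applied to HVG expression before PCA.
#'
#' @param logm genes x cells matrix.
#' @param clip clip magnitude.
#' @return matrix of the same shape.
#' @export
scale_clip <- function(logm, clip = 10) {
  mu <- rowMeans(logm)
  s <- apply(logm, 1, stats::sd)
  s[s == 0] <- 1
  out <- (logm - mu) / s
  pmin(pmax(out, -clip), clip)
}
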