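# Cross-modality integration: lncRNA-to-module pairing by genomic
# proximity, PCA of lncRNA expression and of TF motif-accessibility
# scores, and directional tests of module loadings on principal axes.

#' Pair lncRNAs with nearby module genes
#'
#' A (lncRNA, gene) pair is reported when both lie on the same chromosome
#' and their interval gap is strictly below \code{max_gap} bases (0 when
#' the intervals overlap; strand is ignored). A lncRNA may pair with genes
#' of several modules; all pairs are kept.
#'
#' @param ann a \code{\link{gene_annotation}} covering the queried genes.
#' @param module_genes named list: module label -> character vector of
#'   (coding) gene ids.
#' @param max_gap gap threshold in bases (strict \code{<}).
#' @return data.frame of class \code{neighbor_pairs}: lncRNA_id, partner,
#'   gap_bp, module.
#' @export
neighbor_pairs <- function(ann, module_genes, max_gap = 50000) {
  lnc <- ann[ann$biotype == "lncRNA", ]
  all_mod <- unique(unlist(module_genes))
  absent <- setdiff(all_mod, ann$gene_id)
  if (length(absent)) {
    warning(length(absent), " module genes absent from annotation skipped")
    module_genes <- lapply(module_genes, intersect, y = ann$gene_id)
  }
  gr_of <- function(df)
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(start = df$start + 1L,
                                            end = df$end))
  lnc_gr <- gr_of(lnc)
  rows <- list()
  for (m in names(module_genes)) {
    g <- ann[ann$gene_id %in% module_genes[[m]], , drop = FALSE]
    if (!nrow(g)) next
    gap <- GenomicRanges::distance(rep(lnc_gr, each = nrow(g)),
                                   rep(gr_of(g), nrow(lnc)),
                                   ignore.strand = TRUE)
    hit <- which(!is.na(gap) & gap < max_gap)
    if (!length(hit)) next
    li <- (hit - 1) %/% nrow(g) + 1
    gi <- (hit - 1) %% nrow(g) + 1
    rows[[m]] <- data.frame(lncRNA_id = lnc$gene_id[li],
                            partner = g$gene_id[gi],
                            gap_bp = gap[hit], module = m,
                            row.names = NULL)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncRNA_id = character(), partner = character(),
               gap_bp = integer(), module = character())
  out <- out[order(out$module, out$lncRNA_id, out$partner), ]
  rownames(out) <- NULL
  class(out) <- c("neighbor_pairs", "data.frame")
  out
}

#' PCA of highly variable lncRNAs
#'
#' Restricts the expression matrix to lncRNA rows, selects highly variable
#' lncRNAs with the binned-dispersion criterion, z-scales, and runs PCA
#' with the shared contract of \code{\link{run_pca}}.
#'
#' @param logm log-normalized genes x cells matrix (all genes).
#' @param ann a \code{\link{gene_annotation}} (used for biotype).
#' @param k number of components.
#' @param n_bins,z_cutoff,mean_bounds HVG parameters (lncRNAs are sparse,
#'   so the defaults are laxer than for coding genes).
#' @return an \code{embedding} over lncRNA features.
#' @export
lncrna_pca <- function(logm, ann, k = 10, n_bins = 10, z_cutoff = 0.5,
                       mean_bounds = c(0.05, Inf)) {
  lnc <- intersect(rownames(logm), ann$gene_id[ann$biotype == "lncRNA"])
  if (length(lnc) < 3) stop("fewer than 3 lncRNAs in the matrix")
  sub <- logm[lnc, , drop = FALSE]
  hvg <- select_hvg(sub, n_bins = n_bins, z_cutoff = z_cutoff,
                    mean_bounds = mean_bounds)
  sel <- hvg$selected
  if (length(sel) < 3) stop("fewer than 3 variable lncRNAs")
  run_pca(scale_clip(sub[sel, , drop = FALSE]), k = min(k, length(sel)))
}

signed_rank_p <- function(x) {
  x <- x[x != 0]
  if (!length(x)) return(1)
  suppressWarnings(stats::wilcox.test(x, mu = 0,
                                      alternative = "two.sided")$p.value)
}

#' Directional segregation of module loadings on principal axes
#'
#' For every (module, axis) pair: collect the PCA loadings of the module's
#' member features, test them against zero with a two-sided Wilcoxon
#' signed-rank test (exact for n <= 25 without ties, normal approximation
#' with continuity correction otherwise), BH-correct across all pairs, and
#' call a direction (sign of the median loading) when q is at or below the
#' threshold.
#'
#' @param emb an \code{embedding}.
#' @param modules named list: module label -> feature ids.
#' @param axes integer component indices to test.
#' @param q_threshold BH threshold for calling a direction.
#' @param min_features modules with fewer present features are reported as
#'   untestable and excluded from the correction.
#' @return data.frame of class \code{projection_result}: module, axis, n,
#'   q1, median, q3, p, q, direction.
#' @export
project_modules <- function(emb, modules, axes = 1:2, q_threshold = 0.05,
                            min_features = 5) {
  feats <- rownames(emb$loadings)
  rows <- list()
  for (m in names(modules)) {
    present <- intersect(modules[[m]], feats)
    for (ax in axes) {
      if (length(present) < min_features) {
        rows[[paste(m, ax)]] <- data.frame(
          module = m, axis = ax, n = length(present), q1 = NA_real_,
          median = NA_real_, q3 = NA_real_, p = NA_real_, testable = FALSE)
        next
      }
      ld <- emb$loadings[present, ax]
      qs <- stats::quantile(ld, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[paste(m, ax)]] <- data.frame(
        module = m, axis = ax, n = length(present), q1 = qs[1],
        median = qs[2], q3 = qs[3], p = signed_rank_p(ld),
        testable = TRUE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  tab$q[tab$testable] <- stats::p.adjust(tab$p[tab$testable], method = "BH")
  tab$direction <- "none"
  sig <- tab$testable & !is.na(tab$q) & tab$q <= q_threshold
  tab$direction[sig] <- ifelse(tab$median[sig] >= 0, "positive",
                               "negative")
  rownames(tab) <- NULL
  class(tab) <- c("projection_result", "data.frame")
  tab
}

#' Project transcriptomic modules onto TF motif-accessibility PCA
#'
#' Runs PCA with TFs as features over the TF x cells score matrix (scores
#' are z-scaled per TF first), then applies \code{\link{project_modules}}
#' to the TF loadings grouped by module via \code{tf_module_map}.
#'
#' @param tf TFs x cells numeric score matrix.
#' @param tf_module_map named list: module label -> TF ids, or a named
#'   character vector TF id -> module label.
#' @param k number of components.
#' @param axes axes to test.
#' @param q_threshold BH threshold.
#' @return list: \code{embedding} (TF-score PCA), \code{projection}
#'   (a \code{projection_result}).
#' @export
atac_project <- function(tf, tf_module_map, k = 10, axes = 1:2,
                         q_threshold = 0.05) {
  if (!is.list(tf_module_map))
    tf_module_map <- split(names(tf_module_map), unname(tf_module_map))
  tf_module_map <- lapply(tf_module_map, intersect, y = rownames(tf))
  if (!any(lengths(tf_module_map) > 0))
    stop("no TF maps to any module")
  if (stats::sd(as.vector(tf)) == 0)
    stop("TF score matrix is constant; PCA undefined")
  emb <- run_pca(scale_clip(tf), k = min(k, nrow(tf), ncol(tf)))
  list(embedding = emb,
       projection = project_modules(emb, tf_module_map, axes,
                                    q_threshold))
}
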