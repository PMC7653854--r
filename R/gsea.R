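# Running-sum gene-set enrichment between two cell compartments with
# permutation significance (phenotype permutation when group sizes allow).

#' Rank genes between two groups by signal-to-noise
#'
#' metric = (mean(A) - mean(B)) / (sd(A) + sd(B)), with each group's sd
#' floored at 0.2 * |group mean| + 1e-8 (the classic variance floor). Genes
#' are sorted by decreasing metric with ties broken by gene id, so the
#' order is strict and deterministic.
#'
#' @param logm log-normalized genes x cells matrix.
#' @param groupA,groupB cell ids of the two groups (A first: positive
#'   metric means higher in A).
#' @return list of class \code{ranked_list}: \code{genes} (sorted),
#'   \code{metric} (same order), \code{contrast}.
#' @export
rank_genes <- function(logm, groupA, groupB) {
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("both groups need at least 3 cells")
  a <- logm[, groupA, drop = FALSE]
  b <- logm[, groupB, drop = FALSE]
  floor_sd <- function(s, m) pmax(s, 0.2 * abs(m) + 1e-8)
  ma <- rowMeans(a); mb <- rowMeans(b)
  sa <- floor_sd(apply(a, 1, stats::sd), ma)
  sb <- floor_sd(apply(b, 1, stats::sd), mb)
  metric <- (ma - mb) / (sa + sb)
  ord <- order(-metric, rownames(logm), method = "radix")
  structure(list(genes = rownames(logm)[ord], metric = unname(metric[ord]),
                 contrast = c(A = deparse(substitute(groupA)),
                              B = deparse(substitute(groupB)))),
            class = "ranked_list")
}

#' Running-sum enrichment score
#'
#' Walking down the ranked list, hitting a set member increments the
#' running sum by |metric|^weight normalized by the sum over all hits;
#' missing decrements by 1/(N - N_hits). The enrichment score is the
#' running-sum value of maximum absolute deviation from zero (signed).
#' With weight 0 this is the classic Kolmogorov-Smirnov form.
#'
#' @param ranked a \code{ranked_list}.
#' @param set gene set (character).
#' @param weight exponent on |metric| for hit increments.
#' @return list: \code{es}, \code{running_sum} (length N), \code{hits}
#'   (logical per position), \code{peak} (position of the extremum).
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  genes <- ranked$genes
  hit <- genes %in% set
  if (!any(hit)) stop("gene set has no member in the ranked list")
  n <- length(genes)
  nh <- sum(hit)
  w <- abs(ranked$metric)^weight
  denom <- sum(w[hit])
  inc <- if (denom > 0) w * hit / denom else hit / nh
  dec <- if (n > nh) (!hit) / (n - nh) else rep(0, n)
  rs <- cumsum(inc - dec)
  peak <- which.max(abs(rs))
  structure(list(es = rs[peak], running_sum = rs, hits = hit, peak = peak),
            class = "gsea_es")
}

snr_metric <- function(logm, idxA, idxB) {
  a <- logm[, idxA, drop = FALSE]
  b <- logm[, idxB, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  na <- ncol(a); nb <- ncol(b)
  sa <- sqrt(pmax(rowSums((a - ma)^2) / (na - 1), 0))
  sb <- sqrt(pmax(rowSums((b - mb)^2) / (nb - 1), 0))
  sa <- pmax(sa, 0.2 * abs(ma) + 1e-8)
  sb <- pmax(sb, 0.2 * abs(mb) + 1e-8)
  (ma - mb) / (sa + sb)
}

es_from_metric <- function(metric, hit, weight) {
  n <- length(metric)
  nh <- sum(hit)
  w <- abs(metric)^weight
  denom <- sum(w[hit])
  inc <- if (denom > 0) w * hit / denom else hit / nh
  dec <- if (n > nh) (!hit) / (n - nh) else rep(0, n)
  rs <- cumsum(inc - dec)
  rs[which.max(abs(rs))]
}

#' Gene-set enrichment with permutation significance
#'
#' Ranks genes by signal-to-noise between the two groups and computes the
#' weighted running-sum enrichment score for every set in the collection.
#' The null is built by phenotype-label permutation when both groups have
#' at least 7 cells, otherwise by gene-set permutation (sampling random
#' sets of the same size; the choice is reported in the result). NES is
#' ES divided by the mean |null ES| of the same sign; the nominal p is the
#' one-sided empirical tail among same-sign null scores. FDR follows the
#' pooled-NES procedure and is reported as 0 when no pooled null NES
#' exceeds the observed one; a smoothed (+1/+1) value is also carried.
#'
#' @param logm log-normalized genes x cells matrix.
#' @param groupA,groupB cell ids of the two compartments (A vs B).
#' @param collection named list of gene sets.
#' @param n_perm number of permutations (>= 100).
#' @param weight running-sum weight.
#' @param seed permutation seed.
#' @param min_size sets with fewer expressed members are skipped.
#' @return data.frame of class \code{gsea_result}: set, size, es, nes, p,
#'   fdr, fdr_smoothed, leading_edge (comma-joined), with attributes
#'   \code{perm_type}, \code{n_perm}, \code{seed}.
#' @export
gsea_significance <- function(logm, groupA, groupB, collection,
                              n_perm = 1000, weight = 1, seed = 1L,
                              min_size = 3) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  idxA <- match(groupA, colnames(logm))
  idxB <- match(groupB, colnames(logm))
  if (anyNA(idxA) || anyNA(idxB)) stop("unknown cells in groups")
  metric <- snr_metric(logm, idxA, idxB)
  ord <- order(-metric, rownames(logm), method = "radix")
  genes <- rownames(logm)[ord]
  metric <- metric[ord]
  collection <- lapply(collection, intersect, y = genes)
  keep <- lengths(collection) >= min_size
  if (!all(keep))
    message(sum(!keep), " sets below min_size skipped")
  collection <- collection[keep]
  if (!length(collection)) stop("no usable sets in collection")
  hits <- lapply(collection, function(s) genes %in% s)
  es_obs <- vapply(hits, function(h) es_from_metric(metric, h, weight), 0)

  phenotype <- min(length(idxA), length(idxB)) >= 7
  null_es <- withr::with_seed(seed, {
    if (phenotype) {
      pool <- c(idxA, idxB)
      nA <- length(idxA)
      vapply(seq_len(n_perm), function(i) {
        pa <- sample(pool, nA)
        pm <- snr_metric(logm, pa, setdiff(pool, pa))
        po <- order(-pm, rownames(logm), method = "radix")
        pg <- rownames(logm)[po]
        pmet <- pm[po]
        vapply(collection, function(s)
          es_from_metric(pmet, pg %in% s, weight), 0)
      }, numeric(length(collection)))
    } else {
      sizes <- lengths(collection)
      vapply(seq_len(n_perm), function(i) {
        vapply(sizes, function(m) {
          h <- logical(length(genes))
          h[sample.int(length(genes), m)] <- TRUE
          es_from_metric(metric, h, weight)
        }, 0)
      }, numeric(length(collection)))
    }
  })
  null_es <- matrix(null_es, nrow = length(collection))  # sets x perms

  nes <- numeric(length(es_obs))
  pval <- numeric(length(es_obs))
  nes_null <- matrix(NA_real_, nrow(null_es), ncol(null_es))
  for (i in seq_along(es_obs)) {
    nul <- null_es[i, ]
    same <- nul * sign(es_obs[i]) >= 0
    pos <- nul[nul >= 0]; neg <- nul[nul < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    nes[i] <- if (es_obs[i] >= 0) es_obs[i] / mpos else es_obs[i] / mneg
    nes_null[i, nul >= 0] <- nul[nul >= 0] / mpos
    nes_null[i, nul < 0] <- nul[nul < 0] / mneg
    n_same <- sum(same)
    n_exceed <- sum(same & abs(nul) >= abs(es_obs[i]))
    pval[i] <- if (n_same == 0) 1 / (n_perm + 1) else
      (1 + n_exceed) / (1 + n_same)
  }
  pool_null <- nes_null[is.finite(nes_null)]
  obs <- nes[is.finite(nes)]
  fdr <- fdr_sm <- numeric(length(nes))
  for (i in seq_along(nes)) {
    if (!is.finite(nes[i])) { fdr[i] <- fdr_sm[i] <- NA_real_; next }
    if (nes[i] >= 0) {
      num_tail <- sum(pool_null >= nes[i]); num_all <- sum(pool_null >= 0)
      den_tail <- sum(obs >= nes[i]); den_all <- sum(obs >= 0)
    } else {
      num_tail <- sum(pool_null <= nes[i]); num_all <- sum(pool_null < 0)
      den_tail <- sum(obs <= nes[i]); den_all <- sum(obs < 0)
    }
    num <- if (num_all > 0) num_tail / num_all else 0
    den <- if (den_all > 0) den_tail / den_all else 1
    fdr[i] <- min(1, if (den > 0) num / den else 0)
    num_s <- (num_tail + 1) / (num_all + 1)
    fdr_sm[i] <- min(1, if (den > 0) num_s / den else num_s)
  }
  leading <- vapply(seq_along(collection), function(i) {
    h <- hits[[i]]
    es <- enrichment_score(structure(list(genes = genes, metric = metric),
                                     class = "ranked_list"),
                           collection[[i]], weight)
    le <- if (es$es >= 0) genes[seq_len(es$peak)][h[seq_len(es$peak)]]
    else genes[es$peak:length(genes)][h[es$peak:length(genes)]]
    paste(le, collapse = ",")
  }, "")
  out <- data.frame(set = names(collection), size = lengths(collection),
                    es = es_obs, nes = nes, p = pval, fdr = fdr,
                    fdr_smoothed = fdr_sm, leading_edge = leading,
                    row.names = NULL)
  attr(out, "perm_type") <- if (phenotype) "phenotype" else "gene_set"
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("gsea_result", "data.frame")
  out
}
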