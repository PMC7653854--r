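# Cell-cycle phase allocation from the transcriptome.

#' Score cells for S and G2/M programs and allocate a phase
#'
#' For each program, the score is the mean expression of the program's
#' genes minus the mean of an expression-matched background (genes sampled
#' from the same mean-expression bins), z-standardized across cells. A cell
#' is allocated to the program with the larger positive standardized score;
#' cells with both scores at or below 0 are G0/G1.
#'
#' @param logm log-normalized genes x cells matrix.
#' @param s_set,g2m_set character vectors of S-phase and G2/M-phase program
#'   genes.
#' @param n_bins number of mean-expression bins for background matching.
#' @param bg_per_gene background genes sampled per program gene.
#' @param seed seed for the background sampling.
#' @return list of class \code{phase_assignment}: \code{phase} (factor per
#'   cell with levels G0/G1, S, G2/M) and \code{scores} (cells x 2 matrix of
#'   standardized S and G2M scores).
#' @export
score_phase <- function(logm, s_set, g2m_set, n_bins = 25,
                        bg_per_gene = 50, seed = 7L) {
  mu <- rowMeans(logm)
  qs <- unique(stats::quantile(mu, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, qs, include.lowest = TRUE, labels = FALSE)
  names(bin) <- rownames(logm)
  one_score <- function(set, excl) {
    set <- intersect(set, rownames(logm))
    if (!length(set)) stop("gene set has no expressed member")
    bg <- withr::with_seed(seed, {
      unlist(lapply(set, function(g) {
        pool <- setdiff(names(bin)[bin == bin[g]], excl)
        if (!length(pool)) return(character())
        sample(pool, min(bg_per_gene, length(pool)))
      }))
    })
    if (!length(bg)) bg <- setdiff(rownames(logm), excl)
    raw <- colMeans(logm[set, , drop = FALSE]) -
      colMeans(logm[unique(bg), , drop = FALSE])
    s <- stats::sd(raw)
    if (s == 0) return(raw * 0)
    (raw - mean(raw)) / s
  }
  excl <- c(s_set, g2m_set)
  s_score <- one_score(s_set, excl)
  g2m_score <- one_score(g2m_set, excl)
  phase <- rep("G0/G1", ncol(logm))
  pos_s <- s_score > 0 & s_score >= g2m_score
  pos_g <- g2m_score > 0 & g2m_score > s_score
  phase[pos_s] <- "S"
  phase[pos_g] <- "G2/M"
  phase <- factor(phase, levels = c("G0/G1", "S", "G2/M"))
  names(phase) <- colnames(logm)
  structure(list(phase = phase,
                 scores = cbind(S = s_score, G2M = g2m_score)),
            class = "phase_assignment")
}

#' Phase composition per group
#'
#' @param phases a \code{phase_assignment} (or a factor of phases).
#' @param groups grouping labels, one per cell.
#' @return data.frame: one row per non-empty group, columns group, n, and
#'   the proportion of each phase (rows sum to 1). Empty groups are omitted
#'   with a warning.
#' @export
phase_composition <- function(phases, groups) {
  ph <- if (inherits(phases, "phase_assignment")) phases$phase else phases
  if (length(ph) != length(groups))
    stop("groups must cover all cells")
  groups <- as.character(groups)
  empty <- setdiff(unique(groups), groups[!is.na(ph)])
  if (length(empty))
    warning("empty groups omitted: ", paste(empty, collapse = ", "))
  tab <- table(groups, ph)
  prop <- sweep(tab, 1, rowSums(tab), "/")
  data.frame(group = rownames(prop), n = as.integer(rowSums(tab)),
             as.data.frame.matrix(prop), check.names = FALSE,
             row.names = NULL)
}
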