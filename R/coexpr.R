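# Multi-branch differential co-expression: per-branch gene-pair correlation
# vectors for a gene set, the dispersion index (DI) summarizing how much
# those vectors disagree, permutation significance, a collection scan, and
# conserved/altered edge calls for network rendering.

#' Per-branch gene-pair correlation vectors for a gene set
#'
#' For each branch, the Pearson correlation of every ordered gene pair
#' (i < j in gene order) over that branch's cells. A gene is usable when
#' expressed (nonzero) in at least \code{min_expr_frac} of a branch's
#' cells; the usable set is intersected across branches so all branch
#' vectors share the same pairs.
#'
#' @param logm log-normalized genes x cells matrix.
#' @param set gene set (character).
#' @param branches named list mapping branch label to cell ids, or a named
#'   character vector of branch labels (names = cell ids; NA cells are
#'   dropped).
#' @param min_expr_frac per-branch expressed-fraction threshold.
#' @param method correlation method (\code{pearson} default;
#'   \code{spearman} available because dropout inflates Pearson artifacts).
#' @return list of class \code{correlation_vectors}: \code{rho} (branches x
#'   pairs matrix, pair columns named "gi|gj"), \code{genes} (usable genes,
#'   set order), \code{n_cells} (per branch).
#' @export
correlation_vectors <- function(logm, set, branches, min_expr_frac = 0.1,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  branches <- as_branch_list(branches)
  if (length(branches) < 2) stop("need at least 2 branches")
  set <- intersect(set, rownames(logm))
  usable <- set
  for (b in names(branches)) {
    cells <- branches[[b]]
    if (length(cells) < 10)
      stop("branch ", b, " has fewer than 10 cells")
    frac <- rowMeans(logm[set, cells, drop = FALSE] > 0)
    usable <- intersect(usable, set[frac >= min_expr_frac])
  }
  if (length(usable) < 3)
    stop("fewer than 3 usable genes for set in branches ",
         paste(names(branches), collapse = "/"))
  m <- length(usable)
  pair_i <- rep(seq_len(m - 1), times = (m - 1):1)
  pair_j <- sequence((m - 1):1, from = 2:m)
  pnames <- paste(usable[pair_i], usable[pair_j], sep = "|")
  rho <- matrix(NA_real_, length(branches), length(pnames),
                dimnames = list(names(branches), pnames))
  for (b in names(branches)) {
    cc <- stats::cor(t(logm[usable, branches[[b]], drop = FALSE]),
                     method = method)
    rho[b, ] <- cc[cbind(pair_i, pair_j)]
  }
  structure(list(rho = rho, genes = usable,
                 pairs = data.frame(gene_i = usable[pair_i],
                                    gene_j = usable[pair_j]),
                 n_cells = vapply(branches, length, 0L)),
            class = "correlation_vectors")
}

#' @rdname correlation_vectors
#' @param cells cell ids of a single branch; usable genes are determined
#'   within this branch alone.
#' @return for \code{correlation_vector}: a named numeric vector of pair
#'   correlations for one branch.
#' @export
correlation_vector <- function(logm, set, cells, min_expr_frac = 0.1,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cv <- correlation_vectors(logm, set,
                            list(branch = cells, branch2 = cells),
                            min_expr_frac, method)
  cv$rho["branch", ]
}

as_branch_list <- function(branches) {
  if (is.list(branches)) return(branches)
  branches <- branches[!is.na(branches)]
  split(names(branches), unname(branches))
}

#' Dispersion index of branch correlation vectors
#'
#' DI = sqrt( mean over pairs of the population variance of the branch
#' correlations about the per-pair mean ). It is 0 exactly when all branch
#' vectors are identical, and is equivalent up to a fixed constant to the
#' mean pairwise Euclidean distance between the branch vectors: for B
#' branches, the mean squared pairwise difference per pair equals
#' 2B/(B-1) times the per-pair variance, so at B = 2 the root-mean squared
#' pairwise distance is exactly 2 x DI.
#'
#' @param vectors a \code{correlation_vectors} object, or a branches x
#'   pairs numeric matrix.
#' @return scalar DI >= 0.
#' @export
dispersion_index <- function(vectors) {
  rho <- if (inherits(vectors, "correlation_vectors")) vectors$rho
  else as.matrix(vectors)
  if (nrow(rho) < 2) stop("need at least 2 branches")
  if (ncol(rho) < 1) stop("no shared pairs")
  ctr <- sweep(rho, 2, colMeans(rho))
  sqrt(mean(colMeans(ctr^2)))
}

#' Permutation test of the dispersion index
#'
#' The null is built by shuffling branch labels over the pooled cells,
#' preserving branch sizes; permutations violating the correlation-vector
#' preconditions (too few usable genes after reshuffling) are resampled,
#' with the count reported. p = (1 + #\{DI_null >= DI_obs\}) / (1 + n_perm).
#'
#' @param logm log-normalized genes x cells matrix.
#' @param set gene set.
#' @param branch_labels named character vector (names = cell ids, values =
#'   branch labels; NA cells excluded) or named list branch -> cells.
#' @param n_perm number of permutations (>= 100).
#' @param seed permutation seed.
#' @param min_expr_frac see \code{\link{correlation_vectors}}.
#' @param method correlation method.
#' @return list of class \code{di_result}: di, p, n_perm, seed, n_cells,
#'   null_di, n_resampled.
#' @export
permute_di <- function(logm, set, branch_labels, n_perm = 1000, seed = 1L,
                       min_expr_frac = 0.1,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (n_perm < 100) stop("n_perm must be >= 100")
  branches <- as_branch_list(branch_labels)
  obs <- dispersion_index(correlation_vectors(logm, set, branches,
                                              min_expr_frac, method))
  pool <- unlist(branches, use.names = FALSE)
  sizes <- vapply(branches, length, 0L)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  n_resampled <- 0L
  null_di <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      for (try in 1:50) {
        perm <- sample(pool)
        bl <- lapply(seq_along(sizes), function(k)
          perm[starts[k]:ends[k]])
        names(bl) <- names(branches)
        di <- tryCatch(
          dispersion_index(correlation_vectors(logm, set, bl,
                                               min_expr_frac, method)),
          error = function(e) NA_real_)
        if (!is.na(di)) return(di)
        n_resampled <<- n_resampled + 1L
      }
      stop("could not find a valid permutation after 50 tries")
    }, 0)
  })
  structure(list(di = obs, p = (1 + sum(null_di >= obs)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed,
                 n_cells = vapply(branches, length, 0L),
                 null_di = null_di, n_resampled = n_resampled),
            class = "di_result")
}

#' @method print di_result
#' @export
print.di_result <- function(x, ...) {
  cat(sprintf("DI = %.4f, permutation p = %.4g (%d permutations)\n",
              x$di, x$p, x$n_perm))
  invisible(x)
}

#' Scan a gene-set collection for differential co-expression
#'
#' Runs \code{\link{permute_di}} on every set; sets failing the
#' correlation-vector preconditions are reported as skipped and excluded
#' from the BH correction.
#'
#' @inheritParams permute_di
#' @param collection named list of gene sets.
#' @return data.frame (set, m usable genes, n_pairs, di, p, q, skipped)
#'   ordered by decreasing DI among tested sets.
#' @export
scan_collection <- function(logm, collection, branch_labels, n_perm = 1000,
                            seed = 1L, min_expr_frac = 0.1,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!length(collection)) stop("empty collection")
  rows <- lapply(seq_along(collection), function(i) {
    r <- tryCatch(
      permute_di(logm, collection[[i]], branch_labels, n_perm,
                 seed = derive_seed(seed, i), min_expr_frac, method),
      error = function(e) e)
    if (inherits(r, "error"))
      return(data.frame(set = names(collection)[i], m = NA_integer_,
                        n_pairs = NA_integer_, di = NA_real_, p = NA_real_,
                        skipped = TRUE))
    cv <- correlation_vectors(logm, collection[[i]],
                              as_branch_list(branch_labels),
                              min_expr_frac, method)
    data.frame(set = names(collection)[i], m = length(cv$genes),
               n_pairs = ncol(cv$rho), di = r$di, p = r$p, skipped = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  tab$q[!tab$skipped] <- stats::p.adjust(tab$p[!tab$skipped], method = "BH")
  tab[order(tab$skipped, -tab$di), ]
}

#' Classify gene-pair edges as conserved or altered across branches
#'
#' An edge (gene pair) is altered when the largest between-branch
#' difference of its correlation exceeds \code{delta}; otherwise conserved.
#' Per-branch signed correlations are retained for network rendering
#' (positive/negative edge coloring).
#'
#' @param vectors a \code{correlation_vectors}.
#' @param delta correlation-difference threshold.
#' @return data.frame: gene_i, gene_j, one correlation column per branch,
#'   max_delta, class.
#' @export
classify_edges <- function(vectors, delta = 0.5) {
  rho <- vectors$rho
  max_delta <- apply(rho, 2, max) - apply(rho, 2, min)
  out <- data.frame(vectors$pairs, t(rho),
                    max_delta = unname(max_delta),
                    class = ifelse(max_delta > delta, "altered",
                                   "conserved"),
                    check.names = FALSE, row.names = NULL)
  out
}
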