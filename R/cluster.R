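# Embedding, density clustering, marker extraction, and cell-type
# assignment by gene-set overlap significance.

#' Principal component analysis of an expression matrix
#'
#' Cells are observations, features (genes) variables. Columns are centered;
#' any scaling (the pipeline z-scales HVGs via \code{\link{scale_clip}}) is
#' applied beforehand. Each loading column is oriented so its
#' largest-magnitude entry is positive, giving reproducible projection
#' directions.
#'
#' @param m features x cells matrix (e.g. log expression restricted to
#'   HVGs).
#' @param k number of components.
#' @return list of class \code{embedding}: \code{scores} (cells x k),
#'   \code{loadings} (features x k, orthonormal), \code{explained_variance}
#'   (length k, non-increasing).
#' @export
run_pca <- function(m, k = 10) {
  x <- t(m)                          # cells x features
  n <- nrow(x)
  if (k > min(dim(x))) stop("k exceeds matrix dimensions")
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = k, nv = k)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncated")
    k <- rank
  }
  if (k < 1) stop("matrix has rank 0; PCA undefined")
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- x %*% loadings
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- rownames(m)
  rownames(scores) <- colnames(m)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = (sv$d[seq_len(k)]^2) / (n - 1)),
            class = "embedding")
}

# default eps from the sorted k-distance curve: the 75th percentile, a
# robust stand-in for the k-distance elbow when the knee is shallow (small
# n); the top quartile of k-distances is treated as the noise tail
kdist_eps <- function(d_sorted) {
  stats::quantile(d_sorted, 0.75, names = FALSE)
}

#' Density-based clustering (DBSCAN) of embedded cells
#'
#' Standard density-reachability semantics on Euclidean distance over the
#' first \code{n_pcs} score columns. A point is core when at least
#' \code{min_pts} points (itself included) lie within \code{eps}. Border
#' points joining several clusters take the cluster discovered first
#' (stable iteration order by cell index). Noise is labelled 0.
#'
#' @param emb an \code{embedding} (or a cells x d coordinate matrix).
#' @param eps neighborhood radius; when \code{NULL}, taken from the elbow of
#'   the sorted \code{min_pts}-distance curve.
#' @param min_pts core-point threshold.
#' @param n_pcs number of leading score columns used.
#' @return list of class \code{cluster_result}: \code{labels} (integer per
#'   cell, 0 = noise, named by cell id) and \code{params}.
#' @export
dbscan_cluster <- function(emb, eps = NULL, min_pts = 5, n_pcs = 10) {
  pts <- if (inherits(emb, "embedding")) emb$scores else as.matrix(emb)
  n_pcs <- min(n_pcs, ncol(pts))
  pts <- pts[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(pts)
  dm <- as.matrix(stats::dist(pts))
  if (is.null(eps)) {
    kd <- apply(dm, 1, function(r) sort(r)[min_pts])  # self at rank 1
    eps <- kdist_eps(sort(kd))
  }
  if (eps <= 0) stop("eps must be positive")
  nb <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  if (all(labels == 0L)) message("dbscan_cluster: all points are noise")
  names(labels) <- rownames(pts)
  structure(list(labels = labels,
                 params = list(eps = eps, min_pts = min_pts,
                               n_pcs = n_pcs)),
            class = "cluster_result")
}

rank_sum_p <- function(x, y, alternative = "greater") {
  suppressWarnings(stats::wilcox.test(x, y,
                                      alternative = alternative)$p.value)
}

#' One-vs-rest marker genes per cluster
#'
#' For every gene and every non-noise cluster with at least 3 cells, a
#' one-sided Wilcoxon rank-sum test of that cluster's cells against all
#' other clustered cells. BH correction is applied over all (gene, cluster)
#' tests. Markers require \code{log_fc >= min_log_fc} and
#' \code{q <= q_max}; within a cluster they are ranked by q then by
#' decreasing log fold change.
#'
#' @param logm log-normalized genes x cells matrix.
#' @param clusters a \code{cluster_result}.
#' @param min_log_fc minimum mean log2 difference (cluster minus rest).
#' @param q_max BH threshold.
#' @return data.frame of class \code{marker_table} with columns cluster,
#'   gene, log_fc, p, q, is_marker, rank (NA for non-markers).
#' @export
cluster_markers <- function(logm, clusters, min_log_fc = 1, q_max = 0.05) {
  labels <- clusters$labels[colnames(logm)]
  keep <- labels != 0L
  cls <- sort(unique(labels[keep]))
  if (length(cls) < 2) stop("need at least 2 non-noise clusters")
  rows <- list()
  for (cl in cls) {
    in_cl <- keep & labels == cl
    if (sum(in_cl) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    out_cl <- keep & labels != cl
    lfc <- rowMeans(logm[, in_cl, drop = FALSE]) -
      rowMeans(logm[, out_cl, drop = FALSE])
    p <- vapply(seq_len(nrow(logm)), function(g)
      rank_sum_p(logm[g, in_cl], logm[g, out_cl]), 0)
    rows[[as.character(cl)]] <- data.frame(cluster = cl,
                                           gene = rownames(logm),
                                           log_fc = lfc, p = p,
                                           row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$is_marker <- tab$log_fc >= min_log_fc & tab$q <= q_max
  tab$rank <- NA_integer_
  for (cl in unique(tab$cluster)) {
    idx <- which(tab$cluster == cl & tab$is_marker)
    if (length(idx))
      tab$rank[idx] <- order(order(tab$q[idx], -tab$log_fc[idx]))
  }
  class(tab) <- c("marker_table", "data.frame")
  tab
}

#' Top markers of each cluster
#'
#' @param markers a \code{marker_table}.
#' @param n markers per cluster.
#' @return subset of the table, ranked.
#' @export
top_markers <- function(markers, n = 10) {
  out <- markers[markers$is_marker & !is.na(markers$rank) &
                   markers$rank <= n, ]
  out[order(out$cluster, out$rank), ]
}

#' Assign an HSPC type to each cluster by marker overlap significance
#'
#' For every (cluster, reference set) pair, a one-sided hypergeometric test
#' (Fisher's exact test upper tail) of the overlap between the cluster's
#' markers and the reference signature within the gene universe, BH-corrected
#' across all pairs. A cluster takes the type with smallest q when
#' \code{q <= q_max}; ties go to the larger overlap, remaining ties are left
#' unassigned.
#'
#' @param markers a \code{marker_table}.
#' @param reference named list of reference signature gene sets.
#' @param universe character vector of genes eligible for testing.
#' @param q_max BH threshold for assignment.
#' @return data.frame of class \code{celltype_assignment}: cluster, type
#'   (NA when unassigned), overlap, p, q.
#' @export
assign_celltype <- function(markers, reference, universe, q_max = 0.05) {
  if (!length(reference) || any(lengths(reference) == 0))
    stop("reference sets must be non-empty")
  universe <- unique(universe)
  cls <- sort(unique(markers$cluster))
  grid <- expand.grid(cluster = cls, type = names(reference),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    mk <- intersect(markers$gene[markers$cluster == grid$cluster[i] &
                                   markers$is_marker], universe)
    ref <- intersect(reference[[grid$type[i]]], universe)
    k <- length(intersect(mk, ref))
    p <- hypergeom_tail(k, length(mk), length(ref), length(universe))
    data.frame(cluster = grid$cluster[i], type = grid$type[i],
               overlap = k, n_markers = length(mk), p = p)
  })
  tab <- do.call(rbind, res)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  out <- lapply(cls, function(cl) {
    sub <- tab[tab$cluster == cl, ]
    if (all(sub$n_markers == 0))
      return(data.frame(cluster = cl, type = NA_character_, overlap = 0L,
                        p = NA_real_, q = NA_real_))
    sub <- sub[sub$q <= q_max, , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(cluster = cl, type = NA_character_, overlap = 0L,
                        p = NA_real_, q = NA_real_))
    best <- sub[order(sub$q, -sub$overlap), ]
    if (nrow(best) > 1 && best$q[1] == best$q[2] &&
        best$overlap[1] == best$overlap[2])
      return(data.frame(cluster = cl, type = NA_character_,
                        overlap = best$overlap[1], p = best$p[1],
                        q = best$q[1]))
    data.frame(cluster = cl, type = best$type[1], overlap = best$overlap[1],
               p = best$p[1], q = best$q[1])
  })
  out <- do.call(rbind, out)
  attr(out, "all_pairs") <- tab
  class(out) <- c("celltype_assignment", "data.frame")
  out
}

# P(X >= k) for overlap of a size-n draw with a size-K set in a size-N
# universe; includes the k = 0 case (p = 1)
hypergeom_tail <- function(k, n, K, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation of a gene list in a set collection
#'
#' Hypergeometric upper-tail p per set (the one-sided Fisher test), BH
#' across sets. The upper tail includes the observed-overlap-or-more region,
#' so a disjoint set yields p = 1.
#'
#' @param genes query gene list (must lie in \code{universe}).
#' @param universe background gene list.
#' @param collection named list of gene sets.
#' @return data.frame (set, overlap, set_size, p, q) ordered by p.
#' @export
overrepresentation <- function(genes, universe, collection) {
  if (!length(genes)) stop("empty gene list")
  universe <- unique(universe)
  if (!all(genes %in% universe)) stop("genes must be a subset of universe")
  genes <- unique(genes)
  res <- lapply(names(collection), function(nm) {
    ref <- intersect(collection[[nm]], universe)
    k <- length(intersect(genes, ref))
    data.frame(set = nm, overlap = k, set_size = length(ref),
               p = hypergeom_tail(k, length(genes), length(ref),
                                  length(universe)))
  })
  tab <- do.call(rbind, res)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab[order(tab$p), ]
}

#' Absorb noise cells into their nearest cluster
#'
#' DBSCAN's noise cells are typically transitional cells on the boundaries
#' between populations. For stages that need every cell labelled -- the
#' cluster connectivity graph (where boundary cells carry the
#' parent-child adjacency signal) and branch inheritance -- each noise
#' cell takes the label of its nearest labelled cell in the embedding.
#'
#' @param clusters a \code{cluster_result}.
#' @param emb the \code{embedding} the clustering was computed on.
#' @return a \code{cluster_result} with no noise labels (params carry
#'   \code{absorbed = TRUE}).
#' @export
absorb_noise <- function(clusters, emb) {
  pts <- if (inherits(emb, "embedding")) emb$scores else as.matrix(emb)
  pts <- pts[, seq_len(min(clusters$params$n_pcs, ncol(pts))),
             drop = FALSE]
  labels <- clusters$labels
  noise <- which(labels == 0L)
  if (length(noise)) {
    lab_idx <- which(labels != 0L)
    if (!length(lab_idx)) stop("no labelled cells to absorb noise into")
    dm <- as.matrix(stats::dist(pts))
    for (i in noise) {
      nn <- lab_idx[order(dm[i, lab_idx])][1:min(5, length(lab_idx))]
      tab <- table(labels[nn])
      labels[i] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  structure(list(labels = labels,
                 params = c(clusters$params, list(absorbed = TRUE))),
            class = "cluster_result")
}
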