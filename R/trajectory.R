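# Diffusion-map embedding, root-anchored pseudotime, cluster-connectivity
# graph with branch assignment, and detection of genes dynamic along
# pseudotime.

#' Diffusion-map embedding
#'
#' Gaussian kernel on Euclidean distances restricted to the symmetrized
#' k-nearest-neighbor graph, density-normalized with anisotropic exponent 1
#' (removing sampling-density effects), row-normalized to a Markov matrix,
#' and eigendecomposed; the trivial stationary component is dropped. The
#' kernel width is the median distance to the k-th neighbor.
#'
#' @param x an \code{embedding} (scores are used), a cells x features
#'   coordinate matrix, or a log-normalized genes x cells matrix (detected
#'   via its \code{normalization} attribute and transposed).
#' @param k_neighbors neighbors per cell for the kNN graph.
#' @param n_comps number of diffusion components (>= 2).
#' @return list of class \code{diffusion_embedding}: \code{components}
#'   (cells x n_comps), \code{eigenvalues} (descending, in (0, 1]),
#'   \code{knn_edges} (2-column matrix of the symmetrized kNN graph),
#'   \code{params}.
#' @export
diffusion_map <- function(x, k_neighbors = 15, n_comps = 10) {
  if (n_comps < 2) stop("n_comps must be >= 2")
  pts <- if (inherits(x, "embedding")) x$scores
  else if (!is.null(attr(x, "normalization"))) t(x)
  else as.matrix(x)
  n <- nrow(pts)
  if (k_neighbors >= n) k_neighbors <- n - 1
  if (n_comps > n - 1) n_comps <- n - 1
  dm <- as.matrix(stats::dist(pts))
  nn_d <- matrix(0, n, k_neighbors)
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ])
    nn <- ord[ord != i][seq_len(k_neighbors)]
    mask[i, nn] <- TRUE
    nn_d[i, ] <- dm[i, nn]
  }
  mask <- mask | t(mask)                       # symmetrize by union
  # connectivity check (BFS over the kNN graph)
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nxt <- which(mask[i, ] & !seen)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  if (!all(seen))
    stop("kNN graph is disconnected; increase k_neighbors")
  sigma <- stats::median(nn_d[, k_neighbors])
  if (sigma == 0) stop("kernel width is zero (coincident points)")
  w <- exp(-dm^2 / (2 * sigma^2))
  w[!mask] <- 0
  diag(w) <- 1
  q <- rowSums(w)
  w1 <- w / outer(q, q)                        # density normalization
  d1 <- rowSums(w1)
  s <- w1 / outer(sqrt(d1), sqrt(d1))          # symmetric conjugate
  eig <- eigen(s, symmetric = TRUE)
  keep <- 2:(n_comps + 1)
  comps <- eig$vectors[, keep, drop = FALSE] / sqrt(d1)
  for (j in seq_len(ncol(comps))) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  rownames(comps) <- rownames(pts)
  colnames(comps) <- paste0("DC", seq_len(ncol(comps)))
  edges <- which(mask & upper.tri(mask), arr.ind = TRUE)
  structure(list(components = comps,
                 eigenvalues = pmin(pmax(eig$values[keep], 0), 1),
                 knn_edges = edges,
                 params = list(k_neighbors = k_neighbors, sigma = sigma)),
            class = "diffusion_embedding")
}

#' Select a root cell by stem-signature score
#'
#' The root is the cell maximizing the mean per-gene z-score of a stem
#' signature set.
#'
#' @param logm log-normalized genes x cells matrix.
#' @param stem_set stem signature gene ids.
#' @return a cell id.
#' @export
select_root <- function(logm, stem_set) {
  set <- intersect(stem_set, rownames(logm))
  if (!length(set)) stop("stem set has no expressed member")
  z <- scale_clip(logm[set, , drop = FALSE], clip = Inf)
  colnames(logm)[which.max(colMeans(z))]
}

#' Diffusion pseudotime from a root cell
#'
#' Pseudotime is the Euclidean distance from the root in the first three
#' eigenvalue-scaled diffusion components, min-max rescaled to [0, 1].
#'
#' @param demb a \code{diffusion_embedding}.
#' @param root root cell id.
#' @return list of class \code{pseudotime_result}: \code{t} (named, in
#'   [0, 1], 0 at the root), \code{root}.
#' @export
pseudotime <- function(demb, root) {
  if (!root %in% rownames(demb$components)) stop("unknown root cell")
  k <- min(3, ncol(demb$components))
  sc <- sweep(demb$components[, seq_len(k), drop = FALSE], 2,
              demb$eigenvalues[seq_len(k)], "*")
  d <- sqrt(rowSums((sc - matrix(sc[root, ], nrow(sc), k,
                                 byrow = TRUE))^2))
  rng <- range(d)
  t <- if (rng[2] > rng[1]) (d - rng[1]) / (rng[2] - rng[1]) else d * 0
  structure(list(t = t, root = root), class = "pseudotime_result")
}

#' Cluster connectivity graph from a kNN graph
#'
#' For each cluster pair, the number of kNN edges joining them divided by
#' its expectation were the observed total of inter-cluster edges placed at
#' random across pairs proportionally to n_a * n_b. Values above 1 mark
#' pairs more connected than expected. Noise cells (label 0) are excluded.
#'
#' @param knn_edges 2-column matrix of undirected edges (cell indices), as
#'   returned by \code{\link{diffusion_map}}.
#' @param clusters a \code{cluster_result} (labels aligned with the cell
#'   indices of \code{knn_edges}).
#' @return list of class \code{connectivity_graph}: \code{weights}
#'   (symmetric clusters x clusters matrix), \code{observed} (edge counts),
#'   \code{n_cells} per cluster.
#' @export
connectivity_graph <- function(knn_edges, clusters) {
  labels <- clusters$labels
  cls <- sort(unique(labels[labels != 0L]))
  if (length(cls) < 2) stop("need at least 2 clusters")
  k <- length(cls)
  obs <- matrix(0, k, k, dimnames = list(cls, cls))
  la <- labels[knn_edges[, 1]]
  lb <- labels[knn_edges[, 2]]
  inter <- la != 0L & lb != 0L & la != lb
  for (e in which(inter)) {
    i <- as.character(la[e]); j <- as.character(lb[e])
    obs[i, j] <- obs[i, j] + 1
    obs[j, i] <- obs[j, i] + 1
  }
  n_cells <- vapply(cls, function(cl) sum(labels == cl), 0L)
  names(n_cells) <- cls
  e_total <- sum(obs) / 2
  share <- outer(n_cells, n_cells)
  tot_share <- sum(share[upper.tri(share)])
  expected <- e_total * share / tot_share
  weights <- matrix(0, k, k, dimnames = list(cls, cls))
  nz <- expected > 0
  weights[nz] <- obs[nz] / expected[nz]
  diag(weights) <- 0
  structure(list(weights = weights, observed = obs, n_cells = n_cells),
            class = "connectivity_graph")
}

# Prim's algorithm for the maximum-weight spanning tree; ties broken by
# cluster label order for determinism
max_spanning_tree <- function(weights, root) {
  cls <- rownames(weights)
  in_tree <- root
  edges <- NULL
  while (length(in_tree) < length(cls)) {
    cand <- expand.grid(a = in_tree, b = setdiff(cls, in_tree),
                        stringsAsFactors = FALSE)
    cand$w <- weights[cbind(cand$a, cand$b)]
    cand <- cand[order(-cand$w, cand$a, cand$b), ]
    best <- cand[1, ]
    edges <- rbind(edges, data.frame(from = best$a, to = best$b,
                                     weight = best$w))
    in_tree <- c(in_tree, best$b)
  }
  edges
}

#' Assign lineage branches from the cluster connectivity graph
#'
#' Builds the maximum-weight spanning tree of the cluster graph rooted at
#' the cluster assigned the root type; each root-to-leaf path defines a
#' branch. A cluster's branch is the common branch of its descendant
#' leaves' types when unique, otherwise its own type's branch; the root is
#' \code{stem}. Cells inherit their cluster's branch.
#'
#' @param graph a \code{connectivity_graph}.
#' @param clusters a \code{cluster_result}.
#' @param assignment a \code{celltype_assignment} (cluster -> type).
#' @param root_type type label of the root (default \code{"HSC"}).
#' @param branch_map named vector mapping type labels to branch labels;
#'   defaults to the canonical hematopoietic map (MEP -> erythro-MK,
#'   GMP -> granulo-mono, MLP/ProB/ETP -> lymphoid).
#' @return list of class \code{branch_assignment}: \code{tree} (edge
#'   data.frame), \code{cluster_branch} (named), \code{cell_branch}
#'   (named per cell; NA for noise cells).
#' @export
assign_branches <- function(graph, clusters, assignment,
                            root_type = "HSC", branch_map = NULL) {
  if (is.null(branch_map))
    branch_map <- c(HSC = "stem", MLP = "lymphoid", MEP = "erythro-MK",
                    GMP = "granulo-mono", ProB = "lymphoid",
                    ETP = "lymphoid")
  types <- stats::setNames(assignment$type, as.character(assignment$cluster))
  root_cl <- names(types)[!is.na(types) & types == root_type]
  if (!length(root_cl)) stop("root type ", root_type, " not assigned")
  root_cl <- root_cl[1]
  tree <- max_spanning_tree(graph$weights, root_cl)
  cls <- rownames(graph$weights)
  children <- function(cl) tree$to[tree$from == cl]
  descend_leaves <- function(cl) {
    ch <- children(cl)
    if (!length(ch)) return(cl)
    unlist(lapply(ch, descend_leaves))
  }
  type_branch <- function(cl) {
    ty <- types[[cl]]
    if (is.na(ty) || !ty %in% names(branch_map)) NA_character_
    else unname(branch_map[ty])
  }
  cluster_branch <- stats::setNames(rep(NA_character_, length(cls)), cls)
  cluster_branch[root_cl] <- "stem"
  for (cl in setdiff(cls, root_cl)) {
    lv <- descend_leaves(cl)
    lb <- unique(stats::na.omit(vapply(lv, type_branch, "")))
    cluster_branch[cl] <- if (length(lb) == 1) lb else type_branch(cl)
  }
  labels <- clusters$labels
  cell_branch <- rep(NA_character_, length(labels))
  names(cell_branch) <- names(labels)
  nz <- labels != 0L
  cell_branch[nz] <- cluster_branch[as.character(labels[nz])]
  structure(list(tree = tree, cluster_branch = cluster_branch,
                 cell_branch = cell_branch, root_cluster = root_cl),
            class = "branch_assignment")
}

#' Genes dynamic along pseudotime, per branch
#'
#' Per gene and branch, a natural cubic spline regression (3 df) of
#' expression on pseudotime is compared with the intercept-only model by an
#' F-test, BH-corrected across genes within the branch. Significant genes
#' are classified from the fitted curve: up / down by the sign of the net
#' endpoint change, or transient_up / transient_down when an interior
#' extremum dominates the net change.
#'
#' @param logm log-normalized genes x cells matrix.
#' @param t named pseudotime vector (or a \code{pseudotime_result}).
#' @param branches named per-cell branch labels (NA cells skipped).
#' @param q_threshold BH threshold below which a pattern other than flat
#'   is called.
#' @param df spline degrees of freedom.
#' @param min_cells branches with fewer cells are skipped with a warning.
#' @return data.frame: gene, branch, statistic, p, q, pattern.
#' @export
dynamic_genes <- function(logm, t, branches, q_threshold = 0.05, df = 3,
                          min_cells = 20) {
  if (inherits(t, "pseudotime_result")) t <- t$t
  rows <- list()
  for (b in stats::na.omit(unique(branches))) {
    cells <- names(branches)[!is.na(branches) & branches == b]
    cells <- intersect(cells, colnames(logm))
    if (length(cells) < min_cells) {
      warning("branch ", b, " has fewer than ", min_cells,
              " cells; skipped")
      next
    }
    tb <- t[cells]
    if (max(tb) == min(tb)) stop("degenerate pseudotime in branch ", b)
    basis <- splines::ns(tb, df = df)
    x <- cbind(1, basis)
    qr_x <- qr(x)
    y <- t(logm[, cells, drop = FALSE])
    res1 <- qr.resid(qr_x, y)
    rss1 <- colSums(res1^2)
    rss0 <- colSums(sweep(y, 2, colMeans(y))^2)
    n <- length(cells)
    df_res <- n - ncol(x)
    fstat <- ((rss0 - rss1) / df) / (rss1 / df_res)
    fstat[rss1 == 0 & rss0 == 0] <- 0
    p <- stats::pf(fstat, df, df_res, lower.tail = FALSE)
    p[!is.finite(fstat)] <- 0
    q <- stats::p.adjust(p, method = "BH")
    # fitted curves on a grid for pattern calls
    grid <- seq(min(tb), max(tb), length.out = 50)
    gx <- cbind(1, stats::predict(basis, grid))
    coefs <- qr.coef(qr_x, y)
    fit <- gx %*% coefs
    pattern <- vapply(seq_len(ncol(y)), function(g) {
      if (is.na(q[g]) || q[g] > q_threshold) return("flat")
      f <- fit[, g]
      rngf <- max(f) - min(f)
      if (rngf == 0) return("flat")
      net <- f[length(f)] - f[1]
      tol <- 0.1 * rngf
      over <- max(f) - max(f[1], f[length(f)])
      under <- min(f[1], f[length(f)]) - min(f)
      if (over > tol && over > abs(net)) "transient_up"
      else if (under > tol && under > abs(net)) "transient_down"
      else if (net >= 0) "up" else "down"
    }, "")
    rows[[b]] <- data.frame(gene = rownames(logm), branch = b,
                            statistic = fstat, p = p, q = q,
                            pattern = pattern, row.names = NULL)
  }
  if (!length(rows)) stop("no branch met the minimum cell count")
  do.call(rbind, rows)
}

#' Symmetrized k-nearest-neighbor graph of embedded cells
#'
#' @param emb an \code{embedding} (or cells x d matrix).
#' @param k neighbors per cell.
#' @param n_dims leading columns used.
#' @return 2-column matrix of undirected edges (cell indices).
#' @export
knn_graph <- function(emb, k = 15, n_dims = Inf) {
  pts <- if (inherits(emb, "embedding")) emb$scores else as.matrix(emb)
  pts <- pts[, seq_len(min(n_dims, ncol(pts))), drop = FALSE]
  n <- nrow(pts)
  if (k >= n) k <- n - 1
  dm <- as.matrix(stats::dist(pts))
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ])
    mask[i, ord[ord != i][seq_len(k)]] <- TRUE
  }
  mask <- mask | t(mask)
  which(mask & upper.tri(mask), arr.ind = TRUE)
}
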