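test_that("PCA handles rank-1 data and the rotated-identity toy", {
  # rank-1: one direction carries all variance
  v <- c(1, 2, 3, 4)
  m <- rbind(v, 2 * v)
  dimnames(m) <- list(c("f1", "f2"), paste0("c", 1:4))
  emb <- suppressWarnings(run_pca(m, k = 2))
  expect_gt(emb$explained_variance[1], 0)
  expect_true(length(emb$explained_variance) == 1 ||
                emb$explained_variance[2] < 1e-20)

  # two features varying only along the (1,1)/sqrt(2) direction
  m2 <- rbind(c(0, 1, 2, 3), c(0, 1, 2, 3) + c(0.05, -0.05, 0.05, -0.05))
  dimnames(m2) <- list(c("f1", "f2"), paste0("c", 1:4))
  emb2 <- run_pca(m2, k = 2)
  expect_equal(abs(unname(emb2$loadings[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 0.01)
})

test_that("PCA reproduces a dense eigendecomposition of the covariance", {
  withr::with_seed(7, {
    m <- matrix(rnorm(30 * 20), 30, 20,
                dimnames = list(paste0("f", 1:30), paste0("c", 1:20)))
  })
  emb <- run_pca(m, k = 5)
  x <- scale(t(m), scale = FALSE)
  ev <- eigen(cov(x), symmetric = TRUE)
  expect_equal(emb$explained_variance, ev$values[1:5], tolerance = 1e-8)
  for (j in 1:5)
    expect_equal(abs(sum(emb$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  # loadings orthonormal; explained variance bounded by total variance
  expect_equal(crossprod(emb$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lte(sum(emb$explained_variance), sum(apply(m, 1, var)) + 1e-8)
  # sign convention: largest-magnitude loading entry positive
  for (j in 1:5)
    expect_gt(emb$loadings[which.max(abs(emb$loadings[, j])), j], 0)
})

test_that("DBSCAN separates two blobs and collapses at tiny eps", {
  withr::with_seed(8, {
    pts <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 2),
                 matrix(rnorm(60, 6, 0.3), ncol = 2))
    rownames(pts) <- paste0("c", 1:60)
  })
  cl <- dbscan_cluster(pts, eps = 1.5, min_pts = 4, n_pcs = 2)
  truth <- rep(1:2, each = 30)
  expect_equal(max(cl$labels), 2)
  expect_equal(adjusted_rand(cl$labels, truth), 1)

  all_noise <- suppressMessages(
    dbscan_cluster(pts, eps = 1e-9, min_pts = 4, n_pcs = 2))
  expect_true(all(all_noise$labels == 0))
})

test_that("DBSCAN labels match a naive density-reachability reference", {
  withr::with_seed(9, {
    pts <- matrix(rnorm(50, sd = 2), 25, 2)
    rownames(pts) <- paste0("c", 1:25)
  })
  eps <- 1.2; min_pts <- 3
  cl <- dbscan_cluster(pts, eps = eps, min_pts = min_pts, n_pcs = 2)

  # reference: mark cores, then connected components of the core graph;
  # border points join the cluster of their first core neighbor
  dm <- as.matrix(dist(pts))
  core <- rowSums(dm <= eps) >= min_pts
  ref <- integer(25)
  comp <- 0
  for (i in which(core)) {
    if (ref[i] != 0) next
    comp <- comp + 1
    frontier <- i
    while (length(frontier)) {
      ref[frontier] <- comp
      nxt <- unique(unlist(lapply(frontier, function(j)
        which(core & dm[j, ] <= eps & ref == 0))))
      frontier <- nxt
    }
  }
  for (i in which(!core)) {
    nb_cores <- which(core & dm[i, ] <= eps)
    if (length(nb_cores)) ref[i] <- ref[min(nb_cores)]
  }
  # identical partition up to label names, identical noise set
  expect_identical(unname(cl$labels == 0), ref == 0)
  expect_equal(adjusted_rand(cl$labels[ref != 0], ref[ref != 0]), 1)
})

test_that("DBSCAN partition is stable under input reordering", {
  withr::with_seed(10, {
    pts <- rbind(matrix(rnorm(40, 0, 0.4), ncol = 2),
                 matrix(rnorm(40, 5, 0.4), ncol = 2))
    rownames(pts) <- paste0("c", 1:40)
  })
  cl1 <- dbscan_cluster(pts, eps = 1.5, min_pts = 4, n_pcs = 2)
  perm <- withr::with_seed(2, sample(40))
  cl2 <- dbscan_cluster(pts[perm, ], eps = 1.5, min_pts = 4, n_pcs = 2)
  expect_equal(adjusted_rand(cl1$labels[perm], cl2$labels), 1)
})

test_that("forced markers are found and flat genes are not", {
  m <- toy_logm(10, 24, seed = 55)
  labels <- rep(1:3, each = 8)
  names(labels) <- colnames(m)
  m[1, labels == 1] <- m[1, labels == 1] + 8   # exclusive to cluster 1
  m[2, ] <- 2                                   # identical everywhere
  cl <- structure(list(labels = labels,
                       params = list(eps = 1, min_pts = 3, n_pcs = 2)),
                  class = "cluster_result")
  mk <- cluster_markers(m, cl, min_log_fc = 1, q_max = 0.05)
  top1 <- mk[mk$cluster == 1 & mk$is_marker, ]
  expect_true("g1" %in% top1$gene)
  expect_equal(top1$gene[top1$rank == 1], "g1")
  expect_false(any(mk$is_marker & mk$gene == "g2"))
})

test_that("rank-sum p equals exact enumeration for small untied groups", {
  withr::with_seed(12, {
    x <- round(rnorm(6, 10), 4)
    y <- round(rnorm(8, 9), 4)
  })
  p_pkg <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater")$p.value)
  # package path used by cluster_markers
  m <- rbind(c(x, y))
  rownames(m) <- "g1"; colnames(m) <- paste0("c", 1:14)
  labels <- stats::setNames(rep(c(1L, 2L), c(6, 8)), colnames(m))
  cl <- structure(list(labels = labels, params = list()),
                  class = "cluster_result")
  mk <- cluster_markers(m, cl, min_log_fc = -Inf, q_max = 1)
  expect_equal(mk$p[mk$cluster == 1], p_pkg)
  expect_equal(p_pkg, rank_sum_exact(x, y), tolerance = 1e-12)
})

test_that("hypergeometric assignment matches a hand tail sum", {
  # overlap 3, markers 10, set 20, universe 100
  hand <- sum(vapply(3:10, function(k)
    choose(20, k) * choose(80, 10 - k) / choose(100, 10), 0))
  expect_equal(hspcflow:::hypergeom_tail(3, 10, 20, 100), hand,
               tolerance = 1e-12)

  universe <- paste0("g", 1:1000)
  markers <- data.frame(cluster = 1L, gene = universe[1:15],
                        log_fc = 2, p = 1e-6, q = 1e-5,
                        is_marker = TRUE, rank = 1:15)
  class(markers) <- c("marker_table", "data.frame")
  ref <- list(typeA = universe[1:15], typeB = universe[501:520])
  asg <- assign_celltype(markers, ref, universe)
  expect_identical(asg$type, "typeA")
  expect_lt(asg$p, 1e-10)
})

test_that("increasing overlap at fixed margins never increases p", {
  ps <- vapply(0:10, function(k) hspcflow:::hypergeom_tail(k, 10, 20, 100),
               0)
  expect_true(all(diff(ps) <= 0))
})

test_that("overrepresentation ranks and matches Fisher's exact test", {
  universe <- paste0("g", 1:60)
  coll <- list(full = universe[1:8], other = universe[31:40],
               disjoint = universe[51:60])
  res <- overrepresentation(universe[1:8], universe, coll)
  expect_identical(res$set[1], "full")
  expect_equal(res$p[res$set == "disjoint"], 1)

  # small-count agreement with the one-sided 2x2 Fisher test
  k <- 3; n_genes <- 7; set_size <- 12; N <- 50
  tab <- matrix(c(k, n_genes - k, set_size - k,
                  N - n_genes - set_size + k), 2, 2)
  expect_equal(hspcflow:::hypergeom_tail(k, n_genes, set_size, N),
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_error(overrepresentation(character(), universe, coll), "empty")
})
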