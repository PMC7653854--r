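line_points <- function(n = 40, seed = 26) {
  withr::with_seed(seed, {
    x <- sort(runif(n, 0, 10))
    pts <- cbind(x, rnorm(n, sd = 0.01))
    rownames(pts) <- paste0("c", seq_len(n))
    pts
  })
}

test_that("DC1 is monotone along a one-dimensional line", {
  pts <- line_points()
  demb <- diffusion_map(pts, k_neighbors = 6, n_comps = 3)
  expect_equal(abs(cor(demb$components[, 1], pts[, 1],
                       method = "spearman")), 1)
  expect_true(all(demb$eigenvalues <= 1 & demb$eigenvalues > 0))
  expect_true(all(diff(demb$eigenvalues) <= 1e-12))
})

test_that("duplicate points receive identical embeddings", {
  pts <- line_points(20)
  pts2 <- rbind(pts, dup = pts[5, , drop = FALSE])
  rownames(pts2) <- c(rownames(pts), "dup")
  demb <- diffusion_map(pts2, k_neighbors = 5, n_comps = 2)
  expect_equal(demb$components["dup", ], demb$components["c5", ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("embedding is invariant to translation and rotation of input", {
  pts <- line_points(25)
  demb1 <- diffusion_map(pts, k_neighbors = 5, n_comps = 2)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  pts2 <- pts %*% rot + 100
  rownames(pts2) <- rownames(pts)
  demb2 <- diffusion_map(pts2, k_neighbors = 5, n_comps = 2)
  expect_equal(abs(demb1$components[, 1]), abs(demb2$components[, 1]),
               tolerance = 1e-6)
})

test_that("eigenpairs match a dense construction of the Markov matrix", {
  pts <- line_points(40, seed = 27)
  k <- 6
  demb <- diffusion_map(pts, k_neighbors = k, n_comps = 4)

  # independent dense construction with the documented steps
  dm <- as.matrix(dist(pts))
  n <- nrow(pts)
  mask <- matrix(FALSE, n, n)
  nn_d <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ]); nn <- ord[ord != i][1:k]
    mask[i, nn] <- TRUE
    nn_d[i] <- dm[i, nn[k]]
  }
  mask <- mask | t(mask)
  sigma <- median(nn_d)
  w <- exp(-dm^2 / (2 * sigma^2)); w[!mask] <- 0; diag(w) <- 1
  q <- rowSums(w); w1 <- w / outer(q, q)
  p_mat <- w1 / rowSums(w1)
  ev <- eigen(p_mat)
  expect_equal(demb$eigenvalues, Re(ev$values[2:5]), tolerance = 1e-8)
  for (j in 1:4) {
    a <- demb$components[, j]
    b <- Re(ev$vectors[, j + 1])
    expect_equal(abs(cor(a, b)), 1, tolerance = 1e-6)
  }
})

test_that("a disconnected kNN graph is rejected with advice", {
  pts <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
               matrix(rnorm(20, 50, 0.1), ncol = 2))
  rownames(pts) <- paste0("c", 1:20)
  expect_error(diffusion_map(pts, k_neighbors = 3),
               "increase k_neighbors")
})

test_that("pseudotime anchors at the root and fills [0, 1]", {
  pts <- line_points(30)
  demb <- diffusion_map(pts, k_neighbors = 6, n_comps = 3)
  pt <- pseudotime(demb, "c1")
  expect_equal(unname(pt$t["c1"]), 0)
  expect_equal(max(pt$t), 1)
  expect_equal(min(pt$t), 0)
  # two cells: {0, 1}
  two <- matrix(c(0, 1, 0, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  demb2 <- diffusion_map(two, k_neighbors = 1, n_comps = 2)
  pt2 <- pseudotime(demb2, "a")
  expect_equal(sort(unname(pt2$t)), c(0, 1))
  expect_error(pseudotime(demb, "missing"), "unknown root")
})

test_that("pseudotime rescaling preserves cell ranking", {
  demb <- diffusion_map(line_points(30), k_neighbors = 6, n_comps = 3)
  pt <- pseudotime(demb, "c1")
  sc <- sweep(demb$components[, 1:3], 2, demb$eigenvalues[1:3], "*")
  raw <- sqrt(rowSums((sc - matrix(sc["c1", ], nrow(sc), 3,
                                   byrow = TRUE))^2))
  expect_equal(order(pt$t), order(raw))
})

test_that("connectivity weights match hand arithmetic on a toy graph", {
  # clusters of sizes 2, 2, 3; inter-cluster edges: a-b 2, a-c 1
  labels <- c(1L, 1L, 2L, 2L, 3L, 3L, 3L)
  names(labels) <- paste0("c", 1:7)
  cl <- structure(list(labels = labels, params = list()),
                  class = "cluster_result")
  edges <- rbind(c(1, 3), c(2, 4), c(1, 5), c(6, 7), c(1, 2))
  g <- connectivity_graph(edges, cl)
  # E_total = 3 inter-cluster edges; pair shares: ab 4, ac 6, bc 6 (sum 16)
  expect_equal(g$weights["1", "2"], 2 / (3 * 4 / 16), tolerance = 1e-12)
  expect_equal(g$weights["1", "3"], 1 / (3 * 6 / 16), tolerance = 1e-12)
  expect_equal(g$weights["2", "3"], 0)
  expect_identical(g$weights, t(g$weights))

  # no inter-cluster edges at all -> all weights zero
  g0 <- connectivity_graph(rbind(c(1, 2), c(6, 7)), cl)
  expect_true(all(g0$weights == 0))
})

test_that("branch assignment handles two clusters and breaks ties stably", {
  w <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(1:2, 1:2))
  g <- structure(list(weights = w, n_cells = c(`1` = 3L, `2` = 3L)),
                 class = "connectivity_graph")
  labels <- stats::setNames(rep(c(1L, 2L), each = 3), paste0("c", 1:6))
  cl <- structure(list(labels = labels, params = list()),
                  class = "cluster_result")
  asg <- data.frame(cluster = 1:2, type = c("HSC", "MEP"),
                    overlap = 5L, p = 1e-5, q = 1e-4)
  br <- assign_branches(g, cl, asg, root_type = "HSC")
  expect_equal(nrow(br$tree), 1)
  expect_identical(unname(br$cluster_branch), c("stem", "erythro-MK"))
  expect_identical(unname(br$cell_branch[4]), "erythro-MK")

  # three-cluster tie: equal weights from the root; added in label order
  w3 <- matrix(0.5, 3, 3, dimnames = list(1:3, 1:3)); diag(w3) <- 0
  g3 <- structure(list(weights = w3), class = "connectivity_graph")
  labels3 <- stats::setNames(rep(1:3, each = 2), paste0("c", 1:6))
  cl3 <- structure(list(labels = labels3, params = list()),
                   class = "cluster_result")
  asg3 <- data.frame(cluster = 1:3, type = c("HSC", "MEP", "GMP"),
                     overlap = 5L, p = 1e-5, q = 1e-4)
  br3 <- assign_branches(g3, cl3, asg3, root_type = "HSC")
  expect_identical(br3$tree$from, c("1", "1"))
  expect_identical(br3$tree$to, c("2", "3"))
  expect_error(assign_branches(g3, cl3, asg3, root_type = "CLP"),
               "not assigned")
})

test_that("dynamic gene patterns are detected per branch", {
  withr::with_seed(28, {
    n <- 60
    t <- sort(runif(n))
    names(t) <- paste0("c", 1:n)
    m <- rbind(up = 2 + 3 * t + rnorm(n, sd = 0.3),
               noise = rnorm(n, mean = 3, sd = 0.5),
               peak = 2 + 3 * exp(-((t - 0.5) / 0.15)^2) +
                 rnorm(n, sd = 0.3),
               down = 5 - 3 * t + rnorm(n, sd = 0.3))
    colnames(m) <- names(t)
  })
  branches <- stats::setNames(rep("b1", n), names(t))
  dyn <- dynamic_genes(m, t, branches, q_threshold = 0.05)
  expect_identical(dyn$pattern[dyn$gene == "up"], "up")
  expect_identical(dyn$pattern[dyn$gene == "down"], "down")
  expect_identical(dyn$pattern[dyn$gene == "peak"], "transient_up")
  expect_identical(dyn$pattern[dyn$gene == "noise"], "flat")
  expect_lt(dyn$q[dyn$gene == "up"], 0.01)

  expect_error(dynamic_genes(m, t * 0, branches), "degenerate")
  mixed <- stats::setNames(c(rep("b2", 5), rep("b1", n - 5)), names(t))
  expect_warning(dyn2 <- dynamic_genes(m, t, mixed, min_cells = 20),
                 "fewer than")
  expect_true(all(dyn2$branch == "b1"))
})

test_that("pure-noise genes stay flat in most replicates", {
  withr::with_seed(29, {
    flat_rate <- mean(vapply(1:20, function(r) {
      n <- 50
      t <- sort(runif(n)); names(t) <- paste0("c", 1:n)
      m <- matrix(rnorm(n, 3), 1, n,
                  dimnames = list("noise", names(t)))
      dyn <- dynamic_genes(m, t,
                           stats::setNames(rep("b", n), names(t)),
                           q_threshold = 0.05)
      dyn$pattern == "flat"
    }, TRUE))
  })
  expect_gte(flat_rate, 0.9)
})
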