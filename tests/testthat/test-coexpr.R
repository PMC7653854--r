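test_that("correlation vectors capture duplication and negation", {
  m <- toy_logm(4, 24, seed = 18)
  m[2, ] <- m[1, ]                       # duplicate row
  m[3, ] <- -(m[1, ] - mean(m[1, ]))     # negation after centering
  bl <- stats::setNames(rep(c("b1", "b2"), each = 12), colnames(m))
  cv <- correlation_vectors(m, rownames(m), bl, min_expr_frac = 0)
  expect_equal(unname(cv$rho[, "g1|g2"]), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(cv$rho[, "g1|g3"]), c(-1, -1), tolerance = 1e-12)
})

test_that("pair correlations equal a nested-loop Pearson oracle", {
  m <- toy_logm(4, 24, seed = 19)
  bl <- stats::setNames(rep(c("b1", "b2"), each = 12), colnames(m))
  cv <- correlation_vectors(m, rownames(m), bl, min_expr_frac = 0)
  for (b in c("b1", "b2")) {
    cells <- names(bl)[bl == b]
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(unname(cv$rho[b, paste0("g", i, "|g", j)]),
                   cor(m[i, cells], m[j, cells]), tolerance = 1e-12)
    }
  }
})

test_that("usable-gene filter intersects across branches", {
  m <- toy_logm(5, 30, seed = 20)
  bl <- stats::setNames(rep(c("b1", "b2"), each = 15), colnames(m))
  m[5, bl == "b1"] <- 0  # unusable in b1 only
  cv <- correlation_vectors(m, rownames(m), bl, min_expr_frac = 0.5)
  expect_false("g5" %in% cv$genes)
  expect_equal(length(cv$genes), 4)
  m[3:5, bl == "b1"] <- 0
  expect_error(correlation_vectors(m, rownames(m), bl,
                                   min_expr_frac = 0.5),
               "fewer than 3 usable")
  expect_error(correlation_vectors(m[, 1:12], rownames(m),
                                   stats::setNames(rep(c("b1", "b2"), 6),
                                                   colnames(m)[1:12])),
               "fewer than 10 cells")
})

test_that("dispersion index closed forms hold", {
  rho_same <- rbind(b1 = c(0.5, -0.2, 0.8), b2 = c(0.5, -0.2, 0.8))
  expect_equal(dispersion_index(rho_same), 0)

  rho_pm <- rbind(b1 = 1, b2 = -1)
  expect_equal(dispersion_index(rho_pm), 1)
})

test_that("dispersion index equals the direct-summation oracle", {
  withr::with_seed(21, {
    for (r in 1:10) {
      rho <- matrix(runif(9, -1, 1), 3, 3,
                    dimnames = list(paste0("b", 1:3), NULL))
      expect_equal(dispersion_index(rho), di_oracle(rho),
                   tolerance = 1e-12)
    }
  })
})

test_that("DI is invariant to branch relabeling and gene reordering", {
  m <- toy_logm(5, 36, seed = 22)
  bl <- stats::setNames(rep(c("b1", "b2", "b3"), each = 12), colnames(m))
  di1 <- dispersion_index(correlation_vectors(m, rownames(m), bl,
                                              min_expr_frac = 0))
  bl2 <- stats::setNames(c(b1 = "x", b2 = "y", b3 = "z")[bl], names(bl))
  di2 <- dispersion_index(correlation_vectors(m, rownames(m), bl2,
                                              min_expr_frac = 0))
  expect_equal(di1, di2, tolerance = 1e-12)
  di3 <- dispersion_index(correlation_vectors(m, rev(rownames(m)), bl,
                                              min_expr_frac = 0))
  expect_equal(di1, di3, tolerance = 1e-12)
})

test_that("DI grows when one branch deviates further from the pair mean", {
  base <- rbind(b1 = c(0.2, 0.4), b2 = c(0.2, 0.4), b3 = c(0.4, 0.6))
  d0 <- dispersion_index(base)
  worse <- base; worse["b3", ] <- c(0.6, 0.8)
  expect_gt(dispersion_index(worse), d0)
})

test_that("permutation p is near 1 when branches are identical by construction", {
  m <- toy_logm(4, 30, seed = 23)
  m2 <- cbind(m, m, m)
  colnames(m2) <- paste0("c", seq_len(90))
  bl <- stats::setNames(rep(c("b1", "b2", "b3"), each = 30), colnames(m2))
  r <- permute_di(m2, rownames(m2), bl, n_perm = 100, seed = 1,
                  min_expr_frac = 0)
  expect_equal(r$di, 0, tolerance = 1e-12)
  expect_gt(r$p, 0.95)
})

test_that("permute_di is deterministic given its seed", {
  m <- toy_logm(4, 36, seed = 24)
  bl <- stats::setNames(rep(c("b1", "b2", "b3"), each = 12), colnames(m))
  r1 <- permute_di(m, rownames(m), bl, n_perm = 100, seed = 9,
                   min_expr_frac = 0)
  r2 <- permute_di(m, rownames(m), bl, n_perm = 100, seed = 9,
                   min_expr_frac = 0)
  expect_identical(r1$null_di, r2$null_di)
  expect_true(r1$p >= 1 / 101 && r1$p <= 1)
})

test_that("scan_collection gives q = p for one set and ranks effect sets", {
  m <- toy_logm(6, 36, seed = 25)
  bl <- stats::setNames(rep(c("b1", "b2", "b3"), each = 12), colnames(m))
  tab <- scan_collection(m, list(only = rownames(m)), bl, n_perm = 100,
                         seed = 2, min_expr_frac = 0)
  expect_equal(tab$q, tab$p)

  tab2 <- scan_collection(m, list(ok = rownames(m)[1:4],
                                  tiny = c("g1", "g2")),
                          bl, n_perm = 100, seed = 2, min_expr_frac = 0)
  expect_true(tab2$skipped[tab2$set == "tiny"])
  expect_true(is.na(tab2$q[tab2$set == "tiny"]))
})

test_that("edge classification matches a one-line threshold oracle", {
  rho <- rbind(b1 = c(0.9, 0.9, 0.3), b2 = c(0.9, 0.9, -0.2),
               b3 = c(0.85, -0.9, 0.1))
  colnames(rho) <- c("g1|g2", "g1|g3", "g2|g3")
  cv <- structure(list(rho = rho,
                       pairs = data.frame(gene_i = c("g1", "g1", "g2"),
                                          gene_j = c("g2", "g3", "g3")),
                       genes = c("g1", "g2", "g3")),
                  class = "correlation_vectors")
  ec <- classify_edges(cv, delta = 0.5)
  oracle <- ifelse(apply(rho, 2, max) - apply(rho, 2, min) > 0.5,
                   "altered", "conserved")
  expect_identical(ec$class, unname(oracle))
  expect_identical(ec$class, c("conserved", "altered", "conserved"))
})
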