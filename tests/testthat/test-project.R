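test_that("the 50 kb rule is strict and overlap counts as gap zero", {
  ann <- crafted_annotation()
  pairs <- neighbor_pairs(ann, list(M = "modA"), max_gap = 50000)
  expect_true("lnc_overlap" %in% pairs$lncRNA_id)
  expect_equal(pairs$gap_bp[pairs$lncRNA_id == "lnc_overlap"], 0)
  expect_equal(pairs$gap_bp[pairs$lncRNA_id == "lnc_adjacent"], 0)
  expect_true("lnc_49999" %in% pairs$lncRNA_id)
  expect_equal(pairs$gap_bp[pairs$lncRNA_id == "lnc_49999"], 49999)
  expect_false("lnc_50000" %in% pairs$lncRNA_id)
  expect_false("lnc_far" %in% pairs$lncRNA_id)
  expect_false("lnc_otherchrom" %in% pairs$lncRNA_id)
})

test_that("pair set equals an exhaustive interval-gap oracle", {
  ds <- memo("small_ds", simulate_hspc(
    sim_params(n_cells = 60L, n_coding_genes = 500L, n_lncrna = 40L,
               module_size = 20L, seed = 6L)))
  ann <- ds$annotation
  modules <- ds$truth$gene_sets[ds$params$cluster_names]
  pairs <- neighbor_pairs(ann, modules, max_gap = 50000)

  oracle <- list()
  lnc <- ann[ann$biotype == "lncRNA", ]
  for (m in names(modules)) {
    for (g in intersect(modules[[m]], ann$gene_id)) {
      for (i in seq_len(nrow(lnc))) {
        if (lnc$chrom[i] != ann[g, "chrom"]) next
        gap <- max(max(lnc$start[i], ann[g, "start"]) -
                     min(lnc$end[i], ann[g, "end"]), 0)
        if (gap < 50000)
          oracle[[length(oracle) + 1]] <-
            paste(lnc$gene_id[i], g, m, gap)
      }
    }
  }
  got <- paste(pairs$lncRNA_id, pairs$partner, pairs$module, pairs$gap_bp)
  expect_setequal(got, unlist(oracle))
})

test_that("neighbor pairing is invariant to chromosome renaming", {
  ann <- crafted_annotation()
  ann2 <- ann
  ann2$chrom <- paste0("renamed_", ann2$chrom)
  p1 <- neighbor_pairs(ann, list(M = "modA"))
  p2 <- neighbor_pairs(ann2, list(M = "modA"))
  expect_identical(p1$lncRNA_id, p2$lncRNA_id)
  expect_identical(p1$gap_bp, p2$gap_bp)
  expect_warning(neighbor_pairs(ann, list(M = c("modA", "ghost"))),
                 "absent")
})

test_that("module loading projections call obvious directions", {
  loadings <- cbind(PC1 = c(seq(0.1, 0.17, 0.01),
                            seq(-0.2, 0.2, length.out = 8)),
                    PC2 = c(seq(-0.17, -0.1, 0.01), rep(0.05, 8)))
  rownames(loadings) <- paste0("f", 1:16)
  emb <- structure(list(scores = matrix(0, 2, 2), loadings = loadings,
                        explained_variance = c(2, 1)),
                   class = "embedding")
  mods <- list(pos = paste0("f", 1:8), sym = paste0("f", 9:16))
  pr <- project_modules(emb, mods, axes = 1:2, q_threshold = 0.05)
  expect_identical(pr$direction[pr$module == "pos" & pr$axis == 1],
                   "positive")
  expect_identical(pr$direction[pr$module == "pos" & pr$axis == 2],
                   "negative")
  expect_identical(pr$direction[pr$module == "sym" & pr$axis == 1],
                   "none")
  # minimal exact p at n = 8, all same sign
  expect_equal(pr$p[pr$module == "pos" & pr$axis == 1], 2 / 256,
               tolerance = 1e-12)
})

test_that("signed-rank p at n = 6 equals exact enumeration", {
  withr::with_seed(30, {
    for (r in 1:5) {
      x <- round(rnorm(6, 0.2, 1), 4)
      x <- x[x != 0]
      p_pkg <- hspcflow:::signed_rank_p(x)
      expect_equal(p_pkg, signed_rank_exact(x), tolerance = 1e-12)
    }
  })
})

test_that("directions flip when an axis is negated", {
  withr::with_seed(31, {
    loadings <- cbind(PC1 = c(rnorm(10, 0.15, 0.05), rnorm(10, 0, 0.2)))
  })
  rownames(loadings) <- paste0("f", 1:20)
  emb <- structure(list(scores = NULL, loadings = loadings,
                        explained_variance = 1), class = "embedding")
  emb_neg <- emb; emb_neg$loadings <- -emb$loadings
  mods <- list(m = paste0("f", 1:10))
  d1 <- project_modules(emb, mods, axes = 1)$direction
  d2 <- project_modules(emb_neg, mods, axes = 1)$direction
  expect_identical(d1, "positive")
  expect_identical(d2, "negative")
})

test_that("small modules are untestable and excluded from correction", {
  loadings <- cbind(PC1 = rnorm(10))
  rownames(loadings) <- paste0("f", 1:10)
  emb <- structure(list(loadings = loadings, explained_variance = 1),
                   class = "embedding")
  pr <- project_modules(emb, list(tiny = c("f1", "f2"),
                                  ok = paste0("f", 1:10)), axes = 1)
  expect_false(pr$testable[pr$module == "tiny"])
  expect_true(is.na(pr$q[pr$module == "tiny"]))
  expect_equal(pr$q[pr$module == "ok"], pr$p[pr$module == "ok"])
})

test_that("lncRNA PCA separates the main truth branches on a leading axis", {
  ds <- default_ds()
  lemb <- lncrna_pca(default_logm(), ds$annotation, k = 5)
  br <- ds$truth$cells$branch
  keep <- br %in% c("erythro-MK", "lymphoid")
  # AUC of PC1 scores for erythro-MK vs lymphoid cells
  sc <- lemb$scores[keep, 1]
  lab <- br[keep] == "erythro-MK"
  auc <- mean(outer(sc[lab], sc[!lab], ">")) +
    0.5 * mean(outer(sc[lab], sc[!lab], "=="))
  expect_gte(max(auc, 1 - auc), 0.8)
})

test_that("ATAC projection handles degenerate and single-module input", {
  tf <- matrix(1, 5, 10, dimnames = list(paste0("T", 1:5),
                                         paste0("c", 1:10)))
  expect_error(atac_project(tf, list(m = paste0("T", 1:5))), "constant")

  withr::with_seed(32, {
    tf2 <- matrix(rnorm(200), 10, 20,
                  dimnames = list(paste0("T", 1:10), paste0("c", 1:20)))
  })
  res <- atac_project(tf2, list(m = paste0("T", 1:10)), axes = 1)
  expect_equal(res$projection$q, res$projection$p)
  expect_error(atac_project(tf2, list(m = c("X1", "X2"))), "no TF maps")
})
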