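# Shared fixtures and independent oracles. Heavy objects (the default
# synthetic dataset and the pipeline stages computed from it) are built
# once per test run and memoized.

.cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

default_ds <- function() memo("ds", simulate_hspc(sim_params()))

default_logm <- function() memo("logm", normalize_log(default_ds()$counts))

default_emb <- function() memo("emb", {
  logm <- default_logm()
  hvg <- select_hvg(logm)
  run_pca(scale_clip(logm[hvg$selected, , drop = FALSE]), k = 10)
})

default_clusters <- function() memo("clusters", dbscan_cluster(default_emb()))

default_markers <- function()
  memo("markers", cluster_markers(default_logm(), default_clusters()))

default_assignment <- function() memo("assignment", {
  logm <- default_logm()
  universe <- rownames(logm)[rowSums(logm > 0) >= 3]
  assign_celltype(default_markers(),
                  default_ds()$truth$gene_sets[default_ds()$params$cluster_names],
                  universe)
})

default_diffusion <- function()
  memo("diffusion", diffusion_map(default_emb(), k_neighbors = 30))

default_pt <- function() memo("pt", {
  root <- select_root(default_logm(), default_ds()$truth$gene_sets$HSC)
  pseudotime(default_diffusion(), root)
})

default_branches <- function() memo("branches", {
  cla <- absorb_noise(default_clusters(), default_emb())
  graph <- connectivity_graph(default_diffusion()$knn_edges, cla)
  assign_branches(graph, cla, default_assignment())
})

# small deterministic log-matrix fixture: g genes x n cells
toy_logm <- function(g = 6, n = 12, seed = 99) {
  withr::with_seed(seed, {
    m <- matrix(abs(rnorm(g * n, mean = 4)), g, n)
    dimnames(m) <- list(paste0("g", seq_len(g)), paste0("c", seq_len(n)))
    m
  })
}

# adjusted Rand index between two label vectors (direct contingency form)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# independent running-sum enrichment oracle: explicit position loop
es_oracle <- function(metric, hit, weight) {
  n <- length(metric)
  nh <- sum(hit)
  w <- abs(metric)^weight
  denom <- sum(w[hit])
  rs <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) {
      if (denom > 0) w[i] / denom else 1 / nh
    } else {
      -1 / (n - nh)
    }
    rs[i] <- cur
  }
  rs[which.max(abs(rs))]
}

# independent dispersion-index oracle: explicit double loop over pairs and
# branches
di_oracle <- function(rho) {
  total <- 0
  for (j in seq_len(ncol(rho))) {
    mu <- mean(rho[, j])
    total <- total + mean((rho[, j] - mu)^2)
  }
  sqrt(total / ncol(rho))
}

# exact one-sided rank-sum p by enumeration of all group assignments
rank_sum_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  obs <- sum(rank(pooled)[seq_len(n)])
  idx <- utils::combn(length(pooled), n)
  stats <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
  mean(stats >= obs)
}

# exact two-sided signed-rank p by enumeration of all sign assignments
signed_rank_exact <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  stats <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  mu <- n * (n + 1) / 4
  mean(abs(stats - mu) >= abs(obs - mu))
}

crafted_annotation <- function() {
  # one chromosome; module gene at [10000, 20000); lncRNAs at exact gaps
  rows <- data.frame(
    gene_id = c("modA", "modB",
                "lnc_overlap", "lnc_49999", "lnc_50000", "lnc_far",
                "lnc_otherchrom", "lnc_adjacent"),
    symbol = c("modA", "modB", "lnc_overlap", "lnc_49999", "lnc_50000",
               "lnc_far", "lnc_otherchrom", "lnc_adjacent"),
    chrom = c("chr1", "chr2", "chr1", "chr1", "chr1", "chr1", "chr3",
              "chr1"),
    start = c(10000, 10000, 15000, 69999, 70000, 500000, 15000, 20000),
    end = c(20000, 20000, 16000, 71000, 71500, 501000, 16000, 21000),
    strand = "+",
    biotype = c("coding", "coding", rep("lncRNA", 6)))
  gene_annotation(rows)
}

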