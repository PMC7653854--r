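# Synthetic branching-hematopoiesis generator.
#
# Emulates a Smart-seq-style HSPC experiment: ~391 cells drawn from six
# clusters (HSC, MLP, MEP, GMP, ProB, ETP) arranged on a tree rooted at HSC,
# with a latent differentiation time per cell, lineage-specific gene modules
# that ramp up along each branch, cell-cycle programs stronger in the
# CD38pos compartment, a quiescence program that decays with
# differentiation, designated gene sets with branch-specific pair
# correlations induced through a Gaussian copula over negative-binomial
# marginals, lncRNAs placed within 50 kb of module genes and co-expressed
# with them, and a TF motif-accessibility score matrix tracking lineage.
# Full ground truth is returned so every downstream stage can be scored.

#' Parameters of the synthetic HSPC simulator
#'
#' @param n_cells total number of cells (default 391, the size of a typical
#'   sorted CD34+ HSPC experiment on the C1 platform).
#' @param cluster_names cluster labels; the first entry is the tree root.
#' @param topology data.frame with columns \code{from}, \code{to}; must form
#'   a tree rooted at the first cluster name.
#' @param cluster_sizes optional integer vector (same order as
#'   \code{cluster_names}) summing to \code{n_cells}; default near-uniform.
#' @param n_coding_genes,n_lncrna gene counts for the two biotypes.
#' @param module_size genes per lineage module.
#' @param module_effect named log2 fold elevation of each cluster's module in
#'   its own cells; the erythro-megakaryocytic module is strongest by
#'   default, mirroring the dominance of the erythroid program.
#' @param ramp_frac fraction of the module effect that ramps with progress
#'   through the cluster's time interval (the rest is a step at entry).
#' @param prime_coef multilineage priming: fraction of a child module's
#'   effect already expressed in late cells of the parent cluster.
#' @param prime_exp exponent of the priming onset curve (higher = priming
#'   confined closer to the cluster boundary).
#' @param cc_effect log2 elevation of S-phase / G2M-phase gene sets in cells
#'   of the matching phase.
#' @param quiescence_effect log2 elevation of the quiescence set at latent
#'   time 0, decaying linearly to 0 at time 1.
#' @param maturation_effect log2 elevation of a global maturation program
#'   rising linearly with latent time (the continuum axis the diffusion
#'   map reads in every branch).
#' @param coexpr_effect named list: for each designated co-expression gene
#'   set, a named numeric vector of target within-branch pair correlations
#'   (names = branch labels; entries in (-1, 1)). Targets are what the
#'   generated counts should show empirically; the latent copula correlation
#'   is calibrated upward to compensate for NB + dropout attenuation.
#' @param coexpr_set_size genes per designated co-expression set.
#' @param dropout_rate dropout probability at zero expression; the
#'   per-entry probability decays with the count (rate * exp(-count/10)),
#'   emulating the expression dependence of dropout in full-length
#'   chemistry.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param neighbor_fraction fraction of lncRNAs placed < 50 kb from a module
#'   gene and co-expressed with it.
#' @param lnc_coef scaling of the partner module's activation inherited by a
#'   neighbor lncRNA.
#' @param compartment_quantile cells with latent time above this quantile are
#'   labelled CD38pos (emulating the enrichment of the FACS gate, not the
#'   gating itself).
#' @param n_donors donors assigned round-robin (metadata only).
#' @param seed integer seed; fixed seed gives byte-identical datasets.
#' @return a list of class \code{sim_params}.
#' @export
sim_params <- function(n_cells = 391L,
                       cluster_names = c("HSC", "MLP", "MEP", "GMP",
                                         "ProB", "ETP"),
                       topology = data.frame(
                         from = c("HSC", "HSC", "MLP", "MLP", "MLP"),
                         to = c("MEP", "MLP", "GMP", "ProB", "ETP")),
                       cluster_sizes = NULL,
                       n_coding_genes = 1000L,
                       n_lncrna = 120L,
                       module_size = 40L,
                       module_effect = NULL,
                       ramp_frac = 0.5,
                       prime_coef = 0.35,
                       prime_exp = 3,
                       cc_effect = 2.5,
                       quiescence_effect = 5,
                       maturation_effect = 5,
                       coexpr_effect = list(
                         COEXPR_DIFF = c("erythro-MK" = 0.6, "lymphoid" = 0,
                                         "granulo-mono" = 0, stem = 0),
                         COEXPR_CONS = c("erythro-MK" = 0.3, "lymphoid" = 0.3,
                                         "granulo-mono" = 0.3, stem = 0.3)),
                       coexpr_set_size = 10L,
                       dropout_rate = 0.05,
                       nb_dispersion = 0.4,
                       neighbor_fraction = 0.7,
                       lnc_coef = 0.8,
                       compartment_quantile = 0.35,
                       n_donors = 4L,
                       seed = 1L) {
  if (is.null(module_effect)) {
    # lineage-restricted markers are near-off outside their lineage, so
    # own-cluster elevations of 16-32x are the realistic regime
    module_effect <- stats::setNames(rep(6.5, length(cluster_names)),
                                     cluster_names)
    module_effect[cluster_names[1]] <- 6
    if ("MEP" %in% cluster_names) module_effect["MEP"] <- 7
  }
  p <- list(n_cells = as.integer(n_cells),
            n_clusters = length(cluster_names),
            cluster_names = cluster_names, topology = topology,
            cluster_sizes = cluster_sizes,
            n_coding_genes = as.integer(n_coding_genes),
            n_lncrna = as.integer(n_lncrna),
            module_size = as.integer(module_size),
            module_effect = module_effect, ramp_frac = ramp_frac,
            prime_coef = prime_coef, prime_exp = prime_exp,
            cc_effect = cc_effect,
            quiescence_effect = quiescence_effect,
            maturation_effect = maturation_effect,
            coexpr_effect = coexpr_effect,
            coexpr_set_size = as.integer(coexpr_set_size),
            dropout_rate = dropout_rate, nb_dispersion = nb_dispersion,
            neighbor_fraction = neighbor_fraction, lnc_coef = lnc_coef,
            compartment_quantile = compartment_quantile,
            n_donors = as.integer(n_donors), seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (p$n_cells < 1) stop("n_cells must be at least 1")
  if (anyDuplicated(p$cluster_names)) stop("duplicate cluster names")
  check_tree(p$topology, p$cluster_names)
  n_cc <- 200L  # S + G2M + quiescence + maturation programs
  n_coexpr <- length(p$coexpr_effect) * p$coexpr_set_size
  if (p$module_size * p$n_clusters + n_cc + n_coexpr > p$n_coding_genes)
    stop("module_size x n_clusters plus reserved programs exceeds ",
         "n_coding_genes")
  if (!is.null(p$cluster_sizes)) {
    if (length(p$cluster_sizes) != p$n_clusters ||
        sum(p$cluster_sizes) != p$n_cells)
      stop("cluster_sizes must match cluster_names and sum to n_cells")
  }
  for (s in names(p$coexpr_effect)) {
    tg <- p$coexpr_effect[[s]]
    if (any(tg <= -1 | tg >= 1))
      stop("co-expression targets must lie in (-1, 1): set ", s)
  }
  if (p$dropout_rate < 0 || p$dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]")
  if (p$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  invisible(p)
}

check_tree <- function(topology, cluster_names) {
  root <- cluster_names[1]
  if (!all(c(topology$from, topology$to) %in% cluster_names))
    stop("topology mentions unknown clusters")
  if (nrow(topology) != length(cluster_names) - 1)
    stop("topology is not a tree (wrong edge count)")
  if (anyDuplicated(topology$to) || root %in% topology$to)
    stop("topology is not a tree rooted at ", root)
  # every cluster reachable from the root
  reached <- root
  repeat {
    nxt <- topology$to[topology$from %in% reached &
                         !(topology$to %in% reached)]
    if (!length(nxt)) break
    reached <- c(reached, nxt)
  }
  if (!setequal(reached, cluster_names))
    stop("topology is not a connected tree rooted at ", root)
  invisible(TRUE)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65537 * 48271 + k * 8191) %% 2147483647L)
}

# depth of each cluster below the root
cluster_depths <- function(p) {
  d <- stats::setNames(rep(NA_integer_, p$n_clusters), p$cluster_names)
  d[p$cluster_names[1]] <- 0L
  while (anyNA(d)) {
    for (i in seq_len(nrow(p$topology))) {
      fr <- p$topology$from[i]; to <- p$topology$to[i]
      if (!is.na(d[fr]) && is.na(d[to])) d[to] <- d[fr] + 1L
    }
  }
  d
}

# latent-time interval occupied by each cluster; leaves extend to 1 so every
# terminal lineage spans the late trajectory
cluster_intervals <- function(p) {
  d <- cluster_depths(p)
  leaves <- setdiff(p$cluster_names, p$topology$from)
  # geometric segment boundaries leave every leaf a long maturation span;
  # a small margin between consecutive segments makes the global
  # maturation gradient itself separate adjacent populations
  bound <- function(k) 0.7 * (1 - 0.5^k)
  lo <- vapply(d, bound, 0)
  hi <- ifelse(p$cluster_names %in% leaves, 1,
               vapply(d + 1, bound, 0))
  width <- hi - lo
  is_root <- p$cluster_names == p$cluster_names[1]
  is_leaf <- p$cluster_names %in% leaves
  lo <- ifelse(is_root, lo, lo + 0.12 * width)
  hi <- ifelse(is_leaf, hi, hi - 0.12 * width)
  data.frame(cluster = p$cluster_names, lo = lo, hi = hi,
             row.names = p$cluster_names)
}

#' Branch label of each cluster
#'
#' Canonical hematopoietic names map to \code{stem}, \code{erythro-MK},
#' \code{lymphoid}, \code{granulo-mono}; for other cluster vocabularies the
#' root maps to \code{stem} and every other cluster to the alphabetically
#' first leaf of its subtree.
#'
#' @param p a \code{sim_params}.
#' @return named character vector, one branch label per cluster.
#' @export
cluster_branch_map <- function(p) {
  canon <- c(HSC = "stem", MLP = "lymphoid", MEP = "erythro-MK",
             GMP = "granulo-mono", ProB = "lymphoid", ETP = "lymphoid")
  if (all(p$cluster_names %in% names(canon)))
    return(canon[p$cluster_names])
  leaves <- setdiff(p$cluster_names, p$topology$from)
  below <- function(cl) {
    reach <- cl
    repeat {
      nxt <- p$topology$to[p$topology$from %in% reach &
                             !(p$topology$to %in% reach)]
      if (!length(nxt)) break
      reach <- c(reach, nxt)
    }
    sort(intersect(reach, leaves))[1]
  }
  out <- vapply(p$cluster_names, below, "")
  out[p$cluster_names[1]] <- "stem"
  out
}

# Deterministic gene architecture: ids, classes, module membership, baseline
# log2 means. Uses a derived seed so make_annotation() and simulate_hspc()
# agree when called independently.
gene_architecture <- function(p) {
  ids <- sprintf("G%04d", seq_len(p$n_coding_genes))
  class <- rep("background", p$n_coding_genes)
  module <- rep(NA_character_, p$n_coding_genes)
  i <- 1L
  for (cl in p$cluster_names) {
    idx <- i:(i + p$module_size - 1L)
    class[idx] <- "module"; module[idx] <- cl
    i <- i + p$module_size
  }
  for (nm in c("phase_S", "phase_G2M", "quiescence", "maturation")) {
    idx <- i:(i + 49L)
    class[idx] <- nm
    i <- i + 50L
  }
  for (s in names(p$coexpr_effect)) {
    idx <- i:(i + p$coexpr_set_size - 1L)
    class[idx] <- "coexpr"; module[idx] <- s
    i <- i + p$coexpr_set_size
  }
  class[class == "background"][] <- "background"
  lnc_ids <- sprintf("LNC%04d", seq_len(p$n_lncrna))
  n_nb <- round(p$neighbor_fraction * p$n_lncrna)
  nb_module <- rep(p$cluster_names, length.out = n_nb)
  if (n_nb > p$n_clusters * p$module_size)
    stop("more neighbor lncRNAs than module genes to pair with")
  # partner = j-th gene of the module for the j-th neighbor of that module
  partner <- rep(NA_character_, p$n_lncrna)
  for (cl in p$cluster_names) {
    which_nb <- which(nb_module == cl)
    partner[which_nb] <- ids[class == "module" & !is.na(module) &
                               module == cl][seq_along(which_nb)]
  }
  lnc_module <- c(nb_module, rep(NA_character_, p$n_lncrna - n_nb))
  base <- withr::with_seed(derive_seed(p$seed, 1L), {
    # broad log-normal-like baseline with a long low tail, so mean bins
    # are populated by unremarkable genes at every expression level
    b <- stats::rnorm(p$n_coding_genes, mean = 2.5, sd = 1.5)
    b <- pmin(pmax(b, -2), 6)
    # an abundant housekeeping stratum (ribosomal-like), populating the
    # high-expression bins that background matching draws from
    hk <- which(class == "background")[seq_len(min(150L,
      sum(class == "background")))]
    b[hk] <- pmin(pmax(stats::rnorm(length(hk), 5.8, 0.5), 4.8), 6.6)
    # lineage-restricted markers are near-silent outside their lineage
    b[class == "module"] <- stats::rnorm(sum(class == "module"),
                                         mean = -1.5, sd = 0.5)
    # cycle and quiescence programs are broadly expressed, modulated genes
    # cycle programs: abundant transcripts read without detection noise,
    # placed in a top expression stratum shared only with housekeeping
    # genes so their matched background is free of trajectory drift
    ph <- class %in% c("phase_S", "phase_G2M")
    b[ph] <- pmin(pmax(stats::rnorm(sum(ph), 5.8, 0.3), 5.4), 6.4)
    # trajectory programs sit below the cycle stratum even after their
    # time-dependent elevation, keeping the matched background static
    qu <- class %in% c("quiescence", "maturation")
    b[qu] <- pmin(pmax(stats::rnorm(sum(qu), 2, 0.4), 1.3), 2.8)
    b[class == "coexpr"] <- 4.5  # well expressed so correlation survives
    bl <- pmax(stats::rnorm(p$n_lncrna, mean = 1, sd = 0.4), 0.2)
    list(coding = b, lnc = bl)
  })
  list(coding = data.frame(gene_id = ids, class = class, module = module,
                           base_log2 = base$coding,
                           stringsAsFactors = FALSE),
       lnc = data.frame(gene_id = lnc_ids,
                        class = ifelse(is.na(lnc_module), "lnc_far",
                                       "lnc_neighbor"),
                        module = lnc_module, partner = partner,
                        base_log2 = base$lnc, stringsAsFactors = FALSE))
}

#' Synthetic gene annotation
#'
#' Places each lineage module on its own synthetic chromosome with
#' non-overlapping, well-separated intervals; neighbor lncRNAs are placed at
#' a gap drawn uniformly below 50,000 bases from their partner module gene,
#' remaining lncRNAs and all non-module coding genes go to a shared far
#' chromosome more than 50 kb apart. Coordinates are 0-based half-open.
#'
#' @param p a \code{\link{sim_params}}.
#' @return a \code{\link{gene_annotation}}.
#' @export
make_annotation <- function(p) {
  validate_sim_params(p)
  arch <- gene_architecture(p)
  coding <- arch$coding; lnc <- arch$lnc
  rows <- list()
  for (cl in p$cluster_names) {
    g <- coding$gene_id[coding$class == "module" & !is.na(coding$module) &
                          coding$module == cl]
    rows[[cl]] <- data.frame(
      gene_id = g, symbol = g, chrom = paste0("chr_", cl),
      start = (seq_along(g) - 1) * 200000, end = (seq_along(g) - 1) *
        200000 + 10000, strand = "+", biotype = "coding")
  }
  far <- coding$gene_id[coding$class != "module" | is.na(coding$module)]
  gaps <- withr::with_seed(derive_seed(p$seed, 2L),
                           floor(stats::runif(nrow(lnc), 0, 50000)))
  nb <- lnc$class == "lnc_neighbor"
  mod_rows <- do.call(rbind, rows)
  lnc_df <- lnc
  lnc_df$start <- NA_real_; lnc_df$end <- NA_real_; lnc_df$chrom <- NA
  if (any(nb)) {
    pe <- mod_rows$end[match(lnc_df$partner[nb], mod_rows$gene_id)]
    lnc_df$chrom[nb] <- paste0("chr_", lnc_df$module[nb])
    lnc_df$start[nb] <- pe + gaps[nb]
    lnc_df$end[nb] <- lnc_df$start[nb] + 2000
  }
  n_far_items <- length(far) + sum(!nb)
  far_starts <- (seq_len(n_far_items) - 1) * 200000
  far_coding <- data.frame(
    gene_id = far, symbol = far, chrom = "chr_far",
    start = far_starts[seq_along(far)],
    end = far_starts[seq_along(far)] + 10000,
    strand = "+", biotype = "coding")
  if (any(!nb)) {
    idx <- length(far) + seq_len(sum(!nb))
    lnc_df$chrom[!nb] <- "chr_far"
    lnc_df$start[!nb] <- far_starts[idx]
    lnc_df$end[!nb] <- far_starts[idx] + 2000
  }
  lnc_rows <- data.frame(gene_id = lnc_df$gene_id, symbol = lnc_df$gene_id,
                         chrom = lnc_df$chrom, start = lnc_df$start,
                         end = lnc_df$end, strand = "+", biotype = "lncRNA")
  gene_annotation(rbind(mod_rows, far_coding, lnc_rows))
}

# activation in [0, 1] of module `m` in each cell, given cluster, latent
# time t and within-cluster progress z. Own cells: step at cluster entry
# plus a ramp with progress; the parent's late cells prime the module
# (anticipatory, rising), the children's early cells retain it (inherited,
# decaying) -- multilineage priming with continuity across boundaries.
module_activation <- function(m, p, cluster, t, z) {
  a <- numeric(length(t))
  own <- cluster == m
  if (m == p$cluster_names[1]) {
    # stem identity program: maximal in the most primitive cells and
    # declining with progress, so the root cell sits at latent time 0
    a[own] <- 1 - p$ramp_frac * z[own]
  } else {
    a[own] <- (1 - p$ramp_frac) + p$ramp_frac * z[own]
  }
  par <- p$topology$from[p$topology$to == m]
  if (length(par)) {
    pc <- cluster == par
    a[pc] <- p$prime_coef * z[pc]^p$prime_exp
  }
  for (ch in p$topology$to[p$topology$from == m]) {
    cc <- cluster == ch
    a[cc] <- p$prime_coef * (1 - z[cc])^p$prime_exp
  }
  a
}

# Monte-Carlo attenuation of a latent Gaussian-copula correlation after the
# NB quantile transform and Bernoulli dropout; used to calibrate the latent
# correlation so the generated counts hit the requested Pearson target.
# observed log-scale Pearson correlation of an NB + dropout pair generated
# at a given latent copula correlation (Monte-Carlo)
copula_observed <- function(rho_lat, size, mu, dropout, seed,
                            cpm_scale = 1, n = 20000) {
  withr::with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho_lat * z1 + sqrt(1 - rho_lat^2) * stats::rnorm(n)
    x1 <- stats::qnbinom(stats::pnorm(z1), size = size, mu = mu)
    x2 <- stats::qnbinom(stats::pnorm(z2), size = size, mu = mu)
    if (dropout > 0) {
      x1[stats::runif(n) < dropout * exp(-x1 / 10)] <- 0
      x2[stats::runif(n) < dropout * exp(-x2 / 10)] <- 0
    }
    # downstream correlations are computed on log2(CPM + 1); the library
    # scale factor controls how far a zero sits from detected values
    stats::cor(log2(x1 * cpm_scale + 1), log2(x2 * cpm_scale + 1))
  })
}

# latent copula correlation whose generated counts hit the requested
# Pearson target on the log scale: one attenuation estimate followed by
# two fixed-point refinements
calibrate_latent <- function(target, size, mu, dropout, seed,
                             cpm_scale = 1) {
  if (target == 0) return(0)
  clamp <- function(x) max(min(x, 0.995), -0.995)
  att <- copula_observed(0.7, size, mu, dropout, seed, cpm_scale) / 0.7
  lat <- clamp(target / att)
  for (i in 1:2) {
    obs <- copula_observed(lat, size, mu, dropout, seed + i, cpm_scale)
    if (abs(obs) > 1e-8) lat <- clamp(lat * target / obs)
  }
  lat
}

# counts for one designated co-expression set in one group of cells:
# equicorrelated Gaussian copula -> NB quantiles (dropout applied globally
# later)
copula_counts <- function(mu_genes, size, rho_latent, n_cells) {
  m <- length(mu_genes)
  if (rho_latent == 0) {
    z <- matrix(stats::rnorm(m * n_cells), m, n_cells)
  } else {
    sigma <- matrix(rho_latent, m, m); diag(sigma) <- 1
    ch <- tryCatch(chol(sigma),
                   error = function(e) stop("co-expression target too ",
                                            "negative for set size ", m))
    z <- t(ch) %*% matrix(stats::rnorm(m * n_cells), m, n_cells)
  }
  u <- stats::pnorm(z)
  matrix(stats::qnbinom(u, size = size, mu = rep(mu_genes, n_cells)),
         m, n_cells)
}

#' Simulate a synthetic branching-hematopoiesis dataset
#'
#' See \code{\link{sim_params}} for the generative model. Deterministic for
#' a fixed seed.
#'
#' @param p a \code{\link{sim_params}}.
#' @return a list of class \code{synthetic_dataset} with elements
#'   \code{counts} (a \code{\link{count_matrix}}, coding + lncRNA rows),
#'   \code{annotation}, \code{atac} (TFs x cells score matrix), and
#'   \code{truth} (per-cell table, per-gene table, truth gene sets, branch
#'   targets, lncRNA neighbor pairs).
#' @export
simulate_hspc <- function(p) {
  validate_sim_params(p)
  arch <- gene_architecture(p)
  ann <- make_annotation(p)
  iv <- cluster_intervals(p)
  bmap <- cluster_branch_map(p)
  sizes <- p$cluster_sizes
  if (is.null(sizes)) {
    sizes <- rep(p$n_cells %/% p$n_clusters, p$n_clusters)
    extra <- p$n_cells - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  names(sizes) <- p$cluster_names
  cluster <- rep(p$cluster_names, sizes)
  n <- p$n_cells
  cell_ids <- sprintf("cell%03d", seq_len(n))
  size_nb <- 1 / p$nb_dispersion

  withr::with_seed(p$seed, {
    # latent time: mildly concentrated within the cluster interval; the
    # sparse boundary cells bridge adjacent clusters in the kNN graph while
    # falling below DBSCAN's core density (the 'undefined' cells)
    z <- stats::rbeta(n, 1.5, 1.5)
    t <- iv[cluster, "lo"] + z * (iv[cluster, "hi"] - iv[cluster, "lo"])
    thr <- stats::quantile(t, p$compartment_quantile, names = FALSE)
    compartment <- ifelse(t > thr, "CD38pos", "CD38neg")
    phase_probs <- rbind(CD38neg = c(0.85, 0.09, 0.06),
                         CD38pos = c(0.40, 0.35, 0.25))
    phase <- vapply(seq_len(n), function(i)
      sample(c("G0/G1", "S", "G2/M"), 1,
             prob = phase_probs[compartment[i], ]), "")
    # cycling cells occupy a continuum of program intensity (entry into a
    # phase is gradual), so cycling cells chain back to their lineage
    # cluster instead of forming detached density blobs
    cc_amp <- ifelse(phase == "G0/G1", 0, stats::rbeta(n, 2, 1))
    donor <- paste0("D", rep_len(seq_len(p$n_donors), n))

    coding <- arch$coding; lnc <- arch$lnc
    acts <- lapply(p$cluster_names, module_activation, p = p,
                   cluster = cluster, t = t, z = z)
    names(acts) <- p$cluster_names

    # log2 mean matrix, coding genes
    lm2 <- matrix(rep(coding$base_log2, n), nrow(coding), n)
    for (cl in p$cluster_names) {
      idx <- which(coding$class == "module" & !is.na(coding$module) &
                     coding$module == cl)
      lm2[idx, ] <- lm2[idx, ] +
        rep(p$module_effect[[cl]] * acts[[cl]], each = length(idx))
    }
    qi <- which(coding$class == "quiescence")
    lm2[qi, ] <- lm2[qi, ] + rep(p$quiescence_effect * (1 - t),
                                 each = length(qi))
    mi <- which(coding$class == "maturation")
    lm2[mi, ] <- lm2[mi, ] + rep(p$maturation_effect * t,
                                 each = length(mi))
    si <- which(coding$class == "phase_S")
    lm2[si, ] <- lm2[si, ] + rep(p$cc_effect * cc_amp * (phase == "S"),
                                 each = length(si))
    gi <- which(coding$class == "phase_G2M")
    lm2[gi, ] <- lm2[gi, ] + rep(p$cc_effect * cc_amp * (phase == "G2/M"),
                                 each = length(gi))

    counts_coding <- matrix(stats::rnbinom(length(lm2), size = size_nb,
                                           mu = 2^lm2),
                            nrow(coding), n)

    # designated co-expression sets: overwrite with copula draws per branch
    branch <- unname(bmap[cluster])
    cpm_scale <- 1e6 / mean(colSums(2^lm2))
    for (s in names(p$coexpr_effect)) {
      idx <- which(coding$class == "coexpr" & coding$module == s)
      mu_genes <- 2^coding$base_log2[idx]
      targets <- p$coexpr_effect[[s]]
      for (b in unique(branch)) {
        tgt <- if (b %in% names(targets)) targets[[b]] else 0
        rho_lat <- calibrate_latent(tgt, size_nb, mean(mu_genes),
                                    p$dropout_rate,
                                    derive_seed(p$seed, 3L), cpm_scale)
        cells_b <- which(branch == b)
        counts_coding[idx, cells_b] <-
          copula_counts(mu_genes, size_nb, rho_lat, length(cells_b))
      }
    }

    # lncRNAs inherit (scaled) partner-module activation
    lml <- matrix(rep(lnc$base_log2, n), nrow(lnc), n)
    nb <- lnc$class == "lnc_neighbor"
    for (cl in p$cluster_names) {
      idx <- which(nb & lnc$module == cl)
      if (length(idx))
        lml[idx, ] <- lml[idx, ] +
          rep(p$lnc_coef * p$module_effect[[cl]] * acts[[cl]],
              each = length(idx))
    }
    counts_lnc <- matrix(stats::rnbinom(length(lml), size = size_nb,
                                        mu = 2^lml), nrow(lnc), n)

    counts <- rbind(counts_coding, counts_lnc)
    rownames(counts) <- c(coding$gene_id, lnc$gene_id)
    colnames(counts) <- cell_ids
    if (p$dropout_rate > 0) {
      # expression-dependent dropout: frequent at low counts, rare for
      # well-expressed genes (full-length chemistry)
      pdrop <- p$dropout_rate * exp(-counts / 10)
      keep <- matrix(stats::runif(length(counts)) >= pdrop,
                     nrow(counts), ncol(counts))
      counts <- counts * keep
    }

    # TF motif-accessibility scores: 10 TFs per module named after module
    # genes (identity mapping to modules) plus unmapped background TFs
    tf_rows <- list()
    for (cl in p$cluster_names) {
      g <- coding$gene_id[coding$class == "module" & !is.na(coding$module) &
                            coding$module == cl][1:10]
      sc <- outer(rep(1, 10), p$module_effect[[cl]] * acts[[cl]]) +
        matrix(stats::rnorm(10 * n, sd = 0.4), 10, n)
      rownames(sc) <- g
      tf_rows[[cl]] <- sc
    }
    bg_tf <- matrix(stats::rnorm(15 * n), 15, n)
    rownames(bg_tf) <- sprintf("TFBG%02d", 1:15)
    atac <- do.call(rbind, c(tf_rows, list(bg_tf)))
    colnames(atac) <- cell_ids

    cell_meta <- data.frame(donor = donor, compartment = compartment,
                            row.names = cell_ids)
    cells_truth <- data.frame(cell_id = cell_ids, cluster = cluster,
                              branch = branch, t = t, phase = phase,
                              compartment = compartment,
                              stringsAsFactors = FALSE)
    genes_truth <- rbind(
      data.frame(gene_id = coding$gene_id, class = coding$class,
                 module = coding$module, partner = NA_character_),
      data.frame(gene_id = lnc$gene_id, class = lnc$class,
                 module = lnc$module, partner = lnc$partner))
    module_sets <- lapply(p$cluster_names, function(cl)
      coding$gene_id[coding$class == "module" & !is.na(coding$module) &
                       coding$module == cl])
    names(module_sets) <- p$cluster_names
    s_set <- coding$gene_id[coding$class == "phase_S"]
    g2m_set <- coding$gene_id[coding$class == "phase_G2M"]
    coexpr_sets <- lapply(names(p$coexpr_effect), function(s)
      coding$gene_id[coding$class == "coexpr" & coding$module == s])
    names(coexpr_sets) <- names(p$coexpr_effect)
    gene_sets <- c(module_sets,
                   list(S_PHASE = s_set, G2M_PHASE = g2m_set,
                        CYCLING = c(s_set, g2m_set),
                        QUIESCENCE = coding$gene_id[coding$class ==
                                                      "quiescence"],
                        MATURATION = coding$gene_id[coding$class ==
                                                      "maturation"]),
                   coexpr_sets)
    nbp <- lnc[nb, c("gene_id", "partner", "module")]
    names(nbp) <- c("lncRNA_id", "partner", "module")
    pe <- ann[nbp$partner, "end"]; ls <- ann[nbp$lncRNA_id, "start"]
    nbp$gap_bp <- ls - pe
    truth <- list(cells = cells_truth, genes = genes_truth,
                  gene_sets = gene_sets,
                  branch_targets = p$coexpr_effect,
                  neighbor_pairs = nbp,
                  compartment_threshold = thr,
                  cluster_intervals = iv,
                  branch_map = bmap)
    structure(list(counts = count_matrix(counts, cell_meta),
                   annotation = ann, atac = atac, truth = truth,
                   params = p),
              class = "synthetic_dataset")
  })
}

#' @method print synthetic_dataset
#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d genes (%d coding, %d lncRNA) x ",
                     "%d cells; %d clusters; %d TFs\n"),
              nrow(x$counts$values), x$params$n_coding_genes,
              x$params$n_lncrna, ncol(x$counts$values),
              x$params$n_clusters, nrow(x$atac)))
  invisible(x)
}

#' Null dataset for differential co-expression calibration
#'
#' Generates a dataset whose designated co-expression gene sets have the
#' same target pair correlation in every branch, so branch labels are
#' exchangeable for those sets and the dispersion-index permutation test is
#' exercised under its null.
#'
#' @param p a \code{\link{sim_params}}.
#' @param target common within-branch pair correlation applied to every
#'   designated set in every branch (scalar, or named per set).
#' @return a \code{synthetic_dataset}.
#' @export
null_coexpression_dataset <- function(p, target = 0.3) {
  validate_sim_params(p)
  if (length(target) == 1)
    target <- stats::setNames(rep(target, length(p$coexpr_effect)),
                              names(p$coexpr_effect))
  branches <- unique(unname(cluster_branch_map(p)))
  p$coexpr_effect <- lapply(names(p$coexpr_effect), function(s)
    stats::setNames(rep(target[[s]], length(branches)), branches))
  names(p$coexpr_effect) <- names(target)
  simulate_hspc(p)
}
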