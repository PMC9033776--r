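#' Simulation configuration for two-factor perturbation RNA-seq counts
#'
#' Builds the configuration object consumed by [simulate_counts()]. The
#' default design mirrors a 2x2 case/control x vehicle/drug study with
#' unbalanced group sizes (4 CTRL+vehicle, 3 SZ+vehicle, 4 CTRL+JQ1,
#' 3 SZ+JQ1 samples). Counts are negative binomial with a decreasing
#' dispersion trend \eqn{\phi(\mu) = \phi_0 + \phi_1/\mu}, log-normal
#' library sizes, and sparse per-gene diagnosis, treatment and interaction
#' (synergy) effects on the log2 scale.
#'
#' @param n_genes number of genes to simulate.
#' @param group_sizes named integer vector of samples per group; names must
#'   be `CTRL_VEH`, `SZ_VEH`, `CTRL_JQ`, `SZ_JQ`.
#' @param baseline_logmean mean and sd of the per-gene natural-log baseline
#'   expression (CPM scale).
#' @param libsize_log log-mean and log-sd of per-sample library sizes.
#' @param dispersion `c(phi0, phi1)` of the trend `phi0 + phi1/mu`;
#'   `phi0` must be positive.
#' @param effect_fractions fractions of genes carrying a nonzero diagnosis,
#'   treatment and synergy (interaction) effect; independent Bernoulli
#'   draws, so genes may carry several effects.
#' @param effect_size mean absolute log2 fold-change and sd, either a
#'   length-2 vector applied to all three effect classes or a 3x2 matrix
#'   with rows `diag`, `treat`, `synergy`.
#' @param n_module_blocks,block_size,block_cor correlated gene blocks for
#'   co-expression testing: number of blocks, genes per block, and target
#'   pairwise gene-gene correlation (in `[0, 1)`). Each block gene loads
#'   on one shared per-sample latent factor with a loading calibrated
#'   against its own negative-binomial log-noise variance
#'   (`lambda_g^2 = v_g rho / (1 - rho)`), so the pairwise correlation of
#'   block genes is approximately `block_cor` at every expression level.
#' @param seed integer seed; a single stream keyed by this seed drives the
#'   whole simulation.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       group_sizes = c(CTRL_VEH = 4L, SZ_VEH = 3L,
                                       CTRL_JQ = 4L, SZ_JQ = 3L),
                       baseline_logmean = c(mean = 2.5, sd = 1.5),
                       libsize_log = c(meanlog = log(1e7), sdlog = 0.3),
                       dispersion = c(phi0 = 0.05, phi1 = 2),
                       effect_fractions = c(diag = 0.1, treat = 0.1,
                                            synergy = 0.05),
                       effect_size = c(mean = 1, sd = 0.3),
                       n_module_blocks = 0L, block_size = 50L,
                       block_cor = 0.8,
                       seed = 1L) {
  grp <- c("CTRL_VEH", "SZ_VEH", "CTRL_JQ", "SZ_JQ")
  if (!all(grp %in% names(group_sizes)))
    stop("group_sizes must be named CTRL_VEH, SZ_VEH, CTRL_JQ, SZ_JQ")
  group_sizes <- as.integer(group_sizes[grp])
  names(group_sizes) <- grp
  if (any(group_sizes <= 0L)) stop("all group sizes must be positive")
  if (dispersion[["phi0"]] <= 0) stop("phi0 must be > 0")
  if (any(effect_fractions < 0 | effect_fractions > 1))
    stop("effect fractions must lie in [0, 1]")
  if (block_cor < 0 || block_cor >= 1) stop("block_cor must be in [0, 1)")
  if (is.matrix(effect_size)) {
    stopifnot(nrow(effect_size) == 3L, ncol(effect_size) == 2L)
    es <- effect_size
  } else {
    es <- matrix(rep(effect_size, each = 3L), nrow = 3L)
  }
  dimnames(es) <- list(c("diag", "treat", "synergy"), c("mean", "sd"))
  structure(list(
    n_genes = as.integer(n_genes), group_sizes = group_sizes,
    baseline_logmean = baseline_logmean, libsize_log = libsize_log,
    dispersion = dispersion, effect_fractions = effect_fractions,
    effect_size = es, n_module_blocks = as.integer(n_module_blocks),
    block_size = as.integer(block_size), block_cor = block_cor,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a two-factor RNA-seq count matrix with known ground truth
#'
#' Draws gene-wise negative-binomial counts with mean
#' \eqn{(L_s/10^6)\,2^{b_0 + b_D[SZ] + b_T[JQ] + b_S[SZ][JQ]}} and
#' dispersion \eqn{\phi(\mu) = \phi_0 + \phi_1/\mu}, where \eqn{L_s} is the
#' sample's library size. Genes assigned to a correlated block additionally
#' share a per-sample latent factor on the log2 scale, inducing pairwise
#' correlation approximately equal to `block_cor`.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (integer matrix genes x samples),
#'   `samples` (sample sheet with `sample_id`, `diagnosis`, `treatment`,
#'   `group`), and `truth` (per-gene `b0`, `bD`, `bT`, `bS`, `dispersion`,
#'   `class` in null/diag/treat/synergy/mixed, `block`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  gs <- config$group_sizes
  n <- sum(gs)

  group <- factor(rep(names(gs), gs), levels = names(gs))
  samples <- data.frame(
    sample_id = paste0(rep(names(gs), gs), "_",
                       unlist(lapply(gs, seq_len), use.names = FALSE)),
    diagnosis = ifelse(grepl("^SZ", group), "SZ", "CTRL"),
    treatment = ifelse(grepl("JQ$", group), "JQ1", "VEH"),
    group = group, stringsAsFactors = FALSE
  )

  gene_ids <- sprintf("g%05d", seq_len(G))
  b0 <- stats::rnorm(G, config$baseline_logmean[["mean"]],
                     config$baseline_logmean[["sd"]]) / log(2)

  draw_effect <- function(frac, mean_sz, sd_sz) {
    on <- stats::rbinom(G, 1L, frac) == 1L
    mag <- abs(stats::rnorm(G, mean_sz, sd_sz))
    sgn <- sample(c(-1, 1), G, replace = TRUE)
    ifelse(on, sgn * mag, 0)
  }
  es <- config$effect_size
  fr <- config$effect_fractions
  bD <- draw_effect(fr[["diag"]], es["diag", "mean"], es["diag", "sd"])
  bT <- draw_effect(fr[["treat"]], es["treat", "mean"], es["treat", "sd"])
  bS <- draw_effect(fr[["synergy"]], es["synergy", "mean"], es["synergy", "sd"])

  n_eff <- (bD != 0) + (bT != 0) + (bS != 0)
  cls <- rep("null", G)
  cls[n_eff > 1L] <- "mixed"
  cls[n_eff == 1L & bD != 0] <- "diag"
  cls[n_eff == 1L & bT != 0] <- "treat"
  cls[n_eff == 1L & bS != 0] <- "synergy"

  block <- integer(G)
  nb <- config$n_module_blocks
  if (nb > 0L) {
    need <- nb * config$block_size
    if (need > G) stop("block structure exceeds the number of genes")
    block[seq_len(need)] <- rep(seq_len(nb), each = config$block_size)
  }

  libsize <- stats::rlnorm(n, config$libsize_log[["meanlog"]],
                           config$libsize_log[["sdlog"]])

  is_sz <- as.numeric(samples$diagnosis == "SZ")
  is_jq <- as.numeric(samples$treatment == "JQ1")
  eta <- outer(b0, rep(1, n)) +
    outer(bD, is_sz) + outer(bT, is_jq) + outer(bS, is_sz * is_jq)

  if (nb > 0L) {
    rho <- config$block_cor
    f <- matrix(stats::rnorm(nb * n), nb, n)           # shared factor per block
    f <- t(scale(t(f)))   # unit realized variance: block_cor is the
                          # in-sample correlation target, not just E[cor]
    idx <- which(block > 0L)
    # loading calibrated to the gene's NB log2-noise variance so that the
    # pairwise correlation of block genes is ~ rho at any expression level
    mu_hat <- 2^b0[idx] * exp(config$libsize_log[["meanlog"]]) / 1e6
    v_g <- (config$dispersion[["phi0"]] + config$dispersion[["phi1"]] / mu_hat +
              1 / mu_hat) / log(2)^2
    lambda <- sqrt(v_g * rho / (1 - rho))
    eta[idx, ] <- eta[idx, ] + lambda * f[block[idx], , drop = FALSE]
  }

  mu <- sweep(2^eta, 2L, libsize / 1e6, "*")
  phi <- config$dispersion[["phi0"]] + config$dispersion[["phi1"]] / mu
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / phi), G, n)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, samples$sample_id)

  mu_bar <- rowMeans(mu)
  truth <- data.frame(
    gene = gene_ids, b0 = b0, bD = bD, bT = bT, bS = bS,
    dispersion = config$dispersion[["phi0"]] +
      config$dispersion[["phi1"]] / mu_bar,
    class = cls, block = block, stringsAsFactors = FALSE
  )
  list(counts = counts, samples = samples, truth = truth,
       libsize = stats::setNames(libsize, samples$sample_id))
}

#' Simulate categorized gene-set collections with planted enrichment
#'
#' Emulates a curated, categorized gene-set resource (e.g. several hundred
#' neural gene sets stratified into eight categories). `n_enriched` sets
#' oversample genes of a chosen ground-truth class at a stated odds ratio;
#' the remaining sets sample uniformly from the gene universe.
#'
#' @param truth ground-truth table from [simulate_counts()].
#' @param n_sets number of gene sets.
#' @param set_size_range inclusive (min, max) of set sizes.
#' @param n_enriched number of sets enriched for `enrich_class` genes.
#' @param enrich_class ground-truth class label to enrich for.
#' @param odds_ratio sampling odds for class genes relative to the rest.
#' @param seed integer seed.
#' @return a `gene_set_collection`: list with `sets` (named list of gene id
#'   vectors), `category` (named character, eight category labels), and
#'   `enriched` (logical per set).
#' @export
simulate_gene_sets <- function(truth, n_sets = 100L,
                               set_size_range = c(10L, 200L),
                               n_enriched = 0L, enrich_class = "synergy",
                               odds_ratio = 10, seed = 1L) {
  stopifnot(nrow(truth) > 0L, n_enriched <= n_sets)
  if (max(set_size_range) > nrow(truth))
    stop("set size exceeds the gene universe")
  set.seed(seed)
  universe <- truth$gene
  in_class <- truth$class == enrich_class
  w_enr <- ifelse(in_class, odds_ratio, 1)
  categories <- c("presynaptic", "postsynaptic", "neurodevelopment",
                  "neurodegeneration", "psychiatric_disorder", "ion_channel",
                  "glial", "transcription_regulation")
  sets <- vector("list", n_sets)
  enriched <- c(rep(TRUE, n_enriched), rep(FALSE, n_sets - n_enriched))
  for (i in seq_len(n_sets)) {
    sz <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
    prob <- if (enriched[i]) w_enr else NULL
    sets[[i]] <- sort(sample(universe, sz, prob = prob))
  }
  names(sets) <- sprintf("set_%03d", seq_len(n_sets))
  category <- stats::setNames(
    categories[((seq_len(n_sets) - 1L) %% length(categories)) + 1L],
    names(sets))
  structure(list(sets = sets, category = category, enriched = enriched,
                 source = "simulated"),
            class = "gene_set_collection")
}

#' Simulate paired promoter-occupancy count tables
#'
#' Generates two per-region integer count vectors (e.g. BRD4 and H2A.Zac
#' promoter reads) from a shared standard-normal latent log2 signal plus
#' independent noise. The mixing weight is calibrated through the Gaussian
#' rank-correlation identity \eqn{\rho_S = (6/\pi)\,\mathrm{asin}(\rho_P/2)}
#' so the RPKM rank correlation lands near `target_rho`. Counts are the
#' rounded scaled log-normal signal, so `target_rho = 1` gives two
#' identical vectors and a Spearman correlation of exactly 1.
#'
#' @param n_regions number of promoter regions (>= 10).
#' @param target_rho target Spearman correlation in `[0, 1]`.
#' @param seed integer seed.
#' @param mean_count approximate mean per-region count.
#' @param region_length region length in bp (promoters default to 2 kb).
#' @param sd_log2 log2 sd of the latent signal.
#' @return list with `regions` (id, length_bp), `counts` (matrix n x 2,
#'   columns `a` and `b`), and `libsize` (per-signal column totals).
#' @export
simulate_promoter_occupancy <- function(n_regions, target_rho, seed = 1L,
                                        mean_count = 200, region_length = 2000L,
                                        sd_log2 = 1.5) {
  if (n_regions < 10L) stop("n_regions must be >= 10")
  if (target_rho < 0 || target_rho > 1) stop("target_rho must be in [0, 1]")
  set.seed(seed)
  rho_p <- 2 * sin(pi * target_rho / 6)
  z <- stats::rnorm(n_regions)
  g_a <- sqrt(rho_p) * z + sqrt(1 - rho_p) * stats::rnorm(n_regions)
  g_b <- sqrt(rho_p) * z + sqrt(1 - rho_p) * stats::rnorm(n_regions)
  to_counts <- function(g) as.integer(round(mean_count * 2^(sd_log2 * g)))
  counts <- cbind(a = to_counts(g_a), b = to_counts(g_b))
  regions <- data.frame(id = sprintf("p%05d", seq_len(n_regions)),
                        length_bp = rep(as.integer(region_length), n_regions),
                        stringsAsFactors = FALSE)
  rownames(counts) <- regions$id
  list(regions = regions, counts = counts, libsize = colSums(counts))
}
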