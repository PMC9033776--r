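make_block_expr <- function(n_genes = 1000, seed = 1, block_cor = 0.8,
                            n_blocks = 2, block_size = 50) {
  sim <- simulate_counts(sim_config(
    n_genes = n_genes, effect_fractions = c(diag = 0, treat = 0, synergy = 0),
    n_module_blocks = n_blocks, block_size = block_size,
    block_cor = block_cor, seed = seed))
  counts <- filter_low_expression(sim$counts)
  expr <- log_cpm(counts, tmm_factors(counts))
  list(expr = expr,
       block = sim$truth$block[match(rownames(expr), sim$truth$gene)])
}

test_that("TOM matches a brute-force triple loop and its boundary cases", {
  set.seed(2)
  expr <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(paste0("g", 1:20), NULL))
  d <- tom_dissimilarity(expr, power = 6)
  a <- abs(cor(t(expr)))^6; diag(a) <- 0
  k <- rowSums(a)
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    if (i == j) { oracle[i, j] <- 0; next }
    s <- 0
    for (u in 1:20) s <- s + a[i, u] * a[u, j]
    oracle[i, j] <- 1 - (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  expect_equal(unname(d), oracle, tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))

  # identical genes: complete graph, zero dissimilarity
  base <- rnorm(10)
  same <- rbind(g1 = base, g2 = base, g3 = base)
  d1 <- tom_dissimilarity(same, power = 7)
  expect_equal(max(abs(d1)), 0, tolerance = 1e-12)

  # exactly orthogonal genes: no overlap, dissimilarity 1 off-diagonal
  orth <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1),
                g3 = c(1, -1, -1, 1))
  d2 <- tom_dissimilarity(orth, power = 7)
  expect_equal(unname(d2[upper.tri(d2)]), rep(1, 3), tolerance = 1e-12)

  expect_error(tom_dissimilarity(rbind(g1 = rep(1, 5), g2 = rnorm(5))),
               "constant")
})

test_that("scale-free fit improves with power on structured data", {
  bl <- make_block_expr(n_genes = 300, seed = 5, n_blocks = 4,
                        block_size = 40)
  sft <- pick_soft_threshold(bl$expr, powers = c(1, 3, 7))
  expect_equal(names(sft), c("power", "sft_r2", "slope", "mean_k"))
  expect_true(all(diff(sft$mean_k) < 0))   # connectivity shrinks with power
  expect_gt(sft$sft_r2[sft$power == 7], sft$sft_r2[sft$power == 1])
})

test_that("module detection recovers planted blocks and nulls go grey", {
  bl <- make_block_expr(seed = 3)
  d <- tom_dissimilarity(bl$expr, power = 7)
  labels <- detect_modules(d)
  mods <- setdiff(unique(labels), "grey")
  expect_length(mods, 2L)
  for (b in 1:2) {
    in_block <- labels[bl$block == b]
    expect_gt(mean(in_block == names(which.max(table(in_block)))), 0.9)
  }

  # independent genes only: everything grey
  noise <- make_block_expr(n_genes = 200, seed = 9, n_blocks = 0)
  d0 <- tom_dissimilarity(noise$expr, power = 7)
  expect_true(all(detect_modules(d0) == "grey"))

  # a cohesive cluster strictly below the size threshold is grey:
  # constructed dissimilarity with a perfect 29-gene clique
  n <- 60
  dsm <- matrix(1, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  dsm[1:29, 1:29] <- 0.1
  diag(dsm) <- 0
  expect_true(all(detect_modules(dsm, min_module_size = 30) == "grey"))
  lab30 <- detect_modules(dsm, min_module_size = 29)
  expect_equal(sum(lab30 != "grey"), 29L)
})

test_that("eigengenes are unit-norm, sign-fixed and equivariant", {
  bl <- make_block_expr(seed = 4)
  genes <- rownames(bl$expr)[bl$block == 1]
  me <- module_eigengene(bl$expr, genes)
  expect_equal(sum(me^2), 1, tolerance = 1e-12)
  expect_gte(cor(me, colMeans(t(scale(t(bl$expr[genes, ]))))), 0)

  # negating the module flips only the sign
  me_neg <- module_eigengene(-bl$expr[genes, , drop = FALSE], genes)
  expect_equal(abs(cor(me, me_neg)), 1, tolerance = 1e-10)

  # identical genes: eigengene is the standardized common profile
  base <- rnorm(12)
  same <- rbind(g1 = base, g2 = base, g3 = base)
  me2 <- module_eigengene(same, rownames(same))
  expect_equal(abs(cor(me2, base)), 1, tolerance = 1e-12)
})

test_that("modules driven by one latent factor merge at 0.17 and not at 0", {
  bl <- make_block_expr(seed = 6, n_blocks = 1, block_size = 60)
  genes <- rownames(bl$expr)[bl$block == 1]
  labels <- setNames(rep("grey", nrow(bl$expr)), rownames(bl$expr))
  labels[genes[1:30]] <- "turquoise"
  labels[genes[31:60]] <- "blue"       # same factor, split in two

  merged <- merge_modules(bl$expr, labels, merge_height = 0.17)
  expect_length(setdiff(unique(merged$labels), "grey"), 1L)
  expect_equal(nrow(merged$merge_history), 1L)

  frozen <- merge_modules(bl$expr, labels, merge_height = 0)
  expect_length(setdiff(unique(frozen$labels), "grey"), 2L)
  expect_equal(nrow(frozen$merge_history), 0L)
})

test_that("module-trait association matches the Student formula and cor.test", {
  set.seed(8)
  me <- matrix(rnorm(14 * 2), 14, 2, dimnames = list(NULL, c("m1", "m2")))
  traits <- cbind(SZ_VEH = rep(c(0, 1, 0, 0), c(4, 3, 4, 3)),
                  SZ_JQ = rep(c(0, 0, 0, 1), c(4, 3, 4, 3)))
  ta <- module_trait_association(me, traits)
  ct <- cor.test(me[, 1], traits[, 1])
  expect_equal(ta$r["m1", "SZ_VEH"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(ta$p["m1", "SZ_VEH"], ct$p.value, tolerance = 1e-12)

  # r = 0.5 at n = 14 gives t = 2 exactly
  r <- 0.5; n <- 14
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(tstat, 2)
  expect_equal(2 * pt(-2, 12), 2 * (1 - pt(2, 12)))

  # a trait used as eigengene correlates perfectly with itself
  me2 <- cbind(self = scale(traits[, 1])[, 1] /
                 sqrt(sum(scale(traits[, 1])^2)))
  ta2 <- module_trait_association(me2, traits[, 1, drop = FALSE])
  expect_equal(unname(ta2$r[1, 1]), 1, tolerance = 1e-12)

  # uniform weights reduce to unweighted Pearson
  ta3 <- module_trait_association(me, traits, weights = rep(2, 14))
  expect_equal(ta3$r, ta$r, tolerance = 1e-12)
  expect_error(module_trait_association(cbind(rep(1, 14)), traits),
               "zero-variance")
})

test_that("planted two-block networks are recovered with high fidelity", {
  bl <- make_block_expr(seed = 2)
  res <- coexpression_modules(bl$expr, traits = NULL)
  expect_gte(ari(res$labels, bl$block), 0.9)
  expect_equal(res$n_modules, 2L)
  expect_equal(res$n_modules_total, 3L)   # grey counted separately

  # trait association runs on the study one-hot groups
  samples <- study_samples()
  traits <- stats::model.matrix(~ 0 + paste0(samples$diagnosis, "_",
                                             ifelse(samples$treatment == "VEH",
                                                    "VEH", "JQ")))
  colnames(traits) <- sub(".*\\)", "", colnames(traits))
  res2 <- coexpression_modules(bl$expr, traits = traits)
  expect_equal(dim(res2$trait_association$r),
               c(res2$n_modules, ncol(traits)))
  expect_true(all(res2$trait_association$p > 0 &
                    res2$trait_association$p <= 1))
})
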