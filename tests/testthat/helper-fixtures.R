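# Shared fixtures, built in code at test time.

# small deterministic count matrix with named dims
toy_counts <- function(values, n_samples = NULL) {
  m <- if (is.matrix(values)) values else
    matrix(values, ncol = n_samples, byrow = TRUE)
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  storage.mode(m) <- "integer"
  m
}

# the study design sample sheet (4/3/4/3)
study_samples <- function() {
  gs <- c(CTRL_VEH = 4L, SZ_VEH = 3L, CTRL_JQ = 4L, SZ_JQ = 3L)
  data.frame(
    sample_id = paste0(rep(names(gs), gs), "_",
                       unlist(lapply(gs, seq_len), use.names = FALSE)),
    diagnosis = rep(c("CTRL", "SZ", "CTRL", "SZ"), gs),
    treatment = rep(c("VEH", "VEH", "JQ1", "JQ1"), gs),
    stringsAsFactors = FALSE
  )
}

# fully null simulation at the study design
null_sim <- function(n_genes = 2000, seed = 1) {
  simulate_counts(sim_config(
    n_genes = n_genes,
    effect_fractions = c(diag = 0, treat = 0, synergy = 0),
    seed = seed))
}

# adjusted Rand index (contingency-table form), independent of any
# clustering code under test
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ij <- sum_a * sum_b / n2
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}
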