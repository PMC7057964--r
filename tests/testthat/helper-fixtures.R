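# shared fixtures and small independent oracles, built in code at test time

# rank-based AUC: probability a positive outranks a negative
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# brute-force topological overlap by explicit double loop
to_bruteforce <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      num <- sum(a[i, ] * a[, j]) + a[i, j]
      out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# tiny expression container around a plain matrix
make_expr <- function(v, colony = NULL, batch = NULL, unit = "tpm") {
  if (is.null(rownames(v))) rownames(v) <- sprintf("g%03d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("s%03d", seq_len(ncol(v)))
  meta <- data.frame(sample = colnames(v), stringsAsFactors = FALSE)
  if (!is.null(colony)) meta$colony <- colony
  if (!is.null(batch)) meta$batch <- batch
  expr_matrix(v, unit = unit, sample_meta = meta)
}

# standard small study config used across integration tests
small_sim_config <- function(seed, n_genes = 600, ...) {
  sim_config(n_colonies = 9L, foragers_per_colony = 10L,
             n_genes = n_genes, seed = seed, ...)
}

# trait-gene ranking fixture: direct trait genes on a clean background
trait_gene_fixture <- function(seed) {
  cfg <- small_sim_config(seed, module_spec = list(),
                          frac_trait_genes = 0.2, trait_effect_sd = 0.8,
                          colony_effect_sd = 0, noise_sd = 0.5)
  traits <- simulate_colony_traits(cfg)
  sim <- simulate_expression(cfg, traits)
  list(cfg = cfg, traits = traits, sim = sim,
       logm = log_transform(sim$expr))
}

# module-recovery fixture: equal-variance planted modules plus noise genes
module_fixture_config <- function(seed, sizes = c(400, 300, 250, 200, 150,
                                                  100),
                                  n_genes = 2000) {
  spec <- lapply(sizes, function(s)
    list(size = s, colony_loading_sd = 0.5, trait_link = "none",
         link_strength = 0))
  small_sim_config(seed, n_genes = n_genes, module_spec = spec,
                   frac_trait_genes = 0, noise_sd = 0.4)
}
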