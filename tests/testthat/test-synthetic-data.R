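test_that("colony trait simulation respects shape, ranges and determinism", {
  cfg <- sim_config(n_colonies = 9, seed = 1,
                    trait_ranges = list(humidity = c(0, 3),
                                        da5ht = c(0.5, 2.5)))
  tr <- simulate_colony_traits(cfg)
  expect_equal(nrow(tr), 9)
  expect_named(tr, c("colony", "humidity", "da5ht"))
  expect_true(all(tr$humidity >= 0 & tr$humidity <= 3))
  expect_true(all(tr$da5ht >= 0.5 & tr$da5ht <= 2.5))
  expect_identical(tr, simulate_colony_traits(cfg))
  expect_error(sim_config(trait_ranges = list(humidity = c(1, 1),
                                              da5ht = c(0.5, 2.5))),
               "degenerate")
})

test_that("expression generator normalizes columns and records truth", {
  cfg <- small_sim_config(3, n_genes = 200,
                          module_spec = list(list(size = 50,
                                                  colony_loading_sd = 0.5,
                                                  trait_link = "humidity",
                                                  link_strength = 0.5)),
                          frac_trait_genes = 0.1)
  tr <- simulate_colony_traits(cfg)
  sim <- simulate_expression(cfg, tr)
  expect_equal(dim(sim$expr$values), c(200, 90))
  expect_true(all(sim$expr$values >= 0))
  expect_equal(colSums(sim$expr$values), rep(1e6, 90),
               tolerance = 1e-6, ignore_attr = TRUE)
  gt <- sim$truth$gene_truth
  expect_equal(sum(gt$module == "M01"), 50)
  # trait effects only on designated trait genes, one trait each
  expect_true(all(gt$effect_humidity[gt$module != "none"] == 0))
  expect_true(all(!(gt$effect_humidity != 0 & gt$effect_da5ht != 0)))
  # deterministic replay
  sim2 <- simulate_expression(cfg, tr)
  expect_identical(sim$expr$values, sim2$expr$values)
  # oversized modules rejected
  expect_error(sim_config(n_genes = 10,
                          module_spec = list(list(size = 20,
                                                  colony_loading_sd = 0.5,
                                                  trait_link = "none",
                                                  link_strength = 0))),
               "module sizes")
})

test_that("with every variance source off, nestmates and colonies agree", {
  cfg <- sim_config(n_colonies = 3, foragers_per_colony = 4, n_genes = 50,
                    module_spec = list(), frac_trait_genes = 0,
                    colony_effect_sd = 0, noise_sd = 0,
                    batch_spec = list(list(batch_id = "b1",
                                           sample_idx = 1:12, shift = 0)),
                    seed = 5)
  tr <- simulate_colony_traits(cfg)
  sim <- simulate_expression(cfg, tr)
  v <- sim$expr$values
  expect_true(max(abs(v - v[, 1])) < 1e-8)
})

test_that("planted positive humidity gene correlates positively in most replicates", {
  hits <- vapply(1:200, function(seed) {
    cfg <- sim_config(n_colonies = 9, foragers_per_colony = 10,
                      n_genes = 20,
                      module_spec = list(list(size = 5,
                                              colony_loading_sd = 0.5,
                                              trait_link = "humidity",
                                              link_strength = 0.8)),
                      frac_trait_genes = 0, colony_effect_sd = 0.3,
                      noise_sd = 0.4, seed = seed)
    tr <- simulate_colony_traits(cfg)
    sim <- simulate_expression(cfg, tr)
    z <- tr$humidity[match(sim$truth$sample_meta$colony, tr$colony)]
    y <- log2(sim$expr$values[1, ] + 1)  # a module member (loading > 0)
    stats::cor(y, z) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("annotation generator plants terms at the configured concentration", {
  cfg <- small_sim_config(11, n_genes = 400, module_spec = list(),
                          frac_trait_genes = 0.3, trait_effect_sd = 0.8,
                          go_spec = list(n_terms = 5, genes_per_term = 20,
                                         planted = list(
                                           list(term = "GO:PLANT",
                                                target = "humidity",
                                                concentration = 1))))
  tr <- simulate_colony_traits(cfg)
  sim <- simulate_expression(cfg, tr)
  ann <- simulate_annotations(cfg, sim$truth)
  gt <- sim$truth$gene_truth
  planted <- ann$gene[ann$term == "GO:PLANT"]
  expect_length(planted, 20)
  expect_true(all(planted %in% gt$gene[gt$effect_humidity > 0]))
  # empty spec gives an empty map
  cfg0 <- small_sim_config(1, n_genes = 50, module_spec = list(),
                           go_spec = list(n_terms = 0, genes_per_term = 5,
                                          planted = list()))
  tr0 <- simulate_colony_traits(cfg0)
  sim0 <- simulate_expression(cfg0, tr0)
  expect_equal(nrow(simulate_annotations(cfg0, sim0$truth)), 0)
})

test_that("random annotation overlap p-values are uniform over seeds", {
  ps <- vapply(1:500, function(seed) {
    cfg <- sim_config(n_colonies = 2, foragers_per_colony = 2,
                      n_genes = 200, module_spec = list(),
                      frac_trait_genes = 0.25, seed = seed,
                      go_spec = list(n_terms = 1, genes_per_term = 20,
                                     planted = list()))
    tr <- simulate_colony_traits(cfg)
    sim <- simulate_expression(cfg, tr)
    ann <- simulate_annotations(cfg, sim$truth)
    gt <- sim$truth$gene_truth
    trait_genes <- gt$gene[gt$effect_humidity != 0 | gt$effect_da5ht != 0]
    fisher_enrichment(ann$gene, trait_genes, gt$gene)$p_one_sided
  }, numeric(1))
  # hypergeometric p is discrete: compare against exact null draws of the
  # same tail statistic rather than a continuous uniform
  withr::with_seed(999, {
    n_trait <- 50  # 0.25 * 200, half per trait, all counted as trait genes
    q_null <- stats::rhyper(5000, n_trait, 200 - n_trait, 20)
    p_null <- stats::phyper(q_null - 1, n_trait, 200 - n_trait, 20,
                            lower.tail = FALSE)
  })
  expect_gt(suppressWarnings(
    stats::ks.test(ps, p_null)$p.value), 0.01)
})

test_that("dN/dS generator plants a negative centrality relationship", {
  cfg <- small_sim_config(7, n_genes = 300,
                          module_spec = list(list(size = 150,
                                                  colony_loading_sd = 0.5,
                                                  trait_link = "none",
                                                  link_strength = 0)),
                          frac_trait_genes = 0,
                          dnds_spec = list(baseline_mean = -1.5,
                                           centrality_slope = 1,
                                           trait_slope = 1,
                                           dispersion = 0.01,
                                           species_sd = 0.01,
                                           n_species = 6))
  tr <- simulate_colony_traits(cfg)
  sim <- simulate_expression(cfg, tr)
  dn <- simulate_dnds(cfg, sim$truth)
  expect_equal(sum(grepl("^dnds_", names(dn))), 6)
  expect_true(all(dn[grep("^dnds_", names(dn))] > 0))
  gt <- sim$truth$gene_truth
  cent <- ifelse(gt$module == "none", 0, gt$loading)
  # noise-free limit: the sign is forced by construction
  expect_lt(stats::cor(dn$dnds_sp1, cent, method = "spearman"), 0)
  expect_error(sim_config(dnds_spec = list(baseline_mean = -1,
                                           centrality_slope = 0,
                                           trait_slope = 0, dispersion = 0,
                                           species_sd = 0.1,
                                           n_species = 2)),
               "dispersion")
})

test_that("null dN/dS generator shows no spurious centrality slope", {
  tstats <- vapply(1:100, function(seed) {
    cfg <- sim_config(n_colonies = 2, foragers_per_colony = 2,
                      n_genes = 200, seed = seed,
                      module_spec = list(list(size = 100,
                                              colony_loading_sd = 0.5,
                                              trait_link = "none",
                                              link_strength = 0)),
                      frac_trait_genes = 0,
                      dnds_spec = list(baseline_mean = -1.5,
                                       centrality_slope = 0,
                                       trait_slope = 0, dispersion = 0.4,
                                       species_sd = 0.2, n_species = 2))
    tr <- simulate_colony_traits(cfg)
    sim <- simulate_expression(cfg, tr)
    dn <- simulate_dnds(cfg, sim$truth)
    gt <- sim$truth$gene_truth
    cent <- ifelse(gt$module == "none", 0, gt$loading)
    fit <- summary(stats::lm(log(dn$dnds_sp1) ~ cent))
    fit$coefficients[2, 3]
  }, numeric(1))
  expect_gte(mean(abs(tstats) < 2), 0.90)
})

test_that("counts emission is consistent with the TPM matrix", {
  cfg <- sim_config(n_colonies = 3, foragers_per_colony = 3, n_genes = 120,
                    module_spec = list(), frac_trait_genes = 0, seed = 2)
  tr <- simulate_colony_traits(cfg)
  sim <- simulate_expression(cfg, tr)
  counts <- simulate_counts(sim$expr, sim$truth$gene_lengths,
                            depth = 5e6, seed = 2)
  expect_equal(counts$unit, "counts")
  back <- counts_to_tpm(counts, sim$truth$gene_lengths)
  # Poisson noise at depth 5e6: strong per-sample agreement in shape
  cors <- vapply(seq_len(ncol(back$values)), function(j)
    stats::cor(back$values[, j], sim$expr$values[, j]), numeric(1))
  expect_true(all(cors > 0.99))
})
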