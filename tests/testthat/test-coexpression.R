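test_that("signed adjacency follows the power transform exactly", {
  # three exactly collinear / anti-collinear genes
  x <- c(1, 2, 3, 4, 5, 6)
  v <- rbind(g1 = x, g2 = 2 * x + 1, g3 = -x)
  colnames(v) <- sprintf("s%d", 1:6)
  a <- signed_adjacency(v, beta = 12)
  expect_equal(a["g1", "g2"], 1)       # cor +1
  expect_equal(a["g1", "g3"], 0)       # cor -1
  expect_equal(diag(a), c(g1 = 0, g2 = 0, g3 = 0))
  # cor 0 maps to 2^-beta
  set.seed(14)
  n <- 2000
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  x2 <- stats::residuals(stats::lm(x2 ~ x1))  # exactly orthogonal
  v2 <- rbind(a = x1, b = x2)
  colnames(v2) <- sprintf("s%d", 1:n)
  a2 <- signed_adjacency(v2, beta = 12)
  expect_equal(a2["a", "b"], 0.5^12, tolerance = 1e-6)
  # monotone shrinkage in beta for cor < 1
  a_lo <- signed_adjacency(v2, beta = 6)
  expect_true(a_lo["a", "b"] >= a2["a", "b"])
})

test_that("soft threshold selection reaches the scale-free fit target", {
  cfg <- module_fixture_config(51, sizes = c(200, 150, 100), n_genes = 700)
  tr <- simulate_colony_traits(cfg)
  sim <- simulate_expression(cfg, tr)
  lg <- log_transform(sim$expr)
  ps <- pick_soft_threshold(lg, candidate_betas = c(2, 4, 6, 8, 10, 12, 14))
  expect_equal(nrow(ps$fit_table), 7)
  chosen <- ps$fit_table$signed_r2[ps$fit_table$beta == ps$beta]
  expect_gte(chosen, 0.8)
})

test_that("topological overlap matches hand values and the brute-force oracle", {
  # 3-gene fully connected unit-weight graph: TO = 1 everywhere
  a3 <- matrix(1, 3, 3); diag(a3) <- 0
  to3 <- topological_overlap(a3)
  expect_equal(to3, matrix(1, 3, 3), ignore_attr = TRUE)
  # isolated pair
  a0 <- matrix(0, 4, 4)
  expect_equal(topological_overlap(a0)[1, 2], 0)
  # random 8-gene adjacency vs explicit double loop
  withr::with_seed(15, {
    r <- matrix(stats::runif(64), 8, 8)
    a8 <- (r + t(r)) / 2
    diag(a8) <- 0
  })
  expect_lt(max(abs(topological_overlap(a8) - to_bruteforce(a8))), 1e-12)
  expect_error(topological_overlap(-a3), "non-negative")
})

test_that("module eigengene and kME behave like a first principal component", {
  set.seed(16)
  # identical genes: |kME| = 1 for every member
  pat <- stats::rnorm(20)
  v <- matrix(rep(pat, each = 5), 5, 20, byrow = FALSE)
  v <- rbind(v, matrix(stats::rnorm(100), 5, 20))
  rownames(v) <- sprintf("g%02d", 1:10); colnames(v) <- sprintf("s%02d", 1:20)
  me <- module_eigengene(v, 1:5)
  expect_equal(abs(unname(kme(v[1:5, ], me))), rep(1, 5), tolerance = 1e-8)
  expect_equal(sum(me^2), 1)  # unit norm
  # sign orientation: mean member kME is non-negative
  expect_gte(mean(kme(v[1:5, ], me)), 0)
  # planted single factor is recovered
  fac <- stats::rnorm(40)
  load <- abs(stats::rnorm(30, 1, 0.25))
  mv <- load %o% fac + matrix(stats::rnorm(1200, 0, 0.3), 30, 40)
  rownames(mv) <- sprintf("m%02d", 1:30); colnames(mv) <- sprintf("s%02d", 1:40)
  me2 <- module_eigengene(mv, 1:30)
  expect_gt(abs(stats::cor(me2, fac)), 0.95)
  expect_error(module_eigengene(matrix(1, 3, 4,
                                       dimnames = list(letters[1:3],
                                                       LETTERS[1:4])), 1:3),
               "zero-variance")
})

test_that("module density and its permutation test honour their definitions", {
  to <- matrix(0.3, 6, 6); diag(to) <- 1
  dimnames(to) <- list(sprintf("g%d", 1:6), sprintf("g%d", 1:6))
  expect_equal(module_density(to, 1:4), 0.3)
  expect_equal(module_density(to, c(2, 5)), to[2, 5])
  expect_error(module_density(to, 3), "at least 2")
  # constant TO: strict inequality forces p = 0
  dp <- density_permutation_test(to, 1:3, n_pseudo = 500, seed = 1)
  expect_equal(dp$p, 0)
  # planted dense block: p = 0
  tob <- matrix(0.01, 60, 60); tob[1:20, 1:20] <- 0.5; diag(tob) <- 1
  dimnames(tob) <- list(sprintf("g%02d", 1:60), sprintf("g%02d", 1:60))
  dpb <- density_permutation_test(tob, 1:20, n_pseudo = 2000, seed = 2)
  expect_equal(dpb$p, 0)
  # reproducibility under seed
  dp2 <- density_permutation_test(tob, 1:20, n_pseudo = 500, seed = 9)
  dp3 <- density_permutation_test(tob, 1:20, n_pseudo = 500, seed = 9)
  expect_identical(dp2, dp3)
})

test_that("pseudo-module p-values are uniform on exchangeable networks", {
  # exchangeable TO from i.i.d. data; a random "module" is itself a
  # pseudo-module, so its p must be uniform across draws
  withr::with_seed(17, {
    v <- matrix(stats::rnorm(200 * 40), 200, 40)
    rownames(v) <- sprintf("g%03d", 1:200); colnames(v) <- sprintf("s%02d", 1:40)
    to <- topological_overlap(signed_adjacency(v, 6))
    ps <- vapply(1:200, function(i) {
      genes <- sample(200, 30)
      density_permutation_test(to, genes, n_pseudo = 2000, seed = 1000 + i)$p
    }, numeric(1))
  })
  expect_gt(suppressWarnings(
    stats::ks.test(ps, stats::runif(5000))$p.value), 0.01)
})

test_that("tree cutting recovers planted blocks exactly", {
  # two blocks with high within-block, low between-block TO
  withr::with_seed(18, {
    f1 <- stats::rnorm(30); f2 <- stats::rnorm(30)
    v <- rbind(abs(stats::rnorm(100, 1, 0.2)) %o% f1,
               abs(stats::rnorm(100, 1, 0.2)) %o% f2) +
      matrix(stats::rnorm(200 * 30, 0, 0.25), 200, 30)
  })
  rownames(v) <- sprintf("g%03d", 1:200); colnames(v) <- sprintf("s%02d", 1:30)
  to <- topological_overlap(signed_adjacency(v, 12))
  cc <- cluster_and_cut(to, min_module_size = 80)
  truth <- rep(c("A", "B"), each = 100)
  expect_equal(length(setdiff(unique(cc$labels), "grey")), 2)
  expect_equal(mclust::adjustedRandIndex(cc$labels, truth), 1)
  # all modules at least the minimum size
  sizes <- table(cc$labels[cc$labels != "grey"])
  expect_true(all(sizes >= 80))
})

test_that("density filter is a fixed point and clears pure-noise input", {
  # pure planted modules, no noise genes: converges first round, no removals
  withr::with_seed(19, {
    f1 <- stats::rnorm(40); f2 <- stats::rnorm(40)
    v <- rbind(abs(stats::rnorm(90, 1, 0.2)) %o% f1,
               abs(stats::rnorm(90, 1, 0.2)) %o% f2) +
      matrix(stats::rnorm(180 * 40, 0, 0.25), 180, 40)
  })
  rownames(v) <- sprintf("g%03d", 1:180); colnames(v) <- sprintf("s%02d", 1:40)
  np <- network_params(beta = 12, min_module_size = 80, n_pseudo = 1000,
                       seed = 4)
  ms <- iterative_density_filter(v, np)
  expect_equal(ms$iterations, 1)
  expect_equal(length(ms$removed_log), 0)
  expect_equal(nrow(ms$modules), 2)
  expect_true(all(ms$modules$density_p <= 0.01))
  # fixed point: filtering its own output changes nothing
  ms2 <- iterative_density_filter(v[names(ms$labels), ], np)
  expect_identical(ms2$labels, ms$labels)
  # all-noise input terminates cleanly with an empty network
  withr::with_seed(20, {
    noise <- matrix(stats::rnorm(150 * 40), 150, 40)
  })
  rownames(noise) <- sprintf("n%03d", 1:150)
  colnames(noise) <- sprintf("s%02d", 1:40)
  ms0 <- iterative_density_filter(noise, np)
  expect_equal(nrow(ms0$modules), 0)
  expect_length(ms0$labels, 0)
})

test_that("module quality Z separates planted from random structure", {
  withr::with_seed(21, {
    f1 <- stats::rnorm(40)
    v <- rbind(abs(stats::rnorm(90, 1, 0.2)) %o% f1,
               matrix(stats::rnorm(110 * 40), 110, 40)) +
      matrix(stats::rnorm(200 * 40, 0, 0.25), 200, 40)
  })
  rownames(v) <- sprintf("g%03d", 1:200); colnames(v) <- sprintf("s%02d", 1:40)
  to <- topological_overlap(signed_adjacency(v, 12))
  labels <- stats::setNames(rep(c("mod", "grey"), c(90, 110)), rownames(v))
  z <- module_quality_z(to, labels, n_perm = 100, seed = 5)
  expect_gt(z[["mod"]], 10)
  # random labels on exchangeable data stay low
  withr::with_seed(22, {
    ve <- matrix(stats::rnorm(150 * 40), 150, 40)
    rownames(ve) <- sprintf("g%03d", 1:150); colnames(ve) <- sprintf("s%02d", 1:40)
    toe <- topological_overlap(signed_adjacency(ve, 6))
    zs <- vapply(1:20, function(i) {
      lab <- stats::setNames(sample(rep(c("a", "grey"), c(40, 110))),
                             rownames(ve))
      module_quality_z(toe, lab, n_perm = 60, seed = 100 + i)[["a"]]
    }, numeric(1))
  })
  expect_gte(mean(abs(zs) < 3), 0.95)
  # invariant to sample order
  perm <- sample(ncol(v))
  z2 <- module_quality_z(to, labels, n_perm = 100, seed = 5)
  expect_identical(z, z2)
})

test_that("module-trait analysis finds the planted trait-linked module", {
  cfg <- small_sim_config(61, n_genes = 800, module_spec = list(
    list(size = 180, colony_loading_sd = 0.5, trait_link = "humidity",
         link_strength = 0.8),
    list(size = 150, colony_loading_sd = 0.5, trait_link = "none",
         link_strength = 0)),
    frac_trait_genes = 0, noise_sd = 0.4)
  tr <- simulate_colony_traits(cfg)
  sim <- simulate_expression(cfg, tr)
  pp <- preprocess_expression(sim$expr)
  np <- network_params(beta = 12, min_module_size = 80, n_pseudo = 1000,
                       seed = 6)
  ms <- iterative_density_filter(pp$matrix, np)
  expect_gte(nrow(ms$modules), 2)
  mta <- module_trait_analysis(pp$matrix, ms, tr)
  gt <- sim$truth$gene_truth
  # identify which detected module carries the planted humidity genes
  overlap <- vapply(ms$modules$module, function(mod)
    mean(gt$module[match(names(ms$labels)[ms$labels == mod],
                         gt$gene)] == "M01"), numeric(1))
  hum_mod <- ms$modules$module[which.max(overlap)]
  r_hum <- abs(mta$me_trait[[paste0("r_", "humidity")]])
  expect_equal(mta$me_trait$module[which.max(r_hum)], hum_mod)
  # within-module kME vs |trait r| coupling is positive for the linked module
  slope <- mta$kme_traitr$slope_humidity[mta$kme_traitr$module == hum_mod]
  expect_gt(slope, 0)
})

test_that("eigengene colony comparisons calibrate and detect shifts", {
  # null: no colony effect on an arbitrary gene set's eigengene
  ps <- vapply(1:60, function(i) {
    withr::with_seed(300 + i, {
      v <- matrix(stats::rnorm(60 * 36), 60, 36)
      rownames(v) <- sprintf("g%02d", 1:60)
      colnames(v) <- sprintf("s%02d", 1:36)
      m <- make_expr(v, colony = rep(sprintf("C%d", 1:6), each = 6),
                     unit = "logtpm")
      me <- module_eigengene(m, 1:20)
      summary(stats::aov(me ~ factor(m$sample_meta$colony)))[[1]]$`Pr(>F)`[1]
    })
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # a 2-SD colony shift on a coherent module is detected
  withr::with_seed(23, {
    fac <- stats::rnorm(36)
    shift <- rep(c(2, 0, 0, 0, 0, 0), each = 6)   # one colony moved 2 SD
    v2 <- abs(stats::rnorm(60, 1, 0.2)) %o% (fac + shift) +
      matrix(stats::rnorm(60 * 36, 0, 0.3), 60, 36)
  })
  rownames(v2) <- sprintf("g%02d", 1:60); colnames(v2) <- sprintf("s%02d", 1:36)
  m2 <- make_expr(v2, colony = rep(sprintf("C%d", 1:6), each = 6),
                  unit = "logtpm")
  ms <- list(labels = stats::setNames(rep("mod", 60), rownames(v2)),
             modules = data.frame(module = "mod", size = 60,
                                  density = NA, density_p = NA))
  class(ms) <- "module_set"
  cmp <- me_colony_comparison(m2, ms)
  expect_lt(cmp$anova$p[1], 0.01)
  expect_equal(nrow(cmp$contrasts), choose(6, 2))
})
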