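#' Network construction parameters
#'
#' @param beta Soft-threshold power (positive integer, default 12).
#' @param min_module_size Smallest allowed module (default 80 genes).
#' @param n_pseudo Pseudo-modules per density test (default 10000).
#' @param density_alpha Density-test removal threshold: modules with
#'   permutation p above this are dropped (default 0.01).
#' @param gap_depth Minimum relative within-branch density gain required to
#'   split a dendrogram branch into two modules (default 0.2).
#' @param kme_reassign kME threshold at which an unassigned gene is rescued
#'   into its best-matching module during the density filter (default 0.5,
#'   the conventional module-membership cutoff).
#' @param max_rounds Cap on density-filter iterations.
#' @param seed Seed for the permutation draws.
#' @return A `network_params` list.
#' @export
network_params <- function(beta = 12L, min_module_size = 80L,
                           n_pseudo = 10000L, density_alpha = 0.01,
                           gap_depth = 0.2, kme_reassign = 0.5,
                           max_rounds = 20L, seed = 1L) {
  stopifnot(beta >= 1, n_pseudo >= 100, min_module_size >= 2)
  structure(list(beta = as.integer(beta),
                 min_module_size = as.integer(min_module_size),
                 n_pseudo = as.integer(n_pseudo),
                 density_alpha = density_alpha,
                 gap_depth = gap_depth,
                 kme_reassign = kme_reassign,
                 max_rounds = as.integer(max_rounds),
                 seed = as.integer(seed)),
            class = "network_params")
}

#' Signed coexpression adjacency
#'
#' Maps the Pearson correlation of every gene pair through
#' \eqn{a_{ij} = ((1 + r_{ij})/2)^\beta}, so perfectly anticorrelated genes
#' are unconnected and perfectly correlated genes fully connected. The
#' diagonal is set to zero so connectivity sums exclude self-adjacency.
#'
#' @param m An `expr_matrix` or numeric genes x samples matrix (at least 3
#'   samples; zero-variance genes must be excluded upstream).
#' @param beta Soft-threshold power.
#' @return Symmetric adjacency matrix in \[0,1\] with zero diagonal.
#' @export
signed_adjacency <- function(m, beta = 12L) {
  v <- if (inherits(m, "expr_matrix")) expr_values(m, "gene_mean") else m
  if (ncol(v) < 3) stop("need at least 3 samples")
  r <- stats::cor(t(v))
  if (any(!is.finite(r))) {
    bad <- which(!is.finite(r), arr.ind = TRUE)[1L, ]
    stop("non-finite correlation for gene pair ",
         rownames(v)[bad[1]], " / ", rownames(v)[bad[2]],
         " (zero-variance gene?)")
  }
  a <- ((1 + r) / 2)^beta
  diag(a) <- 0
  a
}

#' Choose the soft threshold by the scale-free topology criterion
#'
#' For each candidate power, gene connectivities k are binned, and the
#' model fit R^2 of log10 p(k) on log10 k is computed with its sign flipped
#' when the slope is positive (scale-free topology requires a negative
#' slope). The chosen power is the smallest whose signed R^2 reaches
#' `fit_target`, or the argmax if none does.
#'
#' @param m Expression matrix (`expr_matrix` or genes x samples numeric).
#' @param candidate_betas Candidate powers.
#' @param fit_target Signed R^2 to reach (default 0.8).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return List with `beta` and `fit_table` (beta, signed_r2, slope,
#'   mean_k).
#' @export
pick_soft_threshold <- function(m, candidate_betas = c(1:10, 12, 14, 16, 18,
                                                       20),
                                fit_target = 0.8, n_bins = 10L) {
  v <- if (inherits(m, "expr_matrix")) expr_values(m, "gene_mean") else m
  r <- stats::cor(t(v))
  base <- (1 + r) / 2
  diag(base) <- NA
  rows <- lapply(candidate_betas, function(b) {
    k <- rowSums(base^b, na.rm = TRUE)
    if (max(k) == min(k)) stop("degenerate connectivity: all genes equal")
    br <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, br, include.lowest = TRUE)
    pk <- tabulate(bin, n_bins) / length(k)
    mid <- (br[-1] + br[-length(br)]) / 2
    ok <- pk > 0 & mid > 0
    if (sum(ok) < 3) {
      sr2 <- NA_real_; slope <- NA_real_
    } else {
      fit <- stats::lm(log10(pk[ok]) ~ log10(mid[ok]))
      slope <- unname(stats::coef(fit)[2])
      r2 <- summary(fit)$r.squared
      sr2 <- -sign(slope) * r2
    }
    data.frame(beta = b, signed_r2 = sr2, slope = slope, mean_k = mean(k))
  })
  ft <- do.call(rbind, rows)
  hit <- which(!is.na(ft$signed_r2) & ft$signed_r2 >= fit_target)
  beta <- if (length(hit)) ft$beta[hit[1L]] else
    ft$beta[which.max(ft$signed_r2)]
  list(beta = beta, fit_table = ft)
}

#' Topological overlap matrix
#'
#' \deqn{TO_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{k_i = \sum_u a_{iu}}; the diagonal is 1.
#'
#' @param adjacency Symmetric non-negative adjacency with zero diagonal.
#' @return Symmetric TO matrix in \[0,1\] with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  if (any(adjacency < 0)) stop("adjacency must be non-negative")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  kmin <- outer(k, k, pmin)
  to <- num / (kmin + 1 - adjacency)
  diag(to) <- 1
  dimnames(to) <- dimnames(adjacency)
  to
}

# Top-down traversal of the average-linkage dendrogram. At each internal
# node whose two branches could both hold a module, the split is accepted
# when the size-weighted mean within-branch TO density exceeds the parent
# density by a relative margin (gap_depth); otherwise the node becomes one
# cluster. Branches too small to be modules are peeled off as grey.
cut_tree_dynamic <- function(d, min_size, gap_depth) {
  n <- attr(d, "Size")
  hc <- stats::hclust(d, method = "average")
  tomat <- 1 - as.matrix(d)
  diag(tomat) <- 1
  # member sets per merge node (negative entries are leaves)
  members <- vector("list", n - 1L)
  node_members <- function(k) {
    if (k < 0) return(-k)
    members[[k]]
  }
  for (k in seq_len(n - 1L)) {
    members[[k]] <- c(node_members(hc$merge[k, 1L]),
                      node_members(hc$merge[k, 2L]))
  }
  dens <- function(idx) {
    if (length(idx) < 2) return(0)
    sub <- tomat[idx, idx]
    mean(sub[upper.tri(sub)])
  }
  clusters <- list()
  stack <- c(n - 1L)  # iterative traversal: deep peeling must not recurse
  while (length(stack)) {
    k <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    idx <- node_members(k)
    if (k < 0 || length(idx) < 2L * min_size) {
      clusters[[length(clusters) + 1L]] <- idx
      next
    }
    a <- hc$merge[k, 1L]; b <- hc$merge[k, 2L]
    A <- node_members(a); B <- node_members(b)
    if (length(A) >= min_size && length(B) >= min_size) {
      gain <- (length(A) * dens(A) + length(B) * dens(B)) / length(idx)
      if (gain >= (1 + gap_depth) * dens(idx)) {
        stack <- c(stack, a, b)
      } else {
        clusters[[length(clusters) + 1L]] <- idx
      }
    } else {
      # peel the undersized branch (becomes grey unless reassigned below)
      small <- if (length(A) < length(B)) A else B
      big_k <- if (length(A) < length(B)) b else a
      clusters[[length(clusters) + 1L]] <- small
      stack <- c(stack, big_k)
    }
  }
  labels <- rep("grey", n)
  mod_i <- 0L
  for (grp in clusters) {
    # a cluster spanning the whole network means no density-improving
    # split exists anywhere: no module structure, not one giant module
    if (length(grp) >= min_size && length(grp) < n) {
      mod_i <- mod_i + 1L
      labels[grp] <- module_colors(mod_i)
    }
  }
  list(labels = labels, hclust = hc)
}

module_colors <- function(i) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue")
  ifelse(i <= length(pal), pal[i], paste0("module", i))
}

#' Cluster the TO matrix and cut modules
#'
#' Average-linkage hierarchical clustering on 1 - TO, followed by a
#' dynamic top-down cut: starting at the root, a branch is split into its
#' two children whenever both could hold a module and the size-weighted
#' mean within-child TO density improves on the parent's by at least
#' `gap_depth` (relative); undersized side branches are peeled off.
#' Peeled genes at least as intramodularly connected as the weakest member
#' of their best-matching module are reassigned to it; the rest stay grey.
#'
#' @param TO Topological overlap matrix.
#' @param min_module_size Smallest allowed module.
#' @param gap_depth See [network_params()].
#' @return List with `labels` (named by gene; `"grey"` = unassigned) and
#'   `hclust` (the merge tree, heights in 1 - TO units).
#' @export
cluster_and_cut <- function(TO, min_module_size = 80L, gap_depth = 0.2) {
  n <- nrow(TO)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all grey")
    return(list(labels = stats::setNames(rep("grey", n), rownames(TO)),
                hclust = NULL))
  }
  d <- stats::as.dist(1 - TO)
  res <- cut_tree_dynamic(d, min_module_size, gap_depth)
  names(res$labels) <- rownames(TO)
  res
}

#' Module eigengene
#'
#' First principal component of the standardized module submatrix across
#' samples, sign-oriented so the mean member kME is non-negative, and
#' scaled to unit norm.
#'
#' @param m An `expr_matrix` or genes x samples numeric matrix.
#' @param module_genes Gene ids (or indices) of the module members.
#' @return Named per-sample eigengene vector (unit norm).
#' @export
module_eigengene <- function(m, module_genes) {
  v <- if (inherits(m, "expr_matrix")) expr_values(m, "gene_mean") else m
  sub <- v[module_genes, , drop = FALSE]
  if (nrow(sub) < 2) stop("module must have at least 2 genes")
  sds <- apply(sub, 1L, stats::sd)
  if (all(sds == 0)) stop("zero-variance module")
  sub <- sub[sds > 0, , drop = FALSE]
  z <- t(scale(t(sub)))
  sv <- svd(t(z), nu = 1L, nv = 0L)
  me <- sv$u[, 1L]
  kme <- as.numeric(stats::cor(t(sub), me))
  if (mean(kme) < 0) me <- -me
  stats::setNames(me, colnames(v))
}

#' Eigengene-based connectivity (kME)
#'
#' Each gene's Pearson correlation with a module eigengene.
#'
#' @param m An `expr_matrix` or genes x samples numeric matrix.
#' @param eigengene Per-sample eigengene vector.
#' @return Named per-gene correlation vector in \[-1, 1\].
#' @export
kme <- function(m, eigengene) {
  v <- if (inherits(m, "expr_matrix")) expr_values(m, "gene_mean") else m
  stats::setNames(suppressWarnings(as.numeric(stats::cor(t(v), eigengene))),
                  rownames(v))
}

#' Module density: mean within-module topological overlap
#'
#' @param TO Topological overlap matrix.
#' @param module_genes Members (ids or indices), at least 2.
#' @return Mean off-diagonal TO among members, in \[0, 1\].
#' @export
module_density <- function(TO, module_genes) {
  if (length(module_genes) < 2) stop("module must have at least 2 genes")
  sub <- TO[module_genes, module_genes]
  mean(sub[upper.tri(sub)])
}

#' Permutation test of module density against random pseudo-modules
#'
#' Draws `n_pseudo` random gene sets of the module's size (without
#' replacement, uniformly from all genes in the network) and reports
#' \eqn{p = \#\{pseudo\ density > observed\} / n\_pseudo} (strict
#' inequality, no small-sample correction, so p can be exactly 0).
#'
#' @param TO Topological overlap matrix.
#' @param module_genes Module members.
#' @param n_pseudo Number of pseudo-modules.
#' @param seed Integer seed.
#' @return List with `p`, `observed`, `pseudo_mean`, `pseudo_sd`.
#' @export
density_permutation_test <- function(TO, module_genes, n_pseudo = 10000L,
                                     seed = 1L) {
  n <- nrow(TO)
  size <- length(module_genes)
  if (size > n) stop("module larger than the network")
  obs <- module_density(TO, module_genes)
  if (size == n) {
    warning("module spans the whole network; p = 0 by convention")
    return(list(p = 0, observed = obs, pseudo_mean = obs, pseudo_sd = 0))
  }
  ut <- upper.tri(matrix(0, size, size))
  withr::with_seed(seed, {
    dens <- vapply(seq_len(n_pseudo), function(b) {
      idx <- sample.int(n, size)
      mean(TO[idx, idx][ut])
    }, numeric(1))
  })
  list(p = sum(dens > obs) / n_pseudo, observed = obs,
       pseudo_mean = mean(dens), pseudo_sd = stats::sd(dens))
}

build_network_once <- function(v, params) {
  a <- signed_adjacency(v, params$beta)
  to <- topological_overlap(a)
  cc <- cluster_and_cut(to, params$min_module_size, params$gap_depth)
  labs <- cc$labels
  # kME rescue: peripheral genes peeled by the tree cut rejoin the module
  # whose eigengene they track most closely, at the conventional 0.5 cutoff
  mods <- setdiff(unique(labs), "grey")
  grey_i <- which(labs == "grey")
  if (length(mods) && length(grey_i) && !is.null(params$kme_reassign)) {
    mes <- vapply(mods, function(mod)
      module_eigengene(v, which(labs == mod)), numeric(ncol(v)))
    km <- stats::cor(t(v[grey_i, , drop = FALSE]), mes)
    best <- max.col(km, ties.method = "first")
    rescue <- km[cbind(seq_along(grey_i), best)] >= params$kme_reassign
    labs[grey_i[rescue]] <- mods[best[rescue]]
  }
  list(TO = to, labels = labs, hclust = cc$hclust)
}

#' Iterative density-based module filtering
#'
#' Builds the signed network, detects modules, density-tests each against
#' pseudo-modules, removes genes in failing modules together with grey
#' genes, and rebuilds on the survivors, iterating until every module
#' passes (p <= `density_alpha`) and no grey genes remain, or nothing is
#' left.
#'
#' @param m Preprocessed `expr_matrix` or genes x samples numeric matrix.
#' @param params A [network_params()].
#' @return A `module_set`: list with `labels` (final named labels),
#'   `modules` (per-module size, density, density_p), `TO` (final matrix),
#'   `hclust`, `iterations`, `removed_log` (genes removed per round),
#'   `params`.
#' @export
iterative_density_filter <- function(m, params = network_params()) {
  v <- if (inherits(m, "expr_matrix")) expr_values(m, "gene_mean") else m
  removed_log <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    if (round_i > params$max_rounds) {
      e <- simpleError("density filter did not converge")
      e$log <- removed_log
      stop(e)
    }
    if (nrow(v) < params$min_module_size) {
      # nothing left big enough to form a module: empty final network
      return(structure(list(labels = stats::setNames(character(0),
                                                     character(0)),
                            modules = data.frame(module = character(0),
                                                 size = integer(0),
                                                 density = numeric(0),
                                                 density_p = numeric(0)),
                            TO = NULL, hclust = NULL,
                            iterations = round_i,
                            removed_log = removed_log, params = params),
                       class = "module_set"))
    }
    net <- build_network_once(v, params)
    labs <- net$labels
    mods <- setdiff(unique(labs), "grey")
    if (length(mods) == 0) {
      removed_log[[round_i]] <- rownames(v)
      v <- v[0, , drop = FALSE]
      next
    }
    dens <- lapply(stats::setNames(mods, mods), function(mod) {
      density_permutation_test(net$TO, which(labs == mod),
                               n_pseudo = params$n_pseudo,
                               seed = params$seed + round_i)
    })
    fail <- vapply(dens, function(x) x$p > params$density_alpha, logical(1))
    grey_genes <- names(labs)[labs == "grey"]
    fail_genes <- names(labs)[labs %in% mods[fail]]
    drop <- union(grey_genes, fail_genes)
    if (length(drop) == 0) {
      mtab <- data.frame(
        module = mods,
        size = as.integer(table(labs)[mods]),
        density = vapply(dens, `[[`, numeric(1), "observed"),
        density_p = vapply(dens, `[[`, numeric(1), "p"),
        stringsAsFactors = FALSE)
      rownames(mtab) <- NULL
      return(structure(list(labels = labs, modules = mtab, TO = net$TO,
                            hclust = net$hclust, iterations = round_i,
                            removed_log = removed_log, params = params),
                       class = "module_set"))
    }
    removed_log[[round_i]] <- drop
    v <- v[setdiff(rownames(v), drop), , drop = FALSE]
  }
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules over %d genes (%d filter rounds)\n",
              nrow(x$modules), length(x$labels), x$iterations))
  if (nrow(x$modules)) print(x$modules)
  invisible(x)
}

#' Module quality Z from label permutations
#'
#' Z = (observed density - mean permuted density) / SD of permuted density,
#' where permutations shuffle the gene-to-module assignment while keeping
#' module sizes; Z > 10 is read as strong evidence of a dense, distinct,
#' reproducible module.
#'
#' @param TO Topological overlap matrix over the labeled genes.
#' @param labels Named module labels (as in a `module_set`).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return Named per-module Z vector (`Inf` when the permutation SD is 0).
#' @export
module_quality_z <- function(TO, labels, n_perm = 200L, seed = 1L) {
  mods <- setdiff(unique(labels), "grey")
  genes <- names(labels)
  stopifnot(all(genes %in% rownames(TO)))
  obs <- vapply(stats::setNames(mods, mods), function(mod)
    module_density(TO[genes, genes], which(labels == mod)), numeric(1))
  perm <- matrix(NA_real_, n_perm, length(mods),
                 dimnames = list(NULL, mods))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pl <- sample(labels)
      perm[b, ] <- vapply(mods, function(mod)
        module_density(TO[genes, genes], which(pl == mod)), numeric(1))
    }
  })
  mu <- colMeans(perm)
  s <- apply(perm, 2L, stats::sd)
  z <- (obs - mu) / s
  z[s == 0] <- Inf
  z
}

#' Eigengenes and kME for every module in a module set
#'
#' @param m The expression matrix the network was built from.
#' @param ms A `module_set`.
#' @return List with `eigengenes` (modules x samples matrix) and `kme`
#'   (genes x modules matrix over the network's genes).
#' @export
module_set_eigengenes <- function(m, ms) {
  v <- if (inherits(m, "expr_matrix")) expr_values(m, "gene_mean") else m
  mods <- ms$modules$module
  genes <- names(ms$labels)
  me <- t(vapply(mods, function(mod)
    module_eigengene(v, genes[ms$labels == mod]), numeric(ncol(v))))
  rownames(me) <- mods
  km <- vapply(mods, function(mod) kme(v[genes, , drop = FALSE], me[mod, ]),
               numeric(length(genes)))
  list(eigengenes = me, kme = km)
}

#' Module-trait analysis
#'
#' Correlates each module eigengene with each colony trait (replicated to
#' samples), regresses member |trait correlation| on kME within each
#' module, and, when a decile table is supplied, regresses module mean
#' trait correlation on module mean dN/dS decile across modules.
#'
#' @param m Expression `expr_matrix` (with colony metadata).
#' @param ms A `module_set`.
#' @param traits Colony trait table.
#' @param trait_names Trait columns to analyse.
#' @param deciles Optional named per-gene aggregate dN/dS deciles.
#' @return List with `me_trait` (module x trait r and p),
#'   `kme_traitr` (per module slope/p of |r| on kME, per trait), and
#'   optionally `module_decile_regression`.
#' @export
module_trait_analysis <- function(m, ms, traits,
                                  trait_names = c("humidity", "da5ht"),
                                  deciles = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  eg <- module_set_eigengenes(m, ms)
  mods <- ms$modules$module
  n_s <- ncol(m$values)
  me_trait <- do.call(rbind, lapply(mods, function(mod) {
    row <- data.frame(module = mod, stringsAsFactors = FALSE)
    for (tr in trait_names) {
      x <- replicate_trait(m, traits, tr)
      if (stats::sd(x) == 0) {
        row[[paste0("r_", tr)]] <- NA_real_
        row[[paste0("p_", tr)]] <- NA_real_
      } else {
        ct <- stats::cor.test(eg$eigengenes[mod, ], x)
        row[[paste0("r_", tr)]] <- unname(ct$estimate)
        row[[paste0("p_", tr)]] <- ct$p.value
      }
    }
    row
  }))
  kme_traitr <- do.call(rbind, lapply(mods, function(mod) {
    members <- names(ms$labels)[ms$labels == mod]
    out <- data.frame(module = mod, stringsAsFactors = FALSE)
    for (tr in trait_names) {
      rr <- abs(per_sample_trait_correlation(
        subset_expr(m, genes = match(members, rownames(m$values))),
        traits, tr))
      kk <- eg$kme[match(members, names(ms$labels)), mod]
      fit <- stats::lm(rr ~ kk)
      sm <- summary(fit)
      out[[paste0("slope_", tr)]] <- unname(stats::coef(fit)[2])
      out[[paste0("p_", tr)]] <-
        if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
    }
    out
  }))
  res <- list(me_trait = me_trait, kme_traitr = kme_traitr,
              eigengenes = eg$eigengenes, kme = eg$kme)
  if (!is.null(deciles)) {
    mdr <- lapply(trait_names, function(tr) {
      mean_r <- vapply(mods, function(mod) {
        members <- names(ms$labels)[ms$labels == mod]
        mean(per_sample_trait_correlation(
          subset_expr(m, genes = match(members, rownames(m$values))),
          traits, tr), na.rm = TRUE)
      }, numeric(1))
      mean_dec <- vapply(mods, function(mod) {
        members <- names(ms$labels)[ms$labels == mod]
        mean(deciles[members], na.rm = TRUE)
      }, numeric(1))
      if (length(mods) >= 3 && stats::sd(mean_dec) > 0) {
        fit <- summary(stats::lm(mean_r ~ mean_dec))
        data.frame(trait = tr, slope = fit$coefficients[2, 1],
                   p = fit$coefficients[2, 4],
                   r_squared = fit$r.squared, n_modules = length(mods))
      } else {
        data.frame(trait = tr, slope = NA_real_, p = NA_real_,
                   r_squared = NA_real_, n_modules = length(mods))
      }
    })
    res$module_decile_regression <- do.call(rbind, mdr)
  }
  res
}

#' Compare module eigengene expression across colonies
#'
#' Per module, a one-way ANOVA of the eigengene across colonies plus
#' Tukey honest-significant-difference pairwise colony contrasts.
#'
#' @param m Expression `expr_matrix` with colony metadata.
#' @param ms A `module_set`.
#' @param min_colony_n Colonies with fewer samples are excluded (warning).
#' @return List with `anova` (module, F, p) and `contrasts` (per module,
#'   one row per colony pair: estimate, p_adj; Tukey-corrected).
#' @export
me_colony_comparison <- function(m, ms, min_colony_n = 2L) {
  stopifnot(inherits(m, "expr_matrix"))
  colony <- m$sample_meta$colony
  tab <- table(colony)
  small <- names(tab)[tab < min_colony_n]
  if (length(small)) {
    warning("excluding singleton colonies: ", paste(small, collapse = ", "))
  }
  keep <- !(colony %in% small)
  if (length(unique(colony[keep])) < 2) stop("need at least 2 colonies")
  eg <- module_set_eigengenes(m, ms)$eigengenes[, keep, drop = FALSE]
  g <- factor(colony[keep])
  anova_rows <- list(); contrast_rows <- list()
  for (mod in rownames(eg)) {
    fit <- stats::aov(eg[mod, ] ~ g)
    sm <- summary(fit)[[1L]]
    anova_rows[[mod]] <- data.frame(module = mod, F = sm$`F value`[1],
                                    p = sm$`Pr(>F)`[1],
                                    stringsAsFactors = FALSE)
    tk <- stats::TukeyHSD(fit)$g
    contrast_rows[[mod]] <- data.frame(module = mod,
                                       contrast = rownames(tk),
                                       estimate = tk[, "diff"],
                                       p_adj = tk[, "p adj"],
                                       stringsAsFactors = FALSE)
  }
  list(anova = do.call(rbind, c(anova_rows, make.row.names = FALSE)),
       contrasts = do.call(rbind, c(contrast_rows,
                                    make.row.names = FALSE)),
       correction = "tukey")
}
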