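#' Principal component analysis of samples
#'
#' PCA on the sample-space of a log-expression matrix: genes are centered
#' (not scaled) and samples projected onto the leading components.
#'
#' @param m An `expr_matrix` (log scale recommended) or numeric matrix
#'   (genes x samples).
#' @param k Number of components to return; truncated to the matrix rank
#'   with a warning if too large.
#' @return List with `scores` (samples x k), `variance_explained` (length
#'   k, fractions of total variance, non-increasing).
#' @export
pca_samples <- function(m, k = 3L) {
  v <- if (inherits(m, "expr_matrix")) expr_values(m, "gene_mean") else m
  if (ncol(v) < 2) stop("need at least 2 samples")
  p <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  r <- sum(p$sdev > max(p$sdev) * 1e-10)
  if (k > r) {
    warning("k exceeds matrix rank; truncating to ", r)
    k <- r
  }
  list(scores = p$x[, seq_len(k), drop = FALSE],
       variance_explained = ve[seq_len(k)],
       rotation = p$rotation[, seq_len(k), drop = FALSE])
}

#' Linear discriminant analysis of colonies on PC scores
#'
#' @param scores Samples x PCs score matrix (typically the first 30 PCs).
#' @param labels Colony label per sample (factor or character).
#' @return List with `axes` (discriminant coefficients), `projections`
#'   (samples x discriminants, at most `nlevels - 1`), `labels`, and `lda`
#'   (the underlying [MASS::lda] fit).
#' @export
lda_on_pcs <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 colony labels")
  if (any(table(labels) < 2))
    stop("every colony needs at least 2 samples: ",
         paste(names(which(table(labels) < 2)), collapse = ", "))
  fit <- MASS::lda(scores, grouping = labels)
  proj <- stats::predict(fit, scores)$x
  list(axes = fit$scaling, projections = proj, labels = labels, lda = fit)
}

#' k-nearest-neighbor sample network on correlation distance
#'
#' Links each sample to its `k_neighbors` nearest samples under
#' 1 - Pearson correlation distance, deduplicates to an undirected edge
#' list, and reports the fraction of edges joining nestmates (same-colony
#' samples) with a label-permutation p-value.
#'
#' @param m An `expr_matrix` or numeric genes x samples matrix.
#' @param k_neighbors Neighbors per sample (< number of samples).
#' @param n_perm Label permutations for the nestmate-fraction null.
#' @param seed Seed for the permutations.
#' @return List with `edges` (data frame from, to, distance),
#'   `nestmate_edge_fraction`, `perm_p`, `n_directed_edges`.
#' @export
sample_distance_network <- function(m, k_neighbors = 3L, n_perm = 1000L,
                                    seed = 1L) {
  v <- if (inherits(m, "expr_matrix")) expr_values(m, "gene_mean") else m
  n <- ncol(v)
  if (k_neighbors >= n) stop("k_neighbors must be < number of samples")
  colony <- if (inherits(m, "expr_matrix")) m$sample_meta$colony else NULL
  d <- 1 - stats::cor(v)
  diag(d) <- Inf
  from <- rep(seq_len(n), each = k_neighbors)
  to <- integer(n * k_neighbors)
  for (i in seq_len(n)) {
    to[((i - 1L) * k_neighbors + 1L):(i * k_neighbors)] <-
      order(d[, i])[seq_len(k_neighbors)]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  edges <- data.frame(from = colnames(v)[a[keep]], to = colnames(v)[b[keep]],
                      distance = d[cbind(a[keep], b[keep])],
                      stringsAsFactors = FALSE)
  res <- list(edges = edges, n_directed_edges = n * k_neighbors,
              nestmate_edge_fraction = NA_real_, perm_p = NA_real_)
  if (!is.null(colony)) {
    ai <- a[keep]; bi <- b[keep]
    frac <- mean(colony[ai] == colony[bi])
    withr::with_seed(seed, {
      null <- replicate(n_perm, {
        cp <- sample(colony)
        mean(cp[ai] == cp[bi])
      })
    })
    res$nestmate_edge_fraction <- frac
    res$perm_p <- (sum(null >= frac) + 1) / (n_perm + 1)
    res$null_mean <- mean(null)
  }
  res
}

replicate_trait <- function(m, traits, trait) {
  colony <- m$sample_meta$colony
  if (!all(colony %in% traits$colony))
    stop("traits table missing colonies: ",
         paste(setdiff(colony, traits$colony), collapse = ", "))
  traits[[trait]][match(colony, traits$colony)]
}

#' Per-gene expression-trait correlation at the single-forager level
#'
#' Pearson correlation of each gene's per-sample expression with the colony
#' trait value replicated to every nestmate (the N = samples estimator).
#' Constant genes yield `NA`.
#'
#' @param m An `expr_matrix` (log scale recommended).
#' @param traits Colony trait table (`colony` plus trait columns).
#' @param trait Trait column name (`"humidity"` or `"da5ht"`).
#' @return Named numeric vector of per-gene correlations.
#' @export
per_sample_trait_correlation <- function(m, traits, trait) {
  v <- expr_values(m, "gene_mean")
  x <- replicate_trait(m, traits, trait)
  r <- suppressWarnings(as.numeric(stats::cor(t(v), x)))
  names(r) <- rownames(v)
  r
}

#' Per-gene expression-trait correlation at the colony-mean level
#'
#' Pearson correlation of colony-average expression with the colony trait
#' (the N = colonies estimator).
#'
#' @inheritParams per_sample_trait_correlation
#' @return Named numeric vector of per-gene correlations.
#' @export
colony_mean_trait_correlation <- function(m, traits, trait) {
  v <- expr_values(m, "gene_mean")
  colony <- m$sample_meta$colony
  cols <- sort(unique(colony))
  cm <- vapply(cols, function(cl)
    rowMeans(v[, colony == cl, drop = FALSE]), numeric(nrow(v)))
  x <- traits[[trait]][match(cols, traits$colony)]
  r <- suppressWarnings(as.numeric(stats::cor(t(cm), x)))
  names(r) <- rownames(v)
  r
}

#' Agreement between the two trait-correlation estimators
#'
#' @param r_sample,r_colony Aligned per-gene correlation vectors; pairs with
#'   a missing value are dropped.
#' @return List with `pearson_r`, `r_squared` (= r^2), `p` (two-sided test
#'   of zero correlation), `n`.
#' @export
correlation_method_agreement <- function(r_sample, r_colony) {
  ok <- is.finite(r_sample) & is.finite(r_colony)
  if (sum(ok) < 3) stop("fewer than 3 complete gene pairs")
  ct <- stats::cor.test(r_sample[ok], r_colony[ok])
  list(pearson_r = unname(ct$estimate),
       r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = sum(ok))
}

#' Per-gene one-way ANOVA F across colonies
#'
#' Among-colony mean square over within-colony mean square, df = (k-1, N-k).
#' Genes with distinct colony means but zero within-colony variance get an
#' `Inf` sentinel.
#'
#' @param m An `expr_matrix`.
#' @param labels Optional colony labels (defaults to `sample_meta$colony`).
#' @return Data frame with `gene`, `F`, `p`, `df1`, `df2`.
#' @export
per_gene_colony_F <- function(m, labels = NULL) {
  v <- if (inherits(m, "expr_matrix")) expr_values(m, "gene_mean") else m
  if (is.null(labels)) labels <- m$sample_meta$colony
  g <- factor(labels)
  k <- nlevels(g); n <- ncol(v)
  if (k < 2) stop("need at least 2 colonies")
  if (any(table(g) < 2)) stop("every colony needs at least 2 samples")
  grand <- rowMeans(v)
  ssb <- rep(0, nrow(v)); ssw <- rep(0, nrow(v))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    cm <- rowMeans(v[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (cm - grand)^2
    ssw <- ssw + rowSums((v[, idx, drop = FALSE] - cm)^2)
  }
  df1 <- k - 1; df2 <- n - k
  Fs <- (ssb / df1) / (ssw / df2)
  Fs[ssw == 0 & ssb > 0] <- Inf
  p <- stats::pf(Fs, df1, df2, lower.tail = FALSE)
  data.frame(gene = rownames(v), F = Fs, p = p, df1 = df1, df2 = df2,
             stringsAsFactors = FALSE)
}

#' One-sample t test of a candidate list's mean trait correlation
#'
#' Tests whether the mean of the list members' summary trait-correlation
#' coefficients differs from zero (two-sided).
#'
#' @param r_values Named per-gene summary coefficients (the per-sample
#'   estimator).
#' @param gene_list Character vector of candidate gene ids.
#' @return List with `t`, `df`, `p_two_sided`, `mean_r`, `n_used`.
#' @export
candidate_list_test <- function(r_values, gene_list) {
  r <- r_values[intersect(gene_list, names(r_values))]
  r <- r[is.finite(r)]
  if (length(r) < 2) stop("fewer than 2 usable genes in the list")
  tt <- stats::t.test(r, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, mean_r = mean(r), n_used = length(r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Standard t transform: \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2 df.
#'
#' @param r Correlation coefficient(s).
#' @param n Number of pairs used.
#' @return Two-sided p-value(s); `NA` where `r` is missing.
#' @export
correlation_p <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Full expression-trait correlation table
#'
#' Both correlation estimators and the colony ANOVA F for every gene and
#' both traits. The summary coefficient carried downstream is `r_sample`.
#'
#' @param m An `expr_matrix`.
#' @param traits Colony trait table.
#' @param trait_names Trait columns to analyse.
#' @return Data frame with one row per gene and, per trait, columns
#'   `r_sample_<trait>` and `r_colony_<trait>`, plus `F`, `F_p`.
#' @export
trait_correlation_table <- function(m, traits,
                                    trait_names = c("humidity", "da5ht")) {
  out <- data.frame(gene = rownames(m$values), stringsAsFactors = FALSE)
  for (tr in trait_names) {
    out[[paste0("r_sample_", tr)]] <- per_sample_trait_correlation(m, traits,
                                                                   tr)
    out[[paste0("r_colony_", tr)]] <- colony_mean_trait_correlation(m,
                                                                    traits,
                                                                    tr)
  }
  f <- per_gene_colony_F(m)
  out$F <- f$F
  out$F_p <- f$p
  out
}
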