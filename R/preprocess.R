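#' Convert raw counts to transcripts per million (TPM)
#'
#' Per sample, TPM for gene g is \eqn{10^6 (c_g/l_g) / \sum_h (c_h/l_h)}:
#' counts are first divided by gene length (in any consistent unit), then
#' rescaled so every column sums to one million.
#'
#' @param counts An `expr_matrix` in `"counts"` unit.
#' @param gene_lengths Named positive numeric vector covering every gene.
#' @return An `expr_matrix` in `"tpm"` unit.
#' @export
counts_to_tpm <- function(counts, gene_lengths) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$unit != "counts") stop("input must be in 'counts' unit")
  genes <- rownames(counts$values)
  if (!all(genes %in% names(gene_lengths)))
    stop("gene_lengths missing for some genes")
  len <- gene_lengths[genes]
  if (any(!is.finite(len)) || any(len <= 0))
    stop("gene lengths must be positive and finite")
  rate <- counts$values / len
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero sample(s): ", paste(colnames(counts$values)[tot == 0],
                                       collapse = ", "))
  out <- counts
  out$values <- sweep(rate, 2L, tot, "/") * 1e6
  out$unit <- "tpm"
  stamp(out, "counts_to_tpm")
}

#' Filter genes on variance, median TPM and zero-expression fraction
#'
#' Removes genes with zero variance across samples, median TPM below 0.5
#' (strictly; a median of exactly 0.5 is kept), or zero expression in more
#' than one-third of samples (exactly one-third is kept).
#'
#' @param m An `expr_matrix` in `"tpm"` unit.
#' @param median_tpm_min Median-TPM threshold (genes with median strictly
#'   below are removed). Default 0.5.
#' @param zero_fraction_max Maximum tolerated fraction of zero-expression
#'   samples. Default 1/3.
#' @return A list with elements `matrix` (filtered `expr_matrix`) and
#'   `report` (per-rule removal counts).
#' @export
filter_genes <- function(m, median_tpm_min = 0.5, zero_fraction_max = 1 / 3) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "tpm") stop("filter_genes expects TPM values")
  v <- m$values
  novar <- apply(v, 1L, stats::var) == 0
  lowmed <- apply(v, 1L, stats::median) < median_tpm_min
  zfrac <- rowMeans(v == 0)
  toozero <- zfrac > zero_fraction_max
  drop <- novar | lowmed | toozero
  report <- list(
    n_genes_in = nrow(v),
    n_genes_removed = sum(drop),
    n_genes_removed_by_rule = c(no_variance = sum(novar),
                                low_median = sum(lowmed),
                                too_many_zeros = sum(toozero)),
    n_genes_retained = sum(!drop)
  )
  if (all(drop)) {
    e <- simpleError("all genes removed by filtering")
    e$report <- report
    stop(e)
  }
  out <- subset_expr(m, genes = which(!drop))
  out <- stamp(out, "filter_genes")
  list(matrix = out, report = report)
}

#' Log-transform TPM values
#'
#' @param m An `expr_matrix` in `"tpm"` unit.
#' @param pseudocount Non-negative offset added before taking log2.
#' @return An `expr_matrix` in `"logtpm"` unit with values
#'   \eqn{\log_2(\mathrm{TPM} + pseudocount)}.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "tpm") stop("log_transform expects TPM values")
  if (!is.finite(pseudocount) || pseudocount < 0)
    stop("pseudocount must be non-negative")
  out <- m
  out$values <- log2(m$values + pseudocount)
  out$unit <- "logtpm"
  stamp(out, "log_transform")
}

#' Iteratively mask outlier expression values and remove outlier samples
#'
#' Within each iteration, values more than `gene_sd_k` standard deviations
#' from their gene's mean (computed over unmasked values) are masked out
#' first; then samples whose mean inter-sample Pearson correlation falls more
#' than `sample_sd_k` SD below or above the overall mean correlation are
#' removed. Repeats until a full pass changes nothing.
#'
#' @param m An `expr_matrix` in `"logtpm"` unit with at least 3 samples.
#' @param gene_sd_k SD multiple for per-gene value masking (default 3).
#' @param sample_sd_k SD multiple for sample removal (default 2).
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   partial report.
#' @return List with `matrix` (masked/trimmed `expr_matrix`) and `report`
#'   (`iterations`, `n_values_masked`, `n_samples_removed`,
#'   `removed_samples`).
#' @export
iterative_outlier_removal <- function(m, gene_sd_k = 3, sample_sd_k = 2,
                                      max_iter = 20L) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "logtpm") stop("expects log-TPM values")
  if (ncol(m$values) < 3) stop("need at least 3 samples")
  v <- m$values
  mask <- if (is.null(m$mask)) {
    matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  } else m$mask
  removed_samples <- character(0)
  n_masked_total <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      e <- simpleError("iterative outlier removal did not converge")
      e$report <- list(iterations = iter - 1L,
                       n_values_masked = n_masked_total,
                       n_samples_removed = length(removed_samples),
                       removed_samples = removed_samples)
      stop(e)
    }
    changed <- FALSE
    vv <- v
    vv[mask] <- NA
    gm <- rowMeans(vv, na.rm = TRUE)
    gsd <- apply(vv, 1L, stats::sd, na.rm = TRUE)
    dev <- abs(vv - gm)
    lim <- gene_sd_k * gsd
    new_mask <- !is.na(dev) & gsd > 0 & dev > lim
    if (any(new_mask)) {
      mask <- mask | new_mask
      n_masked_total <- n_masked_total + sum(new_mask)
      changed <- TRUE
      vv[new_mask] <- NA
    }
    # sample pass on the freshly masked values
    if (ncol(vv) >= 3) {
      cc <- stats::cor(vv, use = "pairwise.complete.obs")
      diag(cc) <- NA
      mic <- rowMeans(cc, na.rm = TRUE)
      mu <- mean(mic); s <- stats::sd(mic)
      bad <- s > 0 & abs(mic - mu) > sample_sd_k * s
      if (any(bad)) {
        removed_samples <- c(removed_samples, colnames(vv)[bad])
        keep <- which(!bad)
        v <- v[, keep, drop = FALSE]
        mask <- mask[, keep, drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- m
  out$values <- v
  out$mask <- mask
  out$sample_meta <- m$sample_meta[match(colnames(v), m$sample_meta$sample), ,
                                   drop = FALSE]
  rownames(out$sample_meta) <- NULL
  out <- stamp(out, "outlier_removal")
  list(matrix = out,
       report = list(iterations = iter,
                     n_values_masked = n_masked_total,
                     n_samples_removed = length(removed_samples),
                     removed_samples = removed_samples))
}

#' Quantile normalize samples
#'
#' Masked cells are first imputed by the gene's unmasked mean, then every
#' sample's empirical distribution is replaced by the vector of cross-sample
#' rank means (ties get the mean of the tied rank values), preserving
#' per-sample ranks.
#'
#' @param m An `expr_matrix`.
#' @return An `expr_matrix` with identical column distributions and no mask.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- expr_values(m, impute = "gene_mean")
  qn <- limma::normalizeQuantiles(v)
  dimnames(qn) <- dimnames(v)
  out <- m
  out$values <- qn
  out$mask <- NULL
  stamp(out, "quantile_normalize")
}

#' Adjust batch effects by per-gene location-scale standardization
#'
#' For each gene, effects of the protected covariates are estimated by linear
#' regression and set aside; the residuals are then centered and rescaled
#' within each batch (each batch's residual mean is moved to the pooled
#' residual mean and its SD to the pooled residual SD), and the protected
#' fit is restored. After adjustment, per-gene batch means are equal up to
#' the protected structure.
#'
#' @param m An `expr_matrix` (typically log-TPM, quantile normalized).
#' @param batch_var Name of the `sample_meta` column holding the batch label.
#' @param protect Character vector of `sample_meta` columns whose effects are
#'   preserved (e.g., `"colony"`). May be empty.
#' @return The adjusted `expr_matrix`.
#' @export
batch_adjust <- function(m, batch_var = "batch", protect = character(0)) {
  stopifnot(inherits(m, "expr_matrix"))
  meta <- m$sample_meta
  if (!batch_var %in% names(meta))
    stop("no '", batch_var, "' column in sample_meta")
  batch <- factor(meta[[batch_var]])
  tab <- table(batch)
  if (any(tab < 2))
    stop("singleton batch: ", paste(names(tab)[tab < 2], collapse = ", "))
  if (nlevels(batch) < 2) return(stamp(m, "batch_adjust(noop)"))
  v <- expr_values(m, impute = "gene_mean")
  if (length(protect)) {
    miss <- setdiff(protect, names(meta))
    if (length(miss)) stop("protected covariates not in sample_meta: ",
                           paste(miss, collapse = ", "))
    X <- stats::model.matrix(
      stats::reformulate(protect), data = meta)
  } else {
    X <- matrix(1, ncol(v), 1L)
  }
  # one multi-response least squares fit for all genes at once
  fit <- stats::lm.fit(X, t(v))
  fitted_part <- t(X %*% fit$coefficients)
  resid <- v - fitted_part
  adj <- resid
  pooled_mean <- rowMeans(resid)
  pooled_sd <- apply(resid, 1L, stats::sd)
  for (b in levels(batch)) {
    idx <- which(batch == b)
    bm <- rowMeans(resid[, idx, drop = FALSE])
    bs <- apply(resid[, idx, drop = FALSE], 1L, stats::sd)
    scale_fac <- ifelse(bs > 0 & pooled_sd > 0, pooled_sd / bs, 1)
    adj[, idx] <- (resid[, idx, drop = FALSE] - bm) * scale_fac + pooled_mean
  }
  out <- m
  out$values <- adj + fitted_part
  out$mask <- NULL
  stamp(out, "batch_adjust")
}

#' Run the full preprocessing chain
#'
#' counts-to-TPM (if needed), gene filtering, log2 transform, iterative
#' outlier masking/sample removal, quantile normalization and batch
#' adjustment, in that fixed order.
#'
#' @param m An `expr_matrix` in `"counts"` or `"tpm"` unit.
#' @param gene_lengths Needed only when `m` is in counts.
#' @param pseudocount Passed to [log_transform()].
#' @param gene_sd_k,sample_sd_k,max_iter Passed to
#'   [iterative_outlier_removal()].
#' @param median_tpm_min,zero_fraction_max Passed to [filter_genes()].
#' @param batch_var,protect Passed to [batch_adjust()]; set
#'   `batch_var = NULL` to skip batch adjustment.
#' @return List with `matrix` (preprocessed `expr_matrix`) and `report`
#'   (combined filter and outlier reports).
#' @export
preprocess_expression <- function(m, gene_lengths = NULL, pseudocount = 1,
                                  gene_sd_k = 3, sample_sd_k = 2,
                                  max_iter = 20L,
                                  median_tpm_min = 0.5,
                                  zero_fraction_max = 1 / 3,
                                  batch_var = "batch",
                                  protect = "colony") {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit == "counts") {
    if (is.null(gene_lengths)) stop("counts input requires gene_lengths")
    m <- counts_to_tpm(m, gene_lengths)
  }
  fg <- filter_genes(m, median_tpm_min = median_tpm_min,
                     zero_fraction_max = zero_fraction_max)
  lg <- log_transform(fg$matrix, pseudocount = pseudocount)
  ol <- iterative_outlier_removal(lg, gene_sd_k = gene_sd_k,
                                  sample_sd_k = sample_sd_k,
                                  max_iter = max_iter)
  qn <- quantile_normalize(ol$matrix)
  out <- if (!is.null(batch_var) &&
             batch_var %in% names(qn$sample_meta) &&
             length(unique(qn$sample_meta[[batch_var]])) > 1) {
    batch_adjust(qn, batch_var = batch_var,
                 protect = intersect(protect, names(qn$sample_meta)))
  } else qn
  list(matrix = out,
       report = list(filter = fg$report, outliers = ol$report))
}
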