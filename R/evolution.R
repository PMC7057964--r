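#' Recode values as deciles
#'
#' Rank-based bins: a gene's decile is `ceiling(10 * rank / n)` with
#' minimum ties ranking, so all tied values share the lower decile and bin
#' sizes stay within one of n/10 for distinct inputs. Invariant under any
#' strictly monotone transform of the values. Missing values stay missing.
#'
#' @param values Numeric vector (at least 10 non-missing values).
#' @return Integer vector of deciles 1-10 (NA preserved).
#' @export
decile_recode <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 10) stop("need at least 10 non-missing values")
  r <- rank(values[ok], ties.method = "min")
  dec <- as.integer(ceiling(10 * r / sum(ok)))
  out <- rep(NA_integer_, length(values))
  out[ok] <- dec
  out
}

#' Build a dN/dS decile table joined with expression covariates
#'
#' Recodes every species' non-missing dN/dS values to deciles, averages
#' them into a per-gene aggregate decile, and joins the expression-side
#' covariates used by the constraint models.
#'
#' @param dnds Data frame with `gene` and one `dnds_*` column per species.
#' @param expr Optional `expr_matrix` (TPM or log) to derive `median_tpm`
#'   and `expr_sd` from; ignored if both are passed directly.
#' @param trait_r Optional named per-gene |summary trait correlation|.
#' @param kme_values Optional named per-gene kME (module centrality).
#' @param module_labels Optional named per-gene module labels.
#' @return Data frame with `gene`, per-species `decile_*` columns,
#'   `decile` (aggregate), and any supplied covariates (`abs_trait_r`,
#'   `kme`, `median_tpm`, `expr_sd`, `module`).
#' @export
dnds_decile_table <- function(dnds, expr = NULL, trait_r = NULL,
                              kme_values = NULL, module_labels = NULL) {
  stopifnot("gene" %in% names(dnds))
  sp_cols <- grep("^dnds_", names(dnds), value = TRUE)
  if (!length(sp_cols)) stop("no dnds_* species columns found")
  out <- data.frame(gene = dnds$gene, stringsAsFactors = FALSE)
  decs <- matrix(NA_real_, nrow(dnds), length(sp_cols))
  for (i in seq_along(sp_cols)) {
    d <- decile_recode(dnds[[sp_cols[i]]])
    out[[sub("^dnds_", "decile_", sp_cols[i])]] <- d
    decs[, i] <- d
  }
  out$decile <- rowMeans(decs, na.rm = TRUE)
  out$decile[!is.finite(out$decile)] <- NA_real_
  if (!is.null(expr)) {
    v <- expr_values(expr, "gene_mean")
    idx <- match(out$gene, rownames(v))
    out$median_tpm <- apply(v, 1L, stats::median)[idx]
    out$expr_sd <- apply(v, 1L, stats::sd)[idx]
  }
  if (!is.null(trait_r)) out$abs_trait_r <- abs(trait_r[out$gene])
  if (!is.null(kme_values)) out$kme <- kme_values[out$gene]
  if (!is.null(module_labels)) {
    out$module <- module_labels[out$gene]
    out$module[is.na(out$module)] <- "none"
  }
  out
}

#' Constraint GLM: dN/dS decile on centrality and trait correlation
#'
#' Gaussian identity-link model of the aggregate decile on |trait r| and
#' kME, with median expression and expression SD as covariates (any subset
#' of predictors present in the table is used). An ordinal-logit
#' alternative is available for sensitivity analysis.
#'
#' @param table Output of [dnds_decile_table()] with the needed columns.
#' @param predictors Predictor column names present in `table`.
#' @param family `"gaussian"` (default) or `"ordinal"` (proportional-odds
#'   logit via [MASS::polr] on the rounded decile).
#' @param max_kappa Condition-number threshold for the collinearity check.
#' @return Data frame with one row per predictor: `term`, `estimate`,
#'   `se`, `p`.
#' @export
constraint_glm <- function(table,
                           predictors = c("abs_trait_r", "kme",
                                          "median_tpm", "expr_sd"),
                           family = c("gaussian", "ordinal"),
                           max_kappa = 1e6) {
  family <- match.arg(family)
  predictors <- intersect(predictors, names(table))
  if (!length(predictors)) stop("no predictor columns present")
  cols <- c("decile", predictors)
  dat <- table[stats::complete.cases(table[, cols]), cols, drop = FALSE]
  if (nrow(dat) < 30) stop("need at least 30 complete rows")
  if (stats::sd(dat$decile) == 0) stop("decile response is constant")
  X <- as.matrix(dat[, predictors, drop = FALSE])
  kap <- kappa(cbind(1, scale(X)), exact = TRUE)
  if (!is.finite(kap) || kap > max_kappa)
    stop("predictors nearly collinear: ", paste(predictors, collapse = ", "))
  f <- stats::reformulate(predictors, response = "decile")
  if (family == "gaussian") {
    fit <- stats::glm(f, data = dat, family = stats::gaussian())
    cf <- summary(fit)$coefficients
    rows <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
    data.frame(term = rownames(rows), estimate = rows[, 1],
               se = rows[, 2], p = rows[, 4], row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    dat$decile <- factor(round(dat$decile), ordered = TRUE)
    fit <- MASS::polr(f, data = dat, Hess = TRUE)
    cf <- summary(fit)$coefficients[predictors, , drop = FALSE]
    p <- 2 * stats::pnorm(-abs(cf[, "t value"]))
    data.frame(term = rownames(cf), estimate = cf[, "Value"],
               se = cf[, "Std. Error"], p = p, row.names = NULL,
               stringsAsFactors = FALSE)
  }
}

#' One-sample t test of a module's mean decile against the genomic mean
#'
#' The reference is the mean aggregate decile over all decile-bearing genes
#' (not the nominal 5.5, which ties and missingness shift).
#'
#' @param table Output of [dnds_decile_table()] with a `module` column.
#' @param module Module label to test.
#' @return List with `mean_decile`, `genomic_mean`, `t`, `df`,
#'   `p_two_sided`, `direction` (`"increased constraint"` for means below
#'   the genomic mean), `n`.
#' @export
module_constraint_test <- function(table, module) {
  stopifnot("module" %in% names(table))
  dec <- table$decile[!is.na(table$decile)]
  genomic_mean <- mean(dec)
  x <- table$decile[table$module == module & !is.na(table$decile)]
  if (length(x) < 3) {
    warning("module '", module, "' has fewer than 3 decile-bearing genes")
    return(NULL)
  }
  tt <- stats::t.test(x, mu = genomic_mean)
  list(mean_decile = mean(x), genomic_mean = genomic_mean,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value,
       direction = if (mean(x) < genomic_mean) "increased constraint"
                   else "decreased constraint",
       n = length(x))
}

#' Two-sample t test of module genes vs background deciles
#'
#' Compares aggregate deciles of genes assigned to any module against
#' unassigned (grey/"none") genes.
#'
#' @param table Output of [dnds_decile_table()] with a `module` column.
#' @return List with `t`, `df`, `p`, `mean_in`, `mean_out`, `direction`.
#' @export
in_module_vs_background_test <- function(table) {
  stopifnot("module" %in% names(table))
  ok <- !is.na(table$decile)
  inm <- table$decile[ok & !(table$module %in% c("none", "grey"))]
  out <- table$decile[ok & table$module %in% c("none", "grey")]
  if (length(inm) < 3 || length(out) < 3)
    stop("both groups need at least 3 decile-bearing genes")
  tt <- stats::t.test(inm, out)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_in = mean(inm), mean_out = mean(out),
       direction = if (mean(inm) < mean(out)) "modules more constrained"
                   else "modules less constrained")
}

#' Per-species regression of dN/dS decile on module centrality
#'
#' One slope per species (decile on kME), with a sign-consistency summary.
#' Species with fewer than `min_genes` complete rows are skipped.
#'
#' @param table Output of [dnds_decile_table()] with a `kme` column.
#' @param min_genes Minimum complete rows per species (default 30).
#' @return Data frame with `species`, `slope`, `p`, `n`; attribute
#'   `"sign_consistency"` = largest share of slopes agreeing in sign.
#' @export
per_species_centrality_slope <- function(table, min_genes = 30L) {
  stopifnot("kme" %in% names(table))
  sp_cols <- grep("^decile_", names(table), value = TRUE)
  rows <- list()
  for (sc in sp_cols) {
    ok <- !is.na(table[[sc]]) & !is.na(table$kme)
    if (sum(ok) < min_genes) next
    fit <- summary(stats::lm(table[[sc]][ok] ~ table$kme[ok]))
    rows[[sc]] <- data.frame(species = sub("^decile_", "", sc),
                             slope = fit$coefficients[2, 1],
                             p = fit$coefficients[2, 4],
                             n = sum(ok), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) stop("no species with enough genes")
  sgn <- sign(out$slope)
  attr(out, "sign_consistency") <- max(mean(sgn < 0), mean(sgn > 0))
  out
}
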