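#' Read a two-column gene-to-term annotation table
#'
#' Genes absent from the expression universe are dropped with a message
#' giving the count.
#'
#' @param x Data frame with columns `gene`, `term`, or a TSV path.
#' @param universe Character vector of genes in the expression universe.
#' @return A named list: term id -> character vector of annotated genes.
#' @export
annotation_map <- function(x, universe) {
  if (is.character(x) && length(x) == 1L)
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "term") %in% names(x)))
  unknown <- !(x$gene %in% universe)
  if (any(unknown)) {
    message(sum(unknown), " annotated gene(s) not in the universe; dropped")
    x <- x[!unknown, , drop = FALSE]
  }
  split(x$gene, x$term)
}

#' One-sided Fisher's exact enrichment test
#'
#' Hypergeometric upper-tail probability of observing at least the realized
#' overlap between a selected gene set and a term's genes within a finite
#' universe, plus the sample odds ratio of the 2x2 table.
#'
#' @param selected Character vector, subset of `universe`.
#' @param term_genes Character vector of the term's genes.
#' @param universe Character vector, the gene universe.
#' @return List with `odds_ratio`, `p_one_sided`, `overlap`, `n_selected`,
#'   `n_term`, `n_universe`.
#' @export
fisher_enrichment <- function(selected, term_genes, universe) {
  if (length(universe) == 0) stop("empty universe")
  selected <- intersect(selected, universe)
  term_genes <- intersect(term_genes, universe)
  q <- length(intersect(selected, term_genes))
  m <- length(term_genes)
  n <- length(universe) - m
  k <- length(selected)
  p <- stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
  a <- q
  b <- k - q
  cc <- m - q
  d <- n - b
  or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
  list(odds_ratio = or, p_one_sided = p, overlap = q, n_selected = k,
       n_term = m, n_universe = length(universe))
}

#' Combine p-values with Fisher's method
#'
#' \eqn{X^2 = -2 \sum \ln p_i} referred to a chi-square with \eqn{2k} df.
#'
#' @param p Vector of p-values in (0, 1].
#' @return List with `X2`, `df`, `p`.
#' @export
fisher_method <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  X2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(X2 = X2, df = df, p = stats::pchisq(X2, df, lower.tail = FALSE))
}

#' Sliding-threshold omnibus gene-set enrichment
#'
#' For each threshold fraction t, the top (or bottom) t share of genes by
#' score is selected (ties at the cut are all included) and every term is
#' tested for enrichment with the one-sided hypergeometric test; per-term
#' p-values across thresholds are combined with Fisher's method and
#' corrected across terms by Benjamini-Hochberg. Terms with fewer than
#' `min_annotated` genes in the universe are excluded. Because the selected
#' sets are nested, the per-threshold p-values are positively dependent and
#' the Fisher combination is anticonservative as a frequentist p; an
#' optional permutation omnibus p (random score rankings) is reported
#' alongside when `n_null_perm > 0`.
#'
#' @param ranking Named per-gene scores (e.g. trait correlations); no
#'   missing values among the universe.
#' @param annotation A list from [annotation_map()], or a data frame/path
#'   accepted by it.
#' @param thresholds Strictly decreasing fractions in (0, 1]; default
#'   0.50 down to 0.05 by 0.05.
#' @param direction `"top"` (largest scores first) or `"bottom"`.
#' @param min_annotated Minimum annotated genes for a term to be tested.
#' @param n_null_perm Optional number of ranking permutations for an
#'   empirical omnibus p (0 = skip).
#' @param seed Seed for the optional permutations.
#' @return Data frame with one row per tested term: `term`, `n_annotated`,
#'   `X2`, `df`, `p_omnibus`, `p_corrected`, optionally `p_perm`, plus an
#'   attribute `"per_threshold"` holding the per-term p matrix.
#' @export
omnibus_enrichment <- function(ranking, annotation,
                               thresholds = seq(0.50, 0.05, by = -0.05),
                               direction = c("top", "bottom"),
                               min_annotated = 10L,
                               n_null_perm = 0L, seed = 1L) {
  direction <- match.arg(direction)
  if (any(diff(thresholds) >= 0) || any(thresholds <= 0) ||
      any(thresholds > 1))
    stop("thresholds must be strictly decreasing fractions in (0,1]")
  if (any(is.na(ranking))) stop("ranking contains missing values")
  universe <- names(ranking)
  if (!is.list(annotation) || is.data.frame(annotation))
    annotation <- annotation_map(annotation, universe)
  annotation <- lapply(annotation, intersect, universe)
  n_ann <- vapply(annotation, length, integer(1))
  keep <- n_ann >= min_annotated
  if (!any(keep)) {
    warning("no term meets the min_annotated threshold")
    return(data.frame(term = character(0), n_annotated = integer(0),
                      X2 = numeric(0), df = integer(0),
                      p_omnibus = numeric(0), p_corrected = numeric(0)))
  }
  annotation <- annotation[keep]
  n_ann <- n_ann[keep]
  score <- if (direction == "top") ranking else -ranking

  per_term_p <- function(score) {
    ord <- order(score, decreasing = TRUE)
    sorted <- score[ord]
    nU <- length(score)
    pm <- matrix(NA_real_, length(annotation), length(thresholds),
                 dimnames = list(names(annotation), NULL))
    for (j in seq_along(thresholds)) {
      n_sel <- ceiling(thresholds[j] * nU)
      cut <- sorted[n_sel]
      sel <- universe[score >= cut]  # ties at the cut included
      for (i in seq_along(annotation)) {
        fe <- fisher_enrichment(sel, annotation[[i]], universe)
        pm[i, j] <- fe$p_one_sided
      }
    }
    pm
  }
  pm <- per_term_p(score)
  comb <- apply(pm, 1L, function(p) unlist(fisher_method(p)[c("X2", "p")]))
  res <- data.frame(term = names(annotation), n_annotated = n_ann,
                    X2 = comb["X2", ], df = 2L * length(thresholds),
                    p_omnibus = comb["p", ],
                    stringsAsFactors = FALSE)
  res$p_corrected <- stats::p.adjust(res$p_omnibus, method = "BH")
  attr(res, "correction") <- "BH"
  attr(res, "per_threshold") <- pm
  if (n_null_perm > 0) {
    obs_X2 <- res$X2
    withr::with_seed(seed, {
      count <- rep(0L, nrow(res))
      for (b in seq_len(n_null_perm)) {
        ps <- stats::setNames(sample(score), universe)
        pmb <- per_term_p(ps)
        X2b <- -2 * rowSums(log(pmb))
        count <- count + (X2b >= obs_X2)
      }
    })
    res$p_perm <- (count + 1) / (n_null_perm + 1)
  }
  rownames(res) <- NULL
  res
}
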