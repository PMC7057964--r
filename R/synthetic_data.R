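#' Simulation configuration for the synthetic colony transcriptome generator
#'
#' Bundles every parameter of the generative model: colonies and foragers,
#' gene count, planted coexpression modules (each a single latent factor with
#' per-gene loadings), trait-linked genes, colony and residual noise scales,
#' sequencing batches, trait ranges, GO annotation structure, and the
#' dN/dS generative parameters.
#'
#' The default configuration mirrors the field study the pipeline is built
#' around: 9 colonies x 10 foragers, 10,000 genes, 11 planted modules with
#' sizes spanning roughly 100-2,200 genes, two sequencing runs, and six
#' comparison species for dN/dS.
#'
#' @param n_colonies Number of colonies.
#' @param foragers_per_colony Foragers (samples) per colony.
#' @param n_genes Number of genes.
#' @param module_spec List of module descriptions, each a list with `size`,
#'   `colony_loading_sd` (SD of the module factor's colony-level component,
#'   log2-expression units), `trait_link` (`"humidity"`, `"da5ht"` or
#'   `"none"`), and `link_strength` in \[0,1\] (share of the module factor
#'   driven by the standardized colony trait).
#' @param frac_trait_genes Fraction of non-module genes given a direct linear
#'   trait effect (half linked to each trait, alternating sign).
#' @param trait_effect_sd SD of the per-gene trait effect sizes
#'   (log2-expression units per trait SD) for direct trait genes.
#' @param colony_effect_sd SD of gene-specific colony shifts (log2 units).
#' @param noise_sd Residual per-cell noise SD (log2 units).
#' @param batch_spec List of batches, each a list with `batch_id`,
#'   `sample_idx` (indices into the sample sequence) and `shift` (log2
#'   units); `NULL` for the default two-run design with a 0.4 log2 shift on
#'   the second run.
#' @param trait_ranges Named list with `humidity` and `da5ht`, each
#'   `c(min, max)`; colony trait values are drawn uniformly within.
#' @param go_spec List with `n_terms`, `genes_per_term`, and `planted`: a
#'   list of planted terms, each with `term`, `target` (`"humidity"`,
#'   `"da5ht"`, or a module index) and `concentration` in \[0,1\].
#' @param dnds_spec List with `baseline_mean` (mean log dN/dS),
#'   `centrality_slope`, `trait_slope`, `dispersion` (gene-level SD of log
#'   dN/dS, must be > 0), `species_sd` (per-species SD around the shared
#'   gene value) and `n_species`.
#' @param seed Integer master seed; every generator draws from
#'   `seed + <fixed stream offset>` so partial reruns are reproducible.
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_colonies = 9L,
                       foragers_per_colony = 10L,
                       n_genes = 10000L,
                       module_spec = default_module_spec(),
                       frac_trait_genes = 0.05,
                       trait_effect_sd = 0.4,
                       colony_effect_sd = 0.3,
                       noise_sd = 0.4,
                       batch_spec = NULL,
                       trait_ranges = list(humidity = c(0, 3),
                                           da5ht = c(0.5, 2.5)),
                       go_spec = list(n_terms = 50L, genes_per_term = 50L,
                                      planted = list()),
                       dnds_spec = list(baseline_mean = -1.5,
                                        centrality_slope = 1,
                                        trait_slope = 1,
                                        dispersion = 0.4,
                                        species_sd = 0.2,
                                        n_species = 6L),
                       seed = 1L) {
  stopifnot(n_colonies >= 1, foragers_per_colony >= 1, n_genes >= 1)
  if (frac_trait_genes < 0 || frac_trait_genes > 1)
    stop("frac_trait_genes must lie in [0,1]")
  for (ms in module_spec) {
    stopifnot(is.list(ms), ms$size >= 1,
              ms$trait_link %in% c("humidity", "da5ht", "none"),
              ms$link_strength >= 0, ms$link_strength <= 1)
  }
  if (sum(vapply(module_spec, `[[`, numeric(1), "size")) > n_genes)
    stop("module sizes sum to more than n_genes")
  for (tr in names(trait_ranges)) {
    r <- trait_ranges[[tr]]
    if (!all(is.finite(r))) stop("trait range must be finite")
    if (r[1] >= r[2] && n_colonies > 1)
      stop("degenerate trait range for '", tr, "'")
  }
  if (!is.null(dnds_spec$dispersion) && dnds_spec$dispersion <= 0)
    stop("dnds dispersion must be positive")
  n_samples <- n_colonies * foragers_per_colony
  if (is.null(batch_spec)) {
    batch_spec <- list(
      list(batch_id = "run1", sample_idx = seq(1L, n_samples, by = 2L),
           shift = 0),
      list(batch_id = "run2", sample_idx = seq(2L, n_samples, by = 2L),
           shift = 0.4))
  }
  cfg <- list(n_colonies = as.integer(n_colonies),
              foragers_per_colony = as.integer(foragers_per_colony),
              n_genes = as.integer(n_genes),
              module_spec = module_spec,
              frac_trait_genes = frac_trait_genes,
              trait_effect_sd = trait_effect_sd,
              colony_effect_sd = colony_effect_sd,
              noise_sd = noise_sd,
              batch_spec = batch_spec,
              trait_ranges = trait_ranges,
              go_spec = go_spec,
              dnds_spec = dnds_spec,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted-module layout
#'
#' Eleven modules with sizes spanning the range observed in real forager
#' brain coexpression networks (about 100 to 2,200 genes), two linked to
#' colony humidity sensitivity and two to the brain DA:5HT ratio.
#' @return A list of module descriptions for [sim_config()].
#' @export
default_module_spec <- function() {
  sizes <- c(2182L, 850L, 600L, 500L, 420L, 355L, 300L, 250L, 200L, 150L,
             108L)
  links <- c("none", "humidity", "none", "da5ht", "none", "humidity",
             "none", "da5ht", "none", "none", "none")
  strength <- ifelse(links == "none", 0, 0.6)
  mapply(function(s, l, st) list(size = s, colony_loading_sd = 0.5,
                                 trait_link = l, link_strength = st),
         sizes, links, strength, SIMPLIFY = FALSE)
}

# fixed stream offsets: every generator call is seeded at seed + offset
.stream <- c(traits = 101L, expression = 202L, annotations = 303L,
             dnds = 404L, counts = 505L)

#' Simulate colony-level trait values
#'
#' Draws each colony's humidity sensitivity (fewer foraging trips per %
#' decrease in daily relative humidity) and forager brain
#' dopamine-to-serotonin ratio uniformly within the configured ranges.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `colony`, `humidity`, `da5ht`.
#' @export
simulate_colony_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_colonies < 2)
    stop("need at least 2 colonies")
  withr::with_seed(config$seed + .stream[["traits"]], {
    data.frame(
      colony = sprintf("C%02d", seq_len(config$n_colonies)),
      humidity = stats::runif(config$n_colonies,
                              config$trait_ranges$humidity[1],
                              config$trait_ranges$humidity[2]),
      da5ht = stats::runif(config$n_colonies,
                           config$trait_ranges$da5ht[1],
                           config$trait_ranges$da5ht[2]),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a forager brain expression matrix with planted structure
#'
#' Generative model on the log2 scale, per gene g and sample s:
#' \deqn{y_{gs} = b_g + c_{g,colony(s)} + \lambda_g f_{m(g),s}
#'   + e_g z_{trait(colony(s))} + batch_{s} + \epsilon_{gs}}
#' with gene baselines \eqn{b_g}, gene-by-colony shifts
#' \eqn{c \sim N(0, colony\_effect\_sd)}, one latent factor per planted
#' module combining a trait-driven part (weight `link_strength`), a
#' colony-level part (`colony_loading_sd`) and a per-sample part, positive
#' per-gene loadings \eqn{\lambda_g}, direct trait effects \eqn{e_g} on a
#' fraction of non-module genes, additive batch shifts, and
#' \eqn{\epsilon \sim N(0, noise\_sd)}. Values are exponentiated (base 2)
#' and each column rescaled to sum to one million (TPM).
#'
#' @param config A [sim_config()].
#' @param traits Output of [simulate_colony_traits()]; must cover all
#'   colonies in the config.
#' @return List with `expr` (an `expr_matrix`, unit `"tpm"`) and `truth`
#'   (see Details): `gene_truth` (gene, module, loading, effect_humidity,
#'   effect_da5ht), `module_factors`, `traits`, `sample_meta`,
#'   `gene_lengths`.
#' @export
simulate_expression <- function(config, traits) {
  stopifnot(inherits(config, "sim_config"))
  n_col <- config$n_colonies
  if (!all(sprintf("C%02d", seq_len(n_col)) %in% traits$colony))
    stop("traits must cover every colony in the config")
  traits <- traits[match(sprintf("C%02d", seq_len(n_col)), traits$colony), ]
  nG <- config$n_genes
  nF <- config$foragers_per_colony
  nS <- n_col * nF
  colony_of <- rep(traits$colony, each = nF)
  sample_ids <- sprintf("%s_f%02d", colony_of, rep(seq_len(nF), n_col))
  gene_ids <- sprintf("g%05d", seq_len(nG))

  sizes <- vapply(config$module_spec, `[[`, numeric(1), "size")
  n_mod <- length(sizes)
  module_of <- rep(NA_integer_, nG)
  if (n_mod > 0)
    module_of[seq_len(sum(sizes))] <- rep(seq_len(n_mod), times = sizes)

  z_trait <- function(name) {
    x <- traits[[name]]
    if (stats::sd(x) == 0) rep(0, length(x)) else as.numeric(scale(x))
  }
  zt <- list(humidity = z_trait("humidity"), da5ht = z_trait("da5ht"),
             none = rep(0, n_col))

  withr::with_seed(config$seed + .stream[["expression"]], {
    baseline <- stats::rnorm(nG, mean = 5, sd = 2)
    colony_shift <- matrix(stats::rnorm(nG * n_col, 0,
                                        config$colony_effect_sd), nG, n_col)
    loading <- rep(0, nG)
    effect_h <- rep(0, nG)
    effect_d <- rep(0, nG)
    factors <- matrix(0, n_mod, nS)
    y <- matrix(baseline, nG, nS) + colony_shift[, match(colony_of,
                                                         traits$colony)]
    if (n_mod > 0) {
      for (mi in seq_len(n_mod)) {
        ms <- config$module_spec[[mi]]
        genes <- which(module_of == mi)
        loading[genes] <- abs(stats::rnorm(length(genes), 1, 0.25))
        col_part <- stats::rnorm(n_col)
        # colony-level factor: unit variance, correlation link_strength
        # with the standardized trait; scaled by colony_loading_sd
        col_fac <- ms$link_strength * zt[[ms$trait_link]] +
          sqrt(1 - ms$link_strength^2) * col_part
        samp_part <- stats::rnorm(nS, 0, 0.35)
        f <- ms$colony_loading_sd * col_fac[match(colony_of,
                                                  traits$colony)] +
          samp_part
        factors[mi, ] <- f
        y[genes, ] <- y[genes, ] + loading[genes] %o% f
      }
    }
    free <- which(is.na(module_of))
    n_tg <- round(config$frac_trait_genes * length(free))
    if (n_tg > 0) {
      tg <- free[seq_len(n_tg)]
      eff <- stats::rnorm(n_tg, 0, config$trait_effect_sd)
      half <- seq_len(n_tg) %% 2L == 1L
      effect_h[tg[half]] <- eff[half]
      effect_d[tg[!half]] <- eff[!half]
      zh <- zt$humidity[match(colony_of, traits$colony)]
      zd <- zt$da5ht[match(colony_of, traits$colony)]
      y[tg[half], ] <- y[tg[half], , drop = FALSE] +
        effect_h[tg[half]] %o% zh
      y[tg[!half], ] <- y[tg[!half], , drop = FALSE] +
        effect_d[tg[!half]] %o% zd
    }
    batch_of <- rep(NA_character_, nS)
    for (b in config$batch_spec) {
      idx <- b$sample_idx[b$sample_idx <= nS]
      batch_of[idx] <- b$batch_id
      y[, idx] <- y[, idx, drop = FALSE] + b$shift
    }
    batch_of[is.na(batch_of)] <- "run1"
    if (config$noise_sd > 0)
      y <- y + matrix(stats::rnorm(nG * nS, 0, config$noise_sd), nG, nS)
    gene_lengths <- stats::setNames(round(stats::runif(nG, 300, 10000)),
                                    gene_ids)
    rna_conc <- stats::runif(nS, 20, 200)
  })

  tpm <- 2^y
  tpm <- sweep(tpm, 2L, colSums(tpm), "/") * 1e6
  dimnames(tpm) <- list(gene_ids, sample_ids)
  meta <- data.frame(sample = sample_ids, colony = colony_of,
                     batch = batch_of, rna_conc = rna_conc,
                     library = seq_len(nS), stringsAsFactors = FALSE)
  expr <- expr_matrix(tpm, unit = "tpm", sample_meta = meta)
  expr <- stamp(expr, "simulate_expression")
  gene_truth <- data.frame(
    gene = gene_ids,
    module = ifelse(is.na(module_of), "none",
                    sprintf("M%02d", module_of)),
    loading = loading,
    effect_humidity = effect_h,
    effect_da5ht = effect_d,
    stringsAsFactors = FALSE)
  list(expr = expr,
       truth = list(gene_truth = gene_truth,
                    module_factors = factors,
                    traits = traits,
                    sample_meta = meta,
                    gene_lengths = gene_lengths))
}

#' Draw sequencing counts consistent with a TPM matrix
#'
#' Expected counts are proportional to TPM times gene length; realized
#' counts are Poisson. Intended for exercising [counts_to_tpm()].
#'
#' @param expr An `expr_matrix` in `"tpm"` unit.
#' @param gene_lengths Named vector of gene lengths.
#' @param depth Mean library size (reads per sample).
#' @param seed Integer seed.
#' @return An `expr_matrix` in `"counts"` unit.
#' @export
simulate_counts <- function(expr, gene_lengths, depth = 2e7, seed = 1L) {
  stopifnot(inherits(expr, "expr_matrix"), expr$unit == "tpm")
  len <- gene_lengths[rownames(expr$values)]
  rate <- expr$values * len
  rate <- sweep(rate, 2L, colSums(rate), "/") * depth
  withr::with_seed(seed + .stream[["counts"]], {
    counts <- matrix(stats::rpois(length(rate), lambda = rate),
                     nrow(rate), ncol(rate), dimnames = dimnames(rate))
  })
  out <- expr
  out$values <- counts + 0.0
  out$unit <- "counts"
  stamp(out, "simulate_counts")
}

#' Simulate a gene-to-GO annotation map
#'
#' Random terms annotate genes drawn uniformly; each planted term draws a
#' `concentration` share of its genes from its target set (a trait-linked
#' gene set or a planted module) and the remainder from outside it.
#'
#' @param config A [sim_config()] with a `go_spec`.
#' @param truth Truth record from [simulate_expression()].
#' @return Data frame with columns `gene`, `term`.
#' @export
simulate_annotations <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  gs <- config$go_spec
  if (is.null(gs)) stop("go_spec missing from config")
  gt <- truth$gene_truth
  genes <- gt$gene
  if (gs$genes_per_term > length(genes))
    stop("genes_per_term exceeds n_genes")
  if (gs$n_terms == 0 && length(gs$planted) == 0)
    return(data.frame(gene = character(0), term = character(0)))
  # trait targets take the positive-effect tail: enrichment is one-sided,
  # so a planted term must concentrate in one tail of the ranking
  target_set <- function(target) {
    if (identical(target, "humidity")) {
      gt$gene[gt$effect_humidity > 0]
    } else if (identical(target, "da5ht")) {
      gt$gene[gt$effect_da5ht > 0]
    } else {
      gt$gene[gt$module == sprintf("M%02d", as.integer(target))]
    }
  }
  withr::with_seed(config$seed + .stream[["annotations"]], {
    pieces <- list()
    if (gs$n_terms > 0) {
      for (i in seq_len(gs$n_terms)) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          gene = sample(genes, gs$genes_per_term),
          term = sprintf("GO:%07d", i), stringsAsFactors = FALSE)
      }
    }
    for (pl in gs$planted) {
      inset <- target_set(pl$target)
      n_in <- min(round(pl$concentration * gs$genes_per_term), length(inset))
      n_out <- gs$genes_per_term - n_in
      outset <- setdiff(genes, inset)
      picked <- c(if (n_in > 0) sample(inset, n_in),
                  if (n_out > 0) sample(outset, n_out))
      pieces[[length(pieces) + 1L]] <- data.frame(
        gene = picked, term = pl$term, stringsAsFactors = FALSE)
    }
    do.call(rbind, pieces)
  })
}

#' Simulate per-species dN/dS values with planted constraint structure
#'
#' Gene-level log dN/dS is
#' \eqn{baseline - centrality\_slope \cdot c_g - trait\_slope \cdot |e_g|
#'   + u_g}, with \eqn{u_g \sim N(0, dispersion)} shared across species;
#' each species column adds independent \eqn{N(0, species\_sd)} noise before
#' exponentiating, so higher centrality or stronger trait linkage yields
#' lower dN/dS (stronger purifying selection).
#'
#' @param config A [sim_config()] with a `dnds_spec`.
#' @param truth Truth record from [simulate_expression()].
#' @param kme_proxy Optional named per-gene centrality; defaults to the
#'   planted module loading (0 for unassigned genes).
#' @return Data frame with `gene`, one dN/dS column per species
#'   (`dnds_sp1`, ...), and the latent `constraint` score.
#' @export
simulate_dnds <- function(config, truth, kme_proxy = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ds <- config$dnds_spec
  if (ds$dispersion <= 0) stop("dispersion must be positive")
  gt <- truth$gene_truth
  if (is.null(kme_proxy)) {
    kme_proxy <- stats::setNames(ifelse(gt$module == "none", 0, gt$loading),
                                 gt$gene)
  }
  if (!all(gt$gene %in% names(kme_proxy)))
    stop("kme_proxy missing for some genes")
  cent <- kme_proxy[gt$gene]
  eff <- pmax(abs(gt$effect_humidity), abs(gt$effect_da5ht))
  withr::with_seed(config$seed + .stream[["dnds"]], {
    u <- stats::rnorm(nrow(gt), 0, ds$dispersion)
    base <- ds$baseline_mean - ds$centrality_slope * cent -
      ds$trait_slope * eff + u
    sp <- matrix(stats::rnorm(nrow(gt) * ds$n_species, 0, ds$species_sd),
                 nrow(gt), ds$n_species)
  })
  dnds <- exp(base + sp)
  colnames(dnds) <- sprintf("dnds_sp%d", seq_len(ds$n_species))
  out <- data.frame(gene = gt$gene, dnds, constraint = base,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a synthetic data set to a directory as plain-text tables
#'
#' Emits the expression TSV (genes as rows), sample metadata TSV, colony
#' trait TSV, annotation TSV (gene, term), dN/dS TSV and a truth JSON.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(config, outdir) {
  traits <- simulate_colony_traits(config)
  sim <- simulate_expression(config, traits)
  ann <- simulate_annotations(config, sim$truth)
  dnds <- simulate_dnds(config, sim$truth)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_expr_tsv(sim$expr, file.path(outdir, "expression.tsv"))
  utils::write.table(sim$truth$sample_meta,
                     file.path(outdir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(traits, file.path(outdir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann, file.path(outdir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dnds, file.path(outdir, "dnds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth$gene_truth,
                       file.path(outdir, "truth.json"), digits = NA)
  invisible(list(config = config, traits = traits, expr = sim$expr,
                 truth = sim$truth, annotations = ann, dnds = dnds))
}

#' Read/write an expression TSV (genes as rows, header = sample ids)
#' @param x An `expr_matrix`.
#' @param path File path.
#' @export
write_expr_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_tsv
#' @param unit Unit of the stored values.
#' @param sample_meta Optional metadata data frame (or path to its TSV).
#' @export
read_expr_tsv <- function(path, unit = "tpm", sample_meta = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- df[[1L]]
  if (is.character(sample_meta))
    sample_meta <- utils::read.delim(sample_meta, stringsAsFactors = FALSE)
  expr_matrix(v, unit = unit, sample_meta = sample_meta)
}
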