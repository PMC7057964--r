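#' Default pipeline configuration
#'
#' One nested list driving [run_pipeline()]: stage enable flags, per-stage
#' parameter blocks, input paths (ignored when `simulate` is enabled) and
#' the global seed. Unknown keys passed through `...` are rejected.
#'
#' @param simulate Generate inputs with the synthetic module (default TRUE).
#' @param sim Arguments for [sim_config()] (a list).
#' @param stages Named logical vector enabling `preprocess`, `traits`,
#'   `enrich`, `network`, `evolve`.
#' @param preprocess,network,enrich Per-stage parameter lists.
#' @param inputs Paths to `expression`, `sample_meta`, `traits`,
#'   `annotations`, `dnds` TSVs when not simulating.
#' @param seed Global seed.
#' @param ... Unknown keys: rejected.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE,
                            sim = list(),
                            stages = c(preprocess = TRUE, traits = TRUE,
                                       enrich = TRUE, network = TRUE,
                                       evolve = TRUE),
                            preprocess = list(),
                            network = list(),
                            enrich = list(),
                            inputs = list(),
                            seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown config keys: ", paste(names(extra), collapse = ", "))
  known_stages <- c("preprocess", "traits", "enrich", "network", "evolve")
  st <- stats::setNames(rep(TRUE, length(known_stages)), known_stages)
  st[names(stages)] <- stages
  structure(list(simulate = simulate, sim = sim, stages = st,
                 preprocess = preprocess, network = network,
                 enrich = enrich, inputs = inputs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$stages)) y$stages <- unlist(y$stages)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or load) -> preprocess -> trait correlation and
#' ordination -> omnibus GO enrichment -> coexpression network -> dN/dS
#' integration. Every enabled stage writes its tables under `outdir` and
#' contributes a section to the JSON report; a stage failure halts with the
#' stage name, leaving earlier outputs in place.
#'
#' @param config A `pipeline_config` (or path to its YAML).
#' @param outdir Output directory.
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs ------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    ds <- run_stage("simulate", function()
      simulate_dataset(cfg, file.path(outdir, "simulated")))
    expr_raw <- ds$expr; traits <- ds$traits
    ann <- ds$annotations; dnds <- ds$dnds
    truth <- ds$truth
    report$stages$simulate <- list(
      n_genes = nrow(expr_raw$values), n_samples = ncol(expr_raw$values),
      n_colonies = cfg$n_colonies,
      n_planted_modules = length(cfg$module_spec))
  } else {
    ip <- config$inputs
    expr_raw <- read_expr_tsv(ip$expression, unit = "tpm",
                              sample_meta = ip$sample_meta)
    traits <- utils::read.delim(ip$traits, stringsAsFactors = FALSE)
    ann <- if (!is.null(ip$annotations))
      utils::read.delim(ip$annotations, stringsAsFactors = FALSE)
    dnds <- if (!is.null(ip$dnds))
      utils::read.delim(ip$dnds, stringsAsFactors = FALSE)
    truth <- NULL
  }
  jsonlite::write_json(unclass(config), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  # --- preprocess --------------------------------------------------------
  expr <- expr_raw
  if (config$stages[["preprocess"]]) {
    pp <- run_stage("preprocess", function()
      do.call(preprocess_expression, c(list(expr_raw), config$preprocess)))
    expr <- pp$matrix
    jsonlite::write_json(pp$report, file.path(outdir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$preprocess <- list(
      n_genes_out = nrow(expr$values), n_samples_out = ncol(expr$values),
      n_genes_removed = pp$report$filter$n_genes_removed,
      n_samples_removed = pp$report$outliers$n_samples_removed)
  }

  # --- trait association -------------------------------------------------
  tc <- NULL
  if (config$stages[["traits"]]) {
    tc <- run_stage("traits", function()
      trait_correlation_table(expr, traits))
    wt(tc, "trait_correlations.tsv")
    pca <- pca_samples(expr, k = min(3L, ncol(expr$values) - 1L))
    scores <- data.frame(sample = rownames(pca$scores), pca$scores)
    wt(scores, "pca_scores.tsv")
    net <- sample_distance_network(expr, seed = config$seed)
    wt(net$edges, "sample_network_edges.tsv")
    agree <- lapply(c("humidity", "da5ht"), function(tr)
      correlation_method_agreement(tc[[paste0("r_sample_", tr)]],
                                   tc[[paste0("r_colony_", tr)]]))
    report$stages$traits <- list(
      n_genes = nrow(tc),
      pca_var_explained = sum(pca$variance_explained),
      nestmate_edge_fraction = net$nestmate_edge_fraction,
      agreement_r = stats::setNames(
        vapply(agree, `[[`, numeric(1), "pearson_r"),
        c("humidity", "da5ht")))
  }

  # --- enrichment --------------------------------------------------------
  if (config$stages[["enrich"]] && !is.null(ann) && !is.null(tc)) {
    enr <- run_stage("enrich", function() {
      ranking <- stats::setNames(tc$r_sample_humidity, tc$gene)
      ranking <- ranking[!is.na(ranking)]
      do.call(omnibus_enrichment,
              c(list(ranking = ranking,
                     annotation = annotation_map(ann, names(ranking))),
                config$enrich))
    })
    wt(enr, "go_omnibus.tsv")
    report$stages$enrich <- list(
      n_terms_tested = nrow(enr),
      n_significant = sum(enr$p_corrected < 0.05))
  }

  # --- coexpression network ---------------------------------------------
  ms <- NULL
  if (config$stages[["network"]]) {
    np_args <- config$network
    if (is.null(np_args$seed)) np_args$seed <- config$seed
    np <- do.call(network_params, np_args)
    ms <- run_stage("network", function()
      iterative_density_filter(expr, np))
    wt(data.frame(gene = names(ms$labels), module = ms$labels),
       "gene_modules.tsv")
    wt(ms$modules, "module_summary.tsv")
    if (nrow(ms$modules)) {
      eg <- module_set_eigengenes(expr, ms)
      wt(data.frame(module = rownames(eg$eigengenes), eg$eigengenes,
                    check.names = FALSE), "module_eigengenes.tsv")
      mta <- module_trait_analysis(expr, ms, traits)
      wt(mta$me_trait, "module_trait.tsv")
      qz <- module_quality_z(ms$TO, ms$labels, seed = np$seed)
      wt(data.frame(module = names(qz), quality_z = qz),
         "module_quality.tsv")
    }
    report$stages$network <- list(
      n_modules = nrow(ms$modules),
      n_genes_final = length(ms$labels),
      filter_rounds = ms$iterations)
  }

  # --- evolution ---------------------------------------------------------
  if (config$stages[["evolve"]] && !is.null(dnds)) {
    ev <- run_stage("evolve", function() {
      trait_r <- if (!is.null(tc))
        stats::setNames(tc$r_sample_humidity, tc$gene)
      kv <- NULL; ml <- NULL
      if (!is.null(ms) && nrow(ms$modules)) {
        eg <- module_set_eigengenes(expr, ms)
        # each gene's kME with respect to its own module
        kv <- stats::setNames(
          eg$kme[cbind(seq_along(ms$labels),
                       match(ms$labels, colnames(eg$kme)))],
          names(ms$labels))
        ml <- ms$labels
      }
      tab <- dnds_decile_table(dnds, expr = expr, trait_r = trait_r,
                               kme_values = kv, module_labels = ml)
      res <- list(table = tab)
      preds <- intersect(c("abs_trait_r", "kme", "median_tpm", "expr_sd"),
                         names(tab))
      res$glm <- tryCatch(constraint_glm(tab, predictors = preds),
                          error = function(e) NULL)
      if ("module" %in% names(tab) &&
          any(!(tab$module %in% c("none", "grey")))) {
        mods <- setdiff(unique(tab$module), c("none", "grey"))
        res$module_tests <- do.call(rbind, lapply(mods, function(mo) {
          mt <- module_constraint_test(tab, mo)
          if (is.null(mt)) return(NULL)
          data.frame(module = mo, mean_decile = mt$mean_decile,
                     t = mt$t, p = mt$p_two_sided,
                     direction = mt$direction, stringsAsFactors = FALSE)
        }))
        res$in_vs_out <- tryCatch(in_module_vs_background_test(tab),
                                  error = function(e) NULL)
      }
      res
    })
    wt(ev$table, "dnds_deciles.tsv")
    if (!is.null(ev$glm)) wt(ev$glm, "constraint_glm.tsv")
    if (!is.null(ev$module_tests)) wt(ev$module_tests,
                                      "module_constraint.tsv")
    report$stages$evolve <- list(
      n_genes = nrow(ev$table),
      glm_terms = if (!is.null(ev$glm)) ev$glm$term else character(0),
      in_vs_out_p = if (!is.null(ev$in_vs_out)) ev$in_vs_out$p else NULL)
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
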