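#' Assemble a pipeline configuration
#'
#' Either real input paths (`maf`, `edges`, optionally `clinical`) or a
#' [synthetic_spec()] must be supplied. Every stage parameter defaults to
#' the pipeline's standard value (score threshold 0.7, restart 0.75,
#' convergence 1e-6, top 500 genes, lambda 150, k 2..9, 100 runs,
#' silhouette 0.20).
#'
#' @param maf,edges,clinical input file paths (TSV).
#' @param synthetic a `synthetic_spec` used instead of file inputs.
#' @param out_dir output directory; created if needed.
#' @param score_threshold,restart,rwr_tol,top_n,variability,lambda,knn
#'   stage parameters.
#' @param k_range,n_runs,silhouette_threshold,alpha_grid,nlambda stage
#'   parameters.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(maf = NULL, edges = NULL, clinical = NULL,
                            synthetic = NULL, out_dir = tempfile("netstrat_"),
                            score_threshold = 0.7, restart = 0.75,
                            rwr_tol = 1e-6, top_n = 500L,
                            variability = "variance", lambda = 150,
                            knn = 5L, k_range = 2:9, n_runs = 100L,
                            silhouette_threshold = 0.20,
                            alpha_grid = seq(0.1, 1, by = 0.1),
                            nlambda = 50L, seed = 1L) {
  if (is.null(synthetic) && (is.null(maf) || is.null(edges))) {
    stop_netstrat("supply either maf + edges paths or a synthetic spec",
                  "netstrat_config_error")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; a `synthetic` block
#' holds [synthetic_spec()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    y$synthetic <- do.call(synthetic_spec, y$synthetic)
  }
  if (!is.null(y$k_range)) y$k_range <- eval(parse(text = y$k_range))
  do.call(pipeline_config, y)
}

#' Run the end-to-end stratification pipeline
#'
#' Executes all stages in order (input/simulation, network, propagation,
#' gene selection, consensus clustering over the k range, model selection,
#' silhouette core extraction, classification, clinical association),
#' writing every stage output and a JSON run manifest under
#' `config$out_dir`. The run is a deterministic function of the
#' configuration (including its master seed).
#'
#' @param config a [pipeline_config()].
#' @return the `netstrat_fit`, invisibly, with attribute `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  log_stage <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    stages <<- c(stages, msg)
    message("[netstrat] ", msg)
  }
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    mutations <- cohort$mutations
    network <- cohort$network
    clinical <- cohort$clinical
    write_cohort(cohort, file.path(config$out_dir, "synthetic"))
    log_stage("io: simulated cohort %d patients x %d genes",
              nrow(mutations), ncol(mutations))
  } else {
    if (!file.exists(config$edges)) {
      stop_netstrat(sprintf("edges file not found: %s", config$edges),
                    "netstrat_format_error")
    }
    records <- read_maf(config$maf)
    mutations <- build_binary_matrix(records)
    network <- read_string_edges(config$edges,
                                 score_threshold = config$score_threshold)
    clinical <- if (!is.null(config$clinical))
      utils::read.delim(config$clinical, stringsAsFactors = FALSE) else NULL
    log_stage("io: %d records -> %d patients x %d genes",
              nrow(records), nrow(mutations), ncol(mutations))
  }
  ns <- network_summary(network)
  log_stage("network: %d nodes, %d edges, %d component(s)",
            ns$n_nodes, ns$n_edges, ns$n_components)
  fit <- netstrat(mutations, network, clinical,
                  restart = config$restart, rwr_tol = config$rwr_tol,
                  top_n = config$top_n, variability = config$variability,
                  lambda = config$lambda, knn = config$knn,
                  k_range = config$k_range, n_runs = config$n_runs,
                  silhouette_threshold = config$silhouette_threshold,
                  alpha_grid = config$alpha_grid, nlambda = config$nlambda,
                  seed = config$seed)
  log_stage("propagation: %d patients smoothed, %d dropped gene(s)",
            nrow(fit$smoothed), length(fit$dropped_genes))
  log_stage("selection: top %d genes by %s", config$top_n,
            config$variability)
  log_stage("consensus: k = %s, %d runs",
            paste(range(config$k_range), collapse = ".."), config$n_runs)
  log_stage("model selection: k* = %d", fit$k_best)
  log_stage("silhouette: %d core of %d", length(fit$core_ids),
            nrow(fit$smoothed))
  if (!is.null(fit$model)) {
    log_stage("classifier: jackknife accuracy %.4f",
              fit$model$jackknife_accuracy)
  } else log_stage("classifier: skipped")
  if (!is.null(fit$battery)) {
    log_stage("clinical: battery over %d labelings",
              ncol(fit$battery$p_values))
  } else log_stage("clinical: no table supplied")

  od <- config$out_dir
  wt <- function(x, f) utils::write.table(
    x, file.path(od, f), sep = "\t", quote = FALSE)
  con <- gzfile(file.path(od, "smoothed_matrix.tsv.gz"))
  utils::write.table(fit$smoothed, con, sep = "\t", quote = FALSE)
  wt(fit$selected_genes, "selected_genes.tsv")
  wt(fit$k_table, "cophenetic_by_k.tsv")
  lab_mat <- vapply(fit$consensus, `[[`, integer(nrow(fit$smoothed)),
                    "labels")
  wt(lab_mat, "labels_by_k.tsv")
  wt(fit$silhouette$widths, "silhouette.tsv")
  if (!is.null(fit$model)) {
    wt(as.matrix(fit$model$coefficients), "biomarker_coefficients.tsv")
    writeLines(jsonlite::toJSON(fit$model$biomarkers, pretty = TRUE),
               file.path(od, "biomarkers.json"))
  }
  if (!is.null(fit$battery)) wt(fit$battery$p_values, "associations.tsv")
  manifest <- list(
    stages = stages,
    config = config[setdiff(names(config), "synthetic")],
    synthetic = if (!is.null(config$synthetic))
      unclass(config$synthetic) else NULL,
    k_best = fit$k_best,
    n_core = length(fit$core_ids),
    jackknife_accuracy = if (!is.null(fit$model))
      fit$model$jackknife_accuracy else NA)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", force = TRUE),
             file.path(od, "manifest.json"))
  attr(fit, "manifest") <- manifest
  invisible(fit)
}
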