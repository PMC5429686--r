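#' Network-based stratification of a mutation cohort
#'
#' The full stratification model: each patient's binary somatic mutation
#' profile is smoothed over the interaction network by a restarting random
#' walk; the most variable smoothed genes are median-centered and
#' factorized by graph-regularized NMF under consensus clustering across
#' random restarts for each candidate cluster count; the count with the
#' largest cophenetic correlation is selected; samples with silhouette
#' width above the core threshold (on the consensus distance) form the
#' core set on which a jackknife-tuned multinomial elastic net is fitted,
#' yielding per-subtype biomarker genes; finally, subtype labels are
#' tested against the clinical covariates.
#'
#' @param mutations binary patients-by-genes matrix (see
#'   [build_binary_matrix()]), or a `synthetic_cohort`.
#' @param network a `ppi_network`; taken from the cohort when `mutations`
#'   is a `synthetic_cohort`.
#' @param clinical optional clinical table; enables the association
#'   battery.
#' @param restart random-walk restart probability (default 0.75).
#' @param rwr_tol random-walk L1 convergence tolerance (default 1e-6).
#' @param top_n number of most-variable smoothed genes kept (default 500).
#' @param variability "variance" (default) or "cv".
#' @param lambda graph-regularization weight of the factorization
#'   (default 150).
#' @param knn neighbors of the patient affinity graph (default 5).
#' @param k_range candidate cluster counts (default 2:9).
#' @param n_runs factorization restarts per k (default 100).
#' @param silhouette_threshold core-sample cutoff (default 0.20).
#' @param classify fit the elastic-net subtype classifier (default TRUE).
#' @param alpha_grid,nlambda classifier tuning grid (see
#'   [jackknife_tune()]).
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class `netstrat_fit` with components `smoothed`,
#'   `selected_genes`, `consensus` (per-k results), `k_table`, `k_best`,
#'   `labels`, `silhouette`, `core_ids`, `model` (subtype model or NULL),
#'   `battery` (or NULL), `config`.
#' @seealso [predict.netstrat_fit()], [coef.netstrat_fit()],
#'   [plot.netstrat_fit()]
#' @export
netstrat <- function(mutations, network = NULL, clinical = NULL,
                     restart = 0.75, rwr_tol = 1e-6,
                     top_n = 500L, variability = "variance",
                     lambda = 150, knn = 5L,
                     k_range = 2:9, n_runs = 100L,
                     silhouette_threshold = 0.20,
                     classify = TRUE,
                     alpha_grid = seq(0.1, 1, by = 0.1), nlambda = 50L,
                     seed = 1L) {
  if (inherits(mutations, "synthetic_cohort")) {
    network <- network %||% mutations$network
    clinical <- clinical %||% mutations$clinical
    mutations <- mutations$mutations
  }
  if (is.null(network)) {
    stop_netstrat("a ppi_network is required", "netstrat_config_error")
  }
  config <- list(restart = restart, rwr_tol = rwr_tol, top_n = top_n,
                 variability = variability, lambda = lambda, knn = knn,
                 k_range = k_range, n_runs = n_runs,
                 silhouette_threshold = silhouette_threshold,
                 alpha_grid = alpha_grid, nlambda = nlambda, seed = seed)

  restricted <- intersect_with_network(mutations, network)
  smoothed <- smooth_cohort(restricted$matrix, network, restart = restart,
                            tol = rwr_tol)
  sel <- rank_by_variability(smoothed, top_n = top_n, method = variability)
  A <- prepare_gnmf_input(smoothed, sel$gene)
  graph <- build_affinity(A, knn = knn)
  consensus <- consensus_cluster(A, k_range = k_range, n_runs = n_runs,
                                 graph = graph, lambda = lambda,
                                 base_seed = derive_seed(seed, 4L))
  ksel <- select_k(consensus)
  best <- consensus[[paste0("k", ksel$k_best)]]
  sil <- silhouette_widths(best$consensus, best$labels,
                           threshold = silhouette_threshold)
  model <- NULL
  if (classify) {
    core <- sil$core_ids
    Xcore <- smoothed[core, sel$gene, drop = FALSE]
    model <- subtype_model(Xcore, best$labels[core],
                           alpha_grid = alpha_grid, nlambda = nlambda)
  }
  battery <- NULL
  if (!is.null(clinical)) {
    lab_mat <- vapply(consensus, `[[`, integer(nrow(smoothed)), "labels")
    battery <- association_battery(lab_mat, clinical)
  }
  structure(list(smoothed = smoothed, selected_genes = sel,
                 gnmf_input = A, affinity = graph,
                 consensus = consensus, k_table = ksel$table,
                 k_best = ksel$k_best, labels = best$labels,
                 silhouette = sil, core_ids = sil$core_ids,
                 model = model, battery = battery,
                 dropped_genes = restricted$dropped_genes,
                 network = network, config = config),
            class = "netstrat_fit")
}

#' @export
print.netstrat_fit <- function(x, ...) {
  cat("Network-based stratification fit\n")
  cat(sprintf("  %d patients x %d network genes smoothed (r = %.2f)\n",
              nrow(x$smoothed), ncol(x$smoothed), x$config$restart))
  cat(sprintf("  top %d genes, consensus over k = %s (%d runs each)\n",
              nrow(x$selected_genes),
              paste(range(x$k_table$k), collapse = ".."),
              x$consensus[[1]]$n_runs))
  cat(sprintf("  selected k = %d (cophenetic %.4f); subtype sizes: %s\n",
              x$k_best,
              x$k_table$cophenetic[x$k_table$k == x$k_best],
              paste(tabulate(x$labels, x$k_best), collapse = "/")))
  cat(sprintf("  core samples: %d of %d (silhouette > %.2f)\n",
              length(x$core_ids), nrow(x$smoothed),
              x$silhouette$threshold))
  if (!is.null(x$model)) {
    cat(sprintf("  jackknife accuracy %.2f%% (alpha = %.2f, lambda = %.4g)\n",
                100 * x$model$jackknife_accuracy, x$model$alpha,
                x$model$lambda))
  }
  invisible(x)
}

#' @export
summary.netstrat_fit <- function(object, ...) {
  print(object)
  cat("\nCophenetic coefficients:\n")
  print(object$k_table, row.names = FALSE)
  if (!is.null(object$model)) {
    sizes <- vapply(object$model$biomarkers, length, integer(1))
    cat("\nBiomarkers per subtype:",
        paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  }
  if (!is.null(object$battery)) {
    cat("\nClinical associations (p-values):\n")
    print(signif(object$battery$p_values, 3))
  }
  invisible(object)
}

#' Biomarker coefficients of the fitted subtype model
#'
#' @param object a `netstrat_fit`.
#' @param ... unused.
#' @return genes-by-subtypes coefficient matrix, or NULL when the
#'   classifier was not fitted.
#' @export
coef.netstrat_fit <- function(object, ...) {
  if (is.null(object$model)) return(NULL)
  object$model$coefficients
}

#' Classify new patients with a fitted stratification model
#'
#' New binary mutation profiles are smoothed over the model's network with
#' the model's restart probability, restricted to the selected genes, and
#' classified by the fitted elastic net.
#'
#' @param object a `netstrat_fit` with a classifier.
#' @param newdata binary patients-by-genes mutation matrix.
#' @param ... unused.
#' @return character vector of predicted subtype labels.
#' @export
predict.netstrat_fit <- function(object, newdata, ...) {
  if (is.null(object$model)) {
    stop_netstrat("model was fitted with classify = FALSE",
                  "netstrat_config_error")
  }
  restricted <- intersect_with_network(newdata, object$network)
  sm <- smooth_cohort(restricted$matrix, object$network,
                      restart = object$config$restart,
                      tol = object$config$rwr_tol)
  X <- sm[, object$selected_genes$gene, drop = FALSE]
  pr <- predict(object$model$glmnet_fit, newx = X, s = object$model$lambda,
                type = "class")
  stats::setNames(as.character(pr[, 1]), rownames(X))
}

#' Diagnostic plots for a stratification fit
#'
#' Draws the cophenetic-coefficient curve over the candidate cluster
#' counts and the consensus matrix heatmap at the selected k (patients
#' ordered by cluster).
#'
#' @param x a `netstrat_fit`.
#' @param ... unused.
#' @export
plot.netstrat_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$k_table$k, x$k_table$cophenetic, type = "b", pch = 19,
                 xlab = "k", ylab = "cophenetic coefficient",
                 main = "Cluster-count selection")
  graphics::abline(v = x$k_best, lty = 2, col = "grey40")
  best <- x$consensus[[paste0("k", x$k_best)]]
  ord <- order(best$labels)
  graphics::image(best$consensus[ord, rev(ord)],
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE,
                  main = sprintf("Consensus matrix (k = %d)", x$k_best))
  invisible(x)
}
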