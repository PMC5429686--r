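#' Consensus clustering over random factorization restarts
#'
#' For each candidate cluster count `k`, runs [gnmf()] `n_runs` times from
#' different random initializations (seeds `base_seed + run`), records for
#' every patient pair the fraction of runs assigning them the same label,
#' and derives final labels by average-linkage hierarchical clustering of
#' the consensus distance `1 - consensus`, cutting the tree at `k`.
#' Stopping at the update cap is a normal termination (the
#' restart-to-restart label variability it leaves is what the consensus
#' matrix measures); a run that fails numerically (non-finite factors) is
#' retried once with a shifted seed, then excluded with a warning, and
#' more than 10% exclusions for a `k` is an error.
#'
#' @param A nonnegative genes-by-patients matrix from
#'   [prepare_gnmf_input()].
#' @param k_range candidate cluster counts (default 2:9).
#' @param n_runs restarts per k (default 100).
#' @param graph patient affinity graph; built from `A` when NULL.
#' @param lambda,knn,max_iter,tol passed to [gnmf()].
#' @param base_seed seed from which the per-run seeds derive.
#' @return named list (one element per k) of `consensus_result` objects:
#'   `k`, `consensus` (patients x patients, unit diagonal), `labels`,
#'   `cophenetic`, `n_runs` (runs actually included).
#' @export
consensus_cluster <- function(A, k_range = 2:9, n_runs = 100L, graph = NULL,
                              lambda = 150, knn = 5L, max_iter = 500L,
                              tol = 1e-5, base_seed = 1L) {
  if (n_runs < 2) stop_netstrat("n_runs must be >= 2", "netstrat_config_error")
  if (is.null(graph)) graph <- build_affinity(A, knn = knn)
  np <- ncol(A)
  ids <- colnames(A)
  out <- lapply(k_range, function(k) {
    agree <- matrix(0, np, np)
    used <- 0L
    for (run in seq_len(n_runs)) {
      fit <- gnmf(A, k, graph = graph, lambda = lambda,
                  max_iter = max_iter, tol = tol,
                  seed = base_seed + run)
      ok <- function(f) all(is.finite(f$U)) && all(is.finite(f$V))
      if (!ok(fit)) {
        fit <- gnmf(A, k, graph = graph, lambda = lambda,
                    max_iter = max_iter, tol = tol,
                    seed = base_seed + n_runs + run)
      }
      if (!ok(fit)) {
        warning(sprintf("excluding numerically failed run %d for k = %d",
                        run, k))
        next
      }
      lab <- fit$labels
      agree <- agree + outer(lab, lab, "==")
      used <- used + 1L
    }
    if (used < 0.9 * n_runs) {
      stop_netstrat(sprintf(
        "more than 10%% of runs excluded for k = %d (%d of %d kept)",
        k, used, n_runs), "netstrat_consensus_error")
    }
    consensus <- agree / used
    diag(consensus) <- 1
    dimnames(consensus) <- list(ids, ids)
    hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
    labels <- stats::cutree(hc, k = k)
    structure(list(k = as.integer(k), consensus = consensus,
                   labels = labels,
                   cophenetic = cophenetic_coefficient(consensus),
                   n_runs = used),
              class = "consensus_result")
  })
  names(out) <- paste0("k", k_range)
  out
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the upper-triangle consensus distances
#' `1 - consensus` and the cophenetic distances of their average-linkage
#' dendrogram. Values near 1 indicate that the dendrogram faithfully
#' reproduces the consensus structure, i.e. stable cluster assignments.
#' A constant distance matrix makes the correlation undefined; since all
#' merges then happen at a single height that reproduces the distances
#' exactly, 1.0 is returned with attribute `degenerate = TRUE`.
#'
#' @param consensus symmetric matrix with entries in \[0, 1\], unit
#'   diagonal, at least 3 patients.
#' @return the coefficient in \[-1, 1\].
#' @export
cophenetic_coefficient <- function(consensus) {
  if (nrow(consensus) < 3) {
    stop_netstrat("need at least 3 patients", "netstrat_data_error")
  }
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(cd) == 0) {
    if (max(abs(cd - d)) < 1e-12) {
      return(structure(1.0, degenerate = TRUE))
    }
    return(structure(NA_real_, degenerate = TRUE))
  }
  cc <- stats::cor(as.numeric(d), as.numeric(cd))
  # a dendrogram that reproduces the distances exactly has correlation 1;
  # snap away float noise so exact recovery is reported as exactly 1
  if (abs(cc - 1) < 1e-12) cc <- 1
  cc
}

#' Select the most robust cluster count
#'
#' Picks the `k` with the largest cophenetic coefficient; ties break
#' toward the smaller `k`.
#'
#' @param results list of `consensus_result` from [consensus_cluster()].
#' @return list with `k_best` and `table` (data.frame of k and
#'   cophenetic coefficient).
#' @export
select_k <- function(results) {
  if (length(results) < 2) {
    stop_netstrat("need at least two candidate k", "netstrat_config_error")
  }
  tab <- data.frame(k = vapply(results, `[[`, integer(1), "k"),
                    cophenetic = vapply(results, function(r)
                      as.numeric(r$cophenetic), numeric(1)))
  tab <- tab[order(tab$k), ]
  rownames(tab) <- NULL
  best <- tab$k[which.max(tab$cophenetic)]  # which.max takes first maximum
  list(k_best = as.integer(best), table = tab)
}

#' Silhouette widths on the consensus distance and core-sample extraction
#'
#' Standard silhouette widths `s(i) = (b(i) - a(i)) / max(a(i), b(i))`
#' computed with distance `1 - consensus`; members of singleton clusters
#' get width 0. Core samples are those with width strictly greater than
#' the threshold.
#'
#' @param consensus consensus matrix.
#' @param labels integer cluster labels (at least 2 nonempty clusters).
#' @param threshold core-sample cutoff (default 0.20, strict).
#' @return object of class `silhouette_report`: data.frame `widths`
#'   (patient, cluster, width), `core_ids`, `threshold`.
#' @export
silhouette_widths <- function(consensus, labels, threshold = 0.20) {
  if (length(unique(labels)) < 2) {
    stop_netstrat("silhouette undefined for a single cluster",
                  "netstrat_data_error")
  }
  sil <- cluster::silhouette(as.integer(labels),
                             dmatrix = 1 - consensus)
  widths <- data.frame(patient = rownames(consensus) %||%
                         seq_len(nrow(consensus)),
                       cluster = as.integer(labels),
                       width = sil[, "sil_width"],
                       stringsAsFactors = FALSE)
  structure(list(widths = widths,
                 core_ids = widths$patient[widths$width > threshold],
                 threshold = threshold),
            class = "silhouette_report")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering: k = %d over %d runs, cophenetic %.4f\n",
              x$k, x$n_runs, as.numeric(x$cophenetic)))
  cat("Cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("Silhouette: %d of %d samples with width > %.2f (core)\n",
              length(x$core_ids), nrow(x$widths), x$threshold))
  invisible(x)
}
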