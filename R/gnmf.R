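#' k-nearest-neighbor affinity graph over patients
#'
#' Links each patient (column of `A`) to its `knn` nearest patients by
#' Euclidean distance, symmetrizes by union, and returns the 0/1
#' adjacency with its degree vector and combinatorial Laplacian
#' `L = D - S`. This graph supplies the Laplacian regularizer of the
#' factorization objective.
#'
#' @param A numeric genes-by-patients matrix.
#' @param knn neighbors per patient (default 5).
#' @return list of class `affinity_graph`: `adjacency` (0/1 symmetric
#'   matrix), `degree` (vector), `laplacian`.
#' @export
build_affinity <- function(A, knn = 5L) {
  m <- ncol(A)
  if (m < knn + 1L) {
    stop_netstrat(sprintf("need at least knn + 1 = %d patients", knn + 1L),
                  "netstrat_config_error")
  }
  d <- as.matrix(stats::dist(t(A)))
  S <- matrix(0, m, m, dimnames = dimnames(d))
  for (i in seq_len(m)) {
    di <- d[i, ]
    di[i] <- Inf
    # tie-inclusive: everything as close as the knn-th neighbor is linked,
    # so the graph is order-independent (identical profiles link completely)
    thr <- sort(di, partial = knn)[knn]
    S[i, di <= thr] <- 1
  }
  S <- pmax(S, t(S))  # union symmetrization
  deg <- rowSums(S)
  structure(list(adjacency = S, degree = deg,
                 laplacian = diag(deg) - S),
            class = "affinity_graph")
}

#' Graph-regularized nonnegative matrix factorization
#'
#' Factorizes a nonnegative matrix `A` (genes x patients) as
#' `A ~ U %*% t(V)` with nonnegative basis `U` (genes x k) and
#' coefficients `V` (patients x k), minimizing
#' `||A - U V'||_F^2 + lambda * tr(V' L V)` where `L` is the Laplacian of
#' a patient affinity graph. Uses the standard multiplicative updates,
#' which keep the factors nonnegative and the objective non-increasing:
#' `U <- U * (A V) / (U V'V)` and
#' `V <- V * (A'U + lambda S V) / (V U'U + lambda D V)`.
#' Factors are initialized entrywise uniform(0, 1) from `seed`.
#'
#' @param A nonnegative genes-by-patients matrix.
#' @param k factorization rank (number of clusters).
#' @param graph an [build_affinity()] result over the patients of `A`;
#'   built from `A` with `knn` neighbors when NULL.
#' @param lambda regularization weight (default 150).
#' @param knn neighbor count used only when `graph` is NULL.
#' @param max_iter maximum multiplicative updates (default 500).
#' @param tol stop when the relative objective change drops below this
#'   (default 1e-5).
#' @param seed RNG seed for the initialization.
#' @return object of class `gnmf`: `U`, `V`, `objective` (per-iteration
#'   trace), `labels` (argmax cluster per patient), `iterations`,
#'   `converged`, `lambda`, `k`, `graph`.
#' @export
gnmf <- function(A, k, graph = NULL, lambda = 150, knn = 5L,
                 max_iter = 500L, tol = 1e-5, seed = NULL) {
  A <- as.matrix(A)
  if (min(A) < 0) {
    stop_netstrat("input matrix must be nonnegative", "netstrat_data_error")
  }
  if (k < 2) stop_netstrat("k must be at least 2", "netstrat_config_error")
  if (lambda < 0) stop_netstrat("lambda must be >= 0", "netstrat_config_error")
  if (is.null(graph)) graph <- build_affinity(A, knn = knn)
  S <- graph$adjacency
  deg <- graph$degree
  ng <- nrow(A); np <- ncol(A)
  eps <- 1e-12
  init <- with_seed(seed, list(U = matrix(stats::runif(ng * k), ng, k),
                               V = matrix(stats::runif(np * k), np, k)))
  U <- init$U; V <- init$V
  normA2 <- sum(A^2)
  objective <- numeric(max_iter)
  converged <- FALSE
  SV <- S %*% V
  for (it in seq_len(max_iter)) {
    VtV <- crossprod(V)
    U <- U * (A %*% V) / pmax(U %*% VtV, eps)
    UtU <- crossprod(U)
    AtU <- crossprod(A, U)
    V <- V * (AtU + lambda * SV) / pmax(V %*% UtU + lambda * deg * V, eps)
    # objective via trace identities (no n x m residual formed)
    VtV <- crossprod(V)
    SV <- S %*% V
    obj <- normA2 - 2 * sum(AtU * V) + sum(UtU * VtV) +
      lambda * (sum(deg * V^2) - sum(V * SV))
    objective[it] <- obj
    if (it > 1) {
      rel <- abs(objective[it - 1] - obj) / max(abs(objective[it - 1]), eps)
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
  }
  objective <- objective[seq_len(it)]
  dimnames(U) <- list(rownames(A), NULL)
  dimnames(V) <- list(colnames(A), NULL)
  structure(list(U = U, V = V, objective = objective,
                 labels = assign_clusters(V), iterations = it,
                 converged = converged, lambda = lambda, k = as.integer(k),
                 graph = graph, seed = seed),
            class = "gnmf")
}

# The objective recomputed directly from its definition; used by summary()
# and available to callers for verification.
#' Evaluate the graph-regularized factorization objective
#'
#' Computes `||A - U V'||_F^2 + lambda * tr(V' L V)` directly.
#'
#' @param A data matrix (genes x patients).
#' @param U,V factor matrices.
#' @param laplacian patient-graph Laplacian.
#' @param lambda regularization weight.
#' @return the objective value.
#' @export
gnmf_objective <- function(A, U, V, laplacian, lambda) {
  R <- A - U %*% t(V)
  sum(R^2) + lambda * sum(diag(t(V) %*% laplacian %*% V))
}

#' Cluster labels from the coefficient matrix
#'
#' Each patient is assigned the component with the largest coefficient;
#' ties break toward the lowest index. An all-zero row triggers a warning
#' and label 1.
#'
#' @param V nonnegative patients-by-k coefficient matrix.
#' @return integer vector of labels in 1..k, named by patient.
#' @export
assign_clusters <- function(V) {
  V <- as.matrix(V)
  if (any(rowSums(V) == 0)) {
    warning("all-zero coefficient row(s); assigning label 1")
  }
  stats::setNames(max.col(V, ties.method = "first"), rownames(V))
}

#' @export
print.gnmf <- function(x, ...) {
  cat(sprintf(
    "GNMF fit: k = %d, lambda = %g, %d iteration(s), objective %.6g (%s)\n",
    x$k, x$lambda, x$iterations, x$objective[length(x$objective)],
    if (x$converged) "converged" else "iteration cap reached"))
  cat("Cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}
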