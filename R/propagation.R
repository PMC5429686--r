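#' Seed vector for a patient's random walk
#'
#' Distributes unit probability mass equally over the patient's mutated
#' genes that are present in the network node set.
#'
#' @param mutated_genes character vector of mutated gene symbols, or a
#'   named binary vector (a row of the mutation matrix).
#' @param network a `ppi_network`.
#' @return numeric vector over `network$nodes` summing to 1.
#' @export
seed_vector <- function(mutated_genes, network) {
  if (!is.character(mutated_genes)) {
    mutated_genes <- names(mutated_genes)[mutated_genes > 0]
  }
  idx <- match(mutated_genes, network$nodes)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    stop_netstrat("patient has no mutated genes in the network",
                  "netstrat_no_seed")
  }
  p0 <- numeric(length(network$nodes))
  p0[idx] <- 1 / length(idx)
  names(p0) <- network$nodes
  p0
}

#' Random walk with restart to steady state
#'
#' Iterates `p <- (1 - r) * W %*% p + r * p0` from `p = p0` until the L1
#' change between successive iterates falls below `tol`. With a
#' column-stochastic `W` the iteration conserves probability mass, and the
#' fixed point is the restarting walk's stationary distribution
#' `r * solve(I - (1 - r) * W) %*% p0`.
#'
#' @param p0 seed distribution (sums to 1).
#' @param W column-normalized adjacency (dense or sparse).
#' @param restart restart probability r in \[0, 1\] (default 0.75).
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   final residual.
#' @return the steady-state vector, with attributes `iterations` and
#'   `residual`.
#' @export
rwr_steady_state <- function(p0, W, restart = 0.75, tol = 1e-6,
                             max_iter = 10000L) {
  if (restart < 0 || restart > 1) {
    stop_netstrat("restart probability must lie in [0, 1]",
                  "netstrat_config_error")
  }
  if (tol <= 0) stop_netstrat("tolerance must be positive", "netstrat_config_error")
  p <- as.numeric(p0)
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - restart) * (W %*% p)) + restart * as.numeric(p0)
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) {
      names(p) <- names(p0) %||% rownames(W)
      attr(p, "iterations") <- it
      attr(p, "residual") <- res
      return(p)
    }
  }
  stop_netstrat(sprintf(
    "random walk did not converge in %d iterations (residual %.3g)",
    max_iter, res), "netstrat_convergence_error")
}

#' Smooth a mutation cohort over a network
#'
#' Runs the restarting random walk for every patient, seeding each walk at
#' the patient's in-network mutated genes. All patients are iterated
#' jointly (one sparse matrix product per step) until each patient's own
#' L1 change is below `tol`; results are identical to per-patient
#' iteration within numerical noise.
#'
#' @param mutations binary patients-by-genes matrix whose columns are
#'   network genes (see [intersect_with_network()]).
#' @param network a `ppi_network`.
#' @param restart,tol,max_iter see [rwr_steady_state()].
#' @param strict if TRUE, a patient with no in-network mutated gene is an
#'   error; default drops such patients with a warning.
#' @return numeric matrix (patients x network nodes) of steady-state
#'   scores, rows summing to 1; attributes `iterations` (per patient,
#'   first step at which it converged), `dropped` (patient ids removed).
#' @export
smooth_cohort <- function(mutations, network, restart = 0.75, tol = 1e-6,
                          max_iter = 10000L, strict = FALSE) {
  stopifnot(inherits(network, "ppi_network"))
  nodes <- network$nodes
  idx <- match(colnames(mutations), nodes)
  if (anyNA(idx)) {
    stop_netstrat("mutation matrix contains genes absent from the network; run intersect_with_network() first",
                  "netstrat_data_error")
  }
  m <- rowSums(mutations)
  dropped <- rownames(mutations)[m == 0]
  if (length(dropped)) {
    if (strict) {
      stop_netstrat(sprintf("patients with no in-network mutated genes: %s",
                            paste(dropped, collapse = ", ")),
                    "netstrat_no_seed")
    }
    warning(sprintf("dropping %d patient(s) with no in-network mutated genes",
                    length(dropped)))
    mutations <- mutations[m > 0, , drop = FALSE]
    m <- m[m > 0]
  }
  np <- nrow(mutations)
  P0 <- matrix(0, np, length(nodes), dimnames = list(rownames(mutations), nodes))
  P0[, idx] <- as.matrix(mutations) / m
  Wt <- Matrix::t(network$W)
  P <- P0
  iters <- rep(NA_integer_, np)
  for (it in seq_len(max_iter)) {
    P_new <- (1 - restart) * as.matrix(P %*% Wt) + restart * P0
    res <- rowSums(abs(P_new - P))
    P <- P_new
    newly <- is.na(iters) & res < tol
    iters[newly] <- it
    if (all(res < tol)) break
    if (it == max_iter) {
      stop_netstrat(sprintf(
        "random walk did not converge in %d iterations (max residual %.3g)",
        max_iter, max(res)), "netstrat_convergence_error")
    }
  }
  dimnames(P) <- list(rownames(mutations), nodes)
  attr(P, "iterations") <- stats::setNames(iters, rownames(mutations))
  attr(P, "dropped") <- dropped
  attr(P, "restart") <- restart
  P
}
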