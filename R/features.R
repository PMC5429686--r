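#' Rank genes by variability across patients
#'
#' Computes each gene's sample variance (n-1 denominator) or coefficient
#' of variation (sd/mean; genes with zero mean have undefined CV and are
#' ranked last) across patients on the smoothed matrix, sorts descending
#' with ties broken by gene symbol ascending, and returns the top `top_n`.
#'
#' @param smoothed numeric patients-by-genes matrix.
#' @param top_n how many genes to keep (default 500).
#' @param method "variance" (default) or "cv".
#' @return data.frame with columns `gene`, `score`, ordered by rank.
#' @export
rank_by_variability <- function(smoothed, top_n = 500L,
                                method = c("variance", "cv")) {
  method <- match.arg(method)
  if (nrow(smoothed) < 2) {
    stop_netstrat("need at least two patients to rank variability",
                  "netstrat_data_error")
  }
  if (top_n < 2 || top_n > ncol(smoothed)) {
    stop_netstrat(sprintf("top_n must be in [2, %d]", ncol(smoothed)),
                  "netstrat_config_error")
  }
  n <- nrow(smoothed)
  mu <- colMeans(smoothed)
  v <- (colSums(smoothed^2) - n * mu^2) / (n - 1)
  v <- pmax(v, 0)  # guard tiny negative from cancellation
  score <- if (method == "variance") v else ifelse(mu > 0, sqrt(v) / mu, -Inf)
  ord <- order(-score, colnames(smoothed))
  sel <- ord[seq_len(top_n)]
  data.frame(gene = colnames(smoothed)[sel],
             score = ifelse(is.finite(score[sel]), score[sel], NA_real_),
             stringsAsFactors = FALSE)
}

#' Prepare the nonnegative input matrix for factorization
#'
#' Restricts the smoothed matrix to the selected genes, transposes to the
#' genes-by-patients orientation expected by [gnmf()], median-centers each
#' gene across patients, restores nonnegativity (`global_shift`, the
#' default, adds the absolute value of the global minimum, preserving all
#' pairwise differences; `clamp_zero` truncates negatives at zero), and
#' finally rescales the whole matrix to unit mean entry.
#'
#' The rescale is a single global factor, so like the global shift it
#' preserves ranks and relative distances; it matters because the
#' smoothed profiles are probability rows whose entries are of order
#' 1e-2 (they scale inversely with the network size), while the
#' graph-regularization weight of [gnmf()] (default `lambda = 150`) is
#' calibrated for data whose typical entry is of order 1. Without a
#' common scale the Laplacian penalty would either swamp the
#' reconstruction term (collapsing clusters) or vanish, and its effect
#' would depend on an arbitrary unit. `"unit_max"` scales by the
#' maximum entry instead; `"none"` disables rescaling.
#'
#' @param smoothed numeric patients-by-genes matrix.
#' @param genes character vector of selected genes (subset of columns),
#'   e.g. `rank_by_variability(...)$gene`.
#' @param center "median" (default) or "none".
#' @param nonneg "global_shift" (default), "clamp_zero" or "none".
#' @param rescale "unit_mean" (default, divide by the mean entry),
#'   "unit_max" (divide by the maximum) or "none".
#' @return nonnegative genes-by-patients matrix; attribute `transform`
#'   records the centering mode, the shift and the scale factor applied.
#' @export
prepare_gnmf_input <- function(smoothed, genes,
                               center = c("median", "none"),
                               nonneg = c("global_shift", "clamp_zero", "none"),
                               rescale = c("unit_mean", "unit_max", "none")) {
  center <- match.arg(center)
  nonneg <- match.arg(nonneg)
  rescale <- match.arg(rescale)
  missing <- setdiff(genes, colnames(smoothed))
  if (length(missing)) {
    stop_netstrat(sprintf("selected genes absent from matrix: %s",
                          paste(utils::head(missing, 5), collapse = ", ")),
                  "netstrat_config_error")
  }
  A <- t(smoothed[, genes, drop = FALSE])  # genes x patients
  if (center == "median") {
    A <- A - apply(A, 1L, stats::median)
  }
  shift <- 0
  if (nonneg == "global_shift") {
    mn <- min(A)
    if (mn < 0) {
      shift <- -mn
      A <- A + shift
    }
  } else if (nonneg == "clamp_zero") {
    A[A < 0] <- 0
  }
  scale <- 1
  if (rescale == "unit_mean" && mean(A) > 0) {
    scale <- 1 / mean(A)
    A <- A * scale
  } else if (rescale == "unit_max" && max(A) > 0) {
    scale <- 1 / max(A)
    A <- A * scale
  }
  attr(A, "transform") <- list(center = center, nonneg = nonneg,
                               shift = shift, scale = scale)
  A
}
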