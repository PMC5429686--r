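#' Fit a multinomial elastic net at a given penalty
#'
#' Penalized multinomial logistic regression with penalty
#' `lambda * ((1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1)`, solved
#' by glmnet. The fit is computed along a short decreasing path ending at
#' `lambda` (warm starts stabilize the solution) and the coefficients at
#' `lambda` are returned.
#'
#' @param X numeric samples-by-genes matrix.
#' @param labels class per sample (2 or more classes, each with at least
#'   2 samples).
#' @param alpha elastic-net mixing in (0, 1].
#' @param lambda penalty strength.
#' @param standardize standardize features before fitting (default TRUE).
#' @return list of class `enet_fit`: `coefficients` (genes x classes
#'   matrix), `intercepts`, `alpha`, `lambda`, `classes`, `glmnet_fit`.
#' @export
fit_elastic_net <- function(X, labels, alpha, lambda, standardize = TRUE) {
  labels <- as.factor(labels)
  sizes <- table(labels)
  if (length(sizes) < 2) {
    stop_netstrat("need at least 2 classes", "netstrat_data_error")
  }
  if (any(sizes < 2)) {
    stop_netstrat(sprintf("class '%s' has fewer than 2 samples",
                          names(sizes)[which(sizes < 2)[1]]),
                  "netstrat_fit_error")
  }
  path <- lambda * c(64, 16, 4, 1)
  fit <- glmnet::glmnet(X, labels, family = "multinomial", alpha = alpha,
                        lambda = path, standardize = standardize)
  co <- stats::coef(fit, s = lambda)
  beta <- do.call(cbind, lapply(co, function(m) as.numeric(m[-1, 1])))
  dimnames(beta) <- list(colnames(X), names(co))
  intercepts <- vapply(co, function(m) m[1, 1], numeric(1))
  structure(list(coefficients = beta, intercepts = intercepts,
                 alpha = alpha, lambda = lambda,
                 classes = levels(labels), glmnet_fit = fit),
            class = "enet_fit")
}

#' @export
predict.enet_fit <- function(object, newx, ...) {
  pr <- predict(object$glmnet_fit, newx = newx, s = object$lambda,
                type = "class")
  as.character(pr[, 1])
}

#' Jackknife (leave-one-out) tuning of the elastic net
#'
#' For each mixing value `alpha`, a shared decreasing lambda path is taken
#' from the full-data glmnet fit; then for every sample the model is
#' refitted on the remaining n - 1 samples and the held-out sample is
#' predicted at every lambda. The grid point minimizing the leave-one-out
#' misclassification error is selected, ties broken toward the larger
#' lambda and then the smaller alpha (the more parsimonious model).
#'
#' @param X samples-by-genes matrix.
#' @param labels class per sample (n >= 10).
#' @param alpha_grid mixing values in (0, 1] (default 0.1..1 step 0.1).
#' @param nlambda length of the per-alpha lambda path (default 50).
#' @param lambda_path optional explicit decreasing path shared across
#'   alphas (overrides `nlambda`).
#' @param standardize passed to glmnet.
#' @return list of class `jackknife_tune`: `alpha`, `lambda`, `error`
#'   (misclassification fraction), `accuracy`, `error_table` (one row per
#'   grid point), `predictions` (LOO prediction per sample at the chosen
#'   grid point).
#' @export
jackknife_tune <- function(X, labels, alpha_grid = seq(0.1, 1, by = 0.1),
                           nlambda = 50L, lambda_path = NULL,
                           standardize = TRUE) {
  labels <- as.factor(labels)
  n <- nrow(X)
  if (n < 10) stop_netstrat("need at least 10 samples", "netstrat_data_error")
  if (length(alpha_grid) == 0) {
    stop_netstrat("alpha grid is empty", "netstrat_config_error")
  }
  if (any(alpha_grid <= 0 | alpha_grid > 1)) {
    stop_netstrat("alpha values must lie in (0, 1]", "netstrat_config_error")
  }
  rows <- list()
  pred_store <- list()
  for (alpha in alpha_grid) {
    path <- lambda_path
    if (is.null(path)) {
      full <- glmnet::glmnet(X, labels, family = "multinomial",
                             alpha = alpha, nlambda = nlambda,
                             standardize = standardize)
      path <- full$lambda
    }
    preds <- matrix(NA_character_, n, length(path))
    for (i in seq_len(n)) {
      fit <- glmnet::glmnet(X[-i, , drop = FALSE], labels[-i],
                            family = "multinomial", alpha = alpha,
                            lambda = path, standardize = standardize)
      pr <- predict(fit, newx = X[i, , drop = FALSE], s = path,
                    type = "class")
      preds[i, ] <- as.character(pr)
    }
    err <- colMeans(preds != as.character(labels))
    rows[[length(rows) + 1L]] <- data.frame(alpha = alpha, lambda = path,
                                            error = err)
    pred_store[[length(pred_store) + 1L]] <- preds
  }
  tab <- do.call(rbind, rows)
  # ties: larger lambda, then smaller alpha
  ord <- order(tab$error, -tab$lambda, tab$alpha)
  best <- tab[ord[1], ]
  ai <- match(best$alpha, alpha_grid)
  li <- which(rows[[ai]]$lambda == best$lambda)[1]
  structure(list(alpha = best$alpha, lambda = best$lambda,
                 error = best$error, accuracy = 1 - best$error,
                 error_table = tab,
                 predictions = stats::setNames(pred_store[[ai]][, li],
                                               rownames(X))),
            class = "jackknife_tune")
}

#' Fit the subtype classification model
#'
#' Tunes (alpha, lambda) by the jackknife, refits on all samples at the
#' chosen grid point, and extracts per-subtype biomarker genes (the genes
#' with a nonzero coefficient for that class in the symmetric multinomial
#' parameterization).
#'
#' @param X core-sample feature matrix (samples x genes).
#' @param labels subtype per sample.
#' @param ... passed to [jackknife_tune()].
#' @return object of class `subtype_model`: the final `enet_fit` fields
#'   plus `jackknife_error`, `jackknife_accuracy`, `biomarkers` (named
#'   list per class), `tuning`.
#' @export
subtype_model <- function(X, labels, ...) {
  tune <- jackknife_tune(X, labels, ...)
  fit <- fit_elastic_net(X, labels, alpha = tune$alpha, lambda = tune$lambda)
  bio <- extract_biomarkers(fit)
  structure(c(unclass(fit),
              list(jackknife_error = tune$error,
                   jackknife_accuracy = tune$accuracy,
                   biomarkers = bio$per_class, overlaps = bio,
                   tuning = tune)),
            class = c("subtype_model", "enet_fit"))
}

#' Biomarker gene lists and their pairwise overlaps
#'
#' @param model an `enet_fit` or `subtype_model`.
#' @return list: `per_class` (genes with nonzero coefficient per class),
#'   `union_size`, `pairwise` (data.frame class_a, class_b, overlap).
#' @export
extract_biomarkers <- function(model) {
  beta <- model$coefficients
  per_class <- lapply(seq_len(ncol(beta)), function(j) {
    rownames(beta)[beta[, j] != 0]
  })
  names(per_class) <- colnames(beta)
  cls <- colnames(beta)
  pairs <- if (length(cls) >= 2) utils::combn(cls, 2) else
    matrix(character(0), 2, 0)
  pairwise <- data.frame(
    class_a = pairs[1, ], class_b = pairs[2, ],
    overlap = apply(pairs, 2, function(p)
      length(intersect(per_class[[p[1]]], per_class[[p[2]]]))),
    stringsAsFactors = FALSE)
  list(per_class = per_class,
       union_size = length(unique(unlist(per_class))),
       pairwise = pairwise)
}

#' Accuracy as a function of the number of selected genes
#'
#' Repeats variability ranking and jackknife tuning for each requested
#' top-N gene count and tabulates the leave-one-out accuracy.
#'
#' @param smoothed patients-by-genes smoothed matrix.
#' @param labels subtype per patient (rows of `smoothed`).
#' @param n_values gene counts to sweep (default 300..1000 by 100).
#' @param variability passed to [rank_by_variability()].
#' @param ... passed to [jackknife_tune()].
#' @return data.frame with columns n_genes, accuracy, error, alpha, lambda.
#' @export
top_n_sweep <- function(smoothed, labels,
                        n_values = seq(300L, 1000L, by = 100L),
                        variability = "variance", ...) {
  if (any(n_values > ncol(smoothed))) {
    stop_netstrat("n_values exceed the number of genes",
                  "netstrat_config_error")
  }
  rows <- lapply(n_values, function(nv) {
    sel <- rank_by_variability(smoothed, top_n = nv, method = variability)
    tune <- jackknife_tune(smoothed[, sel$gene, drop = FALSE], labels, ...)
    data.frame(n_genes = nv, accuracy = tune$accuracy, error = tune$error,
               alpha = tune$alpha, lambda = tune$lambda)
  })
  do.call(rbind, rows)
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf(
    "Elastic-net subtype model: alpha = %.2f, lambda = %.4g\n",
    x$alpha, x$lambda))
  cat(sprintf("Jackknife accuracy %.2f%% (misclassification error %.2f%%)\n",
              100 * x$jackknife_accuracy, 100 * x$jackknife_error))
  sizes <- vapply(x$biomarkers, length, integer(1))
  cat("Biomarkers per subtype:",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}
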