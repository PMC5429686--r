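new_test_result <- function(statistic, df, p_value, method, table_or_n,
                            degenerate = FALSE) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method,
                 table_or_n = table_or_n, degenerate = degenerate),
            class = "netstrat_test")
}

#' @export
print.netstrat_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.3g%s\n", x$method,
              x$statistic,
              if (!is.null(x$df) && !is.na(x$df))
                sprintf(" (df = %g)", x$df) else "",
              x$p_value,
              if (isTRUE(x$degenerate)) " [degenerate input]" else ""))
  invisible(x)
}

#' Chi-square test of a contingency table
#'
#' Pearson chi-square test of independence; for 2x2 tables the Yates
#' continuity correction is applied by default (and never for larger
#' tables). Margins must all be positive.
#'
#' @param tab r-by-c matrix of nonnegative integer counts (r, c >= 2).
#' @param yates_2x2 apply the continuity correction when the table is 2x2.
#' @return a `netstrat_test` with statistic, df = (r-1)(c-1), p-value.
#' @export
chi_square <- function(tab, yates_2x2 = TRUE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop_netstrat("table must be at least 2x2", "netstrat_test_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    margin <- if (any(rowSums(tab) == 0)) "row" else "column"
    stop_netstrat(sprintf("zero %s margin in contingency table", margin),
                  "netstrat_test_error")
  }
  correct <- yates_2x2 && nrow(tab) == 2 && ncol(tab) == 2
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_test_result(ht$statistic, ht$parameter, ht$p.value,
                  if (correct) "Chi-square (Yates)" else "Chi-square",
                  tab)
}

#' Kruskal-Wallis rank-sum test
#'
#' @param values numeric observations (NA dropped pairwise with groups).
#' @param groups group per observation (at least 2 nonempty groups).
#' @return a `netstrat_test` (tie-corrected H, chi-square p). All values
#'   identical gives statistic 0 and p = 1 with a degenerate flag.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) {
    stop_netstrat("need at least 2 groups", "netstrat_test_error")
  }
  if (length(unique(values)) == 1) {
    return(new_test_result(0, nlevels(groups) - 1, 1, "Kruskal-Wallis",
                           table(groups), degenerate = TRUE))
  }
  ht <- stats::kruskal.test(values, groups)
  new_test_result(ht$statistic, ht$parameter, ht$p.value, "Kruskal-Wallis",
                  table(groups))
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test using the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples (NA dropped).
#' @return a `netstrat_test`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop_netstrat("both samples must be nonempty", "netstrat_test_error")
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  new_test_result(ht$statistic, NA_real_, ht$p.value,
                  "Wilcoxon rank-sum", c(n_x = length(x), n_y = length(y)))
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimate per group and the two-sided log-rank
#' test across groups (chi-square with groups - 1 df). With no events
#' anywhere the curves are identically 1 and p = 1 with a degenerate flag.
#'
#' @param followup_days nonnegative follow-up times.
#' @param event 0/1 death indicator.
#' @param groups group per patient.
#' @return list with `curves` (data.frame group, time, survival, n_risk,
#'   n_event) and `test` (a `netstrat_test`).
#' @export
km_logrank <- function(followup_days, event, groups) {
  keep <- !is.na(followup_days) & !is.na(event) & !is.na(groups)
  followup_days <- followup_days[keep]
  event <- event[keep]
  groups <- factor(groups[keep])
  if (any(followup_days < 0)) {
    stop_netstrat("negative follow-up time", "netstrat_test_error")
  }
  if (!all(event %in% c(0, 1))) {
    stop_netstrat("event indicator must be 0/1", "netstrat_test_error")
  }
  if (any(table(groups) == 0) || nlevels(groups) < 2) {
    stop_netstrat("each group needs at least one observation and 2+ groups",
                  "netstrat_test_error")
  }
  fit <- survival::survfit(survival::Surv(followup_days, event) ~ groups)
  strata_names <- sub("^groups=", "", rep(names(fit$strata),
                                          fit$strata %||% length(fit$time)))
  curves <- data.frame(group = strata_names, time = fit$time,
                       survival = fit$surv, n_risk = fit$n.risk,
                       n_event = fit$n.event, stringsAsFactors = FALSE)
  if (sum(event) == 0) {
    test <- new_test_result(0, nlevels(groups) - 1, 1, "Log-rank",
                            table(groups), degenerate = TRUE)
  } else {
    sd <- survival::survdiff(survival::Surv(followup_days, event) ~ groups)
    p <- stats::pchisq(sd$chisq, df = nlevels(groups) - 1,
                       lower.tail = FALSE)
    test <- new_test_result(sd$chisq, nlevels(groups) - 1, p, "Log-rank",
                            table(groups))
  }
  list(curves = curves, test = test)
}

# Designated test per clinical variable, mirroring the usual association
# battery layout: ordinal/continuous vs subtype -> Kruskal-Wallis,
# categorical vs subtype -> chi-square, survival -> log-rank.
battery_variables <- function() {
  list(gleason = "kw", positive_node_count = "kw", psa = "kw",
       path_n = "chisq", path_t = "chisq", clin_t = "chisq",
       lymph_status = "chisq", survival = "logrank")
}

#' Clinical association battery
#'
#' Tests every clinical variable against one or several subtype labelings:
#' Gleason score, positive-node count and PSA by Kruskal-Wallis;
#' pathologic N/T, clinical T and lymph-node status by chi-square (Yates
#' only for 2x2); survival by log-rank. Missing values are excluded
#' variable by variable. Degenerate cases (a single label, constant
#' values) are flagged, not errors.
#'
#' @param labels integer vector (one labeling, named by patient id) or a
#'   patients-by-k matrix/data.frame of labelings (columns = candidate k).
#' @param clinical clinical table as produced by [generate_clinical()];
#'   rows matched to labels by `patient_id` when names are available.
#' @return object of class `association_battery`: `p_values` (variables x
#'   labelings), `tests` (nested list of `netstrat_test`).
#' @export
association_battery <- function(labels, clinical) {
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1,
                                             dimnames = list(names(labels),
                                                             "labels"))
  labels <- as.matrix(labels)
  if (!is.null(rownames(labels)) && "patient_id" %in% names(clinical)) {
    idx <- match(rownames(labels), clinical$patient_id)
    miss <- is.na(idx)
    if (any(miss)) {
      message(sprintf("dropping %d labelled patient(s) without clinical rows",
                      sum(miss)))
    }
    labels <- labels[!miss, , drop = FALSE]
    clinical <- clinical[idx[!miss], , drop = FALSE]
  } else if (nrow(labels) != nrow(clinical)) {
    stop_netstrat("labels and clinical table sizes differ and ids are unavailable",
                  "netstrat_data_error")
  }
  vars <- battery_variables()
  vars <- vars[names(vars) == "survival" |
                 names(vars) %in% names(clinical)]
  pm <- matrix(NA_real_, length(vars), ncol(labels),
               dimnames = list(names(vars),
                               colnames(labels) %||% seq_len(ncol(labels))))
  tests <- list()
  for (ci in seq_len(ncol(labels))) {
    lab <- labels[, ci]
    col_tests <- list()
    for (v in names(vars)) {
      res <- tryCatch({
        if (vars[[v]] == "kw") {
          kruskal_wallis(as.numeric(clinical[[v]]), lab)
        } else if (vars[[v]] == "chisq") {
          keep <- !is.na(clinical[[v]])
          tab <- table(factor(lab[keep]), clinical[[v]][keep])
          tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
          if (nrow(tab) < 2 || ncol(tab) < 2) {
            new_test_result(NA_real_, NA_real_, NA_real_, "Chi-square",
                            tab, degenerate = TRUE)
          } else chi_square(tab)
        } else {
          if (length(unique(lab)) < 2) {
            new_test_result(NA_real_, NA_real_, NA_real_, "Log-rank",
                            table(lab), degenerate = TRUE)
          } else {
            km_logrank(clinical$followup_days, clinical$event, lab)$test
          }
        }
      }, netstrat_error = function(e) {
        new_test_result(NA_real_, NA_real_, NA_real_, vars[[v]],
                        NULL, degenerate = TRUE)
      })
      col_tests[[v]] <- res
      pm[v, ci] <- res$p_value
    }
    tests[[ci]] <- col_tests
  }
  names(tests) <- colnames(pm)
  structure(list(p_values = pm, tests = tests),
            class = "association_battery")
}

#' @export
print.association_battery <- function(x, digits = 3, ...) {
  cat("Clinical association battery (p-values):\n")
  print(signif(x$p_values, digits))
  invisible(x)
}
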