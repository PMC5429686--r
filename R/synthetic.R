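#' Specification for a synthetic mutation cohort
#'
#' Collects the parameters of the synthetic study system: a modular
#' (planted-partition) protein-protein interaction network in which each
#' planted subtype owns a module containing its driver genes, and a sparse
#' binary patient-by-gene mutation matrix in which drivers mutate at a high
#' rate, all genes mutate at a low background rate, and a small fraction of
#' patients are hypermutators whose background rate is multiplied by a large
#' factor (so per-patient burden spans orders of magnitude, as in real
#' exome cohorts).
#'
#' @param n_genes total number of genes (network nodes).
#' @param n_modules number of network modules; must be at least the number
#'   of subtypes, since subtype `s` draws its drivers from module `s`.
#' @param module_sizes integer vector summing to `n_genes`; default splits
#'   the genes evenly.
#' @param intra_edge_prob,inter_edge_prob edge probabilities within and
#'   between modules.
#' @param n_patients cohort size.
#' @param subtype_proportions mixing proportions of the planted subtypes;
#'   must sum to 1.
#' @param drivers_per_subtype number of driver genes per subtype, sampled
#'   from that subtype's module.
#' @param driver_mut_prob per-patient mutation probability of each of its
#'   subtype's drivers.
#' @param background_mut_prob per-gene background mutation probability.
#' @param hypermutator_fraction expected fraction of hypermutator patients.
#' @param hypermutator_multiplier factor applied to the background rate of
#'   hypermutators (capped so probabilities stay at most 1).
#' @param seed master seed; all generator randomness derives from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L,
                           n_modules = 5L,
                           module_sizes = NULL,
                           intra_edge_prob = 0.02,
                           inter_edge_prob = 0.002,
                           n_patients = 300L,
                           subtype_proportions = c(1, 1, 1) / 3,
                           drivers_per_subtype = 5L,
                           driver_mut_prob = 0.8,
                           background_mut_prob = 0.002,
                           hypermutator_fraction = 0.05,
                           hypermutator_multiplier = 100,
                           seed = 1L) {
  if (is.null(module_sizes)) {
    module_sizes <- rep(n_genes %/% n_modules, n_modules)
    module_sizes[n_modules] <- module_sizes[n_modules] + n_genes %% n_modules
  }
  if (length(module_sizes) != n_modules || sum(module_sizes) != n_genes) {
    stop_netstrat("module_sizes must have length n_modules and sum to n_genes",
                  "netstrat_config_error")
  }
  probs <- c(intra_edge_prob, inter_edge_prob, driver_mut_prob,
             background_mut_prob, hypermutator_fraction,
             subtype_proportions)
  if (any(probs < 0 | probs > 1)) {
    stop_netstrat("probabilities must lie in [0, 1]", "netstrat_config_error")
  }
  if (abs(sum(subtype_proportions) - 1) > 1e-12) {
    stop_netstrat("subtype_proportions must sum to 1", "netstrat_config_error")
  }
  if (n_modules < 1L) {
    stop_netstrat("n_modules must be >= 1", "netstrat_config_error")
  }
  if (drivers_per_subtype > min(module_sizes[seq_along(subtype_proportions)])) {
    stop_netstrat("drivers_per_subtype exceeds its module size",
                  "netstrat_config_error")
  }
  if (length(subtype_proportions) > n_modules) {
    stop_netstrat("need at least one module per subtype", "netstrat_config_error")
  }
  if (hypermutator_multiplier <= 0) {
    stop_netstrat("hypermutator_multiplier must be positive",
                  "netstrat_config_error")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    intra_edge_prob = intra_edge_prob, inter_edge_prob = inter_edge_prob,
    n_patients = as.integer(n_patients),
    subtype_proportions = subtype_proportions,
    drivers_per_subtype = as.integer(drivers_per_subtype),
    driver_mut_prob = driver_mut_prob,
    background_mut_prob = background_mut_prob,
    hypermutator_fraction = hypermutator_fraction,
    hypermutator_multiplier = hypermutator_multiplier,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Map linear indices over the upper triangle of an s x s matrix
# (pairs a < b ordered (1,2),(1,3),(2,3),...) back to (a, b).
pair_from_index <- function(idx, s) {
  b <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  off <- (b - 1) * (b - 2) / 2
  over <- idx <= off
  b[over] <- b[over] - 1
  a <- idx - (b - 1) * (b - 2) / 2
  cbind(a, b)
}

gene_names <- function(n) sprintf("g%0*d", nchar(n), seq_len(n))

#' Generate a planted-partition interaction network
#'
#' Genes are partitioned into modules; within-module pairs are linked with
#' `intra_edge_prob`, between-module pairs with `inter_edge_prob`. Every
#' edge carries a confidence score drawn uniformly in (0.7, 1], so the
#' whole graph survives the default high-confidence score threshold.
#'
#' @param spec a [synthetic_spec()].
#' @return a `ppi_network` (see [read_string_edges()] for the class).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nodes <- gene_names(spec$n_genes)
  bounds <- cumsum(c(0L, spec$module_sizes))
  module_of <- rep(seq_len(spec$n_modules), spec$module_sizes)
  with_seed(derive_seed(spec$seed, 1L), {
    ea <- integer(0); eb <- integer(0)
    for (m in seq_len(spec$n_modules)) {
      s <- spec$module_sizes[m]
      if (s >= 2) {
        npairs <- s * (s - 1) / 2
        ne <- rbinom(1L, npairs, spec$intra_edge_prob)
        if (ne > 0) {
          ab <- pair_from_index(sample(npairs, ne), s)
          ea <- c(ea, bounds[m] + ab[, 1]); eb <- c(eb, bounds[m] + ab[, 2])
        }
      }
    }
    if (spec$n_modules >= 2 && spec$inter_edge_prob > 0) {
      for (m1 in seq_len(spec$n_modules - 1L)) {
        for (m2 in (m1 + 1L):spec$n_modules) {
          s1 <- spec$module_sizes[m1]; s2 <- spec$module_sizes[m2]
          npairs <- s1 * s2
          ne <- rbinom(1L, npairs, spec$inter_edge_prob)
          if (ne > 0) {
            idx <- sample(npairs, ne)
            ea <- c(ea, bounds[m1] + ((idx - 1L) %% s1) + 1L)
            eb <- c(eb, bounds[m2] + ((idx - 1L) %/% s1) + 1L)
          }
        }
      }
    }
    score <- 1 - 0.3 * runif(length(ea))  # in (0.7, 1]
    edges <- data.frame(gene_a = nodes[ea], gene_b = nodes[eb],
                        score = score, stringsAsFactors = FALSE)
    net <- new_ppi_network(edges, nodes = nodes, score_threshold = 0.7)
    net$module <- stats::setNames(module_of, nodes)
    net
  })
}

#' Generate a synthetic mutation cohort over a network
#'
#' Assigns each patient a planted subtype, mutates that subtype's driver
#' genes with `driver_mut_prob`, all genes with the (possibly hypermutated)
#' background rate, resamples any all-zero patient, and attaches a clinical
#' table whose grade/nodal/PSA distributions shift by subtype while
#' survival is subtype-independent.
#'
#' @param spec a [synthetic_spec()].
#' @param network optionally, a network already produced by
#'   [generate_network()] from the same spec; generated if missing.
#' @param effects clinical effect specification, see [clinical_effects()].
#' @return an object of class `synthetic_cohort`: list with elements
#'   `mutations` (binary patients-by-genes matrix, all-zero gene columns
#'   dropped), `true_labels`, `network`, `clinical`, `drivers`, `spec`.
#' @export
generate_cohort <- function(spec, network = NULL,
                            effects = clinical_effects(length(spec$subtype_proportions))) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(network)) network <- generate_network(spec)
  nodes <- gene_names(spec$n_genes)
  K <- length(spec$subtype_proportions)
  n <- spec$n_patients
  G <- spec$n_genes
  bounds <- cumsum(c(0L, spec$module_sizes))
  with_seed(derive_seed(spec$seed, 2L), {
    labels <- sample.int(K, n, replace = TRUE, prob = spec$subtype_proportions)
    drivers <- lapply(seq_len(K), function(s) {
      sort(nodes[bounds[s] + sample.int(spec$module_sizes[s],
                                        spec$drivers_per_subtype)])
    })
    hyper <- stats::runif(n) < spec$hypermutator_fraction
    bg <- pmin(1, spec$background_mut_prob *
                 ifelse(hyper, spec$hypermutator_multiplier, 1))
    draw_rows <- function(rows) {
      m <- matrix(stats::rbinom(length(rows) * G, 1L, rep(bg[rows], times = G)),
                  nrow = length(rows), ncol = G)
      for (s in seq_len(K)) {
        rs <- which(labels[rows] == s)
        if (length(rs)) {
          cols <- match(drivers[[s]], nodes)
          dm <- matrix(stats::rbinom(length(rs) * length(cols), 1L,
                                     spec$driver_mut_prob),
                       nrow = length(rs))
          m[rs, cols] <- pmax(m[rs, cols], dm)
        }
      }
      m
    }
    M <- draw_rows(seq_len(n))
    tries <- 0L
    while (any(zero <- rowSums(M) == 0)) {
      tries <- tries + 1L
      if (tries > 100L) {
        stop_netstrat("cannot produce a nonzero mutation profile; raise mutation probabilities",
                      "netstrat_config_error")
      }
      M[zero, ] <- draw_rows(which(zero))
    }
    dimnames(M) <- list(sprintf("P%0*d", nchar(n), seq_len(n)), nodes)
    M <- M[, colSums(M) > 0, drop = FALSE]
    clinical <- generate_clinical(labels, effects,
                                  seed = derive_seed(spec$seed, 3L),
                                  patient_ids = rownames(M))
    structure(list(mutations = M,
                   true_labels = stats::setNames(labels, rownames(M)),
                   network = network, clinical = clinical,
                   drivers = drivers, hypermutators = rownames(M)[hyper],
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' Per-subtype clinical effect specification
#'
#' Defines how the synthetic clinical covariates shift across planted
#' subtypes: row `s` of `gleason_probs` gives subtype `s`'s distribution
#' over Gleason scores 6-10, `nodal_p1` the probability of pathologic N1,
#' `lymph_pos_p` the probability of positive lymph nodes, `psa_meanlog`
#' the log-mean of the lognormal PSA level (ng/mL). Survival is exponential
#' with a shared `surv_rate` (events per day) regardless of subtype, so the
#' default cohort carries no survival signal; `censor_prob` is the
#' probability a patient is censored (at a uniform fraction of the event
#' time). `null = TRUE` makes every distribution identical across subtypes.
#'
#' @param n_subtypes number of subtypes the labels refer to.
#' @param null if TRUE, no covariate differs by subtype.
#' @param surv_rate exponential event rate per day.
#' @param censor_prob probability of censoring; 1 censors everyone.
#' @param na_prob probability a clinical covariate entry is missing.
#' @return a list of class `clinical_effects`.
#' @export
clinical_effects <- function(n_subtypes = 3L, null = FALSE,
                             surv_rate = 1 / 2000, censor_prob = 0.85,
                             na_prob = 0.04) {
  K <- as.integer(n_subtypes)
  sh <- if (null || K == 1L) rep(0.5, K) else seq(0.65, 0.25, length.out = K)
  gleason_probs <- t(vapply(sh, function(p) stats::dbinom(0:4, 4, p),
                            numeric(5)))
  structure(list(
    gleason_probs = gleason_probs,
    nodal_p1 = if (null) rep(0.15, K) else seq(0.25, 0.08, length.out = K),
    lymph_pos_p = if (null) rep(0.16, K) else seq(0.26, 0.09, length.out = K),
    path_t_probs = if (null) matrix(rep(c(0.45, 0.5, 0.05), each = K), K)
                   else cbind(seq(0.3, 0.55, length.out = K),
                              seq(0.62, 0.42, length.out = K),
                              seq(0.08, 0.03, length.out = K)),
    clin_t_probs = matrix(rep(c(0.35, 0.35, 0.25, 0.05), each = K), K),
    psa_meanlog = if (null) rep(0, K) else seq(0.4, -0.4, length.out = K),
    psa_sdlog = 0.8,
    surv_rate = surv_rate, censor_prob = censor_prob, na_prob = na_prob
  ), class = "clinical_effects")
}

#' Generate a clinical table for labelled patients
#'
#' @param true_labels integer subtype per patient (1-based).
#' @param effects a [clinical_effects()] whose dimension matches the number
#'   of subtypes referenced by `true_labels`.
#' @param seed RNG seed.
#' @param patient_ids optional ids; defaults to `P001`-style.
#' @return data.frame with columns patient_id, age, followup_days, event,
#'   gleason, path_n, path_t, clin_t, lymph_status, positive_node_count, psa.
#' @export
generate_clinical <- function(true_labels, effects = clinical_effects(max(true_labels)),
                              seed = NULL, patient_ids = NULL) {
  K <- nrow(effects$gleason_probs)
  if (any(!true_labels %in% seq_len(K))) {
    stop_netstrat(sprintf("labels contain subtypes outside 1..%d", K),
                  "netstrat_data_error")
  }
  n <- length(true_labels)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%0*d", nchar(n), seq_len(n))
  with_seed(seed, {
    draw_cat <- function(levels, probs) {
      vapply(true_labels, function(s) {
        sample(levels, 1L, prob = probs[s, ])
      }, levels[1])
    }
    gleason <- as.integer(draw_cat(as.character(6:10), effects$gleason_probs))
    path_n <- ifelse(stats::runif(n) < effects$nodal_p1[true_labels], "N1", "N0")
    lymph <- ifelse(stats::runif(n) < effects$lymph_pos_p[true_labels],
                    "positive", "negative")
    npos <- ifelse(lymph == "positive", 1L + stats::rpois(n, 1.5), 0L)
    path_t <- draw_cat(c("T2", "T3", "T4"), effects$path_t_probs)
    clin_t <- draw_cat(c("T1", "T2", "T3", "T4"), effects$clin_t_probs)
    psa <- stats::rlnorm(n, effects$psa_meanlog[true_labels], effects$psa_sdlog)
    age <- round(pmin(85, pmax(40, stats::rnorm(n, 62, 8))))
    t_event <- stats::rexp(n, effects$surv_rate)
    censored <- stats::runif(n) < effects$censor_prob
    followup <- ifelse(censored, t_event * stats::runif(n), t_event)
    event <- as.integer(!censored)
    blank <- function(x) {
      x[stats::runif(n) < effects$na_prob] <- NA
      x
    }
    data.frame(patient_id = patient_ids, age = age,
               followup_days = round(followup, 1), event = event,
               gleason = blank(gleason), path_n = blank(path_n),
               path_t = blank(path_t), clin_t = blank(clin_t),
               lymph_status = blank(lymph),
               positive_node_count = blank(npos),
               psa = blank(round(psa, 2)),
               stringsAsFactors = FALSE)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits a MAF-like mutation TSV (`Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`), a 3-column scored edge list, a clinical TSV
#' and a true-labels TSV, all consumable unchanged by the reader functions.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(cohort$mutations == 1L, arr.ind = TRUE)
  maf <- data.frame(
    Hugo_Symbol = colnames(cohort$mutations)[idx[, 2]],
    Tumor_Sample_Barcode = rownames(cohort$mutations)[idx[, 1]],
    Variant_Classification = "Missense_Mutation",
    stringsAsFactors = FALSE)
  maf <- maf[order(maf$Tumor_Sample_Barcode, maf$Hugo_Symbol), ]
  paths <- list(
    maf = file.path(dir, "mutations.maf.tsv"),
    edges = file.path(dir, "network_edges.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    labels = file.path(dir, "true_labels.tsv"))
  utils::write.table(maf, paths$maf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$network$edges, paths$edges, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, paths$clinical, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(patient_id = names(cohort$true_labels),
               subtype = cohort$true_labels),
    paths$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients x %d mutated genes, %d subtypes\n",
              nrow(x$mutations), ncol(x$mutations),
              length(x$spec$subtype_proportions)))
  cat(sprintf("Network: %d nodes, %d edges (%d modules)\n",
              length(x$network$nodes), nrow(x$network$edges),
              x$spec$n_modules))
  invisible(x)
}
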