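test_that("spec validation enforces the documented invariants", {
  expect_error(synthetic_spec(n_genes = 10, module_sizes = c(4, 4)),
               class = "netstrat_config_error")
  expect_error(synthetic_spec(intra_edge_prob = 1.2),
               class = "netstrat_config_error")
  expect_error(synthetic_spec(subtype_proportions = c(0.5, 0.4)),
               class = "netstrat_config_error")
  expect_error(synthetic_spec(n_genes = 30, n_modules = 3,
                              drivers_per_subtype = 20),
               class = "netstrat_config_error")
})

test_that("forced planted-partition topologies come out exactly", {
  # intra 1, inter 0, two modules of 3 -> two disjoint triangles
  spec <- synthetic_spec(n_genes = 6, n_modules = 2, intra_edge_prob = 1,
                         inter_edge_prob = 0, n_patients = 4,
                         subtype_proportions = c(0.5, 0.5),
                         drivers_per_subtype = 2, seed = 3)
  net <- generate_network(spec)
  expect_equal(nrow(net$edges), 6)
  expect_equal(network_summary(net)$n_components, 2)
  expect_true(all(net$edges$score > 0.7 & net$edges$score <= 1))
  expect_false(any(net$edges$gene_a == net$edges$gene_b))
  # inter = 0 -> at least as many components as modules
  spec2 <- synthetic_spec(n_genes = 60, n_modules = 4,
                          module_sizes = c(15, 15, 15, 15),
                          intra_edge_prob = 0.4, inter_edge_prob = 0,
                          n_patients = 4, drivers_per_subtype = 3, seed = 5)
  expect_gte(network_summary(generate_network(spec2))$n_components, 4)
})

test_that("intra-module edge count sits within binomial bounds", {
  spec <- synthetic_spec(n_genes = 100, n_modules = 4,
                         module_sizes = rep(25, 4), intra_edge_prob = 0.3,
                         inter_edge_prob = 0.01, n_patients = 4,
                         drivers_per_subtype = 5, seed = 11)
  net <- generate_network(spec)
  module <- net$module
  intra <- sum(module[net$edges$gene_a] == module[net$edges$gene_b])
  npairs <- 4 * choose(25, 2)
  expected <- npairs * 0.3
  sdev <- sqrt(npairs * 0.3 * 0.7)
  expect_lt(abs(intra - expected), 3 * sdev)
})

test_that("network generation is deterministic given the seed", {
  spec <- small_spec(seed = 8)
  n1 <- generate_network(spec)
  n2 <- generate_network(spec)
  expect_identical(n1$edges, n2$edges)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$mutations, co2$mutations)
  expect_identical(co1$clinical, co2$clinical)
})

test_that("pure driver cohorts mutate exactly the driver sets", {
  spec <- synthetic_spec(n_genes = 60, n_modules = 3,
                         module_sizes = rep(20, 3), intra_edge_prob = 0.5,
                         inter_edge_prob = 0, n_patients = 30,
                         drivers_per_subtype = 4, driver_mut_prob = 1,
                         background_mut_prob = 0, hypermutator_fraction = 0,
                         seed = 21)
  co <- generate_cohort(spec)
  for (i in seq_len(nrow(co$mutations))) {
    mut <- colnames(co$mutations)[co$mutations[i, ] == 1]
    expect_identical(mut, co$drivers[[co$true_labels[i]]])
  }
})

test_that("background burden and subtype counts obey binomial oracles", {
  spec <- synthetic_spec(n_genes = 5000, n_modules = 5,
                         n_patients = 200, drivers_per_subtype = 5,
                         driver_mut_prob = 1, background_mut_prob = 0.002,
                         hypermutator_fraction = 0, seed = 33)
  co <- generate_cohort(spec)
  # non-driver mutations per patient ~ Binomial(4985, 0.002), mean ~ 9.97
  driver_cols <- unique(unlist(co$drivers))
  bg <- rowSums(co$mutations[, !colnames(co$mutations) %in% driver_cols])
  n_bg <- spec$n_genes - length(driver_cols)
  expect_lt(abs(mean(bg) - n_bg * 0.002),
            3 * sqrt(n_bg * 0.002 / nrow(co$mutations)))

  spec2 <- synthetic_spec(n_genes = 300, n_modules = 3,
                          subtype_proportions = c(0.5, 0.3, 0.2),
                          n_patients = 1000, drivers_per_subtype = 5,
                          intra_edge_prob = 0.2, seed = 9)
  co2 <- generate_cohort(spec2)
  counts <- tabulate(co2$true_labels, 3)
  for (j in 1:3) {
    p <- c(0.5, 0.3, 0.2)[j]
    expect_lt(abs(counts[j] - 1000 * p), 3 * sqrt(1000 * p * (1 - p)))
  }
})

test_that("mutation matrices are binary with no empty patients", {
  for (sd in 1:3) {
    co <- generate_cohort(small_spec(seed = sd))
    expect_true(all(co$mutations %in% 0:1))
    expect_true(all(rowSums(co$mutations) >= 1))
    expect_true(all(colSums(co$mutations) >= 1))
    expect_true(all(unlist(co$drivers) %in% co$network$nodes))
    expect_equal(length(co$true_labels), co$spec$n_patients)
  }
})

test_that("hypermutators stretch the burden range beyond 50-fold", {
  ratios <- vapply(1:3, function(sd) {
    co <- generate_cohort(synthetic_spec(seed = sd))
    b <- rowSums(co$mutations)
    max(b) / min(b)
  }, numeric(1))
  expect_gt(median(ratios), 50)
})

test_that("null clinical effects produce uniform Kruskal-Wallis p-values", {
  ps <- vapply(1:200, function(i) {
    lab <- rep(1:3, each = 20)
    cl <- generate_clinical(lab, clinical_effects(3, null = TRUE),
                            seed = 5000 + i)
    suppressWarnings(kruskal_wallis(cl$gleason, lab)$p_value)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("deterministic grade effects and full censoring behave as forced", {
  eff <- clinical_effects(3)
  eff$gleason_probs <- cbind(diag(3), 0, 0)  # grade = subtype + 5, no noise
  eff$na_prob <- 0
  lab <- rep(1:3, each = 100)
  cl <- generate_clinical(lab, eff, seed = 4)
  expect_lt(kruskal_wallis(cl$gleason, lab)$p_value, 1e-6)
  eff2 <- clinical_effects(3, censor_prob = 1)
  cl2 <- generate_clinical(rep(1:3, 10), eff2, seed = 4)
  expect_true(all(cl2$event == 0))
  expect_error(generate_clinical(c(1, 4), clinical_effects(3)),
               class = "netstrat_data_error")
})

test_that("written cohort files are mutually consistent", {
  co <- generate_cohort(small_spec(seed = 14))
  d <- tempfile()
  paths <- write_cohort(co, d)
  lab <- utils::read.delim(paths$labels)
  expect_equal(lab$subtype, unname(co$true_labels))
  cl <- utils::read.delim(paths$clinical)
  expect_equal(cl$patient_id, co$clinical$patient_id)
  net <- read_string_edges(paths$edges)
  expect_equal(nrow(net$edges), nrow(co$network$edges))
  unlink(d, recursive = TRUE)
})
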