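# Shared fixture builders. Everything is generated in code; no stored data.

# A small, strongly modular cohort that every downstream stage can recover.
small_spec <- function(seed = 1, ...) {
  args <- list(n_genes = 300L, n_modules = 3L, intra_edge_prob = 0.15,
               inter_edge_prob = 0.01, n_patients = 60L,
               drivers_per_subtype = 10L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

# Tiny deterministic record set for the binary-matrix operations.
toy_records <- function() {
  data.frame(
    sample_id = c("S1", "S1", "S2", "S2", "S2", "S1"),
    gene_symbol = c("TP53", "SPOP", "TP53", "FOXA1", "TTN", "TP53"),
    variant_class = "Missense_Mutation",
    stringsAsFactors = FALSE)
}

# Path graph a - b - c as a ppi_network via the edge-list reader.
path_network <- function() {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.9", "b\tc\t0.9"), f)
  on.exit(unlink(f))
  read_string_edges(f)
}

# Random weighted symmetric adjacency with no self-loops.
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a
}

# Closed-form RWR steady state by direct linear solve (the oracle).
rwr_solve <- function(p0, W, r) {
  as.numeric(r * solve(diag(length(p0)) - (1 - r) * as.matrix(W), p0))
}

expect_ari <- function(a, b, min) {
  expect_gte(mclust::adjustedRandIndex(a, b), min)
}

# Memoized default-condition cohorts (3 subtypes, n = 300, driver_mut_prob
# 0.8, background 0.002) with their smoothed matrices: several acceptance
# checks reuse the same study conditions and smoothing is the slow part.
.cohort_cache <- new.env(parent = emptyenv())
default_smoothed <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    co <- generate_cohort(synthetic_spec(seed = seed))
    sm <- smooth_cohort(intersect_with_network(co$mutations,
                                               co$network)$matrix,
                        co$network)
    .cohort_cache[[key]] <- list(cohort = co, smoothed = sm)
  }
  .cohort_cache[[key]]
}
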