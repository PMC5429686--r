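#' Read a MAF-like somatic mutation table
#'
#' Reads a tab-separated mutation table with a header line; lines starting
#' with `#` are skipped. Only the gene-symbol and sample-barcode columns
#' are required; a variant-classification column is carried along when
#' present but plays no role in the binary coding.
#'
#' @param path TSV file.
#' @param gene_col,sample_col,variant_col column names (TCGA MAF defaults).
#' @return data.frame of mutation records with columns `sample_id`,
#'   `gene_symbol`, `variant_class` (NA when absent), one row per data
#'   line, input order preserved.
#' @export
read_maf <- function(path, gene_col = "Hugo_Symbol",
                     sample_col = "Tumor_Sample_Barcode",
                     variant_col = "Variant_Classification") {
  if (!file.exists(path)) {
    stop_netstrat(sprintf("MAF file not found: %s", path),
                  "netstrat_format_error")
  }
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop_netstrat(
      sprintf("cannot parse MAF file: %s", conditionMessage(e)),
      "netstrat_format_error"))
  if (nrow(df) == 0 && ncol(df) == 0) {
    stop_netstrat("MAF file is empty", "netstrat_format_error")
  }
  for (col in c(gene_col, sample_col)) {
    if (!col %in% names(df)) {
      stop_netstrat(sprintf("required column missing from MAF: %s", col),
                    "netstrat_format_error")
    }
  }
  data.frame(
    sample_id = trimws(as.character(df[[sample_col]])),
    gene_symbol = trimws(as.character(df[[gene_col]])),
    variant_class = if (variant_col %in% names(df))
      as.character(df[[variant_col]]) else NA_character_,
    stringsAsFactors = FALSE)
}

#' Build the binary patient-by-gene mutation matrix
#'
#' A gene is coded 1 for a patient if at least one record links them,
#' 0 otherwise; record multiplicity is collapsed. Patients are ordered by
#' barcode and genes by symbol. Genes never mutated cannot arise from
#' records and so are never carried.
#'
#' @param records data.frame from [read_maf()] (columns `sample_id`,
#'   `gene_symbol`, optionally `variant_class`).
#' @param exclude_variant_classes optional character vector of variant
#'   classes to drop before coding (no default exclusion).
#' @return integer matrix (patients x genes) of 0/1 with dimnames.
#' @export
build_binary_matrix <- function(records, exclude_variant_classes = NULL) {
  if (NROW(records) < 1) {
    stop_netstrat("no mutation records", "netstrat_data_error")
  }
  if (!is.null(exclude_variant_classes)) {
    records <- records[!(records$variant_class %in% exclude_variant_classes), ,
                       drop = FALSE]
  }
  sid <- trimws(records$sample_id)
  gs <- trimws(records$gene_symbol)
  if (any(sid == "") || any(gs == "")) {
    stop_netstrat("empty sample id or gene symbol in records",
                  "netstrat_data_error")
  }
  patients <- sort(unique(sid))
  genes <- sort(unique(gs))
  m <- matrix(0L, length(patients), length(genes),
              dimnames = list(patients, genes))
  m[cbind(match(sid, patients), match(gs, genes))] <- 1L
  m
}

#' Per-patient somatic mutation rate per megabase
#'
#' Converts each patient's mutated-gene count into mutations per Mb under
#' a simplified exome model: `n_genes_assumed` genes of equal coding
#' length `coding_length_nt`, i.e. a 30 Mb exome by default.
#'
#' @param mutations binary patients-by-genes matrix.
#' @param n_genes_assumed,coding_length_nt exome model (defaults 20000
#'   genes x 1500 nt).
#' @return named numeric vector of per-patient rates (mutations/Mb).
#' @export
mutation_rate_per_mb <- function(mutations, n_genes_assumed = 20000,
                                 coding_length_nt = 1500) {
  if (n_genes_assumed <= 0 || coding_length_nt <= 0) {
    stop_netstrat("exome model dimensions must be positive",
                  "netstrat_config_error")
  }
  mb <- n_genes_assumed * coding_length_nt / 1e6
  rowSums(mutations) / mb
}

#' Per-gene fraction of mutated patients
#'
#' @param mutations binary patients-by-genes matrix.
#' @param threshold genes mutated in more than this fraction of patients
#'   are additionally reported (default 0.05, strictly greater).
#' @return list with `fraction` (named vector, column mean) and
#'   `above_threshold` (gene symbols with fraction > threshold).
#' @export
gene_mutation_fraction <- function(mutations, threshold = 0.05) {
  if (nrow(mutations) < 1) {
    stop_netstrat("need at least one patient", "netstrat_data_error")
  }
  frac <- colSums(mutations) / nrow(mutations)
  list(fraction = frac,
       above_threshold = names(frac)[frac > threshold])
}

#' Cohort summary table (counts, percentages, medians)
#'
#' Produces the usual clinicopathological characteristics layout: for each
#' categorical variable the per-category count and percentage of the whole
#' cohort (rounded half-up to 2 decimals, missing values tabulated as an
#' `NA` row); for each continuous variable the median and range.
#'
#' @param clinical data.frame, one row per patient.
#' @param categorical,continuous column names to summarize.
#' @return list with `categorical` (named list of data.frames with columns
#'   category/count/percent) and `continuous` (named list with median,
#'   min, max, n_missing).
#' @export
cohort_summary <- function(clinical,
                           categorical = intersect(
                             c("gleason", "path_n", "path_t", "clin_t",
                               "lymph_status"), names(clinical)),
                           continuous = intersect(
                             c("age", "followup_days", "psa"),
                             names(clinical))) {
  n <- nrow(clinical)
  cat_out <- lapply(categorical, function(v) {
    tab <- table(clinical[[v]], useNA = "ifany")
    data.frame(category = ifelse(is.na(names(tab)), "NA", names(tab)),
               count = as.integer(tab),
               percent = round_half_up(100 * as.integer(tab) / n, 2),
               stringsAsFactors = FALSE)
  })
  names(cat_out) <- categorical
  cont_out <- lapply(continuous, function(v) {
    x <- clinical[[v]]
    list(median = stats::median(x, na.rm = TRUE),
         min = suppressWarnings(min(x, na.rm = TRUE)),
         max = suppressWarnings(max(x, na.rm = TRUE)),
         n_missing = sum(is.na(x)))
  })
  names(cont_out) <- continuous
  list(categorical = cat_out, continuous = cont_out, n_patients = n)
}
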