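#' Published reference tallies for consistency checking
#'
#' Small reference tables from large-scale FAERS/JADER pharmacovigilance
#' analyses of immune checkpoint inhibitors and neurological
#' immune-mediated adverse events, shipped as plain TSV. They serve as
#' fixed inputs for internal-consistency checks of the statistics (e.g.
#' that the information component equals log2 of the empirical-Bayes
#' geometric mean row by row) and for reproducing printed summary rates;
#' they are not outputs of this package.
#'
#' * `reference_signal_table()`: per-database ICI rows of a published
#'   autoimmune-encephalitis signal table (N, ROR with CI, PRR with
#'   chi-squared, EBGM with EBGM05, IC with IC025).
#' * `reference_annual_counts()`: annual counts of neurological
#'   immune-mediated events vs all other events among ICI reports.
#' * `reference_group_outcomes()`: deaths and total reports per
#'   composite event group.
#' * `reference_report_shares()`: headline numerator/denominator pairs
#'   (event share of all reports, death share, per-drug shares).
#'
#' @return A tibble.
#' @name reference_tables
NULL

read_ref <- function(file, types) {
  readr::read_tsv(system.file("extdata", file, package = "pvsignals",
                              mustWork = TRUE),
                  col_types = types, progress = FALSE)
}

#' @rdname reference_tables
#' @export
reference_signal_table <- function() {
  read_ref("aie_reference_signals.tsv",
           readr::cols(database = "c", drug = "c", .default = "d"))
}

#' @rdname reference_tables
#' @export
reference_annual_counts <- function() {
  read_ref("nae_annual_counts.tsv", readr::cols(.default = "d"))
}

#' @rdname reference_tables
#' @export
reference_group_outcomes <- function() {
  read_ref("nae_group_outcomes.tsv",
           readr::cols(group = "c", .default = "d"))
}

#' @rdname reference_tables
#' @export
reference_report_shares <- function() {
  read_ref("nae_report_shares.tsv",
           readr::cols(label = "c", .default = "d"))
}
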