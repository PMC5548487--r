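#' @import data.table
#' @importFrom stats setNames
#' @keywords internal
"_PACKAGE"

# data.table columns referenced non-standardly across the package
utils::globalVariables(c(
  "report_id", "case_id", "event_date", "receipt_date", "drug_seq",
  "verbatim_name", "role", "indication", "indication_pt", "ingredient_keys",
  "mapping_score", "mapping_method", "verbatim", "pt", "match_score",
  "ingredient_key", "adr_pt", "N", "E", "RRR", "p", "q", "R", "C", "Tm",
  "month", "n", "fraction", "fingerprint", "term", "year", "conflated",
  "n_conflated", "n_with_indication", "passes_filter", "outcome"))
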