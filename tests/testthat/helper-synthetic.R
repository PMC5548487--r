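# Shared builders: run the generator and push the corpus through mapping
# and PT normalization with the generator's own tables.

prepared_corpus <- function(cfg) {
  gen <- generate_faers(cfg)
  mapped <- map_corpus(gen$corpus, synthetic_synonym_table(cfg))
  norm <- normalize_corpus(mapped$corpus, synthetic_vocabulary(cfg))
  list(corpus = norm$corpus, truth = gen$truth,
       coverage = mapped$coverage, rates = norm$rates)
}

# the spec-pinned null world: 50 drugs x 50 ADRs
null_config <- function(n_reports = 10000, seed = 1L,
                        n_ingredients = 50, n_adrs = 50, ...) {
  synthetic_config(n_reports = n_reports, n_ingredients = n_ingredients,
                   n_adrs = n_adrs, seed = seed, ...)
}

# sparser vocabulary used for planted-signal power/estimation scenarios
# (see the methods vignette for the dimensioning rationale)
power_config <- function(n_reports = 50000, seed = 1L,
                         rho = 8, ingredient = 1, adr = 2, ...) {
  synthetic_config(n_reports = n_reports, n_ingredients = 100, n_adrs = 200,
                   planted_associations = list(
                     list(ingredient = ingredient, adr = adr, rho = rho)),
                   seed = seed, ...)
}

fixture_quarter_corpus <- function() {
  fq <- system.file("extdata/fixture_quarter", package = "faerstools")
  suppressWarnings(parse_quarter(
    file.path(fq, "demo.txt"), file.path(fq, "drug.txt"),
    file.path(fq, "reac.txt"), file.path(fq, "indi.txt"),
    file.path(fq, "outc.txt"), dialect = "canonical_fixture"))
}

make_small_corpus <- function(rows) {
  # rows: list of lists(id, drugs, reacs, date, age, sex)
  reports <- data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(report_id = r$id, case_id = paste0("C", r$id),
                           event_date = as.Date(r$date),
                           receipt_date = as.Date(r$date) + 10,
                           occupation = "physician",
                           age = r$age, sex = r$sex)))
  drugs <- data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(report_id = r$id,
                           drug_seq = seq_along(r$drugs),
                           verbatim_name = r$drugs, role = "PS",
                           ingredient_keys = r$drugs)))
  reacs <- data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(report_id = r$id, verbatim = r$reacs,
                           pt = r$reacs)))
  faers_corpus(reports, drugs, reacs)
}

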