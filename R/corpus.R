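# Data model for spontaneous-report corpora and FAERS quarterly ASCII ingest.

#' Controlled vocabularies used throughout the package
#'
#' `faers_occupations()` returns the reporter-occupation enum,
#' `faers_outcomes()` the seven FAERS outcome descriptors,
#' `faers_roles()` the drug role codes (primary suspect, secondary suspect,
#' concomitant, interacting), and `faers_sexes()` the patient-sex enum.
#'
#' @return Character vector of allowed values.
#' @export
faers_occupations <- function() {
  c("physician", "pharmacist", "other_health_professional",
    "consumer", "lawyer", "unknown")
}

#' @rdname faers_occupations
#' @export
faers_outcomes <- function() {
  c("Death", "Life-Threatening", "Disability", "Congenital Anomaly",
    "Required Intervention", "Hospitalization", "Other")
}

#' @rdname faers_occupations
#' @export
faers_roles <- function() c("PS", "SS", "C", "I")

#' @rdname faers_occupations
#' @export
faers_sexes <- function() c("M", "F", "unknown")

# sentinel used when a fingerprint/serialization field is missing
.na_sentinel <- "·NA·"

.key_sep <- ";"

#' Construct a report corpus
#'
#' A `faers_corpus` bundles four relational tables keyed by `report_id`:
#' `reports` (one row per safety report: case id, dates, reporter occupation,
#' age in years, sex), `drugs` (one row per drug entry: verbatim name, role,
#' verbatim indication, and -- once mapped -- ingredient keys and the match
#' score), `reactions` (one row per reported reaction verbatim, plus the
#' standardized preferred term once normalized) and `outcomes` (one row per
#' outcome mention).  `provenance` is free-form metadata about where the data
#' came from and what was dropped on ingest.
#'
#' Invariants enforced: unique `report_id`; every report has at least one
#' drug and one reaction; `event_date <= receipt_date` where both present;
#' ages outside \[0, 120\] are rejected.
#'
#' @param reports data.frame with columns `report_id`, `case_id`,
#'   `event_date`, `receipt_date` (Date or NA), `occupation`, `age`, `sex`.
#' @param drugs data.frame with columns `report_id`, `drug_seq`,
#'   `verbatim_name`, `role`, `indication`; optional mapping columns
#'   `ingredient_keys` (`;`-joined), `mapping_score`, `mapping_method`,
#'   `indication_pt`.
#' @param reactions data.frame with columns `report_id`, `verbatim`;
#'   optional `pt`, `match_score`.
#' @param outcomes data.frame with columns `report_id`, `outcome`.
#' @param provenance list of free-form metadata.
#' @param validate run invariant checks (disable only for trusted callers).
#' @return An object of class `faers_corpus`.
#' @export
faers_corpus <- function(reports, drugs, reactions,
                         outcomes = NULL, provenance = list(),
                         validate = TRUE) {
  reports   <- data.table::as.data.table(reports)
  drugs     <- data.table::as.data.table(drugs)
  reactions <- data.table::as.data.table(reactions)
  outcomes  <- if (is.null(outcomes)) {
    data.table::data.table(report_id = character(), outcome = character())
  } else data.table::as.data.table(outcomes)

  for (col in c("ingredient_keys", "mapping_method")) {
    if (!col %in% names(drugs)) drugs[, (col) := NA_character_]
  }
  if (!"mapping_score" %in% names(drugs)) drugs[, mapping_score := NA_real_]
  if (!"indication" %in% names(drugs)) drugs[, indication := NA_character_]
  if (!"indication_pt" %in% names(drugs)) drugs[, indication_pt := NA_character_]
  if (!"pt" %in% names(reactions)) reactions[, pt := NA_character_]
  if (!"match_score" %in% names(reactions)) reactions[, match_score := NA_real_]

  obj <- structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         outcomes = outcomes, provenance = provenance),
    class = "faers_corpus")
  if (validate) validate_corpus(obj)
  obj
}

#' Validate corpus invariants
#'
#' @param corpus a `faers_corpus`.
#' @return `corpus`, invisibly; errors on violation.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "faers_corpus"))
  rep <- corpus$reports
  need <- c("report_id", "case_id", "event_date", "receipt_date",
            "occupation", "age", "sex")
  missing_cols <- setdiff(need, names(rep))
  if (length(missing_cols))
    stop("reports table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(rep$report_id))
    stop("report_id values must be unique within a corpus")
  if (nrow(rep)) {
    if (!all(rep$occupation %in% faers_occupations()))
      stop("unrecognized occupation value(s); map codes before construction")
    if (!all(rep$sex %in% faers_sexes()))
      stop("unrecognized sex value(s)")
    bad_age <- !is.na(rep$age) & (rep$age < 0 | rep$age > 120)
    if (any(bad_age)) stop(sum(bad_age), " report(s) with age outside [0, 120]")
    both <- !is.na(rep$event_date) & !is.na(rep$receipt_date)
    if (any(rep$event_date[both] > rep$receipt_date[both]))
      stop("event_date must not exceed receipt_date")
    no_drug <- setdiff(rep$report_id, corpus$drugs$report_id)
    if (length(no_drug))
      stop(length(no_drug), " report(s) have no drug entry")
    no_reac <- setdiff(rep$report_id, corpus$reactions$report_id)
    if (length(no_reac))
      stop(length(no_reac), " report(s) have no reaction")
  }
  if (nrow(corpus$drugs)) {
    if (any(!nzchar(corpus$drugs$verbatim_name)))
      stop("verbatim_name must be non-empty")
    if (!all(corpus$drugs$role %in% faers_roles()))
      stop("unrecognized drug role code(s)")
  }
  if (nrow(corpus$outcomes) &&
      !all(corpus$outcomes$outcome %in% faers_outcomes()))
    stop("unrecognized outcome value(s)")
  invisible(corpus)
}

#' @export
print.faers_corpus <- function(x, ...) {
  cat("<faers_corpus>\n")
  cat("  reports:  ", nrow(x$reports),
      " (", data.table::uniqueN(x$reports$case_id), " cases)\n", sep = "")
  cat("  drugs:    ", nrow(x$drugs), " entries, ",
      sum(!is.na(x$drugs$ingredient_keys)), " mapped\n", sep = "")
  cat("  reactions:", nrow(x$reactions), "entries,",
      sum(!is.na(x$reactions$pt)), "standardized\n")
  cat("  outcomes: ", nrow(x$outcomes), "mentions\n")
  invisible(x)
}

#' Number of reports in a corpus
#' @param corpus a `faers_corpus`.
#' @return integer count.
#' @export
n_reports <- function(corpus) nrow(corpus$reports)

# ---------------------------------------------------------------------------
# FAERS quarterly ASCII ingest

# Column maps per dialect.  Pre-2012Q4 LAERS files key rows by ISR; later
# FAERS files use primaryid/caseid; the fixture dialect uses canonical names.
.dialect_columns <- list(
  legacy_LAERS = list(
    demo = c(report_id = "ISR", case_id = "CASE", event_date = "EVENT_DT",
             receipt_date = "FDA_DT", occupation = "OCP_COD", age = "AGE",
             age_unit = "AGE_COD", sex = "GNDR_COD"),
    drug = c(report_id = "ISR", drug_seq = "DRUG_SEQ", role = "ROLE_COD",
             verbatim_name = "DRUGNAME"),
    reac = c(report_id = "ISR", verbatim = "PT"),
    indi = c(report_id = "ISR", drug_seq = "DRUG_SEQ", indication = "INDI_PT"),
    outc = c(report_id = "ISR", outcome = "OUTC_COD")),
  `FAERS_2012Q4+` = list(
    demo = c(report_id = "primaryid", case_id = "caseid", event_date = "event_dt",
             receipt_date = "fda_dt", occupation = "occp_cod", age = "age",
             age_unit = "age_cod", sex = "sex"),
    drug = c(report_id = "primaryid", drug_seq = "drug_seq", role = "role_cod",
             verbatim_name = "drugname"),
    reac = c(report_id = "primaryid", verbatim = "pt"),
    indi = c(report_id = "primaryid", drug_seq = "indi_drug_seq",
             indication = "indi_pt"),
    outc = c(report_id = "primaryid", outcome = "outc_cod")),
  canonical_fixture = list(
    demo = c(report_id = "report_id", case_id = "case_id",
             event_date = "event_date", receipt_date = "receipt_date",
             occupation = "occupation", age = "age", age_unit = "age_unit",
             sex = "sex"),
    drug = c(report_id = "report_id", drug_seq = "drug_seq", role = "role",
             verbatim_name = "verbatim_name"),
    reac = c(report_id = "report_id", verbatim = "reaction"),
    indi = c(report_id = "report_id", drug_seq = "drug_seq",
             indication = "indication"),
    outc = c(report_id = "report_id", outcome = "outcome")))

.occupation_codes <- c(
  MD = "physician", PH = "pharmacist", OT = "other_health_professional",
  HP = "other_health_professional", CN = "consumer", LW = "lawyer")

.outcome_codes <- c(
  DE = "Death", LT = "Life-Threatening", DS = "Disability",
  CA = "Congenital Anomaly", RI = "Required Intervention",
  HO = "Hospitalization", OT = "Other")

.map_occupation <- function(x) {
  x <- trimws(as.character(x))
  out <- unname(.occupation_codes[toupper(x)])
  # canonical fixture files may carry the enum words directly
  direct <- tolower(x) %in% faers_occupations()
  out[direct] <- tolower(x[direct])
  out[is.na(out)] <- "unknown"
  out
}

.map_outcome <- function(x) {
  x <- trimws(as.character(x))
  out <- unname(.outcome_codes[toupper(x)])
  direct <- match(tolower(x), tolower(faers_outcomes()))
  out[!is.na(direct)] <- faers_outcomes()[direct[!is.na(direct)]]
  out[is.na(out)] <- "Other"
  out
}

.map_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- ifelse(x %in% c("M", "F"), x, "unknown")
  out
}

# AGE_COD units per FAERS documentation; unparseable values become NA
.age_to_years <- function(age, unit) {
  age <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(as.character(unit)))
  mult <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
            DY = 1 / 365.25, HR = 1 / 8766)
  m <- mult[unit]
  m[is.na(m) & (unit == "" | is.na(unit))] <- 1   # blank unit: assume years
  yrs <- age * m
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 120)] <- NA_real_
  yrs
}

.parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | is.na(x)] <- NA_character_
  out <- rep(as.Date(NA), length(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[iso] <- as.Date(x[iso])
  ymd <- grepl("^\\d{8}$", x)
  out[ymd] <- as.Date(x[ymd], format = "%Y%m%d")
  out
}

.read_dollar <- function(path, colmap, what) {
  dt <- tryCatch(
    data.table::fread(path, sep = "$", header = TRUE, quote = "",
                      colClasses = "character", fill = TRUE,
                      showProgress = FALSE),
    error = function(e) stop("cannot read ", what, " file '", path, "': ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L && ncol(dt) == 0L) return(NULL)   # empty file
  missing_cols <- setdiff(unname(colmap), names(dt))
  if (length(missing_cols))
    stop("format error in ", what, " file '", basename(path),
         "': missing mandatory column(s) ", paste(missing_cols, collapse = ", "))
  out <- dt[, unname(colmap), with = FALSE]
  data.table::setnames(out, names(colmap))
  out
}

#' Parse one FAERS quarter from `$`-delimited ASCII tables
#'
#' Reads the DEMO/DRUG/REAC/INDI/OUTC tables of one quarterly extract, joins
#' rows on the report key, maps occupation/outcome/role codes to the package
#' enums (unrecognized codes fall back to `unknown`/`Other`), converts ages
#' to years and drops rows whose report key appears in no DEMO row (orphans)
#' as well as reports lacking a drug or a reaction.  All drop counts are
#' recorded in `provenance`.
#'
#' @param demo_file,drug_file,reac_file,indi_file,outc_file paths to the five
#'   tables; `indi_file` and `outc_file` may be `NULL`.
#' @param dialect one of `"legacy_LAERS"` (ISR-keyed, pre-2012Q4),
#'   `"FAERS_2012Q4+"` (primaryid-keyed) or `"canonical_fixture"`.
#' @return A [faers_corpus()].
#' @export
parse_quarter <- function(demo_file, drug_file, reac_file,
                          indi_file = NULL, outc_file = NULL,
                          dialect = c("canonical_fixture", "legacy_LAERS",
                                      "FAERS_2012Q4+")) {
  dialect <- match.arg(dialect)
  cm <- .dialect_columns[[dialect]]
  drug_seq <- report_id <- NULL  # NSE note suppression

  demo <- .read_dollar(demo_file, cm$demo, "DEMO")
  drug <- .read_dollar(drug_file, cm$drug, "DRUG")
  reac <- .read_dollar(reac_file, cm$reac, "REAC")
  indi <- if (!is.null(indi_file)) .read_dollar(indi_file, cm$indi, "INDI")
  outc <- if (!is.null(outc_file)) .read_dollar(outc_file, cm$outc, "OUTC")

  prov <- list(source_files = c(demo = demo_file, drug = drug_file,
                                reac = reac_file,
                                indi = if (is.null(indi_file)) NA else indi_file,
                                outc = if (is.null(outc_file)) NA else outc_file),
               dialect = dialect, ingest_time = format(Sys.time(), tz = "UTC"),
               warnings = character())
  if (is.null(demo) || nrow(demo) == 0L) {
    prov$warnings <- c(prov$warnings, "empty DEMO file: empty corpus")
    warning("empty DEMO input; returning empty corpus")
    return(faers_corpus(
      reports = data.table::data.table(report_id = character(),
        case_id = character(), event_date = as.Date(character()),
        receipt_date = as.Date(character()), occupation = character(),
        age = numeric(), sex = character()),
      drugs = data.table::data.table(report_id = character(),
        drug_seq = integer(), verbatim_name = character(), role = character()),
      reactions = data.table::data.table(report_id = character(),
        verbatim = character()),
      provenance = prov))
  }
  if (is.null(drug)) drug <- data.table::data.table(report_id = character(),
    drug_seq = character(), role = character(), verbatim_name = character())
  if (is.null(reac)) reac <- data.table::data.table(report_id = character(),
    verbatim = character())

  rows_in <- c(demo = nrow(demo), drug = nrow(drug), reac = nrow(reac),
               indi = if (is.null(indi)) 0L else nrow(indi),
               outc = if (is.null(outc)) 0L else nrow(outc))

  # drop rows with unparseable (blank) keys
  key_ok <- function(dt) !is.na(dt$report_id) & nzchar(trimws(dt$report_id))
  dropped <- c(demo = 0L, drug = 0L, reac = 0L, indi = 0L, outc = 0L)
  for (nm in c("demo", "drug", "reac", "indi", "outc")) {
    dt <- get(nm)
    if (is.null(dt)) next
    ok <- key_ok(dt)
    dropped[[nm]] <- dropped[[nm]] + sum(!ok)
    assign(nm, dt[ok])
  }

  known <- unique(demo$report_id)
  for (nm in c("drug", "reac", "indi", "outc")) {
    dt <- get(nm)
    if (is.null(dt)) next
    ok <- dt$report_id %in% known
    dropped[[nm]] <- dropped[[nm]] + sum(!ok)   # orphan rows
    assign(nm, dt[ok])
  }

  reports <- data.table::data.table(
    report_id = demo$report_id,
    case_id = ifelse(is.na(demo$case_id) | !nzchar(demo$case_id),
                     demo$report_id, demo$case_id),
    event_date = .parse_faers_date(demo$event_date),
    receipt_date = .parse_faers_date(demo$receipt_date),
    occupation = .map_occupation(demo$occupation),
    age = .age_to_years(demo$age, demo$age_unit),
    sex = .map_sex(demo$sex))
  # impossible chronology treated as data error: blank the event date
  bad_chrono <- !is.na(reports$event_date) & !is.na(reports$receipt_date) &
    reports$event_date > reports$receipt_date
  if (any(bad_chrono)) {
    reports$event_date[bad_chrono] <- as.Date(NA)
    prov$warnings <- c(prov$warnings,
      paste0(sum(bad_chrono), " report(s) with event_date > receipt_date; ",
             "event_date blanked"))
  }

  drug[, drug_seq := suppressWarnings(as.integer(drug_seq))]
  drug[is.na(drug_seq), drug_seq := seq_len(.N), by = report_id]
  drug$role <- ifelse(toupper(trimws(drug$role)) %in% faers_roles(),
                      toupper(trimws(drug$role)), "C")
  drug <- drug[nzchar(trimws(verbatim_name))]
  if (!is.null(indi) && nrow(indi)) {
    indi[, drug_seq := suppressWarnings(as.integer(drug_seq))]
    drug <- merge(drug, indi[, list(report_id, drug_seq,
                                    indication = indication)],
                  by = c("report_id", "drug_seq"), all.x = TRUE, sort = FALSE)
  } else drug[, indication := NA_character_]

  reac <- reac[nzchar(trimws(verbatim))]
  outcomes <- if (!is.null(outc) && nrow(outc)) {
    data.table::data.table(report_id = outc$report_id,
                           outcome = .map_outcome(outc$outcome))
  } else NULL

  # enforce >=1 drug and >=1 reaction per report
  keep <- reports$report_id %in% drug$report_id &
    reports$report_id %in% reac$report_id
  dropped[["demo"]] <- dropped[["demo"]] + sum(!keep)
  reports <- reports[keep]
  kept_ids <- reports$report_id
  drug <- drug[report_id %in% kept_ids]
  reac <- reac[report_id %in% kept_ids]
  if (!is.null(outcomes)) outcomes <- outcomes[report_id %in% kept_ids]

  prov$rows_in <- rows_in
  prov$rows_dropped <- dropped
  prov$rows_kept <- c(demo = nrow(reports), drug = nrow(drug),
                      reac = nrow(reac),
                      indi = rows_in[["indi"]] - dropped[["indi"]],
                      outc = if (is.null(outcomes)) 0L else nrow(outcomes))

  faers_corpus(reports = reports,
               drugs = drug[, list(report_id, drug_seq, verbatim_name,
                                   role, indication)],
               reactions = reac[, list(report_id, verbatim)],
               outcomes = outcomes, provenance = prov)
}

#' Keep only the most recent report of each case
#'
#' A patient's condition is often followed over several reports of the same
#' case; counting each would inflate signals.  For each `case_id` the report
#' with the greatest `receipt_date` is retained (missing receipt dates sort
#' first; ties broken by greatest `report_id` lexicographically).  The
#' operation is idempotent.
#'
#' @param corpus a `faers_corpus`.
#' @return A `faers_corpus` with exactly one report per case.
#' @export
latest_report_per_case <- function(corpus) {
  stopifnot(inherits(corpus, "faers_corpus"))
  rep <- data.table::copy(corpus$reports)
  ord <- order(rep$case_id,
               data.table::fifelse(is.na(rep$receipt_date),
                                   as.Date("0001-01-01"), rep$receipt_date),
               rep$report_id)
  rep <- rep[ord]
  keep_ids <- rep[, list(report_id = report_id[.N]), by = "case_id"]$report_id
  subset_corpus(corpus, keep_ids,
                note = "latest_report_per_case")
}

#' Subset a corpus to a set of report ids
#' @param corpus a `faers_corpus`.
#' @param report_ids character vector of report ids to keep.
#' @param note provenance annotation.
#' @return the filtered `faers_corpus`.
#' @export
subset_corpus <- function(corpus, report_ids, note = "subset") {
  report_id <- NULL
  prov <- corpus$provenance
  prov$filters <- c(prov$filters,
                    sprintf("%s: %d -> %d reports", note,
                            nrow(corpus$reports), length(unique(report_ids))))
  faers_corpus(reports = corpus$reports[report_id %in% report_ids],
               drugs = corpus$drugs[report_id %in% report_ids],
               reactions = corpus$reactions[report_id %in% report_ids],
               outcomes = corpus$outcomes[report_id %in% report_ids],
               provenance = prov, validate = FALSE)
}

# ---------------------------------------------------------------------------
# normalized on-disk format

.normalized_format_version <- "1.0"

#' Write / read the normalized tabular representation
#'
#' `write_normalized()` serializes a corpus to a directory of tab-separated
#' tables (`reports.tsv`, `report_drugs.tsv`, `report_reactions.tsv`,
#' `report_outcomes.tsv`) plus `manifest.json` carrying the format version
#' and provenance; `read_normalized()` is its inverse and errors on a format
#' version it does not understand.  The round trip is lossless.
#'
#' @param corpus a `faers_corpus`.
#' @param path directory to write to (created if absent).
#' @return `write_normalized()` returns `path` invisibly; `read_normalized()`
#'   returns a `faers_corpus`.
#' @export
write_normalized <- function(corpus, path) {
  stopifnot(inherits(corpus, "faers_corpus"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(dt, file) {
    out <- data.table::copy(dt)
    for (col in names(out)) {
      if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]])
    }
    data.table::fwrite(out, file.path(path, file), sep = "\t", quote = TRUE,
                       na = "")
  }
  wr(corpus$reports, "reports.tsv")
  wr(corpus$drugs, "report_drugs.tsv")
  wr(corpus$reactions, "report_reactions.tsv")
  wr(corpus$outcomes, "report_outcomes.tsv")
  manifest <- list(format = "faerstools-normalized",
                   format_version = .normalized_format_version,
                   n_reports = nrow(corpus$reports),
                   provenance = corpus$provenance)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under '", path, "'")
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$format_version, .normalized_format_version))
    stop("normalized-format version mismatch: file has '",
         manifest$format_version, "', this package reads '",
         .normalized_format_version, "'")
  rd <- function(file, date_cols = character(), num_cols = character(),
                 int_cols = character()) {
    dt <- data.table::fread(file.path(path, file), sep = "\t",
                            colClasses = "character", na.strings = "",
                            showProgress = FALSE)
    for (col in intersect(date_cols, names(dt))) dt[[col]] <- as.Date(dt[[col]])
    for (col in intersect(num_cols, names(dt))) dt[[col]] <- as.numeric(dt[[col]])
    for (col in intersect(int_cols, names(dt))) dt[[col]] <- as.integer(dt[[col]])
    dt
  }
  faers_corpus(
    reports = rd("reports.tsv", date_cols = c("event_date", "receipt_date"),
                 num_cols = "age"),
    drugs = rd("report_drugs.tsv", num_cols = "mapping_score",
               int_cols = "drug_seq"),
    reactions = rd("report_reactions.tsv", num_cols = "match_score"),
    outcomes = rd("report_outcomes.tsv"),
    provenance = manifest$provenance)
}
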