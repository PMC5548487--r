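# Detection and collapse of multiplied reports: entries with identical
# drugs, identical ADRs, event date, patient age and sex.  Equality is
# exact (no fuzzy linkage), computed after ingredient mapping and ADR
# normalization so synonym variants of one event collapse together.

#' Canonical duplicate-detection fingerprints
#'
#' The fingerprint is a canonical string over the sorted ingredient-key set,
#' sorted preferred-term set, event date, age and sex.  Missing fields are
#' encoded with a sentinel so two missing values compare equal only to each
#' other.  Unmapped drugs (or unstandardized reactions) fall back to the
#' verbatim string prefixed with `V:`, flagging the degraded comparison.
#'
#' @param corpus a `faers_corpus`.
#' @return data.table with columns `report_id`, `fingerprint`.
#' @export
report_fingerprints <- function(corpus) {
  stopifnot(inherits(corpus, "faers_corpus"))
  report_id <- ingredient_keys <- verbatim_name <- verbatim <- pt <- NULL
  enc <- function(x) ifelse(is.na(x), .na_sentinel, as.character(x))
  dpart <- corpus$drugs[, {
    rowkeys <- ifelse(is.na(ingredient_keys),
                      paste0("V:", verbatim_name), ingredient_keys)
    list(drugs_key = paste(sort(unique(unlist(
      strsplit(rowkeys, .key_sep, fixed = TRUE)))), collapse = "|"))
  }, by = "report_id"]
  rpart <- corpus$reactions[, list(
    reacs_key = paste(sort(unique(
      ifelse(is.na(pt), paste0("V:", verbatim), pt))), collapse = "|")),
    by = "report_id"]
  out <- merge(merge(corpus$reports[, list(report_id,
                                           event_date = enc(event_date),
                                           age = enc(age), sex)],
                     dpart, by = "report_id", all.x = TRUE),
               rpart, by = "report_id", all.x = TRUE)
  out[, list(report_id,
             fingerprint = paste(drugs_key, reacs_key, event_date, age, sex,
                                 sep = "@"))]
}

#' @rdname report_fingerprints
#' @param report_id one report id.
#' @return `report_fingerprint()` returns the fingerprint string of one
#'   report.
#' @export
report_fingerprint <- function(corpus, report_id) {
  fp <- report_fingerprints(subset_corpus(corpus, report_id))
  fp$fingerprint[[1]]
}

#' Find groups of exactly duplicated reports
#'
#' Groups are the fingerprint equivalence classes of size >= 2 (singletons
#' omitted), ordered by fingerprint so output is deterministic.
#'
#' @param corpus a `faers_corpus`.
#' @return list of `duplicate_group` lists with elements `fingerprint` and
#'   `report_ids` (sorted character vector, length >= 2).
#' @export
find_duplicate_groups <- function(corpus) {
  fingerprint <- report_id <- NULL
  fp <- report_fingerprints(corpus)
  grp <- fp[, list(report_ids = list(sort(report_id)), n = .N),
            by = "fingerprint"]
  grp <- grp[n >= 2L]
  data.table::setorder(grp, fingerprint)
  lapply(seq_len(nrow(grp)), function(i)
    structure(list(fingerprint = grp$fingerprint[[i]],
                   report_ids = grp$report_ids[[i]]),
              class = "duplicate_group"))
}

#' Collapse duplicate groups
#'
#' Under `policy = "keep_first"` the lexicographically smallest report id of
#' each duplicate group is retained; the report count decreases by the sum of
#' (group size - 1).  Idempotent.
#'
#' @param corpus a `faers_corpus`.
#' @param policy collapse policy; only `"keep_first"` is defined.
#' @return the deduplicated `faers_corpus`.
#' @export
deduplicate <- function(corpus, policy = "keep_first") {
  if (!identical(policy, "keep_first"))
    stop("unknown deduplication policy: ", policy)
  groups <- find_duplicate_groups(corpus)
  drop <- unlist(lapply(groups, function(g) g$report_ids[-1]))
  keep <- setdiff(corpus$reports$report_id, drop)
  subset_corpus(corpus, keep, note = "deduplicate(keep_first)")
}
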