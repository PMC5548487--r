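# Verbatim drug-name -> molecular-ingredient normalization.
#
# Names are tokenized (lowercase, non-alphanumerics stripped, stopwords
# removed, set semantics) and compared to a synonym table with the Tanimoto
# coefficient on token sets.  The best synonym wins if tc >= t_min (0.2);
# a synonym with tc >= t_exact (0.99) short-circuits the scan.

#' Default low-information tokens removed before matching
#'
#' Articles plus frequently occurring words that carry little identity
#' information ("acid").  Extend per corpus as needed.
#' @return character vector.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "of", "with", "for", "acid")
}

#' Construct a drug synonym table
#'
#' @param entries data.frame with columns `synonym` and `ingredient_keys`
#'   (one key or several joined by `;` for combination products).
#' @param stopwords tokens removed during normalization.
#' @param manual_overrides named character vector: verbatim name ->
#'   `;`-joined ingredient keys, consulted before any matching.
#' @return a `synonym_table` object (keeps the entry order, which governs the
#'   exact-match early exit).
#' @export
synonym_table <- function(entries, stopwords = default_stopwords(),
                          manual_overrides = character()) {
  entries <- data.table::as.data.table(entries)
  stopifnot(all(c("synonym", "ingredient_keys") %in% names(entries)))
  if (any(!nzchar(entries$synonym))) stop("synonym strings must be non-empty")
  if (any(is.na(entries$ingredient_keys) | !nzchar(entries$ingredient_keys)))
    stop("every synonym must map to at least one ingredient key")
  tokens <- normalize_tokens(entries$synonym, stopwords)
  obj <- structure(
    list(entries = entries, stopwords = stopwords,
         manual_overrides = manual_overrides, tokens = tokens),
    class = "synonym_table")
  obj$index <- .token_index(tokens)
  obj
}

#' @export
print.synonym_table <- function(x, ...) {
  cat("<synonym_table> ", nrow(x$entries), " synonyms, ",
      length(x$manual_overrides), " manual overrides\n", sep = "")
  invisible(x)
}

# token -> integer row ids of synonyms containing it
.token_index <- function(token_sets) {
  rows <- rep.int(seq_along(token_sets), lengths(token_sets))
  split(rows, unlist(token_sets))
}

#' Read / write a synonym table from tab-separated text
#'
#' Format: `synonym<TAB>ingredient_key[;ingredient_key...]`, no header.
#' @param path file path.
#' @param stopwords,manual_overrides see [synonym_table()].
#' @return a `synonym_table`.
#' @export
read_synonym_table <- function(path, stopwords = default_stopwords(),
                               manual_overrides = character()) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("synonym", "ingredient_keys"),
                          colClasses = "character", showProgress = FALSE)
  synonym_table(dt, stopwords = stopwords, manual_overrides = manual_overrides)
}

#' Tokenize a drug name
#'
#' Lowercases, strips non-alphanumeric characters (digits are kept), splits
#' on whitespace, removes stopwords, and collapses duplicates: token *sets*,
#' not multisets.  May be empty.
#'
#' @param raw_name character vector of names.
#' @param stopwords tokens to drop.
#' @return list of character vectors (one token set per input).
#' @export
normalize_tokens <- function(raw_name, stopwords = default_stopwords()) {
  x <- tolower(raw_name)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), " ", fixed = TRUE)
  lapply(toks, function(tk) {
    tk <- unique(tk[nzchar(tk) & !(tk %in% stopwords)])
    tk
  })
}

#' Tanimoto coefficient on token sets
#'
#' `|A n B| / |A u B|`; defined as 0 when the union is empty.  Symmetric,
#' equal to 1 exactly when both sets are non-empty and equal.
#'
#' @param tokens_a,tokens_b character vectors treated as sets.
#' @return number in \[0, 1\].
#' @export
token_tanimoto <- function(tokens_a, tokens_b) {
  a <- unique(tokens_a); b <- unique(tokens_b)
  u <- length(a) + length(b) - (i <- sum(a %in% b))
  if (u == 0L) return(0)
  i / u
}

# scan candidates (table row ids, ascending = table order) for one query
.match_tokens <- function(qtok, table, t_min, t_exact) {
  if (!length(qtok)) return(NULL)
  cand <- unlist(table$index[qtok], use.names = FALSE)
  if (!length(cand)) return(NULL)
  tab <- tabulate(cand, nbins = nrow(table$entries))
  cand <- which(tab > 0L)               # ascending: preserves table order
  inter <- tab[cand]
  tc <- inter / (length(qtok) + lengths(table$tokens[cand]) - inter)
  hit <- which(tc >= t_exact)
  if (length(hit)) {                    # early exit at first exact synonym
    r <- cand[hit[1]]
    return(list(row = r, tc = tc[hit[1]], method = "exact"))
  }
  ok <- tc >= t_min
  if (!any(ok)) return(NULL)
  cand <- cand[ok]; tc <- tc[ok]
  best <- tc == max(tc)
  cand <- cand[best]
  if (length(cand) > 1L) {              # ties: longer synonym, then lexicographic
    syn <- table$entries$synonym[cand]
    cand <- cand[order(-nchar(syn), syn)]
  }
  list(row = cand[1], tc = max(tc), method = "fuzzy")
}

#' Map one verbatim drug name to ingredient keys
#'
#' Manual overrides are consulted first; otherwise synonyms are scanned in
#' table order, returning at the first Tanimoto coefficient `>= t_exact`
#' (0.99: exact match), else the argmax if `>= t_min` (0.2); ties are broken
#' by the longer synonym string, then lexicographically.  Below `t_min` the
#' name is unmatched -- a value, not an error.
#'
#' @param raw_name one verbatim name.
#' @param table a [synonym_table()].
#' @param t_min minimum acceptable coefficient (default 0.2).
#' @param t_exact exact-match threshold (default 0.99).
#' @return list with `ingredient_keys` (character vector, empty if
#'   unmatched), `tc`, `matched_synonym` and `method` in
#'   `{"exact", "fuzzy", "override", "unmatched"}`.
#' @export
map_drug_name <- function(raw_name, table, t_min = 0.2, t_exact = 0.99) {
  stopifnot(inherits(table, "synonym_table"), length(raw_name) == 1L)
  ov <- table$manual_overrides
  if (length(ov) && raw_name %in% names(ov)) {
    return(list(ingredient_keys = strsplit(ov[[raw_name]], .key_sep,
                                           fixed = TRUE)[[1]],
                tc = 1, matched_synonym = raw_name, method = "override"))
  }
  qtok <- normalize_tokens(raw_name, table$stopwords)[[1]]
  m <- .match_tokens(qtok, table, t_min, t_exact)
  if (is.null(m))
    return(list(ingredient_keys = character(), tc = 0,
                matched_synonym = NA_character_, method = "unmatched"))
  list(ingredient_keys = strsplit(table$entries$ingredient_keys[m$row],
                                  .key_sep, fixed = TRUE)[[1]],
       tc = m$tc, matched_synonym = table$entries$synonym[m$row],
       method = m$method)
}

#' Map every drug entry of a corpus to ingredient keys
#'
#' Annotates each drug row with its `;`-joined ingredient keys, match score
#' and method, and returns a coverage report listing matched/unmatched row
#' counts and the most frequent unmatched names (candidates for manual
#' overrides).  Unique names are matched once and the result broadcast.
#'
#' @param corpus a `faers_corpus`.
#' @param table a [synonym_table()].
#' @param t_min,t_exact see [map_drug_name()].
#' @return list with `corpus` (annotated) and `coverage` (list: `n_rows`,
#'   `n_matched`, `n_unmatched`, `coverage`, `report_coverage`,
#'   `top_unmatched` data.table).
#' @export
map_corpus <- function(corpus, table, t_min = 0.2, t_exact = 0.99) {
  stopifnot(inherits(corpus, "faers_corpus"))
  if (!inherits(table, "synonym_table") || nrow(table$entries) == 0L)
    stop("empty synonym table")
  verbatim_name <- ingredient_keys <- mapping_score <- mapping_method <- NULL
  drugs <- data.table::copy(corpus$drugs)
  uniq <- unique(drugs$verbatim_name)
  res <- lapply(uniq, map_drug_name, table = table,
                t_min = t_min, t_exact = t_exact)
  keys <- vapply(res, function(r)
    if (length(r$ingredient_keys)) paste(r$ingredient_keys, collapse = .key_sep)
    else NA_character_, "")
  scores <- vapply(res, function(r) r$tc, 0)
  methods <- vapply(res, function(r) r$method, "")
  idx <- match(drugs$verbatim_name, uniq)
  drugs[, `:=`(ingredient_keys = keys[idx], mapping_score = scores[idx],
               mapping_method = methods[idx])]
  unmatched <- drugs[is.na(ingredient_keys)]
  top_unmatched <- if (nrow(unmatched)) {
    u <- unmatched[, list(n = .N), by = "verbatim_name"]
    data.table::setorder(u, -n, verbatim_name)
    utils::head(u, 25L)
  } else data.table::data.table(verbatim_name = character(), n = integer())
  mapped_reports <- drugs[, list(ok = all(!is.na(ingredient_keys))),
                          by = "report_id"]
  out <- corpus
  out$drugs <- drugs
  list(corpus = out,
       coverage = list(
         n_rows = nrow(drugs),
         n_matched = sum(!is.na(drugs$ingredient_keys)),
         n_unmatched = nrow(unmatched),
         coverage = mean(!is.na(drugs$ingredient_keys)),
         report_coverage = mean(mapped_reports$ok),
         top_unmatched = top_unmatched))
}
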