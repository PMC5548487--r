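# Standardization of verbatim reaction/indication strings to MedDRA
# preferred terms (PTs) by normalized Levenshtein similarity.
#
# Similarity is 1 - d(a', b') / max(|a'|, |b'|) on case-folded,
# whitespace-collapsed strings.  A PT with similarity >= s_perfect (0.95)
# short-circuits; otherwise the best PT wins if >= s_min (0.90).

#' Construct a preferred-term vocabulary
#'
#' @param preferred_terms character vector of PTs, unique case-insensitively;
#'   order governs the perfect-match short circuit.
#' @param manual_overrides named character vector: verbatim -> PT, consulted
#'   before any similarity computation (house for terms standardized by
#'   hand).
#' @return a `meddra_vocabulary` object.
#' @export
meddra_vocabulary <- function(preferred_terms, manual_overrides = character()) {
  preferred_terms <- as.character(preferred_terms)
  if (!length(preferred_terms)) stop("empty vocabulary")
  if (any(!nzchar(preferred_terms))) stop("preferred terms must be non-empty")
  if (anyDuplicated(tolower(preferred_terms)))
    stop("preferred terms must be unique case-insensitively")
  if (length(manual_overrides) &&
      !all(manual_overrides %in% preferred_terms))
    stop("manual overrides must map to vocabulary PTs")
  folded <- .fold_term(preferred_terms)
  structure(list(preferred_terms = preferred_terms,
                 manual_overrides = manual_overrides,
                 folded = folded,
                 lookup = stats::setNames(seq_along(folded), folded)),
            class = "meddra_vocabulary")
}

#' @export
print.meddra_vocabulary <- function(x, ...) {
  cat("<meddra_vocabulary> ", length(x$preferred_terms), " preferred terms, ",
      length(x$manual_overrides), " manual overrides\n", sep = "")
  invisible(x)
}

#' Read a vocabulary (one PT per line) and optional overrides
#' @param path UTF-8 text file, one preferred term per line.
#' @param overrides_path optional `verbatim<TAB>PT` file, no header.
#' @return a `meddra_vocabulary`.
#' @export
read_meddra_vocabulary <- function(path, overrides_path = NULL) {
  pts <- readLines(path, encoding = "UTF-8", warn = FALSE)
  pts <- pts[nzchar(trimws(pts))]
  ov <- character()
  if (!is.null(overrides_path)) {
    dt <- data.table::fread(overrides_path, sep = "\t", header = FALSE,
                            col.names = c("verbatim", "pt"),
                            colClasses = "character", showProgress = FALSE)
    ov <- stats::setNames(dt$pt, dt$verbatim)
  }
  meddra_vocabulary(pts, manual_overrides = ov)
}

.fold_term <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Normalized Levenshtein similarity
#'
#' `1 - edit_distance(a', b') / max(|a'|, |b'|)` on case-folded,
#' whitespace-collapsed strings; equals 1 iff the folded strings are equal.
#' Two empty strings score 1 by convention.  Vectorized over `b`.
#'
#' @param a one string.
#' @param b character vector.
#' @return numeric vector of similarities in \[0, 1\].
#' @export
levenshtein_similarity <- function(a, b) {
  stopifnot(length(a) == 1L)
  af <- .fold_term(a); bf <- .fold_term(b)
  mx <- pmax(nchar(af), nchar(bf))
  d <- as.numeric(utils::adist(af, bf))
  out <- ifelse(mx == 0, 1, 1 - d / mx)
  unname(out)
}

#' Standardize one verbatim term to a preferred term
#'
#' Manual overrides first; else the first PT (vocabulary order) with
#' similarity `>= s_perfect` short-circuits; else the best-scoring PT if
#' `>= s_min`, ties going to the lexicographically smallest PT; else
#' unmatched.
#'
#' @param verbatim one verbatim ADR/indication string.
#' @param vocab a [meddra_vocabulary()].
#' @param s_perfect perfect-match similarity threshold (default 0.95).
#' @param s_min minimum acceptable similarity (default 0.90).
#' @return list with `pt` (`NA` if unmatched), `score` and `method` in
#'   `{"exact", "fuzzy", "override", "unmatched"}`.
#' @export
normalize_adr <- function(verbatim, vocab, s_perfect = 0.95, s_min = 0.90) {
  stopifnot(inherits(vocab, "meddra_vocabulary"), length(verbatim) == 1L)
  ov <- vocab$manual_overrides
  if (length(ov) && verbatim %in% names(ov))
    return(list(pt = unname(ov[[verbatim]]), score = 1, method = "override"))
  vf <- .fold_term(verbatim)
  hit <- vocab$lookup[vf]            # identical folded string: similarity 1
  if (!is.na(hit))
    return(list(pt = vocab$preferred_terms[[hit]], score = 1,
                method = "exact"))
  s <- levenshtein_similarity(verbatim, vocab$preferred_terms)
  perfect <- which(s >= s_perfect)
  if (length(perfect)) {
    i <- perfect[1]
    return(list(pt = vocab$preferred_terms[[i]], score = s[[i]],
                method = "exact"))
  }
  ok <- which(s >= s_min)
  if (!length(ok))
    return(list(pt = NA_character_, score = max(s, 0), method = "unmatched"))
  best <- ok[s[ok] == max(s[ok])]
  i <- best[order(vocab$preferred_terms[best])][1]
  list(pt = vocab$preferred_terms[[i]], score = s[[i]], method = "fuzzy")
}

#' Standardize all reactions and indications of a corpus
#'
#' Every reaction verbatim and drug indication is replaced by its preferred
#' term (or flagged unmatched).  Unique strings are normalized once; folded
#' exact matches take a fast path past the edit-distance computation.
#'
#' @param corpus a `faers_corpus`.
#' @param vocab a [meddra_vocabulary()].
#' @param s_perfect,s_min see [normalize_adr()].
#' @return list with `corpus` (standardized: `reactions$pt`,
#'   `drugs$indication_pt` filled) and `rates` (list: `reaction_match_rate`,
#'   `indication_match_rate`, `n_unmatched_reactions`,
#'   `n_unmatched_indications`).
#' @export
normalize_corpus <- function(corpus, vocab, s_perfect = 0.95, s_min = 0.90) {
  stopifnot(inherits(corpus, "faers_corpus"))
  pt <- match_score <- indication_pt <- NULL
  norm_unique <- function(strings) {
    uniq <- unique(strings[!is.na(strings)])
    res <- lapply(uniq, normalize_adr, vocab = vocab,
                  s_perfect = s_perfect, s_min = s_min)
    list(uniq = uniq,
         pt = vapply(res, function(r) r$pt, ""),
         score = vapply(res, function(r) r$score, 0))
  }
  reactions <- data.table::copy(corpus$reactions)
  nr <- norm_unique(reactions$verbatim)
  i <- match(reactions$verbatim, nr$uniq)
  reactions[, `:=`(pt = nr$pt[i], match_score = nr$score[i])]

  drugs <- data.table::copy(corpus$drugs)
  ni <- norm_unique(drugs$indication)
  j <- match(drugs$indication, ni$uniq)
  drugs[, indication_pt := ifelse(is.na(j), NA_character_, ni$pt[j])]

  out <- corpus
  out$reactions <- reactions
  out$drugs <- drugs
  has_ind <- !is.na(drugs$indication)
  list(corpus = out,
       rates = list(
         reaction_match_rate = mean(!is.na(reactions$pt)),
         indication_match_rate = if (any(has_ind))
           mean(!is.na(drugs$indication_pt[has_ind])) else NA_real_,
         n_unmatched_reactions = sum(is.na(reactions$pt)),
         n_unmatched_indications = sum(has_ind & is.na(drugs$indication_pt))))
}
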