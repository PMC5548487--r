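# Seeded generator of FAERS-like corpora with planted ground truth.
#
# The generator states a small world: drug and reaction independent under the
# null, planted drug-ADR associations as reporting-rate multipliers, synonym
# fragmentation of ingredients across name strings, exact-duplicate and
# follow-up injection, indication=ADR conflation, occupation mixtures that
# shift over calendar time, and month-localized reporting spikes.

.filler_tokens <- c("10mg", "20mg", "50mg", "100mg", "tablets", "capsules",
                    "oral", "solution", "injection", "cream", "hcl",
                    "extended release")

# deterministic pseudo-words (independent of the RNG so ingredient identities
# are stable across seeds); index-addressed, collision-free by construction
.pseudo_word <- function(idx, salt = 0L) {
  on1 <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vo <- c("a", "e", "i", "o", "u")
  on2 <- c("b", "c", "d", "l", "m", "n", "r", "x", "z", "th", "pr", "st")
  end <- c("ib", "ol", "in", "ax", "on", "ide", "ine", "ate", "um", "il")
  i <- as.integer(idx) - 1L + as.integer(salt) * 997L
  n1 <- length(on1); n2 <- length(vo); n3 <- length(on2); n4 <- length(end)
  paste0(on1[i %% n1 + 1L],
         vo[(i %/% n1) %% n2 + 1L],
         on2[(i %/% (n1 * n2)) %% n3 + 1L],
         vo[(i %/% (n1 * n2 * n3)) %% n2 + 1L],
         end[(i %/% (n1 * n2 * n3 * n2)) %% n4 + 1L])
}

.synth_ingredient_key <- function(i) sprintf("ING:%s", .pseudo_word(i, salt = 1L))
.synth_canonical_name <- function(i) {
  paste(.pseudo_word(i, salt = 2L), .pseudo_word(i, salt = 3L))
}
.synth_pt <- function(j) {
  paste(.pseudo_word(j, salt = 11L), .pseudo_word(j, salt = 12L), "disorder")
}

#' Configuration of the synthetic report generator
#'
#' Defaults describe a moderately sized null world: uniform background drug
#' and reaction frequencies, no planted associations, one synonym per
#' ingredient with no name noise, no duplicates or conflation, a single
#' FAERS-like occupation mixture, and dates uniform over 2004--2008.
#'
#' @param n_reports number of base reports (duplicates/follow-ups add more).
#' @param n_ingredients,n_adrs vocabulary sizes.
#' @param background_drug_weights,background_adr_weights probability vectors
#'   (length `n_ingredients` / `n_adrs`, summing to 1); default uniform.
#' @param planted_associations list of lists with elements `ingredient`
#'   (index), `adr` (index), `rho` (reporting-rate multiplier > 0) and
#'   optional `window = c(first, last)` month labels (`"YYYY-MM"`).
#' @param synonyms_per_ingredient number of distinct clean name strings per
#'   ingredient (first is the canonical name; the rest are brand-like).
#' @param synonym_noise token-perturbation intensity in \[0, 1\] applied to
#'   emitted verbatim names (see [perturb_name()]).
#' @param duplicate_fraction fraction of reports copied verbatim under a new
#'   report id (exact-duplicate injection).
#' @param followup_fraction fraction of reports that receive a later
#'   follow-up version sharing the `case_id`.
#' @param conflation_fraction fraction of reports whose suspect-drug
#'   indication is set equal to one of the report's reactions.
#' @param occupation_mixture named list `period-start ("YYYY-MM") ->`
#'   probability vector over [faers_occupations()]; periods extend to the
#'   next break.
#' @param outcome_weights probability vector over [faers_outcomes()].
#' @param spike_windows list of lists with `ingredient`, `adr`,
#'   `window = c(first, last)` month labels and `intensity` (> 1): the pair's
#'   reporting rate is multiplied by `intensity` inside the window only.
#' @param extra_drug_prob probability that a report carries one additional
#'   concomitant drug.
#' @param n_adr_weights probabilities of 1, 2 or 3 reactions per report.
#' @param date_range two month labels (`"YYYY-MM"`) bounding event dates.
#' @param missing_age_fraction fraction of reports with missing age.
#' @param seed integer RNG seed; the corpus is a pure function of the config.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports = 10000,
                             n_ingredients = 50,
                             n_adrs = 50,
                             background_drug_weights = NULL,
                             background_adr_weights = NULL,
                             planted_associations = list(),
                             synonyms_per_ingredient = 1,
                             synonym_noise = 0,
                             duplicate_fraction = 0,
                             followup_fraction = 0,
                             conflation_fraction = 0,
                             occupation_mixture = NULL,
                             outcome_weights = c(0.15, 0.05, 0.05, 0.01,
                                                 0.04, 0.30, 0.40),
                             spike_windows = list(),
                             extra_drug_prob = 0,
                             n_adr_weights = c(0.6, 0.3, 0.1),
                             date_range = c("2004-01", "2008-12"),
                             missing_age_fraction = 0.05,
                             seed = 1L) {
  if (is.null(background_drug_weights))
    background_drug_weights <- rep(1 / n_ingredients, n_ingredients)
  if (is.null(background_adr_weights))
    background_adr_weights <- rep(1 / n_adrs, n_adrs)
  if (is.null(occupation_mixture))
    occupation_mixture <- stats::setNames(
      list(c(0.25, 0.10, 0.15, 0.35, 0.03, 0.12)), date_range[1])
  cfg <- list(n_reports = as.integer(n_reports),
              n_ingredients = as.integer(n_ingredients),
              n_adrs = as.integer(n_adrs),
              background_drug_weights = background_drug_weights,
              background_adr_weights = background_adr_weights,
              planted_associations = planted_associations,
              synonyms_per_ingredient = as.integer(synonyms_per_ingredient),
              synonym_noise = synonym_noise,
              duplicate_fraction = duplicate_fraction,
              followup_fraction = followup_fraction,
              conflation_fraction = conflation_fraction,
              occupation_mixture = occupation_mixture,
              outcome_weights = outcome_weights,
              spike_windows = spike_windows,
              extra_drug_prob = extra_drug_prob,
              n_adr_weights = n_adr_weights,
              date_range = date_range,
              missing_age_fraction = missing_age_fraction,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' @rdname synthetic_config
#' @param config a `synthetic_config`.
#' @export
validate_synthetic_config <- function(config) {
  stopifnot(config$n_reports > 0, config$n_ingredients > 0, config$n_adrs > 0,
            config$synonyms_per_ingredient > 0)
  chk_prob <- function(p, len, what) {
    if (length(p) != len)
      stop(what, " must have length ", len)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(what, " must be a probability vector summing to 1")
  }
  chk_prob(config$background_drug_weights, config$n_ingredients,
           "background_drug_weights")
  chk_prob(config$background_adr_weights, config$n_adrs,
           "background_adr_weights")
  chk_prob(config$outcome_weights, 7L, "outcome_weights")
  chk_prob(config$n_adr_weights, 3L, "n_adr_weights")
  for (f in c("synonym_noise", "duplicate_fraction", "followup_fraction",
              "conflation_fraction", "missing_age_fraction")) {
    v <- config[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  for (pl in c(config$planted_associations, config$spike_windows)) {
    rho <- if (!is.null(pl$rho)) pl$rho else pl$intensity
    if (is.null(rho) || rho <= 0)
      stop("planted associations / spikes need a positive rate multiplier")
    if (pl$ingredient < 1 || pl$ingredient > config$n_ingredients ||
        pl$adr < 1 || pl$adr > config$n_adrs)
      stop("planted association indexes out of range")
    p <- config$background_adr_weights[pl$adr]
    if (rho * p / (1 + (rho - 1) * p) > 1 + 1e-12)
      stop("infeasible planted association: rho * p cannot renormalize")
  }
  for (occ in config$occupation_mixture)
    chk_prob(occ, length(faers_occupations()), "each occupation mixture")
  if (!grepl("^\\d{4}-\\d{2}$", config$date_range[1]) ||
      !grepl("^\\d{4}-\\d{2}$", config$date_range[2]))
    stop("date_range must be 'YYYY-MM' labels")
  invisible(config)
}

# month-label helpers shared with the timeseries module
month_label <- function(dates) format(dates, "%Y-%m")

#' Sequence of month labels between two labels (inclusive)
#' @param from,to `"YYYY-MM"` labels.
#' @return character vector of consecutive month labels.
#' @export
month_seq <- function(from, to) {
  s <- seq(as.Date(paste0(from, "-01")), as.Date(paste0(to, "-01")),
           by = "month")
  format(s, "%Y-%m")
}

.run_seeded <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Perturb a drug-name string
#'
#' Stresses name normalization with the kinds of variation seen in verbatim
#' FAERS drug fields: casing changes, appended filler tokens (dosage words,
#' formulations), inserted punctuation and token reordering.  Each operation
#' fires independently with probability `noise`; `noise = 0` returns the
#' input unchanged.  At least one original token always survives
#' tokenization.  Reproducible under a fixed RNG state (pass `seed` or seed
#' the session RNG).
#'
#' @param name character vector of names.
#' @param noise perturbation intensity in \[0, 1\].
#' @param seed optional integer; when given, the RNG state is set (and
#'   restored) locally.
#' @return character vector of perturbed names.
#' @export
perturb_name <- function(name, noise, seed = NULL) {
  stopifnot(noise >= 0, noise <= 1)
  if (noise == 0) return(name)
  if (!is.null(seed)) return(.run_seeded(seed, perturb_name(name, noise)))
  n <- length(name)
  out <- name
  # token reordering (reverse token order)
  do <- stats::runif(n) < noise
  if (any(do)) {
    out[do] <- vapply(strsplit(out[do], "\\s+"),
                      function(tk) paste(rev(tk), collapse = " "), "")
  }
  # casing
  do <- stats::runif(n) < noise
  out[do] <- toupper(out[do])
  # punctuation insertion: parenthesize the final token
  do <- stats::runif(n) < noise
  if (any(do)) {
    out[do] <- sub("(\\S+)$", "(\\1)", out[do])
  }
  # appended filler tokens
  do <- stats::runif(n) < noise
  if (any(do)) {
    out[do] <- paste(out[do],
                     sample(.filler_tokens, sum(do), replace = TRUE))
  }
  out
}

# clean synonym strings for ingredient i: canonical two-token name first,
# then brand-like single-token names
.synth_synonyms <- function(i, k) {
  if (k == 1L) return(.synth_canonical_name(i))
  c(.synth_canonical_name(i),
    vapply(seq_len(k - 1L),
           function(j) .pseudo_word((i - 1L) * 64L + j, salt = 21L), ""))
}

#' Synonym table and MedDRA vocabulary of a synthetic world
#'
#' `synthetic_synonym_table()` returns the clean synonym strings the
#' generator draws from, as a [synonym_table()]; `synthetic_vocabulary()`
#' returns the generator's preferred-term list as a [meddra_vocabulary()].
#'
#' @param config a `synthetic_config`.
#' @return See description.
#' @export
synthetic_synonym_table <- function(config) {
  k <- config$synonyms_per_ingredient
  entries <- data.table::rbindlist(lapply(seq_len(config$n_ingredients),
    function(i) data.table::data.table(
      synonym = .synth_synonyms(i, k),
      ingredient_keys = .synth_ingredient_key(i))))
  synonym_table(entries)
}

.synth_indication <- function(j) paste(.pseudo_word(j, salt = 31L), "chronica")

#' @rdname synthetic_synonym_table
#' @export
synthetic_vocabulary <- function(config) {
  # reaction PTs plus the disjoint indication PTs the generator draws from,
  # so background indications standardize like real MedDRA-coded fields
  meddra_vocabulary(c(vapply(seq_len(config$n_adrs), .synth_pt, ""),
                      vapply(seq_len(8L), .synth_indication, "")))
}

#' Generate a synthetic report corpus with ground truth
#'
#' Draws `n_reports` reports with drug and reaction independent under the
#' null; planted `(ingredient, adr, rho)` associations multiply that pair's
#' reaction weight by `rho` (renormalized) for reports of the ingredient
#' within the active window; spike windows do the same but only inside their
#' window.  Each ingredient mention is emitted under one of its synonym
#' strings chosen uniformly, then perturbed by `synonym_noise`.  A configured
#' fraction of reports is copied verbatim (new report id), given follow-up
#' versions (same case id, later receipt date), or conflated
#' (indication := one reaction).  Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `corpus` (a [faers_corpus()]) and `truth`
#'   (a `ground_truth` list: `planted_associations`, `spike_windows`,
#'   `duplicate_groups`, `followup_case_ids`, `conflated_report_ids`,
#'   `synonym_map`, `ingredient_keys`, `pts`, `n_base_reports`).
#' @export
generate_faers <- function(config) {
  validate_synthetic_config(config)
  .run_seeded(config$seed, .generate_faers_impl(config))
}

.generate_faers_impl <- function(config) {
  n <- config$n_reports
  months <- month_seq(config$date_range[1], config$date_range[2])
  keys <- vapply(seq_len(config$n_ingredients), .synth_ingredient_key, "")
  pts <- vapply(seq_len(config$n_adrs), .synth_pt, "")

  report_id <- sprintf("R%07d", seq_len(n))
  month_idx <- sample.int(length(months), n, replace = TRUE)
  month_first <- as.Date(paste0(months, "-01"))
  days_in_month <- as.integer(
    seq(month_first[1], by = "month", length.out = length(months) + 1L)[-1] -
      month_first)
  event_date <- month_first[month_idx] +
    floor(stats::runif(n) * days_in_month[month_idx])
  receipt_date <- event_date + sample.int(60L, n, replace = TRUE)

  ing_idx <- sample.int(config$n_ingredients, n, replace = TRUE,
                        prob = config$background_drug_weights)

  # reactions: 1-3 mentions per report, background multinomial
  n_adr <- sample.int(3L, n, replace = TRUE, prob = config$n_adr_weights)
  mention_report <- rep.int(seq_len(n), n_adr)
  adr_idx <- sample.int(config$n_adrs, length(mention_report), replace = TRUE,
                        prob = config$background_adr_weights)

  # planted associations and spikes: resample affected mentions from the
  # tilted reaction distribution (rho on one ADR, renormalized)
  plants <- c(lapply(config$planted_associations, function(p) {
    list(ingredient = p$ingredient, adr = p$adr, rho = p$rho,
         window = if (is.null(p$window)) range(months) else p$window)
  }), lapply(config$spike_windows, function(p) {
    list(ingredient = p$ingredient, adr = p$adr, rho = p$intensity,
         window = p$window)
  }))
  if (length(plants)) {
    report_month <- months[month_idx]
    affected <- matrix(FALSE, n, length(plants))
    for (j in seq_along(plants)) {
      pl <- plants[[j]]
      win <- month_seq(pl$window[1], pl$window[2])
      affected[, j] <- ing_idx == pl$ingredient & report_month %in% win
    }
    # reports hit by several plants get the jointly tilted distribution
    grp <- as.integer(affected %*% 2L^(seq_along(plants) - 1L))
    for (g in setdiff(unique(grp), 0L)) {
      w <- config$background_adr_weights
      for (j in seq_along(plants)) {
        if (bitwAnd(g, 2L^(j - 1L)) != 0L)
          w[plants[[j]]$adr] <- w[plants[[j]]$adr] * plants[[j]]$rho
      }
      slots <- which((grp == g)[mention_report])
      if (!length(slots)) next
      adr_idx[slots] <- sample.int(config$n_adrs, length(slots),
                                   replace = TRUE, prob = w / sum(w))
    }
  }

  # demographics
  age <- 18 + floor(stats::runif(n) * 68)
  age[stats::runif(n) < config$missing_age_fraction] <- NA_real_
  sex <- sample(c("M", "F", "unknown"), n, replace = TRUE,
                prob = c(0.49, 0.49, 0.02))

  # occupation mixture by calendar period
  month_num <- function(lab) {
    as.integer(substr(lab, 1, 4)) * 12L + as.integer(substr(lab, 6, 7))
  }
  occ_breaks <- names(config$occupation_mixture)
  ord <- order(occ_breaks)
  occ_breaks <- occ_breaks[ord]
  occ_mix <- config$occupation_mixture[ord]
  period_of <- findInterval(month_num(months[month_idx]),
                            month_num(occ_breaks))
  period_of[period_of == 0L] <- 1L
  occupation <- character(n)
  for (p in seq_along(occ_mix)) {
    idx <- which(period_of == p)
    if (length(idx))
      occupation[idx] <- sample(faers_occupations(), length(idx),
                                replace = TRUE, prob = occ_mix[[p]])
  }

  outcome <- sample(faers_outcomes(), n, replace = TRUE,
                    prob = config$outcome_weights)

  # verbatim names: synonym chosen uniformly, then perturbed
  k <- config$synonyms_per_ingredient
  syn_strings <- lapply(seq_len(config$n_ingredients), .synth_synonyms, k = k)
  syn_choice <- sample.int(k, n, replace = TRUE)
  clean_name <- vapply(seq_len(config$n_ingredients),
                       function(i) syn_strings[[i]][1], "")
  verbatim <- mapply(function(i, j) syn_strings[[i]][j], ing_idx, syn_choice,
                     USE.NAMES = FALSE)
  verbatim <- perturb_name(verbatim, config$synonym_noise)

  # background (non-conflated) indication pool, disjoint from the ADR PTs
  # so conflation can only arise from the planted overwrite below
  indication_pool <- vapply(seq_len(8L), .synth_indication, "")
  indication <- sample(indication_pool, n, replace = TRUE)

  reactions <- data.table::data.table(
    report_id = report_id[mention_report], verbatim = pts[adr_idx])
  # drop within-report repeats of the same PT so margins stay report-level
  reactions <- unique(reactions)

  # conflation: indication of the suspect drug := one of the reactions
  n_confl <- round(config$conflation_fraction * n)
  conflated_ids <- character(0)
  if (n_confl > 0) {
    conflated <- sample.int(n, n_confl)
    conflated_ids <- report_id[conflated]
    first_reac <- reactions[, list(v = verbatim[1]), by = "report_id"]
    fr <- stats::setNames(first_reac$v, first_reac$report_id)
    indication[conflated] <- unname(fr[report_id[conflated]])
  }

  drugs <- data.table::data.table(
    report_id = report_id, drug_seq = 1L, verbatim_name = verbatim,
    role = "PS", indication = indication)

  # optional concomitant second drug
  if (config$extra_drug_prob > 0) {
    extra <- which(stats::runif(n) < config$extra_drug_prob)
    if (length(extra)) {
      e_idx <- sample.int(config$n_ingredients, length(extra), replace = TRUE,
                          prob = config$background_drug_weights)
      e_verb <- mapply(function(i, j) syn_strings[[i]][j], e_idx,
                       sample.int(k, length(extra), replace = TRUE),
                       USE.NAMES = FALSE)
      e_verb <- perturb_name(e_verb, config$synonym_noise)
      drugs <- rbind(drugs, data.table::data.table(
        report_id = report_id[extra], drug_seq = 2L, verbatim_name = e_verb,
        role = "C", indication = NA_character_))
    }
  }

  reports <- data.table::data.table(
    report_id = report_id, case_id = paste0("C", report_id),
    event_date = event_date, receipt_date = receipt_date,
    occupation = occupation, age = age, sex = sex)
  outcomes <- data.table::data.table(report_id = report_id, outcome = outcome)

  # exact duplicates: verbatim copies under a fresh report id and case id
  n_dup <- round(config$duplicate_fraction * n)
  duplicate_groups <- list()
  if (n_dup > 0) {
    src <- sort(sample.int(n, n_dup))
    dup_ids <- sprintf("RD%06d", seq_len(n_dup))
    dup_rep <- reports[src]
    dup_rep[, `:=`(report_id = dup_ids, case_id = paste0("C", dup_ids))]
    copy_rows <- function(dt) {
      m <- match(dt$report_id, report_id[src])
      out <- dt[!is.na(m)]
      out[, report_id := dup_ids[m[!is.na(m)]]]
      out
    }
    dup_drugs <- copy_rows(drugs)
    dup_reac <- copy_rows(reactions)
    dup_outc <- copy_rows(outcomes)
    reports <- rbind(reports, dup_rep)
    drugs <- rbind(drugs, dup_drugs)
    reactions <- rbind(reactions, dup_reac)
    outcomes <- rbind(outcomes, dup_outc)
    duplicate_groups <- mapply(function(a, b) sort(c(a, b)),
                               report_id[src], dup_ids, SIMPLIFY = FALSE,
                               USE.NAMES = FALSE)
  }

  # follow-ups: same case, later receipt date, fresh report id
  n_fu <- round(config$followup_fraction * n)
  followup_case_ids <- character(0)
  if (n_fu > 0) {
    src <- sort(sample.int(n, n_fu))
    fu_ids <- sprintf("RF%06d", seq_len(n_fu))
    fu_rep <- reports[src]
    followup_case_ids <- fu_rep$case_id
    fu_rep[, `:=`(report_id = fu_ids,
                  receipt_date = receipt_date + 30L +
                    sample.int(150L, n_fu, replace = TRUE))]
    copy_rows <- function(dt) {
      m <- match(dt$report_id, report_id[src])
      out <- dt[!is.na(m)]
      out[, report_id := fu_ids[m[!is.na(m)]]]
      out
    }
    reports <- rbind(reports, fu_rep)
    drugs <- rbind(drugs, copy_rows(drugs))
    reactions <- rbind(reactions, copy_rows(reactions))
    outcomes <- rbind(outcomes, copy_rows(outcomes))
  }

  synonym_map <- stats::setNames(
    rep(keys, vapply(syn_strings, length, 0L)), unlist(syn_strings))

  corpus <- faers_corpus(
    reports = reports, drugs = drugs, reactions = reactions,
    outcomes = outcomes,
    provenance = list(source = "synthetic", seed = config$seed,
                      n_base_reports = n))
  truth <- structure(
    list(planted_associations = lapply(config$planted_associations, function(p)
      list(ingredient_key = keys[p$ingredient], adr_pt = pts[p$adr],
           rho = p$rho,
           window = if (is.null(p$window)) config$date_range else p$window)),
      spike_windows = lapply(config$spike_windows, function(p)
        list(ingredient_key = keys[p$ingredient], adr_pt = pts[p$adr],
             intensity = p$intensity, window = p$window)),
      duplicate_groups = duplicate_groups,
      followup_case_ids = followup_case_ids,
      conflated_report_ids = conflated_ids,
      synonym_map = synonym_map,
      ingredient_keys = keys, pts = pts,
      n_base_reports = n),
    class = "ground_truth")
  list(corpus = corpus, truth = truth)
}
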