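# Quantification of reporting biases: indication-ADR conflation,
# reporter-occupation composition over time, outcome distributions,
# reporter-driven association modeling, and exposure-margin classification.

#' Find reports whose indication is also listed as the adverse event
#'
#' A conflation is a (report, primary-suspect drug) pair whose standardized
#' indication preferred term also appears among the report's standardized
#' reactions -- the drug's treatment indication reported as the ADR itself.
#' Comparison is case-insensitive on preferred terms; each drug entry is
#' compared against its own indication only.
#'
#' @param corpus a normalized `faers_corpus` (indications and reactions
#'   standardized).
#' @param date_field date used for the yearly series (`"event_date"`, with
#'   receipt-date fallback, or `"receipt_date"`).
#' @return list with `records` (data.table: `report_id`, `ingredient_key`
#'   -- verbatim name if unmapped -- and `term`) and `yearly` (data.table:
#'   `year`, `n_conflated`, `n_with_indication`, `fraction`).
#' @export
find_conflations <- function(corpus, date_field = "event_date") {
  stopifnot(inherits(corpus, "faers_corpus"))
  role <- indication_pt <- ingredient_keys <- verbatim_name <- pt <- NULL
  report_id <- term <- year <- n_conflated <- n_with_indication <- NULL
  conflated <- fraction <- NULL
  d <- corpus$drugs[role == "PS" & !is.na(indication_pt)]
  d <- d[, list(report_id,
                ingredient_key = ifelse(is.na(ingredient_keys),
                                        verbatim_name, ingredient_keys),
                ind_pt = tolower(indication_pt), indication_pt)]
  r <- corpus$reactions[!is.na(pt), list(report_id, pt, ptl = tolower(pt))]
  rec <- merge(d, r, by = "report_id", allow.cartesian = TRUE)
  rec <- rec[rec$ind_pt == rec$ptl,
             list(report_id, ingredient_key, term = pt)]
  rec <- unique(rec)
  data.table::setorder(rec, report_id, ingredient_key, term)

  months_of <- .report_months(corpus, date_field)
  yr <- substr(months_of, 1, 4)
  # denominator: reports whose suspect drug carries any indication verbatim
  # (matched or not), so unmatched indications do not deflate it
  has_ind <- corpus$drugs[role == "PS" & !is.na(indication),
                          unique(report_id)]
  yearly <- data.table::data.table(
    report_id = corpus$reports$report_id, year = unname(yr))
  yearly <- yearly[report_id %in% has_ind]
  yearly[, conflated := report_id %in% rec$report_id]
  yearly <- yearly[, list(n_conflated = sum(conflated),
                          n_with_indication = .N), by = "year"]
  yearly[, fraction := n_conflated / n_with_indication]
  data.table::setorder(yearly, year)
  list(records = rec, yearly = yearly[])
}

#' Reporter-occupation composition by calendar period
#'
#' @param corpus a `faers_corpus`.
#' @param period_breaks `"YYYY-MM"` labels starting each period; reports
#'   before the first break fall into the first period.  `NULL` gives one
#'   overall period.
#' @param date_field see [find_conflations()].
#' @return data.table with `period`, `occupation`, `n`, `fraction`
#'   (fractions sum to 1 within each period with data; empty periods are
#'   absent).
#' @export
reporter_composition <- function(corpus, period_breaks = NULL,
                                 date_field = "event_date") {
  fraction <- n <- NULL
  months_of <- .report_months(corpus, date_field)
  if (is.null(period_breaks)) {
    period <- rep("all", nrow(corpus$reports))
  } else {
    period_breaks <- sort(period_breaks)
    # "YYYY-MM" labels order lexicographically
    idx <- rowSums(outer(months_of, period_breaks, ">="))
    idx[idx == 0L] <- 1L
    period <- period_breaks[idx]
  }
  dt <- data.table::data.table(period = period,
                               occupation = corpus$reports$occupation)
  out <- dt[, list(n = .N), by = c("period", "occupation")]
  out[, fraction := n / sum(n), by = "period"]
  data.table::setorder(out, period, occupation)
  out[]
}

#' Distribution of reports over the seven outcome categories
#'
#' In `"mentions"` mode (default) every outcome listed counts once, so a
#' multi-outcome report contributes to several categories and the
#' denominator is the total number of outcome mentions.  In
#' `"worst_per_report"` mode each report contributes only its most serious
#' outcome (severity order: Death, Life-Threatening, Disability, Congenital
#' Anomaly, Required Intervention, Hospitalization, Other).
#'
#' @param corpus a `faers_corpus`.
#' @param mode `"mentions"` or `"worst_per_report"`.
#' @return data.table with `outcome`, `n`, `fraction` covering all seven
#'   categories (zeros included).
#' @export
outcome_distribution <- function(corpus, mode = c("mentions",
                                                  "worst_per_report")) {
  mode <- match.arg(mode)
  oc <- corpus$outcomes
  if (mode == "worst_per_report" && nrow(oc)) {
    sev <- match(oc$outcome, faers_outcomes())   # enum is in severity order
    oc <- oc[order(oc$report_id, sev)]
    oc <- oc[!duplicated(oc$report_id)]
  }
  counts <- table(factor(oc$outcome, levels = faers_outcomes()))
  data.table::data.table(outcome = faers_outcomes(),
                         n = as.integer(counts),
                         fraction = if (sum(counts) > 0)
                           as.numeric(counts) / sum(counts) else NA_real_)
}

#' Logistic model of reporting odds
#'
#' Fits, by maximum likelihood (IRLS, the binomial GLM with logit link),
#' the probability that a report mentions `response_adr` as a function of
#' report-level covariates: an indicator that `suspect_ingredient` is a
#' primary suspect in the report, reporter-occupation indicators, and an
#' indicator that the report predates `cutoff_date`.
#'
#' @param corpus a mapped, normalized `faers_corpus`.
#' @param response_adr preferred term serving as the outcome variable.
#' @param suspect_ingredient ingredient key for the drug indicator.
#' @param covariates subset of `c("drug", "occupation", "pre_cutoff")`.
#' @param cutoff_date `Date` used by the `pre_cutoff` indicator.
#' @param occupation_ref reference occupation level (dropped indicator).
#' @param date_field see [find_conflations()].
#' @return a `glm_fit` list: `coefficients` (data.table with `term`,
#'   `estimate`, `std_error`, `z`), `converged`, `n_obs`, `model` (the
#'   underlying `glm` object).
#' @export
logistic_model <- function(corpus, response_adr, suspect_ingredient = NULL,
                           covariates = c("drug", "occupation", "pre_cutoff"),
                           cutoff_date = as.Date("2005-01-01"),
                           occupation_ref = "physician",
                           date_field = "event_date") {
  covariates <- if (length(covariates))
    match.arg(covariates, several.ok = TRUE) else character(0)
  ingredient_key <- adr_pt <- NULL
  ids <- corpus$reports$report_id
  y <- ids %in% .adr_reports(corpus)[adr_pt == response_adr, report_id]
  dat <- data.frame(y = as.integer(y))
  if ("drug" %in% covariates) {
    if (is.null(suspect_ingredient))
      stop("the 'drug' covariate needs a suspect_ingredient")
    dat$drug <- as.integer(
      ids %in% .drug_reports(corpus, "PS")[ingredient_key ==
                                             suspect_ingredient, report_id])
  }
  if ("occupation" %in% covariates) {
    occ <- factor(corpus$reports$occupation,
                  levels = c(occupation_ref,
                             setdiff(faers_occupations(), occupation_ref)))
    dat$occupation <- occ
  }
  if ("pre_cutoff" %in% covariates) {
    months_of <- .report_months(corpus, date_field)
    dat$pre_cutoff <- as.integer(months_of < format(cutoff_date, "%Y-%m"))
  }
  fml <- if (ncol(dat) > 1L) y ~ . else y ~ 1
  fit <- stats::glm(fml, data = dat, family = stats::binomial())
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = data.table::data.table(
      term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
      z = sm[, 3]),
    converged = fit$converged &&
      all(is.finite(stats::coef(fit))) &&
      all(sm[, 2] < 1e3),             # huge SEs signal (near-)separation
    n_obs = nrow(dat), model = fit), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> n =", x$n_obs,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$coefficients)
  invisible(x)
}

#' Exposure margin and ADR-liability flag
#'
#' `EM = IC50 / Cmax` for a target's biochemical potency and the drug's free
#' maximal plasma concentration, in the same concentration units (the caller
#' must guarantee unit agreement -- no unit metadata is carried).  Margins
#' below `threshold` (default 10) predict target engagement at clinical
#' exposure and hence ADR liability.
#'
#' @param ic50 biochemical IC50 (> 0), same units as `cmax`.
#' @param cmax free maximal plasma concentration (> 0).
#' @param threshold classification cutoff (default 10).
#' @return data.table with `EM` and `flag` (`TRUE` = predicted liability),
#'   vectorized over inputs.
#' @export
exposure_margin <- function(ic50, cmax, threshold = 10) {
  if (any(!is.finite(ic50)) || any(!is.finite(cmax)) ||
      any(ic50 <= 0) || any(cmax <= 0))
    stop("ic50 and cmax must be positive and finite")
  em <- ic50 / cmax
  data.table::data.table(EM = em, flag = em < threshold)
}
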