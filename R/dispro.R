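# Ingredient-ADR disproportionality statistics.
#
# Report-level 2x2 contingency tables; relative reporting ratio RRR = N/E
# with E = R*C/T under independence; Yates-corrected chi-square p-values;
# Holm step-down adjustment (q-values); the selection filter N >= 5,
# q < 0.05, RRR > 1; age/sex-stratified expected counts; and gamma-Poisson
# empirical-Bayes shrinkage (EBGM, EB05, EB95) under a two-component gamma
# mixture prior fitted to the whole array of (N, E) pairs.

#' Construct a 2x2 contingency summary for one ingredient-ADR pair
#'
#' Counting is report-level: a report counts once for the ingredient if any
#' drug entry with an allowed role maps to it, and once for the ADR if the
#' preferred term appears among its reactions.
#'
#' @param n11 reports with both ingredient and ADR.
#' @param row_total reports with the ingredient (R).
#' @param col_total reports with the ADR (C).
#' @param grand_total reports in scope (T).
#' @return a `contingency_table` list.
#' @export
contingency_table <- function(n11, row_total, col_total, grand_total) {
  stopifnot(n11 >= 0, row_total >= 0, col_total >= 0, grand_total >= 0,
            n11 <= row_total, n11 <= col_total,
            row_total <= grand_total, col_total <= grand_total,
            # both margins must fit: n22 >= 0
            grand_total - row_total - col_total + n11 >= 0)
  structure(list(n11 = as.numeric(n11), row_total = as.numeric(row_total),
                 col_total = as.numeric(col_total),
                 grand_total = as.numeric(grand_total)),
            class = "contingency_table")
}

#' Expected count under independence
#' @param table a [contingency_table()].
#' @return `R * C / T` (0 when `T = 0`).
#' @export
expected_count <- function(table) {
  if (table$grand_total == 0) return(0)
  table$row_total * table$col_total / table$grand_total
}

# report-level drug-side and reaction-side incidence tables
.drug_reports <- function(corpus, role_filter) {
  role <- ingredient_keys <- report_id <- NULL
  d <- corpus$drugs[role %in% role_filter & !is.na(ingredient_keys)]
  if (!nrow(d))
    return(data.table::data.table(report_id = character(),
                                  ingredient_key = character()))
  keys <- strsplit(d$ingredient_keys, .key_sep, fixed = TRUE)
  unique(data.table::data.table(
    report_id = rep.int(d$report_id, lengths(keys)),
    ingredient_key = unlist(keys)))
}

.adr_reports <- function(corpus) {
  pt <- report_id <- NULL
  unique(corpus$reactions[!is.na(pt), list(report_id, adr_pt = pt)])
}

#' Build the contingency table of one ingredient-ADR pair
#'
#' @param corpus a mapped and normalized `faers_corpus`.
#' @param ingredient ingredient key.
#' @param adr preferred term.
#' @param role_filter drug roles that count as exposure (default primary
#'   suspect only).
#' @return a [contingency_table()].
#' @export
build_contingency <- function(corpus, ingredient, adr, role_filter = "PS") {
  stopifnot(inherits(corpus, "faers_corpus"))
  if (all(is.na(corpus$drugs$ingredient_keys)))
    stop("corpus has no mapped drugs; run map_corpus() first")
  if (all(is.na(corpus$reactions$pt)))
    stop("corpus has no standardized reactions; run normalize_corpus() first")
  ingredient_key <- adr_pt <- NULL
  dr <- .drug_reports(corpus, role_filter)
  ar <- .adr_reports(corpus)
  ids_i <- dr[ingredient_key == ingredient, report_id]
  ids_a <- ar[adr_pt == adr, report_id]
  contingency_table(n11 = length(intersect(ids_i, ids_a)),
                    row_total = length(ids_i), col_total = length(ids_a),
                    grand_total = nrow(corpus$reports))
}

#' Relative reporting ratio
#'
#' `RRR = N / E` with `E = R * C / T`; defined as 0 when `N = 0`.  `E = 0`
#' with `N > 0` is impossible under the margin invariants and raises an
#' error.
#'
#' @param table a [contingency_table()].
#' @return non-negative number.
#' @export
rrr <- function(table) {
  if (table$n11 == 0) return(0)
  e <- expected_count(table)
  if (e == 0) stop("E = 0 with N > 0 violates the margin invariants")
  table$n11 / e
}

# vectorized Yates chi-square p-value from (n11, R, C, T); the correction is
# clamped so cells with |O - E| < 0.5 contribute 0
.yates_p_vec <- function(n11, R, C, T) {
  e11 <- R * C / T
  e12 <- R * (T - C) / T
  e21 <- (T - R) * C / T
  e22 <- (T - R) * (T - C) / T
  degenerate <- !(e11 > 0 & e12 > 0 & e21 > 0 & e22 > 0)
  degenerate[is.na(degenerate)] <- TRUE      # T = 0
  # all four |O - E| are equal for a 2x2 with fixed margins
  dev <- pmax(abs(n11 - e11) - 0.5, 0)
  stat <- dev^2 * (1 / e11 + 1 / e12 + 1 / e21 + 1 / e22)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[degenerate] <- 1
  p
}

#' Yates-corrected chi-square p-value of a 2x2 table
#'
#' Cells are reconstructed from `(n11, R, C, T)`; the statistic is
#' `sum((|O - E| - 0.5)^2 / E)` with the continuity correction clamped at 0,
#' referred to a chi-square distribution with one degree of freedom.  A
#' degenerate table (any expected cell 0) yields `p = 1` with attribute
#' `degenerate = TRUE`.
#'
#' @param table a [contingency_table()].
#' @return p-value in \[0, 1\].
#' @export
yates_chi2_p <- function(table) {
  R <- table$row_total; C <- table$col_total; T <- table$grand_total
  p <- .yates_p_vec(table$n11, R, C, T)
  degenerate <- T == 0 || R == 0 || C == 0 || R == T || C == T
  if (degenerate) attr(p, "degenerate") <- TRUE
  p
}

#' Holm step-down adjustment
#'
#' Sorts p ascending, sets `q(i) = max_{j<=i} min(1, (m - j + 1) * p(j))`
#' and maps back to input order.  Controls the family-wise error rate; the
#' output is capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q <- pmin(1, (m - seq_len(m) + 1) * p_values[o])
  q <- cummax(q)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Detect disproportionality signals across all observed pairs
#'
#' Builds the report-level 2x2 table of every observed (ingredient,
#' preferred term) pair, computes E, RRR, Yates chi-square p and Holm q over
#' the family of all pairs with `N >= 1` in scope, and applies the selection
#' filter: `N >= min_n`, `q < q_max`, `RRR > rrr_min`.
#'
#' @param corpus a mapped and normalized `faers_corpus`.
#' @param min_n minimum report count (default 5).
#' @param q_max q-value cutoff (default 0.05).
#' @param rrr_min RRR cutoff (default 1).
#' @param role_filter drug roles counting as exposure (default `"PS"`).
#' @param stratify_by optional strata specification (see
#'   [stratified_expected()]); when given, `E` is the stratum-summed
#'   expectation and RRR = N/E uses it.
#' @return data.table with one row per pair: `ingredient_key`, `adr_pt`,
#'   `N`, `E`, `RRR`, `p`, `q`, `passes_filter`; empty corpus gives an empty
#'   table.
#' @export
detect_signals <- function(corpus, min_n = 5, q_max = 0.05, rrr_min = 1,
                           role_filter = "PS", stratify_by = NULL) {
  stopifnot(inherits(corpus, "faers_corpus"))
  N <- E <- RRR <- p <- q <- ingredient_key <- adr_pt <- NULL
  empty <- data.table::data.table(
    ingredient_key = character(), adr_pt = character(), N = numeric(),
    E = numeric(), RRR = numeric(), p = numeric(), q = numeric(),
    passes_filter = logical())
  if (nrow(corpus$reports) == 0L) return(empty)
  dr <- .drug_reports(corpus, role_filter)
  ar <- .adr_reports(corpus)
  if (!nrow(dr) || !nrow(ar)) return(empty)
  T_all <- nrow(corpus$reports)
  pairs <- merge(dr, ar, by = "report_id", allow.cartesian = TRUE)[
    , list(N = as.numeric(.N)), by = c("ingredient_key", "adr_pt")]
  Rm <- dr[, list(R = as.numeric(.N)), by = "ingredient_key"]
  Cm <- ar[, list(C = as.numeric(.N)), by = "adr_pt"]
  pairs <- merge(merge(pairs, Rm, by = "ingredient_key"), Cm, by = "adr_pt")
  if (is.null(stratify_by)) {
    pairs[, E := R * C / T_all]
  } else {
    pairs[, E := mapply(function(i, a) stratified_expected(
      corpus, i, a, strata_spec = stratify_by, role_filter = role_filter),
      ingredient_key, adr_pt)]
  }
  pairs[, RRR := data.table::fifelse(N == 0, 0, N / E)]
  pairs[, p := .yates_p_vec(N, R, C, T_all)]
  pairs[, q := holm_adjust(p)]
  pairs[, passes_filter := N >= min_n & q < q_max & RRR > rrr_min]
  data.table::setorder(pairs, ingredient_key, adr_pt)
  pairs[, list(ingredient_key, adr_pt, N, E, RRR, p, q, passes_filter)]
}

#' Default age-band by sex strata
#'
#' Age bands `<18, 18-44, 45-64, 65+, missing` crossed with sex
#' `M, F, unknown`.
#' @return a `strata_spec` list with `age_breaks` and `use_sex`.
#' @export
default_strata <- function() {
  list(age_breaks = c(18, 45, 65), use_sex = TRUE)
}

.stratum_of <- function(reports, strata_spec) {
  ageb <- findInterval(reports$age, strata_spec$age_breaks)
  ageb[is.na(reports$age)] <- -1L
  if (isTRUE(strata_spec$use_sex)) paste(ageb, reports$sex, sep = "/")
  else as.character(ageb)
}

#' Stratified expected count
#'
#' `E_strat = sum_s R_s * C_s / T_s` over the strata of `strata_spec`
#' (default: age bands crossed with sex), the expected number of reports of
#' the pair if drug and event were independent conditional on stratum.
#' Strata with `T_s = 0` contribute 0.
#'
#' @param corpus a mapped, normalized `faers_corpus`.
#' @param ingredient ingredient key.
#' @param adr preferred term.
#' @param strata_spec list with `age_breaks` (ascending numeric) and
#'   `use_sex` (logical); see [default_strata()].
#' @param role_filter drug roles counting as exposure.
#' @return non-negative number; equals the unstratified `E` when the corpus
#'   has a single stratum.
#' @export
stratified_expected <- function(corpus, ingredient, adr,
                                strata_spec = default_strata(),
                                role_filter = "PS") {
  ingredient_key <- adr_pt <- NULL
  strata <- .stratum_of(corpus$reports, strata_spec)
  names(strata) <- corpus$reports$report_id
  dr <- .drug_reports(corpus, role_filter)[ingredient_key == ingredient]
  ar <- .adr_reports(corpus)[adr_pt == adr]
  Ts <- table(strata)
  Rs <- table(factor(strata[dr$report_id], levels = names(Ts)))
  Cs <- table(factor(strata[ar$report_id], levels = names(Ts)))
  sum(ifelse(Ts == 0, 0, as.numeric(Rs) * as.numeric(Cs) / as.numeric(Ts)))
}

# ---------------------------------------------------------------------------
# gamma-Poisson empirical Bayes (two-component gamma mixture prior)

#' Construct an empirical-Bayes prior
#'
#' Two-component gamma mixture on the true reporting ratio lambda:
#' `lambda ~ w * Gamma(alpha1, beta1) + (1 - w) * Gamma(alpha2, beta2)`
#' (shape/rate), with `N | lambda ~ Poisson(lambda * E)`.
#'
#' @param w mixture weight in \[0, 1\].
#' @param alpha1,beta1,alpha2,beta2 positive shape/rate parameters.
#' @param loglik optional marginal log-likelihood achieved during fitting.
#' @return an `eb_prior` list.
#' @export
eb_prior <- function(w, alpha1, beta1, alpha2, beta2, loglik = NA_real_) {
  stopifnot(w >= 0, w <= 1, alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0)
  structure(list(w = w, alpha1 = alpha1, beta1 = beta1,
                 alpha2 = alpha2, beta2 = beta2, loglik = loglik),
            class = "eb_prior")
}

#' @export
print.eb_prior <- function(x, ...) {
  cat(sprintf(paste0("<eb_prior> w = %.3f, Gamma(%.3g, %.3g) / ",
                     "Gamma(%.3g, %.3g), loglik = %.2f\n"),
              x$w, x$alpha1, x$beta1, x$alpha2, x$beta2, x$loglik))
  invisible(x)
}

# marginal log-likelihood: mixture of negative-binomial marginals
.eb_marginal_loglik <- function(par, N, E) {
  w <- stats::plogis(par[1])
  a1 <- exp(par[2]); b1 <- exp(par[3])
  a2 <- exp(par[4]); b2 <- exp(par[5])
  l1 <- stats::dnbinom(N, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- stats::dnbinom(N, size = a2, prob = b2 / (b2 + E), log = TRUE)
  hi <- pmax(l1, l2)
  ll <- hi + log(w * exp(l1 - hi) + (1 - w) * exp(l2 - hi))
  -sum(ll)
}

#' Fit the empirical-Bayes prior to an array of (N, E) pairs
#'
#' Maximizes the marginal likelihood of the two-component gamma-Poisson
#' mixture (negative-binomial marginals) by L-BFGS-B on transformed
#' parameters, from `n_starts` seeded multi-starts; parameters are bounded
#' to `[1e-4, 1e4]`.  Deterministic given the pairs and `seed`.
#'
#' @param N,E equal-length vectors of observed and expected counts; pairs
#'   with `E <= 0` are dropped; at least 50 usable pairs required.
#' @param n_starts number of optimizer starts (>= 5 recommended).
#' @param seed integer seed governing start-point jitter.
#' @return an [eb_prior()] with the achieved `loglik`.
#' @export
fit_eb_prior <- function(N, E, n_starts = 5, seed = 1L) {
  keep <- is.finite(N) & is.finite(E) & E > 0
  N <- N[keep]; E <- E[keep]
  if (length(N) < 50)
    stop("need at least 50 pairs with E > 0 to fit the prior")
  bl <- log(1e-4); bu <- log(1e4)
  starts <- list(c(2, log(2), log(2), log(2), log(0.2)),
                 c(0, log(1), log(1), log(1), log(0.1)),
                 c(-1, log(0.5), log(0.5), log(2), log(2)),
                 c(1, log(5), log(5), log(0.5), log(0.05)),
                 c(0, log(0.2), log(0.2), log(10), log(10)))
  .run_seeded(seed, {
    extra <- max(0, n_starts - length(starts))
    if (extra > 0)
      starts <- c(starts, lapply(seq_len(extra), function(i)
        c(stats::rnorm(1), stats::runif(4, bl / 2, bu / 2))))
    starts <- lapply(starts[seq_len(max(n_starts, length(starts)))],
                     function(s) s + c(0, stats::rnorm(4, sd = 0.01)))
    fits <- lapply(starts, function(s) {
      tryCatch(stats::optim(s, .eb_marginal_loglik, N = N, E = E,
                            method = "L-BFGS-B",
                            lower = c(-10, rep(bl, 4)),
                            upper = c(10, rep(bu, 4)),
                            control = list(maxit = 500)),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits))
      stop("empirical-Bayes prior fit failed to converge from any start")
    best <- fits[[which.min(vapply(fits, function(f) f$value, 0))]]
    p <- best$par
    eb_prior(w = stats::plogis(p[1]), alpha1 = exp(p[2]), beta1 = exp(p[3]),
             alpha2 = exp(p[4]), beta2 = exp(p[5]), loglik = -best$value)
  })
}

# posterior mixture parameters for one (N, E): updated gammas and weights
.eb_posterior <- function(N, E, prior) {
  l1 <- stats::dnbinom(N, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- stats::dnbinom(N, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  lw1 <- log(prior$w) + l1
  lw2 <- log1p(-prior$w) + l2
  hi <- max(lw1, lw2)
  q1 <- exp(lw1 - hi) / (exp(lw1 - hi) + exp(lw2 - hi))
  list(q1 = q1,
       a = c(prior$alpha1 + N, prior$alpha2 + N),
       b = c(prior$beta1 + E, prior$beta2 + E))
}

#' Empirical-Bayes shrinkage scores for one pair
#'
#' The posterior of lambda given `(N, E)` is again a two-gamma mixture with
#' updated parameters `(alpha_k + N, beta_k + E)` and weights proportional
#' to the component marginal likelihoods.  `EBGM = exp(E[log lambda])`;
#' `EB05`/`EB95` are the 5th/95th posterior percentiles found by root
#' finding on the mixture CDF (tolerance 1e-8).
#'
#' @param N,E observed and expected counts (`E > 0`).
#' @param prior an [eb_prior()].
#' @return named numeric vector `c(EBGM, EB05, EB95)`.
#' @export
eb_scores <- function(N, E, prior) {
  stopifnot(inherits(prior, "eb_prior"))
  if (length(N) > 1L) {
    out <- t(mapply(eb_scores, N, E, MoreArgs = list(prior = prior)))
    colnames(out) <- c("EBGM", "EB05", "EB95")
    return(out)
  }
  if (!is.finite(E) || E <= 0)
    stop("eb_scores undefined for E <= 0")
  po <- .eb_posterior(N, E, prior)
  wts <- c(po$q1, 1 - po$q1)
  ebgm <- exp(sum(wts * (digamma(po$a) - log(po$b))))
  cdf <- function(x) sum(wts * stats::pgamma(x, shape = po$a, rate = po$b))
  qtile <- function(prob) {
    # bracket the quantile around the component quantiles
    guess <- stats::qgamma(prob, shape = po$a, rate = po$b)
    lo <- min(guess) * 0.5
    hi <- max(guess) * 2 + 1e-8
    while (cdf(lo) > prob && lo > 1e-300) lo <- lo / 8
    while (cdf(hi) < prob) hi <- hi * 8
    stats::uniroot(function(x) cdf(x) - prob, lower = lo, upper = hi,
                   tol = 1e-8)$root
  }
  c(EBGM = ebgm, EB05 = qtile(0.05), EB95 = qtile(0.95))
}

#' Append EBGM/EB05/EB95 columns to a signal table
#'
#' @param signals output of [detect_signals()].
#' @param prior an [eb_prior()]; when `NULL`, fitted to the table's own
#'   (N, E) array.
#' @param seed passed to [fit_eb_prior()] when fitting here.
#' @return the signal table with `EBGM`, `EB05`, `EB95` columns.
#' @export
add_eb_scores <- function(signals, prior = NULL, seed = 1L) {
  if (is.null(prior)) prior <- fit_eb_prior(signals$N, signals$E, seed = seed)
  sc <- eb_scores(signals$N, signals$E, prior)
  out <- data.table::copy(signals)
  out[, c("EBGM", "EB05", "EB95") := list(sc[, "EBGM"], sc[, "EB05"],
                                          sc[, "EB95"])]
  out
}
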