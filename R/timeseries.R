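# Month-resolved disproportionality and clustering of ADR time-evolution
# profiles.  Each month's 2x2 tables use only that month's reports; Holm is
# applied within each month across the pairs tested that month.

.report_months <- function(corpus, date_field = "event_date") {
  d <- corpus$reports[[date_field]]
  if (identical(date_field, "event_date")) {
    # fall back to receipt_date when the event date is missing
    miss <- is.na(d)
    d[miss] <- corpus$reports$receipt_date[miss]
  }
  stats::setNames(month_label(d), corpus$reports$report_id)
}

#' Month-resolved signal table for all observed pairs
#'
#' For each month in `month_range`, report-level 2x2 tables are built from
#' that month's reports only and Holm adjustment is applied within the month
#' across all pairs with `N_t >= 1` that month.  Months with zero reports
#' are absent from the output.
#'
#' @param corpus a mapped, normalized `faers_corpus`.
#' @param month_range two `"YYYY-MM"` labels (inclusive); default spans the
#'   corpus.
#' @param role_filter drug roles counting as exposure.
#' @param date_field `"event_date"` (default; missing values fall back to
#'   `receipt_date`) or `"receipt_date"`.
#' @return data.table with columns `month`, `ingredient_key`, `adr_pt`,
#'   `N`, `E`, `RRR`, `p`, `q`.
#' @export
monthly_signal_table <- function(corpus, month_range = NULL,
                                 role_filter = "PS",
                                 date_field = "event_date") {
  month <- N <- E <- RRR <- p <- q <- NULL
  months_of <- .report_months(corpus, date_field)
  if (is.null(month_range)) month_range <- range(months_of)
  if (!length(month_range) || month_range[1] > month_range[2])
    stop("empty month range")
  months <- month_seq(month_range[1], month_range[2])
  keep <- names(months_of)[months_of %in% months]
  dr <- .drug_reports(corpus, role_filter)
  ar <- .adr_reports(corpus)
  dr <- dr[dr$report_id %in% keep]
  ar <- ar[ar$report_id %in% keep]
  dr$month <- months_of[dr$report_id]
  ar$month <- months_of[ar$report_id]
  T_m <- table(months_of[keep])
  pairs <- merge(dr, ar, by = c("report_id", "month"),
                 allow.cartesian = TRUE)[
    , list(N = as.numeric(.N)), by = c("month", "ingredient_key", "adr_pt")]
  Rm <- dr[, list(R = as.numeric(.N)), by = c("month", "ingredient_key")]
  Cm <- ar[, list(C = as.numeric(.N)), by = c("month", "adr_pt")]
  out <- merge(merge(pairs, Rm, by = c("month", "ingredient_key")),
               Cm, by = c("month", "adr_pt"))
  out[, Tm := as.numeric(T_m[month])]
  out[, E := R * C / Tm]
  out[, RRR := N / E]
  out[, p := .yates_p_vec(N, R, C, Tm)]
  out[, q := holm_adjust(p), by = "month"]
  data.table::setorder(out, month, ingredient_key, adr_pt)
  out[, list(month, ingredient_key, adr_pt, N, E, RRR, p, q)]
}

#' Monthly series for one ingredient-ADR pair
#'
#' Extracts the month-indexed `N/E/RRR/q` vectors of one pair from the
#' within-month analysis.  Months inside the range with zero reports overall
#' yield `NA` (missing, not zero); months with data but no report of the
#' pair yield `N = 0`, `RRR = 0`, `q = 1`.
#'
#' @param corpus a mapped, normalized `faers_corpus`.
#' @param pair list or vector: `(ingredient_key, adr_pt)`.
#' @param month_range two `"YYYY-MM"` labels; default spans the corpus.
#' @param role_filter,date_field see [monthly_signal_table()].
#' @return a `monthly_series` list: `pair`, `months`, `N_t`, `E_t`, `RRR_t`,
#'   `q_t`, `n_sig_months`, `n_nonsig_months`.
#' @export
monthly_signals <- function(corpus, pair, month_range = NULL,
                            role_filter = "PS", date_field = "event_date") {
  ingredient_key <- adr_pt <- NULL
  months_of <- .report_months(corpus, date_field)
  if (is.null(month_range)) month_range <- range(months_of)
  tab <- monthly_signal_table(corpus, month_range = month_range,
                              role_filter = role_filter,
                              date_field = date_field)
  months <- month_seq(month_range[1], month_range[2])
  has_data <- months %in% months_of
  sel <- tab[ingredient_key == pair[[1]] & adr_pt == pair[[2]]]
  i <- match(months, sel$month)
  N_t <- ifelse(has_data, 0, NA_real_)
  RRR_t <- ifelse(has_data, 0, NA_real_)
  q_t <- ifelse(has_data, 1, NA_real_)
  E_t <- ifelse(has_data, 0, NA_real_)
  hit <- !is.na(i)
  N_t[hit] <- sel$N[i[hit]]
  E_t[hit] <- sel$E[i[hit]]
  RRR_t[hit] <- sel$RRR[i[hit]]
  q_t[hit] <- sel$q[i[hit]]
  structure(list(pair = c(ingredient_key = pair[[1]], adr_pt = pair[[2]]),
                 months = months, N_t = N_t, E_t = E_t, RRR_t = RRR_t,
                 q_t = q_t,
                 n_sig_months = sum(q_t < 0.05, na.rm = TRUE),
                 n_nonsig_months = sum(q_t >= 0.05, na.rm = TRUE)),
            class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  cat("<monthly_series> ", x$pair[["ingredient_key"]], " ~ ",
      x$pair[["adr_pt"]], ": ", length(x$months), " months, ",
      x$n_sig_months, " significant\n", sep = "")
  invisible(x)
}

#' Per-month ADR composition of one ingredient
#'
#' For every month, the fraction of the ingredient's primary-suspect ADR
#' mentions attributed to each preferred term; fractions sum to 1 within
#' each month that has data.
#'
#' @param corpus a mapped, normalized `faers_corpus`.
#' @param ingredient ingredient key.
#' @param date_field see [monthly_signal_table()].
#' @return data.table with columns `month`, `adr_pt`, `n`, `fraction`.
#' @export
monthly_fraction_profile <- function(corpus, ingredient,
                                     date_field = "event_date") {
  ingredient_key <- fraction <- n <- month <- adr_pt <- NULL
  months_of <- .report_months(corpus, date_field)
  dr <- .drug_reports(corpus, "PS")[ingredient_key == ingredient]
  ar <- corpus$reactions[!is.na(corpus$reactions$pt),
                         list(report_id, adr_pt = pt)]
  mentions <- merge(dr[, list(report_id)], ar, by = "report_id")
  if (!nrow(mentions))
    return(data.table::data.table(month = character(), adr_pt = character(),
                                  n = integer(), fraction = numeric()))
  mentions$month <- months_of[mentions$report_id]
  out <- mentions[, list(n = .N), by = c("month", "adr_pt")]
  out[, fraction := n / sum(n), by = "month"]
  data.table::setorder(out, month, adr_pt)
  out[]
}

# ---------------------------------------------------------------------------
# k-medoids clustering of RRR trajectories under 1 - Pearson correlation

#' Correlation distance matrix between trajectory rows
#'
#' `d = 1 - r` with Pearson `r` across columns.  Rows with zero variance
#' cannot be correlated; by convention their correlation with anything is 0
#' (distance 1, distance 0 to themselves) and they are flagged.
#'
#' @param series_matrix numeric matrix, rows = per-ADR monthly RRR vectors
#'   (impute missing months as 0 beforehand).
#' @return list with `d` (distance matrix) and `flagged` (zero-variance row
#'   indices).
#' @export
trajectory_distance <- function(series_matrix) {
  m <- as.matrix(series_matrix)
  if (anyNA(m)) stop("impute missing months (as 0) before clustering")
  sds <- apply(m, 1, stats::sd)
  flagged <- as.integer(which(sds == 0))
  r <- suppressWarnings(stats::cor(t(m)))
  r[!is.finite(r)] <- 0
  d <- 1 - r
  diag(d) <- 0
  list(d = d, flagged = flagged)
}

# total cost of a medoid set: sum over rows of min distance to a medoid
.kmed_cost <- function(d, medoids) {
  sum(apply(d[, medoids, drop = FALSE], 1, min))
}

#' Cluster ADR trajectories by k-medoids on correlation distance
#'
#' Partitions per-ADR monthly RRR trajectories into `k` groups under
#' `d = 1 - Pearson r`.  Initial medoids follow the maximum-dissimilarity
#' build heuristic (first medoid: row with the largest total distance; each
#' next: the row maximizing its minimum distance to the chosen medoids),
#' then medoid swaps are iterated to convergence.  Because single-swap
#' descent can stall in a local optimum, the build-and-swap cycle is
#' restarted from every row as the alternative first medoid (cheap at these
#' instance sizes) and the best final objective wins.  Deterministic; ties
#' break toward the lowest row index.
#'
#' @param series_matrix numeric matrix (rows = trajectories, `>= k` rows);
#'   missing months must be imputed (conventionally as 0) beforehand.
#' @param k number of clusters, `2 <= k <= nrow`.
#' @return list with `clusters` (integer assignment per row, named by row
#'   names), `medoids` (row indices), `objective` (total within-cluster
#'   distance to medoid) and `flagged` (zero-variance rows).
#' @export
cluster_trajectories <- function(series_matrix, k) {
  m <- as.matrix(series_matrix)
  n <- nrow(m)
  stopifnot(k >= 2, k <= n)
  td <- trajectory_distance(m)
  d <- td$d
  build <- function(first) {
    medoids <- first
    while (length(medoids) < k) {
      mind <- apply(d[, medoids, drop = FALSE], 1, min)
      mind[medoids] <- -Inf
      medoids <- c(medoids, which.max(mind))
    }
    medoids
  }
  swap <- function(medoids) {
    # accept the best improving (medoid, candidate) swap until convergence
    repeat {
      best <- list(gain = 0)
      cost0 <- .kmed_cost(d, medoids)
      for (mi in seq_along(medoids)) {
        for (cand in setdiff(seq_len(n), medoids)) {
          trial <- medoids
          trial[mi] <- cand
          gain <- cost0 - .kmed_cost(d, trial)
          if (gain > best$gain + 1e-12)
            best <- list(gain = gain, trial = trial)
        }
      }
      if (best$gain <= 0) break
      medoids <- best$trial
    }
    medoids
  }
  # exhaustive restarts only where they are cheap; large instances keep the
  # single maximum-dissimilarity start
  starts <- if (n <= 30) unique(c(which.max(rowSums(d)), seq_len(n)))
            else which.max(rowSums(d))
  best_medoids <- NULL
  best_cost <- Inf
  for (s in starts) {
    cand <- swap(build(s))
    cost <- .kmed_cost(d, cand)
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best_medoids <- cand
    }
  }
  medoids <- sort(best_medoids)
  assign <- apply(d[, medoids, drop = FALSE], 1, which.min)
  names(assign) <- rownames(m)
  list(clusters = assign, medoids = medoids,
       objective = .kmed_cost(d, medoids), flagged = td$flagged)
}
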