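test_that("contingency tables, E and RRR have the stated arithmetic", {
  ct <- contingency_table(n11 = 20, row_total = 100, col_total = 50,
                          grand_total = 1000)
  expect_equal(expected_count(ct), 5)
  expect_equal(rrr(ct), 4)
  expect_equal(rrr(contingency_table(5, 50, 100, 1000)), 1)
  expect_equal(rrr(contingency_table(0, 10, 10, 100)), 0)
  expect_error(contingency_table(20, 10, 50, 1000))   # n11 > R
  expect_error(contingency_table(0, 990, 990, 1000))  # n22 < 0
})

test_that("build_contingency counts report-level with role filtering", {
  co <- fixture_quarter_corpus()
  tab <- read_synonym_table(system.file("extdata/synonyms.tsv",
                                        package = "faerstools"))
  voc <- read_meddra_vocabulary(system.file("extdata/vocabulary.txt",
                                            package = "faerstools"))
  expect_error(build_contingency(co, "x", "y"), "map_corpus")
  co <- normalize_corpus(map_corpus(co, tab)$corpus, voc)$corpus
  flx <- "RTHCYVBBDHJXIQ-UHFFFAOYSA-N"
  asp <- "BSYNRYMUTXBXSQ-UHFFFAOYSA-N"
  ct <- build_contingency(co, flx, "Nausea")
  expect_equal(ct$n11, 1); expect_equal(ct$row_total, 3)
  expect_equal(ct$col_total, 1); expect_equal(ct$grand_total, 3)
  # aspirin appears only as concomitant: absent under the PS default
  ct2 <- build_contingency(co, asp, "Nausea")
  expect_equal(ct2$row_total, 0); expect_equal(ct2$n11, 0)
  ct3 <- build_contingency(co, asp, "Nausea", role_filter = c("PS", "C"))
  expect_equal(ct3$row_total, 1); expect_equal(ct3$n11, 1)
  # absent ingredient
  ct4 <- build_contingency(co, "NOKEY", "Nausea")
  expect_equal(ct4$row_total, 0)
})

test_that("Yates chi-square p matches the textbook oracle to 1e-10", {
  p <- yates_chi2_p(contingency_table(20, 100, 50, 1000))
  expect_equal(as.numeric(p), oracle_yates_p(20, 100, 50, 1000),
               tolerance = 1e-12)
  # perfectly proportional table: correction clamps to 0, p = 1
  expect_equal(as.numeric(yates_chi2_p(contingency_table(5, 100, 50, 1000))),
               1)
  # degenerate margins flagged with p = 1
  pd <- yates_chi2_p(contingency_table(0, 0, 50, 1000))
  expect_equal(as.numeric(pd), 1)
  expect_true(attr(pd, "degenerate"))
  set.seed(31)
  tabs <- random_tables(2000)
  for (i in sample(nrow(tabs), 400)) {
    with(tabs[i, ], {
      mine <- as.numeric(yates_chi2_p(contingency_table(n11, R, C, T)))
      expect_equal(mine, oracle_yates_p(n11, R, C, T), tolerance = 1e-10)
      # invariant under transposing the margins
      expect_equal(mine,
                   as.numeric(yates_chi2_p(contingency_table(n11, C, R, T))),
                   tolerance = 1e-12)
    })
  }
  # agreement with stats::chisq.test on non-degenerate tables
  m <- matrix(c(20, 80, 30, 870), 2, byrow = TRUE)
  expect_equal(as.numeric(yates_chi2_p(contingency_table(20, 100, 50, 1000))),
               stats::chisq.test(m, correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("holm_adjust matches hand values and the step-down oracle", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(holm_adjust(numeric()), numeric())
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(37)
  for (i in 1:40) {
    p <- stats::runif(sample(1:200, 1))^sample(1:3, 1)
    q <- holm_adjust(p)
    expect_equal(q, oracle_holm(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, method = "holm"), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
})

test_that("detect_signals applies the three-part filter over the full family", {
  prep <- prepared_corpus(power_config(n_reports = 30000, seed = 41))
  sig <- detect_signals(prep$corpus)
  tp <- prep$truth$planted_associations[[1]]
  sel <- sig[sig$ingredient_key == tp$ingredient_key &
               sig$adr_pt == tp$adr_pt]
  expect_true(sel$passes_filter)
  expect_true(all(sig$q >= sig$p))
  expect_true(all(sig$q <= 1))
  # filter thresholds are conjunctive: N >= 5 required regardless of q
  tiny <- sig[sig$N == 4]
  if (nrow(tiny)) expect_false(any(tiny$passes_filter))
  expect_false(any(sig[sig$RRR <= 1]$passes_filter))
  # permutation invariance to report order
  co <- prep$corpus
  perm <- sample(nrow(co$reports))
  co$reports <- co$reports[perm]
  sig2 <- detect_signals(co)
  expect_equal(as.data.frame(sig2), as.data.frame(sig), ignore_attr = TRUE)
  # empty corpus -> empty table
  expect_equal(nrow(detect_signals(subset_corpus(prep$corpus, character()))),
               0L)
})

test_that("single-pair corpus with N = 4 fails on min_n regardless of q", {
  rows <- lapply(1:50, function(i)
    list(id = sprintf("s%02d", i), drugs = if (i <= 4) "KD" else "KX",
         reacs = if (i <= 4) "PD" else paste0("PX", i %% 7),
         date = "2004-01-01", age = 40, sex = "M"))
  co <- make_small_corpus(rows)
  sig <- detect_signals(co)
  sel <- sig[sig$ingredient_key == "KD" & sig$adr_pt == "PD"]
  expect_equal(sel$N, 4)
  expect_false(sel$passes_filter)
})

test_that("monotonicity: increasing n11 at fixed margins raises RRR, lowers p", {
  R <- 80; C <- 120; T <- 2000
  n11 <- 5:60
  rrrs <- vapply(n11, function(n) rrr(contingency_table(n, R, C, T)), 0)
  expect_true(all(diff(rrrs) >= 0))
  n_dec <- (ceiling(R * C / T) + 1):60      # above E: p strictly falls
  ps <- vapply(n_dec, function(n)
    as.numeric(yates_chi2_p(contingency_table(n, R, C, T))), 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("stratified_expected reduces, detects confounding, conserves strata", {
  rows <- c(lapply(1:40, function(i)
    list(id = sprintf("y%03d", i), drugs = "KD", reacs = "POther",
         date = "2004-01-01", age = 30, sex = "M")),
    lapply(41:80, function(i)
      list(id = sprintf("y%03d", i), drugs = "KX", reacs = "PA",
           date = "2004-01-01", age = 70, sex = "F")))
  co <- make_small_corpus(rows)
  # drug KD only in young men, ADR PA only in old women: E_strat = 0 < E
  e_pooled <- expected_count(build_contingency(co, "KD", "PA"))
  e_strat <- stratified_expected(co, "KD", "PA")
  expect_gt(e_pooled, 0)
  expect_equal(e_strat, 0)
  # single stratum: equals unstratified E
  rows2 <- lapply(1:30, function(i)
    list(id = sprintf("z%02d", i), drugs = sample(c("K1", "K2"), 1),
         reacs = sample(c("P1", "P2"), 1), date = "2004-01-01",
         age = 40, sex = "M"))
  set.seed(43); co2 <- make_small_corpus(rows2)
  expect_equal(stratified_expected(co2, "K1", "P1"),
               expected_count(build_contingency(co2, "K1", "P1")))
  # strata partition the corpus
  strata <- faerstools:::.stratum_of(co$reports, default_strata())
  expect_equal(length(strata), n_reports(co))
})

test_that("eb_scores order correctly, shrink, and concentrate at large N", {
  prior <- eb_prior(w = 0.9, alpha1 = 2, beta1 = 2, alpha2 = 2, beta2 = 0.2)
  set.seed(47)
  for (i in 1:30) {
    N <- sample(0:200, 1); E <- stats::runif(1, 0.1, 50)
    sc <- eb_scores(N, E, prior)
    expect_lt(sc[["EB05"]], sc[["EBGM"]] + 1e-9)
    expect_lt(sc[["EBGM"]], sc[["EB95"]] + 1e-9)
  }
  # N/E = 10 with an informative prior centered at 1: strict shrinkage
  informative <- eb_prior(w = 1, alpha1 = 50, beta1 = 50,
                          alpha2 = 2, beta2 = 2)
  sc <- eb_scores(50, 5, informative)
  expect_gt(sc[["EBGM"]], 1)
  expect_lt(sc[["EBGM"]], 10)
  # numerical-integration oracle of the posterior geometric mean
  po_mean_log <- integrate(function(x) log(x) * stats::dgamma(x, 100, 55),
                           0, Inf)$value
  expect_equal(sc[["EBGM"]], exp(po_mean_log), tolerance = 1e-6)
  # large-N limit: EBGM within 1% of N/E
  sc2 <- eb_scores(10000, 1000, prior)
  expect_equal(sc2[["EBGM"]], 10, tolerance = 0.01)
  # E = 0 undefined
  expect_error(eb_scores(3, 0, prior), "E <= 0")
})

test_that("fit_eb_prior recovers a known prior in marginal likelihood", {
  set.seed(53)
  true <- eb_prior(w = 0.9, alpha1 = 2, beta1 = 2, alpha2 = 2, beta2 = 0.2)
  n <- 5000
  comp <- stats::runif(n) < true$w
  lam <- ifelse(comp, stats::rgamma(n, true$alpha1, true$beta1),
                stats::rgamma(n, true$alpha2, true$beta2))
  E <- stats::runif(n, 0.5, 20)
  N <- stats::rpois(n, lam * E)
  fit <- fit_eb_prior(N, E, seed = 7)
  ll <- function(pr) -faerstools:::.eb_marginal_loglik(
    c(stats::qlogis(pr$w), log(pr$alpha1), log(pr$beta1),
      log(pr$alpha2), log(pr$beta2)), N, E)
  expect_gte(fit$loglik, ll(true) - 1)
  # deterministic given pairs + seed
  fit2 <- fit_eb_prior(N, E, seed = 7)
  expect_equal(fit$loglik, fit2$loglik)
  expect_equal(fit$w, fit2$w)
  # all-zero data pushes the prior mean toward 0
  fit0 <- fit_eb_prior(rep(0, 200), rep(5, 200), seed = 7)
  prior_mean <- fit0$w * fit0$alpha1 / fit0$beta1 +
    (1 - fit0$w) * fit0$alpha2 / fit0$beta2
  expect_lt(prior_mean, 0.5)
  # too few pairs errors
  expect_error(fit_eb_prior(1:10, rep(1, 10)), "at least 50")
})

test_that("EBGM dominates the raw ratio in RMSE on gamma-Poisson pairs", {
  set.seed(59)
  true <- eb_prior(w = 0.85, alpha1 = 3, beta1 = 3, alpha2 = 1.5,
                   beta2 = 0.3)
  n <- 1000
  comp <- stats::runif(n) < true$w
  lam <- ifelse(comp, stats::rgamma(n, true$alpha1, true$beta1),
                stats::rgamma(n, true$alpha2, true$beta2))
  E <- stats::runif(n, 0.2, 10)
  N <- stats::rpois(n, lam * E)
  fit <- fit_eb_prior(N, E, seed = 11)
  sc <- eb_scores(N, E, fit)
  rmse_eb <- sqrt(mean((sc[, "EBGM"] - lam)^2))
  rmse_raw <- sqrt(mean((N / E - lam)^2))
  expect_lte(rmse_eb, rmse_raw)
})
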