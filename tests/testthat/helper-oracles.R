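# Independent oracles used to cross-check package statistics.  Each is a
# deliberately naive implementation kept free of package internals.

# textbook Yates-corrected chi-square p for a 2x2 given (n11, R, C, T)
oracle_yates_p <- function(n11, R, C, T) {
  m <- matrix(c(n11, R - n11, C - n11, T - R - C + n11), nrow = 2)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(e == 0)) return(1)
  stat <- sum((pmax(abs(m - e) - 0.5, 0))^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# step-down Holm coded directly from the definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    q[o[i]] <- running
  }
  q
}

# dynamic-programming Levenshtein distance
oracle_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  na <- length(a); nb <- length(b)
  d <- matrix(0, na + 1, nb + 1)
  d[, 1] <- 0:na; d[1, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                           d[i, j] + (a[i] != b[j]))
  d[na + 1, nb + 1]
}

# exhaustive k-medoids optimum for small instances
oracle_kmedoids_best <- function(d, k) {
  n <- nrow(d)
  combos <- utils::combn(n, k)
  best <- Inf
  for (j in seq_len(ncol(combos))) {
    cost <- sum(apply(d[, combos[, j], drop = FALSE], 1, min))
    best <- min(best, cost)
  }
  best
}

# logistic MLE by generic second-order optimization (BFGS on the deviance)
oracle_logistic_mle <- function(y, X) {
  nll <- function(beta) {
    eta <- as.vector(X %*% beta)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(beta) {
    eta <- as.vector(X %*% beta)
    as.vector(t(X) %*% (stats::plogis(eta) - y))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit$par
}

# adjusted Rand index between two partitions
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# random contingency tables with valid margins
random_tables <- function(n, max_T = 5000) {
  T <- sample(4:max_T, n, replace = TRUE)
  R <- vapply(T, function(t) sample.int(t, 1), 0L)
  C <- vapply(T, function(t) sample.int(t, 1), 0L)
  lo <- pmax(0, R + C - T)
  hi <- pmin(R, C)
  n11 <- lo + floor(stats::runif(n) * (hi - lo + 1))
  data.frame(n11 = n11, R = R, C = C, T = T)
}
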