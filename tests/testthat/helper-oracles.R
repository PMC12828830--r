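# Independent oracles used across the suite. Each is a deliberately naive
# implementation (brute force / enumeration / explicit loop), kept separate
# from the package's own code paths.

# Benjamini-Hochberg step-up by direct definition: sort, take the running
# minimum of p_(i) * m / i from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  cur <- 1
  for (i in m:1) {
    cur <- min(cur, ps[i] * m / i)
    adj[i] <- min(cur, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# AUC by brute force over all case-control pairs, ties counted 1/2
auc_brute <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls)
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  s / (length(cases) * length(controls))
}

# AUC as the trapezoidal integral of the empirical ROC curve
auc_trapezoid <- function(score, is_case) {
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(score[is_case] >= t), 0), 1)
  fpr <- c(0, vapply(th, function(t) mean(score[!is_case] >= t), 0), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# GSEA-style running sum by explicit step-through
es_oracle <- function(metric, hit, p = 1) {
  n <- length(metric)
  nh <- sum(hit)
  w <- abs(metric)^p
  denom <- sum(w[hit])
  rs <- 0; hi <- -Inf; lo <- Inf
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) {
      if (denom == 0) 1 / nh else w[i] / denom
    } else -1 / (n - nh)
    hi <- max(hi, rs); lo <- min(lo, rs)
  }
  if (hi >= -lo - 1e-9) hi else lo
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of probabilities of all tables (fixed margins) no more probable than
# the observed one
fisher_enum <- function(a, b, c, d) {
  m <- a + b   # row 1 total
  n <- c + d   # row 2 total
  k <- a + c   # column 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small fast configs used by several files
tiny_config <- function(seed = 11, n = 20, ...) {
  generator_config(seed = seed, n_per_group = n, samples_per_batch = 2 * n, ...)
}

null_multipliers <- c(gsl_c18 = 1, dhs_cer = 1, noncanonical_cer = 1,
                      c22 = 1, c24 = 1)
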