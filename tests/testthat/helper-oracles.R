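# Independent oracles used across the suite. These deliberately re-derive
# the statistics from first principles (loops, enumeration, closed forms)
# and never call the implementation they check.

# Literal element-by-element running sum for the weighted KS enrichment
# score: sort by value descending (ties by name), walk the list.
brute_es <- function(values, gene_set, p = 1) {
  ord <- order(-values, names(values))
  v <- values[ord]
  n <- length(v)
  hits <- names(v) %in% gene_set
  n_h <- sum(hits)
  n_r <- sum(abs(v[hits])^p)
  if (n_r == 0 && p == 0) n_r <- n_h
  run <- 0
  best <- 0
  for (j in seq_len(n)) {
    run <- run + if (hits[j]) abs(v[j])^p / n_r else -1 / (n - n_h)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Both running-sum extrema, for detecting sign-ambiguous instances where
# the maximal positive and negative deviations have equal magnitude.
brute_es_extrema <- function(values, gene_set, p = 1) {
  ord <- order(-values, names(values))
  v <- values[ord]
  n <- length(v)
  hits <- names(v) %in% gene_set
  n_h <- sum(hits)
  n_r <- sum(abs(v[hits])^p)
  if (n_r == 0 && p == 0) n_r <- n_h
  run <- 0; lo <- 0; hi <- 0
  for (j in seq_len(n)) {
    run <- run + if (hits[j]) abs(v[j])^p / n_r else -1 / (n - n_h)
    lo <- min(lo, run); hi <- max(hi, run)
  }
  c(lo = unname(lo), hi = unname(hi))
}

# Classical unweighted KS enrichment statistic (all hit increments equal),
# written independently of the weighted implementation.
unweighted_ks_es <- function(values, gene_set) {
  ord <- order(-values, names(values))
  hits <- names(values)[ord] %in% gene_set
  n <- length(values)
  n_h <- sum(hits)
  steps <- ifelse(hits, 1 / n_h, -1 / (n - n_h))
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

# Exact combinatorial enumeration of the hypergeometric upper tail.
hyper_upper_oracle <- function(N, K, n, k) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Breslow partial log-likelihood for a single binary covariate, for the
# dense-grid maximization oracle.
breslow_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t0 in sort(unique(times[events == 1]))) {
    ev <- events == 1 & times == t0
    at_risk <- times >= t0
    ll <- ll + beta * sum(x[ev]) -
      sum(ev) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Small homoscedastic two-group expression matrix with optional planted
# mean shifts (tumor group only).
sim_two_group <- function(n_genes, n1, n2, shift = NULL, sd = 1,
                          seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n1 + n2), sd = sd), n_genes, n1 + n2,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              c(sprintf("t%03d", seq_len(n1)),
                                sprintf("n%03d", seq_len(n2)))))
  if (!is.null(shift)) m[names(shift), seq_len(n1)] <-
    m[names(shift), seq_len(n1)] + shift
  m
}
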