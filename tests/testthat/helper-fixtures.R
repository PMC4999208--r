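# Shared fixture builders and independent oracles.

# Small named beta matrix from a vector (byrow), features f1.., samples s1..
beta_fixture <- function(values, nrow, ncol) {
  matrix(values, nrow = nrow, ncol = ncol, byrow = TRUE,
         dimnames = list(paste0("f", seq_len(nrow)),
                         paste0("s", seq_len(ncol))))
}

batch_fixture <- function(beta, batch_ids) {
  data.frame(sample_id = colnames(beta), batch_id = batch_ids,
             stringsAsFactors = FALSE)
}

# Independent KS oracle: exact permutation p-value by enumerating every
# split of the pooled sample, with the statistic computed from scratch via
# empirical CDFs evaluated on the pooled support.
oracle_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
}

oracle_ks_exact_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  d_obs <- oracle_ks_stat(x, y)
  splits <- utils::combn(length(pooled), nx)
  d_perm <- apply(splits, 2, function(idx)
    oracle_ks_stat(pooled[idx], pooled[-idx]))
  mean(d_perm >= d_obs - 1e-12)
}

# Independent Benjamini-Hochberg step-up: sort ascending, p_(i) * m / i,
# running minimum from the largest rank down, clip at 1, restore order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  pmin(1, adj)[order(o)]
}

# Independent Dixon ratio (one-sided max), duplicated on purpose so the
# package implementation is cross-checked, not reused.
oracle_dixon_ratio <- function(x) {
  n <- length(x)
  s <- sort(x)
  if (s[n] == s[1]) return(0)
  if (n <= 7) (s[n] - s[n - 1]) / (s[n] - s[1])
  else if (n <= 10) (s[n] - s[n - 1]) / (s[n] - s[2])
  else if (n <= 13) (s[n] - s[n - 2]) / (s[n] - s[2])
  else (s[n] - s[n - 2]) / (s[n] - s[3])
}

# Small benchmark spec used by several tests (fast but non-trivial).
small_bench_spec <- function(seed = 1, k = 3, n_features = 300,
                             n_samples = 48, n_affected = 150) {
  simulation_spec(n_features = n_features, n_samples = n_samples,
                  batch_sizes = c(8, rep(8, (n_samples - 8) / 8)),
                  n_affected = n_affected, k = k, seed = seed)
}
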