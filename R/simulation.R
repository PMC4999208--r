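# Synthetic benchmark: beta matrices with a bimodal methylation landscape,
# correlated (co-methylation / sample-level) structure and a gold-standard
# batch-effect injection of k standard deviations plus noise.

#' Specification of a synthetic beta-value data set
#'
#' The generator emulates genome-scale methylation data: per-feature
#' baseline means drawn from a two-mode (unmethylated ~0.1 / methylated
#' ~0.8) distribution, a low-dimensional latent structure shared across
#' samples (co-methylated feature groups and sample-level effects, the
#' "neighbor information" matrix completion relies on), and independent
#' per-entry noise. Per-feature total standard deviation is
#' `sqrt(sd_structured^2 + sd_noise^2)`.
#'
#' Defaults mirror a scaled-down version of the benchmark this package is
#' validated on: 2000 features, 96 samples in 13 batches (a 10-sample
#' batch that will receive the injected effect, the rest of roughly equal
#' size), 1000 affected features.
#'
#' @param n_features,n_samples matrix dimensions.
#' @param batch_sizes integer vector of batch sizes summing to
#'   `n_samples`; default: first batch 10 samples, remainder split evenly.
#' @param affected_batch batch id receiving the injected effect (default
#'   the first batch).
#' @param n_affected number of features to shift (default 1000).
#' @param k shift magnitude in multiples of the per-feature SD.
#' @param noise_sd SD of the additive noise term of the injection
#'   (beta units, default 0.01).
#' @param mode_means,mode_sds,mode_weight two-mode baseline distribution
#'   of per-feature means (weight = probability of the unmethylated mode).
#' @param n_factors number of latent structure factors (default 12).
#' @param sd_structured_range,sd_noise_range ranges from which per-feature
#'   structured and independent SDs are drawn uniformly.
#' @param baseline_means,sd_structured,sd_noise optional explicit
#'   per-feature vectors overriding the draws above.
#' @param seed master seed.
#' @return object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_features = 2000, n_samples = 96,
                            batch_sizes = NULL, affected_batch = NULL,
                            n_affected = 1000, k = 2, noise_sd = 0.01,
                            mode_means = c(0.1, 0.8), mode_sds = c(0.05, 0.05),
                            mode_weight = 0.5, n_factors = 12,
                            sd_structured_range = c(0.025, 0.05),
                            sd_noise_range = c(0.012, 0.022),
                            baseline_means = NULL, sd_structured = NULL,
                            sd_noise = NULL, seed = 1L) {
  if (is.null(batch_sizes)) {
    rest <- n_samples - 10L
    n_other <- max(1L, round(rest / 7))
    base <- rest %/% n_other
    batch_sizes <- c(10L, rep(base, n_other))
    extra <- rest - base * n_other
    if (extra > 0) batch_sizes[1L + seq_len(extra)] <- batch_sizes[1L + seq_len(extra)] + 1L
  }
  if (sum(batch_sizes) != n_samples)
    stopf("batch_sizes must sum to n_samples (%d != %d)", sum(batch_sizes), n_samples)
  if (any(batch_sizes < 1L)) stopf("batch sizes must be >= 1")
  if (length(batch_sizes) < 2L) stopf("need at least 2 batches")
  if (n_affected < 0 || n_affected > n_features)
    stopf("n_affected must lie in [0, n_features]")
  if (k < 0) stopf("k must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  batch_ids <- sprintf("B%02d", seq_along(batch_sizes))
  spec <- list(n_features = as.integer(n_features),
               n_samples = as.integer(n_samples),
               batch_sizes = as.integer(batch_sizes),
               batch_ids = batch_ids,
               affected_batch = affected_batch %||% batch_ids[1L],
               n_affected = as.integer(n_affected),
               k = k, noise_sd = noise_sd,
               mode_means = mode_means, mode_sds = mode_sds,
               mode_weight = mode_weight,
               n_factors = as.integer(n_factors),
               sd_structured_range = sd_structured_range,
               sd_noise_range = sd_noise_range,
               baseline_means = baseline_means,
               sd_structured = sd_structured,
               sd_noise = sd_noise,
               seed = as.integer(seed))
  if (!spec$affected_batch %in% batch_ids) stopf("affected_batch not among batch ids")
  structure(spec, class = "simulation_spec")
}

#' Simulate a pristine beta-value matrix with batch structure
#'
#' Draws per-feature baselines and SDs per the spec, builds the latent
#' structure and clips all values to \[0, 1\]. No batch effect is
#' injected here; batches merely group the samples. Fully deterministic
#' given `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return list with `beta` (matrix), `batches` (data.frame `sample_id`,
#'   `batch_id`) and the realized per-feature parameters (`means`,
#'   `sd_structured`, `sd_noise`).
#' @export
simulate_beta_matrix <- function(spec) {
  if (!inherits(spec, "simulation_spec")) stopf("spec must be a simulation_spec")
  m <- spec$n_features; n <- spec$n_samples; q <- spec$n_factors
  out <- local_seed(spec$seed, {
    mu <- spec$baseline_means %||% {
      lo <- stats::runif(m) < spec$mode_weight
      mm <- ifelse(lo, stats::rnorm(m, spec$mode_means[1], spec$mode_sds[1]),
                       stats::rnorm(m, spec$mode_means[2], spec$mode_sds[2]))
      pmin(pmax(mm, 0.01), 0.99)
    }
    s_str <- spec$sd_structured %||%
      stats::runif(m, spec$sd_structured_range[1], spec$sd_structured_range[2])
    s_iid <- spec$sd_noise %||%
      stats::runif(m, spec$sd_noise_range[1], spec$sd_noise_range[2])
    vals <- mu + matrix(stats::rnorm(m * n, 0, s_iid), m, n)
    if (q > 0 && any(s_str > 0)) {
      loadings <- matrix(stats::rnorm(m * q), m, q) * (s_str / sqrt(q))
      scores <- matrix(stats::rnorm(q * n), q, n)
      vals <- vals + loadings %*% scores
    }
    list(vals = pmin(pmax(vals, 0), 1), mu = mu, s_str = s_str, s_iid = s_iid)
  })
  beta <- out$vals
  dimnames(beta) <- list(sprintf("f%05d", seq_len(m)), sprintf("s%03d", seq_len(n)))
  batches <- data.frame(sample_id = colnames(beta),
                        batch_id = rep(spec$batch_ids, spec$batch_sizes),
                        stringsAsFactors = FALSE)
  list(beta = beta, batches = batches, means = out$mu,
       sd_structured = out$s_str, sd_noise = out$s_iid)
}

#' Inject a standard-deviation-scaled batch effect
#'
#' For every affected feature g and every sample of the affected batch the
#' value is shifted by `k * s_hat_g` plus Gaussian noise, where `s_hat_g`
#' is the feature's SD estimated from the samples *outside* the affected
#' batch, and clipped to \[0, 1\]. The unmodified input is returned as the
#' gold standard together with the mask of injected entries.
#'
#' @param beta pristine beta matrix.
#' @param batches batch assignment data.frame.
#' @param affected_features character vector of feature ids to shift.
#' @param affected_batch batch id receiving the shift.
#' @param k shift in multiples of the per-feature SD (k >= 0).
#' @param noise_sd SD of the additive noise term.
#' @param seed seed for the noise draws.
#' @return list with `beta` (shifted copy), `gold` (pristine input) and
#'   `injected_mask` (logical matrix, TRUE at modified entries).
#' @export
inject_batch_effect <- function(beta, batches, affected_features,
                                affected_batch, k, noise_sd = 0.01,
                                seed = 1L) {
  validate_beta_matrix(beta)
  if (k < 0) stopf("k must be >= 0")
  col_batch <- batch_of_columns(beta, batches)
  if (!affected_batch %in% col_batch) stopf("unknown affected batch '%s'", affected_batch)
  if (!all(affected_features %in% rownames(beta)))
    stopf("affected_features contains unknown feature ids")
  cols <- which(col_batch == affected_batch)
  rows <- match(affected_features, rownames(beta))

  injected <- beta
  mask <- matrix(FALSE, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  if (k > 0 && length(rows) > 0) {
    s_hat <- apply(beta[rows, -cols, drop = FALSE], 1,
                   stats::sd, na.rm = TRUE)
    eta <- local_seed(seed,
      matrix(stats::rnorm(length(rows) * length(cols), 0, noise_sd),
             length(rows), length(cols)))
    shifted <- injected[rows, cols, drop = FALSE] + k * s_hat + eta
    injected[rows, cols] <- pmin(pmax(shifted, 0), 1)
    mask[rows, cols] <- TRUE
  }
  list(beta = injected, gold = beta, injected_mask = mask)
}

#' One-call benchmark data set
#'
#' Simulates the pristine matrix, picks the affected features at random
#' (seeded) and injects the batch effect per the spec.
#'
#' @param spec a [simulation_spec()].
#' @return list with `beta` (injected), `gold`, `injected_mask`,
#'   `batches`, `affected_features`, `affected_batch`, `spec`.
#' @export
simulate_benchmark <- function(spec) {
  sim <- simulate_beta_matrix(spec)
  aff <- local_seed(spec$seed + 1L,
                    sample(rownames(sim$beta), spec$n_affected))
  inj <- inject_batch_effect(sim$beta, sim$batches, aff, spec$affected_batch,
                             k = spec$k, noise_sd = spec$noise_sd,
                             seed = spec$seed + 2L)
  list(beta = inj$beta, gold = inj$gold, injected_mask = inj$injected_mask,
       batches = sim$batches, affected_features = aff,
       affected_batch = spec$affected_batch, spec = spec)
}

#' Total absolute deviation from the gold standard
#'
#' Sum of absolute differences between a (corrected) matrix and the gold
#' standard, over all entries or over the injected entries only.
#'
#' @param corrected candidate matrix.
#' @param gold gold-standard matrix (same shape).
#' @param scope `"all"` or `"affected_only"`.
#' @param injected_mask logical matrix of injected entries (required for
#'   `scope = "affected_only"`).
#' @return non-negative scalar.
#' @export
total_absolute_deviation <- function(corrected, gold,
                                     scope = c("all", "affected_only"),
                                     injected_mask = NULL) {
  scope <- match.arg(scope)
  if (!identical(dim(corrected), dim(gold)))
    stopf("corrected and gold matrices have different shapes")
  dev <- abs(corrected - gold)
  if (scope == "affected_only") {
    if (is.null(injected_mask)) stopf("injected_mask required for scope = 'affected_only'")
    sum(dev[injected_mask], na.rm = TRUE)
  } else {
    sum(dev, na.rm = TRUE)
  }
}

#' Count batch-affected genes remaining after correction
#'
#' Re-runs [detect_be_genes()] on a corrected matrix and counts the
#' features still flagged per batch.
#'
#' @param corrected corrected beta matrix.
#' @param batches batch assignment data.frame.
#' @param ... passed to [detect_be_genes()].
#' @return named integer vector (count per batch id).
#' @export
remaining_be_genes <- function(corrected, batches, ...) {
  tab <- detect_be_genes(corrected, batches, ...)
  counts <- tapply(tab$is_BE, tab$batch_id, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Differentially methylated features between two groups
#'
#' Calls a feature differential when the two-sample KS test between the
#' groups has p below `p_threshold` (raw p-values; the threshold follows
#' the p < 0.01 convention of KS-based differential methylation calling).
#'
#' @param beta beta matrix.
#' @param groups factor/character vector of group labels aligned with the
#'   columns of `beta` (exactly 2 levels, each with >= 2 samples).
#' @param p_threshold KS p-value threshold (default 0.01).
#' @return character vector of differential feature ids.
#' @export
differential_features <- function(beta, groups, p_threshold = 0.01) {
  validate_beta_matrix(beta)
  groups <- as.character(groups)
  if (length(groups) != ncol(beta))
    stopf("groups must have one label per sample")
  lev <- unique(groups)
  if (length(lev) != 2L) stopf("exactly two groups required")
  if (any(table(groups) < 2L)) stopf("each group needs at least 2 samples")
  g1 <- which(groups == lev[1L]); g2 <- which(groups == lev[2L])
  ps <- vapply(seq_len(nrow(beta)), function(i) {
    x <- beta[i, g1]; x <- x[!is.na(x)]
    y <- beta[i, g2]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    ks_two_sample(x, y)$p_value
  }, numeric(1))
  rownames(beta)[!is.na(ps) & ps < p_threshold]
}

#' Accuracy of differential-methylation calls against a gold set
#'
#' Computes the differential feature set of a candidate matrix
#' ([differential_features()]) and compares its membership against a gold
#' standard set over all features: accuracy = (TP + TN) / (TP + TN + FP +
#' FN).
#'
#' @param candidate candidate (e.g. corrected) beta matrix.
#' @param groups group labels, see [differential_features()].
#' @param gold_dmg_set character vector: the gold-standard differential
#'   features.
#' @param p_threshold KS p-value threshold (default 0.01).
#' @return accuracy in \[0, 1\].
#' @export
dmg_accuracy <- function(candidate, groups, gold_dmg_set, p_threshold = 0.01) {
  called <- rownames(candidate) %in%
    differential_features(candidate, groups, p_threshold)
  truth <- rownames(candidate) %in% gold_dmg_set
  mean(called == truth)
}

#' Count strongly co-methylated feature pairs
#'
#' Number of unordered feature pairs whose Pearson correlation across
#' samples exceeds `r_threshold` in absolute value (strict). Correlations
#' use pairwise-complete observations; zero-variance features are skipped.
#'
#' @param beta beta matrix (>= 3 samples).
#' @param r_threshold absolute correlation threshold (default 0.75).
#' @return integer pair count.
#' @export
comethylation_pairs <- function(beta, r_threshold = 0.75) {
  validate_beta_matrix(beta)
  if (ncol(beta) < 3L) stopf("need at least 3 samples for correlations")
  v <- apply(beta, 1, stats::var, na.rm = TRUE)
  keep <- !is.na(v) & v > 0
  if (any(!keep))
    mc_log("comethylation_pairs: skipped %d zero-variance feature(s)", sum(!keep))
  if (sum(keep) < 2L) return(0L)
  cc <- suppressWarnings(stats::cor(t(beta[keep, , drop = FALSE]),
                                    use = "pairwise.complete.obs"))
  hits <- abs(cc[upper.tri(cc)]) > r_threshold
  sum(hits, na.rm = TRUE)
}
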