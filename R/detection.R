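#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the two-sided KS statistic `D`, the supremum over t of the
#' absolute difference between the empirical CDFs of `x` and `y`, and its
#' p-value. The p-value is exact (permutation distribution of `D`, ties
#' respected) when `length(x) * length(y) <= exact_limit` and uses the
#' asymptotic Kolmogorov distribution otherwise.
#'
#' @param x,y numeric vectors of observations (length >= 1, finite).
#' @param exact_limit use the exact null distribution when
#'   `length(x) * length(y)` does not exceed this (default 10000).
#' @return list with elements `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y, exact_limit = 10000) {
  if (length(x) < 1L || length(y) < 1L)
    stopf("ks_two_sample needs at least one observation per sample")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("ks_two_sample requires finite values")
  nx <- length(x); ny <- length(y)
  w <- c(x, y)
  o <- order(w)
  ws <- w[o]
  # ECDF difference walk; at ties only the value after the full tie group counts
  z <- cumsum(ifelse(o <= nx, 1 / nx, -1 / ny))
  keep <- c(diff(ws) != 0, TRUE)
  D <- max(abs(z[keep]))
  if (nx * ny <= exact_limit) {
    p <- stats::psmirnov(D, sizes = c(nx, ny), z = ws,
                         two.sided = TRUE, lower.tail = FALSE)
  } else {
    p <- ks_asymptotic_p(D, nx, ny)
  }
  list(statistic = D, p_value = min(1, max(0, p)))
}

# Asymptotic two-sided KS p-value: P(sup|B(t)| >= lambda) by the
# alternating Kolmogorov series.
ks_asymptotic_p <- function(D, nx, ny) {
  lambda <- sqrt(nx * ny / (nx + ny)) * D
  if (lambda < 1e-8) return(1)
  k <- seq_len(101)
  2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
}

#' Absolute difference of medians between a batch and all other batches
#'
#' `mdif` is the absolute difference between the median beta-value of a
#' feature inside a batch and its median over all remaining samples.
#' Missing values are dropped before taking medians; for even counts the
#' median is the midpoint of the two central order statistics.
#'
#' @param in_batch values of the feature in the batch.
#' @param out_batch values of the feature in all other batches.
#' @return non-negative scalar.
#' @export
median_difference <- function(in_batch, out_batch) {
  in_batch <- in_batch[!is.na(in_batch)]
  out_batch <- out_batch[!is.na(out_batch)]
  if (length(in_batch) == 0L || length(out_batch) == 0L)
    stopf("median_difference: empty sample after removing missing values")
  abs(stats::median(in_batch) - stats::median(out_batch))
}

#' Multiple-testing adjustment of p-values
#'
#' Thin wrapper around [stats::p.adjust()] accepting the method names used
#' throughout this package: `"fdr"` (Benjamini-Hochberg step-up),
#' `"bonferroni"`, `"hommel"`. Output is clipped to \[0, 1\] and paired
#' with the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method adjustment method.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("fdr", "bonferroni", "hommel")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  r_method <- c(fdr = "BH", bonferroni = "bonferroni", hommel = "hommel")[[method]]
  pmin(1, pmax(0, stats::p.adjust(p, method = r_method)))
}

#' Detect batch-affected features (BE-genes)
#'
#' For every (feature, batch) pair the feature's non-missing values inside
#' the batch are compared against its pooled values in all other batches:
#' test 1 is the two-sample KS test with multiplicity adjustment of the
#' p-values, test 2 requires the absolute median difference (`mdif`) to
#' exceed `mdif_threshold`. A feature is batch-affected (BE) in a batch
#' when the adjusted p-value is below `p_threshold` *and* `mdif` is
#' strictly larger than `mdif_threshold`.
#'
#' P-values are adjusted within each batch by default (`fdr_family =
#' "per_batch"`), i.e. one family per batch of size n-features, matching
#' the per-batch definition of the BE-gene list; `"global"` adjusts across
#' all (feature, batch) tests jointly and is markedly more conservative.
#'
#' Batches with fewer than 5 samples are tested but trigger a warning:
#' with so few observations the KS test has little power and single
#' aberrant samples dominate the batch median.
#'
#' @param beta beta-value matrix (features x samples).
#' @param batches batch assignment data.frame (`sample_id`, `batch_id`).
#' @param p_threshold threshold on the adjusted p-value (default 0.01).
#' @param mdif_threshold threshold on the median difference (default 0.05,
#'   strict inequality).
#' @param method p-value adjustment method, see [adjust_pvalues()].
#' @param fdr_family `"per_batch"` (default) or `"global"` adjustment
#'   family.
#' @return data.frame (one row per feature x batch with >= 1 non-missing
#'   in-batch value) with columns `feature_id`, `batch_id`, `ks_p`,
#'   `adj_p`, `mdif`, `n_in_batch`, `is_BE`.
#' @export
detect_be_genes <- function(beta, batches, p_threshold = 0.01,
                            mdif_threshold = 0.05,
                            method = c("fdr", "bonferroni", "hommel"),
                            fdr_family = c("per_batch", "global")) {
  method <- match.arg(method)
  fdr_family <- match.arg(fdr_family)
  validate_beta_matrix(beta)
  if (nrow(beta) == 0L || ncol(beta) == 0L) stopf("beta matrix is empty")
  col_batch <- batch_of_columns(beta, batches)
  batch_ids <- unique(col_batch)
  if (length(batch_ids) < 2L) stopf("detection needs at least 2 batches")

  sizes <- table(col_batch)
  small <- names(sizes)[sizes < 5L]
  if (length(small) > 0)
    warning(sprintf("batch(es) with fewer than 5 samples: %s; KS detection has limited power below 5 samples",
                    paste(small, collapse = ", ")), call. = FALSE)

  pieces <- vector("list", length(batch_ids))
  n_skipped <- 0L
  for (bi in seq_along(batch_ids)) {
    b <- batch_ids[bi]
    in_cols <- which(col_batch == b)
    out_cols <- which(col_batch != b)
    m <- nrow(beta)
    ks_p <- mdif <- rep(NA_real_, m)
    n_in <- integer(m)
    for (i in seq_len(m)) {
      x <- beta[i, in_cols]; x <- x[!is.na(x)]
      y <- beta[i, out_cols]; y <- y[!is.na(y)]
      if (length(x) == 0L || length(y) == 0L) next
      ks <- ks_two_sample(x, y)
      ks_p[i] <- ks$p_value
      mdif[i] <- abs(stats::median(x) - stats::median(y))
      n_in[i] <- length(x)
    }
    ok <- !is.na(ks_p)
    n_skipped <- n_skipped + sum(!ok)
    pieces[[bi]] <- data.frame(
      feature_id = rownames(beta)[ok],
      batch_id = b,
      ks_p = ks_p[ok],
      mdif = mdif[ok],
      n_in_batch = n_in[ok],
      stringsAsFactors = FALSE
    )
  }
  if (n_skipped > 0)
    mc_log("detect_be_genes: omitted %d feature-by-batch row(s) without non-missing values", n_skipped)
  tab <- do.call(rbind, pieces)

  if (fdr_family == "per_batch") {
    tab$adj_p <- stats::ave(tab$ks_p, tab$batch_id,
                            FUN = function(p) adjust_pvalues(p, method))
  } else {
    tab$adj_p <- adjust_pvalues(tab$ks_p, method)
  }
  tab$is_BE <- tab$adj_p < p_threshold & tab$mdif > mdif_threshold
  tab[c("feature_id", "batch_id", "ks_p", "adj_p", "mdif", "n_in_batch", "is_BE")]
}
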