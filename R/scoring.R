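# Per-batch batch-effect scoring: every feature of a batch is binned by its
# median difference (mdif); the BE-score of the batch is the weighted bin
# count divided by the number of features tested in that batch. Outlying
# scores are then identified with a Dixon-type ratio test whose null
# distribution is obtained by seeded Monte Carlo.

#' Bin index and weight for a median difference
#'
#' Differences below 0.05 carry no weight. The interval \[0.05, 0.1) is
#' bin 0 with weight 1; \[0.1 m, 0.1 (m+1)) is bin m for m >= 1. A
#' difference of exactly 1 is assigned to the top bin (m = 9). Under the
#' default `"doubling"` scheme bin m >= 1 has weight `2^m`; the
#' alternative `"linear"` scheme uses weight `m + 1`.
#'
#' @param mdif numeric vector of median differences in \[0, 1\].
#' @param weight_scheme `"doubling"` (default) or `"linear"`.
#' @return data.frame with columns `bin` (integer, `NA` below 0.05) and
#'   `weight`.
#' @export
bin_weight <- function(mdif, weight_scheme = c("doubling", "linear")) {
  weight_scheme <- match.arg(weight_scheme)
  if (any(mdif < 0 | mdif > 1, na.rm = TRUE))
    stopf("mdif values must lie in [0, 1]")
  bin <- ifelse(mdif < 0.05, NA_integer_,
         ifelse(mdif < 0.1, 0L, pmin(floor(mdif * 10), 9L)))
  weight <- ifelse(is.na(bin), 0,
            ifelse(bin == 0L, 1,
                   if (weight_scheme == "doubling") 2^bin else bin + 1))
  data.frame(bin = as.integer(bin), weight = weight)
}

#' BE-score of one batch from its median differences
#'
#' `BEscore = sum_i(count_i * w_i) / N` where `count_i` is the number of
#' features of the batch whose mdif falls in bin i, `w_i` the bin weight
#' and `N` the total number of features tested in the batch. Every
#' feature contributes according to its mdif; features below 0.05 fall in
#' the weight-0 region and contribute nothing.
#'
#' @param mdif median differences of all features tested in the batch.
#' @param N total number of features tested in the batch (defaults to
#'   `length(mdif)`).
#' @param weight_scheme see [bin_weight()].
#' @return list with `BEscore`, `bin_counts` (named integer vector for
#'   bins 0..9) and `N`.
#' @export
compute_be_score <- function(mdif, N = length(mdif),
                             weight_scheme = c("doubling", "linear")) {
  weight_scheme <- match.arg(weight_scheme)
  if (!is_scalar_number(N) || N < 1) stopf("N must be a positive integer")
  bw <- bin_weight(mdif, weight_scheme)
  counts <- vapply(0:9, function(b) sum(bw$bin == b, na.rm = TRUE), integer(1))
  names(counts) <- paste0("bin_", 0:9)
  w <- c(1, 2^(1:9))
  if (weight_scheme == "linear") w <- c(1, (1:9) + 1)
  list(BEscore = sum(counts * w) / N, bin_counts = counts, N = as.integer(N))
}

#' Batch-effect score table for all batches
#'
#' Applies [compute_be_score()] to every batch of a BE-gene table (as
#' returned by [detect_be_genes()]).
#'
#' @param be_table data.frame from [detect_be_genes()].
#' @param weight_scheme see [bin_weight()].
#' @return data.frame with one row per batch: `batch_id`, `N`, bin counts
#'   `bin_0` .. `bin_9`, `BEscore`.
#' @export
score_batches <- function(be_table, weight_scheme = c("doubling", "linear")) {
  weight_scheme <- match.arg(weight_scheme)
  ids <- unique(be_table$batch_id)
  rows <- lapply(ids, function(b) {
    sub <- be_table[be_table$batch_id == b, ]
    sc <- compute_be_score(sub$mdif, N = nrow(sub), weight_scheme = weight_scheme)
    cbind(data.frame(batch_id = b, N = sc$N, stringsAsFactors = FALSE),
          as.data.frame(as.list(sc$bin_counts)),
          data.frame(BEscore = sc$BEscore))
  })
  do.call(rbind, rows)
}

# --- Dixon-type outlier test ------------------------------------------------

# Dixon ratio for the one-sided test of the maximum; the variant depends on
# the panel size n (r10 for n <= 7, r11 for 8-10, r21 for 11-13, r22 above).
dixon_ratio <- function(x) {
  n <- length(x)
  s <- sort(x)
  rng <- s[n] - s[1]
  if (rng == 0) return(0)
  if (n <= 7) (s[n] - s[n - 1]) / rng
  else if (n <= 10) (s[n] - s[n - 1]) / (s[n] - s[2])
  else if (n <= 13) (s[n] - s[n - 2]) / (s[n] - s[2])
  else (s[n] - s[n - 2]) / (s[n] - s[3])
}

# Cache of simulated null ratio samples, keyed by (n, nrep, seed); sorted
# ascending so p-values are a binary search away.
.dixon_cache <- new.env(parent = emptyenv())

dixon_null_ratios <- function(n, nrep, seed) {
  key <- paste(n, nrep, seed, sep = "_")
  got <- .dixon_cache[[key]]
  if (!is.null(got)) return(got)
  sims <- local_seed(seed, {
    draws <- matrix(stats::rnorm(n * nrep), nrow = n)
    apply(draws, 2, dixon_ratio)
  })
  sims <- sort(sims)
  .dixon_cache[[key]] <- sims
  sims
}

#' Dixon outlier test for the maximum of a score panel
#'
#' One-sided test of whether the largest value of a small panel deviates
#' from the rest, using the Dixon gap-to-range ratio (variant chosen by
#' panel size). The p-value is the Monte Carlo tail probability of the
#' ratio under a standard normal null, `(1 + #\{null >= observed\}) /
#' (nrep + 1)`, with a fixed seed so results are reproducible. Panels
#' smaller than 3 return `p = NA`; a panel with zero range returns
#' `p = 1`.
#'
#' @param scores numeric vector of BE-scores (one per batch).
#' @param nrep Monte Carlo replicates for the null distribution
#'   (default 100000).
#' @param mc_seed seed for the null simulation.
#' @return list with `p_value`, `statistic` (observed ratio) and
#'   `outlier` (index of the maximum score).
#' @export
dixon_test <- function(scores, nrep = 1e5, mc_seed = 181L) {
  n <- length(scores)
  if (n < 3L) return(list(p_value = NA_real_, statistic = NA_real_,
                          outlier = if (n > 0) which.max(scores) else NA_integer_))
  if (n > 30L)
    warning("dixon_test: panel larger than 30; the ratio statistic loses power, consider a different outlier test",
            call. = FALSE)
  obs <- dixon_ratio(scores)
  if (max(scores) == min(scores))
    return(list(p_value = 1, statistic = 0, outlier = which.max(scores)))
  null <- dixon_null_ratios(n, nrep, mc_seed)
  n_ge <- length(null) - findInterval(obs, null, left.open = TRUE)
  list(p_value = (1 + n_ge) / (nrep + 1),
       statistic = obs,
       outlier = which.max(scores))
}

#' Flag batch-effected batches from their BE-scores
#'
#' The Dixon-identified maximum is flagged when its p-value is below
#' `alpha` *and* its BE-score is at least `score_floor` (the floor guards
#' against significant deviations among scores that are all close to 0).
#' With `iterate = TRUE` (default) the flagged batch is removed and the
#' remainder re-tested until no further batch is flagged or fewer than 3
#' batches remain. With fewer than 3 batches overall the Dixon test is
#' undefined and any batch at or above the floor is flagged.
#'
#' @param score_table data.frame from [score_batches()] (needs columns
#'   `batch_id`, `BEscore`).
#' @param alpha significance level for the Dixon test (default 0.01).
#' @param score_floor minimum BE-score for flagging (default 0.1).
#' @param iterate re-test after removing each flagged batch.
#' @param nrep,mc_seed passed to [dixon_test()].
#' @return `score_table` with added columns `dixon_p` (p-value of the
#'   Dixon round in which the batch was the tested maximum, `NA`
#'   otherwise) and `flagged`.
#' @export
flag_affected_batches <- function(score_table, alpha = 0.01, score_floor = 0.1,
                                  iterate = TRUE, nrep = 1e5, mc_seed = 181L) {
  if (!all(c("batch_id", "BEscore") %in% names(score_table)))
    stopf("score_table needs columns batch_id and BEscore")
  out <- score_table
  out$dixon_p <- NA_real_
  out$flagged <- FALSE

  if (nrow(out) < 3L) {
    out$flagged <- out$BEscore >= score_floor
    return(out)
  }

  active <- rep(TRUE, nrow(out))
  repeat {
    if (sum(active) < 3L) break
    dx <- dixon_test(out$BEscore[active], nrep = nrep, mc_seed = mc_seed)
    idx <- which(active)[dx$outlier]
    out$dixon_p[idx] <- dx$p_value
    if (!is.na(dx$p_value) && dx$p_value < alpha && out$BEscore[idx] >= score_floor) {
      out$flagged[idx] <- TRUE
      if (!iterate) break
      active[idx] <- FALSE
    } else break
  }
  out
}
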