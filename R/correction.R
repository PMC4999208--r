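# Latent-factor-model matrix completion. Affected entries are removed from
# the training set, the remaining entries of each block are approximated by
# a low-rank product L %*% R fitted by gradient descent, and only the
# affected entries are overwritten by the (clipped) predictions.

#' Build the replacement mask for correction
#'
#' An entry is marked for replacement when its feature is batch-affected
#' (`is_BE`) in the batch of its sample and that batch is flagged, or when
#' the entry is missing in the input (missing entries are imputed, never
#' used for training).
#'
#' @param beta beta-value matrix.
#' @param be_table BE-gene table from [detect_be_genes()].
#' @param flagged_batches character vector of flagged batch ids.
#' @param batches batch assignment data.frame.
#' @return logical matrix of the same shape as `beta`.
#' @export
replacement_mask <- function(beta, be_table, flagged_batches, batches) {
  validate_beta_matrix(beta)
  col_batch <- batch_of_columns(beta, batches)
  mask <- is.na(beta)
  for (b in intersect(flagged_batches, unique(col_batch))) {
    feats <- be_table$feature_id[be_table$batch_id == b & be_table$is_BE]
    if (length(feats) == 0L) next
    mask[rownames(beta) %in% feats, col_batch == b] <- TRUE
  }
  mask
}

#' Partition a matrix into randomized tiles
#'
#' Rows and columns are independently permuted with a seeded RNG and then
#' cut into contiguous chunks of at most `block_rows` x `block_cols`; edge
#' blocks may be smaller. The permutation spreads any contiguous batch
#' across blocks so no block lies wholly inside one batch. The blocks
#' partition the index set exactly.
#'
#' @param m,n matrix dimensions.
#' @param block_rows,block_cols maximal block dimensions (default 60).
#' @param seed RNG seed for the permutations.
#' @return list of blocks, each a list with integer vectors `rows` and
#'   `cols` (original indices).
#' @export
partition_blocks <- function(m, n, block_rows = 60, block_cols = 60, seed = 1L) {
  if (block_rows < 2 || block_cols < 2) stopf("block sizes must be >= 2")
  perm <- local_seed(seed, list(rows = sample.int(m), cols = sample.int(n)))
  rb <- split(perm$rows, ceiling(seq_len(m) / min(block_rows, m)))
  cb <- split(perm$cols, ceiling(seq_len(n) / min(block_cols, n)))
  blocks <- vector("list", length(rb) * length(cb))
  k <- 0L
  for (r in rb) for (cc in cb) {
    k <- k + 1L
    blocks[[k]] <- list(rows = r, cols = cc)
  }
  blocks
}

#' Fit a latent factor model to one block
#'
#' Minimizes `sum_train (D_ij - [LR]_ij)^2 + lambda (||L||^2 + ||R||^2)`
#' over an m x r matrix `L` and an r x n matrix `R` by full gradient
#' descent with simultaneous updates. `L` and `R` are initialized from a
#' seeded uniform distribution on \[0, 0.1\]. The step size follows a
#' bold-driver schedule: a step that increases the loss (or makes it
#' non-finite) is rejected and the step size halved; accepted steps grow
#' it by 5 percent. Fitting stops after `epochs` accepted steps or when an
#' accepted step improves the loss by less than `tol`. The loss trace over
#' accepted steps is non-increasing by construction.
#'
#' The rank is clamped to `min(r, nrow, ncol)`. Blocks whose training set
#' is smaller than the parameter count are permitted (the L2 penalty keeps
#' them well-posed) but reported in the result.
#'
#' @param block numeric sub-matrix (values outside the training mask are
#'   ignored).
#' @param train_mask logical matrix, `TRUE` for entries used in the loss.
#' @param r latent rank (default 10).
#' @param gamma initial learning rate (default 0.01).
#' @param lambda L2 penalty weight (default 0.1).
#' @param epochs maximum accepted gradient steps (default 300).
#' @param seed seed for the factor initialization.
#' @param tol stop when an accepted step improves the loss by less than
#'   this (default 1e-6).
#' @return object of class `"lfm_model"`: list with `L`, `R`, `rank`,
#'   `loss_trace`, `epochs_run`, `n_rejected`, `underdetermined`.
#' @export
fit_lfm <- function(block, train_mask, r = 10, gamma = 0.01, lambda = 0.1,
                    epochs = 300, seed = 1L, tol = 1e-6) {
  m <- nrow(block); n <- ncol(block)
  if (!any(train_mask)) stopf("fit_lfm: no training entries in block")
  r_used <- max(1L, min(as.integer(r), m, n))
  n_train <- sum(train_mask)
  under <- n_train < r_used * (m + n)

  D0 <- block
  D0[!train_mask] <- 0
  loss_of <- function(L, R) {
    E <- D0 - L %*% R
    E[!train_mask] <- 0
    sum(E * E) + lambda * (sum(L * L) + sum(R * R))
  }

  init <- local_seed(seed, list(
    L = matrix(stats::runif(m * r_used, 0, 0.1), m, r_used),
    R = matrix(stats::runif(r_used * n, 0, 0.1), r_used, n)
  ))
  L <- init$L; R <- init$R
  prev <- loss_of(L, R)
  trace <- prev
  accepted <- 0L; rejected <- 0L
  while (accepted < epochs) {
    E <- D0 - L %*% R
    E[!train_mask] <- 0
    L_new <- L + gamma * (2 * E %*% t(R) - 2 * lambda * L)
    R_new <- R + gamma * (2 * t(L) %*% E - 2 * lambda * R)
    loss <- loss_of(L_new, R_new)
    if (!is.finite(loss) || loss > prev) {
      gamma <- gamma / 2
      rejected <- rejected + 1L
      if (gamma < 1e-14) break   # step size exhausted: converged numerically
      next
    }
    improvement <- prev - loss
    L <- L_new; R <- R_new; prev <- loss
    accepted <- accepted + 1L
    trace <- c(trace, loss)
    gamma <- gamma * 1.05
    if (improvement < tol) break
  }
  structure(list(L = L, R = R, rank = r_used, loss_trace = trace,
                 epochs_run = accepted, n_rejected = rejected,
                 underdetermined = under),
            class = "lfm_model")
}

#' @export
predict.lfm_model <- function(object, ...) {
  object$L %*% object$R
}

#' Replace masked entries by latent-factor-model predictions
#'
#' The matrix is partitioned into randomized blocks
#' ([partition_blocks()]); each block's model is fitted on its unmasked
#' entries only and its masked entries are overwritten by the low-rank
#' predictions, clipped to \[0, 1\]. Entries outside the mask are copied
#' from the input unchanged (bit-exact). Each block uses a seed derived
#' deterministically from `seed` and the block index, so the result does
#' not depend on execution order.
#'
#' A block whose entries are all masked cannot be fitted; its entries fall
#' back to the mean of the feature's and the sample's unmasked values in
#' the full matrix (logged in the diagnostics).
#'
#' @param beta beta-value matrix.
#' @param mask logical matrix, `TRUE` for entries to replace.
#' @param block_rows,block_cols block dimensions (default 60).
#' @param r,gamma,lambda,epochs,tol passed to [fit_lfm()].
#' @param seed master seed (block permutation and factor initialization).
#' @return object of class `"correction_result"`: list with `corrected`
#'   (matrix), `replaced_mask`, and `diagnostics` (per-block data.frame:
#'   training size, epochs run, initial and final loss, fallback flag).
#' @export
predict_and_replace <- function(beta, mask, block_rows = 60, block_cols = 60,
                                r = 10, gamma = 0.01, lambda = 0.1,
                                epochs = 300, tol = 1e-6, seed = 1L) {
  validate_beta_matrix(beta)
  if (!identical(dim(mask), dim(beta)))
    stopf("mask shape does not match the beta matrix")
  mask <- mask | is.na(beta)
  corrected <- beta
  blocks <- partition_blocks(nrow(beta), ncol(beta), block_rows, block_cols, seed)

  row_means <- rowMeans(ifelse(mask, NA, beta), na.rm = TRUE)
  col_means <- colMeans(ifelse(mask, NA, beta), na.rm = TRUE)

  diag_rows <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    rows <- blocks[[k]]$rows; cols <- blocks[[k]]$cols
    sub_mask <- mask[rows, cols, drop = FALSE]
    if (!any(sub_mask)) {
      diag_rows[[k]] <- data.frame(block = k, n_rows = length(rows),
                                   n_cols = length(cols), n_train = sum(!sub_mask),
                                   n_replaced = 0L, epochs_run = 0L,
                                   initial_loss = NA_real_, final_loss = NA_real_,
                                   fallback = FALSE)
      next
    }
    if (all(sub_mask)) {
      # degenerate: nothing to train on inside the block
      mc_log("predict_and_replace: block %d fully masked; falling back to row/column means", k)
      fill <- (outer(row_means[rows], rep(1, length(cols))) +
               outer(rep(1, length(rows)), col_means[cols])) / 2
      if (anyNA(fill)) {
        global_mean <- mean(beta[!mask], na.rm = TRUE)
        if (!is.finite(global_mean)) global_mean <- 0.5  # nothing observed at all
        fill[is.na(fill)] <- global_mean
      }
      corrected[rows, cols][sub_mask] <- pmin(1, pmax(0, fill[sub_mask]))
      diag_rows[[k]] <- data.frame(block = k, n_rows = length(rows),
                                   n_cols = length(cols), n_train = 0L,
                                   n_replaced = sum(sub_mask), epochs_run = 0L,
                                   initial_loss = NA_real_, final_loss = NA_real_,
                                   fallback = TRUE)
      next
    }
    sub <- beta[rows, cols, drop = FALSE]
    sub[sub_mask] <- NA     # ensure masked values cannot leak into the fit
    sub0 <- sub; sub0[is.na(sub0)] <- 0
    fit <- fit_lfm(sub0, !sub_mask, r = r, gamma = gamma, lambda = lambda,
                   epochs = epochs, seed = seed + k, tol = tol)
    pred <- pmin(1, pmax(0, predict(fit)))
    corrected[rows, cols][sub_mask] <- pred[sub_mask]
    diag_rows[[k]] <- data.frame(block = k, n_rows = length(rows),
                                 n_cols = length(cols), n_train = sum(!sub_mask),
                                 n_replaced = sum(sub_mask),
                                 epochs_run = fit$epochs_run,
                                 initial_loss = fit$loss_trace[1L],
                                 final_loss = fit$loss_trace[length(fit$loss_trace)],
                                 fallback = FALSE)
  }
  structure(list(corrected = corrected, replaced_mask = mask,
                 diagnostics = do.call(rbind, diag_rows)),
            class = "correction_result")
}

#' Held-out prediction accuracy of the matrix completion
#'
#' Hides a seeded random fraction of the known (non-missing) entries,
#' predicts them with [predict_and_replace()] and reports the mean,
#' median, minimum and maximum absolute deviation between the known and
#' the predicted values. At least one entry is always held out.
#'
#' @param beta beta-value matrix.
#' @param fraction fraction of known entries to hide (in (0, 0.5),
#'   default 0.06).
#' @param block_rows,block_cols,r,gamma,lambda,epochs,tol see
#'   [predict_and_replace()].
#' @param seed seed for both the hold-out draw and the completion.
#' @return list with `mean`, `median`, `min`, `max` absolute deviation and
#'   `n_held_out`.
#' @export
held_out_accuracy <- function(beta, fraction = 0.06, block_rows = 60,
                              block_cols = 60, r = 10, gamma = 0.01,
                              lambda = 0.1, epochs = 300, tol = 1e-6,
                              seed = 1L) {
  validate_beta_matrix(beta)
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 0.5)
    stopf("fraction must lie in (0, 0.5)")
  known <- which(!is.na(beta))
  n_hide <- max(1L, round(fraction * length(known)))
  hidden <- local_seed(seed, sample(known, n_hide))
  mask <- matrix(FALSE, nrow(beta), ncol(beta))
  mask[hidden] <- TRUE
  res <- predict_and_replace(beta, mask, block_rows = block_rows,
                             block_cols = block_cols, r = r, gamma = gamma,
                             lambda = lambda, epochs = epochs, tol = tol,
                             seed = seed)
  dev <- abs(res$corrected[hidden] - beta[hidden])
  list(mean = mean(dev), median = stats::median(dev),
       min = min(dev), max = max(dev), n_held_out = n_hide)
}
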