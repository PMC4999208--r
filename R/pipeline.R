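#' Default configuration for the detection-scoring-correction pipeline
#'
#' Collects every tunable threshold and hyperparameter in one list so a
#' run can be reproduced from its recorded configuration. Values override
#' the defaults; unknown names are rejected.
#'
#' @param ... name = value overrides.
#' @return named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  defaults <- list(
    p_threshold = 0.01,      # adjusted KS p-value cut-off (test 1)
    mdif_threshold = 0.05,   # median-difference cut-off (test 2, strict)
    method = "fdr",          # p-value adjustment: fdr | bonferroni | hommel
    fdr_family = "per_batch",# adjustment family: per_batch | global
    weight_scheme = "doubling", # BE-score bin weights: doubling | linear
    alpha = 0.01,            # Dixon significance level
    score_floor = 0.1,       # minimal BE-score for flagging
    iterate = TRUE,          # iterative Dixon flagging
    dixon_nrep = 1e5,        # Monte Carlo replicates for the Dixon null
    dixon_seed = 181L,
    r = 10,                  # latent rank
    gamma = 0.01,            # initial gradient-descent step size
    lambda = 0.1,            # L2 penalty weight
    epochs = 300,            # max accepted gradient steps per block
    tol = 1e-6,              # loss-improvement stopping tolerance
    block_rows = 60,
    block_cols = 60,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' Detect, score, flag and correct batch effects in one call
#'
#' Runs the full pipeline: per-batch BE-gene detection
#' ([detect_be_genes()]), BE-score computation ([score_batches()]), Dixon
#' flagging ([flag_affected_batches()]) and latent-factor-model
#' replacement of the BE-gene entries in flagged batches
#' ([predict_and_replace()]). Entries outside the replacement mask are
#' preserved bit-exactly; when no batch is flagged and no entry is
#' missing, the corrected matrix equals the input.
#'
#' @param beta beta-value matrix (features x samples).
#' @param batches batch assignment data.frame (`sample_id`, `batch_id`).
#' @param config a [run_config()].
#' @return list with `corrected`, `be_table`, `score_table`,
#'   `flagged_batches`, `replaced_mask`, `diagnostics` and `config`.
#' @export
correct_batch_effects <- function(beta, batches, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  be_table <- detect_be_genes(beta, batches,
                              p_threshold = config$p_threshold,
                              mdif_threshold = config$mdif_threshold,
                              method = config$method,
                              fdr_family = config$fdr_family)
  score_table <- score_batches(be_table, weight_scheme = config$weight_scheme)
  score_table <- flag_affected_batches(score_table,
                                       alpha = config$alpha,
                                       score_floor = config$score_floor,
                                       iterate = config$iterate,
                                       nrep = config$dixon_nrep,
                                       mc_seed = config$dixon_seed)
  flagged <- score_table$batch_id[score_table$flagged]
  mask <- replacement_mask(beta, be_table, flagged, batches)
  if (any(mask)) {
    res <- predict_and_replace(beta, mask,
                               block_rows = config$block_rows,
                               block_cols = config$block_cols,
                               r = config$r, gamma = config$gamma,
                               lambda = config$lambda,
                               epochs = config$epochs, tol = config$tol,
                               seed = config$seed)
    corrected <- res$corrected
    diagnostics <- res$diagnostics
  } else {
    corrected <- beta
    diagnostics <- NULL
  }
  list(corrected = corrected, be_table = be_table,
       score_table = score_table, flagged_batches = flagged,
       replaced_mask = mask, diagnostics = diagnostics, config = config)
}

#' Write a JSON run report
#'
#' Records inputs, configuration, package version, flagged batches and
#' summary counts of a pipeline run; together with the input files the
#' report allows bit-exact re-execution.
#'
#' @param result return value of [correct_batch_effects()].
#' @param path output JSON path.
#' @param inputs optional named list of input file paths to record.
#' @export
write_run_report <- function(result, path, inputs = list()) {
  report <- list(
    package = "methclear",
    version = as.character(utils::packageVersion("methclear")),
    inputs = inputs,
    config = unclass(result$config),
    flagged_batches = result$flagged_batches,
    n_features = nrow(result$corrected),
    n_samples = ncol(result$corrected),
    n_be_rows = sum(result$be_table$is_BE),
    n_replaced = sum(result$replaced_mask),
    be_scores = stats::setNames(as.list(result$score_table$BEscore),
                                result$score_table$batch_id)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
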