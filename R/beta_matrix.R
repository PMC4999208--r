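#' Validate a beta-value matrix
#'
#' A beta-value matrix is a plain numeric matrix with unique feature
#' identifiers as row names (genes, or probes in level-1 mode) and unique
#' sample identifiers as column names. Values are proportions of methylated
#' signal and must lie in \[0, 1\]; missing values are encoded as `NA`.
#'
#' @param beta numeric matrix with row and column names.
#' @param what label used in error messages.
#' @return `beta`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(beta, what = "beta matrix") {
  if (!is.matrix(beta) || !is.numeric(beta))
    stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stopf("%s must have feature row names and sample column names", what)
  if (anyDuplicated(rownames(beta)))
    stopf("%s has duplicated feature ids (e.g. '%s')", what,
          rownames(beta)[duplicated(rownames(beta))][1L])
  if (anyDuplicated(colnames(beta)))
    stopf("%s has duplicated sample ids (e.g. '%s')", what,
          colnames(beta)[duplicated(colnames(beta))][1L])
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("%s contains %d value(s) outside [0, 1]; first offender: feature '%s', sample '%s' (value %g)",
          what, nrow(bad), rownames(beta)[bad[1L, 1L]],
          colnames(beta)[bad[1L, 2L]], beta[bad[1L, , drop = FALSE]])
  }
  invisible(beta)
}

#' Read a beta-value matrix from delimited text
#'
#' The first row holds sample ids, the first column feature ids. Cells are
#' numeric beta-values or the `na` token. Values outside \[0, 1\] and
#' duplicated identifiers are rejected with an error that names the
#' offending feature and sample.
#'
#' @param path file path.
#' @param delimiter field separator (default tab).
#' @param na token representing a missing value (default `"NA"`).
#' @return numeric matrix (features x samples) with `NA` for missing entries.
#' @export
read_beta_matrix <- function(path, delimiter = "\t", na = "NA") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          row.names = NULL, check.names = FALSE,
                          na.strings = na, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stopf("malformed header in %s: need a feature-id column plus >= 1 sample", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stopf("duplicate feature id '%s' in %s", ids[duplicated(ids)][1L], path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad_cell <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad_cell) > 0)
    stopf("non-numeric cell '%s' at feature '%s', sample '%s' in %s",
          vals[bad_cell[1L, , drop = FALSE]], ids[bad_cell[1L, 1L]],
          colnames(vals)[bad_cell[1L, 2L]], path)
  dimnames(num) <- list(ids, colnames(vals))
  validate_beta_matrix(num, what = sprintf("beta matrix '%s'", path))
  num
}

#' Write a beta-value matrix as delimited text
#'
#' Inverse of [read_beta_matrix()]: `read_beta_matrix(write_beta_matrix(m))`
#' reproduces values, identifiers and the missing mask exactly (up to the
#' NA token).
#'
#' @param beta numeric beta matrix.
#' @param path output file path.
#' @param delimiter field separator.
#' @param na token written for missing entries.
#' @export
write_beta_matrix <- function(beta, path, delimiter = "\t", na = "NA") {
  validate_beta_matrix(beta)
  df <- data.frame(feature_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, na = na)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write beta matrix to %s", path)
  invisible(path)
}

#' Read a sample-to-batch assignment table
#'
#' Two-column delimited text with a header: sample id, batch id. Batch ids
#' are treated as opaque strings.
#'
#' @param path file path.
#' @param delimiter field separator.
#' @return data.frame with columns `sample_id`, `batch_id` (both character).
#' @export
read_batch_assignment <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stopf("batch assignment %s must have two columns (sample_id, batch_id)", path)
  out <- data.frame(sample_id = df[[1L]], batch_id = df[[2L]],
                    stringsAsFactors = FALSE)
  validate_batch_assignment(out)
  out
}

#' Validate a batch assignment against an optional beta matrix
#'
#' Each sample must map to exactly one batch; when `beta` is supplied every
#' sample of the matrix must be covered.
#'
#' @param batches data.frame with columns `sample_id`, `batch_id`.
#' @param beta optional beta matrix whose samples must all be assigned.
#' @return `batches`, invisibly.
#' @export
validate_batch_assignment <- function(batches, beta = NULL) {
  if (!is.data.frame(batches) || !all(c("sample_id", "batch_id") %in% names(batches)))
    stopf("batch assignment must be a data.frame with columns sample_id and batch_id")
  if (anyDuplicated(batches$sample_id))
    stopf("sample '%s' assigned to more than one batch",
          batches$sample_id[duplicated(batches$sample_id)][1L])
  if (any(is.na(batches$batch_id)) || any(batches$batch_id == ""))
    stopf("batch assignment contains empty batch ids")
  if (!is.null(beta)) {
    missing <- setdiff(colnames(beta), batches$sample_id)
    if (length(missing) > 0)
      stopf("%d sample(s) of the beta matrix have no batch (e.g. '%s')",
            length(missing), missing[1L])
  }
  invisible(batches)
}

# Batch id of every column of beta, in column order.
batch_of_columns <- function(beta, batches) {
  validate_batch_assignment(batches, beta)
  batches$batch_id[match(colnames(beta), batches$sample_id)]
}

#' Write a batch assignment table
#' @param batches data.frame with columns `sample_id`, `batch_id`.
#' @param path output file path.
#' @param delimiter field separator.
#' @export
write_batch_assignment <- function(batches, path, delimiter = "\t") {
  validate_batch_assignment(batches)
  utils::write.table(batches, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Manifest-style delimited text with columns probe_id, chromosome,
#' position (1-based bp), gene_name.
#'
#' @param path file path.
#' @param delimiter field separator (default comma).
#' @return data.frame with columns `probe_id`, `chromosome`, `position`,
#'   `gene_name`.
#' @export
read_probe_annotation <- function(path, delimiter = ",") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  need <- c("probe_id", "chromosome", "position", "gene_name")
  if (!all(need %in% names(df)))
    stopf("probe annotation %s must have columns %s", path, paste(need, collapse = ", "))
  out <- df[need]
  out$position <- as.integer(out$position)
  validate_probe_annotation(out)
  out
}

validate_probe_annotation <- function(ann) {
  if (anyDuplicated(ann$probe_id))
    stopf("duplicated probe_id '%s' in probe annotation",
          ann$probe_id[duplicated(ann$probe_id)][1L])
  if (any(!is.na(ann$position) & ann$position < 1L))
    stopf("probe positions must be >= 1 (1-based)")
  invisible(ann)
}

#' Read a TSS annotation table
#'
#' Either a 4+ column delimited table with named columns `chromosome`,
#' `tss_position`, `strand`, `gene_name`, or a 6-column BED file
#' (chrom, start, end, name, score, strand) in which case the TSS is taken
#' as `start + 1` on the plus strand and `end` on the minus strand
#' (BED intervals are 0-based half-open).
#'
#' @param path file path.
#' @param delimiter field separator.
#' @param format `"table"` (header with named columns) or `"bed6"`.
#' @return data.frame with columns `gene_name`, `chromosome`,
#'   `tss_position`, `strand`.
#' @export
read_tss_annotation <- function(path, delimiter = "\t", format = c("table", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "bed6") {
    df <- utils::read.table(path, header = FALSE, sep = delimiter,
                            check.names = FALSE, colClasses = "character",
                            comment.char = "", quote = "\"")
    if (ncol(df) < 6L) stopf("BED6 file %s needs 6 columns", path)
    strand <- df[[6L]]
    start0 <- as.integer(df[[2L]]); end0 <- as.integer(df[[3L]])
    out <- data.frame(gene_name = df[[4L]], chromosome = df[[1L]],
                      tss_position = ifelse(strand == "-", end0, start0 + 1L),
                      strand = strand, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = delimiter,
                            check.names = FALSE, colClasses = "character",
                            comment.char = "", quote = "\"")
    need <- c("chromosome", "tss_position", "strand", "gene_name")
    if (!all(need %in% names(df)))
      stopf("TSS annotation %s must have columns %s", path, paste(need, collapse = ", "))
    out <- df[c("gene_name", "chromosome", "tss_position", "strand")]
    out$tss_position <- as.integer(out$tss_position)
  }
  if (!all(out$strand %in% c("+", "-")))
    stopf("TSS strand must be '+' or '-'")
  if (anyDuplicated(out[c("gene_name", "chromosome")]))
    stopf("duplicated (gene_name, chromosome) record in TSS annotation")
  out
}

#' Write a result table (BE-gene table or batch score table) as TSV
#' @param table data.frame.
#' @param path output file path.
#' @param delimiter field separator.
#' @export
write_result_table <- function(table, path, delimiter = "\t") {
  utils::write.table(table, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
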