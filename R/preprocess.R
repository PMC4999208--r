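#' Remove features with missing or indistinct gene names
#'
#' Cleaning step applied before promoter mapping: features whose annotation
#' has an empty or NA-like gene name, or a gene name listing several genes
#' (separator-delimited, e.g. `"GENE1;GENE2"`), are dropped, as are features
#' without any annotation record and features whose values are all missing.
#'
#' @param beta beta-value matrix (features x samples).
#' @param annotation probe annotation data.frame with columns `probe_id`
#'   and `gene_name` (see [read_probe_annotation()]).
#' @param na_tokens gene-name values treated as missing.
#' @param separator_pattern regular expression matching list separators in
#'   a gene name; a match marks the name as indistinct.
#' @return list with the filtered `beta` matrix and the matching
#'   `annotation` rows, plus counts of dropped features by reason.
#' @export
clean_entries <- function(beta, annotation,
                          na_tokens = c("", "NA", "."),
                          separator_pattern = "[;,]") {
  validate_beta_matrix(beta)
  if (!all(c("probe_id", "gene_name") %in% names(annotation)))
    stopf("annotation must have columns probe_id and gene_name")

  ann <- annotation[match(rownames(beta), annotation$probe_id), , drop = FALSE]
  unannotated <- is.na(ann$probe_id)
  gene <- ann$gene_name
  missing_name <- !unannotated & (is.na(gene) | gene %in% na_tokens)
  indistinct <- !unannotated & !missing_name & grepl(separator_pattern, gene)
  all_missing <- rowSums(!is.na(beta)) == 0L

  drop <- unannotated | missing_name | indistinct | all_missing
  if (any(drop)) {
    mc_log("clean_entries: dropped %d feature(s) (%d unannotated, %d missing gene name, %d indistinct gene name, %d all-missing)",
           sum(drop), sum(unannotated), sum(missing_name), sum(indistinct),
           sum(all_missing & !(unannotated | missing_name | indistinct)))
  }
  keep <- !drop
  list(beta = beta[keep, , drop = FALSE],
       annotation = ann[keep, , drop = FALSE],
       n_dropped = sum(drop),
       dropped = rownames(beta)[drop])
}

#' Select probes lying within a promoter window around annotated TSS
#'
#' A probe is kept if some TSS record matches its gene name and chromosome
#' and the probe position lies within `window_bp` of the TSS (inclusive,
#' i.e. a probe exactly `window_bp` away is kept). The window is symmetric
#' around the TSS, so the kept set does not depend on strand.
#'
#' @param probes probe annotation data.frame (`probe_id`, `chromosome`,
#'   `position`, `gene_name`).
#' @param tss TSS annotation data.frame (`gene_name`, `chromosome`,
#'   `tss_position`, `strand`).
#' @param window_bp half-width of the promoter window in base pairs
#'   (default 2000).
#' @return character vector of probe ids falling in a promoter window.
#' @export
map_probes_to_promoters <- function(probes, tss, window_bp = 2000) {
  if (!is_scalar_number(window_bp) || window_bp <= 0)
    stopf("window_bp must be a positive number")
  merged <- merge(probes, tss, by = c("gene_name", "chromosome"))
  if (nrow(merged) == 0L) return(character(0))
  hit <- abs(merged$position - merged$tss_position) <= window_bp
  unique(merged$probe_id[hit])
}

#' Aggregate probe-level beta-values to gene level
#'
#' Each gene's entry in a sample is the arithmetic mean of that gene's
#' non-missing probe values in the sample; it is missing only when every
#' contributing probe is missing. Aggregated values therefore always lie
#' within the range of the contributing probes.
#'
#' @param beta probe-level beta matrix.
#' @param probe_to_gene named character vector mapping probe id to gene
#'   name (names = probe ids), or a data.frame with columns `probe_id` and
#'   `gene_name`. Every feature of `beta` must be mapped.
#' @return gene-level beta matrix (genes x samples).
#' @export
aggregate_probes_to_genes <- function(beta, probe_to_gene) {
  validate_beta_matrix(beta)
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(probe_to_gene$gene_name, probe_to_gene$probe_id)
  } else map <- probe_to_gene
  if (length(map) == 0L) stopf("probe_to_gene mapping is empty")
  genes <- unname(map[rownames(beta)])
  if (anyNA(genes))
    stopf("feature '%s' has no gene mapping", rownames(beta)[is.na(genes)][1L])

  vals <- beta; vals[is.na(vals)] <- 0
  sums <- rowsum(vals, group = genes)
  counts <- rowsum((!is.na(beta)) * 1, group = genes)
  out <- sums / counts          # 0/0 -> NaN where all probes missing
  out[counts == 0] <- NA_real_
  out <- as.matrix(out)
  validate_beta_matrix(out, what = "aggregated beta matrix")
  out
}
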