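#' Normalize intensities to parts-per-million of the sample total
#'
#' Rescales every sample column so its detected intensities sum to 10^6:
#' X' = X / sum(X_i) * 10^6, the sum running over the detected (non-missing)
#' entries of that sample only. Missing entries stay missing -- an absence
#' carries no measured precursor area, so it contributes nothing to the
#' total and is never imputed before normalization.
#'
#' @param table A raw [master_table][as_master_table].
#' @return The table with `normalized = TRUE`; each column's detected
#'   entries sum to 10^6 (relative tolerance 1e-9).
#' @examples
#' mt <- as_master_table(
#'   tibble::tibble(accession = c("A", "B", "C"), S1 = c(2, 3, 5))
#' )
#' # (single-sample tables are allowed here; assembly requires >= 2 reports)
#' normalize_ppm(mt)
#' @export
normalize_ppm <- function(table) {
  stopifnot(is_master_table(table))
  if (is_normalized(table)) abort("table is already ppm-normalized")
  out <- as_tibble(table)
  for (s in sample_ids(table)) {
    v <- out[[s]]
    tot <- sum(v, na.rm = TRUE)
    if (!any(!is.na(v)) || tot <= 0) {
      abort(paste0("sample '", s, "' has no detected proteins"))
    }
    out[[s]] <- v / tot * 1e6
  }
  new_master_table(out, normalized = TRUE)
}

#' Group-wise presence filter
#'
#' Retains the proteins detected in at least `threshold` of the samples of at
#' least one of the named groups (default 55%, evaluated as an exact fraction:
#' 4 of 7 samples passes at 0.55, 3 of 7 does not). By default the filter is
#' scoped to the two groups of the comparison at hand; pass all group names to
#' filter once across the whole design instead.
#'
#' @param table A [master_table][as_master_table].
#' @param design Group design tibble (`sample_id`, `group`).
#' @param threshold Minimum detected fraction within a group, in \[0, 1\].
#' @param groups Group names over which presence is assessed; defaults to all
#'   groups in the design whose samples appear in the table.
#' @return The filtered table (same columns, subset of rows, flags kept).
#' @export
presence_filter <- function(table, design, threshold = 0.55, groups = NULL) {
  stopifnot(is_master_table(table))
  design <- validate_design(design)
  if (is.null(groups)) {
    groups <- unique(design$group[design$sample_id %in% sample_ids(table)])
  }
  if (length(groups) == 0) abort("no groups to filter on")
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    abort("threshold must lie in [0, 1]")
  }
  members <- design_samples(design, groups)
  missing_samples <- setdiff(unlist(members), sample_ids(table))
  if (length(missing_samples)) {
    abort(paste0("design sample(s) not in table: ",
                 paste(missing_samples, collapse = ", ")))
  }
  m <- mt_matrix(table)
  keep <- rep(FALSE, nrow(m))
  for (g in groups) {
    frac <- rowMeans(!is.na(m[, members[[g]], drop = FALSE]))
    keep <- keep | frac >= threshold
  }
  new_master_table(as_tibble(table)[keep, , drop = FALSE],
                   normalized = is_normalized(table))
}

#' Per-group detection fractions
#'
#' Helper view behind [presence_filter()]: fraction of samples of each group
#' in which each protein was detected.
#'
#' @inheritParams presence_filter
#' @return A tibble `accession` x one column per group, values in \[0, 1\].
#' @export
detection_fractions <- function(table, design, groups = NULL) {
  stopifnot(is_master_table(table))
  design <- validate_design(design)
  if (is.null(groups)) {
    groups <- unique(design$group[design$sample_id %in% sample_ids(table)])
  }
  members <- design_samples(design, groups)
  m <- mt_matrix(table)
  out <- tibble(accession = accessions(table))
  for (g in groups) {
    out[[g]] <- unname(rowMeans(!is.na(m[, members[[g]], drop = FALSE])))
  }
  out
}
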