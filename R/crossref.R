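#' Cross-study Spearman correlation of mean log-intensities
#'
#' Correlates per-protein mean normalized intensities from this study with an
#' external study's summary table. Means are taken over the detected values
#' of the chosen sample subset, transformed to the natural-log scale, and
#' rank-correlated (Spearman) with the external values on the shared
#' accessions. Being rank-based, the result is invariant to any strictly
#' monotone transform of either side; the log transform mirrors the scale on
#' which such comparisons are conventionally reported.
#'
#' @param table A normalized [master_table][as_master_table].
#' @param external Data frame with columns `accession` and `mean_intensity`
#'   (the external study's per-protein summary).
#' @param samples Sample ids to average over (default: all).
#' @return Spearman's rho (single number in \[-1, 1\]); attribute
#'   `n_shared` gives the number of shared accessions used.
#' @export
spearman_external <- function(table, external, samples = NULL) {
  stopifnot(is_master_table(table))
  external <- as_tibble(external)
  if (!all(c("accession", "mean_intensity") %in% names(external))) {
    abort("external table needs 'accession' and 'mean_intensity' columns")
  }
  samples <- samples %||% sample_ids(table)
  bad <- setdiff(samples, sample_ids(table))
  if (length(bad)) abort(paste0("unknown sample(s): ", paste(bad, collapse = ", ")))
  m <- mt_matrix(table)[, samples, drop = FALSE]
  means <- rowMeans(m, na.rm = TRUE)
  means <- means[!is.nan(means) & means > 0]
  shared <- intersect(names(means), external$accession)
  if (length(shared) < 3) {
    abort("fewer than 3 shared accessions between table and external study")
  }
  ext <- external$mean_intensity[match(shared, external$accession)]
  rho <- cor(log(means[shared]), ext, method = "spearman")
  structure(rho, n_shared = length(shared))
}

#' Fraction of one identifier set found in another
#'
#' @param a Non-empty character vector (the set whose coverage is reported).
#' @param b Character vector to look up in.
#' @return `|a intersect b| / |a|`.
#' @export
overlap_fraction <- function(a, b) {
  a <- unique(a)
  if (length(a) == 0) abort("overlap_fraction: first set is empty")
  length(intersect(a, b)) / length(a)
}

#' Z-scaled, Ward-clustered expression matrix for heatmaps
#'
#' Standardizes each selected protein row to mean 0, variance 1 (sample
#' standard deviation, n - 1) over its detected values, sets missing entries
#' to 0 after scaling (the row mean, i.e. neutral for clustering), and
#' clusters both rows and columns by Ward's minimum-variance method
#' (`ward.D2`) on Euclidean distances. Rows are ordered lexicographically by
#' accession before clustering so that distance ties resolve
#' deterministically; identical rows therefore always end up adjacent.
#'
#' @param table A normalized [master_table][as_master_table].
#' @param rows Accessions to include (default: all). Each needs at least two
#'   detected values and non-zero variance.
#' @return A `lfq_clustering` list: `z` (tibble, accession + sample columns),
#'   `row_order` / `col_order` (labels in dendrogram leaf order),
#'   `row_hclust` / `col_hclust` (the `hclust` objects), `n_imputed`
#'   (missing entries set to 0 after scaling).
#' @export
zscale_cluster <- function(table, rows = NULL) {
  stopifnot(is_master_table(table))
  rows <- rows %||% accessions(table)
  bad <- setdiff(rows, accessions(table))
  if (length(bad)) abort(paste0("unknown accession(s): ", paste(bad, collapse = ", ")))
  m <- mt_matrix(table)[sort(rows), , drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least 2 rows and 2 samples")
  z <- t(apply(m, 1, function(v) {
    det <- !is.na(v)
    if (sum(det) < 2) abort(paste0("row with <2 detected values"))
    s <- sd(v[det])
    (v - mean(v[det])) / s
  }))
  const <- apply(m, 1, function(v) sd(v[!is.na(v)]) == 0)
  if (any(const)) {
    abort(paste0("constant (zero-variance) row: ",
                 rownames(m)[const][1]))
  }
  n_imputed <- sum(is.na(z))
  if (n_imputed) {
    inform(paste0(n_imputed, " missing entries set to 0 after z-scaling"))
    z[is.na(z)] <- 0
  }
  rh <- hclust(dist(z, method = "euclidean"), method = "ward.D2")
  ch <- hclust(dist(t(z), method = "euclidean"), method = "ward.D2")
  structure(list(
    z = as_tibble(cbind(tibble(accession = rownames(z)), as_tibble(z))),
    row_order = rownames(z)[rh$order],
    col_order = colnames(z)[ch$order],
    row_hclust = rh, col_hclust = ch, n_imputed = n_imputed
  ), class = "lfq_clustering")
}

#' @export
print.lfq_clustering <- function(x, ...) {
  cat(sprintf("# z-scaled clustering: %d proteins x %d samples (ward.D2)\n",
              nrow(x$z), length(x$col_order)))
  invisible(x)
}
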