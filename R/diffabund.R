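#' Differential-abundance thresholds
#'
#' The significance and fold-change cut-offs used throughout the pipeline: a
#' protein is called up when p <= `alpha` and ratio >= `up_cut`, down when
#' p <= `alpha` and ratio <= `down_cut`, otherwise unchanged. Defaults follow
#' the common LFQ convention of p <= 0.05 with 1.5-fold change (0.67 on the
#' down side).
#'
#' @param alpha Significance level (0 < alpha < 1). Compared as `p <= alpha`.
#' @param up_cut Upregulation ratio cut-off (> 1).
#' @param down_cut Downregulation ratio cut-off (< 1).
#' @return A `lfq_thresholds` list.
#' @export
thresholds <- function(alpha = 0.05, up_cut = 1.5, down_cut = 0.67) {
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)")
  if (!(down_cut < 1 && 1 < up_cut)) abort("need down_cut < 1 < up_cut")
  structure(list(alpha = alpha, up_cut = up_cut, down_cut = down_cut),
            class = "lfq_thresholds")
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) p-value
#'
#' Exact by enumeration of the rank-sum null distribution when both groups
#' have at most `exact_max_n` observations and the pooled values are free of
#' ties; otherwise the normal approximation with tie correction and (by
#' default) continuity correction. Deterministic.
#'
#' @param x,y Non-empty numeric vectors (the two groups).
#' @param exact_max_n Largest per-group size for which the exact null
#'   distribution is used (ties always force the approximation).
#' @param continuity Apply the continuity correction in the normal
#'   approximation. The exact path is unaffected.
#' @return A single p-value in \[0, 1\].
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # 1/3: most extreme of C(4,2) arrangements
#' @export
mann_whitney <- function(x, y, exact_max_n = 8, continuity = TRUE) {
  if (length(x) == 0 || length(y) == 0) {
    abort("mann_whitney needs two non-empty groups")
  }
  if (anyNA(x) || anyNA(y)) abort("mann_whitney does not accept NA values")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)  # degenerate: all values equal
  exact <- anyDuplicated(pooled) == 0 &&
    length(x) <= exact_max_n && length(y) <= exact_max_n
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = exact, correct = continuity)
  )
  min(1, unname(res$p.value))
}

#' Group fold-change ratio over detected values
#'
#' Ratio of group means of normalized intensities, each mean taken over the
#' detected (non-missing) values only. When one group has no detections the
#' ratio is not a number but a detection sentinel: `only_in_case` /
#' `only_in_control` (printed as e.g. "only in wt" when the control group is
#' wild-type).
#'
#' @param case_values,control_values Numeric vectors from a normalized master
#'   table; `NA` marks a missing (not-detected) entry.
#' @return One-row tibble: `mean_case`, `mean_control`, `ratio` (`NA` when a
#'   sentinel applies), `detection` in `both` / `only_in_case` /
#'   `only_in_control`, `n_detected_case`, `n_detected_control`.
#' @export
group_ratio <- function(case_values, control_values) {
  ncase <- sum(!is.na(case_values))
  nctrl <- sum(!is.na(control_values))
  if (ncase == 0 && nctrl == 0) {
    abort("protein undetected in both groups; presence-filter the table first")
  }
  mc <- if (ncase) mean(case_values, na.rm = TRUE) else NA_real_
  mk <- if (nctrl) mean(control_values, na.rm = TRUE) else NA_real_
  detection <- if (nctrl == 0) {
    "only_in_case"
  } else if (ncase == 0) {
    "only_in_control"
  } else {
    "both"
  }
  tibble(
    mean_case = mc, mean_control = mk,
    ratio = if (detection == "both") mc / mk else NA_real_,
    detection = detection,
    n_detected_case = ncase, n_detected_control = nctrl
  )
}

classify_call <- function(p_value, ratio, detection, thr) {
  sig <- !is.na(p_value) & p_value <= thr$alpha
  up <- detection == "only_in_case" |
    (detection == "both" & !is.na(ratio) & ratio >= thr$up_cut)
  down <- detection == "only_in_control" |
    (detection == "both" & !is.na(ratio) & ratio <= thr$down_cut)
  dplyr::case_when(
    sig & up ~ "up",
    sig & down ~ "down",
    .default = "unchanged"
  )
}

#' Ratio-only classification
#'
#' Classifies a fold-change ratio against the thresholds alone (no p-value);
#' used when screening printed ratio columns for direction concordance.
#'
#' @param ratio Numeric vector of fold changes.
#' @param thr A [thresholds()] object.
#' @return Character vector in `up` / `down` / `unchanged`.
#' @export
classify_ratio <- function(ratio, thr = thresholds()) {
  dplyr::case_when(
    !is.na(ratio) & ratio >= thr$up_cut ~ "up",
    !is.na(ratio) & ratio <= thr$down_cut ~ "down",
    .default = "unchanged"
  )
}

#' Per-protein differential abundance for one case-vs-control comparison
#'
#' For every protein of a normalized, presence-filtered master table: the
#' two-sided Mann-Whitney p-value on per-sample intensities with missing
#' entries entering the test as 0 (a detection-aware test -- absences tie at
#' the bottom ranks and the tie correction applies, which is what lets a
#' protein detected only in controls still attain significance), the
#' fold-change ratio of detected-group means, and the up/down/unchanged
#' call under the thresholds.
#'
#' @param table A normalized [master_table][as_master_table], already
#'   presence-filtered for the two groups compared.
#' @param design Group design tibble (`sample_id`, `group`).
#' @param case,control Group names (case means the numerator of the ratio).
#' @param thr A [thresholds()] object.
#' @param adjust_p Also append a Benjamini-Hochberg adjusted p column
#'   (annotation only; the classification always uses the raw p-value).
#' @param exact_max_n,continuity Passed to [mann_whitney()].
#' @return A `lfq_diff` tibble: `accession`, `p_value`, `ratio`, `detection`,
#'   `mean_case`, `mean_control`, `n_detected_case`, `n_detected_control`,
#'   `classification` (+ `p_adjusted` when `adjust_p`); attributes `case`,
#'   `control`, `thresholds`.
#' @export
differential_abundance <- function(table, design, case, control,
                                   thr = thresholds(), adjust_p = FALSE,
                                   exact_max_n = 8, continuity = TRUE) {
  stopifnot(is_master_table(table))
  if (!is_normalized(table)) abort("normalize the table before testing")
  if (identical(case, control)) abort("case and control must differ")
  design <- validate_design(design)
  members <- design_samples(design, c(case, control))
  m <- mt_matrix(table)
  missing_samples <- setdiff(unlist(members), colnames(m))
  if (length(missing_samples)) {
    abort(paste0("design sample(s) not in table: ",
                 paste(missing_samples, collapse = ", ")))
  }
  xs <- m[, members[[case]], drop = FALSE]
  ys <- m[, members[[control]], drop = FALSE]

  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    gr <- group_ratio(xs[i, ], ys[i, ])
    x0 <- ifelse(is.na(xs[i, ]), 0, xs[i, ])
    y0 <- ifelse(is.na(ys[i, ]), 0, ys[i, ])
    gr$p_value <- mann_whitney(x0, y0, exact_max_n = exact_max_n,
                               continuity = continuity)
    gr
  })
  out <- bind_rows(rows)
  out$accession <- accessions(table)
  out$classification <- classify_call(out$p_value, out$ratio,
                                      out$detection, thr)
  out <- out[c("accession", "p_value", "ratio", "detection",
               "mean_case", "mean_control",
               "n_detected_case", "n_detected_control", "classification")]
  if (adjust_p) out$p_adjusted <- bh_adjust(out$p_value)
  structure(out,
            class = c("lfq_diff", class(tibble())),
            case = case, control = control, thresholds = thr)
}

#' @export
print.lfq_diff <- function(x, ...) {
  cat(sprintf("# differential abundance: %s vs %s (%d proteins)\n",
              attr(x, "case"), attr(x, "control"), nrow(x)))
  NextMethod()
}
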