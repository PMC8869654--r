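#' Proteins with concordant direction across two disease-stage comparisons
#'
#' Intersects two differential-abundance results (e.g. early and late disease
#' versus stage-matched controls) and keeps the proteins classified `up` in
#' both or `down` in both. Proteins absent from either result (typically
#' because they failed that comparison's presence filter) cannot be
#' consistent and are excluded.
#'
#' @param early,late `lfq_diff` tibbles from [differential_abundance()] run
#'   with identical thresholds.
#' @param labels Length-2 character provenance labels for the two
#'   comparisons (defaults taken from the inputs' case/control attributes).
#' @return A `lfq_consistent` tibble: `accession`, `direction` (`up`/`down`),
#'   per-comparison `p_value_early`, `ratio_early`, `detection_early`,
#'   `p_value_late`, `ratio_late`, `detection_late`; attributes `provenance`
#'   and `aging_corrected = FALSE`.
#' @export
consistent_across <- function(early, late, labels = NULL) {
  lab <- labels %||% c(diff_label(early), diff_label(late))
  e <- as_tibble(early)[c("accession", "p_value", "ratio", "detection",
                          "classification")]
  l <- as_tibble(late)[c("accession", "p_value", "ratio", "detection",
                         "classification")]
  joined <- inner_join(e, l, by = "accession",
                       suffix = c("_early", "_late"))
  keep <- joined$classification_early == joined$classification_late &
    joined$classification_early %in% c("up", "down")
  out <- joined[keep, , drop = FALSE]
  out$direction <- out$classification_early
  out <- out[c("accession", "direction",
               "p_value_early", "ratio_early", "detection_early",
               "p_value_late", "ratio_late", "detection_late")]
  new_consistent(out, provenance = lab, aging_corrected = FALSE)
}

new_consistent <- function(x, provenance, aging_corrected) {
  structure(as_tibble(x),
            class = c("lfq_consistent", class(tibble())),
            provenance = provenance,
            aging_corrected = isTRUE(aging_corrected))
}

diff_label <- function(d) {
  paste0(attr(d, "case") %||% "case", "_vs_", attr(d, "control") %||% "control")
}

#' Remove aging-driven candidates from a consistent set
#'
#' Subtracts the aging effect: any candidate protein that is itself
#' significantly changed between the age-matched control groups (the aging
#' comparison, e.g. older controls vs younger controls) is removed, so the
#' surviving changes reflect disease rather than age. By default any
#' significant aging change disqualifies a candidate regardless of its
#' direction; set `match_direction = TRUE` to remove only candidates whose
#' aging change runs in the same direction as their disease change.
#'
#' @param candidates A `lfq_consistent` set from [consistent_across()].
#' @param aging A `lfq_diff` result for the control-vs-control comparison,
#'   run with the same thresholds.
#' @param match_direction Require the aging classification to equal the
#'   candidate's direction before removing it.
#' @return The filtered `lfq_consistent` set with `aging_corrected = TRUE`.
#' @export
aging_correction <- function(candidates, aging, match_direction = FALSE) {
  stopifnot(inherits(candidates, "lfq_consistent"))
  ag <- as_tibble(aging)[c("accession", "classification")]
  out <- as_tibble(candidates)
  hit <- left_join(out["accession"], ag, by = "accession")$classification
  hit[is.na(hit)] <- "unchanged"
  remove <- if (match_direction) hit == out$direction else hit != "unchanged"
  new_consistent(out[!remove, , drop = FALSE],
                 provenance = attr(candidates, "provenance"),
                 aging_corrected = TRUE)
}

#' Cross-tissue / cross-model overlap table
#'
#' Restricts a reference consistent set to the proteins whose classification
#' in an independent comparison (another tissue or disease model) matches the
#' reference direction, carrying the fold-change ratios of every comparison
#' side by side.
#'
#' @param reference A `lfq_consistent` set.
#' @param other A `lfq_diff` result from the other tissue/model.
#' @param other_label Column prefix for the other comparison (defaults to its
#'   case-vs-control label).
#' @return Tibble: `accession`, `direction`, reference ratio columns, and
#'   `ratio_<other_label>` / `p_value_<other_label>`.
#' @export
cross_overlap <- function(reference, other, other_label = NULL) {
  stopifnot(inherits(reference, "lfq_consistent"))
  lab <- other_label %||% diff_label(other)
  ot <- as_tibble(other)[c("accession", "p_value", "ratio", "classification")]
  names(ot) <- c("accession", paste0("p_value_", lab), paste0("ratio_", lab),
                 "classification_other")
  joined <- inner_join(as_tibble(reference), ot, by = "accession")
  joined <- joined[joined$classification_other == joined$direction, ,
                   drop = FALSE]
  joined$classification_other <- NULL
  joined
}

#' @export
print.lfq_consistent <- function(x, ...) {
  cat(sprintf("# consistent set: %d up, %d down (%s aging correction)\n",
              sum(x$direction == "up"), sum(x$direction == "down"),
              if (isTRUE(attr(x, "aging_corrected"))) "after" else "before"))
  NextMethod()
}
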