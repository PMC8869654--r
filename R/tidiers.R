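#' Broom-style summaries of pipeline results
#'
#' `tidy()` returns the per-row result as a plain tibble; `glance()` returns
#' one-row summaries (counts of calls, set sizes, significant sets).
#'
#' @param x A pipeline result object.
#' @param ... Unused.
#' @return A tibble.
#' @name lfqpipe-tidiers
NULL

#' @rdname lfqpipe-tidiers
#' @exportS3Method generics::tidy
tidy.lfq_diff <- function(x, ...) as_tibble(x)

#' @rdname lfqpipe-tidiers
#' @exportS3Method generics::glance
glance.lfq_diff <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble(
    case = attr(x, "case"), control = attr(x, "control"),
    n_proteins = nrow(x),
    n_up = sum(x$classification == "up"),
    n_down = sum(x$classification == "down"),
    n_unchanged = sum(x$classification == "unchanged"),
    alpha = thr$alpha, up_cut = thr$up_cut, down_cut = thr$down_cut
  )
}

#' @rdname lfqpipe-tidiers
#' @exportS3Method generics::tidy
tidy.lfq_consistent <- function(x, ...) as_tibble(x)

#' @rdname lfqpipe-tidiers
#' @exportS3Method generics::glance
glance.lfq_consistent <- function(x, ...) {
  tibble(
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_total = nrow(x),
    aging_corrected = isTRUE(attr(x, "aging_corrected"))
  )
}

#' @rdname lfqpipe-tidiers
#' @exportS3Method generics::tidy
tidy.lfq_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  out$members_hit <- vapply(out$members_hit, paste, character(1),
                            collapse = ";")
  out
}

#' @rdname lfqpipe-tidiers
#' @exportS3Method generics::glance
glance.lfq_enrichment <- function(x, ...) {
  tibble(
    n_sets_tested = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha")
  )
}

#' @rdname lfqpipe-tidiers
#' @exportS3Method generics::tidy
tidy.lfq_reclass <- function(x, ...) as_tibble(x)

#' @rdname lfqpipe-tidiers
#' @exportS3Method generics::glance
glance.lfq_reclass <- function(x, ...) {
  tibble(
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_discordant = sum(x$direction == "discordant"),
    n_total = nrow(x)
  )
}
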