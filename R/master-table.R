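#' Master intensity tables
#'
#' A master table is the central container of the pipeline: one row per
#' protein accession, one numeric column per sample, with `NA` marking a
#' protein that was not detected in a sample (absence of evidence, kept
#' distinct from a measured zero -- raw LFQ reports never contain true
#' zeros). It is an ordinary tibble subclass, so all dplyr verbs work on it;
#' the pipeline's own functions preserve the class and its `normalized`
#' attribute, which records whether columns have been rescaled to
#' parts-per-million of the per-sample total.
#'
#' @param x A data frame with an `accession` character column and one or
#'   more numeric sample columns.
#' @param normalized Logical flag: have the columns been ppm-normalized?
#' @return A `master_table` (tibble subclass).
#' @examples
#' mt <- as_master_table(
#'   tibble::tibble(accession = c("P1", "P2"), S1 = c(2, 3), S2 = c(4, NA))
#' )
#' is_normalized(mt)
#' @export
as_master_table <- function(x, normalized = FALSE) {
  x <- as_tibble(x)
  if (!"accession" %in% names(x)) {
    abort("a master table needs an 'accession' column")
  }
  x$accession <- as.character(x$accession)
  if (anyDuplicated(x$accession)) {
    dup <- x$accession[duplicated(x$accession)][1]
    abort(paste0("duplicate accession in master table: ", dup))
  }
  smp <- setdiff(names(x), "accession")
  if (anyDuplicated(smp)) {
    abort("duplicate sample columns in master table")
  }
  for (s in smp) {
    if (!is.numeric(x[[s]])) {
      abort(paste0("sample column '", s, "' is not numeric"))
    }
    bad <- !is.na(x[[s]]) & x[[s]] < 0
    if (any(bad)) abort(paste0("negative intensity in sample '", s, "'"))
  }
  x <- x[c("accession", smp)]
  new_master_table(x, normalized = normalized)
}

new_master_table <- function(x, normalized = FALSE) {
  structure(x,
    class = c("master_table", class(as_tibble(x))),
    normalized = isTRUE(normalized)
  )
}

#' @rdname as_master_table
#' @export
is_master_table <- function(x) inherits(x, "master_table")

#' @rdname as_master_table
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' @rdname as_master_table
#' @export
sample_ids <- function(x) setdiff(names(x), "accession")

#' @rdname as_master_table
#' @export
accessions <- function(x) x[["accession"]]

# numeric matrix view (rows = accessions), used internally
mt_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x[sample_ids(x)]))
  rownames(m) <- accessions(x)
  m
}

#' Write / read a master table as TSV
#'
#' The on-disk dialect is lossless and diff-friendly: first column
#' `accession`, one column per sample, an empty cell for a missing
#' (not-detected) entry. Intensities are written with full precision so a
#' round trip reproduces values bit-exactly.
#'
#' @param x A [master_table][as_master_table].
#' @param path File path.
#' @return `write_master_table()` returns `x` invisibly; `read_master_table()`
#'   returns a `master_table`.
#' @export
write_master_table <- function(x, path) {
  stopifnot(is_master_table(x))
  out <- as_tibble(x)
  for (s in sample_ids(x)) {
    v <- out[[s]]
    out[[s]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  readr::write_tsv(out, path, na = "")
  invisible(x)
}

#' @rdname write_master_table
#' @param normalized Flag to set on the table read back (the dialect does not
#'   embed it; pipelines record it in their run log).
#' @export
read_master_table <- function(path, normalized = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    .default = readr::col_character()
  ), na = character(), progress = FALSE)
  for (s in setdiff(names(raw), "accession")) {
    v <- raw[[s]]
    v[v == ""] <- NA_character_
    raw[[s]] <- as.numeric(v)
  }
  as_master_table(raw, normalized = normalized)
}

#' @export
print.master_table <- function(x, ...) {
  cat(sprintf(
    "# master_table: %d proteins x %d samples (%s)\n",
    nrow(x), length(sample_ids(x)),
    if (is_normalized(x)) "ppm-normalized" else "raw"
  ))
  NextMethod()
}
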