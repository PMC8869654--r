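#' Read a per-sample protein quantification report
#'
#' Reads one tab-separated report as exported from an MS search /
#' quantification engine: one row per protein with its accession, an optional
#' description and a raw precursor-area intensity. Rows with a zero or empty
#' intensity are dropped -- a protein that produced no precursor area was not
#' detected, and detection state is carried as missingness, never as 0.
#'
#' @param path Path to a TSV file with a header line.
#' @param sample_id Label for this sample.
#' @param accession_col,intensity_col,description_col Column names in the
#'   report (the export schema varies by engine, so they are configurable).
#'   `description_col = NULL` if the report has none.
#' @return A tibble with columns `sample_id`, `accession`, `description`,
#'   `raw_intensity`; attribute `dropped` lists accessions whose intensity was
#'   zero/empty (logged absences).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("accession\tdescription\tintensity",
#'              "P1\tprotein one\t100", "P2\tprotein two\t300"), tf)
#' read_quant_report(tf, "S1")
#' @export
read_quant_report <- function(path, sample_id,
                              accession_col = "accession",
                              intensity_col = "intensity",
                              description_col = "description") {
  if (!file.exists(path)) abort(paste0("report file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  for (col in c(accession_col, intensity_col)) {
    if (!col %in% names(raw)) {
      abort(paste0("column '", col, "' not found in ", path))
    }
  }
  acc <- raw[[accession_col]]
  if (anyDuplicated(acc)) {
    dup <- acc[duplicated(acc)][1]
    abort(paste0("duplicate accession '", dup, "' in report ", path))
  }
  ints <- raw[[intensity_col]]
  blank <- is.na(ints) | trimws(ints) == ""
  val <- suppressWarnings(as.numeric(ints))
  bad <- !blank & is.na(val)
  if (any(bad)) {
    abort(paste0("unparsable intensity at line ", which(bad)[1] + 1L,
                 " of ", path, ": '", ints[bad][1], "'"))
  }
  if (any(!blank & val < 0)) {
    abort(paste0("negative intensity in report ", path))
  }
  desc <- if (!is.null(description_col) && description_col %in% names(raw)) {
    raw[[description_col]]
  } else {
    NA_character_
  }
  absent <- blank | (!is.na(val) & val == 0)
  dropped <- acc[absent]
  if (length(dropped)) {
    inform(paste0("sample ", sample_id, ": ", length(dropped),
                  " zero/empty intensities treated as not detected"))
  }
  out <- tibble(
    sample_id = sample_id,
    accession = acc[!absent],
    description = desc[!absent],
    raw_intensity = val[!absent]
  )
  attr(out, "dropped") <- dropped
  out
}

#' Concatenate per-sample reports into a master table
#'
#' Rows are the union of accessions over all reports; a protein absent from a
#' sample's report becomes a missing (`NA`) entry. Output column order follows
#' the order of the input reports; the assembled values themselves do not
#' depend on that order.
#'
#' @param reports List of tibbles from [read_quant_report()] (at least two:
#'   a single sample has nothing to compare).
#' @return A raw (un-normalized) [master_table][as_master_table].
#' @export
build_master_table <- function(reports) {
  if (length(reports) < 2) {
    abort("need at least 2 sample reports to build a master table")
  }
  ids <- vapply(reports, function(r) r$sample_id[1], character(1))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample_id: ", ids[duplicated(ids)][1]))
  }
  long <- bind_rows(reports)
  wide <- tidyr::pivot_wider(
    long[c("accession", "sample_id", "raw_intensity")],
    names_from = "sample_id", values_from = "raw_intensity"
  )
  wide <- wide[order(wide$accession), c("accession", ids)]
  as_master_table(wide, normalized = FALSE)
}

#' Read a group design
#'
#' Two-column TSV (`sample_id`, `group`) mapping each sample to exactly one
#' named group.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
read_group_design <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), group = readr::col_character()
  ), progress = FALSE)
  validate_design(d)
}

validate_design <- function(design) {
  design <- as_tibble(design)
  if (!all(c("sample_id", "group") %in% names(design))) {
    abort("design needs 'sample_id' and 'group' columns")
  }
  if (anyDuplicated(design$sample_id)) {
    abort(paste0("sample assigned to more than one group: ",
                 design$sample_id[duplicated(design$sample_id)][1]))
  }
  if (nrow(design) == 0) abort("empty group design")
  design
}

design_samples <- function(design, groups) {
  unknown <- setdiff(groups, design$group)
  if (length(unknown)) {
    abort(paste0("unknown group(s): ", paste(unknown, collapse = ", ")))
  }
  lapply(setNames(groups, groups),
         function(g) design$sample_id[design$group == g])
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one or more member identifiers.
#'
#' @param path Path to the GMT file.
#' @param toupper_members Upper-case member identifiers (gene symbols are
#'   conventionally compared case-insensitively).
#' @return A tibble with columns `set_name`, `description` and a `members`
#'   list-column of character vectors.
#' @export
read_gene_sets <- function(path, toupper_members = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("malformed GMT line ", which(nf < 3)[1],
                 ": fewer than 3 tab-separated fields"))
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate gene-set name: ", nm[duplicated(nm)][1]))
  }
  members <- lapply(fields, function(f) {
    m <- unique(f[-c(1, 2)][nzchar(f[-c(1, 2)])])
    if (toupper_members) toupper(m) else m
  })
  if (any(lengths(members) == 0)) {
    abort(paste0("gene set with no members: ",
                 nm[lengths(members) == 0][1]))
  }
  tibble(
    set_name = nm,
    description = vapply(fields, `[[`, character(1), 2),
    members = members
  )
}
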