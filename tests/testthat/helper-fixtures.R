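# Small fixture builders shared across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

write_report_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("accession\tdescription\tintensity", lines), path)
  path
}

tiny_master <- function(..., normalized = FALSE) {
  as_master_table(tibble::tibble(...), normalized = normalized)
}

two_group_design <- function(n_case = 8, n_control = 7,
                             case = "case", control = "control") {
  tibble::tibble(
    sample_id = c(sprintf("%s_%d", case, seq_len(n_case)),
                  sprintf("%s_%d", control, seq_len(n_control))),
    group = c(rep(case, n_case), rep(control, n_control))
  )
}

# Filter + test one comparison the way the pipeline does.
run_comparison <- function(tab, design, case, control, thr = thresholds()) {
  filt <- presence_filter(tab, design, threshold = 0.55,
                          groups = c(case, control))
  differential_abundance(filt, design, case, control, thr = thr)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "lfqpipe", mustWork = TRUE)
}
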