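#' Reclassify a published differential-abundance table
#'
#' Re-applies the pipeline's classification rule to a transcription of a
#' published result table that prints, per protein, a p-value and a
#' fold-change ratio for each of two disease-stage comparisons. Ratio cells
#' may carry a detection sentinel (by default `"only in wt"`, meaning the
#' protein was detected only in the wild-type control group, which counts
#' toward downregulation). Each comparison is classified under the
#' thresholds and the cross-stage consistency rule is applied.
#'
#' @param path TSV file with columns `accession`, `description`, `p_early`,
#'   `ratio_early`, `p_late`, `ratio_late` (names configurable via `cols`).
#' @param thr A [thresholds()] object.
#' @param cols Named character vector mapping the canonical roles
#'   (`accession`, `p_early`, `ratio_early`, `p_late`, `ratio_late`) to the
#'   file's column names.
#' @param sentinel_control Ratio cell text meaning "detected only in the
#'   control group".
#' @param sentinel_case Ratio cell text meaning "detected only in the case
#'   group".
#' @return A `lfq_reclass` tibble: `accession`, per-stage ratio, detection
#'   and classification columns, and `direction` (`up` / `down` /
#'   `discordant`). Use [glance()] for the counts.
#' @export
reclassify_table <- function(path, thr = thresholds(),
                             cols = c(accession = "accession",
                                      p_early = "p_early",
                                      ratio_early = "ratio_early",
                                      p_late = "p_late",
                                      ratio_late = "ratio_late"),
                             sentinel_control = "only in wt",
                             sentinel_case = "only in case") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  need <- c("accession", "p_early", "ratio_early", "p_late", "ratio_late")
  missing_roles <- setdiff(need, names(cols))
  if (length(missing_roles)) {
    abort(paste0("cols mapping lacks: ", paste(missing_roles, collapse = ", ")))
  }
  absent <- setdiff(unname(cols[need]), names(raw))
  if (length(absent)) {
    abort(paste0("column(s) not in ", path, ": ", paste(absent, collapse = ", ")))
  }
  acc <- raw[[cols[["accession"]]]]

  parse_num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & !is.na(x)
    if (any(bad)) {
      abort(paste0("unparsable ", what, " for row '", acc[bad][1], "': '",
                   x[bad][1], "'"))
    }
    v
  }
  parse_ratio <- function(x, what) {
    x <- trimws(x)
    det <- dplyr::case_when(
      tolower(x) == tolower(sentinel_control) ~ "only_in_control",
      tolower(x) == tolower(sentinel_case) ~ "only_in_case",
      .default = "both"
    )
    num <- ifelse(det == "both", x, NA_character_)
    list(ratio = parse_num(num, what), detection = det)
  }

  pe <- parse_num(raw[[cols[["p_early"]]]], "early p-value")
  pl <- parse_num(raw[[cols[["p_late"]]]], "late p-value")
  re <- parse_ratio(raw[[cols[["ratio_early"]]]], "early ratio")
  rl <- parse_ratio(raw[[cols[["ratio_late"]]]], "late ratio")

  out <- tibble(
    accession = acc,
    p_early = pe, ratio_early = re$ratio, detection_early = re$detection,
    p_late = pl, ratio_late = rl$ratio, detection_late = rl$detection
  )
  out$class_early <- classify_call(out$p_early, out$ratio_early,
                                   out$detection_early, thr)
  out$class_late <- classify_call(out$p_late, out$ratio_late,
                                  out$detection_late, thr)
  out$direction <- ifelse(
    out$class_early == out$class_late & out$class_early %in% c("up", "down"),
    out$class_early, "discordant"
  )
  structure(out, class = c("lfq_reclass", class(tibble())), thresholds = thr)
}

#' Run the full pipeline from a YAML configuration
#'
#' Orchestrates the whole analysis and writes every result table to
#' `output_dir` as TSV with a fixed column order, plus a `run_log.yaml`
#' recording the seed, thresholds and toggles used. Given the same
#' configuration and seed, outputs are byte-identical across runs.
#'
#' The configuration (a YAML file or an equivalent named list) provides:
#' \describe{
#'   \item{`input`}{either `synthetic:` (fields of [synthetic_config()],
#'     spikes as a list of `accession`/`groups`/`fold`/`only_in` records) or
#'     `reports:` (list of `path` + `sample_id`) with `design:` (TSV path).}
#'   \item{`comparisons`}{list of `label` / `case` / `control` sections
#'     (at least one; each is presence-filtered on its own two groups).}
#'   \item{`consistency`}{optional: `early` and `late` comparison labels,
#'     optional `aging` label and `match_direction` flag.}
#'   \item{`thresholds`, `presence_threshold`, `seed`}{analysis parameters.}
#'   \item{`gene_sets`}{optional GMT path; the consistent set is tested
#'     against the background of proteins retained in the early comparison.}
#'   \item{`external`}{optional TSV (`accession`, `mean_intensity`) for the
#'     cross-study Spearman correlation.}
#'   \item{`cluster`}{optional: `rows: consistent` to export the z-scaled,
#'     Ward-clustered matrix of the consistent proteins.}
#' }
#'
#' @param config Path to a YAML file, or a named list with the same shape.
#' @param output_dir Output directory (created if needed); overrides
#'   `output_dir` in the config.
#' @return Invisibly, a list with every in-memory result (`table`,
#'   `diff` per comparison, `consistent`, `consistent_corrected`,
#'   `enrichment`, `clustering`, `spearman_rho`, `paths`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) abort("config must be a YAML path or a named list")
  out_dir <- output_dir %||% cfg$output_dir
  if (is.null(out_dir)) abort("config key 'output_dir' is required")
  if (is.null(cfg$comparisons) || length(cfg$comparisons) == 0) {
    abort("config key 'comparisons' is required (at least one comparison)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  thr <- do.call(thresholds, cfg$thresholds %||% list())
  presence_thr <- cfg$presence_threshold %||% 0.55

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "': ", conditionMessage(e)))
    })
  }

  # --- input ---------------------------------------------------------------
  res <- list()
  if (!is.null(cfg$input$synthetic)) {
    sim_args <- cfg$input$synthetic
    if (!is.null(sim_args$spikes)) {
      sim_args$spikes <- bind_rows(lapply(sim_args$spikes, as_tibble))
    }
    if (!is.null(sim_args$aging_spikes)) {
      sim_args$aging_spikes <- bind_rows(lapply(sim_args$aging_spikes, as_tibble))
    }
    sim_args$seed <- sim_args$seed %||% seed
    sim <- stage("simulate", generate_dataset(do.call(synthetic_config, sim_args)))
    raw_tab <- sim$table
    design <- sim$config$design
    res$truth <- sim$truth
    readr::write_tsv(sim$truth, file.path(out_dir, "truth_labels.tsv"))
  } else if (!is.null(cfg$input$reports)) {
    reports <- stage("read_reports", purrr::map(cfg$input$reports, function(r) {
      read_quant_report(r$path, r$sample_id)
    }))
    raw_tab <- stage("master_table", build_master_table(reports))
    design <- stage("design", read_group_design(cfg$input$design))
  } else {
    abort("config needs input.synthetic or input.reports")
  }
  res$table <- norm_tab <- stage("normalize", normalize_ppm(raw_tab))
  write_master_table(norm_tab, file.path(out_dir, "master_table_ppm.tsv"))

  # --- per-comparison differential abundance -------------------------------
  comps <- purrr::map(cfg$comparisons, as_tibble) |> bind_rows()
  res$diff <- purrr::pmap(comps, function(label, case, control) {
    stage(paste0("diff_", label), {
      filt <- presence_filter(norm_tab, design, threshold = presence_thr,
                              groups = c(case, control))
      d <- differential_abundance(filt, design, case, control, thr = thr)
      flat <- as_tibble(d)
      readr::write_tsv(flat, file.path(out_dir, paste0("diff_", label, ".tsv")))
      d
    })
  })
  names(res$diff) <- comps$label

  # --- consistency + aging correction --------------------------------------
  cons_cfg <- cfg$consistency
  if (!is.null(cons_cfg)) {
    for (key in c("early", "late")) {
      if (is.null(cons_cfg[[key]]) || !cons_cfg[[key]] %in% comps$label) {
        abort(paste0("consistency.", key, " must name a comparison label"))
      }
    }
    res$consistent <- stage("consistency", consistent_across(
      res$diff[[cons_cfg$early]], res$diff[[cons_cfg$late]]
    ))
    readr::write_tsv(as_tibble(res$consistent),
                     file.path(out_dir, "consistent_raw.tsv"))
    if (!is.null(cons_cfg$aging)) {
      if (!cons_cfg$aging %in% comps$label) {
        abort("consistency.aging must name a comparison label")
      }
      res$consistent_corrected <- stage("aging_correction", aging_correction(
        res$consistent, res$diff[[cons_cfg$aging]],
        match_direction = isTRUE(cons_cfg$match_direction)
      ))
      readr::write_tsv(as_tibble(res$consistent_corrected),
                       file.path(out_dir, "consistent_aging_corrected.tsv"))
    }
    final_set <- res$consistent_corrected %||% res$consistent

    # cross-overlap against every comparison not used for the set itself
    others <- setdiff(comps$label,
                      c(cons_cfg$early, cons_cfg$late, cons_cfg$aging))
    for (lab in others) {
      ov <- stage(paste0("cross_overlap_", lab),
                  cross_overlap(final_set, res$diff[[lab]], other_label = lab))
      readr::write_tsv(ov, file.path(out_dir, paste0("cross_overlap_", lab, ".tsv")))
      res$cross_overlap[[lab]] <- ov
    }

    if (!is.null(cfg$gene_sets)) {
      res$enrichment <- stage("enrichment", {
        sets <- read_gene_sets(cfg$gene_sets)
        background <- toupper(accessions(
          presence_filter(norm_tab, design, threshold = presence_thr,
                          groups = unlist(comps[comps$label == cons_cfg$early,
                                                c("case", "control")]))
        ))
        enr <- enrich(toupper(final_set$accession), background, sets,
                      alpha = thr$alpha)
        flat <- enr
        flat$members_hit <- vapply(flat$members_hit, paste, character(1),
                                   collapse = ";")
        readr::write_tsv(as_tibble(flat), file.path(out_dir, "enrichment.tsv"))
        enr
      })
    }
    if (!is.null(cfg$cluster) && nrow(final_set) >= 2) {
      res$clustering <- stage("cluster", {
        cl <- zscale_cluster(norm_tab, rows = final_set$accession)
        z <- cl$z[match(cl$row_order, cl$z$accession),
                  c("accession", cl$col_order)]
        readr::write_tsv(z, file.path(out_dir, "zscaled_matrix.tsv"))
        cl
      })
    }
  }

  if (!is.null(cfg$external)) {
    res$spearman_rho <- stage("spearman_external", {
      ext <- readr::read_tsv(cfg$external, col_types = readr::cols(
        accession = readr::col_character(),
        mean_intensity = readr::col_double()
      ), progress = FALSE)
      as.numeric(spearman_external(norm_tab, ext))
    })
  }

  log <- list(
    package_version = as.character(utils::packageVersion("lfqpipe")),
    seed = seed,
    thresholds = unclass(thr),
    presence_threshold = presence_thr,
    comparisons = purrr::pmap(comps, function(label, case, control) {
      list(label = label, case = case, control = control)
    }),
    consistency = cons_cfg,
    gene_sets = cfg$gene_sets,
    external = cfg$external,
    spearman_rho = res$spearman_rho
  )
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  res$paths <- list.files(out_dir, full.names = TRUE)
  invisible(res)
}
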