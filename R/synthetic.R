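#' Study group design: two mouse models of diabetic kidney disease
#'
#' The sample layout the simulator emulates: glomeruli from the Ins2Akita
#' type-1 diabetes model at 2 months (INS2, n = 8; controls WT2, n = 7) and
#' 4 months (INS4, n = 8; controls WT4, n = 8), plus kidney cortex from the
#' db/db type-2 model at 6 months (dbdb, n = 3; controls dbdm, n = 5) --
#' 39 samples in total.
#'
#' @return A group design tibble (`sample_id`, `group`).
#' @export
paper_design <- function() {
  sizes <- c(WT2 = 7L, INS2 = 8L, WT4 = 8L, INS4 = 8L, dbdm = 5L, dbdb = 3L)
  bind_rows(purrr::imap(sizes, function(n, g) {
    tibble(sample_id = sprintf("%s_%02d", g, seq_len(n)), group = g)
  }))
}

#' The standard disease-stage comparisons for the default design
#'
#' @return Tibble with columns `label`, `case`, `control`: the early and
#'   late Ins2Akita comparisons, the aging (control-vs-control) comparison
#'   and the db/db cortex comparison.
#' @export
paper_comparisons <- function() {
  tibble(
    label = c("early", "late", "aging", "dbdb"),
    case = c("INS2", "INS4", "WT4", "dbdb"),
    control = c("WT2", "WT4", "WT2", "dbdm")
  )
}

#' Configuration for the LFQ spike-in simulator
#'
#' Defines the statistical law the generator draws from: log10-normal
#' baseline abundances, multiplicative log-normal within-group noise at a
#' given coefficient of variation, group-specific fold-change spikes with
#' known truth, and abundance-dependent detection (logistic dropout in
#' log10-abundance, times a uniform detection rate).
#'
#' @param design Group design tibble; defaults to [paper_design()].
#' @param n_proteins Number of simulated proteins.
#' @param baseline_log_mean,baseline_log_sd Mean and sd of the log10
#'   baseline abundance (defaults 6 and 1: a typical LFQ dynamic range).
#' @param within_group_cv Within-group coefficient of variation of the
#'   multiplicative noise (default 0.20).
#' @param detection_rate Uniform detection probability multiplier in (0, 1].
#' @param dropout_midpoint log10-abundance at which logistic detection
#'   probability is 50% (`-Inf` disables abundance-dependent dropout).
#' @param dropout_steepness Positive slope of the logistic dropout curve.
#' @param spikes Tibble with columns `accession`, `groups` (character,
#'   `;`-separated group names), `fold` (> 0), and optionally `only_in`
#'   (logical: protein exists only in the listed groups, missing elsewhere).
#' @param aging_spikes Tibble with columns `accession`, `fold`: aging
#'   confounds, applied to both 4-month groups (`WT4` and `INS4`) relative
#'   to the 2-month groups.
#' @param seed Integer seed; one generator stream governs all draws, so a
#'   fixed seed gives bit-identical tables.
#' @return A validated `lfq_sim_config` list.
#' @export
synthetic_config <- function(design = paper_design(), n_proteins = 2000,
                             baseline_log_mean = 6, baseline_log_sd = 1,
                             within_group_cv = 0.2, detection_rate = 1,
                             dropout_midpoint = 3.5, dropout_steepness = 1.5,
                             spikes = NULL, aging_spikes = NULL, seed = 1L) {
  design <- validate_design(design)
  if (n_proteins < 1) abort("n_proteins must be positive")
  if (within_group_cv < 0) abort("within_group_cv must be >= 0")
  if (!(detection_rate > 0 && detection_rate <= 1)) {
    abort("detection_rate must lie in (0, 1]")
  }
  if (!(dropout_steepness > 0)) abort("dropout_steepness must be > 0")
  spikes <- normalize_spikes(spikes, design)
  if (!is.null(aging_spikes)) {
    aging_spikes <- as_tibble(aging_spikes)
    if (!all(c("accession", "fold") %in% names(aging_spikes)) ||
        any(aging_spikes$fold <= 0)) {
      abort("aging_spikes needs 'accession' and positive 'fold' columns")
    }
    if (!all(c("WT4", "INS4") %in% design$group)) {
      abort("aging_spikes require WT4 and INS4 groups in the design")
    }
  }
  cfg <- list(
    design = design, n_proteins = as.integer(n_proteins),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    within_group_cv = within_group_cv, detection_rate = detection_rate,
    dropout_midpoint = dropout_midpoint, dropout_steepness = dropout_steepness,
    spikes = spikes, aging_spikes = aging_spikes, seed = as.integer(seed)
  )
  all_acc <- sim_accessions(cfg$n_proteins)
  spike_acc <- c(if (!is.null(spikes)) spikes$accession,
                 if (!is.null(aging_spikes)) aging_spikes$accession)
  if (!all(spike_acc %in% all_acc)) {
    abort("spike accessions must be among the generated accessions (SIM0001...)")
  }
  structure(cfg, class = "lfq_sim_config")
}

normalize_spikes <- function(spikes, design) {
  if (is.null(spikes)) return(NULL)
  spikes <- as_tibble(spikes)
  if (!all(c("accession", "groups") %in% names(spikes))) {
    abort("spikes need 'accession' and 'groups' columns")
  }
  if (!"only_in" %in% names(spikes)) spikes$only_in <- FALSE
  if (!"fold" %in% names(spikes)) spikes$fold <- NA_real_
  spikes$fold <- ifelse(spikes$only_in & is.na(spikes$fold), 1, spikes$fold)
  if (any(!spikes$only_in & (is.na(spikes$fold) | spikes$fold <= 0))) {
    abort("spike fold changes must be positive")
  }
  glist <- strsplit(spikes$groups, ";", fixed = TRUE)
  unknown <- setdiff(unlist(glist), design$group)
  if (length(unknown)) {
    abort(paste0("spike references unknown group(s): ",
                 paste(unknown, collapse = ", ")))
  }
  spikes
}

sim_accessions <- function(n) sprintf("SIM%04d", seq_len(n))

# per-protein x per-group fold multipliers implied by the config
sim_fold_map <- function(config) {
  acc <- sim_accessions(config$n_proteins)
  groups <- unique(config$design$group)
  fold <- matrix(1, nrow = length(acc), ncol = length(groups),
                 dimnames = list(acc, groups))
  present <- matrix(TRUE, nrow = length(acc), ncol = length(groups),
                    dimnames = list(acc, groups))
  sp <- config$spikes
  if (!is.null(sp)) {
    for (i in seq_len(nrow(sp))) {
      gs <- strsplit(sp$groups[i], ";", fixed = TRUE)[[1]]
      fold[sp$accession[i], gs] <- fold[sp$accession[i], gs] * sp$fold[i]
      if (isTRUE(sp$only_in[i])) {
        present[sp$accession[i], setdiff(groups, gs)] <- FALSE
      }
    }
  }
  ag <- config$aging_spikes
  if (!is.null(ag)) {
    for (i in seq_len(nrow(ag))) {
      fold[ag$accession[i], c("WT4", "INS4")] <-
        fold[ag$accession[i], c("WT4", "INS4")] * ag$fold[i]
    }
  }
  list(fold = fold, present = present)
}

#' Intended (ground-truth) status per comparison
#'
#' Derives, from the spike configuration alone, what each protein's
#' classification should be in each comparison: `up`, `down` or `null` from
#' the implied fold ratio (including one-sided presence spikes), plus an
#' `aging_confounded` flag for proteins carrying an aging spike.
#'
#' @param config A [synthetic_config()] object.
#' @param comparisons Tibble (`label`, `case`, `control`); defaults to the
#'   comparisons of [paper_comparisons()] present in the design.
#' @return Tibble: `accession`, `comparison` (label), `status`,
#'   `aging_confounded`.
#' @export
truth_labels <- function(config, comparisons = NULL) {
  stopifnot(inherits(config, "lfq_sim_config"))
  if (is.null(comparisons)) {
    comparisons <- paper_comparisons()
    comparisons <- comparisons[
      comparisons$case %in% config$design$group &
        comparisons$control %in% config$design$group, ]
  }
  fm <- sim_fold_map(config)
  aging_acc <- if (is.null(config$aging_spikes)) character(0) else
    config$aging_spikes$accession
  out <- purrr::pmap(comparisons, function(label, case, control) {
    pc <- fm$present[, case]
    pk <- fm$present[, control]
    r <- fm$fold[, case] / fm$fold[, control]
    status <- dplyr::case_when(
      pc & !pk ~ "up",
      !pc & pk ~ "down",
      !pc & !pk ~ "null",
      r > 1 ~ "up",
      r < 1 ~ "down",
      .default = "null"
    )
    tibble(accession = rownames(fm$fold), comparison = label, status = status)
  })
  out <- bind_rows(out)
  out$aging_confounded <- out$accession %in% aging_acc
  out
}

#' Generate an LFQ-like master table with known ground truth
#'
#' Draws, per protein, a log10-normal baseline abundance; multiplies it by
#' the group fold implied by the spike configuration; adds multiplicative
#' log-normal noise per sample at the configured CV (mean 1, so the expected
#' group ratio equals the spiked fold); then thins detections with
#' probability `detection_rate * plogis(steepness * (log10 A - midpoint))`,
#' so low-abundance measurements drop out preferentially -- the mechanism
#' behind "detected only in controls" proteins. All draws come from a single
#' seeded stream: the same seed reproduces the table bit for bit, and the
#' caller's RNG state is left untouched.
#'
#' @param config A [synthetic_config()] object.
#' @return List: `table` (raw [master_table][as_master_table]), `truth`
#'   (tibble from [truth_labels()]), `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "lfq_sim_config"))
  d <- config$design
  acc <- sim_accessions(config$n_proteins)
  fm <- sim_fold_map(config)
  sdlog <- sqrt(log(1 + config$within_group_cv^2))
  m <- withr::with_seed(config$seed, {
    base <- 10^rnorm(config$n_proteins, config$baseline_log_mean,
                     config$baseline_log_sd)
    vals <- matrix(NA_real_, nrow = config$n_proteins, ncol = nrow(d),
                   dimnames = list(acc, d$sample_id))
    for (j in seq_len(nrow(d))) {
      g <- d$group[j]
      noise <- exp(rnorm(config$n_proteins, -sdlog^2 / 2, sdlog))
      x <- base * fm$fold[, g] * noise
      p_det <- config$detection_rate *
        plogis(config$dropout_steepness *
                 (log10(x) - config$dropout_midpoint))
      detected <- runif(config$n_proteins) < p_det & fm$present[, g]
      vals[detected, j] <- x[detected]
    }
    vals
  })
  tab <- as_master_table(
    as_tibble(cbind(tibble(accession = acc), as_tibble(m))),
    normalized = FALSE
  )
  list(table = tab, truth = truth_labels(config), config = config)
}
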