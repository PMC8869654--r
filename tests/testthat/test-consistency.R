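# A compact pair of differential results for the set-algebra tests: build
# lfq_diff-shaped tibbles directly so each case is explicit.
fake_diff <- function(acc, cls, case = "INS", control = "WT",
                      ratio = NULL, p = NULL) {
  structure(
    tibble::tibble(
      accession = acc,
      p_value = p %||% ifelse(cls == "unchanged", 0.5, 0.01),
      ratio = ratio %||% ifelse(cls == "up", 3,
                                ifelse(cls == "down", 0.3, 1)),
      detection = "both",
      mean_case = 1, mean_control = 1,
      n_detected_case = 8L, n_detected_control = 7L,
      classification = cls
    ),
    class = c("lfq_diff", class(tibble::tibble())),
    case = case, control = control, thresholds = thresholds()
  )
}

test_that("consistency keeps only proteins concordant in both stages", {
  early <- fake_diff(c("GLS", "NUDT19", "FLIP", "ONLYEARLY", "NULL1"),
                     c("up", "down", "up", "up", "unchanged"))
  late <- fake_diff(c("GLS", "NUDT19", "FLIP", "NULL1", "ONLYLATE"),
                    c("up", "down", "down", "unchanged", "down"))
  cs <- consistent_across(early, late)
  expect_setequal(cs$accession[cs$direction == "up"], "GLS")
  expect_setequal(cs$accession[cs$direction == "down"], "NUDT19")
  # discordant, absent-from-one and unchanged proteins are all excluded
  expect_false(any(c("FLIP", "ONLYEARLY", "ONLYLATE", "NULL1") %in%
                     cs$accession))
  expect_false(attr(cs, "aging_corrected"))
  expect_equal(glance(cs)$n_total, 2)

  # symmetric up to provenance and column naming
  sw <- consistent_across(late, early)
  expect_setequal(sw$accession, cs$accession)
  expect_equal(setNames(sw$direction, sw$accession)[cs$accession],
               setNames(cs$direction, cs$accession))
})

test_that("aging correction removes aging-significant candidates", {
  early <- fake_diff(c("A", "B", "C"), c("up", "up", "down"))
  late <- fake_diff(c("A", "B", "C"), c("up", "up", "down"))
  cs <- consistent_across(early, late)

  aging <- fake_diff(c("A", "B", "C"), c("up", "unchanged", "unchanged"))
  corrected <- aging_correction(cs, aging)
  expect_setequal(corrected$accession, c("B", "C"))
  expect_true(attr(corrected, "aging_corrected"))

  # subset + idempotence
  expect_true(all(corrected$accession %in% cs$accession))
  twice <- aging_correction(corrected, aging)
  expect_identical(as.data.frame(twice), as.data.frame(corrected))

  # no aging signal: identity
  none <- fake_diff(c("A", "B", "C"), rep("unchanged", 3))
  expect_setequal(aging_correction(cs, none)$accession, cs$accession)

  # direction-matched variant only removes same-direction aging changes
  aging2 <- fake_diff(c("A", "C"), c("down", "down"))
  kept <- aging_correction(cs, aging2, match_direction = TRUE)
  expect_setequal(kept$accession, c("A", "B"))  # A up vs aging down: kept
})

test_that("cross-tissue overlap keeps direction-concordant proteins", {
  cs <- consistent_across(
    fake_diff(c("NUDT19", "AMACR", "GLS"), c("down", "down", "up")),
    fake_diff(c("NUDT19", "AMACR", "GLS"), c("down", "down", "up"))
  )
  cortex <- fake_diff(c("NUDT19", "AMACR", "GLS"), c("down", "up", "unchanged"),
                      ratio = c(0.236, 2, 1))
  ov <- cross_overlap(cs, cortex, other_label = "cortex")
  expect_equal(ov$accession, "NUDT19")
  expect_equal(ov$ratio_cortex, 0.236)
  expect_true(all(c("ratio_early", "ratio_late") %in% names(ov)))

  empty <- consistent_across(fake_diff("X", "unchanged"),
                             fake_diff("X", "unchanged"))
  expect_equal(nrow(cross_overlap(empty, cortex)), 0)
})

test_that("aging correction recovers the spiked confound structure", {
  # 43 disease-consistent spikes, 4 of them carrying an aging confound
  spikes <- dplyr::bind_rows(
    tibble::tibble(accession = sprintf("SIM%04d", 1:25),
                   groups = "INS2;INS4", fold = 4),
    tibble::tibble(accession = sprintf("SIM%04d", 26:43),
                   groups = "INS2;INS4", fold = 0.25)
  )
  aging_sp <- tibble::tibble(accession = sprintf("SIM%04d", 1:4), fold = 4)
  cfg <- synthetic_config(n_proteins = 1000, within_group_cv = 0.2,
                          dropout_midpoint = -Inf,
                          spikes = spikes, aging_spikes = aging_sp, seed = 3)
  tab <- normalize_ppm(generate_dataset(cfg)$table)
  early <- run_comparison(tab, cfg$design, "INS2", "WT2")
  late <- run_comparison(tab, cfg$design, "INS4", "WT4")
  aging <- run_comparison(tab, cfg$design, "WT4", "WT2")

  cs <- consistent_across(early, late)
  corrected <- aging_correction(cs, aging)
  expect_equal(nrow(cs), 43)
  expect_equal(nrow(corrected), 39)
  expect_false(any(aging_sp$accession %in% corrected$accession))
  expect_setequal(setdiff(cs$accession, corrected$accession),
                  aging_sp$accession)
})
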