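test_that("Mann-Whitney p-values match hand-enumerated cases", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(mann_whitney(c(1, 3), c(2, 4)), 2 / 3)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3)), 1)  # maximal symmetry
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
  expect_error(mann_whitney(c(1, NA), c(2, 3)), "NA")
})

test_that("exact Mann-Whitney equals the permutation-enumeration oracle", {
  withr::with_seed(20, {
    for (m in 1:6) {
      for (n in 1:6) {
        x <- runif(m)
        y <- runif(n)
        expect_equal(mann_whitney(x, y), mw_perm_pvalue(x, y),
                     tolerance = 1e-12,
                     label = sprintf("m=%d n=%d", m, n))
      }
    }
  })
})

test_that("Mann-Whitney is symmetric in its two groups", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      x <- runif(sample(2:9, 1))
      y <- runif(sample(2:9, 1))
      expect_equal(mann_whitney(x, y), mann_whitney(y, x))
      # with ties from zero-imputation the approximate path must agree too
      x0 <- c(x, 0, 0)
      y0 <- c(y, 0)
      expect_equal(mann_whitney(x0, y0), mann_whitney(y0, x0))
    }
  })
})

test_that("group ratios are detected-value mean ratios with sentinels", {
  r <- group_ratio(c(2, 4), c(1, 2))
  expect_equal(r$ratio, 2)
  expect_equal(r$detection, "both")

  s <- group_ratio(c(NA_real_, NA_real_), c(5, 6))
  expect_equal(s$detection, "only_in_control")
  expect_true(is.na(s$ratio))
  expect_equal(s$n_detected_case, 0)

  expect_equal(group_ratio(3, 3)$ratio, 1)
  expect_error(group_ratio(NA_real_, NA_real_), "presence-filter")

  # reciprocal symmetry when both numeric
  withr::with_seed(22, {
    a <- runif(5, 1, 10)
    b <- runif(4, 1, 10)
  })
  expect_equal(group_ratio(a, b)$ratio, 1 / group_ratio(b, a)$ratio)
})

test_that("differential abundance classifies by p-value and ratio jointly", {
  design <- two_group_design(n_case = 4, n_control = 4)
  mt <- tiny_master(
    accession = c("UP", "FLAT", "SMALLN", "ONLYCASE"),
    case_1 = c(30, 10, 11, 5), case_2 = c(31, 11, 10.5, 6),
    case_3 = c(29, 10.5, 11.2, 5.5), case_4 = c(30.5, 10.2, 10.8, 5.2),
    control_1 = c(10, 10.1, 10.9, NA), control_2 = c(11, 10.6, 11.1, NA),
    control_3 = c(10.5, 10.3, 10.4, NA), control_4 = c(10.2, 10.4, 11.3, NA)
  )
  # ballast row equalizes per-sample totals so ppm rescaling does not
  # induce spurious fold changes in the flat proteins
  tot <- colSums(as.data.frame(mt[-1]), na.rm = TRUE)
  ballast <- as_tibble(mt)[1, ]
  ballast$accession <- "BALLAST"
  ballast[1, -1] <- as.list(100 - tot)
  norm <- normalize_ppm(as_master_table(dplyr::bind_rows(as_tibble(mt),
                                                         ballast)))
  d <- differential_abundance(norm, design, "case", "control")
  cls <- setNames(d$classification, d$accession)
  expect_equal(cls[["UP"]], "up")
  expect_equal(cls[["FLAT"]], "unchanged")
  # detected only in cases: zero-imputed control ranks make it significant
  expect_equal(d$detection[d$accession == "ONLYCASE"], "only_in_case")
  expect_equal(cls[["ONLYCASE"]], "up")

  # every record is exactly one of up/down/unchanged
  expect_true(all(d$classification %in% c("up", "down", "unchanged")))
  expect_error(differential_abundance(norm, design, "case", "case"),
               "must differ")
  expect_error(differential_abundance(mt, design, "case", "control"),
               "normalize")
})

test_that("a significant ratio without a significant p stays unchanged", {
  # n = 2 vs 2: the smallest attainable two-sided exact p is 1/3 > 0.05
  design <- two_group_design(n_case = 2, n_control = 2)
  mt <- tiny_master(accession = c("A", "B"),
                    case_1 = c(30, 1), case_2 = c(31, 1.1),
                    control_1 = c(10, 1.2), control_2 = c(10.5, 0.9))
  d <- differential_abundance(normalize_ppm(mt), design, "case", "control")
  expect_true(all(d$classification == "unchanged"))
  expect_gte(min(d$p_value), 1 / 3)
})

test_that("missing values enter the test as zeros (detection-aware ranks)", {
  design <- two_group_design(n_case = 5, n_control = 5)
  # detected in all controls, in no cases: zeros occupy the bottom case ranks
  mt <- tiny_master(
    accession = c("ONLYWT", "REF"),
    case_1 = c(NA, 10), case_2 = c(NA, 11), case_3 = c(NA, 10.4),
    case_4 = c(NA, 10.8), case_5 = c(NA, 10.2),
    control_1 = c(5, 10.1), control_2 = c(6, 10.6), control_3 = c(5.5, 10.3),
    control_4 = c(5.8, 10.9), control_5 = c(5.2, 10.7)
  )
  d <- differential_abundance(normalize_ppm(mt), design, "case", "control")
  row <- d[d$accession == "ONLYWT", ]
  expect_lte(row$p_value, 0.05)
  expect_equal(row$classification, "down")
})
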