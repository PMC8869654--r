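test_that("quant reports parse, drop zero intensities, and reject bad input", {
  p <- write_report_file(c("P1\tdesc one\t100.0", "P2\tdesc two\t300.0"))
  rep1 <- read_quant_report(p, "S1")
  expect_equal(nrow(rep1), 2)
  expect_equal(rep1$raw_intensity, c(100, 300))
  expect_equal(rep1$sample_id, c("S1", "S1"))

  # zero intensity means "not detected": dropped and logged
  pz <- write_report_file(c("P1\td\t10", "P3\td\t0"))
  expect_message(rz <- read_quant_report(pz, "S2"), "not detected")
  expect_equal(rz$accession, "P1")
  expect_equal(attr(rz, "dropped"), "P3")

  pd <- write_report_file(c("P1\td\t1", "P1\td\t2"))
  expect_error(read_quant_report(pd, "S3"), "duplicate accession 'P1'")

  pb <- write_report_file(c("P1\td\t1", "P2\td\tabc"))
  expect_error(read_quant_report(pb, "S4"), "unparsable intensity at line 3")

  expect_error(read_quant_report(tempfile(), "S5"), "not found")
})

test_that("report columns are configurable", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("Acc\tArea", "P1\t5.5"), p)
  r <- read_quant_report(p, "S1", accession_col = "Acc",
                         intensity_col = "Area", description_col = NULL)
  expect_equal(r$raw_intensity, 5.5)
  expect_error(read_quant_report(p, "S1"), "column 'accession' not found")
})

test_that("master table assembly takes the union with explicit missingness", {
  r1 <- read_quant_report(write_report_file(c("P1\td\t2", "P2\td\t3")), "S1")
  r2 <- read_quant_report(write_report_file("P1\td\t4"), "S2")
  mt <- build_master_table(list(r1, r2))
  expect_s3_class(mt, "master_table")
  expect_false(is_normalized(mt))
  expect_equal(dim(mt), c(2L, 3L))
  expect_equal(mt$S1, c(2, 3))
  expect_equal(mt$S2, c(4, NA))

  expect_error(build_master_table(list(r1)), "at least 2")
  expect_error(build_master_table(list(r1, r1)), "duplicate sample_id")

  # disjoint accessions: exactly one detected entry per row
  r3 <- read_quant_report(write_report_file("P9\td\t7"), "S3")
  mt2 <- build_master_table(list(r2, r3))
  m <- as.matrix(as.data.frame(mt2[-1]))
  expect_equal(rowSums(!is.na(m)), c(1, 1), ignore_attr = TRUE)
})

test_that("assembly is invariant to report order up to column order", {
  reps <- list(
    read_quant_report(write_report_file(c("P1\td\t2", "P2\td\t3")), "S1"),
    read_quant_report(write_report_file(c("P2\td\t5", "P3\td\t1")), "S2"),
    read_quant_report(write_report_file("P1\td\t9"), "S3")
  )
  a <- build_master_table(reps)
  b <- build_master_table(rev(reps))
  expect_equal(as.data.frame(a)[names(a)], as.data.frame(b)[names(a)])
})

test_that("master table TSV round trip is bit-exact and keeps missingness", {
  withr::with_seed(42, {
    vals <- matrix(10^runif(60, 2, 8), 12, 5)
    vals[sample(60, 14)] <- NA
  })
  df <- tibble::as_tibble(as.data.frame(vals))
  names(df) <- paste0("S", 1:5)
  mt <- as_master_table(dplyr::bind_cols(
    tibble::tibble(accession = sprintf("P%02d", 1:12)), df
  ))
  path <- tempfile(fileext = ".tsv")
  write_master_table(mt, path)
  back <- read_master_table(path)
  expect_identical(as.data.frame(back), as.data.frame(mt))
})

test_that("master table construction enforces its invariants", {
  expect_error(as_master_table(tibble::tibble(x = 1)), "accession")
  expect_error(
    as_master_table(tibble::tibble(accession = c("A", "A"), S1 = 1:2)),
    "duplicate accession"
  )
  expect_error(
    as_master_table(tibble::tibble(accession = "A", S1 = -1)),
    "negative"
  )
})

test_that("GMT gene sets parse and enforce the three-field dialect", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("SetA\tfirst\tp1\tP2", "SetB\tsecond\tP3\tP4\tP5"), p)
  gs <- read_gene_sets(p)
  expect_equal(gs$set_name, c("SetA", "SetB"))
  expect_equal(gs$members[[1]], c("P1", "P2"))  # upper-cased
  expect_equal(lengths(gs$members), c(2L, 3L))

  writeLines(c("SetA\td\tP1", "SetA\td\tP2"), p)
  expect_error(read_gene_sets(p), "duplicate gene-set name")
  writeLines(c("SetA\td\tP1", "SetB\tdesc"), p)
  expect_error(read_gene_sets(p), "line 2")
})

test_that("group designs map each sample to exactly one group", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "a\tG1", "b\tG2"), p)
  d <- read_group_design(p)
  expect_equal(d$group, c("G1", "G2"))
  writeLines(c("sample_id\tgroup", "a\tG1", "a\tG2"), p)
  expect_error(read_group_design(p), "more than one group")
})
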