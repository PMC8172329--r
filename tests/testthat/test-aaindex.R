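test_that("a single well-formed AAindex record parses into 20 mapped values", {
  tmp <- withr::local_tempfile(lines = c(
    "H TEST000101",
    "D one complete record",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    1.0     2.0     3.0     4.0     5.0     6.0     7.0     8.0     9.0    10.0",
    "   11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0",
    "//"))
  props <- read_aaindex(tmp, quiet = TRUE)
  expect_equal(nrow(props), 1L)
  expect_equal(props$accession, "TEST000101")
  # I-line order: row 1 = A R N D C Q E G H I, row 2 = L K M F P S T W Y V
  expect_equal(props$A, 1.0)
  expect_equal(props$I, 10.0)
  expect_equal(props$L, 11.0)
  expect_equal(props$V, 20.0)
  expect_equal(attr(props, "skipped"), 0L)
})

test_that("records with missing values are skipped and counted", {
  tmp <- withr::local_tempfile(lines = c(
    "H TESTNA0101",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    1.0      NA     3.0     4.0     5.0     6.0     7.0     8.0     9.0    10.0",
    "   11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0",
    "//"))
  props <- read_aaindex(tmp, quiet = TRUE)
  expect_equal(nrow(props), 0L)
  expect_equal(attr(props, "skipped"), 1L)
})

test_that("malformed records fail with the accession named", {
  bad_count <- withr::local_tempfile(lines = c(
    "H TESTBAD101",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    1.0     2.0     3.0",
    "   11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0",
    "//"))
  expect_error(read_aaindex(bad_count, quiet = TRUE), "TESTBAD101")
  bad_num <- withr::local_tempfile(lines = c(
    "H TESTBAD102",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    1.0     2.0     3.0     4.0     x.y     6.0     7.0     8.0     9.0    10.0",
    "   11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0",
    "//"))
  expect_error(read_aaindex(bad_num, quiet = TRUE), "TESTBAD102.*x\\.y")
})

test_that("bundled fixture parses with expected skip and dedup counts", {
  props <- read_aaindex(fixture_aaindex(), quiet = TRUE)
  expect_equal(nrow(props), 7L)              # 8 records, 1 holds NA
  expect_equal(attr(props, "skipped"), 1L)
  kept <- dedupe_properties(props)
  expect_equal(nrow(kept), 6L)               # exact duplicate removed
  expect_true("SYNI000101" %in% kept$accession)   # first of the dup pair kept
  expect_false("SYNI000104" %in% kept$accession)
})

test_that("deduplication keeps the first of an identical pair, is exact and idempotent", {
  p <- synthetic_properties(4, seed = 11)
  dup <- p
  dup[3, AA20] <- dup[1, AA20]                       # exact copy of row 1
  out <- dedupe_properties(dup)
  expect_equal(out$accession, p$accession[c(1, 2, 4)])
  # a 1e-9 perturbation is NOT a duplicate
  near <- p
  near[3, AA20] <- near[1, AA20]
  near[3, "A"] <- near[3, "A"] + 1e-9
  expect_equal(nrow(dedupe_properties(near)), 4L)
  # idempotence
  expect_identical(dedupe_properties(out), out)
})

test_that("parse -> write -> parse round-trips record values", {
  props <- fixture_properties()
  vals <- as.matrix(props[, AA20])
  tmp <- withr::local_tempfile()
  lines <- unlist(lapply(seq_len(nrow(props)), function(i) {
    v <- vals[i, ]
    row1 <- v[c("A","R","N","D","C","Q","E","G","H","I")]
    row2 <- v[c("L","K","M","F","P","S","T","W","Y","V")]
    c(paste("H", props$accession[i]),
      paste("D", props$description[i]),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste(sprintf("%.10g", row1), collapse = " "),
      paste(sprintf("%.10g", row2), collapse = " "),
      "//")
  }))
  writeLines(lines, tmp)
  again <- read_aaindex(tmp, quiet = TRUE)
  expect_equal(again$accession, props$accession)
  expect_equal(as.matrix(again[, AA20]), vals, tolerance = 1e-9)
})

test_that("amino_acid_order sorts ascending with alphabetical tie-break", {
  asc <- stats::setNames(1:20, AA20)
  expect_equal(amino_acid_order(asc), AA20)
  # all equal -> pure tie-break -> alphabetical
  expect_equal(amino_acid_order(stats::setNames(rep(1, 20), AA20)), AA20)
  # reversed values -> reverse order, checked against an independent sort
  rev_vals <- stats::setNames(20:1, AA20)
  expect_equal(amino_acid_order(rev_vals), rev(AA20))
  expect_equal(amino_acid_order(rev_vals),
               names(sort(rev_vals)))  # base-R sort oracle (no ties here)
})

test_that("amino_acid_order always returns a permutation of the 20 codes", {
  set.seed(101)
  for (rep in 1:25) {
    v <- stats::setNames(sample(c(rnorm(15), rep(0.5, 5))), AA20)
    ord <- amino_acid_order(v)
    expect_setequal(ord, AA20)
    expect_equal(anyDuplicated(ord), 0L)
    expect_true(all(diff(v[ord]) >= 0))
  }
})

test_that("select_properties pins rows by accession list in list order", {
  props <- fixture_properties()
  tmp <- withr::local_tempfile(
    lines = c("# pinned subset", "SYNI000103", "SYNI000101"))
  sel <- select_properties(props, tmp)
  expect_equal(sel$accession, c("SYNI000103", "SYNI000101"))
  bad <- withr::local_tempfile(lines = "NOPE999999")
  expect_error(select_properties(props, bad), "NOPE999999")
})
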