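test_that("a clean proteinGroups fixture parses with no missing cells", {
  path <- write_pg_fixture(withr::local_tempfile(fileext = ".tsv"))
  qt <- read_protein_groups(path, fixture_spec())
  expect_s3_class(qt, "quant_table")
  expect_equal(dim(qt), c(3L, 2L))
  expect_identical(qt$proteins$protein_id, c("P1", "P2", "P3"))
  expect_equal(sum(is.na(qt$ratio_hl)) + sum(is.na(qt$ibaq_h)) +
                 sum(is.na(qt$ibaq_l)), 0L)
  expect_equal(qt$ratio_hl[, "s2"], c(P1 = 2, P2 = 0.25, P3 = 3))
  expect_true(all(qt$proteins$has_lysine_peptides))
})

test_that("zero iBAQ and blank/NaN cells are normalised to missing", {
  path <- write_pg_fixture(withr::local_tempfile(fileext = ".tsv"),
    tweak = function(rows) {
      rows[[1]][5] <- "0"     # iBAQ H s1 zero -> missing
      rows[[2]][3] <- ""      # Ratio H/L s1 empty -> missing
      rows[[3]][4] <- "NaN"   # Ratio H/L s2 NaN -> missing
      rows
    })
  qt <- read_protein_groups(path, fixture_spec())
  expect_true(is.na(qt$ibaq_h["P1", "s1"]))
  expect_true(is.na(qt$ratio_hl["P2", "s1"]))
  expect_true(is.na(qt$ratio_hl["P3", "s2"]))
  expect_equal(sum(is.na(qt$ratio_hl)), 2L)
})

test_that("structural problems are hard errors naming the culprit", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  # declared sample column absent
  write_pg_fixture(tmp)
  spec3 <- sample_spec(c("s1", "s2", "s3"), "A", "cartilage")
  expect_error(read_protein_groups(tmp, spec3), "Ratio H/L s3")
  # duplicate first accession
  write_pg_fixture(tmp, tweak = function(rows) {
    rows[[2]][1] <- "P1;other"
    rows
  })
  expect_error(read_protein_groups(tmp, fixture_spec()), "duplicate protein_id")
  # non-numeric cell with coordinates
  write_pg_fixture(tmp, tweak = function(rows) {
    rows[[2]][4] <- "oops"
    rows
  })
  expect_error(read_protein_groups(tmp, fixture_spec()),
               "row 2.*Ratio H/L s2")
})

test_that("missing lysine-count column warns and defaults to imputable", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_pg_fixture(tmp)
  txt <- readLines(tmp)
  keep <- which(strsplit(txt[1], "\t")[[1]] != "Lysine peptides")
  writeLines(vapply(strsplit(txt, "\t"),
                    function(f) paste(f[keep], collapse = "\t"),
                    character(1)), tmp)
  expect_warning(qt <- read_protein_groups(tmp, fixture_spec()),
                 "lysine")
  expect_true(all(qt$proteins$has_lysine_peptides))
})

test_that("filter_quantifiable removes flags, keeps lysine-less rows, and never
           touches numbers", {
  ratio <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 5, 2)
  qt <- make_qt(ratio,
                lysine = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                reverse = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  out <- filter_quantifiable(qt)
  expect_equal(nrow(out$proteins), 4L)
  expect_false("P002" %in% out$proteins$protein_id)
  # lysine-less row retained but annotated non-imputable
  expect_true("P003" %in% out$proteins$protein_id)
  expect_false(out$proteins$has_lysine_peptides[out$proteins$protein_id == "P003"])
  expect_identical(out$ratio_hl, qt$ratio_hl[-2, , drop = FALSE])
  # all-clean input is the identity
  clean <- make_qt(ratio)
  expect_identical(filter_quantifiable(clean), clean)
})

test_that("read -> write -> read round-trips on the value level", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_pg_fixture(tmp, tweak = function(rows) {
    rows[[1]][3] <- ""  # leave one missing ratio in play
    rows
  })
  qt1 <- read_protein_groups(tmp, fixture_spec())
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_table(qt1, tmp2)
  # missing cells are serialised as the literal NA token
  expect_match(readLines(tmp2)[2], "\tNA\t")
  qt2 <- read_protein_groups(tmp2, fixture_spec())
  expect_equal(qt1, qt2)
  # and a second cycle is exactly idempotent
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  write_table(qt2, tmp3)
  expect_identical(readLines(tmp2), readLines(tmp3))
})

test_that("an empty table writes a header-only file", {
  qt <- make_qt(matrix(numeric(0), 0, 2))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_table(qt, tmp)
  expect_length(readLines(tmp), 1L)
})
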