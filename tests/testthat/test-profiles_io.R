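test_that("quantification tables round-trip through write and read", {
  scheme <- fraction_scheme("sec_superdex", 24, void_fraction = 2)
  tab <- tiny_quant_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)

  parsed <- read_quant_table(path, scheme)
  expect_named(parsed$profiles$intensities, c("bio1", "bio2"))
  expect_identical(unname(parsed$profiles$intensities$bio1["A1", ]),
                   c(0, 0, 5, 9, 4, rep(0, 19)))
  expect_equal(parsed$records$peptide_count, c(3L, 1L))

  # full write -> read -> identical intensities, bit-exact
  out <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(parsed$profiles, parsed$records, out)
  again <- read_quant_table(out, scheme)
  expect_identical(again$profiles$intensities, parsed$profiles$intensities)
})

test_that("header-only tables give an empty profile set", {
  scheme <- fraction_scheme("sec_superdex", 24, void_fraction = 2)
  tab <- tiny_quant_table()[0, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- read_quant_table(path, scheme)
  expect_equal(nrow(parsed$profiles$intensities$bio1), 0)
  expect_equal(nrow(parsed$records), 0)
})

test_that("blank intensity cells are read as zero", {
  scheme <- fraction_scheme("sec_superdex", 24, void_fraction = 2)
  tab <- tiny_quant_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  tab[["Intensity.bio1.07"]] <- c("", "12")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- read_quant_table(path, scheme)
  expect_identical(parsed$profiles$intensities$bio1[, 7], c(A1 = 0, A2 = 12))
})

test_that("comma-separated dialect is sniffed from the header", {
  scheme <- fraction_scheme("sec_superdex", 24, void_fraction = 2)
  tab <- tiny_quant_table()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  parsed <- read_quant_table(path, scheme)
  expect_equal(unname(parsed$profiles$intensities$bio1["A1", 4]), 9)
})

test_that("missing fraction columns and duplicate ids are hard errors", {
  scheme <- fraction_scheme("sec_superdex", 24, void_fraction = 2)
  tab <- tiny_quant_table()
  path <- withr::local_tempfile(fileext = ".tsv")

  bad <- tab[, names(tab) != "Intensity.bio2.11"]
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_quant_table(path, scheme), "fraction.*11")

  dup <- tab; dup$protein_id <- c("A1", "A1")
  utils::write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_quant_table(path, scheme), "duplicate")
})

test_that("single-peptide identifications need score >= 5", {
  rec <- data.frame(protein_id = c("a", "b", "c", "d"),
                    peptide_count = c(1L, 1L, 2L, 1L),
                    id_score = c(4.9, 5.0, 0.1, 300))
  kept <- filter_identifications(rec)
  expect_setequal(kept$protein_id, c("b", "c", "d"))
  expect_identical(attr(kept, "dropped"), "a")
  # idempotent, never grows
  again <- filter_identifications(kept)
  expect_equal(again$protein_id, kept$protein_id)
  expect_lte(nrow(kept), nrow(rec))
})

test_that("replicate pairing keeps shared proteins and logs the rest", {
  scheme <- fraction_scheme("sec_superdex", 24, void_fraction = 2)
  m1 <- matrix(0, 5, 24, dimnames = list(paste0("p", 1:5), NULL))
  m2 <- m1
  m1[c("p1", "p2", "p3", "p4"), 10] <- 5   # p5 absent in bio1
  m2[c("p1", "p2", "p3", "p5"), 11] <- 7   # p4 absent in bio2
  profiles <- structure(list(scheme = scheme,
                             intensities = list(bio1 = m1, bio2 = m2)),
                        class = "elution_profiles")
  pr <- pair_replicates(profiles)
  expect_setequal(pr$protein_ids, c("p1", "p2", "p3"))
  expect_setequal(pr$drop_log$protein_id, c("p4", "p5"))
  expect_equal(pr$drop_log$present_in[pr$drop_log$protein_id == "p4"], "bio1")

  profiles$intensities$bio3 <- m1
  expect_error(pair_replicates(profiles), "exactly 2")
})
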