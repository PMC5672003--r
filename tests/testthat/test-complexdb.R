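toy_complexes <- function() {
  data.frame(
    complex_id = c(rep("CPX1", 3), rep("CPX1", 3), rep("CPX2", 2)),
    species = c(rep("human", 3), rep("mouse", 3), rep("human", 2)),
    subunit_id = c("hA", "hB", "hC", "mA", "mB", "mC", "hD", "hE"))
}

toy_orthologs <- function() {
  data.frame(source_id = c("hA", "hB", "hC", "mA", "mB", "mC", "hD"),
             target_id = c("t1", "t2", "t3", "t1", "t2", "t3", "t4"))
}

test_that("cross-species duplicates collapse to one record with aliases", {
  mapped <- map_orthologs(toy_complexes(), toy_orthologs())
  dd <- dedupe_complexes(mapped)
  tgt <- lapply(dd, `[[`, "target_ids")
  expect_equal(sum(vapply(tgt, identical, TRUE, c("t1", "t2", "t3"))), 1L)
  kept <- dd[[which(vapply(tgt, identical, TRUE, c("t1", "t2", "t3")))]]
  expect_length(kept$aliases, 1L)
  # idempotent
  expect_equal(length(dedupe_complexes(dd)), length(dd))
})

test_that("disjoint and subset target sets are all kept", {
  cx <- data.frame(complex_id = c("A", "A", "B", "B", "B"),
                   species = c("h", "h", "m", "m", "m"),
                   subunit_id = c("s1", "s2", "s3", "s4", "s5"))
  om <- data.frame(source_id = c("s1", "s2", "s3", "s4", "s5"),
                   target_id = c("t1", "t2", "t1", "t2", "t3"))
  dd <- dedupe_complexes(map_orthologs(cx, om))
  expect_length(dd, 2L)    # {t1,t2} vs {t1,t2,t3}: subset, both kept
})

test_that("coverage classes are exact at every stated boundary", {
  expect_equal(classify_coverage(3, 4), "high")    # special case
  expect_equal(classify_coverage(2, 3), "high")    # special case
  expect_equal(classify_coverage(4, 5), "high")    # 80%
  expect_equal(classify_coverage(3, 5), "medium")  # 60%
  expect_equal(classify_coverage(2, 5), "low")     # 40%
  expect_equal(classify_coverage(1, 5), "none")    # 20%
  # fraction grid around the boundaries
  expect_equal(classify_coverage(39, 100), "none")
  expect_equal(classify_coverage(40, 100), "low")
  expect_equal(classify_coverage(59, 100), "low")
  expect_equal(classify_coverage(60, 100), "medium")
  expect_equal(classify_coverage(79, 100), "medium")
  expect_equal(classify_coverage(80, 100), "high")
  expect_error(classify_coverage(5, 4), "n_matched")
})

test_that("assembled mass sums subunit monomer masses once each", {
  expect_equal(calc_complex_mass(100), 100)
  expect_equal(calc_complex_mass(c(50, 50, 100)), 200)
  expect_equal(calc_complex_mass(rep(1, 23)), 23)
  expect_error(calc_complex_mass(numeric(0)), "no subunit")
  expect_error(calc_complex_mass(c(10, -1)), "positive")
})

test_that("coverage table reports target mass only at full coverage", {
  mapped <- dedupe_complexes(map_orthologs(toy_complexes(), toy_orthologs()))
  tgt_mass <- data.frame(protein_id = c("t1", "t2", "t3", "t4"),
                         monomer_mass_kda = c(10, 20, 30, 40))
  cov <- coverage_table(mapped, target_masses = tgt_mass)
  full <- cov[cov$complex_id == "CPX1" & cov$n_matched == 3, ][1, ]
  expect_equal(full$coverage_class, "high")
  expect_equal(full$m_calc_target_kda, 60)
  half <- cov[cov$complex_id == "CPX2", ]
  expect_equal(half$n_matched, 1L)
  expect_true(is.na(half$m_calc_target_kda))   # 1 of 2 mapped
})

test_that("mass comparison reproduces a closed-form Pearson correlation", {
  cov <- data.frame(complex_id = c("c1", "c2", "c3", "c4"),
                    m_calc_target_kda = c(100, 250, 470, 900),
                    target_ids = c("p1", "p2", "p3", "p4"))
  set.seed(21)
  m_app <- cov$m_calc_target_kda * rlnorm(4, 0, 0.2)
  calls <- data.frame(protein_id = c("p1", "p2", "p3", "p4"),
                      m_app_mean = m_app)
  cmp <- compare_masses(cov, calls)
  expect_equal(attr(cmp, "pearson_r"),
               cor(log10(cov$m_calc_target_kda), log10(m_app)))
  # perfect concordance: all log ratios zero
  cmp0 <- compare_masses(cov, data.frame(protein_id = calls$protein_id,
                                         m_app_mean = cov$m_calc_target_kda))
  expect_equal(cmp0$median_log10_ratio, rep(0, 4))
  # complex with no measured subunits -> empty measurement row
  cmpNA <- compare_masses(cov, data.frame(protein_id = "zz", m_app_mean = 5))
  expect_equal(cmpNA$n_measured, rep(0L, 4))
  expect_true(all(is.na(cmpNA$median_m_app_kda)))
})

test_that("the shipped synthetic reference fixture classifies as expected", {
  cx <- read.csv(system.file("extdata", "synthetic_reference_complexes.csv",
                             package = "pcpfit"))
  om <- read.csv(system.file("extdata", "synthetic_ortholog_map.csv",
                             package = "pcpfit"))
  dd <- dedupe_complexes(map_orthologs(cx, om))
  cov <- coverage_table(dd)
  # human and mouse proteasome entries collapse to one record
  expect_equal(sum(cov$complex_id == "CPX_PROTEASOME_CORE"), 1L)
  cls <- setNames(cov$coverage_class, cov$complex_id)
  expect_equal(unname(cls["CPX_PROTEASOME_CORE"]), "high")   # 4 of 4
  expect_equal(unname(cls["CPX_COATOMER"]), "high")          # 2 of 3
  expect_equal(unname(cls["CPX_VATPASE_V1"]), "high")        # 4 of 5
  expect_equal(unname(cls["CPX_EXOCYST"]), "low")            # 2 of 4
  expect_equal(unname(cls["CPX_LSM"]), "high")               # 3 of 3
})
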