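test_that("unit-max normalization scales rows to max 1 and drops zero rows", {
  m <- rbind(a = c(0, 5, 10), b = c(2, 2, 2), c = c(0, 0, 0))
  nm <- normalize_unit_max(m)
  expect_equal(nm["a", ], c(0, 0.5, 1))
  expect_equal(attr(nm, "dropped"), "c")
  expect_equal(unname(apply(nm, 1, max)), rep(1, 2))
  # idempotent, element-wise oracle
  expect_equal(unname(normalize_unit_max(nm)[, ]), unname(nm[, ]))
  m2 <- matrix(runif(12), 3, 4, dimnames = list(letters[1:3], NULL))
  expect_equal(unname(normalize_unit_max(m2)[, ]),
               unname(m2 / apply(m2, 1, max)))
})

test_that("fraction correlation of a dataset with itself has unit diagonal", {
  set.seed(31)
  m <- matrix(runif(240), 10, 24, dimnames = list(paste0("p", 1:10), NULL))
  cc <- fraction_correlation(m, m)
  expect_equal(unname(diag(cc)), rep(1, 24))
  expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))
  expect_error(fraction_correlation(m[1:2, ], m[1:2, ]), "3 shared")
})

test_that("a circular fraction shift moves the correlation ridge off-diagonal", {
  set.seed(32)
  m1 <- matrix(rlnorm(50 * 24), 50, 24, dimnames = list(paste0("p", 1:50), NULL))
  m2 <- m1[, c(23, 24, 1:22)]   # rep2 shifted by +2 fractions
  cc <- fraction_correlation(m1, m2)
  ridge <- apply(cc, 1, which.max)
  expect_true(all((ridge - seq_len(24)) %% 24 == 2))
})

test_that("clustering recovers well-separated elution groups", {
  set.seed(33)
  centers <- rep(c(5, 12, 20), each = 6)
  m <- t(vapply(centers + runif(18, -0.5, 0.5),
                function(mu) gauss_profile(mu, 1.5, 100), numeric(24)))
  rownames(m) <- paste0("p", 1:18)
  hc <- cluster_profiles(m)
  groups <- cutree(hc, k = 3)
  truth <- rep(1:3, each = 6)
  for (g in 1:3) expect_length(unique(groups[truth == g]), 1L)
  expect_length(unique(unlist(tapply(groups, truth, unique))), 3L)
})

test_that("identical profiles merge first and row order does not matter", {
  set.seed(34)
  m <- rbind(p1 = gauss_profile(8, 1.5, 50), p2 = gauss_profile(8, 1.5, 100),
             p3 = gauss_profile(16, 2, 80), p4 = gauss_profile(12, 1, 30))
  hc <- cluster_profiles(m)
  first <- rownames(m)[-hc$merge[1, ]]
  expect_setequal(first, c("p1", "p2"))      # same shape: distance 0
  expect_equal(hc$height[1], 0, tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  hc2 <- cluster_profiles(m[perm, ])
  co1 <- as.matrix(cophenetic(hc))
  co2 <- as.matrix(cophenetic(hc2))[rownames(co1), colnames(co1)]
  expect_equal(co1, co2)                     # identical tree topology
})

test_that("reconstructed fitted profiles evaluate the mixture on the grid", {
  fits <- list(
    a = fit_elution_peaks(gauss_profile(10, 1.5, 100)),
    b = fit_elution_peaks(gauss_profile(c(6, 14), c(1.5, 2), c(80, 40))))
  rec <- reconstruct_profiles(fits, 1:24)
  expect_equal(dim(rec), c(2L, 24L))
  expect_equal(rec["a", ], predict(fits$a, 1:24))
  expect_lt(max(abs(rec["b", ] - gauss_profile(c(6, 14), c(1.5, 2),
                                               c(80, 40)))), 1)
})

test_that("dendrograms export as readable Newick trees", {
  m <- rbind(p1 = gauss_profile(5, 1.5, 10), p2 = gauss_profile(12, 1.5, 10),
             p3 = gauss_profile(20, 1.5, 10))
  hc <- cluster_profiles(m)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("p1", "p2", "p3"))
})
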