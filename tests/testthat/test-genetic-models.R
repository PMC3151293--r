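test_that("the five canonical architectures give the published locus counts", {
  grid <- model_grid()
  expect_equal(grid$n_loci, c(8L, 15L, 35L, 68L, 179L))
})

test_that("locus familial relative risks match the published values", {
  frr <- vapply(c("I", "II", "III", "V"), function(nm) {
    locus_frr(model_preset(nm))
  }, numeric(1))
  expect_equal(round(frr[["I"]], 3), 1.036)
  expect_equal(round(frr[["II"]], 2), 1.02)
  expect_equal(round(frr[["III"]], 3), 1.008)
  expect_equal(round(frr[["V"]], 4), 1.0016)
  # model IV: the printed 1.0036 is inconsistent with its own locus count;
  # the exact enumeration gives ~1.0042, which is what N = 68 requires
  # (log(1.33)/log(1.0036) would give ~79 loci)
  lam4 <- locus_frr(model_preset("IV"))
  expect_equal(round(log(1.33) / log(lam4)), 68)
})

test_that("prevalence equals direct genotype enumeration", {
  m <- genetic_model(q = 1e-4, f0 = 0.02, grr = 20)
  q <- 1e-4
  expected <- (1 - q)^2 * 0.02 + (2 * q * (1 - q) + q^2) * 0.4
  expect_equal(prevalence(m), expected)
  expect_equal(round(prevalence(m), 6), 0.020076)
  # no risk alleles, or no risk increase, reduce to the sporadic rate
  expect_equal(prevalence(genetic_model(q = 0, f0 = 0.02, grr = 20)), 0.02)
  expect_equal(prevalence(genetic_model(q = 1e-4, f0 = 0.02, grr = 1)), 0.02)
})

test_that("locus FRR degenerates to 1 without genetic variance", {
  expect_equal(locus_frr(genetic_model(q = 0, f0 = 0.02, grr = 20)), 1)
  expect_equal(locus_frr(genetic_model(q = 1e-4, f0 = 0.02, grr = 1)), 1)
  expect_error(num_loci(genetic_model(q = 0, f0 = 0.02, grr = 20)),
               "FRR")
})

test_that("locus FRR increases with the genotype relative risk", {
  frr <- vapply(c(2, 5, 10, 20, 40), function(g) {
    locus_frr(genetic_model(q = 1e-4, f0 = 0.02, grr = g))
  }, numeric(1))
  expect_true(all(diff(frr) > 0))
})

test_that("exact FRR agrees with the variance-components approximation", {
  for (q in c(1e-5, 1e-4, 1e-3)) {
    for (grr in c(5, 10, 20)) {
      m <- genetic_model(q = q, f0 = 0.02, grr = grr)
      K <- prevalence(m)
      a <- (m$f1 - m$f0) / 2
      alpha <- a + a * (1 - 2 * q) # dominance deviation d equals a here
      va <- 2 * q * (1 - q) * alpha^2
      approx <- 1 + va / (2 * K^2)
      expect_lt(abs(locus_frr(m) - approx), 5e-4)
    }
  }
})

test_that("a locus FRR equal to the aggregate target implies one locus", {
  m <- genetic_model(q = 0.05, f0 = 0.02, grr = 10)
  m$frr_total_target <- locus_frr(m)
  expect_equal(num_loci(m), 1L)
})

test_that("invalid parameters are rejected", {
  expect_error(genetic_model(q = 1e-4, f0 = 0.2, grr = 10), "exceeds 1")
  expect_error(genetic_model(q = 2, f0 = 0.02, grr = 10))
  expect_error(genetic_model(q = 1e-4, f0 = 0.02, grr = 0.5))
})

test_that("tidy() returns the derived quantities in one row", {
  td <- tidy(model_preset("II"))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$n_loci, 15L)
  expect_equal(td$f1, 0.3)
})
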