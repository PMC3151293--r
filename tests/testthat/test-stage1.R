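m2 <- model_preset("II")

test_that("an empty background profile passes no false genes", {
  prof <- variant_profile(n_rms = 0, n_tsj = 0)
  des <- stage1_design(m2, 1)
  set.seed(1)
  out <- simulate_stage1(des, 10, 15, prof)
  expect_equal(out$n_false, rep(0L, 5))
})

test_that("zero detection sensitivity passes no true genes", {
  prof <- variant_profile(sensitivity = 0)
  des <- stage1_design(m2, 1)
  set.seed(2)
  out <- purrr::map_dfr(1:5, ~simulate_stage1(des, 20, 15, prof))
  expect_equal(sum(out$n_true), 0L)
  expect_gt(sum(out$n_false), 0L)
})

test_that("with all-truncating true variants N1TS equals N1RV on true genes", {
  prof <- variant_profile(p_tsj_true = 1)
  des <- stage1_design(m2, 1)
  set.seed(3)
  for (i in 1:5) {
    out <- simulate_stage1(des, 20, 15, prof)
    expect_equal(out$n_true[out$filter == "N1TS"],
                 out$n_true[out$filter == "N1RV"])
  }
})

test_that("filters are nested: stricter filters pass subsets", {
  des <- stage1_design(m2, 2)
  set.seed(4)
  for (i in 1:10) {
    out <- simulate_stage1(des, 20, 15)
    g <- function(f, col) out[[col]][out$filter == f]
    for (col in c("n_true", "n_false")) {
      expect_lte(g("N3RV", col), g("N2RV", col))
      expect_lte(g("N2RV", col), g("N1RV", col))
      expect_lte(g("N2TS", col), g("N2RV", col))
      expect_lte(g("N1TS", col), g("N1RV", col))
    }
  }
})

test_that("single-sequenced false-gene means match the distinct-gene closed form", {
  des <- stage1_design(m2, 1)
  set.seed(5)
  n_rep <- 40
  out <- purrr::map_dfr(seq_len(n_rep), ~simulate_stage1(des, 10, 15))
  # N1RV: expected distinct genes hit by 10 exomes of E[Bin(400,.3)] + 20
  # = 1400 pooled variants
  m_rv <- out$n_false[out$filter == "N1RV"]
  exp_rv <- expected_distinct_genes(10 * (400 * 0.3 + 20))
  expect_lt(abs(mean(m_rv) - exp_rv), 3 * stats::sd(m_rv) / sqrt(n_rep))
  # N1TS: 10 exomes x 20 TSJ variants
  m_ts <- out$n_false[out$filter == "N1TS"]
  exp_ts <- expected_distinct_genes(10 * 20)
  expect_lt(abs(mean(m_ts) - exp_ts), 3 * stats::sd(m_ts) / sqrt(n_rep))
})

test_that("cousin concordance thins background to the retention rate", {
  # expected concordant variants per pedigree: (400*.3 + 20) / 8
  des <- stage1_design(m2, 2)
  set.seed(6)
  n_rep <- 40
  out <- purrr::map_dfr(seq_len(n_rep), ~simulate_stage1(des, 10, 15))
  m_conc <- out$n_false[out$filter == "N1RV"]
  exp_conc <- expected_distinct_genes(10 * (400 * 0.3 + 20) / 8)
  expect_lt(abs(mean(m_conc) - exp_conc),
            3 * stats::sd(m_conc) / sqrt(n_rep) + 1)
})

test_that("false-gene counts do not depend on the disease model", {
  des2 <- stage1_design(m2, 1)
  des5 <- stage1_design(model_preset("V"), 1)
  prof <- variant_profile(sensitivity = 0) # isolate the background
  set.seed(7)
  a <- simulate_stage1(des2, 10, 15, prof)
  set.seed(7)
  b <- simulate_stage1(des5, 10, 179, prof)
  expect_equal(a$n_false, b$n_false)
})

test_that("true-gene concordance rate tracks the pedigree probability", {
  # among segregating, detected variants with two sequenced members, the
  # concordant fraction estimates P(cousin carries | proband carries)
  des <- stage1_design(m2, 2)
  expect_equal(round(des$p_conc_true, 2), 0.73)
  prof <- variant_profile(n_rms = 0, n_tsj = 0, sensitivity = 1,
                          bioinf_pass_true_missense = 1)
  set.seed(8)
  out <- purrr::map_dfr(1:60, ~simulate_stage1(des, 20, 15, prof))
  # N1RV (concordant only) over N1RV-with-any: estimate via filters
  n_conc <- sum(out$n_true[out$filter == "N1RV"])
  # count segregating genes from an equivalent run without concordance
  # requirement: min_pedigrees = 1 on ped_any is not exposed, so compare
  # against the expected count instead
  n_seg_expected <- 60 * 15 * (1 - (1 - des$p_carrier)^20)
  frac <- n_conc / n_seg_expected
  # each segregating gene is retained if concordant in >= 1 pedigree;
  # with k segregating pedigrees the retention is 1-(1-.73)^k, so the
  # gene-level rate exceeds .73; just bracket it
  expect_gt(frac, 0.70)
  expect_lte(frac, 1)
})

test_that("unknown filters are rejected", {
  expect_error(filter_specs("N9XX"), "unknown filter")
})

test_that("variant profiles validate their fractions", {
  expect_error(variant_profile(sensitivity = 1.2))
  expect_error(variant_profile(n_genes = 0))
})
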