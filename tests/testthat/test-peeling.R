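test_that("an isolated founder with unknown phenotype has the HW prior", {
  ped <- tibble::tibble(fam = "f", id = 1, dadid = 0, momid = 0, sex = 1,
                        aff = 0L, seq = 0L)
  m <- model_preset("II")
  q <- m$q
  expect_equal(carrier_probability(ped, m, 1), 2 * q * (1 - q) + q^2)
})

test_that("without phenocopies an affected member is almost surely a carrier", {
  # grr * f0 = 1: carriers always affected, non-carriers almost never
  m <- genetic_model(q = 1e-4, f0 = 1e-9, grr = 1e9)
  ped <- tibble::tibble(fam = "f", id = 1, dadid = 0, momid = 0, sex = 1,
                        aff = 2L, seq = 0L)
  expect_gt(carrier_probability(ped, m, 1), 0.99)
})

test_that("peeling equals brute-force enumeration on random pedigrees", {
  set.seed(7101)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    ped <- make_random_pedigree(n)
    m <- genetic_model(
      q = stats::runif(1, 1e-4, 0.2),
      f0 = stats::runif(1, 0.01, 0.2),
      grr = stats::runif(1, 1, 4)
    )
    person <- sample(ped$id, 1)
    expect_equal(
      carrier_probability(ped, m, person),
      brute_carrier_probability(ped, m, person),
      tolerance = 1e-12
    )
  }
})

test_that("joint and conditional carrier probabilities are consistent", {
  set.seed(402)
  for (i in 1:8) {
    ped <- make_random_pedigree(sample(4:8, 1))
    m <- genetic_model(q = 0.05, f0 = 0.05, grr = 3)
    ab <- sample(ped$id, 2)
    joint <- joint_carrier_probability(ped, m, ab)
    pa <- carrier_probability(ped, m, ab[1])
    cond <- joint_carrier_probability(ped, m, ab[2], condition_on = ab[1])
    expect_equal(joint, pa * cond, tolerance = 1e-12)
    # brute-force cross-check of the joint
    ind <- c(0, 1, 1)
    brute_joint <- brute_likelihood(
      ped, m, stats::setNames(list(ind, ind), ab)
    ) / brute_likelihood(ped, m)
    expect_equal(joint, brute_joint, tolerance = 1e-12)
  }
})

test_that("conditioning on a member carrying is idempotent", {
  ped <- make_cousin_ped(aff = c(0, 0, 2, 1, 2, 1, 2, 2))
  m <- model_preset("I")
  expect_equal(joint_carrier_probability(ped, m, 7, condition_on = 7), 1)
})

test_that("genotype posteriors sum to one", {
  set.seed(11)
  for (i in 1:5) {
    ped <- make_random_pedigree(sample(3:7, 1))
    m <- genetic_model(q = 0.1, f0 = 0.1, grr = 2.5)
    for (p in sample(ped$id, 2)) {
      expect_equal(sum(genotype_posterior(ped, m, p)), 1, tolerance = 1e-12)
    }
  }
})

test_that("phenotype evidence moves carrier probabilities as expected", {
  m <- model_preset("II")
  base <- make_trio(aff = c(0, 0, 2))
  richer <- make_trio(aff = c(2, 0, 2)) # affected father too
  expect_gt(carrier_probability(richer, m, 3),
            carrier_probability(base, m, 3))
  # an unaffected parent lowers it
  poorer <- make_trio(aff = c(1, 1, 2))
  expect_lt(carrier_probability(poorer, m, 3),
            carrier_probability(base, m, 3))
})

test_that("multi-family tables are rejected by the peeling layer", {
  two <- dplyr::bind_rows(
    make_trio(),
    dplyr::mutate(make_trio(), fam = "other")
  )
  expect_error(carrier_probability(two, model_preset("I"), 3),
               "single family")
})
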