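# Independent oracles used across tests.

# Brute-force pedigree likelihood: enumerate all 3^n genotype vectors.
# Kept deliberately independent of the peeling implementation (only the
# model-parameter helpers are shared).
brute_likelihood <- function(ped, model, extra = list()) {
  n <- nrow(ped)
  prior <- c((1 - model$q)^2, 2 * model$q * (1 - model$q), model$q^2)
  tp <- c(0, 0.5, 1)
  pen <- c(model$f0, model$f1, model$f1)
  aff_lik <- function(aff, g) {
    switch(as.character(aff),
      "2" = pen[g + 1],
      "1" = 1 - pen[g + 1],
      "0" = 1
    )
  }
  idx <- stats::setNames(seq_len(n), ped$id)
  gs <- as.matrix(expand.grid(rep(list(0:2), n)))
  total <- 0
  for (r in seq_len(nrow(gs))) {
    g <- gs[r, ]
    lik <- 1
    for (i in seq_len(n)) {
      if (ped$dadid[i] == 0) {
        lik <- lik * prior[g[i] + 1]
      } else {
        gf <- g[idx[as.character(ped$dadid[i])]]
        gm <- g[idx[as.character(ped$momid[i])]]
        pf <- tp[gf + 1]
        pm <- tp[gm + 1]
        ptrans <- c((1 - pf) * (1 - pm),
                    pf * (1 - pm) + (1 - pf) * pm,
                    pf * pm)
        lik <- lik * ptrans[g[i] + 1]
      }
      lik <- lik * aff_lik(ped$aff[i], g[i])
      if (lik == 0) break
    }
    if (lik > 0) {
      for (nm in names(extra)) {
        lik <- lik * extra[[nm]][g[idx[nm]] + 1]
      }
    }
    total <- total + lik
  }
  total
}

brute_carrier_probability <- function(ped, model, person) {
  ind <- stats::setNames(list(c(0, 1, 1)), person)
  brute_likelihood(ped, model, ind) / brute_likelihood(ped, model)
}

# closed-form expected number of distinct genes hit by M variants thrown
# uniformly (with replacement) at n_genes genes
expected_distinct_genes <- function(M, n_genes = 25000) {
  n_genes * (1 - (1 - 1 / n_genes)^M)
}

# small fixed trio used in several tests
make_trio <- function(aff = c(1, 1, 2)) {
  tibble::tibble(
    fam = "trio", id = 1:3, dadid = c(0, 0, 1), momid = c(0, 0, 2),
    sex = c(1, 2, 1), aff = as.integer(aff), seq = 0L
  )
}

# first-cousin pedigree: grandparents 1x2; children 3, 5 married to
# founders 4, 6; cousins 7 (of 3,4) and 8 (of 5,6)
make_cousin_ped <- function(aff = rep(0L, 8)) {
  tibble::tibble(
    fam = "c", id = 1:8,
    dadid = c(0, 0, 1, 0, 1, 0, 3, 5),
    momid = c(0, 0, 2, 0, 2, 0, 4, 6),
    sex = c(1, 2, 1, 2, 1, 2, 1, 1),
    aff = as.integer(aff), seq = 0L
  )
}
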