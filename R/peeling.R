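# Exact single-locus pedigree likelihoods by variable elimination.
#
# The genotype of each member (0/1/2 copies of the risk allele) is a
# discrete variable; founders carry Hardy-Weinberg priors, non-founders a
# Mendelian transmission factor linking them to both parents, and every
# member a penetrance factor determined by affection status. Peeling is
# implemented as sum-product variable elimination with a greedy
# smallest-clique ordering, which reproduces Elston-Stewart peeling on
# zero-loop pedigrees and remains exact on pedigrees with marriage loops.

# factor: list(vars = integer ids, tab = array dim rep(3, length(vars)));
# an empty scope holds a scalar
make_factor <- function(vars, tab) {
  vars <- as.integer(vars)
  if (length(vars) == 0) {
    return(list(vars = vars, tab = as.numeric(tab)))
  }
  list(vars = vars, tab = array(tab, dim = rep(3, length(vars))))
}

# expand factor to a variable union (vars must contain f$vars)
factor_expand <- function(f, vars) {
  extra <- setdiff(vars, f$vars)
  tab <- f$tab
  if (length(extra) > 0) {
    tab <- array(tab, dim = c(rep(3, length(f$vars)), rep(3, length(extra))))
  }
  cur <- c(f$vars, extra)
  perm <- match(vars, cur)
  if (length(vars) > 1) tab <- aperm(tab, perm)
  make_factor(vars, tab)
}

factor_multiply <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  make_factor(vars, factor_expand(f1, vars)$tab * factor_expand(f2, vars)$tab)
}

factor_sum_out <- function(f, var) {
  i <- match(var, f$vars)
  keep <- f$vars[-i]
  if (length(keep) == 0) {
    return(make_factor(integer(0), sum(f$tab)))
  }
  tab <- apply(f$tab, seq_along(f$vars)[-i], sum)
  make_factor(keep, tab)
}

# affection-status likelihood vector over genotypes 0/1/2
affection_likelihood <- function(aff, model) {
  pen <- penetrance_vector(model)
  switch(as.character(aff),
    "2" = pen,
    "1" = 1 - pen,
    "0" = rep(1, 3),
    rlang::abort("affection status must be 0, 1 or 2")
  )
}

# Build the factor list for one family; `extra` is a named list mapping
# id -> length-3 genotype weight (e.g. a carrier indicator c(0, 1, 1)).
pedigree_factors <- function(ped, model, extra = list()) {
  trans <- transmission_array()
  prior <- hw_prior(model$q)
  factors <- list()
  for (r in seq_len(nrow(ped))) {
    id <- ped$id[r]
    if (ped$dadid[r] == 0) {
      factors[[length(factors) + 1]] <- make_factor(id, prior)
    } else {
      # trans is [child, father, mother]
      factors[[length(factors) + 1]] <-
        make_factor(c(id, ped$dadid[r], ped$momid[r]), trans)
    }
    factors[[length(factors) + 1]] <-
      make_factor(id, affection_likelihood(ped$aff[r], model))
  }
  for (nm in names(extra)) {
    factors[[length(factors) + 1]] <- make_factor(as.integer(nm), extra[[nm]])
  }
  factors
}

# Sum-product over all genotype configurations; returns the scalar
# likelihood of the phenotypes (times any extra weights).
peel_likelihood <- function(ped, model, extra = list()) {
  if (length(unique(ped$fam)) > 1) {
    rlang::abort("peeling operates on a single family at a time")
  }
  validate_pedigree(ped)
  factors <- pedigree_factors(ped, model, extra)
  vars <- unique(unlist(lapply(factors, `[[`, "vars")))
  for (v in order_elimination(factors, vars)) {
    idx <- which(vapply(factors, function(f) v %in% f$vars, logical(1)))
    prod <- Reduce(factor_multiply, factors[idx])
    factors <- c(factors[-idx], list(factor_sum_out(prod, v)))
  }
  prod <- Reduce(factor_multiply, factors)
  sum(prod$tab)
}

# greedy ordering: repeatedly eliminate the variable whose elimination
# clique is smallest
order_elimination <- function(factors, vars) {
  scopes <- lapply(factors, `[[`, "vars")
  ord <- integer(0)
  vars <- as.integer(vars)
  while (length(vars) > 0) {
    size <- vapply(vars, function(v) {
      length(unique(unlist(scopes[vapply(scopes, function(s) v %in% s,
                                         logical(1))])))
    }, numeric(1))
    v <- vars[which.min(size)]
    idx <- vapply(scopes, function(s) v %in% s, logical(1))
    merged <- setdiff(unique(unlist(scopes[idx])), v)
    scopes <- c(scopes[!idx], list(merged))
    ord <- c(ord, v)
    vars <- setdiff(vars, v)
  }
  ord
}

carrier_indicator <- c(0, 1, 1)

#' Conditional carrier probability of a pedigree member
#'
#' Exact probability that `person` carries at least one risk allele at the
#' locus, given every member's affection status, computed by peeling
#' (sum-product variable elimination) over the three-genotype single-locus
#' model. Equivalent to (but far cheaper than) brute-force enumeration of
#' all genotype vectors.
#'
#' @param ped A single-family pedigree tibble (see [pedigree-format]).
#' @param model A [genetic_model()].
#' @param person Individual id whose carrier status is queried.
#' @return Probability in \[0, 1\].
#' @examples
#' trio <- tibble::tibble(
#'   fam = "f", id = 1:3, dadid = c(0, 0, 1), momid = c(0, 0, 2),
#'   sex = c(1, 2, 1), aff = c(1, 1, 2), seq = 0L
#' )
#' carrier_probability(trio, model_preset("II"), person = 3)
#' @export
carrier_probability <- function(ped, model, person) {
  stopifnot(person %in% ped$id)
  extra <- stats::setNames(list(carrier_indicator), person)
  peel_likelihood(ped, model, extra) / peel_likelihood(ped, model)
}

#' Joint conditional carrier probability of several members
#'
#' Probability that all `persons` carry a risk allele given the pedigree
#' phenotypes, optionally conditioned on a designated carrier
#' (`condition_on`) — the "allele segregating in the family" sense used
#' when asking whether other sequenced relatives share the proband's
#' susceptibility allele.
#'
#' @inheritParams carrier_probability
#' @param persons Ids that must all carry.
#' @param condition_on Optional id assumed to carry.
#' @return Probability in \[0, 1\].
#' @export
joint_carrier_probability <- function(ped, model, persons,
                                      condition_on = NULL) {
  stopifnot(all(persons %in% ped$id))
  ids <- unique(c(persons, condition_on))
  num <- stats::setNames(rep(list(carrier_indicator), length(ids)), ids)
  if (is.null(condition_on)) {
    peel_likelihood(ped, model, num) / peel_likelihood(ped, model)
  } else {
    stopifnot(condition_on %in% ped$id)
    den <- stats::setNames(list(carrier_indicator), condition_on)
    peel_likelihood(ped, model, num) / peel_likelihood(ped, model, den)
  }
}

#' Conditional genotype posterior for one member
#'
#' @inheritParams carrier_probability
#' @return Length-3 numeric vector of posterior probabilities for carrying
#'   0, 1 or 2 risk alleles; sums to 1.
#' @export
genotype_posterior <- function(ped, model, person) {
  stopifnot(person %in% ped$id)
  L <- peel_likelihood(ped, model)
  probs <- vapply(0:2, function(g) {
    ind <- as.numeric(0:2 == g)
    peel_likelihood(ped, model, stats::setNames(list(ind), person)) / L
  }, numeric(1))
  probs
}
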