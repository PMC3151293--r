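#' Stage-II validation design
#'
#' Stage II screens each candidate gene in a panel of `n_peds` additional
#' pedigrees and calls the gene validated when `k_min` or more pedigrees
#' yield a qualifying rare variant. For a gene unrelated to disease, each
#' pedigree yields a qualifying variant with probability `p_false_per_ped`
#' (0.001 by default, reflecting frequency plus bioinformatics filtering);
#' for a true susceptibility gene the per-pedigree probability is the index
#' case's carrier probability under the genetic model (defaults are the
#' canonical values 0.061, 0.040, 0.019, 0.011, 0.005 for models I-V).
#'
#' @param n_peds Number of stage-II pedigrees (default 250).
#' @param k_min Qualifying variants required for validation (default 3).
#' @param p_false_per_ped Per-pedigree qualifying probability for an
#'   unrelated gene (default 0.001).
#' @param p_true_per_ped Named vector of per-model index carrier
#'   probabilities.
#' @return An object of class `stage2_design`.
#' @export
stage2_design <- function(n_peds = 250, k_min = 3, p_false_per_ped = 0.001,
                          p_true_per_ped = c(I = 0.061, II = 0.040,
                                             III = 0.019, IV = 0.011,
                                             V = 0.005)) {
  stopifnot(k_min <= n_peds, p_false_per_ped >= 0, p_false_per_ped <= 1,
            all(p_true_per_ped >= 0), all(p_true_per_ped <= 1))
  structure(
    list(n_peds = as.integer(n_peds), k_min = as.integer(k_min),
         p_false_per_ped = p_false_per_ped,
         p_true_per_ped = p_true_per_ped),
    class = "stage2_design"
  )
}

#' Probability a gene meets the stage-II validation criterion
#'
#' Exact binomial upper tail `P(X >= k)` with `X ~ Binomial(n, p)`: the
#' probability that qualifying variants are found in at least `k` of `n`
#' independent stage-II pedigrees when each yields one with probability
#' `p`.
#'
#' @param p Per-pedigree qualifying-variant probability.
#' @param n Number of stage-II pedigrees.
#' @param k Validation threshold.
#' @return Probability in \[0, 1\].
#' @examples
#' validation_probability(0.019, 250, 3) # ~0.86
#' validation_probability(0.001, 250, 3) # ~0.002
#' @export
validation_probability <- function(p, n, k) {
  stopifnot(all(p >= 0), all(p <= 1), all(n >= 0), all(k >= 0))
  out <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  out[rep_len(k == 0, length(out))] <- 1
  out
}

#' Per-pedigree carrier probability of the stage-II index case
#'
#' Exact peeling of the stage-II pedigree: the probability that the index
#' case (id 8 in the shipped fixture) carries a risk allele at one
#' susceptibility locus given the pedigree phenotypes. This is the
#' per-pedigree success probability for a true gene in the stage-II
#' binomial.
#'
#' @param model A [genetic_model()].
#' @param ped Stage-II pedigree; defaults to the shipped fixture
#'   ([fig1b_pedigree()]).
#' @param index Index-case id (default the fixture's flagged member).
#' @return Probability in \[0, 1\].
#' @export
index_carrier_probability <- function(model, ped = fig1b_pedigree(),
                                      index = NULL) {
  if (is.null(index)) {
    flagged <- ped$id[ped$seq == 1]
    index <- if (length(flagged) > 0) flagged[1] else 8
  }
  carrier_probability(ped, model, index)
}

#' Expected false validations among the screened non-disease genes
#'
#' Each of `n_false_genes` unrelated genes is validated independently with
#' probability `p_gene` (by default the exact binomial tail implied by the
#' design). Returns the expectation and the upper tail
#' `P(more than m validations)`.
#'
#' @param n_false_genes Number of unrelated genes screened in stage II.
#' @param design A [stage2_design()].
#' @param m Tail threshold (default 2: probability of more than 2 false
#'   positives).
#' @param p_gene Per-gene validation probability; defaults to the exact
#'   tail `validation_probability(design$p_false_per_ped, ...)`. Pass a
#'   rounded value (e.g. 0.002) to reproduce back-of-envelope figures.
#' @return A tibble with `expected`, `p_gene`, `m`, `p_more_than_m`.
#' @examples
#' expected_false_validations(300, stage2_design(), p_gene = 0.002)
#' @export
expected_false_validations <- function(n_false_genes,
                                       design = stage2_design(), m = 2,
                                       p_gene = NULL) {
  stopifnot(n_false_genes >= 0)
  if (is.null(p_gene)) {
    p_gene <- validation_probability(design$p_false_per_ped, design$n_peds,
                                     design$k_min)
  }
  if (n_false_genes == 0) {
    return(tibble::tibble(expected = 0, p_gene = p_gene, m = m,
                          p_more_than_m = 0))
  }
  tibble::tibble(
    expected = n_false_genes * p_gene,
    p_gene = p_gene,
    m = m,
    p_more_than_m = stats::pbinom(m, n_false_genes, p_gene,
                                  lower.tail = FALSE)
  )
}

#' Stage-II validation probability table
#'
#' Validation probabilities for true genes under each model and for an
#' unrelated gene, over grids of panel size and validation threshold — the
#' analytic power / type-I-error table of the stage-II design.
#'
#' @param n_peds Panel sizes (default 150, 250, 350).
#' @param k_min Validation thresholds (default 2, 3, 4).
#' @param design A [stage2_design()] supplying the per-pedigree
#'   probabilities.
#' @return A tibble with columns `model` (including `"not_associated"`),
#'   `n_peds`, `k_min`, `p_per_ped`, `p_validated`.
#' @export
stage2_table <- function(n_peds = c(150, 250, 350), k_min = 2:4,
                         design = stage2_design()) {
  probs <- c(not_associated = unname(design$p_false_per_ped),
             design$p_true_per_ped)
  tidyr::expand_grid(
    model = names(probs), n_peds = n_peds, k_min = k_min
  ) |>
    dplyr::mutate(
      p_per_ped = unname(probs[.data$model]),
      p_validated = validation_probability(.data$p_per_ped, .data$n_peds,
                                           .data$k_min)
    )
}
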