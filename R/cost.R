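#' Study cost model
#'
#' Stage I pays per sequenced exome; stage II pays per gene per screened
#' sample. At the defaults an exome costs 400 times one candidate-gene
#' screen ($4000 vs $10) and 250 stage-II samples are screened per gene.
#'
#' @param exome_cost Cost per sequenced exome in stage I (default 4000).
#' @param gene_screen_cost Cost of screening one average-sized gene in one
#'   sample (default 10).
#' @param n_stage2_samples Number of stage-II samples screened per gene
#'   (default 250).
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(exome_cost = 4000, gene_screen_cost = 10,
                       n_stage2_samples = 250) {
  stopifnot(exome_cost > 0, gene_screen_cost > 0, n_stage2_samples > 0)
  structure(
    list(exome_cost = exome_cost, gene_screen_cost = gene_screen_cost,
         n_stage2_samples = n_stage2_samples),
    class = "cost_model"
  )
}

#' Total cost of a two-stage design
#'
#' `exome_cost * N_p * N_s + gene_screen_cost * n_stage2_samples * n_genes`:
#' the sum of stage-I exome sequencing and stage-II per-gene screening.
#' Fractional gene counts (replicate averages) are costed directly.
#'
#' @param n_pedigrees Stage-I pedigrees (N_p).
#' @param n_sequenced_per_ped Sequenced individuals per pedigree (N_s).
#' @param n_genes_stage2 Genes passed to stage II (may be a replicate
#'   average, hence fractional).
#' @param cm A [cost_model()].
#' @return Cost in the cost model's currency units.
#' @examples
#' study_cost(60, 1, 7119 + 14.69) / 1e6 # ~18.1 (million USD)
#' @export
study_cost <- function(n_pedigrees, n_sequenced_per_ped, n_genes_stage2,
                       cm = cost_model()) {
  stopifnot(all(n_pedigrees >= 0), all(n_sequenced_per_ped >= 0),
            all(n_genes_stage2 >= 0))
  cm$exome_cost * n_pedigrees * n_sequenced_per_ped +
    cm$gene_screen_cost * cm$n_stage2_samples * n_genes_stage2
}
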