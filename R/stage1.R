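#' Background variant profile of a sequenced exome
#'
#' Describes the rare-variant landscape assumed per sequenced exome after
#' frequency filtering: 400 rare missense (rms) and 20 truncating/splice
#' junction (TSJ) non-disease variants drawn from 25,000 genes. A
#' bioinformatics filter (conservation, severity of substitution, splicing
#' prediction) passes 30% of background missense variants but 90% of true
#' pathogenic missense variants; TSJ variants are not subject to it. True
#' variants are detected with 90% sensitivity, and a fraction `p_tsj_true`
#' of pathogenic mutations are TSJ.
#'
#' @param n_genes Number of genes in the genome (default 25000).
#' @param n_rms Background rare missense variants per exome (default 400).
#' @param n_tsj Background TSJ variants per exome (default 20).
#' @param bioinf_pass_background Fraction of background rms passing the
#'   bioinformatics filter (default 0.30).
#' @param bioinf_pass_true_missense Fraction of true pathogenic missense
#'   variants passing it (default 0.90).
#' @param sensitivity Detection probability for a true variant present in
#'   the DNA (default 0.90).
#' @param p_tsj_true Fraction of pathogenic mutations that are TSJ
#'   (default 0.50; 0.30 and 0.70 are the examined alternatives).
#' @param sensitivity_per_individual If `TRUE`, detection sensitivity is
#'   applied independently per sequenced individual rather than once per
#'   familial variant (default `FALSE`).
#' @return An object of class `variant_profile`.
#' @export
variant_profile <- function(n_genes = 25000, n_rms = 400, n_tsj = 20,
                            bioinf_pass_background = 0.30,
                            bioinf_pass_true_missense = 0.90,
                            sensitivity = 0.90, p_tsj_true = 0.50,
                            sensitivity_per_individual = FALSE) {
  fracs <- c(bioinf_pass_background, bioinf_pass_true_missense,
             sensitivity, p_tsj_true)
  stopifnot(all(fracs >= 0), all(fracs <= 1),
            n_genes >= 1, n_rms >= 0, n_tsj >= 0)
  structure(
    list(
      n_genes = as.integer(n_genes), n_rms = as.integer(n_rms),
      n_tsj = as.integer(n_tsj),
      bioinf_pass_background = bioinf_pass_background,
      bioinf_pass_true_missense = bioinf_pass_true_missense,
      sensitivity = sensitivity, p_tsj_true = p_tsj_true,
      sensitivity_per_individual = sensitivity_per_individual
    ),
    class = "variant_profile"
  )
}

#' Gene-selection filters applied between stage I and stage II
#'
#' The five named filters combine three ideas: how many distinct pedigrees
#' must contribute a rare variant (RV) to a gene (1, 2 or 3), whether at
#' least one contributing RV must be truncating/splice (TSJ), and — when
#' two or more individuals are sequenced per pedigree — within-pedigree
#' concordance. For the single-observation filters (N1RV/N1TS) the
#' qualifying variant itself must be concordant; for the multi-pedigree
#' filters (N2RV/N2TS/N3RV) pedigrees contribute with any variant but at
#' least one contributing pedigree must be concordant.
#'
#' @param names Filters to return (default all five).
#' @return A tibble with columns `filter`, `min_pedigrees`, `require_tsj`.
#' @export
filter_specs <- function(names = c("N1RV", "N1TS", "N2RV", "N2TS", "N3RV")) {
  all <- tibble::tibble(
    filter = c("N1RV", "N1TS", "N2RV", "N2TS", "N3RV"),
    min_pedigrees = c(1L, 1L, 2L, 2L, 3L),
    require_tsj = c(FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  bad <- setdiff(names, all$filter)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown filter(s): ", paste(bad, collapse = ", ")))
  }
  all[match(names, all$filter), ]
}

#' Precompute the pedigree-derived quantities a stage-I design needs
#'
#' From the stage-I pedigree, the genetic model, and the number of
#' sequenced members, derives everything the per-replicate simulator
#' consumes: the per-locus carrier posterior of the proband given the
#' pedigree phenotypes (via exact peeling), the probability that the other
#' sequenced members also carry a segregating susceptibility allele
#' (true-variant concordance), and the IBD sharing pattern distribution of
#' rare background variants among the sequenced members.
#'
#' @param model A [genetic_model()].
#' @param n_s Number of sequenced members (1, 2, or 3).
#' @param ped Stage-I pedigree; defaults to the shipped high-risk pedigree
#'   fixture ([fig1a_pedigree()]).
#' @param members Ids of sequenced members, proband first; defaults to the
#'   fixture's flagged members ordered as proband, cousin, aunt/uncle.
#' @return A list of class `stage1_design` with elements `n_s`, `members`,
#'   `p_carrier`, `p_conc_true`, and `bg_pattern` (per-variant probability
#'   over sharing patterns of the non-proband members).
#' @export
stage1_design <- function(model, n_s, ped = fig1a_pedigree(),
                          members = NULL) {
  stopifnot(n_s %in% 1:3)
  if (is.null(members)) {
    flagged <- ped$id[ped$seq == 1]
    # canonical order for the shipped fixture: proband 8, cousin 11,
    # aunt/uncle 5; otherwise take the flagged members in file order
    canonical <- intersect(c(8, 11, 5), flagged)
    members <- if (length(canonical) == length(flagged)) canonical else flagged
  }
  if (length(members) < n_s) {
    rlang::abort("fewer sequenced members available than n_s")
  }
  members <- members[seq_len(n_s)]
  p_carrier <- carrier_probability(ped, model, members[1])
  p_conc_true <- if (n_s >= 2) {
    joint_carrier_probability(ped, model, members[-1],
                              condition_on = members[1])
  } else {
    1
  }
  bg_pattern <- bg_sharing_pattern(ped, members)
  structure(
    list(
      n_s = n_s, members = members, model = model$name,
      p_carrier = p_carrier, p_conc_true = p_conc_true,
      bg_pattern = bg_pattern
    ),
    class = "stage1_design"
  )
}

# joint distribution of which non-proband sequenced members share a rare
# background variant carried by the proband; returns a matrix of patterns
# (columns = other members, 0/1) with a probability per row
bg_sharing_pattern <- function(ped, members) {
  k <- length(members)
  if (k == 1) {
    return(list(patterns = matrix(0L, 1, 0), prob = 1))
  }
  others <- members[-1]
  if (k == 2) {
    p <- pairwise_sharing_probability(ped, members[1], others)
    return(list(
      patterns = matrix(c(0L, 1L), 2, 1,
                        dimnames = list(NULL, as.character(others))),
      prob = c(1 - p, p)
    ))
  }
  p2 <- pairwise_sharing_probability(ped, members[1], others[1])
  p3 <- pairwise_sharing_probability(ped, members[1], others[2])
  t3 <- ibd_concordance_probability(ped, members[1], others)
  prob <- c(
    `00` = 1 - p2 - p3 + t3,
    `10` = p2 - t3,
    `01` = p3 - t3,
    `11` = t3
  )
  list(
    patterns = matrix(c(0L, 1L, 0L, 1L, 0L, 0L, 1L, 1L), 4, 2,
                      dimnames = list(NULL, as.character(others))),
    prob = prob
  )
}

# --- per-replicate simulation -----------------------------------------

# background variants for one pedigree; returns parallel vectors
# gene / tsj / concordant over the union of the sequenced members' variants
sim_background_pedigree <- function(profile, design) {
  n_rms_pass <- stats::rbinom(1, profile$n_rms, profile$bioinf_pass_background)
  n1 <- n_rms_pass + profile$n_tsj
  gene <- sample.int(profile$n_genes, n1, replace = TRUE)
  tsj <- c(rep(FALSE, n_rms_pass), rep(TRUE, profile$n_tsj))
  if (design$n_s == 1) {
    return(list(gene = gene, tsj = tsj, conc = rep(TRUE, n1)))
  }
  bp <- design$bg_pattern
  pat_idx <- sample.int(length(bp$prob), n1, replace = TRUE, prob = bp$prob)
  shared <- bp$patterns[pat_idx, , drop = FALSE]
  conc <- rowSums(shared) == ncol(shared)
  # top up the other members to their own per-exome totals with variants
  # that cannot be concordant (absent from the proband)
  extra_gene <- integer(0)
  extra_tsj <- logical(0)
  for (j in seq_len(ncol(shared))) {
    own_rms <- stats::rbinom(1, profile$n_rms, profile$bioinf_pass_background)
    shared_rms <- sum(shared[, j] == 1L & !tsj)
    shared_tsj <- sum(shared[, j] == 1L & tsj)
    add_rms <- max(0L, own_rms - shared_rms)
    add_tsj <- max(0L, profile$n_tsj - shared_tsj)
    extra_gene <- c(extra_gene,
                    sample.int(profile$n_genes, add_rms + add_tsj,
                               replace = TRUE))
    extra_tsj <- c(extra_tsj, rep(FALSE, add_rms), rep(TRUE, add_tsj))
  }
  list(
    gene = c(gene, extra_gene),
    tsj = c(tsj, extra_tsj),
    conc = c(conc, rep(FALSE, length(extra_gene)))
  )
}

# true susceptibility variants for one pedigree: each of the n_loci genes
# segregates independently with the proband's per-locus carrier posterior
sim_true_pedigree <- function(profile, design, n_loci) {
  seg <- which(stats::runif(n_loci) < design$p_carrier)
  if (length(seg) == 0) {
    return(list(gene = integer(0), tsj = logical(0), conc = logical(0)))
  }
  tsj <- stats::runif(length(seg)) < profile$p_tsj_true
  detected <- stats::runif(length(seg)) < profile$sensitivity
  bioinf <- tsj | (stats::runif(length(seg)) <
                     profile$bioinf_pass_true_missense)
  keep <- detected & bioinf
  conc <- if (design$n_s >= 2) {
    stats::runif(length(seg)) < design$p_conc_true
  } else {
    rep(TRUE, length(seg))
  }
  if (design$n_s >= 2 && profile$sensitivity_per_individual) {
    conc <- conc &
      (stats::runif(length(seg)) <
         profile$sensitivity^(design$n_s - 1))
  }
  list(gene = seg[keep], tsj = tsj[keep], conc = conc[keep])
}

#' Simulate one stage-I replicate
#'
#' Simulates `n_p` pedigrees: background variants per sequenced exome
#' (binomially thinned by the bioinformatics filter and assigned uniformly
#' over genes, with IBD-driven sharing among co-sequenced relatives) plus
#' true susceptibility variants segregating with the pedigree's carrier
#' posterior, then applies each requested filter.
#'
#' @param design A [stage1_design()].
#' @param n_p Number of stage-I pedigrees.
#' @param n_loci Number of true susceptibility loci (genes 1..`n_loci`).
#' @param profile A [variant_profile()].
#' @param filters A [filter_specs()] tibble.
#' @return A tibble with one row per filter: `filter`, `n_true`, `n_false`.
#' @export
simulate_stage1 <- function(design, n_p, n_loci,
                            profile = variant_profile(),
                            filters = filter_specs()) {
  # Background (false-gene) and true-gene evidence are tallied separately:
  # a true gene is counted as passed only on the strength of its own
  # segregating variants, and the 25,000-gene background universe yields
  # the false-gene count (gene-index collisions between the two are
  # negligible at these scales and are not modelled).
  tally <- function(n) {
    list(ped_any = integer(n), ped_conc = integer(n),
         ped_conc_tsj = integer(n), any_tsj = logical(n))
  }
  add_ped <- function(tl, gene, tsj, conc) {
    if (length(gene) == 0) return(tl)
    g <- unique(gene)
    tl$ped_any[g] <- tl$ped_any[g] + 1L
    g <- unique(gene[conc])
    tl$ped_conc[g] <- tl$ped_conc[g] + 1L
    g <- unique(gene[conc & tsj])
    tl$ped_conc_tsj[g] <- tl$ped_conc_tsj[g] + 1L
    tl$any_tsj[unique(gene[tsj])] <- TRUE
    tl
  }
  bg_tally <- tally(profile$n_genes)
  true_tally <- tally(n_loci)
  # background for all pedigrees first, so that at a fixed seed the
  # background realization does not depend on the disease model
  for (i in seq_len(n_p)) {
    bg <- sim_background_pedigree(profile, design)
    bg_tally <- add_ped(bg_tally, bg$gene, bg$tsj, bg$conc)
  }
  for (i in seq_len(n_p)) {
    tr <- sim_true_pedigree(profile, design, n_loci)
    true_tally <- add_ped(true_tally, tr$gene, tr$tsj, tr$conc)
  }
  passing <- function(tl, min_pedigrees, require_tsj) {
    if (min_pedigrees == 1L) {
      pass <- (if (require_tsj) tl$ped_conc_tsj else tl$ped_conc) >= 1L
    } else {
      pass <- tl$ped_any >= min_pedigrees & tl$ped_conc >= 1L
      if (require_tsj) pass <- pass & tl$any_tsj
    }
    sum(pass)
  }
  purrr::pmap_dfr(filters, function(filter, min_pedigrees, require_tsj) {
    tibble::tibble(
      filter = filter,
      n_true = passing(true_tally, min_pedigrees, require_tsj),
      n_false = passing(bg_tally, min_pedigrees, require_tsj)
    )
  })
}
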