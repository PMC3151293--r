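# Identity-by-descent algebra for rare background variants.
#
# Background (non-disease) variants are so rare that two relatives share
# one only by descent from a common ancestor, never by independent
# recurrence. Sharing probabilities therefore reduce to kinship/descent
# computations on the pedigree graph.

#' Kinship coefficient between two pedigree members
#'
#' Classic recursive kinship: `phi(a, a) = 1/2 (1 + phi(father, mother))`,
#' `phi(a, b) = 1/2 (phi(father_a, b) + phi(mother_a, b))` taking `a` as
#' the member that is not an ancestor of `b`.
#'
#' @param ped A single-family pedigree tibble (see [pedigree-format]).
#' @param a,b Individual ids.
#' @return The kinship coefficient.
#' @export
kinship_coef <- function(ped, a, b) {
  stopifnot(all(c(a, b) %in% ped$id))
  dad <- stats::setNames(ped$dadid, ped$id)
  mom <- stats::setNames(ped$momid, ped$id)
  # generation depth so recursion always descends
  depth <- stats::setNames(rep(0L, nrow(ped)), ped$id)
  repeat {
    new <- ifelse(dad[as.character(ped$id)] == 0, 0L,
                  pmax(depth[as.character(dad[as.character(ped$id)])],
                       depth[as.character(mom[as.character(ped$id)])]) + 1L)
    new <- stats::setNames(as.integer(new), ped$id)
    if (identical(new, depth)) break
    depth <- new
  }
  phi <- function(x, y) {
    cx <- as.character(x); cy <- as.character(y)
    if (x == y) {
      if (dad[cx] == 0) return(0.5)
      return(0.5 * (1 + phi(dad[cx], mom[cx])))
    }
    # recurse on the deeper member
    if (depth[cx] < depth[cy]) { tmp <- x; x <- y; y <- tmp }
    cx <- as.character(x)
    if (dad[cx] == 0) return(0)
    0.5 * (phi(dad[cx], y) + phi(mom[cx], y))
  }
  phi(a, b)
}

#' Probability a rare variant carried by one member is shared by another
#'
#' For an outbred pair this is twice the kinship coefficient: the chance
#' that a variant observed on one of `a`'s haplotypes is identical by
#' descent with a haplotype of `b`.
#'
#' @inheritParams kinship_coef
#' @return Probability in \[0, 1\].
#' @examples
#' # parent-child: 1/2; first cousins: 1/8
#' @export
pairwise_sharing_probability <- function(ped, a, b) {
  stopifnot(a != b)
  2 * kinship_coef(ped, a, b)
}

#' Background-variant retention under a two-relative concordance filter
#'
#' Two relatives of degree `D` share a rare neutral variant with
#' probability `2^-D`. Requiring concordance across the union of their
#' variants therefore retains `1 / (2^(D+1) - 1)` of the union and
#' excludes `(2^(D+1) - 2) / (2^(D+1) - 1)`.
#'
#' @param D Degree of relationship (1 = sibling/parent-offspring,
#'   3 = first cousins).
#' @return Tibble with columns `degree`, `sharing`, `retained`, `excluded`.
#' @examples
#' background_retention(3) # cousins: excluded 14/15
#' @export
background_retention <- function(D) {
  stopifnot(all(D >= 1), all(D == round(D)))
  tibble::tibble(
    degree = D,
    sharing = 2^-D,
    retained = 1 / (2^(D + 1) - 1),
    excluded = (2^(D + 1) - 2) / (2^(D + 1) - 1)
  )
}

# enumerate/sample inheritance vectors: each non-founder draws one paternal
# and one maternal meiosis bit. Returns haplotype label matrices.
gene_drop_labels <- function(ped, bits) {
  n <- nrow(ped)
  id_idx <- stats::setNames(seq_len(n), ped$id)
  # topological order (parents before children)
  ord <- integer(0)
  placed <- rep(FALSE, n)
  while (length(ord) < n) {
    ready <- which(!placed &
                     (ped$dadid == 0 | placed[id_idx[as.character(ped$dadid)]]) &
                     (ped$momid == 0 | placed[id_idx[as.character(ped$momid)]]))
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  n_cfg <- nrow(bits)
  pat <- mat <- matrix(0L, n_cfg, n)
  lab <- 0L
  bit_col <- 0L
  for (i in ord) {
    if (ped$dadid[i] == 0) {
      pat[, i] <- lab + 1L
      mat[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      di <- id_idx[as.character(ped$dadid[i])]
      mi <- id_idx[as.character(ped$momid[i])]
      b1 <- bits[, bit_col + 1L]
      b2 <- bits[, bit_col + 2L]
      bit_col <- bit_col + 2L
      pat[, i] <- ifelse(b1 == 0L, pat[, di], mat[, di])
      mat[, i] <- ifelse(b2 == 0L, pat[, mi], mat[, mi])
    }
  }
  list(pat = pat, mat = mat, id_idx = id_idx)
}

#' Joint IBD concordance probability among a set of members
#'
#' Probability that a rare neutral variant observed in `from` (on a
#' uniformly chosen haplotype) is carried identical-by-descent by every
#' member of `others`. Computed exactly by enumerating all inheritance
#' vectors when the pedigree has at most `max_exact` non-founders, and by
#' seeded Monte Carlo gene dropping otherwise.
#'
#' @inheritParams kinship_coef
#' @param from Id of the member observed to carry the variant.
#' @param others Ids that must share it.
#' @param max_exact Maximum number of non-founders for exact enumeration
#'   (default 10; 4^10 inheritance vectors).
#' @param n_mc Monte Carlo drops used beyond that (default 2e5).
#' @param seed Seed for the Monte Carlo fallback.
#' @return Probability in \[0, 1\].
#' @export
ibd_concordance_probability <- function(ped, from, others, max_exact = 10,
                                        n_mc = 2e5, seed = 1L) {
  validate_pedigree(ped)
  stopifnot(from %in% ped$id, all(others %in% ped$id), !(from %in% others))
  nonf <- sum(ped$dadid != 0)
  if (nonf <= max_exact) {
    m <- 2L * nonf
    if (m == 0) {
      bits <- matrix(0L, 1, 0)
    } else {
      bits <- as.matrix(expand.grid(rep(list(0:1), m)))
    }
  } else {
    withr_seed <- seed
    old <- .Random.seed_exists()
    set.seed(withr_seed)
    bits <- matrix(sample(0:1, 2L * nonf * n_mc, replace = TRUE),
                   nrow = n_mc)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  gd <- gene_drop_labels(ped, bits)
  fi <- gd$id_idx[as.character(from)]
  # average over which of `from`'s two haplotypes bears the variant
  share_given <- function(label_vec) {
    ok <- rep(TRUE, length(label_vec))
    for (o in others) {
      oi <- gd$id_idx[as.character(o)]
      ok <- ok & (gd$pat[, oi] == label_vec | gd$mat[, oi] == label_vec)
    }
    mean(ok)
  }
  0.5 * share_given(gd$pat[, fi]) + 0.5 * share_given(gd$mat[, fi])
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

#' Monte Carlo gene-dropping check of concordance filtering
#'
#' Drops `n_variants` independent rare neutral variants (each assigned to a
#' uniformly chosen founder haplotype) through the pedigree and reports the
#' realized union size and concordant count over a set of sequenced
#' members. Used to validate the closed-form retention/exclusion algebra.
#'
#' @inheritParams kinship_coef
#' @param members Ids of the sequenced members.
#' @param n_variants Number of neutral variants to drop.
#' @return Tibble with columns `union`, `concordant`, `retained_fraction`.
#' @export
gene_drop_concordance <- function(ped, members, n_variants = 1e4) {
  validate_pedigree(ped)
  stopifnot(all(members %in% ped$id))
  nonf <- sum(ped$dadid != 0)
  bits <- matrix(sample(0:1, 2L * nonf * n_variants, replace = TRUE),
                 nrow = n_variants)
  gd <- gene_drop_labels(ped, bits)
  founders <- which(ped$dadid == 0)
  # one variant per drop, on a random founder haplotype
  lab <- 2L * (sample(seq_along(founders), n_variants, replace = TRUE) - 1L) +
    sample(1:2, n_variants, replace = TRUE)
  idx <- gd$id_idx[as.character(members)]
  carried <- vapply(idx, function(i) {
    gd$pat[cbind(seq_len(n_variants), i)] == lab |
      gd$mat[cbind(seq_len(n_variants), i)] == lab
  }, logical(n_variants))
  in_union <- rowSums(carried) > 0
  concordant <- rowSums(carried) == length(members)
  tibble::tibble(
    union = sum(in_union),
    concordant = sum(concordant),
    retained_fraction = sum(concordant) / sum(in_union)
  )
}

#' Expected union and concordant background-variant fractions for a set of
#' sequenced relatives
#'
#' Inclusion-exclusion over the IBD sharing probabilities: with each member
#' carrying `v` variants, the expected union is
#' `v * (k - sum of pairwise sharings + higher-order terms)` and the
#' expected concordant count is `v * P(all share)`. Returns the scale-free
#' fractions (per `v`).
#'
#' @inheritParams kinship_coef
#' @param members Ids of sequenced members (2 or 3 supported analytically).
#' @return Tibble with `union_per_v`, `concordant_per_v`, `retained`,
#'   `excluded`.
#' @export
concordance_fractions <- function(ped, members) {
  k <- length(members)
  stopifnot(k %in% c(2, 3))
  if (k == 2) {
    p <- pairwise_sharing_probability(ped, members[1], members[2])
    union <- 2 - p
    conc <- p
  } else {
    p12 <- pairwise_sharing_probability(ped, members[1], members[2])
    p13 <- pairwise_sharing_probability(ped, members[1], members[3])
    p23 <- pairwise_sharing_probability(ped, members[2], members[3])
    t3 <- ibd_concordance_probability(ped, members[1], members[-1])
    union <- 3 - p12 - p13 - p23 + t3
    conc <- t3
  }
  tibble::tibble(
    union_per_v = union,
    concordant_per_v = conc,
    retained = conc / union,
    excluded = 1 - conc / union
  )
}
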