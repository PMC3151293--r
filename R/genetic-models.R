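#' Define a single-locus genetic architecture
#'
#' A genetic model describes one susceptibility locus of a multiplicative
#' multi-locus architecture: the aggregate frequency `q` of risk alleles in
#' the gene, the sporadic (non-carrier) disease rate `f0`, and the genotype
#' relative risk `grr` conferred by carrying at least one risk allele
#' (dominant penetrance, so carrier penetrance is `f1 = grr * f0`).  The
#' number of such loci in the genome is derived so that, acting
#' multiplicatively, they account for a target aggregate familial relative
#' risk to first-degree relatives (`frr_total_target`, default 1.33).
#'
#' @param q Risk-allele frequency of the locus (aggregate over all
#'   pathogenic variants in the gene), in (0, 1).
#' @param f0 Sporadic rate: disease probability for non-carriers, in (0, 1).
#' @param grr Genotype relative risk (>= 1); carrier penetrance is
#'   `grr * f0` and must not exceed 1.
#' @param name Optional label for the model.
#' @param frr_total_target Aggregate first-degree familial relative risk the
#'   full set of loci should explain (default 1.33).
#'
#' @return An object of class `genetic_model`: a list with fields `name`,
#'   `q`, `f0`, `grr`, `f1`, `frr_total_target`.
#' @seealso [model_preset()] for the five canonical architectures,
#'   [prevalence()], [locus_frr()], [num_loci()].
#' @examples
#' m <- genetic_model(q = 1e-4, f0 = 0.02, grr = 15, name = "II")
#' locus_frr(m)
#' num_loci(m)
#' @export
genetic_model <- function(q, f0, grr, name = NULL,
                          frr_total_target = 1.33) {
  stopifnot(is.numeric(q), length(q) == 1, q >= 0, q < 1)
  stopifnot(is.numeric(f0), length(f0) == 1, f0 > 0, f0 < 1)
  stopifnot(is.numeric(grr), length(grr) == 1, grr >= 1)
  f1 <- grr * f0
  if (f1 > 1) {
    rlang::abort("carrier penetrance grr * f0 exceeds 1")
  }
  structure(
    list(
      name = name %||% sprintf("q=%g,f0=%g,grr=%g", q, f0, grr),
      q = q, f0 = f0, grr = grr, f1 = f1,
      frr_total_target = frr_total_target
    ),
    class = "genetic_model"
  )
}

#' @export
print.genetic_model <- function(x, ...) {
  cat(sprintf(
    "<genetic_model %s>  q = %g, f0 = %g, GRR = %g, f1 = %g\n",
    x$name, x$q, x$f0, x$grr, x$f1
  ))
  if (x$q > 0 && x$grr > 1) {
    cat(sprintf(
      "  prevalence %.6f, locus FRR %.5f, loci for aggregate FRR %.2f: %d\n",
      prevalence(x), locus_frr(x), x$frr_total_target, num_loci(x)
    ))
  }
  invisible(x)
}

# Hardy-Weinberg genotype prior over 0/1/2 copies of the risk allele
hw_prior <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# dominant penetrance vector over genotypes 0/1/2
penetrance_vector <- function(model) c(model$f0, model$f1, model$f1)

# P(child genotype | father genotype, mother genotype); 3x3x3 array
# indexed [child+1, father+1, mother+1]
transmission_array <- function() {
  tp <- c(0, 0.5, 1) # P(transmit risk allele | genotype)
  arr <- array(0, dim = c(3, 3, 3))
  for (gf in 0:2) {
    for (gm in 0:2) {
      pf <- tp[gf + 1]
      pm <- tp[gm + 1]
      arr[1, gf + 1, gm + 1] <- (1 - pf) * (1 - pm)
      arr[2, gf + 1, gm + 1] <- pf * (1 - pm) + (1 - pf) * pm
      arr[3, gf + 1, gm + 1] <- pf * pm
    }
  }
  arr
}

#' Population prevalence under a genetic model
#'
#' Exact enumeration of the three Hardy-Weinberg genotypes:
#' `K = sum_g P(g) * penetrance(g)` with dominant penetrance.
#'
#' @param model A [genetic_model()].
#' @return Disease prevalence (probability).
#' @examples
#' prevalence(genetic_model(q = 1e-4, f0 = 0.02, grr = 20))
#' @export
prevalence <- function(model) {
  stopifnot(inherits(model, "genetic_model"))
  sum(hw_prior(model$q) * penetrance_vector(model))
}

#' Locus-specific familial relative risk to first-degree relatives
#'
#' Computes `lambda_R = P(relative affected | proband affected) / K` for a
#' parent-offspring pair by exact enumeration of the joint genotype
#' distribution under Hardy-Weinberg equilibrium and Mendelian transmission.
#' For the rare, dominant architectures considered here sibling and
#' offspring relative risks agree to printed precision, so the unambiguous
#' parent-offspring pair is used.
#'
#' @inheritParams prevalence
#' @return The locus familial relative risk (dimensionless, >= 1).
#' @examples
#' locus_frr(genetic_model(q = 1e-4, f0 = 0.02, grr = 15)) # ~1.02
#' @export
locus_frr <- function(model) {
  stopifnot(inherits(model, "genetic_model"))
  prior <- hw_prior(model$q)
  pen <- penetrance_vector(model)
  trans <- transmission_array()
  K <- sum(prior * pen)
  # joint expectation E[f(g_parent) f(g_child)]; spouse genotype integrated
  # over the population
  joint <- 0
  for (gp in 0:2) {
    # P(child genotype | one parent gp, other parent random)
    p_child <- numeric(3)
    for (gs in 0:2) {
      p_child <- p_child + prior[gs + 1] * trans[, gp + 1, gs + 1]
    }
    joint <- joint + prior[gp + 1] * pen[gp + 1] * sum(p_child * pen)
  }
  joint / K^2
}

#' Number of susceptibility loci implied by the aggregate familial risk
#'
#' Under multiplicative loci, `N = log(FRR_total) / log(lambda_R)` rounded
#' to the nearest integer, where `lambda_R` is the *unrounded* locus
#' familial relative risk from [locus_frr()].
#'
#' @inheritParams prevalence
#' @return Integer number of loci (>= 1).
#' @examples
#' num_loci(genetic_model(q = 1e-4, f0 = 0.02, grr = 5)) # 179
#' @export
num_loci <- function(model) {
  lam <- locus_frr(model)
  if (lam <= 1) {
    rlang::abort("locus FRR <= 1: no familial effect, locus count undefined")
  }
  as.integer(round(log(model$frr_total_target) / log(lam)))
}

# the five canonical architectures: GRR 20/15/10/7.5/5 on a 0.02 sporadic
# rate with per-gene allele frequency 1e-4
.model_presets <- list(
  I   = list(grr = 20,  f1 = 0.40),
  II  = list(grr = 15,  f1 = 0.30),
  III = list(grr = 10,  f1 = 0.20),
  IV  = list(grr = 7.5, f1 = 0.15),
  V   = list(grr = 5,   f1 = 0.10)
)

#' Canonical disease architectures ("I" .. "V")
#'
#' Five named presets spanning genotype relative risks 20, 15, 10, 7.5 and
#' 5 at sporadic rate 0.02 and per-gene risk-allele frequency 1e-4. Their
#' derived locus counts are 8, 15, 35, 68 and 179 respectively.
#'
#' @param name One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @return A [genetic_model()].
#' @examples
#' model_preset("IV")
#' @export
model_preset <- function(name) {
  name <- match.arg(name, names(.model_presets))
  p <- .model_presets[[name]]
  genetic_model(q = 1e-4, f0 = 0.02, grr = p$grr, name = name)
}

#' All preset architectures as a tibble
#'
#' One row per preset model with its parameters and the derived prevalence,
#' locus familial relative risk, and locus count.
#'
#' @param names Which presets to include (default all five).
#' @return A tibble with columns `model`, `q`, `f0`, `grr`, `f1`,
#'   `prevalence`, `locus_frr`, `n_loci`.
#' @examples
#' model_grid()
#' @export
model_grid <- function(names = c("I", "II", "III", "IV", "V")) {
  purrr::map_dfr(names, function(nm) {
    m <- model_preset(nm)
    tibble::tibble(
      model = nm, q = m$q, f0 = m$f0, grr = m$grr, f1 = m$f1,
      prevalence = prevalence(m),
      locus_frr = locus_frr(m),
      n_loci = num_loci(m)
    )
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genetic model into a one-row tibble
#'
#' @param x A [genetic_model()].
#' @param ... Unused.
#' @return A one-row tibble of parameters and derived quantities.
#' @method tidy genetic_model
#' @export
tidy.genetic_model <- function(x, ...) {
  tibble::tibble(
    model = x$name, q = x$q, f0 = x$f0, grr = x$grr, f1 = x$f1,
    prevalence = prevalence(x),
    locus_frr = locus_frr(x),
    n_loci = if (x$q > 0 && x$grr > 1) num_loci(x) else NA_integer_
  )
}
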