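#' Build a grid of design cells
#'
#' One row per (model, filter, stage-I pedigree count, sequenced members)
#' combination to be evaluated by [run_grid()]. The default grid mirrors
#' the full study: models I-V, all five filters, 10-80 pedigrees, 1-3
#' sequenced members, 100 replicates.
#'
#' @param models Model preset names.
#' @param filters Filter names (see [filter_specs()]).
#' @param n_p Stage-I pedigree counts.
#' @param n_s Sequenced members per pedigree.
#' @param n_replicates Replicates per cell.
#' @return A tibble of design cells.
#' @export
design_grid <- function(models = c("I", "II", "III", "IV", "V"),
                        filters = c("N1RV", "N1TS", "N2RV", "N2TS", "N3RV"),
                        n_p = c(10, 20, 30, 40, 60, 80),
                        n_s = 1:3, n_replicates = 100) {
  filter_specs(filters) # validates names
  for (m in models) model_preset(m) # validates names
  tidyr::expand_grid(
    model = models, filter = filters, n_p = as.integer(n_p),
    n_s = as.integer(n_s), n_replicates = as.integer(n_replicates)
  )
}

# deterministic 32-bit seed from a base seed and a cell/replicate key;
# stable across platforms and execution order
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(paste0(seed, ":", key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate a grid of two-stage designs by Monte Carlo simulation
#'
#' For every cell, simulates `n_replicates` independent stage-I
#' experiments (see [simulate_stage1()]), records the number of true and
#' false genes passed to stage II, and prices the study with the cost
#' model. Replicates are seeded individually from `seed` and the cell
#' coordinates, so results are reproducible and independent of execution
#' order.
#'
#' @param cells A tibble from [design_grid()] (any subset of its rows).
#' @param profile A [variant_profile()].
#' @param ped Stage-I pedigree (default [fig1a_pedigree()]).
#' @param cm A [cost_model()].
#' @param seed Integer base seed.
#' @return A tibble of class `design_eval`: one row per cell with
#'   `mean_true`, `sd_true`, `mean_false`, `sd_false`, `mean_cost`,
#'   `proportion_true`.
#' @examples
#' \donttest{
#' cells <- design_grid(models = "II", filters = "N2RV", n_p = 20,
#'                      n_s = 1, n_replicates = 20)
#' run_grid(cells, seed = 1)
#' }
#' @export
run_grid <- function(cells, profile = variant_profile(),
                     ped = fig1a_pedigree(), cm = cost_model(), seed = 1L) {
  stopifnot(all(c("model", "filter", "n_p", "n_s", "n_replicates")
                %in% names(cells)))
  if (nrow(cells) == 0 || all(cells$n_replicates == 0)) {
    out <- tibble::tibble(
      model = character(0), filter = character(0), n_p = integer(0),
      n_s = integer(0), n_replicates = integer(0),
      mean_true = numeric(0), sd_true = numeric(0),
      mean_false = numeric(0), sd_false = numeric(0),
      mean_cost = numeric(0), proportion_true = numeric(0)
    )
    class(out) <- c("design_eval", class(out))
    return(out)
  }
  groups <- dplyr::distinct(cells, .data$model, .data$n_p, .data$n_s,
                            .data$n_replicates)
  res <- purrr::pmap_dfr(groups, function(model, n_p, n_s, n_replicates) {
    gm <- model_preset(model)
    des <- stage1_design(gm, n_s, ped = ped)
    n_loci <- num_loci(gm)
    flt_names <- unique(cells$filter[cells$model == model &
                                       cells$n_p == n_p &
                                       cells$n_s == n_s])
    flts <- filter_specs(flt_names)
    reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
      key <- paste(model, n_p, n_s, r, sep = "/")
      set.seed(derive_seed(seed, key))
      out <- simulate_stage1(des, n_p, n_loci, profile, flts)
      out$replicate <- r
      out
    })
    reps |>
      dplyr::mutate(
        cost = study_cost(n_p, n_s, .data$n_true + .data$n_false, cm)
      ) |>
      dplyr::group_by(.data$filter) |>
      dplyr::summarise(
        mean_true = mean(.data$n_true), sd_true = stats::sd(.data$n_true),
        mean_false = mean(.data$n_false),
        sd_false = stats::sd(.data$n_false),
        mean_cost = mean(.data$cost), .groups = "drop"
      ) |>
      dplyr::mutate(
        model = model, n_p = n_p, n_s = n_s, n_replicates = n_replicates,
        proportion_true = .data$mean_true / n_loci
      )
  })
  out <- dplyr::select(
    res, "model", "filter", "n_p", "n_s", "n_replicates",
    "mean_true", "sd_true", "mean_false", "sd_false", "mean_cost",
    "proportion_true"
  )
  class(out) <- c("design_eval", class(out))
  out
}

#' Per-replicate stage-I results in tidy form
#'
#' Like [run_grid()] but returns one row per replicate x filter, for
#' inspection of replicate variability or custom summaries.
#'
#' @inheritParams run_grid
#' @return A tibble with columns `model`, `filter`, `n_p`, `n_s`,
#'   `replicate`, `n_true`, `n_false`, `cost`.
#' @export
run_replicates <- function(cells, profile = variant_profile(),
                           ped = fig1a_pedigree(), cm = cost_model(),
                           seed = 1L) {
  groups <- dplyr::distinct(cells, .data$model, .data$n_p, .data$n_s,
                            .data$n_replicates)
  purrr::pmap_dfr(groups, function(model, n_p, n_s, n_replicates) {
    gm <- model_preset(model)
    des <- stage1_design(gm, n_s, ped = ped)
    n_loci <- num_loci(gm)
    flt_names <- unique(cells$filter[cells$model == model &
                                       cells$n_p == n_p &
                                       cells$n_s == n_s])
    flts <- filter_specs(flt_names)
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      key <- paste(model, n_p, n_s, r, sep = "/")
      set.seed(derive_seed(seed, key))
      out <- simulate_stage1(des, n_p, n_loci, profile, flts)
      tibble::tibble(
        model = model, filter = out$filter, n_p = n_p, n_s = n_s,
        replicate = r, n_true = out$n_true, n_false = out$n_false,
        cost = study_cost(n_p, n_s, out$n_true + out$n_false, cm)
      )
    })
  })
}

#' Plot a design evaluation: true-gene yield against study cost
#'
#' @param object A `design_eval` tibble from [run_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot design_eval
#' @export
autoplot.design_eval <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$mean_cost / 1e6, y = .data$mean_true,
                 colour = .data$filter,
                 shape = factor(.data$n_s))
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(
      .data$filter, .data$n_s
    )), linewidth = 0.3, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
    ggplot2::labs(
      x = "mean study cost (million USD)",
      y = "mean true genes passed to stage II",
      colour = "filter", shape = "sequenced/pedigree"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summarise a design evaluation
#'
#' @param x A `design_eval` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of cells, replicate count range, and
#'   the cheapest cell recovering at least half of the true genes.
#' @method glance design_eval
#' @export
glance.design_eval <- function(x, ...) {
  best <- x |>
    dplyr::filter(.data$proportion_true >= 0.5) |>
    dplyr::arrange(.data$mean_cost) |>
    dplyr::slice_head(n = 1)
  tibble::tibble(
    n_cells = nrow(x),
    min_replicates = min(x$n_replicates),
    max_replicates = max(x$n_replicates),
    best_filter = if (nrow(best)) best$filter else NA_character_,
    best_cost = if (nrow(best)) best$mean_cost else NA_real_
  )
}

#' Plot stage-II validation probabilities
#'
#' @param tbl A tibble from [stage2_table()].
#' @return A ggplot of validation probability against panel size, one line
#'   per model, faceted by threshold.
#' @export
plot_stage2 <- function(tbl = stage2_table()) {
  ggplot2::ggplot(
    tbl,
    ggplot2::aes(x = .data$n_peds, y = .data$p_validated,
                 colour = .data$model)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$k_min),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "stage-II pedigrees", y = "P(validated)") +
    ggplot2::theme_minimal()
}
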