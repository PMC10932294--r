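#' Production and consumption of a metabolite under a flux solution
#'
#' Production sums the positive per-reaction contributions
#' `stoichiometric coefficient x flux` over all reactions involving the
#' metabolite; consumption sums the negative contributions. Positive
#' contributions indicate the metabolite being produced, negative
#' contributions indicate consumption.
#'
#' @param model A [metabolic_model()].
#' @param solution An `fba_solution` (or [flux_solution()]).
#' @param metabolite Metabolite id, e.g. `"h_i"`.
#' @return One-row tibble: `metabolite`, `production`, `consumption`
#'   (reported as a negative total), `net`.
#' @export
metabolite_production <- function(model, solution, metabolite) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!metabolite %in% model$metabolites$metabolite) {
    abort(sprintf("Unknown metabolite '%s'.", metabolite))
  }
  contrib <- metabolite_contributions(model, solution, metabolite)
  tibble::tibble(
    metabolite = metabolite,
    production = sum(pmax(contrib, 0)),
    consumption = sum(pmin(contrib, 0)),
    net = sum(contrib)
  )
}

#' @noRd
metabolite_contributions <- function(model, solution, metabolite) {
  v <- setNames(solution$fluxes$flux, solution$fluxes$reaction)
  out <- numeric(0)
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[j]]
    id <- model$reactions$reaction[j]
    if (metabolite %in% names(s) && id %in% names(v)) {
      out[id] <- s[[metabolite]] * v[[id]]
    }
  }
  out
}

#' Percent reduction in metabolite production between two conditions
#'
#' Computes `100 * (1 - dysregulated / optimized)` production for one
#' metabolite, reported both at full precision and truncated to an integer
#' percent (the convention used when quoting e.g. "a 58% reduction in proton
#' production").
#'
#' @inheritParams metabolite_production
#' @param optimized,dysregulated `fba_solution`s for the baseline and the
#'   perturbed (disease) condition.
#' @return One-row tibble: `metabolite`, `production_optimized`,
#'   `production_dysregulated`, `percent_reduction`,
#'   `percent_reduction_int`. When the optimized production is zero the
#'   change is undefined and reported as `NA` with a warning.
#' @examples
#' toy <- simulate_toy_model("etc_toy", capacity = 2)
#' base <- fba(toy$model)
#' production_change(toy$model, base, base, "h_i")
#' @export
production_change <- function(model, optimized, dysregulated, metabolite) {
  p_opt <- metabolite_production(model, optimized, metabolite)$production
  p_dys <- metabolite_production(model, dysregulated, metabolite)$production
  if (p_opt <= 0) {
    warn(sprintf("Optimized production of '%s' is zero; change undefined.",
                 metabolite))
    pct <- NA_real_
  } else {
    pct <- 100 * (1 - p_dys / p_opt)
  }
  tibble::tibble(
    metabolite = metabolite,
    production_optimized = p_opt,
    production_dysregulated = p_dys,
    percent_reduction = pct,
    percent_reduction_int = trunc(pct)
  )
}

#' Compare optimized and dysregulated flux solutions
#'
#' Pairs the two flux vectors reaction-by-reaction and, when the model is
#' supplied, totals per-metabolite production under both conditions.
#' The relative change is undefined (reported `NA`) where the optimized flux
#' is zero.
#'
#' @param optimized,dysregulated `fba_solution`s over the same reaction set.
#' @param model Optional [metabolic_model()] for the metabolite panel.
#' @return A `flux_comparison`: list with `reactions` (tibble `reaction`,
#'   `flux_optimized`, `flux_dysregulated`, `delta`, `relative_change`) and
#'   `metabolites` (tibble of production/consumption totals, `NULL` without
#'   a model).
#' @export
compare_fluxes <- function(optimized, dysregulated, model = NULL) {
  a <- optimized$fluxes
  b <- dysregulated$fluxes
  if (!setequal(a$reaction, b$reaction)) {
    abort("The two solutions cover different reaction sets.")
  }
  reactions <- dplyr::inner_join(
    dplyr::rename(a, flux_optimized = "flux"),
    dplyr::rename(b, flux_dysregulated = "flux"),
    by = "reaction"
  ) |>
    dplyr::mutate(
      delta = .data$flux_dysregulated - .data$flux_optimized,
      relative_change = dplyr::if_else(
        .data$flux_optimized == 0, NA_real_,
        .data$delta / .data$flux_optimized
      )
    )
  metabolites <- NULL
  if (!is.null(model)) {
    metabolites <- purrr::map_dfr(model$metabolites$metabolite, function(m) {
      po <- metabolite_production(model, optimized, m)
      pd <- metabolite_production(model, dysregulated, m)
      tibble::tibble(
        metabolite = m,
        production_optimized = po$production,
        production_dysregulated = pd$production,
        consumption_optimized = po$consumption,
        consumption_dysregulated = pd$consumption
      )
    })
  }
  structure(list(reactions = reactions, metabolites = metabolites),
            class = "flux_comparison")
}

#' @export
print.flux_comparison <- function(x, ...) {
  cat(sprintf("<flux_comparison> %d reactions", nrow(x$reactions)))
  if (!is.null(x$metabolites)) cat(sprintf(", %d metabolites", nrow(x$metabolites)))
  cat("\n")
  print(x$reactions, n = 10)
  invisible(x)
}
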