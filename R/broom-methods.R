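#' Tidy a differential-expression analysis
#'
#' @param x A `dep_analysis`.
#' @param ... Unused.
#' @return Per-protein tibble: `protein`, group means, `fold_change`,
#'   `log2_fc`, `p_value`, `adj_p_value`, `overexpressing_group`,
#'   `n_present`, `n_runs`, `sentinel`, `dep`.
#' @method tidy dep_analysis
#' @export
tidy.dep_analysis <- function(x, ...) {
  x$table
}

#' Summarize a differential-expression analysis
#'
#' @param x A `dep_analysis`.
#' @param ... Unused.
#' @return One-row tibble: contrast labels, protein counts, numbers of
#'   tested, sentinel-coded and DEP-flagged proteins.
#' @method glance dep_analysis
#' @export
glance.dep_analysis <- function(x, ...) {
  tb <- x$table
  tibble::tibble(
    control = x$control,
    experimental = x$experimental,
    n_proteins = nrow(tb),
    n_tested = sum(!is.na(tb$p_value)),
    n_sentinel = sum(tb$sentinel != "none"),
    n_dep = sum(tb$dep),
    n_dep_sentinel = sum(tb$dep & tb$sentinel != "none")
  )
}

#' @rdname tidy.dep_analysis
#' @method tidy fba_solution
#' @export
tidy.fba_solution <- function(x, ...) {
  x$fluxes
}

#' @rdname glance.dep_analysis
#' @method glance fba_solution
#' @export
glance.fba_solution <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    objective_reaction = x$objective_reaction,
    objective_value = x$objective_value,
    n_reactions = nrow(x$fluxes),
    total_abs_flux = sum(abs(x$fluxes$flux))
  )
}

#' @rdname tidy.dep_analysis
#' @method tidy flux_comparison
#' @export
tidy.flux_comparison <- function(x, ...) {
  x$reactions
}

#' @rdname glance.dep_analysis
#' @method glance flux_comparison
#' @export
glance.flux_comparison <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x$reactions),
    n_changed = sum(abs(x$reactions$delta) > 1e-8),
    max_abs_delta = if (nrow(x$reactions)) max(abs(x$reactions$delta)) else NA_real_
  )
}

#' @rdname tidy.dep_analysis
#' @method tidy eeg_screen
#' @export
tidy.eeg_screen <- function(x, ...) {
  x$events
}

#' @rdname glance.dep_analysis
#' @method glance eeg_screen
#' @export
glance.eeg_screen <- function(x, ...) {
  tibble::tibble(
    duration_s = x$duration_s,
    background_rms = x$background,
    n_events = nrow(x$events),
    n_rejected = nrow(x$rejected),
    total_event_s = sum(x$events$duration)
  )
}

#' @rdname tidy.dep_analysis
#' @method tidy eeg_trace
#' @export
tidy.eeg_trace <- function(x, ...) {
  tibble::tibble(
    time = x$start_s + (seq_along(x$values) - 1) / x$fs,
    value = x$values
  )
}
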