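#' Normalize run totals of a peptide/protein intensity table
#'
#' Rescales every sample run so that the summed intensity of all detected
#' features is equal across runs (equal to the mean of the input run
#' totals). Relative intensities within a run are preserved.
#'
#' @param abundance Long tibble with columns `feature`, `sample`,
#'   `intensity` (detected measurements only; absent = not detected).
#' @return The rescaled abundance tibble.
#' @export
normalize_intensities <- function(abundance) {
  check_abundance(abundance)
  totals <- abundance |>
    dplyr::summarise(total = sum(.data$intensity), .by = "sample")
  if (any(totals$total <= 0)) {
    abort(sprintf("Sample run '%s' has zero total intensity.",
                  totals$sample[totals$total <= 0][1]))
  }
  target <- mean(totals$total)
  abundance |>
    dplyr::left_join(totals, by = "sample") |>
    dplyr::mutate(intensity = .data$intensity * target / .data$total) |>
    dplyr::select(!"total")
}

#' Roll up peptide intensities to protein intensities
#'
#' Protein intensity in a run is the sum of its detected peptides'
#' intensities there; a protein is absent from a run iff all its peptides
#' are absent there.
#'
#' @param abundance Long peptide-level tibble (`feature` = peptide id).
#' @param peptide_map Tibble with columns `peptide`, `protein`; every
#'   peptide must map to exactly one protein.
#' @param unmapped `"error"` (default) to fail on peptides without a
#'   mapping, `"drop"` to discard them with a warning.
#' @return Protein-level abundance tibble (`feature` = protein id).
#' @export
rollup_proteins <- function(abundance, peptide_map,
                            unmapped = c("error", "drop")) {
  check_abundance(abundance)
  unmapped <- rlang::arg_match(unmapped)
  peptide_map <- tibble::as_tibble(peptide_map)
  if (!all(c("peptide", "protein") %in% names(peptide_map))) {
    abort("`peptide_map` needs columns `peptide`, `protein`.")
  }
  if (anyDuplicated(peptide_map$peptide)) {
    abort("Each peptide must map to exactly one protein.")
  }
  lost <- setdiff(unique(abundance$feature), peptide_map$peptide)
  if (length(lost) > 0) {
    if (unmapped == "error") {
      abort(sprintf("%d peptide(s) have no protein mapping (e.g. '%s').",
                    length(lost), lost[1]))
    }
    warn(sprintf("Dropping %d unmapped peptide(s).", length(lost)))
    abundance <- dplyr::filter(abundance, !.data$feature %in% lost)
  }
  abundance |>
    dplyr::inner_join(peptide_map, by = c(feature = "peptide")) |>
    dplyr::summarise(intensity = sum(.data$intensity),
                     .by = c("protein", "sample")) |>
    dplyr::rename(feature = "protein")
}

#' Average technical replicate runs within each biological replicate
#'
#' For every feature and animal, the abundance is the mean over the
#' technical runs in which the feature was detected; the feature counts as
#' detected for the animal iff it was detected in at least one technical
#' run. The per-animal detection count is retained for the downstream
#' replicate-presence filter.
#'
#' @param abundance Long abundance tibble (`feature`, `sample`,
#'   `intensity`).
#' @param design Tibble with columns `sample`, `group`,
#'   `biological_replicate`, `technical_replicate`.
#' @return Tibble with one row per detected (feature, animal):
#'   `feature`, `group`, `biological_replicate`, `intensity`,
#'   `n_detected`, `n_technical`.
#' @export
average_technical_replicates <- function(abundance, design) {
  check_abundance(abundance)
  design <- check_design(design)
  runs_per_animal <- design |>
    dplyr::summarise(n_technical = dplyr::n(),
                     .by = c("group", "biological_replicate"))
  abundance |>
    dplyr::inner_join(design, by = "sample") |>
    dplyr::summarise(
      intensity = mean(.data$intensity),
      n_detected = dplyr::n(),
      .by = c("feature", "group", "biological_replicate")
    ) |>
    dplyr::left_join(runs_per_animal, by = c("group", "biological_replicate"))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: with order statistics `p_(1) <= ... <= p_(n)`,
#' `adj_(i) = min_{j >= i} min(1, p_(j) * n / j)`, reported in the input
#' order. A thin, input-validating wrapper around the standard step-up
#' implementation so the adjustment used across the package is one function.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA`s preserved).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Differential protein abundance between two groups
#'
#' The workhorse of the differential-expression stage. Technical replicates
#' are averaged per animal first; group means and the linear fold change
#' (experimental / control) are computed over detected biological
#' replicates; a two-sample t-test (Welch by default) is run per protein,
#' by default on log2 intensities; and p-values are adjusted across all
#' tested proteins by Benjamini-Hochberg.
#'
#' Proteins undetected in one entire group get a sentinel fold-change code
#' instead of a ratio: `"100"` when absent from every control-group run
#' (detected only in the experimental group) and `"0.1"` when absent from
#' every experimental-group run; no p-value is computed for them. Proteins
#' detected in fewer than two biological replicates of either group are
#' reported but not tested (t-test undefined). Proteins absent from both
#' groups are dropped with a warning.
#'
#' The replicate-presence count (`n_present` out of `n_runs`) counts
#' technical runs of the overexpressing group - the group with the higher
#' mean (the detected group, for sentinel proteins) - in which the protein
#' was detected.
#'
#' @param abundance Long abundance tibble at protein level.
#' @param design Sample design tibble (see
#'   [average_technical_replicates()]).
#' @param control,experimental Group labels to contrast.
#' @param log_scale Test log2-transformed intensities (default `TRUE`;
#'   variance stabilization); set `FALSE` to test the raw scale.
#' @param var_equal `FALSE` (default) for Welch's unequal-variance t-test,
#'   `TRUE` for Student's pooled test.
#' @return A `dep_analysis` object; see [tidy.dep_analysis()] for the
#'   per-protein table. DEP flags are all `FALSE` until [call_deps()] is
#'   applied.
#' @examples
#' sim <- simulate_abundance(40, planted = tibble::tibble(
#'   protein = 1:2, group = "pte", log2fc = c(2, -2)
#' ), seed = 7)
#' de <- differential_expression(sim$abundance, sim$design, "sham", "pte")
#' head(tidy(de))
#' @export
differential_expression <- function(abundance, design, control, experimental,
                                    log_scale = TRUE, var_equal = FALSE) {
  check_abundance(abundance)
  design <- check_design(design)
  groups <- unique(design$group)
  if (!control %in% groups || !experimental %in% groups) {
    abort("`control` and `experimental` must be groups present in `design`.")
  }
  design <- dplyr::filter(design, .data$group %in% c(control, experimental))
  abundance <- dplyr::filter(abundance, .data$sample %in% design$sample)

  avg <- average_technical_replicates(abundance, design)
  tech_runs <- design |>
    dplyr::summarise(n_runs = dplyr::n(), .by = "group")
  n_runs_of <- setNames(tech_runs$n_runs, tech_runs$group)

  per_group <- function(g) {
    avg |>
      dplyr::filter(.data$group == g) |>
      dplyr::summarise(
        mean = mean(.data$intensity),
        mean_log2 = mean(log2(.data$intensity)),
        var_log2 = stats::var(log2(.data$intensity)),
        var_raw = stats::var(.data$intensity),
        n_bio = dplyr::n(),
        n_present = sum(.data$n_detected),
        .by = "feature"
      )
  }
  ctrl <- per_group(control)
  expt <- per_group(experimental)

  res <- dplyr::full_join(ctrl, expt, by = "feature",
                          suffix = c("_control", "_experimental"))

  n_ctrl <- dplyr::coalesce(res$n_bio_control, 0L)
  n_expt <- dplyr::coalesce(res$n_bio_experimental, 0L)
  sentinel <- dplyr::case_when(
    n_ctrl == 0 & n_expt > 0 ~ "100",
    n_expt == 0 & n_ctrl > 0 ~ "0.1",
    .default = "none"
  )

  fc <- dplyr::case_when(
    sentinel == "100" ~ 100,
    sentinel == "0.1" ~ 0.1,
    .default = res$mean_experimental / res$mean_control
  )

  # Welch / Student two-sample t-test, vectorized across proteins.
  if (log_scale) {
    m1 <- res$mean_log2_control; m2 <- res$mean_log2_experimental
    s1 <- res$var_log2_control;  s2 <- res$var_log2_experimental
  } else {
    m1 <- res$mean_control; m2 <- res$mean_experimental
    s1 <- res$var_raw_control; s2 <- res$var_raw_experimental
  }
  testable <- n_ctrl >= 2 & n_expt >= 2
  p_raw <- rep(NA_real_, nrow(res))
  if (any(testable)) {
    i <- which(testable)
    if (var_equal) {
      df <- n_ctrl[i] + n_expt[i] - 2
      sp2 <- ((n_ctrl[i] - 1) * s1[i] + (n_expt[i] - 1) * s2[i]) / df
      se <- sqrt(sp2 * (1 / n_ctrl[i] + 1 / n_expt[i]))
    } else {
      se2 <- s1[i] / n_ctrl[i] + s2[i] / n_expt[i]
      se <- sqrt(se2)
      df <- se2^2 / ((s1[i] / n_ctrl[i])^2 / (n_ctrl[i] - 1) +
                       (s2[i] / n_expt[i])^2 / (n_expt[i] - 1))
    }
    tstat <- (m2[i] - m1[i]) / se
    p_i <- 2 * pt(-abs(tstat), df)
    # degenerate zero-variance case: identical groups are null, distinct
    # groups are a sure difference
    zero_se <- se == 0
    p_i[zero_se] <- ifelse(m2[i][zero_se] == m1[i][zero_se], 1, 0)
    p_raw[i] <- p_i
  }
  adj <- rep(NA_real_, nrow(res))
  adj[testable] <- bh_adjust(p_raw[testable])

  over <- ifelse(sentinel == "0.1", control,
                 ifelse(sentinel == "100", experimental,
                        ifelse(fc >= 1, experimental, control)))
  n_present <- ifelse(over == control,
                      dplyr::coalesce(res$n_present_control, 0L),
                      dplyr::coalesce(res$n_present_experimental, 0L))

  table <- tibble::tibble(
    protein = res$feature,
    mean_control = res$mean_control,
    mean_experimental = res$mean_experimental,
    fold_change = fc,
    log2_fc = log2(fc),
    p_value = p_raw,
    adj_p_value = adj,
    overexpressing_group = over,
    n_present = as.integer(n_present),
    n_runs = as.integer(n_runs_of[over]),
    sentinel = sentinel,
    dep = FALSE
  ) |>
    dplyr::arrange(.data$protein)

  structure(
    list(
      table = table,
      control = control, experimental = experimental,
      log_scale = log_scale, var_equal = var_equal,
      thresholds = NULL
    ),
    class = "dep_analysis"
  )
}

#' Flag differentially expressed proteins
#'
#' Applies the conjunction rule: a tested protein is a DEP iff its fold
#' change passes the two-sided threshold (`FC >= fc_threshold` or
#' `FC <= 1 / fc_threshold`, i.e. `|log2 FC| >= log2(fc_threshold)`), its
#' BH-adjusted p-value is below `adj_p_threshold`, and it was detected in at
#' least `presence_fraction` of the overexpressing group's technical runs
#' (the "5 out of 10 technical replicates" rule at the default design
#' size). Sentinel-coded proteins carry no p-value; they are flagged as
#' DEPs in their clearly marked sentinel stratum iff they pass the presence
#' filter (the fold-change criterion is trivially met).
#'
#' @param x A `dep_analysis` from [differential_expression()].
#' @param fc_threshold Linear fold-change threshold (default 1.2).
#' @param adj_p_threshold Adjusted-p threshold (default 0.1, strict `<`).
#' @param presence_fraction Minimum detected fraction of the overexpressing
#'   group's technical runs (default 0.5).
#' @return The `dep_analysis` with the `dep` flag set and thresholds
#'   recorded.
#' @export
call_deps <- function(x, fc_threshold = 1.2, adj_p_threshold = 0.1,
                      presence_fraction = 0.5) {
  stopifnot(inherits(x, "dep_analysis"))
  assert_scalar_number(fc_threshold, "fc_threshold", lower = 1)
  assert_scalar_number(adj_p_threshold, "adj_p_threshold", lower = 0, upper = 1)
  assert_scalar_number(presence_fraction, "presence_fraction", lower = 0, upper = 1)
  tb <- x$table
  presence_ok <- tb$n_present >= presence_fraction * tb$n_runs
  fc_ok <- abs(tb$log2_fc) >= log2(fc_threshold)
  p_ok <- !is.na(tb$adj_p_value) & tb$adj_p_value < adj_p_threshold
  tb$dep <- ifelse(tb$sentinel == "none",
                   fc_ok & p_ok & presence_ok,
                   presence_ok)
  x$table <- tb
  x$thresholds <- list(fc_threshold = fc_threshold,
                       adj_p_threshold = adj_p_threshold,
                       presence_fraction = presence_fraction)
  x
}

#' @export
print.dep_analysis <- function(x, ...) {
  cat(sprintf("<dep_analysis> %s vs %s: %d proteins", x$control,
              x$experimental, nrow(x$table)))
  if (!is.null(x$thresholds)) {
    cat(sprintf("; %d DEPs (%d sentinel-coded)",
                sum(x$table$dep),
                sum(x$table$dep & x$table$sentinel != "none")))
  }
  cat("\n")
  invisible(x)
}

#' @noRd
check_abundance <- function(abundance) {
  if (!is.data.frame(abundance) ||
      !all(c("feature", "sample", "intensity") %in% names(abundance))) {
    abort("Abundance tables need columns `feature`, `sample`, `intensity`.")
  }
  if (any(!is.finite(abundance$intensity)) || any(abundance$intensity <= 0)) {
    abort("Detected intensities must be positive; encode missing values as absent rows.")
  }
  invisible(abundance)
}

#' @noRd
check_design <- function(design) {
  design <- tibble::as_tibble(design)
  needed <- c("sample", "group", "biological_replicate", "technical_replicate")
  if (!all(needed %in% names(design))) {
    abort(sprintf("Design needs columns %s.", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(design$sample)) {
    abort("Every sample must have exactly one design row.")
  }
  design
}
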