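#' Simulate a label-free proteomics abundance table with planted fold changes
#'
#' Generates grouped log-normal protein (optionally peptide-level) intensities
#' with the replicate hierarchy of a typical label-free LC-MS/MS design: each
#' biological replicate (animal) is run several times, technical runs being
#' more similar to each other than biological replicates are. Selected
#' proteins carry a planted log2 fold change in one group, so downstream
#' differential-expression calls can be scored against a known truth.
#'
#' The generative model is multiplicative on the intensity scale:
#' \deqn{\log_2 I_{p,s} = \mu_p + \Delta_{p,g(s)} + b_{p,a(s)} + e_{p,s}}
#' where \eqn{\mu_p} is a protein baseline, \eqn{\Delta} the planted group
#' effect, \eqn{b} biological noise with standard deviation `noise_sd`, and
#' \eqn{e} technical noise with standard deviation `noise_sd / 4` (technical
#' replicates of the same animal share everything but \eqn{e}). Missing
#' values are encoded as absent rows, never as zeros.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param groups Character vector of group labels (first label is the
#'   reference in downstream contrasts by convention).
#' @param n_biological Biological replicates (animals) per group.
#' @param n_technical Technical replicate runs per animal.
#' @param planted Optional tibble/data frame with columns `protein` (id such
#'   as `"P0007"` or integer index), `group` (the shifted group) and `log2fc`
#'   (finite, nonzero planted effect added to that group).
#' @param noise_sd Standard deviation of biological noise on the log2 scale.
#' @param dropout_rate Probability, in `[0, 1)`, that any detected
#'   peptide-run measurement is dropped (recorded as absent).
#' @param peptides_per_protein If greater than 1, the table is emitted at
#'   peptide level (protein intensity split across peptides with fixed
#'   per-peptide shares) together with a peptide-to-protein map.
#' @param baseline_log2_range Range of the uniform protein baseline on the
#'   log2 scale.
#' @param seed Integer seed; identical arguments reproduce identical output.
#'
#' @return A list with components:
#' \describe{
#'   \item{abundance}{tibble with columns `feature`, `sample`, `intensity`
#'     (detected measurements only; intensities are strictly positive).}
#'   \item{design}{tibble with columns `sample`, `group`,
#'     `biological_replicate`, `technical_replicate`.}
#'   \item{truth}{tibble of planted effects (`protein`, `group`, `log2fc`).}
#'   \item{peptide_map}{tibble `peptide` -> `protein` (`NULL` at protein
#'     level).}
#' }
#' @examples
#' sim <- simulate_abundance(50, planted = tibble::tibble(
#'   protein = "P0001", group = "pte", log2fc = 1
#' ), noise_sd = 0, seed = 1)
#' head(sim$abundance)
#' @export
simulate_abundance <- function(n_proteins,
                               groups = c("sham", "pte"),
                               n_biological = 5,
                               n_technical = 2,
                               planted = NULL,
                               noise_sd = 0.2,
                               dropout_rate = 0,
                               peptides_per_protein = 1,
                               baseline_log2_range = c(18, 24),
                               seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins")
  n_biological <- assert_count(n_biological, "n_biological")
  n_technical <- assert_count(n_technical, "n_technical")
  peptides_per_protein <- assert_count(peptides_per_protein, "peptides_per_protein")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(dropout_rate, "dropout_rate", lower = 0, upper = 1)
  if (dropout_rate >= 1) abort("`dropout_rate` must be < 1.")
  if (!is.character(groups) || length(groups) < 1L || anyDuplicated(groups)) {
    abort("`groups` must be distinct group labels.")
  }

  proteins <- sprintf("P%04d", seq_len(n_proteins))
  truth <- normalize_planted(planted, proteins, groups)

  design <- tidyr::expand_grid(
    group = groups,
    biological_replicate = seq_len(n_biological),
    technical_replicate = seq_len(n_technical)
  ) |>
    dplyr::mutate(
      sample = sprintf("%s_b%d_t%d", .data$group, .data$biological_replicate,
                       .data$technical_replicate),
      .before = 1
    )

  with_seed(seed, {
    baseline <- runif(n_proteins, baseline_log2_range[1], baseline_log2_range[2])
    shift <- matrix(0, n_proteins, length(groups),
                    dimnames = list(proteins, groups))
    if (nrow(truth) > 0) {
      shift[cbind(truth$protein, truth$group)] <- truth$log2fc
    }

    n_runs <- nrow(design)
    animal <- paste(design$group, design$biological_replicate)
    bio <- matrix(rnorm(n_proteins * length(groups) * n_biological, 0, noise_sd),
                  n_proteins)
    colnames(bio) <- unique(animal)
    tech <- matrix(rnorm(n_proteins * n_runs, 0, noise_sd / 4), n_proteins)

    log2_int <- baseline + shift[, design$group, drop = FALSE] +
      bio[, animal, drop = FALSE] + tech

    if (peptides_per_protein > 1L) {
      shares <- matrix(rexp(n_proteins * peptides_per_protein),
                       n_proteins, peptides_per_protein)
      shares <- shares / rowSums(shares)
      peptides <- sprintf("%s_pep%02d", rep(proteins, each = peptides_per_protein),
                          rep(seq_len(peptides_per_protein), n_proteins))
      intensity <- 2^log2_int[rep(seq_len(n_proteins), each = peptides_per_protein), ,
                              drop = FALSE] *
        as.vector(t(shares))
      feature <- peptides
      peptide_map <- tibble::tibble(
        peptide = peptides,
        protein = rep(proteins, each = peptides_per_protein)
      )
    } else {
      intensity <- 2^log2_int
      feature <- proteins
      peptide_map <- NULL
    }

    detected <- matrix(runif(length(intensity)) >= dropout_rate,
                       nrow(intensity))

    n_features <- length(feature)
    abundance <- tibble::tibble(
      feature = rep(feature, times = n_runs),
      sample = rep(design$sample, each = n_features),
      intensity = as.vector(intensity),
      detected = as.vector(detected)
    ) |>
      dplyr::filter(.data$detected) |>
      dplyr::select(!"detected")

    list(
      abundance = abundance,
      design = dplyr::select(design, "sample", "group",
                             "biological_replicate", "technical_replicate"),
      truth = truth,
      peptide_map = peptide_map
    )
  })
}

#' @noRd
normalize_planted <- function(planted, proteins, groups) {
  if (is.null(planted) || nrow(tibble::as_tibble(planted)) == 0) {
    return(tibble::tibble(protein = character(), group = character(),
                          log2fc = numeric()))
  }
  planted <- tibble::as_tibble(planted)
  if (!all(c("protein", "group", "log2fc") %in% names(planted))) {
    abort("`planted` needs columns `protein`, `group`, `log2fc`.")
  }
  if (is.numeric(planted$protein)) {
    if (any(planted$protein < 1 | planted$protein > length(proteins))) {
      abort("Planted protein index out of range.")
    }
    planted$protein <- proteins[planted$protein]
  }
  if (!all(planted$protein %in% proteins)) {
    abort("Planted protein id not present in the simulated table.")
  }
  if (!all(planted$group %in% groups)) {
    abort("Planted group label not among `groups`.")
  }
  if (any(!is.finite(planted$log2fc)) || any(planted$log2fc == 0)) {
    abort("Planted log2 fold changes must be finite and nonzero.")
  }
  planted[c("protein", "group", "log2fc")]
}
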