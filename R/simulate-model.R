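#' Generate a toy metabolic model with a known LP optimum
#'
#' Desk-scale stand-ins for a genome-scale reconstruction, each with a single
#' biomass-maintenance objective reaction and a closed-form optimum, used to
#' validate the flux-balance machinery:
#' \describe{
#'   \item{`linear_chain`}{uptake -> conversion -> biomass; the uptake bound
#'     is the bottleneck, so the optimum equals `capacity`.}
#'   \item{`branched`}{two parallel substrate paths feeding the objective;
#'     the optimum is the sum of the branch capacities.}
#'   \item{`etc_toy`}{a miniature electron transport chain: complex III- and
#'     complex IV-like reactions both pump protons into the inner
#'     mitochondrial membrane (`h_i`), an ATP synthase consumes them, and
#'     biomass maintenance turns ATP over. Compartment suffixes follow BiGG
#'     conventions (`_c` cytosol, `_m` mitochondria, `_i` inner membrane).
#'     The optimum is `1.5 * capacity`.}
#' }
#'
#' @param kind One of `"linear_chain"`, `"branched"`, `"etc_toy"`.
#' @param capacity Positive flux capacity of the bottleneck uptake.
#' @param branch_capacities For `"branched"`, the two parallel path
#'   capacities; defaults to a 40/60 split of `capacity`.
#' @param seed Integer seed (the toys are deterministic; kept so all
#'   generators share one calling convention).
#'
#' @return A list with `model` (a [metabolic_model()]) and `truth`, a list
#'   holding the known `model_optimum` and, for `etc_toy`, the
#'   `proton_metabolite` id.
#' @examples
#' toy <- simulate_toy_model("linear_chain", capacity = 10)
#' toy$truth$model_optimum
#' @export
simulate_toy_model <- function(kind = c("linear_chain", "branched", "etc_toy"),
                               capacity = 10,
                               branch_capacities = NULL,
                               seed = 1L) {
  kind <- rlang::arg_match(kind)
  assert_scalar_number(capacity, "capacity", lower = 0, strict_lower = TRUE)
  big <- 1000

  rxn <- function(reaction, eq, lb = 0, ub = big, gpr = NA_character_) {
    tibble::tibble(reaction = reaction, stoich = list(parse_reaction_equation(eq)),
                   lb = lb, ub = ub, gpr = gpr)
  }

  if (kind == "linear_chain") {
    reactions <- dplyr::bind_rows(
      rxn("EX_a", "-> a_c", ub = capacity, gpr = "TransP"),
      rxn("CONV", "a_c -> b_c", gpr = "ConvP"),
      rxn("BIOMASS_maint", "b_c ->")
    )
    truth <- list(model_optimum = capacity)
  } else if (kind == "branched") {
    caps <- branch_capacities %||% (c(0.4, 0.6) * capacity)
    if (length(caps) != 2L || any(caps <= 0)) {
      abort("`branch_capacities` must be two positive capacities.")
    }
    reactions <- dplyr::bind_rows(
      rxn("EX_a1", "-> a_c", ub = caps[1], gpr = "BranchP1"),
      rxn("EX_a2", "-> b_c", ub = caps[2], gpr = "BranchP2"),
      rxn("J1", "a_c -> x_c", gpr = "JoinP1"),
      rxn("J2", "b_c -> x_c", gpr = "JoinP2"),
      rxn("BIOMASS_maint", "x_c ->")
    )
    truth <- list(model_optimum = sum(caps))
  } else {
    # Electron-transport toy: complexes III and IV both produce h_i.
    reactions <- dplyr::bind_rows(
      rxn("EX_qh2", "-> q10h2_m", ub = capacity, gpr = "Sdha"),
      rxn("CYOR_toy", "q10h2_m + 2 ficytc_m -> q10_m + 2 focytc_m + 4 h_i",
          gpr = "Uqcrc1 and Uqcrfs1"),
      rxn("CYOO_toy", "4 focytc_m + o2_m -> 4 ficytc_m + 2 h2o_m + 4 h_i",
          gpr = "Cox4i1 and Cox5a"),
      rxn("EX_o2", "-> o2_m"),
      rxn("DM_q10", "q10_m ->"),
      rxn("DM_h2o", "h2o_m ->"),
      rxn("ATPS_toy", "4 h_i + adp_m -> atp_m", gpr = "Atp5a1"),
      rxn("BIOMASS_maint", "atp_m -> adp_m + pi_c"),
      rxn("DM_pi", "pi_c ->")
    )
    truth <- list(model_optimum = 1.5 * capacity, proton_metabolite = "h_i")
  }

  model <- metabolic_model(reactions, objective = "BIOMASS_maint")
  list(model = model, truth = truth)
}
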