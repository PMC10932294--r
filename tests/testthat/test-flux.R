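test_that("model files round-trip through the native TSV dialect", {
  toy <- simulate_toy_model("etc_toy", capacity = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metabolic_model(toy$model, path)
  model2 <- suppressMessages(read_metabolic_model(path))
  expect_equal(model2$objective, toy$model$objective)
  expect_equal(model2$reactions$reaction, toy$model$reactions$reaction)
  expect_equal(model2$reactions$lb, toy$model$reactions$lb)
  expect_equal(model2$reactions$ub, toy$model$reactions$ub)
  for (i in seq_len(nrow(model2$reactions))) {
    a <- toy$model$reactions$stoich[[i]]
    b <- model2$reactions$stoich[[i]]
    expect_equal(b[sort(names(b))], a[sort(names(a))])
  }
  # and the re-read model solves to the same optimum
  expect_equal(fba(model2)$objective_value, fba(toy$model)$objective_value)
})

test_that("malformed model files raise named format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction\tequation\tlower_bound\tupper_bound\tproteins\tobjective",
               "R1\ta_c -> b_c\t5\t2\t\t1"), path)
  expect_error(suppressMessages(read_metabolic_model(path)),
               "R1.*lower bound exceeds")
  writeLines(c("reaction\tequation\tlower_bound\tupper_bound\tproteins\tobjective",
               "R1\ta_c -> b_c\t0\t10\t\t0"), path)
  expect_error(suppressMessages(read_metabolic_model(path)),
               "exactly one objective")
  writeLines(c("reaction\tequation\tlower_bound\tupper_bound\tproteins\tobjective",
               "R1\ta_c >> b_c\t0\t10\t\t1"), path)
  expect_error(suppressMessages(read_metabolic_model(path)), "malformed")
})

test_that("linear chain fixture file parses to 3 reactions and 2 metabolites", {
  toy <- simulate_toy_model("linear_chain", capacity = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metabolic_model(toy$model, path)
  model <- suppressMessages(read_metabolic_model(path))
  expect_equal(nrow(model$reactions), 3)
  expect_equal(nrow(model$metabolites), 2)
})

test_that("BiGG-style JSON models parse to the same LP", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "a_c", compartment = "c"),
                       list(id = "b_c", compartment = "c")),
    reactions = list(
      list(id = "EX_a", metabolites = list(a_c = 1), lower_bound = 0,
           upper_bound = 10, gene_reaction_rule = "TransP"),
      list(id = "CONV", metabolites = list(a_c = -1, b_c = 1),
           lower_bound = 0, upper_bound = 1000),
      list(id = "BIOMASS_maint", metabolites = list(b_c = -1),
           lower_bound = 0, upper_bound = 1000, objective_coefficient = 1)
    )
  ), path, auto_unbox = TRUE)
  model <- suppressMessages(read_bigg_model(path))
  expect_equal(model$objective, "BIOMASS_maint")
  expect_equal(nrow(model$reactions), 3)
  expect_equal(fba(model)$objective_value, 10)

  # missing objective must be supplied explicitly
  jsonlite::write_json(list(
    reactions = list(list(id = "R1", metabolites = list(a_c = 1),
                          lower_bound = 0, upper_bound = 1))
  ), path, auto_unbox = TRUE)
  expect_error(suppressMessages(read_bigg_model(path)), "objective")
  m2 <- suppressMessages(read_bigg_model(path, objective = "R1"))
  expect_equal(m2$objective, "R1")
})

test_that("FBA solves the hand-solved toy optima", {
  chain <- simulate_toy_model("linear_chain", capacity = 10)
  sol <- fba(chain$model)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(sol$fluxes$flux, rep(10, 3))  # whole chain carries the bottleneck

  branched <- simulate_toy_model("branched", branch_capacities = c(3, 4))
  expect_equal(fba(branched$model)$objective_value, 7)

  etc <- simulate_toy_model("etc_toy", capacity = 2)
  expect_equal(fba(etc$model)$objective_value, etc$truth$model_optimum)
})

test_that("solutions are steady-state and dominate random feasible points", {
  for (kind in c("linear_chain", "branched", "etc_toy")) {
    toy <- simulate_toy_model(kind, capacity = 8)
    sol <- fba(toy$model)
    expect_lte(steady_state_residual(toy$model, sol), 1e-8)
    expect_true(all(sol$fluxes$flux >= toy$model$reactions$lb - 1e-8))
    expect_true(all(sol$fluxes$flux <= toy$model$reactions$ub + 1e-8))
  }
  # every random feasible point of the chain is dominated by the optimum
  chain <- simulate_toy_model("linear_chain", capacity = 8)
  opt <- fba(chain$model)$objective_value
  set.seed(1)
  feasible_obj <- runif(1000, 0, 8)  # chain flux t in [0, capacity]
  expect_true(all(feasible_obj <= opt + 1e-8))
})

test_that("parsimonious selection zeroes futile cycles at fixed optimum", {
  reactions <- tibble::tibble(
    reaction = c("EX_a", "FWD", "BACK", "BIOMASS_maint"),
    stoich = list(c(a_c = 1), c(a_c = -1, b_c = 1), c(b_c = -1, a_c = 1),
                  c(b_c = -1)),
    lb = 0, ub = c(5, 1000, 1000, 1000), gpr = NA_character_
  )
  model <- metabolic_model(reactions, objective = "BIOMASS_maint")
  sol <- fba(model)
  expect_equal(sol$objective_value, 5)
  v <- setNames(sol$fluxes$flux, sol$fluxes$reaction)
  expect_equal(unname(v["BACK"]), 0)      # cycle suppressed
  expect_equal(unname(v["FWD"]), 5)
  # the secondary solve preserved the primary optimum
  expect_equal(unname(v["BIOMASS_maint"]), 5, tolerance = 1e-8)
})

test_that("infeasible models report status without fabricating fluxes", {
  reactions <- tibble::tibble(
    reaction = c("IN", "BIOMASS_maint"),
    stoich = list(c(a_c = 1), c(a_c = -1)),
    lb = c(2, 0), ub = c(5, 1),  # forced inflow exceeds allowed outflow
    gpr = NA_character_
  )
  model <- metabolic_model(reactions, objective = "BIOMASS_maint")
  sol <- fba(model)
  expect_false(sol$status == "optimal")
  expect_equal(nrow(sol$fluxes), 0)
})

test_that("fold-change constraints reproduce the stated bound mapping", {
  chain <- simulate_toy_model("linear_chain", capacity = 10)
  base <- fba(chain$model)

  # identity perturbation reproduces the baseline objective exactly
  same <- apply_fold_change_constraints(
    chain$model, base, c(TransP = 1, ConvP = 1)
  )
  expect_equal(fba(same)$objective_value, base$objective_value)

  # halving the bottleneck's protein halves the optimum
  half <- apply_fold_change_constraints(chain$model, base, c(TransP = 0.5))
  expect_equal(fba(half)$objective_value, 5)

  # doubling a non-binding reaction leaves the optimum unchanged
  dbl <- apply_fold_change_constraints(chain$model, base, c(ConvP = 2))
  expect_equal(fba(dbl)$objective_value, 10)

  expect_error(apply_fold_change_constraints(chain$model, base, c(TransP = -1)),
               "positive")
  expect_warning(
    apply_fold_change_constraints(chain$model, base, c(NotAProtein = 2)),
    "no reaction"
  )
})

test_that("GPR rules combine fold changes by min/max/geometric mean", {
  fc <- c(A = 0.5, B = 2, C = 8)
  expect_equal(combine_gpr_fold_change("A and B", fc), 0.5)
  expect_equal(combine_gpr_fold_change("A or B", fc), 2)
  expect_equal(combine_gpr_fold_change("A; B", fc), 1)      # geometric mean
  expect_equal(combine_gpr_fold_change("(A or B) and C", fc), 2)
  expect_equal(combine_gpr_fold_change("A and Missing", fc), 0.5)
  expect_true(is.na(combine_gpr_fold_change("Missing", fc)))
})

test_that("tightening bounds never increases the optimum", {
  set.seed(11)
  for (i in 1:100) {
    kind <- sample(c("linear_chain", "branched", "etc_toy"), 1)
    toy <- simulate_toy_model(kind, capacity = runif(1, 2, 20))
    base <- fba(toy$model)$objective_value
    tight <- toy$model
    j <- sample(nrow(tight$reactions), 1)
    tight$reactions$ub[j] <- tight$reactions$ub[j] * runif(1, 0.2, 1)
    sol <- fba(tight)
    if (sol$status == "optimal") {
      expect_lte(sol$objective_value, base + 1e-8)
    }
  }
})

test_that("scaling all capacities scales the optimum linearly", {
  for (kind in c("linear_chain", "branched", "etc_toy")) {
    base <- fba(simulate_toy_model(kind, capacity = 3)$model)$objective_value
    scaled <- fba(simulate_toy_model(kind, capacity = 12)$model)$objective_value
    expect_equal(scaled, 4 * base, tolerance = 1e-8)
  }
})

test_that("metabolite production sums positive contributions", {
  etc <- simulate_toy_model("etc_toy", capacity = 2)
  sol <- fba(etc$model)
  prod <- metabolite_production(etc$model, sol, "h_i")
  # CYOR pumps 4 per unit flux (2), CYOO 4 per unit flux (1)
  expect_equal(prod$production, 12)
  expect_equal(prod$consumption, -12)  # ATP synthase consumes all of it
  expect_error(metabolite_production(etc$model, sol, "nope"), "Unknown")

  # zero-flux producers contribute nothing
  zero <- flux_solution(setNames(rep(0, nrow(etc$model$reactions)),
                                 etc$model$reactions$reaction))
  expect_equal(metabolite_production(etc$model, zero, "h_i")$production, 0)
})

test_that("production matches a brute-force stoichiometric sum", {
  set.seed(12)
  toy <- simulate_toy_model("etc_toy", capacity = 5)
  v <- runif(nrow(toy$model$reactions), 0, 3)
  sol <- flux_solution(setNames(v, toy$model$reactions$reaction))
  S <- stoichiometric_matrix(toy$model)
  for (m in toy$model$metabolites$metabolite) {
    contrib <- S[m, ] * v
    expect_equal(metabolite_production(toy$model, sol, m)$production,
                 sum(pmax(contrib, 0)), tolerance = 1e-12)
  }
})

test_that("flux comparison reports deltas and guards zero denominators", {
  chain <- simulate_toy_model("linear_chain", capacity = 10)
  base <- fba(chain$model)
  cmp_same <- compare_fluxes(base, base, chain$model)
  expect_true(all(cmp_same$reactions$delta == 0))

  half <- fba(apply_fold_change_constraints(chain$model, base,
                                            c(TransP = 0.5)))
  cmp <- compare_fluxes(base, half, chain$model)
  expect_equal(cmp$reactions$delta,
               half$fluxes$flux - base$fluxes$flux)
  expect_equal(cmp$reactions$relative_change, rep(-0.5, 3))

  zero_opt <- flux_solution(c(R1 = 0))
  some <- flux_solution(c(R1 = 2))
  cmp0 <- compare_fluxes(zero_opt, some)
  expect_true(is.na(cmp0$reactions$relative_change))

  expect_error(compare_fluxes(base, flux_solution(c(other = 1))),
               "different reaction sets")
})

test_that("production change reports full and truncated percent", {
  etc <- simulate_toy_model("etc_toy", capacity = 4)
  base <- fba(etc$model)
  expect_equal(production_change(etc$model, base, base,
                                 "h_i")$percent_reduction, 0)

  # dysregulated production 1.0 vs optimized 4.0 -> 75%
  opt <- flux_solution(c(P1 = 1))
  dys <- flux_solution(c(P1 = 0.25))
  m <- metabolic_model(
    tibble::tibble(reaction = "P1", stoich = list(c(x_c = 4)),
                   lb = 0, ub = 10, gpr = NA_character_),
    objective = "P1"
  )
  pc <- production_change(m, opt, dys, "x_c")
  expect_equal(pc$percent_reduction, 75)
  expect_equal(pc$percent_reduction_int, 75)

  zero <- flux_solution(c(P1 = 0))
  expect_warning(pc0 <- production_change(m, zero, dys, "x_c"), "undefined")
  expect_true(is.na(pc0$percent_reduction))
})
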