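#' Flux balance analysis with a parsimonious secondary objective
#'
#' Maximizes the flux through the model's objective (biomass-maintenance)
#' reaction subject to the steady-state constraint \eqn{S v = 0} and the
#' reaction flux bounds, by linear programming. FBA optima are typically
#' degenerate; to make reported flux vectors reproducible, a secondary LP
#' minimizes the total absolute flux \eqn{\sum_j |v_j|} while holding the
#' primary objective at its optimum (the parsimonious convention). The
#' secondary solution is verified to preserve the primary optimum to
#' `1e-8` before being accepted.
#'
#' @param model A [metabolic_model()].
#' @param minimize_total_flux Run the parsimonious secondary LP
#'   (default `TRUE`).
#' @param big_bound Finite stand-in for infinite bounds.
#' @return An `fba_solution`: list with `fluxes` (tibble `reaction`, `flux`),
#'   `objective_value`, `objective_reaction` and `status` (one of
#'   `"optimal"`, `"infeasible"`, `"not_converged"`). No flux vector is
#'   fabricated when the problem is not solved to optimality.
#' @examples
#' toy <- simulate_toy_model("linear_chain", capacity = 10)
#' fba(toy$model)$objective_value
#' @export
fba <- function(model, minimize_total_flux = TRUE, big_bound = 1000) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  lb <- pmax(model$reactions$lb, -big_bound)
  ub <- pmin(model$reactions$ub, big_bound)
  obj <- as.numeric(model$reactions$reaction == model$objective)

  # Primary LP in shifted variables x = v - lb >= 0.
  primal <- lp_solve(
    objective = obj,
    A_le = diag(n), b_le = ub - lb,
    A_eq = S, b_eq = as.numeric(-S %*% lb),
    maximize = TRUE
  )
  if (primal$status != "optimal") {
    return(new_fba_solution(tibble::tibble(reaction = character(),
                                           flux = numeric()),
                            NA_real_, model$objective, primal$status))
  }
  # Sub-picoscale solver noise is rounded away so identical models yield
  # byte-identical flux tables; the steady-state residual stays below 1e-8.
  v <- round(primal$solution + lb, 12)
  z_star <- sum(obj * v)

  if (minimize_total_flux) {
    # v = p - q, p,q >= 0; minimize sum(p + q) at fixed primary optimum.
    A_pair <- cbind(diag(n), -diag(n))
    second <- lp_solve(
      objective = rep(1, 2 * n),
      A_le = A_pair, b_le = ub,
      A_ge = A_pair, b_ge = lb,
      A_eq = rbind(cbind(S, -S), c(obj, -obj)),
      b_eq = c(rep(0, nrow(S)), z_star),
      maximize = FALSE
    )
    if (second$status == "optimal") {
      v2 <- round(second$solution[seq_len(n)] - second$solution[n + seq_len(n)],
                  12)
      if (abs(sum(obj * v2) - z_star) <= 1e-8) v <- v2
    }
  }

  new_fba_solution(
    tibble::tibble(reaction = model$reactions$reaction, flux = v),
    objective_value = z_star,
    objective_reaction = model$objective,
    status = "optimal"
  )
}

#' @noRd
new_fba_solution <- function(fluxes, objective_value, objective_reaction,
                             status) {
  structure(
    list(fluxes = fluxes, objective_value = objective_value,
         objective_reaction = objective_reaction, status = status),
    class = "fba_solution"
  )
}

#' Construct a flux solution from user-supplied fluxes
#'
#' Wraps an externally obtained flux vector (e.g. values transcribed from a
#' published flux table) in the container that the comparison and
#' metabolite-production helpers consume.
#'
#' @param fluxes Named numeric vector (reaction -> flux) or a tibble with
#'   columns `reaction`, `flux`.
#' @param objective_value Optional objective value.
#' @param objective_reaction Optional objective reaction id.
#' @return An `fba_solution` with status `"supplied"`.
#' @export
flux_solution <- function(fluxes, objective_value = NA_real_,
                          objective_reaction = NA_character_) {
  if (is.numeric(fluxes) && !is.null(names(fluxes))) {
    fluxes <- tibble::tibble(reaction = names(fluxes), flux = unname(fluxes))
  }
  fluxes <- tibble::as_tibble(fluxes)
  if (!all(c("reaction", "flux") %in% names(fluxes))) {
    abort("`fluxes` must be a named vector or have columns reaction, flux.")
  }
  new_fba_solution(fluxes, objective_value, objective_reaction, "supplied")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("<fba_solution> status: %s; objective (%s) = %s\n",
              x$status, x$objective_reaction, format(x$objective_value)))
  invisible(x)
}

#' Maximum steady-state residual of a flux solution
#'
#' @param model A [metabolic_model()].
#' @param solution An `fba_solution` over the model's reactions.
#' @return `max(abs(S %*% v))`.
#' @export
steady_state_residual <- function(model, solution) {
  S <- stoichiometric_matrix(model)
  v <- setNames(solution$fluxes$flux, solution$fluxes$reaction)
  max(abs(S %*% v[colnames(S)]))
}

# ---- generic LP front-end over pracma::linprog ------------------------------

# Solves max/min c'x s.t. A_le x <= b_le, A_ge x >= b_ge, A_eq x == b_eq,
# x >= 0. The >= block is folded into the <= block; redundant equality rows
# (conserved moieties make stoichiometric matrices rank-deficient) are
# dropped, keeping an independent subset - each dropped row is a linear
# combination of the kept ones with a matching right-hand side for the
# consistent steady-state systems built here.
#' @noRd
lp_solve <- function(objective, A_le = NULL, b_le = NULL,
                     A_ge = NULL, b_ge = NULL,
                     A_eq = NULL, b_eq = NULL, maximize = TRUE) {
  n <- length(objective)
  as_mat <- function(A) if (is.null(A)) NULL else matrix(A, ncol = n)
  A_le <- as_mat(A_le); A_ge <- as_mat(A_ge); A_eq <- as_mat(A_eq)
  if (!is.null(A_ge)) {
    A_le <- rbind(A_le, -A_ge)
    b_le <- c(b_le, -b_ge)
  }
  if (!is.null(A_eq) && nrow(A_eq) > 1) {
    qd <- qr(t(A_eq))
    if (qd$rank < nrow(A_eq)) {
      keep <- sort(qd$pivot[seq_len(qd$rank)])
      A_eq <- A_eq[keep, , drop = FALSE]
      b_eq <- b_eq[keep]
    }
  }
  m <- length(b_le) + length(b_eq)
  # Multithreaded BLAS occasionally yields a spuriously singular basis;
  # a plain retry resolves those, so only persistent failures surface.
  for (attempt in 1:3) {
    res <- tryCatch(
      pracma::linprog(
        cc = objective,
        A = A_le, b = b_le,
        Aeq = A_eq, beq = b_eq,
        maximize = maximize,
        maxiter = max(500L, 50L * (n + m)) * attempt
      ),
      error = function(e) list(x = NULL, fval = NA_real_, errno = 0L)
    )
    if (isTRUE(res$errno == 1) || isTRUE(res$errno %in% c(-2, -3, -4))) break
  }
  status <- if (isTRUE(res$errno == 1)) {
    "optimal"
  } else if (isTRUE(res$errno %in% c(-2, -4))) {
    "infeasible"
  } else if (isTRUE(res$errno == -3)) {
    "unbounded"
  } else {
    "not_converged"
  }
  list(solution = if (status == "optimal") unname(res$x) else NULL,
       value = res$fval, status = status)
}
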