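#' Constrain reaction bounds by measured protein fold changes
#'
#' Links differential protein abundance to the metabolic model: for every
#' reaction regulated by at least one measured protein, the flux bound on
#' the active side of its baseline (optimized) flux `v*` is rescaled by the
#' combined fold change `f`:
#' \itemize{
#'   \item `v* > 0`: upper bound becomes `f * v*` (lower bound dropped to 0
#'     if it would exceed the new upper bound);
#'   \item `v* < 0`: lower bound becomes `f * v*` (upper bound raised to 0
#'     symmetrically);
#'   \item `v* = 0`: bounds unchanged.
#' }
#' Reactions without measured regulators are untouched. Fold changes of
#' several proteins on one reaction are combined through the reaction's
#' gene-protein-reaction (GPR) rule: `and` takes the minimum (the scarcest
#' complex member limits), `or` the maximum (isoenzymes substitute);
#' proteins listed without a rule combine by geometric mean.
#'
#' @param model A [metabolic_model()].
#' @param baseline An `fba_solution` optimal for `model`.
#' @param fold_changes Named numeric vector (protein -> positive linear
#'   fold change) or a tibble with columns `protein`, `fold_change`.
#' @param unmatched What to do with measured proteins that map to no
#'   reaction: `"warn"` (default) or `"ignore"`.
#' @return A new `metabolic_model` with updated bounds (`lb <= ub`
#'   guaranteed).
#' @examples
#' toy <- simulate_toy_model("linear_chain", capacity = 10)
#' base <- fba(toy$model)
#' hit <- apply_fold_change_constraints(toy$model, base, c(TransP = 0.5))
#' fba(hit)$objective_value  # 5
#' @export
apply_fold_change_constraints <- function(model, baseline, fold_changes,
                                          unmatched = c("warn", "ignore")) {
  stopifnot(inherits(model, "metabolic_model"))
  unmatched <- rlang::arg_match(unmatched)
  if (is.data.frame(fold_changes)) {
    fold_changes <- setNames(fold_changes$fold_change, fold_changes$protein)
  }
  if (is.null(names(fold_changes)) || any(names(fold_changes) == "")) {
    abort("`fold_changes` must be named by protein id.")
  }
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0)) {
    abort("Fold changes must be positive finite linear ratios.")
  }
  v <- setNames(baseline$fluxes$flux, baseline$fluxes$reaction)
  rx <- model$reactions
  tol <- 1e-9
  matched <- character(0)

  for (j in seq_len(nrow(rx))) {
    rule <- rx$gpr[j]
    if (is.na(rule)) next
    members <- gpr_proteins(rule)
    measured <- intersect(members, names(fold_changes))
    if (length(measured) == 0) next
    matched <- c(matched, measured)
    f <- combine_gpr_fold_change(rule, fold_changes)
    if (is.na(f)) next
    vstar <- v[[rx$reaction[j]]]
    if (vstar > tol) {
      rx$ub[j] <- f * vstar
      if (rx$lb[j] > rx$ub[j]) rx$lb[j] <- 0
    } else if (vstar < -tol) {
      rx$lb[j] <- f * vstar
      if (rx$ub[j] < rx$lb[j]) rx$ub[j] <- 0
    }
  }

  lost <- setdiff(names(fold_changes), matched)
  if (length(lost) > 0 && unmatched == "warn") {
    warn(sprintf("%d measured protein(s) map to no reaction (e.g. '%s'); ignored.",
                 length(lost), lost[1]))
  }
  metabolic_model(rx, objective = model$objective,
                  metabolites = model$metabolites)
}

# ---- tiny GPR rule parser ---------------------------------------------------
# Grammar: expr := term ("or" term)*; term := factor ("and" factor)*;
# factor := protein | "(" expr ")". Protein ids may also be ";"-separated
# (no boolean rule -> geometric-mean combination).

#' @noRd
gpr_tokens <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[toks != ""]
}

#' @noRd
gpr_proteins <- function(rule) {
  if (grepl(";", rule, fixed = TRUE)) {
    return(trimws(strsplit(rule, ";", fixed = TRUE)[[1]]))
  }
  toks <- gpr_tokens(rule)
  setdiff(toks, c("and", "or", "AND", "OR", "(", ")"))
}

#' Combine per-protein fold changes through a GPR rule
#'
#' `and` -> min over measured members, `or` -> max; a plain protein list
#' (`;`-separated or a single id) -> geometric mean. Members without a
#' measured fold change are dropped; `NA` if none are measured.
#'
#' @param rule GPR rule string.
#' @param fold_changes Named numeric vector of measured linear fold changes.
#' @return Combined fold change, or `NA`.
#' @export
combine_gpr_fold_change <- function(rule, fold_changes) {
  geo <- function(x) exp(mean(log(x)))
  if (grepl(";", rule, fixed = TRUE) || !grepl("\\b(and|or|AND|OR)\\b", rule)) {
    vals <- fold_changes[intersect(gpr_proteins(rule), names(fold_changes))]
    return(if (length(vals)) geo(vals) else NA_real_)
  }
  toks <- tolower_ops(gpr_tokens(rule))
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    vals <- parse_term()
    while (!is.na(peek()) && peek() == "or") {
      take()
      vals <- c(vals, parse_term())
    }
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }
  parse_term <- function() {
    vals <- parse_factor()
    while (!is.na(peek()) && peek() == "and") {
      take()
      vals <- c(vals, parse_factor())
    }
    if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) abort(sprintf("Malformed GPR rule '%s'.", rule))
    if (t == "(") {
      v <- parse_expr()
      if (is.na(peek()) || take() != ")") {
        abort(sprintf("Unbalanced parentheses in GPR rule '%s'.", rule))
      }
      return(v)
    }
    if (t %in% names(fold_changes)) fold_changes[[t]] else NA_real_
  }
  out <- parse_expr()
  if (pos <= length(toks)) abort(sprintf("Malformed GPR rule '%s'.", rule))
  out
}

#' @noRd
tolower_ops <- function(toks) {
  ifelse(toks %in% c("AND", "OR"), tolower(toks), toks)
}
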