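#' Construct a constraint-based metabolic model
#'
#' A metabolic model is a set of reactions, each a sparse stoichiometry over
#' compartment-tagged metabolites with flux bounds, plus exactly one
#' designated objective reaction (conventionally biomass maintenance).
#' Metabolite compartments follow BiGG-style id suffixes (`_c` cytosol,
#' `_m` mitochondria, `_i` inner mitochondrial membrane).
#'
#' @param reactions Tibble/data frame with columns `reaction` (id), `stoich`
#'   (list column of named numeric vectors, metabolite -> coefficient;
#'   negative = consumed, positive = produced), `lb`, `ub` (flux bounds) and
#'   optionally `gpr` (gene-protein-reaction rule such as `"CoxA and CoxB"`;
#'   `NA` for unregulated reactions).
#' @param objective Id of the objective (biomass-maintenance) reaction.
#' @param metabolites Optional tibble with columns `metabolite`,
#'   `compartment`; derived from the stoichiometries when omitted
#'   (compartment = id suffix after the last underscore).
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, objective, metabolites = NULL) {
  reactions <- tibble::as_tibble(reactions)
  required <- c("reaction", "stoich", "lb", "ub")
  if (!all(required %in% names(reactions))) {
    abort("`reactions` needs columns reaction, stoich, lb, ub.")
  }
  if (!"gpr" %in% names(reactions)) reactions$gpr <- NA_character_
  if (anyDuplicated(reactions$reaction)) abort("Duplicate reaction ids.")
  bad <- reactions$reaction[reactions$lb > reactions$ub]
  if (length(bad) > 0) {
    abort(sprintf("Reaction '%s': lower bound exceeds upper bound.", bad[1]))
  }
  used <- unique(unlist(lapply(reactions$stoich, names)))
  if (is.null(metabolites)) {
    metabolites <- tibble::tibble(
      metabolite = used,
      compartment = sub("^.*_", "", used)
    )
  } else {
    metabolites <- tibble::as_tibble(metabolites)
    missing <- setdiff(used, metabolites$metabolite)
    if (length(missing) > 0) {
      abort(sprintf("Stoichiometry references undeclared metabolite '%s'.",
                    missing[1]))
    }
  }
  if (length(objective) != 1L || !objective %in% reactions$reaction) {
    abort("`objective` must name exactly one reaction in the model.")
  }
  structure(
    list(reactions = reactions, metabolites = metabolites,
         objective = objective),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "<metabolic_model> %d reactions, %d metabolites; objective: %s\n",
    nrow(x$reactions), nrow(x$metabolites), x$objective
  ))
  invisible(x)
}

#' Stoichiometric matrix of a metabolic model
#'
#' @param model A `metabolic_model`.
#' @return Dense numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites$metabolite
  S <- matrix(0, length(mets), nrow(model$reactions),
              dimnames = list(mets, model$reactions$reaction))
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[j]]
    S[names(s), j] <- s
  }
  S
}

# ---- BiGG-style JSON --------------------------------------------------------

#' Read a BiGG-style JSON metabolic model
#'
#' Parses the JSON schema used by the BiGG model repository: a
#' `metabolites` array (`id`, `compartment`), a `reactions` array (`id`,
#' `metabolites` map of id -> coefficient, `lower_bound`, `upper_bound`,
#' `gene_reaction_rule`), and an objective marked either by
#' `objective_coefficient` on a reaction or a top-level `objective` id.
#'
#' @param path JSON file path.
#' @param objective Optional objective reaction id, overriding whatever the
#'   file designates (required if the file designates none).
#' @return A [metabolic_model()].
#' @export
read_bigg_model <- function(path, objective = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$reactions)) abort("No `reactions` array in model file.")
  reactions <- purrr::map_dfr(doc$reactions, function(r) {
    stoich <- unlist(r$metabolites)
    if (is.null(r$id) || length(stoich) == 0) {
      abort("Malformed reaction record: missing id or stoichiometry.")
    }
    tibble::tibble(
      reaction = r$id,
      stoich = list(stoich),
      lb = r$lower_bound %||% -1000,
      ub = r$upper_bound %||% 1000,
      gpr = if (is.null(r$gene_reaction_rule) || r$gene_reaction_rule == "") {
        NA_character_
      } else {
        r$gene_reaction_rule
      },
      obj_coef = r$objective_coefficient %||% 0
    )
  })
  metabolites <- if (!is.null(doc$metabolites)) {
    purrr::map_dfr(doc$metabolites, function(m) {
      tibble::tibble(metabolite = m$id,
                     compartment = m$compartment %||% sub("^.*_", "", m$id))
    })
  } else {
    NULL
  }
  objective <- objective %||% doc$objective %||%
    reactions$reaction[reactions$obj_coef != 0]
  if (length(objective) != 1L) {
    abort("Model must designate exactly one objective reaction.")
  }
  model <- metabolic_model(reactions[setdiff(names(reactions), "obj_coef")],
                           objective = objective, metabolites = metabolites)
  inform(sprintf("Read model: %d reactions, %d metabolites.",
                 nrow(model$reactions), nrow(model$metabolites)))
  model
}

# ---- native TSV dialect -----------------------------------------------------

#' Read a metabolic model from the native TSV dialect
#'
#' One reaction per line with columns `reaction`, `equation`, `lower_bound`,
#' `upper_bound`, `proteins` (GPR rule, empty for unregulated) and
#' `objective` (1 marks the single biomass-maintenance reaction). Equations
#' use compartment-suffixed metabolite ids, e.g.
#' `"2 ficytc_m + q10h2_m -> 2 focytc_m + 4 h_i"`; an empty side denotes an
#' exchange reaction.
#'
#' @param path File path.
#' @return A `metabolic_model`. Reaction and metabolite counts are reported
#'   with a message.
#' @export
read_metabolic_model <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("reaction", "equation", "lower_bound", "upper_bound")
  if (!all(required %in% names(raw))) {
    abort(sprintf("Model file lacks required columns (%s).",
                  paste(setdiff(required, names(raw)), collapse = ", ")))
  }
  lb <- suppressWarnings(as.numeric(raw$lower_bound))
  ub <- suppressWarnings(as.numeric(raw$upper_bound))
  if (anyNA(lb) || anyNA(ub)) {
    bad <- raw$reaction[is.na(lb) | is.na(ub)][1]
    abort(sprintf("Reaction '%s': non-numeric flux bound.", bad))
  }
  stoich <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    stoich[[i]] <- tryCatch(
      parse_reaction_equation(raw$equation[i]),
      error = function(e) abort(sprintf("Reaction '%s': %s",
                                        raw$reaction[i], conditionMessage(e)))
    )
  }
  gpr <- if ("proteins" %in% names(raw)) {
    ifelse(is.na(raw$proteins) | raw$proteins == "", NA_character_, raw$proteins)
  } else {
    NA_character_
  }
  obj_flag <- if ("objective" %in% names(raw)) {
    !is.na(raw$objective) & raw$objective %in% c("1", "TRUE", "true")
  } else {
    logical(nrow(raw))
  }
  if (sum(obj_flag) != 1L) {
    abort("Model file must mark exactly one objective reaction.")
  }
  reactions <- tibble::tibble(
    reaction = raw$reaction, stoich = stoich, lb = lb, ub = ub, gpr = gpr
  )
  model <- metabolic_model(reactions, objective = raw$reaction[obj_flag])
  inform(sprintf("Read model: %d reactions, %d metabolites.",
                 nrow(model$reactions), nrow(model$metabolites)))
  model
}

#' Write a metabolic model in the native TSV dialect
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  out <- tibble::tibble(
    reaction = rx$reaction,
    equation = vapply(seq_len(nrow(rx)), function(i) {
      deparse_reaction_equation(rx$stoich[[i]], reversible = rx$lb[i] < 0)
    }, character(1)),
    lower_bound = rx$lb,
    upper_bound = rx$ub,
    proteins = ifelse(is.na(rx$gpr), "", rx$gpr),
    objective = as.integer(rx$reaction == model$objective)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

# "2 a_c + b_m -> 3 c_i" -> c(a_c = -2, b_m = -1, c_i = 3); "<->" also accepted.
#' @noRd
parse_reaction_equation <- function(eq) {
  if (!is.character(eq) || length(eq) != 1L || is.na(eq)) {
    abort("malformed equation.")
  }
  parts <- strsplit(eq, "<->|<=>|->", perl = TRUE)[[1]]
  if (!grepl("<->|<=>|->", eq) || length(parts) > 2L) {
    abort(sprintf("malformed equation '%s'.", eq))
  }
  if (length(parts) == 1L) parts <- c(parts, "")
  side <- function(txt, sign) {
    txt <- trimws(txt)
    if (txt == "") return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(length(terms))
    ids <- character(length(terms))
    for (k in seq_along(terms)) {
      tok <- strsplit(terms[k], "\\s+")[[1]]
      if (length(tok) == 1L) {
        coef <- 1
        id <- tok
      } else if (length(tok) == 2L && !is.na(suppressWarnings(as.numeric(tok[1])))) {
        coef <- as.numeric(tok[1])
        id <- tok[2]
      } else {
        abort(sprintf("malformed stoichiometric term '%s'.", terms[k]))
      }
      if (coef <= 0) abort(sprintf("non-positive coefficient in '%s'.", terms[k]))
      out[k] <- sign * coef
      ids[k] <- id
    }
    setNames(out, ids)
  }
  lhs <- side(parts[1], -1)
  rhs <- side(parts[2], +1)
  both <- c(lhs, rhs)
  if (length(both) == 0L) abort("empty equation.")
  tapply_sum <- tapply(both, names(both), sum)
  setNames(as.numeric(tapply_sum), names(tapply_sum))
}

#' @noRd
deparse_reaction_equation <- function(stoich, reversible = FALSE) {
  fmt <- function(s) {
    paste(vapply(names(s), function(m) {
      coef <- abs(s[[m]])
      if (coef == 1) m else paste(format(coef, trim = TRUE), m)
    }, character(1)), collapse = " + ")
  }
  arrow <- if (reversible) "<->" else "->"
  paste(fmt(stoich[stoich < 0]), arrow, fmt(stoich[stoich > 0])) |> trimws()
}
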