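#' Construct a constraint-based metabolic model
#'
#' The central container of the package: a stoichiometric matrix `S`
#' (metabolites x reactions), per-reaction flux bounds and reversibility
#' flags, compartment labels per metabolite, and optional named reaction
#' sets (e.g. `"biomass"`, `"inputs"`).
#'
#' Sign convention: for exchange reactions (single coefficient -1 on the
#' exchanged metabolite) a negative flux is an uptake and a positive flux a
#' production/export rate.  All fluxes are in umol min^-1 gDW^-1.
#'
#' @param stoichiometry numeric matrix, metabolites x reactions.
#' @param lower_bounds,upper_bounds numeric vectors, one entry per reaction.
#' @param reaction_ids,metabolite_ids unique character ids; defaults taken
#'   from the dimnames of `stoichiometry`.
#' @param reversible logical per reaction; default inferred from the bounds
#'   (`lower_bounds < 0`).
#' @param compartment character per metabolite (e.g. `"matrix"`,
#'   `"intermembrane"`, `"external"`); default `"matrix"`.
#' @param is_exchange logical per reaction; default detected structurally
#'   (single nonzero coefficient equal to -1).
#' @param named_sets named list of character vectors of reaction ids.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(stoichiometry, lower_bounds, upper_bounds,
                            reaction_ids = colnames(stoichiometry),
                            metabolite_ids = rownames(stoichiometry),
                            reversible = NULL, compartment = NULL,
                            is_exchange = NULL, named_sets = list()) {
  stoichiometry <- as.matrix(stoichiometry)
  storage.mode(stoichiometry) <- "double"
  if (is.null(reaction_ids))
    reaction_ids <- paste0("R", seq_len(ncol(stoichiometry)))
  if (is.null(metabolite_ids))
    metabolite_ids <- paste0("M", seq_len(nrow(stoichiometry)))
  if (is.null(reversible)) reversible <- lower_bounds < 0
  if (is.null(compartment))
    compartment <- rep("matrix", nrow(stoichiometry))
  if (is.null(is_exchange)) {
    is_exchange <- apply(stoichiometry, 2, function(col) {
      nz <- which(col != 0)
      length(nz) == 1L && col[nz] == -1
    })
  }
  dimnames(stoichiometry) <- list(metabolite_ids, reaction_ids)
  model <- structure(
    list(stoichiometry = stoichiometry,
         lower_bounds = as.numeric(lower_bounds),
         upper_bounds = as.numeric(upper_bounds),
         reversible = as.logical(reversible),
         reaction_ids = as.character(reaction_ids),
         metabolite_ids = as.character(metabolite_ids),
         compartment = as.character(compartment),
         is_exchange = as.logical(is_exchange),
         named_sets = named_sets),
    class = "metabolic_model")
  validate_model(model)
}

#' Validate a metabolic model
#'
#' Checks dimension agreement, id uniqueness, bound ordering
#' (`lb <= ub`, naming the offending reaction) and the
#' irreversibility convention (`reversible = FALSE` implies `lb >= 0`).
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly unchanged, or an error.
#' @export
validate_model <- function(model) {
  S <- model$stoichiometry
  n <- ncol(S); m <- nrow(S)
  if (anyDuplicated(model$reaction_ids))
    stop("duplicate reaction ids: ",
         paste(unique(model$reaction_ids[duplicated(model$reaction_ids)]),
               collapse = ", "))
  if (anyDuplicated(model$metabolite_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(model$metabolite_ids[duplicated(model$metabolite_ids)]),
               collapse = ", "))
  for (fld in c("lower_bounds", "upper_bounds", "reversible", "is_exchange"))
    if (length(model[[fld]]) != n)
      stop(fld, " has length ", length(model[[fld]]), ", expected ", n)
  if (length(model$compartment) != m)
    stop("compartment has length ", length(model$compartment), ", expected ", m)
  bad <- which(model$lower_bounds > model$upper_bounds)
  if (length(bad))
    stop("lower bound exceeds upper bound for reaction ",
         paste(model$reaction_ids[bad], collapse = ", "))
  bad <- which(!model$reversible & model$lower_bounds < 0)
  if (length(bad))
    stop("irreversible reaction with negative lower bound: ",
         paste(model$reaction_ids[bad], collapse = ", "))
  for (nm in names(model$named_sets)) {
    unknown <- setdiff(model$named_sets[[nm]], model$reaction_ids)
    if (length(unknown))
      stop("named set '", nm, "' refers to unknown reactions: ",
           paste(unknown, collapse = ", "))
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", length(x$metabolite_ids), "metabolites x",
      length(x$reaction_ids), "reactions\n")
  cat("  exchanges:", sum(x$is_exchange),
      " reversible:", sum(x$reversible), "\n")
  if (length(x$named_sets))
    cat("  named sets:", paste(names(x$named_sets), collapse = ", "), "\n")
  invisible(x)
}

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reaction_ids)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

met_index <- function(model, ids) {
  idx <- match(ids, model$metabolite_ids)
  if (anyNA(idx))
    stop("unknown metabolite id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Add an exchange reaction for a metabolite
#'
#' Appends one column with a single coefficient of -1 on `metabolite_id`,
#' so that positive flux exports the metabolite and negative flux imports
#' it.  Used e.g. to expose NADH availability as an optimizable flux.
#'
#' @param model a `metabolic_model`.
#' @param metabolite_id metabolite to exchange; must exist and must not
#'   already have an exchange reaction.
#' @param lb,ub bounds of the new reaction.
#' @param reaction_id id for the new reaction; default `EX_<metabolite>`.
#' @return A new model (the input is unmodified).
#' @export
add_exchange_reaction <- function(model, metabolite_id, lb, ub,
                                  reaction_id = paste0("EX_", metabolite_id)) {
  i <- met_index(model, metabolite_id)
  existing <- which(model$is_exchange &
                    apply(model$stoichiometry, 2, function(col)
                          col[i] == -1 && sum(col != 0) == 1L))
  if (length(existing))
    stop("metabolite '", metabolite_id, "' already has an exchange reaction: ",
         model$reaction_ids[existing[1]])
  col <- numeric(nrow(model$stoichiometry))
  col[i] <- -1
  metabolic_model(
    cbind(model$stoichiometry, col),
    c(model$lower_bounds, lb), c(model$upper_bounds, ub),
    reaction_ids = c(model$reaction_ids, reaction_id),
    metabolite_ids = model$metabolite_ids,
    reversible = c(model$reversible, lb < 0),
    compartment = model$compartment,
    is_exchange = c(model$is_exchange, TRUE),
    named_sets = model$named_sets)
}

#' Build a composite (summed) objective over reactions
#'
#' Returns a unit-weight objective over `reaction_ids` minus `exclude`,
#' e.g. "biomass = sum of the five biomass component fluxes except ATP" or
#' the all-six variant.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to sum.
#' @param exclude reactions to drop from the sum.
#' @return Named numeric vector of unit weights.
#' @export
composite_objective <- function(model, reaction_ids, exclude = character()) {
  rxn_index(model, reaction_ids)
  if (length(exclude)) rxn_index(model, exclude)
  keep <- setdiff(reaction_ids, exclude)
  if (!length(keep)) stop("composite objective is empty after exclusion")
  stats::setNames(rep(1, length(keep)), keep)
}

#' Set bounds on reactions
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to modify.
#' @param lb,ub new bounds (recycled); `NULL` leaves a side unchanged.
#' @return A new model.
#' @export
set_bounds <- function(model, reaction_ids, lb = NULL, ub = NULL) {
  idx <- rxn_index(model, reaction_ids)
  if (!is.null(lb)) model$lower_bounds[idx] <- rep_len(lb, length(idx))
  if (!is.null(ub)) model$upper_bounds[idx] <- rep_len(ub, length(idx))
  model$reversible[idx] <- model$lower_bounds[idx] < 0
  validate_model(model)
}
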