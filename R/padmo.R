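#' Protein-abundance flux-bound multiplier
#'
#' The piecewise logarithmic multiplier mapping a dimensionless protein
#' abundance `y` (wild type = 1) to a flux-bound scale factor:
#' `f(y) = 1 + ln(y)` for `y > 1`, `f(y) = 1 / (1 + |ln(y)|)` for
#' `0 < y < 1`, with the removable discontinuity patched by `f(1) = 1`
#' and the knockout limit `f(0) = 0`.  The function is continuous and
#' strictly increasing on `(0, Inf)`, with `f <= 1` on `(0, 1]` and
#' `f >= 1` on `[1, Inf)`; the logarithmic growth keeps the optimizer
#' from being driven towards implausibly large abundances.
#'
#' @param y non-negative abundance (vectorized).
#' @return Multiplier value(s).
#' @export
abundance_multiplier <- function(y) {
  if (any(y < 0)) stop("abundance must be non-negative")
  ifelse(y == 0, 0,
    ifelse(y > 1, 1 + log(y),
      ifelse(y < 1, 1 / (1 + abs(log(y))), 1)))
}

#' Abundance profile
#'
#' @param abundances non-negative numeric vector named by the controlled
#'   reaction ids (or use `reaction_ids`).
#' @param reaction_ids optional explicit id vector.
#' @return An `abundance_profile`.
#' @export
abundance_profile <- function(abundances, reaction_ids = names(abundances)) {
  if (is.null(reaction_ids))
    stop("abundances must be named by reaction id")
  if (any(abundances < 0)) stop("abundance must be non-negative")
  structure(list(y = stats::setNames(as.numeric(abundances), reaction_ids),
                 reaction_ids = reaction_ids),
            class = "abundance_profile")
}

#' Apply an abundance profile to a model
#'
#' Scales the flux bounds of each controlled reaction by the abundance
#' multiplier: `lb = V_min f(y_i)`, `ub = V_max f(y_i)`, where `V_min`
#' and `V_max` are always the *wild-type* bounds of `model` (never a
#' previously scaled version, so applying the same profile twice from
#' wild type equals applying it once).  `y = 1` leaves a reaction
#' untouched; `y = 0` closes it (the knockout limit, in which a binary
#' abundance search reduces to a gene-knockout search).  An optional
#' protein-to-reaction table lets one abundance control several reactions
#' (the minimum applies when several proteins control one reaction).
#'
#' @param model a wild-type `metabolic_model`.
#' @param profile an [abundance_profile()] (or named numeric vector).
#' @param protein_map optional data.frame with columns `protein`,
#'   `reaction` overriding the identity protein-to-reaction mapping.
#' @return A new model with scaled bounds.
#' @export
apply_abundances <- function(model, profile, protein_map = NULL) {
  if (!inherits(profile, "abundance_profile"))
    profile <- abundance_profile(profile)
  f_rxn <- if (is.null(protein_map)) {
    stats::setNames(abundance_multiplier(profile$y), profile$reaction_ids)
  } else {
    stopifnot(all(c("protein", "reaction") %in% names(protein_map)))
    fp <- abundance_multiplier(
      profile$y[match(protein_map$protein, profile$reaction_ids)])
    tapply(fp, protein_map$reaction, min)
  }
  idx <- rxn_index(model, names(f_rxn))
  model$lower_bounds[idx] <- model$lower_bounds[idx] * f_rxn
  model$upper_bounds[idx] <- model$upper_bounds[idx] * f_rxn
  validate_model(model)
}

#' Evaluator for abundance decision vectors
#'
#' Maps an abundance vector onto the model with [apply_abundances()] and
#' computes each declared objective by a separate FBA solve on the scaled
#' model; the constraint value is the graded steady-state infeasibility
#' (zero whenever the scaled model admits a steady state).
#'
#' @param model wild-type model.
#' @param controlled reaction ids controlled by the decision vector.
#' @param objectives list of named weight vectors or character vector of
#'   reaction ids.
#' @param senses per-objective FBA sense (recycled).
#' @param value_set optional discrete set the abundances are snapped to
#'   (e.g. `c(0, 1)` for a pure knockout search).
#' @return Evaluator function for [run_optbiocad()].
#' @export
padmo_evaluator <- function(model, controlled, objectives, senses = "max",
                            value_set = NULL) {
  if (is.character(objectives))
    objectives <- lapply(objectives, function(id) stats::setNames(1, id))
  senses <- rep_len(senses, length(objectives))
  rxn_index(model, controlled)
  function(x) {
    if (!is.null(value_set))
      x <- vapply(x, function(v)
        value_set[which.min(abs(value_set - v))], numeric(1))
    m <- apply_abundances(model, stats::setNames(x, controlled))
    vals <- numeric(length(objectives))
    for (k in seq_along(objectives)) {
      fd <- solve_fba(m, objectives[[k]], senses[k])
      if (fd$status != "optimal")
        return(list(objectives = rep(NA_real_, length(objectives)),
                    constraint = steady_state_violation(m)))
      vals[k] <- fd$objective_value
    }
    list(objectives = vals, constraint = 0)
  }
}

#' Protein-Abundance Design through Multi-objective Optimization
#'
#' Runs [run_optbiocad()] with the abundance vector as the decision
#' vector (box `[0, y_max]` per controlled reaction).  Every front point
#' carries its abundance array, so each Pareto-optimal design is both an
#' objective-space optimum and a concrete protein-abundance condition.
#'
#' @param model wild-type `metabolic_model`.
#' @param objectives list of named weight vectors or reaction ids.
#' @param controlled controlled reaction ids (default: all non-exchange
#'   reactions).
#' @param config an [opt_config()].
#' @param senses per-objective sense.
#' @param y_max abundance box ceiling.
#' @param value_set optional discrete abundance set (e.g. `c(0, 1)`).
#' @param constraint optional extra constraint function of the abundance
#'   vector (added to the steady-state infeasibility), e.g. a knockout
#'   budget.
#' @return A `padmo_result`: the underlying `optbiocad_result` plus the
#'   abundance arrays of the final front.
#' @export
run_padmo <- function(model, objectives, controlled = NULL,
                      config = opt_config(), senses = "max", y_max = 100,
                      value_set = NULL, constraint = NULL) {
  if (is.null(controlled))
    controlled <- model$reaction_ids[!model$is_exchange]
  base_eval <- padmo_evaluator(model, controlled, objectives, senses,
                               value_set)
  snap <- function(x) {
    if (is.null(value_set)) return(x)
    vapply(x, function(v) value_set[which.min(abs(value_set - v))],
           numeric(1))
  }
  evaluator <- if (is.null(constraint)) base_eval else function(x) {
    out <- base_eval(x)
    out$constraint <- out$constraint + constraint(snap(x))
    out
  }
  spec <- objective_spec(
    vapply(seq_along(objectives), function(k)
      if (is.character(objectives)) objectives[k]
      else paste0("obj_", k), character(1)),
    senses = rep_len(senses, length(objectives)))
  bounds <- cbind(rep(0, length(controlled)), rep(y_max, length(controlled)))
  res <- run_optbiocad(evaluator, bounds, spec, config)
  front_y <- res$front$decisions
  if (!is.null(value_set) && !is.null(front_y))
    front_y <- apply(front_y, c(1, 2), function(v)
      value_set[which.min(abs(value_set - v))])
  if (!is.null(front_y)) colnames(front_y) <- controlled
  structure(c(res, list(controlled = controlled, abundances = front_y)),
            class = c("padmo_result", "optbiocad_result"))
}

#' Write abundance profiles as CSV
#'
#' Columns `reaction_id,abundance`, one file per profile row or a single
#' long table with a `design` column.
#'
#' @param abundances matrix (designs x reactions, named columns).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_abundances <- function(abundances, path) {
  abundances <- rbind(abundances)
  df <- data.frame(design = rep(seq_len(nrow(abundances)),
                                each = ncol(abundances)),
                   reaction_id = rep(colnames(abundances),
                                     nrow(abundances)),
                   abundance = as.vector(t(abundances)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
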