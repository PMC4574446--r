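#' Flux decision-vector encoding
#'
#' Describes how an optimizer decision vector maps onto a metabolic
#' model.  Three encodings are provided:
#'
#' * `input_fluxes`: decision variables act on exchange reactions.  Each
#'   target uses one of three mappings:
#'   `"uptake_delta"` (default) adds `x_i >= 0` to the nominal uptake
#'   capacity, so the zero vector reproduces the wild type and the box
#'   upper limit defaults to 33 percent of the nominal capacity;
#'   `"uptake_cap"` sets the uptake capacity to `x_i` directly
#'   (box `[0, min(|nominal lb|, cap)]`); `"pin"` fixes the exchange flux,
#'   `lb = ub = x_i` (box = the reaction's bounds).  All uptake magnitudes
#'   are clipped at `cap` (default 1000 umol min^-1 gDW^-1).
#' * `internal_fluxes`: the decision vector is a full flux vector over the
#'   target reactions; objectives are read from it directly and the
#'   constraint value is the mass-balance residual `max |S v|`.
#' * `abundance`: see [padmo_evaluator()].
#'
#' @param model a `metabolic_model`.
#' @param mode `"input_fluxes"` or `"internal_fluxes"`.
#' @param targets reaction ids the decision vector controls; defaults to
#'   all exchange reactions (input mode) or all reactions (internal mode).
#' @param mapping per-target mapping for input mode (recycled).
#' @param cap maximum uptake magnitude.
#' @param delta_frac box width of `uptake_delta` targets as a fraction of
#'   the nominal capacity.
#' @return A `flux_decision` with a `bounds` matrix (the optimizer box).
#' @export
flux_decision <- function(model, mode = c("input_fluxes", "internal_fluxes"),
                          targets = NULL,
                          mapping = "uptake_delta", cap = 1000,
                          delta_frac = 0.33) {
  mode <- match.arg(mode)
  if (is.null(targets))
    targets <- if (mode == "input_fluxes")
      model$reaction_ids[model$is_exchange] else model$reaction_ids
  idx <- rxn_index(model, targets)
  if (mode == "input_fluxes" && !all(model$is_exchange[idx]))
    stop("input_fluxes targets must be exchange reactions: ",
         paste(targets[!model$is_exchange[idx]], collapse = ", "))
  if (mode == "internal_fluxes") {
    bounds <- cbind(model$lower_bounds[idx], model$upper_bounds[idx])
    mapping <- rep("direct", length(idx))
  } else {
    mapping <- rep_len(match.arg(mapping,
                                 c("uptake_delta", "uptake_cap", "pin"),
                                 several.ok = TRUE), length(idx))
    nominal <- abs(pmin(model$lower_bounds[idx], 0))
    bounds <- matrix(0, length(idx), 2)
    for (k in seq_along(idx)) {
      bounds[k, ] <- switch(mapping[k],
        uptake_delta = c(0, delta_frac * nominal[k]),
        uptake_cap = c(0, min(nominal[k], cap)),
        pin = c(model$lower_bounds[idx[k]], model$upper_bounds[idx[k]]))
    }
  }
  structure(list(model = model, mode = mode, targets = targets,
                 index = idx, mapping = mapping, cap = cap,
                 bounds = bounds),
            class = "flux_decision")
}

apply_decision <- function(decision, x) {
  model <- decision$model
  for (k in seq_along(decision$index)) {
    j <- decision$index[k]
    nominal <- abs(min(model$lower_bounds[j], 0))
    switch(decision$mapping[k],
      uptake_delta = {
        u <- min(nominal + max(x[k], 0), decision$cap)
        model$lower_bounds[j] <- -u
      },
      uptake_cap = {
        u <- min(max(x[k], 0), decision$cap)
        model$lower_bounds[j] <- -u
      },
      pin = {
        v <- min(max(x[k], model$lower_bounds[j]), model$upper_bounds[j])
        model$lower_bounds[j] <- v
        model$upper_bounds[j] <- v
      })
  }
  model$reversible <- model$reversible | model$lower_bounds < 0
  model
}

#' Build an optBioCAD evaluator from a flux decision
#'
#' `input_fluxes` mode maps the decision vector onto exchange bounds,
#' solves one FBA with the inner objective, and reads every declared
#' objective off the optimal flux distribution; the constraint value is
#' the graded steady-state infeasibility of the perturbed bounds (zero
#' when a steady state exists).  `internal_fluxes` mode evaluates the
#' candidate flux vector directly and returns the mass-balance residual
#' as the constraint value.
#'
#' @param decision a [flux_decision()].
#' @param objectives list of named weight vectors (one per objective), or
#'   a character vector of reaction ids (unit weights).
#' @param inner_objective named weight vector for the inner FBA solve
#'   (input mode); defaults to the first objective.
#' @param inner_sense sense of the inner solve.
#' @return function of a decision vector `x` returning
#'   `list(objectives, constraint)`, suitable for [run_optbiocad()].
#' @export
flux_evaluator <- function(decision, objectives,
                           inner_objective = NULL,
                           inner_sense = "max") {
  if (is.character(objectives))
    objectives <- lapply(objectives, function(id)
      stats::setNames(1, id))
  objw <- lapply(objectives, function(w) {
    v <- numeric(length(decision$model$reaction_ids))
    v[rxn_index(decision$model, names(w))] <- as.numeric(w)
    v
  })
  if (decision$mode == "internal_fluxes") {
    model <- decision$model
    function(x) {
      v <- numeric(length(model$reaction_ids))
      v[decision$index] <- x
      list(objectives = vapply(objw, function(w) sum(w * v), numeric(1)),
           constraint = mass_balance_residual(model, v))
    }
  } else {
    if (is.null(inner_objective))
      inner_objective <- objectives[[1]]
    function(x) {
      m <- apply_decision(decision, x)
      fd <- solve_fba(m, inner_objective, inner_sense)
      if (fd$status != "optimal")
        return(list(objectives = rep(NA_real_, length(objw)),
                    constraint = steady_state_violation(m)))
      list(objectives = vapply(objw, function(w) sum(w * fd$fluxes),
                               numeric(1)),
           constraint = 0)
    }
  }
}

#' Feasibility-preserving mutation of internal fluxes
#'
#' The C/N retry operator: `k ~ Uniform{1..C}` target fluxes are redrawn
#' uniformly within their bounds (irreversible reactions never receive a
#' negative draw), pinned as equalities, and the remaining fluxes are
#' repaired by an LP feasibility solve so that `S v = 0` holds exactly.
#' On infeasibility the draw is repeated, up to `N` times; after `N`
#' failures the parent flux vector is returned unchanged.
#'
#' @param v feasible flux vector (steady state within tolerance).
#' @param model a `metabolic_model`.
#' @param C maximum number of perturbed fluxes.
#' @param N maximum number of retry trials.
#' @param targets reaction ids eligible for perturbation (default: all).
#' @param tol mass-balance tolerance on the parent.
#' @return A steady-state-feasible flux vector (or the parent).
#' @export
mutate_internal_fluxes <- function(v, model, C = 5, N = 20,
                                   targets = model$reaction_ids,
                                   tol = 1e-6) {
  stopifnot(C >= 1, N >= 1)
  if (mass_balance_residual(model, v) > tol * max(1, max(abs(v))) ||
      any(v < model$lower_bounds - tol) || any(v > model$upper_bounds + tol))
    stop("parent flux vector is not feasible")
  eligible <- rxn_index(model, targets)
  for (trial in seq_len(N)) {
    k <- sample.int(C, 1)
    pick <- eligible[sample.int(length(eligible), min(k, length(eligible)))]
    m2 <- model
    for (j in pick) {
      val <- stats::runif(1, model$lower_bounds[j], model$upper_bounds[j])
      m2$lower_bounds[j] <- val
      m2$upper_bounds[j] <- val
    }
    m2$reversible <- m2$reversible | m2$lower_bounds < 0
    fd <- solve_fba(m2, stats::setNames(0, model$reaction_ids[1]), "max")
    if (fd$status == "optimal" &&
        mass_balance_residual(model, fd$fluxes) <=
          tol * max(1, max(abs(fd$fluxes))))
      return(fd$fluxes)
  }
  v
}
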