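#' @useDynLib biocad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# finite stand-in used when a model declares an infinite bound; unboundedness
# is detected by re-solving with the stand-in enlarged (see solve_lp).
BIG_BOUND <- 1e7

#' Solve a bounded linear program
#'
#' Minimizes or maximizes `obj' x` subject to `A x = b` and
#' `lb <= x <= ub`, with a deterministic bounded-variable primal simplex
#' (Bland's rule, two phases).  Infinite bounds are replaced by a large
#' finite stand-in; if the optimum moves when the stand-in is enlarged the
#' problem is reported unbounded.
#'
#' @param obj objective coefficients.
#' @param A equality constraint matrix.
#' @param b right-hand side.
#' @param lb,ub variable bounds (may contain `-Inf`/`Inf`).
#' @param maximize logical.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x`, and `objval`.
#' @export
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == nrow(A))
  if (any(lb > ub)) return(list(status = "infeasible", x = rep(NA_real_, n),
                                objval = NA_real_))
  had_inf <- any(!is.finite(lb)) || any(!is.finite(ub))
  clamp <- function(M) {
    list(lb = pmax(lb, -M), ub = pmin(ub, M))
  }
  bb <- clamp(BIG_BOUND)
  res <- .simplex_bounded(A, as.numeric(b), bb$lb, bb$ub,
                          as.numeric(obj), maximize)
  if (res$status == "optimal" && had_inf) {
    bb2 <- clamp(10 * BIG_BOUND)
    res2 <- .simplex_bounded(A, as.numeric(b), bb2$lb, bb2$ub,
                             as.numeric(obj), maximize)
    if (res2$status == "optimal" &&
        abs(res2$objval - res$objval) >
          1e-6 * max(1, abs(res$objval)))
      return(list(status = "unbounded", x = as.numeric(res$x),
                  objval = if (maximize) Inf else -Inf))
  }
  if (res$status %in% c("singular", "maxit"))
    stop("LP solver failed with status '", res$status, "'")
  list(status = res$status, x = as.numeric(res$x), objval = res$objval)
}

#' Flux balance analysis
#'
#' Computes the steady-state flux distribution optimizing a linear
#' objective over reactions: `opt  w' v  s.t.  S v = 0, lb <= v <= ub`.
#' The objective value of the LP is unique even when the optimal flux
#' vector is degenerate; downstream code relies only on the value.
#'
#' @param model a `metabolic_model`.
#' @param objective named numeric vector of weights per reaction id, or a
#'   single reaction id (unit weight).
#' @param sense `"max"` or `"min"`.
#' @return A `flux_distribution`: list with `fluxes` (named), `objective_value`
#'   and `status` (`"optimal"`, `"infeasible"`, `"unbounded"`).
#' @export
solve_fba <- function(model, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (is.character(objective))
    objective <- stats::setNames(rep(1, length(objective)), objective)
  idx <- rxn_index(model, names(objective))
  w <- numeric(length(model$reaction_ids))
  w[idx] <- as.numeric(objective)
  res <- solve_lp(w, model$stoichiometry, rep(0, nrow(model$stoichiometry)),
                  model$lower_bounds, model$upper_bounds,
                  maximize = (sense == "max"))
  fl <- res$x
  names(fl) <- model$reaction_ids
  structure(list(fluxes = fl,
                 objective_value = if (res$status == "optimal") res$objval
                                   else res$objval,
                 status = res$status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("flux_distribution: status =", x$status,
      " objective =", format(x$objective_value), "\n")
  invisible(x)
}

#' Mass-balance residual of a flux vector
#'
#' @param model a `metabolic_model`.
#' @param v flux vector.
#' @return `max |S v|` (infinity norm).
#' @export
mass_balance_residual <- function(model, v) {
  max(abs(model$stoichiometry %*% v))
}

#' Graded steady-state infeasibility of pinned bounds
#'
#' Solves the phase-1 problem `min sum(s+ + s-)` s.t.
#' `S v + s+ - s- = 0`, `lb <= v <= ub`: zero iff a steady state exists
#' within the given bounds, otherwise a graded measure of how far the
#' bounds are from admitting one (used to rank infeasible candidates).
#'
#' @param model a `metabolic_model`.
#' @return Non-negative scalar.
#' @export
steady_state_violation <- function(model) {
  S <- model$stoichiometry
  m <- nrow(S); n <- ncol(S)
  A <- cbind(S, diag(m), -diag(m))
  obj <- c(numeric(n), rep(1, 2 * m))
  lb <- c(model$lower_bounds, numeric(2 * m))
  ub <- c(model$upper_bounds, rep(Inf, 2 * m))
  res <- .simplex_bounded(A, numeric(m), pmax(lb, -BIG_BOUND),
                          pmin(ub, BIG_BOUND), obj, FALSE)
  if (res$status != "optimal") return(Inf)
  max(0, res$objval)
}
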