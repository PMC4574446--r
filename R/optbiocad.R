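#' optBioCAD configuration
#'
#' Algorithm parameters with the published defaults: population size
#' `d = 20`, `dup = 2` copies per member, age limit `tau_B = 50`,
#' mutation-rate parameters `rho = 1` and `beta = 7`, archive capacity
#' `s_a = 160`.
#'
#' @param d population size.
#' @param dup copies per population member in the copying phase.
#' @param tau_B age limit; candidates older than `tau_B + 1` are retired
#'   to the archive.
#' @param rho local-search rate parameter (`alpha = exp(-rho * F)`).
#' @param beta global-search rate parameter (`alpha = exp(-F) / beta`).
#' @param s_a archive capacity.
#' @param t_final generation budget.
#' @param theta feasibility threshold on the constraint function.
#' @param seed integer seed governing the whole run.
#' @param classical_es_rates use the classical evolution-strategy learning
#'   rates `1/sqrt(2n)`, `1/sqrt(2 sqrt(n))` instead of the literal
#'   `gamma = gamma' = 1/(2n)`.
#' @param stagnation stop early after this many generations without any
#'   change of the running front (`Inf` disables the test).
#' @param literal_min_selection break feasible-vs-feasible tournaments by
#'   the literal "lowest objective value" reading instead of best
#'   normalized fitness.
#' @return An `opt_config` list.
#' @export
opt_config <- function(d = 20, dup = 2, tau_B = 50, rho = 1, beta = 7,
                       s_a = 160, t_final = 100, theta = 1e-6, seed = 1L,
                       classical_es_rates = FALSE, stagnation = Inf,
                       literal_min_selection = FALSE) {
  stopifnot(d >= 1, dup >= 1, s_a >= 1, t_final >= 1, beta > 0)
  structure(list(d = d, dup = dup, tau_B = tau_B, rho = rho, beta = beta,
                 s_a = s_a, t_final = t_final, theta = theta,
                 seed = as.integer(seed),
                 classical_es_rates = classical_es_rates,
                 stagnation = stagnation,
                 literal_min_selection = literal_min_selection),
            class = "opt_config")
}

new_candidate <- function(x, sigma, age = 0L) {
  list(x = x, sigma = sigma, age = age, objectives = NULL,
       fitness = NA_real_, violation = NA_real_, feasible = NA)
}

check_bounds <- function(bounds) {
  bounds <- rbind(bounds)
  if (ncol(bounds) != 2) bounds <- t(bounds)
  if (any(!is.finite(bounds))) stop("decision bounds must be finite")
  if (any(bounds[, 1] > bounds[, 2])) stop("lower bound exceeds upper bound")
  bounds
}

#' Initialize a random population
#'
#' `d` candidates drawn uniformly within the decision box; ages start at 0
#' and every step size at `sigma_i = 0.4 (x_i_max - x_i_min) / n`.
#'
#' @param bounds n x 2 matrix of decision bounds.
#' @param config an [opt_config()].
#' @return List of candidates.
#' @export
initialize_population <- function(bounds, config = opt_config()) {
  bounds <- check_bounds(bounds)
  n <- nrow(bounds)
  sig <- 0.4 * (bounds[, 2] - bounds[, 1]) / n
  lapply(seq_len(config$d), function(i)
    new_candidate(stats::runif(n, bounds[, 1], bounds[, 2]), sig))
}

#' Normalized fitness
#'
#' `F = (sum_i f_i / f_max_i) / r` clamped to `[0, 1]`; `f_max`
#' coordinates that are not (yet) positive are replaced by 1 so that the
#' fitness is defined from the first generation.  The unclamped value is
#' returned as attribute `"raw"` and used for tie-breaking in selection.
#'
#' @param objectives objective vector (maximization scale).
#' @param f_max running best value per objective (maximization scale).
#' @return Fitness in `[0, 1]` with attribute `raw`.
#' @export
normalized_fitness <- function(objectives, f_max) {
  r <- length(objectives)
  if (length(f_max) != r) stop("objective/f_max length mismatch (r = ",
                               r, " vs ", length(f_max), ")")
  denom <- ifelse(is.finite(f_max) & f_max > 0, f_max, 1)
  raw <- sum(objectives / denom) / r
  structure(min(1, max(0, raw)), raw = raw)
}

#' Copying phase
#'
#' Each member is copied `dup` times; copies inherit the parent's age
#' while each parent ages by one.
#'
#' @param P population (list of candidates).
#' @param dup copy count.
#' @return list with `parents` (aged) and `copies` (size `d * dup`).
#' @export
copying <- function(P, dup) {
  copies <- list()
  for (i in seq_along(P)) {
    for (k in seq_len(dup)) copies[[length(copies) + 1L]] <- P[[i]]
    P[[i]]$age <- P[[i]]$age + 1L
  }
  list(parents = P, copies = copies)
}

es_rates <- function(n, classical) {
  if (classical) c(1 / sqrt(2 * n), 1 / sqrt(2 * sqrt(n)))
  else c(1 / (2 * n), 1 / (2 * n))
}

#' Local search: self-adaptive Gaussian mutation
#'
#' With probability `alpha = exp(-rho F)` one uniformly chosen variable is
#' mutated: its step size is updated log-normally,
#' `sigma_i <- sigma_i exp(gamma N(0,1) + gamma' N_i(0,1))` with
#' `gamma = gamma' = 1/(2n)`, then `x_i <- x_i + sigma_i N(0,1)`, clipped
#' to the box.  Otherwise the candidate is returned unchanged.
#'
#' @param cand candidate (with fitness evaluated).
#' @param rho rate parameter.
#' @param bounds decision box.
#' @param classical_es_rates see [opt_config()].
#' @return Mutated candidate.
#' @export
local_search <- function(cand, rho, bounds, classical_es_rates = FALSE) {
  bounds <- check_bounds(bounds)
  n <- length(cand$x)
  f <- if (is.na(cand$fitness)) 0 else cand$fitness
  alpha <- exp(-rho * f)
  if (stats::runif(1) > alpha) return(cand)
  g <- es_rates(n, classical_es_rates)
  i <- sample.int(n, 1)
  cand$sigma[i] <- cand$sigma[i] *
    exp(g[1] * stats::rnorm(1) + g[2] * stats::rnorm(1))
  cand$x[i] <- min(max(cand$x[i] + cand$sigma[i] * stats::rnorm(1),
                       bounds[i, 1]), bounds[i, 2])
  cand
}

#' Global search: convex recombination with a random donor
#'
#' With probability `alpha = exp(-F) / beta` one variable `x_i` is blended
#' with a donor value `x_k` taken from a uniformly random *other* position
#' of a uniformly random *other* pool member (resampled once if the values
#' coincide): `x_i <- (1 - gamma) x_i + gamma x_k` with
#' `gamma ~ N(0, 1)`, clipped to the box (the Gaussian weight makes the
#' perturbation occasionally non-convex).
#'
#' @param cand candidate.
#' @param pool population supplying donors.
#' @param beta rate parameter.
#' @param bounds decision box.
#' @param self_index index of `cand` inside `pool`, excluded from donor
#'   draws (optional).
#' @return Mutated candidate.
#' @export
global_search <- function(cand, pool, beta, bounds, self_index = NA) {
  bounds <- check_bounds(bounds)
  if (!length(pool)) stop("donor pool is empty")
  n <- length(cand$x)
  f <- if (is.na(cand$fitness)) 0 else cand$fitness
  alpha <- exp(-f) / beta
  if (stats::runif(1) > alpha) return(cand)
  i <- sample.int(n, 1)
  pick <- function() {
    ks <- if (!is.na(self_index) && length(pool) > 1)
      setdiff(seq_along(pool), self_index) else seq_along(pool)
    k <- ks[sample.int(length(ks), 1)]
    js <- if (n > 1) setdiff(seq_len(n), i) else i
    pool[[k]]$x[js[sample.int(length(js), 1)]]
  }
  xk <- pick()
  if (isTRUE(all.equal(xk, cand$x[i]))) xk <- pick()
  gam <- stats::rnorm(1)
  cand$x[i] <- min(max((1 - gam) * cand$x[i] + gam * xk,
                       bounds[i, 1]), bounds[i, 2])
  cand
}

#' Constraint evaluation
#'
#' A candidate is feasible when `g(x) <= theta`; the violation is
#' `max(0, g(x) - theta)`.  A non-evaluable constraint (e.g. an infeasible
#' FBA subproblem) yields an infeasible candidate with infinite violation.
#'
#' @param g_value constraint function value (may be `NA`/`NaN`).
#' @param theta feasibility threshold.
#' @return list `(feasible, violation)`.
#' @export
evaluate_constraints <- function(g_value, theta) {
  if (is.null(g_value) || !is.finite(g_value))
    return(list(feasible = FALSE, violation = Inf))
  list(feasible = g_value <= theta, violation = max(0, g_value - theta))
}

#' Create an empty archive
#' @param s_a capacity.
#' @return An `archive` object with `s_a` empty slots.
#' @export
create_archive <- function(s_a) {
  structure(list(slots = vector("list", s_a), s_a = s_a), class = "archive")
}

archive_occupancy <- function(archive)
  sum(!vapply(archive$slots, is.null, logical(1)))

#' Insert a candidate into the archive
#'
#' First free slot if any, otherwise a uniformly random slot is
#' overwritten (occupancy never exceeds the capacity).
#'
#' @param archive an archive.
#' @param cand candidate.
#' @return Updated archive.
#' @export
archive_insert <- function(archive, cand) {
  free <- which(vapply(archive$slots, is.null, logical(1)))
  slot <- if (length(free)) free[1] else sample.int(archive$s_a, 1)
  archive$slots[[slot]] <- cand
  archive
}

#' Diversity enforcing: age-based retirement
#'
#' Removes candidates whose age exceeds `tau_B + 1` from both populations
#' and inserts them into the archive; age exactly `tau_B + 1` survives.
#'
#' @param P,P_GS populations.
#' @param tau_B age limit.
#' @param archive the run archive.
#' @return list `(P, P_GS, archive)`.
#' @export
diversity_enforcing <- function(P, P_GS, tau_B, archive) {
  sift <- function(pop) {
    keep <- list()
    for (cand in pop) {
      if (cand$age > tau_B + 1) archive <<- archive_insert(archive, cand)
      else keep[[length(keep) + 1L]] <- cand
    }
    keep
  }
  P <- sift(P); P_GS <- sift(P_GS)
  list(P = P, P_GS = P_GS, archive = archive)
}

selection_key <- function(cand, literal_min = FALSE) {
  # smaller key = better
  if (isTRUE(cand$feasible)) {
    val <- if (literal_min) sum(cand$objectives)
           else -attr_raw_fitness(cand)
    c(0, val)
  } else c(1, cand$violation)
}

attr_raw_fitness <- function(cand) {
  raw <- attr(cand$fitness, "raw")
  if (is.null(raw)) as.numeric(cand$fitness) else raw
}

#' Selection
#'
#' Builds the next population of size `d` from parents and mutants using
#' the tournament ordering: feasible beats infeasible, two feasibles are
#' ranked by fitness, two infeasibles by violation.  A deficit is filled
#' with uniformly random archive members, then with fresh uniform
#' candidates if the archive is empty.
#'
#' @param P,P_GS parent and mutant populations (evaluated).
#' @param archive the run archive.
#' @param d target population size.
#' @param bounds decision box (for fresh candidates).
#' @param literal_min_selection see [opt_config()].
#' @return Population of size `d`.
#' @export
selection <- function(P, P_GS, archive, d, bounds,
                      literal_min_selection = FALSE) {
  pool <- c(P, P_GS)
  if (length(pool)) {
    keys <- t(vapply(pool, selection_key, numeric(2),
                     literal_min = literal_min_selection))
    pool <- pool[order(keys[, 1], keys[, 2])]
  }
  newP <- pool[seq_len(min(d, length(pool)))]
  deficit <- d - length(newP)
  if (deficit > 0) {
    occ <- which(!vapply(archive$slots, is.null, logical(1)))
    while (deficit > 0 && length(occ)) {
      pickv <- occ[sample.int(length(occ), 1)]
      newP[[length(newP) + 1L]] <- archive$slots[[pickv]]
      deficit <- deficit - 1
    }
    if (deficit > 0) {
      bounds <- check_bounds(bounds)
      n <- nrow(bounds)
      sig <- 0.4 * (bounds[, 2] - bounds[, 1]) / n
      for (k in seq_len(deficit))
        newP[[length(newP) + 1L]] <-
          new_candidate(stats::runif(n, bounds[, 1], bounds[, 2]), sig)
    }
  }
  newP
}

# incremental non-dominated store (standard weak dominance on max scale).
# Comparisons carry a small relative tolerance so that solver-level
# floating-point noise (~1e-12 on LP optima) cannot smuggle weakly
# dominated points onto the reported front.
front_update <- function(front, obj, dec) {
  if (is.null(front$obj)) {
    return(list(obj = rbind(obj), dec = rbind(dec)))
  }
  F <- front$obj
  tol <- 1e-8 * pmax(1, abs(obj))
  D <- sweep(F, 2, obj, `-`)               # incumbent minus newcomer
  ge <- rowSums(sweep(D, 2, -tol, `>=`)) == ncol(F)
  gt <- rowSums(sweep(D, 2, tol, `>`)) > 0
  if (any(ge & gt)) return(front)          # dominated by an incumbent
  if (any(ge & !gt)) return(front)         # duplicate of an incumbent
  dominated <- (rowSums(sweep(D, 2, tol, `<=`)) == ncol(F)) &
               (rowSums(sweep(D, 2, -tol, `<`)) > 0)
  keep <- !dominated
  list(obj = rbind(F[keep, , drop = FALSE], obj),
       dec = rbind(front$dec[keep, , drop = FALSE], dec))
}

evaluate_candidate <- function(cand, evaluator, spec, theta) {
  out <- tryCatch(evaluator(cand$x), error = function(e) NULL)
  if (is.null(out) || is.null(out$objectives) ||
      anyNA(out$objectives)) {
    cand$objectives <- rep(NA_real_, spec$r)
    cand$feasible <- FALSE; cand$violation <- Inf
    cand$failed <- TRUE
    return(cand)
  }
  cand$objectives <- drop(to_max_scale(out$objectives, spec))
  fc <- evaluate_constraints(out$constraint, theta)
  cand$feasible <- fc$feasible; cand$violation <- fc$violation
  cand$failed <- FALSE
  cand
}

#' Run the optBioCAD evolutionary multi-objective optimizer
#'
#' Executes the generational loop: copying, self-adaptive local search,
#' convex global search, evaluation, age update (reset to 0 on objective
#' improvement, else +1), age-based diversity enforcing with archival,
#' archive union, and tournament selection.  The per-objective best values
#' `f_max` used by the normalized fitness are tracked globally over all
#' generations.  The running non-dominated front over every feasible
#' candidate evaluated so far is recorded at each generation.
#'
#' @param evaluator function of a decision vector returning
#'   `list(objectives = <numeric r>, constraint = <numeric scalar>)`.
#' @param bounds n x 2 matrix of decision bounds.
#' @param spec an [objective_spec()].
#' @param config an [opt_config()].
#' @return An `optbiocad_result`: final population, archive, per-generation
#'   fronts (objective and decision matrices on the original objective
#'   scale), the final front, `f_max`, and a per-generation log.
#' @export
run_optbiocad <- function(evaluator, bounds, spec, config = opt_config()) {
  bounds <- check_bounds(bounds)
  with_seed(config$seed, run_optbiocad_impl(evaluator, bounds, spec, config))
}

run_optbiocad_impl <- function(evaluator, bounds, spec, config) {
  d <- config$d; r <- spec$r
  f_max <- rep(-Inf, r)
  archive <- create_archive(config$s_a)
  front <- list(obj = NULL, dec = NULL)

  refresh_fmax <- function(pop) {
    for (cand in pop)
      if (isTRUE(cand$feasible))
        f_max <<- pmax(f_max, cand$objectives)
  }
  refit <- function(pop) lapply(pop, function(cand) {
    if (isTRUE(cand$feasible))
      cand$fitness <- normalized_fitness(cand$objectives, f_max)
    cand
  })
  absorb <- function(pop) {
    for (cand in pop)
      if (isTRUE(cand$feasible))
        front <<- front_update(front, cand$objectives, cand$x)
  }

  P <- initialize_population(bounds, config)
  P <- lapply(P, evaluate_candidate, evaluator = evaluator, spec = spec,
              theta = config$theta)
  refresh_fmax(P); P <- refit(P); absorb(P)

  fronts <- list(); log <- list()
  stagnant <- 0L; prev_front_n <- -1L
  for (t in seq_len(config$t_final)) {
    cp <- copying(P, config$dup)
    P_aged <- cp$parents
    P_LS <- lapply(cp$copies, local_search, rho = config$rho,
                   bounds = bounds,
                   classical_es_rates = config$classical_es_rates)
    P_GS <- vector("list", length(P_LS))
    for (i in seq_along(P_LS))
      P_GS[[i]] <- global_search(P_LS[[i]], P_LS, config$beta, bounds,
                                 self_index = i)
    pre <- cp$copies  # pre-mutation objectives for the improvement test
    P_GS <- lapply(P_GS, evaluate_candidate, evaluator = evaluator,
                   spec = spec, theta = config$theta)
    nfail <- sum(vapply(P_GS, function(cand) isTRUE(cand$failed),
                        logical(1)))
    if (length(P_GS) && nfail > 0.5 * length(P_GS))
      stop("evaluator failed on ", nfail, " of ", length(P_GS),
           " candidates in generation ", t)
    refresh_fmax(P_GS)
    P_aged <- refit(P_aged); P_GS <- refit(P_GS)
    for (i in seq_along(P_GS)) {
      old <- pre[[i]]
      old_fit <- if (!is.null(old$objectives) && isTRUE(old$feasible))
        attr(normalized_fitness(old$objectives, f_max), "raw") else -Inf
      new_fit <- if (isTRUE(P_GS[[i]]$feasible))
        attr_raw_fitness(P_GS[[i]]) else -Inf
      improved <- is.finite(new_fit) && new_fit > old_fit
      P_GS[[i]]$age <- if (improved) 0L else old$age + 1L
    }
    absorb(P_GS)
    de <- diversity_enforcing(P_aged, P_GS, config$tau_B, archive)
    archive <- de$archive
    for (cand in c(de$P, de$P_GS)) archive <- archive_insert(archive, cand)
    P <- selection(de$P, de$P_GS, archive, d, bounds,
                   config$literal_min_selection)
    fresh <- vapply(P, function(cand) is.null(cand$objectives), logical(1))
    P[fresh] <- lapply(P[fresh], evaluate_candidate, evaluator = evaluator,
                       spec = spec, theta = config$theta)
    refresh_fmax(P); P <- refit(P); absorb(P[fresh])

    fr_obj <- sweep(front$obj, 2, ifelse(spec$senses == "min", -1, 1), `*`)
    fronts[[t]] <- list(objectives = fr_obj, decisions = front$dec)
    bestF <- suppressWarnings(
      max(vapply(P, function(cand)
        if (isTRUE(cand$feasible)) as.numeric(cand$fitness) else -Inf,
        numeric(1))))
    log[[t]] <- data.frame(generation = t, front_size = nrow(front$obj),
                           best_F = if (is.finite(bestF)) bestF else NA,
                           archive_occupancy = archive_occupancy(archive))
    if (nrow(front$obj) == prev_front_n) stagnant <- stagnant + 1L
    else { stagnant <- 0L; prev_front_n <- nrow(front$obj) }
    if (stagnant >= config$stagnation) break
  }
  structure(list(population = P, archive = archive, fronts = fronts,
                 front = fronts[[length(fronts)]], f_max = f_max,
                 spec = spec, config = config,
                 log = do.call(rbind, log)),
            class = "optbiocad_result")
}

#' @export
print.optbiocad_result <- function(x, ...) {
  cat("optbiocad_result:", length(x$fronts), "generations,",
      nrow(x$front$objectives), "front points,",
      archive_occupancy(x$archive), "archived candidates\n")
  invisible(x)
}

#' @export
summary.optbiocad_result <- function(object, ...) {
  cat("Objectives:", paste(object$spec$names, object$spec$senses,
                           sep = ":", collapse = ", "), "\n")
  cat("Final front (", nrow(object$front$objectives), " points):\n",
      sep = "")
  print(utils::head(object$front$objectives, 10))
  invisible(object)
}
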