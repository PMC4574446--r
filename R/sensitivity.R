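#' Morris elementary-effects screening
#'
#' Randomized one-at-a-time trajectories on the unit-scaled input box:
#' inputs are rescaled to `[0, 1]`, base points are drawn from a `p`-level
#' grid restricted to `[0, 1 - delta]`, and each trajectory perturbs every
#' input once by `+delta` in a random order.  The elementary effect of
#' input `i` is `EE_i = (y(x + delta e_i) - y(x)) / delta`, so on an
#' affine model every `EE_i` equals the unit-scaled coefficient and the
#' per-input standard deviation is exactly zero.  Unit scaling makes the
#' mean effects comparable across inputs, which is what the importance
#' ranking needs.
#'
#' @param evaluator function of an input vector (on the original scale)
#'   returning a scalar output.
#' @param bounds n x 2 matrix of input bounds.
#' @param r number of trajectories (default 20).
#' @param p number of grid levels (even, default 4).
#' @param delta step on the unit-scaled box; default `p / (2 (p - 1))`.
#' @param input_ids optional input names.
#' @return An `elementary_effects` summary: per-input `mu`, `mu_star`,
#'   `sigma`, the raw effects matrix (`r` x n), and the settings.
#' @export
morris_screening <- function(evaluator, bounds, r = 20, p = 4,
                             delta = p / (2 * (p - 1)),
                             input_ids = NULL) {
  bounds <- check_bounds(bounds)
  n <- nrow(bounds)
  if (p %% 2 != 0) stop("p must be even")
  if (is.null(input_ids)) input_ids <- paste0("x", seq_len(n))
  unscale <- function(u) bounds[, 1] + u * (bounds[, 2] - bounds[, 1])
  levels0 <- seq(0, 1 - delta, by = 1 / (p - 1))
  EE <- matrix(NA_real_, r, n, dimnames = list(NULL, input_ids))
  attempts <- 0
  traj <- 1
  while (traj <= r) {
    attempts <- attempts + 1
    if (attempts > 3 * r)
      stop("evaluator kept failing; gave up after ", attempts,
           " trajectory attempts")
    u <- levels0[sample.int(length(levels0), n, replace = TRUE)]
    ord <- sample.int(n)
    y0 <- tryCatch(evaluator(unscale(u)), error = function(e) NA_real_)
    if (!is.finite(y0)) next
    row <- rep(NA_real_, n)
    ok <- TRUE
    for (i in ord) {
      u2 <- u; u2[i] <- u[i] + delta
      y1 <- tryCatch(evaluator(unscale(u2)), error = function(e) NA_real_)
      if (!is.finite(y1)) { ok <- FALSE; break }
      row[i] <- (y1 - y0) / delta
      u <- u2; y0 <- y1
    }
    if (!ok) next
    EE[traj, ] <- row
    traj <- traj + 1
  }
  structure(list(mu = colMeans(EE), mu_star = colMeans(abs(EE)),
                 sigma = apply(EE, 2, stats::sd), effects = EE,
                 r = r, p = p, delta = delta, input_ids = input_ids),
            class = "elementary_effects")
}

#' @export
print.elementary_effects <- function(x, ...) {
  print(data.frame(input_id = x$input_ids, mu = x$mu, mu_star = x$mu_star,
                   sigma = x$sigma, row.names = NULL))
  invisible(x)
}

#' Rank inputs by Morris importance
#'
#' Descending `mu_star`; ties broken by larger `sigma`, then input order.
#'
#' @param summary an `elementary_effects` object.
#' @return Character vector of input ids, most influential first.
#' @export
rank_inputs <- function(summary) {
  ord <- order(-summary$mu_star, -summary$sigma,
               seq_along(summary$input_ids))
  summary$input_ids[ord]
}

#' One-at-a-time local robustness
#'
#' Perturbs each input alone by uniform draws within a relative step of
#' its nominal value and reports the fraction of draws whose output stays
#' within a relative tolerance `rho` of the nominal output (absolute
#' tolerance when the nominal output is zero).
#'
#' @param evaluator scalar evaluator.
#' @param nominal nominal input vector (must be evaluable).
#' @param rel_step relative perturbation half-width (e.g. 0.1 for 10%).
#' @param samples draws per input.
#' @param rho relative output tolerance defining "robust".
#' @param abs_tol absolute fallback tolerance when the nominal output is 0.
#' @return Named numeric vector of robust fractions in `[0, 1]`.
#' @export
local_robustness <- function(evaluator, nominal, rel_step = 0.1,
                             samples = 200, rho = 0.05, abs_tol = 1e-8) {
  y0 <- evaluator(nominal)
  if (!is.finite(y0)) stop("nominal input is not evaluable")
  tol <- if (abs(y0) > 0) rho * abs(y0) else abs_tol
  n <- length(nominal)
  out <- numeric(n)
  for (i in seq_len(n)) {
    width <- rel_step * if (nominal[i] != 0) abs(nominal[i]) else 1
    ok <- 0
    for (s in seq_len(samples)) {
      x <- nominal
      x[i] <- x[i] + stats::runif(1, -width, width)
      y <- tryCatch(evaluator(x), error = function(e) NA_real_)
      if (is.finite(y) && abs(y - y0) <= tol) ok <- ok + 1
    }
    out[i] <- ok / samples
  }
  names(out) <- names(nominal)
  out
}

#' First-order Sobol indices (pick-freeze)
#'
#' Saltelli's estimator on two independent uniform sample matrices `A`
#' and `B`: for each input `i`, `AB_i` is `A` with column `i` taken from
#' `B`, and `S1_i = mean(yB * (yAB_i - yA)) / var(y)`.  Estimates are
#' clamped to `[-0.05, 1]`.
#'
#' @param evaluator scalar evaluator.
#' @param bounds n x 2 input box.
#' @param n_base number of base samples (>= 256).
#' @param input_ids optional input names.
#' @return Named numeric vector of first-order indices.
#' @export
sobol_first_order <- function(evaluator, bounds, n_base = 4096,
                              input_ids = NULL) {
  bounds <- check_bounds(bounds)
  k <- nrow(bounds)
  if (n_base < 256) stop("n_base must be at least 256")
  if (is.null(input_ids)) input_ids <- paste0("x", seq_len(k))
  unscale <- function(U)
    sweep(sweep(U, 2, bounds[, 2] - bounds[, 1], `*`), 2, bounds[, 1], `+`)
  A <- unscale(matrix(stats::runif(n_base * k), n_base, k))
  B <- unscale(matrix(stats::runif(n_base * k), n_base, k))
  evalm <- function(M) apply(M, 1, evaluator)
  yA <- evalm(A); yB <- evalm(B)
  vy <- stats::var(c(yA, yB))
  if (vy <= 1e-300) {
    warning("output variance is zero; all indices reported 0")
    return(stats::setNames(numeric(k), input_ids))
  }
  s1 <- numeric(k)
  for (i in seq_len(k)) {
    ABi <- A; ABi[, i] <- B[, i]
    yABi <- evalm(ABi)
    s1[i] <- mean(yB * (yABi - yA)) / vy
  }
  stats::setNames(pmin(1, pmax(-0.05, s1)), input_ids)
}

#' Write a sensitivity summary as CSV
#'
#' Columns `input_id,mu,mu_star,sigma` for Morris summaries, or
#' `input_id,value` for named vectors (Sobol, robustness).
#'
#' @param x an `elementary_effects` object or named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(x, path) {
  df <- if (inherits(x, "elementary_effects"))
    data.frame(input_id = x$input_ids, mu = x$mu, mu_star = x$mu_star,
               sigma = x$sigma)
  else data.frame(input_id = names(x), value = as.numeric(x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
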