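#' Fixed-flux disease scan
#'
#' Pins one reaction's flux (`lb = ub = g`) at each grid value, solves FBA
#' for the given objective, and collects the optimal flux vectors as the
#' columns of a reactions x scan-points matrix.  Pins whose LP is
#' infeasible yield an all-missing, flagged column.  Pinning with an
#' equality (rather than an upper bound) is what makes each column the
#' network state *given* that flux, which is what the downstream
#' identifiability analysis requires.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to pin (e.g. a disease-impaired enzyme).
#' @param grid numeric vector of pinned flux values, each within the
#'   reaction's wild-type bounds.
#' @param objective FBA objective (named weights or reaction id).
#' @param sense FBA sense.
#' @return A `scan_matrix`: list with `V` (reactions x points), `grid`,
#'   `objective_values`, `feasible` flags, `reaction_id`.
#' @export
disease_scan <- function(model, reaction_id, grid, objective,
                         sense = "max") {
  j <- rxn_index(model, reaction_id)
  if (any(grid < model$lower_bounds[j] - 1e-9) ||
      any(grid > model$upper_bounds[j] + 1e-9))
    stop("grid value outside the wild-type bounds of ", reaction_id)
  n <- length(model$reaction_ids)
  V <- matrix(NA_real_, n, length(grid),
              dimnames = list(model$reaction_ids, NULL))
  ov <- rep(NA_real_, length(grid))
  ok <- logical(length(grid))
  for (k in seq_along(grid)) {
    m2 <- model
    m2$lower_bounds[j] <- grid[k]
    m2$upper_bounds[j] <- grid[k]
    m2$reversible[j] <- m2$reversible[j] | grid[k] < 0
    fd <- solve_fba(m2, objective, sense)
    if (fd$status == "optimal") {
      V[, k] <- fd$fluxes
      ov[k] <- fd$objective_value
      ok[k] <- TRUE
    }
  }
  structure(list(V = V, grid = grid, objective_values = ov,
                 feasible = ok, reaction_id = reaction_id,
                 objective = objective),
            class = "scan_matrix")
}

#' Disease-stage classification from ATP output
#'
#' Labels a condition by its ATP production relative to the normal
#' optimum: `ratio <= 0.33` is `disease`, `0.33 < ratio <= 0.66` is
#' `inflammation`, anything above is `healthy` — a total partition of
#' `[0, Inf)`.
#'
#' @param atp non-negative ATP production of the condition (vectorized).
#' @param atp_normal positive ATP production under normal conditions.
#' @return Factor with levels `healthy`, `inflammation`, `disease`.
#' @export
classify_stage <- function(atp, atp_normal) {
  if (atp_normal <= 0) stop("atp_normal must be positive")
  if (any(atp < 0)) stop("negative ATP production")
  ratio <- atp / atp_normal
  factor(ifelse(ratio <= 0.33, "disease",
                ifelse(ratio <= 0.66, "inflammation", "healthy")),
         levels = c("healthy", "inflammation", "disease"))
}

# local-linear Gaussian kernel smoother evaluated on a grid, then
# interpolated back to the sample points
smooth_ll <- function(x, y, bandwidth = NULL, gridsize = 101) {
  n <- length(x)
  if (is.null(bandwidth)) bandwidth <- 1.06 * stats::sd(x) * n^(-1 / 5)
  if (bandwidth <= 0 || !is.finite(bandwidth)) bandwidth <- 1e-8
  g <- seq(min(x), max(x), length.out = gridsize)
  D <- outer(g, x, `-`)                  # gridsize x n
  W <- exp(-0.5 * (D / bandwidth)^2)
  s0 <- W %*% rep(1, n); s1 <- rowSums(W * D); s2 <- rowSums(W * D^2)
  t0 <- W %*% y;        t1 <- rowSums(W * D * y)
  den <- s0 * s2 - s1^2
  est <- ifelse(abs(den) > 1e-12 * pmax(1, s0 * s2),
                (s2 * t0 - s1 * t1) / den,   # local linear
                t0 / pmax(s0, 1e-300))        # Nadaraya-Watson fallback
  stats::approx(g, est, xout = x, rule = 2)$y
}

#' Alternating conditional expectations (ACE)
#'
#' Estimates the optimal transformations `alpha(x_response)` and
#' `beta_j(x_j)` such that `alpha = sum_j beta_j` in least squares,
#' starting from `alpha = x_i / ||x_i||`, `beta_j = 0` and alternating
#' conditional expectations computed with a scatterplot smoother.
#' `alpha` is kept at unit variance, so the squared residual
#' `e2 = mean((alpha - sum beta)^2)` is the fraction of unexplained
#' variance and `r2 = 1 - e2`.
#'
#' The conditional expectations are computed with Friedman's
#' super-smoother ([stats::supsmu()], the smoother classically used with
#' ACE), whose cross-validated span suppresses the rough
#' noise-eigenfunctions that a fixed-bandwidth kernel smoother lets the
#' alternation drift towards.  A local-linear Gaussian kernel smoother is
#' available via `smoother = "kernel"` with `bandwidth` controlling its
#' width.
#'
#' @param K numeric sample matrix (rows = samples, columns = variables).
#' @param response column index (or name) of the response.
#' @param predictors column indices/names of the predictors.
#' @param smoother `"supsmu"` (default) or `"kernel"`.
#' @param bandwidth kernel bandwidth for `smoother = "kernel"`; default
#'   `1.06 sd(x) n^(-1/5)` per variable.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the change of `e2`.
#' @return A `transformation_set`: tabulated `alpha` and `beta` at the
#'   sample points, `r_squared`, `max_correlation`, `iterations`,
#'   `converged`, and the per-iteration residual trace `e2_trace`.
#' @export
ace <- function(K, response, predictors, smoother = c("supsmu", "kernel"),
                bandwidth = NULL, max_iter = 100, tol = 1e-6) {
  smoother <- match.arg(smoother)
  K <- as.matrix(K)
  if (is.character(response)) response <- match(response, colnames(K))
  if (is.character(predictors)) predictors <- match(predictors, colnames(K))
  if (nrow(K) < 20) stop("ACE needs at least 20 samples")
  if (response %in% predictors)
    stop("response must not be among the predictors")
  used <- c(response, predictors)
  sds <- apply(K[, used, drop = FALSE], 2, stats::sd)
  if (any(sds <= 1e-12 * pmax(1, abs(colMeans(K[, used, drop = FALSE])))))
    stop("constant column among response/predictors")
  xr <- K[, response]
  n <- nrow(K); p <- length(predictors)
  smooth_fn <- if (smoother == "supsmu") {
    function(x, y, bandwidth) {
      f <- stats::supsmu(x, y)
      stats::approx(f$x, f$y, xout = x, rule = 2, ties = "ordered")$y
    }
  } else smooth_ll
  alpha <- xr / sqrt(sum(xr^2))
  alpha <- (alpha - mean(alpha)) / stats::sd(alpha)
  B <- matrix(0, n, p)
  e2_trace <- numeric(0)
  e2_prev <- Inf; converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    for (j in seq_len(p)) {
      resid <- alpha - rowSums(B[, -j, drop = FALSE])
      bj <- smooth_fn(K[, predictors[j]], resid, bandwidth)
      B[, j] <- bj - mean(bj)
    }
    sumb <- rowSums(B)
    a <- smooth_fn(xr, sumb, bandwidth)
    a <- a - mean(a)
    sda <- stats::sd(a)
    if (sda < 1e-12) { converged <- FALSE; break }
    alpha <- a / sda
    e2 <- mean((alpha - sumb)^2)
    e2_trace <- c(e2_trace, e2)
    if (abs(e2_prev - e2) < tol) { converged <- TRUE; break }
    e2_prev <- e2
  }
  sumb <- rowSums(B)
  e2 <- mean((alpha - sumb)^2)
  r2 <- min(1, max(0, 1 - e2))
  structure(list(response = response, predictors = predictors,
                 alpha = alpha, beta = B,
                 x_response = xr,
                 x_predictors = K[, predictors, drop = FALSE],
                 r_squared = r2,
                 max_correlation = suppressWarnings(
                   abs(stats::cor(alpha, sumb))),
                 iterations = it, converged = converged,
                 e2_trace = e2_trace),
            class = "transformation_set")
}

#' @export
print.transformation_set <- function(x, ...) {
  cat("ACE transformation_set: response", x$response, "on",
      length(x$predictors), "predictor(s); r2 =",
      format(x$r_squared, digits = 4),
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' MOTA functional-variable grouping
#'
#' Mean-optimal-transformation grouping: every non-constant variable is
#' taken once as the response of an ACE fit on all remaining variables;
#' predictors are ranked by the variance of their fitted transformation
#' `beta_j`, and the smallest top-ranked predictor set whose ACE refit
#' reaches `r2 >= r2_threshold` (at most `max_group_size - 1` predictors)
#' is reported as a functional group with the response.  A member set
#' detected from two or more of its members as response is flagged
#' *strong*.  Each member is annotated with its coefficient of variation
#' `cv = sd/mean` as a practical-identifiability hint (no hard cv
#' filter is applied).
#'
#' @param K numeric sample matrix (rows = samples/conditions, columns =
#'   variables); constant columns are excluded up front.
#' @param max_group_size maximum group cardinality (default 10).
#' @param r2_threshold minimum explained variance for a reported group.
#' @param min_samples minimum number of rows (default 30).
#' @param smoother,bandwidth,max_iter,tol passed to [ace()].
#' @return List of `functional_group`s: `members`, `response`,
#'   `r_squared`, `strong`, `cv` (named per member).
#' @export
mota_groups <- function(K, max_group_size = 10, r2_threshold = 0.8,
                        min_samples = 30, smoother = "supsmu",
                        bandwidth = NULL, max_iter = 100, tol = 1e-6) {
  K <- as.matrix(K)
  if (nrow(K) < min_samples)
    stop("need at least ", min_samples, " samples, got ", nrow(K))
  if (is.null(colnames(K))) colnames(K) <- paste0("x", seq_len(ncol(K)))
  sds <- apply(K, 2, stats::sd)
  mus <- colMeans(K)
  usable <- which(sds > 1e-10 * pmax(1, abs(mus)))
  if (length(usable) < 2) return(list())
  groups <- list()
  for (i in usable) {
    preds <- setdiff(usable, i)
    full <- tryCatch(ace(K, i, preds, smoother = smoother,
                         bandwidth = bandwidth, max_iter = max_iter,
                         tol = tol),
                     error = function(e) NULL)
    if (is.null(full)) next
    rank_idx <- preds[order(apply(full$beta, 2, stats::var),
                            decreasing = TRUE)]
    found <- NULL
    for (k in seq_len(min(max_group_size - 1, length(rank_idx)))) {
      fit <- if (k == length(rank_idx)) full
             else tryCatch(ace(K, i, rank_idx[seq_len(k)],
                               smoother = smoother, bandwidth = bandwidth,
                               max_iter = max_iter, tol = tol),
                           error = function(e) NULL)
      if (!is.null(fit) && fit$r_squared >= r2_threshold) {
        found <- list(members = sort(c(i, rank_idx[seq_len(k)])),
                      response = i, r_squared = fit$r_squared)
        break
      }
    }
    if (!is.null(found)) groups[[length(groups) + 1L]] <- found
  }
  # strong flag: same member set recovered from >= 2 responses
  keys <- vapply(groups, function(g) paste(g$members, collapse = ","),
                 character(1))
  counts <- table(keys)
  lapply(groups, function(g) {
    key <- paste(g$members, collapse = ",")
    structure(list(members = colnames(K)[g$members],
                   member_index = g$members,
                   response = colnames(K)[g$response],
                   r_squared = g$r_squared,
                   strong = counts[[key]] >= 2,
                   cv = stats::setNames(sds[g$members] / mus[g$members],
                                        colnames(K)[g$members])),
              class = "functional_group")
  })
}

#' @export
print.functional_group <- function(x, ...) {
  cat("functional_group {", paste(x$members, collapse = ", "), "}",
      if (x$strong) "**" else "", " r2 =",
      format(x$r_squared, digits = 4),
      " (response ", x$response, ")\n", sep = "")
  invisible(x)
}

assign_stages <- function(grid, objective_values, atp_normal,
                          stage_breaks = NULL) {
  if (is.null(stage_breaks))
    return(classify_stage(pmax(objective_values, 0), atp_normal))
  stopifnot(length(stage_breaks) == 2)
  b1 <- stage_breaks[1]; b2 <- stage_breaks[2]
  lab <- if (b1 > b2) {
    # descending convention: healthy [hi, b1), inflammation [b1, b2),
    # disease [b2, 0] — half-open intervals include their
    # first (larger) endpoint
    ifelse(grid > b1, "healthy",
           ifelse(grid > b2, "inflammation", "disease"))
  } else {
    ifelse(grid < b1, "healthy",
           ifelse(grid < b2, "inflammation", "disease"))
  }
  factor(lab, levels = c("healthy", "inflammation", "disease"))
}

#' Stage-resolved identifiability analysis of a monogenic deficiency
#'
#' Builds the fixed-flux [disease_scan()] for the impaired reaction,
#' splits the scan columns into healthy / inflammation / disease stages
#' (by ATP-based [classify_stage()] against the unpinned optimum, or by
#' explicit flux breakpoints), restricts the rows to the requested
#' (matrix-compartment) reactions, and runs [mota_groups()] within each
#' stage.  Functional relations can differ between stages and between
#' diseases, which is the basis for stage characterization.  Infeasible
#' scan columns are dropped listwise; a stage with fewer than
#' `min_samples` columns is reported empty with a warning.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id impaired reaction to scan.
#' @param grid pinned flux grid.
#' @param objective FBA objective (ATP production).
#' @param stage_breaks optional two flux breakpoints (see
#'   `assign_stages`); `NULL` classifies by ATP ratio.
#' @param matrix_reactions reaction ids used as identifiability
#'   variables; default all reactions.
#' @param ... passed to [mota_groups()].
#' @return A `disease_report`: per-stage group lists, the stage factor,
#'   and the underlying scan.
#' @export
characterize_disease <- function(model, reaction_id, grid, objective,
                                 stage_breaks = NULL,
                                 matrix_reactions = NULL, ...) {
  scan <- disease_scan(model, reaction_id, grid, objective)
  wt <- solve_fba(model, objective, "max")
  keep <- scan$feasible
  stages <- assign_stages(scan$grid[keep], scan$objective_values[keep],
                          wt$objective_value, stage_breaks)
  V <- scan$V[, keep, drop = FALSE]
  if (!is.null(matrix_reactions))
    V <- V[rxn_index(model, matrix_reactions), , drop = FALSE]
  dots <- list(...)
  min_samples <- if (!is.null(dots$min_samples)) dots$min_samples else 30
  res <- list()
  for (st in levels(stages)) {
    cols <- which(stages == st)
    if (length(cols) == 0) { res[[st]] <- list(); next }
    if (length(cols) < min_samples) {
      warning("stage '", st, "' has only ", length(cols),
              " scan points; reported empty")
      res[[st]] <- list()
      next
    }
    res[[st]] <- do.call(mota_groups, c(list(K = t(V[, cols])), dots))
  }
  structure(list(stages = res, stage_of_column = stages, scan = scan,
                 atp_normal = wt$objective_value,
                 reaction_id = reaction_id),
            class = "disease_report")
}

#' @export
print.disease_report <- function(x, ...) {
  cat("disease_report for", x$reaction_id, "\n")
  for (st in names(x$stages))
    cat("  ", st, ": ", length(x$stages[[st]]), " group(s)\n", sep = "")
  invisible(x)
}

#' Write a stage-resolved group report as CSV
#'
#' Columns `stage,response_id,predictor_ids,r2,strong,cv_members`.
#'
#' @param report a `disease_report` (or named list of group lists).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_group_report <- function(report, path) {
  stages <- if (inherits(report, "disease_report")) report$stages else report
  rows <- list()
  for (st in names(stages)) {
    for (g in stages[[st]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, response_id = g$response,
        predictor_ids = paste(setdiff(g$members, g$response),
                              collapse = ";"),
        r2 = g$r_squared, strong = g$strong,
        cv_members = paste(sprintf("%s=%.4g", names(g$cv), g$cv),
                           collapse = ";"))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(stage = character(), response_id = character(),
                        predictor_ids = character(), r2 = numeric(),
                        strong = logical(), cv_members = character())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
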