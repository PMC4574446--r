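# Shared fixtures and independent oracles, all built in code.

# linear chain EX_A -> A -> B -> sink
chain_model <- function(cap = 5) {
  S <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("EX_A", "R_AB", "SINK")))
  metabolic_model(S, c(0, 0, 0), c(cap, 10, 10))
}

# small respiration network used for exhaustive vertex enumeration
mini_respiration <- function() {
  mets <- c("GLC", "O2", "PYR", "NADH", "ATP", "LAC")
  rxn <- list(
    EX_glc = c(GLC = -1), EX_o2 = c(O2 = -1),
    GLYC = c(GLC = -1, PYR = 2, NADH = 2, ATP = 2),
    TCA = c(PYR = -1, NADH = 3),
    ETC = c(NADH = -1, O2 = -0.5, ATP = 2.5),
    LDH = c(PYR = -1, NADH = -1, LAC = 1),
    EX_lac = c(LAC = -1),
    DM_atp = c(ATP = -1))
  S <- matrix(0, length(mets), length(rxn),
              dimnames = list(mets, names(rxn)))
  for (j in seq_along(rxn)) S[names(rxn[[j]]), j] <- rxn[[j]]
  metabolic_model(S,
                  lower_bounds = c(-5, -10, 0, 0, 0, -50, 0, 0),
                  upper_bounds = c(0, 0, 100, 100, 100, 50, 50, 100),
                  is_exchange = grepl("^EX_", names(rxn)))
}

# exhaustive basic-feasible-solution enumeration oracle for
# max w'v s.t. S v = 0, lb <= v <= ub (tiny networks only)
vertex_enum_max <- function(model, w, tol = 1e-8) {
  S <- model$stoichiometry
  lb <- model$lower_bounds; ub <- model$upper_bounds
  n <- ncol(S)
  r <- qr(S)$rank
  if (r < nrow(S)) {
    keep <- qr(t(S))$pivot[seq_len(r)]
    S <- S[keep, , drop = FALSE]
  }
  m <- nrow(S)
  best <- -Inf
  for (basic in utils::combn(n, m, simplify = FALSE)) {
    SB <- S[, basic, drop = FALSE]
    if (abs(det(SB)) < 1e-10) next
    nonbasic <- setdiff(seq_len(n), basic)
    grid <- expand.grid(rep(list(c(1, 2)), length(nonbasic)))
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[nonbasic] <- ifelse(grid[g, ] == 1, lb[nonbasic], ub[nonbasic])
      v[basic] <- solve(SB, -S[, nonbasic, drop = FALSE] %*% v[nonbasic])
      if (all(v >= lb - tol) && all(v <= ub + tol))
        best <- max(best, sum(w * v))
    }
  }
  best
}

# O(n^2) brute-force Pareto filter
brute_pareto <- function(points, senses = "max",
                         mode = c("standard", "strict")) {
  mode <- match.arg(mode)
  senses <- rep_len(senses, ncol(points))
  P <- sweep(points, 2, ifelse(senses == "min", -1, 1), `*`)
  n <- nrow(P)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (i == j) next
      if (mode == "strict") {
        if (all(P[j, ] > P[i, ])) { dominated <- TRUE; break }
      } else if (all(P[j, ] >= P[i, ]) && any(P[j, ] > P[i, ])) {
        dominated <- TRUE; break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# directed/symmetric Hausdorff distance between a point set and a
# piecewise-linear front polyline, normalized per objective
front_hausdorff <- function(points, front_vertices) {
  stopifnot(ncol(points) == 2, ncol(front_vertices) == 2)
  rng <- apply(front_vertices, 2, function(z) max(z) - min(z))
  rng[rng == 0] <- 1
  norm_p <- sweep(points, 2, rng, `/`)
  fv <- front_vertices[order(front_vertices[, 1]), , drop = FALSE]
  norm_f <- sweep(fv, 2, rng, `/`)
  # dense sampling of the polyline
  samp <- norm_f
  if (nrow(norm_f) > 1) {
    for (k in seq_len(nrow(norm_f) - 1)) {
      t <- seq(0, 1, length.out = 50)
      seg <- outer(1 - t, norm_f[k, ]) + outer(t, norm_f[k + 1, ])
      samp <- rbind(samp, seg)
    }
  }
  dmat <- function(A, B) {
    d2 <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
    sqrt(d2)
  }
  d1 <- max(apply(dmat(norm_p, samp), 1, min))   # points -> front
  d2 <- max(apply(dmat(samp, norm_p), 1, min))   # front -> points
  max(d1, d2)
}

quad_evaluator <- function(center = 3, n = 5) {
  function(x) list(objectives = -sum((x - center)^2), constraint = 0)
}

new_candidate_for_test <- function(n = 3, age = 0L, fitness = NA) {
  cand <- list(x = seq_len(n) / 2, sigma = rep(0.4, n), age = age,
               objectives = NULL, fitness = fitness,
               violation = NA_real_, feasible = NA)
  if (!is.na(fitness)) attr(cand$fitness, "raw") <- fitness
  cand
}
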