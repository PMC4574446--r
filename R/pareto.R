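#' Objective specification
#'
#' Declares `r` objectives by name and optimization sense.  Internally all
#' comparisons are performed on a maximization scale (minimized objectives
#' have their sign flipped).
#'
#' @param names character vector of objective names.
#' @param senses `"max"` or `"min"` per objective (recycled).
#' @return An `objective_spec`.
#' @export
objective_spec <- function(names, senses = "max") {
  senses <- rep_len(match.arg(senses, c("max", "min"), several.ok = TRUE),
                    length(names))
  if (length(names) < 1) stop("at least one objective is required")
  structure(list(names = as.character(names), senses = senses,
                 r = length(names)), class = "objective_spec")
}

to_max_scale <- function(points, spec) {
  points <- rbind(points)
  if (ncol(points) != spec$r)
    stop("objective length ", ncol(points), " does not match spec (r = ",
         spec$r, ")")
  sweep(points, 2, ifelse(spec$senses == "min", -1, 1), `*`)
}

#' Pareto dominance between two objective vectors
#'
#' Two notions are supported.  `"strict"` declares `a` dominant over
#' `b` only when `a` is strictly better in every objective; `"standard"`
#' uses the usual weak definition (at least as good everywhere, strictly
#' better somewhere).  Minimized objectives are compared with flipped sign.
#'
#' @param a,b numeric objective vectors of equal length.
#' @param spec an [objective_spec()].
#' @param mode `"standard"` or `"strict"`.
#' @return Logical: does `a` dominate `b`?
#' @export
dominates <- function(a, b, spec = objective_spec(paste0("f", seq_along(a))),
                      mode = c("standard", "strict")) {
  mode <- match.arg(mode)
  if (length(a) != length(b))
    stop("objective vectors have different lengths")
  am <- drop(to_max_scale(a, spec)); bm <- drop(to_max_scale(b, spec))
  if (mode == "strict") all(am > bm)
  else all(am >= bm) && any(am > bm)
}

dominance_matrix <- function(P, mode) {
  # P on max scale, n x r; returns n x n logical: [i,j] = i dominates j
  n <- nrow(P)
  ge <- matrix(TRUE, n, n); gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(P))) {
    dif <- outer(P[, k], P[, k], `-`)
    ge <- ge & (dif >= 0)
    gt <- gt | (dif > 0)
  }
  if (identical(mode, "strict")) {
    st <- matrix(TRUE, n, n)
    for (k in seq_len(ncol(P))) st <- st & (outer(P[, k], P[, k], `-`) > 0)
    st
  } else ge & gt
}

#' Extract the Pareto-optimal subset of a point set
#'
#' Returns the indices of points not dominated by any other point.
#' Duplicate objective points are all retained (under either mode a point
#' never dominates its duplicate), so front cardinalities are well defined
#' under resampling.
#'
#' @param points numeric matrix (rows = points) or list of vectors.
#' @param spec an [objective_spec()]; defaults to maximizing all columns.
#' @param mode dominance mode, see [dominates()].
#' @return Integer vector of row indices of the non-dominated points.
#' @export
pareto_front <- function(points, spec = NULL,
                         mode = c("standard", "strict")) {
  mode <- match.arg(mode)
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point set")
  if (is.null(spec)) spec <- objective_spec(paste0("f", seq_len(ncol(points))))
  P <- to_max_scale(points, spec)
  dom <- dominance_matrix(P, mode)
  which(colSums(dom) == 0)
}

#' Epsilon-non-dominated subset
#'
#' Relaxed dominance post-analysis: a point `y*` is retained unless some
#' point exceeds it by at least `eps_i` in *every* objective.  The result
#' always contains the Pareto front of the same input and grows
#' monotonically with `eps`.
#'
#' @param points numeric matrix of objective vectors (rows = points).
#' @param eps strictly positive numeric vector, one tolerance per
#'   objective (recycled).
#' @param spec an [objective_spec()].
#' @return Integer vector of row indices of epsilon-non-dominated points.
#' @export
epsilon_nondominated <- function(points, eps, spec = NULL) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point set")
  if (is.null(spec)) spec <- objective_spec(paste0("f", seq_len(ncol(points))))
  eps <- rep_len(as.numeric(eps), spec$r)
  if (any(eps <= 0)) stop("eps must be strictly positive in every objective")
  P <- to_max_scale(points, spec)
  n <- nrow(P)
  dom <- matrix(TRUE, n, n)
  for (k in seq_len(ncol(P)))
    dom <- dom & (outer(P[, k], P[, k], `-`) >= eps[k])
  diag(dom) <- FALSE
  which(colSums(dom) == 0)
}

#' Write a Pareto front as CSV (with JSON mirror)
#'
#' Columns `obj_1..obj_r`, then `x_1..x_n` when decision vectors are
#' present, then `generation`.
#'
#' @param objectives numeric matrix of objective points (rows = points).
#' @param decisions optional matrix of paired decision vectors.
#' @param generation integer tag per row (recycled).
#' @param path CSV output path.
#' @param json also write `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_front <- function(objectives, decisions = NULL, generation = NA,
                        path, json = FALSE) {
  objectives <- rbind(objectives)
  df <- as.data.frame(objectives)
  names(df) <- paste0("obj_", seq_len(ncol(objectives)))
  if (!is.null(decisions)) {
    decisions <- rbind(decisions)
    dd <- as.data.frame(decisions)
    names(dd) <- paste0("x_", seq_len(ncol(decisions)))
    df <- cbind(df, dd)
  }
  df$generation <- rep_len(generation, nrow(df))
  # fixed formatting so identical runs produce byte-identical files
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, format = "g",
                                                 digits = 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (json)
    jsonlite::write_json(df, paste0(path, ".json"), digits = NA)
  invisible(path)
}
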