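test_that("initialization draws inside the box with the prescribed step sizes", {
  bounds <- cbind(rep(0, 10), rep(10, 10))
  set.seed(1)
  P <- initialize_population(bounds, opt_config(d = 20))
  expect_length(P, 20)
  for (cand in P) {
    expect_true(all(cand$x >= 0 & cand$x <= 10))
    expect_equal(cand$sigma, rep(0.4, 10))   # 0.4 * (10 - 0) / 10
    expect_equal(cand$age, 0L)
  }
  set.seed(5); P1 <- initialize_population(bounds, opt_config(d = 3))
  set.seed(5); P2 <- initialize_population(bounds, opt_config(d = 3))
  expect_identical(P1, P2)
  expect_length(initialize_population(bounds, opt_config(d = 1)), 1)
  expect_error(initialize_population(cbind(1, 0), opt_config()), "bound")
})

test_that("normalized fitness reproduces its defining arithmetic", {
  expect_equal(as.numeric(normalized_fitness(c(5, 10), c(10, 10))), 0.75)
  expect_equal(as.numeric(normalized_fitness(c(10, 10), c(10, 10))), 1)
  expect_equal(as.numeric(normalized_fitness(c(0, 0), c(10, 10))), 0)
  # non-positive f_max coordinates fall back to a unit denominator
  expect_equal(as.numeric(normalized_fitness(c(0.5, 2), c(-Inf, 4))), 0.5)
  # clamped, raw kept for tie-breaking
  f <- normalized_fitness(c(30), c(10))
  expect_equal(as.numeric(f), 1)
  expect_equal(attr(f, "raw"), 3)
  expect_error(normalized_fitness(c(1, 2), 1), "mismatch")
})

test_that("copying produces dup copies and ages the parents", {
  P <- replicate(3, new_candidate_for_test(age = 7L), simplify = FALSE)
  cp <- copying(P, 2)
  expect_length(cp$copies, 6)
  expect_true(all(vapply(cp$copies, `[[`, integer(1), "age") == 7L))
  expect_true(all(vapply(cp$parents, `[[`, integer(1), "age") == 8L))
  cp1 <- copying(P, 1)
  expect_identical(cp1$copies, P)
  cp4 <- copying(P[1], 4)
  expect_length(cp4$copies, 4)
  expect_true(all(vapply(cp4$copies, `[[`, integer(1), "age") == 7L))
})

test_that("local search fires with certainty at F = 0 and mutates one variable", {
  bounds <- cbind(rep(-5, 6), rep(5, 6))
  cand <- new_candidate_for_test(n = 6, fitness = 0)
  set.seed(11)
  for (k in 1:25) {
    out <- local_search(cand, rho = 1, bounds)  # alpha = exp(0) = 1
    changed <- sum(out$x != cand$x)
    expect_equal(changed, 1)
    expect_true(all(out$x >= -5 & out$x <= 5))
  }
  # fixed seed reproduces the mutation exactly
  set.seed(4); a <- local_search(cand, 1, bounds)
  set.seed(4); b <- local_search(cand, 1, bounds)
  expect_identical(a, b)
  # at high fitness the mutation fires with probability exp(-rho)
  cand1 <- new_candidate_for_test(n = 6, fitness = 1)
  set.seed(12)
  fired <- sum(replicate(400, {
    out <- local_search(cand1, rho = 1, bounds)
    any(out$x != cand1$x)
  }))
  expect_gt(fired / 400, exp(-1) - 0.08)
  expect_lt(fired / 400, exp(-1) + 0.08)
})

test_that("global search applies the convex blend at rate exp(-F)/beta", {
  bounds <- cbind(rep(0, 4), rep(10, 4))
  pool <- replicate(5, new_candidate_for_test(n = 4, fitness = 0),
                    simplify = FALSE)
  cand <- pool[[1]]
  set.seed(21)
  fired <- sum(replicate(2000, {
    out <- global_search(cand, pool, beta = 7, bounds, self_index = 1)
    any(out$x != cand$x)
  }))
  expect_equal(fired / 2000, 1 / 7, tolerance = 0.15)
  # at most one coordinate moves, and it stays in the box
  set.seed(22)
  for (k in 1:50) {
    out <- global_search(cand, pool, beta = 1e-9, bounds, self_index = 1)
    expect_lte(sum(out$x != cand$x), 1)
    expect_true(all(out$x >= 0 & out$x <= 10))
  }
})

test_that("constraint evaluation respects the feasibility threshold", {
  expect_equal(evaluate_constraints(3, theta = 5),
               list(feasible = TRUE, violation = 0))
  expect_equal(evaluate_constraints(7, theta = 5),
               list(feasible = FALSE, violation = 2))
  expect_equal(evaluate_constraints(NA, theta = 5),
               list(feasible = FALSE, violation = Inf))
})

test_that("diversity enforcing retires by age with the +1 grace", {
  arch <- create_archive(10)
  old <- new_candidate_for_test(age = 52L)
  edge <- new_candidate_for_test(age = 51L)
  out <- diversity_enforcing(list(old, edge), list(), tau_B = 50, arch)
  expect_length(out$P, 1)
  expect_equal(out$P[[1]]$age, 51L)
  expect_equal(archive_occupancy(out$archive), 1)
})

test_that("a full archive overwrites a random slot, occupancy unchanged", {
  arch <- create_archive(4)
  for (k in 1:4)
    arch <- archive_insert(arch, new_candidate_for_test(age = k))
  expect_equal(archive_occupancy(arch), 4)
  set.seed(9)
  arch2 <- archive_insert(arch, new_candidate_for_test(age = 99L))
  expect_equal(archive_occupancy(arch2), 4)
  ages <- vapply(arch2$slots, `[[`, integer(1), "age")
  expect_true(99L %in% ages)
})

test_that("selection prefers feasibility, fitness, then low violation", {
  mk <- function(feasible, fit = NA, viol = NA) {
    cand <- new_candidate_for_test(fitness = if (is.na(fit)) 0 else fit)
    cand$feasible <- feasible
    cand$violation <- viol
    cand$objectives <- 1
    cand
  }
  feas_low <- mk(TRUE, fit = 0.3)
  feas_hi <- mk(TRUE, fit = 0.9)
  infeas_a <- mk(FALSE, viol = 2)
  infeas_b <- mk(FALSE, viol = 5)
  arch <- create_archive(4)
  sel <- selection(list(feas_low, infeas_a), list(), arch, 1,
                   cbind(0, 1))
  expect_true(sel[[1]]$feasible)       # feasible beats infeasible
  sel2 <- selection(list(feas_low, feas_hi), list(), arch, 1, cbind(0, 1))
  expect_equal(as.numeric(sel2[[1]]$fitness), 0.9)
  sel3 <- selection(list(infeas_a, infeas_b), list(), arch, 1, cbind(0, 1))
  expect_equal(sel3[[1]]$violation, 2)
  # deficit filled from the archive, then with fresh candidates
  for (k in 1:3) arch <- archive_insert(arch, mk(TRUE, fit = 0.1))
  set.seed(31)
  sel4 <- selection(list(feas_low), list(), arch, 4, cbind(0, 1))
  expect_length(sel4, 4)
})

test_that("the optimizer solves a separable quadratic to 1e-2", {
  res <- run_optbiocad(quad_evaluator(center = 3, n = 5),
                       bounds = cbind(rep(0, 5), rep(6, 5)),
                       spec = objective_spec("loss"),
                       config = opt_config(t_final = 100, seed = 17))
  best <- res$front$objectives[which.max(res$front$objectives[, 1]), ]
  expect_gt(best, -1e-2)   # -(sum (x-3)^2) close to 0
  xbest <- res$front$decisions[which.max(res$front$objectives[, 1]), ]
  expect_true(all(abs(xbest - 3) < 0.1))
})

test_that("best observed loss is non-increasing across generations", {
  # elitism-in-effect on the quadratic, checked over 10 seeds
  for (seed in 1:10) {
    res <- run_optbiocad(quad_evaluator(center = 3, n = 3),
                         bounds = cbind(rep(0, 3), rep(6, 3)),
                         spec = objective_spec("loss"),
                         config = opt_config(t_final = 30, seed = seed))
    best_by_gen <- vapply(res$fronts, function(fr)
      max(fr$objectives[, 1]), numeric(1))
    expect_true(all(diff(best_by_gen) >= 0), info = paste("seed", seed))
  }
})

test_that("runs are deterministic generation by generation under a seed", {
  cfg <- opt_config(t_final = 15, seed = 99)
  run <- function() run_optbiocad(quad_evaluator(center = 1, n = 3),
                                  cbind(rep(0, 3), rep(2, 3)),
                                  objective_spec("loss"), cfg)
  r1 <- run(); r2 <- run()
  expect_identical(r1$fronts, r2$fronts)
  expect_identical(r1$log, r2$log)
})

test_that("population size is restored to d every generation", {
  res <- run_optbiocad(quad_evaluator(center = 0, n = 2),
                       cbind(rep(-1, 2), rep(1, 2)),
                       objective_spec("loss"),
                       opt_config(d = 8, t_final = 10, seed = 2,
                                  tau_B = 1))  # aggressive retirement
  expect_length(res$population, 8)
})

test_that("every reported front is internally non-dominated", {
  res <- run_optbiocad(
    function(x) list(objectives = c(x[1], 1 - x[1]^2), constraint = 0),
    bounds = cbind(0, 1), spec = objective_spec(c("a", "b")),
    config = opt_config(t_final = 20, seed = 5))
  for (fr in res$fronts) {
    idx <- brute_pareto(fr$objectives, "max", "standard")
    expect_equal(sort(idx), seq_len(nrow(fr$objectives)))
  }
})

test_that("an evaluator failing on most of a generation aborts loudly", {
  bad <- function(x) stop("boom")
  expect_error(
    run_optbiocad(bad, cbind(0, 1), objective_spec("f"),
                  opt_config(t_final = 2, seed = 1)),
    "evaluator failed")
})
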