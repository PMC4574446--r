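test_that("the abundance multiplier matches its closed forms", {
  expect_equal(abundance_multiplier(1), 1)
  expect_equal(abundance_multiplier(exp(1)), 2)
  expect_equal(abundance_multiplier(1 / exp(1)), 0.5)
  expect_equal(abundance_multiplier(0), 0)
  expect_equal(abundance_multiplier(1e-9), 1 / (1 + 9 * log(10)))
  expect_lt(abundance_multiplier(1e-9), 0.05)
  expect_error(abundance_multiplier(-0.1), "non-negative")
})

test_that("the multiplier is continuous, increasing, and bounded by 1", {
  y <- exp(seq(log(1e-8), log(1e4), length.out = 10000))
  f <- abundance_multiplier(y)
  expect_true(all(diff(f) > 0))              # strictly increasing
  expect_true(all(f[y <= 1] <= 1 + 1e-12))
  expect_true(all(f[y >= 1] >= 1 - 1e-12))
  # continuity across the patched point and the knockout limit
  expect_equal(abundance_multiplier(1 - 1e-9), 1, tolerance = 1e-8)
  expect_equal(abundance_multiplier(1 + 1e-9), 1, tolerance = 1e-8)
  expect_lt(abundance_multiplier(1e-300), 0.002)
})

test_that("abundance scaling acts on wild-type bounds", {
  m <- toy_mitochondrion(42)
  ids <- c("GLYC", "LDH", "ETC")
  # y = 1 reproduces the wild type bit-exact
  m1 <- apply_abundances(m, stats::setNames(c(1, 1, 1), ids))
  expect_identical(m1, m)
  # y = 0 closes the reaction
  m0 <- apply_abundances(m, stats::setNames(0, "ETC"))
  j <- match("ETC", m$reaction_ids)
  expect_equal(m0$lower_bounds[j], 0)
  expect_equal(m0$upper_bounds[j], 0)
  # y = e doubles a symmetric box
  me <- apply_abundances(m, stats::setNames(exp(1), "LDH"))
  j <- match("LDH", m$reaction_ids)
  expect_equal(me$lower_bounds[j], 2 * m$lower_bounds[j])
  expect_equal(me$upper_bounds[j], 2 * m$upper_bounds[j])
  # idempotence from wild type: scaling once equals scaling once more
  y <- stats::setNames(c(0.5, 3), c("GLYC", "ETC"))
  expect_equal(apply_abundances(m, y), apply_abundances(m, y))
  # bound order survives scaling
  expect_true(all(me$lower_bounds <= me$upper_bounds))
  expect_error(apply_abundances(m, stats::setNames(1, "NOPE")), "unknown")
})

test_that("one protein may control several reactions via the min rule", {
  m <- mini_respiration()
  pm <- data.frame(protein = c("P1", "P1", "P2"),
                   reaction = c("GLYC", "TCA", "TCA"))
  y <- stats::setNames(c(exp(1), 1 / exp(1)), c("P1", "P2"))
  m2 <- apply_abundances(m, abundance_profile(y, names(y)),
                         protein_map = pm)
  expect_equal(m2$upper_bounds[match("GLYC", m2$reaction_ids)],
               2 * m$upper_bounds[match("GLYC", m$reaction_ids)])
  # TCA takes min(f(e), f(1/e)) = 0.5
  expect_equal(m2$upper_bounds[match("TCA", m2$reaction_ids)],
               0.5 * m$upper_bounds[match("TCA", m$reaction_ids)])
})

test_that("PADMO front contains or dominates the wild-type point", {
  m <- toy_mitochondrion(42)
  objs <- list(c(DM_atp = 1),
               composite_objective(m, m$named_sets$biomass,
                                   exclude = "DM_atp"))
  wt <- c(solve_fba(m, objs[[1]])$objective_value,
          solve_fba(m, objs[[2]])$objective_value)
  res <- run_padmo(m, objs, config = opt_config(d = 10, t_final = 15,
                                                seed = 7, theta = 0),
                   y_max = 100)
  fr <- res$front$objectives
  ok <- apply(fr, 1, function(p) all(p >= wt - 1e-6)) |
    apply(fr, 1, function(p) all(abs(p - wt) < 1e-6))
  expect_true(any(ok))
  expect_equal(ncol(res$abundances), ncol(res$front$decisions))
})

test_that("binary PADMO reproduces the exhaustive knockout front", {
  m <- toy_mitochondrion(42)
  controlled <- m$reaction_ids[!m$is_exchange]
  objs <- list(c(DM_atp = 1),
               composite_objective(m, m$named_sets$biomass,
                                   exclude = "DM_atp"))
  # oracle: enumerate every 0-, 1- and 2-knockout configuration
  sets <- c(list(integer(0)),
            lapply(seq_along(controlled), function(i) i),
            utils::combn(length(controlled), 2, simplify = FALSE))
  pairs <- t(vapply(sets, function(ko) {
    y <- stats::setNames(rep(1, length(controlled)), controlled)
    y[ko] <- 0
    m2 <- apply_abundances(m, y)
    c(solve_fba(m2, objs[[1]])$objective_value,
      solve_fba(m2, objs[[2]])$objective_value)
  }, numeric(2)))
  oracle <- unique(round(pairs[brute_pareto(pairs, "max", "standard"), ,
                               drop = FALSE], 6))
  res <- run_padmo(m, objs, controlled,
                   config = opt_config(d = 12, t_final = 25, seed = 5,
                                       theta = 0),
                   value_set = c(0, 1),
                   constraint = function(y) max(0, sum(y == 0) - 2))
  found <- unname(unique(round(res$front$objectives, 6)))
  expect_equal(found[order(found[, 1]), , drop = FALSE],
               unname(oracle[order(oracle[, 1]), , drop = FALSE]))
  # the recovered designs are binary with at most two knockouts
  expect_true(all(res$abundances %in% c(0, 1)))
  expect_true(all(rowSums(res$abundances == 0) <= 2))
})

test_that("all-ones abundances for one generation give the wild type", {
  m <- mini_respiration()
  objs <- list(c(DM_atp = 1))
  wt <- solve_fba(m, objs[[1]])$objective_value
  res <- run_padmo(m, objs, config = opt_config(d = 4, t_final = 1,
                                                seed = 1, theta = 0),
                   value_set = 1)   # every candidate snaps to y = 1
  expect_true(all(abs(res$front$objectives[, 1] - wt) < 1e-9))
})

test_that("abundance profiles are written as tidy CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  ab <- rbind(c(GLYC = 1, ETC = 0), c(GLYC = 2, ETC = 1))
  write_abundances(ab, path)
  df <- read.csv(path)
  expect_equal(names(df), c("design", "reaction_id", "abundance"))
  expect_equal(nrow(df), 4)
  expect_equal(df$abundance[df$design == 1 & df$reaction_id == "ETC"], 0)
})
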