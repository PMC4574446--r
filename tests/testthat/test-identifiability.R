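# Scan fixture with a planted stage-specific coupling: ATP comes only
# from the scanned reaction (A -> ATP + 0.35 X); a fixed demand for X
# (2 units) is met by the scan by-product when the scanned flux g is
# high, and otherwise by a two-step backup chain B -> Y -> X whose two
# reactions are forced to carry the identical flux 2 - 0.35 g.  The
# backup pair is therefore active (and linearly coupled) only at low g.
scan_demo_model <- function() {
  mets <- c("A", "B", "Y", "X", "ATP")
  rxn <- list(
    EX_A = c(A = -1), EX_B = c(B = -1),
    R_scan = c(A = -1, ATP = 1, X = 0.35),
    B1 = c(B = -1, Y = 1), B2 = c(Y = -1, X = 1),
    D_X = c(X = -1), EX_X = c(X = -1),
    DM_atp = c(ATP = -1))
  S <- matrix(0, length(mets), length(rxn),
              dimnames = list(mets, names(rxn)))
  for (j in seq_along(rxn)) S[names(rxn[[j]]), j] <- rxn[[j]]
  metabolic_model(S,
                  lower_bounds = c(-10, -10, 0, 0, 0, 2, 0, 0),
                  upper_bounds = c(0, 0, 10, 100, 100, 2, 100, 100),
                  is_exchange = grepl("^EX_", names(rxn)))
}

test_that("a disease scan pins fluxes and keeps columns mass-balanced", {
  m <- scan_demo_model()
  grid <- seq(0, 10, length.out = 50)
  scan <- disease_scan(m, "R_scan", grid, "DM_atp")
  expect_true(all(scan$feasible))
  expect_equal(dim(scan$V), c(8, 50))
  for (k in c(1, 25, 50))
    expect_lt(mass_balance_residual(m, scan$V[, k]), 1e-6)
  # ATP output equals the pinned flux by construction
  expect_equal(scan$objective_values, grid, tolerance = 1e-8)
  # pinning at the wild-type optimum reproduces the unpinned optimum
  wt <- solve_fba(m, "DM_atp")
  pinned <- disease_scan(m, "R_scan",
                         unname(wt$fluxes["R_scan"]), "DM_atp")
  expect_equal(pinned$objective_values, wt$objective_value,
               tolerance = 1e-8)
  expect_error(disease_scan(m, "R_scan", 11, "DM_atp"), "outside")
  expect_error(disease_scan(m, "NOPE", 1, "DM_atp"), "unknown")
})

test_that("stage classification partitions the ATP ratio axis", {
  expect_equal(as.character(classify_stage(0.33, 1)), "disease")
  expect_equal(as.character(classify_stage(0.50, 1)), "inflammation")
  expect_equal(as.character(classify_stage(1.00, 1)), "healthy")
  # totality on [0, Inf): every ratio gets exactly one label
  ratios <- c(0, 1e-9, seq(0, 2, by = 0.001), 10, 1e6)
  labels <- classify_stage(ratios, 1)
  expect_false(anyNA(labels))
  expect_equal(as.character(classify_stage(0.66, 1)), "inflammation")
  expect_equal(as.character(classify_stage(0.661, 1)), "healthy")
  expect_error(classify_stage(1, 0), "positive")
  expect_error(classify_stage(-1, 1), "negative")
})

test_that("ACE recovers linear, nonlinear, and null relations", {
  set.seed(1)
  n <- 500
  x1 <- rnorm(n)
  x2 <- 2 * x1 + rnorm(n, 0, 0.1)
  fit <- ace(cbind(x1, x2), response = 2, predictors = 1)
  expect_gte(fit$r_squared, 0.99)
  expect_lt(abs(fit$max_correlation - abs(cor(x1, x2))), 0.02)

  xq <- runif(n, -1, 1)
  yq <- xq^2
  expect_lt(abs(cor(xq, yq)), 0.1)
  fitq <- ace(cbind(xq, yq), response = 2, predictors = 1)
  expect_gte(fitq$r_squared, 0.95)
  # the recovered predictor transformation is even in x
  bpos <- fitq$beta[xq > 0.3, 1]
  bneg <- fitq$beta[xq < -0.3, 1]
  expect_gt(mean(bpos), mean(fitq$beta[abs(xq) < 0.2, 1]))
  expect_gt(mean(bneg), mean(fitq$beta[abs(xq) < 0.2, 1]))

  fitn <- ace(cbind(rnorm(n), rnorm(n)), response = 2, predictors = 1)
  expect_lte(fitn$r_squared, 0.3)
})

test_that("ACE rejects degenerate inputs and bad call shapes", {
  K <- cbind(rnorm(50), rnorm(50))
  expect_error(ace(K[1:10, ], 2, 1), "20 samples")
  expect_error(ace(K, 1, 1), "must not be among")
  expect_error(ace(cbind(K, 7), 3, 1:2), "constant")
})

test_that("ACE residual is non-increasing and affine-invariant", {
  set.seed(8)
  n <- 400
  x1 <- rnorm(n); x2 <- x1^3 + rnorm(n, 0, 0.2)
  fit <- ace(cbind(x1, x2), 2, 1)
  # supsmu re-selects its span each pass, so allow a whisker of noise
  expect_true(all(diff(fit$e2_trace) <= 1e-4))
  fit2 <- ace(cbind(1000 * x1 + 57, x2), 2, 1)
  expect_lt(abs(fit2$r_squared - fit$r_squared), 1e-3)
  fit3 <- ace(cbind(x1, -0.01 * x2 + 3), 2, 1)
  expect_lt(abs(fit3$r_squared - fit$r_squared), 1e-3)
})

test_that("MOTA finds exactly the planted three-variable group", {
  set.seed(2)
  K <- matrix(rnorm(1000 * 6), 1000, 6)
  K[, 3] <- K[, 1] + K[, 2] + rnorm(1000, 0, 0.1)
  groups <- mota_groups(K, r2_threshold = 0.8)
  expect_gt(length(groups), 0)
  resp3 <- Filter(function(g) g$response == "x3", groups)
  expect_length(resp3, 1)
  expect_setequal(resp3[[1]]$members, c("x1", "x2", "x3"))
  expect_gte(resp3[[1]]$r_squared, 0.8)
  # no group should involve the independent columns x4..x6
  others <- unlist(lapply(groups, `[[`, "members"))
  expect_false(any(c("x4", "x5", "x6") %in% others))
  # cv annotation present for every member
  expect_length(resp3[[1]]$cv, 3)
})

test_that("a bijective nonlinear pair is detected from both sides", {
  set.seed(4)
  K <- matrix(rnorm(600 * 4), 600, 4)
  K[, 1] <- runif(600, -pi / 2, pi / 2)
  K[, 2] <- sin(K[, 1])
  groups <- mota_groups(K)
  pair <- Filter(function(g) setequal(g$members, c("x1", "x2")), groups)
  expect_gte(length(pair), 2)          # found from both responses
  expect_true(all(vapply(pair, `[[`, logical(1), "strong")))
})

test_that("independent columns yield no groups at threshold 0.8", {
  set.seed(5)
  expect_length(mota_groups(matrix(rnorm(500 * 5), 500, 5),
                            r2_threshold = 0.8), 0)
  expect_error(mota_groups(matrix(rnorm(20), 10, 2)), "at least 30")
})

test_that("MOTA grouping is invariant to column order up to relabeling", {
  set.seed(6)
  K <- matrix(rnorm(400 * 5), 400, 5)
  K[, 2] <- 3 * K[, 5] + rnorm(400, 0.05)
  colnames(K) <- paste0("v", 1:5)
  perm <- c(4, 2, 5, 1, 3)
  g1 <- mota_groups(K)
  g2 <- mota_groups(K[, perm])
  sets1 <- sort(vapply(g1, function(g)
    paste(sort(g$members), collapse = "+"), character(1)))
  sets2 <- sort(vapply(g2, function(g)
    paste(sort(g$members), collapse = "+"), character(1)))
  expect_equal(sets1, sets2)
})

test_that("the planted coupling appears only in the disease stage", {
  m <- scan_demo_model()
  grid <- seq(0, 10, length.out = 120)
  rep <- characterize_disease(m, "R_scan", grid, "DM_atp",
                              r2_threshold = 0.8)
  # stage assignment follows the ATP ratio (normal optimum = 10)
  expect_equal(sum(rep$stage_of_column == "disease"),
               sum(grid / 10 <= 0.33))
  members <- function(stage)
    unlist(lapply(rep$stages[[stage]], `[[`, "members"))
  expect_true("B1" %in% members("disease"))
  backup_resp <- Filter(function(g) g$response %in% c("B1", "B2"),
                        rep$stages$disease)
  expect_gt(length(backup_resp), 0)
  expect_true(all(vapply(backup_resp, `[[`, numeric(1),
                         "r_squared") >= 0.8))
  # the backup chain is silent (constant) in the healthy stage
  expect_false(any(c("B1", "B2") %in% members("healthy")))
})

test_that("explicit stage breaks follow the half-open convention", {
  m <- scan_demo_model()
  # descending convention: inflammation interval [5.69, 3.69) includes
  # its larger endpoint
  st <- biocad:::assign_stages(c(10, 5.69, 5.70, 3.69, 3.68, 0),
                               NULL, NULL, stage_breaks = c(5.69, 3.69))
  expect_equal(as.character(st),
               c("healthy", "inflammation", "healthy", "disease",
                 "disease", "disease"))
  # ascending convention (impairment grows with flux)
  st2 <- biocad:::assign_stages(c(0, 8.31, 10.31, 12),
                                NULL, NULL, stage_breaks = c(8.31, 10.31))
  expect_equal(as.character(st2),
               c("healthy", "inflammation", "disease", "disease"))
})

test_that("a one-stage grid leaves the other stages empty", {
  m <- scan_demo_model()
  grid <- seq(8, 10, length.out = 35)   # healthy only
  rep <- characterize_disease(m, "R_scan", grid, "DM_atp")
  expect_length(rep$stages$disease, 0)
  expect_length(rep$stages$inflammation, 0)
  # a stage with too few points is reported empty with a warning
  w <- capture_warnings(
    characterize_disease(m, "R_scan", seq(0, 10, length.out = 40),
                         "DM_atp"))
  expect_true(any(grepl("reported empty", w)))
})

test_that("group reports round-trip through the CSV writer", {
  m <- scan_demo_model()
  rep <- characterize_disease(m, "R_scan", seq(0, 10, length.out = 120),
                              "DM_atp")
  path <- withr::local_tempfile(fileext = ".csv")
  write_group_report(rep, path)
  df <- read.csv(path)
  expect_equal(names(df), c("stage", "response_id", "predictor_ids",
                            "r2", "strong", "cv_members"))
  expect_true(any(df$stage == "disease" & df$response_id == "B1"))
})
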