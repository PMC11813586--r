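test_that("the repetition harness books retries and is deterministic", {
  params <- quick_params()   # short horizon: persistence is common
  reps <- run_repetitions(params, n_reps = 4, max_retries = 5, base_seed = 3)
  expect_equal(nrow(reps), 4L)
  expect_true(all(reps$retries >= 1 & reps$retries <= 5))
  expect_true(all(reps$persisted | is.na(reps$speciation)))

  reps2 <- run_repetitions(params, n_reps = 4, max_retries = 5, base_seed = 3)
  expect_identical(as.data.frame(reps), as.data.frame(reps2))
})

test_that("summaries use the documented denominators", {
  df <- data.frame(rep = 1:5,
                   seed = 1:5,
                   retries = 1,
                   persisted = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                   speciation = c(TRUE, TRUE, FALSE, FALSE, NA),
                   onset_year = c(8000, 9000, NA, NA, NA),
                   duration_years = c(2000, 3000, NA, NA, NA))
  s <- summarize_repetitions(df)
  expect_equal(s$n_persisted, 4L)
  expect_equal(s$speciation_percentage, 50)   # over persisted only
  expect_equal(s$median_onset_year, 8500)     # over speciating only
  expect_equal(s$median_duration_years, 2500)
  expect_true(s$speciation_percentage >= 0 && s$speciation_percentage <= 100)
})

test_that("PRCC recovers exact and noisy monotone structure", {
  set.seed(1)
  n <- 500
  X <- cbind(x1 = runif(n), x2 = runif(n))
  pr <- compute_prcc(X, X[, "x1"])
  expect_equal(pr$prcc[pr$parameter == "x1"], 1, tolerance = 1e-6)
  expect_false(pr$significant[pr$parameter == "x2"])

  # 1 driving + 8 irrelevant parameters + dummy
  X2 <- matrix(runif(n * 10), n, 10,
               dimnames = list(NULL, c(paste0("v", 1:9), "dummy")))
  y <- 5 * rank(X2[, 1]) / n + rnorm(n, 0, 0.2)
  pr2 <- compute_prcc(X2, y)
  expect_gt(pr2$prcc[1], 0.9)
  expect_false(pr2$significant[pr2$parameter == "dummy"])

  # invariance under strictly monotone transforms of a column
  X3 <- X2; X3[, 1] <- exp(3 * X3[, 1]); X3[, 4] <- -1 / (1 + X3[, 4])
  pr3 <- compute_prcc(X3, y)
  expect_equal(pr2$prcc, pr3$prcc, tolerance = 1e-12)

  expect_error(compute_prcc(cbind(a = rep(1, n), b = runif(n)), y[1:n]),
               "constant|degenera")
})

test_that("eFAST reproduces the Ishigami total-order indices", {
  set.seed(2)
  ranges <- list(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi),
                 dummy = c(0, 1))
  des <- efast_design(ranges, NS = 257, M = 4, NR = 4)
  y <- with(as.data.frame(des$X),
            sin(x1) + 7 * sin(x2)^2 + 0.1 * x3^4 * sin(x1))
  out <- compute_efast(des, y)

  # analytic variance decomposition with a = 7, b = 0.1
  a <- 7; b <- 0.1
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  ST <- c((V1 + V13) / V, V2 / V, V13 / V)
  expect_equal(out$S_total[1:3], ST, tolerance = 0.05)
  expect_lt(out$S_total[4], 0.1)     # dummy stays at the noise floor
})

test_that("degenerate outcomes collapse the eFAST indices", {
  set.seed(3)
  ranges <- list(x1 = c(0, 1), x2 = c(0, 1), dummy = c(0, 1))
  des <- efast_design(ranges, NS = 65, M = 4, NR = 4)

  yx1 <- des$X[, "x1"]                 # outcome = x1 alone
  out1 <- compute_efast(des, yx1)
  expect_gt(out1$S_total[1], 0.9)
  expect_lt(out1$S_total[3], out1$S_total[1] / 4)

  ynoise <- rnorm(nrow(des$X))         # outcome ignores all parameters
  out0 <- compute_efast(des, ynoise)
  spread <- max(out0$S_total) - min(out0$S_total)
  expect_lt(spread, 0.35)              # indistinguishable from the dummy
})

test_that("log-flagged parameters are sampled on the log scale", {
  set.seed(4)
  ranges <- list(m = list(min = 1e-3, max = 1e-1, log = TRUE),
                 q = c(0.4, 0.6))
  des <- efast_design(ranges, NS = 65, M = 4, NR = 1)
  m <- des$X[, "m"]
  expect_true(all(m >= 1e-3 & m <= 1e-1))
  expect_gt(mean(m < 1e-2), 0.35)      # half the mass below the geometric mid
  expect_lt(mean(m < 1e-2), 0.65)
})

test_that("a tiny campaign executes end to end and keeps bookkeeping", {
  params <- protodom_params(horizon = 120, streak_years = 40,
                            census_interval = 10)
  ranges <- list(sigma_F = list(min = 0.5, max = 4, log = TRUE),
                 h_max = c(0.1, 0.5), dummy = c(0, 1))
  camp <- sensitivity_campaign(params, method = "prcc",
                               outcome = "speciation",
                               n_sets = 8, reps_per_set = 1,
                               max_retries = 2, base_seed = 5,
                               ranges = ranges)
  expect_equal(nrow(camp$X), 8L)
  expect_equal(length(camp$y), 8L)
  expect_true(all(camp$y >= 0 & camp$y <= 100, na.rm = TRUE))
  expect_equal(sort(camp$indices$parameter), sort(names(ranges)))
  expect_true(all(abs(camp$indices$prcc) <= 1))
})

test_that("the monotonicity pre-check reports a grid and a rank trend", {
  params <- protodom_params(horizon = 120, streak_years = 40)
  mc <- monotonicity_check(params, "h_max", c(0.05, 0.5), grid_n = 3,
                           reps_per_point = 1, outcome = "speciation",
                           base_seed = 6)
  expect_equal(nrow(mc), 3L)
  expect_true(all(!is.na(mc$outcome)))
  expect_true(is.numeric(attr(mc, "spearman")) || is.na(attr(mc, "spearman")))
})
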