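test_that("no significance means no event", {
  cens <- make_census_pattern(list(c(FALSE, 5)))
  expect_null(detect_speciation(cens))
  cens2 <- data.frame(year = seq(10, 15000, by = 10), p_value = 1)
  expect_null(detect_speciation(cens2))
})

test_that("run-length arithmetic matches the streak rule", {
  # 150 consecutive significant censuses ending at year 15000
  years <- seq(10, 15000, by = 10)
  p <- rep(0.9, length(years))
  p[years >= 13510] <- 0.001
  ev <- detect_speciation(data.frame(year = years, p_value = p))
  expect_equal(ev$onset_year, 13510)
  expect_equal(ev$end_year, 15000)
  expect_equal(ev$duration_years, 1500)
  expect_equal(ev$n_censuses, 150)

  # one census short of the streak -> no event
  p149 <- rep(0.9, length(years))
  p149[years >= 13520] <- 0.001
  expect_null(detect_speciation(data.frame(year = years, p_value = p149)))
})

test_that("only the latest qualifying event is reported", {
  years <- seq(10, 15000, by = 10)
  p <- rep(0.9, length(years))
  p[years >= 2000 & years <= 4000] <- 0.001
  p[years >= 9000 & years <= 12000] <- 0.001
  ev <- detect_speciation(data.frame(year = years, p_value = p))
  expect_equal(ev$onset_year, 9000)
  expect_equal(ev$end_year, 12000)
  expect_equal(ev$duration_years, 3010)
})

test_that("the detector ignores p-values outside the reported run", {
  base <- make_census_pattern(list(c(FALSE, 10), c(TRUE, 150), c(FALSE, 5)))
  ev1 <- detect_speciation(base)
  jitter <- base
  jitter$p_value[1:10] <- runif(10, 0.05, 1)   # outside the run
  ev2 <- detect_speciation(jitter)
  expect_equal(ev1, ev2)
  expect_equal(ev1$duration_years %% 10, 0)
  expect_gte(ev1$duration_years, 1500)
})

test_that("missing p-values break a streak", {
  years <- seq(10, 3000, by = 10)
  p <- rep(0.001, length(years))
  p[150] <- NA
  ev <- detect_speciation(data.frame(year = years, p_value = p),
                          streak_years = 1500)
  expect_equal(ev$onset_year, years[151])
  p[170] <- NA   # longest clean run now < 150 censuses
  expect_null(detect_speciation(data.frame(year = years, p_value = p),
                                streak_years = 1500))
})

test_that("non-contiguous census years do not merge runs", {
  cens <- data.frame(year = c(seq(10, 700, 10), seq(1010, 1800, 10)),
                     p_value = 0.001)
  expect_null(detect_speciation(cens, streak_years = 1000))
  ev <- detect_speciation(cens, streak_years = 700)
  expect_equal(ev$onset_year, 1010)
})

test_that("events found in simulated output satisfy their invariants", {
  params <- protodom_params(horizon = 2000, streak_years = 200)
  sim <- run_simulation(params, seed = 7, keep_agents = FALSE)
  ev <- detect_speciation(sim)
  if (!is.null(ev)) {
    expect_equal(ev$duration_years %% params$census_interval, 0)
    expect_gte(ev$duration_years, params$streak_years)
    expect_equal(ev$duration_years,
                 ev$end_year - ev$onset_year + params$census_interval)
  }
  expect_error(detect_speciation(data.frame(year = c(10, 10),
                                            p_value = c(0.5, 0.5))))
})
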