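test_that("breeding probability follows the logistic-derived form", {
  p <- protodom_params()   # r = 4.08, q = 0.5, mu_L = 6.8, c = 500
  expect_equal(reproduction_probability(250, 500, p), 0)     # at capacity
  expect_equal(reproduction_probability(125, 250, p), 0.6)   # half capacity
  expect_equal(reproduction_probability(1, 2, p), 1)         # clipped high
  expect_equal(reproduction_probability(400, 800, p), 0)     # clipped low
  expect_error(reproduction_probability(10, 0, p))
  expect_error(reproduction_probability(11, 10, p))
  p0 <- protodom_params(); p0$q <- 0
  expect_error(reproduction_probability(10, 20, p0))
})

test_that("pickiness restricts the eligible male set strictly", {
  set.seed(1)
  p <- protodom_params(mate_preference = "on", p = 0.2)
  tau <- c(0.5, 0.1, 0.45, 0.65, 0.9)  # female then male pool
  for (i in 1:200) {
    pairs <- select_mates(1L, 2:5, tau, L_t = 1, p)
    if (nrow(pairs)) expect_true(tau[pairs[, "sire"]] %in% c(0.45, 0.65))
  }
})

test_that("mate-choice frequencies match the similarity weights", {
  set.seed(2)
  p <- protodom_params(mate_preference = "on", p = 0.2)
  tau <- c(0.5, 0.45, 0.60)
  B <- 4e4
  picks <- replicate(B, select_mates(1L, 2:3, tau, 1, p)[1, "sire"])
  w <- c(1 - 0.05, 1 - 0.10) / (2 - 0.15)      # (0.95, 0.90) / 1.85
  f <- mean(picks == 2L)
  expect_lt(abs(f - w[1]), 3 * sqrt(w[1] * w[2] / B))
})

test_that("without preference a lone pair always mates", {
  set.seed(3)
  p <- protodom_params(mate_preference = "off")
  for (i in 1:20) {
    pairs <- select_mates(1L, 2L, c(0.1, 0.9), L_t = 1, p)
    expect_equal(nrow(pairs), 1L)
    expect_equal(pairs[1, ], c(dam = 1L, sire = 2L))
  }
})

test_that("mating is annually monogamous and halts when males run out", {
  set.seed(4)
  for (pref in c("on", "off")) {
    p <- protodom_params(mate_preference = pref, p = 1)
    tau <- runif(30)
    pairs <- select_mates(1:20, 21:30, tau, L_t = 1, p)
    expect_lte(nrow(pairs), 10)
    expect_false(anyDuplicated(pairs[, "sire"]) > 0)
    expect_false(anyDuplicated(pairs[, "dam"]) > 0)
  }
})

test_that("zero pickiness with distinct tolerances blocks all mating", {
  set.seed(5)
  p <- protodom_params(mate_preference = "on", p = 0)
  tau <- seq(0.05, 0.95, length.out = 20)
  pairs <- select_mates(1:10, 11:20, tau, L_t = 1, p)
  expect_equal(nrow(pairs), 0L)
})

test_that("litters inherit within the parental interval and stay in [0,1]", {
  set.seed(6)
  p <- protodom_params(sigma_e = 0, m = 0)
  lt <- make_litter(0.4, 0.4, p)
  if (length(lt$tau)) expect_true(all(lt$tau == 0.4))

  for (i in 1:200) {
    d <- runif(1); s <- runif(1)
    lt <- make_litter(d, s, p)
    if (length(lt$tau))
      expect_true(all(lt$tau >= min(d, s) & lt$tau <= max(d, s)))
  }

  # with noise, tolerances are still truncated to [0, 1]
  pn <- protodom_params(sigma_e = 0.5)
  taus <- protodom:::make_litters_batch(runif(2000), runif(2000), pn)$tau
  expect_true(all(taus >= 0 & taus <= 1))
})

test_that("mutant pups are uniform on [0, 1]", {
  set.seed(7)
  p <- protodom_params(m = 1)
  taus <- protodom:::make_litters_batch(rep(0.5, 2e4), rep(0.5, 2e4), p)$tau
  expect_gt(length(taus), 5e4)
  ks <- suppressWarnings(stats::ks.test(taus, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("surviving pups per litter match the rounded-normal mean", {
  set.seed(8)
  p <- protodom_params()
  # E[q * max(0, [S])], S ~ N(6.8, 2.2^2), by numeric integration over the
  # rounding cells
  k <- 1:60
  pk <- pnorm(k + 0.5, p$mu_L, p$sigma_L) - pnorm(k - 0.5, p$mu_L, p$sigma_L)
  expected <- p$q * sum(k * pk)
  B <- 2e4
  sizes <- numeric(B)
  for (b in 1:B) sizes[b] <- length(make_litter(0.3, 0.7, p)$tau)
  se <- sd(sizes) / sqrt(B)
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})

test_that("the composed submodel matches a straight-line re-implementation", {
  # 2 mature females, 2 mature males, far below capacity, no preference
  p <- protodom_params(mate_preference = "off")
  mk_pop <- function() protodom:::new_population(
    id = 1:4, age = c(3L, 3L, 4L, 5L),
    female = c(TRUE, TRUE, FALSE, FALSE),
    tau = c(0.2, 0.4, 0.6, 0.8), next_id = 5L)
  B <- 2e4
  set.seed(9)
  pups_pkg <- replicate(B, n_canines(reproduce(mk_pop(), p)) - 4L)

  # independent oracle: every female breeds with prob L, each mated pair
  # has a litter round(N(mu,sd)) filtered by q
  set.seed(10)
  L <- p$r * (1 - 4 / 500) / (p$q * p$mu_L)
  pups_ora <- replicate(B, {
    nf <- rbinom(1, 2, min(1, L))
    np <- min(nf, 2)
    tot <- 0
    if (np > 0) {
      sizes <- pmax(0, round_nearest(rnorm(np, p$mu_L, p$sigma_L)))
      tot <- sum(rbinom(np, sizes, p$q))
    }
    tot
  })
  se <- sqrt(var(pups_pkg) / B + var(pups_ora) / B)
  expect_lt(abs(mean(pups_pkg) - mean(pups_ora)), 3 * se)
  expect_lt(abs(var(pups_pkg) - var(pups_ora)),
            4 * sd(c(var(pups_pkg), var(pups_ora))) + 2)
})

test_that("no mature males or a full environment mean no pups", {
  set.seed(11)
  p <- protodom_params()
  pop_females <- protodom:::new_population(
    id = 1:6, age = rep(4L, 6), female = rep(TRUE, 6), tau = runif(6),
    next_id = 7L)
  expect_equal(n_canines(reproduce(pop_females, p)), 6L)

  n <- p$c
  pop_full <- protodom:::new_population(
    id = 1:n, age = rep(4L, n), female = rep(c(TRUE, FALSE), n / 2),
    tau = runif(n), next_id = n + 1L)
  expect_equal(n_canines(reproduce(pop_full, p)), n)
})
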