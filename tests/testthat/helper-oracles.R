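# Independent oracles used across the test suite.  Everything here is a
# straight-line re-derivation from first principles, kept deliberately
# separate from the package's implementation paths.

# closed-form mean of N(mu, sd^2) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# closed-form sd of the truncated normal
truncnorm_sd <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  v <- 1 + (a * dnorm(a) - b * dnorm(b)) / Z - ((dnorm(a) - dnorm(b)) / Z)^2
  sd * sqrt(v)
}

# Exhaustive enumeration of the literal two-round hunt on a tiny
# population: repeatedly draw a candidate with probability proportional to
# its weight, let it attempt once (success prob = weight, consuming a unit
# on success only), candidates leave the round either way.  Returns the
# probability that each canine ends up fed.
hunt_enumerate <- function(tau, human_units, wild_units) {
  n <- length(tau)
  fed_prob <- numeric(n)
  enum_round <- function(X, w, units, prob, fed, cont) {
    tot <- sum(w[X])
    if (length(X) == 0L || units == 0L || tot <= 0) {
      cont(X, prob, fed)
      return(invisible())
    }
    for (j in X) {
      psel <- w[j] / tot
      rest <- setdiff(X, j)
      # success
      f2 <- fed; f2[j] <- TRUE
      enum_round(rest, w, units - 1L, prob * psel * w[j], f2, cont)
      # failure (unit not consumed)
      if (w[j] < 1)
        enum_round(rest, w, units, prob * psel * (1 - w[j]), fed, cont)
    }
  }
  enum_round(seq_len(n), tau, as.integer(human_units), 1, logical(n),
             function(X1, p1, fed1) {
               unfed <- which(!fed1)
               enum_round(unfed, 1 - tau, as.integer(wild_units), p1, fed1,
                          function(X2, p2, fed2) {
                            fed_prob <<- fed_prob + p2 * fed2
                          })
             })
  fed_prob
}

# Definition-based dip statistic: for each mode position, the minimal
# sup-distance from the ecdf to a convex-below / concave-above cdf (atom
# allowed at the mode) is a small LP, solved with boot::simplex and
# verified for feasibility before being trusted.
dip_bruteforce <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  x <- sort(x)
  u <- unique(x)
  k <- length(u)
  if (k == 1) return(0)
  cnt <- tabulate(match(x, u), k)
  b <- cumsum(cnt) / n
  a <- c(0, b[-k])

  solve_mode <- function(at_point, j0) {
    nv <- k + at_point + 1L
    ie <- nv
    iL <- if (at_point) k + 1L else NA
    A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
    add1 <- function(row, rhs) { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
    add2 <- function(row, rhs) { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
    row <- function() numeric(nv)
    for (j in seq_len(k)) {
      if (at_point && j == j0) next
      r <- row(); r[j] <- 1; r[ie] <- -1; add1(r, a[j])
      r <- row(); r[j] <- 1; r[ie] <- 1;  add2(r, b[j])
      r <- row(); r[j] <- 1; add1(r, 1)
    }
    if (at_point) {
      r <- row(); r[iL] <- 1; r[ie] <- -1; add1(r, a[j0])
      r <- row(); r[j0] <- 1; r[ie] <- 1;  add2(r, b[j0])
      r <- row(); r[iL] <- 1; add1(r, 1)
      r <- row(); r[j0] <- 1; add1(r, 1)
    }
    pos <- seq_len(k)
    if (at_point) {
      left <- if (j0 > 1) pos[seq_len(j0 - 1L)] else integer()
      chainL <- c(left, iL); chainR <- pos[j0:k]
      xs_L <- u[seq_len(j0)]; xs_R <- u[j0:k]
      ordered <- c(left, iL, pos[j0:k])
    } else {
      chainL <- if (j0 >= 1) pos[seq_len(j0)] else integer()
      chainR <- if (j0 < k) pos[(j0 + 1L):k] else integer()
      xs_L <- u[seq_len(j0)]
      xs_R <- if (j0 < k) u[(j0 + 1L):k] else numeric()
      ordered <- c(chainL, chainR)
    }
    for (i in seq_len(length(ordered) - 1L)) {
      r <- row(); r[ordered[i]] <- 1; r[ordered[i + 1L]] <- -1; add1(r, 0)
    }
    shape <- function(vars, xs, convex) {
      m <- length(vars)
      if (m < 3) return(invisible())
      for (i in 2:(m - 1L)) {
        d1 <- xs[i] - xs[i - 1L]; d2 <- xs[i + 1L] - xs[i]
        r <- row()
        r[vars[i - 1L]] <- r[vars[i - 1L]] - d2
        r[vars[i]] <- r[vars[i]] + d2 + d1
        r[vars[i + 1L]] <- r[vars[i + 1L]] - d1
        if (convex) add1(r, 0) else add2(r, 0)
      }
    }
    shape(chainL, xs_L, TRUE)
    shape(chainR, xs_R, FALSE)
    obj <- row(); obj[ie] <- 1
    for (eps in c(1e-12, 1e-10, 1e-8)) {
      s <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                         maxi = FALSE, n.iter = 500 + 50 * nv, eps = eps)
      if (s$solved != 1) next
      viol <- max(c(A1 %*% s$soln - b1, b2 - A2 %*% s$soln, 0))
      if (viol < 1e-8) return(s$value)
    }
    NA_real_
  }

  vals <- c(vapply(0:k, function(j0) solve_mode(FALSE, j0), 0),
            vapply(seq_len(k), function(j0) solve_mode(TRUE, j0), 0))
  min(vals, na.rm = TRUE)
}

# short-horizon parameter set for fast engine-level tests
quick_params <- function(horizon = 200L, streak_years = 50L, ...) {
  protodom_params(horizon = horizon, streak_years = streak_years, ...)
}
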