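#' Replicated simulation campaign with persistence retries
#'
#' Runs `n_reps` repetitions at a fixed parameter set.  Each repetition is
#' re-run with a fresh derived seed (deterministic schedule
#' `mix(base_seed, rep, retry)`) until the population persists to the
#' horizon or `max_retries` is exhausted; repetitions that never persist
#' are recorded but excluded from speciation statistics.  For each
#' persisted repetition the latest qualifying speciation event is detected.
#'
#' @param params a [protodom_params()] object.
#' @param n_reps number of repetitions.
#' @param max_retries maximum realisations per repetition.
#' @param base_seed integer seed of the campaign.
#' @return a `protodom_reps` data frame with one row per repetition:
#'   `rep`, `seed`, `retries`, `persisted`, `speciation`, `onset_year`,
#'   `duration_years`.
#' @seealso [summarize_repetitions()]
#' @export
#' @examples
#' params <- protodom_params(horizon = 300, streak_years = 100)
#' run_repetitions(params, n_reps = 2, base_seed = 1)
run_repetitions <- function(params, n_reps, max_retries = 50L,
                            base_seed = 1L) {
  stopifnot(n_reps >= 1, max_retries >= 1)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    res <- NULL; used <- NA_integer_; seed <- NA_integer_
    for (j in seq_len(max_retries)) {
      seed <- mix_seed(base_seed, i, j)
      sim <- run_simulation(params, seed, keep_agents = FALSE)
      if (sim$persisted) { res <- sim; used <- j; break }
    }
    if (is.null(res)) {
      rows[[i]] <- data.frame(rep = i, seed = seed, retries = max_retries,
                              persisted = FALSE, speciation = NA,
                              onset_year = NA_real_,
                              duration_years = NA_real_)
    } else {
      ev <- detect_speciation(res)
      rows[[i]] <- data.frame(rep = i, seed = seed, retries = used,
                              persisted = TRUE,
                              speciation = !is.null(ev),
                              onset_year = if (is.null(ev)) NA_real_ else
                                ev$onset_year,
                              duration_years = if (is.null(ev)) NA_real_ else
                                ev$duration_years)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("protodom_reps", class(out))
  out
}

#' Aggregate a repetition campaign
#'
#' The speciation percentage is taken over persisted repetitions only; the
#' median onset year and median streak duration are taken over speciating
#' repetitions only.
#'
#' @param reps output of [run_repetitions()] (several campaigns may be
#'   row-bound, e.g. to pool human-food styles).
#' @return list with `n_reps`, `n_persisted`, `n_speciating`,
#'   `speciation_percentage`, `median_onset_year`, `median_duration_years`.
#' @export
summarize_repetitions <- function(reps) {
  pers <- reps[reps$persisted %in% TRUE, , drop = FALSE]
  spec <- pers[pers$speciation %in% TRUE, , drop = FALSE]
  list(n_reps = nrow(reps),
       n_persisted = nrow(pers),
       n_speciating = nrow(spec),
       speciation_percentage =
         if (nrow(pers)) 100 * nrow(spec) / nrow(pers) else NA_real_,
       median_onset_year =
         if (nrow(spec)) median(spec$onset_year) else NA_real_,
       median_duration_years =
         if (nrow(spec)) median(spec$duration_years) else NA_real_)
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every parameter column and the outcome, then computes,
#' for each parameter, the correlation of the residuals of the two linear
#' regressions on the remaining parameters' ranks.  Significance uses the
#' t approximation with `n - k - 1` degrees of freedom (`k` parameters).
#'
#' @param X numeric matrix or data frame of parameter samples (columns =
#'   parameters, named).
#' @param y outcome vector, `length(y) == nrow(X)`.
#' @param alpha significance level for the `significant` flag.
#' @return data frame with columns `parameter`, `prcc`, `t`, `p_value`,
#'   `significant`.
#' @export
#' @examples
#' set.seed(1)
#' X <- cbind(a = runif(100), b = runif(100))
#' compute_prcc(X, X[, "a"]^3)
compute_prcc <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("X needs at least 2 columns")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X); k <- ncol(X)
  if (n < k + 3) stop("too few complete rows for a PRCC")
  if (any(apply(X, 2, function(col) length(unique(col)) == 1L)))
    stop("constant parameter column: rank degeneracy")
  rX <- apply(X, 2, rank)
  ry <- rank(y)
  prcc <- numeric(k)
  for (i in seq_len(k)) {
    Z <- cbind(1, rX[, -i, drop = FALSE])
    e1 <- stats::lm.fit(Z, ry)$residuals
    e2 <- stats::lm.fit(Z, rX[, i])$residuals
    if (sd(e2) == 0) stop("rank degeneracy for parameter ",
                          colnames(X)[i])
    prcc[i] <- cor(e1, e2)
  }
  df <- n - k - 1
  tval <- prcc * sqrt(pmax(df, 1) / pmax(1 - prcc^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tval), df = pmax(df, 1))
  data.frame(parameter = colnames(X), prcc = prcc, t = tval,
             p_value = pval, significant = pval < alpha,
             row.names = NULL)
}

#' eFAST sampling design
#'
#' Builds the search curves of the extended Fourier amplitude sensitivity
#' test.  Each parameter in turn is assigned the high frequency
#' `floor((NS - 1) / (2 * M))` while the complementary set cycles through
#' low frequencies at most `max(1, floor(omega / (2 * M)))`; `NR` resample
#' curves use independent random phase shifts.  Parameters flagged
#' `log = TRUE` are sampled log-uniformly over their range.
#'
#' @param ranges named list; each element `c(lo, hi)` or
#'   `list(min =, max =, log = TRUE)`.
#' @param NS samples per search curve (odd is recommended).
#' @param M interference factor of the Fourier decomposition.
#' @param NR number of resample curves per parameter.
#' @return an `efast_design`: list with the sample matrix `X`
#'   (`NS * k * NR` rows), bookkeeping vectors `factor` and `curve`, and
#'   the frequency assignment.
#' @export
efast_design <- function(ranges, NS = 65L, M = 4L, NR = 1L) {
  k <- length(ranges)
  if (k < 2) stop("need at least 2 parameters (including the dummy)")
  nm <- names(ranges)
  if (is.null(nm) || any(nm == "")) stop("ranges must be named")
  omega <- (NS - 1) %/% (2L * M)
  if (omega < 1) stop("NS too small for the frequency set: need NS >= ",
                      2 * M + 1)
  om_c_max <- max(1L, omega %/% (2L * M))
  s <- 2 * pi * (seq_len(NS) - 1) / NS
  rows <- NS * k * NR
  X <- matrix(NA_real_, rows, k, dimnames = list(NULL, nm))
  fac <- integer(rows); curve <- integer(rows)
  row0 <- 0L
  for (r in seq_len(NR)) {
    for (i in seq_len(k)) {
      freqs <- rep(seq_len(om_c_max), length.out = k)
      freqs[i] <- omega
      phase <- runif(k, 0, 2 * pi)
      idx <- row0 + seq_len(NS)
      for (j in seq_len(k)) {
        g <- 0.5 + asin(sin(freqs[j] * s + phase[j])) / pi
        rg <- ranges[[j]]
        if (is.list(rg)) {
          lo <- rg$min; hi <- rg$max
          lg <- isTRUE(rg$log)
        } else { lo <- rg[1]; hi <- rg[2]; lg <- FALSE }
        X[idx, j] <- if (lg) 10^(log10(lo) + g * (log10(hi) - log10(lo)))
                     else lo + g * (hi - lo)
      }
      fac[idx] <- i; curve[idx] <- r
      row0 <- row0 + NS
    }
  }
  structure(list(X = X, factor = fac, curve = curve, NS = NS, M = M,
                 NR = NR, omega = omega, parameters = nm),
            class = "efast_design")
}

#' eFAST total-order sensitivity indices
#'
#' For each parameter's search curves, the variance at the fundamental
#' frequency and its first `M` harmonics estimates the parameter's
#' first-order contribution, while everything at or below `omega / 2`
#' belongs to the complementary set; the total-order index is
#' `1 - V_complementary / V`.  The index of the dummy parameter estimates
#' the noise floor of the decomposition.
#'
#' @param design an [efast_design()].
#' @param y model outcome for every row of `design$X`.
#' @return data frame with columns `parameter`, `S_total` (mean across
#'   resample curves), `S_first`, and `S_total_sd` across curves.
#' @export
compute_efast <- function(design, y) {
  if (length(y) != nrow(design$X)) stop("length(y) must match the design")
  NS <- design$NS; M <- design$M; omega <- design$omega
  hmax <- (NS - 1) %/% 2
  st <- matrix(NA_real_, design$NR, length(design$parameters))
  s1 <- st
  for (r in seq_len(design$NR)) {
    for (i in seq_along(design$parameters)) {
      yi <- y[design$factor == i & design$curve == r]
      ft <- stats::fft(yi)
      lam <- (Mod(ft[2:(hmax + 1)]) / NS)^2  # spectrum at freqs 1..hmax
      V <- sum(lam)
      if (V <= 0) { st[r, i] <- 0; s1[r, i] <- 0; next }
      Vi <- sum(lam[seq_len(M) * omega])
      Vc <- sum(lam[seq_len(max(1L, omega %/% 2L))])
      st[r, i] <- 1 - Vc / V
      s1[r, i] <- Vi / V
    }
  }
  data.frame(parameter = design$parameters,
             S_total = colMeans(st), S_first = colMeans(s1),
             S_total_sd = apply(st, 2, sd),
             row.names = NULL)
}

#' Default sensitivity ranges of the varied parameters
#'
#' The ranges used by the sensitivity campaigns: 20% bands around the
#' default for the demographically estimated parameters (`mu_L`,
#' `sigma_L`, `r`, `d`), explicit ranges for `q` (0.4-0.6), `h_max`
#' (0.01-0.5), `c` (400-600) and `p` (0-0.4), log-uniform ranges for `m`
#' (1e-3 to 1e-1) and `sigma_F` (1e-2 to 10^0.5), a log-uniform range
#' 1e-3 to 1e-1 for `sigma_e`, and a `dummy` parameter on \[0, 1\] that the
#' model never reads (the noise floor of the analysis).
#'
#' @param params a [protodom_params()] object supplying the defaults.
#' @return named list of ranges suitable for [efast_design()] and
#'   [sensitivity_campaign()].
#' @export
default_param_ranges <- function(params = protodom_params()) {
  band <- function(x) c(0.8 * x, 1.2 * x)
  list(
    mu_L = band(params$mu_L),
    sigma_L = band(params$sigma_L),
    r = band(params$r),
    q = c(0.4, 0.6),
    m = list(min = 1e-3, max = 1e-1, log = TRUE),
    sigma_F = list(min = 1e-2, max = 10^0.5, log = TRUE),
    h_max = c(0.01, 0.5),
    c = c(400, 600),
    p = c(0, 0.4),
    d = band(params$d),
    sigma_e = list(min = 1e-3, max = 1e-1, log = TRUE),
    dummy = c(0, 1)
  )
}

# stratified latin hypercube on [0,1]^k (one permuted stratum per column)
lhs_sample <- function(n, k) {
  vapply(seq_len(k), function(j) (sample.int(n) - runif(n)) / n,
         numeric(n))
}

# outcome of a batch of repetitions at one parameter point
.campaign_outcome <- function(summary, outcome, horizon) {
  switch(outcome,
         speciation = summary$speciation_percentage,
         onset = summary$median_onset_year,
         streak = summary$median_duration_years)
}

#' Global sensitivity campaign
#'
#' Samples parameter sets (eFAST search curves or latin hypercube for
#' PRCC) over `ranges`, runs a repetition batch at each set, computes the
#' requested speciation outcome per set, and returns the sensitivity
#' indices.  Outcomes are: `"speciation"` (percentage of persisted
#' repetitions with a qualifying event), `"onset"` (median onset year among
#' speciating repetitions) and `"streak"` (median event duration).  For
#' `onset`/`streak`, parameter sets with no speciating repetition yield
#' missing outcomes and are dropped from the PRCC (with a warning when
#' fewer than half the sets remain).
#'
#' @param params baseline [protodom_params()]; sampled fields override it.
#' @param method `"prcc"` or `"efast"`.
#' @param outcome `"speciation"`, `"onset"` or `"streak"`.
#' @param n_sets number of parameter sets (PRCC method).
#' @param reps_per_set repetitions per parameter set.
#' @param max_retries persistence retries per repetition.
#' @param base_seed campaign seed.
#' @param ranges named ranges; defaults to [default_param_ranges()].
#' @param NS,M,NR eFAST design settings (eFAST method).
#' @return list with `indices` (PRCC or eFAST data frame), `X` (sampled
#'   sets), `y` (per-set outcomes) and the design metadata.
#' @export
sensitivity_campaign <- function(params, method = c("prcc", "efast"),
                                 outcome = c("speciation", "onset", "streak"),
                                 n_sets = 20L, reps_per_set = 3L,
                                 max_retries = 50L, base_seed = 1L,
                                 ranges = default_param_ranges(params),
                                 NS = 65L, M = 4L, NR = 1L) {
  method <- match.arg(method)
  outcome <- match.arg(outcome)
  set.seed(mix_seed(base_seed, 777L, 0L))
  if (method == "efast") {
    design <- efast_design(ranges, NS = NS, M = M, NR = NR)
    X <- design$X
  } else {
    design <- NULL
    U <- lhs_sample(n_sets, length(ranges))
    X <- matrix(NA_real_, n_sets, length(ranges),
                dimnames = list(NULL, names(ranges)))
    for (j in seq_along(ranges)) {
      rg <- ranges[[j]]
      if (is.list(rg))
        X[, j] <- 10^(log10(rg$min) + U[, j] * (log10(rg$max) - log10(rg$min)))
      else X[, j] <- rg[1] + U[, j] * (rg[2] - rg[1])
    }
  }
  y <- numeric(nrow(X))
  for (s in seq_len(nrow(X))) {
    pset <- params
    for (nm in setdiff(colnames(X), "dummy")) pset[[nm]] <- X[s, nm]
    pset$c <- max(1L, as.integer(round_nearest(pset$c)))
    validate_params(pset)
    reps <- run_repetitions(pset, reps_per_set, max_retries = max_retries,
                            base_seed = mix_seed(base_seed, s, 0L))
    y[s] <- .campaign_outcome(summarize_repetitions(reps), outcome,
                              params$horizon)
  }
  indices <- if (method == "efast") {
    compute_efast(design, ifelse(is.na(y), 0, y))
  } else {
    ok <- !is.na(y)
    if (sum(ok) < nrow(X) / 2)
      warning("fewer than half the parameter sets produced the outcome")
    compute_prcc(X[ok, , drop = FALSE], y[ok])
  }
  list(indices = indices, X = X, y = y, method = method, outcome = outcome,
       design = design)
}

#' Monotonicity pre-check of an outcome along one parameter
#'
#' Evaluates the campaign outcome on a coarse grid of one parameter
#' (others at their defaults) and reports the grid values together with the
#' Spearman correlation of outcome against parameter -- a quick diagnostic
#' for choosing between variance-based (non-monotone) and rank-correlation
#' (monotone) sensitivity methods.
#'
#' @param params baseline parameters.
#' @param parameter name of the parameter to vary.
#' @param range `c(lo, hi)` or a log-flagged list, as in
#'   [default_param_ranges()].
#' @param grid_n grid points.
#' @param reps_per_point repetitions per grid point.
#' @param outcome see [sensitivity_campaign()].
#' @param base_seed seed.
#' @return data frame of grid values and outcomes, with attribute
#'   `spearman`.
#' @export
monotonicity_check <- function(params, parameter, range, grid_n = 5L,
                               reps_per_point = 3L,
                               outcome = c("speciation", "onset", "streak"),
                               base_seed = 1L) {
  outcome <- match.arg(outcome)
  if (is.list(range))
    grid <- 10^seq(log10(range$min), log10(range$max), length.out = grid_n)
  else grid <- seq(range[1], range[2], length.out = grid_n)
  y <- numeric(grid_n)
  for (g in seq_len(grid_n)) {
    pset <- params
    pset[[parameter]] <- if (parameter == "c")
      as.integer(round_nearest(grid[g])) else grid[g]
    validate_params(pset)
    reps <- run_repetitions(pset, reps_per_point,
                            base_seed = mix_seed(base_seed, g, 0L))
    y[g] <- .campaign_outcome(summarize_repetitions(reps), outcome,
                              params$horizon)
  }
  out <- data.frame(value = grid, outcome = y)
  ok <- !is.na(y)
  attr(out, "spearman") <- if (sum(ok) >= 3)
    suppressWarnings(cor(grid[ok], y[ok], method = "spearman")) else NA_real_
  out
}
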