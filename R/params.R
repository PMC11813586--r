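#' Placeholder initial age distribution
#'
#' Synthetic stand-in for an empirical initial age distribution of a canine
#' population under low hunting pressure: a geometric decay over ages
#' `0..max_age`, normalised to sum to one.  It emulates the shape of a wild
#' canid age pyramid (many young, few old animals) but makes no claim about
#' any measured wolf population; supply your own curve via
#' [protodom_params()] or a config file to use empirical estimates.
#'
#' @param max_age maximum attainable age in years.
#' @param decay per-year geometric decay factor of the age class sizes.
#' @return numeric vector of length `max_age + 1` summing to 1.
#' @export
#' @examples
#' default_age_pmf()
default_age_pmf <- function(max_age = 10L, decay = 0.75) {
  stopifnot(max_age >= 0, decay > 0)
  w <- decay^(0:max_age)
  w / sum(w)
}

#' Placeholder age-specific death probability curve
#'
#' Synthetic stand-in for an empirical all-cause probability of death at age
#' `a`, L(a), over ages `0..max_age`.  The shape is the classic U-shaped
#' mammalian mortality curve: elevated first-year mortality, low prime-age
#' mortality and a senescent rise, with L(max_age) = 1 so that no animal
#' outlives the age cap.  It is a documented placeholder, not an empirical
#' wolf estimate; override it to use measured survival data.
#'
#' @inheritParams default_age_pmf
#' @return numeric vector of length `max_age + 1` with values in \[0, 1\].
#' @export
#' @examples
#' default_death_curve()
default_death_curve <- function(max_age = 10L) {
  stopifnot(max_age >= 1)
  a <- (0:max_age) / max_age
  l <- 0.18 + 0.5 * a^3 + 0.22 * exp(-8 * a)
  l[length(l)] <- 1
  pmin(pmax(l, 0), 1)
}

#' Model parameters
#'
#' Builds the full, validated parameter set of the simulation.  Defaults are
#' the model's default values: initial tolerance \eqn{N_{[0,1]}(0.1, 0.2^2)},
#' litter size \eqn{N(6.8, 2.2^2)}, growth rate 4.08/yr, pup survival 0.5,
#' mutation probability 1e-2, food random-walk s.d. \eqn{10^{0.3}}, maximum
#' human food proportion 0.3, capacity 500, mate pickiness 0.2, and
#' non-starvation death fraction 0.68.
#'
#' @param mu_tau,sigma_tau mean and s.d. of the initial human-tolerance
#'   distribution (truncated normal on \[0, 1\]).
#' @param mu_L,sigma_L mean and s.d. of litter size (pups).
#' @param r logistic growth rate (per year).
#' @param q probability a pup survives its first stage.
#' @param m mutation probability per pup.
#' @param sigma_F s.d. of the bounded food random walk (food units).
#' @param sigma_e s.d. of environmental noise added to a non-mutant pup's
#'   tolerance.
#' @param h_max maximum human food proportion.
#' @param c total food carrying capacity and initial population size.
#' @param p mate pickiness: a female only considers males with
#'   \eqn{|\tau_f - \tau_m| < p}.
#' @param d probability a death is due to non-starvation causes.
#' @param human_food_style `"constant"` (h = h_max/2 every year) or
#'   `"increasing"` (h grows linearly from 0 to h_max over the horizon).
#' @param mate_preference `"on"` or `"off"`.
#' @param horizon simulated years.
#' @param census_interval years between censuses (and dip tests).
#' @param streak_years consecutive significant years required for a
#'   speciation event; must be a multiple of `census_interval`.
#' @param alpha significance level of the dip test.
#' @param min_population extirpation threshold: the run terminates when the
#'   population drops below this count.
#' @param max_age maximum attainable age.
#' @param maturity_age minimum breeding age.
#' @param age_pmf initial age distribution over `0:max_age` (sums to 1).
#' @param death_curve probability of death at each age `0:max_age`.
#' @return an object of class `protodom_params` (a validated named list).
#' @seealso [load_config()], [save_config()], [run_simulation()]
#' @export
#' @examples
#' p <- protodom_params(mate_preference = "off")
#' p$h_max
protodom_params <- function(mu_tau = 0.1, sigma_tau = 0.2,
                            mu_L = 6.8, sigma_L = 2.2,
                            r = 4.08, q = 0.5, m = 1e-2,
                            sigma_F = 10^0.3, sigma_e = 0.01,
                            h_max = 0.3, c = 500, p = 0.2, d = 0.68,
                            human_food_style = c("constant", "increasing"),
                            mate_preference = c("on", "off"),
                            horizon = 15000L, census_interval = 10L,
                            streak_years = 1500L, alpha = 0.05,
                            min_population = 3L, max_age = 10L,
                            maturity_age = 2L,
                            age_pmf = NULL, death_curve = NULL) {
  human_food_style <- match.arg(human_food_style)
  mate_preference <- match.arg(mate_preference)
  if (is.null(age_pmf)) age_pmf <- default_age_pmf(max_age)
  if (is.null(death_curve)) death_curve <- default_death_curve(max_age)
  obj <- structure(list(
    mu_tau = mu_tau, sigma_tau = sigma_tau,
    mu_L = mu_L, sigma_L = sigma_L,
    r = r, q = q, m = m,
    sigma_F = sigma_F, sigma_e = sigma_e,
    h_max = h_max, c = as.integer(c), p = p, d = d,
    human_food_style = human_food_style,
    mate_preference = mate_preference,
    horizon = as.integer(horizon),
    census_interval = as.integer(census_interval),
    streak_years = as.integer(streak_years),
    alpha = alpha,
    min_population = as.integer(min_population),
    max_age = as.integer(max_age),
    maturity_age = as.integer(maturity_age),
    age_pmf = as.numeric(age_pmf),
    death_curve = as.numeric(death_curve)
  ), class = "protodom_params")
  validate_params(obj)
  obj
}

#' Validate a parameter set
#'
#' Checks every model invariant (probability bounds, positive scales,
#' divisibility of the streak length by the census interval, normalisation of
#' the age distribution, ...) and stops with the offending field name on the
#' first violation.
#'
#' @param params a `protodom_params` object or plain named list.
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid parameter `", field, "`: ", why,
                          call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  prob <- function(x) num1(x) && x >= 0 && x <= 1
  for (f in c("q", "m", "h_max", "p", "d", "alpha"))
    chk(prob(params[[f]]), f, "must be a probability in [0, 1]")
  for (f in c("sigma_tau", "sigma_L", "sigma_F", "sigma_e"))
    chk(num1(params[[f]]) && params[[f]] >= 0, f, "must be >= 0")
  chk(num1(params$mu_tau), "mu_tau", "must be a finite number")
  chk(num1(params$mu_L), "mu_L", "must be a finite number")
  chk(num1(params$r) && params$r >= 0, "r", "must be >= 0")
  chk(num1(params$c) && params$c >= 1, "c", "must be >= 1")
  for (f in c("horizon", "census_interval", "streak_years"))
    chk(num1(params[[f]]) && params[[f]] >= 1, f, "must be positive")
  chk(params$streak_years %% params$census_interval == 0,
      "streak_years", "must be divisible by census_interval")
  chk(num1(params$min_population) && params$min_population >= 1,
      "min_population", "must be >= 1")
  chk(num1(params$max_age) && params$max_age >= 1, "max_age", "must be >= 1")
  chk(num1(params$maturity_age) && params$maturity_age >= 0 &&
        params$maturity_age <= params$max_age,
      "maturity_age", "must be in [0, max_age]")
  na <- params$max_age + 1L
  chk(is.numeric(params$age_pmf) && length(params$age_pmf) == na,
      "age_pmf", sprintf("must have length max_age + 1 = %d", na))
  chk(all(params$age_pmf >= 0), "age_pmf", "must be non-negative")
  chk(abs(sum(params$age_pmf) - 1) <= 1e-9, "age_pmf",
      "must sum to 1 (tolerance 1e-9)")
  chk(is.numeric(params$death_curve) && length(params$death_curve) == na,
      "death_curve", sprintf("must have length max_age + 1 = %d", na))
  chk(all(params$death_curve >= 0 & params$death_curve <= 1),
      "death_curve", "values must be in [0, 1]")
  invisible(params)
}

# fields serialised as scalars in a config file
.scalar_fields <- c("mu_tau", "sigma_tau", "mu_L", "sigma_L", "r", "q", "m",
                    "sigma_F", "sigma_e", "h_max", "c", "p", "d",
                    "human_food_style", "mate_preference", "horizon",
                    "census_interval", "streak_years", "alpha",
                    "min_population", "max_age", "maturity_age")

#' Read a parameter configuration from a YAML file
#'
#' Any field missing from the file keeps its default; unknown keys are an
#' error.  `age_pmf` and `death_curve` may be given inline as numeric
#' sequences or via `age_pmf_file` / `death_curve_file`, two-column CSV
#' files (`age,value`) resolved relative to the config file.
#'
#' @param path path to a YAML config file.
#' @return a validated [protodom_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  read_curve <- function(file) {
    f <- if (file.exists(file)) file else file.path(dirname(path), file)
    tab <- read.csv(f)
    if (ncol(tab) < 2) stop("curve file needs two columns (age, value): ", f)
    tab[[2]][order(tab[[1]])]
  }
  for (key in c("age_pmf", "death_curve")) {
    fkey <- paste0(key, "_file")
    if (!is.null(cfg[[fkey]])) {
      cfg[[key]] <- read_curve(cfg[[fkey]])
      cfg[[fkey]] <- NULL
    }
  }
  known <- c(.scalar_fields, "age_pmf", "death_curve")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(protodom_params, cfg)
}

#' Write a parameter configuration to a YAML file
#'
#' The written file round-trips through [load_config()] field by field.
#'
#' @param params a [protodom_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  validate_params(params)
  out <- params[.scalar_fields]
  out$age_pmf <- as.numeric(params$age_pmf)
  out$death_curve <- as.numeric(params$death_curve)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.protodom_params <- function(x, ...) {
  cat("<protodom_params>\n")
  cat(sprintf("  capacity c = %d, horizon = %d yr, census every %d yr\n",
              x$c, x$horizon, x$census_interval))
  cat(sprintf("  human food: %s (h_max = %g), mate preference: %s (p = %g)\n",
              x$human_food_style, x$h_max, x$mate_preference, x$p))
  cat(sprintf("  tau0 ~ N[0,1](%g, %g^2); litter N(%g, %g^2); r = %g, q = %g\n",
              x$mu_tau, x$sigma_tau, x$mu_L, x$sigma_L, x$r, x$q))
  cat(sprintf("  m = %g, sigma_F = %g, sigma_e = %g, d = %g\n",
              x$m, x$sigma_F, x$sigma_e, x$d))
  invisible(x)
}

# deterministic seed schedule for repetition i, retry j
mix_seed <- function(base_seed, i, j = 1L) {
  s <- as.numeric(base_seed) %% 2147483647
  for (v in c(i, j)) s <- (s * 69069 + v + 1) %% 2147483647
  as.integer(s)
}
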