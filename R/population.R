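# The population is a column-oriented structure: parallel vectors id, age,
# female, tau plus the next unused id.  This keeps the yearly loop free of
# per-agent object overhead.

new_population <- function(id = integer(), age = integer(),
                           female = logical(), tau = numeric(),
                           next_id = 1L) {
  structure(list(id = as.integer(id), age = as.integer(age),
                 female = as.logical(female), tau = as.numeric(tau),
                 next_id = as.integer(next_id)),
            class = "canine_population")
}

pop_subset <- function(pop, keep) {
  pop$id <- pop$id[keep]
  pop$age <- pop$age[keep]
  pop$female <- pop$female[keep]
  pop$tau <- pop$tau[keep]
  pop
}

#' Number of canines in a population
#' @param pop a population as returned by [initialize_population()].
#' @return integer count.
#' @export
n_canines <- function(pop) length(pop$tau)

#' @export
print.canine_population <- function(x, ...) {
  cat(sprintf("<canine_population> %d canines (%d female), ages %s, mean tau %.3f\n",
              n_canines(x), sum(x$female),
              if (n_canines(x)) paste0(min(x$age), "-", max(x$age)) else "-",
              if (n_canines(x)) mean(x$tau) else NA_real_))
  invisible(x)
}

#' @export
as.data.frame.canine_population <- function(x, ...) {
  data.frame(id = x$id, age = x$age,
             sex = ifelse(x$female, "F", "M"), tau = x$tau)
}

#' Initialise the founding population
#'
#' Creates exactly `c` canines: sexes i.i.d. with equal probability, ages
#' i.i.d. from `age_pmf`, and tolerances i.i.d. from the truncated normal
#' \eqn{N_{[0,1]}(\mu_\tau, \sigma_\tau^2)}.  Draws from the current RNG
#' stream.
#'
#' @param params a [protodom_params()] object.
#' @return a `canine_population`.
#' @export
#' @examples
#' set.seed(1)
#' pop <- initialize_population(protodom_params(c = 50))
#' n_canines(pop)
initialize_population <- function(params) {
  n <- params$c
  new_population(
    id = seq_len(n),
    age = sample(0:params$max_age, n, replace = TRUE, prob = params$age_pmf),
    female = runif(n) < 0.5,
    tau = rtruncnorm(n, params$mu_tau, params$sigma_tau, 0, 1),
    next_id = n + 1L
  )
}

#' Advance every canine's age by one year
#'
#' Canines whose new age would exceed `max_age` are removed: the age cap is
#' enforced at the age update (the age-specific death curve can absorb the
#' same role by setting its last value to 1).
#'
#' @param pop a `canine_population`.
#' @param max_age maximum attainable age.
#' @return the aged population.
#' @export
increment_ages <- function(pop, max_age = 10L) {
  pop$age <- pop$age + 1L
  if (length(pop$age) && max(pop$age) > max_age)
    pop <- pop_subset(pop, pop$age <= max_age)
  pop
}
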