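#' Probability of a non-starvation death at a given age
#'
#' The joint probability that a canine of age `a` dies of a non-starvation
#' cause in a year: the age-specific all-cause death probability L(a) times
#' the fraction `d` of deaths that are non-starvation related.
#'
#' @param age integer age(s) in the domain of `death_curve`.
#' @param death_curve L(a) over ages `0:(length - 1)`.
#' @param d probability a death is due to non-starvation causes.
#' @return probability vector, elementwise `L(age) * d`.
#' @export
#' @examples
#' natural_death_probability(3, default_death_curve(), d = 0.68)
natural_death_probability <- function(age, death_curve, d) {
  if (d < 0 || d > 1) stop("d must be in [0, 1]")
  if (any(age < 0 | age > length(death_curve) - 1L))
    stop("age outside the domain of death_curve")
  death_curve[age + 1L] * d
}

#' Apply non-starvation mortality to a population
#'
#' Each canine is independently removed with probability
#' `L(age) * d`.  Newborn pups are not present at this stage of the yearly
#' schedule (reproduction runs afterwards); their only first-year mortality
#' is the `q` survival filter at birth.
#'
#' @param pop a `canine_population`.
#' @param params a [protodom_params()] object.
#' @return the surviving population.
#' @export
apply_non_starvation_death <- function(pop, params) {
  n <- n_canines(pop)
  if (n == 0L) return(pop)
  pr <- params$death_curve[pop$age + 1L] * params$d
  pop_subset(pop, runif(n) >= pr)
}
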