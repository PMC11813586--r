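#' Select one candidate by the cumulative-weight rule
#'
#' Draws \eqn{u \sim U[0, \sum_i w_i]} and returns the smallest index `j`
#' whose cumulative weight reaches `u` -- the single-selection step of the
#' hunt.  Candidates are expected in decreasing weight order (the hunt sorts
#' canines by decreasing competitiveness, ties broken by id).
#'
#' @param weights non-negative selection weights.
#' @return the selected index, or `NA_integer_` when the total weight is
#'   zero (no realistic pursuit is possible, so no attempt occurs).
#' @export
#' @examples
#' set.seed(1)
#' weighted_select(c(0.8, 0.2))
weighted_select <- function(weights) {
  if (any(weights < 0)) stop("weights must be >= 0")
  tot <- sum(weights)
  if (length(weights) == 0L || tot <= 0) return(NA_integer_)
  u <- runif(1, 0, tot)
  which(cumsum(weights) >= u)[1L]
}

# One hunt round, equal in law to the sequential process: repeatedly select
# an unfed candidate with probability proportional to its weight, let it
# attempt once (success probability = its weight, consuming one unit on
# success only), until units or candidates run out.  The selection order of
# weighted sampling without replacement is realised in one shot by sorting
# Exp(1)/w keys (successive-sampling equivalence), which keeps the round
# vectorised; zero-weight candidates are never able to feed.
hunt_round <- function(weights, units) {
  n <- length(weights)
  fed <- logical(n)
  if (n == 0L || units <= 0L) return(fed)
  key <- rexp(n) / weights            # w = 0 -> Inf: effectively never picked
  ord <- order(key)
  success <- runif(n) < weights[ord]
  fed[ord] <- success & cumsum(success) <= units
  fed
}

#' Run the two-round hunt
#'
#' Round 1 (human food): canines attempt in a tolerance-weighted random
#' order; a selected canine succeeds with probability equal to its tolerance
#' \eqn{\tau}, consuming one human unit on success; a failed attempt does
#' not consume the unit, and each canine attempts at most once per round.
#' Round 2 (wild food): the canines left unfed repeat the process with
#' weights and success probabilities \eqn{1 - \tau}.  Canines unfed after
#' both rounds starve.
#'
#' @param tau tolerances of the pre-hunt population.
#' @param human_units,wild_units available food units (non-negative).
#' @return a list with logical vector `fed` (aligned with `tau`), the
#'   logical `starved` complement, and the per-round counts `fed_human` and
#'   `fed_wild`.
#' @export
#' @examples
#' set.seed(1)
#' run_hunt(c(0.9, 0.1, 0.5), human_units = 1, wild_units = 1)
run_hunt <- function(tau, human_units, wild_units) {
  if (human_units < 0 || wild_units < 0) stop("unit counts must be >= 0")
  fed1 <- hunt_round(tau, human_units)
  rest <- which(!fed1)
  fed2_rest <- hunt_round(1 - tau[rest], wild_units)
  fed <- fed1
  fed[rest[fed2_rest]] <- TRUE
  list(fed = fed, starved = !fed,
       fed_human = sum(fed1), fed_wild = sum(fed2_rest))
}
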