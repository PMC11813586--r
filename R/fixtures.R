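#' Parameter sets of the model-verification scenarios
#'
#' Three stylised configurations used to check that the model can produce
#' the qualitative dynamics it is meant to discriminate between:
#' `"saturating-human-food"` (linearly increasing human food reaching the
#' whole food supply at the horizon) should sustain a robust dog-like
#' population; `"equal-food-with-preference"` (human and wild food split
#' 50/50 every year, mate preference on) should force a sustained
#' separation of tolerance values; `"equal-food-no-preference"` (same food
#' split, preference off) should not produce any sustained adoption of
#' extreme tolerance strategies.
#'
#' @param scenario scenario name.
#' @param ... overrides forwarded to [protodom_params()].
#' @return a [protodom_params()] object.
#' @export
#' @examples
#' make_verification_config("equal-food-with-preference")$h_max
make_verification_config <- function(scenario = c("saturating-human-food",
                                                  "equal-food-with-preference",
                                                  "equal-food-no-preference"),
                                     ...) {
  scenario <- match.arg(scenario)
  switch(scenario,
         "saturating-human-food" =
           protodom_params(human_food_style = "increasing", h_max = 1,
                           mate_preference = "on", ...),
         "equal-food-with-preference" =
           protodom_params(human_food_style = "constant", h_max = 1,
                           mate_preference = "on", ...),
         "equal-food-no-preference" =
           protodom_params(human_food_style = "constant", h_max = 1,
                           mate_preference = "off", ...))
}

#' Sample from a clipped normal mixture
#'
#' Seeded generator of unimodal or multimodal tolerance samples on
#' \[0, 1\], used to study the power of the dip test.
#'
#' @param n sample size.
#' @param means,sds,weights mixture component parameters; `weights` are
#'   normalised and must sum to a positive value.
#' @param seed optional integer; when given, the sample is drawn from a
#'   fresh stream seeded with it, otherwise from the current stream.
#' @return numeric vector of `n` values in \[0, 1\].
#' @export
#' @examples
#' x <- make_bimodal_sample(500, c(0.1, 0.9), c(0.05, 0.05), c(1, 1), seed = 1)
make_bimodal_sample <- function(n, means, sds, weights = rep(1, length(means)),
                                seed = NULL) {
  stopifnot(length(means) == length(sds), length(means) == length(weights),
            all(sds >= 0), all(weights >= 0), sum(weights) > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n == 0) return(numeric())
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  pmin(pmax(rnorm(n, means[comp], sds[comp]), 0), 1)
}

#' Construct a synthetic census p-value sequence
#'
#' Builds a census data frame (10-year spacing, starting at year 10) from
#' run-length instructions, with p-values 0.001 for significant stretches
#' and 0.9 otherwise -- input for unit-testing the speciation detector.
#'
#' @param run_lengths list of `c(significant, k)` pairs: `significant` is
#'   logical (or 0/1) and `k` the number of consecutive censuses.
#' @param census_interval years between censuses.
#' @return data frame with columns `year` and `p_value`.
#' @export
#' @examples
#' make_census_pattern(list(c(FALSE, 2), c(TRUE, 3)))
make_census_pattern <- function(run_lengths, census_interval = 10L) {
  sig <- unlist(lapply(run_lengths, function(rl) {
    k <- as.integer(rl[[2]])
    if (k < 1) stop("run lengths must be >= 1")
    rep(as.logical(rl[[1]]), k)
  }))
  data.frame(year = seq_along(sig) * census_interval,
             p_value = ifelse(sig, 0.001, 0.9))
}
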