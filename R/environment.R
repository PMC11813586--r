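#' Nearest-integer rounding, ties away from zero
#'
#' The rounding convention used throughout the model for the `[.]` nearest
#' integer operation (food random walk, food partition, litter sizes).
#' Unlike base [round()] (banker's rounding), halves round away from zero,
#' so `round_nearest(3.5) == 4` and `round_nearest(-3.5) == -4`.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
#' @examples
#' round_nearest(c(2.5, 3.5, -0.5))
round_nearest <- function(x) sign(x) * floor(abs(x) + 0.5)

# inverse-cdf sampler of N(mean, sd^2) truncated to [lower, upper];
# sd = 0 degenerates to the (clamped) mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  pmin(pmax(qnorm(u, mean, sd), lower), upper)
}

#' Human food proportion at a given year
#'
#' Under the `"constant"` style the proportion is `h_max / 2` every year;
#' under the `"increasing"` style it grows linearly, `h_t = (t / horizon) *
#' h_max`.  Both schedules accrue the same total proportion over the run
#' (equal area under the curve), which makes the two styles comparable.
#'
#' @param t year, in `0:horizon`.
#' @param style `"constant"` or `"increasing"`.
#' @param h_max maximum human food proportion.
#' @param horizon the simulation horizon in years.
#' @return the proportion of food of human type at year `t`.
#' @export
#' @examples
#' human_food_fraction(7500, "increasing", 0.3, 15000)
human_food_fraction <- function(t, style = c("constant", "increasing"),
                                h_max, horizon = 15000) {
  style <- match.arg(style)
  if (any(t < 0 | t > horizon)) stop("t must be in [0, horizon]")
  if (style == "constant") rep(h_max / 2, length(t)) else (t / horizon) * h_max
}

#' Update total food by a bounded random walk
#'
#' Draws the new amount of food from a truncated normal distribution on
#' `[0, c]` centred at the previous amount with s.d. `sigma_F`, rounded to
#' the nearest integer.  Sampling is by inversion of the renormalised
#' truncated-normal cdf (not clip-after-draw, which would inflate boundary
#' mass).
#'
#' @param F_prev previous total food (in `[0, c]`).
#' @param sigma_F random-walk standard deviation (>= 0).
#' @param c environmental capacity.
#' @return integer amount of food in `[0, c]`.
#' @export
update_food <- function(F_prev, sigma_F, c) {
  if (sigma_F < 0) stop("sigma_F must be >= 0")
  if (F_prev < 0 || F_prev > c) stop("F_prev must be in [0, c]")
  as.integer(round_nearest(rtruncnorm(1L, F_prev, sigma_F, 0, c)))
}

#' Partition food into human-type and wild-type units
#'
#' Human units are the nearest integer to `h * F` (ties away from zero);
#' wild units are the remainder.
#'
#' @param F total food units (non-negative integer).
#' @param h proportion of food of human type, in \[0, 1\].
#' @return named integer vector with components `human` and `wild`.
#' @export
#' @examples
#' partition_food(100, 0.3)
partition_food <- function(F, h) {
  if (F < 0) stop("F must be >= 0")
  if (h < 0 || h > 1) stop("h must be in [0, 1]")
  human <- as.integer(round_nearest(h * F))
  c(human = human, wild = as.integer(F) - human)
}
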