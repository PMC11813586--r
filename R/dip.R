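# cache for the shipped null quantile table
.protodom_cache <- new.env(parent = emptyenv())

#' Hartigan's dip statistic
#'
#' The dip is the smallest sup-norm distance between the empirical cdf of
#' `x` and any unimodal cdf (convex below its mode, concave above, with a
#' possible atom at the mode).  Larger values indicate stronger departure
#' from unimodality.  Samples with fewer than two distinct values have dip
#' 0 by convention (a point mass fits them exactly).
#'
#' @param x numeric sample.
#' @return the dip statistic, a number in \[0, 0.25\].
#' @export
#' @examples
#' dip_statistic(c(rnorm(50, 0), rnorm(50, 6)))
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("x must not contain missing values")
  .dip_stat_cpp(x)
}

#' Null quantiles of the dip statistic under uniformity
#'
#' Loads the Monte Carlo table of dip quantiles for uniform samples shipped
#' with the package (10,000 replicates per tabulated sample size, generated
#' by the package's own sampler with a fixed recorded seed).  Used by
#' [dip_pvalue()] for interpolated p-values.
#'
#' @return a list with `n` (tabulated sample sizes), `probs` (quantile
#'   levels) and `q` (matrix of dip quantiles, rows = sample sizes).
#' @export
dip_null_table <- function() {
  if (!is.null(.protodom_cache$dip_table)) return(.protodom_cache$dip_table)
  path <- system.file("extdata", "dip_null_table.csv", package = "protodom",
                      mustWork = TRUE)
  tab <- read.csv(path, check.names = FALSE)
  out <- list(n = tab[[1]],
              probs = as.numeric(sub("^p", "", names(tab)[-1])),
              q = as.matrix(tab[, -1, drop = FALSE]))
  .protodom_cache$dip_table <- out
  out
}

# p-value at one tabulated size: fraction of the null above `d`, by linear
# interpolation in the quantile grid
.dip_p_row <- function(d, qrow, probs) {
  if (d <= qrow[1]) return(1)
  k <- length(qrow)
  if (d >= qrow[k]) return(1 - probs[k])
  pos <- stats::approx(qrow, probs, xout = d, ties = max)$y
  1 - pos
}

#' P-value of the dip test of unimodality
#'
#' Calibrates the dip against its Monte Carlo null distribution for uniform
#' samples (the least favourable unimodal case).  `method = "table"`
#' interpolates the shipped quantile table, scaling the statistic by
#' \eqn{\sqrt{n}} between tabulated sample sizes; `method = "montecarlo"`
#' simulates the null at exactly `n` (drawing from the current RNG stream).
#'
#' @param dip observed dip statistic.
#' @param n sample size the statistic was computed from.
#' @param method calibration method.
#' @param B Monte Carlo replicates (montecarlo method).
#' @return a p-value in \[0, 1\].
#' @export
dip_pvalue <- function(dip, n, method = c("table", "montecarlo"), B = 2000L) {
  method <- match.arg(method)
  if (n < 2) return(1)
  if (method == "montecarlo") return(mean(.dip_null_cpp(n, B) >= dip))
  tab <- dip_null_table()
  ns <- tab$n
  if (n <= ns[1]) return(.dip_p_row(dip * sqrt(n / ns[1]), tab$q[1, ], tab$probs))
  k <- length(ns)
  if (n >= ns[k]) return(.dip_p_row(dip * sqrt(n / ns[k]), tab$q[k, ], tab$probs))
  i <- findInterval(n, ns)
  p1 <- .dip_p_row(dip * sqrt(n / ns[i]), tab$q[i, ], tab$probs)
  p2 <- .dip_p_row(dip * sqrt(n / ns[i + 1]), tab$q[i + 1, ], tab$probs)
  w <- (log(n) - log(ns[i])) / (log(ns[i + 1]) - log(ns[i]))
  (1 - w) * p1 + w * p2
}

#' Dip test of unimodality
#'
#' Convenience wrapper returning the dip statistic of `x` together with its
#' calibrated p-value; `p < alpha` rejects unimodality.
#'
#' @inheritParams dip_pvalue
#' @param x numeric sample.
#' @return a list with `statistic`, `p_value`, `n` and `method`, of class
#'   `protodom_diptest`.
#' @export
#' @examples
#' set.seed(1)
#' dip_test(c(rnorm(100, 0.2, 0.05), rnorm(100, 0.8, 0.05)))
dip_test <- function(x, method = c("table", "montecarlo"), B = 2000L) {
  method <- match.arg(method)
  x <- as.numeric(x)
  d <- dip_statistic(x)
  structure(list(statistic = d,
                 p_value = dip_pvalue(d, length(x), method = method, B = B),
                 n = length(x), method = method),
            class = "protodom_diptest")
}

#' @export
print.protodom_diptest <- function(x, ...) {
  cat(sprintf("Hartigan dip test: D = %.5f, n = %d, p = %.4f (%s)\n",
              x$statistic, x$n, x$p_value, x$method))
  invisible(x)
}
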