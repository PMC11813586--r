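#' Detect the latest speciation event in a census series
#'
#' Scans the decennial dip-test p-values backwards from the end of the run
#' for maximal runs of consecutive significant censuses (`p < alpha`;
#' missing p-values break a run).  A run of `k` consecutive censuses spans
#' `k * census_interval` years, so the 1500-year rule is exactly 150
#' decennial censuses.  The latest run at least `streak_years` long is
#' reported; earlier qualifying runs are ignored.
#'
#' @param x a `protodom_sim` object, or a data frame with columns `year`
#'   and `p_value` (censuses in increasing year order).
#' @param alpha significance level.
#' @param streak_years minimum span of consecutive significant years.
#' @param census_interval years between censuses.
#' @return a `speciation_event` (list with `onset_year`, `end_year`,
#'   `duration_years`, `n_censuses`), or `NULL` if no qualifying run exists.
#' @export
#' @examples
#' cens <- make_census_pattern(list(c(FALSE, 10), c(TRUE, 150)))
#' detect_speciation(cens)
detect_speciation <- function(x, alpha = 0.05, streak_years = 1500L,
                              census_interval = 10L) {
  if (inherits(x, "protodom_sim")) {
    alpha <- x$params$alpha
    streak_years <- x$params$streak_years
    census_interval <- x$params$census_interval
    x <- census_frame(x)
  }
  if (streak_years %% census_interval != 0)
    stop("streak_years must be divisible by census_interval")
  if (nrow(x) == 0L) return(NULL)
  if (is.unsorted(x$year, strictly = TRUE))
    stop("censuses must be in strictly increasing year order")
  k_req <- streak_years %/% census_interval
  sig <- !is.na(x$p_value) & x$p_value < alpha
  i <- nrow(x)
  while (i >= 1L) {
    if (!sig[i]) { i <- i - 1L; next }
    j <- i
    while (j > 1L && sig[j - 1L] &&
           x$year[j] - x$year[j - 1L] == census_interval) j <- j - 1L
    if (i - j + 1L >= k_req) {
      return(structure(list(onset_year = x$year[j],
                            end_year = x$year[i],
                            duration_years = (i - j + 1L) * census_interval,
                            n_censuses = i - j + 1L),
                       class = "speciation_event"))
    }
    i <- j - 1L
  }
  NULL
}

#' @export
print.speciation_event <- function(x, ...) {
  cat(sprintf("<speciation_event> onset year %d, end year %d, streak %d years\n",
              x$onset_year, x$end_year, x$duration_years))
  invisible(x)
}
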