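#' Write a simulation result to CSV files
#'
#' Writes `census.csv` (long format: one row per censused agent, columns
#' `year,id,age,sex,tau`; header only when agent state was not kept),
#' `environment.csv` (`year,F,human_units,wild_units`), `pvalues.csv`
#' (`year,dip,p`), and `events.json` (speciation flag, onset and duration
#' of the latest qualifying event).  Row order is deterministic (year,
#' then id), so identical runs produce byte-identical files.
#'
#' @param sim a `protodom_sim` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_census <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cf <- census_frame(sim)
  af <- agent_frame(sim)
  af <- af[order(af$year, af$id), , drop = FALSE]
  write.csv(af, file.path(dir, "census.csv"), row.names = FALSE)
  env <- cf[, c("year", "F", "human_units", "wild_units")]
  write.csv(env, file.path(dir, "environment.csv"), row.names = FALSE)
  pv <- data.frame(year = cf$year, dip = cf$dip, p = cf$p_value)
  write.csv(pv, file.path(dir, "pvalues.csv"), row.names = FALSE)
  ev <- detect_speciation(sim)
  writeLines(c(
    sprintf("seed: %d", sim$seed),
    sprintf("persisted: %s", sim$persisted),
    sprintf("termination_year: %s", sim$termination_year),
    sprintf("censuses: %d", length(sim$censuses)),
    sprintf("speciation: %s",
            if (is.null(ev)) "none" else
              sprintf("onset %d, streak %d years", ev$onset_year,
                      ev$duration_years))
  ), file.path(dir, "run.log"))
  jsonlite::write_json(
    list(speciation = !is.null(ev),
         onset_year = if (is.null(ev)) NA else ev$onset_year,
         duration_years = if (is.null(ev)) NA else ev$duration_years,
         persisted = sim$persisted,
         seed = sim$seed,
         p_value_series = "pvalues.csv"),
    file.path(dir, "events.json"), auto_unbox = TRUE, digits = NA,
    null = "null", na = "null")
  invisible(dir)
}

#' Read back a written simulation
#'
#' Reconstructs the census stream (p-values, food series and, when
#' present, per-agent state) from a directory written by [write_census()].
#'
#' @param dir directory containing `census.csv`, `environment.csv`,
#'   `pvalues.csv`.
#' @return list with data frames `pvalues`, `environment`, `agents`.
#' @export
read_census <- function(dir) {
  list(pvalues = read.csv(file.path(dir, "pvalues.csv")),
       environment = read.csv(file.path(dir, "environment.csv")),
       agents = read.csv(file.path(dir, "census.csv")))
}
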