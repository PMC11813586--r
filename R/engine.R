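#' Advance the model by one year
#'
#' Executes the yearly schedule in fixed order: (1) environment update
#' (food random walk, partition into human/wild units), (2) two-round hunt
#' with starvation, (3) non-starvation death, (4) reproduction, (5)
#' extirpation check, (6) census with dip test on census years, (7) age
#' increment.  Exposed mainly for instrumentation and testing;
#' [run_simulation()] drives it.
#'
#' @param pop a `canine_population`.
#' @param env list with elements `F` (total food) and `t` (year).
#' @param params a [protodom_params()] object.
#' @param year current year (>= 1).
#' @param dip_min_n smallest census size on which the dip test is run;
#'   smaller censuses record a missing p-value (treated as not significant).
#' @param keep_agents snapshot the per-agent state into the census record?
#' @param h human food proportion for this year; defaults to the schedule
#'   implied by `params` (precomputed by [run_simulation()] for speed).
#' @return list with updated `pop`, `env`, `census` (a census record or
#'   `NULL`), and flag `terminate`.
#' @export
simulate_year <- function(pop, env, params, year, dip_min_n = 8L,
                          keep_agents = FALSE,
                          h = human_food_fraction(year,
                                                  params$human_food_style,
                                                  params$h_max,
                                                  params$horizon)) {
  # 1. environment
  env$F <- update_food(env$F, params$sigma_F, params$c)
  human <- as.integer(round_nearest(h * env$F))
  env$t <- year
  env$h <- h
  env$human_units <- human
  env$wild_units <- as.integer(env$F) - human

  # 2. hunt (unfed after both rounds starve)
  hunt <- run_hunt(pop$tau, env$human_units, env$wild_units)
  pop <- pop_subset(pop, hunt$fed)

  # 3. non-starvation death
  pop <- apply_non_starvation_death(pop, params)

  # 4. reproduction
  pop <- reproduce(pop, params)

  # 5. extirpation check
  if (n_canines(pop) < params$min_population)
    return(list(pop = pop, env = env, census = NULL, terminate = TRUE))

  # 6. census + dip test
  census <- NULL
  if (year %% params$census_interval == 0L) {
    n <- n_canines(pop)
    if (n >= dip_min_n) {
      dip <- dip_statistic(pop$tau)
      p <- dip_pvalue(dip, n)
    } else {
      dip <- NA_real_; p <- NA_real_
    }
    census <- list(year = year, dip = dip, p_value = p, n = n,
                   F = env$F, human_units = env$human_units,
                   wild_units = env$wild_units,
                   mean_tau = mean(pop$tau),
                   agents = if (keep_agents)
                     list(id = pop$id, age = pop$age,
                          female = pop$female, tau = pop$tau))
  }

  # 7. age update (removes canines beyond max_age)
  pop <- increment_ages(pop, params$max_age)

  list(pop = pop, env = env, census = census, terminate = FALSE)
}

#' Run one realisation of the model
#'
#' Initialises food and population at capacity, then iterates
#' [simulate_year()] until the horizon or until the population falls below
#' `min_population`.  All stochasticity flows from the single seed, so a
#' run is exactly reproducible from `(params, seed)`.
#'
#' @param params a [protodom_params()] object.
#' @param seed integer seed for the realisation.
#' @param keep_agents store the per-agent state (id, age, sex, tau) in each
#'   census?  Disable for large campaigns to save memory.
#' @param dip_min_n see [simulate_year()].
#' @return a `protodom_sim` object: list with `censuses` (time-ordered
#'   census records), `terminated_early`, `termination_year`, `persisted`,
#'   `params` and `seed`.
#' @export
#' @examples
#' params <- protodom_params(horizon = 200)
#' sim <- run_simulation(params, seed = 1)
#' sim$persisted
run_simulation <- function(params, seed, keep_agents = TRUE,
                           dip_min_n = 8L) {
  validate_params(params)
  set.seed(as.integer(seed))
  pop <- initialize_population(params)
  env <- list(t = 0L, F = params$c, h = NA_real_,
              human_units = NA_integer_, wild_units = NA_integer_)
  censuses <- vector("list", params$horizon %/% params$census_interval)
  nc <- 0L
  terminated <- FALSE
  term_year <- NA_integer_
  h_sched <- human_food_fraction(seq_len(params$horizon),
                                 params$human_food_style, params$h_max,
                                 params$horizon)
  for (year in seq_len(params$horizon)) {
    st <- simulate_year(pop, env, params, year, dip_min_n = dip_min_n,
                        keep_agents = keep_agents, h = h_sched[year])
    pop <- st$pop; env <- st$env
    if (!is.null(st$census)) {
      nc <- nc + 1L
      censuses[[nc]] <- st$census
    }
    if (st$terminate) { terminated <- TRUE; term_year <- year; break }
  }
  structure(list(censuses = censuses[seq_len(nc)],
                 terminated_early = terminated,
                 termination_year = term_year,
                 persisted = !terminated,
                 final_population = pop,
                 params = params, seed = as.integer(seed)),
            class = "protodom_sim")
}

#' @export
print.protodom_sim <- function(x, ...) {
  cat(sprintf("<protodom_sim> seed %d: %s, %d censuses\n", x$seed,
              if (x$persisted) sprintf("persisted to year %d", x$params$horizon)
              else sprintf("extirpated in year %d", x$termination_year),
              length(x$censuses)))
  invisible(x)
}

#' Census p-value series of a run
#'
#' @param sim a `protodom_sim` object.
#' @return data frame with columns `year`, `dip`, `p_value`, `n`, `F`,
#'   `human_units`, `wild_units`, `mean_tau`.
#' @export
census_frame <- function(sim) {
  cs <- sim$censuses
  data.frame(
    year = vapply(cs, `[[`, 0, "year"),
    dip = vapply(cs, `[[`, 0, "dip"),
    p_value = vapply(cs, `[[`, 0, "p_value"),
    n = vapply(cs, `[[`, 0, "n"),
    F = vapply(cs, `[[`, 0, "F"),
    human_units = vapply(cs, `[[`, 0, "human_units"),
    wild_units = vapply(cs, `[[`, 0, "wild_units"),
    mean_tau = vapply(cs, `[[`, 0, "mean_tau")
  )
}

# keep the agent-level census stream as one long data frame
agent_frame <- function(sim) {
  cs <- Filter(function(z) !is.null(z$agents), sim$censuses)
  if (!length(cs))
    return(data.frame(year = integer(), id = integer(), age = integer(),
                      sex = character(), tau = numeric()))
  do.call(rbind, lapply(cs, function(z) {
    data.frame(year = z$year, id = z$agents$id, age = z$agents$age,
               sex = ifelse(z$agents$female, "F", "M"), tau = z$agents$tau)
  }))
}
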