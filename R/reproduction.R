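#' Probability a female attempts to reproduce
#'
#' Derived from the logistic difference equation
#' \eqn{C_{t+1} = C_t + r C_t (1 - C_t/c)}: the per-capita growth
#' contribution \eqn{r(1 - C_t/c)}, divided by the expected surviving pups
#' per litter \eqn{q \mu_L} and restricted to females (which cancels to the
#' total-count ratio, since the female share of capacity scales with the
#' female share of the population), clipped to \[0, 1\]:
#' \deqn{L_t = \mathrm{clip}\!\left(\frac{r (1 - C_t/c)}{q \mu_L},\, 0,\, 1\right).}
#' At capacity the probability is exactly zero, reflecting alloparental care
#' and the cost of breeding in a resource-depleted environment.
#'
#' @param C_female number of females (any age).
#' @param C_total total number of canines (> 0, `>= C_female`).
#' @param params a [protodom_params()] object (uses `r`, `q`, `mu_L`, `c`).
#' @return the breeding probability \eqn{L_t}.
#' @export
#' @examples
#' p <- protodom_params()
#' reproduction_probability(125, 250, p)  # half capacity -> 0.6
reproduction_probability <- function(C_female, C_total, params) {
  if (C_total <= 0) stop("C_total must be > 0")
  if (C_female < 0 || C_female > C_total)
    stop("C_female must be in [0, C_total]")
  if (params$q * params$mu_L == 0) stop("q * mu_L must be > 0")
  raw <- params$r * (1 - C_total / params$c) / (params$q * params$mu_L)
  min(max(raw, 0), 1)
}

#' Assign mates to breeding females
#'
#' Females are processed in uniformly random order; each first passes an
#' independent Bernoulli(`L_t`) trial to decide whether she attempts to
#' breed this year.  With mate preference off, a breeding female picks a
#' male uniformly from the remaining pool.  With preference on, she only
#' considers males with \eqn{|\tau_f - \tau_m| < p} (strict), choosing among
#' them with probability proportional to \eqn{1 - |\tau_f - \tau_m|}; if no
#' male qualifies she does not mate this year.  A chosen male leaves the
#' pool (annual monogamy), and assignment halts when the pool is empty.
#'
#' @param female_idx,male_idx indices (into `tau`) of the sexually mature
#'   females and males.
#' @param tau tolerance vector of the whole population.
#' @param L_t breeding probability, from [reproduction_probability()].
#' @param params a [protodom_params()] object (uses `mate_preference`, `p`).
#' @return integer matrix with one row per mated pair, columns `dam`, `sire`.
#' @export
select_mates <- function(female_idx, male_idx, tau, L_t, params) {
  nf <- length(female_idx)
  empty <- matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("dam", "sire")))
  if (nf == 0L || length(male_idx) == 0L) return(empty)
  females <- female_idx[sample.int(nf)]
  females <- females[runif(nf) < L_t]
  if (length(females) == 0L) return(empty)

  if (params$mate_preference == "off") {
    npair <- min(length(females), length(male_idx))
    sires <- male_idx[sample.int(length(male_idx))][seq_len(npair)]
    return(cbind(dam = females[seq_len(npair)], sire = sires))
  }

  pairs <- .select_mates_pref_cpp(tau[females], tau[male_idx], params$p)
  cbind(dam = females[pairs[, 1L]], sire = male_idx[pairs[, 2L]])
}

#' Produce one litter
#'
#' Litter size is the nearest integer of a \eqn{N(\mu_L, \sigma_L^2)} draw
#' (non-positive draws give an empty litter, the pair still counts as
#' mated).  Each pup gets a uniform random sex.  With probability `m` a pup
#' is a mutant and draws \eqn{\tau \sim U[0, 1]} (no extra noise);
#' otherwise \eqn{\tau \sim U[\min(\tau_d, \tau_s), \max(\tau_d, \tau_s)] +
#' N(0, \sigma_e^2)}, truncated to \[0, 1\].  Each pup then survives
#' independently with probability `q`; non-survivors are discarded
#' immediately.
#'
#' @param tau_dam,tau_sire parental tolerances.
#' @param params a [protodom_params()] object.
#' @return list with `size` (the realised litter size before the survival
#'   filter) and vectors `female`, `tau` for the surviving pups.
#' @export
make_litter <- function(tau_dam, tau_sire, params) {
  size <- max(0, round_nearest(rnorm(1, params$mu_L, params$sigma_L)))
  if (size == 0) return(list(size = 0L, female = logical(), tau = numeric()))
  female <- runif(size) < 0.5
  mutant <- runif(size) < params$m
  lo <- min(tau_dam, tau_sire); hi <- max(tau_dam, tau_sire)
  tau <- runif(size, lo, hi) + rnorm(size, 0, params$sigma_e)
  tau <- pmin(pmax(tau, 0), 1)
  tau[mutant] <- runif(sum(mutant))
  alive <- runif(size) < params$q
  list(size = as.integer(size), female = female[alive], tau = tau[alive])
}

# all litters of one year in a single batch of vectorised draws
# (equal in law to independent make_litter() calls per pair)
make_litters_batch <- function(tau_dam, tau_sire, params) {
  np <- length(tau_dam)
  sizes <- pmax(0, round_nearest(rnorm(np, params$mu_L, params$sigma_L)))
  tot <- sum(sizes)
  if (tot == 0) return(list(female = logical(), tau = numeric()))
  pair <- rep.int(seq_len(np), sizes)
  female <- runif(tot) < 0.5
  mutant <- runif(tot) < params$m
  lo <- pmin(tau_dam, tau_sire)[pair]
  hi <- pmax(tau_dam, tau_sire)[pair]
  tau <- runif(tot, lo, hi) + rnorm(tot, 0, params$sigma_e)
  tau <- pmin(pmax(tau, 0), 1)
  nm <- sum(mutant)
  if (nm) tau[mutant] <- runif(nm)
  alive <- runif(tot) < params$q
  list(female = female[alive], tau = tau[alive])
}

#' Run the yearly reproduction submodel
#'
#' Computes the breeding probability once from the pre-breeding counts,
#' assigns mates with [select_mates()], generates litters, applies the pup
#' survival filter and appends the surviving age-0 pups to the population.
#'
#' @param pop a `canine_population`.
#' @param params a [protodom_params()] object.
#' @return the population including this year's surviving pups.
#' @export
reproduce <- function(pop, params) {
  n <- n_canines(pop)
  if (n == 0L) return(pop)
  L_t <- reproduction_probability(sum(pop$female), n, params)
  mature <- pop$age >= params$maturity_age
  fidx <- which(mature & pop$female)
  midx <- which(mature & !pop$female)
  pairs <- select_mates(fidx, midx, pop$tau, L_t, params)
  if (nrow(pairs) == 0L) return(pop)
  pups <- make_litters_batch(pop$tau[pairs[, "dam"]],
                             pop$tau[pairs[, "sire"]], params)
  np <- length(pups$tau)
  if (np == 0L) return(pop)
  pop$id <- c(pop$id, seq.int(pop$next_id, length.out = np))
  pop$age <- c(pop$age, integer(np))
  pop$female <- c(pop$female, pups$female)
  pop$tau <- c(pop$tau, pups$tau)
  pop$next_id <- pop$next_id + np
  pop
}
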