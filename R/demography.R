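#' Construct a colony demographic timeline
#'
#' A colony timeline records every ant's caste, eclosion (emergence) day and
#' optional death day, together with the experiment duration and the days on
#' which the nest was photographed. It is the demographic input to
#' [simulate_excavation()].
#'
#' @param ants data frame with columns `ant_id`, `caste` (`"queen"` or
#'   `"worker"`), `eclosion_day` (may be negative: the ant emerged before the
#'   experiment started) and `death_day` (`NA` = alive throughout).
#' @param duration_days experiment length in days.
#' @param kind `"maturation"` (colony grows from a founding queen) or
#'   `"fixed"` (fixed-demographics group introduced on day 0).
#' @param sampling_days increasing vector of observation days in
#'   `[0, duration_days]`; defaults to every day.
#' @return an object of class `colony_timeline`.
#' @examples
#' ants <- data.frame(ant_id = c("Q", "w1"), caste = c("queen", "worker"),
#'                    eclosion_day = c(-365, -40), death_day = NA_real_)
#' colony_timeline(ants, duration_days = 30, kind = "fixed")
#' @export
colony_timeline <- function(ants, duration_days,
                            kind = c("maturation", "fixed"),
                            sampling_days = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(ants),
            all(c("ant_id", "caste", "eclosion_day") %in% names(ants)))
  if (is.null(ants$death_day)) ants$death_day <- NA_real_
  ants <- ants[, c("ant_id", "caste", "eclosion_day", "death_day")]
  ants$caste <- as.character(ants$caste)
  if (!all(ants$caste %in% c("queen", "worker"))) {
    stop("caste must be 'queen' or 'worker'")
  }
  if (sum(ants$caste == "queen") != 1L) {
    stop("a colony must contain exactly one queen")
  }
  if (anyDuplicated(ants$ant_id)) stop("duplicate ant_id")
  dead <- !is.na(ants$death_day)
  if (any(ants$death_day[dead] <= ants$eclosion_day[dead])) {
    stop("death_day must be greater than eclosion_day")
  }
  if (is.null(sampling_days)) sampling_days <- seq(0, duration_days)
  sampling_days <- sort(unique(as.numeric(sampling_days)))
  if (any(sampling_days < 0) || any(sampling_days > duration_days)) {
    stop("sampling_days must lie in [0, duration_days]")
  }
  structure(list(ants = ants, duration_days = as.numeric(duration_days),
                 kind = kind, sampling_days = sampling_days),
            class = "colony_timeline")
}

#' @export
print.colony_timeline <- function(x, ...) {
  nw <- sum(x$ants$caste == "worker")
  cat(sprintf("<colony_timeline> kind=%s, %d worker(s) + queen, %g days, %d sampling days\n",
              x$kind, nw, x$duration_days, length(x$sampling_days)))
  invisible(x)
}

#' Logistic population growth parameters
#'
#' Parameters of the worker population model
#' \eqn{N(t) = K / (1 + ((K - N_0)/N_0) e^{-\rho (t - t_{first})})} for
#' \eqn{t \ge t_{first}} and 0 workers before, used both to generate synthetic
#' colony-maturation timelines and as the fitted form in
#' [fit_logistic_population()].
#'
#' @param K carrying capacity (workers at saturation), `>= 1`.
#' @param rho intrinsic growth rate per day, `> 0`.
#' @param t_first day of first worker emergence.
#' @param N0 worker count at `t_first`.
#' @return an object of class `population_params`.
#' @export
population_params <- function(K, rho = 0.05, t_first = 30, N0 = 1) {
  stopifnot(K >= 1, is.na(rho) || rho > 0, N0 >= 1, N0 <= K)
  structure(list(K = K, rho = rho, t_first = t_first, N0 = N0),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("<population_params> K=%.3g workers, rho=%.3g /day, t_first=%.3g d, N0=%.3g\n",
              x$K, x$rho, x$t_first, x$N0))
  invisible(x)
}

#' Expected worker count under logistic growth
#'
#' @param t day (vectorised).
#' @param p a [population_params()] object.
#' @return expected number of workers at day `t`; 0 before `p$t_first`.
#' @examples
#' p <- population_params(K = 12, rho = 0.05, t_first = 30, N0 = 1)
#' logistic_population(30, p)   # 1
#' logistic_population(1e5, p)  # ~12
#' @export
logistic_population <- function(t, p) {
  stopifnot(inherits(p, "population_params"))
  out <- p$K / (1 + ((p$K - p$N0) / p$N0) * exp(-p$rho * (t - p$t_first)))
  out[t < p$t_first] <- 0
  out
}

#' Configuration for the synthetic-data generators
#'
#' Bundles the study conditions emulated by the generators: logistic colony
#' growth saturating at 5--20 workers over ~190 days, fixed-demographics
#' cohorts with young (40 +/- 16 d) or old (171.56 +/- 20 d) workers,
#' photography every 1--3 days, 5% multiplicative observation noise on areas,
#' and a 10-day maturation delay before a newly eclosed worker digs.
#'
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param K_range inclusive integer range the worker carrying capacity is
#'   drawn from.
#' @param obs_noise_sd_frac observation noise standard deviation as a
#'   fraction of the measured area.
#' @param young_age,old_age `c(mean, sd)` of worker age (days) at day 0 for
#'   the two fixed-demographics cohorts.
#' @param maturation_delay days after eclosion before a worker digs.
#' @param rho,t_first,N0 logistic growth parameters for maturation colonies.
#' @param duration_days experiment length for maturation colonies.
#' @param queen_eclosion_day queen eclosion day (far in the past, so that her
#'   age-dependent target area is zero once workers are present).
#' @param sampling_gap inclusive integer range of days between photographs.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = NULL,
                             K_range = c(5, 20),
                             obs_noise_sd_frac = 0.05,
                             young_age = c(mean = 40, sd = 16),
                             old_age = c(mean = 171.56, sd = 20),
                             maturation_delay = 10,
                             rho = 0.05, t_first = 30, N0 = 1,
                             duration_days = 190,
                             queen_eclosion_day = -365,
                             sampling_gap = c(1, 3)) {
  stopifnot(obs_noise_sd_frac >= 0, young_age[2] >= 0, old_age[2] >= 0,
            maturation_delay >= 0, length(K_range) == 2, K_range[1] >= 1)
  structure(list(seed = seed, K_range = K_range,
                 obs_noise_sd_frac = obs_noise_sd_frac,
                 young_age = unname(young_age), old_age = unname(old_age),
                 maturation_delay = maturation_delay,
                 rho = rho, t_first = t_first, N0 = N0,
                 duration_days = duration_days,
                 queen_eclosion_day = queen_eclosion_day,
                 sampling_gap = sampling_gap),
            class = "generator_config")
}

# Random sampling schedule: day 0, then gaps drawn uniformly from
# sampling_gap[1]..sampling_gap[2], truncated at the duration.
draw_sampling_days <- function(duration_days, gap_range) {
  gaps <- sample(seq(gap_range[1], gap_range[2]),
                 size = ceiling(duration_days / gap_range[1]) + 1,
                 replace = TRUE)
  days <- cumsum(c(0, gaps))
  days[days <= duration_days]
}

#' Generate a synthetic colony-maturation timeline
#'
#' Emulates a colony growing from a single founding queen: the worker
#' carrying capacity `K` is drawn uniformly from `config$K_range`, and worker
#' `k` ecloses on the day the expected logistic worker count first rounds to
#' `k` (deterministic given `K`, so a seed fully reproduces the timeline).
#' Deaths are not generated (mortality was rare on this timescale).
#'
#' @param config a [generator_config()].
#' @param K optionally fix the worker carrying capacity (must lie inside
#'   `config$K_range`).
#' @return a [colony_timeline()] of kind `"maturation"`, with attributes
#'   `K` and `pop_params`.
#' @export
synth_maturation_colony <- function(config = generator_config(), K = NULL) {
  with_seed(config$seed, {
    if (is.null(K)) {
      K <- sample(seq(config$K_range[1], config$K_range[2]), 1L)
    } else if (K < config$K_range[1] || K > config$K_range[2]) {
      stop("K outside the configured K_range")
    }
    p <- population_params(K = K, rho = config$rho,
                           t_first = config$t_first, N0 = config$N0)
    # worker k emerges when the logistic expectation crosses k - 1/2
    k <- seq_len(K)
    thr <- k - 0.5
    t_k <- ifelse(thr <= p$N0, p$t_first,
                  p$t_first + log(((p$K - p$N0) / p$N0) / (p$K / thr - 1)) / p$rho)
    t_k <- t_k[t_k <= config$duration_days]
    ants <- data.frame(
      ant_id = c("queen", sprintf("w%02d", seq_along(t_k))),
      caste = c("queen", rep("worker", length(t_k))),
      eclosion_day = c(config$queen_eclosion_day, t_k),
      death_day = NA_real_)
    tl <- colony_timeline(ants, duration_days = config$duration_days,
                          kind = "maturation",
                          sampling_days = draw_sampling_days(
                            config$duration_days, config$sampling_gap))
    attr(tl, "K") <- K
    attr(tl, "pop_params") <- p
    tl
  })
}

#' Generate a synthetic fixed-demographics timeline
#'
#' A queen plus `group_size - 1` workers whose ages at day 0 are drawn from
#' the cohort's normal distribution (young: 40 +/- 16 d; old:
#' 171.56 +/- 20 d), truncated at >= 1 day.
#'
#' @param group_size total ants including the queen (the study used 5, 10
#'   and 15).
#' @param cohort `"young"` or `"old"`.
#' @param config a [generator_config()].
#' @param duration_days experiment length (default 30 d: these experiments
#'   saturate in about three weeks).
#' @return a [colony_timeline()] of kind `"fixed"`.
#' @export
synth_fixed_colony <- function(group_size, cohort = c("young", "old"),
                               config = generator_config(),
                               duration_days = 30) {
  cohort <- match.arg(cohort)
  stopifnot(group_size >= 2)
  with_seed(config$seed, {
    par <- if (cohort == "young") config$young_age else config$old_age
    ages <- rnorm_trunc(group_size - 1L, par[1], par[2], lower = 1)
    ants <- data.frame(
      ant_id = c("queen", sprintf("w%02d", seq_len(group_size - 1L))),
      caste = c("queen", rep("worker", group_size - 1L)),
      eclosion_day = c(config$queen_eclosion_day, -ages),
      death_day = NA_real_)
    tl <- colony_timeline(ants, duration_days = duration_days, kind = "fixed",
                          sampling_days = draw_sampling_days(
                            duration_days, config$sampling_gap))
    attr(tl, "cohort") <- cohort
    tl
  })
}

#' Ants alive at a given day, with their ages
#'
#' @param timeline a [colony_timeline()].
#' @param day day index within the experiment.
#' @return data frame `ant_id`, `caste`, `age` for ants with
#'   `eclosion_day <= day` and (`death_day` absent or `> day`).
#' @export
ages_at <- function(timeline, day) {
  stopifnot(inherits(timeline, "colony_timeline"),
            day >= 0, day <= timeline$duration_days)
  a <- timeline$ants
  alive <- a$eclosion_day <= day & (is.na(a$death_day) | a$death_day > day)
  out <- a[alive, c("ant_id", "caste")]
  out$age <- day - a$eclosion_day[alive]
  rownames(out) <- NULL
  out
}

#' Colony size over time
#'
#' @param timeline a [colony_timeline()].
#' @param days vector of days.
#' @return number of ants (queen included) alive on each day.
#' @export
population_at <- function(timeline, days) {
  a <- timeline$ants
  vapply(days, function(d) {
    sum(a$eclosion_day <= d & (is.na(a$death_day) | a$death_day > d))
  }, numeric(1))
}

#' Age threshold separating young from old ants
#'
#' The threshold is the mean plus one standard deviation of the young
#' cohort's age; with the study's young cohort (40 +/- 16 d) this gives the
#' 56-day cutoff used when attributing excavated area to age groups.
#'
#' @param mean_age,sd_age mean and standard deviation (days) of the young
#'   cohort's age.
#' @return threshold age in days.
#' @examples
#' young_old_threshold(40, 16)  # 56
#' @export
young_old_threshold <- function(mean_age, sd_age) {
  stopifnot(sd_age >= 0)
  mean_age + sd_age
}
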