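#' Age-dependent target-area line
#'
#' The per-ant target area (the steady-state area per ant at which digging
#' ceases, the reciprocal of the tolerated density) decreases linearly with
#' ant age: \eqn{a_{age} = max(0, intercept + slope \cdot age)}. The default
#' coefficients are the fitted line \eqn{y = -0.032 x + 11.22}.
#'
#' @param slope change in target area per day of age (cm2/day), typically
#'   negative.
#' @param intercept target area of a newly eclosed ant (cm2), `> 0`.
#' @return an object of class `target_line`.
#' @export
target_line <- function(slope = -0.032, intercept = 11.22) {
  stopifnot(intercept > 0)
  structure(list(slope = slope, intercept = intercept),
            class = c("target_line", "target_spec"))
}

#' Age-independent constant target area (null model)
#'
#' Every ant shares one target area per ant regardless of age; the default
#' 11.6 cm2/ant is the value fitted from colony-maturation experiments.
#'
#' @param a_star target area per ant in cm2.
#' @return an object of class `constant_target`.
#' @export
constant_target <- function(a_star = 11.6) {
  stopifnot(a_star > 0)
  structure(list(a_star = a_star),
            class = c("constant_target", "target_spec"))
}

#' Target area per ant at a given age
#'
#' @param age age in days (vectorised), `>= 0`.
#' @param target a [target_line()] or [constant_target()].
#' @return target area in cm2 per ant, clamped at zero (a negative target
#'   area is meaningless; the line reaches zero near age 350 d with the
#'   default coefficients).
#' @examples
#' target_area(0, target_line())    # 11.22
#' target_area(40, target_line())   # 9.94
#' target_area(400, target_line())  # 0
#' @export
target_area <- function(age, target) {
  stopifnot(inherits(target, "target_spec"), all(age >= 0))
  if (inherits(target, "constant_target")) {
    rep(target$a_star, length(age))
  } else {
    pmax(0, target$intercept + target$slope * age)
  }
}

#' Construct an excavation model
#'
#' The density-regulation digging model: an ant of age \eqn{age} facing a
#' current area per ant \eqn{a} digs at
#' \eqn{da/dt = r (1 - a / a_{age})}, rectified at zero (ants do not refill
#' the nest), where \eqn{a_{age}} is the age-dependent target area. Workers
#' younger than `maturation_delay` do not dig. In colony-maturation
#' experiments the founding queen's excavation is lump-credited at first
#' worker emergence with mean `queen_area_mean`.
#'
#' @param r basal digging rate constant in cm2/(ant day); the per-ant rate
#'   never exceeds `r`, whatever the ant's age.
#' @param target a [target_line()] (age-dependent model, default) or
#'   [constant_target()] (age-independent null model).
#' @param maturation_delay days after eclosion before a worker digs.
#' @param queen_area_mean,queen_area_sd mean and (sampling) standard
#'   deviation of the founding queen's excavated area, cm2.
#' @param rectify if `TRUE` (default) negative digging rates are taken to be
#'   zero.
#' @return an object of class `excavation_model`.
#' @examples
#' m <- excavation_model()
#' predict(m, age = 40, area_per_ant = 0)  # basal rate 2.2 cm2/day
#' @export
excavation_model <- function(r = 2.2, target = target_line(),
                             maturation_delay = 10,
                             queen_area_mean = 23.8, queen_area_sd = 8.0,
                             rectify = TRUE) {
  stopifnot(r > 0, inherits(target, "target_spec"), maturation_delay >= 0,
            queen_area_mean >= 0, queen_area_sd >= 0)
  structure(list(r = r, target = target,
                 maturation_delay = maturation_delay,
                 queen_area_mean = queen_area_mean,
                 queen_area_sd = queen_area_sd,
                 rectify = rectify),
            class = "excavation_model")
}

#' @export
print.excavation_model <- function(x, ...) {
  tgt <- if (inherits(x$target, "constant_target")) {
    sprintf("constant a* = %.3g cm2/ant", x$target$a_star)
  } else {
    sprintf("line a_age = %.4g + (%.4g) age", x$target$intercept, x$target$slope)
  }
  cat("<excavation_model>\n",
      sprintf("  basal rate r        : %.3g cm2/(ant day)\n", x$r),
      sprintf("  target area         : %s\n", tgt),
      sprintf("  maturation delay    : %g d\n", x$maturation_delay),
      sprintf("  queen founding area : %.3g (sd %.3g) cm2\n",
              x$queen_area_mean, x$queen_area_sd),
      sprintf("  rectified rates     : %s\n", x$rectify), sep = "")
  invisible(x)
}

#' Instantaneous digging rate of a single ant
#'
#' @param a current area per ant (cm2), `>= 0`.
#' @param age ant age in days (same length as `a` or scalar).
#' @param model an [excavation_model()].
#' @param mature logical; override the maturation gate (by default an ant
#'   digs only if `age >= model$maturation_delay`).
#' @return digging rate in cm2/day, in `[0, r]` under rectification; zero
#'   when the target area at that age is zero or the ant is immature.
#' @export
per_ant_rate <- function(a, age, model = excavation_model(), mature = NULL) {
  stopifnot(all(a >= 0))
  n <- max(length(a), length(age))
  a <- rep_len(a, n); age <- rep_len(age, n)
  ta <- target_area(age, model$target)
  rate <- ifelse(ta > 0, model$r * (1 - a / ta), 0)
  if (model$rectify) rate <- pmax(0, rate)
  if (is.null(mature)) mature <- age >= model$maturation_delay
  rate * as.numeric(rep_len(mature, n))
}

#' Colony-level excavation rate
#'
#' Sum of per-ant digging rates, all ants sharing the same current area per
#' ant \eqn{a = A/N} (density is a global cue; no spatial structure).
#'
#' @param A total excavated area (cm2).
#' @param ages ages (days) of the ants present.
#' @param model an [excavation_model()].
#' @param mature optional logical vector overriding the maturation gate.
#' @return total digging rate in cm2/day, at most `length(ages) * r`.
#' @export
colony_rate <- function(A, ages, model = excavation_model(), mature = NULL) {
  if (length(ages) == 0L) stop("colony_rate requires at least one ant")
  sum(per_ant_rate(A / length(ages), ages, model, mature = mature))
}

#' Closed-form excavation trajectory for a single-age cohort
#'
#' For `N` ants sharing one (frozen) age the colony dynamics reduce to a
#' single linear ODE with solution
#' \eqn{A(t) = N [a_{age} + (a_0 - a_{age}) e^{-r t / a_{age}}]}. Used as an
#' independent oracle for the forward simulator and as the fitted form in
#' [estimate_r()].
#'
#' @param t time since introduction, days (vectorised).
#' @param N number of ants.
#' @param age shared ant age (days).
#' @param a0 initial area per ant (cm2), below the target area.
#' @param model an [excavation_model()].
#' @return total area in cm2; constant `N * a0` when the target is zero.
#' @export
closed_form_single_cohort <- function(t, N, age, a0 = 0,
                                      model = excavation_model()) {
  ta <- target_area(age, model$target)
  if (ta <= 0) return(rep(N * a0, length(t)))
  stopifnot(a0 <= ta)
  N * (ta + (a0 - ta) * exp(-model$r * t / ta))
}

#' Nest collapse operator
#'
#' @param A excavated area (cm2).
#' @param fraction fraction of area lost, in (0, 1).
#' @return remaining area `A * (1 - fraction)`.
#' @export
induce_collapse <- function(A, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  A * (1 - fraction)
}

#' Construct a collapse event
#'
#' The study's protocol collapsed 25--30% of the steady-state excavated
#' area; fractions outside that band are allowed only with
#' `allow_any = TRUE`.
#'
#' @param day day of the artificial collapse.
#' @param fraction fraction of the current excavated area removed.
#' @param allow_any allow fractions outside `[0.25, 0.30]`.
#' @return a one-row data frame with class `collapse_event`.
#' @export
collapse_event <- function(day, fraction, allow_any = FALSE) {
  stopifnot(fraction > 0, fraction < 1)
  if (!allow_any && (fraction < 0.25 || fraction > 0.30)) {
    stop("collapse fraction outside the protocol band [0.25, 0.30]; ",
         "use allow_any = TRUE to override")
  }
  structure(data.frame(day = day, fraction = fraction),
            class = c("collapse_event", "data.frame"))
}

#' Simulate colony excavation over a demographic timeline
#'
#' Explicit-Euler integration of the colony excavation rate over the
#' timeline, with a per-ant ledger of dug area. For maturation timelines the
#' trajectory starts at zero and the queen's founding area is credited (to
#' her ledger entry) on the day the first worker ecloses; fixed-demographics
#' groups start digging from an empty setup on day 0. Collapse events remove
#' `fraction` of the current area without touching the ledger (the area was
#' genuinely dug); re-excavation accrues new credit.
#'
#' A worker enters the excavation dynamics only once mature: before
#' `maturation_delay` days of age a callow ant neither digs nor loads the
#' shared density (it stays on the brood pile), so the nest's response to an
#' emergence is delayed by the maturation time. The observed population
#' census (`$n_ants`) still counts every ant alive.
#'
#' Ages advance during maturation simulations. For fixed-demographics
#' simulations the default holds every ant's target at its age on day 0: the
#' cohort age is an experiment label, and the experiments are short enough
#' (~3 weeks) that within-experiment ageing of the target is not modelled.
#' Override with `age_advance`.
#'
#' @param timeline a [colony_timeline()].
#' @param model an [excavation_model()].
#' @param events `NULL`, a [collapse_event()], or a data frame with columns
#'   `day`, `fraction`.
#' @param dt Euler step in days (`<= 0.25`; default 0.1).
#' @param method `"rk4"` (default: classical fourth-order Runge-Kutta on
#'   the area dynamics within each step, needed for sub-0.1% agreement with
#'   the closed form at dt = 0.1) or `"euler"` (explicit Euler).
#' @param age_advance logical; default `TRUE` for maturation timelines,
#'   `FALSE` for fixed ones.
#' @param queen_area founding-queen area in cm2 for maturation timelines;
#'   defaults to `model$queen_area_mean`.
#' @return an object of class `excavation_sim`: daily trajectory
#'   (`$days`, `$area`, `$n_ants`), per-ant cumulative ledger (`$ledger`,
#'   and `$ledger_daily`, a days x ants matrix), applied `$events` with
#'   realised losses, and echoes of model/timeline.
#' @export
simulate_excavation <- function(timeline, model = excavation_model(),
                                events = NULL, dt = 0.1,
                                method = c("rk4", "euler"),
                                age_advance = NULL, queen_area = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(timeline, "colony_timeline"),
            inherits(model, "excavation_model"), dt > 0, dt <= 0.25)
  if (is.null(age_advance)) age_advance <- timeline$kind == "maturation"
  dur <- timeline$duration_days
  if (!is.null(events)) {
    events <- as.data.frame(events)[, c("day", "fraction")]
    if (any(events$day < 0 | events$day > dur)) {
      stop("collapse event day outside the experiment duration")
    }
    events <- events[order(events$day), , drop = FALSE]
  } else {
    events <- data.frame(day = numeric(0), fraction = numeric(0))
  }
  ants <- timeline$ants
  n_ants <- nrow(ants)
  ecl <- ants$eclosion_day
  death <- ifelse(is.na(ants$death_day), Inf, ants$death_day)
  is_worker <- ants$caste == "worker"

  # Maturation colonies open with a founding phase: the queen digs her
  # founding area at a constant rate from introduction until the first
  # worker ecloses (she then ceases digging, her age-dependent target being
  # long exhausted). The area at first emergence is exactly `queen_area`.
  qa <- 0
  fe_day <- NA_real_
  if (timeline$kind == "maturation") {
    qa <- queen_area %||% model$queen_area_mean
    emerged <- which(is_worker & ecl >= 0)
    fe_day <- if (length(emerged)) min(ecl[emerged]) else min(30, dur)
  }

  t_grid <- seq(0, dur, by = dt)
  n_steps <- length(t_grid)
  area <- numeric(n_steps)
  cum <- numeric(n_ants)            # per-ant cumulative dug area
  day_idx <- 0:floor(dur)
  ledger_daily <- matrix(0, nrow = length(day_idx), ncol = n_ants,
                         dimnames = list(NULL, ants$ant_id))
  losses <- numeric(nrow(events))
  queen_credited <- timeline$kind != "maturation" || !is.finite(fe_day)

  A <- 0
  next_day_row <- 1L
  ev_i <- 1L
  age0 <- -ecl                      # age at day 0 (fixed timelines)
  q_ix <- which(!is_worker)
  for (s in seq_len(n_steps)) {
    t <- t_grid[s]
    if (!queen_credited && fe_day <= 0 && t >= fe_day) {
      # degenerate founding phase: workers present from the start
      A <- A + qa
      cum[q_ix] <- cum[q_ix] + qa
      queen_credited <- TRUE
    }
    # collapse events applied when the grid reaches them
    while (ev_i <= nrow(events) && t >= events$day[ev_i]) {
      loss <- A * events$fraction[ev_i]
      A <- A - loss
      losses[ev_i] <- loss
      ev_i <- ev_i + 1L
    }
    area[s] <- A
    while (next_day_row <= length(day_idx) && t >= day_idx[next_day_row]) {
      ledger_daily[next_day_row, ] <- cum
      next_day_row <- next_day_row + 1L
    }
    if (s == n_steps) break
    if (!queen_credited && fe_day > 0) {
      # founding phase: queen digs at constant rate until first emergence
      step_in_phase <- min(dt, max(fe_day - t, 0))
      if (step_in_phase > 0) {
        inc_q <- qa / fe_day * step_in_phase
        A <- A + inc_q
        cum[q_ix] <- cum[q_ix] + inc_q
      }
      if (t + dt >= fe_day) queen_credited <- TRUE
    }
    # only mature ants take part in the dynamics (dig and occupy space)
    active <- ecl <= t & t < death & (t - ecl) >= model$maturation_delay
    N <- sum(active)
    if (N > 0L) {
      ages_t <- if (age_advance) t - ecl[active] else pmax(age0[active], 0)
      rate_fn <- function(Ax) per_ant_rate(Ax / N, ages_t, model, mature = TRUE)
      if (method == "euler") {
        inc <- rate_fn(A) * dt
      } else {
        k1 <- rate_fn(A)
        k2 <- rate_fn(A + dt / 2 * sum(k1))
        k3 <- rate_fn(A + dt / 2 * sum(k2))
        k4 <- rate_fn(A + dt * sum(k3))
        inc <- dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
      }
      A <- A + sum(inc)
      cum[active] <- cum[active] + inc
    }
  }
  if (next_day_row <= length(day_idx)) {
    ledger_daily[next_day_row:length(day_idx), ] <-
      matrix(cum, nrow = length(day_idx) - next_day_row + 1L,
             ncol = n_ants, byrow = TRUE)
  }
  events$loss <- losses

  daily_area <- approx(t_grid, area, xout = day_idx)$y
  structure(list(
    days = day_idx,
    area = daily_area,
    n_ants = population_at(timeline, day_idx),
    grid_days = t_grid,
    grid_area = area,
    ledger = setNames(cum, ants$ant_id),
    ledger_daily = ledger_daily,
    events = events,
    model = model,
    timeline = timeline,
    age_advance = age_advance,
    queen_area = if (timeline$kind == "maturation") qa else 0,
    dt = dt), class = "excavation_sim")
}

#' @rdname simulate_excavation
#' @param object an [excavation_model()].
#' @param nsim number of simulations (timelines recycled if fewer).
#' @param seed optional seed.
#' @param ... passed on to [simulate_excavation()].
#' @return for the `simulate()` method, a list of `excavation_sim` objects
#'   (a single object if `nsim = 1`).
#' @export
simulate.excavation_model <- function(object, nsim = 1, seed = NULL,
                                      timeline, ...) {
  with_seed(seed, {
    sims <- replicate(nsim,
                      simulate_excavation(timeline, model = object, ...),
                      simplify = FALSE)
    if (nsim == 1L) sims[[1L]] else sims
  })
}

#' @export
print.excavation_sim <- function(x, ...) {
  cat(sprintf("<excavation_sim> %s colony, %d ants, %g days, final area %.1f cm2",
              x$timeline$kind, nrow(x$timeline$ants),
              max(x$days), x$area[length(x$area)]))
  if (nrow(x$events)) {
    cat(sprintf(", %d collapse event(s)", nrow(x$events)))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.excavation_sim <- function(x, ...) {
  data.frame(day = x$days, area_cm2 = x$area, n_ants = x$n_ants)
}

#' @export
plot.excavation_sim <- function(x, ...) {
  plot(x$grid_days, x$grid_area, type = "l", xlab = "day",
       ylab = expression(excavated ~ area ~ (cm^2)), ...)
  if (nrow(x$events)) abline(v = x$events$day, lty = 2, col = "grey40")
  invisible(x)
}

#' Predicted per-ant digging rate and target area
#'
#' @param object an [excavation_model()].
#' @param age ant age(s) in days.
#' @param area_per_ant current area per ant (cm2).
#' @param ... unused.
#' @return data frame with `age`, `target_cm2` and `rate_cm2_per_day`.
#' @export
predict.excavation_model <- function(object, age, area_per_ant = 0, ...) {
  data.frame(age = age,
             target_cm2 = target_area(age, object$target),
             rate_cm2_per_day = per_ant_rate(area_per_ant, age, object))
}

#' Observe a simulated trajectory as sampled, noisy measurements
#'
#' Emulates the photographic record: the excavated area is read off on the
#' timeline's sampling days with multiplicative Gaussian observation noise;
#' ant counts are exact (a census, not an image measurement).
#'
#' @param sim an `excavation_sim`.
#' @param sampling_days observation days; defaults to the timeline's.
#' @param noise_sd_frac observation noise sd as a fraction of the area.
#' @param seed optional seed.
#' @return data frame `day`, `area_cm2`, `n_ants`.
#' @export
observe_trajectory <- function(sim, sampling_days = NULL,
                               noise_sd_frac = 0.05, seed = NULL) {
  stopifnot(inherits(sim, "excavation_sim"), noise_sd_frac >= 0)
  days <- sampling_days %||% sim$timeline$sampling_days
  a <- approx(sim$grid_days, sim$grid_area, xout = days)$y
  with_seed(seed, {
    noisy <- pmax(0, a * (1 + rnorm(length(a), 0, noise_sd_frac)))
    data.frame(day = days, area_cm2 = noisy,
               n_ants = population_at(sim$timeline, days))
  })
}

#' Saturation (plateau) area of a trajectory
#'
#' The nest is considered saturated once the daily digging rate stays below
#' `eps` for `k` consecutive days; the saturation area is the mean area over
#' the first such window.
#'
#' @param x an `excavation_sim` or a data frame with columns `day` and
#'   `area_cm2` (daily or near-daily sampling).
#' @param eps rate threshold in cm2/day.
#' @param k required number of consecutive quiet days.
#' @param after ignore days before this (e.g. to look past a collapse);
#'   defaults to the last event day for simulations, otherwise 0.
#' @return plateau area in cm2, with attribute `window` (first and last day
#'   of the qualifying window). Errors if the trajectory never stabilizes.
#' @export
saturation_area <- function(x, eps = 0.1, k = 5, after = NULL) {
  if (inherits(x, "excavation_sim")) {
    if (is.null(after) && nrow(x$events)) after <- max(x$events$day)
    x <- as.data.frame(x)
  }
  after <- after %||% 0
  stopifnot(is.data.frame(x), all(c("day", "area_cm2") %in% names(x)))
  x <- x[order(x$day), ]
  x <- x[x$day >= after, ]
  if (nrow(x) < k + 1) stop("trajectory too short to assess saturation")
  rate <- diff(x$area_cm2) / diff(x$day)
  quiet <- rate < eps
  run <- rle(quiet)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & (x$day[ends + 1L] - x$day[starts]) >= k)
  if (!length(ok)) stop("no plateau: digging rate never stayed below eps for k days")
  i0 <- starts[ok[1L]]
  i1 <- which(x$day >= x$day[i0] + k)[1L]
  out <- mean(x$area_cm2[i0:i1])
  attr(out, "window") <- c(x$day[i0], x$day[i1])
  out
}

#' Attribute excavated area to queen, young and old ants
#'
#' Splits each ant's ledger by its age at the moment of digging against the
#' young/old threshold (see [young_old_threshold()]); the queen's share is
#' reported separately. The three shares sum to the total area dug, i.e. the
#' final area plus any collapse losses.
#'
#' @param sim an `excavation_sim`.
#' @param threshold age threshold in days (default 56).
#' @return named numeric vector `queen`, `young`, `old` (cm2).
#' @export
attribute_by_group <- function(sim, threshold = 56) {
  stopifnot(inherits(sim, "excavation_sim"))
  ants <- sim$timeline$ants
  total <- unname(sim$ledger)
  queen <- sum(total[ants$caste == "queen"])
  young <- 0; old <- 0
  wk <- which(ants$caste == "worker")
  for (i in wk) {
    if (!sim$age_advance) {
      # frozen cohort age: the whole ledger goes to the cohort's side
      age_i <- max(-ants$eclosion_day[i], 0)
      if (age_i <= threshold) young <- young + total[i] else old <- old + total[i]
      next
    }
    cross <- ants$eclosion_day[i] + threshold   # day the ant turns `threshold`
    if (cross >= max(sim$days)) {
      young <- young + total[i]
    } else if (cross <= min(sim$days)) {
      old <- old + total[i]
    } else {
      at_cross <- approx(sim$days, sim$ledger_daily[, i], xout = cross)$y
      young <- young + at_cross
      old <- old + (total[i] - at_cross)
    }
  }
  c(queen = unname(queen), young = young, old = old)
}

#' Per-worker excavation statistics
#'
#' @param sim an `excavation_sim`.
#' @param exclude_queen drop the queen's ledger entry (default).
#' @param band inclusive per-ant range in cm2; the band area fraction is the
#'   dug area contributed by ants inside the band divided by the total dug
#'   area (area-weighted, not a head count).
#' @return list with `mean`, `sd`, `band_area_fraction` and `amounts` (the
#'   per-ant totals). Errors when no worker dug anything.
#' @export
per_ant_stats <- function(sim, exclude_queen = TRUE, band = c(5, 13)) {
  stopifnot(inherits(sim, "excavation_sim"), length(band) == 2)
  keep <- if (exclude_queen) sim$timeline$ants$caste == "worker"
          else rep(TRUE, nrow(sim$timeline$ants))
  x <- sim$ledger[keep]
  if (length(x) == 0L) stop("no workers in the ledger")
  if (sum(x) <= 0) stop("total excavated area is zero; statistics undefined")
  inb <- x >= band[1] & x <= band[2]
  list(mean = mean(x), sd = sd(x),
       band_area_fraction = sum(x[inb]) / sum(x),
       amounts = x)
}
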