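#' Infusion events and dose schedules
#'
#' An infusion event is a constant-rate intravenous administration of
#' `dose_mg` milligrams over `duration` seconds starting at `start` seconds.
#' A schedule is an ordered, non-overlapping set of events together with the
#' total simulated horizon.
#'
#' @param start infusion start time (s).
#' @param duration infusion duration (s), strictly positive.
#' @param dose_mg dose in mg, non-negative.
#' @return `infusion_event()`: a list of class `ifx_event`.
#' @examples
#' # the standard protocol: 350 mg over 2 h at weeks 0, 4 and 8
#' sched <- regular_schedule(dose_mg = 350, n_doses = 3, interval = weeks(4))
#' @export
infusion_event <- function(start, duration, dose_mg) {
  if (start < 0) stop("event start must be >= 0", call. = FALSE)
  if (duration <= 0) stop("infusion duration must be > 0", call. = FALSE)
  if (dose_mg < 0) stop("dose must be >= 0", call. = FALSE)
  structure(list(start = start, duration = duration, dose_mg = dose_mg),
            class = "ifx_event")
}

#' @param events list of [infusion_event()]s.
#' @param horizon total simulated time (s); defaults to one dosing interval
#'   past the last event start (or the last event end if there is a single
#'   event).
#' @return `dose_schedule()`: a list of class `ifx_schedule` with sorted
#'   `events` and `horizon`.
#' @rdname infusion_event
#' @export
dose_schedule <- function(events, horizon = NULL) {
  if (length(events)) {
    starts <- vapply(events, `[[`, numeric(1), "start")
    events <- events[order(starts)]
    starts <- sort(starts)
    ends <- starts + vapply(events, `[[`, numeric(1), "duration")
    if (length(events) > 1L && any(starts[-1] < ends[-length(ends)])) {
      stop("infusion events overlap", call. = FALSE)
    }
    if (is.null(horizon)) {
      gap <- if (length(starts) > 1L) min(diff(starts)) else 0
      horizon <- max(ends) + gap
      if (length(starts) > 1L) horizon <- starts[length(starts)] + gap
    }
    if (max(ends) > horizon) {
      stop("last infusion event ends after the schedule horizon",
           call. = FALSE)
    }
  } else if (is.null(horizon)) {
    stop("an empty schedule needs an explicit horizon", call. = FALSE)
  }
  structure(list(events = events, horizon = horizon), class = "ifx_schedule")
}

#' @param n_doses number of doses.
#' @param interval inter-dose interval (s).
#' @param first_start start of the first infusion (s).
#' @return `regular_schedule()`: an `ifx_schedule` of `n_doses` identical
#'   events spaced `interval` apart, with horizon one interval after the
#'   last dose.
#' @rdname infusion_event
#' @export
regular_schedule <- function(dose_mg, n_doses, interval = weeks(4),
                             duration = hours(2), first_start = 0) {
  starts <- first_start + (seq_len(n_doses) - 1) * interval
  events <- lapply(starts, infusion_event, duration = duration,
                   dose_mg = dose_mg)
  dose_schedule(events, horizon = starts[n_doses] + interval)
}

#' @export
print.ifx_schedule <- function(x, ...) {
  cat(sprintf("Dose schedule: %d infusion(s), horizon %.3g weeks\n",
              length(x$events), x$horizon / weeks(1)))
  for (e in x$events) {
    cat(sprintf("  %6.2f wk: %g mg over %.2g h\n",
                e$start / weeks(1), e$dose_mg, e$duration / hours(1)))
  }
  invisible(x)
}

#' Convert a mg dose to a molar input rate
#'
#' A dose of `dose_mg` milligrams infused at a constant rate over `duration`
#' seconds into the reference volume corresponds to
#' `dose_mg * 1e-3 / (duration * ifx_molar_mass * reference_volume)` M/s.
#' With the default conventions, 350 mg over 2 h gives 3.3713e-10 M/s.
#'
#' @param dose_mg dose (mg).
#' @param duration infusion duration (s).
#' @param conv a [unit_conventions()].
#' @return Input rate omega (M/s).
#' @examples
#' dose_to_input_rate(350, hours(2))
#' @export
dose_to_input_rate <- function(dose_mg, duration, conv = unit_conventions()) {
  if (any(duration <= 0)) stop("duration must be > 0", call. = FALSE)
  if (any(dose_mg < 0)) stop("dose must be >= 0", call. = FALSE)
  dose_mg * 1e-3 / (duration * conv$ifx_molar_mass * conv$reference_volume)
}

#' Molar/mass concentration conversions
#'
#' `molar_to_mass_conc()` converts mol/L to mg/L
#' (`conc * molar_mass * 1000`); `mass_to_molar_conc()` is its inverse.
#' With the default TNF-alpha molar mass, 2.6e-13 M corresponds to
#' 4.42e-6 mg/L; with the infliximab molar mass, the 3 mg/L therapeutic
#' threshold corresponds to 2.0806e-8 M.
#'
#' @param conc concentration in mol/L (or mg/L for the inverse).
#' @param molar_mass molar mass (g/mol).
#' @return Converted concentration.
#' @examples
#' molar_to_mass_conc(2.6e-13, 17000)     # TNF-alpha level in mg/L
#' mass_to_molar_conc(3, 144190)          # infliximab threshold in M
#' @export
molar_to_mass_conc <- function(conc, molar_mass) {
  if (any(conc < 0) || any(molar_mass <= 0)) {
    stop("non-negative concentration and positive molar mass required",
         call. = FALSE)
  }
  conc * molar_mass * 1000
}

#' @rdname molar_to_mass_conc
#' @export
mass_to_molar_conc <- function(conc, molar_mass) {
  if (any(conc < 0) || any(molar_mass <= 0)) {
    stop("non-negative concentration and positive molar mass required",
         call. = FALSE)
  }
  conc / (molar_mass * 1000)
}

#' Weight-based dose convenience
#'
#' Clinical dosing is often quoted per kg of body weight (e.g. 5 mg/kg for a
#' 70 kg patient = 350 mg).
#'
#' @param mg_per_kg dose per body weight (mg/kg).
#' @param weight_kg body weight (kg).
#' @return Absolute dose in mg.
#' @export
dose_from_weight <- function(mg_per_kg, weight_kg = 70) mg_per_kg * weight_kg

#' Piecewise-constant infusion rate profile
#'
#' Builds the drug input rate omega_a(t) for a schedule: the rate takes the
#' event's constant value during each infusion and zero otherwise. The
#' integrator is restarted at every breakpoint (infusion on/off), so the
#' discontinuities are never stepped over.
#'
#' @param schedule an `ifx_schedule`.
#' @param conv a [unit_conventions()].
#' @return List with `rate` (a vectorized function of time, M/s),
#'   `breakpoints` (ordered times of every infusion start and end, s) and
#'   `segments` (data frame with `start`, `end`, `rate` covering
#'   `[0, horizon]`).
#' @export
build_infusion_profile <- function(schedule, conv = unit_conventions()) {
  stopifnot(inherits(schedule, "ifx_schedule"))
  ev <- schedule$events
  starts <- vapply(ev, `[[`, numeric(1), "start")
  ends <- starts + vapply(ev, `[[`, numeric(1), "duration")
  rates <- vapply(ev, function(e) {
    dose_to_input_rate(e$dose_mg, e$duration, conv)
  }, numeric(1))
  breakpoints <- sort(unique(c(starts, ends)))
  bounds <- sort(unique(c(0, starts, ends, schedule$horizon)))
  bounds <- bounds[bounds <= schedule$horizon]
  seg <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  seg$rate <- vapply(seq_len(nrow(seg)), function(i) {
    mid <- (seg$start[i] + seg$end[i]) / 2
    j <- which(starts <= mid & mid < ends)
    if (length(j)) rates[j[1]] else 0
  }, numeric(1))
  rate_fun <- function(t) {
    out <- numeric(length(t))
    for (j in seq_along(starts)) {
      out[t >= starts[j] & t < ends[j]] <- rates[j]
    }
    out
  }
  list(rate = rate_fun, breakpoints = breakpoints, segments = seg)
}
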