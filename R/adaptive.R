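#' Inverted Hill clearance model
#'
#' The clearance rate of infliximab depends on the inflammatory burden,
#' which is itself reflected in trough drug exposure: low troughs go with
#' active inflammation and fast (partly fecal) drug loss. The relation is
#' modelled as a decreasing Hill function of the trough concentration,
#' `delta_a(A_min) = V / (1 + (A_min/K)^n)`: `V` is the maximal clearance
#' (as `A_min -> 0`), `K` the trough at which clearance is half-maximal,
#' and `n` the Hill coefficient controlling steepness. Defaults are the
#' values fitted to the standard-protocol clearance sweep.
#'
#' @param V maximal clearance rate (1/s).
#' @param K half-maximal trough concentration (M).
#' @param n Hill coefficient (dimensionless).
#' @return `hill_params()`: an object of class `ifx_hill`.
#' @examples
#' hp <- hill_params()
#' hill_clearance(0, hp)               # V
#' hill_clearance(hp$K, hp)            # V/2
#' @export
hill_params <- function(V = 6.8939e-6, K = 0.5809e-9, n = 0.2590) {
  for (nm in c("V", "K", "n")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("Hill parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  structure(list(V = V, K = K, n = n), class = "ifx_hill")
}

#' @export
print.ifx_hill <- function(x, ...) {
  cat(sprintf(
    "Inverted Hill clearance model: V = %.4g 1/s, K = %.4g M, n = %.4g\n",
    x$V, x$K, x$n))
  rss <- attr(x, "residual_norm")
  if (!is.null(rss)) cat(sprintf("  fit residual norm: %.4g\n", rss))
  invisible(x)
}

#' @param A_min trough infliximab concentration(s) (M), non-negative.
#' @param hp a `hill_params()`.
#' @return `hill_clearance()`: clearance rate(s) `delta_a` (1/s), strictly
#'   decreasing in `A_min`, equal to `V` at zero.
#' @rdname hill_params
#' @export
hill_clearance <- function(A_min, hp = hill_params()) {
  if (any(A_min < 0)) stop("A_min must be non-negative", call. = FALSE)
  hp$V / (1 + (A_min / hp$K)^hp$n)
}

#' Fit the inverted Hill model to trough/clearance pairs
#'
#' Nonlinear least squares (Levenberg-Marquardt) on untransformed clearance
#' residuals, minimizing `sum((delta_a - V/(1+(A_min/K)^n))^2)`. Starting
#' values are `V0` = the largest observed clearance, `K0` = the geometric
#' mean trough and `n0 = 0.5`, with positivity bounds; this is robust in the
#' shallow-slope regime (`n` around 0.26) that the sweep data occupy.
#'
#' @param A_min trough concentrations (M); may also be an `ifx_sweep`, in
#'   which case its `A_min` and `delta_a` columns are used.
#' @param delta_a matching clearance rates (1/s).
#' @param start optional named list of starting values `V`, `K`, `n`.
#' @return A [hill_params()] with attributes `residual_norm` (square root of
#'   the residual sum of squares) and `fit` (the underlying `nls` object).
#' @examples
#' hp <- hill_params()
#' A <- 10^seq(-11, -7, length.out = 30)
#' refit <- fit_hill(A, hill_clearance(A, hp))
#' @export
fit_hill <- function(A_min, delta_a, start = NULL) {
  if (inherits(A_min, "ifx_sweep") && missing(delta_a)) {
    sw <- A_min[A_min$status == "ok", ]
    delta_a <- sw$delta_a
    A_min <- sw$A_min
  }
  if (length(A_min) < 4L) {
    stop("at least 4 (A_min, delta_a) pairs are required", call. = FALSE)
  }
  if (length(A_min) != length(delta_a)) {
    stop("A_min and delta_a lengths differ", call. = FALSE)
  }
  if (any(A_min <= 0)) stop("A_min values must be positive", call. = FALSE)
  if (anyDuplicated(A_min)) {
    stop("A_min values must be distinct", call. = FALSE)
  }
  if (diff(range(delta_a)) <= 0) {
    stop("degenerate data: delta_a is constant", call. = FALSE)
  }
  if (is.null(start)) {
    start <- list(V = max(delta_a), K = exp(mean(log(A_min))), n = 0.5)
  }
  dat <- data.frame(A = A_min, d = delta_a)
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ V / (1 + (A / K)^n), data = dat, start = start,
                      lower = c(V = 1e-12, K = 1e-15, n = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("Hill fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  hp <- hill_params(V = cf[["V"]], K = cf[["K"]], n = cf[["n"]])
  attr(hp, "residual_norm") <- sqrt(sum(stats::resid(fit)^2))
  attr(hp, "fit") <- fit
  hp
}

#' Adaptive-clearance dosing simulation
#'
#' Simulates repeated fixed doses at a fixed interval while updating the
#' infliximab clearance before each administration, the way therapeutic
#' drug monitoring would: the first interval uses `delta_a0`; just before
#' each subsequent dose the trough concentration is read and the inverted
#' Hill model converts it into the clearance held constant over the next
#' interval.
#'
#' The dose count convention: dose `k` "reaches the therapeutic level" when
#' the trough at the end of interval `k` (one interval after dose `k`) first
#' meets `threshold`; `doses_to_therapeutic` is that `k`, or `NA` if the
#' level is not reached within `n_doses`. Set `count_mode = "any_time"` to
#' count instead the first interval during which the drug concentration
#' ever meets the threshold (post-infusion peaks make this far laxer).
#'
#' @param params an [ifx_params()]; its `delta_a` is overridden per
#'   interval.
#' @param delta_a0 clearance assumed for the first interval (1/s).
#' @param dose_mg dose per administration (mg).
#' @param n_doses number of doses simulated (13 four-weekly doses = one
#'   year).
#' @param interval inter-dose interval (s).
#' @param duration infusion duration (s).
#' @param hp a [hill_params()].
#' @param threshold therapeutic trough threshold (M); default 3 mg/L
#'   converted with the infliximab molar mass.
#' @param init initial state; defaults to the CD preset.
#' @param conv a [unit_conventions()].
#' @param count_mode see Details.
#' @param ... further arguments to [integrate_regimen()].
#' @return Object of class `ifx_regimen`: list with `timeseries` (the
#'   concatenated `ifx_timeseries`), `per_dose` (data frame: `dose`,
#'   `delta_a`, `trough_A_M`, `trough_A_mgL`, `trough_L_M`,
#'   `trough_time_s`), `doses_to_therapeutic` (integer or `NA`), `reached`,
#'   `threshold`, `hp`, `dose_mg`, `delta_a0`.
#' @examples
#' \donttest{
#' pre <- ifx_preset("CD")
#' reg <- simulate_adaptive_regimen(pre$params, delta_a0 = 3.5e-6,
#'                                  dose_mg = 500, n_doses = 13)
#' reg$doses_to_therapeutic  # 9
#' }
#' @export
simulate_adaptive_regimen <- function(params, delta_a0, dose_mg,
                                      n_doses = 13, interval = weeks(4),
                                      duration = hours(2),
                                      hp = hill_params(),
                                      threshold = NULL,
                                      init = ifx_preset("CD")$init,
                                      conv = unit_conventions(),
                                      count_mode = c("end_of_interval",
                                                     "any_time"),
                                      ...) {
  count_mode <- match.arg(count_mode)
  if (n_doses < 1) stop("n_doses must be >= 1", call. = FALSE)
  if (is.null(threshold)) {
    threshold <- mass_to_molar_conc(3, conv$ifx_molar_mass)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive molar concentration", call. = FALSE)
  }
  one_dose <- dose_schedule(list(infusion_event(0, duration, dose_mg)),
                            horizon = interval)
  da <- delta_a0
  y <- validate_state(init, action = "error")
  times <- numeric(0)
  states <- NULL
  per_dose <- vector("list", n_doses)
  reached <- NA_integer_
  for (k in seq_len(n_doses)) {
    p <- params
    p$delta_a <- da
    ts <- integrate_regimen(p, structure(y, class = "ifx_state"), one_dose,
                            system = "full", conv = conv, ...)
    offset <- (k - 1) * interval
    keep <- if (length(times)) -1L else TRUE
    times <- c(times, ts$times[keep] + offset)
    states <- rbind(states, ts$states[keep, , drop = FALSE])
    y <- ts$states[nrow(ts$states), ]
    trough <- y[["A"]]
    per_dose[[k]] <- data.frame(
      dose = k, delta_a = da,
      trough_A_M = trough,
      trough_A_mgL = molar_to_mass_conc(trough, conv$ifx_molar_mass),
      trough_L_M = y[["L"]],
      trough_time_s = offset + interval)
    hit <- if (count_mode == "end_of_interval") trough >= threshold else
      max(ts$states[, "A"]) >= threshold
    if (is.na(reached) && hit) reached <- k
    da <- hill_clearance(trough, hp)
  }
  sched <- regular_schedule(dose_mg, n_doses, interval = interval,
                            duration = duration)
  full_ts <- structure(list(times = times, states = states, params = params,
                            schedule = sched,
                            P0 = conserved_total(init, params),
                            system = "full", conv = conv),
                       class = "ifx_timeseries")
  structure(list(timeseries = full_ts,
                 per_dose = do.call(rbind, per_dose),
                 doses_to_therapeutic = reached,
                 reached = !is.na(reached),
                 threshold = threshold, hp = hp,
                 dose_mg = dose_mg, delta_a0 = delta_a0),
            class = "ifx_regimen")
}

#' @export
print.ifx_regimen <- function(x, ...) {
  cat(sprintf(
    "Adaptive regimen: %g mg every %.3g weeks, initial clearance %.3g 1/s\n",
    x$dose_mg, diff(x$per_dose$trough_time_s[1:2] %||% c(0, weeks(4))) /
      weeks(1), x$delta_a0))
  cat(sprintf("  therapeutic trough threshold: %.4g M (%.3g mg/L)\n",
              x$threshold, molar_to_mass_conc(
                x$threshold, x$timeseries$conv$ifx_molar_mass)))
  if (x$reached) {
    cat(sprintf("  therapeutic level reached after %d dose(s)\n",
                x$doses_to_therapeutic))
  } else {
    cat(sprintf("  therapeutic level NOT reached within %d dose(s)\n",
                nrow(x$per_dose)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a) || anyNA(a)) b else a

#' Doses-to-therapeutic table
#'
#' Runs the adaptive-clearance regimen over a grid of initial clearance
#' values and doses and tabulates how many doses are needed to reach the
#' therapeutic trough level.
#'
#' @inheritParams simulate_adaptive_regimen
#' @param delta_a0_list initial clearance rates (1/s).
#' @param dose_list doses (mg).
#' @return A data frame of class `ifx_dose_table`, rows indexed by
#'   `delta_a0`, one column per dose; entries are dose counts, `NA` when the
#'   level is not reached within `n_doses`. [format()] renders `NA` as
#'   `"NR"`.
#' @export
doses_to_therapeutic_table <- function(params, delta_a0_list, dose_list,
                                       hp = hill_params(), threshold = NULL,
                                       n_doses = 13,
                                       init = ifx_preset("CD")$init,
                                       conv = unit_conventions(), ...) {
  if (!length(delta_a0_list) || !length(dose_list)) {
    stop("delta_a0_list and dose_list must be non-empty", call. = FALSE)
  }
  m <- matrix(NA_integer_, nrow = length(delta_a0_list),
              ncol = length(dose_list),
              dimnames = list(format(delta_a0_list, digits = 3),
                              paste0(dose_list, "mg")))
  for (i in seq_along(delta_a0_list)) {
    for (j in seq_along(dose_list)) {
      reg <- simulate_adaptive_regimen(params, delta_a0_list[i],
                                       dose_list[j], n_doses = n_doses,
                                       hp = hp, threshold = threshold,
                                       init = init, conv = conv, ...)
      m[i, j] <- reg$doses_to_therapeutic
    }
  }
  res <- as.data.frame(m)
  res <- cbind(data.frame(delta_a0 = delta_a0_list), res)
  class(res) <- c("ifx_dose_table", "data.frame")
  res
}

#' @export
format.ifx_dose_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (j in seq_along(y)[-1]) {
    y[[j]] <- ifelse(is.na(y[[j]]), "NR", as.character(y[[j]]))
  }
  format.data.frame(y, ...)
}

#' @export
print.ifx_dose_table <- function(x, ...) {
  print(format(x), row.names = FALSE)
  invisible(x)
}

#' Dose recommendation from an estimated clearance
#'
#' Given an initial clearance estimate (for instance obtained by plugging a
#' measured trough into the inverted Hill model), recommends the smallest
#' candidate dose whose adaptive regimen reaches the therapeutic trough
#' level within the horizon.
#'
#' @inheritParams simulate_adaptive_regimen
#' @param candidate_doses sorted ascending candidate doses (mg).
#' @param horizon_doses maximum number of doses allowed (13 four-weekly
#'   doses = one year).
#' @return Object of class `ifx_recommendation`: list with `dose` (mg, or
#'   `NA` if no candidate suffices), `sufficient` (logical),
#'   `doses_to_therapeutic` for the recommended dose, and `tried` (data
#'   frame of candidates and their counts).
#' @export
recommend_dose <- function(delta_a0, candidate_doses = c(350, 500, 700),
                           horizon_doses = 13, params = ifx_params(),
                           hp = hill_params(), threshold = NULL,
                           init = ifx_preset("CD")$init,
                           conv = unit_conventions(), ...) {
  if (is.unsorted(candidate_doses)) {
    stop("candidate_doses must be sorted ascending", call. = FALSE)
  }
  tried <- data.frame(dose_mg = numeric(0), doses_to_therapeutic = integer(0))
  pick <- NA_real_
  pick_n <- NA_integer_
  if (horizon_doses >= 1) {
    for (d in candidate_doses) {
      reg <- simulate_adaptive_regimen(params, delta_a0, d,
                                       n_doses = horizon_doses, hp = hp,
                                       threshold = threshold, init = init,
                                       conv = conv, ...)
      tried <- rbind(tried, data.frame(
        dose_mg = d, doses_to_therapeutic = reg$doses_to_therapeutic))
      if (reg$reached) {
        pick <- d
        pick_n <- reg$doses_to_therapeutic
        break
      }
    }
  }
  structure(list(dose = pick, sufficient = !is.na(pick),
                 doses_to_therapeutic = pick_n, tried = tried,
                 delta_a0 = delta_a0, horizon_doses = horizon_doses),
            class = "ifx_recommendation")
}

#' @export
print.ifx_recommendation <- function(x, ...) {
  if (x$sufficient) {
    cat(sprintf(
      "Recommended dose: %g mg (therapeutic trough after %d doses, horizon %d)\n",
      x$dose, x$doses_to_therapeutic, x$horizon_doses))
  } else {
    cat(sprintf(
      "No candidate dose sufficient within %d doses at delta_a0 = %.3g 1/s\n",
      x$horizon_doses, x$delta_a0))
  }
  invisible(x)
}
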