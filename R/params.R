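#' Kinetic and clearance parameters of the TNF-alpha/infliximab model
#'
#' Constructs the nine rate constants of the model. Defaults are the
#' literature estimates used for IBD patients; all rates are per-second and
#' concentrations molar.
#'
#' @param k1 TNF-receptor association rate (1/M/s).
#' @param k_m1 TNF-receptor dissociation rate (1/s).
#' @param R_tot total receptor concentration (M).
#' @param eps internalization (endocytosis) rate of bound receptors (1/s).
#' @param delta1 clearance rate of free TNF-alpha (1/s).
#' @param ka TNF-infliximab association rate (1/M/s).
#' @param k_ma TNF-infliximab dissociation rate (1/s).
#' @param delta_c clearance rate of the TNF-infliximab complex (1/s).
#' @param delta_a clearance rate of free infliximab (1/s). Values outside
#'   `delta_a_window` trigger a warning (not an error): the window is the
#'   plausible clinical range, not a hard constraint.
#' @param delta_a_window length-2 numeric, plausibility window for `delta_a`.
#'
#' @return An object of class `ifx_params` (a named list of the nine rates).
#' @examples
#' p <- ifx_params()
#' p$delta_a
#' @export
ifx_params <- function(k1 = 1.7e7, k_m1 = 5.5e-4, R_tot = 1.5e-10,
                       eps = 6e-4, delta1 = 1e-5, ka = 1e6, k_ma = 1e-4,
                       delta_c = 8.5e-7, delta_a = 3.5e-6,
                       delta_a_window = c(1.5e-6, 5e-6)) {
  p <- list(k1 = k1, k_m1 = k_m1, R_tot = R_tot, eps = eps, delta1 = delta1,
            ka = ka, k_ma = k_ma, delta_c = delta_c, delta_a = delta_a)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
    }
  }
  if (delta_a < delta_a_window[1] || delta_a > delta_a_window[2]) {
    warning(sprintf(
      "delta_a = %.3g 1/s is outside the plausible range [%.3g, %.3g]",
      delta_a, delta_a_window[1], delta_a_window[2]), call. = FALSE)
  }
  structure(p, class = "ifx_params", delta_a_window = delta_a_window)
}

#' @export
print.ifx_params <- function(x, ...) {
  cat("TNF-alpha / infliximab model parameters (SI-molar units):\n")
  for (nm in names(x)) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Model state at a time point
#'
#' A state is the quadruple (`L`, `r`, `A`, `C`): free TNF-alpha, bound
#' receptor proportion, free infliximab and TNF-infliximab complex. `L`, `A`
#' and `C` are molar; `r` is a proportion in \[0, 1\].
#'
#' @param L free TNF-alpha concentration (M).
#' @param r bound receptor proportion (dimensionless, in \[0, 1\]).
#' @param A free infliximab concentration (M).
#' @param C TNF-infliximab complex concentration (M).
#' @return Named numeric vector of class `ifx_state`.
#' @examples
#' ifx_state(L = 4.35e-11, r = 0.0827)
#' @export
ifx_state <- function(L, r, A = 0, C = 0) {
  s <- c(L = L, r = r, A = A, C = C)
  validate_state(s, action = "error")
  structure(s, class = "ifx_state")
}

# Soft state validation. Solver output can undershoot zero by tiny amounts;
# anything within `clamp_tol` below a bound is clamped, larger violations are
# reported via `action`.
validate_state <- function(state, clamp_tol = 1e-18,
                           action = c("warn", "error", "none")) {
  action <- match.arg(action)
  if (!is.numeric(state) || length(state) != 4L || anyNA(state) ||
      any(!is.finite(state))) {
    stop("model state must be four finite numbers (L, r, A, C)", call. = FALSE)
  }
  nm <- c("L", "r", "A", "C")
  lower <- c(0, 0, 0, 0)
  upper <- c(Inf, 1, Inf, Inf)
  bad <- character(0)
  out <- unname(state)
  for (i in 1:4) {
    if (out[i] < lower[i]) {
      if (out[i] >= lower[i] - clamp_tol) out[i] <- lower[i]
      else bad <- c(bad, sprintf("%s = %.4g < %g", nm[i], out[i], lower[i]))
    }
    if (out[i] > upper[i]) {
      if (out[i] <= upper[i] + clamp_tol) out[i] <- upper[i]
      else bad <- c(bad, sprintf("%s = %.4g > %g", nm[i], out[i], upper[i]))
    }
  }
  if (length(bad)) {
    msg <- paste("state invariant violated:", paste(bad, collapse = "; "))
    if (action == "error") stop(msg, call. = FALSE)
    if (action == "warn") warning(msg, call. = FALSE)
  }
  names(out) <- nm
  out
}

#' Disease presets
#'
#' Initial conditions used throughout: `A0 = C0 = 0`, `r0 = 0.0827`, and a
#' baseline free TNF-alpha chosen so that the drug-free equilibrium matches
#' reported values in active disease: `L0 = 4.35e-11` M for Crohn's disease
#' (CD) and `L0 = 2.75e-11` M for ulcerative colitis (UC).
#'
#' @param preset `"CD"` or `"UC"`.
#' @param ... overrides passed to [ifx_params()].
#' @return List with elements `params` (an `ifx_params`) and `init`
#'   (an `ifx_state`).
#' @examples
#' ifx_preset("CD")$init
#' @export
ifx_preset <- function(preset = c("CD", "UC"), ...) {
  preset <- match.arg(preset)
  L0 <- switch(preset, CD = 4.35e-11, UC = 2.75e-11)
  list(preset = preset,
       params = ifx_params(...),
       init = ifx_state(L = L0, r = 0.0827, A = 0, C = 0))
}

#' Mass/volume conventions for unit conversion
#'
#' Molar masses and the reference distribution volume used to convert
#' clinical dose specifications (mg, mg/L) to molar units. The defaults
#' reproduce the reference correspondences exactly: a 350 mg dose infused
#' over 2 h gives an input rate of 3.3713e-10 M/s
#' (`0.35 / (7200 * 144190 * 1)`), and 2.6e-13 M TNF-alpha corresponds to
#' 4.42e-6 mg/L. Neither molar mass nor the volume is a measured quantity
#' here; they are interface conventions and can be overridden.
#'
#' @param ifx_molar_mass infliximab molar mass (g/mol).
#' @param tnf_molar_mass TNF-alpha molar mass (g/mol).
#' @param reference_volume distribution volume (L) over which a dose is
#'   diluted.
#' @return Object of class `ifx_conventions`.
#' @export
unit_conventions <- function(ifx_molar_mass = 144190,
                             tnf_molar_mass = 17000,
                             reference_volume = 1) {
  v <- list(ifx_molar_mass = ifx_molar_mass,
            tnf_molar_mass = tnf_molar_mass,
            reference_volume = reference_volume)
  for (nm in names(v)) {
    if (!is.numeric(v[[nm]]) || length(v[[nm]]) != 1L || !is.finite(v[[nm]]) ||
        v[[nm]] <= 0) {
      stop("convention '", nm, "' must be a single strictly positive number",
           call. = FALSE)
    }
  }
  structure(v, class = "ifx_conventions")
}

#' Clinical time units in seconds
#'
#' @param x numeric vector.
#' @return `x` converted to seconds.
#' @examples
#' weeks(4)   # a four-week dosing interval
#' hours(2)   # a standard infusion duration
#' @export
weeks <- function(x) x * 604800

#' @rdname weeks
#' @export
days <- function(x) x * 86400

#' @rdname weeks
#' @export
hours <- function(x) x * 3600
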