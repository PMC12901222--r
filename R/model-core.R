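#' Right-hand side of the dynamic-production model
#'
#' The four coupled ODEs for (`L`, `r`, `A`, `C`) with dynamic TNF-alpha
#' production: the production term equals the internalization, complex
#' clearance and (implicitly cancelled) direct clearance losses at steady
#' state, so the total TNF pool `L + R_tot*r + C` is conserved for any drug
#' input. The `L` derivative is evaluated as `-(R_tot*dr + dC)`, which is
#' algebraically identical to the expanded form and keeps the conservation
#' law exact to machine precision during integration.
#'
#' @param t time (s).
#' @param state model state, an [ifx_state()] or named numeric (L, r, A, C).
#' @param params an [ifx_params()].
#' @param drug_input_rate function of time giving the infliximab input rate
#'   (M/s); defaults to no input.
#' @return Named numeric vector of derivatives `(dL, dr, dA, dC)` in
#'   (M/s, 1/s, M/s, M/s).
#' @seealso [rhs_constant_production()], [rhs_reduced()], [conserved_total()]
#' @examples
#' pre <- ifx_preset("CD")
#' rhs_full(0, pre$init, pre$params)
#' @export
rhs_full <- function(t, state, params, drug_input_rate = function(t) 0) {
  w <- drug_input_rate(t)
  if (!is.finite(w) || w < 0) {
    stop("drug input rate must be finite and non-negative at t = ", t,
         call. = FALSE)
  }
  if (anyNA(state) || any(!is.finite(state))) {
    stop("non-finite model state: invalid integration state", call. = FALSE)
  }
  L <- state[[1]]; r <- state[[2]]; A <- state[[3]]; C <- state[[4]]
  dr <- params$k1 * (1 - r) * L - params$k_m1 * r - params$eps * r
  dC <- params$ka * L * A - params$k_ma * C - params$delta_c * C
  dL <- -(params$R_tot * dr + dC)
  dA <- w - params$ka * L * A + params$k_ma * C - params$delta_a * A
  c(dL = dL, dr = dr, dA = dA, dC = dC)
}

#' Right-hand side of the constant-production model
#'
#' The original variant in which TNF-alpha is produced at a fixed external
#' rate `omega1` and cleared at rate `delta1`. It differs from [rhs_full()]
#' only in the `L` equation: `omega1 - delta1*L` replaces the recycling terms
#' `eps*r*R_tot + delta_c*C`. The total TNF pool is not conserved here.
#'
#' @inheritParams rhs_full
#' @param omega1 constant TNF-alpha production rate (M/s).
#' @return Named derivative vector as in [rhs_full()].
#' @export
rhs_constant_production <- function(t, state, params, omega1,
                                    drug_input_rate = function(t) 0) {
  if (!is.numeric(omega1) || length(omega1) != 1L || !is.finite(omega1) ||
      omega1 < 0) {
    stop("omega1 must be a single non-negative number", call. = FALSE)
  }
  w <- drug_input_rate(t)
  if (!is.finite(w) || w < 0) {
    stop("drug input rate must be finite and non-negative at t = ", t,
         call. = FALSE)
  }
  if (anyNA(state) || any(!is.finite(state))) {
    stop("non-finite model state: invalid integration state", call. = FALSE)
  }
  L <- state[[1]]; r <- state[[2]]; A <- state[[3]]; C <- state[[4]]
  dL <- omega1 - params$k1 * params$R_tot * (1 - r) * L +
    params$k_m1 * params$R_tot * r - params$ka * L * A + params$k_ma * C -
    params$delta1 * L
  dr <- params$k1 * (1 - r) * L - params$k_m1 * r - params$eps * r
  dA <- w - params$ka * L * A + params$k_ma * C - params$delta_a * A
  dC <- params$ka * L * A - params$k_ma * C - params$delta_c * C
  c(dL = dL, dr = dr, dA = dA, dC = dC)
}

#' Right-hand side of the conservation-reduced model
#'
#' The three-equation system in (`r`, `A`, `C`) obtained by eliminating `L`
#' through the conservation law `L = P0 - R_tot*r - C`. Equivalent to
#' [rhs_full()] on the conserved manifold.
#'
#' @inheritParams rhs_full
#' @param reduced_state numeric vector `(r, A, C)`.
#' @param P0 conserved total TNF pool (M), see [conserved_total()].
#' @return Named derivative vector `(dr, dA, dC)`.
#' @export
rhs_reduced <- function(t, reduced_state, params, P0,
                        drug_input_rate = function(t) 0) {
  if (anyNA(reduced_state) || any(!is.finite(reduced_state))) {
    stop("non-finite model state: invalid integration state", call. = FALSE)
  }
  r <- reduced_state[[1]]; A <- reduced_state[[2]]; C <- reduced_state[[3]]
  L <- P0 - params$R_tot * r - C
  if (L < -1e-18) {
    stop(sprintf(
      "conservation violation: reconstructed L = %.4g M < 0 (P0 = %.4g M)",
      L, P0), call. = FALSE)
  }
  L <- max(L, 0)
  w <- drug_input_rate(t)
  if (!is.finite(w) || w < 0) {
    stop("drug input rate must be finite and non-negative at t = ", t,
         call. = FALSE)
  }
  dr <- params$k1 * (1 - r) * L - params$k_m1 * r - params$eps * r
  dA <- w - params$ka * L * A + params$k_ma * C - params$delta_a * A
  dC <- params$ka * L * A - params$k_ma * C - params$delta_c * C
  c(dr = dr, dA = dA, dC = dC)
}

#' Conserved total TNF pool
#'
#' Under the dynamic-production model, `L + R_tot*r + C` is constant in time
#' and equal to its initial value `P0`.
#'
#' @inheritParams rhs_full
#' @return `P0` in molar.
#' @examples
#' pre <- ifx_preset("CD")
#' conserved_total(pre$init, pre$params)  # 5.5905e-11 M
#' @export
conserved_total <- function(state, params) {
  unname(state[[1]] + params$R_tot * state[[2]] + state[[4]])
}

#' Closed-form drug-free equilibria
#'
#' With no drug (`A* = C* = 0`) the equilibria of the reduced system are the
#' roots of the quadratic `a*r^2 + b*r + c = 0` with `a = k1*R_tot`,
#' `b = -k1*(P0 + R_tot) - k_m1 - eps` and `c = k1*P0`, where
#' `P0 = L0 + R_tot*r0 + C0`. The TNF-alpha levels follow from conservation,
#' `L* = P0 - R_tot*r*`. The biologically admissible pair is the one with
#' `r*` in \[0, 1\] and `L*` in \[0, P0\]; for the default parameters this is
#' always the smaller root.
#'
#' @param params an [ifx_params()].
#' @param L0,r0,C0 initial free TNF-alpha (M), bound receptor proportion and
#'   complex concentration (M).
#' @return Object of class `ifx_equilibrium`: a list with the quadratic
#'   coefficients `a`, `b`, `c`, the roots `r1_star`, `r2_star`, the TNF
#'   levels `L1_star`, `L2_star`, `P0`, a logical vector `admissible` and
#'   `meaningful_root` (1 or 2, or `NA` if zero or both roots are
#'   admissible, in which case a warning is raised).
#' @examples
#' pre <- ifx_preset("CD")
#' eq <- drug_free_equilibria(pre$params, L0 = 4.35e-11, r0 = 0.0827)
#' eq$L2_star  # about 2.07e-11 M, the active-CD equilibrium
#' @export
drug_free_equilibria <- function(params, L0, r0, C0 = 0) {
  if (L0 < 0 || r0 < 0 || r0 > 1 || C0 < 0) {
    stop("require L0 >= 0, 0 <= r0 <= 1, C0 >= 0", call. = FALSE)
  }
  P0 <- L0 + params$R_tot * r0 + C0
  a <- params$k1 * params$R_tot
  b <- -params$k1 * (P0 + params$R_tot) - params$k_m1 - params$eps
  cc <- params$k1 * P0
  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    stop(sprintf("no real drug-free equilibrium: discriminant = %.4g < 0",
                 disc), call. = FALSE)
  }
  sq <- sqrt(disc)
  r1 <- (-b + sq) / (2 * a)
  r2 <- (-b - sq) / (2 * a)
  # L* from conservation; reduces to L0 + R_tot*(r0 - r*) when C0 = 0
  L1 <- P0 - params$R_tot * r1 - 0
  L2 <- P0 - params$R_tot * r2 - 0
  tol <- 1e-12 * max(1, P0)
  adm <- c(r1 >= -1e-12 && r1 <= 1 + 1e-12 && L1 >= -tol && L1 <= P0 + tol,
           r2 >= -1e-12 && r2 <= 1 + 1e-12 && L2 >= -tol && L2 <= P0 + tol)
  meaningful <- if (sum(adm) == 1L) which(adm) else NA_integer_
  if (is.na(meaningful)) {
    warning(sum(adm), " admissible equilibrium roots; caller must choose",
            call. = FALSE)
  }
  structure(list(a = a, b = b, c = cc,
                 r1_star = r1, r2_star = r2,
                 L1_star = L1, L2_star = L2,
                 P0 = P0, admissible = adm,
                 meaningful_root = meaningful),
            class = "ifx_equilibrium")
}

#' @export
print.ifx_equilibrium <- function(x, ...) {
  cat("Drug-free equilibria (A* = C* = 0):\n")
  cat(sprintf("  root 1: r* = %.6g, L* = %.6g M%s\n", x$r1_star, x$L1_star,
              if (isTRUE(x$meaningful_root == 1)) "  [admissible]" else ""))
  cat(sprintf("  root 2: r* = %.6g, L* = %.6g M%s\n", x$r2_star, x$L2_star,
              if (isTRUE(x$meaningful_root == 2)) "  [admissible]" else ""))
  cat(sprintf("  P0 = %.6g M\n", x$P0))
  invisible(x)
}

# The admissible (r*, L*) pair, as a list(r, L); NULL if ambiguous.
meaningful_equilibrium <- function(eq) {
  k <- eq$meaningful_root
  if (is.na(k)) return(NULL)
  if (k == 1L) list(r = eq$r1_star, L = eq$L1_star)
  else list(r = eq$r2_star, L = eq$L2_star)
}

#' Equilibrium bound receptor fraction at a given TNF-alpha level
#'
#' Setting the receptor equation to zero gives
#' `r = k1*L / (k1*L + k_m1 + eps)`, a saturating function of `L` bounded in
#' \[0, 1).
#'
#' @param L free TNF-alpha concentration (M), vectorized.
#' @param params an [ifx_params()].
#' @return Bound receptor proportion(s).
#' @export
equilibrium_bound_fraction <- function(L, params) {
  if (any(L < 0)) stop("L must be non-negative", call. = FALSE)
  params$k1 * L / (params$k1 * L + params$k_m1 + params$eps)
}

#' TNF-alpha production rate balancing a given equilibrium
#'
#' The steady-state calibration: the constant production rate that exactly
#' compensates the losses at the equilibrium,
#' `omega1 = eps*r*R_tot + delta_c*C + delta1*L`. Used to compare the
#' constant-production system against the dynamic-production one on an equal
#' footing.
#'
#' @param params an [ifx_params()].
#' @param L_eq,r_eq,C_eq equilibrium values of `L` (M), `r` and `C` (M).
#' @return `omega1` in M/s.
#' @examples
#' pre <- ifx_preset("CD")
#' eq <- drug_free_equilibria(pre$params, 4.35e-11, 0.0827)
#' production_rate_at_equilibrium(pre$params, eq$L2_star, eq$r2_star)
#' # 2.1315e-14 M/s
#' @export
production_rate_at_equilibrium <- function(params, L_eq, r_eq, C_eq = 0) {
  if (L_eq < 0 || r_eq < 0 || C_eq < 0) {
    stop("equilibrium inputs must be non-negative", call. = FALSE)
  }
  params$eps * r_eq * params$R_tot + params$delta_c * C_eq +
    params$delta1 * L_eq
}

#' A priori solution bounds
#'
#' The uniform bounds satisfied by every trajectory of the
#' dynamic-production system: `r <= 1`,
#' `A + C <= max(A0 + C0, omega_star/delta)` with
#' `delta = min(delta_a, delta_c)`, and `L <= P0`.
#'
#' @param init an [ifx_state()], the initial condition.
#' @param params an [ifx_params()].
#' @param omega_star maximal drug input rate over the run (M/s).
#' @return List with `r_max`, `AC_max` and `L_max`.
#' @export
theoretical_bounds <- function(init, params, omega_star) {
  if (omega_star < 0) stop("omega_star must be non-negative", call. = FALSE)
  delta <- min(params$delta_a, params$delta_c)
  list(r_max = 1,
       AC_max = max(init[[3]] + init[[4]], omega_star / delta),
       L_max = conserved_total(init, params))
}
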