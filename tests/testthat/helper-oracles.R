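# Shared fixtures and independent numerical oracles.

cd <- ifx_preset("CD")
uc <- ifx_preset("UC")

# Brute-force drug-free equilibrium on the A = C = 0 slice of the full
# system: nested 1-D root finds on the rhs components and the conserved
# total, independent of the closed-form quadratic.
brute_force_equilibrium <- function(params, L0, r0, C0 = 0) {
  P0 <- L0 + params$R_tot * r0 + C0
  rstar <- function(L) {
    if (L == 0) return(0)
    stats::uniroot(function(r) {
      rhs_full(0, c(L = L, r = r, A = 0, C = 0), params)[["dr"]]
    }, c(0, 1), tol = 1e-15)$root
  }
  if (P0 == 0) return(list(r = 0, L = 0))
  Lstar <- stats::uniroot(function(L) {
    L + params$R_tot * rstar(L) - P0
  }, c(0, P0), tol = 1e-16 * max(P0, 1e-12))$root
  list(r = rstar(Lstar), L = Lstar)
}

# Random parameter sets within the orders of magnitude of the literature
# estimates (log-uniform factor 1/3 .. 3 around each default).
random_params <- function() {
  jitter3 <- function(x) x * exp(stats::runif(1, log(1 / 3), log(3)))
  ifx_params(k1 = jitter3(1.7e7), k_m1 = jitter3(5.5e-4),
             R_tot = jitter3(1.5e-10), eps = jitter3(6e-4),
             delta1 = jitter3(1e-5), ka = jitter3(1e6),
             k_ma = jitter3(1e-4), delta_c = jitter3(8.5e-7),
             delta_a = 3.5e-6)
}

random_state <- function() {
  c(L = 10^stats::runif(1, -13, -10), r = stats::runif(1, 0, 0.9),
    A = 10^stats::runif(1, -12, -6), C = 10^stats::runif(1, -12, -7))
}

# Trajectory comparison relative to each component's scale on the run.
scale_relative_diff <- function(ts1, ts2) {
  stopifnot(length(ts1$times) == length(ts2$times))
  max(vapply(colnames(ts1$states), function(nm) {
    sc <- max(abs(ts1$states[, nm]))
    if (sc == 0) return(0)
    max(abs(ts1$states[, nm] - ts2$states[, nm])) / sc
  }, numeric(1)))
}

therapeutic_threshold_M <- mass_to_molar_conc(3, 144190)
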