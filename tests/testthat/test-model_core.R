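test_that("conserved total reproduces hand arithmetic for the presets", {
  expect_equal(conserved_total(cd$init, cd$params), 5.5905e-11,
               tolerance = 1e-12)
  expect_equal(conserved_total(uc$init, uc$params), 3.9905e-11,
               tolerance = 1e-12)
  expect_identical(conserved_total(c(L = 0, r = 0, A = 0, C = 0),
                                   cd$params), 0)
})

test_that("closed-form drug-free equilibria match the reported disease baselines", {
  eq_cd <- drug_free_equilibria(cd$params, 4.35e-11, 0.0827)
  expect_identical(eq_cd$meaningful_root, 2L)
  expect_lt(abs(eq_cd$L2_star - 2.07e-11), 0.005e-11)  # printed precision

  # With the printed UC baseline L0 = 2.75e-11 the closed form gives
  # 1.4073e-11, which the source rounds to its literature target 1.40e-11;
  # 1% tolerance covers that rounding of L0.
  eq_uc <- drug_free_equilibria(uc$params, 2.75e-11, 0.0827)
  expect_equal(eq_uc$L2_star, 1.40e-11, tolerance = 1e-2)

  # quadratic residual, both roots
  for (r in c(eq_cd$r1_star, eq_cd$r2_star)) {
    resid <- eq_cd$a * r^2 + eq_cd$b * r + eq_cd$c
    expect_lt(abs(resid) / abs(eq_cd$c), 1e-12)
  }

  # degenerate pool: P0 = 0 forces the zero equilibrium
  eq0 <- drug_free_equilibria(cd$params, 0, 0)
  me <- list(r = c(eq0$r1_star, eq0$r2_star)[eq0$meaningful_root],
             L = c(eq0$L1_star, eq0$L2_star)[eq0$meaningful_root])
  expect_equal(me$r, 0)
  expect_equal(me$L, 0)
})

test_that("the full system is stationary at the meaningful equilibrium", {
  eq <- drug_free_equilibria(cd$params, 4.35e-11, 0.0827)
  d <- rhs_full(0, c(L = eq$L2_star, r = eq$r2_star, A = 0, C = 0),
                cd$params)
  expect_lt(abs(d[["dL"]]), 1e-18)
  expect_lt(abs(d[["dr"]]), 1e-17)
  expect_identical(d[["dA"]], 0)
  expect_identical(d[["dC"]], 0)

  # empty system is trivially stationary
  expect_equal(unname(rhs_full(0, c(L = 0, r = 0, A = 0, C = 0), cd$params)),
               rep(0, 4))
})

test_that("the weighted derivative sum vanishes for any state and input", {
  set.seed(11)
  for (i in 1:100) {
    p <- random_params()
    s <- random_state()
    w <- stats::runif(1, 0, 1e-9)
    d <- rhs_full(0, s, p, function(t) w)
    expect_lt(abs(d[["dL"]] + p$R_tot * d[["dr"]] + d[["dC"]]), 1e-25)
  }
})

test_that("closed-form equilibria agree with a brute-force root find", {
  set.seed(7)
  for (i in 1:50) {
    p <- random_params()
    L0 <- 10^stats::runif(1, -11.5, -10)
    r0 <- stats::runif(1, 0.01, 0.5)
    eq <- drug_free_equilibria(p, L0, r0)
    expect_false(is.na(eq$meaningful_root))
    Lc <- c(eq$L1_star, eq$L2_star)[eq$meaningful_root]
    rc <- c(eq$r1_star, eq$r2_star)[eq$meaningful_root]
    bf <- brute_force_equilibrium(p, L0, r0)
    expect_equal(Lc, bf$L, tolerance = 1e-10)
    expect_equal(rc, bf$r, tolerance = 1e-10)
  }
})

test_that("constant-production variant reduces to the full system when calibrated", {
  eq <- drug_free_equilibria(cd$params, 4.35e-11, 0.0827)
  w1 <- production_rate_at_equilibrium(cd$params, eq$L2_star, eq$r2_star)
  s_eq <- c(L = eq$L2_star, r = eq$r2_star, A = 0, C = 0)
  d <- rhs_constant_production(0, s_eq, cd$params, w1)
  expect_true(all(abs(d) < 1e-17))

  # omega1 = 0: only loss terms survive in the L equation
  s <- c(L = 1e-11, r = 0, A = 0, C = 0)
  d0 <- rhs_constant_production(0, s, cd$params, 0)
  expect_equal(d0[["dL"]],
               -cd$params$k1 * cd$params$R_tot * 1e-11 -
                 cd$params$delta1 * 1e-11)

  # the two L-equations differ by omega1 - (eps*r*R_tot + delta_c*C + delta1*L)
  set.seed(3)
  for (i in 1:20) {
    s <- random_state()
    w1 <- stats::runif(1, 0, 1e-13)
    dcp <- rhs_constant_production(0, s, cd$params, w1)
    dfu <- rhs_full(0, s, cd$params)
    gap <- w1 - (cd$params$eps * s[["r"]] * cd$params$R_tot +
                   cd$params$delta_c * s[["C"]] +
                   cd$params$delta1 * s[["L"]])
    expect_equal(dcp[["dL"]] - dfu[["dL"]], gap, tolerance = 1e-10)
    expect_equal(dcp[c("dr", "dA", "dC")], dfu[c("dr", "dA", "dC")])
  }
})

test_that("reduced system equals the full system on the conserved manifold", {
  # the CD preset state: L reconstructs with no loss of precision
  s0 <- cd$init
  d3 <- rhs_reduced(0, c(s0[["r"]], s0[["A"]], s0[["C"]]), cd$params,
                    conserved_total(s0, cd$params))
  d4 <- rhs_full(0, s0, cd$params)
  expect_equal(unname(d3), unname(d4[c("dr", "dA", "dC")]),
               tolerance = 1e-15)

  # random admissible states; reconstructing L = P0 - R_tot*r - C loses
  # relative precision when C dominates the pool, so C is kept comparable
  # to L here and the tolerance reflects the conditioning
  set.seed(5)
  for (i in 1:20) {
    p <- random_params()
    s <- c(L = 10^stats::runif(1, -12, -10), r = stats::runif(1, 0, 0.9),
           A = 10^stats::runif(1, -12, -6), C = 10^stats::runif(1, -13, -11))
    P0 <- conserved_total(s, p)
    d3 <- rhs_reduced(0, c(s[["r"]], s[["A"]], s[["C"]]), p, P0)
    d4 <- rhs_full(0, s, p)
    expect_equal(unname(d3), unname(d4[c("dr", "dA", "dC")]),
                 tolerance = 1e-12)
  }

  # all mass in the complex: L reconstructs to 0, pure complex decay
  p <- cd$params
  P0 <- 1e-10
  d <- rhs_reduced(0, c(0, 1e-8, P0), p, P0)
  expect_equal(d[["dC"]], -(p$k_ma + p$delta_c) * P0)

  # zero pool
  expect_equal(unname(rhs_reduced(0, c(0, 0, 0), p, 0)), rep(0, 3))

  # conservation violation is an error
  expect_error(rhs_reduced(0, c(0.5, 0, 1e-10), p, P0 = 1e-12),
               "conservation")
})

test_that("production-rate calibration matches the reported value", {
  eq <- drug_free_equilibria(cd$params, 4.35e-11, 0.0827)
  w1 <- production_rate_at_equilibrium(cd$params, eq$L2_star, eq$r2_star)
  expect_lt(abs(w1 - 2.1315e-14), 5e-19)  # printed precision
  expect_identical(production_rate_at_equilibrium(cd$params, 0, 0, 0), 0)

  eq_uc <- drug_free_equilibria(uc$params, 2.75e-11, 0.0827)
  w1_uc <- production_rate_at_equilibrium(uc$params, eq_uc$L2_star,
                                          eq_uc$r2_star)
  expect_equal(w1_uc, 1.565e-14, tolerance = 2e-3)
})

test_that("equilibrium bound fraction is a saturating function of TNF-alpha", {
  expect_identical(equilibrium_bound_fraction(0, cd$params), 0)
  eq <- drug_free_equilibria(cd$params, 4.35e-11, 0.0827)
  r <- equilibrium_bound_fraction(eq$L2_star, cd$params)
  expect_lt(abs(r - 0.2345), 1e-4)
  expect_equal(r, eq$r2_star, tolerance = 1e-12)  # self-consistency

  L <- 10^seq(-14, -2, length.out = 50)
  rr <- equilibrium_bound_fraction(L, cd$params)
  expect_true(all(diff(rr) > 0))
  expect_true(all(rr >= 0 & rr < 1))
  expect_gt(equilibrium_bound_fraction(1, cd$params), 0.99999)
})

test_that("a priori bounds follow the clearance-limited formula", {
  z <- ifx_state(0, 0, 0, 0)
  expect_identical(theoretical_bounds(z, cd$params, 0)$AC_max, 0)
  b <- theoretical_bounds(z, cd$params, 3.3713e-10)
  expect_equal(b$AC_max, 3.3713e-10 / 8.5e-7, tolerance = 1e-12)
  expect_equal(b$AC_max, 3.966e-4, tolerance = 1e-4)
  expect_identical(b$r_max, 1)
  expect_equal(theoretical_bounds(cd$init, cd$params, 0)$L_max,
               5.5905e-11, tolerance = 1e-12)
})

test_that("parameter and state validation enforce the domain invariants", {
  expect_error(ifx_params(k1 = -1), "strictly positive")
  expect_error(ifx_params(delta_c = 0), "strictly positive")
  expect_warning(ifx_params(delta_a = 1e-5), "outside the plausible range")
  expect_silent(ifx_params(delta_a = 2e-6))
  expect_error(ifx_state(-1e-12, 0.5), "invariant")
  expect_error(ifx_state(1e-11, 1.5), "invariant")
  expect_error(rhs_full(0, c(NaN, 0, 0, 0), cd$params), "non-finite")
  expect_error(rhs_full(0, c(1e-11, 0, 0, 0), cd$params,
                        function(t) -1), "non-negative")
})
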