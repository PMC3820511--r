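# WKB action, quasi-stationary distributions, click rates, scaling form.

test_that("action is minimal at the fixed point and convex around it", {
  tc <- twoclass_params(300, 0.03, 0.1)
  xs <- x_star(tc)
  expect_lt(abs(wkb_action_deriv(tc, xs)), 1e-12)
  expect_equal(wkb_action(tc, xs), 0)
  # strictly decreasing below x*, strictly increasing above
  grid_lo <- seq(0.01, xs - 0.01, length.out = 50)
  grid_hi <- seq(xs + 0.01, 1, length.out = 50)
  expect_true(all(diff(wkb_action(tc, grid_lo)) < 0))
  expect_true(all(diff(wkb_action(tc, grid_hi)) > 0))
  # curvature formula at the fixed point
  expect_equal(wkb_action_curvature(tc, xs),
               tc$s_eff^2 / (tc$u * (1 - tc$u)), tolerance = 1e-12)
})

test_that("closed-form action matches adaptive quadrature of ln(T-/T+)", {
  for (par in list(c(0.03, 0.1), c(0.06, 0.12), c(0.1, 0.5))) {
    tc <- twoclass_params(100, par[1], par[2])
    for (x in seq(0.02, 1, length.out = 25)) {
      quad <- stats::integrate(function(z) wkb_action_deriv(tc, z),
                               x_star(tc), x, rel.tol = 1e-12,
                               abs.tol = 1e-13)$value
      expect_lt(abs(wkb_action(tc, x) - quad), 1e-10)
    }
  }
})

test_that("WKB QSDs agree with the eigen-oracle and improve with the prefactor", {
  tc <- twoclass_params(300, 0.03, 0.1)
  eig <- qsd_eigen(build_rates(tc))$qsd
  qp <- wkb_qsd(tc, "prefactor")
  ql <- wkb_qsd(tc, "leading")
  expect_equal(sum(qp$mass), 1, tolerance = 1e-12)
  # leading-order peak sits at the fixed point
  expect_equal(ql$n[which.max(ql$mass)], round(300 * x_star(tc)))
  # prefactor-corrected QSD is very close to the dominant eigenvector
  expect_lt(tv_distance(qp, eig), 0.05)
  # ... and strictly closer than the Gaussian-normalized leading order
  expect_lt(tv_distance(qp, eig), tv_distance(ql, eig))
})

test_that("WKB click time converges to the exact solution at large N", {
  ratios <- vapply(c(100, 200, 400), function(N) {
    tc <- twoclass_params(N, 0.03, 0.1)
    w <- suppressWarnings(wkb_mte(tc))
    ex <- exact_mfpt(build_rates(tc))
    c(w$mte / ex, abs(w$log_mte - log(ex)) / log(ex),
      w$rate_leading * ex)
  }, numeric(3))
  # relative log-error shrinks with N (1/N-accurate MTE)
  expect_true(all(diff(ratios[2, ]) < 0))
  expect_lt(ratios[2, 2], 0.01)   # N = 200 already within 1% in log
  # MTE ratio approaches 1 from below as 1/N corrections die out
  expect_true(all(diff(ratios[1, ]) > 0))
  # the exponential-accuracy-only leading rate drifts away from the truth
  expect_true(all(diff(ratios[3, ]) < 0))
  expect_lt(ratios[3, 3], ratios[3, 1])
})

test_that("simplified click time is the small-s limit of the full form", {
  # small s_eff at large N*s: nearly indistinguishable from the full WKB form
  tc <- twoclass_params(6000, 0.0015, 0.005)
  ws <- wkb_mte_simplified(tc)
  expect_lt(abs(ws$deviation_vs_full), 0.05)
  # outside the small-s regime the simplification is visibly off, even at
  # N * s_eff above the large-N*s threshold
  ws2 <- wkb_mte_simplified(twoclass_params(100, 0.03, 0.1))
  expect_gt(abs(ws2$deviation_vs_full), 0.05)
  expect_warning(wkb_mte_simplified(twoclass_params(20, 0.03, 0.1)),
                 "threshold")

  # 1/s_eff is a pure timescale at fixed (N s, lambda0)
  a <- wkb_mte_simplified(twoclass_params(2000, 0.003, 0.01))
  b <- wkb_mte_simplified(twoclass_params(4000, 0.0015, 0.005))
  expect_equal(b$mte / a$mte, 2, tolerance = 1e-12)
})

test_that("scaling decomposition reconstructs the click time exactly", {
  tc <- twoclass_params(3000, 0.003, 0.01)
  sf <- scaling_form(tc)
  ws <- wkb_mte_simplified(tc)
  expect_equal(sf$prefactor * exp(sf$exponent), ws$mte, tolerance = 1e-14)
  expect_equal(sf$haigh_factor, haigh_factor(lambda_twoclass(tc)))

  # the analytic Haigh factor decreases in lambda0 and tends to 1 as
  # lambda0 -> 0 (compare the historical ad hoc constants ~0.5-0.6)
  grid <- seq(0.01, 0.6, length.out = 20)
  expect_true(all(diff(haigh_factor(grid)) < 0))
  expect_equal(haigh_factor(1e-9), 1, tolerance = 1e-6)
  expect_gt(haigh_factor(0.2), 0.4)
  expect_lt(haigh_factor(0.2), 0.6)
})

test_that("WKB computations are deterministic and carry validity flags", {
  tc <- twoclass_params(250, 0.02, 0.08)
  expect_identical(wkb_mte(tc), wkb_mte(tc))
  expect_identical(wkb_qsd(tc)$mass, wkb_qsd(tc)$mass)
  fl <- wkb_validity(tc)
  expect_true(all(c("x_star", "N_s", "N_s_xstar", "barrier", "ok") %in%
                    names(fl)))
  expect_true(fl$ok)
  # near-critical parameters: flagged, warned, but still computed
  tc_bad <- twoclass_params(250, 0.07, 0.08)
  expect_false(wkb_validity(tc_bad)$ok)
  expect_warning(w <- wkb_mte(tc_bad), "regime")
  expect_true(is.finite(w$mte))
  # no metastable state at all: hard error
  expect_error(wkb_mte(twoclass_params(100, 0.2, 0.1)), "metastable")
})
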