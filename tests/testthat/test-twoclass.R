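# The reduced two-class birth-death chain: rates, exact click time,
# Monte Carlo, eigen-solution, master equation.

test_that("transition rates match the model's verbal construction", {
  r <- build_rates(twoclass_params(2, u = 0.1, s_eff = 0.5))
  # n = 1: birth weight 1 vs 0.5, no mutation (0.9), mutated death (1/2)
  expect_equal(r$t_plus[2], (1 / 1.5) * 0.9 * 0.5)
  expect_equal(r$t_minus[2], ((0.5 + 0.1) / 1.5) * 0.5)
  # absorbing and upper boundaries
  expect_equal(r$t_plus[1], 0)
  expect_equal(r$t_minus[1], 0)
  expect_equal(r$t_plus[r$N + 1], 0)

  rr <- build_rates(twoclass_params(150, 0.04, 0.2))
  expect_true(all(rr$t_plus >= 0 & rr$t_minus >= 0))
  expect_true(all(rr$t_plus + rr$t_minus <= 1))

  expect_error(build_rates(structure(list(N = 10L, u = 0.1, s_eff = 1.5),
                                     class = "twoclass_params")))
})

test_that("up and down rates balance once, at the deterministic fixed point", {
  for (l0 in c(0.15, 0.4)) {
    tc <- twoclass_params(200, l0 * 0.2, 0.2)
    r <- build_rates(tc)
    d <- (r$t_plus - r$t_minus)[2:200]  # n = 1..N-1
    # single up-to-down crossing: all positive below, all non-positive above
    pos <- which(d > 0)
    expect_equal(pos, seq_len(length(pos)))  # contiguous from n = 1
    expect_true(all(d[(max(pos) + 1):length(d)] <= 0))
    expect_lt(abs(max(pos) - 200 * x_star(tc)), 1 + 1e-9)
  }
})

test_that("exact mean click time agrees with its oracles", {
  # N = 1: geometric waiting time, MFPT = 1/u steps = 1/u generations
  r1 <- build_rates(twoclass_params(1, 0.05, 0.3))
  expect_equal(as.numeric(exact_mfpt(r1, 1)), 1 / 0.05, tolerance = 1e-12)

  # product formula vs tridiagonal first-step solve
  for (N in c(50, 120)) for (l0 in c(0.1, 0.5)) {
    r <- build_rates(twoclass_params(N, l0 * 0.15, 0.15))
    expect_equal(as.numeric(exact_mfpt(r)), mfpt_linsolve(r),
                 tolerance = 1e-11)
  }

  # fully independent dense LU route (accuracy limited by its conditioning)
  rr <- build_rates(twoclass_params(80, 0.03, 0.1))
  N <- 80
  tp <- rr$t_plus[-1]; tm <- rr$t_minus[-1]
  A <- matrix(0, N, N)
  for (n in 1:N) {
    A[n, n] <- tp[n] + tm[n]
    if (n < N) A[n, n + 1] <- -tp[n]
    if (n > 1) A[n, n - 1] <- -tm[n]
  }
  dense <- solve(A, rep(1, N))[round(N * 0.7)] / N
  expect_equal(as.numeric(exact_mfpt(rr, round(N * 0.7))), dense,
               tolerance = 1e-8)

  # monotone in the starting occupancy
  mf <- vapply(c(5, 20, 40, 80), function(n0) exact_mfpt(rr, n0), 0)
  expect_true(all(diff(mf) > 0))

  # u = 0 makes n = N absorbing too: absorption unreachable from above
  expect_equal(as.numeric(exact_mfpt(build_rates(twoclass_params(30, 0, 0.2)))),
               Inf)
})

test_that("Monte Carlo click times match the exact solution", {
  tc <- twoclass_params(60, 0.012, 0.12)
  ex <- exact_mfpt(build_rates(tc))
  mc <- mc_click_times(tc, reps = 1500, seed = 7)
  s <- summary(mc)
  expect_equal(s$n_censored, 0)
  expect_lt(abs(s$mean - ex), 3 * s$se)

  # determinism under the seed
  mc2 <- mc_click_times(tc, reps = 1500, seed = 7)
  expect_identical(mc$time, mc2$time)

  # jump-chain and per-step implementations agree in distribution
  tc50 <- twoclass_params(50, 0.02, 0.1)
  mj <- summary(mc_click_times(tc50, reps = 1200, seed = 3, method = "jump"))
  ms <- summary(mc_click_times(tc50, reps = 1200, seed = 4, method = "step"))
  expect_lt(abs(mj$mean - ms$mean), 3 * sqrt(mj$se^2 + ms$se^2))
})

test_that("eigen-solution yields the QSD and the decay rate", {
  tc <- twoclass_params(200, 0.03, 0.1)
  r <- build_rates(tc)
  e <- qsd_eigen(r)
  expect_equal(sum(e$qsd$mass), 1, tolerance = 1e-12)
  expect_true(all(e$qsd$mass >= 0))
  # metastable peak at the deterministic fixed point, within a small
  # fraction of the QSD width (finite-N prefactor shifts the mode slightly)
  qsd_sd <- sqrt(200 * tc$u * (1 - tc$u) / tc$s_eff^2)
  expect_lt(abs(e$qsd$n[which.max(e$qsd$mass)] - 200 * x_star(tc)),
            0.3 * qsd_sd)
  # decay rate equals the probability flux into the absorbing state
  expect_lt(e$flux_rel_error, 1e-6)
  # rate ~ 1/MFPT in the rare-clicking regime
  expect_lt(abs(e$rate * exact_mfpt(r) - 1), 0.01)
})

test_that("master equation conserves probability and decays at the eigen rate", {
  tc <- twoclass_params(40, 0.03, 0.15)
  r <- build_rates(tc)
  p <- master_evolve(r, round(40 * x_star(tc)), 200000)
  expect_lt(abs(sum(p) - 1), 1e-10)

  # survival decay over t in [2, 5] MTE matches the dominant eigenvalue
  e <- qsd_eigen(r)
  rate_fit <- survival_decay_rate(r)
  expect_lt(abs(rate_fit / e$rate - 1), 0.02)
})
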