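# Parameter types, the Haigh steady state, and the two-class mapping.

test_that("haigh_steady_state reproduces the Poisson balance", {
  # no mutation: all mass in the mutation-free class
  p0 <- haigh_steady_state(0, k_max = 5)
  expect_equal(as.numeric(p0), c(1, 0, 0, 0, 0, 0))
  expect_equal(attr(p0, "tail_mass"), 0)

  # closed form of the zero-class mass
  expect_equal(haigh_steady_state(1)[1], exp(-1), tolerance = 1e-12)

  # masses are non-negative and sum to 1 minus the reported tail
  p <- haigh_steady_state(3.7, k_max = 25)
  expect_true(all(p >= 0))
  expect_equal(sum(p) + attr(p, "tail_mass"), 1, tolerance = 1e-12)

  expect_error(haigh_steady_state(-1), "lam")
})

test_that("Poisson profile is the fixed point of the deterministic recursion", {
  # independent oracle: iterate selection + Poisson mutation directly
  U <- 0.2; s <- 0.1; k_max <- 50
  freq <- rep(1 / (k_max + 1), k_max + 1)
  for (i in 1:5000) {
    w <- freq * (1 - s)^(0:k_max)
    w <- w / sum(w)
    nxt <- numeric(k_max + 1)
    for (j in 0:k_max)
      nxt[j + (0:(k_max - j)) + 1] <- nxt[j + (0:(k_max - j)) + 1] +
        w[j + 1] * dpois(0:(k_max - j), U)
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - freq)) < 1e-15) break
    freq <- nxt
  }
  expect_lt(max(abs(freq - haigh_steady_state(U / s, k_max))), 1e-10)
})

test_that("map_parameters satisfies both fitness-matching conditions", {
  tc <- map_parameters(full_params(100, U = 0.1, s = 0.2))
  # frozen values from the closed-form solution of the matching conditions
  expect_equal(tc$u, 1 - exp(-0.1), tolerance = 1e-12)
  expect_equal(tc$u, 0.0951626, tolerance = 1e-6)
  expect_equal(tc$s_eff, (1 - exp(-0.1)) / (1 - exp(-0.5)), tolerance = 1e-12)
  expect_equal(lambda_twoclass(tc), 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(x_star(tc), exp(-0.5), tolerance = 1e-12)

  # verify each matching condition numerically, independently of the solver:
  # population mean fitness and mutated-class mean fitness agree across models
  for (g in list(c(0.1, 0.2), c(0.05, 0.05), c(0.3, 0.4))) {
    U <- g[1]; s <- g[2]; lam <- U / s
    tc <- map_parameters(full_params(1000, U, s))
    pik <- dpois(0:400, lam)
    wbar_full <- sum(pik * (1 - s)^(0:400))
    expect_equal(1 - tc$u, wbar_full, tolerance = 1e-12)
    wmut_full <- sum(pik[-1] * (1 - s)^(1:400)) / (1 - pik[1])
    expect_equal(1 - tc$s_eff, wmut_full, tolerance = 1e-12)
  }
})

test_that("mapping identities hold across the parameter plane", {
  set.seed(11)
  for (i in 1:25) {
    U <- runif(1, 0.001, 0.5)
    s <- runif(1, 0.02, 0.6)
    full <- full_params(500, U, s)
    tc <- suppressWarnings(map_parameters(full))
    # consequence of the matching conditions: lambda0 = 1 - exp(-lambda)
    # exactly (compared without the cancellation-prone 1 - x form)
    expect_equal(tc$u / tc$s_eff, -expm1(-U / s), tolerance = 1e-13)
    # u < s_eff always: lambda0 = 1 - exp(-lambda) < 1 for every lambda > 0
    expect_lt(lambda_twoclass(tc), 1)
    expect_gt(tc$s_eff, tc$u)
  }
})

test_that("mapping limits and conventions behave", {
  # U -> 0: classes decouple, u -> 0, s_eff -> s, x* -> 1
  tc <- map_parameters(full_params(100, U = 1e-12, s = 0.2))
  expect_equal(tc$u, 1e-12, tolerance = 1e-6)
  expect_equal(tc$s_eff, 0.2, tolerance = 1e-9)
  expect_equal(x_star(tc), 1, tolerance = 1e-9)

  # linear convention keeps u = U
  tl <- map_parameters(full_params(100, 0.1, 0.2), u_convention = "linear")
  expect_equal(tl$u, 0.1)

  # mapping is N-free except for the validity warning
  t1 <- map_parameters(full_params(50, 0.1, 0.2))
  t2 <- map_parameters(full_params(5000, 0.1, 0.2))
  expect_equal(t1$u, t2$u)
  expect_equal(t1$s_eff, t2$s_eff)
  expect_warning(map_parameters(full_params(20, 0.8, 0.2)),
                 "outside its regime")
})

test_that("parameter validation rejects nonsense", {
  expect_error(full_params(0, 0.1, 0.1), "N")
  expect_error(full_params(10, -0.1, 0.1), "U")
  expect_error(full_params(10, 0.1, 1.2), "s")
  expect_error(twoclass_params(10, 1.2, 0.5), "u")
  expect_error(twoclass_params(10, 0.1, 0), "s_eff")
})
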