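# Full multi-class Moran simulator: conservation, neutral limits, clicks,
# equilibrium occupancy, determinism.

test_that("population size is conserved and monomorphic states are absorbing", {
  set.seed(1)
  st <- population_state(c(37L, 41L, 22L, 0L, 0L))
  p <- full_params(100, 0.08, 0.1)
  for (i in 1:50) {
    st <- moran_step(st, p)
    expect_equal(sum(st$counts), 100)
  }
  # U = 0, all mass in class 0: births and deaths both hit class 0
  p0 <- full_params(50, 0, 0.1)
  st0 <- population_state(c(50L, 0L, 0L))
  for (i in 1:20) st0 <- moran_step(st0, p0)
  expect_equal(st0$counts, c(50L, 0L, 0L))
})

test_that("with s = 0, U = 0 class 0 fixes with probability n/N", {
  # neutral Moran fixation probability, exact by symmetry / martingale
  set.seed(42)
  N <- 6L; n <- 2L
  reps <- 4000
  fixed <- logical(reps)
  for (r in seq_len(reps)) {
    res <- ratchetr:::cpp_moran_until_boundary(c(n, N - n), 0, 1e-12, 1e6)
    fixed[r] <- res$fixed
  }
  p_hat <- mean(fixed)
  se <- sqrt((n / N) * (1 - n / N) / reps)
  expect_lt(abs(p_hat - n / N), 3 * se)
})

test_that("U = 0 never clicks: censored timeout at the budget", {
  p <- full_params(40, 0, 0.1)
  ct <- run_until_clicks(p, n_clicks = 1, seed = 3, max_gens = 50)
  expect_true(ct$censored[1])
  expect_equal(ct$time[1], 50, tolerance = 1e-9)
})

test_that("same seed reproduces click times exactly", {
  p <- full_params(80, 0.1, 0.1)
  a <- moran_click_times(p, 5, seed = 99)
  b <- moran_click_times(p, 5, seed = 99)
  expect_identical(a$time, b$time)
  # successive clicks from one trajectory expose inter-click intervals
  rc <- run_until_clicks(p, n_clicks = 4, seed = 99)
  expect_equal(length(attr(rc, "intervals")), sum(!rc$censored))
  expect_true(all(rc$time > 0))
  expect_true(all(diff(rc$time) > 0))
})

test_that("time-averaged fittest-class occupancy sits at the Haigh mean", {
  # rare-clicking point: occupancy fluctuates around N exp(-lambda)
  p <- full_params(200, 0.05, 0.1)
  m <- moran_click_times(p, 3, seed = 11, max_gens = 1500, track_n0 = TRUE)
  n0_bar <- mean(attr(m, "mean_n0"))
  expect_lt(abs(n0_bar - 200 * exp(-0.5)) / (200 * exp(-0.5)), 0.05)
})

test_that("bernoulli mutation convention preserves the class-0 loss rate", {
  # same per-birth probability of leaving the fittest class, so click times
  # agree with the poisson convention within sampling error (fast regime)
  p <- full_params(60, 0.1, 0.05)
  a <- summary(moran_click_times(p, 300, seed = 5))
  b <- summary(moran_click_times(p, 300, seed = 6,
                                 mutation_model = "bernoulli"))
  expect_lt(abs(a$mean - b$mean), 3 * sqrt(a$se^2 + b$se^2))
})

test_that("mean inter-click interval is seed-invariant within sampling error", {
  p <- full_params(100, 0.05, 0.05)  # lambda = 1, fast-clicking
  r1 <- run_until_clicks(p, n_clicks = 400, seed = 21)
  r2 <- run_until_clicks(p, n_clicks = 400, seed = 22)
  i1 <- attr(r1, "intervals"); i2 <- attr(r2, "intervals")
  m1 <- mean(i1); m2 <- mean(i2)
  ci <- 2.58 * sqrt(var(i1) / length(i1) + var(i2) / length(i2))
  expect_lt(abs(m1 - m2), ci)
})

test_that("fittest-class histogram is a normalized QSD estimate", {
  p <- full_params(100, 0.05, 0.15)
  h <- sample_fittest_histogram(p, replicates = 400, sample_fraction = 0.05,
                                seed = 2)
  expect_s3_class(h, "qsd_table")
  expect_equal(sum(h$mass), 1, tolerance = 1e-12)
  expect_true(all(h$mass >= 0))

  # vanishing sampling time: mass concentrated at the rounded Haigh mean
  h0 <- sample_fittest_histogram(p, replicates = 150,
                                 sample_fraction = 1e-5, seed = 2)
  expect_lt(abs(h0$n[which.max(h0$mass)] - round(100 * exp(-1 / 3))), 2)

  # fast-clicking regime with a late sampling time: too many clicked
  pf <- full_params(50, 0.2, 0.05)
  expect_error(
    sample_fittest_histogram(pf, replicates = 100, sample_fraction = 0.9,
                             seed = 2,
                             mean_click_time = 2000),
    "sample_fraction")
})
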