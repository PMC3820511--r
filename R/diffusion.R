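# Mesoscopic diffusion limit: frequencies x_k of the mutation classes follow
#   dx_k = [ s (kbar - k) x_k + U (x_{k-1} - x_k) ] dt + sqrt(2 x_k / N) dW_k
# with independent Gaussian white noise per class modeling genetic drift.
# Time is measured in Moran generations, hence the drift-variance 2 x_k / N:
# with this convention the SDE at population size N matches the Moran model
# at N and the Wright-Fisher model at N/2. The deterministic skeleton has the
# Poisson(lambda) profile as its unique attracting fixed point.

# Smaller default window than the microscopic simulators: the integration
# cost is proportional to the window size, and the deterministic profile
# keeps the occupied classes within a few standard deviations of lambda.
sde_window <- function(lam) max(ceiling(6 * lam + 12), 15)

sde_default_dt <- function(params, K) {
  0.01 / max(params$s * K, params$U, 1)
}

#' Drift field of the class-frequency SDE
#'
#' Selection against the class mean plus mutation flux from class `k - 1`
#' into class `k`; this is the deterministic skeleton of the diffusion
#' limit. It vanishes identically on the Poisson(`U/s`) profile.
#'
#' @param x Numeric vector of class frequencies over classes `0..(K-1)`.
#' @param params A [full_params()] object.
#' @return Vector of time derivatives (per generation) of each frequency.
#' @export
sde_drift <- function(x, params) {
  stopifnot(inherits(params, "full_params"), is.numeric(x))
  K <- length(x)
  k <- 0:(K - 1)
  kbar <- sum(k * x)
  params$s * (kbar - k) * x + params$U * (c(0, x[-K]) - x)
}

#' Integrate the class-frequency SDE without click bookkeeping
#'
#' Euler-Maruyama integration over a fixed horizon; with
#' `noise_factor = 0` this is a deterministic ODE solve of the
#' mutation-selection dynamics (used by the steady-state tests).
#'
#' @param x0 Initial frequency vector (normalized internally).
#' @param params A [full_params()] object.
#' @param t_end Integration horizon (generations).
#' @param dt Step size (generations); default `0.01 / max(s K, U, 1)`.
#' @param noise_factor Multiplier on the genetic-drift noise amplitude;
#'   `1` for the full SDE, `0` for the deterministic skeleton.
#' @return Frequency vector at `t_end` (clamped to the simplex).
#' @export
sde_integrate <- function(x0, params, t_end, dt = NULL, noise_factor = 1) {
  stopifnot(inherits(params, "full_params"))
  x0 <- x0 / sum(x0)
  if (is.null(dt)) dt <- sde_default_dt(params, length(x0))
  res <- cpp_sde_sim(x0, params$N, params$U, params$s, dt, 0L, t_end,
                     noise_factor)
  res$x
}

#' First-click times of the diffusion (SDE) model
#'
#' Independent replicates of the Euler-Maruyama integration of the
#' class-frequency SDE, started at the Haigh equilibrium profile. A click is
#' declared when the fittest-class frequency falls below the absorption
#' threshold `1/(2N)` (half an individual, the natural microscopic
#' resolution); the window then re-indexes to the next occupied class.
#' Frequencies are clamped at zero and renormalized after each step; the
#' step size is halved automatically if a pre-clamp frequency undershoots
#' `-10 sqrt(2 dt / N)`.
#'
#' @inheritParams moran_click_times
#' @param dt Step size in generations; default `0.01 / max(s K, U, 1)`.
#' @return A `click_time_sample` (model tag `"diffusion"`) with the step
#'   size recorded in the `"dt"` attribute.
#' @export
sde_click_times <- function(params, replicates, dt = NULL, seed = NULL,
                            max_gens = 1e6) {
  stopifnot(inherits(params, "full_params"), replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  lam <- lambda_full(params)
  K <- sde_window(lam)
  if (is.null(dt)) dt <- sde_default_dt(params, K)
  x0 <- stats::dpois(0:(K - 1), lam)
  x0 <- x0 / sum(x0)
  times <- numeric(replicates)
  censored <- logical(replicates)
  dt_final <- dt
  for (r in seq_len(replicates)) {
    res <- cpp_sde_sim(x0, params$N, params$U, params$s, dt, 1L, max_gens, 1)
    censored[r] <- res$censored
    times[r] <- if (res$censored) res$t_done else res$click_gens[1]
    dt_final <- res$dt_final
  }
  out <- new_click_time_sample(times, censored, "diffusion", params, seed)
  attr(out, "dt") <- dt_final
  out
}
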