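#' Parameters of the full multi-class ratchet
#'
#' Bundles the three parameters that define Muller's ratchet in its standard
#' multiplicative form: population size `N`, genomic deleterious mutation rate
#' `U` (per genome per generation) and selection coefficient `s` per mutation,
#' so that an individual carrying `k` mutations has fitness `(1 - s)^k`.
#' The rescaled mutation rate `lambda = U/s` is always recomputed from `U`
#' and `s` (see [lambda_full()]), never stored, so it cannot drift out of
#' sync with its parents.
#'
#' @param N Population size (single positive integer).
#' @param U Deleterious mutation rate per genome per generation (`>= 0`).
#' @param s Selection coefficient per mutation, in `(0, 1)`.
#' @return An object of class `full_params`.
#' @examples
#' p <- full_params(N = 200, U = 0.05, s = 0.1)
#' lambda_full(p) # 0.5
#' @seealso [map_parameters()], [haigh_steady_state()]
#' @export
full_params <- function(N, U, s) {
  stopifnot(length(N) == 1L, length(U) == 1L, length(s) == 1L)
  if (!is.finite(N) || N < 1 || N != round(N))
    stop("`N` must be a positive integer")
  if (!is.finite(U) || U < 0) stop("`U` must be >= 0")
  if (!is.finite(s) || s <= 0 || s >= 1) stop("`s` must lie in (0, 1)")
  structure(list(N = as.integer(N), U = U, s = s), class = "full_params")
}

#' Rescaled mutation rate of the full model
#'
#' @param params A [full_params()] object.
#' @return `lambda = U/s`, the ratio of mutation rate to selection
#'   coefficient. `N * exp(-lambda)` is the equilibrium size of the fittest
#'   class.
#' @export
lambda_full <- function(params) {
  stopifnot(inherits(params, "full_params"))
  params$U / params$s
}

#' @export
print.full_params <- function(x, ...) {
  cat(sprintf("Full ratchet parameters: N = %d, U = %g, s = %g (lambda = %g, N e^-lambda = %.2f)\n",
              x$N, x$U, x$s, lambda_full(x), x$N * exp(-lambda_full(x))))
  invisible(x)
}

#' Effective parameters of the reduced two-class model
#'
#' Constructs the parameter set of the one-dimensional two-class Moran chain:
#' the fittest (mutation-free) class competes against a single merged class of
#' all mutated individuals with effective fitness `1 - s_eff`; `u` is the
#' effective mutation rate out of the fittest class. The derived quantities
#' `lambda0 = u/s_eff` and the deterministic equilibrium frequency
#' `x_star = 1 - lambda0` of the fittest class are recomputed on demand via
#' [lambda_twoclass()] and [x_star()].
#'
#' A metastable (non-zero) equilibrium of the fittest class requires
#' `u < s_eff`; construction succeeds outside that regime (the chain is still
#' well defined) but downstream WKB routines will refuse or warn.
#'
#' @param N Population size (single positive integer).
#' @param u Effective mutation rate out of the fittest class, in `[0, 1)`.
#' @param s_eff Effective selection disadvantage of the mutated class, in
#'   `(0, 1)`.
#' @return An object of class `twoclass_params`.
#' @examples
#' tc <- twoclass_params(N = 300, u = 0.03, s_eff = 0.1)
#' x_star(tc) # 0.7
#' @export
twoclass_params <- function(N, u, s_eff) {
  stopifnot(length(N) == 1L, length(u) == 1L, length(s_eff) == 1L)
  if (!is.finite(N) || N < 1 || N != round(N))
    stop("`N` must be a positive integer")
  if (!is.finite(u) || u < 0 || u >= 1) stop("`u` must lie in [0, 1)")
  if (!is.finite(s_eff) || s_eff <= 0 || s_eff >= 1)
    stop("`s_eff` must lie in (0, 1)")
  structure(list(N = as.integer(N), u = u, s_eff = s_eff),
            class = "twoclass_params")
}

#' Rescaled mutation rate of the two-class model
#' @param params A [twoclass_params()] object.
#' @return `lambda0 = u / s_eff`.
#' @export
lambda_twoclass <- function(params) {
  stopifnot(inherits(params, "twoclass_params"))
  params$u / params$s_eff
}

#' Deterministic equilibrium frequency of the fittest class
#' @param params A [twoclass_params()] object.
#' @return `x_star = 1 - u/s_eff`, the frequency at which the up- and
#'   down-transition rates of the two-class chain balance. Non-positive when
#'   `u >= s_eff` (no metastable state).
#' @export
x_star <- function(params) {
  1 - lambda_twoclass(params)
}

#' @export
print.twoclass_params <- function(x, ...) {
  cat(sprintf("Two-class parameters: N = %d, u = %g, s_eff = %g (lambda0 = %g, x* = %g)\n",
              x$N, x$u, x$s_eff, lambda_twoclass(x), x_star(x)))
  invisible(x)
}

#' Haigh's infinite-population mutation-selection balance
#'
#' In the deterministic (infinite `N`) limit, the per-class frequencies of the
#' ratchet settle into a Poisson profile with mean `lambda = U/s`:
#' `pi_k = exp(-lambda) lambda^k / k!`. This is the fixed point of the
#' mutation-selection recursion (see [haigh_recursion_step()]) and the
#' reference profile for all equilibrium-based checks in the package.
#'
#' @param lam Rescaled mutation rate `lambda >= 0`.
#' @param k_max Largest mutation class returned. Default
#'   `ceiling(10 * (lam + 1) + 20)`, beyond which the Poisson tail is
#'   negligible for all `lambda` of interest.
#' @return Numeric vector of length `k_max + 1` with the masses of classes
#'   `0..k_max`; the (tiny) probability beyond `k_max` is reported in the
#'   `tail_mass` attribute, so `sum(pi) == 1 - tail_mass`.
#' @examples
#' haigh_steady_state(1)[1] # exp(-1)
#' @export
haigh_steady_state <- function(lam, k_max = NULL) {
  stopifnot(length(lam) == 1L)
  if (!is.finite(lam) || lam < 0) stop("`lam` must be >= 0")
  if (is.null(k_max)) k_max <- ceiling(10 * (lam + 1) + 20)
  if (k_max < 0 || k_max != round(k_max)) stop("`k_max` must be >= 0")
  pi_k <- stats::dpois(0:k_max, lam)
  structure(pi_k, tail_mass = stats::ppois(k_max, lam, lower.tail = FALSE))
}

#' One step of the deterministic mutation-selection recursion
#'
#' The infinite-population limit of the Wright-Fisher ratchet: frequencies are
#' reweighted by fitness `(1 - s)^k` and then convolved with a Poisson(`U`)
#' number of new mutations. Iterating from any profile converges to the
#' Poisson(`U/s`) balance of [haigh_steady_state()]; this function is the
#' deterministic skeleton used by the steady-state tests and by
#' [wf_step()]'s expectation.
#'
#' @param freq Numeric vector of class frequencies over classes `0..(K-1)`
#'   (need not be normalized; it is renormalized internally).
#' @param params A [full_params()] object.
#' @return Next-generation frequency vector of the same length; mutation mass
#'   that would leave the truncated window is folded into the last class.
#' @export
haigh_recursion_step <- function(freq, params) {
  stopifnot(inherits(params, "full_params"), is.numeric(freq))
  K <- length(freq)
  w <- freq * (1 - params$s)^(0:(K - 1))
  w <- w / sum(w)
  pois <- stats::dpois(0:(K - 1), params$U)
  out <- numeric(K)
  for (j in seq_len(K)) {
    mmax <- K - j  # mutations that stay inside the window
    if (mmax > 0)
      out[j:(K - 1)] <- out[j:(K - 1)] + w[j] * pois[1:mmax]
    out[K] <- out[K] + w[j] * (1 - if (mmax > 0) sum(pois[1:mmax]) else 0)
  }
  out / sum(out)
}

#' Map full-ratchet parameters onto the two-class model
#'
#' Derives the effective parameters `(u, s_eff)` of the reduced two-class
#' chain from `(N, U, s)` by matching the infinite-population equilibria of
#' the two models:
#' \enumerate{
#'   \item the mean fitness of the whole population is equal in both models,
#'   \item the mean fitness of all mutation-carrying individuals is equal in
#'     both models.
#' }
#' With the Poisson mutation convention (a reproducing individual acquires a
#' Poisson(`U`) number of new mutations, so the probability of leaving the
#' fittest class is `1 - exp(-U)`), the full model's equilibrium mean fitness
#' is `exp(-U)` and the two conditions give
#' \deqn{u = 1 - e^{-U}, \qquad s_{eff} = \frac{1 - e^{-U}}{1 - e^{-\lambda}},}
#' hence `lambda0 = u/s_eff = 1 - exp(-lambda)` and
#' `x_star = exp(-lambda)`: the equilibrium fittest-class size
#' `N * exp(-lambda)` agrees with Haigh's steady state exactly, and the
#' mutation rates out of the fittest class coincide in both models. Note
#' `lambda0 < 1` for every `lambda`, so the mapped chain always satisfies the
#' `u < s_eff` requirement of the metastable regime.
#'
#' `u_convention = "linear"` instead takes `u = U` (at most one mutation per
#' reproduction); it is provided for sensitivity analysis only and keeps
#' condition 2, so `s_eff = U / (1 - exp(-lambda))` and
#' `x_star = 1 - lambda0` deviates from `exp(-lambda)` at order `U^2`.
#'
#' @param full A [full_params()] object.
#' @param u_convention `"poisson_total"` (default) or `"linear"`, see Details.
#' @return A [twoclass_params()] object. If the mapped equilibrium fittest
#'   class holds fewer than one individual (`N * exp(-lambda) < 1`) a warning
#'   flags that the two-class approximation is outside its validity regime.
#' @examples
#' tc <- map_parameters(full_params(100, U = 0.1, s = 0.2))
#' c(tc$u, tc$s_eff, lambda_twoclass(tc))
#' @export
map_parameters <- function(full, u_convention = c("poisson_total", "linear")) {
  stopifnot(inherits(full, "full_params"))
  u_convention <- match.arg(u_convention)
  lam <- lambda_full(full)
  u <- switch(u_convention, poisson_total = -expm1(-full$U), linear = full$U)
  if (lam == 0) {
    # no mutation: classes decouple, the fittest class keeps disadvantage s
    s_eff <- full$s
  } else {
    s_eff <- u / (-expm1(-lam))
  }
  if (full$N * exp(-lam) < 1)
    warning(sprintf(
      "two-class approximation outside its regime: N e^-lambda = %.3g < 1",
      full$N * exp(-lam)), call. = FALSE)
  out <- twoclass_params(full$N, u = u, s_eff = s_eff)
  out$u_convention <- u_convention
  out
}

#' Equilibrium mean fitness of the full ratchet
#'
#' Population mean fitness at Haigh's mutation-selection balance,
#' `sum_k pi_k (1-s)^k = exp(-U)`; exposed for the round-trip consistency
#' checks of the parameter mapping.
#'
#' @param params A [full_params()] object.
#' @return `exp(-U)`.
#' @keywords internal
#' @export
mean_fitness_full <- function(params) {
  stopifnot(inherits(params, "full_params"))
  exp(-params$U)
}

#' Equilibrium mean fitness of the two-class model
#'
#' `x* + (1 - x*)(1 - s_eff) = 1 - u` at the deterministic equilibrium.
#'
#' @param params A [twoclass_params()] object.
#' @return `1 - u`.
#' @keywords internal
#' @export
mean_fitness_twoclass <- function(params) {
  stopifnot(inherits(params, "twoclass_params"))
  1 - params$u
}
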