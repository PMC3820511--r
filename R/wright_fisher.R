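#' One Wright-Fisher generation of the ratchet
#'
#' Replaces the whole generation by a single multinomial draw of `N`
#' offspring whose class probabilities are the fitness-weighted parent
#' frequencies convolved with a Poisson(`U`) number of new mutations — the
#' classical non-overlapping-generations formulation of Haigh. The
#' expectation of one step equals the deterministic recursion
#' [haigh_recursion_step()].
#'
#' @param state A [population_state()].
#' @param params A [full_params()] object.
#' @return The updated [population_state()] (`t_steps` counts generations
#'   here). Mutation mass beyond the class window is folded into the last
#'   class, as in the Moran simulator.
#' @export
wf_step <- function(state, params) {
  stopifnot(inherits(state, "population_state"), inherits(params, "full_params"))
  cnt <- cpp_wf_gens(state$counts, params$U, params$s, 1L)
  population_state(cnt, state$k_min, state$t_steps + 1)
}

#' First-click times of the Wright-Fisher ratchet
#'
#' Independent replicates, each started at the rounded Haigh equilibrium
#' profile and run until the least-loaded class is first lost. One
#' Wright-Fisher step is one generation. In the diffusion limit the
#' Wright-Fisher model has twice the genetic-drift variance of the Moran
#' model at equal `N`, so click times of `wf_click_times()` at population
#' size `floor(N/2)` are comparable with [moran_click_times()] at `N` (see
#' [run_comparison()]).
#'
#' @inheritParams moran_click_times
#' @return A `click_time_sample` (model tag `"wright_fisher"`).
#' @export
wf_click_times <- function(params, replicates, seed = NULL,
                           init = "haigh_equilibrium", max_gens = 1e6) {
  stopifnot(inherits(params, "full_params"), replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  K <- class_window(lambda_full(params))
  counts <- resolve_init(params, init, K)
  times <- numeric(replicates)
  censored <- logical(replicates)
  for (r in seq_len(replicates)) {
    res <- cpp_wf_sim(counts, params$U, params$s, 1L, max_gens)
    censored[r] <- res$censored
    times[r] <- if (res$censored) res$gens_done else res$click_gens[1]
  }
  new_click_time_sample(times, censored, "wright_fisher", params, seed)
}

#' Successive Wright-Fisher click times of one trajectory
#'
#' @inheritParams run_until_clicks
#' @return A `click_time_sample` with cumulative click times and an
#'   `"intervals"` attribute, as in [run_until_clicks()].
#' @export
wf_run_until_clicks <- function(params, n_clicks, seed = NULL,
                                init = "haigh_equilibrium", max_gens = 1e6) {
  stopifnot(inherits(params, "full_params"), n_clicks >= 1)
  if (!is.null(seed)) set.seed(seed)
  K <- class_window(lambda_full(params))
  counts <- resolve_init(params, init, K)
  res <- cpp_wf_sim(counts, params$U, params$s, as.integer(n_clicks), max_gens)
  times <- res$click_gens
  censored <- logical(length(times))
  if (res$censored) {
    times <- c(times, res$gens_done)
    censored <- c(censored, TRUE)
  }
  new_click_time_sample(times, censored, "wright_fisher", params, seed,
                        intervals = diff(c(0, times[!censored])))
}
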