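#' Population state of the multi-class ratchet
#'
#' Integer counts per mutation class inside a sliding window of `K` classes;
#' `counts[1]` is the current least-loaded (fittest) class, carrying
#' `k_min` mutations in absolute terms.
#'
#' @param counts Integer vector of per-class counts (sums to the population
#'   size).
#' @param k_min Absolute mutation count of the first window class.
#' @param t_steps Elapsed Moran steps.
#' @return An object of class `population_state`.
#' @export
population_state <- function(counts, k_min = 0L, t_steps = 0) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("class counts must be non-negative")
  if (sum(counts) < 1) stop("population is empty")
  structure(list(counts = counts, k_min = as.integer(k_min),
                 t_steps = t_steps), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state: N = %d over %d classes (k_min = %d, t = %s steps)\n",
              sum(x$counts), length(x$counts), x$k_min,
              format(x$t_steps, big.mark = ",")))
  invisible(x)
}

# Number of classes kept above the least-loaded one.
class_window <- function(lam) max(ceiling(10 * lam + 20), 40)

# Deterministic largest-remainder rounding of N * p so counts sum to N.
largest_remainder <- function(N, p) {
  p <- p / sum(p)
  raw <- N * p
  cnt <- floor(raw)
  short <- N - sum(cnt)
  if (short > 0) {
    idx <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[idx] <- cnt[idx] + 1
  }
  as.integer(cnt)
}

# Initial class counts: Haigh equilibrium profile rounded to N individuals.
haigh_counts <- function(params, K = NULL) {
  lam <- lambda_full(params)
  if (is.null(K)) K <- class_window(lam)
  largest_remainder(params$N, stats::dpois(0:(K - 1), lam))
}

resolve_init <- function(params, init, K) {
  if (is.character(init)) {
    init <- match.arg(init, "haigh_equilibrium")
    return(haigh_counts(params, K))
  }
  counts <- as.integer(init)
  if (sum(counts) != params$N) stop("custom init counts must sum to N")
  if (length(counts) < K) counts <- c(counts, integer(K - length(counts)))
  counts
}

#' One step of the full Moran ratchet
#'
#' Applies a single overlapping-generation update: one individual is chosen
#' to reproduce with probability proportional to its class fitness
#' `(1 - s)^k`, its offspring acquires a Poisson(`U`) number of new
#' mutations, and one individual chosen uniformly (possibly the reproducer)
#' dies. The population size is conserved exactly.
#'
#' @param state A [population_state()].
#' @param params A [full_params()] object.
#' @return The updated [population_state()] (`t_steps` advanced by one).
#'   Mutations falling beyond the class window are folded into the last
#'   class. Uses R's RNG; seed with [set.seed()].
#' @export
moran_step <- function(state, params) {
  stopifnot(inherits(state, "population_state"), inherits(params, "full_params"))
  cnt <- cpp_moran_steps(state$counts, params$U, params$s, 1)
  population_state(cnt, state$k_min, state$t_steps + 1)
}

new_click_time_sample <- function(times, censored, model, params, seed,
                                  intervals = NULL) {
  out <- data.frame(replicate = seq_along(times), time = times,
                    censored = censored)
  structure(out, class = c("click_time_sample", "data.frame"),
            model = model, params = params, seed = seed, intervals = intervals)
}

#' @export
print.click_time_sample <- function(x, ...) {
  ok <- !x$censored
  cat(sprintf("Click times [%s]: %d replicates (%d censored)\n",
              attr(x, "model"), nrow(x), sum(x$censored)))
  if (any(ok))
    cat(sprintf("  mean = %.4g generations (SE %.3g)\n",
                mean(x$time[ok]), stats::sd(x$time[ok]) / sqrt(sum(ok))))
  invisible(x)
}

#' Summary statistics of a click-time sample
#' @param object A `click_time_sample`.
#' @param ... Unused.
#' @return List with `mean`, `se`, `n`, `n_censored` (censored replicates are
#'   excluded from the mean; their times are lower bounds).
#' @export
summary.click_time_sample <- function(object, ...) {
  ok <- !object$censored
  list(mean = mean(object$time[ok]),
       se = stats::sd(object$time[ok]) / sqrt(sum(ok)),
       n = sum(ok), n_censored = sum(object$censored))
}

#' Successive click times of one full-Moran trajectory
#'
#' Runs a single trajectory of the full multi-class Moran ratchet until
#' `n_clicks` clicks have occurred (a click: the least-loaded class is lost;
#' the class window then re-indexes to the new least-loaded class). Times are
#' in generations (1 generation = `N` Moran steps), measured from `t = 0`.
#'
#' @param params A [full_params()] object.
#' @param n_clicks Number of clicks to collect.
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param init `"haigh_equilibrium"` (default: Haigh profile rounded to `N`
#'   individuals, the equilibrium initial condition) or an integer count
#'   vector summing to `N`.
#' @param max_gens Step budget in generations. If exhausted before
#'   `n_clicks` clicks, the result is censored at the budget (no error), so
#'   rare-click regimes degrade gracefully.
#' @param mutation_model `"poisson"` (default; a reproducing individual
#'   acquires a Poisson(`U`) number of new mutations, the Haigh convention)
#'   or `"bernoulli"` (at most one new mutation, with the same per-birth
#'   probability `1 - exp(-U)` of leaving the parent class; provided for
#'   sensitivity analysis).
#' @return A `click_time_sample` with the cumulative click times; the
#'   `"intervals"` attribute holds inter-click intervals.
#' @examples
#' run_until_clicks(full_params(100, 0.1, 0.05), n_clicks = 3, seed = 1)
#' @export
run_until_clicks <- function(params, n_clicks, seed = NULL,
                             init = "haigh_equilibrium", max_gens = 1e6,
                             mutation_model = c("poisson", "bernoulli")) {
  stopifnot(inherits(params, "full_params"), n_clicks >= 1)
  mutation_model <- match.arg(mutation_model)
  if (!is.null(seed)) set.seed(seed)
  K <- class_window(lambda_full(params))
  counts <- resolve_init(params, init, K)
  res <- cpp_moran_sim(counts, params$U, params$s, as.integer(n_clicks),
                       max_gens * params$N, FALSE,
                       mutation_model == "bernoulli")
  times <- res$click_steps / params$N
  censored <- logical(length(times))
  if (res$censored) {  # pad with the censored budget time
    times <- c(times, res$steps_done / params$N)
    censored <- c(censored, TRUE)
  }
  new_click_time_sample(times, censored, "moran", params, seed,
                        intervals = diff(c(0, times[!censored])))
}

#' First-click times over independent replicates of the full Moran ratchet
#'
#' Each replicate starts from the (rounded) Haigh equilibrium profile and
#' runs until the first click; this matches the initial condition of the
#' analytic mean-first-passage computations and is the sampling scheme used
#' by all cross-model comparisons.
#'
#' @inheritParams run_until_clicks
#' @param replicates Number of independent replicates.
#' @param track_n0 If `TRUE`, also record the time-averaged occupancy of the
#'   fittest class per replicate (attribute `"mean_n0"`).
#' @return A `click_time_sample` (model tag `"moran"`).
#' @export
moran_click_times <- function(params, replicates, seed = NULL,
                              init = "haigh_equilibrium", max_gens = 1e6,
                              track_n0 = FALSE,
                              mutation_model = c("poisson", "bernoulli")) {
  stopifnot(inherits(params, "full_params"), replicates >= 1)
  mutation_model <- match.arg(mutation_model)
  if (!is.null(seed)) set.seed(seed)
  K <- class_window(lambda_full(params))
  counts <- resolve_init(params, init, K)
  times <- numeric(replicates)
  censored <- logical(replicates)
  mean_n0 <- if (track_n0) numeric(replicates) else NULL
  for (r in seq_len(replicates)) {
    res <- cpp_moran_sim(counts, params$U, params$s, 1L,
                         max_gens * params$N, track_n0,
                         mutation_model == "bernoulli")
    censored[r] <- res$censored
    times[r] <- (if (res$censored) res$steps_done else res$click_steps[1]) /
      params$N
    if (track_n0) mean_n0[r] <- res$mean_n0
  }
  out <- new_click_time_sample(times, censored, "moran", params, seed)
  attr(out, "mean_n0") <- mean_n0
  out
}

#' Sampled occupancy distribution of the fittest class
#'
#' Estimates the quasi-stationary distribution (QSD) of the least-loaded
#' class of the full ratchet: each replicate starts at the Haigh equilibrium
#' profile and the fittest-class count `n0` is recorded at
#' `sample_fraction * T`, where `T` is the (estimated) mean click time. At
#' the default fraction 0.1 the occupancy has relaxed to the metastable
#' state while almost no replicate has clicked yet. Replicates that click
#' before the sampling time are excluded (their number is reported).
#'
#' @inheritParams moran_click_times
#' @param sample_fraction Fraction of the mean click time at which to sample,
#'   in `(0, 1)`.
#' @param mean_click_time Optional externally supplied mean click time
#'   (generations). Default: the exact mean first-passage time of the mapped
#'   two-class chain ([exact_mfpt()]), which is accurate in the rare-click
#'   regime where this sampling scheme makes sense.
#' @return A `qsd_table` over `n = 1..N` (source `"simulation"`), with
#'   attributes `n_clicked` (excluded replicates) and `sample_time`.
#'   Errors if more than half the replicates clicked before the sampling
#'   time (`sample_fraction` too large for the regime).
#' @export
sample_fittest_histogram <- function(params, replicates, sample_fraction = 0.1,
                                     seed = NULL, mean_click_time = NULL) {
  stopifnot(inherits(params, "full_params"), replicates >= 100)
  if (sample_fraction <= 0 || sample_fraction >= 1)
    stop("`sample_fraction` must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mean_click_time))
    mean_click_time <- exact_mfpt(build_rates(map_parameters(params)))
  t_steps <- sample_fraction * mean_click_time * params$N
  K <- class_window(lambda_full(params))
  counts <- haigh_counts(params, K)
  n0 <- integer(replicates)
  clicked <- logical(replicates)
  for (r in seq_len(replicates)) {
    res <- cpp_moran_sample_n0(counts, params$U, params$s, t_steps)
    n0[r] <- res$n0
    clicked[r] <- res$clicked
  }
  if (mean(clicked) > 0.5)
    stop(sprintf(
      "%.0f%% of replicates clicked before the sampling time; `sample_fraction` too large for this regime",
      100 * mean(clicked)))
  mass <- tabulate(n0[!clicked], nbins = params$N)
  mass <- mass / sum(mass)
  qsd_table(mass, source = "simulation", params = params,
            n_clicked = sum(clicked),
            sample_time = sample_fraction * mean_click_time)
}
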