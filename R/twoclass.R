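# The reduced two-class Moran chain: n individuals in the fittest
# (mutation-free) class vs N - n mutated individuals with relative fitness
# 1 - s_eff. Per Moran step, with fitness-weighted birth, probability u of
# the offspring mutating, and uniform death:
#
#   t+(n) = [ n / (n + (1-s)(N-n)) ] (1-u) (N-n)/N
#   t-(n) = [ ((1-s)(N-n) + u n) / (n + (1-s)(N-n)) ] n/N
#
# n = 0 is absorbing (a ratchet click); t+(N) = 0 when the population is
# monomorphic only via mutation pressure (offspring of the fittest class can
# still mutate, which is the u n term in t-).

#' Transition rates of the two-class Moran chain
#'
#' Per-step probabilities of the fittest-class count increasing
#' (`t_plus`) or decreasing (`t_minus`) by one, for `n = 0..N`. An increase
#' requires a fittest-class birth (weight `n` against `(1-s_eff)(N-n)`), an
#' unmutated offspring (probability `1-u`) and a death in the mutated class;
#' a decrease requires a death in the fittest class together with either a
#' mutated-class birth or a fittest-class birth whose offspring mutates.
#' The boundary conditions `t_plus[0] = t_minus[0] = 0` (absorbing click
#' state) and `t_plus[N] = 0` hold by construction.
#'
#' @param params A [twoclass_params()] object.
#' @return An object of class `transition_rates`: list with `t_plus` and
#'   `t_minus` (numeric vectors indexed by `n = 0..N`), `N`, and `params`.
#' @examples
#' r <- build_rates(twoclass_params(N = 2, u = 0.1, s_eff = 0.5))
#' r$t_plus[2] # n = 1: 0.3
#' @export
build_rates <- function(params) {
  stopifnot(inherits(params, "twoclass_params"))
  N <- params$N
  u <- params$u
  s <- params$s_eff
  if (!is.finite(s) || s <= 0 || s >= 1) stop("`s_eff` must lie in (0, 1)")
  if (!is.finite(u) || u < 0 || u >= 1) stop("`u` must lie in [0, 1)")
  n <- 0:N
  w <- n + (1 - s) * (N - n)  # total fitness weight
  t_plus <- n / w * (1 - u) * (N - n) / N
  t_minus <- ((1 - s) * (N - n) + u * n) / w * n / N
  t_plus[1] <- 0
  t_minus[1] <- 0
  structure(list(t_plus = t_plus, t_minus = t_minus, N = N, params = params),
            class = "transition_rates")
}

#' @export
print.transition_rates <- function(x, ...) {
  cat(sprintf("Two-class transition rates, n = 0..%d ", x$N))
  print(x$params)
  invisible(x)
}

# log-sum-exp, guarding empty and all -Inf inputs
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

default_n0 <- function(params) {
  n0 <- round(params$N * x_star(params))
  max(1L, min(params$N, as.integer(n0)))
}

#' Exact mean click time of the two-class chain
#'
#' Closed-form mean first-passage time from `n0` to the absorbing state
#' `n = 0` of the birth-death chain, as a nested sum of products of the
#' transition-rate ratios:
#' \deqn{T(n_0) = \sum_{k=1}^{n_0} \sum_{m=k}^{N} \frac{1}{t^-_m}
#'       \prod_{j=k}^{m-1} \frac{t^+_j}{t^-_j}}
#' (in Moran steps; divided by `N` for generations). All products and sums
#' are accumulated in the log domain, so the result is finite-precision-safe
#' even when the click time is astronomically large; the `"log_generations"`
#' attribute carries `log(T)` even when `T` itself overflows.
#'
#' @param rates A [build_rates()] object.
#' @param n0 Initial fittest-class count; default `round(N * x_star)`, the
#'   deterministic equilibrium.
#' @return Mean click time in generations (scalar), with attribute
#'   `"log_generations"`. `Inf` (with a message attribute) if absorption is
#'   unreachable from some occupied state (e.g. `u = 0`).
#' @seealso [mfpt_linsolve()] for the independent linear-system route,
#'   [mc_click_times()] for Monte Carlo.
#' @export
exact_mfpt <- function(rates, n0 = NULL) {
  stopifnot(inherits(rates, "transition_rates"))
  N <- rates$N
  if (is.null(n0)) n0 <- default_n0(rates$params)
  stopifnot(n0 >= 1, n0 <= N)
  tp <- rates$t_plus[2:(N + 1)]   # n = 1..N
  tm <- rates$t_minus[2:(N + 1)]
  if (any(tm == 0))
    return(structure(Inf, log_generations = Inf,
                     message = "absorption unreachable: t_minus vanishes at an occupied state"))
  # C[i] = sum_{j<=i} log(t+_j / t-_j); product over j = k..m-1 of the rate
  # ratios is exp(C[m-1] - C[k-1]).
  lr <- log(tp) - log(tm)
  C <- c(0, cumsum(lr[-N]))  # C[1] = C(0) = 0 ... C[N] = C(N-1)
  a <- C - log(tm)           # a_m = C(m-1) - log t-_m, m = 1..N
  # suffix log-sum-exp: L[k] = log sum_{m >= k} exp(a_m)
  L <- numeric(N)
  L[N] <- a[N]
  if (N > 1) for (k in (N - 1):1) L[k] <- {
    m <- max(L[k + 1], a[k])
    m + log(exp(L[k + 1] - m) + exp(a[k] - m))
  }
  log_steps <- logsumexp(L[1:n0] - C[1:n0])
  log_gens <- log_steps - log(N)
  structure(exp(log_gens), log_generations = log_gens)
}

#' Mean click time via the first-step linear system
#'
#' Independent cross-check of [exact_mfpt()]: solves the first-step
#' equations `T(n) = 1 + t_plus T(n+1) + t_minus T(n-1) +
#' (1 - t_plus - t_minus) T(n)` with `T(0) = 0` and a reflecting upper
#' boundary, i.e. the tridiagonal linear system over the transient states
#' `1..N`, by Gaussian elimination from the reflecting boundary (Thomas
#' algorithm). The system matrix is a weakly diagonally dominant M-matrix,
#' so the elimination needs no pivoting and every intermediate quantity is
#' a sum of positive terms — the solve is accurate to close to machine
#' precision even when the click time is astronomically large.
#'
#' @inheritParams exact_mfpt
#' @return Mean click time in generations.
#' @export
mfpt_linsolve <- function(rates, n0 = NULL) {
  stopifnot(inherits(rates, "transition_rates"))
  N <- rates$N
  if (is.null(n0)) n0 <- default_n0(rates$params)
  tp <- rates$t_plus[2:(N + 1)]
  tm <- rates$t_minus[2:(N + 1)]
  if (any(tm == 0)) return(Inf)
  # Eliminate from the reflecting boundary: T(n) = e[n] + f[n] T(n-1) with
  # f[n] = tm[n] / (tm[n] + tp[n] g[n+1]) and g[n] = 1 - f[n] tracked
  # directly — the naive update tp + tm - tp * f cancels catastrophically
  # because the reflecting boundary forces f -> 1.
  e <- g <- numeric(N + 1)
  e[N + 1] <- 0
  g[N + 1] <- 1  # "f[N+1] = 0"
  for (n in N:1) {
    denom <- tm[n] + tp[n] * g[n + 1]
    e[n] <- (1 + tp[n] * e[n + 1]) / denom
    g[n] <- tp[n] * g[n + 1] / denom
  }
  # back-substitute from T(0) = 0
  Tn <- 0
  for (n in 1:n0) Tn <- e[n] + (1 - g[n]) * Tn
  Tn / N
}

#' Monte Carlo click times of the two-class chain
#'
#' Simulates independent absorption times of the birth-death chain. The
#' default `method = "jump"` samples geometric holding times on the embedded
#' jump chain, which is equivalent in distribution to stepping the lazy
#' chain one Moran step at a time (`method = "step"`, kept for validation).
#'
#' @param params A [twoclass_params()] object.
#' @param n0 Initial count; default `round(N * x_star)`.
#' @param reps Number of replicates.
#' @param seed Optional integer seed.
#' @param method `"jump"` (default) or `"step"`.
#' @param max_gens Budget per replicate in generations; exhausted budgets
#'   are reported as censored.
#' @return A `click_time_sample` (model tag `"twoclass_mc"`).
#' @export
mc_click_times <- function(params, n0 = NULL, reps = 1000, seed = NULL,
                           method = c("jump", "step"), max_gens = 1e8) {
  stopifnot(inherits(params, "twoclass_params"), reps >= 1)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n0)) n0 <- default_n0(params)
  rates <- build_rates(params)
  res <- cpp_twoclass_mc(rates$t_plus, rates$t_minus, as.integer(n0),
                         as.integer(reps), max_gens * params$N,
                         method == "jump")
  new_click_time_sample(res$steps / params$N, res$censored, "twoclass_mc",
                        params, seed)
}

#' Quasi-stationary distribution table
#'
#' Probability mass of the fittest-class occupancy `n = 1..N` conditioned on
#' non-extinction, tagged with its provenance.
#'
#' @param mass Numeric vector of masses over `n = 1..N` (normalized
#'   internally).
#' @param source One of `"wkb_leading"`, `"wkb_prefactor"`, `"eigen"`,
#'   `"simulation"`.
#' @param params The generating parameter object.
#' @param ... Further attributes to attach.
#' @return A `qsd_table`: data.frame with columns `n`, `x = n/N`, `mass`.
#' @export
qsd_table <- function(mass, source, params = NULL, ...) {
  stopifnot(all(mass >= 0), sum(mass) > 0)
  N <- length(mass)
  out <- data.frame(n = 1:N, x = (1:N) / N, mass = mass / sum(mass))
  extra <- list(...)
  out <- structure(out, class = c("qsd_table", "data.frame"),
                   source = source, params = params)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
print.qsd_table <- function(x, ...) {
  cat(sprintf("QSD over n = 1..%d [%s]; mode at n = %d, mean = %.2f\n",
              nrow(x), attr(x, "source"), x$n[which.max(x$mass)],
              sum(x$n * x$mass)))
  invisible(x)
}

#' Total-variation distance between two QSD tables
#'
#' @param p,q `qsd_table`s (or bare mass vectors) on the same support
#'   `1..N`.
#' @return `0.5 * sum(|p - q|)`, in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  pm <- if (inherits(p, "qsd_table")) p$mass else p / sum(p)
  qm <- if (inherits(q, "qsd_table")) q$mass else q / sum(q)
  stopifnot(length(pm) == length(qm))
  0.5 * sum(abs(pm - qm))
}

#' Eigen-solution of the quasi-stationary distribution and decay rate
#'
#' The sub-stochastic transition operator of the chain restricted to the
#' transient states `1..N` has a dominant (Perron) eigenvalue `rho < 1`;
#' the associated left eigenvector, normalized to unit mass, is the
#' quasi-stationary distribution, and the ratchet rate is the survival decay
#' rate `(1 - rho) * N` per generation. The tridiagonal operator is
#' symmetrized by an explicit diagonal similarity (in the log domain, so the
#' transform never overflows) and solved with a dense symmetric
#' eigendecomposition. The flux identity — the decay rate equals the
#' probability flux `N * t_minus[1] * qsd[1]` into the absorbing state — is
#' evaluated and stored as a consistency diagnostic.
#'
#' @param rates A [build_rates()] object; `N` capped at 5000.
#' @return List with `rate` (clicks per generation), `mte` (`1/rate`),
#'   `qsd` (a [qsd_table()], source `"eigen"`), `eigenvalue`, and
#'   `flux_rel_error` (relative difference between eigenvalue- and
#'   flux-based rates).
#' @export
qsd_eigen <- function(rates) {
  stopifnot(inherits(rates, "transition_rates"))
  N <- rates$N
  if (N > 5000) stop("dense eigensolver capped at N = 5000")
  tp <- rates$t_plus[2:(N + 1)]
  tm <- rates$t_minus[2:(N + 1)]
  # similarity diag: log d_{n+1} = log d_n + (log t+_n - log t-_{n+1}) / 2
  logd <- c(0, cumsum(0.5 * (log(tp[-N]) - log(tm[-1]))))
  S <- matrix(0, N, N)
  diag(S) <- 1 - tp - tm
  off <- sqrt(tp[-N] * tm[-1])
  S[cbind(1:(N - 1), 2:N)] <- off
  S[cbind(2:N, 1:(N - 1))] <- off
  es <- eigen(S, symmetric = TRUE)
  rho <- es$values[1]
  v <- es$vectors[, 1]
  if (sum(v) < 0) v <- -v
  q <- pmax(v, 0) * exp(logd - max(logd))
  q <- q / sum(q)
  rate <- (1 - rho) * N
  flux <- N * tm[1] * q[1]
  structure(list(rate = rate, mte = 1 / rate,
                 qsd = qsd_table(q, "eigen", rates$params),
                 eigenvalue = rho,
                 flux_rel_error = abs(flux - rate) / rate),
            class = "qsd_eigen")
}

#' @export
print.qsd_eigen <- function(x, ...) {
  cat(sprintf("Eigen QSD: rate = %.6g per generation (MTE = %.6g), flux check %.2g\n",
              x$rate, x$mte, x$flux_rel_error))
  invisible(x)
}

#' Evolve the two-class master equation
#'
#' Explicit per-step integration of the master equation of the chain,
#' including the absorbed mass at `n = 0`; total probability is conserved
#' exactly up to floating-point roundoff.
#'
#' @param rates A [build_rates()] object.
#' @param p0 Initial distribution over `n = 0..N` (length `N + 1`), or a
#'   single state index `n0` to start from a point mass.
#' @param steps Number of Moran steps to advance.
#' @return Probability vector over `n = 0..N` after `steps` steps.
#' @export
master_evolve <- function(rates, p0, steps) {
  stopifnot(inherits(rates, "transition_rates"))
  N <- rates$N
  tp <- rates$t_plus
  tm <- rates$t_minus
  if (length(p0) == 1) {
    p <- numeric(N + 1)
    p[p0 + 1] <- 1
  } else {
    stopifnot(length(p0) == N + 1)
    p <- p0
  }
  stay <- 1 - tp - tm
  for (i in seq_len(steps)) {
    p <- stay * p + c(0, (tp * p)[-(N + 1)]) + c((tm * p)[-1], 0)
  }
  p
}

#' Survival probability decay rate from the master equation
#'
#' Integrates the master equation from the equilibrium point mass and fits
#' `log P(survival)` against time over a late-time window, where the decay
#' is a clean exponential at the ratchet rate (the dominant eigenvalue gap).
#'
#' @param rates A [build_rates()] object.
#' @param t_window Fit window in units of the mean click time, default
#'   `c(2, 5)`.
#' @param n_fit Number of fit points across the window.
#' @return Decay rate in clicks per generation.
#' @export
survival_decay_rate <- function(rates, t_window = c(2, 5), n_fit = 12) {
  mte_gens <- exact_mfpt(rates)
  N <- rates$N
  t_pts <- seq(t_window[1], t_window[2], length.out = n_fit) * mte_gens
  steps <- round(t_pts * N)
  p <- master_evolve(rates, default_n0(rates$params), steps[1])
  surv <- numeric(n_fit)
  surv[1] <- 1 - p[1]
  for (i in 2:n_fit) {
    p <- master_evolve(rates, p, steps[i] - steps[i - 1])
    surv[i] <- 1 - p[1]
  }
  fit <- stats::lm(log(surv) ~ t_pts)
  -unname(stats::coef(fit)[2])
}
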