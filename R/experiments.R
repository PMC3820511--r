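# Orchestration of the cross-model comparison studies: the same (N, U, s)
# grid is pushed through the microscopic simulators, the mapped two-class
# chain, and the analytic click-time formulas, and collected in one long
# table. Replicate counts follow the simulation studies these experiments
# reproduce (1000 realizations per point by default).

#' A grid of comparison points
#'
#' @param points `data.frame` with columns `N`, `U`, `s` (full-ratchet
#'   parameters, one row per grid point).
#' @param models Character subset of `"moran"`, `"wf"`, `"sde"`,
#'   `"twoclass_mc"`, `"exact"`, `"wkb_full"`, `"wkb_simplified"`. `"wf"`
#'   runs the Wright-Fisher model at population size `floor(N/2)` so its
#'   diffusion constant matches the Moran model at `N`.
#' @param replicates Clicks per simulated point.
#' @param seed Base seed; each (point, model) pair gets a deterministic
#'   sub-seed, so the full table is reproducible end to end.
#' @return A `comparison_grid` object.
#' @export
comparison_grid <- function(points,
                            models = c("moran", "wf", "sde", "exact"),
                            replicates = 1000, seed = 1) {
  stopifnot(is.data.frame(points), all(c("N", "U", "s") %in% names(points)))
  models <- match.arg(models, c("moran", "wf", "sde", "twoclass_mc", "exact",
                                "wkb_full", "wkb_simplified"),
                      several.ok = TRUE)
  structure(list(points = points, models = models, replicates = replicates,
                 seed = seed),
            class = "comparison_grid")
}

# Predicted simulation cost in elementary events (Moran steps / class-gens).
estimate_cost <- function(grid) {
  total <- 0
  for (i in seq_len(nrow(grid$points))) {
    p <- with(grid$points[i, ], full_params(N, U, s))
    mte <- exact_mfpt(build_rates(map_parameters(p)))
    if (!is.finite(mte)) mte <- 1e12
    per_click <- 0
    if ("moran" %in% grid$models) per_click <- per_click + mte * p$N
    if ("wf" %in% grid$models) per_click <- per_click + mte * 40
    if ("sde" %in% grid$models) {
      K <- sde_window(lambda_full(p))
      per_click <- per_click + mte / sde_default_dt(p, K) * K
    }
    if ("twoclass_mc" %in% grid$models) per_click <- per_click + mte * p$N
    total <- total + per_click * grid$replicates
  }
  total
}

#' Run a cross-model click-time comparison
#'
#' Computes the mean click time (and its standard error) of every requested
#' model at every grid point. Simulated models draw `replicates` independent
#' first-click times from the Haigh-equilibrium initial condition; analytic
#' rows (`exact`, `wkb_*`) are deterministic. Before running, the predicted
#' simulation cost is checked against a budget so that an accidentally
#' rare-clicking grid point fails fast instead of hanging.
#'
#' @param grid A [comparison_grid()].
#' @param budget Refuse (with a per-point cost estimate) if the predicted
#'   number of elementary simulation events exceeds this, unless
#'   `force = TRUE`.
#' @param force Run regardless of the budget estimate.
#' @return Long-format `data.frame`: one row per (point, model) with
#'   `model`, `N`, `U`, `s`, `lambda`, `mean_click_time`, `se`, `n_reps`,
#'   `censored`, and the WKB validity flag `wkb_ok` of the mapped
#'   parameters.
#' @export
run_comparison <- function(grid, budget = 6e9, force = FALSE) {
  stopifnot(inherits(grid, "comparison_grid"))
  cost <- estimate_cost(grid)
  if (cost > budget && !force)
    stop(sprintf(
      "predicted simulation cost %.3g events exceeds budget %.3g; reduce the grid or use force = TRUE",
      cost, budget))
  rows <- list()
  for (i in seq_len(nrow(grid$points))) {
    p <- with(grid$points[i, ], full_params(N, U, s))
    tc <- map_parameters(p)
    flags <- wkb_validity(tc)
    for (m in grid$models) {
      sub_seed <- (grid$seed + 7919L * i +
                     101L * match(m, grid$models)) %% .Machine$integer.max
      res <- switch(m,
        moran = summary(moran_click_times(p, grid$replicates, seed = sub_seed)),
        wf = summary(wf_click_times(full_params(max(2, floor(p$N / 2)), p$U, p$s),
                                    grid$replicates, seed = sub_seed)),
        sde = summary(sde_click_times(p, grid$replicates, seed = sub_seed)),
        twoclass_mc = summary(mc_click_times(tc, reps = grid$replicates,
                                             seed = sub_seed)),
        exact = list(mean = exact_mfpt(build_rates(tc)), se = 0, n = NA,
                     n_censored = 0),
        wkb_full = list(mean = suppressWarnings(wkb_mte(tc))$mte, se = 0,
                        n = NA, n_censored = 0),
        wkb_simplified = list(mean = suppressWarnings(
          wkb_mte_simplified(tc))$mte, se = 0, n = NA, n_censored = 0))
      rows[[length(rows) + 1]] <- data.frame(
        model = m, N = p$N, U = p$U, s = p$s, lambda = lambda_full(p),
        mean_click_time = res$mean, se = res$se, n_reps = res$n,
        censored = res$n_censored, wkb_ok = flags$ok)
    }
  }
  do.call(rbind, rows)
}

#' Compare the fittest-class distribution across routes
#'
#' Runs the full-Moran occupancy histogram ([sample_fittest_histogram()]),
#' the eigen-solution of the mapped two-class chain ([qsd_eigen()]) and both
#' WKB orders ([wkb_qsd()]) for one parameter set, and reports all pairwise
#' total-variation distances.
#'
#' @param params A [full_params()] object.
#' @param replicates Histogram replicates (default 5000).
#' @param seed Optional integer seed.
#' @param sample_fraction Passed to [sample_fittest_histogram()].
#' @return List with the four `qsd_table`s (`histogram`, `eigen`,
#'   `wkb_prefactor`, `wkb_leading`), the `tv` matrix of pairwise
#'   total-variation distances, and the WKB validity `flags` of the mapped
#'   parameters.
#' @export
run_qsd_study <- function(params, replicates = 5000, seed = NULL,
                          sample_fraction = 0.1) {
  stopifnot(inherits(params, "full_params"))
  tc <- map_parameters(params)
  eig <- qsd_eigen(build_rates(tc))
  hist <- sample_fittest_histogram(params, replicates, sample_fraction, seed,
                                   mean_click_time = eig$mte)
  qp <- suppressWarnings(wkb_qsd(tc, "prefactor"))
  ql <- suppressWarnings(wkb_qsd(tc, "leading"))
  tabs <- list(histogram = hist, eigen = eig$qsd, wkb_prefactor = qp,
               wkb_leading = ql)
  tv <- outer(seq_along(tabs), seq_along(tabs),
              Vectorize(function(i, j) tv_distance(tabs[[i]], tabs[[j]])))
  dimnames(tv) <- list(names(tabs), names(tabs))
  list(histogram = hist, eigen = eig$qsd, wkb_prefactor = qp,
       wkb_leading = ql, tv = tv, flags = wkb_validity(tc))
}
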