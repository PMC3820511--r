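---
title: "Quantifying Muller's ratchet: models, reductions and WKB asymptotics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Muller's ratchet: models, reductions and WKB asymptotics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratchetr)
```

## The process

An asexual population of fixed size $N$ accumulates deleterious mutations at
genomic rate $U$ per individual per generation; each mutation multiplies
fitness by $(1-s)$, so an individual carrying $k$ mutations has fitness
$(1-s)^k$. Without back mutation or recombination, the class of individuals
with the fewest mutations (the *least-loaded class*) can only shrink by
chance: once it is lost — a *click* of Muller's ratchet — it never returns,
and the whole fitness distribution shifts one class down. The central
quantity is the mean time $T$ between clicks, the inverse ratchet rate.

In the infinite-population limit mutation and selection balance at Haigh's
steady state, a Poisson profile with mean $\lambda = U/s$
(`haigh_steady_state()`); the equilibrium size of the least-loaded class is
$\bar n_0 = N e^{-\lambda}$. In the *rare-clicking regime* the population
relaxes to a metastable state close to this profile between clicks, and a
click is a rare, large fluctuation — which is why naive diffusion
approximations of the tail can fail, and why this package implements both
exact birth–death results and a WKB (eikonal) treatment designed for rare
events.

## Three microscopic models, one diffusion limit

The package implements three standard dynamical formulations:

* **Moran** (`moran_click_times()`, `run_until_clicks()`): overlapping
  generations. Each elementary step picks one individual to reproduce with
  probability proportional to class fitness, gives the offspring a
  Poisson($U$) number of new mutations, and removes one individual chosen
  uniformly. One generation is $N$ steps; all click times are reported in
  generations. A `mutation_model = "bernoulli"` switch (at most one new
  mutation per birth, with the same leaving probability $1-e^{-U}$) is
  provided for sensitivity analysis.
* **Wright–Fisher** (`wf_click_times()`): non-overlapping generations; the
  next generation is one multinomial draw of size $N$ whose class
  probabilities are the fitness-weighted parent frequencies convolved with
  Poisson($U$) mutation.
* **Diffusion SDE** (`sde_click_times()`): the mesoscopic limit
  $dx_k = [\,s(\bar k - k)x_k + U(x_{k-1}-x_k)\,]dt + \sqrt{2x_k/N}\,dW_k$,
  integrated by Euler–Maruyama with clamping at $0$ and renormalization to
  the simplex. The noise variance $2x_k/N$ per generation is the Moran-model
  diffusion constant: the Wright–Fisher model has half of it, so the package
  compares Moran at $N$, the SDE at $N$, and Wright–Fisher at $N/2$
  (`run_comparison()` does this automatically). A click is declared when
  $x_0$ falls below $1/(2N)$ — half an individual, the natural microscopic
  resolution. The deterministic skeleton of this SDE has the Poisson
  profile as its unique attracting fixed point, which the test suite
  verifies to $10^{-8}$.

The three models agree on click times within sampling error across slow and
fast regimes; this cross-validation is one of the package's acceptance
properties.

Numerical conventions worth knowing: the Moran and Wright–Fisher simulators
keep a sliding window of $\max(\lceil 10\lambda + 20\rceil, 40)$ mutation
classes above the current least-loaded class, folding deeper mutants into
the last class (the Poisson tail there is negligible for any $\lambda$ of
interest); the SDE uses a smaller window, $\max(\lceil 6\lambda+12\rceil,15)$,
because its cost is proportional to the window and its deterministic profile
confines the occupied classes more tightly. The SDE step defaults to
$dt = 0.01/\max(sK, U, 1)$ generations and is halved automatically if a
pre-clamp frequency undershoots $-10\sqrt{2\,dt/N}$; the click-time
distribution is verified stable under $dt \to dt/2$. Initial conditions are
the Haigh profile rounded to $N$ individuals by largest remainders.

## The two-class reduction

Because total size is fixed, tracking only the least-loaded class count $n$
gives a one-dimensional birth–death chain if all mutated individuals are
merged into a single class with effective fitness $1-s_{\text{eff}}$ and
effective mutation rate $u$ out of the fittest class. Matching the
infinite-population equilibria of the two descriptions — equal population
mean fitness, and equal mean fitness among mutation carriers — fixes the
effective parameters (`map_parameters()`):

$$u = 1 - e^{-U}, \qquad
  s_{\text{eff}} = \frac{1-e^{-U}}{1-e^{-\lambda}}, \qquad
  \lambda_0 \equiv \frac{u}{s_{\text{eff}}} = 1 - e^{-\lambda}.$$

The equilibrium frequency of the fittest class is then
$x^* = 1-\lambda_0 = e^{-\lambda}$, exactly Haigh's mean, and the mutation
rates out of the fittest class coincide in both models. Note
$\lambda_0 < 1$ for every $\lambda$: the mapped chain always has a
metastable state. These relations hold to machine precision and are
asserted in the tests.

Per Moran step the chain moves $n \to n+1$ with probability
$t^+(n) = \frac{n}{n+(1-s_{\text{eff}})(N-n)}(1-u)\frac{N-n}{N}$ and
$n \to n-1$ with probability
$t^-(n) = \frac{(1-s_{\text{eff}})(N-n)+un}{n+(1-s_{\text{eff}})(N-n)}\frac{n}{N}$
(`build_rates()`); $n=0$ is absorbing. The mean click time from $n_0$
(default: $\mathrm{round}(Nx^*)$, the equilibrium) has the classical
closed form as a double sum of products of rate ratios (`exact_mfpt()`),
accumulated entirely in the log domain because the products overflow double
precision already around $N \sim 10^3$. Two independent routes guard this
computation: a cancellation-free Thomas elimination of the first-step
linear system (`mfpt_linsolve()`; the two agree to $\sim 10^{-13}$
relative), and Monte Carlo simulation of the chain (`mc_click_times()`,
using geometric holding times on the embedded jump chain).

The quasi-stationary distribution (QSD) of $n$ conditioned on survival, and
the decay rate of the survival probability, come from the dominant
eigenpair of the chain restricted to $\{1..N\}$ (`qsd_eigen()`; the
tridiagonal operator is symmetrized by a log-domain diagonal similarity and
handed to a dense symmetric eigensolver, practical to $N = 5000$). The
eigen-rate, the probability flux $N\,t^-(1)\,\pi_1$ into the absorbing
state, and $1/T$ from `exact_mfpt()` agree closely in the metastable
regime — three views of the same click rate.

## WKB (eikonal) asymptotics

Writing the QSD as $\pi(x) \propto e^{-N S(x)}$ with $x = n/N$ and
expanding the quasi-stationary master equation in $1/N$ gives
$S'(x) = \ln[T^-(x)/T^+(x)]$ with the frequency-form rates
$T^\pm$. The action has an elementary closed form (`wkb_action()`), with
$S(x^*) = 0$, $S''(x^*) = s_{\text{eff}}^2/(u(1-u))$, and barrier $S(0)$
against extinction. Two QSD orders are available (`wkb_qsd()`):

* *leading*: $\pi_n \propto e^{-NS(x)}$ with Gaussian-peak normalization —
  correct near the peak, Gaussian by construction, wrong in the tails;
* *prefactor*: the next-order amplitude $1/\sqrt{T^+T^-}$ together with a
  boundary-layer factor $1-\rho^{-n}$, $\rho = (1-u)/(1-s_{\text{eff}})$,
  obtained by matching the WKB bulk onto the exact constant-flux recursion
  of the quasi-stationary master equation near the absorbing state. This
  order captures the distinctly non-Gaussian tails and tracks the
  eigen-QSD to total-variation distances of order $10^{-3}$ or below in
  regime.

The matched solution yields a closed-form mean time to extinction
(`wkb_mte()`):

$$T \;=\; \sqrt{\frac{2\pi}{N}}\;
   \frac{s_{\text{eff}}(1-u)\sqrt{(1-s_{\text{eff}})/u}}{(s_{\text{eff}}-u)^2}\;
   e^{N S(0)} \quad\text{generations},$$

accurate up to relative corrections of order $1/N$; the test suite verifies
convergence of $T_{\mathrm{WKB}}/T_{\mathrm{exact}} \to 1$ along
$N \in \{100, 200, 400\}$ and sub-1% log accuracy from $N = 200$. The
leading-order rate (flux of the Gaussian-normalized leading QSD) is
reported as a diagnostic: it is exponentially accurate only, and its ratio
to the true rate drifts with $N$ — a concrete reminder of why the
prefactor matters.

Expanding at fixed $(Ns_{\text{eff}}, \lambda_0)$ to leading order in
$s_{\text{eff}}$ gives the compact form (`wkb_mte_simplified()`,
`scaling_form()`):

$$T = \sqrt{\frac{2\pi}{N s_{\text{eff}}^3}}\;
      \frac{e^{\,N s_{\text{eff}} f(\lambda_0)}}{\sqrt{\lambda_0}\,(1-\lambda_0)^2},
  \qquad f(\lambda_0) = 1 - \lambda_0 + \lambda_0\ln\lambda_0 .$$

Here $1/s_{\text{eff}}$ is a pure timescale ($T \propto 1/s_{\text{eff}}$
exactly at fixed $Ns_{\text{eff}}$ and $\lambda_0$), and $f$ is the
analytic, $\lambda$-dependent counterpart of the constant "Haigh factor"
that classical click-rate fits inserted ad hoc: $f$ decreases from
$f(0^+)=1$ with slope $\ln\lambda_0$, passing through the historically
fitted $0.5$–$0.6$ range around $\lambda_0 \approx 0.2$. The simplified
form agrees with the full expression only where $s_{\text{eff}}$ is small:
the relative deviation is
$(1-u)(1-s_{\text{eff}})e^{N\,O(s_{\text{eff}}^2)} - 1$, which the package
reports (`deviation_vs_full`) rather than hiding — at
$N s_{\text{eff}} = 30$ it is a few percent when
$s_{\text{eff}} = 0.005$ but large when $s_{\text{eff}} = 0.1$.

Every WKB result carries machine-checkable validity flags
(`wkb_validity()`): the defaults demand $x^* \ge 0.4$ (fixed point far from
the absorbing boundary) and $N s_{\text{eff}} \ge 10$. Out-of-regime calls
warn and still compute, so degradation is visible rather than fatal.

## How well does the two-class reduction describe the full ratchet?

This is the question the comparison experiments (`run_comparison()`,
`run_qsd_study()`) are built to answer, and the answer has two parts.

**Distributions: very well.** The occupancy histogram of the least-loaded
class of the full Moran ratchet, sampled at a fraction (default $0.1$) of
the mean click time when the metastable state has formed but almost no
realization has clicked (`sample_fittest_histogram()`; the sampling time is
estimated from the mapped chain's `exact_mfpt()`), matches the mapped
chain's eigen-QSD and the prefactor WKB QSD to small total-variation
distances in the rare-clicking regime.

**Rates: well on the logarithmic scale that matters, with a quantifiable
bias.** The comparison experiments show that the mapped chain's mean click
time tracks the full ratchet's over orders of magnitude, but systematically
underestimates it: empirically the two-class barrier is a few percent
(of order $5$–$10\%$ for $\lambda_0$ between $0.1$ and $0.4$) smaller than
the full model's effective barrier, so the click-time ratio behaves like
$e^{\delta \cdot N S(0)}$ with small $\delta > 0$. Two consequences shape
the test design. First, on log-scale comparisons across parameter sweeps
(how such results are normally plotted) the agreement looks excellent.
Second, a fixed *linear* accuracy target (say, mean click times within
10%) is only met while the barrier $N S(0)$ is moderate — the deeper the
rare-click regime, the larger the exponentiated bias. The acceptance tests
therefore compare full-model and two-class click times at marginally
metastable points (barrier $N S(0) \approx 2$–$4$, click time still one to
two orders of magnitude above the relaxation time) and additionally assert
the log-scale agreement at deeper points. The merged-class approximation
ignores the delayed response of the mutant bulk to fluctuations of the
fittest class, which is the known physical origin of such a bias; modeling
that feedback is outside this package's scope.

## What the synthetic study conditions do and do not cover

All inputs are model parameters; there is no external data. The study
conditions baked into the tests and the acceptance script are:
$\lambda \le 1$ (fitness distributions narrow enough for the two-class
merge), populations $N$ between $30$ and $200$ for simulation-backed checks (a
law-of-large-numbers check runs at $N = 10^4$; analytic routes are
exercised to $N = 6000$), $500$–$3500$ clicks or up to $5000$ histogram
replicates per simulated point, and fixed seeds throughout. These sizes keep the full suite within desk-scale runtimes
while leaving every claim statistically resolvable; they are stated here as
the package's chosen conditions, and `run_comparison()`'s budget estimator
refuses grids that would silently explode beyond them. What passing tests
show is internal consistency of the five routes to the same quantities
(two microscopic simulators, one mesoscopic integrator, exact birth–death
algebra, WKB asymptotics) under the stated regimes; they do not certify
regimes the package flags as invalid ($x^*$ near $0$, $\lambda$ well above
$1$, fast-clicking traveling-wave dynamics), and real genomes with variable
mutation effects, epistasis, back mutation or recombination are outside the
model class entirely.

## Other design choices

* **Mutation convention.** Offspring acquire Poisson($U$) new mutations
  (Haigh's convention), making the per-birth probability of leaving the
  fittest class $1-e^{-U}$ — the same quantity the mapping matches. The
  Bernoulli alternative changes the bulk distribution slightly but not
  this rate; it is exposed as a switch rather than hidden.
* **Click bookkeeping.** A click is recorded at the exact step where the
  fittest-class count reaches zero; the class window then re-indexes.
  Replicate-level comparisons use first clicks from the equilibrium
  initial condition, matching the analytic initial condition
  $n_0 = \mathrm{round}(Nx^*)$; successive-click intervals from single
  trajectories are available and their means agree within sampling error.
* **Degenerate inputs.** $U = 0$ can never click: simulators return a
  censored time at the budget instead of hanging or throwing.
  $u \ge s_{\text{eff}}$ has no metastable state: WKB routines refuse
  ($x^* \le 0$) or warn (regime flags), while exact routes still work.
  $u = 0$ makes absorption unreachable from above: `exact_mfpt()` returns
  `Inf` with an explanatory attribute rather than a numeric overflow.
* **Precision.** Log-domain accumulation appears wherever products of $N$
  rate ratios occur (action sums, MFPT products, eigensolver similarity);
  `exact_mfpt()` also returns `log_generations` so callers can work with
  click times beyond double-precision range.

## Limitations

Multiplicative fitness only; no epistasis, back mutation, recombination, or
variable population size. The two-class rate carries the bias discussed
above, growing with barrier height. The WKB forms require
$u < s_{\text{eff}}$ and degrade when $x^*$ approaches $0$ or
$N s_{\text{eff}}$ is small — exactly what the validity flags report. The
dense eigensolver is the limiting factor for very large $N$; the WKB
closed forms are the intended tool there.
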