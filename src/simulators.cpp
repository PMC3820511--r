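// Stochastic simulators for Muller's ratchet.
//
// All randomness goes through R's RNG (unif_rand / norm_rand / R::rpois /
// R::rgeom), so set.seed() on the R side makes every simulator reproducible.
// Times are accumulated in doubles: step counts routinely exceed 2^31 in the
// rare-clicking regime.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Sample a deleterious mutation count ~ Poisson(U), cheaply: with U of order
// 0.1 the zero branch is taken ~90% of the time and costs one uniform.
inline int rpois_mut(double U, double exp_mU) {
  double u = unif_rand();
  if (u <= exp_mU) return 0;
  int m = 0;
  double cum = exp_mU, pk = exp_mU;
  while (cum < u && m < 200) {
    ++m;
    pk *= U / m;
    cum += pk;
  }
  return m;
}

struct MoranChain {
  // Sliding window of K mutation classes; cnt[0] is the current fittest
  // (least-loaded) class. Only relative fitness (1-s)^j within the window
  // matters for birth sampling, so the absolute class index never enters.
  std::vector<int> cnt;
  std::vector<double> pw;  // (1-s)^j
  int N, K;
  double U, s, exp_mU, W;  // W = sum cnt[j] * pw[j]
  bool bernoulli;  // at most one new mutation per birth, prob 1 - exp(-U)
  long long steps_since_refresh;

  MoranChain(IntegerVector counts0, double U_, double s_, bool bern = false)
      : cnt(counts0.begin(), counts0.end()), U(U_), s(s_), bernoulli(bern) {
    K = cnt.size();
    N = 0;
    for (int j = 0; j < K; ++j) N += cnt[j];
    pw.resize(K);
    pw[0] = 1.0;
    for (int j = 1; j < K; ++j) pw[j] = pw[j - 1] * (1.0 - s);
    exp_mU = std::exp(-U);
    refresh_weight();
  }

  void refresh_weight() {
    W = 0.0;
    for (int j = 0; j < K; ++j) W += cnt[j] * pw[j];
    steps_since_refresh = 0;
  }

  // One Moran event: fitness-weighted birth, Poisson(U) mutation of the
  // offspring, uniform death. Population size is conserved by construction.
  inline void step() {
    double r = unif_rand() * W;
    int b = 0;
    double acc = cnt[0] * pw[0];
    while (acc < r && b < K - 1) {
      ++b;
      acc += cnt[b] * pw[b];
    }
    int c;
    if (bernoulli)
      c = b + (unif_rand() > exp_mU ? 1 : 0);
    else
      c = b + rpois_mut(U, exp_mU);
    if (c > K - 1) c = K - 1;  // fold deep tail into last class
    int di = (int)(unif_rand() * N);
    if (di >= N) di = N - 1;
    int d = 0;
    int a2 = cnt[0];
    while (a2 <= di && d < K - 1) {
      ++d;
      a2 += cnt[d];
    }
    ++cnt[c];
    --cnt[d];
    W += pw[c] - pw[d];
    if (++steps_since_refresh >= 1000000) refresh_weight();
  }

  // After a click, re-index so the new least-loaded class sits at 0.
  int shift_window() {
    int j0 = 0;
    while (j0 < K && cnt[j0] == 0) ++j0;
    if (j0 == 0 || j0 == K) return 0;
    for (int j = 0; j + j0 < K; ++j) cnt[j] = cnt[j + j0];
    for (int j = K - j0; j < K; ++j) cnt[j] = 0;
    refresh_weight();
    return j0;
  }
};

}  // namespace

// Run the full Moran ratchet until n_clicks clicks or max_steps events.
// Returns click times in Moran steps (cumulative from t = 0).
// [[Rcpp::export]]
List cpp_moran_sim(IntegerVector counts0, double U, double s, int n_clicks,
                   double max_steps, bool track_n0, bool bernoulli = false) {
  MoranChain ch(counts0, U, s, bernoulli);
  std::vector<double> clicks;
  clicks.reserve(n_clicks);
  double t = 0.0, sum_n0 = 0.0;
  int kmin_shift = 0;
  while ((int)clicks.size() < n_clicks && t < max_steps) {
    ch.step();
    t += 1.0;
    if (track_n0) sum_n0 += ch.cnt[0];
    if (ch.cnt[0] == 0) {
      clicks.push_back(t);
      kmin_shift += ch.shift_window();
    }
  }
  return List::create(
      _["click_steps"] = NumericVector(clicks.begin(), clicks.end()),
      _["steps_done"] = t, _["censored"] = ((int)clicks.size() < n_clicks),
      _["mean_n0"] = track_n0 && t > 0 ? sum_n0 / t : NA_REAL,
      _["k_min"] = kmin_shift,
      _["counts"] = IntegerVector(ch.cnt.begin(), ch.cnt.end()));
}

// Raw Moran stepping without click bookkeeping (unit-test surface).
// [[Rcpp::export]]
IntegerVector cpp_moran_steps(IntegerVector counts0, double U, double s,
                              double nsteps) {
  MoranChain ch(counts0, U, s);
  for (double t = 0; t < nsteps; t += 1.0) ch.step();
  return IntegerVector(ch.cnt.begin(), ch.cnt.end());
}

// Run until the fittest class is lost or fixed (class-0 count hits 0 or N).
// [[Rcpp::export]]
List cpp_moran_until_boundary(IntegerVector counts0, double U, double s,
                              double max_steps) {
  MoranChain ch(counts0, U, s);
  double t = 0.0;
  while (ch.cnt[0] > 0 && ch.cnt[0] < ch.N && t < max_steps) {
    ch.step();
    t += 1.0;
  }
  return List::create(_["counts"] = IntegerVector(ch.cnt.begin(), ch.cnt.end()),
                      _["steps"] = t, _["fixed"] = (ch.cnt[0] == ch.N),
                      _["lost"] = (ch.cnt[0] == 0));
}

// Record the fittest-class occupancy after t_steps events, or report that a
// click occurred first (used to histogram the quasi-stationary distribution).
// [[Rcpp::export]]
List cpp_moran_sample_n0(IntegerVector counts0, double U, double s,
                         double t_steps) {
  MoranChain ch(counts0, U, s);
  double t = 0.0;
  bool clicked = false;
  while (t < t_steps) {
    ch.step();
    t += 1.0;
    if (ch.cnt[0] == 0) {
      clicked = true;
      break;
    }
  }
  return List::create(_["n0"] = ch.cnt[0], _["clicked"] = clicked);
}

namespace {

// One Wright-Fisher generation: fitness weighting, Poisson(U) mutation
// convolution (tail mass folded into the last window class), multinomial
// resampling of N individuals.
void wf_generation(std::vector<int>& cnt, int N, int K,
                   const std::vector<double>& pw,
                   const std::vector<double>& pois,
                   const std::vector<double>& pois_cum, std::vector<double>& p,
                   std::vector<int>& draw) {
  double Wt = 0.0;
  for (int j = 0; j < K; ++j) Wt += cnt[j] * pw[j];
  std::fill(p.begin(), p.end(), 0.0);
  for (int j = 0; j < K; ++j) {
    if (cnt[j] == 0) continue;
    double psel = cnt[j] * pw[j] / Wt;
    int mmax = K - 1 - j;
    for (int m = 0; m < mmax; ++m) p[j + m] += psel * pois[m];
    // all mutants that would leave the window land in the last class
    p[K - 1] += psel * (1.0 - (mmax > 0 ? pois_cum[mmax - 1] : 0.0));
  }
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += p[k];
  for (int k = 0; k < K; ++k) p[k] /= tot;
  rmultinom(N, p.data(), K, draw.data());
  for (int k = 0; k < K; ++k) cnt[k] = draw[k];
}

void pois_tables(double U, int K, std::vector<double>& pois,
                 std::vector<double>& pois_cum) {
  pois.resize(K);
  pois_cum.resize(K);
  pois[0] = std::exp(-U);
  pois_cum[0] = pois[0];
  for (int m = 1; m < K; ++m) {
    pois[m] = pois[m - 1] * U / m;
    pois_cum[m] = pois_cum[m - 1] + pois[m];
  }
}

}  // namespace

// Wright-Fisher ratchet; one generation = one multinomial resampling.
// [[Rcpp::export]]
List cpp_wf_sim(IntegerVector counts0, double U, double s, int n_clicks,
                double max_gens) {
  int K = counts0.size();
  std::vector<int> cnt(counts0.begin(), counts0.end());
  int N = 0;
  for (int j = 0; j < K; ++j) N += cnt[j];
  std::vector<double> pw(K), pois, pois_cum, p(K);
  std::vector<int> draw(K);
  pw[0] = 1.0;
  for (int j = 1; j < K; ++j) pw[j] = pw[j - 1] * (1.0 - s);
  pois_tables(U, K, pois, pois_cum);
  std::vector<double> clicks;
  double t = 0.0;
  int kmin_shift = 0;
  while ((int)clicks.size() < n_clicks && t < max_gens) {
    wf_generation(cnt, N, K, pw, pois, pois_cum, p, draw);
    t += 1.0;
    if (cnt[0] == 0) {
      clicks.push_back(t);
      int j0 = 0;
      while (j0 < K && cnt[j0] == 0) ++j0;
      if (j0 > 0 && j0 < K) {
        for (int j = 0; j + j0 < K; ++j) cnt[j] = cnt[j + j0];
        for (int j = K - j0; j < K; ++j) cnt[j] = 0;
        kmin_shift += j0;
      }
    }
  }
  return List::create(
      _["click_gens"] = NumericVector(clicks.begin(), clicks.end()),
      _["gens_done"] = t, _["censored"] = ((int)clicks.size() < n_clicks),
      _["k_min"] = kmin_shift,
      _["counts"] = IntegerVector(cnt.begin(), cnt.end()));
}

// Raw Wright-Fisher generations without click bookkeeping.
// [[Rcpp::export]]
IntegerVector cpp_wf_gens(IntegerVector counts0, double U, double s,
                          int ngens) {
  int K = counts0.size();
  std::vector<int> cnt(counts0.begin(), counts0.end());
  int N = 0;
  for (int j = 0; j < K; ++j) N += cnt[j];
  std::vector<double> pw(K), pois, pois_cum, p(K);
  std::vector<int> draw(K);
  pw[0] = 1.0;
  for (int j = 1; j < K; ++j) pw[j] = pw[j - 1] * (1.0 - s);
  pois_tables(U, K, pois, pois_cum);
  for (int g = 0; g < ngens; ++g)
    wf_generation(cnt, N, K, pw, pois, pois_cum, p, draw);
  return IntegerVector(cnt.begin(), cnt.end());
}

// Euler-Maruyama integration of the mesoscopic frequency SDE
//   dx_k = [ s (kbar - k) x_k + U (x_{k-1} - x_k) ] dt
//          + noise_factor * sqrt(2 x_k / N) dW_k,
// time in Moran generations (hence the diffusion constant 2/N, matching the
// overlapping-generation model and a Wright-Fisher population of size N/2).
// Frequencies are clamped at 0 and renormalized after every step; a click is
// declared when x_0 falls below x_abs = 1/(2N) (half an individual).
// [[Rcpp::export]]
List cpp_sde_sim(NumericVector x0, double Nsize, double U, double s, double dt,
                 int n_clicks, double max_t, double noise_factor) {
  int K = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), xn(K);
  double x_abs = 1.0 / (2.0 * Nsize);
  std::vector<double> clicks;
  double t = 0.0;
  int halvings = 0, kmin_shift = 0;
  const int max_halvings = 12;
  // n_clicks = 0 means: integrate to max_t without click bookkeeping
  bool track_clicks = n_clicks > 0;
  while ((!track_clicks || (int)clicks.size() < n_clicks) && t < max_t) {
    double kbar = 0.0;
    for (int k = 1; k < K; ++k) kbar += k * x[k];
    double floor_violation = -10.0 * std::sqrt(2.0 * dt / Nsize);
    bool violated = false;
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double drift = s * (kbar - k) * x[k] + U * ((k > 0 ? x[k - 1] : 0.0) - x[k]);
      double xi = x[k] > 0.0 ? x[k] : 0.0;
      double v = x[k] + drift * dt;
      if (noise_factor != 0.0 && xi > 0.0)
        v += noise_factor * std::sqrt(2.0 * xi / Nsize * dt) * norm_rand();
      if (v < floor_violation) violated = true;
      if (v < 0.0) v = 0.0;
      xn[k] = v;
      tot += v;
    }
    if (violated) {
      dt *= 0.5;
      if (++halvings > max_halvings)
        stop("sde_click_times: step-size control failed (dt halved %d times)",
             max_halvings);
      continue;  // retry the step with the finer dt
    }
    for (int k = 0; k < K; ++k) x[k] = xn[k] / tot;
    t += dt;
    if (track_clicks && x[0] <= x_abs) {
      clicks.push_back(t);
      int j0 = 1;
      while (j0 < K && x[j0] <= x_abs) ++j0;
      if (j0 >= K) j0 = K - 1;
      for (int j = 0; j + j0 < K; ++j) x[j] = x[j + j0];
      for (int j = K - j0; j < K; ++j) x[j] = 0.0;
      double tt = 0.0;
      for (int k = 0; k < K; ++k) tt += x[k];
      for (int k = 0; k < K; ++k) x[k] /= tt;
      kmin_shift += j0;
    }
  }
  return List::create(
      _["click_gens"] = NumericVector(clicks.begin(), clicks.end()),
      _["t_done"] = t, _["censored"] = ((int)clicks.size() < n_clicks),
      _["dt_final"] = dt, _["k_min"] = kmin_shift,
      _["x"] = NumericVector(x.begin(), x.end()));
}

// Two-class birth-death chain: absorption times at n = 0, in Moran steps.
// jump = true uses geometric holding times on the embedded jump chain
// (equivalent in distribution to per-step simulation; see tests).
// [[Rcpp::export]]
List cpp_twoclass_mc(NumericVector t_plus, NumericVector t_minus, int n0,
                     int reps, double max_steps, bool jump) {
  NumericVector out(reps);
  LogicalVector cens(reps);
  for (int r = 0; r < reps; ++r) {
    int n = n0;
    double steps = 0.0;
    bool censored = false;
    while (n > 0) {
      double a = t_plus[n], b = t_minus[n], q = a + b;
      if (q <= 0.0) {
        censored = true;  // absorption unreachable (e.g. u = 0 at n = N)
        steps = max_steps;
        break;
      }
      if (jump) {
        steps += 1.0 + R::rgeom(q);
        n += (unif_rand() * q < a) ? 1 : -1;
      } else {
        double u = unif_rand();
        steps += 1.0;
        if (u < a)
          ++n;
        else if (u < q)
          --n;
      }
      if (steps >= max_steps) {
        censored = true;
        break;
      }
    }
    out[r] = steps;
    cens[r] = censored;
    if (n < 0) stop("internal error: negative state");
  }
  return List::create(_["steps"] = out, _["censored"] = cens);
}
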