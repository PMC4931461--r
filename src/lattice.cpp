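#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fixed-timestep Monte Carlo sweeps for the lattice polymerization model.
// Strands are represented by (site, length) pairs; monomers are strands of
// length 1. All randomness flows through R's RNG so set.seed() controls a
// whole run. Per sweep, at most one bond forms per site and at most one
// break occurs per strand; probabilities are clamped at 1 and clamp events
// counted (discretization bias is visible, not silent).

static inline int unif_index(int n) {
  // uniform integer in [0, n); guard the rare unif_rand() == 1.0 draw
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Moore-neighbourhood offsets (8 neighbours), periodic boundary
static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

struct Recorder {
  int every, countdown;
  std::vector<double> t;
  std::vector<int> strands, monomers;
  Recorder(int every_) : every(every_), countdown(every_) {}
  void maybe(double time, int S, int M) {
    if (every <= 0) return;
    if (--countdown == 0) {
      countdown = every;
      t.push_back(time); strands.push_back(S); monomers.push_back(M);
    }
  }
};

static void hydrolysis_pass(std::vector<int> &site, std::vector<int> &len,
                            double rate, double dt, long &clamps) {
  // strands created by this pass's breaks are appended and not revisited
  size_t s0 = len.size();
  for (size_t i = 0; i < s0; ++i) {
    int m = len[i];
    if (m < 2) continue;
    double p = rate * (m - 1) * dt;
    if (p > 1.0) { ++clamps; p = 1.0; }
    if (unif_rand() < p) {
      int left = 1 + unif_index(m - 1);  // break bond after position 'left'
      len[i] = left;
      site.push_back(site[i]);           // fragment stays on the parent site
      len.push_back(m - left);
    }
  }
}

static void influx_step(std::vector<int> &site, std::vector<int> &len,
                        int N, double b, double mu_max, double dt,
                        long &monomers) {
  double mu = (double)monomers / N;
  if (mu >= mu_max) return;
  double mean = N * b * (1.0 - mu / mu_max) * dt;
  int k = (int)R::rpois(mean);
  for (int j = 0; j < k; ++j) {
    site.push_back(unif_index(N));
    len.push_back(1);
  }
  monomers += k;
}

// Dry-phase sweeps: bond formation (site pass) -> hydrolysis (strand pass)
// -> hopping (strand pass) -> optional influx -> optional scramble.
// [[Rcpp::export]]
List cpp_dry_run(IntegerVector site0, IntegerVector len0, int L,
                 double k_plus, double k_minus, double h,
                 double dt, int n_steps, double t0,
                 bool scramble_each, double b, double mu_max,
                 int record_every) {
  int N = L * L;
  std::vector<int> site(site0.begin(), site0.end());
  std::vector<int> len(len0.begin(), len0.end());
  long monomers = 0;
  for (size_t i = 0; i < len.size(); ++i) monomers += len[i];
  long clamps = 0;
  Recorder rec(record_every);
  std::vector<int> cnt(N), head(N), nxt;
  std::vector<char> dead;

  for (int step = 0; step < n_steps; ++step) {
    size_t S = len.size();
    // --- bond formation: per-site linked lists, one bond max per site
    if (k_plus > 0.0) {
      std::fill(cnt.begin(), cnt.end(), 0);
      std::fill(head.begin(), head.end(), -1);
      nxt.assign(S, -1);
      for (size_t i = 0; i < S; ++i) {
        int s = site[i];
        ++cnt[s];
        nxt[i] = head[s];
        head[s] = (int)i;
      }
      dead.assign(S, 0);
      bool any_dead = false;
      for (int s = 0; s < N; ++s) {
        int n = cnt[s];
        if (n < 2) continue;
        double p = k_plus * (double)n * (n - 1) * dt;
        if (p > 1.0) { ++clamps; p = 1.0; }
        if (unif_rand() < p) {
          int r1 = unif_index(n);
          int r2 = unif_index(n - 1);
          if (r2 >= r1) ++r2;           // two distinct strands on the site
          int a = -1, bidx = -1, ord = 0;
          for (int i = head[s]; i != -1; i = nxt[i], ++ord) {
            if (ord == r1) a = i;
            if (ord == r2) bidx = i;
          }
          len[a] += len[bidx];
          dead[bidx] = 1;
          any_dead = true;
        }
      }
      if (any_dead) {
        size_t keep = 0;
        for (size_t i = 0; i < S; ++i) {
          if (!dead[i]) { site[keep] = site[i]; len[keep] = len[i]; ++keep; }
        }
        site.resize(keep);
        len.resize(keep);
      }
    }
    // --- hydrolysis
    if (k_minus > 0.0) hydrolysis_pass(site, len, k_minus, dt, clamps);
    // --- hopping: always accepted (no occupancy limit)
    if (h > 0.0) {
      double ph = h * dt;
      if (ph > 1.0) { ++clamps; ph = 1.0; }
      for (size_t i = 0; i < len.size(); ++i) {
        if (unif_rand() < ph) {
          int d = unif_index(8);
          int x = site[i] % L, y = site[i] / L;
          x = (x + DX[d] + L) % L;
          y = (y + DY[d] + L) % L;
          site[i] = y * L + x;
        }
      }
    }
    if (b >= 0.0) influx_step(site, len, N, b, mu_max, dt, monomers);
    if (scramble_each)
      for (size_t i = 0; i < site.size(); ++i) site[i] = unif_index(N);
    rec.maybe(t0 + (step + 1) * dt, (int)len.size(), (int)monomers);
  }
  return List::create(_["site"] = wrap(site), _["len"] = wrap(len),
                      _["clamp_count"] = (double)clamps,
                      _["rec_time"] = wrap(rec.t),
                      _["rec_strands"] = wrap(rec.strands),
                      _["rec_monomers"] = wrap(rec.monomers));
}

// Wet-phase sweeps: hydrolysis at rate w only (no bond formation, no
// hopping), with optional monomer influx. Scrambling at the end of the
// phase is applied by the caller.
// [[Rcpp::export]]
List cpp_wet_run(IntegerVector site0, IntegerVector len0, int N,
                 double w, double dt, int n_steps, double t0,
                 double b, double mu_max, int record_every) {
  std::vector<int> site(site0.begin(), site0.end());
  std::vector<int> len(len0.begin(), len0.end());
  long monomers = 0;
  for (size_t i = 0; i < len.size(); ++i) monomers += len[i];
  long clamps = 0;
  Recorder rec(record_every);
  for (int step = 0; step < n_steps; ++step) {
    if (w > 0.0) hydrolysis_pass(site, len, w, dt, clamps);
    if (b >= 0.0) influx_step(site, len, N, b, mu_max, dt, monomers);
    rec.maybe(t0 + (step + 1) * dt, (int)len.size(), (int)monomers);
  }
  return List::create(_["site"] = wrap(site), _["len"] = wrap(len),
                      _["clamp_count"] = (double)clamps,
                      _["rec_time"] = wrap(rec.t),
                      _["rec_strands"] = wrap(rec.strands),
                      _["rec_monomers"] = wrap(rec.monomers));
}

// [[Rcpp::export]]
IntegerVector cpp_scramble(int n_strands, int N) {
  IntegerVector out(n_strands);
  for (int i = 0; i < n_strands; ++i) out[i] = unif_index(N) + 1; // 1-based
  return out;
}
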