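// Lattice kernels for the reaction-diffusion engine: synchronous
// multi-particle diffusion (MPD) hopping, and a next-subvolume-method (NSM)
// sampler specialised to the Ndc80 phosphorylation network (the general NSM
// lives in R; this one carries the heavy per-event load of the stationarity
// runs).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Free-space MPD: n molecules start in one subcell of an unbounded lattice;
// each epoch every molecule hops to one of the 6 face neighbors with
// probability p_hop each (6 p_hop <= 1).  Records per-axis displacement
// variance (in subcell^2 units) at the requested epochs.  Errors out if any
// molecule travels farther than max_cells from the origin, which would
// invalidate a bounded-lattice reading of the same process.
// [[Rcpp::export]]
NumericMatrix mpd_free_variance_cpp(int n, double p_hop,
                                    IntegerVector record_epochs,
                                    int max_cells) {
  if (6.0 * p_hop > 1.0) stop("hop probability violates 6p <= 1");
  RNGScope scope;
  std::vector<int> x(n, 0), y(n, 0), z(n, 0);
  int nrec = record_epochs.size();
  NumericMatrix out(nrec, 3);
  int max_epoch = nrec ? record_epochs[nrec - 1] : 0;
  int rec = 0;
  for (int e = 1; e <= max_epoch; ++e) {
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      if (u < 6.0 * p_hop) {
        int dir = (int)(u / p_hop);
        if (dir > 5) dir = 5;
        switch (dir) {
          case 0: ++x[i]; break; case 1: --x[i]; break;
          case 2: ++y[i]; break; case 3: --y[i]; break;
          case 4: ++z[i]; break; default: --z[i]; break;
        }
      }
    }
    while (rec < nrec && record_epochs[rec] == e) {
      const std::vector<int>* ax[3] = {&x, &y, &z};
      for (int k = 0; k < 3; ++k) {
        double m = 0.0, s2 = 0.0;
        const std::vector<int>& v = *ax[k];
        for (int i = 0; i < n; ++i) m += v[i];
        m /= n;
        for (int i = 0; i < n; ++i) s2 += (v[i] - m) * (v[i] - m);
        out(rec, k) = s2 / (n - 1);
      }
      ++rec;
    }
    if (e % 1000 == 0) {
      for (int i = 0; i < n; ++i)
        if (std::abs(x[i]) > max_cells || std::abs(y[i]) > max_cells ||
            std::abs(z[i]) > max_cells)
          stop("molecule reached the lattice bound; free-diffusion oracle "
               "invalid");
      Rcpp::checkUserInterrupt();
    }
  }
  return out;
}

// Bounded-lattice MPD epochs on integer counts.  counts: J x V; p_hop per
// species (0 = immobile); nbr: V x 6 neighbor indices (1-based; 0 means the
// hop is reflected, i.e. the molecule stays).  Synchronous: all hops are
// drawn from the epoch-start state.
// [[Rcpp::export]]
IntegerMatrix mpd_epochs_cpp(IntegerMatrix counts, NumericVector p_hop,
                             IntegerMatrix nbr, int n_epochs) {
  int J = counts.nrow(), V = counts.ncol();
  for (int j = 0; j < J; ++j)
    if (6.0 * p_hop[j] > 1.0) stop("hop probability violates 6p <= 1");
  RNGScope scope;
  IntegerMatrix out = clone(counts);
  std::vector<int> cur(V), nxt(V);
  for (int j = 0; j < J; ++j) {
    double p = p_hop[j];
    if (p <= 0) continue;
    for (int v = 0; v < V; ++v) cur[v] = out(j, v);
    for (int e = 0; e < n_epochs; ++e) {
      std::fill(nxt.begin(), nxt.end(), 0);
      for (int v = 0; v < V; ++v) {
        int c = cur[v];
        if (c == 0) continue;
        int moved[6] = {0, 0, 0, 0, 0, 0};
        if (c <= 16) {
          for (int m = 0; m < c; ++m) {
            double u = unif_rand();
            if (u < 6.0 * p) {
              int dir = (int)(u / p); if (dir > 5) dir = 5;
              ++moved[dir];
            }
          }
        } else {
          // binomial splitting of the multinomial(c; p,...,p, 1-6p)
          int rem = (int)R::rbinom(c, 6.0 * p);
          for (int d = 0; d < 5 && rem > 0; ++d) {
            int m = (int)R::rbinom(rem, 1.0 / (6 - d));
            moved[d] = m; rem -= m;
          }
          moved[5] = rem;
        }
        int stay = c;
        for (int d = 0; d < 6; ++d) {
          int m = moved[d];
          if (m == 0) continue;
          int w = nbr(v, d);
          if (w > 0) { nxt[w - 1] += m; stay -= m; }
          // w == 0: reflecting wall, molecules stay
        }
        nxt[v] += stay;
      }
      cur.swap(nxt);
      if (e % 2000 == 0) Rcpp::checkUserInterrupt();
    }
    for (int v = 0; v < V; ++v) out(j, v) = cur[v];
  }
  return out;
}

// NSM for the Ndc80 phosphorylation/dephosphorylation network.
// x: (p_max+1) x V integer site counts by phosphostate; ab, ph: per-subcell
// kinase / phosphatase weights (expected or integer counts); c_up, c_dn:
// per-pair propensities (1/s).  Per-site rates are independent of p except
// at the boundaries, so the per-subcell propensities are
//   a_up = c_up * ab_v * (#sites with p < p_max)
//   a_dn = c_dn * ph_v * (#sites with p > 0).
// Returns the time-averaged mean phosphostate over [t_burn, t_end] and the
// event count.
// [[Rcpp::export]]
List nsm_phospho_cpp(IntegerMatrix x_init, NumericVector ab, NumericVector ph,
                     double c_up, double c_dn, double t_end, double t_burn) {
  int P = x_init.nrow() - 1, V = x_init.ncol();
  IntegerMatrix x = clone(x_init);
  long long n_sites = 0;
  for (int v = 0; v < V; ++v)
    for (int p = 0; p <= P; ++p) n_sites += x(p, v);
  if (n_sites == 0) stop("no Ndc80 sites on the lattice");

  RNGScope scope;
  std::vector<double> a(V), tv(V);
  double sum_p = 0.0;  // current total phosphate count
  for (int v = 0; v < V; ++v)
    for (int p = 0; p <= P; ++p) sum_p += (double)p * x(p, v);

  auto prop = [&](int v) {
    int tot = 0;
    for (int p = 0; p <= P; ++p) tot += x(p, v);
    double up = c_up * ab[v] * (tot - x(P, v));
    double dn = c_dn * ph[v] * (tot - x(0, v));
    return up + dn;
  };
  double t = 0.0;
  for (int v = 0; v < V; ++v) {
    a[v] = prop(v);
    tv[v] = a[v] > 0 ? t + exp_rand() / a[v] : R_PosInf;
  }

  double integral = 0.0;
  long long n_events = 0;
  while (true) {
    int vmin = 0;
    double tmin = tv[0];
    for (int v = 1; v < V; ++v)
      if (tv[v] < tmin) { tmin = tv[v]; vmin = v; }
    double t_next = tmin < t_end ? tmin : t_end;
    // accumulate the piecewise-constant integral over [t_burn, t_end]
    double lo = t > t_burn ? t : t_burn;
    double hi = t_next;
    if (hi > lo) integral += sum_p * (hi - lo);
    if (tmin >= t_end) break;
    t = tmin;
    ++n_events;
    // fire one reaction in vmin
    int v = vmin;
    int tot = 0;
    for (int p = 0; p <= P; ++p) tot += x(p, v);
    double up = c_up * ab[v] * (tot - x(P, v));
    double dn = c_dn * ph[v] * (tot - x(0, v));
    double u = unif_rand() * (up + dn);
    if (u < up) {
      // phosphorylate one site with p < P, chosen uniformly among them
      double pick = unif_rand() * (tot - x(P, v));
      double acc = 0.0;
      for (int p = 0; p < P; ++p) {
        acc += x(p, v);
        if (pick < acc) { --x(p, v); ++x(p + 1, v); sum_p += 1.0; break; }
      }
    } else {
      double pick = unif_rand() * (tot - x(0, v));
      double acc = 0.0;
      for (int p = 1; p <= P; ++p) {
        acc += x(p, v);
        if (pick < acc) { --x(p, v); ++x(p - 1, v); sum_p -= 1.0; break; }
      }
    }
    a[v] = prop(v);
    tv[v] = a[v] > 0 ? t + exp_rand() / a[v] : R_PosInf;
    if (n_events % 10000 == 0) Rcpp::checkUserInterrupt();
  }
  double mean_p = integral / ((t_end - t_burn) * (double)n_sites);
  return List::create(_["mean_p"] = mean_p, _["n_events"] = (double)n_events,
                      _["x_final"] = x);
}

// Isotropic 1D Brownian integrator used by the rigid-dimer benchmark:
// trajectories of independent coordinates with per-step displacement
// variance 2*D*dt each (one column per coordinate).
// [[Rcpp::export]]
NumericMatrix brownian_paths_cpp(NumericVector step_var, int n_samples,
                                 int steps_per_sample) {
  RNGScope scope;
  int k = step_var.size();
  NumericMatrix out(n_samples, k);
  std::vector<double> xcur(k, 0.0), s(k);
  for (int j = 0; j < k; ++j) s[j] = std::sqrt(step_var[j]);
  for (int i = 0; i < n_samples; ++i) {
    for (int j = 0; j < k; ++j)
      for (int m = 0; m < steps_per_sample; ++m) xcur[j] += s[j] * norm_rand();
    for (int j = 0; j < k; ++j) out(i, j) = xcur[j];
  }
  return out;
}
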