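#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Event kind codes shared with the R side (see pack_events()):
// 1 = birth (state 1 pinned at age 0), 2 = visit, 3 = exact death,
// 4 = interval-censored death.
static const int K_BIRTH = 1, K_VISIT = 2, K_DEXACT = 3, K_DINT = 4;

// Nudge (near-)duplicated rates apart so the distinct-rate closed form is
// numerically safe.  The closed-form coefficients scale like 1/gap, so
// machine round-off is amplified by ~1/gap under cancellation; a relative
// separation of 2e-3 keeps transition probabilities accurate to ~1e-13
// while perturbing them by at most ~1e-4 — far below estimation noise, and
// only when the optimiser drives two rates together.
static std::vector<double> distinct_rates(const NumericVector &rates) {
  const int ns = rates.size() + 1;
  std::vector<double> q(ns);
  double mx = 0.0;
  for (int i = 0; i < ns - 1; ++i) { q[i] = rates[i]; mx = std::max(mx, q[i]); }
  q[ns - 1] = 0.0;
  const double eps = 2e-3 * (1.0 + mx);
  for (int k = 0; k < ns; ++k) {
    bool moved = true;
    int guard = 0;
    while (moved && guard++ < 64) {
      moved = false;
      for (int l = 0; l < ns; ++l) {
        if (l != k && std::fabs(q[k] - q[l]) < eps) {
          q[k] += (k + 1) * eps;
          moved = true;
        }
      }
    }
  }
  return q;
}

// Hypoexponential closed form: P_ij(t) = sum_{k=i..j} C(i,j,k) exp(-q_k t)
// with C(i,j,k) = prod_{l=i..j-1} q_l / prod_{l=i..j, l != k} (q_l - q_k).
// The coefficients depend only on the rates, so they are computed once per
// likelihood evaluation; each event then needs only ns exponentials plus a
// small assembly.
static std::vector<double> tpm_coefs(const std::vector<double> &q) {
  const int ns = (int) q.size();
  std::vector<double> C(ns * ns * ns, 0.0);
  for (int i = 0; i < ns; ++i) {
    C[(i * ns + i) * ns + i] = 1.0;
    double cp = 1.0;
    for (int j = i + 1; j < ns; ++j) {
      cp *= q[j - 1];
      if (cp == 0.0) break;
      for (int k = i; k <= j; ++k) {
        double denom = 1.0;
        for (int l = i; l <= j; ++l)
          if (l != k) denom *= (q[l] - q[k]);
        C[(i * ns + j) * ns + k] = cp / denom;
      }
    }
  }
  return C;
}

static inline double gauss_dens(double x, double mu, double sd) {
  const double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// Forward-algorithm log-likelihood for a progressive CTHMM over packed
// per-patient event sequences.
//
// offsets: 0-based CSR offsets into the event arrays, length n_patients + 1.
// kind, age, lo, hi: per-event arrays (lo/hi used for interval deaths only).
// feat: n_events x n_features matrix (visit rows carry data, others ignored).
// rates: living exit rates (length ns - 1).
// means, sds: (ns - 1) x n_features emission parameters.
// Returns per-patient log-likelihoods (nats); sum for the total.
// [[Rcpp::export(name = ".cthmm_loglik_cpp")]]
NumericVector cthmm_loglik_cpp(IntegerVector offsets, IntegerVector kind,
                               NumericVector age, NumericVector lo,
                               NumericVector hi, NumericMatrix feat,
                               NumericVector rates, NumericMatrix means,
                               NumericMatrix sds) {
  const int npat = offsets.size() - 1;
  const int ns = rates.size() + 1;
  const int nf = feat.ncol();
  std::vector<double> q = distinct_rates(rates);
  std::vector<double> C = tpm_coefs(q);
  std::vector<double> a(ns), anew(ns), e(ns), eh(ns);
  NumericVector out(npat);

  for (int p = 0; p < npat; ++p) {
    double ll = 0.0, t = 0.0;
    bool dead_end = false;
    std::fill(a.begin(), a.end(), 0.0);
    a[0] = 1.0;
    for (int ev = offsets[p]; ev < offsets[p + 1]; ++ev) {
      const int k = kind[ev];
      if (k == K_BIRTH) continue;  // state 1 at age 0 is the starting point
      if (k == K_VISIT) {
        double dt = age[ev] - t;
        if (dt < 0) dt = 0;
        for (int m = 0; m < ns; ++m) e[m] = std::exp(-q[m] * dt);
        for (int j = 0; j < ns - 1; ++j) {
          double s = 0.0;
          for (int i = 0; i <= j; ++i) {
            if (a[i] == 0.0) continue;
            const double *Cij = &C[(i * ns + j) * ns];
            double pij = 0.0;
            for (int m = i; m <= j; ++m) pij += Cij[m] * e[m];
            s += a[i] * pij;
          }
          if (s < 0.0) s = 0.0;  // round-off guard
          for (int f = 0; f < nf; ++f)
            s *= gauss_dens(feat(ev, f), means(j, f), sds(j, f));
          anew[j] = s;
        }
        anew[ns - 1] = 0.0;  // a visit implies the patient is alive
        double c = 0.0;
        for (int j = 0; j < ns; ++j) c += anew[j];
        if (!(c > 0.0) || !std::isfinite(c)) { ll = R_NegInf; break; }
        ll += std::log(c);
        for (int j = 0; j < ns; ++j) a[j] = anew[j] / c;
        t = age[ev];
      } else if (k == K_DEXACT) {
        // density of entering death at this instant: occupancy of the last
        // living state times its exit rate
        double dt = age[ev] - t;
        if (dt < 0) dt = 0;
        for (int m = 0; m < ns; ++m) e[m] = std::exp(-q[m] * dt);
        const int j = ns - 2;
        double occ = 0.0;
        for (int i = 0; i <= j; ++i) {
          if (a[i] == 0.0) continue;
          const double *Cij = &C[(i * ns + j) * ns];
          double pij = 0.0;
          for (int m = i; m <= j; ++m) pij += Cij[m] * e[m];
          occ += a[i] * pij;
        }
        double lik = occ * rates[ns - 2];
        if (!(lik > 0.0)) { ll = R_NegInf; break; }
        ll += std::log(lik);
        t = age[ev];
        dead_end = true;
      } else if (k == K_DINT) {
        // probability of absorption into death within [lo, hi]
        double dlo = lo[ev] - t, dhi = hi[ev] - t;
        if (dlo < 0) dlo = 0;
        if (dhi < dlo) dhi = dlo;
        for (int m = 0; m < ns; ++m) {
          e[m] = std::exp(-q[m] * dlo);
          eh[m] = std::exp(-q[m] * dhi);
        }
        const int j = ns - 1;
        double pr = 0.0;
        for (int i = 0; i < ns - 1; ++i) {
          if (a[i] == 0.0) continue;
          const double *Cij = &C[(i * ns + j) * ns];
          double d = 0.0;
          for (int m = i; m <= j; ++m) d += Cij[m] * (eh[m] - e[m]);
          pr += a[i] * d;
        }
        if (!(pr > 0.0)) { ll = R_NegInf; break; }
        ll += std::log(pr);
        dead_end = true;
      }
      if (dead_end) break;
    }
    out[p] = ll;
  }
  return out;
}
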