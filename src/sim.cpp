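// Euler--Maruyama integrator for the stochastic neural field
//
//   dU = [ -U + eps*C0*g'(U)g(U) + (w * F(U)) + I(x - v t) ] dt
//        + sqrt(eps) g(U) dW,   <dW dW> = 2 C0 dt / (per-site lattice noise)
//
// i.e. the Ito form equivalent to Stratonovich multiplicative noise, with
// the Novikov drift correction written out explicitly.  The convolution is
// evaluated spectrally (circular FFT on the simulation grid; the domain is
// sized / buffered by the caller so wrap-around images are negligible).
// Trials evolve in parallel as matrix columns, packed two-per-complex-column
// for the FFT.  Level-set crossing positions are extracted on the fly at the
// recording cadence so ensembles never require storing full space-time
// fields.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// all up-/down-crossings of level a, with linear interpolation
static void find_crossings(const arma::vec& u, double a, bool periodic,
                           double dx, double x_min,
                           std::vector<double>& ups,
                           std::vector<double>& downs) {
  const int n = u.n_elem;
  ups.clear(); downs.clear();
  const int last = periodic ? n : (n - 1);
  for (int i = 0; i < last; ++i) {
    int j = (i + 1) % n;
    double ui = u(i), uj = u(j);
    if (ui <= a && uj > a) {
      double t = (a - ui) / (uj - ui);
      ups.push_back(x_min + (i + t) * dx);
    } else if (ui > a && uj <= a) {
      double t = (ui - a) / (ui - uj);
      downs.push_back(x_min + (i + t) * dx);
    }
  }
}

// x wrapped into [0, L)  (floor-based; avoids libm fmod)
static inline double wrap_pos(double x, double L) {
  return x - L * std::floor(x / L);
}

// signed circular difference b - a wrapped into (-L/2, L/2]
static inline double circ_diff(double b, double a, double L) {
  double d = wrap_pos(b - a, L);
  if (d > L / 2) d -= L;
  return d;
}

// pick the crossing closest to the previous (wrapped) position and return
// the unwrapped update; NaN when no crossing exists
static double track_edge(const std::vector<double>& cand, double prev_unwrapped,
                         bool periodic, double L) {
  if (cand.empty()) return NA_REAL;
  double prev_wrapped = prev_unwrapped;
  if (periodic) prev_wrapped = wrap_pos(prev_unwrapped, L);
  double best = 0, bestd = 1e300;
  for (double c : cand) {
    double d = periodic ? circ_diff(c, prev_wrapped, L) : (c - prev_wrapped);
    if (std::abs(d) < bestd) { bestd = std::abs(d); best = d; }
  }
  return prev_unwrapped + best;
}

// first frame: outermost crossings of the widest superthreshold run
static bool seed_edges(const arma::vec& u, double a, bool periodic,
                       double dx, double x_min, double L,
                       double& trail, double& lead) {
  std::vector<double> ups, downs;
  find_crossings(u, a, periodic, dx, x_min, ups, downs);
  if (ups.empty() || downs.empty()) return false;
  // widest run: for each up-crossing find the next down-crossing
  double bestw = -1;
  for (double up : ups) {
    double bestdn = 1e300; bool found = false;
    for (double dn : downs) {
      double w = periodic ? wrap_pos(dn - up, L) : (dn - up);
      if (w > 0 && w < bestdn) { bestdn = w; found = true; }
    }
    if (found && bestdn > bestw) { bestw = bestdn; trail = up;
      lead = periodic ? up + bestdn : trail + bestdn; }
  }
  return bestw > 0;
}

// [[Rcpp::export]]
List em_simulate_cpp(arma::mat u0, arma::cx_vec what,
                     double x_min, double dx, double dt, int nsteps,
                     double kappa, int firing_kind, double gain,
                     double eps, double C0, double g0, int g_kind,
                     bool has_stim, double I0, double stim_width,
                     double v, double stim_pos0,
                     bool periodic, int nbuf,
                     arma::vec levels, int record_every,
                     int n_snapshot_trials, double blowup) {
  const int nx = u0.n_rows, ntr = u0.n_cols, nlev = levels.n_elem;
  const double L = nx * dx;
  const int nrec = nsteps / record_every + 1;
  const int npair = (ntr + 1) / 2;

  arma::mat U = u0;
  arma::cx_mat Z(nx, npair);
  arma::mat conv(nx, ntr);
  arma::mat Fmat(nx, ntr);

  // recording containers
  NumericVector pos(static_cast<R_xlen_t>(nrec) * ntr * nlev * 2, NA_REAL);
  // state: unwrapped positions per (trial, level, edge)
  arma::mat trail(ntr, nlev), lead(ntr, nlev);
  arma::umat inited(ntr, nlev, arma::fill::zeros);
  NumericVector times(nrec);
  arma::cube snaps(nx, std::min(n_snapshot_trials, ntr),
                   n_snapshot_trials > 0 ? nrec : 0);
  bool blew_up = false, boundary_touch = false;
  int rec = 0;
  const double namp = std::sqrt(2.0 * C0 * dt) * std::sqrt(eps);

  std::vector<double> ups, downs;

  auto record = [&](double t, int r) {
    times[r] = t;
    for (int tr = 0; tr < ntr; ++tr) {
      arma::vec col = U.col(tr);
      for (int l = 0; l < nlev; ++l) {
        double a = levels(l);
        double tpos = NA_REAL, lpos = NA_REAL;
        if (!inited(tr, l)) {
          double tw, ld;
          if (seed_edges(col, a, periodic, dx, x_min, L, tw, ld)) {
            trail(tr, l) = tw; lead(tr, l) = ld; inited(tr, l) = 1;
            tpos = tw; lpos = ld;
          }
        } else {
          find_crossings(col, a, periodic, dx, x_min, ups, downs);
          tpos = track_edge(ups, trail(tr, l), periodic, L);
          lpos = track_edge(downs, lead(tr, l), periodic, L);
          if (R_finite(tpos)) trail(tr, l) = tpos;
          if (R_finite(lpos)) lead(tr, l) = lpos;
        }
        // layout: [rec, trial, level, edge]
        R_xlen_t base = r + (R_xlen_t)nrec * (tr + (R_xlen_t)ntr * l);
        pos[base] = tpos;
        pos[base + (R_xlen_t)nrec * ntr * nlev] = lpos;
      }
    }
    for (int trs = 0; trs < (int)snaps.n_cols; ++trs)
      snaps.slice(r).col(trs) = U.col(trs);
  };

  record(0.0, rec++);

  for (int st = 0; st < nsteps; ++st) {
    double t = st * dt;
    // firing rate
    if (firing_kind == 0) {
      for (int j = 0; j < ntr; ++j)
        for (int i = 0; i < nx; ++i)
          Fmat(i, j) = U(i, j) > kappa ? 1.0 : 0.0;
    } else {
      for (int j = 0; j < ntr; ++j)
        for (int i = 0; i < nx; ++i)
          Fmat(i, j) = 1.0 / (1.0 + std::exp(-gain * (U(i, j) - kappa)));
    }
    // spectral convolution, trials packed in pairs
    for (int pck = 0; pck < npair; ++pck) {
      int j1 = 2 * pck, j2 = 2 * pck + 1;
      for (int i = 0; i < nx; ++i)
        Z(i, pck) = arma::cx_double(Fmat(i, j1),
                                    j2 < ntr ? Fmat(i, j2) : 0.0);
    }
    {
      arma::cx_mat Fz = arma::fft(Z);
      Fz.each_col() %= what;
      Z = arma::ifft(Fz);
    }
    for (int pck = 0; pck < npair; ++pck) {
      int j1 = 2 * pck, j2 = 2 * pck + 1;
      for (int i = 0; i < nx; ++i) {
        conv(i, j1) = Z(i, pck).real();
        if (j2 < ntr) conv(i, j2) = Z(i, pck).imag();
      }
    }
    // stimulus profile at time t (shared across trials)
    arma::vec stim(nx, arma::fill::zeros);
    if (has_stim) {
      double s = stim_pos0 + v * t;
      for (int i = 0; i < nx; ++i) {
        double r0 = x_min + i * dx - s;
        if (periodic) r0 = wrap_pos(r0, L);
        if (r0 >= 0 && r0 <= stim_width) stim(i) = I0;
      }
    }
    // Euler--Maruyama update
    for (int j = 0; j < ntr; ++j) {
      for (int i = 0; i < nx; ++i) {
        double u = U(i, j);
        double g = (g_kind == 0) ? g0 * u : g0;
        double gpg = (g_kind == 0) ? g0 * g0 * u : 0.0;
        double drift = -u + eps * C0 * gpg + conv(i, j) + stim(i);
        double du = drift * dt;
        // draw only where the multiplicative amplitude is non-negligible
        // (far tails of linear g contribute < 1e-9 per step); skipping
        // unused iid draws leaves the law of the process unchanged
        if (eps > 0 && std::abs(g) * namp > 1e-9)
          du += namp * g * norm_rand();
        U(i, j) = u + du;
      }
    }
    if (!periodic && nbuf > 0) {
      U.head_rows(nbuf).zeros();
      U.tail_rows(nbuf).zeros();
    }
    if ((st + 1) % record_every == 0) record((st + 1) * dt, rec++);
    if ((st + 1) % 50 == 0) {
      if (U.has_nan() || arma::abs(U).max() > blowup) { blew_up = true; break; }
      if (!periodic) {
        int m = nbuf + 5;
        if (arma::abs(U.rows(nbuf, std::min(m, nx - 1))).max() > kappa ||
            arma::abs(U.rows(std::max(0, nx - 1 - m), nx - 1 - nbuf)).max()
              > kappa)
          boundary_touch = true;
      }
    }
  }

  pos.attr("dim") = IntegerVector::create(nrec, ntr, nlev, 2);
  return List::create(_["positions"] = pos, _["times"] = times,
                      _["snapshots"] = snaps, _["final"] = U,
                      _["blew_up"] = blew_up,
                      _["boundary_touch"] = boundary_touch,
                      _["n_recorded"] = rec);
}
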