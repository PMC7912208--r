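// Euler-Maruyama steppers for the bundled potentials.
//
// Potential ids:
//   1 quadratic_2d : par = (ax, ay),  V = (ax*x^2 + ay*y^2)/2
//   2 lemon_slice  : V = cos(4*phi) + 1/cos(phi/2) + 10*(r-1)^2 + 1/r
//   3 double_well  : V = 3*x^4 - 5*x^2 + 1.5*x + 3*y^2
//   4 chain5       : par = (kb, r0, ka, theta0, c1, n1, c2, n2), 15-dim
//                    5-bead chain with harmonic bonds/angles + cosine dihedrals
//
// Noise is drawn from R's RNG (norm_rand) so a single set.seed() in R makes
// trajectories bit-reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void cross3(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline double norm3(const double *a) { return std::sqrt(dot3(a, a)); }

// gradient of a harmonic angle term k*(theta - theta0)^2 at vertex j
static void angle_grad(const double *ri, const double *rj, const double *rk,
                       double k, double theta0, double *gi, double *gj,
                       double *gk) {
  double u[3], w[3];
  for (int c = 0; c < 3; ++c) {
    u[c] = ri[c] - rj[c];
    w[c] = rk[c] - rj[c];
  }
  double nu = norm3(u), nw = norm3(w);
  double ct = dot3(u, w) / (nu * nw);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  double st = std::sqrt(1.0 - ct * ct);
  if (st < 1e-10) st = 1e-10;
  double theta = std::acos(ct);
  double pref = 2.0 * k * (theta - theta0) * (-1.0 / st);
  for (int c = 0; c < 3; ++c) {
    double dti = (w[c] / nw - ct * u[c] / nu) / nu; // d cos(theta)/d ri
    double dtk = (u[c] / nu - ct * w[c] / nw) / nw;
    gi[c] += pref * dti;
    gk[c] += pref * dtk;
    gj[c] += -pref * (dti + dtk);
  }
}

// dihedral angle over atoms 1-2-3-4 and its gradient (standard MD formulas)
static double dihedral(const double *r1, const double *r2, const double *r3,
                       const double *r4, double *g1, double *g2, double *g3,
                       double *g4) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m[3];
  for (int c = 0; c < 3; ++c) {
    b1[c] = r2[c] - r1[c];
    b2[c] = r3[c] - r2[c];
    b3[c] = r4[c] - r3[c];
  }
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  cross3(n1, n2, m);
  double nb2 = norm3(b2);
  double phi = std::atan2(dot3(m, b2) / nb2, dot3(n1, n2));
  double nn1 = dot3(n1, n1), nn2 = dot3(n2, n2);
  if (nn1 < 1e-14) nn1 = 1e-14;
  if (nn2 < 1e-14) nn2 = 1e-14;
  double f1[3], f4[3];
  for (int c = 0; c < 3; ++c) {
    f1[c] = -nb2 / nn1 * n1[c]; // d phi / d r1
    f4[c] = nb2 / nn2 * n2[c];  // d phi / d r4
  }
  double t12 = dot3(b1, b2) / (nb2 * nb2);
  double t32 = dot3(b3, b2) / (nb2 * nb2);
  for (int c = 0; c < 3; ++c) {
    g1[c] = f1[c];
    g2[c] = -(1.0 + t12) * f1[c] + t32 * f4[c];
    g3[c] = t12 * f1[c] - (1.0 + t32) * f4[c];
    g4[c] = f4[c];
  }
  return phi;
}

// gradient of the bundled potentials; writes d components into g
static void grad_pot(int pid, const double *par, const double *x, double *g,
                     int d) {
  switch (pid) {
  case 1: { // quadratic_2d
    g[0] = par[0] * x[0];
    g[1] = par[1] * x[1];
    break;
  }
  case 2: { // lemon_slice
    double r2 = x[0] * x[0] + x[1] * x[1];
    double r = std::sqrt(r2);
    if (r < 1e-12) r = 1e-12;
    double phi = std::atan2(x[1], x[0]);
    double Vr = 20.0 * (r - 1.0) - 1.0 / (r * r);
    double ch = std::cos(0.5 * phi);
    double Vphi = -4.0 * std::sin(4.0 * phi) + 0.5 * std::sin(0.5 * phi) / (ch * ch);
    // chain rule with dr = (x,y)/r, dphi = (-y, x)/r^2
    g[0] = Vr * x[0] / r - Vphi * x[1] / r2;
    g[1] = Vr * x[1] / r + Vphi * x[0] / r2;
    break;
  }
  case 3: { // double_well
    g[0] = 12.0 * x[0] * x[0] * x[0] - 10.0 * x[0] + 1.5;
    g[1] = 6.0 * x[1];
    break;
  }
  case 4: { // chain5
    double kb = par[0], r0 = par[1], ka = par[2], th0 = par[3];
    double c1 = par[4], n1 = par[5], c2 = par[6], n2 = par[7];
    for (int i = 0; i < d; ++i) g[i] = 0.0;
    const double *at[5];
    double *ga[5];
    for (int i = 0; i < 5; ++i) {
      at[i] = x + 3 * i;
      ga[i] = g + 3 * i;
    }
    for (int i = 0; i < 4; ++i) { // bonds
      double dv[3];
      for (int c = 0; c < 3; ++c) dv[c] = at[i + 1][c] - at[i][c];
      double r = norm3(dv);
      if (r < 1e-12) r = 1e-12;
      double pref = 2.0 * kb * (r - r0) / r;
      for (int c = 0; c < 3; ++c) {
        ga[i][c] -= pref * dv[c];
        ga[i + 1][c] += pref * dv[c];
      }
    }
    for (int i = 0; i < 3; ++i) // angles at vertices 2,3,4
      angle_grad(at[i], at[i + 1], at[i + 2], ka, th0, ga[i], ga[i + 1],
                 ga[i + 2]);
    for (int i = 0; i < 2; ++i) { // dihedrals 1-2-3-4 and 2-3-4-5
      double g1[3], g2[3], g3[3], g4[3];
      double phi = dihedral(at[i], at[i + 1], at[i + 2], at[i + 3], g1, g2, g3, g4);
      double cc = (i == 0) ? c1 : c2;
      double nn = (i == 0) ? n1 : n2;
      double pref = -cc * nn * std::sin(nn * phi); // d/dphi of c*(1+cos(n phi))
      for (int c = 0; c < 3; ++c) {
        ga[i][c] += pref * g1[c];
        ga[i + 1][c] += pref * g2[c];
        ga[i + 2][c] += pref * g3[c];
        ga[i + 3][c] += pref * g4[c];
      }
    }
    break;
  }
  default:
    stop("unknown potential id");
  }
}

// [[Rcpp::export]]
NumericVector potential_grad_cpp(int pid, NumericVector par, NumericMatrix x) {
  int n = x.nrow(), d = x.ncol();
  NumericMatrix g(n, d);
  std::vector<double> xi(d), gi(d);
  for (int m = 0; m < n; ++m) {
    for (int k = 0; k < d; ++k) xi[k] = x(m, k);
    grad_pot(pid, par.begin(), xi.data(), gi.data(), d);
    for (int k = 0; k < d; ++k) g(m, k) = gi[k];
  }
  g.attr("dim") = Dimension(n, d);
  return g;
}

// [[Rcpp::export]]
List sim_overdamped_cpp(int pid, NumericVector par, NumericVector x0,
                        double dt, double n_steps_d, double beta, double gamma,
                        int burn_in, double guard, double noise_factor) {
  R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  int d = x0.size();
  R_xlen_t keep = n_steps + 1 - burn_in;
  NumericMatrix out(keep, d);
  std::vector<double> x(x0.begin(), x0.end()), g(d);
  double sig = noise_factor * std::sqrt(2.0 / (beta * gamma) * dt);
  double ig = 1.0 / gamma;
  if (burn_in == 0)
    for (int k = 0; k < d; ++k) out(0, k) = x[k];
  for (R_xlen_t s = 1; s <= n_steps; ++s) {
    grad_pot(pid, par.begin(), x.data(), g.data(), d);
    bool bad = false;
    for (int k = 0; k < d; ++k) {
      x[k] += -ig * g[k] * dt + sig * norm_rand();
      if (!std::isfinite(x[k]) || std::fabs(x[k]) > guard) bad = true;
    }
    if (bad) stop("simulation diverged at step %td", (ptrdiff_t)s);
    if (s >= burn_in)
      for (int k = 0; k < d; ++k) out(s - burn_in, k) = x[k];
  }
  return List::create(_["states"] = out);
}

// [[Rcpp::export]]
List sim_underdamped_cpp(int pid, NumericVector par, NumericVector x0,
                         double dt, double n_steps_d, double beta, double gamma,
                         int burn_in, double guard, double noise_factor) {
  R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  int d2 = x0.size();
  int d = d2 / 2;
  R_xlen_t keep = n_steps + 1 - burn_in;
  NumericMatrix out(keep, d2);
  std::vector<double> q(d), p(d), g(d);
  for (int k = 0; k < d; ++k) {
    q[k] = x0[k];
    p[k] = x0[d + k];
  }
  double sig = noise_factor * std::sqrt(2.0 * gamma / beta * dt);
  if (burn_in == 0)
    for (int k = 0; k < d; ++k) {
      out(0, k) = q[k];
      out(0, d + k) = p[k];
    }
  for (R_xlen_t s = 1; s <= n_steps; ++s) {
    grad_pot(pid, par.begin(), q.data(), g.data(), d);
    bool bad = false;
    for (int k = 0; k < d; ++k) {
      double qn = q[k] + p[k] * dt;
      double pn = p[k] + (-g[k] - gamma * p[k]) * dt + sig * norm_rand();
      q[k] = qn;
      p[k] = pn;
      if (!std::isfinite(qn) || !std::isfinite(pn) || std::fabs(qn) > guard)
        bad = true;
    }
    if (bad) stop("simulation diverged at step %td", (ptrdiff_t)s);
    if (s >= burn_in)
      for (int k = 0; k < d; ++k) {
        out(s - burn_in, k) = q[k];
        out(s - burn_in, d + k) = p[k];
      }
  }
  return List::create(_["states"] = out);
}

// dihedral values + Jacobians for a matrix of chain states (one dihedral
// defined by columns of idx, 1-based atom indices)
// [[Rcpp::export]]
List dihedral_batch_cpp(NumericMatrix x, IntegerVector idx) {
  int n = x.nrow();
  NumericVector phi(n);
  NumericMatrix J(n, x.ncol());
  int a1 = (idx[0] - 1) * 3, a2 = (idx[1] - 1) * 3, a3 = (idx[2] - 1) * 3,
      a4 = (idx[3] - 1) * 3;
  double r1[3], r2[3], r3[3], r4[3], g1[3], g2[3], g3[3], g4[3];
  for (int m = 0; m < n; ++m) {
    for (int c = 0; c < 3; ++c) {
      r1[c] = x(m, a1 + c);
      r2[c] = x(m, a2 + c);
      r3[c] = x(m, a3 + c);
      r4[c] = x(m, a4 + c);
    }
    phi[m] = dihedral(r1, r2, r3, r4, g1, g2, g3, g4);
    for (int c = 0; c < 3; ++c) {
      J(m, a1 + c) = g1[c];
      J(m, a2 + c) = g2[c];
      J(m, a3 + c) = g3[c];
      J(m, a4 + c) = g4[c];
    }
  }
  return List::create(_["phi"] = phi, _["jacobian"] = J);
}
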