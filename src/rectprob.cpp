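// Multivariate-normal rectangle probabilities for ordinal twin-pair likelihoods.
//
// bvnu(): Genz's hybrid algorithm for the bivariate normal upper-tail
// probability (Gauss-Legendre on the tetrachoric series for moderate |r|,
// asymptotic expansion near |r| = 1); absolute error below 5e-16.
//
// rect_prob(): rectangle probability for a 2-4 dimensional standard normal
// with correlation matrix R.  Dimensions with (-Inf, Inf) bounds are
// marginalised out; the two narrowest remaining dimensions are integrated by
// panelled tensor Gauss-Legendre quadrature and the other dimensions by the
// analytic conditional bivariate CDF.  Deterministic by construction.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586;
static const double ZCLAMP = 37.0;  // standardised conditional bounds clamp

static inline double phid(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// Gauss-Legendre half-rules (positive nodes) as in Genz's TVPACK
static const double GX3[3] = {0.9324695142031522, 0.6612093864662647,
                              0.2386191860831970};
static const double GW3[3] = {0.1713244923791705, 0.3607615730481384,
                              0.4679139345726904};
static const double GX6[6] = {0.9815606342467191, 0.9041172563704750,
                              0.7699026741943050, 0.5873179542866171,
                              0.3678314989981802, 0.1252334085114692};
static const double GW6[6] = {0.04717533638651177, 0.1069393259953183,
                              0.1600783285433464,  0.2031674267230659,
                              0.2334925365383547,  0.2491470458134029};
static const double GX10[10] = {0.9931285991850949,  0.9639719272779138,
                                0.9122344282513259,  0.8391169718222188,
                                0.7463319064601508,  0.6360536807265150,
                                0.5108670019508271,  0.3737060887154196,
                                0.2277858511416451,  0.07652652113349733};
static const double GW10[10] = {0.01761400713915212, 0.04060142980038694,
                                0.06267204833410906, 0.08327674157670475,
                                0.1019301198172404,  0.1181945319615184,
                                0.1316886384491766,  0.1420961093183821,
                                0.1491729864726037,  0.1527533871307259};

// P(X > dh, Y > dk) for standard bivariate normal, finite dh, dk, |r| < 1.
static double bvnu_raw(double dh, double dk, double r) {
  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  const double *x, *w;
  int lg;
  double ar = std::fabs(r);
  if (ar < 0.3)       { lg = 3;  x = GX3;  w = GW3;  }
  else if (ar < 0.75) { lg = 6;  x = GX6;  w = GW6;  }
  else                { lg = 10; x = GX10; w = GW10; }
  if (ar < 0.925) {
    double hs = (h * h + k * k) / 2.0, asr = std::asin(r);
    for (int i = 0; i < lg; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
        bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / (2.0 * TWOPI) + phid(-h) * phid(-k);
  } else {
    if (r < 0) { k = -k; hk = -hk; }
    if (ar < 1) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asr0 = -(bs / as + hk) / 2.0;
      if (asr0 > -100.0)
        bvn = a * std::exp(asr0) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs), sp = std::sqrt(TWOPI) * phid(-b / a);
        bvn -= std::exp(-hk / 2.0) * sp * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr1 = -(bs / xs + hk) / 2.0;
          if (asr1 > -100.0) {
            double sp2 = 1.0 + c * xs * (1.0 + d * xs);
            double ep = std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs;
            bvn += a * w[i] * std::exp(asr1) * (ep - sp2);
          }
        }
      }
      bvn = -bvn / TWOPI;
    }
    if (r > 0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// P(X > h, Y > k) with infinite bounds and degenerate r handled.
static double bvnu(double h, double k, double r) {
  if (h == R_PosInf || k == R_PosInf) return 0.0;
  if (h == R_NegInf) return (k == R_NegInf) ? 1.0 : phid(-k);
  if (k == R_NegInf) return phid(-h);
  if (r > 1.0) r = 1.0;
  if (r < -1.0) r = -1.0;
  if (r == 1.0) return phid(-std::max(h, k));
  if (r == -1.0) return std::max(0.0, phid(-k) - phid(h));
  return bvnu_raw(h, k, r);
}

// P(l1 < X < u1, l2 < Y < u2)
static double rect2(double l1, double u1, double l2, double u2, double r) {
  double p = bvnu(l1, l2, r) - bvnu(u1, l2, r) - bvnu(l1, u2, r) +
             bvnu(u1, u2, r);
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

static double rect1(double l, double u) {
  double p = phid(u == R_PosInf ? ZCLAMP : u) - phid(l == R_NegInf ? -ZCLAMP : l);
  return std::max(0.0, p);
}

// 8-point full rule (positive half)
static const double GX4[4] = {0.1834346424956498, 0.5255324099163290,
                              0.7966664774136267, 0.9602898564975363};
static const double GW4[4] = {0.3626837833783620, 0.3137066458778873,
                              0.2223810344533745, 0.1012285362903763};

// Fill node/weight arrays for panelled quadrature over [a, b].
// Returns number of nodes written (caller guarantees capacity).
static int panel_nodes(double a, double b, double pw, int np, double *xs,
                       double *ws) {
  int m = (int)std::ceil((b - a) / pw);
  if (m < 1) m = 1;
  const double *hx, *hw;
  int hn;
  if (np >= 10) { hx = GX6; hw = GW6; hn = 6; }
  else          { hx = GX4; hw = GW4; hn = 4; }
  int cnt = 0;
  double step = (b - a) / m;
  for (int j = 0; j < m; j++) {
    double c = a + (j + 0.5) * step, h = step / 2.0;
    for (int i = 0; i < hn; i++) {
      xs[cnt] = c - h * hx[i]; ws[cnt] = h * hw[i]; cnt++;
      xs[cnt] = c + h * hx[i]; ws[cnt] = h * hw[i]; cnt++;
    }
  }
  return cnt;
}

#define MAXNODES 1024

// General rectangle probability, d in 1..4, R col-major d x d.
static double rect_prob(int d, const double *L, const double *U,
                        const double *Rm, double pw, int np, double xtr) {
  // drop dimensions with (-Inf, Inf) bounds (exact marginalisation)
  int idx[4], m = 0;
  for (int i = 0; i < d; i++)
    if (!(L[i] == R_NegInf && U[i] == R_PosInf)) idx[m++] = i;
  if (m == 0) return 1.0;
  if (m == 1) return rect1(L[idx[0]], U[idx[0]]);
  if (m == 2) {
    double r = Rm[idx[0] + d * idx[1]];
    return rect2(L[idx[0]], U[idx[0]], L[idx[1]], U[idx[1]], r);
  }

  // truncated widths; pick the narrowest dims for numeric integration
  double wd[4];
  for (int j = 0; j < m; j++) {
    double a = std::max(L[idx[j]], -xtr), b = std::min(U[idx[j]], xtr);
    wd[j] = b - a;
    if (wd[j] <= 0.0) return 0.0;  // interval entirely beyond truncation
  }

  if (m == 3) {
    // outer = narrowest dim, conditioned = other two
    int jo = 0;
    for (int j = 1; j < 3; j++) if (wd[j] < wd[jo]) jo = j;
    int o = idx[jo], c0 = -1, c1 = -1;
    for (int j = 0; j < 3; j++) {
      if (j == jo) continue;
      if (c0 < 0) c0 = idx[j]; else c1 = idx[j];
    }
    double b0 = Rm[c0 + d * o], b1 = Rm[c1 + d * o];
    double s00 = 1.0 - b0 * b0, s11 = 1.0 - b1 * b1;
    double s01 = Rm[c0 + d * c1] - b0 * b1;
    double sd0 = std::sqrt(std::max(s00, 1e-12));
    double sd1 = std::sqrt(std::max(s11, 1e-12));
    double rho = s01 / (sd0 * sd1);
    if (rho > 1.0) rho = 1.0;
    if (rho < -1.0) rho = -1.0;
    double a = std::max(L[o], -xtr), b = std::min(U[o], xtr);
    double xs[MAXNODES], ws[MAXNODES];
    int n = panel_nodes(a, b, pw, np, xs, ws);
    double sum = 0.0;
    for (int i = 0; i < n; i++) {
      double x = xs[i];
      double mu0 = b0 * x, mu1 = b1 * x;
      double l0 = (L[c0] == R_NegInf) ? R_NegInf : (L[c0] - mu0) / sd0;
      double u0 = (U[c0] == R_PosInf) ? R_PosInf : (U[c0] - mu0) / sd0;
      double l1 = (L[c1] == R_NegInf) ? R_NegInf : (L[c1] - mu1) / sd1;
      double u1 = (U[c1] == R_PosInf) ? R_PosInf : (U[c1] - mu1) / sd1;
      sum += ws[i] * R::dnorm(x, 0.0, 1.0, 0) * rect2(l0, u0, l1, u1, rho);
    }
    return std::max(0.0, std::min(1.0, sum));
  }

  // m == 4: outer = two narrowest dims
  int ord[4] = {0, 1, 2, 3};
  for (int a = 0; a < 3; a++)
    for (int b2 = a + 1; b2 < 4; b2++)
      if (wd[ord[b2]] < wd[ord[a]]) { int t = ord[a]; ord[a] = ord[b2]; ord[b2] = t; }
  int o0 = idx[ord[0]], o1 = idx[ord[1]], c0 = idx[ord[2]], c1 = idx[ord[3]];
  double roo = Rm[o0 + d * o1];
  if (roo > 0.999999) roo = 0.999999;
  if (roo < -0.999999) roo = -0.999999;
  double det = 1.0 - roo * roo;
  // B = Sigma_co Sigma_oo^{-1}, rows = conditioned dims
  double r00 = Rm[c0 + d * o0], r01 = Rm[c0 + d * o1];
  double r10 = Rm[c1 + d * o0], r11 = Rm[c1 + d * o1];
  double B00 = (r00 - roo * r01) / det, B01 = (r01 - roo * r00) / det;
  double B10 = (r10 - roo * r11) / det, B11 = (r11 - roo * r10) / det;
  double s00 = 1.0 - (B00 * r00 + B01 * r01);
  double s11 = 1.0 - (B10 * r10 + B11 * r11);
  double s01 = Rm[c0 + d * c1] - (B00 * r10 + B01 * r11);
  double sd0 = std::sqrt(std::max(s00, 1e-12));
  double sd1 = std::sqrt(std::max(s11, 1e-12));
  double rho = s01 / (sd0 * sd1);
  if (rho > 1.0) rho = 1.0;
  if (rho < -1.0) rho = -1.0;

  double a0 = std::max(L[o0], -xtr), b0 = std::min(U[o0], xtr);
  double a1 = std::max(L[o1], -xtr), b1 = std::min(U[o1], xtr);
  double x0[MAXNODES], w0[MAXNODES], x1[MAXNODES], w1[MAXNODES];
  int n0 = panel_nodes(a0, b0, pw, np, x0, w0);
  int n1 = panel_nodes(a1, b1, pw, np, x1, w1);
  double dens_c = 1.0 / (TWOPI * std::sqrt(det));
  double sum = 0.0;
  for (int i = 0; i < n0; i++) {
    double x = x0[i];
    for (int j = 0; j < n1; j++) {
      double y = x1[j];
      double q = (x * x - 2.0 * roo * x * y + y * y) / (2.0 * det);
      if (q > 40.0) continue;
      double f = dens_c * std::exp(-q);
      double mu0 = B00 * x + B01 * y, mu1 = B10 * x + B11 * y;
      double l0 = (L[c0] == R_NegInf) ? R_NegInf : (L[c0] - mu0) / sd0;
      double u0 = (U[c0] == R_PosInf) ? R_PosInf : (U[c0] - mu0) / sd0;
      double l1 = (L[c1] == R_NegInf) ? R_NegInf : (L[c1] - mu1) / sd1;
      double u1 = (U[c1] == R_PosInf) ? R_PosInf : (U[c1] - mu1) / sd1;
      sum += w0[i] * w1[j] * f * rect2(l0, u0, l1, u1, rho);
    }
  }
  return std::max(0.0, std::min(1.0, sum));
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_bvnu(NumericVector h, NumericVector k, NumericVector r) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = bvnu(h[i], k[i], r[i]);
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_rect_probs(NumericMatrix Rm, NumericMatrix lower,
                             NumericMatrix upper, double panel_width = 2.0,
                             int gl_pts = 8, double xtrunc = 8.5) {
  int d = Rm.ncol(), n = lower.nrow();
  NumericVector out(n);
  std::vector<double> R(d * d);
  for (int j = 0; j < d; j++)
    for (int i = 0; i < d; i++) R[i + d * j] = Rm(i, j);
  std::vector<double> L(d), U(d);
  for (int c = 0; c < n; c++) {
    for (int i = 0; i < d; i++) { L[i] = lower(c, i); U[i] = upper(c, i); }
    out[c] = rect_prob(d, L.data(), U.data(), R.data(), panel_width, gl_pts,
                       xtrunc);
  }
  return out;
}
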