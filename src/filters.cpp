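// Scale-space filtering: separable Gaussian smoothing and multiscale
// Hessian-based vesselness on 3D volumes stored column-major (R arrays).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<float> fvec;

// mirror boundary: -1 -> 0, n -> n-1 (edge-inclusive reflection)
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static std::vector<float> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<float> k(2 * r + 1);
  double s = 0.0;
  for (int m = -r; m <= r; ++m) {
    double w = std::exp(-0.5 * (m / sigma) * (m / sigma));
    k[m + r] = (float)w;
    s += w;
  }
  for (auto &w : k) w = (float)(w / s);
  return k;
}

// in-place separable convolution along one axis with reflected boundaries
static void conv_axis(fvec &a, const int n1, const int n2, const int n3,
                      int axis, const std::vector<float> &ker) {
  const int r = (int)ker.size() / 2;
  const int len = (axis == 0) ? n1 : (axis == 1) ? n2 : n3;
  const long stride = (axis == 0) ? 1L : (axis == 1) ? (long)n1 : (long)n1 * n2;
  std::vector<float> buf(len), out(len);
  // iterate over all lines perpendicular to `axis`
  const int u1 = (axis == 0) ? n2 : n1;
  const int u2 = (axis == 2) ? n2 : n3;
  for (int b = 0; b < u2; ++b) {
    for (int a2 = 0; a2 < u1; ++a2) {
      long base;
      if (axis == 0) base = (long)n1 * (a2 + (long)n2 * b);
      else if (axis == 1) base = a2 + (long)n1 * n2 * b;
      else base = a2 + (long)n1 * b;
      for (int t = 0; t < len; ++t) buf[t] = a[base + stride * t];
      for (int t = 0; t < len; ++t) {
        float s = 0.0f;
        if (t >= r && t + r < len) {
          const float *bp = &buf[t - r];
          for (int m = 0; m < (int)ker.size(); ++m) s += ker[m] * bp[m];
        } else {
          for (int m = -r; m <= r; ++m) s += ker[m + r] * buf[refl(t + m, len)];
        }
        out[t] = s;
      }
      for (int t = 0; t < len; ++t) a[base + stride * t] = out[t];
    }
  }
}

static void smooth3(fvec &a, int n1, int n2, int n3, double sigma) {
  std::vector<float> ker = gauss_kernel(sigma);
  conv_axis(a, n1, n2, n3, 0, ker);
  conv_axis(a, n1, n2, n3, 1, ker);
  conv_axis(a, n1, n2, n3, 2, ker);
}

// [[Rcpp::export]]
NumericVector gauss_smooth3d_cpp(NumericVector vol, IntegerVector dims,
                                 double sigma) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  long N = (long)n1 * n2 * n3;
  fvec a(N);
  for (long i = 0; i < N; ++i) a[i] = (float)vol[i];
  smooth3(a, n1, n2, n3, sigma);
  NumericVector out(N);
  for (long i = 0; i < N; ++i) out[i] = a[i];
  out.attr("dim") = dims;
  return out;
}

// analytic eigenvalues of a symmetric 3x3 matrix (trigonometric method)
static inline void eig3_sym(double a11, double a22, double a33, double a12,
                            double a13, double a23, double &e1, double &e2,
                            double &e3) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) { e1 = a11; e2 = a22; e3 = a33; return; }
  double q = (a11 + a22 + a33) / 3.0;
  double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
  double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  double ip = 1.0 / p;
  // det(B)/2 with B = (A - qI)/p
  double detB = (b11 * (b22 * b33 - a23 * a23) - a12 * (a12 * b33 - a23 * a13) +
                 a13 * (a12 * a23 - b22 * a13)) * ip * ip * ip;
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  e1 = q + 2.0 * p * std::cos(phi);
  e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  e2 = 3.0 * q - e1 - e3;
}

// Multiscale Frangi vesselness. `dark`: tubes darker than background (the
// volume is negated internally so the bright-tube eigenvalue convention
// applies). Second derivatives are gamma-normalized (multiplied by s^2).
// [[Rcpp::export]]
NumericVector frangi_cpp(NumericVector vol, IntegerVector dims,
                         NumericVector scales, double alpha, double beta,
                         double cpar, bool dark) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long N = (long)n1 * n2 * n3;
  fvec base(N);
  for (long i = 0; i < N; ++i) base[i] = dark ? -(float)vol[i] : (float)vol[i];
  fvec best(N, 0.0f);
  const double ia2 = 1.0 / (2.0 * alpha * alpha);
  const double ib2 = 1.0 / (2.0 * beta * beta);
  const double ic2 = 1.0 / (2.0 * cpar * cpar);

  // precomputed reflected neighbour indices per axis
  std::vector<int> xm(n1), xp(n1), ym(n2), yp(n2), zm(n3), zp(n3);
  for (int i = 0; i < n1; ++i) { xm[i] = refl(i - 1, n1); xp[i] = refl(i + 1, n1); }
  for (int j = 0; j < n2; ++j) { ym[j] = refl(j - 1, n2); yp[j] = refl(j + 1, n2); }
  for (int k = 0; k < n3; ++k) { zm[k] = refl(k - 1, n3); zp[k] = refl(k + 1, n3); }

  fvec sm(N);
  for (int si = 0; si < scales.size(); ++si) {
    double s = scales[si];
    sm = base;
    smooth3(sm, n1, n2, n3, s);
    const double s2 = s * s;
    for (int k = 0; k < n3; ++k) {
      const long ozm = (long)n1 * n2 * zm[k], ozp = (long)n1 * n2 * zp[k];
      const long oz = (long)n1 * n2 * k;
      for (int j = 0; j < n2; ++j) {
        const long oym = (long)n1 * ym[j], oyp = (long)n1 * yp[j];
        const long oy = (long)n1 * j;
        for (int i = 0; i < n1; ++i) {
          const long c = i + oy + oz;
          const double f0 = sm[c];
          const double hxx = s2 * (sm[xm[i] + oy + oz] + sm[xp[i] + oy + oz] - 2.0 * f0);
          const double hyy = s2 * (sm[i + oym + oz] + sm[i + oyp + oz] - 2.0 * f0);
          const double hzz = s2 * (sm[i + oy + ozm] + sm[i + oy + ozp] - 2.0 * f0);
          const double hxy = 0.25 * s2 *
            (sm[xp[i] + oyp + oz] - sm[xp[i] + oym + oz] -
             sm[xm[i] + oyp + oz] + sm[xm[i] + oym + oz]);
          const double hxz = 0.25 * s2 *
            (sm[xp[i] + oy + ozp] - sm[xp[i] + oy + ozm] -
             sm[xm[i] + oy + ozp] + sm[xm[i] + oy + ozm]);
          const double hyz = 0.25 * s2 *
            (sm[i + oyp + ozp] - sm[i + oyp + ozm] -
             sm[i + oym + ozp] + sm[i + oym + ozm]);
          double l1, l2, l3;
          eig3_sym(hxx, hyy, hzz, hxy, hxz, hyz, l1, l2, l3);
          // sort by |lambda| ascending
          double a1 = std::fabs(l1), a2 = std::fabs(l2), a3 = std::fabs(l3);
          double t;
          if (a1 > a2) { t = l1; l1 = l2; l2 = t; t = a1; a1 = a2; a2 = t; }
          if (a2 > a3) { t = l2; l2 = l3; l3 = t; t = a2; a2 = a3; a3 = t; }
          if (a1 > a2) { t = l1; l1 = l2; l2 = t; t = a1; a1 = a2; a2 = t; }
          if (l2 > 0.0 || l3 > 0.0 || a3 == 0.0) continue; // not a bright ridge
          const double Ra = a2 / a3;
          const double Rb2 = (a1 * a1) / (a2 * a3);
          const double S2 = a1 * a1 + a2 * a2 + a3 * a3;
          const double v = (1.0 - std::exp(-Ra * Ra * ia2)) *
                           std::exp(-Rb2 * ib2) *
                           (1.0 - std::exp(-S2 * ic2));
          if (v > best[c]) best[c] = (float)v;
        }
      }
    }
  }
  NumericVector out(N);
  for (long i = 0; i < N; ++i) out[i] = best[i];
  out.attr("dim") = dims;
  return out;
}
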