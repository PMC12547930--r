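// Texture feature extraction for small 2D subimages.
//
// Implements the 118-feature catalogue: 23 first-order (FOS), 25 grey-level
// co-occurrence (GLCM), 16 run-length (GLRLM), 16 size-zone (GLSZM), 16
// distance-zone (GLDZM), 5 neighbourhood grey-tone difference (NGTDM) and 17
// neighbouring grey-level dependence (NGLDM) features, following the IBSI
// reference definitions. All texture families operate on fixed-bin-number
// discretised grey levels; FOS intensity statistics operate on raw values.
//
// Conventions for degenerate (constant) inputs are fixed so that no feature
// is ever non-finite: variance-normalised quantities (skewness, kurtosis,
// CoV, GLCM correlation, information correlations) are 0; NGTDM coarseness
// saturates at 1e6 (IBSI convention).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double LOG2 = 0.6931471805599453;

static inline double log2d(double x) { return std::log(x) / LOG2; }

// R type-7 quantile on a sorted vector
static double quantile7(const std::vector<double>& s, double p) {
  int n = s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return s[n - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// ---------------------------------------------------------------------------
// discretisation: fixed bin number over the window's own min-max range
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_discretise")]]
IntegerMatrix cpp_discretise(NumericMatrix x, int ng) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lv(nr, nc);
  double mn = R_PosInf, mx = R_NegInf;
  for (int i = 0; i < nr * nc; i++) {
    if (x[i] < mn) mn = x[i];
    if (x[i] > mx) mx = x[i];
  }
  double rng = mx - mn;
  for (int i = 0; i < nr * nc; i++) {
    if (rng <= 0) { lv[i] = 1; continue; }
    int k = (int)std::floor(ng * (x[i] - mn) / rng) + 1;
    if (k > ng) k = ng;
    if (k < 1) k = 1;
    lv[i] = k;
  }
  return lv;
}

// ---------------------------------------------------------------------------
// FOS: 23 first-order features (raw intensities + discretised histogram)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_fos")]]
NumericVector cpp_fos(NumericMatrix x, IntegerMatrix lv, int ng) {
  int n = x.nrow() * x.ncol();
  std::vector<double> v(x.begin(), x.end());
  std::vector<double> s(v);
  std::sort(s.begin(), s.end());

  double mean = 0;
  for (double xi : v) mean += xi;
  mean /= n;
  double m2 = 0, m3 = 0, m4 = 0;
  for (double xi : v) {
    double d = xi - mean;
    m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
  }
  m2 /= n; m3 /= n; m4 /= n;
  double var = m2;
  double skew = (var > 0) ? m3 / std::pow(var, 1.5) : 0.0;
  double kurt = (var > 0) ? m4 / (var * var) - 3.0 : 0.0;

  double med = quantile7(s, 0.5);
  double mn = s.front(), mx = s.back();
  double p10 = quantile7(s, 0.10), p90 = quantile7(s, 0.90);
  double q25 = quantile7(s, 0.25), q75 = quantile7(s, 0.75);
  double iqr = q75 - q25, range = mx - mn;

  double mad = 0;
  for (double xi : v) mad += std::fabs(xi - mean);
  mad /= n;

  // robust MAD: values within [p10, p90], absolute deviation from their mean
  double rsum = 0; int rn = 0;
  for (double xi : v) if (xi >= p10 && xi <= p90) { rsum += xi; rn++; }
  double rmad = 0;
  if (rn > 0) {
    double rmean = rsum / rn;
    for (double xi : v) if (xi >= p10 && xi <= p90) rmad += std::fabs(xi - rmean);
    rmad /= rn;
  }

  double medad = 0;
  for (double xi : v) medad += std::fabs(xi - med);
  medad /= n;

  double cov = (var > 0 && mean != 0) ? std::sqrt(var) / mean : 0.0;
  double qcd = (q75 + q25 != 0) ? (q75 - q25) / (q75 + q25) : 0.0;

  // discretised histogram
  std::vector<double> h(ng, 0.0);
  for (int i = 0; i < n; i++) h[lv[i] - 1] += 1.0;
  int mode = 1; double hmax = h[0];
  for (int k = 1; k < ng; k++) if (h[k] > hmax) { hmax = h[k]; mode = k + 1; }
  double entropy = 0, unif = 0;
  for (int k = 0; k < ng; k++) {
    double p = h[k] / n;
    if (p > 0) entropy -= p * log2d(p);
    unif += p * p;
  }

  // histogram gradient (IBSI): central differences, one-sided at the ends
  double gmax = 0, gmin = 0; int gmaxl = 1, gminl = 1;
  if (ng >= 2) {
    std::vector<double> g(ng);
    g[0] = h[1] - h[0];
    g[ng - 1] = h[ng - 1] - h[ng - 2];
    for (int k = 1; k < ng - 1; k++) g[k] = (h[k + 1] - h[k - 1]) / 2.0;
    gmax = g[0]; gmin = g[0];
    for (int k = 1; k < ng; k++) {
      if (g[k] > gmax) { gmax = g[k]; gmaxl = k + 1; }
      if (g[k] < gmin) { gmin = g[k]; gminl = k + 1; }
    }
  }

  NumericVector out(23);
  out[0] = mean;  out[1] = var;   out[2] = skew;  out[3] = kurt;
  out[4] = med;   out[5] = mn;    out[6] = p10;   out[7] = p90;
  out[8] = mx;    out[9] = mode;  out[10] = iqr;  out[11] = range;
  out[12] = mad;  out[13] = rmad; out[14] = medad; out[15] = cov;
  out[16] = qcd;  out[17] = entropy; out[18] = unif;
  out[19] = gmax; out[20] = gmaxl; out[21] = gmin; out[22] = gminl;
  return out;
}

// ---------------------------------------------------------------------------
// GLCM: distance 1, 4 directions, symmetric; features averaged
// ---------------------------------------------------------------------------

static const int DIR_DR[4] = { 0, -1, -1, -1 };  // 0, 45, 90, 135 degrees
static const int DIR_DC[4] = { 1,  1,  0, -1 };

static NumericMatrix glcm_one(const IntegerMatrix& lv, int ng, int dir) {
  int nr = lv.nrow(), nc = lv.ncol();
  NumericMatrix m(ng, ng);
  int dr = DIR_DR[dir], dc = DIR_DC[dir];
  double tot = 0;
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      int r2 = r + dr, c2 = c + dc;
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int a = lv(r, c) - 1, b = lv(r2, c2) - 1;
      m(a, b) += 1; m(b, a) += 1; tot += 2;
    }
  }
  if (tot > 0) for (int i = 0; i < ng * ng; i++) m[i] /= tot;
  return m;
}

// [[Rcpp::export(name = ".cpp_glcm_matrices")]]
List cpp_glcm_matrices(IntegerMatrix lv, int ng) {
  return List::create(glcm_one(lv, ng, 0), glcm_one(lv, ng, 1),
                      glcm_one(lv, ng, 2), glcm_one(lv, ng, 3));
}

static void glcm_features_one(const NumericMatrix& p, int ng, double* f) {
  std::vector<double> px(ng, 0.0);
  double jmax = 0, javg = 0, jent = 0, asm_ = 0, contrast = 0, dissim = 0;
  double id = 0, idn = 0, idm = 0, idmn = 0, invvar = 0, autoc = 0;
  std::vector<double> pdiff(ng, 0.0), psum(2 * ng - 1, 0.0);
  for (int i = 0; i < ng; i++) {
    for (int j = 0; j < ng; j++) {
      double pij = p(i, j);
      px[i] += pij;
      if (pij > jmax) jmax = pij;
      javg += (i + 1) * pij;
      if (pij > 0) jent -= pij * log2d(pij);
      asm_ += pij * pij;
      int d = std::abs(i - j);
      contrast += d * d * pij;
      dissim += d * pij;
      id += pij / (1.0 + d);
      idn += pij / (1.0 + (double)d / ng);
      idm += pij / (1.0 + (double)d * d);
      idmn += pij / (1.0 + (double)d * d / ((double)ng * ng));
      if (d > 0) invvar += pij / ((double)d * d);
      autoc += (double)(i + 1) * (j + 1) * pij;
      pdiff[d] += pij;
      psum[i + j] += pij;
    }
  }
  double jvar = 0;
  for (int i = 0; i < ng; i++)
    for (int j = 0; j < ng; j++)
      jvar += (i + 1 - javg) * (i + 1 - javg) * p(i, j);

  double da = 0, dv = 0, de = 0;
  for (int k = 0; k < ng; k++) da += k * pdiff[k];
  for (int k = 0; k < ng; k++) {
    dv += (k - da) * (k - da) * pdiff[k];
    if (pdiff[k] > 0) de -= pdiff[k] * log2d(pdiff[k]);
  }
  double sa = 0, sv = 0, se = 0;
  for (int k = 0; k < 2 * ng - 1; k++) sa += (k + 2) * psum[k];
  for (int k = 0; k < 2 * ng - 1; k++) {
    sv += (k + 2 - sa) * (k + 2 - sa) * psum[k];
    if (psum[k] > 0) se -= psum[k] * log2d(psum[k]);
  }

  // marginal mean/var (symmetric matrix: px == py)
  double mu = 0, s2 = 0;
  for (int i = 0; i < ng; i++) mu += (i + 1) * px[i];
  for (int i = 0; i < ng; i++) s2 += (i + 1 - mu) * (i + 1 - mu) * px[i];
  double corr = (s2 > 0) ? (autoc - mu * mu) / s2 : 0.0;

  double ct = 0, cs = 0, cp = 0;
  for (int i = 0; i < ng; i++) {
    for (int j = 0; j < ng; j++) {
      double z = (i + 1) + (j + 1) - 2 * mu;
      ct += z * z * p(i, j);
      cs += z * z * z * p(i, j);
      cp += z * z * z * z * p(i, j);
    }
  }

  double hx = 0;
  for (int i = 0; i < ng; i++) if (px[i] > 0) hx -= px[i] * log2d(px[i]);
  double hxy1 = 0, hxy2 = 0;
  for (int i = 0; i < ng; i++) {
    for (int j = 0; j < ng; j++) {
      double q = px[i] * px[j];
      if (q > 0) {
        if (p(i, j) > 0) hxy1 -= p(i, j) * log2d(q);
        hxy2 -= q * log2d(q);
      }
    }
  }
  double ic1 = (hx > 0) ? (jent - hxy1) / hx : 0.0;
  double ic2arg = 1.0 - std::exp(-2.0 * (hxy2 - jent));
  double ic2 = (ic2arg > 0) ? std::sqrt(ic2arg) : 0.0;

  f[0] = jmax; f[1] = javg; f[2] = jvar; f[3] = jent;
  f[4] = da;   f[5] = dv;   f[6] = de;
  f[7] = sa;   f[8] = sv;   f[9] = se;
  f[10] = asm_; f[11] = contrast; f[12] = dissim;
  f[13] = id;  f[14] = idn; f[15] = idm; f[16] = idmn; f[17] = invvar;
  f[18] = corr; f[19] = autoc; f[20] = ct; f[21] = cs; f[22] = cp;
  f[23] = ic1; f[24] = ic2;
}

// [[Rcpp::export(name = ".cpp_glcm_features")]]
NumericVector cpp_glcm_features(IntegerMatrix lv, int ng) {
  NumericVector out(25);
  double f[25];
  for (int d = 0; d < 4; d++) {
    NumericMatrix p = glcm_one(lv, ng, d);
    glcm_features_one(p, ng, f);
    for (int k = 0; k < 25; k++) out[k] += f[k] / 4.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// GLRLM: 4 directions; features averaged
// ---------------------------------------------------------------------------

static NumericMatrix glrlm_one(const IntegerMatrix& lv, int ng, int dir) {
  int nr = lv.nrow(), nc = lv.ncol();
  int maxlen = std::max(nr, nc);
  NumericMatrix m(ng, maxlen);
  int dr = DIR_DR[dir], dc = DIR_DC[dir];
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      // start of a run: predecessor out of bounds or different level
      int rp = r - dr, cp = c - dc;
      bool start = (rp < 0 || rp >= nr || cp < 0 || cp >= nc ||
                    lv(rp, cp) != lv(r, c));
      if (!start) continue;
      int len = 1, r2 = r + dr, c2 = c + dc;
      while (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc &&
             lv(r2, c2) == lv(r, c)) {
        len++; r2 += dr; c2 += dc;
      }
      m(lv(r, c) - 1, len - 1) += 1;
    }
  }
  return m;
}

// [[Rcpp::export(name = ".cpp_glrlm_matrices")]]
List cpp_glrlm_matrices(IntegerMatrix lv, int ng) {
  return List::create(glrlm_one(lv, ng, 0), glrlm_one(lv, ng, 1),
                      glrlm_one(lv, ng, 2), glrlm_one(lv, ng, 3));
}

// shared 16-feature block for run/zone/distance matrices m(level, j)
// where j is run length, zone size, or zone distance; nv = pixel count
static void rlszm_features(const NumericMatrix& m, int nv, double* f) {
  int ng = m.nrow(), nj = m.ncol();
  double ns = 0;
  std::vector<double> mg(ng, 0.0), mj(nj, 0.0);
  for (int i = 0; i < ng; i++)
    for (int j = 0; j < nj; j++) {
      ns += m(i, j); mg[i] += m(i, j); mj[j] += m(i, j);
    }
  double sre = 0, lre = 0, lgl = 0, hgl = 0, srl = 0, srh = 0, lrl = 0, lrh = 0;
  double glv = 0, rlv = 0, re = 0, mug = 0, muj = 0;
  for (int i = 0; i < ng; i++) {
    double g = i + 1;
    for (int j = 0; j < nj; j++) {
      double pij = m(i, j) / ns, l = j + 1;
      if (pij == 0) continue;
      sre += pij / (l * l); lre += pij * l * l;
      lgl += pij / (g * g); hgl += pij * g * g;
      srl += pij / (g * g * l * l); srh += pij * g * g / (l * l);
      lrl += pij * l * l / (g * g); lrh += pij * g * g * l * l;
      mug += pij * g; muj += pij * l;
      re -= pij * log2d(pij);
    }
  }
  for (int i = 0; i < ng; i++)
    for (int j = 0; j < nj; j++) {
      double pij = m(i, j) / ns;
      glv += pij * (i + 1 - mug) * (i + 1 - mug);
      rlv += pij * (j + 1 - muj) * (j + 1 - muj);
    }
  double gln = 0, rln = 0;
  for (int i = 0; i < ng; i++) gln += mg[i] * mg[i];
  for (int j = 0; j < nj; j++) rln += mj[j] * mj[j];
  f[0] = sre; f[1] = lre; f[2] = lgl; f[3] = hgl;
  f[4] = srl; f[5] = srh; f[6] = lrl; f[7] = lrh;
  f[8] = gln / ns; f[9] = gln / (ns * ns);
  f[10] = rln / ns; f[11] = rln / (ns * ns);
  f[12] = ns / nv; f[13] = glv; f[14] = rlv; f[15] = re;
}

// [[Rcpp::export(name = ".cpp_glrlm_features")]]
NumericVector cpp_glrlm_features(IntegerMatrix lv, int ng) {
  NumericVector out(16);
  double f[16];
  int nv = lv.nrow() * lv.ncol();
  for (int d = 0; d < 4; d++) {
    NumericMatrix m = glrlm_one(lv, ng, d);
    rlszm_features(m, nv, f);
    for (int k = 0; k < 16; k++) out[k] += f[k] / 4.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// zones: 8-connected components of equal grey level
// ---------------------------------------------------------------------------

struct Zone { int level; int size; int dist; };

static std::vector<Zone> find_zones(const IntegerMatrix& lv) {
  int nr = lv.nrow(), nc = lv.ncol();
  std::vector<int> seen(nr * nc, 0);
  std::vector<Zone> zones;
  std::vector<int> stack;
  for (int r0 = 0; r0 < nr; r0++) {
    for (int c0 = 0; c0 < nc; c0++) {
      if (seen[r0 + c0 * nr]) continue;
      int g = lv(r0, c0);
      int size = 0, dist = INT_MAX;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      seen[r0 + c0 * nr] = 1;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        size++;
        // chessboard distance to outside the window, border pixels = 1
        int d = std::min(std::min(r, nr - 1 - r), std::min(c, nc - 1 - c)) + 1;
        if (d < dist) dist = d;
        for (int dr = -1; dr <= 1; dr++) {
          for (int dc = -1; dc <= 1; dc++) {
            if (dr == 0 && dc == 0) continue;
            int r2 = r + dr, c2 = c + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            int idx2 = r2 + c2 * nr;
            if (!seen[idx2] && lv(r2, c2) == g) {
              seen[idx2] = 1; stack.push_back(idx2);
            }
          }
        }
      }
      zones.push_back({ g, size, dist });
    }
  }
  return zones;
}

// zones as a 3-column matrix (level, size, distance), row order = discovery
// order (column-major scan of first pixel)
// [[Rcpp::export(name = ".cpp_zones")]]
IntegerMatrix cpp_zones(IntegerMatrix lv) {
  std::vector<Zone> z = find_zones(lv);
  IntegerMatrix out(z.size(), 3);
  for (size_t i = 0; i < z.size(); i++) {
    out(i, 0) = z[i].level; out(i, 1) = z[i].size; out(i, 2) = z[i].dist;
  }
  colnames(out) = CharacterVector::create("level", "size", "distance");
  return out;
}

static NumericMatrix zones_to_matrix(const std::vector<Zone>& z, int ng,
                                     bool use_dist) {
  int mx = 1;
  for (const Zone& zi : z) {
    int v = use_dist ? zi.dist : zi.size;
    if (v > mx) mx = v;
  }
  NumericMatrix m(ng, mx);
  for (const Zone& zi : z)
    m(zi.level - 1, (use_dist ? zi.dist : zi.size) - 1) += 1;
  return m;
}

// [[Rcpp::export(name = ".cpp_glszm_features")]]
NumericVector cpp_glszm_features(IntegerMatrix lv, int ng) {
  std::vector<Zone> z = find_zones(lv);
  NumericMatrix m = zones_to_matrix(z, ng, false);
  NumericVector out(16);
  rlszm_features(m, lv.nrow() * lv.ncol(), out.begin());
  return out;
}

// [[Rcpp::export(name = ".cpp_gldzm_features")]]
NumericVector cpp_gldzm_features(IntegerMatrix lv, int ng) {
  std::vector<Zone> z = find_zones(lv);
  NumericMatrix m = zones_to_matrix(z, ng, true);
  NumericVector out(16);
  rlszm_features(m, lv.nrow() * lv.ncol(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// NGTDM: 8-neighbourhood grey tone difference
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_ngtdm")]]
List cpp_ngtdm(IntegerMatrix lv, int ng) {
  int nr = lv.nrow(), nc = lv.ncol();
  NumericVector s(ng), cnt(ng);
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      double sum = 0; int k = 0;
      for (int dr = -1; dr <= 1; dr++)
        for (int dc = -1; dc <= 1; dc++) {
          if (dr == 0 && dc == 0) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          sum += lv(r2, c2); k++;
        }
      int g = lv(r, c);
      if (k > 0) s[g - 1] += std::fabs(g - sum / k);
      cnt[g - 1] += 1;
    }
  }
  return List::create(_["s"] = s, _["n"] = cnt);
}

// [[Rcpp::export(name = ".cpp_ngtdm_features")]]
NumericVector cpp_ngtdm_features(IntegerMatrix lv, int ng) {
  List td = cpp_ngtdm(lv, ng);
  NumericVector s = td["s"], cnt = td["n"];
  double nv = lv.nrow() * lv.ncol();
  NumericVector p(ng);
  int ngp = 0;
  double sumps = 0, sums = 0;
  for (int i = 0; i < ng; i++) {
    p[i] = cnt[i] / nv;
    if (p[i] > 0) ngp++;
    sumps += p[i] * s[i];
    sums += s[i];
  }
  double coarse = (sumps > 0) ? 1.0 / sumps : 1e6;
  double contrast = 0, busy_den = 0, complexity = 0, strength_num = 0;
  for (int i = 0; i < ng; i++) {
    if (p[i] == 0) continue;
    for (int j = 0; j < ng; j++) {
      if (p[j] == 0) continue;
      double d = i - j;
      contrast += p[i] * p[j] * d * d;
      busy_den += std::fabs((i + 1) * p[i] - (j + 1) * p[j]);
      complexity += std::fabs(d) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j]);
      strength_num += (p[i] + p[j]) * d * d;
    }
  }
  contrast = (ngp > 1) ? contrast / (ngp * (ngp - 1.0)) * (sums / nv) : 0.0;
  double busy = (busy_den > 0) ? sumps / busy_den : 0.0;
  complexity /= nv;
  double strength = (sums > 0) ? strength_num / sums : 0.0;
  return NumericVector::create(coarse, contrast, busy, complexity, strength);
}

// ---------------------------------------------------------------------------
// NGLDM: 8-neighbourhood grey level dependence, coarseness alpha = 0
// dependence count k in 0..8 stored at column j = k + 1
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_ngldm_matrix")]]
NumericMatrix cpp_ngldm_matrix(IntegerMatrix lv, int ng, int alpha) {
  int nr = lv.nrow(), nc = lv.ncol();
  NumericMatrix m(ng, 9);
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      int k = 0;
      for (int dr = -1; dr <= 1; dr++)
        for (int dc = -1; dc <= 1; dc++) {
          if (dr == 0 && dc == 0) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (std::abs(lv(r2, c2) - lv(r, c)) <= alpha) k++;
        }
      m(lv(r, c) - 1, k) += 1;
    }
  }
  return m;
}

// [[Rcpp::export(name = ".cpp_ngldm_features")]]
NumericVector cpp_ngldm_features(IntegerMatrix lv, int ng) {
  NumericMatrix m = cpp_ngldm_matrix(lv, ng, 0);
  int nj = m.ncol();
  double nv = lv.nrow() * lv.ncol(), ns = 0;
  std::vector<double> mg(ng, 0.0), mj(nj, 0.0);
  for (int i = 0; i < ng; i++)
    for (int j = 0; j < nj; j++) { ns += m(i, j); mg[i] += m(i, j); mj[j] += m(i, j); }
  double lde = 0, hde = 0, lgl = 0, hgl = 0, ldl = 0, ldh = 0, hdl = 0, hdh = 0;
  double mug = 0, muj = 0, dce = 0, dcen = 0;
  for (int i = 0; i < ng; i++) {
    double g = i + 1;
    for (int j = 0; j < nj; j++) {
      double pij = m(i, j) / ns, d = j + 1;
      if (pij == 0) continue;
      lde += pij / (d * d); hde += pij * d * d;
      lgl += pij / (g * g); hgl += pij * g * g;
      ldl += pij / (g * g * d * d); ldh += pij * g * g / (d * d);
      hdl += pij * d * d / (g * g); hdh += pij * g * g * d * d;
      mug += pij * g; muj += pij * d;
      dce -= pij * log2d(pij);
      dcen += pij * pij;
    }
  }
  double glv = 0, dcv = 0;
  for (int i = 0; i < ng; i++)
    for (int j = 0; j < nj; j++) {
      double pij = m(i, j) / ns;
      glv += pij * (i + 1 - mug) * (i + 1 - mug);
      dcv += pij * (j + 1 - muj) * (j + 1 - muj);
    }
  double gln = 0, dcn = 0;
  for (int i = 0; i < ng; i++) gln += mg[i] * mg[i];
  for (int j = 0; j < nj; j++) dcn += mj[j] * mj[j];
  NumericVector out(17);
  out[0] = lde; out[1] = hde; out[2] = lgl; out[3] = hgl;
  out[4] = ldl; out[5] = ldh; out[6] = hdl; out[7] = hdh;
  out[8] = gln / ns; out[9] = gln / (ns * ns);
  out[10] = dcn / ns; out[11] = dcn / (ns * ns);
  out[12] = ns / nv; out[13] = glv; out[14] = dcv;
  out[15] = dce; out[16] = dcen;
  return out;
}

// ---------------------------------------------------------------------------
// full 118-feature vector; fast path over stacks of subimages
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_extract_one")]]
NumericVector cpp_extract_one(NumericMatrix x, int ng) {
  IntegerMatrix lv = cpp_discretise(x, ng);
  NumericVector out(118);
  NumericVector fos = cpp_fos(x, lv, ng);
  NumericVector glcm = cpp_glcm_features(lv, ng);
  NumericVector glrlm = cpp_glrlm_features(lv, ng);
  NumericVector glszm = cpp_glszm_features(lv, ng);
  NumericVector gldzm = cpp_gldzm_features(lv, ng);
  NumericVector ngtdm = cpp_ngtdm_features(lv, ng);
  NumericVector ngldm = cpp_ngldm_features(lv, ng);
  int k = 0;
  for (int i = 0; i < 23; i++) out[k++] = fos[i];
  for (int i = 0; i < 25; i++) out[k++] = glcm[i];
  for (int i = 0; i < 16; i++) out[k++] = glrlm[i];
  for (int i = 0; i < 16; i++) out[k++] = glszm[i];
  for (int i = 0; i < 16; i++) out[k++] = gldzm[i];
  for (int i = 0; i < 5; i++) out[k++] = ngtdm[i];
  for (int i = 0; i < 17; i++) out[k++] = ngldm[i];
  return out;
}

// arr: side x side x n array of subimages
// [[Rcpp::export(name = ".cpp_extract_many")]]
NumericMatrix cpp_extract_many(NumericVector arr, int side, int ng) {
  int n = arr.size() / (side * side);
  NumericMatrix out(n, 118);
  NumericMatrix x(side, side);
  for (int s = 0; s < n; s++) {
    std::copy(arr.begin() + s * side * side,
              arr.begin() + (s + 1) * side * side, x.begin());
    NumericVector f = cpp_extract_one(x, ng);
    for (int k = 0; k < 118; k++) out(s, k) = f[k];
  }
  return out;
}
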