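// Hot path of the tracker: detector bank rasterization (exact area
// integrals), correlation responses, the per-step lattice optimizer,
// step tests, the bidirectional tracer, the 7x7 seed scan, and two small
// rasterization helpers used by the synthetic generator.
//
// Image convention (shared with the R layer): x = column, y = row, origin
// at the centre of the top-left pixel.  An R matrix with nrow = height
// stores intensity I(x, y) at img(y + 1, x + 1) (1-based in R); here we
// index img(y, x) with Rcpp's (row, col) accessor.

#pragma GCC optimize("O3")
#include <Rcpp.h>
#include <cmath>
#include <memory>
#include <vector>
#include <algorithm>
#include <array>
#include <cstdint>

using namespace Rcpp;

static const double OFF_STEP = 0.1;
static const double W_STEP   = 0.2;
static const double A_STEP   = 2.5;
static const double W_MIN    = 0.4;
static const double W_MAX    = 6.0;
static const int    NOFF     = 10;   // offsets -0.5, -0.4, ..., 0.4 per axis
static const int    NW       = 29;   // widths 0.4 .. 6.0
static const int    NANG     = 144;  // angles 0 .. 357.5
static const double KD2R     = M_PI / 180.0;

// positive modulo without libm fmod (avoids a glibc >= 2.38 symbol)
static inline double pmod(double a, double b) {
  double r = a - b * std::floor(a / b);
  if (r >= b) r -= b;
  if (r < 0) r += b;
  return r;
}

// ---------------------------------------------------------------- geometry

typedef std::vector<std::pair<double,double> > Poly;

// Clip convex polygon against halfplane keep ? (axis-aligned):
// axis 0: x, axis 1: y;  keep side: sign*coord <= sign*bound.
static void clip_axis(const Poly &in, Poly &out, int axis, double bound, int sign) {
  out.clear();
  size_t n = in.size();
  if (n == 0) return;
  for (size_t i = 0; i < n; ++i) {
    const std::pair<double,double> &a = in[i];
    const std::pair<double,double> &b = in[(i + 1) % n];
    double ca = axis == 0 ? a.first : a.second;
    double cb = axis == 0 ? b.first : b.second;
    bool ina = sign * ca <= sign * bound;
    bool inb = sign * cb <= sign * bound;
    if (ina) out.push_back(a);
    if (ina != inb) {
      double t = (bound - ca) / (cb - ca);
      out.push_back(std::make_pair(a.first + t * (b.first - a.first),
                                   a.second + t * (b.second - a.second)));
    }
  }
}

static double poly_area(const Poly &p) {
  double s = 0;
  size_t n = p.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    s += p[i].first * p[j].second - p[j].first * p[i].second;
  }
  return 0.5 * std::fabs(s);
}

// Area of (convex) polygon intersected with pixel square centred at (ix, iy).
static double pixel_overlap(const Poly &poly, int ix, int iy) {
  static Poly t1, t2;
  clip_axis(poly, t1, 0, ix + 0.5,  1);
  clip_axis(t1,   t2, 0, ix - 0.5, -1);
  clip_axis(t2,   t1, 1, iy + 0.5,  1);
  clip_axis(t1,   t2, 1, iy - 0.5, -1);
  return poly_area(t2);
}

// ---------------------------------------------------------------- stencils

struct Stencil {
  std::vector<int> dx, dy;
  std::vector<double> w;
  int x0, x1, y0, y1;            // bbox of entries (relative to anchor)
};

struct PairDense {                // all NOFF*NOFF offsets for one (angle,width)
  int x0, x1, y0, y1, nbx, nby, nb;
  std::vector<float> m;           // (NOFF*NOFF) rows x nb cols
};

struct Bank {
  int len;
  std::vector<std::unique_ptr<Stencil> >   st;  // NANG*NW*NOFF*NOFF, lazy
  std::vector<std::unique_ptr<PairDense> > pd;  // NANG*NW, lazy
  std::vector<std::vector<int> > off_order;     // tie-break order per prev offset
  Bank(int L) : len(L),
    st((size_t)NANG * NW * NOFF * NOFF),
    pd((size_t)NANG * NW),
    off_order(NOFF * NOFF) {
    for (int p = 0; p < NOFF * NOFF; ++p) {
      double pox = -0.5 + (p / NOFF) * OFF_STEP;
      double poy = -0.5 + (p % NOFF) * OFF_STEP;
      std::vector<int> idx(NOFF * NOFF);
      for (int i = 0; i < NOFF * NOFF; ++i) idx[i] = i;
      std::vector<double> key1(NOFF * NOFF), key2(NOFF * NOFF);
      for (int i = 0; i < NOFF * NOFF; ++i) {
        double ox = -0.5 + (i / NOFF) * OFF_STEP;
        double oy = -0.5 + (i % NOFF) * OFF_STEP;
        key1[i] = (ox - pox) * (ox - pox) + (oy - poy) * (oy - poy);
        key2[i] = ox * ox + oy * oy;
      }
      std::sort(idx.begin(), idx.end(), [&](int a, int b) {
        if (key1[a] != key1[b]) return key1[a] < key1[b];
        if (key2[a] != key2[b]) return key2[a] < key2[b];
        return a < b;
      });
      off_order[p] = idx;
    }
  }
};

static inline size_t st_index(int ia, int iw, int io) {
  return ((size_t)ia * NW + iw) * (NOFF * NOFF) + io;
}

// Continuous detector: two step-edge elements of length `len` along the
// direction, at perpendicular distance +-w/2; each is a +1 band (1 px,
// outside) adjacent to a -1 band (1 px, inside).  Overlapping bands add.
static Stencil *build_stencil(int len, double ox, double oy, double w, double adeg) {
  double th = adeg * KD2R;
  double ux = std::cos(th), uy = std::sin(th);
  double nx = -uy, ny = ux;
  double hw = w / 2.0, hl = len / 2.0;
  // bands: [p0, p1] perpendicular interval, sign
  double bands[4][3] = {
    { hw,       hw + 1.0,  1.0},
    { hw - 1.0, hw,       -1.0},
    {-hw - 1.0, -hw,       1.0},
    {-hw,       -hw + 1.0, -1.0}
  };
  // accumulate on a dense temp grid
  double ext = hl + hw + 2.5;
  int g0 = (int)std::floor(-ext), g1 = (int)std::ceil(ext);
  int gn = g1 - g0 + 1;
  std::vector<double> grid((size_t)gn * gn, 0.0);
  Poly poly(4);
  for (int b = 0; b < 4; ++b) {
    double p0 = bands[b][0], p1 = bands[b][1], s = bands[b][2];
    poly[0] = std::make_pair(ox - ux * hl + nx * p0, oy - uy * hl + ny * p0);
    poly[1] = std::make_pair(ox + ux * hl + nx * p0, oy + uy * hl + ny * p0);
    poly[2] = std::make_pair(ox + ux * hl + nx * p1, oy + uy * hl + ny * p1);
    poly[3] = std::make_pair(ox - ux * hl + nx * p1, oy - uy * hl + ny * p1);
    double mnx = poly[0].first, mxx = poly[0].first;
    double mny = poly[0].second, mxy = poly[0].second;
    for (int k = 1; k < 4; ++k) {
      mnx = std::min(mnx, poly[k].first);  mxx = std::max(mxx, poly[k].first);
      mny = std::min(mny, poly[k].second); mxy = std::max(mxy, poly[k].second);
    }
    int ix0 = std::max(g0, (int)std::floor(mnx - 0.5));
    int ix1 = std::min(g1, (int)std::ceil(mxx + 0.5));
    // clip to each column strip once, then only the rows it spans
    Poly colpoly, tmp;
    for (int ix = ix0; ix <= ix1; ++ix) {
      clip_axis(poly, tmp, 0, ix + 0.5, 1);
      clip_axis(tmp, colpoly, 0, ix - 0.5, -1);
      if (colpoly.size() < 3) continue;
      double cy0 = colpoly[0].second, cy1 = colpoly[0].second;
      for (size_t k = 1; k < colpoly.size(); ++k) {
        cy0 = std::min(cy0, colpoly[k].second);
        cy1 = std::max(cy1, colpoly[k].second);
      }
      int iy0 = std::max(g0, (int)std::floor(cy0 - 0.5));
      int iy1 = std::min(g1, (int)std::ceil(cy1 + 0.5));
      for (int iy = iy0; iy <= iy1; ++iy) {
        static Poly r1, r2;
        clip_axis(colpoly, r1, 1, iy + 0.5, 1);
        clip_axis(r1, r2, 1, iy - 0.5, -1);
        double a = poly_area(r2);
        if (a > 0) grid[(size_t)(ix - g0) * gn + (iy - g0)] += s * a;
      }
    }
  }
  Stencil *st = new Stencil();
  double sum = 0; int cnt = 0;
  for (int ix = g0; ix <= g1; ++ix)
    for (int iy = g0; iy <= g1; ++iy) {
      double v = grid[(size_t)(ix - g0) * gn + (iy - g0)];
      if (std::fabs(v) > 1e-12) { sum += v; ++cnt; }
    }
  double mean = cnt ? sum / cnt : 0.0;
  double l2 = 0;
  st->x0 = st->y0 = 1000; st->x1 = st->y1 = -1000;
  for (int ix = g0; ix <= g1; ++ix)
    for (int iy = g0; iy <= g1; ++iy) {
      double v = grid[(size_t)(ix - g0) * gn + (iy - g0)];
      if (std::fabs(v) > 1e-12) {
        double vv = v - mean;
        st->dx.push_back(ix); st->dy.push_back(iy); st->w.push_back(vv);
        l2 += vv * vv;
        st->x0 = std::min(st->x0, ix); st->x1 = std::max(st->x1, ix);
        st->y0 = std::min(st->y0, iy); st->y1 = std::max(st->y1, iy);
      }
    }
  // scale so positive and negative masses are each ~1 (sum |w| = 2): the
  // response is then contrast-linear and approximately equals the valley
  // depth on a matched line, and the argmax over the lattice is unbiased
  // (an L2-normalized bank rewards smeared stencils and overestimates
  // width on pixel-integrated valleys).
  (void)l2;
  double sa = 0;
  for (size_t i = 0; i < st->w.size(); ++i) sa += std::fabs(st->w[i]);
  if (sa > 0) for (size_t i = 0; i < st->w.size(); ++i) st->w[i] *= 2.0 / sa;
  return st;
}

static Stencil *get_stencil(Bank *bank, int ia, int iw, int io) {
  size_t k = st_index(ia, iw, io);
  if (!bank->st[k]) {
    double ox = -0.5 + (io / NOFF) * OFF_STEP;
    double oy = -0.5 + (io % NOFF) * OFF_STEP;
    double w  = W_MIN + iw * W_STEP;
    double a  = ia * A_STEP;
    bank->st[k].reset(build_stencil(bank->len, ox, oy, w, a));
  }
  return bank->st[k].get();
}

static PairDense *get_pair(Bank *bank, int ia, int iw) {
  size_t k = (size_t)ia * NW + iw;
  if (!bank->pd[k]) {
    PairDense *pd = new PairDense();
    pd->x0 = pd->y0 = 1000; pd->x1 = pd->y1 = -1000;
    for (int io = 0; io < NOFF * NOFF; ++io) {
      Stencil *s = get_stencil(bank, ia, iw, io);
      pd->x0 = std::min(pd->x0, s->x0); pd->x1 = std::max(pd->x1, s->x1);
      pd->y0 = std::min(pd->y0, s->y0); pd->y1 = std::max(pd->y1, s->y1);
    }
    pd->nbx = pd->x1 - pd->x0 + 1;
    pd->nby = pd->y1 - pd->y0 + 1;
    pd->nb  = pd->nbx * pd->nby;
    pd->m.assign((size_t)(NOFF * NOFF) * pd->nb, 0.0f);
    for (int io = 0; io < NOFF * NOFF; ++io) {
      Stencil *s = get_stencil(bank, ia, iw, io);
      float *row = &pd->m[(size_t)io * pd->nb];
      for (size_t i = 0; i < s->w.size(); ++i)
        row[(s->dx[i] - pd->x0) * pd->nby + (s->dy[i] - pd->y0)] = (float)s->w[i];
    }
    bank->pd[k] = std::unique_ptr<PairDense>(pd);
  }
  return bank->pd[k].get();
}

// ---------------------------------------------------------------- lattice

static inline int snap_angle_idx(double adeg) {
  double a = pmod(adeg, 360.0);
  int ia = (int)std::lround(a / A_STEP);
  return ((ia % NANG) + NANG) % NANG;
}
static inline int snap_width_idx(double w) {
  int iw = (int)std::lround((w - W_MIN) / W_STEP);
  return std::max(0, std::min(NW - 1, iw));
}
// position -> anchor + offset index
static inline void snap_pos(double x, double y, int &ax, int &ay, int &io) {
  ax = (int)std::lround(x);
  ay = (int)std::lround(y);
  int iox = (int)std::lround((x - ax + 0.5) / OFF_STEP);
  if (iox >= NOFF) { ax += 1; iox = 0; }
  if (iox < 0)     { ax -= 1; iox = NOFF - 1; }
  int ioy = (int)std::lround((y - ay + 0.5) / OFF_STEP);
  if (ioy >= NOFF) { ay += 1; ioy = 0; }
  if (ioy < 0)     { ay -= 1; ioy = NOFF - 1; }
  io = iox * NOFF + ioy;
}
static inline int snap_off_idx(double ox, double oy) {
  int iox = std::max(0, std::min(NOFF - 1, (int)std::lround((ox + 0.5) / OFF_STEP)));
  int ioy = std::max(0, std::min(NOFF - 1, (int)std::lround((oy + 0.5) / OFF_STEP)));
  return iox * NOFF + ioy;
}

// ---------------------------------------------------------------- response

static double response_sparse(const NumericMatrix &img, double meanI,
                              int ax, int ay, const Stencil *s) {
  int H = img.nrow(), W = img.ncol();
  double acc = 0;
  if (ax + s->x0 >= 0 && ax + s->x1 < W && ay + s->y0 >= 0 && ay + s->y1 < H) {
    const double *p = &img(0, 0);
    for (size_t i = 0; i < s->w.size(); ++i)
      acc += s->w[i] * (p[(size_t)(ax + s->dx[i]) * H + (ay + s->dy[i])] - meanI);
  } else {
    for (size_t i = 0; i < s->w.size(); ++i) {
      int x = ax + s->dx[i], y = ay + s->dy[i];
      double v = (x >= 0 && x < W && y >= 0 && y < H) ? img(y, x) : meanI;
      acc += s->w[i] * (v - meanI);
    }
  }
  return acc;
}

struct OptResult { int io, iw, ia; double score; };

// Candidate offsets along the perpendicular of heading `ia` through the
// offset pio: the along-track offset component of a matched line
// detector is unidentifiable on a locally straight ridge, so the tracer
// searches only the ~10 lattice offsets nearest the perpendicular line
// (the exported optimizer still searches the full grid).  Ordered by
// |shift| (ties: positive first), deduplicated.
static void perp_candidates(int pio, int ia, std::vector<int> &out) {
  static const int k_order[10] = {0, 1, -1, 2, -2, 3, -3, 4, -4, 5};
  double th = ia * A_STEP * KD2R;
  double nx = -std::sin(th), ny = std::cos(th);
  double ox0 = -0.5 + (pio / NOFF) * OFF_STEP;
  double oy0 = -0.5 + (pio % NOFF) * OFF_STEP;
  out.clear();
  for (int r = 0; r < 10; ++r) {
    double ox = ox0 + k_order[r] * OFF_STEP * nx;
    double oy = oy0 + k_order[r] * OFF_STEP * ny;
    int iox = (int)std::lround((ox + 0.5) / OFF_STEP);
    int ioy = (int)std::lround((oy + 0.5) / OFF_STEP);
    if (iox < 0 || iox >= NOFF || ioy < 0 || ioy >= NOFF) continue;
    int io = iox * NOFF + ioy;
    bool seen = false;
    for (size_t i = 0; i < out.size(); ++i) if (out[i] == io) seen = true;
    if (!seen) out.push_back(io);
  }
  if (out.empty()) out.push_back(pio);
}

// Exhaustive search over the lattice neighbourhood of prev: all offsets,
// angles within +-10 deg, widths within +-0.4 px.  Ties broken toward the
// smallest change from prev: |d angle| first (then +), |d width| (then +),
// |d offset| (then a fixed offset order); strict improvement required.
// cand = ordered candidate offset indices (tie-preference order); when
// null, all NOFF*NOFF offsets in the smallest-change order for pio.
static OptResult optimize_core(Bank *bank, const NumericMatrix &img, double meanI,
                               int ax, int ay, int pio, int piw, int pia,
                               const std::vector<int> *cand = 0) {
  int H = img.nrow(), W = img.ncol();
  static const int da_order[9] = {0, 1, -1, 2, -2, 3, -3, 4, -4};
  static const int dw_order[5] = {0, 1, -1, 2, -2};
  OptResult best;
  best.io = pio; best.iw = piw; best.ia = pia;
  best.score = -1e300;
  std::vector<float> patch;
  const std::vector<int> &oord = cand ? *cand : bank->off_order[pio];
  for (int aii = 0; aii < 9; ++aii) {
    int ia = ((pia + da_order[aii]) % NANG + NANG) % NANG;
    for (int wii = 0; wii < 5; ++wii) {
      int iw = piw + dw_order[wii];
      if (iw < 0 || iw >= NW) continue;
      PairDense *pd = get_pair(bank, ia, iw);
      patch.resize(pd->nb);
      bool inside = (ax + pd->x0 >= 0 && ax + pd->x1 < W &&
                     ay + pd->y0 >= 0 && ay + pd->y1 < H);
      // store intensities relative to the frame mean: the stencils are
      // zero-sum, so this leaves responses unchanged in exact arithmetic
      // while removing the large common term that costs float precision
      if (inside) {
        const double *p = &img(0, 0);
        float *q = patch.data();
        for (int kx = 0; kx < pd->nbx; ++kx) {
          const double *col = p + (size_t)(ax + pd->x0 + kx) * H + (ay + pd->y0);
          for (int ky = 0; ky < pd->nby; ++ky)
            q[kx * pd->nby + ky] = (float)(col[ky] - meanI);
        }
      } else {
        for (int kx = 0; kx < pd->nbx; ++kx)
          for (int ky = 0; ky < pd->nby; ++ky) {
            int x = ax + pd->x0 + kx, y = ay + pd->y0 + ky;
            patch[kx * pd->nby + ky] =
              (x >= 0 && x < W && y >= 0 && y < H) ? (float)(img(y, x) - meanI)
                                                   : 0.0f;
          }
      }
      const float * __restrict q = patch.data();
      int nb = pd->nb;
      for (size_t r = 0; r < oord.size(); ++r) {
        int io = oord[r];
        const float * __restrict row = &pd->m[(size_t)io * pd->nb];
        float s0 = 0.0f, s1 = 0.0f, s2 = 0.0f, s3 = 0.0f;
        float s4 = 0.0f, s5 = 0.0f, s6 = 0.0f, s7 = 0.0f;
        int k = 0;
        for (; k + 7 < nb; k += 8) {
          s0 += row[k]     * q[k];     s1 += row[k + 1] * q[k + 1];
          s2 += row[k + 2] * q[k + 2]; s3 += row[k + 3] * q[k + 3];
          s4 += row[k + 4] * q[k + 4]; s5 += row[k + 5] * q[k + 5];
          s6 += row[k + 6] * q[k + 6]; s7 += row[k + 7] * q[k + 7];
        }
        for (; k < nb; ++k) s0 += row[k] * q[k];
        float acc = ((s0 + s1) + (s2 + s3)) + ((s4 + s5) + (s6 + s7));
        if ((double)acc > best.score) {
          best.score = (double)acc;
          best.io = io; best.iw = iw; best.ia = ia;
        }
      }
    }
  }
  return best;
}

// ---------------------------------------------------------------- tests

static inline double bilin(const NumericMatrix &img, double x, double y, double meanI) {
  int H = img.nrow(), W = img.ncol();
  if (x < 0 || y < 0 || x > W - 1 || y > H - 1) return meanI;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  double fx = x - x0, fy = y - y0;
  return img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x1) * fx * (1 - fy) +
         img(y1, x0) * (1 - fx) * fy      + img(y1, x1) * fx * fy;
}

// returns bit flags of failing tests: 1 score, 2 asymmetry, 4 mean
// intensity, 8 angle step.  0 = all pass.
static int step_tests_core(const NumericMatrix &img, double meanI, int len,
                           double cx, double cy, double w, double adeg,
                           double score, double prev_adeg,
                           double min_score, double max_asym,
                           double min_mean_frac, double max_angle_step) {
  int fail = 0;
  if (score < min_score) fail |= 1;
  double th = adeg * KD2R;
  double ux = std::cos(th), uy = std::sin(th);
  double nx = -uy, ny = ux;
  // left/right intensity about the detector, measured over the spans of
  // its two step-edge elements (perp in +-[w/2-1, w/2+1]); a detector
  // riding the flank of a line, with the dark core under just one
  // element, is strongly asymmetric here
  double IL = 0, IR = 0; int acnt = 0;
  for (int i = 0; i < len; ++i) {
    double s = -(len - 1) / 2.0 + i;
    for (int k = 0; k < 4; ++k) {
      double d = w / 2.0 - 0.75 + 0.5 * k;
      IL += bilin(img, cx + ux * s + nx * d, cy + uy * s + ny * d, meanI);
      IR += bilin(img, cx + ux * s - nx * d, cy + uy * s - ny * d, meanI);
      ++acnt;
    }
  }
  IL /= acnt; IR /= acnt;
  double asym = std::fabs(IL - IR) / std::max(IL + IR, 1e-6);
  if (asym > max_asym) fail |= 2;
  // mean intensity over the detector support (length x (w + 2))
  double hp = w / 2.0 + 1.0;
  double acc = 0; int cnt = 0;
  for (int i = 0; i < len; ++i) {
    double s = -(len - 1) / 2.0 + i;
    for (double p = -hp; p <= hp + 1e-9; p += 0.5) {
      acc += bilin(img, cx + ux * s + nx * p, cy + uy * s + ny * p, meanI);
      ++cnt;
    }
  }
  if (acc / cnt < min_mean_frac * meanI) fail |= 4;
  double dd = pmod(adeg - prev_adeg, 360.0);
  if (dd > 180.0) dd = 360.0 - dd;
  if (dd > 90.0) dd = 180.0 - dd;
  if (dd > max_angle_step) fail |= 8;
  return fail;
}

// ---------------------------------------------------------------- exports

// [[Rcpp::export(name = ".wt_bank_new")]]
SEXP wt_bank_new(int length = 20) {
  Bank *b = new Bank(length);
  XPtr<Bank> p(b, true);
  return p;
}

// [[Rcpp::export(name = ".wt_bank_len")]]
int wt_bank_len(SEXP bankp) { return XPtr<Bank>(bankp)->len; }

// [[Rcpp::export(name = ".wt_stencil")]]
List wt_stencil(SEXP bankp, double ox, double oy, double width, double angle) {
  XPtr<Bank> b(bankp);
  int io = snap_off_idx(ox, oy);
  Stencil *s = get_stencil(b, snap_angle_idx(angle), snap_width_idx(width), io);
  return List::create(_["dx"] = wrap(s->dx), _["dy"] = wrap(s->dy),
                      _["w"] = wrap(s->w));
}

// [[Rcpp::export(name = ".wt_response")]]
double wt_response(SEXP bankp, NumericMatrix img, double meanI,
                   int ax, int ay, double ox, double oy,
                   double width, double angle) {
  XPtr<Bank> b(bankp);
  Stencil *s = get_stencil(b, snap_angle_idx(angle), snap_width_idx(width),
                           snap_off_idx(ox, oy));
  return response_sparse(img, meanI, ax, ay, s);
}

// [[Rcpp::export(name = ".wt_optimize_step")]]
NumericVector wt_optimize_step(SEXP bankp, NumericMatrix img, double meanI,
                               int ax, int ay, double ox, double oy,
                               double width, double angle) {
  XPtr<Bank> b(bankp);
  OptResult r = optimize_core(b, img, meanI, ax, ay, snap_off_idx(ox, oy),
                              snap_width_idx(width), snap_angle_idx(angle));
  return NumericVector::create(
    -0.5 + (r.io / NOFF) * OFF_STEP, -0.5 + (r.io % NOFF) * OFF_STEP,
    W_MIN + r.iw * W_STEP, r.ia * A_STEP, r.score);
}

// [[Rcpp::export(name = ".wt_step_tests")]]
IntegerVector wt_step_tests(NumericMatrix img, double meanI, int len,
                            double cx, double cy, double width, double angle,
                            double score, double prev_angle,
                            double min_score, double max_asym,
                            double min_mean_frac, double max_angle_step) {
  int f = step_tests_core(img, meanI, len, cx, cy, width, angle, score,
                          prev_angle, min_score, max_asym, min_mean_frac,
                          max_angle_step);
  return IntegerVector::create(f == 0, (f & 1) != 0, (f & 2) != 0,
                               (f & 4) != 0, (f & 8) != 0);
}

// [[Rcpp::export(name = ".wt_trace")]]
NumericMatrix wt_trace(SEXP bankp, NumericMatrix img, double meanI,
                       double sx, double sy, double seed_angle,
                       double min_score, double max_asym,
                       double min_mean_frac, double max_angle_step,
                       int max_gap, Nullable<LogicalMatrix> occupied = R_NilValue) {
  XPtr<Bank> bptr(bankp);
  Bank *bank = bptr.get();
  int H = img.nrow(), W = img.ncol();
  int len = bank->len;
  const int MAXPTS = 100000;

  int ax, ay, io;
  snap_pos(sx, sy, ax, ay, io);
  int ia0 = snap_angle_idx(seed_angle);
  // initialization: alternate a 1-D width scan with a perpendicular
  // re-centring step a few times, so seeds landing ~1-2 px off the
  // backbone converge onto it instead of locking a wide detector onto
  // the flank of the line
  std::vector<int> cand;
  OptResult p0; p0.io = io; p0.iw = 0; p0.ia = ia0; p0.score = -1e300;
  double c0x = sx, c0y = sy;
  for (int it = 0; it < 8; ++it) {
    int iw0 = 0; double bestw = -1e300;
    for (int iw = 0; iw < NW; ++iw) {
      double r = response_sparse(img, meanI, ax, ay, get_stencil(bank, ia0, iw, io));
      if (r > bestw) { bestw = r; iw0 = iw; }
    }
    perp_candidates(io, ia0, cand);
    p0 = optimize_core(bank, img, meanI, ax, ay, io, iw0, ia0, &cand);
    c0x = ax - 0.5 + (p0.io / NOFF) * OFF_STEP;
    c0y = ay - 0.5 + (p0.io % NOFF) * OFF_STEP;
    ia0 = p0.ia;
    if (p0.score < min_score) break;   // nothing to centre on
    int ax2, ay2, io2;
    snap_pos(c0x, c0y, ax2, ay2, io2);
    if (ax2 == ax && ay2 == ay && io2 == io) break;   // converged
    ax = ax2; ay = ay2; io = io2;
  }
  if (step_tests_core(img, meanI, len, c0x, c0y, W_MIN + p0.iw * W_STEP,
                      p0.ia * A_STEP, p0.score, ia0 * A_STEP,
                      min_score, max_asym, min_mean_frac, max_angle_step))
    return NumericMatrix(0, 5);
  if (occupied.isNotNull()) {
    // a seed whose centred position lands on an already-traced curve
    // would only retrace it; skip before paying for the full trace
    LogicalMatrix occ(occupied);
    int ox_ = (int)std::lround(c0x), oy_ = (int)std::lround(c0y);
    if (ox_ >= 0 && ox_ < W && oy_ >= 0 && oy_ < H && occ(oy_, ox_))
      return NumericMatrix(0, 5);
  }

  // rows: x, y, score, width, angle
  std::vector<std::array<double,5> > fwd, bwd, seedrow;
  seedrow.push_back({c0x, c0y, p0.score, W_MIN + p0.iw * W_STEP,
                     (double)(p0.ia * A_STEP)});

  for (int dir = 0; dir < 2; ++dir) {
    std::vector<std::array<double,5> > &out = dir == 0 ? fwd : bwd;
    int ia = dir == 0 ? p0.ia : (p0.ia + NANG / 2) % NANG;
    int iw = p0.iw;
    double px = c0x, py = c0y;     // current trusted position
    bool alive = true;
    while (alive && (int)(fwd.size() + bwd.size()) < MAXPTS) {
      double h = ia * A_STEP * KD2R;
      double ux = std::cos(h), uy = std::sin(h);
      double nxp = -uy, nyp = ux;
      double nx0 = px + ux, ny0 = py + uy;   // 1 px step along heading
      if (nx0 < 0 || nx0 > W - 1 || ny0 < 0 || ny0 > H - 1) break;
      int bx, by, bio;
      snap_pos(nx0, ny0, bx, by, bio);
      perp_candidates(bio, ia, cand);
      OptResult r = optimize_core(bank, img, meanI, bx, by, bio, iw, ia, &cand);
      double cx = bx - 0.5 + (r.io / NOFF) * OFF_STEP;
      double cy = by - 0.5 + (r.io % NOFF) * OFF_STEP;
      int fail = step_tests_core(img, meanI, len, cx, cy,
                                 W_MIN + r.iw * W_STEP, r.ia * A_STEP,
                                 r.score, ia * A_STEP, min_score, max_asym,
                                 min_mean_frac, max_angle_step);
      if (!fail) {
        // keep the 1 px advance; apply the optimizer's perpendicular refinement
        double dperp = (cx - nx0) * nxp + (cy - ny0) * nyp;
        px = nx0 + dperp * nxp;  py = ny0 + dperp * nyp;
        out.push_back({px, py, r.score, W_MIN + r.iw * W_STEP,
                       (double)(r.ia * A_STEP)});
        ia = r.ia; iw = r.iw;
        continue;
      }
      // gap mode: linear probes along the last trusted direction
      bool recovered = false;
      for (int g = 2; g <= max_gap && !recovered; ++g) {
        double gx = px + g * ux, gy = py + g * uy;
        if (gx < 0 || gx > W - 1 || gy < 0 || gy > H - 1) break;
        int gax, gay, gio;
        snap_pos(gx, gy, gax, gay, gio);
        perp_candidates(gio, ia, cand);
        OptResult rg = optimize_core(bank, img, meanI, gax, gay, gio, iw, ia, &cand);
        double gcx = gax - 0.5 + (rg.io / NOFF) * OFF_STEP;
        double gcy = gay - 0.5 + (rg.io % NOFF) * OFF_STEP;
        int gfail = step_tests_core(img, meanI, len, gcx, gcy,
                                    W_MIN + rg.iw * W_STEP, rg.ia * A_STEP,
                                    rg.score, ia * A_STEP, min_score, max_asym,
                                    min_mean_frac, max_angle_step);
        if (!gfail) {
          // bridge with a straight segment, ~1 px spacing, score 0
          double ddx = gcx - px, ddy = gcy - py;
          double dist = std::sqrt(ddx * ddx + ddy * ddy);
          int k = std::max(1, (int)std::floor(dist));
          double w0 = W_MIN + iw * W_STEP, w1 = W_MIN + rg.iw * W_STEP;
          for (int j = 1; j < k; ++j) {
            double t = (double)j / k;
            out.push_back({px + t * ddx, py + t * ddy, 0.0,
                           w0 + t * (w1 - w0), (double)(ia * A_STEP)});
          }
          px = gcx; py = gcy;
          out.push_back({px, py, rg.score, w1, (double)(rg.ia * A_STEP)});
          ia = rg.ia; iw = rg.iw;
          recovered = true;
        }
      }
      if (!recovered) alive = false;
    }
  }

  size_t n = bwd.size() + 1 + fwd.size();
  NumericMatrix res(n, 5);
  size_t r = 0;
  for (size_t i = bwd.size(); i-- > 0; ++r)
    for (int c = 0; c < 5; ++c) res(r, c) = bwd[i][c];
  for (int c = 0; c < 5; ++c) res(r, c) = seedrow[0][c];
  ++r;
  for (size_t i = 0; i < fwd.size(); ++i, ++r)
    for (int c = 0; c < 5; ++c) res(r, c) = fwd[i][c];
  return res;
}

// ---------------------------------------------------------------- seeding

// 7x7 two-partition minima detector at integer centres (boxes must fit).
// Returns (eccentricity, angle_deg) per centre.  Constant boxes score 0;
// partition ties are resolved toward the partition with darker minima.
// [[Rcpp::export(name = ".wt_seed_scan")]]
NumericMatrix wt_seed_scan(NumericMatrix img, IntegerVector cx, IntegerVector cy) {
  int H = img.nrow(), W = img.ncol();
  int n = cx.size();
  NumericMatrix out(n, 4);   // ecc, angle, minima centroid x, y
  for (int q = 0; q < n; ++q) {
    int x0 = cx[q] - 3, y0 = cy[q] - 3;
    if (x0 < 0 || y0 < 0 || x0 + 6 >= W || y0 + 6 >= H)
      stop("seed box does not fit at centre (%d, %d)", cx[q], cy[q]);
    double mn = 1e300, mx = -1e300;
    for (int i = 0; i < 7; ++i)
      for (int j = 0; j < 7; ++j) {
        double v = img(y0 + j, x0 + i);
        mn = std::min(mn, v); mx = std::max(mx, v);
      }
    if (mx - mn < 1e-12) {
      out(q, 0) = 0; out(q, 1) = 0; out(q, 2) = cx[q]; out(q, 3) = cy[q];
      continue;
    }
    double axp[7], ayp[7], bxp[7], byp[7], aint = 0, bint = 0;
    for (int i = 0; i < 7; ++i) {       // partition A: columns (scan down)
      int bj = 0; double bv = img(y0, x0 + i);
      for (int j = 1; j < 7; ++j)
        if (img(y0 + j, x0 + i) < bv) { bv = img(y0 + j, x0 + i); bj = j; }
      axp[i] = x0 + i; ayp[i] = y0 + bj; aint += bv;
    }
    for (int j = 0; j < 7; ++j) {       // partition B: rows (scan right)
      int bi = 0; double bv = img(y0 + j, x0);
      for (int i = 1; i < 7; ++i)
        if (img(y0 + j, x0 + i) < bv) { bv = img(y0 + j, x0 + i); bi = i; }
      bxp[j] = x0 + bi; byp[j] = y0 + j; bint += bv;
    }
    double ea, eb;
    const double *pxs[2] = {axp, bxp};
    const double *pys[2] = {ayp, byp};
    double eccs[2], angs[2];
    // minima hugging one box edge mean the dark structure lies outside
    // the box (a monotone intensity tail), not through it: degenerate
    bool edge[2];
    {
      int top = 0, bot = 0, lef = 0, rig = 0;
      for (int i = 0; i < 7; ++i) {
        if (ayp[i] == y0) ++top;
        if (ayp[i] == y0 + 6) ++bot;
        if (bxp[i] == x0) ++lef;
        if (bxp[i] == x0 + 6) ++rig;
      }
      edge[0] = top >= 6 || bot >= 6;
      edge[1] = lef >= 6 || rig >= 6;
    }
    for (int p = 0; p < 2; ++p) {
      double mxx = 0, myy = 0;
      for (int i = 0; i < 7; ++i) { mxx += pxs[p][i]; myy += pys[p][i]; }
      mxx /= 7; myy /= 7;
      double cxx = 0, cyy = 0, cxy = 0;
      for (int i = 0; i < 7; ++i) {
        double dx = pxs[p][i] - mxx, dy = pys[p][i] - myy;
        cxx += dx * dx; cyy += dy * dy; cxy += dx * dy;
      }
      cxx /= 7; cyy /= 7; cxy /= 7;
      double half = std::sqrt(std::max(0.0, (cxx - cyy) * (cxx - cyy) / 4 + cxy * cxy));
      double l1 = (cxx + cyy) / 2 + half, l2 = (cxx + cyy) / 2 - half;
      if (l1 <= 0) { eccs[p] = 0; angs[p] = 0; continue; }
      eccs[p] = std::sqrt(std::max(0.0, 1.0 - l2 / l1));
      double vx, vy;
      if (std::fabs(cxy) > 1e-15) { vx = l1 - cyy; vy = cxy; }
      else if (cxx >= cyy)        { vx = 1; vy = 0; }
      else                        { vx = 0; vy = 1; }
      double ang = std::atan2(vy, vx) / KD2R;
      ang = pmod(ang, 180.0);
      angs[p] = ang;
    }
    if (edge[0]) eccs[0] = 0;
    if (edge[1]) eccs[1] = 0;
    ea = eccs[0]; eb = eccs[1];
    int pick;
    if (std::fabs(ea - eb) < 1e-9) pick = (aint <= bint) ? 0 : 1;
    else pick = (ea > eb) ? 0 : 1;
    out(q, 0) = eccs[pick];
    out(q, 1) = angs[pick];
    double sx = 0, sy = 0;
    for (int i = 0; i < 7; ++i) { sx += pxs[pick][i]; sy += pys[pick][i]; }
    out(q, 2) = sx / 7;   // minima centroid: a point on the backbone,
    out(q, 3) = sy / 7;   // the position tracing actually starts from
  }
  return out;
}

// ------------------------------------------------------------ rasterizers

// Coverage areas of a rotated rectangle (segment with a width) per pixel.
// [[Rcpp::export(name = ".wt_rect_coverage")]]
List wt_rect_coverage(double x0, double y0, double x1, double y1, double width) {
  double ddx = x1 - x0, ddy = y1 - y0;
  double L = std::sqrt(ddx * ddx + ddy * ddy);
  if (L <= 0) stop("degenerate segment");
  double ux = ddx / L, uy = ddy / L, nx = -uy, ny = ux;
  double hw = width / 2.0;
  Poly poly(4);
  poly[0] = std::make_pair(x0 + nx * hw, y0 + ny * hw);
  poly[1] = std::make_pair(x1 + nx * hw, y1 + ny * hw);
  poly[2] = std::make_pair(x1 - nx * hw, y1 - ny * hw);
  poly[3] = std::make_pair(x0 - nx * hw, y0 - ny * hw);
  double mnx = poly[0].first, mxx = poly[0].first;
  double mny = poly[0].second, mxy = poly[0].second;
  for (int k = 1; k < 4; ++k) {
    mnx = std::min(mnx, poly[k].first);  mxx = std::max(mxx, poly[k].first);
    mny = std::min(mny, poly[k].second); mxy = std::max(mxy, poly[k].second);
  }
  std::vector<int> xs, ys; std::vector<double> areas;
  for (int ix = (int)std::floor(mnx - 0.5); ix <= (int)std::ceil(mxx + 0.5); ++ix)
    for (int iy = (int)std::floor(mny - 0.5); iy <= (int)std::ceil(mxy + 0.5); ++iy) {
      double a = pixel_overlap(poly, ix, iy);
      if (a > 1e-12) { xs.push_back(ix); ys.push_back(iy); areas.push_back(a); }
    }
  return List::create(_["x"] = wrap(xs), _["y"] = wrap(ys), _["area"] = wrap(areas));
}

// Max-combine a Gaussian-profile curve into a darkness canvas (in place).
// pts: n x 2 sub-pixel sample points (~0.25 px apart); sigma, amp per point.
// [[Rcpp::export(name = ".wt_render_curve")]]
void wt_render_curve(NumericMatrix canvas, NumericMatrix pts,
                     NumericVector sigma, NumericVector amp) {
  int H = canvas.nrow(), W = canvas.ncol();
  int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    double s = sigma[i], a = amp[i];
    if (s <= 0 || a <= 0) continue;
    int r = (int)std::ceil(3 * s + 1);
    int ix0 = std::max(0, (int)std::floor(x) - r);
    int ix1 = std::min(W - 1, (int)std::ceil(x) + r);
    int iy0 = std::max(0, (int)std::floor(y) - r);
    int iy1 = std::min(H - 1, (int)std::ceil(y) + r);
    double inv = 1.0 / (2 * s * s);
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy) {
        double d2 = (ix - x) * (ix - x) + (iy - y) * (iy - y);
        double v = a * std::exp(-d2 * inv);
        if (v > canvas(iy, ix)) canvas(iy, ix) = v;
      }
  }
}
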