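#include <Rcpp.h>
using namespace Rcpp;

// Classic lattice gradient noise ("improved" variant): smoothstep fade,
// 12 cube-edge gradients selected by a hashed permutation table.

static inline double fade(double t) { return t * t * t * (t * (t * 6.0 - 15.0) + 10.0); }
static inline double lerp(double t, double a, double b) { return a + t * (b - a); }

static inline double grad(int hash, double x, double y, double z) {
  int h = hash & 15;
  double u = h < 8 ? x : y;
  double v = h < 4 ? y : (h == 12 || h == 14 ? x : z);
  return ((h & 1) == 0 ? u : -u) + ((h & 2) == 0 ? v : -v);
}

// perm: length-512 table (a 0..255 permutation repeated twice)
static double perlin3(const int *perm, double x, double y, double z) {
  int X = (int)std::floor(x) & 255;
  int Y = (int)std::floor(y) & 255;
  int Z = (int)std::floor(z) & 255;
  x -= std::floor(x); y -= std::floor(y); z -= std::floor(z);
  double u = fade(x), v = fade(y), w = fade(z);
  int A  = perm[X] + Y,     AA = perm[A] + Z, AB = perm[A + 1] + Z;
  int B  = perm[X + 1] + Y, BA = perm[B] + Z, BB = perm[B + 1] + Z;
  return lerp(w,
    lerp(v, lerp(u, grad(perm[AA], x, y, z),     grad(perm[BA], x - 1, y, z)),
            lerp(u, grad(perm[AB], x, y - 1, z), grad(perm[BB], x - 1, y - 1, z))),
    lerp(v, lerp(u, grad(perm[AA + 1], x, y, z - 1),     grad(perm[BA + 1], x - 1, y, z - 1)),
            lerp(u, grad(perm[AB + 1], x, y - 1, z - 1), grad(perm[BB + 1], x - 1, y - 1, z - 1))));
}

// fractal sum of octaves, rescaled from [-1, 1] to [0, 1] and clamped
static double fbm3(const int *perm, double x, double y, double z,
                   int octaves, double persistence) {
  double total = 0.0, amp = 1.0, norm = 0.0, freq = 1.0;
  for (int o = 0; o < octaves; ++o) {
    total += amp * perlin3(perm, x * freq, y * freq, z * freq);
    norm += amp;
    amp *= persistence;
    freq *= 2.0;
  }
  double v = 0.5 * (1.0 + total / norm);
  if (v < 0.0) v = 0.0;
  if (v > 1.0) v = 1.0;
  return v;
}

// [[Rcpp::export]]
NumericVector noise3_cpp(IntegerVector perm, NumericVector x, NumericVector y,
                         NumericVector z, int octaves, double persistence) {
  if (perm.size() != 512) stop("permutation table must have length 512");
  R_xlen_t n = x.size();
  if (y.size() != n || z.size() != n) stop("coordinate vectors must have equal length");
  NumericVector out(n);
  const int *p = INTEGER(perm);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!R_finite(x[i]) || !R_finite(y[i]) || !R_finite(z[i]))
      stop("non-finite coordinate");
    out[i] = fbm3(p, x[i], y[i], z[i], octaves, persistence);
  }
  return out;
}

static inline double mod_pos(double x, double m) {
  double r = x - std::floor(x / m) * m;
  if (r < 0) r += m;
  if (r >= m) r = 0.0;
  return r;
}

// standard HSB -> 8-bit RGB (hue in degrees, s/b in percent)
static inline void hsb2rgb(double h, double s, double b, int *rgb) {
  h = mod_pos(h, 360.0);
  double S = s / 100.0, V = b / 100.0;
  double C = V * S;
  double hp = h / 60.0;
  double X = C * (1.0 - std::fabs(mod_pos(hp, 2.0) - 1.0));
  double r = 0, g = 0, bl = 0;
  if (hp < 1)      { r = C; g = X; }
  else if (hp < 2) { r = X; g = C; }
  else if (hp < 3) { g = C; bl = X; }
  else if (hp < 4) { g = X; bl = C; }
  else if (hp < 5) { r = X; bl = C; }
  else             { r = C; bl = X; }
  double m = V - C;
  rgb[0] = (int)std::lround((r + m) * 255.0);
  rgb[1] = (int)std::lround((g + m) * 255.0);
  rgb[2] = (int)std::lround((bl + m) * 255.0);
}

// [[Rcpp::export]]
IntegerVector hsb_to_rgb_cpp(NumericVector h, NumericVector s, NumericVector b) {
  R_xlen_t n = h.size();
  IntegerVector out(n * 3);
  int rgb[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    hsb2rgb(h[i], s[i], b[i], rgb);
    out[i] = rgb[0]; out[n + i] = rgb[1]; out[2 * n + i] = rgb[2];
  }
  out.attr("dim") = Dimension((int)n, 3);
  return out;
}

// Frame loop of the particle simulator. Particles move along the noise
// field direction, are re-drawn uniformly when they leave the canvas, and
// deposit 1-px dots with saturating additive blending. Uses R's RNG for
// re-initialization so a run is reproducible from set.seed().
// [[Rcpp::export]]
List run_sim_cpp(IntegerVector perm, int octaves, double persistence,
                 double spatial_scale, double time_step,
                 int width, int height, double v, double c,
                 double hue_L, double hue_U, double saturation, double brightness,
                 int n_frames, int sample_every,
                 NumericVector x0, NumericVector y0) {
  if (perm.size() != 512) stop("permutation table must have length 512");
  if (c <= 0) stop("direction range constant c must be positive");
  const int n = x0.size();
  const int npix = width * height;
  std::vector<int> cr(npix, 0), cg(npix, 0), cb(npix, 0);
  std::vector<double> px(x0.begin(), x0.end()), py(y0.begin(), y0.end());
  // last canvas pixel each particle painted: a dot is deposited when the
  // particle enters a pixel, so sub-pixel dwell does not re-blend
  std::vector<int> last(n, -1);
  const int n_samples = n_frames / sample_every;
  IntegerVector images((R_xlen_t)npix * 3 * n_samples);
  std::vector<char> hue_seen(361, 0);
  const int *pp = INTEGER(perm);
  RNGScope rng;
  int rgb[3];
  int slot = 0;
  for (int f = 1; f <= n_frames; ++f) {
    double z = (f - 1) * time_step;
    for (int i = 0; i < n; ++i) {
      double nx = px[i] / width * spatial_scale;
      double ny = py[i] / height * spatial_scale;
      double nv = fbm3(pp, nx, ny, z, octaves, persistence);
      double d = nv * c;
      double deg = d * 180.0 / M_PI;
      double hue = deg / 90.0 * (hue_U - hue_L) + hue_L;
      int hr = (int)std::lround(hue);
      if (hr >= 0 && hr <= 360) hue_seen[hr] = 1;
      double xn = px[i] + std::cos(d) * v;
      double yn = py[i] + std::sin(d) * v;
      if (xn < 0 || xn >= width || yn < 0 || yn >= height) {
        xn = R::runif(0.0, (double)width);
        yn = R::runif(0.0, (double)height);
        // runif(0, w) < w almost surely; guard the boundary anyway
        if (xn >= width) xn = 0.0;
        if (yn >= height) yn = 0.0;
      }
      px[i] = xn; py[i] = yn;
      int ix = (int)std::lround(xn); if (ix < 0) ix = 0; if (ix >= width) ix = width - 1;
      int iy = (int)std::lround(yn); if (iy < 0) iy = 0; if (iy >= height) iy = height - 1;
      int idx = iy + ix * height;  // column-major [row = y, col = x]
      if (idx != last[i]) {
        hsb2rgb(hue, saturation, brightness, rgb);
        cr[idx] = std::min(255, cr[idx] + rgb[0]);
        cg[idx] = std::min(255, cg[idx] + rgb[1]);
        cb[idx] = std::min(255, cb[idx] + rgb[2]);
        last[i] = idx;
      }
    }
    if (f % sample_every == 0 && slot < n_samples) {
      R_xlen_t off = (R_xlen_t)slot * npix * 3;
      for (int k = 0; k < npix; ++k) {
        images[off + k] = cr[k];
        images[off + npix + k] = cg[k];
        images[off + 2 * npix + k] = cb[k];
      }
      ++slot;
    }
  }
  std::vector<int> hues;
  for (int h = 0; h <= 360; ++h) if (hue_seen[h]) hues.push_back(h);
  return List::create(_["images"] = images,
                      _["hues"] = wrap(hues),
                      _["n_samples"] = n_samples);
}
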