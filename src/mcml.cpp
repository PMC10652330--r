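// Layered Monte-Carlo photon transport (MCML-style).
//
// Photon packets with weighted absorption, Henyey-Greenstein scattering,
// Fresnel reflection/refraction at layer boundaries, pencil beam at normal
// incidence. Termination is weight-conserving: when a packet's weight
// falls below `w_min` the residual is deposited in the current layer, so
// specular + diffuse reflectance + transmittance + absorbed sums to the
// launched energy to floating-point precision on every run.
//
// Randomness comes from R's RNG (unif_rand), so results are reproducible
// with set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double rnd() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

// Fresnel reflectance for unpolarised light, incidence cosine ca1 >= 0.
static double fresnel(double n1, double n2, double ca1, double *ca2_out) {
  if (n1 == n2) { *ca2_out = ca1; return 0.0; }
  if (ca1 > 1.0 - 1e-12) {  // normal incidence
    *ca2_out = 1.0;
    double r = (n2 - n1) / (n2 + n1);
    return r * r;
  }
  double sa1 = std::sqrt(1.0 - ca1 * ca1);
  double sa2 = n1 * sa1 / n2;
  if (sa2 >= 1.0) { *ca2_out = 0.0; return 1.0; }  // total internal reflection
  double ca2 = std::sqrt(1.0 - sa2 * sa2);
  *ca2_out = ca2;
  double cap = ca1 * ca2 - sa1 * sa2;  // cos(a1 + a2)
  double cam = ca1 * ca2 + sa1 * sa2;  // cos(a1 - a2)
  double sap = sa1 * ca2 + ca1 * sa2;  // sin(a1 + a2)
  double sam = sa1 * ca2 - ca1 * sa2;  // sin(a1 - a2)
  double r = 0.5 * sam * sam * (cam * cam + cap * cap) /
             (sap * sap * cam * cam);
  return r;
}

// [[Rcpp::export(name = ".mcml_run")]]
List mcml_run(NumericVector mua, NumericVector mus, NumericVector g,
              NumericVector nidx, NumericVector thickness,
              int n_photons, double n_ambient = 1.0,
              double w_min = 1e-4, int n_batches = 20) {
  const int nl = mua.size();
  if (n_photons < 1) stop("n_photons must be >= 1");
  std::vector<double> z_top(nl), z_bot(nl);
  double z = 0.0;
  for (int i = 0; i < nl; ++i) {
    z_top[i] = z;
    double d = thickness[i];
    z_bot[i] = R_finite(d) ? z + d : R_PosInf;
    if (R_finite(d)) z += d;
  }
  RNGScope scope;

  // specular reflection at the top surface
  double r0 = (n_ambient - nidx[0]) / (n_ambient + nidx[0]);
  double rsp = r0 * r0;

  std::vector<double> absorbed(nl, 0.0), reach(nl, 0.0);
  double refl = 0.0, trans = 0.0;
  // per-batch accumulators for standard errors
  std::vector< std::vector<double> > b_abs(n_batches,
      std::vector<double>(nl, 0.0));
  std::vector< std::vector<double> > b_reach(n_batches,
      std::vector<double>(nl, 0.0));
  std::vector<double> b_refl(n_batches, 0.0), b_trans(n_batches, 0.0);
  int per_batch = n_photons / n_batches + 1;

  for (int ip = 0; ip < n_photons; ++ip) {
    int batch = ip / per_batch;
    if (batch >= n_batches) batch = n_batches - 1;
    double x = 0.0, y = 0.0, pz = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    int layer = 0;
    unsigned visited = 1u;  // photon starts in layer 0
    reach[0] += w;
    b_reach[batch][0] += w;
    bool alive = true;
    double sleft = 0.0;  // dimensionless step left over from a boundary hit

    while (alive) {
      double mt = mua[layer] + mus[layer];
      double s;
      if (mt > 0.0) {
        if (sleft == 0.0) sleft = -std::log(rnd());
        s = sleft / mt;
      } else {
        s = 1e30;  // ballistic traversal of a clear layer
      }
      // distance to the boundary along the flight direction
      double db = 1e30;
      int to_layer = layer;
      if (uz > 0.0) {
        db = (z_bot[layer] - pz) / uz;
        to_layer = layer + 1;
      } else if (uz < 0.0) {
        db = (z_top[layer] - pz) / uz;
        to_layer = layer - 1;
      }
      if (db <= s) {
        // move to the boundary, bank the unused step
        x += ux * db; y += uy * db; pz += uz * db;
        if (mt > 0.0) sleft -= db * mt; else sleft = 0.0;
        double n1 = nidx[layer];
        double n2 = (to_layer < 0) ? n_ambient
                    : (to_layer >= nl) ? n_ambient : nidx[to_layer];
        double ca1 = std::fabs(uz), ca2;
        double R = fresnel(n1, n2, ca1, &ca2);
        if (rnd() <= R) {
          uz = -uz;  // internal reflection
        } else {
          if (to_layer < 0) { refl += w; b_refl[batch] += w; alive = false; }
          else if (to_layer >= nl) { trans += w; b_trans[batch] += w; alive = false; }
          else {
            double ratio = n1 / n2;
            ux *= ratio; uy *= ratio;
            uz = (uz > 0.0) ? ca2 : -ca2;
            layer = to_layer;
            unsigned bit = 1u << layer;
            if (!(visited & bit)) {
              visited |= bit;
              reach[layer] += w;
              b_reach[batch][layer] += w;
            }
          }
        }
        continue;
      }
      // full step inside the layer: absorb and scatter
      x += ux * s; y += uy * s; pz += uz * s;
      sleft = 0.0;
      if (mt <= 0.0) continue;  // should not happen (db < 1e30 always)
      double dw = w * mua[layer] / mt;
      absorbed[layer] += dw;
      b_abs[batch][layer] += dw;
      w -= dw;
      if (w < w_min) {
        // weight-conserving termination: deposit the residual here
        absorbed[layer] += w;
        b_abs[batch][layer] += w;
        alive = false;
        continue;
      }
      // Henyey-Greenstein deflection
      double gg = g[layer];
      double ct;
      if (std::fabs(gg) < 1e-6) {
        ct = 2.0 * rnd() - 1.0;
      } else {
        double tmp = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * rnd());
        ct = (1.0 + gg * gg - tmp * tmp) / (2.0 * gg);
        if (ct < -1.0) ct = -1.0;
        if (ct > 1.0) ct = 1.0;
      }
      double st = std::sqrt(1.0 - ct * ct);
      double phi = 2.0 * M_PI * rnd();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0.0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        ux = nux; uy = nuy; uz = nuz;
      }
      double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= norm; uy /= norm; uz /= norm;
    }
  }

  double np = static_cast<double>(n_photons);
  NumericVector abs_frac(nl), reach_frac(nl), abs_se(nl), reach_se(nl);
  auto batch_se = [&](std::vector< std::vector<double> > &b, int il) {
    // SE of the total from the spread of batch means
    std::vector<double> means(n_batches);
    for (int k = 0; k < n_batches; ++k) {
      int nb = std::min(per_batch, n_photons - k * per_batch);
      if (nb <= 0) { means[k] = NA_REAL; continue; }
      means[k] = b[k][il] / nb;
    }
    int used = 0; double mu = 0.0;
    for (int k = 0; k < n_batches; ++k)
      if (R_finite(means[k])) { mu += means[k]; ++used; }
    mu /= used;
    double v = 0.0;
    for (int k = 0; k < n_batches; ++k)
      if (R_finite(means[k])) v += (means[k] - mu) * (means[k] - mu);
    v /= (used - 1);
    return std::sqrt(v / used);
  };
  for (int i = 0; i < nl; ++i) {
    abs_frac[i] = absorbed[i] / np;
    reach_frac[i] = reach[i] / np;
    abs_se[i] = batch_se(b_abs, i);
    reach_se[i] = batch_se(b_reach, i);
  }
  auto batch_se1 = [&](std::vector<double> &b) {
    std::vector<double> means;
    for (int k = 0; k < n_batches; ++k) {
      int nb = std::min(per_batch, n_photons - k * per_batch);
      if (nb > 0) means.push_back(b[k] / nb);
    }
    double mu = 0.0;
    for (double m : means) mu += m;
    mu /= means.size();
    double v = 0.0;
    for (double m : means) v += (m - mu) * (m - mu);
    v /= (means.size() - 1);
    return std::sqrt(v / means.size());
  };
  return List::create(
    _["specular"] = rsp,
    _["diffuse_reflectance"] = refl / np,
    _["transmittance"] = trans / np,
    _["absorbed"] = abs_frac,
    _["reached"] = reach_frac,
    _["se"] = List::create(
      _["diffuse_reflectance"] = batch_se1(b_refl),
      _["transmittance"] = batch_se1(b_trans),
      _["absorbed"] = abs_se,
      _["reached"] = reach_se),
    _["n_photons"] = n_photons);
}
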