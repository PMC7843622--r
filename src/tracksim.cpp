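// Event-by-event transport of sub-keV electrons and positrons in water
// with a parameterized discrete-energy-loss physics model.
//
// Each primary history alternates exponential free flights (combined
// inelastic+elastic mean free path) with collisions. Inelastic collisions
// deposit a sampled energy locally (a "spur") and degrade the particle;
// elastic collisions only deflect the direction. Once the particle energy
// falls to the transport cutoff it terminates: the residual energy is
// deposited as a terminal "blob" (optionally Gaussian-smeared for
// positrons), and positrons additionally append annihilation-channel
// ionization events at the terminus. Annihilation photons (0.511 MeV) are
// not transported: their interaction probability over nanometre scales is
// negligible.
//
// Reproducibility: every history owns an independent RNG stream seeded
// from (campaign seed, primary id) via SplitMix64, so campaigns are
// reproducible history-by-history and electron/positron runs with the
// same seed share identical flight/collision sequences until the terminal
// step.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// --- minimal, self-contained RNG (xoshiro256++ seeded by SplitMix64) ---
struct TrackRng {
  uint64_t s[4];
  explicit TrackRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {  // Box-Muller, one value per call
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// log-linear interpolation of the inelastic mfp table, clamped at the ends
double mfp_at(double e, const std::vector<double>& loge,
              const std::vector<double>& logm) {
  double le = std::log(e);
  size_t n = loge.size();
  if (le <= loge.front()) return std::exp(logm.front());
  if (le >= loge.back()) return std::exp(logm.back());
  size_t i = 1;
  while (i < n - 1 && loge[i] < le) ++i;
  double f = (le - loge[i - 1]) / (loge[i] - loge[i - 1]);
  return std::exp(logm[i - 1] + f * (logm[i] - logm[i - 1]));
}

// rotate unit vector d by polar angle theta (rad) about a random azimuth
void deflect(double* d, double theta, double azimuth) {
  double ct = std::cos(theta), st = std::sin(theta);
  double ca = std::cos(azimuth), sa = std::sin(azimuth);
  double dz = d[2];
  double w[3];
  if (std::fabs(dz) < 0.999999) {
    // u = d x z_hat normalised, v = d x u
    double nx = d[1], ny = -d[0];
    double nn = std::sqrt(nx * nx + ny * ny);
    nx /= nn; ny /= nn;
    double vx = d[1] * 0.0 - d[2] * ny;
    double vy = d[2] * nx - d[0] * 0.0;
    double vz = d[0] * ny - d[1] * nx;
    w[0] = ct * d[0] + st * (ca * nx + sa * vx);
    w[1] = ct * d[1] + st * (ca * ny + sa * vy);
    w[2] = ct * d[2] + st * (sa * vz);
  } else {
    double sign = dz > 0 ? 1.0 : -1.0;
    w[0] = st * ca;
    w[1] = st * sa;
    w[2] = sign * ct;
  }
  double nn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  d[0] = w[0] / nn; d[1] = w[1] / nn; d[2] = w[2] / nn;
}

struct EventBuf {
  std::vector<double> primary_id, step, kind, x, y, z, energy;
  void push(int pid, int st, int kd, const double* p, double e) {
    primary_id.push_back(pid); step.push_back(st); kind.push_back(kd);
    x.push_back(p[0]); y.push_back(p[1]); z.push_back(p[2]);
    energy.push_back(e);
  }
};

}  // namespace

// kind codes: 1 = ionization (spur), 3 = blob, 4 = annihilation
// loss_type: 0 = constant (loss_a eV), 1 = truncated exponential
//            (scale loss_a eV, truncated at loss_b eV)
// [[Rcpp::export(name = ".cpp_simulate_tracks")]]
List cpp_simulate_tracks(int n_primaries, double energy, bool positron,
                         NumericVector mfp_energy_ev, NumericVector mfp_nm,
                         double elastic_ratio, double elastic_sigma_deg,
                         int loss_type, double loss_a, double loss_b,
                         double cutoff_ev, double blob_sigma_nm,
                         int annih_n_ion, double annih_energy_ev,
                         double core_annih_prob,
                         double src_radius, double src_zmin, double src_zmax,
                         double seed, bool record_events,
                         bool fixed_start,
                         NumericVector start_pos, NumericVector start_dir) {
  if (energy <= 0) stop("initial energy must be positive");
  if (elastic_ratio <= 0 || elastic_sigma_deg < 0)
    stop("elastic parameters must be positive");
  if (cutoff_ev < 0 || blob_sigma_nm < 0 || annih_n_ion < 0 ||
      annih_energy_ev < 0 || core_annih_prob < 0 || core_annih_prob > 1)
    stop("non-physical physics model parameters");
  if (loss_a <= 0 || (loss_type == 1 && loss_b <= 0))
    stop("energy-loss parameters must be positive");

  std::vector<double> loge(mfp_energy_ev.size()), logm(mfp_nm.size());
  for (int i = 0; i < mfp_energy_ev.size(); ++i) {
    if (mfp_energy_ev[i] <= 0 || mfp_nm[i] <= 0)
      stop("mfp table entries must be positive");
    loge[i] = std::log(mfp_energy_ev[i]);
    logm[i] = std::log(mfp_nm[i]);
  }

  EventBuf buf;
  NumericVector path_length(n_primaries), e_dep(n_primaries),
      e_annih(n_primaries), n_inelastic(n_primaries);
  double sigma_rad = elastic_sigma_deg * M_PI / 180.0;
  uint64_t base = static_cast<uint64_t>(seed);

  for (int pid = 0; pid < n_primaries; ++pid) {
    TrackRng rng(base * 0x100000000ULL + static_cast<uint64_t>(pid));
    double pos[3], dir[3];
    if (fixed_start) {
      pos[0] = start_pos[0]; pos[1] = start_pos[1]; pos[2] = start_pos[2];
      dir[0] = start_dir[0]; dir[1] = start_dir[1]; dir[2] = start_dir[2];
    } else {
      double r = src_radius * std::sqrt(rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      pos[0] = r * std::cos(phi);
      pos[1] = r * std::sin(phi);
      pos[2] = src_zmin + (src_zmax - src_zmin) * rng.unif();
      double ct = 2.0 * rng.unif() - 1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double az = 2.0 * M_PI * rng.unif();
      dir[0] = st * std::cos(az); dir[1] = st * std::sin(az); dir[2] = ct;
    }

    double E = energy, path = 0.0, edep = 0.0, eann = 0.0;
    int step = 0, ninel = 0;

    while (E > cutoff_ev) {
      double lam_in = mfp_at(E, loge, logm);
      double lam_el = lam_in * elastic_ratio;
      double lam_tot = 1.0 / (1.0 / lam_in + 1.0 / lam_el);
      double s = -lam_tot * std::log(rng.unif());
      pos[0] += s * dir[0]; pos[1] += s * dir[1]; pos[2] += s * dir[2];
      path += s;
      ++step;
      if (rng.unif() < lam_tot / lam_in) {
        // inelastic: sample the spur energy loss
        double d;
        if (loss_type == 0) {
          d = loss_a;
        } else {
          double fmax = 1.0 - std::exp(-loss_b / loss_a);
          d = -loss_a * std::log(1.0 - fmax * rng.unif());
        }
        if (d > E) d = E;
        if (record_events) buf.push(pid, step, 1, pos, d);
        edep += d;
        E -= d;
        ++ninel;
      } else {
        deflect(dir, std::fabs(rng.norm()) * sigma_rad,
                2.0 * M_PI * rng.unif());
      }
    }

    // terminal blob: residual energy deposited where the particle stops;
    // positron blobs are smeared over a Gaussian of width blob_sigma_nm
    if (E > 0) {
      double bp[3] = {pos[0], pos[1], pos[2]};
      if (positron && blob_sigma_nm > 0) {
        bp[0] += blob_sigma_nm * rng.norm();
        bp[1] += blob_sigma_nm * rng.norm();
        bp[2] += blob_sigma_nm * rng.norm();
      }
      if (record_events) buf.push(pid, step + 1, 3, bp, E);
      edep += E;
    }

    // annihilation-channel ionizations at the terminus (positrons only);
    // a core annihilation (Auger channel, qualitative) doubles the count
    if (positron && annih_n_ion > 0) {
      int n_ion = annih_n_ion;
      if (core_annih_prob > 0 && rng.unif() < core_annih_prob)
        n_ion *= 2;
      for (int k = 0; k < n_ion; ++k) {
        double ap[3] = {pos[0], pos[1], pos[2]};
        if (blob_sigma_nm > 0) {
          ap[0] += blob_sigma_nm * rng.norm();
          ap[1] += blob_sigma_nm * rng.norm();
          ap[2] += blob_sigma_nm * rng.norm();
        }
        if (record_events) buf.push(pid, step + 2, 4, ap, annih_energy_ev);
        eann += annih_energy_ev;
      }
    }

    path_length[pid] = path;
    e_dep[pid] = edep;
    e_annih[pid] = eann;
    n_inelastic[pid] = ninel;
  }

  List out = List::create(
      _["path_length"] = path_length,
      _["e_deposited"] = e_dep,
      _["e_annihilation"] = e_annih,
      _["n_inelastic"] = n_inelastic);
  if (record_events) {
    size_t ne = buf.primary_id.size();
    out["events"] = DataFrame::create(
        _["primary_id"] = NumericVector(buf.primary_id.begin(), buf.primary_id.end()),
        _["step"] = NumericVector(buf.step.begin(), buf.step.end()),
        _["kind"] = NumericVector(buf.kind.begin(), buf.kind.end()),
        _["x_nm"] = NumericVector(buf.x.begin(), buf.x.end()),
        _["y_nm"] = NumericVector(buf.y.begin(), buf.y.end()),
        _["z_nm"] = NumericVector(buf.z.begin(), buf.z.end()),
        _["energy_ev"] = NumericVector(buf.energy.begin(), buf.energy.end()));
    (void)ne;
  }
  return out;
}
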