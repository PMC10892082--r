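#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Tangent-sphere chain Monte Carlo engine.
//
// The chain state is a flat coords array (x,y,z per bead).  All moves are
// rigid rotations or end re-grafts, so bond lengths are preserved to machine
// precision.  Energy is the (negative) count of non-adjacent pairs within the
// square-well range; moves update it incrementally by rescanning only the
// pairs that a move can change (O(n) for single-bead moves, O(k*(n-k)) for
// pivots), which beats a cell list at n = 80.
//
// All randomness comes from R's RNG (RNGScope), so set.seed() on the R side
// makes every run reproducible.

static const double OVERLAP_TOL = 1.0 - 1e-9;

struct Chain {
  int n;
  std::vector<double> x; // 3*n
  double sigma;          // hard-core diameter == bond length
  double ratt;           // attraction range
  long E;                // energy in units of -eps (E <= 0)
};

static inline double dist2(const std::vector<double> &x, int i, int j) {
  double dx = x[3 * i] - x[3 * j];
  double dy = x[3 * i + 1] - x[3 * j + 1];
  double dz = x[3 * i + 2] - x[3 * j + 2];
  return dx * dx + dy * dy + dz * dz;
}

static inline double pdist2(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// contacts of bead i against all beads |i-j| >= 2; returns -1 on overlap
static long bead_contacts(const Chain &c, int i, const double *pos,
                          int skip_lo, int skip_hi) {
  double r2 = c.ratt * c.ratt;
  double s2 = c.sigma * c.sigma * OVERLAP_TOL * OVERLAP_TOL;
  long cnt = 0;
  for (int j = 0; j < c.n; ++j) {
    if (j >= i - 1 && j <= i + 1) continue;
    if (j >= skip_lo && j <= skip_hi) continue;
    double d2 = pdist2(pos, &c.x[3 * j]);
    if (d2 < s2) return -1;
    if (d2 <= r2) ++cnt;
  }
  return cnt;
}

static long total_energy_raw(const Chain &c) {
  double r2 = c.ratt * c.ratt;
  long cnt = 0;
  for (int i = 0; i < c.n - 2; ++i)
    for (int j = i + 2; j < c.n; ++j)
      if (dist2(c.x, i, j) <= r2) ++cnt;
  return -cnt;
}

static bool has_overlap(const Chain &c) {
  double s2 = c.sigma * c.sigma * OVERLAP_TOL * OVERLAP_TOL;
  for (int i = 0; i < c.n - 2; ++i)
    for (int j = i + 2; j < c.n; ++j)
      if (dist2(c.x, i, j) < s2) return true;
  return false;
}

static inline void unit_sphere(double *u) {
  // Marsaglia normals -> normalized direction
  double v[3];
  for (;;) {
    v[0] = norm_rand(); v[1] = norm_rand(); v[2] = norm_rand();
    double nrm = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    if (nrm > 1e-12) { u[0] = v[0] / nrm; u[1] = v[1] / nrm; u[2] = v[2] / nrm; return; }
  }
}

// uniform random rotation matrix via unit quaternion
static void random_rotation(double R[3][3]) {
  double q[4], nrm = 0.0;
  for (;;) {
    nrm = 0.0;
    for (int k = 0; k < 4; ++k) { q[k] = norm_rand(); nrm += q[k] * q[k]; }
    nrm = std::sqrt(nrm);
    if (nrm > 1e-12) break;
  }
  for (int k = 0; k < 4; ++k) q[k] /= nrm;
  double w = q[0], xx = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (xx * y - w * z); R[0][2] = 2 * (xx * z + w * y);
  R[1][0] = 2 * (xx * y + w * z); R[1][1] = 1 - 2 * (xx * xx + z * z); R[1][2] = 2 * (y * z - w * xx);
  R[2][0] = 2 * (xx * z - w * y); R[2][1] = 2 * (y * z + w * xx); R[2][2] = 1 - 2 * (xx * xx + y * y);
}

// Rodrigues rotation of point p about axis (through origin, unit u) by angle a
static inline void rotate_about(const double *u, double ca, double sa, double *p) {
  double ux = u[0], uy = u[1], uz = u[2];
  double px = p[0], py = p[1], pz = p[2];
  double dot = ux * px + uy * py + uz * pz;
  double cx = uy * pz - uz * py, cy = uz * px - ux * pz, cz = ux * py - uy * px;
  p[0] = px * ca + cx * sa + ux * dot * (1 - ca);
  p[1] = py * ca + cy * sa + uy * dot * (1 - ca);
  p[2] = pz * ca + cz * sa + uz * dot * (1 - ca);
}

// One elementary move attempt.  beta < 0 encodes T = infinity (athermal:
// every self-avoiding candidate accepted).  Returns move type (0..3) in
// *mtype and true if accepted.
static bool attempt_move(Chain &c, double beta, int *mtype,
                         std::vector<double> &scratch) {
  int n = c.n;
  int mt = (int)(unif_rand() * 4.0);
  if (mt > 3) mt = 3;
  *mtype = mt;

  if (mt == 0 || mt == 1) {
    // 0: crankshaft (interior bead about the chord of its neighbours)
    // 1: endpoint re-graft
    int i;
    double np[3];
    if (mt == 0) {
      if (n < 3) return false;
      i = 1 + (int)(unif_rand() * (n - 2));
      if (i > n - 2) i = n - 2;
      double ax[3] = {c.x[3 * (i + 1)] - c.x[3 * (i - 1)],
                      c.x[3 * (i + 1) + 1] - c.x[3 * (i - 1) + 1],
                      c.x[3 * (i + 1) + 2] - c.x[3 * (i - 1) + 2]};
      double nrm = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
      ax[0] /= nrm; ax[1] /= nrm; ax[2] /= nrm;
      double ang = (unif_rand() * 2.0 - 1.0) * M_PI;
      double ca = std::cos(ang), sa = std::sin(ang);
      np[0] = c.x[3 * i] - c.x[3 * (i - 1)];
      np[1] = c.x[3 * i + 1] - c.x[3 * (i - 1) + 1];
      np[2] = c.x[3 * i + 2] - c.x[3 * (i - 1) + 2];
      rotate_about(ax, ca, sa, np);
      np[0] += c.x[3 * (i - 1)]; np[1] += c.x[3 * (i - 1) + 1]; np[2] += c.x[3 * (i - 1) + 2];
    } else {
      i = (unif_rand() < 0.5) ? 0 : n - 1;
      int nb = (i == 0) ? 1 : n - 2;
      double u[3];
      unit_sphere(u);
      np[0] = c.x[3 * nb] + c.sigma * u[0];
      np[1] = c.x[3 * nb + 1] + c.sigma * u[1];
      np[2] = c.x[3 * nb + 2] + c.sigma * u[2];
    }
    long c_old = bead_contacts(c, i, &c.x[3 * i], -1, -1);
    long c_new = bead_contacts(c, i, np, -1, -1);
    if (c_new < 0) return false; // overlap
    long dE = -(c_new - c_old);  // E = -contacts
    if (beta >= 0.0 && dE > 0 && unif_rand() >= std::exp(-beta * (double)dE))
      return false;
    c.x[3 * i] = np[0]; c.x[3 * i + 1] = np[1]; c.x[3 * i + 2] = np[2];
    c.E += dE;
    return true;
  }

  if (mt == 2) {
    // reptation: delete one end bead, regrow at the other end
    bool head = unif_rand() < 0.5; // remove bead 0, grow past n-1
    int rem = head ? 0 : n - 1;
    int grow_nb = head ? n - 1 : 0;
    double u[3], np[3];
    unit_sphere(u);
    np[0] = c.x[3 * grow_nb] + c.sigma * u[0];
    np[1] = c.x[3 * grow_nb + 1] + c.sigma * u[1];
    np[2] = c.x[3 * grow_nb + 2] + c.sigma * u[2];
    // contacts lost with removed end bead
    long c_rem = bead_contacts(c, rem, &c.x[3 * rem], -1, -1);
    // contacts gained by new bead: non-adjacent to everything except grow_nb,
    // and the removed bead no longer exists
    double r2 = c.ratt * c.ratt;
    double s2 = c.sigma * c.sigma * OVERLAP_TOL * OVERLAP_TOL;
    long c_new = 0;
    for (int j = 0; j < n; ++j) {
      if (j == rem || j == grow_nb) continue;
      double d2 = pdist2(np, &c.x[3 * j]);
      if (d2 < s2) return false;
      if (d2 <= r2) ++c_new;
    }
    long dE = -(c_new - c_rem);
    if (beta >= 0.0 && dE > 0 && unif_rand() >= std::exp(-beta * (double)dE))
      return false;
    if (head) {
      std::memmove(&c.x[0], &c.x[3], sizeof(double) * 3 * (n - 1));
      c.x[3 * (n - 1)] = np[0]; c.x[3 * (n - 1) + 1] = np[1]; c.x[3 * (n - 1) + 2] = np[2];
    } else {
      std::memmove(&c.x[3], &c.x[0], sizeof(double) * 3 * (n - 1));
      c.x[0] = np[0]; c.x[1] = np[1]; c.x[2] = np[2];
    }
    c.E += dE;
    return true;
  }

  // pivot: rigid random rotation of one chain arm about an interior bead
  if (n < 3) return false;
  int i = 1 + (int)(unif_rand() * (n - 2));
  if (i > n - 2) i = n - 2;
  bool tail = unif_rand() < 0.5; // rotate beads i+1..n-1, else 0..i-1
  int lo = tail ? i + 1 : 0;
  int hi = tail ? n - 1 : i - 1;
  double Rm[3][3];
  random_rotation(Rm);
  double *piv = &c.x[3 * i];
  scratch.resize(3 * (hi - lo + 1));
  for (int j = lo; j <= hi; ++j) {
    double v[3] = {c.x[3 * j] - piv[0], c.x[3 * j + 1] - piv[1], c.x[3 * j + 2] - piv[2]};
    double *q = &scratch[3 * (j - lo)];
    q[0] = piv[0] + Rm[0][0] * v[0] + Rm[0][1] * v[1] + Rm[0][2] * v[2];
    q[1] = piv[1] + Rm[1][0] * v[0] + Rm[1][1] * v[1] + Rm[1][2] * v[2];
    q[2] = piv[2] + Rm[2][0] * v[0] + Rm[2][1] * v[1] + Rm[2][2] * v[2];
  }
  // cross pairs between moved and fixed beads (internal pairs unchanged)
  double r2 = c.ratt * c.ratt;
  double s2 = c.sigma * c.sigma * OVERLAP_TOL * OVERLAP_TOL;
  long c_old = 0, c_new = 0;
  for (int j = lo; j <= hi; ++j) {
    const double *q = &scratch[3 * (j - lo)];
    for (int k = 0; k < n; ++k) {
      if (k >= lo && k <= hi) continue;
      if (k >= j - 1 && k <= j + 1) continue;
      double d2n = pdist2(q, &c.x[3 * k]);
      if (d2n < s2) return false;
      if (d2n <= r2) ++c_new;
      if (pdist2(&c.x[3 * j], &c.x[3 * k]) <= r2) ++c_old;
    }
  }
  long dE = -(c_new - c_old);
  if (beta >= 0.0 && dE > 0 && unif_rand() >= std::exp(-beta * (double)dE))
    return false;
  std::memcpy(&c.x[3 * lo], &scratch[0], sizeof(double) * 3 * (hi - lo + 1));
  c.E += dE;
  return true;
}

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix coords, double sigma, double ratt) {
  Chain c;
  c.n = coords.nrow();
  c.sigma = sigma;
  c.ratt = ratt;
  c.x.resize(3 * c.n);
  for (int i = 0; i < c.n; ++i)
    for (int k = 0; k < 3; ++k) c.x[3 * i + k] = coords(i, k);
  if (has_overlap(c)) stop("conformation violates the hard core");
  return (double)total_energy_raw(c);
}

// [[Rcpp::export]]
bool cpp_has_overlap(NumericMatrix coords, double sigma) {
  Chain c;
  c.n = coords.nrow();
  c.sigma = sigma;
  c.ratt = sigma;
  c.x.resize(3 * c.n);
  for (int i = 0; i < c.n; ++i)
    for (int k = 0; k < 3; ++k) c.x[3 * i + k] = coords(i, k);
  return has_overlap(c);
}

// Single-temperature MC run.  temperature <= 0 means T = infinity.
// Returns sampled energies, coordinate snapshots and acceptance counters.
// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix coords0, double sigma, double ratt,
                double temperature, int sweeps, int burnin,
                int sample_stride, int snapshot_stride) {
  RNGScope scope;
  Chain c;
  c.n = coords0.nrow();
  c.sigma = sigma;
  c.ratt = ratt;
  c.x.resize(3 * c.n);
  for (int i = 0; i < c.n; ++i)
    for (int k = 0; k < 3; ++k) c.x[3 * i + k] = coords0(i, k);
  if (has_overlap(c)) stop("initial conformation violates the hard core");
  c.E = total_energy_raw(c);
  double beta = (temperature > 0.0) ? 1.0 / temperature : -1.0;

  std::vector<double> energies, snaps;
  std::vector<long> acc(4, 0), att(4, 0);
  std::vector<double> scratch;
  int mtype;
  for (int s = 1; s <= sweeps; ++s) {
    for (int m = 0; m < c.n; ++m) {
      bool ok = attempt_move(c, beta, &mtype, scratch);
      ++att[mtype];
      if (ok) ++acc[mtype];
    }
    if (s > burnin) {
      int t = s - burnin;
      if (sample_stride > 0 && t % sample_stride == 0)
        energies.push_back((double)c.E);
      if (snapshot_stride > 0 && t % snapshot_stride == 0)
        snaps.insert(snaps.end(), c.x.begin(), c.x.end());
    }
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  int nsnap = (int)(snaps.size() / (3 * c.n));
  NumericVector snap_out(snaps.begin(), snaps.end());
  snap_out.attr("dim") = IntegerVector::create(3, c.n, nsnap);
  NumericMatrix final_coords(c.n, 3);
  for (int i = 0; i < c.n; ++i)
    for (int k = 0; k < 3; ++k) final_coords(i, k) = c.x[3 * i + k];
  return List::create(
      _["energies"] = NumericVector(energies.begin(), energies.end()),
      _["snapshots"] = snap_out,
      _["final"] = final_coords,
      _["final_energy"] = (double)c.E,
      _["attempts"] = IntegerVector(att.begin(), att.end()),
      _["accepts"] = IntegerVector(acc.begin(), acc.end()));
}

// Replica-exchange run over a finite temperature ladder.  Snapshots are
// collected for the replica slots listed (1-based) in snap_idx.
// [[Rcpp::export]]
List cpp_run_re(NumericMatrix coords0, double sigma, double ratt,
                NumericVector temps, int sweeps, int burnin, int swap_stride,
                int sample_stride, IntegerVector snap_idx,
                int snapshot_stride) {
  RNGScope scope;
  int m = temps.size();
  int n = coords0.nrow();
  std::vector<Chain> reps(m);
  for (int r = 0; r < m; ++r) {
    reps[r].n = n;
    reps[r].sigma = sigma;
    reps[r].ratt = ratt;
    reps[r].x.resize(3 * n);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) reps[r].x[3 * i + k] = coords0(i, k);
  }
  if (has_overlap(reps[0])) stop("initial conformation violates the hard core");
  long E0 = total_energy_raw(reps[0]);
  std::vector<double> beta(m);
  for (int r = 0; r < m; ++r) {
    reps[r].E = E0;
    beta[r] = 1.0 / temps[r];
  }

  std::vector<std::vector<double> > etrace(m);
  std::vector<std::vector<double> > snaps(snap_idx.size());
  std::vector<long> swap_acc(m > 1 ? m - 1 : 0, 0), swap_att(m > 1 ? m - 1 : 0, 0);
  std::vector<long> acc(4, 0), att(4, 0);
  std::vector<double> scratch;
  int mtype;
  int parity = 0;

  for (int s = 1; s <= sweeps; ++s) {
    for (int r = 0; r < m; ++r) {
      for (int mv = 0; mv < n; ++mv) {
        bool ok = attempt_move(reps[r], beta[r], &mtype, scratch);
        ++att[mtype];
        if (ok) ++acc[mtype];
      }
    }
    if (swap_stride > 0 && s % swap_stride == 0 && m > 1) {
      for (int r = parity; r + 1 < m; r += 2) {
        ++swap_att[r];
        double del = (beta[r] - beta[r + 1]) * ((double)reps[r].E - (double)reps[r + 1].E);
        if (del >= 0.0 || unif_rand() < std::exp(del)) {
          std::swap(reps[r].x, reps[r + 1].x);
          std::swap(reps[r].E, reps[r + 1].E);
          ++swap_acc[r];
        }
      }
      parity = 1 - parity;
    }
    if (s > burnin) {
      int t = s - burnin;
      if (sample_stride > 0 && t % sample_stride == 0)
        for (int r = 0; r < m; ++r) etrace[r].push_back((double)reps[r].E);
      if (snapshot_stride > 0 && t % snapshot_stride == 0)
        for (int q = 0; q < snap_idx.size(); ++q) {
          const Chain &cc = reps[snap_idx[q] - 1];
          snaps[q].insert(snaps[q].end(), cc.x.begin(), cc.x.end());
        }
    }
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List etr(m);
  for (int r = 0; r < m; ++r)
    etr[r] = NumericVector(etrace[r].begin(), etrace[r].end());
  List snp(snap_idx.size());
  for (int q = 0; q < snap_idx.size(); ++q) {
    int nsnap = (int)(snaps[q].size() / (3 * n));
    NumericVector v(snaps[q].begin(), snaps[q].end());
    v.attr("dim") = IntegerVector::create(3, n, nsnap);
    snp[q] = v;
  }
  NumericVector sacc(swap_acc.size());
  for (size_t r = 0; r < swap_acc.size(); ++r)
    sacc[r] = swap_att[r] > 0 ? (double)swap_acc[r] / (double)swap_att[r] : NA_REAL;
  return List::create(
      _["energies"] = etr, _["snapshots"] = snp, _["swap_acceptance"] = sacc,
      _["attempts"] = IntegerVector(att.begin(), att.end()),
      _["accepts"] = IntegerVector(acc.begin(), acc.end()));
}

// Circumsphere radii for a batch of quartets (rows: x1 y1 z1 ... z4).
// Coplanar quartets (singular 3x3 system) get R = Inf.
// [[Rcpp::export]]
NumericVector cpp_quartet_radii(NumericMatrix pts, double det_tol) {
  int nr = pts.nrow();
  NumericVector out(nr);
  for (int r = 0; r < nr; ++r) {
    double p[4][3];
    for (int i = 0; i < 4; ++i)
      for (int k = 0; k < 3; ++k) p[i][k] = pts(r, 3 * i + k);
    // center c solves 2 (p_i - p_0) . c = |p_i|^2 - |p_0|^2, i = 1..3
    double A[3][3], b[3], nrm = 0.0;
    for (int i = 0; i < 3; ++i) {
      double rowsq = 0.0;
      for (int k = 0; k < 3; ++k) {
        A[i][k] = 2.0 * (p[i + 1][k] - p[0][k]);
        rowsq += A[i][k] * A[i][k];
      }
      nrm += std::sqrt(rowsq);
      b[i] = 0.0;
      for (int k = 0; k < 3; ++k)
        b[i] += p[i + 1][k] * p[i + 1][k] - p[0][k] * p[0][k];
    }
    double det =
        A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
        A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
        A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
    double scale = nrm / 3.0;
    if (std::fabs(det) < det_tol * scale * scale * scale) {
      out[r] = R_PosInf;
      continue;
    }
    double cx[3];
    // Cramer
    double B[3][3];
    for (int k = 0; k < 3; ++k) {
      std::memcpy(B, A, sizeof(B));
      for (int i = 0; i < 3; ++i) B[i][k] = b[i];
      cx[k] = (B[0][0] * (B[1][1] * B[2][2] - B[1][2] * B[2][1]) -
               B[0][1] * (B[1][0] * B[2][2] - B[1][2] * B[2][0]) +
               B[0][2] * (B[1][0] * B[2][1] - B[1][1] * B[2][0])) / det;
    }
    double dx = p[0][0] - cx[0], dy = p[0][1] - cx[1], dz = p[0][2] - cx[2];
    out[r] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return out;
}

// Nearest non-local contact for every bead of every snapshot.
// coords: 3 x n x nsnap array (as produced by the MC engines).
// Returns nearest partner index (1-based) and distance, n x nsnap each.
// [[Rcpp::export]]
List cpp_nearest_contacts(NumericVector coords, int n, int nsnap, int min_sep) {
  IntegerMatrix jmat(n, nsnap);
  NumericMatrix dmat(n, nsnap);
  const double *base = coords.begin();
  for (int s = 0; s < nsnap; ++s) {
    const double *x = base + (size_t)3 * n * s;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bj = NA_INTEGER;
      for (int j = 0; j < n; ++j) {
        int sep = j - i; if (sep < 0) sep = -sep;
        if (sep < min_sep) continue;
        double dx = x[3 * i] - x[3 * j];
        double dy = x[3 * i + 1] - x[3 * j + 1];
        double dz = x[3 * i + 2] - x[3 * j + 2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) { best = d2; bj = j + 1; }
      }
      jmat(i, s) = bj;
      dmat(i, s) = std::sqrt(best);
    }
  }
  return List::create(_["j"] = jmat, _["distance"] = dmat);
}
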