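// Gauss-writhe pair kernel and Metropolis Monte Carlo sampler for the
// discretized twistable worm-like chain under force and torque.
//
// Energies are in kBT: E = sum_n a (1 - t_n . t_{n+1})
//                        + sum_n (c/2) s_n^2        (s_n = [u_n x u_{n+1}] . t_n)
//                        - b f sum_n t_n.z
//                        - tau sum_n s_n - 2 pi tau Wr_Gauss.
// The Gauss writhe uses the closed-form mutual solid angle of straight
// segment pairs (Klenin & Langowski method 1a); moves update it through the
// moved-vs-unmoved cross terms only.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
};
static inline Vec3 operator-(const Vec3& a, const Vec3& b) {
  return Vec3(a.x - b.x, a.y - b.y, a.z - b.z);
}
static inline Vec3 operator+(const Vec3& a, const Vec3& b) {
  return Vec3(a.x + b.x, a.y + b.y, a.z + b.z);
}
static inline Vec3 operator*(double s, const Vec3& a) {
  return Vec3(s * a.x, s * a.y, s * a.z);
}
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
static inline double norm3(const Vec3& a) { return std::sqrt(dot(a, a)); }

static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// Mutual solid angle Omega of segments (p1,p2) and (p3,p4); the pair's
// contribution to the writhe is Omega / (2 pi) counted once per unordered
// pair.  Sets *singular if the segments (nearly) intersect.
static double pair_omega(const Vec3& p1, const Vec3& p2, const Vec3& p3,
                         const Vec3& p4, bool* singular) {
  Vec3 r12 = p2 - p1, r34 = p4 - p3;
  Vec3 r13 = p3 - p1, r14 = p4 - p1, r23 = p3 - p2, r24 = p4 - p2;
  Vec3 n1 = cross(r13, r14), n2 = cross(r14, r24);
  Vec3 n3 = cross(r24, r23), n4 = cross(r23, r13);
  double l1 = norm3(n1), l2 = norm3(n2), l3 = norm3(n3), l4 = norm3(n4);
  if (l1 < 1e-14 || l2 < 1e-14 || l3 < 1e-14 || l4 < 1e-14) {
    // coplanar degenerate quadrangle: zero solid angle unless intersecting
    return 0.0;
  }
  Vec3 m1 = (1.0 / l1) * n1, m2 = (1.0 / l2) * n2;
  Vec3 m3 = (1.0 / l3) * n3, m4 = (1.0 / l4) * n4;
  double om = std::asin(clamp1(dot(m1, m2))) + std::asin(clamp1(dot(m2, m3))) +
              std::asin(clamp1(dot(m3, m4))) + std::asin(clamp1(dot(m4, m1)));
  double d = dot(cross(r34, r12), r13);
  if (std::fabs(d) < 1e-12 && std::fabs(om) > 1e-6) {
    // potentially intersecting in a plane: Gauss kernel singular
    *singular = true;
    return 0.0;
  }
  return (d >= 0) ? om : -om;
}

// [[Rcpp::export]]
List cpp_writhe_gauss(NumericMatrix vertices) {
  int nv = vertices.nrow();
  int N = nv - 1;
  std::vector<Vec3> v(nv);
  for (int i = 0; i < nv; ++i)
    v[i] = Vec3(vertices(i, 0), vertices(i, 1), vertices(i, 2));
  double wr = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 2; j < N; ++j) {
      bool sing = false;
      wr += pair_omega(v[i], v[i + 1], v[j], v[j + 1], &sing);
      if (sing && bi < 0) { bi = i; bj = j; }
    }
  }
  return List::create(_["wr"] = wr / (2.0 * M_PI), _["singular_i"] = bi,
                      _["singular_j"] = bj);
}

// Sum of writhe cross terms between segments [i0, i1] and the rest.
// [[Rcpp::export]]
double cpp_writhe_cross(NumericMatrix vertices, int i0, int i1) {
  int nv = vertices.nrow();
  int N = nv - 1;
  std::vector<Vec3> v(nv);
  for (int i = 0; i < nv; ++i)
    v[i] = Vec3(vertices(i, 0), vertices(i, 1), vertices(i, 2));
  double wr = 0.0;
  bool sing = false;
  for (int i = i0; i <= i1; ++i) {
    for (int j = 0; j < N; ++j) {
      if (j >= i0 && j <= i1) continue;
      if (std::abs(i - j) <= 1) continue;
      wr += pair_omega(v[i], v[i + 1], v[j], v[j + 1], &sing);
    }
  }
  return wr / (2.0 * M_PI);
}

// ---------------------------------------------------------------------------
// Monte Carlo sampler (single structural state)

struct Chain {
  int N;
  double b, a, c, f, tau;
  bool use_writhe;
  double hard_core;  // 0 disables
  std::vector<double> R;    // N x 9, row-major 3x3 (columns u, v, t)
  std::vector<Vec3> vert;   // N + 1
  std::vector<double> bend; // N-1: 1 - t.t'
  std::vector<double> tws;  // N-1: s_n
  double sum_tz, wr;

  Vec3 colv(int n, int c_) const {
    return Vec3(R[9 * n + c_], R[9 * n + 3 + c_], R[9 * n + 6 + c_]);
  }
  Vec3 tangent(int n) const { return colv(n, 2); }

  void rebuild_vertices() {
    vert[0] = Vec3(0, 0, 0);
    sum_tz = 0;
    for (int n = 0; n < N; ++n) {
      Vec3 t = tangent(n);
      vert[n + 1] = vert[n] + b * t;
      sum_tz += t.z;
    }
  }
  void junction(int n, double* be, double* s) const {
    Vec3 t1 = tangent(n), t2 = tangent(n + 1);
    Vec3 u1 = colv(n, 0), u2 = colv(n + 1, 0);
    *be = 1.0 - dot(t1, t2);
    *s = dot(cross(u1, u2), t1);
  }
  void rebuild_junctions() {
    for (int n = 0; n < N - 1; ++n) junction(n, &bend[n], &tws[n]);
  }
  double writhe_full(bool* sing) const {
    double w = 0;
    for (int i = 0; i < N; ++i)
      for (int j = i + 2; j < N; ++j)
        w += pair_omega(vert[i], vert[i + 1], vert[j], vert[j + 1], sing);
    return w / (2.0 * M_PI);
  }
  double writhe_cross(int i0, int i1) const {
    double w = 0;
    bool sing = false;
    for (int i = i0; i <= i1; ++i)
      for (int j = 0; j < N; ++j) {
        if (j >= i0 && j <= i1) continue;
        if (std::abs(i - j) <= 1) continue;
        w += pair_omega(vert[i], vert[i + 1], vert[j], vert[j + 1], &sing);
      }
    return w / (2.0 * M_PI);
  }
  bool core_clash(int i0, int i1) const {
    if (hard_core <= 0) return false;
    double d2 = hard_core * hard_core;
    for (int i = i0; i <= i1; ++i)
      for (int j = 0; j < N; ++j) {
        if (j >= i0 - 1 && j <= i1 + 1) continue;
        if (std::abs(i - j) <= 1) continue;
        if (seg_dist2(vert[i], vert[i + 1], vert[j], vert[j + 1]) < d2)
          return true;
      }
    return false;
  }
  static double seg_dist2(const Vec3& p1, const Vec3& p2, const Vec3& q1,
                          const Vec3& q2) {
    // squared minimum distance between segments p1-p2 and q1-q2
    Vec3 d1 = p2 - p1, d2v = q2 - q1, r = p1 - q1;
    double A = dot(d1, d1), E = dot(d2v, d2v), F = dot(d2v, r);
    double C = dot(d1, r), B = dot(d1, d2v);
    double den = A * E - B * B;
    double s = 0, t = 0;
    if (den > 1e-14) s = clamp01((B * F - C * E) / den);
    t = (B * s + F) / E;
    if (t < 0) { t = 0; s = clamp01(-C / A); }
    else if (t > 1) { t = 1; s = clamp01((B - C) / A); }
    Vec3 diff = (p1 + s * d1) - (q1 + t * d2v);
    return dot(diff, diff);
  }
  static double clamp01(double x) {
    return x < 0 ? 0 : (x > 1 ? 1 : x);
  }
};

static void rotmat_axis(const Vec3& axis, double th, double M[9]) {
  double x = axis.x, y = axis.y, z = axis.z;
  double ct = std::cos(th), st = std::sin(th), om = 1.0 - ct;
  M[0] = ct + x * x * om;     M[1] = x * y * om - z * st; M[2] = x * z * om + y * st;
  M[3] = y * x * om + z * st; M[4] = ct + y * y * om;     M[5] = y * z * om - x * st;
  M[6] = z * x * om - y * st; M[7] = z * y * om + x * st; M[8] = ct + z * z * om;
}

static void left_mult(const double M[9], double* Rn) {
  double out[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      out[3 * i + j] = M[3 * i] * Rn[j] + M[3 * i + 1] * Rn[3 + j] +
                       M[3 * i + 2] * Rn[6 + j];
  for (int k = 0; k < 9; ++k) Rn[k] = out[k];
}

// rotate frame n about its own tangent by dphi (right-multiplication by Rz)
static void twist_frame(double* Rn, double dphi) {
  double cd = std::cos(dphi), sd = std::sin(dphi);
  for (int i = 0; i < 3; ++i) {
    double u = Rn[3 * i], v = Rn[3 * i + 1];
    Rn[3 * i] = u * cd + v * sd;
    Rn[3 * i + 1] = -u * sd + v * cd;
  }
}

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix frames0, double b, double a, double c,
                double f, double tau, int n_sweeps, int burn_in, int thin,
                NumericVector move_probs, double max_rot, int window,
                int pivot_window, double hard_core, bool record_writhe) {
  RNGScope scope;
  Chain ch;
  ch.N = frames0.nrow();
  ch.b = b; ch.a = a; ch.c = c; ch.f = f; ch.tau = tau;
  ch.use_writhe = (tau != 0.0);
  ch.hard_core = hard_core;
  ch.R.resize(9 * ch.N);
  for (int n = 0; n < ch.N; ++n)
    for (int k = 0; k < 9; ++k) ch.R[9 * n + k] = frames0(n, k);
  ch.vert.resize(ch.N + 1);
  ch.bend.resize(ch.N - 1);
  ch.tws.resize(ch.N - 1);
  ch.rebuild_vertices();
  ch.rebuild_junctions();
  bool sing = false;
  ch.wr = ch.use_writhe ? ch.writhe_full(&sing) : 0.0;

  const int N = ch.N;
  double p_crank = move_probs[0], p_pivot = move_probs[1];
  long attempts[3] = {0, 0, 0}, accepts[3] = {0, 0, 0};

  int n_rec = (n_sweeps - burn_in + thin - 1) / thin;
  NumericMatrix samples(n_rec > 0 ? n_rec : 0, 4);  // z, tw, wr, wrF
  int rec = 0;

  std::vector<double> Rsave;
  std::vector<Vec3> vsave;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int step = 0; step < N; ++step) {
      double um = unif_rand();
      int mtype = (um < p_crank) ? 0 : (um < p_crank + p_pivot ? 1 : 2);
      attempts[mtype]++;
      if (mtype == 2) {
        // local twist about the tangent: positions unchanged
        int n = (int)(unif_rand() * N);
        if (n >= N) n = N - 1;
        double dphi = (2.0 * unif_rand() - 1.0) * max_rot;
        double old0 = 0, old1 = 0, olds0 = 0, olds1 = 0;
        if (n > 0) { old0 = ch.bend[n - 1]; olds0 = ch.tws[n - 1]; }
        if (n < N - 1) { old1 = ch.bend[n]; olds1 = ch.tws[n]; }
        twist_frame(&ch.R[9 * n], dphi);
        double dE = 0;
        if (n > 0) {
          double be, s; ch.junction(n - 1, &be, &s);
          dE += ch.c / 2 * (s * s - olds0 * olds0) - ch.tau * (s - olds0);
          ch.bend[n - 1] = be; ch.tws[n - 1] = s;
        }
        if (n < N - 1) {
          double be, s; ch.junction(n, &be, &s);
          dE += ch.c / 2 * (s * s - olds1 * olds1) - ch.tau * (s - olds1);
          ch.bend[n] = be; ch.tws[n] = s;
        }
        if (dE <= 0 || unif_rand() < std::exp(-dE)) {
          accepts[2]++;
        } else {
          twist_frame(&ch.R[9 * n], -dphi);
          if (n > 0) { ch.bend[n - 1] = old0; ch.tws[n - 1] = olds0; }
          if (n < N - 1) { ch.bend[n] = old1; ch.tws[n] = olds1; }
        }
        continue;
      }

      // crankshaft or pivot: a rigid rotation of segments [i0, i1]
      int i0, i1;
      Vec3 axis;
      Vec3 pivot;
      double th = (2.0 * unif_rand() - 1.0) * max_rot;
      if (mtype == 0) {
        int len = 2 + (int)(unif_rand() * (window - 1));
        if (len > N - 1) len = N - 1;
        i0 = (int)(unif_rand() * (N - len));
        i1 = i0 + len - 1;  // segments i0..i1 rotate about chord v[i0]-v[i1+1]
        axis = ch.vert[i1 + 1] - ch.vert[i0];
        double la = norm3(axis);
        if (la < 1e-10) continue;
        axis = (1.0 / la) * axis;
        pivot = ch.vert[i0];
      } else {
        // pivot of the tail about a vertex near the free end
        int off = (int)(unif_rand() * pivot_window) + 1;  // tail length
        if (off > N) off = N;
        i0 = N - off; i1 = N - 1;
        pivot = ch.vert[i0];
        // uniform random axis
        double zz = 2.0 * unif_rand() - 1.0, ph = 2.0 * M_PI * unif_rand();
        double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
        axis = Vec3(rr * std::cos(ph), rr * std::sin(ph), zz);
      }

      double M[9];
      rotmat_axis(axis, th, M);
      int nsave = i1 - i0 + 1;
      Rsave.assign(ch.R.begin() + 9 * i0, ch.R.begin() + 9 * (i1 + 1));
      vsave.assign(ch.vert.begin() + i0, ch.vert.begin() + i1 + 2);

      double wr_old_cross = ch.use_writhe ? ch.writhe_cross(i0, i1) : 0.0;
      double dz_old = 0;
      for (int n = i0; n <= i1; ++n) dz_old += ch.tangent(n).z;
      double bend_old0 = 0, tws_old0 = 0, bend_old1 = 0, tws_old1 = 0;
      if (i0 > 0) { bend_old0 = ch.bend[i0 - 1]; tws_old0 = ch.tws[i0 - 1]; }
      if (i1 < N - 1) { bend_old1 = ch.bend[i1]; tws_old1 = ch.tws[i1]; }

      for (int n = i0; n <= i1; ++n) left_mult(M, &ch.R[9 * n]);
      for (int n = i0; n <= i1; ++n)
        ch.vert[n + 1] = ch.vert[n] + ch.b * ch.tangent(n);

      double dE = 0;
      double dz_new = 0;
      for (int n = i0; n <= i1; ++n) dz_new += ch.tangent(n).z;
      dE += -ch.b * ch.f * (dz_new - dz_old);
      if (i0 > 0) {
        double be, s; ch.junction(i0 - 1, &be, &s);
        dE += ch.a * (be - bend_old0) +
              ch.c / 2 * (s * s - tws_old0 * tws_old0) -
              ch.tau * (s - tws_old0);
        ch.bend[i0 - 1] = be; ch.tws[i0 - 1] = s;
      }
      if (i1 < N - 1) {
        double be, s; ch.junction(i1, &be, &s);
        dE += ch.a * (be - bend_old1) +
              ch.c / 2 * (s * s - tws_old1 * tws_old1) -
              ch.tau * (s - tws_old1);
        ch.bend[i1] = be; ch.tws[i1] = s;
      }
      double dwr = 0;
      if (ch.use_writhe) {
        dwr = ch.writhe_cross(i0, i1) - wr_old_cross;
        dE += -2.0 * M_PI * ch.tau * dwr;
      }
      bool reject = ch.core_clash(i0, i1);
      if (!reject && (dE <= 0 || unif_rand() < std::exp(-dE))) {
        accepts[mtype]++;
        ch.sum_tz += dz_new - dz_old;
        ch.wr += dwr;
      } else {
        std::copy(Rsave.begin(), Rsave.end(), ch.R.begin() + 9 * i0);
        std::copy(vsave.begin(), vsave.end(), ch.vert.begin() + i0);
        if (i0 > 0) { ch.bend[i0 - 1] = bend_old0; ch.tws[i0 - 1] = tws_old0; }
        if (i1 < N - 1) { ch.bend[i1] = bend_old1; ch.tws[i1] = tws_old1; }
        (void)nsave;
      }
    }

    // periodic exact refresh against floating-point drift
    if ((sweep + 1) % 200 == 0) {
      ch.rebuild_vertices();
      ch.rebuild_junctions();
      if (ch.use_writhe) {
        bool s2 = false;
        ch.wr = ch.writhe_full(&s2);
      }
    }

    if (sweep >= burn_in && (sweep - burn_in) % thin == 0 && rec < n_rec) {
      double tw = 0;
      for (int n = 0; n < N - 1; ++n) tw += ch.tws[n];
      tw /= 2.0 * M_PI;
      double wrg = ch.wr;
      if (!ch.use_writhe) {
        if (record_writhe) {
          bool s2 = false;
          wrg = ch.writhe_full(&s2);
        } else {
          wrg = NA_REAL;
        }
      }
      // Fuller writhe of the tangent path (signed spherical areas vs +z)
      double wrF = 0;
      for (int n = 0; n < N - 1; ++n) {
        Vec3 t1 = ch.tangent(n), t2 = ch.tangent(n + 1);
        double num = dot(t1, cross(t2, Vec3(0, 0, 1)));
        double den = 1.0 + dot(t1, t2) + t2.z + t1.z;
        wrF += 2.0 * std::atan2(num, den);
      }
      wrF /= 2.0 * M_PI;
      samples(rec, 0) = ch.vert[N].z - ch.vert[0].z;
      samples(rec, 1) = tw;
      samples(rec, 2) = wrg;
      samples(rec, 3) = wrF;
      rec++;
    }
  }

  NumericMatrix framesN(N, 9);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < 9; ++k) framesN(n, k) = ch.R[9 * n + k];
  return List::create(
      _["samples"] = samples,
      _["attempts"] = NumericVector::create(attempts[0], attempts[1], attempts[2]),
      _["accepts"] = NumericVector::create(accepts[0], accepts[1], accepts[2]),
      _["frames"] = framesN);
}
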