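// Lagrangian particle tracking through a tube network with an analytic
// Poiseuille velocity field. The drag term is integrated exactly per substep
// (exponential integrator with frozen coefficients), which keeps the scheme
// stable for relaxation times far below the outer time step; all other
// forces (buoyancy, pressure gradient, virtual-mass fluid acceleration) are
// explicit. Wall collisions are resolved by bisection to the lumen boundary
// followed by a restitution reflection.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
  bool finite() const {
    return std::isfinite(x) && std::isfinite(y) && std::isfinite(z);
  }
};

struct Net {
  const double* px; const double* py; const double* pz;
  const int* ptr;            // nseg+1 offsets into the point array
  const double* radius;
  const double* mvel;        // signed mean velocity, proximal -> distal
  const double* dpds;        // signed pressure gradient along the tangent
  const int* terminal;
  int nseg;
  // junction mixing spheres: per-junction ball (centre, radius) and softened
  // source/sink ports with strengths equal to the solved signed flows
  const double* jx; const double* jy; const double* jz;
  const double* jR;
  const int* pptr;           // njn+1 offsets into the port arrays
  const double* ppx; const double* ppy; const double* ppz;
  const double* pq;
  const double* pdx; const double* pdy; const double* pdz;
  int njn = 0;
  Vec3 point(int i) const { return Vec3(px[i], py[i], pz[i]); }
  Vec3 jpos(int i) const { return Vec3(jx[i], jy[i], jz[i]); }
  Vec3 port(int c) const { return Vec3(ppx[c], ppy[c], ppz[c]); }
  Vec3 pdir(int c) const { return Vec3(pdx[c], pdy[c], pdz[c]); }
};

const double AXIS_EPS = 1e-5;   // m; junction-blend regularization (0.01 mm)

struct Eval {
  bool inside = false;
  Vec3 uf, gp;                  // blended fluid velocity / pressure gradient
  int best = -1;                // containing segment with the nearest axis
  double d_axis = 0, wall = 0, axial = 0;
  Vec3 normal;                  // outward radial normal in the best segment
  int exit_seg = -1;            // terminal segment whose distal cap p lies beyond
  int near = -1;                // globally nearest axis (set whether inside or not)
  double near_d = 1e300;
  Vec3 near_normal;
  int ball = -1;                // containing junction sphere (nearest centre)
  double ball_dn = 1e300;
};

// rp: particle radius. A finite particle's centre cannot approach the wall
// closer than rp, so containment (and hence collision detection) uses the
// contact surface r - rp while the velocity profile is still evaluated at the
// centre position with the true lumen radius.
Eval eval_point(const Net& net, const Vec3& p, double rp, bool want_field) {
  Eval ev;
  double bestd = 1e300;
  double wsum_u = 0, wsum_g = 0;
  for (int s = 0; s < net.nseg; ++s) {
    const int i0 = net.ptr[s], i1 = net.ptr[s + 1];
    double segd2 = 1e300, seg_arc = 0;
    Vec3 seg_q, seg_tan;
    double cum = 0;
    bool beyond_prox = false, beyond_dist = false;
    for (int j = i0; j < i1 - 1; ++j) {
      Vec3 a = net.point(j), b = net.point(j + 1);
      Vec3 d = b - a;
      const double L2 = d.dot(d);
      const double L = std::sqrt(L2);
      double t = (p - a).dot(d) / L2;
      if (j == i0 && t < 0) beyond_prox = true;
      if (j == i1 - 2 && t > 1) beyond_dist = true;
      const double tc = t < 0 ? 0 : (t > 1 ? 1 : t);
      Vec3 q = a + d * tc;
      Vec3 w = p - q;
      const double d2 = w.dot(w);
      if (d2 < segd2) {
        segd2 = d2; seg_q = q; seg_tan = d * (1.0 / L);
        seg_arc = cum + tc * L;
      }
      cum += L;
    }
    const double dseg = std::sqrt(segd2);
    const double r = net.radius[s];
    const double r_eff = std::max(r - rp, 0.05 * r);
    if (dseg < ev.near_d) {
      ev.near = s; ev.near_d = dseg;
      ev.near_normal = dseg > 1e-12 ? (p - seg_q) * (1.0 / dseg) : Vec3(0, 0, 0);
    }
    // the tube is capped by planes at both ends: beyond an end plane is
    // outside (at a junction the parent's cap plays the role of the
    // bifurcation apex wall; at a terminal outlet the crossing is an exit)
    if (dseg <= r_eff && !beyond_prox && !beyond_dist) {
      if (want_field) {
        const double w = 1.0 / (AXIS_EPS + dseg);
        const double shape = 1.0 - (dseg / r) * (dseg / r);
        ev.uf += seg_tan * (w * 2.0 * net.mvel[s] * shape);
        ev.gp += seg_tan * (w * net.dpds[s]);
        wsum_u += w; wsum_g += w;
      }
      ev.inside = true;
      if (dseg < bestd) {
        bestd = dseg;
        ev.best = s; ev.d_axis = dseg; ev.wall = r_eff - dseg; ev.axial = seg_arc;
        ev.normal = dseg > 1e-12 ? (p - seg_q) * (1.0 / dseg) : Vec3(0, 0, 0);
      }
    }
    // distal end-cap crossing of a terminal segment = exit through that outlet
    if (net.terminal[s] && beyond_dist) {
      Vec3 a = net.point(i1 - 2), b = net.point(i1 - 1);
      Vec3 u = b - a;
      u = u * (1.0 / u.norm());
      Vec3 w = p - b;
      const double ax = w.dot(u);
      // only a short collar beyond the cap counts: crossings are caught within
      // one substep (displacement-guarded), and the bound keeps far-away
      // points out of the cap's extended cylinder
      if (ax > 0 && ax <= 2.0 * r) {
        Vec3 lat = w - u * ax;
        if (lat.norm() <= r) ev.exit_seg = s;
      }
    }
  }
  // junction mixing spheres: part of the lumen; potential-flow port field.
  // The ball admits the particle centre within the full radius (junctions
  // bulge, and the attached tubes' contact surfaces already shrink with the
  // particle radius), so large particles keep a connected path through the
  // bifurcation wedge.
  for (int k = 0; k < net.njn; ++k) {
    const double dn = (p - net.jpos(k)).norm();
    const double R = net.jR[k];
    if (dn <= R) {
      ev.inside = true;
      if (dn < ev.ball_dn) { ev.ball = k; ev.ball_dn = dn; }
      if (want_field) {
        const double a = 0.3 * R;  // softening length
        Vec3 vb(0, 0, 0);
        for (int c = net.pptr[k]; c < net.pptr[k + 1]; ++c) {
          Vec3 rv = p - net.port(c);
          const double d = rv.norm();
          // confined (channel-like) 1/d influence, softened at the port, so
          // that the transit flow stays above particle settling speeds
          // throughout the ball
          const double mag = 1.0 / (2.0 * M_PI * a * (a + d));
          if (net.pq[c] > 0)      // inflow: directed softened jet
            vb += net.pdir(c) * (net.pq[c] * mag);
          else if (d > 1e-12)     // outflow: softened converging sink
            vb += rv * (net.pq[c] * mag / d);
        }
        const double w = 1.0 / (AXIS_EPS + dn);
        ev.uf += vb * w;
        wsum_u += w;
      }
    }
  }
  if (ev.inside && want_field) {
    if (wsum_u > 0) ev.uf = ev.uf * (1.0 / wsum_u);
    if (wsum_g > 0) ev.gp = ev.gp * (1.0 / wsum_g);
  }
  return ev;
}

// relation of a point to one segment, for collision-normal classification
struct SegRel {
  double d = 1e300;       // clamped distance to the axis polyline
  bool beyond_prox = false, beyond_dist = false;
  Vec3 radial_normal, prox_dir, dist_dir;
};

SegRel seg_relation(const Net& net, int s, const Vec3& p) {
  SegRel rel;
  const int i0 = net.ptr[s], i1 = net.ptr[s + 1];
  for (int j = i0; j < i1 - 1; ++j) {
    Vec3 a = net.point(j), b = net.point(j + 1);
    Vec3 d = b - a;
    const double L2 = d.dot(d);
    double t = (p - a).dot(d) / L2;
    if (j == i0) {
      rel.prox_dir = d * (1.0 / std::sqrt(L2));
      if (t < 0) rel.beyond_prox = true;
    }
    if (j == i1 - 2) {
      rel.dist_dir = d * (1.0 / std::sqrt(L2));
      if (t > 1) rel.beyond_dist = true;
    }
    const double tc = t < 0 ? 0 : (t > 1 ? 1 : t);
    Vec3 q = a + d * tc;
    const double dd = (p - q).norm();
    if (dd < rel.d) {
      rel.d = dd;
      rel.radial_normal = dd > 1e-12 ? (p - q) * (1.0 / dd) : Vec3(0, 0, 0);
    }
  }
  return rel;
}

struct ParticlePhys {
  double Vp, A, m_eff, tau_p, phi, rho_p, rho_f, mu, cvm, cap;
  Vec3 Fb;  // buoyancy force vector
};

ParticlePhys make_phys(double phi, double rho_p, double rho_f, double mu,
                       const Vec3& g, double cvm, double cap) {
  ParticlePhys ph;
  ph.phi = phi; ph.rho_p = rho_p; ph.rho_f = rho_f; ph.mu = mu;
  ph.cvm = cvm; ph.cap = cap;
  ph.Vp = M_PI / 6.0 * phi * phi * phi;
  ph.A = M_PI * phi * phi / 4.0;
  ph.m_eff = ph.Vp * (rho_p + cvm * rho_f);
  ph.tau_p = rho_p * phi * phi / (18.0 * mu);
  ph.Fb = g * (ph.Vp * (rho_p - rho_f));
  return ph;
}

// one drag-implicit exponential substep; returns new position and velocity
void exp_substep(const ParticlePhys& ph, const Vec3& uf, const Vec3& a_other,
                 double h, const Vec3& x, const Vec3& v,
                 Vec3& xn, Vec3& vn) {
  Vec3 slip = uf - v;
  const double s = slip.norm();
  const double Re = ph.rho_f * s * ph.phi / ph.mu;
  double beta = 3.0 * M_PI * ph.mu * ph.phi * (1.0 + 0.15 * std::pow(Re, 0.687));
  const double beta_cap = 0.5 * ph.cap * ph.rho_f * ph.A * s;
  if (beta_cap > beta) beta = beta_cap;
  const double tau = ph.m_eff / beta;
  const double E = std::exp(-h / tau);
  Vec3 vinf = uf + a_other * tau;
  Vec3 dv = v - vinf;
  xn = x + vinf * h + dv * (tau * (1.0 - E));
  vn = vinf + dv * E;
}

const double ACC_CLAMP = 50.0;  // m/s^2 cap on the finite-difference fluid accel.

}  // namespace

// [[Rcpp::export]]
List cpp_track_particle(NumericMatrix pts, IntegerVector seg_ptr,
                        NumericVector radius, NumericVector mean_vel,
                        NumericVector dpds, IntegerVector terminal,
                        NumericMatrix jn_pos, NumericVector jn_R,
                        IntegerVector port_ptr, NumericMatrix port_pos,
                        NumericVector port_q, NumericMatrix port_dir,
                        NumericVector x0, NumericVector v0,
                        double t0, double t_end, double dt,
                        double phi, double rho_p, double rho_f, double mu,
                        NumericVector gvec, double c_vm, double cap,
                        double e_perp, double e_par, double sub_factor) {
  Net net;
  const int npts = pts.nrow();
  net.px = &pts(0, 0); net.py = &pts(0, 0) + npts; net.pz = &pts(0, 0) + 2 * npts;
  net.ptr = &seg_ptr[0];
  net.radius = &radius[0]; net.mvel = &mean_vel[0]; net.dpds = &dpds[0];
  net.terminal = &terminal[0];
  net.nseg = radius.size();
  net.njn = jn_R.size();
  if (net.njn > 0) {
    const int nj = jn_pos.nrow();
    const int np = port_pos.nrow();
    net.jx = &jn_pos(0, 0); net.jy = &jn_pos(0, 0) + nj; net.jz = &jn_pos(0, 0) + 2 * nj;
    net.jR = &jn_R[0];
    net.pptr = &port_ptr[0];
    net.ppx = &port_pos(0, 0); net.ppy = &port_pos(0, 0) + np;
    net.ppz = &port_pos(0, 0) + 2 * np;
    net.pq = &port_q[0];
    net.pdx = &port_dir(0, 0); net.pdy = &port_dir(0, 0) + np;
    net.pdz = &port_dir(0, 0) + 2 * np;
  }
  net.njn = jn_R.size();
  if (net.njn > 0) {
    const int nj = jn_pos.nrow();
    const int np = port_pos.nrow();
    net.jx = &jn_pos(0, 0); net.jy = &jn_pos(0, 0) + nj; net.jz = &jn_pos(0, 0) + 2 * nj;
    net.jR = &jn_R[0];
    net.pptr = &port_ptr[0];
    net.ppx = &port_pos(0, 0); net.ppy = &port_pos(0, 0) + np;
    net.ppz = &port_pos(0, 0) + 2 * np;
    net.pq = &port_q[0];
    net.pdx = &port_dir(0, 0); net.pdy = &port_dir(0, 0) + np;
    net.pdz = &port_dir(0, 0) + 2 * np;
  }

  ParticlePhys ph = make_phys(phi, rho_p, rho_f, mu,
                              Vec3(gvec[0], gvec[1], gvec[2]), c_vm, cap);
  double h_base = sub_factor * ph.tau_p;
  if (h_base < dt / 100.0) h_base = dt / 100.0;
  if (h_base > dt) h_base = dt;

  const double rp = phi / 2.0;
  Vec3 x(x0[0], x0[1], x0[2]), v(v0[0], v0[1], v0[2]);
  double t = t0, path = 0;
  int bounces = 0, status = 0, exit_seg = -1;
  Vec3 uf_prev; double h_prev = 0; bool have_prev = false;

  const int n_outer = (int)std::ceil((t_end - t0) / dt - 1e-9);
  std::vector<double> s_t, s_x, s_y, s_z, s_v;
  s_t.reserve(n_outer + 1);
  s_t.push_back(t); s_x.push_back(x.x); s_y.push_back(x.y); s_z.push_back(x.z);
  s_v.push_back(v.norm());

  for (int outer = 0; outer < n_outer && status == 0; ++outer) {
    double trem = std::min(dt, t_end - t);
    while (trem > 1e-15 && status == 0) {
      Eval ev = eval_point(net, x, rp, true);
      if (!ev.inside) {
        // numerical drift just past a wall: pull back inside the nearest tube
        if (ev.near >= 0 && ev.near_d < 1.5 * net.radius[ev.near]) {
          const double r_eff = std::max(net.radius[ev.near] - rp,
                                        0.05 * net.radius[ev.near]);
          x += ev.near_normal * (-(ev.near_d - 0.999 * r_eff));
          ev = eval_point(net, x, rp, true);
        }
        if (!ev.inside) {  // or into the nearest junction sphere
          for (int k = 0; k < net.njn; ++k) {
            Vec3 rel = x - net.jpos(k);
            const double dn = rel.norm();
            if (dn < 1.5 * net.jR[k] && dn > 1e-12) {
              x = net.jpos(k) + rel * (0.999 * net.jR[k] / dn);
              ev = eval_point(net, x, rp, true);
              break;
            }
          }
        }
        if (!ev.inside) { status = 4; break; }
      }
      Vec3 a_f(0, 0, 0);
      if (have_prev && h_prev > 0) {
        a_f = (ev.uf - uf_prev) * (1.0 / h_prev);
        if (a_f.x > ACC_CLAMP) a_f.x = ACC_CLAMP; if (a_f.x < -ACC_CLAMP) a_f.x = -ACC_CLAMP;
        if (a_f.y > ACC_CLAMP) a_f.y = ACC_CLAMP; if (a_f.y < -ACC_CLAMP) a_f.y = -ACC_CLAMP;
        if (a_f.z > ACC_CLAMP) a_f.z = ACC_CLAMP; if (a_f.z < -ACC_CLAMP) a_f.z = -ACC_CLAMP;
      }
      Vec3 a_other = (ph.Fb + ev.gp * (-ph.Vp) + a_f * (ph.cvm * ph.rho_f * ph.Vp))
                     * (1.0 / ph.m_eff);
      double h = std::min(h_base, trem);
      Vec3 xn, vn;
      double max_disp = 2.5e-4;
      if (ev.best >= 0) max_disp = 0.5 * net.radius[ev.best];
      else if (ev.ball >= 0) max_disp = 0.5 * net.jR[ev.ball];
      for (int halve = 0; ; ++halve) {
        exp_substep(ph, ev.uf, a_other, h, x, v, xn, vn);
        if ((xn - x).norm() <= max_disp || halve >= 8) break;
        h *= 0.5;
      }
      if (!xn.finite() || !vn.finite()) { status = 4; break; }

      Eval evn = eval_point(net, xn, rp, false);
      if (evn.exit_seg >= 0) {          // crossed an outlet plane
        path += (xn - x).norm();
        x = xn; v = vn; t += h;
        status = 1; exit_seg = evn.exit_seg;
        break;
      }
      if (!evn.inside) {                // wall hit: bisect to the boundary
        Vec3 lo = x, hi = xn;
        for (int it = 0; it < 40; ++it) {
          Vec3 mid = (lo + hi) * 0.5;
          if (eval_point(net, mid, rp, false).inside) lo = mid; else hi = mid;
        }
        Eval evb = eval_point(net, lo, rp, false);
        Vec3 n;
        if (evb.best >= 0) {
          SegRel rel = seg_relation(net, evb.best, hi);
          if (rel.beyond_prox && rel.d <= net.radius[evb.best])
            n = rel.prox_dir * (-1.0);          // entry-plane cap
          else if (rel.beyond_dist && rel.d <= net.radius[evb.best])
            n = rel.dist_dir;                   // junction apex cap
          else if (evb.d_axis > 1e-12)
            n = evb.normal;                     // lateral tube wall
          else {
            Vec3 d = xn - x;
            n = d * (1.0 / d.norm());
          }
        } else if (evb.ball >= 0 && evb.ball_dn > 1e-12) {
          n = (lo - net.jpos(evb.ball)) * (1.0 / evb.ball_dn);  // sphere wall
        } else {
          Vec3 d = xn - x;
          n = d * (1.0 / d.norm());
        }
        path += (lo - x).norm();
        x = lo;
        const double vnrm = vn.dot(n);
        Vec3 vt = vn - n * vnrm;
        v = vt * e_par - n * (e_perp * vnrm);
        ++bounces;
        have_prev = false;
        t += h; trem -= h;
        if (e_perp == 0 && e_par == 0) { v = Vec3(0, 0, 0); status = 2; }
        continue;
      }
      path += (xn - x).norm();
      x = xn; v = vn;
      uf_prev = ev.uf; h_prev = h; have_prev = true;
      t += h; trem -= h;
    }
    s_t.push_back(t); s_x.push_back(x.x); s_y.push_back(x.y); s_z.push_back(x.z);
    s_v.push_back(v.norm());
  }

  const int ns = s_t.size();
  NumericMatrix pos(ns, 3);
  NumericVector times(ns), speed(ns);
  for (int i = 0; i < ns; ++i) {
    times[i] = s_t[i]; speed[i] = s_v[i];
    pos(i, 0) = s_x[i]; pos(i, 1) = s_y[i]; pos(i, 2) = s_z[i];
  }
  return List::create(
    _["status"] = status, _["exit_seg"] = exit_seg + 1,
    _["t_end"] = t, _["path"] = path, _["bounces"] = bounces,
    _["x_end"] = NumericVector::create(x.x, x.y, x.z),
    _["v_end"] = NumericVector::create(v.x, v.y, v.z),
    _["times"] = times, _["pos"] = pos, _["speed"] = speed);
}

// [[Rcpp::export]]
List cpp_track_free(double phi, double rho_p, double rho_f, double mu,
                    NumericVector gvec, double c_vm, double cap,
                    NumericVector u_fluid, NumericVector v0,
                    double duration, double dt, double sub_factor) {
  ParticlePhys ph = make_phys(phi, rho_p, rho_f, mu,
                              Vec3(gvec[0], gvec[1], gvec[2]), c_vm, cap);
  double h_base = sub_factor * ph.tau_p;
  if (h_base < dt / 100.0) h_base = dt / 100.0;
  if (h_base > dt) h_base = dt;
  Vec3 uf(u_fluid[0], u_fluid[1], u_fluid[2]);
  Vec3 x(0, 0, 0), v(v0[0], v0[1], v0[2]);
  Vec3 a_other = ph.Fb * (1.0 / ph.m_eff);  // steady uniform field: no dUf/dt
  double t = 0;
  const int n_outer = (int)std::ceil(duration / dt - 1e-9);
  NumericVector times(n_outer + 1), speed(n_outer + 1);
  times[0] = 0; speed[0] = v.norm();
  for (int outer = 0; outer < n_outer; ++outer) {
    double trem = std::min(dt, duration - t);
    while (trem > 1e-15) {
      const double h = std::min(h_base, trem);
      Vec3 xn, vn;
      exp_substep(ph, uf, a_other, h, x, v, xn, vn);
      x = xn; v = vn; t += h; trem -= h;
    }
    times[outer + 1] = t; speed[outer + 1] = v.norm();
  }
  return List::create(
    _["v_end"] = NumericVector::create(v.x, v.y, v.z),
    _["x_end"] = NumericVector::create(x.x, x.y, x.z),
    _["times"] = times, _["speed"] = speed);
}

// [[Rcpp::export]]
List cpp_locate(NumericMatrix pts, IntegerVector seg_ptr, NumericVector radius,
                NumericMatrix query) {
  Net net;
  const int npts = pts.nrow();
  net.px = &pts(0, 0); net.py = &pts(0, 0) + npts; net.pz = &pts(0, 0) + 2 * npts;
  net.ptr = &seg_ptr[0];
  net.radius = &radius[0];
  net.nseg = radius.size();
  std::vector<double> zero(net.nseg, 0.0);
  std::vector<int> zeroi(net.nseg, 0);
  net.mvel = zero.data(); net.dpds = zero.data(); net.terminal = zeroi.data();

  const int nq = query.nrow();
  IntegerVector inside(nq), segment(nq);
  NumericVector axial(nq), radial(nq), wall(nq);
  NumericMatrix normal(nq, 3);
  for (int i = 0; i < nq; ++i) {
    Eval ev = eval_point(net, Vec3(query(i, 0), query(i, 1), query(i, 2)), 0.0, false);
    inside[i] = ev.inside ? 1 : 0;
    segment[i] = ev.best + 1;
    axial[i] = ev.axial; radial[i] = ev.d_axis; wall[i] = ev.wall;
    normal(i, 0) = ev.normal.x; normal(i, 1) = ev.normal.y; normal(i, 2) = ev.normal.z;
  }
  return List::create(_["inside"] = inside, _["segment"] = segment,
                      _["axial"] = axial, _["radial"] = radial,
                      _["wall_dist"] = wall, _["normal"] = normal);
}

// [[Rcpp::export]]
List cpp_field_eval(NumericMatrix pts, IntegerVector seg_ptr,
                    NumericVector radius, NumericVector mean_vel,
                    NumericVector dpds, IntegerVector terminal,
                    NumericMatrix jn_pos, NumericVector jn_R,
                    IntegerVector port_ptr, NumericMatrix port_pos,
                    NumericVector port_q, NumericMatrix port_dir,
                    NumericMatrix query) {
  Net net;
  const int npts = pts.nrow();
  net.px = &pts(0, 0); net.py = &pts(0, 0) + npts; net.pz = &pts(0, 0) + 2 * npts;
  net.ptr = &seg_ptr[0];
  net.radius = &radius[0]; net.mvel = &mean_vel[0]; net.dpds = &dpds[0];
  net.terminal = &terminal[0];
  net.nseg = radius.size();
  const int nq = query.nrow();
  IntegerVector inside(nq), exit_seg(nq);
  NumericMatrix vel(nq, 3), gradp(nq, 3);
  for (int i = 0; i < nq; ++i) {
    Eval ev = eval_point(net, Vec3(query(i, 0), query(i, 1), query(i, 2)), 0.0, true);
    inside[i] = ev.inside ? 1 : 0;
    exit_seg[i] = ev.exit_seg + 1;
    vel(i, 0) = ev.uf.x; vel(i, 1) = ev.uf.y; vel(i, 2) = ev.uf.z;
    gradp(i, 0) = ev.gp.x; gradp(i, 1) = ev.gp.y; gradp(i, 2) = ev.gp.z;
  }
  return List::create(_["inside"] = inside, _["velocity"] = vel,
                      _["gradp"] = gradp, _["exit_seg"] = exit_seg);
}
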