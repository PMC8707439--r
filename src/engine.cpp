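// MC-DEM engine: soft-sphere dynamics with a hysteretic adhesive
// elastic-plastic normal law and a stress-coupled multi-contact correction.
// Laterally periodic box (x, y), rigid top/bottom plates in z.
//
// Conventions:
//  - SI units throughout.
//  - Pair normal n points from particle i to particle j; the scalar normal
//    force Fn is repulsive when positive and acts on i along -n.
//  - Per-particle stress tensors are compression-positive:
//    sigma_i = -(1/V_i) sum_c sym(l_c (x) F_c), l_c from center to contact.
//  - The multi-contact pressure P_ij uses the previous step's tensors
//    (explicit lagging) and is applied to particle-particle contacts only.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double SQ56 = 0.9128709291752769; // sqrt(5/6)

struct Mat {
  double E, nu, rho, Ew, nuw;
  double e_pp, e_pw, mu_pp, mu_pw, mur_pp, mur_pw;
};

struct CPar {
  double k2r, kcr, phif, beta, F0;
  bool dashpot, friction, rolling;
};

static inline double beta_coef(double e) {
  // restitution -> damping coefficient for the nonlinear dashpot
  double le = std::log(std::max(e, 1e-6));
  return -le / std::sqrt(le * le + M_PI * M_PI);
}

struct PairC {
  int i, j;
  double dmax;          // maximum overlap seen while the contact persists
  double sx, sy, sz;    // tangential spring
};

class Engine {
public:
  int n;
  std::vector<double> r, px, py, pz, vx, vy, vz, wx, wy, wz;
  std::vector<double> fx, fy, fz, tqx, tqy, tqz, m, inert, vol;
  std::vector<double> sig, sig_prev;        // 6*n: xx yy zz xy xz yz
  std::vector<double> wdt, wdb;             // plate-contact max overlaps
  std::vector<double> wst, wsb;             // plate tangential springs (3*n)
  double Lx, Ly, zlo, zhi;
  Mat mat; CPar cp;
  double skin;
  std::vector<double> rx0, ry0, rz0;        // positions at last rebuild
  std::vector<PairC> pairs;
  double ftop, fbot;                        // axial plate reactions (|Fz|)
  double pe;                                // elastic energy estimate
  int ncontact;
  double max_overlap_ratio;
  double gravity;
  bool walls_on;
  bool elastic_clip;                        // pure-elastic mode: clip Fn >= 0

  Engine() : ftop(0), fbot(0), pe(0), ncontact(0), max_overlap_ratio(0),
             gravity(0), walls_on(true), elastic_clip(false) {}

  void init(NumericVector radii, NumericMatrix pos, double Lx_, double Ly_,
            double zlo_, double zhi_, const Mat& mat_, const CPar& cp_,
            double mass_scale) {
    n = radii.size();
    r.assign(radii.begin(), radii.end());
    px.resize(n); py.resize(n); pz.resize(n);
    for (int i = 0; i < n; ++i) { px[i]=pos(i,0); py[i]=pos(i,1); pz[i]=pos(i,2); }
    vx.assign(n,0); vy.assign(n,0); vz.assign(n,0);
    wx.assign(n,0); wy.assign(n,0); wz.assign(n,0);
    fx.assign(n,0); fy.assign(n,0); fz.assign(n,0);
    tqx.assign(n,0); tqy.assign(n,0); tqz.assign(n,0);
    Lx = Lx_; Ly = Ly_; zlo = zlo_; zhi = zhi_;
    mat = mat_; cp = cp_;
    set_masses(mass_scale);
    sig.assign(6*n, 0.0); sig_prev.assign(6*n, 0.0);
    wdt.assign(n,0); wdb.assign(n,0); wst.assign(3*n,0); wsb.assign(3*n,0);
    double rmin = *std::min_element(r.begin(), r.end());
    skin = 0.5 * rmin;
    pairs.clear();
    rebuild();
  }

  void set_masses(double mass_scale) {
    m.resize(n); inert.resize(n); vol.resize(n);
    for (int i = 0; i < n; ++i) {
      vol[i] = 4.0/3.0 * M_PI * r[i]*r[i]*r[i];
      m[i] = vol[i] * mat.rho * mass_scale;
      inert[i] = 0.4 * m[i] * r[i]*r[i];
    }
  }

  inline void minimg(double& dx, double& dy) const {
    dx -= Lx * std::nearbyint(dx / Lx);
    dy -= Ly * std::nearbyint(dy / Ly);
  }

  // ---- neighbor list ------------------------------------------------------
  void rebuild() {
    double rmax = *std::max_element(r.begin(), r.end());
    double h = 2.0 * rmax + skin;
    int ncx = std::max(1, (int)std::floor(Lx / h));
    int ncy = std::max(1, (int)std::floor(Ly / h));
    double zspan = (zhi - zlo) + 2.0 * rmax;
    int ncz = std::max(1, (int)std::floor(zspan / h));
    double hx = Lx / ncx, hy = Ly / ncy, hz = zspan / ncz;
    double zmin = zlo - rmax;

    std::vector<int> head(ncx * ncy * ncz, -1), nxt(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(px[i] / hx); cx = ((cx % ncx) + ncx) % ncx;
      int cy = (int)std::floor(py[i] / hy); cy = ((cy % ncy) + ncy) % ncy;
      int cz = (int)std::floor((pz[i] - zmin) / hz);
      if (cz < 0) cz = 0; if (cz >= ncz) cz = ncz - 1;
      int c = (cz * ncy + cy) * ncx + cx;
      nxt[i] = head[c]; head[c] = i;
    }

    // carry over contact histories
    std::unordered_map<uint64_t, PairC> old;
    old.reserve(pairs.size() * 2 + 8);
    for (const PairC& p : pairs)
      old[((uint64_t)p.i << 32) | (uint64_t)p.j] = p;

    std::vector<PairC> np;
    np.reserve(pairs.size() + 64);
    std::unordered_set<uint64_t> seen;
    seen.reserve(pairs.size() * 2 + 64);
    // half stencil: for every nonzero offset exactly one of {d, -d} appears,
    // so each unordered cell pair is enumerated once; periodic wrapping in
    // x/y can alias offsets for very small grids, which the `seen` set and
    // the aliased-self skip handle.
    for (int cz = 0; cz < ncz; ++cz)
    for (int cy = 0; cy < ncy; ++cy)
    for (int cx = 0; cx < ncx; ++cx) {
      int c = (cz * ncy + cy) * ncx + cx;
      for (int di = 0; di <= 1; ++di)
      for (int dj = (di==0?0:-1); dj <= 1; ++dj)
      for (int dk = (di==0&&dj==0?0:-1); dk <= 1; ++dk) {
        int czz = cz + di;
        if (czz < 0 || czz >= ncz) continue;
        int cyy = ((cy + dj) % ncy + ncy) % ncy;
        int cxx = ((cx + dk) % ncx + ncx) % ncx;
        int c2 = (czz * ncy + cyy) * ncx + cxx;
        bool self = (di == 0 && dj == 0 && dk == 0);
        if (!self && c2 == c) continue;   // wrapped back onto itself
        for (int i = head[c]; i >= 0; i = nxt[i])
        for (int j = (self ? nxt[i] : head[c2]); j >= 0; j = nxt[j]) {
          double dx = px[j]-px[i], dy = py[j]-py[i], dz = pz[j]-pz[i];
          minimg(dx, dy);
          double cut = r[i] + r[j] + skin;
          if (dx*dx + dy*dy + dz*dz < cut*cut) {
            uint64_t a = std::min(i, j), b = std::max(i, j);
            uint64_t key = (a << 32) | b;
            if (!seen.insert(key).second) continue;
            PairC pc; pc.i = (int)a; pc.j = (int)b;
            pc.dmax = 0; pc.sx = pc.sy = pc.sz = 0;
            auto it = old.find(key);
            if (it != old.end()) pc = it->second;
            np.push_back(pc);
          }
        }
      }
    }
    pairs.swap(np);
    rx0.assign(px.begin(), px.end());
    ry0.assign(py.begin(), py.end());
    rz0.assign(pz.begin(), pz.end());
  }

  bool need_rebuild() const {
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = px[i]-rx0[i], dy = py[i]-ry0[i], dz = pz[i]-rz0[i];
      dx -= Lx * std::nearbyint(dx / Lx);
      dy -= Ly * std::nearbyint(dy / Ly);
      if (dx*dx + dy*dy + dz*dz > lim) return true;
    }
    return false;
  }

  // ---- hysteretic normal law (Eq. 6/7/11/12 family) -----------------------
  static inline double hysteretic(double dn, double dmax, double k1,
                                  double k2, double kc, double phif,
                                  double Rstar, double F0) {
    double dn32 = dn * std::sqrt(dn);
    if (k2 <= k1) return F0 + k1 * dn32;     // elastic special case
    double dstar = k2 / (k2 - k1) * phif * 2.0 * Rstar;
    double k2s = (dmax >= dstar) ? k2 : k1 + (k2 - k1) * dmax / dstar;
    double d0 = std::pow(1.0 - k1 / k2s, 2.0/3.0) * dmax;
    double f1 = k1 * dn32;
    double f2 = k2s * (dn32 - d0 * std::sqrt(d0));
    double f3 = -kc * dn32;
    // ties go to the virgin branch; the 1e-12 relative slack absorbs the
    // rounding of ((1 - k1/k2*)^{2/3})^{3/2} during monotone loading
    if (f2 >= f1 - 1e-12 * std::fabs(f1)) return F0 + f1;  // virgin loading
    if (f2 > f3)  return F0 + f2;            // unload / reload
    return F0 + f3;                          // adhesive branch
  }

  inline void addsig(int i, double lx_, double ly_, double lz_,
                     double Fx, double Fy, double Fz) {
    // compression-positive Love-Weber increment
    double* s = &sig[6*i];
    s[0] -= lx_*Fx; s[1] -= ly_*Fy; s[2] -= lz_*Fz;
    s[3] -= 0.5*(lx_*Fy + ly_*Fx);
    s[4] -= 0.5*(lx_*Fz + lz_*Fx);
    s[5] -= 0.5*(ly_*Fz + lz_*Fy);
  }

  // ---- force assembly -----------------------------------------------------
  void compute_forces(double dt, double vplate) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    std::fill(tqx.begin(), tqx.end(), 0.0);
    std::fill(tqy.begin(), tqy.end(), 0.0);
    std::fill(tqz.begin(), tqz.end(), 0.0);
    std::fill(sig.begin(), sig.end(), 0.0);
    ftop = fbot = 0.0; pe = 0.0; ncontact = 0; max_overlap_ratio = 0.0;

    double E = mat.E, nu = mat.nu;
    double Estar_pp = E / (2.0 * (1.0 - nu*nu));
    double G = E / (2.0 * (1.0 + nu));
    double Gstar_pp = G / (2.0 * (2.0 - nu));
    double Gw = mat.Ew / (2.0 * (1.0 + mat.nuw));
    double Estar_pw = 1.0 / ((1.0-nu*nu)/E + (1.0-mat.nuw*mat.nuw)/mat.Ew);
    double Gstar_pw = 1.0 / ((2.0-nu)/G + (2.0-mat.nuw)/Gw);
    double bc_pp = beta_coef(mat.e_pp), bc_pw = beta_coef(mat.e_pw);

    if (gravity != 0.0)
      for (int i = 0; i < n; ++i) fz[i] -= m[i] * gravity;

    if (walls_on) {
      for (int i = 0; i < n; ++i) {
        // top plate (moving): outward normal +z as seen from the particle
        double dn = pz[i] + r[i] - zhi;
        wall_contact(i, dn, +1.0, vplate, Estar_pw, Gstar_pw, bc_pw,
                     &wdt[i], &wst[3*i], dt, &ftop);
        // bottom plate (static)
        dn = zlo - (pz[i] - r[i]);
        wall_contact(i, dn, -1.0, 0.0, Estar_pw, Gstar_pw, bc_pw,
                     &wdb[i], &wsb[3*i], dt, &fbot);
      }
    }

    for (PairC& p : pairs) {
      int i = p.i, j = p.j;
      double dx = px[j]-px[i], dy = py[j]-py[i], dz = pz[j]-pz[i];
      minimg(dx, dy);
      double dist = std::sqrt(dx*dx + dy*dy + dz*dz);
      double dn = r[i] + r[j] - dist;
      if (dn <= 0.0) {
        p.dmax = 0.0; p.sx = p.sy = p.sz = 0.0;
        continue;
      }
      ++ncontact;
      double nxv = dx/dist, nyv = dy/dist, nzv = dz/dist;
      if (dn > p.dmax) p.dmax = dn;
      double rr = dn / std::min(r[i], r[j]);
      if (rr > max_overlap_ratio) max_overlap_ratio = rr;

      double Rstar = r[i]*r[j] / (r[i]+r[j]);
      double k1 = 4.0/3.0 * Estar_pp * std::sqrt(Rstar);
      double k2 = cp.k2r * k1, kc = cp.kcr * k1;
      double Fel = hysteretic(dn, p.dmax, k1, k2, kc, cp.phif, Rstar, cp.F0);

      if (cp.beta > 0.0) {
        double A = M_PI * Rstar * dn;
        double P = (sig_prev[6*i] + sig_prev[6*i+1] + sig_prev[6*i+2] +
                    sig_prev[6*j] + sig_prev[6*j+1] + sig_prev[6*j+2]) / 3.0;
        Fel += cp.beta * nu * A * P;
      }

      double mstar = m[i]*m[j] / (m[i]+m[j]);
      double Fn = Fel;
      double ddot = (vx[i]-vx[j])*nxv + (vy[i]-vy[j])*nyv + (vz[i]-vz[j])*nzv;
      if (cp.dashpot) {
        double Sn = 2.0 * Estar_pp * std::sqrt(Rstar * dn);
        Fn += 2.0 * SQ56 * bc_pp * std::sqrt(Sn * mstar) * ddot;
      }
      if (elastic_clip && Fn < 0.0) Fn = 0.0;

      fx[i] -= Fn*nxv; fy[i] -= Fn*nyv; fz[i] -= Fn*nzv;
      fx[j] += Fn*nxv; fy[j] += Fn*nyv; fz[j] += Fn*nzv;

      double ai = r[i] - 0.5*dn, aj = r[j] - 0.5*dn;
      double Ftx = 0, Fty = 0, Ftz = 0;
      if (cp.friction && Fn > 0.0) {
        // surface velocity of i relative to j at the contact point
        double cxv = (wy[i]*nzv - wz[i]*nyv)*ai + (wy[j]*nzv - wz[j]*nyv)*aj;
        double cyv = (wz[i]*nxv - wx[i]*nzv)*ai + (wz[j]*nxv - wx[j]*nzv)*aj;
        double czv = (wx[i]*nyv - wy[i]*nxv)*ai + (wx[j]*nyv - wy[j]*nxv)*aj;
        double rvx = vx[i]-vx[j] + cxv;
        double rvy = vy[i]-vy[j] + cyv;
        double rvz = vz[i]-vz[j] + czv;
        double vn = rvx*nxv + rvy*nyv + rvz*nzv;
        double vtx = rvx - vn*nxv, vty = rvy - vn*nyv, vtz = rvz - vn*nzv;
        p.sx += vtx*dt; p.sy += vty*dt; p.sz += vtz*dt;
        double sn = p.sx*nxv + p.sy*nyv + p.sz*nzv;
        p.sx -= sn*nxv; p.sy -= sn*nyv; p.sz -= sn*nzv;
        double smag = std::sqrt(p.sx*p.sx + p.sy*p.sy + p.sz*p.sz);
        double kt = 8.0 * Gstar_pp * std::sqrt(Rstar);
        Ftx = -kt*std::sqrt(smag)*p.sx;
        Fty = -kt*std::sqrt(smag)*p.sy;
        Ftz = -kt*std::sqrt(smag)*p.sz;
        if (cp.dashpot) {
          double St = 8.0 * Gstar_pp * std::sqrt(Rstar * dn);
          double gt = 2.0 * SQ56 * bc_pp * std::sqrt(St * mstar);
          Ftx -= gt*vtx; Fty -= gt*vty; Ftz -= gt*vtz;
        }
        double Fmag = std::sqrt(Ftx*Ftx + Fty*Fty + Ftz*Ftz);
        double Fcap = mat.mu_pp * Fn;
        if (Fmag > Fcap && Fmag > 0.0) {
          double sc = Fcap / Fmag;
          Ftx *= sc; Fty *= sc; Ftz *= sc;
          if (smag > 0.0) {
            double snew = std::pow(Fcap / kt, 2.0/3.0) / smag;
            p.sx *= snew; p.sy *= snew; p.sz *= snew;
          }
        }
        fx[i] += Ftx; fy[i] += Fty; fz[i] += Ftz;
        fx[j] -= Ftx; fy[j] -= Fty; fz[j] -= Ftz;
        // torque = l x Ft
        tqx[i] += ai*(nyv*Ftz - nzv*Fty);
        tqy[i] += ai*(nzv*Ftx - nxv*Ftz);
        tqz[i] += ai*(nxv*Fty - nyv*Ftx);
        tqx[j] += aj*(nyv*Ftz - nzv*Fty);
        tqy[j] += aj*(nzv*Ftx - nxv*Ftz);
        tqz[j] += aj*(nxv*Fty - nyv*Ftx);
      } else if (Fn <= 0.0) {
        p.sx = p.sy = p.sz = 0.0;
      }
      if (cp.rolling && Fn > 0.0) {
        double ox = wx[i]-wx[j], oy = wy[i]-wy[j], oz = wz[i]-wz[j];
        double om = std::sqrt(ox*ox + oy*oy + oz*oz);
        if (om > 1e-12) {
          double tq = mat.mur_pp * Rstar * Fn / om;
          tqx[i] -= tq*ox; tqy[i] -= tq*oy; tqz[i] -= tq*oz;
          tqx[j] += tq*ox; tqy[j] += tq*oy; tqz[j] += tq*oz;
        }
      }
      // stress (compression-positive): force on i at l = +a_i n
      addsig(i, ai*nxv, ai*nyv, ai*nzv, -Fn*nxv + Ftx, -Fn*nyv + Fty, -Fn*nzv + Ftz);
      addsig(j, -aj*nxv, -aj*nyv, -aj*nzv, Fn*nxv - Ftx, Fn*nyv - Fty, Fn*nzv - Ftz);
      pe += 0.4 * k1 * dn*dn * std::sqrt(dn);
    }

    for (int i = 0; i < 6*n; ++i) sig_prev[i] = sig[i] / vol[i/6];
  }

  // wall contact: sgn = +1 top plate, -1 bottom plate
  void wall_contact(int i, double dn, double sgn, double vplate,
                    double Estar, double Gstar, double bc,
                    double* dmax, double* spr, double dt, double* plate) {
    if (dn <= 0.0) { *dmax = 0.0; spr[0]=spr[1]=spr[2]=0.0; return; }
    ++ncontact;
    if (dn > *dmax) *dmax = dn;
    double rr = dn / r[i];
    if (rr > max_overlap_ratio) max_overlap_ratio = rr;
    double Rstar = r[i];
    double k1 = 4.0/3.0 * Estar * std::sqrt(Rstar);
    double k2 = cp.k2r * k1, kc = cp.kcr * k1;
    double Fn = hysteretic(dn, *dmax, k1, k2, kc, cp.phif, Rstar, cp.F0);
    double ddot = sgn * vz[i] - sgn * (sgn > 0 ? vplate : 0.0);
    if (cp.dashpot) {
      double Sn = 2.0 * Estar * std::sqrt(Rstar * dn);
      Fn += 2.0 * SQ56 * bc * std::sqrt(Sn * m[i]) * ddot;
    }
    if (elastic_clip && Fn < 0.0) Fn = 0.0;
    fz[i] -= sgn * Fn;
    *plate += Fn;  // axial reaction magnitude on the plate
    double a = r[i] - 0.5*dn;
    double Ftx = 0, Fty = 0;
    if (cp.friction && Fn > 0.0) {
      // tangential (x-y) surface velocity; plate moves only in z
      double vtx = vx[i] + (wy[i]*sgn)*a;    // omega x (a*sgn*z)
      double vty = vy[i] - (wx[i]*sgn)*a;
      spr[0] += vtx*dt; spr[1] += vty*dt;   // normal is z: spring stays in-plane
      double smag = std::sqrt(spr[0]*spr[0] + spr[1]*spr[1]);
      double kt = 8.0 * Gstar * std::sqrt(Rstar);
      Ftx = -kt*std::sqrt(smag)*spr[0];
      Fty = -kt*std::sqrt(smag)*spr[1];
      if (cp.dashpot) {
        double St = 8.0 * Gstar * std::sqrt(Rstar * dn);
        double gt = 2.0 * SQ56 * bc * std::sqrt(St * m[i]);
        Ftx -= gt*vtx; Fty -= gt*vty;
      }
      double Fmag = std::sqrt(Ftx*Ftx + Fty*Fty);
      double Fcap = mat.mu_pw * Fn;
      if (Fmag > Fcap && Fmag > 0.0) {
        double sc = Fcap / Fmag;
        Ftx *= sc; Fty *= sc;
        if (smag > 0.0) {
          double snew = std::pow(Fcap / kt, 2.0/3.0) / smag;
          spr[0] *= snew; spr[1] *= snew;
        }
      }
      fx[i] += Ftx; fy[i] += Fty;
      // l = a * sgn * z ; torque = l x Ft
      tqx[i] += -a*sgn*Fty;
      tqy[i] +=  a*sgn*Ftx;
    } else if (Fn <= 0.0) {
      spr[0] = spr[1] = spr[2] = 0.0;
    }
    if (cp.rolling && Fn > 0.0) {
      double om = std::sqrt(wx[i]*wx[i] + wy[i]*wy[i] + wz[i]*wz[i]);
      if (om > 1e-12) {
        double tq = mat.mur_pw * Rstar * Fn / om;
        tqx[i] -= tq*wx[i]; tqy[i] -= tq*wy[i]; tqz[i] -= tq*wz[i];
      }
    }
    addsig(i, 0.0, 0.0, a*sgn, Ftx, Fty, -sgn*Fn);
  }

  void step(double dt, double vplate, double vcap) {
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / m[i];
      vx[i] += h*fx[i]; vy[i] += h*fy[i]; vz[i] += h*fz[i];
    }
    if (vcap > 0.0) clamp_speeds(vcap);
    for (int i = 0; i < n; ++i) {
      px[i] += dt*vx[i]; py[i] += dt*vy[i]; pz[i] += dt*vz[i];
      px[i] -= Lx * std::floor(px[i] / Lx);
      py[i] -= Ly * std::floor(py[i] / Ly);
    }
    zhi += vplate * dt;
    if (need_rebuild()) rebuild();
    compute_forces(dt, vplate);
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / m[i];
      vx[i] += h*fx[i]; vy[i] += h*fy[i]; vz[i] += h*fz[i];
      double hi = dt / inert[i];
      wx[i] += hi*tqx[i]; wy[i] += hi*tqy[i]; wz[i] += hi*tqz[i];
    }
  }

  void clamp_speeds(double vcap) {
    for (int i = 0; i < n; ++i) {
      double v2 = vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i];
      if (v2 > vcap*vcap) {
        double s = vcap / std::sqrt(v2);
        vx[i] *= s; vy[i] *= s; vz[i] *= s;
      }
    }
  }

  double kinetic() const {
    double k = 0;
    for (int i = 0; i < n; ++i) {
      k += 0.5*m[i]*(vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
      k += 0.5*inert[i]*(wx[i]*wx[i] + wy[i]*wy[i] + wz[i]*wz[i]);
    }
    return k;
  }

  double mean_contact_overlap() const {
    double s = 0; int k = 0;
    for (const PairC& p : pairs) {
      double dx = px[p.j]-px[p.i], dy = py[p.j]-py[p.i], dz = pz[p.j]-pz[p.i];
      double ddx = dx, ddy = dy;
      const_cast<Engine*>(this)->minimg(ddx, ddy);
      double dist = std::sqrt(ddx*ddx + ddy*ddy + dz*dz);
      double dn = r[p.i] + r[p.j] - dist;
      if (dn > 0) { s += dn; ++k; }
    }
    return k ? s / k : 0.0;
  }

  double solid_volume() const {
    double s = 0;
    for (int i = 0; i < n; ++i) s += vol[i];
    return s;
  }
};

static Mat mat_from_list(List L) {
  Mat m;
  m.E = L["young_modulus"]; m.nu = L["poisson_ratio"]; m.rho = L["density"];
  m.Ew = L["wall_young"]; m.nuw = L["wall_poisson"];
  m.e_pp = L["restitution_pp"]; m.e_pw = L["restitution_pw"];
  m.mu_pp = L["sliding_friction_pp"]; m.mu_pw = L["sliding_friction_pw"];
  m.mur_pp = L["rolling_friction_pp"]; m.mur_pw = L["rolling_friction_pw"];
  return m;
}

static CPar cpar_from_list(List L) {
  CPar c;
  c.k2r = L["k2_over_k1"]; c.kcr = L["kc_over_k1"];
  c.phif = L["phi_f"]; c.beta = L["beta"]; c.F0 = L["F0"];
  c.dashpot = L["dashpot"]; c.friction = L["friction"]; c.rolling = L["rolling"];
  return c;
}

static List state_list(const Engine& e) {
  NumericMatrix pos(e.n, 3), vel(e.n, 3);
  NumericVector rad(e.n);
  for (int i = 0; i < e.n; ++i) {
    pos(i,0)=e.px[i]; pos(i,1)=e.py[i]; pos(i,2)=e.pz[i];
    vel(i,0)=e.vx[i]; vel(i,1)=e.vy[i]; vel(i,2)=e.vz[i];
    rad[i]=e.r[i];
  }
  NumericMatrix st(e.n, 6);
  for (int i = 0; i < e.n; ++i)
    for (int k = 0; k < 6; ++k) st(i,k) = e.sig_prev[6*i+k];
  return List::create(_["position"]=pos, _["velocity"]=vel, _["radius"]=rad,
                      _["z_lo"]=e.zlo, _["z_hi"]=e.zhi, _["stress"]=st);
}

// [[Rcpp::export]]
List cpp_pack(NumericVector radii_final, double Lx, double Ly,
              double zlo, double zhi, List material, List control) {
  int n = radii_final.size();
  Mat mat = mat_from_list(material);
  CPar cp; cp.k2r = 1.0; cp.kcr = 0.0; cp.phif = 0.99; cp.beta = 0.0;
  cp.F0 = 0.0; cp.dashpot = true; cp.friction = false; cp.rolling = false;
  double grow_rate = control["grow_rate"];
  int relax_cap = control["relax_cap"];
  int final_cap = control["final_cap"];
  double mean_overlap_tol = control["mean_overlap_tol"];

  Mat gm = mat; gm.e_pp = 0.1; gm.e_pw = 0.1;   // heavily damped growth phase

  // initial scale: start dilute
  double vbox = Lx * Ly * (zhi - zlo);
  double vsol = 0; for (int i = 0; i < n; ++i)
    vsol += 4.0/3.0*M_PI*std::pow(radii_final[i],3);
  double phi = vsol / vbox;
  double s0 = (phi > 0.1) ? std::cbrt(0.1 / phi) : 1.0;

  // random sequential placement at scale s0 (R RNG: reproducible via set.seed)
  NumericMatrix pos(n, 3);
  bool placed_all = false;
  for (int attempt_glob = 0; attempt_glob < 8 && !placed_all; ++attempt_glob) {
    // grid for overlap checks
    double rmax = 0; for (int i = 0; i < n; ++i) rmax = std::max(rmax, s0*radii_final[i]);
    double h = 2.0 * rmax * 1.0001;
    int ncx = std::max(1,(int)(Lx/h)), ncy = std::max(1,(int)(Ly/h));
    int ncz = std::max(1,(int)((zhi-zlo)/h));
    double hx = Lx/ncx, hy = Ly/ncy, hz = (zhi-zlo)/ncz;
    std::vector<std::vector<int>> cells(ncx*ncy*ncz);
    placed_all = true;
    for (int i = 0; i < n; ++i) {
      double ri = s0 * radii_final[i];
      bool ok = false;
      for (int tr = 0; tr < 30000; ++tr) {
        double xi = R::unif_rand() * Lx;
        double yi = R::unif_rand() * Ly;
        double zi = zlo + ri + R::unif_rand() * std::max(zhi - zlo - 2*ri, 1e-300);
        int cx = std::min((int)(xi/hx), ncx-1), cy = std::min((int)(yi/hy), ncy-1);
        int cz = std::min((int)((zi-zlo)/hz), ncz-1);
        bool clash = false;
        for (int a = -1; a <= 1 && !clash; ++a)
        for (int b = -1; b <= 1 && !clash; ++b)
        for (int c = -1; c <= 1 && !clash; ++c) {
          int czz = cz + a; if (czz < 0 || czz >= ncz) continue;
          int cxx = ((cx+b)%ncx+ncx)%ncx, cyy = ((cy+c)%ncy+ncy)%ncy;
          for (int q : cells[(czz*ncy + cyy)*ncx + cxx]) {
            double dx = pos(q,0)-xi, dy = pos(q,1)-yi, dz = pos(q,2)-zi;
            dx -= Lx*std::nearbyint(dx/Lx); dy -= Ly*std::nearbyint(dy/Ly);
            double rs = ri + s0*radii_final[q];
            if (dx*dx+dy*dy+dz*dz < rs*rs) { clash = true; break; }
          }
        }
        if (!clash) {
          pos(i,0)=xi; pos(i,1)=yi; pos(i,2)=zi;
          cells[(cz*ncy + cy)*ncx + cx].push_back(i);
          ok = true; break;
        }
      }
      if (!ok) { placed_all = false; s0 *= 0.85; break; }
    }
  }
  if (!placed_all)
    return List::create(_["converged"]=false, _["reason"]="seeding-failed",
                        _["fraction"]=0.0);

  Engine e;
  std::vector<double> rfin(radii_final.begin(), radii_final.end());
  NumericVector r0(n); for (int i = 0; i < n; ++i) r0[i] = s0*rfin[i];
  e.init(r0, pos, Lx, Ly, zlo, zhi, gm, cp, 1.0);
  e.elastic_clip = true;

  double rmin_f = *std::min_element(rfin.begin(), rfin.end());
  std::vector<double> frac_hist;
  double s = s0;
  int total_steps = 0;
  bool ok = true;
  while (true) {
    double s_new = std::min(1.0, s * grow_rate);
    for (int i = 0; i < e.n; ++i) e.r[i] = s_new * rfin[i];
    e.set_masses(1.0);
    s = s_new;
    frac_hist.push_back(s*s*s*phi);
    // relax
    double rmin = s * rmin_f;
    double Estar = gm.E / (2*(1-gm.nu*gm.nu));
    double k1 = 4.0/3.0*Estar*std::sqrt(rmin/2.0);
    double klin = 1.5 * k1 * std::sqrt(0.05*rmin);
    double mmin = 4.0/3.0*M_PI*rmin*rmin*rmin*gm.rho;
    double dt = 0.2 * std::sqrt(mmin / klin);
    double vcap = 0.05 * rmin / dt;
    int cap = (s >= 1.0) ? final_cap : relax_cap;
    double tol = (s >= 1.0) ? mean_overlap_tol : 2e-2;
    e.rebuild();
    double mean_r = 0; for (int i = 0; i < e.n; ++i) mean_r += e.r[i];
    mean_r /= e.n;
    int it = 0;
    for (; it < cap; ++it) {
      e.step(dt, 0.0, vcap);
      for (int i = 0; i < e.n; ++i) { e.vx[i]*=0.9; e.vy[i]*=0.9; e.vz[i]*=0.9; }
      ++total_steps;
      if (it % 10 == 9 && e.mean_contact_overlap() / mean_r < tol) break;
    }
    if (s >= 1.0) {
      if (e.mean_contact_overlap() / mean_r >= mean_overlap_tol) ok = false;
      break;
    }
  }
  std::fill(e.vx.begin(), e.vx.end(), 0.0);
  std::fill(e.vy.begin(), e.vy.end(), 0.0);
  std::fill(e.vz.begin(), e.vz.end(), 0.0);
  std::fill(e.wx.begin(), e.wx.end(), 0.0);
  std::fill(e.wy.begin(), e.wy.end(), 0.0);
  std::fill(e.wz.begin(), e.wz.end(), 0.0);

  double frac = e.solid_volume() / (Lx*Ly*(e.zhi - e.zlo));
  List st = state_list(e);
  double mr = 0; for (int i = 0; i < e.n; ++i) mr += e.r[i];
  return List::create(_["converged"]=ok, _["reason"]="",
                      _["position"]=st["position"], _["radius"]=st["radius"],
                      _["fraction"]=frac,
                      _["fraction_history"]=NumericVector(frac_hist.begin(), frac_hist.end()),
                      _["mean_overlap_ratio"]=e.mean_contact_overlap()/(mr/e.n),
                      _["n_steps"]=total_steps);
}

// [[Rcpp::export]]
List cpp_compress(NumericMatrix pos, NumericVector radii,
                  double Lx, double Ly, double zlo, double zhi,
                  List material, List params, List protocol, List control) {
  Engine e;
  Mat mat = mat_from_list(material);
  CPar cp = cpar_from_list(params);
  double mass_scaling = control["mass_scaling"];
  e.gravity = control["gravity"];
  e.init(radii, pos, Lx, Ly, zlo, zhi, mat, cp, mass_scaling);

  double dt = control["dt"];
  double plate_speed = protocol["plate_speed"];
  double max_strain = protocol["max_strain"];
  double max_stress = protocol["max_stress"];
  bool decompress = protocol["decompress"];
  int record_every = control["record_every"];
  int max_steps = control["max_steps"];

  double h0 = zhi - zlo, area = Lx * Ly;
  double vsol = e.solid_volume();
  double vplate = -plate_speed;
  int phase = 1;
  std::vector<double> c_strain, c_stress, c_rho, c_ke, c_nc, c_pe;
  double wsum = 0; int wcnt = 0;
  double peak = 0;
  bool unstable = false;
  int steps_done = 0;

  e.compute_forces(dt, vplate);
  for (int step = 1; step <= max_steps; ++step) {
    e.step(dt, vplate, 0.0);
    wsum += e.ftop / area; ++wcnt;
    ++steps_done;
    if (step % record_every == 0) {
      double h = e.zhi - e.zlo;
      double strain = (h0 - h) / h0;
      double sbar = wsum / wcnt; wsum = 0; wcnt = 0;
      double ke = e.kinetic();
      c_strain.push_back(strain); c_stress.push_back(sbar);
      c_rho.push_back(vsol / (area * h));
      c_ke.push_back(ke); c_nc.push_back((double)e.ncontact);
      c_pe.push_back(e.pe);
      if (!std::isfinite(ke)) { unstable = true; break; }
      if (peak < sbar) peak = sbar;
      if (phase == 1 && (strain >= max_strain || sbar >= max_stress)) {
        if (!decompress) break;
        phase = 2; vplate = plate_speed;
      } else if (phase == 2 && (sbar <= std::max(0.0, 1e-4*peak) || strain <= 0.0)) {
        break;
      }
    }
  }

  List st = state_list(e);
  return List::create(
    _["strain"]=NumericVector(c_strain.begin(), c_strain.end()),
    _["stress"]=NumericVector(c_stress.begin(), c_stress.end()),
    _["relative_density"]=NumericVector(c_rho.begin(), c_rho.end()),
    _["kinetic_energy"]=NumericVector(c_ke.begin(), c_ke.end()),
    _["elastic_energy"]=NumericVector(c_pe.begin(), c_pe.end()),
    _["n_contacts"]=NumericVector(c_nc.begin(), c_nc.end()),
    _["state"]=st, _["unstable"]=unstable,
    _["max_overlap_ratio"]=e.max_overlap_ratio,
    _["steps"]=steps_done, _["dt"]=dt, _["plate_speed"]=plate_speed);
}

// [[Rcpp::export]]
List cpp_free_run(NumericMatrix pos, NumericVector radii,
                  NumericMatrix vel, NumericMatrix angvel,
                  double Lx, double Ly, double zlo, double zhi,
                  List material, List params, double dt, int n_steps,
                  int record_every, bool walls) {
  Engine e;
  Mat mat = mat_from_list(material);
  CPar cp = cpar_from_list(params);
  e.init(radii, pos, Lx, Ly, zlo, zhi, mat, cp, 1.0);
  e.walls_on = walls;
  for (int i = 0; i < e.n; ++i) {
    e.vx[i]=vel(i,0); e.vy[i]=vel(i,1); e.vz[i]=vel(i,2);
    e.wx[i]=angvel(i,0); e.wy[i]=angvel(i,1); e.wz[i]=angvel(i,2);
  }
  std::vector<double> t_ke, t_px, t_py, t_pz, t_t;
  e.compute_forces(dt, 0.0);
  for (int s = 1; s <= n_steps; ++s) {
    e.step(dt, 0.0, 0.0);
    if (s % record_every == 0) {
      double mx=0,my=0,mz=0;
      for (int i = 0; i < e.n; ++i) {
        mx += e.m[i]*e.vx[i]; my += e.m[i]*e.vy[i]; mz += e.m[i]*e.vz[i];
      }
      t_t.push_back(s*dt); t_ke.push_back(e.kinetic());
      t_px.push_back(mx); t_py.push_back(my); t_pz.push_back(mz);
    }
  }
  List st = state_list(e);
  return List::create(_["time"]=NumericVector(t_t.begin(), t_t.end()),
                      _["kinetic_energy"]=NumericVector(t_ke.begin(), t_ke.end()),
                      _["momentum_x"]=NumericVector(t_px.begin(), t_px.end()),
                      _["momentum_y"]=NumericVector(t_py.begin(), t_py.end()),
                      _["momentum_z"]=NumericVector(t_pz.begin(), t_pz.end()),
                      _["state"]=st);
}
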