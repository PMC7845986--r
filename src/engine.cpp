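// Compiled integration core: Crank-Nicolson cable solve on the tree
// (Hines-ordered elimination), analytic two-state synaptic kinetics,
// ionic flux injection into the submembrane shell, implicit radial and
// longitudinal anion diffusion, and exact-exponential relaxation
// transport. Mirrors the pure-R reference implementations in R/ (which
// serve as oracles in the test suite).
//
// Units: mV, ms, nA, uS, nF, mM, um (volumes um3, areas um2).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FARADAY = 96485.0;
static const int NSH = 5;  // core + 4 shells

struct Engine {
  int n;                       // nodes
  std::vector<int> parent;     // -1 for root
  std::vector<double> gax, cmn, gl, epas, area;
  // shells
  std::vector<double> vol;     // n*NSH
  std::vector<double> iface;   // n*(NSH-1)
  std::vector<double> dr;      // n
  std::vector<double> cross;   // n*NSH
  std::vector<double> ddx;     // n (to parent)
  // tonic + hh
  std::vector<double> tgcl, tghco3;
  std::vector<double> gna, gk, gca;
  double ena, ek, eca;
  bool has_hh = false;
  std::vector<double> m_, h_, ngate, sgate;
  // synapses
  int ns;
  std::vector<int> snode, skind;
  std::vector<double> samp, dec1, dec2, A, B, se, sp, smg, sslope, sscale;
  // ions
  std::vector<double> cl, hco3;  // n*NSH
  double cl_out, hco3_out, rtf;
  double d_cl, d_hco3, cl_rest, hco3_rest, tau_in, tau_out, tau_hco3;
  bool diffusion_on = true, transport_on = true;

  // precomputed radial factorizations (per node, per D)
  // Thomas: for matrix diag[k] = vol/dt + couplings, off = -gk
  struct RadFac { double cp[NSH - 1]; double denom[NSH]; double gk[NSH - 1]; };
  std::vector<RadFac> rad_cl, rad_hco3;
  // longitudinal factorization per shell layer per D (Hines, constant)
  // store per layer: dprime[i], factor[i] (= off_i / dprime_i of child i)
  struct LonFac { std::vector<double> dprime, factor, off; };
  std::vector<LonFac> lon_cl, lon_hco3;  // NSH layers each

  double dt, theta;

  void prep_radial(double D, std::vector<RadFac>& out) {
    out.resize(n);
    for (int i = 0; i < n; ++i) {
      double diag[NSH];
      RadFac f;
      for (int k = 0; k < NSH; ++k) diag[k] = vol[i * NSH + k] / dt;
      for (int k = 0; k < NSH - 1; ++k) {
        double g = D * iface[i * (NSH - 1) + k] / dr[i];
        f.gk[k] = g;
        diag[k] += g;
        diag[k + 1] += g;
      }
      // Thomas factorization (symmetric: sub = super = -g)
      f.denom[0] = 1.0 / diag[0];
      for (int k = 1; k < NSH; ++k) {
        f.cp[k - 1] = -f.gk[k - 1] * f.denom[k - 1];
        f.denom[k] = 1.0 / (diag[k] + f.gk[k - 1] * f.cp[k - 1]);
      }
      out[i] = f;
    }
  }

  void radial_apply(const RadFac& f, double* c, const double* v) {
    // rhs = vol*c/dt ; forward sweep then back substitution
    double d[NSH];
    for (int k = 0; k < NSH; ++k) d[k] = v[k] * c[k] / dt;
    d[0] = d[0] * f.denom[0];
    for (int k = 1; k < NSH; ++k)
      d[k] = (d[k] + f.gk[k - 1] * d[k - 1]) * f.denom[k];
    c[NSH - 1] = d[NSH - 1];
    for (int k = NSH - 2; k >= 0; --k)
      c[k] = d[k] - f.cp[k] * c[k + 1];
  }

  void prep_longitudinal(double D, std::vector<LonFac>& out) {
    out.resize(NSH);
    for (int k = 0; k < NSH; ++k) {
      LonFac f;
      f.dprime.assign(n, 0.0);
      f.factor.assign(n, 0.0);
      f.off.assign(n, 0.0);
      std::vector<double> diag(n);
      for (int i = 0; i < n; ++i) diag[i] = vol[i * NSH + k] / dt;
      for (int i = 1; i < n; ++i) {
        int p = parent[i];
        if (p < 0) continue;
        double shared = std::min(cross[i * NSH + k], cross[p * NSH + k]);
        double g = D * shared / ddx[i];
        f.off[i] = -g;
        diag[i] += g;
        diag[p] += g;
      }
      // Hines elimination on the constant matrix (children have larger
      // indices than parents)
      for (int i = n - 1; i >= 1; --i) {
        int p = parent[i];
        f.dprime[i] = diag[i];
        if (p < 0) continue;
        double fac = f.off[i] / diag[i];
        f.factor[i] = fac;
        diag[p] -= fac * f.off[i];
      }
      f.dprime[0] = diag[0];
      out[k] = f;
    }
  }

  void longitudinal_apply(const LonFac& f, std::vector<double>& conc, int k) {
    // rhs
    std::vector<double>& rhs = scratch;
    for (int i = 0; i < n; ++i) rhs[i] = vol[i * NSH + k] / dt * conc[i * NSH + k];
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      if (p < 0) continue;
      rhs[p] -= f.factor[i] * rhs[i];
    }
    std::vector<double>& x = scratch2;
    x[0] = rhs[0] / f.dprime[0];
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      x[i] = (p < 0) ? rhs[i] / f.dprime[i]
                     : (rhs[i] - f.off[i] * x[p]) / f.dprime[i];
    }
    for (int i = 0; i < n; ++i) conc[i * NSH + k] = x[i];
  }

  std::vector<double> scratch, scratch2;

  inline double ecl_at(int i) const {
    return rtf * std::log(cl[i * NSH + NSH - 1] / cl_out);
  }
  inline double ehco3_at(int i) const {
    return rtf * std::log(hco3[i * NSH + NSH - 1] / hco3_out);
  }
};

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List nodes, List syn, List events, List ions, List cfg) {
  Engine E;
  IntegerVector parent = nodes["parent"];
  NumericVector gax = nodes["gax"], cmn = nodes["cm_nF"], gl = nodes["gl_uS"];
  NumericVector area = nodes["area_cm2"], ddx = nodes["ddx_um"];
  NumericMatrix vol = nodes["vol"], iface = nodes["iface"], cross = nodes["cross"];
  NumericVector drv = nodes["dr"];
  NumericVector tgcl = nodes["tonic_gcl_uS"], tghco3 = nodes["tonic_ghco3_uS"];
  NumericVector gna = nodes["gna_uS"], gk = nodes["gk_uS"], gca = nodes["gca_uS"];
  E.n = parent.size();
  int n = E.n;
  E.parent.assign(parent.begin(), parent.end());
  E.gax.assign(gax.begin(), gax.end());
  E.cmn.assign(cmn.begin(), cmn.end());
  E.gl.assign(gl.begin(), gl.end());
  E.area.assign(area.begin(), area.end());
  E.ddx.assign(ddx.begin(), ddx.end());
  E.dr.assign(drv.begin(), drv.end());
  E.epas.assign(n, as<double>(nodes["e_pas"]));
  E.tgcl.assign(tgcl.begin(), tgcl.end());
  E.tghco3.assign(tghco3.begin(), tghco3.end());
  E.gna.assign(gna.begin(), gna.end());
  E.gk.assign(gk.begin(), gk.end());
  E.gca.assign(gca.begin(), gca.end());
  E.ena = as<double>(nodes["e_na"]);
  E.ek = as<double>(nodes["e_k"]);
  E.eca = as<double>(nodes["e_ca"]);
  for (int i = 0; i < n; ++i)
    if (E.gna[i] > 0 || E.gk[i] > 0 || E.gca[i] > 0) E.has_hh = true;

  E.vol.resize(n * NSH); E.cross.resize(n * NSH); E.iface.resize(n * (NSH - 1));
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < NSH; ++k) {
      E.vol[i * NSH + k] = vol(i, k);
      E.cross[i * NSH + k] = cross(i, k);
    }
    for (int k = 0; k < NSH - 1; ++k) E.iface[i * (NSH - 1) + k] = iface(i, k);
  }

  // synapses
  IntegerVector snode = syn["node"], skind = syn["kind"];
  NumericVector sg = syn["gmax_nS"], st1 = syn["tau1"], st2 = syn["tau2"];
  NumericVector snf = syn["nf"], se = syn["e_rev"], sp = syn["p"];
  NumericVector smg = syn["mg"], ssl = syn["mg_slope"], ssc = syn["mg_scale"];
  E.ns = snode.size();
  E.snode.assign(snode.begin(), snode.end());
  E.skind.assign(skind.begin(), skind.end());
  E.se.assign(se.begin(), se.end());
  E.sp.assign(sp.begin(), sp.end());
  E.smg.assign(smg.begin(), smg.end());
  E.sslope.assign(ssl.begin(), ssl.end());
  E.sscale.assign(ssc.begin(), ssc.end());

  double dt = as<double>(cfg["dt"]);
  int n_steps = as<int>(cfg["n_steps"]);
  int stride = as<int>(cfg["stride"]);
  double theta = as<double>(cfg["theta"]);
  IntegerVector probes = cfg["probes"];
  NumericVector v_init = cfg["v_init"];
  int ic_node = as<int>(cfg["iclamp_node"]);
  double ic_amp = as<double>(cfg["iclamp_amp"]);
  double ic_start = as<double>(cfg["iclamp_start"]);
  double ic_stop = as<double>(cfg["iclamp_stop"]);
  E.diffusion_on = as<bool>(cfg["diffusion_on"]);
  E.transport_on = as<bool>(cfg["transport_on"]);
  E.dt = dt; E.theta = theta;

  // synapse amplitudes and per-step decay factors; conductances are
  // evaluated at the step midpoint (analytic half-decay) for second-order
  // accuracy of the conductance treatment
  E.samp.resize(E.ns); E.dec1.resize(E.ns); E.dec2.resize(E.ns);
  std::vector<double> hdec1(E.ns), hdec2(E.ns);
  E.A.assign(E.ns, 0.0); E.B.assign(E.ns, 0.0);
  for (int s = 0; s < E.ns; ++s) {
    E.samp[s] = sg[s] * snf[s];
    E.dec1[s] = std::exp(-dt / st1[s]);
    E.dec2[s] = std::exp(-dt / st2[s]);
    hdec1[s] = std::exp(-0.5 * dt / st1[s]);
    hdec2[s] = std::exp(-0.5 * dt / st2[s]);
  }

  // events, sorted by time (R guarantees)
  IntegerVector ev_syn = events["syn"];
  NumericVector ev_t = events["time"];
  int nev = ev_syn.size(), ev_ptr = 0;

  // ions
  NumericMatrix cl0 = ions["cl"], hco30 = ions["hco3"];
  E.cl.resize(n * NSH); E.hco3.resize(n * NSH);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSH; ++k) {
      E.cl[i * NSH + k] = cl0(i, k);
      E.hco3[i * NSH + k] = hco30(i, k);
    }
  E.cl_out = as<double>(ions["cl_out"]);
  E.hco3_out = as<double>(ions["hco3_out"]);
  E.rtf = as<double>(ions["rtf_mV"]);
  E.d_cl = as<double>(ions["d_cl"]);
  E.d_hco3 = as<double>(ions["d_hco3"]);
  E.cl_rest = as<double>(ions["cl_rest"]);
  E.hco3_rest = as<double>(ions["hco3_rest"]);
  E.tau_in = as<double>(ions["tau_influx_ms"]);
  E.tau_out = as<double>(ions["tau_efflux_ms"]);
  E.tau_hco3 = as<double>(ions["tau_hco3_ms"]);
  double fac_in = std::exp(-dt / E.tau_in);
  double fac_out = std::exp(-dt / E.tau_out);
  double fac_hc = std::exp(-dt / E.tau_hco3);

  E.scratch.assign(n, 0.0);
  E.scratch2.assign(n, 0.0);
  if (E.diffusion_on) {
    E.prep_radial(E.d_cl, E.rad_cl);
    E.prep_radial(E.d_hco3, E.rad_hco3);
    E.prep_longitudinal(E.d_cl, E.lon_cl);
    E.prep_longitudinal(E.d_hco3, E.lon_hco3);
  }

  // HH gates at steady state of v_init
  std::vector<double> m(n, 0), h(n, 0), ng(n, 0), sg_(n, 0);
  auto vtrap = [](double x, double y) {
    return (std::fabs(x / y) < 1e-6) ? y * (1 - x / y / 2) : x / (std::exp(x / y) - 1.0);
  };
  auto rate_set = [&](double v, double* r) {
    r[0] = 0.1 * vtrap(-(v + 40.0), 10.0);       // am
    r[1] = 4.0 * std::exp(-(v + 65.0) / 18.0);   // bm
    r[2] = 0.07 * std::exp(-(v + 65.0) / 20.0);  // ah
    r[3] = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));  // bh
    r[4] = 0.01 * vtrap(-(v + 55.0), 10.0);      // an
    r[5] = 0.125 * std::exp(-(v + 65.0) / 80.0); // bn
  };
  std::vector<double> V(v_init.begin(), v_init.end());
  if (E.has_hh) {
    for (int i = 0; i < n; ++i) {
      double r[6];
      rate_set(V[i], r);
      m[i] = r[0] / (r[0] + r[1]);
      h[i] = r[2] / (r[2] + r[3]);
      ng[i] = r[4] / (r[4] + r[5]);
      sg_[i] = 1.0 / (1.0 + std::exp(-(V[i] + 20.0) / 9.0));
    }
  }

  int n_rec = n_steps / stride + 1;
  int np = probes.size();
  NumericVector time(n_rec);
  NumericMatrix Vrec(n_rec, np), CLrec(n_rec, np), HCrec(n_rec, np),
      CLmean(n_rec, np), ICLrec(n_rec, np);
  NumericVector totcl(n_rec), tothc(n_rec);

  std::vector<double> diag(n), rhs(n), off(n), gtot(n), ge(n), inj(n);
  std::vector<double> icl_probe(n, 0.0);  // per-node chloride current (nA)
  std::vector<double> sgcl(E.ns, 0.0), secl(E.ns, 0.0), sehc(E.ns, 0.0),
      sghc(E.ns, 0.0);

  int rec = 0;
  auto record = [&](int step) {
    double t = step * dt;
    time[rec] = t;
    for (int j = 0; j < np; ++j) {
      int i = probes[j];
      Vrec(rec, j) = V[i];
      CLrec(rec, j) = E.cl[i * NSH + NSH - 1];
      HCrec(rec, j) = E.hco3[i * NSH + NSH - 1];
      double vsum = 0, csum = 0;
      for (int k = 0; k < NSH; ++k) {
        vsum += E.vol[i * NSH + k];
        csum += E.vol[i * NSH + k] * E.cl[i * NSH + k];
      }
      CLmean(rec, j) = csum / vsum;
      ICLrec(rec, j) = icl_probe[i];
    }
    double tc = 0, th = 0;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < NSH; ++k) {
        tc += E.cl[i * NSH + k] * E.vol[i * NSH + k];
        th += E.hco3[i * NSH + k] * E.vol[i * NSH + k];
      }
    totcl[rec] = tc;
    tothc[rec] = th;
    ++rec;
  };
  record(0);

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    // 1. deliver due events
    while (ev_ptr < nev && ev_t[ev_ptr] <= t + 1e-9) {
      int s = ev_syn[ev_ptr];
      E.A[s] += E.samp[s];
      E.B[s] += E.samp[s];
      ++ev_ptr;
    }
    // 2. membrane terms frozen at step start
    for (int i = 0; i < n; ++i) {
      gtot[i] = E.gl[i];
      ge[i] = E.gl[i] * E.epas[i];
      inj[i] = 0.0;
      icl_probe[i] = 0.0;
    }
    if (ic_node >= 0 && t >= ic_start - 1e-9 && t < ic_stop - 1e-9)
      inj[ic_node] += ic_amp;
    // tonic GABA
    for (int i = 0; i < n; ++i) {
      if (E.tgcl[i] > 0 || E.tghco3[i] > 0) {
        double ecl = E.ecl_at(i), ehc = E.ehco3_at(i);
        gtot[i] += E.tgcl[i] + E.tghco3[i];
        ge[i] += E.tgcl[i] * ecl + E.tghco3[i] * ehc;
      }
    }
    // synapses
    for (int s = 0; s < E.ns; ++s) {
      sgcl[s] = sghc[s] = 0.0;
      // mid-step conductance, nS -> uS
      double g = (E.B[s] * hdec2[s] - E.A[s] * hdec1[s]) * 1e-3;
      if (g <= 0) continue;
      int i = E.snode[s];
      if (E.skind[s] == 0) {  // GABA: Cl/HCO3 split, dynamic reversals
        double ecl = E.ecl_at(i), ehc = E.ehco3_at(i);
        double gcl = g / (1.0 + E.sp[s]);
        double ghc = g * E.sp[s] / (1.0 + E.sp[s]);
        gtot[i] += gcl + ghc;
        ge[i] += gcl * ecl + ghc * ehc;
        sgcl[s] = gcl; sghc[s] = ghc; secl[s] = ecl; sehc[s] = ehc;
      } else if (E.skind[s] == 1) {  // AMPA
        gtot[i] += g;
        ge[i] += g * E.se[s];
      } else {  // NMDA with Mg block at step-start voltage
        double blk = 1.0 / (1.0 + E.smg[s] / E.sscale[s] *
                                      std::exp(-E.sslope[s] * V[i]));
        gtot[i] += g * blk;
        ge[i] += g * blk * E.se[s];
      }
    }
    // HH conductances frozen at step start
    if (E.has_hh) {
      for (int i = 0; i < n; ++i) {
        if (E.gna[i] > 0) {
          double gg = E.gna[i] * m[i] * m[i] * m[i] * h[i];
          gtot[i] += gg; ge[i] += gg * E.ena;
        }
        if (E.gk[i] > 0) {
          double gg = E.gk[i] * ng[i] * ng[i] * ng[i] * ng[i];
          gtot[i] += gg; ge[i] += gg * E.ek;
        }
        if (E.gca[i] > 0) {
          double gg = E.gca[i] * sg_[i] * sg_[i];
          gtot[i] += gg; ge[i] += gg * E.eca;
        }
      }
    }
    // 3. Crank-Nicolson cable solve (Hines)
    for (int i = 0; i < n; ++i) {
      diag[i] = E.cmn[i] / dt + theta * gtot[i];
      rhs[i] = E.cmn[i] / dt * V[i] - (1.0 - theta) * gtot[i] * V[i] + ge[i] + inj[i];
      off[i] = 0.0;
    }
    for (int i = 1; i < n; ++i) {
      int p = E.parent[i];
      if (p < 0) continue;
      double g = E.gax[i];
      diag[i] += theta * g;
      diag[p] += theta * g;
      off[i] = -theta * g;
      // explicit part of the axial current
      double iax = g * (V[p] - V[i]);
      rhs[i] += (1.0 - theta) * iax;
      rhs[p] -= (1.0 - theta) * iax;
    }
    for (int i = n - 1; i >= 1; --i) {
      int p = E.parent[i];
      if (p < 0) continue;
      double fac = off[i] / diag[i];
      diag[p] -= fac * off[i];
      rhs[p] -= fac * rhs[i];
    }
    std::vector<double> Vnew(n);
    Vnew[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      int p = E.parent[i];
      Vnew[i] = (p < 0) ? rhs[i] / diag[i] : (rhs[i] - off[i] * Vnew[p]) / diag[i];
    }
    // 4. HH gate update at the new voltage (exact exponential)
    if (E.has_hh) {
      for (int i = 0; i < n; ++i) {
        if (E.gna[i] <= 0 && E.gk[i] <= 0 && E.gca[i] <= 0) continue;
        double r[6];
        rate_set(Vnew[i], r);
        double inf, tau;
        inf = r[0] / (r[0] + r[1]); tau = 1.0 / (r[0] + r[1]);
        m[i] = inf + (m[i] - inf) * std::exp(-dt / tau);
        inf = r[2] / (r[2] + r[3]); tau = 1.0 / (r[2] + r[3]);
        h[i] = inf + (h[i] - inf) * std::exp(-dt / tau);
        inf = r[4] / (r[4] + r[5]); tau = 1.0 / (r[4] + r[5]);
        ng[i] = inf + (ng[i] - inf) * std::exp(-dt / tau);
        double sinf = 1.0 / (1.0 + std::exp(-(Vnew[i] + 20.0) / 9.0));
        sg_[i] = sinf + (sg_[i] - sinf) * std::exp(-dt / 1.0);
      }
    }
    // 5. anion fluxes at the mid-step voltage into the submembrane shell
    for (int s = 0; s < E.ns; ++s) {
      if (sgcl[s] <= 0 && sghc[s] <= 0) continue;
      int i = E.snode[s];
      double vm = 0.5 * (V[i] + Vnew[i]);
      double icl = sgcl[s] * (vm - secl[s]);
      double ihc = sghc[s] * (vm - sehc[s]);
      double volm = E.vol[i * NSH + NSH - 1];
      E.cl[i * NSH + NSH - 1] += icl * dt / (FARADAY * volm) * 1e6;
      E.hco3[i * NSH + NSH - 1] += ihc * dt / (FARADAY * volm) * 1e6;
      icl_probe[i] += icl;
    }
    for (int i = 0; i < n; ++i) {
      if (E.tgcl[i] <= 0 && E.tghco3[i] <= 0) continue;
      double ecl = E.ecl_at(i), ehc = E.ehco3_at(i);
      double vm = 0.5 * (V[i] + Vnew[i]);
      double icl = E.tgcl[i] * (vm - ecl);
      double ihc = E.tghco3[i] * (vm - ehc);
      double volm = E.vol[i * NSH + NSH - 1];
      E.cl[i * NSH + NSH - 1] += icl * dt / (FARADAY * volm) * 1e6;
      E.hco3[i * NSH + NSH - 1] += ihc * dt / (FARADAY * volm) * 1e6;
      icl_probe[i] += icl;
    }
    // 6. radial diffusion (implicit, prefactored Thomas)
    if (E.diffusion_on) {
      for (int i = 0; i < n; ++i) {
        E.radial_apply(E.rad_cl[i], &E.cl[i * NSH], &E.vol[i * NSH]);
        E.radial_apply(E.rad_hco3[i], &E.hco3[i * NSH], &E.vol[i * NSH]);
      }
      // 7. longitudinal diffusion per shell layer (implicit, prefactored)
      if (n > 1) {
        for (int k = 0; k < NSH; ++k) {
          E.longitudinal_apply(E.lon_cl[k], E.cl, k);
          E.longitudinal_apply(E.lon_hco3[k], E.hco3, k);
        }
      }
    }
    // 8. relaxation transport (exact exponential, bimodal chloride rule
    //    selected from the submembrane deviation per node)
    if (E.transport_on) {
      for (int i = 0; i < n; ++i) {
        double fac = (E.cl[i * NSH + NSH - 1] < E.cl_rest) ? fac_in : fac_out;
        for (int k = 0; k < NSH; ++k) {
          E.cl[i * NSH + k] = E.cl_rest + (E.cl[i * NSH + k] - E.cl_rest) * fac;
          E.hco3[i * NSH + k] =
              E.hco3_rest + (E.hco3[i * NSH + k] - E.hco3_rest) * fac_hc;
        }
      }
    }
    // analytic decay of the two-state synaptic kinetics
    for (int s = 0; s < E.ns; ++s) {
      E.A[s] *= E.dec1[s];
      E.B[s] *= E.dec2[s];
    }
    V = Vnew;
    if ((step & 1023) == 0 && !std::isfinite(V[0]))
      stop("numerical divergence at t = %f ms", t);
    if ((step + 1) % stride == 0) record(step + 1);
  }
  if (!std::isfinite(V[0])) stop("numerical divergence at end of run");

  NumericMatrix clf(n, NSH), hcf(n, NSH);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSH; ++k) {
      clf(i, k) = E.cl[i * NSH + k];
      hcf(i, k) = E.hco3[i * NSH + k];
    }
  NumericVector vf(V.begin(), V.end());
  return List::create(
      _["time"] = time, _["v"] = Vrec, _["cl"] = CLrec, _["hco3"] = HCrec,
      _["cl_mean"] = CLmean, _["icl"] = ICLrec, _["total_cl"] = totcl,
      _["total_hco3"] = tothc, _["cl_final"] = clf, _["hco3_final"] = hcf,
      _["v_final"] = vf);
}
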