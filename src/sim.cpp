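// Fixed-step RK4 integrator for the HVC network ODE system, with
// Euler-Maruyama treatment of the stochastic background current and
// on-the-fly spike (peak) detection.
//
// Sign convention: ionic and synaptic currents are written g*(V - E) and
// subtracted in dV/dt; stimulus and noise currents are added.
// Units: mV, ms, nS, pA, pF, Ca in uM.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// ---- parameter column indices (pars matrix, one row per neuron) ----
enum {
  P_C = 0, P_GL, P_EL, P_GNA, P_ENA, P_GK, P_EK, P_GCAL, P_ECA,
  P_GCAT, P_GSK, P_GA, P_GH, P_EH, P_ACA, P_TAUCA, P_CA0, NPAR
};

// ---- kinetics row layout (kin matrix, one row per class) ----
// m: theta,sigma | h: theta,sigma,tau0,tau1,thetat,sigmat | n: 6 |
// s(CaL): 2 | mT: 6 | hT: 6 | a: 2 | e: 6 | r: 6 | z: ks,tau
enum {
  K_M = 0, K_H = 2, K_N = 8, K_S = 14, K_MT = 16, K_HT = 22,
  K_A = 28, K_E = 30, K_R = 36, K_ZKS = 42, K_ZTAU = 43, NKIN
};

// syn_kin layout
enum {
  SK_THETA = 0, SK_SLOPE, SK_AA, SK_BA, SK_AG, SK_BG, SK_EA, SK_EG
};

static inline double xinf(double V, const double* k) {
  return 1.0 / (1.0 + std::exp((V - k[0]) / k[1]));
}
static inline double xtau(double V, const double* k) {
  // k: theta,sigma,tau0,tau1,thetat,sigmat
  return k[2] + k[3] / std::cosh((V - k[4]) / k[5]);
}

// counter-based RNG: one N(0,1) draw per (seed, step, neuron), order-free
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
static inline double noise_normal(uint64_t seed, uint64_t step, uint64_t id) {
  uint64_t h = splitmix64(seed ^ splitmix64(step ^ splitmix64(id + 0x51ED2701ULL)));
  uint64_t h2 = splitmix64(h);
  double u1 = ((h >> 11) + 1.0) * (1.0 / 9007199254740993.0);   // (0,1)
  double u2 = (h2 >> 11) * (1.0 / 9007199254740992.0);          // [0,1)
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

struct Net {
  int n;                        // neurons
  int ns;                       // synapses
  const int* cls;               // 0 RA, 1 X, 2 INT
  const double* pars;           // column-major n x NPAR
  const double* kin;            // column-major 3 x NKIN
  const int* spre; const int* spost; const int* skind;
  const double* sg;
  const double* skin;
  std::vector<int> off;         // state offset per neuron
  std::vector<int> dim;         // state dim per neuron
  int nstate;                   // total incl synapse gates
  int syn0;                     // offset of first synapse gate

  double par(int i, int p) const { return pars[p * n + i]; }
};

// state layout per class:
// RA (6):  V h n e z Ca
// X  (8):  V h n mT hT z r Ca
// INT(7):  V h n mT hT r Ca
static const int CLASS_DIM[3] = {6, 8, 7};

// deterministic RHS; Iext = stim (added); synaptic current computed from gates
static void rhs(const Net& net, const double* y, double* dy,
                const double* Iext) {
  const int n = net.n;
  // accumulate synaptic currents onto each neuron
  std::vector<double> Isyn(n, 0.0);
  for (int s = 0; s < net.ns; ++s) {
    int post = net.spost[s];
    double Vpost = y[net.off[post]];
    double E = net.skind[s] == 0 ? net.skin[SK_EA] : net.skin[SK_EG];
    Isyn[post] += net.sg[s] * y[net.syn0 + s] * (Vpost - E);
  }
  for (int i = 0; i < n; ++i) {
    const int c = net.cls[i];
    const int o = net.off[i];
    const double V = y[o];
    const double h = y[o + 1];
    const double nK = y[o + 2];
    double kbuf[6];
    // Na (instantaneous m^3 h)
    for (int j = 0; j < 2; ++j) kbuf[j] = net.kin[(K_M + j) * 3 + c];
    double minf = xinf(V, kbuf);
    double INa = net.par(i, P_GNA) * minf * minf * minf * h * (V - net.par(i, P_ENA));
    // K (n^4)
    double IK = net.par(i, P_GK) * nK * nK * nK * nK * (V - net.par(i, P_EK));
    // leak
    double IL = net.par(i, P_GL) * (V - net.par(i, P_EL));
    // CaL (instantaneous s^2)
    for (int j = 0; j < 2; ++j) kbuf[j] = net.kin[(K_S + j) * 3 + c];
    double sinf = xinf(V, kbuf);
    double ICaL = net.par(i, P_GCAL) * sinf * sinf * (V - net.par(i, P_ECA));

    double ICaT = 0.0, IA = 0.0, ISK = 0.0, IH = 0.0, Ca = 0.0;
    int ze = -1;  // index of z gate (SK), e gate (A) handled per class
    if (c == 0) {            // RA: V h n e z Ca
      double e = y[o + 3], z = y[o + 4];
      Ca = y[o + 5];
      for (int j = 0; j < 2; ++j) kbuf[j] = net.kin[(K_A + j) * 3 + c];
      double ainf = xinf(V, kbuf);
      IA = net.par(i, P_GA) * ainf * e * (V - net.par(i, P_EK));
      // RA SK gate enters at the 4th power: a sharp, calcium-clocked
      // burst terminator (X uses first-order SK activation)
      double z4 = z * z * z * z;
      ISK = net.par(i, P_GSK) * z4 * (V - net.par(i, P_EK));
      // gate ODEs
      for (int j = 0; j < 6; ++j) kbuf[j] = net.kin[(K_E + j) * 3 + c];
      dy[o + 3] = (xinf(V, kbuf) - e) / xtau(V, kbuf);
      double ks = net.kin[K_ZKS * 3 + c], tz = net.kin[K_ZTAU * 3 + c];
      double zinf = Ca * Ca / (Ca * Ca + ks * ks);
      dy[o + 4] = (zinf - z) / tz;
      ze = o + 5;
    } else {                 // X / INT share V h n mT hT ... r Ca
      double mT = y[o + 3], hT = y[o + 4];
      ICaT = net.par(i, P_GCAT) * mT * mT * hT * (V - net.par(i, P_ECA));
      for (int j = 0; j < 6; ++j) kbuf[j] = net.kin[(K_MT + j) * 3 + c];
      dy[o + 3] = (xinf(V, kbuf) - mT) / xtau(V, kbuf);
      for (int j = 0; j < 6; ++j) kbuf[j] = net.kin[(K_HT + j) * 3 + c];
      dy[o + 4] = (xinf(V, kbuf) - hT) / xtau(V, kbuf);
      int ro;
      if (c == 1) {          // X: ... z r Ca
        double z = y[o + 5];
        ISK = net.par(i, P_GSK) * z * (V - net.par(i, P_EK));
        double ks = net.kin[K_ZKS * 3 + c], tz = net.kin[K_ZTAU * 3 + c];
        Ca = y[o + 7];
        double zinf = Ca * Ca / (Ca * Ca + ks * ks);
        dy[o + 5] = (zinf - z) / tz;
        ro = o + 6; ze = o + 7;
      } else {               // INT: ... r Ca
        Ca = y[o + 6];
        ro = o + 5; ze = o + 6;
      }
      double r = y[ro];
      IH = net.par(i, P_GH) * r * (V - net.par(i, P_EH));
      for (int j = 0; j < 6; ++j) kbuf[j] = net.kin[(K_R + j) * 3 + c];
      dy[ro] = (xinf(V, kbuf) - r) / xtau(V, kbuf);
    }
    // Na h and K n gate ODEs
    for (int j = 0; j < 6; ++j) kbuf[j] = net.kin[(K_H + j) * 3 + c];
    dy[o + 1] = (xinf(V, kbuf) - h) / xtau(V, kbuf);
    for (int j = 0; j < 6; ++j) kbuf[j] = net.kin[(K_N + j) * 3 + c];
    dy[o + 2] = (xinf(V, kbuf) - nK) / xtau(V, kbuf);
    // Ca balance (influx from Ca currents, first-order removal)
    dy[ze] = -net.par(i, P_ACA) * (ICaL + ICaT)
             - (Ca - net.par(i, P_CA0)) / net.par(i, P_TAUCA);
    dy[o] = (-(IL + IK + INa + ICaL + ICaT + IA + ISK + IH)
             - Isyn[i] + Iext[i]) / net.par(i, P_C);
  }
  // synapse gates: two-state transmitter-driven kinetics
  for (int s = 0; s < net.ns; ++s) {
    double Vpre = y[net.off[net.spre[s]]];
    double T = 1.0 / (1.0 + std::exp(-(Vpre - net.skin[SK_THETA]) / net.skin[SK_SLOPE]));
    double a = net.skind[s] == 0 ? net.skin[SK_AA] : net.skin[SK_AG];
    double b = net.skind[s] == 0 ? net.skin[SK_BA] : net.skin[SK_BG];
    double sv = y[net.syn0 + s];
    dy[net.syn0 + s] = a * T * (1.0 - sv) - b * sv;
  }
}

// [[Rcpp::export]]
List sim_network_cpp(IntegerVector cls, NumericMatrix pars, NumericMatrix kin,
                     IntegerVector syn_pre, IntegerVector syn_post,
                     IntegerVector syn_kind, NumericVector syn_g,
                     NumericVector syn_kin, NumericMatrix stim,
                     double dt, double duration, int record_stride,
                     double sigma_noise, double noise_seed,
                     NumericVector init, double spike_thresh,
                     double spike_refrac, bool record_traces) {
  Net net;
  net.n = cls.size();
  net.ns = syn_pre.size();
  net.cls = INTEGER(cls);
  net.pars = REAL(pars);
  net.kin = REAL(kin);
  net.spre = INTEGER(syn_pre);
  net.spost = INTEGER(syn_post);
  net.skind = INTEGER(syn_kind);
  net.sg = REAL(syn_g);
  net.skin = REAL(syn_kin);
  if (pars.nrow() != net.n || pars.ncol() != NPAR)
    stop("parameter matrix has wrong shape");
  if (kin.nrow() != 3 || kin.ncol() != NKIN)
    stop("kinetics matrix has wrong shape");

  net.off.resize(net.n);
  net.dim.resize(net.n);
  int acc = 0;
  for (int i = 0; i < net.n; ++i) {
    net.off[i] = acc;
    net.dim[i] = CLASS_DIM[net.cls[i]];
    acc += net.dim[i];
  }
  net.syn0 = acc;
  net.nstate = acc + net.ns;

  std::vector<double> y(net.nstate, 0.0);
  if (init.size() == net.nstate) {
    for (int i = 0; i < net.nstate; ++i) y[i] = init[i];
  } else if (init.size() == 0) {
    stop("initial state required (length %d)", net.nstate);
  } else {
    stop("initial state has length %d, expected %d", (int)init.size(), net.nstate);
  }

  const long nsteps = (long)std::llround(duration / dt);
  const uint64_t seed = (uint64_t)std::llround(noise_seed);
  const long nrec = record_traces ? (nsteps / record_stride + 1) : 0;
  NumericMatrix V(record_traces ? nrec : 0, record_traces ? net.n : 0);
  NumericVector tgrid(record_traces ? nrec : 0);

  std::vector<std::vector<double>> spikes(net.n);
  std::vector<int> above(net.n, 0);
  std::vector<double> peakV(net.n, -1e9), peakT(net.n, 0.0), lastSpk(net.n, -1e9);
  for (int i = 0; i < net.n; ++i) above[i] = y[net.off[i]] >= spike_thresh;

  std::vector<double> Iext(net.n, 0.0);
  std::vector<double> k1(net.nstate), k2(net.nstate), k3(net.nstate),
      k4(net.nstate), yt(net.nstate);
  const int nstim = stim.nrow();

  long irec = 0;
  if (record_traces) {
    tgrid[0] = 0.0;
    for (int i = 0; i < net.n; ++i) V(0, i) = y[net.off[i]];
    irec = 1;
  }

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    // external stimulus (held constant over the step)
    std::fill(Iext.begin(), Iext.end(), 0.0);
    for (int s = 0; s < nstim; ++s) {
      if (t >= stim(s, 1) && t < stim(s, 2)) Iext[(int)stim(s, 0)] += stim(s, 3);
    }
    // RK4 deterministic step
    rhs(net, y.data(), k1.data(), Iext.data());
    for (int i = 0; i < net.nstate; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    rhs(net, yt.data(), k2.data(), Iext.data());
    for (int i = 0; i < net.nstate; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    rhs(net, yt.data(), k3.data(), Iext.data());
    for (int i = 0; i < net.nstate; ++i) yt[i] = y[i] + dt * k3[i];
    rhs(net, yt.data(), k4.data(), Iext.data());
    for (int i = 0; i < net.nstate; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    // Euler-Maruyama noise increment on V
    if (sigma_noise > 0.0) {
      double sq = std::sqrt(dt);
      for (int i = 0; i < net.n; ++i) {
        double xi = noise_normal(seed, (uint64_t)step, (uint64_t)i);
        y[net.off[i]] += sigma_noise * xi * sq / net.par(i, P_C);
      }
    }
    double tn = (step + 1) * dt;
    // spike peak tracking
    for (int i = 0; i < net.n; ++i) {
      double Vi = y[net.off[i]];
      if (!R_finite(Vi))
        stop("non-finite membrane potential in neuron %d at t = %.3f ms", i + 1, tn);
      if (!above[i] && Vi >= spike_thresh) {
        above[i] = 1; peakV[i] = Vi; peakT[i] = tn;
      } else if (above[i]) {
        if (Vi > peakV[i]) { peakV[i] = Vi; peakT[i] = tn; }
        if (Vi < spike_thresh) {
          above[i] = 0;
          if (peakT[i] - lastSpk[i] >= spike_refrac) {
            spikes[i].push_back(peakT[i]);
            lastSpk[i] = peakT[i];
          }
        }
      }
    }
    if (record_traces && ((step + 1) % record_stride == 0) && irec < nrec) {
      tgrid[irec] = tn;
      for (int i = 0; i < net.n; ++i) V(irec, i) = y[net.off[i]];
      ++irec;
    }
  }

  List spk(net.n);
  for (int i = 0; i < net.n; ++i) spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  NumericVector fin(y.begin(), y.end());
  return List::create(_["time"] = tgrid, _["V"] = V, _["spikes"] = spk,
                      _["state"] = fin);
}

// [[Rcpp::export]]
NumericVector network_rhs_cpp(IntegerVector cls, NumericMatrix pars,
                              NumericMatrix kin, IntegerVector syn_pre,
                              IntegerVector syn_post, IntegerVector syn_kind,
                              NumericVector syn_g, NumericVector syn_kin,
                              NumericVector y, NumericVector Iext) {
  Net net;
  net.n = cls.size();
  net.ns = syn_pre.size();
  net.cls = INTEGER(cls);
  net.pars = REAL(pars);
  net.kin = REAL(kin);
  net.spre = INTEGER(syn_pre);
  net.spost = INTEGER(syn_post);
  net.skind = INTEGER(syn_kind);
  net.sg = REAL(syn_g);
  net.skin = REAL(syn_kin);
  net.off.resize(net.n);
  net.dim.resize(net.n);
  int acc = 0;
  for (int i = 0; i < net.n; ++i) {
    net.off[i] = acc;
    net.dim[i] = CLASS_DIM[net.cls[i]];
    acc += net.dim[i];
  }
  net.syn0 = acc;
  net.nstate = acc + net.ns;
  if (y.size() != net.nstate) stop("state vector has wrong length");
  NumericVector dy(net.nstate);
  std::vector<double> ie(net.n, 0.0);
  for (int i = 0; i < net.n && i < Iext.size(); ++i) ie[i] = Iext[i];
  rhs(net, REAL(y), REAL(dy), ie.data());
  return dy;
}
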