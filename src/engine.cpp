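// Clock-driven simulation engine for the AB / ABC / ABD SSA networks.
//
// All state (Poisson inputs, three-state synapses, OU background
// conductances, AdEx membranes) advances on one global step dt. Pathways
// are processed before the AdEx updates of a step, using the presynaptic
// spikes of the previous step for AdEx presynaptic populations (an
// effective one-step latency) and the current step's draws for the Poisson
// population A. RNG draws come from R's generator in a fixed order, so a
// run is a pure function of (network, sequence, seed).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ with Box-Muller normals; seeded from R's RNG at engine
// entry so every run remains a pure function of the R-level seed while
// avoiding the per-draw overhead of the R RNG API in the inner loop.
struct FastRNG {
  uint64_t s[4];
  double spare;
  bool hasSpare;

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit FastRNG(uint64_t seed) : spare(0), hasSpare(false) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double uniform() { // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    if (hasSpare) { hasSpare = false; return spare; }
    double u = uniform(), v = uniform();
    double r = std::sqrt(-2.0 * std::log(u)), a = 6.283185307179586 * v;
    spare = r * std::sin(a);
    hasSpare = true;
    return r * std::cos(a);
  }
};

struct Pathway {
  std::vector<int> pre, post;          // 0-based
  std::vector<double> w, pulse, rev;
  std::vector<double> kr, kd, kc;      // per-step outflow fractions
  bool depressing;
  int prePop, postPop;                 // 0 = A, 1 = B, 2 = C, 3 = D
  // state
  std::vector<double> R, E, I, timer;
};

struct AdExPop {
  std::vector<double> v, wad, ge, gi, cur;
  std::vector<int> spikePrev, spikeNow;
  std::vector<int> recUnit;
  std::vector<double> recTime;
};

inline int popCode(const std::string &s) {
  if (s == "A") return 0;
  if (s == "B") return 1;
  if (s == "C") return 2;
  return 3;
}

} // namespace

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(List net, NumericMatrix tones, List tuning, double dt,
                double tEnd, Nullable<IntegerMatrix> aSpikes, bool recordA) {
  const int nB = as<int>(net["nB"]);
  const int nSub = as<int>(net["nSub"]);
  const int nA = nB * nSub;
  const std::string arch = as<std::string>(net["arch"]);
  const bool hasC = arch == "ABC";
  const bool hasD = arch == "ABD";

  List adex = net["adex"];
  const double C = adex["capacitance"], gL = adex["leakConductance"],
               EL = adex["leakReversal"], dT = adex["slopeFactor"],
               VT = adex["threshold"], tauw = adex["tauAdaptation"],
               aw = adex["adaptationCoupling"], bw = adex["adaptationIncrement"],
               Vr = adex["reset"], Vcut = adex["cutoff"];

  List noise = net["noise"];
  const double ge0 = noise["ge0"], gi0 = noise["gi0"], sige = noise["sige"],
               sigi = noise["sigi"], taue = noise["taue"], taui = noise["taui"],
               Ee = noise["Ee"], Ei = noise["Ei"], nscale = noise["scale"];
  const double ae = std::exp(-dt / taue), ai = std::exp(-dt / taui);
  const double se = sige * std::sqrt(1.0 - ae * ae);
  const double si = sigi * std::sqrt(1.0 - ai * ai);

  // tuning
  NumericVector bestFreq = tuning["bestFreq"];
  const double r0 = tuning["spontaneousRate"], rmax = tuning["maxRate"],
               tsig = tuning["sigma"];

  // pathways
  List pws = net["pathways"];
  CharacterVector pwNames = pws.names();
  std::vector<Pathway> paths(pws.size());
  for (int p = 0; p < pws.size(); ++p) {
    List pw = pws[p];
    IntegerVector pre = pw["pre"], post = pw["post"];
    NumericVector w = pw["weight"], tr = pw["tau_rise"], td = pw["tau_decay"],
                  trec = pw["tau_rec"], pu = pw["pulse"], rv = pw["reversal"];
    Pathway &P = paths[p];
    int n = pre.size();
    P.pre.resize(n); P.post.resize(n);
    P.w.resize(n); P.pulse.resize(n); P.rev.resize(n);
    P.kr.resize(n); P.kd.resize(n); P.kc.resize(n);
    for (int i = 0; i < n; ++i) {
      P.pre[i] = pre[i] - 1; P.post[i] = post[i] - 1;
      P.w[i] = w[i]; P.pulse[i] = pu[i]; P.rev[i] = rv[i];
      // pool transfer rates (1/ms) for the Heun step
      P.kr[i] = 1.0 / tr[i];
      P.kd[i] = 1.0 / td[i];
      P.kc[i] = 1.0 / trec[i];
    }
    P.depressing = as<bool>(pw["depressing"]);
    P.prePop = popCode(as<std::string>(pw["prePop"]));
    P.postPop = popCode(as<std::string>(pw["postPop"]));
    P.R.assign(n, 1.0); P.E.assign(n, 0.0); P.I.assign(n, 0.0);
    P.timer.assign(n, 0.0);
  }

  // AdEx populations: index 1 = B, 2 = C, 3 = D
  AdExPop pops[4];
  for (int c = 1; c <= 3; ++c) {
    if (c == 2 && !hasC) continue;
    if (c == 3 && !hasD) continue;
    AdExPop &P = pops[c];
    P.v.assign(nB, EL); P.wad.assign(nB, 0.0);
    P.ge.assign(nB, ge0); P.gi.assign(nB, gi0);
    P.cur.assign(nB, 0.0);
    P.spikePrev.assign(nB, 0); P.spikeNow.assign(nB, 0);
  }

  // tone schedule
  const int nTones = tones.nrow();
  std::vector<double> onset(nTones), toff(nTones), tfreq(nTones);
  for (int j = 0; j < nTones; ++j) {
    onset[j] = tones(j, 0);
    toff[j] = tones(j, 0) + tones(j, 1);
    tfreq[j] = tones(j, 2);
  }

  std::vector<double> pSpike(nSub);
  const double pSpont = 1.0 - std::exp(-r0 * dt / 1000.0);
  int curTone = -1, lastSeg = -1000000;

  IntegerMatrix aFixed;
  const bool useFixedA = aSpikes.isNotNull();
  if (useFixedA) aFixed = IntegerMatrix(aSpikes);

  std::vector<int> spikeA(nA, 0);
  std::vector<int> aRecUnit;
  std::vector<double> aRecTime;

  const long nSteps = (long)std::lround(tEnd / dt);
  uint64_t seed64;
  {
    RNGScope rngScope;
    seed64 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
             (uint64_t)(unif_rand() * 4294967296.0);
  }
  FastRNG rng(seed64);

  for (long k = 0; k < nSteps; ++k) {
    const double t = k * dt;
    const double tNext = (k + 1) * dt;

    // segment / rate lookup
    while (curTone + 1 < nTones && t >= onset[curTone + 1]) ++curTone;
    const bool active = curTone >= 0 && t < toff[curTone];
    const int seg = active ? curTone : -(curTone + 2);
    if (seg != lastSeg) {
      if (active) {
        for (int s2 = 0; s2 < nSub; ++s2) {
          double d = tfreq[curTone] - bestFreq[s2];
          double r = r0 + (rmax - r0) * std::exp(-d * d / (2 * tsig * tsig));
          pSpike[s2] = 1.0 - std::exp(-r * dt / 1000.0);
        }
      } else {
        std::fill(pSpike.begin(), pSpike.end(), pSpont);
      }
      lastSeg = seg;
    }

    // population A draws
    if (useFixedA) {
      for (int u = 0; u < nA; ++u) spikeA[u] = aFixed(k, u);
    } else {
      for (int u = 0; u < nA; ++u)
        spikeA[u] = rng.uniform() < pSpike[u / nB] ? 1 : 0;
    }
    if (recordA) {
      for (int u = 0; u < nA; ++u)
        if (spikeA[u]) { aRecUnit.push_back(u + 1); aRecTime.push_back(tNext); }
    }

    // clear current accumulators
    for (int c = 1; c <= 3; ++c)
      if (!pops[c].v.empty()) std::fill(pops[c].cur.begin(), pops[c].cur.end(), 0.0);

    // synapses
    for (size_t p = 0; p < paths.size(); ++p) {
      Pathway &P = paths[p];
      const int *preSpk = P.prePop == 0 ? spikeA.data()
                                        : pops[P.prePop].spikePrev.data();
      std::vector<double> &postV = pops[P.postPop].v;
      std::vector<double> &postI = pops[P.postPop].cur;
      const size_t n = P.pre.size();
      for (size_t i = 0; i < n; ++i) {
        if (preSpk[P.pre[i]]) P.timer[i] = P.pulse[i];
        // fully rested and unstimulated synapses carry no current and do
        // not change state; skipping them is exact up to resource mass
        // below 1e-14
        if (P.timer[i] <= 0 && P.E[i] < 1e-14 && P.I[i] < 1e-14) continue;
        // Heun (second-order) step of the three-pool flow; stage fluxes
        // are antisymmetric so mass is conserved exactly
        {
          const double a = P.timer[i] > 0 ? P.kr[i] : 0.0;
          const double b = P.kd[i];
          const double c = P.depressing ? P.kc[i] : 0.0;
          double R0 = P.R[i], E0 = P.E[i], I0 = P.I[i];
          double r1 = c * I0 - a * R0;
          double e1 = a * R0 - b * E0;
          double i1 = b * E0 - c * I0;
          double Rm = R0 + dt * r1, Em = E0 + dt * e1, Im = I0 + dt * i1;
          double r2 = c * Im - a * Rm;
          double e2 = a * Rm - b * Em;
          double i2 = b * Em - c * Im;
          P.R[i] = R0 + dt * 0.5 * (r1 + r2);
          P.E[i] = E0 + dt * 0.5 * (e1 + e2);
          P.I[i] = I0 + dt * 0.5 * (i1 + i2);
          if (!P.depressing) { P.R[i] += P.I[i]; P.I[i] = 0.0; }
        }
        if (P.timer[i] > 0) {
          P.timer[i] -= dt;
          if (P.timer[i] < 1e-9) P.timer[i] = 0;  // fp-residue guard
        }
        postI[P.post[i]] += P.w[i] * P.E[i] * (P.rev[i] - postV[P.post[i]]);
      }
    }

    // OU noise + AdEx update, populations in fixed order B, C, D
    for (int c = 1; c <= 3; ++c) {
      AdExPop &P = pops[c];
      if (P.v.empty()) continue;
      for (int u = 0; u < nB; ++u) {
        P.ge[u] = ge0 + (P.ge[u] - ge0) * ae + se * rng.normal();
        P.gi[u] = gi0 + (P.gi[u] - gi0) * ai + si * rng.normal();
        double Iin = P.cur[u] +
          nscale * (P.ge[u] * (Ee - P.v[u]) + P.gi[u] * (Ei - P.v[u]));
        double varg = (P.v[u] - VT) / dT;
        if (varg > 30) varg = 30;
        double dv = (-gL * (P.v[u] - EL) + gL * dT * std::exp(varg) -
                     P.wad[u] + Iin) / C;
        double dw = (aw * (P.v[u] - EL) - P.wad[u]) / tauw;
        double v2 = P.v[u] + dt * dv;
        double w2 = P.wad[u] + dt * dw;
        if (!std::isfinite(v2) || !std::isfinite(w2))
          stop("AdEx state became non-finite at t = %.1f ms (population %d, unit %d): dt too large",
               t, c, u + 1);
        int spk = v2 >= Vcut ? 1 : 0;
        if (spk) {
          v2 = Vr;
          w2 += bw;
          P.recUnit.push_back(u + 1);
          P.recTime.push_back(tNext);
        }
        P.v[u] = v2; P.wad[u] = w2; P.spikeNow[u] = spk;
      }
      std::swap(P.spikePrev, P.spikeNow);
    }
  }

  const char *popNames[4] = {"A", "B", "C", "D"};
  List out;
  if (recordA)
    out.push_back(List::create(_["unit"] = wrap(aRecUnit),
                               _["time"] = wrap(aRecTime)), "A");
  for (int c = 1; c <= 3; ++c) {
    if (pops[c].v.empty()) continue;
    out.push_back(List::create(_["unit"] = wrap(pops[c].recUnit),
                               _["time"] = wrap(pops[c].recTime)),
                  popNames[c]);
  }
  return out;
}
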