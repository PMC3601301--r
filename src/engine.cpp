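// Millisecond-resolution simulation engine for conductance-based Izhikevich
// networks with short-term plasticity, STDP (eligibility trace) and
// homeostatic synaptic scaling.
//
// The engine is fully deterministic: all randomness (initial recovery
// variables, wiring, stimulus patterns) is drawn on the R side.  Spikes
// generated in tick t modify conductances from tick t+1 onwards; no synaptic
// delays are modelled.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double E_AMPA = 0.0;
static const double E_NMDA = 0.0;
static const double E_GABAA = -70.0;
static const double E_GABAB = -90.0;
static const double E_SH = -90.0;

static const double TAU_AMPA = 5.0;
static const double TAU_NMDA = 150.0;
static const double TAU_GABAA = 6.0;
static const double TAU_GABAB = 150.0;
static const double TAU_SH = 5000.0;

struct Population {
  int n;
  double C, k, vr, vt, a, b, creset, d, vpeak;
  std::vector<double> v, u;
  std::vector<double> gA, gN, gGA, gGB, gSH;
  std::vector<double> last_spike;   // ms; -1e18 = never
  std::vector<int> fired;           // neuron indices fired this tick
};

struct Projection {
  int src, dst;                 // population indices
  int nsyn;
  // pre-major CSR
  std::vector<int> pre_ptr;     // length n_pre + 1
  std::vector<int> syn_post;    // target neuron per synapse
  std::vector<double> w;        // weight (nS) per synapse
  std::vector<int> syn_pre;     // source neuron per synapse
  // post-major index into the synapse arrays
  std::vector<int> post_ptr;    // length n_post + 1
  std::vector<int> post_syn;
  bool inhibitory;
  double nmda_gain, gabab_gain, gabash_gain;
  double tau_x, pfac;
  std::vector<double> x;        // short-term plasticity factor per pre neuron
  bool plastic;
  double alpha;
  std::vector<double> ctr;      // eligibility trace per synapse (plastic only)
  std::vector<double> s_total;  // per post neuron; <0 disables scaling
  double s_max;
  double gain_mult;             // runtime multiplier on delivered conductance
};

struct Engine {
  std::vector<Population> pops;
  std::vector<Projection> projs;
  double dt;
  long tick;
  int plast_every;              // ticks between weight update + scaling
  double A_plus, A_minus, tau_plus, tau_minus, tau_c;
  // recording
  bool recording;
  std::vector<double> rec_t;
  std::vector<int> rec_pop, rec_neuron;
};

static void scale_posts(Projection &pr, int n_post) {
  // clip -> multiplicative rescale toward s_total -> re-clip, per post neuron
  for (int i = 0; i < n_post; ++i) {
    double st = pr.s_total[i];
    if (st < 0) continue;
    double sum = 0.0;
    for (int s = pr.post_ptr[i]; s < pr.post_ptr[i + 1]; ++s) {
      int id = pr.post_syn[s];
      double wv = pr.w[id];
      if (wv < 0) wv = 0;
      if (wv > pr.s_max) wv = pr.s_max;
      pr.w[id] = wv;
      sum += wv;
    }
    if (sum <= 0) continue;    // no active synapses: leave untouched
    double f = st / sum;
    for (int s = pr.post_ptr[i]; s < pr.post_ptr[i + 1]; ++s) {
      int id = pr.post_syn[s];
      double wv = pr.w[id] * f;
      if (wv > pr.s_max) wv = pr.s_max;
      pr.w[id] = wv;
    }
  }
}

// [[Rcpp::export(name = ".engine_create")]]
SEXP engine_create(List pops, List projs, double dt, List stdp, int plast_every) {
  Engine *e = new Engine();
  e->dt = dt;
  e->tick = 0;
  e->plast_every = plast_every;
  e->A_plus = as<double>(stdp["a_plus"]);
  e->A_minus = as<double>(stdp["a_minus"]);
  e->tau_plus = as<double>(stdp["tau_plus"]);
  e->tau_minus = as<double>(stdp["tau_minus"]);
  e->tau_c = as<double>(stdp["tau_c"]);
  e->recording = false;

  for (int p = 0; p < pops.size(); ++p) {
    List pl = pops[p];
    NumericVector par = pl["params"];   // C,k,vr,vt,a,b,c,d,vpeak
    Population pop;
    pop.n = as<int>(pl["n"]);
    pop.C = par[0]; pop.k = par[1]; pop.vr = par[2]; pop.vt = par[3];
    pop.a = par[4]; pop.b = par[5]; pop.creset = par[6]; pop.d = par[7];
    pop.vpeak = par[8];
    NumericVector v0 = pl["v"], u0 = pl["u"];
    pop.v.assign(v0.begin(), v0.end());
    pop.u.assign(u0.begin(), u0.end());
    pop.gA.assign(pop.n, 0.0); pop.gN.assign(pop.n, 0.0);
    pop.gGA.assign(pop.n, 0.0); pop.gGB.assign(pop.n, 0.0);
    pop.gSH.assign(pop.n, 0.0);
    pop.last_spike.assign(pop.n, -1e18);
    e->pops.push_back(pop);
  }

  for (int q = 0; q < projs.size(); ++q) {
    List pl = projs[q];
    Projection pr;
    pr.src = as<int>(pl["src"]) - 1;
    pr.dst = as<int>(pl["dst"]) - 1;
    IntegerVector pre = pl["pre"], post = pl["post"];
    NumericVector w = pl["weight"];
    pr.nsyn = pre.size();
    int n_pre = e->pops[pr.src].n, n_post = e->pops[pr.dst].n;
    // sort synapses by pre (counting sort) to build pre-major CSR
    std::vector<int> cnt(n_pre + 1, 0);
    for (int s = 0; s < pr.nsyn; ++s) cnt[pre[s]]++;   // pre is 1-based
    pr.pre_ptr.assign(n_pre + 1, 0);
    for (int i = 0; i < n_pre; ++i) pr.pre_ptr[i + 1] = pr.pre_ptr[i] + cnt[i + 1];
    std::vector<int> cursor(pr.pre_ptr.begin(), pr.pre_ptr.end() - 1);
    pr.syn_post.assign(pr.nsyn, 0);
    pr.syn_pre.assign(pr.nsyn, 0);
    pr.w.assign(pr.nsyn, 0.0);
    for (int s = 0; s < pr.nsyn; ++s) {
      int j = pre[s] - 1;
      int id = cursor[j]++;
      pr.syn_pre[id] = j;
      pr.syn_post[id] = post[s] - 1;
      pr.w[id] = w[s];
    }
    // post-major index
    std::vector<int> pcnt(n_post + 1, 0);
    for (int s = 0; s < pr.nsyn; ++s) pcnt[pr.syn_post[s] + 1]++;
    pr.post_ptr.assign(n_post + 1, 0);
    for (int i = 0; i < n_post; ++i) pr.post_ptr[i + 1] = pr.post_ptr[i] + pcnt[i + 1];
    std::vector<int> pcur(pr.post_ptr.begin(), pr.post_ptr.end() - 1);
    pr.post_syn.assign(pr.nsyn, 0);
    for (int s = 0; s < pr.nsyn; ++s) pr.post_syn[pcur[pr.syn_post[s]]++] = s;

    pr.inhibitory = as<bool>(pl["inhibitory"]);
    pr.nmda_gain = as<double>(pl["nmda_gain"]);
    pr.gabab_gain = as<double>(pl["gabab_gain"]);
    pr.gabash_gain = as<double>(pl["gabash_gain"]);
    pr.tau_x = as<double>(pl["tau_x"]);
    pr.pfac = as<double>(pl["p"]);
    pr.x.assign(n_pre, 1.0);
    pr.plastic = as<bool>(pl["plastic"]);
    pr.alpha = as<double>(pl["alpha"]);
    if (pr.plastic) pr.ctr.assign(pr.nsyn, 0.0);
    NumericVector st = pl["s_total"];
    if (st.size() == 1) pr.s_total.assign(n_post, st[0]);
    else pr.s_total.assign(st.begin(), st.end());
    pr.s_max = as<double>(pl["s_max"]);
    pr.gain_mult = 1.0;
    e->projs.push_back(pr);
  }
  XPtr<Engine> ptr(e, true);
  return ptr;
}

static void run_ticks(Engine *e, long n_ticks,
                      const std::vector<const double*> &ext) {
  double dt = e->dt;
  int npop = e->pops.size();
  double dA = std::exp(-dt / TAU_AMPA), dN = std::exp(-dt / TAU_NMDA);
  double dGA = std::exp(-dt / TAU_GABAA), dGB = std::exp(-dt / TAU_GABAB);
  double dSH = std::exp(-dt / TAU_SH);
  std::vector<double> xdecay(e->projs.size());
  for (size_t q = 0; q < e->projs.size(); ++q)
    xdecay[q] = std::exp(-dt / e->projs[q].tau_x);
  double cdecay = std::exp(-(e->plast_every * dt) / e->tau_c);
  double dt_s = e->plast_every * dt / 1000.0;   // weight-update interval in s

  for (long t = 0; t < n_ticks; ++t) {
    double tnow = e->tick * dt;

    // conductance decay, membrane/recovery integration, spike detection
    for (int p = 0; p < npop; ++p) {
      Population &pop = e->pops[p];
      pop.fired.clear();
      const double *ix = ext[p];
      for (int i = 0; i < pop.n; ++i) {
        pop.gA[i] *= dA; pop.gN[i] *= dN; pop.gGA[i] *= dGA;
        pop.gGB[i] *= dGB; pop.gSH[i] *= dSH;
        double v = pop.v[i], u = pop.u[i];
        double iext = ix ? ix[i] : 0.0;
        // Two half-steps.  The conductance current is linear in v and can be
        // arbitrarily stiff (C/g below the step at strong coupling), so it is
        // treated semi-implicitly; the quadratic intrinsic term stays
        // explicit.  Both solve the same ODE: Cv' = k(v-vr)(v-vt) - u - Isyn
        // + Iext with Isyn = sum_r g_r (v - E_r), NMDA carrying the
        // magnesium-block factor evaluated at the current v.
        for (int h = 0; h < 2; ++h) {
          double mg = (v + 80.0) / 60.0; mg = mg * mg; mg = mg / (1.0 + mg);
          double gsum = pop.gA[i] + pop.gN[i] * mg + pop.gGA[i]
            + pop.gGB[i] + pop.gSH[i];
          double gE = pop.gA[i] * E_AMPA + pop.gN[i] * mg * E_NMDA
            + pop.gGA[i] * E_GABAA + pop.gGB[i] * E_GABAB + pop.gSH[i] * E_SH;
          double hh = 0.5 * dt / pop.C;
          v = (v + hh * (pop.k * (v - pop.vr) * (v - pop.vt) - u + iext + gE))
            / (1.0 + hh * gsum);
          if (v > pop.vpeak) break;   // spike: stop integrating this tick
        }
        u += dt * pop.a * (pop.b * ((v > pop.vpeak ? pop.vpeak : v) - pop.vr) - u);
        if (!std::isfinite(v) || !std::isfinite(u))
          stop("non-finite neuron state at t=%f ms (population %d, neuron %d)",
               tnow, p + 1, i + 1);
        if (v > pop.vpeak) {
          pop.fired.push_back(i);
          v = pop.creset;
          u += pop.d;
          if (e->recording) {
            e->rec_t.push_back(tnow);
            e->rec_pop.push_back(p + 1);
            e->rec_neuron.push_back(i + 1);
          }
        }
        pop.v[i] = v;
        pop.u[i] = u;
      }
    }

    // short-term plasticity relaxation, spike delivery, STP reset, STDP
    for (size_t q = 0; q < e->projs.size(); ++q) {
      Projection &pr = e->projs[q];
      Population &src = e->pops[pr.src];
      Population &dst = e->pops[pr.dst];
      double xd = xdecay[q];
      for (int j = 0; j < src.n; ++j)
        pr.x[j] = 1.0 - (1.0 - pr.x[j]) * xd;
      // deliver spikes using x prior to its spike-triggered reset
      for (size_t f = 0; f < src.fired.size(); ++f) {
        int j = src.fired[f];
        double xj = pr.x[j] * pr.gain_mult;
        if (pr.inhibitory) {
          for (int s = pr.pre_ptr[j]; s < pr.pre_ptr[j + 1]; ++s) {
            int i = pr.syn_post[s];
            double g = xj * pr.w[s];
            dst.gGA[i] += g;
            dst.gGB[i] += pr.gabab_gain * g;
            dst.gSH[i] += pr.gabash_gain * g;
          }
        } else {
          for (int s = pr.pre_ptr[j]; s < pr.pre_ptr[j + 1]; ++s) {
            int i = pr.syn_post[s];
            double g = xj * pr.w[s];
            dst.gA[i] += g;
            dst.gN[i] += pr.nmda_gain * g;
          }
        }
        pr.x[j] *= pr.pfac;
      }
      if (pr.plastic && pr.alpha != 0.0) {
        // pre spike: pair with most recent post spike (depression, dt <= 0)
        for (size_t f = 0; f < src.fired.size(); ++f) {
          int j = src.fired[f];
          for (int s = pr.pre_ptr[j]; s < pr.pre_ptr[j + 1]; ++s) {
            double tp = dst.last_spike[pr.syn_post[s]];
            if (tp > -1e17)
              pr.ctr[s] -= pr.alpha * e->A_minus *
                std::exp(-(tnow - tp) / e->tau_minus);
          }
        }
        // post spike: pair with most recent pre spike (potentiation, dt > 0)
        for (size_t f = 0; f < dst.fired.size(); ++f) {
          int i = dst.fired[f];
          for (int s = pr.post_ptr[i]; s < pr.post_ptr[i + 1]; ++s) {
            int id = pr.post_syn[s];
            double tp = src.last_spike[pr.syn_pre[id]];
            if (tp > -1e17)
              pr.ctr[id] += pr.alpha * e->A_plus *
                std::exp(-(tnow - tp) / e->tau_plus);
          }
        }
      }
    }

    // last-spike times updated after all pairings (same-tick pairs use the
    // previous spike of the partner, avoiding an ill-defined dt = 0 pairing)
    for (int p = 0; p < npop; ++p) {
      Population &pop = e->pops[p];
      for (size_t f = 0; f < pop.fired.size(); ++f)
        pop.last_spike[pop.fired[f]] = tnow;
    }

    e->tick++;

    // 50-ms cadence: Euler weight update from the eligibility trace, trace
    // decay, then homeostatic scaling on every pathway with a sum target
    if (e->tick % e->plast_every == 0) {
      for (size_t q = 0; q < e->projs.size(); ++q) {
        Projection &pr = e->projs[q];
        if (pr.plastic && pr.alpha != 0.0) {
          for (int s = 0; s < pr.nsyn; ++s) {
            pr.w[s] += pr.ctr[s] * dt_s;
            pr.ctr[s] *= cdecay;
          }
        }
        if (pr.plastic && pr.alpha != 0.0)
          scale_posts(pr, e->pops[pr.dst].n);
      }
    }
  }
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(SEXP eptr, int n_ticks, List ext_currents, bool record) {
  XPtr<Engine> e(eptr);
  std::vector<const double*> ext(e->pops.size(), (const double*)0);
  std::vector<NumericVector> keep;   // protect from gc
  for (int p = 0; p < (int)e->pops.size(); ++p) {
    if (p < ext_currents.size() && !Rf_isNull(ext_currents[p])) {
      NumericVector cur = ext_currents[p];
      if ((int)cur.size() != e->pops[p].n)
        stop("external current length mismatch for population %d", p + 1);
      keep.push_back(cur);
      ext[p] = keep.back().begin();
    }
  }
  e->recording = record;
  e->rec_t.clear(); e->rec_pop.clear(); e->rec_neuron.clear();
  run_ticks(e, n_ticks, ext);
  List out = List::create(
    _["time"] = wrap(e->rec_t),
    _["pop"] = wrap(e->rec_pop),
    _["neuron"] = wrap(e->rec_neuron));
  e->rec_t.clear(); e->rec_pop.clear(); e->rec_neuron.clear();
  e->recording = false;
  return out;
}

// [[Rcpp::export(name = ".engine_time")]]
double engine_time(SEXP eptr) {
  XPtr<Engine> e(eptr);
  return e->tick * e->dt;
}

// [[Rcpp::export(name = ".engine_get_weights")]]
NumericVector engine_get_weights(SEXP eptr, int proj) {
  XPtr<Engine> e(eptr);
  Projection &pr = e->projs[proj - 1];
  return wrap(pr.w);
}

// [[Rcpp::export(name = ".engine_get_synapses")]]
List engine_get_synapses(SEXP eptr, int proj) {
  XPtr<Engine> e(eptr);
  Projection &pr = e->projs[proj - 1];
  IntegerVector pre(pr.nsyn), post(pr.nsyn);
  for (int s = 0; s < pr.nsyn; ++s) {
    pre[s] = pr.syn_pre[s] + 1;
    post[s] = pr.syn_post[s] + 1;
  }
  return List::create(_["pre"] = pre, _["post"] = post, _["weight"] = wrap(pr.w));
}

// [[Rcpp::export(name = ".engine_set_gain")]]
void engine_set_gain(SEXP eptr, int proj, double gain) {
  XPtr<Engine> e(eptr);
  e->projs[proj - 1].gain_mult = gain;
}

// [[Rcpp::export(name = ".engine_set_gabash")]]
void engine_set_gabash(SEXP eptr, int proj, double gain) {
  XPtr<Engine> e(eptr);
  e->projs[proj - 1].gabash_gain = gain;
}

// [[Rcpp::export(name = ".engine_set_alpha")]]
void engine_set_alpha(SEXP eptr, int proj, double alpha) {
  XPtr<Engine> e(eptr);
  e->projs[proj - 1].alpha = alpha;
}

// [[Rcpp::export(name = ".engine_get_x")]]
NumericVector engine_get_x(SEXP eptr, int proj) {
  XPtr<Engine> e(eptr);
  return wrap(e->projs[proj - 1].x);
}

// [[Rcpp::export(name = ".engine_get_state")]]
List engine_get_state(SEXP eptr, int pop) {
  XPtr<Engine> e(eptr);
  Population &p = e->pops[pop - 1];
  return List::create(
    _["v"] = wrap(p.v), _["u"] = wrap(p.u),
    _["g_ampa"] = wrap(p.gA), _["g_nmda"] = wrap(p.gN),
    _["g_gabaa"] = wrap(p.gGA), _["g_gabab"] = wrap(p.gGB),
    _["g_sh"] = wrap(p.gSH));
}
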