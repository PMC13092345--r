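#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Forward Wright-Fisher engines.
//
// Two entry points:
//   cpp_single_locus_wf : frequency-only diploid WF at one selected site
//                         (deterministic genotype-selection update followed
//                         by binomial gamete sampling).
//   cpp_sequence_wf     : individual-based diploid WF on a recombining
//                         sequence with infinite-sites neutral (and optional
//                         deleterious) mutation and a selected central locus.
//
// Seasons are binary blocks of g generations; generation 0 is the first
// summer generation. Selection modes: 0 neutral, 1 fluctuating,
// 2 heterozygote advantage, 3 hard sweep, 4 soft sweep.

static inline bool is_summer(int t, int g) { return ((t / g) % 2) == 0; }

// genotype fitnesses (wWW, wSW, wSS) at the selected locus
static inline void mode_fitness(int mode, bool summer, double s_s, double s_w,
                                double h_s, double h_w, double *w) {
  switch (mode) {
  case 0: w[0] = 1.0; w[1] = 1.0; w[2] = 1.0; break;
  case 1:
    if (summer) { w[0] = 1.0; w[1] = 1.0 + h_s * s_s; w[2] = 1.0 + s_s; }
    else        { w[0] = 1.0 + s_w; w[1] = 1.0 + h_w * s_w; w[2] = 1.0; }
    break;
  case 2: w[0] = 1.0 - s_s; w[1] = 1.0; w[2] = 1.0 - s_s; break;
  case 3: case 4:
    w[0] = 1.0; w[1] = 1.0 + h_s * s_s; w[2] = 1.0 + s_s; break;
  default: stop("unknown selection mode");
  }
}

static inline double det_update(double p, const double *w) {
  if (p <= 0.0) return 0.0;
  if (p >= 1.0) return 1.0;
  double q = 1.0 - p;
  double num = p * p * w[2] + p * q * w[1];
  double den = p * p * w[2] + 2.0 * p * q * w[1] + q * q * w[0];
  if (den <= 0.0) stop("degenerate population: mean fitness is zero");
  return num / den;
}

// [[Rcpp::export]]
List cpp_single_locus_wf(int N, int n_gen, int mode,
                         double s_s, double s_w, double h_s, double h_w,
                         int g, double p0, bool restart_on_loss,
                         int max_restarts, bool stop_at_fixation) {
  if (N < 2) stop("N must be >= 2");
  if (g < 1) stop("season length must be >= 1");
  const double twoN = 2.0 * N;
  NumericVector freq(n_gen + 1);
  double w[3];
  int restarts = 0;
  double p = p0;
  freq[0] = p;
  int t = 0;
  while (t < n_gen) {
    bool summer = is_summer(t, g);
    mode_fitness(mode, summer, s_s, s_w, h_s, h_w, w);
    double pd = det_update(p, w);
    p = R::rbinom(twoN, pd) / twoN;
    freq[t + 1] = p;
    ++t;
    bool mono = (p <= 0.0 || p >= 1.0);
    bool lost = (p <= 0.0);
    if (mode == 1 || mode == 2) {
      if (mono && restart_on_loss && t < n_gen) {
        if (++restarts > max_restarts)
          stop("restart limit (%d) exceeded for selected locus", max_restarts);
        p = p0; t = 0; freq[0] = p0;
      } else if (mono) {
        for (int k = t; k <= n_gen; ++k) freq[k] = p;
        break;
      }
    } else if (mode == 3) {
      if (lost && restart_on_loss && t < n_gen) {
        if (++restarts > max_restarts)
          stop("restart limit (%d) exceeded for selected locus", max_restarts);
        p = p0; t = 0; freq[0] = p0;
      } else if (mono) {
        for (int k = t; k <= n_gen; ++k) freq[k] = p;
        if (p >= 1.0 && stop_at_fixation) break;
        if (lost) break;
      }
    } else if (mono) { // neutral: absorb, no restart
      for (int k = t; k <= n_gen; ++k) freq[k] = p;
      break;
    }
  }
  double pe = freq[n_gen];
  std::string terminal = (pe <= 0.0) ? "lost" : (pe >= 1.0) ? "fixed" : "polymorphic";
  return List::create(_["freq"] = freq, _["restarts"] = restarts,
                      _["terminal"] = terminal);
}

// ---------------------------------------------------------------------------
// Sequence engine

struct MutTab {
  std::vector<double> pos;
  std::vector<int> klass;    // 0 neutral, 2 deleterious
  std::vector<double> s, h;  // deleterious only
  int add(double p, int k, double ss, double hh) {
    pos.push_back(p); klass.push_back(k); s.push_back(ss); h.push_back(hh);
    return (int)pos.size() - 1;
  }
};

typedef std::vector<int> Hap;

struct SampleRec {
  int generation;
  std::string label;      // "early" / "long" / "fixed" / "scheduled"
  IntegerMatrix mat;
  NumericVector pos;
  IntegerVector klass;
  IntegerVector indiv;
};

// one recombinant gamete from parent haplotypes a/b; returns which source
// haplotype covered sel_pos via *sel_src (0 = a, 1 = b)
static void make_gamete(const Hap &a, const Hap &b, const MutTab &mut,
                        double rL, double L, double sel_pos,
                        Hap &out, int *sel_src) {
  out.clear();
  int k = (rL > 0.0) ? (int)R::rpois(rL) : 0;
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  if (k == 0) {
    out = (cur == 0) ? a : b;
    *sel_src = cur;
    return;
  }
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  bp.push_back(L);
  size_t ia = 0, ib = 0;
  double lo = 0.0;
  *sel_src = cur;
  for (size_t s = 0; s < bp.size(); ++s) {
    double hi = bp[s];
    // advance both pointers past positions < lo
    while (ia < a.size() && mut.pos[a[ia]] < lo) ++ia;
    while (ib < b.size() && mut.pos[b[ib]] < lo) ++ib;
    if (lo <= sel_pos && sel_pos < hi) *sel_src = cur;
    if (cur == 0) {
      while (ia < a.size() && mut.pos[a[ia]] < hi) out.push_back(a[ia++]);
    } else {
      while (ib < b.size() && mut.pos[b[ib]] < hi) out.push_back(b[ib++]);
    }
    cur = 1 - cur;
    lo = hi;
  }
}

static void add_new_mutations(Hap &h, MutTab &mut, double muL, double L,
                              int klass, double gmean, double gshape,
                              double del_h) {
  if (muL <= 0.0) return;
  int m = (int)R::rpois(muL);
  for (int i = 0; i < m; ++i) {
    double p = unif_rand() * L;
    double s = 0.0, hh = 0.0;
    if (klass == 2) { s = -R::rgamma(gshape, gmean / gshape); hh = del_h; }
    int id = mut.add(p, klass, s, hh);
    // insert keeping position order
    size_t lo = 0, hi = h.size();
    while (lo < hi) {
      size_t mid = (lo + hi) / 2;
      if (mut.pos[h[mid]] < p) lo = mid + 1; else hi = mid;
    }
    h.insert(h.begin() + lo, id);
  }
}

// remove ids fixed in all 2N haplotypes
static void purge_fixed(std::vector<Hap> &pop, const MutTab &mut,
                        std::vector<int> &scratch) {
  scratch.assign(mut.pos.size(), 0);
  for (const Hap &h : pop) for (int id : h) ++scratch[id];
  int n = (int)pop.size();
  bool any = false;
  for (size_t i = 0; i < scratch.size() && !any; ++i)
    if (scratch[i] == n) any = true;
  if (!any) return;
  for (Hap &h : pop) {
    size_t w = 0;
    for (size_t r = 0; r < h.size(); ++r)
      if (scratch[h[r]] != n) h[w++] = h[r];
    h.resize(w);
  }
}

// sample n distinct individuals; matrix over sites segregating in the sample
static SampleRec take_sample(const std::vector<Hap> &pop,
                             const std::vector<int> &ben,
                             const MutTab &mut, int n_ind, double sel_pos,
                             int generation, const std::string &label) {
  int N = (int)pop.size() / 2;
  if (n_ind > N) n_ind = N;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_ind; ++i) {
    int j = i + (int)(unif_rand() * (N - i));
    if (j >= N) j = N - 1;
    std::swap(idx[i], idx[j]);
  }
  int H = 2 * n_ind;
  // tally ids within sample
  std::vector<int> cnt(mut.pos.size(), 0);
  for (int i = 0; i < n_ind; ++i) {
    for (int id : pop[2 * idx[i]]) ++cnt[id];
    for (int id : pop[2 * idx[i] + 1]) ++cnt[id];
  }
  int ben_cnt = 0;
  for (int i = 0; i < n_ind; ++i)
    ben_cnt += (ben[2 * idx[i]] > 0) + (ben[2 * idx[i] + 1] > 0);
  struct Site { double pos; int id; int klass; };
  std::vector<Site> sites;
  for (size_t id = 0; id < cnt.size(); ++id)
    if (cnt[id] > 0 && cnt[id] < H)
      sites.push_back({mut.pos[id], (int)id, mut.klass[id]});
  bool sel_site = (ben_cnt > 0 && ben_cnt < H);
  if (sel_site) sites.push_back({sel_pos, -1, 1});
  std::sort(sites.begin(), sites.end(),
            [](const Site &x, const Site &y) { return x.pos < y.pos; });
  int S = (int)sites.size();
  std::vector<int> col(mut.pos.size(), -1);
  IntegerMatrix M(H, S);
  NumericVector pos(S);
  IntegerVector kl(S);
  int sel_col = -1;
  for (int j = 0; j < S; ++j) {
    pos[j] = sites[j].pos; kl[j] = sites[j].klass;
    if (sites[j].id >= 0) col[sites[j].id] = j; else sel_col = j;
  }
  for (int i = 0; i < H; ++i) {
    const Hap &h = pop[2 * idx[i / 2] + (i % 2)];
    for (int id : h) if (col[id] >= 0) M(i, col[id]) = 1;
    if (sel_col >= 0 && ben[2 * idx[i / 2] + (i % 2)] > 0) M(i, sel_col) = 1;
  }
  IntegerVector ind(n_ind);
  for (int i = 0; i < n_ind; ++i) ind[i] = idx[i] + 1;
  SampleRec r;
  r.generation = generation; r.label = label;
  r.mat = M; r.pos = pos; r.klass = kl; r.indiv = ind;
  return r;
}

// one generation of reproduction (selection + recombination + mutation)
static void reproduce(std::vector<Hap> &pop, std::vector<int> &ben,
                      std::vector<Hap> &next, std::vector<int> &next_ben,
                      MutTab &mut, int N, double L, double sel_pos,
                      double muL, double rL, int mode, bool summer,
                      double s_s, double s_w, double h_s, double h_w,
                      bool dfe, double dfe_mean, double dfe_shape,
                      double del_frac, double del_h, bool neutral_phase) {
  double w[3];
  std::vector<double> cum(N);
  double tot = 0.0;
  if (!neutral_phase) {
    mode_fitness(mode, summer, s_s, s_w, h_s, h_w, w);
    for (int i = 0; i < N; ++i) {
      int gcount = (ben[2 * i] > 0) + (ben[2 * i + 1] > 0);
      double f = w[gcount];
      if (dfe) {
        // multiplicative fitness over deleterious genotypes
        const Hap &a = pop[2 * i], &b = pop[2 * i + 1];
        size_t ia = 0, ib = 0;
        while (ia < a.size() || ib < b.size()) {
          int id; int copies;
          if (ib >= b.size() || (ia < a.size() && mut.pos[a[ia]] <= mut.pos[b[ib]])) {
            id = a[ia];
            if (ib < b.size() && b[ib] == id) { copies = 2; ++ia; ++ib; }
            else { copies = 1; ++ia; }
          } else { id = b[ib]; copies = 1; ++ib; }
          if (mut.klass[id] == 2)
            f *= (copies == 2) ? (1.0 + mut.s[id])
                               : (1.0 + mut.h[id] * mut.s[id]);
        }
      }
      if (f < 0.0) f = 0.0;
      tot += f;
      cum[i] = tot;
    }
    if (tot <= 0.0) stop("degenerate population: all fitnesses are zero");
  }
  for (int i = 0; i < N; ++i) {
    for (int gam = 0; gam < 2; ++gam) {
      int par;
      if (neutral_phase) {
        par = (int)(unif_rand() * N); if (par >= N) par = N - 1;
      } else {
        double u = unif_rand() * tot;
        par = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (par >= N) par = N - 1;
      }
      int src;
      Hap &out = next[2 * i + gam];
      make_gamete(pop[2 * par], pop[2 * par + 1], mut, rL, L, sel_pos, out, &src);
      next_ben[2 * i + gam] = ben[2 * par + src];
      add_new_mutations(out, mut, muL, L, 0, 0, 0, 0);
      if (dfe && del_frac > 0.0)
        add_new_mutations(out, mut, del_frac * muL, L, 2, dfe_mean, dfe_shape, del_h);
    }
  }
  pop.swap(next);
  ben.swap(next_ben);
}

static List export_population(const std::vector<Hap> &pop,
                              const std::vector<int> &ben, const MutTab &mut) {
  // compact: keep only referenced mutation ids
  std::vector<int> remap(mut.pos.size(), 0);
  for (const Hap &h : pop) for (int id : h) remap[id] = 1;
  std::vector<int> keep;
  for (size_t i = 0; i < remap.size(); ++i)
    if (remap[i]) { remap[i] = (int)keep.size() + 1; keep.push_back((int)i); }
  int M = (int)keep.size();
  NumericVector pos(M); IntegerVector kl(M); NumericVector s(M), h(M);
  for (int j = 0; j < M; ++j) {
    pos[j] = mut.pos[keep[j]]; kl[j] = mut.klass[keep[j]];
    s[j] = mut.s[keep[j]]; h[j] = mut.h[keep[j]];
  }
  List haps(pop.size());
  for (size_t i = 0; i < pop.size(); ++i) {
    IntegerVector v((int)pop[i].size());
    for (size_t j = 0; j < pop[i].size(); ++j) v[j] = remap[pop[i][j]];
    haps[i] = v;
  }
  return List::create(_["haplotypes"] = haps,
                      _["beneficial"] = IntegerVector(ben.begin(), ben.end()),
                      _["mut_position"] = pos, _["mut_class"] = kl,
                      _["mut_s"] = s, _["mut_h"] = h);
}

// [[Rcpp::export]]
List cpp_sequence_wf(List cfg) {
  const int N = as<int>(cfg["N"]);
  const double L = as<double>(cfg["L"]);
  const double mu = as<double>(cfg["mu"]);
  const double r = as<double>(cfg["r"]);
  const int g = as<int>(cfg["g"]);
  const int n_gen = as<int>(cfg["n_generations"]);
  const int mode = as<int>(cfg["mode"]);
  const double s_s = as<double>(cfg["s_s"]), s_w = as<double>(cfg["s_w"]);
  const double h_s = as<double>(cfg["h_s"]), h_w = as<double>(cfg["h_w"]);
  const double sel_pos = as<double>(cfg["selected_position"]);
  const double soft_rate = as<double>(cfg["soft_sweep_rate"]);
  const int burn_in = as<int>(cfg["burn_in"]);
  const bool dfe = as<bool>(cfg["dfe_enabled"]);
  const double dfe_mean = as<double>(cfg["dfe_mean"]);
  const double dfe_shape = as<double>(cfg["dfe_shape"]);
  const double del_frac = as<double>(cfg["deleterious_fraction"]);
  const double del_h = as<double>(cfg["deleterious_h"]);
  const bool restart_on_loss = as<bool>(cfg["restart_on_loss"]);
  const int max_restarts = as<int>(cfg["max_restarts"]);
  const bool stop_at_fixation = as<bool>(cfg["stop_at_fixation"]);
  const bool return_population = as<bool>(cfg["return_population"]);
  IntegerVector sample_gens = cfg["sample_gens"];
  const int sample_n = as<int>(cfg["sample_n"]);
  const bool eq_sampling = as<bool>(cfg["eq_sampling"]);
  const double p_eq = as<double>(cfg["p_eq"]);
  const int early_at = as<int>(cfg["early_at"]); // -1 => detect via p_eq
  IntegerVector cyc_off = cfg["cycle_offsets"];
  const int purge_every = 50;

  const double muL = mu * L, rL = r * L;
  const int H = 2 * N;
  const bool do_introduce = as<bool>(cfg["introduce"]);
  MutTab mut;
  std::vector<Hap> pop(H), next(H);
  std::vector<int> ben(H, 0), next_ben(H, 0), scratch;
  int origin_counter = 0;

  // starting population: imported or founded empty
  if (cfg.containsElementNamed("init_pop") && !Rf_isNull(cfg["init_pop"])) {
    List ip = cfg["init_pop"];
    List haps = ip["haplotypes"];
    NumericVector mp = ip["mut_position"];
    IntegerVector mk = ip["mut_class"];
    NumericVector ms = ip["mut_s"], mh = ip["mut_h"];
    if (haps.size() != H) stop("imported population must have 2N haplotypes");
    for (int j = 0; j < mp.size(); ++j) mut.add(mp[j], mk[j], ms[j], mh[j]);
    for (int i = 0; i < H; ++i) {
      IntegerVector v = haps[i];
      Hap h(v.size());
      for (int j = 0; j < v.size(); ++j) h[j] = v[j] - 1;
      std::sort(h.begin(), h.end(), [&](int a, int b) {
        return mut.pos[a] < mut.pos[b];
      });
      pop[i] = h;
    }
    if (ip.containsElementNamed("beneficial") && !Rf_isNull(ip["beneficial"])) {
      IntegerVector bv = ip["beneficial"];
      for (int i = 0; i < H && i < bv.size(); ++i) {
        ben[i] = bv[i];
        if (bv[i] > origin_counter) origin_counter = bv[i];
      }
    }
  }

  // neutral burn-in
  for (int t = 0; t < burn_in; ++t) {
    reproduce(pop, ben, next, next_ben, mut, N, L, sel_pos, muL, rL,
              0, true, 0, 0, 0, 0, dfe, dfe_mean, dfe_shape, del_frac, del_h,
              /*neutral_phase=*/!dfe);
    if ((t + 1) % purge_every == 0) purge_fixed(pop, mut, scratch);
  }
  purge_fixed(pop, mut, scratch);

  // snapshot for restarts (burn-in state is re-used, as for a stored burn-in)
  std::vector<Hap> snap = pop;
  std::vector<int> snap_ben = ben;
  const int snap_origin_counter = origin_counter;

  NumericVector freq(n_gen + 1);
  IntegerVector n_origins(n_gen + 1);
  LogicalVector trait_fixed(n_gen + 1);
  std::vector<SampleRec> samples;
  int restarts = 0, t_eq = -1, fix_gen = -1;

  // selected-mutation introduction at generation 0 (start of summer)
  auto introduce = [&]() {
    if (!do_introduce) return;
    if (mode == 1 || mode == 2 || mode == 3) {
      int j = (int)(unif_rand() * H); if (j >= H) j = H - 1;
      ben[j] = ++origin_counter;
    }
  };
  introduce();

  auto record_state = [&](int t) {
    int c = 0;
    for (int i = 0; i < H; ++i) if (ben[i] > 0) ++c;
    freq[t] = (double)c / H;
    std::vector<int> seen;
    for (int i = 0; i < H; ++i)
      if (ben[i] > 0 &&
          std::find(seen.begin(), seen.end(), ben[i]) == seen.end())
        seen.push_back(ben[i]);
    n_origins[t] = (int)seen.size();
    bool covered = (c == H);
    if (mode == 4 && c > 0) {
      covered = true;
      for (int i = 0; i < N && covered; ++i)
        if (ben[2 * i] == 0 || ben[2 * i + 1] == 0) covered = false;
    }
    trait_fixed[t] = covered;
    return freq[t];
  };
  record_state(0);

  // pending equilibrium-cycle samples
  std::vector<std::pair<int, std::string>> pending;
  auto schedule_cycle = [&](int cycle_start, const std::string &label) {
    for (int j = 0; j < cyc_off.size(); ++j)
      pending.push_back({cycle_start + cyc_off[j], label});
  };
  if (eq_sampling && early_at >= 0) schedule_cycle(early_at, "early");
  if (eq_sampling) {
    int lc = (n_gen / (2 * g)) * 2 * g - 2 * g;
    if (lc >= 0) schedule_cycle(lc, "long");
  }

  int t = 0;
  while (t < n_gen) {
    bool summer = is_summer(t, g);
    reproduce(pop, ben, next, next_ben, mut, N, L, sel_pos, muL, rL,
              mode, summer, s_s, s_w, h_s, h_w, dfe, dfe_mean, dfe_shape,
              del_frac, del_h, /*neutral_phase=*/(mode == 0 && !dfe));
    // soft sweep: recurrent beneficial origins at the selected site
    if (mode == 4 && soft_rate > 0.0) {
      int nm = (int)R::rpois(soft_rate);
      for (int k = 0; k < nm; ++k) {
        int j = (int)(unif_rand() * H); if (j >= H) j = H - 1;
        if (ben[j] == 0) ben[j] = ++origin_counter;
      }
    }
    ++t;
    double p = record_state(t);
    if ((t % purge_every) == 0) purge_fixed(pop, mut, scratch);

    if (eq_sampling && early_at < 0 && t_eq < 0 && p >= p_eq) {
      t_eq = t;
      int cs = ((t_eq / (2 * g)) + 1) * 2 * g;
      schedule_cycle(cs, "early");
    }
    // restart logic
    bool mono = (p <= 0.0 || p >= 1.0);
    bool need_restart = false;
    if (mode == 1 || mode == 2) need_restart = mono && t < n_gen;
    else if (mode == 3 || mode == 4) need_restart = (p <= 0.0) && mode == 3;
    if (need_restart && restart_on_loss) {
      if (++restarts > max_restarts)
        stop("restart limit (%d) exceeded for selected locus", max_restarts);
      pop = snap;
      ben = snap_ben;
      origin_counter = snap_origin_counter;
      introduce();
      t = 0; t_eq = -1; fix_gen = -1;
      samples.clear();
      pending.clear();
      if (eq_sampling && early_at >= 0) schedule_cycle(early_at, "early");
      if (eq_sampling) {
        int lc = (n_gen / (2 * g)) * 2 * g - 2 * g;
        if (lc >= 0) schedule_cycle(lc, "long");
      }
      record_state(0);
      continue;
    }
    // fixation of the beneficial trait (sweep modes)
    if ((mode == 3 || mode == 4) && fix_gen < 0 && trait_fixed[t]) {
      fix_gen = t;
      if (stop_at_fixation) {
        purge_fixed(pop, mut, scratch);
        if (sample_n > 0)
          samples.push_back(take_sample(pop, ben, mut, sample_n, sel_pos, t, "fixed"));
        for (int k = t; k <= n_gen; ++k) {
          freq[k] = freq[t]; n_origins[k] = n_origins[t]; trait_fixed[k] = true;
        }
        break;
      }
    }
    // scheduled samples
    for (int j = 0; j < sample_gens.size(); ++j)
      if (sample_gens[j] == t && sample_n > 0)
        samples.push_back(take_sample(pop, ben, mut, sample_n, sel_pos, t, "scheduled"));
    for (size_t j = 0; j < pending.size(); ++j)
      if (pending[j].first == t && sample_n > 0)
        samples.push_back(take_sample(pop, ben, mut, sample_n, sel_pos, t,
                                      pending[j].second));
  }

  List out_samples(samples.size());
  for (size_t i = 0; i < samples.size(); ++i) {
    out_samples[i] = List::create(
      _["generation"] = samples[i].generation, _["label"] = samples[i].label,
      _["matrix"] = samples[i].mat, _["positions"] = samples[i].pos,
      _["site_class"] = samples[i].klass, _["individuals"] = samples[i].indiv);
  }
  double pe = freq[n_gen];
  std::string terminal = (mode == 0)
    ? "polymorphic"
    : (pe <= 0.0) ? "lost" : (pe >= 1.0) ? "fixed" : "polymorphic";
  List out = List::create(
    _["freq"] = freq, _["n_origins"] = n_origins, _["trait_fixed"] = trait_fixed,
    _["restarts"] = restarts, _["terminal"] = terminal,
    _["t_eq"] = t_eq, _["fixation_generation"] = fix_gen,
    _["samples"] = out_samples);
  if (return_population)
    out["population"] = export_population(pop, ben, mut);
  return out;
}
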