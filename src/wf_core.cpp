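// Forward-time diploid Wright-Fisher core: fecundity selection, Poisson
// crossovers on the map (Morgan) scale, infinite-sites mutation with
// position re-draw on collision, partial selfing, arbitrary census path.
// All randomness flows through R's RNG so set.seed() gives bit-identical
// runs.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Piecewise-linear cumulative genetic map: anchors in bp and Morgans.
struct GMap {
  std::vector<double> bp;
  std::vector<double> m;
  double total() const { return m.back(); }
  double to_m(double x) const {
    size_t k = std::upper_bound(bp.begin(), bp.end(), x) - bp.begin();
    if (k == 0) return m.front();
    if (k >= bp.size()) return m.back();
    double f = (x - bp[k - 1]) / (bp[k] - bp[k - 1]);
    return m[k - 1] + f * (m[k] - m[k - 1]);
  }
  double to_bp(double mm) const {
    size_t k = std::upper_bound(m.begin(), m.end(), mm) - m.begin();
    if (k == 0) return bp.front();
    if (k >= m.size()) return bp.back();
    double span = m[k] - m[k - 1];
    if (span <= 0) return bp[k - 1];
    return bp[k - 1] + (mm - m[k - 1]) / span * (bp[k] - bp[k - 1]);
  }
};

struct Registry {
  std::vector<double> pos, mpos, s, h;
  std::vector<int> origin;
  std::vector<char> active;
  size_t size() const { return pos.size(); }
  int add(double p, double mp, double ss, double hh, int g) {
    pos.push_back(p); mpos.push_back(mp); s.push_back(ss); h.push_back(hh);
    origin.push_back(g); active.push_back(1);
    return (int)pos.size() - 1;
  }
};

typedef std::vector<int> Hap;

// Draw (s, h) for one new mutation.  kind: 0 neutral, 1 background
// selection (deleterious gamma), 2 selective sweeps (beneficial gamma),
// 3 overdominance (fixed s, h).  Gamma draws that would push s <= -1 are
// re-drawn (shape 0.2 has appreciable mass far into the tail).
void draw_effect(int kind, double p_sel, double shape, double scale,
                 double od_s, double od_h, double &s, double &h) {
  s = 0.0; h = 0.5;
  if (kind == 0 || p_sel <= 0.0) return;
  if (unif_rand() >= p_sel) return;
  if (kind == 1) {
    double g;
    do { g = R::rgamma(shape, scale); } while (g >= 1.0);
    s = -g;
  } else if (kind == 2) {
    s = R::rgamma(shape, scale);
  } else {
    s = od_s; h = od_h;
  }
}

// Multiplicative fitness over loci: 1 (wild-type hom), 1+sh (het),
// 1+s (mutant hom); floored at zero.  Haplotypes are sorted by bp and
// positions are unique per mutation, so a positional merge identifies
// heterozygous vs homozygous sites.
double fitness_of(const Hap &a, const Hap &b, const Registry &reg) {
  double w = 1.0;
  size_t i = 0, j = 0;
  while (i < a.size() || j < b.size()) {
    if (j == b.size() ||
        (i < a.size() && reg.pos[a[i]] < reg.pos[b[j]])) {
      double s = reg.s[a[i]];
      if (s != 0.0) w *= 1.0 + s * reg.h[a[i]];
      ++i;
    } else if (i == a.size() || reg.pos[b[j]] < reg.pos[a[i]]) {
      double s = reg.s[b[j]];
      if (s != 0.0) w *= 1.0 + s * reg.h[b[j]];
      ++j;
    } else {
      double s = reg.s[a[i]];
      if (s != 0.0) w *= 1.0 + s;
      ++i; ++j;
    }
  }
  return w < 0.0 ? 0.0 : w;
}

Hap make_gamete(const Hap &h1, const Hap &h2, Registry &reg,
                const GMap &map, std::unordered_set<long long> &used,
                double mu_total, double L, int gen,
                int kind, double p_sel, double shape, double scale,
                double od_s, double od_h) {
  const Hap *hv[2] = { &h1, &h2 };
  int cur = unif_rand() < 0.5 ? 0 : 1;
  Hap out;
  int ncx = (int) R::rpois(map.total());
  if (ncx == 0) {
    out = *hv[cur];
  } else {
    std::vector<double> bx((size_t)ncx);
    for (int t = 0; t < ncx; ++t) bx[t] = unif_rand() * map.total();
    std::sort(bx.begin(), bx.end());
    size_t idx[2] = { 0, 0 };
    out.reserve(h1.size());
    for (size_t t = 0; t <= bx.size(); ++t) {
      double b = (t < bx.size()) ? bx[t] : R_PosInf;
      const Hap &hc = *hv[cur];
      while (idx[cur] < hc.size() && reg.mpos[hc[idx[cur]]] < b)
        out.push_back(hc[idx[cur]++]);
      int oth = 1 - cur;
      const Hap &ho = *hv[oth];
      while (idx[oth] < ho.size() && reg.mpos[ho[idx[oth]]] < b)
        ++idx[oth];
      cur = oth;
    }
  }
  int nm = (int) R::rpois(mu_total);
  for (int t = 0; t < nm; ++t) {
    long long p;
    do {
      p = (long long) std::floor(unif_rand() * L);
      if (p >= (long long)L) p = (long long)L - 1;
    } while (used.count(p));
    used.insert(p);
    double s, h;
    draw_effect(kind, p_sel, shape, scale, od_s, od_h, s, h);
    int id = reg.add((double)p, map.to_m((double)p), s, h, gen);
    Hap::iterator it = std::lower_bound(
        out.begin(), out.end(), id,
        [&reg](int x, int y) { return reg.pos[x] < reg.pos[y]; });
    out.insert(it, id);
  }
  return out;
}

int draw_weighted(const std::vector<double> &cumw, double total) {
  double u = unif_rand() * total;
  return (int)(std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

} // namespace

// [[Rcpp::export]]
List cpp_evolve(List haps_in,
                NumericVector pos0, NumericVector mpos0,
                NumericVector s0, NumericVector h0,
                IntegerVector origin0, LogicalVector active0,
                IntegerVector census, double mu, double L,
                NumericVector map_bp, NumericVector map_m,
                double beta, int dfe_kind, double p_sel,
                double gamma_shape, double gamma_scale,
                double od_s, double od_h,
                int start_gen, int max_sites) {
  GMap map;
  map.bp.assign(map_bp.begin(), map_bp.end());
  map.m.assign(map_m.begin(), map_m.end());

  Registry reg;
  size_t R0 = pos0.size();
  reg.pos.assign(pos0.begin(), pos0.end());
  reg.mpos.assign(mpos0.begin(), mpos0.end());
  reg.s.assign(s0.begin(), s0.end());
  reg.h.assign(h0.begin(), h0.end());
  reg.origin.assign(origin0.begin(), origin0.end());
  reg.active.resize(R0);
  std::unordered_set<long long> used;
  for (size_t i = 0; i < R0; ++i) {
    reg.active[i] = active0[i] ? 1 : 0;
    if (reg.active[i]) used.insert((long long)reg.pos[i]);
  }

  std::vector<Hap> haps(haps_in.size());
  for (int i = 0; i < haps_in.size(); ++i) {
    IntegerVector hv = haps_in[i];
    haps[i].resize(hv.size());
    for (int j = 0; j < hv.size(); ++j) haps[i][j] = hv[j] - 1;
  }

  int G = census.size();
  NumericVector vk_out(G), kbar_out(G);
  double mu_total = mu * L;
  long long fixed_total = 0;
  std::vector<int> fam;

  for (int g = 0; g < G; ++g) {
    int Ncur = (int)haps.size() / 2;
    int Nnext = census[g];
    int gen = start_gen + g + 1;

    // fitness-weighted parent sampling (uniform when neutral)
    std::vector<double> cumw;
    double wtot = 0.0;
    bool weighted = (dfe_kind != 0);
    if (weighted) {
      cumw.resize(Ncur);
      for (int i = 0; i < Ncur; ++i) {
        wtot += fitness_of(haps[2 * i], haps[2 * i + 1], reg);
        cumw[i] = wtot;
      }
      if (wtot <= 0.0)
        stop("all individual fitness values are zero at generation %d: population inviable", gen);
    }

    fam.assign(Ncur, 0);
    std::vector<Hap> next;
    next.reserve(2 * (size_t)Nnext);
    for (int j = 0; j < Nnext; ++j) {
      int p1, p2;
      if (weighted) p1 = draw_weighted(cumw, wtot);
      else { p1 = (int)(unif_rand() * Ncur); if (p1 >= Ncur) p1 = Ncur - 1; }
      bool selfed = (beta > 0.0) && (unif_rand() < beta);
      if (selfed) p2 = p1;
      else if (weighted) p2 = draw_weighted(cumw, wtot);
      else { p2 = (int)(unif_rand() * Ncur); if (p2 >= Ncur) p2 = Ncur - 1; }
      ++fam[p1]; ++fam[p2];
      next.push_back(make_gamete(haps[2 * p1], haps[2 * p1 + 1], reg, map,
                                 used, mu_total, L, gen, dfe_kind, p_sel,
                                 gamma_shape, gamma_scale, od_s, od_h));
      next.push_back(make_gamete(haps[2 * p2], haps[2 * p2 + 1], reg, map,
                                 used, mu_total, L, gen, dfe_kind, p_sel,
                                 gamma_shape, gamma_scale, od_s, od_h));
    }

    double kb = 0.0, vk = 0.0;
    for (int i = 0; i < Ncur; ++i) kb += fam[i];
    kb /= Ncur;
    if (Ncur > 1) {
      for (int i = 0; i < Ncur; ++i)
        vk += (fam[i] - kb) * (fam[i] - kb);
      vk /= (Ncur - 1);
    }
    kbar_out[g] = kb;
    vk_out[g] = vk;

    // prune fixed/lost mutations, then compact the registry: renumber
    // surviving mutations densely in position order so that haplotype id
    // lists are ascending and every later walk is cache-sequential
    std::vector<int> cnt(reg.size(), 0);
    for (size_t i = 0; i < next.size(); ++i)
      for (size_t j = 0; j < next[i].size(); ++j) ++cnt[next[i][j]];
    int twoN = 2 * Nnext;
    std::vector<int> act;
    act.reserve(reg.size());
    for (size_t id = 0; id < reg.size(); ++id) {
      if (!reg.active[id]) continue;
      if (cnt[id] == 0) {
        reg.active[id] = 0;
        used.erase((long long)reg.pos[id]);
      } else if (cnt[id] == twoN) {
        reg.active[id] = 0;
        used.erase((long long)reg.pos[id]);
        ++fixed_total;
      } else {
        act.push_back((int)id);
      }
    }
    if ((long long)act.size() > (long long)max_sites)
      stop("segregating-site count (%ld) exceeds max_sites (%d); reduce theta*L or raise max_sites",
           (long)act.size(), max_sites);
    std::sort(act.begin(), act.end(),
              [&reg](int a, int b) { return reg.pos[a] < reg.pos[b]; });
    std::vector<int> remap(reg.size(), -1);
    for (size_t k = 0; k < act.size(); ++k) remap[act[k]] = (int)k;
    Registry nreg;
    nreg.pos.reserve(act.size()); nreg.mpos.reserve(act.size());
    nreg.s.reserve(act.size()); nreg.h.reserve(act.size());
    nreg.origin.reserve(act.size()); nreg.active.reserve(act.size());
    for (size_t k = 0; k < act.size(); ++k) {
      int id = act[k];
      nreg.add(reg.pos[id], reg.mpos[id], reg.s[id], reg.h[id],
               reg.origin[id]);
    }
    reg = std::move(nreg);
    for (size_t i = 0; i < next.size(); ++i) {
      Hap &hp = next[i];
      size_t w = 0;
      for (size_t j = 0; j < hp.size(); ++j) {
        int nid = remap[hp[j]];
        if (nid >= 0) hp[w++] = nid;
      }
      hp.resize(w);
    }
    haps.swap(next);

    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }

  List haps_out(haps.size());
  for (size_t i = 0; i < haps.size(); ++i) {
    IntegerVector hv(haps[i].size());
    for (size_t j = 0; j < haps[i].size(); ++j) hv[j] = haps[i][j] + 1;
    haps_out[i] = hv;
  }
  size_t R1 = reg.size();
  NumericVector pos1(R1), mpos1(R1), s1(R1), h1(R1);
  IntegerVector origin1(R1);
  LogicalVector active1(R1);
  for (size_t i = 0; i < R1; ++i) {
    pos1[i] = reg.pos[i]; mpos1[i] = reg.mpos[i];
    s1[i] = reg.s[i]; h1[i] = reg.h[i];
    origin1[i] = reg.origin[i]; active1[i] = reg.active[i] != 0;
  }
  IntegerVector fam_out(fam.size());
  for (size_t i = 0; i < fam.size(); ++i) fam_out[i] = fam[i];

  return List::create(
      _["haplotypes"] = haps_out,
      _["pos"] = pos1, _["mpos"] = mpos1, _["s"] = s1, _["h"] = h1,
      _["origin"] = origin1, _["active"] = active1,
      _["vk"] = vk_out, _["kbar"] = kbar_out,
      _["family_sizes"] = fam_out,
      _["fixed_total"] = (double)fixed_total);
}
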