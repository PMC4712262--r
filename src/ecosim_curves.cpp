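#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find with path halving.
static int find_root(std::vector<int>& p, int x) {
  while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
  return x;
}

// Replicate clade-bin curves under the Stable Ecotype Model.
//
// Simulates nrep genealogies of n_sample lineages among npop ecotypes
// (within-ecotype coalescence; ecotype formation at rate omega per lineage,
// merging the derived ecotype's lineages backwards into a parent ecotype;
// periodic selection at rate sigma per ecotype, coalescing all its lineages
// at once).  With one remaining ecotype the process is a plain Kingman
// coalescent.  Mutations fall on branches at theta_site * L / 2 per lineage
// per unit time onto uniform sites; for each identity cutoff the number of
// single-linkage clusters (pairs link when their difference count is at
// most max_diff) is returned.
//
// Draws come from R's RNG, so set.seed() on the R side fixes the output.
// [[Rcpp::export]]
List ecosim_curves_cpp(int nrep, int n_sample, int npop,
                       double omega, double sigma,
                       double theta_site, int L,
                       IntegerVector max_diff,
                       int max_events = 1000000) {
  int nc = max_diff.size();
  IntegerMatrix out(nrep, nc);
  NumericVector mean_pwd(nrep);
  NumericVector mean_tpair(nrep);
  RNGScope scope;
  double mut_rate = theta_site * (double)L / 2.0;

  for (int rep = 0; rep < nrep; rep++) {
    std::vector<std::vector<int>> tips(n_sample);
    std::vector<int> comp(n_sample);
    std::vector<double> births(n_sample, 0.0);
    for (int i = 0; i < n_sample; i++) {
      tips[i].assign(1, i);
      int c = (int)(unif_rand() * npop);
      comp[i] = c >= npop ? npop - 1 : c;
    }
    std::vector<double> e_start, e_end;
    std::vector<std::vector<int>> e_tips;
    double t = 0.0;
    double tpair_sum = 0.0;
    int n_ev = 0;

    while ((int)tips.size() > 1) {
      if (++n_ev > max_events) stop("simulation error: event cap exceeded");
      int k = tips.size();
      std::vector<int> cnt(npop, 0);
      for (int i = 0; i < k; i++) cnt[comp[i]]++;
      std::vector<int> active;
      double rate_coal = 0.0;
      std::vector<double> pairs_e;
      for (int c = 0; c < npop; c++) {
        if (cnt[c] > 0) {
          active.push_back(c);
          double pe = cnt[c] * (cnt[c] - 1) / 2.0;
          pairs_e.push_back(pe);
          rate_coal += pe;
        }
      }
      int ncomp = active.size();
      double rate_form = (ncomp > 1) ? omega * k : 0.0;
      double rate_ps = (ncomp > 1) ? sigma * ncomp : 0.0;
      double total = rate_coal + rate_form + rate_ps;
      t += exp_rand() / total;
      double u = unif_rand() * total;

      if (u < rate_coal) {
        // within-ecotype coalescence
        double acc = 0.0; int ci = 0;
        for (; ci < ncomp; ci++) { acc += pairs_e[ci]; if (u < acc) break; }
        if (ci >= ncomp) ci = ncomp - 1;
        int ce = active[ci];
        std::vector<int> members;
        for (int i = 0; i < k; i++) if (comp[i] == ce) members.push_back(i);
        int m = members.size();
        int a = (int)(unif_rand() * m); if (a >= m) a = m - 1;
        int b = (int)(unif_rand() * (m - 1)); if (b >= m - 1) b = m - 2;
        if (b >= a) b++;
        int ia = members[a], ib = members[b];
        e_start.push_back(births[ia]); e_end.push_back(t); e_tips.push_back(tips[ia]);
        e_start.push_back(births[ib]); e_end.push_back(t); e_tips.push_back(tips[ib]);
        tpair_sum += (double)tips[ia].size() * (double)tips[ib].size() * t;
        tips[ia].insert(tips[ia].end(), tips[ib].begin(), tips[ib].end());
        births[ia] = t;
        tips.erase(tips.begin() + ib);
        comp.erase(comp.begin() + ib);
        births.erase(births.begin() + ib);
      } else if (u < rate_coal + rate_form) {
        // ecotype formation (backwards: derived ecotype merges into parent)
        int lin = (int)(unif_rand() * k); if (lin >= k) lin = k - 1;
        int ce = comp[lin];
        int pick = (int)(unif_rand() * (ncomp - 1)); if (pick >= ncomp - 1) pick = ncomp - 2;
        int target = -1, seen = 0;
        for (int ci = 0; ci < ncomp; ci++) {
          if (active[ci] == ce) continue;
          if (seen++ == pick) { target = active[ci]; break; }
        }
        for (int i = 0; i < k; i++) if (comp[i] == ce) comp[i] = target;
      } else {
        // periodic selection: all lineages of one ecotype coalesce
        int ci = (int)(unif_rand() * ncomp); if (ci >= ncomp) ci = ncomp - 1;
        int ce = active[ci];
        std::vector<int> members;
        for (int i = 0; i < k; i++) if (comp[i] == ce) members.push_back(i);
        if (members.size() >= 2) {
          for (size_t j = 0; j < members.size(); j++) {
            int i = members[j];
            e_start.push_back(births[i]); e_end.push_back(t);
            e_tips.push_back(tips[i]);
          }
          int keep = members[0];
          for (size_t j = 1; j < members.size(); j++) {
            int i = members[j];
            tpair_sum += (double)tips[keep].size() * (double)tips[i].size() * t;
            tips[keep].insert(tips[keep].end(), tips[i].begin(), tips[i].end());
          }
          births[keep] = t;
          for (int j = members.size() - 1; j >= 1; j--) {
            int i = members[j];
            tips.erase(tips.begin() + i);
            comp.erase(comp.begin() + i);
            births.erase(births.begin() + i);
          }
        }
      }
    }

    // mutation overlay: (site, time, edge, offset), sorted per site by age
    struct Mut { int site; double time; int edge; int offset; };
    std::vector<Mut> muts;
    for (size_t e = 0; e < e_start.size(); e++) {
      double len = e_end[e] - e_start[e];
      int nm = (int)R::rpois(mut_rate * len);
      for (int j = 0; j < nm; j++) {
        Mut mu;
        mu.site = (int)(unif_rand() * L); if (mu.site >= L) mu.site = L - 1;
        mu.time = e_start[e] + unif_rand() * len;
        mu.edge = (int)e;
        mu.offset = (int)(unif_rand() * 3); if (mu.offset >= 3) mu.offset = 2;
        muts.push_back(mu);
      }
    }
    std::sort(muts.begin(), muts.end(), [](const Mut& a, const Mut& b) {
      if (a.site != b.site) return a.site < b.site;
      return a.time > b.time;  // oldest first within a site
    });

    // resolve tip states per mutated site and accumulate pairwise diffs
    std::vector<int> D(n_sample * n_sample, 0);
    std::vector<int> state(n_sample);
    size_t m = 0;
    while (m < muts.size()) {
      int s = muts[m].site;
      std::fill(state.begin(), state.end(), 0);
      while (m < muts.size() && muts[m].site == s) {
        const std::vector<int>& tt = e_tips[muts[m].edge];
        int cur = state[tt[0]];
        // offset picks one of the three non-current bases
        int nb = muts[m].offset;
        if (nb >= cur) nb++;
        for (size_t q = 0; q < tt.size(); q++) state[tt[q]] = nb;
        m++;
      }
      for (int i = 0; i < n_sample; i++)
        for (int j = i + 1; j < n_sample; j++)
          if (state[i] != state[j]) D[i * n_sample + j]++;
    }

    double npairs = n_sample * (n_sample - 1) / 2.0;
    double dsum = 0.0;
    for (int i = 0; i < n_sample; i++)
      for (int j = i + 1; j < n_sample; j++)
        dsum += D[i * n_sample + j];
    mean_pwd[rep] = dsum / npairs;
    mean_tpair[rep] = n_sample > 1 ? tpair_sum / npairs : 0.0;

    // single-linkage cluster counts at each difference threshold
    for (int c = 0; c < nc; c++) {
      std::vector<int> parent(n_sample);
      for (int i = 0; i < n_sample; i++) parent[i] = i;
      int thr = max_diff[c];
      for (int i = 0; i < n_sample; i++)
        for (int j = i + 1; j < n_sample; j++)
          if (D[i * n_sample + j] <= thr) {
            int ri = find_root(parent, i), rj = find_root(parent, j);
            if (ri != rj) parent[ri] = rj;
          }
      int ncl = 0;
      for (int i = 0; i < n_sample; i++) if (find_root(parent, i) == i) ncl++;
      out(rep, c) = ncl;
    }
  }
  return List::create(_["curves"] = out, _["mean_pwd"] = mean_pwd,
                      _["mean_tpair"] = mean_tpair);
}
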