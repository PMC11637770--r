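#include <Rcpp.h>
using namespace Rcpp;

// Event-driven structured-coalescent simulation of gene trees for exactly
// three sampled sequences on an arbitrary species tree with migration.
//
// Time runs backward from 0. Populations are the nodes of the species tree
// (tips and internal), each alive on [tau[i], tau[parent[i]]); the root is
// alive forever. A lineage in population P coalesces with a co-located
// lineage at rate 2/theta[P] per pair, and is traced into donor D at rate
// 4*M_{D->P}/theta[P] for each migration event D->P whose donor and
// recipient branches are both alive. At a species-tree node the lineages in
// its daughters relocate into it. Only the identity of the first coalescing
// pair and the two coalescence times are needed to classify the topology.
//
// Lineages 0 and 1 are the duplicated pair (their coalescing first gives
// topology G1; before taufocal, G1a); lineage 2 is the single outgroup
// sample. Uses R's RNG so results are reproducible under set.seed().

static inline bool alive(int i, double t, const IntegerVector& parent,
                         const NumericVector& tau) {
  if (t < tau[i]) return false;
  int p = parent[i];
  return p < 0 || t < tau[p];
}

// [[Rcpp::export(name = ".simFirstCoalCpp")]]
List sim_first_coal(IntegerVector parent, NumericVector tau,
                    NumericVector theta, IntegerVector mdonor,
                    IntegerVector mrecip, NumericVector mrate,
                    IntegerVector initpop, double taufocal, int reps,
                    bool record) {
  const int npop = parent.size();
  const int nmig = mdonor.size();
  const int pairs_i[3] = {0, 0, 1};
  const int pairs_j[3] = {1, 2, 2};

  // boundaries: sorted ages of internal nodes (tau > 0 entries suffice,
  // but keep all parents' ages to handle zero-age internal nodes too)
  std::vector<double> bounds;
  for (int i = 0; i < npop; ++i)
    if (parent[i] >= 0) bounds.push_back(tau[parent[i]]);
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());

  int nG[3] = {0, 0, 0};   // first pair = (0,1), (0,2), (1,2)
  int nG1a = 0;
  NumericMatrix rec(record ? reps : 0, 3);  // pairid, t1, t2

  std::vector<double> rate;  // event rates within an epoch
  std::vector<int> etype;    // encoded event

  for (int r = 0; r < reps; ++r) {
    int pop[3] = {initpop[0], initpop[1], initpop[2]};
    bool dead[3] = {false, false, false};
    int nlin = 3;
    double t = 0.0;
    size_t bidx = 0;
    int firstpair = -1;
    double t1 = -1.0, t2 = -1.0;

    while (nlin > 1) {
      // relocate lineages whose branch has ended
      for (int l = 0; l < 3; ++l) {
        if (dead[l]) continue;
        while (parent[pop[l]] >= 0 && t >= tau[parent[pop[l]]])
          pop[l] = parent[pop[l]];
      }
      while (bidx < bounds.size() && bounds[bidx] <= t) ++bidx;
      double tb = bidx < bounds.size() ? bounds[bidx]
                                       : std::numeric_limits<double>::max();

      rate.clear(); etype.clear();
      double total = 0.0;
      for (int k = 0; k < 3; ++k) {  // coalescence of a co-located pair
        int i = pairs_i[k], j = pairs_j[k];
        if (dead[i] || dead[j] || pop[i] != pop[j]) continue;
        double rr = 2.0 / theta[pop[i]];
        rate.push_back(rr); etype.push_back(k); total += rr;
      }
      for (int e = 0; e < nmig; ++e) {  // backward migration
        if (mrate[e] <= 0.0) continue;
        if (!alive(mdonor[e], t, parent, tau) ||
            !alive(mrecip[e], t, parent, tau)) continue;
        double rr = 4.0 * mrate[e] / theta[mrecip[e]];
        for (int l = 0; l < 3; ++l) {
          if (dead[l] || pop[l] != mrecip[e]) continue;
          rate.push_back(rr); etype.push_back(100 + 10 * e + l); total += rr;
        }
      }

      if (total <= 0.0) { t = tb; continue; }
      double tnew = t + R::exp_rand() / total;
      if (tnew >= tb) { t = tb; continue; }
      t = tnew;

      double u = unif_rand() * total;
      size_t pick = 0;
      for (; pick + 1 < rate.size(); ++pick) {
        u -= rate[pick];
        if (u <= 0.0) break;
      }
      int ev = etype[pick];
      if (ev < 100) {  // coalescence
        int i = pairs_i[ev], j = pairs_j[ev];
        dead[j] = true;  // lineage i becomes the ancestor
        --nlin;
        if (firstpair < 0) { firstpair = ev; t1 = t; }
        else t2 = t;
      } else {         // migration
        int e = (ev - 100) / 10, l = (ev - 100) % 10;
        pop[l] = mdonor[e];
      }
    }

    ++nG[firstpair];
    if (firstpair == 0 && t1 < taufocal) ++nG1a;
    if (record) {
      rec(r, 0) = firstpair + 1;
      rec(r, 1) = t1;
      rec(r, 2) = t2;
    }
  }

  List out = List::create(
      _["counts"] = IntegerVector::create(_["p12"] = nG[0], _["p13"] = nG[1],
                                          _["p23"] = nG[2],
                                          _["p12a"] = nG1a));
  if (record) out["record"] = rec;
  return out;
}
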