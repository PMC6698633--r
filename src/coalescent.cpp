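#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Structured coalescent with demes, instantaneous merges, size/growth/migration
// changes, exponential growth within demes, and infinite-sites mutation.
//
// Conventions (haploid time scale): sizes are numbers of gene copies N; a pair
// of lineages in a deme of size N coalesces at rate 1/N per generation, so k
// lineages coalesce at rate k(k-1)/(2N). Backward in time a deme growing
// forward at rate g shrinks as N(t) = N(0) * exp(-g t). Mutations fall on
// branches as Poisson(mu_locus * branch length) and each creates a new
// biallelic site (infinite sites).
//
// Events matrix rows: time, type, a, b, value with demes 1-based.
//   type 0: merge  -- all lineages of deme a move to deme b, deme a retired
//   type 1: size   -- deme a size set to value at that time
//   type 2: growth -- deme a growth rate set to value
//   type 3: migmat -- migration rate a -> b set to value (b == 0: whole row)
//
// All randomness comes from R's RNG (unif_rand / exp_rand / R::rpois) so
// set.seed() in R makes results reproducible.

static inline int rand_int(int k) {
  int v = (int)(unif_rand() * k);
  return (v >= k) ? (k - 1) : v;
}

// [[Rcpp::export]]
List coalsim_cpp(NumericVector sizes, NumericVector growth, NumericMatrix mig,
                 IntegerVector samples, NumericMatrix events,
                 NumericVector mu_loci) {
  const int D = sizes.size();
  const int n = sum(samples);
  if (n < 2) stop("need at least 2 sampled lineages in total");
  const int n_loci = mu_loci.size();
  const int n_nodes = 2 * n - 1;
  List out(n_loci);

  for (int locus = 0; locus < n_loci; ++locus) {
    // reset mutable state per locus
    std::vector<double> N(sizes.begin(), sizes.end());
    std::vector<double> g(growth.begin(), growth.end());
    NumericMatrix M(clone(mig));
    std::vector<bool> alive(D, true);
    std::vector<std::vector<int> > pool(D);   // lineage node ids per deme
    int tip = 0;
    for (int d = 0; d < D; ++d)
      for (int s = 0; s < samples[d]; ++s) pool[d].push_back(tip++);
    std::vector<double> node_time(n_nodes, 0.0);
    std::vector<int> parent(n_nodes, -1);
    std::vector<int> child1(n_nodes, -1), child2(n_nodes, -1);
    int next_node = n;
    int n_active = n;
    double t = 0.0;
    int ei = 0;
    const int n_ev = events.nrow();
    long guard = 0;

    while (n_active > 1) {
      if (++guard > 100000000L) stop("coalescent simulation did not terminate");
      // candidate waiting times from current state
      double dt_best = R_PosInf;
      int what = -1, deme_co = -1;       // 0 coalesce, 1 migrate
      for (int d = 0; d < D; ++d) {
        int k = pool[d].size();
        if (k < 2) continue;
        double rate0 = (double)k * (k - 1) / (2.0 * N[d]);
        double s;
        if (g[d] == 0.0) {
          s = exp_rand() / rate0;
        } else {
          double arg = 1.0 + g[d] * exp_rand() / rate0;
          s = (arg <= 0.0) ? R_PosInf : std::log(arg) / g[d];
        }
        if (s < dt_best) { dt_best = s; what = 0; deme_co = d; }
      }
      double mig_tot = 0.0;
      for (int d = 0; d < D; ++d) {
        if (pool[d].empty()) continue;
        double row = 0.0;
        for (int e = 0; e < D; ++e) if (e != d && alive[e]) row += M(d, e);
        mig_tot += pool[d].size() * row;
      }
      if (mig_tot > 0.0) {
        double s = exp_rand() / mig_tot;
        if (s < dt_best) { dt_best = s; what = 1; }
      }
      double t_ev = (ei < n_ev) ? events(ei, 0) : R_PosInf;

      if (t + dt_best >= t_ev) {
        if (!R_finite(t_ev)) stop("lineages can never coalesce: disconnected demes with zero migration and no merge events");
        double delta = t_ev - t;
        for (int d = 0; d < D; ++d) if (g[d] != 0.0) N[d] *= std::exp(-g[d] * delta);
        t = t_ev;
        while (ei < n_ev && events(ei, 0) <= t) {
          int type = (int)events(ei, 1);
          int a = (int)events(ei, 2) - 1;
          int b = (int)events(ei, 3) - 1;
          double val = events(ei, 4);
          if (type == 0) {
            for (size_t j = 0; j < pool[a].size(); ++j) pool[b].push_back(pool[a][j]);
            pool[a].clear();
            alive[a] = false;
            for (int e = 0; e < D; ++e) { M(a, e) = 0.0; M(e, a) = 0.0; }
          } else if (type == 1) {
            N[a] = val;
          } else if (type == 2) {
            g[a] = val;
          } else if (type == 3) {
            if (b < 0) { for (int e = 0; e < D; ++e) if (e != a) M(a, e) = val; }
            else M(a, b) = val;
          }
          ++ei;
        }
        continue;
      }

      for (int d = 0; d < D; ++d) if (g[d] != 0.0) N[d] *= std::exp(-g[d] * dt_best);
      t += dt_best;
      if (what == 0) {
        std::vector<int> &P = pool[deme_co];
        int k = P.size();
        int i = rand_int(k);
        int j = rand_int(k - 1);
        if (j >= i) ++j;
        int node = next_node++;
        node_time[node] = t;
        parent[P[i]] = node; parent[P[j]] = node;
        child1[node] = P[i]; child2[node] = P[j];
        int hi2 = std::max(i, j), lo2 = std::min(i, j);
        P[hi2] = P.back(); P.pop_back();
        P[lo2] = node;
        --n_active;
      } else {
        // choose source deme weighted by k_d * rowsum
        double u = unif_rand() * mig_tot, acc = 0.0;
        int src = -1;
        for (int d = 0; d < D && src < 0; ++d) {
          if (pool[d].empty()) continue;
          double row = 0.0;
          for (int e = 0; e < D; ++e) if (e != d && alive[e]) row += M(d, e);
          acc += pool[d].size() * row;
          if (u <= acc) src = d;
        }
        if (src < 0) src = D - 1;
        double row = 0.0;
        for (int e = 0; e < D; ++e) if (e != src && alive[e]) row += M(src, e);
        double u2 = unif_rand() * row, acc2 = 0.0;
        int dst = -1;
        for (int e = 0; e < D && dst < 0; ++e) {
          if (e == src || !alive[e]) continue;
          acc2 += M(src, e);
          if (u2 <= acc2) dst = e;
        }
        if (dst < 0) { for (int e = D - 1; e >= 0; --e) if (e != src && alive[e] && M(src, e) > 0) { dst = e; break; } }
        int i = rand_int(pool[src].size());
        int lin = pool[src][i];
        pool[src][i] = pool[src].back(); pool[src].pop_back();
        pool[dst].push_back(lin);
      }
    }

    // DFS intervals over tips for fast mutation painting
    int root = next_node - 1;
    std::vector<int> lo(n_nodes), hi(n_nodes), tip_order(n);
    {
      int cursor = 0;
      std::vector<int> stack2; stack2.push_back(root);
      std::vector<int> state(n_nodes, 0);
      while (!stack2.empty()) {
        int v = stack2.back();
        if (child1[v] < 0) { // tip
          lo[v] = cursor; hi[v] = cursor + 1; tip_order[cursor] = v; ++cursor;
          stack2.pop_back();
        } else if (state[v] == 0) {
          state[v] = 1; stack2.push_back(child1[v]);
        } else if (state[v] == 1) {
          state[v] = 2; stack2.push_back(child2[v]);
        } else {
          lo[v] = lo[child1[v]]; hi[v] = hi[child2[v]];
          stack2.pop_back();
        }
      }
    }

    // mutations
    double muL = mu_loci[locus];
    std::vector<int> mut_node;
    for (int v = 0; v < root; ++v) {
      double blen = node_time[parent[v]] - node_time[v];
      int m = (int)R::rpois(muL * blen);
      for (int s = 0; s < m; ++s) mut_node.push_back(v);
    }
    int S = mut_node.size();
    IntegerMatrix G(n, S);
    NumericVector pos(S);
    for (int s = 0; s < S; ++s) {
      pos[s] = unif_rand();
      int v = mut_node[s];
      for (int q = lo[v]; q < hi[v]; ++q) G(tip_order[q], s) = 1;
    }
    out[locus] = List::create(_["G"] = G, _["pos"] = pos,
                              _["tmrca"] = node_time[root]);
  }
  return out;
}

// Raw ingredients of the per-clade summary panel computed jointly over loci.
// mats: list of n x S_l 0/1 integer matrices; grp: 1-based group index per row.
// Returns per-group S, pi (mean pairwise differences, absolute, summed over
// loci), multilocus haplotype count K, haplotype diversity Hd, and the matrix
// of mean between-group pairwise differences.
// [[Rcpp::export]]
List panel_raw_cpp(List mats, IntegerVector grp, int ngrp) {
  const int n = grp.size();
  std::vector<int> gsz(ngrp, 0);
  for (int i = 0; i < n; ++i) gsz[grp[i] - 1]++;
  NumericVector S(ngrp), pi(ngrp), K(ngrp), Hd(ngrp);
  NumericMatrix between(ngrp, ngrp);
  std::vector<std::string> key(n);
  for (int li = 0; li < mats.size(); ++li) {
    IntegerMatrix G = mats[li];
    const int Sl = G.ncol();
    for (int s = 0; s < Sl; ++s) {
      std::vector<int> cnt(ngrp, 0);
      for (int i = 0; i < n; ++i) cnt[grp[i] - 1] += G(i, s);
      for (int c = 0; c < ngrp; ++c) {
        if (cnt[c] > 0 && cnt[c] < gsz[c]) {
          S[c] += 1.0;
          pi[c] += (double)cnt[c] * (gsz[c] - cnt[c]) / (gsz[c] * (gsz[c] - 1.0) / 2.0);
        }
        for (int d = c + 1; d < ngrp; ++d) {
          double p1 = (double)cnt[c], p2 = (double)cnt[d];
          between(c, d) += (p1 * (gsz[d] - p2) + p2 * (gsz[c] - p1)) / ((double)gsz[c] * gsz[d]);
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      std::string &k = key[i];
      for (int s = 0; s < Sl; ++s) k.push_back(G(i, s) ? '1' : '0');
      k.push_back('|');
    }
  }
  for (int c = 0; c < ngrp; ++c) {
    std::map<std::string, int> tab;
    for (int i = 0; i < n; ++i) if (grp[i] - 1 == c) tab[key[i]]++;
    K[c] = tab.size();
    double sumf2 = 0.0;
    for (std::map<std::string, int>::iterator it = tab.begin(); it != tab.end(); ++it) {
      double f = (double)it->second / gsz[c];
      sumf2 += f * f;
    }
    Hd[c] = (gsz[c] > 1) ? (double)gsz[c] / (gsz[c] - 1.0) * (1.0 - sumf2) : 0.0;
  }
  return List::create(_["n"] = wrap(gsz), _["S"] = S, _["pi"] = pi,
                      _["K"] = K, _["Hd"] = Hd, _["between"] = between);
}

// Hamming distance matrix over equal-length strings (alignment rows).
// [[Rcpp::export]]
IntegerMatrix hamming_strings_cpp(std::vector<std::string> seqs) {
  const int n = seqs.size();
  IntegerMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const std::string &a = seqs[i], &b = seqs[j];
      int d = 0;
      for (size_t s = 0; s < a.size(); ++s) d += (a[s] != b[s]);
      D(i, j) = d; D(j, i) = d;
    }
  return D;
}
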