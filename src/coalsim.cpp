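#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Structured coalescent with demes, SPLIT (backward-time lineage merge) and
// SIZE_CHANGE events, continuous time in generations. Uses R's RNG so that
// set.seed() on the R side governs reproducibility.
//
// Event encoding (parallel vectors, sorted by time ascending):
//   type 0: split  -- move all lineages of deme `a` into deme `b`; if newN > 0
//                     also set the size of deme `b` to newN at that time
//   type 1: size   -- set size of deme `a` to newN
//
// Deme indices are 0-based. Sizes are diploid Ne: pairwise coalescence rate
// within a deme holding k lineages is k(k-1)/2 / (2N).

struct Lineage {
  double tstart;
  std::vector<int> leaves; // 0-based global leaf indices, kept sorted
};

// [[Rcpp::export(name = ".coal_simulate")]]
List coal_simulate(NumericVector sizes0,
                   NumericVector ev_time,
                   IntegerVector ev_type,
                   IntegerVector ev_a,
                   IntegerVector ev_b,
                   NumericVector ev_n,
                   IntegerVector nsam,
                   int nreps,
                   double mu_L,
                   bool keep_mutations) {
  const int npop = sizes0.size();
  int ntot = 0;
  for (int d = 0; d < npop; ++d) ntot += nsam[d];
  if (ntot < 2) stop("need at least 2 sampled lineages in total");

  // column-major strides over dims (nsam_d + 1)
  std::vector<double> stride(npop);
  double ncell_d = 1.0;
  for (int d = 0; d < npop; ++d) { stride[d] = ncell_d; ncell_d *= (nsam[d] + 1); }
  const R_xlen_t ncell = (R_xlen_t) ncell_d;
  NumericVector branch_sfs(ncell); // accumulated branch length per joint cell

  // fixed deme-of-origin per leaf
  std::vector<int> leaf_deme(ntot);
  {
    int idx = 0;
    for (int d = 0; d < npop; ++d)
      for (int i = 0; i < nsam[d]; ++i) leaf_deme[idx++] = d;
  }

  NumericVector tmrca(nreps), total_len(nreps);
  List mut_carriers; // flat list of integer vectors (1-based leaf indices)
  std::vector<int> mut_rep;
  if (keep_mutations) mut_carriers = List(0);
  std::vector<IntegerVector> mut_store;

  const int nev = ev_time.size();
  std::vector<int> cnt(npop);

  for (int rep = 0; rep < nreps; ++rep) {
    std::vector<std::vector<Lineage> > deme(npop);
    std::vector<double> N(sizes0.begin(), sizes0.end());
    {
      int idx = 0;
      for (int d = 0; d < npop; ++d) {
        deme[d].reserve(nsam[d] * 2);
        for (int i = 0; i < nsam[d]; ++i) {
          Lineage L; L.tstart = 0.0; L.leaves.assign(1, idx++);
          deme[d].push_back(L);
        }
      }
    }
    double t = 0.0, tot = 0.0;
    int nlin = ntot, e = 0;

    while (nlin > 1) {
      double R = 0.0;
      for (int d = 0; d < npop; ++d) {
        double k = (double) deme[d].size();
        if (k > 1 && N[d] > 0) R += k * (k - 1.0) / (4.0 * N[d]);
      }
      double tnext;
      bool have_wait = false;
      if (R > 0) { tnext = t + R::exp_rand() / R; have_wait = true; }
      else tnext = R_PosInf;

      if (e < nev && ev_time[e] <= tnext) {
        // apply event
        t = ev_time[e];
        int a = ev_a[e];
        if (ev_type[e] == 0) {
          int b = ev_b[e];
          if (!deme[a].empty()) {
            for (size_t i = 0; i < deme[a].size(); ++i)
              deme[b].push_back(deme[a][i]);
            deme[a].clear();
          }
          if (ev_n[e] > 0) N[b] = ev_n[e];
        } else {
          N[a] = ev_n[e];
        }
        ++e;
        continue;
      }
      if (!have_wait)
        stop("lineages stranded: no coalescence possible and no further events");
      t = tnext;
      // choose deme proportional to rate
      double u = R::unif_rand() * R, acc = 0.0;
      int dsel = -1;
      for (int d = 0; d < npop; ++d) {
        double k = (double) deme[d].size();
        if (k > 1 && N[d] > 0) {
          acc += k * (k - 1.0) / (4.0 * N[d]);
          if (u <= acc) { dsel = d; break; }
        }
      }
      if (dsel < 0) dsel = npop - 1;
      // choose distinct pair
      int k = (int) deme[dsel].size();
      int i = (int) (R::unif_rand() * k); if (i == k) i = k - 1;
      int j = (int) (R::unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      Lineage &A = deme[dsel][i], &B = deme[dsel][j];

      // close both child branches
      for (int c = 0; c < 2; ++c) {
        Lineage &L = (c == 0) ? A : B;
        double len = t - L.tstart;
        tot += len;
        std::fill(cnt.begin(), cnt.end(), 0);
        for (size_t q = 0; q < L.leaves.size(); ++q) cnt[leaf_deme[L.leaves[q]]]++;
        double idx = 0.0;
        for (int d = 0; d < npop; ++d) idx += cnt[d] * stride[d];
        branch_sfs[(R_xlen_t) idx] += len;
        if (keep_mutations && mu_L > 0 && len > 0) {
          int nm = (int) R::rpois(mu_L * len);
          for (int m = 0; m < nm; ++m) {
            IntegerVector carriers(L.leaves.size());
            for (size_t q = 0; q < L.leaves.size(); ++q)
              carriers[q] = L.leaves[q] + 1; // 1-based for R
            mut_store.push_back(carriers);
            mut_rep.push_back(rep + 1);
          }
        }
      }
      // merged lineage
      Lineage M; M.tstart = t;
      M.leaves.reserve(A.leaves.size() + B.leaves.size());
      std::merge(A.leaves.begin(), A.leaves.end(), B.leaves.begin(),
                 B.leaves.end(), std::back_inserter(M.leaves));
      deme[dsel].erase(deme[dsel].begin() + j);
      deme[dsel].erase(deme[dsel].begin() + i);
      deme[dsel].push_back(M);
      --nlin;
    }
    tmrca[rep] = t;
    total_len[rep] = tot;
  }

  List out = List::create(
    _["branch_sfs"] = branch_sfs,
    _["tmrca"] = tmrca,
    _["total_length"] = total_len);
  if (keep_mutations) {
    List carriers(mut_store.size());
    for (size_t q = 0; q < mut_store.size(); ++q) carriers[q] = mut_store[q];
    out["carriers"] = carriers;
    out["mut_rep"] = IntegerVector(mut_rep.begin(), mut_rep.end());
  }
  return out;
}
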