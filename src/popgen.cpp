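#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Compiled kernels for the microsatellite summary statistics that run inside
// the ABC reference-table and confidence-in-choice loops.  Genotypes arrive
// as two integer allele matrices (individuals x loci, NA = missing) plus a
// 1-based population index vector.

namespace {

// per-locus, per-population allele counts as a map state -> count
typedef std::unordered_map<int, int> CntMap;

void locus_counts(const IntegerMatrix& a1, const IntegerMatrix& a2,
                  const IntegerVector& pop, int npop, int l,
                  std::vector<CntMap>& cnt, std::vector<int>& tot) {
  cnt.assign(npop, CntMap());
  tot.assign(npop, 0);
  const int n = a1.nrow();
  for (int i = 0; i < n; ++i) {
    const int p = pop[i] - 1;
    const int x = a1(i, l), y = a2(i, l);
    if (x == NA_INTEGER || y == NA_INTEGER) continue;
    ++cnt[p][x]; ++cnt[p][y];
    tot[p] += 2;
  }
}

} // namespace

// Per-population mean number of alleles and mean Garza-Williamson
// M = k / (range + 1) over loci (allele states in repeat units).
// [[Rcpp::export(name = ".allele_number_m_cpp")]]
NumericMatrix allele_number_m_cpp(IntegerMatrix a1, IntegerMatrix a2,
                                  IntegerVector pop, int npop) {
  const int L = a1.ncol();
  NumericMatrix out(npop, 2);
  IntegerVector used(npop);
  std::vector<CntMap> cnt; std::vector<int> tot;
  for (int l = 0; l < L; ++l) {
    locus_counts(a1, a2, pop, npop, l, cnt, tot);
    for (int p = 0; p < npop; ++p) {
      if (tot[p] == 0) continue;
      int k = cnt[p].size(), lo = INT_MAX, hi = INT_MIN;
      for (auto& kv : cnt[p]) { lo = std::min(lo, kv.first); hi = std::max(hi, kv.first); }
      out(p, 0) += k;
      out(p, 1) += (double)k / (double)(hi - lo + 1);
      ++used[p];
    }
  }
  for (int p = 0; p < npop; ++p)
    if (used[p] > 0) { out(p, 0) /= used[p]; out(p, 1) /= used[p]; }
  return out;
}

// Weir & Cockerham (1984) variance components summed over alleles, per locus.
// Returns L x 3 matrix of (sum_a, sum_b, sum_c); with a single population the
// "a" (among-population) component is 0 and b, c use the r = 1 reduction.
// [[Rcpp::export(name = ".wc_components_cpp")]]
NumericMatrix wc_components_cpp(IntegerMatrix a1, IntegerMatrix a2,
                                IntegerVector pop, int npop) {
  const int n = a1.nrow(), L = a1.ncol();
  NumericMatrix out(L, 3);
  for (int l = 0; l < L; ++l) {
    // genotype-level counts per population: n_i (individuals), allele counts,
    // and heterozygote counts per allele
    std::vector<int> ni(npop, 0);
    std::vector<CntMap> ac(npop), het(npop);
    for (int i = 0; i < n; ++i) {
      const int p = pop[i] - 1;
      const int x = a1(i, l), y = a2(i, l);
      if (x == NA_INTEGER || y == NA_INTEGER) continue;
      ++ni[p];
      ++ac[p][x]; ++ac[p][y];
      if (x != y) { ++het[p][x]; ++het[p][y]; }
    }
    // populations with data at this locus
    std::vector<int> pops;
    for (int p = 0; p < npop; ++p) if (ni[p] > 0) pops.push_back(p);
    const int r = pops.size();
    if (r == 0) { out(l, 0) = out(l, 1) = out(l, 2) = NA_REAL; continue; }
    // allele universe at this locus
    CntMap uni;
    for (int p : pops) for (auto& kv : ac[p]) uni[kv.first] += kv.second;
    if (uni.size() < 2) { out(l, 0) = out(l, 1) = out(l, 2) = NA_REAL; continue; }
    double nbar = 0.0, nsum = 0.0, nsq = 0.0;
    for (int p : pops) { nbar += ni[p]; nsq += (double)ni[p] * ni[p]; }
    nsum = nbar; nbar /= r;
    double suma = 0.0, sumb = 0.0, sumc = 0.0;
    if (r == 1) {
      const int p = pops[0];
      const double nn = ni[p];
      if (nn < 2) { out(l, 0) = out(l, 1) = out(l, 2) = NA_REAL; continue; }
      for (auto& kv : uni) {
        const int al = kv.first;
        const double pa = ac[p].count(al) ? ac[p][al] / (2.0 * nn) : 0.0;
        const double hb = het[p].count(al) ? het[p][al] / nn : 0.0;
        sumb += nn / (nn - 1.0) * (pa * (1.0 - pa) - (2.0 * nn - 1.0) / (4.0 * nn) * hb);
        sumc += hb / 2.0;
      }
    } else {
      const double nc = (nsum - nsq / nsum) / (r - 1.0);
      for (auto& kv : uni) {
        const int al = kv.first;
        double pbar = 0.0, hbar = 0.0;
        std::vector<double> pi(r);
        for (int q = 0; q < r; ++q) {
          const int p = pops[q];
          pi[q] = ac[p].count(al) ? ac[p][al] / (2.0 * ni[p]) : 0.0;
          pbar += ni[p] * pi[q];
          hbar += het[p].count(al) ? (double)het[p][al] : 0.0;
        }
        pbar /= nsum; hbar /= nsum;
        double s2 = 0.0;
        for (int q = 0; q < r; ++q)
          s2 += ni[pops[q]] * (pi[q] - pbar) * (pi[q] - pbar);
        s2 /= (r - 1.0) * nbar;
        const double pq = pbar * (1.0 - pbar);
        const double a = nbar / nc *
          (s2 - 1.0 / (nbar - 1.0) * (pq - (r - 1.0) / r * s2 - hbar / 4.0));
        const double b = nbar / (nbar - 1.0) *
          (pq - (r - 1.0) / r * s2 - (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
        const double c = hbar / 2.0;
        suma += a; sumb += b; sumc += c;
      }
    }
    out(l, 0) = suma; out(l, 1) = sumb; out(l, 2) = sumc;
  }
  return out;
}

// Multilocus pairwise Weir-Cockerham F_ST (ratio of summed components).
// [[Rcpp::export(name = ".pairwise_fst_cpp")]]
NumericMatrix pairwise_fst_cpp(IntegerMatrix a1, IntegerMatrix a2,
                               IntegerVector pop, int npop) {
  const int n = a1.nrow(), L = a1.ncol();
  NumericMatrix out(npop, npop);
  for (int p = 0; p < npop; ++p)
    for (int q = p + 1; q < npop; ++q) {
      // subset individuals of pops p, q
      std::vector<int> idx; IntegerVector sub;
      for (int i = 0; i < n; ++i)
        if (pop[i] == p + 1 || pop[i] == q + 1) idx.push_back(i);
      IntegerMatrix b1((int)idx.size(), L), b2((int)idx.size(), L);
      IntegerVector pp((int)idx.size());
      for (size_t k = 0; k < idx.size(); ++k) {
        pp[k] = (pop[idx[k]] == p + 1) ? 1 : 2;
        for (int l = 0; l < L; ++l) { b1(k, l) = a1(idx[k], l); b2(k, l) = a2(idx[k], l); }
      }
      NumericMatrix comp = wc_components_cpp(b1, b2, pp, 2);
      double sa = 0.0, st = 0.0;
      for (int l = 0; l < L; ++l) {
        if (NumericVector::is_na(comp(l, 0))) continue;
        sa += comp(l, 0);
        st += comp(l, 0) + comp(l, 1) + comp(l, 2);
      }
      const double fst = (st != 0.0) ? sa / st : NA_REAL;
      out(p, q) = fst; out(q, p) = fst;
    }
  return out;
}

// Rannala-Mountain mean individual assignment log-likelihoods for all ordered
// population pairs (row = population of origin, column = reference population;
// leave-one-out on the diagonal).  Dirichlet(1/k) prior with k = number of
// distinct alleles at the locus in the whole data set.
// [[Rcpp::export(name = ".assign_loglik_cpp")]]
NumericMatrix assign_loglik_cpp(IntegerMatrix a1, IntegerMatrix a2,
                                IntegerVector pop, int npop) {
  const int n = a1.nrow(), L = a1.ncol();
  NumericMatrix sum(npop, npop);
  IntegerMatrix cntind(npop, npop);
  std::vector<std::vector<CntMap>> ac(L, std::vector<CntMap>(npop));
  std::vector<std::vector<int>> tot(L, std::vector<int>(npop, 0));
  std::vector<double> kl(L);
  for (int l = 0; l < L; ++l) {
    std::vector<CntMap> c; std::vector<int> t;
    locus_counts(a1, a2, pop, npop, l, c, t);
    ac[l] = c; tot[l] = t;
    CntMap uni;
    for (int p = 0; p < npop; ++p) for (auto& kv : c[p]) uni[kv.first] += 1;
    kl[l] = (double)uni.size();
  }
  // per individual x reference pop log-likelihood, averaged within origin pop
  NumericMatrix acc(npop, npop);
  IntegerMatrix nind(npop, npop);
  for (int i = 0; i < n; ++i) {
    const int o = pop[i] - 1;
    for (int j = 0; j < npop; ++j) {
      double ll = 0.0; bool any = false;
      for (int l = 0; l < L; ++l) {
        const int x = a1(i, l), y = a2(i, l);
        if (x == NA_INTEGER || y == NA_INTEGER) continue;
        if (tot[l][j] == 0 && o != j) continue;
        const double pri = 1.0 / kl[l];
        double nx = ac[l][j].count(x) ? ac[l][j][x] : 0.0;
        double ny = ac[l][j].count(y) ? ac[l][j][y] : 0.0;
        double N = tot[l][j];
        if (o == j) {  // leave this individual's gene copies out
          nx -= (x == y) ? 2.0 : 1.0;
          if (x != y) ny -= 1.0;
          N -= 2.0;
        }
        const double denom = N + 1.0;
        if (x == y) {
          const double px = (nx + pri) / denom;
          ll += 2.0 * std::log(px);
        } else {
          const double px = (nx + pri) / denom;
          const double py = (ny + pri) / denom;
          ll += std::log(2.0 * px * py);
        }
        any = true;
      }
      if (any) { acc(o, j) += ll; ++nind(o, j); }
    }
  }
  for (int o = 0; o < npop; ++o)
    for (int j = 0; j < npop; ++j)
      acc(o, j) = nind(o, j) > 0 ? acc(o, j) / nind(o, j) : NA_REAL;
  return acc;
}

// Per-population mean unbiased genic diversity (Nei 1987) and mean sample
// variance of allele size, over loci.
// [[Rcpp::export(name = ".gendiv_sizevar_cpp")]]
NumericMatrix gendiv_sizevar_cpp(IntegerMatrix a1, IntegerMatrix a2,
                                 IntegerVector pop, int npop) {
  const int L = a1.ncol();
  NumericMatrix out(npop, 2);
  IntegerVector u1(npop), u2(npop);
  std::vector<CntMap> cnt; std::vector<int> tot;
  for (int l = 0; l < L; ++l) {
    locus_counts(a1, a2, pop, npop, l, cnt, tot);
    for (int p = 0; p < npop; ++p) {
      const double N = tot[p];
      if (N < 2) continue;
      double ssq = 0.0, mean = 0.0, m2 = 0.0;
      for (auto& kv : cnt[p]) {
        const double f = kv.second / N;
        ssq += f * f;
        mean += kv.first * (double)kv.second;
        m2 += (double)kv.first * kv.first * (double)kv.second;
      }
      mean /= N; m2 /= N;
      out(p, 0) += N / (N - 1.0) * (1.0 - ssq);
      ++u1[p];
      out(p, 1) += (m2 - mean * mean) * N / (N - 1.0);
      ++u2[p];
    }
  }
  for (int p = 0; p < npop; ++p) {
    out(p, 0) = u1[p] > 0 ? out(p, 0) / u1[p] : NA_REAL;
    out(p, 1) = u2[p] > 0 ? out(p, 1) / u2[p] : NA_REAL;
  }
  return out;
}

// Chakraborty & Jin shared allele distance between populations:
// DAS = 1 - mean over cross-population individual pairs and loci of the
// proportion of alleles shared (0, 0.5 or 1 per diploid genotype pair).
// [[Rcpp::export(name = ".das_cpp")]]
NumericMatrix das_cpp(IntegerMatrix a1, IntegerMatrix a2,
                      IntegerVector pop, int npop) {
  const int n = a1.nrow(), L = a1.ncol();
  NumericMatrix out(npop, npop);
  for (int p = 0; p < npop; ++p)
    for (int q = p + 1; q < npop; ++q) {
      double s = 0.0; long cnt = 0;
      for (int i = 0; i < n; ++i) {
        if (pop[i] != p + 1) continue;
        for (int j = 0; j < n; ++j) {
          if (pop[j] != q + 1) continue;
          for (int l = 0; l < L; ++l) {
            const int x1 = a1(i, l), x2 = a2(i, l);
            const int y1 = a1(j, l), y2 = a2(j, l);
            if (x1 == NA_INTEGER || y1 == NA_INTEGER ||
                x2 == NA_INTEGER || y2 == NA_INTEGER) continue;
            // shared alleles between two diploid genotypes (bipartite match)
            int sh;
            if (x1 == x2) {
              sh = (y1 == x1) + (y2 == x1);
            } else if (y1 == y2) {
              sh = (x1 == y1) + (x2 == y1);
            } else {
              sh = ((x1 == y1 || x1 == y2) ? 1 : 0) + ((x2 == y1 || x2 == y2) ? 1 : 0);
            }
            s += sh / 2.0;
            ++cnt;
          }
        }
      }
      const double d = cnt > 0 ? 1.0 - s / cnt : NA_REAL;
      out(p, q) = d; out(q, p) = d;
    }
  return out;
}
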