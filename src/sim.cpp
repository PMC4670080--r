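// Forward pedigree simulator for admixed cohorts under pulse-migration schedules.
// Generations are indexed 1 (sampled) .. T0 (founding); all founders are migrants.
// Meiosis: Poisson(L in Morgans) crossovers at uniform positions, fair-coin start,
// no interference. Monogamous random pairs re-drawn each generation.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Hap {
  std::vector<double> ends;  // tract end positions, cM; last == L
  std::vector<int> anc;      // 1-based ancestry codes
};

Hap pure_hap(double L, int src) {
  Hap h;
  h.ends.push_back(L);
  h.anc.push_back(src);
  return h;
}

// gamete from a parent's two haplotypes
Hap meiosis(const Hap& h1, const Hap& h2, double L) {
  int nco = (int) R::rpois(L / 100.0);
  std::vector<double> xo(nco);
  for (int i = 0; i < nco; ++i) xo[i] = R::runif(0.0, L);
  std::sort(xo.begin(), xo.end());
  int cur = (R::unif_rand() < 0.5) ? 0 : 1;
  const Hap* hp[2] = { &h1, &h2 };
  Hap out;
  out.ends.reserve(h1.ends.size() + h2.ends.size() + nco);
  out.anc.reserve(out.ends.capacity());
  double s0 = 0.0;
  for (int seg = 0; seg <= nco; ++seg) {
    double e0 = (seg < nco) ? xo[seg] : L;
    if (e0 > s0) {
      const Hap& h = *hp[cur];
      size_t k = 0;
      while (k < h.ends.size() && h.ends[k] <= s0) ++k;
      while (k < h.ends.size() && s0 < e0) {
        double e = std::min(h.ends[k], e0);
        int a = h.anc[k];
        if (!out.anc.empty() && out.anc.back() == a) out.ends.back() = e;
        else { out.ends.push_back(e); out.anc.push_back(a); }
        s0 = e;
        ++k;
      }
      s0 = e0;
    }
    cur = 1 - cur;
  }
  if (out.ends.empty()) { out.ends.push_back(L); out.anc.push_back(hp[1 - cur]->anc[0]); }
  out.ends.back() = L;  // guard against fp drift
  return out;
}

int draw_source(const std::vector<double>& w) {
  double tot = 0.0;
  for (double x : w) tot += x;
  double u = R::unif_rand() * tot, c = 0.0;
  for (size_t i = 0; i < w.size(); ++i) { c += w[i]; if (u <= c) return (int)(i + 1); }
  return (int) w.size();
}

}  // namespace

// sched: T0 x P migration matrix, row t = replacement fractions at generation t
// (row 1 all zero, row T0 sums to 1). Returns per-haplotype true ancestry tracts
// for the n_ind generation-1 individuals (2 haplotypes each).
// [[Rcpp::export]]
List simulate_pedigree_cpp(NumericMatrix sched, NumericVector chrom_cM,
                           int n_ind, int n_ped) {
  const int T0 = sched.nrow(), P = sched.ncol(), C = chrom_cM.size();
  if (T0 < 2) stop("founding generation must be >= 2");
  if (n_ind < 1) stop("n_ind must be >= 1");
  for (int c = 0; c < C; ++c)
    if (!(chrom_cM[c] > 0)) stop("chromosome lengths must be positive");
  std::vector<double> M(T0 + 1, 0.0);
  std::vector<std::vector<double>> mrow(T0 + 1, std::vector<double>(P));
  for (int t = 1; t <= T0; ++t) {
    double s = 0.0;
    for (int p = 0; p < P; ++p) { mrow[t][p] = sched(t - 1, p); s += mrow[t][p]; }
    M[t] = s;
  }

  // --- pedigree: migrant status/source or parent pair, per generation ---
  // gen T0: n_ped founders (all migrants). gens T0-1..2: n_ped individuals.
  // gen 1: n_ind individuals (never migrants).
  std::vector<std::vector<int>> mig_src(T0 + 1);   // 0 = non-migrant, else source
  std::vector<std::vector<int>> par1(T0 + 1), par2(T0 + 1);
  for (int t = T0; t >= 1; --t) {
    int nt = (t == 1) ? n_ind : n_ped;
    mig_src[t].assign(nt, 0);
    if (t == T0) {
      for (int i = 0; i < nt; ++i) mig_src[t][i] = draw_source(mrow[T0]);
      continue;
    }
    int np = n_ped;
    // random pairing of generation t+1 (Fisher-Yates on R's RNG)
    std::vector<int> perm(np);
    for (int i = 0; i < np; ++i) perm[i] = i;
    for (int i = np - 1; i > 0; --i) {
      int j = (int) std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    int npairs = np / 2;
    par1[t].assign(nt, -1); par2[t].assign(nt, -1);
    for (int i = 0; i < nt; ++i) {
      if (t > 1 && R::unif_rand() < M[t]) {
        mig_src[t][i] = draw_source(mrow[t]);
      } else {
        int k = (int) std::floor(R::unif_rand() * npairs);
        if (k >= npairs) k = npairs - 1;
        par1[t][i] = perm[2 * k];
        par2[t][i] = perm[2 * k + 1];
      }
    }
  }

  // --- prune to ancestors of the sample ---
  std::vector<std::vector<char>> need(T0 + 1);
  need[1].assign(n_ind, 1);
  for (int t = 1; t < T0; ++t) {
    int ntup = (t + 1 == T0) ? n_ped : n_ped;
    need[t + 1].assign(ntup, 0);
    int nt = (t == 1) ? n_ind : n_ped;
    for (int i = 0; i < nt; ++i) {
      if (!need[t][i] || mig_src[t][i] != 0) continue;
      need[t + 1][par1[t][i]] = 1;
      need[t + 1][par2[t][i]] = 1;
    }
  }

  // --- per-chromosome transmission ---
  std::vector<int> out_hap, out_chr, out_anc;
  std::vector<double> out_start, out_end;
  for (int c = 0; c < C; ++c) {
    double L = chrom_cM[c];
    std::vector<Hap> upA(n_ped), upB(n_ped);  // generation t+1
    for (int i = 0; i < n_ped; ++i) {
      if (need[T0][i]) { upA[i] = pure_hap(L, mig_src[T0][i]); upB[i] = upA[i]; }
    }
    for (int t = T0 - 1; t >= 1; --t) {
      int nt = (t == 1) ? n_ind : n_ped;
      std::vector<Hap> curA(nt), curB(nt);
      for (int i = 0; i < nt; ++i) {
        if (!need[t][i]) continue;
        if (mig_src[t][i] != 0) {
          curA[i] = pure_hap(L, mig_src[t][i]);
          curB[i] = curA[i];
        } else {
          int a = par1[t][i], b = par2[t][i];
          curA[i] = meiosis(upA[a], upB[a], L);
          curB[i] = meiosis(upA[b], upB[b], L);
        }
      }
      upA.swap(curA); upB.swap(curB);
    }
    for (int i = 0; i < n_ind; ++i) {
      for (int which = 0; which < 2; ++which) {
        const Hap& h = which ? upB[i] : upA[i];
        double s0 = 0.0;
        for (size_t k = 0; k < h.ends.size(); ++k) {
          out_hap.push_back(2 * i + which + 1);
          out_chr.push_back(c + 1);
          out_start.push_back(s0);
          out_end.push_back(h.ends[k]);
          out_anc.push_back(h.anc[k]);
          s0 = h.ends[k];
        }
      }
    }
  }
  return List::create(_["hap"] = out_hap, _["chrom"] = out_chr,
                      _["start"] = out_start, _["end"] = out_end,
                      _["anc"] = out_anc);
}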