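#include <Rcpp.h>
using namespace Rcpp;

// Seed-and-extend unphased IBD detection for one sample pair on one
// chromosome. A candidate run is a maximal marker window containing at
// most max_hom_mismatch opposite-homozygote genotype markers; a run is
// reported only if some haplotype pairing of the two samples matches
// exactly over >= word_size consecutive markers inside it (the seed).
// Heterozygous genotype mismatches never break a run.
//
// a1,a2,b1,b2: 0/1 haplotype alleles of samples A and B.
// Returns an integer matrix with columns (start, end) of 1-based marker
// indices of runs that contain a seed.
// [[Rcpp::export]]
IntegerMatrix pair_seed_runs(IntegerVector a1, IntegerVector a2,
                             IntegerVector b1, IntegerVector b2,
                             int word_size, int max_hom_mismatch) {
  const int m = a1.size();
  std::vector<int> opp;   // indices of opposite-homozygote markers
  opp.reserve(64);
  for (int i = 0; i < m; ++i) {
    int ga = a1[i] + a2[i], gb = b1[i] + b2[i];
    if ((ga == 0 && gb == 2) || (ga == 2 && gb == 0)) opp.push_back(i);
  }

  // candidate maximal windows with <= k opposite homozygotes
  std::vector<std::pair<int,int>> runs;
  const int k = max_hom_mismatch;
  const int nopp = (int) opp.size();
  if (nopp <= k) {
    runs.emplace_back(0, m - 1);
  } else {
    // window skipping opp[i..i+k-1]; bounded by opp[i-1] and opp[i+k]
    for (int i = 0; i <= nopp - k; ++i) {
      int lo = (i == 0) ? 0 : opp[i - 1] + 1;
      int hi = (i + k == nopp) ? m - 1 : opp[i + k] - 1;
      if (hi >= lo) runs.emplace_back(lo, hi);
    }
  }

  // seed check per run: longest exact agreement streak per hap pairing
  std::vector<std::pair<int,int>> out;
  for (auto &r : runs) {
    bool seeded = false;
    const IntegerVector *ha[2] = { &a1, &a2 };
    const IntegerVector *hb[2] = { &b1, &b2 };
    for (int x = 0; x < 2 && !seeded; ++x)
      for (int y = 0; y < 2 && !seeded; ++y) {
        int streak = 0;
        for (int i = r.first; i <= r.second; ++i) {
          streak = ((*ha[x])[i] == (*hb[y])[i]) ? streak + 1 : 0;
          if (streak >= word_size) { seeded = true; break; }
        }
      }
    if (seeded) out.push_back(r);
  }

  IntegerMatrix res((int) out.size(), 2);
  for (size_t i = 0; i < out.size(); ++i) {
    res(i, 0) = out[i].first + 1;
    res(i, 1) = out[i].second + 1;
  }
  return res;
}

// Batch driver: scan many pairs over all chromosomes in one call.
// alleles_t: m x (2 n_samples) matrix of 0/1 haplotype alleles (markers in
// rows so each haplotype is a contiguous column), sample i on columns
// 2i-1, 2i (1-based). ia/ib: 1-based sample indices per pair.
// chrom_start/chrom_end: 1-based first/last marker row per chromosome.
// Returns a list of integer vectors (pair, chrom, start, end) giving
// 1-based marker bounds of seeded runs; cM filtering happens in R.
// [[Rcpp::export]]
List detect_pairs_batch(IntegerMatrix alleles_t, IntegerVector ia,
                        IntegerVector ib, IntegerVector chrom_start,
                        IntegerVector chrom_end, int word_size,
                        int max_hom_mismatch) {
  std::vector<int> r_pair, r_chrom, r_start, r_end;
  const int npair = ia.size(), nchrom = chrom_start.size();
  const int m_all = alleles_t.nrow();
  const int *base = INTEGER(alleles_t);
  std::vector<int> opp;
  for (int p = 0; p < npair; ++p) {
    const int *a1 = base + (size_t) m_all * (2 * (ia[p] - 1));
    const int *a2 = a1 + m_all;
    const int *b1 = base + (size_t) m_all * (2 * (ib[p] - 1));
    const int *b2 = b1 + m_all;
    for (int c = 0; c < nchrom; ++c) {
      const int lo = chrom_start[c] - 1, hi = chrom_end[c] - 1;
      const int m = hi - lo + 1;
      opp.clear();
      for (int j = lo; j <= hi; ++j) {
        int ga = a1[j] + a2[j], gb = b1[j] + b2[j];
        if ((ga == 0 && gb == 2) || (ga == 2 && gb == 0))
          opp.push_back(j - lo);
      }
      std::vector<std::pair<int,int>> runs;
      const int k = max_hom_mismatch, nopp = (int) opp.size();
      if (nopp <= k) runs.emplace_back(0, m - 1);
      else for (int i = 0; i <= nopp - k; ++i) {
        int wlo = (i == 0) ? 0 : opp[i - 1] + 1;
        int whi = (i + k == nopp) ? m - 1 : opp[i + k] - 1;
        if (whi >= wlo) runs.emplace_back(wlo, whi);
      }
      const int *ha[2] = { a1, a2 }, *hb[2] = { b1, b2 };
      for (auto &r : runs) {
        if (r.second - r.first + 1 < word_size) continue;
        bool seeded = false;
        for (int x = 0; x < 2 && !seeded; ++x)
          for (int y = 0; y < 2 && !seeded; ++y) {
            int streak = 0;
            for (int j = lo + r.first; j <= lo + r.second; ++j) {
              streak = (ha[x][j] == hb[y][j]) ? streak + 1 : 0;
              if (streak >= word_size) { seeded = true; break; }
            }
          }
        if (seeded) {
          r_pair.push_back(p + 1);
          r_chrom.push_back(c + 1);
          r_start.push_back(lo + r.first + 1);
          r_end.push_back(lo + r.second + 1);
        }
      }
    }
  }
  return List::create(_["pair"] = wrap(r_pair), _["chrom"] = wrap(r_chrom),
                      _["start"] = wrap(r_start), _["end"] = wrap(r_end));
}

// Maximal opposite-homozygote-free runs (no seed requirement): the
// genotype-level extension limit, used by the locus-overlap path and by
// tests. Same return convention as pair_seed_runs.
// [[Rcpp::export]]
IntegerMatrix pair_clean_runs(IntegerVector ga, IntegerVector gb) {
  const int m = ga.size();
  std::vector<std::pair<int,int>> out;
  int start = 0;
  for (int i = 0; i <= m; ++i) {
    bool brk = (i == m);
    if (!brk) {
      int a = ga[i], b = gb[i];
      brk = (a == 0 && b == 2) || (a == 2 && b == 0);
    }
    if (brk) {
      if (i - 1 >= start) out.emplace_back(start, i - 1);
      start = i + 1;
    }
  }
  IntegerMatrix res((int) out.size(), 2);
  for (size_t i = 0; i < out.size(); ++i) {
    res(i, 0) = out[i].first + 1;
    res(i, 1) = out[i].second + 1;
  }
  return res;
}
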