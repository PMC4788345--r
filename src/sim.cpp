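#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Ancestry haplotype as a tract list: bp[i] is the right end (Morgans) of
// tract i, bp.back() == chromlen; anc[i] is 1 for source A, 0 for source B.
struct Hap {
  std::vector<double> bp;
  std::vector<int> anc;
};

static Hap pure_hap(int a, double chromlen) {
  Hap h;
  h.bp.push_back(chromlen);
  h.anc.push_back(a);
  return h;
}

static int anc_at(const Hap &h, double pos) {
  size_t i = 0;
  while (i + 1 < h.bp.size() && h.bp[i] <= pos) ++i;
  return h.anc[i];
}

static void push_tract(Hap &g, double end, int a) {
  if (!g.anc.empty() && g.anc.back() == a) {
    g.bp.back() = end;
  } else {
    g.bp.push_back(end);
    g.anc.push_back(a);
  }
}

// One meiosis: exactly one crossover at Uniform(0, chromlen), fair coin for
// the starting haplotype.
static Hap gamete(const Hap &h1, const Hap &h2, double chromlen) {
  const Hap *a = &h1, *b = &h2;
  if (R::unif_rand() < 0.5) std::swap(a, b);
  double u = R::unif_rand() * chromlen;
  Hap g;
  g.bp.reserve(a->bp.size() + b->bp.size());
  g.anc.reserve(a->bp.size() + b->bp.size());
  size_t ia = 0;
  while (ia + 1 < a->bp.size() && a->bp[ia] <= u) ++ia;
  for (size_t i = 0; i < ia; ++i) push_tract(g, a->bp[i], a->anc[i]);
  push_tract(g, u, a->anc[ia]);
  size_t ib = 0;
  while (ib + 1 < b->bp.size() && b->bp[ib] <= u) ++ib;
  for (size_t i = ib; i < b->bp.size(); ++i) push_tract(g, b->bp[i], b->anc[i]);
  return g;
}

typedef std::vector<Hap> Ind; // 2 * nchrom haplotypes: chrom c -> 2c, 2c+1

// dosage (0/1/2 copies of source A) at marker positions for one individual
static void dosage_at_markers(const Ind &ind, int nchrom,
                              const std::vector<double> &mpos, int nmark,
                              int *out) {
  for (int c = 0; c < nchrom; ++c) {
    const Hap &h1 = ind[2 * c], &h2 = ind[2 * c + 1];
    size_t i1 = 0, i2 = 0;
    for (int k = 0; k < nmark; ++k) {
      double p = mpos[k];
      while (i1 + 1 < h1.bp.size() && h1.bp[i1] <= p) ++i1;
      while (i2 + 1 < h2.bp.size() && h2.bp[i2] <= p) ++i2;
      out[c * nmark + k] = h1.anc[i1] + h2.anc[i2];
    }
  }
}

// per-haplotype ancestry at markers (for genotype emission)
static void hap_anc_at_markers(const Hap &h, const std::vector<double> &mpos,
                               int nmark, int *out) {
  size_t i = 0;
  for (int k = 0; k < nmark; ++k) {
    while (i + 1 < h.bp.size() && h.bp[i] <= mpos[k]) ++i;
    out[k] = h.anc[i];
  }
}

static double genome_avg_ancestry(const Ind &ind, int nchrom, double chromlen) {
  double tot = 0.0;
  for (int c = 0; c < nchrom; ++c) {
    for (int hh = 0; hh < 2; ++hh) {
      const Hap &h = ind[2 * c + hh];
      double prev = 0.0;
      for (size_t i = 0; i < h.bp.size(); ++i) {
        if (h.anc[i] == 1) tot += h.bp[i] - prev;
        prev = h.bp[i];
      }
    }
  }
  return tot / (2.0 * nchrom * chromlen);
}

// number of selected loci at which the individual carries one copy from each
// source (ancestry heterozygosity); sel loci given as (chrom index, position)
static int n_het_selected(const Ind &ind, const IntegerVector &sel_chrom,
                          const NumericVector &sel_pos) {
  int l = 0;
  for (int s = 0; s < sel_pos.size(); ++s) {
    int c = sel_chrom[s] - 1;
    int a = anc_at(ind[2 * c], sel_pos[s]) + anc_at(ind[2 * c + 1], sel_pos[s]);
    if (a == 1) ++l;
  }
  return l;
}

// [[Rcpp::export]]
List cpp_simulate_tracts(int N, int t, int nchrom, double chromlen, double m,
                         double s, IntegerVector sel_chrom,
                         NumericVector sel_pos, bool f1_founders, int nsample,
                         int nmark, bool record_series) {
  if (nsample > N) stop("sample size exceeds population size");
  std::vector<Ind> pop(N), newpop(N);
  for (int i = 0; i < N; ++i) {
    pop[i].resize(2 * nchrom);
    for (int c = 0; c < nchrom; ++c) {
      if (f1_founders) {
        pop[i][2 * c] = pure_hap(1, chromlen);
        pop[i][2 * c + 1] = pure_hap(0, chromlen);
      } else {
        int a = (i < N / 2) ? 1 : 0; // half pure A, half pure B
        pop[i][2 * c] = pure_hap(a, chromlen);
        pop[i][2 * c + 1] = pure_hap(a, chromlen);
      }
    }
  }

  std::vector<double> mpos(nmark);
  for (int k = 0; k < nmark; ++k)
    mpos[k] = (nmark == 1) ? 0.0 : chromlen * k / (nmark - 1.0);
  int L = nchrom * nmark;

  NumericMatrix series(record_series ? t + 1 : 0, 3);
  std::vector<int> dosbuf(L);
  std::vector<double> qsum(L);

  // per-generation population summaries (generation 0 = founders)
  auto record = [&](int gen) {
    std::fill(qsum.begin(), qsum.end(), 0.0);
    double hsum = 0.0, hsq = 0.0, het = 0.0;
    for (int i = 0; i < N; ++i) {
      double hbar = genome_avg_ancestry(pop[i], nchrom, chromlen);
      hsum += hbar;
      hsq += hbar * hbar;
      dosage_at_markers(pop[i], nchrom, mpos, nmark, dosbuf.data());
      for (int x = 0; x < L; ++x) {
        qsum[x] += dosbuf[x];
        if (dosbuf[x] == 1) het += 1.0;
      }
    }
    double mh = hsum / N;
    series(gen, 0) = hsq / N - mh * mh;
    double qm = 0.0, qv = 0.0;
    for (int x = 0; x < L; ++x) {
      double q = qsum[x] / (2.0 * N);
      qm += q;
      qv += q * q;
    }
    qm /= L;
    series(gen, 1) = qv / L - qm * qm;
    series(gen, 2) = het / ((double)N * L);
  };
  if (record_series) record(0);

  std::vector<double> cumw(N);
  for (int g = 1; g <= t; ++g) {
    bool selected = (s > 0.0 && sel_pos.size() > 0);
    double tot = 0.0;
    if (selected) {
      for (int i = 0; i < N; ++i) {
        int l = n_het_selected(pop[i], sel_chrom, sel_pos);
        tot += std::pow(1.0 - s, l);
        cumw[i] = tot;
      }
    }
    for (int i = 0; i < N; ++i) {
      if (m > 0.0 && R::unif_rand() < m) { // unadmixed immigrant
        int a = (R::unif_rand() < 0.5) ? 1 : 0;
        Ind im(2 * nchrom);
        for (int c = 0; c < 2 * nchrom; ++c) im[c] = pure_hap(a, chromlen);
        newpop[i] = im;
        continue;
      }
      int p1, p2;
      if (selected) {
        double u1 = R::unif_rand() * tot, u2 = R::unif_rand() * tot;
        p1 = std::lower_bound(cumw.begin(), cumw.end(), u1) - cumw.begin();
        p2 = std::lower_bound(cumw.begin(), cumw.end(), u2) - cumw.begin();
      } else {
        p1 = (int)(R::unif_rand() * N);
        p2 = (int)(R::unif_rand() * N);
        if (p1 >= N) p1 = N - 1;
        if (p2 >= N) p2 = N - 1;
      }
      Ind child(2 * nchrom);
      for (int c = 0; c < nchrom; ++c) {
        child[2 * c] = gamete(pop[p1][2 * c], pop[p1][2 * c + 1], chromlen);
        child[2 * c + 1] = gamete(pop[p2][2 * c], pop[p2][2 * c + 1], chromlen);
      }
      newpop[i] = child;
    }
    std::swap(pop, newpop);
    if (record_series) record(g);
    if (g % 50 == 0) Rcpp::checkUserInterrupt();
  }

  // population ancestry frequency at markers (all N individuals)
  std::fill(qsum.begin(), qsum.end(), 0.0);
  for (int i = 0; i < N; ++i) {
    dosage_at_markers(pop[i], nchrom, mpos, nmark, dosbuf.data());
    for (int x = 0; x < L; ++x) qsum[x] += dosbuf[x];
  }
  NumericVector q_true(L);
  for (int x = 0; x < L; ++x) q_true[x] = qsum[x] / (2.0 * N);

  // sample without replacement
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < nsample; ++i) {
    int j = i + (int)(R::unif_rand() * (N - i));
    if (j >= N) j = N - 1;
    std::swap(idx[i], idx[j]);
  }

  IntegerMatrix z(L, nsample), a1(L, nsample), a2(L, nsample);
  List tracts(nsample);
  for (int i = 0; i < nsample; ++i) {
    const Ind &ind = pop[idx[i]];
    dosage_at_markers(ind, nchrom, mpos, nmark, dosbuf.data());
    for (int x = 0; x < L; ++x) z(x, i) = dosbuf[x];
    List per_chrom(nchrom);
    for (int c = 0; c < nchrom; ++c) {
      hap_anc_at_markers(ind[2 * c], mpos, nmark, &a1(c * nmark, i));
      hap_anc_at_markers(ind[2 * c + 1], mpos, nmark, &a2(c * nmark, i));
      per_chrom[c] = List::create(
          _["h1_bp"] = NumericVector(ind[2 * c].bp.begin(), ind[2 * c].bp.end()),
          _["h1_anc"] = IntegerVector(ind[2 * c].anc.begin(), ind[2 * c].anc.end()),
          _["h2_bp"] = NumericVector(ind[2 * c + 1].bp.begin(), ind[2 * c + 1].bp.end()),
          _["h2_anc"] = IntegerVector(ind[2 * c + 1].anc.begin(), ind[2 * c + 1].anc.end()));
    }
    tracts[i] = per_chrom;
  }

  return List::create(_["z"] = z, _["hap1"] = a1, _["hap2"] = a2,
                      _["q_true"] = q_true, _["tracts"] = tracts,
                      _["series"] = series);
}
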