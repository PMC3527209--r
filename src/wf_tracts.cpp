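// Forward Wright-Fisher simulation of migrant-ancestry tracts.
//
// Chromosomes are breakpoint lists on a genetic map of `morgans` Morgans:
// per chromosome a vector of segment start positions (first = 0) and a
// parallel vector of ancestry labels (0 native, 1 migrant).  Each
// generation every one of N haploid offspring is formed by recombining two
// uniformly chosen parents with Poisson(morgans) crossovers at uniform
// map positions.  Migration either seeds the founding generation (pulse
// model: admixture g generations before sampling) or replaces offspring
// each generation with probability m (continuous model).
//
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Chrom {
  std::vector<double> start;  // segment starts, start[0] == 0
  std::vector<int> label;
};

static Chrom recombine(const Chrom &a, const Chrom &b, double morgans) {
  int ncx = (int) R::rpois(morgans);
  if (ncx == 0) return a;
  std::vector<double> cx(ncx);
  for (int i = 0; i < ncx; ++i) cx[i] = R::runif(0.0, morgans);
  std::sort(cx.begin(), cx.end());
  Chrom out;
  out.start.reserve(a.start.size() + b.start.size() + ncx);
  out.label.reserve(out.start.capacity());
  const Chrom *cur = &a, *oth = &b;
  double from = 0.0;
  size_t icx = 0;
  while (true) {
    double to = (icx < cx.size()) ? cx[icx] : morgans;
    // copy segments of *cur overlapping [from, to)
    for (size_t s = 0; s < cur->start.size(); ++s) {
      double seg_lo = cur->start[s];
      double seg_hi = (s + 1 < cur->start.size()) ? cur->start[s + 1]
                                                  : morgans;
      if (seg_hi <= from || seg_lo >= to) continue;
      double lo = std::max(seg_lo, from);
      int lab = cur->label[s];
      if (!out.label.empty() && out.label.back() == lab) continue;
      out.start.push_back(lo);
      out.label.push_back(lab);
    }
    if (icx >= cx.size()) break;
    from = cx[icx++];
    std::swap(cur, oth);
  }
  if (out.start.empty() || out.start[0] != 0.0) {
    // guard: ensure a leading segment (can only happen via fp edge cases)
    out.start.insert(out.start.begin(), 0.0);
    out.label.insert(out.label.begin(), a.label[0]);
  }
  return out;
}

// [[Rcpp::export(name = ".wf_tracts_cpp")]]
List wf_tracts_cpp(int N, double m, int g, double morgans, int n_sample,
                   bool pulse) {
  if (N < 2 || n_sample > N) stop("need 2 <= n_sample <= N");
  std::vector<Chrom> pop(N), nxt(N);
  Chrom native; native.start.push_back(0.0); native.label.push_back(0);
  Chrom migrant; migrant.start.push_back(0.0); migrant.label.push_back(1);
  for (int i = 0; i < N; ++i)
    pop[i] = (pulse && R::unif_rand() < m) ? migrant : native;
  for (int gen = 0; gen < g; ++gen) {
    for (int i = 0; i < N; ++i) {
      if (!pulse && R::unif_rand() < m) {
        nxt[i] = migrant;
        continue;
      }
      int p1 = (int) (R::unif_rand() * N);
      int p2 = (int) (R::unif_rand() * N);
      if (p1 >= N) p1 = N - 1;
      if (p2 >= N) p2 = N - 1;
      nxt[i] = recombine(pop[p1], pop[p2], morgans);
    }
    std::swap(pop, nxt);
    if (gen % 64 == 0) Rcpp::checkUserInterrupt();
  }
  // sample without replacement
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_sample; ++i) {
    int j = i + (int) (R::unif_rand() * (N - i));
    if (j >= N) j = N - 1;
    std::swap(idx[i], idx[j]);
  }
  List out(n_sample);
  for (int s = 0; s < n_sample; ++s) {
    const Chrom &c = pop[idx[s]];
    std::vector<double> ts, te;
    for (size_t k = 0; k < c.start.size(); ++k) {
      if (c.label[k] != 1) continue;
      double hi = (k + 1 < c.start.size()) ? c.start[k + 1] : morgans;
      ts.push_back(c.start[k]);
      te.push_back(hi);
    }
    NumericMatrix mat(ts.size(), 2);
    for (size_t k = 0; k < ts.size(); ++k) {
      mat(k, 0) = ts[k];
      mat(k, 1) = te[k];
    }
    colnames(mat) = CharacterVector::create("start", "end");
    out[s] = mat;
  }
  return out;
}
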