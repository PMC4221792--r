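// Dynamic-programming ensemble analyzer for the adaptive compressed
// depth-first search under the error-free sequencing-and-assembly model.
//
// State: (p, I, a_parent) = cell counts per genome in the node, capture
// state on entry, and the parent assembly size the allocation is based on.
// The value is the expected total nucleotides sequenced in the subtree
// rooted at the node plus the distribution of the capture state after the
// subtree completes, averaged over the multivariate-hypergeometric ensemble
// of all ways the node's cells can split into two halves.
//
// Assemblies saturate once coverage reaches M_u, so a_parent takes few
// distinct values; memo keys quantize it to 1 bp, which is lossless at the
// scales involved.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>

namespace {

struct Key {
  std::vector<int> p;
  int I;
  long long ap;
  bool operator==(const Key &o) const {
    return I == o.I && ap == o.ap && p == o.p;
  }
};

struct KeyHash {
  std::size_t operator()(const Key &k) const {
    std::size_t h = 1469598103934665603ull;
    for (int x : k.p) { h ^= (std::size_t)x; h *= 1099511628211ull; }
    h ^= (std::size_t)k.I; h *= 1099511628211ull;
    h ^= (std::size_t)k.ap; h *= 1099511628211ull;
    return h;
  }
};

struct Val {
  double Et;
  std::vector<double> P;
};

class EnsembleDP {
public:
  EnsembleDP(const std::vector<double> &g, double Mu, double Ml, double tau,
             double sf, int csum_min)
      : g_(g), s_((int)g.size()), npow_(1 << (int)g.size()), Mu_(Mu),
        Ml_(Ml), tau_(tau), sf_(sf), csum_min_(csum_min), nodes_(0) {
    // Pascal triangle in long double: exact for the binomials needed here
    int N = 2048;
    ch_.assign(N, std::vector<long double>());
  }

  long double choose(int n, int k) {
    if (k < 0 || k > n) return 0.0L;
    if ((int)ch_[n].size() == 0) {
      ch_[n].assign(n + 1, 0.0L);
      ch_[n][0] = 1.0L;
      for (int j = 1; j <= n; j++)
        ch_[n][j] = ch_[n][j - 1] * (long double)(n - j + 1) / (long double)j;
    }
    return ch_[n][k];
  }

  struct Sense {
    double t, c, suma;
    std::vector<double> a;
  };

  void oracle(const std::vector<int> &p, double ap, Sense &o) {
    int n = 0;
    for (int j = 0; j < s_; j++) n += p[j];
    double t = sf_ * Mu_ * ap;
    double tpc = t / n;
    o.a.assign(s_, 0.0);
    double cmin = R_PosInf, suma = 0.0;
    for (int j = 0; j < s_; j++) {
      if (p[j] > 0) {
        double cj = tpc * p[j] / g_[j];
        o.a[j] = (cj <= Mu_) ? g_[j] * cj / Mu_ : g_[j];
        if (cj < cmin) cmin = cj;
      }
      suma += o.a[j];
    }
    o.t = t;
    o.suma = suma;
    o.c = csum_min_ ? cmin : t / suma;
  }

  bool subsumed(const Sense &o, int I) const {
    if (o.c <= Ml_) return false;
    double x = 0.0;
    for (int j = 0; j < s_; j++)
      if (!((I >> j) & 1)) x += o.a[j];
    return tau_ - x / o.suma >= -1e-12;
  }

  // all v with 0 <= v_j <= p_j and sum v = ceil(n/2), with hypergeometric
  // weights
  void enumerate_divisions(const std::vector<int> &p,
                           std::vector<std::vector<int> > &vs,
                           std::vector<double> &pis) {
    int n = 0;
    for (int j = 0; j < s_; j++) n += p[j];
    int h = (n + 1) / 2;
    std::vector<int> v(s_, 0);
    long double den = choose(n, h);
    rec_div(p, v, 0, h, den, vs, pis);
  }

  void rec_div(const std::vector<int> &p, std::vector<int> &v, int j, int rem,
               long double den, std::vector<std::vector<int> > &vs,
               std::vector<double> &pis) {
    if (j == s_ - 1) {
      if (rem <= p[j]) {
        v[j] = rem;
        long double pi = 1.0L;
        for (int k = 0; k < s_; k++) pi *= choose(p[k], v[k]);
        vs.push_back(v);
        pis.push_back((double)(pi / den));
      }
      return;
    }
    int tail = 0;
    for (int k = j + 1; k < s_; k++) tail += p[k];
    int lo = rem - tail > 0 ? rem - tail : 0;
    int hi = rem < p[j] ? rem : p[j];
    for (int vj = lo; vj <= hi; vj++) {
      v[j] = vj;
      rec_div(p, v, j + 1, rem - vj, den, vs, pis);
    }
  }

  const Val &cost(const std::vector<int> &p, int I, double ap) {
    Key key{p, I, (long long)std::llround(ap)};
    auto it = memo_.find(key);
    if (it != memo_.end()) return it->second;
    nodes_++;

    Sense o;
    oracle(p, ap, o);
    Val val;
    val.Et = o.t;
    val.P.assign(npow_, 0.0);

    if (!subsumed(o, I)) {
      int n = 0;
      for (int j = 0; j < s_; j++) n += p[j];
      if (n == 1) {
        // leaf: repeat the allocation until coverage reaches 2 M_u
        double c = o.c;
        std::vector<double> a = o.a;
        int guard = 0;
        while (c < 2.0 * Mu_ && guard++ < 1000) {
          double suma = 0.0;
          for (int j = 0; j < s_; j++) suma += a[j];
          Sense l;
          oracle(p, suma, l);
          val.Et += l.t;
          c = l.c;
          a = l.a;
        }
        int k = 0;
        for (int j = 1; j < s_; j++)
          if (p[j] > p[k]) k = j;
        val.P[I | (1 << k)] = 1.0;
      } else {
        double apc = o.suma;
        std::vector<std::vector<int> > vs;
        std::vector<double> pis;
        enumerate_divisions(p, vs, pis);
        std::vector<double> Pp(npow_), Ppp(npow_);
        std::vector<int> w(s_);
        for (std::size_t d = 0; d < vs.size(); d++) {
          for (int j = 0; j < s_; j++) w[j] = p[j] - vs[d][j];
          double tacc = 0.0;
          std::fill(Pp.begin(), Pp.end(), 0.0);
          Pp[I] = 1.0;
          for (int half = 0; half < 2; half++) {
            const std::vector<int> &u = half == 0 ? vs[d] : w;
            std::fill(Ppp.begin(), Ppp.end(), 0.0);
            for (int b = 0; b < npow_; b++) {
              double q = Pp[b];
              if (q > 0.0) {
                const Val &child = cost(u, b, apc);
                tacc += q * child.Et;
                for (int k2 = 0; k2 < npow_; k2++)
                  Ppp[k2] += q * child.P[k2];
              }
            }
            Pp = Ppp;
          }
          val.Et += pis[d] * tacc;
          for (int k2 = 0; k2 < npow_; k2++) val.P[k2] += pis[d] * Pp[k2];
        }
      }
    } else {
      val.P[I] = 1.0;
    }
    auto res = memo_.emplace(std::move(key), std::move(val));
    return res.first->second;
  }

  // top level: root either sensed as one pool or split immediately
  void run(const std::vector<int> &p0, double a0, bool root_sensed,
           double &Et, std::vector<double> &P) {
    if (root_sensed) {
      const Val &v = cost(p0, 0, a0);
      Et = v.Et;
      P = v.P;
      return;
    }
    int n = 0;
    for (int j = 0; j < s_; j++) n += p0[j];
    if (n == 1) {
      const Val &v = cost(p0, 0, a0);
      Et = v.Et;
      P = v.P;
      return;
    }
    std::vector<std::vector<int> > vs;
    std::vector<double> pis;
    enumerate_divisions(p0, vs, pis);
    Et = 0.0;
    P.assign(npow_, 0.0);
    std::vector<double> Pp(npow_), Ppp(npow_);
    std::vector<int> w(s_);
    for (std::size_t d = 0; d < vs.size(); d++) {
      for (int j = 0; j < s_; j++) w[j] = p0[j] - vs[d][j];
      double tacc = 0.0;
      std::fill(Pp.begin(), Pp.end(), 0.0);
      Pp[0] = 1.0;
      for (int half = 0; half < 2; half++) {
        const std::vector<int> &u = half == 0 ? vs[d] : w;
        std::fill(Ppp.begin(), Ppp.end(), 0.0);
        for (int b = 0; b < npow_; b++) {
          double q = Pp[b];
          if (q > 0.0) {
            const Val &child = cost(u, b, a0);
            tacc += q * child.Et;
            for (int k2 = 0; k2 < npow_; k2++) Ppp[k2] += q * child.P[k2];
          }
        }
        Pp = Ppp;
      }
      Et += pis[d] * tacc;
      for (int k2 = 0; k2 < npow_; k2++) P[k2] += pis[d] * Pp[k2];
    }
  }

  long nodes() const { return nodes_; }

private:
  std::vector<double> g_;
  int s_, npow_;
  double Mu_, Ml_, tau_, sf_;
  int csum_min_;
  long nodes_;
  std::unordered_map<Key, Val, KeyHash> memo_;
  std::vector<std::vector<long double> > ch_;
};

}  // namespace

// [[Rcpp::export(name = ".ensemble_cost_cpp")]]
Rcpp::List ensemble_cost_cpp(Rcpp::IntegerVector p, Rcpp::NumericVector g,
                             double M_u, double M_l, double tau,
                             double safety_factor, double root_assembly,
                             bool root_sensed, bool coverage_min,
                             Rcpp::IntegerVector I0) {
  int s = g.size();
  if (s > 12)
    Rcpp::stop("ensemble analysis supports at most 12 distinct genomes");
  std::vector<int> pv(p.begin(), p.end());
  std::vector<double> gv(g.begin(), g.end());
  EnsembleDP dp(gv, M_u, M_l, tau, safety_factor, coverage_min ? 1 : 0);
  double Et = 0.0;
  std::vector<double> P;
  int Ibits = 0;
  for (int j = 0; j < s; j++)
    if (I0[j]) Ibits |= (1 << j);
  if (Ibits != 0) {
    // non-empty starting capture state: evaluate the node directly
    const auto &v = dp.cost(pv, Ibits, root_assembly);
    Et = v.Et;
    P = v.P;
  } else {
    dp.run(pv, root_assembly, root_sensed, Et, P);
  }
  return Rcpp::List::create(
      Rcpp::Named("expected_total") = Et,
      Rcpp::Named("P") = Rcpp::NumericVector(P.begin(), P.end()),
      Rcpp::Named("node_evaluations") = (double)dp.nodes());
}
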