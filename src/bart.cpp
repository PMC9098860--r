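// Sum-of-trees (BART) sampler: Gibbs-within-Metropolis-Hastings with
// grow/prune/change tree proposals, conjugate leaf means, and an
// inverse-chi-squared sigma^2 update.  A probit variant (Albert-Chib latent
// augmentation) and a two-forest causal decomposition (BCF: prognostic mu
// forest plus treatment-moderating tau forest) reuse the same tree engine.
//
// All randomness goes through R's RNG so set.seed() governs every draw.
// Single-threaded by design: results are bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  // node arrays; var = -1 marks a leaf, var = -9 a free slot
  std::vector<int> var, left, right, parent;
  std::vector<double> cut, mu;
  std::vector<int> freelist;

  Tree() { newnode(-1); }

  int newnode(int par) {
    int id;
    if (!freelist.empty()) {
      id = freelist.back();
      freelist.pop_back();
      var[id] = -1; left[id] = -1; right[id] = -1;
      parent[id] = par; cut[id] = 0.0; mu[id] = 0.0;
    } else {
      id = (int)var.size();
      var.push_back(-1); left.push_back(-1); right.push_back(-1);
      parent.push_back(par); cut.push_back(0.0); mu.push_back(0.0);
    }
    return id;
  }
  void freenode(int id) { var[id] = -9; freelist.push_back(id); }
  bool isleaf(int id) const { return var[id] == -1; }
  int depth(int id) const {
    int d = 0;
    while (parent[id] >= 0) { id = parent[id]; ++d; }
    return d;
  }
  // internal nodes whose two children are both leaves
  void prunable(std::vector<int> &out) const {
    out.clear();
    for (int i = 0; i < (int)var.size(); ++i)
      if (var[i] >= 0 && isleaf(left[i]) && isleaf(right[i]))
        out.push_back(i);
  }
  void leaves(std::vector<int> &out) const {
    out.clear();
    for (int i = 0; i < (int)var.size(); ++i)
      if (var[i] == -1) out.push_back(i);
  }
  int evalLeaf(const NumericMatrix &X, int row) const {
    int id = 0;
    while (var[id] >= 0)
      id = (X(row, var[id]) < cut[id]) ? left[id] : right[id];
    return id;
  }
};

inline double logLeafLik(double n, double s, double sig2, double sigmu2) {
  // marginal likelihood of leaf residuals with the mean integrated out
  double v = sig2 + n * sigmu2;
  return 0.5 * std::log(sig2 / v) + (sigmu2 * s * s) / (2.0 * sig2 * v);
}

// One forest bound to (a subset of rows of) a design matrix.
class Forest {
public:
  const NumericMatrix &X;
  std::vector<int> rows;  // training rows (0-based indices into X)
  int n, p, m;
  double alpha, beta, sigmu2;
  double pgrow, pprune, pchange;
  std::vector<Tree> trees;
  std::vector<std::vector<int> > nodeOf;      // per tree: local row -> node
  std::vector<std::vector<double> > tfit;     // per tree: local row fit
  long n_try, n_acc;
  // scratch buffers reused across tree updates (hot path: no allocation)
  std::vector<double> buf_resid, buf_old, leaf_s;
  std::vector<int> leaf_cnt, bcount, bstart, bitems;
  std::vector<std::vector<double> > uniq;  // per-var sorted unique values

  Forest(const NumericMatrix &X_, const std::vector<int> &rows_, int m_,
         double alpha_, double beta_, double sigmu2_,
         double pg, double pp, double pc)
      : X(X_), rows(rows_), n((int)rows_.size()), p(X_.ncol()), m(m_),
        alpha(alpha_), beta(beta_), sigmu2(sigmu2_),
        pgrow(pg), pprune(pp), pchange(pc), n_try(0), n_acc(0) {
    trees.resize(m);
    nodeOf.assign(m, std::vector<int>(n, 0));
    tfit.assign(m, std::vector<double>(n, 0.0));
    buf_resid.resize(n); buf_old.resize(n);
    bitems.resize(n);
    uniq.resize(p);
    for (int j = 0; j < p; ++j) {
      std::vector<double> v(n);
      for (int i = 0; i < n; ++i) v[i] = X(rows[i], j);
      std::sort(v.begin(), v.end());
      v.erase(std::unique(v.begin(), v.end()), v.end());
      uniq[j] = v;
    }
  }

  // sorted unique values of var j over a node's rows; uses the global
  // cache when the node holds the full training set
  void nodeUnique(const std::vector<int> &rr, int j,
                  std::vector<double> &vals) const {
    if ((int)rr.size() == n) { vals = uniq[j]; return; }
    vals.clear();
    for (size_t k = 0; k < rr.size(); ++k) vals.push_back(X(rows[rr[k]], j));
    std::sort(vals.begin(), vals.end());
    vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
  }

  double psplit(int d) const { return alpha * std::pow(1.0 + d, -beta); }

  // rows (local indices) currently in a given node of tree t
  void rowsInNode(int t, int node, std::vector<int> &out) const {
    out.clear();
    for (int i = 0; i < n; ++i)
      if (nodeOf[t][i] == node) out.push_back(i);
  }

  bool rowsVary(const int *rr, int len, int j) const {
    if (len < 2 || uniq[j].size() < 2) return false;
    if (len == n) return true;  // nonconstant globally => varies at root
    double v0 = X(rows[rr[0]], j);
    for (int k = 1; k < len; ++k)
      if (X(rows[rr[k]], j) != v0) return true;
    return false;
  }
  bool anyVary(const int *rr, int len) const {
    for (int j = 0; j < p; ++j)
      if (rowsVary(rr, len, j)) return true;
    return false;
  }

  // counting-sort local rows by node id into bstart/bitems (reused buffers)
  void bucketRows(int t) {
    int nn = (int)trees[t].var.size();
    bcount.assign(nn, 0);
    bstart.assign(nn + 1, 0);
    const std::vector<int> &nd = nodeOf[t];
    for (int i = 0; i < n; ++i) ++bcount[nd[i]];
    for (int b = 0; b < nn; ++b) bstart[b + 1] = bstart[b] + bcount[b];
    std::vector<int> pos(bstart.begin(), bstart.end() - 1);
    for (int i = 0; i < n; ++i) bitems[pos[nd[i]]++] = i;
  }
  const int *bucketPtr(int node) const { return &bitems[bstart[node]]; }
  int bucketLen(int node) const { return bstart[node + 1] - bstart[node]; }

  int countGrowable(int t, int skip1 = -1, int skip2 = -1) {
    std::vector<int> lv;
    trees[t].leaves(lv);
    bucketRows(t);
    int b = 0;
    for (size_t k = 0; k < lv.size(); ++k) {
      if ((int)lv[k] == skip1 || (int)lv[k] == skip2) continue;
      if (bucketLen(lv[k]) >= 2 && anyVary(bucketPtr(lv[k]), bucketLen(lv[k])))
        ++b;
    }
    return b;
  }

  void refreshFit(int t) {
    Tree &tr = trees[t];
    for (int i = 0; i < n; ++i) tfit[t][i] = tr.mu[nodeOf[t][i]];
  }

  // one MH structural move on tree t given residuals
  void proposeMove(int t, const std::vector<double> &resid, double sig2) {
    Tree &tr = trees[t];
    double u = unif_rand();
    std::vector<int> rr, pn;
    if (u < pgrow) {
      // ---- GROW ----
      std::vector<int> lv, grow;
      tr.leaves(lv);
      bucketRows(t);
      for (size_t k = 0; k < lv.size(); ++k) {
        if (bucketLen(lv[k]) >= 2 &&
            anyVary(bucketPtr(lv[k]), bucketLen(lv[k])))
          grow.push_back(lv[k]);
      }
      int b = (int)grow.size();
      if (b == 0) return;
      int L = grow[(int)(unif_rand() * b) % b];
      rr.assign(bucketPtr(L), bucketPtr(L) + bucketLen(L));
      std::vector<int> vars;
      for (int j = 0; j < p; ++j)
        if (rowsVary(rr.data(), (int)rr.size(), j)) vars.push_back(j);
      int j = vars[(int)(unif_rand() * vars.size()) % vars.size()];
      std::vector<double> vals;
      nodeUnique(rr, j, vals);
      // cutpoints exclude the minimum so both children are populated
      int ncut = (int)vals.size() - 1;
      double cut = vals[1 + ((int)(unif_rand() * ncut) % ncut)];
      double nl = 0, sl = 0, nr = 0, sr = 0, ntot = 0, stot = 0;
      for (size_t k = 0; k < rr.size(); ++k) {
        double r = resid[rr[k]];
        ntot += 1; stot += r;
        if (X(rows[rr[k]], j) < cut) { nl += 1; sl += r; }
        else { nr += 1; sr += r; }
      }
      int d = tr.depth(L);
      // prunable count after the grow
      int par = tr.parent[L];
      bool parPrunable = (par >= 0) && tr.isleaf(tr.left[par]) &&
                         tr.isleaf(tr.right[par]);
      std::vector<int> pr;
      tr.prunable(pr);
      int w2star = (int)pr.size() + 1 - (parPrunable ? 1 : 0);
      double logr = std::log(pprune) - std::log(pgrow) + std::log((double)b) -
                    std::log((double)w2star) + std::log(psplit(d)) +
                    2.0 * std::log(1.0 - psplit(d + 1)) -
                    std::log(1.0 - psplit(d)) +
                    logLeafLik(nl, sl, sig2, sigmu2) +
                    logLeafLik(nr, sr, sig2, sigmu2) -
                    logLeafLik(ntot, stot, sig2, sigmu2);
      ++n_try;
      if (std::log(unif_rand()) < logr) {
        ++n_acc;
        int cl = tr.newnode(L), cr = tr.newnode(L);
        tr.var[L] = j; tr.cut[L] = cut; tr.left[L] = cl; tr.right[L] = cr;
        for (size_t k = 0; k < rr.size(); ++k)
          nodeOf[t][rr[k]] = (X(rows[rr[k]], j) < cut) ? cl : cr;
      }
    } else if (u < pgrow + pprune) {
      // ---- PRUNE ----
      tr.prunable(pn);
      if (pn.empty()) return;
      int P = pn[(int)(unif_rand() * pn.size()) % pn.size()];
      int cl = tr.left[P], cr = tr.right[P];
      double nl = 0, sl = 0, nr = 0, sr = 0;
      for (int i = 0; i < n; ++i) {
        if (nodeOf[t][i] == cl) { nl += 1; sl += resid[i]; }
        else if (nodeOf[t][i] == cr) { nr += 1; sr += resid[i]; }
      }
      int d = tr.depth(P);
      // growable leaves of the pruned tree: drop the two children, the
      // merged node has >=2 rows and (having been split) must vary
      int bstar = countGrowable(t, cl, cr) + 1;
      double logr = std::log(pgrow) - std::log(pprune) +
                    std::log((double)pn.size()) - std::log((double)bstar) +
                    std::log(1.0 - psplit(d)) - std::log(psplit(d)) -
                    2.0 * std::log(1.0 - psplit(d + 1)) +
                    logLeafLik(nl + nr, sl + sr, sig2, sigmu2) -
                    logLeafLik(nl, sl, sig2, sigmu2) -
                    logLeafLik(nr, sr, sig2, sigmu2);
      ++n_try;
      if (std::log(unif_rand()) < logr) {
        ++n_acc;
        tr.var[P] = -1;
        tr.freenode(cl); tr.freenode(cr);
        tr.left[P] = -1; tr.right[P] = -1;
        for (int i = 0; i < n; ++i)
          if (nodeOf[t][i] == cl || nodeOf[t][i] == cr) nodeOf[t][i] = P;
      }
    } else {
      // ---- CHANGE (rule of a node with two leaf children) ----
      tr.prunable(pn);
      if (pn.empty()) return;
      int P = pn[(int)(unif_rand() * pn.size()) % pn.size()];
      int cl = tr.left[P], cr = tr.right[P];
      rr.clear();
      for (int i = 0; i < n; ++i)
        if (nodeOf[t][i] == cl || nodeOf[t][i] == cr) rr.push_back(i);
      std::vector<int> vars;
      for (int j = 0; j < p; ++j)
        if (rowsVary(rr.data(), (int)rr.size(), j)) vars.push_back(j);
      if (vars.empty()) return;
      int j = vars[(int)(unif_rand() * vars.size()) % vars.size()];
      std::vector<double> vals;
      nodeUnique(rr, j, vals);
      int ncut = (int)vals.size() - 1;
      double cut = vals[1 + ((int)(unif_rand() * ncut) % ncut)];
      double nlo = 0, slo = 0, nro = 0, sro = 0;  // old children
      double nln = 0, sln = 0, nrn = 0, srn = 0;  // new children
      for (size_t k = 0; k < rr.size(); ++k) {
        int i = rr[k];
        double r = resid[i];
        if (nodeOf[t][i] == cl) { nlo += 1; slo += r; }
        else { nro += 1; sro += r; }
        if (X(rows[i], j) < cut) { nln += 1; sln += r; }
        else { nrn += 1; srn += r; }
      }
      // same row set reaches the node before and after: proposal symmetric
      // up to the (var, cut) counts, which we take uniform over valid pairs
      // in both directions, hence the ratio reduces to the likelihoods
      double logr = logLeafLik(nln, sln, sig2, sigmu2) +
                    logLeafLik(nrn, srn, sig2, sigmu2) -
                    logLeafLik(nlo, slo, sig2, sigmu2) -
                    logLeafLik(nro, sro, sig2, sigmu2);
      ++n_try;
      if (std::log(unif_rand()) < logr) {
        ++n_acc;
        tr.var[P] = j; tr.cut[P] = cut;
        for (size_t k = 0; k < rr.size(); ++k) {
          int i = rr[k];
          nodeOf[t][i] = (X(rows[i], j) < cut) ? cl : cr;
        }
      }
    }
  }

  // full update of tree t (structure + leaves), maintaining the global
  // residual R_i = y_i - (full forest fit)_i (minus any fixed offset)
  void updateTreeR(int t, std::vector<double> &R, double sig2) {
    for (int i = 0; i < n; ++i) buf_resid[i] = R[i] + tfit[t][i];
    proposeMove(t, buf_resid, sig2);
    // conjugate leaf draws fused with the fit/residual refresh
    Tree &tr = trees[t];
    size_t nn = tr.var.size();
    leaf_s.assign(nn, 0.0);
    leaf_cnt.assign(nn, 0);
    const std::vector<int> &nd = nodeOf[t];
    for (int i = 0; i < n; ++i) {
      leaf_s[nd[i]] += buf_resid[i];
      leaf_cnt[nd[i]] += 1;
    }
    for (size_t k = 0; k < nn; ++k) {
      if (tr.var[k] != -1) continue;
      double v = sig2 + leaf_cnt[k] * sigmu2;
      double mean = sigmu2 * leaf_s[k] / v;
      double sdv = std::sqrt(sig2 * sigmu2 / v);
      tr.mu[k] = mean + sdv * norm_rand();
    }
    std::vector<double> &tf = tfit[t];
    for (int i = 0; i < n; ++i) {
      tf[i] = tr.mu[nd[i]];
      R[i] = buf_resid[i] - tf[i];
    }
  }

  double predictRow(int row) const {
    double s = 0.0;
    for (int t = 0; t < m; ++t) {
      const Tree &tr = trees[t];
      s += tr.mu[tr.evalLeaf(X, row)];
    }
    return s;
  }

  // flatten live nodes of all trees into one matrix (1-based child indices
  // local to the matrix; var 0 marks a leaf)
  NumericMatrix serialize() const {
    int total = 0;
    std::vector<std::vector<int> > maps(m);
    for (int t = 0; t < m; ++t) {
      maps[t].assign(trees[t].var.size(), -1);
      for (size_t nd = 0; nd < trees[t].var.size(); ++nd)
        if (trees[t].var[nd] != -9) maps[t][nd] = total++;
    }
    NumericMatrix out(total, 6);
    for (int t = 0; t < m; ++t) {
      const Tree &tr = trees[t];
      for (size_t nd = 0; nd < tr.var.size(); ++nd) {
        if (tr.var[nd] == -9) continue;
        int r = maps[t][nd];
        out(r, 0) = t + 1;
        out(r, 1) = (tr.var[nd] == -1) ? 0 : tr.var[nd] + 1;
        out(r, 2) = tr.cut[nd];
        out(r, 3) = (tr.var[nd] == -1) ? 0 : maps[t][tr.left[nd]] + 1;
        out(r, 4) = (tr.var[nd] == -1) ? 0 : maps[t][tr.right[nd]] + 1;
        out(r, 5) = tr.mu[nd];
      }
    }
    return out;
  }
};

inline double rtruncnorm(double mean, int positive) {
  // inverse-CDF truncated normal with sd 1, truncation at zero
  double p0 = R::pnorm(0.0, mean, 1.0, 1, 0);
  double u = unif_rand(), q;
  if (positive) q = p0 + u * (1.0 - p0);
  else q = u * p0;
  q = std::min(std::max(q, 1e-12), 1.0 - 1e-12);
  return R::qnorm(q, mean, 1.0, 1, 0);
}

}  // namespace

// [[Rcpp::export(name = ".fit_bart_cpp")]]
List fit_bart_cpp(NumericMatrix X, NumericVector y, LogicalVector zbin,
                  bool probit, int m, double alpha, double beta,
                  double sigmu, double nu, double lambda, int nburn,
                  int nkeep, double pgrow, double pprune, double pchange,
                  Nullable<NumericMatrix> Xtest, bool keepforest) {
  int n = X.nrow();
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  Forest fo(X, rows, m, alpha, beta, sigmu * sigmu, pgrow, pprune, pchange);

  std::vector<double> ywork(n), totalfit(n, 0.0);
  if (probit) {
    for (int i = 0; i < n; ++i) ywork[i] = zbin[i] ? 0.5 : -0.5;  // init
  } else {
    for (int i = 0; i < n; ++i) ywork[i] = y[i];
  }
  double sig2 = 1.0;
  if (!probit) {
    double mu0 = 0, v0 = 0;
    for (int i = 0; i < n; ++i) mu0 += ywork[i];
    mu0 /= n;
    for (int i = 0; i < n; ++i) v0 += (ywork[i] - mu0) * (ywork[i] - mu0);
    sig2 = (n > 1) ? v0 / (n - 1) : 1.0;
    if (sig2 <= 0) sig2 = 1e-6;  // zero-variance guard
  }

  bool hastest = Xtest.isNotNull();
  NumericMatrix Xt;
  int ntest = 0;
  if (hastest) { Xt = NumericMatrix(Xtest); ntest = Xt.nrow(); }

  NumericVector sigdraws(nkeep);
  NumericMatrix fitdraws(nkeep, n);
  NumericMatrix testdraws(hastest ? nkeep : 1, hastest ? ntest : 1);
  List forests(keepforest ? nkeep : 0);

  // R_i = ywork_i - (forest fit)_i, maintained across tree updates
  std::vector<double> &Rres = totalfit;  // reuse storage
  for (int i = 0; i < n; ++i) Rres[i] = ywork[i];
  int total = nburn + nkeep;
  for (int it = 0; it < total; ++it) {
    for (int t = 0; t < m; ++t) fo.updateTreeR(t, Rres, sig2);
    if (probit) {
      for (int i = 0; i < n; ++i) {
        double fiti = ywork[i] - Rres[i];
        double ynew = rtruncnorm(fiti, zbin[i] ? 1 : 0);
        Rres[i] = ynew - fiti;
        ywork[i] = ynew;
      }
      sig2 = 1.0;
    } else {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += Rres[i] * Rres[i];
      sig2 = (nu * lambda + sse) / R::rchisq(nu + n);
    }
    if (it >= nburn) {
      int k = it - nburn;
      sigdraws[k] = std::sqrt(sig2);
      for (int i = 0; i < n; ++i) fitdraws(k, i) = ywork[i] - Rres[i];
      if (hastest) {
        Forest &f = fo;
        for (int i = 0; i < ntest; ++i) {
          double s = 0.0;
          for (int t = 0; t < m; ++t) {
            const Tree &tr = f.trees[t];
            int id = 0;
            while (tr.var[id] >= 0)
              id = (Xt(i, tr.var[id]) < tr.cut[id]) ? tr.left[id]
                                                    : tr.right[id];
            s += tr.mu[id];
          }
          testdraws(k, i) = s;
        }
      }
      if (keepforest) forests[k] = fo.serialize();
    }
  }
  double accrate = fo.n_try > 0 ? (double)fo.n_acc / (double)fo.n_try : 0.0;
  return List::create(_["sigma"] = sigdraws, _["fit"] = fitdraws,
                      _["test"] = testdraws, _["forests"] = forests,
                      _["accept_rate"] = accrate,
                      _["n_proposals"] = (double)fo.n_try);
}

// [[Rcpp::export(name = ".predict_forest_cpp")]]
NumericMatrix predict_forest_cpp(List forests, NumericMatrix X) {
  int nkeep = forests.size(), n = X.nrow();
  NumericMatrix out(nkeep, n);
  for (int k = 0; k < nkeep; ++k) {
    NumericMatrix F = forests[k];
    // locate tree roots: first row of each tree id
    std::vector<int> roots;
    int lastTree = -1;
    for (int r = 0; r < F.nrow(); ++r) {
      if ((int)F(r, 0) != lastTree) { roots.push_back(r); lastTree = (int)F(r, 0); }
    }
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (size_t t = 0; t < roots.size(); ++t) {
        int id = roots[t];
        while ((int)F(id, 1) != 0) {
          int j = (int)F(id, 1) - 1;
          id = (X(i, j) < F(id, 2)) ? (int)F(id, 3) - 1 : (int)F(id, 4) - 1;
        }
        s += F(id, 5);
      }
      out(k, i) = s;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".fit_bcf_cpp")]]
List fit_bcf_cpp(NumericMatrix Xmu, NumericMatrix Xtau, IntegerVector z,
                 NumericVector y, int mmu, int mtau, double alpha_mu,
                 double beta_mu, double alpha_tau, double beta_tau,
                 double sigmu_mu, double sigmu_tau, double nu, double lambda,
                 int nburn, int nkeep, double pgrow, double pprune,
                 double pchange) {
  int n = Xmu.nrow();
  std::vector<int> allrows(n), trows;
  for (int i = 0; i < n; ++i) {
    allrows[i] = i;
    if (z[i] == 1) trows.push_back(i);
  }
  int ntreat = (int)trows.size();

  Forest fmu(Xmu, allrows, mmu, alpha_mu, beta_mu, sigmu_mu * sigmu_mu,
             pgrow, pprune, pchange);
  Forest ftau(Xtau, trows, mtau, alpha_tau, beta_tau, sigmu_tau * sigmu_tau,
              pgrow, pprune, pchange);

  std::vector<double> yall(n), taufit_all(n, 0.0);
  for (int i = 0; i < n; ++i) yall[i] = y[i];
  std::vector<double> taufit_t(ntreat, 0.0);
  double mu0 = 0, v0 = 0;
  for (int i = 0; i < n; ++i) mu0 += yall[i];
  mu0 /= n;
  for (int i = 0; i < n; ++i) v0 += (yall[i] - mu0) * (yall[i] - mu0);
  double sig2 = (n > 1) ? v0 / (n - 1) : 1.0;
  if (sig2 <= 0) sig2 = 1e-6;

  NumericVector sigdraws(nkeep);
  NumericMatrix taudraws(nkeep, n), mudraws(nkeep, n);

  // Residual bookkeeping:
  //   Rmu_i  = y_i - mu(x_i) - z_i * tau(x_i)   (all rows)
  //   Rtau_l = y_l - mu(x_l) - tau(x_l)         (treated rows, local index)
  // At the start of each sweep ztau is synced with the moderating forest,
  // after which y - mu on treated rows equals ztau + Rmu, so the
  // moderating forest's target residual is simply Rmu restricted to
  // treated rows.
  std::vector<double> ztau(n, 0.0), Rmu(n), Rtau(ntreat);
  for (int i = 0; i < n; ++i) Rmu[i] = yall[i];
  int total = nburn + nkeep;
  for (int it = 0; it < total; ++it) {
    for (int li = 0; li < ntreat; ++li) {
      int i = trows[li];
      Rmu[i] += ztau[i] - taufit_t[li];
      ztau[i] = taufit_t[li];
    }
    for (int t = 0; t < mmu; ++t) fmu.updateTreeR(t, Rmu, sig2);
    for (int li = 0; li < ntreat; ++li) Rtau[li] = Rmu[trows[li]];
    for (int t = 0; t < mtau; ++t) ftau.updateTreeR(t, Rtau, sig2);
    // taufit refreshed from the residual identity; ztau stays one sweep old
    for (int li = 0; li < ntreat; ++li)
      taufit_t[li] = ztau[trows[li]] + Rmu[trows[li]] - Rtau[li];
    double sse = 0.0;
    for (int i = 0; i < n; ++i)
      if (z[i] == 0) sse += Rmu[i] * Rmu[i];
    for (int li = 0; li < ntreat; ++li) sse += Rtau[li] * Rtau[li];
    sig2 = (nu * lambda + sse) / R::rchisq(nu + n);
    if (it >= nburn) {
      int k = it - nburn;
      sigdraws[k] = std::sqrt(sig2);
      // evaluate tau on every row (controls included) only at kept draws
      for (int i = 0; i < n; ++i) taufit_all[i] = ftau.predictRow(i);
      for (int i = 0; i < n; ++i) {
        taudraws(k, i) = taufit_all[i];
        mudraws(k, i) = yall[i] - ztau[i] - Rmu[i];
      }
    }
  }
  double atry = fmu.n_try + ftau.n_try;
  double aacc = fmu.n_acc + ftau.n_acc;
  return List::create(_["sigma"] = sigdraws, _["tau"] = taudraws,
                      _["mu"] = mudraws,
                      _["accept_rate"] = atry > 0 ? aacc / atry : 0.0);
}
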