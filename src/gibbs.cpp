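#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact edge-subset expansion of the allocation-prior normalizing constant
//   Z = sum_{j_1..j_M} prod_m gamma_{m j_m} prod_edges (1 + rho 1{j_m = j_k})
// and of its linear coefficients in gamma_{mj} and rho_e.  Each (1 + rho d)
// factor expands over inclusion/exclusion, giving 2^E terms; a term factors
// over the connected components the included edges induce on the views.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
  return x;
}

// component product-sums: for each root, T = sum_k prod_{m in comp} gamma(m,k)
static double component_product(const NumericMatrix& gamma,
                                const std::vector<int>& comp,
                                int skip_view, // -1 for none
                                std::vector<double>* vec_out, // per-k, for comp of skip_view
                                int root_of_skip) {
  int M = gamma.nrow(), K = gamma.ncol();
  double out = 1.0;
  std::vector<bool> done(M, false);
  for (int m = 0; m < M; ++m) {
    int r = comp[m];
    if (done[r]) continue;
    done[r] = true;
    if (skip_view >= 0 && r == root_of_skip) {
      // vector over k of prod over members except skip_view
      for (int k = 0; k < K; ++k) {
        double p = 1.0;
        for (int mm = 0; mm < M; ++mm)
          if (comp[mm] == r && mm != skip_view) p *= gamma(mm, k);
        (*vec_out)[k] = p;
      }
    } else {
      double T = 0.0;
      for (int k = 0; k < K; ++k) {
        double p = 1.0;
        for (int mm = 0; mm < M; ++mm)
          if (comp[mm] == r) p *= gamma(mm, k);
        T += p;
      }
      out *= T;
    }
  }
  return out;
}

static void components_for_subset(int M, const IntegerMatrix& em,
                                  const std::vector<int>& edges,
                                  std::vector<int>& comp) {
  std::vector<int> parent(M);
  for (int m = 0; m < M; ++m) parent[m] = m;
  for (size_t j = 0; j < edges.size(); ++j) {
    int a = uf_find(parent, em(edges[j], 0) - 1);
    int b = uf_find(parent, em(edges[j], 1) - 1);
    if (a != b) parent[a] = b;
  }
  comp.resize(M);
  for (int m = 0; m < M; ++m) comp[m] = uf_find(parent, m);
}

// [[Rcpp::export]]
double compute_Z_cpp(NumericMatrix gamma, NumericVector rho, IntegerMatrix em) {
  int E = em.nrow(), M = gamma.nrow();
  double total = 0.0;
  std::vector<int> sel, comp;
  for (unsigned S = 0; S < (1u << E); ++S) {
    sel.clear();
    double rp = 1.0;
    for (int e = 0; e < E; ++e)
      if (S >> e & 1u) { sel.push_back(e); rp *= rho[e]; }
    components_for_subset(M, em, sel, comp);
    total += rp * component_product(gamma, comp, -1, nullptr, -1);
  }
  return total;
}

// dZ/dgamma_{m j} for all j (m is 1-based)
// [[Rcpp::export]]
NumericVector gamma_rate_coef_cpp(NumericMatrix gamma, NumericVector rho,
                                  IntegerMatrix em, int m) {
  int E = em.nrow(), M = gamma.nrow(), K = gamma.ncol();
  int mi = m - 1;
  NumericVector A(K);
  std::vector<int> sel, comp;
  std::vector<double> vec(K);
  for (unsigned S = 0; S < (1u << E); ++S) {
    sel.clear();
    double rp = 1.0;
    for (int e = 0; e < E; ++e)
      if (S >> e & 1u) { sel.push_back(e); rp *= rho[e]; }
    components_for_subset(M, em, sel, comp);
    double others = component_product(gamma, comp, mi, &vec, comp[mi]);
    for (int k = 0; k < K; ++k) A[k] += rp * others * vec[k];
  }
  return A;
}

// coefficient of rho_{edge_id} in Z (edge_id 1-based)
// [[Rcpp::export]]
double rho_rate_coef_cpp(NumericMatrix gamma, NumericVector rho,
                         IntegerMatrix em, int edge_id) {
  int E = em.nrow(), M = gamma.nrow();
  int e0 = edge_id - 1;
  double total = 0.0;
  std::vector<int> rest;
  for (int e = 0; e < E; ++e) if (e != e0) rest.push_back(e);
  int R = rest.size();
  std::vector<int> sel, comp;
  for (unsigned S = 0; S < (1u << R); ++S) {
    sel.clear();
    double rp = 1.0;
    for (int r = 0; r < R; ++r)
      if (S >> r & 1u) { sel.push_back(rest[r]); rp *= rho[rest[r]]; }
    sel.push_back(e0); // equality enforced, factor rho_e0 excluded
    components_for_subset(M, em, sel, comp);
    total += rp * component_product(gamma, comp, -1, nullptr, -1);
  }
  return total;
}

// ---------------------------------------------------------------------------
// Collapsed Gibbs sampler
// ---------------------------------------------------------------------------

struct ViewData {
  NumericMatrix X;            // N x D
  NumericVector mu0;          // length D
  std::vector<int> count;     // K
  std::vector<double> sum;    // K*D
  std::vector<double> ssq;    // K*D
  int D;
};

static inline void stats_add(ViewData& v, int c, int i, int sgn) {
  v.count[c] += sgn;
  for (int d = 0; d < v.D; ++d) {
    double x = v.X(i, d);
    v.sum[c * v.D + d] += sgn * x;
    v.ssq[c * v.D + d] += sgn * x * x;
  }
}

// Student-t posterior-predictive log density of observation i of view v in
// cluster c (given current members of c)
static double pred_logpdf(const ViewData& v, int c, int i,
                          double kappa0, double a0, double b0) {
  int n = v.count[c];
  double lp = 0.0;
  double kn = kappa0 + n, an = a0 + 0.5 * n;
  double lgam = std::lgamma(0.5 * (2 * an + 1)) - std::lgamma(an);
  for (int d = 0; d < v.D; ++d) {
    double s = v.sum[c * v.D + d], q = v.ssq[c * v.D + d];
    double mu0 = v.mu0[d];
    double xbar = n > 0 ? s / n : 0.0;
    double ss = q - n * xbar * xbar;
    if (ss < 0) ss = 0;
    double bn = b0 + 0.5 * ss +
      (n > 0 ? kappa0 * n * (xbar - mu0) * (xbar - mu0) / (2 * kn) : 0.0);
    double mun = (kappa0 * mu0 + s) / kn;
    double nu = 2 * an;
    double sc2 = bn * (kn + 1) / (an * kn);
    double x = v.X(i, d);
    double z2 = (x - mun) * (x - mun) / sc2;
    lp += lgam - 0.5 * std::log(nu * M_PI * sc2)
        - 0.5 * (nu + 1) * std::log1p(z2 / nu);
  }
  return lp;
}

// [[Rcpp::export]]
List gibbs_run_cpp(List data, List mu0_list, IntegerMatrix em,
                   NumericVector prior_rate, int K, double alpha_conc,
                   double kappa0, double a0, double b0,
                   int iterations, int burn_in, int thinning,
                   IntegerMatrix L_init, NumericMatrix gamma_init,
                   NumericVector rho_init, double xi_init,
                   bool update_xi, bool update_gamma, bool update_rho,
                   bool verbose) {
  int M = data.size();
  int E = em.nrow();
  int N = L_init.nrow();
  std::vector<ViewData> V(M);
  for (int m = 0; m < M; ++m) {
    V[m].X = as<NumericMatrix>(data[m]);
    V[m].mu0 = as<NumericVector>(mu0_list[m]);
    V[m].D = V[m].X.ncol();
    V[m].count.assign(K, 0);
    V[m].sum.assign((size_t)K * V[m].D, 0.0);
    V[m].ssq.assign((size_t)K * V[m].D, 0.0);
  }
  IntegerMatrix L = clone(L_init); // N x M, 1-based from R
  NumericMatrix gamma = clone(gamma_init);
  NumericVector rho = clone(rho_init);
  double xi = xi_init;

  for (int m = 0; m < M; ++m)
    for (int i = 0; i < N; ++i)
      stats_add(V[m], L(i, m) - 1, i, +1);

  // adjacency: edges incident to each view
  std::vector<std::vector<int>> in_edges(M), out_edges(M);
  for (int e = 0; e < E; ++e) {
    out_edges[em(e, 0) - 1].push_back(e);
    in_edges[em(e, 1) - 1].push_back(e);
  }

  int n_keep = 0;
  for (int it = burn_in + 1; it <= iterations; ++it)
    if ((it - burn_in) % thinning == 0) ++n_keep;

  IntegerVector L_chain((size_t)n_keep * N * M);
  L_chain.attr("dim") = IntegerVector::create(n_keep, N, M);
  NumericMatrix rho_chain(n_keep, E);
  NumericVector xi_chain(n_keep), Z_chain(n_keep);
  IntegerMatrix occ_chain(n_keep, M);
  NumericVector gamma_chain((size_t)n_keep * M * K);
  gamma_chain.attr("dim") = IntegerVector::create(n_keep, M, K);

  std::vector<int> cand; cand.reserve(K + 4);
  std::vector<double> logw; logw.reserve(K + 4);
  std::vector<char> in_cand(K, 0);

  int keep_idx = 0;
  for (int it = 1; it <= iterations; ++it) {
    double Z = compute_Z_cpp(gamma, rho, em);
    if (!std::isfinite(Z) || Z <= 0)
      stop("non-finite or non-positive Z at iteration %d", it);
    // --- xi ---
    if (update_xi) xi = R::rgamma((double)N, 1.0 / Z);
    // --- gamma ---
    if (update_gamma) {
      for (int m = 0; m < M; ++m) {
        NumericVector A = gamma_rate_coef_cpp(gamma, rho, em, m + 1);
        for (int j = 0; j < K; ++j) {
          double shape = V[m].count[j] + alpha_conc / K;
          double rate = xi * A[j] + 1.0;
          gamma(m, j) = R::rgamma(shape, 1.0 / rate);
          if (gamma(m, j) <= 0) gamma(m, j) = 1e-300;
        }
      }
    }
    // --- rho ---
    if (update_rho) {
      for (int e = 0; e < E; ++e) {
        int vm = em(e, 0) - 1, vp = em(e, 1) - 1;
        int agree = 0;
        for (int i = 0; i < N; ++i) if (L(i, vm) == L(i, vp)) ++agree;
        double D = rho_rate_coef_cpp(gamma, rho, em, e + 1);
        rho[e] = R::rgamma(agree + 0.5, 1.0 / (xi * D + prior_rate[e]));
      }
    }
    // --- allocations ---
    for (int m = 0; m < M; ++m) {
      double Gtot = 0.0;
      for (int j = 0; j < K; ++j) Gtot += gamma(m, j);
      for (int i = 0; i < N; ++i) {
        int c_old = L(i, m) - 1;
        stats_add(V[m], c_old, i, -1);
        // candidate set: occupied clusters + neighbour labels
        cand.clear();
        for (int j = 0; j < K; ++j)
          if (V[m].count[j] > 0) { cand.push_back(j); in_cand[j] = 1; }
        for (size_t a = 0; a < in_edges[m].size(); ++a) {
          int j = L(i, em(in_edges[m][a], 0) - 1) - 1;
          if (!in_cand[j]) { cand.push_back(j); in_cand[j] = 1; }
        }
        for (size_t a = 0; a < out_edges[m].size(); ++a) {
          int j = L(i, em(out_edges[m][a], 1) - 1) - 1;
          if (!in_cand[j]) { cand.push_back(j); in_cand[j] = 1; }
        }
        int nc = cand.size();
        // prior predictive of an empty cluster (independent of the index)
        double lp_empty = 0.0;
        {
          double kn = kappa0, an = a0;
          double lgam = std::lgamma(0.5 * (2 * an + 1)) - std::lgamma(an);
          for (int d = 0; d < V[m].D; ++d) {
            double mu0 = V[m].mu0[d];
            double nu = 2 * an;
            double sc2 = b0 * (kn + 1) / (an * kn);
            double x = V[m].X(i, d);
            double z2 = (x - mu0) * (x - mu0) / sc2;
            lp_empty += lgam - 0.5 * std::log(nu * M_PI * sc2)
                      - 0.5 * (nu + 1) * std::log1p(z2 / nu);
          }
        }
        logw.clear();
        double gamma_cand = 0.0;
        for (int a = 0; a < nc; ++a) {
          int c = cand[a];
          gamma_cand += gamma(m, c);
          double lw = std::log(gamma(m, c));
          lw += (V[m].count[c] > 0)
                  ? pred_logpdf(V[m], c, i, kappa0, a0, b0)
                  : lp_empty;
          for (size_t q = 0; q < in_edges[m].size(); ++q) {
            int e = in_edges[m][q];
            if (L(i, em(e, 0) - 1) - 1 == c) lw += std::log1p(rho[e]);
          }
          for (size_t q = 0; q < out_edges[m].size(); ++q) {
            int e = out_edges[m][q];
            if (L(i, em(e, 1) - 1) - 1 == c) lw += std::log1p(rho[e]);
          }
          logw.push_back(lw);
        }
        // pooled atom for the remaining (empty, non-neighbour) clusters
        double g_rest = Gtot - gamma_cand;
        bool has_rest = g_rest > 0 && nc < K;
        if (has_rest) logw.push_back(std::log(g_rest) + lp_empty);
        int natoms = logw.size();
        double mx = logw[0];
        for (int a = 1; a < natoms; ++a) if (logw[a] > mx) mx = logw[a];
        double tot = 0.0;
        for (int a = 0; a < natoms; ++a) { logw[a] = std::exp(logw[a] - mx); tot += logw[a]; }
        if (!(tot > 0) || !std::isfinite(tot))
          stop("degenerate allocation weights at iteration %d (view %d, object %d)",
               it, m + 1, i + 1);
        double uu = unif_rand() * tot;
        int pick = natoms - 1;
        double acc = 0.0;
        for (int a = 0; a < natoms; ++a) {
          acc += logw[a];
          if (uu <= acc) { pick = a; break; }
        }
        int c_new;
        if (has_rest && pick == natoms - 1) {
          // choose among pooled empties proportional to gamma
          double uu2 = unif_rand() * g_rest;
          double acc2 = 0.0;
          c_new = -1;
          for (int j = 0; j < K; ++j) {
            if (in_cand[j]) continue;
            acc2 += gamma(m, j);
            if (uu2 <= acc2) { c_new = j; break; }
          }
          if (c_new < 0) { // numerical slack: last non-candidate
            for (int j = K - 1; j >= 0; --j) if (!in_cand[j]) { c_new = j; break; }
          }
        } else {
          c_new = cand[pick];
        }
        for (int a = 0; a < nc; ++a) in_cand[cand[a]] = 0;
        stats_add(V[m], c_new, i, +1);
        L(i, m) = c_new + 1;
      }
    }
    if (verbose && it % 100 == 0) {
      Rcout << "iter " << it << " xi=" << xi << " Z=" << Z << "\n";
    }
    if (it > burn_in && (it - burn_in) % thinning == 0) {
      for (int m = 0; m < M; ++m) {
        int occ = 0;
        for (int j = 0; j < K; ++j) if (V[m].count[j] > 0) ++occ;
        occ_chain(keep_idx, m) = occ;
        for (int i = 0; i < N; ++i)
          L_chain[keep_idx + (size_t)n_keep * (i + (size_t)N * m)] = L(i, m);
        for (int j = 0; j < K; ++j)
          gamma_chain[keep_idx + (size_t)n_keep * (m + (size_t)M * j)] = gamma(m, j);
      }
      for (int e = 0; e < E; ++e) rho_chain(keep_idx, e) = rho[e];
      xi_chain[keep_idx] = xi;
      Z_chain[keep_idx] = compute_Z_cpp(gamma, rho, em);
      ++keep_idx;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["L_chain"] = L_chain, _["gamma_chain"] = gamma_chain,
    _["rho_chain"] = rho_chain, _["xi_chain"] = xi_chain,
    _["Z_chain"] = Z_chain, _["occupied"] = occ_chain,
    _["L_final"] = L, _["gamma_final"] = gamma, _["rho_final"] = rho,
    _["xi_final"] = xi);
}

// posterior similarity: fraction of iterations allocating i and j together
// labels: n_iter x N matrix
// [[Rcpp::export]]
NumericMatrix similarity_cpp(IntegerMatrix labels) {
  int T = labels.nrow(), N = labels.ncol();
  NumericMatrix S(N, N);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      int li = labels(t, i);
      for (int j = i + 1; j < N; ++j)
        if (labels(t, j) == li) S(i, j) += 1.0;
    }
  }
  for (int i = 0; i < N; ++i) {
    S(i, i) = 1.0;
    for (int j = i + 1; j < N; ++j) {
      S(i, j) /= T;
      S(j, i) = S(i, j);
    }
  }
  return S;
}
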