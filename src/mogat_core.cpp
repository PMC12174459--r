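// Core numerical engine: per-view fully connected reduction + multi-head
// graph attention branches, cross-omics product-tensor fusion, manual
// backpropagation and Adam. Kept in one translation unit so forward and
// backward stay side by side.
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <array>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::IntegerVector;

static const double LN_EPS = 1e-5;
static const double P_FLOOR = 1e-12;

// ---------------------------------------------------------------- structures

struct Graph {
  uvec ei, ej;  // directed edges (incl. self loops), sorted by source ei
  uvec ptr;     // CSR offsets, length n+1
};

// All parameters are arma::mat; biases are 1 x d, attention probes dh x heads.
struct ViewParams {
  mat W1, b1, W2, b2, W3, b3;  // three FC layers
  mat G1W, G1a1, G1a2;         // attention layer 1 (multi-head, concat)
  mat G2W, G2a1, G2a2;         // attention layer 2 (single head)
  mat OW, Ob;                  // linear head to C classes
};

struct FusionParams { mat W1, b1, W2, b2; };

struct FCCache {
  mat A1, A2, A3;     // pre-ReLU activations
  mat XH1, XH2, XH3;  // layer-norm normalized values
  vec IS1, IS2, IS3;  // per-row inverse std
  mat O1, O2, O3;     // block outputs (post dropout)
};

struct GATCache {
  mat HW;     // n x H*dh projected features
  mat Epre;   // E x H raw scores (pre-LeakyReLU)
  mat Alpha;  // E x H attention coefficients
  mat Spre;   // n x H*dh pre-activation aggregate
  mat Out;    // post activation
};

struct BranchCache { FCCache fc; GATCache g1, g2; mat logits, probs; };

struct Config {
  int heads, dh, C;
  double slope, delta;
  bool use_vcdn, use_ln;
};

// ------------------------------------------------------------- element-wise

static mat relu_f(const mat& X) {
  mat Y = X; Y.transform([](double v) { return v > 0 ? v : 0.0; }); return Y;
}
static mat relu_g(const mat& X) { return conv_to<mat>::from(X > 0.0); }

static mat leaky_f(const mat& X, double s) {
  mat Y = X; Y.transform([s](double v) { return v > 0 ? v : s * v; }); return Y;
}
static mat leaky_g(const mat& X, double s) {
  mat Y = X; Y.transform([s](double v) { return v > 0 ? 1.0 : s; }); return Y;
}
static mat elu_f(const mat& X) {
  mat Y = X; Y.transform([](double v) { return v > 0 ? v : std::expm1(v); }); return Y;
}
static mat elu_g(const mat& X) {
  mat Y = X; Y.transform([](double v) { return v > 0 ? 1.0 : std::exp(v); }); return Y;
}

static mat softmax_rows(const mat& L) {
  mat P(size(L));
  for (uword i = 0; i < L.n_rows; ++i) {
    rowvec r = L.row(i) - L.row(i).max();
    rowvec e = exp(r);
    P.row(i) = e / accu(e);
  }
  return P;
}

// ---------------------------------------------------------------- layernorm

static void layernorm_fwd(const mat& R, mat& xhat, vec& invstd) {
  const uword n = R.n_rows;
  xhat.set_size(n, R.n_cols);
  invstd.set_size(n);
  for (uword i = 0; i < n; ++i) {
    rowvec r = R.row(i);
    double mu = mean(r);
    double v = mean(square(r - mu));
    double is = 1.0 / std::sqrt(v + LN_EPS);
    invstd(i) = is;
    xhat.row(i) = (r - mu) * is;
  }
}

static mat layernorm_bwd(const mat& dY, const mat& xhat, const vec& invstd) {
  mat dX(size(dY));
  for (uword i = 0; i < dY.n_rows; ++i) {
    rowvec dy = dY.row(i);
    double m1 = mean(dy);
    double m2 = mean(dy % xhat.row(i));
    dX.row(i) = invstd(i) * (dy - m1 - xhat.row(i) * m2);
  }
  return dX;
}

// --------------------------------------------------------------------- FC

static void fc_forward(const mat& X, const ViewParams& p, const Config& cf,
                       const std::array<mat, 3>* masks, FCCache& c) {
  c.A1 = X * p.W1; c.A1.each_row() += p.b1.row(0);
  mat R1 = relu_f(c.A1);
  if (cf.use_ln) { layernorm_fwd(R1, c.XH1, c.IS1); } else { c.XH1 = R1; }
  c.O1 = masks ? mat(c.XH1 % (*masks)[0]) : c.XH1;

  c.A2 = c.O1 * p.W2; c.A2.each_row() += p.b2.row(0);
  mat R2 = relu_f(c.A2);
  if (cf.use_ln) { layernorm_fwd(R2, c.XH2, c.IS2); } else { c.XH2 = R2; }
  c.O2 = masks ? mat(c.XH2 % (*masks)[1]) : c.XH2;

  c.A3 = c.O2 * p.W3; c.A3.each_row() += p.b3.row(0);
  mat R3 = relu_f(c.A3);
  if (cf.use_ln) { layernorm_fwd(R3, c.XH3, c.IS3); } else { c.XH3 = R3; }
  c.O3 = masks ? mat(c.XH3 % (*masks)[2]) : c.XH3;
}

static void fc_backward(const mat& X, const ViewParams& p, const Config& cf,
                        const FCCache& c, const std::array<mat, 3>* masks,
                        mat dZ, ViewParams& g, mat* dX) {
  if (masks) dZ = dZ % (*masks)[2];
  if (cf.use_ln) dZ = layernorm_bwd(dZ, c.XH3, c.IS3);
  dZ = dZ % relu_g(c.A3);
  g.W3 = c.O2.t() * dZ; g.b3 = sum(dZ, 0);
  mat d2 = dZ * p.W3.t();

  if (masks) d2 = d2 % (*masks)[1];
  if (cf.use_ln) d2 = layernorm_bwd(d2, c.XH2, c.IS2);
  d2 = d2 % relu_g(c.A2);
  g.W2 = c.O1.t() * d2; g.b2 = sum(d2, 0);
  mat d1 = d2 * p.W2.t();

  if (masks) d1 = d1 % (*masks)[0];
  if (cf.use_ln) d1 = layernorm_bwd(d1, c.XH1, c.IS1);
  d1 = d1 % relu_g(c.A1);
  g.W1 = X.t() * d1; g.b1 = sum(d1, 0);
  if (dX) *dX = d1 * p.W1.t();
}

// -------------------------------------------------------------------- GAT

static void gat_forward(const mat& Z, const mat& W, const mat& a1, const mat& a2,
                        const Graph& g, int heads, int dh, double slope, bool elu,
                        GATCache& c) {
  const uword n = Z.n_rows, E = g.ei.n_elem;
  c.HW = Z * W;
  // transposed (feature-major) copies keep the per-edge inner loops on
  // contiguous memory
  mat HWt = c.HW.t();
  c.Epre.set_size(E, heads);
  c.Alpha.set_size(E, heads);
  mat St((uword)heads * dh, n, fill::zeros);
  const uword* ei = g.ei.memptr();
  const uword* ej = g.ej.memptr();
  for (int h = 0; h < heads; ++h) {
    const uword l = (uword)h * dh, r = l + dh - 1;
    rowvec s1 = a1.col(h).t() * HWt.rows(l, r);
    rowvec s2 = a2.col(h).t() * HWt.rows(l, r);
    double* Ep = c.Epre.colptr(h);
    double* Al = c.Alpha.colptr(h);
    for (uword e = 0; e < E; ++e) Ep[e] = s1(ei[e]) + s2(ej[e]);
    for (uword i = 0; i < n; ++i) {
      const uword lo = g.ptr(i), hi = g.ptr(i + 1);
      double mx = -datum::inf;
      for (uword e = lo; e < hi; ++e) {
        double v = Ep[e] > 0 ? Ep[e] : slope * Ep[e];
        if (v > mx) mx = v;
      }
      double ssum = 0.0;
      for (uword e = lo; e < hi; ++e) {
        double v = Ep[e] > 0 ? Ep[e] : slope * Ep[e];
        double ex = std::exp(v - mx);
        Al[e] = ex; ssum += ex;
      }
      for (uword e = lo; e < hi; ++e) Al[e] /= ssum;
    }
    for (uword e = 0; e < E; ++e) {
      const double a = Al[e];
      double* dst = St.colptr(ei[e]) + l;
      const double* src = HWt.colptr(ej[e]) + l;
      for (int d = 0; d < dh; ++d) dst[d] += a * src[d];
    }
  }
  c.Spre = St.t();
  c.Out = elu ? elu_f(c.Spre) : c.Spre;
}

static mat gat_backward(const mat& Z, const mat& W, const mat& a1, const mat& a2,
                        const Graph& g, int heads, int dh, double slope, bool elu,
                        const GATCache& c, const mat& dOut,
                        mat& dW, mat& da1, mat& da2) {
  const uword n = Z.n_rows, E = g.ei.n_elem;
  mat dS = elu ? mat(dOut % elu_g(c.Spre)) : dOut;
  mat dSt = dS.t();
  mat HWt = c.HW.t();
  mat dHWt((uword)heads * dh, n, fill::zeros);
  da1.zeros(dh, heads); da2.zeros(dh, heads);
  vec dalpha(E), de(E), ds1(n), ds2(n);
  const uword* ei = g.ei.memptr();
  const uword* ej = g.ej.memptr();
  for (int h = 0; h < heads; ++h) {
    const uword l = (uword)h * dh, r = l + dh - 1;
    const double* Ep = c.Epre.colptr(h);
    const double* Al = c.Alpha.colptr(h);
    for (uword e = 0; e < E; ++e) {
      const double* dsi = dSt.colptr(ei[e]) + l;
      const double* hwj = HWt.colptr(ej[e]) + l;
      double* dhwj = dHWt.colptr(ej[e]) + l;
      const double a = Al[e];
      double acc = 0.0;
      for (int d = 0; d < dh; ++d) {
        acc += dsi[d] * hwj[d];
        dhwj[d] += a * dsi[d];
      }
      dalpha(e) = acc;
    }
    for (uword i = 0; i < n; ++i) {
      double s = 0.0;
      for (uword e = g.ptr(i); e < g.ptr(i + 1); ++e) s += Al[e] * dalpha(e);
      for (uword e = g.ptr(i); e < g.ptr(i + 1); ++e)
        de(e) = Al[e] * (dalpha(e) - s);
    }
    for (uword e = 0; e < E; ++e) de(e) *= (Ep[e] > 0 ? 1.0 : slope);
    ds1.zeros(); ds2.zeros();
    for (uword e = 0; e < E; ++e) { ds1(ei[e]) += de(e); ds2(ej[e]) += de(e); }
    da1.col(h) = HWt.rows(l, r) * ds1;
    da2.col(h) = HWt.rows(l, r) * ds2;
    dHWt.rows(l, r) += a1.col(h) * ds1.t() + a2.col(h) * ds2.t();
  }
  mat dHW = dHWt.t();
  dW = Z.t() * dHW;
  return dHW * W.t();
}

// ------------------------------------------------------------------ branch

static void branch_forward(const mat& X, const ViewParams& p, const Graph& g,
                           const Config& cf, const std::array<mat, 3>* masks,
                           BranchCache& c) {
  fc_forward(X, p, cf, masks, c.fc);
  gat_forward(c.fc.O3, p.G1W, p.G1a1, p.G1a2, g, cf.heads, cf.dh, cf.slope, true, c.g1);
  gat_forward(c.g1.Out, p.G2W, p.G2a1, p.G2a2, g, 1, cf.dh, cf.slope, false, c.g2);
  c.logits = c.g2.Out * p.OW;
  c.logits.each_row() += p.Ob.row(0);
  c.probs = softmax_rows(c.logits);
}

static void branch_backward(const mat& X, const ViewParams& p, const Graph& g,
                            const Config& cf, const std::array<mat, 3>* masks,
                            const BranchCache& c, const mat& dlogits,
                            ViewParams& grad, mat* dX = nullptr) {
  grad.OW = c.g2.Out.t() * dlogits;
  grad.Ob = sum(dlogits, 0);
  mat dH2 = dlogits * p.OW.t();
  mat dH1 = gat_backward(c.g1.Out, p.G2W, p.G2a1, p.G2a2, g, 1, cf.dh, cf.slope,
                         false, c.g2, dH2, grad.G2W, grad.G2a1, grad.G2a2);
  mat dZ = gat_backward(c.fc.O3, p.G1W, p.G1a1, p.G1a2, g, cf.heads, cf.dh,
                        cf.slope, true, c.g1, dH1, grad.G1W, grad.G1a1, grad.G1a2);
  fc_backward(X, p, cf, c.fc, masks, dZ, grad, dX);
}

// ------------------------------------------------------------------ fusion

// digits(t, v): class index of view v in flat cell t; view 0 is the slowest
// axis (row-major flattening).
static umat tensor_digits(int C, int m) {
  int K = 1; for (int v = 0; v < m; ++v) K *= C;
  umat D(K, m);
  for (int t = 0; t < K; ++t) {
    int rem = t;
    for (int v = 0; v < m; ++v) {
      int stride = 1; for (int u = v + 1; u < m; ++u) stride *= C;
      D(t, v) = rem / stride;
      rem %= stride;
    }
  }
  return D;
}

static mat build_tensor(const std::vector<BranchCache>& br, const umat& dig) {
  const uword n = br[0].probs.n_rows, K = dig.n_rows, m = dig.n_cols;
  mat T(n, K);
  for (uword j = 0; j < n; ++j)
    for (uword t = 0; t < K; ++t) {
      double v = 1.0;
      for (uword u = 0; u < m; ++u) v *= br[u].probs(j, dig(t, u));
      T(j, t) = v;
    }
  return T;
}

// ------------------------------------------------------------- conversions

static mat get_m(const List& L, const char* nm) { return Rcpp::as<mat>(L[nm]); }

static ViewParams view_from_list(const List& L) {
  ViewParams p;
  p.W1 = get_m(L, "W1"); p.b1 = get_m(L, "b1");
  p.W2 = get_m(L, "W2"); p.b2 = get_m(L, "b2");
  p.W3 = get_m(L, "W3"); p.b3 = get_m(L, "b3");
  p.G1W = get_m(L, "G1W"); p.G1a1 = get_m(L, "G1a1"); p.G1a2 = get_m(L, "G1a2");
  p.G2W = get_m(L, "G2W"); p.G2a1 = get_m(L, "G2a1"); p.G2a2 = get_m(L, "G2a2");
  p.OW = get_m(L, "OW"); p.Ob = get_m(L, "Ob");
  return p;
}

static List view_to_list(const ViewParams& p) {
  return List::create(
    Named("W1") = p.W1, Named("b1") = p.b1, Named("W2") = p.W2,
    Named("b2") = p.b2, Named("W3") = p.W3, Named("b3") = p.b3,
    Named("G1W") = p.G1W, Named("G1a1") = p.G1a1, Named("G1a2") = p.G1a2,
    Named("G2W") = p.G2W, Named("G2a1") = p.G2a1, Named("G2a2") = p.G2a2,
    Named("OW") = p.OW, Named("Ob") = p.Ob);
}

static FusionParams fusion_from_list(const List& L) {
  FusionParams f;
  f.W1 = get_m(L, "W1"); f.b1 = get_m(L, "b1");
  f.W2 = get_m(L, "W2"); f.b2 = get_m(L, "b2");
  return f;
}

static List fusion_to_list(const FusionParams& f) {
  return List::create(Named("W1") = f.W1, Named("b1") = f.b1,
                      Named("W2") = f.W2, Named("b2") = f.b2);
}

static Graph graph_from_r(const IntegerVector& ei, const IntegerVector& ej,
                          const IntegerVector& ptr) {
  Graph g;
  g.ei = Rcpp::as<uvec>(ei); g.ej = Rcpp::as<uvec>(ej); g.ptr = Rcpp::as<uvec>(ptr);
  return g;
}

static void unpack_model(const List& params, std::vector<ViewParams>& P,
                         FusionParams& F, bool& has_fusion) {
  List views = params["views"];
  P.clear();
  for (int v = 0; v < views.size(); ++v) P.push_back(view_from_list(views[v]));
  has_fusion = params.containsElementNamed("fusion") &&
               !Rf_isNull(params["fusion"]);
  if (has_fusion) F = fusion_from_list(params["fusion"]);
}

// -------------------------------------------------------------- loss + grad

// Forward pass over all branches (and fusion if active); optionally computes
// gradients of total = sum(branch CE) + delta * fusion CE, means over train.
static double model_pass(const std::vector<mat>& Xs, const std::vector<Graph>& graphs,
                         const ivec& y, const uvec& tr,
                         const std::vector<ViewParams>& P, const FusionParams& F,
                         bool fuse, const Config& cf,
                         const std::vector<std::array<mat, 3>>* masks,
                         bool want_grad,
                         std::vector<ViewParams>& G, FusionParams& GF,
                         vec& branch_losses, double& fusion_loss,
                         std::vector<BranchCache>& br, mat& fused_probs,
                         std::vector<mat>* dXs = nullptr) {
  const int m = (int)Xs.size();
  const uword ntr = tr.n_elem;
  br.assign(m, BranchCache());
  for (int v = 0; v < m; ++v)
    branch_forward(Xs[v], P[v], graphs[v], cf,
                   masks ? &((*masks)[v]) : nullptr, br[v]);

  branch_losses.set_size(m);
  for (int v = 0; v < m; ++v) {
    double L = 0.0;
    for (uword k = 0; k < ntr; ++k)
      L -= std::log(std::max(br[v].probs(tr(k), (uword)y(tr(k))), P_FLOOR));
    branch_losses(v) = L / ntr;
  }

  umat dig;
  mat T, F1pre, F1a, logits2;
  fusion_loss = 0.0;
  if (fuse) {
    dig = tensor_digits(cf.C, m);
    T = build_tensor(br, dig);
    F1pre = T * F.W1; F1pre.each_row() += F.b1.row(0);
    F1a = leaky_f(F1pre, cf.slope);
    logits2 = F1a * F.W2; logits2.each_row() += F.b2.row(0);
    fused_probs = softmax_rows(logits2);
    double L = 0.0;
    for (uword k = 0; k < ntr; ++k)
      L -= std::log(std::max(fused_probs(tr(k), (uword)y(tr(k))), P_FLOOR));
    fusion_loss = L / ntr;
  }
  double total = accu(branch_losses) + (fuse ? cf.delta * fusion_loss : 0.0);
  if (!want_grad) return total;

  // branch CE gradient on logits
  const uword n = Xs[0].n_rows;
  std::vector<mat> dlogits(m);
  for (int v = 0; v < m; ++v) {
    dlogits[v].zeros(n, cf.C);
    for (uword k = 0; k < ntr; ++k) {
      const uword i = tr(k);
      dlogits[v].row(i) = br[v].probs.row(i) / (double)ntr;
      dlogits[v](i, (uword)y(i)) -= 1.0 / ntr;
    }
  }

  if (fuse) {
    mat dlogits2(n, cf.C, fill::zeros);
    for (uword k = 0; k < ntr; ++k) {
      const uword i = tr(k);
      dlogits2.row(i) = cf.delta * fused_probs.row(i) / (double)ntr;
      dlogits2(i, (uword)y(i)) -= cf.delta / ntr;
    }
    GF.W2 = F1a.t() * dlogits2;
    GF.b2 = sum(dlogits2, 0);
    mat dF1 = (dlogits2 * F.W2.t()) % leaky_g(F1pre, cf.slope);
    GF.W1 = T.t() * dF1;
    GF.b1 = sum(dF1, 0);
    mat dT = dF1 * F.W1.t();
    // tensor backward: dL/dp_v(j,c) = sum over cells with digit_v == c of
    // dT * product of the other views' probabilities
    for (int v = 0; v < m; ++v) {
      mat dp(n, cf.C, fill::zeros);
      for (uword k = 0; k < ntr; ++k) {  // dT is zero off the train rows
        const uword j = tr(k);
        for (uword t = 0; t < dig.n_rows; ++t) {
          double prod = 1.0;
          for (int u = 0; u < m; ++u)
            if (u != v) prod *= br[u].probs(j, dig(t, u));
          dp(j, dig(t, v)) += dT(j, t) * prod;
        }
      }
      // through the branch softmax: dlogit = p .* (dp - <p, dp>)
      for (uword k = 0; k < ntr; ++k) {
        const uword j = tr(k);
        double s = dot(br[v].probs.row(j), dp.row(j));
        dlogits[v].row(j) += br[v].probs.row(j) % (dp.row(j) - s);
      }
    }
  }

  G.assign(m, ViewParams());
  if (dXs) dXs->assign(m, mat());
  for (int v = 0; v < m; ++v)
    branch_backward(Xs[v], P[v], graphs[v], cf,
                    masks ? &((*masks)[v]) : nullptr, br[v], dlogits[v], G[v],
                    dXs ? &((*dXs)[v]) : nullptr);
  return total;
}

// --------------------------------------------------------------------- Adam

struct Adam {
  std::vector<mat*> par;
  std::vector<mat> m1, m2;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(std::vector<mat*> p, double lr_) {
    par = p; lr = lr_;
    m1.clear(); m2.clear();
    for (mat* w : par) { m1.emplace_back(size(*w), fill::zeros);
                         m2.emplace_back(size(*w), fill::zeros); }
  }
  void step(const std::vector<mat*>& grads) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t k = 0; k < par.size(); ++k) {
      m1[k] = b1 * m1[k] + (1 - b1) * (*grads[k]);
      m2[k] = b2 * m2[k] + (1 - b2) * square(*grads[k]);
      *par[k] -= lr * (m1[k] / c1) / (sqrt(m2[k] / c2) + eps);
    }
  }
};

static std::vector<mat*> collect(std::vector<ViewParams>& P, FusionParams* F) {
  std::vector<mat*> out;
  for (auto& p : P)
    for (mat* w : {&p.W1, &p.b1, &p.W2, &p.b2, &p.W3, &p.b3,
                   &p.G1W, &p.G1a1, &p.G1a2, &p.G2W, &p.G2a1, &p.G2a2,
                   &p.OW, &p.Ob})
      out.push_back(w);
  if (F) for (mat* w : {&F->W1, &F->b1, &F->W2, &F->b2}) out.push_back(w);
  return out;
}

// ------------------------------------------------------------------ inputs

static void unpack_data(const List& Xs_, const List& ei_, const List& ej_,
                        const List& ptr_, std::vector<mat>& Xs,
                        std::vector<Graph>& graphs) {
  const int m = Xs_.size();
  Xs.clear(); graphs.clear();
  for (int v = 0; v < m; ++v) {
    Xs.push_back(Rcpp::as<mat>(Xs_[v]));
    graphs.push_back(graph_from_r(ei_[v], ej_[v], ptr_[v]));
  }
}

// ----------------------------------------------------------------- exports

// [[Rcpp::export]]
List cpp_branch_forward(const arma::mat& X, const IntegerVector& ei,
                        const IntegerVector& ej, const IntegerVector& ptr,
                        const List& vparams, int heads, int dh, double slope,
                        bool use_ln) {
  Config cf; cf.heads = heads; cf.dh = dh; cf.C = 0; cf.slope = slope;
  cf.delta = 0; cf.use_vcdn = false; cf.use_ln = use_ln;
  ViewParams p = view_from_list(vparams);
  Graph g = graph_from_r(ei, ej, ptr);
  BranchCache c;
  branch_forward(X, p, g, cf, nullptr, c);
  return List::create(Named("probs") = c.probs, Named("logits") = c.logits,
                      Named("fc_out") = c.fc.O3, Named("h1") = c.g1.Out,
                      Named("h2") = c.g2.Out, Named("alpha1") = c.g1.Alpha,
                      Named("alpha2") = c.g2.Alpha);
}

// [[Rcpp::export]]
List cpp_forward(const List& Xs_, const List& ei_, const List& ej_,
                 const List& ptr_, const List& params, int C, int heads,
                 int dh, double slope, bool use_vcdn, bool use_ln) {
  std::vector<mat> Xs; std::vector<Graph> graphs;
  unpack_data(Xs_, ei_, ej_, ptr_, Xs, graphs);
  std::vector<ViewParams> P; FusionParams F; bool has_fusion;
  unpack_model(params, P, F, has_fusion);
  Config cf; cf.heads = heads; cf.dh = dh; cf.C = C; cf.slope = slope;
  cf.delta = 1.0; cf.use_vcdn = use_vcdn; cf.use_ln = use_ln;
  const int m = (int)Xs.size();
  const bool fuse = use_vcdn && m >= 2 && has_fusion;

  std::vector<BranchCache> br(m);
  for (int v = 0; v < m; ++v)
    branch_forward(Xs[v], P[v], graphs[v], cf, nullptr, br[v]);
  List bp(m);
  for (int v = 0; v < m; ++v) bp[v] = br[v].probs;
  if (!fuse) return List::create(Named("branch_probs") = bp,
                                 Named("fused") = R_NilValue);
  umat dig = tensor_digits(C, m);
  mat T = build_tensor(br, dig);
  mat F1 = leaky_f(T * F.W1 + repmat(F.b1.row(0), T.n_rows, 1), slope);
  mat logits2 = F1 * F.W2 + repmat(F.b2.row(0), T.n_rows, 1);
  return List::create(Named("branch_probs") = bp,
                      Named("fused") = softmax_rows(logits2));
}

// [[Rcpp::export]]
List cpp_loss_grad(const List& Xs_, const List& ei_, const List& ej_,
                   const List& ptr_, const IntegerVector& y_,
                   const IntegerVector& tr_, const List& params, int C,
                   int heads, int dh, double slope, double delta,
                   bool use_vcdn, bool use_ln) {
  std::vector<mat> Xs; std::vector<Graph> graphs;
  unpack_data(Xs_, ei_, ej_, ptr_, Xs, graphs);
  std::vector<ViewParams> P; FusionParams F; bool has_fusion;
  unpack_model(params, P, F, has_fusion);
  Config cf; cf.heads = heads; cf.dh = dh; cf.C = C; cf.slope = slope;
  cf.delta = delta; cf.use_vcdn = use_vcdn; cf.use_ln = use_ln;
  const int m = (int)Xs.size();
  const bool fuse = use_vcdn && m >= 2 && has_fusion;
  ivec y = Rcpp::as<ivec>(y_);
  uvec tr = Rcpp::as<uvec>(tr_);

  std::vector<ViewParams> G; FusionParams GF;
  vec bl; double fl; std::vector<BranchCache> br; mat fp;
  std::vector<mat> dXs;
  double total = model_pass(Xs, graphs, y, tr, P, F, fuse, cf, nullptr, true,
                            G, GF, bl, fl, br, fp, &dXs);
  List gv(m), gx(m);
  for (int v = 0; v < m; ++v) { gv[v] = view_to_list(G[v]); gx[v] = dXs[v]; }
  SEXP gf = fuse ? (SEXP)Rcpp::wrap(fusion_to_list(GF)) : R_NilValue;
  List grads = List::create(Named("views") = gv, Named("fusion") = gf,
                            Named("X") = gx);
  return List::create(Named("total") = total, Named("branch_losses") = bl,
                      Named("fusion_loss") = fuse ? fl : NA_REAL,
                      Named("grads") = grads);
}

// [[Rcpp::export]]
List cpp_train(const List& Xs_, const List& ei_, const List& ej_,
               const List& ptr_, const IntegerVector& y_,
               const IntegerVector& tr_, const List& params, int C, int heads,
               int dh, double slope, double delta, bool use_vcdn, bool use_ln,
               double lr, int epochs, double dropout, int seed) {
  std::vector<mat> Xs; std::vector<Graph> graphs;
  unpack_data(Xs_, ei_, ej_, ptr_, Xs, graphs);
  std::vector<ViewParams> P; FusionParams F; bool has_fusion;
  unpack_model(params, P, F, has_fusion);
  Config cf; cf.heads = heads; cf.dh = dh; cf.C = C; cf.slope = slope;
  cf.delta = delta; cf.use_vcdn = use_vcdn; cf.use_ln = use_ln;
  const int m = (int)Xs.size();
  const bool fuse = use_vcdn && m >= 2 && has_fusion;
  ivec y = Rcpp::as<ivec>(y_);
  uvec tr = Rcpp::as<uvec>(tr_);
  const uword n = Xs[0].n_rows;

  Adam adam;
  adam.init(collect(P, fuse ? &F : nullptr), lr);

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keep = 1.0 - dropout;

  mat loss_log(epochs, m + 2);
  std::vector<std::array<mat, 3>> masks(m);
  for (int ep = 0; ep < epochs; ++ep) {
    const std::vector<std::array<mat, 3>>* mk = nullptr;
    if (dropout > 0) {
      for (int v = 0; v < m; ++v)
        for (int l = 0; l < 3; ++l) {
          const uword d = (l == 0) ? P[v].W1.n_cols
                        : (l == 1) ? P[v].W2.n_cols : P[v].W3.n_cols;
          masks[v][l].set_size(n, d);
          for (uword a = 0; a < n; ++a)
            for (uword b = 0; b < d; ++b)
              masks[v][l](a, b) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
        }
      mk = &masks;
    }
    std::vector<ViewParams> G; FusionParams GF;
    vec bl; double fl; std::vector<BranchCache> br; mat fp;
    double total = model_pass(Xs, graphs, y, tr, P, F, fuse, cf, mk, true,
                              G, GF, bl, fl, br, fp);
    if (!std::isfinite(total))
      Rcpp::stop("training loss became non-finite at epoch %d", ep + 1);
    std::vector<mat*> g = collect(G, fuse ? &GF : nullptr);
    adam.step(g);
    for (int v = 0; v < m; ++v) loss_log(ep, v) = bl(v);
    loss_log(ep, m) = fuse ? fl : NA_REAL;
    loss_log(ep, m + 1) = total;
    if (ep % 20 == 0) Rcpp::checkUserInterrupt();
  }

  List pv(m);
  for (int v = 0; v < m; ++v) pv[v] = view_to_list(P[v]);
  SEXP fp_out = fuse ? (SEXP)Rcpp::wrap(fusion_to_list(F)) : R_NilValue;
  List out_params = List::create(Named("views") = pv, Named("fusion") = fp_out);
  return List::create(Named("params") = out_params, Named("log") = loss_log);
}
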