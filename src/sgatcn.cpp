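// Stacked graph-attention + convolution network: forward pass and
// analytic backpropagation. One two-layer GAT stack is shared across
// the four band snapshots; the per-band node embeddings are stacked
// as channels of a 2-D valid convolution, flattened, and classified
// by a softmax head.
//
// Parameter list (named):
//   W1 (F0 x F1), a1s (F1), a1d (F1)   first GAT layer
//   W2 (F1 x F2), a2s (F2), a2d (F2)   second GAT layer
//   K  (filters x C*kr*kc), bconv (filters)
//   Wfc (classes x flat), bfc (classes)
//   conv_kernel (kr, kc), leaky_slope
// Attention logits use e_ij = LeakyReLU(a_src.Wh_i + a_dst.Wh_j),
// softmax over each node's closed neighbourhood (self-loop added);
// node update nonlinearity is ELU.
//
// Internals run in transposed (feature-major) layout with the
// attention coefficients stored along the CSR support, so the hot
// loops are contiguous axpy/dot operations of length F.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double leaky1(double x, double slope) {
  return x > 0 ? x : slope * x;
}

// closed neighbourhoods (self-loop first) in CSR form: indptr has
// N+1 entries, indices holds each node's closed neighbourhood
struct NbCsr {
  std::vector<int> indptr;
  std::vector<int> indices;
  uword n_nodes() const { return indptr.size() - 1; }
  uword nnz() const { return indices.size(); }
};

static NbCsr neighbour_csr(const mat& A) {
  uword N = A.n_rows;
  NbCsr nb;
  nb.indptr.reserve(N + 1);
  nb.indptr.push_back(0);
  for (uword i = 0; i < N; ++i) {
    nb.indices.push_back(i);
    for (uword j = 0; j < N; ++j) {
      if (j != i && A(j, i) > 0.5) nb.indices.push_back(j);
    }
    nb.indptr.push_back(nb.indices.size());
  }
  return nb;
}

static NbCsr csr_from_r(const Rcpp::List& l) {
  NbCsr nb;
  Rcpp::IntegerVector ip = l["indptr"];
  Rcpp::IntegerVector ix = l["indices"];
  nb.indptr.assign(ip.begin(), ip.end());
  nb.indices.assign(ix.begin(), ix.end());
  return nb;
}

struct Params {
  mat W1, W2, K, Wfc;
  vec a1s, a1d, a2s, a2d, bconv, bfc;
  uword kr, kc;
  double slope;
};

static Params unpack(const Rcpp::List& params) {
  Params p;
  p.W1 = Rcpp::as<mat>(params["W1"]);
  p.W2 = Rcpp::as<mat>(params["W2"]);
  p.K = Rcpp::as<mat>(params["K"]);
  p.Wfc = Rcpp::as<mat>(params["Wfc"]);
  p.a1s = Rcpp::as<vec>(params["a1s"]);
  p.a1d = Rcpp::as<vec>(params["a1d"]);
  p.a2s = Rcpp::as<vec>(params["a2s"]);
  p.a2d = Rcpp::as<vec>(params["a2d"]);
  p.bconv = Rcpp::as<vec>(params["bconv"]);
  p.bfc = Rcpp::as<vec>(params["bfc"]);
  Rcpp::IntegerVector kdim = params["conv_kernel"];
  p.kr = kdim[0];
  p.kc = kdim[1];
  p.slope = Rcpp::as<double>(params["leaky_slope"]);
  return p;
}

struct Grads {
  mat W1, W2, K, Wfc;
  vec a1s, a1d, a2s, a2d, bconv, bfc;
  void zero_like(const Params& p) {
    W1.zeros(size(p.W1));
    W2.zeros(size(p.W2));
    K.zeros(size(p.K));
    Wfc.zeros(size(p.Wfc));
    a1s.zeros(size(p.a1s));
    a1d.zeros(size(p.a1d));
    a2s.zeros(size(p.a2s));
    a2d.zeros(size(p.a2d));
    bconv.zeros(size(p.bconv));
    bfc.zeros(size(p.bfc));
  }
  void scale(double f) {
    W1 *= f; W2 *= f; K *= f; Wfc *= f;
    a1s *= f; a1d *= f; a2s *= f; a2d *= f;
    bconv *= f; bfc *= f;
  }
};

// one GAT layer, transposed layout: Xt is F_in x N, Ht is F_out x N
struct GatCache {
  mat Xt, Zt, Pt, Ht;
  vec s, t;
  std::vector<double> aval; // attention, aligned with nb.indices
};

static void gat_forward(const mat& Xt, const NbCsr& nb, const mat& W,
                        const vec& as_, const vec& ad_, double slope,
                        GatCache& c) {
  c.Xt = Xt;
  c.Zt = W.t() * Xt; // F' x N
  c.s = (as_.t() * c.Zt).t();
  c.t = (ad_.t() * c.Zt).t();
  uword N = Xt.n_cols;
  uword Fp = c.Zt.n_rows;
  c.aval.resize(nb.nnz());
  for (uword i = 0; i < N; ++i) {
    int lo = nb.indptr[i], hi = nb.indptr[i + 1];
    double si = c.s(i);
    double mx = -std::numeric_limits<double>::infinity();
    for (int k = lo; k < hi; ++k) {
      double e = leaky1(si + c.t(nb.indices[k]), slope);
      if (e > mx) mx = e;
    }
    double tot = 0.0;
    for (int k = lo; k < hi; ++k) {
      double v = std::exp(leaky1(si + c.t(nb.indices[k]), slope) - mx);
      c.aval[k] = v;
      tot += v;
    }
    for (int k = lo; k < hi; ++k) c.aval[k] /= tot;
  }
  c.Pt.zeros(Fp, N);
  for (uword i = 0; i < N; ++i) {
    int lo = nb.indptr[i], hi = nb.indptr[i + 1];
    double* pi = c.Pt.colptr(i);
    for (int k = lo; k < hi; ++k) {
      const double* zj = c.Zt.colptr(nb.indices[k]);
      double a = c.aval[k];
      for (uword f = 0; f < Fp; ++f) pi[f] += a * zj[f];
    }
  }
  c.Ht = c.Pt;
  for (uword q = 0; q < c.Ht.n_elem; ++q) {
    if (c.Ht(q) <= 0) c.Ht(q) = std::exp(c.Ht(q)) - 1.0; // ELU
  }
}

// backward; accumulates dW, das, dad; returns dXt
static mat gat_backward(const GatCache& c, const NbCsr& nb, const mat& W,
                        const vec& as_, const vec& ad_, const mat& dHt,
                        double slope, mat& dW, vec& das, vec& dad) {
  uword N = c.Xt.n_cols;
  uword Fp = c.Zt.n_rows;
  mat dPt = dHt;
  for (uword q = 0; q < dPt.n_elem; ++q) {
    // ELU'(x) = 1 for x > 0, exp(x) = H + 1 otherwise
    if (c.Pt(q) <= 0) dPt(q) *= c.Ht(q) + 1.0;
  }
  // dAlpha on the support only, then softmax/leaky backward
  vec ds(N, fill::zeros), dt(N, fill::zeros);
  std::vector<double> dAl(nb.nnz());
  for (uword i = 0; i < N; ++i) {
    int lo = nb.indptr[i], hi = nb.indptr[i + 1];
    const double* dpi = dPt.colptr(i);
    double rowdot = 0.0;
    for (int k = lo; k < hi; ++k) {
      const double* zj = c.Zt.colptr(nb.indices[k]);
      double acc = 0.0;
      for (uword f = 0; f < Fp; ++f) acc += dpi[f] * zj[f];
      dAl[k] = acc;
      rowdot += c.aval[k] * acc;
    }
    double si = c.s(i);
    for (int k = lo; k < hi; ++k) {
      int j = nb.indices[k];
      double de = c.aval[k] * (dAl[k] - rowdot);
      double deraw = de * (si + c.t(j) > 0 ? 1.0 : slope);
      ds(i) += deraw;
      dt(j) += deraw;
    }
  }
  // dZ from P = sum_j alpha_ij Z_j
  mat dZt(Fp, N, fill::zeros);
  for (uword i = 0; i < N; ++i) {
    int lo = nb.indptr[i], hi = nb.indptr[i + 1];
    const double* dpi = dPt.colptr(i);
    for (int k = lo; k < hi; ++k) {
      double* dzj = dZt.colptr(nb.indices[k]);
      double a = c.aval[k];
      for (uword f = 0; f < Fp; ++f) dzj[f] += a * dpi[f];
    }
  }
  dZt += as_ * ds.t() + ad_ * dt.t();
  das += c.Zt * ds;
  dad += c.Zt * dt;
  dW += c.Xt * dZt.t();
  return W * dZt; // dXt
}

// write one band channel's sliding-window patches into the im2col
// matrix; H is stored transposed (F x N), patches read H(i+m, j+n)
static void im2col_fill(mat& cols, const mat& Ht, uword c, uword kr,
                        uword kc, uword orr, uword occ) {
  for (uword m = 0; m < kr; ++m) {
    for (uword n = 0; n < kc; ++n) {
      uword r = c * kr * kc + m * kc + n;
      for (uword i = 0; i < orr; ++i) {
        for (uword j = 0; j < occ; ++j) {
          cols(r, i * occ + j) = Ht(j + n, i + m);
        }
      }
    }
  }
}

struct NetCache {
  std::vector<GatCache> l1, l2; // per band
  std::vector<NbCsr> nb;        // per-band closed neighbourhoods
  mat cols;                     // im2col matrix
  mat convpre;                  // filters x (or*oc) pre-ReLU
  vec flat;                     // flattened ReLU(conv)
  vec logits, probs;
  uword N, F2, orr, occ, C;
};

static void net_forward(const Params& p, const Rcpp::List& adj,
                        const Rcpp::List& feats, NetCache& nc) {
  nc.C = adj.size();
  nc.l1.resize(nc.C);
  nc.l2.resize(nc.C);
  nc.nb.clear();
  for (uword b = 0; b < nc.C; ++b) {
    Rcpp::RObject a = adj[b];
    mat X = feats[b];
    if (Rf_isMatrix(a)) {
      nc.nb.push_back(neighbour_csr(Rcpp::as<mat>(a)));
    } else {
      nc.nb.push_back(csr_from_r(Rcpp::List(a)));
    }
    mat Xt = X.t();
    gat_forward(Xt, nc.nb[b], p.W1, p.a1s, p.a1d, p.slope, nc.l1[b]);
    gat_forward(nc.l1[b].Ht, nc.nb[b], p.W2, p.a2s, p.a2d, p.slope,
                nc.l2[b]);
  }
  nc.N = nc.l2[0].Ht.n_cols;
  nc.F2 = nc.l2[0].Ht.n_rows;
  if (p.kr > nc.N || p.kc > nc.F2)
    Rcpp::stop("convolution kernel larger than the embedding plane");
  nc.orr = nc.N - p.kr + 1;
  nc.occ = nc.F2 - p.kc + 1;
  nc.cols.set_size(nc.C * p.kr * p.kc, nc.orr * nc.occ);
  for (uword c = 0; c < nc.C; ++c) {
    im2col_fill(nc.cols, nc.l2[c].Ht, c, p.kr, p.kc, nc.orr, nc.occ);
  }
  nc.convpre = p.K * nc.cols;
  nc.convpre.each_col() += p.bconv;
  mat act = nc.convpre % (nc.convpre > 0); // ReLU
  nc.flat = vectorise(act.t());            // filter-major blocks
  nc.logits = p.Wfc * nc.flat + p.bfc;
  vec z = nc.logits - nc.logits.max();
  vec ez = exp(z);
  nc.probs = ez / accu(ez);
}

static double net_backward(const Params& p, NetCache& nc, int label,
                           Grads& g) {
  double loss = -std::log(std::max(nc.probs(label), 1e-300));
  vec dlogits = nc.probs;
  dlogits(label) -= 1.0;
  g.Wfc += dlogits * nc.flat.t();
  g.bfc += dlogits;
  vec dflat = p.Wfc.t() * dlogits;
  uword plane = nc.orr * nc.occ;
  mat dact(plane, p.K.n_rows);
  for (uword f = 0; f < p.K.n_rows; ++f)
    dact.col(f) = dflat.subvec(f * plane, (f + 1) * plane - 1);
  mat dconvpre = dact.t() % (nc.convpre > 0);
  g.K += dconvpre * nc.cols.t();
  g.bconv += sum(dconvpre, 1);
  mat dcols = p.K.t() * dconvpre;
  for (uword c = 0; c < nc.C; ++c) {
    mat dH2t(nc.F2, nc.N, fill::zeros);
    for (uword m = 0; m < p.kr; ++m) {
      for (uword n = 0; n < p.kc; ++n) {
        uword r = c * p.kr * p.kc + m * p.kc + n;
        for (uword i = 0; i < nc.orr; ++i) {
          for (uword j = 0; j < nc.occ; ++j) {
            dH2t(j + n, i + m) += dcols(r, i * nc.occ + j);
          }
        }
      }
    }
    mat dH1t = gat_backward(nc.l2[c], nc.nb[c], p.W2, p.a2s, p.a2d, dH2t,
                            p.slope, g.W2, g.a2s, g.a2d);
    gat_backward(nc.l1[c], nc.nb[c], p.W1, p.a1s, p.a1d, dH1t, p.slope,
                 g.W1, g.a1s, g.a1d);
  }
  return loss;
}

// [[Rcpp::export]]
Rcpp::List sgatcn_forward_cpp(Rcpp::List params, Rcpp::List adj,
                              Rcpp::List feats) {
  Params p = unpack(params);
  NetCache nc;
  net_forward(p, adj, feats, nc);
  return Rcpp::List::create(Rcpp::Named("probs") = nc.probs,
                            Rcpp::Named("logits") = nc.logits);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix sgatcn_predict_batch_cpp(Rcpp::List params,
                                             Rcpp::List adj_list,
                                             Rcpp::List feat_list) {
  Params p = unpack(params);
  int B = adj_list.size();
  Rcpp::NumericMatrix probs(B, p.bfc.n_elem);
  NetCache nc;
  for (int s = 0; s < B; ++s) {
    net_forward(p, adj_list[s], feat_list[s], nc);
    for (uword k = 0; k < nc.probs.n_elem; ++k) probs(s, k) = nc.probs(k);
  }
  return probs;
}

// [[Rcpp::export]]
Rcpp::List sgatcn_batch_grad_cpp(Rcpp::List params, Rcpp::List adj_list,
                                 Rcpp::List feat_list,
                                 Rcpp::IntegerVector labels) {
  Params p = unpack(params);
  int B = adj_list.size();
  Grads g;
  g.zero_like(p);
  double loss = 0.0;
  Rcpp::NumericMatrix probs(B, p.bfc.n_elem);
  NetCache nc;
  for (int s = 0; s < B; ++s) {
    net_forward(p, adj_list[s], feat_list[s], nc);
    loss += net_backward(p, nc, labels[s], g);
    for (uword k = 0; k < nc.probs.n_elem; ++k) probs(s, k) = nc.probs(k);
  }
  g.scale(1.0 / B);
  Rcpp::List grads = Rcpp::List::create(
      Rcpp::Named("W1") = g.W1, Rcpp::Named("a1s") = g.a1s,
      Rcpp::Named("a1d") = g.a1d, Rcpp::Named("W2") = g.W2,
      Rcpp::Named("a2s") = g.a2s, Rcpp::Named("a2d") = g.a2d,
      Rcpp::Named("K") = g.K, Rcpp::Named("bconv") = g.bconv,
      Rcpp::Named("Wfc") = g.Wfc, Rcpp::Named("bfc") = g.bfc);
  return Rcpp::List::create(Rcpp::Named("loss") = loss / B,
                            Rcpp::Named("grads") = grads,
                            Rcpp::Named("probs") = probs);
}

// Precompute a graph's closed-neighbourhood CSR lists (one per band)
// so training does not rebuild them from the dense adjacency at
// every epoch.
// [[Rcpp::export]]
Rcpp::List adj_to_csr_cpp(Rcpp::List adj) {
  Rcpp::List out(adj.size());
  for (int b = 0; b < adj.size(); ++b) {
    mat A = adj[b];
    NbCsr nb = neighbour_csr(A);
    out[b] = Rcpp::List::create(
        Rcpp::Named("indptr") = Rcpp::IntegerVector(nb.indptr.begin(),
                                                    nb.indptr.end()),
        Rcpp::Named("indices") = Rcpp::IntegerVector(nb.indices.begin(),
                                                     nb.indices.end()));
  }
  return out;
}

// Convolution stage alone (valid cross-correlation over the
// nodes x embedding plane with bands as input channels, plus ReLU),
// sharing the im2col path of the full forward pass.
// [[Rcpp::export]]
Rcpp::List conv_forward_cpp(Rcpp::List channels, arma::mat K,
                            arma::vec bconv, Rcpp::IntegerVector kernel) {
  uword kr = kernel[0], kc = kernel[1];
  uword C = channels.size();
  mat H0 = channels[0];
  if (kr > H0.n_rows || kc > H0.n_cols)
    Rcpp::stop("convolution kernel larger than the input plane");
  uword orr = H0.n_rows - kr + 1, occ = H0.n_cols - kc + 1;
  mat cols(C * kr * kc, orr * occ);
  for (uword c = 0; c < C; ++c) {
    mat H = channels[c];
    im2col_fill(cols, H.t(), c, kr, kc, orr, occ);
  }
  mat out = K * cols;
  out.each_col() += bconv;
  out = out % (out > 0);
  Rcpp::List maps(K.n_rows);
  for (uword f = 0; f < K.n_rows; ++f) {
    mat m(orr, occ);
    for (uword i = 0; i < orr; ++i)
      for (uword j = 0; j < occ; ++j) m(i, j) = out(f, i * occ + j);
    maps[f] = m;
  }
  return maps;
}

// Per-band GAT embeddings (list of nodes x out matrices) for
// inspection and tests.
// [[Rcpp::export]]
Rcpp::List sgat_embed_cpp(Rcpp::List params, Rcpp::List adj,
                          Rcpp::List feats) {
  Params p = unpack(params);
  Rcpp::List out(adj.size());
  GatCache c1, c2;
  for (int b = 0; b < adj.size(); ++b) {
    Rcpp::RObject a = adj[b];
    mat X = feats[b];
    NbCsr nb = Rf_isMatrix(a) ? neighbour_csr(Rcpp::as<mat>(a))
                              : csr_from_r(Rcpp::List(a));
    mat Xt = X.t();
    gat_forward(Xt, nb, p.W1, p.a1s, p.a1d, p.slope, c1);
    gat_forward(c1.Ht, nb, p.W2, p.a2s, p.a2d, p.slope, c2);
    out[b] = mat(c2.Ht.t());
  }
  return out;
}

// Attention coefficients of a single GAT layer (exposed for tests).
// [[Rcpp::export]]
arma::mat gat_attention_cpp(arma::mat X, arma::mat A, arma::mat W,
                            arma::vec a_src, arma::vec a_dst,
                            double slope = 0.2) {
  NbCsr nb = neighbour_csr(A);
  GatCache c;
  mat Xt = X.t();
  gat_forward(Xt, nb, W, a_src, a_dst, slope, c);
  uword N = X.n_rows;
  mat Alpha(N, N, fill::zeros);
  for (uword i = 0; i < N; ++i) {
    for (int k = nb.indptr[i]; k < nb.indptr[i + 1]; ++k) {
      Alpha(i, nb.indices[k]) = c.aval[k];
    }
  }
  return Alpha;
}

// One GAT layer output (exposed for tests).
// [[Rcpp::export]]
arma::mat gat_layer_cpp(arma::mat X, arma::mat A, arma::mat W,
                        arma::vec a_src, arma::vec a_dst,
                        double slope = 0.2) {
  NbCsr nb = neighbour_csr(A);
  GatCache c;
  mat Xt = X.t();
  gat_forward(Xt, nb, W, a_src, a_dst, slope, c);
  return mat(c.Ht.t());
}
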