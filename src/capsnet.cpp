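// Model core: embedding -> BiLSTM -> capsule layer (dynamic routing) -> dense head,
// with hand-derived backpropagation and Adam. All tensors are double precision.
//
// Conventions used throughout:
//  * token ids are 0-based; id 0 is the padding token whose embedding row is frozen at zero.
//  * LSTM gate blocks are stacked row-wise in the order [input; forget; candidate; output],
//    each of size h, acting on the concatenation [h_{t-1}; x_t].
//  * the capsule transform W is a cube of N_in slices; slice i is a (N_out*d_out) x d_in
//    matrix whose row j*d_out + q gives component q of the prediction vector u_{j|i}.
//  * prediction vectors for one sample are a cube U(d_out, N_out, N_in): U.slice(i).col(j)
//    is u_{j|i}.
//  * softmax_axis: 0 = couplings normalized over output capsules j for fixed input i
//    (capsule-network convention, the default); 1 = over inputs i for fixed j.
//  * squash_variant: 0 = ||s||^2/(1+||s||^2) * s/||s|| (standard); 1 = ||s||/(1+||s||^2) * s/||s||.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

struct Cfg {
  int k, h, L, d_in, n_in, n_out, d_out, r;
  int axis, variant;
  bool use_capsule;
};

static Cfg parse_cfg(const List& c) {
  Cfg g;
  g.k = Rcpp::as<int>(c["embed_dim"]);
  g.h = Rcpp::as<int>(c["hidden"]);
  g.L = Rcpp::as<int>(c["L"]);
  g.d_in = Rcpp::as<int>(c["d_in"]);
  g.n_in = Rcpp::as<int>(c["n_in"]);
  g.n_out = Rcpp::as<int>(c["n_out"]);
  g.d_out = Rcpp::as<int>(c["d_out"]);
  g.r = Rcpp::as<int>(c["routing_iters"]);
  g.axis = Rcpp::as<int>(c["softmax_axis"]);
  g.variant = Rcpp::as<int>(c["squash_variant"]);
  g.use_capsule = Rcpp::as<bool>(c["use_capsule"]);
  if (g.r < 1) Rcpp::stop("routing_iters must be >= 1");
  return g;
}

// ---------------------------------------------------------------- squash

static vec squash_fwd(const vec& s, int variant) {
  double n2 = dot(s, s);
  if (n2 < 1e-300) return zeros<vec>(s.n_elem);
  double n = std::sqrt(n2);
  double alpha = (variant == 0) ? n / (1.0 + n2) : 1.0 / (1.0 + n2);
  return alpha * s;
}

// J^T g for a = alpha(||s||) * s
static vec squash_bwd(const vec& s, const vec& g, int variant) {
  double n2 = dot(s, s);
  if (n2 < 1e-300) {
    // standard: Jacobian -> 0 at the origin; norm1: Jacobian -> identity
    return (variant == 0) ? zeros<vec>(s.n_elem) : g;
  }
  double n = std::sqrt(n2);
  double alpha, dalpha;
  if (variant == 0) {
    alpha = n / (1.0 + n2);
    dalpha = (1.0 - n2) / ((1.0 + n2) * (1.0 + n2));
  } else {
    alpha = 1.0 / (1.0 + n2);
    dalpha = -2.0 * n / ((1.0 + n2) * (1.0 + n2));
  }
  return alpha * g + (dalpha * dot(s, g) / n) * s;
}

// [[Rcpp::export]]
arma::vec cpp_squash(const arma::vec& s, int variant) {
  return squash_fwd(s, variant);
}

// ---------------------------------------------------------------- routing

static mat softmax_axis(const mat& b, int axis) {
  mat c(size(b));
  if (axis == 0) {           // over output capsules j: rows sum to 1
    for (uword i = 0; i < b.n_rows; ++i) {
      rowvec row = b.row(i) - b.row(i).max();
      rowvec e = exp(row);
      c.row(i) = e / accu(e);
    }
  } else {                   // over input capsules i: columns sum to 1
    for (uword j = 0; j < b.n_cols; ++j) {
      vec col = b.col(j) - b.col(j).max();
      vec e = exp(col);
      c.col(j) = e / accu(e);
    }
  }
  return c;
}

// One sample. U: cube(d_out, n_out, n_in). Caches per iteration:
// c_h (n_in x n_out x r), s_h and a_h (d_out x n_out x r). b_final is the last
// computed logit matrix (the agreement update is skipped after the final iteration).
static void routing_fwd(const cube& U, int r, int axis, int variant,
                        cube& c_h, cube& s_h, cube& a_h, mat& b_final) {
  const uword d = U.n_rows, J = U.n_cols, I = U.n_slices;
  c_h.set_size(I, J, r);
  s_h.set_size(d, J, r);
  a_h.set_size(d, J, r);
  mat b(I, J, fill::zeros);
  for (int t = 0; t < r; ++t) {
    mat c = softmax_axis(b, axis);
    mat s(d, J, fill::zeros);
    for (uword i = 0; i < I; ++i)
      for (uword j = 0; j < J; ++j)
        s.col(j) += c(i, j) * U.slice(i).col(j);
    mat a(d, J);
    for (uword j = 0; j < J; ++j) a.col(j) = squash_fwd(s.col(j), variant);
    c_h.slice(t) = c;
    s_h.slice(t) = s;
    a_h.slice(t) = a;
    if (t < r - 1)
      for (uword i = 0; i < I; ++i)
        for (uword j = 0; j < J; ++j)
          b(i, j) += dot(a.col(j), U.slice(i).col(j));
  }
  b_final = b;
}

// Backward through the unrolled routing loop; Ga_final = dL/da at the final iteration.
static cube routing_bwd(const cube& U, const cube& c_h, const cube& s_h, const cube& a_h,
                        const mat& Ga_final, int r, int axis, int variant) {
  const uword d = U.n_rows, J = U.n_cols, I = U.n_slices;
  cube GU(d, J, I, fill::zeros);
  mat Gb(I, J, fill::zeros);        // dL/db entering iteration t (from later iterations)
  for (int t = r - 1; t >= 0; --t) {
    mat Ga(d, J, fill::zeros);
    if (t == r - 1) {
      Ga = Ga_final;
    } else {
      // b_{t+1} = b_t + <a_t, u>: route Gb into a_t and u; identity path stays in Gb
      for (uword i = 0; i < I; ++i)
        for (uword j = 0; j < J; ++j) {
          Ga.col(j) += Gb(i, j) * U.slice(i).col(j);
          GU.slice(i).col(j) += Gb(i, j) * a_h.slice(t).col(j);
        }
    }
    mat Gs(d, J);
    for (uword j = 0; j < J; ++j)
      Gs.col(j) = squash_bwd(s_h.slice(t).col(j), Ga.col(j), variant);
    mat Gc(I, J);
    for (uword i = 0; i < I; ++i)
      for (uword j = 0; j < J; ++j) {
        Gc(i, j) = dot(Gs.col(j), U.slice(i).col(j));
        GU.slice(i).col(j) += c_h.slice(t)(i, j) * Gs.col(j);
      }
    // softmax backward along the chosen axis
    mat Gb_sm(I, J);
    const mat& c = c_h.slice(t);
    if (axis == 0) {
      for (uword i = 0; i < I; ++i) {
        double dd = dot(c.row(i), Gc.row(i));
        Gb_sm.row(i) = c.row(i) % (Gc.row(i) - dd);
      }
    } else {
      for (uword j = 0; j < J; ++j) {
        double dd = dot(c.col(j), Gc.col(j));
        Gb_sm.col(j) = c.col(j) % (Gc.col(j) - dd);
      }
    }
    Gb += Gb_sm;                    // now Gb = dL/db_t
  }
  return GU;
}

// [[Rcpp::export]]
List cpp_dynamic_routing(const arma::cube& U, int r, int axis, int variant) {
  if (r < 1) Rcpp::stop("routing iterations must be >= 1");
  cube c_h, s_h, a_h;
  mat b_final;
  routing_fwd(U, r, axis, variant, c_h, s_h, a_h, b_final);
  int last = r - 1;
  return List::create(
      Named("a") = a_h.slice(last),
      Named("c") = c_h.slice(last),
      Named("b") = b_final,
      Named("s") = s_h.slice(last),
      Named("c_history") = c_h);
}

// [[Rcpp::export]]
List cpp_capsule_forward(const arma::mat& V, const arma::cube& Wcap,
                         int n_out, int d_out, int r, int axis, int variant) {
  // V: d_in x n_in (column i = input capsule v_i)
  const uword I = V.n_cols;
  if (Wcap.n_slices != I) Rcpp::stop("Wcap slice count != number of input capsules");
  if (Wcap.n_cols != V.n_rows) Rcpp::stop("Wcap/d_in shape mismatch");
  cube U(d_out, n_out, I);
  for (uword i = 0; i < I; ++i) {
    vec u = Wcap.slice(i) * V.col(i);
    U.slice(i) = reshape(u, d_out, n_out);
  }
  cube c_h, s_h, a_h;
  mat b_final;
  routing_fwd(U, r, axis, variant, c_h, s_h, a_h, b_final);
  int last = r - 1;
  return List::create(
      Named("a") = a_h.slice(last),
      Named("c") = c_h.slice(last),
      Named("b") = b_final,
      Named("s") = s_h.slice(last),
      Named("u_hat") = U,
      Named("c_history") = c_h);
}

// ---------------------------------------------------------------- LSTM

static mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Batched single-direction pass. X: cube(k, B, L). Outputs H_all/C_all: cube(h, B, L)
// indexed by original position t; Gates: cube(4h, B, L) of gate *activations*.
static void lstm_fwd_batch(const cube& X, const mat& W, const vec& b, bool reverse,
                           int h, cube& H_all, cube& Gates, cube& C_all) {
  const uword k = X.n_rows, B = X.n_cols, L = X.n_slices;
  H_all.set_size(h, B, L);
  C_all.set_size(h, B, L);
  Gates.set_size(4 * h, B, L);
  mat Hprev(h, B, fill::zeros), Cprev(h, B, fill::zeros);
  for (uword step = 0; step < L; ++step) {
    uword t = reverse ? (L - 1 - step) : step;
    mat inp = join_cols(Hprev, X.slice(t));      // (h+k) x B
    mat Z = W * inp;
    Z.each_col() += b;
    mat gi = sigm(Z.rows(0, h - 1));
    mat gf = sigm(Z.rows(h, 2 * h - 1));
    mat gc = tanh(Z.rows(2 * h, 3 * h - 1));
    mat go = sigm(Z.rows(3 * h, 4 * h - 1));
    mat C = gf % Cprev + gi % gc;
    mat H = go % tanh(C);
    Gates.slice(t) = join_cols(join_cols(gi, gf), join_cols(gc, go));
    C_all.slice(t) = C;
    H_all.slice(t) = H;
    Hprev = H;
    Cprev = C;
    (void)k;
  }
}

// BPTT for one direction. dH_out: cube(h, B, L) of output gradients by position.
static void lstm_bwd_batch(const cube& X, const cube& H_all, const cube& Gates,
                           const cube& C_all, const mat& W, bool reverse, int h,
                           const cube& dH_out, mat& dW, vec& db, cube& dX) {
  const uword k = X.n_rows, B = X.n_cols, L = X.n_slices;
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(W.n_rows);
  dX.set_size(k, B, L);
  mat dHnext(h, B, fill::zeros), dCnext(h, B, fill::zeros);
  for (uword step = L; step-- > 0;) {
    // walk processing order backwards
    uword t = reverse ? (L - 1 - step) : step;
    bool first = (step == 0);                    // first processed step in time order
    uword tprev = reverse ? t + 1 : t - 1;       // only valid when !first
    mat dH = dH_out.slice(t) + dHnext;
    mat gi = Gates.slice(t).rows(0, h - 1);
    mat gf = Gates.slice(t).rows(h, 2 * h - 1);
    mat gc = Gates.slice(t).rows(2 * h, 3 * h - 1);
    mat go = Gates.slice(t).rows(3 * h, 4 * h - 1);
    mat tC = tanh(C_all.slice(t));
    mat dO = dH % tC;
    mat dC = dCnext + dH % go % (1.0 - tC % tC);
    mat Cprev = first ? mat(h, B, fill::zeros) : C_all.slice(tprev);
    mat dF = dC % Cprev;
    mat dI = dC % gc;
    mat dG = dC % gi;
    dCnext = dC % gf;
    mat dZ = join_cols(join_cols(dI % gi % (1.0 - gi), dF % gf % (1.0 - gf)),
                       join_cols(dG % (1.0 - gc % gc), dO % go % (1.0 - go)));
    mat Hprev = first ? mat(h, B, fill::zeros) : H_all.slice(tprev);
    mat inp = join_cols(Hprev, X.slice(t));
    dW += dZ * inp.t();
    db += sum(dZ, 1);
    mat dInp = W.t() * dZ;
    dHnext = dInp.rows(0, h - 1);
    dX.slice(t) = dInp.rows(h, h + k - 1);
  }
}

// [[Rcpp::export]]
List cpp_lstm_cell_step(const arma::vec& x, const arma::vec& h0, const arma::vec& C0,
                        const arma::mat& W, const arma::vec& b) {
  int h = h0.n_elem;
  if ((int)W.n_rows != 4 * h || W.n_cols != h0.n_elem + x.n_elem)
    Rcpp::stop("LSTM parameter dimensions inconsistent with state/input");
  vec inp = join_cols(h0, x);
  vec z = W * inp + b;
  vec gi = 1.0 / (1.0 + exp(-z.subvec(0, h - 1)));
  vec gf = 1.0 / (1.0 + exp(-z.subvec(h, 2 * h - 1)));
  vec gc = tanh(z.subvec(2 * h, 3 * h - 1));
  vec go = 1.0 / (1.0 + exp(-z.subvec(3 * h, 4 * h - 1)));
  vec C = gf % C0 + gi % gc;
  vec H = go % tanh(C);
  return List::create(Named("h") = H, Named("C") = C,
                      Named("gates") = List::create(Named("i") = gi, Named("f") = gf,
                                                    Named("c") = gc, Named("o") = go));
}

// [[Rcpp::export]]
arma::mat cpp_bilstm_forward(const arma::mat& X, const arma::mat& Wf, const arma::vec& bf,
                             const arma::mat& Wb, const arma::vec& bb) {
  // X: L x k (row t = embedded token t); returns L x 2h
  const uword L = X.n_rows, k = X.n_cols;
  int h = Wf.n_rows / 4;
  cube Xc(k, 1, L);
  for (uword t = 0; t < L; ++t) Xc.slice(t).col(0) = X.row(t).t();
  cube Hf, Gf, Cf, Hb, Gb, Cb;
  lstm_fwd_batch(Xc, Wf, bf, false, h, Hf, Gf, Cf);
  lstm_fwd_batch(Xc, Wb, bb, true, h, Hb, Gb, Cb);
  mat O(L, 2 * h);
  for (uword t = 0; t < L; ++t) {
    O.row(t).cols(0, h - 1) = Hf.slice(t).col(0).t();
    O.row(t).cols(h, 2 * h - 1) = Hb.slice(t).col(0).t();
  }
  return O;
}

// ---------------------------------------------------------------- parameters

struct Params {
  mat We;
  mat Wlf, Wlb;
  vec blf, blb;
  cube Wcap;
  mat W1, W2, W3;
  vec b1, b2, b3;
  bool use_capsule;
};

static Params params_from_list(const List& p, bool use_capsule) {
  Params P;
  P.use_capsule = use_capsule;
  P.We = Rcpp::as<mat>(p["We"]);
  P.Wlf = Rcpp::as<mat>(p["Wlf"]);
  P.blf = Rcpp::as<vec>(p["blf"]);
  P.Wlb = Rcpp::as<mat>(p["Wlb"]);
  P.blb = Rcpp::as<vec>(p["blb"]);
  if (use_capsule) P.Wcap = Rcpp::as<cube>(p["Wcap"]);
  P.W1 = Rcpp::as<mat>(p["W1"]);
  P.b1 = Rcpp::as<vec>(p["b1"]);
  P.W2 = Rcpp::as<mat>(p["W2"]);
  P.b2 = Rcpp::as<vec>(p["b2"]);
  P.W3 = Rcpp::as<mat>(p["W3"]);
  P.b3 = Rcpp::as<vec>(p["b3"]);
  return P;
}

static List params_to_list(const Params& P) {
  List out = List::create(
      Named("We") = P.We, Named("Wlf") = P.Wlf, Named("blf") = P.blf,
      Named("Wlb") = P.Wlb, Named("blb") = P.blb,
      Named("W1") = P.W1, Named("b1") = P.b1, Named("W2") = P.W2, Named("b2") = P.b2,
      Named("W3") = P.W3, Named("b3") = P.b3);
  if (P.use_capsule) out["Wcap"] = P.Wcap;
  return out;
}

// flat views over every tensor, for Adam / clipping
struct View { double* ptr; uword n; };
static std::vector<View> views(Params& P) {
  std::vector<View> v;
  auto add = [&](double* p, uword n) { v.push_back({p, n}); };
  add(P.We.memptr(), P.We.n_elem);
  add(P.Wlf.memptr(), P.Wlf.n_elem);
  add(P.blf.memptr(), P.blf.n_elem);
  add(P.Wlb.memptr(), P.Wlb.n_elem);
  add(P.blb.memptr(), P.blb.n_elem);
  if (P.use_capsule) add(P.Wcap.memptr(), P.Wcap.n_elem);
  add(P.W1.memptr(), P.W1.n_elem);
  add(P.b1.memptr(), P.b1.n_elem);
  add(P.W2.memptr(), P.W2.n_elem);
  add(P.b2.memptr(), P.b2.n_elem);
  add(P.W3.memptr(), P.W3.n_elem);
  add(P.b3.memptr(), P.b3.n_elem);
  return v;
}

static Params zeros_like(const Params& P) {
  Params Z = P;
  Z.We.zeros(); Z.Wlf.zeros(); Z.blf.zeros(); Z.Wlb.zeros(); Z.blb.zeros();
  if (P.use_capsule) Z.Wcap.zeros();
  Z.W1.zeros(); Z.b1.zeros(); Z.W2.zeros(); Z.b2.zeros(); Z.W3.zeros(); Z.b3.zeros();
  return Z;
}

// ---------------------------------------------------------------- forward/backward

struct FwdCache {
  cube X;                        // k x B x L
  cube Hf, Gf, Cf, Hb, Gb, Cb;   // per-direction LSTM caches
  cube Vall;                     // d_in x B x n_in (capsule inputs)
  std::vector<cube> U_h;         // per-sample prediction vectors
  std::vector<cube> c_h, s_h, a_h;
  mat feats;                     // f_in x B
  mat z1, r1, z2, r2;
  rowvec z3, p;
};

static void forward_batch(const imat& ids, const ivec& lens, const Params& P,
                          const Cfg& g, FwdCache& C) {
  const uword B = ids.n_cols;
  const int h = g.h, L = g.L;
  C.X.set_size(g.k, B, L);
  for (int t = 0; t < L; ++t)
    for (uword b = 0; b < B; ++b)
      C.X.slice(t).col(b) = P.We.row(ids(t, b)).t();
  lstm_fwd_batch(C.X, P.Wlf, P.blf, false, h, C.Hf, C.Gf, C.Cf);
  lstm_fwd_batch(C.X, P.Wlb, P.blb, true, h, C.Hb, C.Gb, C.Cb);

  int fin = g.use_capsule ? g.n_out * g.d_out : 2 * h;
  C.feats.set_size(fin, B);
  if (g.use_capsule) {
    // capsule inputs: the L x 2h output matrix flattened row-major, cut into
    // n_in blocks of d_in (with d_in = 2h this is one capsule per time step)
    C.Vall.set_size(g.d_in, B, g.n_in);
    vec flat(L * 2 * h);
    for (uword b = 0; b < B; ++b) {
      for (int t = 0; t < L; ++t) {
        flat.subvec(t * 2 * h, t * 2 * h + h - 1) = C.Hf.slice(t).col(b);
        flat.subvec(t * 2 * h + h, (t + 1) * 2 * h - 1) = C.Hb.slice(t).col(b);
      }
      for (int i = 0; i < g.n_in; ++i)
        C.Vall.slice(i).col(b) = flat.subvec((uword)i * g.d_in, (uword)(i + 1) * g.d_in - 1);
    }
    // prediction vectors, batched per input capsule
    C.U_h.assign(B, cube());
    for (uword b = 0; b < B; ++b) C.U_h[b].set_size(g.d_out, g.n_out, g.n_in);
    for (int i = 0; i < g.n_in; ++i) {
      mat Ui = P.Wcap.slice(i) * C.Vall.slice(i);   // (n_out*d_out) x B
      for (uword b = 0; b < B; ++b)
        C.U_h[b].slice(i) = reshape(Ui.col(b), g.d_out, g.n_out);
    }
    C.c_h.assign(B, cube());
    C.s_h.assign(B, cube());
    C.a_h.assign(B, cube());
    for (uword b = 0; b < B; ++b) {
      mat b_final;
      routing_fwd(C.U_h[b], g.r, g.axis, g.variant, C.c_h[b], C.s_h[b], C.a_h[b], b_final);
      C.feats.col(b) = vectorise(C.a_h[b].slice(g.r - 1));
    }
  } else {
    // ablation: mask-aware mean pooling of BiLSTM outputs over real positions
    for (uword b = 0; b < B; ++b) {
      vec m(2 * h, fill::zeros);
      int n = lens(b);
      for (int t = 0; t < n; ++t) {
        m.head(h) += C.Hf.slice(t).col(b);
        m.tail(h) += C.Hb.slice(t).col(b);
      }
      C.feats.col(b) = m / std::max(n, 1);
    }
  }
  C.z1 = P.W1 * C.feats;
  C.z1.each_col() += P.b1;
  C.r1 = C.z1;
  C.r1.elem(find(C.z1 < 0)).zeros();
  C.z2 = P.W2 * C.r1;
  C.z2.each_col() += P.b2;
  C.r2 = C.z2;
  C.r2.elem(find(C.z2 < 0)).zeros();
  C.z3 = P.W3 * C.r2 + P.b3(0);
  C.p = 1.0 / (1.0 + exp(-C.z3));
}

static double bce_loss(const rowvec& p, const vec& y) {
  double eps = 1e-12, s = 0.0;
  for (uword b = 0; b < p.n_elem; ++b) {
    double pb = std::min(std::max((double)p(b), eps), 1.0 - eps);
    s += -(y(b) * std::log(pb) + (1.0 - y(b)) * std::log(1.0 - pb));
  }
  return s / p.n_elem;
}

static double backward_batch(const imat& ids, const ivec& lens, const vec& y,
                             const Params& P, const Cfg& g, FwdCache& C, Params& G) {
  const uword B = ids.n_cols;
  const int h = g.h, L = g.L;
  double loss = bce_loss(C.p, y);

  rowvec dz3 = (C.p - y.t()) / (double)B;
  G.W3 = dz3 * C.r2.t();
  G.b3(0) = accu(dz3);
  mat dr2 = P.W3.t() * dz3;
  mat dz2 = dr2;
  dz2.elem(find(C.z2 <= 0)).zeros();
  G.W2 = dz2 * C.r1.t();
  G.b2 = sum(dz2, 1);
  mat dr1 = P.W2.t() * dz2;
  mat dz1 = dr1;
  dz1.elem(find(C.z1 <= 0)).zeros();
  G.W1 = dz1 * C.feats.t();
  G.b1 = sum(dz1, 1);
  mat dfeats = P.W1.t() * dz1;         // fin x B

  cube dHf(h, B, L, fill::zeros), dHb(h, B, L, fill::zeros);
  if (g.use_capsule) {
    G.Wcap.zeros();
    cube GUall(g.n_out * g.d_out, B, g.n_in);   // vectorised dL/du per (i, sample)
    for (uword b = 0; b < B; ++b) {
      mat Ga = reshape(dfeats.col(b), g.d_out, g.n_out);
      cube GU = routing_bwd(C.U_h[b], C.c_h[b], C.s_h[b], C.a_h[b], Ga,
                            g.r, g.axis, g.variant);
      for (int i = 0; i < g.n_in; ++i)
        GUall.slice(i).col(b) = vectorise(GU.slice(i));
    }
    vec dflat(L * 2 * h);
    cube GV(g.d_in, B, g.n_in);
    for (int i = 0; i < g.n_in; ++i) {
      G.Wcap.slice(i) = GUall.slice(i) * C.Vall.slice(i).t();
      GV.slice(i) = P.Wcap.slice(i).t() * GUall.slice(i);
    }
    for (uword b = 0; b < B; ++b) {
      for (int i = 0; i < g.n_in; ++i)
        dflat.subvec((uword)i * g.d_in, (uword)(i + 1) * g.d_in - 1) = GV.slice(i).col(b);
      for (int t = 0; t < L; ++t) {
        dHf.slice(t).col(b) += dflat.subvec(t * 2 * h, t * 2 * h + h - 1);
        dHb.slice(t).col(b) += dflat.subvec(t * 2 * h + h, (t + 1) * 2 * h - 1);
      }
    }
  } else {
    for (uword b = 0; b < B; ++b) {
      int n = std::max((int)lens(b), 1);
      vec df = dfeats.col(b) / n;
      for (int t = 0; t < (int)lens(b); ++t) {
        dHf.slice(t).col(b) += df.head(h);
        dHb.slice(t).col(b) += df.tail(h);
      }
    }
  }

  cube dXf, dXb;
  lstm_bwd_batch(C.X, C.Hf, C.Gf, C.Cf, P.Wlf, false, h, dHf, G.Wlf, G.blf, dXf);
  lstm_bwd_batch(C.X, C.Hb, C.Gb, C.Cb, P.Wlb, true, h, dHb, G.Wlb, G.blb, dXb);

  G.We.zeros();
  for (int t = 0; t < L; ++t)
    for (uword b = 0; b < B; ++b) {
      int id = ids(t, b);
      if (id != 0)  // padding embedding is frozen at zero
        G.We.row(id) += dXf.slice(t).col(b).t() + dXb.slice(t).col(b).t();
    }
  return loss;
}

// ---------------------------------------------------------------- exported passes

// [[Rcpp::export]]
List cpp_forward(const arma::imat& ids, const arma::ivec& lens, const List& params,
                 const List& cfg) {
  Cfg g = parse_cfg(cfg);
  Params P = params_from_list(params, g.use_capsule);
  FwdCache C;
  forward_batch(ids, lens, P, g, C);
  return List::create(Named("p") = C.p, Named("features") = C.feats);
}

// [[Rcpp::export]]
List cpp_grad(const arma::imat& ids, const arma::ivec& lens, const arma::vec& y,
              const List& params, const List& cfg) {
  Cfg g = parse_cfg(cfg);
  Params P = params_from_list(params, g.use_capsule);
  FwdCache C;
  forward_batch(ids, lens, P, g, C);
  Params G = zeros_like(P);
  double loss = backward_batch(ids, lens, y, P, g, C, G);
  return List::create(Named("loss") = loss, Named("grads") = params_to_list(G));
}

// [[Rcpp::export]]
List cpp_train(const arma::imat& ids, const arma::ivec& lens, const arma::vec& y,
               const List& params0, const List& cfg, const arma::imat& perms,
               const arma::ivec& val_idx, double lr, int batch_size,
               int patience, double clip) {
  Cfg g = parse_cfg(cfg);
  Params P = params_from_list(params0, g.use_capsule);
  Params M = zeros_like(P), V = zeros_like(P), G = zeros_like(P);
  std::vector<View> vP = views(P), vM = views(M), vV = views(V), vG = views(G);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long adam_t = 0;
  const int n_train = perms.n_rows, epochs = perms.n_cols;
  const uword n_val = val_idx.n_elem;

  std::vector<double> h_train, h_val_loss, h_val_acc;
  double best_val = datum::inf;
  Params best = P;
  int best_epoch = 0, wait = 0, ran = 0;

  for (int e = 0; e < epochs; ++e) {
    double ep_loss = 0.0;
    int ep_n = 0;
    for (int start = 0; start < n_train; start += batch_size) {
      int stop_ = std::min(start + batch_size - 1, n_train - 1);
      int B = stop_ - start + 1;
      imat bid(g.L, B);
      ivec blen(B);
      vec by(B);
      for (int j = 0; j < B; ++j) {
        int col = perms(start + j, e);          // 0-based column index into ids
        bid.col(j) = ids.col(col);
        blen(j) = lens(col);
        by(j) = y(col);
      }
      FwdCache C;
      forward_batch(bid, blen, P, g, C);
      double loss = backward_batch(bid, blen, by, P, g, C, G);
      if (!std::isfinite(loss))
        Rcpp::stop("training aborted: non-finite loss at epoch %d", e + 1);
      ep_loss += loss * B;
      ep_n += B;
      // global-norm gradient clipping
      double sq = 0.0;
      for (auto& w : vG) for (uword q = 0; q < w.n; ++q) sq += w.ptr[q] * w.ptr[q];
      double gn = std::sqrt(sq);
      double scale = (clip > 0 && gn > clip) ? clip / gn : 1.0;
      ++adam_t;
      double bc1 = 1.0 - std::pow(beta1, (double)adam_t);
      double bc2 = 1.0 - std::pow(beta2, (double)adam_t);
      for (size_t w = 0; w < vG.size(); ++w) {
        double* gp = vG[w].ptr; double* mp = vM[w].ptr;
        double* vp = vV[w].ptr; double* pp = vP[w].ptr;
        for (uword q = 0; q < vG[w].n; ++q) {
          double gq = gp[q] * scale;
          mp[q] = beta1 * mp[q] + (1.0 - beta1) * gq;
          vp[q] = beta2 * vp[q] + (1.0 - beta2) * gq * gq;
          pp[q] -= lr * (mp[q] / bc1) / (std::sqrt(vp[q] / bc2) + eps);
        }
      }
      Rcpp::checkUserInterrupt();
    }
    ep_loss /= std::max(ep_n, 1);
    h_train.push_back(ep_loss);

    // validation (falls back to the training loss when no slice was provided)
    double vloss = ep_loss, vacc = datum::nan;
    if (n_val > 0) {
      double s = 0.0; int correct = 0;
      for (uword start = 0; start < n_val; start += batch_size) {
        uword stop_ = std::min(start + (uword)batch_size - 1, n_val - 1);
        int B = stop_ - start + 1;
        imat bid(g.L, B);
        ivec blen(B);
        vec by(B);
        for (int j = 0; j < B; ++j) {
          int col = val_idx(start + j);
          bid.col(j) = ids.col(col);
          blen(j) = lens(col);
          by(j) = y(col);
        }
        FwdCache C;
        forward_batch(bid, blen, P, g, C);
        s += bce_loss(C.p, by) * B;
        for (int j = 0; j < B; ++j)
          if ((C.p(j) >= 0.5 ? 1.0 : 0.0) == by(j)) ++correct;
      }
      vloss = s / n_val;
      vacc = (double)correct / n_val;
    }
    h_val_loss.push_back(vloss);
    h_val_acc.push_back(vacc);
    ran = e + 1;
    if (vloss < best_val - 1e-12) {
      best_val = vloss;
      best = P;
      best_epoch = e + 1;
      wait = 0;
    } else if (++wait > patience && patience >= 0) {
      break;
    }
  }
  return List::create(
      Named("params") = params_to_list(best),
      Named("final_params") = params_to_list(P),
      Named("train_loss") = h_train,
      Named("val_loss") = h_val_loss,
      Named("val_acc") = h_val_acc,
      Named("best_epoch") = best_epoch,
      Named("epochs_run") = ran);
}
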