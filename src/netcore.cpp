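// Compiled core of the SMILES language model: stacked LSTM blocks with an
// inter-block rectifier + projection, causal multi-head self-attention over
// the final block, a linear vocabulary head, and full backpropagation for
// teacher-forced NLL / per-sequence-weighted REINFORCE objectives.
//
// Parameters are a named R list of matrices:
//   E                       vocab x embed
//   Wx_<b>_<l>, Wh_<b>_<l>, b_<b>_<l>   LSTM weights, gate order [i f g o]
//   P_<b>, bP_<b>           inter-block projection (blocks 1..B-1)
//   Wq, Wk, Wv, Wo          attention (width = hidden = heads * dk)
//   Wout, bout              output head
// All token indices crossing the interface are 1-based (R convention).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct NetConfig {
  int V, e, h, L, B, heads, dk;
};

NetConfig readConfig(const List& config) {
  NetConfig c;
  c.V = as<int>(config["vocab_size"]);
  c.e = as<int>(config["embed_dim"]);
  c.h = as<int>(config["hidden_size"]);
  c.L = as<int>(config["block_layers"]);
  c.B = as<int>(config["num_blocks"]);
  c.heads = as<int>(config["attention_heads"]);
  c.dk = as<int>(config["key_dim"]);
  if (c.heads * c.dk != c.h)
    stop("attention_heads * key_dim must equal hidden_size");
  return c;
}

std::string pname(const char* stem, int b, int l) {
  char buf[32];
  std::snprintf(buf, sizeof(buf), "%s_%d_%d", stem, b, l);
  return std::string(buf);
}
std::string pname1(const char* stem, int b) {
  char buf[32];
  std::snprintf(buf, sizeof(buf), "%s_%d", stem, b);
  return std::string(buf);
}

struct Params {
  mat E;
  std::vector<std::vector<mat>> Wx, Wh;
  std::vector<std::vector<rowvec>> b;
  std::vector<mat> P;
  std::vector<rowvec> bP;
  mat Wq, Wk, Wv, Wo, Wout;
  rowvec bout;
};

Params readParams(const List& params, const NetConfig& c) {
  Params p;
  p.E = as<mat>(params["E"]);
  p.Wx.resize(c.B); p.Wh.resize(c.B); p.b.resize(c.B);
  for (int bb = 0; bb < c.B; ++bb) {
    p.Wx[bb].resize(c.L); p.Wh[bb].resize(c.L); p.b[bb].resize(c.L);
    for (int l = 0; l < c.L; ++l) {
      p.Wx[bb][l] = as<mat>(params[pname("Wx", bb + 1, l + 1)]);
      p.Wh[bb][l] = as<mat>(params[pname("Wh", bb + 1, l + 1)]);
      p.b[bb][l] = as<rowvec>(params[pname("b", bb + 1, l + 1)]);
    }
  }
  p.P.resize(std::max(0, c.B - 1)); p.bP.resize(std::max(0, c.B - 1));
  for (int bb = 0; bb + 1 < c.B; ++bb) {
    p.P[bb] = as<mat>(params[pname1("P", bb + 1)]);
    p.bP[bb] = as<rowvec>(params[pname1("bP", bb + 1)]);
  }
  p.Wq = as<mat>(params["Wq"]); p.Wk = as<mat>(params["Wk"]);
  p.Wv = as<mat>(params["Wv"]); p.Wo = as<mat>(params["Wo"]);
  p.Wout = as<mat>(params["Wout"]); p.bout = as<rowvec>(params["bout"]);
  return p;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// One LSTM step for a whole batch; gates cached for backprop.
void lstmStep(const mat& x, const mat& Wx, const mat& Wh, const rowvec& bias,
              mat& h, mat& cc, mat& gates, mat& cNew) {
  const int H = h.n_cols;
  mat z = x * Wx + h * Wh;
  z.each_row() += bias;
  mat gi = sigm(z.cols(0, H - 1));
  mat gf = sigm(z.cols(H, 2 * H - 1));
  mat gg = arma::tanh(z.cols(2 * H, 3 * H - 1));
  mat go = sigm(z.cols(3 * H, 4 * H - 1));
  cNew = gf % cc + gi % gg;
  gates = arma::join_rows(arma::join_rows(gi, gf), arma::join_rows(gg, go));
  h = go % arma::tanh(cNew);
  cc = cNew;
}

}  // namespace

// Teacher-forced forward pass with optional backward pass.
//
// input, target: n x T 1-based token matrices (input starts with GO, target
// ends with EOS); mask: n x T 0/1 loss mask; seqWeight: per-sequence loss
// weights (all 1 for NLL pretraining, rewards R* for the policy gradient).
// Loss = -(1/n) * sum_b w_b * sum_t mask * log p(target). Returns the loss,
// per-sequence unweighted log-probabilities, and (optionally) gradients.
// [[Rcpp::export]]
List nc_forward_backward(List params, List config, IntegerMatrix input,
                         IntegerMatrix target, IntegerMatrix mask,
                         NumericVector seqWeight, bool wantGrads) {
  const NetConfig c = readConfig(config);
  const Params p = readParams(params, c);
  const int n = input.nrow(), T = input.ncol();
  if (target.nrow() != n || target.ncol() != T || mask.nrow() != n ||
      mask.ncol() != T || seqWeight.size() != n)
    stop("input, target, mask and seqWeight shapes disagree");
  const double scale = 1.0 / std::sqrt((double)c.dk);

  // ---- forward ------------------------------------------------------------
  // caches[b][l]: gates (n x 4h x T), cells (n x h x T), hidden (n x h x T)
  std::vector<std::vector<arma::cube>> gateC(c.B), cellC(c.B), hidC(c.B);
  std::vector<arma::cube> blockIn(c.B);   // input fed to each block (n x e x T)
  arma::cube Hfin(n, c.h, T);             // final block output
  for (int bb = 0; bb < c.B; ++bb) {
    gateC[bb].assign(c.L, arma::cube(n, 4 * c.h, T));
    cellC[bb].assign(c.L, arma::cube(n, c.h, T));
    hidC[bb].assign(c.L, arma::cube(n, c.h, T));
    blockIn[bb].set_size(n, c.e, T);
  }

  // embedding lookup
  for (int t = 0; t < T; ++t) {
    mat xt(n, c.e);
    for (int i = 0; i < n; ++i) xt.row(i) = p.E.row(input(i, t) - 1);
    blockIn[0].slice(t) = xt;
  }

  for (int bb = 0; bb < c.B; ++bb) {
    std::vector<mat> h(c.L, mat(n, c.h, arma::fill::zeros));
    std::vector<mat> cc(c.L, mat(n, c.h, arma::fill::zeros));
    for (int t = 0; t < T; ++t) {
      mat x = blockIn[bb].slice(t);
      for (int l = 0; l < c.L; ++l) {
        mat gates, cNew;
        lstmStep(l == 0 ? x : h[l - 1], p.Wx[bb][l], p.Wh[bb][l], p.b[bb][l],
                 h[l], cc[l], gates, cNew);
        gateC[bb][l].slice(t) = gates;
        cellC[bb][l].slice(t) = cNew;
        hidC[bb][l].slice(t) = h[l];
      }
      if (bb + 1 < c.B) {
        mat z = arma::clamp(h[c.L - 1], 0.0, arma::datum::inf);  // ReLU
        blockIn[bb + 1].slice(t) = z * p.P[bb];
        blockIn[bb + 1].slice(t).each_row() += p.bP[bb];
      } else {
        Hfin.slice(t) = h[c.L - 1];
      }
    }
  }

  // ---- causal multi-head self-attention (per sequence) --------------------
  arma::cube Att(n, c.h, T);
  // per-sequence caches for backprop
  std::vector<mat> Qc(n), Kc(n), Vc(n), Ac(n);
  std::vector<std::vector<mat>> Sc(n, std::vector<mat>(c.heads));
  for (int i = 0; i < n; ++i) {
    mat Hs(T, c.h);
    for (int t = 0; t < T; ++t) Hs.row(t) = Hfin.slice(t).row(i);
    mat Q = Hs * p.Wq, K = Hs * p.Wk, Vv = Hs * p.Wv;
    mat A(T, c.h);
    for (int hd = 0; hd < c.heads; ++hd) {
      const int c0 = hd * c.dk, c1 = (hd + 1) * c.dk - 1;
      mat S = Q.cols(c0, c1) * K.cols(c0, c1).t() * scale;  // T x T
      // causal softmax row-wise over s <= t
      mat W(T, T, arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        rowvec row = S.row(t).cols(0, t);
        row -= row.max();
        rowvec ex = arma::exp(row);
        W.row(t).cols(0, t) = ex / arma::accu(ex);
      }
      A.cols(c0, c1) = W * Vv.cols(c0, c1);
      if (wantGrads) Sc[i][hd] = W;
    }
    mat out = A * p.Wo;
    for (int t = 0; t < T; ++t) Att.slice(t).row(i) = out.row(t);
    if (wantGrads) { Qc[i] = Q; Kc[i] = K; Vc[i] = Vv; Ac[i] = A; }
  }

  // ---- output head, loss --------------------------------------------------
  double loss = 0.0;
  NumericVector logp(n);
  arma::cube dAtt;  // gradient wrt attention output
  if (wantGrads) dAtt.set_size(n, c.h, T), dAtt.zeros();
  mat dWout(c.h, c.V, arma::fill::zeros);
  rowvec dbout(c.V, arma::fill::zeros);

  for (int t = 0; t < T; ++t) {
    mat logits = Att.slice(t) * p.Wout;
    logits.each_row() += p.bout;
    vec mx = arma::max(logits, 1);
    logits.each_col() -= mx;
    mat ex = arma::exp(logits);
    vec sm = arma::sum(ex, 1);
    mat prob = ex.each_col() / sm;
    mat dlogits;
    if (wantGrads) dlogits = prob;
    for (int i = 0; i < n; ++i) {
      if (mask(i, t)) {
        const int tg = target(i, t) - 1;
        const double lp = std::log(std::max(prob(i, tg), 1e-300));
        logp[i] += lp;
        loss -= seqWeight[i] * lp / n;
        if (wantGrads) {
          dlogits(i, tg) -= 1.0;
          dlogits.row(i) *= seqWeight[i] / n;
        }
      } else if (wantGrads) {
        dlogits.row(i).zeros();
      }
    }
    if (wantGrads) {
      dWout += Att.slice(t).t() * dlogits;
      dbout += arma::sum(dlogits, 0);
      dAtt.slice(t) = dlogits * p.Wout.t();
    }
  }

  if (!wantGrads)
    return List::create(_["loss"] = loss, _["logp"] = logp);

  // ---- backward: attention ------------------------------------------------
  arma::cube dHfin(n, c.h, T, arma::fill::zeros);
  mat dWq(c.h, c.h, arma::fill::zeros), dWk(c.h, c.h, arma::fill::zeros);
  mat dWv(c.h, c.h, arma::fill::zeros), dWo(c.h, c.h, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    mat dOut(T, c.h);
    for (int t = 0; t < T; ++t) dOut.row(t) = dAtt.slice(t).row(i);
    mat dA = dOut * p.Wo.t();
    dWo += Ac[i].t() * dOut;
    mat dQ(T, c.h, arma::fill::zeros), dK(T, c.h, arma::fill::zeros),
        dV(T, c.h, arma::fill::zeros);
    for (int hd = 0; hd < c.heads; ++hd) {
      const int c0 = hd * c.dk, c1 = (hd + 1) * c.dk - 1;
      const mat& W = Sc[i][hd];
      mat dW = dA.cols(c0, c1) * Vc[i].cols(c0, c1).t();
      dV.cols(c0, c1) = W.t() * dA.cols(c0, c1);
      // softmax backward, row-wise, respecting the causal support
      mat dS(T, T, arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        rowvec w = W.row(t).cols(0, t);
        rowvec g = dW.row(t).cols(0, t);
        const double dot = arma::accu(w % g);
        dS.row(t).cols(0, t) = w % (g - dot);
      }
      dS *= scale;
      dQ.cols(c0, c1) = dS * Kc[i].cols(c0, c1);
      dK.cols(c0, c1) = dS.t() * Qc[i].cols(c0, c1);
    }
    mat Hs(T, c.h);
    for (int t = 0; t < T; ++t) Hs.row(t) = Hfin.slice(t).row(i);
    dWq += Hs.t() * dQ; dWk += Hs.t() * dK; dWv += Hs.t() * dV;
    mat dHs = dQ * p.Wq.t() + dK * p.Wk.t() + dV * p.Wv.t();
    for (int t = 0; t < T; ++t) dHfin.slice(t).row(i) += dHs.row(t);
  }

  // ---- backward: blocks (top down) ---------------------------------------
  mat dE(c.V, c.e, arma::fill::zeros);
  std::vector<std::vector<mat>> dWx(c.B), dWh(c.B);
  std::vector<std::vector<rowvec>> db(c.B);
  std::vector<mat> dP(std::max(0, c.B - 1));
  std::vector<rowvec> dbP(std::max(0, c.B - 1));
  for (int bb = 0; bb + 1 < c.B; ++bb) {
    dP[bb].zeros(c.h, c.e);
    dbP[bb].zeros(c.e);
  }
  for (int bb = 0; bb < c.B; ++bb) {
    dWx[bb].resize(c.L); dWh[bb].resize(c.L); db[bb].resize(c.L);
    for (int l = 0; l < c.L; ++l) {
      dWx[bb][l].zeros(p.Wx[bb][l].n_rows, p.Wx[bb][l].n_cols);
      dWh[bb][l].zeros(c.h, 4 * c.h);
      db[bb][l].zeros(4 * c.h);
    }
  }
  // dBlockOut: gradient wrt the top-layer hidden states of block bb at each t
  arma::cube dBlockOut = dHfin;
  for (int bb = c.B - 1; bb >= 0; --bb) {
    arma::cube dBlockIn(n, c.e, T, arma::fill::zeros);
    std::vector<mat> dhNext(c.L, mat(n, c.h, arma::fill::zeros));
    std::vector<mat> dcNext(c.L, mat(n, c.h, arma::fill::zeros));
    for (int t = T - 1; t >= 0; --t) {
      mat dx;  // gradient wrt this block's input at t (filled by l == 0)
      mat dhDown;  // gradient flowing to the hidden state of layer l-1
      for (int l = c.L - 1; l >= 0; --l) {
        mat dh = dhNext[l];
        if (l == c.L - 1) dh += dBlockOut.slice(t);
        else dh += dhDown;
        const mat& gates = gateC[bb][l].slice(t);
        const mat gi = gates.cols(0, c.h - 1);
        const mat gf = gates.cols(c.h, 2 * c.h - 1);
        const mat gg = gates.cols(2 * c.h, 3 * c.h - 1);
        const mat go = gates.cols(3 * c.h, 4 * c.h - 1);
        const mat& cNew = cellC[bb][l].slice(t);
        mat tc = arma::tanh(cNew);
        mat dc = dcNext[l] + dh % go % (1.0 - tc % tc);
        mat cPrev = (t > 0) ? cellC[bb][l].slice(t - 1)
                            : mat(n, c.h, arma::fill::zeros);
        mat dgi = dc % gg % gi % (1.0 - gi);
        mat dgf = dc % cPrev % gf % (1.0 - gf);
        mat dgg = dc % gi % (1.0 - gg % gg);
        mat dgo = dh % tc % go % (1.0 - go);
        mat dz = arma::join_rows(arma::join_rows(dgi, dgf),
                                 arma::join_rows(dgg, dgo));
        mat xin = (l == 0) ? blockIn[bb].slice(t) : hidC[bb][l - 1].slice(t);
        mat hPrev = (t > 0) ? hidC[bb][l].slice(t - 1)
                            : mat(n, c.h, arma::fill::zeros);
        dWx[bb][l] += xin.t() * dz;
        dWh[bb][l] += hPrev.t() * dz;
        db[bb][l] += arma::sum(dz, 0);
        dhNext[l] = dz * p.Wh[bb][l].t();
        dcNext[l] = dc % gf;
        if (l == 0) dx = dz * p.Wx[bb][l].t();
        else dhDown = dz * p.Wx[bb][l].t();
      }
      dBlockIn.slice(t) = dx;
    }
    if (bb > 0) {
      // back through projection + ReLU into the lower block's top layer
      dBlockOut.zeros(n, c.h, T);
      for (int t = 0; t < T; ++t) {
        mat hTop = hidC[bb - 1][c.L - 1].slice(t);
        mat z = arma::clamp(hTop, 0.0, arma::datum::inf);
        dP[bb - 1] += z.t() * dBlockIn.slice(t);
        dbP[bb - 1] += arma::sum(dBlockIn.slice(t), 0);
        mat dz = dBlockIn.slice(t) * p.P[bb - 1].t();
        dBlockOut.slice(t) = dz % arma::conv_to<mat>::from(hTop > 0.0);
      }
    } else {
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < n; ++i)
          dE.row(input(i, t) - 1) += dBlockIn.slice(t).row(i);
    }
  }

  List grads;
  grads["E"] = dE;
  for (int bb = 0; bb < c.B; ++bb)
    for (int l = 0; l < c.L; ++l) {
      grads[pname("Wx", bb + 1, l + 1)] = dWx[bb][l];
      grads[pname("Wh", bb + 1, l + 1)] = dWh[bb][l];
      grads[pname("b", bb + 1, l + 1)] = db[bb][l];
    }
  for (int bb = 0; bb + 1 < c.B; ++bb) {
    grads[pname1("P", bb + 1)] = dP[bb];
    grads[pname1("bP", bb + 1)] = dbP[bb];
  }
  grads["Wq"] = dWq; grads["Wk"] = dWk; grads["Wv"] = dWv; grads["Wo"] = dWo;
  grads["Wout"] = dWout; grads["bout"] = dbout;
  return List::create(_["loss"] = loss, _["logp"] = logp,
                      _["grads"] = grads);
}

// Multi-head scaled dot-product self-attention on one sequence.
//
// H is a T x width sequence (width = heads * dk). Per head i the slice is
// projected by the corresponding columns of Wq/Wk/Wv, scored as
// softmax(Q K' / sqrt(dk)) (optionally causal), applied to V, and the
// concatenated heads are projected by Wo. Exposed so the layer can be checked
// against a plain dense-algebra oracle.
// [[Rcpp::export]]
arma::mat nc_attention(arma::mat H, arma::mat Wq, arma::mat Wk, arma::mat Wv,
                       arma::mat Wo, int heads, int dk, bool causal) {
  const int T = H.n_rows, width = H.n_cols;
  if (heads * dk != width) stop("heads * dk must equal the input width");
  const double scale = 1.0 / std::sqrt((double)dk);
  mat Q = H * Wq, K = H * Wk, V = H * Wv, A(T, width);
  for (int hd = 0; hd < heads; ++hd) {
    const int c0 = hd * dk, c1 = (hd + 1) * dk - 1;
    mat S = Q.cols(c0, c1) * K.cols(c0, c1).t() * scale;
    mat W(T, T, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      const int hi = causal ? t : T - 1;
      rowvec row = S.row(t).cols(0, hi);
      row -= row.max();
      rowvec ex = arma::exp(row);
      W.row(t).cols(0, hi) = ex / arma::accu(ex);
    }
    A.cols(c0, c1) = W * V.cols(c0, c1);
  }
  return A * Wo;
}

namespace {

// Incremental (one token at a time) state of one model during sampling.
struct SamplerState {
  const Params* p;
  NetConfig c;
  int n;
  std::vector<std::vector<mat>> h, cc;   // [block][layer] n x h
  std::vector<mat> Khist, Vhist, Hhist;  // per emitted step: n x h
  SamplerState(const Params* pp, const NetConfig& cfg, int nn)
      : p(pp), c(cfg), n(nn) {
    h.assign(c.B, std::vector<mat>(c.L, mat(nn, c.h, arma::fill::zeros)));
    cc = h;
  }
  // feed tokens (1-based), return probability matrix n x V (given temp)
  mat step(const std::vector<int>& tokens, double temperature) {
    mat x(n, c.e);
    for (int i = 0; i < n; ++i) x.row(i) = p->E.row(tokens[i] - 1);
    for (int bb = 0; bb < c.B; ++bb) {
      for (int l = 0; l < c.L; ++l) {
        mat gates, cNew;
        lstmStep(l == 0 ? x : h[bb][l - 1], p->Wx[bb][l], p->Wh[bb][l],
                 p->b[bb][l], h[bb][l], cc[bb][l], gates, cNew);
      }
      if (bb + 1 < c.B) {
        x = arma::clamp(h[bb][c.L - 1], 0.0, arma::datum::inf) * p->P[bb];
        x.each_row() += p->bP[bb];
      }
    }
    const mat& Hf = h[c.B - 1][c.L - 1];
    Hhist.push_back(Hf);
    Khist.push_back(Hf * p->Wk);
    Vhist.push_back(Hf * p->Wv);
    const int t = (int)Hhist.size();
    const double scale = 1.0 / std::sqrt((double)c.dk);
    mat q = Hf * p->Wq;
    mat att(n, c.h);
    for (int hd = 0; hd < c.heads; ++hd) {
      const int c0 = hd * c.dk, c1 = (hd + 1) * c.dk - 1;
      mat scores(n, t);
      for (int s = 0; s < t; ++s)
        scores.col(s) =
            arma::sum(q.cols(c0, c1) % Khist[s].cols(c0, c1), 1) * scale;
      scores.each_col() -= arma::max(scores, 1);
      mat ex = arma::exp(scores);
      ex.each_col() /= arma::sum(ex, 1);
      mat ah(n, c.dk, arma::fill::zeros);
      for (int s = 0; s < t; ++s)
        ah += Vhist[s].cols(c0, c1).each_col() % ex.col(s);
      att.cols(c0, c1) = ah;
    }
    mat logits = (att * p->Wo) * p->Wout;
    logits.each_row() += p->bout;
    if (temperature > 1e-8 && temperature != 1.0) logits /= temperature;
    logits.each_col() -= arma::max(logits, 1);
    mat exl = arma::exp(logits);
    exl.each_col() /= arma::sum(exl, 1);
    return exl;  // probabilities (softmax of temperature-scaled logits)
  }
};

}  // namespace

// Autoregressive sampling, optionally with evolutionary crossover/mutation.
//
// With croverParams/priorParams = R_NilValue this is plain sampling from the
// agent. Otherwise, per sequence and per step: a mutation draw below
// mutationRate hands the step distribution to the prior; otherwise a
// crossover draw above crossoverThreshold hands it to the crover model, else
// the agent emits. All models advance on the chosen token in lockstep.
// Randomness comes from R's RNG (set.seed reproduces batches exactly).
// Returns 1-based token matrices (0-padded after EOS), sequence lengths, and
// the agent's summed log-probability of each emitted sequence.
// [[Rcpp::export]]
List nc_sample(List agentParams, List config, int n, double temperature,
               int maxLen, int goIdx, int eosIdx,
               Nullable<List> croverParams = R_NilValue,
               Nullable<List> priorParams = R_NilValue,
               double mutationRate = 0.0, double crossoverThreshold = 0.5) {
  if (n <= 0) stop("n must be positive");
  const NetConfig c = readConfig(config);
  const Params agent = readParams(agentParams, c);
  const bool evo = croverParams.isNotNull();
  Params crover, prior;
  if (evo) {
    crover = readParams(croverParams.get(), c);
    if (priorParams.isNotNull()) prior = readParams(priorParams.get(), c);
    else prior = agent;
  }
  const bool greedy = temperature <= 1e-8;

  SamplerState sAgent(&agent, c, n);
  SamplerState sCrover(evo ? &crover : &agent, c, n);
  SamplerState sPrior(evo ? &prior : &agent, c, n);

  IntegerMatrix tokens(n, maxLen);
  std::fill(tokens.begin(), tokens.end(), 0);
  IntegerVector lengths(n);
  NumericVector logp(n);
  std::vector<bool> active(n, true);
  std::vector<int> cur(n, goIdx);

  RNGScope rng;
  for (int t = 0; t < maxLen; ++t) {
    mat pa = sAgent.step(cur, temperature);
    mat pc, pp;
    if (evo) {
      pc = sCrover.step(cur, temperature);
      pp = sPrior.step(cur, temperature);
    }
    bool anyActive = false;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      const mat* src = &pa;
      if (evo) {
        const double uMut = unif_rand();
        const double uCross = unif_rand();
        if (uMut < mutationRate) src = &pp;
        else if (uCross > crossoverThreshold) src = &pc;
      }
      int tok;
      if (greedy) {
        tok = (int)arma::index_max(src->row(i)) + 1;
      } else {
        const double u = unif_rand();
        double acc = 0.0;
        tok = c.V;
        for (int v = 0; v < c.V; ++v) {
          acc += (*src)(i, v);
          if (u <= acc) { tok = v + 1; break; }
        }
      }
      tokens(i, t) = tok;
      logp[i] += std::log(std::max(pa(i, tok - 1), 1e-300));
      lengths[i] = t + 1;
      cur[i] = tok;
      if (tok == eosIdx) active[i] = false;
      else anyActive = true;
    }
    if (!anyActive) break;
    // finished rows keep feeding EOS so the batch stays rectangular
    for (int i = 0; i < n; ++i) if (!active[i]) cur[i] = eosIdx;
  }
  return List::create(_["tokens"] = tokens, _["lengths"] = lengths,
                      _["logp"] = logp);
}
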