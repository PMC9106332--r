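// Closed-loop simulation and backpropagation-through-time gradients for the
// feedback-modulated feedforward networks. All randomness lives on the R side;
// these routines are deterministic given their inputs.
//
// Conventions shared with the R layer:
//  - LSTM gate order in the stacked weight matrices is [input; forget; cell;
//    output], i.e. rows [0,H) input gate, [H,2H) forget, [2H,3H) candidate,
//    [3H,4H) output gate. No peephole connections.
//  - The modulator input at step t is [mask_x .* x(t); mask_y .* y(t-1)]:
//    the feedforward output enters with a one-step delay, which removes the
//    algebraic loop of the instantaneous definition.
//  - Batched arrays are cubes with dimensions (channels, batch, time).
//  - The modulation matrix M of the simple model is stored column-major as a
//    vector of length n_s^2, matching R's matrix(l, n_s, n_s).
//  - Filtered modulation uses forward Euler: v <- v + (dt/tau) * (-v + drive).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::as;
using Rcpp::stop;

namespace {

struct Lstm {
  mat Wi, Wh, Wl;
  vec b, bl;
  uword H, n_in, n_out;
};

Lstm lstm_from_list(const List& par) {
  Lstm P;
  P.Wi = as<mat>(par["Wi"]);
  P.Wh = as<mat>(par["Wh"]);
  P.b  = as<vec>(par["b"]);
  P.Wl = as<mat>(par["Wl"]);
  P.bl = as<vec>(par["bl"]);
  P.H = P.Wh.n_cols;
  P.n_in = P.Wi.n_cols;
  P.n_out = P.Wl.n_rows;
  if (P.Wi.n_rows != 4 * P.H || P.Wh.n_rows != 4 * P.H || P.b.n_elem != 4 * P.H)
    stop("inconsistent LSTM parameter shapes");
  return P;
}

inline mat sigm(const mat& a) { return 1.0 / (1.0 + exp(-a)); }

// One LSTM step for a batch. gates receives [i; f; g; o] stacked (4H x B).
void lstm_step(const Lstm& P, const mat& u, const mat& hprev, const mat& cprev,
               mat& gates, mat& cnew, mat& hnew, mat& l) {
  const uword H = P.H;
  mat a = P.Wi * u + P.Wh * hprev;
  a.each_col() += P.b;
  mat gi = sigm(a.rows(0, H - 1));
  mat gf = sigm(a.rows(H, 2 * H - 1));
  mat gg = tanh(a.rows(2 * H, 3 * H - 1));
  mat go = sigm(a.rows(3 * H, 4 * H - 1));
  cnew = gf % cprev + gi % gg;
  hnew = go % tanh(cnew);
  gates = join_cols(join_cols(gi, gf), join_cols(gg, go));
  l = P.Wl * hnew;
  l.each_col() += P.bl;
}

struct LstmGrads {
  mat gWi, gWh, gWl;
  vec gb, gbl;
  void init(const Lstm& P) {
    gWi.zeros(size(P.Wi));
    gWh.zeros(size(P.Wh));
    gWl.zeros(size(P.Wl));
    gb.zeros(size(P.b));
    gbl.zeros(size(P.bl));
  }
};

// Reverse one LSTM step. dl: gradient w.r.t. the readout l at this step.
// dh_next/dc_next carry gradients from step t+1 (updated in place to become
// the carries for step t-1). du receives the gradient w.r.t. the input u.
void lstm_back(const Lstm& P, const mat& gates, const mat& c_t, const mat& c_prev,
               const mat& h_t, const mat& h_prev, const mat& u, const mat& dl,
               mat& dh_next, mat& dc_next, mat& du, LstmGrads& G) {
  const uword H = P.H;
  const mat gi = gates.rows(0, H - 1);
  const mat gf = gates.rows(H, 2 * H - 1);
  const mat gg = gates.rows(2 * H, 3 * H - 1);
  const mat go = gates.rows(3 * H, 4 * H - 1);

  G.gWl += dl * h_t.t();
  G.gbl += sum(dl, 1);

  mat dh = P.Wl.t() * dl + dh_next;
  mat tc = tanh(c_t);
  mat dgo = dh % tc;
  mat dc = dc_next + dh % go % (1.0 - tc % tc);
  mat dgi = dc % gg;
  mat dgf = dc % c_prev;
  mat dgg = dc % gi;

  mat da = join_cols(join_cols(dgi % gi % (1.0 - gi), dgf % gf % (1.0 - gf)),
                     join_cols(dgg % (1.0 - gg % gg), dgo % go % (1.0 - go)));

  G.gWi += da * u.t();
  G.gWh += da * h_prev.t();
  G.gb += sum(da, 1);

  du = P.Wi.t() * da;
  dh_next = P.Wh.t() * da;
  dc_next = dc % gf;
}

// Smooth L1 (Huber with unit transition): h(d) = d^2/2 for |d|<1, |d|-1/2 else.
inline double huber_sum(const mat& d) {
  mat a = abs(d);
  return accu(clamp(a, 0.0, 1.0) % (a - 0.5 * clamp(a, 0.0, 1.0)));
}
inline mat huber_grad(const mat& d) { return clamp(d, -1.0, 1.0); }

struct Opts {
  double tau;      // <=0 means no temporal filter (simple model only)
  double dt;
  double lambda_out;
  vec mask_x, mask_y;
};

Opts opts_from_list(const List& opt, uword n_s) {
  Opts o;
  o.tau = opt.containsElementNamed("tau") && !Rf_isNull(opt["tau"])
              ? as<double>(opt["tau"]) : -1.0;
  o.dt = opt.containsElementNamed("dt") ? as<double>(opt["dt"]) : 1.0;
  o.lambda_out = opt.containsElementNamed("lambda_out")
                     ? as<double>(opt["lambda_out"]) : 0.0;
  o.mask_x = opt.containsElementNamed("mask_x") ? as<vec>(opt["mask_x"])
                                                : vec(n_s, fill::ones);
  o.mask_y = opt.containsElementNamed("mask_y") ? as<vec>(opt["mask_y"])
                                                : vec(n_s, fill::ones);
  return o;
}

inline mat masked_input(const Opts& o, const mat& xt, const mat& yprev) {
  mat ux = xt.each_col() % o.mask_x;
  mat uy = yprev.each_col() % o.mask_y;
  return join_cols(ux, uy);
}

}  // namespace

// ---------------------------------------------------------------------------
// Simple model: y(t) = (M(t) .* W0) x(t), M driven by the LSTM readout,
// optionally low-pass filtered with time constant tau.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_grad_simple(List par, arma::cube x, arma::cube s, List opt) {
  Lstm P = lstm_from_list(par);
  const mat W0 = as<mat>(par["W0"]);
  const uword n_s = x.n_rows, B = x.n_cols, T = x.n_slices;
  if (P.n_out != n_s * n_s) stop("LSTM readout must have n_s^2 outputs");
  Opts o = opts_from_list(opt, n_s);
  const bool filt = o.tau > 0;
  const double alpha = filt ? o.dt / o.tau : 1.0;

  cube gates(4 * P.H, B, T), cs(P.H, B, T), hs(P.H, B, T);
  cube ls(P.n_out, B, T), Ms(P.n_out, B, T), ys(n_s, B, T);

  mat h(P.H, B, fill::zeros), c(P.H, B, fill::zeros);
  mat M(P.n_out, B, fill::zeros), yprev(n_s, B, fill::zeros);
  double loss_rec = 0.0, reg = 0.0;

  for (uword t = 0; t < T; ++t) {
    mat xt = x.slice(t);
    mat u = masked_input(o, xt, yprev);
    mat g, cn, hn, l;
    lstm_step(P, u, h, c, g, cn, hn, l);
    gates.slice(t) = g; cs.slice(t) = cn; hs.slice(t) = hn; ls.slice(t) = l;
    h = hn; c = cn;
    M = filt ? mat(M + alpha * (l - M)) : l;
    Ms.slice(t) = M;
    mat y(n_s, B, fill::zeros);
    for (uword r = 0; r < n_s; ++r)
      for (uword cc = 0; cc < n_s; ++cc)
        y.row(r) += W0(r, cc) * (M.row(r + cc * n_s) % xt.row(cc));
    ys.slice(t) = y;
    loss_rec += huber_sum(y - s.slice(t));
    reg += accu(abs(l));
    yprev = y;
  }
  const double wloss = 1.0 / double(n_s * B * T);
  loss_rec *= wloss;
  reg *= o.lambda_out / double(B);

  // backward
  LstmGrads G; G.init(P);
  mat dh(P.H, B, fill::zeros), dc(P.H, B, fill::zeros);
  mat dMcarry(P.n_out, B, fill::zeros), dycarry(n_s, B, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat xt = x.slice(t);
    mat dy = wloss * huber_grad(ys.slice(t) - s.slice(t)) + dycarry;
    mat dM(P.n_out, B, fill::zeros);
    for (uword r = 0; r < n_s; ++r)
      for (uword cc = 0; cc < n_s; ++cc)
        dM.row(r + cc * n_s) = W0(r, cc) * (dy.row(r) % xt.row(cc));
    dM += dMcarry;
    mat dl = filt ? mat(alpha * dM) : dM;
    dMcarry = filt ? mat((1.0 - alpha) * dM) : mat(P.n_out, B, fill::zeros);
    dl += (o.lambda_out / double(B)) * sign(ls.slice(t));

    mat cprev = (t == 0) ? mat(P.H, B, fill::zeros) : cs.slice(t - 1);
    mat hprev = (t == 0) ? mat(P.H, B, fill::zeros) : hs.slice(t - 1);
    mat ypv = (t == 0) ? mat(n_s, B, fill::zeros) : ys.slice(t - 1);
    mat u = masked_input(o, xt, ypv);
    mat du;
    lstm_back(P, gates.slice(t), cs.slice(t), cprev, hs.slice(t), hprev, u, dl,
              dh, dc, du, G);
    dycarry = du.rows(n_s, 2 * n_s - 1);
    dycarry.each_col() %= o.mask_y;
  }

  return List::create(
      Named("loss") = loss_rec + reg, Named("loss_rec") = loss_rec,
      Named("reg") = reg,
      Named("grads") = List::create(
          Named("Wi") = G.gWi, Named("Wh") = G.gWh, Named("b") = G.gb,
          Named("Wl") = G.gWl, Named("bl") = G.gbl));
}

// ---------------------------------------------------------------------------
// Population model: z = m .* (Wx x), y = Wro z,
// tau dm/dt = -m + K l with l the LSTM readout (N_FB feedback signals).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_grad_population(List par, arma::cube x, arma::cube s, List opt) {
  Lstm P = lstm_from_list(par);
  const mat Wx = as<mat>(par["Wx"]);
  const mat Wro = as<mat>(par["Wro"]);
  const mat K = as<mat>(par["K"]);
  const uword n_s = x.n_rows, B = x.n_cols, T = x.n_slices;
  const uword Nz = Wx.n_rows;
  Opts o = opts_from_list(opt, n_s);
  if (o.tau <= 0) stop("population modulation requires tau > 0");
  const double alpha = o.dt / o.tau;

  cube gates(4 * P.H, B, T), cs(P.H, B, T), hs(P.H, B, T);
  cube ls(P.n_out, B, T), ms(Nz, B, T), ys(n_s, B, T);

  mat h(P.H, B, fill::zeros), c(P.H, B, fill::zeros);
  mat m(Nz, B, fill::zeros), yprev(n_s, B, fill::zeros);
  double loss_rec = 0.0, reg = 0.0;

  for (uword t = 0; t < T; ++t) {
    mat xt = x.slice(t);
    mat u = masked_input(o, xt, yprev);
    mat g, cn, hn, l;
    lstm_step(P, u, h, c, g, cn, hn, l);
    gates.slice(t) = g; cs.slice(t) = cn; hs.slice(t) = hn; ls.slice(t) = l;
    h = hn; c = cn;
    m += alpha * (K * l - m);
    ms.slice(t) = m;
    mat z = m % (Wx * xt);
    mat y = Wro * z;
    ys.slice(t) = y;
    loss_rec += huber_sum(y - s.slice(t));
    reg += accu(abs(l));
    yprev = y;
  }
  const double wloss = 1.0 / double(n_s * B * T);
  loss_rec *= wloss;
  reg *= o.lambda_out / double(B);

  LstmGrads G; G.init(P);
  mat dh(P.H, B, fill::zeros), dc(P.H, B, fill::zeros);
  mat dmcarry(Nz, B, fill::zeros), dycarry(n_s, B, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat xt = x.slice(t);
    mat dy = wloss * huber_grad(ys.slice(t) - s.slice(t)) + dycarry;
    mat dz = Wro.t() * dy;
    mat dm = dz % (Wx * xt) + dmcarry;
    mat dl = alpha * (K.t() * dm) + (o.lambda_out / double(B)) * sign(ls.slice(t));
    dmcarry = (1.0 - alpha) * dm;

    mat cprev = (t == 0) ? mat(P.H, B, fill::zeros) : cs.slice(t - 1);
    mat hprev = (t == 0) ? mat(P.H, B, fill::zeros) : hs.slice(t - 1);
    mat ypv = (t == 0) ? mat(n_s, B, fill::zeros) : ys.slice(t - 1);
    mat u = masked_input(o, xt, ypv);
    mat du;
    lstm_back(P, gates.slice(t), cs.slice(t), cprev, hs.slice(t), hprev, u, dl,
              dh, dc, du, G);
    dycarry = du.rows(n_s, 2 * n_s - 1);
    dycarry.each_col() %= o.mask_y;
  }

  return List::create(
      Named("loss") = loss_rec + reg, Named("loss_rec") = loss_rec,
      Named("reg") = reg,
      Named("grads") = List::create(
          Named("Wi") = G.gWi, Named("Wh") = G.gWh, Named("b") = G.gb,
          Named("Wl") = G.gWl, Named("bl") = G.gbl));
}

// ---------------------------------------------------------------------------
// Hierarchical Dalean model:
//   zL = [WLx x]+, zI = [|WIL| zL]+, zH = [p .* (|WHL| zL - |WHI| zI)]+,
//   y = Wro zH, p = 1/(1+exp(m)), tau dm/dt = -m + K l.
// Inter-population weights enter as absolute values (Dale's principle).
// Feedforward weights are trainable alongside the modulator.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_grad_dalean(List par, arma::cube x, arma::cube s, List opt) {
  Lstm P = lstm_from_list(par);
  const mat WLx = as<mat>(par["WLx"]);
  const mat WIL = as<mat>(par["WIL"]);
  const mat WHL = as<mat>(par["WHL"]);
  const mat WHI = as<mat>(par["WHI"]);
  const mat Wro = as<mat>(par["Wro"]);
  const mat K = as<mat>(par["K"]);
  const mat AIL = abs(WIL), AHL = abs(WHL), AHI = abs(WHI);
  const uword n_s = x.n_rows, B = x.n_cols, T = x.n_slices;
  const uword NL = WLx.n_rows, NI = WIL.n_rows, NH = WHL.n_rows;
  Opts o = opts_from_list(opt, n_s);
  if (o.tau <= 0) stop("gain modulation requires tau > 0");
  const double alpha = o.dt / o.tau;

  cube gates(4 * P.H, B, T), cs(P.H, B, T), hs(P.H, B, T);
  cube ls(P.n_out, B, T), ms(NH, B, T), ys(n_s, B, T);
  cube zLs(NL, B, T), zIs(NI, B, T), es(NH, B, T), zHs(NH, B, T);

  mat h(P.H, B, fill::zeros), c(P.H, B, fill::zeros);
  mat m(NH, B, fill::zeros), yprev(n_s, B, fill::zeros);
  double loss_rec = 0.0, reg = 0.0;

  for (uword t = 0; t < T; ++t) {
    mat xt = x.slice(t);
    mat u = masked_input(o, xt, yprev);
    mat g, cn, hn, l;
    lstm_step(P, u, h, c, g, cn, hn, l);
    gates.slice(t) = g; cs.slice(t) = cn; hs.slice(t) = hn; ls.slice(t) = l;
    h = hn; c = cn;
    m += alpha * (K * l - m);
    ms.slice(t) = m;
    mat p = 1.0 / (1.0 + exp(m));
    mat zL = clamp(WLx * xt, 0.0, datum::inf);
    mat zI = clamp(AIL * zL, 0.0, datum::inf);
    mat e = AHL * zL - AHI * zI;
    mat zH = clamp(p % e, 0.0, datum::inf);
    mat y = Wro * zH;
    zLs.slice(t) = zL; zIs.slice(t) = zI; es.slice(t) = e; zHs.slice(t) = zH;
    ys.slice(t) = y;
    loss_rec += huber_sum(y - s.slice(t));
    reg += accu(abs(l));
    yprev = y;
  }
  const double wloss = 1.0 / double(n_s * B * T);
  loss_rec *= wloss;
  reg *= o.lambda_out / double(B);

  LstmGrads G; G.init(P);
  mat gWLx(size(WLx), fill::zeros), gAIL(size(WIL), fill::zeros);
  mat gAHL(size(WHL), fill::zeros), gAHI(size(WHI), fill::zeros);
  mat gWro(size(Wro), fill::zeros);
  mat dh(P.H, B, fill::zeros), dc(P.H, B, fill::zeros);
  mat dmcarry(NH, B, fill::zeros), dycarry(n_s, B, fill::zeros);

  for (uword t = T; t-- > 0;) {
    mat xt = x.slice(t);
    mat dy = wloss * huber_grad(ys.slice(t) - s.slice(t)) + dycarry;
    const mat& zL = zLs.slice(t);
    const mat& zI = zIs.slice(t);
    const mat& e = es.slice(t);
    const mat& zH = zHs.slice(t);
    mat p = 1.0 / (1.0 + exp(ms.slice(t)));

    gWro += dy * zH.t();
    mat dzH = Wro.t() * dy;
    mat dvH = dzH % conv_to<mat>::from(zH > 0);
    mat dp = dvH % e;
    mat de = dvH % p;
    mat dm = dp % (-p % (1.0 - p)) + dmcarry;

    mat dzL = AHL.t() * de;
    gAHL += de * zL.t();
    mat dzI = -AHI.t() * de;
    gAHI += -de * zI.t();
    mat dvI = dzI % conv_to<mat>::from(zI > 0);
    dzL += AIL.t() * dvI;
    gAIL += dvI * zL.t();
    mat dvL = dzL % conv_to<mat>::from(zL > 0);
    gWLx += dvL * xt.t();

    mat dl = alpha * (K.t() * dm) + (o.lambda_out / double(B)) * sign(ls.slice(t));
    dmcarry = (1.0 - alpha) * dm;

    mat cprev = (t == 0) ? mat(P.H, B, fill::zeros) : cs.slice(t - 1);
    mat hprev = (t == 0) ? mat(P.H, B, fill::zeros) : hs.slice(t - 1);
    mat ypv = (t == 0) ? mat(n_s, B, fill::zeros) : ys.slice(t - 1);
    mat u = masked_input(o, xt, ypv);
    mat du;
    lstm_back(P, gates.slice(t), cs.slice(t), cprev, hs.slice(t), hprev, u, dl,
              dh, dc, du, G);
    dycarry = du.rows(n_s, 2 * n_s - 1);
    dycarry.each_col() %= o.mask_y;
  }

  return List::create(
      Named("loss") = loss_rec + reg, Named("loss_rec") = loss_rec,
      Named("reg") = reg,
      Named("grads") = List::create(
          Named("Wi") = G.gWi, Named("Wh") = G.gWh, Named("b") = G.gb,
          Named("Wl") = G.gWl, Named("bl") = G.gbl,
          Named("WLx") = gWLx, Named("WIL") = sign(WIL) % gAIL,
          Named("WHL") = sign(WHL) % gAHL, Named("WHI") = sign(WHI) % gAHI,
          Named("Wro") = gWro));
}

// ---------------------------------------------------------------------------
// Forward simulation of a single stimulus stream (no gradients), with the
// manipulation hooks used by the testing protocols:
//  - freeze_from/freeze_to (0-based, half-open): the modulation variable
//    (M for the simple model, m for population/Dalean) is clamped while the
//    LSTM keeps running unseen;
//  - delta/delta_from/delta_to: additive drive to the m-dynamics
//    (modulation-unit manipulation; population/Dalean only).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(std::string arch, List par, arma::mat x, List opt) {
  Lstm P = lstm_from_list(par);
  const uword n_s = x.n_rows, T = x.n_cols;
  Opts o = opts_from_list(opt, n_s);
  const bool filt = o.tau > 0;
  const double alpha = filt ? o.dt / o.tau : 1.0;

  long f0 = opt.containsElementNamed("freeze_from") ? as<long>(opt["freeze_from"]) : -1;
  long f1 = opt.containsElementNamed("freeze_to") ? as<long>(opt["freeze_to"]) : -1;
  double delta = opt.containsElementNamed("delta") ? as<double>(opt["delta"]) : 0.0;
  long d0 = opt.containsElementNamed("delta_from") ? as<long>(opt["delta_from"]) : 0;
  long d1 = opt.containsElementNamed("delta_to") ? as<long>(opt["delta_to"]) : (long)T;

  mat W0, Wx, Wro, K, WLx, AIL, AHL, AHI;
  uword nmod = 0;
  if (arch == "simple") {
    W0 = as<mat>(par["W0"]);
    nmod = n_s * n_s;
  } else if (arch == "population") {
    Wx = as<mat>(par["Wx"]); Wro = as<mat>(par["Wro"]); K = as<mat>(par["K"]);
    nmod = Wx.n_rows;
    if (!filt) stop("population modulation requires tau > 0");
  } else if (arch == "dalean") {
    WLx = as<mat>(par["WLx"]);
    AIL = abs(as<mat>(par["WIL"]));
    AHL = abs(as<mat>(par["WHL"]));
    AHI = abs(as<mat>(par["WHI"]));
    Wro = as<mat>(par["Wro"]); K = as<mat>(par["K"]);
    nmod = AHL.n_rows;
    if (!filt) stop("gain modulation requires tau > 0");
  } else {
    stop("unknown architecture '%s'", arch.c_str());
  }

  mat ys(n_s, T), ls(P.n_out, T), mods(nmod, T);
  mat zs, zLs, zIs, ps;
  if (arch == "population") zs.set_size(nmod, T);
  if (arch == "dalean") {
    zLs.set_size(WLx.n_rows, T);
    zIs.set_size(AIL.n_rows, T);
    zs.set_size(nmod, T);
    ps.set_size(nmod, T);
  }

  vec h(P.H, fill::zeros), c(P.H, fill::zeros);
  vec mod(nmod, fill::zeros), yprev(n_s, fill::zeros);
  if (opt.containsElementNamed("h0") && !Rf_isNull(opt["h0"])) h = as<vec>(opt["h0"]);
  if (opt.containsElementNamed("c0") && !Rf_isNull(opt["c0"])) c = as<vec>(opt["c0"]);
  if (opt.containsElementNamed("mod0") && !Rf_isNull(opt["mod0"])) mod = as<vec>(opt["mod0"]);

  for (uword t = 0; t < T; ++t) {
    vec xt = x.col(t);
    mat u = masked_input(o, mat(xt), mat(yprev));
    mat g, cn, hn, lm;
    lstm_step(P, u, mat(h), mat(c), g, cn, hn, lm);
    h = hn.col(0); c = cn.col(0);
    vec l = lm.col(0);
    ls.col(t) = l;

    const bool frozen = (f0 >= 0 && (long)t >= f0 && (long)t < f1);
    const bool perturbed = (delta != 0.0 && (long)t >= d0 && (long)t < d1);
    if (!frozen) {
      if (arch == "simple") {
        vec drive = l;
        mod = filt ? vec(mod + alpha * (drive - mod)) : drive;
      } else {
        vec drive = K * l;
        if (perturbed) drive += delta;
        mod += alpha * (drive - mod);
      }
    }
    mods.col(t) = mod;

    vec y;
    if (arch == "simple") {
      y.zeros(n_s);
      for (uword r = 0; r < n_s; ++r)
        for (uword cc = 0; cc < n_s; ++cc)
          y(r) += W0(r, cc) * mod(r + cc * n_s) * xt(cc);
    } else if (arch == "population") {
      vec z = mod % (Wx * xt);
      zs.col(t) = z;
      y = Wro * z;
    } else {
      vec p = 1.0 / (1.0 + exp(mod));
      vec zL = clamp(WLx * xt, 0.0, datum::inf);
      vec zI = clamp(AIL * zL, 0.0, datum::inf);
      vec zH = clamp(p % (AHL * zL - AHI * zI), 0.0, datum::inf);
      zLs.col(t) = zL; zIs.col(t) = zI; zs.col(t) = zH; ps.col(t) = p;
      y = Wro * zH;
    }
    ys.col(t) = y;
    yprev = y;
  }

  List out = List::create(
      Named("y") = ys, Named("feedback") = ls, Named("mod") = mods,
      Named("state") = List::create(Named("h") = h, Named("c") = c,
                                    Named("mod") = mod));
  if (arch == "population") out["z"] = zs;
  if (arch == "dalean") {
    out["zL"] = zLs; out["zI"] = zIs; out["zH"] = zs; out["p"] = ps;
  }
  return out;
}
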