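// Fused forward/backward engine for the multi-view gating retrieval network.
// The R level owns data structures, optimisation and protocols; this file
// owns the per-patient computation graph: GRU encoders for the three views,
// the gating drug retrieval module, the joint loss, and its analytic
// gradients (verified against finite differences in the test suite).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// numerically stable softplus: the gating unit's output activation
// (non-negative retrieval weights, unbounded above)
static inline vec softplus(const vec& x) {
  return clamp(x, 0.0, datum::inf) + log1p(exp(-abs(x)));
}

// ---- GRU -------------------------------------------------------------------
// Gate rows stacked [update z; reset r; candidate n]; the candidate bias is
// applied inside the reset-gated recurrent term:
//   z = s(Wz x + Uz h + bz); r = s(Wr x + Ur h + br)
//   n = tanh(Wn x + r .* (Un h + bn));  h' = (1-z).*n + z.*h
struct Gru { mat W, U; vec b; int h; };

struct GruCache { mat X, H, Z, R, N, UN; int L = 0; };

static void gru_forward(const Gru& g, const mat& X, GruCache& c) {
  const int L = X.n_cols, h = g.h;
  c.X = X; c.L = L;
  c.H.zeros(h, L); c.Z.set_size(h, L); c.R.set_size(h, L);
  c.N.set_size(h, L); c.UN.set_size(h, L);
  if (L == 0) return;
  mat A = g.W * X;
  vec hp(h, fill::zeros);
  for (int t = 0; t < L; ++t) {
    vec uh = g.U * hp;
    vec z = sigm(A.col(t).subvec(0, h - 1) + uh.subvec(0, h - 1) + g.b.subvec(0, h - 1));
    vec r = sigm(A.col(t).subvec(h, 2 * h - 1) + uh.subvec(h, 2 * h - 1) + g.b.subvec(h, 2 * h - 1));
    vec un = uh.subvec(2 * h, 3 * h - 1) + g.b.subvec(2 * h, 3 * h - 1);
    vec n = tanh(A.col(t).subvec(2 * h, 3 * h - 1) + r % un);
    hp = (1.0 - z) % n + z % hp;
    c.Z.col(t) = z; c.R.col(t) = r; c.N.col(t) = n; c.UN.col(t) = un;
    c.H.col(t) = hp;
  }
}

struct GruGrad { mat dW, dU; vec db; };

// dH holds the externally injected gradient at every hidden state.
// Accumulates parameter gradients into gr; returns dX (in x L).
static mat gru_backward(const Gru& g, const GruCache& c, const mat& dH,
                        GruGrad& gr) {
  const int h = g.h, L = c.L;
  if (L == 0) return mat(g.W.n_cols, 0);
  mat Dz(h, L), Dr(h, L), Dn(h, L), DnR(h, L);
  vec carry(h, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    vec dh = dH.col(t) + carry;
    vec z = c.Z.col(t), r = c.R.col(t), n = c.N.col(t), un = c.UN.col(t);
    vec hp = (t > 0) ? vec(c.H.col(t - 1)) : vec(h, fill::zeros);
    vec dn = dh % (1.0 - z);
    vec dz = dh % (hp - n);
    carry = dh % z;
    vec dnp = dn % (1.0 - n % n);       // pre-tanh
    vec dun = dnp % r;                  // grad of (Un h + bn)
    vec dzp = dz % z % (1.0 - z);
    vec drp = (dnp % un) % r % (1.0 - r);
    Dz.col(t) = dzp; Dr.col(t) = drp; Dn.col(t) = dnp; DnR.col(t) = dun;
    carry += g.U.rows(0, h - 1).t() * dzp
           + g.U.rows(h, 2 * h - 1).t() * drp
           + g.U.rows(2 * h, 3 * h - 1).t() * dun;
  }
  mat Hprev(h, L, fill::zeros);
  if (L > 1) Hprev.cols(1, L - 1) = c.H.cols(0, L - 2);
  gr.dW.rows(0, h - 1)         += Dz * c.X.t();
  gr.dW.rows(h, 2 * h - 1)     += Dr * c.X.t();
  gr.dW.rows(2 * h, 3 * h - 1) += Dn * c.X.t();
  gr.dU.rows(0, h - 1)         += Dz * Hprev.t();
  gr.dU.rows(h, 2 * h - 1)     += Dr * Hprev.t();
  gr.dU.rows(2 * h, 3 * h - 1) += DnR * Hprev.t();
  gr.db.subvec(0, h - 1)         += sum(Dz, 1);
  gr.db.subvec(h, 2 * h - 1)     += sum(Dr, 1);
  gr.db.subvec(2 * h, 3 * h - 1) += sum(DnR, 1);
  return g.W.rows(0, h - 1).t() * Dz
       + g.W.rows(h, 2 * h - 1).t() * Dr
       + g.W.rows(2 * h, 3 * h - 1).t() * Dn;
}

// ---- model bundle ----------------------------------------------------------
struct Model {
  mat Ed, Ep, m_v, m_s, m_t;
  Gru vd, vp, sdf, sdb, spf, spb, tdf, tdb, tpf, tpb;
  mat gv_W1, gv_W2, gs_W1, gs_W2;
  vec gv_b1, gv_b2, gs_b1, gs_b2;
};

struct Cfg {
  int d, hv, hs, mlp, Nm;
  double dropout, phi;
  bool vst, seq, tkn, gdr;
};

static mat getm(const Rcpp::List& P, const std::string& n) {
  return Rcpp::as<mat>(P[n]);
}
static Gru getgru(const Rcpp::List& P, const std::string& p) {
  Gru g;
  g.W = getm(P, p + "_W"); g.U = getm(P, p + "_U");
  g.b = vec(getm(P, p + "_b").col(0));
  g.h = g.U.n_cols;
  return g;
}

static Model parse_model(const Rcpp::List& P) {
  Model m;
  m.Ed = getm(P, "Ed"); m.Ep = getm(P, "Ep");
  m.m_v = getm(P, "m_v"); m.m_s = getm(P, "m_s"); m.m_t = getm(P, "m_t");
  m.vd = getgru(P, "vd"); m.vp = getgru(P, "vp");
  m.sdf = getgru(P, "sdf"); m.sdb = getgru(P, "sdb");
  m.spf = getgru(P, "spf"); m.spb = getgru(P, "spb");
  m.tdf = getgru(P, "tdf"); m.tdb = getgru(P, "tdb");
  m.tpf = getgru(P, "tpf"); m.tpb = getgru(P, "tpb");
  m.gv_W1 = getm(P, "gv_W1"); m.gv_W2 = getm(P, "gv_W2");
  m.gs_W1 = getm(P, "gs_W1"); m.gs_W2 = getm(P, "gs_W2");
  m.gv_b1 = vec(getm(P, "gv_b1").col(0)); m.gv_b2 = vec(getm(P, "gv_b2").col(0));
  m.gs_b1 = vec(getm(P, "gs_b1").col(0)); m.gs_b2 = vec(getm(P, "gs_b2").col(0));
  return m;
}

static Cfg parse_cfg(const Rcpp::List& L) {
  Cfg c;
  c.d = Rcpp::as<int>(L["d"]); c.hv = Rcpp::as<int>(L["hv"]);
  c.hs = Rcpp::as<int>(L["hs"]); c.mlp = Rcpp::as<int>(L["mlp"]);
  c.Nm = Rcpp::as<int>(L["Nm"]);
  c.dropout = Rcpp::as<double>(L["dropout"]);
  c.phi = Rcpp::as<double>(L["phi"]);
  c.vst = Rcpp::as<bool>(L["use_vst"]); c.seq = Rcpp::as<bool>(L["use_seq"]);
  c.tkn = Rcpp::as<bool>(L["use_tkn"]); c.gdr = Rcpp::as<bool>(L["use_gdr"]);
  return c;
}

struct Patient { std::vector<uvec> diag, proc; std::vector<vec> mhot; };

static Patient parse_patient(const Rcpp::List& L, int Nm) {
  Patient p;
  Rcpp::List dg = L["diag"], pc = L["proc"], dr = L["drugs"];
  const int T = dg.size();
  for (int t = 0; t < T; ++t) {
    Rcpp::IntegerVector di = dg[t], pi = pc[t], mi = dr[t];
    uvec du(di.size()), pu(pi.size());
    for (int i = 0; i < di.size(); ++i) du[i] = (uword)di[i];
    for (int i = 0; i < pi.size(); ++i) pu[i] = (uword)pi[i];
    p.diag.push_back(du); p.proc.push_back(pu);
    vec mh(Nm, fill::zeros);
    for (int i = 0; i < mi.size(); ++i) mh[mi[i]] = 1.0;
    p.mhot.push_back(mh);
  }
  return p;
}

// ---- forward caches --------------------------------------------------------
struct VisitFwd {
  mat De, Pe, maskD, maskP;
  GruCache sdf, sdb, spf, spb, tdf, tdb, tpf, tpb;
  mat Rtd, Rtp;
  vec Cs, rv, rs, rt, rh, s, o;
  std::vector<vec> gvhid, gvg, gvgd, gshid, gsg, gsgd;
};

struct PatFwd {
  std::vector<VisitFwd> V;
  mat DR, PR;
  GruCache vd, vp;
  mat Cv;
};

static mat dropout_mask(int n, int m, double p, std::mt19937& rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  mat M(n, m);
  const double scale = 1.0 / (1.0 - p);
  for (uword j = 0; j < M.n_cols; ++j)
    for (uword i = 0; i < M.n_rows; ++i)
      M(i, j) = (U(rng) >= p) ? scale : 0.0;
  return M;
}

static void forward_patient(const Patient& pt, const Model& M, const Cfg& c,
                            bool training, std::mt19937& rng, PatFwd& pf) {
  const int T = pt.diag.size();
  const bool drop = training && c.dropout > 0.0;
  pf.V.assign(T, VisitFwd());
  pf.DR.zeros(c.d, T); pf.PR.zeros(c.d, T);
  for (int t = 0; t < T; ++t) {
    VisitFwd& vf = pf.V[t];
    vf.De = M.Ed.rows(pt.diag[t]);
    vf.Pe = pt.proc[t].n_elem ? mat(M.Ep.rows(pt.proc[t])) : mat(0, c.d);
    if (drop) {
      vf.maskD = dropout_mask(vf.De.n_rows, c.d, c.dropout, rng);
      vf.maskP = dropout_mask(vf.Pe.n_rows, c.d, c.dropout, rng);
      vf.De %= vf.maskD;
      if (vf.Pe.n_rows) vf.Pe %= vf.maskP;
    }
    if (vf.De.n_rows) pf.DR.col(t) = sum(vf.De, 0).t();
    if (vf.Pe.n_rows) pf.PR.col(t) = sum(vf.Pe, 0).t();
    vf.rv.zeros(c.Nm); vf.rs.zeros(c.Nm); vf.rt.zeros(c.Nm); vf.rh.zeros(c.Nm);
    if (c.seq) {
      vec Ds(2 * c.hs, fill::zeros), Ps(2 * c.hs, fill::zeros);
      if (vf.De.n_rows) {
        gru_forward(M.sdf, vf.De.t(), vf.sdf);
        gru_forward(M.sdb, fliplr(vf.De.t()), vf.sdb);
        Ds = join_cols(vf.sdf.H.col(vf.sdf.L - 1), vf.sdb.H.col(vf.sdb.L - 1));
      }
      if (vf.Pe.n_rows) {
        gru_forward(M.spf, vf.Pe.t(), vf.spf);
        gru_forward(M.spb, fliplr(vf.Pe.t()), vf.spb);
        Ps = join_cols(vf.spf.H.col(vf.spf.L - 1), vf.spb.H.col(vf.spb.L - 1));
      }
      vf.Cs = join_cols(Ds, Ps);
      vf.rs = M.m_s * vf.Cs;
    } else {
      vf.Cs.zeros(4 * c.hs);
    }
    if (c.tkn) {
      vec sd_(c.Nm, fill::zeros), sp_(c.Nm, fill::zeros);
      if (vf.De.n_rows) {
        vf.Rtd = vf.De * M.m_t.t();
        gru_forward(M.tdf, vf.Rtd.t(), vf.tdf);
        gru_forward(M.tdb, fliplr(vf.Rtd.t()), vf.tdb);
        sd_ = vf.tdf.H.col(vf.tdf.L - 1) + vf.tdb.H.col(vf.tdb.L - 1);
      }
      if (vf.Pe.n_rows) {
        vf.Rtp = vf.Pe * M.m_t.t();
        gru_forward(M.tpf, vf.Rtp.t(), vf.tpf);
        gru_forward(M.tpb, fliplr(vf.Rtp.t()), vf.tpb);
        sp_ = vf.tpf.H.col(vf.tpf.L - 1) + vf.tpb.H.col(vf.tpb.L - 1);
      }
      vf.rt = sd_ + sp_;
    }
  }
  if (c.vst) {
    gru_forward(M.vd, pf.DR, pf.vd);
    gru_forward(M.vp, pf.PR, pf.vp);
    pf.Cv = join_cols(pf.vd.H, pf.vp.H);
    for (int t = 0; t < T; ++t) pf.V[t].rv = M.m_v * pf.Cv.col(t);
  } else {
    pf.Cv.zeros(2 * c.hv, T);
  }
  for (int t = 0; t < T; ++t) {
    VisitFwd& vf = pf.V[t];
    if (c.gdr && t > 0) {
      for (int i = 0; i < t; ++i) {
        if (c.vst) {
          vec in = join_cols(pf.Cv.col(t), pf.Cv.col(i));
          vec hid = tanh(M.gv_W1 * in + M.gv_b1);
          vec pre = M.gv_W2 * hid + M.gv_b2;
          vec g = softplus(pre);
          vf.gvhid.push_back(hid); vf.gvg.push_back(g);
          vf.gvgd.push_back(sigm(pre));
          vf.rh += g % pt.mhot[i];
        }
        if (c.seq) {
          vec in = join_cols(vf.Cs, pf.V[i].Cs);
          vec hid = tanh(M.gs_W1 * in + M.gs_b1);
          vec pre = M.gs_W2 * hid + M.gs_b2;
          vec g = softplus(pre);
          vf.gshid.push_back(hid); vf.gsg.push_back(g);
          vf.gsgd.push_back(sigm(pre));
          vf.rh += g % pt.mhot[i];
        }
      }
    }
    vf.s = vf.rv + vf.rs + vf.rt + vf.rh;
    vf.o = sigm(vf.s);
  }
}

// ---- gradients container ---------------------------------------------------
struct AllGrads {
  mat Ed, Ep, m_v, m_s, m_t;
  GruGrad vd, vp, sdf, sdb, spf, spb, tdf, tdb, tpf, tpb;
  mat gv_W1, gv_W2, gs_W1, gs_W2;
  vec gv_b1, gv_b2, gs_b1, gs_b2;
};

static void init_gru_grad(GruGrad& g, const Gru& m) {
  g.dW.zeros(m.W.n_rows, m.W.n_cols);
  g.dU.zeros(m.U.n_rows, m.U.n_cols);
  g.db.zeros(m.b.n_elem);
}

static void init_grads(AllGrads& G, const Model& M) {
  G.Ed.zeros(size(M.Ed)); G.Ep.zeros(size(M.Ep));
  G.m_v.zeros(size(M.m_v)); G.m_s.zeros(size(M.m_s)); G.m_t.zeros(size(M.m_t));
  init_gru_grad(G.vd, M.vd); init_gru_grad(G.vp, M.vp);
  init_gru_grad(G.sdf, M.sdf); init_gru_grad(G.sdb, M.sdb);
  init_gru_grad(G.spf, M.spf); init_gru_grad(G.spb, M.spb);
  init_gru_grad(G.tdf, M.tdf); init_gru_grad(G.tdb, M.tdb);
  init_gru_grad(G.tpf, M.tpf); init_gru_grad(G.tpb, M.tpb);
  G.gv_W1.zeros(size(M.gv_W1)); G.gv_W2.zeros(size(M.gv_W2));
  G.gs_W1.zeros(size(M.gs_W1)); G.gs_W2.zeros(size(M.gs_W2));
  G.gv_b1.zeros(M.gv_b1.n_elem); G.gv_b2.zeros(M.gv_b2.n_elem);
  G.gs_b1.zeros(M.gs_b1.n_elem); G.gs_b2.zeros(M.gs_b2.n_elem);
}

// backward through one patient given dS (Nm x T): the gradient of the batch
// loss with respect to the pre-sigmoid score s_t of every visit.
static void backward_patient(const Patient& pt, PatFwd& pf,
                             const Model& M, const Cfg& c, const mat& dS,
                             bool training, AllGrads& G) {
  const int T = pt.diag.size();
  const bool drop = training && c.dropout > 0.0;
  mat dCv(2 * c.hv, T, fill::zeros);
  mat dCs(4 * c.hs, T, fill::zeros);
  std::vector<mat> dDe(T), dPe(T);
  for (int t = 0; t < T; ++t) {
    dDe[t].zeros(pf.V[t].De.n_rows, c.d);
    dPe[t].zeros(pf.V[t].Pe.n_rows, c.d);
  }
  for (int t = 0; t < T; ++t) {
    VisitFwd& vf = pf.V[t];
    vec ds = dS.col(t);
    if (c.vst) {
      G.m_v += ds * pf.Cv.col(t).t();
      dCv.col(t) += M.m_v.t() * ds;
    }
    if (c.seq) {
      G.m_s += ds * vf.Cs.t();
      dCs.col(t) += M.m_s.t() * ds;
    }
    if (c.tkn) {
      if (vf.De.n_rows) {
        mat dH(c.Nm, vf.tdf.L, fill::zeros);
        dH.col(vf.tdf.L - 1) = ds;
        mat dXf = gru_backward(M.tdf, vf.tdf, dH, G.tdf);
        mat dXb = gru_backward(M.tdb, vf.tdb, dH, G.tdb);
        mat dRtd = (dXf + fliplr(dXb)).t();
        G.m_t += dRtd.t() * vf.De;
        dDe[t] += dRtd * M.m_t;
      }
      if (vf.Pe.n_rows) {
        mat dH(c.Nm, vf.tpf.L, fill::zeros);
        dH.col(vf.tpf.L - 1) = ds;
        mat dXf = gru_backward(M.tpf, vf.tpf, dH, G.tpf);
        mat dXb = gru_backward(M.tpb, vf.tpb, dH, G.tpb);
        mat dRtp = (dXf + fliplr(dXb)).t();
        G.m_t += dRtp.t() * vf.Pe;
        dPe[t] += dRtp * M.m_t;
      }
    }
    if (c.gdr && t > 0) {
      int k = 0;
      for (int i = 0; i < t; ++i, ++k) {
        vec dg = ds % pt.mhot[i];
        if (c.vst) {
          const vec& hid = vf.gvhid[k];
          vec da2 = dg % vf.gvgd[k];  // d softplus = logistic
          G.gv_W2 += da2 * hid.t();
          G.gv_b2 += da2;
          vec dhid = (M.gv_W2.t() * da2) % (1.0 - hid % hid);
          vec in = join_cols(pf.Cv.col(t), pf.Cv.col(i));
          G.gv_W1 += dhid * in.t();
          G.gv_b1 += dhid;
          vec din = M.gv_W1.t() * dhid;
          dCv.col(t) += din.head(2 * c.hv);
          dCv.col(i) += din.tail(2 * c.hv);
        }
        if (c.seq) {
          const vec& hid = vf.gshid[k];
          vec da2 = dg % vf.gsgd[k];
          G.gs_W2 += da2 * hid.t();
          G.gs_b2 += da2;
          vec dhid = (M.gs_W2.t() * da2) % (1.0 - hid % hid);
          vec in = join_cols(vf.Cs, pf.V[i].Cs);
          G.gs_W1 += dhid * in.t();
          G.gs_b1 += dhid;
          vec din = M.gs_W1.t() * dhid;
          dCs.col(t) += din.head(4 * c.hs);
          dCs.col(i) += din.tail(4 * c.hs);
        }
      }
    }
  }
  if (c.seq) {
    for (int t = 0; t < T; ++t) {
      VisitFwd& vf = pf.V[t];
      vec dcs = dCs.col(t);
      if (vf.De.n_rows) {
        vec dhf = dcs.subvec(0, c.hs - 1);
        vec dhb = dcs.subvec(c.hs, 2 * c.hs - 1);
        mat dHf(c.hs, vf.sdf.L, fill::zeros); dHf.col(vf.sdf.L - 1) = dhf;
        mat dHb(c.hs, vf.sdb.L, fill::zeros); dHb.col(vf.sdb.L - 1) = dhb;
        mat dXf = gru_backward(M.sdf, vf.sdf, dHf, G.sdf);
        mat dXb = gru_backward(M.sdb, vf.sdb, dHb, G.sdb);
        dDe[t] += (dXf + fliplr(dXb)).t();
      }
      if (vf.Pe.n_rows) {
        vec dhf = dcs.subvec(2 * c.hs, 3 * c.hs - 1);
        vec dhb = dcs.subvec(3 * c.hs, 4 * c.hs - 1);
        mat dHf(c.hs, vf.spf.L, fill::zeros); dHf.col(vf.spf.L - 1) = dhf;
        mat dHb(c.hs, vf.spb.L, fill::zeros); dHb.col(vf.spb.L - 1) = dhb;
        mat dXf = gru_backward(M.spf, vf.spf, dHf, G.spf);
        mat dXb = gru_backward(M.spb, vf.spb, dHb, G.spb);
        dPe[t] += (dXf + fliplr(dXb)).t();
      }
    }
  }
  if (c.vst) {
    mat dHvd = dCv.rows(0, c.hv - 1);
    mat dHvp = dCv.rows(c.hv, 2 * c.hv - 1);
    mat dDR = gru_backward(M.vd, pf.vd, dHvd, G.vd);
    mat dPR = gru_backward(M.vp, pf.vp, dHvp, G.vp);
    for (int t = 0; t < T; ++t) {
      if (dDe[t].n_rows) dDe[t].each_row() += dDR.col(t).t();
      if (dPe[t].n_rows) dPe[t].each_row() += dPR.col(t).t();
    }
  }
  for (int t = 0; t < T; ++t) {
    VisitFwd& vf = pf.V[t];
    mat dd = dDe[t];
    if (drop && dd.n_rows) dd %= vf.maskD;
    for (uword r = 0; r < dd.n_rows; ++r) G.Ed.row(pt.diag[t][r]) += dd.row(r);
    mat dp = dPe[t];
    if (drop && dp.n_rows) dp %= vf.maskP;
    for (uword r = 0; r < dp.n_rows; ++r) G.Ep.row(pt.proc[t][r]) += dp.row(r);
  }
}

static void put_gru(Rcpp::List& out, const std::string& p, const GruGrad& g) {
  out[p + "_W"] = Rcpp::wrap(g.dW);
  out[p + "_U"] = Rcpp::wrap(g.dU);
  out[p + "_b"] = Rcpp::wrap(mat(g.db));
}

static Rcpp::List grads_to_list(const AllGrads& G) {
  Rcpp::List out;
  out["Ed"] = Rcpp::wrap(G.Ed); out["Ep"] = Rcpp::wrap(G.Ep);
  out["m_v"] = Rcpp::wrap(G.m_v); out["m_s"] = Rcpp::wrap(G.m_s);
  out["m_t"] = Rcpp::wrap(G.m_t);
  put_gru(out, "vd", G.vd); put_gru(out, "vp", G.vp);
  put_gru(out, "sdf", G.sdf); put_gru(out, "sdb", G.sdb);
  put_gru(out, "spf", G.spf); put_gru(out, "spb", G.spb);
  put_gru(out, "tdf", G.tdf); put_gru(out, "tdb", G.tdb);
  put_gru(out, "tpf", G.tpf); put_gru(out, "tpb", G.tpb);
  out["gv_W1"] = Rcpp::wrap(G.gv_W1); out["gv_b1"] = Rcpp::wrap(mat(G.gv_b1));
  out["gv_W2"] = Rcpp::wrap(G.gv_W2); out["gv_b2"] = Rcpp::wrap(mat(G.gv_b2));
  out["gs_W1"] = Rcpp::wrap(G.gs_W1); out["gs_b1"] = Rcpp::wrap(mat(G.gs_b1));
  out["gs_W2"] = Rcpp::wrap(G.gs_W2); out["gs_b2"] = Rcpp::wrap(mat(G.gs_b2));
  return out;
}

// ---- exported: evaluation-mode forward over a list of patients -------------
// [[Rcpp::export]]
Rcpp::List cpp_forward_cohort(Rcpp::List patients, Rcpp::List params,
                              Rcpp::List cfgL) {
  Model M = parse_model(params);
  Cfg c = parse_cfg(cfgL);
  std::mt19937 rng(0);
  Rcpp::List out(patients.size());
  for (int p = 0; p < patients.size(); ++p) {
    Patient pt = parse_patient(patients[p], c.Nm);
    PatFwd pf;
    forward_patient(pt, M, c, false, rng, pf);
    const int T = pt.diag.size();
    mat O(c.Nm, T), RV(c.Nm, T), RS(c.Nm, T), RT(c.Nm, T), RH(c.Nm, T), RG(c.Nm, T);
    mat CS(4 * c.hs, T);
    for (int t = 0; t < T; ++t) {
      const VisitFwd& vf = pf.V[t];
      O.col(t) = vf.o; RV.col(t) = vf.rv; RS.col(t) = vf.rs; RT.col(t) = vf.rt;
      RH.col(t) = vf.rh; RG.col(t) = vf.rv + vf.rs + vf.rt;
      CS.col(t) = vf.Cs;
    }
    out[p] = Rcpp::List::create(
      Rcpp::Named("o") = O, Rcpp::Named("rv") = RV, Rcpp::Named("rs") = RS,
      Rcpp::Named("rt") = RT, Rcpp::Named("rh") = RH, Rcpp::Named("rg") = RG,
      Rcpp::Named("Cv") = pf.Cv, Rcpp::Named("Cs") = CS);
  }
  return out;
}

// ---- exported: joint loss + gradients over a mini-batch --------------------
// Returns summed gradients, mean per-visit loss components, the batch DDI
// rate of the thresholded predictions, and the adaptive DDI weight.
// [[Rcpp::export]]
Rcpp::List cpp_batch_grad(Rcpp::List patients, Rcpp::List params,
                          Rcpp::List cfgL, Rcpp::List lossL, arma::mat ddi,
                          int dropout_seed, bool training = true) {
  Model M = parse_model(params);
  Cfg c = parse_cfg(cfgL);
  const double alpha = Rcpp::as<double>(lossL["alpha"]);
  const double beta = Rcpp::as<double>(lossL["beta"]);
  const double gamma = Rcpp::as<double>(lossL["gamma"]);
  const double kappa = Rcpp::as<double>(lossL["kappa"]);
  const double leps = Rcpp::as<double>(lossL["eps"]);
  std::mt19937 rng((unsigned)dropout_seed);

  const int P = patients.size();
  std::vector<Patient> pts(P);
  std::vector<PatFwd> fwds(P);
  int n_visits = 0;
  double pair_total = 0.0, pair_int = 0.0;
  for (int p = 0; p < P; ++p) {
    pts[p] = parse_patient(patients[p], c.Nm);
    forward_patient(pts[p], M, c, training, rng, fwds[p]);
    const int T = pts[p].diag.size();
    n_visits += T;
    for (int t = 0; t < T; ++t) {
      uvec pred = find(fwds[p].V[t].o >= c.phi);
      const int k = pred.n_elem;
      if (k >= 2) {
        pair_total += k * (k - 1) / 2.0;
        for (int a = 0; a < k; ++a)
          for (int b = a + 1; b < k; ++b)
            pair_int += ddi(pred[a], pred[b]);
      }
    }
  }
  const double ddi_rate = pair_total > 0 ? pair_int / pair_total : 0.0;
  double w = 0.0;
  if (ddi_rate > gamma) w = std::min(1.0, (ddi_rate - gamma) / kappa);

  const double Zdd = std::max(1.0, accu(ddi) / 2.0);
  AllGrads G;
  init_grads(G, M);
  double bce_sum = 0, mlh_sum = 0, addi_sum = 0;
  for (int p = 0; p < P; ++p) {
    const int T = pts[p].diag.size();
    mat dS(c.Nm, T, fill::zeros);
    for (int t = 0; t < T; ++t) {
      const vec& o = fwds[p].V[t].o;
      const vec& s = fwds[p].V[t].s;
      const vec& y = pts[p].mhot[t];
      vec oc = clamp(o, leps, 1.0 - leps);
      bce_sum += mean(-(y % log(oc) + (1.0 - y) % log(1.0 - oc)));
      vec ds = (o - y) / (double)c.Nm;
      uvec pos = find(y > 0.5), neg = find(y < 0.5);
      if (pos.n_elem > 0 && neg.n_elem > 0) {
        const double denom = (double)(pos.n_elem * neg.n_elem);
        double mlh = 0.0;
        for (uword a = 0; a < pos.n_elem; ++a)
          for (uword b = 0; b < neg.n_elem; ++b) {
            double m = 1.0 - (s[pos[a]] - s[neg[b]]);
            if (m > 0) {
              mlh += m;
              ds[pos[a]] -= alpha / denom;
              ds[neg[b]] += alpha / denom;
            }
          }
        mlh_sum += mlh / denom;
      }
      vec Av = ddi * o;
      addi_sum += 0.5 * dot(o, Av) / Zdd;
      ds += (w * beta / Zdd) * (Av % o % (1.0 - o));
      dS.col(t) = ds / (double)n_visits;
    }
    backward_patient(pts[p], fwds[p], M, c, dS, training, G);
  }
  const double bce = bce_sum / n_visits;
  const double mlh = mlh_sum / n_visits;
  const double addi = addi_sum / n_visits;
  return Rcpp::List::create(
    Rcpp::Named("grads") = grads_to_list(G),
    Rcpp::Named("bce") = bce, Rcpp::Named("mlh") = mlh,
    Rcpp::Named("addi") = addi,
    Rcpp::Named("adaptive_weight") = w,
    Rcpp::Named("total") = bce + alpha * mlh + w * beta * addi,
    Rcpp::Named("ddi_rate") = ddi_rate,
    Rcpp::Named("n_visits") = n_visits);
}
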