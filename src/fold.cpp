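// Reference secondary-structure engine: Zuker-style minimum free energy and
// McCaskill partition function / base-pair probabilities over a simplified
// nearest-neighbour model.
//
// Model (all energies kcal/mol):
//   hairpin(size)            = hairpin_a + hairpin_b * (size - min_hairpin)
//   stack(outer, inner)      = -(stack_half[outer] + stack_half[inner])
//   interior/bulge(size)     = interior_a + interior_b * size   (size >= 1)
//   multiloop                = ml_a + ml_b * branches + ml_c * unpaired
//                              (branches counts the closing helix too)
// Interior loops are capped at max_interior unpaired residues; loops closed
// by a pair with exactly one inner branch and more than max_interior
// unpaired residues are outside the model (as in standard implementations).
// Pairs: AU, UA, GC, CG, GU, UG; a pair (i,j) requires j - i - 1 >=
// min_hairpin. No lonely-pair prohibition.
//
// The partition function uses per-nucleotide scaling (factor s, estimated
// from the MFE) so that whole-UTR-sized sequences do not overflow doubles.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF_E = 1e9;

struct Model {
  double stack_half[6];   // AU UA GC CG GU UG
  double hairpin_a, hairpin_b;
  double interior_a, interior_b;
  double ml_a, ml_b, ml_c;
  int max_interior;
  int min_hairpin;
  double rt;              // kcal/mol at folding temperature
};

// residue codes: 0=A 1=C 2=G 3=U
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 3 && b == 0) return 1;  // UA
  if (a == 2 && b == 1) return 2;  // GC
  if (a == 1 && b == 2) return 3;  // CG
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

static Model read_model(const List& par) {
  Model m;
  NumericVector sh = par["stack_half"];
  for (int k = 0; k < 6; ++k) m.stack_half[k] = sh[k];
  m.hairpin_a   = as<double>(par["hairpin_a"]);
  m.hairpin_b   = as<double>(par["hairpin_b"]);
  m.interior_a  = as<double>(par["interior_a"]);
  m.interior_b  = as<double>(par["interior_b"]);
  m.ml_a        = as<double>(par["ml_a"]);
  m.ml_b        = as<double>(par["ml_b"]);
  m.ml_c        = as<double>(par["ml_c"]);
  m.max_interior = as<int>(par["max_interior"]);
  m.min_hairpin  = as<int>(par["min_hairpin"]);
  m.rt           = as<double>(par["rt"]);
  return m;
}

static inline double hairpin_e(const Model& m, int size) {
  return m.hairpin_a + m.hairpin_b * (size - m.min_hairpin);
}

// energy of the two-loop (stack / bulge / interior) between closing pair
// (i,j) and inner pair (k,l); u = unpaired count
static inline double two_loop_e(const Model& m, int ptij, int ptkl, int u) {
  if (u == 0) return -(m.stack_half[ptij] + m.stack_half[ptkl]);
  return m.interior_a + m.interior_b * u;
}

// upper-triangular storage helper
struct Tri {
  int n; std::vector<double> v;
  Tri(int n_, double init) : n(n_), v((size_t)n_ * n_, init) {}
  double& at(int i, int j) { return v[(size_t)i * n + j]; }
  double at(int i, int j) const { return v[(size_t)i * n + j]; }
};

// ---------------------------------------------------------------- MFE ----

struct MfeResult {
  double energy;
  std::vector<int> pair;  // 0-based partner, -1 unpaired
};

static MfeResult fold_mfe_engine(const std::vector<int>& s, const Model& m) {
  const int n = (int)s.size();
  MfeResult res;
  res.pair.assign(n, -1);
  res.energy = 0.0;
  if (n < m.min_hairpin + 2) return res;

  Tri C(n, INF_E), M(n, INF_E), M1(n, INF_E);
  std::vector<double> F(n + 1, 0.0);

  for (int span = m.min_hairpin + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      const int j = i + span - 1;
      const int pt = pair_type(s[i], s[j]);
      if (pt >= 0) {
        double best = hairpin_e(m, j - i - 1);
        // two-loops
        const int kmax = std::min(i + m.max_interior + 1, j - 2);
        for (int k = i + 1; k <= kmax; ++k) {
          const int lu = (k - i - 1);
          const int lmin = std::max(k + m.min_hairpin + 1,
                                    j - 1 - (m.max_interior - lu));
          for (int l = j - 1; l >= lmin; --l) {
            const int ptkl = pair_type(s[k], s[l]);
            if (ptkl < 0) continue;
            const double ckl = C.at(k, l);
            if (ckl >= INF_E) continue;
            const double e = two_loop_e(m, pt, ptkl, lu + (j - l - 1)) + ckl;
            if (e < best) best = e;
          }
        }
        // multiloop: closing pair + >=2 inner branches
        for (int u = i + 2; u <= j - 2; ++u) {
          const double a = M.at(i + 1, u - 1), b = M1.at(u, j - 1);
          if (a >= INF_E || b >= INF_E) continue;
          const double e = m.ml_a + m.ml_b + a + b;
          if (e < best) best = e;
        }
        C.at(i, j) = best;
      }
      // M1: exactly one branch starting at i, trailing unpaired to j
      {
        double best = INF_E;
        if (j - 1 >= i && M1.at(i, j - 1) < INF_E)
          best = M1.at(i, j - 1) + m.ml_c;
        if (pt >= 0 && C.at(i, j) < INF_E)
          best = std::min(best, C.at(i, j) + m.ml_b);
        M1.at(i, j) = best;
      }
      // M: >=1 branch, decomposition on the start u of the last branch
      {
        double best = INF_E;
        for (int u = i; u <= j - m.min_hairpin - 1; ++u) {
          const double right = M1.at(u, j);
          if (right >= INF_E) continue;
          double left = (u - i) * m.ml_c;               // all unpaired
          if (u - 1 >= i + m.min_hairpin + 1 && M.at(i, u - 1) < INF_E)
            left = std::min(left, M.at(i, u - 1));
          if (left + right < best) best = left + right;
        }
        M.at(i, j) = best;
      }
    }
  }

  // external segment
  for (int j = 1; j <= n; ++j) {
    double best = F[j - 1];
    for (int i = 1; i <= j - m.min_hairpin - 1; ++i) {
      const double c = C.at(i - 1, j - 1);
      if (c < INF_E && F[i - 1] + c < best) best = F[i - 1] + c;
    }
    F[j] = best;
  }
  res.energy = F[n];

  // traceback
  const double eps = 1e-7;
  struct Seg { int i, j; char t; };
  std::vector<Seg> st;
  st.push_back({0, n - 1, 'F'});
  while (!st.empty()) {
    Seg sg = st.back(); st.pop_back();
    int i = sg.i, j = sg.j;
    if (sg.t == 'F') {
      int jj = j + 1;               // 1-based end
      while (jj >= 1) {
        if (std::fabs(F[jj] - F[jj - 1]) < eps) { --jj; continue; }
        bool found = false;
        for (int i1 = 1; i1 <= jj - m.min_hairpin - 1; ++i1) {
          const double c = C.at(i1 - 1, jj - 1);
          if (c < INF_E && std::fabs(F[jj] - (F[i1 - 1] + c)) < eps) {
            st.push_back({i1 - 1, jj - 1, 'C'});
            jj = i1 - 1; found = true; break;
          }
        }
        if (!found) --jj;           // defensive; should not happen
      }
    } else if (sg.t == 'C') {
      res.pair[i] = j; res.pair[j] = i;
      const int pt = pair_type(s[i], s[j]);
      const double target = C.at(i, j);
      if (std::fabs(target - hairpin_e(m, j - i - 1)) < eps) continue;
      bool found = false;
      const int kmax = std::min(i + m.max_interior + 1, j - 2);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        const int lu = (k - i - 1);
        const int lmin = std::max(k + m.min_hairpin + 1,
                                  j - 1 - (m.max_interior - lu));
        for (int l = j - 1; l >= lmin; --l) {
          const int ptkl = pair_type(s[k], s[l]);
          if (ptkl < 0 || C.at(k, l) >= INF_E) continue;
          if (std::fabs(target - (two_loop_e(m, pt, ptkl, lu + (j - l - 1))
                                  + C.at(k, l))) < eps) {
            st.push_back({k, l, 'C'}); found = true; break;
          }
        }
      }
      if (found) continue;
      for (int u = i + 2; u <= j - 2 && !found; ++u) {
        const double a = M.at(i + 1, u - 1), b = M1.at(u, j - 1);
        if (a >= INF_E || b >= INF_E) continue;
        if (std::fabs(target - (m.ml_a + m.ml_b + a + b)) < eps) {
          st.push_back({i + 1, u - 1, 'M'});
          st.push_back({u, j - 1, '1'});
          found = true;
        }
      }
    } else if (sg.t == 'M') {
      const double target = M.at(i, j);
      for (int u = i; u <= j - m.min_hairpin - 1; ++u) {
        const double right = M1.at(u, j);
        if (right >= INF_E) continue;
        if (std::fabs(target - ((u - i) * m.ml_c + right)) < eps) {
          st.push_back({u, j, '1'});
          goto done_m;
        }
        if (u - 1 >= i + m.min_hairpin + 1 && M.at(i, u - 1) < INF_E &&
            std::fabs(target - (M.at(i, u - 1) + right)) < eps) {
          st.push_back({i, u - 1, 'M'});
          st.push_back({u, j, '1'});
          goto done_m;
        }
      }
      done_m: ;
    } else {  // '1' : M1 segment, branch starts at i
      int jj = j;
      while (jj > i && std::fabs(M1.at(i, jj) - (M1.at(i, jj - 1) + m.ml_c))
               < eps)
        --jj;
      st.push_back({i, jj, 'C'});
    }
  }
  return res;
}

// ---------------------------------------------------- partition function ----

struct PfResult {
  double g_ensemble;
  bool have_bppm;
  NumericMatrix bppm;
};

static PfResult partition_engine(const std::vector<int>& s, const Model& m,
                                 bool want_bppm, double mfe_estimate) {
  const int n = (int)s.size();
  PfResult out;
  out.g_ensemble = 0.0;
  out.have_bppm = want_bppm;
  if (want_bppm) out.bppm = NumericMatrix(n, n);
  if (n < m.min_hairpin + 2) return out;

  const double beta = 1.0 / m.rt;
  // per-nucleotide scale factor; s_scale >= 1 when structure is stabilising
  double s_scale = 1.0;
  if (mfe_estimate < 0)
    s_scale = std::exp(-beta * 1.07 * mfe_estimate / n);
  const double inv_s = 1.0 / s_scale;
  const double ec = std::exp(-beta * m.ml_c) * inv_s;  // scaled unpaired-in-ML
  const double eb = std::exp(-beta * m.ml_b);
  const double ea = std::exp(-beta * m.ml_a);

  Tri Qb(n, 0.0), Qm(n, 0.0), Qm1(n, 0.0);
  std::vector<double> Qf(n + 1, 0.0), Qfr(n + 2, 0.0);
  // powers of the scaled unpaired weight outside multiloops
  std::vector<double> inv_pow(n + 2);
  inv_pow[0] = 1.0;
  for (int k = 1; k <= n + 1; ++k) inv_pow[k] = inv_pow[k - 1] * inv_s;
  std::vector<double> ec_pow(n + 2);
  ec_pow[0] = 1.0;
  for (int k = 1; k <= n + 1; ++k) ec_pow[k] = ec_pow[k - 1] * ec;

  for (int span = m.min_hairpin + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      const int j = i + span - 1;
      const int pt = pair_type(s[i], s[j]);
      if (pt >= 0) {
        double q = std::exp(-beta * hairpin_e(m, j - i - 1)) * inv_pow[span];
        const int kmax = std::min(i + m.max_interior + 1, j - 2);
        for (int k = i + 1; k <= kmax; ++k) {
          const int lu = (k - i - 1);
          const int lmin = std::max(k + m.min_hairpin + 1,
                                    j - 1 - (m.max_interior - lu));
          for (int l = j - 1; l >= lmin; --l) {
            const int ptkl = pair_type(s[k], s[l]);
            if (ptkl < 0) continue;
            const double qkl = Qb.at(k, l);
            if (qkl <= 0) continue;
            const int d = (k - i) + (j - l);
            q += std::exp(-beta * two_loop_e(m, pt, ptkl,
                                             lu + (j - l - 1)))
                 * qkl * inv_pow[d];
          }
        }
        // multiloop (>=2 inner branches): left Qm, last branch Qm1
        double qml = 0.0;
        for (int u = i + 2; u <= j - 2; ++u) {
          const double a = Qm.at(i + 1, u - 1), b = Qm1.at(u, j - 1);
          if (a > 0 && b > 0) qml += a * b;
        }
        q += ea * eb * qml * inv_pow[2];
        Qb.at(i, j) = q;
      }
      {
        double q = (j - 1 >= i) ? Qm1.at(i, j - 1) * ec : 0.0;
        if (pt >= 0) q += Qb.at(i, j) * eb;
        Qm1.at(i, j) = q;
      }
      {
        double q = 0.0;
        for (int u = i; u <= j - m.min_hairpin - 1; ++u) {
          const double right = Qm1.at(u, j);
          if (right <= 0) continue;
          double left = ec_pow[u - i];
          if (u - 1 >= i + m.min_hairpin + 1) left += Qm.at(i, u - 1);
          q += left * right;
        }
        Qm.at(i, j) = q;
      }
    }
  }

  Qf[0] = 1.0;
  for (int j = 1; j <= n; ++j) {
    double q = Qf[j - 1] * inv_s;
    for (int i = 1; i <= j - m.min_hairpin - 1; ++i)
      q += Qf[i - 1] * Qb.at(i - 1, j - 1);
    Qf[j] = q;
  }
  out.g_ensemble = -m.rt * (std::log(Qf[n]) + n * std::log(s_scale));

  if (!want_bppm) return out;

  // suffix external partition function: Qfr[i] over residues i..n (1-based)
  Qfr[n + 1] = 1.0;
  for (int i = n; i >= 1; --i) {
    double q = Qfr[i + 1] * inv_s;
    for (int j = i + m.min_hairpin + 1; j <= n; ++j)
      q += Qb.at(i - 1, j - 1) * Qfr[j + 1];
    Qfr[i] = q;
  }

  NumericMatrix& P = out.bppm;
  const double Zhat = Qf[n];
  // exterior contributions
  for (int i = 0; i < n; ++i)
    for (int j = i + m.min_hairpin + 1; j < n; ++j) {
      if (Qb.at(i, j) <= 0) continue;
      P(i, j) = Qf[i] * Qb.at(i, j) * Qfr[j + 2] / Zhat;
    }
  // push contributions from enclosing pairs, largest spans first
  for (int span = n; span >= m.min_hairpin + 2; --span) {
    for (int k = 0; k + span - 1 < n; ++k) {
      const int l = k + span - 1;
      const double qkl = Qb.at(k, l);
      if (qkl <= 0) continue;
      const double pkl = P(k, l);
      if (pkl <= 1e-16) continue;
      const int ptkl = pair_type(s[k], s[l]);
      const double base = pkl / qkl;
      // interior loops
      const int imax = std::min(k + m.max_interior + 1, l - 2);
      for (int i = k + 1; i <= imax; ++i) {
        const int lu = (i - k - 1);
        const int jmin = std::max(i + m.min_hairpin + 1,
                                  l - 1 - (m.max_interior - lu));
        for (int j = l - 1; j >= jmin; --j) {
          const double qij = Qb.at(i, j);
          if (qij <= 0) continue;
          const int d = (i - k) + (l - j);
          P(i, j) += base * std::exp(-beta * two_loop_e(m, ptkl,
                       pair_type(s[i], s[j]), lu + (l - j - 1)))
                     * qij * inv_pow[d];
        }
      }
      // multiloop branches
      const double fac = base * ea * eb * eb * inv_pow[2];
      if (fac > 0) {
        for (int i = k + 1; i <= l - 1 - m.min_hairpin - 1; ++i) {
          const double lun = ec_pow[i - k - 1];
          const double lqm = (i - 1 >= k + 1 + m.min_hairpin + 1)
                             ? Qm.at(k + 1, i - 1) : 0.0;
          for (int j = i + m.min_hairpin + 1; j <= l - 1; ++j) {
            const double qij = Qb.at(i, j);
            if (qij <= 0) continue;
            const double run = ec_pow[l - 1 - j];
            const double rqm = (l - 1 >= j + 1 + m.min_hairpin + 1)
                               ? Qm.at(j + 1, l - 1) : 0.0;
            const double w = lun * rqm + lqm * run + lqm * rqm;
            if (w > 0) P(i, j) += fac * qij * w;
          }
        }
      }
    }
  }
  // symmetrise and clamp tiny negatives from rounding
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (j > i) {
        double p = P(i, j);
        if (p < 0) p = 0;
        if (p > 1) p = std::min(p, 1.0);
        P(i, j) = p; P(j, i) = p;
      } else if (j == i) P(i, j) = 0;
    }
  return out;
}

// ------------------------------------------------------------ interface ----

// [[Rcpp::export]]
List c_fold(IntegerVector seq, List par, bool do_mfe, bool do_pf,
            bool do_bppm) {
  std::vector<int> s(seq.begin(), seq.end());
  Model m = read_model(par);
  List out;
  double emfe = NA_REAL;
  if (do_mfe || do_pf) {
    MfeResult r = fold_mfe_engine(s, m);
    emfe = r.energy;
    if (do_mfe) {
      IntegerVector pr(r.pair.size());
      for (size_t k = 0; k < r.pair.size(); ++k)
        pr[k] = r.pair[k] < 0 ? NA_INTEGER : r.pair[k] + 1;
      out["e_mfe"] = r.energy;
      out["mfe_pairs"] = pr;
    }
  }
  if (do_pf) {
    PfResult p = partition_engine(s, m, do_bppm, emfe);
    out["g_ensemble"] = p.g_ensemble;
    if (do_bppm) out["bppm"] = p.bppm;
  }
  return out;
}

// batch energies for scans: rows = sequences, cols = (e_mfe, g_ensemble)
// [[Rcpp::export]]
NumericMatrix c_fold_energies(List seqs, List par, bool do_pf) {
  Model m = read_model(par);
  const int nseq = seqs.size();
  NumericMatrix out(nseq, 2);
  for (int q = 0; q < nseq; ++q) {
    IntegerVector sv = seqs[q];
    std::vector<int> s(sv.begin(), sv.end());
    MfeResult r = fold_mfe_engine(s, m);
    out(q, 0) = r.energy;
    if (do_pf) {
      PfResult p = partition_engine(s, m, false, r.energy);
      out(q, 1) = p.g_ensemble;
    } else {
      out(q, 1) = NA_REAL;
    }
  }
  return out;
}
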