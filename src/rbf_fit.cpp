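#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Internal parameter matrix layout (8 x G), positives on log scale:
// row 0: log h, 1: log a, 2: tau, 3: log gamma, 4: log beta,
// row 5: log b, 6: o, 7: i
static const int R_LH = 0, R_LA = 1, R_TAU = 2, R_LG = 3, R_LB = 4,
                 R_LPREC = 5, R_O = 6, R_I = 7;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Per-gene negative log-likelihood: pi * b^2 * sum_i |e_i|^2 - log(b),
// residuals taken jointly in the (u, s) plane.
// [[Rcpp::export]]
List cpp_loss(const NumericMatrix& Mu, const NumericMatrix& Ms,
              const NumericMatrix& T, const NumericMatrix& theta) {
  const int n = Mu.nrow(), G = Mu.ncol();
  NumericVector per_gene(G);
  double total = 0.0;
  for (int g = 0; g < G; ++g) {
    const double h = std::exp(theta(R_LH, g)), a = std::exp(theta(R_LA, g));
    const double tau = theta(R_TAU, g), gam = std::exp(theta(R_LG, g));
    const double bet = std::exp(theta(R_LB, g)), b = std::exp(theta(R_LPREC, g));
    const double o = theta(R_O, g), ii = theta(R_I, g);
    double D = 0.0;
    for (int c = 0; c < n; ++c) {
      const double d = T(c, g) - tau;
      const double E = std::exp(-a * d * d);
      const double s = h * E + o;
      const double sp = h * E * (-2.0 * a * d);
      const double u = (sp + gam * s) / bet + ii;
      const double es = s - Ms(c, g), eu = u - Mu(c, g);
      D += es * es + eu * eu;
    }
    per_gene[g] = M_PI * b * b * D - std::log(b);
    total += per_gene[g];
  }
  return List::create(_["total"] = total, _["per_gene"] = per_gene);
}

// Run n_steps Adam updates of all gene parameters against the summed
// negative log-likelihood, holding the time matrix T fixed. Returns the
// updated parameters, Adam state and the loss recorded before each step.
// fix_toi freezes (tau, o, i) for independent-mode fits.
// [[Rcpp::export]]
List cpp_adam_steps(const NumericMatrix& Mu, const NumericMatrix& Ms,
                    const NumericMatrix& T, NumericMatrix theta,
                    NumericMatrix m, NumericMatrix v, int step0,
                    int n_steps, double lr, double beta1, double beta2,
                    double eps, bool fix_toi) {
  const int n = Mu.nrow(), G = Mu.ncol();
  NumericMatrix th = clone(theta), mm = clone(m), vv = clone(v);
  NumericVector trace(n_steps);
  double grad[8];

  for (int step = 0; step < n_steps; ++step) {
    const int t_adam = step0 + step + 1;
    const double bc1 = 1.0 - std::pow(beta1, (double)t_adam);
    const double bc2 = 1.0 - std::pow(beta2, (double)t_adam);
    double total_loss = 0.0;

    for (int g = 0; g < G; ++g) {
      const double h = std::exp(th(R_LH, g)), a = std::exp(th(R_LA, g));
      const double tau = th(R_TAU, g), gam = std::exp(th(R_LG, g));
      const double bet = std::exp(th(R_LB, g)), b = std::exp(th(R_LPREC, g));
      const double o = th(R_O, g), ii = th(R_I, g);
      double D = 0.0, gh = 0.0, ga = 0.0, gtau = 0.0, ggam = 0.0, gbet = 0.0,
             go = 0.0, gi = 0.0;

      for (int c = 0; c < n; ++c) {
        const double d = T(c, g) - tau;
        const double d2 = d * d;
        const double E = std::exp(-a * d2);
        const double P = -2.0 * a * d;
        const double hE = h * E;
        const double s = hE + o;
        const double sp = hE * P;
        const double u = (sp + gam * s) / bet + ii;
        const double es = s - Ms(c, g), eu = u - Mu(c, g);
        D += es * es + eu * eu;
        // partials of s and u wrt raw parameters
        gh   += es * E + eu * (E * (P + gam) / bet);
        ga   += es * (-h * d2 * E) +
                eu * (hE * (-d2 * P - 2.0 * d - gam * d2) / bet);
        gtau += es * (2.0 * a * d * hE) +
                eu * (hE * (2.0 * a * d * P + 2.0 * a + 2.0 * a * gam * d) / bet);
        ggam += eu * (s / bet);
        gbet += eu * (-(u - ii) / bet);
        go   += es + eu * (gam / bet);
        gi   += eu;
      }

      const double scale = 2.0 * M_PI * b * b;
      grad[R_LH] = scale * gh * h;
      grad[R_LA] = scale * ga * a;
      grad[R_TAU] = scale * gtau;
      grad[R_LG] = scale * ggam * gam;
      grad[R_LB] = scale * gbet * bet;
      grad[R_LPREC] = 2.0 * M_PI * b * b * D - 1.0;
      grad[R_O] = scale * go;
      grad[R_I] = scale * gi;
      if (fix_toi) { grad[R_TAU] = 0.0; grad[R_O] = 0.0; grad[R_I] = 0.0; }

      for (int p = 0; p < 8; ++p) {
        if (!std::isfinite(grad[p]))
          stop("non-finite gradient for gene index %d (parameter row %d)",
               g + 1, p + 1);
        mm(p, g) = beta1 * mm(p, g) + (1.0 - beta1) * grad[p];
        vv(p, g) = beta2 * vv(p, g) + (1.0 - beta2) * grad[p] * grad[p];
        th(p, g) -= lr * (mm(p, g) / bc1) / (std::sqrt(vv(p, g) / bc2) + eps);
      }
      th(R_LH, g) = clampd(th(R_LH, g), -18.0, 18.0);
      th(R_LA, g) = clampd(th(R_LA, g), -18.0, 18.0);
      th(R_LG, g) = clampd(th(R_LG, g), -18.0, 18.0);
      th(R_LB, g) = clampd(th(R_LB, g), -18.0, 18.0);
      th(R_LPREC, g) = clampd(th(R_LPREC, g), -18.0, 18.0);
      th(R_TAU, g) = clampd(th(R_TAU, g), -5.0, 6.0);

      total_loss += M_PI * b * b * D - std::log(b);
    }
    trace[step] = total_loss;
  }
  return List::create(_["theta"] = th, _["m"] = mm, _["v"] = vv,
                      _["step"] = step0 + n_steps, _["trace"] = trace);
}

// Grid-search time assignment: for each cell and gene, the candidate time
// in `grid` minimizing the squared (u, s)-plane distance between the
// smoothed observation and the parametric trajectory. Ties keep the
// smallest candidate (grid is ascending, strict improvement required).
// [[Rcpp::export]]
NumericMatrix cpp_assign_time(const NumericMatrix& Mu, const NumericMatrix& Ms,
                              const NumericMatrix& theta,
                              const NumericVector& grid) {
  const int n = Mu.nrow(), G = Mu.ncol(), K = grid.size();
  NumericMatrix T(n, G);
  std::vector<double> sg(K), ug(K);
  for (int g = 0; g < G; ++g) {
    const double h = std::exp(theta(R_LH, g)), a = std::exp(theta(R_LA, g));
    const double tau = theta(R_TAU, g), gam = std::exp(theta(R_LG, g));
    const double bet = std::exp(theta(R_LB, g));
    const double o = theta(R_O, g), ii = theta(R_I, g);
    for (int k = 0; k < K; ++k) {
      const double d = grid[k] - tau;
      const double E = std::exp(-a * d * d);
      const double s = h * E + o;
      const double sp = h * E * (-2.0 * a * d);
      sg[k] = s;
      ug[k] = (sp + gam * s) / bet + ii;
    }
    for (int c = 0; c < n; ++c) {
      const double ms = Ms(c, g), mu = Mu(c, g);
      double best = R_PosInf;
      int kbest = 0;
      for (int k = 0; k < K; ++k) {
        const double ds = sg[k] - ms, du = ug[k] - mu;
        const double dist = ds * ds + du * du;
        if (dist < best) { best = dist; kbest = k; }
      }
      T(c, g) = grid[kbest];
    }
  }
  return T;
}
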