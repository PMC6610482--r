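#include <Rcpp.h>
using namespace Rcpp;

// Two-variable Aliev-Panfilov excitable medium on a masked grid.
// type: 0 = background (inert), 1 = myocyte, 2 = fibroblast (passive).
// amap: per-pixel excitation threshold a (myocytes only).
// dmap: per-pixel diffusion coefficient (mm^2/ms); edges use the harmonic mean.
// Time unit is ms; the dimensionless reaction is scaled by 1/time_scale.

// [[Rcpp::export]]
NumericVector sim_core(IntegerMatrix type, NumericMatrix amap, NumericMatrix dmap,
                       double k, double eps0, double mu1, double mu2,
                       double time_scale, double g_fb, double u_fb_rest,
                       double dx, double dt, int n_steps, int record_every,
                       LogicalMatrix stim_mask, NumericVector stim_start,
                       double stim_dur, double stim_amp) {
  const int H = type.nrow(), W = type.ncol(), N = H * W;
  std::vector<double> u(N, 0.0), v(N, 0.0), du(N, 0.0);
  std::vector<int> act;           // active (tissue) pixel indices
  act.reserve(N);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (type[i + H * j] > 0) act.push_back(i + H * j);
  const int NA_ = (int) act.size();

  // neighbour indices (-1 outside tissue) and edge weights D_edge/dx^2
  std::vector<int> nb(4 * NA_, -1);
  std::vector<double> wt(4 * NA_, 0.0);
  const double dx2 = dx * dx;
  for (int p = 0; p < NA_; ++p) {
    int idx = act[p], i = idx % H, j = idx / H;
    int off[4][2] = {{-1, 0}, {1, 0}, {0, -1}, {0, 1}};
    for (int q = 0; q < 4; ++q) {
      int ii = i + off[q][0], jj = j + off[q][1];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      int nidx = ii + H * jj;
      if (type[nidx] == 0) continue;
      double d1 = dmap[idx], d2 = dmap[nidx];
      if (d1 <= 0.0 || d2 <= 0.0) continue;
      nb[4 * p + q] = nidx;
      wt[4 * p + q] = 2.0 * d1 * d2 / (d1 + d2) / dx2;
    }
  }

  const int n_rec = n_steps / record_every + 1;
  NumericVector out(n_rec * (R_xlen_t) N, 0.0);
  const double its = 1.0 / time_scale;
  const int n_pulse = stim_start.size();
  int pulse = 0;

  int rec = 0;
  for (int p = 0; p < NA_; ++p) out[(R_xlen_t) rec + (R_xlen_t) n_rec * act[p]] = u[act[p]];
  ++rec;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    while (pulse < n_pulse && t >= stim_start[pulse] + stim_dur) ++pulse;
    bool stim_on = (pulse < n_pulse && t >= stim_start[pulse]);

    for (int p = 0; p < NA_; ++p) {
      int idx = act[p];
      double uc = u[idx], lap = 0.0;
      for (int q = 0; q < 4; ++q) {
        int nidx = nb[4 * p + q];
        if (nidx >= 0) lap += wt[4 * p + q] * (u[nidx] - uc);
      }
      double d;
      if (type[idx] == 1) {
        double a = amap[idx], vc = v[idx];
        double react = -k * uc * (uc - a) * (uc - 1.0) - uc * vc;
        double istim = (stim_on && stim_mask[idx]) ? stim_amp : 0.0;
        d = lap + (react + istim) * its;
        double eps = eps0 + mu1 * vc / (uc + mu2);
        v[idx] += dt * its * eps * (-vc - k * uc * (uc - a - 1.0));
      } else { // fibroblast: passive leak toward a less-negative rest level
        d = lap + g_fb * (u_fb_rest - uc) * its;
      }
      du[idx] = d;
    }
    for (int p = 0; p < NA_; ++p) u[act[p]] += dt * du[act[p]];

    if ((s + 1) % record_every == 0) {
      bool bad = false;
      for (int p = 0; p < NA_; ++p) {
        double val = u[act[p]];
        if (!R_FINITE(val)) { bad = true; break; }
        out[(R_xlen_t) rec + (R_xlen_t) n_rec * act[p]] = val;
      }
      if (bad) stop("numerical instability: non-finite membrane potential at t = %f ms", t);
      ++rec;
    }
  }
  out.attr("dim") = IntegerVector::create(n_rec, H, W);
  return out;
}
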