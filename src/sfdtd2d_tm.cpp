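#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// TM-mode (Ez, Hx, Hy) staged stepper, the companion of the TE kernel in
// sfdtd2d.cpp. Same conventions: E-units (H stored as Z0 * H), staged
// split-operator composition, selectable stencil (a1, a2), analytic TF/SF
// plane wave travelling +x (Ez polarised: Hy_inc = -Ez_inc, Hx_inc = 0),
// per-stage Mur or PEC on the boundary Ez ring. Hot loops use raw column
// pointers: the SEXP-backed matrix accessors defeat the optimiser when
// three arrays are live in one statement.
//
// Layout (nx x ny cells, spacing delta):
//   Ez(i, j) at (i d, j d),                i = 0..nx, j = 0..ny
//   Hx(i, j) at (i d, (j + 1/2) d),        i = 0..nx, j = 0..ny-1
//   Hy(i, j) at ((i + 1/2) d, j d),        i = 0..nx-1, j = 0..ny
//
//   dDz/dt = c0 (dHy/dx - dHx/dy) - Jz/eps0
//   dHx/dt = -c0 dEz/dy
//   dHy/dt =  c0 dEz/dx

static const double C0 = 299792458.0;
static const double EPS0 = 8.8541878128e-12;

struct IncidentTM {
  double amp, freq, ramp_t, xs;
  double operator()(double x, double t) const {
    if (amp == 0.0) return 0.0;
    double u = t - (x - xs) / C0;
    if (u <= 0.0) return 0.0;
    double r = (u >= ramp_t) ? 1.0 : 0.5 * (1.0 - std::cos(M_PI * u / ramp_t));
    return amp * r * std::sin(2.0 * M_PI * freq * u);
  }
};

// [[Rcpp::export(name = ".sfdtd2d_tm_run")]]
List sfdtd2d_tm_run(int nx, int ny, double delta, double dt, int nsteps,
                    NumericVector cs, NumericVector ds, double a1, double a2,
                    NumericMatrix ezEps, NumericMatrix ezSig, IntegerMatrix ezPl,
                    double fp, double nu,
                    int tfi0, int tfi1, int tfj0, int tfj1,
                    double srcAmp, double srcFreq, double rampPeriods,
                    int boundary,   // 0 = mur, 1 = pec
                    int trackStart,
                    IntegerVector probeI, IntegerVector probeJ) {
  const int m = cs.size();
  const bool hasSrc = srcAmp != 0.0;
  if (hasSrc) {
    if (tfi0 < 4 || tfj0 < 4 || tfi1 > nx - 5 || tfj1 > ny - 5)
      stop("TF/SF window must keep >= 4 cells from the outer boundary");
  }
  IncidentTM inc{srcAmp, srcFreq, rampPeriods / srcFreq,
                 static_cast<double>(tfi0) * delta};

  const int le = nx + 1;           // leading dimension of node arrays
  NumericMatrix Ez(le, ny + 1), Dz(le, ny + 1), acc(le, ny + 1), Jz(le, ny + 1);
  NumericMatrix Hx(le, ny), Hy(nx, ny + 1);
  NumericMatrix peakEz(le, ny + 1);

  double *pEz = REAL(Ez), *pDz = REAL(Dz), *pAcc = REAL(acc), *pJz = REAL(Jz);
  double *pHx = REAL(Hx), *pHy = REAL(Hy), *pPk = REAL(peakEz);
  const double *pEps = REAL(ezEps), *pSig = REAL(ezSig);
  const int *pPl = INTEGER(ezPl);

  const int np = probeI.size();
  NumericMatrix probes(np > 0 ? nsteps : 0, np);

  const double wpl = 2.0 * M_PI * fp, nur = nu; // nu is the collision rate (1/s)
  const bool hasPlasma = fp > 0.0;
  const double alphaJ = hasPlasma ? std::exp(-nur * dt) : 1.0;
  const double betaJ = hasPlasma
    ? ((nur > 0.0) ? EPS0 * wpl * wpl * (1.0 - alphaJ) / nur
                   : EPS0 * wpl * wpl * dt)
    : 0.0;
  int lastEStage = 0;
  for (int l = 0; l < m; ++l) if (cs[l] != 0.0) lastEStage = l;

  // Mur stores: previous Ez on the boundary ring and its inner neighbour
  std::vector<double> oL0(ny + 1), oL1(ny + 1), oR0(ny + 1), oR1(ny + 1);
  std::vector<double> oB0(nx + 1), oB1(nx + 1), oT0(nx + 1), oT1(nx + 1);

  double tE = 0.0, tH = 0.0;
  const double id = 1.0 / delta;

  for (int n = 0; n < nsteps; ++n) {
    for (int l = 0; l < m; ++l) {
      const double dts = cs[l] * dt;
      if (dts != 0.0) {
        const double f = dts * C0;
        if (boundary == 0) {
          for (int j = 0; j <= ny; ++j) {
            oL0[j] = pEz[0 + le * j]; oL1[j] = pEz[1 + le * j];
            oR0[j] = pEz[nx + le * j]; oR1[j] = pEz[nx - 1 + le * j];
          }
          for (int i = 0; i <= nx; ++i) {
            oB0[i] = pEz[i]; oB1[i] = pEz[i + le];
            oT0[i] = pEz[i + le * ny]; oT1[i] = pEz[i + le * (ny - 1)];
          }
        }
        // --- Dz += dts c0 (dHy/dx - dHx/dy) at interior nodes ---
        for (int j = 1; j < ny; ++j) {
          const bool wideY = (j >= 2 && j <= ny - 2);
          double *dz = pDz + le * j;
          const double *hy = pHy + nx * j;
          const double *hx0 = pHx + le * j, *hxm = pHx + le * (j - 1);
          const double *hxp = pHx + le * (j + 1), *hxm2 = pHx + le * (j - 2);
          if (wideY) {
            for (int i = 2; i <= nx - 2; ++i) {
              const double dhy = (a1 * (hy[i] - hy[i - 1]) +
                                  a2 * (hy[i + 1] - hy[i - 2])) * id;
              const double dhx = (a1 * (hx0[i] - hxm[i]) +
                                  a2 * (hxp[i] - hxm2[i])) * id;
              dz[i] += f * (dhy - dhx);
            }
            const int edge[2] = {1, nx - 1};
            for (int t = 0; t < 2; ++t) {
              // i = 1 and i = nx - 1: second-order in x, fourth in y
              const int i = edge[t];
              const double dhy = (hy[i] - hy[i - 1]) * id;
              const double dhx = (a1 * (hx0[i] - hxm[i]) +
                                  a2 * (hxp[i] - hxm2[i])) * id;
              dz[i] += f * (dhy - dhx);
            }
          } else {
            for (int i = 1; i < nx; ++i) {
              double dhy;
              if (i >= 2 && i <= nx - 2)
                dhy = (a1 * (hy[i] - hy[i - 1]) + a2 * (hy[i + 1] - hy[i - 2])) * id;
              else
                dhy = (hy[i] - hy[i - 1]) * id;
              const double dhx = (hx0[i] - hxm[i]) * id;
              dz[i] += f * (dhy - dhx);
            }
          }
        }
        // --- TF/SF corrections on the Hy taps (x-crossings);
        //     Hx_inc = 0 so the y-derivative needs none ---
        if (hasSrc) {
          const double wts[4] = {-a2 * id, -a1 * id, a1 * id, a2 * id};
          const int iband[6] = {tfi0 - 1, tfi0, tfi0 + 1,
                                tfi1, tfi1 + 1, tfi1 + 2};
          for (int b = 0; b < 6; ++b) {
            const int i = iband[b];
            if (i < 1 || i > nx - 1) continue;
            const bool kE = (i >= tfi0 && i <= tfi1 + 1);
            const int it[4] = {i - 2, i - 1, i, i + 1};
            for (int t = 0; t < 4; ++t) {
              const bool kH = (it[t] >= tfi0 && it[t] <= tfi1);
              if (kE == kH) continue;
              // Hy_inc = -Ez_inc at the Hy position
              const double corr = f * wts[t] * (kE ? 1.0 : -1.0) *
                (-inc((it[t] + 0.5) * delta, tH));
              for (int j = tfj0; j <= tfj1 + 1; ++j) pDz[i + le * j] += corr;
            }
          }
        }
        // --- plasma current (frozen within the step) and constitutive ---
        const bool lastE = (l == lastEStage);
        for (int j = 1; j < ny; ++j) {
          double *dz = pDz + le * j, *ez = pEz + le * j, *ac = pAcc + le * j;
          double *jz = pJz + le * j;
          const double *ep = pEps + le * j, *sg = pSig + le * j;
          const int *plm = pPl + le * j;
          for (int i = 1; i < nx; ++i) {
            if (hasPlasma && plm[i])
              dz[i] -= dts * jz[i] / EPS0;
            const double q = sg[i] * dt / EPS0;
            if (q != 0.0) {
              const double e = (dz[i] - q * ac[i]) / (ep[i] + q);
              ez[i] = e;
              if (lastE) ac[i] += e;
            } else {
              ez[i] = dz[i] / ep[i];
            }
            if (lastE && hasPlasma && plm[i])
              jz[i] = alphaJ * jz[i] + betaJ * ez[i];
          }
        }
        tE += dts;
        if (boundary == 1) { // PEC ring
          for (int j = 0; j <= ny; ++j) {
            pEz[0 + le * j] = pDz[0 + le * j] = 0.0;
            pEz[nx + le * j] = pDz[nx + le * j] = 0.0;
          }
          for (int i = 0; i <= nx; ++i) {
            pEz[i] = pDz[i] = 0.0;
            pEz[i + le * ny] = pDz[i + le * ny] = 0.0;
          }
        } else { // per-stage Mur, sub-step-scaled coefficient
          const double murK = (C0 * dts - delta) / (C0 * dts + delta);
          for (int j = 1; j < ny; ++j) {
            pEz[0 + le * j] = oL1[j] + murK * (pEz[1 + le * j] - oL0[j]);
            pDz[0 + le * j] = pEps[0 + le * j] * pEz[0 + le * j];
            pEz[nx + le * j] = oR1[j] + murK * (pEz[nx - 1 + le * j] - oR0[j]);
            pDz[nx + le * j] = pEps[nx + le * j] * pEz[nx + le * j];
          }
          for (int i = 0; i <= nx; ++i) {
            pEz[i] = oB1[i] + murK * (pEz[i + le] - oB0[i]);
            pDz[i] = pEps[i] * pEz[i];
            pEz[i + le * ny] = oT1[i] + murK * (pEz[i + le * (ny - 1)] - oT0[i]);
            pDz[i + le * ny] = pEps[i + le * ny] * pEz[i + le * ny];
          }
        }
      }

      const double dtl = ds[l] * dt;
      if (dtl != 0.0) {
        const double f = dtl * C0;
        // Hx -= dtl c0 dEz/dy
        for (int j = 0; j < ny; ++j) {
          const bool wideY = (j >= 1 && j <= ny - 2);
          double *hx = pHx + le * j;
          const double *e0 = pEz + le * j, *e1 = pEz + le * (j + 1);
          if (wideY) {
            const double *e2 = pEz + le * (j + 2), *em = pEz + le * (j - 1);
            for (int i = 0; i <= nx; ++i)
              hx[i] -= f * (a1 * (e1[i] - e0[i]) + a2 * (e2[i] - em[i])) * id;
          } else {
            for (int i = 0; i <= nx; ++i)
              hx[i] -= f * (e1[i] - e0[i]) * id;
          }
        }
        // Hy += dtl c0 dEz/dx
        for (int j = 0; j <= ny; ++j) {
          double *hy = pHy + nx * j;
          const double *e = pEz + le * j;
          for (int i = 1; i <= nx - 2; ++i)
            hy[i] += f * (a1 * (e[i + 1] - e[i]) + a2 * (e[i + 2] - e[i - 1])) * id;
          hy[0] += f * (e[1] - e[0]) * id;
          hy[nx - 1] += f * (e[nx] - e[nx - 1]) * id;
        }
        // --- TF/SF corrections ---
        if (hasSrc) {
          const double wts[4] = {-a2 * id, -a1 * id, a1 * id, a2 * id};
          // Hy update, left/right bands (Ez taps cross the x-boundaries)
          const int ibandC[8] = {tfi0 - 2, tfi0 - 1, tfi0, tfi0 + 1,
                                 tfi1 - 1, tfi1, tfi1 + 1, tfi1 + 2};
          for (int b = 0; b < 8; ++b) {
            const int i = ibandC[b];
            if (i < 0 || i > nx - 1) continue;
            const bool kH = (i >= tfi0 && i <= tfi1);
            const int it[4] = {i - 1, i, i + 1, i + 2};
            for (int t = 0; t < 4; ++t) {
              const bool kEz = (it[t] >= tfi0 && it[t] <= tfi1 + 1);
              if (kH == kEz) continue;
              const double corr = f * wts[t] * (kH ? 1.0 : -1.0) *
                inc(it[t] * delta, tE);
              for (int j = tfj0; j <= tfj1 + 1; ++j) pHy[i + nx * j] += corr;
            }
          }
          // Hx update, top/bottom bands (Ez taps cross the y-boundaries;
          // Ez_inc depends on x only but the window kind changes with j)
          const int jbandD[8] = {tfj0 - 2, tfj0 - 1, tfj0, tfj0 + 1,
                                 tfj1 - 1, tfj1, tfj1 + 1, tfj1 + 2};
          for (int b = 0; b < 8; ++b) {
            const int j = jbandD[b];
            if (j < 0 || j > ny - 1) continue;
            const bool kH = (j >= tfj0 && j <= tfj1); // Hx window kind
            const int jt[4] = {j - 1, j, j + 1, j + 2};
            for (int t = 0; t < 4; ++t) {
              const bool kEz = (jt[t] >= tfj0 && jt[t] <= tfj1 + 1);
              if (kH == kEz) continue;
              const double sgn = (kH ? 1.0 : -1.0);
              double *hx = pHx + le * j;
              for (int i = tfi0; i <= tfi1 + 1; ++i)
                hx[i] -= f * wts[t] * sgn * inc(i * delta, tE);
            }
          }
        }
        tH += dtl;
      }
    }

    if (n + 1 > trackStart) {
      const int ntot = le * (ny + 1);
      for (int k = 0; k < ntot; ++k) {
        const double v = std::fabs(pEz[k]);
        if (v > pPk[k]) pPk[k] = v;
      }
    }
    for (int p = 0; p < np; ++p)
      probes(n, p) = pEz[probeI[p] + le * probeJ[p]];

    if ((n & 63) == 0) {
      if (!std::isfinite(pEz[nx / 2 + le * (ny / 2)]))
        stop("instability detected: non-finite field at step %d", n + 1);
      checkUserInterrupt();
    }
  }
  if (!std::isfinite(pEz[nx / 2 + le * (ny / 2)]))
    stop("instability detected: non-finite field at step %d", nsteps);

  return List::create(_["Ez"] = Ez, _["Hx"] = Hx, _["Hy"] = Hy,
                      _["peak_ez"] = peakEz, _["probes"] = probes,
                      _["time"] = tE, _["steps"] = nsteps);
}
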