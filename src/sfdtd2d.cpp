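#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Staged split-operator TE-mode (Ex, Ey, Hz) stepper on the staggered Yee
// lattice with selectable stencil weights (a1, a2). Fields are stored in
// E-units: electric fields in V/m, Hz as Z0 * H so a vacuum plane wave has
// equal numeric amplitudes and both curl updates carry a factor c0.
//
// Layout (grid of nx x ny cells, spacing delta):
//   Ex(i, j) at ((i + 1/2) d, j d),        i = 0..nx-1, j = 0..ny
//   Ey(i, j) at (i d, (j + 1/2) d),        i = 0..nx,   j = 0..ny-1
//   Hz(i, j) at ((i + 1/2) d, (j + 1/2) d) i = 0..nx-1, j = 0..ny-1
//
// A monochromatic plane wave travelling +x (Ey polarised) enters through a
// rectangular total-field/scattered-field window spanning cells
// [tfi0, tfi1] x [tfj0, tfj1]; the incident field is analytic, and the
// one-sided stencil taps crossing the window boundary are compensated at the
// stage-accumulated electric/magnetic times.

static const double C0 = 299792458.0;
static const double EPS0 = 8.8541878128e-12;

struct Incident {
  double amp, freq, ramp_t, xs;
  double operator()(double x, double t) const {
    if (amp == 0.0) return 0.0;
    double u = t - (x - xs) / C0;
    if (u <= 0.0) return 0.0;
    double r = (u >= ramp_t) ? 1.0 : 0.5 * (1.0 - std::cos(M_PI * u / ramp_t));
    return amp * r * std::sin(2.0 * M_PI * freq * u);
  }
};

// [[Rcpp::export(name = ".sfdtd2d_run")]]
List sfdtd2d_run(int nx, int ny, double delta, double dt, int nsteps,
                 NumericVector cs, NumericVector ds, double a1, double a2,
                 NumericMatrix exEps, NumericMatrix exSig, IntegerMatrix exPl,
                 NumericMatrix eyEps, NumericMatrix eySig, IntegerMatrix eyPl,
                 double fp, double nu,
                 int tfi0, int tfi1, int tfj0, int tfj1,
                 double srcAmp, double srcFreq, double rampPeriods,
                 int boundary,        // 0 = mur, 1 = pec
                 int trackStart,      // completed steps before peak tracking
                 IntegerVector probeI, IntegerVector probeJ) {
  const int m = cs.size();
  const bool hasSrc = srcAmp != 0.0;
  if (hasSrc) {
    if (tfi0 < 4 || tfj0 < 4 || tfi1 > nx - 5 || tfj1 > ny - 5)
      stop("TF/SF window must keep >= 4 cells from the outer boundary");
  }
  Incident inc{srcAmp, srcFreq, rampPeriods / srcFreq,
               static_cast<double>(tfi0) * delta};

  NumericMatrix Ex(nx, ny + 1), Dx(nx, ny + 1), accX(nx, ny + 1), Jx(nx, ny + 1);
  NumericMatrix Ey(nx + 1, ny), Dy(nx + 1, ny), accY(nx + 1, ny), Jy(nx + 1, ny);
  NumericMatrix Hz(nx, ny);
  NumericMatrix peakEx(nx, ny + 1), peakEy(nx + 1, ny);

  const int np = probeI.size();
  NumericMatrix probes(np > 0 ? nsteps : 0, np);

  const double wpl = 2.0 * M_PI * fp, nur = nu; // nu is the collision rate (1/s)
  const bool hasPlasma = fp > 0.0;
  // exponential (exact-in-J) one-step Drude rule over the full time step
  const double alphaJ = hasPlasma ? std::exp(-nur * dt) : 1.0;
  const double betaJ = hasPlasma
    ? ((nur > 0.0) ? EPS0 * wpl * wpl * (1.0 - alphaJ) / nur
                   : EPS0 * wpl * wpl * dt)
    : 0.0;
  int lastEStage = 0;
  for (int l = 0; l < m; ++l) if (cs[l] != 0.0) lastEStage = l;

  // Mur boundary stores (captured per electric stage)
  NumericVector oL0(ny), oL1(ny), oR0(ny), oR1(ny);
  NumericVector oB0(nx), oB1(nx), oT0(nx), oT1(nx);

  double tE = 0.0, tH = 0.0;
  const double id = 1.0 / delta;

  for (int n = 0; n < nsteps; ++n) {
    for (int l = 0; l < m; ++l) {
      const double dts = cs[l] * dt;
      if (dts != 0.0) {
        const double f = dts * C0;
        if (boundary == 0) {
          for (int j = 0; j < ny; ++j) {
            oL0[j] = Ey(0, j); oL1[j] = Ey(1, j);
            oR0[j] = Ey(nx, j); oR1[j] = Ey(nx - 1, j);
          }
          for (int i = 0; i < nx; ++i) {
            oB0[i] = Ex(i, 0); oB1[i] = Ex(i, 1);
            oT0[i] = Ex(i, ny); oT1[i] = Ex(i, ny - 1);
          }
        }
        // --- Dx += dts c0 dHz/dy ---
        for (int j = 1; j < ny; ++j) {
          const bool wide = (j >= 2 && j <= ny - 2);
          for (int i = 0; i < nx; ++i) {
            double dz;
            if (wide)
              dz = (a1 * (Hz(i, j) - Hz(i, j - 1)) +
                    a2 * (Hz(i, j + 1) - Hz(i, j - 2))) * id;
            else
              dz = (Hz(i, j) - Hz(i, j - 1)) * id;
            Dx(i, j) += f * dz;
          }
        }
        // --- Dy -= dts c0 dHz/dx ---
        for (int j = 0; j < ny; ++j) {
          for (int i = 1; i < nx; ++i) {
            double dz;
            if (i >= 2 && i <= nx - 2)
              dz = (a1 * (Hz(i, j) - Hz(i - 1, j)) +
                    a2 * (Hz(i + 1, j) - Hz(i - 2, j))) * id;
            else
              dz = (Hz(i, j) - Hz(i - 1, j)) * id;
            Dy(i, j) -= f * dz;
          }
        }
        // --- TF/SF flux corrections (incident Hz at magnetic time tH) ---
        if (hasSrc) {
          const double wts[4] = {-a2 * id, -a1 * id, a1 * id, a2 * id};
          // Dx rows crossing the y-boundaries of the window
          const int jbandA[6] = {tfj0 - 1, tfj0, tfj0 + 1,
                                 tfj1, tfj1 + 1, tfj1 + 2};
          for (int b = 0; b < 6; ++b) {
            const int j = jbandA[b];
            const bool kE = (j >= tfj0 && j <= tfj1 + 1);
            const int jt[4] = {j - 2, j - 1, j, j + 1};
            for (int t = 0; t < 4; ++t) {
              const bool kH = (jt[t] >= tfj0 && jt[t] <= tfj1);
              if (kE == kH) continue;
              const double sgn = kE ? 1.0 : -1.0;
              for (int i = tfi0; i <= tfi1; ++i) {
                Dx(i, j) += f * wts[t] * sgn * inc((i + 0.5) * delta, tH);
              }
            }
          }
          // Dy columns crossing the x-boundaries
          const int ibandB[6] = {tfi0 - 1, tfi0, tfi0 + 1,
                                 tfi1, tfi1 + 1, tfi1 + 2};
          for (int b = 0; b < 6; ++b) {
            const int i = ibandB[b];
            const bool kE = (i >= tfi0 && i <= tfi1 + 1);
            const int it[4] = {i - 2, i - 1, i, i + 1};
            for (int t = 0; t < 4; ++t) {
              const bool kH = (it[t] >= tfi0 && it[t] <= tfi1);
              if (kE == kH) continue;
              const double corr = f * wts[t] * (kE ? 1.0 : -1.0) *
                inc((it[t] + 0.5) * delta, tH);
              for (int j = tfj0; j <= tfj1; ++j) Dy(i, j) -= corr;
            }
          }
        }
        // --- plasma current and constitutive update ---
        // Loss and plasma current are applied once per full step (the frozen
        // running sum / current is used in the earlier stages): with
        // backward (negative) sub-steps a per-sub-step loss term turns into
        // gain and destabilises the composition.
        const bool lastE = (l == lastEStage);
        for (int j = 1; j < ny; ++j) {
          for (int i = 0; i < nx; ++i) {
            if (hasPlasma && exPl(i, j))
              Dx(i, j) -= dts * Jx(i, j) / EPS0;
            const double q = exSig(i, j) * dt / EPS0;
            if (q != 0.0) {
              const double e = (Dx(i, j) - q * accX(i, j)) / (exEps(i, j) + q);
              Ex(i, j) = e;
              if (lastE) accX(i, j) += e;
            } else {
              Ex(i, j) = Dx(i, j) / exEps(i, j);
            }
            if (lastE && hasPlasma && exPl(i, j))
              Jx(i, j) = alphaJ * Jx(i, j) + betaJ * Ex(i, j);
          }
        }
        for (int j = 0; j < ny; ++j) {
          for (int i = 1; i < nx; ++i) {
            if (hasPlasma && eyPl(i, j))
              Dy(i, j) -= dts * Jy(i, j) / EPS0;
            const double q = eySig(i, j) * dt / EPS0;
            if (q != 0.0) {
              const double e = (Dy(i, j) - q * accY(i, j)) / (eyEps(i, j) + q);
              Ey(i, j) = e;
              if (lastE) accY(i, j) += e;
            } else {
              Ey(i, j) = Dy(i, j) / eyEps(i, j);
            }
            if (lastE && hasPlasma && eyPl(i, j))
              Jy(i, j) = alphaJ * Jy(i, j) + betaJ * Ey(i, j);
          }
        }
        tE += dts;
        if (boundary == 1) { // PEC: zero tangential E on the outer edges
          for (int j = 0; j < ny; ++j) { Ey(0, j) = Dy(0, j) = 0.0;
                                         Ey(nx, j) = Dy(nx, j) = 0.0; }
          for (int i = 0; i < nx; ++i) { Ex(i, 0) = Dx(i, 0) = 0.0;
                                         Ex(i, ny) = Dx(i, ny) = 0.0; }
        } else { // first-order Mur per stage, sub-step-scaled coefficient
          const double murK = (C0 * dts - delta) / (C0 * dts + delta);
          for (int j = 0; j < ny; ++j) {
            Ey(0, j) = oL1[j] + murK * (Ey(1, j) - oL0[j]);
            Dy(0, j) = eyEps(0, j) * Ey(0, j);
            Ey(nx, j) = oR1[j] + murK * (Ey(nx - 1, j) - oR0[j]);
            Dy(nx, j) = eyEps(nx, j) * Ey(nx, j);
          }
          for (int i = 0; i < nx; ++i) {
            Ex(i, 0) = oB1[i] + murK * (Ex(i, 1) - oB0[i]);
            Dx(i, 0) = exEps(i, 0) * Ex(i, 0);
            Ex(i, ny) = oT1[i] + murK * (Ex(i, ny - 1) - oT0[i]);
            Dx(i, ny) = exEps(i, ny) * Ex(i, ny);
          }
        }
      }

      const double dtl = ds[l] * dt;
      if (dtl != 0.0) {
        const double f = dtl * C0;
        for (int j = 0; j < ny; ++j) {
          const bool wideY = (j >= 1 && j <= ny - 2);
          for (int i = 0; i < nx; ++i) {
            double dxdy, dydx;
            if (wideY)
              dxdy = (a1 * (Ex(i, j + 1) - Ex(i, j)) +
                      a2 * (Ex(i, j + 2) - Ex(i, j - 1))) * id;
            else
              dxdy = (Ex(i, j + 1) - Ex(i, j)) * id;
            if (i >= 1 && i <= nx - 2)
              dydx = (a1 * (Ey(i + 1, j) - Ey(i, j)) +
                      a2 * (Ey(i + 2, j) - Ey(i - 1, j))) * id;
            else
              dydx = (Ey(i + 1, j) - Ey(i, j)) * id;
            Hz(i, j) += f * (dxdy - dydx);
          }
        }
        // --- TF/SF corrections for the Ey taps (incident Ey at time tE) ---
        if (hasSrc) {
          const double wts[4] = {-a2 * id, -a1 * id, a1 * id, a2 * id};
          const int ibandC[8] = {tfi0 - 2, tfi0 - 1, tfi0, tfi0 + 1,
                                 tfi1 - 1, tfi1, tfi1 + 1, tfi1 + 2};
          for (int b = 0; b < 8; ++b) {
            const int i = ibandC[b];
            const bool kH = (i >= tfi0 && i <= tfi1);
            const int it[4] = {i - 1, i, i + 1, i + 2};
            for (int t = 0; t < 4; ++t) {
              const bool kEy = (it[t] >= tfi0 && it[t] <= tfi1 + 1);
              if (kH == kEy) continue;
              const double corr = f * wts[t] * (kH ? 1.0 : -1.0) *
                inc(it[t] * delta, tE);
              for (int j = tfj0; j <= tfj1; ++j) Hz(i, j) -= corr;
            }
          }
        }
        tH += dtl;
      }
    }

    if (n + 1 > trackStart) {
      for (int j = 0; j <= ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const double v = std::fabs(Ex(i, j));
          if (v > peakEx(i, j)) peakEx(i, j) = v;
        }
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i <= nx; ++i) {
          const double v = std::fabs(Ey(i, j));
          if (v > peakEy(i, j)) peakEy(i, j) = v;
        }
    }
    for (int p = 0; p < np; ++p) probes(n, p) = Ey(probeI[p], probeJ[p]);

    if ((n & 63) == 0) {
      if (!std::isfinite(Hz(nx / 2, ny / 2)))
        stop("instability detected: non-finite field at step %d", n + 1);
      checkUserInterrupt();
    }
  }
  if (!std::isfinite(Hz(nx / 2, ny / 2)))
    stop("instability detected: non-finite field at step %d", nsteps);

  return List::create(_["Ex"] = Ex, _["Ey"] = Ey, _["Hz"] = Hz,
                      _["peak_ex"] = peakEx, _["peak_ey"] = peakEy,
                      _["probes"] = probes, _["time"] = tE, _["steps"] = nsteps);
}
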