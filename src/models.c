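/* Right-hand sides of the Epileptor, its isolated fast subsystem and the
 * DTB bursting model, in the compiled-code interface of deSolve.
 *
 * Parameter vectors are passed from R in a fixed order (see R/simulate.R);
 * the initfunc for each model copies them into a static buffer.
 */

#include <R.h>
#include <math.h>

/* ---------------- full Epileptor (6 states + low-pass filter u) ---------- */
/* state order: x1, y1, z, x2, y2, u
 * parms order: x0, y0, tau0, tau1, tau2, Irest1, Irest2, gamma, m, alpha  */

static double ep_p[10];

void epileptor_init(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, ep_p);
}

void epileptor_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double x1 = y[0], y1 = y[1], z = y[2], x2 = y[3], y2 = y[4], u = y[5];
    double x0 = ep_p[0], y0 = ep_p[1], tau0 = ep_p[2];
    double tau2 = ep_p[4], Irest1 = ep_p[5], Irest2 = ep_p[6];
    double gamma = ep_p[7], m = ep_p[8], alpha = ep_p[9];
    double zm4 = z - 4.0;

    if (x1 < 0.0)
        ydot[0] = y1 - x1 * x1 * x1 + 3.0 * x1 * x1 - z + Irest1;
    else
        ydot[0] = y1 + (m - x2 + 0.6 * alpha * zm4 * zm4) * x1 - z + Irest1;

    ydot[1] = y0 - 5.0 * x1 * x1 - y1;
    ydot[2] = (4.0 * (x1 - x0) - z) / tau0;
    ydot[3] = -y2 + x2 - x2 * x2 * x2 + Irest2 + u - 0.3 * (z - 3.5);
    ydot[4] = (x2 < -0.25) ? -y2 / tau2 : (-y2 + 6.0 * (x2 + 0.25)) / tau2;
    ydot[5] = 0.002 * x1 - gamma * u;
}

/* ---------------- isolated fast subsystem (x, y) -------------------------- */
/* parms order: nu, a, b, mu, mbar, y0, B, N */

static double fs_p[8];

void fastsub_init(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, fs_p);
}

void fastsub_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double x = y[0], yy = y[1];
    double nu = fs_p[0], a = fs_p[1], b = fs_p[2], mu = fs_p[3];
    double mbar = fs_p[4], y0 = fs_p[5], B = fs_p[6], N = fs_p[7];

    if (x < 0.0)
        ydot[0] = nu * yy + a * x * x * x + b * x * x + mu;
    else
        ydot[0] = nu * yy + mbar * x + mu;

    ydot[1] = y0 + B * x * x + N * yy;
}

/* ---------------- DTB bursting model (x, y, z) ---------------------------- */
/* parms order: mu2, mu1_0, nu_0, d_mu1, d_nu, c, x0 */

static double dtb_p[7];

void dtb_init(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, dtb_p);
}

void dtb_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double x = y[0], yy = y[1], z = y[2];
    double mu2 = dtb_p[0];
    double mu1 = dtb_p[1] + dtb_p[3] * z;
    double nu = dtb_p[2] + dtb_p[4] * z;

    ydot[0] = -yy;
    ydot[1] = x * x * x - mu2 * x - mu1 - yy * (nu + x + x * x);
    ydot[2] = dtb_p[5] * (x - dtb_p[6]);
}

/* ---------------- DTB fast subsystem (x, y; mu1, nu frozen) --------------- */
/* parms order: mu2, mu1, nu */

static double dtbf_p[3];

void dtbfast_init(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, dtbf_p);
}

void dtbfast_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double x = y[0], yy = y[1];
    double mu2 = dtbf_p[0], mu1 = dtbf_p[1], nu = dtbf_p[2];

    ydot[0] = -yy;
    ydot[1] = x * x * x - mu2 * x - mu1 - yy * (nu + x + x * x);
}
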