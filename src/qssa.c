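#include "gc_model.h"

/* Quasi-steady-state fast path for the in vitro system, used by the
 * calibration likelihood where hundreds of thousands of model evaluations
 * are needed.
 *
 * Reduction: hormone exchange between one cell and its medium share
 * relaxes on a time scale V_GC/K_out (~ seconds), and intracellular FSH
 * equilibrates equally fast, while the observable dynamics (gene
 * expression, medium-pool turnover) evolve over hours.  Hence
 *  - intracellular FSH is held at its partition equilibrium,
 *  - gene expression is integrated in closed form (linear cascade with
 *    constant FSH),
 *  - the four intracellular steroid quantities are slaved to the slow
 *    totals by solving the transport/metabolism balance with a damped
 *    Newton iteration,
 *  - only the five slow states (total A, T, E1, E2 and cumulative T2O)
 *    are integrated numerically (adaptive Cash-Karp Runge-Kutta).
 * Agreement with the full deSolve solution is asserted by the test suite.
 */

typedef struct {
    double p[GC_NPAR];
    double Kin[4], Kout[4];
    double Fgc;                       /* equilibrium intracellular FSH, pg */
    double m0[3], minf[3];            /* mRNA initial / asymptotic, pg */
    double P0[3], Pinf[3], Cp1[3], Cp2[3];
} qssa_sys;

static void qssa_gene_coef(qssa_sys *q)
{
    const double *p = q->p;
    double nm[3] = { p[IP_NMC], p[IP_NMH1], p[IP_NMH2] };
    double np[3] = { p[IP_NPC], p[IP_NPH1], p[IP_NPH2] };
    double ind[3] = { p[IP_FC] * (1.0 + p[IP_KC] * q->Fgc),
                      p[IP_FH] * (1.0 + p[IP_KH] * q->Fgc),
                      1.0 };
    double dm = p[IP_DM], dp = p[IP_DP];
    int i;
    for (i = 0; i < 3; i++) {
        q->minf[i] = p[IP_SL] * ind[i] * nm[i] / dm;
        q->Pinf[i] = np[i] * q->minf[i] / dp;
        /* protein transient has two modes exp(-dp t), exp(-dm t) */
        q->Cp2[i] = (fabs(dp - dm) > 1e-12 * dp)
                    ? np[i] * (q->m0[i] - q->minf[i]) / (dp - dm)
                    : np[i] * (q->m0[i] - q->minf[i]);  /* degenerate */
        q->Cp1[i] = q->P0[i] - q->Pinf[i] - q->Cp2[i];
    }
}

static void qssa_enzymes(const qssa_sys *q, double t, double *P)
{
    double ep = exp(-q->p[IP_DP] * t), em = exp(-q->p[IP_DM] * t);
    int i;
    for (i = 0; i < 3; i++) {
        P[i] = q->Pinf[i] + q->Cp1[i] * ep + q->Cp2[i] * em;
        if (P[i] < 0.0) P[i] = 0.0;
    }
}

/* solve a 4x4 linear system by partial-pivot Gaussian elimination */
static int gc_solve4(double A[16], double b[4])
{
    int idx[4] = { 0, 1, 2, 3 }, i, j, k;
    double x[4];
    for (k = 0; k < 4; k++) {
        int piv = k;
        double mx = fabs(A[4 * idx[k] + k]);
        for (i = k + 1; i < 4; i++)
            if (fabs(A[4 * idx[i] + k]) > mx) {
                mx = fabs(A[4 * idx[i] + k]); piv = i;
            }
        if (mx < 1e-300) return 1;
        j = idx[k]; idx[k] = idx[piv]; idx[piv] = j;
        for (i = k + 1; i < 4; i++) {
            double f = A[4 * idx[i] + k] / A[4 * idx[k] + k];
            for (j = k; j < 4; j++) A[4 * idx[i] + j] -= f * A[4 * idx[k] + j];
            b[idx[i]] -= f * b[idx[k]];
        }
    }
    for (k = 3; k >= 0; k--) {
        double s = b[idx[k]];
        for (j = k + 1; j < 4; j++) s -= A[4 * idx[k] + j] * x[j];
        x[k] = s / A[4 * idx[k] + k];
    }
    memcpy(b, x, 4 * sizeof(double));
    return 0;
}

/* Newton solve of K_in (Xtot - X)/V_med - K_out X/V_GC + S(X) = 0 */
static int qssa_solve_cell(const qssa_sys *q, const double *P,
                           const double *Xtot, double *X)
{
    const double *p = q->p;
    double a[6], Jf[24], r[4], J[16], step[4];
    int it, i, j;
    for (it = 0; it < 200; it++) {
        double maxr = 0.0, damp = 1.0;
        gc_fluxes(p, P, X, a, Jf);
        {
            double S[4];
            gc_sources(a, S);
            for (i = 0; i < 4; i++) {
                double cin = q->Kin[i] * (Xtot[i] - X[i]) / p[IP_VMED];
                double cout = q->Kout[i] * X[i] / p[IP_VGC];
                double sc = q->Kin[i] * fabs(Xtot[i]) / p[IP_VMED]
                            + cout + 1e-280;
                r[i] = cin - cout + S[i];
                if (fabs(r[i]) / sc > maxr) maxr = fabs(r[i]) / sc;
            }
        }
        if (maxr < 1e-8) return 0;
        for (j = 0; j < 4; j++) {
            J[0 * 4 + j] = Jf[2 * 4 + j] - Jf[0 * 4 + j] - Jf[1 * 4 + j];
            J[1 * 4 + j] = Jf[1 * 4 + j] - Jf[2 * 4 + j] - Jf[3 * 4 + j];
            J[2 * 4 + j] = Jf[0 * 4 + j] + Jf[5 * 4 + j] - Jf[4 * 4 + j];
            J[3 * 4 + j] = Jf[3 * 4 + j] + Jf[4 * 4 + j] - Jf[5 * 4 + j];
        }
        for (i = 0; i < 4; i++)
            J[4 * i + i] -= q->Kin[i] / p[IP_VMED] + q->Kout[i] / p[IP_VGC];
        for (i = 0; i < 4; i++) step[i] = -r[i];
        if (gc_solve4(J, step)) return 2;
        for (i = 0; i < 4; i++)
            if (X[i] + step[i] < 0.0 && step[i] < 0.0) {
                double d = X[i] > 0.0 ? 0.5 * X[i] / (-step[i]) : 0.0;
                if (d < damp) damp = d;
            }
        if (damp <= 0.0) damp = 1e-3;
        for (i = 0; i < 4; i++) X[i] += damp * step[i];
    }
    return 3;
}

static void qssa_rhs(const qssa_sys *q, double t, const double *y,
                     double *dy, double *Xgc)
{
    double P[3], a[6], S[4];
    qssa_enzymes(q, t, P);
    qssa_solve_cell(q, P, y, Xgc);
    gc_fluxes(q->p, P, Xgc, a, NULL);
    gc_sources(a, S);
    dy[0] = S[0]; dy[1] = S[1]; dy[2] = S[2]; dy[3] = S[3];
    dy[4] = a[0];
}

static void qssa_emit(const qssa_sys *q, double t, const double *y,
                      double *Xgc, double *row, int nt)
{
    double P[3], a[6];
    int i;
    qssa_enzymes(q, t, P);
    qssa_solve_cell(q, P, y, Xgc);
    gc_fluxes(q->p, P, Xgc, a, NULL);
    row[0] = t;
    for (i = 0; i < 5; i++) row[nt * (1 + i)]  = y[i];
    for (i = 0; i < 4; i++) row[nt * (6 + i)]  = Xgc[i];
    for (i = 0; i < 6; i++) row[nt * (10 + i)] = a[i];
    for (i = 0; i < 3; i++) row[nt * (16 + i)] = P[i];
}

/* .Call entry.
 * par:  GC_NPAR parameter vector
 * y0:   c(Atot, Ttot, E1tot, E2tot, T2O, FSHtot, mRNA0 (3), prot0 (3))
 *       totals = medium + cell, per cell
 * tout: increasing output times from 0
 * tol:  c(rtol, atol)
 * Returns nt x 19 matrix: t, totals (4), T2O, intracellular (4),
 * alpha1..6, protein (3). */
SEXP C_qssa_run(SEXP par, SEXP y0_, SEXP tout_, SEXP tol_)
{
    static const double b21 = 0.2, b31 = 3.0 / 40, b32 = 9.0 / 40,
        b41 = 0.3, b42 = -0.9, b43 = 1.2,
        b51 = -11.0 / 54, b52 = 2.5, b53 = -70.0 / 27, b54 = 35.0 / 27,
        b61 = 1631.0 / 55296, b62 = 175.0 / 512, b63 = 575.0 / 13824,
        b64 = 44275.0 / 110592, b65 = 253.0 / 4096,
        c1 = 37.0 / 378, c3 = 250.0 / 621, c4 = 125.0 / 594, c6 = 512.0 / 1771,
        dc1 = c1 - 2825.0 / 27648, dc3 = c3 - 18575.0 / 48384,
        dc4 = c4 - 13525.0 / 55296, dc5 = -277.0 / 14336, dc6 = c6 - 0.25;
    qssa_sys q;
    double *yy = REAL(y0_), *tout = REAL(tout_);
    double rtol = REAL(tol_)[0], atol = REAL(tol_)[1];
    int nt = LENGTH(tout_), iout = 0, nstep = 0;
    SEXP ans = PROTECT(allocMatrix(REALSXP, nt, 19));
    double *A = REAL(ans);
    double y[5], Xgc[4] = { 0, 0, 0, 0 };
    double k1[5], k2[5], k3[5], k4[5], k5[5], k6[5], yt[5], yerr, ynew[5];
    double t = 0.0, h, tend;
    int i;

    memcpy(q.p, REAL(par), GC_NPAR * sizeof(double));
    q.Kin[0] = q.p[IP_KOUTA] / q.p[IP_ROIA];
    q.Kin[1] = q.p[IP_KOUTT] / q.p[IP_ROIT];
    q.Kin[2] = q.p[IP_KOUTE1] / q.p[IP_ROIE1];
    q.Kin[3] = q.p[IP_KOUTE2] / q.p[IP_ROIE2];
    q.Kout[0] = q.p[IP_KOUTA]; q.Kout[1] = q.p[IP_KOUTT];
    q.Kout[2] = q.p[IP_KOUTE1]; q.Kout[3] = q.p[IP_KOUTE2];
    /* FSH partition equilibrium on the conserved total */
    {
        double vr = q.p[IP_VGC] / q.p[IP_ROIF];
        q.Fgc = yy[5] * vr / (q.p[IP_VMED] + vr);
    }
    for (i = 0; i < 3; i++) { q.m0[i] = yy[6 + i]; q.P0[i] = yy[9 + i]; }
    qssa_gene_coef(&q);

    for (i = 0; i < 5; i++) y[i] = yy[i];
    tend = tout[nt - 1];
    h = tend > 600.0 ? 30.0 : tend / 20.0;

    while (iout < nt && tout[iout] <= t + 1e-12) {
        qssa_emit(&q, tout[iout], y, Xgc, A + iout, nt);
        iout++;
    }
    while (t < tend && nstep < 100000) {
        double errmax = 0.0;
        nstep++;
        if (t + h > tend) h = tend - t;
        if (iout < nt && t + h > tout[iout]) h = tout[iout] - t;
        qssa_rhs(&q, t, y, k1, Xgc);
        for (i = 0; i < 5; i++) yt[i] = y[i] + h * b21 * k1[i];
        qssa_rhs(&q, t + 0.2 * h, yt, k2, Xgc);
        for (i = 0; i < 5; i++) yt[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
        qssa_rhs(&q, t + 0.3 * h, yt, k3, Xgc);
        for (i = 0; i < 5; i++)
            yt[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
        qssa_rhs(&q, t + 0.6 * h, yt, k4, Xgc);
        for (i = 0; i < 5; i++)
            yt[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i]
                                + b54 * k4[i]);
        qssa_rhs(&q, t + h, yt, k5, Xgc);
        for (i = 0; i < 5; i++)
            yt[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i]
                                + b64 * k4[i] + b65 * k5[i]);
        qssa_rhs(&q, t + 0.875 * h, yt, k6, Xgc);
        for (i = 0; i < 5; i++) {
            double sc, e;
            ynew[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i]
                                  + c6 * k6[i]);
            yerr = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i]
                        + dc5 * k5[i] + dc6 * k6[i]);
            sc = atol + rtol * fmax(fabs(y[i]), fabs(ynew[i]));
            e = fabs(yerr) / sc;
            if (e > errmax) errmax = e;
        }
        if (errmax <= 1.0) {
            t += h;
            for (i = 0; i < 5; i++) y[i] = ynew[i] > 0.0 ? ynew[i] : 0.0;
            while (iout < nt && tout[iout] <= t + 1e-9) {
                qssa_emit(&q, tout[iout], y, Xgc, A + iout, nt);
                iout++;
            }
            h *= errmax > 1e-8 ? 0.9 * pow(errmax, -0.2) : 5.0;
        } else {
            h *= fmax(0.1, 0.9 * pow(errmax, -0.25));
        }
        if (h < 1e-10) { warning("qssa: step size underflow"); break; }
    }
    if (iout < nt)
        error("qssa: integration did not reach final output time");
    UNPROTECT(1);
    return ans;
}
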