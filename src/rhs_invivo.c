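#include "gc_model.h"

/* Three-compartment ovary (granulosa cells, "other cells", extracellular
 * space) right-hand side for deSolve, with time-varying forcings.
 *
 * State vector (22):
 *   0-2   mRNA Cyp19, Hsd17b1, Hsd17b2                (pg/cell)
 *   3-5   protein Cyp19, Hsd17b1, Hsd17b2             (pg/cell)
 *   6-9   GC intracellular A, T, E1, E2               (pmoles/cell)
 *   10    GC intracellular FSH                        (pg/cell)
 *   11-14 "other cell" A, T, E1, E2 (per cell)        (pmoles/cell)
 *   15    "other cell" FSH (per cell)                 (pg/cell)
 *   16-19 extracellular A, T, E1, E2 (whole ovary)    (pmoles)
 *   20    extracellular FSH (whole ovary)             (pg)
 *   21    cumulative tritiated water (per GC)         (pmoles/cell)
 *
 * Forcings (10, in this order): Q_input FSH (pg/min), Q_input A (pmoles/min),
 * Q_input T (pmoles/min), N_GCs, N_others, V_ext (ml), V_others (ml),
 * f_X Cyp19, f_X Hsd17b1, f_M.
 */

static double par_invivo[GC_NPAR];
static double forc_invivo[10];

void gc_initmod_invivo(void (*odeparms)(int *, double *))
{
    int n = GC_NPAR;
    odeparms(&n, par_invivo);
}

void gc_initforc_invivo(void (*odeforcs)(int *, double *))
{
    int n = 10;
    odeforcs(&n, forc_invivo);
}

void gc_derivs_invivo(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double p[GC_NPAR];
    double X[4], a[6], S[4];
    double Q[5], trGC[5], trO[5];
    double Kout[5], Kin[5];
    int i;

    memcpy(p, par_invivo, sizeof(p));
    p[IP_FC] = forc_invivo[7];
    p[IP_FH] = forc_invivo[8];
    p[IP_FM] = forc_invivo[9];

    {
    double Ngc  = forc_invivo[3], Noth = forc_invivo[4];
    double Vext = forc_invivo[5], Voth = forc_invivo[6];
    double Vgc  = p[IP_VGC];
    double Vo   = Voth / Noth;  /* per-cell volume of "other cells" */

    Kout[0] = p[IP_KOUTA];  Kout[1] = p[IP_KOUTT];  Kout[2] = p[IP_KOUTE1];
    Kout[3] = p[IP_KOUTE2]; Kout[4] = p[IP_KOUTF];
    Kin[0] = Kout[0] / p[IP_ROIA];  Kin[1] = Kout[1] / p[IP_ROIT];
    Kin[2] = Kout[2] / p[IP_ROIE1]; Kin[3] = Kout[3] / p[IP_ROIE2];
    Kin[4] = Kout[4] / p[IP_ROIF];

    Q[0] = forc_invivo[1];  /* A */
    Q[1] = forc_invivo[2];  /* T */
    Q[2] = 0.0;             /* E1 */
    Q[3] = 0.0;             /* E2 */
    Q[4] = forc_invivo[0];  /* FSH */
    for (i = 0; i < 5; i++) if (Q[i] < 0.0) Q[i] = 0.0;

    for (i = 0; i < 4; i++) X[i] = y[6 + i] > 0.0 ? y[6 + i] : 0.0;
    gc_fluxes(p, y + 3, X, a, NULL);
    gc_sources(a, S);

    /* gene expression, identical to the in vitro cell */
    ydot[0] = p[IP_SL] * p[IP_FC] * p[IP_NMC] * (1.0 + p[IP_KC] * y[10])
              - p[IP_DM] * y[0];
    ydot[1] = p[IP_SL] * p[IP_FH] * p[IP_NMH1] * (1.0 + p[IP_KH] * y[10])
              - p[IP_DM] * y[1];
    ydot[2] = p[IP_SL] * p[IP_NMH2] - p[IP_DM] * y[2];
    ydot[3] = p[IP_NPC] * y[0] - p[IP_DP] * y[3];
    ydot[4] = p[IP_NPH1] * y[1] - p[IP_DP] * y[4];
    ydot[5] = p[IP_NPH2] * y[2] - p[IP_DP] * y[5];

    for (i = 0; i < 5; i++) {
        trGC[i] = Kin[i] * y[16 + i] / Vext - Kout[i] * y[6 + i] / Vgc;
        trO[i]  = Kin[i] * y[16 + i] / Vext - Kout[i] * y[11 + i] / Vo;
    }
    for (i = 0; i < 4; i++) {
        ydot[6 + i]  = trGC[i] + S[i];
        ydot[11 + i] = trO[i];
        ydot[16 + i] = Q[i] - Ngc * trGC[i] - Noth * trO[i]
                       - p[IP_FOV] * y[16 + i] / p[IP_VOV];
    }
    ydot[10] = trGC[4];
    ydot[15] = trO[4];
    ydot[20] = Q[4] - Ngc * trGC[4] - Noth * trO[4]
               - p[IP_FOV] * y[20] / p[IP_VOV];
    ydot[21] = a[0];

    if (*ip >= 6)
        for (i = 0; i < 6; i++) yout[i] = a[i];
    }
}
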