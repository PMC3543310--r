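#include "gc_model.h"

/* Two-compartment (granulosa cell + culture medium) right-hand side for
 * deSolve.  State vector (17):
 *   0-2   mRNA Cyp19, Hsd17b1, Hsd17b2           (pg/cell)
 *   3-5   protein Cyp19, Hsd17b1, Hsd17b2        (pg/cell)
 *   6-9   intracellular A, T, E1, E2             (pmoles/cell)
 *   10    intracellular FSH                      (pg/cell)
 *   11-14 medium A, T, E1, E2 (per cell)         (pmoles/cell)
 *   15    medium FSH (per cell)                  (pg/cell)
 *   16    cumulative tritiated water             (pmoles/cell)
 */

static double par_invitro[GC_NPAR];

void gc_initmod_invitro(void (*odeparms)(int *, double *))
{
    int n = GC_NPAR;
    odeparms(&n, par_invitro);
}

void gc_derivs_invitro(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const double *p = par_invitro;
    double X[4], a[6], S[4];
    double Vgc = p[IP_VGC], Vmed = p[IP_VMED];
    double Kout[5] = { p[IP_KOUTA], p[IP_KOUTT], p[IP_KOUTE1],
                       p[IP_KOUTE2], p[IP_KOUTF] };
    double Kin[5]  = { p[IP_KOUTA] / p[IP_ROIA], p[IP_KOUTT] / p[IP_ROIT],
                       p[IP_KOUTE1] / p[IP_ROIE1], p[IP_KOUTE2] / p[IP_ROIE2],
                       p[IP_KOUTF] / p[IP_ROIF] };
    double tr[5];
    int i;

    for (i = 0; i < 4; i++) X[i] = y[6 + i] > 0.0 ? y[6 + i] : 0.0;
    gc_fluxes(p, y + 3, X, a, NULL);
    gc_sources(a, S);

    /* gene expression: FSH induction and EDC fold on Cyp19/Hsd17b1 only */
    ydot[0] = p[IP_SL] * p[IP_FC] * p[IP_NMC] * (1.0 + p[IP_KC] * y[10])
              - p[IP_DM] * y[0];
    ydot[1] = p[IP_SL] * p[IP_FH] * p[IP_NMH1] * (1.0 + p[IP_KH] * y[10])
              - p[IP_DM] * y[1];
    ydot[2] = p[IP_SL] * p[IP_NMH2] - p[IP_DM] * y[2];
    ydot[3] = p[IP_NPC] * y[0] - p[IP_DP] * y[3];
    ydot[4] = p[IP_NPH1] * y[1] - p[IP_DP] * y[4];
    ydot[5] = p[IP_NPH2] * y[2] - p[IP_DP] * y[5];

    /* passive diffusion: uptake from medium, excretion from cell */
    for (i = 0; i < 5; i++)
        tr[i] = Kin[i] * y[11 + i] / Vmed - Kout[i] * y[6 + i] / Vgc;

    for (i = 0; i < 4; i++) {
        ydot[6 + i]  = tr[i] + S[i];
        ydot[11 + i] = -tr[i];
    }
    ydot[10] = tr[4];
    ydot[15] = -tr[4];
    ydot[16] = a[0];            /* one T2O per aromatization of A */

    if (*ip >= 6)
        for (i = 0; i < 6; i++) yout[i] = a[i];
}
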