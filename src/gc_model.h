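#ifndef GC_MODEL_H
#define GC_MODEL_H

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>

/* Shared parameter vector layout (all doubles, see R/zzz-pack.R).
 * Quantities are per cell: pg for mRNA/protein/FSH, pmoles for steroids,
 * ml for volumes, minutes for time. */
#define IP_KC     0   /* kappa_Cyp19 (/pg FSH) */
#define IP_KH     1   /* kappa_Hsd17b1 (/pg FSH) */
#define IP_LCA    2   /* Vmax aromatase A->E1 (pmol/min/pg) */
#define IP_LCT    3   /* Vmax aromatase T->E2 */
#define IP_LHA    4   /* Vmax Hsd17b1 A->T */
#define IP_LHE1   5   /* Vmax Hsd17b1 E1->E2 */
#define IP_XCA    6   /* Km aromatase for A (pmoles) */
#define IP_XCT    7   /* Km aromatase for T */
#define IP_XHA    8   /* Km Hsd17b1 for A */
#define IP_XHE1   9   /* Km Hsd17b1 for E1 */
#define IP_LH2T   10  /* Vmax Hsd17b2 T->A */
#define IP_LH2E2  11  /* Vmax Hsd17b2 E2->E1 */
#define IP_XH2T   12  /* Km Hsd17b2 for T */
#define IP_XH2E2  13  /* Km Hsd17b2 for E2 */
#define IP_DM     14  /* mRNA degradation rate (/min) */
#define IP_DP     15  /* protein degradation rate (/min) */
#define IP_NMC    16  /* mRNA synthesis Cyp19 (pg/min) */
#define IP_NMH1   17
#define IP_NMH2   18
#define IP_NPC    19  /* protein synthesis rate constants (/min) */
#define IP_NPH1   20
#define IP_NPH2   21
#define IP_ROIA   22  /* extra/intra partition coefficients */
#define IP_ROIT   23
#define IP_ROIE1  24
#define IP_ROIE2  25
#define IP_ROIF   26
#define IP_KOUTA  27  /* excretion rate constants (ml/min) */
#define IP_KOUTT  28
#define IP_KOUTE1 29
#define IP_KOUTE2 30
#define IP_KOUTF  31
#define IP_VGC    32  /* single-cell volume (ml) */
#define IP_VMED   33  /* culture medium volume per cell (ml) */
#define IP_FM     34  /* aromatase Km fold-change f_M */
#define IP_FC     35  /* Cyp19 transcription fold-change f_X */
#define IP_FH     36  /* Hsd17b1 transcription fold-change f_X */
#define IP_SL     37  /* inter-study transcription factor sigma_L */
#define IP_FOV    38  /* ovary blood flow (ml/min), in vivo only */
#define IP_VOV    39  /* ovarian volume at diestrus (ml), in vivo only */
#define GC_NPAR   40

/* Six competitive Michaelis-Menten interconversion fluxes, pmoles/min/cell.
 * X = (A, T, E1, E2) intracellular quantities, P = (Cyp19, Hsd17b1, Hsd17b2)
 * protein quantities.  J (optional, 6x4 row-major) receives d(alpha)/dX. */
static R_INLINE void gc_fluxes(const double *p, const double *P,
                               const double *X, double *a, double *J)
{
    double A = X[0], T = X[1], E1 = X[2], E2 = X[3];
    double fM = p[IP_FM];
    /* each reaction: V * Z / (K + cc*C + Z), C the competing substrate */
    double V[6]  = { p[IP_LCA] * P[0], p[IP_LHA] * P[1], p[IP_LH2T] * P[2],
                     p[IP_LCT] * P[0], p[IP_LHE1] * P[1], p[IP_LH2E2] * P[2] };
    double Z[6]  = { A, A, T, T, E1, E2 };
    double K[6]  = { p[IP_XCA] * fM, p[IP_XHA], p[IP_XH2T],
                     p[IP_XCT] * fM, p[IP_XHE1], p[IP_XH2E2] };
    /* competition coefficient = own Km / competitor Km; f_M cancels for
     * the two aromatase reactions */
    double cc[6] = { p[IP_XCA] / p[IP_XCT], p[IP_XHA] / p[IP_XHE1],
                     p[IP_XH2T] / p[IP_XH2E2], p[IP_XCT] / p[IP_XCA],
                     p[IP_XHE1] / p[IP_XHA], p[IP_XH2E2] / p[IP_XH2T] };
    double C[6]  = { T, E1, E2, A, A, T };
    int zi[6] = { 0, 0, 1, 1, 2, 3 };   /* substrate index in X */
    int ci[6] = { 1, 2, 3, 0, 0, 1 };   /* competitor index in X */
    int i;
    if (J) memset(J, 0, 24 * sizeof(double));
    for (i = 0; i < 6; i++) {
        double den = K[i] + cc[i] * C[i] + Z[i];
        a[i] = (den > 0.0 && Z[i] > 0.0) ? V[i] * Z[i] / den : 0.0;
        if (J && den > 0.0) {
            J[4 * i + zi[i]] = V[i] * (K[i] + cc[i] * C[i]) / (den * den);
            J[4 * i + ci[i]] += -V[i] * Z[i] * cc[i] / (den * den);
        }
    }
}

/* net metabolic source terms for (A, T, E1, E2) from the six fluxes */
static R_INLINE void gc_sources(const double *a, double *S)
{
    S[0] = a[2] - a[0] - a[1];
    S[1] = a[1] - a[2] - a[3];
    S[2] = a[0] + a[5] - a[4];
    S[3] = a[3] + a[4] - a[5];
}

#endif
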