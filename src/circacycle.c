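/* Right-hand side of the 46-variable coupled circadian clock / cell-cycle
 * ODE model, in the deSolve compiled-model convention.
 *
 * State layout (0-based, see circacycle_indices.h): 46 species.  45 of them
 * carry rate equations (cell cycle eq 1-26, clock eq 27-45); RB1p_N is the
 * conserved phosphorylated RB1 pool (rb_tot - RB1_N - RBE2F) and its
 * reported derivative is the bookkeeping value -(dRB1_N + dRBE2F).
 *
 * Parameter vector passed from R (length 218):
 *   [0..169]   the 170 kinetic parameters, canonical order of cc_parameters()
 *   [170]      ktt   - RAS factor scaling CLOCK/BMAL transcriptional activity
 *   [171]      fkd   - Bmal1 knockdown fraction (1 = none)
 *   [172..217] mask  - per-species freeze flag (1 = derivative forced to 0;
 *                      used for knockouts and clamps)
 */

#include <R.h>
#include <Rmath.h>
#include "circacycle_indices.h"

#define N_SPEC 46
#define N_PAR_KIN 170
#define IDX_KTT 170
#define IDX_FKD 171
#define IDX_MASK 172
#define N_PAR_TOT (IDX_MASK + N_SPEC)

static double parms[N_PAR_TOT];

void cc_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PAR_TOT;
    odeparms(&n, parms);
}

static double hact(double x, double k, double n)
{
    double xn, kn;
    if (x <= 0.0) return 0.0;
    xn = R_pow(x, n);
    kn = R_pow(k, n);
    return xn / (kn + xn);
}

static double hinh(double x, double k, double n)
{
    return 1.0 - hact(x, k, n);
}

/* Michaelis-Menten mRNA decay flux */
static double mm(double vmax, double x, double km)
{
    double xx = x > 0.0 ? x : 0.0;
    return vmax * xx / (km + xx);
}

static void cc_core(double t, const double *y, const double *p, double *dy)
{
    const double ktt = p[IDX_KTT];
    const double fkd = p[IDX_FKD];

    /* effective transcriptional activity of CLOCK/BMAL at E-boxes */
    const double cbk = ktt * (y[S_CB] > 0.0 ? y[S_CB] : 0.0);
    /* MYC competitive interference with E-box transcription */
    const double fmyc = hinh(y[S_MYC_N], p[P_KI_EBOX_MYC], p[P_HI_EBOX_MYC]);
    /* p53 block of RB1 phosphorylation (p21/CDK/CycE merged) */
    const double fp53rb = hinh(y[S_P53_N], p[P_KI_RBP_P53], p[P_HI_RBP_P53]);
    /* conserved RB1 pool */
    double rb1p = p[P_RB_TOT] - y[S_RB1_N] - y[S_RBE2F];
    if (rb1p < 0.0) rb1p = 0.0;

    const double phos_flux = p[P_K_PHOS] * y[S_CDC_N] * fp53rb *
        (y[S_RB1_N] > 0.0 ? y[S_RB1_N] : 0.0) / (p[P_KM_PHOS] + (y[S_RB1_N] > 0.0 ? y[S_RB1_N] : 0.0));
    const double phos2_flux = p[P_K_PHOS2] * y[S_CDC_N] * y[S_RBE2F] * fp53rb;

    /* ---- cell cycle: mRNAs (eq 1-7) ---- */
    dy[S_INK4A] = p[P_VB_INK] +
        p[P_V_INK] * hact(y[S_PERCRY_N], p[P_KA_INK_PC], p[P_HA_INK_PC]) -
        mm(p[P_DM_INK], y[S_INK4A], p[P_KM_INK]);
    dy[S_ARF] = p[P_VB_ARF] +
        p[P_V_ARF] * hact(y[S_MYC_N], p[P_KA_ARF_MYC], p[P_HA_ARF_MYC]) -
        mm(p[P_DM_ARF], y[S_ARF], p[P_KM_ARF]);
    dy[S_MYC] = p[P_VB_MYC] +
        p[P_V_MYC] * hinh(cbk, p[P_KI_MYC_CB], p[P_HI_MYC_CB]) -
        mm(p[P_DM_MYC], y[S_MYC], p[P_KM_MYC]);
    dy[S_WEE1] = p[P_VB_WEE1] +
        p[P_V_WEE1] * hact(cbk, p[P_KA_WEE1_CB], p[P_HA_WEE1_CB]) * fmyc -
        mm(p[P_DM_WEE1], y[S_WEE1], p[P_KM_WEE1]);
    dy[S_MDM2] = p[P_VB_MDM2] +
        p[P_V_MDM2] * hact(y[S_P53_N], p[P_KA_MDM2_P53], p[P_HA_MDM2_P53]) -
        mm(p[P_DM_MDM2], y[S_MDM2], p[P_KM_MDM2]);
    dy[S_P53] = p[P_VB_P53] - mm(p[P_DM_P53], y[S_P53], p[P_KM_P53]);
    dy[S_E2F] = p[P_VB_E2F] +
        p[P_V_E2F] * hact(y[S_MYC_N], p[P_KA_E2F_MYC], p[P_HA_E2F_MYC]) +
        p[P_V_E2F_AUTO] * hact(y[S_E2F_N], p[P_KA_E2F_AUTO], p[P_HA_E2F_AUTO]) -
        mm(p[P_DM_E2F], y[S_E2F], p[P_KM_E2F]);

    /* ---- cell cycle: cytoplasmic proteins (eq 8-13) ---- */
    dy[S_INK4A_C] = p[P_KT_INK4A] * y[S_INK4A] -
        (p[P_KI_INK4A] + p[P_DC_INK4A]) * y[S_INK4A_C];
    dy[S_MYC_C] = p[P_KT_MYC] * y[S_MYC] -
        (p[P_KI_MYC] + p[P_DC_MYC]) * y[S_MYC_C];
    dy[S_ARF_C] = p[P_KT_ARF] * y[S_ARF] -
        (p[P_KI_ARF] + p[P_DC_ARF]) * y[S_ARF_C];
    dy[S_MDM2_C] = p[P_KT_MDM2] * y[S_MDM2] -
        (p[P_KI_MDM2] + p[P_DC_MDM2]) * y[S_MDM2_C];
    dy[S_E2F_C] = p[P_KT_E2F] * y[S_E2F] -
        (p[P_KI_E2F] + p[P_DC_E2F]) * y[S_E2F_C];
    dy[S_WEE1_C] = p[P_KT_WEE1] * y[S_WEE1] -
        (p[P_KI_WEE1] + p[P_DC_WEE1]) * y[S_WEE1_C];

    /* ---- cell cycle: nuclear proteins and complexes (eq 14-26) ---- */
    dy[S_INK4A_N] = p[P_KI_INK4A] * y[S_INK4A_C] - p[P_DN_INK4A] * y[S_INK4A_N] -
        p[P_KF_ICK] * y[S_INK4A_N] * y[S_CDC_N] + p[P_KD_ICK] * y[S_CDCI];
    dy[S_MYC_N] = p[P_KI_MYC] * y[S_MYC_C] - p[P_DN_MYC] * y[S_MYC_N];
    dy[S_P53_N] = p[P_KT_P53] * y[S_P53] -
        p[P_D_P53] * y[S_P53_N] * (1.0 + p[P_V_DP53_MDM2] *
            hact(y[S_MDM2_N], p[P_KD_P53_MDM2], p[P_HD_P53_MDM2]));
    dy[S_MDM2_N] = p[P_KI_MDM2] * y[S_MDM2_C] -
        p[P_DN_MDM2] * y[S_MDM2_N] * (1.0 + p[P_V_DMDM2_ARF] *
            hact(y[S_ARF_N], p[P_KD_MDM2_ARF], p[P_HD_MDM2_ARF]));
    dy[S_WEE1_N] = p[P_KI_WEE1] * y[S_WEE1_C] - p[P_DN_WEE1] * y[S_WEE1_N];
    dy[S_ARF_N] = p[P_KI_ARF] * y[S_ARF_C] - p[P_DN_ARF] * y[S_ARF_N];
    /* E2F keeps turning over while RB1-bound (rate dn_e2f); RB1 is recycled */
    dy[S_RB1_N] = p[P_K_DEPHOS] * rb1p - phos_flux -
        p[P_KF_RE] * y[S_RB1_N] * y[S_E2F_N] + p[P_KD_RE] * y[S_RBE2F] +
        p[P_DN_E2F] * y[S_RBE2F];
    dy[S_RBE2F] = p[P_KF_RE] * y[S_RB1_N] * y[S_E2F_N] -
        p[P_KD_RE] * y[S_RBE2F] - phos2_flux - p[P_DN_E2F] * y[S_RBE2F];
    dy[S_E2F_N] = p[P_KI_E2F] * y[S_E2F_C] - p[P_DN_E2F] * y[S_E2F_N] -
        p[P_KF_RE] * y[S_RB1_N] * y[S_E2F_N] + p[P_KD_RE] * y[S_RBE2F] +
        phos2_flux;
    dy[S_CDC] = p[P_VB_CDC] +
        p[P_V_CDC] * hact(y[S_E2F_N], p[P_KA_CDC_E2F], p[P_HA_CDC_E2F]) -
        mm(p[P_DM_CDC], y[S_CDC], p[P_KM_CDC]);
    dy[S_CDC_C] = p[P_KT_CDC] * y[S_CDC] -
        (p[P_KI_CDC] + p[P_DC_CDC]) * y[S_CDC_C];
    dy[S_CDC_N] = p[P_KI_CDC] * y[S_CDC_C] - p[P_DN_CDC] * y[S_CDC_N] -
        p[P_KF_ICK] * y[S_INK4A_N] * y[S_CDC_N] + p[P_KD_ICK] * y[S_CDCI];
    dy[S_CDCI] = p[P_KF_ICK] * y[S_INK4A_N] * y[S_CDC_N] -
        (p[P_KD_ICK] + p[P_D_CDCI]) * y[S_CDCI];

    /* ---- clock: mRNAs (eq 27-31) ---- */
    dy[S_BMAL] = fkd * (p[P_VB_BMAL] +
        p[P_V_BMAL] * hact(y[S_ROR_N], p[P_KA_BMAL_ROR], p[P_HA_BMAL_ROR]) *
            hinh(y[S_REV_N], p[P_KI_BMAL_REV], p[P_HI_BMAL_REV]) +
        p[P_V_BMAL_E2F] * hact(y[S_E2F_N], p[P_KA_BMAL_E2F], p[P_HA_BMAL_E2F])) -
        mm(p[P_DM_BMAL], y[S_BMAL], p[P_KM_BMAL]);
    dy[S_PER] = p[P_VB_PER] +
        p[P_V_PER] * hact(cbk, p[P_KA_PER_CB], p[P_HA_PER_CB]) * fmyc *
            hinh(y[S_P53_N], p[P_KI_PER_P53], p[P_HI_PER_P53]) -
        mm(p[P_DM_PER], y[S_PER], p[P_KM_PER]);
    dy[S_CRY] = p[P_VB_CRY] +
        p[P_V_CRY] * hact(cbk, p[P_KA_CRY_CB], p[P_HA_CRY_CB]) * fmyc *
            hinh(y[S_REV_N], p[P_KI_CRY_REV], p[P_HI_CRY_REV]) -
        mm(p[P_DM_CRY], y[S_CRY], p[P_KM_CRY]);
    dy[S_REV] = p[P_VB_REV] +
        p[P_V_REV] * hact(cbk, p[P_KA_REV_CB], p[P_HA_REV_CB]) * fmyc -
        mm(p[P_DM_REV], y[S_REV], p[P_KM_REV]);
    dy[S_ROR] = p[P_VB_ROR] +
        p[P_V_ROR] * hact(cbk, p[P_KA_ROR_CB], p[P_HA_ROR_CB]) * fmyc -
        mm(p[P_DM_ROR], y[S_ROR], p[P_KM_ROR]);

    /* ---- clock: cytoplasmic proteins (eq 32-36) ---- */
    dy[S_BMAL_C] = p[P_KT_BMAL] * y[S_BMAL] -
        (p[P_KI_BMAL] + p[P_DC_BMAL]) * y[S_BMAL_C];
    dy[S_PER_C] = p[P_KT_PER] * y[S_PER] -
        (p[P_KI_PER] + p[P_DC_PER]) * y[S_PER_C] -
        p[P_KF_PC] * y[S_PER_C] * y[S_CRY_C] + p[P_KD_PC] * y[S_PERCRY_C];
    dy[S_CRY_C] = p[P_KT_CRY] * y[S_CRY] -
        (p[P_KI_CRY] + p[P_DC_CRY]) * y[S_CRY_C] -
        p[P_KF_PC] * y[S_PER_C] * y[S_CRY_C] + p[P_KD_PC] * y[S_PERCRY_C];
    dy[S_REV_C] = p[P_KT_REV] * y[S_REV] -
        (p[P_KI_REV] + p[P_DC_REV]) * y[S_REV_C];
    dy[S_ROR_C] = p[P_KT_ROR] * y[S_ROR] -
        (p[P_KI_ROR] + p[P_DC_ROR]) * y[S_ROR_C];

    /* ---- clock: nuclear proteins (eq 37-41) ---- */
    dy[S_BMAL_N] = p[P_KI_BMAL] * y[S_BMAL_C] -
        (p[P_DN_BMAL] + p[P_K_CBFORM]) * y[S_BMAL_N];
    dy[S_PER_N] = p[P_KI_PER] * y[S_PER_C] - p[P_DN_PER] * y[S_PER_N] -
        p[P_KF_PCN] * y[S_PER_N] * y[S_CRY_N] + p[P_KD_PCN] * y[S_PERCRY_N];
    dy[S_CRY_N] = p[P_KI_CRY] * y[S_CRY_C] - p[P_DN_CRY] * y[S_CRY_N] -
        p[P_KF_PCN] * y[S_PER_N] * y[S_CRY_N] + p[P_KD_PCN] * y[S_PERCRY_N];
    dy[S_REV_N] = p[P_KI_REV] * y[S_REV_C] - p[P_DN_REV] * y[S_REV_N];
    dy[S_ROR_N] = p[P_KI_ROR] * y[S_ROR_C] - p[P_DN_ROR] * y[S_ROR_N];

    /* ---- clock: complexes (eq 42-45) ---- */
    dy[S_PERCRY_C] = p[P_KF_PC] * y[S_PER_C] * y[S_CRY_C] -
        (p[P_KD_PC] + p[P_KI_PC] + p[P_DC_PERCRY]) * y[S_PERCRY_C] +
        p[P_KE_PC] * y[S_PERCRY_N];
    dy[S_PERCRY_N] = p[P_KI_PC] * y[S_PERCRY_C] +
        p[P_KF_PCN] * y[S_PER_N] * y[S_CRY_N] -
        (p[P_KD_PCN] + p[P_KE_PC] + p[P_DN_PERCRY]) * y[S_PERCRY_N] -
        p[P_KF_CBI] * y[S_PERCRY_N] * y[S_CB] + p[P_KD_CBI] * y[S_CBI];
    dy[S_CB] = p[P_K_CBFORM] * y[S_BMAL_N] - p[P_D_CB] * y[S_CB] -
        p[P_KF_CBI] * y[S_PERCRY_N] * y[S_CB] + p[P_KD_CBI] * y[S_CBI];
    dy[S_CBI] = p[P_KF_CBI] * y[S_PERCRY_N] * y[S_CB] -
        (p[P_KD_CBI] + p[P_D_CBI]) * y[S_CBI];

    /* conserved RB1p_N bookkeeping row */
    dy[S_RB1P_N] = -(dy[S_RB1_N] + dy[S_RBE2F]);

    /* knockout / clamp freezes */
    {
        int i;
        for (i = 0; i < N_SPEC; i++)
            if (p[IDX_MASK + i] > 0.5) dy[i] = 0.0;
        /* keep the conservation row consistent when RB species are frozen */
        if (p[IDX_MASK + S_RB1P_N] > 0.5) dy[S_RB1P_N] = 0.0;
    }
}

void cc_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
               int *ip)
{
    cc_core(*t, y, parms, ydot);
}

/* Direct entry point for R-level rhs(): parameters supplied per call. */
void cc_rhs_direct(double *t, double *y, double *p, double *ydot)
{
    cc_core(*t, y, p, ydot);
}
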