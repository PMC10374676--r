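/* Compiled right-hand side of the integrated hematopoiesis model.
 *
 * State layout (0-based):
 *   0  S      stem cells (normalized, normal = 1)
 *   1  O      osteoblast niche activity (normalized)
 *   2  D      dormant precursors (normalized)
 *   3  CMP    active common myeloid progenitors (normalized)
 *   4  Gp     proliferating granulopoietic precursors
 *   5-8  M1..M4  granulopoietic maturation chain
 *   9  ANC    circulating neutrophils (1e9/L)
 *   10 CM     megakaryocyte precursors (normalized)
 *   11-16 K2..K64 megakaryocyte ploidy classes 2,4,8,16,32,64
 *   17 PPT    proplatelet release pool
 *   18-27 P1..P10 circulating platelet age chain (sum in 1e9/L)
 *   28 Lp     proliferating lymphoid precursors
 *   29 LYM    circulating lymphocytes (1e9/L)
 *   30 MON    circulating monocytes (1e9/L)
 *   31 G      G-CSF (normalized, normal = 1)
 *   32 T      TPO (normalized, normal = 1)
 *   33-35 oxaliplatin PK amounts (mg), central first
 *   36-37 fluorouracil PK amounts
 *   38-40 irinotecan PK amounts
 *   41-43 docetaxel PK amounts
 *
 * All compartments are written in normalized relaxation form so that the
 * drug-free steady state is exactly the all-normal state for any
 * admissible parameter values.
 */

#include <R.h>
#include <math.h>

#define NP 77

static double p[NP];

/* parameter indices (0-based) */
#define b_S_act   p[0]
#define b_A_CM    p[1]
#define b_MKC64   p[2]
#define w_PLC     p[3]
#define d_Osteo   p[4]
#define PD_oxa    p[5]
#define PD_fu     p[6]
#define PD_iri    p[7]
#define PD_doc    p[8]
#define ANC_nor   p[9]
#define PLT_nor   p[10]
#define LYM_nor   p[11]
#define MON_nor   p[12]
#define k_S       p[13]
#define b_MKC_S   p[14]
#define k_O       p[15]
#define k_D       p[16]
#define k_CMP     p[17]
#define k_Gp      p[18]
#define k_mat     p[19]
#define k_ANC     p[20]
#define b_G_amp   p[21]
#define k_CM      p[22]
#define k_pl      p[23]
#define k_PPT     p[24]
#define k_e       p[25]
#define k_Lp      p[26]
#define k_L       p[27]
#define k_MON     p[28]
#define h_TPO     p[29]
#define s_TPO     p[30]
#define k_G_ren   p[31]
#define k_G_anc   p[32]
#define k_T_ren   p[33]
#define w_mkc     p[34]
#define f_kill_S  p[35]
#define f_kill_O  p[36]
#define f_kill_L  p[37]
#define z_min     p[38]
#define z_max     p[39]
#define plt_prod  p[40]
/* per-drug lineage vulnerability weights (granulopoietic, thrombopoietic) */
#define wg_oxa    p[41]
#define wg_fu     p[42]
#define wg_iri    p[43]
#define wg_doc    p[44]
#define wt_oxa    p[45]
#define wt_fu     p[46]
#define wt_iri    p[47]
#define wt_doc    p[48]
/* PK constants: 49..54 oxa (V,k10,k12,k21,k13,k31), 55..58 fu (V,k10,k12,k21),
 * 59..64 iri, 65..70 doc */
/* current input rates (set per integration chunk): */
#define rate_oxa  p[71]
#define rate_fu   p[72]
#define rate_iri  p[73]
#define rate_doc  p[74]
#define rate_gcsf p[75]
#define xkill     p[76]

void initmod(void (*odeparms)(int *, double *))
{
    int n = NP;
    odeparms(&n, p);
}

/* clamped power-law regulation, Z(1) = 1 */
static double zreg(double x, double b, double lo, double hi)
{
    double v = pow(fmax(x, 1e-12), b);
    if (v < lo) v = lo;
    if (v > hi) v = hi;
    return v;
}

/* biphasic TPO stimulation, f(1) = 1, interior maximum */
static double biph(double u, double h, double s)
{
    double uh = pow(fmax(u, 0.0), h);
    return (1.0 + s) * uh / (1.0 + s * uh * uh);
}

void derivs(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    double S = y[0], O = y[1], D = y[2], CMP = y[3], Gp = y[4];
    double ANC = y[9], CM = y[10], PPT = y[17];
    double Lp = y[28], LYM = y[29], MON = y[30], G = y[31], T = y[32];
    int i;

    /* PK: linear compartmental models, amounts in mg */
    double Vo = p[49], ko10 = p[50], ko12 = p[51], ko21 = p[52], ko13 = p[53], ko31 = p[54];
    double Vf = p[55], kf10 = p[56], kf12 = p[57], kf21 = p[58];
    double Vi = p[59], ki10 = p[60], ki12 = p[61], ki21 = p[62], ki13 = p[63], ki31 = p[64];
    double Vd = p[65], kd10 = p[66], kd12 = p[67], kd21 = p[68], kd13 = p[69], kd31 = p[70];

    ydot[33] = rate_oxa - (ko10 + ko12 + ko13) * y[33] + ko21 * y[34] + ko31 * y[35];
    ydot[34] = ko12 * y[33] - ko21 * y[34];
    ydot[35] = ko13 * y[33] - ko31 * y[35];

    ydot[36] = rate_fu - (kf10 + kf12) * y[36] + kf21 * y[37];
    ydot[37] = kf12 * y[36] - kf21 * y[37];

    ydot[38] = rate_iri - (ki10 + ki12 + ki13) * y[38] + ki21 * y[39] + ki31 * y[40];
    ydot[39] = ki12 * y[38] - ki21 * y[39];
    ydot[40] = ki13 * y[38] - ki31 * y[40];

    ydot[41] = rate_doc - (kd10 + kd12 + kd13) * y[41] + kd21 * y[42] + kd31 * y[43];
    ydot[42] = kd12 * y[41] - kd21 * y[42];
    ydot[43] = kd13 * y[41] - kd31 * y[43];

    /* per-drug kill pressures; shared compartments see the unweighted sum,
     * the granulopoietic and thrombopoietic branches see lineage-weighted
     * sums (fixed per-drug vulnerability weights) */
    double k_d[4] = { PD_oxa * y[33] / Vo, PD_fu * y[36] / Vf,
                      PD_iri * y[38] / Vi, PD_doc * y[41] / Vd };
    double kill  = k_d[0] + k_d[1] + k_d[2] + k_d[3] + xkill;
    double kill_g = wg_oxa * k_d[0] + wg_fu * k_d[1] + wg_iri * k_d[2]
                  + wg_doc * k_d[3] + xkill;
    double kill_t = wt_oxa * k_d[0] + wt_fu * k_d[1] + wt_iri * k_d[2]
                  + wt_doc * k_d[3] + xkill;

    /* mean megakaryocyte mass over the ploidy ladder (normal = 1) */
    double m_mkc = 0.0;
    for (i = 11; i <= 16; i++) m_mkc += y[i];
    m_mkc /= 6.0;

    /* stem cell activation: G-CSF stimulation x compensatory MKC feedback */
    double a_S = 0.5 * k_S; /* baseline activation rate; fixes S* = 1 */
    double a_rate = a_S * zreg(G, b_S_act, z_min, z_max)
                        * zreg(fmax(2.0 - m_mkc, 0.05), b_MKC_S, z_min, z_max);
    ydot[0] = k_S * S * (1.0 - 0.5 * S) - a_rate * S - f_kill_S * kill * S;

    /* normalized stem outflux, gated by dormant-precursor support */
    double u_flux = (a_rate * S / a_S) * D;

    /* osteoblast niche and dormant precursors */
    ydot[1] = k_O * (1.0 - O) - f_kill_O * kill * O;
    ydot[2] = k_D * (1.0 - D) - d_Osteo * fmax(1.0 - O, 0.0) * D;

    /* common myeloid progenitors */
    ydot[3] = k_CMP * (zreg(G, b_A_CM, z_min, z_max) * u_flux - CMP) - kill * CMP;

    /* granulopoiesis */
    ydot[4] = k_Gp * (zreg(G, b_G_amp, z_min, z_max) * CMP - Gp) - kill_g * Gp;
    ydot[5] = k_mat * (Gp - y[5]);
    ydot[6] = k_mat * (y[5] - y[6]);
    ydot[7] = k_mat * (y[6] - y[7]);
    ydot[8] = k_mat * (y[7] - y[8]);
    ydot[9] = k_ANC * (y[8] * ANC_nor - ANC);

    /* thrombopoiesis: CM -> ploidy ladder -> proplatelets -> platelet chain */
    double ftpo = biph(T, h_TPO, s_TPO);
    ydot[10] = k_CM * (zreg(G, b_A_CM, z_min, z_max) * ftpo * u_flux - CM) - kill_t * CM;
    ydot[11] = k_pl * (CM - y[11]) - kill_t * y[11];
    ydot[12] = k_pl * (y[11] - y[12]) - kill_t * y[12];
    ydot[13] = k_pl * (y[12] - y[13]) - kill_t * y[13];
    ydot[14] = k_pl * (y[13] - y[14]) - kill_t * y[14];
    ydot[15] = k_pl * (y[14] - y[15]) - kill_t * y[15];
    double z64 = zreg(T, b_MKC64, z_min, z_max);
    ydot[16] = k_pl * (y[15] - z64 * y[16]) - kill_t * y[16];
    ydot[17] = k_PPT * (z64 * y[16] - PPT);

    /* Erlang-10 platelet age chain; production normalized to PLT_nor */
    double prod = plt_prod * PPT * PLT_nor * k_e / 10.0;
    ydot[18] = prod - k_e * y[18];
    for (i = 19; i <= 27; i++) ydot[i] = k_e * (y[i - 1] - y[i]);

    /* lymphocytes and monocytes */
    ydot[28] = k_Lp * (u_flux - Lp) - f_kill_L * kill * Lp;
    ydot[29] = k_L * (Lp * LYM_nor - LYM);
    ydot[30] = k_MON * (CMP * MON_nor - MON);

    /* cytokines: constant production, cell-mediated saturable clearance */
    double plt_tot = 0.0;
    for (i = 18; i <= 27; i++) plt_tot += y[i];
    double m_T = (plt_tot / PLT_nor + w_mkc * m_mkc) / (1.0 + w_mkc);

    double p_G = k_G_ren + 0.5 * k_G_anc;
    ydot[31] = p_G - k_G_ren * G - k_G_anc * (ANC / ANC_nor) * G / (1.0 + G) + rate_gcsf;

    double p_T = k_T_ren + 0.5 * w_PLC;
    ydot[32] = p_T - k_T_ren * T - w_PLC * m_T * T / (1.0 + T);
}
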