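/* Two-layer (parent + glucuronide) flow-limited PBK model.
 *
 * States (nmol):
 *  0 A_st   parent, stomach lumen        12 G_gut  glucuronide, gut wall
 *  1 A_lum  parent, intestinal lumen     13 G_liv  liver
 *  2 A_gut  parent, gut wall             14 G_kid  kidney
 *  3 A_liv  liver                        15 G_thy  thyroid
 *  4 A_kid  kidney                       16 G_gon  testes/breast
 *  5 A_thy  thyroid                      17 G_slw  slowly perfused
 *  6 A_gon  testes/breast                18 G_rpd  rapidly perfused
 *  7 A_slw  slowly perfused              19 G_bld  blood
 *  8 A_rpd  rapidly perfused             20 G_ur   cumulative urine
 *  9 A_bld  blood                        21 G_bile cumulative biliary flux
 * 10 A_ur   cumulative urine                       (accumulator only)
 * 11 A_fe   cumulative feces
 *
 * Oral doses are event additions to A_st. Biliary glucuronide reverts to the
 * parent on transfer into the intestinal lumen (instant, complete), so the
 * bile flux feeds A_lum. Moles are conserved over states 0..20.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 40

static double p[N_PARMS];

#define KST    p[0]
#define KA     p[1]
#define KCOL   p[2]
#define QLART  p[3]
#define QGUT   p[4]
#define QK     p[5]
#define QTHY   p[6]
#define QGON   p[7]
#define QSLW   p[8]
#define QRPD   p[9]
#define VLIV   p[10]
#define VGUT   p[11]
#define VKID   p[12]
#define VTHY   p[13]
#define VGON   p[14]
#define VSLW   p[15]
#define VRPD   p[16]
#define VBLD   p[17]
/* parent Kp: gut liver kidney thyroid gonad slowly rapidly -> p[18..24] */
/* glucuronide Kp: same order -> p[25..31] */
#define FU_P   p[32]
#define FU_G   p[33]
#define GFR    p[34]
#define VMAX   p[35]
#define KM     p[36]
#define EHCR   p[37]
#define HASTHY p[38]
#define HASGON p[39]

void bispbk_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void bispbk_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double CA  = y[9]  / VBLD;
    double CAg = y[19] / VBLD;

    double cv_gut = y[2] / (VGUT * p[18]);
    double cv_liv = y[3] / (VLIV * p[19]);
    double cv_kid = y[4] / (VKID * p[20]);
    double cv_thy = HASTHY > 0.5 ? y[5] / (VTHY * p[21]) : 0.0;
    double cv_gon = HASGON > 0.5 ? y[6] / (VGON * p[22]) : 0.0;
    double cv_slw = y[7] / (VSLW * p[23]);
    double cv_rpd = y[8] / (VRPD * p[24]);

    double cvg_gut = y[12] / (VGUT * p[25]);
    double cvg_liv = y[13] / (VLIV * p[26]);
    double cvg_kid = y[14] / (VKID * p[27]);
    double cvg_thy = HASTHY > 0.5 ? y[15] / (VTHY * p[28]) : 0.0;
    double cvg_gon = HASGON > 0.5 ? y[16] / (VGON * p[29]) : 0.0;
    double cvg_slw = y[17] / (VSLW * p[30]);
    double cvg_rpd = y[18] / (VRPD * p[31]);

    double qltot = QLART + QGUT;
    double qc = QLART + QGUT + QK + QTHY + QGON + QSLW + QRPD;

    double c_liv = y[3] / VLIV;                 /* liver tissue conc, nM   */
    double met = VMAX * c_liv / (KM + c_liv);   /* glucuronidation, nmol/h */

    /* biliary excretion as the clearance QL*EHCr applied to the liver
       venous glucuronide; the remainder of the outflow reaches blood */
    double bile = EHCR * QLART * cvg_liv;
    double renal_p = GFR * FU_P * CA;
    double ksec = QK * EHCR * (VKID / VLIV);
    double renal_g = (GFR * FU_G + ksec) * CAg;

    /* parent */
    ydot[0] = -KST * y[0];
    ydot[1] = KST * y[0] + bile - (KA + KCOL) * y[1];
    ydot[2] = KA * y[1] + QGUT * (CA - cv_gut);
    ydot[3] = QLART * CA + QGUT * cv_gut - qltot * cv_liv - met;
    ydot[4] = QK * (CA - cv_kid);
    ydot[5] = HASTHY > 0.5 ? QTHY * (CA - cv_thy) : 0.0;
    ydot[6] = HASGON > 0.5 ? QGON * (CA - cv_gon) : 0.0;
    ydot[7] = QSLW * (CA - cv_slw);
    ydot[8] = QRPD * (CA - cv_rpd);
    ydot[9] = qltot * cv_liv + QK * cv_kid + QTHY * cv_thy + QGON * cv_gon
            + QSLW * cv_slw + QRPD * cv_rpd - qc * CA - renal_p;
    ydot[10] = renal_p;
    ydot[11] = KCOL * y[1];

    /* glucuronide */
    ydot[12] = QGUT * (CAg - cvg_gut);
    ydot[13] = met + QLART * CAg + QGUT * cvg_gut - qltot * cvg_liv;
    ydot[14] = QK * (CAg - cvg_kid);
    ydot[15] = HASTHY > 0.5 ? QTHY * (CAg - cvg_thy) : 0.0;
    ydot[16] = HASGON > 0.5 ? QGON * (CAg - cvg_gon) : 0.0;
    ydot[17] = QSLW * (CAg - cvg_slw);
    ydot[18] = QRPD * (CAg - cvg_rpd);
    ydot[19] = (qltot * cvg_liv - bile) + QK * cvg_kid
             + QTHY * cvg_thy + QGON * cvg_gon + QSLW * cvg_slw
             + QRPD * cvg_rpd - qc * CAg - renal_g;
    ydot[20] = renal_g;
    ydot[21] = bile;
}

static const R_CMethodDef cMethods[] = {
    {NULL, NULL, 0}
};

void R_init_bispbk(DllInfo *info)
{
    R_registerRoutines(info, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
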