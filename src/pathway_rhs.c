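/* Mass-action ODE right-hand side of the TGFbeta receptor/SMAD/feedback
 * pathway, in the compiled-model form expected by deSolve.
 *
 * State vector (15 species, concentrations in arbitrary units except the
 * extracellular ligand L which is in pM):
 *   0  L      extracellular ligand
 *   1  Rs     surface free receptor
 *   2  Re     endosomal free receptor
 *   3  Cs     surface ligand-receptor complex
 *   4  Ce     endosomal ligand-receptor complex
 *   5  S2c    cytoplasmic SMAD2
 *   6  S2n    nuclear SMAD2
 *   7  pS2c   cytoplasmic phospho-SMAD2
 *   8  pS2n   nuclear phospho-SMAD2
 *   9  S4c    cytoplasmic SMAD4
 *  10  S4n    nuclear SMAD4
 *  11  Gc     cytoplasmic pSMAD2-SMAD4 complex
 *  12  Gn     nuclear pSMAD2-SMAD4 complex
 *  13  Fm     feedback mRNA
 *  14  Fp     feedback protein
 *
 * The nuclear/cytoplasmic volume ratio is absorbed into the import/export
 * rate constants; there is no explicit volume parameter.
 */
#include <R.h>

static double parms[29];

#define ka        parms[0]   /* ligand-receptor association, pM^-1 min^-1   */
#define ki_R      parms[1]   /* receptor internalization, min^-1            */
#define krec_R    parms[2]   /* receptor recycling, min^-1                  */
#define pr        parms[3]   /* receptor production, conc min^-1            */
#define kdeg_R    parms[4]   /* receptor degradation, min^-1                */
#define ki_C      parms[5]   /* complex internalization, min^-1             */
#define kdeg_C    parms[6]   /* basal complex degradation, min^-1           */
#define kphos     parms[7]   /* SMAD2 phosphorylation catalytic, conc^-1 min^-1 */
#define kon       parms[8]   /* pSMAD2-SMAD4 association, conc^-1 min^-1    */
#define koff      parms[9]   /* complex dissociation, min^-1                */
#define kin_s2    parms[10]  /* nuclear import SMAD2, min^-1                */
#define kex_s2    parms[11]  /* nuclear export SMAD2, min^-1                */
#define kin_ps2   parms[12]  /* nuclear import pSMAD2, min^-1               */
#define kex_ps2   parms[13]  /* nuclear export pSMAD2, min^-1               */
#define kin_s4    parms[14]  /* nuclear import SMAD4, min^-1                */
#define kex_s4    parms[15]  /* nuclear export SMAD4, min^-1                */
#define kin_g     parms[16]  /* nuclear import pSMAD2-SMAD4, min^-1         */
#define kex_g     parms[17]  /* nuclear export pSMAD2-SMAD4, min^-1         */
#define kdephos   parms[18]  /* nuclear dephosphorylation, min^-1           */
#define ktx_b     parms[19]  /* basal feedback transcription, conc min^-1   */
#define ktx       parms[20]  /* induced feedback transcription, min^-1      */
#define kdeg_m    parms[21]  /* feedback mRNA degradation, min^-1           */
#define ktl       parms[22]  /* translation, min^-1                         */
#define kdeg_p    parms[23]  /* feedback protein degradation, min^-1        */
#define kfb       parms[24]  /* feedback inhibition strength, conc^-1       */
#define rho       parms[25]  /* cells-to-medium depletion scaling           */
#define fb_scale  parms[26]  /* feedback expression multiplier (1 = wild type) */
#define sb_active parms[27]  /* receptor kinase inhibitor flag (0/1)        */
#define drb_active parms[28] /* transcription inhibitor flag (0/1)         */

void pathway_init(void (*odeparms)(int *, double *))
{
    int n = 29;
    odeparms(&n, parms);
}

void pathway_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double L = y[0], Rs = y[1], Re = y[2], Cs = y[3], Ce = y[4];
    double S2c = y[5], S2n = y[6], pS2c = y[7], pS2n = y[8];
    double S4c = y[9], S4n = y[10], Gc = y[11], Gn = y[12];
    double Fm = y[13], Fp = y[14];

    double bind  = ka * L * Rs;
    double phos  = (sb_active > 0.5) ? 0.0 : kphos * (Cs + Ce) * S2c;
    double fbdeg = kdeg_C * (1.0 + kfb * Fp); /* receptor-level feedback */
    double assoc = kon * pS2c * S4c;
    double tx    = (drb_active > 0.5) ? 0.0
                   : fb_scale * (ktx_b + ktx * Gn);

    ydot[0]  = -rho * bind;                                        /* L    */
    ydot[1]  = pr - bind - ki_R * Rs + krec_R * Re - kdeg_R * Rs;  /* Rs   */
    ydot[2]  = ki_R * Rs - krec_R * Re - kdeg_R * Re;              /* Re   */
    ydot[3]  = bind - ki_C * Cs - fbdeg * Cs;                      /* Cs   */
    ydot[4]  = ki_C * Cs - fbdeg * Ce;                             /* Ce   */
    ydot[5]  = -phos - kin_s2 * S2c + kex_s2 * S2n;                /* S2c  */
    ydot[6]  = kin_s2 * S2c - kex_s2 * S2n
               + kdephos * (pS2n + Gn);                            /* S2n  */
    ydot[7]  = phos - assoc + koff * Gc
               - kin_ps2 * pS2c + kex_ps2 * pS2n;                  /* pS2c */
    ydot[8]  = kin_ps2 * pS2c - kex_ps2 * pS2n - kdephos * pS2n;   /* pS2n */
    ydot[9]  = -assoc + koff * Gc - kin_s4 * S4c + kex_s4 * S4n;   /* S4c  */
    ydot[10] = kin_s4 * S4c - kex_s4 * S4n + kdephos * Gn;         /* S4n  */
    ydot[11] = assoc - koff * Gc - kin_g * Gc + kex_g * Gn;        /* Gc   */
    ydot[12] = kin_g * Gc - kex_g * Gn - kdephos * Gn;             /* Gn   */
    ydot[13] = tx - kdeg_m * Fm;                                   /* Fm   */
    ydot[14] = ktl * Fm - kdeg_p * Fp;                             /* Fp   */
}
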