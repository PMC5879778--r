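/* 13-species Myc-Rb-E2F restriction-point network.
 *
 * Oxygen enters only through three algebraic inputs computed in R and passed
 * as the first three parameters: the Hif1a and Hif2a concentrations and the
 * ROS deactivation multiplier DEG.  The remaining slots carry the kinetic
 * constants in the fixed order defined in R/model.R (.parm_layout).
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define NPARMS 53
#define NSPEC  13

static double parms[NPARMS];

/* parameter slots */
enum {
  iH1 = 0, iH2, iDEG,
  ikf3A, ikr3A, ikf3B, ikr3B, ikf6B, ikr6B, ikf12, ikr12, ik8,
  im9, ik9, im13, ik13, ikp13,
  im_E2F, ik_E2F, im_E2F_RbP, ik_E2F_RbP,
  im_5cycD, ik_5cycD, im_cycD_Rb, ik_cycD_Rb,
  im_RbP, ik_RbP, im_cycE_RbP, ik_cycE_RbP,
  im_Rb_nP, ik_Rb_nP,
  ik3a, ik4, ieps,
  ig_Myc, ig_cycD, ig_pp, ig_Rb,
  id_Myc, id_H1M, id_H2M, id_cycE, id_E2F, id_cycD, id_pp,
  id_cycD_pp, id_cycE_pp, id_Rb, id_E2F_Rb, id_RbP,
  in_hyper, iunify, ie2f_th
};

/* species slots */
enum {
  sH1M = 0, sH2M, sMyc, sCycE, sE2F, sCycD, sPP,
  sCycDPP, sCycEPP, sRb, sE2FRb, sRbP, sRbnP
};

static void cc_rhs_core(const double *y, double *ydot, const double *p)
{
  const double H1 = p[iH1], H2 = p[iH2], DEG = p[iDEG];
  const double H1M = y[sH1M], H2M = y[sH2M], Myc = y[sMyc], cycE = y[sCycE],
    E2F = y[sE2F], cycD = y[sCycD], pp = y[sPP], cycD_pp = y[sCycDPP],
    cycE_pp = y[sCycEPP], Rb = y[sRb], E2F_Rb = y[sE2FRb], RbP = y[sRbP],
    Rb_nP = y[sRbnP];

  const double cycDtot = cycD + cycD_pp;
  const int n = (int) p[in_hyper];
  const double rbp_n1  = pow(RbP,  (double)(n - 1));
  const double rbnp_n1 = pow(Rb_nP, (double)(n - 1));

  /* E2F-Rb dissociation flux; as printed its denominator differs between the
   * E2F/E2F-Rb balances (k_E2F-RbP) and the RbP balance (k_cycE-RbP); the
   * unify switch collapses both onto k_E2F-RbP. */
  const double diss_e2f = p[im_E2F_RbP] * E2F_Rb * cycDtot /
    (E2F_Rb + p[ik_E2F_RbP]);
  const double k14 = p[iunify] > 0.5 ? p[ik_E2F_RbP] : p[ik_cycE_RbP];
  const double diss_rbp = p[im_E2F_RbP] * E2F_Rb * cycDtot / (E2F_Rb + k14);

  const double bindA = p[ikf3A] * H1 * Myc;
  const double bindB = p[ikf3B] * H2 * Myc;
  const double cd_bind = p[ikf6B] * pp * cycD;
  const double ce_bind = p[ikf12] * pp * cycE;
  const double rb_e2f  = p[ik8] * Rb * E2F;
  const double rb_phos = p[im_cycD_Rb] * cycDtot * Rb / (Rb + p[ik_cycD_Rb]);
  const double rbp_deph = p[im_RbP] * RbP / (RbP + p[ik_RbP]);
  const double hyper = p[im_cycE_RbP] * cycE * rbp_n1 /
    (rbp_n1 + p[ik_cycE_RbP]);
  const double hyper_back = p[im_Rb_nP] * rbnp_n1 / (rbnp_n1 + p[ik_Rb_nP]);

  ydot[sH1M] = -p[ikr3A] * H1M + bindA - p[id_H1M] * H1M * DEG;
  ydot[sH2M] = -p[ikr3B] * H2M + bindB - p[id_H2M] * H2M * DEG;
  ydot[sMyc] = p[ig_Myc] + p[ikr3A] * H1M - bindA + p[ikr3B] * H2M - bindB
    - p[id_Myc] * Myc * DEG;
  ydot[sCycE] = p[ikr12] * cycE_pp - ce_bind
    + p[im9] * E2F / (E2F + p[ik9]) - p[id_cycE] * cycE * DEG;
  ydot[sE2F] =
      p[im13] * (Myc / (Myc + p[ik13])) * (E2F / (E2F + p[ikp13]))
    + p[im_E2F] * Myc / (Myc + p[ik_E2F])
    + p[im13] * p[ieps] * (H2M / (H2M + p[ik13])) * (E2F / (E2F + p[ikp13]))
    + p[im_E2F] * H2M / (H2M + p[ik_E2F])
    + diss_e2f - rb_e2f - p[id_E2F] * E2F * DEG;
  ydot[sCycD] = p[ig_cycD] * (1.0 - H1 / (H1 + p[ik3a]))
    - cd_bind + p[ikr6B] * cycD_pp
    + p[im_5cycD] * p[ieps] * H2M / (H2M + p[ik_5cycD])
    + p[im_5cycD] * Myc / (Myc + p[ik_5cycD])
    - p[id_cycD] * cycD * DEG;
  ydot[sPP] = p[ig_pp] * (1.0 - p[ik4] * Myc)
    - cd_bind + p[ikr6B] * cycD_pp - ce_bind + p[ikr12] * cycE_pp
    - p[id_pp] * pp * DEG;
  ydot[sCycDPP] = cd_bind - p[ikr6B] * cycD_pp
    - p[id_cycD_pp] * cycD_pp * DEG;
  ydot[sCycEPP] = ce_bind - p[ikr12] * cycE_pp
    - p[id_cycE_pp] * cycE_pp * DEG;
  ydot[sRb] = p[ig_Rb] - rb_phos + rbp_deph - rb_e2f
    - p[id_Rb] * Rb * DEG;
  ydot[sE2FRb] = rb_e2f - diss_e2f - p[id_E2F_Rb] * E2F_Rb * DEG;
  ydot[sRbP] = rb_phos - hyper - rbp_deph + diss_rbp + hyper_back
    - p[id_RbP] * RbP * DEG;
  ydot[sRbnP] = hyper - hyper_back;
}

/* deSolve compiled-model interface */
void cc_initmod(void (*odeparms)(int *, double *))
{
  int n = NPARMS;
  odeparms(&n, parms);
}

void cc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
  cc_rhs_core(y, ydot, parms);
}

/* root: E2F crossing its commitment threshold */
void cc_root(int *neq, double *t, double *y, int *ng, double *gout,
             double *out, int *ip)
{
  gout[0] = y[sE2F] - parms[ie2f_th];
}

/* direct evaluation from R (used by the exported derivative function) */
SEXP C_cc_derivs(SEXP y, SEXP p)
{
  if (LENGTH(y) != NSPEC) error("state must have %d entries", NSPEC);
  if (LENGTH(p) != NPARMS) error("parameter vector must have %d entries",
                                 NPARMS);
  SEXP ans = PROTECT(allocVector(REALSXP, NSPEC));
  cc_rhs_core(REAL(y), REAL(ans), REAL(p));
  UNPROTECT(1);
  return ans;
}
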