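/* Compiled right-hand sides for the niche competition models, in the form
 * deSolve expects (initfunc/derivs/rootfunc triples).  The R-level functions
 * rhs_model_a() etc. are the reference implementations; these C versions must
 * agree with them exactly (tested) and exist only because ABC-SMC integrates
 * the models tens of thousands of times per run.
 *
 * Parameter vector layouts (set from R, see integrate_model):
 *   model A : a1 b1 c1 e1 f a2 b2 g K cap                      (10)
 *   model B : lam1 lam2 lam3 mu4 lam5 mu6 chi1 mu8
 *             kap1 kap2 kap3 nu4 nu8 gam1 gam2 gam3 cap        (17)
 *   lv2     : alpha beta gamma cap                             (4)
 *   toy     : r cap                                            (2)
 * 'cap' is the blow-up cap used by the root function (integration stops when
 * the summed state crosses it).
 */

#include <R.h>
#include <math.h>

static double pA[10];
static double pB[17];
static double pL[4];
static double pT[2];

void nf_init_a(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, pA);
}

void nf_derivs_a(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double S = y[0], A = y[1], D = y[2], L = y[3], T = y[4];
    double a1 = pA[0], b1 = pA[1], c1 = pA[2], e1 = pA[3], f = pA[4];
    double a2 = pA[5], b2 = pA[6], g = pA[7], K = pA[8];
    double room = 1.0 - (S + A + D + L + T) / K;

    ydot[0] = a1 * S * room - b1 * S;
    ydot[1] = b1 * S + c1 * A * room - e1 * A;
    ydot[2] = e1 * A - f * D;
    ydot[3] = a2 * L * room - b2 * L;
    ydot[4] = b2 * L - g * T;
}

void nf_root_a(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    gout[0] = pA[9] - (y[0] + y[1] + y[2] + y[3] + y[4]);
}

void nf_init_b(void (*odeparms)(int *, double *))
{
    int n = 17;
    odeparms(&n, pB);
}

void nf_derivs_b(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double S = y[0], A = y[1], D = y[2], L = y[3], T = y[4];
    double lam1 = pB[0], lam2 = pB[1], lam3 = pB[2], mu4 = pB[3];
    double lam5 = pB[4], mu6 = pB[5], chi1 = pB[6], mu8 = pB[7];
    double kap1 = pB[8], kap2 = pB[9], kap3 = pB[10], nu4 = pB[11];
    double nu8 = pB[12], gam1 = pB[13], gam2 = pB[14], gam3 = pB[15];
    double phi1 = exp(-gam1 * (S + L));
    double phi2 = exp(-gam2 * (A + D + T));
    double phi3 = exp(-gam3 * (A + D + T));

    ydot[0] = lam1 * phi1 * S - lam3 * phi2 * S - mu4 * S;
    ydot[1] = (lam2 + 2.0 * lam3) * phi2 * S + lam5 * A - mu6 * A
              - chi1 * phi3 * A;
    ydot[2] = chi1 * phi3 * A - mu8 * D;
    ydot[3] = kap1 * phi1 * L - kap3 * phi2 * L - nu4 * L;
    ydot[4] = (kap2 + 2.0 * kap3) * phi2 * L - nu8 * T;
}

void nf_root_b(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    gout[0] = pB[16] - (y[0] + y[1] + y[2] + y[3] + y[4]);
}

void nf_init_lv2(void (*odeparms)(int *, double *))
{
    int n = 4;
    odeparms(&n, pL);
}

void nf_derivs_lv2(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double X = y[0], Y = y[1];
    double crowd = pL[2] * (X + Y);

    ydot[0] = X * (pL[0] - crowd);
    ydot[1] = Y * (pL[1] - crowd);
}

void nf_root_lv2(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip)
{
    gout[0] = pL[3] - (y[0] + y[1]);
}

void nf_init_toy(void (*odeparms)(int *, double *))
{
    int n = 2;
    odeparms(&n, pT);
}

void nf_derivs_toy(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    ydot[0] = -pT[0] * y[0];
}

void nf_root_toy(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip)
{
    gout[0] = pT[1] - y[0];
}
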