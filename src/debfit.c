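/* Compiled dynamics for the DEB life-cycle stage machine and the embryo
 * initial-value problem (deSolve compiled-function interface).
 *
 * Stage states: y = (E, L, EH, ER, q, h, S, SC).
 * Parameter vector layout (see stage_parms() on the R side):
 *  0 assim, 1 f, 2 sM_mode (0 iso, 1 accel), 3 sM_base, 4 L_ref,
 *  5 growth_mode (0 normal, 1 none, 2 shrink, 3 fetal, 4 frozen),
 *  6 maturing, 7 repro_mode (0 none, 1 buffer, 2 excess), 8 imago,
 *  9 t_entry, 10 end_type (0 maturity, 1 duration, 2 repro_density, 3 none),
 * 11 end_value, 12 S_floor,
 * 13 p_Am, 14 v, 15 kap, 16 p_M, 17 p_T, 18 k_J, 19 E_G, 20 E_Hb, 21 E_Hp,
 * 22 s_G, 23 h_a, 24 kap_shrink, 25 E_m, 26 L_m
 */

#include <R.h>

#define N_STAGE_PARMS 27

static double sp[N_STAGE_PARMS];

void stage_init(void (*odeparms)(int *, double *))
{
    int n = N_STAGE_PARMS;
    odeparms(&n, sp);
}

void stage_deriv(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double E = y[0], L = y[1], EH = y[2];
    double q = y[4], h = y[5], S = y[6];

    double p_Am = sp[13], v = sp[14], kap = sp[15], p_M = sp[16], p_T = sp[17];
    double k_J = sp[18], E_G = sp[19], E_Hp = sp[21];
    double s_G = sp[22], h_a = sp[23], kap_shrink = sp[24];
    double E_m = sp[25], L_m = sp[26];

    double sM = (sp[2] > 0.5) ? sp[3] * L / sp[4] : sp[3];
    if (sM < 1.0) sM = 1.0;

    double L2 = L * L, L3 = L2 * L;
    double pA = (sp[0] > 0.5) ? p_Am * sp[1] * sM * L2 : 0.0;
    double pS = p_M * L3 + p_T * sM * L2;
    double pJ = k_J * (EH < E_Hp ? EH : E_Hp);
    double pC = E * (E_G * v * sM * L2 + pS) / (E_G * L3 + kap * E);
    double pG = kap * pC - pS;
    double pR = (1.0 - kap) * pC - pJ;

    double dE, dL, dEH, dER, r;
    int growth = (int) sp[5];

    if (sp[8] > 0.5) { /* imago: mobilization matches maintenance */
        dE = -(pS + pJ);
        dL = 0.0; r = 0.0; dEH = 0.0; dER = 0.0;
    } else {
        switch (growth) {
        case 3:  dE = E_m * v * sM * L2; break;        /* fetal: e = 1 */
        case 4:  dE = 0.0; break;                      /* frozen preparation */
        default: dE = pA - pC;
        }
        switch (growth) {
        case 0:  dL = pG / (3.0 * E_G * L2); break;
        case 2:  dL = (pG >= 0.0) ? 0.0
                     : pG / (3.0 * kap_shrink * E_G * L2); break;
        case 3:  dL = v * sM / 3.0; break;
        default: dL = 0.0;
        }
        r = 3.0 * dL / L;
        dEH = (sp[6] > 0.5 && EH < E_Hp && pR > 0.0) ? pR : 0.0;
        switch ((int) sp[7]) {
        case 1:  dER = (pR > 0.0) ? pR : 0.0; break;
        case 2: {
            double ex = pC - pS - pJ;
            dER = (ex > 0.0) ? ex : 0.0;
            break;
        }
        default: dER = 0.0;
        }
    }

    double dq, dh, dS;
    if (growth == 4) {
        dq = dh = dS = 0.0;
    } else {
        double e = E / (L3 * E_m);
        dq = (q * (L3 / (L_m * L_m * L_m)) * s_G + h_a) * e *
             (v * sM / L - r) - r * q;
        dh = q - r * h;
        dS = -h * S;
    }

    ydot[0] = dE;  ydot[1] = dL; ydot[2] = dEH; ydot[3] = dER;
    ydot[4] = dq;  ydot[5] = dh; ydot[6] = dS;  ydot[7] = S;
}

void stage_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip)
{
    double end;
    switch ((int) sp[10]) {
    case 0:  end = y[2] - sp[11]; break;
    case 1:  end = *t - (sp[9] + sp[11]); break;
    case 2:  end = y[3] - sp[11] * y[1] * y[1] * y[1]; break;
    default: end = 1.0;
    }
    gout[0] = end;
    gout[1] = y[6] - sp[12];
    gout[2] = y[0] - 1e-9 * sp[25] * y[1] * y[1] * y[1];
}

/* embryo system: y = (E, L, EH); parms: p_Am, v, kap, p_M, p_T, k_J, E_G,
 * E_Hb (8) */

#define N_EMB_PARMS 8

static double ep[N_EMB_PARMS];

void embryo_init(void (*odeparms)(int *, double *))
{
    int n = N_EMB_PARMS;
    odeparms(&n, ep);
}

void embryo_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double E = y[0], L = y[1], EH = y[2];
    double v = ep[1], kap = ep[2], p_M = ep[3], p_T = ep[4];
    double k_J = ep[5], E_G = ep[6];
    double L2 = L * L, L3 = L2 * L;
    double pS = p_M * L3 + p_T * L2;
    double pC = E * (E_G * v * L2 + pS) / (E_G * L3 + kap * E);
    double pG = kap * pC - pS;
    double pR = (1.0 - kap) * pC - k_J * EH;
    ydot[0] = -pC;
    ydot[1] = pG / (3.0 * E_G * L2);
    ydot[2] = (pR > 0.0) ? pR : 0.0;
}

void embryo_root(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip)
{
    double E = y[0], L = y[1];
    double v = ep[1], kap = ep[2], p_M = ep[3], p_T = ep[4];
    double k_J = ep[5], E_G = ep[6];
    double L2 = L * L, L3 = L2 * L;
    double pS = p_M * L3 + p_T * L2;
    double pC = E * (E_G * v * L2 + pS) / (E_G * L3 + kap * E);
    gout[0] = y[2] - ep[7];
    gout[1] = (1.0 - kap) * pC - k_J * y[2]; /* maturation stalls */
}
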