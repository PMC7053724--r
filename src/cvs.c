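/* Closed-loop cardiovascular system: compiled right-hand side for deSolve.
 *
 * State vector y (length 18):
 *   0..9  volumes (mL): lv, la, rv, ra, ao, sa, sv, vc, pa, pv
 *   10..17 valves, pairs (Q mL/s, xi): mitral, aortic, tricuspid, pulmonary
 *
 * Parameter vector p (length 74), packed by pack_parms() on the R side:
 *   0  T (heart period, s)
 *   1..4   driver clock offsets: lv, rv, la, ra (s, activation instants mod T)
 *   5..14  LV:  E_es, V_d, P_0, lambda, V_0, k, a1, a2, n1, n2
 *   15..24 RV:  same layout
 *   25..29 LA:  E_max, E_min, V_d, B, C
 *   30..34 RA:  same layout
 *   35     rho_conv = rho / 1333.22 (pressure in mmHg, lengths in cm)
 *   36..55 valves (mitral, aortic, tricuspid, pulmonary), each:
 *          A_eff_max, A_eff_min (cm^2), l_eff (cm), K_vo, K_vc (1/(mmHg s))
 *   56..67 vessel chambers (ao, sa, sv, vc, pa, pv), each: E (mmHg/mL), V_d (mL)
 *   68..73 resistances: R_ao, R_sys, R_vc, R_ra, R_pul, R_pv (mmHg s/mL)
 *
 * Output (yout, length 10): pressures lv, la, rv, ra, ao, sa, sv, vc, pa, pv.
 */

#include <R.h>
#include <math.h>

#define NP 74
static double p[NP];

void cvs_init(void (*odeparms)(int *, double *))
{
    int n = NP;
    odeparms(&n, p);
}

/* phase of a periodic driver clock: time since last activation, in [0, T) */
static double drv_tau(double t, double off, double T)
{
    double tau = fmod(t - off, T);
    if (tau < 0.0) tau += T;
    return tau;
}

/* double-Hill ventricular driver; pv points at {E_es,...,n2} block */
static double hill_driver(double tau, const double *pv, double T)
{
    double k = pv[5], a1 = pv[6], a2 = pv[7], n1 = pv[8], n2 = pv[9];
    double x1 = pow(tau / (a1 * T), n1);
    double x2 = pow(tau / (a2 * T), n2);
    return k * (x1 / (1.0 + x1)) * (1.0 / (1.0 + x2));
}

static double ventricle_p(double V, double tau, const double *pv, double T)
{
    double e = hill_driver(tau, pv, T);
    double pes = pv[0] * (V - pv[1]);
    double ped = pv[2] * (exp(pv[3] * (V - pv[4])) - 1.0);
    return e * pes + (1.0 - e) * ped;
}

static double atrium_p(double V, double tau, const double *pa)
{
    double g = exp(-pa[3] * (tau - pa[4]) * (tau - pa[4]));
    double E = pa[0] * (g + pa[1] / pa[0]);
    return E * (V - pa[2]);
}

/* one valve: given dP = upstream - downstream, state (Q, xi); writes dQ, dxi */
static void valve_rhs(double dP, double Q, double xi, const double *pv,
                      double rho_conv, double *dQ, double *dxi)
{
    double Amax = pv[0], Amin = pv[1], leff = pv[2], Kvo = pv[3], Kvc = pv[4];
    double xic = xi < 0.0 ? 0.0 : (xi > 1.0 ? 1.0 : xi);
    double A = (Amax - Amin) * xic + Amin;
    double B = rho_conv / (2.0 * A * A);
    double L = rho_conv * leff / A;

    *dQ = (dP - B * Q * fabs(Q)) / L;
    if (dP > 0.0)
        *dxi = (1.0 - xic) * Kvo * dP;
    else
        *dxi = xic * Kvc * dP;
    /* keep xi inside [0,1]: boundaries are invariant, protect against
       solver overshoot only */
    if ((xi >= 1.0 && *dxi > 0.0) || (xi <= 0.0 && *dxi < 0.0)) *dxi = 0.0;
}

void cvs_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    if (ip[0] < 10) error("nout should be at least 10");

    double T = p[0];
    double tau_lv = drv_tau(*t, p[1], T);
    double tau_rv = drv_tau(*t, p[2], T);
    double tau_la = drv_tau(*t, p[3], T);
    double tau_ra = drv_tau(*t, p[4], T);

    double V_lv = y[0], V_la = y[1], V_rv = y[2], V_ra = y[3];
    double V_ao = y[4], V_sa = y[5], V_sv = y[6], V_vc = y[7];
    double V_pa = y[8], V_pv = y[9];

    double P_lv = ventricle_p(V_lv, tau_lv, p + 5, T);
    double P_rv = ventricle_p(V_rv, tau_rv, p + 15, T);
    double P_la = atrium_p(V_la, tau_la, p + 25);
    double P_ra = atrium_p(V_ra, tau_ra, p + 30);

    double P_ao = p[56] * (V_ao - p[57]);
    double P_sa = p[58] * (V_sa - p[59]);
    double P_sv = p[60] * (V_sv - p[61]);
    double P_vc = p[62] * (V_vc - p[63]);
    double P_pa = p[64] * (V_pa - p[65]);
    double P_pv = p[66] * (V_pv - p[67]);

    double rho_conv = p[35];

    /* valves: mitral LA->LV, aortic LV->ao, tricuspid RA->RV, pulm RV->pa */
    double Q_mv = y[10], xi_mv = y[11];
    double Q_av = y[12], xi_av = y[13];
    double Q_tv = y[14], xi_tv = y[15];
    double Q_pu = y[16], xi_pu = y[17];
    double dQ_mv, dxi_mv, dQ_av, dxi_av, dQ_tv, dxi_tv, dQ_pu, dxi_pu;
    valve_rhs(P_la - P_lv, Q_mv, xi_mv, p + 36, rho_conv, &dQ_mv, &dxi_mv);
    valve_rhs(P_lv - P_ao, Q_av, xi_av, p + 41, rho_conv, &dQ_av, &dxi_av);
    valve_rhs(P_ra - P_rv, Q_tv, xi_tv, p + 46, rho_conv, &dQ_tv, &dxi_tv);
    valve_rhs(P_rv - P_pa, Q_pu, xi_pu, p + 51, rho_conv, &dQ_pu, &dxi_pu);

    /* resistive flows along the closed loop */
    double q_ao_sa = (P_ao - P_sa) / p[68];
    double q_sa_sv = (P_sa - P_sv) / p[69];
    double q_sv_vc = (P_sv - P_vc) / p[70];
    double q_vc_ra = (P_vc - P_ra) / p[71];
    double q_pa_pv = (P_pa - P_pv) / p[72];
    double q_pv_la = (P_pv - P_la) / p[73];

    ydot[0] = Q_mv - Q_av;          /* lv */
    ydot[1] = q_pv_la - Q_mv;       /* la */
    ydot[2] = Q_tv - Q_pu;          /* rv */
    ydot[3] = q_vc_ra - Q_tv;       /* ra */
    ydot[4] = Q_av - q_ao_sa;       /* ao */
    ydot[5] = q_ao_sa - q_sa_sv;    /* sa */
    ydot[6] = q_sa_sv - q_sv_vc;    /* sv */
    ydot[7] = q_sv_vc - q_vc_ra;    /* vc */
    ydot[8] = Q_pu - q_pa_pv;       /* pa */
    ydot[9] = q_pa_pv - q_pv_la;    /* pv */

    ydot[10] = dQ_mv; ydot[11] = dxi_mv;
    ydot[12] = dQ_av; ydot[13] = dxi_av;
    ydot[14] = dQ_tv; ydot[15] = dxi_tv;
    ydot[16] = dQ_pu; ydot[17] = dxi_pu;

    yout[0] = P_lv; yout[1] = P_la; yout[2] = P_rv; yout[3] = P_ra;
    yout[4] = P_ao; yout[5] = P_sa; yout[6] = P_sv; yout[7] = P_vc;
    yout[8] = P_pa; yout[9] = P_pv;
}
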