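/* Compiled right-hand side of the whole-body PBPK + ACAT gut system.
 *
 * Mirrors the reference R implementation in build_ode() exactly; the
 * two are cross-checked in the test suite. State layout (0-based):
 *   0-8   undissolved gut amounts (stomach..ascending colon), mg
 *   9-17  dissolved gut amounts, mg
 *   18    cumulative fecal loss, mg
 *   19    cumulative absorbed, mg
 *   20    cumulative gut first-pass extracted, mg
 *   21-32 tissue amounts: heart, brain, muscle, adipose, skin,
 *         bone_rest, kidney, reproductive, spleen, gut, liver, lung
 *   33    arterial blood, 34 venous blood
 *   35    cumulative urinary excretion, 36 cumulative hepatic elimination
 *
 * Parameter vector layout:
 *   0-8   1/transit_h per gut compartment
 *   9-17  luminal volumes, mL
 *   18    solubility, mg/mL
 *   19    dissolution rate coefficient
 *   20-28 Peff * ASF per gut compartment (1/h)
 *   29    fraction gut extracted
 *   30-41 tissue volumes, L
 *   42-53 tissue plasma flows, L/h (liver entry = hepatic artery)
 *   54-65 exit coefficients Rbp/Kp per tissue
 *   66    cardiac plasma output, 67 hepatic vein flow QH,
 *   68    hepatic artery flow, 69 hepatic clearance (capped),
 *   70    renal filtration clearance GFR*fup, 71 arterial volume,
 *   72    venous volume
 */
#include <R.h>

static double parms[73];

void sgltsim_initmod(void (*odeparms)(int *, double *))
{
    int n = 73;
    odeparms(&n, parms);
}

void sgltsim_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double *kt = parms, *gvol = parms + 9;
    const double cs = parms[18], kdiss = parms[19];
    const double *pa = parms + 20;
    const double gfrac = parms[29];
    const double *v_t = parms + 30, *q_t = parms + 42, *ek = parms + 54;
    const double co = parms[66], qh = parms[67], q_ha = parms[68];
    const double cl_hep = parms[69], cl_ren_u = parms[70];
    const double v_art = parms[71], v_ven = parms[72];

    double tr_u[9], tr_d[9], diss[9], af[9], ce[12];
    double absorbed = 0.0, qsys = 0.0, vsum = 0.0;
    int i;

    for (i = 0; i < 9; i++) {
        tr_u[i] = kt[i] * y[i];
        tr_d[i] = kt[i] * y[9 + i];
        diss[i] = kdiss * y[i] * (cs - y[9 + i] / gvol[i]);
        af[i]   = pa[i] * y[9 + i];
        absorbed += af[i];
    }
    ydot[0] = -tr_u[0] - diss[0];
    ydot[9] = -tr_d[0] + diss[0] - af[0];
    for (i = 1; i < 9; i++) {
        ydot[i]     = tr_u[i - 1] - tr_u[i] - diss[i];
        ydot[9 + i] = tr_d[i - 1] - tr_d[i] + diss[i] - af[i];
    }
    ydot[18] = tr_u[8] + tr_d[8];
    ydot[19] = absorbed;
    ydot[20] = gfrac * absorbed;

    {
        const double ca = y[33] / v_art, cv = y[34] / v_ven;
        const double portal = (1.0 - gfrac) * absorbed;
        for (i = 0; i < 12; i++)
            ce[i] = y[21 + i] / v_t[i] * ek[i];
        /* tissues perfused from arterial blood (all but liver, lung) */
        for (i = 0; i < 10; i++)
            ydot[21 + i] = q_t[i] * (ca - ce[i]);
        /* liver: hepatic artery + portal streams + absorbed drug */
        ydot[31] = q_ha * ca + q_t[8] * ce[8] + q_t[9] * ce[9] + portal
                   - (qh + cl_hep) * ce[10];
        /* lung between venous and arterial blood */
        ydot[32] = co * (cv - ce[11]);
        for (i = 0; i < 11; i++)
            qsys += q_t[i];
        ydot[33] = co * ce[11] - qsys * ca - cl_ren_u * ca;
        vsum = 0.0;
        for (i = 0; i < 8; i++)
            vsum += q_t[i] * ce[i];
        ydot[34] = vsum + qh * ce[10] - co * cv;
        ydot[35] = cl_ren_u * ca;
        ydot[36] = cl_hep * ce[10];
    }
    (void) neq; (void) t; (void) yout; (void) ip;
}
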