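#ifndef CYTOPATTERN_DIFFUSION_H
#define CYTOPATTERN_DIFFUSION_H

#include <vector>

// Advances the extracellular concentration profile by `dt` seconds and
// returns the domain length at the end of the interval.
// scheme 0: Lagrangian material coordinate xi = x/L(t) on [0,1];
//           dC/dt = (D/L(t)^2) d2C/dxi2 - kappa*C, L(t) = L_start*exp(kappa*t).
// scheme 1: Eulerian fixed grid of spacing dx_phys with literal constant
//           advection velocity u; dC/dt = D d2C/dx2 - u dC/dx.
// Dirichlet boundaries C[0] = C0, C[n-1] = 0. Explicit Euler with automatic
// substepping to satisfy the stability bound.
double advance_field(std::vector<double>& C, double L_start, double D,
                     double kappa, double C0, double dt, int scheme,
                     double u, double dx_phys, int min_substeps);

#endif
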