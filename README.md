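# smolsph

Meshless solver for diffusion-limited ligand binding: `smolsph` computes the
time-dependent Smoluchowski drift–diffusion equation around a reactive target
with a smoothed particle hydrodynamics (SPH) discretization, and extracts
bimolecular association rate constants from the steady flux across the
reactive boundary.

It is aimed at computational biophysicists who estimate protein–ligand
on-rates from continuum diffusion — the classic setting being
acetylcholinesterase, whose buried active-site gorge and strong electrostatic
steering make the encounter step rate-limiting — and who want
**imperfect-reactivity (Robin) boundaries** without building a boundary mesh.

## The model

The normalized ligand concentration $p(\mathbf{x},t)$ obeys

$$\partial_t p = \nabla\cdot D\left[\nabla p + p\,\nabla(\beta W)\right]$$

with diffusion coefficient $D$, potential of mean force $W$ (analytic radial
forms, or an electrostatic grid in OpenDX format sampled by trilinear
interpolation), bulk Dirichlet condition $p=p_\mathrm{bulk}$ on an outer
sphere, reflective molecular surfaces, and a reactive surface $\Gamma_a$
carrying either an absorbing condition $p=0$ or the reactive Robin condition
$\mathbf{n}\cdot\mathbf{J} = \alpha p$. The Robin condition is imposed by a
continuum surface reaction construction: a kernel-smoothed color function
supplies surface normals and a surface delta function, which converts the
boundary flux into a volumetric sink $-\alpha\,p_i\,s_i$ near the surface —
no surface triangulation at any point. The on-rate is the bulk-normalized
steady flux

$$k_\mathrm{on} = p_\mathrm{bulk}^{-1}\iint_{\Gamma_a}
  \mathbf{n}\cdot\mathbf{J}\,dS,$$

reported in Å³/µs and M⁻¹min⁻¹. Rate-versus-ionic-strength series can be
fitted to the Debye–Hückel limiting law
$k(I) = (k^0-k^H)\,10^{-1.18|Z_EZ_I|\sqrt{I}} + k^H$.

Everything is particle sums on a uniform cubic lattice (spacing `dx`, cubic
spline kernel, smoothing length $h = 1.3\,dx$), assembled once into a sparse
operator and integrated explicitly to steady state. See
`vignettes/smolsph-methods.Rmd` for the discretization, estimators, defaults
and limitations.

## Worked example

A reactive (Robin) shell: ligand diffusing between an outer bulk boundary at
$R_2 = 125$ Å and a reactive sphere of radius $R_1 = 50$ Å with reactivity
$\alpha = 10^3$ Å/µs, repulsive +1/+1 Coulomb interaction, $D = 78000$
Å²/µs, at lattice spacing 8 Å:

```r
library(smolsph)

fix <- make_fixture("sphere_robin", dx = 8)   # ~25k particles
res <- run_to_steady(fix$system, fix$pmf, fix$config)
k   <- kon_robin(res$state, fix$system, fix$config)

cat(sprintf("k_on = %.4g A^3/us = %.4g 1/(M min)\n", k, convert_rate(k)))
cat(sprintf("analytic: %.4g A^3/us; relative error %+.1f%%\n",
            fix$manifest$k_analytic, 100 * (k / fix$manifest$k_analytic - 1)))
```

```
k_on = 2.257e+07 A^3/us = 8.154e+11 1/(M min)
analytic: 2.107e+07 A^3/us; relative error +7.1%
```

The run reaches steady state after ~180 ns of simulated diffusion; the rate
sits 7% above the closed-form Robin rate at this coarse spacing and tightens
to +2% at `dx = 4`. The steady concentration profile agrees with the
analytic solution to a relative L2 error of 0.0088:

```r
sol <- fix$system$region == "solvent"
r   <- sqrt(rowSums(fix$system$positions[sol, ]^2))
l2_error(res$state$p[sol],
         steady_profile(pmin(pmax(r, 50), 125), fix$problem))
#> [1] 0.0088
```

Fitting a rate-versus-ionic-strength series to the Debye–Hückel limiting
law (here a noise-free synthetic series, recovered exactly):

```r
I <- c(0, 0.05, 0.1, 0.15, 0.2, 0.5, 0.67)          # ionic strengths, M
k <- dh_rate(I, k0 = 9.8, kH = 1.30, Z_E = 2.3)     # units of 1e11 / (M min)
fit_debye_huckel(I, k, kH_policy = "fixed", kH = 1.30)
#> Debye-Hueckel fit: k0 = 9.8, kH = 1.3 (fixed), Z_E = 2.3 (Z_I = 1)
```

Other entry points: `verify_spherical()` runs the full spherical benchmark
ladder and prints an error table; `build_reactive_patch()` +
`gorge_patch_spheres()` construct gorge-style reactive patches on an
obstacle; `read_dx_grid()` / `grid_pmf()` bring in electrostatic potential
grids; `inst/cli/smolsph.R` is a thin command-line front end
(`verify`, `run`, `fit`, `fixture` subcommands).

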