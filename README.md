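# longrangefit

Symmetry-adapted spherical-tensor multipole expansions of long-range
intermolecular interactions, and their staged nonlinear fitting to
scattered interaction energies.

## The problem

At large centre-of-mass separation $R$, the interaction energy of two
rigid molecules is governed by electrostatics, induction and dispersion,
an asymptotic series in $1/R$.  Getting this region right matters most
exactly where ab initio data are scarce and absolute energies are tiny —
cold collisions, scattering resonances, spectroscopy of van der Waals
complexes — and hand-deriving the system-specific expansion is laborious
and error-prone: the allowed terms depend on each molecule's point-group
symmetry, its charge, and whether the partners are distinct, identical
or mirror images.

`longrangefit` automates the whole chain for any pair of molecules of
any point-group symmetry (including cubic and icosahedral groups and
the continuous linear groups), neutral or charged, through 15th order:

* **Expansion generation.**  In the real spherical-tensor basis, the
  model is
  $E = E_{\mathrm{asym}} + \sum Q^A_t Q^B_u T_{t,u}
  - \tfrac12\sum \alpha^A_{t;t'} Q^B_u Q^B_{u'} T_{t,u}T_{t',u'}
  - \tfrac12\sum \alpha^B_{u;u'} Q^A_t Q^A_{t'} T_{t,u}T_{t',u'}
  - \sum D_{t,u;t',u'} T_{t,u}T_{t',u'}$,
  where the T-tensors $T_{t,u} \propto R^{-(l_t+l_u+1)}$ carry all
  distance and orientation dependence.  Which coefficients survive is
  decided numerically by group-averaged projection, so every point group
  is handled uniformly; identical or chiral partners get their
  coefficient sets tied exactly.
* **Fitting.**  Coefficients are determined from scattered energies by
  staged Levenberg–Marquardt least squares: terms enter order by order,
  each stage warm-starts from the last, and the asymptote is itself a
  fitted coefficient (no zeroing of the data).  Initialization comes
  from a linear prefit on the far long range; pinning one known
  coefficient (for example an ionic charge) cascades through the whole
  set.
* **Diagnostics and export.**  Term tables by interaction and order,
  per-stage RMSE/$R^2$ history, relative-error-weighted outlier
  detection, residual histograms, a LeRoy minimal-atom-pair-distance
  filter for strongly anisotropic molecules, coefficient serialization,
  and export of a standalone Fortran evaluator of the fitted potential.
* **Validation built in.**  Exact point-charge Coulomb oracles, a
  synthetic-data generator with symmetry-exact ground truths, and an
  independent Wigner-D reference path for the T-tensors.

## Worked example

A packaged synthetic dataset mimics a 4D ion + centrosymmetric-diatomic
complex (think CF⁺–H₂): 250 energies at 1·10⁻⁸ hartree noise, generated
from a known coefficient set
(`inst/extdata/ion_diatomic_synthetic*`).

```r
library(longrangefit)

ion <- lr_molecule("ionA", "Cinfv", charge = 1)
dia <- lr_molecule("diatomB", "Dinfh")
sys <- lr_system(ion, dia)

render_term_table(sys, "electrostatic", max_order = 6)
#>   order active                    terms
#> 1     1  FALSE
#> 2     2  FALSE
#> 3     3   TRUE              Q0(A).Q2(B)
#> 4     4   TRUE              Q1(A).Q2(B)
#> 5     5   TRUE Q0(A).Q4(B), Q2(A).Q2(B)
#> 6     6   TRUE Q1(A).Q4(B), Q3(A).Q2(B)

dat <- read_dataset(system.file("extdata", "ion_diatomic_synthetic.dat",
                                package = "longrangefit"), sys)
fit <- lr_fit(dat, sys, plan = lr_plan(c(elec = 5, ind = 5, disp = 6),
                                       seed = 1))
fit
#> <lr_fit> ionA -- diatomB (distinct)
#>   250 points, 4 stages, final caps 5/5/6
#>   final RMSE 9.0258e-09 hartree (0.001981 cm-1), R2 0.999983

fit$history[, c("stage", "elec", "ind", "disp", "n_par", "rmse", "r2")]
#>  stage elec ind disp n_par         rmse        r2
#>      1    3   3    3     2 1.082382e-06 0.7523878
#>      2    4   4    4     5 1.149721e-07 0.9972062
#>      3    5   5    5     7 9.343777e-09 0.9999815
#>      4    5   5    6    11 9.025799e-09 0.9999828
```

The leading charge–quadrupole model (stage 1) is clearly insufficient;
adding the fourth-order dipole–quadrupole and induction terms improves
the error by an order of magnitude, and by fifth order the fit sits at
the noise floor of the data — the characteristic rapid-improvement-then-
plateau progression of a healthy staged fit.  Because the ionic charge
is pinned, the partner's coefficients come out in a physical scale:

```r
coef(fit)[["QB.2.1"]]   # fitted quadrupole coordinate of the diatomic
#> [1] 0.02115602
# ground truth used by the generator: 0.0211872  (noise-limited recovery)

predict(fit, data.frame(R = 30, alpha = 0, beta_A = 0, beta_B = pi/2)) *
  lr_constants$hartree_cm1
#> [1] 11.35394      # cm-1, side-on approach at R = 30 bohr

export_evaluator(fit, "pot")   # writes pot.json + self-contained pot.f90
```

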