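---
title: "Methods: symmetry-adapted long-range expansions and their fitting"
author: "longrangefit"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: symmetry-adapted long-range expansions and their fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

At separations where the charge clouds of two rigid molecules no longer
overlap, their interaction energy is a convergent-in-practice asymptotic
series in inverse powers of the centre-of-mass distance $R$.
`longrangefit` represents that series in the real spherical-tensor form.
Each molecule carries multipole moments $Q_t$ indexed by Stone labels
$t = l m (c/s)$, polarizabilities $\alpha_{t;t'}$, and the pair carries
dispersion coefficients $D_{t,u;t',u'}$.  The geometric content of every
term is an interaction tensor $T_{t,u}(R,\Omega_A,\Omega_B) \propto
R^{-(l_t+l_u+1)}$, and the model energy is

$$E = E_{\mathrm{asym}}
 + \sum_{t,u} Q^A_t Q^B_u\, T_{t,u}
 - \tfrac12 \sum_{t,t',u,u'} \alpha^A_{t;t'} Q^B_u Q^B_{u'} T_{t,u}T_{t',u'}
 - \tfrac12 \sum_{t,t',u,u'} \alpha^B_{u;u'} Q^A_t Q^A_{t'} T_{t,u}T_{t',u'}
 - \sum_{t,t',u,u'} D_{t,u;t',u'}\, T_{t,u}T_{t',u'},$$

with all double sums taken in full (cross terms $u \ne u'$, $t \ne t'$
included) and terms grouped by the inverse-power order $n$ (a term
$\propto R^{-n}$).  The asymptote $E_{\mathrm{asym}}$ — the energy of the
separated monomers — is a fitted coefficient, so input data need not be
shifted to zero beforehand.

The expansion's coefficients are not computed from wavefunctions here;
they are free parameters determined by least squares from scattered
interaction energies, which is the package's purpose.  Spherical-tensor
coefficients are irreducible: through order $n$ the electrostatic series
carries $2n^2$ numbers against $3^n - 1$ in the redundant Cartesian form
(`spherical_coefficient_count()`, `cartesian_coefficient_count()`), which
is what makes high orders tractable at all.

## Conventions

* **Units.** All internal computation is in Hartree atomic units
  ($4\pi\epsilon_0 = 1$, lengths in bohr, energies in hartree) and
  radians.  File and CLI boundaries default to angstrom, degrees and
  cm$^{-1}$; the conversion constants live in `lr_constants`
  (1 hartree = 219474.6313632 cm$^{-1}$, 1 bohr = 0.529177210903 Å).
* **Real components.** Rank-$l$ components are ordered
  $l0, l1c, l1s, \dots, llc, lls$ with the convention $10 \mapsto z$,
  $11c \mapsto x$, $11s \mapsto y$: the real combinations are
  $Q_{lmc} = ((-1)^m Q_{l,m} + Q_{l,-m})/\sqrt2$ and
  $Q_{lms} = ((-1)^m Q_{l,m} - Q_{l,-m})/(i\sqrt2)$ with Condon–Shortley
  phases carried by the complex harmonics.  The convention is pinned by
  tests through `multipole_of_point_charges()` on explicit charge
  arrangements, not assumed.
* **Frames and angles.** The dimer frame has its origin at molecule A
  and its $z$-axis pointing at molecule B.  Orientations are z-y-z Euler
  angles; a molecule-fixed site $\mathbf r$ sits at
  $R_z(\alpha)R_y(\beta)R_z(\gamma)\,\mathbf r$ in the dimer frame.  Only
  the azimuth difference $\alpha = \alpha_A - \alpha_B$ is physical, and
  the free angle set follows the dimensionality class of the pair (atoms
  contribute no angles, linear molecules no $\gamma$), giving 1D
  (atom–atom) through 6D (two nonlinear molecules) problems.
* **Orientation per point group.** The principal axis lies along $z$, a
  $C_2$ axis along $x$ where the group has one, $\sigma_h$ is the $xy$
  plane (also the mirror of $C_s$), cubic groups carry their $C_3$ along
  $(1,1,1)$, icosahedral groups their $C_5$ along $(1,-\varphi,0)$ with
  $\varphi$ the golden ratio.  Two details are worth stating explicitly
  as this package's convention: for $D_{nh}$ with even $n$ the pair
  $\{C_2^x, S_n^z\}$ alone closes only to an order-$2n$ subgroup, so the
  principal $C_n^z$ is always included among the generators; and the
  roto-reflection axis used for $D_{nd}$ and $S_{2n}$ has order $2n$
  (an $S_n$ operation is not an element of $D_{nd}$).

## Symmetry adaptation

Which coefficients can be nonzero is decided numerically, not from
stored tables.  The action of any orthogonal operation $g$ on the
rank-$l$ real components is the matrix $\Delta^l(g)$ defined by
$S_t(g\mathbf r) = \sum_{t'}\Delta^l_{tt'}(g) S_{t'}(\mathbf r)$; it is
computed by evaluating the real solid harmonics on a fixed
well-conditioned set of directions and solving the linear system, so
improper operations pick up the parity factor $(-1)^l$ automatically and
no rotation-matrix phase conventions can leak in.  The surviving
multipole subspace at rank $l$ is the column space of the group-averaged
projector $P_l = |G|^{-1}\sum_g \Delta^l(g)$ (singular-value threshold
$10^{-8}$; group closure by fixed-point iteration with a matrix-hash
tolerance of $10^{-9}$).  For cubic and icosahedral groups the surviving
object is a fixed linear combination (for example the rank-4
$(40)/(44c)$ mix of $O_h$): the package therefore always works with a
basis of combination vectors carrying one free coefficient each, and
individual component values are reconstructed through that basis.  This
is the mathematically safe superset of a plain "nonzero component" list
and reduces to it whenever the basis vectors are pure components.  Basis
columns are deterministically oriented (first sizeable entry positive,
columns ordered by that entry's position) so exports are reproducible
byte for byte.

Continuous groups bypass enumeration with the closed-form rules
($C_{\infty v}$: only $m = 0$; $D_{\infty h}$: $m = 0$ and $l$ even;
atoms: rank 0 only); the test suite cross-checks them against a dense
cyclic-subgroup projector ($C_{37}$, exact for $l \le 15$).

Polarizability blocks $\{l_1, l_2\}$ are the invariants of the
(symmetrized, for $l_1 = l_2$) tensor product of the two rank
representations; dispersion patterns are products of the two molecules'
polarizability patterns, which is exact because $D$ is separately
symmetric in $(t,t')$ and $(u,u')$.  Exchange constraints for identical
molecules tie the two coefficient sets equal through exact identity maps
(the tied blocks are bitwise equal in fitted results); chiral partners
are tied through the numeric image of the $\sigma_{xz}$ mirror computed
from $\Delta^l$, so $s$-type components flip sign — the package's own
convention, verified by a mirror-plus-exchange invariance test of
assembled energies.

## Evaluation

For a geometry, the T-tensor block coupling rank $l_a$ on A with rank
$l_b$ on B is $T = W_A^\top X_0 W_B / R^{l_a+l_b+1}$, where $W$ are the
real rotation matrices of the two orientations and $X_0$ is the
geometry-independent dimer-frame coupling matrix built from a Wigner 3-j
symbol and a binomial-type prefactor (only $m_a' = -m_b'$ survives
because the dimer $z$-axis points from A to B).  The production path
caches $X_0$ per rank pair and the invariant bases per molecule; a
literal contraction through complex Wigner D matrices
(`t_tensor_direct()`) is kept as an independent reference and the two
agree to better than $10^{-10}$ relative — with near-zero degenerate
components compared against the natural block scale $R^{-(l_a+l_b+1)}$
rather than against themselves.  The decisive validation is physical:
truncating the electrostatic series for random point-charge fragments
reproduces the exact pairwise Coulomb energy with truncation error
decaying as $R^{-(N+1)}$ (log–log slopes within 0.3 of the analytic
value for $N = 2..5$ over $R \in [20, 200]$ bohr; the validation
fragments are kept compact, sites within half a bohr, so the first
missing order dominates over the whole fitted window).

For fitting, all T blocks for a dataset are precomputed once; evaluating
the model for a new coefficient vector is then dense linear algebra, and
the dispersion part is exactly linear in its parameters (its regressors
are precomputed too).

## Fitting strategy

`lr_fit()` proceeds in stages, one per overall order from the leading
allowed term up to the requested caps (separate caps per interaction
type; a term enters when its full order is within the cap).  Each stage
warm-starts from the previous optimum, activates newly allowed
coefficients at zero, and refits *all* active coefficients with
Levenberg–Marquardt least squares (`minpack.lm`, function/parameter
tolerances $10^{-12}$/$10^{-10}$, up to 1024 iterations per stage, and a
stage never accepts an iterate worse than its warm start) — so the
training RMSE is non-increasing across stages by construction.
Statistics per stage are the RMSE and $R^2$ about the data mean.

Initialization uses the portion of the data furthest into the long range
(largest-$R$ 25% by default; the fraction is configurable and immaterial
for clean data).  A linear least-squares prefit estimates the asymptote
together with the *lumped* coefficient products of the first two leading
orders — built directly in symmetry-adapted coordinates, so
symmetry-forbidden products never enter and the solve stays well
conditioned.  Per-molecule values are then back-assigned by a cascade:
a pinned charge determines the partner's moments from the
charge–multipole products, which determine further moments, then the
polarizability lumps; when nothing is pinned the leading product block
is split by a rank-one factorization with the sign gauge applied.  Two
guards matter in practice: lumped products are zeroed when the far-range
data is flat (the rank-one square root would otherwise amplify numeric
noise into spurious moments), and a zero multipole start is avoided
because the electrostatic model is bilinear — the origin is a saddle
where Levenberg–Marquardt cannot move.

**Gauge.**  For two distinct neutral molecules the data determine only
products: rescaling A's moments by $s$, B's by $1/s$ (and
$\alpha^A \to s^2\alpha^A$, $\alpha^B \to \alpha^B/s^2$) changes no model
energy, and a sign ambiguity remains even for identical molecules.  The
package resolves the *sign* deterministically — the leading multipole
coordinate of molecule A is oriented non-negative whenever no pinned
charge or fixed coefficient already decides it — and leaves the
continuous scale to the damped optimizer, since it is invisible in every
prediction.  `gauge_align()` maps a fitted set into the gauge of a
reference set for one-to-one comparison; fixing a single known
coefficient (`lr_plan(fixed = ...)`) removes the ambiguity entirely and
triggers the cascade of determinations through the remaining
coefficients.

Duplicate geometries are kept as separate points (a warning lists exact
duplicates carrying different energies).  Weights in the objective are
uniform; relative-error weighting is reserved for diagnostics.

## Diagnostics

`detect_outliers()` uses weighted residuals
$w_i = |r_i| / \max(|E_i - E_{\mathrm{asym}}|, \epsilon)$ with
$\epsilon$ set to $10^{-3}$ of the interaction-energy scale, which makes
the detector increasingly sensitive at large $R$.  Two refinements are
this package's own choices.  First, a point is flagged only when $w_i$
lies beyond $k$ robust scales (1.4826 MAD) above the median *and* its
raw residual is itself beyond $k$ robust scales of the residual
distribution — without the second condition, ordinary uniform noise at
the far points (where any fixed noise level is a large relative error)
would be reported on perfectly healthy fits.  Second, because least
squares is not robust, a gross outlier distorts the very fit it is
judged against; when absolute spikes beyond 10 robust scales are
present, the detector refits once without them and judges all points
against the clean model.  `residual_histogram()` exposes the balance of
the final residuals: an under-fitted model (for example an ion–diatomic
complex fitted with its leading electrostatic term while the strictly
negative induction energy is missing) leaves a strongly one-sided
distribution, while a sufficient expansion at the data's noise level is
narrow and symmetric.

The `leroy_filter()` admits a point into the fitting set when the
minimal distance over inter-fragment atom pairs is at least a threshold
(inclusive boundary — deterministic and easy to reason about), which
carves out the negligible-overlap region for strongly anisotropic
molecules beyond what a radial cutoff can do.

## The synthetic-data generator

`random_coefficients()` draws ground-truth sets with magnitudes decaying
as $2^{-l}$ per rank (configurable), so leading terms dominate the way
physically realistic multipole series do and recovery tests are not
dominated by unidentifiable high-order terms; the always-allowed
isotropic polarizability entries are kept away from zero so induction
carries realistic weight, and the asymptote is drawn at the
$10^{-4}$-hartree scale typical of supermolecular baselines.
`synthetic_dataset()` samples $R$ uniformly over a stated window
(defaults within the long-range regime) and orientations uniformly on
the sphere ($\cos\beta$ uniform), then adds i.i.d. Gaussian noise; an
option injects outliers as multiples of the local interaction energy.
`symmetric_point_charge_model()` builds orbit-symmetrized random charge
distributions that are *exactly* group invariant, the oracle for the
whole symmetry machinery.

What the generator does **not** emulate: correlated or
geometry-dependent noise from electronic-structure artifacts
(basis-set incompleteness, auxiliary-basis glitches in explicitly
correlated methods, local-correlation domain errors), realistic
magnitudes of any specific molecule's moments, or short-range exchange
repulsion.  Passing recovery tests therefore demonstrate the
correctness and identifiability of the machinery under its own model
assumptions — they do not certify accuracy for any particular real
complex, which depends on the quality and placement of the user's ab
initio data.

## Problem sizes and numerical choices

The shipped validation runs at sizes chosen to give clean signals:
convergence slopes from 8 logarithmic points over $R \in [20, 200]$
bohr; recovery over 20 random mixed-symmetry systems with orders up to
6 and $n = 8\times$ the free-parameter count (noiseless, pooled median
relative coefficient error below $10^{-5}$ — observed orders of
magnitude better); noise calibration at $n = 500$ with the fitted RMSE
within $[0.8, 1.2]\sigma$.  Rotation-matrix construction uses $2l + 7$
Fibonacci-sphere directions per rank (cached together with their
least-squares inverse); factorials are handled in log space
(`lgamma`), exact to about $10^{-14}$ relative through rank 15.

## Limitations

Rigid monomers in nondegenerate electronic states, two-body terms only,
no damping functions, and no Cartesian-form energy evaluation (the
Cartesian representation appears only in the coefficient-counting
comparison).  Ranks above 15 are not supported.  For two distinct
neutral molecules without any fixed coefficient, individual multipole
values are reported in an arbitrary scale gauge — only their products
are physical; fix one known coefficient to obtain physically scaled
values.  Chiral-partner dispersion ties require the mirror's image on
the pattern bases to be diagonal, which holds for the orientation
conventions above; an informative error is raised otherwise.
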