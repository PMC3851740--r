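---
title: "Methods: whole-tree vascular scaling and steady-state Münch transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-tree vascular scaling and steady-state Münch transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `treevasc`, the
assumptions behind them, the parameters that matter, and the numerical and
design choices that were genuinely open. The package follows a single
thread: from branch-level allometry, through pipe-model bookkeeping, to
whole-tree totals and a coupled xylem–phloem transport model.

## 1. Diameter allometry and the stem taper

Every tissue property is modelled as a power law of branch/stem diameter
$d$ (mm), and the taper links diameter to distance from the apex $x$ (m):

$$d = \gamma x^{\delta}, \qquad
  A_x = \alpha_1 d^{\beta_1},\; A_p = \alpha_2 d^{\beta_2},\;
  \rho_{N,x} = \alpha_3 d^{\beta_3},\; \rho_{N,p} = \alpha_4 d^{\beta_4},$$

with conduit radius and conduit-lumen fraction following
$r \propto d^{\beta_5}$ ($\beta_5 = \beta_6 = 0.25$, the conduit-taper
exponent of metabolic-scaling theory and phloem anatomy surveys) and
$\rho_c \propto d^{0}$ (a constant conducting fraction of the
cross-section). The built-in parameter sets for Scots pine and Eurasian
aspen (`scaling_params("pine")`, `scaling_params("aspen")`) carry the
field-measured bases and exponents plus leaf constants ($C_{ls}$, leaf
area per basal sapwood area; $\rho_{SLA}$, leaf mass per area;
$\rho_{N,leaf}$, leaf N%). Conduit bases $\alpha_5..\alpha_8$ are
relative: every conductance in the package is defined up to one common
factor, which cancels in all exponent results and is fixed only inside
the transport model by explicit calibration.

Two tissue densities (defaults: wood 400 kg m$^{-3}$, phloem
1000 kg m$^{-3}$) convert nitrogen mass fractions into absolute nitrogen
amounts. They scale the nitrogen totals linearly and cancel in every
fitted exponent.

## 2. Synthetic measurement generator

No segment-level measurement table is distributed with the package, so
`generate_segments()` emulates one: diameters are drawn log-uniformly
over 0.9–276.2 mm (the observed distribution is strongly right-skewed,
with a median near 4 mm; log-uniform reproduces that qualitative shape
with one fewer free parameter than a lognormal), and each response is its
species power law times a multiplicative lognormal factor with median 1.
The default noise level of each response is back-computed from the
reported $R^2$ of the corresponding published fit via
$\sigma^2 = E^2\,\mathrm{var}(\ln d)\,(1/R^2 - 1)$
(`noise_sdlog_for_r2()`), because residual variances themselves were not
reported — the generator is calibrated to the only dispersion statistic
available.

What the generator does *not* emulate: within-tree topology and
correlated sampling of segments from the same branch, measurement error
structure that differs between calipers and image analysis, and
periderm-specific quantities (whole-bark nitrogen is generated from the
living-bark law with a fixed 0.9 dilution factor and is labelled
synthetic). Passing recovery tests on these data therefore shows that
the estimators are correct and consistent under multiplicative noise,
not that they are robust to the correlation structure of real campaigns.
Where the independently fitted bark and phloem laws would cross at small
diameters, consistency ($A_p \le A_b$) is enforced by raising the bark
area, leaving the recovery-relevant responses exactly on their laws.

## 3. Fitting

`fit_power_law()` exposes both estimators that matter in practice:
raw-scale nonlinear least squares (Levenberg–Marquardt, initialised from
the log-scale estimate) as the default — matching how the original
coefficients were obtained — and log-scale OLS, which is the correct
estimator under multiplicative noise and the scale on which species are
compared. The two differ noticeably on heteroscedastic data; both are
reported rather than adjudicated. Species exponents are compared by
ANCOVA on the log scale (`log P ~ species * log d`) with pairwise
slope contrasts (unadjusted p-values, plus a Holm column).

## 4. Pipe-model bookkeeping and heartwood

The pipe model enters twice: summed sapwood cross-sectional area is
conserved across branching junctions, and leaf area is proportional to
basal sapwood area. The furcation number is therefore
$n(x) = A_{sw}(d(L)) / A_{sw}(d(x))$, anchored so that $n(L) = 1$ at the
tree base; without heartwood this is exactly $(L/x)^{\delta\beta_1}$.
Heartwood is modelled by capping the conducting sapwood at a maximum
radial depth $r_{sw,max}$ measured inward from the xylem surface
("the outermost 2 cm"): the sapwood is the annulus
$\pi\!\left(r^2 - (r - r_{sw,max})^2\right)$ with
$r = \sqrt{A_x/\pi}$ the equivalent xylem radius — derived from the
xylem area rather than from half the over-bark diameter, to avoid
counting bark. The annulus reading (rather than a maximum *disc* radius)
is the one consistent with the large-tree sapwood-volume scaling
$V_{sw} \sim L^{\approx 2}$: an annulus gives $A_{sw} \propto d$
asymptotically, a capped disc would give $A_{sw} \to$ const and
$V_{sw} \sim L$.

A note on anchoring: one could instead anchor sapwood conservation at
the crown (so that a heartwood-forming tree keeps the crown's furcation
numbers and has $n(L) > 1$ at the base). That reading makes heartwood
*increase* the amount of phloem at a given height, but it is
incompatible with the leaf-nitrogen and sapwood-volume height scalings
this package reproduces (both require leaf area and total sapwood to
follow the *basal* sapwood area), so base anchoring is used throughout
and $n(L)=1$ is an invariant.

Axial profiles (`axial_profiles()`) evaluate, on a grid over
$[L_0, L]$, the summed areas $n A$, nitrogen line densities (g m$^{-1}$)
and relative conductivities $k = n\,A\,\rho_c\,r^2$ (Hagen–Poiseuille
proportionality). $L_0 = 0.1$ m by default: below that distance from the
apex (diameters $\lesssim 2$ mm) the allometries are extrapolation, so
integrals start there; for aspen phloem nitrogen the exponent
$\beta_4 = -0.80$ is steep enough that the integrand is dominated by the
smallest branches, and $L_0 = 1.0$ m is used for that quantity only.

**Numerical choices.** Quadrature grids are log-spaced (the integrands
are near power laws, so log spacing equidistributes relative error);
whole-tree totals use the composite trapezoid rule with grid doubling to
a $10^{-4}$ relative tolerance, cross-checked against closed forms (all
no-heartwood integrals have exact antiderivatives) to better than 0.1%.
*Fitted axial exponents*, by contrast, are computed on a linearly spaced
grid: for profiles that are not exact power laws (the heartwood
scenarios) the fitted slope depends on the grid weighting, and equal
weight per metre of transport path is the physically meaningful choice —
it is also the weighting under which the capped-sapwood phloem profile
of a 10 m pine fits $A_{p,tot} \sim x^{-0.46}$ rather than the $-0.60$
a log-spaced fit would give.

## 5. Whole-tree height scaling

`scaling_exponent()` fits $\log(\text{total})$ against $\log L$ over a
stated height range. Whole-tree scaling is close to, but not exactly,
allometric, so the fitted exponent is range-dependent and the range is a
recorded parameter of every fit. Defaults: 1–25 m for the no-heartwood
scenario, where the totals are near-exact power laws and the choice is
almost immaterial (xylem volume fits $L^{2.95}$ against an asymptote
$\delta\beta_1 + 1 = 2.92$). The capped-sapwood scenario is strongly
non-allometric below ~10 m (the cap only binds once the basal xylem
radius exceeds 2 cm, at a height of about 2.6 m, and the annulus only
approaches its asymptotic $A_{sw}\propto d$ behaviour well above that),
so heartwood-scenario exponents are fitted over 10–100 m, the regime the
published sapwood-volume exponent of ~1.99 describes; over 5–30 m the
same quantity fits with an exponent of ~2.1, which is worth remembering
when comparing numbers fitted over unstated ranges.

The sensitivity sweep draws $\beta_1..\beta_6$ and $\delta$ uniformly
within ±25% of their base values and $r_{sw,max}$ log-uniformly over
2–200 cm (log-uniform because the quantity spans two decades and acts
multiplicatively; a linear-uniform draw would concentrate 90% of the
mass above 20 cm), normalises every curve at the 10 m reference tree,
and reports pointwise min/max envelopes. The base curve is the
unperturbed parameter set at the centre of the sapwood-depth range.

## 6. The steady-state transport model

The transport model couples the two vascular streams on a discretised
root-to-apex path:

* **Xylem**: all transpiration $E$ is extracted at the apex (in the
  aggregated path coordinate, every branch tip sits at small $x$, so
  lumping the canopy at the apex node is the model-consistent reading),
  water enters at the base at soil water potential; segment flow is
  $K_{x,seg}\,(\Delta\psi - \rho g\,\Delta z)$.
* **Equilibrium coupling**: local water-potential equilibrium
  $P = \psi_x + RTc$ (van 't Hoff, osmotic coefficient 1) at every node.
* **Phloem**: volume flow down a segment is
  $K_{p,seg}\,(\Delta P + \rho g\,\Delta z)/\eta_{rel}(c)$ — gravity
  aids the downward stream — and carries the steady-state sugar flux
  $F(x)$ with the segment-midpoint concentration. $F(x)$ is known in
  advance from the boundary conditions: constant and equal to the
  loading rate for root unloading, declining linearly to zero for
  unloading distributed evenly per unit path length.

Because loading and unloading *rates* are prescribed, the pressure and
concentration *differences* are fully determined but the absolute
concentration level is not: some closure must pin it. The closure used
here prescribes the sugar concentration at the unloading end of the path
(`c_sink`, default 300 mol m$^{-3}$, a typical sink-tissue sucrose
concentration); concentrations are then solved segment-by-segment from
the sink upward, each segment being a scalar root-find taken on the
physical low-concentration branch. A conserved-total-sugar closure
(prescribing the volume-weighted mean concentration) was prototyped and
rejected: for realistic means it drives the basal concentration to zero.
The marching solve is exact per segment (no global iteration is needed
for this boundary structure), deterministic, and second-order accurate
through the midpoint advection rule; doubling the grid changes the
turgor difference by well under 1%.

Sap viscosity uses an exponential-in-mass-fraction correlation for
aqueous sucrose, $\eta = \eta_w(T)\exp\!\big(4.68\cdot 0.956\,w/(1 -
0.956\,w)\big)$, $w$ the sucrose mass fraction (about 2× water at 15%
w/w, about 14× at 38%). It is exposed as a pluggable function on the
boundary object. The steep rise at high concentration is what makes tall
trees with low phloem conductance fail to reach a steady state: beyond a
critical concentration the transportable flux $\propto c\,/\,\eta(c)$
declines, the per-segment root-find loses its solution, and the solver
raises a diagnostic non-convergence condition reporting where the flux
became unsustainable.

**Absolute scales and calibration.** Relative conductivity profiles are
given absolute scales in two steps. The xylem scale is set so that the
10 m reference tree transpires at 1 mmol m$^{-2}$ s$^{-1}$ of leaf area
while holding leaf water potential at −2.0 MPa (isohydric behaviour);
that scale is then a material constant across heights, and transpiration
at other heights follows from
$E = K_{x,tot}(L)\,(\psi_{soil} - \psi_{leaf} - \rho g L)$.
Photosynthesis is $E/\mathrm{WUE}$ (WUE = 250 mol H$_2$O per mol CO$_2$)
and sucrose loading is that divided by 12 carbons. The phloem scale is
calibrated so the 10 m root-unloading reference tree shows a leaf-root
turgor difference of 0.7 MPa (log-scale bisection to $10^{-3}$ MPa),
separately per heartwood scenario. Both the loading magnitude and the
conduit base units cancel out of dimensionless results such as the
optimal allocation exponent — a property the test suite asserts.

## 7. The three simulations

1. *Axial gradients*: the calibrated 10 m pine shows the xylem potential
   dropping steeply near the apex (where the summed conduit
   cross-section is smallest) and the phloem turgor drop shifted toward
   the base, the more so the more apex-concentrated the phloem
   conductivity is (no-heartwood > 2 cm cap) and the more basal the
   unloading (root > distributed).
2. *Optimal allocation*: `optimize_phloem_allocation()` redistributes
   $A_{p,tot}(x) \propto x^\theta$ at exactly conserved whole-tree
   phloem volume (the per-area conduit taper keeps its baseline
   profile), re-solves the steady state over a 13-point $\theta$ grid
   spanning $[-1, 0.5]$, and refines the minimiser by golden-section
   search to $|\Delta\theta| < 0.005$. With the defaults the optimum is
   $\theta \approx -0.27$ for root unloading and $\approx -0.48$ for
   distributed unloading: phloem belongs toward the apex, more so when
   sugars are consumed along the way, and far less steeply than the
   measured allocation ($x^{-0.69}$/$x^{-0.46}$). The $\Delta P(\theta)$
   landscape is flat near its minimum (variation below ~10% over
   $\pm 0.2$ in $\theta$), so the precise optimum is sensitive to model
   internals that the available sources do not pin down — the sink
   concentration, the viscosity law, and the taper kept under
   reallocation each move it by up to ~0.1. Earlier reports of this
   experiment place the optima at −0.17 and −0.33; our defaults, chosen
   on physical grounds rather than to match, land below both, with the
   same sign, the same ordering between unloading modes, and the same
   qualitative conclusion.
3. *Height sweep*: under the isohydric rule, transpiration per unit leaf
   area falls with height as gravity erodes the driving potential; the
   turgor difference needed to export the assimilate stream rises only
   sublinearly with height (and falls again in tall trees, where gravity
   both throttles gas exchange and assists the phloem), stays near
   constant in the capped-sapwood scenario, and collapses entirely —
   no steady state, viscosity runaway — only for low initial phloem
   conductance in tall no-heartwood trees.

## 8. Problem sizes and limitations

Default resolutions (axial profiles 200–256 points, transport grids
61–121 nodes, 16 heights per scaling fit, 1000 draws in the full
sensitivity sweep) were chosen so that every reported digit is converged:
halving any of them changes no headline number at its printed precision.
The test suite runs the sweep at reduced draw counts; the analysis
drivers run it in full.

Known limitations: no explicit 3-D architecture or within-ring conduit
distributions; a single aggregated transport path (no per-branch
hydraulics); leaves lumped at the apex; no transient dynamics, embolism,
starch buffering, or active loading mechanisms; heartwood nitrogen
handled as a scenario fraction rather than a turnover model; and the
transport closure discussed in §6, which is the main structural
uncertainty inherited from the underlying model family.
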