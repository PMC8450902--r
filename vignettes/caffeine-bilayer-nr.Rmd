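---
title: "Locating a guest molecule in a supported lipid bilayer by multi-contrast neutron reflectometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating a guest molecule in a supported lipid bilayer by multi-contrast neutron reflectometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrbilayer)
```

## The problem

A supported lipid bilayer (SLB) is a single phospholipid membrane adsorbed
on a polished silicon crystal. When a small amphiphilic solute such as
caffeine is co-deposited with the lipids, the questions are *where* in the
membrane it sits and *how much* of it is there. Specular neutron
reflectometry (NR) answers both: the reflectivity $R(Q)$ of the
solid/liquid interface encodes the scattering length density (SLD) profile
$\rho(z)$ normal to the surface, and isotopic contrast variation
(re-measuring the same sample in D$_2$O, H$_2$O and intermediate mixtures)
breaks the degeneracies of a single measurement. A quartz-crystal
microbalance with dissipation monitoring (QCM-D) independently verifies
that vesicle fusion produced a complete, rigid bilayer before the neutron
experiment is interpreted.

`nrbilayer` implements this analysis chain end to end: SLD arithmetic,
slab-model construction, an exact reflectivity kernel, multi-contrast
co-refinement with $\chi^2$-profiled uncertainties, conversion of fitted
SLDs into guest composition, and Sauerbrey analysis of QCM-D traces. A
synthetic-data generator stands in for the instruments so that every stage
is testable.

## Scattering length density arithmetic

The SLD of a molecule of formula $\{n_i\}$ occupying volume $V$ is
$\rho = \sum_i n_i b_i / V$, with bound coherent scattering lengths $b_i$
from the standard Sears tabulation, stored internally so no download is
needed. Deuterium is a distinct symbol (`D`).

```{r}
compute_sld("C8H10N4O2", 194)   # caffeine
compute_sld("C32H64", 923)      # POPC acyl chains (carbonyls on the head)
compute_sld("C10H18NO8P", 332)  # phosphocholine + glycerol + carbonyls
```

The POPC partition convention places both carbonyl groups in the headgroup
(head C$_{10}$H$_{18}$NO$_8$P at 332 Å$^3$, tails C$_{32}$H$_{64}$ at
923 Å$^3$); it is the only split consistent with the reference tail SLD of
$-0.29\times10^{-6}$ Å$^{-2}$ at that volume. The shipped materials
database pins the customary literature values (head 1.79, tails $-0.29$,
caffeine 3.3, d31 tails 3.16, all $\times 10^{-6}$ Å$^{-2}$) while keeping
the formula-derived number alongside (`sld_computed`). Two such gaps are
worth noting: the headgroup computes to 1.81 vs the quoted 1.79, and the
d31 tails compute to 3.21 vs the quoted 3.16; both stem from volume/b-value
conventions in the source tabulations, are at the 1–2% level, and are far
below the contrast between the components. Solvent SLDs interpolate
linearly between fixed endpoints ($-0.56$ for H$_2$O, $6.35$ for D$_2$O) so
that the standard contrasts come out exactly: silicon-matched water (38%
D$_2$O) at 2.07 and four-matched water (66%) at 4.0.

## The slab model and its molecular constraints

The interface is modelled as slabs, in fixed order from the silicon:
native oxide, a water gap, inner headgroups, two hydrophobic leaflets,
outer headgroups. Each slab carries thickness, dry-component SLD, water
volume fraction and an interfacial roughness; the effective SLD is
$\rho_{\rm dry}(1-f) + \rho_{\rm solvent} f$. The bilayer is symmetric
about the core midplane (both leaflets share $t_H, t_C, \rho_H, \rho_C,
f_H, f_C$) and one roughness $\sigma$ is shared by all interfaces — the
parameterisation under which the reference structural values were obtained.
Roughness is the Gaussian width of an error-function transition,
$\mathrm{erf}\!\big((z-z_0)/(\sigma\sqrt2)\big)$.

For a pure bilayer, molecular constraints tie the slabs together: with an
anhydrous core ($f_C = 0$) and one lipid per leaflet unit cell, the area
per lipid is $A = V_{\rm tails}/t_C$ and headgroup hydration follows from
volume filling, $f_H = 1 - V_{\rm head}/(A\,t_H)$:

```{r}
apply_molecular_constraints(t_C = 15.0, V_tails = 923,
                            V_head = 332, t_H = 6.8)
```

For guest-loaded bilayers these constraints are deliberately *disabled* —
the guest changes packing and SLDs in ways the constraint algebra does not
describe — and the slab parameters float freely, seeded from the pure-lipid
fit. The water gap is modelled as a slab of pure solvent of fitted
thickness. Substrate parameters (oxide thickness/SLD/hydration) are fixed
from a bare-substrate measurement; the defaults (12 Å, 3.47, 0.12, and a
3 Å water gap) are typical of polished Si(111) with native oxide.

## Reflectivity engine

`parratt_reflectivity()` evaluates the exact dynamical reflectivity by the
Parratt recursion, run bottom-up from the backing medium (numerically
stable for thick slabs), with Névot–Croce factors
$\exp(-2 k_j k_{j+1} \sigma_j^2)$ damping each Fresnel coefficient and the
evanescent branch chosen below the critical edge
$Q_c = 4\sqrt{\pi\,\Delta\rho}$. The kernel is compiled (Rcpp). Two
independent checks guard it: an Abeles transfer-matrix oracle coded
separately in the test suite (agreement to ~$10^{-13}$ relative on random
stacks), and a microsliced-profile path (`microslice_reflectivity()`) that
renders the rough profile into 0.5 Å zero-roughness slices. The
Névot–Croce factor is a small-$Q\sigma$ approximation: against the
microsliced exact result it agrees within 0.5% for $Q\sigma \lesssim 0.9$
(for the fitted roughness of ~6 Å that covers $Q \le 0.15$ Å$^{-1}$) and
drifts to at most ~1.2% at the top of the measured range — far below the
counting noise there.

Instrumental resolution is a Gaussian kernel of width
$\sigma_Q = (dQ/Q)\,Q$ with $dQ/Q = 5\%$ by default (typical time-of-flight
operation; the true wavelength-dependent resolution of a two-angle
measurement is deliberately not modelled). The convolution uses 11-point
Gauss–Legendre quadrature over $\pm3.5\sigma$ with truncated-Gaussian
weights; away from the critical edge it agrees with a converged
quadrature to better than $10^{-4}$ relative, with percent-level ripple
confined to the kink at the edge itself (the `n_nodes` argument raises
the order where that matters). The
measurement model is completed by a per-curve scale factor and constant
background, $R_{\rm obs} = s\,R + b$.

## Co-refinement and uncertainties

All contrasts of one sample are fitted simultaneously:
$\chi^2 = \sum_{c}\sum_i \big(R_{{\rm model},ci} - R_{{\rm data},ci}\big)^2
/ dR_{ci}^2$. Scale and background are free per-contrast nuisance
parameters by default (bounds 0.5–1.5 and 0–$10^{-5}$), and the solvent
SLD of each contrast may optionally float within $\pm0.2\times10^{-6}$
Å$^{-2}$ to absorb imperfect exchange — off by default, since the
generator exchanges solvents perfectly. Optimisation maps the free
parameters to a unit box and minimises the weighted residual vector with
bounded Levenberg–Marquardt (`minpack.lm`), restarted from its own
solution until the deviance stops improving; least squares with a
finite-difference Jacobian converges in tens of iterations where generic
quasi-Newton search needs thousands in the long curved valley that
correlated reflectometry parameters produce (a `nlminb` path remains for
scalar objectives). `max_starts` adds uniformly drawn extra starts,
seeded and reproducible; every stochastic entry point takes an explicit
seed.

Parameter uncertainties use $\chi^2$ profiling: each free parameter is
scanned away from the optimum, re-optimising all others, until $\chi^2$
rises by exactly 1 — the 68% interval in the Gaussian limit (the test
suite verifies equality with analytic errors on a linear fixture). A side
that reaches its bound first is reported open. $\Delta\chi^2 = 1$ on the
raw (not reduced) $\chi^2$ is used.

## From SLDs to composition

Caffeine in the hydrophobic core raises the fitted tail SLD from the pure
value $\rho_{\rm host}$ to $\rho_{\rm mix}$; inverting linear volume-
fraction mixing of the dry components gives
$\phi = (\rho_{\rm mix}-\rho_{\rm host})/(\rho_{\rm guest}-\rho_{\rm host})$,
and molecular volumes convert $\phi$ to a mole ratio
$r = (\phi/V_{\rm guest})\,/\,((1-\phi)/V_{\rm tails})$, mole percent
$100r/(1+r)$ and lipids-per-guest $1/r$. The host unit is the tail volume
(923 Å$^3$) because the guest resides in the core and the core was fitted
anhydrous; using the whole-lipid volume (1256 Å$^3$) is exposed as an
option. The guest's share of the *total* bilayer volume is
$r V_{\rm guest}/(V_{\rm lipid} + r V_{\rm guest})$.

```{r}
composition_report(reference_bilayer("popc_caffeine"))
```

A note on error propagation: the first-order derivative
$\partial\phi/\partial\rho_{\rm mix} = 1/(\rho_{\rm guest}-\rho_{\rm host})
\approx 0.28$ per $10^{-6}$ Å$^{-2}$ means a $\pm0.05$ SLD uncertainty
maps to $\pm1.4\%$ absolute in $\phi$ — *larger than $\phi$ itself* — and
to roughly $\pm6$ mol%. A sub-mol% uncertainty on the loading therefore
corresponds to a $\pm0.1\%$ uncertainty on $\phi$, i.e. to an effective
tail-SLD uncertainty of a few $10^{-3}$, which is what a four-contrast
co-refinement with shared structural parameters can deliver even when the
single-parameter profile is wider. `composition_report()` propagates
whatever SLD standard deviation the caller supplies, at first order, and
reports the resulting `*_sd` fields; it does not second-guess it.

Component-group volume-fraction profiles re-express the same structure per
chemical species: each component is a box smoothed by two symmetric
error-function edges (headgroup boxes of amplitude $1-f_H$, a tail box of
amplitude $1-f_C$, an optional guest step of width $w$ carved out of the
tail component), water fills the complement to 1 everywhere, and
$\mathrm{SLD}(z) = \sum_i \phi_i\rho_i + \phi_w\rho_{\rm solvent}$. The
test suite verifies normalisation to $10^{-12}$, volume bookkeeping
($\int\phi_{\rm tails}\,A\,dz = 2V_{\rm tails}$), and agreement with the
slab rendering of the same structure. The exact shape of the guest
distribution is not identifiable from the data — only its confinement to
the core is — so the geometry is exposed as input rather than asserted.

## QCM-D module

The Sauerbrey relation $\Delta m = -C_f\,\Delta F_n/n$ with
$C_f = 17.7$ ng cm$^{-2}$ Hz$^{-1}$ (5 MHz sensor) converts normalised
frequency shifts of a *rigid* film to areal mass; rigidity is recognised
by overlapping overtones (spread $\le 1$ Hz by default) and low
dissipation ($\le 1\times10^{-6}$). `detect_plateau()` segments a trace
into quasi-stationary stretches (|slope| $\le 0.1$ Hz/min over $\ge
10$ min, slope estimated by local regression over a 2 min window), and
`qcmd_analyze()` combines the pieces into a classification: a final
plateau near $-25$ Hz that passes the rigidity check is a formed SLB
(mass $\approx 442$ ng/cm$^2$); a record whose final plateau returns to
the initial baseline is a reversible excursion. These defaults classify a
textbook vesicle-fusion run as "SLB formed, rigid" and a
concentrated-solute incubation that rinses back to baseline as
"reversible"; all thresholds are arguments.

## The synthetic-data generator

`generate_nr_dataset()` emulates a four-contrast solid/liquid NR
measurement from known ground truth: D$_2$O, 4MW, SiMW and H$_2$O
contrasts, $Q$ from 0.008 to 0.28 Å$^{-1}$ on a 120-point logarithmic grid
(approximating time-of-flight binning), 5% $dQ/Q$ smearing, scale 1,
background $5\times10^{-7}$, and multiplicative Gaussian noise
$\sigma = 0.02\,R + b/3$ whose width is recorded in the `dR` column.
These defaults are the study conditions; the 2% relative noise stands in
for counting statistics after reduction (Poisson counts are deliberately
not simulated), and the background floor is typical of a reflectometer
operating at a solid/liquid cell. What the generator does *not* emulate:
wavelength-dependent resolution, imperfect solvent exchange, sample
misalignment, off-specular background structure. Passing recovery tests
on these data therefore demonstrates correctness of the estimator chain,
not robustness to every systematic of a beamline.

`generate_qcmd_trace()` produces piecewise-exponential relaxations toward
per-stage targets (2 s sampling), with overtone splitting and elevated
dissipation during soft stages; `qcmd_schedule_slb()` mirrors a successful
fusion run (adsorption overshoot, osmotic-shock rupture to $-24$ Hz at
$t = 12.5$ min, stable rinse) and `qcmd_schedule_reversible()` a
reversible incubation.

## Parameter identifiability and recovery, with problem sizes

The test suite exercises the chain at sizes chosen to keep the default run
in minutes: oracle equivalence on 100 random stacks at 200 $Q$ points;
noiseless round-trip fits (4 contrasts × 60 points) recovering the
generating parameters to better than $10^{-3}$; a 20-replicate recovery
study at the full study conditions (4 × 120 points, 2% noise, start at the
guest-free parameter set, all seven Table-style structural parameters plus
the water gap and eight nuisance parameters free); and 20-replicate
profile-interval coverage. Fits weight noiseless data with the standard
2% uncertainty model — weights do not move a $\chi^2 = 0$ minimum, but
they keep the objective well scaled.

Two honest observations from the recovery study belong in any reading of
the results. First, with sixteen free parameters the 2%-noise likelihood
surface has a long, curved, nearly-degenerate valley: per-replicate
estimates of $t_H$ and $t_C$ scatter with a standard deviation of
~0.5 Å — consistent with the ±0.2–0.4 Å intervals quoted for the
reference analysis — and solutions over 1 Å from the truth can fit
individual noise realisations as well as the truth does, while the
ensemble means recover the truth to ~0.1 Å and the tail SLD to
better than 0.01. Second, the $\Delta\chi^2 = 1$ construction is
asymptotic: its coverage is near nominal (0.65 observed over 20
replicates) on a well-conditioned three-parameter version of the problem,
but in the full sixteen-parameter fit the boundary parameter ($f_C$ at
its physical bound of 0) and the degenerate valley make the intervals
undercover — the coverage property is therefore tested at the reduced
size, and full-size intervals should be read as lower bounds on the
uncertainty.

## Numerical choices and degenerate inputs

* SLD units are $10^{-6}$ Å$^{-2}$ at every interface of the package; fm
  and Å$^3$ conversions happen inside `compute_sld()`.
* Zero-roughness transitions degrade gracefully to exact steps; zero
  thickness slabs and zero-contrast slabs leave the reflectivity unchanged
  to machine precision (tested).
* Reflectivity is clipped to $[0, 1]$; the Névot–Croce factor can
  marginally exceed 1 near total reflection with large roughness.
* $dQ/Q = 0$ bypasses the smearing code path entirely.
* Profile-interval bisection resolves to 0.5% of the half-width; a bound
  reached before the $\Delta\chi^2 = 1$ crossing flags the side as open
  rather than inventing a finite limit.
* Curve files store full double precision (`%.17g`) so write→read round
  trips are bit exact; printed reports round to the conventional figures.

## Limitations

Asymmetric leaflets, multilamellar stacks, tilted-phase models,
off-specular scattering, polarised neutrons, absorption, viscoelastic
(Voigt) QCM-D modelling and Bayesian posterior sampling are out of scope.
Model comparison beyond $\chi^2$ inspection (e.g. of alternative guest
locations) is supported only insofar as competing `fit_problem`s can be
fitted and their $\chi^2$ compared.
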