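---
title: "Ion-pair and salt-bridge dynamics from MD trajectories: models and methods"
author: "ionpairdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-pair and salt-bridge dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ionpairdyn)
```

ionpairdyn implements the trajectory-analysis battery used to characterize a
solvated salt bridge (an Arg–Asp-type pair of oppositely charged side
chains) interacting with simple dissolved salts: water reorientation
dynamics, intermittent ion-pair lifetimes, radial coordination structure,
regional ion densities, and the mean force along a forced-dissociation
coordinate. Because production MD output at the hundreds-of-nanoseconds
scale is not practical to ship or regenerate, every analysis is validated
against seeded synthetic trajectories with closed-form ground truth; this
vignette explains each model, its assumptions, the tunable parameters, and
the deliberate numerical choices.

All internal units are nm (length), ps (time), kJ/mol (energy) and
kJ mol⁻¹ nm⁻¹ (force). Distance criteria quoted in pm in the ion-pairing
literature are converted at the configuration boundary (300 pm = 0.30 nm).
Atom indices are 1-based, following R convention; file formats keep their
native numbering on write. Only orthorhombic periodic boxes are supported —
triclinic input is rejected rather than half-supported — and frames are
never wrapped on read, so intra-molecular vectors remain continuous;
wrapping happens lazily inside every distance computation via the
minimum-image convention (valid up to half the smallest box edge, which all
range parameters are checked against).

## Water reorientation

The stiffness of the hydrogen-bond network is probed by the reorientation
of molecular unit vectors (dipole or OH-bond vectors). `vector_acf()`
computes the rank-1 correlation

$$C_1(t) = \langle \hat u(t_0) \cdot \hat u(t_0 + t) \rangle,$$

pooled over all molecules and *all* time origins (maximal averaging;
per-lag origin counts are reported so standard errors can be formed).
Rank 1 rather than rank 2 is used because the dipole-vector convention of
common trajectory-analysis tools is P₁; the choice is recorded in the
output metadata of the pipeline stage. `max_lag` defaults to half the
series length, beyond which origin statistics degrade.

Two implementations coexist deliberately: the default zero-padded-FFT
route (one inverse transform of the summed power spectrum, processed in
column chunks to bound memory) and a literal double loop over lags and
origins (`method = "direct"`). They agree to ~10⁻¹² and serve as mutual
oracles; the tests assert that equality.

`fit_exponentials()` fits $\sum_i a_i e^{-t/\tau_i}$ (1 or 2 components)
by unweighted least squares on C(t) — not on log C, which would overweight
the noisy tail. Initialization is deterministic: a log-linear fit of the
window tail seeds the slow component, the early-time residual seeds the
fast one, and Levenberg–Marquardt refines. For a salt ensemble,
`time_constant_ratio()` reports the slowest constant relative to a
mono-exponential pure-water reference; it refuses a bi-exponential
reference because the ratio is only meaningful against a single reference
process.

The synthetic substrate (`gen_rotor_ensemble()`) evolves unit vectors by
isotropic rotational diffusion: per step, two Gaussian rotations of
variance $2 D_r \Delta t$ about axes orthogonal to the current vector.
This scheme has the closed form $C_1(t) = e^{-2 D_r t}$ exactly in the
$\Delta t \to 0$ limit, and the precondition $D_r \Delta t \le 0.05$
keeps the discretization error far below sampling noise. Vectors are
renormalized each step; without that, floating-point drift feeds back
through the axis construction and grows exponentially over long runs. A
`slow_fraction` of rotors diffusing with `d_rot_slow` emulates the
ion-affected water subpopulation that produces the bi-exponential decay
and the ~5× slowdown of the slow constant.

## Intermittent ion-pair lifetimes

Aggregates (ion pairs, ion–water and water–amino-acid contacts) are
defined by a pure distance criterion: pair p is bonded at frame t iff its
minimum-image distance is ≤ cutoff (the boundary counts as bonded — ties
are measure-zero in real data but the convention must be fixed for
reproducibility). All a×b pairs of the two site groups are enumerated;
there is no nearest-partner exclusivity. The shipped default profile
(`default_pair_criteria()`) covers the six standard pairings with cutoffs
at the first RDF minima: 0.30 nm for cation–O(Asp), 0.33 nm for
anion–H(Arg), anion–H(water) and cation–O(water), 0.25 nm for
H(water)–O(Asp) and O(water)–H(Arg).

The intermittent (Rapaport-style) ACF

$$C_{\text{raw}}(t) = \frac{\langle b(t_0)\, b(t_0+t) \rangle}{\langle b \rangle}$$

lets bonds break and re-form between the correlated times, which makes it
far less noise-prone than its continuous counterpart (deliberately not
implemented). In a finite system C_raw does not decay to zero but to the
*ensemble average* p — the probability of re-observing the bond at random.
The correction applied here is the affine map

$$C_{\text{corr}}(t) = \frac{C_{\text{raw}}(t) - p}{1 - p},$$

i.e. subtraction *and* renormalization. Bare subtraction would leave
C(0) = 1 − p, and the integral of the corrected function would no longer
equal the exponential time constant of a mono-exponential decay — the
property that justifies calling the integral a lifetime — so the
renormalized form is adopted. p is estimated as the pooled occupancy over
all pairs and frames (pairs are exchangeable and pooling is stabler for
rare bonds than averaging per-pair means); p = 1 (always bonded) is
rejected as degenerate.

`lifetime_integral()` integrates C_corr by the trapezoid rule over the lag
window and adds the analytic tail of a mono-exponential fitted
log-linearly to the final quarter of the window. Windowed and tail
contributions are reported separately, because lifetimes far beyond the
feasible lag window (nanoseconds against a window of hundreds of ps) are
dominated by the extrapolation and the reader should see that. For the
two-state Markov ground truth with rates $k_{on}, k_{off}$,

$$C_{\text{raw}}(t) = p_{eq} + (1 - p_{eq})\, e^{-(k_{on}+k_{off})t},
\qquad p_{eq} = \frac{k_{on}}{k_{on}+k_{off}},$$

so the corrected integral must recover $1/(k_{on}+k_{off})$; the test
suite checks a 3×3 rate grid and the acceptance workload uses
$k_{on} = 0.01$, $k_{off} = 0.04$ ps⁻¹ (lifetime 20 ps, occupancy 0.2).
`gen_two_state_bonds()` samples the chains run-length-wise (geometric
sojourns, exactly the law of the per-step chain with transition
probabilities $1 - e^{-k\Delta t}$) and starts from stationarity, so the
ACF is stationary from lag zero with no burn-in. Per-lag standard errors
use the naive binomial formula; they ignore origin–origin correlation and
are used only for relative comparisons (they do scale correctly with bond
rarity).

## Radial coordination structure

`compute_rdf()` normalizes pair counts to uniform partner density,

$$g(r) = \frac{\text{counts}(r)}{n_a\, \rho_b\, V_{\text{shell}}(r)\, n_{\text{frames}}},$$

with exact spherical-shell volumes per bin (no midpoint approximation), so
g = 1 means "as likely as at a random point of the cell". The default bin
width of 0.002 nm resolves first minima at the 10-pm scale at which
aggregation cutoffs are chosen; r_max defaults to (and may not exceed)
half the smallest box edge. The running coordination number
$n(r) = 4\pi\rho_b \int_0^r g\, r'^2 dr'$ reduces to a normalized
cumulative count and is therefore exactly conservation-consistent with the
histogram — a property the tests assert.

Extremum detection for cutoff derivation operates on a centered
moving-average copy (default 5 bins; the raw curve is never modified). A
first peak must exceed 1 by three times the bin-noise estimate, and a
first minimum must additionally dip below halfway between peak and bulk
level — without that condition, plateau wiggles inside a broad peak get
mistaken for shell boundaries.

Shell occupancy is computed by frame counting ("at least one partner
within the cutoff of any reference site") and reported *alongside* the
first-peak integral n(r): the two agree only when shells are rarely
multiply occupied, and conflating them silently is a classic source of
confusion when quoting "the complex exists X% of the time". The
between-sites density ratio (`region_density_ratio()`) uses a sphere at
the minimum-image midpoint of two tagged sites, re-evaluated every frame;
the region geometry of such statistics is not canonical, so the radius is
a mandatory explicit argument, never defaulted.

`gen_ideal_gas()` (uniform positions; g ≡ 1) validates the normalization;
`gen_shell_config()` plants centres on a sparse grid with exactly
`shell_occupants` partners at `shell_radius` (±0.005 nm jitter, redrawn
isotropically each frame) so coordination number, occupancy and
first-minimum location all have designed values.

## Mean force along the dissociation coordinate

`gen_umbrella_pull()` emulates forced dissociation: an overdamped
coordinate in an analytic potential of mean force V(x) plus a harmonic
restraint whose minimum moves at constant speed,

$$\zeta\,dx = -\left[V'(x) + k(x - x_0(t))\right]dt + \sqrt{2 k_B T \zeta}\; dW,
\qquad x_0(t) = x_{\text{start}} + v t.$$

The friction argument is the coefficient ζ in kJ mol⁻¹ nm⁻² ps (force per
velocity); the integrator is Euler–Maruyama, adequate at the enforced step
sizes ($k\,\Delta t/\zeta \le 0.1$). The restraint force
$k(x_0 - x)$ is positive while the restraint drags the coordinate
forward. Pull speed and duration are independent arguments — the simulator
does not hard-code any particular protocol's bookkeeping.

Sign conventions are the one place this analysis can silently go wrong,
so they are fixed at the type boundary: a `force_profile` is always in the
*pair-force* convention, positive = repulsive. Quasi-statically
$\langle k(x_0 - x)\rangle = +V'(x)$, which is *minus* the mean force, so
`as_pull_record()` negates a restraint-force column by default;
`bin_mean_force()` then bins samples by coordinate into half-open bins and
reports per-bin means, naive standard errors and counts (empty bins are
dropped, never interpolated; the profile is invariant under time reversal
of the record, which is tested).

Two systematic artifacts of the stiff-spring estimator are documented
rather than hidden. First, profiles are thermally smeared over
$\sigma = \sqrt{k_B T/k}$, biasing bins by roughly
$(k_B T/2k)\,V'''(x)$ — made negligible by a stiff spring (the validation
uses $k = 5\times10^4$ kJ mol⁻¹ nm⁻², σ ≈ 0.007 nm). Second, coordinates
near the start and end of a finite sweep are visited only by transient
fluctuations, where the restraint-force mean does not estimate the mean
force at all; `bin_mean_force(x_range=)` therefore evaluates with an
explicit margin inside the swept range. The quasi-static regime itself is
checked by a property test: halving the pull speed may not degrade the
recovery of the known pmf gradient.

`find_regimes()` collapses the profile into consecutive same-sign groups
whose |mean force| exceeds a noise floor (default: the median per-bin
standard error; a higher explicit floor is appropriate when samples are
strongly correlated), interpolates zero crossings between opposite-sign
neighbours, and labels alternating attractive/repulsive windows — the
structure of a contact / solvent-separated ion-pair profile: repulsive
below the contact minimum, attractive up to the barrier, repulsive beyond
it, then the long-range attraction. The double-well validation potential
$V(x) = h\,[((x-c)/w)^2 - 1]^2$ with h = 8 kJ/mol, c = 0.5 nm, w = 0.1 nm
reproduces exactly this topology with extrema at 0.4 / 0.5 / 0.6 nm.
`screened_coulomb_force()` provides the continuum reference
$f_C z_a z_b/(\varepsilon_r r^2)$ with the Coulomb constant frozen at
$f_C = 138.935458$ kJ mol⁻¹ nm e⁻² for a bit-stable curve
($\varepsilon_r = 80$ for bulk water); `compare_to_reference()` reports
per-bin residuals against it.

## What the synthetic data does and does not emulate

The generators reproduce the *statistical structure* each estimator
consumes: exponential reorientation with a slow subpopulation, two-state
bond kinetics with a finite-system plateau, uniform and shell-structured
coordination, and a restrained coordinate crossing a multi-well free-energy
profile. They deliberately do not emulate solvent-mediated
cross-correlations between pairs (pairs are independent), non-Markovian
bond dynamics (real hydrogen-bond survival has algebraic tails), jump
reorientation (real water reorients partly by large-angle jumps, which P₁
integrates over), multiple shells (one designed shell plus uniform bulk),
or inertial dynamics. Passing tests therefore demonstrate estimator
correctness against known ground truth — not force-field realism. On real
trajectories the same functions apply unchanged through the `trajectory`
readers and `run_config()`.

## Orchestration and reproducibility

`run_config()` validates a YAML-expressible configuration exhaustively
before touching the output directory (unknown stages, unresolvable roles,
bad cutoffs all fail up front; no partial writes on an invalid config),
then executes synth → acf → lifetimes → rdf → meanforce, logging one line
per stage and letting later independent stages run even if one fails. All
randomness derives from the single config seed through documented
per-stage sub-seeds, and every table is written by a fixed-format writer
(`write_tsv_fixed()`), so a rerun with the same config is byte-identical —
a property both the tests and the acceptance workload assert. The echoed
config with all defaults filled in is part of the output, so no silent
defaults exist. `ion_count_for_concentration()` handles the box-setup
arithmetic (1 mol/L in a 6×4×4 nm box → 58 ions per species).

## Problem sizes and numerical guardrails

The statistical validations run at sizes chosen to put sampling error
well below the asserted tolerances while completing in minutes on one
core: 1000 rotors × 10⁴ steps for the 5% time-constant recovery; 500
pairs × 2×10⁵ steps for the 10% lifetime and 2% occupancy recovery; 2000
particles × 50 frames for the RDF null model (RMS |g−1| < 0.02); 1.87×10⁷
Langevin steps for the 10% mean-force recovery with crossings within one
0.01-nm bin. Unit tests reuse the same constructions at smaller sizes
with correspondingly looser, 3σ-calibrated bounds.

Degenerate inputs are first-class: an all-zero indicator ("no aggregates
observed"), p = 1 correction, empty groups, overlapping groups, cutoffs or
radii beyond the half-box, fit windows with fewer than 10 points, and
profiles with fewer than 3 occupied bins all raise informative errors;
an anti-correlated ACF integrating to a negative lifetime warns but
reports the value.

## Known limitations

Orthorhombic boxes only; rank-1 ACFs only (no P₂/NMR observables or
spectra); no weighted-histogram or umbrella-integration estimators (the
single-slow-pull protocol does not need them); no angle-dependent
hydrogen-bond criteria; no 3-D spatial distribution functions. Reported
ACF and profile standard errors assume independent samples and understate
the truth for correlated data — they are for relative comparison, and any
absolute inference should use block averaging on top.
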