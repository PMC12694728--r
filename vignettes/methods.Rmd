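---
title: "Models and methods behind photocarrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photocarrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocarrier)
```

# The experimental system

photocarrier analyzes voltage-clamp recordings from planar lipid bilayers
(PLBs) doped with azobenzene photolipids and mobile ion carriers. Intense UV
light drives the photolipid toward its *cis* photostationary state, blue
light back toward *trans*; the isomerization changes bilayer packing and
interfacial properties within milliseconds and thereby switches
carrier-mediated conductance between two levels. The package provides the
full data-reduction chain for such experiments — epoch-averaged I--V curves,
supralinear conductance fits, relaxation kinetics, boundary potentials from
capacitance--voltage curves — together with the electrostatic barrier model
used to interpret the conductance changes, and a synthetic-data generator so
that every stage is testable without recordings.

# Steady-state conductance model

Currents through a broad (trapezoidal) permeation barrier are steeper than
ohmic. I--V curves are fitted with

$$I(V) = g_0\,(1 + \alpha V^2)\,V + o$$

where $g_0$ (nS) is the conductance at $V = 0$, $\alpha$ (V$^{-2}$) the
supralinearity factor and $o$ (pA) a residual offset. The model is linear in
$(g_0,\ g_0\alpha,\ o)$, so `fit_supralinear()` is an exact linear
least-squares solve; the covariance of $(g_0, \alpha, o)$ follows by the
delta method. $\alpha$ is fitted separately per illumination epoch and the
offset is not shared between epochs by default; both choices are exposed
because nothing in the physics forces UV and blue curves to share them.

For a single symmetric Eyring barrier the current is proportional to
$\sinh(zFV/2RT)$, whose small-V expansion gives
$\alpha = (zF/2RT)^2/6 \approx 63.1\ \mathrm{V^{-2}}$ at 298.15 K
(`alpha_from_single_barrier()`). A practical caveat, verified numerically in
the test suite: fitting the cubic model to an exact sinh over a $\pm 50$ mV
window already inflates the fitted $\alpha$ by about 6% because of the
5th-order sinh term. Comparisons between a fitted $\alpha$ and the analytic
expansion are therefore made either on windows of $\pm 30$ mV or less, or
against the analytic curve *fitted over the same window*.

# Epoch averaging and reversal potentials

`epoch_mean()` and `build_iv()` reduce sweeps to I--V points by averaging
the current over half-open windows $[t_0, t_1)$ — half-open so that every
sample belongs to exactly one epoch. The command voltage must be constant
inside the window; a window straddling the voltage step is an error, not a
silent average. Reversal potentials are obtained by linear interpolation
between the two points bracketing the sign change, taking the crossing
nearest 0 mV if several exist. Interpolation on a 20 mV grid is exact for
linear (two-conductance bi-ionic) curves; for constant-field GHK-shaped
curves its curvature bias is below 1 mV, which is smaller than typical
experimental scatter in $V_r$.

# Light-response kinetics

The current rise upon UV exposure is fitted with

$$I(t) = I_0 + \Delta I_1 (1 - e^{-t/\tau_1}) + \Delta I_2 (1 - e^{-t/\tau_2})$$

globally across sweeps: the two time constants are shared, the amplitudes
are free per sweep (`fit_biexp()`). Sharing only the time constants is the
weakest global constraint that still stabilizes $\tau_2$ when the fitted
window contains few slow-component time constants; amplitudes must stay free
because they scale with the driving voltage. Sweeps at $|V| \le 30$ mV are
excluded by default — their small currents carry little kinetic information.

Numerically the fit is a variable-projection scheme: for fixed
$(\tau_1, \tau_2)$ the amplitudes are exact linear solves, and a
Nelder--Mead search runs on the two log time constants. Starting values are
deterministic (log-linear regression on the residual tail of the
largest-amplitude sweep, $\tau_1$ started a decade below $\tau_2$), so the
fit needs no seed. When the second amplitude is degenerate or the time
constants coalesce, the result is flagged `effective_monoexp`.

Photoisomerization rates scale linearly with irradiance; the generator
multiplies both UV rates by the relative irradiance, and the suite verifies
that fitted $1/\tau_1$ versus irradiance is linear with $R^2 > 0.999$ in the
noiseless limit.

# Hydrophobic-anion transients

At low bulk concentration, a voltage step redistributes membrane-adsorbed
hydrophobic anions (tetraphenylborate-like) between the leaflets, giving an
exponentially decaying current $I_0 e^{-t/\tau}$. The recording chain — a
series resistance against the membrane capacitance plus a low-pass Bessel
filter — smooths the first instants of the transient, so
`fit_monoexp_window()` fits the 1--8 ms window by default and extrapolates
$I_0$ back to $t = 0$. With the default chain (2 M$\Omega$, 100 pF, 10 kHz)
the refitted $\tau$ is biased by well under 2% for $\tau \approx 3$ ms,
which the suite checks by round trip.

# Boundary potentials from Cm--V curves

Membrane capacitance depends parabolically on the applied DC voltage;
its minimum sits where the external field cancels the intramembrane field,
i.e. at the transmembrane boundary-potential difference
$\Delta\phi_b = \Delta\phi_s + \Delta\phi_d$ (surface + dipole).
`fit_cmv_parabola()` fits $C_m(V) = aV^2 + bV + c$ and reports the vertex
$-b/2a$ with a delta-method standard error; `boundary_potential_difference()`
subtracts vertices between conditions (perturbed $-$ reference, with
$V$ = side 1 $-$ side 2).

The surface-potential bookkeeping (`decompose_surface_contributions()`,
`binding_site_ratio()`) treats $\phi_s$ as proportional to the interfacial
concentration of the adsorbed charged carrier — the linearized
(small-potential) double-layer regime; no nonlinear Gouy--Chapman model is
fitted, and $\Delta\phi_d$ is assumed condition-invariant, an assumption the
functions record in their output. Binding ratios scale linearly with the
number of azobenzene moieties per photolipid and are homogeneous of degree
zero in a common rescaling of the two potentials.

# The three-slab barrier model

The membrane is modelled as three slabs: two interfacial (headgroup) slabs
holding the transportable species at concentration $[S]$, and a hydrophobic
core crossed over a free-energy barrier $\Delta G$. In the small-potential
limit

$$g_0 = \frac{z^2 F^2 A\, P\, [S]}{RT}, \qquad
  P = \frac{D}{d}\, e^{-\Delta G / RT}.$$

Only ratios of these quantities are physically interpreted here, so the
prefactor cancels in every headline number. The electrostatic components of
$\Delta G$ — the Born self-energy and the dipole-potential term
$zF\phi_d$ — scale as $1/\varepsilon_{hc}$; `rescale_barrier_dielectric()`
rescales the *whole* barrier by $\varepsilon_{old}/\varepsilon_{new}$,
treating it as entirely electrostatic, which matches the arithmetic used for
the reference numbers (16 kcal/mol at $\varepsilon$ 2.1 $\to$ 14.6 kcal/mol
at 2.3). `fold_change_from_barriers()` converts a barrier change into a
Boltzmann conductance ratio. The Born energy uses constant-density spherical
scaling when expressed against molecular mass ($r \propto m^{1/3}$, so
$\Delta G_b \propto m^{-1/3}$); for a 4.3-fold mass increase this is a
reduction factor of 1.63 — "almost a factor of two" only under more
generous radius models, which is why `born_scaling_from_mass()` documents
the cube-root value explicitly.

Weak-acid/weak-base speciation is plain Henderson--Hasselbalch with the pKa
taken equal in bulk and at the surface. Reversal potentials come from the
Nernst equation or, for multi-ion situations, the monovalent GHK equation
under the same sign convention ($V$ = side 1 $-$ side 2); the GHK
single-ion limit reduces to Nernst exactly.

# The four-step carrier cycle

`steady_state_current()` implements the minimal mechanistic cycle:
interfacial association ($k_{on}[ion]$), translocation of the carrier--ion
complex, release, and return of the free carrier, as a linear four-state
Markov system solved in closed form (stationary distribution of the rate
matrix). The charged translocation leg — the complex for a neutral carrier
like valinomycin, the free carrier for an anionic protonophore — is
voltage-biased by symmetric Eyring factors $e^{\pm zFV/2RT}$; the neutral
leg is voltage-independent. Association uses the bulk ion concentration (no
unstirred-layer correction).

Two structural properties are worth knowing. First, with symmetric
solutions the cycle satisfies detailed balance at $V = 0$ and the current
vanishes identically. Second, the small-V conductance is proportional to
$K_A [ion] \cdot$ carrier density only while interfacial binding is
sub-saturating ($K_A[ion] \lesssim 1$); beyond that the cycle shows the
classic carrier turnover — free carrier depletes, and conductance falls
again. The test suite asserts monotonicity in $K_A$ only in the
sub-saturating regime and verifies the closed form against an independent
ODE integration (deSolve) on random parameter sets.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

* step protocols (hold 0 mV for 50 ms, then 130 to $-130$ mV in $-20$ mV
  steps over 300 ms sweeps, 1 s between sweeps), sample-centered
  timestamps;
* conductance switching between photostationary states: biexponential rise
  under UV, held in the dark, fast exponential return under blue
  ($k \approx 7000\ \mathrm{s^{-1}}$), rates linear in irradiance. The
  amplitude split and the exact $\tau_1/\tau_2$ of the rise are free
  generator parameters (defaults 0.7, 2 ms, 15 ms) — they are not
  literature constants;
* supralinear instantaneous I--V with additive white Gaussian current noise
  (no 1/f component);
* an acquisition chain of a first-order series-RC stage and an n-pole
  digital Bessel low-pass (bilinear transform of the analog prototype with
  cutoff prewarping, DC gain pinned to exactly 1 and applied from rest at
  the first sample, so constant traces pass through unchanged);
* exponential redistribution transients and noisy Cm--V parabolas on the
  $-100$ to $+100$ mV, 20 mV DC grid.

It does **not** model capacitive charging spikes at voltage steps,
photothermal or photodynamic artifacts, 1/f or shot noise, or acquisition
hardware beyond the two filter stages. Parameter-recovery tests on these
synthetic data therefore demonstrate correctness of the estimators under
the assumed noise model, not robustness to every artifact of real
recordings.

All generators are seeded and bit-reproducible; seeding is scoped (via
`withr::with_seed`) so it never disturbs the caller's RNG stream.

# Problem sizes and calibration

The calibration experiments in the test suite use 14-sweep sets sampled at
0.1--0.25 ms (the estimators are grid-agnostic; denser acquisition-grade
sampling at 0.02 ms changes nothing but runtime). The ratio-recovery
calibration synthesizes 100 independent 4-replicate UV/blue experiments at
a generating conductance ratio of 7.5 with 2 pA current noise and asks how
often the replicate mean falls within 2 SEM of the truth.

One statistical point deserves emphasis: with $N = 4$ replicates, an
interval of $\pm 2\,\widehat{\mathrm{SEM}}$ built from the *sample* SEM is
a $t_3$ interval whose exact coverage is
$P(|t_3| \le 2) = 86.1\%$ — not the 95.45% a $2\sigma$ normal interval
suggests. The measured coverage of the pipeline sits at that $t_3$ ceiling,
which is precisely what an unbiased, correctly calibrated estimator should
do at this replicate count.

# Worked example

```{r example}
light <- light_protocol(uv_ms = c(100, 150), blue_ms = c(200, 250))
kin <- photoswitch_kinetics(g_trans_nS = 1, g_cis_nS = 7.5,
                            tau1_ms = 0.5, tau2_ms = 2)
ss <- synthesize_sweeps(step_protocol(dt_ms = 0.25), light, kin,
                        nf = noise_filter_spec(noise_sd_pA = 2), seed = 1)
fit_uv <- fit_supralinear(build_iv(ss, c(125, 150), epoch = "uv"))
fit_blue <- fit_supralinear(build_iv(ss, c(225, 250), epoch = "blue"))
fit_uv
fit_blue
fit_uv$g0_nS / fit_blue$g0_nS
```

```{r reference}
reproduce_reference_values()
```

# Known limitations

* The carrier cycle is the minimal linear four-state model; explicit proton
  binding kinetics, diffusion polarization and carrier partitioning
  kinetics are out of scope (protonation is assumed at equilibrium).
* The boundary-potential decomposition yields only transmembrane
  *differences*; absolute surface potentials and ionic-strength (Grahame)
  corrections are not modelled.
* `born_scaling_from_mass()` exposes only the constant-density cube-root
  scaling; alternative radius models must be applied by the caller.
* The GHK implementation covers monovalent ions only.
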