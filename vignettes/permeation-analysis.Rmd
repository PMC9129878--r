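---
title: "Free energies, selectivity and conductance of narrow-pore ion channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free energies, selectivity and conductance of narrow-pore ion channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeon)
```

## The scientific problem

Lysosomal K+ channels of the TMEM175 family select potassium over sodium
without the canonical selectivity filter: their pore is a largely
hydrophobic tube whose rate-limiting element is a narrow isoleucine
constriction. Understanding how such a pore conducts and selects ions
requires connecting several layers of analysis: enhanced-sampling molecular
dynamics to obtain the free-energy profile of permeation, hydration-shell
accounting to quantify the partial dehydration of the permeating ion,
continuum electrostatics to quantify the stabilising field generated by
acidic residues at the pore mouths, a one-dimensional transport model to
convert the free-energy profile into a single-channel conductance,
alchemical free-energy perturbation to measure site-versus-bulk ion
preference, and patch-clamp analysis to anchor the computations in
measurable permeability ratios.

`permeon` implements this full analysis chain as reusable, tested R
functions. Because the original data live at the microsecond all-atom MD
scale, the package also ships a Brownian-dynamics *toy pore* whose free
energy is known analytically; every stage of the chain can therefore be
validated end to end at desk scale. This vignette records the models, the
parameter choices and their rationale, the numerical decisions, and what
the desk-scale validations do and do not demonstrate.

## Collective variables and metadynamics bookkeeping

Permeation is driven and analysed through a pair of *soft-minimum proximity*
collective variables. For ions indexed by $k$ with axial offsets
$\Delta Z_k$ from a virtual centre,

$$\zeta \;=\; \frac{\beta}{\ln \sum_k \exp\{\beta/(|\Delta Z_k| + C)\}} - C ,$$

with smoothing $\beta = 100$ Å and regulariser $C = 2$ Å. The variable is a
smooth lower bound on $\min_k |\Delta Z_k|$: it measures how close the
*nearest* ion is to the centre without committing in advance to which ion
permeates. For a single ion it reduces exactly to $|\Delta Z|$ — this
identity is the normative test of the implementation, because common
typesettings of this expression are ambiguous between $\beta \log(\cdot)$
and $\beta / \log(\cdot)$, and only the latter has the correct units and
limiting behaviour. Evaluation uses log-sum-exp throughout, so large
$\beta$ is numerically safe.

Two such variables, $\zeta_A$ and $\zeta_B$, are defined against two
centres ~1 Å apart flanking the constriction. Metadynamics deposits 2-D
Gaussian hills (width 0.25 Å, every 4 ps) on $(\zeta_A, \zeta_B)$;
multiple walkers share a single growing bias. Because $\zeta \ge -C$ with a
hard physical boundary at $\zeta = 0$, each hill is accompanied by mirror
images reflected across $\zeta = 0$ in each CV dimension plus the double
mirror. The four-term construction factorises as
$[g(\zeta_A - c_A) + g(\zeta_A + c_A)][g(\zeta_B - c_B) + g(\zeta_B + c_B)]$
and makes the bias gradient normal to each boundary vanish — the property
the images exist to guarantee. A per-dimension mirror alone would leave a
nonzero cross-term gradient at the boundary, which is why the double mirror
is included.

Hill heights follow a piecewise-linear rise/hold/decay schedule
(0.0035 → 0.007 → 0.0035 kcal/mol; "gradually" is interpreted as linear,
the simplest monotone reading). The bias lattice uses 0.05 Å spacing —
five points per hill width — over $\zeta \in [-2, 45]$ Å.

## Reweighting and free-energy profiles

After the bias becomes approximately stationary, the *time-averaged* bias
$\bar V(\zeta_A, \zeta_B)$ over a trailing window converts biased samples
into unbiased expectations. Snapshot $X_i$ receives weight

$$w(X_i) \propto \exp\{\bar V(\zeta_A(X_i), \zeta_B(X_i))/k_BT\},$$

normalised over snapshots, with the snapshot assigned to the *nearest*
lattice cell (no interpolation — fidelity to the grid-assignment procedure,
and at 0.05 Å spacing the difference is negligible). The ion occupancy of
axial bin $\alpha$ sums $w(X_i)$ over ions within the bin and within
$R_0 = 10$ Å of the pore axis; the potential of mean force is
$F(z_\alpha) = -k_BT \ln \rho(z_\alpha) + C'$, anchored so that its
occupancy-weighted mean over the bulk region vanishes. Defaults the data do
not dictate, chosen once:

* **bin width 0.5 Å** — resolves the ~15 Å hydrophobic span with ~30 bins
  while keeping per-bin statistics usable;
* **bulk anchor $|z| \in [30, 40]$ Å**, both sides pooled — the toy
  reservoirs (and the profile flats of the motivating system) lie there;
* **empty bins are masked (`NA`), never zero-filled** — downstream
  conductance integration refuses masked bins rather than silently
  extrapolating;
* a warning is emitted if the effective sample size $1/\sum_i w_i^2$ of a
  weight set falls below 10.

Observable profiles (hydration counts, electrostatic energies) use the same
weights: $\bar O(z_\alpha) = \rho^{-1}\sum w\,O$.

The convergence diagnostic is the *split-half comparison*: the analysis
window is cut into two temporal halves and a fully independent profile is
computed from each — each half gets its own time-averaged bias, its own
renormalised weights, and its own anchoring. The mean absolute difference
over shared bins estimates the statistical error. We deliberately average
the bias per half rather than sharing the full-window average: the first
half's samples were generated under the earlier, lower bias, and weighting
them with the late-time average mixes a systematic error into what should
be a statistical comparison (empirically the shared-bias variant is
uniformly worse on the toy pore).

## The toy pore: what it emulates and what it does not

The synthetic generator `simulate_toy_pore()` runs overdamped Langevin
(Brownian) dynamics, $x \leftarrow x + (D/k_BT)F\,\Delta t +
\sqrt{2D\Delta t}\,\eta$, for non-interacting monovalent cations in a
radially confined cylinder with a Gaussian axial barrier and optional
constant field. Defaults and why:

| parameter | default | rationale |
|---|---|---|
| barrier height $U_0$ | 7 kcal/mol | the scale of the constriction barrier in a narrow K+ channel |
| barrier width | 2 Å (sd) | constriction-like; sets the stability limit for $\Delta t$ |
| box length | 80 Å ($z \in \pm 40$) | pore region $\pm 15$ Å plus bulk reservoirs |
| pore radius / stiffness | 5 Å, 10 kcal/(mol Å$^2$) | sub-$R_0$ cylinder; soft edge ~0.24 Å |
| ions per walker | 8 | "multiple diffusing ions" so the soft-min CV is genuinely multi-ion |
| $D$ | 0.2 Å$^2$/ps | bulk K+ (2×10$^{-9}$ m$^2$/s) |
| $\Delta t$ | 0.1 ps | drift per step ≪ barrier width; $D\Delta t/w^2 = 0.005$ |
| walkers | 8 | the multiple-walker protocol |
| hill schedule | rise to 2 ns, decay by 6 ns | the production ramp compressed to the toy run length |

The radial confinement applies at **all** z, so the accessible
cross-section is uniform and the exact free-energy profile equals the
imposed axial potential — the property that makes `analytic_toy_pmf()` a
ground truth rather than an approximation. (A pore-only confinement with
wide reservoirs would fold an entropy term into $F(z)$ and forfeit the
closed form.) With `periodic_z = TRUE` the axial boundary wraps instead of
reflecting, which under a field sustains a steady-state flux — the setup
used to count permeation events under voltage.

What the toy pore does **not** emulate: explicit water and ion hydration,
ion–ion interactions (no knock-on), a fluctuating protein, or
position-dependent diffusion. Passing the end-to-end test therefore
demonstrates that the *analysis machinery* — CVs, bias bookkeeping,
reweighting, anchoring, integration — is correct and internally consistent;
it does not certify force fields or sampling adequacy of any all-atom
system.

Typical desk-scale problem sizes, chosen so a full validation runs in
minutes: 8 walkers × 625 000 steps (5×10$^6$ Brownian steps, 500 ns
aggregate) for PMF recovery, which lands at ~0.15 kcal/mol RMS against the
analytic profile over $|z| \le 20$ Å; three run lengths (20k/80k/320k
steps, three replicas each) for the split-half trend. The split-half value
of a *single* run fluctuates strongly at the longer lengths (the metric
decays toward a statistical floor), so the convergence helper averages a
few replicas per length; this estimates the same expectation with usable
variance. Even so, an occasional seed can invert one adjacent pair — the
diagnostic is a trend, not a theorem.

## Hydration-shell counting

Coordination numbers use the smooth switching function
$\sum_j [1 - (r_j/r_0)^{100}]/[1 - (r_j/r_0)^{200}]$, evaluated in the
equivalent stable form $\sum_j 1/(1 + (r_j/r_0)^{100})$ whose removable
singularity at $r = r_0$ is exactly 1/2. Shell radii follow the bulk-water
RDF minima: K+ 3.5 Å (first shell) and 6.0 Å (first+second); Na+ 3.2 and
5.7 Å. The exponents are fixed at 100/200, the values calibrated against the bulk-water RDF integral, and are not re-tuned. With
these exponents the function is a near-step: outside a ±5 % band around
$r_0$ no single oxygen deviates from the hard count by more than
$1/(1 + 0.95^{-100}) \approx 6\times10^{-3}$, and inside the band by at
most 1/2 — the bound the test suite asserts. (A ±2 % band would *not*
bound the deviation: at $0.98\,r_0$ the function is 0.88, a 0.12
deviation; the wider band is the mathematically attainable statement of
the same "virtually a step" property.) Protein coordination counts all
protein oxygens — backbone and side chain — identified by element;
distances use the minimum-image convention when a box is supplied.

## Continuum electrostatics

Ion–protein interaction energies use the linearized Poisson equation
$\nabla\cdot(\varepsilon\nabla\Phi) = -4\pi k\rho$ (zero ionic strength; no
screening term is part of the model) on a cubic lattice, by default
150³ points at 1 Å. Dielectric regions, in precedence order protein >
ion cavity > pore water > membrane > bulk: protein 2 (or 1), ion cavity 2
(or 1), pore-water cylinder (radius 18 Å, height 28.8 Å) at 40, membrane
slab (28.8 Å) at 2, bulk water 80. The protein interior is the union of
atom spheres inflated by a 1 Å probe with one morphological closing pass —
an *approximation* to a reentrant molecular surface, documented as such
(the exact construction used with the original solver is not reproducible
from its description). The solver is Gauss–Seidel SOR with
$\omega = 2/(1+\pi/n)$, arithmetic face permittivities, trilinear charge
spreading, and Dirichlet boundaries from the bulk-screened Coulomb
potential of the charges (an analytic boundary can be supplied when known,
as in the planar-interface validation). Convergence is declared when the
largest per-sweep update falls below the tolerance; non-convergence is an
error, never a silent return. Validation: a point charge in uniform
$\varepsilon = 80$ matches Coulomb within 3 % beyond five spacings on a
64³ grid, and a charge above a planar 80/2 interface matches the
image-charge closed form within 5 %. The ion's own charge is *absent* from
the solve (its cavity is present in the dielectric); the reported energy
is $E_k = q_k\Phi(\mathbf r_k)$ by trilinear interpolation.

## Conductance, voltage and rates

The one-dimensional diffusion estimate converts an anchored PMF into a
single-channel conductance,

$$\gamma = \frac{q^2 C S}{k_B T}\left[\int_{z_1}^{z_2}
\frac{e^{F(z)/k_BT}}{D(z)}\,dz\right]^{-1},$$

with $C$ = 100 mM, $S$ = 314 Å², flat $D$ (2×10$^{-9}$ m²/s for K+,
1.5×10$^{-9}$ for Na+) unless a profile is supplied, and trapezoidal
integration. All unit bridging between molecular (Å, kcal/mol, e) and SI
units happens inside this one function; results are in pS. A flat profile
recovers $q^2 C S D/(k_BT L)$ to 1 part in 10⁹, and halving the bin width
changes a smooth-PMF result by <0.1 %. A uniform field $E_z$ over a box of
length $L_z$ corresponds to the membrane potential $\Phi = E_z L_z \times
0.0434$ V; $-0.1045$ kcal/(mol Å e) over 110.5 Å is $-501$ mV. On the toy
pore, the ohmic rate predicted from the equilibrium PMF agrees with
directly counted crossings under voltage within a factor of two — the
accuracy class expected of this diffusion-limited estimate.

## FEP selectivity analysis

Alchemical K+→Na+ transformations are analysed by per-window exponential
averaging, $\Delta G_i = -k_BT\ln\langle e^{-\Delta U/k_BT}\rangle$
(log-sum-exp stabilised), over the standard λ schedules: bulk 0.04
increments on [0, 0.8] then 0.02 on [0.8, 1] (30 windows); pore 0.04 on
[0, 0.96] then 0.02 on [0.96, 1] (26 windows; a commonly quoted count of 26 steps
matches the pore schedule, while the bulk increments yield 30).
One-sided exponential averaging in each direction is used deliberately —
the protocol validates by forward/backward *hysteresis*, not by
overlap-optimal estimators like BAR, so the package measures exactly that:
the maximum gap between the forward curve and the forward curve implied by
the backward run, on the union λ grid. Gaussian window samples with
$\Delta U \sim N(\mu, \sigma^2)$ have the closed form
$\Delta G = \mu - \sigma^2/2k_BT$, which the generator exposes as ground
truth; the Jensen bound $\Delta G \le \langle\Delta U\rangle$ is asserted
on every synthetic run. The site-versus-bulk differential
$\Delta\Delta G = \Delta G_{\rm bulk} - \Delta G_{\rm site}$ converts to a
fold preference $e^{\Delta\Delta G/k_BT}$; at 298 K, 0.5 kcal/mol is
2.33-fold (the Boltzmann value is reported even where rounded folds
circulate in the literature). Harmonic exchange restraints and flat-bottom
confinement parameters are carried as metadata on the sample tables; they
are sampling-engine concerns, not analysis inputs.

## Patch-clamp analysis

IV curves are plateau-window averages of voltage-step sweeps
(−100…+100 mV in 20 mV steps from a 0 mV holding potential);
channel-specific currents are isolated by subtracting the IV measured
under a channel inhibitor. The reversal potential is linearly interpolated
at the zero crossing (exact for an ohmic IV; multiple crossings resolve to
the one nearest 0 mV, with a warning). Under monovalent bi-ionic
conditions the permeability ratio is

$$P_{\rm in}/P_{\rm out} = \frac{[{\rm out}]}{[{\rm in}]}
\exp(-E_{\rm rev}F/RT).$$

The recording temperature is taken as **295 K** (room temperature, not
stated with the measurements): this is the choice that reconciles
$E_{\rm rev} = -76$ mV at 150/150 mM with the measured ratio of 20, and
it simultaneously reproduces 1.7 at −13 mV and 1.9 at −16 mV. Dose-response
inhibition is fit to $I = I_{min} + (I_{max}-I_{min})\,{\rm IC}_{50}/({\rm
IC}_{50}+[{\rm inh}])$ by Levenberg–Marquardt with IC$_{50} > 0$; the
noiseless model is recovered to 10⁻⁶ and 5 % multiplicative noise leaves
the median IC$_{50}$ error under 10 % across 100 replicates.

## Degenerate inputs and tie-breaks

Empty selections, coincident axis centres, zero-width bins, all-zero
occupancies, λ gaps/overlaps, IVs without a zero crossing and non-converged
solves are errors, not silent results. Hills at the same timestamp merge by
walker id (deposition is additive, so the order cannot change the grid).
CV values outside the bias lattice are clamped to its hull with a warning
and count toward the weight normalisation. The permeation counter requires
a completed bound-to-bound transit with the ion inside $R_0$ throughout the
pore region; re-entries and off-axis excursions do not count, which makes
the count robust to recrossing noise at the thresholds ($z = \pm 15$ Å by
default).

## Known limitations

* External MD formats: the package analyses its own tabular trajectory
  format natively; PDB+DCD ingestion is available through the suggested
  bio3d readers, but XTC/GRO parsing is out of scope.
* The Poisson solver is a desk-scale SOR implementation — correct and
  validated, but not performance-engineered (no multigrid); per-frame
  profile solves should use modest grids.
* No well-tempered metadynamics, no 2-D PMFs, no block-bootstrap error
  bars (the split-half comparison is the error model), no
  position-dependent diffusion estimation.
* Axon binary patch-clamp formats are not parsed; sweeps arrive as tables.

## A worked desk-scale example

```{r example, eval = FALSE}
p  <- toy_pore_params()       # 7 kcal/mol barrier
md <- toy_metadynamics()
sim <- simulate_toy_pore(p, n_steps = 625000, n_walkers = 8,
                         metadynamics = md, seed = 1)
res <- reweighted_pmf(sim)
f_true <- analytic_toy_pmf(p, res$pmf$z)
sel <- abs(res$pmf$z) <= 20
sqrt(mean((res$pmf$value[sel] - f_true[sel])^2))  # ~0.15 kcal/mol

gamma <- conductance_from_pmf(res$pmf, bounds = c(-20, 20))
ohmic_current_and_rate(gamma, 500)
```

The same pipeline, run end to end with fresh seeds, is what
`scripts/acceptance.R` executes.
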