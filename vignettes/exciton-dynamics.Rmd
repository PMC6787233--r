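---
title: "Modelling exciton transport and annihilation on double-walled nanotubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exciton transport and annihilation on double-walled nanotubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitube)
```

## The system and the model

Double-walled J-aggregate nanotubes (the C8S3 system) consist of two
concentric cylinders of strongly coupled dye molecules. Light absorbed by
either wall creates Frenkel excitons that diffuse along the wall, hop
between walls, decay radiatively, and — when two excitons on the *same*
wall approach each other — undergo exciton–exciton annihilation (EEA),
leaving a single survivor. Exciton–exciton-interaction 2D (EEI2D)
spectroscopy measures, as a function of the waiting time $T$, both the
total surviving population (absorptive transients) and the population of
annihilation-involved excitons (EEI transients), separately for each wall
(diagonal peaks) and for excitons that changed wall (cross peaks).

`excitube` models this with a kinetic Monte Carlo simulation on one or two
periodic rectangular grids of molecules wrapped on cylinders:

* **Lattice.** The inner wall is a $30 \times 1000$ grid, the outer wall
  $55 \times 1000$, lattice constant $a = 0.74$ nm, periodic in both the
  circumferential and the axial direction. The 55-site circumference
  reproduces the ~13 nm outer diameter ($55 a / \pi$).
* **Planting.** $N_e = \mathrm{round}(N_m / \rho)$ excitons per wall
  ($\rho$ = molecules per exciton, identical on both walls) are placed
  uniformly without double occupancy; an annihilation sweep runs at
  $t = 0$, so at high density the EEI signal is maximal at essentially
  zero waiting time.
* **Per step** (1 fs): each alive exciton, visited in a freshly shuffled
  order, first draws for decay (probability $dt/\tau$, $\tau$ = 58 ps for
  isolated inner tubes, 33 ps for complete nanotubes), then draws once
  more to either hop to one of its four neighbours (total probability
  $H = 0.04$, i.e. $1/4$ each), attempt inter-wall transfer (probability
  $k\,dt$ with $k_{io} = 0.0013$, $k_{oi} = 0.0031$ fs$^{-1}$, executed
  only onto an unoccupied partner site), or stay.
* **Annihilation sweep.** After all excitons have moved, every same-wall
  pair strictly closer than $R_0 = 3$ lattice units (minimum-image metric)
  annihilates: pairs are resolved in random order, one member of each pair
  is deleted uniformly at random, and survivors may participate in further
  events in the same sweep. Cross-wall pairs never annihilate — the
  ~3.5 nm wall separation makes inter-wall dipole–dipole interactions
  negligible.

$H$ is the *total* per-step probability to move. This is the only reading
consistent with pairing $H = 0.04$/fs with $D_{2D} = 5.5$ nm$^2$/ps: the
mean-square displacement grows by $H$ lattice units$^2$ per step, so
$D = H a^2 / (4\,dt) = 5.476$ nm$^2$/ps, equivalent to 10 molecules/ps.

Several micro-ordering choices are not fixed by the physics and were made
once: the event order within a step is decay → movement → annihilation
sweep; the strict inequality $d < R_0$ implements "closer than the
annihilation radius" (a pair at exactly 3 sites does not annihilate);
occupancy exclusion applies only to inter-wall transfer (intra-wall hops
may transiently stack excitons, which the sweep then resolves when
$R_0 > 0$); and clustered groups are cleared within a single sweep rather
than deferred, since deletions cannot create new sub-$R_0$ pairs the sweep
terminates after one pass over the initially violating pairs. Observables
are sampled after each step's sweep, including the $t = 0$ sweep.

The walls of unequal circumference are registered by the nearest-site map
$i' = \mathrm{round}(i \cdot n^{to}_{circ} / n^{from}_{circ})$ (round half
up) with the axial index preserved; this preserves local adjacency and
density and round-trips to within one circumferential site.

## Observables

Each exciton is labelled with its origin wall and a per-event record of
annihilation partners' origin walls. Six predicates generate the simulated
transients (`observable_ids()`): absorptive diagonal and cross signals
count alive excitons by (origin, current) wall; EEI signals additionally
require participation in at least one annihilation event with a
same-origin partner. The EEI cross peak ($2\omega_{outer} \to
\omega_{inner}$) counts excitons planted on the outer wall that
annihilated with a same-origin partner and reside on the inner wall at
$T$. Only the absorptive totals, EEI totals, and this cross peak follow
directly from the published level scheme; the remaining predicates mirror
them by symmetry and carry `reconstructed = TRUE` in their metadata.

Derived quantities:

* `msd_series()` / `diffusion_constant()` use *unwrapped* displacements
  (periodic folding would cap the MSD at $(\mathrm{grid}/2)^2$ and bias
  $D$ low) and fit $\langle x^2 \rangle = 4 D \tau$ excluding $\tau = 0$.
* `transfer_efficiency()` is the fraction of outer-origin excitons whose
  terminal event (decay or annihilation-deletion) occurred on the inner
  wall; excitons alive at the horizon (default study horizon $10\tau$) are
  censored at their current wall. In the sparse limit this approaches the
  equilibrium occupancy $k_{oi}/(k_{io}+k_{oi}) = 0.705$, slightly
  depressed (to $\approx 0.700$) because an exciton spends its first
  $\sim (k_{io}+k_{oi})^{-1} \approx 0.23$ ps equilibrating from its
  outer-wall starting point, and a fraction $\sim 1/(1 + (k_{io}+k_{oi})\tau)$
  of decays samples that transient. At finite density the efficiency
  *rises* above 0.705 before falling: EEA concentrates on the denser inner
  wall and annihilation-on-inner counts as successful transfer, while at
  high density EEA on the outer wall destroys excitons before they
  transfer. `efficiency_curve()` exposes this non-monotonic behaviour
  against the linear exciton density (excitons per nm of tube length).
* `peak_time()` refines the discrete argmax by a three-point parabola,
  which is robust on the log-spaced waiting-time grids the experiment
  uses; a maximum at the first sample reports 0.
* `multi_annihilation_fraction()` reports the share of annihilation
  *participants* with two or more events. "The excitons" admits two
  denominators; participants are used because deleted partners can never
  reach two events, and the all-planted alternative is attached as an
  attribute.

## The HSR diffusion tensor

As an independent, fully quantum-mechanical estimate of exciton
diffusivity, the package evaluates the Haken–Strobl–Reineker white-noise
dephasing model on a Frenkel-exciton Hamiltonian $H_{nm} = \delta_{nm} E_n
+ (1-\delta_{nm}) J_{nm}$. Couplings use the extended-dipole
approximation (two point charges $\pm q$ separated by $l$ along each
transition dipole), which reduces to the point-dipole form beyond a few
$l$ but is accurate at nearest-neighbour range. For eigenstates $\mu,\nu$
with angular frequencies $\omega_\mu$,

$$D_{u,w} = \frac{1}{Z} \sum_{\mu,\nu}
\frac{\Gamma}{\Gamma^2 + \omega_{\mu\nu}^2}\,
\hat j^{*}_{\mu\nu}(u)\, \hat j_{\mu\nu}(w)\,
e^{-\hbar\omega_\nu / k_B T}, \qquad
\hat j_{\mu\nu}(u) = i \sum_{n,m} \langle\mu|m\rangle\,
(u \cdot r_{mn})\, J_{nm}\, \langle n|\nu\rangle,$$

with $\Gamma$ the dephasing rate and $Z$ the exciton partition function.
Numerical conventions: energies are kept in cm$^{-1}$ and converted to
rad/fs ($\times 2\pi c$) before the tensor evaluation so $\Gamma$ and
$\omega_{\mu\nu}$ share units and $D$ emerges in nm$^2$/fs (reported
$\times 10^3$ as nm$^2$/ps); Boltzmann weights are referenced to the band
bottom (an overall shift that cancels against $Z$, avoiding overflow); the
circumferential ($\phi$) direction uses the unrolled arc-length coordinate
with an antisymmetric minimum-image wrap
$x - 2\pi\,\mathrm{round}(x/2\pi)$ — round-half-even keeps $w(-x) = -w(x)$
so antipodal pairs get $\pm\pi$ consistently and the flux operator stays
Hermitian.

The real nanotube's helical lattice (two molecules per unit cell, dipole
tilt angles, $l$, $q$, $\Gamma$) is not hard-coded: `build_helical_cylinder()`
is fully parameterised and the model accepts explicit geometries and
coupling matrices. Published axial values for the real geometry
(23.9/16.3 nm$^2$/ps, i.e. 43/29 molecules/ps at 1.8 molecules/nm$^2$)
require structural parameters from the original structural model that are
not reproduced here; the implementation is instead validated by
properties: term-by-term brute-force equivalence for small aggregates,
dimer closed forms, invariance under uniform energy shifts and rigid
translations, non-negative diagonal elements, and the $1/\Gamma$
large-dephasing tail.

## Global fitting

The fluence series is fitted with exactly two free physics parameters,
$H$ and $R_0$, shared across all densities. One amplitude scale factor is
fitted jointly over *all* absorptive series and one over all EEI series
(closed-form weighted least squares), enforcing the constraint that a
single scaling relates simulated counts to measured amplitudes. The
goodness of fit is the detection-noise-weighted sum of squared errors —
the scale-factor constraint is physical (one detector, one scaling per
signal class), while the metric is this package's own standard choice. The fit is an exhaustive grid
search ($H \in [0.005, 0.1]$, $R_0 \in \{1..6\}$ by default): the Monte
Carlo objective is noisy, so gradient methods are avoided and the full
objective surface is returned. Model curves are interpolated to data
times linearly in log-time, matching the log-sampled waiting-time axis.
Nominal densities can float within their experimental uncertainties via
`density_factors`; the default keeps them nominal.

Because the forward model is independent of the data, forward ensembles
are memoised in a user-visible cache (`forward_cache`), which makes
repeated fits (parameter-recovery studies, objective comparisons) cheap.
A recovery experiment with truth $H = 0.04$, $R_0 = 3$, four densities
(18, 83, 165, 404 molecules per exciton) and 5% noise recovers $R_0$
exactly and $H$ within ±20% in at least 8 of 10 noise replicates.
Replicates share the clean forward curve and differ in the noise draw —
the noise is the replicated quantity. A literal $\Delta\chi^2 = 1$
confidence contour is *not* meaningful here: the Monte Carlo noise floor
of the objective is far above one unit, so recovery is assessed on the
grid instead.

## Synthetic data

`truth_params()` / `generate_bundle()` emulate the structure of the
measured fluence series: per-density bundles of absorptive and EEI
transients on a log-spaced 0–50 ps grid (40 points; the experimental grid
is not printed), with additive white Gaussian noise of standard deviation
$\sigma \times$ series maximum ($\sigma = 0.05$ by default) and that value
as the per-point uncertainty, matching "error bars refer to the detection
noise level". Default density lists are the experimental ones: 18, 83,
165, 404 molecules per exciton (flash-diluted single-wall series) and 19,
64, 625 (complete nanotubes). The generator reproduces the data's
*structure*, not its physics beyond the model itself: real data contain
transient-heating distortions at high fluence, possible correlated noise,
and blue-shifted side transitions, none of which are emulated — passing
tests therefore validate the pipeline, not those effects.

## Problem sizes, determinism, degenerate inputs

Simulations are bit-reproducible given (seed, n_real, parameters): every
realization gets an independent counter-seeded RNG stream spawned from the
master seed, and all outputs embed seed, parameter hash and version.
Study sizes used by the package's own validation runs: the diffusion
constant uses 150 realizations of 100 sparse non-interacting walkers over
10 ps (seed-to-seed SD ~0.07 nm$^2$/ps); the transfer-efficiency plateau
uses 2500 sparse realizations to $10\tau$; the cross-peak timing uses 200
realizations of the full double-wall system to 30 ps; the recovery study
uses a 30 × 250 axial section with 6 realizations per grid point, which
leaves the objective's noise floor well below the parameter contrast.

Degenerate inputs are defined rather than rejected where the physics
allows: a 1 × 1 lattice's neighbours are the site itself; `density = 1`
fills every site; `ann_radius = 0` disables EEA (and is required for MSD
runs); `lifetime = Inf` disables decay; a single-point fit grid returns
that point. Hard errors guard the probability budget
($dt/\tau + H + k\,dt \le 1$), cross-wall distance queries, unequal axial
lengths in transfer maps, and single-wall efficiency queries.

## Known limitations

Transport is purely diffusive and isotropic — no coherent/wavelike
component, no exciton coherences, and no anisotropic hopping along the
helical strands. Annihilation is deterministic within $R_0$ (probability
one) with no distance-dependent rate. The transient-heating feedback seen
at the highest fluence for $T > 2$ ps is outside the model, as are
absolute signal amplitudes in mOD and the construction of 2D spectra
themselves. The HSR tensor and the random-walk picture are two ends of a
modelling spectrum; their ~4× disagreement for this system
(43 vs 10 molecules/ps axially) is expected and informative, not a defect
of either implementation.
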