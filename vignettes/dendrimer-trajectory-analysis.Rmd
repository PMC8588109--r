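---
title: "Methods: dendrimer trajectory analysis with dendritrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dendrimer trajectory analysis with dendritrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendritrace)
```

`dendritrace` analyses molecular configurations of charged dendrimers — the
coordinates, masses, partial charges and group labels of one or more time
frames — and reports the observables that characterise such polyelectrolytes:
global size and shape, the radial structure of the counterion double layer,
hydrogen bonding, stacking ("pairing") of planar side groups, and guest
uptake. This vignette records the models behind each stage, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
ground-truth generators do and do not emulate.

Units are fixed package-wide: lengths in nm, times in ps, charges in
elementary charges e, masses in g/mol. Readers convert at the boundary
(PDB Angstrom input is divided by 10); nothing downstream carries unit
metadata.

## Shape metrics

The radius of gyration is the mass-weighted RMS distance from the centre of
mass, $R_g = (M^{-1}\sum_i m_i r_i^2)^{1/2}$, evaluated per frame with
all-atom mass weighting. Frame averages are arithmetic means; pooling across
independent runs is the default, with per-run grouping left to the caller
(the per-frame `tidy()` table carries everything needed).

Asphericity is computed from the eigenvalues $\lambda_x,\lambda_y,\lambda_z$
of the **mass-weighted gyration tensor**
$S = M^{-1}\sum_i m_i\,\Delta r_i\Delta r_i^{\mathsf T}$:
$$\alpha = 1 - 3\,\frac{\lambda_x\lambda_y + \lambda_x\lambda_z +
\lambda_y\lambda_z}{(\lambda_x+\lambda_y+\lambda_z)^2}.$$
A deliberate and load-bearing choice: with gyration-tensor eigenvalues the
limits come out as commonly quoted — 0 for an ideal sphere, 1 for an
infinitely thin rod, and exactly 1/4 for a flat disc (eigenvalues
$\lambda,\lambda,0$). Substituting true moment-of-inertia eigenvalues
instead would send a rod to 1/4, not 1, because inertia moments measure mass
*away from* each axis. The result is clipped to $[0,1]$ against round-off.

The Kirkwood hydrodynamic radius is the reciprocal mean reciprocal pair
distance, $R_h^{-1} = \langle r_{ij}^{-1}\rangle_{i\neq j}$, over heavy
atoms (element ≠ H) by default — hydrogens carry almost no hydrodynamic
weight and double the pair count. The sum is accumulated in blocks so a
$10^4$-atom selection never materialises the full distance matrix.
For a uniform ball of radius $R$ the closed forms
$R_g = \sqrt{3/5}\,R$, $R_h = 5R/6$ and therefore
$R_h/R_g = (5/6)/\sqrt{3/5} \approx 1.076$ anchor the tests. The
dense-sphere outer boundary is $\sqrt{5/3}\,R_g$, i.e. the radius of the
uniform ball with the observed $R_g$; note this Kirkwood $R_h/R_g$ is a
double-sum property, not the rigid-sphere hydrodynamic bound.

The terminal radius $R_e$ is the RMS radial distance of terminal-group
nitrogens from the dendrimer centre of mass, and spacer statistics are
plain histograms of distances between consecutive branching points,
normalised to unit integral.

## Radial profiles and the double layer

Profiles are histograms of mass or charge versus distance from the
dendrimer centre of mass, averaged over frames, on a regular grid
(default bin width 0.05 nm — fine enough that conservation closes to 0.1%
yet coarse enough that a few thousand atoms populate every occupied bin).
Two conventions matter:

* Mass density divides per-bin mass by the **exact** shell volume
  $\frac{4\pi}{3}(r_+^3 - r_-^3)$. The thin-shell approximation
  $4\pi r^2\Delta r$ under-counts the innermost bins by up to 30% and is
  not used.
* Charge is reported as a *linear* density $q(r)$ (e/nm), defined so that
  $\int q\,dr$ equals the selection's net charge exactly; the cumulative
  charge $Q(r) = \int_0^r q\,dx$ is its running (per-bin upper edge) sum.

The effective charge $Q^\*$ is the global maximum of $Q(r)$ over the
dendrimer-plus-counterions selection — the charge seen just outside the
condensed layer — and $R_{max}$ is the bin centre where it is attained,
taking the smallest $r$ on ties (ties arise on plateaus of exactly
conserved charge; the inner edge is the physically meaningful boundary).

The electrostatic potential solves the spherically symmetric Poisson
equation $\psi'' + \tfrac{2}{r}\psi' = -4\pi\lambda_B\rho_c(r)$ for the
dimensionless $\psi = e\Psi/k_BT$, with $\rho_c = q/4\pi r^2$, the symmetry
condition $\psi'(0)=0$, and the electroneutral-cell gauge $\psi(D)=0$ at
the cell radius $D$ (default $\sqrt{3}\,a_{cell}/2$ for a cubic cell of
edge $a_{cell}$ — the circumscribing radius, so the whole box is inside the
gauge point). Under exactly these conditions the ODE integrates in closed
form to
$$\psi(r) = \lambda_B\int_r^D \frac{Q(x)}{x^2}\,dx,$$
which the solver evaluates by trapezoidal quadrature on the bin-edge grid.
$Q$ at the edges is exact (a cumulative sum of bin charges), the integrand
at $r=0$ is set to 0 ($Q\sim r^3$ for any bounded density), and the scheme
is second order in the bin width: halving the bin quarters the error
against the uniformly charged ball's piecewise closed form, and at the
default 0.01 nm validation grid the relative error is below $10^{-4}$,
comfortably inside the 0.5% tolerance asserted in the tests. The zeta
potential is $\Psi(R_{max})$ in mV ($k_BT/e = 26.7$ mV at 310 K).

Two surface-charge conventions circulate for a sphere; the package uses
the areal density $\sigma = Q^\*/4\pi R_{max}^2$ as written, and reports it
without further interpretation — published tables sometimes carry a
diameter-based variant roughly 4x smaller, so cross-source comparisons of
$\sigma$ should check the convention first.

The Bjerrum length $\lambda_B = e^2/4\pi\varepsilon\varepsilon_0k_BT$
(0.70 nm in water at 298 K, 0.674 nm at 310 K) uses CODATA constants;
temperature enters only through it and through $k_BT/e$.

The soft-sphere cell model predicts the effective charge of a penetrable
charged sphere of radius $R$ in a cell of radius $D$ from
$$Q^\* = \frac{R}{\lambda_B}\,\frac{1}{2\nu}\,
\ln\!\Big[\Big(\frac{Q}{Q^\*}-1\Big)\Big(\frac{D^3}{R^3}-1\Big)\Big],
\qquad \nu = 3/5.$$
The right-hand side falls monotonically from $+\infty$ to $-\infty$ as
$Q^\*$ runs over $(0,Q)$, so a unique root exists; it is found by bracketed
root-finding plus a Newton polish to a self-consistency residual below
$10^{-10}$. One property worth recording: $Q^\*$ increases with $R$ only in
the dilute regime $R \ll D$. As $R$ approaches $D$ the free volume factor
$D^3/R^3-1$ collapses, condensation wins, and $Q^\*$ turns over (numerically,
for $Q=16$, $D=6.5$ nm the maximum sits near $R \approx 2.2$ nm). The test
suite therefore asserts monotonicity only for $R \le D/3$.

Ion pairs are counted from ion-to-charged-site distances: the contact peak
sits near 0.3 nm, and the default counting cut-off of 0.4 nm is the first
minimum beyond it; the cut-off is a parameter because the integration limit
of a contact peak is a convention, not a measurement. Osmotic ions follow
by bookkeeping, $\langle n_{osm}\rangle = Q - Q^\* - \langle
n_{pairs}\rangle$; a negative value is reported with a warning since it
signals inconsistent inputs (e.g. paired ions sitting outside $R_{max}$).

## Hydrogen bonds

Detection is geometric: donor–acceptor distance below `d_max` (default
0.35 nm) and near-linearity of D–H⋯A. "Near-linearity" is implemented the
way MD analysis tools usually do it — the angle at the **donor** between
the D–H and D–A vectors must not exceed `angle_max` (default 30°). A
literal "D-H-A angle < 30°" criterion, which one sometimes sees quoted,
would select strongly *bent* geometries (a linear bond has D-H-A ≈ 180°);
it is available behind `angle_def = "dha"` for comparison but is not the
default. Count series are partitioned by the roles of donor and acceptor
(intra-dendrimer, dendrimer–water, dendrimer–guest, counting both
directions of the cross partitions).

Continuous lifetimes average the lengths of maximal uninterrupted on-runs.
Runs touching either end of the observation window are excluded: their true
duration is censored, and including them biases the mean low for long-lived
bonds. An all-on series therefore has *no* measurable lifetime and raises
an error rather than returning the window length.

## Planar-group pairing

Each planar group (an imidazole or guanidine ring) is represented by three
non-collinear atoms defining its plane and a set of centre atoms whose
centroid is the group centre — the whole-ring centroid, not the triple's,
since stacking distances are between ring centres. The unit normal is the
cross product of two edge vectors (equivalent to the determinant form of
the plane equation); a triangle area below $10^{-6}$ nm² is rejected as
degenerate. The inter-plane angle folds the arbitrary normal signs away,
$\theta = \arccos|\hat n_1\!\cdot\!\hat n_2| \in [0^\circ, 90^\circ]$.

Pair matrices accumulate, per frame, every unordered group pair of a class
— *neighbouring* (same spacer) or *non-neighbouring* (different spacers) —
with centre distance under 1.8 nm into a $(\theta, r)$ histogram, default
bins 2° x 0.05 nm, averaged over frames. The 1.8 nm cut-off reflects the
topological reach of groups on a common spacer; more distant pairs carry no
stacking signal. The radial marginal sums over angle bins, and the
first-peak count $n_p$ sums the marginal below `r_cut_peak` (default
0.55 nm, bracketing the contact peak near 0.4 nm). The same 0.55 nm
threshold defines "pair formed" for the time-correlation analysis, keeping
$n_p$ and the kinetics consistent.

The intermittent pairing autocorrelation is
$$C(t) = \frac{\langle b(0)\,b(t)\rangle}{\langle b\rangle},$$
with $b(t)$ the 0/1 formation indicator averaged over pairs and time
origins; for a 0/1 signal $\langle b^2\rangle = \langle b\rangle$, so
$C(0)=1$ under this normalisation. Relaxation-time extraction from an
empirical ACF is under-determined, so the package defines it explicitly:
$\tau_{LF}$ is the time integral of $C$ up to its first crossing of
$e^{-1}$ (linearly interpolated) plus a single-exponential tail closure
with decay time equal to the crossing time. For a pure exponential this
returns the decay time exactly; integrating only to the crossing would
under-estimate by the factor $1-e^{-1}$, and integrating the raw tail of a
noisy ACF diverges. A pure crossing-time variant is exposed via
`method = "crossing"`. For a stationary two-state (telegraph) process with
mean sojourns $t_{on}, t_{off}$ the ground-truth correlation time is
$\tau_c = t_{on}t_{off}/(t_{on}+t_{off})$ with a plateau at the occupancy
$p = t_{on}/(t_{on}+t_{off})$; the estimator carries an $O(p)$ positive
bias from that plateau, which is why recovery tests run at low occupancy.

## Complexation

A guest molecule is "in complex" when at least one guest–host atom pair is
strictly closer than $s\cdot r_{ij,min}$, where $r_{ij,min}$ is the
separation at the minimum of the non-bonded pair potential for elements
$i,j$. The shipped table uses Lennard-Jones-style per-element radii
(H 0.12, C 0.38, N 0.365, O 0.33, Cl 0.44 nm) combined arithmetically —
typical biomolecular force-field magnitudes, supplied as data so users can
substitute their force field's actual minima. The factor $s$ (1.5 and 2.0
by default) makes the criterion deliberately generous; a well-separated
bound/unbound geometry gives identical counts at both values, which is the
insensitivity the defaults are meant to demonstrate. Bound status is
evaluated per frame with no hysteresis, and the complex radius of gyration
applies the mass-weighted $R_g$ to the union of host and currently bound
guest atoms, averaged over **all** frames (not only frames with a bound
guest — a documented convention, since the alternative conditions the
average on occupancy).

## Synthetic ground truth

The generators produce scenes whose analysis answers are known at
construction time:

* `gen_dendrimer()` samples beads uniformly in a ball — the dense-sphere
  idealisation of a compact dendrimer. It reproduces the target $R_g$,
  $R_h$ and $\alpha \to 0$ laws, and carries terminal/spacer charge
  bookkeeping (e.g. 16 terminal + 28 spacer unit charges give a bare
  charge of +44). It does **not** emulate connectivity, excluded volume,
  or density dips at the core.
* `gen_ion_cloud()` realises a schematic double layer: a chosen fraction of
  counterions inside a condensation radius, a chosen fraction of those in
  contact pairs at exactly `pair_distance` from a charged site, the rest
  uniform in the box. Rejection sampling keeps every non-paired ion at
  least `exclusion` (default 0.5 nm) from any charged site, so constructed
  pair counts are exact under any counting cut-off between the pair
  distance and the exclusion radius. Real double layers are smooth; this
  one is piecewise by design, so that $Q^\*$, ion-pair and osmotic counts
  have integer ground truths.
* `gen_planar_groups()` builds rigid equilateral triples at exact requested
  $(r, \theta)$, with pair clusters laid out more than 3 nm apart so no
  unintended pair enters the 1.8 nm window.
* `gen_telegraph_series()` draws alternating exponential sojourns with the
  initial state from the stationary distribution; by memorylessness the
  sampled series is exactly stationary. Exponential sojourns are the
  simplest process consistent with a single lifetime per bond class.
  Sampling at interval $\Delta$ merges on-runs whose separating off-sojourn
  misses every sample point (probability $\approx \Delta/2t_{off}$),
  inflating lifetimes by under 1% at the test settings.
* `gen_complex_scene()` places rigid 4-bead guests (net charge −2, split
  evenly) either in contact with the dendrimer (one bead at `contact_gap`)
  or with every bead over 2 nm away, measuring separation from dendrimer
  atoms only, never from the counterion cloud.

Passing tests on these scenes certify the estimators — the geometry,
histogramming, quadrature, counting and lifetime machinery — under known
truth. They do not certify force fields, sampling quality, or any claim
about real dendrimer chemistry; configurational realism (connectivity,
water structure, correlated fluctuations) is explicitly out of the
generators' scope.

## Problem sizes and determinism

The shipped test suite and the acceptance script size their simulations for
statistical headroom at interactive runtimes: $10^5$ beads for uniform-ball
$R_g$ (1% tolerance), $10^4$ for the Kirkwood radius (2%), $10^6$ sampled
pair-frames for lifetime recovery (5%), $8\times10^6$ for ACF relaxation
recovery (10%), and 0.01 nm grids for the Poisson validation (0.5%).
Every stochastic step takes an explicit seed; generators save and restore
the caller's RNG state. Pipeline outputs print numbers at 4 significant
digits so reruns diff bit-identically.

## Known limitations

* Periodic images are not unwrapped; analyses assume molecules are compact
  within the frame. Minimum-image corrections are the caller's job.
* The Poisson stage is a direct quadrature of the *measured* charge
  distribution — not a Poisson–Boltzmann self-consistent solve — and
  assumes spherical symmetry and a salt-free cell (counterions only).
* Stokes radii from diffusion coefficients are out of scope (they need
  dynamics, not configurations); $R_h$ here is always the Kirkwood
  estimate.
* The H-bond search is all-pairs within the donor/acceptor lists; it is
  intended for solute-scale selections, not for full explicit-water boxes.
* `Q^\*` extraction assumes the cumulative charge has a genuine interior
  maximum; flat or monotone profiles (no counterions in the selection)
  raise errors instead of guessing.
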