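---
title: "Coarse-grained steered dynamics of beta-rich folds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained steered dynamics of beta-rich folds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gopull simulates the mechanical unfolding of beta-rich protein modules with
a Calpha Go-like model pulled at constant velocity under Langevin dynamics,
and analyzes the resulting force spectra: maximum-unfolding-force
distributions, averaged force-extension curves, and qualitative unfolding
scenarios. This vignette is the package's own account of the model, its
parameters, the numerical machinery, and what the synthetic test systems do
and do not show.

## The coarse-grained model

Each residue is a single bead at its Calpha position carrying the average
residue mass of its amino-acid type. Consecutive beads are connected by
bonds fixed at their native lengths and treated as holonomic constraints, so
the stiffest degrees of freedom are removed rather than integrated. Bond
angles are harmonic around the native angle,
$V_\theta = \tfrac12 k_\theta (\theta-\theta_0)^2$, and each quadruplet of
consecutive beads carries a single-cosine torsion
$V_\phi = k_\phi\,[1 - \cos(\phi-\phi_0)]$ referenced to the native dihedral.

Structure defines the attractive interactions: residue pairs in contact in
the native structure (and only those) interact through the modified
Lennard-Jones well

$$V_{ij}(r) = \varepsilon_{ij}\left[\,13\left(\frac{\sigma_{ij}}{r}\right)^{12}
 - 18\left(\frac{\sigma_{ij}}{r}\right)^{10}
 + 4\left(\frac{\sigma_{ij}}{r}\right)^{6}\right],$$

whose minimum of depth $-\varepsilon_{ij}$ sits exactly at the native pair
distance $r = \sigma_{ij}$ and which carries a small desolvation-like barrier
(height $\approx 0.143\,\varepsilon$ at $r \approx 1.449\,\sigma$, located by
a dense numeric scan) before the attractive tail decays. All remaining pairs
separated by more than `min_seq_sep` bonds repel as
$\varepsilon_{rep}(\sigma_{rep}/r)^{12}$, which keeps the chain from passing
through itself.

Native contacts are detected by a distance criterion: for all-atom input,
any heavy-atom pair across two residues within 4.5 Å; for Calpha-only input
(the synthetic structures), a Calpha-Calpha distance within 6.5 Å. In both
schemes pairs closer than five residues apart (`j - i <= 3`) are excluded:
the (i, i+2) and (i, i+3) geometry is governed by the angle and torsion
terms. Backbone N(i)...O(j) pairs within 3.5 Å mark native hydrogen bonds;
hydrogen-bonded contacts have their well depth multiplied by `hbond_factor`.
Beta-strand mechanics in this class of model is dominated by these
cross-strand contact clusters ("force clamps"), so the hydrogen-bond bonus
is the main knob controlling rupture forces.

### Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `epsilon` | 1.0 | kcal/mol | contact well depth (uniform scheme) |
| `hbond_factor` | 1.5 | — | well-depth multiplier for H-bonded contacts |
| `k_theta` | 40 | kcal mol⁻¹ rad⁻² | angle stiffness |
| `k_phi` | 1.0 | kcal/mol | torsion amplitude |
| `sigma_rep`, `epsilon_rep` | 4.0 Å, 0.01 kcal/mol | | excluded volume |
| `timestep` | 0.01 | ps | integration step (10 fs) |
| `temperature` | 300 | K | thermostat target |
| `friction` | 0.5 | ps⁻¹ | Langevin coupling (sensitivity knob) |
| `speed` | 0.025 | Å/ps | anchor velocity |
| `spring_constant` | 100 | pN/Å | pulling spring |

The well depth is deliberately generic: the published statistical
parameterizations of this model family assign per-pair energies from folding
thermodynamics, which is out of scope here, and the absolute force scale
tracks `epsilon` nearly linearly. Two assignment schemes are exposed —
`uniform` (all wells equal) and `statistical` (pair wells weighted by the
product of shifted Kyte–Doolittle hydropathies of the two residues,
renormalized so the mean equals the configured value). The statistical
scheme is this package's own weighting, not a reproduction of any published
energy table; users comparing against experimental forces should calibrate
`epsilon` on a reference system first.

The angle and torsion constants are not taken from any published set either:
`k_theta = 40 kcal mol⁻¹ rad⁻²` keeps strands locally stiff without freezing
the chain, and `k_phi = 1 kcal/mol` is of the order of a contact well so
torsional barriers neither dominate nor vanish. The friction default
0.5 ps⁻¹ is a light coupling that thermostats reliably while perturbing the
conservative dynamics little; it is configurable and results that depend on
it should be checked across a range.

### Units

Internally: Å, ps, Da, kcal/mol, with $k_B = 0.0019872$ kcal mol⁻¹ K⁻¹.
Forces convert to pN at the reporting boundary with
1 kcal mol⁻¹ Å⁻¹ = 69.477 pN, which is why a 4 kcal mol⁻¹ Å⁻² spring is the
familiar 278 pN/Å.

## Integration and constraints

The integrator is a BAOAB-splitting Langevin scheme: half kick, half drift,
Ornstein–Uhlenbeck velocity update, half drift, half kick. Holonomic bond
constraints are enforced after every drift by a SHAKE-type solver and
velocities are projected back onto the constraint manifold (RATTLE) after
every kick and after the stochastic update. Because the constrained bonds
form a simple chain, the Lagrange-multiplier system is tridiagonal and is
solved exactly (Thomas algorithm) inside a Newton iteration, with constraint
impulses directed along the pre-drift bond vectors. Two numerical points
deserve mention:

* Gauss–Seidel SHAKE converges painfully slowly on *perfectly collinear*
  bead triplets — and idealized beta strands are exactly collinear — which
  is why the direct tridiagonal solve is used.
* Directing the constraint impulses along current rather than reference bond
  directions looks equivalent at first order but breaks time reversibility
  and produces a visible energy drift; the reference-direction form
  conserves energy to the expected bounded oscillation.

In the frictionless, zero-temperature limit the scheme reduces to velocity
Verlet with SHAKE/RATTLE: total energy then shows a bounded oscillation of
order (ω dt)² (about 0.2% of the total here) and a secular drift two orders
of magnitude smaller. The acceptance check therefore measures *drift* — the
difference between the time-averaged energy at the start and end of the run
— not the oscillation amplitude.

The torsion angle is singular when three consecutive beads become collinear.
Native quadruplets with a near-collinear flank (sin θ₀ ≤ 0.2; all
intra-strand quadruplets of the idealized geometries) are excluded at build
time — a straight strand has no meaningful torsion reference. At run time
the remaining torsions are multiplied by a smooth switch
$S(\sin^2\theta)$ per flanking angle (smoothstep from 0 at
$\sin^2\theta = 0.01$ to 1 at $0.16$), differentiated alongside, so the
force field stays C¹ when the chain straightens under load. A hard cutoff
here injects energy at every crossing and visibly heats the system.

## The pulling protocol

The first bead is held fixed; the last is tethered by a 3-D harmonic spring
of stiffness K to a dummy anchor that starts on the bead and moves at
constant speed v along the native N-to-C direction. The reported force is
$F = K (D - D_0)$ with D the anchor-to-bead distance and $D_0$ its value
when pulling starts (after 10⁴ unbiased equilibration steps). Note that D is
a scalar distance: at low loads its thermal lateral component biases the
mean force upward by roughly $K\,\langle\Delta_\perp^2\rangle/2D$, which is
negligible once the axial stretch dominates.

Recording (default every 100 steps = 1 ps) stops at 80% of the contour
length $(N-1)\times3.8$ Å by default. Beyond that point every native
contact has long ruptured and the spring is simply straightening a taut
backbone; the force there rises steeply with the angle stiffness and carries
no information about unfolding. Published spectra in this field likewise end
well before full stretch. A detachment guard additionally excludes the final
2% of the recorded extension range from the F_max search.

Each replica differs only in the Maxwell–Boltzmann velocity assignment
(and thermostat noise), seeded as `base_seed + replica - 1`. Trajectories
are bit-reproducible for a fixed seed: the noise stream is a
mt19937_64/Box–Muller generator implemented in the package, so it does not
depend on any library's unspecified distribution algorithm.

## Analysis

* **Running averages** are centered moving means with shrinking edge
  windows; the default window (51 samples = 51 ps) matches what smoothed
  published spectra look like. The scenario classifier caps the window at
  10% of the trace so short traces are not edge-distorted. When spectra at
  *different pulling speeds* are compared (the speed scan), the window is
  converted to a fixed stretch of anchor travel (1.275 Å, the default
  window at the reference speed): a fixed-duration window smooths a
  ten-fold faster pull over ten times more extension and clips its rupture
  peaks correspondingly harder, while the slower run records ten times more
  samples whose thermal force spikes inflate an under-smoothed maximum —
  biases large enough to invert the apparent speed dependence.
* **F_max** is the global maximum of the smoothed force inside the guard
  region; the extension and time at that sample are reported with it.
* **Force distributions** are fitted with one- and two-component Gaussian
  mixtures (EM via mclust); BIC selects the description, and the
  two-component (bimodal) form must improve BIC by more than 2 points to be
  preferred. Both candidates are always reported.
* **Scenario labels**: contacts are split at the chain midpoint by the
  midpoint of their bead pair; at the first major force peak (peaks are
  prominence-merged so noise bumps on a rising flank coalesce into the
  rupture peak they precede) the cumulative rupture fractions of the two
  halves are compared (margin δ = 0.2, intermediate threshold 0.3, both
  configurable since the underlying classification is qualitative). Each
  peak is read out where its rupture has completed — the force fallen to
  half the peak value, or the valley before the next peak — because the
  distance-criterion rupture flags lag the force maximum by a few frames.
  C-half leading → type C, N-half → type N, both engaged without a leader →
  type NC, neither engaged → type 0. The same rule is evaluated at the
  largest later peak; "/0" is appended when no secondary peak exists.

## The synthetic structures

The generators produce idealized geometries on textbook beta-lattice
parameters (3.4 Å rise, 4.8 Å inter-strand spacing, 10 Å sheet separation,
3-residue loops): an antiparallel two-strand hairpin whose 14+3+14 layout
matches the 31-residue fibroin-H-like fragment, with optional pseudo-backbone
N/O atoms placed to give one ideal 2.9 Å hydrogen-bond geometry per
registered cross-strand pair (13 when the turn-adjacent pair donates its
carbonyl to the turn, as in real hairpins); and flat two-sheet sandwiches
with a configurable strand count, strands-per-sheet split and
sequence-to-slot permutation, emulating 7-strand FnIII-like and 13-strand
LNS-like topologies. Everything is deterministic given the specification.

What they deliberately do **not** have: sheet twist and pleat, side chains,
sequence-specific contact energies, or realistic loop conformations. Tests
passing on these systems therefore validate the *machinery* — contact
detection, integration, statistics — under controlled geometry; they do not
certify quantitative force predictions for real proteins, which additionally
require calibrated per-pair energies and real structures.

### What the hairpin ensembles show

Pulling the hairpin apart at its termini unzips the cross-strand rungs
sequentially. With uniform well depths the fully-zipped state is the
strongest point: the force peak is the *first* rupture, after which
unzipping proceeds at a lower plateau (~100–130 pN at the defaults). A
first-rupture force under a ramping load is an extreme-value statistic: its
distribution has a heavy right tail (replicas whose terminal cluster
survives to high load) and is measurably right-skewed, and ensembles of
~200 replicas reliably *fail* strict normality tests even though the bulk
looks Gaussian. Near-Gaussian maximum-force distributions arise when the
global maximum samples a mid-path collective clamp, as happens with
heterogeneous (statistically parameterized) well depths in real folds; the
acceptance script reports the ensemble's skewness and Shapiro–Wilk p-value
so this property is measured rather than assumed.

## Problem sizes

Dynamics-heavy checks run at deliberately compact sizes: the 31-bead hairpin
(1 ns thermostat run; 200-replica pulling ensembles recorded to 40% of
contour, which comfortably brackets every observed force peak at under 20%
of the path) and a 29-residue four-strand sandwich for the speed scan
(20 replicas per speed, recorded to 55% of contour; peaks sit below 40%).
The analysis scripts under `analysis/` use the same systems with replica
counts stated in each script.

## Known limitations

* Uniform contact energies invert one feature of heterogeneous models: the
  force maximum of the zipper sits at the first rupture rather than
  mid-path (discussed above).
* The torsion switch slightly weakens torsions whose flanking angles sit
  between 156° and 174°; native beta geometry is far from this window, but
  strongly bent custom inputs would feel it.
* The scalar-distance force definition carries a small positive bias at low
  loads (lateral thermal motion of the pulled bead).
* Scenario classification compresses a continuum of pathways into four
  labels with configurable thresholds; treat the labels as qualitative.
* No solvent, no side chains, no constant-force mode, single chains only.
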