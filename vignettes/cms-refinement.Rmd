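---
title: "Refining docked protein-protein complexes in contact map space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining docked protein-protein complexes in contact map space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmsrefine)
```

## The problem

Rigid-body docking often places a ligand protein within, or on the edge of,
the native binding funnel of its receptor, but rarely at atomic accuracy.
Local refinement asks: given one docked pose (and possibly an ensemble of
similar poses from several docking methods), can we sample nearby
conformations that are closer to the native complex, recognize them, and
assemble them into a single better model?

`cmsrefine` implements a complete refinement pipeline around a scalar
*contact map space* (CMS) collective variable:

1. build an interface contact map from the docked ensemble (`build_cmif()`);
2. bias sampling along the CMS coordinate with well-tempered metadynamics —
   at desk scale through a surrogate Langevin sampler
   (`run_toy_sampler()`), at production scale by exporting a PLUMED input
   (`export_plumed()`);
3. reconstruct the free energy surface (FES) along the CMS
   (`reconstruct_fes()`);
4. score trajectory snapshots with an interface energy score and with the
   mixed function CS\_alpha (`score_table()`, `cs_alpha()`);
5. quantify how well a scoring variant ranks snapshots
   (`ranking_error()`, `alpha_n_sweep()`);
6. average the best snapshots into a refined model and relax it
   (`build_model()`);
7. assess models with the CAPRI metrics FNAT / LRMSD / IRMSD
   (`assess_model()`).

## The contact map space coordinate

A receptor residue and a ligand residue form an *interface contact* when
their C-alpha atoms are closer than 8 Angstrom (strictly below; boundary
equality is excluded). The contact map `CM_if` is the union of such contacts
over an ensemble of docked solutions; each contact stores a reference
distance `r0` (by default the mean over the members exhibiting it — the
least committal pooling; median is available) and a support count. By
default no support filtering is applied (`min_support = 1`), so a contact
seen in a single member still shapes the coordinate.

Contact formation is quantified by the rational switching function

$$D(r) = \frac{1 - (r/r_0)^n}{1 - (r/r_0)^m}, \qquad n = 6,\; m = 10,$$

and the scalar CMS coordinate of a structure $R$ is

$$\mathrm{CMS}(R) = \sum_{\gamma \in CM_{if}} \left(D_\gamma(R) - D_{ref}\right)^2 .$$

At $r = r_0$ the switching function has a removable singularity with limit
$n/m = 0.6$; we therefore fix $D_{ref} = 0.6$, which makes the reference
term constant and `cms_value()` exactly zero for any structure reproducing
all reference distances. (The alternative — per-member reference values —
would make the reference term depend on which member is evaluated; with
$r_\gamma = r_{\gamma 0}$ the switching value is pinned to 0.6 anyway, so
the constant reading is the consistent one. The exponents, cutoff and
pooling rule are all arguments of `build_cmif()`.)

**Numerical evaluation.** The naive form of $D$ suffers catastrophic
cancellation near $x = r/r_0 = 1$. `switching_D()` evaluates the equivalent
geometric-sum form
$(1 + x + \dots + x^{n-1})/(1 + x + \dots + x^{m-1})$, which is exact at
$x = 1$ (returning 0.6 to the last bit for the default exponents) and
smooth everywhere else, so no tolerance guard is needed.

## Well-tempered metadynamics engine

The bias is a sum of Gaussian kernels deposited along the CMS coordinate
every `pace_ps` (default 2 ps) with width `sigma = 0.5` and initial height
5 kJ/mol. Heights follow the standard well-tempered damping

$$h_k = h_0 \, e^{-V(s_k)/k_B \Delta T}, \qquad \Delta T = (\gamma - 1)T,$$

with bias factor $\gamma = 10$ and $T = 300$ K by default; $\gamma = \infty$
recovers standard metadynamics with constant heights. The free energy
estimator is the standard well-tempered form
$F(s) = -\frac{\gamma}{\gamma - 1} V(s)$, shifted so its minimum is zero.
Both rules are documented constants of the engine. FES profiles can also be
reconstructed from PLUMED HILLS files (`read_hills()`), so the same
analysis applies to production runs.

### The surrogate sampler

Explicit-solvent molecular dynamics is out of scope by design: the sampler
(`run_toy_sampler()`) propagates a single scalar coordinate by overdamped
Langevin dynamics in an analytic potential, which exercises every part of
the bias machinery (deposition, tempering, reconstruction, replicas)
without an MD engine. Five replicas with distinct seeds, mirroring the
replicated production protocol, are run by `run_replicas()`; each replica
keeps its own bias state, and per-replica FES profiles are the default for
scoring that replica's snapshots (a pooled mean FES is a caller-side
one-liner).

Numerical choices, made once and verified by the test suite:

* **Integrator.** The noise term uses the Leimkuhler-Matthews scheme — the
  average of the current and previous Gaussian increments — instead of
  plain Euler-Maruyama. Euler's $O(\Delta t)$ configurational bias distorts
  the sampled landscape by $\approx \frac{\Delta t}{4\gamma_f}U'(s)^2$,
  which reaches several kJ/mol on the steep walls of the reference
  double-well; the LM scheme removes this at identical cost while leaving
  the drift term, the marginal noise variance and seed-determinism
  unchanged.
* **Toy-system defaults.** Friction 1/ps and timestep 0.02 ps keep the
  stiffness ratio $U''\Delta t/\gamma_f \le 0.75$ at the stiffest point of
  the reference double-well (stable and accurate for the LM integrator)
  while letting $10^6$ steps cover 20 ns of dynamics.
* **Kernel evaluation.** `bias_energy()` is exact summation over kernels.
  Inside the sampler the walker's bias energy and force are interpolated
  from a uniform grid (spacing 0.05 CV units $= \sigma/10$) updated at
  every deposit; the cached values agree with exact summation at the grid
  nodes to floating-point precision (enforced in the tests), and deposit
  heights themselves always use exact summation.
* **Divergence guard.** A non-finite coordinate aborts with advice to
  reduce the timestep.

### The double-well test bed

`double_well()` provides the quartic
$U(s) = B\,((s/a)^2 - 1)^2$ with analytic gradient, minima at $\pm a$ and
barrier exactly $B$ at $s = 0$. The default separation ($2a = 6$ CV units)
keeps the wells several kernel widths wide for the standard
$\sigma = 0.5$: that mirrors the production regime, where $\sigma = 0.5$
sits on a CMS range of tens of units, and a narrower well would test the
method outside its operating regime. With a 15 $k_BT$ barrier
(37.4 kJ/mol) and the defaults above, a single $10^6$-step run crosses the
barrier repeatedly and reconstructs the potential with RMSE below 1 kJ/mol
over the visited range (defined as the 0.5-99.5% quantile range of the
sampled coordinate — outside it the estimator is undefined by
construction, as hardly any kernels were deposited there), locating both
minima within one 0.1-unit grid spacing.

## Snapshot scoring and CS_alpha

Snapshots are scored by two components:

* an **external interface score** (lower = better, the convention of
  empirical docking scores). The built-in surrogate
  (`surrogate_interface_score()`) is a deterministic additive stand-in: a
  soft Lennard-Jones term over heavy-atom interface pairs within 10
  Angstrom ($\varepsilon = 0.2$ kJ/mol, $\sigma = 3.5$ Angstrom, repulsion
  linearized below 2.5 Angstrom), a screened Coulomb term between
  side-chain charge centers (ARG/LYS/HIS +1, ASP/GLU -1, screening length
  8 Angstrom), and a desolvation proxy of -0.2 kJ/mol per residue-residue
  contact. Scores from a real scorer can be supplied as a TSV table
  (`read_external_scores()`) and used everywhere the surrogate would be.
* the **free energy** of the snapshot's CMS value, linearly interpolated
  from the reconstructed FES (`attach_fes()`; values outside the grid are
  clamped to the nearest edge with a warning).

Both components are normalized to [0, 1] with 1 = best
(`normalize_01()`), so the mixed score

$$CS_\alpha = \alpha\,\mathrm{ZRANK}_\eta + (1 - \alpha)\,\mathrm{FES}_\eta$$

is higher-is-better for every $\alpha$, and predicted ranks are the
descending order of $CS_\alpha$. Normalization is performed over all
snapshots of a target pooled across replicas (pass per-replica subsets for
the per-replica alternative). A constant score vector maps to all 0.5 — a
documented degenerate rule that keeps $CS_\alpha$ defined without
privileging either component.

## Ranking error

The reference rank of a snapshot is its position in ascending order of
LRMSD to the reference crystal structure (rank 1 = best; ties broken by
replica then time, deterministically). Ranks are capped at `max_rank`
(default 100, the upper end of the selection-depth sweep; the cap is fully
configurable). For a selection of the $n$ top-scored snapshots per target,

$$\varepsilon = \sum_{TR}\sum_{i \in C_{:n}} \mathrm{rank}(r_i), \qquad
\varepsilon_\eta = \frac{\varepsilon - rank_{min}}{rank_{max} - rank_{min}},$$

with $rank_{min} = |TR|\,n(n+1)/2$ (perfect selection) and
$rank_{max} = |TR|\,(max+1)\,n$. Note that the worst capped rank is $max$,
not $max + 1$, so $\varepsilon_\eta$ cannot reach exactly 1; the formula
is implemented as printed and the slack is intentional.
`alpha_n_sweep()` evaluates $\varepsilon_\eta$ over a grid of $\alpha$ and
$n$ and reports the best $\alpha$ per selection depth.

## Model building

`build_model()` implements the ensemble-averaging strategy: select the $n$
best-scored snapshots (default $n = 14$, selection by the normalized
external score — the recommended generic choice; $CS_\alpha$ selection is
available for acceptable-quality workflows), superpose each onto the
best-scored one using receptor C-alpha atoms, average equivalent atomic
coordinates, and relax the average. All atoms present in every snapshot are
averaged. The superposition step is needed because arbitrary frame lists do
not share a simulation box; the receptor frame is the natural choice since
it is also the CAPRI reference frame.

Relaxation (`relax()`) is a lightweight restrained steepest descent, not a
force-field minimization: soft-sphere repulsion between non-bonded heavy
atoms (onset 2.8 Angstrom), a harmonic tether to the input coordinates,
and flat-bottom restraints on bonded distances. Its only contract is the
stated purpose of the post-averaging step — resolve non-physical local
geometry with minimal displacement: the heavy-atom clash count (non-bonded
pairs < 2 Angstrom) never ends above its initial value, the energy sequence
is non-increasing (backtracking line search), and a clash-free input is
returned essentially unchanged.

## CAPRI assessment

* **FNAT**: fraction of reference interface residue-residue contacts
  (any heavy-atom pair < 5 Angstrom) reproduced by the model.
* **LRMSD**: ligand C-alpha RMSD after optimal superposition of the
  receptor C-alpha atoms.
* **IRMSD**: C-alpha RMSD over reference-defined interface residues
  (any-atom < 10 Angstrom — a documented variation from the classic CAPRI
  interface definition, and the one this pipeline uses) after fitting on
  those same atoms.

Residues are mapped between model and reference by chain + author residue
number + insertion code; no sequence-alignment fallback. Hydrogens are
excluded from contact criteria so models with and without protons assess
identically. Quality classes use the standard CAPRI thresholds (high:
FNAT >= 0.5 and LRMSD <= 1 or IRMSD <= 1; medium: FNAT >= 0.3 and
LRMSD <= 5 or IRMSD <= 2; acceptable: FNAT >= 0.1 and LRMSD <= 10 or
IRMSD <= 4), evaluated from high downward; classification is monotone in
each metric. Superposition uses the Kabsch algorithm with a
proper-rotation (det = +1) correction.

## Synthetic fixtures: what they do and do not show

Every stage is testable without downloads through `make_toy_complex()`,
`make_decoy_ensemble()` and `make_synthetic_trajectory()`:

* **Toy complexes** are two gently curved bead chains (exact 3.8 Angstrom
  C-alpha spacing; an idealized helix variant is available) running
  roughly parallel 4.8 Angstrom apart, each residue carrying a C-alpha
  plus pseudo side-chain heavy atoms (CB, O) so that any-atom contact
  criteria and the surrogate score are exercised separately from
  C-alpha-only logic. Receptor side chains reach into the interface and
  pair with the ligand backbone at ~3.8 Angstrom — comfortably inside the
  5 Angstrom contact criterion and near the Lennard-Jones optimum — while
  ligand side chains point away, so interface quality degrades smoothly
  with any rigid-body motion rather than flipping on a knife edge.
  Residue names cycle through a fixed set including charged types to
  exercise the Coulomb term.
* **Decoy ensembles** are rigid ligand perturbations of graded magnitude
  (rotation of 2 degrees per Angstrom of translation, random axis and
  direction), with the true LRMSD of every decoy computed and returned —
  a monotone quality ladder with at least one member per grade.
* **Synthetic trajectories** are Ornstein-Uhlenbeck walks of the rigid
  ligand pose attracted toward the native pose, emulating the downhill
  drift of a refinement run; attraction strength and noise are tunable,
  and zero attraction with zero noise yields constant frames.

These fixtures are deliberately *not* physically realistic: no backbone
flexibility, no sequence realism, no solvent, and rigid-ligand trajectories
only. Passing tests therefore demonstrate the correctness of the geometry,
the bias mathematics, the scoring conventions and the selection/averaging
machinery — not refinement performance on real proteins, which depends on
force fields and sampling far outside desk scale. The problem sizes used in
the tests (30 + 20 residue complexes, 40-80 frame trajectories, 10-seed
medians, one million sampler steps) were chosen as the smallest sizes at
which each property is stably exhibited.

## A worked desk-scale example

```{r example, eval = FALSE}
set.seed(1)
truth <- make_toy_complex(jitter = 0.1, seed = 1L)
start <- make_decoy_ensemble(truth, magnitudes = 5, seed = 1L)$members[[1L]]

# contact map from a small docked ensemble around the start
ens <- c(list(start),
         make_decoy_ensemble(truth, magnitudes = c(4, 5, 6), seed = 2L)$members)
cmap <- build_cmif(ens)

# synthetic refinement trajectory + scoring
trj <- make_synthetic_trajectory(truth, start, n_frames = 40L,
                                 funnel_strength = 0.15, noise = 0.4,
                                 seed = 1L)
tab <- score_table(trj$frames, replica = rep(1L, 40L),
                   time_ps = trj$time_ps, cmap = cmap)

# ensemble-averaged model from the 14 best snapshots
built <- build_model(trj$frames, tab, n = 14L)
assess_model(built$model, truth, start = start)
```

## Known limitations

* One-dimensional CV only; no multi-CV or replica-exchange metadynamics.
* The surrogate sampler moves a scalar coordinate, not atoms: snapshot
  structures for scoring come from trajectories (synthetic or imported as
  PDB frame lists), not from the sampler itself.
* Residue mapping is by identifier; models renumbered relative to the
  reference are not assessed.
* The relaxation potential resolves clashes; it does not produce
  force-field-quality geometry.
* GROMACS binary trajectory formats are not parsed; convert to multi-model
  PDB or per-frame PDB lists first.
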