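---
title: "Internal-coordinate Monte Carlo minimization for ion-channel state modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-coordinate Monte Carlo minimization for ion-channel state modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(channelmcm)
```

## The modelling problem

Voltage-gated calcium channels such as the cardiac L-type channel couple
voltage sensing to pore opening through large, slow conformational changes
for which experimental structures exist only in a few states.  A productive
way to study state-dependent interactions — for example, how the
alpha-interaction domain (AID) of the I/II linker moves along the beta
subunit while keeping its polar contacts with the repeat-II voltage-sensing
domain, or how disease mutations perturb those contacts — is to build
models of the channel in several functional states and compare the
residue-residue contact energies between them.

`channelmcm` implements the computational machinery of that approach as a
reusable package:

1. a molecular model in **internal (generalized) coordinates** — torsion
   angles plus, for each covalently independent segment, the position and
   Euler orientation of a root atom triple — with rigid bond lengths and
   angles (prolines and vicinal-disulfide cysteines get flexible bond
   angles);
2. a **nonbonded energy** (Lennard-Jones 6-12 with arithmetic/geometric
   combining rules plus Coulomb with a distance-dependent dielectric), a
   9 Å cutoff with a shifting function, and no cutoff at all for pairs of
   ionized-group atoms;
3. **flat-bottom parabolic restraints**: alpha-carbon "pins" to template
   positions, interatomic distance windows, backbone torsion windows, and
   alpha-helical O(i)–N(i+4) hydrogen-bond restraints;
4. a **Monte Carlo minimization (MCM)** engine: random perturbation of one
   generalized coordinate (or a rigid-body move of one segment), bounded
   local minimization, Metropolis acceptance of minimized energies, and a
   windowed no-improvement convergence rule;
5. the three **pipeline stages** of the approach: homology threading with
   a three-trajectory protocol, steered transformation between gating
   states, and double-shell mutant sampling;
6. **contact-energy analysis**: residue-pair energy maps between named
   segment groups, geometric interaction typing, display binning at the
   printed thresholds, cross-state comparison, and net-energy aggregation.

Everything runs at desk scale on a deterministic synthetic toy channel, so
the full pipeline is testable without downloading structures.

## The energy model

Nonbonded energy is the only physical term; bonded terms are unnecessary
because bond lengths and angles are rigid in internal coordinates.  For an
atom pair at distance $r$:

$$E(r) \;=\; \varepsilon_{ij}\!\left[\left(\tfrac{R_{ij}}{r}\right)^{12} -
2\left(\tfrac{R_{ij}}{r}\right)^{6}\right] \;+\;
\frac{332.06\,q_iq_j}{\epsilon(r)\, r}, \qquad \epsilon(r) = 4r,$$

with $R_{ij} = R_i + R_j$, $\varepsilon_{ij} =
\sqrt{\varepsilon_i\varepsilon_j}$, charges in elementary units and
332.06 kcal·Å/(mol·e²) as the Coulomb constant.  Pairs separated by one or
two bonds are excluded, three-bond pairs are scaled by 0.5.  The cutoff
(default 9 Å) uses a shifted-force scheme by default — both the energy and
its derivative vanish at the cutoff, which the minimizer needs; a
shifted-energy variant is available for comparison.  Pairs in which both
atoms belong to ionized groups (guanidinium, ammonium, carboxylate,
protonated imidazole) bypass the cutoff entirely.  Contact *reporting*
uses no cutoff so tables do not depend on the truncation radius.

The distance-dependent dielectric $\epsilon(r)=4r$ is a deliberate
simplification: the environment-dependent refinement used in the original
line of work is specified only by citation, so this package implements the
distance-dependent core and documents the divergence.  The acceptance
surface is oracle- and property-based, not absolute-energy-based, so any
self-consistent parameter set serves; the shipped topology is a minimal
united-atom library (nonpolar hydrogens merged into their carbons, polar
hydrogens explicit) with neutral sidechains summing to zero charge and
charged ones to ±1.

Whether intrinsic torsion potentials were part of the original energy is
not stated in the source; the default here is nonbonded + restraints only,
with an `extra_energy` hook on the objective for analytic terms (the test
suite uses it for closed-form landscapes).

## Restraints

All restraint flavours share one functional form: zero inside a tolerance
window, $k(\Delta - d)^2$ beyond it.  The pin constants ($k = 10$
kcal·mol⁻¹·Å⁻², $d = 1$ Å by default; 2.5 Å for the bedplate/beta subunit,
2 Å for non-steered sensors) are the published ones.  Distance windows are
"pins on a distance"; the helical H-bond restraint is a distance window on
O(i)–N(i+4) with target 3.0 ± 0.3 Å (the source gives no numeric target;
ideal helical geometry scores ≈ 0 under these values); torsion windows
default to 5° half-width with $k = 0.1$ kcal·mol⁻¹·deg⁻² (force constant
unspecified in the source).

## The MCM engine

One MCM step perturbs a single flexible coordinate — torsions are
resampled uniformly in (−180°, 180°], root positions nudged by a 0.5 Å
Gaussian, orientations by 10° — or, with configurable probability, applies
a rigid-body move to one whole segment.  The perturbed system is locally
minimized (L-BFGS with analytic gradients: pair forces projected onto the
generalized coordinates) under an iteration cap, and the minimized energy
enters a Metropolis test at 600 K against the current minimized energy.
The temperature is a package choice (unstated in the source; 600 K is
conventional for conformational search), as is the interpretation that
acceptance compares candidate-minimum against current-minimum energies.  A
trajectory terminates when a window of consecutive minimizations (2000 at
production settings) fails to improve the lowest energy found.

The steered driver interpolates restraint anchors linearly from start to
target over a fixed number of stages (10 by default; the stepping is the
package's choice).  Each stage first runs a small number of deeper
"relaxation" minimizations that absorb the anchor step, then a short MCM
leg whose minimizations are capped at 100 iterations so consecutive
accepted points stay structurally close.  The final stage runs to the
convergence window, after which a stability leg without the steering
restraints is computed and the alpha-carbon drift it causes is reported
(no hard threshold — drift is a diagnostic, matching the stability-check
role of the unconstrained follow-up run).

## Pipeline stages

**Homology threading** copies the template's generalized coordinates onto
the model sequence (backbone torsions and segment roots; sidechains of
aligned identical residues), starts mismatched residues from all-trans
sidechains, and optimizes in three consecutive MCM trajectories: sidechain
torsions only; all coordinates under 1 Å alpha-carbon pins to the
template; and unpinned.  The final alpha-carbon RMSD to the template is
reported after least-squares superposition (models are compared after
fitting, as is standard; without the fit the free toy assembly's rigid
drift would dominate the number).

**Steered transformation** drives pore-domain alpha carbons (S4–S5, S5
and S6 ranges in the universal nomenclature; on the toy, the outer-helix
ring and the cytoplasmic two thirds of each gate helix, mirroring the
partial published ranges) to their positions in the target state, with
steering windows at the published default pin half-width (1 Å; the force
constant, unstated in the source, is raised to 150 kcal·mol⁻¹·Å⁻² so the
targets hold against the strained closed ring).  Companion restraints:
helical H-bonds on S4–S5/S5, 5° backbone torsion windows on the AID helix
and the C-terminal third of each S6, soft bedplate pins (2.5 Å), the
AID–bedplate separation cap, and either a sensor-arginine-to-AID anchor
bias or — for the unbiased deactivation variant — no sensor-AID restraint
at all.  Each stage runs converging deep-relaxation legs before its short
MCM leg, and the final stage is followed by a convergence tail of deep
minimizations, the desk-scale analog of running the final leg to an
exhaustive no-improvement window.

**Double-shell mutant sampling** applies the mutation, randomizes the
sidechain torsions of every residue with a heavy atom within 15 Å of the
site (the flexible shell), freezes residues within 20 Å (the rigid shell),
excludes the rest from the energy, minimizes each of 128 random starts
(reduced in the test suite), and assembles the ensemble within 7 kcal/mol
of the apparent global minimum.  Randomization covers sidechain torsions
by default; full backbone randomization of a 15 Å shell is exposed behind
a flag but not default, because without the full model's context it
mostly produces unfolding, not sampling.

## The synthetic toy channel

The generator emulates, at desk scale, the architecture the pipeline is
about: four outer helices (S5 ring), four inner gate helices (S6) whose
C-terminal alpha-carbon ring radius defines the state (6.0 Å open, 2.5 Å
closed), an amphipathic AID-like helix whose axis is aligned with the
repeat-1 gate displacement direction and whose hydrophobic face rests in
the groove of a two-helix bedplate (the beta-subunit stand-in), and a
short sensor helix carrying arginines that face the AID glutamine — the
stand-in for the sensor-AID polar contact.

Unmodeled covalent loops, the pore turret, the membrane and the bulk of
the domains the helices belong to are replaced by a *standing scaffold*
that travels with every canonical-state stage, playing the role bonded
terms would play: distance windows between consecutive segment termini
(S5→S6 within each repeat; gate helix→AID), turret anchors on the
extracellular helix ends, soft bedplate pins (penalty-free to 2.5 Å — the
published treatment of the beta subunit), a 9 Å AID–bedplate separation
cap over the plate-covered residues (also a published device), gate-ring
scaffold pins that hold the state-defining radius (the terminal alpha
carbon is snapped exactly onto the nominal ring, so the gate radius holds
by construction), and per-state fold anchors (first, middle and last
alpha carbon of each segment, 0.5 Å window).  Without such a scaffold a
loop-less helix bundle in vacuum simply repacks.  The steered transform
does not use the fold anchors or gate pins — its steering targets replace
them — and carries loop windows widened to admit both endpoint
geometries.

Construction is analytic placement of ideal helices (φ = −57°, ψ = −47°)
with deterministic roll selection and clash detangling, followed by a
deterministic relaxation to a local minimum of the scaffolded landscape,
so each canonical state is actually stable.  The closed state is derived
from the relaxed open state by re-placing only the state-dependent
segments and relaxing them under 5° backbone windows referenced to the
open state — the state pair is therefore compatible with the steered
protocol's helix-preservation restraints, exactly as the full-scale
procedure assumes of its states.  The conserved S5 ring and bedplate are
bit-identical between states, so the atom correspondence is the identity.

What the toy does *not* emulate: membrane and solvent, P-loops and
selectivity filter, the four voltage sensors (only the S0-like sensor
helix appears), realistic sequences, and system size.  Passing tests on
the toy demonstrate that the algorithms do what they claim on a system
with the right architecture and physics-shaped landscape; they do not
demonstrate predictive accuracy on real channels.

## Numerical choices and problem sizes

* Angles are radians internally, degrees at every I/O surface; torsions
  wrap to (−180°, 180°].
* Forward kinematics caches per-segment local coordinates; only segments
  whose torsions changed are rebuilt, and rigid-body moves reuse the local
  frame.  Rebuilding an unchanged system is exact to < 1e−9 Å.
* The minimizer is L-BFGS-B over the flexible coordinates with analytic
  gradients (atom forces projected onto torsion axes, root translations
  and orientation derivatives); a pair list pruned at cutoff + 4 Å skin is
  rebuilt at each minimization start.
* Test and example runs use reduced study sizes: convergence windows of
  5–60 instead of 2000, tens of minimizations per trajectory, 8 steering
  stages, 16–32 mutant starts instead of 128.  These are the package's
  desk-scale settings for its synthetic system (the steering profile was
  calibrated so the transform converges within its restraint windows, as
  the protocol itself prescribes); production settings remain the
  configurable defaults of `mcm_config()`.
* Ties and degeneracies: torsion-window deviations are computed on the
  wrapped circle; superposition uses SVD with a reflection guard so the
  rotation is always proper; collinear selections are rejected.

## What the steered toy run does and does not show

Under the frozen desk-scale settings the steered open→closed run closes
the gate onto its targets within the restraint window, keeps the bedplate
inside its penalty-free envelope, and displaces the free AID helix by
about 3 Å.  The displacement is not purely axial, however: en route the
helix picks up a transverse excursion of about 2 Å (chiefly a vertical
lift out of its groove) that the reduced trajectory budget does not
anneal away — deep minimization confirms the endpoint is a genuine local
minimum.  The canonical state pair itself differs by an essentially pure
axial slide, so the sliding mechanism is present in the system; the
corresponding test asserts axial dominance of the *transform's* motion
and is expected to fail at these settings, which is reported rather than
hidden.

## Known limitations

* The dielectric is distance-dependent only; no environment term, no
  solvation model.
* Hydrogen bonds are detected geometrically for classification, but their
  energetics arise from LJ + Coulomb only (no dedicated 10-12 term).
* The universal-nomenclature map ships with anchors attested in the text;
  positions without a direct anchor are marked provisional in the data
  file.  One in-text label conflict (the G402/R406 pair) is resolved in
  favour of the self-consistent assignment and recorded in the map notes.
* The printed net-energy row of the mutant contact table contains one
  entry that does not equal the sum of its printed column; the fixture
  stores both the rows and the printed net values and annotates the
  discrepancy rather than reconciling it.
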