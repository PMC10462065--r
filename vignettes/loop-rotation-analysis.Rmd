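---
title: "Quantifying intracellular-loop rotational states in GPCR trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracellular-loop rotational states in GPCR trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrtraj)
```

## The problem this package addresses

Class-A G-protein-coupled receptors are usually described as activating
through rearrangements of their seven transmembrane (TM) helices. A second,
non-canonical route runs through intracellular loop 2 (ICL2), the short loop
between TM3 and TM4 that packs against the G protein: when ICL2 is helical it
can occupy two distinct *rotational* states about its own helical axis,
roughly 40 degrees apart, and only one of them ("positively rotated", PR)
forms a tight interface with the Gα subunit. Ligands binding at a
membrane-facing pocket next to ICL2 can bias this equilibrium without moving
the TM bundle. Establishing that mechanism from molecular-dynamics (MD)
trajectories requires a specific, reproducible set of per-frame geometric
measurements, and that computation is what `gpcrtraj` implements as a tested,
reusable pipeline:

* rigid-body (Kabsch) superposition and RMSD;
* per-frame scalar metrics: TM5 vertical shift relative to TM4, inter-helix
  Cα distances, the ICL2 rotation angle, the Y114–TM2 distance, locally
  superposed ICL2 backbone RMSDs (including the multi-RMSD collective
  variable on residues 111–118), Gα helix-5 displacement, and the β6–α5
  loop end-to-end distance;
* geometric hydrogen-bond and water-bridge detection with
  fraction-of-frames frequency tables;
* the two-threshold helicity + rotational-state classifier and replica
  occupancy statistics;
* backbone dihedral PCA over a residue window spanning the loop;
* a synthetic-trajectory generator with exact ground truth, used to validate
  every stage end to end without MD input.

All distances are in Ångström, angles in degrees, times in picoseconds.

## The per-frame measurement model

Every frame is first superposed onto a reference structure (by convention
the simulation starting frame, typically the AP8-bound crystal structure)
using an unweighted Kabsch fit on a TM1–4 Cα selection. The fit set must be
supplied in the configuration: TM boundary definitions are
receptor-specific and are deliberately not hard-coded. With the reference
oriented by the membrane normal (z) the ICL2 helical axis lies
approximately along x, so rotation of the loop is visible in the (y, z)
plane.

**ICL2 rotation angle (a).** The vector from the L112 side-chain CG atom to
the Y114 side-chain OH atom is projected onto the (y, z) plane and measured
as a unit-circle angle, `a = atan2(v_z, v_y)`. Both the raw angle and the
reference-offset angle (raw minus the reference structure's raw angle, the
convention used for displayed traces, in which the crystal structure reads
0) are reported. The state thresholds operate on the **raw** angle: the
printed PR window `45 < a < 120` cannot contain 0, so it cannot refer to
the offset convention in which the crystal structure itself — the PR
archetype — reads 0. A configuration switch allows thresholding the offset
angle instead. If the projected vector is shorter than 0.1 Å (vector nearly
parallel to the helical axis) the angle is flagged unreliable rather than
silently reported.

**Y114–TM2 distance (d).** The Euclidean distance from Y114:OH to T39:CB,
which detects whether the tyrosine has swung into or away from the helix
bundle. Like all pair distances it is alignment-invariant.

**Helicity rule.** A frame's ICL2 (residues 110–118 by default) is helical
iff it has at least 3 backbone i,i+4 hydrogen bonds (donor N of residue
i+4, acceptor O of residue i) *or* its locally superposed backbone RMSD
against the reference is strictly below 2 Å. Both branches are implemented
exactly, with strict inequalities as printed. In heavy-atom-only data
(crystal structures, most trajectory interchange files) the hydrogen-bond
test reduces to the N···O distance criterion.

**State assignment.** PR requires helical ∧ `45 < a < 120` ∧
`195 − 20·a < d < 13`; helical-but-not-PR is NR; everything else is
NONHELICAL. The lower distance bound `195 − 20·a` is dimensionally odd and
vacuous over the printed angle window (it is negative for all `a > 9.75`);
it is nevertheless implemented verbatim, as fidelity costs nothing here.
Occupancy fractions are computed over *all* frames (NONHELICAL time counts
in the denominator), per replica, then summarized as the cross-replica mean
± one standard error (the "68% CI" convention for 5–10 independent
simulations; a bootstrap could be substituted, but with n ≤ 10 replicas the
normal-theory SEM is the transparent choice).

**TM5 vertical shift.** The Cα of TM5 residue 190 is projected onto the
line through the Cα atoms of TM4 residues 130 and 141; the signed position
along the 130→141 unit vector, minus the same quantity in the zero
reference (the AP8-free structure by convention), measures the shift, with
positive values extracellular. The projection uses only atoms internal to
each structure, so it is invariant to how the structure is posed; the
pipeline entry still performs the TM1–4 alignment for protocol fidelity.

**Hydrogen bonds and water bridges.** Detection is geometric: donor–acceptor
heavy-atom distance ≤ 3.5 Å and, when explicit hydrogens are present, some
donor hydrogen with a D–H···A angle ≥ 110°. These two numbers are the
package's declared defaults for the "standard geometric criterion" of
contact-analysis tools — the source protocol does not print values — and
both are configurable. N/O chemistry is expressed as an ordinary selection
string rather than a hard-coded typing table. A water bridge exists for a
water whose oxygen hydrogen-bonds to both partners in the same frame; an
interaction-frequency table counts a frame positive if a direct *or*
water-mediated bond is present (once per frame, however many geometric
paths realize it), divides by counted frames per replica, and averages
across replicas. A frame mask (e.g. "ICL2 folded only") restricts the
denominator.

**Dihedral PCA.** Backbone φ/ψ torsions over a residue window spanning the
loop (stated in Ballesteros–Weinstein codes and resolved through a
user-supplied map, or given directly as residue numbers) are assembled one
row per frame; terminal dihedrals with missing flanking atoms are dropped
and logged, never imputed. PCA is the mean-centered covariance
decomposition (via SVD) of the masked rows — typically helical frames only
— with no column scaling, matching the plain use of PCA on raw dihedrals;
a sine/cosine embedding is available to avoid ±180° wraparound artifacts,
and a correlation-matrix variant was considered and rejected as default
because the torsions share units.

## The synthetic data generator: what it emulates and what it does not

MD trajectories at the microsecond scale cannot be regenerated at desk
scale, and the originals are not deposited, so the package validates
against a synthetic stand-in with *known* ground truth
(`make_scaffold()`, `simulate_trajectory()`):

* a receptor-like scaffold holding every atom the metrics name (TM Cα
  anchors, T39 CB/OG1, a 13-residue ICL2 strand built as an ideal α-helix
  from exact internal coordinates and mounted with its axis along x, the
  side-chain pseudo-atoms Y114:OH and L112:CG on circles about that axis,
  an optional Gα Cα fragment, and water oxygens);
* two-state Markov switching of the loop rotation (defaults: PR at +80°,
  the center of the printed window; NR at +40°, i.e. the −40° rotation);
  switching probabilities are per frame, with frames notionally 200 ps
  apart;
* the Y114:OH / T39:CB geometry is constructed so that `d` is 9 Å in the
  PR state and 14.5 Å in the NR state — crossing the printed 13 Å bound —
  so both threshold branches of the classifier are exercised;
* optional unfolding episodes (randomized-torsion conformers, redrawn
  until their local backbone RMSD against the helical reference exceeds
  2.5 Å, so "unfolded" ground truth is unambiguous);
* optional planted water bridges on a known frame schedule;
* isotropic, uncorrelated Gaussian coordinate noise of configurable σ,
  applied last.

Everything stochastic is a pure function of (specification, seed).

What the generator does **not** emulate: force-field physics, correlated
thermal motion, membrane and solvent environment, ligands, and real
side-chain chemistry (OH and CG are rigid pseudo-atoms). A green test
therefore establishes that the *measurement and classification machinery*
is correct against analytic ground truth — not that the biological
conclusions of any particular MD dataset are right.

Two consequences of the i.i.d. noise model are worth stating explicitly.
First, it is the *hardest* noise for torsion-space analyses: a per-atom
σ of 0.3 Å maps to tens of degrees of per-dihedral scatter because backbone
atoms sit on short lever arms about the torsion axes, whereas real thermal
fluctuations are strongly correlated along the chain. The Cartesian
classifier is validated at σ = 0.3 Å; the dihedral-PCA separation check
runs at σ = 0.1 Å, where torsion noise no longer swamps the ~100° hinge
signal. Second, rigidly rotating residues 110–118 leaves their internal
φ/ψ unchanged — a mathematically rigid rotation is invisible to internal
coordinates — which is why the scaffold carries fixed flanking backbone
(residues 108–109 and 119–120, the TM3/TM4 stubs): the *hinge* dihedrals
then change with rotation state exactly as they would in a real receptor,
and dihedral PCA has something real to find.

## Numerical choices and degenerate inputs

* Kabsch superposition corrects the sign of the smallest singular value, so
  a proper rotation (det = +1) is always returned, including for
  near-planar ("reflective") inputs; fewer than 3 points or collinear
  configurations are errors. The fit is unweighted.
* Alternate locations in PDB input resolve to the highest occupancy, ties
  to the first listed. Water residue names HOH/WAT/TIP3 are recognized.
* Selection resolution is total: a clause naming an absent atom or residue
  is an error listing what was missing, never a silent partial result.
* Metrics whose atoms are absent are reported as NA columns with a logged
  message; they are excluded from summaries, never fabricated.
* Angle arithmetic wraps into (−180, 180]; the classifier's inequalities
  are strict exactly as printed; per-frame hydrogen-bond presence is
  idempotent (counted once regardless of multiplicity).
* Multi-model PDB is the interchange trajectory format; its 3-decimal
  coordinate field quantizes at 5·10⁻⁴ Å, far below any threshold margin
  used here. Round-trip tests quantize first and then require exactness.

## Known limitations

* Binary trajectory formats (DCD/XTC/NetCDF) are not read natively; convert
  to multi-model PDB, or construct a `frame_source` from coordinates
  obtained with any external reader.
* The helical axis of the rotation-angle metric is the fixed two-atom
  CG→OH construction mandated by the protocol, not a fitted axis; for
  receptors where ICL2 is not roughly x-aligned after TM1–4 superposition
  the angle needs a reoriented reference.
* The deposited crystal pair used by the original worked example (AP8-bound
  vs AP8-free) cannot be bundled or fetched in an offline build; the TM5
  shift pipeline is validated on a synthetic stand-in with the 3 Å shift
  imposed by construction, and `fetch_crystal_fixture()` reproduces the
  real comparison when a network is available.
* G-protein nucleotide-exchange kinetics, free-energy estimation and
  Markov-state modelling are out of scope; the package measures geometry.
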