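---
title: "Glycan shielding of sodium-channel surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycan shielding of sodium-channel surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoshield)
```

## The scientific question

Voltage-gated sodium (NaV) channel α-subunits carry N-linked glycans on the
extracellular turret loops (ECTLs) that surround the pore. Cryo-EM resolves
only the innermost GlcNAc of each tree; the mature, flexible tree occupies a
much larger conformational envelope. `glycoshield` asks three geometric
questions about that envelope:

1. Which sequons (N-X-[S/T], X ≠ P) exist on each isoform, which are
   conserved across the family, and which are isoform-unique?
2. What does the envelope of full glycan trees cover on the channel surface —
   in particular, the β-subunit Ig-domain binding footprints and the
   conductance path above the pore?
3. If a β1 Ig-domain is displaced from its binding site, how far apart can
   two membranes be while β1 Ig-domains still bridge them in *trans*?

Plus a clinical corollary: which reported missense variants delete
glycosylation sites, and by which mechanism?

## Sequon discovery and conservation mapping

`scan_sequons()` reports every window N-X-[S/T] with X ≠ P. An `X`
(unknown) residue never satisfies any motif position: an unknown could be a
proline or a non-S/T, so the conservative call is no sequon. Overlapping
motifs are each reported; positions are 1-based throughout (UniProt
convention).

`align_isoforms()` delegates to MAFFT, pinned to a single thread and default
strategy so that a fixed input yields a fixed alignment. The alignment
engine is interchangeable for this purpose — at the ~50–90 % identity of the
NaV family, sequon columns are anchored by their conserved flanks — but it
must be *fixed*, which the pinned flags guarantee. Degapping any aligned row
must reproduce its input exactly; the function verifies this invariant and
fails otherwise.

`map_conserved_sequons()` groups sequons whose asparagines share an
alignment column — strict column identity, no ±1 fuzz, which is the most
conservative reading of homology at well-aligned sites. Classes:

* `all` — every isoform in the alignment carries a sequon at the column;
* `unique` — exactly one isoform does (a single-member family classes all of
  its sites `unique`, since "present in all" is vacuous there);
* `subset` — anything in between.

With `resolved_only = TRUE`, groups are *seeded* only from columns carrying
at least one structurally resolved glycosite, but group membership still
spans all isoforms: an unresolved sequon (e.g., in the flexible ECTL I, or on
NaV1.9, which has no structure) joins the group of its column. This mirrors
how resolved sites serve as experimental anchors while the sequence carries
the conservation signal.

Region annotations (domains DI–DIV, VSD I–IV, ECTL I–IV) are supplied as
configuration tables rather than auto-detected, because loop boundaries are
a curation decision, not a computable one.

## Variant classification

A substitution removes a glycosylation site when it hits the Asn itself
(N-loss), the Ser/Thr at N+2 (ST-loss), or places a proline at N+1
(X-to-proline). Rather than hard-coding these three rules,
`classify_variant()` applies the substitution and re-scans the ±2 window,
then diffs wild-type versus mutant sequon starts; the mechanism label is
derived afterwards from the position of the lost Asn. This makes the
semantics exact: S→T at N+2 is silent (the motif is preserved), a
substitution can simultaneously disrupt one sequon and create another (both
are reported; `disrupting` takes precedence in the summary class), and any
wild-residue mismatch against the supplied sequence is a hard data-integrity
error, never silently ignored. Frameshift and nonsense variants are classed
`structural` with no sequon call — their phenotypes stem from downstream
protein disruption, not glycosylation.

## The glycan model

The packaged representative tree is a complex-type, core-fucosylated,
bi-antennary N-glycan with one terminal sialic acid: Asn–GlcNAc(+Fuc
α1-6)–GlcNAc–Man–(Man α1-3 / Man α1-6), each arm GlcNAc–Gal, one arm capped
by Neu5Ac (11 residues: GlcNAc 4, Man 3, Gal 2, Fuc 1, Neu5Ac 1). The sialic
linkage is recorded as α2-6 on the α1-3 arm by default; the JSON document is
the single source of truth and can be edited to α2-3 or the other arm —
neither choice affects any excluded-volume result, only the labelling.

Monosaccharides are rigid idealized chairs (ring bonds 1.52 Å, all within
the 1.3–1.6 Å plausibility band) with exocyclic attachment oxygens at C2/C3/
C4 and a C6–O6 arm; one geometry serves all five sugars, since an
excluded-volume model does not resolve epimers. All flexibility is
torsional: φ and ψ per glycosidic linkage, ω for 1→6 linkages, and a φ/ψ
pair on the Asn–GlcNAc root. Coordinates are rebuilt from the torsion vector
by forward kinematics, so bond lengths and ring geometry are preserved
*exactly* under any move — there is no way for sampling to distort the
chemistry.

## Conformer sampling as the MD stand-in

The reference analysis superimposed MD snapshots taken every 5 ns over
150 ns. Its conclusions rest on the *geometric envelope* of glycan
conformers, not on force-field energetics, so the package replaces MD with
torsional Metropolis Monte Carlo under a hard-sphere-soft-penalty excluded
volume:

* energy = Σ over atom pairs closer than the clash cutoff of
  `(cutoff − d)²`, summed over glycan–protein, glycan–glycan,
  glycan–membrane-slab and intra-glycan pairs (pairs within one residue or
  within two linkages — parent, grandparent, sibling — are exempt, as their
  proximity is fixed by the linkage geometry);
* moves perturb one torsion, uniform in ±30°;
* Metropolis acceptance at temperature factor 0.5 Ų.

Defaults and their reasoning:

| parameter | default | why |
|---|---|---|
| snapshots (`n_frames`) | 30 | the 150/5 sampling-protocol analog; the t = 0 graft pose is not a frame |
| clash cutoff | 2.4 Å | heavy-atom hard-core distance |
| move width | ±30° | large enough to mix, small enough to keep acceptance useful |
| temperature | 0.5 Ų | tolerates grazing contacts during mixing; snapshots themselves are always strictly clash-free |
| sweeps per frame | 15 | decorrelates consecutive frames (they differ unless moves were rejected) |
| membrane | planar slab, head planes ±15 Å, 1.5 Å head-group tolerance | lipids as excluded volume only; the leaflet composition table is carried as metadata for reporting, not energetics |

With a pure excluded-volume energy most proposed moves are clash-free, so
the acceptance rate on the toy system sits near 0.9 rather than in the
0.3–0.6 band one would tune for with a smooth energy surface; the
temperature only modulates how readily grazing contacts are traversed.
Snapshots are recorded only in strictly clash-free states; if a snapshot
cannot be repaired within the attempt budget (repair runs at one-fifth
temperature to bias downhill), the ensemble is returned truncated with
`status = "partial"` and a warning rather than silently padded.

`graft_glycan()` builds the initial pose at default torsions and repairs
clashes by greedy descent with basin hopping (re-randomizing all torsions
after 100 stale moves); a site that cannot be made clash-free is a hard
error ("steric lock"). Grafting validates the sequon chemistry first: no
Asn, a proline at N+1, or a missing side-chain nitrogen all refuse the
graft.

Determinism: every stochastic routine takes a seed, uses R's Mersenne
Twister through an isolated RNG scope, and records the seed in its output;
fixed seed means bit-identical ensembles.

## Occupancy, occlusion, and the pore check

`build_grid()` voxelizes the ensemble (default 1 Å voxels) into per-voxel
fractions of frames containing at least one glycan heavy atom.
`occlusion_score()` computes, per region residue, the fraction of frames
with a glycan atom within the contact cutoff (4.5 Å), calls a residue
covered when that frequency reaches the frame-fraction threshold (0.5), and
reports the region's coverage fraction. Verdicts: coverage ≥ 0.8 →
`blocked`, ≤ 0.2 → `accessible`, else `partial`. The reference analysis
presents these verdicts visually ("completely covered", "exposed"), so the
0.8/0.2 boundaries are artifact decisions, pinned in configuration and
echoed into every report; boundaries are inclusive on the decisive side
(coverage exactly 0.8 is `blocked`), a deterministic tie rule. Coverage is
monotone non-decreasing in the contact cutoff and non-increasing in the
frame threshold, which the test suite checks over parameter grids.

Interface footprints are extracted from complex structures as the α-chain
residues with any heavy atom within 5 Å of the partner chain; an empty
footprint is a warning, not an error, since displaced-partner controls are
legitimate inputs.

The pore check models the conductance path as a cylinder (radius 6 Å,
extending 30 Å outward from the extracellular mouth along the membrane
normal) and reports the fraction of frames with any glycan atom inside. On
the default toy channel the loop anchors sit ~11 Å from the axis — within
glycan reach of the cylinder — so its measured fraction is an honest
property of that toy, not a claim about real channels; the genuinely
off-axis construction (used in the acceptance checks) widens the anchor ring
to 40 Å, beyond which the sampled envelope never approaches the axis.

## Trans-bridge geometry and pulling

`build_dimer()` assembles two copies of an Ig domain between opposed
membranes: copy B is copy A rotated 180° about a membrane-parallel axis, so
its linker anchor faces the opposite membrane. Tip-to-tip stacks the
membrane-distal turns with a 4 Å contact gap; side-to-side packs the β-sheet
faces laterally with an 8 Å stagger (strands interdigitate rather than align
flush). Interface contacts are cross-copy Cα pairs within 6 Å; an empty
interface refuses the assembly.

The maximum membrane-to-membrane distance is closed-form:

```
distance = 2 × (linker residues × 3.63 Å) + span + 2 × anchor offset
```

where 3.63 Å is the trans Cα–Cα contour per residue, the span is the
anchor-to-anchor separation projected on the membrane normal, and the
default linker is 15 residues (the flexible neck between the Ig-domain
boundary and the pulled C-terminal residue). This is the "maximum estimate,
fully extended neck" quantity; it is invariant under rigid transforms of the
assembly and strictly monotone in linker length.

`coarse_pull()` mirrors the constant-velocity rupture protocol with a
deliberately coarse mechanical model: each Ig copy is a rigid body (its
internal deformation is not the quantity of interest), the linkers are bead
chains with harmonic bonds at a 3.0 Å relaxed rest length *hard-capped* at
the 3.63 Å contour by constraint projection, and the interface contacts are
breakable springs that fail beyond a 0.5 Å extension. Pull restraints on the
linker termini move apart at constant velocity (defaults: velocity 5,
spring constant 100 — the steered-protocol analogs). Because the linkers ride
below their contour at rupture tensions and the domains cannot stretch, the
rupture-time distance always stays below the closed-form maximum — the
geometric bound the tests assert. Integration is overdamped with zero
thermal noise by default, making every trajectory deterministic; noise > 0
remains bit-reproducible under a fixed seed. The reported structure is taken
25 steps before rupture (the 10-ps-before-rupture analog at the default
0.4 ps/step mapping).

## The synthetic study system

Real UniProt sequences and PDB structures are not bundled; the
`synthetic_data` generators build stand-ins that carry the *published site
architecture* while everything else is random:

* `synthetic_nav_family()` emits nine full-length sequences at the canonical
  isoform lengths with sequons planted so that: NaV1.5 N291/N1365/N1380 are
  conserved in all nine isoforms (NaV1.1 N338/N1378/N1392, NaV1.6 N1358,
  NaV1.4 N1191/N1205 in their own numbering), N328 is shared by all but
  NaV1.7/1.9, N1374 by NaV1.5/1.7/1.8, N283/N288/N318/N1388 are
  NaV1.5-unique, NaV1.6 has two and NaV1.7 one unique DI site, NaV1.8 has
  the unique DII site N819, and NaV1.4's ECTL I carries seven motifs. The
  wild-type residues required by the packaged clinical variant table (S340,
  H1393, T1394 on NaV1.1; T320, S1382 on NaV1.5; T1360 on NaV1.6) are part
  of the planted motifs. Non-member isoforms receive the motif with N→Q at
  homologous columns — a destroyed site that still anchors the alignment.
  Background divergence is 6 % substitutions plus inter-domain indels that
  realize each isoform's numbering offsets; accidental sequons are removed
  (N→Q) after planting. What this family does *not* emulate: real
  amino-acid composition, real secondary structure, real evolutionary rate
  variation — so a passing conservation test shows the mapping machinery is
  correct on a family whose ground truth is known, not that the alignment
  of the real family is trivial.
* `make_toy_channel()` builds a four-helix transmembrane bundle with
  extracellular loops carrying Asn-Ala-Thr glycosites (full Asn side chains
  for grafting) around a central pore axis, inside a membrane slab. It is a
  topology caricature: real channels have 24 TM helices and far wider turret
  rings.
* `make_toy_complex()` places a partner chain 4 Å from a designated residue
  window of a straight Cα peptide, so the interface footprint is exact by
  construction.
* `make_toy_ig()` is a Cα β-sandwich with realistic Ig proportions (two
  four-stranded sheets, ~41 Å long axis, 9.5 Å sheet separation). With the
  15-residue linker this geometry gives tip-to-tip and side-to-side
  extensions that the tests compare against the published 18.72 / 15.34 nm
  values within the declared ±2 nm band — a geometric estimate standing in
  for a steered-MD measurement.

The packaged tables (`load_paper_tables()`) carry the clinical variant lists
per isoform with phenotypes, the per-leaflet plasma-membrane lipid
composition (each leaflet sums to 100 %), the resolved-glycosite table, and
the representative glycan tree. The resolved-site table is a synthetic
reconstruction: positions named in the source text are authoritative, the
remaining cells follow the stated conservation architecture.

## Problem sizes

The shipped tests and the acceptance script run: nine ~2000-residue
sequences through MAFFT; 30-frame ensembles of two 11-residue glycans
(121 heavy atoms each) on the toy channel; 10–15-frame ensembles for the
pore constructions; and pulls of a few thousand steps over ~250 beads.
These sizes were chosen so a full verification runs in about a minute on a
single core while still exercising every code path at non-trivial scale.

## Known limitations

* Excluded volume only: no electrostatics, no solvent, no lipid chemistry.
  Claims about sialic-acid/VSD attraction or head-group contacts are outside
  this model's reach and are deliberately not asserted anywhere.
* One representative glycan form; real glycosylation is heterogeneous.
* The occlusion verdict thresholds (0.8/0.2) are artifact conventions; use
  the raw coverage fractions for quantitative work.
* The pulling model resolves rupture *ordering* and the geometric bound, not
  force–extension physics; forces are in model units, not kJ/mol/nm.
* Conservation results on the synthetic family validate machinery against
  planted ground truth; applying the pipeline to the real isoforms requires
  supplying the real sequences and structures through the same interfaces
  (`read_isoform_fasta()`, `read_structure()`).
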