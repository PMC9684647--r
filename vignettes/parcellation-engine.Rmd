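---
title: "Rule-based comparative cortical parcellation: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based comparative cortical parcellation: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The parcellation model

hoacompare encodes the revised Harvard-Oxford cortical parcellation as
*data plus a geometric interpreter*. The atlas defines each cortical region
(parcellation unit, PU) by four border slots — anterior, posterior,
medial/inferior, lateral/superior for the human; superior, inferior,
anterior, posterior for the macaque — each naming limiting sulci, coronal
limiting planes anchored at anatomical events, or derived lines (the
45-degree Sylvian lines, the calcarine bank lines, the pre- and postcentral
omega lines, the parietal line, the macaque arcuate lines, the
supratemporal-plane midline, and the hemispheric margin). The human
ontology has 73 units (27 frontal, 13 parietal, 15 temporal, 9 occipital,
7 paralimbic, 2 insular), the macaque 40 (16/7/5/7/4/1), plus a shared
equivalence table linking each human unit to its Brodmann areas, its
macaque homolog and, in the frontal lobe, Walker areas.

The engine's job is the converse of atlas lookup: given a cortical-ribbon
label volume with surface-class tags (lateral, medial, ventral, opercular,
insular), labeled sulcal traces and landmark-event coordinates, apply the
border rules and return exactly one unit label per ribbon voxel.

Assumptions the engine makes about its input:

* the ribbon is a single connected voxel component in an RAS frame
  (x right, y anterior, z superior);
* every sulcus and landmark a rule needs is either annotated or declared
  absent;
* surface classes are correct — the hemispheric margin is derived as the
  lateral/medial class boundary, the Sylvian lips as the lateral/opercular
  boundaries, and the insular circular sulcus as the insular class
  boundary, so these folds need no traces.

## How labeling works

1. **Realize borders.** Coronal planes become integer cuts on the
   posterior-anterior axis (one per landmark event; sulcus-end qualifiers
   such as "(ant)" become cuts at the trace terminus). Sulcal traces and
   derived lines become *walls*: voxelized staircases whose consecutive
   points differ by at most one voxel per axis, so a face-connected fill
   cannot slip through them. Fold borders (hemispheric margin, circular
   sulcus, 45-degree lines at the opercular lips) block class-boundary
   crossings rather than occupying voxels.
2. **Conditional merge.** For the human, if the lateral orbital sulcus is
   traced once, the lateral fronto-orbital unit and its partner are
   replaced by the combined unit `FOCL/F3o`; if it is duplicated they stay
   separate, divided on the duplicated sulcus, and the orbital strip
   lateral to the outermost instance belongs to the partner unit.
3. **Compartment growth.** Units are processed in the published table
   order. For each unit, the engine enumerates the connected compartments
   of still-unclaimed ribbon voxels of the unit's surface classes, where
   growth cannot cross the unit's own plane cuts, walls, or fold margins.
   The compartment touching the most of the unit's own borders wins
   (side-aware: a unit lies posterior of its anterior border, and for the
   macaque's printed superior/inferior columns, below/above it); ties go to
   the compartment least surrounded by already-claimed territory, then the
   smaller one. Compartments that the unit's *own interior* plane cuts
   split off are re-united when they also touch the unit's borders — this
   is what lets a unit listing several planes in one slot (different
   planes bounding different parts of its perimeter) come out whole.
4. **Tie-break.** Wall voxels and any other unclaimed ribbon voxels are
   assigned iteratively to the neighboring unit with the most face-adjacent
   claimed voxels; remaining ties go to the unit earlier in the table.
   The result is a partition: coverage 1, zero overlaps, by construction.

Left hemispheres are mirrored into the canonical right-handed orientation,
labeled, and mirrored back, which makes mirror symmetry of the output exact
rather than approximate.

### Numerical conventions

* **Half-open planes.** A plane at coordinate *p* blocks growth between
  *y = p* and *y = p + 1*; the plane's own coordinate belongs to the
  posterior unit. Two units sharing a plane therefore tile their strip with
  no gap or overlap.
* **Wall ownership.** Trace voxels are barred only to units that list the
  sulcus; they end up assigned by the tie-break, so label differences along
  traces are confined to a one-voxel band. All correctness claims are
  therefore stated for voxels farther than one voxel from a ground-truth
  border.
* **Calcarine band.** A unit bounded by the calcarine sulcus that is not
  itself a bank unit is kept out of the whole band (fundus plus both bank
  lines); the bank units see the fundus and their own bank line. With bank
  width 0 the bank lines coincide with the fundus and the intracalcarine
  units are reported empty and flagged, rather than grown from spurious
  compartments.
* **Geodesics.** The parietal line is the metric shortest path on the
  ribbon voxel graph (26-connectivity, Euclidean step costs — the metric
  makes the geodesic unique and mirror-stable), bridged to 6-connectivity
  so it blocks face-connected growth.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `calc_bank_width` | 3 (human), 2 (macaque) | voxels | offset of the calcarine superior/inferior lines from the fundus; the height of the intracalcarine banks |
| `omega_half_width` | 5 | voxels | half-height of the middle pre/postcentral band around the omega apex |
| `lorb_instances` | 2 | count | number of lateral orbital sulcus traces; 1 triggers the conditional merge |
| voxel size | 1 mm isotropic | mm | frame resolution; volumes scale with its cube |

Defaults were chosen once as plausible proportions for the phantom
geometry (bank and band heights a few millimetres at 1 mm resolution) and
are inputs on real data, where they would come from the tracing protocol.

## What the phantom is, and is not

The synthetic hemisphere is a folded box shell: lateral and medial walls, a
dorsal face split by the hemispheric margin, orbital and temporo-occipital
ventral sheets, anterior and posterior pole faces, a Sylvian slot with two
opercular shelves (the lower one is the macaque supratemporal plane), an
insular wall, and callosal/subcortical openings in the medial wall. Sulci
are straight or L-shaped grooves; the pre-, post-central and
parieto-occipital sulci are oblique staircases; the calcarine and
ectocalcarine grooves wrap onto the occipital pole face. Every placement is
a fixed design constant, so the true label of every voxel follows
analytically from the same conventions the engine uses — an independent
derivation, not a second run of the engine.

At the default sizes (96 x 128 x 96 human, 64 x 80 x 64 macaque, about
28,000 and 12,000 ribbon voxels) a full human labeling takes seconds. The
human fixtures exercise all 73 units including planes Q and R, the omega
lines, the 45-degree lines and the conditional merge; the macaque fixtures
exercise the arcuate extension (ASL/APL), the premotor split at the
anterior-commissure plane, the orbital subdivision and the
supratemporal-plane midline.

What passing on phantoms does **not** show: robustness to realistic
cortical folding, to interrupted or branching sulci, to annotation errors
beyond small jitter, or to partial-volume effects — none of which the
phantom models. The phantom demonstrates that the rule encoding, geometry
and bookkeeping are correct, not that tracing real MRI is easy.

## Design choices where the rules underdetermine the geometry

Several border constructions are named but not procedurally defined in the
atlas tables; the package fixes one convention each and treats it as part
of its contract:

* **45-degree Sylvian lines.** Realized as rays from the posterior terminus
  of the posterior horizontal ramus at +/-45 degrees to the fissure
  direction (total-least-squares fit of the trace) in the parasagittal
  projection, plus class-boundary blocking at the opercular lips, where the
  band between fissure and ray collapses onto the opercular sheets. A
  near-vertical fissure direction is an error.
* **Calcarine lines.** Per-point normal offsets of the fundus trace at the
  bank width; `SCL` and `CSL` in the printed footnotes are treated as two
  expansions of the same superior calcarine line.
* **Supratemporal-plane midline.** "Geometric mean" is read as the
  arithmetic midpoint of the region's posterior-anterior extent (the only
  reading that yields a coronal cut); a single-slice region leaves the
  posterior half empty and flagged.
* **Hemispheric margin for opercular units.** Units printing the margin in
  their superior (or inferior) slot are opercular sheets whose outer edge
  is the Sylvian lip; the engine scores that slot against the
  corresponding lip fold.
* **Conditional merge partners.** The printed footnote names `FOCL` and
  `F3o` as the conditionally combined pair and the package follows the
  text, although the footnote markers sit on the orbital rows; the merged
  unit keeps the later table row so that tie-breaks along unrelated borders
  do not move when the merge fires.
* **Surface-class hints.** Each unit carries the set of surface classes it
  may occupy (packaged as a table next to the border rules). The printed
  slot labels assume this knowledge implicitly; making it explicit is what
  lets a purely voxel-based fill respect, say, that the frontal medial
  cortex lives on the ventral sheet while the medial frontal pole does not.
* **Units bounded by the margin on three sides** (frontal pole, temporal
  pole, occipital pole) are delimited only by their single plane plus the
  ribbon extent; the pole wrap is re-united across the margin because the
  margin appears in two or more of their slots.

In the phantom, a few anchors are deliberately simplified: the anterior
horizontal ramus trace is a short segment just anterior of its plane
anchor; plane I sits anterior of the truncated calcarine trace (the
subcortical opening shortens the trace); the macaque superior calcarine
sulcus is present as a trace but does not shape any label in this geometry;
and the macaque lateral parietal units are kept lateral-class only, their
printed cingulate-sulcus bound being inert on this shell. The macaque
posterior cingulate unit includes the retrosplenial strip behind the
splenium down to the calcarine band, which is how its printed posterior
borders (calcarine anterior plane, inferior-occipital plane, subparietal
sulcus) jointly read.

## Degenerate inputs and failure modes

Missing required traces or events raise completeness errors naming the
symbols. Declared-absent sulci drop their walls, so the adjacent units
merge into the earlier unit's claim with the difference confined to the
vanished border. Zero calcarine bank width empties the bank units
(flagged). Jitter beyond half the minimal inter-border spacing is refused
by the perturbation helper. A unit whose compartment score is zero is
reported empty rather than guessed.

## Limitations

* The engine is volumetric and voxel-based; it does not produce
  surface-mesh parcellations, probabilistic maps, or multi-subject
  averages.
* Compartment selection is heuristic where the printed rules are locally
  ambiguous; the heuristics are validated against the analytic phantoms,
  not against manually parcellated MRI.
* The packaged single-subject volume tables are reference data for lookup
  and descriptive comparison only; nothing in the package can or should
  reproduce them from synthetic data.
* The functional-type slot of each unit exists in the schema but ships
  unpopulated.
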