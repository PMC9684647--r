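# hoacompare

Comparative, rule-based cortical parcellation for the human and rhesus
macaque brain.

The revised Harvard-Oxford parcellation scheme divides the cerebral cortex
into parcellation units (PUs) — 73 in the human, 40 in the macaque — each
defined by four border slots that name limiting sulci, coronal limiting
planes anchored at anatomical events, and derived lines (the 45° Sylvian
lines, the calcarine bank lines CSL/CIL, the pre/postcentral omega lines
SPRCL/IPRCL/SPOCL/IPOCL, the parietal line PAL, the macaque arcuate lines
ASL/APL, the supratemporal-plane midline, and the hemispheric margin HM).
Because the two species' schemes were aligned on Brodmann's comparative
cytoarchitecture, every human unit also carries its Brodmann areas, its
macaque homolog, and (in the frontal lobe) Walker areas.

hoacompare ships that scheme as machine-readable data and implements the
machinery around it, for anyone who needs the atlas as *computable rules*
rather than a picture:

* **ontology** — the unit inventories, limiting sulci (with
  Neuronames/TNA2/FIPAT identifiers), landmark planes, border definitions
  and the human↔macaque↔Brodmann↔Walker equivalence table, as validated,
  queryable tibbles;
* **geometry** — constructors realizing every border primitive as voxel
  geometry in an RAS hemisphere frame, with a half-open plane convention
  (the plane's own coordinate belongs to the posterior unit) so adjacent
  units tile exactly;
* **engine** — a deterministic constrained region-growing labeler that
  applies a unit's own four border slots to an annotated hemisphere
  (cortical-ribbon mask with surface classes + sulcal traces + landmark
  events) and emits a complete, disjoint label map, including the
  conditional `FOCL/F3o` merge when the lateral orbital sulcus is single;
* **phantom** — synthetic folded-slab hemispheres with analytically known
  ground truth, so every stage is testable without imaging data;
* **morphometry** — voxel-count regional volumes in cm³, lobar aggregation,
  laterality indices, and the packaged single-subject reference volume
  tables for descriptive comparison.

## Worked example

Query the ontology:

```r
library(hoacompare)

ont <- load_ontology("human")
ont
#> <hoa_ontology> human: 73 parcellation units, 34 sulci, 20 landmarks, 10 derived lines

count_units(ont, "lobe")
#> # A tibble: 6 × 2
#>   lobe           n
#>   <chr>      <int>
#> 1 frontal       27
#> 2 insular        2
#> 3 occipital      9
#> 4 paralimbic     7
#> 5 parietal      13
#> 6 temporal      15

get_unit(ont, "AGa")
#> <hoa_unit> AGa (Angular gyrus, anterior, parietal lobe)
#>   anterior:         CP E, im
#>   posterior:        CP F
#>   medial_inferior:  ip
#>   lateral_superior: st, lo

homolog(ont, "SMA")$mhoa_pu[[1]]
#> [1] "PRGm/SMA"
brodmann_to_units(ont, "17", "human")
#> [1] "CALCi" "CALCs" "OP"    "SCALC"
```

The six lobar counts are the atlas inventory (27 + 13 + 15 + 9 + 7 + 2 =
73). `AGa`'s slots read: the anterior angular gyrus runs from coronal
plane E (with the intermediate sulcus of Jensen) back to plane F, between
the intraparietal sulcus and the superior temporal / lateral occipital
sulci.

Generate a phantom hemisphere, label it with the engine, and measure:

```r
ph <- generate_phantom(phantom_spec("macaque"))
lm <- assign_labels(load_ontology("macaque"), ph$hemisphere)
lm
#> <hoa_labelmap> macaque, right side: 12350 labeled voxels across 40 of 40 units

check_partition(lm, ph$hemisphere)
#> <hoa_partition_report> coverage 1.0000, 0 overlaps, 0 unlabeled, 0 labels outside ribbon

vol <- compute_volumes(lm)
aggregate_volumes(vol, "lobe")
#> # A tibble: 6 × 4
#>   lobe       hemisphere voxels volume_cm3
#>   <chr>      <chr>       <int>      <dbl>
#> 1 frontal    right        5286      5.29
#> 2 insular    right          63      0.063
#> 3 occipital  right        3111      3.11
#> 4 paralimbic right        1099      1.10
#> 5 parietal   right        1361      1.36
#> 6 temporal   right        1430      1.43
```

Coverage 1.0 with zero overlaps means every ribbon voxel received exactly
one unit label; the lobar volumes are exact voxel counts times the 1 mm³
voxel volume. Against the phantom's analytic ground truth, the engine
agrees on 100% of voxels farther than one voxel from any border (the
one-voxel band along sulcal walls is resolved by a deterministic
tie-break). `tidy(lm)`, `glance(lm)`, `autoplot(lm)` and `plot_volumes()`
give tabular and graphical views; `write_label_volume()` writes NIfTI with
a TSV lookup sidecar.

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","hoa2.R",package="hoacompare"))') \
    ontology counts --species human --by lobe
```

## Layout

```
inst/extdata/ontology/    transcribed atlas tables (TSV, one per source table)
inst/extdata/reference/   packaged single-subject volume tables
inst/cli/hoa2.R           command-line front end
R/                        ontology, geometry, engine, phantom, morphometry, IO
vignettes/                methods vignette: model, conventions, limits
scripts/acceptance.R      end-to-end reproduction script
```
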