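---
title: "Profiling the geometry of bridge-like lipid transfer proteins"
author: "bltpgeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the geometry of bridge-like lipid transfer proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bltpgeom)
```

## The problem

Bridge-like lipid transfer proteins (BLTPs) — the VPS13 family, ATG2, and
relatives — are rod-shaped proteins hundreds of ångströms long that span
membrane contact sites. Their core is a series of repeating beta groove
(RBG) motifs arrayed end-to-end into an elongated, one-side-open β-sheet
("taco shell"). Lipids are thought to slide along the groove's hydrophobic
interior with their head groups facing solvent through the open mouth.

The geometric quantities of interest are simple but tedious to obtain by
hand: how wide is the channel at each position along its axis, what is the
cross-sectional area of the lumen, how much lumen volume (and therefore
roughly how many lipids) does the groove hold, which residues line the
transport path versus face solvent, and how much surface is buried at
interfaces with partner proteins such as calmodulin. `bltpgeom` computes
all of these deterministically from an atomic model.

## The procedure and its assumptions

**Axis.** The channel axis is the first principal component of the
selected atoms' coordinates. This assumes the groove is, to first order,
straight — adequate for bridge domains, which are gently curved at most;
a spline (curved-axis) fit is deliberately out of scope, because the
downstream slicing model is a sweep of parallel planes. The axis sign is
fixed by requiring the atom with the lowest residue number of the
lowest-ordered chain (the N terminus) to sit at axial coordinate
`s ≈ 0`, and the origin is chosen so all selected atoms have
`s ∈ [0, extent]`. If the two leading principal extents are within 1% the
axis is geometrically ambiguous; the fit warns and breaks the tie
deterministically.

**Slabs.** Atoms are partitioned into half-open intervals
`[s_lo, s_hi)` of fixed thickness (default 5 Å, the conventional slice
increment for this kind of analysis); the final slab is closed so an atom
exactly at the extent belongs to it. Slab thickness equals the step — no
overlap, no gap — and both are parameters. All slabs share a single
in-plane orthonormal basis derived deterministically from the axis (the
global coordinate axis least aligned with the channel direction,
orthogonalised), so consecutive slices are mutually registered like
frames from a fixed camera.

**Lumen.** Within a slab, atoms are projected onto the slab plane. The
groove mouth must be closed before an area is defined; the default
closure is the 2-D convex hull of the projected atom centres, which
closes the opening with a chord. This is the simplest deterministic rule,
it is exact on the synthetic fixtures, and it mirrors what a person
tracing a blob on a slice rendering would do. For strongly non-convex
walls a morphological closure is provided instead (`mouth_closure =
"morphological"`): the wall mask is closed with a disc structuring
element of radius `alpha` (default 8 Å) and interior holes are filled.
No alpha-shape is used; the disc-closing achieves the same intent
(bridging mouth gaps narrower than ~2·alpha) on a raster, with one fewer
geometric dependency.

The slab plane is rasterized (default 0.5 Å cells; 0.25 Å for
benchmark-grade numbers) over the projected bounding box padded by 5 Å
(or by `alpha` plus the largest disk radius in morphological mode, so the
closing is never clipped). Wall cells are cells inside any atom's
projected disk of radius vdW + `probe_inflate` (default bare vdW radii).

* **Area** uses anti-aliased cell coverage: each cell contributes the
  clamped fraction `0.5 + d/res`, where `d` is the exact signed distance
  to the hull boundary (and analogously to the nearest disk rim). Plain
  binary counting was measured to be sensitive to how the grid happens to
  align with the walls (errors up to ~1.7% on the analytic semicircle);
  the coverage form is alignment-insensitive and accurate to ~0.2% at a
  0.25 Å grid.
* **Inscribed width** is twice the maximum of the Euclidean distance
  transform of the binary lumen mask. The transform measures cell-centre
  to cell-centre distances: the background starts about half a cell
  beyond the true boundary while the optimal circle centre is quantized
  by about half a cell in the other direction, so the raw maximum is the
  least biased estimator (verified on the semicircle and ring fixtures).
  It is additionally capped at the max-chord value, since a degenerate
  few-cell lumen can otherwise overstate its own diameter.
* **Max chord** is the largest pairwise distance between lumen boundary
  cells (computed on their convex hull). It is the "rim-to-rim" width; a
  published "~20 Å across" could mean either metric, so both are always
  emitted and the headline choice is a flag.

**Volume and capacity.** Lumen volume is exactly `Σ area·Δs`. Lipid
capacity divides by a per-lipid molecular volume, default 1300 Å³ — a
typical glycerophospholipid volume, exposed as an explicit, logged
parameter because any such count is only as meaningful as its divisor.
Both the unrounded and nearest-integer values are reported.

**Lining classification.** Within each slab an atom is channel-lining if
the 2-D segment from the slab's lumen centroid to the atom's projected
centre is not blocked by another atom's disk. A blocker must both
intersect the sight line and be *radially interposed* — closer to the
centroid than the target by at least its own radius. Without the second
condition, wall atoms whose projections overlap (stacked rings of a
lattice, or touching neighbours in the same wall) would shadow each other
at the segment endpoint and the rule would mislabel the wall itself.
Atoms in slabs with no lumen are unassigned. The rule is purely
geometric, deterministic, and fast; a SASA-differencing alternative was
rejected because it conflates solvent exposure with lumen-facing.

**Hydropathy.** Per slab, the mean Kyte–Doolittle hydropathy is computed
over lining residues and over exterior residues. A residue contributes
once per slab regardless of its atom count; its slab class is the
majority label of its atoms (ties count as lining). Residues absent from
the 20-entry table are excluded, and an empty class yields a missing
value, never zero.

**SASA and interfaces.** The Shrake–Rupley engine places a deterministic
golden-spiral lattice of `n_points` (default 960) on each atom's sphere
of radius vdW + probe (default 1.4 Å, water) and counts points outside
every neighbour's inflated sphere; neighbours come from spatial binning
with cell size `2·(max radius + probe)`. There is no randomness anywhere
in the engine, so totals are bit-reproducible. Interface burial between
two disjoint groups is the two-sided sum
`BSA = SASA(A) + SASA(B) − SASA(A∪B)`; published "total buried surface"
figures usually follow this convention, but because some reports quote
the one-sided area, `bsa_one_sided = BSA/2` is always emitted alongside.
Per-residue SASA losses (alone minus in-complex) are also tabulated.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `thickness` | 5 | Å | conventional slice step for channel profiles |
| `grid_resolution` | 0.5 | Å | <2% area error at 4× the speed of 0.25 Å |
| `mouth_closure` | convex | — | deterministic, exact on fixtures |
| `alpha` | 8 | Å | disc radius of the morphological closure |
| `probe_inflate` | 0 | Å | bare vdW walls; set ~1.4 for solvent-excluded style |
| `per_lipid_volume` | 1300 | Å³ | typical glycerophospholipid volume |
| `trim_fraction` | 0.25 | — | end-cap slabs with < 25% of the median atom count are excluded from summary min/max widths (tapering caps would otherwise dominate the minimum) |
| `probe_radius` | 1.4 | Å | water probe |
| `n_points` | 960 | — | quadrature error ≈ 0.3% on touching spheres |
| radii set | Bondi-type | Å | C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20; default 1.70 for unlisted elements |

Structure handling defaults: hydrogens and HETATM records are excluded
(cryo-EM depositions of these proteins lack hydrogens; waters/ligands are
not wall material), with flags to include both; only the first MODEL
block is read; for alternate locations the highest-occupancy conformer is
kept (ties: first in file); author residue numbering is preserved exactly
and selections (`"A:2-3753"`) are 1-based inclusive.

## The synthetic generator: what it emulates, and what it does not

`make_groove()` builds the idealized object the analysis assumes: wall
pseudo-atoms (single-atom `CA` residues) on a cylindrical lattice spanning
the closed part of the circumference, with a configurable opening angle
(180° = half-pipe), optional concentric wall layers that stack radially
(so outer atoms sit behind inner ones), a constant or axially varying
inner radius, and seeded isotropic Gaussian jitter. Ground truth — axis,
per-atom interior/exterior labels, radius profile, and the analytic
convex-closure lumen area — comes with the model, so axis fitting, slab
areas and widths, lining labels and hydropathy ordering can all be
checked against known answers. Identical spec and seed give bitwise
identical coordinates, and the jitter RNG never leaks into the caller's
RNG state.

What the generator does *not* emulate: real β-sheet backbone geometry and
side chains, residue-level atom multiplicity, wall curvature along the
axis (the lattice is straight), sequence composition, and crystallographic
artefacts. Passing the synthetic tests therefore shows that the geometry
pipeline measures what it claims on structures satisfying its assumptions
— not that a particular deposited model will yield any particular number.
When applied to real structures, the mouth-closure convention and the
choice of width metric dominate the uncertainty; both are parameters, and
reported geometry should cite them.

Generator defaults are chosen once for pseudo-Cα realism: 3.8 Å lattice
step (consecutive Cα distance), 1.70 Å atom radius (carbon), 4.5 Å layer
spacing (typical sheet–sheet packing). The shipped presets pin the
benchmark conditions: `halfpipe10`/`tube10` (point atoms on a 1 Å
lattice, radius 10 Å — the analytic area/width fixtures), `twolayer`
(Leu inside / Asp outside, 2 Å lattice, 0.9 Å atoms, 3 Å layer gap — the
lining fixture), and `flare8to16` (radius growing 8→16 Å — the monotone
area fixture).

## Estimator notes

Recovering a groove's inner radius from jittered data illustrates a bias
worth knowing about. The inscribed width is a minimum statistic: it is set
by the most inward-jittered atom in the slab, so at jitter SD 0.3 Å it
understates a 10 Å radius by ~6%. The max chord is the mirror-image
maximum statistic and overstates it similarly. Under symmetric jitter the
two biases cancel, so `recover_inner_radius()` averages the
inscribed-plus-atom-radius and half-chord estimates; on seeded test
grooves this recovers the nominal radius to ~1%.

## Problem sizes

The test suite and the acceptance script run entirely on generated
structures: grooves of 100 Å length (roughly 500–3,200 pseudo-atoms),
sphere systems of 1–40 atoms, SASA models up to ~1,600 atoms, and
0.25–0.5 Å lumen grids. The full suite completes in well under a minute
on one CPU; profiling a full-length deposited bridge model
(tens of thousands of atoms, ~300 Å extent) takes on the order of a
minute per stage at default resolution.

## Known limitations

* The axis is straight; strongly bent or superhelical channels would need
  a curved-centreline method (HOLE-style), which this package does not
  attempt.
* The convex closure overestimates lumen area when the wall is strongly
  non-convex in cross-section or when multiple wall layers widen the
  hull; the morphological mode is the fallback, at the cost of an `alpha`
  choice.
* PDB files do not store radii, so a written-then-reread synthetic model
  gets element-table radii (1.70 Å for carbon) rather than the
  generator's `atom_radius`; in-memory analysis keeps the generator
  values.
* SASA is accessible-surface only (no molecular/solvent-excluded
  surface), and buried-surface conventions differ between tools — compare
  like with like, and prefer the two-sided/one-sided pair this package
  emits over a single undocumented number.
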