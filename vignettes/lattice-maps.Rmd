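---
title: "Continuous classification and geographic maps of 2D lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous classification and geographic maps of 2D lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geolattice)
```

## The model

A planar lattice is determined by a basis (v1, v2), but infinitely many
bases generate the same lattice and any *unique* reduced basis is
necessarily discontinuous somewhere along a deformation loop. `geolattice`
therefore classifies lattices by quantities attached to the *obtuse
superbase* v0 = −v1 − v2, v1, v2 with all conorms p_ij = −v_i·v_j ≥ 0.
Every lattice has one, it is unique up to isometry, and the sorted square
roots r_ij = √p_ij — the root invariant RI — are complete and continuous:
two lattices are isometric exactly when their RIs agree, and a small basis
perturbation moves RI slightly.

Chirality is carried separately. Mirror-symmetric lattices (rectangular,
centred rectangular, square, hexagonal) have sign 0; these are exactly the
lattices with a repeated root component or r12 = 0. Oblique lattices get
sign ±1 from the orientation of the length-ordered superbase, so RI plus
the sign classifies up to rigid motion, and reflection flips only the sign.

Normalizing by the size σ = r12 + r01 + r02 yields the scale-free projected
invariant PI = (x, y) = ((r02 − r01)/σ, 3 r12/σ) in the quotient triangle
QT with vertices (0,0), (1,0), (0,1). The five Bravais classes partition
QT: the square vertex (0,0), hexagonal vertex (0,1), rectangular open
bottom edge, centred-rectangular open vertical edge and hypotenuse, and the
oblique interior. The vertex (1,0) is the unattained limit of infinitely
eccentric rectangular cells.

Gluing the two chirality copies of QT along their common boundary gives a
(punctured) sphere. The spherical map sends the QT incentre
(t, t), t = 1 − 1/√2, to the poles and the boundary to the equator;
latitude interpolates linearly along incentre rays, and longitude is the
planar bearing from the incentre measured anticlockwise from the Greenwich
direction. The Greenwich point G = (0, √2 − 1) is fixed by the line through
the incentre and (1, 0); its planar bearing is 157.5°. Lattices on the open
segment from (1,0) to the incentre receive longitude +180° rather than
−180°, making the longitude half-open in (−180°, 180°].

Four printed anchors pin this construction down and are enforced in the
tests: the square lattice maps to longitude 67.5°, the hexagonal lattice to
−45°, the centred-rectangular lattice at the hypotenuse midpoint to
−112.5°, and the rectangular lattice with cell 1 × (2√2 − 1) to 112.5°.
The centred-rectangular family on the vertical edge crosses G at the side
ratio b/a ≈ 1.098 (`greenwich_ratio()` solves this with `uniroot` to
1e−14), matching the two-significant-figure value 1.1 quoted for the
construction.

```{r anchors}
lattice_invariants(basis2d(c(1, 0), c(0, 1)))$sphere       # square
lattice_invariants(cell_to_basis(cell2d(1, 1, 120)))$sphere # hexagonal
greenwich_ratio()
```

## Parameters that matter

* `sym_tol` (default `1e-9`, dimensionless, relative to σ) controls when a
  lattice is declared mirror-symmetric and which Bravais subspace it is
  snapped to. The default is deliberately strict: real experimental cells
  that are oblique by 0.01° *stay* oblique, mirroring how database-scale
  studies count near-rectangular lattices as oblique rather than snapping
  them. Workflows on measured cells should opt into a larger tolerance
  explicitly (`--sym-tol` in the CLI).
* `pixel` (QT maps, default 0.005 dimensionless; sphere maps, default 1°;
  parameter maps, default 0.1 Å) sets heat-map resolution. Binning is
  half-open and lower-inclusive, with the top edge closed so domain maxima
  are retained; points on the QT hypotenuse simply fall into their
  containing bin.
* `tol` in `selling_reduce` (default `1e-12`, relative to max |v_i|²) is
  the acuteness threshold of the reduction loop. It is scale-aware so that
  exactly-right angles do not trigger endless sign flips.

## Numerical choices

The Selling step for an acute pair (v_i, v_j) replaces v_i → −v_i and
v_k → v_k + 2 v_i, decreasing the superbase norm sum by 4 v_i·v_j > 0, so
termination is guaranteed; the iteration cap (10 000) only guards against
float pathologies. When several pairs are acute the scan order
(1,2), (0,1), (0,2) is fixed, which makes runs bit-reproducible. The
canonical superbase orders vectors by length, which provably sorts the
conorm triple; remaining ties are genuine symmetries of the lattice and
harmless. Collinear bases are rejected, never repaired.

One floating-point effect deserves emphasis: for an achiral lattice whose
basis has been rotated or re-based, a conorm that is exactly zero in exact
arithmetic is computed as ~1e−16·σ², and the square root amplifies this to
~1e−8·σ in root space. Root-space equalities on scrambled inputs can
therefore only be trusted to about 1e−7 relative, even though conorms
themselves agree to 1e−9 and better. The test suite reflects this: exact
family bases are checked at 1e−9, rotated/re-based ones at the
noise-floor-aware tolerances (3e−7 for classification). Users classifying
rotated coordinate data should not set `sym_tol` below ~1e−7.

`qt_latitude` raises an error for an interior QT point tagged with sign 0,
since sign 0 and boundary membership are equivalent for genuine lattices —
an interior achiral point indicates an upstream tolerance mismatch rather
than a valid input. The consistency window scales with `sym_tol` (a sign-0
verdict at tolerance τ displaces (x, y) from the exact boundary by at most
3τ).

## The synthetic generator

`gen_lattices()` draws each Bravais family with closed-form ground truth:
squares and hexagons from one length, rectangles from a ≤ b, centred
rectangles from the printed superbase (2a, 0), (−a, b), (−a, −b), and
oblique lattices directly as reduced cells (a ≤ b, obtuse γ restricted so
the standard superbase is already obtuse). Lengths default to 0.5–5 Å,
ordinary molecular-crystal scale. Oblique sampling excludes a guard band
(1e−6 relative) around the symmetric loci so every generated sign is
unambiguous, and a mirror-pair mode emits exact enantiomorph pairs for
chirality-balance checks. Random rotations and unimodular re-basings
(elementary factors, entries capped at 5) exercise invariance without
changing the lattice.

`gen_cell_table()` emulates a heterogeneous crystal-database cell table:
cubic, orthorhombic, monoclinic, triclinic and hexagonal cells with edges
3–20 Å, plus an optional cluster mode that piles near-identical monoclinic
cells (short axis ≈ 3.5 Å by default) onto a single parameter-map pixel,
the way heavily redeposited benchmark structures dominate real maps. What
the generator does **not** emulate: the empirical length/angle correlations
of real databases, space-group frequencies, or measurement error models.
Passing tests therefore demonstrate the correctness of the invariant
machinery, not distributional realism of any database.

Problem sizes in the shipped tests — 500 lattices × 10 re-bases for
invariance, 200 bases against the brute-force oracle (all ~2000 unimodular
matrices with entries ≤ 10), 10 000 lattices for triangle containment,
1000-cell tables for count conservation — are the package's chosen balance
between coverage and a comfortably fast default test run.

## Design decisions taken where the design was open

* **Rigid-motion representative.** The full inequality list for a
  rigid-motion reduced *basis* is not reproduced; rigid-motion classes are
  represented as (reduced-cell parameters, sign), which is equivalent via
  the 1–1 correspondence between reduced bases and obtuse superbases and
  avoids re-deriving boundary cases.
* **Quadratic invariant middle component.** QI is returned as
  (√q11, √(−q12), √q22) from the non-acute reduced form (q12 ≤ 0), the
  unique choice with homogeneous length units.
* **Distances.** `ri_distance` is the L∞ metric on root triples;
  `dissymmetry` reports Euclidean QT distances to the four non-generic
  Bravais subspaces. Both are convenience measures; calibrated
  lattice-space metrics and chirality distances are deliberately out of
  scope.
* **Quotient-square fold.** Negative-sign points are folded into the
  quotient square by the enantiomorph pairing (x, y) ↔ (1 − y, 1 − x).
* **Poles in spherical binning.** Coordinates with undefined longitude
  (exact poles) are binned at longitude 0 within their polar cap.
* **Degrees end-to-end.** All angular quantities are degrees, matching
  crystallographic convention, with the half-open wrap (−180°, 180°].

## Known limitations

Only 2D lattices are classified; 3D cells are seen through their three
coordinate-pair sublattices, which is informative but not a complete 3D
invariant. Root-space comparisons below the √eps noise floor are
meaningless for rotated inputs (see above). The CLI is a thin dispatcher
intended for batch tables, not a full crystallographic toolchain; CIF
ingestion is left to adapters that produce the delimited cell-table format.
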