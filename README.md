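# geolattice

Continuous isometry classification and geographic-style maps of
two-dimensional lattices.

## The problem

A 2D lattice is the set of integer combinations of two independent plane
vectors — the geometry that remains when a periodic crystal is stripped to a
single point per cell. The classical classifications (five Bravais classes,
wallpaper groups) are *discrete*: an arbitrarily small perturbation of a
rectangular cell turns it oblique, so symmetry labels and reduced cells jump
under the noise inherent in any experimental or simulated structure
determination. Modern structure databases and crystal-structure-prediction
runs hold millions of cells, which demands a classification that is
*complete* (distinguishes all non-isometric lattices), *continuous* under
perturbation, and cheap to compute.

`geolattice` implements such a classification for planar lattices, and a
pipeline that applies it to tables of 3D unit cells (each 3D cell
contributes the three 2D sublattices spanned by the vector pairs
{v2, v3}, {v1, v3}, {v1, v2}), producing quotient-triangle and spherical
heat maps of large cell collections.

## The invariants

For a basis (v1, v2), the *superbase* adds v0 = −v1 − v2. Selling/Delaunay
reduction makes all *conorms*

    p12 = −v1·v2,  p01 = −v0·v1,  p02 = −v0·v2

non-negative (every planar lattice admits such an *obtuse superbase*, unique
up to isometry). The package computes, per lattice:

* **Root invariant** RI = (r12, r01, r02), r_ij = √p_ij, sorted — a complete
  isometry invariant, in ångströms;
* **Chirality sign** ∈ {−1, 0, +1} — 0 exactly for mirror-symmetric
  lattices; RI plus the sign is complete up to rigid motion;
* **Projected invariant** PI = (x, y) with x = (r02 − r01)/σ, y = 3 r12/σ,
  σ = r12 + r01 + r02 — scale-free coordinates in the quotient triangle QT
  with vertices (0,0) (square), (0,1) (hexagonal), open edges for
  rectangular / centred-rectangular lattices and the interior for oblique
  ones;
* **Bravais label** (tp/hp/op/oc/mp) by nearest-subspace assignment in QT
  with an explicit tolerance;
* **Spherical coordinates**: the two chirality copies of QT glue into a
  sphere; the QT incentre (t, t), t = 1 − 1/√2, maps to the poles, the
  boundary (mirror-symmetric lattices) to the equator, and the Greenwich
  meridian passes through G = (0, √2 − 1), giving every lattice a latitude
  φ ∈ [−90°, 90°] and longitude μ ∈ (−180°, 180°].

The inverse direction is also available: `lattice_from_ri()` rebuilds an
explicit basis from any valid root invariant and sign.

## Worked example

```r
library(geolattice)

# the inversely designed lattice whose invariant sits near the QT incentre
li <- lattice_invariants(basis2d(c(1.9, 0), c(-0.18, 3.63)))
li$ri
#> <root_invariant>  (r12, r01, r02) = (0.584808, 1.80776, 3.5871)
li$pi
#> <projected_invariant>  (x, y) = (0.297565, 0.293398)  sign = +1
li$sphere
#> <sphere_coord>  latitude 88.8752 deg, longitude -151.33405 deg
```

The root invariant says the obtuse superbase of this lattice has conorm
square roots (0.58, 1.81, 3.59) Å; the projected invariant (0.298, 0.293)
lies within 0.01 of the incentre (t, t) ≈ (0.2929, 0.2929), so the lattice
is deep in the oblique interior — its latitude 88.9° is almost at the north
pole (sign +1), which is exactly what this basis was designed for.

A batch run over a synthetic cell table:

```r
tab <- gen_cell_table(n = 200, seed = 42, cluster_n = 50)  # 250 cells
rec <- map_table(tab)                                      # 750 sublattices
figure_report(rec)
#> lattice map report
#>   total                        750
#>   sign>0                       81
#>   sign>=0                      629
#>   sign<0                       121
#>   ...
#>   Bravais classes:
#>     tp       126  (0.168)
#>     hp        36  (0.048)
#>     op       386  (0.515)
#>     mp       202  (0.269)
grid <- bin_qt(rec, pixel = 0.005)    # Fig.-style QT heat map
sum(grid$counts)                      # 750: counts are conserved
```

The same operations are scriptable from a shell through the thin CLI at
`inst/cli/lat2d` (subcommands `reduce`, `invariants`, `map`, `fixtures`).

## Scope

The package covers planar lattices only: 3D cells enter through their three
2D sublattices. 3D reduction theory (Niggli cells, 3D root invariants), the
calibrated metrics and chirality distances of the full lattice-space
theory, and database connectivity are out of scope.
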