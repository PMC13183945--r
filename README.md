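# cyclohelix

Structural analysis of self-assembled cyclo-dipeptide crystals that pack
into supramolecular triple-helical "micro-ropes" — most prominently the
cyclo-Trp-Pro (c-WP) stereoisomer family, whose crystals wind three
hydrogen-bonded strands of stacked molecules about a common axis with a
handedness (S = left, Z = right, in rope-maker's nomenclature) set by the
configuration of the tryptophan residue.

The package is for structural bioinformaticians and crystallographers who
want to go from coordinates (small-molecule CIF, PDB, extended XYZ, or
MD-style coordinate trajectories) to quantitative calls about such
assemblies:

* **Supramolecular chirality.** The central statistic is the H-bond
  rotation-angle profile: for every stacking layer `n` along the helix
  axis, the signed angle `theta_n` between the projection of the layer's
  Trp main-chain H-bond vector onto the plane perpendicular to the axis
  and the projection of the reference bond in the first layer
  (`theta_0 = 0`, counterclockwise positive viewed from the +axis tip,
  cumulatively unwrapped). A decreasing profile (slope below −1°/layer by
  default) is a clockwise rotation along the axis and is classified S; an
  increasing one, Z.
* **Helix geometry.** Strands are traced through the H-bond graph, each
  fitted with a circular helix (radius `r`, twist per layer `Δθ`, rise
  `Δz`, pitch `= 360/|Δθ|·Δz`), and the "inner diameter" is measured as
  the circumcircle through the three Trp Cα atoms of one layer.
* **Interactions.** Geometric H-bonds (D···A ≤ 3.5 Å and D-H···A ≥ 150°),
  heavy-atom contacts (≤ 5.4 Å C–C, ≤ 4.6 Å otherwise), π–π stacking
  (ring-centroid separation ≤ 6.5 Å, patterns I/II inter-helix, III
  intra-helix), per-crystal-unit normalization, and free-energy
  landscapes `G = −RT ln P(distance, angle)`.
* **Mechanics.** Tensile stress–strain metrics (modulus over the 0–0.2 %
  strain window, fracture stress, work of rupture) and AFM
  nanoindentation via the Hertz model
  `F = (4/3)·E/(1−ν²)·√R·δ^{3/2}` with joint contact-point fitting and
  cantilever-deflection-corrected point stiffness.
* **Synthetic ground truth.** A seeded generator builds triple-helix
  structures (and trajectories, and force curves) with known handedness,
  pitch, radius and H-bond geometry, so the whole pipeline is testable
  end to end; idealized P6₃ crystal models of the four c-WP stereoisomer
  forms are included (`synthetic_cwp_crystal()`, clearly labelled
  synthetic).

## Worked example

```r
library(cyclohelix)

# idealized model of the anhydrous L-Trp crystal form, expanded from its
# P6_3 asymmetric unit, analyzed as a 1x1x3 supercell
s <- synthetic_cwp_crystal("cLWLP")
m <- triple_helix_metrics(s, supercell = c(1, 1, 3))
m
#> twist: S (slope -60.000 +/- 0.000 deg/layer, threshold 1.00)
#> strands: 3 over 6 layers; pitch 32.464 A, strand radius 6.035 A
#> inner (C-alpha circle) diameter 15.698 A; 2 x strand radius 12.070 A

min(m$hbonds$da_distance)   # shortest diketopiperazine N...O H-bond
#> [1] 2.916
```

The verdict S says the Trp main-chain H-bonds rotate clockwise along the
c axis (−60° per stacking layer, the 6₃ screw); the inner diameter
15.698 Å is the Cα circumcircle of one layer; 2.916 Å is the
strand-forming N–H···O=C bond. Mirroring the structure
(`mirror_structure(s)`) flips the verdict to Z exactly, the behaviour of
the D-Trp forms.

A free-standing strand model with six molecules per helical turn gives
the fitted pitch directly:

```r
g <- gen_triple_helix(helix_spec(delta_theta = -60, delta_z = 35.806 / 6,
                                 radius = 7, ca_radius = 15.698 / 2,
                                 d_no = 2.916, decorations = character(0)))
triple_helix_metrics(g$structure)$pitch
#> [1] 35.806
```

A thin command-line front end over the same functions is in
`inst/scripts/cyclohelix-cli.R` (subcommands `analyze`, `chirality`,
`simulate-helix`, `mech-indent`, `mech-tensile`, `selftest`).

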