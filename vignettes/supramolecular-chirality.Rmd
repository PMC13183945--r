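---
title: "Classifying supramolecular twist in peptide micro-rope crystals"
author: "cyclohelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying supramolecular twist in peptide micro-rope crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclohelix)
```

## The system and the question

Cyclo-Trp-Pro (c-WP) dipeptides crystallize as hexagonal micro-prisms in
which stacked molecules, linked by N–H···O=C hydrogen bonds between the
diketopiperazine rings of adjacent Trp segments, wind into helical
strands; three strands intertwine about a common axis into a
supramolecular triple helix, and neighbouring helices pack into
micro-rope-like crystals. The scientific question this package answers
quantitatively is: *given coordinates, which way does the rope twist* —
S (left-handed) or Z (right-handed), in rope-maker's nomenclature — *and
what are the helix dimensions and the interactions that hold it
together?*

## The rotation-angle statistic

The chirality call rests on one statistic. Along the stacking axis
(crystallographic **c** by default), molecules fall into discrete layers.
For each layer $n$, take the strand-forming H-bond vector (donor
nitrogen to acceptor oxygen), project it onto the plane perpendicular to
the axis, and measure the signed angle $\theta_n$ between that
projection and the projection of the reference bond in the first
(lowest) layer, with $\theta_0 = 0$. Angles are measured
counterclockwise-positive when viewed from the $+$axis tip — a
right-handed convention fixed once throughout the package. The profile
is cumulatively unwrapped (assuming the true twist stays below
180°/layer), and its least-squares slope classifies the structure:

* slope $< -\tau$: angles decrease, the bonds rotate clockwise along the
  axis — **S** twist;
* slope $> +\tau$: counterclockwise — **Z** twist;
* otherwise **undetermined**,

with $\tau = 1$°/layer by default. Mirror reflection negates every
projected angle exactly, so the verdict flips exactly — an invariant the
test suite enforces with no tolerance.

Two implementation details matter. First, with several strands the
profile is assembled from per-strand *azimuth increments* between
consecutive layers rather than absolute angles: increments are
reference-free, so strands broken by thermal disorder still contribute,
and for an intact strand the cumulative sum reduces to the textbook
angle-from-reference definition. Second, the profile uses only bonds
between consecutive layers (the strand-forming ones); in periodic cells
this also excludes bonds wrapping across the boundary.

## Geometric criteria

All cutoffs are held in configuration objects and default to the
standard values for this class of analysis (lengths in Å internally;
criteria quoted in nm elsewhere are converted once):

| quantity | default | notes |
|---|---|---|
| H-bond D···A | ≤ 3.5 Å | donor = N/O carrying a covalent H |
| H-bond D-H···A angle | ≥ 150° | measured at the hydrogen |
| contact, C–C | ≤ 5.4 Å | non-hydrogen atoms, intermolecular |
| contact, other pairs | ≤ 4.6 Å | |
| π–π centroid distance | ≤ 6.5 Å | interplanar angle folded to [0°, 90°] |
| π–π pattern bands | 6.5 / 8.0 Å | I/II inter-helix split, III intra-helix floor |
| FEL temperature | 300 K | $G = -RT\ln P$, $R = 8.3145\times10^{-3}$ kJ mol⁻¹ K⁻¹ |
| twist threshold | 1°/layer | |

Hydrogens attach to their nearest heavy atom within 1.5 Å — generous
enough to survive thermally stretched X–H bonds, comfortably below the
~1.9 Å H···acceptor distance of a strong H-bond. For water oxygens with
no modelled hydrogens (the usual riding-model X-ray case) a heavy-atom
fallback accepts donors on the distance criterion alone and flags them;
the fallback is restricted to water residues so a carbonyl oxygen can
never masquerade as a donor. Strand *connectivity* (not the reported
H-bond statistics) uses a relaxed 90° angle floor: a single bent bond
should not sever a strand, and at zero disorder the two criteria select
identical bond sets.

Group labels (`W_mc`, `W_sc`, `W_aro`, `W_NH`, `P_mc`, `P_sc`, `water`)
partition each molecule by an ordered pattern table (shipped as
`inst/extdata/cwp_groups.yaml`, user-replaceable). The labels are
exclusive — indole N-H and aromatic carbons take precedence over the
generic side chain — because contact maps over overlapping memberships
would double-count; both the mean contact count per frame and the
contact probability (fraction of frames with ≥ 1 contact) are reported,
since either normalization is defensible. The indole is treated as two
rings (pyrrole + benzene) by default, with a fused 9-atom mode
available.

## Helix fitting and the reported diameters

Each traced strand is fitted with a circular helix. The axis direction
is optimized as a 2-parameter problem (for any trial axis the circle
centre, radius, phase, twist and rise have closed-form estimates), then
all nine parameters are polished jointly; at zero noise the fit is exact
to solver tolerance, and fits are deterministic, which makes
rigid-motion invariance testable at 10⁻⁶ Å. Fragments shorter than 60 %
of the longest strand are excluded (a 4-point fragment has barely more
coordinates than the model has parameters) and the remaining fits are
averaged weighted by strand length. Radius is only well-conditioned when
a strand covers a full turn, so the synthetic recovery study scales the
layer count as $\max(10, \lceil 400°/|\Delta\theta|\rceil)$.

"Diameter" is genuinely ambiguous for a triple helix, so the report
exposes the candidates separately: twice the fitted strand-axis radius
(`diameter_axis`), and the circumcircle diameter through the three Trp
Cα atoms of one layer (`inner_diameter`, the Methods-style inner
diameter). For the c-WP forms the printed 15.698 Å value coincides with
the Cα circle. Similarly the printed 35.806 Å pitch is not an integer
multiple of the 6₃ screw (which would give $6 \times c/2 = 32.46$ Å);
operationally the package reports the fitted pitch of whatever strand it
is given, and the bundled strand model reproduces the printed value from
its six-molecules-per-turn geometry.

In periodic supercells, strand tracing re-anchors every molecule to the
lattice image nearest its predecessor and then aligns whole strands by
their fitted axis centres, so helix fits and Cα triangles never mix
periodic images (nearest-image reasoning alone fails here because
neighbouring bundles interdigitate: the Cα circle, 15.7 Å across, is
wider than the 14.9 Å cell).

## Layers

Molecule centroids are projected on the axis and split by 1-D single
linkage wherever the gap exceeds `gap_tol`. The default threshold is
derived from the gap distribution itself — a quarter of the way from the
median (within-layer) gap to the maximum (between-layer) gap — and an
error is raised when the distribution shows no bimodal structure rather
than returning arbitrary layers. The "first crystal layer" is the lowest
along the axis.

## The synthetic generator

`gen_triple_helix()` builds the study system: molecule $(s, n)$ of
strand $s$, layer $n$ sits at azimuth $\phi_0 + 360°s/S + n\Delta\theta$
and height $n\Delta z$, each molecule rigidly co-rotated with its
azimuth. The rigid molecule carries the analysis-relevant chemistry: a
donor N with its H aimed at the next layer, an acceptor O placed so the
consecutive-layer N···O distance is exactly `d_no` (2.9 Å by default)
and collinear with N–H, a Cα marker at a controllable radius, a planar
indole (5 + 6 fused rings, standard 1.40 Å aromatic bonds) stacked
perpendicular to the axis, and optionally a compact proline-like cluster
placed by an automatic clearance search. Ground truth (handedness
$= \mathrm{sign}(\Delta\theta)$ mapped to Z/S, pitch
$360/|\Delta\theta| \cdot \Delta z$, radii, layer count) is attached to
every structure. Construction fails loudly when the geometry is
impossible: intermolecular approaches below 1.5 Å at zero jitter, or a
consecutive-layer N–N separation leaving no room for the acceptor.

What the generator emulates: the helical lattice geometry, exact H-bond
chemistry, hexagonal bundle packing, water sites, and Gaussian thermal
jitter (i.i.d. per coordinate, one seeded RNG per call). What it does
not: real force-field dynamics, correlated motions, anisotropic
displacement, disorder, or realistic side-chain conformations. Passing
the recovery studies therefore demonstrates that the *analysis* is
correct and robust to uncorrelated noise at crystallographic amplitudes
(the studies use 0.1 Å jitter, a typical thermal displacement, within
the ≤ 0.2 Å regime the generator supports); it does not validate the
analysis against MD-specific artefacts.

`synthetic_cwp_crystal()` supplies idealized P6₃ models of the four
c-WP stereoisomer forms, built from their published lattice constants
(c-LWLP: a = 14.9474, c = 10.8213 Å; hydrated c-LWDP: a = 15.1447,
c = 10.8688 Å), six molecules per cell, the 2.916 Å interlayer N···O
bond, a 15.698 Å Cα circle, and — in the hydrated forms — a core water
at 2.959 Å from the carbonyl oxygen. The D-Trp forms are exact mirror
images. These are *synthetic stand-ins*, useful for validating the
pipeline's lattice-level geometry; contact or stacking statistics on
them are qualitative only because the surrogate molecule is schematic.

## Mechanics

Tensile curves: the modulus is the least-squares slope over the initial
0–0.2 % strain window, fracture is at maximum stress, work of rupture is
the trapezoidal integral to fracture. Indentation: the Hertz model is
fitted with the contact point $z_0$ as a free parameter (initialized at
the first force sample above 3× the pre-contact noise floor), the
indentation deflection-corrected as $\delta = (z - z_0) - F/k_c$, and a
soft-L1 loss by default to damp snap-in artefacts (plain least squares
available). Point stiffness follows the ratio definition — maximum force
over corrected deformation at that point — with a slope variant over the
top 20 % of the curve as an option, since either reading of "ratio of
normal force to sample deformation" is found in practice.

## Numerical choices and limitations

* Minimum-image distances use exact 27-image enumeration on the wrapped
  fractional difference (cell lists sized by the perpendicular cell
  heights prescreen candidates); the tests compare against independent
  125-image enumeration on random triclinic cells.
* Molecules are covalent connected components under a 1.2× covalent
  radius-sum bond rule; duplicates after symmetry expansion are removed
  at 0.1 Å (standard special-position handling).
* Unwrapping assumes |true twist| < 180°/layer; helices at the Nyquist
  edge alias.
* The twist call needs ≥ 3 layers with consecutive-layer H-bonds; highly
  fragmented H-bond networks return `undetermined` rather than a guess.
* Trajectory statistics windows are frame-index ranges (default: the
  final half, the equilibrated portion of a production run); callers
  needing an absolute time window can map times to indices via the
  trajectory's `times`.
* Problem sizes in the bundled studies — 200 seeded helices (with mirror
  checks), 50 random 200-atom frames for the oracle equivalences, 100
  noisy indentation curves — were chosen to exercise the full parameter
  ranges at comfortable statistical margins on a single CPU.

## A complete run

```{r example, eval = FALSE}
s <- synthetic_cwp_crystal("cLWLP")
report <- run_analysis(analysis_config(s, supercell = c(1, 1, 3),
                                       out_dir = "cwp-out"))
report$chirality$twist     # S, slope -60 deg/layer
report$hbonds_per_unit     # strand-forming bonds per crystal unit
```
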