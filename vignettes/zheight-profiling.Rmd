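---
title: "Profiling particle z-heights and interface adsorption in vitreous ice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling particle z-heights and interface adsorption in vitreous ice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryolayer)
```

## The problem

In single-particle cryo-EM, macromolecules embedded in a thin film of
vitreous ice are often not where one would like them to be: instead of
floating mid-ice they adsorb to the air-water interface (AWI) or to the
supporting-film interface (for graphene supports, the graphene-water
interface, GWI). Adsorption damages particles, biases their orientations
and degrades reconstructions. `cryolayer` quantifies *where particles sit
in the ice* and *how their orientations are distributed*, using only
refinement metadata — no images or volumes are read.

The key observation is that a particle's refined defocus tracks its depth
along the optical axis. Per-particle defocus values from CTF refinement
therefore give a relative z-coordinate for every particle in a micrograph,
and the shape of the per-micrograph z distribution distinguishes a mid-ice
layer (symmetric, Gaussian-like) from interface adsorption (a steep slope
at the interface and a long tail of free particles) and from two-interface
adsorption (bimodal).

## The procedure

For each micrograph:

1. **Defocus to z.** The particle defocus is the mean of the two
   astigmatic values (astigmatism is in-plane and carries no height
   information). z is the mean-centred defocus, with sign set by a
   convention: by default smaller underfocus maps to larger z
   (`defocus_decreasing_up`). The physical identity of the positive side
   (AWI or GWI) is dataset-level configuration: in real data the
   correspondence differs between specimens, so it is never inferred from
   the sign.
2. **Plane fit.** Ice films are tilted relative to the detector, so a
   least-squares plane `z = a*x + b*y + c` is fitted to the (x, y, z)
   cloud. Vertical (z-residual) least squares is used rather than total
   least squares: film tilts are at most a few degrees, where the two
   agree to first order, and the vertical form has a closed-form solution
   whose standard errors are easy to validate.
3. **Signed orthogonal distances.** Each particle's signed distance to the
   fitted plane (`distances_to_plane()`) is the z-height used everywhere
   downstream. By the least-squares property these average to zero over
   the fitting cloud.
4. **Distribution shape.** The distance set is summarised by a
   Gaussian-kernel KDE (mode = grid argmax), the moment-coefficient
   skewness `g1 = m3 / m2^(3/2)`, a tier classification, a layering call,
   and the central-80% ice thickness.

Dataset-level summaries collect per-micrograph skewness into a Tukey
boxplot (whiskers at the furthest datum within 1.5 x IQR), tier fractions,
and a thickness mean with a normal-approximation 95% confidence interval.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_particles` | 10 | micrographs below this are excluded from summaries |
| `bandwidth` | Silverman | KDE bandwidth rule; overridable with a value in Angstrom |
| `prominence_frac` | 0.2 | KDE peak prominence (fraction of the global maximum) required to count as a layer |
| `thickness_fraction` | 0.8 | central fraction of particles defining the ice-thickness extent |
| `z_convention` | `defocus_decreasing_up` | sign of the defocus-to-z map |
| `interface_map` | `AWI_positive` | which interface sits on the positive z side |

Skewness tiers follow the conventional guideline: |g1| < 0.5 is
approximately symmetric, 0.5 <= |g1| <= 1 moderately skewed, |g1| > 1
highly skewed, signed by the tail direction. Boundary values (exactly 0.5
or 1) are assigned to the more-skewed tier, making the symmetric band an
open interval; the choice is arbitrary but deterministic and documented.

Two deliberate readings are worth stating. First, skewness is computed on
the **raw distances**, not on the KDE curve: Gaussian-kernel smoothing
leaves the third central moment unchanged while inflating the second by
the squared bandwidth, so the raw moments are the stabler estimator of the
same asymmetry. Second, the thickness rule is a quantile extent
(10th-to-90th percentile by default), which for a Gaussian layer of width
sigma equals `2 * 1.2816 * sigma` — a closed form used throughout the
tests. No trimming of extreme distances is applied.

## Orientation heatmaps

Orientations use the RELION ZYZ Euler convention (rot about z, tilt about
the new y, psi about the new z); the projection direction is the third row
of the orientation matrix and is independent of psi, which is why heatmaps
marginalise psi and plot (rot, tilt) only. Point groups (Cn, Dn, T, O, I)
are built as explicit rotation operators by generator closure and verified
closed under composition. Each particle is mapped to a canonical
representative of its symmetry-equivalence class: among all
group-composed orientations, the one with lexicographically minimal
(tilt, rot). Any deterministic fundamental domain yields equivalent
heatmaps up to relabelling, so the tested contract is equivalence-class
invariance — two datasets differing only by symmetry operators produce
bin-identical heatmaps — rather than a particular domain shape. Heatmap
extents are analytic for Cn/Dn (rot width 360/n; tilt folds to 90 degrees
for dihedral groups) and are determined numerically for T/O/I by reducing
a fine orientation grid once at group construction. Counts are binned raw,
matching refinement-package displays; a sin(tilt)-deweighted option
exists. `coverage_fraction()` (occupied bin fraction) is the single-number
summary of angular coverage.

## Tomogram analysis

Where tomograms are available, particle centres and interface marker
points (ice-crystal contamination for the AWI, supporting-film features
for the GWI) give a direct geometric picture. `analyze_tomogram()` fits
the three planes with the same least-squares machinery, converts voxels to
Angstrom, and reports the lower-edge particle-to-interface gaps: mean
orthogonal centre-to-plane distance minus one spherical particle radius
(the simplest shape model consistent with reporting an edge distance).
Gaps are also reported in slices (gap / voxel size). The monolayer flag
tests whether the central-80% extent of particle distances to their own
plane is at most one particle diameter (factor configurable).

## What the synthetic generator emulates

The generator produces RELION-style particle metadata with known ground
truth: per-micrograph tilted planes (slopes ~ N(0, 0.01), about half a
degree), uniform (x, y), z from a placement model, defocus consistent with
the chosen sign convention plus N(0, 30 Angstrom) measurement noise
standing in for CTF-refinement error, and orientations that are either
uniform over SO(3) or concentrated about an axis (von Mises-Fisher
direction with uniform psi).

Placement models inside a slab of thickness T (default 250 Angstrom):

- `mid_gauss`: truncated Normal, default sigma 50 Angstrom. The resulting
  central-80% particle extent is ~150 Angstrom, the lower end of the
  15-30 nm range typical of usable ice.
- `interface`: with probability `1 - free_frac` an exponential decay from
  the chosen interface inward, else uniform across the slab — the steep
  slope plus long tail of adsorption. The default decay length of 60
  Angstrom keeps the skewness magnitude above 1 (a pure exponential has
  skewness 2) after convolution with the 30 Angstrom defocus noise, i.e.
  the highly skewed regime observed for interface-adsorbed specimens.
  Note the sign relation: particles piled at the +z interface leave a
  tail toward -z, so the skewness sign is *opposite* to the adsorption
  side.
- `bimodal`: mixture of opposite-interface exponentials (both-interface
  adsorption, as seen on some supported films).
- `uniform_slab` and `double_layer` (two parallel Gaussian sheets)
  complete the set.

The generator emulates the *statistical* structure of real metadata, not
its physics: there are no images, no CTF model, no doming or motion, no
correlation between orientation and z, and defocus noise is homoscedastic
Gaussian. Passing recovery tests therefore demonstrates that the pipeline
correctly inverts the stated placement models at realistic noise — not
that real specimens obey those models.

## Numerical choices and degenerate inputs

- Plane fits require >= 3 non-collinear points (rank-checked QR); clouds
  below `min_particles` are excluded and logged rather than fitted.
- Zero-variance distance sets make the KDE and skewness undefined; both
  raise errors, and the layering call returns `indeterminate`.
- KDE grids span the data range plus three bandwidths; densities
  integrate to 1 within 1e-3.
- Peak prominence uses the standard walk-to-higher-ground definition, so
  a heavy tail (e.g. Laplace) never registers as a second layer.
- Truncated samplers use inverse-CDF forms (no rejection loops); a model
  length scale at or above the slab triggers a truncation warning.
- Asymmetric-unit ties in tilt are broken by rot within 1e-9 degrees.

## Problem sizes

The shipped tests and the acceptance script run the statistical checks at
the sizes where their oracles are sharp while staying desk-scale: 1e6
draws for the exponential-skewness oracle, 1e5 for quantile closed forms,
50 micrographs x 2000 particles for the full-pipeline thickness check, 20
seeded replicates per placement model (1500 particles each) for recovery
rates, and 20 replicates for the tomogram gap. The complete suite runs in
well under a minute.

## Known limitations

- Defocus-derived z is relative within a micrograph; absolute height in
  the film and the physical identity of the positive side require outside
  knowledge (`interface_map`).
- Vertical least squares biases coefficients for steep tilts; the
  implementation targets the small-tilt regime of flat ice films.
- The monolayer criterion and the spherical "lower edge" correction are
  operationalizations; both factors are exposed as parameters.
- The layering call counts KDE peaks; two layers closer than roughly the
  KDE bandwidth will read as one.
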