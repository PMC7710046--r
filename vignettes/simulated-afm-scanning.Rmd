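---
title: "Simulated AFM scanning: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated AFM scanning: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmscan)
```

## The scanning model and its assumptions

`afmscan` computes the image a hard AFM tip would record over a rigid
molecule. Three idealizations define the model, and all three matter when
interpreting output:

1. **Hard, non-elastic contact.** Atoms are van der Waals spheres; the tip
   is a rigid solid. There is no sample deformation, no tip–sample force
   curve, no compression. Real AFM flattens soft proteins, so simulated
   height scales are systematically *larger* than experimental ones. This is
   deliberate: the goal is shape and relative protrusion, not absolute
   calibration, and the comparison score is intensity-affine-invariant for
   exactly this reason.
2. **Noise-free scanning.** No instrument noise or background is added.
   Background "cleaning" exists only for preparing *experimental* images.
3. **Geometric tip.** The tip is a probe sphere of radius $R$ capped by a
   tangent cone of half-angle $\alpha$ about a vertical axis. The cone is
   infinite: a tall feature far from the cell can legitimately set the
   height through a cone-flank contact, which is physically the shadowing a
   wide tip produces. No tip-length truncation is applied.

For a tip axis at lateral distance $d$ from an atom of radius $r$ centred at
height $z$, the first-contact height of the tip's lowest point is

$$h = \begin{cases}
z - R + \sqrt{(R+r)^2 - d^2}, & d \le (R+r)\cos\alpha \quad\text{(probe sphere)}\\
z - R + \dfrac{R+r}{\sin\alpha} - d\cot\alpha, & d > (R+r)\cos\alpha \quad\text{(cone flank)}
\end{cases}$$

The branch boundary is the tangency circle where the probe sphere meets its
cone; the expressions agree there to machine precision (a dedicated test
draws 1500 random $(R, r, \alpha)$ and checks $|h_s - h_c| < 10^{-12}$ nm).
A cell's height is the maximum over all atoms, clamped at the stage
($h \ge 0$). Because no closed-form derivation should certify itself, the
test suite carries an independent brute-force oracle: the tip profile is
discretized at $10^{-4}$ nm and lowered until first overlap; full maps from
20 random structures agree with the closed form to better than
$2\times10^{-6}$ nm.

## Parameters, units, defaults

| Parameter | Meaning | Unit | Default | Why |
|---|---|---|---|---|
| $R$ | probe sphere radius | nm | 1.0 | middle of the demonstrated 0.5–1.5 nm range; larger $R$ smooths |
| $\alpha$ | cone half-angle | degrees at interfaces, radians internally | 10 | middle of 5–15°; larger $\alpha$ blurs boundaries and cavities |
| $a$ | scanning step | nm | 0.5 | typical demonstrated resolution; 1.0 nm gives visibly pixelated maps |
| margin | grid padding | nm | 2.0 | captures cone-flank contacts near the boundary at typical $R, \alpha$ |
| $\sigma$ | Gaussian blur | nm (converted to pixels by the pixel size) | 0 (off) | emulates experimental averaging when comparing to real images |

Both monotonicities are exact theorems of the model, not trends: increasing
$R$ or $\alpha$ can never decrease any cell height (tested pointwise over
the $3\times3$ parameter grid). Coarsening $a$ on an aligned grid subsamples
the identical underlying surface, exactly.

## Geometry conventions

- **Units**: nm everywhere after parsing; PDB files are Å and are converted
  on read/write.
- **Rotation**: about the structure centroid, intrinsic Z-Y-Z Euler angles
  in degrees at the CLI ($R_z(\phi) R_y(\theta) R_z(\psi)$), or an explicit
  row-major rotation matrix. The convention is stated because upstream
  tools differ and none is canonical.
- **Staging**: the structure is translated so
  $\min_i (z_i - r_i) = 0$ — the molecule rests on the stage by its
  lowest *sphere bottom*, not atom centre. The alternative (centres) shifts
  every height by a constant and nothing else; bottoms were chosen so a
  bare stage reads exactly 0.
- **Grid registration**: the origin is snapped so one cell centre sits at
  the centroid's lateral position. This makes maps reproducible under
  bounding-box jitter, makes a $2a$ grid an exact subsample of an $a$ grid
  built around the same centroid, and keeps the literal span contract
  (single atom, $r=0.2$, $a=0.1$, no margin $\rightarrow$ $5\times5$).
- **Row order**: `heights[j, i]` has rows indexing $y$ ascending; rendering
  flips rows so +y points up in the image.

## The synthetic-data generator

`make_fixture()` emits structures with closed-form geometry: single atom,
dimer, chain, parametric helix, ring, and uniform-random atom clouds
(seeded). Two features deserve justification:

- **Pseudo-domain spheres.** Real AFM-scale features are whole protein
  domains (~1 nm radii), not atoms. The `radius` override encodes a domain
  as one oversized sphere. The ring-opening trajectory uses 0.8 nm spheres
  on a 1.2 nm circle: at atomic scale a 2 nm-radius ring leaves the cavity
  floor at 0 in every frame (the tip bottoms out on the stage) and no trend
  can exist; at domain scale the closed ring roofs its cavity and the
  central mean height falls strictly monotonically as subunits pivot
  outward — the fixture-scale analogue of a chaperone ring's
  closed-to-open transition.
- **Opening motion.** Each subunit pivots rigidly about its base-circle
  position, tilt interpolated linearly from 0 to `tilt_max_deg` across
  frames. This is a geometric mock, not a physical pathway.

What a green test on fixtures establishes: the scanner, geometry, formats
and scores behave exactly as specified on structures with known answers.
What it does not establish: agreement with any particular experimental
image, which depends on orientation search, tip shape uncertainty and
sample deformation — all outside the model.

## Movies

All frames are rotated identically, staged with the *first frame's* offset,
and scanned on one grid covering the union of all frames' bounding boxes.
A shared grid prevents spurious apparent motion from per-frame grids; a
shared stage offset keeps genuine vertical motion visible (per-frame
restaging is behind `restage_per_frame = TRUE`, since upstream conventions
differ and the choice is observable in the output). Export fixes one
z-colour scale at the global maximum so protrusion changes read correctly
across frames.

## Image comparison

The score is the Pearson correlation of pixel intensities over the joint
region of interest. Pearson was chosen over raw overlap metrics because it
is invariant under affine intensity rescaling of either image, absorbing
the unknown experimental height calibration (and the deliberate
hard-contact height inflation). Cosine similarity is offered as an
alternative (`method = "cosine"`) for workflows that want the zero level to
matter. Degenerate inputs fail loudly: fewer than 3 joint ROI pixels or
zero variance on either side is an error, not an `NA`.

Background cleaning is plain thresholding — pixels strictly below
`threshold * max` are zeroed and dropped from the ROI. The original
hand-drawn ROIs it stands in for are not reproducible; the threshold is a
parameter, and rectangle or 0/1-mask ROIs can be supplied explicitly.

## Numerical choices

- Blur kernel truncated at $4\sigma$, reflect (edge-repeating) boundaries,
  normalized; $\sigma = 0$ is the exact identity.
- Resampling is bilinear between pixel centres with linear extrapolation at
  borders, so affine intensity fields are reproduced exactly — the property
  that makes resample-then-correlate trustworthy.
- Height-map text files print 17 significant digits and re-import
  bit-exactly; they carry the full run configuration in `#` headers.
- PNG output is written with fixed filter-0 rows, so identical maps yield
  byte-identical files (used by the determinism tests). The GIF writer
  emits literal 9-bit LZW codes with periodic clear codes — valid,
  uncompressed, deterministic.
- The altLoc rule (first conformer wins), water exclusion (`HOH/WAT/DOD`),
  and the Bondi radius table with per-element overrides are all exposed as
  arguments; radius assignment is a pure function of the element symbol.

## Known limitations

- Hard-contact heights overshoot experimental ones by design; compare
  shapes and relative protrusions, not absolute scales.
- The infinite cone means one tall feature can dominate a wide area at
  large $\alpha$; physical tips are finite.
- No automated orientation fitting: the orientation is an input. Scoring a
  grid of candidate orientations is possible with the existing pieces but
  is intentionally out of scope.
- The 16-bit PNG and interlaced variants are rejected by the reader; use
  8-bit exports or the text-matrix format for experimental input.
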