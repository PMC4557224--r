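---
title: "Scalar-field representation of histological objects: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalar-field representation of histological objects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histofield)
```

## The problem

Bone-marrow histology poses a hard localization problem: cell populations
that need several immunohistochemical (IHC) markers for identification
(e.g. regulatory T cells) cannot be stained in one brightfield section, so
markers are spread over *serial sections*. After registration, the "same"
cell appears in adjacent sections at slightly shifted positions, with a
different cut plane, or not at all. Pixel-level colocalization of the raw
stains therefore collapses: two binary masks of the same cell shifted by a
single pixel have zero overlap.

`histofield` implements the remedy this package is built around: every
discrete object (a nucleus centroid, every pixel of a bone-trabecula mask)
is replaced by a smooth scalar *density field*, and all downstream analysis
— colocalization, distance surrogates, cluster detection — operates on
fields instead of pixels. Fields of nearby objects overlap substantially
even under small registration errors, which is the entire point.

## The field model

Each object centroid \((x_P, y_P)\) contributes an inverse multiquadric
radial basis function

\[
C(x, y) \;=\; \alpha \sqrt{\frac{1}{\beta + \gamma (x - x_P)^2}
                         + \frac{1}{\beta + \gamma (y - y_P)^2}},
\]

and the field of a population is the pixel-wise *sum* of the per-object
fields (additivity is exact, pre-normalization). Two named parameter sets
model two biological interaction ranges:

| mode | \(\beta\) | \(\gamma\) | shape | models |
|------|-----------|------------|-------|--------|
| `direct` | 3 | 0.01 | narrow, high only over the nucleus/cell | direct cell–cell or cell–niche contact |
| `indirect` | 3 | \(2\times 10^{-5}\) | broad, medium values across \(\approx 250\,\mu m\) | paracrine signalling |

\(\alpha\) is always chosen per kernel as \(100/\sqrt{2/\beta}\) so that the
peak value at the centroid is exactly 100 arbitrary units. At the package's
pixel-scale convention of 0.5 µm/px ("`pixel_size_um`", reporting only),
250 px is 125 µm.

**Anisotropy.** The formula is a *separable sum*, not a true radial
function: along the centroid's own row or column it never falls below
\(\alpha\sqrt{1/\beta}\) (≈ 70.7 on the peak-100 scale). Level sets above
50 therefore include image-spanning "ridges" along the centroid's axes.
This is implemented exactly as stated and has real consequences discussed
under *Limitations*.

### Convolution and truncation

Fields are built by zero-padded linear FFT convolution of the source
indicator image with a kernel grid, cropped back to the image size
(`extent = "image"`), with the kernel sized to the image and centred at
`(floor(h/2)+1, floor(w/2)+1)`. Two properties follow:

1. A point at the kernel centre reproduces the kernel exactly (delta
   identity — a test anchors this).
2. Any *off-centre* source has its field truncated at one border, leaving a
   zero strip whose width equals the source's offset from the centre.

The truncation is not a defect here: it is what makes the histogram of a
field depend on the position of its source, and hence what makes the
histogram-intersection distance surrogate work at all (see below). For
differential analysis (gradient, divergence, sinks), where the crop seams of
off-centre sources would register as spurious structures, the package
provides `extent = "full"`: the kernel covers every offset
(\((2h-1)\times(2w-1)\)) and the field is the exact, strictly positive,
untruncated superposition.

### Normalization

Summation fields of many objects easily exceed \(10^4\) raw units, so each
field is mapped affinely onto \([0, 100]\):
\(C' = 100\,(C - C_{\min})/(C_{\max} - C_{\min})\). The formula the source
material prints for this mapping has inconsistent signs/denominators
(\(C_{\min}+C_{\max}\), sending \(C_{\max}\) to a negative value); the
implemented mapping is the evident intent, and all thresholds in this
package (pair threshold 25, split-coefficient threshold 50) refer to this
0–100 scale.

**Generic placement.** One subtlety discovered while validating: a point at
the *exact* kernel centre is the unique placement whose truncated field
never reaches zero, so its min–max normalization stretches differently from
every other field's, and its histogram becomes incomparable. All reference
experiments therefore anchor the fixed object one pixel off the kernel
centre (position (252, 252) on a 500×500 grid) — the generic case.

## Colocalization statistics

Given two normalized fields on the same (registered) grid,
`coloc_stats()` computes:

- **PCC** — Pearson correlation over paired pixel densities;
- **MOC** — Manders overlap, \(\sum ab / \sqrt{\sum a^2 \sum b^2}\);
- **M1/M2** — split coefficients: the fraction of one field's total mass
  lying where the partner exceeds the threshold (default 50).

Near-zero background densities would inflate PCC (most pixels of both
fields are concordantly "empty"), so a background threshold of 25 is
applied first. Four rules are available in `pair_fields()`; the default,
`"zero"`, sets sub-threshold densities to zero and retains all pixels.
This choice is empirical: among the four rules it is the only one
consistent with the reference behaviour of PCC for single-point pairs at
both 10 px and 100 px separations (the rule that *drops* pixels where both
fields are low leaves PCC near −0.05 at 100 px, because the discordant
background pairs that carry the distance signal are exactly the ones
removed). The alternative rules remain available for sensitivity analysis.

```{r coloc-example}
sh <- c(500, 500)
fa <- point_field(cbind(252, 252), sh, rbf_direct())
fb <- point_field(cbind(252, 262), sh, rbf_direct())
glance(coloc_stats(fa, fb))
```

The no-convolution contrast is `baseline_binary_coloc()`: on raw binary
images, PCC and MOC are 1 at distance 0 and collapse to (essentially) 0 at
one pixel of separation — the brittleness the field representation removes.

## Histogram intersection as a distance surrogate

A normalized field is summarized by a 100-bin histogram over \([0, 100]\)
(`field_histogram()`), and two objects are compared by the intersection
\(\sum_b \min(h_1, h_2) \in [0,1]\) (`histogram_intersection()`). For
single-point fields the mechanism is concrete: a source at offset \(d\)
from the fixed one carries a truncation strip wider by \(d\) columns, so
roughly \(d \cdot h\) pixels move into the zero bin and the intersection
falls approximately linearly, \(1 - d/w\) for a \(h\times w\) image. The
intersection is therefore a monotone surrogate for distance within the
image scale, which is what the niche-allocation analysis needs. It is *not*
a metric, and beyond the image scale (moving point near the border) the
linear mechanism saturates and reverses; `intersection_distance_profile()`
exposes the raw profile so users can see where the surrogate is valid.

```{r intersection-example}
intersection_distance_profile(rbf_direct(), c(10, 50, 100, 150, 200))
```

## Gradient, divergence, sinks

`normalized_gradient()` returns the central-difference gradient magnitude
divided by its own mean (output mean exactly 1), making slope structure
comparable across images with different object counts. Borders use
one-sided differences (the convention of `gradient` in the numerical
environment the method originated in; interior pixels are identical to
edge replication up to the outermost ring).

`divergence_sinks()` computes the divergence of the gradient field and
extracts *sinks* — 8-connected components of pixels with divergence below
`rel_threshold` × (global minimum). Sinks mark objects and object
clusters: five points in a cross pattern fuse into one compound sink at
25 px spacing and resolve into five separate sinks by 125 px, with the
count monotone in spacing. The default `rel_threshold = 0.3` is calibrated
to reproduce exactly this 1-versus-5 behaviour; at 0.5 the threshold dips
into the separable kernel's ridge troughs and picks up arm artefacts.
Sink analysis requires `extent = "full"` fields — on cropped fields the
truncation seams of off-centre sources appear as spurious sinks.

## Niche allocation

`niche_allocation()` scores each object field against a niche field (for
example, the field of a bone-trabecula mask, where every mask pixel is a
unit source) by histogram intersection, and allocates the object to the
niche when the intersection reaches a threshold. On a synthetic bone-band
fixture the intersection decreases strictly with the object's distance
from the band and has a small spread (< 0.1 sd) among objects at equal
offset — the properties the allocation rule relies on. Note that a *point*
object never reaches intersection 1 against an *extended* niche (their
histograms differ structurally even at distance zero); thresholds should
be calibrated against an on-niche reference population, which is how the
package's tests do it.

## The synthetic generator: what it emulates, what it does not

`make_point_image()` / `make_cluster_image()` reproduce the binary
500×500 proof-of-principle patterns (single points, pairs at controlled
distances, five-point cross clusters with exact nearest-neighbour
spacing). `make_pseudo_ihc()` emulates a brightfield H-DAB section: round
nuclei as hematoxylin (blue) or DAB+hematoxylin (brown) discs composed
through the Beer–Lambert law from the Ruifrok–Johnston stain vectors — so
`colour_deconvolve()` recovers the generating densities exactly — plus
pale-green bone bands and a ground-truth centroid table. Placement is
rejection-sampled with a minimum separation, seeded and bit-reproducible.

It does **not** emulate: overlapping or touching nuclei in dense
infiltrates, staining-intensity variation, sectioning artefacts, tissue
deformation, or registration error. A green preprocessing test therefore
establishes correct recovery on well-separated blobs, not performance on
crowded marrow; the watershed path is exercised by dedicated
two-overlapping-disc fixtures instead.

## Numerical choices

- FFT sizes are padded to 2/3/5-smooth lengths; FFT and direct-summation
  fields agree to 1e−9 relative error (tested on ≤ 32×32 grids).
- Small negative FFT round-off is clipped to zero after convolution.
- Histogram bins are left-closed, right-open, the last bin closed at 100.
- Otsu's threshold (256 bins) binarizes stain channels; watershed seeds are
  chamfer-3-4 distance-transform maxima with ≥ 5 px separation, ties broken
  by scan order; foreground pixels join their nearest seed within their
  connected component.
- Stained classification is an exact Euclidean distance test against the
  stained mask (default range 5 px ≈ 2.5 µm).
- Connected components use 8-connectivity throughout.

## Known limitations

- The separable kernel's axis ridges make threshold-based *area/mass*
  statistics direction-dependent: cluster-versus-point split coefficients
  computed along a cluster axis differ from diagonal placements. Reference
  computations therefore use diagonal offsets for cluster-point geometry.
  For the same reason, split coefficients of the wide cluster field never
  exceed those of a compact single-point partner, and sink detection on
  many scattered points can report ridge-crossing artefacts in addition to
  true object sinks.
- The histogram-intersection distance surrogate is only valid within the
  image scale and for fields normalized under the same truncation regime.
- Registration is out of scope: multi-section inputs are assumed
  pre-registered, and no deformation model is applied.
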