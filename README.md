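# retvasc

Retinal vascular morphometry and cardiovascular risk flagging from fundus
photographs, for researchers quantifying microvascular change from
segmented retinal images.

Microvascular geometry visible in the retina — arteriolar narrowing, a
reduced arteriole-to-venule caliber ratio, increased tortuosity, altered
branching — tracks systemic cardiovascular health. `retvasc` takes a
fundus photograph together with an artery/vein label mask and an
optic-disc mask (produced by any segmentation method; segmentation itself
is out of scope) and computes the standard parameter set of retinal
vasculometry, localized in the conventional optic-disc-centred zones. It
then flags cardiovascular risk against user-supplied reference ranges,
combines that flag with an external image-classifier verdict through a
conservative AND rule, and scores decision sets with confusion-matrix
metrics. A synthetic phantom generator with exact ground truth makes
every stage testable without clinical data.

## The measurements

With parent width $r_0$ and daughter widths $r_1 \ge r_2 (\ge r_3)$ at a
bifurcation:

- **Branching coefficient** $\mathrm{BC} = (r_1^2 + r_2^2)/r_0^2$ (2 at a
  symmetric equal-width junction).
- **Junction exponent** (as a cubic deviation) $\mathrm{JE} = r_0^3 -
  (r_1^3 + r_2^3 + r_3^3)$; the classical exponent solving
  $r_0^x = \sum_i r_i^x$ is also reported.
- **Optimality ratio** $\mathrm{OR} = \big((r_1^3 + r_2^3)/(2
  r_0^3)\big)^{1/3}$ (1 when all widths are equal, $\approx 0.794$ under
  Murray's law).
- **Vessel diameter reduction** $1 - \overline{r_{1,2}}/r_0$.
- **Mean vessel width**: cross-sections are measured by ray search — from
  each centerline sample, rays march at every degree until the first
  background run, and the width is the minimum distance between opposite
  edge points.
- **Simple tortuosity** $(L - C)/C$ for arc length $L$ and chord $C$,
  i.e. the fractional excess path length (0 for a straight vessel).
- **Path-length tree statistics**: largest and total external (root to
  leaf) path length and the number of external paths per vascular tree.
- **CRAE / CRVE** (central retinal arteriolar/venular equivalents): the
  six largest arterioles/venules are combined pairwise, largest with
  smallest, through the Knudtson–Parr–Hubbard formula
  $w = f\sqrt{w_1^2 + w_2^2}$ ($f = 0.88$ for arteries, $0.95$ for
  veins), iterated until a single caliber remains.
- **AVR** $= \mathrm{CRAE}/\mathrm{CRVE}$.
- **Fractal dimension**: box counting, $\log N(s) = \log K + D
  \log(1/s)$ over grids of side $s$.

Measurements are localized in annuli around the optic disc, in units of
optic-disc diameter (ODD) beyond the disc margin: zone A (0–0.5 ODD),
zone B (0.5–1 ODD) and zone C (0.5–2 ODD); caliber summaries default to
zone B, the convention of the Knudtson framework.

The enhancement chain applied before analysis mirrors common fundus
practice: black-border masking, green-channel CLAHE (clip limit 1.0,
25×25 tiles), green attenuation by 0.8, and a gamma lookup table.

## Worked example

Generate a synthetic eye with known geometry and run the full pipeline:

```r
library(retvasc)

ph  <- generate_phantom(random_phantom_spec(seed = 42, with_branches = TRUE))
eye <- run_eye(ph$image, ph$vessel_mask, ph$od_mask)
eye$report
#> Retinal morphometry report
#>   CRAE 16.703 px, CRVE 22.594 px, AVR 0.7393 (zone B)
#>   Fractal dimension (combined vessels): 1.467
#>   artery: width 9.52 px, tortuosity 0.0376, BC 0.914, JE 261.0, OR 0.685, DR 0.333 (2 junctions)
#>     paths: largest 224.1 px, sum 1661.6 px, n 8
#>   vein: width 10.56 px, tortuosity 0.0250, BC 0.763, JE 562.0, OR 0.622, DR 0.394 (2 junctions)
#>     paths: largest 226.7 px, sum 1652.4 px, n 8
```

The phantom's six arteries had generating widths 12, 10, 9, 9, 9, 8 px;
CRAE 16.7 px is their Knudtson summary as measured in zone B. AVR 0.74
reflects the wider vein draw of this phantom. Each bifurcation was
generated as (9, 7, 5) or (11, 7, 5) px and is recovered within a pixel
(`phantom_recovery(ph)` tabulates measured against truth).

Risk flagging needs clinically sourced reference intervals — the shipped
constructor deliberately has no usable defaults:

```r
rng <- reference_ranges(crae = c(-Inf, 15), avr = c(-Inf, 0.667),
                        mean_artery_width = c(-Inf, 6))
eye <- run_eye(ph$image, ph$vessel_mask, ph$od_mask,
               classifier_flag = TRUE, ranges = rng)
eye$verdict
#> <risk_verdict: parameter cardio_suspect, classifier cardio_suspect -> cardio_suspect>
```

Scoring a validation set:

```r
m <- confusion_metrics(confusion_matrix(tp = 28, fn = 4, fp = 5, tn = 29))
round_metrics(m)
#>    accuracy sensitivity specificity   precision          f1
#>       86.36       87.50       85.29       84.85       86.15
```

A thin command line lives at `inst/cli/retvasc.R`
(`Rscript inst/cli/retvasc.R run --image img.png --mask vessels.png
--od od.png --out report.json`), with subcommands for each stage.

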