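---
title: "Quantifying motion-capture errors with spqc: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motion-capture errors with spqc: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spqc)
```

## The measurement model

A stereophotogrammetric (SP) system reconstructs the 3D position of each
marker on each frame. Its errors decompose into two components with
different causes and different remedies:

- **random error**: frame-to-frame reconstruction noise intrinsic to the
  cameras and the vendor's reconstruction algorithms;
- **systematic error**: a spatially structured bias that depends on where in
  the capture volume a marker sits, left behind by camera placement and the
  calibration outcome.

`spqc` estimates both from a rigid calibration object whose inter-marker
distances (mm) and angles (degrees) are known by construction. Rigidity is
the key assumption: every declared check has a single true value $y$, so on
frame $i$ the reconstruction error of that check is simply
$e_i = \hat{y}_i - y$ (we store reconstructed-minus-nominal; the squared
metrics are indifferent to the sign convention, and this direction makes a
positive mean error read as "the system reconstructs long").

**Static trial.** With the object resting at the centre of the volume — the
most favourable spot, minimising the influence of calibration quality and
camera coverage — the error series of a check contains (almost) pure random
noise. It is summarised by the *expanded uncertainty*

$$U = \mathrm{SDE} \times k,$$

where SDE is the *sample* standard deviation (the $n-1$ denominator of
metrological practice) of $e_i$ and $k$ is a coverage factor. With $k = 3$
and Gaussian noise the interval mean $\pm\, U$ covers 99.7 % of the random
errors. The SD is taken about the series mean rather than about zero: a
constant bias in the static pose (which belongs to the systematic component)
must not inflate the random-error estimate, so the bias is reported
separately as `mean_error`. Both the centring and $k$ itself are exposed as
parameters; $k = 3$ is the default.

**Dynamic trial.** Sweeping the object through the whole volume exposes it
to the spatially varying part of the error field. Each check is summarised
by the root-mean-square error over the $N$ valid frames,

$$\mathrm{RMSE} = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N} e_i^2},$$

which absorbs both the noise floor and any position-dependent bias. Under
pure noise of per-axis SD $\sigma$ on two markers, a distance-error series
has SD $\sqrt{2}\sigma$, so the dynamic RMSE of a distance check has a floor
of $\sqrt{2}\sigma$; anything above it is systematic.

**Reporting.** Error magnitudes show no systematic dependence on which
distance or which angle is checked, so the report headlines the four maxima
(static/dynamic × distance/angle) over all declared checks, with the full
per-check table underneath. No pass/fail thresholds are built in: what is
acceptable depends on the downstream quantities (a 2.4 mm maximum over a 5 m
volume is immaterial for stride length, fatal for tremor amplitude).
Thresholds are user-configured, and without them the report is
"report-only".

## Protocol parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `k` | 3 | — | 99.7 % Gaussian coverage |
| `min_duration_s` (static) | 5 | s | protocol minimum; shorter trials still compute, with a warning |
| `min_duration_s` (dynamic) | 20 | s | long enough to sweep a room-sized volume by hand |
| `max_dropped_fraction` | 0.2 | — | above this, occlusion makes the estimate untrustworthy; warn |
| `degenerate_mm` | 1 | mm | vectors shorter than this make an angle numerically meaningless |
| manufacturing tolerance | 0.5 / 0.5 | mm / deg | config self-consistency bound between declared nominals and `local_positions` |
| volume bounds | 5 × 4 × 2 | m | the common target volume of multicentre gait studies |
| coverage cell | 500 | mm | floor-plan grid for the sweep-coverage fraction |

Frames on which any marker a check references is invalid are dropped *for
that check only* — occlusion of one wand tip should not discard perfectly
good frames of the opposite segment. The dropped fraction is reported per
check. Vendors flag unreconstructed points either with a negative residual
or with all-zero coordinates; the c3d reader masks both.

## What the simulator emulates — and what it does not

The simulator exists to exercise the QC mathematics end to end, including
the file formats, with known ground truth. Per frame it (1) poses the rigid
object along a motion path (static; a serpentine *raster* sweep, which is
what an operator walking the volume produces; or a smooth *lissajous* path),
(2) applies a deterministic spatial distortion to the true marker positions,
(3) adds iid isotropic Gaussian noise per marker, and (4) drops markers
independently with a fixed probability. All randomness flows from one seed;
the same config is bit-reproducible.

The distortion menu maps onto failure modes of real calibrations: a
`uniform_scale` (global volume stretch, the classic wand-length
miscalibration: distances scale by $1+s$, angles are untouched), a general
`affine` map, and a `smooth_field` — a bounded quadratic vector polynomial
of position, standing in for the smoothly varying residual field a
partially covered volume leaves.

Real SP noise is *not* iid isotropic Gaussian: it is anisotropic (depth is
worse than image-plane), spatially varying, and temporally correlated
through the tracker; real occlusion is geometric, not Bernoulli. Passing the
recovery tests therefore demonstrates that the estimators measure what they
claim on their own model — noise in gives $3\sqrt{2}\sigma$ expanded
uncertainty and $\sqrt{2}\sigma$ RMSE back, scale in gives $s \times$
nominal back — not that any particular laboratory meets a given error
level. Real sessions remain the point of the check.

The analytic anchors used in the tests and the acceptance script:

- Gaussian coverage: the fraction of static-trial errors within
  mean $\pm\, 3\,$SDE approaches 99.7 % (checked at 120 000 frames);
- noise recovery: static expanded uncertainty $\to 3\sqrt{2}\sigma$,
  dynamic distance RMSE $\to \sqrt{2}\sigma$ (checked at $\sigma \in
  \{0.05, 0.1, 0.5\}$ mm, 10 000 frames, 5 seeds);
- similarity recovery: distance RMSE $= s \cdot$ nominal exactly, angle
  RMSE at machine precision, strictly monotone in $s$;
- rigid invariance: per-frame random rigid transforms of a noiseless object
  leave every metric below $10^{-9}$;
- both metrics agree with brute-force loop implementations to $10^{-12}$
  relative.

## Numerical and design choices

- **Angles** are computed as $\mathrm{atan2}(\lVert u \times v\rVert,
  u \cdot v)$, stable near 0° and 180°, and always land in $[0, 180]$
  degrees. A vector-pair check whose vectors share an endpoint is
  normalised to the equivalent vertex form.
- **Canonical units** are millimetres and degrees throughout; c3d files in
  m or cm are converted on read using the file's units parameter, and an
  unrecognised units string is a hard error naming the value found (silent
  unit guessing would corrupt every nominal comparison).
- **Label matching is exact** (after an optional user-supplied rename map).
  Fuzzy matching risks scoring the wrong marker pair against a nominal.
- **c3d subset.** The reader/writer covers the modern common denominator of
  the format: Intel byte order, floating-point point data, the POINT
  parameter group. Integer-scaled or non-Intel files are refused with a
  clear message rather than mis-read. The 16-bit header field caps writable
  trials at 65 535 frames; longer simulations simply stay in memory.
  Positions survive a c3d round trip to float32 resolution (about
  $3 \times 10^{-5}$ mm at room scale — three orders of magnitude below
  any error this check cares about); CSV keeps full double precision.
- **Report JSON** is written at 17 significant digits, so a report
  round-trips bit-exactly; Markdown/HTML display rounds to 0.1 mm / 0.1°,
  the granularity at which QC results are read.
- **Coverage** is measured on the floor-plan (x–y) grid of the declared
  volume: a hand-held sweep cannot visit every height at every position,
  so full 3D voxel coverage would flag every honest trial.
- **Example geometry.** Manufacturers do not publish wand dimensions for
  redistribution, so the shipped T-wand config uses placeholder dimensions
  (240 mm bar and stem) chosen to be the right order of magnitude. Every
  computation takes nominals from the config; nothing is hard-coded.

## Problem sizes

The test suite simulates trials of 200–10 000 frames (2 s–100 s at 100 Hz)
and one 120 000-frame static run for the coverage check; the whole suite
runs in well under a minute on a laptop-class core, and
`scripts/acceptance.R` in a few seconds.

## Known limitations

- Accuracy inherits the calibration object's manufacturing accuracy and
  assumes the object has not deformed; the manufacturing-tolerance check
  only catches configs that contradict their own declared coordinates.
- No gap filling: occluded frames are excluded, never interpolated.
- No per-region error maps — the dynamic RMSE aggregates over the whole
  sweep; a locally bad corner shows up only as far as it moves the mean
  square.
- No cross-session or cross-site statistics; the JSON reports are designed
  to be aggregated by downstream tooling.
- Analog channels, force plates and camera-level effects (projection,
  merging, ghost markers) are out of scope: the package consumes
  reconstructed, labelled trajectories.
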