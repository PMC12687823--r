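# lensrecon

Complete three-dimensional reconstruction of the human crystalline lens from
multi-incidence anterior-segment OCT.

Standard on-axis OCT sees the lens only through the pupil: the equator and
the peripheral surfaces are hidden behind the iris, so lens diameter, volume
and surface area cannot be measured directly in vivo. `lensrecon` implements
the full computational pipeline that makes those measurements possible when
the eye is imaged from several gaze directions (on-axis; nasal 30/45&deg;;
temporal 30/45&deg;; superior 20/30&deg;; inferior 45&deg;), each view
exposing a different part of the lens periphery through the (dilated) pupil:

1. **Segmentation cleaning** — iterative low-order polynomial fitting with
   3-SD outlier rejection for eyelash artifacts; densification of sparse
   manual click-points; clipping of lens boundaries to the pupil.
2. **Per-incidence 3-D model building** — pixel-to-millimetre calibration
   (9.2&nbsp;&micro;m/pixel axially), mapping of the 65 radial B-scans
   (0.048&nbsp;rad spacing, 256 A-scans over 14&nbsp;mm) into a common 3-D
   frame, and least-squares fitting of each ocular surface with 15 Zernike
   terms (OSA/ANSI ordering).
3. **Optical distortion correction** — OCT measures optical path length
   along refracted rays, not geometry. Each A-scan ray is refracted at the
   anterior cornea by the vector form of Snell's law and advanced by the
   measured OPL divided by the group index of the medium (cornea 1.385,
   aqueous 1.345, lens 1.417), surface by surface (posterior cornea, then
   anterior lens, then posterior lens), refitting each corrected surface
   before the next refraction. The correction is fully three-dimensional:
   off-axis rays leave their B-scan plane, which per-meridian 2-D
   corrections cannot represent.
4. **Registration** — each corrected model is aligned by its iris: a
   total-least-squares plane undoes the gaze tilt and a Taubin +
   Gauss-Newton circle fit places the iris centre at the origin; trimmed
   iterative-closest-point then refines each view against the union of the
   already-registered lens surfaces.
5. **Eigenlens projection** — the merged cloud is centred at the lens shape
   origin, resampled to radial elevations I on a fixed polar grid of P = 100
   elevation by Q = 100 azimuth angles (M = 10&nbsp;000 nodes), and
   projected onto the first K = 6 principal components ("eigenlenses") of a
   training population: `a = Mᵀ(I − Ī)` and `Î = Ī + Σ aₖeₖ`. The projection
   smooths residual noise and completes nodes hidden from every view, giving
   a closed full shape.
6. **Quantification and statistics** — equatorial diameter DIA (maximum
   through-axis caliper), volume VOL (split anterior/posterior double
   integration over the equatorial disc), surface area LSA (triangulated
   mesh area); repeatability CV, Spearman rank correlation with exact
   small-sample permutation p-values, Bland-Altman limits of agreement
   (MD &plusmn; 1.96 SD) and a Shapiro-Wilk normality gate.

A synthetic eye-phantom simulator (`make_phantom()`, `forward_simulate()`)
generates optically distorted, iris-occluded multi-incidence acquisitions
from an analytic eye with known lens geometry, so every stage — and the
whole pipeline — is testable by parameter recovery without any real OCT
data.

## Worked example

```r
library(lensrecon)

ph   <- make_phantom("young_adult")   # 9.2 mm lens, 3.8 mm thick
phantom_truth(ph)
#> # A tibble: 1 × 3
#>   dia_mm vol_mm3 lsa_mm2
#>    <dbl>   <dbl>   <dbl>
#> 1    9.2    168.    171.

prot <- acquisition_protocol()        # 8 gaze orientations, 65 x 256 samples
mer  <- simulate_protocol(ph, prot)   # distorted, iris-occluded acquisitions

rec  <- run_pipeline(mer)             # correct, register, project, quantify
rec
#> <lens_reconstruction>
#>   DIA 9.178 mm, VOL 168.12 mm^3, LSA 170.83 mm^2 (100x100 grid)
#>   8 incidences registered; 8917 / 10000 grid nodes observed
```

The reconstructed diameter (9.178 mm), volume (168.1 mm&sup3;) and surface
area (170.8 mm&sup2;) recover the phantom ground truth (9.200 / 168.4 /
171.2) to 0.24&nbsp;%, 0.17&nbsp;% and 0.22&nbsp;%. About 11&nbsp;% of the
polar grid — an equatorial band no gaze direction can see past the iris —
is completed by the eigenlens projection. `tidy(rec)` returns the six
eigenlens coefficients, `glance(rec)` the metrics with coverage, and
`autoplot(rec)` a meridional profile plot.

Repeatability of repeated measurements is summarized the way clinical
studies report it:

```r
coefficient_of_variation(c(9.45, 9.48, 9.55))   # DIA triplet -> 0.54 %
coefficient_of_variation(c(135, 134, 136))      # VOL triplet -> 0.74 %
```

A thin command-line front end is installed as `exec/lensrecon`
(`lensrecon simulate|reconstruct|run-all --seed 1 --out-dir out/`), and
`index_sensitivity()` re-runs the pipeline across lens group indices
(1.40 / 1.417 / 1.44) to quantify the constant-index assumption.

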