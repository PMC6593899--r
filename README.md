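# shgphasor

Phasor-based mapping of collagen micro-architecture from
polarization-resolved second harmonic generation (P-SHG) microscopy, with
density-peak clustering and entropy-based tissue segmentation.

## The problem

Fibrillar collagen generates a strong second harmonic signal whose
dependence on the incident laser polarization encodes two microscopic
parameters per pixel: the mean in-plane fibril orientation θ_F and the
susceptibility anisotropy γ = χ⁽²⁾_zzz / χ⁽²⁾_zxx. Pathological tissue
remodels its collagen scaffold, so maps of (θ_F, γ) — and especially their
*local heterogeneity* — can discriminate tissue regions (e.g. tumor versus
surrounding skin) without any staining. This package implements the full
chain from a raw polarization stack to a segmented section, for
microscopists and image-analysis researchers working with P-SHG data.

## The model and the method

Each pixel's intensity along the polarization sweep follows

```
I(θ_L) = k { sin²[2(θ_L − θ_F)] + [ sin²(θ_L − θ_F) + γ cos²(θ_L − θ_F) ]² }
```

which is π-periodic and contains exactly three harmonics; the first
harmonic's amplitude is (γ² − 1)/2 and vanishes at γ = 1. The pipeline:

1. **Phasor retrieval** — each pixel's response is Fourier-transformed into
   normalized phasor coordinates (g, s). The orientation is read from the
   first-harmonic phase through a reference curve (the γ → ∞ limit of the
   model, swept over [0, π)); the response is then resampled onto the
   fibril-aligned quarter-period window and γ read off a second reference
   curve (the model swept over γ ∈ [0, 10]). The 90° ambiguity of the first
   harmonic is resolved by the smaller least-squares residual against the
   forward model.
2. **Density-peak clustering** — valid pixels are clustered in (θ_F, γ)
   space by the maximum-density approach on a quantized feature grid, then
   pruned by per-axis cutoffs (θ_C = 5°, γ_C = 0.2) and an element
   threshold (ET = 1% of analyzed pixels).
3. **Phasor-space descriptors** — per region or ROI: the number of clusters
   N_C, the cluster elements ratio CER (occupancy over the main cluster's
   occupancy), and the *fibril entropy*

   ```
   S = ( −Σ_i p_i log p_i ) / log E_C ,   p_i = x_i / E_C ,
   ```

   the normalized Shannon entropy of the cluster occupancies: S = 0 for a
   single cluster (ordered), S = 1 when every clustered element is its own
   cluster (maximally disordered).
4. **ROI analysis and segmentation** — the section is tiled into
   non-overlapping 150 µm (or 75 µm) ROIs, descriptors are computed per
   ROI, and each ROI is labeled high- or low-entropy against the
   section-mean threshold; back-projecting the labels yields a pixel mask
   whose accuracy can be scored against a reference delineation.

A fully ground-truthed synthetic phantom generator (ordered "skin-like"
versus disordered "tumor-like" collagen, rendered through the forward model
with Poisson noise) makes every stage testable end to end.

## Worked example

```r
library(shgphasor)

# ground-truthed two-region phantom: left ordered, right disordered
ph    <- makePhantom(phantomSpec(), seed = 1)
stack <- renderStack(ph, seed = 1)
ret   <- retrieveMaps(stack)
ret$maps
#> MicroMaps: 406 x 812 px, 280221 valid pixels (85.0%), 0 degenerate
#>   theta median 89.8 deg; gamma median 1.82

grid     <- tileGrid(dim(thetaMap(ret$maps)), 150, pixelSize(ret$maps))
analysis <- analyzeSection(ret$maps, grid)
analysis
#> ROIAnalysis: 2 x 4 ROIs of 150 um (203 px), 8 valid
#>   entropy 0.068-0.271 (mean 0.162); N_C 2-13

seg <- segmentSection(analysis)
seg
#> SegmentationResult: S_th=0.1623; 50.0% low-S, 50.0% high-S, 0.0% unclassified
segmentationAccuracy(seg, ph$regionMask)$combined
#> [1] 100
```

The ordered half collapses into two clusters per ROI (S ≈ 0.07) while the
disordered half spreads over a dozen clusters (S ≈ 0.27); thresholding at
the section mean separates the two regions pixel-perfectly on this phantom.
`runPipeline(pipelineConfig())` performs the same chain end to end and
writes maps, tables and a JSON report; `inst/cli/shgphasor` exposes each
stage as a shell subcommand.

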