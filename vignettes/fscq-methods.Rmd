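---
title: "FSC-Q: method, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FSC-Q: method, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measure

`fscq` scores how well an atomic model is supported by the reproducible
signal of a single-particle cryoEM experiment. Two per-voxel local
resolution volumes are computed with a sliding-window Fourier shell
correlation (FSC): one between the two half maps
(`V_FSC_half`, threshold 1/2), one between the full map and a density map
simulated from the model (`V_FSC_map-model`, threshold 2/3). Their
difference is FSC-Q (Å):

```
FSC-Q   = V_FSC_map-model - V_FSC_half
FSC-Q_R = FSC-Q / V_FSC_half
```

A value near zero says the model demands no more resolution than the half
maps deliver. Positive values mark misfit or low resolvability; negative
values mark model density correlating better than the half maps correlate
with each other, which is what fitting into noise looks like. FSC-Q_R
rescales the disagreement by the local resolution itself, since half an
Ångström means something different at 2 Å than at 4 Å.

### Why 1/2 and 2/3

The half-map branch uses the conventional 1/2 threshold for local
resolution from two half-data-set reconstructions. For the map-model
branch there is no exact statistical model of how a refined model deviates
from truth; the working hypothesis is that the model-derived map errs like
an independent full-data-set reconstruction, for which the established
threshold is 2/3. Under that hypothesis the two branches cross their
thresholds at the same signal-to-noise level and FSC-Q centres on zero for
a well-fitted model. The hypothesis matters: a *perfect*, noise-free model
map violates it and biases FSC-Q negative (the model then genuinely
correlates better than the half maps do). This drove one design decision
in the synthetic scenes, described below.

## Pipeline parameters

| parameter | default | meaning |
|---|---|---|
| `global_resolution` | (required) | reported overall resolution, Å; used only for the window rule |
| `window` | `default_window(res, voxel)` | odd cube edge, voxels: `round(5·res/voxel)` raised to odd, floored at 11 when res < 2 Å |
| `thr_half`, `thr_map_model` | 1/2, 2/3 | FSC thresholds of the two branches |
| `mask_threshold` | 0.02 | core threshold on the model map normalised to unit maximum |
| `mask_dilation` | 3 voxels | Euclidean dilation of the core |
| `mask_soft_edge` | 3 voxels | raised-cosine falloff width |
| `step` | 1 | evaluation stride; skipped voxels filled from the nearest evaluated one |
| `cutoff` | 0.5 Å | per-atom flagging threshold |

The window floor guards against unstable FSC estimates from very small
windows at high resolution. The soft edge is not specified by the mask
recipe's threshold-and-dilation core; a raised cosine of 3 voxels is
standard practice to limit the correlation that a sharp mask edge induces
between Fourier coefficients. The threshold is applied on the unit-max
scale because an absolute 0.02 is only meaningful after normalisation.
The mask *gates* where local FSC is evaluated (support = mask ≥ 0.5); it is
not multiplied into the extracted windows, to avoid double-counting
mask-induced correlation. A `mask_mode = "multiply"` variant exists for
comparison.

## Density simulation

Atoms contribute the analytic real-space pair of their element's
five-Gaussian electron scattering factor (International Tables vol. C,
table 4.3.2.2 parameterization; `f(s) = Σ aᵢ exp(−bᵢ s²)`, `s = sin θ/λ`),
i.e. `ρ(r) = Σ aᵢ (4π/bᵢ)^{3/2} exp(−4π² r²/bᵢ)`, scaled by occupancy.
Unknown elements fall back to carbon with a warning. Three numerical
choices:

* **Grid anti-aliasing.** The sharpest Gaussian terms have real-space
  widths far below a cryoEM voxel (σ ≈ 0.06 Å), so direct sampling would
  alias and lose mass unpredictably with sub-voxel atom position. Every
  term is convolved with a Gaussian grid PSF of 0.6 voxels
  (`bᵢ → bᵢ + 8π²(0.6·voxel)²`), which preserves each term's integral
  `aᵢ` exactly and keeps residual aliasing below 0.1%. This is a
  rasterization step, not a map low-pass: no additional blurring of the
  model map is applied before FSC.
* **Kernel truncation** at `max(5 Å, radius where the kernel falls below
  1e-4 of its peak)` — the latter matters only for large ADPs.
* **ADPs off by default.** Per-atom B-factors can be folded into the
  kernel widths (`use_adp = TRUE`), but the default simulation treats the
  model as sharp, and ADPs are carried through I/O untouched.

## The synthetic scenes

The scenario generator exists so that every claim the package makes about
itself is checkable without downloading data. A schematic α-helix
(rise 1.5 Å, 100°/residue, repeating ALA-LYS-SER-GLN so long and short
side chains both occur) is rendered to density; half maps add independent
white Gaussian noise; the full map is their mean. White real-space noise
satisfies the half-map independence assumption but is *not* a microscope
model: no CTF, no solvent, no alignment errors, no spectrally coloured
noise. Passing tests therefore demonstrate the correctness and the
designed behaviour of the machinery, not performance on real micrographs.

Three constants are part of the scene definitions, calibrated once when
the scenarios were created and then frozen:

* `noise_sigma = 0.057` (scene `matched_noisy`, 64³ at 1 Å/voxel): chosen
  so the global half-map FSC crosses 0.143 near 3 Å on this grid.
* `fit_jitter = 0.25 Å`: per-axis Gaussian coordinate error applied to the
  *fitted* model (the truth model still generates the maps). This encodes
  the threshold hypothesis above — a refined-but-correct model carries
  error comparable to a full reconstruction's. It was calibrated by
  matching the mask-weighted global map-model FSC crossing at 2/3 to the
  half-map crossing at 1/2, i.e. against the hypothesis itself, not
  against any acceptance quantity. Without it the perfect model biases
  FSC-Q to about −0.3 Å median on this scene.
* the matched-model median tolerance band, registered as ±0.25 Å: the
  acceptance suite requires the per-atom FSC-Q median of `matched_noisy`
  to fall inside it (observed medians across creation-time seeds were
  within ±0.06 Å of zero).

The `rotamer_flip` scene displaces the side chain of GLN-28 — the last
residue of the helix — by 2 Å radially away from the helix axis. Two
deliberate choices: an end-of-chain residue, because its windows contain
little other structure and so behave like the marginal-resolvability
regions where misfit detection matters; and a deterministic outward
direction rather than a random one, because random directions frequently
push the side chain onto the adjacent LYS stack, a real but different
failure mode (density overlap) that also perturbs the neighbours' scores
and makes "exactly one residue flagged" the wrong expectation for the
scene. `perturb_side_chain()` itself defaults to a seeded random
direction.

## Numerical choices in the FSC machinery

* **Shells** are one Fourier voxel wide; coefficient `k` belongs to shell
  `round(|k|)`, up to the Nyquist index. Shells with zero power in either
  window are reported `NA` and skipped by the crossing search.
* **Threshold crossing**: the *first* downward crossing, linearly
  interpolated in frequency between the bracketing shells. A curve that
  never crosses maps to the Nyquist resolution (2·voxel); a curve already
  below threshold at the first informative shell maps to the worst
  representable value (window·voxel). Both ends are therefore bounded and
  monotone encodings of "better/worse than measurable".
* **Windows** are plain cubes (no apodization), zero-padded where they
  overhang the box; all-zero windows inside the mask are assigned the
  worst representable resolution.
* **Stride fill** (`step > 1`) copies the nearest evaluated voxel, never
  interpolating across the mask boundary.
* **Sign safety**: local resolution maps carry a `provenance` field
  (`half` / `map_model`) and `compute_fscq()` refuses swapped arguments,
  since a silent sign flip would invert the interpretation of every
  score.
* **NaN policy**: voxels outside the mask, and atoms landing outside the
  volume or on undefined neighbourhoods, propagate NaN and are counted in
  the report — never coerced to zero. In MRC output NaN is encoded as
  −999 (score volumes) or −1 (local resolution), documented sentinels.
* **Per-atom sampling** is trilinear by default (`nearest` available);
  the occupancy column of the labeled PDB clamps scores to
  [−9.99, 99.99] to fit the fixed-width field.
* **B-factor invariance**: unmasked FSC is exactly invariant to an
  amplitude scaling that is constant on each shell; the invariance test
  applies `exp(−B s²/4)` at the shell-centre frequency so the property
  holds to float precision. The smooth scaling is invariant only up to
  within-shell variation, which the tests bound separately.

## Problem sizes

The test-suite and the acceptance script run on 16³ volumes for oracle
comparisons, 24³–48³ scenes for pipeline behaviour, and the 64³ scenes for
the matched/rotamer properties; a full 64³ pipeline run evaluates roughly
1.5·10⁴ windowed FSCs per branch and takes a few tens of seconds on one
core. These sizes were chosen as the smallest at which the helix scene has
a meaningful interior, a stable masked region and a window (15 voxels)
that fits comfortably in the box.

## Limitations

* Local resolution is isotropic here; directional FSC effects are out of
  scope.
* No phase-randomization correction for mask-induced correlation is
  applied; the mask gates evaluation rather than multiplying the data,
  which limits but does not eliminate the effect.
* The comparison of a half-data-set resolution with a full-data-set one
  rests on the threshold hypothesis above; FSC-Q is a support measure,
  not a resolution discrepancy in the strict sense.
* The synthetic scenes validate machinery, not microscopy: results on
  real maps depend on mask quality, sharpening history and the realism of
  the deposited half maps.
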