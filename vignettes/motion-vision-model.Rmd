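---
title: "A Drosophila motion-vision pathway model for decoding foreground direction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Drosophila motion-vision pathway model for decoding foreground direction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyvis)
```

## The model

`flyvis` implements a five-layer feed-forward model of the fly's motion-vision
pathways whose scalar readouts — the activated membrane potentials of the
wide-field HS (horizontal-sensitive) and VS (vertical-sensitive) systems —
signal the principal direction of a foreground object translating in front of
a possibly cluttered, possibly moving background. Positive HS means rightward
(the preferred direction, PD), negative HS leftward (null direction, ND);
positive/negative VS mean downward/upward.

The layers, per frame $t$ of a grey-scale sequence $L(x,y,t)$:

1. **Retina.** Photoreceptors compute a temporal difference with a short
   persistence: $P(t) = L(t) - L(t-1) + \sum_{i=1}^{n_p} a_i P(t-i)$ with
   decay $a_i = (1+e^i)^{-1}$, so a brightness change continues and decays for
   a few frames.
2. **Lamina (vDoG).** A centre–surround antagonism with a narrow excitatory
   Gaussian ($\sigma_e$, kernel truncated at radius $\sigma_e$) and a broad
   inhibitory one ($\sigma_i = 2\sigma_e$, twice the radius). The output
   keeps $|P_e - P_i|$ with the common sign where centre and surround agree
   and is zero where they disagree — an ambiguous centre–surround polarity
   carries no reliable ON/OFF label. Kernels keep their analytic amplitude
   $e^{-(u^2+v^2)/2\sigma^2}/(2\pi\sigma^2)$ and are deliberately *not*
   renormalised after truncation; the subtraction absorbs the small DC
   mismatch. Borders are zero padded.
3. **ON/OFF splitting and FDSR adaptation.** Half-wave rectification yields
   the parallel ON ($L1$) and OFF ($L2$) channels
   ($L1 \cdot L2 = 0$ pixel-wise). Each channel carries a
   fast-depolarising–slow-repolarising trace: rises mix with
   $\alpha_1 = \tau_i/(\tau_1+\tau_i)$, falls with
   $\alpha_2 = \tau_i/(\tau_2+\tau_i)$, and the trace is subtracted,
   suppressing sustained input. The medulla signals are
   $M_k = L_k - \hat L_k$.
4. **Direction-selective layer (T4/T5).** Per pixel, an *ensemble* of
   two-quadrant correlators: for each sampling distance
   $i \in \{sd, 2sd, \dots, n_c \cdot sd\}$ the delayed signal at the
   reference cell multiplies the instantaneous signal at the partner cell,
   e.g. $T4_r(x,y) = \sum_i \hat M1_i(x,y) \cdot M1(x+i,y)$, and analogously
   for leftward, downward and upward. The delay is *dynamic*: the nearest
   pair carries the largest latency $\tau_s$ and the farthest the smallest,
   linearly over $[\tau_{s,\min}, \tau_{s,\max}]$, so the ensemble covers a
   range of image speeds. ON (T4) and OFF (T5) ensembles are identical in
   structure.
5. **Lobula plate.** Each direction's T4+T5 maps are summed over the field
   (LPTCs), opponent sub-layers subtract (LPi inhibition):
   $HS_{raw} = LP_r - LP_l$, $VS_{raw} = LP_d - LP_u$, and a sigmoid
   normalised by field area maps the raw sums to
   $f(x) = 2\,\mathrm{sgn}(x)\,((1+e^{-|x|/(CRk)})^{-1} - \tfrac12) \in (-1,1)$.

## Parameters

| Parameter | Meaning | Default |
|---|---|---|
| `fps` | frame rate (drives $\tau_i = 1000/\mathrm{fps}$ ms) | 30 |
| `n_p` | retina persistence, frames | 2 |
| `tau1`, `tau2` | FDSR fast / slow constants, ms | 1, 100 |
| `sigma_e`, `sigma_i` | vDoG std-devs, px | 2, 4 |
| `sd` | correlator sampling distance, px | 4 |
| `n_c` | correlated cells per direction | 4 |
| `tau_s_min`, `tau_s_max` | dynamic delay bounds, ms | 10, 200 |
| `k` | sigmoid scale | 0.01 |
| `luminance_scale` | input divisor (8-bit greys to unit range) | 255 |

At 30 fps these give $\alpha_1 \approx 0.971$, $\alpha_2 = 0.25$, and delay
mixing factors $\alpha_3 = \tau_i/(\tau_i+\tau_s)$ from $0.143$ (nearest
pair) to $0.769$ (farthest).

Two calibration choices deserve emphasis:

* **Unit-range luminance.** The correlator is quadratic in luminance, so
  processing 8-bit values directly would put the raw wide-field sums about
  five orders of magnitude above the sigmoid's linear range; every output
  would saturate to exactly $\pm 1$ and the model's graded speed, size and
  contrast preferences would be invisible. Inputs are therefore divided by
  `luminance_scale = 255`; `k = 0.01` is calibrated to that range.
* **Angular calibration.** One pixel subtends 0.25°, so at 30 fps a velocity
  of $v$ °/s is $v/7.5$ px/frame. All angular quantities pass through this
  single scalar; a different calibration is one configuration change.

## Recursive traces and medulla rectification

Two points of the temporal filtering are genuinely open to interpretation and
are implemented behind switches:

* The FDSR and delay low-passes can mix the current sample with the previous
  *raw* sample (a 2-tap FIR) or with their own previous *output* (a
  first-order IIR). The package defaults to the recursive IIR form
  (`fdsr_recursive = TRUE`, `delay_recursive = TRUE`): a 2-tap FIR can only
  look back one frame, so a 200 ms latency constant would be meaningless at
  30 fps and the ensemble's speed-range tuning — the point of the dynamic
  delay — would collapse.
* The medulla signals $M_k = L_k - \hat L_k$ are signed: the slow-repolarising
  branch makes decrements pass with weight $1-\alpha_2 = 0.75$ versus
  $1-\alpha_1 \approx 0.029$ for increments, so negative components dominate.
  A two-quadrant correlator multiplies *same-polarity* channel signals; a
  negative value inside the ON channel is effectively an OFF signal and
  corrupts that contract — in practice the negative rebounds of a drifting
  background then swamp the foreground entirely. The DS layer therefore
  half-wave rectifies its inputs (`rectify_medulla = TRUE`), which also makes
  all T4/T5 maps non-negative.

## Initialisation and numerical conventions

All state is seeded from the first frame (previous-frame buffer = first
frame, persistence history and delay traces = 0, FDSR traces = first
rectified maps), so the model's output on frame 1 is exactly zero and there
is no spurious onset transient. Convolution borders are zero padded;
correlator partners outside the field contribute nothing (no wrap-around,
which would correlate opposite screen edges). Sub-pixel target positions are
rounded to the nearest pixel — targets stay hard-edged, as rendered bar
stimuli are. "Response during crossing" statistics are medians over the
frames in which the target is fully inside the field.

The sigmoid's range is open, $(-1, 1)$, but at double precision
$e^{-|x|/(CRk)}$ underflows for very large $|x|$ and the activation then
returns exactly $\pm 1$; model responses to actual stimuli sit far below
this saturation.

## The synthetic stimulus generator

No recorded stimuli ship with the package; `render_stimulus()` regenerates
every experiment class deterministically:

* **Translating bars/squares** at controlled grey level, size and angular
  velocity in the four cardinal directions, over uniform or cluttered ground.
* **Approaching/receding discs**, centred, with linearly growing or
  shrinking radius; by construction each frame is exactly mirror symmetric,
  which is what makes the depth-suppression test sharp.
* **Cluttered moving backgrounds**: a seeded procedural stand-in for natural
  scenes. A reflectance pattern with a natural-image power-law amplitude
  spectrum ($\sim 1/f^{1.4}$) is multiplied by a smooth illumination field
  with sparse dark pockets (dappled light, so shadows are both dark and
  low-contrast, as in woodland scenes), smoothed by a ~2 px Gaussian (the
  antialiasing a large photograph picks up when downscaled to the stimulus
  raster), and scrolled with sub-pixel bilinear interpolation, the way an
  OpenGL-textured display drifts an image. The FFT construction makes the
  texture periodic so the scroll wraps seamlessly.

What the stand-in does *not* emulate: occlusion structure (opaque objects
hiding each other), anisotropy (vertical tree trunks), photometric camera
noise, and the exact contrast statistics of any particular photograph.
Passing the bundled battery therefore demonstrates the model's behaviour on
scenes with natural second-order statistics, not on any specific natural
image.

## Experiment suites and problem sizes

The `suite_*` functions regenerate the experiment classes as tidy tables:
cardinal-direction decoding (320×180 px, 60 frames, dark and white bars at
27 °/s), depth suppression (90-frame disc sequences), the 45-cell
foreground-vs-clutter sweep (700×180 px, 100 frames per cell; 3 speeds ×
3 greys × 5 background velocities), the correlator-ensemble sweep
($n_c \in \{1,2,4,8\}$), the vDoG+FDSR ablation, the target-size sweep
(10–100 px squares vs a −40 °/s background) and the high-speed background
suite (−50…−200 °/s). These sizes keep the full battery at desk scale (a
few minutes on one core) while using the full stimulus geometry for the
cluttered conditions.

Grey levels for the sweep are white 255, moderate 190 and dark 0: the
texture's mean is ≈127, so a "moderate" grey at the mean would have exactly
zero average contrast and could not show the weaker-but-real responses the
moderate condition is meant to probe.

## Known limitations

* **Slow targets against fast clutter.** The model's response grows steeply
  with target speed (a hard-edged target refreshes proportionally more
  correlator inputs per frame at higher speed), while the residual
  directional drive of the moving background grows with background speed. At
  the slowest tested target speed (9 °/s) against −30…−40 °/s backgrounds
  the two are of the same order, and the bundled battery records negative
  HS medians in a handful of those cells. This is an honest property of the
  implemented model under the procedural background, not a tuning target.
* **Very fast backgrounds** (beyond the ensemble's tuned range) keep the HS
  sign correct but activate the VS system noticeably — the expected-degraded
  regime, asserted as such.
* Contrast normalisation, binocular processing and coordination with
  looming- or small-target-selective pathways are out of scope.
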