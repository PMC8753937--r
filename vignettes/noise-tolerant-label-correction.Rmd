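---
title: "Noise-tolerant segmentation with temporal memory and label correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-tolerant segmentation with temporal memory and label correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmend)
```

## The model

`vesselmend` addresses learning with noisy labels for dense binary
segmentation of thin curvilinear structures. The training set provides,
per image, an initial label map $L^0$ that is known to contain pixel
errors and no clean reference. The framework trains a segmenter $G$ and
rewrites the labels simultaneously, on the assumption that underlies
temporal-consistency methods: across the random exploration of training,
predictions at correctly-labeled pixels are *stably* close to their
target, while predictions at mislabeled pixels oscillate.

Training is organized as an initialization phase (plain supervised
training on $L^0$) followed by $M$ cycles of $E$ epochs. Within cycle
$j$ the supervision map $L^j$ is frozen, and a per-image, per-pixel
**memory bank** tracks the historical best prediction
$\tilde S_{x,y} = S^k_{x,y}$ with $k=\arg\min_u |S^u_{x,y}-L^j_{x,y}|$,
and the worst, $\bar S$, via the corresponding $\arg\max$. Because $L^j$
is constant within the cycle, strict-inequality incremental replacement
is exactly the arg-min/arg-max over all recorded epochs while storing
only four maps per image; an oracle-equivalence test checks this against
a brute-force stack scan.

After $T$ warm-up epochs (plain criterion $E(S, L^j)$, giving the bank
time to accumulate) the loss becomes the temporal memory loss
$E(S^e,\tilde S^e) + \lambda\,E(S^e,L^j)$ with $\lambda = 0.1$. $E$ is
binary cross-entropy applied to *soft* targets: corrected labels and
$\tilde S$ are continuous, and nothing in the update rules binarizes
them during training. $\tilde S$ is a constant target — no gradient
flows into the bank.

At the cycle's end, the rangeability $d = |\tilde S - \bar S|$ acts as
an instability score (large $d$ = low confidence in the final
prediction), and the compensation
$Q^j = D\odot\tilde S^j + (1-D)\odot S^j$ blends the stable historical
best into the last-epoch prediction $S^j$. The labels then move along
the anchored convex path $L^{j+1} = \tfrac{1}{j+1}L^0 +
\tfrac{j}{j+1}Q^j$; cycle 1 trains on $L^0$ itself. The update can never
overshoot past its anchor, converges monotonically to $Q$ as $j$ grows,
and preserves $[0,1]$ by convexity.

## Parameters that matter

* `total_epochs = 100`, `init_epochs = 50`, `n_cycles = 5`,
  `epochs_per_cycle = 10` — the reference schedule. The desk-scale
  benchmark in the tests scales this to $14 + 4\times4$ epochs.
* `warmup_epochs` ($T$, default 3): the source schedule states only that
  the bank "needs several epochs"; 3 of 10 is our choice, configurable.
* `lambda_weight = 0.1`: the preset weight of the label term.
* `base_lr = 7e-3` (Adam), `sgdr_start_epoch = 40`, `sgdr_period = 10`:
  cosine annealing with warm restarts, $\eta_{\min}=0$. The 10-epoch
  offset between scheduler start and the first cycle is reproduced
  verbatim; scaled-down schedules keep the same relation
  (`sgdr_start = init_epochs − epochs_per_cycle`).
* `swa_enabled`: snapshots are averaged at each restart from
  `sgdr_start_epoch` on. The cycle-end prediction $S^j$ comes from the
  SWA-averaged model by default (`sj_source = "swa"`), consistent with
  the weight-averaging practice the schedule adopts, in which the
  averaged model is the one whose predictions refresh the labels;
  `"online"` uses the raw end-of-cycle weights instead.
* `model_width = 8`: first-level channels of the depth-4 U-Net-style
  segmenter. No autodiff framework exists in this R stack, so forward
  and backward passes are written out explicitly with compiled
  convolution/pooling primitives; a finite-difference test guards the
  gradients.

## Design choices where the design was open

* **Bank reset per cycle.** The arg-min runs over "the epoch index in
  cycle $j$"; accumulating across cycles would compare predictions
  against a stale $L^j$. The bank therefore resets at every cycle start
  (including cycle 1: warm-up epochs repopulate it), and asserts via
  checksum that $L^j$ did not change mid-cycle.
* **Ties keep the earliest value** — strict-inequality replacement,
  documented and tested; stable and reproducible.
* **Four flip views are independent batch items**; each view's
  prediction is reversed to canonical orientation and recorded as a
  separate bank update (4 per image per epoch). Whether the source
  averaged views is unstated; independence is the simplest choice.
* **Warm-up drops the weight entirely**: the warm-up loss is plain
  $E(S, L^j)$, not $\lambda E(S, L^j)$, following the stated schedule
  wording.
* **$S^j$ comes from the last epoch** of the cycle, on the canonical
  (un-augmented) view.
* **The final correction is exported, never trained on**: cycle $M$'s
  update produces $L^{M+1}$, which is the framework's output.
* **Soft labels throughout**; binarization at 0.5 happens only in
  metrics and PNG export. PR area treats soft maps as pixel scores and
  uses the step-wise average-precision rule (the trapezoid is optimistic
  on PR curves). Per-image metrics are macro-averaged; the convention is
  recorded in the output.

## The synthetic world

The generator emulates what the method needs from fundus data and
nothing more: thin, branching, curvilinear foreground (tapering jittered
random walks, ~4–7% foreground fraction) on a textured background with
Gaussian noise. It does not emulate photometric realism, the optic disc,
field-of-view masks, or inter-vessel contrast; a green test therefore
establishes that the *mechanism* recovers polluted labels on
vessel-like geometry, not clinical performance on real fundus images.

Label pollution follows the contour-approximation mechanism: each
component's traced boundary (Moore tracing, 8-connectivity, holes
handled via interior background components) is simplified
Douglas–Peucker-style at tolerance $\varepsilon$ and refilled
(nonzero-winding scanline, boundary-inclusive; the winding rule is
required so that out-and-back contours of 1-px strokes cancel instead of
flipping parity). Components whose polygon degenerates below 3 vertices
are deleted — thin diagonal branches vanish at coarse tolerance, which
realizes label deletion. $\varepsilon$ defaults to 1.5/3/6 px for
LV-1/2/3 **in absolute pixels**: phantom vessels have the same absolute
thickness (1–4 px) as vessels in native-resolution fundus images, so
scaling $\varepsilon$ with image size would make the levels a no-op at
desk scale; an optional `scale_ref` restores proportional scaling. At
these defaults the corrupted labels score mean F1 ≈ 0.81/0.66/0.49
against gold at the three levels — strictly ordered, with severity
comparable to the regime the method was designed for. The tolerance
values are calibration choices fixed before any end-to-end experiment
was run, not published facts.

## Numerical choices and degenerate inputs

* Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ inside the loss;
  gradients are taken w.r.t. the sigmoid pre-activation, so clamping
  never destabilizes backpropagation.
* A `tml`-phase epoch with an unpopulated bank falls back to the
  warm-up loss with a warning (this can only happen in hand-built
  schedules; the planner always places warm-up first).
* `f1_score` returns 1 when both maps are empty and 0 when the
  denominator vanishes against non-empty gold; `pr_auc` refuses
  single-class gold.
* Training-path code cannot read gold masks: access goes through
  `sample_gold()`, which errors while the trainer holds the gold lock;
  a gold-free dataset trains identically.
* Fixed seeds make every generator and the full training loop
  bit-reproducible on CPU (one BLAS thread configuration).

## Known limitations

* Desk-scale only: full-resolution multi-dataset training is out of
  scope, as are comparison reimplementations and real second-annotator
  noise. The surrogate `dilation_erosion` and `dropout` noise kinds are
  labeled stand-ins, not reproductions of published pollution sources.
* The hand-written segmenter is deliberately small; it is the vehicle
  for the label-correction mechanism, not a competitive vessel
  segmenter.
* Cycle 1's correction cannot change binarized labels (the half-half
  blend cannot cross the 0.5 threshold) — visible as a flat first point
  in the correction-F1 curve.
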