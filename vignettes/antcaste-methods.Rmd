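---
title: "Quantifying caste-specific olfaction and behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying caste-specific olfaction and behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antcaste)
```

`antcaste` packages the quantification stack used in caste-comparative
studies of ant chemosensation: electroantennogram (EAG) normalization and
odor-panel statistics, rank-concordance odor-coding analysis, arena video
tracking with trail-following event scoring, and frame-wise aggression
scoring. This vignette explains the underlying models, the tunable
parameters and the numerical choices, and states what the synthetic-data
generators do and do not emulate.

## EAG sessions and solvent normalization

An EAG session delivers odor pulses to one antennal preparation in a fixed
order — solvent control, odor blends 1–18, solvent, blends 19–36, solvent —
recording one peak response amplitude (mV) per pulse. Antennae degrade over
a session, so raw amplitudes drift. The package removes this drift by
piecewise-linear interpolation of the solvent responses *over stimulus
index* and subtracting the interpolated baseline from every odor response:

$$\tilde r_i = r_i - \mathrm{interp}(i;\ \{(i_s, r_s)\}_{s \in \text{solvent}}).$$

Positive normalized values are above-solvent (excitatory relative to
control); negative values are sub-solvent (suppression below the control
response).

Design notes:

* **Index, not wall-clock time.** Stimuli are delivered at approximately
  regular intervals, so the stimulus index is the reliable coordinate; the
  recording software's clock is not part of the data model.
* **No extrapolation.** Sessions must begin and end with a solvent event;
  queries outside the solvent anchor range are errors rather than guesses.
* **Quality gate.** Before a session is analyzed, the preparation must
  respond to the positive control TETQ (5,6,7,8-tetrahydroquinoline) at
  more than 1.5× the mean of the flanking solvent responses. The comparison
  is strict: a response of exactly 1.5× fails. The denominator is the mean
  of the two flanking diethyl-ether responses, since the control sequence
  is ether, TETQ, ether.
* Amplitudes are stored as positive peak magnitudes; raw trace polarity and
  peak picking from continuous recordings are out of scope.

Because the generator's drift is exactly linear in stimulus index and the
normalization interpolates linearly over the same coordinate, planted blend
effects are recovered to machine precision at zero noise — this anchors the
correctness tests.

## Panel statistics

`compare_castes()` runs a Welch (unequal-variance) two-sample *t*-test per
blend between the castes' replicate normalized responses.
`classify_vs_solvent()` runs one-sample *t*-tests against zero per blend
and caste and combines the FDR-adjusted decision with the sign of the mean
into four categories (`sig_above`, `ns_above`, `ns_below`, `sig_below`).
`sub_solvent_fisher()` compares the castes' sub-solvent proportions (by
sign of the mean) with the two-sided exact hypergeometric test.

Multiplicity is controlled with the adaptive **two-stage step-up**
procedure (Benjamini–Krieger–Yekutieli 2006, Definition 6): a first
Benjamini–Hochberg pass at $\alpha/(1+\alpha)$ estimates the number of true
nulls $m_0$, and the second pass reruns the step-up inflated by $m/m_0$.
Reported q-values are scaled so that rejection is simply $q \le \alpha$,
and on a single test $q \ge p$. The single-stage BH procedure is available
behind `fdr_method = "bh"` for sensitivity analysis. The implementation is
checked against an independent reference implementation on random p-value
vectors.

### Rank concordance

`concordance_analysis()` labels every unordered pair of blends by whether
the two castes order their mean responses the same way: concordant when
$(x_i - x_j)(y_i - y_j) > 0$, discordant when negative, tied when zero.
Exact ties are excluded from both tallies; with continuous data none should
occur. Kendall's tie-corrected $\tau_b$ summarizes the counts, with a
normal-approximation p-value using the tie-corrected variance of
$S = C - D$. The pair-enumeration path and the closed-form $\tau_b$ are
tested against each other and against an independent implementation.

Concordance operates on caste-mean responses per blend; replicate-level
rank analyses are out of scope.

### Per-class discordance

For a chemical class with $k$ member blends in an $n$-blend panel, the
class's pair set contains every pair with at least one member in the class:
$k(n-k) + \binom{k}{2}$ pairs. For a single-blend class in a 36-blend
panel this is 35 pairs. This denominator is a package decision — the
alternative (within-class pairs only) degenerates for single-blend classes,
which real panels contain (the alkane class here).

### Dose-response models

`fit_dose_response()` fits the four-parameter logistic on log10 molar dose

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
      {1 + 10^{(\log_{10}\mathrm{EC}_{50} - x)\,h}}$$

by bounded Levenberg–Marquardt least squares from a small grid of starting
values (both Hill-slope signs, three EC50 quantiles), keeping the best
residual sum of squares. The hormetic variant adds a linear term
$s \cdot x$, allowing the dip-then-recover profile seen in sub-solvent
dose series. With `model = "auto"` both models are fitted and compared by
small-sample AICc; when the data are too few for AICc ($n \le k + 1$) the
comparison falls back to residual sum of squares, which favors the more
flexible model — with five single observations this is the only defined
choice. The monotonic flag requires both the fitted curve (on a fine grid)
and the per-dose means to be monotone, so a decrease-then-rise pattern in
the means is flagged non-monotonic even under the (always monotone) 4PL.

## Arena tracking

`detect_ants()` consumes binarized video frames (dark animals on a light
background, the standard contrast-adjusted preparation), labels connected
components, discards blobs below `min_blob_area_px`, and returns centroids
in continuous image coordinates (origin at the top-left pixel corner,
x right, y down; pixel `[i, j]` centers at `(j - 0.5, i - 0.5)`).

`update_tracks()` implements a centroid tracker with an explicit lifecycle:

* detections are associated to active tracks greedily by ascending
  Euclidean distance, rejecting pairs beyond `max_match_distance_px`
  (default 200 px = 2 cm at the 10 px/cm rendering scale);
* distance ties resolve to the lowest track id, making updates fully
  deterministic;
* unmatched detections register new tracks; tracks unmatched for more than
  `max_disappeared_frames` consecutive frames (default 15, half a second at
  30 fps) are closed and never resurrected — a later nearby detection
  starts a fresh id.

Greedy association is the canonical choice for this tracker family; the
per-frame invariant `matched + new registrations = detections` and a
tested identity-preservation property (exact trajectory recovery whenever
all inter-animal distances exceed twice the maximum per-frame displacement
and there is no dropout) pin down its behavior. No appearance model,
occlusion reasoning or posture estimation is attempted.

## Trail-following analysis

`calibrate_tracks()` maps pixel tracks to arena centimetres
(21.59 × 27.94 cm by default), flipping the y axis to the arena convention
(origin bottom-left). The odor trail runs along the vertical centerline of
the long dimension, laid as six droplets every 4 cm.

`detect_trail_events()` segments each track into maximal runs whose
cross-trail coordinate stays within `band_half_width_cm` (default 0.5 cm)
of the centerline. A run is a trail-following event only if its **net**
displacement along the trail axis reaches `min_traversal_cm`. The minimum
traversal length is not something the assay description pins down; the
package defaults to one inter-droplet spacing (4 cm), which cleanly
separates a traversal along the trail from a perpendicular crossing (in
band only briefly, with negligible axial progress — never an event). Net
rather than gross displacement makes the criterion robust to positional
jitter; brief band exits are not bridged by default
(`gap_tolerance_frames = 0`), and both knobs are exposed and reported.
Event counts are invariant to mirroring across the trail and to time
reversal (displacement is thresholded unsigned).

`density_map()` bins track points on a regular grid (counts are exactly
conserved) with optional Gaussian smoothing for contour rendering; the
smoothing renormalizes kernel mass at the arena edges so the smoothed map
still sums to the point count. `trail_anova()` fits the standard two-way
ANOVA (caste × treatment) on per-replicate event counts with Tukey-adjusted
comparisons of the four cells.

## Aggression analysis

Trials are scored frame-wise as 0/1 (no aggression / aggression). A 3-min
recording at 30 fps is stored as 5401 frames — both endpoints captured —
and the aggression duration is (count of 1-frames)/30 s, which is linear in
the count and invariant to arrangement. `time_course()` gives the per-frame
proportion of aggressive trials per group; its frame average equals mean
duration over total duration. `severe_outcome_tests()` compares the
fraction of trials with at least one dismemberment (or death) between
pairings with the pooled two-proportion z-test at the Bonferroni-corrected
level $\alpha/m$ (0.05/3 ≈ 0.0167 for the three pairings; pooled variance
is the default, unpooled available behind a flag). When both proportions
are 0 or both 1, z is undefined and the comparison is reported
non-significant with a degeneracy flag. `duration_anova()` mirrors
`trail_anova()` on durations (pairing × relation).

## The synthetic-data generators

Every analysis stage has a seeded generator producing inputs with the
statistical structure the stage assumes, so the whole pipeline is testable
without recordings.

**EAG screen.** `simulate_eag_sessions()` builds balanced minor/major
sessions in the canonical stimulus order with a linear solvent drift
(default −0.005 mV/index from a 1 mV baseline) and i.i.d. Gaussian
replicate noise. No replicate-level variance components are published for
this kind of screen, so the default `noise_sd = 0.25` mV is a package
choice sized so that a ~0.35 mV caste contrast at n = 25 is comfortably
detectable while ~0.1 mV contrasts are not — it is not a claim about any
study. The default latent effect table, `study_blend_effects()`, encodes
the qualitative architecture reported for a 36-blend screen: twelve
divergent blends (at the published blend ids) with a large minor-over-major
contrast, eleven of them above-solvent in minors and sub-solvent in majors;
the other blends tracking each other with a small minor-leaning offset; a
single alkane blend at the bottom of both rankings. The realized counts
(significant blends, sig-below blends, concordant/discordant pairs)
therefore land in the published regime but fluctuate with the seed — the
generator emulates the design, it does not reproduce the deposited data.
Real EAG data also carry session-level correlations, colony effects and
occasional failed preparations that the generator does not model, so green
tests here validate the machinery, not field realism.

**Arena trajectories.** `simulate_arena_tracks()` is a correlated random
walk: von Mises turning increments (concentration `turn_kappa`, default 4),
folded-normal step lengths (scale `step_sd_cm`, default 0.3 cm ≈ 9 cm/s at
30 fps), reflecting walls. Trail attraction is a per-frame restoring force
on the cross-trail coordinate (`trail_bias`, default 0); it is the simplest
mechanism producing both trail-followers and crossers, not a model of ant
chemotaxis. Detection dropout is independent Bernoulli per ant-frame
(default 0) to exercise the track lifecycle. Rendering draws black discs on
white for the image-based detection path.

**Aggression.** `simulate_aggression_trials()` draws frame scores either
i.i.d. or from a two-state Markov chain started at its stationary law
(giving bout structure); severe events are placed uniformly inside
aggressive frames, so they can only occur while aggression is scored.
`simulate_aggression_study()` assembles the full pairing × relation design
with near-zero nestmate aggression, sustained non-nestmate aggression, a
faster-ending mixed pairing, and severe outcomes concentrated in pairings
involving majors.

## Problem sizes and reproducibility

All generators take explicit integer seeds and are byte-reproducible. The
test-suite simulations use the study design sizes where they matter
(n = 25 preparations per caste, 36 blends, n = 7 trail replicates,
n = 10–11 aggression trials, 5401 frames) and smaller arenas/durations for
pure mechanics checks. The acceptance script (`scripts/acceptance.R`) uses
2-minute arena simulations for its 28 trail trials and the study sizes
everywhere else; it states the problem size alongside every reported
quantity.

## Known limitations

* The EAG generator's noise model is i.i.d. Gaussian; it cannot express
  preparation-level sensitivity differences or heavy-tailed artifacts.
* Greedy association can swap identities when animals pass within the
  match radius of each other; the identity guarantee holds only under the
  separation premise stated above.
* The hormetic dose-response model is a phenomenological 4PL-plus-linear
  term, adequate for flagging non-monotonicity but not mechanistic.
* Event counting depends on two explicit knobs (`min_traversal_cm`,
  `gap_tolerance_frames`); comparisons across studies should fix them and
  report them, as the output metadata does.
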