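---
title: "Models and methods behind ecmonitor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ecmonitor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmonitor)
```

# The monitored system

`ecmonitor` analyzes experiments in which *Escherichia coli* grow inside a
confined, non-fluidic microchannel (60 µm wide, a few µm deep) that crosses a
set of gold microelectrodes. Before bacteria arrive, the channel is empty:
the electrodes have no electrical contact and the measured signals are
dominated by stray potentials and capacitive charging. Once the expanding
colony front covers the electrode-enabled active area — the *colonization
event* — the cell mass forms a conductive, electrochemically active bridge:
the cyclic voltammetry (CV) current rises and develops a redox peak pair,
and the impedance (EIS) drops. The package quantifies this transition from
three data streams: time-lapse micrographs of the channel, CV sessions
(three 201-point triangular sweeps from −0.5 V to 0.5 V at 50 mV/s every
30 min), and EIS sessions (one 25-frequency spectrum, 200 Hz–50 kHz, every
30 min).

No public raw data exist for this kind of experiment, so the package ships
seeded generators that emulate all three streams with known ground truth.
Every analysis stage is exercised against those generators; the final
section of this vignette states what that does and does not demonstrate.

# Normalized-variance changepoint detection

For each sample (one sweep's 201 currents, or one spectrum's 25 |Z| or phase
values) the unbiased variance

$$\sigma^2_n = \frac{1}{M-1}\sum_{i=1}^{M} (x_i - \mu_n)^2$$

is computed, and the per-sample variance series is min–max normalized to
$V_n \in [0,1]$. Normalization matters because absolute current levels vary
by up to three orders of magnitude between microsystems (electrode
resistivity, contact resistance); all decisions are therefore built on
ratios, never on absolute levels.

A single step change is located by minimizing the two-segment
log-variance cost

$$J(k) = (k-1)\,\log\operatorname{var}(V_1 \dots V_{k-1})
       + (n-k+1)\,\log\operatorname{var}(V_k \dots V_n),$$

the standard Gaussian single-changepoint cost with segment-length weights.
Numerical choices: the variance inside $J$ is the population (1/count)
form; each segment must contain at least two points, so $k \in [3, n-1]$;
segment variances are floored at $10^{-12}$ before the logarithm so that
noiseless fixtures cannot produce $\log 0$; ties break toward the smallest
$k$ (the earliest event), deterministically. The per-sample variance uses
the unbiased $1/(M-1)$ form — the two conventions serve different purposes
and both are exposed.

The *change ratio* of a series across its changepoint is the ratio of true
segment means,

$$R = \frac{\tfrac{1}{n-k+1}\sum_{i=k}^{n} x_i}
          {\tfrac{1}{k-1}\sum_{j=1}^{k-1} x_j}.$$

Both segments are averaged by their term counts. (A transcription of this
ratio sometimes divides the post-event sum by $n-k$; `change_ratio()`
exposes that variant behind `denominator = "printed"`, but the true-mean
convention is the default and is what every downstream number uses.)

# Image pipeline

Each frame is collapsed to luminance and contrast-stretched to the full
0–255 range. Channel borders are found with a straight-line Hough transform
on a gradient edge map (edge threshold: the 0.99 gradient quantile of the
frame, "determined individually for each image set"): the accumulator scans
inclinations ±10° in 0.5° steps with 1-px offset bins, takes the two
highest-scoring near-parallel lines at least 100 px apart, and refines each
by a least-squares line fit through its supporting edge pixels (this removes
both quantization biases; the round-trip test recovers borders within 1 px
after rotations up to 10°). Frames are rectified by rotating about the
weighted center and cropped to the channel plus a 6-px margin.

Segmentation uses a local-variance texture statistic (5×5 window): bacteria
and channel borders are strongly textured, empty background is not. The
threshold is the 70th percentile of the statistic on the *reference frame*
of the set (the first, pre-growth frame) and is then applied to every frame
of the set — a per-frame percentile would pin every frame's foreground
fraction at 30% and could not report growth. With the default percentile, a
bacteria-free frame reports the ~30% "image analysis offset" contributed by
the borders, and a fully colonized frame reports ≥95%.

Growth phases are read off the colonized-percentage series: the offset is
the median of the pre-growth plateau; the lag end is the (sub-frame,
linearly interpolated) time at which the curve first exceeds offset + 3
percentage points; the stationary start is the first frame after the rise
whose median-smoothed forward difference falls below 0.5 points/frame; the
colonization duration is their difference. The margins are configurable;
the interpolation at the lag end removes most of the one-frame quantization
bias of a "first frame above threshold" rule, while the stationary start
deliberately stays on the frame grid (the plateau is flat, so interpolation
would not be meaningful there). With the nominal conditions (65-min
traversal, 10-min frames) the recovered duration is biased high by roughly
two minutes — the stationary frame quantizes upward — which is well inside
the one-frame-interval tolerance used throughout.

# CV analytics

The colonization event splits a session's sweeps into before/after groups.
At each applied-potential point the across-sweep current variance is
computed; *primary* peak candidates are the strict local maxima of that
variance curve, and *secondary* candidates are local maxima of
$|\sigma^2/\sigma^{2\prime}|$ and $|\sigma^{2\prime}/\sigma^{2\prime\prime}|$
(central differences, denominators floored at $10^{-15}$) — a fallback for
peaks the raw curve does not resolve. Candidates are clustered on the
potential axis by single-linkage with a 50-mV merge distance (comparable to
the 27–44 mV peak-potential spreads seen in practice), each cluster is
represented by its largest-|current| member, and the top anodic and
cathodic representatives form the redox pair. Sign conventions: anodic
(oxidation) currents are positive and live on the forward (increasing)
branch; cathodic on the reverse branch.

Peak change ratios evaluate the mean after-event current at the detected
peak-potential grid point against the mean before-event current at the same
point — the change-ratio construction applied at the peak. The formal
potential of a reversible couple is $(E_{pa}+E_{pc})/2$; with the
ferro/ferricyanide couple as internal standard (241 mV vs. Ag/AgCl), the
reference correction is simply 241 mV minus the measured formal potential.

# EIS analytics

The interface is modelled by the simplified equivalent circuit

$$Z(\omega) = R_{elec} + \Big[\, j\omega C_{belec}
  + \big(R_b + Z_{CPE}(\omega)\big)^{-1} \Big]^{-1},
\qquad Z_{CPE}(\omega) = \frac{1}{Q_i (j\omega)^{n_i}},$$

with the microsystem series resistance $R_{elec}$, the bacteria–electrode
interface capacitance $C_{belec}$, the charge-transfer resistance of the
bacteria $R_b$, and a constant phase element for the non-uniform
accumulation of adsorbed species ($Q_i$ in S·s^n^, $n_i \in (0,1]$). The
generalized model — two electrode Randles cells bridged by an
inter-electrode capacitance, in series with the bacterial cell
$(R_b + CPE)\,\|\,C_b$ — is implemented (`full_circuit_impedance()`) with an
explicitly documented topology, reduces exactly to the simplified model
when the electrode interface cells are shorted, and is kept for reference:
all quantitative work uses the simplified circuit, whose elements are the
ones that can actually be resolved below 50 kHz.

Fitting is complex nonlinear least squares with modulus weighting
($\sum_f |Z_{model}-Z_{data}|^2/|Z_{data}|^2$ — the standard choice when
|Z| spans orders of magnitude across the band), by Levenberg–Marquardt over
log-transformed parameters ($n_i$ through a logit), with a data-driven
initialization ($R_{elec}$ from the high-frequency real part, $C_{belec}$
from the high-frequency imaginary part, $R_b$ and $Q_i$ from the
low-frequency excess) and a small deterministic multistart over $R_b$ and
$n_i$. Noiseless spectra are recovered to machine precision; the identity
and limit behavior of every circuit element is unit-tested.

Identifiability deserves a plain statement: on a *single* 1%-noise spectrum
over 200 Hz–50 kHz the CPE parameters are very poorly determined — before
colonization the faradaic branch carries almost no current (that is the
physics of an open, bacteria-free channel), and even after colonization the
median $Q_i$ error of per-spectrum fits is tens of percent regardless of
optimizer. The pipeline therefore fits the *epoch-mean spectrum* (the
complex mean of all spectra in an epoch) for quantitative element values,
where all five elements are recovered with median errors below 5% in the
after epoch; per-spectrum fits are used only for trajectory plots.
`parameter_trajectory()` races a warm start from the previous spectrum
against the auto-initialized multistart and keeps the better residual,
which avoids the local minimum a warm start falls into right after the
parameter jump at the event.

The per-spectrum variance of |Z| and of the phase (degrees — the Bode
convention) feed the same changepoint machinery as the CV currents;
`max_change_frequency()` reports where the epoch-mean |Z| and phase differ
most.

# Event classification

A channel "steps" when its change ratio leaves $[1/\theta, \theta]$
(default $\theta = 2$) *and* its changepoint objective beats the no-split
cost of its segment by more than $\log 4$ per point — the margin filters
the spurious changepoints that min–max normalized noise always produces.
Because a damaged experiment produces two steps on one channel (the
colonization rise, then the damage fall), each channel's evidence comes
from binary segmentation to depth two: the primary changepoint plus
sub-changepoints in the segments before and after it, with each step's
ratio evaluated between its neighboring steps and its margin evaluated
locally. Labels follow the observed signatures:

* **colonization** — concurrent steps (within 2 measurement intervals) on
  all three channels: current variance up, impedance variance down, phase
  variance down;
* **damage_after_colonization** — colonization followed by a current
  decrement and a phase increment;
* **early_damage** — exactly two stepping channels with no faradaic
  signature (no current up-step): a resistance change without bacteria;
* **control** — no steps; and
* **indeterminate** — an honest fallback for flag patterns matching none of
  the above.

`image_echem_concordance()` compares the electrochemical event time with
the image-derived stationary start and flags offsets beyond 2.5 h.

# The synthetic generators

All generators are pure functions of (scenario, seed), restore the caller's
RNG state, and attach ground truth so recovery tests never peek at
generator internals.

**Images.** A frame holds two 3-px dark wall lines 240 px (60 µm at
4 px/µm) apart, granular artifact bands flanking the walls, background
Gaussian noise, and bacteria rendered as clipped-Gaussian granular texture.
The artifact bands stand in for the border shadows and cumulative imaging
errors that make the real offset ~30%: their thickness is sized by a
closed-form smear model (each wall contributes its 3 px plus ~4 px of
texture-window smear) so that segmentation of a bacteria-free crop returns
`border_offset_fraction`. The front enters at `front_arrival_time_s` and
crosses the segment linearly in `colonization_duration_s` (nominal 3900 s);
scouting colonies appear ahead of the front as Poisson-seeded disks
(default 0.15 per frame — the behavior is documented in this system, its
rate is not, so the rate is a free parameter chosen to keep colonies an
occasional feature) and persist once seeded, which keeps the ground-truth
fraction monotone.

**CV.** Currents are a capacitive box (±5 nA by sweep direction) plus an
ohmic slope (2 nA/V) plus 0.2 nA stray noise. After the event, Gaussian
peaks (σ = 30 mV) appear at $E_{pa}$ = 139.8 mV (forward) and $E_{pc}$ =
−204.55 mV (reverse); their steady-state amplitude makes the current at the
peak potential exactly `anodic_change_ratio` (8.29) and
`cathodic_change_ratio` (6.07) times the pre-event current there. The
amplitude envelope is an onset logistic — zero at the event, ~96% after
2 h — so the variance series steps sharply at the event while the signal
stabilizes over the observed 2–5 h scale; a symmetric logistic centered
after the event would leak amplitude backwards and bias both the detected
changepoint and the Eq-style ratios. Peak amplitudes carry 5% lognormal
sweep-to-sweep jitter, reflecting the scatter of real peak currents; this
jitter is also what keeps the changepoint objective from trading a one-
interval detection delay for plateau purity. Electrode damage multiplies
post-damage currents by a factor decaying to 0.3.

**EIS.** Spectra come from the simplified circuit with the average fitted
element values before/after colonization as regimes ($C_{belec}$
0.919→6.72 nF, $R_{elec}$ 15.96→3.904 kΩ, $R_b$ 5.71→0.107 MΩ, $Q_i$
31.4→69.8 nS·s^n^, $n_i$ 0.774→0.865) and 1% relative complex Gaussian
noise (total complex sd per point; the paper-scale noise level is not
stated, 1% is a typical potentiostat figure). The event is a sharp
log-space jump to an intermediate parameter point followed by a slow settle
to the after regime — colonization establishes contact quickly, the biofilm
then densifies. The intermediate point is *solved*, not hand-picked: two
nested root-finds over a two-weight blend (resistive elements vs. interface
elements) place the within-spectrum impedance variance at
`variance_drop_fraction` (0.30) of the before-to-final range while the
phase variance lands directly at its after value. The settle is scheduled
to be linear in the impedance variance. Consequences, by construction: the
normalized impedance variance steps at the event and then declines linearly
from 0.30 to 0, so its change ratio is ~0.15; the phase variance steps once
at the event and stays near its after level. A plain parameter step cannot
reproduce the 0.15 ratio — min–max normalization pins a stable after-epoch
at ~0 — which is why the trajectory has this shape. Post-colonization
damage is contact degradation on both the series path ($R_{elec}\times 2$)
and the faradaic path ($R_b\times 8$, ramped over 1 h, noise ×4), which
raises the phase variance deterministically while the faradaic branch
remains; early damage is a pure series-resistance step ($R_{elec}\times
8$) with no faradaic change.

Inoculum-to-event times are not constrained by any published distribution;
`front_arrival_time_s` and `colonization_time_s` are free scenario
parameters with defaults (3000 s; 8 h) in the observed range.

# Problem sizes and limitations

The default test and acceptance runs use 15-frame stacks of 283×1200-px
frames, 24-h CV sessions (144 sweeps), 35-h EIS sessions (70 spectra),
20-seed recovery panels and a 4×25-seed classification panel — sizes chosen
so the full suite completes in minutes on one CPU while keeping the Monte
Carlo error of every recovered mean well inside its tolerance.

What passing tests show — and what they do not: the generators reproduce
the *statistical structure* the analysis relies on (variance steps, peak
geometry, circuit regimes, border offsets), so the tests demonstrate that
the pipeline recovers known truth under that structure, including under
rotation, intensity scaling, and bit-depth changes. They do not demonstrate
robustness to everything real micrographs and potentiostat traces contain:
uneven illumination, focus drift, agar degradation, electrode drift within
an epoch, correlated (non-Gaussian) instrument noise, or biofilm optics.
The image generator renders bacteria as stationary texture rather than
moving cells; the CV generator's baseline is an idealized capacitive box;
the EIS noise is frequency-independent. Real deployments should expect the
configurable margins (rise margin, derivative floor, ratio threshold,
objective margin) to need site-specific tuning — which is why every one of
them is an explicit argument with the defaults documented here.
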