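---
title: "Deriving contractility and compliance from dynamic PV loops: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving contractility and compliance from dynamic PV loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Contractility and compliance are slopes in the pressure–volume (PV)
plane. During a transient inferior-vena-cava occlusion, each heartbeat
fills a little less than the one before; the end-systolic points of the
resulting loops sweep down the end-systolic PV relationship (ESPVR) and
the end-diastolic points down the EDPVR. Linear fits through those points
give contractility (ESPVR slope, mmHg/ml) and compliance (inverse EDPVR
slope, ml/mmHg).

In the CMR environment the two coordinates come from different
instruments on different clocks and rates: LV pressure from a
fluid-filled catheter recorded at 1 kHz alongside ECG and the scanner's
gradient waveforms, and volume from real-time long-axis cine frames at
roughly 76 ms resolution, contoured offline. `cmrpv` turns those two
streams into paired loops and fitted slopes. This vignette records the
model, the tunable parameters, and the design decisions that were
genuinely open, in the order the pipeline runs.

# Synchronization and resampling

The recorded gradient activity is the bridge between the imaging clock
and the physiology clock: gradients are active exactly while the scanner
acquires frames. `detect_imaging_window()` combines the gradient axes by
root-sum-of-squares, envelopes the result with a 50 ms sliding RMS, and
thresholds at 10% of the envelope maximum; sub-threshold gaps shorter
than 200 ms (sequence dead times) are merged, and the window edges are
refined on the raw gradient magnitude because a centered RMS envelope
leaks half a window beyond the burst. The threshold and gap defaults are
package choices — any value that separates "gradients on" from "gradients
off" works, and the edge refinement makes the recovered window accurate
to a sample or two regardless.

Pressure-side signals are then cropped to the window and down-sampled
fourfold to 250 Hz through a zero-phase 4th-order Butterworth low-pass at
0.8 × the output Nyquist frequency. Zero-phase (forward–backward)
filtering matters throughout this package: every fiducial is a *time*,
and a causal filter would shift all of them by its group delay. Channels
are filtered around their mean so DC offsets (e.g. a pressure baseline)
pass exactly.

Volume is up-sampled from the frame grid to the 250 Hz pressure grid by
linear interpolation. The frame spacing is taken from the frame
timestamps rather than hard-coded, because acquisition and processing
descriptions of real-time cine protocols commonly quote slightly
different nominal resolutions (76 vs 73 ms); the data are authoritative.

# Fiducial detection

**End-diastole (pressure side)** is the ECG R-peak: the ventricle is
maximally filled at the onset of electrical activation.
`detect_r_peaks()` band-passes the dominant lead at 5–25 Hz, squares it,
and thresholds at 0.4 × a rolling 2 s maximum with a 200 ms refractory
period, then refines each candidate to the raw R apex within ±40 ms.
These are conventional choices that stay robust at high porcine heart
rates; the refinement step makes the reported time the waveform apex
rather than an energy centroid.

**End-systole (pressure side)** is the onset of isovolumic relaxation.
The standard surrogate is the minimum of dP/dt, and
`detect_es_pressure()` starts there: central-difference dP/dt, smoothed
by a zero-phase 25 ms moving average, scanned for its minimum inside each
beat (excluding the first 100 ms after ED, which belongs to the
contraction upstroke). The detection is then *backtracked* to the
earliest contiguous sample at or below 0.5 × that minimum. The reason is
a systematic property of smoothed one-sided decays: isovolumic pressure
decay is approximately exponential from its onset, so the raw |dP/dt| is
largest essentially *at* the onset, but a centered smoothing window drags
the argmin later by about half its width (~12 ms at 25 ms smoothing).
During those milliseconds the elastance has already begun to collapse, so
reading pressure at the lagged argmin systematically underestimates
end-systolic pressure — by enough to bias the fitted ESPVR slope by
10–20% in simulation. Backtracking to the dip onset removes the lag while
keeping the argmin's noise robustness (the threshold is relative to the
beat's own dip, which also makes the detector invariant to pressure
offset and scale). On a smooth symmetric dip such as a raised-cosine
pressure wave the backtracked detection sits where dP/dt first reaches
half its steepest value, slightly before the steepest fall — the
closed-form case the unit tests pin down.

**Volume fiducials** are the per-beat maximum (ED) and minimum (ES)
volume. Frames are lightly smoothed (zero-phase Savitzky–Golay,
quadratic, 5 frames) before peak picking because each frame's volume
carries segmentation noise on the order of a couple of millilitres;
candidate maxima must be separated by at least `min_rr` (default 0.4 s)
and survive a prominence filter at a quarter of the median beat
amplitude, so small preload-depleted beats late in an occlusion are still
detected while noise wiggles are not. Detected frames are refined to the
raw-series extremum within one frame so that on clean data the fiducials
are exactly the per-beat argmax/argmin. The smoothed trace is also the
one paired into loops: with ~20 frames per fit contributing, the
frame-level noise would otherwise both scatter and — through the
errors-in-predictors effect on an ordinary least-squares fit of P on V —
systematically flatten the fitted slopes.

# Volumetry by centerline rotation

A single long-axis contour determines a volume only under a symmetry
assumption: the cavity is treated as circularly symmetric about its long
axis. The implementation takes the centerline from the mitral-annulus
midpoint to the apex, slices the cavity into `n_slabs` slabs
perpendicular to it (default 200; phantom error is below 0.5% and cost is
negligible), measures the perpendicular distance from the axis to the
contour on each side, and sums

$$V = \sum_i \frac{\pi}{2}\left(r_{L,i}^2 + r_{R,i}^2\right)\,\Delta h,$$

i.e. the average of the two half-solids of revolution. Averaging the two
sides uses all contour information and halves the first-order error from
left–right asymmetry, which is the main systematic weakness of the
rotational model (regional wall-motion abnormalities and irregular
cavities violate it in ways a long-axis view cannot see). The basal
boundary is the flat annulus chord. Slabs that miss the contour on one
side are an error except within the apical 5% of the axis, where a
vanishing radius is geometrically expected and is taken as zero with a
warning. Analytic phantoms (spheroid, sphere, cylinder), the k³ scaling
law, and rigid-motion invariance pin the implementation down in the test
suite.

Contours travel in a small versioned JSON format (points in mm, the two
annulus points, the apex, a frame timestamp), with a converter from pixel
coordinates plus pixel spacing. Orientation is normalized on load.

# Pairing and fitting

Within the analysis window the package requires that the pressure side
and the volume side found the *same number* of beats — a disagreement
means detection failed somewhere, and silently pairing mismatched beats
would corrupt every downstream number, so it is a hard error reporting
both counts. Each pressure beat's fiducials (ED, ES, next ED) are then
anchored to the corresponding volume fiducials and the volume timeline is
warped piecewise-linearly between anchors before interpolation onto the
250 Hz pressure grid. The warp is the minimal construction that honors
both fiducials; pressure is chosen as the master grid because it is ~19×
finer.

Fitting uses ordinary least squares of pressure on volume over the first
10 post-occlusion beats (onset from a configured occlusion time, or
auto-detected as the first beat whose peak pressure drops 2 SD below the
first-3-beat baseline). Ten beats balances two failure modes: fewer
points make the line unstable; later beats are contaminated by the
autonomic response to hypotension, which changes inotropy and bends the
sweep. A warning is raised if heart rate rises more than 5% across the
included beats. Flagged beats (short RR, no relaxation dip, or manual
exclusion list) are skipped and later beats pulled in. The EDPVR is
fitted as a line even though the true relation is exponential; over the
narrow strain range of ten beats the linear slope is the standard
compliance summary, and its inverse is reported. A non-positive EDPVR
slope is reported as an error, never clamped. For a linear fit the phrase
"compliance at end-diastole" is vacuous — the slope is constant — and the
package documents it as such.

Agreement statistics for method-comparison studies (long-axis vs
short-axis volumes, CMR vs conductance catheter) are Bland–Altman bias
with 1.96 SD limits and the intraclass correlation. The ICC variant is
fixed to ICC(2,1) — two-way random effects, absolute agreement, single
measure — which is the defensible default when neither method is a gold
standard; published reports often omit the variant, so this is stated as
an assumption. Labels follow the conventional banding (poor ≤ 0.30, weak
≤ 0.50, moderate ≤ 0.70, strong ≤ 0.90, excellent ≤ 1.00) applied to the
coefficient rounded half-up to two decimals.

# The simulator

The test strategy is parameter recovery: simulate a heart whose true
contractility and compliance are inputs, render realistic measurements,
run the pipeline, and compare. The model is a time-varying elastance
ventricle,

$$P_{LV}(t) = E(t)\,\big(V(t) - V_0\big), \qquad
E(t) = E_{min} + (E_{max}-E_{min})\,\hat e(t),$$

with resistive diode valves, a single-compartment windkessel afterload,
and a venous source pressure that is constant until balloon inflation,
decays exponentially during occlusion (`tau_occ`), and recovers after
deflation. Integration is fixed-step RK4 at 2 kHz via `deSolve`; the
diode `max(ΔP, 0)` flows make valve events implicit in every sub-step.

The activation shape matters more than is obvious. A popular closed form
(the double-Hill) rises and falls as smooth sigmoids; its relaxation limb
declines fastest near *half*-maximal elastance, which places the dP/dt
minimum — and hence any dP/dt-based end-systole detector — at a moment
when elastance is far below its peak. A heart like that would make the
detected "end-systolic" points fall on a line with roughly two-thirds of
the true slope, not because the pipeline is wrong but because the
waveform separates peak elastance from relaxation onset in a way real
ventricles do not: physiologically, relaxation sets in essentially at
peak elastance and pressure then falls exponentially with a time constant
of a few tens of milliseconds. The simulator therefore uses a
raised-cosine upstroke to peak elastance at 30% of the beat period,
followed by exponential relaxation with `tau_r` = 40 ms (a typical
relaxation constant for a healthy large-animal ventricle). With this
waveform the true ES (peak elastance), the fine-grid dP/dt minimum, and
the pipeline's backtracked detection all coincide to within a few
milliseconds, and per-beat true ES points lie exactly on
$P = E_{max}(V - V_0)$ — the ground-truth line the tests regress
against. Activation is exactly zero at the beat onset, so true ED points
lie exactly on $P = E_{min}(V - V_0)$.

Default parameters are scale-matched to a healthy adolescent-pig cohort:
`emax` 0.6 mmHg/ml, `emin` 0.2 mmHg/ml (compliance 5 ml/mmHg), `v0`
10 ml, heart rate 77 bpm, venous pressure 22 mmHg, peripheral resistance
0.55 mmHg·s/ml, arterial compliance 3 ml/mmHg. These give EDV ≈ 112 ml,
ESV ≈ 70 ml, SV ≈ 42 ml, EF ≈ 38% — the scale of healthy ~50 kg swine.
Two values deserve comment:

- *Venous pressure 22 mmHg.* With a linear passive line of slope
  `emin` = 0.2 through `v0` = 10, a 110 ml ventricle necessarily sits at
  an EDP near 20 mmHg. Real ventricles reconcile normal EDP (~9 mmHg)
  with 110 ml EDV through an exponential EDPVR that is shallow at low
  volume; a strictly linear-EDPVR model cannot, so the simulator accepts
  the elevated EDP in exchange for volumes, stroke volume and ejection
  fraction on the measured scale. The filling pressure is what the model
  needs, not a physiological claim.
- *Arterial compliance 3 ml/mmHg.* Together with the peripheral
  resistance this sets the windkessel time constant (~1.7 s), keeping
  diastolic aortic pressure above venous pressure. With a stiffer
  arterial compartment the aorta would decay below the filling pressure
  within one diastole and the model would transiently fill and eject at
  once — the flow-conservation test in the suite guards exactly this.
- *Occlusion decay `tau_occ` = 15 s, deflation after 15 s with a 2 s
  recovery.* Over ten beats this produces a ~30% ESV reduction and a
  ~35% peak-pressure reduction — the measured scale of a balloon IVC
  occlusion — while every beat in the imaging window keeps enough stroke
  volume to be detectable on the volume side. A much faster decay
  empties the ventricle entirely within the window: stroke volume falls
  below the frame noise, the volume-side beat detector (correctly)
  stops finding beats, and the pressure/volume beat-count check fails —
  a degenerate regime outside what the method is for.

Rendering adds the measurement layer: sampling at 1 kHz, Gaussian
pressure noise (default 1 mmHg), an ECG built from Gaussian P/QRS/T
templates with the R apex exactly at the activation onset, gradient
bursts as alternating trapezoid lobes strictly inside the imaging window,
and optionally a causal second-order catheter model (natural frequency,
damping ratio) reproducing the underdamped overshoot and ringing of
fluid-filled lines. Contour sequences are full ellipses whose short axis
realizes a prescribed volume trace through the spheroid relation
$b = \sqrt{3000 V / (4\pi a)}$, with frame-level volume noise (default
2 ml) injected into the prescription. All randomness flows from one seed;
the ground truth itself is deterministic and noise-free.

What the simulator does *not* emulate — and what recovery tests therefore
cannot certify — includes breathing and through-plane motion, arrhythmia,
autonomic reflexes (heart rate is fixed, so the heart-rate-drift warning
never fires on synthetic data), asymmetric ventricles that violate the
rotational volume model, and baseline drift or RF interference in the
electrical channels.

# Numerical choices and degenerate inputs

- Non-uniform recording timestamps are rejected (tolerance 1 µs), not
  resampled: the acquisition hardware guarantees a uniform clock, so
  non-uniformity signals corruption that silent resampling would hide.
- Windows are closed intervals sampled inclusively; all times are seconds
  from recording start.
- Fits require ≥ 3 points and non-zero volume variance; two-point or
  degenerate inputs are classed errors, as are beat-count mismatches,
  out-of-range windows, missing columns, and contour landmarks off the
  polygon (checked against the polygon boundary, not just its vertices).
- The 20-replicate recovery study in the acceptance material judges
  accuracy on the replicate mean. A single replicate's fit carries
  irreducible sampling error — ten fitted points whose volume coordinate
  is measured with ~1–1.4 ml effective noise against a ~20 ml ESV sweep
  — so individual replicates scatter by several percent around the truth
  (observed SD ≈ 6–7% for contractility) while the ensemble mean settles
  well within a few percent. Beat-count consistency, by contrast, is
  asserted on every run.
- Problem sizes used in the shipped tests: 30 s simulations at 2 kHz,
  326-frame contour sequences at 76 ms, 200 volume slabs, 20 noise
  replicates, 100-seed fiducial-interleaving sweeps. These keep the whole
  suite at a few minutes on one core while leaving every tolerance
  meaningfully tight.

# Known limitations

The volume model assumes rotational symmetry; the EDPVR is linear by
construction; the ES detector assumes a clean relaxation dip (heavily
damped catheter traces can smear it — the catheter model exists so that
this degradation can be studied, not to claim immunity); and the
occlusion-onset auto-detector needs three clean baseline beats. The
package analyzes conditioned signals: it does not remove gradient-induced
interference from the ECG, and it does not segment images — contours are
inputs.
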