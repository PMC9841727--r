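# cmrpv

Dynamic left-ventricular pressure–volume (PV) loop analysis for the CMR
environment.

During a transient inferior-vena-cava (IVC) occlusion the heart is swept
through a range of preloads, and the per-beat end-systolic and
end-diastolic points trace out two lines in the PV plane:

- the **ESPVR** (end-systolic pressure–volume relationship), whose slope
  `Ees` (mmHg/ml) is a load-independent index of **contractility**:
  `P_es = Ees (V_es − V0)`;
- the **EDPVR** (end-diastolic pressure–volume relationship), whose inverse
  slope is **compliance** (ml/mmHg).

Measuring both simultaneously inside an MR scanner is attractive because
real-time long-axis cine imaging gives calibration-free ventricular
volumes, while a fluid-filled catheter and an MR-conditioned recording
system give invasive LV pressure, ECG, and the scanner's gradient
waveforms on one 1 kHz clock. `cmrpv` implements the complete signal
processing chain from those raw recordings to contractility and
compliance:

1. **Signal extraction** — the image-acquisition window is detected from
   the recorded gradient activity (sliding-RMS envelope) and the pressure
   and ECG channels are cropped to it and down-sampled fourfold
   (1 kHz → 250 Hz, zero-phase anti-alias filter).
2. **Pressure fiducials** — end-diastole from ECG R-peaks (band-passed,
   squared, adaptive threshold); end-systole at the onset of isovolumic
   relaxation, located from the smoothed-dP/dt minimum with backtracking
   to the dip onset.
3. **Volume** — per-frame LV volume from long-axis endocardial contours by
   centerline rotation: the cavity is sliced perpendicular to the
   annulus-midpoint-to-apex axis and each slab contributes the average of
   the two half-discs of revolution,
   `V = Σ (π/2)(r_L² + r_R²) Δh`.
4. **Volume fiducials** — per-beat maximum (ED) and minimum (ES) volume,
   then linear up-sampling from the ~76 ms frame grid to the 250 Hz
   pressure grid.
5. **PV loops** — pressure and volume are paired beat-by-beat with a
   piecewise-linear time warp anchored at ED/ES/next-ED, over the first 10
   beats after balloon inflation.
6. **Fits** — ordinary least squares through the 10 end-systolic and 10
   end-diastolic points; contractility = ESPVR slope, compliance =
   1/EDPVR slope. Bland–Altman and ICC(2,1) agreement statistics support
   method-comparison studies.

Because animal recordings are not distributable, the package ships a
lumped-parameter cardiovascular simulator (`simulate_lv`,
`render_recording`, `contours_from_volume`): a time-varying-elastance
ventricle with diode valves and a windkessel afterload, an exponential
venous-pressure decay after occlusion (with balloon deflation), a
Gaussian-template ECG, trapezoidal gradient bursts, an optional
second-order fluid-filled-catheter model, and contour sequences whose
centerline-rotation volume realizes a prescribed volume trace. Every
pipeline stage is therefore testable by parameter recovery; the
ground-truth contractility and compliance are the simulator inputs `emax`
and `1/emin`.

## Worked example

```r
library(cmrpv)

# simulate a 30 s occlusion study and write recording + contour files
paths <- cmd_simulate(outdir = "fixture", seed = 42)

# run the full pipeline
res <- cmd_run(run_config(paths$recording, paths$contours,
                          occlusion = "auto", outdir = "out"))
print(res$contractility)
print(res$compliance)
print(res$baseline)
```

Output from this exact run:

```
ESPVR fit: slope 0.509 mmHg/ml, intercept -0.99 mmHg, r2 0.9854 (n = 10)
  contractility = 0.509 mmHg/ml, V0 = 2.0 ml
EDPVR fit: slope 0.192 mmHg/ml, intercept -1.54 mmHg, r2 0.9693 (n = 10)
  compliance = 5.207 ml/mmHg, V0 = 8.0 ml
EDV 108.4 ml  ESV 67.7 ml  SV 40.6 ml  EF 37.5%  HR 77 bpm  CO 3.13 l/min
EDP 21.1  ESP 35.8  peak LVP 37.6 mmHg
```

The simulator's true values are contractility 0.6 mmHg/ml and compliance
5.0 ml/mmHg. A single replicate carries sampling error from the injected
measurement noise (pressure 1 mmHg, volume 2 ml on ten fitted points);
this seed lands 15% low on contractility and 4% high on compliance, and
the mean over 20 noise replicates recovers 0.598 mmHg/ml and
5.05 ml/mmHg (see `scripts/acceptance.R` below). `out/` receives the
per-beat table, the fiducial PV points, a JSON report, a run log, and a
PV-loop plot with the fitted ESPVR/EDPVR lines.

A thin command-line front-end with the same functionality is installed at
`inst/exec/cmrpv` (subcommands `run`, `simulate`, `validate-volume`).

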