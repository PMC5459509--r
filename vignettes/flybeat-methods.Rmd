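---
title: "Methods: optical heartbeat and action-potential analysis in flybeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical heartbeat and action-potential analysis in flybeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flybeat)
```

## The measurement problem

The adult *Drosophila* heart is a linear tube of myocardial cells that, in
the denervated semi-intact preparation, beats with an intrinsic myogenic
rhythm of roughly 1–3 Hz. Cardiac phenotyping in this system rests on two
recordings: high-speed movies of the beating tube (100–250 frames/s), from
which wall positions and beat timing are extracted, and sharp-electrode
intracellular recordings of myocardial action potentials (APs). flybeat
implements the full quantification chain for both, plus the TTL-based
alignment used when the two are recorded simultaneously, and the
cycle-threshold arithmetic used for companion expression assays.

The headline optical parameters are the systolic interval SI (one full
contraction/relaxation event), the diastolic interval DI (the relaxation
pause between events), the heart period HP = SI + DI, the arrhythmia index
AI = sd(HP)/median(HP) (sample standard deviation, n−1 denominator; the
normalization makes rhythm irregularity comparable across rates), the
diastolic and systolic diameters DD and SD, and fractional shortening
FS = (DD − SD)/DD. In young wildtype hearts SIs fall in roughly
0.2–0.28 s and DIs in 0.5–0.8 s, with DIs much more variable than SIs;
hERG/*seizure*-deficient hearts lengthen and broaden the DI distribution
(bradycardia and arrhythmia) and lose contractility, while KCNQ-deficient
hearts show mostly electrical (burst) phenotypes.

## The synthetic world

No real recordings ship with the package. Instead a generator
(`synth_spec()`, `make_beat_schedule()`, `render_*()`) produces movies,
diameter traces, voltage traces and synchronized pairs from an explicit
parameter set with exact ground truth, and every analysis stage is
validated as a closed loop against it.

Design choices worth stating:

* **Piecewise-linear beat waveform.** Each beat is a diastolic plateau at
  DD, a linear shortening ramp (SP) to SD, a flat isometric hold (ISO),
  and a linear lengthening ramp (LP) back to DD. Published traces show,
  but do not parameterize, the waveform; linear segments make every
  ground-truth quantity analytic (interval endpoints, phase durations,
  time-at-bottom, APDs), which is what lets tests assert sub-frame
  accuracy rather than vague similarity.
* **Phases fill the SI exactly.** Per beat, the nominal SP/ISO/LP are
  scaled so SP+ISO+LP equals the realized SI. An alternative — flat slack
  at the diastolic level inside the SI — was rejected: trace-wise, slack
  at DD is indistinguishable from diastole, so no segmentation algorithm
  could recover the scheduled SI, and the closed-loop tests would be
  meaningless.
* **Interval draws.** DI and SI are independent Gaussians per beat
  (means/sds set by preset), truncated below at two frame periods.
  Draw order is fixed (leading DI, then per beat SI, DI), so a spec plus
  its seed reproduces schedules bit-identically.
* **Presets are the stated world.** `wt_young` uses DI ~ N(0.65, 0.05) s,
  SI ~ N(0.25, 0.02) s, DD 80 µm, SD 60 µm (FS 0.25), rest −40 mV,
  amplitude 49 mV, and almost exclusively single-peak APs. `sei_like`
  lengthens and broadens DI (N(1.0, 0.35) s), narrows DD to 70 µm
  (FS ≈ 0.14), slows repolarization (160 ms) and adds EAD double peaks
  (30%) and short bursts (15%). `kcnq_like` is burst-dominated (80% of
  events, ~8 peaks/burst at 120 ms spacing) with long events. `load`
  doubles the isometric hold (0.03 → 0.06 s) relative to `wt_young`,
  emulating contraction against 20% Ficoll. Where the literature gives a
  range, the preset mean sits inside it; where it gives nothing (noise
  scale 1 µm / 1 mV, upstroke 4 ms, wall thickness 8 µm), values were
  chosen once as plausible for EM-CCD imaging at these magnifications and
  sharp-electrode recordings, and are not tuned thereafter.
* **EAD geometry.** The secondary depolarization is a narrow bump
  (half-width 3% of repolarization) placed at 50–60% of repolarization,
  rising 12–18% of the AP amplitude above the decay line. A wider or
  shallower bump is not geometrically a local maximum over the decay; this
  parameterization guarantees a true double peak with a few-mV prominence
  on both sides, at ~50–68% of the primary amplitude.
* **Burst mechanics are a coarse stand-in.** Fibrillatory wall movement in
  burst mode has no published quantitative waveform; mechanically the
  generator simply schedules beats at the burst rate. Green sync tests
  therefore establish clock alignment and 1:1 event matching, not
  realism of fibrillatory wall kinematics.
* **Scheduled electrical events never overlap**, and bursts are capped so
  the gap to the next event exceeds the 300 ms analysis grouping window —
  otherwise two scheduled events would legitimately merge into one
  analyzed event and "number of events" would stop being well-defined in
  the oracle.

What the generator does **not** emulate: optics (point-spread, ostia,
pericardial cells, conical-chamber geometry), baseline drift, movement
artifacts, electrode drift or penetration damage, temperature. A green
closed-loop test shows the algorithms are correct on clean, stationary
signals with Gaussian noise; it does not certify performance on degraded
real recordings.

## Wall tracking (M-mode)

`extract_mmode()` samples intensity bilinearly along a fixed transverse
line in every frame (0-based pixel centers; one column per frame).
`track_walls()` then, per column: smooths (5 px running mean), finds the
two deepest below-midlevel intensity runs (the wall bands), and localizes
each band's inner edge as the centroid of the intensity-gradient lobe on
the lumen side of the band center. For a symmetrically blurred step edge
the gradient centroid is exactly the edge position, which is why the
closed loop recovers diameters at ≈0.07 µm RMSE noise-free — an
interpolating quadratic around the gradient extremum was tried first and
left ~1 µm of plateau bias. All decision levels are relative to the
per-column intensity range, making tracking invariant to global intensity
scaling and vertical reflection. Columns failing detection (< 2 bands,
inverted edges) are linearly interpolated and flagged; more than 10%
failures aborts with a diagnostic. The exact wall-detection operator of
the interactive reference instrument is not published; this gradient
method is a documented substitute validated against the synthetic oracle
only.

## Beat segmentation

Detection works on the diameter trace relative to a rolling diastolic
baseline (upper 0.95 quantile over a 2 s window, evaluated on a 0.25 s
grid and interpolated — diastole occupies most of each cycle, so an upper
quantile tracks the plateau through slow drift). A contraction is armed by
a downward crossing of 90% of the local baseline, confirmed only if the
trace reaches 75% of the local beat depth (hysteresis against noise), and
closed by the upward re-crossing; a closed beat is committed only after
the trace re-arms near baseline, so noise dips on the rising limb extend
the current beat instead of double-counting it.

Crossing times alone are biased (a 90% threshold sits two-fifths of the
way down an FS-0.25 beat), so onset and relaxation end are refined:
the per-beat diastolic plateau is estimated as the trimmed mean of the
preceding inter-beat samples, a line is fit to the mid-portion (12–88% of
beat depth) of the descending/ascending limb, and the crossing of that
line with the plateau level is the refined time. On noise-free
piecewise-linear beats this is exact to ~1e-11 s; with 1 µm noise at
200 fps, ≥95% of recovered intervals fall within two frame periods of the
schedule. Partial beats touching the record edges are discarded. DD is
the per-beat pre-onset plateau mean and SD the per-beat minimum (lightly
smoothed); per-beat values are the default (whole-record alternatives are
a trivial summary away), and AI is reported absent — not zero — below
three beats.

## Contraction phases

`movement_trace()` gives |dd/dt| by central differences; the default adds
no further smoothing (the difference already spans two frame periods and
noise-free exactness tests depend on it), while noisy traces benefit from
`smooth_window = 5`, which is what the cohort-level pipeline uses. Within
each beat, supra-threshold speed episodes are found with a movable
threshold — by default 15% of the per-beat peak speed; a relative default
keeps behavior stable across noise levels and magnifications, and an
absolute µm/s override mirrors the instrument's movable bar. SP is the
first episode, LP the last, ISO the full sub-threshold span between them
(whether brief sub-threshold jitter inside that span should be excluded
is unspecified in the source methodology; the full span is the documented
choice here). Episode boundaries are measured at the interpolated
crossing of max(threshold, half the episode's peak speed): the half-peak
floor cancels the one-sample skirt that central differencing smears onto
each side of a speed plateau, so noise-free piecewise-linear beats parse
exactly (and identically to the brute-force crossing-scan oracle), while
the user's threshold still governs episode existence and sub-half-peak
durations. Raising the threshold can only shrink SP/LP and grow ISO.
Shortening velocity is (DD − SD)/SP with per-beat DD/SD.

## Action potentials

The resting potential is the median of samples in the baseline band
(below minimum + 25% of range; at least 1 s of baseline required). Peaks
are local maxima at least 10 mV above rest on a 2 ms-smoothed trace, with
a 10 ms minimum separation and a 3 mV prominence requirement — height
above rest alone would count every noise ripple on a slow repolarization
as a peak. Peaks within 300 ms group into one event; the 300 ms window is
a documented package default (burst statistics are published, the
grouping rule is not). Event onset/end are the interpolated crossings of
rest + 10% of event amplitude outside the outermost peaks, event duration
their difference — whether published single-AP "event duration" means
full return to baseline or a threshold crossing is ambiguous; the 10%
crossing is the documented choice. APD10/50/90 run from the onset (the
10% upstroke crossing) to the decaying-phase crossing of rest +
90%/50%/10% of amplitude; the start reference is configurable
(`ref = "peak"`) because only the repolarization endpoints are defined by
convention. Classification: one peak = single; two peaks = EAD double
when the second rises within 150 ms and stays below 90% of the first's
amplitude, otherwise a (two-full-amplitude-peak) burst; three or more =
burst. APDs are reported absent for multi-peak events. All features are
invariant to a constant voltage offset.

## Synchronization

The TTL channel is thresholded at half amplitude; exactly one contiguous
high run is required, and the half-open window [first rise, last fall) is
exact to one electrical sample on generator output. Optical frame j gets
electrical time t_on + j/fps; a mismatch between optical duration and
window length beyond two frames is an error. AP events are matched to
contraction onsets greedily by increasing |latency| within a 0.15 s
tolerance, each event used once — at fly heart rates events are well
separated and greedy matching equals optimal assignment in practice,
while remaining symmetric in which table is the query. Excitation–
contraction latency is reported descriptively (median), not modeled.

## Expression arithmetic

ΔCt = Ct(gene) − Ct(reference) per sample (replicates averaged per
sample first — biological-first averaging is the documented default when
the replicate structure is unstated), with lower ΔCt annotated as higher
relative expression. ΔΔCt subtracts the control-group mean ΔCt per gene,
so control ΔΔCt has mean zero by construction; fold change 2^(−ΔΔCt) is
emitted alongside raw ΔΔCt and labeled as the standard convention. The
reference defaults are `MCM2` for ΔCt (nanofluidic panel) and `actin` for
ΔΔCt, both configurable. Per-sample constant Ct offsets cancel exactly.
No amplification-efficiency correction is attempted.

## Numerical conventions and limits

Coordinates are 0-based pixel centers; time indices 0-based; intervals
half-open [start, end). Seeds: every renderer derives its stream from the
spec seed plus a fixed per-renderer offset, so a spec is a complete,
reproducible description of a recording. TIFF I/O is a minimal baseline
codec (8-bit grayscale, uncompressed, little-endian, one IFD per frame)
written for this package because no TIFF library is available in the
supported dependency set; it is validated by bit-exact round-trips and
was cross-checked against an independent Python reader during
development. 8-bit quantization adds ≤ 0.2% intensity error, which the
tracking loop absorbs (RMSE stays ≈0.09 µm).

Known limitations: beats shallower than ~10% of the local baseline are
invisible to the 90% threshold by construction; the frame-rate floor for
trustworthy phase parsing is 150 fps (200–250 fps is the norm for load
experiments); wall tracking assumes exactly two wall bands on the
sampling line (no automatic ROI selection, no motion registration); and
the generator's fibrillatory mechanics are schematic, as noted above.
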