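---
title: "Brain-mimetic coupled stimulation and its iEEG readouts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-mimetic coupled stimulation and its iEEG readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacstim)
```

pacstim synthesizes a phase-amplitude-coupled deep-brain-stimulation
waveform — biphasic current pulses fired at a Gaussian-dithered fast rate
whose amplitudes follow the phase of a slow sinusoid — together with the
analysis stack used to evaluate such stimulation on intracranial EEG:
complex Morlet wavelet scalograms, baseline z-scoring with
stimulation-epoch gating, Tort-style phase-amplitude-coupling (PAC)
comodulograms, an interictal delta-suppression dose-response biomarker,
and an afterdischarge-duration readout. A synthetic iEEG simulator with
known ground truth closes the loop so every stage is testable without
animal recordings. This vignette records the models, the parameters that
matter, and the design choices made where the design was genuinely open.

## The stimulus model

The therapeutic waveform couples two rhythms. A slow rhythm at
$f_L$ (default 1 Hz) contributes only its phase $\varphi_L(t) = 2\pi f_L t$;
a fast pulse train at mean rate $f_H$ (default 100 Hz) contributes the
pulses. Each pulse fired at time $t$ receives the amplitude

$$a(t) = A_0 \sin(\varphi_L(t)),$$

with $A_0$ the peak current (default 40 uA, a typical interictal
excitation threshold). Under the default `signed_sine` envelope the pulse
polarity flips on the negative half-cycle, so the train visibly swings
both polarities over each slow cycle; `rectified_sine`
($A_0(1+\sin\varphi)/2$) is offered for hardware that cannot invert
leads, and `constant` expresses the degenerate unmodulated case.

**Dither.** The instantaneous pulse rate is not fixed: before each
inter-pulse interval a rate $g_i \sim \mathcal N(f_H, \sigma^2)$ is
drawn and the interval set to $1/g_i$. The spread parameter is quoted in
Hz, so it is interpreted as the **standard deviation** (default 10 Hz),
not a variance; the raw parameter `dither_spread` is exposed, so a
variance reading can be configured as `sqrt(v)`. Draws below $f_H/2$ are
redrawn, keeping intervals within one octave of the mean — at the
default spread the rejected mass is about $3\times10^{-7}$, so the
truncation is a numerical safeguard, not a distributional change (the
truncated-normal SD is 10 Hz to five decimals). Whether an in vivo
implementation would truncate or redraw is unknowable from a published
description; redraw-on-violation was chosen because it preserves the
stated mean exactly in expectation. Because the distribution's stated
mean is a *frequency*, the draw is performed in the frequency domain and
inverted, rather than drawing the interval itself.

**Pulse placement.** Dithered trains place their first pulse after the
first drawn interval (there is a virtual pulse at $t=0$), generating on
the half-open window $[0, \mathrm{duration})$. Deterministic trains
(`lfs`, `hfs`, kindling) fire their first pulse at $t = 0$, giving the
intuitive count $\lfloor \mathrm{duration}\cdot f\rfloor$ — 100 pulses
for one second at 100 Hz, 120 for the 60 Hz / 2 s kindling train.
Consequently a zero-dither `depacer` train equals the `hfs` train
shifted by exactly one interval; the test suite asserts that alignment
sample-for-sample. Overlapping pulse blocks (possible only at extreme
parameter combinations) are an error, never silently truncated.

**Pulse shape.** Biphasic pulses are the simplest charge-balanced square
form: positive phase first, equal halves, no inter-phase gap, total
width 1 ms (an even number of samples is required so the two phases can
balance; every rendered waveform sums to zero exactly). The kindling
train uses monophasic 0.5-ms squares at 60 Hz for 2 s, with currents
outside the conventional 10–150 uA sweep range warned about rather than
rejected so dose-series scripts can sweep freely.

Waveforms are exported as plain text, one sample per line at 10 kHz,
with a `#`-prefixed header carrying every generation parameter and the
seed; export, re-import and re-export are byte-identical.

## The wavelet transform

Spectral analysis uses a complex Morlet mother wavelet

$$\Psi(t) = \frac{1}{\sqrt{\pi f_b}}\, e^{2\pi i f_c t}\, e^{-t^2/f_b},$$

with central frequency $f_c = 0.8125$ Hz and bandwidth parameter
$f_b = 5$, the values conventionally used for EEG with this wavelet
family. (Printed statements of this formula sometimes carry an $x$ where
$t$ is meant in the Gaussian; the formula is used literally in $t$, and
$f_b$ is treated as the dimensionless Gaussian width it is in the
formula.) An analysis frequency $f$ is reached at scale $a = f_c/f$.
Two numerical choices matter:

* **L1 scale normalization with analytic doubling.** The scaled kernel
  is $\psi_a(t) = \tfrac{2}{a}\Psi(t/a)$, so a pure tone of amplitude
  $A$ has $|W| \approx A$ at its own frequency *independent of
  frequency*. PAC compares amplitudes across frequencies; an
  energy-preserving (L2) normalization would tilt that comparison.
* **Edges.** Convolution uses reflection padding, and samples within
  3 Gaussian standard deviations ($3a\sqrt{f_b/2}$ seconds) of either
  edge are flagged as the cone of influence.

The default analysis grid is logarithmic at 8 voices per octave from
0.5 to 512 Hz; display grids are a presentation choice, not part of the
method.

**Baseline z-scoring.** Scalograms are standardized per frequency
against a pre-stimulation baseline:
$z(t,f) = (|W(t,f)| - \mu_f)/\sigma_f$ with $\mu_f,\sigma_f$ estimated
from unmasked baseline samples only. z-scoring is applied to the
coefficient magnitude $|W|$ by default; a `power` flag switches to
$|W|^2$. The two are monotone-equivalent for sign-of-change claims,
which is all the biomarker uses. Samples inside stimulation epochs
(plus a guard margin, default 1 s) are masked: they are excluded from
baseline statistics and propagate as `NA` in the z-map rather than being
zero-filled.

## Phase, amplitude, and the modulation index

Phase and amplitude are both read from the same Morlet scalogram (no
separate band-pass/Hilbert chain): $\phi(t, f_L)$ is the two-argument
arctangent of the complex coefficient — the printed shorthand
$\arctan(\mathrm{Im}/\mathrm{Re})$ resolved to `atan2` so quadrants are
unambiguous — and $A(t, f_H)$ is its modulus. Two phase conventions are
offered because two natural reference points exist: the default `"sine"`
convention reports the $\phi$ for which the band signal is
$A\sin(\phi)$, matching the envelope definition $A_0\sin(\varphi_L)$
(a sinusoid's maxima sit at $\pi/2$); `"cosine"` is the raw
analytic-signal angle with exact conjugation antisymmetry. The
modulation index is invariant to the choice.

Coupling strength is the normalized Kullback–Leibler distance of the
phase-binned amplitude distribution from uniform: phases are sorted into
18 bins of 20°, $P_j$ is the mean amplitude in bin $j$ normalized to sum
to one, and

$$\mathrm{MI} = \frac{\log n - H(P)}{\log n} \in [0, 1],$$

0 for amplitude flat over phase, 1 for all mass in one bin. Empty bins
(possible in short windows at low phase frequencies) contribute zero
mean amplitude, handled by $0\log 0 = 0$; windows are never dropped for
shape reasons, so output dimensions stay predictable.

Comodulograms scan phase frequencies over 1–32 Hz and amplitude
frequencies over 32–512 Hz, both logarithmic. The grid density is a
display choice; 4 voices per octave (21 × 17 points) is the default. The
sliding window is 4 s — at least 4 cycles at the 1 Hz phase floor — with
a default stride of 1 s (75% overlap). Whether published comodulograms
pool windows or display single windows is usually unstated; pacstim
outputs per-window matrices and provides `pool_comodulogram()` as an
explicit mean-across-windows reducer.

**Surrogate floor.** `surrogate_threshold()` recomputes MI on circularly
time-shifted amplitude series (shift ≥ 1 s) and returns the 95th
percentile. One caveat discovered while validating it: circular shifts
only destroy phase-amplitude alignment when the modulating phase
*drifts*. A strictly periodic modulator is realigned by any shift near a
multiple of its period, so the surrogate floor is meaningful for
physiological (quasi-periodic) rhythms and for the simulator's drifting
oscillators, but not for exactly sinusoidal test signals. The test suite
uses a drifting-phase modulator for this reason.

## The delta-suppression dose-response biomarker

Interictal probes apply the stimulus for 30 s at ascending amplitudes
(conventionally 10-uA steps). For each probe, the recording is z-scored
against its own pre-stimulation interval (≥ 30 s of unmasked data
required), the stimulation epoch is masked, and the summary is the mean
z over the delta band in the post interval. Choices, each configurable:

* **Delta band 1–4 Hz** — the standard EEG convention; published
  descriptions of "delta suppression" rarely bound the band explicitly.
* **Post interval: 60 s starting 1 s after stimulation offset** — the
  1 s guards against residual artifact; evaluation intervals are rarely
  printed, so this is a package choice.
* **Suppression criterion $z \le -1.96$** — per-animal thresholding
  rules are usually qualitative ("sufficient to induce changes"); a
  fixed z-criterion keeps the dose series automatic, with the Wilcoxon
  group test retained for cohort-level claims. Note the statistical
  subtlety: the summary is a *mean* of per-sample z values, so under no
  change its spread is far smaller than 1 and $-1.96$ is a conservative
  criterion. For it to fire at all, the band must contain
  amplitude-stable rhythmic activity: if delta were Gaussian band noise,
  $|W|$ would be Rayleigh-distributed with $\sigma \approx 0.52\mu$, and
  even *complete* suppression would only reach
  $z = -\mu/\sigma \approx -1.9$. The criterion therefore encodes a
  physiological assumption (high-amplitude rhythmic slow activity with a
  steady envelope, as in kindled hippocampus) that the simulator
  reproduces deliberately — see below.

The detected threshold is the smallest tested amplitude whose summary
falls at or below the criterion; detection contains no randomness.
`paired_group_test()` supplies the cohort statistic: a two-sided
Wilcoxon signed-rank with the exact null distribution for n ≤ 25
(computed by dynamic programming over doubled midranks, so tied
|differences| are handled exactly; `stats::wilcox.test` refuses exact
p-values under ties) and the tie-corrected normal approximation beyond,
reporting group means ± SEM alongside, as is conventional in this
literature.

**Afterdischarge duration.** `evoked_duration()` is deliberately simple
scaffolding, not a clinical seizure detector: line length (sum of
absolute first differences) in 1-s windows, thresholded at $k = 3$ times
the pre-stimulus baseline mean, with runs allowed to bridge one
sub-threshold window (brief mid-discharge attenuations) and an onset
tolerance of 10 s after the stimulus. Line length is baseline-relative,
so the result is invariant to overall gain. Any monotone afterdischarge
detector would serve; this one was chosen for transparency.

## The synthetic iEEG simulator

The simulator emulates the signal features the analyses are designed to
detect, with every feature config-exposed and the ground truth recorded:

| Component | Default | Why |
|---|---|---|
| Background | 1/f pink noise, 50 uV RMS | generic broadband LFP floor |
| Delta rhythm | 4 amplitude-stable oscillators at 1.25/1.81/2.63/3.81 Hz, 80 uV RMS, 8% slow amplitude drift | see below |
| Interictal spikes | 6/min, 300 uV biphasic sharp waves | kindled interictal activity |
| SLE | 37 s: 10% low-voltage fast onset, spike-wave body sweeping 8→3 Hz with fast (30 Hz) overlay, final 25% delta–HFO PAC at (1, 100) Hz, depth 0.9 | the three classic electrographic phases; termination carries the coupling the stimulus mimics |
| Dose response | threshold 40 uA, delta gain 0.5, sigmoid steepness 1 uA, midpoint 5 uA below threshold | the planted effect the biomarker must recover |
| Stimulation epochs | saturating square artifact, 20x background | forces the masking path to be exercised |

Two defaults deserve their rationale spelled out:

* **The delta rhythm is an oscillator bank, not filtered noise.** As
  noted above, Gaussian band noise cannot produce mean-z suppression
  below about $-1$ even at full suppression, because its wavelet
  magnitude is Rayleigh-distributed. Kindled hippocampal slow activity
  is rhythmic with a comparatively steady envelope; modelling it as
  amplitude-stable oscillators (spaced more than a Morlet bandwidth
  apart so their magnitudes do not beat against each other) gives
  per-frequency baselines with small variance, which is exactly the
  regime in which a z-based suppression criterion is meaningful. The
  50% suppression planted at threshold then lands near $z \approx -2.3$.
* **The dose sigmoid's midpoint sits half a 10-uA step below the
  planted threshold** (steepness 1 uA), so the threshold amplitude
  itself expresses essentially the full planted gain and the step below
  essentially none — the planted threshold is well-defined to within
  one step, which is the resolution the ascending protocol can resolve
  anyway.

The evoked-trial generator lays out a quiet lead-in, an optional
therapeutic stimulation epoch ending 6 s after the evoked-stimulus
marker, and either a full SLE (control) or a quiescent, spike-reduced
response (treated). The therapeutic epoch defaults to 60 s in analyses
and tests — standing in for the full 15-min protocol, which remains one
parameter away (`pre_stim_s = 900`) — because nothing in the analysis
chain depends on the epoch's absolute length beyond its masking.

Two channels ("hippocampus", "thalamus") are emitted, differing only in
gain; relative channel morphology is not something the package pretends
to model.

**What the simulator does not capture.** No biophysics: no conductance
dynamics, no network topology, no spatial field model, no electrode
physics beyond a saturation artifact. The SLE morphology is schematic.
Passing round-trip tests therefore demonstrates that the *analysis
machinery* is correct and calibrated — it says nothing about whether a
real brain responds to the stimulus, which only the in vivo experiment
can show.

## Problem sizes and numerics

Simulated validation runs use scaled sample rates — 250 Hz for
delta-band dose-response work, 500 Hz for line-length durations, 1250 Hz
for comodulograms reaching 512 Hz — chosen as the smallest rates that
keep every analysis frequency comfortably below Nyquist; the synthesis
side always runs at the full 10 kHz of the stimulator format. Dither
statistics are validated on ~12,000 pulses (120 s trains), dose-response
recovery on 20 seeded sessions of six amplitudes each, and the
signed-rank implementation against exhaustive enumeration for n ≤ 10
plus a 2,000-replicate null calibration compared with the exact
attainable size of the discrete test.

Floating-point conventions: times in seconds, intervals half-open
$[start, end)$, sample indices 0-based in file formats; waveform text
files print the shortest decimal that reparses exactly, making
export/import round trips bit-exact. MI comparisons between the
windowed implementation and a naive recompute agree to $10^{-12}$
absolutely (relative comparisons are meaningless at MI values near the
numerical floor).

## Known limitations

* The CWT is computed per frequency by FFT convolution; memory scales
  with signal length x grid size (complex doubles), so hour-long 10 kHz
  recordings should be decimated before analysis (all analysis
  frequencies live below 512 Hz).
* The surrogate floor assumes a drifting modulator (above).
* `evoked_duration()` is a synthetic-validation tool; scoring real
  seizures requires video-EEG review.
* The z-criterion biomarker presumes rhythmic baseline delta; on
  recordings whose delta band is noise-like it will (correctly, but
  perhaps surprisingly) almost never fire, and the criterion should be
  recalibrated against the observed null spread of the summary.
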