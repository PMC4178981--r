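---
title: "Digital multigate PW Doppler: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital multigate PW Doppler: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement and its model

Pulsed-wave (PW) Doppler fires short ultrasound bursts at a pulse repetition
frequency (PRF) and records one radio-frequency (RF) echo line per pulse.
Two time axes coexist: *fast time*, the sample index within one line, which
maps to depth through the pulse-echo range equation $z = c\,i/(2 f_s)$; and
*slow time*, the pulse index, which samples motion at the PRF. A scatterer
at depth $z(t)$ delays its echo by $2 z(t)/c$; at a fixed depth sample the
echo phase therefore rotates at the Doppler rate

$$ f_d = \frac{2 v \cos\theta\, f_0}{c}, $$

with $v$ the speed along the motion axis, $\theta$ the beam-to-motion
(Doppler) angle, $f_0$ the carrier and $c$ the sound speed. `pwdoppler`
implements the fully digital version of this measurement:

1. **Band-pass filtering** of each RF line (zero-phase FIR, windowed-sinc
   design with a Hamming design window, default band
   $f_0(1 \pm \mathrm{bw})$, transition width $\le 0.1 f_0$). Zero-phase
   (forward–backward) application keeps gate depth indices free of filter
   delay.
2. **Hilbert-transform quadrature demodulation**: the discrete analytic
   signal of each line via the one-sided-spectrum FFT construction
   ($h[0]=1$, $h[n/2]=1$ for even $n$, $h[k]=2$ on positive bins, $0$ on
   negative bins). The real part is the filtered RF $A(t)\cos\theta(t)$;
   the imaginary part is its Hilbert transform $A(t)\sin\theta(t)$, valid
   in the Bedrosian regime (envelope spectrum below the carrier), which
   holds here because the pulse's fractional bandwidth is below unity.
   No analog mixer is involved; this is the point of the digital chain.
3. **Multigate extraction**: each interrogation gate reduces the analytic
   samples in a depth window to one complex value per pulse (complex mean),
   giving a slow-time Doppler signal per gate at rate PRF.
4. **Optional clutter filtering** along slow time (zero-phase FIR
   high-pass), off by default because wall-motion measurements need the
   slow components it removes.
5. **Sonogram generation**: Hamming-windowed short-time complex FFT
   (symmetric window $w_i = 0.54 - 0.46\cos(2\pi i/(L-1))$), zero-padded,
   zero-centred frequency axis, envelope (magnitude) in dB relative to the
   gate's maximum, clipped at the display dynamic range (default 50 dB).
   Negative frequencies encode motion away from the transducer.
6. **Velocity estimation and integration**: a Doppler frequency per gate
   and time slot, angle-corrected through $v = f_d c/(2 f_0 \cos\theta)$,
   assembled into a depth-by-time velocity profile; wall-velocity traces
   integrate to displacement by cumulative trapezoids.

The package-wide sign convention is *positive velocity toward the
transducer*; flow away from the probe appears at negative frequencies and
negative velocities.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `f0` | 35e6 | Hz | carrier; sets Doppler scale factor and depth resolution |
| `fs` | 250e6 | Hz | fast-time rate; depth quantum $c/(2f_s) \approx 3.1\,\mu$m |
| `prf` | — | Hz | slow-time rate; Nyquist velocity $\mathrm{prf}\,c/(4 f_0 \cos\theta)$ |
| `doppler_angle` | — | deg | $1/\cos\theta$ angle correction; must be $< 90$ |
| `tx_cycles`, `fractional_bandwidth` | 7, 0.55 | —, — | pulse length and $-6$ dB spectral width |
| `window_length` | 128 | pulses | STFT window; frequency resolution $\mathrm{prf}/L$ |
| `hop` | `window_length/4` | pulses | time resolution of the profile |
| `nfft` | `4*window_length` | bins | zero-padding; peak localisation $\mathrm{prf}/\mathrm{nfft}$ |
| `dynamic_range_db` | 50 | dB | sonogram clipping floor |
| `gate_length` | 1 | samples | depth window per gate (see below) |
| `floor_db` | 12 | dB | envelope-edge threshold below the column max |
| `noise_margin_db` | 14 | dB | below-noise mask margin (see below) |

**Gate length.** The default gate takes the single analytic sample at the
gate index (the digital analogue of a sample-and-hold gate). Averaging the
analytic signal at RF over a longer depth window rotates the carrier across
the window — at $f_0/f_s = 0.14$ the carrier period is ~7 samples, so a
9-sample mean already cancels most of the signal. Longer gates only make
sense after mixing to baseband, which this chain deliberately avoids;
`gate_length` is therefore kept at 1 unless the caller knows better.

# The maximum-frequency estimator and its broadening correction

The profile estimator reads the *envelope edge* of each sonogram column:
the outermost frequency of the above-threshold region containing the peak,
threshold `max − floor_db`. This is the natural reading of "peak velocity
from the maximal waveform envelope", but the raw edge is biased outward by
the intrinsic spectral broadening of the measurement itself:

* the analysis-window mainlobe (the $-12$ dB half-width of a 128-pulse
  Hamming window is $1.24\,\mathrm{prf}/128$);
* *transit-time broadening*: a scatterer crossing the pulse's axial
  resolution cell $\sigma_z = c\,\sigma_t/2$ at axial speed $v$ produces a
  Gaussian magnitude spectrum of width $\sigma_f = v/(2\pi\sigma_z)$.
  Because $f_d$ and $\sigma_f$ are both proportional to $v$, the *relative*
  broadening is a constant of the pulse: $\sigma_f = \beta |f_d|$ with
  $\beta = \mathrm{bw}/(2\sqrt{2\ln 10^{0.3}}) \approx 0.425\,\mathrm{bw}$
  ($0.234$ at 55% bandwidth). At a 12 dB threshold the raw edge then
  overreads speed by roughly $1.66\beta \approx 39\%$, uniformly.

Both kernels are known from the acquisition configuration, so the default
estimator inverts them: modelling the expected envelope as a Gaussian of
width $\sigma^2 = (\beta f_d)^2 + \sigma_w^2$ (window mainlobe and the
smoothing width below folded into $\sigma_w$), the measured edge
$|f_e| = |f_d| + \gamma\sigma$ with $\gamma = \sqrt{2\ln 10^{\mathrm{floor}/20}}$
is solved for $|f_d|$ in closed form. On a pure tone the correction reduces
to subtracting the window half-width; on a scatterer stream it removes the
multiplicative transit bias. `correct_broadening = FALSE` returns the raw
edge.

**Speckle and smoothing.** A single STFT column of a many-scatterer signal
has fully developed speckle (Rayleigh magnitudes, ~100% contrast), so a
bin-wise threshold reading jitters by hundreds of Hz. Before edge
detection the column is therefore smoothed in the linear domain by a
moving average one window-mainlobe wide ($4\,\mathrm{nfft}/L$ bins), and
the threshold crossing is linearly interpolated between bins; the
rectangular smoothing kernel's width enters the correction as
$\sigma_{\mathrm{rect}} = w/\sqrt{12}$. Without smoothing (standalone
`estimate_doppler` calls, `smooth_bins = 0`) the raw bin is reported.

**Below-noise masking.** A column is masked when its maximum is within
`noise_margin_db` of its median. The statistic is scale-free (per-gate dB
normalisation cancels), which is why a median-proximity rule is used at
all; the margin itself must clear the Rayleigh order statistics of a
noise-only column, whose maximum over ~128 independent bins sits 8.5–10 dB
above the median. The default margin of 14 dB masks pure noise with high
probability while coherent signals, which enjoy ~20 dB of STFT processing
gain, clear it easily. (A margin of a few dB would mask nothing, ever.)

**Peak mode.** For narrowband targets — a single reflector, wall echoes —
`mode = "peak"` reads the maximum-magnitude bin (ties resolved toward the
lower $|f|$, the conservative velocity). The spectrum of such targets is
symmetric about $f_d$, so the mode is unbiased without any correction.

# The synthetic RF generator

The simulator produces the RF an ideal single-element system would record
from point scatterers on the beam line, with three motion models mirroring
the validation experiments of high-frequency Doppler platforms:

* **Translating reflector** (`motion_translation`): one strong scatterer
  advancing at $v\cos\theta$ per pulse. The study condition is 20 mm/s at
  a 75° angle, 3 kHz PRF, 35 MHz / 55% bandwidth / 7-cycle pulse, sampled
  at 250 MSPS — the reflector crosses the gate's resolution cell
  mid-ensemble and the chain must read back 20 mm/s after angle
  correction.
* **Parabolic vessel flow** (`motion_parabolic_flow`): scatterers fill a
  4.5 mm lumen, each tagged with a radial coordinate $r$ mapped to its
  depth offset from the vessel centre, moving at the Poiseuille speed
  $v(r) = v_{\max}(1 - (r/R)^2)$ projected by $\cos\theta$. Each
  scatterer is refreshed periodically within a 0.3 mm window around its
  home depth (reflectivity redrawn per cycle). This *local refresh*
  deserves a note: letting scatterers drift freely (or wrap across the
  whole lumen) decorrelates depth from radius within a fraction of a
  second, flattening exactly the depth–velocity profile the multigate
  method exists to measure. In reality the depth–velocity correlation is
  maintained by fresh scatterers continuously entering the beam; the
  local refresh emulates that finite beam transit while keeping slow-time
  statistics stationary. The wrap window is larger than the gate's reach
  (pulse extent plus gate window), so refresh events are invisible to the
  gate at the window centre.
* **Oscillating walls** (`motion_sinusoidal_wall`): two strong specular
  reflectors in antiphase (lumen pulsation) — anterior toward the
  transducer while posterior moves away. The study condition is a 50 µm,
  2 Hz oscillation at 1 kHz PRF, measured along the beam (0° angle).

Amplitudes are arbitrary linear units (reflectivities standard normal for
flow, 1 for specular targets); white Gaussian noise is added in fast time,
independent across pulses, at a stated level relative to the noiseless
ensemble's RMS. Defaults chosen once as realistic study conditions:
scatterer density 30/mm (the physical phantom's backscatter concentration
is not a constraint here; 30/mm gives several scatterers per resolution
cell, enough for developed speckle), noise −30 dB for reflector and flow
runs, −50 dB for wall runs (specular interfaces dominate thermal noise by
far), $c = 1540$ m/s throughout (the standard soft-tissue value; every
velocity in the chain is self-consistent for any fixed $c$).

What the generator does **not** model: diffraction and beam geometry
(the Doppler angle enters only as $\cos\theta$; the lumen extent along the
beam equals the diameter), attenuation, nonlinear propagation, speckle
decorrelation from lateral motion, and transducer impulse-response detail
beyond a single Gaussian envelope. Passing tests therefore demonstrate the
*processing chain's* correctness against known kinematics — not robustness
to beam physics or tissue inhomogeneity.

# Study-scale choices

The packaged end-to-end checks run at these problem sizes, picked to give
stable statistics with comfortable desk-scale runtimes:

* reflector: 1024 pulses × 3200 fast-time samples; single gate at the
  trajectory midpoint (the reflector travels 1.77 mm during the ensemble,
  so gating at the start depth would truncate the transit at the first
  STFT window);
* flow: 1024 pulses × 3500 samples, 135 scatterers, 25 gates every
  0.25 mm spanning 4–10 mm, clutter high-pass at 200 Hz (0.02 PRF);
* walls: 1280 pulses (2.5 oscillation cycles) × 2432 samples, two gates.
  The wall run uses a 64-pulse window (hop 16, nfft 1024): the wall's
  frequency modulation sweeps through zero twice per cycle, and windows
  long relative to the 0.5 s period would park the STFT peak at the sweep
  turning points (stationary phase), inflating the integrated displacement.
  64 ms windows keep that bias under ~5% while 0.98 Hz bins keep peak
  quantisation small relative to the 28 Hz peak Doppler shift.

# Numerical choices and degenerate inputs

* Analytic signal at native line length (no padding): keeps the
  sample-to-depth map exact; the FFT construction makes the one-sided
  spectrum and real-part identity exact to machine precision.
* Zero-phase filtering by FFT convolution with the filter's
  autocorrelation; edges see implicit zero padding, so the first/last
  ~filter-length samples are attenuated — tests measure on interior
  regions, and slow-time ensembles are long relative to the 129-tap
  clutter filter.
* Even-length FFT frequency axes drop the single ambiguous −Nyquist bin so
  the sonogram axis is exactly symmetric about zero.
* All-zero gate signals produce a uniform sonogram floor with a warning
  rather than NaNs from `log(0)`; their columns are below-noise by
  construction.
* Peak ties resolve toward the lower $|f|$; an envelope edge inside the
  window's own width of zero corrects to exactly 0, never negative speed.
* Aliasing (axial Doppler beyond PRF/2) warns at simulation time and
  wraps in the spectrum, as it does physically; estimates are bounded by
  the Nyquist velocity by construction.
* Container payloads are float32 (matching 12-bit ADC provenance); all
  internal computation is double.

# Known limitations

* The broadening correction assumes the Gaussian transit model; for
  motions that do not cross the resolution cell (bounded oscillation of a
  wall) it does not apply — use `peak` mode there, as the packaged wall
  analysis does.
* The envelope-edge estimator needs the signal maximum well above the
  noise median (in practice ~20 dB); between 14 and ~18 dB a column is
  unmasked but its edge reading is noisy.
* `max_envelope` reads the *largest* in-gate velocity; with very long
  gates spanning a strong velocity gradient it reports the fast edge of
  the gate, not its centre.
* No spectral-broadening correction for geometric (aperture) broadening,
  no mean-frequency estimator, no adaptive clutter filtering — all out of
  scope for this chain.
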