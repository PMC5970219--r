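---
title: "Modelling the developmental divergence of ON and OFF receptive fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the developmental divergence of ON and OFF receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onoffrf)
```

## The scientific question

Neurons in primary auditory cortex respond to both the onset and the offset
of sounds, through separate populations of ON and OFF synapses with their
own frequency tuning. In young animals the ON and OFF receptive fields (RFs)
of a neuron largely coincide; in adults they are segregated but adjacently
aligned in frequency. `onoffrf` implements a rate-based feedforward model in
which this divergence emerges from ordinary Hebbian plasticity driven by the
natural alternation of sound onsets and offsets, together with the analysis
pipeline that measures its two signature predictions:

1. the distribution of absolute ON/OFF characteristic-frequency (CF)
   differences widens progressively between hearing onset, a young time
   point, and an adult time point, and
2. in the adult network, the signed ON/OFF CF difference predicts direction
   selectivity for frequency-modulated (FM) sweeps, with and without
   synaptic inhibition.

The package also contains the corresponding *in vivo* spike-train analysis
procedures (FRA smoothing, iso-response edges, CF/bandwidth/overlap, DSI and
its regression onto functional unit properties) and a synthetic
spiking-unit generator so that every empirical procedure is testable by
parameter recovery.

## The neuron and its inputs

One model cell receives 40 inputs over `N = 10` tonotopic channels:
excitatory and inhibitory ON inputs and excitatory and inhibitory OFF
inputs. The membrane potential is the weighted sum

$$u = \sum_{i=1}^{N} w_i^{ON,e} x_i^{ON,e} + w_i^{OFF,e} x_i^{OFF,e}
      + w_i^{ON,i} x_i^{ON,i} + w_i^{OFF,i} x_i^{OFF,i},$$

and the output rate is threshold-linear, $y = \max(u - \theta, 0)$ with
$\theta = 2.5$. Inputs inherit a Gaussian tuning over the stimulus channels,
$x_i = \sum_j T_{ij} s_j$ with $T_{ij} = e^{-d(i,j)^2 / (2\sigma)}$,
$\sigma = 1.5$, where $d$ is the circular index distance (channel 1 and
channel 10 are neighbours). The `tuning_denominator` option switches to the
conventional $2\sigma^2$ form; the default keeps $2\sigma$, and the two give
very similar tuning widths at $\sigma = 1.5$.

Excitatory and inhibitory inputs of a class always receive the same drive.
One time step is interpreted as 1 ms, so the input decay constant
$\tau = 10$ steps matches the time course of sensory-evoked EPSPs.

## Plasticity

Excitatory synapses follow a Hebbian rule with multiplicative synaptic
noise, $\Delta w^e_i = \alpha^e x^e_i y + \eta_i w^e_i$, with
$\alpha^e = 10^{-4}$ and $\eta_i$ drawn per synapse and per step from
$U(-0.0025, 0.0025)$. Because Hebbian growth is unstable, weights are
clipped to $[0, 1]$ and each class (ON and OFF separately) is
renormalised multiplicatively to a fixed L1 norm of 2 after every step.
Inhibitory synapses follow a rate-based co-tuning rule,
$\Delta m_j = \alpha^i x_j (y - \rho)$ on the weight magnitudes
($w = -m$), with $\alpha^i = 10^{-5}$ and target rate $\rho = 0.01$; the
inhibitory synapses jointly undergo an L1 normalisation of 1 (0.5 per
class).

Three normalisation details are deliberate design choices:

* **L1 targets.** The ON and OFF excitatory classes are normalised
  separately (L1 = 2 each); a joint normalisation would allow one class
  to silence the other, making the ON/OFF comparison ill-posed, and a
  smaller excitatory scale leaves the sweep drive (capped at 2 per input,
  threshold 2.5) mathematically unable to reach threshold, so direction
  selectivity could not exist. The inhibitory target is applied jointly
  (0.5 per class), so evoked excitation dominates co-tuned inhibition
  and tone-evoked firing persists in the adult network.
* **Inhibitory L1 as a cap.** Inhibitory weights start at zero. Rescaling
  a nonzero class *exactly* to its target would make inhibition jump to
  full strength at the first spike, which freezes learning immediately;
  instead the target acts as a ceiling (`inhib_norm = "cap"`), so
  co-tuned inhibition grows gradually under the rate-based rule, as it
  would with a slow inhibitory learning rate. The exact variant is kept
  as an option.
* **Sign convention of the inhibitory rule.** Applied to magnitudes
  (default), the rule strengthens inhibition when the cell fires above
  target, producing excitatory/inhibitory co-tuning. Applied literally to
  the negative weights (`inhib_rule = "literal"`), inhibition withdraws
  from driving channels and accumulates in sidebands. The co-tuning form
  is the behaviour attributed to this rule in the literature and is the
  default.

An alternative homeostatic control, multiplicative synaptic scaling, can
replace Hebbian learning entirely (`condition = "scaling_only"`): all
excitatory weights are scaled by $1 \mp 10^{-5}$ according to whether the
output exceeds or falls short of its running average. Because scaling
replaces the whole Hebbian framework, the clip/renormalisation step and
the — likewise Hebbian — inhibitory rule are inactive, and the control
runs on the excitatory circuit alone; scaling then preserves excitatory
weight ratios exactly, so receptive-field *shape* cannot change, which is
the point of the control.

## Stimulus ensembles

**Before hearing onset** each channel carries independent uniform noise on
$[-0.5, 0.5]$, low-pass filtered with time constant 5 steps, reduced by
$\theta_x = 0.1$, rectified, and rescaled to a temporal mean of 1. ON and
OFF populations share the same trace per channel — synchronised
spontaneous activity — which is what makes ON and OFF RFs identical at
hearing onset. Channels are mutually independent; without that
independence no channel selectivity could develop.

**During sound exposure** a two-state process switches sounds on and off:
in the single-channel condition one global sound alternates between
silence and a uniformly drawn channel ($p_{ON} = p_{OFF} = 1/50$); in the
overlapping condition every channel switches independently
($p_{OFF} = 1/500$). Each switch-on event adds a unit pulse to the ON
trace of its channel and each switch-off to the OFF trace; pulses decay by
$e^{-1/\tau}$ per step, are tuned through $T$, and jointly rescaled
against the ceiling of 40. In the independent-channels condition the ON
inputs are pulsed by the onsets of one sequence and the OFF inputs by the
offsets of a second, independent sequence, removing the temporal
alternation of onsets and offsets while preserving their statistics.

**How the ceiling is applied** matters for the model's operating point.
The default (`input_rescale = "total_joint"`) caps the maximal momentary
population input — the sum over all twenty tuned ON and OFF input
channels — at 40, which puts single evoked pulses at roughly 4–6 units
and a matched tone just above threshold: tone-evoked firing is then
frequency selective with and without inhibition, plasticity is gradual
(divergence develops over the full 100,000 steps rather than saturating
immediately), and receptive fields stay compact in the excitation-only
condition. Capping each individual input at 40 instead (`"per_input"`)
makes every tone fire the cell strongly regardless of frequency, so
receptive fields flatten and divergence saturates within a few hundred
steps; that variant is retained for comparison, as is the per-class form
(`"total"`).

**Probes.** FRAs are measured with plasticity frozen: sustained tones at 8
intensities from 19.5 to 65 in every channel, ON responses averaged over
30 steps from the onset pulse and OFF responses over 30 steps from the
offset pulse (the probe tone lasts 100 steps; both window lengths are
package choices, roughly $3\tau$). FM sweeps last 3000 steps, with the
tone dwelling 50 steps per channel before moving one channel up or down
(circularly); when the tone leaves a band, that band's OFF pulse coincides
with the next band's ON pulse, so offset- and onset-evoked inputs of
adjacent channels summate. This coincidence is the mechanism of direction
selectivity: a cell whose ON CF sits one channel above its OFF CF receives
a simultaneous full-strength OFF + ON volley on UP sweeps but only partial
overlap on DOWN sweeps. Sweep inputs are rescaled against a per-input
ceiling of 2, which puts the best-aligned transitions just above
threshold.

## Measuring the model

* **CF** is the response-weighted centre of mass of an FRA surface. The
  channel axis is circular, so the surface is recentred on its peak before
  the plain centre of mass is taken (`fra_cf()`); a surface wrapping the
  seam between channels 10 and 1 would otherwise produce a meaningless
  mid-ring CF. Index differences convert to octaves at 0.5 oct per
  channel, signed along the shorter circular arc.
* **Sweep selectivity** is $(r_{UP} - r_{DOWN}) / (r_{UP} + r_{DOWN})$
  from the mean rates over the two sweeps; cells silent in both directions
  are flagged undefined.
* **The CF-difference/selectivity correlation** follows the published axis
  convention — positive differences mean the OFF CF sits above the ON CF —
  so the mechanism above yields a negative correlation. Mirroring the
  *in vivo* analysis, which included only units with clear V-shaped ON and
  OFF receptive fields, cells enter the correlation only if both FRAs are
  well formed (at least 60% of response mass within one octave of the
  peak, `fra_well_formed()`), their CFs are defined, and their sweep
  response is measurable; excluded cells are counted. Multi-peaked
  surfaces fail the screen because a centre of mass between two peaks is
  not a characteristic frequency.
* **Population divergence** compares the absolute CF differences of all
  cells between two snapshots (means plus a two-sample
  Kolmogorov–Smirnov test).

## The empirical (in vivo style) pipeline

Spike-count FRAs on the 25-frequency (7–56 kHz, 0.125 oct) by 8-level
(10–80 dB) grid are smoothed with a 3×3 pyramidal kernel (edge-renormalised),
and FRA edges are taken at a 30% increase over the pre-stimulus baseline
rate (inclusive; with a zero baseline the threshold falls back to 30% of
the surface maximum). The analysis keeps the connected component containing
the peak (`fra_core()`), an automated stand-in for the manual rejection of
isolated supra-threshold noise islands. CF is the response-weighted
geometric-mean frequency of defined cells at the lowest defined level; BF
is the maximal cell (ties towards low level, then low frequency); bandwidth
is the octave span of the defined region 30 dB above threshold (undefined
if that row is off the grid). DSI is $(r_1 - r_2)/(r_1 + r_2)$ with $r_1$
the mean UP-sweep count, and units are direction selective when the
absolute mean DSI at 2.2 and 4.4 oct/s exceeds 0.05 (strictly).

The DSI regression z-scores ten functional properties and fits DSI at the
lowest sweep speed by least squares. The proportional reduction of error
of a predictor drops its term *while keeping the full-model coefficients*
(the refit variant is available), and performance is reported as adjusted
R².

## The synthetic-recordings generator

`synth_unit()` plants V-shaped ON and OFF mean-rate fields (responsive
where the level exceeds the local threshold, which rises away from the CF
at a slope set so the field is `bw` octaves wide 30 dB above threshold),
adds spontaneous activity, and draws Poisson counts per repeat; sweep
counts are constructed so the planted low-speed DSI equals
`dsi_slope * (off_cf - on_cf)` octaves (clamped to $[-1, 1]$), constant up
to 17.5 oct/s and decaying linearly to zero at 35 oct/s — direction
selectivity at slow speeds only. Default population profiles: adult-like
units have CF offsets up to 0.5 oct with mode 0.25 and `dsi_slope = -1`
per octave; young-like units have offsets within ±0.125 oct and no
coupling. Peak rates of 80–150 spikes/s and spontaneous rates of 6–15
spikes/s are typical of cortical recordings; at very low spontaneous rates
the 30%-above-baseline edge criterion degenerates (the threshold falls
within counting noise), so the spontaneous range is chosen where the
printed criterion is discriminative. Ten repeats per tone mirror standard
recording sessions.

What passing parameter-recovery tests shows — and what it does not: the
generator produces independent Poisson counts around smooth planted
fields. Real recordings have correlated trial-to-trial variability,
bursting, non-stationarity, and curated unit selection; recovery results
here validate the analysis code, not its behaviour on any particular
recording.

## Numerical and reproducibility choices

* All randomness flows through R's RNG; every driver takes explicit seeds,
  and population seeds are split deterministically from a master seed
  (`split_seeds()`), so populations are reproducible and independent of
  execution order.
* The compiled simulation core draws its synaptic noise from the same RNG
  stream in a documented order (ON class, then OFF class, per step), so a
  plain-R scalar loop reproduces trajectories bit for bit; the test suite
  asserts agreement to 1e-12.
* Constraints are applied every step. Update order: voltage and rate,
  excitatory update, inhibitory update, constraints.
* Degenerate inputs: an all-zero excitatory class makes the L1 constraint
  unsatisfiable and raises an error; an empty event train yields all-zero
  traces with a warning; an all-zero FRA has no CF and the cell is
  excluded (and counted) from population statistics; exact half-ring CF
  differences resolve positive.

## Problem sizes

The package's reference analyses use 100-cell populations with 100,000
pre-hearing plus 100,000 sound-exposure steps per cell, probed at hearing
onset, the young time point (t = 1500) and the adult time point
(t = 100,000) — the full published scale. A single cell takes well under a
second in the compiled core; a full population with probing takes about
half a minute on one CPU. Parameter-recovery calibrations for the
regression use 200 replicates of 30-unit synthetic populations.

## Known limitations

* The model is a single-cell feedforward caricature: no recurrence, no
  conductances, no spiking, one effective sweep speed (one channel per 50
  steps). Velocity-resolved sweep tuning is outside its scope.
* Several normalisation conventions are stated loosely in the source
  description of the model; the package fixes them (per-class L1 targets,
  population-total input ceiling, capped inhibitory normalisation) and
  exposes the alternatives as options. The qualitative results — gradual
  ON/OFF divergence, adjacency under alternation, its loss under
  independent sequences, no divergence under scaling, and the negative
  CF-difference/selectivity correlation that strengthens without
  inhibition — are the behaviours these choices were required to
  reproduce jointly.
* The centre-of-mass CF of a strongly multi-peaked FRA is not meaningful;
  such cells are screened out of the correlation analysis exactly as
  non-V-shaped units were excluded in vivo.
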