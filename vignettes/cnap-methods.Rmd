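---
title: "Filter-based CNAP simulation: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-based CNAP simulation: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnapsim)
```

## The model

A compound nerve action potential (CNAP) recorded from a peripheral nerve is
the sum of the single fiber action potentials (SFAPs) of every active fiber.
Each SFAP, in turn, is a weighted sum of transmembrane currents over the
fiber's compartments,

$$ f(n) \;=\; \sum_{m=1}^{M} i(n, m)\, w(m), $$

where $i$ is the $N \times M$ transmembrane current matrix (mA), and $w$ is
the recording sensitivity function (lead field, V/mA): the voltage the
electrode registers per unit current injected at compartment $m$. By
reciprocity, $w$ equals the potential along the fiber produced by a unit
current applied at the recording contact, so any volume conductor — analytic
or exported from a finite-element model — enters the simulation only through
$w$.

Storing $i$ for every fiber is prohibitive. The package instead assumes each
compartment repeats the same current waveform delayed by the propagation
time: $i(n, m) = i(n - \tfrac{L}{TV}(m - K),\, K)$, with $L$ the spacing of
same-type compartments (µm), $V$ the conduction velocity (m/s), $T$ the
sampling period (ms) and $K$ a reference compartment. The weighted sum then
collapses to a single convolution

$$ f(n) = i(n, K) \ast S(n), $$

where the *shift filter* $S$ contains the values of $w$ separated by
$L/(TV)$ inserted zeros. `sfap_time_domain()` evaluates this convolution
directly; `sfap_freq_domain()` evaluates it as a product of discrete Fourier
transforms zero-padded to a common duration (hence linear, not circular,
convolution) at matched frequency resolution. Myelinated fibers carry eleven
compartment types per internode (node of Ranvier, MYSA, FLUT, STIN
segments); `sfap_multitype()` applies one filter per type column and sums.

Every filter path is validated against `sfap_brute_force()`, an independent
weighted summation over the reconstructed current matrix
(`reconstruct_current_matrix()`); the test suite holds this equivalence to
better than $10^{-9}$ relative error across randomized compartment counts,
shift counts, fiber kinds and representations.

## Templates and interpolation across diameters

A template bank stores one aligned action potential template per diameter on
a geometric grid (`build_diameter_grid()`); the default grids are
0.105–1.896 µm in 3.06 % steps (97 unmyelinated templates) and
1.013–9.809 µm in 1.19 % steps (193 myelinated templates). Alignment puts
the nodal current maximum at $t = 0$ (earliest sample on ties), recording
the original clock time as `ref_time`. At an arbitrary diameter
$d_1 \le d_i \le d_2$ the template is the weighted average

$$ s_i(t) = \frac{d_2 - d_i}{d_2 - d_1}\, s_1(t)
          + \frac{d_i - d_1}{d_2 - d_1}\, s_2(t), $$

after band-limited resampling of the bracketing templates to the finer of
their native periods over the intersection of their windows. Conduction
velocity is interpolated linearly between the bracketing values with the
same weights: the source material for this method interpolates currents only
and leaves CV assignment unstated, so linear interpolation is this package's
explicit choice — it is exact for myelinated fibers (whose CV model is
linear in diameter) and a second-order approximation for unmyelinated
fibers. Nearest-neighbor lookup (`method = "nearest"`) is provided for
accuracy comparisons and is consistently worse; the acceptance suite
verifies that the CNAP discrepancy statistic
$100 \cdot \max|\mathrm{CNAP}_k - \mathrm{CNAP}_\mathrm{full}| /
V_\mathrm{pk\mbox{-}pk,full}$ decreases with template count $k$ and is zero
at the full bank.

## The synthetic template generator

The generator stands in for biophysical membrane simulations so that every
stage is testable without external data. It derives the nodal current
analytically from an intracellular action potential waveform

$$ V_m(t) = 36{,}864\ \mathrm{mV} \cdot t^3 e^{-8t} - 70\ \mathrm{mV}, $$

a classical analytic AP time course with a ~97 mV excursion and ~1 ms
footprint. The transmembrane current of the reference compartment is taken
proportional to $d^2 V_m / dt^2$ — the traveling-wave cable surrogate — which
guarantees a realistic triphasic shape and an exactly zero temporal integral
(charge balance of a complete propagating action potential; the residual DC
of the sampled waveform is removed so the discrete sum is zero to machine
precision). Amplitude scales with diameter squared by default, matching the
approximately quadratic growth of SFAP amplitude with fiber caliber; both
the derivative order's scale rule and coefficient are configurable
(`synthetic_template_params()`). Myelinated templates repeat the nodal
waveform over the 11 type columns scaled by a fixed attenuation vector —
a documented testing constant, not a biophysical claim.

What the generator does *not* emulate: stimulus artifacts, initiation
dynamics at the stimulation site, diameter-dependent waveform shape changes,
afterpotentials, or membrane noise. Tests passing on synthetic banks
therefore demonstrate the correctness of the reconstruction machinery, not
the fidelity of any particular membrane model; imported template banks are
the intended path for biophysically derived currents.

## Sensitivity functions

`analytic_point_source_sensitivity()` provides the closed-form lead field of
a point contact in an unbounded, longitudinally anisotropic medium,
$w = \frac{1}{4\pi}\left[\sigma_r \sigma_z (\Delta x^2 + \Delta y^2) +
\sigma_r^2 \Delta z^2\right]^{-1/2}$ (V/A, distances in metres), reducing to
$1/(4\pi\sigma r)$ when isotropic; the default conductivity 0.16 S/m is a
typical effective tissue value. Tabulated profiles (e.g. finite-element
exports) load from CSV and are sampled along fiber trajectories by
piecewise-linear interpolation — dense profile exports make higher-order
schemes unnecessary and they risk ringing near cuff edges. Positions are mm
externally, converted to metres internally; weights are always V/mA.
Sampling outside the tabulated range is an error, never an extrapolation.

## Monopolar versus dipolar representations

Compartments can be represented as monopolar point currents weighted by $w$,
or as point current dipoles — the negative cumulative spatial sum of the
currents — weighted by the first spatial difference of $w$. The two are
algebraically equivalent encodings of the same spatiotemporal information.
The package pairs `monopolar_to_dipolar()` with a zero-boundary difference
convention, $w'(m) = w(m+1) - w(m)$ with $w(M+1) := 0$, chosen because Abel
summation then makes the monopolar and dipolar weighted sums agree *exactly*
on every finite matrix, with no assumption about spatial charge closure.

For the filter path, the dipolar template is built from the monopolar one as
the cumulative upstream sum of the traveling wave,
$h(\nu) = -\sum_{u \ge 0} g(\nu + s u)$. This model is exact once the wave
is fully developed inside the fiber but cannot represent the initiation
transient at the fiber end (the true dipolar matrix is not shift-invariant
during wave entry). Because this package's synthetic templates are exactly
charge balanced, the robustness benefit that motivates the dipolar
representation for imported simulation outputs (templates with residual
charge imbalance from imprecise CV estimates) does not arise here, while the
boundary truncation error does. The pipeline default is therefore the
monopolar representation; `representation = "dipolar"` is available and is
validated filter-against-brute-force in its own terms.

## Fiber populations

Populations are built from diameter lists or binned histograms.
`inverse_transform_sample()` maps uniform variates through the
piecewise-linear empirical CDF — uniform density within bins, the standard
choice, which recovers raw measurement lists as bin width shrinks to zero —
and is preferable to `bin_center_expand()`, which piles identical fibers
onto bin centers and biases the CNAP through reduced destructive
interference. Conduction velocity follows $CV = 4.01\,D - 2.5$ m/s
(myelinated, linear in diameter) or $CV = 0.70\sqrt{D} - 1.9\times10^{-3}$
m/s (unmyelinated, linear in $\sqrt{D}$).

Myelinated internode geometry comes from empirical fits
(`ultrastructure_geometry()`): nodal length 1 µm, MYSA 3 µm, quadratic fits
for FLUT and internodal length anchored at 44.85 µm (D = 9.45 µm) and
900.88 µm (D = 9.04 µm), linear fits for internodal and nodal axon diameter,
exponential for lamellae count, and six equal STIN segments filling the
remaining internode. Fibers below 1.01 µm are rejected as having an invalid
modeled ultrastructure; positivity of every derived length and at least one
lamella are enforced in addition, since "invalid" is otherwise imprecise.
The multiplicative/additive normal variability factors are drawn once per
fiber (they model inter-fiber variability of the fits, not per-internode
noise) and are fixed at their means in deterministic mode.

Unmyelinated compartment spacing defaults to 25 µm: the compartment passage
interval $L/V$ must oversample the action potential's temporal footprint
severalfold for the spatial sums underlying the dipolar representation to be
well resolved; coarser spacings visibly under-sample the slowest fibers.

Fibers within 0.001 µm of diameter are grouped (greedy over ascending
diameters, anchored at each group's first member) and their sensitivity
functions summed, so one SFAP serves the whole group; at tolerance zero the
CNAP is unchanged to machine precision.

## Superposition and timing

`simulate_cnap()` places each group SFAP on a common output grid (default
0.01 ms, i.e. the 100 kHz digitization rate typical of in vivo recordings)
by band-limited (sinc) evaluation, which keeps grid placement an exactly
linear operation — the CNAP equals the sum of per-fiber SFAPs to machine
precision. Absolute timing of a fiber's SFAP is
`ref_time + (z_K - z_stim)/V + z_offset/V`: the template's reference-feature
time plus propagation from the stimulation site (z = 0) to the reference
compartment, plus any longitudinal jitter. Initiation delays that vary with
diameter are not modeled beyond `ref_time`; this residual sub-millisecond
timing uncertainty is inherited from the template metadata.

The per-fiber sampling period satisfies two constraints: $L/(TV)$ integer
(never approximated by rounding — $T$ is adjusted instead) and sampling rate
at least twice the template bandwidth, estimated as the frequency below
which 99.99 % of spectral energy lies — a robust, configurable stand-in for
the highest frequency of a smooth waveform.

## Metrics

`peak_to_peak()` (max − min, optionally windowed to exclude the stimulus
artifact region), `negative_peak_latency()` (earliest global minimum),
`max_percent_discrepancy()` (largest pointwise difference as a percentage of
the reference peak-to-peak) and `fit_amplitude_distance_power()`
(least-squares in log–log space, $a \cdot d^{\,b}$) summarize simulated
signals. Over conduction-distance sweeps of heterogeneous populations,
temporal dispersion makes peak-to-peak amplitude fall and negative-peak
latency grow monotonically; scaling all diameters up (emulating shrinkage
correction) raises amplitude and shortens latency. The test suite asserts
these directions on a 40-fiber synthetic population at 5.8–21 mm.

## Problem sizes and determinism

The shipped tests run synthetic banks of up to 34 templates, populations of
up to 40 fibers, 6 mm fibers and 100 randomized oracle fixtures — sizes
chosen so the whole suite completes in about a minute while every code path
(both fiber kinds, both representations, both domains, both sampling
schemes) is exercised; the machinery is linear in fiber count and output
duration, so production runs scale up without structural change. All
randomness flows through explicit seeds; identical configuration plus seed
reproduces byte-identical CSV/JSON outputs (numeric formatting is fixed at
9 significant digits), and every output embeds the MD5 hash of its
configuration.

## Known limitations

- No stimulus-artifact modeling and no bipolar/tripolar re-referencing;
  channels are monopolar.
- The shifted-template assumption ignores initiation and termination
  transients at the fiber ends (see the dipolar discussion above).
- Imported template banks must already contain net extracellular currents;
  no periaxonal current correction is applied.
- No finite-element volume conductor: sensitivity comes from the analytic
  medium or from tabulated exports only.
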