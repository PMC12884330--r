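---
title: "Models and methods behind phevents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phevents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phevents` quantifies single synaptic-vesicle fusion events recorded with
pH-sensitive fluorescent reporters (pHluorin) at nanoscale precision, and
ships a ground-truth-labelled simulator of such recordings so that every
stage of the quantification can be verified end to end without real data.
This vignette explains the models, the defaults, and the numerical and
design choices, in that order. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## The measurement being emulated

A field of hippocampal boutons expressing vGlut1-pHluorin is stimulated at
1 Hz for 200 s and imaged at 50 ms/frame under near-TIRF illumination.
Each action potential releases, with probability $P_r$, one vesicle
(uni-vesicular release, UVR) or — with probability `p_mvr` — two
near-simultaneously (multi-vesicular release, MVR), visible as a second
peak at $q_2 \approx 2 q_1$ in the quantal amplitude distribution. After
fusion the fluorescence decays as the reporter is retrieved and
re-acidified; at the single-event level this decay is mono-exponential
with one of two characteristic constants (ultrafast endocytosis,
$\tau \approx 100$ ms, or fast endocytosis, $\tau \approx 500$ ms),
sometimes after a plateau ("dwell time") and to a variable depth
("retrieval fraction").

## The event trace model

With the event at $t = 0$, the noiseless trace is

$$F(t) = \begin{cases}
0 & t < 0\\
A & 0 \le t < d\\
A\left[(1 - f) + f\, e^{-(t - d)/\tau}\right] & t \ge d
\end{cases}$$

where $A$ is the peak amplitude (in quantal units), $d$ the dwell time,
$\tau$ the endocytic decay constant, and $f$ the asymptotic undershoot
($f > 1$ drives the tail below baseline: excessive retrieval; $f = 0$ is a
flat, non-retrieving event). Gaussian noise of SD `noise_sd` (default 0.1
$q_1$) is added to every 50 ms sample.

The **retrieval fraction** is defined operationally as the fractional drop
of the fitted curve over the 1 s window after the peak:
$\phi = (F(t_{peak}) - F(t_{peak} + 1\,\mathrm{s}))/F(t_{peak})$, and is
categorized as *partial* ($\phi < 0.8$), *quantal* ($0.8 \le \phi \le
1.2$, bounds inclusive — "between 0.8 and 1.2" is read inclusively and
documented here), *excessive* ($\phi > 1.2$), or *none* when no decay is
detectable. Because $\phi$ is evaluated at a finite window, the generator
does **not** sample $f$ directly: it samples the target fraction $\phi$
uniformly within its category interval (0.3–0.8 / 0.8–1.2 / 1.2–1.6) and
solves $f = \phi / (1 - e^{-(1 - d)/\tau})$, so the true measured-at-1-s
fraction of every synthetic event equals its label. Had $f$ been sampled
directly, fast-decaying categories would systematically leak across the
0.8 boundary (the attenuation factor is ≈0.84 at $\tau = 0.5$ s) and no
classifier evaluating the stated definition could recover the generating
proportions.

## Generator defaults (the stated baseline world)

| parameter | default | rationale |
|---|---|---|
| `n_stimuli`, `stim_interval_s`, `frame_interval_s` | 200, 1 s, 50 ms | the recording protocol |
| `pr_true` | 0.3 | mid-range functional hippocampal bouton; well above the 0.05 inclusion cut |
| `p_mvr` | 0.1 | MVR is the minority synchronous mode |
| `q1`, `q_cv` | 1.0, 0.1 | single-quantum scale; clean but overlapping quantal peaks |
| `p_ultrafast` | 0.2 | fast endocytosis carries ~80% of events, ultrafast ~20% |
| `tau_ultrafast_s`, `tau_fast_s`, `tau_cv` | 0.1 s, 0.5 s, 0.2 | the two endocytic modes; CV chosen so the two tau populations are distinct but not trivially separable |
| `dwell_mean_s` | 0.1 s | exponential, truncated at 0.5 s; no distribution is established for real data, so this is a modelling choice |
| `p_retrieval` | (0.35, 0.38, 0.24, 0.03) | baseline partial/quantal/excessive/none composition |
| `sigma_loc_nm` | 20 | the ~20 nm localization precision scale |
| `az_radius_nm`, `n_sites`, `site_min_sep_nm` | 150, 8, 60 | a plausible hippocampal active-zone footprint; separation above the 50 nm clustering diameter |
| `noise_sd` | 0.1 | ~10:1 peak SNR for a single quantum |
| `p_async` | 0.05 | asynchronous release is present but rare at 1 Hz |

Positional scatter is applied twice, as two physically distinct things:
biological scatter of the fusion position around its release-site center
(SD `sigma_loc_nm`) and localization error on the observed coordinates
(again `sigma_loc_nm`), so observed positions scatter around site centers
with SD $\sqrt{2}\,\sigma$. Tests of release-site recovery therefore use
configurations whose site separation exceeds twice the *total* scatter
plus margin.

Optics defaults (86.7 nm pixels = 13 µm EMCCD pixel / 150×; PSF
$\sigma$ = 130 nm; 2000 detected photons per quantum per frame; 50
background photons/pixel; unit read noise) are reconstructed from the
class of instrument the protocol names, and are configurable. Rendering
uses the *integrated* Gaussian PSF (erf differences per pixel), Poisson
shot noise on signal plus background, then Gaussian read noise, clipped
with a warning at the 16-bit ceiling.

What the generator deliberately does **not** emulate: pHluorin
photophysics (bleaching, quenching kinetics), vesicle pool depletion,
calcium dynamics, stage drift, EM-gain excess noise, and MVR of order
three or higher. A green round-trip test therefore establishes that the
analysis implements its definitions correctly on data of the assumed
structure — not that it is robust to every artifact of real recordings.

## Fitting: numerical choices

**Plateau + decay fits.** All kinetic fits minimize least squares of
$F(t) = B e^{-(t - t_d)/\tau} + c$ (with the plateau value $B + c$ for
$t < t_d$). For fixed $(t_d, \tau)$ the problem is linear in $(B, c)$ and
solved in closed form; $\tau$ is profiled on a log grid (30 points in
[0.01, 10] s) with *every* local minimum refined by golden-section —
with a free offset the SSE profile in $\tau$ is regularly bimodal, and a
single descent misses the global optimum on ~25% of noisy traces. The
onset $t_d$ is profiled over the frame grid (50 ms resolution, up to
0.5 s), matching the data resolution and keeping fits reproducible; the
selected onset is the *earliest* one whose SSE is within half a residual
variance of the optimum. Taking the raw SSE minimum lets noise fabricate
plateaus and shortens fitted $\tau$ by ~10% for slow decays, while a
full AIC-style step ($2 s^2$) suppresses genuine short plateaus and
inflates $\tau$ instead; the half step balances the two failure modes
(both were quantified on synthetic traces before fixing the rule).
Standard errors come from the residual-variance-scaled inverse normal
matrix of the full Jacobian.

**Peak frame.** The peak is the first post-stimulus frame, moved to the
second only when that frame is higher by more than twice the baseline
noise SD. Taking the plain maximum of the first two frames would select
an upward noise excursion on ~25% of traces and bias fitted $\tau$ ~5%
low; the margin keeps the intended tolerance to one-frame onset jitter
without that conditioning.

**Mono-exponential fits.** `fit_monoexp_decay()` defaults to profiling
the decay origin (`onset = "auto"`), i.e. it fits the mono-exponential to
the decay segment rather than across the plateau; `onset = "peak"` forces
the literal from-the-peak fit. The default matters: with the dwell
distribution above, from-peak fits inflate the ultrafast component's
median $\tau$ beyond any 10% recovery band, while the decay itself is
still fitted by exactly one exponential with offset — which is what the
tau histogram is meant to measure. The offset $c$ is free by default (its
role is untestable on real data and flagged for sensitivity analysis).

**"No detectable decay."** Operationalized on the fitted curve's drop
over the 1 s window: $B(1 - e^{-(1 - d)/\tau}) < \max(2 \times
\text{noise SD}, 2\%\ \text{of } A)$ means no detectable decay; such
events are categorized *none* and carry `fit_ok = FALSE`. Judging the
*observed* drop rather than the asymptotic amplitude matters for
shallow slow decays, where $\tau$ runs into its upper bound with a
degenerate, large $B$: the decay is real and measurable even though
$\tau$ itself is not identifiable (those events keep their category but
are excluded, via `fit_ok`, from the tau-distribution decomposition).

**Bi-Gaussian decompositions.** Histograms (default bin widths: 0.05 s
for $\tau$; $0.1\,\hat q_1$ for amplitudes) are fitted with a sum of two
Gaussians by Nelder-Mead least squares from four quantile-based starts;
components are ordered by mean and areas are $a\sigma\sqrt{2\pi}$. The
*ultrafast ratio* is the small-mean area over the total. Every histogram
fit is cross-checked against a hand-rolled two-component ML normal
mixture (EM) on the raw values; a discrepancy in the second-component
proportion above 0.1 sets `crosscheck_flag`. The histogram fit is
authoritative for reported numbers, as the ratio is defined through the
fitted areas.

**MVR classification.** Per synapse, single pass, sample SD ($n - 1$),
strict inequality at mean + 2 SD; events below the threshold are UVR.
Fewer than two events leaves everything UVR with a degeneracy flag.

## Detection and localization

Detection operates on $\Delta F$ frames (frame minus per-pixel running
median of the preceding 10 frames), band-pass filtered with a
Laplacian-of-Gaussian kernel at the PSF scale. Candidates must exceed
`threshold_k` × the per-frame robust noise SD (1.4826·MAD of the filtered
frame), be 8-neighborhood local maxima, survive greedy non-maximum
suppression at 3 px, and constitute a *step*: the response must have
risen since the previous frame by more than max(thr/2, 40% of its own
value). The relative term exists because shot noise on a bright plateau
scales with the signal, not the background. The default `threshold_k`
is 5: at 4, the Gaussian tail alone yields of order 0.07 false maxima per
2000-pixel frame — tens of spurious events over a 200 s movie, more than
the tolerated spurious fraction. Events are localized on their onset
frame only; there is no temporal linking.

Localization fits $\text{offset} + A\exp(-((x - x_0)^2 + (y -
y_0)^2)/2\sigma^2)$ over a 9×9 ROI, with $(x_0, y_0, \sigma)$ optimized
and $(A, \text{offset})$ profiled linearly; the reported per-axis
precision is the 1-SD uncertainty from the scaled inverse normal matrix,
in nm. Pixel centers sit at integer coordinates with pixel (0,0) centered
at the origin, so $x_{nm} = x_{px} \cdot \text{pixel size}$ exactly.
Non-converged fits (non-positive amplitude, $\sigma$ outside (0.5, 7.5)
px, center outside the ROI, or a singular normal matrix) are flagged and
kept in the event log but excluded from spatial statistics.

## Spatial statistics

The functional active zone is the **convex** hull of a bouton's release
events ("convolute hull" is read as convex hull — the alternative concave
reading would not "encompass all detected release events" uniquely);
area by the shoelace formula, center as the area-weighted polygon
centroid (the mean-of-points alternative is deliberately not the
default). Hulls of fewer than three distinct or collinear points are
degenerate: zero area, flagged, excluded from area statistics but kept
for distance statistics. Release sites are complete-linkage hierarchical
clusters cut at 50 nm — complete linkage is the one standard linkage for
which the cut height bounds the intra-cluster diameter, which is what a
"clustering diameter" asserts.

## Conditions as parameter remaps

Pharmacological conditions (MβCD extraction ladder, water-soluble
cholesterol supplementation ladder, and the 2-day supply-chain blocks
with ±LDL rescue) are emulated purely as monotone remaps of generator
parameters: cholesterol lowering decreases `p_mvr`, `pr_true` and the
spatial scale and increases `p_ultrafast` and the excessive-retrieval
weight; raising cholesterol does the opposite; LDL restores control
values for the transporter block but not for the lysosomal (NPC1) block,
which sits downstream of LDL uptake. Directions are biologically
anchored; magnitudes are emulation choices (the top MβCD dose suppresses
`p_mvr` >14-fold). Nothing here is fitted to real dose-response data.

## Inclusion filters and statistics plumbing

Synapses enter analysis with ≥10 events and $P_r \ge 0.05$ (both
inclusive), applied before all spatial and kinetic population
statistics. A stimulus with both a synchronous and an asynchronous event
counts once toward overall $P_r$; asynchronous events are tallied
separately (the synchronous window, 100 ms = 2 frames, is a convention —
no criterion is established for real data, so `pr_async` results are
convention-dependent). Group comparisons are thin wrappers over the
two-tailed Welch t test, one-way ANOVA with Tukey-Kramer post-hoc, and
the two-sample K-S test; no multiple-testing correction by default, with
Benjamini-Hochberg available as an option.

## Known limitations

- The simulator's noise is Gaussian on traces and Poisson+read on
  movies; real EMCCDs add excess noise (effectively doubling shot
  variance), so real-data precision will be somewhat worse than the
  rendered-spot calibration suggests.
- Mono-exponential $\tau$ estimates on a 1 s window with a free offset
  are slightly biased low for $\tau \gtrsim 0.5$ s (a few percent); the
  bias is inherent to the window, not the optimizer, and is visible in
  the simulation oracle as well.
- Retrieval categories near the 0.8/1.2 bounds are noise-limited;
  at `noise_sd = 0.1` roughly 7% of events land in the adjacent
  category. This is a property of the definition, mirrored faithfully.
- `pr_async` and dwell-time results depend on stated conventions (the
  asynchronous window and the dwell distribution) that real data do not
  pin down.
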