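---
title: "Cortical coherence networks: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical coherence networks: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexnet)
```

## The analysis in one paragraph

`cortexnet` treats the cerebral cortex as a weighted functional network
observed indirectly through scalp EEG. A linear inverse operator maps the
28 scalp channels to 258 radially oriented cortical dipoles; within each of
six canonical frequency bands (delta through gamma), magnitude-squared
coherence (MSC) between every dipole pair defines a complete, unthresholded
weighted adjacency matrix; each matrix is summarized by weighted graph
metrics — node strength (NS), global efficiency (Eglob), local efficiency
(Eloc), clustering coefficient (CC), characteristic path length (L) and
small-worldness (SWN) — and task conditions are compared subject-wise with
asymptotic two-tailed Mann–Whitney U tests under Benjamini–Hochberg FDR
control at q = 0.05. A cohort of 24 subjects, 4 tasks and 6 bands yields
24 × 6 × 4 = 576 adjacency matrices. Because no EEG recordings ship with
the package, a seeded synthetic-cohort generator with planted, band-specific
coupling provides inputs whose source-space coherence structure is known by
construction.

## The synthetic cohort: what it emulates, and what it does not

Each source signal starts as independent broadband (white) Gaussian
background. A *planted network* declares, for one band, a set of disjoint
source pairs that share a band-limited common component: a member of an
edge with mixing $a$ carries

$$y_i = \sqrt{a}\, s_e + \sqrt{1-a}\, n_i$$

inside the band ($s_e$ shared per edge, $n_i$ private, all unit variance),
and the member's broadband background is band-stopped there so the in-band
content is exactly the mixture. For equal spectra this gives the closed
form $\mathrm{MSC} = a^2$, the basis of the generator's recovery tests.

Band-limited processes are white noise passed through zero-phase 4th-order
Butterworth high-/low-pass sections (applied forward–backward via
`signal::filtfilt`). One subtlety matters: a forward–backward filter leaves
only *quarter* power at its nominal corner, so filters whose corners sit
exactly on the band edges depress the outermost analysis bins well below
the $a^2$ target. The generator therefore places its corners 0.25 Hz
outside the band; the response is then flat across the bins the coherence
analysis averages, while leakage into the first bin of the neighbouring
band stays inside the Welch estimator's bias envelope (verified in the
cross-band leakage tests).

Design choices, fixed once:

* **Cohort defaults** (the study conditions): 24 subjects; tasks FIX, DL,
  SM, DM; 10 s segments at 500 Hz; sensor SNR 10 dB; master seed per
  cohort. Reduced-scale runs (20–40 dipoles) use the same defaults except
  for source count.
* **Planted defaults**: three disjoint delta-band edges among sources 1–6
  with mixing 0.75, present only in the DM condition — a planted analogue
  of a condition-specific low-frequency coupling increase.
* **Subject heterogeneity**: each subject perturbs every edge's mixing by
  a uniform draw in ±0.05. Inter-subject MSC variability has no canonical
  value, so this magnitude is our choice; it is exposed in the
  configuration and makes group tests nondegenerate.
* **Sensor noise** is white, Gaussian and *constant across tasks*: its
  standard deviation is set once per cohort from the expected sensor power
  of the unit-variance source background under the lead field,
  $\overline{\sum_j A_{ij}^2}$, and the configured SNR (total signal power
  over noise power, in dB). Instrument noise does not track task power; if
  it did (noise rescaled per recording), a planted manipulation in one band
  would leak into *every* band through the noise scale — an artifact we
  observed and designed out.

The generator does **not** emulate ocular or muscle artifacts, realistic
1/f spectra beyond the configurable broadband background, or task
psychophysics. Passing tests therefore demonstrate that the estimators and
statistics recover known coupling under idealized, stationary Gaussian
conditions — not that they are robust to real-world EEG artifacts.

## Head model and inverse operator

The forward model is the analytic three-concentric-spheres solution (brain
/ skull / scalp radii 0.87, 0.92, 1.0; conductivities 0.33, 0.0042,
0.33 S/m — the conventional 1:1/80:1 ratio), evaluated per spherical
harmonic degree by solving the five boundary conditions and summed to
degree 80. Sensors occupy a symmetric 28-label 10/10 montage on the scalp
sphere; dipoles sit on a Fibonacci lattice at radius 0.78 with a small
seeded jitter, radially oriented so each contributes one scalar time
series. An anatomy-based boundary-element model is out of scope; the
spherical model preserves exactly the structure the analysis needs — a
28 × 258 linear kernel. One analytic caveat: a radial dipole approaching
the sphere's center does *not* produce a vanishing surface pattern (the
degree-1 harmonic survives), only an attenuated one; the depth-attenuation
test asserts monotone decay rather than a zero limit.

The inverse is the column-norm-normalized (depth-weighted) regularized
minimum-norm solution

$$K = C A^\top (A C A^\top + \lambda^2 I)^{-1}, \qquad
  C = \mathrm{diag}(1/\lVert a_j \rVert^2),$$

i.e. the minimizer of $\lVert y - Ax\rVert^2 + \lambda^2 \lVert W x
\rVert^2$ with $W = \mathrm{diag}(\lVert a_j\rVert)$ — the standard reading
of column-norm normalization in the weighted-minimum-norm literature,
counteracting the superficial-source bias. Neither the inverse family
beyond this normalization nor $\lambda$ has a canonical value for this kind
of analysis; both are configuration here, and by default $\lambda$ follows the
discrepancy principle, $\lambda^2 = \mathrm{tr}(ACA^\top) / (n_{\rm
sensors}\, \mathrm{SNR})$, against the cohort's configured SNR. The kernel
is validated against an independent SVD-based solve and against the
algebraic identity $AK = I$ at $\lambda = 0$ for full-row-rank systems.

## Coherence estimation

MSC uses Welch averaging: 1 s Hann windows, 50 % overlap, `nfft` equal to
the window — at 500 Hz this gives 1 Hz bins (resolving the delta band) and
19 segments per 10 s record. The per-bin estimate is
$|P_{xy}|^2/(P_{xx}P_{yy})$; the band-level weight is the mean over bins
whose centers lie in the half-open interval $[f_{\rm lo}, f_{\rm hi})$.
Band edges default to delta 1–4, theta 4–8, alpha1 8–10, alpha2 10–13,
beta 13–30, gamma 30–45 Hz; neither the edges nor the Welch parameters are
reconstructions — they are documented conventional choices, fully
configurable. Whether a per-band scalar should be a bin average or a
coherence of band-filtered series was genuinely open; bin averaging is the
simpler faithful reading and is what the estimator bias analysis assumes.

For an $n$-channel recording the full adjacency matrix comes from one
cross-spectral-density pass — segment FFTs of all channels at once, then a
rank-$K$ outer product per frequency bin — rather than $\binom{n}{2}$
independent pair calls; the two routes agree to $10^{-12}$ and the naive
pair call is kept precisely to serve as that oracle. The estimator's bias
floor for independent signals is $\approx 1/K$ (about 0.053 at $K = 19$),
it shrinks monotonically with record length, and the estimate is invariant
to channel scaling and sign flips. The diagonal is set to 0, not 1:
self-loops are excluded from every downstream metric.

## Graph metrics

All metrics operate on the complete weighted matrix; no thresholding is
applied anywhere. Edge lengths are reciprocal weights $\ell = 1/w$ — the
convention of the Brain Connectivity Toolbox family of definitions this
module follows. Shortest paths use Dijkstra from every node
(`igraph::distances`); a Floyd–Warshall transcription lives in the test
suite as the independent oracle. Specifics worth stating:

* **CC** is Onnela's geometric-mean triangle intensity, averaged over
  nodes of degree ≥ 2; it reduces to the binary coefficient on 0/1
  weights.
* **Eloc** follows the Rubinov–Sporns weighted form: cube-root products of
  the two anchoring weights and the inverse shortest path *within the
  neighbourhood subgraph* (paths may not pass through the center node);
  nodes of degree < 2 contribute 0.
* **SWN** is $(CC/CC_{\rm rand})/(L/L_{\rm rand})$ against surrogates that
  permute the off-diagonal weight multiset while preserving symmetry —
  a null that preserves the weight distribution exactly; 100 surrogates by
  default, seeded. A degenerate matrix with all-equal weights returns 1
  without sampling. Other SWN variants in the literature are scaled
  differently and can lie below 1 even for genuinely small-world graphs;
  this package's ratio form is its own scale and no numeric agreement
  with any other variant is claimed anywhere in the package.
* **Disconnected graphs**: efficiency terms use $1/\infty = 0$; L averages
  the finite pairs and flags the summary.

On a complete graph with uniform weight $w$ the closed forms are
$E_{glob} = E_{loc} = CC = w$, $L = 1/w$, $NS_i = (n-1)w$, $SWN = 1$; every
metric is tested against them, against literal term-by-term
transcriptions, and for scale equivariance (weights scaled by $c$ scale
NS, Eglob, Eloc, CC by $c$, L by $1/c$, SWN not at all).

## Group statistics

Shapiro–Wilk and Lilliefors (KS) screening justifies the nonparametric
path; comparisons are asymptotic two-tailed Mann–Whitney U tests with tie
and continuity corrections (`stats::wilcox.test`, reported as
$\min(U_a, U_b)$), validated against exact enumeration at tiny $n$ and
against $10^5$-permutation oracles at $n = 24$ per group (agreement within
0.01). FDR control is Benjamini–Hochberg step-up via `stats::p.adjust`.
The choice of FDR family is genuinely open; here it is **within
(band, metric) across the six task pairs** for scalar metrics and **across
nodes within one contrast** for node strength, recorded in output
metadata. Edge difference maps subtract the control (FIX) mean matrix from
each task's and zero sub-threshold entries for display only (0.10 for the
four low bands, 0.05 for beta/gamma, configurable); the full difference is
always retained.

## Problem sizes and numerical choices

The package's own test and verification scales, chosen to keep every run
deterministic and fast on a single CPU:

* Unit tests use 2–40 sources and seconds-to-minutes of synthetic signal.
* The full-scale pipeline check runs the complete study shape — 24
  subjects × 4 tasks × 6 bands at 258 dipoles — streaming matrices through
  memory and summarizing each with NS, Eglob, CC and L (one shortest-path
  pass per matrix). Weighted Eloc costs a shortest-path problem per node
  per matrix ($O(n^4)$ work) and SWN multiplies CC and L by the surrogate
  count, so those two are exercised in full at the reduced scales below
  rather than at 258 dipoles; their definitions are identical at any size.
* End-to-end recovery calibration runs 50 seeded cohorts at 30 dipoles
  with bands delta and gamma (the perturbed and a distant unperturbed
  band) and metrics NS, Eglob, Eloc.

Other numerical details: substream seeds are derived deterministically
from the master seed and (subject, task) indices so any single recording
can be regenerated in isolation; all surrogate and noise draws restore the
caller's RNG state; the Welch minimum is 8 segments and violations report
the required record length; MSC denominators of zero (a silent channel)
yield 0 rather than NaN.

## Known limitations

* The spherical head model is a structural stand-in: kernels are
  well-conditioned and realistic in rank and smearing, but dipole
  positions do not correspond to anatomy, so node-level findings cannot be
  mapped to cortical regions.
* Source leakage is real and intended: with 28 sensors driving 258
  dipoles, neighbouring estimated sources are strongly coherent, so
  node-level inference at full scale detects leakage-smeared neighbourhoods
  rather than single dipoles. The per-node recovery guarantees are stated
  (and tested) in source space and at reduced dipole counts.
* MSC is not robust to volume conduction; plain MSC is the deliberate
  choice here, and imaginary-coherence-type estimators are out of scope.
* The Mann–Whitney tests treat the four task conditions as independent
  groups, although the same 24 subjects
  performed all tasks; a within-subject design would be more powerful.
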