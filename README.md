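# cortexnet

Weighted cortical-network analysis of multichannel EEG: from scalp
recordings (or a fully synthetic cohort with known ground truth) to
source-space coherence graphs, weighted network metrics and nonparametric
group statistics.

## The problem

Task-related reorganization of cortical functional networks is commonly
studied by (1) estimating cortical source activity from scalp EEG with a
regularized linear inverse, (2) quantifying coupling between every pair of
cortical sources within canonical frequency bands, and (3) summarizing the
resulting weighted graphs and comparing conditions across subjects. Each
stage has well-known pitfalls — depth bias of minimum-norm inverses,
estimator bias of spectral coherence, thresholding artifacts in graph
analysis, and non-normal metric distributions at small n. `cortexnet`
implements the complete chain as tested, reusable R functions, and ships a
seeded synthetic-cohort generator whose band-specific coupling structure is
known *by construction*, so every stage can be validated end to end without
any EEG downloads.

## The model

**Inverse mapping.** With lead field `A` (sensors × dipoles, three-shell
spherical head model, radial dipoles), the column-norm-normalized
regularized minimum-norm inverse is

    K = C Aᵀ (A C Aᵀ + λ² I)⁻¹,   C = diag(1 / ‖aⱼ‖²)

the minimizer of ‖y − Ax‖² + λ²‖Wx‖² with depth weighting W = diag(‖aⱼ‖).
At the study scale this maps 28 scalp channels to 258 cortical dipole
time series.

**Connectivity.** Edge weights are magnitude-squared coherence,
`MSC(f) = |P_xy(f)|² / (P_xx(f) P_yy(f))` from Welch-averaged spectra
(1 s Hann windows, 50% overlap), averaged over the bins of each band
(delta 1–4, theta 4–8, alpha1 8–10, alpha2 10–13, beta 13–30,
gamma 30–45 Hz). Every subject × band × task cell yields one complete,
unthresholded weighted adjacency matrix — 24 × 6 × 4 = 576 matrices at
study scale, each 258 × 258.

**Graph metrics.** Node strength NSᵢ = Σⱼ wᵢⱼ; global efficiency
Eglob = mean of 1/dᵢⱼ with path lengths dᵢⱼ over edge lengths 1/w
(Dijkstra); Onnela weighted clustering CC; Rubinov–Sporns weighted local
efficiency Eloc; characteristic path length L; and small-worldness
SWN = (CC/CC_rand)/(L/L_rand) against weight-multiset-preserving random
surrogates.

**Statistics.** After Shapiro–Wilk / Lilliefors normality screening,
pairwise task contrasts use the asymptotic two-tailed Mann–Whitney U test
(tie and continuity corrected, U = min(U_a, U_b)) with Benjamini–Hochberg
FDR at q = 0.05 — across the six task pairs within each (band, metric),
and across nodes within each node-strength contrast. Task-minus-control
edge difference maps use display thresholds 0.10 (delta–alpha2) and 0.05
(beta, gamma).

## Worked example

The numbered drivers under `analysis/` run a reduced-scale study (24
subjects × 4 tasks, 30 dipoles, 10 s @ 500 Hz, bands delta + gamma) with
three delta-band edges planted only in the difficult-multiplication (DM)
condition:

```sh
Rscript analysis/01_simulate_cohort.R   # synthetic cohort -> scratch/analysis/
Rscript analysis/02_head_model.R        # lead field + inverse kernel -> results/headmodel/
Rscript analysis/03_connectivity.R      # per-band MSC adjacency matrices
Rscript analysis/04_graph_metrics.R     # NS, Eglob, Eloc, CC, L, SWN per matrix
Rscript analysis/05_group_statistics.R  # U tests + FDR, node maps, edge maps
```

Stage 3 prints the planted edge surfacing in the estimated sources:

    S01 delta MSC edge (1,2): DM = 0.602 vs FIX = 0.052

(0.052 is the Welch bias floor ≈ 1/19 for independent signals; the planted
mixing of ≈ 0.78 after subject jitter predicts MSC ≈ 0.6). Stage 4 shows
the group-level effect confined to the planted band:

    per-task delta-band means:
      task     eglob       eloc       swn
    1   DL 0.1380914 0.08876131 0.8146005
    2   DM 0.4448723 0.38573225 0.7851040
    3  FIX 0.1402516 0.09104007 0.8221229
    4   SM 0.1379873 0.08937315 0.7982869

and stage 5 rejects exactly the DM contrasts for delta Eglob/Eloc
(FDR p ≈ 6 × 10⁻⁹) with zero significant node-strength differences in the
unperturbed gamma band:

    delta band, DM vs FIX: significant nodes: 1 2 ... 30
    gamma band, DM vs FIX: significant nodes:
    delta band DM-FIX:  347 edges above the display threshold 0.1
    gamma band DM-FIX:  0 edges above the display threshold 0.05

(in delta, inverse-mapping leakage spreads the planted coupling across the
estimated sources, so all node strengths rise — see the vignette's
discussion of source leakage).

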