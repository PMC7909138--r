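---
title: "Identifying representative scanpaths: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying representative scanpaths: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

When a group of observers free-views the same stimulus, each produces a
*scanpath*: an ordered sequence of fixations, each with pixel coordinates
and a gaze duration. Individual scanpaths are idiosyncratic, but the group
usually shares structure — which regions attract attention, in what order,
and for how long. gazerep condenses a set of scanpaths into a single
*representative scanpath*: an ordered sequence of areas of interest (AOIs)
with center coordinates and per-visit gaze durations, chosen to minimize
the average dynamic time warping (DTW) dissimilarity to the individual
scanpaths.

```{r}
library(gazerep)
g <- generate_scanpaths(synth_config(K = 3, n_subjects = 12, seed = 42,
                                     outliers = 1))
res <- run_pipeline(g$set, method = "heuristic")
res[[1]]$representative
```

The pipeline has three stages — preprocessing, aggregation, duration
analysis — described in turn below, with the numerical and design choices
a maintainer would want to know.

## Dissimilarity: dynamic time warping on coordinates

Two scanpaths $A = \langle a_1,\dots,a_m\rangle$ and
$B = \langle b_1,\dots,b_n\rangle$ are compared by DTW with Euclidean
local cost on the $(x, y)$ coordinates:

$$D(i,j) = \lVert a_i - b_j \rVert + \min\{D(i{-}1,j),\; D(i,j{-}1),\;
D(i{-}1,j{-}1)\},$$

with $D(0,0)=0$ and infinite borders; the dissimilarity is $D(m,n)$.
Durations never enter the distance — aggregation treats spatial shape
only, and duration is attached afterwards.

Two choices deserve a note:

* **No path-length normalization by default.** Reported dissimilarities
  are accumulated pixel costs, so magnitudes scale with sequence length
  and image size (hundreds of pixels on an 800×600 stimulus). A
  `normalize` flag divides by the alignment path length for users who
  want length-free values; nothing downstream depends on it.
* **Deterministic backtracking.** The optimal alignment path is recovered
  with the fixed tie order diagonal ≻ up ≻ left. CDBA consumes these
  paths, so determinism here makes the whole pipeline reproducible.

The recursion is implemented in C++ (`src/dtw.cpp`); tests check it
against an independent R enumerator of all monotone alignments.

## Preprocessing

**Outlier removal.** Each subject is scored by the mean DTW distance from
their scanpath to every other scanpath; Tukey fences
$[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$ (quartiles by linear
interpolation, `k = 1.5`) are applied to the scores. Removal is
*one-sided*: only scores above the upper fence are dropped, because
unusually *low* mean dissimilarity signals conformity with the group, not
anomaly. One pass is made — no iterative re-removal — and sets with fewer
than three scanpaths are kept whole with a warning, since fences are then
undefined. If the rule would leave fewer than two scanpaths, nothing is
removed (aggregation would be undefined).

**AOI extraction.** Fixations of all kept scanpaths are pooled and
clustered by the density-peaks method: each fixation gets a local density
$\rho_i = \sum_{j \ne i} \exp(-(d_{ij}/d_c)^2)$ and a separation
$\delta_i$, the distance to the nearest fixation of higher density (the
global density maximum takes $\delta = \max_j d_{ij}$). Cluster exemplars
are fixations with large $\gamma = \rho\,\delta$. The cutoff `d_c`
defaults to the 2nd percentile of all pairwise distances, the usual
density-peaks rule of thumb; density ties are broken by fixation
enumeration order so the clustering is deterministic.

The number of AOIs follows from a threshold on $\gamma$: fixations
strictly above it become exemplars. The threshold is a weighted geometric
mean of the scores that emphasizes larger $\gamma$ (and therefore yields
fewer, less overlapping clusters than the plain geometric mean). The
default weighting concentrates on the two scores flanking the
exemplar/tail boundary, so the threshold is $\sqrt{\gamma_K
\gamma_{K+1}}$ at the boundary index $K$. Locating that boundary was the
one genuinely open design point:

* Weighting each score by itself makes the threshold track the top peak,
  whose $\delta$ is the max-distance convention (frame scale); with many
  or unevenly occupied clusters the weakest peaks fall below it.
* Gap-seeking on the $\gamma$ spectrum alone is ambiguous when a
  rarely-visited AOI's peak is only a few times the tail top.
* The $\delta$ spectrum separates sharply in exactly the regime where
  clustered fixations are meaningful: peak $\delta$ sits at the
  between-cluster scale, everything else at the within-cluster neighbor
  spacing. The boundary is therefore taken at the widest multiplicative
  gap of the ordered $\delta$ spectrum (restricted to splits whose upper
  flank is at least the spectrum's geometric mean, which keeps near-zero
  deep-tail values from capturing the split; coincident duplicates, whose
  $\delta$ is 0, are represented by one pseudo-tail entry).

`gamma_mean = "self-weighted"`, `"geometric"` and `"arithmetic"` remain
available for comparison. All-equal scores (e.g. fully coincident input)
produce a single AOI with a warning.

**Center identification.** Each AOI's center is the equilibrium of a
random walk over its member fixations: transition affinities
$q(j,i) \propto \exp(-D(j,i)^2 / 2\sigma^2)$, column-normalized; the
coefficient vector starts at the within-AOI-normalized densities and is
iterated $l \leftarrow Q\,l$ (renormalized) to its fixed point; the
center is the $l$-weighted mean of the member coordinates. This
downweights edge points relative to the arithmetic mean. $\sigma$
defaults to `d_c` — it shifts the center only subtly — with tolerance
`1e-8` on the max coefficient change and an iteration cap of 1000. Plain
power iteration stalls when $\sigma$ is small relative to the cluster
extent (the chain's spectral gap vanishes), so the iteration is
accelerated by operator squaring: update $k$ applies $Q^{2^{k-1}}$, and
convergence is reached in a handful of updates regardless of the gap. A
single-member AOI is its own center.

## Aggregation

The representative scanpath minimizes the average DTW to the individual
scanpaths over candidate sequences of AOI centers, subject to three
constraints that keep it interpretable: (1) components are AOIs; (2)
every adjacent pair must occur contiguously in at least one individual
AOI sequence; (3) no AOI may appear more often than its maximum
occurrence count in any individual sequence. Individual AOI sequences are
obtained by mapping each subject's fixations to AOIs and merging
consecutive same-AOI runs (durations summed). The observed bigrams define
a candidate-successor graph; `validate_constraints()` checks any proposed
sequence against it.

Three aggregators are provided:

* **`heuristic_aggregate()`** enumerates every constraint-valid sequence
  of length 1..`n_max` depth-first through the successor graph and
  returns the global argmin. Any AOI may start a sequence (the
  constraints restrict pairs and counts, not starts; `start_observed`
  restricts starts to observed first visits). Ties break toward shorter,
  then lexicographically smaller sequences. Because the occurrence caps
  bound total sequence length, the objective saturates once `n_max`
  reaches the longest feasible sequence; the default `n_max = 8` is past
  that point for typical free-viewing sequences.
* **`cdba_aggregate()`** is the scalable alternative: DTW barycenter
  averaging constrained to the candidate graph. Each iteration aligns
  every scanpath to the current reference and replaces each reference
  component, left to right, by the AOI — among those keeping the whole
  sequence constraint-valid when substituted at that position — whose
  center minimizes the summed (plain, not squared) Euclidean distance to
  the fixations aligned to that component. Plain distances match the DTW
  local cost, which is what makes the objective provably non-increasing:
  the incumbent is always a feasible candidate, so the aligned cost never
  rises, and the old alignment paths remain feasible warpings for the
  updated reference. Cost ties keep the incumbent (guaranteeing that an
  optimum is a fixed point and ruling out equal-cost oscillation), then
  break lexicographically. The reference length is fixed at
  initialization (components are replaced, never inserted or deleted),
  the standard barycenter-averaging convention. The default
  initialization is the IOC selection, which is deterministic and makes
  objective(CDBA) ≤ objective(IOC) hold by construction; `"medoid"` and
  `"random"` inits are available.
* **`ioc_select()`** (inter-observer consistency, adapted to DTW) simply
  returns the individual AOI sequence with the smallest average DTW —
  always a member of the transformed individual set, and a useful
  baseline and initializer.

By construction, objective(heuristic) ≤ objective(CDBA) ≤ objective(IOC)
when CDBA starts from IOC and `n_max` covers the feasible lengths; the
test suite asserts this ordering, CDBA's per-iteration non-increase, and
heuristic optimality against an independently coded brute-force
enumerator.

## Gaze duration analysis

Visit durations are pooled across subjects by *occurrence*: an AOI
appearing more than once in a sequence is treated as distinct occurrences
keyed by appearance order, so the first and second visits to the same
region keep separate duration statistics. The representative's visits are
then walked with a running occurrence counter and each visit receives the
arithmetic mean (optionally median) of its key's pooled durations.

The mean is taken over the subjects that *contain* the occurrence, not
over all subjects with zeros imputed — zero-imputation would bias spans
toward zero for rarely revisited AOIs; `duration_denominator =
"all-subjects"` exposes the alternative reading. A representative
occurrence observed in no individual sequence (possible after CDBA edits)
falls back to the statistic over all occurrences of that AOI, and an AOI
never visited at all to the grand mean; the `duration_source` column
records which rule produced each value. Duration assignment never alters
visit order or AOI identity.

## The synthetic generator, and what passing tests mean

`generate_scanpaths()` emulates the structure the pipeline assumes: K
well-separated fixation clusters (isotropic Gaussians, pairwise center
separation at least 8× the within-cluster sd when auto-placed, so layouts
are recoverable), a consensus visit order shared by the group (covering
every AOI at least once), per-subject deviations as visit skips and
adjacent transpositions, 1–3 fixations per visit (exercising the
consecutive-merge rule), lognormal visit durations (mean 250 ms, sd
100 ms — positive and right-skewed like real fixation durations), and
optional far-outlier subjects: unedited template copies rigidly
translated toward the frame corner farthest from the layout, at least 10×
the fixation spread. Defaults (800×600 px, 15 subjects, 15 px spread,
10% skip and swap rates) mirror free-viewing conditions on saliency
datasets. Identical configuration and seed reproduce a set bit for bit.

What the generator does *not* emulate bounds what green tests show:
fixation clusters in real data are anisotropic, overlapping, and
content-driven; consensus order is soft and subgroup structure is common;
calibration drift correlates errors within subjects. Passing the recovery
tests demonstrates that each stage does what it claims under its own
assumptions — not that those assumptions hold for any particular
eye-tracking dataset.

Test problem sizes were chosen to make each property sharp at desk scale:
DTW is checked against exhaustive alignment enumeration on 500 pairs of
length ≤ 6; heuristic optimality against brute force on 100 instances
with ≤ 4 AOIs and `n_max` ≤ 5; the method ordering over 50 seeded noisy
sets; layout recovery for K = 2..6 over 20 seeds each with 40 subjects
and 3 fixations per visit, so every cluster has ≥ ~120 fixations and the
0.5σ center-accuracy bound sits ≈ 4 sampling standard deviations out —
testing estimator accuracy rather than sampling luck.

## Degenerate inputs and numerical conventions

* Sets with one scanpath refuse aggregation; two scanpaths skip the
  outlier stage with a warning.
* Fully coincident fixations collapse to one AOI (all $\gamma$ equal, a
  warning is emitted, the single exemplar is the enumeration-first score
  maximum).
* Objective comparisons in tests use 1e-9 tolerances; CDBA's stopping
  rule is exact sequence equality with a 50-iteration cap.
* All tie-breaks (backtracking direction, density order, exemplar order,
  sequence enumeration, CDBA updates, IOC selection) are fixed and
  documented at the function level, so identical inputs and parameters
  reproduce identical outputs on any platform.

## Limitations

AOIs are fixation clusters, not semantic objects; a cluster spanning two
overlapping objects is one AOI. The heuristic's enumeration grows
exponentially in dense successor graphs, so large AOI counts with long
sequences should prefer CDBA. DTW here is spatial-only; duration-aware
alignment is out of scope. The boxplot outlier rule scores whole
scanpaths — within-scanpath fixation outliers are not rejected.
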