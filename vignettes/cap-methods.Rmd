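---
title: "Hierarchical co-activation pattern analysis: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical co-activation pattern analysis: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicap)
```

## The method

Co-activation pattern (CAP) analysis treats each individual fMRI volume —
not a sliding window, not a connectivity matrix — as the unit of analysis.
A volume is a snapshot of the brain's spatial activation pattern; volumes
that look alike, whenever they occurred and in whomever, are grouped
together, and the group's average image is a brain state. `hicap`
implements the hierarchical, seed-free variant of this idea:

1. **Normalization** (`temporal_normalize`). Each subject's voxel time
   series is z-scored over its retained (non-censored) volumes: subtract
   the temporal mean, divide by the temporal SD. Volumes become unitless
   deviation maps; "activation" means above that subject's own average.
2. **Stacking** (`apply_mask_and_stack`). All subjects' retained volumes
   are masked and stacked into one N × V matrix with row provenance
   (subject, original volume index).
3. **Clustering** (`cosine_distance_matrix`, `ward_linkage`). Pairwise
   cosine distances `1 − cos(x_i, x_j)` between volume vectors feed Ward
   (ward.D2) agglomeration. Cosine distance is invariant to positive
   rescaling of a volume, so spatially similar patterns at different
   amplitudes cluster together, while anticorrelated patterns are pushed
   apart; unlike the Pearson correlation it is *not* invariant to adding a
   constant, which would act like global signal regression.
4. **Nested CAPs** (`cut_levels`). The merge tree is cut at every level
   from 2 to 30 clusters. Each (level, cluster) gets a `"LL-OO"`
   level–ordinal label; because consecutive cuts of a binary tree differ
   by one split, the distinct member-sets across levels number exactly
   `2 + 2 × 28 = 58`. The registry deduplicates them and records
   parent/child (cladogram) relations.
5. **CAP maps** (`compute_cap_zmap`). Per CAP and voxel: mean over member
   volumes, standard error across them, and `z = mean / se`, quantifying
   how reliably the CAP deviates from zero at that voxel.
6. **Occupancy statistics** (`occupancy_table`, `group_median_ci`,
   `mannwhitney_fdr`). Per-subject volume counts per CAP; group medians
   with percentile-bootstrap CIs (10,000 resamples by default); two-sided
   Mann–Whitney group tests with Benjamini–Hochberg correction across all
   58 CAPs.
7. **Voxel-wise contrasts** (`build_design`, `permutation_ttest`, `tfce`,
   `pooled_fdr`). Within each CAP, a two-sample t statistic over member
   volumes contrasts the groups voxel-wise. Volumes of one subject are
   *not* independent, so the t distribution is never used: inference comes
   from permuting group labels at the subject level — a subject's volumes
   travel together, the subject being the exchangeability block. TFCE
   integrates `extent(h)^E · h^H · dh` over thresholds (E = 0.5, H = 2,
   26-connectivity, dh = max/100 — the standard defaults of the method),
   boosting spatially contiguous signal without a cluster-forming
   threshold; the permuted TFCE value at each voxel forms that voxel's
   null. Uncorrected p-maps from every CAP and both directions are pooled
   into one Benjamini–Hochberg family at q = 0.05.
8. **Network summaries** (`assign_voxels`, `cap_rsn_mean_matrix`,
   `bicluster_matrix`, `significant_fractions`). An atlas of network
   z-maps is collapsed to a partition by assigning each voxel to the
   network with the highest absolute z. The networks × CAPs matrix of mean
   z-scores is biclustered (same cosine + Ward machinery) for display; the
   percentage of each network's voxels significant per CAP and direction
   is tabulated, entries at or above the 90th percentile of nonzero
   percentages are highlighted, and a ranked report lists the largest
   CAP × direction effects with per-network `"x% (a/b)"` strings and
   26-connected component counts.

## The synthetic generator

Real resting-state data with two diagnostic groups cannot be redistributed,
so validation runs on a generator with known ground truth
(`synth_config`, `generate_dataset`). Each subject's volumes follow a
latent first-order Markov chain over two macro-states — a "DMN-positive"
state in which a default-mode-like module of networks is active and a
task-like module deactivated, and its mirror image — with optional
sub-states nested inside each macro-state. A volume is
`Σ_k a_k(state, group) · map_k + ε`, where the `map_k` are isotropic
Gaussian blobs (σ = 2 voxels, peak 1) with disjoint argmax voxels, and
`ε` is white Gaussian noise. Censoring is i.i.d. Bernoulli per volume.

Default conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| subjects | 6 + 6 (`"study"` preset: 27 + 28) | smallest size at which subject-block permutation is meaningful (C(12,6) = 924 relabelings); study preset mirrors a two-group adolescent cohort |
| volumes/subject | 100 (study: 250) | ~10 dwells per subject at the default switch rate |
| networks K | 8 (study: 14) | enough for distinct modules on a 16 × 16 × 12 grid |
| amplitudes | +1 active / −0.8 deactivated, ±35% sub-state tweaks | anti-phase modules; sub-states differ in *direction*, not scale, since cosine distance ignores scale |
| `macro_transition_prob` | 0.1 | mean dwell 10 volumes |
| `noise_sd` | 1 | matched to the peak signal amplitude |
| `censor_fraction` | 0.132 | typical adolescent motion-censoring rate |
| group effect (`"effect"` preset) | +1 on networks 1–2 during macro-state 2 | "reduced deactivation" of two default-mode-module networks, one noise SD in size |

The `"study"` preset also uses asymmetric macro leave-probabilities
(0.078 / 0.122), giving a 61/39 stationary occupancy of the two
macro-states.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: hemodynamic convolution, temporal
autocorrelation (volumes are exchangeable given the state), physiological
and motion artifacts (censoring is i.i.d., not bursty), spatial noise
correlation, and realistic network geometry. Occupancy statistics depend
only on counts, so i.i.d. censoring is adequate there; TFCE behavior on
smooth real noise fields will differ from white noise.

## Numerical and inferential choices

* **SD conventions.** Temporal normalization and the CAP-map SE both use
  the sample (n − 1) denominator; a `sd_denom = "population"` switch
  exists for parity experiments. Zero-variance voxels are set to 0 and
  flagged rather than dropped, keeping V constant across subjects.
* **Voxel order.** In-mask voxels are linearized x-fastest (R's native
  `which(mask)` order), recorded as `flat_order`; NIfTI round-trips are
  bit-exact (float64).
* **Cosine edge cases.** Zero-norm volume rows are rejected with their
  provenance; the distance matrix is symmetrized and clamped at 0 against
  floating-point drift.
* **Ties.** Ward tie-breaking follows `hclust`; ties have probability
  zero on continuous data. Atlas assignment ties go to the lowest network
  index and are counted.
* **Singleton CAPs** produce flagged (all-undefined) z-maps, not errors —
  they legitimately occur high in the hierarchy.
* **Permutation scheme.** When the distinct subject-label assignments
  number at most `n_perm`, they are enumerated exhaustively (exact
  p-values). Otherwise `n_perm` *distinct* assignments are drawn without
  replacement, excluding the observed labeling; with the observed
  labeling standing in for the identity, `p = (1 + #extreme)/(1 + n_perm)`
  never returns 0 and attains 1/(n_perm + 1). Drawing with replacement
  would re-draw the identity with high probability at small designs and
  waste resolution. A permuted assignment that empties one group's
  volumes in a CAP is counted as extreme (conservative).
* **FDR masks.** `pooled_fdr` pools every contrast direction into one BH
  family and reports both the pooled cutoff and the halved per-tail
  threshold used in two-tailed reporting. Masks default to the pooled
  cutoff: the family already contains both one-tailed directions of every
  test, and since opposite-direction p-values at a voxel sum to at least
  1, the two directions can never both be flagged. The stricter
  `mask_threshold = "per_tail"` convention is available; note that at
  validation scale (500 permutations) the halved threshold lies below the
  permutation resolution, so it can flag nothing.
* **Contrast deduplication.** A CAP persisting across several levels is
  the same member-set and hence the same test; `run_group_contrast` tests
  each unique member-set once rather than replicating identical p-maps in
  the BH family.

## What the validation suite establishes

The acceptance checks (see `tests/testthat/test-acceptance.R`) verify the
desk-reproducible arithmetic (58 unique CAPs; the 39/61 split formatting;
the .004 → .002 two-tailed mapping), equivalence of the Ward path with a
brute-force minimum-variance oracle on 200 small instances, the TFCE
closed form `h³/3` for an isolated voxel and the cubic scaling law, and
three statistical properties of the full pipeline on synthetic ground
truth:

* **Null calibration.** Voxel p-values *within* one dataset share the
  realized subject state composition and are strongly correlated — a
  single-realization uniformity test would reject for most seeds even for
  a perfectly valid procedure. Calibration is therefore assessed
  *across* 35 independent null realizations: a KS uniformity test on one
  randomly drawn voxel p-value per realization, rejection-rate bounds
  (α + 0.025 at α = 0.05, α + 0.015 at α = 0.01, fixed in advance)
  averaged over realizations, and binomial 99% bounds on one randomly
  chosen occupancy test per clustered realization.
* **Effect recovery.** With the default injected effect (one noise SD,
  6 + 6 subjects, 500 permutations, level-2 contrasts), at least 80% of
  the affected networks' FWHM-core voxels (map ≥ half peak — the
  conventional extent of a Gaussian blob) are flagged at q = 0.05, and
  the network-summary column maximum lands on an affected network. At the
  blob periphery the injected amplitude decays to ~0.1 SD and is not
  recoverable by any method at this sample size; peripheral voxels are
  deliberately excluded from the recovery denominator. Note that a
  6 + 6-subject design with 500 permutations operates near its detection
  limit: the permutation null is shared across voxels, so dataset
  realizations close to the threshold can tip either way, and the check
  is defined at the fixed validation seed.
* **State recovery.** Noiseless data cluster perfectly at level 2
  (adjusted Rand index 1 against the ground-truth macro-states); with
  noise matched to the signal amplitude the ARI stays at or above 0.8.

Problem sizes throughout (6 + 6 subjects × 100 volumes ≈ 1,000 stacked
volumes, ~1,800 in-mask voxels, 500 permutations) are the package's
chosen validation scale; the same code paths run unchanged at study scale
via `synth_preset("study")`.

## Known limitations

* Exact Ward requires the full N × N distance matrix: memory grows as
  O(N²) (~1 GB near N = 12,000).
* The per-volume t statistic ignores within-subject correlation by
  design; its validity rests entirely on subject-level permutation, so it
  should never be compared against a t distribution.
* Within-level CAP ordinal numbers follow leaf order of first appearance;
  other implementations may number differently, so cross-study label
  matching needs the member-set registry, not the labels.
* With few subjects, permutation p-values are coarse
  (multiples of 1/(n_perm + 1) or of the enumeration count); FDR
  thresholds below that resolution cannot flag anything.
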