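---
title: "Scoring 3' splice sites and modelling their drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring 3' splice sites and modelling their drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchsense)
```

# Background

Small molecules that bind SF3B1, the largest subunit of the U2 snRNP SF3B
complex, interfere with branch point (BP) recognition during spliceosome
assembly. At moderate doses they do not shut splicing down globally:
individual 3' splice sites respond very differently, from complete intron
retention or exon skipping to no measurable change. The differential
response is encoded in the pre-mRNA sequence itself — transferable sequence
elements 5' of the BP modulate sensitivity, and the strength of the BP and
the polypyrimidine (Py) tract, intron length and GC content all correlate
with the outcome. branchsense implements the computational side of that
analysis and a synthetic data model rich enough to exercise every step with
known ground truth.

This vignette documents the models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions that were
genuinely open.

# Coordinate and sequence conventions

* On disk, intervals are BED: 0-based, half-open. Intron sequences are
  always handled on the sense strand of transcription (minus-strand BED
  records are reverse-complemented on reading), so the last two characters
  of a correctly annotated intron are the 3' splice site AG.
* All intron-internal offsets are negative positions with −1 the last
  intron nucleotide (the G of the AG), −2 the A, and so on 5'-wards. "The
  3' 150 nucleotides" therefore means positions −150..−1.
* Sequences are upper-cased and U is converted to T on input. `N` is
  treated conservatively everywhere: it never matches any IUPAC motif
  symbol (not even pattern `N`), scores 0 in the U2 pairing register,
  contributes background odds (0) in PWM scans, takes the most disruptive
  weight in Py-tract scoring, and is excluded from both numerator and
  denominator of GC content.

# Branch point scoring

## U2 pairing score

The BP region pairs with the GUAGUA recognition register of U2 snRNA, with
the branch adenosine bulged out of the helix. `u2_pairing_score()` scores a
heptamer whose position 6 is the putative branch nucleotide: the six paired
positions contribute +1.0 for the Watson–Crick partner of the U2 base, +0.5
for a G:U wobble (a G opposite a U2 uridine at heptamer positions 2 and 5,
a T opposite a U2 guanosine at positions 3 and 7), and 0 otherwise:

```{r}
u2_pairing_score(c("TACTAAC", "CTCTCAC", "TTTTTTT"))
```

The score lies in [0, 6] and is maximal only for TACTAAC, the optimal BP
sequence from yeast to mammals. The scale is deliberately simple — a
hydrogen-bond count rather than a thermodynamic stacking model — because
the analyses that consume it only compare distributions between event
groups.

## Candidates, decoys and tie-breaking

`bp_candidates()` enumerates every heptamer whose branch nucleotide lies in
the 3' `bp_window` (default 150 nt) and at least 3 nt from the intron end
(the terminal AG plus one nucleotide cannot host a branch for geometric
reasons; this floor is our choice, not an empirical value). Candidates
without an adenosine at position 6 are *decoys*: sequences that can pair
with U2 snRNA but cannot form the 2'-5' lariat bond. They are retained in
the candidate table for reporting — decoy engagement is a real phenomenon
under drug treatment — but are never selected as the best functional BP.

The best functional BP maximises the pairing score, with ties broken first
by the SF1 PWM score of the heptamer and then toward the 3'-most candidate
(when several BPs are available, splicing tends to use the most 3' one).
`bp_distance` is the distance of the chosen branch nucleotide from the 3'
splice site.

## SF1 PWM score

The BP strength proxy used alongside pairing is the maximal binding score
of an SF1 position weight matrix over the 3' window: the maximum over all
windows of the summed per-base log2 odds against a uniform background.
The bundled matrix (`sf1_pwm()`) is a declared stand-in built from the
degenerate BP consensus YNYYRAY, with each position spreading its weight
equally over the allowed bases and a 0.01 pseudocount; the published SF1
matrix is not redistributable here, and users who have it can load it with
`read_pwm()`. A trained support-vector BP model is likewise out of scope —
the deterministic pairing + PWM pair plays that role and is documented as
such. Within `pwm_max_score()`, ties go to the 3'-most window.

# Py-tract scoring

No standard closed-form Py-tract score exists; branchsense defines one:
the maximum-sum contiguous segment of the region between the BP heptamer
and position −3 (the heptamer's own 3' base and the terminal AG are
excluded) under per-base weights T = +1.0, C = +0.5, A = −1.5, G = −2.0.
The weights encode two observations: C-rich tracts are weaker than T-rich
tracts of the same length, and purines — especially G — disrupt U2AF65
binding more than they dilute it. The empty segment is allowed (score 0),
and ties are resolved toward the segment closest to the 3' end. The
implementation is a prefix-sum scan; the tests hold it against an
exhaustive enumeration of all O(n²) segments.

# Multi-BP counting and RNA maps

`count_bp_matches()` counts degenerate matches of YNYYRAY within the 3'
100 nt (both the consensus and the window width follow the published
convention) and partitions events into zero, single-BP ("1 BP") and
multi-BP ("BPs") classes. `rna_map()` generalises this to positional
profiles: for groups of 3'-aligned sequences, the fraction of sequences in
which a motif match covers each position −W..−1, smoothed with a centered
moving average (default 15 nt, partial windows at the edges). Sequences
shorter than the window contribute only where defined.

# Splicing quantification and classification

PSI (cassette exons) and PIR (retained introns) are junction-count ratios:

$$\mathrm{PSI} = 100\,\frac{i_1 + i_2}{i_1 + i_2 + 2e}, \qquad
  \mathrm{PIR} = 100\,\frac{(e_{i1}+e_{i2})/2}{(e_{i1}+e_{i2})/2 + e_e}.$$

These are stand-ins for a full read-rescaling quantifier: they are
scale-invariant, monotone in the expected directions, and sufficient for
threshold-based classification, which is all the downstream analyses use.
Per-replicate values are averaged within each condition before
Δ = treated − control. Classification uses closed thresholds: |Δ| ≥ 25
regulated (sign gives direction), |Δ| ≤ 5 non-differential, in between
intermediate; events with fewer than `min_reads` (default 10) informative
reads in either condition are `low_coverage` regardless of Δ. The
published analysis pipeline reports per-event quality scores whose exact
read thresholds are not documented; the 10-read floor is our configurable
default.

# Group statistics

Feature comparisons use the two-sided Mann–Whitney U test: exact
enumeration when min(n₁, n₂) ≤ 8 with no ties (the enumeration bound keeps
C(n₁+n₂, n₁) tractable), otherwise the normal approximation with tie and
continuity corrections. Enrichment against a detection universe uses the
Pearson χ² on the 2×2 table without Yates correction; replicate-level
validation uses Welch's t. Significance stars follow the figure-legend
convention * p < 0.01, ** p < 0.001, *** p < 0.0001, with raw p values
always reported and no multiplicity correction applied (matching the
source convention; a Benjamini–Hochberg column is trivial to add with
`p.adjust` if wanted). The expression–splicing correlation defaults to
Pearson on log10(FPKM + 1) — the estimator and transform are not named in
the source, and FPKM is heavy-tailed enough that the log is the defensible
default; a raw-FPKM option exists. Heatmap ordering is agglomerative
hierarchical clustering with Euclidean distance and complete linkage, with
rows containing missing values dropped and reported. Boxplot summaries are
Tukey (type-7 quartiles, whiskers at 1.5 IQR); outliers are hidden in
plots but never excluded from tests.

# The synthetic cohort generator

`sim_params()` fixes the study conditions. Each intron is random sequence
at a Beta(14, 16) GC target (mean 0.47, realistic for human introns) with
length drawn log-normally (μ = 3.2, σ = 0.55 in log10 nt, truncated to
70–100,000 nt; the median of ~1.6 kb and the long right tail mimic human
intron length distributions, for which we only have boxplot-level
guidance). Into this background the generator plants:

* one BP heptamer from a pool spanning pairing scores 3–6, with its start
  offset uniform in −40..−18 (covering the common BP distance range);
* a Py tract of strength drawn uniform in [0, 1], controlling both length
  (8–24 nt) and T-richness, placed directly 5' of position −3 and clipped
  so it never overwrites the BP;
* with probability 0.5, one or two additional YNYYRAY-conforming
  heptamers in −100..−41 (the "protective element" region);
* a forced terminal AG.

The drug response is logistic in the standardized planted features,

$$\Delta = \Delta_{\max}\,
  \sigma(\beta_0 - \beta_{bp} z_{bp} - \beta_{ppt} z_{ppt}
         - \beta_{len} z_{len} + \beta_{gc} z_{gc} - \beta_{multi}\,m),$$

positive for retained introns and negative for cassette exons, with
defaults β = (0, 1, 1, 1, 1, 1) and Δmax = 60. Observed treated values add
N(0, 3) event-level noise (the visual spread of triplicate minigene PSI
measurements), and junction counts are Binomial at per-sample
negative-binomial coverage (mean 50, size 10, two replicates per
condition). Host-gene FPKM is log-normal and independent of the response
by default — a built-in null for the expression–splicing correlation — and
the full planting record is retained for recovery tests. Generation is
fully deterministic given the seed.

What the generator does *not* emulate: alternative 5' splice sites,
overlapping or nested events, mappability and positional read biases,
quality-score-based coverage filters, transcript-level interdependence
between events of one gene, and any chromatin context. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers effects
of the kind and size planted — not that real drug-treated transcriptomes
have those effects.

# Recovering the response model

`fit_response()` closes the loop: given per-event features and observed Δ,
it refits the logistic coefficients by ridge-regularised IRLS (λ = 1e-4 on
the slopes, intercept unpenalised, convergence at max |step| < 1e-8 or 100
iterations). Two response codings are available, and the difference is a
genuine methodological point:

* **binary**: code each event as regulated (|Δ| ≥ 25) or not and fit
  logistic regression. Because the underlying response is a thresholded
  deterministic function plus noise, the binary likelihood identifies the
  *direction* of β well but its scale absorbs the inverse of the noise
  scale: at the default study conditions the fitted slopes come out
  roughly 2.5× the planted values, and on noiseless data they diverge
  (the classes become separable and only the ridge bounds them).
* **fractional** (default): fit the generative mean model directly,
  regressing |Δ|/Δmax on the features with a logistic link
  (quasi-binomial IRLS, same machinery). This uses the continuous
  response the binary coding throws away and recovers both signs and
  magnitudes — at n = 5,000 the per-coefficient relative error is about
  0.2, dominated by measurement noise in Δ.

Both estimators are exposed and tested; the fractional fit is the default
because parameter recovery — the purpose of the harness — is only
well-posed for it.

```{r, eval = FALSE}
sim <- generate_event_set(sim_params(n_events = 5000, seed = 1))
quant <- quantify_events(sim$events, "DMSO", "SudC1")
fit <- fit_response(truth_features(sim$truth), quant$delta)
tidy(fit)
```

# Problem sizes and determinism

The shipped analyses use cohorts of 2,000 events for group comparisons
(regulated and non-differential groups of several hundred events each,
comfortably powering the Mann–Whitney comparisons at the planted effect
sizes), 5,000 events for coefficient recovery, and 250 events for the
bundled demo pipeline. All randomness flows from the single seed in
`sim_params()` through R's default RNG under `withr::with_seed()`, so
every table the pipeline writes is byte-identical between runs with the
same config; the run manifest records MD5 checksums of all outputs.

# Known limitations

* The Py-tract weights and the U2 pairing scale are ordinal scoring
  devices; absolute values have no thermodynamic meaning.
* The SF1 matrix is a consensus-derived stand-in; with the published
  matrix the `bp_best_pwm` feature would discriminate more sharply (the
  stand-in saturates on any intron containing a perfect YNYYRAY match).
* PSI/PIR ignore read-length and mappability rescaling, so values are not
  numerically comparable to full quantifiers on real data, only to
  themselves.
* `quantify_events()` compares exactly two conditions; multi-drug designs
  are handled by quantifying per drug and combining with
  `regulated_sets()` / `overlap_matrix()`.
* Branch candidates require the branch A at heptamer position 6;
  non-adenosine branch points (rare but documented) are visible only as
  decoys.
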