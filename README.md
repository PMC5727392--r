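# branchsense

Why do some 3′ splice sites respond to SF3B1-targeting splicing modulators
(Spliceostatin A, Sudemycins) while others resist? The drug response of a 3′
splice site tracks the sequence context of its intron 3′ end: the strength of
the branch point (BP), the polypyrimidine (Py) tract, intron length and GC
content, and — strikingly — the presence of *additional* BP-like sequences 5′
of the main BP, which protect against the drug. `branchsense` packages that
analysis for computational splicing biologists: sequence-feature scoring of
intron 3′ ends, PSI/PIR splicing quantification from junction read counts,
event classification, group statistics and RNA maps, cross-drug set
comparisons, and a synthetic-cohort generator with planted, recoverable
effects so the whole pipeline can be validated end to end without any
sequencing data.

## The model at the core

**Branch point strength** is scored as base-pairing potential between an
intronic heptamer and the GUAGUA recognition register of U2 snRNA. With the
branch adenosine (heptamer position 6) bulged out and unscored, each of the
six paired positions contributes +1 for the Watson–Crick partner, +0.5 for a
G:U wobble, 0 otherwise, so the score lies in [0, 6] and the optimal yeast
consensus TACTAAC — and only it — scores 6. An SF1 binding score is computed
in parallel as the maximal log2-odds of a position weight matrix over the 3′
150 intronic nucleotides (the bundled matrix is a stand-in built from the
degenerate BP consensus YNYYRAY; a published SF1 PWM can be supplied).

**Py-tract strength** is the maximum-sum contiguous segment under per-base
weights T = +1, C = +0.5, A = −1.5, G = −2 on the region between the BP and
position −3, so long T-rich tracts outscore short or C-interrupted ones.

**Splicing quantification** follows the junction-ratio definitions

```
PSI = 100 · (inc1 + inc2) / (inc1 + inc2 + 2·exc)        (cassette exons)
PIR = 100 · mean(ei1, ei2) / (mean(ei1, ei2) + ee)       (retained introns)
```

with replicate averaging per condition before ΔPSI/ΔPIR = treated − control.
Events with |Δ| ≥ 25 are regulated, |Δ| ≤ 5 non-differential, and groups are
compared feature by feature with two-sided Mann–Whitney U tests (stars:
\* p < 0.01, \*\* p < 0.001, \*\*\* p < 0.0001).

**The synthetic generator** plants a BP heptamer, a Py tract of drawn
strength, and (with probability 0.5) extra YNYYRAY matches into random intron
sequence, then draws the drug response from a logistic model

```
Δ = Δmax · logistic(β0 − βbp·z_bp − βppt·z_ppt − βlen·z_len + βgc·z_gc − βmulti·multi)
```

so that weak BPs and Py tracts, short and GC-rich introns respond and extra
BPs protect. Junction counts are binomial at negative-binomial coverage, and
the planted truth is retained for recovery tests.

## Worked example

```r
library(branchsense)
cfg <- system.file("extdata", "demo_config.json", package = "branchsense")
manifest <- run_pipeline(cfg, out_dir = "demo_run")
report_run(manifest)
```

```
branchsense 0.1.0 run (seed 7): 250 events
  classes: regulated_up=72, regulated_down=47, intermediate=84, nondiff=47
  feature comparisons (regulated vs nondiff, Mann-Whitney two-sided):
    bp_best_pairing  median        5 vs      5.5  p = 1.04e-07 ***
    bp_best_pwm      median     6.82 vs     6.82  p = 0.0913 n.s.
    ppt_score        median        5 vs      9.5  p = 7.61e-06 ***
    gc_intron        median    0.489 vs    0.409  p = 7.45e-06 ***
    len_intron       median 1.09e+03 vs 3.01e+03  p = 1.2e-06 ***
  |delta| multi-BP vs single-BP: median 21.5 vs 35.5, p = 0.00584 *
```

Reading the output: of 250 simulated events, 119 crossed the |Δ| ≥ 25
regulation threshold. Regulated events have weaker branch points (median U2
pairing 5 vs 5.5), weaker Py tracts (5 vs 9.5), higher GC (0.489 vs 0.409)
and are roughly threefold shorter (1.1 kb vs 3.0 kb) than non-differential
events — each the direction the planted model encodes — and events carrying
multiple BP consensus matches in their 3′ 100 nt change about 14 points less
than single-BP events. Every TSV written to `demo_run/` (features,
quantification, comparisons, RNA map profile, manifest with checksums) is
byte-identical on re-run with the same config.

The individual pieces compose with the pipe, e.g.

```r
sim <- generate_event_set(sim_params(n_events = 500, seed = 42))
sim$introns |>
  score_introns() |>
  dplyr::left_join(quantify_events(sim$events, "DMSO", "SudC1"),
                   by = c(name = "event_id")) |>
  compare_features("class", "regulated_up", "nondiff")
```

A thin command-line wrapper with `simulate`, `features`, `quantify`,
`compare`, `rnamap`, `run` and `report` subcommands is installed at
`system.file("cli", "branchsense.R", package = "branchsense")`.

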