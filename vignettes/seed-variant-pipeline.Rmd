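---
title: "Methods: allele-aware seed-site scanning and candidate-variant statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-aware seed-site scanning and candidate-variant statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvar)
```

`mirvar` chains four analyses around one scientific question: does a
single-nucleotide substitution in a 3′UTR create a microRNA binding site,
and does carrying that substitution associate with disease status and with
intermediate phenotypes? This vignette documents the models, the
conventions, the tunable parameters, and the design choices made where the
underlying methodology leaves the design genuinely open.

## Seed matching model

A miRNA recognises most of its targets through its *seed*, nucleotides 2–7
counted from the 5′ end. `scan_sites()` performs an exhaustive search: every
6-nt UTR window that is the perfect Watson–Crick reverse complement of a
seed (U ≡ T across the RNA/DNA boundary) is a candidate site. Because the
duplex is antiparallel, a window starting at UTR position *s* pairs miRNA
nt 7 down to nt 2; the UTR base at *s* − 1 sits opposite miRNA nt 8, and
the base at *s* + 6 sits opposite nt 1 (the "A1" position).

Each match is classified by the canonical upgrade rules and reported once,
at the single highest class it attains:

| class | condition beyond the 6mer | footprint |
|---|---|---|
| `6mer` | — | 6 nt |
| `7mer-m8` | UTR base 5′ of the window pairs miRNA nt 8 | 7 nt |
| `7mer-A1` | UTR base 3′ of the window satisfies the A1 rule | 7 nt |
| `8mer` | both | 8 nt |

Two deliberately separated quantities are reported per site:

* `site_type` — the canonical class above;
* `match_len` — the length of the maximal *contiguous* run of perfect
  Watson–Crick pairs through the seed, extending 5′-ward on the UTR against
  miRNA nt 8, 9, … until the first mismatch or a sequence end, and counting
  the A1 position when it actually pairs nt 1.

The separation matters because an "8-base binding site" can mean either a
canonical 8mer (A1 + m8) or 8 contiguous pairs spanning miRNA nt 1–8; the
two readings coincide only when miRNA nt 1 is a U. Reporting both makes
either reading checkable without committing the scanner to one.

**A1 rule.** The canonical convention is that the UTR base opposite miRNA
nt 1 must be an adenine regardless of whether it pairs (target-site A1s are
recognised by the silencing complex as an A, not as a pair). That is the
default (`a1_rule = "adenine"`); `a1_rule = "pair"` requires a Watson–Crick
pair instead, for users who want the strict-duplex reading.

**Other matching conventions.** `N` never pairs and windows containing `N`
never match. G:U wobble is never counted as a pair: the scan is defined by
perfect complementarity. Only the sense (mRNA) strand is scanned. Two
miRNAs with identical seeds yield two sites — the de-duplication identity
is (`mirna_id`, `start`, `site_type`). Output order is deterministic
(`start`, then `mirna_id`).

**Allele diffing.** `diff_sites()` scans both alleles of a
single-nucleotide variant and compares the site lists under the identity
key. Sites present only on the alternate allele are *gained*; only on the
reference allele, *lost*. Because only substitutions are supported (indels
are rejected), coordinates are directly comparable across alleles, and
swapping ref/alt in the variant exchanges the gained and lost sets exactly
— a property the test suite checks on 1,000 random variants. The default
report keeps only sites whose footprint covers the variant position, since
a substitution can only change windows it touches; `report = "all"` adds
the allele-invariant sites with status `"unchanged"`.

The implementation finds overlapping window matches with a compiled
lookahead regular expression per unique seed target; the test suite proves
it equal, site for site, to a naive window-by-window enumeration oracle on
1,000 random UTR/library instances (UTR ≤ 200 nt, ≤ 50 miRNAs) — two
independently written routes to the same definition.

**Coordinates.** c.\* numbering is 1-based: position 1 is the first base 3′
of the stop codon. Site spans are 1-based inclusive. Which UTR span to scan
is left to the user-supplied FASTA; the scanner imposes no assumption about
how much of the UTR is provided.

## Association model

`test_association()` analyses a biallelic variant in a case–control design.
The default model is the **carrier (dominant) 2×2 table**: subjects are
classified by presence of at least one minor allele. This is the natural
model when no homozygous-minor subjects are observed, and it is the model
under which the published summary statistics of the motivating study are
internally consistent; an allele-count model (two alleles per subject) is
available via `model = "allele"`.

* **χ² test**: Pearson's statistic without Yates continuity correction
  (`yates = TRUE` to enable), two-sided, df = 1. The no-correction
  convention is what standard association practice uses at these counts.
* **Odds ratio**: `(a·d)/(b·c)` with the Woolf logit interval. If any cell
  is zero, the Haldane–Anscombe correction (+0.5 everywhere) is applied to
  both estimate and interval, so degenerate tables never error.
* **Fisher's exact test**: the conventional conditional two-sided rule —
  sum of hypergeometric probabilities of tables at most as probable as the
  observed. The implementation delegates to `stats::fisher.test`; the test
  suite verifies it against an explicit enumeration oracle exhaustively for
  all tables up to n = 16 and on seeded random tables up to n = 40 (the
  p-value depends on the table only through its margins and one cell, so
  the sampled sizes add no untested structure).
* **MAF**: minor-allele count over 2n, oriented to ≤ 0.5, with a percent
  rendering at caller-chosen display precision.

No multiple-testing adjustment is applied at this level: the pipeline
analyses a single candidate variant. Genotype strings are unordered pairs
("C/T" ≡ "T/C").

`af_study_genotypes()` ships the motivating cohort as a *reconstruction
built in code*: 15/378 case carriers are printed directly; the control
carrier counts (28 of 1576 long-lived, 4 of 294 healthy) are recovered from
the printed control MAFs of 0.9 % and 0.7 % and validated by exact
agreement with the printed odds ratio and p-value. Per-subject rows are
synthetic; only the group-level counts are meaningful.

## Phenotype comparisons

Continuous phenotypes (ECG intervals in ms, expression values) are compared
with:

* `two_sample_t()` — unpaired, two-sided; default `"student"` (pooled
  variance, df = n₁+n₂−2), which is both the stated convention of the
  motivating analyses and the GraphPad default; `"welch"` by flag.
* `paired_t()` — one-sample t on within-pair differences.
* `anova_sidak()` — one-way omnibus F, then *planned* pairwise comparisons
  using the pooled within-group mean square (t, df = N−k), Šidák-adjusted
  over the m requested comparisons: `p_adj = 1 − (1−p)^m`. The adjustment
  family is the explicit comparison list (e.g. each treatment against one
  control), not all pairs — adjusting over all pairs when only three were
  planned would be needlessly conservative.

Summaries are mean ± SEM (`group_summary()`). Conventions for degenerate
input: groups of n = 1 report a mean but a missing SEM and refuse tests;
zero variance with unequal means is an error rather than an infinite
statistic; missing values are dropped per comparison with counts reported.
All tests are two-sided. Per-cohort p-values of the motivating study are
not reproducible from published data (raw per-subject values are not
printed), so the suite validates these functions on closed-form worked
examples and on simulation, not on cohort values.

## qPCR quantification

Plasma miRNA has no validated endogenous housekeeping normaliser, so
quantification is against an exogenous spike-in added at fixed amount per
fixed plasma volume: `value = 2^−(Ct_target − Ct_spike)`. Tissue mRNA is
normalised to a housekeeping gene the same way. Conventions:

* ΔCt is computed on **mean Cts** per replicate set (the common instrument
  convention), not on per-replicate pairings.
* **Replicate outlier rule**: triplicates with a maximum pairwise spread
  above 1.0 cycles (configurable) drop the single replicate farthest from
  the median before averaging. The threshold is a pragmatic instrument
  default; the rule is deterministic and affects at most one replicate.
* Spike-in volumes (plasma volume, spike amount) are metadata: no
  volumetric correction is applied beyond the stated formula.
* Group fold changes are ratios of group means of the per-sample values,
  computed on the linear 2^−ΔCt scale by default. Whether group comparisons
  should be run on the linear or log₂ scale is genuinely open; the values
  column is trivially log-transformable and the choice is the caller's.
* Dual-reporter assays: per-well reporter/normaliser ratio (orientation
  configurable, since transactivation and 3′UTR constructs put the
  experimental reporter on opposite channels), averaged per condition,
  divided by a designated control condition. Fold changes are invariant to
  any global luminescence scale factor.

## Synthetic data: what it emulates and what it does not

The generators in `sim_config()` / `simulate_study()` produce data with the
statistical structure the analyses assume, at the magnitudes of the
motivating study:

* cohort sizes 378 cases / 1870 controls (split 1576:294 between control
  groups), carrier probabilities 15/378 and 32/1870 — generating carrier
  odds ratio 2.37;
* PR interval normal with a +45 ms carrier shift on a 165 ms non-carrier
  mean (SD 25 ms), so carrier means sit above the 200 ms prolongation
  threshold; RR/QRS/QT genotype-independent normals at typical adult values
  (900/95/400 ms). Exact cohort means and SDs are not published, so these
  are illustrative magnitudes, and recovery tests target the *generator's*
  parameters, not cohort values;
* plasma target Ct normal around 30 cycles (SD 0.8) with a +log₂(3) ≈ 1.585
  cycle carrier shift — an expected threefold expression decrease, exact in
  the zero-noise limit; spike-in Ct around 20 cycles (SD 0.3); triplicate
  technical noise SD 0.1 cycles;
* UTR background uniform over {A,C,G,T} (no GC bias), 200 nt; libraries of
  50 uniform random 22-nt miRNAs;
* `plant_gain_variant()` constructs a UTR/variant pair where the alternate
  allele carries exactly one site of a requested class for one miRNA,
  overlapping the variant, and the reference allele carries none — verified
  internally by scanning both alleles and resampling the background within
  a bounded retry budget. Flanking bases are set so the planted site is
  exactly the requested class and the paired run ends at the intended
  footprint, making planted-site properties deterministic.

Deliberately **not** emulated: linkage disequilibrium and population
structure, Hardy–Weinberg sampling of homozygous-minor genotypes (off by
default; none were observed in the motivating cohort), realistic Ct
right-skew or amplification-efficiency variation, GC-content bias, and any
correlation between ECG intervals. Passing tests therefore demonstrate that
the pipeline recovers what it was fed under its own model assumptions — not
that those assumptions hold in real cohorts.

All generators are pure functions of (config, seed): the same seed gives
byte-identical output, and the CLI `simulate` subcommand writes a manifest
recording the full configuration.

## Validation problem sizes

The test suite validates at these sizes, chosen to exercise the properties
at full strength while keeping a complete run in a few minutes: 1,000
random scanner instances against the enumeration oracle and 1,000
random-variant diff-symmetry checks; exhaustive Fisher enumeration to
n = 16 plus 1,500 random tables to n = 40; 500 simulated cohorts at the
study's sample sizes for odds-ratio recovery (median within ±20 % of the
generating value 2.37, Woolf CI coverage within [93 %, 97 %]) and 500 under
the null (median OR in [0.8, 1.25]); 200 replicates for the
uniform-p-value null calibration of the PR t test.

## Known limitations

* Only single-nucleotide substitutions; no indels, haplotypes, or
  multi-variant interactions.
* No thermodynamic or context scoring of sites: a seed match is treated as
  a site, which over-calls relative to experimentally validated targeting.
* The association module is a single-variant analysis: no covariates,
  no logistic regression, no genome-wide error control.
* Ct processing starts from cycle thresholds; no raw-fluorescence QC,
  standard curves, or efficiency correction.
* The reconstructed study cohort reproduces published *summary* counts
  only; per-subject structure in it is synthetic.
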