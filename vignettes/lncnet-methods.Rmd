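---
title: "Methods: co-expression and TF-overlap network analysis of lncRNA/mRNA arrays"
author: "lncnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression and TF-overlap network analysis of lncRNA/mRNA arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

## The problem

Single-channel expression microarrays that probe long non-coding RNAs
(lncRNAs) and mRNAs on the same chip are a standard way to screen for
transcripts that respond to a treatment — for example, a dietary
intervention in an atherosclerosis-prone mouse strain, contrasting a
normal-diet and a high-fat-diet group of three animals each. The lncRNAs
themselves are mostly unannotated, so the analysis leans on two
guilt-by-association ideas:

1. an lncRNA inherits candidate functions from the mRNAs it is
   co-expressed with, via over-representation of those mRNAs in functional
   term sets; and
2. an lncRNA is a candidate target of a transcription factor (TF) when its
   co-expressed mRNA set overlaps that TF's known target genes more than
   chance would allow.

`lncnet` implements the full chain — preprocessing, differential
expression, co-expression, enrichment, TF inference, network construction,
and qPCR concordance — as composable functions with a one-command driver
(`run_full()`), plus a synthetic-data generator whose planted structure
makes every step's recovery testable.

## Pipeline model, stage by stage

**Quantile normalization** (`quantile_normalize()`). Each column's sorted
values are replaced by the across-column mean of sorted values, forcing
identical empirical distributions. Ties within a column receive the mean
of the sorted-mean values over the tied rank span — a deterministic rule
that is symmetric in the tied entries. This differs from interpolation-style
tie handling (as in `limma::normalizeQuantiles`) only for ties spanning
three or more ranks; on tie-free data the two agree to machine precision,
which the test suite verifies.

**Detection-flag filtering** (`filter_by_flags()`). A probe is kept iff
*all* samples of at least one group carry the Present flag. With three
samples per group this demands a fully consistent detection in either
condition. A laxer reading — at least one `P` anywhere — exists as
`rule = "any_present"` but is not the default, because the strict rule is
the one that gives the filter any real bite at n = 3. Normalization runs
before filtering by default (`preprocess()`); the opposite order is
available for sensitivity checks.

**Log2 transform** (`log2_transform()`). Fold changes and t-tests operate
on log2 intensities. The default offset of +1 guards zeros from scanner
output; the transform refuses to run twice (`scale` is tracked in the
dataset object).

**Differential expression** (`differential_expression()`). Per-probe
two-sample t-test with fold change defined on log2 group means (a
geometric-mean fold change). A probe is differentially expressed when
FC ≥ 2.0 *and* p ≤ 0.05, both boundaries inclusive. Raw p-values are used
for calling, as is conventional for this array-screen design; BH-adjusted
values can be obtained with `bh_adjust()` but are deliberately not part of
the default call. The default test variant is Welch (unequal variances),
which is the safer choice on real arrays where variance heterogeneity
between groups is common. Note that at n = 3 per group the
Welch–Satterthwaite approximation is conservative: its true null size is
about 0.035 at nominal 0.05 (the suite measures this). Calibration
checks that assert an *exact* 5% null rejection rate therefore run the
Student variant, which is exact under homoscedastic Gaussian noise — the
regime the synthetic generator produces. Probes with zero variance in both
groups are never `NaN`: equal means give p = 1, unequal means give the
smallest representable positive double and a `zero_variance` flag.

**Co-expression** (`coexpression_pairs()`). Pearson correlation of every
DE lncRNA probe against every DE mRNA probe, across all samples pooled.
With three samples per group a within-group correlation carries almost no
information (one degree of freedom), so pooling is the default; note that
pooled correlations partly reflect the shared group effect, which is
exactly what makes co-responding transcripts correlate. The p-value uses
the t transform `t = r sqrt((m−2)/(1−r²))` with m − 2 degrees of freedom.
Pairs are ranked by p (ties by |r|, then ids) and the top 500 feed
enrichment; "top 500" is a global count over pairs, not per-lncRNA. An
lncRNA's *correlated set* is the distinct symbols of its mRNA partners
with p < 0.05.

**Enrichment** (`enrich()`, `hypergeom_upper_tail()`). The
over-representation p-value is the hypergeometric upper tail
P[X ≥ k], accumulated in log space via `lchoose` so that extreme
parameters neither overflow nor lose precision; results that underflow the
double range are floored at the smallest positive double to preserve the
(0, 1] contract. The universe defaults to the mRNA symbols actually
measured on the filtered array intersected with the collection's declared
universe — an array experiment queries array genes, and a genome-wide
universe would inflate significance. GMT files carry no universe, so the
pipeline accepts an explicit background list (`universe` input); without
one, the member union is used. BH FDR is reported alongside raw p; raw p
orders the output.

**TF inference and networks** (`tf_associations()`,
`build_lncrna_tf_network()`, `build_lncrna_target_tf_network()`). Each
lncRNA's correlated set is tested against every TF target set; all
(lncRNA, TF) pairs are reported (including k = 0 with p = 1), pooled, and
ordered globally by p. Duplicate pairs (multiple probes of one symbol)
keep their best p. The TF network takes the top 200 pairs as TF → lncRNA
edges. The tripartite network around the 20 strongest DE lncRNAs (10 up,
10 down, ranked by |log2FC|) combines the top 100 association records with
the top 200 correlation records, restricted to those lncRNAs; "top 100
TFs" is resolved as the 100 best association records globally rather than
per lncRNA. Edges carry −log10 p weights for Cytoscape; SIF and GraphML
writers round-trip through igraph.

**qPCR concordance** (`delta_delta_ct()`, `concordance_report()`).
Relative quantification assumes 100% amplification efficiency (one cycle
per doubling): ΔCt = Ct(target) − Ct(reference) per sample, ΔΔCt is the
treatment-minus-control difference of group means, RQ = 2^(−ΔΔCt), so
log2(RQ) = −ΔΔCt identically. Per-sample RQs are anchored at the
control-group mean ΔCt; group significance uses an unpaired Student's
t-test on ΔCt. The concordance report compares RQ direction with the array
direction of the best-supported probe per symbol.

## The synthetic generator

`generate_dataset()` draws log2 intensities from a latent-factor model:

    y_is = baseline_i + Δ_i·1[s ∈ treatment] + Σ_t β_it a_ts + ε_is

with Δ_i = ±`planted_log2fc` for a `de_fraction` of probes, β_it = 1 iff
probe i belongs to TF t's module (disjoint modules of `module_size` target
mRNAs and `n_regulated_lncrnas_per_tf` lncRNA probes), activities
a_ts ~ N(0, `tf_activity_sd`) and noise ε_is ~ N(0, `noise_sd`).
Intensities are exported as 2^y; Absent flags are assigned with
probability `flag_absent_rate` to lowest-decile intensities only, so the
flag filter is exercised where real absent calls live. The TF target GMT
is built *exactly* from the planted modules, making "TF targets overlap
the co-expressed set" literally true in the generative process — the
hypergeometric inference has a recoverable signal by construction. Two
probes sharing a module have expected Pearson correlation
`tf_activity_sd² / (tf_activity_sd² + noise_sd²)`; at the defaults
(1 and 0.5) that is 0.8, and the suite checks the empirical mean over 200
planted pairs against this closed form.

Defaults mirror a small two-group array study: 3 + 3 samples, 2,000 lncRNA
and 3,000 mRNA probes (a desk-scale stand-in for a 180K-feature chip),
baseline log2 intensities N(8, 1.5), 10 TFs with 30 targets and 5
regulated lncRNAs each, 5% planted DE at |log2FC| = 3, noise s.d. 0.5.
Generation is a pure function of the seed; the caller's RNG state is
restored afterwards.

The synthetic qPCR table uses Ct = c0 − y with the same planted effects
and a reference gene with no group effect, so in the noiseless limit
RQ = 2^(planted log2FC) exactly.

What the generator does *not* emulate: probe-level cross-hybridization,
dye or spatial artifacts, batch structure, heavy-tailed or heteroscedastic
noise, correlated TF activities, and symbol multiplicity (each probe maps
to its own symbol). Passing recovery tests therefore demonstrates the
statistical machinery is correct under the stated model, not that real
arrays meet that model.

## Calibration checks and their design

Two calibration subtleties deserve a note, because naive versions of these
checks are mathematically unattainable:

* *t-test null calibration.* The check that 5% of null probes reject at
  p ≤ 0.05 (within the exact binomial 99% interval) runs the Student
  variant. Welch at n = 3 + 3 is conservative by construction (size
  ≈ 0.035), so an exact-5% assertion would test the approximation's known
  bias, not the implementation. Under the generator's homoscedastic noise
  the Student test is exact, making the uniformity of its p-values a sharp
  implementation check; the Welch path is instead verified against
  `stats::t.test` to 10 significant digits.

* *Enrichment null calibration.* The hypergeometric test is discrete: for
  any set/query size its exact size P(p ≤ 0.05 | null) sits strictly below
  0.05 by up to one tail point mass. The Monte-Carlo rejection rate is
  therefore compared against the binomial interval around the *exact*
  discrete size (computed from `dhyper`, an independent oracle), with
  set and query sizes (K = 250, n = 500, N = 5,000) chosen large enough
  that this exact size stays within (0.03, 0.05].

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
sizes chosen to make every check sharp yet quick on a laptop: 10,000 probes
for null calibration, 5,000 for DE recovery, 20 independent simulations of
60 lncRNA × 500 mRNA probes for TF recovery, exhaustive enumeration of
every hypergeometric configuration up to N = 12, and 1,000-case
brute-force comparisons for the scalar statistics. The standard end-to-end
configuration (2,000 + 3,000 probes) completes in seconds and is verified
byte-identical across reruns under a fixed seed.

## Known limitations

* Raw p-values drive DE calling and pair ranking (by design, to mirror the
  conventional array screen); FDR is reported for enrichment but nothing
  is multiplicity-adjusted elsewhere.
* With three samples per group, correlation p-values are coarse (df = 4):
  p < 0.05 requires |r| > 0.81, so correlated sets are small and noisy;
  the hypergeometric aggregation across a whole target set is what makes
  TF recovery robust regardless.
* Gene symbols are compared case-sensitively with no alias resolution;
  collections whose symbol vocabulary differs from the annotation's will
  silently shrink the effective universe.
* Hierarchical clustering treats zero-variance probes as uninformative
  (distance 1 to everything) and reports them rather than failing.
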