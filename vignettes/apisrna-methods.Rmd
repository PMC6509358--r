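---
title: "Methods: duplex screening, composition, enrichment and binding-curve analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex screening, composition, enrichment and binding-curve analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`apisrna` analyses the extracellular RNA that honeybee nurses secrete into
royal jelly together with its main protein partner, major royal jelly
protein 3 (MRJP-3) — a non-sequence-specific RNA-binding oligomer. The
package covers four connected questions: where in stranded RNA-seq data
two distinct RNA molecules appear base-paired (putative double-stranded
RNA); how the RNA content of a library decomposes into species and RNA
biotypes, and whether a viral species is enriched in the protein-bound
fraction; which functional gene classes are overrepresented among a gene
set once gene-length bias is accounted for; and what dissociation
constants underlie multiphasic microscale-thermophoresis (MST) binding
curves. A synthetic-data module generates all inputs with the statistical
structure these analyses assume, so the full pipeline runs, and is tested,
without any external data.

```{r setup}
library(apisrna)
```

## The putative-dsRNA screen

Stranded libraries preserve the strand of origin of each fragment. If two
*distinct* RNA molecules formed a duplex, their reads map to opposite
genomic strands at overlapping positions. The screen calls a candidate
duplex for every pair of a forward-strand and a reverse-strand read, on
the same reference and in the same sample, whose overlap
`min(ends) − max(starts)` is at least 25 nt and whose single-stranded
overhangs (`max(starts) − min(starts)` on the left,
`max(ends) − min(ends)` on the right) are each at most 100 nt. The 25 nt
floor excludes the short 4–7 nt intramolecular pairings typical of tRNA
structure by construction; the overhang cap keeps the two reads anchored
to one duplexed locus rather than merely sharing a gene.

Two rules the overlap geometry alone does not fix:

* **Mate exclusion.** The two mates of one sequenced fragment map to
  opposite strands yet are one molecule. Pairs with equal fragment
  identifiers are excluded by default (`exclude_mates`), since the screen
  is after *two distinct molecules*.
* **Duplicate key.** Unique duplexes are keyed by the overlap interval —
  the duplexed region itself — so candidates that duplex the same region
  with different overhangs collapse into one record whose `support`
  counts them. Keying by the union interval is available
  (`key = "union"`).

Each unique duplex is assigned to every gene whose span intersects the
overlap interval, strand-agnostically (a duplex involves both strands) —
a duplex intersecting *k* genes counts once for each; with no
intersecting gene it is classed `unannotated`. Reported duplex length is
the overlap length. Per-gene counts across samples are normalized by
median-of-ratios size factors: per sample, the median over genes (with
positive geometric mean across samples) of the ratio of the sample's
count to the gene's geometric mean.

The caller joins per-reference sorted interval indexes rather than
enumerating all pairs; a brute-force all-pairs oracle is kept in the test
suite and the two are checked for exact agreement on hundreds of random
instances, alongside a coordinate-mirroring symmetry and a validator that
re-checks every emitted candidate against the rule.

```{r screen-demo}
reads <- aligned_reads(
  read_id = c("a/1", "b/1"), fragment_id = c("a", "b"), mate = 1L,
  reference = "bee1", start = c(0L, 60L), end = c(100L, 160L),
  strand = c("+", "-"), sample = "s1")
call_duplexes(reads, screen_params())[, c("overlap_start", "overlap_end",
                                          "overlap_len", "left_overhang",
                                          "right_overhang")]
```

## Composition, normalization and viral enrichment

Fragment sense strands follow the dUTP chemistry of stranded total-RNA
library preparation: mate 2 carries the fragment's sense strand (an `fr`
option inverts this). A fragment is assigned to a gene when its interval
overlaps the gene span *and* its sense strand matches the gene strand;
fragments with two or more eligible genes are dropped as ambiguous (the
conventional default of gene-level counting — tallied, never silently
lost), and fragments in unannotated regions are reported as `Other`.
Gene spans, not exon models, carry the assignment: the toy annotation has
no exon structure, and at this scale gene-level counting is the target
semantics.

Counts are summed per species and, within the bee, per RNA biotype.
Library-size factors are *mean-ratio*: each sample's total mapped count
divided by the mean total, so factors average to 1 by construction.
Groups below a 1% mapped fraction in every sample are collapsed out of
the report (the full table is retained as an attribute). Species
enrichment — bee versus the VDV-1-like virus, separately within the
total-jelly and protein-bound fractions — uses the two-sided Welch
unequal-variance t test on normalized counts. Normalized counts are the
default test input; per-sample fractions are available behind a flag
(`use = "fractions"`), as the choice is not forced by the analysis
definition. Strand-specific per-base coverage supports the
`log10(x + 1)` transform; tracks are emitted unflipped with strand
labels, axis-flipping for antisense display being presentation only.

## GO overrepresentation with length bias

Long genes accumulate reads (and hence "expressed" or "hit" status) more
easily than short ones, which inflates naive enrichment tests for
length-correlated categories. The analysis follows the established
length-aware protocol: the universe is genes with a count of at least 2
in any sample; terms with fewer than 5 annotated universe genes are
dropped; each remaining term receives an upper-tail p value from the
Wallenius noncentral hypergeometric distribution; terms with raw
p < 0.05 are flagged (no multiple-testing correction by default —
Benjamini–Hochberg is available behind `adjust = TRUE`).

Two deliberate simplifications relative to spline-based implementations,
both stated here as approximations:

* The probability-weighting function P(member | length) is estimated by
  equal-occupancy length bins and pool-adjacent-violators isotonic
  smoothing — monotone by construction, free of smoothing parameters,
  and well behaved at the few-hundred-gene scale this package targets.
* Each term is tested with a single Wallenius odds parameter,
  `[w̄_in/(1−w̄_in)] / [w̄_out/(1−w̄_out)]`, the odds ratio of mean
  weights inside versus outside the term.

The Wallenius distribution itself is computed exactly, by dynamic
programming over its defining process — sequential draws without
replacement with probability proportional to remaining weight; since
weights are equal within the two colours, the number of whites drawn is
a sufficient state and the pmf follows from an O(n²) recurrence. At
odds 1 it reproduces the central hypergeometric to machine precision
(tested across all universe sizes up to 20), and at biased odds it
matches an independent draw-sequence enumeration oracle on small urns.

One behaviour worth knowing: with a raw p < 0.05 rule on a *discrete*
null, the attainable type-I rate is below 0.05, because each term's
attainable p values jump over the threshold. The null-calibration test
therefore compares the observed flag rate to the exactly computed
attainable rate (summing hypergeometric mass where the tail is below
α), not to α itself.

## Multiphasic binding curves

MST titrations of MRJP-3 against labeled RNA show several discrete
binding events. Each event is modelled by the exact 1:1 ligand-depletion
isotherm

θ(P) = 2P / ((P + L + K_d) + sqrt((P + L + K_d)² − 4PL)),

the conjugate form of the quadratic solution, numerically stable when
L ≪ K_d and exact when K_d is comparable to the labeled concentration L —
which matters here, since the tightest reported event (4 nM) is of the
same order as plausible labeled-RNA concentrations. In the L → 0 limit θ
reduces to P/(P + K_d). Events are assumed independent, so the signal is
a baseline plus an amplitude-weighted sum of isotherms.

Fitting is least squares over (baseline, log K_d's, amplitudes), with
the K_d ordering enforced by parameterizing log-gaps (strictly increasing
by construction), Levenberg–Marquardt refinement, and eight multi-starts
on a log-spaced K_d lattice spanning the titration range — multiphasic
surfaces have local minima, and the lattice makes recovery reproducible.
The number of phases is chosen by BIC,
`n·ln(rss/n) + k·ln(n)` with `k = 2·n_phases + 1`; at the simulated
noise levels this recovers the true phase count as the modal choice
across seeds. Self-association follows a Hill curve with the coefficient
fixed at 1 unless freed explicitly.

Simulated titrations mirror the assay design: a 16-step two-fold
dilution series of the unlabeled protein, mixed 1:1 (equal volumes — so
both the protein and the labeled RNA are halved in the capillary),
triplicate curves, i.i.d. Gaussian noise of 1–2% of the dynamic range.
Values the assay description leaves open were fixed once as realistic
choices: the series tops out at 160 µM prepared protein (self-association
saturates around 40 µM, so the series must comfortably exceed it, and
two-fold steps from 160 µM reach ~5 nM, bracketing the tightest event);
labeled RNA is 10 nM prepared (5 nM in the capillary); phase amplitudes
are equal. Parameter-recovery checks use a 2-fold tolerance on the
median fitted K_d over 20 seeds: 16-point designs at MST-scale noise do
not constrain the tightest and loosest phases more finely.

```{r binding-demo}
cfg <- titration_sim_config(
  phases = data.frame(kd = c(4e-9, 3e-7, 25e-6), amplitude = 1),
  noise_sd = 0.01, seed = 1)
curve <- simulate_titration(cfg)
fit <- fit_multiphase(curve, n_phases = 3)
signif(fit$model$phases$kd, 3)
```

## What the synthetic data does and does not emulate

`make_reference()` builds a bee chromosome (default 100 kb) tiled by
protein-coding, tRNA and pre-miRNA genes separated by unannotated gaps,
plus a VDV-1-like viral genome (default 10 kb). `simulate_fragments()`
draws stranded 100 bp paired-end fragments per sample — three
total-jelly and two protein-bound samples by default, with the viral
species strongly enriched in the bound fraction and viral reads on both
strands at a 3:1 sense:antisense ratio. Fragment lengths are
Normal(250, 40) truncated to [100, 600] nt, a typical stranded
total-RNA insert distribution. Planted duplex pairs are two distinct
molecules, one per strand, with overlap ≥ 25 nt and overhangs ≤ 100 nt
by construction, and a ground-truth sidecar that is validated against
its own constraints before use. Ordinary mate pairs exercise the
screen's mate-exclusion rule (short inserts would otherwise be called).

Two placement modes matter for interpreting the tests. Under the default
uniform placement, background fragments overlap freely, as in real
libraries — so opposite-sense background reads can legitimately satisfy
the duplex rule, and the screen's guarantees there are *recall*
(every planted duplex is called) and *mate safety* (no mate pair is
called). Under `placement = "disjoint"`, all molecule footprints are
kept disjoint except the planted pairs, making the planted duplexes
provably the only qualifying overlaps; this is the configuration in
which precision 1 is asserted. Real data differ from both: sequencing
error, splicing, multi-mapping, PCR duplicates and coverage
heterogeneity are all absent, so passing tests demonstrate algorithmic
correctness under the stated model, not robustness to those artefacts.

The GO generator assigns terms as independent per-gene Bernoulli draws,
optionally with a logistic length bias, and can plant one genuinely
enriched term in a designated gene set; it emulates annotation-size and
length-bias structure, not the ontology DAG (ancestor propagation is out
of scope, and the analysis treats gene→term as a flat table).

## Numerical and design notes

* Internal coordinates are 0-based half-open everywhere; GFF3 (1-based
  closed) and BED/bedGraph (0-based half-open) convert only at the I/O
  boundary, in one place.
* The minimal SAM dialect accepts only pure-`M` CIGARs and rejects
  spliced or clipped alignments with an explicit error: the screen
  operates on intervals, and the simulator only emits `M`.
* Degenerate inputs: empty candidate sets, empty histograms and empty GO
  mappings all produce empty, well-typed results; a Welch test on two
  zero-variance equal groups returns p = 1, and unequal zero-variance
  groups are an error rather than an infinite statistic.
* Size-factor edge case: when no gene has positive counts in every
  sample the median-of-ratios factor is undefined; the error message
  points to the mean-ratio alternative.
* All generators are pure functions of (config, seed); the pipeline
  derives stage seeds from one master seed, and end-to-end reruns are
  byte-identical.
* Test and example problem sizes (20-seed recovery experiments, 16×3
  titration points, 100 kb genomes, a few thousand fragments per
  sample) were chosen as the smallest instances at which the studied
  effects are comfortably resolved.

## Known limitations

The screen cannot distinguish genuine intermolecular duplexes from
coincidental opposite-strand transcription overlaps; at high coverage
the rule will fire on any locus transcribed from both strands, which is
why quantification and normalization, not a single call, carry the
inference. Gene-level (span) assignment overcounts intronic signal for
genes with long introns. The single-odds Wallenius approximation ignores
weight heterogeneity within a term. Binding-curve fits assume additive
independent events and i.i.d. noise; correlated thermophoresis drift,
aggregation and fluorescence quenching are not modelled, and amplitudes
of opposite sign, while accepted by the fitter, are outside the
simulated regime.
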