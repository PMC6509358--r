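# apisrna

Honeybee royal jelly carries extracellular RNA — bee transcripts of every
biotype, viral RNA, and putative double-stranded RNA — bound by major
royal jelly protein 3 (MRJP-3), a secreted, non-sequence-specific
RNA-binding oligomer. `apisrna` is an R package for the computational
side of studying that system, aimed at anyone analysing stranded RNA-seq
of protein-bound RNA fractions or multiphasic binding assays:

* **Putative-dsRNA screen** — calls candidate duplexes from pairs of
  opposite-strand reads of *distinct* molecules whose overlap is
  ≥ 25 nt with ≤ 100 nt overhang on either side; deduplicates them by
  duplexed-interval key, classifies them by gene and biotype, quantifies
  them per gene, and normalizes counts with median-of-ratios size
  factors (factor *s* = median over genes of counts(g, s) / geometric
  mean of gene g).
* **Composition & enrichment** — strand-aware gene-level fragment
  assignment under the dUTP stranded protocol, species/biotype
  composition tables with mean-ratio size factors
  (factor *s* = total(s) / mean of totals), two-sided Welch t tests for
  species enrichment between sample fractions, and strand-specific
  per-base coverage with the log10(x+1) transform.
* **Length-aware GO overrepresentation** — expressed-gene universe
  (count ≥ 2), terms with ≥ 5 annotated genes, upper-tail p values from
  an exact Wallenius noncentral hypergeometric implementation with
  term odds derived from isotonically smoothed length-bias weights.
* **Binding-curve analysis** — multiphasic MST titrations modelled as a
  baseline plus independent binding events under the exact 1:1
  ligand-depletion isotherm
  θ(P) = 2P / ((P+L+K_d) + √((P+L+K_d)² − 4PL)); multi-start
  least-squares fitting with ordered K_d's, BIC phase-count selection,
  and a Hill-type self-association model.
* **Synthetic data** — toy bee + virus references, stranded 100 bp
  paired-end fragments with planted ground-truth duplexes, gene→GO
  tables with controllable length bias, and noisy titrations, so every
  stage runs without downloads.

## Worked example

Simulate a three-phase titration at dissociation constants of
4 nM / 300 nM / 25 µM with 1% noise, then fit it back and let BIC pick
the phase count:

```r
library(apisrna)
cfg <- titration_sim_config(
  phases = data.frame(kd = c(4e-9, 3e-7, 25e-6), amplitude = 1),
  noise_sd = 0.01, seed = 1)
curve <- simulate_titration(cfg)
sel <- select_phase_count(curve, max_phases = 4)
sel$best_n
#> [1] 3
signif(sel$best_fit$model$phases$kd, 3)
#> [1] 4.25e-09 3.17e-07 3.06e-05
```

The fitted constants land within a few tens of percent of the simulated
truth — about the resolution a 16-point triplicate design at this noise
level supports — and the BIC comparison of 1–4 phase fits identifies
three discrete binding events.

The genomics side runs end to end from one seed:

```r
res <- run_pipeline("out", seed = 101, n_fragments = 300,
                    duplex_pairs = 9, n_go_terms = 60)
head(res$unique_duplexes[, c("reference", "key_start", "key_end",
                             "length", "biotype_class", "support")], 3)
#>   reference key_start key_end length  biotype_class support
#> 1      bee1       383     415     32 protein_coding       2
#> 2      bee1       402     486     84 protein_coding       1
#> 3      bee1       405     486     81 protein_coding       1
res$enrichment
#>      fraction        t df            p significant
#> 1 mrjp3_bound  31.5841  2 1.000946e-03        TRUE
#> 2    total_rj 306.1772  4 6.826982e-10        TRUE
```

Both fractions flag a significant bee-versus-virus difference here: with
tight replicates even the 55/45 split of the bound fraction separates
cleanly, while the total fraction is overwhelmingly bee. What
distinguishes the fractions is the magnitude of the difference, visible
in the normalized composition table (`res$composition`).

`out/` then contains the reference FASTA/GFF3, per-sample SAM and FASTQ,
candidate BED, unique-duplex and histogram tables, composition and
enrichment TSVs, strand-specific bedGraph coverage, GO results, the
titration CSV with its fit, and a `manifest.jsonl` enumerating every
artifact. Rerunning with the same seed reproduces all of it
byte-identically.

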