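# sialoshift

Temporal transcriptome profiling of blood feeding in soft ticks.

Soft ticks (Argasidae, e.g. *Ornithodoros*) feed in minutes and are
thought to transcribe the machinery for blood-meal acquisition,
digestion, and molting *before* attaching to a host. Whole-body RNA-seq
of immature stages (larva, 1st and 2nd nymphal stage) sampled unfed
(UF) and at 6 h, 12 h, 24 h, and 5 days after a blood meal — three
biological replicates per cell, 45 libraries — resolves that temporal
program as three transcriptional profiles: unfed, early-fed, and
late-fed.

`sialoshift` implements the downstream analysis of such a design as a
tested, reusable R package:

* **CDS extraction** from de novo assembled transcripts by two evidence
  routes: best database hit covering ≥ 70% of the matched protein
  (full-DP local alignment, BLOSUM62, affine gaps 11/1, ORFs ≥ 100 nt),
  and a rule-based signal-peptide heuristic on Met-initiated ORFs
  ≥ 40 aa, taking the most 5′ methionine as the start;
* **redundancy consolidation** at ≥ 95% nucleotide identity (greedy
  incremental clustering, longest representative);
* **contaminant removal** of CDS whose best hits are vertebrate or
  bacterial;
* **TPM quantification** with the replicate-consistent filter
  (TPM ≥ 5 in all replicates of at least one biological group);
* **functional classification** into 25 classes by scanning an ordered
  keyword vocabulary against hit descriptions ("order of appearance"
  semantics; `unknown` / `unknown conserved` assigned by rule);
* **differential expression** per stage between feeding groups with an
  exact conditional negative-binomial test (trimmed-mean size factors,
  method-of-moments common dispersion), calling |log2FC| ≥ 2 at
  BH-FDR < 0.05;
* **profiles and ordination**: class-level percent-TPM profiles,
  Z-score heatmap with average-linkage clustering, and classical MDS of
  libraries on a leading-fold-change distance.

A synthetic-study generator (`simulate_study()`) plants CDS, signal
peptides, contaminants, class keywords, and the three temporal profiles
with known ground truth, so the whole pipeline is testable end to end
without any sequencing download. The statistical model and every design
choice are documented in `vignettes/sialoshift-methods.Rmd`.

## Worked example

```r
library(sialoshift)

study <- simulate_study(sim_params(transcripts_per_class = 4, rng_seed = 11))
pipe  <- run_pipeline(study$transcripts, study$proteome,
                      study$counts, study$design)
ev    <- evaluate_against_truth(pipe, study)
```

The pipeline logs its stage counts as it runs:

```
homology search: 944 ORF queries vs 104 proteins
extracted 136 CDS from 108 transcripts; 108 primary
108 representatives after clustering; 8 contaminant(s) removed
100 CDS pass TPM >= 5 in all replicates of one group
```

Recovery against the planted truth, the larval unfed-vs-6 h contrast,
and the unknown class's temporal profile:

```r
ev[c("class_recovery", "contaminant_recovery", "interval_recovery")]
#> class recovery: 1.000 | contaminant recovery: 1.000 | interval recovery: 0.970

de6 <- subset(pipe$de, stage == "larva" & contrast == "UF_vs_FED6h")
sum(de6$significant)
#> larva UF vs FED6h: 26 significant of 100 CDS (4 up, 22 down)

subset(pipe$profiles$profile, class_label == "unknown" & stage == "larva")
#>   group mean_percent sd_percent
#>      UF         3.61      0.935
#>   FED6h        62.08      1.898
#>  FED12h        65.28      2.521
#>  FED24h        59.25      3.719
#>   FED5d         4.82      1.211

pipe$mds$larva$silhouette
#> 0.57
```

Read: most classes are loaded before feeding and collapse at 6 h (22
down-regulated CDS), while the `unknown` class — sequences with no
database relative — is strongly induced by the blood meal (3.6% of
library TPM unfed, ~60% during early feeding, back to ~5% by day 5).
The silhouette of 0.57 confirms the unfed / early-fed / late-fed
library clusters in the larval stage.

A thin command-line front end over the same functions ships in
`inst/scripts/sialoshift-cli.R` (subcommands `simulate`, `extract-cds`,
`search`, `cluster`, `quantify`, `classify`, `de`, `profile`,
`run-all`).

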