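# m7Gseq

Analysis pipeline linking **N7-methylguanosine (m7G) tRNA modification**
to selective mRNA translation. m7G sits in the variable loop of a subset
of tRNAs (canonical position 46, installed by METTL1/WDR4); when it is
lost, the modified tRNAs are depleted and mRNAs rich in the codons they
decode are translated less efficiently, with ribosomes pausing at those
codons. `m7Gseq` implements every computational stage of that argument
for R users working from sequencing-derived tables:

* **TRAC-seq m7G site calling** — per-position cleavage scores
  `log2` of pseudocounted 5'-end start frequency, treated (cleaved) over
  control, gated on the `ABGWY` variable-loop motif with score and
  coverage thresholds;
* **tRNA expression** — isotype aggregation, CPM and
  log2-relative-to-mean normalization, Mann–Whitney comparison of m7G
  vs non-m7G expression shifts under knockdown, LC-MS m7G level ratio;
* **anticodon decoding** — strict Watson–Crick, Crick wobble, or
  wobble+inosine policies mapping each anticodon to the codons it reads;
* **translation efficiency** — FPKM-based TE (polysome or Ribo-seq over
  input RNA), up/down/non classification with configurable thresholds;
* **codon statistics** — m7G-decoded codon counts per mRNA, TE-class and
  gene-set (GMT) comparisons;
* **ribosome pausing** — A-site offset assignment, within-gene
  mean-normalized pause scores, m7G vs other codon-type shift tests;
* **a seeded synthetic-data generator** for all of the above, with
  ground truth, so the whole pipeline runs and is testable without any
  sequencing download.

## Worked example

```r
library(m7Gseq)

cfg  <- simulation_config(seed = 42)         # study-scale defaults
ref  <- simulate_trna_reference(cfg)         # 50 tRNAs, 20 with implanted m7G
libs <- simulate_trac_libraries(ref, cfg)    # treated + control pileups

calls <- call_m7g_sites(libs$treated, libs$control, ref$genes)
head(calls[calls$called, ], 3)
#>          trna_id position read_start    score coverage motif_ok called
#> tRNA-Pro-AGG-4-1       63         64 5.283256     1343     TRUE   TRUE
#> tRNA-Ala-TGC-5-1       59         60 5.009813     1401     TRUE   TRUE
#> tRNA-Thr-GGT-8-1       55         56 4.550580     1347     TRUE   TRUE
length(m7g_modified_trnas(calls))
#> [1] 20
```

Each called row is a modified G (0-based `position`) whose cleavage
read-start (`position + 1`) shows a ~2^5-fold start-frequency excess in
the treated library at ~1300–1400 reads of coverage; all 20 implanted
sites are recovered, with none called elsewhere.

```r
cm   <- simulate_trna_counts(ref, cfg)       # NB counts, 40% m7G depletion
norm <- normalize_expression_matrix(aggregate_isotypes(cm, ref$genes))
res  <- compare_m7g_vs_non(norm, ref$m7g_isotypes)
c(res$median_m7g, res$median_non, res$test$p)
#> [1] -5.9e-01  2.7e-01  4.4e-08
```

m7G isotypes drop by ~0.6 log2 units relative to their overall mean
while non-m7G isotypes do not (Mann–Whitney p = 4.4e-08).

```r
codons <- m7g_codon_set(ref$genes[ref$genes$m7g, ])   # 32 codons (inosine policy)
tx   <- simulate_transcriptome(cfg, codons)           # 2000 mRNAs, codon gradient
recs <- codon_count_records(tx$genes, codons)
mlib <- simulate_mrna_libraries(tx$genes, cfg,
                                setNames(recs$m7g_codon_count, recs$gene))
te   <- te_table(tx$genes, mlib$input_control, mlib$input_kd,
                 mlib$polysome_control, mlib$polysome_kd)
table(te$te_class)
#> down  non   up
#>  320 1366  314
compare_counts_by_te_class(recs, te, comparisons = list(c("down", "non")))$tests
#>  comparison       statistic        U            p median_1 median_2 n_1  n_2
#> down_vs_non m7g_codon_count 364615.5 1.661418e-77       47       24 320 1366
```

mRNAs whose TE falls ≥ 2-fold under knockdown carry a median 47
m7G-decoded codons versus 24 for unaffected mRNAs — the codon-usage
coupling the pipeline is built to expose.

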