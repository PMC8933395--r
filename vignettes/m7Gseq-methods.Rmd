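---
title: "m7Gseq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m7Gseq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m7Gseq)
```

# The biological question

N7-methylguanosine (m7G) is installed in the variable loop of a subset of
cytoplasmic tRNAs (canonically position 46) by the METTL1/WDR4
methyltransferase complex. When the modification is lost — for example
under METTL1 knockdown — the modified tRNAs are destabilized, and mRNAs
whose coding sequences lean heavily on the codons those tRNAs decode are
translated less efficiently, with ribosomes pausing at exactly those
codons. `m7Gseq` implements the computational chain that establishes this
link from sequencing readouts:

1. **Site calling** — which tRNAs carry m7G, from TRAC-seq (tRNA
   reduction and cleavage sequencing) 5'-end pileups;
2. **Expression** — how m7G-modified versus unmodified tRNAs respond to
   methyltransferase knockdown;
3. **Decoding** — which codons the m7G tRNAs read, under an explicit
   wobble policy;
4. **Translation efficiency (TE)** — which mRNAs gain or lose ribosome
   association, from input/polysome (or ribosome-footprint) counts;
5. **Codon statistics** — whether TE-down mRNAs are enriched for
   m7G-decoded codons;
6. **Pausing** — whether ribosome dwell time rises at m7G-decoded codons
   after knockdown.

A seeded generator (`simulate_*`) produces every input with the
statistical structure the analysis assumes, so each stage is testable
without sequencing data.

# Site calling from TRAC-seq

TRAC-seq chemistry (NaBH4 reduction, then aniline) cleaves the tRNA
backbone at m7G, so the treated library acquires new read 5' ends **one
nucleotide 3'** of the modified G relative to the uncleaved control. The
per-position **cleavage score** is

$$s_i = \log_2 \frac{(t_i + c_0) / (T + c_0 L)}{(u_i + c_0) / (U + c_0 L)}$$

where $t_i, u_i$ are 5'-end start counts at position $i$ in the treated
and control libraries, $T, U$ the library totals, $L$ the profile length
and $c_0$ a pseudocount. The published protocol this score descends from
does not print a formula; this log-ratio form was chosen because it is
antisymmetric under swapping the libraries and invariant to joint
rescaling of counts and pseudocount — both properties are tested.

A variable-loop position is **called** as an m7G site iff

* it is the modified G of an `ABGWY` motif match (IUPAC: B = C/G/T,
  W = A/T, Y = C/T) starting inside the variable loop — matches may
  overhang the loop's 3' end, since the biology anchors the G, not the
  whole motif, to the loop;
* the score at the cleavage read-start position (site + 1, configurable)
  is at least `min_score` (default 1, i.e. two-fold); and
* the treated read-start count there is at least `min_coverage`
  (default 10).

`min_score`, `min_coverage` and the pseudocount (default 0.5) are
heuristics with no published values behind them; they are arguments, are
echoed into every output, and the defaults give ≥ 95% recall and
precision at the simulated depths described below. A tRNA is reported
m7G-modified iff it has at least one called site. High-scoring loop
positions without a motif are reported with `motif_ok = FALSE` but never
called.

The **variable loop** itself is located from a dot-bracket secondary
structure when one is supplied: the unpaired stretch strictly between the
anticodon stem's 3' side and the T-stem's 5' side of the cloverleaf.
Without a structure a fallback window `[len - 27, len - 12)` relative to
the 3' end is used (CCA-trimmed when flagged); it brackets canonical
positions 44–48 on a 76-nt tRNA and is deliberately generous, because the
motif gate — not the window — carries the specificity. The structure
parser assumes contiguous stems (no bulges), which is adequate for
cloverleaf annotations; references with bulged stems should rely on the
fallback window or per-gene overrides.

# Expression of m7G vs non-m7G tRNAs

Isodecoder counts are summed to isotypes (amino acid + anticodon),
depth-normalized to counts per million, and each isotype is expressed as
$\log_2(v / \bar v)$ against its mean across **all** samples of both
conditions. Zeros are floored to half the smallest nonzero value before
the log (configurable; disabling the floor restores exact invertibility,
which is tested to 1e-12). Replicates are averaged **after** the log
transform by default; the per-replicate variant is exposed
(`replicate_mean = FALSE`) because the published displays do not state
the order.

The class comparison takes, per isotype, the knockdown-minus-control
difference of normalized values, and applies a two-sided Mann–Whitney U
test between m7G-class and non-m7G-class differences. The U statistic is
$U = \#\{(i,j): a_i > b_j\} + \tfrac12\#\text{ties}$; the p-value is
exact when $\min(n, m) \le 8$ with no ties, and otherwise the normal
approximation with tie and continuity corrections. The implementation
delegates to `stats::wilcox.test`, whose `W` is exactly this `U`; the
test suite verifies the exact path against a full-enumeration permutation
oracle written independently of it.

The LC-MS m7G level is the m7G nucleoside's normalized peak area over
the summed areas of all detected nucleosides.

# Decoding policy

Which codons count as "decoded by an m7G tRNA" depends on the wobble
rule, and no published enumeration exists to copy. Three policies are
implemented; every downstream statistic records which one produced it:

| policy | position-34 rule |
|---|---|
| `strict_wc` | Watson–Crick only |
| `crick_wobble` | + G34→{C,U}, U34→{A,G} |
| `crick_wobble_inosine` | + A34 (as inosine)→{U,C,A} |

The default is `crick_wobble_inosine`: eukaryotic cytoplasmic A34 tRNAs
are essentially always inosine-edited, and multi-codon decoding by
tRNA-Val-AAC is presumed by the rescue experiments this analysis
supports. Codon positions 1–2 are always the reverse complement of
anticodon positions 36–35; nesting (strict ⊆ wobble ⊆ wobble+inosine) is
a tested invariant. Note that wobble sets occasionally include stop
codons (e.g. inosine A34 against a UA- codon box); stop codons are
excluded wherever codons are counted or pause-scored.

# Translation efficiency

FPKM is `count / ((length/1000) * (total/1e6))`. TE is translated FPKM
over input FPKM; polysome-seq and Ribo-seq share one code path, with the
translated FPKM using the CDS length for footprint libraries and the
transcript length otherwise. Whether the input FPKM should use CDS or
transcript length is not documented for the polysome protocol; both are
supported and the default is transcript length, the convention of
standard RNA-seq quantification. Genes are classified `up` / `down` /
`non` by `|log2(TE_kd / TE_control)| >= 1`, with an input-FPKM floor of 1
in both conditions (`filtered` otherwise). Both thresholds are unstated
in the source analyses and are exposed as arguments.

# Codon statistics and pausing

Per mRNA, the number of frame-0 CDS codons in the m7G-decoded set is the
primary statistic (raw count, matching the published "numbers of
codons"); the length-normalized density is computed alongside because CDS
length is a genuine confounder. Classes (down vs non, up vs non, down vs
up) and gene-set memberships (GMT files; members restricted to TE-down
genes vs all other detected mRNAs) are compared by two-sided
Mann–Whitney tests. No enrichment statistics (GO/GSEA) are computed —
gene sets are consumed, not discovered.

For pausing, footprints are assigned to codons through a length → A-site
offset rule (default: 28–31-nt footprints, +15 nt; others discarded and
tallied). Per-codon occupancy is normalized within each gene by its mean
(**pause score**; genes under 0.5 mean counts/codon are excluded), pause
scores are aggregated per codon type (mean by default, median by flag),
and the knockdown-minus-control shift of m7G-decoded codon types is
tested against all other types.

Because pause scores are renormalized within each gene, a true occupancy
multiplier $\mu$ at m7G codons inflates the gene mean and the raw
m7G-class pause ratio understates $\mu$. The reported `ratio_ratio` —
the m7G-class KD/control pause ratio divided by the non-m7G-class ratio —
cancels that inflation exactly, and recovers simulated multipliers of
1.5/2/3 within 10% in the acceptance suite.

# The synthetic-data generator

`simulation_config()` fixes every stream from one seed (fanned out into
per-stage substreams so stages can be regenerated independently; equal
seeds give byte-identical outputs). The noise models are the minimal
standard ones needed to exercise each statistic, not estimates from any
dataset: multinomial read starts for pileups, negative-binomial counts
for tRNA and mRNA libraries, lognormal abundances, Poisson codon
occupancy.

Default conditions (each a config knob):

* **Reference**: 50 isotypes, one isodecoder each, lengths 74–80 nt,
  40% m7G. m7G genes carry exactly one implanted `ABGWY` instance in the
  variable loop (the ground truth); non-m7G genes are rejection-sampled
  to contain none.
* **TRAC-seq**: 2e5 read starts per library; per-position background
  weight 5e-3; additional cleavage weight 0.15 at site + 1 in the treated
  library. This ~31-fold start-rate excess is what the ≥95%
  recall/precision checks run at.
* **Expression**: baseline ~500 counts/isodecoder (lognormal, sd 0.5
  logs), NB size 20, 2 replicates per arm, knockdown multiplier 0.6 on
  m7G isotypes — i.e. the 40% depletion / n = 2 design of the comparison
  it feeds.
* **Transcriptome / TE**: 2000 genes, ~300 codons each (lognormal,
  minimum 60) plus a terminal stop; per-gene m7G-codon propensity uniform
  on [0.02, 0.15]; TE_kd = TE_control × 2^(−0.04 × m7G-codon count); NB
  size 15; depth 2e7. With these values a typical gene loses ~1 log2 TE
  and the down-class/non-class codon contrast is strongly detectable at
  2000 genes, while the β = 0 null rejects at ~5%.
* **Footprints**: 200 genes at 50 mean counts/codon for the pause
  checks; knockdown pause multiplier 2 by default. Codons 0–4 carry no
  occupancy because their read 5' ends would precede the transcript
  under the +15 offset; records carry an aggregated `count` column.

What the generator does **not** emulate: sequence-dependent ligation or
PCR bias, position-dependent coverage along tRNAs, isoform structure,
codon–anticodon kinetics beyond a flat multiplier, or correlated
gene-level effects. Passing tests therefore demonstrate that the
statistics recover the structure they assume, at realistic depths — not
that the pipeline is robust to every artifact of real libraries.

# Problem sizes and determinism

The acceptance-level checks run at the study scales above: 50 seeds for
site calling, 100 + 200 seeds for the depletion comparison and its null,
one 2000-gene TE run with a 200-seed null at 800 genes (the null
rejection rate is sample-size-free, so the smaller size is used there),
and 3 × 20 seeds for pause recovery. Null calibrations are judged
against the binomial 95% band around 5%.

All tie-breaks are deterministic: motif matches are reported in
ascending coordinate order, candidate sites are enumerated left to
right, and every randomized procedure takes an explicit seed.

# Known limitations

* The cleavage-score formula and all calling thresholds are
  reimplementation choices (flagged above), not published constants.
* Whether the published 19 m7G tRNAs are isotypes or isodecoders is not
  stated in the source text; `m7g_modified_trnas()` returns isodecoder
  ids and the caller can aggregate by `isotype_key`, so both
  granularities are reportable.
* The structure parser requires a clean cloverleaf (three hairpin arms,
  contiguous stems).
* Mitochondrial decoding rules, modifications other than m7G, and read
  alignment are out of scope; the pipeline consumes pileups and counts.
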