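# circbalance

Exonic circular RNAs (ecircRNAs) arise when the spliceosome joins a
downstream splice donor back to an upstream acceptor — a backsplice — instead
of splicing linearly. Because backsplicing and linear splicing compete for
the same pre-mRNA, RNA-binding proteins (RBPs) that occupy the introns
flanking circularized exons can tip a gene's output between its mRNA and its
circRNA. `circbalance` is an R toolkit for analysing exactly this kind of
perturbation experiment: wild-type versus RBP-knockout RNA-seq (steady-state
and metabolically labelled nascent libraries) together with CLIP/FLASH-style
binding peaks, asking whether the RBP suppresses circRNA biogenesis, where it
binds, and for which genes the circRNA:mRNA balance shifts.

It is written for computational biologists who have backsplice-junction (BSJ)
count tables, gene-level count tables, a GTF annotation and a peak table, and
who want the full chain of analyses as tested, reusable functions rather than
one-off scripts.

## What it computes

With per-sample library sizes, counts are normalized to reads per million
(RPM = count / library size × 10⁶). For each circRNA detected with ≥ 2 BSJ
reads in both conditions, the fold change

FC = (RPM_KO + c) / (RPM_WT + c),  c = 0.5

is classified **up** (FC ≥ 2), **down** (FC ≤ 0.5) or unchanged. Nascent
libraries get a per-gene circRNA fraction (BSJ reads / all nascent reads of
the gene, for genes showing both linear splicing and backsplicing), compared
between conditions with a paired two-tailed t-test, and a single nascent
up-call boundary FC ≥ 1.4.

Binding peaks are filtered to a high-confidence set (p < 0.05 and reads > 5,
both strict), annotated to genomic features with the precedence
CDS > 3′UTR > 5′UTR > noncoding exon > intron > intergenic, and summarized by
nucleotide/k-mer composition of the strand-corrected peak sequences. Exons of
circRNA-producing genes are split into backsplicing exons (**circ-E**, inside
a detected circRNA span) and non-backsplicing exons (**NE**); each group's
**flanking introns** (FI — the introns immediately up/downstream in
transcription direction) are profiled for length, number of overlapping
sites and binding intensity (summed site reads), and compared between classes
and between up/non-up regulation groups (chi-square on binding presence and
binned site counts, two-tailed t on length and intensity; Wilcoxon rank-sum
for bound vs unbound gene lengths).

Finally, each circRNA-producing gene gets a circRNA:mRNA ratio
(circ RPM + c)/(mRNA RPM + c) per condition; the KO/WT ratio fold change is
classed **increased** (> 2), **decreased** (< 1) or **unchanged** ([1, 2]).

A deterministic synthetic-study generator (`simulate_study()`) emits a small
genome (FASTA), annotation (GTF), peaks (BED6+2), WT/KO count tables (TSV)
and a truth table, with planted effects — a KO boost of regulated circRNAs, a
4× site rate and 2× length in their flanking introns, a planted U/A-rich
motif, and a small "CDK1-like" gene subset whose circRNA gain is coupled to
an mRNA loss — so every stage of the pipeline is testable without downloads.

## Worked example

```r
library(circbalance)
report <- run_pipeline(run_config(seed = 42))
report
#> circ_report
#>   shared circRNAs: 300; DE: 90 (up 89 = 98.9%, down 1 = 1.1%)
#>   KS circ WT vs KO: p = 5.22e-09; KS mRNA: p = 0.819
#>   nascent fraction WT 0.0893 vs KO 0.1294 (p = 5.15e-16, n = 300)
#>   high-confidence sites: 627 (81.4% intronic on coding genes)
#>   exonic binding: 15/300 (5.0%); genes with binding: 56.4%
#>   ratio labels: increased 92, decreased 95, unchanged 113
```

Reading the report: of 300 circRNAs detected in both conditions, 89 rise at
least two-fold in the knockout and the whole circRNA population shifts up
(Kolmogorov–Smirnov p ≈ 5e-9) while mRNA levels do not move (p ≈ 0.82) —
the signature of a biogenesis suppressor. The per-gene nascent circRNA
fraction increases from 8.9% to 12.9% (paired t, p ≈ 5e-16), confirming more
backsplicing rather than mere stabilization. Individual calls and the
flanking-intron comparison live in the report's tables:

```r
head(report$de_results[report$de_results$label == "up", ], 3)
#>               circ_id norm_wt norm_ko fold_change label
#> circ_G0002 circ_G0002      31     151    4.809524    up
#> circ_G0014 circ_G0014      37     112    3.000000    up
#> circ_G0028 circ_G0028     128     296    2.307393    up

round(report$composition, 3)      # strand-corrected peak sequences, U/A-rich
#>     A     C     G     U
#> 0.263 0.207 0.210 0.320
head(report$kmers, 3)             # the planted ARE-like hexamer ranks first
#>     kmer count        freq
#> 1 UAUUUA   500 0.032016392
#> ...
g <- report$fi_group_test         # FIs of up circRNAs vs the rest
#> length 1983 vs 1241 bp (t p = 0.0019); intensity 46 vs 23 (p = 9.2e-05)
```

`plot_summaries(report, "figs")` renders the MA plot, cumulative-fraction
curves, feature bar chart and FI boxplots from the same tables;
`run_pipeline(run_config(out_dir = "run1", ...))` writes every table as TSV
plus a JSON summary. Real data enter through
`run_config(paths = list(annotation = ..., sites = ..., circ_counts = ...,
...))` using the formats above.

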