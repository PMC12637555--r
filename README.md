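# piregulon

Target-centered analysis of pachytene piRNA regulons.

Pachytene piRNAs — the 26–31 nt small RNAs loaded onto PIWIL1 during male
meiosis — are individually so diverse that their targets stayed hidden for
decades. Looked at collectively, the picture inverts: for some mRNAs,
*swarms* of piRNAs pair antisense and nearly perfectly across kilobases of
CDS and 3′UTR. Those piRNAs trace back to discrete piRNA clusters, where
they arise from inserted pseudogene fragments (PGFs) of the very genes
they silence — 5′-truncated, spliced, target-site-duplication-flanked
copies pointing antisense, the anatomy of a LINE-mediated
retrotransposition. Each such cluster forms a one-to-one *regulon* with
its cognate gene: deleting the cluster derepresses the target.

`piregulon` implements this analysis for anyone with a genome, a gene
annotation, a piRNA cluster annotation, and a collapsed small-RNA
library — plus a fully seeded synthetic-data generator with a
machine-readable truth manifest, so the entire pipeline is testable with
no downloads.

## The model in brief

A piRNA `g` targets mRNA `m` at window `[p, p+20)` iff

```
HammingDistance( revcomp(g[2..21]), m[p..p+20) ) <= 1
```

— strict Watson–Crick pairing of the guide core (nt 2–21; nt 1 is the
non-pairing 1U position), no wobbles, no indels. The predicted cleavage
site sits opposite guide nt 10/11 (recorded as transcript index `p+10`).
Genes are ranked by the read-weighted fraction of all mRNA-targeting
piRNAs converging on them; each targeting species is traced to its
perfect genomic origins, apportioned across piRNA clusters, and the
dominant cluster per gene is called a one-to-one regulon when it holds at
least half of the gene's targeting mass. Clusters are scanned for PGFs by
chained local alignment against mature mRNAs (identity, exon composition,
processing status, 5′ truncation, TSD), expression response is quantified
by ECDF/Kolmogorov–Smirnov comparison of log2 fold-change tiers and a
BH-corrected volcano table, and 1U/10A positional signatures distinguish
primary biogenesis from ping-pong amplification.

## Worked example

Simulate the default study conditions (500 kb genome, 40 genes, 6
clusters, three planted antisense PGFs, 200,000 reads with a 0.8 1U
bias), then run every stage:

```r
library(piregulon)

cfg <- simulation_config(seed = 7)
ds  <- simulate_dataset(cfg, dir = "demo")

rep <- run_pipeline("demo/genome.fa", "demo/genes.gtf", "demo/clusters.bed",
                    "demo/pirnas.fa", "demo/counts.tsv", "demo/conditions.tsv",
                    out_dir = "demo/out")

rep$targeting_fraction
#> [1] 0.0191
head(rep$ranking$table[, c("gene_id", "targeting_reads", "fraction", "rank", "in_top")], 4)
#>   gene_id targeting_reads   fraction rank in_top
#> 1 gene002            1928 0.50431598    1   TRUE
#> 2 gene001            1001 0.26183625    2   TRUE
#> 3 gene003             470 0.12294010    3  FALSE
#> 4 gene020             115 0.03008109    4  FALSE
rep$regulons[, c("gene_id", "dominant_cluster", "dominant_fraction", "one_to_one")]
#>   gene_id dominant_cluster dominant_fraction one_to_one
#> 1 gene002            piC02         0.7479253       TRUE
#> 2 gene001            piC01         0.8561439       TRUE
#> 3 gene003            piC03         0.5797872       TRUE
rep$pgf_calls[, c("cluster_id", "gene_id", "identity", "exons", "processed",
                  "five_prime_truncated", "tsd_seq")]
#>   cluster_id gene_id  identity     exons processed five_prime_truncated        tsd_seq
#> 1      piC01 gene001 0.9406897     1,2,3      TRUE                 TRUE   GGTAAGCGCGAG
#> 2      piC02 gene002 0.9186441 1,2,3,4,5      TRUE                 TRUE TTGGGGCTCGTGCT
#> 3      piC03 gene003 0.9635499     4,5,6      TRUE                 TRUE     GTTCTAGAGT
c(u1 = rep$u1, a10 = rep$a10)
#>    u1   a10
#> 0.811 0.247
```

Reading this: 1.9% of the library's reads are mRNA-targeting; the two top
genes absorb ~70% of that targeting mass; each of the three planted
regulons is called with the correct dominant cluster (compare
`ds$manifest$planted_regulons` — e.g. gene001's planted dominant share is
0.8561, recovered 0.8561); the three PGFs are found processed,
5′-truncated and antisense with identities matching their planted
divergences (0.05/0.08/0.03) and their target-site duplications recovered
verbatim; the strong 1U (0.81) with flat 10A (0.25) is the primary-
biogenesis signature the generator planted. `demo/out/` holds the
stage-by-stage TSVs (hits, ranking, origins, cis/trans, attribution,
regulons, PGF calls + GFF3, tiled rpm coverage, signatures, volcano and
ECDF tables) and `report.json`.

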