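# sporomir

Conserved-miRNA identification, degradome peak calling, and conservation
statistics for plant lineages without good genomes — lycophytes, ferns,
and anything else where genome-anchored miRNA annotation is off the
table.

## What it does

Given a small RNA-seq library, a catalog of annotated plant mature
miRNAs, and (optionally) genomic/transcript sequence and degradome/PARE
tags, sporomir runs the homology-first workflow used for genome-poor
plant surveys:

1. **Preprocess** — keep 16–26-nt reads; drop rRNA/tRNA/snoRNA/snRNA
   fragments (≤ 2 mismatches vs a structural reference, both strands);
   collapse 3′ U-tails (a run of ≥ 2 U becomes one U). RPM uses the
   18–26-nt read total as denominator.
2. **Identify** — a read is a candidate for a reference family at ≤ 2
   substitutions (5′-anchored) and ≤ 1 nt length difference;
   confusable families are merged (miR156 + miR157 → miR156/157);
   isoforms sharing 5′ nucleotides 1–16 form one cluster represented by
   the most abundant member; clusters are kept when the representative
   count exceeds max(10 reads, 5 RPM). Names:
   `{Species}-{family}-{arm}.{serial}_{rawcount}`.
3. **Hairpin-validate** — exact genome mapping, ± 200-nt windows, and
   the mature arm must have < 4 unpaired positions against its best
   star-arm register (a base-pair–maximization folder and a plug-in
   point for thermodynamic engines are included).
4. **Degradome** — exact sense mapping of ≥ 19-nt tags; a position is a
   cleavage peak iff the transcript has ≥ 12 unique tags, the position
   is in the top 12 by count, its RPM > 5, and its RPM > mean + 5 × SE
   over mapped positions. Peaks link to candidates when the site
   implied by cleavage between miRNA positions 10–11 scores ≤ 2.5.
5. **Targets & conservation** — plant-style target scoring (match 0,
   G:U 0.5, mismatch 1, gap 2; doubled at positions 2–13; cutoff 2.5),
   30-nt sliding-window nucleotide variation across orthogroups, size
   distributions, 24/21-nt ratios with an exact Wilcoxon rank-sum test,
   5′-nucleotide composition with Pearson χ², per-family
   consensus/variation, and clustering of the family × species
   log2(RPM+1) matrix into conservation classes I–V.

A seeded synthetic-data generator (catalogs, genomes with planted
hairpins, isomiR-structured libraries, degradome tags) makes every
stage verifiable by parameter recovery; see the methods vignette
(`vignettes/sporomir-methods.Rmd`) for the model, parameter meanings,
and design decisions.

## Worked example

```r
library(sporomir)

cfg     <- sim_config(seed = 42, n_families = 6, depth = 50000)
catalog <- generate_reference_catalog(cfg)
set.seed(7)
genome  <- paste(sample(c("A","C","G","U"), 3000, TRUE), collapse = "")
sim     <- simulate_library(catalog, genome, cfg)

rs    <- preprocess_reads(sim$reads)
cands <- identify_mirnas(rs, catalog, species_code = "Sim")
head(cands[, c("name","seq","raw_count","cluster_count","RPM")], 4)
```

```
                 name                     seq raw_count cluster_count   RPM
 Sim-miR104-3p.1_3668    CACGCCCUAAAGUACAAUUA      3668          6957 73360
 Sim-miR101-5p.2_2269    AAACUCCAUGUGUAACUCCG      2269          6849 45380
 Sim-miR106-5p.3_1716  AUGCCGAACGUUCUAAUAAACG      1716          5341 34320
 Sim-miR103-3p.4_3318 UUUCCAUAUCUCGUGAACCCCCU      3318          4314 66360
```

Each row is one candidate cluster: `raw_count` is the representative
isoform's reads, `cluster_count` sums all isoforms sharing its 5′
1–16 nt (here roughly half the family's reads sit in 3′-truncated and
U-tailed variants), and `RPM` normalizes by the 50,000-read 18–26-nt
total — so 3668 reads → 73,360 RPM. Serials follow descending cluster
count. `ratio_24_21(rs)` on this library returns `1.602566`: the 30%
planted 24-nt siRNA background against the 21-nt-dominant miRNA reads.

The same pipeline runs from the command line on files:

```sh
Rscript inst/scripts/sporomir.R all --config config.yaml --outdir out/
```

which writes `candidates.tsv`, `hairpin_loci.tsv`, `peaks.tsv`,
`peak_links.tsv`, `targets.tsv`, the summary statistics, and a log of
every threshold applied. Reruns are byte-identical.

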