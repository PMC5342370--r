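# pirliver

Profiling of PIWI-interacting RNAs (piRNAs) and novel piRNA-like loci
from small RNA sequencing of liver lesions.

`pirliver` is for researchers analysing bulk small RNA-seq across the
stepwise lesions of human hepatocarcinogenesis — cirrhotic nodule (CN),
low/high-grade dysplastic nodule (LGDN/HGDN), early and progressed
hepatocellular carcinoma (eHCC/pHCC) — who need a reproducible path from
adapter-trimmed reads to piRNA signatures, discovered piRNA-like
("piR_LLi") loci, biogenesis statistics, genomic context and predicted
transcript targets. Everything is seedable and validated end-to-end on a
synthetic study with planted ground truth.

## What it computes

* **Classification** — reads collapse to unique sequences with per-sample
  counts and are assigned by exact match to a known sncRNA annotation
  (`>ID|CLASS` FASTA), with a class priority (miRNA > rRNA > tRNA >
  snoRNA > piRNA) absorbing ambiguous sequences before piRNA counting.
* **Discovery** — unannotated 25–35 nt reads are scored by a k-mer
  (k = 1..5) log-odds discriminant trained on the known piRNAs vs decoy
  sncRNAs, placed on the genome by exact match (placement cap 30), and
  merged strand-aware into `piR_LLi_N` loci with per-sample coverage.
* **Expression** — RPM = 10⁶·c/N normalisation; mean-RPM-per-group
  filtering; two-sided Wilcoxon Mann–Whitney differential expression
  (exact for groups ≤ 8 without ties, tie-corrected normal otherwise);
  fold change as the ratio of group medians; Benjamini–Hochberg FDR per
  feature family; signature = |FC| ≥ 1.5 and FDR ≤ 0.05; stage-wise
  pattern labels (`flat`, `LGDN-restricted`, `up-from-HGDN`, ...);
  high-expression flagging (group mean ≥ 5000 RPM) with repertoire share.
* **Sequence features** — positional nucleotide composition (logo data)
  and the biogenesis signature: 5'-U bias present, position-10 A absent
  (primary pathway).
* **Genomic context** — 5'UTR/CDS/3'UTR/intron/intergenic assignment with
  exon-over-intron precedence and a ≥ 50 % overlap rule; sense/antisense
  orientation; piRNA-cluster membership; nuclear vs mitochondrial-like
  contigs.
* **Targets** — 20-nt guides cut from piRNA position 2, matched to the
  reverse complement of transcript windows with ≤ 3 mismatches
  (seed-and-extend, provably equal to a full Hamming scan), summarised
  per region and per molecule.
* **Clustering** — Ward agglomeration on the 1 − Kendall-τ (tau-b)
  sample dissimilarity, Newick export, and the log2 median-centered
  heatmap matrix.
* **Synthetic data** — a generator producing genome, annotation, reads,
  transcripts and ground truth (planted differential features, loci and
  target sites) under the study's sample design.

## A worked example

```r
library(pirliver)
cfg <- sim_config(seed = 7)        # the default synthetic liver study
res <- run_pipeline(cfg, out_dir = "pirliver_run")
```

The run logs each stage to stderr and prints:

```
pirliver pipeline result
  160 features x 55 samples simulated
  36 piR_LLi loci
  pirna signature: 10 features
  pirlli signature: 7 features
```

160 features (60 known piRNAs, 60 decoy sncRNAs, 40 planted loci) were
simulated over 55 samples across the five stages; discovery rebuilt 36
piR_LLi loci from the unannotated read pool (loci in the 81 %
low-expression tail emit too few reads to be seen); CN-vs-pHCC testing
called 10 known piRNAs and 7 piR_LLi loci into the |FC| ≥ 1.5,
FDR ≤ 0.05 signatures. The biogenesis report on the same run,

```
          test position base  fraction      p_value biased
T     5prime_U        1    T 0.7894737 4.165950e-28   TRUE
A position10_A       10    A 0.2315789 7.239605e-01  FALSE
```

shows the repertoire's 5'-T fraction (0.79, near the generator's
`u1_prob = 0.8`) flagged as biased while position-10 A stays at
background — the primary-pathway profile. Target search over the 17
signature guides found 36 sites (8 in 5'UTR, 20 in CDS, 8 in 3'UTR).

A command-line wrapper drives the same pipeline from YAML:

```sh
Rscript inst/scripts/pirliver.R all \
    --config inst/extdata/toy_config.yaml --out toy_out
```

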