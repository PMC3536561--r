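# estsnp

Discovery and validation of EST-derived SNPs in partially duplicated
(salmonid-like) genomes.

SNPs mined from EST contig assemblies are unreliable until genotyped:
sequencing errors create pseudo-SNPs that turn out monomorphic, and in a
semi-tetraploid genome (salmonids retain up to half of their loci in
duplicate after the 4R whole-genome duplication) co-assembled paralogues
masquerade as high-frequency variants. `estsnp` is for researchers
building genotyping panels from transcriptome resources in such species.
It implements the complete pipeline:

* **Discovery** — stringent candidate calling from per-contig gapped
  alignments: informative depth ≥ 7, the 4 flanking bases on each side
  exactly conserved, minor base seen ≥ 3 times, `N`/gap-aware counting.
  Frequency statistics by direct count: `p`, MAF, expected
  heterozygosity `He = 2pq`, polymorphism information content
  `PIC = He − 2p²q²`.
* **Panel selection** — spacing (≥ 60 nt between candidates), 100-nt
  flanks, genomic-contiguity check against a reference (exon–intron
  junction guard), a pluggable design scorer (threshold 0.6) and a
  31-mer cross-similarity filter, with a full per-candidate failure
  report.
* **Classification** — after GenCall/GenTrain ≥ 0.25 quality control,
  each assayed SNP becomes `failed`, `monomorphic`, `psv` (paralogous
  sequence variant: every valid call heterozygous, doubled haploids
  included) or `true`, with a multisite-variant (MSV) candidate flag when
  doubled-haploid calls mix `AB` with exactly one homozygote class — the
  signature of one fixed and one segregating paralogue.
* **Population-genetic summaries** — per-population allele frequencies by
  direct count, MAF bins, and transition/transversion tables with Ts/Tv
  ratios.
* **Annotation** — best-hit filtering of tabular homology results
  (e-value ≤ 1e−5, gene collapsing, HSP-product tie-break) and
  synonymous/non-synonymous calling by translating the hit window under
  both alleles.
* **Simulation** — a ground-truth-labelled generator of a
  pseudo-tetraploid gene set, EST alignments (with error and paralogue
  co-assembly) and a doubled-haploid + diploid genotyping panel, so the
  whole pipeline is testable end to end.

## Worked example

Simulate a 200-locus study, discover SNPs from the EST alignments, assay
the discovered candidates and classify them:

```r
library(estsnp)

cfg   <- sim_config(n_loci = 200, seed = 7)
truth <- simulate_gene_set(cfg)
est   <- simulate_est_alignments(truth, cfg)
cand  <- call_candidate_snps_all(est$alignments)
nrow(cand)
#> [1] 536
lab   <- label_candidates(cand, est$site_labels)
panel <- simulate_genotype_panel(truth, cfg, sites = lab)
cls   <- classify_genotypes(panel$matrix, panel$manifest)
table(cls$status)
#>
#>      failed monomorphic         psv        true
#>         112          14         360          50
```

The 536 discovered candidates partition into the four validation
statuses. The large `psv` class is the expected signature of a genome
with ~50% duplicated loci and co-assembling paralogues; `monomorphic`
SNPs are sequencing-error artefacts or polymorphisms absent from the
genotyped samples; the `true` class contains 4 MSV-flagged SNPs,
matching all 4 simulated multisite variants whose assays succeeded.

Ts/Tv arithmetic on a set of allele pairs:

```r
tt <- ts_tv_table(list(panel = c(rep("AG", 325), rep("CT", 529),
                                 rep("AC", 98), rep("AT", 49),
                                 rep("CG", 58), rep("GT", 93))))
tt$ratio
#> panel
#>  2.87
```

A thin command-line wrapper ships in `exec/estsnp`
(`simulate`, `discover`, `panel`, `classify`, `stats`, `annotate`):

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "estsnp", package = "estsnp"))')
Rscript "$CLI" simulate --out simdir --seed 5
Rscript "$CLI" discover --alignments simdir/alignments --out snps.tsv
Rscript "$CLI" classify --matrix simdir/calls.csv \
    --manifest simdir/samples.tsv --out class.tsv
```

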