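---
title: "Validating EST-derived SNPs in a partially duplicated genome"
author: "estsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating EST-derived SNPs in a partially duplicated genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estsnp)
```

## The problem

SNPs mined *in silico* from EST assemblies are cheap but unreliable. Two
failure modes dominate in salmonid-like genomes:

* **Pseudo-SNPs** — single-pass cDNA reads carry sequencing errors, so an
  apparent variant in an alignment may not exist; when genotyped it is
  monomorphic.
* **Paralogue artefacts** — salmonids descend from a fourth (4R)
  whole-genome duplication and remain semi-tetraploid, with up to half of
  loci still duplicated. When the two diverged copies of a gene
  co-assemble into one EST contig, their fixed differences look exactly
  like high-frequency SNPs. These *paralogous sequence variants* (PSVs)
  are false positives: the "alleles" never segregate, and a genotyping
  assay that reads both loci at once calls every individual heterozygous.
  A related, subtler class is the *multisite variant* (MSV): a site inside
  a duplicated pair where one copy is fixed and the other genuinely
  segregates — a true but duplicated SNP.

`estsnp` implements the full validation pipeline: stringent SNP discovery
from contig alignments, validation-panel selection, genotype-based
classification into failed / monomorphic / PSV / true (with MSV-candidate
flagging), population-genetic summaries, and synonymous/non-synonymous
annotation — together with a ground-truth-labelled simulator of the whole
data-generating process so that every stage is testable without external
data.

## Doubled haploids as a duplication detector

The classification hinges on doubled haploid (DH) individuals, whose
genomes are fully homozygous. Any heterozygous call in a DH betrays an
assay reading two paralogous loci at once:

| signal over valid calls | interpretation | status |
|---|---|---|
| one homozygote class everywhere | pseudo-SNP or absent polymorphism | `monomorphic` |
| every sample `AB`, including DHs | fixed inter-paralogue difference | `psv` |
| two or more genotype classes | segregating site | `true` |
| `true`, and DH calls mix `AB` with exactly one homozygote class | one paralogue fixed, one segregating | `true` + `msv_candidate` |

The MSV flag is a heuristic: confirming an MSV requires linkage mapping of
both homeologous positions, which is out of scope here. The flag's logic
follows from the assay superposition model: with paralogue 1 fixed for
allele A, a sample is called `AA` when its paralogue-2 genotype is `AA`
and `AB` otherwise, so DHs show a mixture of `AA` and `AB` and never
`BB`.

Quality control precedes classification: calls with GenCall < 0.25 are
masked, and SNPs with GenTrain < 0.25 or a valid-call rate below 0.80 are
`failed`. The score thresholds are the platform-standard stringent
cutoffs; the 0.80 call-rate rule is this package's operational stand-in
for "did not cluster well or failed to amplify", and is configurable. A
PSV tolerance knob (default 0, i.e. *every* valid call must be `AB`)
exists because real data are noisier than the strict rule.

## Discovery filters

`call_candidate_snps()` applies five stringent per-column filters:
informative depth ≥ 7; the 4 bases on each side of the site exactly
conserved between reads and consensus; lowest represented base seen ≥ 3
times; consensus gap columns skipped; and reads contributing `N`/gaps at a
column excluded from its counts. Two conventions the filters leave open
are resolved as follows: flank conservation is judged against the
*consensus* (not pairwise between reads); a read participates in a side's
conservation check only if it has no `N`/gap in that side's window, at
least one read must participate per side, and sites whose flank window is
truncated by the contig edge are rejected (panel selection requires 100-nt
flanks anyway). Sites with three or more observed bases are rejected, and
ties for the major base break alphabetically. Frequency statistics come by
direct count of sequence depth: `p = major/(major+minor)`, expected
heterozygosity `He = 2pq`, and polymorphism information content
`PIC = He − 2p²q²` (maxima 0.5 and 0.375 at `p = 0.5`).

## Panel selection

`select_panel()` evaluates five pure predicates over the full candidate
set, so the report is order-independent and partitions the input:

* **spacing** — candidates closer than 60 nt are removed, *both* members
  of a close pair (the source procedure does not say whether one member
  was retained; a keep-better-scored variant is available behind a flag);
* **flank length** — at least 100 nt of contig on each side;
* **genomic contiguity** — the full 201-nt window (either allele at the
  site) must occur contiguously in a supplied reference on either strand,
  guarding against probes spanning exon–intron junctions; skipped with a
  warning when no reference is given;
* **design score** — the proprietary assay-design score is replaced by a
  pluggable scorer. The built-in proxy starts at 1 and penalises flank GC
  outside [0.30, 0.70] (−0.3), a ≥ 6-nt homopolymer within 60 nt of the
  site (−0.3), any `N` in the flanks (−0.5) and another candidate within
  60 nt (−0.2), floored at 0; the published acceptance threshold of 0.6
  is kept;
* **similarity** — cross-similarity/repeat screening is operationalised
  as exact 31-mer sharing between the flank windows of candidates on
  *different* contigs (same-contig windows overlap by construction at the
  spacing distance and are ignored); both sharers are removed.

## Annotation

Homology searching itself is consumed, not executed: hits arrive as
standard 12/13-column tabular files. `filter_best_hits()` applies the
three published filtration steps — e-value ≤ 1e−5, protein-to-gene
collapsing, minimal e-value per query with ties broken by the largest
HSP product (% identity × alignment length); residual cross-gene ties are
flagged ambiguous. `classify_substitution()` replaces the second
homology round with exact translation comparison, which is equivalent for
perfect-match / one-mismatch logic: the hit window is translated under
both alleles (standard genetic code, no initiator special-casing; a codon
containing `N` is unresolved; internal stops truncate). Both peptides
identical to the reference window ⇒ synonymous; exactly one amino-acid
difference with one allele matching the reference ⇒ non-synonymous; a
SNP-level hit to a different gene than the contig's ⇒ `discordant_hit`,
excluded from the synonymous/non-synonymous call, mirroring the published
exclusion. Multi-HSP queries use single-best-HSP semantics. Frames come
from the hit record (default +1 when the column is absent);
`infer_frame()` offers stop-minimising inference for frameless inputs.

## What the simulator emulates

`simulate_gene_set()` → `simulate_est_alignments()` →
`simulate_genotype_panel()` generate a labelled pseudo-tetraploid gene
set, its EST alignments and a genotyping panel. Defaults are the study
conditions where the study states them, and documented choices where it
does not:

* `dup_fraction = 0.5` — about half of loci residually duplicated.
* `mean_depth = 12.7` in `[7, 466]` — the reported coverage; depths are
  drawn from a lognormal (sdlog 0.7) truncated to the range, with meanlog
  solved numerically so the truncated mean matches.
* Panel of 47 DH plus 20/20/44 diploids over three populations;
  per-population allele frequencies follow a Balding–Nichols draw around
  the ancestral frequency with `fst = 0.15` per group, a typical
  differentiation among domestic strains (`fst = 0` reproduces the
  ancestral frequency exactly).
* Ancestral frequencies of segregating sites are uniform on
  `[0.2, 0.8]`, matching the reported mean minor sequence frequency of
  ≈ 0.36–0.37 (± 0.10) in the source database and panel.
* `per_base_error_rate = 0.003` i.i.d. with a uniform substitution
  target — the simplest model generating pseudo-SNPs.
* `private_snp_frac = 0.25`: a quarter of segregating sites are present
  in the EST source but absent from the genotyped populations. EST
  libraries derive from few, genetically narrow individuals, and absent
  polymorphisms are a documented cause of monomorphic assays; at depth
  12.7 a 0.3% error rate alone cannot produce a sizeable monomorphic
  class.
* `paralog_divergence = 0.02` fixed differences per base between
  paralogues; `co_assembly_prob = 0.8` of a duplicated pair assembling
  into one contig (all-or-nothing; partial assembly is not modelled);
  `msv_fraction = 0.1` of duplicated loci carry one site segregating on
  exactly one paralogue.
* `true_snp_rate = 1.5` expected segregating sites per non-duplicated
  locus; `gene_length = 600` nt of stop-free coding sequence.
* Assay noise: miscalls (0.5% of calls) are emitted with GenCall scores
  *below* the 0.25 validity cutoff — the model assumes miscalls cluster
  poorly and are exactly what the GenCall filter exists to remove.
  `assay_fail_rate = 0.17` of SNPs are injected as failures (the reported
  failed-assay rate), half via sub-threshold GenTrain and half via
  degraded per-call scores.

Everything is deterministic given the seed; the three stages use
`seed`, `seed + 1` and `seed + 2`.

What the simulator does **not** model: read-level assembly (no
overlap-layout, all reads span the contig), indels and recombination,
shared segregating sites on both paralogues of a duplicated pair,
high-confidence miscalls that survive quality control, and intensity-space
cluster calling. Consequently, passing recovery tests demonstrates the
*logic* of the classification rules under the assay superposition model,
not robustness to clustered real-world noise — on real data the PSV
tolerance knob and call-rate threshold would need tuning.

The per-SNP truth table emitted by `simulate_genotype_panel()` carries
both the generative class (`true_snp`, `psv`, `msv`, `pseudo_snp`) and an
`expected_status`: the status a perfect classifier should output *given
the drawn genotypes*. The two differ legitimately — a true SNP whose
minor allele was never sampled into the panel is expected `monomorphic`;
an MSV whose every sample carries both alleles is expected `psv`. Recovery
is scored against `expected_status`.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_loci = 200, seed = 7)
truth <- simulate_gene_set(cfg)
est <- simulate_est_alignments(truth, cfg)
cand <- call_candidate_snps_all(est$alignments)
lab <- label_candidates(cand, est$site_labels)
panel <- simulate_genotype_panel(truth, cfg, sites = lab)
cls <- classify_genotypes(panel$matrix, panel$manifest)
table(cls$status)
```

## Numerical conventions

* Coordinates are 0-based half-open internally and 1-based inclusive in
  all on-disk tables, matching the homology-table convention.
* Genotypes are unordered (`BA` ≡ `AB`); `NC` calls always carry GenCall
  0.
* Ts/Tv ratios are rounded half-away-from-zero to two decimals and type
  percentages to one decimal. On the published panel counts this
  reproduces 2.87 (validation panel), 4.07 (synonymous) and 1.15
  (non-synonymous); the polymorphic column's own counts give
  272/78 = 3.487, i.e. 3.49 — one hundredth above the figure printed in
  the source table, whose rounding is internally inconsistent there.
* MAF bins are half-open `[0, 0.05), …, [0.40, 0.50]` with a closed top
  edge, since a MAF cannot exceed 0.5; the published bin table contains
  an obvious typo in its fifth bin label, read here as `[0.30, 0.40)` so
  that the bins partition `[0, 0.5]`.
* A genotype matrix written by the package renders quality scores at four
  decimals (the granularity the simulator draws), so simulator output
  round-trips bit-identically.

## Problem sizes used in the checks

The shipped test suite exercises discovery–classification recovery on a
2,000-locus simulation (≈ 5,700 assayed SNPs after discovery), discovery
equivalence against an independent brute-force scanner on 500 contigs,
and annotation recovery on 500 coding SNPs — sizes chosen to estimate
per-class precision and recall with narrow binomial error while keeping a
single-CPU run short.

## Limitations

The pipeline validates biallelic substitutions only (no indels), assumes
unlinked sites (no LD or pedigree structure), and flags MSV candidates
heuristically rather than by linkage confirmation. Deleteriousness
prediction and population-structure inference are intentionally out of
scope; `nonsynonymous` records are export-ready for external tools.
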