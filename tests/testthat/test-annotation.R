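test_that("best-hit filtering: e-value, gene collapse, HSP tie-break", {
  h <- make_hit_table(query = rep("q1", 2), subject = c("p1", "p2"),
                      pct = c(90, 90), len = c(100, 100),
                      evalue = c(1e-10, 1e-8))
  best <- filter_best_hits(h)
  expect_identical(nrow(best), 1L)
  expect_identical(best$subject_protein_id, "p1")

  # tie at minimal e-value: highest pct_identity x aln_len wins
  h2 <- make_hit_table(query = rep("q1", 2), subject = c("p1", "p2"),
                       pct = c(95, 90), len = c(100, 120),
                       evalue = c(1e-10, 1e-10))
  best2 <- filter_best_hits(h2)
  expect_identical(best2$subject_protein_id, "p2")   # 10800 > 9500
  expect_false(best2$ambiguous)

  # a hit above the cutoff is dropped entirely
  h3 <- make_hit_table("q1", "p1", 90, 100, evalue = 1e-4)
  expect_identical(nrow(filter_best_hits(h3)), 0L)

  # protein ids collapse to gene ids before the tie-break: an exact tie
  # within one gene is not ambiguous
  h4 <- make_hit_table(query = rep("q1", 2), subject = c("p1a", "p1b"),
                       pct = c(90, 90), len = c(100, 100),
                       evalue = c(1e-10, 1e-10))
  best4 <- filter_best_hits(h4, protein_to_gene = c(p1a = "g1", p1b = "g1"))
  expect_identical(nrow(best4), 1L)
  expect_identical(best4$subject_gene_id, "g1")
  expect_false(best4$ambiguous)

  # across different genes the tie is flagged ambiguous, both retained
  best5 <- filter_best_hits(h4, protein_to_gene = c(p1a = "g1", p1b = "g2"))
  expect_identical(nrow(best5), 2L)
  expect_true(all(best5$ambiguous))
})

test_that("peptide windows translate, reverse-complement and stop-truncate", {
  w <- build_peptide_window("ATGGCTTAA", 1, 9, 1)
  expect_identical(w$peptide, "MA")
  expect_true(w$truncated)

  w2 <- build_peptide_window("ATGGCTGCA", 1, 9, 1)
  expect_identical(w2$peptide, "MAA")
  expect_false(w2$truncated)

  # reverse-strand window equals translation of the reverse complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGCTGCA")))
  w3 <- build_peptide_window(rc, 1, 9, -1)
  expect_identical(w3$peptide, "MAA")

  # trailing partial codon dropped; too-short window errors
  expect_identical(build_peptide_window("ATGGC", 1, 5, 1)$peptide, "M")
  expect_error(build_peptide_window("ATGGC", 1, 2, 1), "3 nt")
  expect_error(build_peptide_window("ATG", 2, 5, 1), "outside")
})

test_that("substitutions classify by the genetic code", {
  hit <- make_hit_table("c1", "g1", 99, 3, 1e-20)
  hit$qend <- 9L
  hit$subject_gene_id <- "g1"
  shit <- hit; shit$query_id <- "s1"
  # GCT vs GCC: both Ala -> synonymous
  r <- classify_substitution("ATGGCTTGG", 5, "T", "C", hit, shit, "s1")
  expect_identical(r$effect, "synonymous")
  expect_identical(r$codon_index, 1L)
  # GCT vs GAT: Ala -> Asp
  r2 <- classify_substitution("ATGGCTTGG", 4, "C", "A", hit, shit, "s1")
  expect_identical(r2$effect, "nonsynonymous")
  expect_identical(r2$ref_aa, "A"); expect_identical(r2$alt_aa, "D")
  # symmetry: allele labels swapped give the same call with roles flipped
  r3 <- classify_substitution("ATGGCTTGG", 4, "A", "C", hit, shit, "s1")
  expect_identical(r3$effect, "nonsynonymous")
  expect_identical(r3$ref_aa, "A"); expect_identical(r3$alt_aa, "D")

  # no SNP-level hit / discordant gene
  expect_identical(classify_substitution("ATGGCTTGG", 5, "T", "C", hit,
                                         NULL, "s1")$effect, "no_hit")
  shit2 <- shit; shit2$subject_gene_id <- "g2"
  expect_identical(classify_substitution("ATGGCTTGG", 5, "T", "C", hit,
                                         shit2, "s1")$effect,
                   "discordant_hit")
  # SNP outside the hit window, N in the codon
  hit2 <- hit; hit2$qstart <- 4L; hit2$qend <- 9L
  expect_identical(classify_substitution("ATGGCTTGG", 0, "A", "G", hit2,
                                         shit, "s1")$effect, "unresolved")
  rN <- classify_substitution("ATGGNTTGG", 5, "T", "C", hit, shit, "s1")
  expect_identical(rN$effect, "unresolved")
  expect_identical(rN$reason, "ambiguous_codon")
  # a nonsense allele changes peptide length -> unresolved
  rS <- classify_substitution("ATGTGCTGG", 5, "C", "A", hit, shit, "s1")
  expect_identical(rS$effect, "unresolved")
  expect_identical(rS$reason, "stop_length_change")
})

test_that("third positions of 4-fold degenerate codons are always synonymous", {
  fourfold <- c("GC", "CG", "GG", "CT", "CC", "TC", "AC", "GT")
  hit <- make_hit_table("c1", "g1", 99, 2, 1e-20); hit$qend <- 6L
  hit$subject_gene_id <- "g1"
  shit <- hit; shit$query_id <- "s1"
  for (pre in fourfold) {
    for (third in list(c("A", "C"), c("G", "T"), c("A", "G"), c("C", "T"))) {
      seqs <- paste0("ATG", pre, third[1], collapse = "")
      r <- classify_substitution(seqs, 5, third[1], third[2], hit, shit, "s1")
      expect_identical(r$effect, "synonymous")
    }
  }
})

test_that("annotation recovers the simulated truth on coding SNPs", {
  sim <- simulate_coding_snps(150, seed = 17)
  ann <- annotate_snps(sim$snps, sim$contigs, sim$contig_hits, sim$snp_hits)
  expect_identical(ann$snp_id, sim$snps$snp_id)
  expect_identical(ann$effect, sim$snps$effect_truth)
  ns <- ann$effect == "nonsynonymous"
  expect_gt(sum(ns), 50)
  expect_identical(ann$ref_aa[ns], sim$snps$ref_aa[ns])
  expect_identical(ann$alt_aa[ns], sim$snps$alt_aa[ns])
  # effects partition the annotated set
  expect_identical(sum(table(ann$effect)), nrow(sim$snps))
})

test_that("package translation agrees with an independent oracle", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(5:40, 1) * 3
    dna <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    pep <- build_peptide_window(dna, 1, n, 1)
    oracle <- paste(seqinr::translate(strsplit(dna, "")[[1]]), collapse = "")
    oracle <- sub("\\*.*$", "", oracle)
    expect_identical(pep$peptide, oracle)
  }
})

test_that("frame inference matches an independent stop-count argmin", {
  # independent oracle: count stops per frame via a literal codon scan
  stop_count <- function(seqs) {
    n <- 3 * (nchar(seqs) %/% 3)
    codons <- substring(seqs, seq(1, n, 3), seq(3, n, 3))
    sum(codons %in% c("TAA", "TAG", "TGA"))
  }
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  set.seed(42)
  for (rep in 1:10) {
    w <- paste(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = "")
    frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
    stops <- vapply(frames, function(f) {
      s <- if (f < 0) rc(w) else w
      stop_count(substr(s, abs(f), nchar(s)))
    }, numeric(1))
    expect_identical(infer_frame(w), frames[which.min(stops)])
  }
  # and a clean CDS is read in frame +1
  cds <- paste(rep(c("ATG", "GCT", "TGG", "CAT"), 15), collapse = "")
  expect_identical(infer_frame(cds), 1L)
})
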