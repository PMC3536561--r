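rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

cand_at <- function(contig_id, pos, major = "A", minor = "G") {
  data.frame(contig_id = contig_id, pos = as.integer(pos),
             major_base = major, minor_base = minor, stringsAsFactors = FALSE)
}

test_that("spacing filter removes both members of close pairs", {
  cands <- cand_at("c1", c(100, 159))
  expect_identical(spacing_filter(cands, 60), c(FALSE, FALSE))  # gap 59
  cands2 <- cand_at("c1", c(100, 160))
  expect_identical(spacing_filter(cands2, 60), c(TRUE, TRUE))   # gap 60 kept
  # candidates on different contigs never conflict
  cands3 <- rbind(cand_at("c1", 100), cand_at("c2", 110))
  expect_identical(spacing_filter(cands3, 60), c(TRUE, TRUE))

  # brute-force all-pairs check on a random 50-candidate contig
  set.seed(31)
  pos <- sample(5000, 50)
  cands4 <- cand_at("c1", pos)
  oracle <- vapply(seq_along(pos), function(i) {
    all(abs(pos[-i] - pos[i]) >= 60)
  }, logical(1))
  expect_identical(spacing_filter(cands4, 60), oracle)
})

test_that("spacing keep-better variant retains the better-scored member", {
  cands <- cand_at("c1", c(100, 140))
  keep <- spacing_filter(cands, 60, keep_better = TRUE, scores = c(0.9, 0.7))
  expect_identical(keep, c(TRUE, FALSE))
})

test_that("flank-length filter is the closed-form position window", {
  lens <- c(c1 = 300L)
  expect_false(flank_length_filter(cand_at("c1", 99), lens, 100))
  expect_true(flank_length_filter(cand_at("c1", 100), lens, 100))
  expect_true(flank_length_filter(cand_at("c1", 199), lens, 100))
  expect_false(flank_length_filter(cand_at("c1", 200), lens, 100))
  # closed form on a simulated candidate set
  set.seed(8)
  cands <- cand_at("c1", sample(0:299, 40))
  expect_identical(flank_length_filter(cands, lens, 100),
                   cands$pos >= 100 & cands$pos <= 199)
})

test_that("genomic contiguity requires an exact window match on either strand", {
  set.seed(21)
  contig <- rand_seq(301)
  contigs <- c(c1 = contig)
  cands <- cand_at("c1", 150, major = substr(contig, 151, 151),
                   minor = setdiff(c("A", "C", "G", "T"),
                                   substr(contig, 151, 151))[1])
  window <- substr(contig, 51, 251)
  ref_hit <- c(chr1 = paste0(rand_seq(200), window, rand_seq(200)))
  expect_true(genomic_contiguity_filter(cands, contigs, ref_hit, 100))

  # reverse strand also counts
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  ref_rc <- c(chr1 = paste0(rand_seq(100), rc(window), rand_seq(100)))
  expect_true(genomic_contiguity_filter(cands, contigs, ref_rc, 100))

  # an intron inserted mid-flank breaks contiguity
  ref_intron <- c(chr1 = paste0(substr(window, 1, 60), rand_seq(80),
                                substr(window, 61, 201)))
  expect_false(genomic_contiguity_filter(cands, contigs, ref_intron, 100))

  # missing reference: skipped with a warning
  expect_warning(res <- genomic_contiguity_filter(cands, contigs, NULL),
                 "skipped")
  expect_true(is.na(res))
})

test_that("proxy design score applies the documented penalties", {
  set.seed(4)
  # clean balanced flank -> 1.0
  clean <- paste(rep("ACGT", 80), collapse = "")
  cands <- cand_at("c1", 160)
  expect_equal(proxy_design_score(cands, c(c1 = clean)), 1.0)

  # homopolymer run near the site -> 0.7 (still kept at 0.6)
  hp <- clean
  substr(hp, 170, 176) <- "AAAAAAA"
  expect_equal(proxy_design_score(cands, c(c1 = hp)), 0.7)

  # homopolymer + extreme GC -> 0.4, removed
  at_rich <- paste(rep("ATAT", 80), collapse = "")
  substr(at_rich, 170, 176) <- "AAAAAAA"
  expect_equal(proxy_design_score(cands, c(c1 = at_rich)), 0.4)
  keep <- design_score_filter(cands, c(c1 = at_rich))
  expect_false(as.logical(keep))

  # N in flank -> -0.5
  nseq <- clean
  substr(nseq, 100, 100) <- "N"
  expect_equal(proxy_design_score(cands, c(c1 = nseq)), 0.5)

  # a neighbouring candidate within 60 nt -> -0.2 for both
  two <- rbind(cand_at("c1", 160), cand_at("c1", 200))
  expect_equal(proxy_design_score(two, c(c1 = clean)), c(0.8, 0.8))

  # constant scorer below threshold removes everything; invalid scorer errors
  low <- function(cands, contigs) rep(0.59, nrow(cands))
  expect_false(any(design_score_filter(two, c(c1 = clean), scorer = low)))
  bad <- function(cands, contigs) rep(1.2, nrow(cands))
  expect_error(design_score_filter(two, c(c1 = clean), scorer = bad), "0, 1")
})

test_that("similarity filter removes cross-contig k-mer sharers", {
  set.seed(12)
  shared <- rand_seq(40)
  c1 <- paste0(rand_seq(130), shared, rand_seq(131))
  c2 <- paste0(rand_seq(110), shared, rand_seq(151))
  c3 <- rand_seq(301)
  contigs <- c(c1 = c1, c2 = c2, c3 = c3)
  cands <- rbind(cand_at("c1", 150), cand_at("c2", 130), cand_at("c3", 150))
  expect_identical(similarity_filter(cands, contigs, k = 31, flank = 100),
                   c(FALSE, FALSE, TRUE))
})

test_that("select_panel reports failures, partitions input, order-free", {
  set.seed(9)
  contig <- rand_seq(600)
  contigs <- c(c1 = contig)
  pos <- c(50, 200, 230, 400)   # 50 fails flank; 200/230 fail spacing
  cands <- do.call(rbind, lapply(pos, function(p) {
    cand_at("c1", p, major = substr(contig, p + 1, p + 1),
            minor = setdiff(c("A", "C", "G", "T"),
                            substr(contig, p + 1, p + 1))[1])
  }))
  rep1 <- select_panel(cands, contigs, reference = NULL)
  expect_identical(attr(rep1, "skipped_filters"), "genomic_contiguity")
  expect_identical(rep1$kept, c(FALSE, FALSE, FALSE, TRUE))
  expect_match(rep1$failed_filters[1], "flank_length")
  expect_match(rep1$failed_filters[2], "spacing")
  expect_identical(rep1$kept, !nzchar(rep1$failed_filters))

  # every filter is computed on the pre-filter set: the report is invariant
  # to candidate row order
  perm <- c(3, 1, 4, 2)
  rep2 <- select_panel(cands[perm, ], contigs, reference = NULL)
  expect_identical(rep2$snp_id, rep1$snp_id[perm])
  expect_identical(rep2$kept, rep1$kept[perm])
  expect_identical(rep2$failed_filters, rep1$failed_filters[perm])
})

test_that("select_panel on simulated discovery output keeps a sane panel", {
  cfg <- sim_config(n_loci = 30, seed = 13, gene_length = 900)
  est <- simulate_est_alignments(simulate_gene_set(cfg), cfg)
  cand <- call_candidate_snps_all(est$alignments)
  contigs <- vapply(est$alignments, function(a) a$consensus, character(1))
  rep <- select_panel(cand, contigs, reference = NULL)
  expect_identical(nrow(rep), nrow(cand))
  expect_identical(rep$kept, !nzchar(rep$failed_filters))
  # capping keeps the best-scoring survivors
  n_kept <- sum(rep$kept)
  if (n_kept > 2) {
    capped <- select_panel(cand, contigs, reference = NULL, n_max = 2)
    expect_identical(sum(capped$kept), 2L)
    expect_true(min(capped$design_score[capped$kept]) >=
                  max(capped$design_score[rep$kept & !capped$kept]))
  }
})
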