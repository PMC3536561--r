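test_that("config validation and YAML round-trip", {
  cfg <- sim_config(n_loci = 10, seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$gene_length %% 3L, 0L)
  expect_error(sim_config(dup_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_loci = 0), "n_loci")
  expect_error(sim_config(depth_min = 0), "depth")

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_loci: 12", "dup_fraction: 0.4", "seed: 9",
               "populations:",
               "  - {label: A, fst: 0.1, n_dh: 5, n_diploid: 0}",
               "  - {label: B, fst: 0.1, n_dh: 0, n_diploid: 8}"), f)
  cfg2 <- read_sim_config(f)
  expect_identical(cfg2$n_loci, 12L)
  expect_identical(nrow(cfg2$populations), 2L)
})

test_that("gene set simulation is seed-deterministic and honours defaults", {
  cfg <- sim_config(n_loci = 80, seed = 11)
  t1 <- simulate_gene_set(cfg)
  t2 <- simulate_gene_set(cfg)
  expect_identical(t1, t2)

  # default panel: 47 DH plus 20/20/44 diploids
  expect_identical(nrow(t1$manifest), 131L)
  expect_identical(sum(t1$manifest$ploidy_class == "DH"), 47L)

  # DH dosages are homozygous (0 or 2) at every site
  dh <- t1$manifest$ploidy_class == "DH"
  g <- t1$genotypes[, dh]
  expect_false(any(g == 1L, na.rm = TRUE))

  # PSV sites carry a fixed inter-paralog difference; MSV sites sit on
  # exactly one paralog
  s <- t1$sites
  expect_true(all(s$allele_A[s$class == "psv"] != s$allele_B[s$class == "psv"]))
  expect_true(all(s$paralog[s$class == "msv"] == 2L))
  expect_true(all(s$paralog[s$class == "true_snp"] == 1L))
})

test_that("dup_fraction controls duplication; degenerate settings are exact", {
  cfg0 <- sim_config(n_loci = 50, dup_fraction = 0, seed = 2)
  t0 <- simulate_gene_set(cfg0)
  expect_false(any(t0$loci$duplicated))
  expect_false(any(t0$sites$class %in% c("psv", "msv")))

  # binomial check at n = 2000
  cfg <- sim_config(n_loci = 2000, dup_fraction = 0.5, seed = 3)
  tr <- simulate_gene_set(cfg)
  frac <- mean(tr$loci$duplicated)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("fst = 0 copies the ancestral frequency into every population", {
  pops <- data.frame(label = c("X", "Y"), fst = 0,
                     n_dh = c(4L, 0L), n_diploid = c(0L, 6L))
  cfg <- sim_config(n_loci = 40, dup_fraction = 0, populations = pops,
                    private_snp_frac = 0, seed = 4)
  tr <- simulate_gene_set(cfg)
  expect_equal(tr$sites$p_X, tr$sites$p_anc)
  expect_equal(tr$sites$p_Y, tr$sites$p_anc)
})

test_that("error-free, invariant, non-duplicated loci give identical reads", {
  cfg <- sim_config(n_loci = 12, dup_fraction = 0, true_snp_rate = 0,
                    per_base_error_rate = 0, seed = 6)
  tr <- simulate_gene_set(cfg)
  est <- simulate_est_alignments(tr, cfg)
  for (a in est$alignments) {
    expect_true(all(a$reads == a$consensus))
  }
  expect_identical(nrow(est$site_labels), 0L)
})

test_that("a PSV site in a co-assembled contig has ~50% minor frequency", {
  cfg <- sim_config(n_loci = 40, dup_fraction = 1, co_assembly_prob = 1,
                    true_snp_rate = 0, msv_fraction = 0,
                    per_base_error_rate = 0, mean_depth = 60,
                    depth_min = 40, depth_max = 120, seed = 7)
  tr <- simulate_gene_set(cfg)
  est <- simulate_est_alignments(tr, cfg)
  cand <- call_candidate_snps_all(est$alignments)
  lab <- label_candidates(cand, est$site_labels)
  psv <- lab[lab$class == "psv", ]
  expect_gt(nrow(psv), 100)
  # reads split binomial(depth, 1/2) between paralogs, so the paralog-2
  # base frequency averages 0.5
  freq_b <- vapply(seq_len(nrow(psv)), function(i) {
    psv[[paste0("count_", psv$allele_B[i])]][i] / psv$depth[i]
  }, numeric(1))
  expect_lt(abs(mean(freq_b) - 0.5), 0.02)
})

test_that("pseudo-SNP call fraction rises with the error rate", {
  frac_pseudo <- vapply(c(0.001, 0.003, 0.01), function(e) {
    cfg <- sim_config(n_loci = 1200, per_base_error_rate = e, seed = 55)
    tr <- simulate_gene_set(cfg)
    est <- simulate_est_alignments(tr, cfg)
    cand <- call_candidate_snps_all(est$alignments)
    mean(label_candidates(cand, est$site_labels)$class == "pseudo_snp")
  }, numeric(1))
  expect_true(all(diff(frac_pseudo) >= 0))
  expect_gt(frac_pseudo[3], frac_pseudo[1])
})

test_that("assay map: PSV all AB; MSV mixes AA/AB without BB; DH homozygous", {
  cfg <- sim_config(n_loci = 120, seed = 19, genotype_error_rate = 0,
                    assay_fail_rate = 0)
  tr <- simulate_gene_set(cfg)
  panel <- simulate_genotype_panel(tr, cfg)
  m <- panel$matrix; lab <- panel$truth
  dh <- panel$manifest$ploidy_class == "DH"

  psv_rows <- lab$class == "psv"
  expect_true(all(m$calls[psv_rows, ] == "AB"))

  msv_rows <- lab$class == "msv"
  expect_gt(sum(msv_rows), 2)
  expect_false(any(m$calls[msv_rows, ] == "BB"))

  # DH calls at non-duplicated SNPs are never heterozygous
  true_rows <- lab$class == "true_snp"
  expect_false(any(m$calls[true_rows, dh] == "AB"))

  # an MSV with segregating-paralog frequency q has expected DH AA
  # fraction 1 - q (direct enumeration of the assay map)
  sites <- tr$sites[match(lab$site_id[msv_rows], tr$sites$site_id), ]
  q_dh <- sites$p_DHL
  aa_frac <- rowMeans(m$calls[msv_rows, dh, drop = FALSE] == "AA")
  expect_lt(max(abs(aa_frac - (1 - q_dh))), 0.35)   # 47 DH, binomial noise
  expect_lt(abs(mean(aa_frac - (1 - q_dh))), 0.05)
})

test_that("panel byte-determinism and truth-label conservation", {
  cfg <- sim_config(n_loci = 40, seed = 29)
  tr <- simulate_gene_set(cfg)
  p1 <- simulate_genotype_panel(tr, cfg)
  p2 <- simulate_genotype_panel(tr, cfg)
  expect_identical(p1, p2)
  expect_false(anyDuplicated(p1$truth$snp_id) > 0)
  expect_true(all(p1$truth$expected_status %in%
                    c("failed", "monomorphic", "psv", "true")))
  # a fixed true SNP (private to the EST source) is expected monomorphic
  priv <- tr$sites$site_id[tr$sites$private]
  lab_priv <- p1$truth[p1$truth$site_id %in% priv & !p1$truth$injected_fail, ]
  expect_true(all(lab_priv$expected_status == "monomorphic"))
})

test_that("simulated alignments round-trip through gapped FASTA", {
  cfg <- sim_config(n_loci = 5, seed = 31, gene_length = 120)
  est <- simulate_est_alignments(simulate_gene_set(cfg), cfg)
  a <- est$alignments[[1]]
  f <- withr::local_tempfile(fileext = ".fa")
  write_contig_alignment(a, f)
  expect_identical(read_contig_alignment(f), a)
})
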