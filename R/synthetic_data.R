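## Ground-truth-labelled simulator of a partially duplicated,
## salmonid-like pseudo-tetraploid gene set: coding loci of which a
## configurable fraction is residually duplicated, EST contig alignments
## with sequencing error and paralog co-assembly, and a doubled-haploid +
## diploid genotyping panel whose assays read the superposition of both
## paralogs at duplicated loci.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                              DNA_BASES, paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

default_populations <- function() {
  data.frame(
    label = c("DHL", "SYN", "SPR", "NCW"),
    fst = 0.15,
    n_dh = c(47L, 0L, 0L, 0L),
    n_diploid = c(0L, 20L, 20L, 44L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults emulate the published study conditions: about half of loci
#' residually duplicated, EST coverage averaging 12.7 reads/contig in
#' \[7, 466\], and a panel of 47 doubled haploids plus 20/20/44 diploids
#' from three differentiated populations. The remaining rates are
#' documented package choices (see the methods vignette).
#'
#' @param n_loci number of gene loci (locus = a gene, possibly duplicated).
#' @param dup_fraction probability a locus is residually duplicated.
#' @param mean_depth target mean EST reads per contig.
#' @param depth_min,depth_max truncation bounds of the depth distribution.
#' @param per_base_error_rate i.i.d. per-base sequencing error probability.
#' @param paralog_divergence per-base fixed-difference rate between
#'   paralogs (each such base is a PSV site).
#' @param co_assembly_prob probability a duplicated pair co-assembles into
#'   a single contig.
#' @param populations data.frame with `label`, `fst`, `n_dh`, `n_diploid`.
#' @param true_snp_rate expected segregating sites per non-duplicated
#'   locus (Poisson).
#' @param msv_fraction fraction of duplicated loci carrying a segregating
#'   site on exactly one paralog (an MSV).
#' @param private_snp_frac fraction of segregating sites present in the
#'   EST source but absent from the genotyped populations (assayed
#'   monomorphic).
#' @param genotype_error_rate per-call probability of a low-confidence
#'   miscall (emitted with a GenCall score below the 0.25 validity
#'   cutoff).
#' @param assay_fail_rate fraction of assays injected as failures (half by
#'   sub-threshold GenTrain, half by degraded call rate).
#' @param gene_length locus length in nt (rounded up to a codon multiple).
#' @param seed integer seed; all three simulation stages derive their
#'   streams from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 200L, dup_fraction = 0.5, mean_depth = 12.7,
                       depth_min = 7L, depth_max = 466L,
                       per_base_error_rate = 0.003,
                       paralog_divergence = 0.02, co_assembly_prob = 0.8,
                       populations = default_populations(),
                       true_snp_rate = 1.5, msv_fraction = 0.1,
                       private_snp_frac = 0.25,
                       genotype_error_rate = 0.005, assay_fail_rate = 0.17,
                       gene_length = 600L, seed = 1L) {
  cfg <- list(n_loci = as.integer(n_loci), dup_fraction = dup_fraction,
              mean_depth = mean_depth, depth_min = as.integer(depth_min),
              depth_max = as.integer(depth_max),
              per_base_error_rate = per_base_error_rate,
              paralog_divergence = paralog_divergence,
              co_assembly_prob = co_assembly_prob,
              populations = as.data.frame(populations),
              true_snp_rate = true_snp_rate, msv_fraction = msv_fraction,
              private_snp_frac = private_snp_frac,
              genotype_error_rate = genotype_error_rate,
              assay_fail_rate = assay_fail_rate,
              gene_length = 3L * ((as.integer(gene_length) + 2L) %/% 3L),
              seed = as.integer(seed))
  probs <- c("dup_fraction", "per_base_error_rate", "paralog_divergence",
             "co_assembly_prob", "msv_fraction", "private_snp_frac",
             "genotype_error_rate", "assay_fail_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$n_loci < 1L) stop("n_loci must be >= 1")
  if (cfg$depth_min < 1L || cfg$depth_max < cfg$depth_min) {
    stop("invalid depth bounds")
  }
  need <- c("label", "fst", "n_dh", "n_diploid")
  if (!all(need %in% names(cfg$populations))) {
    stop("populations needs columns: ", paste(need, collapse = ", "))
  }
  if (any(cfg$populations$fst < 0 | cfg$populations$fst >= 1)) {
    stop("fst must lie in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML or key=value text
#' @param path YAML file (flat `key: value` entries; `populations` may be
#'   a list of records with `label`, `fst`, `n_dh`, `n_diploid`).
#' @return a [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$populations)) {
    y$populations <- do.call(rbind, lapply(y$populations, as.data.frame))
  }
  do.call(sim_config, y)
}

random_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

other_bases <- function(b) DNA_BASES[DNA_BASES != b]

# Balding-Nichols draw of per-population allele frequency around an
# ancestral frequency p with differentiation fst (fst = 0: no drift).
bn_freq <- function(p, fst, n = 1L) {
  if (fst == 0) return(rep(p, n))
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  rbeta(n, a, b)
}

#' Simulate the ground-truth gene set, sites and panel genotypes
#'
#' Draws, deterministically for a given config and seed: the duplication
#' status and sequences of every locus (paralog pairs diverge at
#' `paralog_divergence` per base, each fixed difference a PSV site);
#' segregating sites on non-duplicated loci (class `true_snp`) and, for a
#' fraction of duplicated loci, a site segregating on exactly one paralog
#' (class `msv`); per-population allele frequencies by a Balding-Nichols
#' draw around the ancestral frequency; and true genotypes for every
#' sample of the panel, doubled haploids being homozygous everywhere.
#'
#' @param config a [sim_config()].
#' @return object of class `SimTruth`: list with `config`, `loci`
#'   (data.frame: `locus_id`, `duplicated`, `co_assembled`, `length`),
#'   `sequences` (per-locus list of `par1`/`par2`), `sites` (data.frame
#'   with class, alleles, ancestral and per-population frequencies),
#'   `genotypes` (site x sample matrix of allele-B dosages; the
#'   segregating paralog's dosage for MSV sites; `NA` for PSV sites) and
#'   `manifest`.
#' @export
simulate_gene_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- config$populations
  manifest <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    ids <- c(sprintf("%s_DH%03d", pops$label[i], seq_len(pops$n_dh[i])),
             sprintf("%s_D%03d", pops$label[i], seq_len(pops$n_diploid[i])))
    if (length(ids) == 0L) return(NULL)
    data.frame(sample_id = ids, population = pops$label[i],
               ploidy_class = rep(c("DH", "diploid"),
                                  c(pops$n_dh[i], pops$n_diploid[i])),
               stringsAsFactors = FALSE)
  }))
  validate_manifest(manifest)
  n_samp <- nrow(manifest)
  samp_pop <- match(manifest$population, pops$label)
  is_dh <- manifest$ploidy_class == "DH"

  L <- config$gene_length
  n <- config$n_loci
  loci <- data.frame(
    locus_id = sprintf("L%05d", seq_len(n)),
    duplicated = runif(n) < config$dup_fraction,
    stringsAsFactors = FALSE)
  loci$co_assembled <- loci$duplicated & runif(n) < config$co_assembly_prob
  loci$length <- L

  sequences <- vector("list", n)
  names(sequences) <- loci$locus_id
  site_rows <- list()
  geno_rows <- list()

  draw_site_freqs <- function(p_anc, private) {
    if (private) return(rep(0, nrow(pops)))
    vapply(seq_len(nrow(pops)),
           function(k) bn_freq(p_anc, pops$fst[k]), numeric(1))
  }
  draw_genotypes <- function(freqs) {
    q <- freqs[samp_pop]           # per-sample frequency of allele B
    ifelse(is_dh, 2L * rbinom(n_samp, 1L, q), rbinom(n_samp, 2L, q))
  }

  for (i in seq_len(n)) {
    par1 <- random_cds(L / 3L)
    par2 <- NULL
    lid <- loci$locus_id[i]
    if (loci$duplicated[i]) {
      par2 <- par1
      n_div <- rbinom(1L, L, config$paralog_divergence)
      div_pos <- sort(sample.int(L, n_div))
      for (pz in div_pos) {
        old <- substr(par2, pz, pz)
        substr(par2, pz, pz) <- sample(other_bases(old), 1L)
      }
      if (n_div > 0L) {
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          locus_id = lid, paralog = NA_integer_, pos = div_pos - 1L,
          class = "psv",
          allele_A = substring(par1, div_pos, div_pos),
          allele_B = substring(par2, div_pos, div_pos),
          p_anc = NA_real_, private = FALSE,
          matrix(NA_real_, n_div, nrow(pops),
                 dimnames = list(NULL, paste0("p_", pops$label))),
          stringsAsFactors = FALSE)
        geno_rows[[length(geno_rows) + 1L]] <-
          matrix(NA_integer_, n_div, n_samp)
      }
      if (runif(1) < config$msv_fraction) {
        free <- setdiff(seq_len(L), div_pos)
        mp <- sample(free, 1L)
        base <- substr(par2, mp, mp)
        p_anc <- runif(1, 0.2, 0.8)
        freqs <- draw_site_freqs(p_anc, FALSE)
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          locus_id = lid, paralog = 2L, pos = mp - 1L, class = "msv",
          allele_A = base, allele_B = sample(other_bases(base), 1L),
          p_anc = p_anc, private = FALSE,
          matrix(freqs, 1L, dimnames = list(NULL, paste0("p_", pops$label))),
          stringsAsFactors = FALSE)
        geno_rows[[length(geno_rows) + 1L]] <-
          matrix(draw_genotypes(freqs), 1L, n_samp)
      }
    } else {
      k <- rpois(1L, config$true_snp_rate)
      if (k > 0L) {
        tp <- sort(sample.int(L, min(k, L)))
        for (pz in tp) {
          base <- substr(par1, pz, pz)
          p_anc <- runif(1, 0.2, 0.8)
          private <- runif(1) < config$private_snp_frac
          freqs <- draw_site_freqs(p_anc, private)
          site_rows[[length(site_rows) + 1L]] <- data.frame(
            locus_id = lid, paralog = 1L, pos = pz - 1L, class = "true_snp",
            allele_A = base, allele_B = sample(other_bases(base), 1L),
            p_anc = p_anc, private = private,
            matrix(freqs, 1L, dimnames = list(NULL, paste0("p_", pops$label))),
            stringsAsFactors = FALSE)
          geno_rows[[length(geno_rows) + 1L]] <-
            matrix(draw_genotypes(freqs), 1L, n_samp)
        }
      }
    }
    sequences[[i]] <- list(par1 = par1, par2 = par2)
  }

  sites <- if (length(site_rows)) do.call(rbind, site_rows) else NULL
  genotypes <- NULL
  if (!is.null(sites)) {
    sites <- cbind(site_id = sprintf("S%06d", seq_len(nrow(sites))), sites,
                   stringsAsFactors = FALSE)
    genotypes <- do.call(rbind, geno_rows)
    dimnames(genotypes) <- list(sites$site_id, manifest$sample_id)
  }
  structure(list(config = config, loci = loci, sequences = sequences,
                 sites = sites, genotypes = genotypes, manifest = manifest),
            class = "SimTruth")
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", nrow(x$loci), "loci (",
      sum(x$loci$duplicated), "duplicated ),",
      if (is.null(x$sites)) 0L else nrow(x$sites), "sites,",
      nrow(x$manifest), "samples\n")
  invisible(x)
}

# meanlog of a lognormal whose [lo, hi]-truncated mean equals target,
# at fixed sdlog
lnorm_meanlog_for_mean <- function(target, lo, hi, sdlog = 0.7) {
  trunc_mean <- function(mu) {
    z1 <- (log(lo) - mu) / sdlog; z2 <- (log(hi) - mu) / sdlog
    num <- pnorm(z2 - sdlog) - pnorm(z1 - sdlog)
    den <- pnorm(z2) - pnorm(z1)
    exp(mu + sdlog^2 / 2) * num / den
  }
  uniroot(function(mu) trunc_mean(mu) - target,
          interval = c(log(lo) - 3, log(hi)))$root
}

draw_depths <- function(n, config) {
  mu <- lnorm_meanlog_for_mean(config$mean_depth, config$depth_min,
                               config$depth_max)
  out <- integer(0)
  while (length(out) < n) {
    d <- round(rlnorm(2L * (n - length(out)) + 8L, mu, 0.7))
    out <- c(out, d[d >= config$depth_min & d <= config$depth_max])
  }
  out[seq_len(n)]
}

#' Simulate EST contig alignments from a simulated gene set
#'
#' Each locus yields one contig (non-duplicated, or a co-assembled
#' duplicated pair whose reads interleave both paralogs 50/50) or two
#' contigs (separately assembled paralogs). Read depth follows a
#' lognormal truncated to the configured range with mean matched to
#' `mean_depth`; reads sample alleles at segregating sites with the
#' ancestral frequency and acquire i.i.d. per-base errors. Fixed
#' inter-paralog differences surface in co-assembled contigs as
#' high-frequency pseudo-alleles (PSV signatures).
#'
#' @param truth a `SimTruth` from [simulate_gene_set()].
#' @param config the same [sim_config()].
#' @return list with `alignments` (named list of `ContigAlignment`) and
#'   `site_labels` (data.frame `contig_id`, `pos`, `site_id`, `class`,
#'   `allele_A`, `allele_B` for every truth site discoverable in its
#'   contig's alignment).
#' @export
simulate_est_alignments <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "SimTruth"))
  set.seed(config$seed + 1L)
  loci <- truth$loci
  sites <- truth$sites
  L <- config$gene_length
  aln <- list()
  labels <- list()

  seg_sites_for <- function(lid, par) {
    if (is.null(sites)) return(NULL)
    s <- sites[sites$locus_id == lid & !is.na(sites$paralog) &
                 sites$paralog == par, , drop = FALSE]
    if (nrow(s)) s else NULL
  }
  psv_sites_for <- function(lid) {
    if (is.null(sites)) return(NULL)
    s <- sites[sites$locus_id == lid & sites$class == "psv", , drop = FALSE]
    if (nrow(s)) s else NULL
  }

  build_contig <- function(contig_id, consensus, paralog_seqs,
                           paralog_of_read, seg_by_par) {
    d <- length(paralog_of_read)
    base <- do.call(rbind, lapply(paralog_of_read, function(p) {
      strsplit(paralog_seqs[[p]], "", fixed = TRUE)[[1]]
    }))
    for (p in seq_along(paralog_seqs)) {
      segs <- seg_by_par[[p]]
      if (is.null(segs)) next
      rows <- which(paralog_of_read == p)
      for (si in seq_len(nrow(segs))) {
        alt <- runif(length(rows)) < segs$p_anc[si]
        base[rows[alt], segs$pos[si] + 1L] <- segs$allele_B[si]
      }
    }
    n_err <- rbinom(1L, d * L, config$per_base_error_rate)
    if (n_err > 0L) {
      idx <- sample.int(d * L, n_err)
      base[idx] <- vapply(base[idx],
                          function(b) sample(other_bases(b), 1L),
                          character(1))
    }
    reads <- apply(base, 1L, paste, collapse = "")
    new_contig_alignment(contig_id, consensus,
                         sprintf("%s_r%04d", contig_id, seq_len(d)), reads)
  }

  label_rows <- function(contig_id, s) {
    if (is.null(s)) return(NULL)
    data.frame(contig_id = contig_id, pos = s$pos, site_id = s$site_id,
               class = s$class, allele_A = s$allele_A, allele_B = s$allele_B,
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(loci))) {
    lid <- loci$locus_id[i]
    seqs <- truth$sequences[[lid]]
    if (!loci$duplicated[i]) {
      d <- draw_depths(1L, config)
      segs <- list(seg_sites_for(lid, 1L))
      aln[[lid]] <- build_contig(lid, seqs$par1, list(seqs$par1),
                                 rep(1L, d), segs)
      labels[[length(labels) + 1L]] <- label_rows(lid, segs[[1]])
    } else if (loci$co_assembled[i]) {
      d <- draw_depths(1L, config)
      par_of_read <- sample(1:2, d, replace = TRUE)
      segs <- list(seg_sites_for(lid, 1L), seg_sites_for(lid, 2L))
      aln[[lid]] <- build_contig(lid, seqs$par1,
                                 list(seqs$par1, seqs$par2),
                                 par_of_read, segs)
      labels[[length(labels) + 1L]] <- label_rows(lid, psv_sites_for(lid))
      labels[[length(labels) + 1L]] <- label_rows(lid, segs[[2]])
    } else {
      d <- draw_depths(2L, config)
      id1 <- paste0(lid, "_p1"); id2 <- paste0(lid, "_p2")
      aln[[id1]] <- build_contig(id1, seqs$par1, list(seqs$par1),
                                 rep(1L, d[1]), list(NULL))
      segs2 <- list(seg_sites_for(lid, 2L))
      aln[[id2]] <- build_contig(id2, seqs$par2, list(seqs$par2),
                                 rep(1L, d[2]), segs2)
      labels[[length(labels) + 1L]] <- label_rows(id2, segs2[[1]])
    }
  }
  site_labels <- do.call(rbind, c(labels, list(
    data.frame(contig_id = character(0), pos = integer(0),
               site_id = character(0), class = character(0),
               allele_A = character(0), allele_B = character(0),
               stringsAsFactors = FALSE))))
  rownames(site_labels) <- NULL
  list(alignments = aln, site_labels = site_labels)
}

#' Attach truth labels to discovered candidates
#'
#' Joins discovery output to the simulator's site-label table by contig
#' and position; candidates without a labelled site are sequencing-error
#' artefacts (`pseudo_snp`).
#'
#' @param candidates data.frame from [call_candidate_snps_all()].
#' @param site_labels data.frame from [simulate_est_alignments()].
#' @return `candidates` with `snp_id`, `site_id`, `class`, `allele_A`,
#'   `allele_B` columns added (truth alleles where labelled, the observed
#'   major/minor bases for pseudo-SNPs).
#' @export
label_candidates <- function(candidates, site_labels) {
  key <- paste(candidates$contig_id, candidates$pos)
  lkey <- paste(site_labels$contig_id, site_labels$pos)
  m <- match(key, lkey)
  candidates$snp_id <- paste0(candidates$contig_id, "_", candidates$pos + 1L)
  candidates$site_id <- site_labels$site_id[m]
  candidates$class <- ifelse(is.na(m), "pseudo_snp", site_labels$class[m])
  candidates$allele_A <- ifelse(is.na(m), candidates$major_base,
                                site_labels$allele_A[m])
  candidates$allele_B <- ifelse(is.na(m), candidates$minor_base,
                                site_labels$allele_B[m])
  candidates
}

#' Simulate the genotyping of a SNP panel
#'
#' The assay at a site on a duplicated locus reads the superposition of
#' both paralogs: a PSV site is called `AB` in every sample; an MSV site
#' (paralog 1 fixed `A`, paralog 2 segregating) is called `AA` when the
#' paralog-2 genotype is `AA` and `AB` otherwise (so doubled haploids mix
#' `AA` and `AB` and never show `BB`). Non-duplicated true SNPs yield
#' Mendelian calls from the truth genotypes; pseudo-SNPs are monomorphic
#' `AA`. Miscalls (rate `genotype_error_rate`) are emitted with GenCall
#' scores below the validity cutoff; a fraction `assay_fail_rate` of SNPs
#' is injected as failures, half via sub-threshold GenTrain and half via
#' degraded per-call GenCall scores.
#'
#' @param truth a `SimTruth`.
#' @param config the same [sim_config()].
#' @param sites data.frame of assayed SNPs (`snp_id`, `site_id`, `class`,
#'   `allele_A`, `allele_B`), e.g. from [label_candidates()]; defaults to
#'   every truth site.
#' @return list with `matrix` (a `GenotypeMatrix`), `manifest`, and
#'   `truth` -- a label table per assayed SNP: generative `class`,
#'   `injected_fail`/`fail_mode`, `msv_truth`, and `expected_status`, the
#'   status a perfect classifier should output given the drawn genotypes
#'   (a true SNP fixed in the sampled panel is expected `monomorphic`; an
#'   MSV whose every sample carries both alleles is expected `psv`).
#' @export
simulate_genotype_panel <- function(truth, config = truth$config,
                                    sites = NULL) {
  stopifnot(inherits(truth, "SimTruth"))
  set.seed(config$seed + 2L)
  if (is.null(sites)) {
    if (is.null(truth$sites)) stop("gene set contains no sites to assay")
    sites <- data.frame(snp_id = truth$sites$site_id,
                        site_id = truth$sites$site_id,
                        class = truth$sites$class,
                        allele_A = truth$sites$allele_A,
                        allele_B = truth$sites$allele_B,
                        stringsAsFactors = FALSE)
  }
  manifest <- truth$manifest
  n_snp <- nrow(sites); n_samp <- nrow(manifest)
  if (n_snp == 0L) stop("no SNPs to assay")
  calls <- matrix("AA", n_snp, n_samp)
  expected <- character(n_snp)
  for (i in seq_len(n_snp)) {
    cls <- sites$class[i]
    if (cls == "psv") {
      calls[i, ] <- "AB"
      expected[i] <- "psv"
    } else if (cls == "pseudo_snp") {
      expected[i] <- "monomorphic"
    } else {
      g <- truth$genotypes[sites$site_id[i], ]
      if (cls == "msv") {
        calls[i, ] <- ifelse(g == 0L, "AA", "AB")
        expected[i] <- if (all(g == 0L)) "monomorphic"
                       else if (all(g >= 1L)) "psv" else "true"
      } else {
        calls[i, ] <- c("AA", "AB", "BB")[g + 1L]
        expected[i] <- if (all(g == 0L) || all(g == 2L)) "monomorphic"
                       else "true"
      }
    }
  }
  gencall <- matrix(round(rbeta(n_snp * n_samp, 9, 3), 4), n_snp, n_samp)
  err <- matrix(runif(n_snp * n_samp) < config$genotype_error_rate,
                n_snp, n_samp)
  if (any(err)) {
    calls[err] <- vapply(calls[err], function(cl) {
      sample(setdiff(c("AA", "AB", "BB"), cl), 1L)
    }, character(1))
    gencall[err] <- round(runif(sum(err), 0, 0.245), 4)
  }
  gentrain <- round(runif(n_snp, 0.45, 0.95), 4)
  fail <- runif(n_snp) < config$assay_fail_rate
  fail_mode <- rep("", n_snp)
  if (any(fail)) {
    mode <- sample(c("gentrain", "callrate"), sum(fail), replace = TRUE)
    fail_mode[fail] <- mode
    low_gt <- which(fail)[mode == "gentrain"]
    gentrain[low_gt] <- round(runif(length(low_gt), 0.02, 0.249), 4)
    low_cr <- which(fail)[mode == "callrate"]
    for (i in low_cr) {
      gencall[i, ] <- round(runif(n_samp, 0, 0.5), 4)
    }
  }
  expected[fail] <- "failed"
  m <- new_genotype_matrix(sites$snp_id, manifest$sample_id, calls, gencall,
                           gentrain,
                           cbind(sites$allele_A, sites$allele_B))
  lab <- data.frame(snp_id = sites$snp_id, site_id = sites$site_id,
                    class = sites$class, injected_fail = fail,
                    fail_mode = fail_mode,
                    msv_truth = sites$class == "msv",
                    expected_status = expected, stringsAsFactors = FALSE)
  list(matrix = m, manifest = manifest, truth = lab)
}

#' Simulate coding SNPs with known codon context
#'
#' Builds `n` single-SNP coding contigs (stop-free CDS; half presented on
#' the reverse strand with frame -1), matching contig- and SNP-level
#' homology tables, and the true synonymous/non-synonymous effect of each
#' substitution from the genetic code. Alternate alleles never create
#' stop codons.
#'
#' @param n number of SNPs.
#' @param seed integer seed.
#' @param n_codons CDS length in codons.
#' @return list with `snps` (data.frame: `snp_id`, `contig_id`, `pos`,
#'   `allele_a`, `allele_b`, `effect_truth`, `ref_aa`, `alt_aa`),
#'   `contigs` (named character vector), `contig_hits` and `snp_hits`
#'   (homology tables).
#' @export
simulate_coding_snps <- function(n, seed = 1L, n_codons = 40L) {
  set.seed(seed)
  L <- 3L * n_codons
  snps <- list(); contigs <- character(n); chits <- list(); shits <- list()
  names(contigs) <- sprintf("C%04d", seq_len(n))
  for (i in seq_len(n)) {
    cds <- random_cds(n_codons)
    repeat {
      pz <- sample.int(L, 1L)
      ci <- (pz - 1L) %/% 3L
      codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
      off <- pz - (3L * ci + 1L)
      ref <- substr(codon, off + 1L, off + 1L)
      alts <- Filter(function(b) {
        alt_codon <- codon
        substr(alt_codon, off + 1L, off + 1L) <- b
        !(alt_codon %in% STOP_CODONS)
      }, other_bases(ref))
      if (length(alts)) break
    }
    alt <- if (length(alts) == 1L) alts else sample(alts, 1L)
    alt_codon <- codon
    substr(alt_codon, off + 1L, off + 1L) <- alt
    ref_aa <- translate_dna(codon); alt_aa <- translate_dna(alt_codon)
    minus <- runif(1) < 0.5
    cid <- names(contigs)[i]
    if (minus) {
      contigs[i] <- revcomp(cds)
      pos <- L - pz                   # 0-based position on the contig
      a_ref <- revcomp(ref); a_alt <- revcomp(alt)
      frame <- -1L
    } else {
      contigs[i] <- cds
      pos <- pz - 1L
      a_ref <- ref; a_alt <- alt
      frame <- 1L
    }
    sid <- paste0(cid, "_", pos + 1L)
    gene <- paste0("GENE", sprintf("%04d", i))
    snps[[i]] <- data.frame(
      snp_id = sid, contig_id = cid, pos = pos, allele_a = a_ref,
      allele_b = a_alt,
      effect_truth = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
      ref_aa = ref_aa, alt_aa = alt_aa, codon_index = ci,
      stringsAsFactors = FALSE)
    chits[[i]] <- make_hit(cid, gene, L, frame)
    shits[[i]] <- make_hit(sid, gene, L, frame)
  }
  list(snps = do.call(rbind, snps), contigs = contigs,
       contig_hits = do.call(rbind, chits),
       snp_hits = do.call(rbind, shits))
}

make_hit <- function(query, subject, L, frame, evalue = 1e-30,
                     pct_identity = 99, qstart = 1L, qend = L) {
  data.frame(query_id = query, subject_protein_id = subject,
             pct_identity = pct_identity, aln_len = as.integer(L %/% 3L),
             mismatches = 0L, gap_open = 0L, qstart = qstart, qend = qend,
             sstart = 1L, send = as.integer(L %/% 3L), evalue = evalue,
             bitscore = 200, frame = as.integer(frame),
             subject_gene_id = "", stringsAsFactors = FALSE)
}

#' Write the simulator's truth table as TSV
#' @param truth a `SimTruth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  s <- truth$sites
  if (is.null(s)) stop("gene set contains no sites")
  write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
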