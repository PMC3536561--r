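# Shared fixtures and independent oracles used across the suite.

# Build a ContigAlignment from plain strings (consensus first).
toy_alignment <- function(consensus, reads, contig_id = "ctg1") {
  new_contig_alignment(contig_id, consensus,
                       sprintf("r%02d", seq_along(reads)), reads)
}

# Independent brute-force candidate caller: re-applies the five discovery
# filters column by column with plain loops over per-read characters,
# sharing no logic with call_candidate_snps().
brute_force_snps <- function(aln, min_depth = 7, min_minor = 3,
                             flank_len = 4) {
  L <- nchar(aln$consensus)
  out <- list()
  for (j in seq_len(L)) {
    bases <- substring(aln$reads, j, j)
    obs <- bases[bases %in% c("A", "C", "G", "T")]        # filter (5)
    tab <- vapply(c("A", "C", "G", "T"), function(b) sum(obs == b), 0)
    tab <- tab[tab > 0]
    if (length(tab) != 2) next                            # biallelic only
    if (sum(tab) < min_depth) next                        # filter (1)
    if (min(tab) < min_minor) next                        # filter (3)
    if (j - flank_len < 1 || j + flank_len > L) next      # edge guard
    ok <- TRUE
    for (side in list(c(j - flank_len, j - 1), c(j + 1, j + flank_len))) {
      fl <- substring(aln$reads, side[1], side[2])
      excluded <- grepl("[N-]", fl)                       # filter (5)
      if (all(excluded)) { ok <- FALSE; break }
      cons_fl <- substring(aln$consensus, side[1], side[2])
      if (!all(fl[!excluded] == cons_fl)) { ok <- FALSE; break }  # filter (2)
    }
    if (!ok) next
    major <- names(tab)[order(-tab, names(tab))][1]
    minor <- setdiff(names(tab), major)
    out[[length(out) + 1]] <- data.frame(
      contig_id = aln$contig_id, pos = j - 1,
      major_base = major, minor_base = minor,
      n_major = as.integer(max(tab)), n_minor = as.integer(min(tab)),
      depth = as.integer(sum(tab)), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(contig_id = character(0), pos = integer(0),
               major_base = character(0), minor_base = character(0),
               n_major = integer(0), n_minor = integer(0),
               depth = integer(0), stringsAsFactors = FALSE)
}

# Small genotype matrix built directly from a call matrix; scores default
# to clean values.
toy_matrix <- function(calls, gentrain = NULL, gencall = NULL,
                       alleles = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  snp_ids <- rownames(calls)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%02d", seq_len(n))
  sample_ids <- colnames(calls)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(m))
  if (is.null(gencall)) gencall <- matrix(0.9, n, m)
  if (is.null(gentrain)) gentrain <- rep(0.8, n)
  if (is.null(alleles)) alleles <- cbind(rep("A", n), rep("G", n))
  new_genotype_matrix(snp_ids, sample_ids, calls, gencall, gentrain, alleles)
}

toy_manifest <- function(n_dh, n_dip, pop = "POP") {
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n_dh + n_dip)),
    population = pop,
    ploidy_class = rep(c("DH", "diploid"), c(n_dh, n_dip)),
    stringsAsFactors = FALSE)
}

# Homology-hit table builder matching read_homology_table()'s shape.
make_hit_table <- function(query, subject, pct, len, evalue, frame = 1L) {
  n <- length(query)
  data.frame(query_id = query, subject_protein_id = subject,
             pct_identity = pct, aln_len = as.integer(len),
             mismatches = 0L, gap_open = 0L,
             qstart = 1L, qend = as.integer(len) * 3L,
             sstart = 1L, send = as.integer(len),
             evalue = evalue, bitscore = 200,
             frame = as.integer(rep_len(frame, n)),
             subject_gene_id = rep("", n), stringsAsFactors = FALSE)
}
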