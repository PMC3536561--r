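## Homology-hit filtering and synonymous/non-synonymous substitution
## calling.  The homology search itself (blastx-like) is consumed as a
## tabular file; substitution calling translates the hit window under both
## alleles with the standard genetic code and compares the peptides:
## both identical to the reference window -> synonymous; exactly one
## amino-acid difference with one allele matching the reference ->
## non-synonymous.

#' Collapse homology hits to the best hit per query
#'
#' Three filtration steps: hits worse than `evalue_max` are dropped;
#' subject protein ids are renamed to gene ids (alternative transcripts of
#' one gene collapse); per query the minimal e-value wins, residual ties
#' broken by the largest HSP product (percent identity times alignment
#' length). Queries still tied across *different* genes after both rules
#' are flagged ambiguous and all tied hits are retained.
#'
#' @param hits data.frame from [read_homology_table()].
#' @param protein_to_gene named character vector mapping protein ids to
#'   gene ids; unmapped proteins keep their own id (identity map allowed).
#' @param evalue_max e-value cutoff (hits with `evalue > evalue_max` drop).
#' @return data.frame of best hits (possibly several rows per ambiguous
#'   query) with `subject_gene_id` filled and a logical `ambiguous`
#'   column.
#' @export
filter_best_hits <- function(hits, protein_to_gene = NULL,
                             evalue_max = 1e-5) {
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  gene <- hits$subject_protein_id
  if (!is.null(protein_to_gene)) {
    mapped <- protein_to_gene[gene]
    gene[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  hits$subject_gene_id <- unname(gene)
  hits$ambiguous <- logical(nrow(hits))
  if (nrow(hits) == 0L) return(hits)
  out <- lapply(split(hits, hits$query_id), function(h) {
    h <- h[h$evalue == min(h$evalue), , drop = FALSE]
    hsp <- h$pct_identity * h$aln_len
    h <- h[hsp == max(hsp), , drop = FALSE]
    if (length(unique(h$subject_gene_id)) > 1L) {
      h$ambiguous <- TRUE
    } else {
      h <- h[1, , drop = FALSE]
    }
    h
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extract and translate the peptide window of a homology hit
#'
#' Takes the contig subsequence between `qstart` and `qend` (1-based
#' inclusive), reverse-complements it when the frame is negative, and
#' translates it with the standard genetic code. A trailing partial codon
#' is dropped; an internal stop truncates the peptide (flagged).
#'
#' @param contig_seq contig nucleotide sequence.
#' @param qstart,qend 1-based inclusive query coordinates of the hit.
#' @param frame hit frame in `-3..-1, 1..3`; `NA` triggers
#'   [infer_frame()].
#' @return list with `peptide` (character), `truncated` (logical: internal
#'   stop) and `frame` (the frame used).
#' @export
build_peptide_window <- function(contig_seq, qstart, qend, frame = 1L) {
  L <- nchar(contig_seq)
  if (qstart < 1L || qend > L || qstart > qend) {
    stop("hit window [", qstart, ", ", qend, "] outside contig of length ", L)
  }
  window <- substr(contig_seq, qstart, qend)
  if (nchar(window) < 3L) stop("hit window shorter than 3 nt")
  if (is.na(frame)) frame <- infer_frame(window)
  if (frame < 0) window <- revcomp(window)
  pep <- translate_dna(window)
  truncated <- grepl("*", pep, fixed = TRUE)
  if (truncated) pep <- sub("\\*.*$", "", pep)
  list(peptide = pep, truncated = truncated, frame = frame)
}

# standard genetic code (Biostrings::GENETIC_CODE, no initiator special
# case); trailing partial codon dropped; codons containing N (or any
# ambiguity) become 'X'
translate_dna <- function(x) {
  n <- 3L * (nchar(x) %/% 3L)
  if (n == 0L) return("")
  codons <- substring(x, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Infer the reading frame of a window as the frame minimising stop codons
#'
#' Tries the six frames of the window itself and returns the one whose
#' translation has the fewest stop codons (ties broken towards +1, +2,
#' +3, -1, -2, -3).
#'
#' @param window nucleotide sequence.
#' @return integer frame.
#' @export
infer_frame <- function(window) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  stops <- vapply(frames, function(f) {
    w <- if (f < 0) revcomp(window) else window
    w <- substr(w, abs(f), nchar(w))
    if (nchar(w) < 3L) return(Inf)
    pep <- translate_dna(w)
    as.numeric(sum(strsplit(pep, "", fixed = TRUE)[[1]] == "*"))
  }, numeric(1))
  frames[which.min(stops)]
}

#' Classify one SNP substitution as synonymous or non-synonymous
#'
#' Uses the contig's best homology hit to place the SNP in a translated
#' window and compares the peptides obtained under the two alleles with
#' the reference (consensus) peptide. Effects: `no_hit` (no SNP-level
#' hit), `discordant_hit` (SNP-level gene differs from the contig-level
#' gene; excluded from synonymous/non-synonymous calling), `synonymous`
#' (both allele peptides identical to the reference window),
#' `nonsynonymous` (one allele matches the reference, the other differs
#' by exactly one amino acid), `unresolved` otherwise (SNP outside the
#' window, ambiguous codon, stop-length change, or multiple differences).
#'
#' @param contig_seq contig consensus sequence.
#' @param snp_pos 0-based SNP position on the contig.
#' @param allele_a,allele_b the two SNP alleles.
#' @param contig_hit single-row best hit for the contig (from
#'   [filter_best_hits()]).
#' @param snp_hit single-row best hit for the SNP flanking sequence, or
#'   `NULL` when the SNP sequence had no hit.
#' @param snp_id identifier recorded in the output.
#' @return one-row data.frame: `snp_id`, `gene_id`, `effect`, `ref_aa`,
#'   `alt_aa`, `codon_index` (0-based within the matched peptide window),
#'   `reason`.
#' @export
classify_substitution <- function(contig_seq, snp_pos, allele_a, allele_b,
                                  contig_hit, snp_hit = NULL,
                                  snp_id = NA_character_) {
  rec <- function(effect, gene_id = "", ref_aa = NA_character_,
                  alt_aa = NA_character_, codon_index = NA_integer_,
                  reason = "") {
    data.frame(snp_id = snp_id, gene_id = gene_id, effect = effect,
               ref_aa = ref_aa, alt_aa = alt_aa,
               codon_index = as.integer(codon_index),
               reason = reason, stringsAsFactors = FALSE)
  }
  if (is.null(snp_hit) || nrow(snp_hit) == 0L) {
    return(rec("no_hit"))
  }
  gene <- contig_hit$subject_gene_id[1]
  if (snp_hit$subject_gene_id[1] != gene) {
    return(rec("discordant_hit", gene_id = gene,
               reason = "snp_hit_gene_differs"))
  }
  qs <- contig_hit$qstart[1]; qe <- contig_hit$qend[1]
  frame <- contig_hit$frame[1]
  pos1 <- snp_pos + 1L
  if (pos1 < qs || pos1 > qe) {
    return(rec("unresolved", gene_id = gene, reason = "snp_outside_window"))
  }
  with_allele <- function(base) {
    s <- contig_seq
    substr(s, pos1, pos1) <- base
    s
  }
  pep_ref <- build_peptide_window(contig_seq, qs, qe, frame)
  pep_a <- build_peptide_window(with_allele(allele_a), qs, qe, frame)
  pep_b <- build_peptide_window(with_allele(allele_b), qs, qe, frame)
  # offset of the SNP within the (strand-oriented) window
  off <- if (frame > 0) pos1 - qs else qe - pos1
  codon_index <- off %/% 3L
  affected <- function(p) {
    if (nchar(p$peptide) <= codon_index) NA_character_
    else substr(p$peptide, codon_index + 1L, codon_index + 1L)
  }
  aa_a <- affected(pep_a); aa_b <- affected(pep_b)
  if (identical(aa_a, "X") || identical(aa_b, "X")) {
    return(rec("unresolved", gene_id = gene, reason = "ambiguous_codon"))
  }
  if (pep_a$peptide == pep_b$peptide) {
    if (pep_a$peptide == pep_ref$peptide) {
      return(rec("synonymous", gene_id = gene, codon_index = codon_index))
    }
    return(rec("unresolved", gene_id = gene, reason = "neither_matches_ref"))
  }
  if (nchar(pep_a$peptide) != nchar(pep_b$peptide)) {
    return(rec("unresolved", gene_id = gene, reason = "stop_length_change"))
  }
  d <- which(strsplit(pep_a$peptide, "")[[1]] !=
               strsplit(pep_b$peptide, "")[[1]])
  if (length(d) != 1L) {
    return(rec("unresolved", gene_id = gene, reason = "multiple_aa_changes"))
  }
  if (pep_a$peptide == pep_ref$peptide) {
    rec("nonsynonymous", gene_id = gene, ref_aa = aa_a, alt_aa = aa_b,
        codon_index = d - 1L)
  } else if (pep_b$peptide == pep_ref$peptide) {
    rec("nonsynonymous", gene_id = gene, ref_aa = aa_b, alt_aa = aa_a,
        codon_index = d - 1L)
  } else {
    rec("unresolved", gene_id = gene, reason = "neither_matches_ref")
  }
}

#' Annotate a set of SNPs from contig and SNP-level homology tables
#'
#' @param snps data.frame with `snp_id`, `contig_id`, `pos` (0-based),
#'   `allele_a`, `allele_b` (the discovery major/minor bases work).
#' @param contigs named character vector of contig sequences.
#' @param contig_hits,snp_hits raw homology tables (contig-level queries
#'   named by `contig_id`, SNP-level queries by `snp_id`).
#' @param protein_to_gene,evalue_max see [filter_best_hits()].
#' @return data.frame of [classify_substitution()] records, one per SNP;
#'   SNPs whose contig has no (unambiguous) gene hit are `no_hit`.
#' @export
annotate_snps <- function(snps, contigs, contig_hits, snp_hits,
                          protein_to_gene = NULL, evalue_max = 1e-5) {
  bc <- filter_best_hits(contig_hits, protein_to_gene, evalue_max)
  bs <- filter_best_hits(snp_hits, protein_to_gene, evalue_max)
  out <- lapply(seq_len(nrow(snps)), function(i) {
    s <- snps[i, ]
    ch <- bc[bc$query_id == s$contig_id, , drop = FALSE]
    if (nrow(ch) == 0L) {
      return(data.frame(snp_id = s$snp_id, gene_id = "", effect = "no_hit",
                        ref_aa = NA_character_, alt_aa = NA_character_,
                        codon_index = NA_integer_, reason = "no_contig_hit",
                        stringsAsFactors = FALSE))
    }
    ch <- ch[1, , drop = FALSE]   # ambiguous contig hits: first retained hit
    sh <- bs[bs$query_id == s$snp_id, , drop = FALSE]
    classify_substitution(contigs[[s$contig_id]], s$pos, s$allele_a,
                          s$allele_b, ch,
                          if (nrow(sh)) sh[1, , drop = FALSE] else NULL,
                          snp_id = s$snp_id)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
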