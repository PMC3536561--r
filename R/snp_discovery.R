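## Candidate SNP mining from EST contig alignments.
##
## Five stringent filters are applied per consensus column:
##   (1) informative local depth >= min_depth (default 7);
##   (2) the flank_len (default 4) bases on each side of the site must be
##       exactly conserved between the reads and the consensus;
##   (3) the lowest represented base must be seen in >= min_minor reads
##       (default 3);
##   (4) consensus gap columns are skipped (the ContigAlignment consensus
##       carries no gaps, so this is vacuous for inputs built here);
##   (5) reads contributing N or '-' at a column are excluded from that
##       column's counts, and from the flank-conservation check wherever
##       their flank contains N or '-'.

#' Call candidate SNPs from one contig alignment
#'
#' Scans every consensus column and emits a biallelic candidate when
#' exactly two distinct bases are observed, informative depth and
#' minor-base count meet their thresholds, and the flanking columns are
#' exactly conserved (see Details). Sites whose flank window is truncated
#' by the contig edge are rejected.
#'
#' @details The flank-conservation check is applied per side: a read takes
#' part in the check for a side only if it has no `N`/gap anywhere in that
#' side's `flank_len` columns; every participating read must match the
#' consensus exactly there, and at least one read must participate on each
#' side, otherwise the site is rejected. Ties for the major base are broken
#' alphabetically. Sites with three or more observed bases are rejected.
#'
#' @param aln a `ContigAlignment`.
#' @param min_depth minimum informative reads at the site.
#' @param min_minor minimum count of the lowest represented base.
#' @param flank_len number of conserved bases required on each side.
#' @param audit if `TRUE`, rejected biallelic-looking sites are returned in
#'   an `audit` attribute with their rejection reason.
#' @return data.frame of candidates: `contig_id`, `pos` (0-based consensus
#'   coordinate), `major_base`, `minor_base`, per-base counts
#'   (`count_A` .. `count_T`), `depth`, frequency statistics (`p`, `q`,
#'   `maf`, `he`, `pic`) and `left_flank`/`right_flank` consensus
#'   substrings.
#' @export
call_candidate_snps <- function(aln, min_depth = 7L, min_minor = 3L,
                                flank_len = 4L, audit = FALSE) {
  stopifnot(inherits(aln, "ContigAlignment"))
  L <- nchar(aln$consensus)
  cons <- strsplit(aln$consensus, "", fixed = TRUE)[[1]]
  n_reads <- length(aln$reads)
  empty <- candidate_frame()
  if (n_reads == 0L || L == 0L) return(finish_audit(empty, NULL, audit))
  M <- matrix(unlist(strsplit(aln$reads, "", fixed = TRUE), use.names = FALSE),
              nrow = n_reads, byrow = TRUE)

  counts <- vapply(DNA_BASES, function(b) colSums(M == b), numeric(L))  # L x 4
  if (L == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, DNA_BASES))
  depth <- rowSums(counts)
  n_obs <- rowSums(counts > 0)
  cand_cols <- which(n_obs == 2L | (audit & n_obs >= 2L))

  keep <- list(); rej <- list()
  for (j in cand_cols) {
    cnt <- counts[j, ]
    reason <- NULL
    if (n_obs[j] > 2L) reason <- "multiallelic"
    else if (depth[j] < min_depth) reason <- "depth"
    else if (min(cnt[cnt > 0]) < min_minor) reason <- "minor_count"
    else if (j - flank_len < 1L || j + flank_len > L) reason <- "edge"
    else {
      for (side in list(left = (j - flank_len):(j - 1L),
                        right = (j + 1L):(j + flank_len))) {
        sub <- M[, side, drop = FALSE]
        eligible <- rowSums(sub == "N" | sub == "-") == 0L
        if (!any(eligible)) { reason <- "flank_all_excluded"; break }
        match_cons <- sub[eligible, , drop = FALSE] ==
          matrix(cons[side], sum(eligible), flank_len, byrow = TRUE)
        if (!all(match_cons)) { reason <- "flank_not_conserved"; break }
      }
    }
    if (is.null(reason)) {
      ord <- order(-cnt, DNA_BASES)           # alphabetical major tie-break
      st <- freq_stats(cnt[ord[1]] / depth[j])
      keep[[length(keep) + 1L]] <- data.frame(
        contig_id = aln$contig_id, pos = j - 1L,
        major_base = DNA_BASES[ord[1]], minor_base = DNA_BASES[ord[2]],
        count_A = cnt[["A"]], count_C = cnt[["C"]],
        count_G = cnt[["G"]], count_T = cnt[["T"]],
        depth = depth[j], p = st$p, q = st$q, maf = st$maf,
        he = st$he, pic = st$pic,
        left_flank = substr(aln$consensus, max(1L, j - flank_len), j - 1L),
        right_flank = substr(aln$consensus, j + 1L, min(L, j + flank_len)),
        stringsAsFactors = FALSE)
    } else if (audit) {
      rej[[length(rej) + 1L]] <- data.frame(
        contig_id = aln$contig_id, pos = j - 1L, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(keep)) do.call(rbind, keep) else empty
  finish_audit(out, if (length(rej)) do.call(rbind, rej) else NULL, audit)
}

candidate_frame <- function() {
  data.frame(contig_id = character(0), pos = integer(0),
             major_base = character(0), minor_base = character(0),
             count_A = numeric(0), count_C = numeric(0),
             count_G = numeric(0), count_T = numeric(0),
             depth = numeric(0), p = numeric(0), q = numeric(0),
             maf = numeric(0), he = numeric(0), pic = numeric(0),
             left_flank = character(0), right_flank = character(0),
             stringsAsFactors = FALSE)
}

finish_audit <- function(out, rej, audit) {
  if (audit) {
    attr(out, "audit") <- if (is.null(rej)) {
      data.frame(contig_id = character(0), pos = integer(0),
                 reason = character(0), stringsAsFactors = FALSE)
    } else rej
  }
  out
}

#' Call candidate SNPs across a list of contig alignments
#'
#' @param alns list of `ContigAlignment` objects.
#' @inheritParams call_candidate_snps
#' @return row-bound candidate data.frame (see [call_candidate_snps()]).
#' @export
call_candidate_snps_all <- function(alns, min_depth = 7L, min_minor = 3L,
                                    flank_len = 4L) {
  res <- lapply(alns, call_candidate_snps, min_depth = min_depth,
                min_minor = min_minor, flank_len = flank_len)
  out <- do.call(rbind, c(res, list(candidate_frame())))
  rownames(out) <- NULL
  out
}

#' Sequence-depth frequency statistics for a biallelic site
#'
#' Allele frequencies are taken by direct count of sequence depth for each
#' base; expected heterozygosity is `He = 2pq` and the polymorphism
#' information content is `PIC = He - 2 p^2 q^2`.
#'
#' @param counts named numeric vector of per-base read counts; exactly two
#'   bases must have positive counts.
#' @return list with `p` (major base frequency), `q`, `maf`, `he`, `pic`.
#' @export
sequence_stats <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) != 2L) {
    stop("sequence_stats requires exactly two observed bases, got ",
         length(counts))
  }
  freq_stats(max(counts) / sum(counts))
}

#' Frequency statistics from an allele frequency
#'
#' @param p frequency of one allele (either allele; `he` and `pic` are
#'   symmetric in `p` and `q = 1 - p`).
#' @return list with `p`, `q`, `maf = min(p, q)`, `he = 2pq` and
#'   `pic = he - 2 p^2 q^2`.
#' @export
freq_stats <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- 1 - p
  he <- 2 * p * q
  list(p = p, q = q, maf = pmin(p, q), he = he, pic = he - 2 * p^2 * q^2)
}

#' Distribution of candidate SNPs per contig
#'
#' Bins contigs holding at least one candidate by their candidate count:
#' `1, 2, ..., 10, >10`.
#'
#' @param candidates candidate data.frame with a `contig_id` column.
#' @return data.frame with `bin` and `n_contigs`; bins partition the set of
#'   contigs with at least one candidate.
#' @export
contig_snp_distribution <- function(candidates) {
  bins <- c(as.character(1:10), ">10")
  n <- table(candidates$contig_id)
  lab <- ifelse(n > 10, ">10", as.character(n))
  data.frame(bin = bins,
             n_contigs = as.integer(table(factor(lab, levels = bins))),
             stringsAsFactors = FALSE)
}
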