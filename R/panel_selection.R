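## Validation-panel selection filters.
##
## Each filter is a pure predicate over the full candidate set (the
## design-score proximity penalty and the spacing filter look at
## neighbouring candidates of the *pre-filter* set), so the combined
## report does not depend on the order in which filters are evaluated.

PANEL_FILTERS <- c("spacing", "flank_length", "genomic_contiguity",
                   "design_score", "similarity")

#' Spacing filter: drop candidates closer than `min_gap` nucleotides
#'
#' Both members of a close pair are removed (set `keep_better = TRUE` and
#' supply scores to retain the better-scored member of each conflict
#' instead).
#'
#' @param candidates candidate data.frame (`contig_id`, `pos`).
#' @param min_gap minimum distance (nt) between neighbouring candidates;
#'   a gap of exactly `min_gap` is allowed.
#' @param keep_better keep the better-scored member of a close pair.
#' @param scores numeric vector (required when `keep_better = TRUE`).
#' @return logical keep vector aligned with `candidates` rows.
#' @export
spacing_filter <- function(candidates, min_gap = 60L, keep_better = FALSE,
                           scores = NULL) {
  n <- nrow(candidates)
  keep <- rep(TRUE, n)
  if (n == 0L) return(keep)
  if (keep_better) {
    if (is.null(scores)) stop("keep_better = TRUE requires scores")
    # greedy by score: a candidate survives unless a better-scored survivor
    # already sits within min_gap on the same contig
    keep <- rep(FALSE, n)
    for (i in order(-scores)) {
      acc <- which(keep & candidates$contig_id == candidates$contig_id[i])
      if (!any(abs(candidates$pos[acc] - candidates$pos[i]) < min_gap)) {
        keep[i] <- TRUE
      }
    }
    return(keep)
  }
  for (cg in unique(candidates$contig_id)) {
    idx <- which(candidates$contig_id == cg)
    pos <- sort(candidates$pos[idx])
    if (length(pos) < 2L) next
    gaps <- diff(pos)
    close_lo <- c(gaps < min_gap, FALSE)   # close to the next candidate
    close_hi <- c(FALSE, gaps < min_gap)   # close to the previous one
    bad_pos <- pos[close_lo | close_hi]
    keep[idx[candidates$pos[idx] %in% bad_pos]] <- FALSE
  }
  keep
}

#' Flank-length filter: require `min_flank` nucleotides on each side
#'
#' @param candidates candidate data.frame (`contig_id`, `pos`, 0-based).
#' @param contig_lengths named integer vector of contig lengths.
#' @param min_flank minimum flank length (nt).
#' @return logical keep vector.
#' @export
flank_length_filter <- function(candidates, contig_lengths, min_flank = 100L) {
  if (nrow(candidates) == 0L) return(logical(0))
  len <- unname(contig_lengths[candidates$contig_id])
  if (anyNA(len)) stop("missing contig length for some candidates")
  candidates$pos >= min_flank & candidates$pos <= len - min_flank - 1L
}

candidate_window <- function(candidates, contigs, flank = 100L,
                             allele = c("ref", "major", "minor")) {
  allele <- match.arg(allele)
  vapply(seq_len(nrow(candidates)), function(i) {
    seqs <- contigs[[candidates$contig_id[i]]]
    j <- candidates$pos[i] + 1L
    w <- substr(seqs, max(1L, j - flank), min(nchar(seqs), j + flank))
    if (allele != "ref") {
      at <- min(j - 1L, flank) + 1L
      substr(w, at, at) <- candidates[[paste0(allele, "_base")]][i]
    }
    w
  }, character(1))
}

#' Genomic-contiguity filter against a reference
#'
#' Keeps a candidate only if its full flanking sequence (both flanks plus
#' the site, with either allele substituted at the site) occurs
#' contiguously in the supplied reference on either strand. This guards
#' against probes spanning exon-intron junctions.
#'
#' @param candidates candidate data.frame (`contig_id`, `pos`,
#'   `major_base`, `minor_base`).
#' @param contigs named character vector of contig consensus sequences.
#' @param reference named character vector of reference sequences, or
#'   `NULL` to skip the filter (all kept, with a warning).
#' @param flank window half-width (nt).
#' @return logical keep vector.
#' @export
genomic_contiguity_filter <- function(candidates, contigs, reference,
                                      flank = 100L) {
  if (nrow(candidates) == 0L) return(logical(0))
  if (is.null(reference)) {
    warning("no reference supplied; genomic-contiguity filter skipped")
    return(rep(NA, nrow(candidates)))
  }
  ref <- Biostrings::DNAStringSet(reference)
  hit_in_ref <- function(pat) {
    p <- Biostrings::DNAString(pat)
    fwd <- sum(Biostrings::vcountPattern(p, ref)) > 0
    if (fwd) return(TRUE)
    sum(Biostrings::vcountPattern(Biostrings::reverseComplement(p), ref)) > 0
  }
  wmaj <- candidate_window(candidates, contigs, flank, "major")
  wmin <- candidate_window(candidates, contigs, flank, "minor")
  vapply(seq_along(wmaj),
         function(i) hit_in_ref(wmaj[i]) || hit_in_ref(wmin[i]),
         logical(1))
}

#' Built-in proxy for the assay design score
#'
#' Scores each candidate's flanking context in \[0, 1\] as 1 minus
#' penalties: flank GC content outside \[0.30, 0.70\] (-0.3); a
#' homopolymer run of 6+ nt within 60 nt of the site (-0.3); any `N` in
#' the flanks (-0.5); another candidate within 60 nt on the same contig,
#' judged on the pre-filter candidate set (-0.2). Floored at 0.
#'
#' @param candidates candidate data.frame.
#' @param contigs named character vector of contig sequences.
#' @param flank flank half-width (nt) used for the GC and N terms.
#' @param near_window distance (nt) for the homopolymer and proximity terms.
#' @return numeric score vector in \[0, 1\].
#' @export
proxy_design_score <- function(candidates, contigs, flank = 100L,
                               near_window = 60L) {
  n <- nrow(candidates)
  if (n == 0L) return(numeric(0))
  score <- numeric(n)
  for (i in seq_len(n)) {
    seqs <- contigs[[candidates$contig_id[i]]]
    j <- candidates$pos[i] + 1L
    left <- substr(seqs, max(1L, j - flank), j - 1L)
    right <- substr(seqs, j + 1L, min(nchar(seqs), j + flank))
    flanks <- paste0(left, right)
    near <- substr(seqs, max(1L, j - near_window),
                   min(nchar(seqs), j + near_window))
    pen <- 0
    gc <- nchar(gsub("[^GC]", "", flanks)) / max(1L, nchar(flanks))
    if (gc < 0.30 || gc > 0.70) pen <- pen + 0.3
    if (grepl("A{6,}|C{6,}|G{6,}|T{6,}", near)) pen <- pen + 0.3
    if (grepl("N", flanks, fixed = TRUE)) pen <- pen + 0.5
    others <- candidates$pos[candidates$contig_id == candidates$contig_id[i]]
    others <- others[others != candidates$pos[i]]
    if (any(abs(others - candidates$pos[i]) <= near_window)) pen <- pen + 0.2
    score[i] <- max(0, 1 - pen)
  }
  score
}

#' Design-score filter
#'
#' @param candidates candidate data.frame.
#' @param contigs named character vector of contig sequences (used by the
#'   built-in proxy scorer).
#' @param scorer function `(candidates, contigs) -> numeric in [0,1]`;
#'   defaults to [proxy_design_score()].
#' @param min_score minimum acceptable score.
#' @return logical keep vector; scores are attached as attribute `scores`.
#' @export
design_score_filter <- function(candidates, contigs, scorer = NULL,
                                min_score = 0.6) {
  scorer <- if (is.null(scorer)) proxy_design_score else scorer
  s <- scorer(candidates, contigs)
  if (any(s < 0 | s > 1, na.rm = TRUE)) {
    stop("design scorer returned values outside [0, 1]")
  }
  keep <- s >= min_score
  attr(keep, "scores") <- s
  keep
}

#' Similarity filter: shared k-mers between candidate flank windows
#'
#' An operational stand-in for cross-similarity / repeat screening: a
#' candidate is removed when its flank window shares any exact k-mer
#' (default 31) with the window of a candidate on a *different* contig
#' (windows of same-contig candidates overlap by construction at the
#' 60-nt spacing and are ignored). Both members of a sharing pair are
#' removed.
#'
#' @param candidates candidate data.frame.
#' @param contigs named character vector of contig sequences.
#' @param k k-mer length.
#' @param flank window half-width (nt).
#' @return logical keep vector.
#' @export
similarity_filter <- function(candidates, contigs, k = 31L, flank = 100L) {
  n <- nrow(candidates)
  if (n == 0L) return(logical(0))
  win <- candidate_window(candidates, contigs, flank, "ref")
  kmers <- lapply(win, function(w) {
    L <- nchar(w)
    if (L < k) return(character(0))
    unique(substring(w, 1:(L - k + 1L), k:L))
  })
  tab <- data.frame(
    kmer = unlist(kmers, use.names = FALSE),
    idx = rep.int(seq_len(n), lengths(kmers)),
    stringsAsFactors = FALSE)
  tab$contig <- candidates$contig_id[tab$idx]
  # a k-mer seen on >= 2 distinct contigs condemns all its candidates
  ncontig <- tapply(tab$contig, tab$kmer, function(x) length(unique(x)))
  bad_kmers <- names(ncontig)[ncontig >= 2L]
  keep <- rep(TRUE, n)
  keep[unique(tab$idx[tab$kmer %in% bad_kmers])] <- FALSE
  keep
}

#' Apply all validation-panel filters and build a report
#'
#' Evaluates the spacing, flank-length, genomic-contiguity, design-score
#' and similarity filters over the full candidate set and reports, for
#' every candidate, whether it was kept and which filters it failed. The
#' report partitions the input: a candidate is kept exactly when its
#' failed-filter list is empty.
#'
#' @param candidates candidate data.frame from [call_candidate_snps_all()].
#' @param contigs named character vector of contig consensus sequences.
#' @param reference optional named character vector of reference genomic
#'   sequences; when `NULL` the contiguity filter is skipped (recorded in
#'   the `skipped_filters` attribute).
#' @param min_gap,min_flank,min_score,k filter thresholds.
#' @param scorer optional design scorer (see [design_score_filter()]).
#' @param keep_better_of_pair spacing variant keeping the better-scored
#'   member of each close pair.
#' @param n_max optional cap: keep at most the `n_max` best-scoring
#'   survivors.
#' @return data.frame report: `snp_id`, `contig_id`, `pos`, `kept`,
#'   `failed_filters` (comma-joined), `design_score`.
#' @export
select_panel <- function(candidates, contigs, reference = NULL,
                         min_gap = 60L, min_flank = 100L, min_score = 0.6,
                         k = 31L, scorer = NULL, keep_better_of_pair = FALSE,
                         n_max = NULL) {
  n <- nrow(candidates)
  lens <- vapply(contigs, nchar, integer(1))
  ds <- design_score_filter(candidates, contigs, scorer, min_score)
  scores <- attr(ds, "scores")
  fails <- list(
    spacing = !spacing_filter(candidates, min_gap,
                              keep_better = keep_better_of_pair,
                              scores = scores),
    flank_length = !flank_length_filter(candidates, lens, min_flank),
    genomic_contiguity = !suppressWarnings(
      genomic_contiguity_filter(candidates, contigs, reference, min_flank)),
    design_score = !as.logical(ds),
    similarity = !similarity_filter(candidates, contigs, k, min_flank)
  )
  skipped <- names(fails)[vapply(fails, anyNA, logical(1))]
  for (s in skipped) fails[[s]] <- rep(FALSE, n)
  failed_mat <- do.call(cbind, fails)
  failed_filters <- apply(failed_mat, 1, function(r) {
    paste(PANEL_FILTERS[r], collapse = ",")
  })
  if (n == 0L) failed_filters <- character(0)
  report <- data.frame(
    snp_id = paste0(candidates$contig_id, "_", candidates$pos + 1L),
    contig_id = candidates$contig_id, pos = candidates$pos,
    kept = !nzchar(failed_filters), failed_filters = failed_filters,
    design_score = scores, stringsAsFactors = FALSE)
  if (!is.null(n_max) && sum(report$kept) > n_max) {
    kept_idx <- which(report$kept)
    drop <- kept_idx[order(-report$design_score[kept_idx])][-seq_len(n_max)]
    report$kept[drop] <- FALSE
    report$failed_filters[drop] <- "panel_cap"
  }
  attr(report, "skipped_filters") <- skipped
  report
}
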