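## SNP validation from genotype calls, using doubled haploids (DH) as the
## duplication detector.  A DH genome is fully homozygous, so a
## heterozygous DH call betrays an assay reading two paralogous loci at
## once: all-heterozygous assays are paralogous sequence variants (PSVs),
## and a DH mixture of one homozygote class plus heterozygotes is the
## signature of a multisite variant (MSV: one paralog fixed, the other
## segregating).

#' Apply per-call and per-SNP quality thresholds
#'
#' Calls with a GenCall score below `gencall_min` are masked to `NC`;
#' SNPs with a GenTrain score below `gentrain_min`, or with a valid-call
#' rate (after masking) below `min_call_rate`, are marked failed.
#'
#' @param m a `GenotypeMatrix`.
#' @param gencall_min,gentrain_min quality score cutoffs.
#' @param min_call_rate minimum proportion of valid calls for a SNP to be
#'   assayable.
#' @return list with `matrix` (the masked `GenotypeMatrix`), `failed`
#'   (character vector of failed snp_ids), `call_rate` (named numeric) and
#'   `valid` (logical matrix of valid calls).
#' @export
apply_quality_thresholds <- function(m, gencall_min = 0.25,
                                     gentrain_min = 0.25,
                                     min_call_rate = 0.80) {
  stopifnot(inherits(m, "GenotypeMatrix"))
  calls <- m$calls
  mask <- m$gencall < gencall_min
  calls[mask] <- "NC"
  gencall <- m$gencall
  gencall[calls == "NC"] <- 0
  valid <- calls != "NC"
  call_rate <- rowMeans(valid)
  failed <- m$snp_ids[m$gentrain < gentrain_min | call_rate < min_call_rate]
  masked <- new_genotype_matrix(m$snp_ids, m$sample_ids, calls, gencall,
                                m$gentrain, m$alleles)
  list(matrix = masked, failed = failed,
       call_rate = setNames(call_rate, m$snp_ids), valid = valid)
}

#' Classify one assayed SNP from its valid calls
#'
#' Rules over valid (non-`NC`) calls: *monomorphic* when every valid call
#' is the same homozygous genotype; *psv* when the fraction of non-`AB`
#' valid calls does not exceed `tolerance` (default 0, i.e. every valid
#' call is `AB`) -- a low-confidence note is added when no valid DH call
#' supports the diagnosis; *true* otherwise (two or more genotype classes
#' observed). The MSV-candidate flag is set on a true SNP whose valid DH
#' calls contain both `AB` and exactly one homozygous class.
#'
#' @param calls character vector of calls (`AA`, `AB`, `BB`, `NC`) named
#'   or ordered by sample.
#' @param manifest sample manifest data.frame aligned with `calls`.
#' @param tolerance maximum fraction of non-`AB` valid calls still counted
#'   as a PSV.
#' @return list: `status` (one of `monomorphic`, `psv`, `true`),
#'   `msv_candidate`, `n_valid`, `n_valid_dh`, `notes` (character).
#' @export
classify_snp <- function(calls, manifest, tolerance = 0) {
  if (length(calls) != nrow(manifest)) {
    stop("calls and manifest must align")
  }
  valid <- calls != "NC"
  if (!any(valid)) {
    stop("classify_snp received a SNP with zero valid calls; ",
         "it should have been marked failed upstream")
  }
  v <- calls[valid]
  dh <- v[manifest$ploidy_class[valid] == "DH"]
  notes <- character(0)
  classes <- unique(v)
  msv <- FALSE
  if (length(classes) == 1L && classes %in% c("AA", "BB")) {
    status <- "monomorphic"
  } else if (mean(v != "AB") <= tolerance) {
    status <- "psv"
    if (length(dh) == 0L) {
      notes <- c(notes, "psv_no_valid_dh")
    }
  } else {
    status <- "true"
    dh_hom <- unique(dh[dh %in% c("AA", "BB")])
    if (any(dh == "AB") && length(dh_hom) == 1L) {
      msv <- TRUE
      notes <- c(notes, "msv_signature")
    }
  }
  list(status = status, msv_candidate = msv, n_valid = length(v),
       n_valid_dh = length(dh), notes = notes)
}

#' Classify every SNP of a genotype matrix
#'
#' Applies [apply_quality_thresholds()] and then [classify_snp()] to each
#' non-failed SNP. The four statuses partition the assayed SNPs:
#' `failed + monomorphic + psv + true = n SNPs`.
#'
#' @param m a `GenotypeMatrix` (raw; thresholds are applied here).
#' @param manifest sample manifest data.frame; sample ids must match the
#'   matrix columns.
#' @param gencall_min,gentrain_min,min_call_rate see
#'   [apply_quality_thresholds()].
#' @param tolerance see [classify_snp()].
#' @return data.frame: `snp_id`, `status` (`failed`, `monomorphic`,
#'   `psv`, `true`), `msv_candidate`, `call_rate`, `n_valid_dh`, `notes`.
#' @export
classify_genotypes <- function(m, manifest, gencall_min = 0.25,
                               gentrain_min = 0.25, min_call_rate = 0.80,
                               tolerance = 0) {
  manifest <- manifest[match(m$sample_ids, manifest$sample_id), ]
  if (anyNA(manifest$sample_id)) {
    stop("manifest is missing samples present in the genotype matrix")
  }
  qc <- apply_quality_thresholds(m, gencall_min, gentrain_min, min_call_rate)
  calls <- qc$matrix$calls
  out <- data.frame(snp_id = m$snp_ids, status = "failed",
                    msv_candidate = FALSE, call_rate = qc$call_rate,
                    n_valid_dh = 0L, notes = "", stringsAsFactors = FALSE)
  todo <- which(!(m$snp_ids %in% qc$failed))
  for (i in todo) {
    cl <- classify_snp(calls[i, ], manifest, tolerance)
    out$status[i] <- cl$status
    out$msv_candidate[i] <- cl$msv_candidate
    out$n_valid_dh[i] <- cl$n_valid_dh
    out$notes[i] <- paste(cl$notes, collapse = ";")
  }
  rownames(out) <- NULL
  out
}

#' Summarise a classification run
#'
#' Produces the three summary views of a validation experiment: status
#' counts (overall and re-classified within each population subset, DH
#' samples forming their own group), minor-allele-frequency bins of true
#' SNPs per subset, and a status-by-SNPs-per-contig table.
#'
#' @param classifications data.frame from [classify_genotypes()] (pooled
#'   classification).
#' @param m the raw `GenotypeMatrix`.
#' @param manifest sample manifest data.frame.
#' @param candidates optional candidate table (`contig_id` per snp_id,
#'   matched by `snp_id = <contig>_<pos+1>`) used for the per-contig view;
#'   when `NULL` the contig table is omitted.
#' @param ... thresholds passed on to [classify_genotypes()].
#' @return list with `status_counts` (data.frame subset x status),
#'   `maf_bins` (data.frame subset x bin counts over true SNPs) and
#'   `contig_table` (status x SNPs-per-contig bins, or `NULL`).
#' @export
classification_summary <- function(classifications, m, manifest,
                                   candidates = NULL, ...) {
  manifest <- manifest[match(m$sample_ids, manifest$sample_id), ]
  subsets <- c(list(pooled = m$sample_ids),
               split(manifest$sample_id, manifest$population))
  statuses <- c("failed", "monomorphic", "psv", "true")
  status_counts <- list(); maf_rows <- list()
  bins <- maf_bin_levels()
  for (nm in names(subsets)) {
    cls <- if (nm == "pooled") classifications else {
      sub <- subset_matrix(m, subsets[[nm]])
      classify_genotypes(sub, manifest[manifest$sample_id %in% subsets[[nm]], ],
                         ...)
    }
    status_counts[[nm]] <- table(factor(cls$status, levels = statuses))
    true_ids <- cls$snp_id[cls$status == "true"]
    qc <- apply_quality_thresholds(subset_matrix(m, subsets[[nm]]))
    mafs <- vapply(true_ids, function(id) {
      allele_frequencies(qc$matrix$calls[id, ])$maf
    }, numeric(1))
    maf_rows[[nm]] <- table(factor(maf_bin(mafs), levels = bins))
  }
  status_counts <- as.data.frame(do.call(rbind, status_counts))
  maf_bins <- as.data.frame(do.call(rbind, maf_rows))
  contig_table <- NULL
  if (!is.null(candidates)) {
    snp_contig <- setNames(candidates$contig_id,
                           paste0(candidates$contig_id, "_",
                                  candidates$pos + 1L))
    cg <- snp_contig[classifications$snp_id]
    per_contig <- table(cg)
    nb <- ifelse(per_contig > 10, ">10", as.character(per_contig))
    bin_lvls <- c(as.character(1:10), ">10")
    contig_table <- table(
      factor(classifications$status, levels = statuses),
      factor(nb[as.character(cg)], levels = bin_lvls))
  }
  list(status_counts = status_counts, maf_bins = maf_bins,
       contig_table = contig_table)
}

#' Restrict a genotype matrix to a subset of samples
#' @param m a `GenotypeMatrix`.
#' @param sample_ids samples to keep.
#' @return a `GenotypeMatrix` over the subset.
#' @export
subset_matrix <- function(m, sample_ids) {
  idx <- match(sample_ids, m$sample_ids)
  if (anyNA(idx)) stop("unknown sample in subset")
  new_genotype_matrix(m$snp_ids, m$sample_ids[idx],
                      m$calls[, idx, drop = FALSE],
                      m$gencall[, idx, drop = FALSE], m$gentrain, m$alleles)
}
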