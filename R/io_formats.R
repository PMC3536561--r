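#' @importFrom stats rbinom rbeta rlnorm runif rpois setNames uniroot pnorm
#' @importFrom utils read.table write.table
NULL

VALID_CALLS <- c("AA", "AB", "BB", "NC")
DNA_BASES <- c("A", "C", "G", "T")

## ---- ContigAlignment --------------------------------------------------------

#' Construct a validated contig alignment
#'
#' A `ContigAlignment` holds an EST contig consensus sequence together with
#' the gapped reads of the underlying multiple alignment, all expressed in
#' consensus coordinates (every gapped read has the same length as the
#' consensus).
#'
#' @param contig_id single contig identifier.
#' @param consensus ungapped consensus sequence over `A,C,G,T,N`.
#' @param read_ids character vector of read identifiers.
#' @param reads character vector of gapped read sequences over
#'   `A,C,G,T,N,-`, each the same length as `consensus`.
#' @return an object of class `ContigAlignment`: a list with elements
#'   `contig_id`, `consensus`, `read_ids`, `reads`.
#' @export
new_contig_alignment <- function(contig_id, consensus, read_ids, reads) {
  stopifnot(is.character(contig_id), length(contig_id) == 1L)
  consensus <- toupper(consensus)
  reads <- toupper(reads)
  if (length(read_ids) != length(reads)) {
    stop("read_ids and reads must have the same length")
  }
  if (grepl("-", consensus, fixed = TRUE)) {
    stop("consensus of contig '", contig_id, "' contains gap characters")
  }
  if (grepl("[^ACGTN]", consensus)) {
    stop("consensus of contig '", contig_id, "' contains invalid characters")
  }
  L <- nchar(consensus)
  bad_len <- which(nchar(reads) != L)
  if (length(bad_len)) {
    stop("read '", read_ids[bad_len[1]], "' of contig '", contig_id,
         "' has length ", nchar(reads[bad_len[1]]),
         " but consensus has length ", L)
  }
  bad_chr <- which(grepl("[^ACGTN-]", reads))
  if (length(bad_chr)) {
    stop("read '", read_ids[bad_chr[1]], "' contains invalid characters")
  }
  structure(
    list(contig_id = contig_id, consensus = consensus,
         read_ids = as.character(read_ids), reads = as.character(reads)),
    class = "ContigAlignment"
  )
}

#' @export
print.ContigAlignment <- function(x, ...) {
  cat("ContigAlignment", x$contig_id, "-", nchar(x$consensus), "nt,",
      length(x$reads), "reads\n")
  invisible(x)
}

#' Read a per-contig gapped FASTA alignment
#'
#' The first record is the consensus (conventionally suffixed
#' `.consensus`); all subsequent records are gapped reads of the same
#' length.
#'
#' @param path FASTA file holding one contig alignment.
#' @return a [new_contig_alignment()] object.
#' @export
read_contig_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty alignment file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  contig_id <- sub("\\.consensus$", "", ids[1])
  new_contig_alignment(
    contig_id = contig_id,
    consensus = as.character(seqs[[1]]),
    read_ids = if (length(seqs) > 1L) ids[-1] else character(0),
    reads = if (length(seqs) > 1L) as.character(seqs[-1]) else character(0)
  )
}

#' Write a contig alignment as gapped FASTA
#'
#' @param aln a `ContigAlignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contig_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "ContigAlignment"))
  seqs <- Biostrings::BStringSet(c(aln$consensus, aln$reads))
  names(seqs) <- c(paste0(aln$contig_id, ".consensus"), aln$read_ids)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

## ---- GenotypeMatrix ---------------------------------------------------------

#' Construct a validated genotype matrix
#'
#' Calls are unordered genotypes over the two assay alleles (`BA` is
#' normalised to `AB`); `NC` (no-call) cells always carry a GenCall score
#' of 0.
#'
#' @param snp_ids,sample_ids character vectors naming the rows / columns.
#' @param calls character matrix (SNP x sample) over `AA, AB, BB, NC`.
#' @param gencall numeric matrix of per-call GenCall scores in \[0, 1\].
#' @param gentrain numeric vector of per-SNP GenTrain scores in \[0, 1\].
#' @param alleles two-column character matrix (`allele_A`, `allele_B`) of
#'   assay alleles, one row per SNP, `allele_A != allele_B`.
#' @return an object of class `GenotypeMatrix`.
#' @export
new_genotype_matrix <- function(snp_ids, sample_ids, calls, gencall,
                                gentrain, alleles) {
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(snp_ids)) {
    stop("duplicate snp_id: ", snp_ids[duplicated(snp_ids)][1])
  }
  calls <- as.matrix(calls)
  gencall <- as.matrix(gencall)
  calls[calls == "BA"] <- "AB"
  if (!all(dim(calls) == c(length(snp_ids), length(sample_ids))) ||
      !all(dim(gencall) == dim(calls))) {
    stop("inconsistent genotype matrix dimensions")
  }
  if (length(gentrain) != length(snp_ids)) {
    stop("gentrain must have one score per SNP")
  }
  bad <- !(calls %in% VALID_CALLS)
  if (any(bad)) stop("unknown call token: ", calls[bad][1])
  if (any(gencall < 0 | gencall > 1, na.rm = TRUE) ||
      any(gentrain < 0 | gentrain > 1, na.rm = TRUE)) {
    stop("quality scores must lie in [0, 1]")
  }
  gencall[calls == "NC"] <- 0
  alleles <- as.matrix(alleles)
  colnames(alleles) <- c("allele_A", "allele_B")
  if (nrow(alleles) != length(snp_ids)) stop("one allele pair per SNP required")
  if (!all(alleles %in% DNA_BASES)) stop("alleles must be A, C, G or T")
  if (any(alleles[, 1] == alleles[, 2])) {
    stop("allele_A must differ from allele_B")
  }
  dimnames(calls) <- dimnames(gencall) <- list(snp_ids, sample_ids)
  rownames(alleles) <- snp_ids
  structure(
    list(snp_ids = snp_ids, sample_ids = sample_ids, calls = calls,
         gencall = gencall, gentrain = setNames(as.numeric(gentrain), snp_ids),
         alleles = alleles),
    class = "GenotypeMatrix"
  )
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", length(x$snp_ids), "SNPs x",
      length(x$sample_ids), "samples\n")
  invisible(x)
}

#' Read a genotype matrix CSV
#'
#' The dialect is a GenomeStudio-like spreadsheet export: a header row
#' `snp_id, allele_A, allele_B, gentrain, <sample 1>, <sample 2>, ...`
#' followed by one row per SNP whose per-sample cells are `CALL:gencall`
#' (e.g. `AB:0.91`). Column names for the four fixed fields can be remapped
#' through `col_map` for other exports.
#'
#' @param path CSV file.
#' @param lenient if `TRUE`, unparseable cells become `NC` with GenCall 0
#'   instead of raising an error.
#' @param col_map named list remapping the fixed column names.
#' @return a [new_genotype_matrix()] object.
#' @export
read_genotype_matrix <- function(path, lenient = FALSE,
                                 col_map = list(snp_id = "snp_id",
                                                allele_A = "allele_A",
                                                allele_B = "allele_B",
                                                gentrain = "gentrain")) {
  df <- read.table(path, sep = ",", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  fixed <- unlist(col_map[c("snp_id", "allele_A", "allele_B", "gentrain")])
  if (!all(fixed %in% names(df))) {
    stop("genotype CSV is missing fixed columns: ",
         paste(setdiff(fixed, names(df)), collapse = ", "))
  }
  sample_ids <- setdiff(names(df), fixed)
  if (length(sample_ids) == 0L) stop("genotype CSV has no sample columns")
  snp_ids <- df[[fixed["snp_id"]]]
  if (anyDuplicated(snp_ids)) {
    stop("duplicate snp_id: ", snp_ids[duplicated(snp_ids)][1])
  }
  cells <- as.matrix(df[, sample_ids, drop = FALSE])
  ok <- grepl("^(AA|AB|BA|BB|NC):[0-9.eE+-]+$", cells)
  if (!all(ok)) {
    if (!lenient) stop("unparseable genotype cell: '", cells[!ok][1], "'")
    cells[!ok] <- "NC:0"
  }
  calls <- sub(":.*$", "", cells)
  gencall <- suppressWarnings(array(as.numeric(sub("^[A-Z]+:", "", cells)),
                                    dim = dim(cells)))
  if (anyNA(gencall)) {
    if (!lenient) stop("non-numeric GenCall score in genotype CSV")
    calls[is.na(gencall)] <- "NC"
    gencall[is.na(gencall)] <- 0
  }
  gentrain <- as.numeric(df[[fixed["gentrain"]]])
  if (anyNA(gentrain)) stop("non-numeric GenTrain score in genotype CSV")
  new_genotype_matrix(snp_ids, sample_ids, calls, gencall, gentrain,
                      cbind(df[[fixed["allele_A"]]], df[[fixed["allele_B"]]]))
}

#' Write a genotype matrix CSV
#'
#' GenCall and GenTrain scores are written with four decimal places, the
#' granularity at which the simulator draws them, so simulator output
#' round-trips exactly.
#'
#' @param m a `GenotypeMatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(m, path) {
  stopifnot(inherits(m, "GenotypeMatrix"))
  cells <- matrix(paste0(m$calls, ":", trim_num(m$gencall)),
                  nrow = length(m$snp_ids))
  df <- data.frame(snp_id = m$snp_ids,
                   allele_A = m$alleles[, 1], allele_B = m$alleles[, 2],
                   gentrain = trim_num(m$gentrain), cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:4)] <- m$sample_ids
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed 4-decimal rendering without trailing-zero loss ("0.9" -> "0.9")
trim_num <- function(x) sub("0+$", "", sub("\\.$", "", sprintf("%.4f", x)))

## ---- SampleManifest ---------------------------------------------------------

#' Read a sample manifest TSV
#'
#' Three tab-separated columns with a header: `sample_id`, `population`,
#' `ploidy_class` (`DH` for doubled haploids, `diploid` otherwise).
#'
#' @param path TSV file.
#' @return a data.frame with the three manifest columns.
#' @export
read_sample_manifest <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("sample_id", "population", "ploidy_class")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  validate_manifest(df)
  df
}

validate_manifest <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         df$sample_id[duplicated(df$sample_id)][1])
  }
  bad <- !(df$ploidy_class %in% c("DH", "diploid"))
  if (any(bad)) stop("invalid ploidy_class: '", df$ploidy_class[bad][1], "'")
  if (nrow(df) == 0L || !any(nzchar(df$population))) {
    stop("manifest must name at least one population")
  }
  invisible(df)
}

#' Write a sample manifest TSV
#' @param manifest data.frame with `sample_id`, `population`, `ploidy_class`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.table(manifest[, c("sample_id", "population", "ploidy_class")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- Homology hits ----------------------------------------------------------

HOMOLOGY_COLS <- c("query_id", "subject_protein_id", "pct_identity", "aln_len",
                   "mismatches", "gap_open", "qstart", "qend", "sstart",
                   "send", "evalue", "bitscore")

#' Read a BLAST-outfmt-6-like homology table
#'
#' Tab-separated, no header, the de facto standard 12 columns
#' (query, subject, \%identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, e-value, bitscore), plus an optional 13th
#' `frame` column in `-3..-1, 1..3`. Coordinates are 1-based inclusive.
#'
#' @param path TSV file; an empty file yields a zero-row table.
#' @param default_frame frame assumed when the 13th column is absent.
#' @return data.frame of hits with a `subject_gene_id` column (empty until
#'   mapped by [filter_best_hits()]).
#' @export
read_homology_table <- function(path, default_frame = 1L) {
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, colClasses = "character"),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)),
                                      length(HOMOLOGY_COLS)), HOMOLOGY_COLS))
    out$frame <- integer(0)
    out$subject_gene_id <- character(0)
    return(out)
  }
  if (ncol(raw) < 12L) stop("homology table needs >= 12 columns")
  out <- setNames(raw[, 1:12], HOMOLOGY_COLS)
  for (col in c("pct_identity", "evalue", "bitscore")) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v)) stop("non-numeric ", col, ": '", out[[col]][is.na(v)][1], "'")
    out[[col]] <- v
  }
  for (col in c("aln_len", "mismatches", "gap_open", "qstart", "qend",
                "sstart", "send")) {
    out[[col]] <- as.integer(out[[col]])
  }
  out$frame <- if (ncol(raw) >= 13L) as.integer(raw[[13]]) else
    rep(as.integer(default_frame), nrow(out))
  if (any(!out$frame %in% c(-3:-1, 1:3), na.rm = TRUE)) {
    stop("frame must lie in -3..-1, 1..3")
  }
  if (any(out$evalue < 0)) stop("evalue must be >= 0")
  plus <- !is.na(out$frame) & out$frame > 0
  if (any(plus & out$qstart > out$qend)) {
    stop("qstart > qend on a plus-frame hit")
  }
  out$subject_gene_id <- rep("", nrow(out))
  out
}

#' Write a homology table (BLAST outfmt-6 columns plus frame)
#' @param hits data.frame as returned by [read_homology_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_homology_table <- function(hits, path) {
  df <- hits[, c(HOMOLOGY_COLS, "frame")]
  df$evalue <- format(df$evalue, digits = 15, trim = TRUE, scientific = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- misc shared helpers ----------------------------------------------------

#' Read a (possibly multi-sequence) FASTA file as named character vector
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta_seqs <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(seqs)), sub("\\s.*$", "", names(seqs)))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

revcomp <- function(x) {
  vapply(chartr("ACGTacgt", "TGCAtgca", x), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
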