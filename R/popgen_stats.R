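## Allele-frequency, heterozygosity/PIC, MAF-bin and
## transition/transversion statistics over classified SNPs.

TS_PAIRS <- c("AG", "CT")
TV_PAIRS <- c("AC", "AT", "CG", "GT")
MUTATION_PAIRS <- c(TS_PAIRS, TV_PAIRS)

#' Allele frequencies by direct count of genotype calls
#'
#' `p` is the frequency of assay allele A: `p = (2 nAA + nAB) / (2 n)`
#' over valid calls; heterozygosity and PIC follow [freq_stats()].
#'
#' @param calls character vector of genotype calls (`AA`, `AB`, `BB`,
#'   `NC`); `NC` calls are ignored.
#' @return list with `n_valid`, `p`, `q`, `maf`, `he`, `pic`.
#' @export
allele_frequencies <- function(calls) {
  v <- calls[calls != "NC"]
  if (length(v) == 0L) stop("no valid calls to count")
  n_aa <- sum(v == "AA"); n_ab <- sum(v == "AB")
  p <- (2 * n_aa + n_ab) / (2 * length(v))
  c(list(n_valid = length(v)), freq_stats(p))
}

maf_bin_levels <- function() {
  c("<0.05", "0.05-0.10", "0.10-0.20", "0.20-0.30", "0.30-0.40", "0.40-0.50")
}

#' Bin a minor allele frequency
#'
#' Half-open bins `[0,0.05)`, `[0.05,0.10)`, `[0.10,0.20)`, `[0.20,0.30)`,
#' `[0.30,0.40)`, `[0.40,0.50]`; the top bin is closed because a MAF
#' cannot exceed 0.5.
#'
#' @param maf numeric vector of minor allele frequencies in \[0, 0.5\].
#' @return character vector of bin labels (factor levels in
#'   ascending order).
#' @export
maf_bin <- function(maf) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    stop("MAF must lie in [0, 0.5]")
  }
  cuts <- c(0, 0.05, 0.10, 0.20, 0.30, 0.40, 0.5)
  as.character(cut(maf, cuts, labels = maf_bin_levels(),
                   right = FALSE, include.lowest = TRUE))
}

#' Classify an allele pair as transition or transversion
#'
#' @param allele_A,allele_B character vectors of distinct bases.
#' @return data.frame with `pair` (canonical, alphabetical, e.g. `AG`) and
#'   `klass` (`transition` for `AG`/`CT`, `transversion` otherwise).
#' @export
mutation_type <- function(allele_A, allele_B) {
  a <- toupper(allele_A); b <- toupper(allele_B)
  if (any(!(a %in% DNA_BASES) | !(b %in% DNA_BASES))) {
    stop("alleles must be A, C, G or T")
  }
  if (any(a == b)) stop("alleles must differ")
  pair <- ifelse(a < b, paste0(a, b), paste0(b, a))
  data.frame(pair = pair,
             klass = ifelse(pair %in% TS_PAIRS, "transition", "transversion"),
             stringsAsFactors = FALSE)
}

#' Round half away from zero
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector (`0.005 -> 0.01`, unlike banker's rounding).
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Transition/transversion table over one or more SNP sets
#'
#' For each named set of allele pairs, counts the six mutation types,
#' reports each type's percentage of the set total (one decimal) and the
#' transition/transversion ratio `(nAG + nCT) / (nAC + nAT + nCG + nGT)`
#' rounded half-away-from-zero to two decimals. A set without
#' transversions reports an infinite ratio.
#'
#' @param sets named list; each element is a data.frame (or matrix) with
#'   columns `allele_A` and `allele_B`, or a character vector of canonical
#'   pairs (e.g. `"AG"`).
#' @return list with `counts` (data.frame, one row per mutation type plus
#'   a `TOTAL` row, one column per set), `percent` (same shape, percent of
#'   set total), and `ratio` (named numeric of Ts/Tv ratios).
#' @export
ts_tv_table <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  count_one <- function(x) {
    pairs <- if (is.character(x)) {
      mutation_type(substr(x, 1, 1), substr(x, 2, 2))$pair
    } else {
      mutation_type(x[, "allele_A"], x[, "allele_B"])$pair
    }
    table(factor(pairs, levels = MUTATION_PAIRS))
  }
  counts <- vapply(sets, count_one, numeric(length(MUTATION_PAIRS)))
  counts <- matrix(counts, nrow = length(MUTATION_PAIRS),
                   dimnames = list(MUTATION_PAIRS, names(sets)))
  totals <- colSums(counts)
  ts <- colSums(counts[TS_PAIRS, , drop = FALSE])
  tv <- colSums(counts[TV_PAIRS, , drop = FALSE])
  ratio <- ifelse(tv == 0, Inf, round_half_up(ts / tv, 2))
  percent <- round_half_up(100 * sweep(counts, 2, pmax(totals, 1), "/"), 1)
  counts_df <- as.data.frame(rbind(counts, TOTAL = totals))
  percent_df <- as.data.frame(percent)
  list(counts = counts_df, percent = percent_df,
       ratio = setNames(as.numeric(ratio), names(sets)))
}
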