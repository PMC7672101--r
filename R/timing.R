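# Timing mutations relative to copy-number events from variant allele
# frequencies. In a region where one allele was duplicated (copy gain or
# copy-neutral LOH), a mutation present on both copies of the duplicated
# allele (multiplicity 2) must predate the duplication; multiplicity-1
# mutations postdate it (or sit on the unduplicated allele). Expected VAF at
# purity p, total copy number T and multiplicity m is
#   p * m / (2 * (1 - p) + p * T).

#' SCNA segment table
#'
#' @param chrom,start,end segment span (1-based inclusive).
#' @param total_cn total copy number T (>= 2).
#' @param minor_cn minor-allele copy number.
#' @param purity tumor purity in (0, 1].
#' @param type "gain" (major >= 2, T >= 3) or "cnLOH" (T = 2, minor = 0).
#' @return data.frame of class \code{scna_segments}.
#' @export
scna_segments <- function(chrom, start, end, total_cn, minor_cn, purity, type) {
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   total_cn = as.integer(total_cn), minor_cn = as.integer(minor_cn),
                   purity = purity, type = type, stringsAsFactors = FALSE)
  .assert(all(df$purity > 0 & df$purity <= 1), "purity must be in (0, 1]")
  .assert(all(df$total_cn >= 2), "total_cn must be >= 2")
  major <- df$total_cn - df$minor_cn
  .assert(all(major >= 2), "segments must carry a duplicated allele (major >= 2)")
  .assert(all(df$type %in% c("gain", "cnLOH")), "type must be gain or cnLOH")
  .assert(all(df$type != "cnLOH" | (df$total_cn == 2 & df$minor_cn == 0)),
          "cnLOH means T = 2 with minor = 0")
  .assert(all(df$type != "gain" | df$total_cn >= 3), "gain means T >= 3")
  class(df) <- c("scna_segments", "data.frame")
  df
}

#' Expected variant allele frequency
#'
#' @param purity tumor purity p in (0, 1].
#' @param total_cn total tumor copy number T at the locus (>= 1).
#' @param multiplicity m, number of tumor copies carrying the variant.
#' @return p * m / (2 * (1 - p) + p * T).
#' @examples
#' expected_vaf(1, 3, 2)  # 2/3
#' @export
expected_vaf <- function(purity, total_cn, multiplicity) {
  .assert(all(purity > 0 & purity <= 1), "purity must be in (0, 1]")
  .assert(all(total_cn >= 1), "total_cn must be >= 1")
  .assert(all(multiplicity >= 1), "multiplicity must be >= 1")
  .assert(all(multiplicity <= total_cn), "multiplicity cannot exceed total_cn")
  purity * multiplicity / (2 * (1 - purity) + purity * total_cn)
}

#' Classify mutations as pre- or post-SCNA from VAF
#'
#' Computes the expected VAFs at multiplicity 2 (v2) and 1 (v1) for the
#' segment and assigns epoch "before" when vaf >= v2 - margin * (v2 - v1),
#' "after" when vaf <= v1 + margin * (v2 - v1), and "ambiguous" otherwise.
#' The symmetric exclusion margin is the conservative-threshold rule; at
#' margin 0 the midpoint partitions all mutations.
#'
#' @param catalog \code{mutation_catalog} rows within the segment.
#' @param segment one row of \code{\link{scna_segments}}.
#' @param margin fraction of the (v1, v2) gap excluded on each side
#'   (default 0.25).
#' @return catalog with \code{multiplicity} (2/1/NA) and \code{epoch}
#'   ("before"/"after"/"ambiguous") columns.
#' @export
classify_epoch <- function(catalog, segment, margin = 0.25) {
  p <- segment$purity; T <- segment$total_cn
  v2 <- expected_vaf(p, T, 2)
  v1 <- expected_vaf(p, T, 1)
  .assert(v2 > v1, "internal error: expected VAF not increasing in multiplicity")
  gap <- v2 - v1
  epoch <- ifelse(catalog$vaf >= v2 - margin * gap, "before",
                  ifelse(catalog$vaf <= v1 + margin * gap, "after", "ambiguous"))
  if (margin == 0) {
    # midpoint rule: partition everything
    epoch <- ifelse(catalog$vaf >= (v1 + v2) / 2, "before", "after")
  }
  out <- as.data.frame(catalog)
  out$multiplicity <- ifelse(epoch == "before", 2L, ifelse(epoch == "after", 1L, NA_integer_))
  out$epoch <- epoch
  class(out) <- class(catalog)
  out
}

#' Fraction of mutations predating the copy-number event
#'
#' Counts are normalized per haploid copy: mutations that predate the event
#' are carried by the single duplicated pre-SCNA lineage copy, mutations
#' after the event accrue on all T copies, so
#' \code{fraction = (N_before / 1) / (N_before / 1 + N_after / T)}.
#'
#' @param timed catalog with an \code{epoch} column from
#'   \code{\link{classify_epoch}}.
#' @param segment the corresponding segment row.
#' @return list with n_before, n_after, n_ambiguous, before_per_copy,
#'   after_per_copy, fraction_before (NA if no unambiguous mutation).
#' @export
fraction_before <- function(timed, segment) {
  nb <- sum(timed$epoch == "before")
  na_ <- sum(timed$epoch == "after")
  namb <- sum(timed$epoch == "ambiguous")
  if (nb + na_ == 0)
    return(list(n_before = nb, n_after = na_, n_ambiguous = namb,
                before_per_copy = NA_real_, after_per_copy = NA_real_,
                fraction_before = NA_real_))
  bpc <- nb / 1
  apc <- na_ / segment$total_cn
  list(n_before = nb, n_after = na_, n_ambiguous = namb,
       before_per_copy = bpc, after_per_copy = apc,
       fraction_before = bpc / (bpc + apc))
}

#' Cohort-level test of pre-SCNA excess
#'
#' Exact two-sided Wilcoxon signed-rank test of per-segment
#' fraction_before values against 0.5.
#'
#' @param fractions numeric vector of per-segment fractions (>= 5 values).
#' @return list with p_value, n, mean_fraction.
#' @export
cohort_timing_test <- function(fractions) {
  fractions <- fractions[!is.na(fractions)]
  .assert(length(fractions) >= 5, "need >= 5 segments")
  list(p_value = wilcoxon_signed_rank_exact(fractions - 0.5),
       n = length(fractions), mean_fraction = mean(fractions))
}
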