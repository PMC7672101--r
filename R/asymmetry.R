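# Strand-asymmetry analyses: transcriptional strand bias (TRB) by class,
# context and expression level, TSS-anchored strand-resolved densities,
# replication-timing consensus and densities, replication-strand bias from
# fork-direction tracks, and chromatin covariates.
#
# Strand convention (pyrimidine-centric): a mutation is labelled
# "untranscribed" when the pyrimidine of the mutated base pair lies on the
# gene's coding (untranscribed) strand, and "transcribed" when it lies on the
# template strand. Under a purine-lesion process with functional
# transcription-coupled repair, lesions on the template strand are repaired,
# depleting the "untranscribed" label (purine on template) relative to
# "transcribed".

.pyr_strand <- function(ref) ifelse(ref %in% PYR, "+", "-")

.pyr_class <- function(ref, alt) {
  ifelse(ref %in% PYR, paste0(ref, ">", alt),
         paste0(.complement_map[ref], ">", .complement_map[alt]))
}

.catalog_gr <- function(catalog) {
  GenomicRanges::GRanges(catalog$chrom, IRanges::IRanges(catalog$pos, catalog$pos))
}

#' Annotate SBS mutations with their transcriptional strand
#'
#' Labels each single-base substitution "transcribed" (pyrimidine of the
#' pair on the template strand), "untranscribed" (pyrimidine on the coding
#' strand), "intergenic" (outside genes) or "excluded" (inside genes on both
#' strands, template ambiguous).
#'
#' @param catalog \code{mutation_catalog}.
#' @param genes GRanges from \code{\link{gene_models}}.
#' @return catalog with \code{strand_label}, \code{sbs_class} (pyrimidine
#'   centric C>A..T>G) and \code{gene_idx} (index of the assigned gene, NA
#'   outside genes) columns; non-SBS rows get NA labels.
#' @export
annotate_strand <- function(catalog, genes) {
  n <- nrow(catalog)
  label <- rep(NA_character_, n)
  gene_idx <- rep(NA_integer_, n)
  idx <- which(catalog$mut_class == "SBS")
  if (length(idx) > 0) {
    gr <- .catalog_gr(catalog[idx, , drop = FALSE])
    hits <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    gstr <- as.character(GenomicRanges::strand(genes))
    lab <- rep("intergenic", length(idx))
    gi <- rep(NA_integer_, length(idx))
    if (length(qh) > 0) {
      for (q in unique(qh)) {
        gs <- unique(gstr[sh[qh == q]])
        if (length(gs) > 1) {
          lab[q] <- "excluded"
        } else {
          g <- sh[qh == q][1]
          gi[q] <- g
          ps <- .pyr_strand(catalog$ref[idx[q]])
          lab[q] <- if (ps == gs) "untranscribed" else "transcribed"
        }
      }
    }
    label[idx] <- lab
    gene_idx[idx] <- gi
  }
  out <- as.data.frame(catalog)
  out$strand_label <- label
  out$sbs_class <- NA_character_
  out$sbs_class[idx] <- .pyr_class(catalog$ref[idx], catalog$alt[idx])
  out$gene_idx <- gene_idx
  class(out) <- class(catalog)
  out
}

#' Transcriptional strand bias per substitution class
#'
#' Per pyrimidine-centric class: counts on the transcribed and untranscribed
#' strands, their ratio (transcribed / untranscribed; under a purine-lesion
#' process with TC-NER this estimates the repair-fold), and the exact
#' two-sided conditional Poisson test p-value.
#'
#' @param annotated catalog from \code{\link{annotate_strand}}.
#' @param opportunity optional named pair of opportunity lengths
#'   (transcribed, untranscribed) turning the test ratio into an
#'   opportunity-adjusted expectation; default NULL = 1:1.
#' @return data.frame: class, n_transcribed, n_untranscribed, ratio, p.
#' @export
trb_by_class <- function(annotated, opportunity = NULL) {
  genic <- annotated[annotated$strand_label %in% c("transcribed", "untranscribed"), ]
  .assert(nrow(genic) >= 1, "no genic mutations")
  exp_ratio <- if (is.null(opportunity)) 1 else opportunity[1] / opportunity[2]
  out <- lapply(SBS_CLASSES, function(cl) {
    nt <- sum(genic$sbs_class == cl & genic$strand_label == "transcribed")
    nu <- sum(genic$sbs_class == cl & genic$strand_label == "untranscribed")
    data.frame(class = cl, n_transcribed = nt, n_untranscribed = nu,
               ratio = if (nt + nu == 0 || nu == 0) NA_real_ else nt / nu,
               p = if (nt + nu == 0) NA_real_ else poisson_pair_test(nt, nu, exp_ratio))
  })
  do.call(rbind, out)
}

#' Transcriptional strand bias per trinucleotide context
#'
#' As \code{\link{trb_by_class}} at SBS96 channel resolution.
#'
#' @param annotated catalog from \code{\link{annotate_strand}}.
#' @param genome named character vector (for trinucleotide contexts).
#' @return data.frame: channel, n_transcribed, n_untranscribed, ratio, p.
#' @export
trb_by_context <- function(annotated, genome) {
  genic <- annotated[annotated$strand_label %in% c("transcribed", "untranscribed"), ]
  ch <- classify_sbs96(genic, genome)
  out <- lapply(sbs96_channels(), function(lab) {
    nt <- sum(!is.na(ch) & ch == lab & genic$strand_label == "transcribed")
    nu <- sum(!is.na(ch) & ch == lab & genic$strand_label == "untranscribed")
    data.frame(channel = lab, n_transcribed = nt, n_untranscribed = nu,
               ratio = if (nt + nu == 0 || nu == 0) NA_real_ else nt / nu,
               p = if (nt + nu == 0) NA_real_ else poisson_pair_test(nt, nu))
  })
  do.call(rbind, out)
}

#' Expression bins
#'
#' @param breaks increasing breakpoints on the RPKM scale; the default
#'   c(0, 0.1, 1, 10, 20000) gives the four bins 0-0.1, 0.1-1, 1-10,
#'   10-20000.
#' @return object of class \code{expression_bins}.
#' @export
expression_bins <- function(breaks = c(0, 0.1, 1, 10, 20000)) {
  .assert(all(diff(breaks) > 0), "breaks must be strictly increasing")
  structure(list(breaks = breaks,
                 labels = paste(head(breaks, -1), breaks[-1], sep = "-")),
            class = "expression_bins")
}

.bin_expression <- function(expr, bins) {
  cut(expr, breaks = bins$breaks, labels = bins$labels, include.lowest = TRUE)
}

#' Transcriptional strand bias by gene expression level
#'
#' Genes are grouped into expression bins; per bin, strand-specific mutation
#' counts are normalized by the summed gene length in the bin (density per
#' Mb per strand) and tested with the exact conditional Poisson test.
#'
#' @param annotated catalog from \code{\link{annotate_strand}}.
#' @param genes GRanges from \code{\link{gene_models}}.
#' @param bins \code{\link{expression_bins}}.
#' @return data.frame: bin, n_genes, length_mb, n_transcribed,
#'   n_untranscribed, density_transcribed, density_untranscribed, ratio, p.
#' @export
trb_by_expression <- function(annotated, genes, bins = expression_bins()) {
  expr <- genes$expression
  gene_bin <- .bin_expression(expr, bins)
  genic <- annotated[!is.na(annotated$gene_idx) &
                       annotated$strand_label %in% c("transcribed", "untranscribed"), ]
  mut_bin <- gene_bin[genic$gene_idx]
  out <- lapply(levels(gene_bin), function(b) {
    gsel <- which(!is.na(gene_bin) & gene_bin == b)
    len <- sum(GenomicRanges::width(genes[gsel]))
    msel <- which(!is.na(mut_bin) & mut_bin == b)
    nt <- sum(genic$strand_label[msel] == "transcribed")
    nu <- sum(genic$strand_label[msel] == "untranscribed")
    if (length(gsel) == 0 || len == 0) {
      return(data.frame(bin = b, n_genes = 0L, length_mb = 0, n_transcribed = NA_integer_,
                        n_untranscribed = NA_integer_, density_transcribed = NA_real_,
                        density_untranscribed = NA_real_, ratio = NA_real_, p = NA_real_))
    }
    mb <- len / 1e6
    data.frame(bin = b, n_genes = length(gsel), length_mb = mb,
               n_transcribed = nt, n_untranscribed = nu,
               density_transcribed = nt / mb, density_untranscribed = nu / mb,
               ratio = if (nu == 0) NA_real_ else nt / nu,
               p = if (nt + nu == 0) NA_real_ else poisson_pair_test(nt, nu))
  })
  do.call(rbind, out)
}

# retained 1-kb bins around each TSS: offsets -flank_bins..-1 (intergenic,
# upstream) and 1..flank_bins (genic); bins overlapping other genes or other
# genes' bins are removed
.tss_bins <- function(genes, flank = 50000, bin = 1000) {
  flank_bins <- flank %/% bin
  gstr <- as.character(GenomicRanges::strand(genes))
  tss <- genes$tss
  rows <- list()
  for (g in seq_along(genes)) {
    off <- c(-(flank_bins:1), 1:flank_bins)
    if (gstr[g] == "+") {
      start <- ifelse(off < 0, tss[g] + off * bin, tss[g] + (off - 1) * bin)
    } else {
      # mirrored: genic side runs into decreasing coordinates
      start <- ifelse(off < 0, tss[g] - off * bin - bin + 1,
                      tss[g] - off * bin + 1)
    }
    rows[[g]] <- data.frame(gene = g, chrom = as.character(GenomicRanges::seqnames(genes))[g],
                            start = start, end = start + bin - 1, offset = off,
                            stringsAsFactors = FALSE)
  }
  bins_df <- do.call(rbind, rows)
  bins_df <- bins_df[bins_df$start >= 1, , drop = FALSE]
  gr <- GenomicRanges::GRanges(bins_df$chrom, IRanges::IRanges(bins_df$start, bins_df$end))
  # genic bins must lie inside their own gene; intergenic bins outside all genes
  own_within <- vapply(seq_len(nrow(bins_df)), function(i)
    bins_df$start[i] >= GenomicRanges::start(genes[bins_df$gene[i]]) &&
      bins_df$end[i] <= GenomicRanges::end(genes[bins_df$gene[i]]), logical(1))
  any_gene <- IRanges::overlapsAny(gr, genes, ignore.strand = TRUE)
  keep <- ifelse(bins_df$offset > 0, own_within, !any_gene)
  bins_df <- bins_df[keep, , drop = FALSE]
  gr <- gr[keep]
  # drop bins overlapping another gene's bins
  ov <- GenomicRanges::findOverlaps(gr, gr)
  bad <- unique(S4Vectors::queryHits(ov)[bins_df$gene[S4Vectors::queryHits(ov)] !=
                                           bins_df$gene[S4Vectors::subjectHits(ov)]])
  if (length(bad) > 0) bins_df <- bins_df[-bad, , drop = FALSE]
  bins_df
}

#' Strand-resolved mutation density around transcription start sites
#'
#' Splits the +/- \code{flank} around every TSS into \code{bin}-sized
#' intervals (genic side: positive offsets, downstream into the gene body;
#' intergenic side: negative offsets upstream), removes intervals
#' overlapping other genes or other genes' intervals, and reports mutation
#' density per offset separately for mutations whose purine lies on the
#' template ("purine_template", the strand cleared by transcription-coupled
#' repair) and on the coding strand ("purine_coding").
#'
#' @param annotated catalog from \code{\link{annotate_strand}}.
#' @param genes GRanges from \code{\link{gene_models}}.
#' @param flank,bin window and bin sizes in bp (defaults 50 kb, 1 kb).
#' @return data.frame: offset (in bins, negative = upstream), side,
#'   category, count, length, density.
#' @export
tss_profiles <- function(annotated, genes, flank = 50000, bin = 1000) {
  bins_df <- .tss_bins(genes, flank, bin)
  gr_bins <- GenomicRanges::GRanges(bins_df$chrom,
                                    IRanges::IRanges(bins_df$start, bins_df$end))
  sbs <- annotated[annotated$mut_class == "SBS", , drop = FALSE]
  gr_mut <- .catalog_gr(sbs)
  hits <- GenomicRanges::findOverlaps(gr_mut, gr_bins, select = "first")
  gstr <- as.character(GenomicRanges::strand(genes))
  hit_ok <- !is.na(hits)
  mut_gene <- bins_df$gene[hits[hit_ok]]
  mut_off <- bins_df$offset[hits[hit_ok]]
  purine_strand <- ifelse(.pyr_strand(sbs$ref[hit_ok]) == "+", "-", "+")
  template_strand <- ifelse(gstr[mut_gene] == "+", "-", "+")
  category <- ifelse(purine_strand == template_strand, "purine_template", "purine_coding")
  len_by_off <- tapply(rep(bin, nrow(bins_df)), bins_df$offset, sum)
  offs <- sort(unique(bins_df$offset))
  out <- expand.grid(offset = offs, category = c("purine_template", "purine_coding"),
                     stringsAsFactors = FALSE)
  out$side <- ifelse(out$offset > 0, "genic", "intergenic")
  out$count <- mapply(function(o, cat) sum(mut_off == o & category == cat),
                      out$offset, out$category)
  out$length <- as.numeric(len_by_off[as.character(out$offset)])
  out$density <- out$count / out$length
  out[order(out$category, out$offset), c("offset", "side", "category",
                                         "count", "length", "density")]
}

#' Consensus replication timing from multiple cell-line tracks
#'
#' Tracks must share one 1-kb grid. Regions whose cross-track standard
#' deviation exceeds \code{sd_max} are dropped; the rest carry the
#' cross-track mean, binned into the five fixed timing bins.
#'
#' @param tracks list of GRanges with \code{score}, identical ranges.
#' @param sd_max maximal allowed cross-cell-line standard deviation
#'   (default 15).
#' @param breaks timing bin breakpoints (default c(10, 25, 40, 55, 70, 85)).
#' @return GRanges with \code{score} (mean timing) and \code{bin} metadata.
#' @export
build_timing_consensus <- function(tracks, sd_max = 15,
                                   breaks = c(10, 25, 40, 55, 70, 85)) {
  .assert(length(tracks) >= 2, "need >= 2 tracks")
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    .assert(length(t) == length(ref) &&
              all(GenomicRanges::start(t) == GenomicRanges::start(ref)) &&
              all(as.character(GenomicRanges::seqnames(t)) ==
                    as.character(GenomicRanges::seqnames(ref))),
            "tracks are not on a common grid")
  }
  vals <- vapply(tracks, function(t) as.numeric(t$score), numeric(length(ref)))
  mu <- rowMeans(vals)
  sdev <- apply(vals, 1, stats::sd)
  keep <- sdev <= sd_max
  out <- ref[keep]
  out$score <- mu[keep]
  out$sd <- sdev[keep]
  out$bin <- cut(mu[keep], breaks = breaks, include.lowest = TRUE)
  out[!is.na(out$bin)]
}

#' Mutation density as a function of replication timing
#'
#' Length-adjusted densities per timing bin for the transcribed,
#' untranscribed and intergenic categories. The genic opportunity territory
#' (per strand category) is the single-strand gene footprint intersected
#' with the consensus regions of each bin; the intergenic territory is its
#' complement within the consensus.
#'
#' @param annotated catalog from \code{\link{annotate_strand}}.
#' @param consensus GRanges from \code{\link{build_timing_consensus}}.
#' @param genes GRanges from \code{\link{gene_models}}.
#' @return data.frame: bin, category, count, length, density (per Mb).
#' @export
density_by_timing <- function(annotated, consensus, genes) {
  sbs <- annotated[annotated$mut_class == "SBS" &
                     annotated$strand_label %in%
                     c("transcribed", "untranscribed", "intergenic"), , drop = FALSE]
  gr_mut <- .catalog_gr(sbs)
  hit <- GenomicRanges::findOverlaps(gr_mut, consensus, select = "first")
  bins <- levels(consensus$bin)
  genic <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
  out <- list()
  for (b in bins) {
    reg <- consensus[consensus$bin == b]
    gen_len <- sum(GenomicRanges::width(GenomicRanges::intersect(
      GenomicRanges::reduce(reg, ignore.strand = TRUE), genic, ignore.strand = TRUE)))
    tot_len <- sum(GenomicRanges::width(reg))
    int_len <- tot_len - gen_len
    in_bin <- !is.na(hit) & !is.na(consensus$bin[hit]) & consensus$bin[hit] == b
    for (cat in c("transcribed", "untranscribed", "intergenic")) {
      cnt <- sum(in_bin & sbs$strand_label == cat)
      len <- if (cat == "intergenic") int_len else gen_len
      out[[paste(b, cat)]] <- data.frame(
        bin = b, category = cat, count = cnt, length = len,
        density = if (len > 0) cnt / (len / 1e6) else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Consensus replication-fork-direction bins
#'
#' With two tracks, regions whose values differ by more than \code{max_diff}
#' are dropped; the consensus value is the mean. Values are assigned to four
#' bins of width 0.5 on [-1, 1] (negative: reference strand preferentially
#' replicated as lagging strand).
#'
#' @param tracks list of GRanges with \code{score} in [-1, 1], shared grid.
#' @param max_diff maximal allowed between-track difference (default 0.4).
#' @return GRanges with \code{score} (consensus) and \code{bin} metadata.
#' @export
fork_direction_bins <- function(tracks, max_diff = 0.4) {
  .assert(length(tracks) >= 1, "need >= 1 track")
  ref <- tracks[[1]]
  if (length(tracks) >= 2) {
    for (t in tracks[-1]) {
      .assert(length(t) == length(ref) &&
                all(GenomicRanges::start(t) == GenomicRanges::start(ref)),
              "tracks are not on a common grid")
    }
    vals <- vapply(tracks, function(t) as.numeric(t$score), numeric(length(ref)))
    keep <- apply(vals, 1, function(v) max(v) - min(v) <= max_diff)
    out <- ref[keep]
    out$score <- rowMeans(vals)[keep]
  } else {
    out <- ref
  }
  out$bin <- cut(out$score, breaks = c(-1, -0.5, 0, 0.5, 1), include.lowest = TRUE)
  out[!is.na(out$bin)]
}

#' Replication strand bias
#'
#' Per fork-direction bin and substitution class: ratio of mutation counts
#' with the reference pyrimidine on the reference strand versus the
#' reference purine (equal territory, so count ratio equals density ratio).
#' Under purine-lesion conversion boosted on the lagging strand, the ratio
#' rises from lagging-reference bins (negative fork values) to
#' leading-reference bins.
#'
#' @param catalog \code{mutation_catalog} (SBS rows used).
#' @param bins GRanges from \code{\link{fork_direction_bins}}.
#' @return data.frame: bin, class, n_pyr, n_pur, ratio, p.
#' @export
replication_strand_bias <- function(catalog, bins) {
  sbs <- catalog[catalog$mut_class == "SBS", , drop = FALSE]
  hit <- GenomicRanges::findOverlaps(.catalog_gr(sbs), bins, select = "first")
  ok <- !is.na(hit)
  bin_of <- bins$bin[hit[ok]]
  pyr <- .pyr_strand(sbs$ref[ok]) == "+"
  cls <- .pyr_class(sbs$ref[ok], sbs$alt[ok])
  out <- list()
  for (b in levels(bins$bin)) for (cl in c(SBS_CLASSES, "all")) {
    sel <- bin_of == b & (cl == "all" | cls == cl)
    n_pyr <- sum(sel & pyr); n_pur <- sum(sel & !pyr)
    out[[paste(b, cl)]] <- data.frame(
      bin = b, class = cl, n_pyr = n_pyr, n_pur = n_pur,
      ratio = if (n_pur == 0) NA_real_ else n_pyr / n_pur,
      p = if (n_pyr + n_pur == 0) NA_real_ else poisson_pair_test(n_pyr, n_pur))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative mutation density across epigenetic-mark quantiles
#'
#' 1-kb windows with alignability 1 over at least \code{min_align_frac} of
#' their length are kept; window mean mark intensities are normalized to the
#' 1-100 range and split into \code{n_quantiles} near-equal-size groups
#' (ties broken by window order). Per group and strand category the mutation
#' density is reported relative to the category's genome-wide density.
#'
#' @param annotated catalog from \code{\link{annotate_strand}}.
#' @param mark GRanges 1-kb grid with \code{score}.
#' @param alignability GRanges with \code{score} (1 = uniquely mappable).
#' @param categories strand categories to report.
#' @param n_quantiles number of groups (default 5).
#' @param min_align_frac minimal mappable fraction per window (default 0.9).
#' @return data.frame: quantile, category, count, length, density,
#'   relative_density.
#' @export
mark_quantile_density <- function(annotated, mark, alignability,
                                  categories = c("transcribed", "untranscribed",
                                                 "intergenic"),
                                  n_quantiles = 5, min_align_frac = 0.9) {
  win <- mark
  # mappable coverage per window
  alig <- alignability[!is.na(alignability$score) & alignability$score >= 1]
  cov <- GenomicRanges::intersect(GenomicRanges::reduce(win, ignore.strand = TRUE),
                                  GenomicRanges::reduce(alig, ignore.strand = TRUE),
                                  ignore.strand = TRUE)
  ovl <- GenomicRanges::findOverlaps(win, cov)
  covered <- numeric(length(win))
  if (length(ovl) > 0) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      win[S4Vectors::queryHits(ovl)], cov[S4Vectors::subjectHits(ovl)]))
    covered <- as.numeric(tapply(w, factor(S4Vectors::queryHits(ovl),
                                           levels = seq_along(win)), sum))
    covered[is.na(covered)] <- 0
  }
  keep <- covered / GenomicRanges::width(win) >= min_align_frac
  win <- win[keep]
  .assert(length(win) > 0, "no windows pass the alignability filter")
  x <- as.numeric(win$score)
  if (max(x) == min(x)) {
    warning("all mark intensities equal; quantiles are degenerate")
    xn <- rep(50, length(x))
  } else {
    xn <- 1 + 99 * (x - min(x)) / (max(x) - min(x))
  }
  # near-equal-size groups: rank order, ties broken by window order
  ord <- order(xn, seq_along(xn))
  grp <- integer(length(xn))
  grp[ord] <- ceiling(seq_along(ord) / (length(ord) / n_quantiles))
  grp[grp > n_quantiles] <- n_quantiles
  sbs <- annotated[annotated$mut_class == "SBS" &
                     annotated$strand_label %in% categories, , drop = FALSE]
  hit <- GenomicRanges::findOverlaps(.catalog_gr(sbs), win, select = "first")
  ok <- !is.na(hit)
  out <- list()
  for (cat in categories) {
    tot_cnt <- sum(ok & sbs$strand_label == cat)
    tot_len <- sum(GenomicRanges::width(win))
    overall <- tot_cnt / tot_len
    for (q in seq_len(n_quantiles)) {
      wsel <- grp == q
      len <- sum(GenomicRanges::width(win)[wsel])
      cnt <- sum(ok & sbs$strand_label == cat & wsel[hit[ok]])
      dens <- if (len > 0) cnt / len else NA_real_
      out[[paste(cat, q)]] <- data.frame(
        quantile = q, category = cat, count = cnt, length = len, density = dens,
        relative_density = if (overall > 0) dens / overall else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative mutation density per chromatin state
#'
#' Density per state normalized so the length-weighted genome-wide mean
#' equals 1.
#'
#' @param catalog \code{mutation_catalog} (SBS rows used).
#' @param states GRanges with a \code{name} (state label) column.
#' @param alignability optional GRanges; windows of \code{states} are kept
#'   only where the mappable fraction is at least \code{min_align_frac}.
#' @param min_align_frac minimal mappable fraction (default 0.9).
#' @return data.frame: state, count, length, relative_density.
#' @export
chromatin_state_density <- function(catalog, states, alignability = NULL,
                                    min_align_frac = 0.9) {
  if (!is.null(alignability)) {
    alig <- GenomicRanges::reduce(
      alignability[!is.na(alignability$score) & alignability$score >= 1])
    ovl <- GenomicRanges::findOverlaps(states, alig)
    covered <- numeric(length(states))
    if (length(ovl) > 0) {
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        states[S4Vectors::queryHits(ovl)], alig[S4Vectors::subjectHits(ovl)]))
      covered <- as.numeric(tapply(w, factor(S4Vectors::queryHits(ovl),
                                             levels = seq_along(states)), sum))
      covered[is.na(covered)] <- 0
    }
    states <- states[covered / GenomicRanges::width(states) >= min_align_frac]
  }
  sbs <- catalog[catalog$mut_class == "SBS", , drop = FALSE]
  hit <- GenomicRanges::findOverlaps(.catalog_gr(sbs), states, select = "first")
  ok <- !is.na(hit)
  lab <- states$name
  tot_cnt <- sum(ok)
  tot_len <- sum(GenomicRanges::width(states))
  overall <- tot_cnt / tot_len
  out <- lapply(unique(lab), function(s) {
    len <- sum(GenomicRanges::width(states)[lab == s])
    cnt <- sum(ok & lab[hit[ok]] == s)
    data.frame(state = s, count = cnt, length = len,
               relative_density = if (len > 0 && overall > 0)
                 (cnt / len) / overall else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Strand-resolved signature contributions in active and silent genes
#'
#' Builds four sub-catalogs (transcribed/untranscribed strand x
#' transcriptionally active/silent genes), refits the given signatures to
#' each, and reports contribution fractions. Sub-catalogs below
#' \code{min_mutations} get NA.
#'
#' @param annotated catalog from \code{\link{annotate_strand}}.
#' @param genes GRanges from \code{\link{gene_models}}.
#' @param signatures channels x K matrix.
#' @param genome named character vector.
#' @param active_min,silent_max expression thresholds (defaults 2 and 0.05).
#' @param min_mutations minimal sub-catalog size (default 50).
#' @return data.frame: strand, activity, n, signature, fraction.
#' @export
strandwise_signature_contrast <- function(annotated, genes, signatures, genome,
                                          active_min = 2, silent_max = 0.05,
                                          min_mutations = 50) {
  expr <- genes$expression
  genic <- annotated[!is.na(annotated$gene_idx) &
                       annotated$strand_label %in% c("transcribed", "untranscribed"), ]
  activity <- ifelse(expr[genic$gene_idx] > active_min, "active",
                     ifelse(expr[genic$gene_idx] < silent_max, "silent", NA))
  out <- list()
  for (s in c("transcribed", "untranscribed")) for (act in c("active", "silent")) {
    sub <- genic[genic$strand_label == s & !is.na(activity) & activity == act, ,
                 drop = FALSE]
    if (nrow(sub) < min_mutations) {
      warning(sprintf("sub-catalog %s/%s has %d mutations (< %d): NA",
                      s, act, nrow(sub), min_mutations))
      frac <- rep(NA_real_, ncol(signatures))
    } else {
      sub$sample_id <- "pooled"
      m <- build_matrix(mutation_catalog(as.data.frame(sub)), "SBS96", genome)
      frac <- refit_exposures(m, signatures)$fractions[1, ]
    }
    out[[paste(s, act)]] <- data.frame(strand = s, activity = act, n = nrow(sub),
                                       signature = colnames(signatures),
                                       fraction = as.numeric(frac))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
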