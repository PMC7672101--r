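# Somatic mutation catalogs: reading, validation, filtering, VCF round-trip.
#
# A catalog is a plain data.frame (class "mutation_catalog") with one row per
# somatic variant: sample_id, chrom, pos (1-based position of the first REF
# base), ref, alt, vaf, fwd_support, rev_support (alt-allele read counts in
# the two read-pair orientations, F1R2/F2R1-like), mut_class (SBS/DBS/ID).
# Genomic intervals (tracks, genes) are GRanges throughout.

CATALOG_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "vaf",
                  "fwd_support", "rev_support", "mut_class")

.mut_class_of <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1 & na == 1, "SBS",
         ifelse(nr == 2 & na == 2, "DBS",
                ifelse(nr != na, "ID", "MNV")))
}

#' Construct a somatic mutation catalog
#'
#' Validates and classes a data.frame of somatic variants. \code{mut_class}
#' is derived from allele lengths when absent (1/1 = SBS, 2/2 = DBS,
#' length difference = ID).
#'
#' @param df data.frame with columns sample_id, chrom, pos, ref, alt, and
#'   optionally vaf, fwd_support, rev_support, mut_class.
#' @return data.frame of class \code{mutation_catalog}.
#' @export
mutation_catalog <- function(df) {
  .assert(all(c("sample_id", "chrom", "pos", "ref", "alt") %in% names(df)),
          "catalog needs sample_id, chrom, pos, ref, alt columns")
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$chrom <- as.character(df$chrom)
  df$sample_id <- as.character(df$sample_id)
  if (is.null(df$vaf)) df$vaf <- NA_real_
  if (is.null(df$fwd_support)) df$fwd_support <- NA_integer_
  if (is.null(df$rev_support)) df$rev_support <- NA_integer_
  if (is.null(df$mut_class)) df$mut_class <- .mut_class_of(df$ref, df$alt)
  .assert(all(df$ref != df$alt), "ref must differ from alt")
  .assert(all(is.na(df$vaf) | (df$vaf >= 0 & df$vaf <= 1)), "vaf must be in [0, 1]")
  .assert(all(is.na(df$fwd_support) | df$fwd_support >= 0) &&
          all(is.na(df$rev_support) | df$rev_support >= 0),
          "strand support counts must be >= 0")
  .assert(all(df$pos >= 1 & df$pos == round(df$pos)), "pos must be a positive integer")
  extra <- setdiff(names(df), CATALOG_COLS)
  df <- df[, c(CATALOG_COLS, extra)]
  class(df) <- c("mutation_catalog", "data.frame")
  rownames(df) <- NULL
  df
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("mutation_catalog: %d variants, %d sample(s) [%s]\n",
              nrow(x), length(unique(x$sample_id)),
              paste(sprintf("%s=%d", names(table(x$mut_class)),
                            as.integer(table(x$mut_class))), collapse = ", ")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read a somatic mutation catalog from a VCF file
#'
#' Keeps PASS variants (FILTER "PASS" or "."), splits multi-allelic records
#' into biallelic ones, and computes VAF as alt depth / total depth from the
#' AD field when no AF is given. Per-orientation alt-read support is taken
#' from the F1R2 / F2R1 FORMAT fields (second, alt, entry) when present.
#' Truth annotations written by the synthetic generator (INFO keys with an
#' \code{XSIM_} prefix) are carried along as extra columns.
#'
#' @param vcf_path path to a VCF 4.x file.
#' @param sample_id label for the sample; defaults to the (single) genotype
#'   column name.
#' @return \code{mutation_catalog}.
#' @export
read_catalog <- function(vcf_path, sample_id = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(mutation_catalog(data.frame(sample_id = character(), chrom = character(),
                                       pos = integer(), ref = character(),
                                       alt = character())))
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  .assert(!anyNA(pos), "malformed coordinates: non-integer POS in VCF")
  keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  gt_cols <- colnames(v@gt)
  has_gt <- !is.null(gt_cols) && length(gt_cols) > 1
  if (is.null(sample_id)) {
    sample_id <- if (has_gt) gt_cols[2] else sub("\\.vcf$", "", basename(vcf_path))
  }

  get_fmt <- function(key) {
    if (!has_gt) return(NULL)
    out <- tryCatch(vcfR::extract.gt(v, element = key),
                    error = function(e) NULL)
    if (is.null(out)) NULL else out[, 1]
  }
  drop_empty <- function(x) if (!is.null(x) && all(is.na(x))) NULL else x
  ad <- drop_empty(get_fmt("AD"))
  f1r2 <- drop_empty(get_fmt("F1R2"))
  f2r1 <- drop_empty(get_fmt("F2R1"))
  af <- drop_empty(get_fmt("AF"))

  nth_field <- function(x, i) {
    if (is.null(x)) return(rep(NA_character_, nrow(fix)))
    vapply(strsplit(ifelse(is.na(x), "", x), ","), function(p) {
      if (length(p) >= i) p[i] else NA_character_
    }, character(1))
  }

  # expand multi-allelic records; allele index selects the matching AD slot
  alts <- strsplit(fix$ALT, ",")
  n_alt <- lengths(alts)
  row_idx <- rep(seq_len(nrow(fix)), n_alt)
  allele_idx <- unlist(lapply(n_alt, seq_len))

  ref_depth <- suppressWarnings(as.numeric(nth_field(ad, 1)))
  alt_depth_all <- lapply(seq_len(max(n_alt) ), function(i)
    suppressWarnings(as.numeric(nth_field(ad, i + 1))))
  alt_depth <- mapply(function(r, ai) alt_depth_all[[ai]][r], row_idx, allele_idx)

  vaf <- if (!is.null(af)) {
    mapply(function(r, ai) suppressWarnings(as.numeric(nth_field(af, ai)[r])),
           row_idx, allele_idx)
  } else if (!is.null(ad)) {
    tot <- ref_depth[row_idx] + vapply(seq_along(row_idx), function(k) {
      sum(vapply(seq_len(n_alt[row_idx[k]]), function(ai)
        alt_depth_all[[ai]][row_idx[k]], numeric(1)), na.rm = TRUE)
    }, numeric(1))
    ifelse(tot > 0, alt_depth / tot, NA_real_)
  } else {
    stop("VCF is missing both AF and AD fields: cannot compute VAF", call. = FALSE)
  }

  fwd <- suppressWarnings(as.integer(mapply(function(r, ai)
    nth_field(f1r2, ai + 1)[r], row_idx, allele_idx)))
  rev_ <- suppressWarnings(as.integer(mapply(function(r, ai)
    nth_field(f2r1, ai + 1)[r], row_idx, allele_idx)))

  df <- data.frame(sample_id = sample_id,
                   chrom = fix$CHROM[row_idx],
                   pos = pos[row_idx],
                   ref = fix$REF[row_idx],
                   alt = unlist(alts),
                   vaf = as.numeric(vaf),
                   fwd_support = fwd,
                   rev_support = rev_,
                   stringsAsFactors = FALSE)

  # carry synthetic-truth INFO keys (XSIM_*) through as columns
  info <- fix$INFO[row_idx]
  if (any(grepl("XSIM_", info))) {
    keys <- unique(unlist(regmatches(info, gregexpr("XSIM_[A-Za-z0-9_]+(?==)", info, perl = TRUE))))
    for (k in keys) {
      m <- regmatches(info, regexpr(paste0(k, "=[^;]+"), info))
      vals <- rep(NA_character_, length(info))
      vals[grepl(paste0(k, "="), info)] <- sub(paste0(k, "="), "", m)
      df[[tolower(k)]] <- utils::type.convert(vals, as.is = TRUE)
    }
  }

  df <- df[keep[row_idx], , drop = FALSE]
  mutation_catalog(df)
}

#' Write a catalog to a plain-text VCF 4.2 file
#'
#' One genotype column carrying GT:AD:F1R2:F2R1; extra catalog columns are
#' emitted as INFO keys (upper-cased). Coordinates and alleles round-trip
#' bit-exactly through \code{\link{read_catalog}}.
#'
#' @param catalog \code{mutation_catalog} for a single sample.
#' @param path output path.
#' @param contigs optional named vector of contig lengths for the header.
#' @return \code{path}, invisibly.
#' @export
write_catalog_vcf <- function(catalog, path, contigs = NULL) {
  .assert(length(unique(catalog$sample_id)) <= 1,
          "write one sample per VCF file")
  sample <- if (nrow(catalog) > 0) catalog$sample_id[1] else "SAMPLE"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mutscape",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=F1R2,Number=R,Type=Integer,Description=\"F1R2 orientation read counts\">",
           "##FORMAT=<ID=F2R1,Number=R,Type=Integer,Description=\"F2R1 orientation read counts\">")
  extra <- setdiff(names(catalog), CATALOG_COLS)
  hdr <- c(hdr, sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"synthetic truth\">",
                        toupper(extra)))
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- character(0)
  if (nrow(catalog) > 0) {
    depth <- 50L
    alt_d <- ifelse(is.na(catalog$vaf), 25L, as.integer(round(catalog$vaf * depth)))
    ref_d <- depth - alt_d
    fwd <- ifelse(is.na(catalog$fwd_support), pmax(1L, alt_d %/% 2L),
                  as.integer(catalog$fwd_support))
    rev_ <- ifelse(is.na(catalog$rev_support), pmax(0L, alt_d - alt_d %/% 2L),
                   as.integer(catalog$rev_support))
    info <- if (length(extra) == 0) rep(".", nrow(catalog)) else {
      apply(as.data.frame(catalog)[, extra, drop = FALSE], 1, function(r)
        paste(sprintf("%s=%s", toupper(extra), sub("^\\s+", "", as.character(r))), collapse = ";"))
    }
    fmt <- sprintf("0/1:%d,%d:%d,%d:%d,%d", ref_d, alt_d,
                   pmax(0L, ref_d %/% 2L), fwd, pmax(0L, ref_d - ref_d %/% 2L), rev_)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:AD:F1R2:F2R1\t%s",
                    catalog$chrom, catalog$pos, catalog$ref, catalog$alt, info, fmt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filtering policy for somatic variants
#'
#' Named presets mirror three filtering regimes for distinct sample types:
#' \code{"leukemia"} (fresh tissue: at least 1 alt read per orientation,
#' VAF >= 0.05), \code{"ffpe_sarcoma"} (FFPE breast sarcoma: 2 reads per
#' orientation, VAF >= 0.3), \code{"ffpe_rms"} (FFPE rhabdomyosarcoma:
#' 1 read per orientation, VAF >= 0.4).
#'
#' @param preset optional preset name.
#' @param min_reads_per_strand minimum alt reads in each orientation.
#' @param min_vaf minimum variant allele frequency.
#' @param mappability_min minimum mappability score at the variant position
#'   (default 1: anything below fully unique mappability is excluded).
#' @return list of class \code{filter_policy}.
#' @export
filter_policy <- function(preset = NULL, min_reads_per_strand = 1,
                          min_vaf = 0.05, mappability_min = 1) {
  if (!is.null(preset)) {
    p <- switch(preset,
                leukemia = list(1, 0.05),
                ffpe_sarcoma = list(2, 0.3),
                ffpe_rms = list(1, 0.4),
                stop("unknown preset: ", preset))
    min_reads_per_strand <- p[[1]]; min_vaf <- p[[2]]
  }
  .assert(min_reads_per_strand >= 0, "min_reads_per_strand must be >= 0")
  .assert(min_vaf >= 0 && min_vaf <= 1, "min_vaf must be in [0, 1]")
  structure(list(min_reads_per_strand = min_reads_per_strand,
                 min_vaf = min_vaf, mappability_min = mappability_min),
            class = "filter_policy")
}

# value of a score track at single positions; uncovered positions -> NA
.track_value_at <- function(chrom, pos, track) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit <- GenomicRanges::findOverlaps(gr, track, select = "first")
  as.numeric(track$score)[hit]
}

#' Filter a mutation catalog
#'
#' Retains variants passing all of: alt-read support of at least
#' \code{min_reads_per_strand} in each read orientation, VAF at least
#' \code{min_vaf}, mappability score at the position at least
#' \code{mappability_min} (positions not covered by the track fail), and
#' position not overlapping the blacklist. Order is preserved and filtering
#' is idempotent.
#'
#' @param catalog \code{mutation_catalog}.
#' @param policy \code{\link{filter_policy}}.
#' @param mappability GRanges with a \code{score} column, or NULL to skip.
#' @param blacklist GRanges of excluded regions, or NULL to skip.
#' @return filtered \code{mutation_catalog}.
#' @export
apply_filters <- function(catalog, policy, mappability = NULL, blacklist = NULL) {
  if (nrow(catalog) == 0) return(catalog)
  keep <- rep(TRUE, nrow(catalog))
  keep <- keep & !is.na(catalog$fwd_support) &
    catalog$fwd_support >= policy$min_reads_per_strand &
    !is.na(catalog$rev_support) &
    catalog$rev_support >= policy$min_reads_per_strand
  keep <- keep & !is.na(catalog$vaf) & catalog$vaf >= policy$min_vaf
  if (!is.null(mappability)) {
    val <- .track_value_at(catalog$chrom, catalog$pos, mappability)
    keep <- keep & !is.na(val) & val >= policy$mappability_min
  }
  if (!is.null(blacklist)) {
    gr <- GenomicRanges::GRanges(catalog$chrom,
                                 IRanges::IRanges(catalog$pos, catalog$pos))
    keep <- keep & !IRanges::overlapsAny(gr, blacklist)
  }
  out <- catalog[keep, , drop = FALSE]
  class(out) <- class(catalog)
  rownames(out) <- NULL
  out
}

#' Merge adjacent same-sample SBS pairs into doublet substitutions
#'
#' Two single-base substitutions in the same sample at adjacent positions on
#' one chromosome are merged into a single DBS record (flagged in a
#' \code{merged_dbs} column), matching the convention of reporting doublet
#' counts separately from SBS.
#'
#' @param catalog \code{mutation_catalog}.
#' @return catalog with adjacent SBS pairs replaced by DBS rows.
#' @export
merge_adjacent_sbs <- function(catalog) {
  sbs <- which(catalog$mut_class == "SBS")
  if (length(sbs) < 2) {
    catalog$merged_dbs <- rep(FALSE, nrow(catalog))
    return(catalog)
  }
  o <- sbs[order(catalog$sample_id[sbs], catalog$chrom[sbs], catalog$pos[sbs])]
  adj <- which(diff(catalog$pos[o]) == 1 &
                 catalog$chrom[o][-length(o)] == catalog$chrom[o][-1] &
                 catalog$sample_id[o][-length(o)] == catalog$sample_id[o][-1])
  # avoid chaining triples: keep the first pair of any run
  adj <- adj[c(TRUE, diff(adj) > 1)]
  if (length(adj) == 0) {
    catalog$merged_dbs <- rep(FALSE, nrow(catalog))
    return(catalog)
  }
  first <- o[adj]; second <- o[adj + 1]
  dbs <- as.data.frame(catalog[first, , drop = FALSE])
  dbs$ref <- paste0(catalog$ref[first], catalog$ref[second])
  dbs$alt <- paste0(catalog$alt[first], catalog$alt[second])
  dbs$mut_class <- "DBS"
  dbs$vaf <- (catalog$vaf[first] + catalog$vaf[second]) / 2
  dbs$fwd_support <- pmin(catalog$fwd_support[first], catalog$fwd_support[second])
  dbs$rev_support <- pmin(catalog$rev_support[first], catalog$rev_support[second])
  rest <- as.data.frame(catalog[-c(first, second), , drop = FALSE])
  rest$merged_dbs <- FALSE
  dbs$merged_dbs <- TRUE
  out <- rbind(rest, dbs)
  out <- out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
  mutation_catalog(out)
}

#' Read an interval track (BED / bedGraph)
#'
#' Thin wrapper over \code{rtracklayer::import}; bedGraph scores land in the
#' \code{score} metadata column.
#'
#' @param path file path; format inferred from the extension.
#' @param format optional explicit format passed to rtracklayer.
#' @return GRanges.
#' @export
read_track <- function(path, format = NULL) {
  if (is.null(format)) rtracklayer::import(path)
  else rtracklayer::import(path, format = format)
}

#' Construct gene models
#'
#' @param chrom,start,end 1-based inclusive gene spans.
#' @param strand "+" or "-".
#' @param gene_id labels.
#' @param expression per-gene expression (RPKM/FPKM scale), >= 0.
#' @return GRanges with gene_id, expression and tss (transcription start
#'   site: start for "+" genes, end for "-" genes) metadata.
#' @export
gene_models <- function(chrom, start, end, strand, gene_id, expression) {
  .assert(all(expression >= 0), "expression must be >= 0")
  .assert(all(strand %in% c("+", "-")), "strand must be + or -")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  gr$gene_id <- as.character(gene_id)
  gr$expression <- as.numeric(expression)
  gr$tss <- ifelse(strand == "+", start, end)
  gr
}

#' Read gene models from BED (+ optional expression TSV)
#'
#' @param bed_path 6-column BED (chrom, start, end, name, score, strand).
#' @param expression_tsv optional TSV with columns gene_id, expression.
#' @return GRanges as from \code{\link{gene_models}}; genes without an
#'   expression value get NA.
#' @export
read_genes <- function(bed_path, expression_tsv = NULL) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  expr <- rep(NA_real_, length(gr))
  if (!is.null(expression_tsv)) {
    tab <- utils::read.table(expression_tsv, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    expr <- tab$expression[match(gr$name, tab$gene_id)]
  }
  gene_models(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr), GenomicRanges::end(gr),
              as.character(GenomicRanges::strand(gr)),
              gr$name, ifelse(is.na(expr), 0, expr))
}
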