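# Channel classification: SBS96 (pyrimidine-centric trinucleotide), DBS78
# (canonical doublet substitutions), ID83 (indel size / repeat / microhomology
# scheme), and construction of samples x channels count matrices.

PYR <- c("C", "T")
SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical SBS96 channel labels
#'
#' Substitution-major ordering (C>A, C>G, C>T, T>A, T>C, T>G), flanks in
#' A, C, G, T order, e.g. "A[C>A]A" ... "T[T>G]T".
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  out <- character(0)
  for (cl in SBS_CLASSES) {
    ref <- substr(cl, 1, 1)
    for (p5 in DNA_BASES) for (p3 in DNA_BASES)
      out <- c(out, paste0(p5, "[", cl, "]", p3))
  }
  out
}

.DBS_CANONICAL <- list(
  AC = c("CA", "CG", "CT", "GA", "GG", "GT", "TA", "TG", "TT"),
  AT = c("CA", "CC", "CG", "GA", "GC", "TA"),
  CC = c("AA", "AG", "AT", "GA", "GG", "GT", "TA", "TG", "TT"),
  CG = c("AT", "GC", "GT", "TA", "TC", "TT"),
  CT = c("AA", "AC", "AG", "GA", "GC", "GG", "TA", "TC", "TG"),
  GC = c("AA", "AG", "AT", "CA", "CG", "TA"),
  TA = c("AT", "CG", "CT", "GC", "GG", "GT"),
  TC = c("AA", "AG", "AT", "CA", "CG", "CT", "GA", "GG", "GT"),
  TG = c("AA", "AC", "AT", "CA", "CC", "CT", "GA", "GC", "GT"),
  TT = c("AA", "AC", "AG", "CA", "CC", "CG", "GA", "GC", "GG"))

#' Canonical DBS78 channel labels
#' @return character vector of length 78 ("AC>CA", ...).
#' @export
dbs78_channels <- function() {
  unlist(lapply(names(.DBS_CANONICAL), function(r)
    paste0(r, ">", .DBS_CANONICAL[[r]])), use.names = FALSE)
}

#' Canonical ID83 channel labels
#'
#' SigProfiler-style text labels, e.g. "1:Del:C:0" (single C deleted from a
#' homopolymer of length 1) through "5:Del:M:5" (5+ bp deletion with 5+ bp of
#' microhomology). See \code{\link{id83_display}} for COSMIC display names.
#' @return character vector of length 83.
#' @export
id83_channels <- function() {
  c(paste0("1:Del:C:", 0:5), paste0("1:Del:T:", 0:5),
    paste0("1:Ins:C:", 0:5), paste0("1:Ins:T:", 0:5),
    paste0("2:Del:R:", 0:5), paste0("3:Del:R:", 0:5),
    paste0("4:Del:R:", 0:5), paste0("5:Del:R:", 0:5),
    paste0("2:Ins:R:", 0:5), paste0("3:Ins:R:", 0:5),
    paste0("4:Ins:R:", 0:5), paste0("5:Ins:R:", 0:5),
    "2:Del:M:1", "3:Del:M:1", "3:Del:M:2",
    "4:Del:M:1", "4:Del:M:2", "4:Del:M:3",
    paste0("5:Del:M:", 1:5))
}

#' COSMIC display names for the ID83 channels
#'
#' Maps the generator-style labels to human-readable descriptions (event
#' size, deleted/inserted base or repeat, homopolymer length / repeat count /
#' microhomology length).
#' @return data.frame with columns channel, display.
#' @export
id83_display <- function() {
  ch <- id83_channels()
  parts <- strsplit(ch, ":")
  display <- vapply(parts, function(p) {
    size <- p[1]; type <- p[2]; sub <- p[3]; n <- p[4]
    if (sub %in% c("C", "T")) {
      hp <- if (type == "Del") as.integer(n) + 1 else as.integer(n)
      cap <- if (type == "Del") 6L else 5L
      sprintf("1bp %s, %s, homopolymer length %s%s",
              tolower(type), sub, min(hp, cap), if (hp >= cap) "+" else "")
    } else if (sub == "R") {
      cap <- 5L
      sprintf("%s%sbp %s at repeat, %s%s unit(s)", size,
              if (size == "5") "+" else "", tolower(type), n,
              if (as.integer(n) >= cap) "+" else "")
    } else {
      sprintf("%s%sbp del with microhomology length %s%s", size,
              if (size == "5") "+" else "", n,
              if (size == "5" && n == "5") "+" else "")
    }
  }, character(1))
  data.frame(channel = ch, display = display, stringsAsFactors = FALSE)
}

#' Load a reference genome from FASTA
#'
#' @param fasta_path path to an uncompressed or gzipped FASTA.
#' @return named character vector of upper-case chromosome sequences.
#' @export
read_genome <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*", "", names(seqs))
  out
}

.genome_fetch <- function(genome, chrom, start, end) {
  seq <- genome[[chrom]]
  n <- nchar(seq)
  if (any(start < 1) || any(end > n)) return(rep(NA_character_, length(start)))
  substring(seq, start, end)
}

#' Classify single-base substitutions into SBS96 channels
#'
#' Pyrimidine-centric 5'[REF>ALT]3' labels; purine-reference mutations are
#' reverse-complemented onto the pyrimidine strand. Records whose
#' trinucleotide context contains an ambiguous base, or that sit on a contig
#' edge, get NA (excluded from matrices, with a count reported).
#'
#' @param catalog \code{mutation_catalog} rows of class SBS (others -> NA).
#' @param genome named character vector from \code{\link{read_genome}}.
#' @return character vector of channel labels (NA where unclassifiable).
#' @export
classify_sbs96 <- function(catalog, genome) {
  out <- rep(NA_character_, nrow(catalog))
  idx <- which(catalog$mut_class == "SBS")
  if (length(idx) == 0) return(out)
  for (ch in unique(catalog$chrom[idx])) {
    ii <- idx[catalog$chrom[idx] == ch]
    seq <- genome[[ch]]
    if (is.null(seq)) next
    pos <- catalog$pos[ii]
    ok <- pos >= 2 & pos <= nchar(seq) - 1
    ctx <- rep(NA_character_, length(ii))
    ctx[ok] <- substring(seq, pos[ok] - 1, pos[ok] + 1)
    ref <- catalog$ref[ii]; alt <- catalog$alt[ii]
    lab <- rep(NA_character_, length(ii))
    valid <- ok & !is.na(ctx) & !grepl("[^ACGT]", ctx) &
      substr(ctx, 2, 2) == ref & alt %in% DNA_BASES
    pyr <- valid & ref %in% PYR
    pur <- valid & !(ref %in% PYR)
    lab[pyr] <- paste0(substr(ctx[pyr], 1, 1), "[", ref[pyr], ">", alt[pyr], "]",
                       substr(ctx[pyr], 3, 3))
    if (any(pur)) {
      rctx <- revcomp(ctx[pur])
      lab[pur] <- paste0(substr(rctx, 1, 1), "[", .complement_map[ref[pur]], ">",
                         .complement_map[alt[pur]], "]", substr(rctx, 3, 3))
    }
    out[ii] <- lab
  }
  out
}

#' Classify doublet substitutions into DBS78 channels
#'
#' Maps a dinucleotide substitution to the canonical 78-channel set,
#' reverse-complementing ref and alt together when the reference dinucleotide
#' (or, for palindromic references, the alt) is not canonical.
#'
#' @param catalog \code{mutation_catalog} rows of class DBS (others -> NA).
#' @param genome unused for doublets; kept for interface symmetry.
#' @return character vector of channel labels.
#' @export
classify_dbs78 <- function(catalog, genome = NULL) {
  out <- rep(NA_character_, nrow(catalog))
  idx <- which(catalog$mut_class == "DBS")
  for (i in idx) {
    ref <- catalog$ref[i]; alt <- catalog$alt[i]
    if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) next
    if (!(ref %in% names(.DBS_CANONICAL))) {
      ref2 <- revcomp(ref); alt2 <- revcomp(alt)
    } else {
      ref2 <- ref; alt2 <- alt
    }
    if (!(ref2 %in% names(.DBS_CANONICAL))) next
    if (!(alt2 %in% .DBS_CANONICAL[[ref2]])) {
      # palindromic reference: alt orientation is the free choice
      alt2 <- revcomp(alt2)
    }
    if (alt2 %in% .DBS_CANONICAL[[ref2]]) out[i] <- paste0(ref2, ">", alt2)
  }
  out
}

# left-align an indel event: (chrom, pos of first changed base, seq of the
# inserted/deleted bases); shift left while the base preceding the event
# equals its last base
.left_align <- function(genome, chrom, pos, seq, is_del) {
  g <- genome[[chrom]]
  len <- nchar(seq)
  repeat {
    prev <- if (pos >= 2) substring(g, pos - 1, pos - 1) else ""
    last <- substring(seq, len, len)
    if (pos < 2 || prev != last) break
    # for deletions the event must keep matching the reference after a shift
    if (is_del && substring(g, pos - 1, pos + len - 2) !=
        paste0(last, substring(seq, 1, len - 1))) break
    seq <- paste0(prev, substring(seq, 1, len - 1))
    pos <- pos - 1
  }
  list(pos = pos, seq = seq)
}

# number of additional tandem copies of `unit` adjacent to the event
.tandem_copies <- function(g, pos_after_event, unit, pos_before_event) {
  len <- nchar(unit)
  n_right <- 0L
  p <- pos_after_event
  while (p + len - 1 <= nchar(g) && substring(g, p, p + len - 1) == unit) {
    n_right <- n_right + 1L; p <- p + len
  }
  n_left <- 0L
  p <- pos_before_event
  while (p - len + 1 >= 1 && substring(g, p - len + 1, p) == unit) {
    n_left <- n_left + 1L; p <- p - len
  }
  n_left + n_right
}

# microhomology length between the deleted sequence and its flanks
.microhomology <- function(g, del_start, del_seq) {
  len <- nchar(del_seq)
  right_start <- del_start + len
  mh_r <- 0L
  while (mh_r < len - 1 && right_start + mh_r <= nchar(g) &&
         substring(g, right_start + mh_r, right_start + mh_r) ==
         substring(del_seq, mh_r + 1, mh_r + 1)) mh_r <- mh_r + 1L
  mh_l <- 0L
  while (mh_l < len - 1 && del_start - 1 - mh_l >= 1 &&
         substring(g, del_start - 1 - mh_l, del_start - 1 - mh_l) ==
         substring(del_seq, len - mh_l, len - mh_l)) mh_l <- mh_l + 1L
  max(mh_l, mh_r)
}

#' Classify small insertions and deletions into ID83 channels
#'
#' Events are left-aligned against the reference first, so the channel does
#' not depend on the VCF representation within a repeat run. 1-bp events are
#' labelled by the pyrimidine identity (C/T) of the affected base and the
#' reference homopolymer length (run containing/adjacent to the event,
#' capped at 6+ for deletions, 5+ for insertions). Longer events at tandem
#' repeats are labelled by size (2,3,4,5+) and the number of additional
#' repeat units (capped 5+); deletions occurring in zero repeat copies but
#' with flanking sequence identity get microhomology categories.
#'
#' @param catalog \code{mutation_catalog} rows of class ID (others -> NA).
#' @param genome named character vector from \code{\link{read_genome}}.
#' @return character vector of channel labels.
#' @export
classify_id83 <- function(catalog, genome) {
  out <- rep(NA_character_, nrow(catalog))
  idx <- which(catalog$mut_class == "ID")
  for (i in idx) {
    ref <- catalog$ref[i]; alt <- catalog$alt[i]
    chrom <- catalog$chrom[i]
    g <- genome[[chrom]]
    if (is.null(g) || grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) next
    nr <- nchar(ref); na_ <- nchar(alt)
    if (nr == na_) next
    is_del <- nr > na_
    # VCF anchored style: shared leading base(s); strip common prefix
    k <- 0L
    while (k < min(nr, na_) && substring(ref, k + 1, k + 1) == substring(alt, k + 1, k + 1))
      k <- k + 1L
    if (is_del) {
      seq <- substring(ref, k + 1, nr)
      pos <- catalog$pos[i] + k          # first deleted base
    } else {
      seq <- substring(alt, k + 1, na_)
      pos <- catalog$pos[i] + k          # insertion before this reference pos
    }
    len <- nchar(seq)
    if (len == 0) next
    la <- .left_align(genome, chrom, pos, seq, is_del)
    pos <- la$pos; seq <- la$seq
    if (pos < 1 || (is_del && pos + len - 1 > nchar(g))) next
    if (len == 1) {
      base <- seq
      pyr <- if (base %in% PYR) base else unname(.complement_map[base])
      if (is_del) {
        run <- 1L
        p <- pos + 1
        while (p <= nchar(g) && substring(g, p, p) == base) { run <- run + 1L; p <- p + 1 }
        p <- pos - 1
        while (p >= 1 && substring(g, p, p) == base) { run <- run + 1L; p <- p - 1 }
        out[i] <- sprintf("1:Del:%s:%d", pyr, min(run - 1L, 5L))
      } else {
        run <- 0L
        p <- pos
        while (p <= nchar(g) && substring(g, p, p) == base) { run <- run + 1L; p <- p + 1 }
        p <- pos - 1
        while (p >= 1 && substring(g, p, p) == base) { run <- run + 1L; p <- p - 1 }
        out[i] <- sprintf("1:Ins:%s:%d", pyr, min(run, 5L))
      }
    } else {
      size <- min(len, 5L)
      if (is_del) {
        copies <- .tandem_copies(g, pos + len, seq, pos - 1)
        if (copies >= 1) {
          out[i] <- sprintf("%d:Del:R:%d", size, min(copies, 5L))
        } else {
          mh <- .microhomology(g, pos, seq)
          if (mh >= 1) {
            mh_cap <- if (len >= 5) 5L else len - 1L
            out[i] <- sprintf("%d:Del:M:%d", size, min(mh, mh_cap))
          } else {
            out[i] <- sprintf("%d:Del:R:0", size)
          }
        }
      } else {
        copies <- .tandem_copies(g, pos, seq, pos - 1)
        out[i] <- sprintf("%d:Ins:R:%d", size, min(copies, 5L))
      }
    }
  }
  out
}

#' Build a samples x channels count matrix
#'
#' @param catalog \code{mutation_catalog}.
#' @param scheme one of "SBS96", "DBS78", "ID83".
#' @param genome named character vector from \code{\link{read_genome}}.
#' @return \code{channel_matrix}: an integer matrix (samples x channels) with
#'   attributes \code{scheme} and \code{n_excluded} (records of the right
#'   class that could not be classified).
#' @export
build_matrix <- function(catalog, scheme = c("SBS96", "DBS78", "ID83"), genome) {
  scheme <- match.arg(scheme)
  labels <- switch(scheme, SBS96 = sbs96_channels(), DBS78 = dbs78_channels(),
                   ID83 = id83_channels())
  cls <- switch(scheme, SBS96 = "SBS", DBS78 = "DBS", ID83 = "ID")
  ch <- switch(scheme,
               SBS96 = classify_sbs96(catalog, genome),
               DBS78 = classify_dbs78(catalog, genome),
               ID83 = classify_id83(catalog, genome))
  samples <- sort(unique(catalog$sample_id))
  mat <- matrix(0L, nrow = length(samples), ncol = length(labels),
                dimnames = list(samples, labels))
  sel <- which(catalog$mut_class == cls & !is.na(ch))
  if (length(sel) > 0) {
    tab <- table(factor(catalog$sample_id[sel], levels = samples),
                 factor(ch[sel], levels = labels))
    mat[] <- as.integer(tab)
  }
  n_excl <- sum(catalog$mut_class == cls & is.na(ch))
  structure(mat, scheme = scheme, n_excluded = n_excl,
            class = c("channel_matrix", "matrix", "array"))
}

#' @export
print.channel_matrix <- function(x, ...) {
  cat(sprintf("channel_matrix (%s): %d sample(s) x %d channels, %d mutations (%d excluded)\n",
              attr(x, "scheme"), nrow(x), ncol(x), sum(x), attr(x, "n_excluded")))
  invisible(x)
}

#' Convert a channel-count vector or matrix row to a probability profile
#'
#' @param counts nonnegative channel counts (vector, or channel_matrix whose
#'   rows are normalized).
#' @return numeric profile(s) summing to 1.
#' @export
as_profile <- function(counts) {
  if (is.matrix(counts)) {
    rs <- rowSums(counts)
    .assert(all(rs > 0), "cannot normalize an all-zero sample")
    sweep(unclass(counts), 1, rs, "/")
  } else {
    s <- sum(counts)
    .assert(s > 0, "cannot normalize an all-zero profile")
    counts / s
  }
}
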