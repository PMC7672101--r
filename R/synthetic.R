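# Synthetic scenes with known ground truth: genome + genes + expression,
# annotation tracks (replication timing with cross-line noise, fork
# direction, marks, mappability, chromatin states), and mutation catalogs
# generated lesion-first so that strand asymmetries arise mechanistically:
# bulky lesions are placed on purines (either strand), modulated by
# replication timing; lesions on template strands of expressed genes are
# repaired (probability 1/repair_factor of conversion), lesions on the
# lagging strand are converted more often (x replication_factor). Every
# emitted variant carries its latent labels in xsim_* truth columns.

#' Genome specification for the synthetic scene
#'
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_length bp per chromosome (default 5e6; >= 1e5 for
#'   TSS-anchored analyses).
#' @param gc_content fraction in (0, 1).
#' @param n_genes total genes placed (both strands, non-overlapping).
#' @param gene_length_range min/max gene length in bp.
#' @param seed RNG seed.
#' @return list of class \code{genome_spec}.
#' @export
genome_spec <- function(n_chroms = 2, chrom_length = 5e6, gc_content = 0.4,
                        n_genes = 100, gene_length_range = c(5000, 20000),
                        seed = 1) {
  .assert(chrom_length >= 1e5, "chromosomes must be >= 100 kb")
  .assert(gc_content > 0 && gc_content < 1, "gc_content must be in (0, 1)")
  structure(list(n_chroms = n_chroms, chrom_length = chrom_length,
                 gc_content = gc_content, n_genes = n_genes,
                 gene_length_range = gene_length_range, seed = seed),
            class = "genome_spec")
}

#' Generate a synthetic genome with genes and expression
#'
#' Random sequence at the requested GC content; genes are placed
#' sequentially with random intergenic gaps, strands drawn at random
#' (never overlapping, so no both-strand ambiguity), and expression drawn
#' log-uniform over 1e-3..2e4 so all standard expression bins are populated.
#'
#' @param spec \code{\link{genome_spec}}.
#' @return list with \code{genome} (named character vector), \code{genes}
#'   (GRanges from \code{\link{gene_models}}), \code{contigs} (named
#'   lengths).
#' @export
make_genome <- function(spec) {
  with_seed(derive_seed(spec$seed, 1L), {
    L <- spec$chrom_length
    p <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
           spec$gc_content / 2, (1 - spec$gc_content) / 2)
    chroms <- paste0("chr", seq_len(spec$n_chroms))
    genome <- stats::setNames(vapply(chroms, function(ch)
      paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = ""),
      character(1)), chroms)
    # sequential gene packing with random gaps
    per_chrom <- ceiling(spec$n_genes / spec$n_chroms)
    rows <- list()
    gid <- 0L
    for (ch in chroms) {
      pos <- 60000
      placed <- 0L
      while (placed < per_chrom && gid < spec$n_genes) {
        len <- round(runif(1, spec$gene_length_range[1], spec$gene_length_range[2]))
        if (pos + len + 60000 > L) break
        gid <- gid + 1L; placed <- placed + 1L
        rows[[gid]] <- data.frame(chrom = ch, start = pos, end = pos + len - 1,
                                  strand = sample(c("+", "-"), 1),
                                  gene_id = sprintf("g%03d", gid))
        pos <- pos + len + round(runif(1, 40000, 90000))
      }
    }
    .assert(gid >= 2, "infeasible gene packing for this genome size")
    gdf <- do.call(rbind, rows)
    expr <- 10^runif(nrow(gdf), -3, log10(2e4))
    genes <- gene_models(gdf$chrom, gdf$start, gdf$end, gdf$strand,
                         gdf$gene_id, expr)
    list(genome = genome, genes = genes,
         contigs = stats::setNames(rep(L, length(chroms)), chroms))
  })
}

.tile_grid <- function(contigs, bin = 1000) {
  gr <- unlist(GenomicRanges::GRangesList(lapply(names(contigs), function(ch) {
    starts <- seq(1, contigs[[ch]], by = bin)
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts,
                                                pmin(starts + bin - 1, contigs[[ch]])))
  })))
  gr
}

#' Generate synthetic annotation tracks
#'
#' Replication timing is a triangular wave over each chromosome (range
#' 10-85, period \code{timing_period}); per-cell-line tracks add Gaussian
#' noise, with a fraction of regions made strongly discordant to exercise
#' the consensus SD filter. Fork direction is the sign of the timing
#' gradient (+1/-1 plateaus; negative = reference strand replicated as
#' lagging). A mark track tracks the timing surface with noise; chromatin
#' states are timing terciles; mappability is 1 everywhere except a random
#' set of zero-score windows.
#'
#' @param scene list from \code{\link{make_genome}}.
#' @param seed RNG seed.
#' @param n_timing_tracks cell-line count (default 3).
#' @param timing_noise_sd per-line Gaussian noise SD (default 3).
#' @param discordant_frac fraction of regions with injected cross-line
#'   discordance (default 0).
#' @param timing_period triangle-wave period in bp (default 2e6).
#' @param low_mappability_frac fraction of 1-kb windows set to score 0.
#' @return list of GRanges tracks: \code{timing} (list), \code{fork}
#'   (list of 2), \code{mark}, \code{mappability}, \code{states}.
#' @export
make_tracks <- function(scene, seed = 1, n_timing_tracks = 3,
                        timing_noise_sd = 3, discordant_frac = 0,
                        timing_period = 2e6, low_mappability_frac = 0) {
  with_seed(derive_seed(seed, 2L), {
    grid <- .tile_grid(scene$contigs, 1000)
    phase <- ((GenomicRanges::start(grid) - 1) %% timing_period) / timing_period
    surface <- 10 + 75 * (1 - 2 * abs(phase - 0.5))   # triangle in [10, 85]
    slope <- ifelse(phase < 0.5, 1, -1)               # rising = +1
    timing <- lapply(seq_len(n_timing_tracks), function(i) {
      t <- grid
      val <- surface + stats::rnorm(length(grid), 0, timing_noise_sd)
      if (discordant_frac > 0 && i == 1) {
        k <- sample(length(grid), round(discordant_frac * length(grid)))
        val[k] <- val[k] + sample(c(-60, 60), length(k), replace = TRUE)
      }
      t$score <- pmin(pmax(val, 0), 100)
      t
    })
    fork <- lapply(1:2, function(i) { f <- grid; f$score <- slope; f })
    mark <- grid
    mark$score <- surface + stats::rnorm(length(grid), 0, 5)
    mapp <- grid
    mapp$score <- rep(1, length(grid))
    if (low_mappability_frac > 0) {
      k <- sample(length(grid), round(low_mappability_frac * length(grid)))
      mapp$score[k] <- 0
    }
    states <- grid
    terc <- cut(surface, breaks = stats::quantile(surface, c(0, 1/3, 2/3, 1)),
                include.lowest = TRUE,
                labels = c("late_quiet", "mid", "early_active"))
    states$name <- as.character(terc)
    list(timing = timing, fork = fork, mark = mark, mappability = mapp,
         states = states)
  })
}

#' Built-in synthetic signature profiles
#'
#' Deterministic SBS96 profiles with distinct support for generator truth:
#' "sigC_like" concentrates on C>T and C>A channels with strong context
#' preferences (a dominant purine-lesion-like signature), "flat_bg" is a
#' mildly varying background over all channels, "sigT" concentrates on T>A /
#' T>C channels.
#'
#' @param which character vector naming the profiles wanted.
#' @return channels x K matrix, columns sum to 1.
#' @export
example_signatures <- function(which = c("sigC_like", "flat_bg")) {
  ch <- sbs96_channels()
  profs <- list()
  w <- numeric(96)
  cls <- sub(".*\\[(.*)\\].*", "\\1", ch)
  p5 <- substr(ch, 1, 1)
  w[cls == "C>T"] <- 3; w[cls == "C>A"] <- 2
  w[cls == "C>T" & p5 %in% c("A", "G")] <- 6
  profs$sigC_like <- w / sum(w)
  w2 <- 1 + 0.5 * sin(seq_len(96) / 7)
  profs$flat_bg <- w2 / sum(w2)
  w3 <- numeric(96)
  w3[cls == "T>A"] <- 2; w3[cls == "T>C"] <- 3
  w3[cls == "T>A" & p5 == "C"] <- 5
  profs$sigT <- w3 / sum(w3)
  out <- do.call(cbind, profs[which])
  rownames(out) <- ch
  out
}

#' Mutagenesis specification
#'
#' @param n_samples samples to simulate (default 6).
#' @param n_sbs SBS per sample (default 5000).
#' @param signatures channels x K SBS96 profile matrix.
#' @param mixture signature mixing fractions (sums to 1).
#' @param trb_factor conversion reduction for purine lesions on template
#'   strands of expressed genes (default 1 = symmetric).
#' @param trb_expression_coupling relative repair strength per expression
#'   bin in [0, 1] (default full strength in every bin).
#' @param expression_breaks breaks defining the bins for the coupling.
#' @param replication_factor conversion multiplier for purine lesions on
#'   the lagging strand (default 1).
#' @param timing_gradient lesion-density ratio latest/earliest replication
#'   (default 1).
#' @param cluster_fraction fraction of mutations placed in planted short
#'   clusters (default 0).
#' @param cluster_max_gap maximal intra-cluster gap (default 12 bp).
#' @param dbs_fraction,id_fraction additional DBS / indel mutations as a
#'   fraction of n_sbs (defaults 0).
#' @param depth mean sequencing depth for simulated read counts.
#' @param seed RNG seed.
#' @return list of class \code{mutagenesis_spec}.
#' @export
mutagenesis_spec <- function(n_samples = 6, n_sbs = 5000,
                             signatures = example_signatures(),
                             mixture = c(0.83, 0.17),
                             trb_factor = 1,
                             trb_expression_coupling = c(1, 1, 1, 1),
                             expression_breaks = c(0, 0.1, 1, 10, 20000),
                             replication_factor = 1, timing_gradient = 1,
                             cluster_fraction = 0, cluster_max_gap = 12,
                             dbs_fraction = 0, id_fraction = 0,
                             depth = 45, seed = 1) {
  .assert(abs(sum(mixture) - 1) < 1e-9, "mixture must sum to 1")
  .assert(length(mixture) == ncol(signatures), "one fraction per signature")
  .assert(trb_factor > 0 && replication_factor > 0 && timing_gradient > 0,
          "factors must be > 0")
  structure(as.list(environment()), class = "mutagenesis_spec")
}

# mixture profile over the 96 channels
.mixture_profile <- function(spec) {
  as.numeric(spec$signatures %*% spec$mixture)
}

# map each genome position batch to its pyrimidine-centric trinucleotide
# context index and per-context alt distribution from the mixture
.draw_alts <- function(ref_tri, mix96) {
  ch <- sbs96_channels()
  ctx_of <- paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7)) # 5' ref 3'
  alt_of <- substr(ch, 5, 5)
  n <- length(ref_tri)
  mid <- substr(ref_tri, 2, 2)
  pyr_tri <- ifelse(mid %in% PYR, ref_tri, revcomp(ref_tri))
  alt_pyr <- character(n)
  for (ctx in unique(pyr_tri)) {
    sel <- which(pyr_tri == ctx)
    chans <- which(ctx_of == ctx)
    wts <- mix96[chans]
    if (sum(wts) == 0) wts <- rep(1, length(chans))
    alt_pyr[sel] <- alt_of[chans][sample.int(length(chans), length(sel),
                                             replace = TRUE, prob = wts)]
  }
  ifelse(mid %in% PYR, alt_pyr, unname(.complement_map[alt_pyr]))
}

#' Generate a synthetic mutation catalog with latent truth labels
#'
#' Lesion-first simulation (see module header). Returns one catalog holding
#' all samples, with truth columns: \code{xsim_purine_strand} (strand
#' carrying the lesion), \code{xsim_template} (lesion on a template strand
#' of a gene), \code{xsim_lagging} (lesion on the lagging strand),
#' \code{xsim_cluster} (planted cluster id, 0 = none). Alternate alleles
#' follow the channel mixture of the configured signatures conditional on
#' each site's trinucleotide context.
#'
#' @param scene from \code{\link{make_genome}}.
#' @param tracks from \code{\link{make_tracks}}.
#' @param spec \code{\link{mutagenesis_spec}}.
#' @return \code{mutation_catalog} with truth columns.
#' @export
make_catalog <- function(scene, tracks, spec) {
  genome <- scene$genome
  genes <- scene$genes
  grid <- tracks$timing[[1]]
  timing <- vapply(tracks$timing, function(t) as.numeric(t$score),
                   numeric(length(grid)))
  surf <- rowMeans(timing)
  tmin <- min(surf); tmax <- max(surf)
  wgt <- 1 + (spec$timing_gradient - 1) * (surf - tmin) / (tmax - tmin)
  fork <- as.numeric(tracks$fork[[1]]$score)
  grid_chrom <- as.character(GenomicRanges::seqnames(grid))
  grid_start <- GenomicRanges::start(grid)
  grid_width <- GenomicRanges::width(grid)
  # per-gene repair factor from expression-bin coupling
  bins <- cut(genes$expression, breaks = spec$expression_breaks,
              include.lowest = TRUE)
  coupling <- spec$trb_expression_coupling[as.integer(bins)]
  repair <- 1 + (spec$trb_factor - 1) * coupling
  gstr <- as.character(GenomicRanges::strand(genes))
  mix96 <- .mixture_profile(spec)
  max_conv <- max(spec$replication_factor, 1)

  sample_sbs <- function(n_target) {
    got <- list(); n_got <- 0L
    while (n_got < n_target) {
      n_draw <- max(1000L, ceiling((n_target - n_got) * 2.5))
      wi <- sample.int(length(grid), n_draw, replace = TRUE, prob = wgt * grid_width)
      pos <- grid_start[wi] + floor(runif(n_draw) * grid_width[wi])
      chrom <- grid_chrom[wi]
      ok <- pos >= 3 & pos <= scene$contigs[chrom] - 2
      wi <- wi[ok]; pos <- pos[ok]; chrom <- chrom[ok]
      ref <- character(length(pos))
      for (ch in unique(chrom)) {
        s <- chrom == ch
        ref[s] <- substring(genome[[ch]], pos[s], pos[s])
      }
      purine_strand <- ifelse(ref %in% c("A", "G"), "+", "-")
      # gene context
      gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
      hit <- GenomicRanges::findOverlaps(gr, genes, select = "first",
                                         ignore.strand = TRUE)
      in_gene <- !is.na(hit)
      template_strand <- rep(NA_character_, length(pos))
      template_strand[in_gene] <- ifelse(gstr[hit[in_gene]] == "+", "-", "+")
      on_template <- in_gene & purine_strand == template_strand
      rep_fac <- rep(1, length(pos))
      rep_fac[on_template] <- repair[hit[on_template]]
      lagging <- (purine_strand == "+" & fork[wi] < 0) |
        (purine_strand == "-" & fork[wi] > 0)
      conv <- ifelse(lagging, spec$replication_factor, 1) / rep_fac
      acc <- runif(length(pos)) < conv / max_conv
      if (any(acc)) {
        got[[length(got) + 1]] <- data.frame(
          chrom = chrom[acc], pos = pos[acc], ref = ref[acc],
          purine_strand = purine_strand[acc],
          template = on_template[acc], lagging = lagging[acc],
          stringsAsFactors = FALSE)
        n_got <- n_got + sum(acc)
      }
    }
    out <- do.call(rbind, got)
    out[seq_len(n_target), , drop = FALSE]
  }

  tri_at <- function(chrom, pos) {
    out <- character(length(pos))
    for (ch in unique(chrom)) {
      s <- chrom == ch
      out[s] <- substring(genome[[ch]], pos[s] - 1, pos[s] + 1)
    }
    out
  }

  all_rows <- list()
  for (si in seq_len(spec$n_samples)) {
    rows <- with_seed(derive_seed(spec$seed, 100L + si), {
      n_clust <- round(spec$cluster_fraction * spec$n_sbs / 2)
      n_base <- spec$n_sbs - 2 * n_clust
      base <- sample_sbs(n_base + n_clust)
      base$cluster <- 0L
      extra <- NULL
      if (n_clust > 0) {
        base$cluster[(n_base + 1):(n_base + n_clust)] <- seq_len(n_clust)
        seeds <- base[(n_base + 1):(n_base + n_clust), , drop = FALSE]
        gaps <- sample(2:spec$cluster_max_gap, n_clust, replace = TRUE)
        epos <- seeds$pos + gaps
        eref <- tri_at(seeds$chrom, epos)
        keep <- !grepl("[^ACGT]", eref) & epos <= scene$contigs[seeds$chrom] - 2
        extra <- data.frame(chrom = seeds$chrom[keep], pos = epos[keep],
                            ref = substr(eref[keep], 2, 2),
                            purine_strand = NA_character_, template = NA,
                            lagging = NA, cluster = seeds$cluster[keep],
                            stringsAsFactors = FALSE)
        extra$purine_strand <- ifelse(extra$ref %in% c("A", "G"), "+", "-")
        base <- rbind(base, extra)
      }
      tri <- tri_at(base$chrom, base$pos)
      ok <- !grepl("[^ACGT]", tri)
      base <- base[ok, , drop = FALSE]; tri <- tri[ok]
      base$alt <- .draw_alts(tri, mix96)
      base
    })
    # DBS and indel extras
    extras <- with_seed(derive_seed(spec$seed, 300L + si), {
      out <- NULL
      n_dbs <- round(spec$dbs_fraction * spec$n_sbs)
      n_id <- round(spec$id_fraction * spec$n_sbs)
      if (n_dbs > 0) {
        ch <- sample(names(genome), n_dbs, replace = TRUE)
        p <- floor(runif(n_dbs, 10, scene$contigs[ch] - 10))
        ref2 <- vapply(seq_len(n_dbs), function(i)
          substring(genome[[ch[i]]], p[i], p[i] + 1), character(1))
        alt2 <- vapply(ref2, function(r) {
          if (grepl("[^ACGT]", r)) return(NA_character_)
          paste0(sample(setdiff(DNA_BASES, substr(r, 1, 1)), 1),
                 sample(setdiff(DNA_BASES, substr(r, 2, 2)), 1))
        }, character(1))
        keep <- !is.na(alt2) & !grepl("[^ACGT]", ref2)
        out <- rbind(out, data.frame(chrom = ch[keep], pos = p[keep],
                                     ref = ref2[keep], alt = alt2[keep]))
      }
      if (n_id > 0) {
        ch <- sample(names(genome), n_id, replace = TRUE)
        p <- floor(runif(n_id, 10, scene$contigs[ch] - 10))
        is_del <- runif(n_id) < 0.5
        len <- sample(1:3, n_id, replace = TRUE)
        anchor <- vapply(seq_len(n_id), function(i)
          substring(genome[[ch[i]]], p[i], p[i]), character(1))
        refv <- altv <- character(n_id)
        for (i in seq_len(n_id)) {
          if (is_del[i]) {
            refv[i] <- substring(genome[[ch[i]]], p[i], p[i] + len[i])
            altv[i] <- anchor[i]
          } else {
            refv[i] <- anchor[i]
            altv[i] <- paste0(anchor[i],
                              paste(sample(DNA_BASES, len[i], replace = TRUE),
                                    collapse = ""))
          }
        }
        keep <- !grepl("[^ACGT]", refv) & !grepl("[^ACGT]", altv)
        out <- rbind(out, data.frame(chrom = ch[keep], pos = p[keep],
                                     ref = refv[keep], alt = altv[keep]))
      }
      out
    })
    sid <- sprintf("S%02d", si)
    df <- data.frame(sample_id = sid, chrom = rows$chrom, pos = rows$pos,
                     ref = rows$ref, alt = rows$alt,
                     xsim_purine_strand = rows$purine_strand,
                     xsim_template = rows$template,
                     xsim_lagging = rows$lagging,
                     xsim_cluster = rows$cluster,
                     stringsAsFactors = FALSE)
    if (!is.null(extras) && nrow(extras) > 0) {
      ex <- data.frame(sample_id = sid, chrom = extras$chrom, pos = extras$pos,
                       ref = extras$ref, alt = extras$alt,
                       xsim_purine_strand = NA_character_, xsim_template = NA,
                       xsim_lagging = NA, xsim_cluster = 0L,
                       stringsAsFactors = FALSE)
      df <- rbind(df, ex)
    }
    all_rows[[si]] <- df
  }
  df <- do.call(rbind, all_rows)
  # simulated read support
  df <- with_seed(derive_seed(spec$seed, 500L), {
    depth <- pmax(10L, stats::rpois(nrow(df), spec$depth))
    altd <- stats::rbinom(nrow(df), depth, 0.5)
    altd <- pmax(altd, 1L)
    df$vaf <- altd / depth
    df$fwd_support <- stats::rbinom(nrow(df), altd, 0.5)
    df$rev_support <- altd - df$fwd_support
    df
  })
  df <- df[order(df$sample_id, df$chrom, df$pos), , drop = FALSE]
  mutation_catalog(df)
}

#' Sample channel-count matrices from a signature mixture
#'
#' Draws per-sample channel counts from a multinomial over
#' \code{signatures \%*\% fractions[s, ]}; the sampling-level truth for
#' factorization and refitting tests.
#'
#' @param signatures channels x K matrix.
#' @param fractions samples x K mixing fractions (rows sum to 1).
#' @param n_mut mutations per sample (scalar or per-sample vector).
#' @param seed RNG seed.
#' @return \code{channel_matrix} (samples x channels).
#' @export
make_channel_matrix <- function(signatures, fractions, n_mut, seed) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, 1)
  S <- nrow(fractions)
  n_mut <- rep_len(n_mut, S)
  with_seed(derive_seed(seed, 7L), {
    counts <- t(vapply(seq_len(S), function(s) {
      p <- as.numeric(signatures %*% fractions[s, ])
      as.integer(stats::rmultinom(1, n_mut[s], p))
    }, integer(nrow(signatures))))
    dimnames(counts) <- list(sprintf("S%02d", seq_len(S)), rownames(signatures))
    structure(counts, scheme = "SBS96", n_excluded = 0L,
              class = c("channel_matrix", "matrix", "array"))
  })
}

#' SCNA timing simulation specification
#'
#' @param segments \code{\link{scna_segments}} table; the default is eight
#'   clonal events (four copy gains T=3, four cnLOH) on synthetic
#'   coordinates with purities 0.6-1.
#' @param true_fraction true normalized fraction of mutations predating the
#'   event (default 0.75).
#' @param n_mut_per_segment mutations per segment (default 290).
#' @param depth mean sequencing depth (default 45; >= 10).
#' @param seed RNG seed.
#' @return list of class \code{scna_sim_spec}.
#' @export
scna_sim_spec <- function(segments = NULL, true_fraction = 0.75,
                          n_mut_per_segment = 290, depth = 45, seed = 1) {
  .assert(depth >= 10, "depth must be >= 10")
  .assert(true_fraction >= 0 && true_fraction <= 1, "fraction in [0, 1]")
  if (is.null(segments)) {
    segments <- scna_segments(
      chrom = sprintf("chr%d", 1:8),
      start = rep(1, 8), end = rep(5e6, 8),
      total_cn = c(3, 3, 3, 3, 2, 2, 2, 2),
      minor_cn = c(1, 1, 1, 1, 0, 0, 0, 0),
      purity = c(0.95, 0.85, 0.75, 0.65, 1, 0.9, 0.8, 0.7),
      type = c(rep("gain", 4), rep("cnLOH", 4)))
  }
  structure(list(segments = segments, true_fraction = true_fraction,
                 n_mut_per_segment = n_mut_per_segment, depth = depth,
                 seed = seed), class = "scna_sim_spec")
}

#' Simulate mutations in SCNA regions with known epochs
#'
#' Per mutation the epoch is drawn so the expected copy-normalized fraction
#' of pre-SCNA mutations equals \code{true_fraction} (pre-SCNA probability
#' q = f / (T - f (T - 1))); multiplicity follows the epoch (before = 2,
#' after = 1), and read counts are binomial at the expected VAF for the
#' segment's purity and copy number.
#'
#' @param spec \code{\link{scna_sim_spec}}.
#' @return list with \code{catalog} (mutation_catalog with
#'   \code{xsim_epoch} truth), \code{segments}.
#' @export
make_scna_catalog <- function(spec) {
  seg <- spec$segments
  rows <- list()
  for (i in seq_len(nrow(seg))) {
    rows[[i]] <- with_seed(derive_seed(spec$seed, 700L + i), {
      n <- spec$n_mut_per_segment
      T <- seg$total_cn[i]; p <- seg$purity[i]
      f <- spec$true_fraction
      q <- f / (T - f * (T - 1))
      before <- runif(n) < q
      m <- ifelse(before, 2L, 1L)
      ev <- expected_vaf(p, T, m)
      depth <- pmax(10L, stats::rpois(n, spec$depth))
      altd <- stats::rbinom(n, depth, ev)
      pos <- sort(sample(seq(seg$start[i] + 1, seg$end[i] - 1), n))
      ref <- sample(DNA_BASES, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), character(1))
      data.frame(sample_id = "T01", chrom = seg$chrom[i], pos = pos,
                 ref = ref, alt = alt, vaf = altd / depth,
                 fwd_support = pmax(1L, altd %/% 2L),
                 rev_support = pmax(1L, altd - altd %/% 2L),
                 xsim_epoch = ifelse(before, "before", "after"),
                 xsim_segment = i, stringsAsFactors = FALSE)
    })
  }
  list(catalog = mutation_catalog(do.call(rbind, rows)), segments = seg)
}

#' Write a synthetic scene to standard file formats
#'
#' FASTA genome, BED genes, TSV expression, bedGraph tracks, BED chromatin
#' states, and one VCF per sample.
#'
#' @param scene from \code{\link{make_genome}}.
#' @param tracks from \code{\link{make_tracks}} (or NULL to skip).
#' @param catalog \code{mutation_catalog} (or NULL to skip).
#' @param dir output directory (created).
#' @return dir, invisibly.
#' @export
write_scene <- function(scene, tracks = NULL, catalog = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(scene$genome),
                              file.path(dir, "genome.fa"))
  genes_bed <- scene$genes
  genes_bed$name <- genes_bed$gene_id
  genes_bed$score <- 0L
  rtracklayer::export(genes_bed, file.path(dir, "genes.bed"), format = "BED")
  utils::write.table(data.frame(gene_id = scene$genes$gene_id,
                                expression = scene$genes$expression),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(tracks)) {
    for (i in seq_along(tracks$timing))
      rtracklayer::export(tracks$timing[[i]],
                          file.path(dir, sprintf("timing_%d.bedGraph", i)),
                          format = "bedGraph")
    for (i in seq_along(tracks$fork))
      rtracklayer::export(tracks$fork[[i]],
                          file.path(dir, sprintf("fork_%d.bedGraph", i)),
                          format = "bedGraph")
    rtracklayer::export(tracks$mark, file.path(dir, "mark.bedGraph"),
                        format = "bedGraph")
    rtracklayer::export(tracks$mappability, file.path(dir, "mappability.bedGraph"),
                        format = "bedGraph")
    st <- tracks$states
    rtracklayer::export(st, file.path(dir, "states.bed"), format = "BED")
  }
  if (!is.null(catalog)) {
    for (s in unique(catalog$sample_id)) {
      sub <- catalog[catalog$sample_id == s, , drop = FALSE]
      class(sub) <- class(catalog)
      write_catalog_vcf(sub, file.path(dir, paste0(s, ".vcf")),
                        contigs = scene$contigs)
    }
  }
  invisible(dir)
}
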