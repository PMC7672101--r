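# Clustered-mutation analysis: context-preserving Monte Carlo null for
# intermutation distances, sliding-window enrichment scan, and single-linkage
# cluster membership.
#
# The simulator realizes a discrete homogeneous Poisson point process
# conditioned on the per-sample nucleotide-context spectrum: positions are
# uniform over the mappable intervals, and draws are accepted only while
# their context count stays below the target spectrum, so every replicate
# reproduces the observed context histogram exactly. The sampler is
# implemented as its stratified equivalent (for each context, positions are
# drawn uniformly over that context's mappable sites), which has the same
# law as the literal accept/reject loop but runs in vectorized time.

#' Simulation configuration for the clustered-mutation null
#'
#' @param regions GRanges of mappable intervals positions are drawn from.
#' @param spectrum named integer vector: target counts per nucleotide
#'   context (names are contexts, e.g. trinucleotides), or a single unnamed
#'   total for context-free simulation.
#' @param n_sim number of replicates (>= 1).
#' @param max_d maximal recorded inter-mutation distance (>= 2).
#' @param context_mode "tri" (3-bp), "penta" (5-bp) or "none".
#' @param seed RNG seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(regions, spectrum, n_sim = 1000, max_d = 10000,
                       context_mode = c("tri", "penta", "none"), seed) {
  context_mode <- match.arg(context_mode)
  .assert(n_sim >= 1, "n_sim must be >= 1")
  .assert(max_d >= 2, "max_d must be >= 2")
  structure(list(regions = regions, spectrum = spectrum, n_sim = n_sim,
                 max_d = max_d, context_mode = context_mode, seed = seed),
            class = "sim_config")
}

#' Context spectrum of an observed catalog
#'
#' @param catalog \code{mutation_catalog} (SBS rows used).
#' @param genome named character vector.
#' @param context_mode "tri", "penta" or "none".
#' @return named integer vector of reference-context counts (or unnamed
#'   total for "none").
#' @export
context_spectrum <- function(catalog, genome, context_mode = c("tri", "penta", "none")) {
  context_mode <- match.arg(context_mode)
  idx <- which(catalog$mut_class == "SBS")
  if (context_mode == "none") return(length(idx))
  k <- if (context_mode == "tri") 1L else 2L
  chrom <- catalog$chrom[idx]; pos <- catalog$pos[idx]
  ctx <- rep(NA_character_, length(idx))
  for (ch in unique(chrom)) {
    s <- which(chrom == ch)
    L <- nchar(genome[[ch]])
    ok <- s[pos[s] - k >= 1 & pos[s] + k <= L]
    ctx[ok] <- substring(genome[[ch]], pos[ok] - k, pos[ok] + k)
  }
  ctx <- ctx[!is.na(ctx) & !grepl("[^ACGT]", ctx)]
  tab <- table(ctx)
  stats::setNames(as.integer(tab), names(tab))
}

#' Precompute per-context mappable site pools
#'
#' Positions within the regions indexed by their nucleotide context, on a
#' global linear coordinate with chromosomes spaced 1e9 apart (so
#' cross-chromosome pairs can never fall within a distance window). Pass
#' the result to \code{\link{simulate_random_catalog}} to avoid rebuilding
#' it per sample.
#'
#' @param regions GRanges of mappable intervals.
#' @param genome named character vector.
#' @param context_mode "tri", "penta" or "none".
#' @return named list: context -> numeric vector of global positions.
#' @export
context_site_index <- function(regions, genome,
                               context_mode = c("tri", "penta", "none")) {
  .context_site_index(regions, genome, match.arg(context_mode))
}

# per-chromosome integer offsets of mappable positions carrying each context
.context_site_index <- function(regions, genome, context_mode) {
  k <- switch(context_mode, none = 0L, tri = 1L, penta = 2L)
  chroms <- unique(as.character(GenomicRanges::seqnames(regions)))
  sites <- list()   # context -> list of (global position ids)
  # build a global linear coordinate: chromosome base offsets spaced far apart
  # so cross-chromosome pairs can never fall within any distance window
  gap <- 1e9
  chrom_off <- stats::setNames((seq_along(chroms) - 1) * gap, chroms)
  all_pos <- integer(0); all_ctx <- character(0)
  for (ch in chroms) {
    rr <- regions[GenomicRanges::seqnames(regions) == ch]
    seq <- genome[[ch]]
    pos <- unlist(lapply(seq_along(rr), function(i)
      GenomicRanges::start(rr)[i]:GenomicRanges::end(rr)[i]))
    pos <- pos[pos - k >= 1 & pos + k <= nchar(seq)]
    if (context_mode == "none") {
      ctx <- rep("*", length(pos))
    } else {
      ctx <- substring(seq, pos - k, pos + k)
      ok <- !grepl("[^ACGT]", ctx)
      pos <- pos[ok]; ctx <- ctx[ok]
    }
    all_pos <- c(all_pos, pos + chrom_off[ch])
    all_ctx <- c(all_ctx, ctx)
  }
  split(all_pos, all_ctx)
}

#' Simulate random mutation catalogs and their intermutation distances
#'
#' Per replicate: positions are drawn uniformly over the mappable regions,
#' constrained so the per-replicate context histogram equals the target
#' spectrum exactly; positions are sorted and successive intra-chromosome
#' distances up to \code{max_d} recorded.
#'
#' @param config \code{\link{sim_config}}.
#' @param genome named character vector.
#' @param site_index optional precomputed \code{\link{context_site_index}}
#'   (must match the config's regions and context mode); avoids rebuilding
#'   the index when simulating many samples over the same regions.
#' @return list of class \code{sim_result} with \code{distance_counts}
#'   (matrix n_sim x max_d: per replicate, tally of distances d = 1..max_d),
#'   \code{n_mutations}, and \code{positions} of the first replicate (for
#'   inspection).
#' @export
simulate_random_catalog <- function(config, genome, site_index = NULL) {
  spectrum <- config$spectrum
  if (is.null(names(spectrum))) {
    .assert(length(spectrum) == 1, "unnamed spectrum must be a single total")
    names(spectrum) <- "*"
    mode <- "none"
  } else mode <- config$context_mode
  sites <- if (is.null(site_index)) .context_site_index(config$regions, genome, mode)
           else site_index
  missing_ctx <- setdiff(names(spectrum)[spectrum > 0], names(sites))
  if (length(missing_ctx) > 0)
    stop("context(s) unattainable within the mappable regions: ",
         paste(missing_ctx, collapse = ", "), call. = FALSE)
  n_total <- sum(spectrum)
  .assert(n_total >= 1, "spectrum must request at least one mutation")
  D <- config$max_d
  counts <- matrix(0L, nrow = config$n_sim, ncol = D)
  first_positions <- NULL
  with_seed(derive_seed(config$seed, 101L), {
    active <- names(spectrum)[spectrum > 0]
    pools <- sites[active]
    ns <- spectrum[active]
    R <- config$n_sim
    # all replicates drawn in one pass per context (draws are iid, so
    # assigning consecutive blocks to replicates preserves the law)
    pos_all <- unlist(lapply(seq_along(active), function(i) {
      pool <- pools[[i]]
      pool[sample.int(length(pool), ns[i] * R, replace = TRUE)]
    }), use.names = FALSE)
    rep_all <- unlist(lapply(ns, function(n) rep(seq_len(R), each = n)),
                      use.names = FALSE)
    o <- order(rep_all, pos_all)
    pos_s <- pos_all[o]; rep_s <- rep_all[o]
    d <- diff(pos_s)
    keep <- diff(rep_s) == 0L & d >= 1 & d <= D
    ridx <- rep_s[-length(rep_s)][keep]
    counts <- matrix(tabulate((d[keep] - 1) * R + ridx, nbins = R * D),
                     nrow = R, ncol = D)
    first_positions <- pos_s[rep_s == 1L]
  })
  structure(list(distance_counts = counts, n_mutations = n_total,
                 positions = first_positions, max_d = D),
            class = "sim_result")
}

#' Observed successive intra-chromosome distances
#'
#' @param catalog \code{mutation_catalog} (one sample).
#' @param max_d maximal recorded distance.
#' @return integer vector of successive distances <= max_d; cross-chromosome
#'   pairs never contribute.
#' @export
observed_distances <- function(catalog, max_d = 10000) {
  out <- integer(0)
  for (ch in unique(catalog$chrom)) {
    pos <- sort(catalog$pos[catalog$chrom == ch])
    if (length(pos) < 2) next
    d <- diff(pos)
    out <- c(out, d[d <= max_d])
  }
  out
}

#' Sliding-window scan for clustered-mutation enrichment
#'
#' For every 5-bp window (1-bp step) over the distance range, compares the
#' per-sample observed count of intermutation distances in the window with
#' the mean count over Monte Carlo replicates. With multiple samples the
#' per-window test is a two-sided exact Wilcoxon signed-rank on the paired
#' (observed - simulated mean) differences; with one sample the empirical
#' simulation null is used (fraction of replicates at least as extreme,
#' two-sided with the +1 correction). Windows in which no sample has any
#' observed pair carry no information and get p = NA. P-values are
#' Bonferroni-corrected over windows; effect sizes come with a percentile
#' interval from the replicate distribution.
#'
#' @param observed list (one element per sample) of distance vectors from
#'   \code{\link{observed_distances}}.
#' @param sims list (same order) of \code{sim_result}s.
#' @param window window width in bp (default 5).
#' @param step step in bp (default 1).
#' @param range distance range scanned, default c(2, 10000).
#' @return data.frame of class \code{cluster_scan}: window start d, observed
#'   and simulated mean counts (summed over samples), effect size
#'   (observed / simulated mean; NA if the mean is 0), p, p_bonferroni.
#' @export
cluster_scan <- function(observed, sims, window = 5, step = 1,
                         range = c(2, 10000)) {
  n_samp <- length(observed)
  .assert(n_samp == length(sims), "observed and sims must pair up")
  D <- min(vapply(sims, `[[`, numeric(1), "max_d"))
  .assert(range[2] <= D, "simulations do not cover the scan range")
  starts <- seq(range[1], range[2] - window + 1, by = step)
  # per-sample histograms of observed distances and simulated mean counts
  obs_h <- lapply(observed, function(d) tabulate(d[d >= 1], nbins = D))
  sim_mean_h <- lapply(sims, function(s) colMeans(s$distance_counts))
  win_sum <- function(h) {
    cs <- cumsum(c(0, h))
    cs[starts + window] - cs[starts]
  }
  # windows x samples (kept as a matrix even for a single-window scan)
  obs_w <- matrix(vapply(obs_h, win_sum, numeric(length(starts))),
                  nrow = length(starts))
  sim_w <- matrix(vapply(sim_mean_h, win_sum, numeric(length(starts))),
                  nrow = length(starts))
  # per-replicate window totals summed over samples (for the empirical
  # single-sample null and the effect-size percentile CI)
  n_rep <- min(vapply(sims, function(s) nrow(s$distance_counts), numeric(1)))
  C <- sims[[1]]$distance_counts[seq_len(n_rep), , drop = FALSE]
  for (s in sims[-1]) C <- C + s$distance_counts[seq_len(n_rep), , drop = FALSE]
  rep_tot <- C[, starts, drop = FALSE]
  for (k in seq_len(window - 1)) rep_tot <- rep_tot + C[, starts + k, drop = FALSE]
  p <- numeric(length(starts))
  # windows no sample has any observed pair in carry no information
  empty <- rowSums(obs_w) == 0
  if (n_samp >= 2) {
    for (i in seq_along(starts)) {
      d <- obs_w[i, ] - sim_w[i, ]
      p[i] <- if (empty[i]) NA_real_ else wilcoxon_signed_rank_exact(d)
    }
  } else {
    # single sample: empirical two-sided p from the replicate distribution
    for (i in seq_along(starts)) {
      o <- obs_w[i, 1]
      hi <- (sum(rep_tot[, i] >= o) + 1) / (n_rep + 1)
      lo <- (sum(rep_tot[, i] <= o) + 1) / (n_rep + 1)
      p[i] <- if (empty[i]) NA_real_ else min(1, 2 * min(hi, lo))
    }
  }
  obs_tot <- rowSums(obs_w)
  sim_tot <- rowSums(sim_w)
  q <- apply(rep_tot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(d = starts,
                    observed = obs_tot,
                    simulated_mean = sim_tot,
                    effect_size = ifelse(sim_tot > 0, obs_tot / sim_tot, NA_real_),
                    effect_ci_low = ifelse(q[2, ] > 0, obs_tot / q[2, ], NA_real_),
                    effect_ci_high = ifelse(q[1, ] > 0, obs_tot / q[1, ], NA_real_),
                    p = p,
                    p_bonferroni = bonferroni(p, m = length(starts)))
  class(out) <- c("cluster_scan", "data.frame")
  out
}

#' @export
print.cluster_scan <- function(x, ...) {
  sig <- which(!is.na(x$p_bonferroni) & x$p_bonferroni < 0.05)
  cat(sprintf("cluster_scan: %d windows (d = %d..%d); %d significant after Bonferroni",
              nrow(x), min(x$d), max(x$d), length(sig)))
  if (length(sig) > 0)
    cat(sprintf(" (d in %d..%d)", min(x$d[sig]), max(x$d[sig])))
  cat("\n")
  invisible(x)
}

#' Single-linkage mutation clusters
#'
#' Chains consecutive mutations at most \code{max_gap} bp apart into
#' clusters; clusters of size >= 2 are returned with their spans and mean
#' intra-cluster gap.
#'
#' @param catalog \code{mutation_catalog} (one sample).
#' @param max_gap maximal chaining distance (default 16).
#' @return data.frame: cluster id, chrom, start, end, size, mean_gap.
#' @export
cluster_membership <- function(catalog, max_gap = 16) {
  res <- list()
  cid <- 0L
  for (ch in unique(catalog$chrom)) {
    pos <- sort(catalog$pos[catalog$chrom == ch])
    if (length(pos) < 2) next
    grp <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
    for (g in unique(grp)) {
      p <- pos[grp == g]
      if (length(p) < 2) next
      cid <- cid + 1L
      res[[cid]] <- data.frame(cluster = cid, chrom = ch, start = min(p),
                               end = max(p), size = length(p),
                               mean_gap = mean(diff(p)))
    }
  }
  if (length(res) == 0)
    return(data.frame(cluster = integer(), chrom = character(), start = integer(),
                      end = integer(), size = integer(), mean_gap = numeric()))
  do.call(rbind, res)
}
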