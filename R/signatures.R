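# De novo signature extraction and exposure refitting.
#
# NMF minimizes the generalized Kullback-Leibler divergence
#   D(V || WH) = sum_ij [ V_ij log(V_ij / (WH)_ij) - V_ij + (WH)_ij ]
# by multiplicative updates, best of n random restarts. V is channels x
# samples, W channels x K (signatures), H K x samples (exposures).

.kl_div <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

.nmf_once <- function(V, K, max_iter = 2000, tol = 1e-6) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * K, 0.1, 1), n, K)
  H <- matrix(runif(K * m, 0.1, 1), K, m)
  eps <- .Machine$double.eps
  obj <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    # Lee-Seung KL updates
    H <- H * (t(W) %*% (V / WH)) / (colSums(W) + eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / matrix(rowSums(H), n, K, byrow = TRUE)
    if (it %% 10 == 0) {
      new_obj <- .kl_div(V, W %*% H + eps)
      if (is.finite(obj) && obj - new_obj < tol * abs(obj)) { obj <- new_obj; break }
      obj <- new_obj
    }
  }
  list(W = W, H = H, objective = .kl_div(V, W %*% H + eps))
}

#' Extract de novo mutational signatures by KL-NMF
#'
#' Multiplicative-update non-negative matrix factorization of a channel
#' count matrix under the generalized Kullback-Leibler objective, returning
#' the best of \code{n_runs} random initializations. Signature columns are
#' normalized to sum to 1 with exposures rescaled compensatorily, leaving
#' the reconstruction unchanged.
#'
#' @param mat \code{channel_matrix} (samples x channels) or plain matrix.
#' @param K factorization rank (number of signatures).
#' @param n_runs random restarts (default 50).
#' @param seed RNG seed (mandatory; results are deterministic given it).
#' @param max_iter,tol update-loop controls.
#' @return object of class \code{nmf_fit}: list with \code{signatures}
#'   (channels x K, columns sum to 1), \code{exposures} (samples x K,
#'   mutation-count scale), \code{objective} (KL divergence), \code{K},
#'   \code{scheme}.
#' @export
nmf_extract <- function(mat, K, n_runs = 50, seed, max_iter = 2000, tol = 1e-6) {
  .assert(!missing(seed), "seed is mandatory")
  V <- t(unclass(mat))                       # channels x samples
  .assert(all(V >= 0), "matrix must be nonnegative")
  zero <- colSums(V) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) excluded from NMF")
    V <- V[, !zero, drop = FALSE]
  }
  .assert(K >= 1 && K <= min(dim(V)), "K must be in 1..min(samples, channels)")
  best <- NULL
  for (r in seq_len(n_runs)) {
    fit <- with_seed(derive_seed(seed, r), .nmf_once(V, K, max_iter, tol))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  csums <- colSums(best$W)
  W <- sweep(best$W, 2, csums, "/")
  H <- sweep(best$H, 1, csums, "*")
  colnames(W) <- rownames(H) <- paste0("S", seq_len(K))
  rownames(W) <- colnames(mat)
  colnames(H) <- colnames(V)
  structure(list(signatures = W, exposures = t(H), objective = best$objective,
                 K = K, scheme = attr(mat, "scheme")),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("nmf_fit: K = %d signatures over %d channels, %d samples; KL objective = %.4g\n",
              x$K, nrow(x$signatures), nrow(x$exposures), x$objective))
  invisible(x)
}

#' @export
coef.nmf_fit <- function(object, ...) object$exposures

#' @export
fitted.nmf_fit <- function(object, ...) t(object$signatures %*% t(object$exposures))

#' Survey factorization ranks
#'
#' Fits NMF at each candidate rank and reports the best-of-restarts
#' reconstruction RSS, explained variance, and the cophenetic correlation of
#' the restart consensus (how stably samples cluster by their dominant
#' signature across restarts). The preferred rank sits at the inflection of
#' the RSS curve with a high cophenetic coefficient.
#'
#' @param mat channel matrix (samples x channels).
#' @param K_range candidate ranks.
#' @param n_runs restarts per rank.
#' @param seed RNG seed.
#' @return data.frame with columns K, rss, explained_variance, cophenetic.
#' @export
rank_survey <- function(mat, K_range, n_runs = 20, seed) {
  .assert(length(K_range) >= 1, "K_range must be nonempty")
  V <- t(unclass(mat))
  tss <- sum((V - mean(V))^2)
  out <- lapply(K_range, function(K) {
    fits <- lapply(seq_len(n_runs), function(r)
      with_seed(derive_seed(seed, K * 1000 + r), .nmf_once(V, K)))
    objs <- vapply(fits, `[[`, numeric(1), "objective")
    best <- fits[[which.min(objs)]]
    rss <- sum((V - best$W %*% best$H)^2)
    # consensus over restarts: samples co-cluster if they share a dominant signature
    m <- ncol(V)
    cons <- matrix(0, m, m)
    for (f in fits) {
      dom <- apply(f$H, 2, which.max)
      cons <- cons + outer(dom, dom, "==")
    }
    cons <- cons / n_runs
    coph <- if (m >= 3 && stats::sd(as.dist(1 - cons)) > 0) {
      hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
      suppressWarnings(stats::cor(stats::as.dist(1 - cons), stats::cophenetic(hc)))
    } else NA_real_
    data.frame(K = K, rss = rss, explained_variance = 1 - rss / tss,
               cophenetic = coph)
  })
  do.call(rbind, out)
}

#' Cosine similarity between two profiles
#'
#' @param p,q nonnegative numeric vectors on the same channel scheme.
#' @return similarity in [0, 1].
#' @export
cosine_similarity <- function(p, q) {
  .assert(length(p) == length(q), "profiles must share a scheme (equal length)")
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  .assert(np > 0 && nq > 0, "cosine similarity undefined for a zero vector")
  sum(p * q) / (np * nq)
}

.cosine_dist_matrix <- function(P) {
  # P: items x channels
  n <- nrow(P)
  D <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d <- 1 - cosine_similarity(P[i, ], P[j, ])
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Low-dimensional embedding of mutation profiles
#'
#' Embeds profiles by their pairwise cosine distances (1 - similarity),
#' either by classical (Torgerson) multidimensional scaling of the
#' double-centered distance matrix, or by principal components of the
#' distance matrix itself (\code{method = "pca_of_dist"}), a variant used in
#' some published analyses.
#'
#' @param profiles matrix, items x channels (rows are profiles).
#' @param method "cmdscale" (default) or "pca_of_dist".
#' @return matrix items x 2 of coordinates.
#' @export
profile_mds <- function(profiles, method = c("cmdscale", "pca_of_dist")) {
  method <- match.arg(method)
  .assert(nrow(profiles) >= 3, "need at least 3 profiles")
  D <- .cosine_dist_matrix(profiles)
  if (all(D == 0)) {
    warning("all profiles identical; returning zero coordinates")
    return(matrix(0, nrow(profiles), 2, dimnames = list(rownames(profiles), NULL)))
  }
  if (method == "cmdscale") {
    xy <- stats::cmdscale(stats::as.dist(D), k = 2)
    if (ncol(xy) < 2) xy <- cbind(xy, 0)
  } else {
    pc <- stats::prcomp(D)
    xy <- pc$x[, 1:2, drop = FALSE]
  }
  colnames(xy) <- c("dim1", "dim2")
  xy
}

#' Hierarchical clustering of profiles on cosine distance
#'
#' Agglomerative clustering of sample profiles together with optional named
#' reference profiles, on pairwise cosine distance.
#'
#' @param profiles matrix, items x channels.
#' @param references optional matrix of named reference profiles (same
#'   channels) appended before clustering.
#' @param linkage agglomeration method (default "average").
#' @return \code{hclust} object; convert with \code{ape::as.phylo} and
#'   export newick via \code{\link{export_newick}}.
#' @export
hier_cluster <- function(profiles, references = NULL, linkage = "average") {
  P <- profiles
  if (!is.null(references)) P <- rbind(P, references)
  .assert(nrow(P) >= 2, "need at least 2 items")
  stats::hclust(stats::as.dist(.cosine_dist_matrix(P)), method = linkage)
}

#' Export a dendrogram in newick format
#' @param hc \code{hclust} object.
#' @param path output file.
#' @return path, invisibly.
#' @export
export_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Refit signature exposures by non-negative least squares
#'
#' For each sample solves min || m - S x ||^2 subject to x >= 0 (quadratic
#' program with nonnegativity constraints, Lawson-Hanson active set).
#'
#' @param mat channel matrix (samples x channels) or a single count vector.
#' @param signatures channels x K matrix, columns sum to 1.
#' @return list with \code{exposures} (samples x K counts), \code{fractions}
#'   (rows sum to 1 for nonempty samples), \code{residuals} (per-sample
#'   Euclidean residual).
#' @export
refit_exposures <- function(mat, signatures) {
  if (is.null(dim(mat))) mat <- matrix(mat, 1, dimnames = list("sample", names(mat)))
  M <- unclass(mat)
  .assert(ncol(M) == nrow(signatures), "channel dimensions disagree")
  K <- ncol(signatures)
  E <- matrix(0, nrow(M), K, dimnames = list(rownames(M), colnames(signatures)))
  res <- numeric(nrow(M))
  for (s in seq_len(nrow(M))) {
    m <- as.numeric(M[s, ])
    if (sum(m) == 0) next
    sol <- pracma::lsqnonneg(signatures, m)
    E[s, ] <- sol$x
    res[s] <- sqrt(max(sol$resnorm, 0))
  }
  rs <- rowSums(E)
  frac <- E
  frac[rs > 0, ] <- E[rs > 0, , drop = FALSE] / rs[rs > 0]
  list(exposures = E, fractions = frac, residuals = res)
}

#' Bootstrap confidence intervals for signature contributions
#'
#' Resamples a sample's mutations over channels (multinomial at the observed
#' proportions), refits exposures for each replicate, and returns percentile
#' intervals of the per-signature contribution fractions.
#'
#' @param counts channel count vector for one sample.
#' @param signatures channels x K matrix.
#' @param n_boot number of replicates (>= 100).
#' @param seed RNG seed.
#' @param conf_level interval coverage (default 0.95).
#' @return data.frame with signature, estimate, lower, upper.
#' @export
bootstrap_exposures <- function(counts, signatures, n_boot = 1000, seed,
                                conf_level = 0.95) {
  .assert(n_boot >= 100, "n_boot must be >= 100")
  n <- sum(counts)
  .assert(n > 0, "empty sample")
  point <- refit_exposures(counts, signatures)$fractions[1, ]
  probs <- counts / n
  boots <- with_seed(derive_seed(seed, 17L), {
    draws <- stats::rmultinom(n_boot, n, probs)
    t(apply(draws, 2, function(m)
      refit_exposures(stats::setNames(m, names(counts)), signatures)$fractions[1, ]))
  })
  alpha <- (1 - conf_level) / 2
  data.frame(signature = colnames(signatures),
             estimate = as.numeric(point),
             lower = apply(boots, 2, stats::quantile, alpha),
             upper = apply(boots, 2, stats::quantile, 1 - alpha),
             row.names = NULL)
}

#' Match signature columns to reference profiles
#'
#' Greedy-optimal (Hungarian-style via full assignment on small K) matching
#' of extracted signatures to reference signatures by cosine similarity.
#'
#' @param sigs,refs channels x K matrices.
#' @return data.frame with extracted, reference, cosine.
#' @export
match_signatures <- function(sigs, refs) {
  K <- ncol(sigs); R <- ncol(refs)
  sim <- matrix(0, K, R)
  for (i in seq_len(K)) for (j in seq_len(R))
    sim[i, j] <- cosine_similarity(sigs[, i], refs[, j])
  # exact assignment by enumeration for small K, greedy otherwise
  if (K <= 6 && K <= R) {
    perms <- .permutations(seq_len(R), K)
    scores <- apply(perms, 1, function(p) sum(sim[cbind(seq_len(K), p)]))
    best <- perms[which.max(scores), ]
  } else {
    best <- integer(K); taken <- logical(R)
    for (i in order(-apply(sim, 1, max))) {
      j <- order(-sim[i, ])
      j <- j[!taken[j]][1]
      best[i] <- j; taken[j] <- TRUE
    }
  }
  data.frame(extracted = colnames(sigs) %||% paste0("S", seq_len(K)),
             reference = (colnames(refs) %||% paste0("R", seq_len(R)))[best],
             cosine = sim[cbind(seq_len(K), best)],
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.permutations <- function(v, k) {
  if (k == 1) return(matrix(v, ncol = 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- .permutations(v[-i], k - 1)
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}
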