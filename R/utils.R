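#' @importFrom stats cmdscale cophenetic cor dist hclust quantile rbinom rmultinom
#' @importFrom stats rpois runif setNames as.dist sd median
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

.complement_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Plain character reverse complement for short allele/context strings.
#' Heavier sequence work goes through Biostrings; this avoids XString
#' round-trips for single labels in hot loops.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(.complement_map[b])), collapse = "")
  }, character(1))
}

#' Base classification helpers
#'
#' @param b character vector of single bases.
#' @return logical vector.
#' @export
is_purine <- function(b) b %in% c("A", "G")

#' @rdname is_purine
#' @export
is_pyrimidine <- function(b) b %in% c("C", "T")

#' @keywords internal
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Derive a stream-specific seed from a master seed
#'
#' Gives independent generators within one analysis distinct RNG streams;
#' results always fit in 31 bits.
#'
#' @param seed master seed (integer-like).
#' @param stream small positive integer naming the consumer.
#' @return integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L %% 2147483647L + stream * 7919L %% 2147483647L
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state exactly.
#'
#' @param seed seed for the block.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% 2147483647L)
  force(expr)
}
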