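## Small shared helpers: dot-bracket parsing, sequence utilities, seeding.

#' Parse a dot-bracket string into a base-pair table
#'
#' @param structure dot-bracket string (round brackets, no pseudoknots).
#' @return two-column integer matrix of pairs (i, j) with i < j, 1-based.
#' @examples
#' pairTable("((..))")
#' @export
pairTable <- function(structure) {
  chars <- strsplit(structure, "")[[1L]]
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("i", "j")))
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (k in seq_along(chars)) {
    c <- chars[[k]]
    if (c == "(") {
      open <- c(open, k)
    } else if (c == ")") {
      if (!length(open)) stop("unbalanced structure: unmatched ')'")
      pairs_i <- c(pairs_i, open[[length(open)]])
      pairs_j <- c(pairs_j, k)
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced structure: unmatched '('")
  if (length(pairs_i)) {
    o <- order(pairs_i)
    out <- cbind(i = pairs_i[o], j = pairs_j[o])
  }
  out
}

.is_balanced <- function(structure) {
  chars <- strsplit(chartr("[]{}<>", "()()()", structure), "")[[1L]]
  depth <- 0L
  for (c in chars) {
    if (c == "(") depth <- depth + 1L
    else if (c == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
  }
  depth == 0L
}

#' Base-pair distance between two structures
#'
#' Size of the symmetric difference of the two base-pair sets; the standard
#' distance used to compare structures of the same sequence length.
#'
#' @param struct1,struct2 dot-bracket strings of equal length.
#' @return non-negative integer.
#' @export
basePairDistance <- function(struct1, struct2) {
  if (nchar(struct1) != nchar(struct2))
    stop("structures must have equal length")
  p1 <- pairTable(struct1); p2 <- pairTable(struct2)
  k1 <- paste(p1[, 1L], p1[, 2L]); k2 <- paste(p2[, 1L], p2[, 2L])
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' GC fraction of a sequence
#' @param seq RNA sequence string.
#' @return fraction of G and C characters.
#' @export
gcContent <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  mean(chars %in% c("G", "C"))
}

#' Random RNA sequence with a given GC content
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(U) = (1-gc)/2, giving the stated expected GC fraction.
#'
#' @param length sequence length in nt.
#' @param gc target GC fraction.
#' @return RNA sequence string.
#' @export
randomSequence <- function(length, gc = 0.5) {
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

# Stable 31-bit string hash (polynomial rolling hash), used to fan a global
# seed out into per-family sub-seeds independent of input order.
.stable_hash <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Derive a per-item sub-seed from a global seed
#'
#' Combines a global integer seed with a stable hash of an identifier so
#' that per-family results do not depend on the order families are
#' processed in.
#'
#' @param seed global integer seed.
#' @param id character identifier (e.g. family id).
#' @return integer sub-seed below 2^31.
#' @export
subSeed <- function(seed, id) {
  # fold the seed into the hashed string: every intermediate stays well
  # below 2^53, so the arithmetic is exact in doubles
  .stable_hash(paste(seed, id, sep = "/"))
}

# run expr with a temporarily-set RNG seed (restores prior RNG state)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

# normalize raw sequence text: upper case, T -> U
.normalize_rna <- function(x) chartr("T", "U", toupper(x))
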