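## Shuffle-based false discovery rate estimation: a background set is
## produced by shuffling each foreground alignment, positives are counted
## on both, and the FDR is estimated as R/F (refined by the fraction f of
## foreground signal that shuffling fails to destroy).

#' Shuffle an alignment, preserving conservation structure
#'
#' Permutes alignment columns uniformly at random within groups of
#' columns sharing an identical gap pattern. Per-column character
#' multisets are preserved exactly, as is the gap pattern of every row;
#' the co-variation between columns that carries secondary-structure
#' signal is destroyed.
#'
#' @param family an [RNAFamily-class].
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return the shuffled [RNAFamily-class].
#' @export
shuffleAlignment <- function(family, seed = NULL) {
  .with_seed(seed, {
    m <- .row_matrix(family)
    pattern <- apply(m == "-", 2L, function(col)
      paste(as.integer(col), collapse = ""))
    perm <- seq_len(ncol(m))
    for (g in unique(pattern)) {
      idx <- which(pattern == g)
      if (length(idx) > 1L) perm[idx] <- sample(idx)
    }
    m <- m[, perm, drop = FALSE]
    new("RNAFamily",
        species = family@species,
        rows = apply(m, 1L, paste, collapse = ""),
        descriptions = family@descriptions)
  })
}

#' Naive shuffle-based FDR estimate
#'
#' With F positive test results on the real (foreground) data and R on a
#' shuffled background of the same size, the false discovery rate is
#' bounded by R/F (an upper bound when shuffling does not destroy all
#' signal).
#'
#' @param F foreground positives (> 0).
#' @param R background positives (>= 0).
#' @return R/F.
#' @examples
#' estimateFdr(111, 50)  # 0.4505
#' @export
estimateFdr <- function(F, R) {
  if (F <= 0) stop("F must be positive")
  if (R < 0) stop("R must be non-negative")
  R / F
}

#' Refined shuffle-based FDR estimate
#'
#' When a fraction f of the foreground positives remain positive after
#' shuffling, that part of the background positives is not a false
#' discovery, and the estimate refines to (1 - f) R / F.
#'
#' @inheritParams estimateFdr
#' @param f retained-signal fraction in \[0, 1\].
#' @return (1 - f) R / F.
#' @export
refinedFdr <- function(F, R, f) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  (1 - f) * estimateFdr(F, R)
}

#' Fraction of positives retained under shuffling
#'
#' Shuffles each positively scored alignment \code{n_reps} times
#' independently, reruns the test, and returns the fraction of
#' (alignment, repetition) pairs that still score positive.
#'
#' @param positive_families named list of [RNAFamily-class] objects that
#'   scored positive on the real data.
#' @param config a [runConfig()].
#' @param n_reps independent randomisations per alignment (default 20).
#' @param seed integer seed.
#' @return retained fraction f in \[0, 1\].
#' @export
retainedFraction <- function(positive_families, config = runConfig(),
                             n_reps = 20L, seed = NULL) {
  if (!length(positive_families)) stop("empty list of alignments")
  stopifnot(n_reps >= 1L)
  ids <- names(positive_families)
  if (is.null(ids)) ids <- sprintf("fam%03d", seq_along(positive_families))
  hits <- 0L
  for (k in seq_along(positive_families)) {
    for (r in seq_len(n_reps)) {
      sseed <- if (is.null(seed)) NULL
               else subSeed(seed, paste("shuffle", ids[[k]], r))
      shuf <- shuffleAlignment(positive_families[[k]], seed = sseed)
      rep <- runFamily(shuf, config,
                       family_id = paste0(ids[[k]], "_shuf", r))
      if (isPositive(rep)) hits <- hits + 1L
    }
  }
  hits / (n_reps * length(positive_families))
}

#' Does a report contain a positive selection call?
#' @param report a [SelectionReport-class].
#' @return TRUE iff any focal species is labelled positive.
#' @export
isPositive <- function(report) {
  any(reportTable(report)$label == "positive")
}

#' Full shuffle-based FDR analysis of a family collection
#'
#' Runs the selection test on every family (foreground count F), on one
#' shuffle of every family (background count R), and optionally estimates
#' the retained-signal fraction f from repeated shuffles of the
#' foreground positives.
#'
#' @param families named list of [RNAFamily-class] objects.
#' @param config a [runConfig()].
#' @param refine also estimate f and the refined FDR (default TRUE).
#' @param n_reps shuffle repetitions for f.
#' @param seed integer seed.
#' @return an [FdrEstimate-class]; per-family calls are attached as
#'   attribute \code{"calls"}.
#' @export
fdrAnalysis <- function(families, config = runConfig(), refine = TRUE,
                        n_reps = 20L, seed = NULL) {
  ids <- names(families)
  if (is.null(ids)) ids <- sprintf("fam%03d", seq_along(families))
  fg <- logical(length(families))
  bg <- logical(length(families))
  for (k in seq_along(families)) {
    fg[[k]] <- isPositive(runFamily(families[[k]], config, ids[[k]]))
    sseed <- if (is.null(seed)) NULL
             else subSeed(seed, paste("null", ids[[k]]))
    shuf <- shuffleAlignment(families[[k]], seed = sseed)
    bg[[k]] <- isPositive(runFamily(shuf, config,
                                    paste0(ids[[k]], "_null")))
  }
  F <- sum(fg); R <- sum(bg)
  if (F == 0L)
    stop("no foreground positives; the FDR estimate R/F is undefined")
  f <- NA_real_; refined <- NA_real_
  if (refine && F > 0L) {
    f <- retainedFraction(families[fg], config, n_reps = n_reps,
                          seed = seed)
    refined <- refinedFdr(F, R, f)
  }
  out <- new("FdrEstimate", F = as.integer(F), R = as.integer(R), f = f,
             fdr_naive = estimateFdr(F, R), fdr_refined = refined)
  attr(out, "calls") <- data.frame(family_id = ids, foreground = fg,
                                   background = bg)
  out
}
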