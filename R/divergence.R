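## Structural divergence of each species from its family, and the family
## divergence (the median over species).

#' Shared, unique and absent base-pair sets
#'
#' Given the base pairs P of one species (projected to alignment columns)
#' and the pairs Q of the consensus structure, returns the shared pairs
#' W = P n Q, the species-unique pairs X = P \ Q and the absent pairs
#' Y = Q \ P. The three sets partition P u Q.
#'
#' @param P,Q two-column matrices of column pairs (i < j).
#' @return list with matrices \code{W}, \code{X}, \code{Y}.
#' @export
pairSets <- function(P, Q) {
  keyP <- if (NROW(P)) paste(P[, 1L], P[, 2L]) else character(0)
  keyQ <- if (NROW(Q)) paste(Q[, 1L], Q[, 2L]) else character(0)
  pick <- function(M, keys, keep) {
    if (!NROW(M)) return(matrix(integer(0), 0, 2))
    M[keys %in% keep, , drop = FALSE]
  }
  list(W = pick(P, keyP, keyQ),
       X = pick(P, keyP, setdiff(keyP, keyQ)),
       Y = pick(Q, keyQ, setdiff(keyQ, keyP)))
}

#' Structural divergence of one species from the family consensus
#'
#' Compares the species' base-pair probabilities (projected to alignment
#' columns) with the alignment's consensus pair probabilities:
#' \deqn{d_s = \frac{100}{n_{cols}} \Big( \sum_{ij \in W_s} |A_{s,ij} -
#'   B_{ij}| + \sum_{ij \in X_s} A_{s,ij} + \sum_{ij \in Y_s} B_{ij}
#'   \Big)}
#' where W, X, Y are the shared, species-unique and absent pair sets of
#' [pairSets()], A the species matrix and B the alignment matrix. A
#' species folding exactly like the consensus scores 0.
#'
#' @param A_s species pair-probability matrix over alignment columns.
#' @param B consensus (alignment) pair-probability matrix.
#' @param P_s,Q base-pair sets of the species and consensus MFE
#'   structures, as column-pair matrices.
#' @param n_cols number of alignment columns.
#' @return non-negative divergence score.
#' @export
speciesDivergence <- function(A_s, B, P_s, Q, n_cols) {
  if (!all(dim(A_s) == dim(B)))
    stop("pair probability matrices must have equal dimensions")
  sets <- pairSets(P_s, Q)
  take <- function(M, pairs) {
    if (!NROW(pairs)) return(0)
    sum(M[pairs])
  }
  w_term <- if (NROW(sets$W))
    sum(abs(A_s[sets$W] - B[sets$W])) else 0
  x_term <- take(A_s, sets$X)
  y_term <- take(B, sets$Y)
  100 / n_cols * (w_term + x_term + y_term)
}

#' Family divergence
#'
#' The median of the per-species divergence scores; an even number of
#' species yields the mean of the two central values.
#'
#' @param d_values numeric vector of per-species divergences.
#' @return the median.
#' @export
familyDivergence <- function(d_values) {
  if (!length(d_values)) stop("no divergence values")
  median(d_values)
}

# project an ungapped-sequence pair probability matrix (or pair table)
# onto alignment columns using the row's coordinate map
.project_matrix <- function(pp, seq_to_col, n_cols) {
  A <- matrix(0, n_cols, n_cols)
  if (length(pp)) A[seq_to_col, seq_to_col] <- pp
  A
}

.project_pairs <- function(pairs, seq_to_col) {
  if (!NROW(pairs)) return(matrix(integer(0), 0, 2))
  cbind(seq_to_col[pairs[, 1L]], seq_to_col[pairs[, 2L]])
}

#' Per-species and family structural divergence of an alignment
#'
#' Folds every species' ungapped sequence and the alignment itself, and
#' evaluates [speciesDivergence()] for each species plus the family
#' median. Pre-computed ensembles can be supplied to avoid refolding.
#'
#' @param family an [RNAFamily-class].
#' @param seq_ens optional named list of [StructureEnsemble-class]
#'   objects per species (with pair probabilities).
#' @param cons_ens optional [ConsensusEnsemble-class] of the family (with
#'   pair probabilities).
#' @param temperature folding temperature in Celsius.
#' @return list with \code{d_s} (named numeric vector) and \code{d}
#'   (family divergence).
#' @export
familyStructureDivergence <- function(family, seq_ens = NULL,
                                      cons_ens = NULL, temperature = 37) {
  if (is.null(seq_ens)) {
    seqs <- vapply(family@species, function(sp)
      ungappedSequence(family, sp), character(1))
    seq_ens <- setNames(foldMany(seqs, pf = TRUE,
                                 temperature = temperature),
                        family@species)
  }
  if (is.null(cons_ens))
    cons_ens <- consensusFold(family, pf = TRUE,
                              temperature = temperature)
  n <- nCols(family)
  B <- cons_ens@consensus_pair_prob
  if (!length(B)) stop("consensus ensemble lacks pair probabilities")
  Q <- pairTable(cons_ens@consensus_structure)
  d_s <- vapply(family@species, function(sp) {
    map <- coordinateMap(alignedRows(family)[[sp]])
    e <- seq_ens[[sp]]
    A <- .project_matrix(pairProbabilities(e), map$seq_to_col, n)
    P <- .project_pairs(pairTable(e@mfe_structure), map$seq_to_col)
    speciesDivergence(A, B, P, Q, n)
  }, numeric(1))
  list(d_s = d_s, d = familyDivergence(d_s))
}
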