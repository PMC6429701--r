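## Placement-rank model for the structural impact of insertions and
## deletions. An indel of length l is slid over every position of the
## consensus sequence; for each placement the fold constrained to keep all
## unaffected consensus base pairs (psi) is compared with the unconstrained
## fold (phi) by tree edit distance, and the observed placement is ranked
## within this ensemble.

#' Enumerate all placements of an indel along the consensus
#'
#' For a deletion of length \eqn{\ell} from a consensus of length L there
#' are \eqn{L - \ell + 1} placements (the run of deleted bases starts after
#' position j, for j = 0..L-\eqn{\ell}); for an insertion there are L + 1
#' placements of the inserted string. Each placement carries the variant
#' sequence and a folding constraint that enforces every base pair of the
#' consensus MFE structure not affected by the indel (both endpoints
#' surviving, with coordinates remapped; pairs whose remapped span falls
#' below the minimal hairpin span are treated as affected and dropped).
#'
#' @param consensus_seq ungapped background consensus sequence.
#' @param event one-row variant event of kind deletion or insertion (from
#'   [callVariants()]), or a list with \code{kind}, \code{length} and (for
#'   insertions) \code{focal_state}.
#' @param consensus_structure optional dot-bracket MFE structure of
#'   \code{consensus_seq}; folded on the fly when missing.
#' @param temperature folding temperature in Celsius.
#' @return data.frame with one row per placement: \code{j} (indel placed
#'   after this consensus position, 0-based by construction),
#'   \code{sequence} and \code{constraint}.
#' @export
enumerateIndelPlacements <- function(consensus_seq, event,
                                     consensus_structure = NULL,
                                     temperature = 37) {
  consensus_seq <- .normalize_rna(consensus_seq)
  L <- nchar(consensus_seq)
  kind <- as.character(event$kind)
  ell <- as.integer(event$length)
  if (!kind %in% c("deletion", "insertion"))
    stop("event is not an indel")
  if (ell >= L) stop("indel length ", ell,
                     " must be smaller than the consensus length ", L)
  if (is.null(consensus_structure))
    consensus_structure <- foldSequence(consensus_seq, pf = FALSE,
                                        temperature = temperature)@mfe_structure
  pairs <- pairTable(consensus_structure)
  chars <- strsplit(consensus_seq, "")[[1L]]

  if (kind == "deletion") {
    js <- 0:(L - ell)
    rows <- lapply(js, function(j) {
      removed <- seq.int(j + 1L, j + ell)
      seq_j <- paste(chars[-removed], collapse = "")
      keep <- pairs[!(pairs[, 1L] %in% removed) &
                    !(pairs[, 2L] %in% removed), , drop = FALSE]
      if (nrow(keep)) {
        keep[, 1L] <- keep[, 1L] - ifelse(keep[, 1L] > j + ell, ell, 0L)
        keep[, 2L] <- keep[, 2L] - ifelse(keep[, 2L] > j + ell, ell, 0L)
        keep <- keep[keep[, 2L] - keep[, 1L] >= 4L, , drop = FALSE]
      }
      list(j = j, sequence = seq_j,
           constraint = .pairs_to_constraint(keep, L - ell))
    })
  } else {
    ins <- .normalize_rna(as.character(event$focal_state))
    if (nchar(ins) != ell)
      stop("inserted string length does not match event length")
    js <- 0:L
    rows <- lapply(js, function(j) {
      seq_j <- paste0(substr(consensus_seq, 1L, j), ins,
                      substr(consensus_seq, j + 1L, L))
      keep <- pairs
      if (nrow(keep)) {
        keep[, 1L] <- keep[, 1L] + ifelse(keep[, 1L] > j, ell, 0L)
        keep[, 2L] <- keep[, 2L] + ifelse(keep[, 2L] > j, ell, 0L)
      }
      list(j = j, sequence = seq_j,
           constraint = .pairs_to_constraint(keep, L + ell))
    })
  }
  data.frame(
    j = vapply(rows, `[[`, integer(1), "j"),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    constraint = vapply(rows, `[[`, character(1), "constraint")
  )
}

.pairs_to_constraint <- function(pairs, n) {
  cst <- rep(".", n)
  if (NROW(pairs)) {
    cst[pairs[, 1L]] <- "("
    cst[pairs[, 2L]] <- ")"
  }
  paste(cst, collapse = "")
}

#' Fold all indel placements and measure their structural impact
#'
#' For every placement, computes the unconstrained MFE fold
#' \eqn{\phi_j}, the fold \eqn{\psi_j} constrained to retain the
#' unaffected consensus pairs, and their tree edit distance
#' \eqn{\delta(\phi_j, \psi_j)}. Folding is batched into two engine calls.
#'
#' @param placements data.frame from [enumerateIndelPlacements()].
#' @param temperature folding temperature in Celsius.
#' @return the placements with added columns \code{phi}, \code{psi} and
#'   \code{delta}.
#' @export
scoreIndelPlacements <- function(placements, temperature = 37) {
  if (!nrow(placements)) stop("no placements to score")
  phi <- foldMany(placements$sequence, pf = FALSE,
                  temperature = temperature)
  psi <- foldMany(placements$sequence, pf = FALSE,
                  constraints = placements$constraint,
                  temperature = temperature)
  placements$phi <- vapply(phi, function(e) e@mfe_structure, character(1))
  placements$psi <- vapply(psi, function(e) e@mfe_structure, character(1))
  placements$delta <- mapply(structuralDistance, placements$phi,
                             placements$psi, USE.NAMES = FALSE)
  placements
}

#' Rank-based p-value for an observed indel placement
#'
#' Combines a rank statistic with a relative structural impact: with
#' \eqn{r} the rank of the observed placement's \eqn{\delta} among all
#' \eqn{n} placements in decreasing order (ties take the largest,
#' i.e. most conservative, rank), \eqn{p_{rank} = r / n}; with \eqn{l} the
#' consensus length, \eqn{p_{struc} = (4l - \delta)/(4l)} clamped below at
#' \eqn{1/(4l)}. The complete p-value is
#' \eqn{p = \min(1, p_{rank} + p_{struc})}.
#'
#' @param deltas numeric vector of structural distances, one per
#'   placement.
#' @param observed_index index (into \code{deltas}) of the placement
#'   actually observed in the focal sequence.
#' @param l consensus sequence length in nt.
#' @return list with \code{r}, \code{n}, \code{p_rank}, \code{p_struc}
#'   and \code{p_raw}.
#' @export
indelPvalue <- function(deltas, observed_index, l) {
  n <- length(deltas)
  if (!n) stop("empty placement set")
  if (observed_index < 1L || observed_index > n)
    stop("observed_index out of range")
  d_obs <- deltas[[observed_index]]
  r <- sum(deltas >= d_obs)  # decreasing order, ties -> worst rank
  p_rank <- r / n
  p_struc <- max(1 / (4 * l), (4 * l - d_obs) / (4 * l))
  list(r = r, n = n, p_rank = p_rank, p_struc = p_struc,
       p_raw = min(1, p_rank + p_struc))
}
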