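## Background consensus, variant calling, compensatory-substitution removal.

# priority for consensus tie-breaks: A < C < G < U, then other IUPAC codes,
# the gap character loses all ties
.cons_priority <- function(chars) {
  base <- c("A", "C", "G", "U")
  rest <- sort(setdiff(unique(chars), c(base, "-")))
  match(chars, c(base, rest, "-"))
}

#' Build the background consensus profile
#'
#' For every alignment column the consensus character is the modal
#' character among the background sequences (gaps counted as characters;
#' ties broken A < C < G < U with the gap losing all ties), together with
#' the fraction of background sequences agreeing with it. Columns whose
#' agreement reaches the threshold form the well-conserved mask; only
#' variants at well-conserved sites are scored by the test.
#'
#' @param background an [RNAFamily-class] (the alignment with the focal
#'   sequence removed).
#' @param threshold agreement fraction required for a well-conserved site
#'   (default 0.6).
#' @return a [ConsensusProfile-class].
#' @export
buildConsensus <- function(background, threshold = 0.6) {
  stopifnot(threshold >= 0, threshold <= 1)
  m <- .row_matrix(background)
  nb <- nrow(m)
  cons <- character(ncol(m))
  agree <- numeric(ncol(m))
  for (k in seq_len(ncol(m))) {
    tab <- table(m[, k])
    chars <- names(tab)
    counts <- as.integer(tab)
    o <- order(-counts, .cons_priority(chars))
    cons[[k]] <- chars[[o[1L]]]
    agree[[k]] <- counts[[o[1L]]] / nb
  }
  new("ConsensusProfile",
      chars = cons,
      agreement = agree,
      well_conserved = agree >= threshold,
      threshold = threshold,
      n_background = as.integer(nb))
}

#' Ungapped consensus sequence of a profile
#' @param profile a [ConsensusProfile-class].
#' @return the consensus with gap characters removed.
#' @export
consensusSequence <- function(profile) {
  paste(profile@chars[profile@chars != "-"], collapse = "")
}

#' Call variants of a focal sequence against the background consensus
#'
#' Compares the focal row with the consensus column by column. Mismatches
#' where both carry a base are substitution events; runs of focal gaps
#' under consensus bases are merged into one deletion event and runs of
#' focal bases over consensus gaps into one insertion event, each treated
#' as a single event independently of its length. Substitutions are
#' reported only at well-conserved columns; an indel event is reported iff
#' at least one of its columns is well-conserved. Columns gapped in both
#' are no difference and do not interrupt an indel run.
#'
#' @param profile a [ConsensusProfile-class] of the background.
#' @param focal_row the focal species' gapped row (same width).
#' @return data.frame of events ordered by start column, with columns
#'   \code{kind} (substitution/deletion/insertion), \code{col_start},
#'   \code{col_end} (1-based inclusive alignment columns),
#'   \code{consensus_state}, \code{focal_state}, \code{length} and
#'   \code{compensatory} (initialised to \code{FALSE}).
#' @export
callVariants <- function(profile, focal_row) {
  cons <- profile@chars
  foc <- strsplit(focal_row, "")[[1L]]
  if (length(foc) != length(cons))
    stop("focal row length ", length(foc),
         " does not match consensus length ", length(cons))
  wc <- profile@well_conserved

  empty <- data.frame(kind = character(0), col_start = integer(0),
                      col_end = integer(0), consensus_state = character(0),
                      focal_state = character(0), length = integer(0),
                      compensatory = logical(0))
  events <- empty

  add_event <- function(kind, cols, cstate, fstate, len) {
    rbind(events, data.frame(
      kind = kind, col_start = cols[1L], col_end = cols[2L],
      consensus_state = cstate, focal_state = fstate,
      length = len, compensatory = FALSE))
  }

  # substitutions at well-conserved columns
  sub_cols <- which(cons != foc & cons != "-" & foc != "-" & wc)
  for (k in sub_cols)
    events <- add_event("substitution", c(k, k), cons[[k]], foc[[k]], 1L)

  # merged indel runs; both-gap columns are invisible and do not break runs
  run_kind <- NULL; run_cols <- integer(0)
  flush_run <- function() {
    if (is.null(run_kind)) return()
    cols <- range(run_cols)
    cs <- cons[run_cols]; fs <- foc[run_cols]
    if (run_kind == "deletion") {
      len <- sum(cs != "-")
      cstate <- paste(cs[cs != "-"], collapse = "")
      fstate <- strrep("-", len)
    } else {
      len <- sum(fs != "-")
      fstate <- paste(fs[fs != "-"], collapse = "")
      cstate <- strrep("-", len)
    }
    if (any(wc[run_cols]))
      events <<- add_event(run_kind, cols, cstate, fstate, len)
  }
  for (k in seq_along(cons)) {
    type <- if (cons[[k]] == "-" && foc[[k]] == "-") "ghost"
            else if (foc[[k]] == "-" && cons[[k]] != "-") "deletion"
            else if (foc[[k]] != "-" && cons[[k]] == "-") "insertion"
            else "none"
    if (type == "ghost") next
    if (type %in% c("deletion", "insertion")) {
      if (!is.null(run_kind) && run_kind == type) {
        run_cols <- c(run_cols, k)
      } else {
        flush_run()
        run_kind <- type; run_cols <- k
      }
    } else {
      flush_run()
      run_kind <- NULL; run_cols <- integer(0)
    }
  }
  flush_run()

  if (!nrow(events)) return(empty)
  events <- events[order(events$col_start, events$kind), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Flag compensatory substitutions
#'
#' A substitution at alignment column i is compensatory when i is paired
#' with some column j in the focal sequence's MFE structure (projected to
#' alignment columns) and columns (i, j) also pair in the background
#' consensus MFE structure: the base pair survived the sequence change, so
#' the site carries no structural signal and is excluded from scoring.
#' Both members of a doubly substituted pair are flagged.
#'
#' @param events variant table from [callVariants()].
#' @param focal_ens [StructureEnsemble-class] of the ungapped focal
#'   sequence.
#' @param background_cons [ConsensusEnsemble-class] of the background
#'   alignment.
#' @param focal_map [coordinateMap()] of the focal row, relating its
#'   ungapped positions to alignment columns.
#' @return the events with the \code{compensatory} flag filled in; scored
#'   events are those with \code{compensatory == FALSE}.
#' @export
flagCompensatory <- function(events, focal_ens, background_cons,
                             focal_map) {
  if (!nrow(events)) return(events)
  fp <- pairTable(focal_ens@mfe_structure)
  cp <- pairTable(background_cons@consensus_structure)
  if (!nrow(fp) || !nrow(cp)) return(events)
  # project focal pairs to alignment columns
  fp_cols <- cbind(focal_map$seq_to_col[fp[, 1L]],
                   focal_map$seq_to_col[fp[, 2L]])
  cons_keys <- paste(cp[, 1L], cp[, 2L])
  partner <- integer(0)
  partner_of <- function(col) {
    hit <- which(fp_cols[, 1L] == col | fp_cols[, 2L] == col)
    if (!length(hit)) return(NA_integer_)
    r <- fp_cols[hit[1L], ]
    if (r[1L] == col) r[2L] else r[1L]
  }
  for (r in which(events$kind == "substitution")) {
    i <- events$col_start[[r]]
    j <- partner_of(i)
    if (!is.na(j) &&
        paste(min(i, j), max(i, j)) %in% cons_keys)
      events$compensatory[[r]] <- TRUE
  }
  events
}
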