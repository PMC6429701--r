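## The per-family test loop: every species in turn is the focal sequence,
## scored against the consensus of the remaining background alignment.

#' Run the selection test on one ortholog family
#'
#' For each species as focal sequence: removes it from the alignment,
#' builds the background consensus and the well-conserved mask, calls
#' substitution and merged-indel variants of the focal row against the
#' consensus, removes compensatory substitutions (pairs preserved in both
#' the focal and the background consensus MFE structures), computes
#' empirical substitution impact p-values and placement-rank indel
#' p-values, corrects each set for multiple testing, and aggregates them
#' into the combined selection score \eqn{2 s + s'}. Per-species
#' structural divergences and the family divergence (their median) are
#' computed from the full alignment, and each focal sequence is labelled
#' positive / conserved / intermediate, or high_divergence when the
#' family is structurally heterogeneous.
#'
#' Runs are deterministic for a fixed \code{config$seed}: the seed is
#' combined with the family id and focal species by stable hashing, so
#' results do not depend on processing order.
#'
#' @param family an [RNAFamily-class] with at least three species.
#' @param config a [runConfig()] list.
#' @param family_id identifier used in the report and in seed fan-out.
#' @return a [SelectionReport-class].
#' @examples
#' \dontrun{
#' fam <- RNAFamily(c(a = "GGGCGCAAAGCGCCC", b = "GGGCGCAAAGCGCCC",
#'                    c = "GGGCGCAAAGCGCCC"))
#' rep <- runFamily(fam, runConfig(null_samples = 20, seed = 1))
#' reportTable(rep)
#' }
#' @export
runFamily <- function(family, config = runConfig(),
                      family_id = "family") {
  stopifnot(is(family, "RNAFamily"))
  if (nSpecies(family) < config$min_species)
    stop("family too small: need at least ", config$min_species,
         " species")
  tC <- config$temperature
  rows <- alignedRows(family)
  n_cols <- nCols(family)

  # fold every species' ungapped sequence once (ensemble quantities are
  # reused for divergence and for the compensatory filter)
  seqs <- vapply(family@species, function(sp)
    ungappedSequence(family, sp), character(1))
  if (any(!nzchar(seqs)))
    stop("species with all-gap row cannot be folded")
  seq_ens <- setNames(foldMany(seqs, pf = TRUE, temperature = tC),
                      family@species)
  cons_full <- consensusFold(family, pf = TRUE, temperature = tC)
  div <- familyStructureDivergence(family, seq_ens = seq_ens,
                                   cons_ens = cons_full,
                                   temperature = tC)

  res <- vector("list", nSpecies(family))
  events_out <- list()
  for (idx in seq_along(family@species)) {
    sp <- family@species[[idx]]
    background <- removeFocal(family, sp)
    profile <- buildConsensus(background, config$conservation_threshold)
    events <- callVariants(profile, rows[[sp]])
    focal_map <- coordinateMap(rows[[sp]])
    cons_map <- coordinateMap(paste(profile@chars, collapse = ""))
    zbar <- consensusSequence(profile)

    n_comp <- 0L
    sub_p <- numeric(0)
    indel_p <- numeric(0)
    if (nrow(events) && nzchar(zbar)) {
      if (any(events$kind == "substitution")) {
        bg_cons <- consensusFold(background, pf = FALSE,
                                 temperature = tC)
        events <- flagCompensatory(events, seq_ens[[sp]], bg_cons,
                                   focal_map)
        n_comp <- sum(events$compensatory)
      }
      sub_events <- events[events$kind == "substitution" &
                           !events$compensatory, , drop = FALSE]
      if (nrow(sub_events)) {
        subs <- data.frame(
          pos = cons_map$col_to_seq[sub_events$col_start],
          from = sub_events$consensus_state,
          to = sub_events$focal_state)
        seed <- if (is.null(config$seed)) NULL
                else subSeed(config$seed, paste(family_id, sp))
        scored <- .with_seed(seed,
          .scoreSubstitutions(zbar, subs, N = config$null_samples,
                              min_region = config$min_region,
                              temperature = tC))
        sub_p <- vapply(scored, `[[`, numeric(1), "p_raw")
        sub_events$p_raw <- sub_p
        sub_events$d_obs <- vapply(scored, `[[`, numeric(1), "d_obs")
      }

      indel_events <- events[events$kind != "substitution", ,
                             drop = FALSE]
      if (nrow(indel_events)) {
        zbar_struct <- foldSequence(zbar, pf = FALSE,
                                    temperature = tC)@mfe_structure
        indel_p <- vapply(seq_len(nrow(indel_events)), function(r) {
          ev <- indel_events[r, ]
          if (ev$length >= nchar(zbar)) return(1)
          pl <- enumerateIndelPlacements(zbar, ev, zbar_struct,
                                         temperature = tC)
          pl <- scoreIndelPlacements(pl, temperature = tC)
          j_obs <- .observed_placement(ev, profile, cons_map)
          indelPvalue(pl$delta, match(j_obs, pl$j),
                      nchar(zbar))$p_raw
        }, numeric(1))
        indel_events$p_raw <- indel_p
      }
      events_out[[sp]] <- list(
        substitutions = if (nrow(sub_events)) sub_events else NULL,
        indels = if (nrow(indel_events)) indel_events else NULL,
        n_compensatory = n_comp)
    }

    if (config$joint_correction) {
      joint <- correctPvalues(c(sub_p, indel_p), config$correction)
      sub_c <- joint[seq_along(sub_p)]
      indel_c <- joint[seq_along(indel_p) + length(sub_p)]
    } else {
      sub_c <- correctPvalues(sub_p, config$correction)
      indel_c <- correctPvalues(indel_p, config$correction)
    }
    s_sub <- substitutionScore(sub_c, config$log_base)
    s_indel <- substitutionScore(indel_c, config$log_base)
    res[[idx]] <- data.frame(
      family_id = family_id,
      species = sp,
      n_subst = length(sub_p),
      n_indel = length(indel_p),
      n_compensatory = n_comp,
      s_sub = s_sub,
      s_indel = s_indel,
      sss_score = sssScore(s_sub, s_indel),
      d_s = unname(div$d_s[[sp]]))
  }

  table <- do.call(rbind, res)
  table$family_d <- div$d
  table$label <- vapply(table$sss_score, classifySelection, character(1),
                        d = div$d,
                        positive_cutoff = config$positive_cutoff,
                        conserved_cutoff = config$conserved_cutoff,
                        divergence_cutoff = config$divergence_cutoff)
  new("SelectionReport", table = table, family_d = div$d,
      events = events_out, metadata = .run_metadata(config))
}

# consensus-sequence position after which the observed indel sits
.observed_placement <- function(event, profile, cons_map) {
  if (event$kind == "deletion") {
    cols <- seq.int(event$col_start, event$col_end)
    del_pos <- cons_map$col_to_seq[cols]
    del_pos <- del_pos[!is.na(del_pos)]
    min(del_pos) - 1L
  } else {
    before <- seq_len(event$col_start - 1L)
    if (!length(before)) 0L
    else sum(profile@chars[before] != "-")
  }
}
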