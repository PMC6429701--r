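## Orthologous local-structure blocks: long RNAs are decomposed into
## locally stable structures per species, the most stable non-overlapping
## ones are kept, and structures whose start positions coincide across
## species (projected to alignment columns) are grouped into blocks.

#' Greedy selection of non-overlapping local structures
#'
#' Keeps the most energetically stable candidates first (ties to the
#' leftmost), discarding any candidate overlapping one already kept, so
#' the chosen structures can co-exist on the molecule. Candidates with
#' fewer than \code{min_pairs} base pairs are dropped beforehand as
#' noise.
#'
#' @param candidates data.frame from [localFold()].
#' @param min_pairs minimum base pairs per candidate (default 3).
#' @return subset of \code{candidates}, ordered by start.
#' @export
selectNonoverlapping <- function(candidates, min_pairs = 3L) {
  if (!nrow(candidates)) return(candidates)
  cand <- candidates[candidates$n_pairs >= min_pairs, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$energy, cand$start), , drop = FALSE]
  kept <- logical(nrow(cand))
  ends <- integer(0); starts <- integer(0)
  for (k in seq_len(nrow(cand))) {
    s <- cand$start[[k]]; e <- cand$end[[k]]
    if (!any(s <= ends & e >= starts)) {
      kept[[k]] <- TRUE
      starts <- c(starts, s); ends <- c(ends, e)
    }
  }
  out <- cand[kept, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Group per-species local structures into orthologous blocks
#'
#' Structures from different species are considered orthologous when
#' their start positions, projected to alignment columns, differ by at
#' most \code{tolerance} times the length of the shorter structure.
#' Groups are formed by single linkage over this criterion (so block
#' membership is independent of species order); groups represented in
#' fewer than \code{min_species} species are dropped, and each species
#' contributes at most one (its most stable) structure per block.
#'
#' @param per_species named list (by species) of selected-structure
#'   data.frames from [selectNonoverlapping()].
#' @param family the [RNAFamily-class] the structures were derived from.
#' @param tolerance maximal start shift as a fraction of the shorter
#'   member's length (default 0.3); the boundary is inclusive.
#' @param min_species minimum species per block (default 3).
#' @return list of blocks; each block is a data.frame with columns
#'   \code{species}, \code{start}, \code{end} (1-based sequence
#'   coordinates), \code{start_col}, \code{end_col}, \code{energy},
#'   \code{structure}.
#' @export
matchBlocks <- function(per_species, family, tolerance = 0.3,
                        min_species = 3L) {
  stopifnot(tolerance >= 0, tolerance <= 1)
  missing <- setdiff(names(per_species), speciesNames(family))
  if (length(missing))
    stop("species absent from alignment: ",
         paste(missing, collapse = ", "))
  nodes <- list()
  for (sp in names(per_species)) {
    df <- per_species[[sp]]
    if (is.null(df) || !nrow(df)) next
    map <- coordinateMap(alignedRows(family)[[sp]])
    for (k in seq_len(nrow(df))) {
      nodes[[length(nodes) + 1L]] <- data.frame(
        species = sp, start = df$start[[k]], end = df$end[[k]],
        start_col = map$seq_to_col[[df$start[[k]]]],
        end_col = map$seq_to_col[[df$end[[k]]]],
        energy = df$energy[[k]], structure = df$structure[[k]])
    }
  }
  if (!length(nodes)) return(list())
  nodes <- do.call(rbind, nodes)
  n <- nrow(nodes)

  # single-linkage union-find on the start-column criterion
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  len <- nodes$end - nodes$start + 1L
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      if (nodes$species[[a]] == nodes$species[[b]]) next
      lim <- tolerance * min(len[[a]], len[[b]])
      if (abs(nodes$start_col[[a]] - nodes$start_col[[b]]) <= lim) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[[rb]] <- ra
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  blocks <- list()
  for (g in unique(comp)) {
    members <- nodes[comp == g, , drop = FALSE]
    # one structure per species: the most stable
    members <- members[order(members$energy), , drop = FALSE]
    members <- members[!duplicated(members$species), , drop = FALSE]
    if (nrow(members) < min_species) next
    members <- members[order(members$species), , drop = FALSE]
    rownames(members) <- NULL
    blocks[[length(blocks) + 1L]] <- members
  }
  # stable order: by leftmost start column
  if (length(blocks)) {
    o <- order(vapply(blocks, function(b) min(b$start_col), integer(1)))
    blocks <- blocks[o]
  }
  names(blocks) <- sprintf("block%03d", seq_along(blocks))
  blocks
}

#' Extract local structures and assemble blocks for a family
#'
#' Convenience pipeline: [localFold()] per species on the ungapped
#' sequences, [selectNonoverlapping()], then [matchBlocks()].
#'
#' @param family an [RNAFamily-class].
#' @param config a [runConfig()] (uses \code{max_span},
#'   \code{block_tolerance}, \code{min_species}, \code{temperature}).
#' @return list of blocks as in [matchBlocks()].
#' @export
familyBlocks <- function(family, config = runConfig()) {
  per_species <- lapply(setNames(nm = speciesNames(family)),
                        function(sp) {
    cand <- localFold(ungappedSequence(family, sp),
                      max_span = config$max_span,
                      temperature = config$temperature)
    selectNonoverlapping(cand)
  })
  matchBlocks(per_species, family, tolerance = config$block_tolerance,
              min_species = config$min_species)
}

#' Score the blocks of a family with the selection test
#'
#' For each block the member species' alignment slice (from the leftmost
#' member start column to the rightmost member end column) is extracted
#' as a sub-family and screened: its family divergence is computed, and
#' blocks within the divergence cutoff are scored with [runFamily()]
#' (high-divergence blocks are flagged and excluded from selection
#' calls).
#'
#' @param blocks list of blocks from [matchBlocks()] or
#'   [familyBlocks()].
#' @param family the parent [RNAFamily-class].
#' @param config a [runConfig()].
#' @param family_id identifier prefix for block reports.
#' @return named list, one entry per block, each with elements
#'   \code{block} (the member table), \code{report} (a
#'   [SelectionReport-class]) and \code{high_divergence} (flag).
#' @export
screenBlocks <- function(blocks, family, config = runConfig(),
                         family_id = "family") {
  rows <- alignedRows(family)
  out <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    from <- min(b$start_col); to <- max(b$end_col)
    sub_rows <- substr(rows[b$species], from, to)
    sub_fam <- RNAFamily(sub_rows, species = b$species,
                         min_species = config$min_species)
    id <- sprintf("%s_%s", family_id, names(blocks)[[k]])
    rep <- runFamily(sub_fam, config, family_id = id)
    out[[k]] <- list(block = b, report = rep,
                     high_divergence =
                       rep@family_d > config$divergence_cutoff)
  }
  setNames(out, names(blocks))
}
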