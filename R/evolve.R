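## Synthetic RNA evolution under negative, neutral (random) and positive
## selection regimes, used to benchmark the selection test. Families are
## evolved from a common ancestor by proposing random point substitutions
## and accepting them by a Metropolis rule on a regime-specific objective.

#' Abstract shape (level 5) of a secondary structure
#'
#' The most abstract coarse-graining of a structure: unpaired stretches
#' are dropped and every run of nested helices (regardless of bulges and
#' interior loops between them) collapses to a single bracket pair, so
#' only the arrangement of helices remains. A hairpin gives \code{"[]"},
#' a cloverleaf \code{"[[][][]]"}, an unstructured sequence the empty
#' shape \code{""}.
#'
#' @param structure dot-bracket string.
#' @return abstract shape string over \code{[} and \code{]}.
#' @examples
#' shape5("(((...)))")  # "[]"
#' @export
shape5 <- function(structure) {
  if (!.is_balanced(structure)) stop("unbalanced structure")
  pairs <- pairTable(structure)
  if (!nrow(pairs)) return("")
  n <- nchar(structure)
  partner <- integer(n)
  partner[pairs[, 1L]] <- pairs[, 2L]
  partner[pairs[, 2L]] <- pairs[, 1L]
  render <- function(from, to) {
    # concatenated shapes of the helices rooted in [from, to]
    out <- ""
    k <- from
    while (k <= to) {
      if (partner[k] > k) {
        out <- paste0(out, render_helix(k, partner[k]))
        k <- partner[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    out
  }
  render_helix <- function(i, j) {
    # collapse the chain of nested helices starting at pair (i, j):
    # descend while exactly one helix lies directly inside
    repeat {
      k <- i + 1L
      first <- 0L
      count <- 0L
      while (k <= j - 1L) {
        if (partner[k] > k) {
          count <- count + 1L
          if (count == 1L) first <- k
          k <- partner[k] + 1L
        } else k <- k + 1L
      }
      if (count == 1L) {
        i <- first; j <- partner[first]
      } else {
        return(paste0("[", render(i + 1L, j - 1L), "]"))
      }
    }
  }
  render(1L, n)
}

#' Alignment cost between two abstract shapes
#'
#' Unit-cost edit distance over the bracket tokens of the two shape
#' strings (insert, delete or substitute one bracket).
#'
#' @param shape_a,shape_b shape strings as returned by [shape5()].
#' @return non-negative integer cost, 0 iff the shapes are equal.
#' @examples
#' shapeDistance("[]", "[[][][]]")  # 6
#' @export
shapeDistance <- function(shape_a, shape_b) {
  as.integer(drop(utils::adist(shape_a, shape_b)))
}

#' Energy-stabilising penalty
#'
#' Keeps evolved sequences from degenerating into unstructured ones: the
#' penalty is zero as long as the current sequence's MFE is at most half
#' the ancestral MFE (both negative), and grows linearly beyond.
#'
#' @param mfe_a ancestral MFE, kcal/mol.
#' @param mfe_m current-sequence MFE, kcal/mol.
#' @return \eqn{\max(0, mfe_m - mfe_a / 2)}.
#' @examples
#' epsilonStabilizer(-40, -30)  # 0
#' epsilonStabilizer(-40, -15)  # 5
#' @export
epsilonStabilizer <- function(mfe_a, mfe_m) {
  max(0, mfe_m - mfe_a / 2)
}

#' Objective value of an evolving sequence under a selection regime
#'
#' \describe{
#'   \item{neg}{\eqn{1000 (\Delta_{centroid}(a, m) + \epsilon(a, m))}:
#'     any centroid base-pair divergence from the ancestor, or loss of
#'     stability, is penalised hard (negative selection).}
#'   \item{rand}{constant 0: every proposal is accepted (free drift).}
#'   \item{pos}{\eqn{gibbs(m) + 50\, \Delta_{shape5}(target, m) + 1000\,
#'     \epsilon(a, m)}: pressure towards the target abstract shape
#'     (default cloverleaf \code{"[[][][]]"}) and towards a stable
#'     ensemble.}
#' }
#'
#' @param mode \code{"neg"}, \code{"rand"} or \code{"pos"}.
#' @param ancestor_ens [StructureEnsemble-class] of the ancestor (with
#'   centroid).
#' @param current_ens [StructureEnsemble-class] of the current sequence.
#' @param target_shape level-5 target shape for \code{pos} mode.
#' @param weight_hard weight of the hard penalties (default 1000).
#' @param weight_shape weight of the shape penalty (default 50).
#' @return objective value (lower is fitter).
#' @export
objectiveValue <- function(mode, ancestor_ens, current_ens,
                           target_shape = "[[][][]]",
                           weight_hard = 1000, weight_shape = 50) {
  mode <- match.arg(mode, c("neg", "rand", "pos"))
  if (mode == "rand") return(0)
  eps <- epsilonStabilizer(ancestor_ens@mfe_energy,
                           current_ens@mfe_energy)
  if (mode == "neg") {
    delta <- basePairDistance(ancestor_ens@centroid_structure,
                              current_ens@centroid_structure)
    return(weight_hard * (delta + eps))
  }
  current_ens@ensemble_free_energy +
    weight_shape * shapeDistance(target_shape,
                                 shape5(current_ens@centroid_structure)) +
    weight_hard * eps
}

#' Evolve a sequence until n substitutions are accepted
#'
#' Proposes uniform single-base substitutions (uniform position, uniform
#' replacement base) and accepts each with Metropolis probability
#' \eqn{\min(1, e^{-(f' - f)/T})} on the regime objective, until exactly
#' \code{n_accepted} proposals have been accepted. \code{rand} mode
#' accepts every proposal and needs no folding.
#'
#' @param ancestor ancestral RNA sequence.
#' @param mode selection regime, see [objectiveValue()].
#' @param n_accepted number of accepted substitutions.
#' @param acceptance_temperature Metropolis temperature T (default 1).
#' @param target_shape level-5 target shape for \code{pos} mode.
#' @param temperature folding temperature in Celsius.
#' @param max_proposals abort guard (default 1e6).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param cache optional environment memoising objective values by
#'   proposal sequence; the objectives depend only on the ancestor and
#'   the proposal, so a cache may be shared between branches evolved
#'   from the same ancestor.
#' @return list with \code{sequence} (the evolved sequence),
#'   \code{n_proposals} and \code{n_accepted}.
#' @export
evolveSequence <- function(ancestor, mode, n_accepted = 5L,
                           acceptance_temperature = 1,
                           target_shape = "[[][][]]",
                           temperature = 37, max_proposals = 1e6,
                           seed = NULL, cache = NULL) {
  mode <- match.arg(mode, c("neg", "rand", "pos"))
  stopifnot(n_accepted >= 1L)
  .with_seed(seed, {
    current <- .normalize_rna(ancestor)
    bases <- c("A", "C", "G", "U")
    accepted <- 0L
    proposals <- 0L
    if (mode != "rand") {
      anc_ens <- foldSequence(current, pf = TRUE, bpp = FALSE,
                              temperature = temperature)
      f_cur <- objectiveValue(mode, anc_ens, anc_ens, target_shape)
    }
    propose <- function() {
      pos <- sample.int(nchar(current), 1L)
      old <- substr(current, pos, pos)
      newb <- sample(setdiff(bases, old), 1L)
      prop <- current
      substr(prop, pos, pos) <- newb
      prop
    }
    if (mode == "rand") {
      while (accepted < n_accepted) {
        current <- propose()
        proposals <- proposals + 1L
        accepted <- accepted + 1L
      }
      return(list(sequence = current, n_proposals = proposals,
                  n_accepted = accepted))
    }
    # a run of rejections leaves the current sequence unchanged, so
    # proposals can be folded speculatively in batches (only the first
    # acceptance invalidates the rest of a batch). Objective values are
    # memoised by proposal sequence - they depend on nothing else - so
    # long rejection runs, which revisit the same single mutants (only
    # 3L exist), pay for each distinct fold once.
    batch <- 4L
    fcache <- if (is.null(cache)) new.env(parent = emptyenv()) else cache
    while (accepted < n_accepted) {
      if (proposals > max_proposals)
        stop("no convergence after ", max_proposals, " proposals")
      props <- vapply(seq_len(batch), function(i) propose(), character(1))
      miss <- props[!vapply(props, function(p)
        !is.null(fcache[[p]]), logical(1))]
      miss <- unique(miss)
      if (length(miss)) {
        enss <- foldMany(miss, pf = TRUE, bpp = FALSE,
                         temperature = temperature)
        for (k in seq_along(miss))
          fcache[[miss[[k]]]] <- objectiveValue(mode, anc_ens,
                                                enss[[k]], target_shape)
      }
      hit <- FALSE
      for (k in seq_len(batch)) {
        proposals <- proposals + 1L
        f_new <- fcache[[props[[k]]]]
        if (f_new <= f_cur ||
            runif(1) < exp(-(f_new - f_cur) / acceptance_temperature)) {
          current <- props[[k]]
          f_cur <- f_new
          accepted <- accepted + 1L
          hit <- TRUE
          break
        }
      }
      batch <- if (hit) 4L else min(32L, batch * 2L)
    }
    list(sequence = current, n_proposals = proposals,
         n_accepted = accepted)
  })
}

#' Sample a Y-shaped ancestral sequence
#'
#' Rejection-samples random RNA sequences until one folds (by centroid)
#' into the level-5 shape \code{"[[][]]"}: two hairpins under one
#' closing helix. The result is an ordinary random sequence conditioned
#' on its shape — with the typical, marginal stability of random
#' sequences, not an artificially deep energy well — which is what makes
#' the positive-selection regime able to remodel it within a few
#' accepted substitutions. Y-shaped centroids occur in several percent
#' of random sequences at the benchmark lengths, so sampling is cheap.
#'
#' @param length total sequence length in nt.
#' @param max_attempts resampling bound (default 2000).
#' @param gc GC fraction of the random sequences.
#' @param temperature folding temperature in Celsius.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return an RNA sequence string of the requested length.
#' @export
designYAncestor <- function(length, max_attempts = 2000L, gc = 0.5,
                            temperature = 37, seed = NULL) {
  if (length < 30L) stop("Y-shape sampling needs at least 30 nt")
  .with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      seq <- randomSequence(length, gc)
      ens <- foldSequence(seq, pf = TRUE, bpp = FALSE,
                          temperature = temperature)
      if (shape5(ens@centroid_structure) == "[[][]]")
        return(seq)
    }
    stop("no Y-shaped ancestor found in ", max_attempts, " attempts")
  })
}

#' Generate synthetic ortholog families under a selection regime
#'
#' Two benchmark designs are supported. Experiment 1 evolves one random
#' ancestor independently into \code{n_branches} extant sequences per
#' family (a star phylogeny), probing family divergence under the regime.
#' Experiment 2 evolves a single branch and keeps the remaining
#' \code{n_branches - 1} sequences identical to the ancestor, emulating a
#' lineage-specific change on an otherwise frozen family; in \code{pos}
#' mode the ancestor is designed as a Y-shape so that the evolving branch
#' is pushed towards the cloverleaf target.
#'
#' Substitution-only evolution means all family members have equal length
#' and the family is returned already aligned.
#'
#' @param mode \code{"neg"}, \code{"rand"} or \code{"pos"}.
#' @param n_families number of families.
#' @param n_accepted accepted substitutions per evolved branch.
#' @param seq_length ancestor length in nt.
#' @param n_branches family size (default 5).
#' @param experiment 1 (all branches evolve) or 2 (one branch evolves).
#' @param acceptance_temperature Metropolis temperature.
#' @param temperature folding temperature in Celsius.
#' @param gc GC content of random ancestors.
#' @param seed global seed; fanned out per family by stable hashing, so
#'   family k is reproducible in isolation.
#' @return named list of [RNAFamily-class] objects
#'   (\code{fam001} ...); each family carries attributes \code{mode} and
#'   \code{evolved_species}.
#' @export
generateFamilies <- function(mode, n_families = 100L, n_accepted = 5L,
                             seq_length = 150L, n_branches = 5L,
                             experiment = 1L,
                             acceptance_temperature = 1,
                             temperature = 37, gc = 0.5, seed = NULL) {
  mode <- match.arg(mode, c("neg", "rand", "pos"))
  stopifnot(experiment %in% c(1L, 2L), n_branches >= 3L)
  fams <- vector("list", n_families)
  ids <- sprintf("fam%03d", seq_len(n_families))
  for (k in seq_len(n_families)) {
    fseed <- if (is.null(seed)) NULL
             else subSeed(seed, paste(mode, experiment, ids[[k]]))
    fams[[k]] <- .with_seed(fseed, {
      ancestor <- if (mode == "pos")
        designYAncestor(seq_length, temperature = temperature)
      else randomSequence(seq_length, gc)
      fam_cache <- new.env(parent = emptyenv())
      if (experiment == 1L) {
        rows <- vapply(seq_len(n_branches), function(b)
          evolveSequence(ancestor, mode, n_accepted,
                         acceptance_temperature,
                         temperature = temperature,
                         cache = fam_cache)$sequence,
          character(1))
        species <- sprintf("species_%d", seq_len(n_branches))
        evolved <- species
      } else {
        derived <- evolveSequence(ancestor, mode, n_accepted,
                                  acceptance_temperature,
                                  temperature = temperature,
                                  cache = fam_cache)$sequence
        rows <- c(derived, rep(ancestor, n_branches - 1L))
        species <- c("derived",
                     sprintf("ancestral_%d", seq_len(n_branches - 1L)))
        evolved <- "derived"
      }
      fam <- RNAFamily(rows, species = species)
      attr(fam, "mode") <- mode
      attr(fam, "evolved_species") <- evolved
      fam
    })
  }
  setNames(fams, ids)
}
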