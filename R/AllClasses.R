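#' @import methods
#' @importFrom stats median runif setNames
#' @importFrom Rcpp sourceCpp
#' @useDynLib SSStest, .registration = TRUE
NULL

#' Family of aligned orthologous RNA sequences
#'
#' An \code{RNAFamily} holds a multiple sequence alignment of orthologous
#' RNA sequences, one gapped row per species. Rows are stored over the
#' alphabet \code{A,C,G,U,-} (plus IUPAC ambiguity codes, which the folding
#' engine treats as unpairable). A full family used as test input must have
#' at least three species; a background alignment obtained by removing the
#' focal sequence may have as few as two.
#'
#' @slot species character vector of unique species identifiers.
#' @slot rows character vector of gapped rows, parallel to \code{species},
#'   all of equal length.
#' @slot descriptions free-text FASTA descriptions, parallel to
#'   \code{species} (may be empty strings).
#'
#' @seealso [readFamily()], [removeFocal()], [runFamily()]
#' @export
setClass("RNAFamily",
  representation(
    species = "character",
    rows = "character",
    descriptions = "character"
  )
)

setValidity("RNAFamily", function(object) {
  msg <- character()
  if (length(object@species) != length(object@rows))
    msg <- c(msg, "'species' and 'rows' must be parallel")
  if (length(object@rows) < 2L)
    msg <- c(msg, "an alignment needs at least two rows")
  if (anyDuplicated(object@species))
    msg <- c(msg, "species identifiers must be unique within a family")
  if (length(unique(nchar(object@rows))) > 1L)
    msg <- c(msg, "all alignment rows must have equal length")
  if (length(object@rows) && nchar(object@rows[[1L]]) == 0L)
    msg <- c(msg, "alignment has zero columns")
  bad <- grepl(sprintf("[^%s]", .iupac_class), object@rows)
  if (any(bad))
    msg <- c(msg, sprintf("row '%s' contains characters outside the IUPAC RNA set",
                          object@species[which(bad)[1L]]))
  if (length(msg)) msg else TRUE
})

# character class of accepted row symbols (upper case, U-alphabet, gap)
.iupac_class <- "ACGUNRYSWKMBDHV-"

#' Thermodynamic structure ensemble of one RNA sequence
#'
#' Results of folding a single ungapped sequence under the Turner
#' nearest-neighbour model: minimum free energy (MFE) structure and energy,
#' ensemble (Gibbs) free energy, centroid structure, and the base-pair
#' probability matrix of the Boltzmann ensemble. Partition-function slots
#' are \code{NA}/empty when only the MFE was requested.
#'
#' @slot sequence ungapped RNA sequence.
#' @slot mfe_structure dot-bracket MFE structure.
#' @slot mfe_energy MFE in kcal/mol.
#' @slot ensemble_free_energy Gibbs free energy of the ensemble, kcal/mol;
#'   always less than or equal to \code{mfe_energy}.
#' @slot centroid_structure dot-bracket structure containing exactly the
#'   pairs with ensemble probability above 1/2.
#' @slot pair_prob symmetric matrix of base-pair probabilities.
#' @export
setClass("StructureEnsemble",
  representation(
    sequence = "character",
    mfe_structure = "character",
    mfe_energy = "numeric",
    ensemble_free_energy = "numeric",
    centroid_structure = "character",
    pair_prob = "matrix"
  )
)

setValidity("StructureEnsemble", function(object) {
  msg <- character()
  n <- nchar(object@sequence)
  if (nchar(object@mfe_structure) != n)
    msg <- c(msg, "MFE structure length differs from sequence length")
  if (!.is_balanced(object@mfe_structure))
    msg <- c(msg, "MFE structure is not balanced")
  if (length(object@pair_prob)) {
    if (!all(dim(object@pair_prob) == c(n, n)))
      msg <- c(msg, "pair probability matrix dimension mismatch")
    if (any(object@pair_prob < -1e-9 | object@pair_prob > 1 + 1e-6))
      msg <- c(msg, "pair probabilities outside [0,1]")
  }
  if (!is.na(object@ensemble_free_energy) &&
      object@ensemble_free_energy > object@mfe_energy + 1e-6)
    msg <- c(msg, "ensemble free energy exceeds MFE energy")
  if (length(msg)) msg else TRUE
})

#' Consensus structure ensemble of an alignment
#'
#' Consensus folding results for a multiple sequence alignment: the
#' consensus MFE structure over alignment columns and the column-pair
#' probability matrix of the alignment ensemble.
#'
#' @slot n_cols number of alignment columns.
#' @slot species species identifiers of the folded alignment.
#' @slot consensus_structure dot-bracket consensus structure over columns;
#'   all-gap columns are unpaired.
#' @slot consensus_pair_prob matrix of column-pair probabilities (empty when
#'   only the consensus MFE was requested).
#' @slot energy consensus folding energy, kcal/mol.
#' @export
setClass("ConsensusEnsemble",
  representation(
    n_cols = "integer",
    species = "character",
    consensus_structure = "character",
    consensus_pair_prob = "matrix",
    energy = "numeric"
  )
)

setValidity("ConsensusEnsemble", function(object) {
  msg <- character()
  if (nchar(object@consensus_structure) != object@n_cols)
    msg <- c(msg, "consensus structure length differs from column count")
  if (!.is_balanced(object@consensus_structure))
    msg <- c(msg, "consensus structure is not balanced")
  if (length(object@consensus_pair_prob) &&
      any(object@consensus_pair_prob < -1e-9 |
          object@consensus_pair_prob > 1 + 1e-6))
    msg <- c(msg, "column pair probabilities outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' Background consensus profile of an alignment
#'
#' Per-column consensus of a background alignment: the modal character of
#' every column (gaps counted as characters, ties broken A < C < G < U with
#' the gap losing all ties), the fraction of background sequences agreeing
#' with it, and the well-conserved mask \code{agreement >= threshold}.
#'
#' @slot chars character vector of consensus characters, one per column.
#' @slot agreement numeric vector of per-column agreement fractions.
#' @slot well_conserved logical mask of well-conserved columns.
#' @slot threshold the agreement threshold used (default 0.6).
#' @slot n_background number of background sequences.
#' @seealso [buildConsensus()]
#' @export
setClass("ConsensusProfile",
  representation(
    chars = "character",
    agreement = "numeric",
    well_conserved = "logical",
    threshold = "numeric",
    n_background = "integer"
  )
)

setValidity("ConsensusProfile", function(object) {
  msg <- character()
  n <- length(object@chars)
  if (length(object@agreement) != n || length(object@well_conserved) != n)
    msg <- c(msg, "per-column slots must have equal length")
  if (any(object@agreement < 0 | object@agreement > 1))
    msg <- c(msg, "agreement fractions outside [0,1]")
  if (!identical(object@well_conserved,
                 object@agreement >= object@threshold))
    msg <- c(msg, "well_conserved mask inconsistent with threshold")
  if (length(msg)) msg else TRUE
})

#' Per-family selection test report
#'
#' One row per focal species with substitution and indel scores, the
#' combined SSS-score, the species structural divergence and the selection
#' label, plus the family divergence and run metadata.
#'
#' @slot table data.frame with columns \code{family_id}, \code{species},
#'   \code{n_subst}, \code{n_indel}, \code{n_compensatory}, \code{s_sub},
#'   \code{s_indel}, \code{sss_score}, \code{d_s}, \code{family_d},
#'   \code{label}.
#' @slot family_d family divergence (median of the per-species d_s).
#' @slot events per-species list of scored variant events (detail tables).
#' @slot metadata list of configuration values and engine identity needed
#'   to reproduce the run.
#' @export
setClass("SelectionReport",
  representation(
    table = "data.frame",
    family_d = "numeric",
    events = "list",
    metadata = "list"
  )
)

#' Shuffle-based false discovery rate estimate
#'
#' @slot F number of positive test results on the real (foreground) data.
#' @slot R number of positive test results on the shuffled background.
#' @slot f fraction of foreground positives whose shuffles stay positive.
#' @slot fdr_naive R/F.
#' @slot fdr_refined (1-f) R/F.
#' @export
setClass("FdrEstimate",
  representation(
    F = "integer",
    R = "integer",
    f = "numeric",
    fdr_naive = "numeric",
    fdr_refined = "numeric"
  )
)

setValidity("FdrEstimate", function(object) {
  msg <- character()
  if (object@F <= 0L) msg <- c(msg, "F must be positive")
  if (object@R < 0L) msg <- c(msg, "R must be non-negative")
  if (!is.na(object@f) && (object@f < 0 || object@f > 1))
    msg <- c(msg, "f must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

## ---- generics ------------------------------------------------------------

#' Number of species in a family
#' @param x an object with species members.
#' @return integer count.
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' Number of alignment columns
#' @param x an alignment-like object.
#' @return integer column count.
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' Species identifiers
#' @param x an object with species members.
#' @return character vector.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Gapped alignment rows
#' @param x an alignment-like object.
#' @return named character vector of gapped rows.
#' @export
setGeneric("alignedRows", function(x) standardGeneric("alignedRows"))

#' Ungapped sequence of one species
#' @param x an alignment-like object.
#' @param species species identifier.
#' @return ungapped RNA sequence.
#' @export
setGeneric("ungappedSequence",
           function(x, species) standardGeneric("ungappedSequence"))

#' Base-pair probability matrix
#' @param x a structure ensemble.
#' @return symmetric numeric matrix of pairing probabilities.
#' @export
setGeneric("pairProbabilities",
           function(x) standardGeneric("pairProbabilities"))

#' MFE structure accessor
#' @param x a structure or consensus ensemble.
#' @return dot-bracket string.
#' @export
setGeneric("mfeStructure", function(x) standardGeneric("mfeStructure"))

#' Report table accessor
#' @param x a SelectionReport.
#' @return data.frame of per-species results.
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

## ---- methods -------------------------------------------------------------

#' @describeIn RNAFamily number of species.
#' @param x an \code{RNAFamily}.
#' @export
setMethod("nSpecies", "RNAFamily", function(x) length(x@species))

#' @describeIn RNAFamily number of alignment columns.
#' @export
setMethod("nCols", "RNAFamily", function(x) nchar(x@rows[[1L]]))

#' @describeIn RNAFamily species identifiers.
#' @export
setMethod("speciesNames", "RNAFamily", function(x) x@species)

#' @describeIn RNAFamily named gapped rows.
#' @export
setMethod("alignedRows", "RNAFamily",
          function(x) setNames(x@rows, x@species))

#' @describeIn RNAFamily ungapped sequence of one species.
#' @param species species identifier.
#' @export
setMethod("ungappedSequence", "RNAFamily", function(x, species) {
  i <- match(species, x@species)
  if (is.na(i)) stop("unknown species '", species, "'")
  gsub("-", "", x@rows[[i]], fixed = TRUE)
})

#' @describeIn StructureEnsemble base-pair probability matrix.
#' @param x a \code{StructureEnsemble}.
#' @export
setMethod("pairProbabilities", "StructureEnsemble", function(x) x@pair_prob)

#' @describeIn StructureEnsemble MFE structure.
#' @export
setMethod("mfeStructure", "StructureEnsemble", function(x) x@mfe_structure)

#' @describeIn ConsensusEnsemble consensus MFE structure.
#' @param x a \code{ConsensusEnsemble}.
#' @export
setMethod("mfeStructure", "ConsensusEnsemble",
          function(x) x@consensus_structure)

#' @describeIn SelectionReport per-species result table.
#' @param x a \code{SelectionReport}.
#' @export
setMethod("reportTable", "SelectionReport", function(x) x@table)

setMethod("show", "RNAFamily", function(object) {
  cat(sprintf("RNAFamily: %d species, %d alignment columns\n",
              nSpecies(object), nCols(object)))
  for (i in seq_along(object@species)) {
    row <- object@rows[[i]]
    if (nchar(row) > 60) row <- paste0(substr(row, 1, 57), "...")
    cat(sprintf("  %-15s %s\n", object@species[[i]], row))
  }
})

setMethod("show", "StructureEnsemble", function(object) {
  cat("StructureEnsemble of", nchar(object@sequence), "nt\n")
  cat("  MFE     ", object@mfe_structure,
      sprintf(" (%.2f kcal/mol)\n", object@mfe_energy))
  if (!is.na(object@ensemble_free_energy)) {
    cat("  centroid", object@centroid_structure, "\n")
    cat(sprintf("  ensemble free energy %.2f kcal/mol\n",
                object@ensemble_free_energy))
  }
})

setMethod("show", "ConsensusEnsemble", function(object) {
  cat(sprintf("ConsensusEnsemble over %d columns (%d species)\n",
              object@n_cols, length(object@species)))
  cat("  ", object@consensus_structure, "\n")
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: %d focal species, family divergence %.2f\n",
              nrow(object@table), object@family_d))
  print(object@table, row.names = FALSE)
})

setMethod("show", "FdrEstimate", function(object) {
  cat(sprintf("FDR estimate: F=%d R=%d naive=%.3f", object@F, object@R,
              object@fdr_naive))
  if (!is.na(object@f))
    cat(sprintf(" f=%.3f refined=%.3f", object@f, object@fdr_refined))
  cat("\n")
})
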