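## Contract over the ViennaRNA thermodynamic folding engine.
##
## All folding goes through batched subprocess calls to RNAfold, RNAalifold
## and RNALfold; pair probabilities are parsed from the engine's dot-plot
## PostScript output (`i j sqrt(p) ubox` records). Each call runs in a
## private temporary directory so concurrent runs cannot collide.

.vienna_identity <- function() {
  out <- tryCatch(system2("RNAfold", "--version", stdout = TRUE,
                          stderr = TRUE),
                  error = function(e) NA_character_)
  paste(out, collapse = " ")
}

.check_engine <- function() {
  if (Sys.which("RNAfold") == "")
    stop("the ViennaRNA programs (RNAfold etc.) must be on the PATH")
}

.temp_args <- function(temperature) {
  if (!is.null(temperature) && temperature != 37)
    c("-T", format(temperature)) else character()
}

# parse `i j sqrt(p) ubox` records from a dot-plot file into a symmetric
# probability matrix of dimension n x n
.parse_dp_ps <- function(path, n) {
  p <- matrix(0, n, n)
  if (!file.exists(path)) return(p)
  lines <- readLines(path, warn = FALSE)
  ub <- lines[endsWith(lines, "ubox") & grepl("^[0-9]|hsb", lines)]
  if (!length(ub)) return(p)
  # records are "i j sqrt(p) ubox", optionally prefixed by colour state
  ub <- sub("^.*hsb ", "", ub)
  f <- scan(text = ub, what = list(i = integer(), j = integer(),
                                   v = double(), tag = character()),
            quiet = TRUE)
  ok <- !is.na(f$i) & !is.na(f$j) & f$i >= 1L & f$j <= n
  v <- f$v[ok]^2
  p[cbind(f$i[ok], f$j[ok])] <- v
  p[cbind(f$j[ok], f$i[ok])] <- v
  p
}

#' Fold many RNA sequences in one engine invocation
#'
#' Batch interface to the folding engine; [foldSequence()] is the
#' single-sequence convenience wrapper. With \code{pf = TRUE} the
#' partition function is computed and each result carries the ensemble
#' free energy, centroid structure and base-pair probability matrix.
#'
#' @param seqs character vector of ungapped RNA sequences.
#' @param pf compute partition-function quantities (default TRUE).
#' @param bpp parse the base-pair probability matrices (default TRUE);
#'   callers needing only energies and the centroid can skip the parse.
#' @param constraints optional character vector of dot-bracket constraint
#'   strings, parallel to \code{seqs} (use \code{NA} for unconstrained
#'   entries); matched brackets are enforced as base pairs.
#' @param temperature folding temperature in Celsius.
#' @return list of [StructureEnsemble-class] objects, one per input.
#' @export
foldMany <- function(seqs, pf = TRUE, constraints = NULL,
                     temperature = 37, bpp = pf) {
  if (!length(seqs)) return(list())
  if (any(!nzchar(seqs))) stop("cannot fold an empty sequence")
  .check_engine()
  seqs <- .normalize_rna(seqs)
  nseq <- length(seqs)
  ids <- sprintf("q%06d", seq_len(nseq))
  use_constraints <- !is.null(constraints) && any(!is.na(constraints))
  recs <- character(nseq)
  for (k in seq_len(nseq)) {
    body <- seqs[[k]]
    if (use_constraints) {
      cst <- constraints[[k]]
      if (is.na(cst)) cst <- strrep(".", nchar(seqs[[k]]))
      if (nchar(cst) != nchar(seqs[[k]]))
        stop("constraint length differs from sequence length")
      body <- paste(body, cst, sep = "\n")
    }
    recs[[k]] <- paste0(">", ids[[k]], "\n", body)
  }
  args <- c("--noPS", .temp_args(temperature))
  if (pf) args <- c(args, "-p")
  if (pf && !bpp) args <- c(args, "--noDP")
  if (use_constraints) args <- c(args, "-C", "--enforceConstraint")

  wd <- tempfile("fold")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  infile <- file.path(wd, "in.fa")
  writeLines(recs, infile)
  old <- setwd(wd); on.exit(setwd(old), add = TRUE, after = FALSE)
  out <- suppressWarnings(
    system2("RNAfold", args, stdout = TRUE, stderr = TRUE,
            stdin = "in.fa"))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("RNAfold failed: ", paste(utils::tail(out, 3), collapse = " "))

  .parse_fold_output(out, seqs, ids, pf, wd, bpp)
}

.parse_fold_output <- function(out, seqs, ids, pf, wd, bpp = pf) {
  hdr <- grep("^>", out)
  if (length(hdr) != length(seqs))
    stop("unexpected RNAfold output: ", length(hdr), " records for ",
         length(seqs), " sequences")
  res <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    block <- out[seq(hdr[k], if (k < length(hdr)) hdr[k + 1L] - 1L
                     else length(out))]
    n <- nchar(seqs[[k]])
    mfe_line <- grep("^[.()]+\\s+\\(", block, value = TRUE)[1L]
    if (is.na(mfe_line))
      stop("no MFE structure in RNAfold output for sequence ", k)
    mfe_struct <- sub("\\s.*$", "", mfe_line)
    mfe_energy <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\).*", "\\1",
                                 mfe_line))
    efe <- NA_real_; centroid <- NA_character_
    pp <- matrix(numeric(0), 0, 0)
    if (pf) {
      ens_line <- grep("\\[", block, value = TRUE)[1L]
      efe <- as.numeric(sub(".*\\[\\s*(-?[0-9.]+)\\].*", "\\1", ens_line))
      cen_line <- grep("^[.()]+\\s+\\{", block, value = TRUE)[1L]
      centroid <- sub("\\s.*$", "", cen_line)
      if (bpp)
        pp <- .parse_dp_ps(file.path(wd, paste0(ids[[k]], "_dp.ps")), n)
    }
    res[[k]] <- new("StructureEnsemble",
                    sequence = seqs[[k]],
                    mfe_structure = mfe_struct,
                    mfe_energy = mfe_energy,
                    ensemble_free_energy = efe,
                    centroid_structure = centroid,
                    pair_prob = pp)
  }
  res
}

#' Fold a single RNA sequence
#'
#' @inheritParams foldMany
#' @param seq ungapped RNA sequence.
#' @return a [StructureEnsemble-class].
#' @examples
#' \dontrun{
#' ens <- foldSequence("GGGGGAAAACCCCC")
#' mfeStructure(ens)  # "(((((....)))))"
#' }
#' @export
foldSequence <- function(seq, pf = TRUE, temperature = 37, bpp = pf) {
  foldMany(seq, pf = pf, temperature = temperature, bpp = bpp)[[1L]]
}

#' Fold with enforced base pairs
#'
#' Computes the MFE structure (and optionally ensemble quantities) under
#' the constraint that a given set of base pairs must be present.
#'
#' @inheritParams foldSequence
#' @param forced_pairs two-column matrix of 1-based position pairs that
#'   must pair; pairs must be non-crossing, disjoint and between
#'   complementary bases (Watson-Crick or GU).
#' @return a [StructureEnsemble-class] whose MFE structure contains every
#'   forced pair.
#' @export
foldConstrained <- function(seq, forced_pairs, pf = FALSE,
                            temperature = 37) {
  seq <- .normalize_rna(seq)
  n <- nchar(seq)
  if (is.null(forced_pairs) || NROW(forced_pairs) == 0L)
    return(foldSequence(seq, pf = pf, temperature = temperature))
  fp <- matrix(as.integer(forced_pairs), ncol = 2L)
  fp <- cbind(pmin(fp[, 1L], fp[, 2L]), pmax(fp[, 1L], fp[, 2L]))
  if (any(fp[, 1L] < 1L | fp[, 2L] > n))
    stop("forced pair outside the sequence")
  if (anyDuplicated(c(fp)))
    stop("conflicting constraints: a position occurs in more than one pair")
  .check_noncrossing(fp)
  chars <- strsplit(seq, "")[[1L]]
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  combos <- paste0(chars[fp[, 1L]], chars[fp[, 2L]])
  if (any(!combos %in% ok))
    stop("unpairable forced pair: ", combos[which(!combos %in% ok)[1L]])
  cst <- rep(".", n)
  cst[fp[, 1L]] <- "("; cst[fp[, 2L]] <- ")"
  ens <- foldMany(seq, pf = pf, constraints = paste(cst, collapse = ""),
                  temperature = temperature)[[1L]]
  have <- pairTable(ens@mfe_structure)
  key <- paste(have[, 1L], have[, 2L])
  if (!all(paste(fp[, 1L], fp[, 2L]) %in% key))
    stop("engine failed to realise a forced pair")
  ens
}

.check_noncrossing <- function(fp) {
  if (nrow(fp) < 2L) return(invisible())
  o <- order(fp[, 1L]); fp <- fp[o, , drop = FALSE]
  for (a in seq_len(nrow(fp) - 1L)) {
    for (b in seq(a + 1L, nrow(fp))) {
      i <- fp[a, 1L]; j <- fp[a, 2L]; k <- fp[b, 1L]; l <- fp[b, 2L]
      if (i < k && k < j && j < l)
        stop("crossing constraints: (", i, ",", j, ") and (",
             k, ",", l, ")")
    }
  }
  invisible()
}

#' Consensus folding of an alignment
#'
#' Folds a multiple sequence alignment into its consensus MFE structure
#' over alignment columns (all-gap columns stay unpaired) and, with
#' \code{pf = TRUE}, the column-pair probability matrix of the alignment
#' ensemble.
#'
#' @param family an [RNAFamily-class].
#' @param pf also compute the column-pair probability matrix.
#' @param temperature folding temperature in Celsius.
#' @return a [ConsensusEnsemble-class].
#' @export
consensusFold <- function(family, pf = FALSE, temperature = 37) {
  .check_engine()
  n <- nCols(family)
  wd <- tempfile("alifold")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  infile <- file.path(wd, "aln.fa")
  writeLines(paste0(">", family@species, "\n", family@rows), infile)
  args <- c("-f", "F", "--noPS", .temp_args(temperature))
  if (pf) args <- c(args, "-p")
  old <- setwd(wd); on.exit(setwd(old), add = TRUE, after = FALSE)
  out <- suppressWarnings(
    system2("RNAalifold", c(args, "aln.fa"), stdout = TRUE,
            stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("RNAalifold failed: ", paste(utils::tail(out, 3), collapse = " "))
  struct_line <- grep("^[.()]+\\s+\\(", out, value = TRUE)[1L]
  if (is.na(struct_line))
    stop("no consensus structure in RNAalifold output")
  cons_struct <- sub("\\s.*$", "", struct_line)
  if (nchar(cons_struct) != n)
    stop("consensus structure length ", nchar(cons_struct),
         " differs from alignment width ", n)
  energy <- as.numeric(sub(".*?\\(\\s*(-?[0-9.]+)\\s*=.*", "\\1",
                           struct_line))
  pp <- matrix(numeric(0), 0, 0)
  if (pf) pp <- .parse_dp_ps(file.path(wd, "alidot.ps"), n)
  new("ConsensusEnsemble",
      n_cols = as.integer(n),
      species = family@species,
      consensus_structure = cons_struct,
      consensus_pair_prob = pp,
      energy = energy)
}

#' Locally stable structures with restricted pair span
#'
#' Scans a sequence for locally stable secondary structures in which all
#' base pairs span at most \code{max_span} nt, as used to decompose long
#' RNAs into structural modules.
#'
#' @param seq ungapped RNA sequence.
#' @param max_span maximum base-pair span in nt (>= 4).
#' @param temperature folding temperature in Celsius.
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive), \code{structure}, \code{energy} (kcal/mol) and
#'   \code{n_pairs}, ordered by start position.
#' @export
localFold <- function(seq, max_span = 200L, temperature = 37) {
  if (max_span < 4L) stop("max_span below the minimal hairpin size")
  .check_engine()
  seq <- .normalize_rna(seq)
  out <- suppressWarnings(
    system2("RNALfold", c("-L", max_span, .temp_args(temperature)),
            stdout = TRUE, stderr = TRUE, input = seq))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("RNALfold failed: ", paste(utils::tail(out, 3), collapse = " "))
  pat <- "^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s+(\\d+)\\s*$"
  hits <- grep(pat, out, value = TRUE)
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      structure = character(0), energy = numeric(0),
                      n_pairs = integer(0)))
  structure <- sub(pat, "\\1", hits)
  energy <- as.numeric(sub(pat, "\\2", hits))
  start <- as.integer(sub(pat, "\\3", hits))
  end <- start + nchar(structure) - 1L
  n_pairs <- vapply(structure, function(s) nrow(pairTable(s)), integer(1),
                    USE.NAMES = FALSE)
  df <- data.frame(start = start, end = end, structure = structure,
                   energy = energy, n_pairs = n_pairs)
  df <- df[df$end <= nchar(seq), , drop = FALSE]  # guard against artifacts
  df[order(df$start, df$end), , drop = FALSE]
}
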