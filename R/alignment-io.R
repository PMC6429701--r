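## Reading, writing and manipulating ortholog family alignments.

#' Construct an RNAFamily from gapped rows
#'
#' @param rows character vector of gapped rows (equal length), named by
#'   species, or unnamed with \code{species} given separately.
#' @param species species identifiers (defaults to \code{names(rows)}).
#' @param descriptions optional FASTA descriptions.
#' @param min_species minimum family size enforced (default 3; background
#'   alignments produced by [removeFocal()] may have 2).
#' @return an [RNAFamily-class] object.
#' @examples
#' fam <- RNAFamily(c(human = "GGGAAACCC", chimp = "GGGAAACCC",
#'                    gorilla = "GGGAAACCC"))
#' nCols(fam)
#' @export
RNAFamily <- function(rows, species = names(rows), descriptions = NULL,
                      min_species = 3L) {
  if (is.null(species))
    stop("species identifiers are required (name the rows)")
  rows <- .normalize_rna(unname(rows))
  if (length(rows) < min_species)
    stop("family too small: need at least ", min_species,
         " sequences, got ", length(rows))
  if (is.null(descriptions)) descriptions <- rep("", length(rows))
  new("RNAFamily", species = as.character(species), rows = rows,
      descriptions = descriptions)
}

#' Read an ortholog family from a FASTA file
#'
#' Record identifiers are taken as species identifiers (first whitespace
#' token; the rest of the header is kept as description). Sequences are
#' upper-cased and DNA T is transcribed to U. With \code{aligned = TRUE}
#' the records must already form an alignment of equal-length rows; with
#' \code{aligned = FALSE} an external aligner is invoked via the
#' configurable command template.
#'
#' @param path FASTA file.
#' @param aligned whether the input is already aligned.
#' @param aligner command template for the external aligner (see
#'   [runConfig()]); only used when \code{aligned = FALSE}.
#' @param min_species minimum number of records (default 3).
#' @return an [RNAFamily-class].
#' @export
readFamily <- function(path, aligned = TRUE,
                       aligner = runConfig()$aligner, min_species = 3L) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  species <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  rows <- .normalize_rna(as.character(set))
  if (!aligned) {
    rows <- .run_aligner(rows, species, aligner)
    rows <- rows[species]  # restore input order
  } else if (length(unique(nchar(rows))) > 1L) {
    stop("aligned=TRUE but records have unequal lengths")
  }
  RNAFamily(unname(rows), species = species,
            descriptions = descriptions, min_species = min_species)
}

#' Write a family to a FASTA file
#'
#' Inverse of [readFamily()] for aligned families: species id plus
#' description as header, gapped row as sequence.
#'
#' @param family an [RNAFamily-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFamily <- function(family, path) {
  headers <- ifelse(nzchar(family@descriptions),
                    paste(family@species, family@descriptions),
                    family@species)
  writeLines(paste0(">", headers, "\n", family@rows), path)
  invisible(path)
}

# invoke the external aligner command template on unaligned sequences
.run_aligner <- function(rows, species, aligner) {
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  writeLines(paste0(">", species, "\n", rows), fa)
  cmd <- sub("{input}", shQuote(fa), aligner, fixed = TRUE)
  out <- suppressWarnings(system(cmd, intern = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("aligner failed (exit ", status, "): ", cmd)
  aligned <- .parse_fasta_lines(out)
  if (length(aligned) != length(rows))
    stop("aligner returned ", length(aligned), " records for ",
         length(rows), " input sequences")
  .normalize_rna(aligned)
}

.parse_fasta_lines <- function(lines) {
  idx <- grep("^>", lines)
  if (!length(idx)) stop("aligner produced no FASTA output")
  ids <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
  starts <- idx + 1L
  ends <- c(idx[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(k) {
    paste(lines[seq(starts[k], ends[k])], collapse = "")
  }, character(1))
  setNames(gsub("\\s", "", seqs), ids)
}

#' Map between alignment columns and ungapped sequence positions
#'
#' For one gapped row, returns the partial map from alignment column to
#' ungapped position and its inverse. Coordinates are 1-based (gap columns
#' map to \code{NA}).
#'
#' @param row gapped sequence string.
#' @return list with \code{col_to_seq} (integer vector of length
#'   \code{nchar(row)}, \code{NA} at gaps) and \code{seq_to_col} (integer
#'   vector of length \code{#non-gaps}).
#' @examples
#' coordinateMap("A-CG")$col_to_seq  # 1 NA 2 3
#' @export
coordinateMap <- function(row) {
  chars <- strsplit(row, "")[[1L]]
  is_base <- chars != "-"
  col_to_seq <- ifelse(is_base, cumsum(is_base), NA_integer_)
  list(col_to_seq = as.integer(col_to_seq),
       seq_to_col = which(is_base))
}

#' Remove the focal sequence from a family
#'
#' Returns the background alignment with the focal species' row removed.
#' Columns that become all-gap are retained so that column indices stay
#' comparable across focal choices.
#'
#' @param family an [RNAFamily-class].
#' @param species focal species identifier.
#' @return the background [RNAFamily-class] (at least two rows).
#' @export
removeFocal <- function(family, species) {
  i <- match(species, family@species)
  if (is.na(i)) stop("unknown species '", species, "'")
  if (nSpecies(family) - 1L < 2L)
    stop("family too small: background would have fewer than two rows")
  new("RNAFamily",
      species = family@species[-i],
      rows = family@rows[-i],
      descriptions = family@descriptions[-i])
}

# alignment rows as a character matrix (columns = alignment columns)
.row_matrix <- function(family) {
  do.call(rbind, strsplit(family@rows, ""))
}
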