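#' Structural distance between two secondary structures
#'
#' Unit-cost tree edit distance between the forest encodings of two
#' dot-bracket structures (one internal node per base pair, one leaf per
#' unpaired base). Insertions and deletions cost 1; nodes match only
#' within their own type, so turning a pair into an unpaired base costs a
#' deletion plus an insertion. The distance is a metric: zero iff the
#' structures are identical, and symmetric.
#'
#' @param struct1,struct2 dot-bracket strings of equal length.
#' @return non-negative integer edit distance.
#' @examples
#' structuralDistance("((....))", "((....))")  # 0
#' structuralDistance("((....))", "........")  # 6
#' @export
structuralDistance <- function(struct1, struct2) {
  if (nchar(struct1) != nchar(struct2))
    stop("structures must have equal length")
  .tree_edit_cpp(struct1, struct2)
}
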