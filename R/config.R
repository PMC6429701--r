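#' Configuration for a selection test run
#'
#' Collects every tunable of the test with its default. Defaults follow the
#' method's reference calibration for closely related species (primates):
#' 60\% consensus agreement for a well-conserved site, SSS-score >= 10 for
#' positive selection, <= 2 for conservation, family divergence <= 10 for a
#' structurally uniform family, and a 30\% start-shift tolerance for
#' orthologous local-structure blocks.
#'
#' @param conservation_threshold fraction of background sequences that must
#'   agree with the consensus for a column to count as well-conserved.
#' @param correction multiple-testing correction, \code{"bh"}
#'   (Benjamini-Hochberg step-up) or \code{"bonferroni"}.
#' @param joint_correction correct substitution and indel p-values as one
#'   joint set instead of two separate sets (default \code{FALSE}).
#' @param positive_cutoff SSS-score at or above which a focal sequence is
#'   labelled positively selected.
#' @param conserved_cutoff SSS-score at or below which a focal sequence is
#'   labelled conserved (negative selection).
#' @param divergence_cutoff family divergence above which no selection call
#'   is made (label \code{high_divergence}).
#' @param null_samples number of null sequences for the substitution
#'   impact p-value.
#' @param min_region minimum length (nt) of the window scanned for the
#'   region of maximal structural discrepancy; capped at sequence length.
#' @param max_span maximum base-pair span for local folding, nt.
#' @param block_tolerance maximum start-column shift between orthologous
#'   local structures, as a fraction of the shorter member's length.
#' @param min_species minimum number of species per family/block.
#' @param log_base base of the logarithm aggregating corrected p-values
#'   into scores (natural log by default).
#' @param temperature folding temperature in Celsius, passed to the engine.
#' @param aligner command template used to align unaligned input; must read
#'   FASTA on \code{\{input\}} and write aligned FASTA to stdout.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return a named list of class \code{sss_config}.
#' @examples
#' cfg <- runConfig(null_samples = 50, seed = 1)
#' cfg$positive_cutoff
#' @export
runConfig <- function(conservation_threshold = 0.6,
                      correction = c("bh", "bonferroni"),
                      joint_correction = FALSE,
                      positive_cutoff = 10.0,
                      conserved_cutoff = 2.0,
                      divergence_cutoff = 10.0,
                      null_samples = 200L,
                      min_region = 20L,
                      max_span = 200L,
                      block_tolerance = 0.3,
                      min_species = 3L,
                      log_base = exp(1),
                      temperature = 37,
                      aligner = "mafft --quiet --auto {input}",
                      seed = NULL) {
  correction <- match.arg(correction)
  stopifnot(conservation_threshold >= 0, conservation_threshold <= 1,
            positive_cutoff > conserved_cutoff, conserved_cutoff >= 0,
            divergence_cutoff > 0, null_samples >= 1, min_region >= 1,
            max_span >= 4, block_tolerance >= 0, block_tolerance <= 1,
            min_species >= 2, log_base > 1)
  structure(list(
    conservation_threshold = conservation_threshold,
    correction = correction,
    joint_correction = isTRUE(joint_correction),
    positive_cutoff = positive_cutoff,
    conserved_cutoff = conserved_cutoff,
    divergence_cutoff = divergence_cutoff,
    null_samples = as.integer(null_samples),
    min_region = as.integer(min_region),
    max_span = as.integer(max_span),
    block_tolerance = block_tolerance,
    min_species = as.integer(min_species),
    log_base = log_base,
    temperature = temperature,
    aligner = aligner,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sss_config")
}

# metadata header describing a run, attached to reports
.run_metadata <- function(config) {
  list(
    package = "SSStest",
    version = as.character(utils::packageVersion("SSStest")),
    engine = .vienna_identity(),
    config = config[setdiff(names(config), "seed")],
    seed = config$seed
  )
}
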