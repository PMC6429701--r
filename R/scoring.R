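## Substitution impact p-values, multiple-testing correction, and the
## aggregation of corrected p-values into selection scores.

#' Empirical p-value for the structural impact of a substitution
#'
#' Measures how strongly a single base exchange perturbs the structure
#' ensemble of the wild-type sequence, relative to the same base exchange
#' in random sequences of the same length and GC content. The observed
#' discrepancy is the maximal-region measure of [maxDiscrepancyRegion()]
#' between the wild-type and mutant pair-probability matrices; the null
#' distribution applies the same exchange at a uniformly chosen position
#' carrying the source base in each random sequence. Null sequences are
#' uniform permutations of the wild type's own bases - random sequences
#' of identical length, GC content and full base composition - which
#' makes the null exchangeable with the observed sequence and the
#' p-value exactly uniform under it. The p-value uses the add-one
#' estimator \eqn{(1 + k)/(N + 1)} where k counts null discrepancies at
#' least as large as the observed one, so it can never be exactly zero.
#'
#' @param consensus_seq wild-type (background consensus) sequence.
#' @param pos 1-based position of the substitution.
#' @param from_base,to_base source and target base; \code{consensus_seq}
#'   must carry \code{from_base} at \code{pos}.
#' @param N number of null samples (>= 1).
#' @param seed integer seed for the null draw; \code{NULL} uses the
#'   current RNG state.
#' @param min_region minimum discrepancy-region length (nt).
#' @param temperature folding temperature in Celsius.
#' @return list with \code{d_obs}, \code{region}, \code{null_d} (length
#'   N) and \code{p_raw}.
#' @export
substitutionPvalue <- function(consensus_seq, pos, from_base, to_base,
                               N = 200L, seed = NULL, min_region = 20L,
                               temperature = 37) {
  if (N < 1L) stop("N must be at least 1")
  subs <- data.frame(pos = as.integer(pos), from = from_base,
                     to = to_base)
  res <- .with_seed(seed,
    .scoreSubstitutions(consensus_seq, subs, N = N,
                        min_region = min_region,
                        temperature = temperature))
  res[[1L]]
}

# Batched scoring of several substitutions on the same wild-type sequence.
# The N random null sequences are shared across the substitutions (each is
# mutated independently per substitution), so one family costs
# 1 + n_subs + N + n_subs*N folds in two engine invocations.
.scoreSubstitutions <- function(wt, subs, N, min_region, temperature) {
  wt <- .normalize_rna(wt)
  L <- nchar(wt)
  chars <- strsplit(wt, "")[[1L]]
  for (r in seq_len(nrow(subs))) {
    if (chars[[subs$pos[[r]]]] != subs$from[[r]])
      stop("wild-type does not carry base ", subs$from[[r]],
           " at position ", subs$pos[[r]])
    if (subs$from[[r]] == subs$to[[r]])
      stop("substitution must change the base")
  }
  # null sequences: random sequences of the same length and GC content,
  # realised as uniform permutations of the wild type's own bases. This
  # matches the full base composition, so the null is exchangeable with
  # the observed sequence given its composition, and every needed source
  # base is present by construction.
  null_wt <- vapply(seq_len(N), function(k)
    paste(sample(chars), collapse = ""), character(1))

  mutate_at <- function(seq, pos, to) {
    substr(seq, pos, pos) <- to
    seq
  }
  ns <- nrow(subs)
  muts <- vapply(seq_len(ns), function(r)
    mutate_at(wt, subs$pos[[r]], subs$to[[r]]), character(1))
  # per (null sequence, substitution): same exchange at a uniform position
  # carrying the source base
  null_mut <- matrix("", N, ns)
  for (k in seq_len(N)) {
    nchars <- strsplit(null_wt[[k]], "")[[1L]]
    for (r in seq_len(ns)) {
      cand_pos <- which(nchars == subs$from[[r]])
      p <- cand_pos[[sample.int(length(cand_pos), 1L)]]
      null_mut[k, r] <- mutate_at(null_wt[[k]], p, subs$to[[r]])
    }
  }

  all_seqs <- c(wt, muts, null_wt, as.vector(null_mut))
  ens <- foldMany(all_seqs, pf = TRUE, temperature = temperature)
  pp <- lapply(ens, pairProbabilities)
  wt_pp <- pp[[1L]]
  mut_pp <- pp[seq.int(2L, 1L + ns)]
  nullwt_pp <- pp[seq.int(2L + ns, 1L + ns + N)]
  nullmut_pp <- matrix(pp[seq.int(2L + ns + N, length(pp))], N, ns)

  lapply(seq_len(ns), function(r) {
    obs <- maxDiscrepancyRegion(wt_pp, mut_pp[[r]], min_region)
    null_d <- vapply(seq_len(N), function(k)
      maxDiscrepancyRegion(nullwt_pp[[k]], nullmut_pp[[k, r]],
                           min_region)$d_obs, numeric(1))
    list(pos = subs$pos[[r]], from = subs$from[[r]], to = subs$to[[r]],
         d_obs = obs$d_obs, region = obs$region, null_d = null_d,
         p_raw = (1 + sum(null_d >= obs$d_obs)) / (N + 1))
  })
}

#' Multiple-testing correction of p-values
#'
#' \code{"bh"} applies the Benjamini-Hochberg step-up rule in its
#' recursive form: with p-values sorted in decreasing order
#' \eqn{p_1 \ge \dots \ge p_n}, \eqn{\tilde p_1 = \min(1, p_1)} and
#' \eqn{\tilde p_i = \min(1, \tilde p_{i-1}, \frac{n}{n-i+1} p_i)}.
#' \code{"bonferroni"} uses \eqn{\min(1, n p)}. Corrected values are
#' returned in the original input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method \code{"bh"} or \code{"bonferroni"}.
#' @return corrected p-values, same length and order as the input.
#' @examples
#' correctPvalues(c(0.9, 0.5, 0.01), "bh")  # 0.90 0.75 0.03
#' @export
correctPvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  n <- length(p)
  if (method == "bonferroni") return(pmin(1, n * p))
  o <- order(p, decreasing = TRUE)
  sorted <- p[o]
  corrected <- numeric(n)
  corrected[[1L]] <- min(1, sorted[[1L]])
  if (n > 1L) {
    for (i in 2:n) {
      corrected[[i]] <- min(1, corrected[[i - 1L]],
                            n / (n - i + 1) * sorted[[i]])
    }
  }
  out <- numeric(n)
  out[o] <- corrected
  out
}

#' Aggregate corrected p-values into a score
#'
#' The substitution score is \eqn{s = -\sum_i \log \tilde p_i} over the
#' corrected substitution p-values (natural logarithm by default); the
#' indel score aggregates the corrected indel p-values the same way. An
#' empty set scores 0, and p-values of 1 contribute nothing.
#'
#' @param p_corrected corrected p-values in (0, 1].
#' @param log_base logarithm base (default natural).
#' @return non-negative score.
#' @export
substitutionScore <- function(p_corrected, log_base = exp(1)) {
  if (!length(p_corrected)) return(0)
  if (any(p_corrected <= 0)) stop("p-values of zero cannot be scored")
  if (any(p_corrected > 1)) stop("p-values must lie in (0, 1]")
  -sum(log(p_corrected, base = log_base))
}

#' Combined selection score
#'
#' \eqn{SSS = 2 s + s'}: the substitution score enters with weight 2, the
#' indel score with weight 1.
#'
#' @param s_sub substitution score (>= 0).
#' @param s_indel indel score (>= 0).
#' @return the combined score.
#' @examples
#' sssScore(5, 2)  # 12
#' @export
sssScore <- function(s_sub, s_indel) {
  if (s_sub < 0 || s_indel < 0) stop("scores must be non-negative")
  2 * s_sub + s_indel
}

#' Classify a focal sequence from its score and family divergence
#'
#' No selection call is made for structurally heterogeneous families
#' (divergence above the cutoff). Otherwise a score at or above the
#' positive cutoff is labelled \code{positive}, at or below the conserved
#' cutoff \code{conserved} (negative selection), and \code{intermediate}
#' in between.
#'
#' @param score SSS-score of the focal sequence.
#' @param d family divergence.
#' @param positive_cutoff,conserved_cutoff,divergence_cutoff decision
#'   thresholds (defaults 10, 2 and 10).
#' @return one of \code{"positive"}, \code{"conserved"},
#'   \code{"intermediate"}, \code{"high_divergence"}.
#' @export
classifySelection <- function(score, d, positive_cutoff = 10,
                              conserved_cutoff = 2,
                              divergence_cutoff = 10) {
  stopifnot(positive_cutoff > conserved_cutoff, divergence_cutoff > 0)
  if (d > divergence_cutoff) return("high_divergence")
  if (score >= positive_cutoff) return("positive")
  if (score <= conserved_cutoff) return("conserved")
  "intermediate"
}
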