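## Region of maximal structural discrepancy between two pair-probability
## matrices, the localisation step of the substitution impact measure.

#' Region of maximal structural discrepancy
#'
#' Scans all contiguous sequence intervals of at least \code{min_len} nt
#' and returns the one maximising the length-normalised Euclidean
#' difference of the two base-pair probability matrices restricted to the
#' interval: \eqn{d(i,j) = \sqrt{\sum_{i \le k < l \le j} (P^{wt}_{kl} -
#' P^{mut}_{kl})^2} / (j - i + 1)}. Ties are resolved towards the shortest,
#' then leftmost interval. When the matrices are identical, or
#' \code{min_len} exceeds the sequence length, the full sequence is
#' returned by convention.
#'
#' @param p_wt,p_mut symmetric pair-probability matrices of equal
#'   dimension.
#' @param min_len minimum interval length in nt (default 20, capped at the
#'   sequence length).
#' @return list with \code{region} (integer start/end, 1-based inclusive)
#'   and \code{d_obs} (the discrepancy measure on that region).
#' @export
maxDiscrepancyRegion <- function(p_wt, p_mut, min_len = 20L) {
  if (!all(dim(p_wt) == dim(p_mut)))
    stop("pair probability matrices must have equal dimensions")
  stopifnot(min_len >= 1L)
  n <- nrow(p_wt)
  min_len <- min(as.integer(min_len), n)

  D <- (p_wt - p_mut)^2
  D[lower.tri(D, diag = TRUE)] <- 0
  if (sum(D) <= 0)
    return(list(region = c(1L, n), d_obs = 0))
  # 2D prefix sums: S[i..j, i..j] box sum picks up exactly the upper
  # triangle entries with both ends inside [i, j]
  C <- apply(apply(D, 2L, cumsum), 1L, cumsum)  # C[j, i] = sum D[1:i,1:j]
  C <- t(C)
  diagC <- diag(C)
  best <- list(d = -Inf, len = Inf, start = 1L, end = n)
  for (i in seq_len(n - min_len + 1L)) {
    j <- seq.int(i + min_len - 1L, n)
    s <- if (i > 1L)
      diagC[j] - C[i - 1L, j] - C[j, i - 1L] + C[i - 1L, i - 1L]
    else diagC[j]
    d <- sqrt(pmax(s, 0)) / (j - i + 1L)
    k <- which.max(d)  # smallest j among maxima: shortest, leftmost end
    cand <- d[[k]]
    len <- j[[k]] - i + 1L
    if (cand > best$d + 1e-12 ||
        (abs(cand - best$d) <= 1e-12 && len < best$len)) {
      best <- list(d = cand, len = len, start = i, end = j[[k]])
    }
  }
  list(region = c(best$start, best$end), d_obs = best$d)
}
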