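# Shared fixtures and independent oracles, all built in code.

# strong GC hairpin with an A-rich 3' tail; substitutions in the tail are
# structurally silent, substitutions in the stem are not
hairpin_tail <- function(tail = 20L) {
  paste0("GGGCGGGCGC", "GAAAG", "GCGCCCGCCC", strrep("A", tail))
}

# family of n identical rows
identical_family <- function(seq, n = 5L) {
  RNAFamily(setNames(rep(seq, n), sprintf("sp%d", seq_len(n))))
}

# random gapped alignment for shuffle tests
random_gapped_family <- function(n_rows = 4L, n_cols = 30L,
                                 gap_prob = 0.15) {
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- sample(c("A", "C", "G", "U"), n_cols, replace = TRUE)
    gaps <- runif(n_cols) < gap_prob
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  RNAFamily(setNames(rows, sprintf("sp%d", seq_len(n_rows))))
}

# random balanced dot-bracket string of the given length
random_structure <- function(len, pair_prob = 0.4) {
  out <- character(0)
  depth <- 0L
  for (k in seq_len(len)) {
    remaining <- len - k + 1L
    if (depth >= remaining) {
      out <- c(out, ")"); depth <- depth - 1L
    } else if (depth > 0L && runif(1) < pair_prob / 2) {
      out <- c(out, ")"); depth <- depth - 1L
    } else if (remaining > depth + 4L && runif(1) < pair_prob) {
      out <- c(out, "("); depth <- depth + 1L
    } else {
      out <- c(out, ".")
    }
  }
  paste(c(out, rep(")", depth)), collapse = "")
}

# Independent oracle: exhaustive memoised forest edit distance on the same
# cost model (unit insert/delete, matching only within node type). Forests
# are represented directly as dot-bracket strings.
forest_edit_oracle <- function(s1, s2) {
  memo <- new.env(parent = emptyenv())
  n_nodes <- function(s) {
    if (!nzchar(s)) return(0L)
    ch <- strsplit(s, "")[[1L]]
    sum(ch != ")")
  }
  split_last <- function(s) {
    # rightmost tree of the forest: returns list(rest, sub, is_pair)
    ch <- strsplit(s, "")[[1L]]
    n <- length(ch)
    if (ch[[n]] != ")")
      return(list(rest = substr(s, 1L, n - 1L), sub = "",
                  is_pair = FALSE))
    depth <- 0L
    for (k in n:1) {
      if (ch[[k]] == ")") depth <- depth + 1L
      if (ch[[k]] == "(") depth <- depth - 1L
      if (depth == 0L) break
    }
    list(rest = substr(s, 1L, k - 1L),
         sub = substr(s, k + 1L, n - 1L), is_pair = TRUE)
  }
  dist <- function(a, b) {
    if (!nzchar(a)) return(n_nodes(b))
    if (!nzchar(b)) return(n_nodes(a))
    key <- paste(a, b, sep = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    pa <- split_last(a); pb <- split_last(b)
    best <- min(
      dist(paste0(pa$rest, pa$sub), b) + 1L,  # delete root of a's last
      dist(a, paste0(pb$rest, pb$sub)) + 1L)  # insert root of b's last
    if (pa$is_pair == pb$is_pair) {
      best <- min(best, dist(pa$rest, pb$rest) + dist(pa$sub, pb$sub))
    }
    memo[[key]] <- best
    best
  }
  dist(s1, s2)
}

# Independent oracle for the BH step-up correction: closed form
# p~_(k) = min(1, min_{m <= k} n p_(m) / m) over p sorted ascending
# (equivalently the printed recursion over descending p-values).
bh_oracle <- function(p) {
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
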