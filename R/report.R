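## Report output: TSV table with a reproducibility header, optional JSON
## event detail.

#' Write selection reports as TSV
#'
#' One row per (family, focal species). A comment header records the
#' package version, folding-engine identity, seed and every configuration
#' value, sufficient to reproduce the run.
#'
#' @param reports a [SelectionReport-class] or list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(reports, path) {
  if (is(reports, "SelectionReport")) reports <- list(reports)
  tabs <- do.call(rbind, lapply(reports, reportTable))
  meta <- reports[[1L]]@metadata
  cfg <- meta$config
  hdr <- c(
    sprintf("# %s %s", meta$package, meta$version),
    sprintf("# engine: %s", meta$engine),
    sprintf("# seed: %s", if (is.null(meta$seed)) "none" else meta$seed),
    vapply(names(cfg), function(k)
      sprintf("# %s: %s", k, paste(format(cfg[[k]]), collapse = " ")),
      character(1))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tabs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-event detail of a report as a data.frame
#'
#' Flattens the scored substitution and indel events of every focal
#' species into one table (kind, columns, states, raw p-value).
#'
#' @param report a [SelectionReport-class].
#' @return data.frame (zero rows when no variants were scored).
#' @export
reportEvents <- function(report) {
  out <- list()
  for (sp in names(report@events)) {
    ev <- report@events[[sp]]
    for (part in c("substitutions", "indels")) {
      t <- ev[[part]]
      if (is.null(t) || !nrow(t)) next
      keep <- intersect(c("kind", "col_start", "col_end",
                          "consensus_state", "focal_state", "length",
                          "compensatory", "p_raw"), names(t))
      t <- t[, keep, drop = FALSE]
      t$species <- sp
      out[[length(out) + 1L]] <- t
    }
  }
  if (!length(out))
    return(data.frame(species = character(0), kind = character(0)))
  merged <- do.call(rbind, out)
  rownames(merged) <- NULL
  merged[, c("species", setdiff(names(merged), "species"))]
}
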