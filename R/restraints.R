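## Export of selected interface couplings as docking distance restraints.

#' Export interface couplings as docking restraints
#'
#' Writes candidate interface pairs either as a TSV table (one line per
#' pair with its scores) or as `air_text`, a versioned plain-text dialect
#' of ambiguous-interaction-restraint blocks: one `assign` statement per
#' pair restraining the C-alpha--C-alpha distance between the two chain
#' copies to at most `upper_bound` Angstrom.  Output ordering is
#' deterministic (decreasing score), so re-export is byte-identical.
#'
#' @param candidates an [interface_candidates()] result (or any data frame
#'   with res_i, res_j and a score column).
#' @param format `"tsv"` or `"air_text"`.
#' @param upper_bound upper distance bound in Angstrom (default 10).
#' @param chain_a,chain_b chain identifiers of the two docking partners.
#' @param top_k optionally keep only the k best-scoring pairs.
#' @param path optional output file.
#' @return The file content as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
export_restraints <- function(candidates, format = c("tsv", "air_text"),
                              upper_bound = 10.0, chain_a = "A", chain_b = "B",
                              top_k = NULL, path = NULL) {
  format <- match.arg(format)
  if (upper_bound <= 0) stop_("upper_bound must be positive")
  score <- candidates$score_norm %||% candidates$score_apc %||%
    candidates$score
  if (!is.null(score) && nrow(candidates) > 1L)
    candidates <- candidates[order(-score), , drop = FALSE]
  if (!is.null(top_k)) candidates <- utils::head(candidates, top_k)
  if (format == "air_text" && nrow(candidates) == 0L)
    stop_("no candidate pairs to export; use format = 'tsv' for an empty table")
  lines <- switch(format,
    tsv = restraints_tsv(candidates, upper_bound, chain_a, chain_b),
    air_text = restraints_air(candidates, upper_bound, chain_a, chain_b))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

restraints_tsv <- function(cand, upper_bound, chain_a, chain_b) {
  df <- data.frame(chain_a = rep(chain_a, nrow(cand)),
                   res_a = cand$res_i, chain_b = rep(chain_b, nrow(cand)),
                   res_b = cand$res_j,
                   upper_bound = rep(upper_bound, nrow(cand)),
                   score_apc = cand$score_apc %||% rep(NA_real_, nrow(cand)),
                   score_norm = cand$score_norm %||% rep(NA_real_, nrow(cand)),
                   z = cand$z %||% rep(NA_real_, nrow(cand)))
  c(paste(names(df), collapse = "\t"),
    if (nrow(df)) apply(df, 1L, function(r) paste(trimws(r), collapse = "\t")))
}

restraints_air <- function(cand, upper_bound, chain_a, chain_b) {
  hdr <- c("! coevoring AIR restraints v1",
           sprintf("! %d pair(s), CA-CA upper bound %.1f A", nrow(cand),
                   upper_bound))
  blocks <- vapply(seq_len(nrow(cand)), function(k) {
    sprintf(
      "assign (segid %s and resid %d and name CA) (segid %s and resid %d and name CA) %.1f %.1f 0.0",
      chain_a, cand$res_i[[k]], chain_b, cand$res_j[[k]],
      upper_bound, upper_bound)
  }, character(1L))
  c(hdr, blocks)
}

#' Parse an exported restraint TSV back into a table
#'
#' @param path_or_lines file path or character vector of TSV lines.
#' @return Data frame with chain_a, res_a, chain_b, res_b, upper_bound and
#'   score columns.
#' @export
parse_restraints_tsv <- function(path_or_lines) {
  txt <- if (length(path_or_lines) == 1L && file.exists(path_or_lines))
    readLines(path_or_lines) else path_or_lines
  utils::read.table(text = txt, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
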