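## Projection of alignment columns and coupling scores onto structures.

#' Map alignment columns onto structure residues
#'
#' Globally aligns the ungapped reference row of the alignment against the
#' one-letter sequence of a structure chain (match +1, mismatch 0, gap -1)
#' and records, for every alignment column whose reference residue aligned
#' to a structure residue, the corresponding author residue number.
#'
#' @param x an [msa] object.
#' @param s a `structure_model`.
#' @param chain chain identifier in `s`.
#' @param min_coverage error below this fraction of mapped columns
#'   (default 0.3).
#' @return Object of class `column_residue_map`: data frame `pairs`
#'   (col, chain, resno) and scalar `coverage`.
#' @export
map_columns_to_residues <- function(x, s, chain, min_coverage = 0.3) {
  stopifnot(inherits(x, "msa"), inherits(s, "structure_model"))
  ref <- reference_row(x)
  ref_cols <- which(ref != GAP)
  refseq <- paste(ref[ref_cols], collapse = "")
  chseq <- structure_sequence(s, chain)
  if (!nzchar(refseq) || !nzchar(chseq))
    stop_("empty reference or chain sequence")
  al <- align_global(refseq, chseq)
  chres <- s$atoms$resno[s$atoms$chain == chain]
  ## only aligned positions with identical residues are trusted: the
  ## structure row is expected to be (near-)identical to the reference, and
  ## this makes unrelated sequences fail the coverage check instead of
  ## producing a spurious end-to-end mismatch alignment
  hit <- al$p_gapped != "-" & al$s_gapped == al$p_gapped
  cols <- ref_cols[al$p_pos[hit]]
  resno <- chres[al$s_pos[hit]]
  coverage <- length(cols) / msa_length(x)
  if (coverage < min_coverage)
    stop_("reference/structure mismatch: only %.0f%% of columns mapped to chain %s",
          100 * coverage, chain)
  structure(list(pairs = data.frame(col = cols, chain = chain, resno = resno,
                                    stringsAsFactors = FALSE),
                 coverage = coverage, chain = chain),
            class = "column_residue_map")
}

## Needleman-Wunsch global alignment via Biostrings (match +1, mismatch 0,
## linear gap -1).  Returns gapped strings plus, per alignment position,
## the 1-based index into each ungapped input (NA at gaps).
align_global <- function(a, b) {
  alpha <- c(AA20, "X")
  sm <- matrix(0, length(alpha), length(alpha),
               dimnames = list(alpha, alpha))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 1)
  pg <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sg <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  p_pos <- ifelse(pg != "-", cumsum(pg != "-"), NA_integer_)
  s_pos <- ifelse(sg != "-", cumsum(sg != "-"), NA_integer_)
  list(p_gapped = pg, s_gapped = sg, p_pos = p_pos, s_pos = s_pos)
}

#' Project couplings onto a structure
#'
#' For every coupling, computes the intra-chain C-alpha distance (minimum
#' over the chains considered) and the minimal cross-chain distance over
#' ordered chain pairings, then classifies the pair: `fold` if the
#' intra-chain distance is below the cutoff, else `interface` if the
#' cross-chain minimum is, else `none`.  Couplings whose columns are not in
#' the map are flagged `mapped = FALSE` and excluded from statistics.
#'
#' @param couplings coupling data frame (from [coevolution_scores()]).
#' @param map a [map_columns_to_residues()] result; the residue numbering
#'   is applied to every chain considered (identical copies in an
#'   oligomer).
#' @param s a `structure_model`.
#' @param chains chains to consider (default: all chains of `s`).
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @return Data frame of class `mapped_couplings`: the coupling columns
#'   plus res_i, res_j, d_intra, d_inter_min, contact_class, mapped.
#' @export
project_couplings <- function(couplings, map, s, chains = NULL, cutoff = 10.0) {
  stopifnot(inherits(map, "column_residue_map"),
            inherits(s, "structure_model"))
  chains <- chains %||% s$chains
  if (length(chains) == 0L) stop_("no chains to project onto")
  lookup <- map$pairs
  coord <- function(chain, resno) {
    k <- which(s$atoms$chain == chain & s$atoms$resno == resno)
    if (length(k) == 0L) return(NULL)
    as.numeric(s$atoms[k[[1L]], c("x", "y", "z")])
  }
  n <- nrow(couplings)
  res_i <- res_j <- rep(NA_integer_, n)
  d_intra <- d_inter <- rep(NA_real_, n)
  cls <- rep("none", n)
  mapped <- rep(FALSE, n)
  for (k in seq_len(n)) {
    mi <- match(couplings$col_i[[k]], lookup$col)
    mj <- match(couplings$col_j[[k]], lookup$col)
    if (is.na(mi) || is.na(mj)) next
    ri <- lookup$resno[[mi]]; rj <- lookup$resno[[mj]]
    res_i[[k]] <- ri; res_j[[k]] <- rj
    dintra <- Inf; dinter <- Inf
    any_intra <- FALSE; any_inter <- FALSE
    for (c1 in chains) {
      p1 <- coord(c1, ri); q1 <- coord(c1, rj)
      if (!is.null(p1) && !is.null(q1)) {
        any_intra <- TRUE
        dintra <- min(dintra, sqrt(sum((p1 - q1)^2)))
      }
      for (c2 in setdiff(chains, c1)) {
        q2 <- coord(c2, rj)
        if (!is.null(p1) && !is.null(q2)) {
          any_inter <- TRUE
          dinter <- min(dinter, sqrt(sum((p1 - q2)^2)))
        }
      }
    }
    if (!any_intra && !any_inter) next
    mapped[[k]] <- TRUE
    if (any_intra) d_intra[[k]] <- dintra
    if (any_inter) d_inter[[k]] <- dinter
    cls[[k]] <- if (any_intra && dintra < cutoff) "fold"
                else if (any_inter && dinter < cutoff) "interface"
                else "none"
  }
  out <- cbind(couplings,
               data.frame(res_i = res_i, res_j = res_j, d_intra = d_intra,
                          d_inter_min = d_inter, contact_class = cls,
                          mapped = mapped, stringsAsFactors = FALSE))
  attr(out, "cutoff") <- cutoff
  class(out) <- c("mapped_couplings", class(out))
  out
}

#' Validation statistics for mapped couplings
#'
#' Class counts, precision (fraction of couplings landing on a fold or
#' interface contact) and the mean +/- standard error of the chosen
#' distance over mapped couplings.
#'
#' @param mapped a [project_couplings()] result.
#' @param distance_choice `"min"` (elementwise min of intra and inter),
#'   `"intra"` or `"inter"`.
#' @return List of class `validation_report`: n_couplings, n_fold,
#'   n_interface, n_none, precision, mean_d, sem_d, n_distance, table.
#' @export
validation_stats <- function(mapped, distance_choice = c("min", "intra", "inter")) {
  distance_choice <- match.arg(distance_choice)
  m <- mapped[mapped$mapped, , drop = FALSE]
  if (nrow(m) == 0L) stop_("no mapped couplings")
  d <- switch(distance_choice,
              intra = m$d_intra,
              inter = m$d_inter_min,
              min = pmin(m$d_intra, m$d_inter_min, na.rm = TRUE))
  d <- d[is.finite(d)]
  if (length(d) == 0L) stop_("no couplings with a defined '%s' distance",
                             distance_choice)
  n_fold <- sum(m$contact_class == "fold")
  n_int <- sum(m$contact_class == "interface")
  n_none <- sum(m$contact_class == "none")
  sem <- if (length(d) > 1L) stats::sd(d) / sqrt(length(d)) else 0
  structure(list(n_couplings = nrow(m), n_fold = n_fold,
                 n_interface = n_int, n_none = n_none,
                 precision = (n_fold + n_int) / nrow(m),
                 mean_d = mean(d), sem_d = sem, n_distance = length(d),
                 single_n = length(d) == 1L,
                 distance_choice = distance_choice, table = m),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "validation_report: %d couplings (fold %d, interface %d, none %d); precision %.2f; mean d = %.1f +/- %.1f A (%s, n=%d)\n",
    x$n_couplings, x$n_fold, x$n_interface, x$n_none, x$precision,
    x$mean_d, x$sem_d, x$distance_choice, x$n_distance))
  invisible(x)
}

#' Candidate interface restraint pairs
#'
#' Selects couplings suitable as docking restraints: high normalised score,
#' not explained by the monomer fold (intra-chain distance at or above the
#' contact cutoff) and with both residues surface-exposed.  Exposure uses a
#' C-alpha coordination-number proxy: a residue is exposed when the number
#' of C-alpha neighbours within 10 A (in the designated monomer chain) does
#' not exceed `exposure_max_neighbors`.
#'
#' @param mapped a [project_couplings()] result.
#' @param s a `structure_model`.
#' @param chain the monomer chain used for the exposure computation.
#' @param score_min minimum normalised score (default 0.2, strict `>`).
#' @param exposure_max_neighbors maximum neighbour count (default 14).
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @return The selected rows of `mapped`, sorted by decreasing score;
#'   possibly empty.
#' @export
interface_candidates <- function(mapped, s, chain, score_min = 0.2,
                                 exposure_max_neighbors = 14L, cutoff = 10.0) {
  stopifnot(inherits(s, "structure_model"))
  a <- s$atoms[s$atoms$chain == chain, ]
  if (nrow(a) == 0L) stop_("chain '%s' not present", chain)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  nb <- rowSums(cross_dist(xyz, xyz) < 10.0) - 1
  neighbors <- function(resno) {
    k <- match(resno, a$resno)
    if (is.na(k)) NA_real_ else nb[[k]]
  }
  m <- mapped[mapped$mapped, , drop = FALSE]
  score <- m$score_norm %||% m$score_apc
  keep <- score > score_min &
    !is.na(m$d_intra) & m$d_intra >= cutoff &
    vapply(m$res_i, neighbors, numeric(1L)) <= exposure_max_neighbors &
    vapply(m$res_j, neighbors, numeric(1L)) <= exposure_max_neighbors
  keep[is.na(keep)] <- FALSE
  out <- m[keep, , drop = FALSE]
  out[order(-score[keep]), , drop = FALSE]
}
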