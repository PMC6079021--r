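## MSA preparation: redundancy clustering, family filtering, trimming to a
## structure sequence, sequence weighting, depth checks and paired
## concatenation of two-protein alignments.

## One-hot encoding of an alignment over the 20-state amino-acid alphabet.
## Returns X (N x 20L, gap rows all-zero at that column) and NG (N x L
## non-gap indicator); both dense, so the pairwise-identity and frequency
## computations below run through BLAS.
msa_onehot <- function(x) {
  ali <- x$ali
  n <- nrow(ali); l <- ncol(ali)
  codes <- match(ali, AA20)           # N*L, NA for gap
  X <- matrix(0, n, 20L * l)
  ok <- !is.na(codes)
  rows <- row(ali)[ok]
  cols <- (col(ali)[ok] - 1L) * 20L + codes[ok]
  X[cbind(rows, cols)] <- 1
  NG <- matrix(as.numeric(ok), n, l)
  list(X = X, NG = NG)
}

#' Pairwise sequence identity within an alignment
#'
#' Identity between two aligned rows is the number of identical residues
#' divided by the number of columns where both rows are non-gap; columns in
#' which either row has a gap are excluded.  Rows sharing no non-gap column
#' have identity 0.
#'
#' @param x an [msa] object.
#' @return An N x N symmetric matrix of identities in `[0, 1]`.
#' @export
identity_matrix <- function(x) {
  oh <- msa_onehot(x)
  matches <- tcrossprod(oh$X)
  shared <- tcrossprod(oh$NG)
  id <- matches / pmax(shared, 1)
  id[shared == 0] <- 0
  id
}

#' Greedy identity clustering of aligned sequences
#'
#' CD-HIT-like greedy incremental clustering: rows are processed in order of
#' decreasing ungapped length (ties broken by input order) and joined to the
#' first existing cluster whose representative has pairwise identity at or
#' above the threshold; otherwise they seed a new cluster.  The
#' representative of a cluster is its founding (longest-ungapped) member.
#'
#' @param x an [msa] object.
#' @param identity identity threshold in `[0, 1]`.
#' @return A list of clusters, each a list with `members` (original row
#'   indices) and `representative` (one row index).
#' @export
cluster_sequences <- function(x, identity = 0.9) {
  stopifnot(inherits(x, "msa"))
  if (!is.numeric(identity) || identity < 0 || identity > 1)
    stop_("identity threshold must lie in [0, 1], got %s", identity)
  idm <- identity_matrix(x)
  lens <- rowSums(x$ali != GAP)
  ord <- order(-lens, seq_along(lens))
  reps <- integer()
  assign <- integer(msa_depth(x))
  for (r in ord) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (idm[r, reps[[k]]] >= identity) { hit <- k; break }
    }
    if (hit == 0L) { reps <- c(reps, r); hit <- length(reps) }
    assign[[r]] <- hit
  }
  lapply(seq_along(reps), function(k)
    list(members = which(assign == k), representative = reps[[k]]))
}

#' Restrict an alignment to clusters related to the reference sequence
#'
#' Removes clusters (e.g. non-flagellar homologs in a mixed Pfam family)
#' whose representative falls below a minimum identity to the reference row.
#' The reference row itself is always retained.
#'
#' @param x an [msa] object.
#' @param clusters output of [cluster_sequences()].
#' @param min_ref_identity minimum representative-to-reference identity.
#' @return A filtered [msa]; if nothing but the reference survives, a
#'   reference-only alignment is returned with a warning.
#' @export
filter_to_reference_family <- function(x, clusters, min_ref_identity = 0.2) {
  stopifnot(inherits(x, "msa"))
  refidx <- match(x$reference_id, x$ids)
  ref <- x$ali[refidx, ]
  keep <- integer()
  for (cl in clusters) {
    rep_row <- x$ali[cl$representative, ]
    if (row_identity(rep_row, ref) >= min_ref_identity)
      keep <- c(keep, cl$members)
  }
  keep <- sort(unique(c(keep, refidx)))
  if (length(keep) == 1L)
    warn_("all clusters fell below identity %.3g to the reference; returning reference-only alignment",
          min_ref_identity)
  subset_msa_rows(x, keep)
}

row_identity <- function(a, b) {
  both <- a != GAP & b != GAP
  if (!any(both)) return(0)
  sum(a[both] == b[both]) / sum(both)
}

subset_msa_rows <- function(x, rows) {
  out <- msa(x$ali[rows, , drop = FALSE], x$ids[rows], x$reference_id)
  out$colmap <- x$colmap
  attr(out, "boundary") <- attr(x, "boundary")
  out
}

#' Trim alignment columns to those resolved in a structure sequence
#'
#' Removes every column in which the named row (typically the row holding
#' the sequence of a crystal structure) has a gap, so that all remaining
#' columns correspond to residues present in the structure.  The column map
#' is renumbered to that row's residue numbering.
#'
#' @param x an [msa] object.
#' @param structure_row_id identifier of the row whose residues define the
#'   retained columns.
#' @return The trimmed [msa]; `colmap` gives the 1-based residue number of
#'   each kept column in the named row.
#' @export
trim_to_reference_columns <- function(x, structure_row_id) {
  stopifnot(inherits(x, "msa"))
  idx <- match(structure_row_id, x$ids)
  if (is.na(idx)) stop_("row '%s' not found in alignment", structure_row_id)
  keep <- x$ali[idx, ] != GAP
  if (!any(keep)) stop_("row '%s' is all gaps: trimming would empty the alignment",
                        structure_row_id)
  out <- msa(x$ali[, keep, drop = FALSE], x$ids, x$reference_id)
  out$colmap <- seq_len(sum(keep))
  attr(out, "boundary") <- NULL
  out
}

#' PSICOV-style sequence redundancy weights
#'
#' Each row is weighted by the reciprocal of the number of rows (itself
#' included) with pairwise identity at or above `theta`; the sum of weights
#' is the effective depth `n_eff`.
#'
#' @param x an [msa] object.
#' @param theta identity threshold (default 0.62).
#' @return An object of class `sequence_weights`: list with `weights`,
#'   `theta`, `n_eff`.
#' @export
sequence_weights <- function(x, theta = 0.62) {
  stopifnot(inherits(x, "msa"))
  idm <- identity_matrix(x)
  w <- 1 / rowSums(idm >= theta)
  structure(list(weights = w, theta = theta, n_eff = sum(w)),
            class = "sequence_weights")
}

#' Alignment depth-to-length ratio
#'
#' The ratio of sequence depth N to alignment length L must exceed 0.3 for
#' the coevolution signal to be considered statistically meaningful; the
#' check is strict (`N/L = 0.3` fails).
#'
#' @param x an [msa] object.
#' @return List with `ratio`, `pass`, `n`, `l`.
#' @export
depth_ratio <- function(x) {
  stopifnot(inherits(x, "msa"))
  n <- msa_depth(x); l <- msa_length(x)
  if (l < 1L) stop_("alignment has no columns")
  if (n < 1L) stop_("alignment has no sequences")
  list(ratio = n / l, pass = (n / l) > 0.3, n = n, l = l)
}

#' Concatenate two alignments row-wise by a pairing key
#'
#' Joins rows of two single-domain alignments end-to-end to form composite
#' (e.g. fused two-protein) sequences for inter-domain coevolution analysis.
#' Rows are paired by exact identifier match by default, or by the organism
#' field of Pfam-style identifiers (`NAME_ORG/start-end`).  Unpaired rows
#' are dropped with a message.
#'
#' @param msa_a,msa_b [msa] objects.
#' @param pairing_key `"exact_id"` or `"organism_field"`.
#' @return An [msa] of width `L_a + L_b`; the index of the last column of
#'   the first domain is recorded in the `"boundary"` attribute.
#' @export
concatenate_paired <- function(msa_a, msa_b,
                               pairing_key = c("exact_id", "organism_field")) {
  pairing_key <- match.arg(pairing_key)
  keyfun <- switch(pairing_key,
    exact_id = identity,
    organism_field = function(ids) {
      base <- sub("/.*$", "", ids)
      vapply(strsplit(base, "_"), function(p) p[[length(p)]], character(1L))
    })
  ka <- keyfun(msa_a$ids); kb <- keyfun(msa_b$ids)
  if (anyDuplicated(ka)) stop_("duplicate pairing key in first alignment: %s",
                               ka[duplicated(ka)][[1L]])
  if (anyDuplicated(kb)) stop_("duplicate pairing key in second alignment: %s",
                               kb[duplicated(kb)][[1L]])
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) stop_("no shared pairing keys between alignments")
  dropped <- (length(ka) - length(shared)) + (length(kb) - length(shared))
  if (dropped > 0L) message(sprintf("concatenate_paired: dropped %d unpaired rows",
                                    dropped))
  ia <- match(shared, ka); ib <- match(shared, kb)
  ali <- cbind(msa_a$ali[ia, , drop = FALSE], msa_b$ali[ib, , drop = FALSE])
  refkey <- keyfun(msa_a$reference_id)
  refid <- if (refkey %in% shared) refkey else shared[[1L]]
  out <- msa(ali, shared, refid)
  attr(out, "boundary") <- msa_length(msa_a)
  out
}
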