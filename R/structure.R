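## Atomic structures reduced to one C-alpha per residue, and the contact
## maps derived from them.

#' Construct a C-alpha structure model from an atom table
#'
#' @param atoms data frame with columns chain, resno, ins, aa, x, y, z (one
#'   C-alpha per residue, coordinates in Angstrom).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "ins", "aa", "x", "y", "z") %in%
                  names(atoms)))
  key <- paste(atoms$chain, atoms$resno, atoms$ins)
  if (anyDuplicated(key))
    stop_("duplicate residue after altloc resolution: %s",
          key[duplicated(key)][[1L]])
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$ins), ]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chains = unique(atoms$chain)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d C-alpha in %d chain(s) [%s]\n",
              nrow(x$atoms), length(x$chains),
              paste(x$chains, collapse = ",")))
  invisible(x)
}

#' Read a PDB structure as a C-alpha model
#'
#' Parses ATOM records (via bio3d), keeps one C-alpha per residue, resolves
#' alternate locations by the chosen policy and drops HETATM/water records.
#' Residues without a C-alpha (disordered) are skipped, not imputed.
#'
#' @param path PDB file path.
#' @param altloc_policy `"highest_occupancy"` (ties broken by altloc
#'   letter) or `"first"`.
#' @param chain_filter optional character vector of chain identifiers to
#'   retain.
#' @return A `structure_model`: data frame `atoms` with chain, author
#'   residue number (`resno`), insertion code (`ins`), one-letter `aa` and
#'   C-alpha coordinates in Angstrom.
#' @export
read_structure <- function(path, altloc_policy = c("highest_occupancy", "first"),
                           chain_filter = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop_("structure file not found: %s", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!is.null(chain_filter)) at <- at[at$chain %in% chain_filter, , drop = FALSE]
  if (nrow(at) == 0L) stop_("no C-alpha atoms found in %s", path)
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$ins)
  pickfun <- switch(altloc_policy,
    highest_occupancy = function(rows) rows[order(-at$o[rows],
                                                  at$alt[rows])][1L],
    first = function(rows) rows[[1L]])
  keep <- vapply(split(seq_len(nrow(at)), key), function(rows) {
    alt <- at$alt[rows]
    alt[is.na(alt)] <- ""
    if (length(unique(alt)) == 1L && length(rows) > 1L)
      stop_("duplicate residue id %s after altloc resolution",
            key[rows[[1L]]])
    if (length(rows) == 1L) rows else pickfun(rows)
  }, integer(1L))
  at <- at[sort(keep), , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa) | !aa %in% AA20] <- "X"
  structure_model(data.frame(chain = at$chain, resno = at$resno,
                                 ins = at$ins, aa = aa,
                                 x = at$x, y = at$y, z = at$z,
                                 stringsAsFactors = FALSE))
}

#' One-letter sequence of a chain
#'
#' @param s a `structure_model`.
#' @param chain chain identifier.
#' @return Character scalar (residues in chain order).
#' @export
structure_sequence <- function(s, chain) {
  stopifnot(inherits(s, "structure_model"))
  a <- s$atoms[s$atoms$chain == chain, ]
  if (nrow(a) == 0L) stop_("chain '%s' not present", chain)
  paste(a$aa, collapse = "")
}

structure_coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' C-alpha contact map of a structure
#'
#' Residue pairs with C-alpha distance strictly below `cutoff` are
#' contacts.  Same-chain pairs closer than `min_separation` in residue
#' numbering are excluded (trivial backbone neighbours); inter-chain pairs
#' are never separation-filtered.  Storage is canonical: same-chain pairs
#' have `res_i < res_j`, cross-chain pairs `chain_i < chain_j`.
#'
#' @param s a `structure_model`.
#' @param cutoff distance cutoff in Angstrom (default 10, strict `<`).
#' @param min_separation minimum intra-chain residue separation (default 5).
#' @return Object of class `contact_map`: data frame `entries` (chain_i,
#'   res_i, chain_j, res_j, distance, class in `{intra, inter}`) plus the
#'   parameters.
#' @export
contact_map <- function(s, cutoff = 10.0, min_separation = 5L) {
  stopifnot(inherits(s, "structure_model"))
  xyz <- structure_coords(s)
  d <- cross_dist(xyz, xyz)
  n <- nrow(xyz)
  hit <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  a <- s$atoms
  ci <- a$chain[hit[, 1L]]; cj <- a$chain[hit[, 2L]]
  ri <- a$resno[hit[, 1L]]; rj <- a$resno[hit[, 2L]]
  dist <- d[hit]
  intra <- ci == cj
  keep <- !intra | abs(ri - rj) >= min_separation
  ci <- ci[keep]; cj <- cj[keep]; ri <- ri[keep]; rj <- rj[keep]
  dist <- dist[keep]; intra <- intra[keep]
  ## canonical order
  swap <- (intra & ri > rj) | (!intra & ci > cj)
  tmpc <- ci[swap]; ci[swap] <- cj[swap]; cj[swap] <- tmpc
  tmpr <- ri[swap]; ri[swap] <- rj[swap]; rj[swap] <- tmpr
  entries <- data.frame(chain_i = ci, res_i = ri, chain_j = cj, res_j = rj,
                        distance = dist,
                        class = ifelse(intra, "intra", "inter"),
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$class, entries$chain_i, entries$res_i,
                           entries$chain_j, entries$res_j), ]
  rownames(entries) <- NULL
  structure(list(entries = entries, cutoff = cutoff,
                 min_separation = min_separation),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  tab <- table(x$entries$class)
  cat(sprintf("contact_map: %d contacts (< %.1f A; intra %d, inter %d)\n",
              nrow(x$entries), x$cutoff,
              sum(x$entries$class == "intra"),
              sum(x$entries$class == "inter")))
  invisible(x)
}

#' Write a C-alpha model as PDB text
#'
#' @param s a `structure_model` or ring model atom table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  a <- if (inherits(s, "structure_model")) s$atoms else s
  aa3 <- vapply(a$aa, function(x) {
    y <- suppressWarnings(bio3d::aa123(x))
    if (is.na(y)) "ALA" else y
  }, character(1L))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(a)) %% 100000L, aa3, substr(a$chain, 1L, 1L),
    a$resno %% 10000L, ifelse(nzchar(a$ins), a$ins, " "),
    a$x, a$y, a$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
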