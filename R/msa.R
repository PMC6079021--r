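#' Multiple sequence alignment container
#'
#' An `msa` object stores an aligned protein family as a character matrix of
#' single residues over the alphabet of the 20 amino acids plus the gap
#' character `-`.  One row is designated the reference (seed) sequence; the
#' column map `colmap` gives, for every alignment column, the 1-based residue
#' number in the reference sequence (`NA` where the reference row has a gap).
#'
#' @param ali character matrix (N rows x L columns) of single characters.
#' @param ids character vector of N unique sequence identifiers.
#' @param reference_id identifier of the reference row (default: first row).
#' @return An object of class `msa` with elements `ali`, `ids`,
#'   `reference_id`, `colmap` and a `boundary` attribute for concatenated
#'   alignments (column index of the last column of the first domain, or
#'   `NULL`).
#' @export
msa <- function(ali, ids, reference_id = ids[[1L]]) {
  if (!is.matrix(ali) || !is.character(ali))
    stop_("'ali' must be a character matrix of single residues")
  if (nrow(ali) < 1L) stop_("alignment must contain at least one sequence")
  if (length(ids) != nrow(ali)) stop_("length(ids) must equal nrow(ali)")
  if (anyDuplicated(ids)) stop_("duplicate sequence identifiers")
  if (!reference_id %in% ids) stop_("reference_id '%s' not found", reference_id)
  rownames(ali) <- NULL
  x <- structure(list(ali = ali, ids = as.character(ids),
                      reference_id = reference_id),
                 class = "msa")
  x$colmap <- reference_colmap(x)
  x
}

reference_colmap <- function(x) {
  ref <- x$ali[match(x$reference_id, x$ids), ]
  cm <- rep(NA_integer_, length(ref))
  nongap <- ref != GAP
  cm[nongap] <- seq_len(sum(nongap))
  cm
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (reference '%s')\n",
              nrow(x$ali), ncol(x$ali), x$reference_id))
  invisible(x)
}

#' @rdname msa
#' @param x an `msa` object.
#' @export
msa_depth <- function(x) nrow(x$ali)

#' @rdname msa
#' @export
msa_length <- function(x) ncol(x$ali)

reference_row <- function(x) x$ali[match(x$reference_id, x$ids), ]

## Normalize raw alignment characters: uppercase, '.' -> '-', unknown -> '-'.
## Returns list(chars, n_unknown).
normalize_chars <- function(chars) {
  chars <- toupper(chars)
  chars[chars %in% c(".", "~")] <- GAP
  known <- chars %in% c(AA20, GAP)
  n_unknown <- sum(!known)
  chars[!known] <- GAP
  list(chars = chars, n_unknown = n_unknown)
}

seqs_to_ali <- function(seqs, ids, a2m_lower_is_insert = FALSE) {
  if (a2m_lower_is_insert) {
    ## A2M insert states (lowercase and '.') are unaligned; drop them.
    seqs <- vapply(seqs, function(s)
      gsub("[a-z.]", "", s), character(1L), USE.NAMES = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop_("alignment rows have unequal lengths (%s): not a valid alignment",
          paste(unique(lens), collapse = ", "))
  if (lens[1L] == 0L) stop_("alignment rows are empty")
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  nm <- normalize_chars(m)
  if (nm$n_unknown > 0L)
    warn_("%d non-standard residue characters mapped to gap", nm$n_unknown)
  matrix(nm$chars, nrow = length(seqs))
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA/A2M or Stockholm file into an [msa] object.
#' Residues are uppercased; `.` and unrecognized characters become gaps
#' (with a warning for the latter).  Under the A2M dialect
#' (`a2m_lower_is_insert = TRUE`) lowercase residues and `.` are treated as
#' unaligned insert states and removed; by default lowercase letters are
#' simply uppercased in place.
#'
#' @param path path to the alignment file.
#' @param format one of `"auto"`, `"fasta"`, `"stockholm"`.  `"auto"` sniffs
#'   the first non-blank line (`# STOCKHOLM` or `>`).
#' @param reference_id reference row identifier (default: first sequence).
#' @param a2m_lower_is_insert logical A2M dialect switch (see Details).
#' @return An [msa] object.  For Stockholm input with a `#=GC RF` line, the
#'   reference mask is attached as attribute `"rf"`.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm"),
                     reference_id = NULL, a2m_lower_is_insert = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("alignment file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1L]
    if (is.na(first)) stop_("empty alignment file: %s", path)
    format <- if (grepl("^#\\s*STOCKHOLM", first)) "stockholm" else "fasta"
  }
  parsed <- if (format == "stockholm") parse_stockholm(lines)
            else parse_fasta(lines)
  if (length(parsed$seqs) == 0L) stop_("no sequences found in %s", path)
  ali <- seqs_to_ali(parsed$seqs, parsed$ids, a2m_lower_is_insert)
  out <- msa(ali, parsed$ids, reference_id %||% parsed$ids[[1L]])
  if (!is.null(parsed$rf)) attr(out, "rf") <- parsed$rf
  out
}

parse_fasta <- function(lines) {
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_("no FASTA headers found")
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1L), 1L)
  body <- split(lines[!hdr & idx > 0L], idx[!hdr & idx > 0L])
  seqs <- vapply(body, function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1L), USE.NAMES = FALSE)
  list(ids = ids, seqs = seqs, rf = NULL)
}

## Minimal Stockholm 1.0 parser: multi-block sequence lines keyed by name,
## '#=GC RF' captured as the reference mask, everything else ignored.
parse_stockholm <- function(lines) {
  seqs <- list()
  order <- character()
  rf <- ""
  for (ln in lines) {
    if (grepl("^//", ln)) break
    if (!nzchar(trimws(ln))) next
    if (grepl("^#", ln)) {
      if (grepl("^#=GC\\s+RF\\s", ln)) {
        parts <- strsplit(trimws(ln), "\\s+")[[1L]]
        rf <- paste0(rf, parts[[length(parts)]])
      }
      next
    }
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L)
      stop_("malformed Stockholm sequence line: '%s'", ln)
    nm <- parts[[1L]]
    if (is.null(seqs[[nm]])) order <- c(order, nm)
    seqs[[nm]] <- paste0(seqs[[nm]] %||% "", parts[[2L]])
  }
  list(ids = order, seqs = unlist(seqs[order], use.names = FALSE),
       rf = if (nzchar(rf)) rf else NULL)
}

#' Write an alignment as aligned FASTA
#'
#' @param x an [msa] object.
#' @param path output file path.
#' @param width line-wrap width for sequence text.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "msa"))
  seqs <- apply(x$ali, 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(x$ids)) {
    writeLines(paste0(">", x$ids[[k]]), con)
    s <- seqs[[k]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
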