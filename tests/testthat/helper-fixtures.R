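# Fixture builders shared across test files; everything is generated in
# code, no data files.

make_msa <- function(rows, ids = sprintf("s%d", seq_along(rows)),
                     reference_id = ids[[1L]]) {
  ali <- do.call(rbind, strsplit(rows, ""))
  msa(ali, ids, reference_id)
}

write_fasta_tmp <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), rows)), path)
  path
}

write_stockholm_tmp <- function(rows, ids = sprintf("s%d", seq_along(rows)),
                                rf = NULL) {
  path <- tempfile(fileext = ".sto")
  lines <- c("# STOCKHOLM 1.0",
             paste(ids, rows),
             if (!is.null(rf)) paste("#=GC RF", rf),
             "//")
  writeLines(lines, path)
  path
}

# Minimal PDB text: one CA ATOM record per row of the spec list
# list(chain=, resno=, x=, y=, z=, alt="", occ=1, ins="", resid="ALA")
write_pdb_tmp <- function(residues) {
  path <- tempfile(fileext = ".pdb")
  lines <- vapply(seq_along(residues), function(k) {
    r <- residues[[k]]
    alt <- r$alt %||% " "
    ins <- r$ins %||% " "
    occ <- r$occ %||% 1
    resid <- r$resid %||% "ALA"
    sprintf("ATOM  %5d  CA %1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f  0.00           C",
            k, alt, resid, r$chain, r$resno, ins, r$x, r$y, r$z, occ)
  }, character(1L))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A Cn dimer: compact random subunit at the given ring radius, chain B the
# copy rotated by 360/n about z.
make_cn_dimer <- function(n, radius = 60, size = 30, seed = 3) {
  set.seed(seed)
  blob <- matrix(rnorm(size * 3), size, 3) * 3
  blob <- sweep(blob, 2, colMeans(blob))
  A <- sweep(blob, 2, c(radius, 0, 0), `+`)
  ang <- 2 * pi / n
  B <- cbind(cos(ang) * A[, 1] - sin(ang) * A[, 2],
             sin(ang) * A[, 1] + cos(ang) * A[, 2], A[, 3])
  atoms <- rbind(
    data.frame(chain = "A", resno = seq_len(size), ins = "", aa = "A",
               x = A[, 1], y = A[, 2], z = A[, 3]),
    data.frame(chain = "B", resno = seq_len(size), ins = "", aa = "A",
               x = B[, 1], y = B[, 2], z = B[, 3]))
  structure_model(atoms)
}

# Empirical mutual information (nats) between two alignment columns,
# gaps excluded.
mi_pair <- function(ali, i, j) {
  a <- ali[, i]; b <- ali[, j]
  ok <- a != "-" & b != "-"
  tab <- table(a[ok], b[ok]) / sum(ok)
  pa <- rowSums(tab); pb <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
}

skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
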