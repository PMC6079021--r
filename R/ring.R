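## Cyclic-symmetry analysis: rotation relating the chains of a homodimer,
## Cn ring construction, and the ring arithmetic (tangent angles, diameter,
## clashes, volume and stoichiometry).

## Kabsch least-squares superposition: rotation R and translation t with
## R p + t ~ q.  Implemented directly (svd with determinant correction)
## because the rotation matrix and axis, not just fitted coordinates, are
## needed downstream.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L)
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, pc), sweep(Q, 2L, qc))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qc - as.numeric(R %*% pc)
  fitted <- sweep(tcrossprod(P, R), 2L, t, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

rotation_axis_angle <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (sin(ang) > 1e-6) {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(ang))
  } else {
    ## angle ~ 0 or ~ pi: take the eigenvector of eigenvalue 1
    ev <- eigen(R)
    k <- which.min(abs(ev$values - 1))
    axis <- Re(ev$vectors[, k])
    axis <- axis / sqrt(sum(axis^2))
  }
  list(angle = ang, axis = axis)
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Cyclic symmetry relating the two chains of a homodimer
#'
#' Superposes chain A onto chain B (Kabsch, over residues shared by author
#' numbering) and extracts the rotation angle, axis and a point on the
#' axis.  For a dimer cut from a Cn ring the implied ring order is
#' `round(360 / angle)`.
#'
#' @param s a `structure_model` with (at least) two chains.
#' @param chain_a,chain_b the two chains (default: first two).
#' @return Object of class `dimer_symmetry`: `angle` (degrees), `axis`
#'   (unit vector), `axis_point`, `implied_order`, `superposition_rmsd`.
#' @export
dimer_symmetry <- function(s, chain_a = NULL, chain_b = NULL) {
  stopifnot(inherits(s, "structure_model"))
  chain_a <- chain_a %||% s$chains[[1L]]
  chain_b <- chain_b %||% s$chains[[2L]]
  a <- s$atoms[s$atoms$chain == chain_a, ]
  b <- s$atoms[s$atoms$chain == chain_b, ]
  shared <- intersect(a$resno, b$resno)
  if (length(shared) < 3L)
    stop_("chains %s and %s share fewer than 3 residues", chain_a, chain_b)
  P <- as.matrix(a[match(shared, a$resno), c("x", "y", "z")])
  Q <- as.matrix(b[match(shared, b$resno), c("x", "y", "z")])
  fit <- kabsch(P, Q)
  ra <- rotation_axis_angle(fit$R)
  angle_deg <- ra$angle * 180 / pi
  if (angle_deg < 1)
    stop_("no cyclic relation: chains are related by a near-pure translation (angle %.3f deg)",
          angle_deg)
  ## point on the axis: least-squares solution of (I - R) p = t_perp
  u <- ra$axis
  t_perp <- fit$t - sum(fit$t * u) * u
  M <- diag(3L) - fit$R
  sv <- svd(M)
  pos <- sv$d > 1e-8 * max(sv$d)
  p0 <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% t_perp) / sv$d[pos])
  structure(list(angle = angle_deg, axis = u,
                 axis_point = as.numeric(p0),
                 implied_order = as.integer(round(360 / angle_deg)),
                 superposition_rmsd = fit$rmsd),
            class = "dimer_symmetry")
}

#' @export
print.dimer_symmetry <- function(x, ...) {
  cat(sprintf(
    "dimer_symmetry: rotation %.3f deg (implied C%d), superposition rmsd %.3f A\n",
    x$angle, x$implied_order, x$superposition_rmsd))
  invisible(x)
}

#' Build an n-fold symmetric ring from a subunit
#'
#' Places `n` copies of the model at rotations of `k * 360 / n` degrees
#' (k = 0..n-1) about the symmetry axis.  When no axis is given it is
#' inferred with [dimer_symmetry()] for multi-chain input, or taken as the
#' z axis through the origin for a pre-aligned single chain.
#'
#' @param s a `structure_model` (typically a homodimer).
#' @param n number of copies (>= 1).
#' @param axis,axis_point symmetry axis (unit vector) and a point on it.
#' @return Object of class `ring_model`: `atoms` (with `copy` index and
#'   cycled chain labels), `n`, `axis`, `axis_point`, and `symmetry_rmsd`
#'   (discrepancy between the ring rotated by 360/n and itself).
#' @export
build_ring <- function(s, n, axis = NULL, axis_point = NULL) {
  stopifnot(inherits(s, "structure_model"))
  n <- as.integer(n)
  if (n <= 0L) stop_("ring order must be positive")
  if (is.null(axis)) {
    if (length(s$chains) >= 2L) {
      ds <- dimer_symmetry(s)
      axis <- ds$axis; axis_point <- ds$axis_point
    } else {
      axis <- c(0, 0, 1); axis_point <- c(0, 0, 0)
    }
  }
  axis <- axis / sqrt(sum(axis^2))
  axis_point <- axis_point %||% c(0, 0, 0)
  xyz0 <- sweep(structure_coords(s), 2L, axis_point)
  pool <- c(LETTERS, letters)
  m <- nrow(s$atoms)
  pieces <- lapply(0:(n - 1L), function(k) {
    R <- rotation_about_axis(axis, 2 * pi * k / n)
    xyz <- sweep(tcrossprod(xyz0, R), 2L, axis_point, `+`)
    chain_idx <- (k * length(s$chains) +
                    match(s$atoms$chain, s$chains) - 1L) %% length(pool) + 1L
    data.frame(copy = k, chain = pool[chain_idx], resno = s$atoms$resno,
               ins = s$atoms$ins, aa = s$atoms$aa,
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, pieces)
  ## symmetry self-consistency: rotating copy k by 360/n must give copy k+1
  if (n > 1L) {
    R1 <- rotation_about_axis(axis, 2 * pi / n)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    rot <- sweep(tcrossprod(sweep(xyz, 2L, axis_point), R1), 2L, axis_point,
                 `+`)
    target <- xyz[c((m + 1L):(n * m), 1:m), , drop = FALSE]
    srmsd <- sqrt(mean(rowSums((rot - target)^2)))
  } else srmsd <- 0
  structure(list(atoms = atoms, n = n, axis = axis, axis_point = axis_point,
                 subunit_atoms = m, symmetry_rmsd = srmsd),
            class = "ring_model")
}

#' @export
print.ring_model <- function(x, ...) {
  cat(sprintf("ring_model: C%d, %d atoms (%d per subunit), symmetry rmsd %.2g A\n",
              x$n, nrow(x$atoms), x$subunit_atoms, x$symmetry_rmsd))
  invisible(x)
}

#' Ring diameter and steric-clash count
#'
#' Diameter is twice the largest radial C-alpha distance from the symmetry
#' axis.  Clashes are C-alpha pairs from non-adjacent subunits (circular
#' adjacency; for n = 2 the single pair of copies is counted) closer than
#' `clash_cutoff`.
#'
#' @param ring a [build_ring()] result.
#' @param clash_cutoff clash distance in Angstrom (default 3).
#' @return List with `diameter`, `clash_count`, `symmetry_rmsd`.
#' @export
ring_metrics <- function(ring, clash_cutoff = 3.0) {
  stopifnot(inherits(ring, "ring_model"))
  xyz <- as.matrix(ring$atoms[, c("x", "y", "z")])
  rel <- sweep(xyz, 2L, ring$axis_point)
  along <- as.numeric(rel %*% ring$axis)
  radial <- sqrt(rowSums((rel - outer(along, ring$axis))^2))
  copy <- ring$atoms$copy
  d <- cross_dist(xyz, xyz)
  ck <- abs(outer(copy, copy, `-`))
  circ <- pmin(ck, ring$n - ck)
  nonadj <- if (ring$n > 2L) circ >= 2L else circ >= 1L
  clash <- sum(d < clash_cutoff & nonadj & upper.tri(d))
  list(diameter = 2 * max(radial), clash_count = clash,
       symmetry_rmsd = ring$symmetry_rmsd)
}

#' Write a ring model as multi-chain PDB text
#'
#' @param ring a [build_ring()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ring_pdb <- function(ring, path) {
  stopifnot(inherits(ring, "ring_model"))
  write_structure_pdb(ring$atoms, path)
}

#' Chord--tangent angles of regular n-gons
#'
#' The angle between a side of a regular n-gon and the tangent of its
#' circumscribed circle is `180 / n` degrees; it measures the curvature a
#' subunit must accommodate in a Cn ring.  Returns the two angles and their
#' absolute difference, quantifying how little the subunit geometry must
#' change between two candidate ring symmetries.
#'
#' @param n1,n2 ring orders (>= 3).
#' @return List with `theta1`, `theta2`, `delta` (degrees).
#' @export
tangent_angle_delta <- function(n1, n2) {
  if (n1 < 3 || n2 < 3) stop_("ring order must be >= 3")
  t1 <- 180 / n1; t2 <- 180 / n2
  list(theta1 = t1, theta2 = t2, delta = abs(t1 - t2))
}

#' Ring volume from monomer mass
#'
#' `V = monomer_mw * copies * gamma`, with the specific volume `gamma` in
#' cubic Angstrom per Dalton.
#'
#' @param monomer_mw monomer molecular weight (Da).
#' @param copies subunit count.
#' @param gamma specific volume (default 1.28 A^3/Da; the common
#'   literature value 1.21 may be substituted).
#' @return Volume in cubic Angstrom.
#' @export
volume_from_mass <- function(monomer_mw, copies, gamma = 1.28) {
  if (monomer_mw <= 0 || copies <= 0 || gamma <= 0)
    stop_("all inputs must be positive")
  monomer_mw * copies * gamma
}

#' Stoichiometry implied by an observed (EM) volume
#'
#' Inverts [volume_from_mass()], correcting for the fraction of the
#' sequence actually present in the fitted models:
#' `n = V / (coverage * monomer_mw * gamma)`.
#'
#' @param observed_volume fitted map volume (A^3).
#' @param monomer_mw monomer molecular weight (Da).
#' @param coverage fraction of the sequence accounted for, in (0, 1].
#' @param gamma specific volume (A^3/Da).
#' @return List with `estimate` (real-valued) and `n` (rounded).
#' @export
estimate_stoichiometry <- function(observed_volume, monomer_mw, coverage = 1,
                                   gamma = 1.28) {
  if (coverage <= 0 || coverage > 1) stop_("coverage must lie in (0, 1]")
  if (observed_volume <= 0 || monomer_mw <= 0 || gamma <= 0)
    stop_("all inputs must be positive")
  est <- observed_volume / (coverage * monomer_mw * gamma)
  list(estimate = est, n = round(est))
}

#' Fraction of a sequence covered by residue intervals
#'
#' @param segments list of 1-based inclusive `c(start, end)` intervals (or
#'   a 2-column matrix).
#' @param total_length sequence length.
#' @return Union length of the merged intervals divided by `total_length`.
#' @export
sequence_coverage <- function(segments, total_length) {
  if (total_length < 1) stop_("total_length must be >= 1")
  if (is.matrix(segments)) segments <- asplit(segments, 1L)
  if (length(segments) == 0L) return(0)
  segs <- do.call(rbind, lapply(segments, function(s) {
    s <- as.numeric(s)
    if (s[[2L]] < s[[1L]]) stop_("inverted interval (%g, %g)", s[[1L]], s[[2L]])
    if (s[[1L]] < 1 || s[[2L]] > total_length)
      stop_("interval (%g, %g) outside [1, %d]", s[[1L]], s[[2L]], total_length)
    s
  }))
  segs <- segs[order(segs[, 1L]), , drop = FALSE]
  total <- 0; cur <- segs[1L, ]
  for (k in seq_len(nrow(segs))[-1L]) {
    s <- segs[k, ]
    if (s[[1L]] <= cur[[2L]] + 1 - 1) cur[[2L]] <- max(cur[[2L]], s[[2L]])
    else { total <- total + cur[[2L]] - cur[[1L]] + 1; cur <- s }
  }
  total <- total + cur[[2L]] - cur[[1L]] + 1
  total / total_length
}
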