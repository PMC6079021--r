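## Coevolution scoring: weighted amino-acid frequencies -> covariance over
## the 20L one-hot states -> sparse inverse covariance (graphical lasso) ->
## per-column-pair coupling scores -> average product correction ->
## sigma-normalisation and thresholding.

#' Weighted single- and pair-column amino-acid frequencies
#'
#' Counts are taken over the 20 amino-acid states only: a row contributes to
#' a column's counts only where it has a residue there, and to a column
#' pair's joint counts only where it has residues at both positions.  A
#' pseudocount of total mass `lambda` mixes the observed frequencies with
#' the uniform distribution: `f <- (1 - l') f_obs + l' u` with
#' `l' = lambda / (lambda + n_eff)` and `u = 1/20` (single) or `1/400`
#' (pair).  Diagonal blocks of the joint table are the single-column
#' frequencies on their diagonal, giving the multinomial covariance form.
#'
#' @param x an [msa] object.
#' @param weights a [sequence_weights] object (default: uniform weight 1).
#' @param lambda pseudocount mass (default 1).
#' @return Object of class `frequency_model`: `f1` (L x 20), `f2`
#'   (20L x 20L), `lambda`, `lambda_prime`, `n_eff`, `L`.
#' @export
pair_frequencies <- function(x, weights = NULL, lambda = 1.0) {
  stopifnot(inherits(x, "msa"))
  l <- msa_length(x)
  if (l < 2L) stop_("need at least 2 columns")
  w <- if (is.null(weights)) rep(1, msa_depth(x)) else weights$weights
  n_eff <- sum(w)
  oh <- msa_onehot(x)
  cw <- as.numeric(crossprod(oh$NG, w))      # per-column non-gap weight
  if (any(cw == 0))
    stop_("column %d has no non-gap rows", which(cw == 0)[[1L]])

  lp <- lambda / (lambda + n_eff)
  Xw <- oh$X * w
  f1 <- matrix(colSums(Xw), nrow = l, ncol = 20L, byrow = TRUE) / cw
  f1 <- (1 - lp) * f1 + lp / 20

  Wp <- crossprod(oh$NG * w, oh$NG)          # pairwise non-gap weight (L x L)
  denom <- Wp[rep(seq_len(l), each = 20L), rep(seq_len(l), each = 20L)]
  f2 <- crossprod(Xw, oh$X) / pmax(denom, .Machine$double.eps)
  f2 <- (1 - lp) * f2 + lp / 400
  ## diagonal blocks: joint of a column with itself is diag(f1_i)
  for (i in seq_len(l)) {
    idx <- ((i - 1L) * 20L + 1L):(i * 20L)
    f2[idx, idx] <- diag(f1[i, ])
  }
  structure(list(f1 = f1, f2 = f2, lambda = lambda, lambda_prime = lp,
                 n_eff = n_eff, L = l),
            class = "frequency_model")
}

#' Covariance matrix over one-hot amino-acid states
#'
#' `C[(i,a),(j,b)] = f2_ij(a,b) - f1_i(a) f1_j(b)`; diagonal blocks take the
#' multinomial form `f(a)(delta_ab - f(b))`.
#'
#' @param fm a [pair_frequencies()] result.
#' @return A symmetric 20L x 20L covariance matrix.
#' @export
build_covariance <- function(fm) {
  stopifnot(inherits(fm, "frequency_model"))
  f1vec <- as.numeric(t(fm$f1))              # (i,a) fast in a
  C <- fm$f2 - tcrossprod(f1vec)
  (C + t(C)) / 2
}

#' Sparse precision (inverse covariance) estimate
#'
#' Estimates the L1-penalised inverse covariance by graphical-lasso block
#' coordinate descent; the penalty `rho` applies to off-diagonal entries.
#' At `rho = 0` the (unique) solution is the direct inverse and is computed
#' by Cholesky inversion.  If the input is not positive definite its
#' diagonal is strengthened with a ridge of `ridge * mean(diag)` (doubled
#' until a Cholesky factorisation succeeds).
#'
#' @param cov symmetric covariance matrix.
#' @param rho penalty (>= 0).
#' @param tol relative convergence tolerance on the covariance update.
#' @param maxit maximum outer sweeps.
#' @param inner_maxit maximum coordinate-descent passes per column.
#' @param ridge relative ridge used when `cov` is not positive definite.
#' @return The precision matrix, with attributes `niter` and `rho`.
#' @export
sparse_precision <- function(cov, rho = 0.005, tol = 1e-3, maxit = 200L,
                             inner_maxit = 50L, ridge = 1e-4) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov))
    stop_("'cov' must be a square matrix")
  if (rho < 0) stop_("rho must be >= 0")
  C <- (cov + t(cov)) / 2
  eps <- ridge * mean(diag(C))
  for (k in 0:40) {
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (!is.null(ch)) break
    C <- C + diag(eps, nrow(C))
    eps <- 2 * eps
  }
  if (is.null(ch)) stop_("covariance matrix could not be made positive definite")
  if (rho == 0) {
    P <- chol2inv(ch)
  } else {
    fit <- cpp_glasso(C, rho, tol, as.integer(maxit), as.integer(inner_maxit))
    if (!fit$converged)
      stop_("graphical lasso did not converge in %d sweeps (tol %g); last sweep %d",
            maxit, tol, fit$niter)
    P <- fit$theta
    attr(P, "niter") <- fit$niter
  }
  attr(P, "rho") <- rho
  P
}

#' Per-column-pair coupling score matrix
#'
#' The coupling score for columns i and j is the sum of absolute values of
#' the 20 x 20 block of the precision matrix linking their amino-acid
#' states; the diagonal is set to zero.
#'
#' @param precision a 20L x 20L precision matrix.
#' @param L number of alignment columns (default inferred).
#' @return A symmetric L x L matrix of non-negative scores, zero diagonal.
#' @export
psicov_score_matrix <- function(precision, L = NULL) {
  p <- nrow(precision)
  L <- L %||% (p %/% 20L)
  if (p != 20L * L)
    stop_("precision dimension %d does not match 20 x L = %d", p, 20L * L)
  PS <- cpp_block_abs_sum(precision, 20L)
  diag(PS) <- 0
  (PS + t(PS)) / 2
}

#' Average product correction
#'
#' Subtracts the entropic/phylogenetic background `(mean_i * mean_j) /
#' mean_all` from each score, where `mean_i` is the mean of row i over
#' off-diagonal entries and `mean_all` the mean over all i < j pairs.
#'
#' @param raw symmetric score matrix with zero diagonal, L >= 3.
#' @return The corrected matrix (zero diagonal).
#' @export
apc_correct <- function(raw) {
  l <- nrow(raw)
  if (l < 3L) stop_("APC needs at least 3 columns")
  if (max(abs(raw - t(raw))) > 1e-8) stop_("score matrix must be symmetric")
  if (max(abs(diag(raw))) > 1e-12) stop_("score matrix must have zero diagonal")
  rowmean <- rowSums(raw) / (l - 1L)
  mean_all <- sum(raw) / (l * (l - 1L))
  if (mean_all == 0) {
    warn_("overall mean score is zero; APC not applied")
    return(raw)
  }
  apc <- raw - outer(rowmean, rowmean) / mean_all
  diag(apc) <- 0
  apc
}

eligible_pairs <- function(l, min_separation) {
  ut <- which(upper.tri(matrix(0, l, l)), arr.ind = TRUE)
  ut[ut[, 2L] - ut[, 1L] >= min_separation, , drop = FALSE]
}

#' Standardise scores and extract top couplings
#'
#' Z-normalises the corrected score matrix over eligible pairs (column
#' separation `|i - j| >= min_separation`), using the population standard
#' deviation, and returns every pair above `sigma_cut` sorted by decreasing
#' z.  A min-max normalised score over eligible pairs is also reported.
#'
#' @param apc corrected score matrix.
#' @param sigma_cut threshold in sigma units (commonly 2.5 or 3).
#' @param min_separation minimum column separation (default 5).
#' @param colmap optional column -> reference residue number map used for
#'   the reported `i`, `j` (defaults to column indices).
#' @param raw optional raw score matrix carried through to the output table.
#' @return List with `z` (full standardized matrix, zero diagonal),
#'   `couplings` (data frame: i, j, col_i, col_j, score_raw, score_apc,
#'   score_norm, z), `fraction_above`, `mu`, `sd`.
#' @export
normalize_and_threshold <- function(apc, sigma_cut = 3.0, min_separation = 5L,
                                    colmap = NULL, raw = NULL) {
  l <- nrow(apc)
  el <- eligible_pairs(l, min_separation)
  if (nrow(el) < 10L)
    stop_("only %d eligible pairs (need >= 10); reduce min_separation", nrow(el))
  s <- apc[el]
  mu <- mean(s)
  sdev <- sqrt(mean((s - mu)^2))
  if (sdev == 0) stop_("degenerate score distribution (zero variance)")
  zmat <- (apc - mu) / sdev
  diag(zmat) <- 0
  zel <- (s - mu) / sdev
  rng <- range(s)
  norm <- if (diff(rng) > 0) (s - rng[[1L]]) / diff(rng) else rep(0, length(s))
  keep <- which(zel > sigma_cut)
  ord <- keep[order(zel[keep], decreasing = TRUE)]
  cm <- colmap %||% seq_len(l)
  couplings <- data.frame(
    i = cm[el[ord, 1L]], j = cm[el[ord, 2L]],
    col_i = el[ord, 1L], col_j = el[ord, 2L],
    score_raw = if (is.null(raw)) NA_real_ else raw[el[ord, , drop = FALSE]],
    score_apc = s[ord], score_norm = norm[ord], z = zel[ord])
  list(z = zmat, couplings = couplings,
       fraction_above = length(keep) / nrow(el),
       sigma_cut = sigma_cut, min_separation = min_separation,
       mu = mu, sd = sdev)
}

#' Within-column shuffle null alignment
#'
#' Independently permutes the rows of every column, preserving each
#' column's residue (and gap) composition while destroying all inter-column
#' covariance.  Used as the randomisation control: rescoring the shuffled
#' alignment yields a symmetric score distribution with no coupling signal.
#'
#' @param x an [msa] object.
#' @param seed integer seed; the same seed reproduces the same shuffle.
#' @return A shuffled [msa] (ids, reference and column map unchanged).
#' @export
column_shuffle_null <- function(x, seed) {
  stopifnot(inherits(x, "msa"))
  n <- msa_depth(x)
  if (n < 2L) stop_("need at least 2 sequences to shuffle")
  ali <- x$ali
  with_seed(seed, {
    for (j in seq_len(ncol(ali))) ali[, j] <- ali[sample.int(n), j]
  })
  out <- msa(ali, x$ids, x$reference_id)
  out$colmap <- x$colmap
  attr(out, "boundary") <- attr(x, "boundary")
  out
}

#' Full coevolution scoring pipeline for one alignment
#'
#' Runs sequence weighting, frequency estimation, covariance construction,
#' sparse precision estimation, block scoring, average product correction
#' and sigma-normalisation; the one-stop entry point for scoring an MSA.
#'
#' @param x an [msa] object.
#' @param weights optional precomputed [sequence_weights()].
#' @param lambda pseudocount mass (default 1).
#' @param theta weighting identity threshold (default 0.62).
#' @param rho graphical-lasso penalty (default 0.005).
#' @param sigma_cut coupling threshold in sigma units (default 3).
#' @param min_separation minimum column separation (default 5).
#' @return Object of class `coevolution_result`: matrices `raw`, `apc`,
#'   `z`; `couplings` data frame; `fraction_above` at `sigma_cut`, 2.5 and
#'   3 sigma; `meta` with all parameters, `n_eff` and the domain boundary of
#'   concatenated alignments (inter-domain couplings are flagged in the
#'   table as `inter_domain`).
#' @export
coevolution_scores <- function(x, weights = NULL, lambda = 1.0, theta = 0.62,
                               rho = 0.005, sigma_cut = 3.0,
                               min_separation = 5L) {
  stopifnot(inherits(x, "msa"))
  if (is.null(weights)) weights <- sequence_weights(x, theta)
  fm <- pair_frequencies(x, weights, lambda)
  C <- build_covariance(fm)
  P <- sparse_precision(C, rho = rho)
  raw <- psicov_score_matrix(P, fm$L)
  apc <- apc_correct(raw)
  nt <- normalize_and_threshold(apc, sigma_cut, min_separation,
                                colmap = x$colmap, raw = raw)
  frac <- vapply(c(sigma_cut = sigma_cut, sigma_2.5 = 2.5, sigma_3 = 3.0),
                 function(ct) {
                   el <- eligible_pairs(fm$L, min_separation)
                   mean((apc[el] - nt$mu) / nt$sd > ct)
                 }, numeric(1L))
  couplings <- nt$couplings
  b <- attr(x, "boundary")
  if (!is.null(b))
    couplings$inter_domain <- couplings$col_i <= b & couplings$col_j > b
  structure(list(raw = raw, apc = apc, z = nt$z, couplings = couplings,
                 fraction_above = frac, mu = nt$mu, sd = nt$sd,
                 meta = list(lambda = lambda, theta = theta, rho = rho,
                             sigma_cut = sigma_cut,
                             min_separation = min_separation,
                             n_eff = weights$n_eff, n = msa_depth(x),
                             l = fm$L, boundary = b)),
            class = "coevolution_result")
}

#' @export
print.coevolution_result <- function(x, ...) {
  cat(sprintf(
    "coevolution_result: L=%d, N=%d (n_eff %.1f), %d couplings > %.2f sigma (%.2f%% of pairs)\n",
    x$meta$l, x$meta$n, x$meta$n_eff, nrow(x$couplings), x$meta$sigma_cut,
    100 * x$fraction_above[[1L]]))
  invisible(x)
}

#' Write coupling scores as TSV
#'
#' One line per eligible pair above the threshold: 1-based reference
#' numbering, raw, APC, min-max normalised and z scores.
#'
#' @param result a [coevolution_scores()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(result, path) {
  stopifnot(inherits(result, "coevolution_result"))
  utils::write.table(result$couplings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
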