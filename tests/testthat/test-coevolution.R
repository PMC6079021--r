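test_that("pair frequencies match hand counts and obey the pseudocount limit", {
  # two perfectly correlated columns, half (A,A), half (C,C)
  x <- make_msa(c("AA", "AA", "CC", "CC"))
  fm <- pair_frequencies(x, lambda = 0)
  expect_equal(fm$f1[1, match("A", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])],
               0.5)
  blk <- fm$f2[1:20, 21:40]
  aa <- match("A", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  cc <- match("C", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(blk[aa, aa], 0.5)
  expect_equal(blk[cc, cc], 0.5)
  expect_equal(sum(blk), 1)
  # lambda -> infinity drives f1 to uniform
  fm_inf <- pair_frequencies(x, lambda = 1e9)
  expect_equal(max(abs(fm_inf$f1 - 1 / 20)), 0, tolerance = 1e-6)
  # a column of only gaps is an error naming the column
  y <- make_msa(c("A-C", "A-C"))
  expect_error(pair_frequencies(y), "column 2")
})

test_that("joint-frequency marginals agree with single-column frequencies", {
  sim <- simulate_msa(L = 8, N = 60, gap_rate = 0, seed = 2)
  fm <- pair_frequencies(sim$msa, sequence_weights(sim$msa), lambda = 1)
  for (i in 1:2) for (j in 5:6) {
    blk <- fm$f2[((i - 1) * 20 + 1):(i * 20), ((j - 1) * 20 + 1):(j * 20)]
    expect_equal(sum(blk), 1, tolerance = 1e-9)
    expect_equal(rowSums(blk), fm$f1[i, ], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(colSums(blk), fm$f1[j, ], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("covariance has the multinomial diagonal and vanishing independent blocks", {
  sim <- simulate_msa(L = 6, N = 4000, gap_rate = 0, n_founders = 4000,
                      seed = 3)
  fm <- pair_frequencies(sim$msa, lambda = 0)
  C <- build_covariance(fm)
  # diagonal block: f(a)(delta_ab - f(b))
  f <- fm$f1[1, ]
  expect_equal(C[1:20, 1:20], diag(f) - outer(f, f), tolerance = 1e-12,
               ignore_attr = TRUE)
  # independent columns: off-diagonal blocks shrink like 1/sqrt(N)
  off <- C[1:20, 21:120]
  expect_lt(max(abs(off)), 3 / sqrt(4000))
  # constant column: all its covariance entries are exactly zero
  const <- make_msa(c("AC", "AD", "AE", "AF", "AC", "AD"))
  Cc <- build_covariance(pair_frequencies(const, lambda = 0))
  expect_equal(max(abs(Cc[1:20, 21:40])), 0)
})

test_that("sparse precision at rho = 0 equals the brute-force inverse", {
  expect_equal(sparse_precision(diag(8), rho = 0), diag(8),
               ignore_attr = TRUE)
  set.seed(11)
  for (p in c(8, 24, 40)) {
    A <- crossprod(matrix(rnorm(p * p), p)) / p + diag(p) * 0.2
    P <- sparse_precision(A, rho = 0)
    ref <- solve(A)                       # independent brute-force oracle
    expect_lt(max(abs(P - ref)) / max(abs(ref)), 1e-6)
  }
})

test_that("penalised precision satisfies the glasso optimality conditions", {
  set.seed(5)
  p <- 25
  A <- crossprod(matrix(rnorm(p * p), p)) / p + diag(p) * 0.3
  rho <- 0.06
  Th <- sparse_precision(A, rho = rho, tol = 1e-7)
  G <- solve(Th) - A                       # must equal rho * subgradient
  expect_lt(max(abs(diag(G) - rho)), 1e-6)
  offd <- G[upper.tri(G)]
  expect_lt(max(abs(offd)) - rho, 1e-6)
  nz <- which(upper.tri(Th) & abs(Th) > 1e-9)
  expect_lt(max(abs(G[nz] - rho * sign(Th[nz]))), 1e-6)
  # heavy penalty kills all off-diagonal structure
  Th_big <- sparse_precision(A, rho = 100)
  expect_equal(Th_big, diag(diag(Th_big)), ignore_attr = TRUE)
})

test_that("block score matrix sums absolute values of 20x20 blocks", {
  L <- 3
  P <- matrix(0, 20 * L, 20 * L)
  diag(P) <- 1
  expect_equal(psicov_score_matrix(P), matrix(0, L, L))
  P[3, 25] <- 0.5; P[25, 3] <- 0.5            # single entry in block (1,2)
  expect_equal(psicov_score_matrix(P)[1, 2], 0.5)
  P[5, 30] <- -0.2; P[30, 5] <- -0.2
  P[3, 25] <- 0.1; P[25, 3] <- 0.1            # entries {0.1, -0.2} -> 0.3
  expect_equal(psicov_score_matrix(P)[1, 2], 0.3)
  expect_equal(psicov_score_matrix(P)[2, 1], 0.3)
  expect_error(psicov_score_matrix(matrix(0, 30, 30)), "does not match")
})

test_that("average product correction reproduces the hand-worked example", {
  raw <- matrix(0, 3, 3)
  raw[1, 2] <- raw[2, 1] <- 1
  raw[1, 3] <- raw[3, 1] <- 2
  raw[2, 3] <- raw[3, 2] <- 3
  apc <- apc_correct(raw)
  # row means (1.5, 2, 2.5), overall mean 2
  expect_equal(apc[1, 2], -0.5, tolerance = 1e-12)
  expect_equal(apc[1, 3], 0.125, tolerance = 1e-12)
  expect_equal(apc[2, 3], 0.5, tolerance = 1e-12)
  # constant matrix cancels exactly
  cm <- matrix(2, 5, 5); diag(cm) <- 0
  expect_equal(apc_correct(cm), matrix(0, 5, 5))
  # brute-force recomputation on random matrices
  set.seed(8)
  for (rep in 1:5) {
    l <- 7
    m <- matrix(0, l, l)
    m[upper.tri(m)] <- runif(l * (l - 1) / 2, 0.1, 2)
    m <- m + t(m)
    got <- apc_correct(m)
    for (i in 1:(l - 1)) for (j in (i + 1):l) {
      mi <- mean(m[i, -i]); mj <- mean(m[j, -j])
      ma <- mean(m[upper.tri(m)])
      expect_equal(got[i, j], m[i, j] - mi * mj / ma, tolerance = 1e-12)
    }
  }
})

test_that("z-normalisation uses the population sd and strict threshold", {
  l <- 10
  apc <- matrix(0, l, l)
  el <- which(upper.tri(apc) & col(apc) - row(apc) >= 5, arr.ind = TRUE)
  set.seed(2)
  vals <- rnorm(nrow(el))
  apc[el] <- vals; apc <- apc + t(apc)
  nt <- normalize_and_threshold(apc, sigma_cut = -Inf, min_separation = 5)
  # all eligible pairs returned, sorted by z
  expect_equal(nrow(nt$couplings), nrow(el))
  expect_true(all(diff(nt$couplings$z) <= 0))
  # z computed with the population sd: mean 0, sd 1 over eligible pairs
  expect_equal(mean(nt$couplings$z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(nt$couplings$z^2)), 1, tolerance = 1e-9)
  # oracle: hand z-score of the largest value
  expect_equal(nt$couplings$z[1],
               (max(vals) - mean(vals)) / sqrt(mean((vals - mean(vals))^2)),
               tolerance = 1e-12)
  # degenerate distribution errors
  flat <- matrix(1, l, l); diag(flat) <- 0
  expect_error(normalize_and_threshold(flat, 2, 5), "degenerate")
  expect_error(normalize_and_threshold(apc, 2, min_separation = 9),
               "eligible")
})

test_that("column shuffle preserves composition and is seed-deterministic", {
  sim <- simulate_msa(L = 12, N = 40, gap_rate = 0.1, seed = 6)
  sh1 <- column_shuffle_null(sim$msa, seed = 42)
  sh2 <- column_shuffle_null(sim$msa, seed = 42)
  expect_identical(sh1$ali, sh2$ali)
  expect_false(identical(sh1$ali, column_shuffle_null(sim$msa, 43)$ali))
  for (j in seq_len(12)) {
    expect_identical(sort(sh1$ali[, j]), sort(sim$msa$ali[, j]))
  }
})

test_that("scores are equivariant under column permutation", {
  sim <- simulate_msa(L = 18, N = 400, planted_pairs = 2, gap_rate = 0.05,
                      seed = 12)
  res <- coevolution_scores(sim$msa, sigma_cut = -Inf)
  set.seed(1)
  perm <- sample(18)
  xp <- msa(sim$msa$ali[, perm], sim$msa$ids)
  resp <- coevolution_scores(xp, sigma_cut = -Inf)
  # raw and apc matrices permute with the columns (up to solver tolerance)
  expect_lt(max(abs(resp$raw - res$raw[perm, perm])) / max(res$raw), 1e-3)
  expect_lt(max(abs(resp$apc - res$apc[perm, perm])) / max(abs(res$apc)),
            5e-3)
})

test_that("duplicating every sequence leaves the raw score matrix unchanged", {
  sim <- simulate_msa(L = 15, N = 150, planted_pairs = 2, gap_rate = 0.05,
                      seed = 13)
  x <- sim$msa
  res <- coevolution_scores(x, sigma_cut = -Inf)
  dup <- msa(rbind(x$ali, x$ali), c(x$ids, paste0(x$ids, "_dup")))
  wd <- sequence_weights(dup)
  w <- sequence_weights(x)
  expect_equal(wd$n_eff, w$n_eff, tolerance = 1e-9)
  expect_equal(wd$weights[1:150], w$weights / 2, tolerance = 1e-9)
  resd <- coevolution_scores(dup, sigma_cut = -Inf)
  expect_equal(resd$raw, res$raw, tolerance = 1e-8)
})

test_that("planted coupling strength raises planted z monotonically", {
  mean_planted_z <- vapply(c(0, 0.3, 0.6, 0.9), function(pc) {
    zs <- vapply(1:5, function(seed) {
      sim <- simulate_msa(L = 30, N = 500, planted_pairs = 3,
                          coupling_prob = pc, gap_rate = 0.05,
                          n_founders = 50, seed = seed)
      res <- coevolution_scores(sim$msa, sigma_cut = -Inf)
      tp <- sim$truth$planted_pairs
      mean(res$z[cbind(tp$i, tp$j)])
    }, numeric(1))
    mean(zs)
  }, numeric(1))
  expect_true(all(diff(mean_planted_z) > 0))
  expect_gt(mean_planted_z[4], 3)
})

test_that("shuffling symmetrises the score distribution on planted alignments", {
  sim <- simulate_msa(L = 30, N = 500, planted_pairs = 3,
                      coupling_prob = 0.9, gap_rate = 0.05, seed = 21)
  res <- coevolution_scores(sim$msa, sigma_cut = -Inf)
  sh <- column_shuffle_null(sim$msa, seed = 22)
  res_sh <- coevolution_scores(sh, sigma_cut = -Inf)
  sk_before <- skewness(res$apc[upper.tri(res$apc)])
  sk_after <- skewness(res_sh$apc[upper.tri(res_sh$apc)])
  expect_lt(abs(sk_after), abs(sk_before))
})

test_that("sequence weighting protects planted ranks under founder redundancy", {
  rank_sum <- function(weighted) {
    vapply(1:5, function(seed) {
      sim <- simulate_msa(L = 30, N = 500, planted_pairs = 3,
                          coupling_prob = 0.9, gap_rate = 0.05,
                          n_founders = 10, founder_divergence = 0.15,
                          seed = seed)
      w <- if (weighted) sequence_weights(sim$msa)
           else structure(list(weights = rep(1, 500), theta = NA,
                               n_eff = 500), class = "sequence_weights")
      res <- coevolution_scores(sim$msa, weights = w, sigma_cut = -Inf)
      rec <- recovery_report(rank_all_couplings(res), sim$truth, k = 3)
      sum(rec$ranks)
    }, numeric(1))
  }
  expect_lte(sum(rank_sum(TRUE)), sum(rank_sum(FALSE)))
})
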