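test_that("greedy clustering matches hand-counted identities", {
  # identical rows collapse
  x <- make_msa(c("AAAA", "AAAA"))
  expect_length(cluster_sequences(x, 0.9), 1L)
  # identity("AAAA","AAAT") = 3/4 = 0.75 < 0.9 -> two clusters
  y <- make_msa(c("AAAA", "AAAT"))
  expect_length(cluster_sequences(y, 0.9), 2L)
  expect_length(cluster_sequences(y, 0.75), 1L)   # >= is inclusive
  # threshold zero puts everything together
  z <- make_msa(c("AAAA", "CCCC", "WWWW"))
  expect_length(cluster_sequences(z, 0.0), 1L)
  expect_error(cluster_sequences(z, 1.2), "\\[0, 1\\]")
})

test_that("clustering is a partition and cluster count grows with threshold", {
  for (seed in 1:5) {
    sim <- simulate_msa(L = 20, N = 40, n_founders = 6,
                        founder_divergence = 0.2, gap_rate = 0.08,
                        seed = seed)
    counts <- vapply(c(0.2, 0.5, 0.7, 0.9, 0.99), function(th) {
      cl <- cluster_sequences(sim$msa, th)
      members <- sort(unlist(lapply(cl, `[[`, "members")))
      expect_identical(members, seq_len(40L))   # exact partition
      length(cl)
    }, numeric(1L))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("family filtering drops clusters unrelated to the reference", {
  rows <- c("ACDEFGHIKL", "ACDEFGHIKV", "WWYYWWYYWW", "WWYYWWYYWY")
  x <- make_msa(rows)
  cl <- cluster_sequences(x, 0.9)
  kept <- filter_to_reference_family(x, cl, min_ref_identity = 0.2)
  expect_identical(kept$ids, c("s1", "s2"))
  # threshold zero keeps everything
  all_kept <- filter_to_reference_family(x, cl, min_ref_identity = 0)
  expect_identical(all_kept$ids, x$ids)
  # nothing but the reference survives -> warning, reference retained
  y <- make_msa(c("ACDEFGHIKL", "WWYYWWYYWW"))
  cly <- cluster_sequences(y, 0.9)
  expect_warning(only_ref <- filter_to_reference_family(y, cly, 0.5),
                 "reference-only")
  expect_identical(only_ref$ids, "s1")
})

test_that("trimming to a structure row drops its gap columns and renumbers", {
  x <- make_msa(c("AACDE", "A-CDE", "AAC-E"), ids = c("r", "pdb", "q"))
  tr <- trim_to_reference_columns(x, "pdb")
  expect_equal(msa_length(tr), 4L)
  expect_equal(paste(tr$ali[2, ], collapse = ""), "ACDE")
  expect_equal(tr$colmap, 1:4)
  # gap-free row is the identity
  tr2 <- trim_to_reference_columns(x, "r")
  expect_identical(tr2$ali, x$ali)
  # all-gap row empties the alignment
  y <- make_msa(c("AC", "--"), ids = c("r", "empty"))
  expect_error(trim_to_reference_columns(y, "empty"), "all gaps")
  expect_error(trim_to_reference_columns(x, "nope"), "not found")
  # depth ratio uses the trimmed length
  expect_equal(depth_ratio(tr)$l, 4L)
  expect_equal(depth_ratio(tr)$ratio, 3 / 4)
})

test_that("sequence weights count identity neighbourhoods", {
  x <- make_msa(rep("ACDEFGHIKL", 4))
  w <- sequence_weights(x, 0.62)
  expect_equal(w$weights, rep(1 / 4, 4))
  expect_equal(w$n_eff, 1)
  # mutually dissimilar rows all keep weight 1
  y <- make_msa(c("AAAAAAAAAA", "CCCCCCCCCC", "WWWWWWWWWW"))
  wy <- sequence_weights(y, 0.62)
  expect_equal(wy$weights, rep(1, 3))
  expect_equal(wy$n_eff, 3)
  # {X, X, Y}: hand-counted neighbourhoods (2, 2, 1)
  z <- make_msa(c("AAAAAAAAAA", "AAAAAAAAAA", "CCCCCCCCCC"))
  wz <- sequence_weights(z, 0.62)
  expect_equal(wz$weights, c(0.5, 0.5, 1))
  expect_equal(wz$n_eff, 2)
})

test_that("weights are equivariant under row permutation", {
  sim <- simulate_msa(L = 15, N = 30, n_founders = 5, gap_rate = 0.05,
                      seed = 9)
  w <- sequence_weights(sim$msa)
  perm <- sample(30)
  xp <- msa(sim$msa$ali[perm, ], sim$msa$ids[perm],
            reference_id = sim$msa$ids[perm][1])
  wp <- sequence_weights(xp)
  expect_equal(wp$weights, w$weights[perm])
  expect_equal(wp$n_eff, w$n_eff)
})

test_that("depth ratio is a strict > 0.3 test", {
  x <- simulate_msa(L = 10, N = 3, gap_rate = 0, seed = 1)$msa
  dr <- depth_ratio(x)
  expect_equal(dr$ratio, 0.3)
  expect_false(dr$pass)
  y <- simulate_msa(L = 10, N = 4, gap_rate = 0, seed = 1)$msa
  expect_true(depth_ratio(y)$pass)
  expect_equal(depth_ratio(y)$ratio, 0.4)
})

test_that("paired concatenation joins by key and records the boundary", {
  a <- make_msa(c("ACDE", "ACDF", "ACDG"), ids = c("p1", "p2", "p3"))
  b <- make_msa(c("KLM", "KLN", "KLW"), ids = c("p2", "p1", "p4"))
  expect_message(ab <- concatenate_paired(a, b), "dropped 2")
  expect_equal(msa_depth(ab), 2L)
  expect_equal(msa_length(ab), 7L)
  expect_equal(attr(ab, "boundary"), 4L)
  expect_equal(paste(ab$ali[match("p1", ab$ids), ], collapse = ""), "ACDEKLN")
  # duplicate key in one input
  dup <- make_msa(c("ACDE", "ACDF"), ids = c("p1", "p1a"))
  dup$ids <- c("p1", "p1")
  expect_error(concatenate_paired(dup, b), "duplicate")
  # organism-field pairing on Pfam-style ids
  a2 <- make_msa(c("ACDE", "ACDF"), ids = c("FLIF_SALTY/3-6", "FLIF_ECOLI/3-6"))
  b2 <- make_msa(c("KLM", "KLN"), ids = c("FLIG_ECOLI/1-3", "FLIG_SALTY/1-3"))
  ab2 <- concatenate_paired(a2, b2, pairing_key = "organism_field")
  expect_equal(sort(ab2$ids), c("ECOLI", "SALTY"))
  expect_equal(paste(ab2$ali[match("SALTY", ab2$ids), ], collapse = ""),
               "ACDEKLN")
})
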