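## Synthetic data: alignments with planted coevolving column pairs and toy
## Cn ring structures with known interface contacts.  These provide ground
## truth for benchmarking the scoring and contact-validation modules.

## Chemically compatible residue pairings used for planted couplings, in
## equal measure ionic, polar and hydrophobic.
COMPAT_PAIRS <- list(
  ionic       = list(c("K", "E"), c("R", "D"), c("K", "D"), c("R", "E"),
                     c("H", "D"), c("H", "E")),
  polar       = list(c("S", "T"), c("N", "Q"), c("S", "N"), c("T", "Q"),
                     c("Y", "S"), c("Q", "N")),
  hydrophobic = list(c("L", "V"), c("I", "L"), c("V", "I"), c("F", "L"),
                     c("M", "L"), c("A", "V")))

#' Simulate an alignment with planted coevolving column pairs
#'
#' Each column receives a Dirichlet-drawn amino-acid profile.  Sequences
#' descend from `n_founders` founder sequences: a descendant copies its
#' founder and substitutes each site with probability `founder_divergence`
#' (a fresh draw from the column profile), which creates the redundancy /
#' phylogenetic structure real families show.  For every planted column
#' pair, each sequence's two residues are then redrawn: with probability
#' `coupling_prob` jointly, as one of `n_compat_states` fixed compatible
#' residue combinations (ionic, polar and hydrophobic pairings in equal
#' measure), otherwise independently from the column profiles.  Gaps are
#' inserted i.i.d. at rate `gap_rate` everywhere except the first
#' (reference) row.  Fully deterministic given `seed`.
#'
#' @param L alignment length (columns).
#' @param N number of sequences.
#' @param planted_pairs either an integer number of pairs to place at
#'   random (separation >= `min_separation`, disjoint) or a 2-column matrix
#'   of column indices.
#' @param coupling_prob probability a planted pair is drawn jointly.
#' @param n_compat_states number of compatible residue combinations per
#'   planted pair.
#' @param gap_rate i.i.d. gap probability.
#' @param n_founders number of founder sequences.
#' @param founder_divergence per-site substitution probability from founder
#'   to descendant.
#' @param min_separation minimum column separation between the members of a
#'   planted pair (and the spacing respected when placing pairs).
#' @param seed integer seed.
#' @param profile_alpha Dirichlet concentration of column profiles (small
#'   values give conserved, low-entropy columns).
#' @return List with `msa` (an [msa]; ids `seq00001`..., reference the
#'   first, gap-free row) and `truth` (class `synthetic_truth`: data frame
#'   `planted_pairs` with columns i, j, coupling_prob, plus all parameters).
#' @export
simulate_msa <- function(L = 50L, N = 200L, planted_pairs = 0L,
                         coupling_prob = 0.9, n_compat_states = 3L,
                         gap_rate = 0.05, n_founders = 50L,
                         founder_divergence = 0.3, min_separation = 5L,
                         seed = 1L, profile_alpha = 0.5) {
  if (coupling_prob < 0 || coupling_prob > 1)
    stop_("coupling_prob must lie in [0, 1]")
  with_seed(seed, {
    pairs <- place_planted_pairs(planted_pairs, L, min_separation)
    ## column profiles over the 20 amino acids
    prof <- matrix(stats::rgamma(L * 20L, shape = profile_alpha), nrow = L)
    prof <- prof / rowSums(prof)

    draw_col <- function(j, n) sample.int(20L, n, replace = TRUE,
                                          prob = prof[j, ])
    ## founders and descendants (codes 1..20 into AA20)
    founders <- vapply(seq_len(L), function(j) draw_col(j, n_founders),
                       integer(n_founders))
    if (n_founders == 1L) founders <- matrix(founders, nrow = 1L)
    anc <- sample.int(n_founders, N, replace = TRUE)
    ali <- founders[anc, , drop = FALSE]
    mut <- matrix(stats::runif(N * L) < founder_divergence, N, L)
    for (j in seq_len(L)) {
      k <- which(mut[, j])
      if (length(k)) ali[k, j] <- draw_col(j, length(k))
    }
    ## plant the coupled pairs
    if (nrow(pairs) > 0L) {
      combos <- planted_combos(nrow(pairs), n_compat_states)
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1L]; j <- pairs[p, 2L]
        joint <- stats::runif(N) < coupling_prob
        pick <- sample.int(n_compat_states, N, replace = TRUE)
        a <- combos[[p]]$a[pick]; b <- combos[[p]]$b[pick]
        ali[joint, i] <- a[joint]
        ali[joint, j] <- b[joint]
        ali[!joint, i] <- draw_col(i, sum(!joint))
        ali[!joint, j] <- draw_col(j, sum(!joint))
      }
    }
    chars <- matrix(AA20[ali], N, L)
    if (gap_rate > 0) {
      g <- matrix(stats::runif(N * L) < gap_rate, N, L)
      g[1L, ] <- FALSE                       # reference row stays gap-free
      chars[g] <- GAP
    }
    ids <- sprintf("seq%05d", seq_len(N))
    truth <- structure(
      list(planted_pairs = data.frame(
             i = pairs[, 1L], j = pairs[, 2L],
             coupling_prob = rep(coupling_prob, nrow(pairs))),
           params = list(L = L, N = N, coupling_prob = coupling_prob,
                         n_compat_states = n_compat_states,
                         gap_rate = gap_rate, n_founders = n_founders,
                         founder_divergence = founder_divergence,
                         min_separation = min_separation,
                         profile_alpha = profile_alpha),
           seed = seed),
      class = "synthetic_truth")
    list(msa = msa(chars, ids), truth = truth)
  })
}

place_planted_pairs <- function(planted_pairs, L, min_separation) {
  if (is.matrix(planted_pairs) || is.data.frame(planted_pairs)) {
    pairs <- as.matrix(planted_pairs)[, 1:2, drop = FALSE]
  } else {
    k <- as.integer(planted_pairs)
    if (k == 0L) return(matrix(integer(), 0L, 2L))
    cols <- sample(L)
    pairs <- matrix(integer(), 0L, 2L)
    used <- integer()
    for (i in cols) {
      if (nrow(pairs) == k) break
      if (i %in% used) next
      cand <- setdiff(which(abs(seq_len(L) - i) >= min_separation), used)
      if (!length(cand)) next
      j <- cand[[sample.int(length(cand), 1L)]]
      pairs <- rbind(pairs, sort(c(i, j)))
      used <- c(used, i, j)
    }
    if (nrow(pairs) < k) stop_("could not place %d disjoint pairs in L=%d", k, L)
  }
  pairs <- t(apply(pairs, 1L, sort))
  if (nrow(pairs) == 0L) return(matrix(integer(), 0L, 2L))
  if (anyDuplicated(as.vector(pairs)))
    stop_("planted pairs overlap")
  if (any(pairs[, 2L] - pairs[, 1L] < min_separation))
    stop_("planted pairs closer than min_separation")
  storage.mode(pairs) <- "integer"
  unname(pairs)
}

## k compatible residue combinations per pair, cycling the ionic / polar /
## hydrophobic categories so the three chemistries appear in equal measure.
planted_combos <- function(n_pairs, k) {
  cats <- names(COMPAT_PAIRS)
  lapply(seq_len(n_pairs), function(p) {
    picks <- lapply(seq_len(k), function(m) {
      cat <- COMPAT_PAIRS[[cats[[(p + m - 1L) %% length(cats) + 1L]]]]
      cat[[sample.int(length(cat), 1L)]]
    })
    list(a = match(vapply(picks, `[[`, character(1L), 1L), AA20),
         b = match(vapply(picks, `[[`, character(1L), 2L), AA20))
  })
}

#' Simulate a toy Cn ring structure with known interface contacts
#'
#' Builds one compact, self-avoiding C-alpha chain ("subunit blob", 3.8 A
#' spacing) and replicates it at `n` rotations about the z axis at the given
#' ring radius.  The ground-truth interface is recorded by construction:
#' all cross-subunit C-alpha pairs closer than `cutoff` between adjacent
#' copies.  Non-adjacent copies are required to stay farther apart than
#' `cutoff`; when `radius` is `NULL` the smallest radius satisfying both
#' that requirement and a clash-free adjacent interface is chosen, which
#' guarantees a non-empty interface.
#'
#' @param n ring order (>= 3).
#' @param radius ring radius in Angstrom, or `NULL` to auto-select.
#' @param subunit_size residues per subunit.
#' @param seed integer seed.
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @param min_approach smallest allowed adjacent-copy distance (default 3.5).
#' @return List with `structure` (a [structure_model] with chains
#'   `A`, `B`, ... numbered 1..subunit_size) and `truth`
#'   (`synthetic_truth` with `interface_pairs` data frame: chain_i, res_i,
#'   chain_j, res_j, distance).
#' @export
simulate_ring_structure <- function(n = 13L, radius = NULL, subunit_size = 30L,
                                    seed = 1L, cutoff = 10.0,
                                    min_approach = 3.5) {
  if (n < 3L) stop_("ring order must be >= 3")
  with_seed(seed, {
    blob <- random_blob(subunit_size)
    blob <- sweep(blob, 2L, colMeans(blob))   # centre at origin
    ext <- max(sqrt(rowSums(blob^2)))
    pick <- function(R) ring_min_dists(blob, n, R)
    if (is.null(radius)) {
      R <- max(ext + min_approach / 2, 2 * ext / (2 * sin(pi / n)))
      repeat {
        d <- pick(R)
        if (d$adjacent >= min_approach && d$nonadjacent > cutoff) break
        R <- R + 0.5
        if (R > 100 * ext) stop_("failed to auto-select a ring radius")
      }
    } else {
      R <- radius
      d <- pick(R)
      if (d$adjacent < 3.0)
        stop_("subunit too large for radius %.1f A: adjacent copies clash (%.2f A)",
              R, d$adjacent)
      if (d$nonadjacent <= cutoff)
        stop_("radius %.1f A leaves non-adjacent copies within the %.1f A cutoff",
              R, cutoff)
    }
    placed <- sweep(blob, 2L, c(R, 0, 0), `+`)
    coords <- do.call(rbind, lapply(0:(n - 1L), function(k)
      rotate_z(placed, 2 * pi * k / n)))
    chains <- rep(chain_letters(n), each = subunit_size)
    atoms <- data.frame(chain = chains,
                        resno = rep(seq_len(subunit_size), n),
                        ins = "", aa = "A",
                        x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                        stringsAsFactors = FALSE)
    s <- structure_model(atoms)
    truth_pairs <- adjacent_interface_pairs(placed, n, subunit_size, cutoff)
    truth <- structure(list(interface_pairs = truth_pairs,
                            params = list(n = n, radius = R,
                                          subunit_size = subunit_size,
                                          cutoff = cutoff),
                            seed = seed),
                       class = "synthetic_truth")
    list(structure = s, truth = truth)
  })
}

chain_letters <- function(n) {
  pool <- c(LETTERS, letters)
  if (n > length(pool)) stop_("at most %d chains supported", length(pool))
  pool[seq_len(n)]
}

rotate_z <- function(xyz, angle) {
  co <- cos(angle); si <- sin(angle)
  cbind(co * xyz[, 1L] - si * xyz[, 2L],
        si * xyz[, 1L] + co * xyz[, 2L],
        xyz[, 3L])
}

## Compact self-avoiding chain: 3.8 A steps inside a sphere whose volume
## allows ~120 A^3 per residue, no two non-consecutive residues closer than
## 3.2 A.  Restarts (bounded) if the walk jams.
random_blob <- function(size, step = 3.8, min_dist = 3.2, max_restarts = 50L) {
  rsub <- max(2 * step, (3 * 120 * size / (4 * pi))^(1 / 3))
  for (attempt in seq_len(max_restarts)) {
    xyz <- matrix(NA_real_, size, 3L)
    xyz[1L, ] <- 0
    ok <- TRUE
    for (i in seq_len(size - 1L)) {
      placed <- FALSE
      for (try in 1:60) {
        u <- stats::rnorm(3L)
        cand <- xyz[i, ] + step * u / sqrt(sum(u^2))
        if (sqrt(sum(cand^2)) > rsub) next
        if (i > 1L) {
          d2 <- rowSums(sweep(xyz[seq_len(i - 1L), , drop = FALSE], 2L,
                              cand)^2)
          if (min(d2) < min_dist^2) next
        }
        xyz[i + 1L, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  stop_("failed to build a self-avoiding subunit of %d residues", size)
}

ring_min_dists <- function(blob, n, R) {
  placed <- sweep(blob, 2L, c(R, 0, 0), `+`)
  dmin <- function(k) {
    other <- rotate_z(placed, 2 * pi * k / n)
    min(cross_dist(placed, other))
  }
  ks <- seq_len(n - 1L)
  nonadj <- ks[ks != 1L & ks != n - 1L]
  list(adjacent = dmin(1L),
       nonadjacent = if (length(nonadj)) min(vapply(nonadj, dmin, numeric(1L)))
                     else Inf)
}

cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

adjacent_interface_pairs <- function(placed, n, size, cutoff) {
  out <- list()
  ch <- chain_letters(n)
  for (k in 0:(n - 1L)) {
    k2 <- (k + 1L) %% n
    a <- rotate_z(placed, 2 * pi * k / n)
    b <- rotate_z(placed, 2 * pi * k2 / n)
    d <- cross_dist(a, b)
    hit <- which(d < cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      ci <- ch[[k + 1L]]; cj <- ch[[k2 + 1L]]
      if (ci > cj) {
        out[[length(out) + 1L]] <- data.frame(
          chain_i = cj, res_i = hit[, 2L], chain_j = ci, res_j = hit[, 1L],
          distance = d[hit], stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          chain_i = ci, res_i = hit[, 1L], chain_j = cj, res_j = hit[, 2L],
          distance = d[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chain_i = character(), res_i = integer(),
                      chain_j = character(), res_j = integer(),
                      distance = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chain_i, res$res_i, res$chain_j, res$res_j), ]
  rownames(res) <- NULL
  res
}

#' Planted-pair recovery report
#'
#' Compares a ranked coupling table against the planted ground truth:
#' precision at k, recall at k, and the rank of every planted pair in the
#' prediction (NA when absent).
#'
#' @param predicted a coupling data frame sorted by decreasing score, with
#'   `col_i`/`col_j` (or `i`/`j`) column indices.
#' @param truth a `synthetic_truth` from [simulate_msa()].
#' @param k evaluation depth (>= 1).
#' @return List with `precision_at_k`, `recall`, `ranks` (named by pair).
#' @export
recovery_report <- function(predicted, truth, k) {
  if (k < 1L) stop_("k must be >= 1")
  if (is.null(predicted) || nrow(predicted) == 0L)
    stop_("empty prediction list")
  ci <- predicted[["col_i"]] %||% predicted[["i"]]
  cj <- predicted[["col_j"]] %||% predicted[["j"]]
  pred_key <- paste(pmin(ci, cj), pmax(ci, cj))
  tp <- truth$planted_pairs
  truth_key <- paste(pmin(tp$i, tp$j), pmax(tp$i, tp$j))
  topk <- pred_key[seq_len(min(k, length(pred_key)))]
  ranks <- match(truth_key, pred_key)
  names(ranks) <- truth_key
  list(precision_at_k = sum(topk %in% truth_key) / k,
       recall = mean(truth_key %in% topk),
       ranks = ranks)
}
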