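---
title: "Methods: coevolution scoring, contact validation and ring geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coevolution scoring, contact validation and ring geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models, numerical
choices and limitations. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The coupling model

The statistical object is the inverse covariance (precision) matrix of the
one-hot residue encoding of an alignment. Each of the `L` columns
contributes 20 binary indicator variables (one per amino acid; gaps
contribute nothing), and the empirical covariance is

    C[(i,a),(j,b)] = f2_ij(a,b) - f1_i(a) f1_j(b),

with `f1`/`f2` the redundancy-weighted single- and pair-column frequencies.
Diagonal blocks take the multinomial form `f(a)(I - f(b))`. Under a
Gaussian working model, zeros of the precision matrix correspond to
conditional independence of positions, so a sparse estimate separates
direct couplings from the chains of indirect correlation that plague raw
mutual information. The precision matrix is estimated by the graphical
lasso and the coupling strength of a column pair is the L1 norm of the
20 x 20 block linking the two positions, corrected by the average product
correction (APC) and z-normalised over all pairs at column separation of
at least `min_separation`.

Assumptions worth keeping in mind:

* Columns are treated exchangeably across sequences after redundancy
  weighting; residual phylogenetic structure is only *attenuated*, not
  modelled, which is why the APC step and the shuffle null exist.
* Gaps are missing data, not a 21st state: a sequence contributes to a
  pair's counts only where it has residues at both positions. Heavily
  gapped columns therefore rest on fewer effective observations.
* The sigma thresholds (2.5–3) are calibrated on the empirical score
  distribution of each run, not on an external null.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `theta` | 0.62 | identity fraction | neighbourhood radius for sequence weights; `w = 1/#neighbours` |
| `lambda` | 1.0 | pseudocount mass | mixes observed frequencies with uniform; `l' = lambda/(lambda + n_eff)` |
| `rho` | 0.005 | covariance units | graphical-lasso L1 penalty (off- and on-diagonal) |
| `min_separation` | 5 | columns | excludes trivial backbone neighbours from scoring and contacts |
| `sigma_cut` | 3.0 | sigma | coupling threshold; 2.5 gives the more permissive list |
| contact `cutoff` | 10 | Angstrom | strict `<` on C-alpha distances |
| `score_min` | 0.2 | min–max normalised score | restraint-candidate floor |
| `exposure_max_neighbors` | 14 | C-alpha count within 10 A | burial proxy for restraint candidates |
| `gamma` | 1.28 | A^3/Da | protein specific volume; 1.21 selectable |

The depth rule `N/L > 0.3` is applied to the raw sequence count `N`;
because redundancy weighting is a separate, threshold-dependent construct,
`n_eff` is reported alongside rather than substituted into the rule.

## Numerical choices

**Graphical lasso.** Block coordinate descent over columns of the
covariance estimate `W`, with an explicitly maintained residual vector so
that a coordinate visit costs O(1), plus active-set refinement within each
column. The diagonal is penalised (`W_ii = S_ii + rho`), the convention of
the original algorithm; some implementations leave the diagonal free,
which changes entries but not the ranking-relevant block structure. At
`rho = 0` the solution is the plain inverse and is computed by Cholesky
inversion. Optimality is verified in the tests through the
Karush–Kuhn–Tucker conditions: `inv(Theta) - S` must equal `rho` on the
diagonal and `rho * sign(Theta)` on the non-zero off-diagonals, with all
off-diagonal magnitudes bounded by `rho`.

**Convergence tolerance.** The outer loop stops when the largest
covariance update falls below `tol` times the mean absolute off-diagonal
of `S`; the default `tol = 1e-3` changes APC scores by less than 1e-4
relative to a `tol = 1e-5` reference while cutting runtime several-fold.
Tests that assert KKT conditions tighten `tol` locally.

**Conditioning.** If the covariance is not positive definite (shallow or
extremely gapped alignments) a ridge of `1e-4 * mean(diag)` is added and
doubled until a Cholesky factorisation succeeds.

**Normalisation.** z-scores use the population standard deviation (divide
by `n`, not `n - 1`) over eligible pairs. A degenerate (zero-variance)
score distribution is an error, as is an alignment with fewer than 10
eligible pairs. The min–max normalised score reported next to `z` is the
one compared against the 0.2 restraint-candidate floor.

**Randomisation control.** "Randomising the matrix" cannot change a score
histogram, so the null is implemented upstream: residues are permuted
within each column, preserving every column's composition while destroying
inter-column covariance, and the shuffled alignment is rescored. On
planted-pair alignments this leaves the planted pairs statistically
indistinguishable from background and pulls the score distribution's
skewness toward zero — both asserted in the tests.

**Column-to-structure mapping.** The ungapped reference row is globally
aligned to the chain sequence (match +1, mismatch 0, gap −1) and only
aligned positions with *identical* residues enter the map. Mismatch
tolerance sounds more general but is a trap with this scoring: two
unrelated sequences align end-to-end without gaps, so a mismatch-tolerant
map would report full coverage where it should fail. In the intended
workflow the structure row is (nearly) identical to the reference, so the
restriction costs nothing; mapping coverage below 30% is an error.

**Ring geometry.** The rotation relating two chains is extracted from a
Kabsch superposition; the axis direction comes from the skew part of the
rotation matrix (eigenvector fallback near 180 degrees) and the axis point
is the minimum-norm least-squares solution of `(I - R) p = t_perp`.
Rotations below 1 degree are rejected as translations. The chord–tangent
angle of a regular n-gon is defined as `180/n` degrees — the definition
under which the 26-to-37-fold change stays below 3.5 degrees (the
exterior-angle definition `360/n` would give 4.1). Clash counting excludes
circularly adjacent subunits, whose interfaces legitimately come close,
except at `n = 2` where the single pair of copies is the only possible
clash and is therefore counted. `gamma = 1.28` A^3/Da is calibrated so
that a 100 kDa 26-mer occupies 3.33e6 A^3; the common literature value
1.21 is selectable. The volume-implied stoichiometry is reported both as
the real-valued estimate and its rounding, because the correction applied
to any particular fitted EM volume is a judgement call the package does
not make: at a fitted volume of 3.81e6 A^3, 78% sequence coverage and the
calibrated gamma the estimate is 38.2.

## The synthetic-data generator

`simulate_msa()` emulates the features of a real family that the scoring
pipeline must survive: per-column Dirichlet profiles (concentration 0.5,
giving realistic conservation heterogeneity), founder-based redundancy
(descendants copy one of `n_founders = 50` founders and substitute each
site with probability 0.3), i.i.d. gaps at rate 0.05, and planted pairs
drawn jointly with probability 0.9 from three fixed compatible residue
combinations cycling the ionic, polar and hydrophobic chemistries in equal
measure. The coupling model is a compatibility-set mixture rather than a
full Potts sampler: exact, fast, and with directly controllable signal
strength. What it does **not** emulate: tree-structured phylogeny beyond
one founder generation, correlated gap blocks, insertions, alignment
errors, or conservation–coupling correlation. Passing the recovery tests
therefore demonstrates correctness of the estimator on its own
assumptions, not performance on any particular protein family.

`simulate_ring_structure()` builds one compact self-avoiding C-alpha chain
(3.8 A steps, 3.2 A self-distance floor, ~120 A^3 per residue) and
replicates it about the z axis. When no radius is given, the smallest
radius with a clash-free adjacent interface and non-adjacent copies beyond
the contact cutoff is chosen, which guarantees a non-empty, exactly
recorded interface truth.

The study conditions exercised by the tests and the acceptance script are
`N = 2000, L = 50`, five planted pairs at coupling probability 0.9 over a
20-seed sweep, and C-n rings at `n` in {4, 13, 26, 37}; smaller
configurations (`N = 500, L = 30`) are used for the monotonicity and
weighting properties.

## Pipeline determinism

`run_pipeline()` validates its configuration against a fixed key schema
(unknown keys are errors), funnels every random choice through the single
integer seed, and writes `scores.tsv`, `report.json` (schema
`coevoring-report/1`) and a parameter log; rerunning an identical
configuration reproduces the report byte for byte. The fractions of pairs
above 2.5 and 3 sigma are always reported without a pass/fail judgement —
where that fraction lands (typically 0.2–1%) depends on the data. A
failing depth rule is a warning by default and an error under
`strict: true`.

## Known limitations

* Single-chain PDB numbering is assumed consistent across oligomer copies
  when projecting couplings; structures with renumbered copies need a
  per-chain map.
* The exposure proxy is a C-alpha coordination number, monotone with
  burial but coarser than SASA.
* Greedy leader clustering is order-dependent by construction (rows are
  processed by decreasing ungapped length); it reproduces CD-HIT's
  behaviour in spirit, not bit for bit.
* The "opposing sides of the monomer" geometry of restraint selection is
  implemented as "not a fold contact and both residues exposed"; no
  direction-cosine check is applied by default.
* mmCIF, insertion-code-rich mappings and flexible (non-rigid)
  symmetrisation are out of scope.
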