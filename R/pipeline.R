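## One-configuration orchestration: MSA preparation -> coevolution scoring
## -> structure validation -> restraint export -> ring arithmetic, with a
## machine-readable JSON report.

PIPELINE_KEYS <- c(
  "msa", "msa_b", "pairing_key", "format", "reference_id", "truth",
  "cluster_identity", "min_ref_identity", "structure_row_id",
  "theta", "lambda", "rho", "sigma_cut", "min_separation",
  "structures", "score_min", "exposure_max_neighbors", "contact_cutoff",
  "restraints", "ring", "seed", "out_dir", "strict")

STRUCTURE_KEYS <- c("path", "chains", "monomer_chain", "name")
RING_KEYS <- c("n", "n_alt", "monomer_mw", "observed_volume", "coverage",
               "gamma", "pdb")
RESTRAINT_KEYS <- c("format", "upper_bound", "top_k", "chain_a", "chain_b")

validate_config <- function(config) {
  check <- function(x, allowed, what) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      stop_("unknown %s key(s): %s", what, paste(unknown, collapse = ", "))
  }
  check(config, PIPELINE_KEYS, "config")
  for (st in config$structures %||% list()) check(st, STRUCTURE_KEYS, "structure")
  if (!is.null(config$ring)) check(config$ring, RING_KEYS, "ring")
  if (!is.null(config$restraints))
    check(config$restraints, RESTRAINT_KEYS, "restraints")
  if (is.null(config$msa)) stop_("config must name an input 'msa'")
  invisible(config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full coevolution-to-ring pipeline from one configuration
#'
#' Executes, in order: alignment reading (and optional pairing of a second
#' alignment), redundancy clustering and family filtering, trimming to a
#' structure row, depth check, coevolution scoring, validation against each
#' configured structure, interface-candidate selection and restraint
#' export, and the ring arithmetic.  All outputs (scores.tsv, report.json,
#' restraint files, a parameter log) land in `out_dir`; re-running an
#' identical configuration reproduces an identical report.
#'
#' @param config configuration list, or path to a YAML file with the same
#'   keys.  Unknown keys are rejected.  See the package vignette for the
#'   schema.
#' @return The report, invisibly (also written to
#'   `file.path(out_dir, "report.json")`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  report <- list(schema = "coevoring-report/1", seed = seed,
                 parameters = config[setdiff(names(config), "out_dir")])

  x <- stage("read_msa", {
    m <- read_msa(config$msa, format = config$format %||% "auto",
                  reference_id = config$reference_id)
    if (!is.null(config$msa_b)) {
      mb <- read_msa(config$msa_b, format = config$format %||% "auto")
      m <- concatenate_paired(m, mb,
                              pairing_key = config$pairing_key %||% "exact_id")
    }
    m
  })

  if (!is.null(config$cluster_identity)) {
    x <- stage("cluster_filter", {
      cl <- cluster_sequences(x, config$cluster_identity)
      filter_to_reference_family(x, cl, config$min_ref_identity %||% 0.2)
    })
  }
  if (!is.null(config$structure_row_id))
    x <- stage("trim", trim_to_reference_columns(x, config$structure_row_id))

  dr <- stage("depth_ratio", depth_ratio(x))
  if (!dr$pass) {
    msg <- sprintf("depth ratio N/L = %.3f is not > 0.3", dr$ratio)
    if (isTRUE(config$strict)) stop_("pipeline stage 'depth_ratio' failed: %s", msg)
    warn_("%s; coevolution estimates may be unreliable", msg)
  }

  scores <- stage("coevolution", coevolution_scores(
    x, lambda = config$lambda %||% 1.0, theta = config$theta %||% 0.62,
    rho = config$rho %||% 0.005, sigma_cut = config$sigma_cut %||% 3.0,
    min_separation = config$min_separation %||% 5L))
  write_scores_tsv(scores, file.path(out_dir, "scores.tsv"))

  report$depth <- c(dr, n_eff = scores$meta$n_eff)
  report$scores <- list(
    n_couplings = nrow(scores$couplings),
    mean = scores$mu, sd = scores$sd,
    fraction_above_sigma_cut = unname(scores$fraction_above[[1L]]),
    fraction_above_2.5_sigma = unname(scores$fraction_above[["sigma_2.5"]]),
    fraction_above_3_sigma = unname(scores$fraction_above[["sigma_3"]]))

  if (!is.null(config$truth)) {
    report$recovery <- stage("recovery", {
      tp <- jsonlite::read_json(config$truth, simplifyVector = TRUE)
      truth <- structure(list(planted_pairs = as.data.frame(tp$planted_pairs)),
                         class = "synthetic_truth")
      all_pairs <- rank_all_couplings(scores)
      rec <- recovery_report(all_pairs, truth, k = nrow(truth$planted_pairs))
      list(k = nrow(truth$planted_pairs),
           precision_at_k = rec$precision_at_k, recall = rec$recall,
           ranks = unname(rec$ranks))
    })
  }

  cutoff <- config$contact_cutoff %||% 10.0
  validations <- list()
  candidates <- NULL
  for (st in config$structures %||% list()) {
    nm <- st$name %||% basename(st$path)
    v <- stage(paste0("validate:", nm), {
      s <- read_structure(st$path, chain_filter = st$chains)
      chain <- st$monomer_chain %||% s$chains[[1L]]
      cmap <- map_columns_to_residues(x, s, chain)
      mapped <- project_couplings(scores$couplings, cmap, s,
                                  chains = st$chains %||% s$chains,
                                  cutoff = cutoff)
      vs <- validation_stats(mapped, "min")
      cand <- interface_candidates(
        mapped, s, chain, score_min = config$score_min %||% 0.2,
        exposure_max_neighbors = config$exposure_max_neighbors %||% 14L,
        cutoff = cutoff)
      list(stats = vs, candidates = cand, coverage = cmap$coverage)
    })
    validations[[nm]] <- list(
      coverage = v$coverage, n_couplings = v$stats$n_couplings,
      n_fold = v$stats$n_fold, n_interface = v$stats$n_interface,
      n_none = v$stats$n_none, precision = v$stats$precision,
      mean_d = v$stats$mean_d, sem_d = v$stats$sem_d,
      n_candidates = nrow(v$candidates))
    if (is.null(candidates) || nrow(v$candidates) > nrow(candidates))
      candidates <- v$candidates
  }
  if (length(validations)) report$validation <- validations

  if (!is.null(candidates) && !is.null(config$restraints)) {
    rc <- config$restraints
    stage("restraints", export_restraints(
      candidates, format = rc$format %||% "tsv",
      upper_bound = rc$upper_bound %||% 10.0,
      chain_a = rc$chain_a %||% "A", chain_b = rc$chain_b %||% "B",
      top_k = rc$top_k,
      path = file.path(out_dir, paste0("restraints.",
                                       rc$format %||% "tsv"))))
    report$restraints <- list(n_exported = min(nrow(candidates),
                                               rc$top_k %||% Inf))
  }

  if (!is.null(config$ring)) {
    rg <- config$ring
    report$ring <- stage("ring", {
      out <- list()
      if (!is.null(rg$pdb)) {
        s <- read_structure(rg$pdb)
        ds <- dimer_symmetry(s)
        ring <- build_ring(s, rg$n %||% ds$implied_order,
                           axis = ds$axis, axis_point = ds$axis_point)
        rm <- ring_metrics(ring)
        write_ring_pdb(ring, file.path(out_dir, "ring.pdb"))
        out <- list(implied_order = ds$implied_order, angle = ds$angle,
                    n = ring$n, diameter = rm$diameter,
                    clash_count = rm$clash_count,
                    symmetry_rmsd = rm$symmetry_rmsd)
      }
      if (!is.null(rg$monomer_mw)) {
        n <- rg$n %||% 26L
        out$volume <- volume_from_mass(rg$monomer_mw, n,
                                       rg$gamma %||% 1.28)
        if (!is.null(rg$observed_volume)) {
          est <- estimate_stoichiometry(rg$observed_volume, rg$monomer_mw,
                                        rg$coverage %||% 1,
                                        rg$gamma %||% 1.28)
          out$stoichiometry_estimate <- est$estimate
          out$stoichiometry <- est$n
        }
      }
      if (!is.null(rg$n_alt) && !is.null(rg$n)) {
        ta <- tangent_angle_delta(rg$n, rg$n_alt)
        out$tangent_angle_delta <- ta$delta
      }
      out
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  log <- c(sprintf("coevoring pipeline, seed %d", seed),
           utils::capture.output(utils::str(config)))
  writeLines(log, file.path(out_dir, "pipeline.log"))
  invisible(report)
}

#' Rank every eligible column pair by corrected score
#'
#' Unthresholded ranking of all pairs at the result's minimum separation,
#' by decreasing APC-corrected score; used for recovery evaluation against
#' planted ground truth.
#'
#' @param scores a [coevolution_scores()] result.
#' @return Data frame with col_i, col_j, score_apc, sorted by decreasing
#'   score.
#' @export
rank_all_couplings <- function(scores) {
  l <- scores$meta$l
  el <- eligible_pairs(l, scores$meta$min_separation)
  s <- scores$apc[el]
  ord <- order(s, decreasing = TRUE)
  data.frame(col_i = el[ord, 1L], col_j = el[ord, 2L], score_apc = s[ord])
}

#' Write planted-pair ground truth as JSON
#'
#' @param truth a `synthetic_truth` from [simulate_msa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(planted_pairs = truth$planted_pairs,
                            params = truth$params, seed = truth$seed),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
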