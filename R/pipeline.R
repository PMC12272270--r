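# End-to-end orchestration: simulate -> parse -> match -> GLM -> MVPA ->
# report, for a configurable number of synthetic subjects.

#' Pipeline configuration
#'
#' Bundles all stage configurations and the experiment-level choices. The
#' defaults state the simulated world: 10 subjects, 6 runs of 28 trials,
#' a 24 x 24 x 16 voxel grid at TR 1250 ms with an amplitude region
#' (T 1.0, RD 0.5, CD 0.2), a mean-matched pattern-only region, and a null
#' region; AR(1) noise with SD 1 and rho 0.3.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param n_runs Runs per subject.
#' @param dim Voxel grid dimensions.
#' @param miss_prob Per-target miss probability for behavior.
#' @param noise_sd,ar1_rho,drift_sd,baseline BOLD noise model.
#' @param amplitude_amps,pattern_amps,pattern_sd Ground-truth region effects.
#' @param gaze [gaze_params()].
#' @param oculo [oculomotor_params()].
#' @param glm [glm_config()].
#' @param mvpa [mvpa_config()].
#' @param parse_gaze If `TRUE`, synthesize 500 Hz traces and recover fixation
#'   events with the oculomotor parser; if `FALSE`, use the generator's
#'   ground-truth fixation logs directly (fast path for large simulation
#'   studies; the parser round trip is validated separately).
#' @param run_mvpa Compute the searchlight stage.
#' @param initial_trial_offset_ms Run-clock onset of the first trial.
#' @param run_tail_ms Scan time appended after the last trial's interval.
#' @return List of class `fixfmri_pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 10, n_runs = 6, dim = c(24, 24, 16),
                            miss_prob = 0.0816, noise_sd = 1, ar1_rho = 0.3,
                            drift_sd = 2, baseline = 100,
                            amplitude_amps = c(T = 1, RD = 0.5, CD = 0.2),
                            pattern_amps = c(T = 1, RD = 1, CD = 0.2),
                            pattern_sd = 0.5,
                            gaze = gaze_params(), oculo = oculomotor_params(),
                            glm = glm_config(), mvpa = mvpa_config(),
                            parse_gaze = TRUE, run_mvpa = TRUE,
                            initial_trial_offset_ms = 5000,
                            run_tail_ms = 15000) {
  structure(as.list(environment()), class = "fixfmri_pipeline_config")
}

# Derive a stream of independent sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate and analyze one synthetic subject
#'
#' Runs the per-subject chain: session plan, gaze/behavior simulation,
#' (optionally) oculomotor parsing of the traces, candidate selection and
#' rank matching, BOLD simulation from the ground-truth fixation logs,
#' first-level GLMs on smoothed (amplitude analysis) and unsmoothed (pattern
#' analysis) data, subject-level contrasts, and the searchlight accuracy map.
#'
#' @param config [pipeline_config()].
#' @param seed Integer seed for this subject.
#' @return List with `trials`, `fixations`, `matched`, `match_report`,
#'   `contrasts` (list of `fixfmri_statmap`), `fits_smoothed`,
#'   `fits_unsmoothed`, `accuracy` (3-D array or `NULL`), `regions`,
#'   `behavior`.
#' @export
simulate_subject <- function(config = pipeline_config(), seed = 1L) {
  seeds <- derive_seeds(seed, 8L)
  session <- generate_session(seeds[1], n_runs = config$n_runs)
  regions <- ground_truth_regions(config$dim,
                                  amplitude_amps = config$amplitude_amps,
                                  pattern_amps = config$pattern_amps,
                                  pattern_sd = config$pattern_sd,
                                  rng_seed = seeds[2])

  set.seed(seeds[3])
  tr_tab <- session$trials
  n_trials <- nrow(tr_tab)
  gaze_list <- vector("list", n_trials)
  beh_list <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    g <- simulate_gaze(session$displays[[i]], config$gaze,
                       rng_seed = sample.int(.Machine$integer.max - 1L, 1),
                       trace = config$parse_gaze)
    b <- simulate_response(session$displays[[i]], g, config$miss_prob,
                           config$gaze,
                           rng_seed = sample.int(.Machine$integer.max - 1L, 1))
    gaze_list[[i]] <- g
    beh_list[[i]] <- b
  }
  beh <- do.call(rbind, beh_list)
  trials <- cbind(tr_tab, beh)

  # run clock: trial i starts after the previous trial's response + ITI
  trials$trial_onset_ms <- NA_real_
  for (run in seq_len(config$n_runs)) {
    idx <- which(trials$run == run)
    t0 <- config$initial_trial_offset_ms
    for (i in idx) {
      trials$trial_onset_ms[i] <- t0
      t0 <- t0 + trials$rt_ms[i] + trials$iti_ms[i]
    }
  }

  # fixation events per trial: parsed from traces or taken from ground truth
  fix_list <- lapply(seq_len(n_trials), function(i) {
    g <- gaze_list[[i]]
    fx <- if (config$parse_gaze) {
      parse_trial(g$trace, session$displays[[i]], config$oculo)
    } else {
      f <- g$fixations
      sa <- g$saccades$amplitude_deg
      out <- data.frame(onset_ms = f$onset_ms, duration_ms = f$duration_ms,
                        x_deg = NA_real_, y_deg = NA_real_,
                        item_id = f$item_id, item_type = f$item_type,
                        prec_sacc_amp = NA_real_, foll_sacc_amp = NA_real_,
                        n_collapsed = f$n_segments, stringsAsFactors = FALSE)
      compute_ranks(out)
    }
    if (nrow(fx) == 0) return(NULL)
    fx$run <- trials$run[i]
    fx$trial <- trials$trial[i]
    fx$run_onset_ms <- trials$trial_onset_ms[i] + fx$onset_ms
    fx
  })
  fixations <- do.call(rbind, Filter(Negate(is.null), fix_list))

  candidates <- select_events(trials, fixations)
  matched <- rank_match(candidates, rng_seed = seeds[4])
  match_report <- matching_report(matched, candidates)
  events <- matched_event_table(matched)

  # forward-model events: ground-truth first item visits of every trial
  truth_events <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    f <- gaze_list[[i]]$fixations
    f <- f[!duplicated(f$item_id), , drop = FALSE]
    data.frame(run = trials$run[i],
               onset_ms = trials$trial_onset_ms[i] + f$onset_ms,
               class = f$item_type, stringsAsFactors = FALSE)
  }))

  fits_sm <- vector("list", config$n_runs)
  fits_raw <- vector("list", config$n_runs)
  set.seed(seeds[5])
  for (run in seq_len(config$n_runs)) {
    idx <- which(trials$run == run)
    run_dur <- max(trials$trial_onset_ms[idx] + trials$rt_ms[idx] +
                     trials$iti_ms[idx]) + config$run_tail_ms
    ev_fwd <- truth_events[truth_events$run == run, , drop = FALSE]
    bold <- simulate_bold(ev_fwd, regions, run_dur,
                          tr_ms = config$glm$tr_ms, baseline = config$baseline,
                          noise_sd = config$noise_sd, ar1_rho = config$ar1_rho,
                          drift_sd = config$drift_sd,
                          n_discarded_leading = config$glm$n_discarded_leading,
                          rng_seed = sample.int(.Machine$integer.max - 1L, 1))
    ev_glm <- events[events$run == run, , drop = FALSE]
    design <- build_design_matrix(ev_glm, bold$n_vols, bold$motion, config$glm)
    bold_sm <- smooth_gaussian(bold, config$glm$smoothing_fwhm_mm)
    fits_sm[[run]] <- fit_first_level(bold_sm, design, config$glm)
    if (config$run_mvpa) {
      fits_raw[[run]] <- fit_first_level(bold, design, config$glm)
    }
  }

  contrasts <- lapply(c("T-RD", "T-CD_T", "RD-CD_RD", "CD_T-CD_RD"),
                      function(nm) compute_contrast(fits_sm, nm))
  names(contrasts) <- c("T-RD", "T-CD_T", "RD-CD_RD", "CD_T-CD_RD")

  accuracy <- NULL
  if (config$run_mvpa) {
    patterns <- extract_patterns(fits_raw)
    accuracy <- searchlight_cv(patterns, config$mvpa)
  }

  list(trials = trials, fixations = fixations, matched = matched,
       match_report = match_report, contrasts = contrasts,
       fits_smoothed = fits_sm,
       fits_unsmoothed = if (config$run_mvpa) fits_raw else NULL,
       accuracy = accuracy, regions = regions,
       behavior = summarize_behavior(trials, fixations),
       seeds = seeds)
}

#' Run the full multi-subject pipeline
#'
#' Simulates `n_subjects` subjects, then performs the group analyses:
#' cluster-level FWE inference on the subject contrast maps (targets vs rare
#' distractors and the rank-control contrast between the two matched
#' common-distractor classes), the group searchlight-accuracy test against
#' chance, and percent signal change in the ground-truth amplitude region.
#'
#' @param config [pipeline_config()].
#' @param seed Master seed.
#' @param out_dir Optional directory: event tables, match reports, cluster
#'   tables and a run manifest are written there as TSV/JSON.
#' @param n_perm Permutations for cluster inference.
#' @return List of class `fixfmri_results`: `group` (cluster results per
#'   contrast and for accuracy), `psc`, `subjects` (per-subject summaries),
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL, n_perm = 500) {
  t_start <- Sys.time()
  seeds <- derive_seeds(seed, config$n_subjects + 2L)
  subjects <- vector("list", config$n_subjects)
  con_maps <- list(); acc_maps <- list()
  psc_tab <- list()
  for (s in seq_len(config$n_subjects)) {
    sub <- simulate_subject(config, seeds[s])
    for (nm in names(sub$contrasts)) {
      con_maps[[nm]] <- c(con_maps[[nm]], list(sub$contrasts[[nm]]$effect))
    }
    if (!is.null(sub$accuracy)) acc_maps[[s]] <- sub$accuracy
    amp_vox <- sub$regions$regions[[1]]$voxels
    psc_tab[[s]] <- psc_by_class(sub$fits_smoothed, amp_vox)
    # keep light-weight per-subject record
    subjects[[s]] <- list(match_report = sub$match_report,
                          behavior = sub$behavior, seed = seeds[s])
    if (s == 1) regions <- sub$regions
  }

  group <- list()
  for (nm in names(con_maps)) {
    group[[nm]] <- cluster_inference(con_maps[[nm]], n_perm = n_perm,
                                     rng_seed = seeds[config$n_subjects + 1L])
  }
  if (length(acc_maps) == config$n_subjects && config$run_mvpa) {
    group$accuracy <- group_accuracy_test(
      acc_maps, config$mvpa, n_perm = n_perm,
      rng_seed = seeds[config$n_subjects + 2L])
  }
  psc <- colMeans(do.call(rbind, psc_tab))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fixfmri")),
    master_seed = seed, subject_seeds = seeds[seq_len(config$n_subjects)],
    n_subjects = config$n_subjects, n_runs = config$n_runs,
    dim = config$dim, parse_gaze = config$parse_gaze,
    stages = c("simulate", "parse", "match", "glm",
               if (config$run_mvpa) "mvpa", "report"),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  res <- structure(list(group = group, psc = psc, subjects = subjects,
                        regions = regions, manifest = manifest),
                   class = "fixfmri_results")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' Write pipeline outputs to disk
#'
#' Cluster tables as TSV, percent signal change and the manifest as JSON.
#'
#' @param results A `fixfmri_results`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(results$group)) {
    p <- file.path(out_dir, paste0("clusters_", gsub("[^A-Za-z0-9]", "_", nm), ".tsv"))
    utils::write.table(results$group[[nm]]$table, p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "psc.json")
  jsonlite::write_json(as.list(results$psc), p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(results$manifest, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

#' Generate a small deterministic fixture bundle
#'
#' Writes event, gaze, and matched-event tables for a reduced experiment
#' (1 subject; `tiny`: 2 runs on a 16 x 16 x 12 grid) used by the test suite.
#' Regeneration with the same seed is byte-identical.
#'
#' @param size `"tiny"` or `"default"`.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(size = c("tiny", "default"), dir = tempfile("fixtures"),
                          seed = 42L) {
  size <- match.arg(size)
  cfg <- if (size == "tiny") {
    pipeline_config(n_subjects = 1, n_runs = 2, dim = c(16, 16, 12),
                    parse_gaze = FALSE, run_mvpa = FALSE)
  } else {
    pipeline_config(n_subjects = 1, run_mvpa = FALSE, parse_gaze = FALSE)
  }
  sub <- simulate_subject(cfg, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trials = file.path(dir, "trials.tsv"),
             fixations = file.path(dir, "fixations.tsv"),
             matched = file.path(dir, "matched_events.tsv"))
  utils::write.table(sub$trials, paths["trials"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sub$fixations, paths["fixations"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(matched_event_table(sub$matched), paths["matched"],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Render a human-readable pipeline report
#'
#' Markdown summary of behavioral descriptives, match rates, cluster tables,
#' percent signal change, and the seeds used. Empty cluster tables render as
#' "no clusters".
#'
#' @param results A `fixfmri_results`.
#' @param file Optional path to write the report to.
#' @return The report as a character vector of lines (invisibly if written).
#' @export
render_report <- function(results, file = NULL) {
  fmt_tab <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("(no clusters)")
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(format(r, digits = 4), collapse = " | ")))
  }
  lines <- c("# fixfmri pipeline report", "",
             paste0("Subjects: ", results$manifest$n_subjects,
                    "; runs: ", results$manifest$n_runs,
                    "; master seed: ", results$manifest$master_seed), "",
             paste0("Subject seeds: ",
                    paste(results$manifest$subject_seeds, collapse = ", ")), "")
  beh <- results$subjects[[1]]$behavior$by_condition
  lines <- c(lines, "## Behavior (subject 1)", fmt_tab(beh), "")
  mr <- results$subjects[[1]]$match_report$table
  lines <- c(lines, "## Match rates (subject 1)", fmt_tab(mr), "")
  for (nm in names(results$group)) {
    lines <- c(lines, paste0("## Clusters: ", nm),
               fmt_tab(results$group[[nm]]$table), "")
  }
  lines <- c(lines, "## Percent signal change (amplitude region)",
             paste(names(results$psc), round(results$psc, 3),
                   sep = " = ", collapse = "; "), "")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
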