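# Fixation-rank matching: pair each first target / rare-distractor fixation
# with a common-distractor fixation of identical rank from a different trial
# of the same condition and run, without reusing any common distractor.

MATCHABLE_CONDITIONS <- c("1T_0RD", "0T_1RD", "1T_1RD")

#' Select candidate events for rank matching
#'
#' Emits first fixations on targets and rare distractors, and all
#' common-distractor first fixations, from correct trials of the three
#' matchable conditions (one target and/or one rare distractor). Error trials,
#' technical-error trials, catch trials and the all-common condition are
#' excluded.
#'
#' @param trials Trial table (`run`, `trial`, `condition`, `correct`,
#'   `technical_error`) with one row per trial.
#' @param fixations Ranked collapsed fixation events for all trials (`run`,
#'   `trial`, `item_id`, `item_type`, `rank`, `onset_ms`,
#'   `is_first_fixation_on_item`); onsets on the trial clock unless a
#'   `run_onset_ms` column is present.
#' @return data.frame of candidate events: `class` (`T`, `RD`, `CD`), `run`,
#'   `trial`, `condition`, `rank`, `onset_ms`, `item_id`.
#' @export
select_events <- function(trials, fixations) {
  ok <- trials[trials$correct & !trials$technical_error &
                 trials$condition %in% MATCHABLE_CONDITIONS, , drop = FALSE]
  key_t <- paste(ok$run, ok$trial)
  fx <- fixations[paste(fixations$run, fixations$trial) %in% key_t &
                    fixations$is_first_fixation_on_item, , drop = FALSE]
  if (nrow(fx) == 0) {
    return(data.frame(class = character(0), run = integer(0), trial = integer(0),
                      condition = character(0), rank = integer(0),
                      onset_ms = numeric(0), item_id = integer(0)))
  }
  cond <- ok$condition[match(paste(fx$run, fx$trial), key_t)]
  onset <- if ("run_onset_ms" %in% names(fx)) fx$run_onset_ms else fx$onset_ms
  data.frame(class = fx$item_type, run = fx$run, trial = fx$trial,
             condition = cond, rank = fx$rank, onset_ms = onset,
             item_id = fx$item_id, stringsAsFactors = FALSE)
}

#' Rank-match target and rare-distractor fixations to common distractors
#'
#' Per run, trial order is randomized (seeded) to avoid preferentially
#' matching distractors from early trials. Target and rare-distractor events
#' are then processed in that trial order (by rank within trial); each is
#' paired with a common-distractor candidate of exactly the same fixation rank
#' from a *different* trial of the *same* condition within the run. A chosen
#' common distractor is removed from the pool and cannot be reused. Events
#' with no exact-rank match available are dropped and logged.
#'
#' When several common distractors share the required rank, one is chosen
#' uniformly at random (seeded).
#'
#' @param candidates Output of [select_events()].
#' @param rng_seed Optional integer seed.
#' @return List of class `fixfmri_matched`: `pairs` (data.frame with the event
#'   and its matched common distractor, `pair_id`, and the derived class label
#'   `CD_T` or `CD_RD` for the distractor), `dropped` (unmatched events with
#'   a reason), and the input candidate count.
#' @export
rank_match <- function(candidates, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  pairs <- list(); dropped <- list()
  pair_id <- 0L
  for (run in sort(unique(candidates$run))) {
    rc <- candidates[candidates$run == run, , drop = FALSE]
    cd_pool <- rc[rc$class == "CD", , drop = FALSE]
    used <- rep(FALSE, nrow(cd_pool))
    trial_order <- sample(unique(rc$trial))
    ev <- rc[rc$class %in% c("T", "RD"), , drop = FALSE]
    ev <- ev[order(match(ev$trial, trial_order), ev$rank), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      avail <- which(!used & cd_pool$rank == e$rank &
                       cd_pool$condition == e$condition &
                       cd_pool$trial != e$trial)
      if (length(avail) == 0) {
        dropped[[length(dropped) + 1]] <-
          cbind(e, reason = "no exact rank match", stringsAsFactors = FALSE)
        next
      }
      pick <- if (length(avail) == 1) avail else sample(avail, 1L)
      used[pick] <- TRUE
      cd <- cd_pool[pick, ]
      pair_id <- pair_id + 1L
      pairs[[pair_id]] <- data.frame(
        pair_id = pair_id, class = e$class, run = e$run, trial = e$trial,
        condition = e$condition, rank = e$rank, onset_ms = e$onset_ms,
        item_id = e$item_id,
        cd_class = paste0("CD_", e$class), cd_trial = cd$trial,
        cd_onset_ms = cd$onset_ms, cd_item_id = cd$item_id,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
    dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
    n_candidates = nrow(candidates)), class = "fixfmri_matched")
}

#' Match-rate report
#'
#' Matched/total counts and percentages per event class and condition, plus
#' the overall loss percentage. Empty candidate sets yield an empty table
#' (no division by zero).
#'
#' @param matched A `fixfmri_matched` from [rank_match()].
#' @param candidates The candidate set given to [rank_match()].
#' @return List with `table` (class x condition match rates) and
#'   `overall_loss_pct`.
#' @export
matching_report <- function(matched, candidates) {
  ev <- candidates[candidates$class %in% c("T", "RD"), , drop = FALSE]
  if (nrow(ev) == 0) {
    return(list(table = data.frame(class = character(0), condition = character(0),
                                   n_total = integer(0), n_matched = integer(0),
                                   match_rate_pct = numeric(0)),
                overall_loss_pct = NA_real_))
  }
  p <- matched$pairs
  cells <- unique(ev[, c("class", "condition")])
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells$class[i]; cc <- cells$condition[i]
    tot <- sum(ev$class == cl & ev$condition == cc)
    got <- if (is.null(p)) 0L else sum(p$class == cl & p$condition == cc)
    data.frame(class = cl, condition = cc, n_total = tot, n_matched = got,
               match_rate_pct = 100 * got / tot, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$class, tab$condition), ]
  rownames(tab) <- NULL
  n_matched <- if (is.null(p)) 0L else nrow(p)
  list(table = tab, overall_loss_pct = 100 * (1 - n_matched / nrow(ev)))
}

#' Matched events in long format
#'
#' Expands a `fixfmri_matched` into one row per event with classes
#' `T`, `RD`, `CD_T`, `CD_RD` — the event set modeled by the first-level GLM.
#'
#' @param matched A `fixfmri_matched`.
#' @return data.frame `class`, `condition`, `run`, `trial`, `onset_ms`,
#'   `item_id`, `pair_id`.
#' @export
matched_event_table <- function(matched) {
  p <- matched$pairs
  if (is.null(p)) {
    return(data.frame(class = character(0), condition = character(0),
                      run = integer(0), trial = integer(0),
                      onset_ms = numeric(0), item_id = integer(0),
                      pair_id = integer(0)))
  }
  rbind(
    data.frame(class = p$class, condition = p$condition, run = p$run,
               trial = p$trial, onset_ms = p$onset_ms, item_id = p$item_id,
               pair_id = p$pair_id, stringsAsFactors = FALSE),
    data.frame(class = p$cd_class, condition = p$condition, run = p$run,
               trial = p$cd_trial, onset_ms = p$cd_onset_ms,
               item_id = p$cd_item_id, pair_id = p$pair_id,
               stringsAsFactors = FALSE))
}
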