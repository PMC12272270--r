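# Display geometry constants (degrees of visual angle).
# 30 items on a jittered 7x7 grid inside a 10.21 x 10.21 deg area centered on
# (0, 0); per-axis jitter at most 0.16 deg; minimum inter-item distance 1.14 deg.
DISPLAY_EXTENT_DEG <- 10.21
DISPLAY_GRID_N <- 7L
DISPLAY_N_ITEMS <- 30L
DISPLAY_JITTER_DEG <- 0.16
DISPLAY_MIN_DIST_DEG <- 1.14

# Grid spacing chosen so grid intersections plus maximal jitter exactly fill the
# display area: outermost intersections sit at +/-(extent/2 - jitter).
display_grid_spacing <- function() {
  (DISPLAY_EXTENT_DEG - 2 * DISPLAY_JITTER_DEG) / (DISPLAY_GRID_N - 1)
}

#' Condition codes of the search task
#'
#' Four exhaustive-search conditions (0 or 1 target crossed with 0 or 1 rare
#' distractor) plus two catch conditions with two targets that allow
#' self-terminating search.
#'
#' @return Character vector of the six condition codes.
#' @export
search_conditions <- function() {
  c("0T_0RD", "0T_1RD", "1T_0RD", "1T_1RD", "2T_0RD", "2T_1RD")
}

#' @rdname search_conditions
#' @export
exhaustive_conditions <- function() c("0T_0RD", "0T_1RD", "1T_0RD", "1T_1RD")

#' @rdname search_conditions
#' @export
catch_conditions <- function() c("2T_0RD", "2T_1RD")

# Number of targets / rare distractors implied by a condition code.
condition_counts <- function(condition) {
  m <- regmatches(condition, regexec("^([0-2])T_([01])RD$", condition))[[1]]
  if (length(m) != 3L) {
    stop("invalid condition code: ", condition, call. = FALSE)
  }
  c(n_target = as.integer(m[2]), n_rare = as.integer(m[3]))
}

#' Generate one search display
#'
#' Places 30 items (targets `T`, rare distractors `RD`, common distractors
#' `CD`) at randomly chosen intersections of a 7x7 grid spanning the
#' 10.21 x 10.21 degree display area, with independent per-axis uniform jitter
#' of at most 0.16 degrees. Item counts of `T` and `RD` follow the condition
#' code; remaining items are common distractors. The generated layout is
#' checked against the minimum inter-item distance of 1.14 degrees by an
#' all-pairs scan and redrawn (bounded retries) if violated.
#'
#' @param condition One of [search_conditions()].
#' @param rng_seed Optional integer seed.
#' @param max_retries Redraw attempts before giving up (geometry guard).
#' @return An object of class `fixfmri_display`: a list with `items`
#'   (data.frame `id`, `x`, `y`, `type`) and `condition`.
#' @export
generate_display <- function(condition, rng_seed = NULL, max_retries = 50L) {
  condition <- match.arg(condition, search_conditions())
  if (!is.null(rng_seed)) set.seed(rng_seed)
  counts <- condition_counts(condition)
  spacing <- display_grid_spacing()
  half <- (DISPLAY_GRID_N - 1) / 2
  coords <- (seq_len(DISPLAY_GRID_N) - 1 - half) * spacing
  grid <- expand.grid(gx = coords, gy = coords)
  # the central intersection is reserved for the fixation disc shown during
  # the drift correction preceding each trial; items never appear there
  grid <- grid[!(grid$gx == 0 & grid$gy == 0), ]

  for (attempt in seq_len(max_retries)) {
    slots <- sample.int(nrow(grid), DISPLAY_N_ITEMS)
    x <- grid$gx[slots] + stats::runif(DISPLAY_N_ITEMS, -DISPLAY_JITTER_DEG, DISPLAY_JITTER_DEG)
    y <- grid$gy[slots] + stats::runif(DISPLAY_N_ITEMS, -DISPLAY_JITTER_DEG, DISPLAY_JITTER_DEG)
    if (min(stats::dist(cbind(x, y))) >= DISPLAY_MIN_DIST_DEG) {
      type <- rep("CD", DISPLAY_N_ITEMS)
      special <- sample.int(DISPLAY_N_ITEMS, counts[["n_target"]] + counts[["n_rare"]])
      if (counts[["n_target"]] > 0) type[special[seq_len(counts[["n_target"]])]] <- "T"
      if (counts[["n_rare"]] > 0) type[special[counts[["n_target"]] + seq_len(counts[["n_rare"]])]] <- "RD"
      items <- data.frame(id = seq_len(DISPLAY_N_ITEMS), x = x, y = y, type = type,
                          stringsAsFactors = FALSE)
      return(structure(list(items = items, condition = condition),
                       class = "fixfmri_display"))
    }
  }
  stop("could not satisfy minimum inter-item distance after ", max_retries,
       " attempts; geometry configuration is infeasible", call. = FALSE)
}

#' Validate display geometry
#'
#' All-pairs brute-force check of the display invariants: exactly 30 items,
#' item-type counts matching the condition code, all pairwise distances at
#' least 1.14 degrees, and every position inside the 10.21-degree square.
#'
#' @param display A `fixfmri_display`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_display <- function(display) {
  it <- display$items
  if (nrow(it) != DISPLAY_N_ITEMS) stop("display must contain exactly 30 items")
  counts <- condition_counts(display$condition)
  if (sum(it$type == "T") != counts[["n_target"]]) stop("target count mismatch")
  if (sum(it$type == "RD") != counts[["n_rare"]]) stop("rare distractor count mismatch")
  if (min(stats::dist(cbind(it$x, it$y))) < DISPLAY_MIN_DIST_DEG) {
    stop("minimum inter-item distance violated")
  }
  lim <- DISPLAY_EXTENT_DEG / 2
  if (any(abs(it$x) > lim) || any(abs(it$y) > lim)) stop("item outside display area")
  invisible(TRUE)
}

#' Generate a full session plan
#'
#' Six runs of 28 trials: 6 trials of each exhaustive condition and 2 of each
#' two-target catch condition per run, in randomized order, with inter-trial
#' intervals drawn uniformly from 3500 to 8500 ms in 500 ms steps.
#'
#' @param rng_seed Optional integer seed.
#' @param n_runs Number of runs (default 6; reduce for desk-scale fixtures).
#' @return An object of class `fixfmri_session`: list with `trials`
#'   (data.frame `run`, `trial`, `condition`, `iti_ms`) and `displays`
#'   (list of `fixfmri_display`, one per row of `trials`).
#' @export
generate_session <- function(rng_seed = NULL, n_runs = 6L) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  iti_values <- seq(3500L, 8500L, by = 500L)
  per_run <- c(rep(exhaustive_conditions(), each = 6L),
               rep(catch_conditions(), each = 2L))
  rows <- list()
  displays <- list()
  for (run in seq_len(n_runs)) {
    conds <- sample(per_run)
    iti <- sample(iti_values, length(conds), replace = TRUE)
    rows[[run]] <- data.frame(run = run, trial = seq_along(conds),
                              condition = conds, iti_ms = iti,
                              stringsAsFactors = FALSE)
    displays <- c(displays, lapply(conds, function(cc) {
      generate_display(cc, rng_seed = sample.int(.Machine$integer.max, 1L))
    }))
  }
  structure(list(trials = do.call(rbind, rows), displays = displays),
            class = "fixfmri_session")
}
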