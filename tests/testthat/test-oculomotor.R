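# Saccade detection, fixation segmentation, item assignment, refixation
# collapsing, ranks, and behavioral summaries.

test_that("constant and slow traces yield no saccades", {
  n <- 300
  flat <- data.frame(time_ms = (0:(n - 1)) * 2, x_deg = rep(1, n),
                     y_deg = rep(-0.5, n))
  expect_equal(nrow(detect_saccades(flat)), 0L)
  # drift at 25 deg/s: below the 30 deg/s threshold
  drift <- data.frame(time_ms = (0:(n - 1)) * 2,
                      x_deg = 25 * (0:(n - 1)) * 0.002, y_deg = 0)
  expect_equal(nrow(detect_saccades(drift)), 0L)
})

test_that("a fast ramp yields exactly one saccade matching the threshold-scan oracle", {
  tr <- make_ramp_trace(rbind(c(0, 0), c(4, 1)), dwell_ms = 200, sacc_ms = 26)
  sac <- detect_saccades(tr)
  expect_equal(nrow(sac), 1L)
  expect_gt(sac$peak_velocity_dps, 100)
  oracle <- oracle_saccade_scan(tr)
  expect_equal(sac$onset_ms, oracle[1, 1])
  expect_equal(sac$offset_ms, oracle[1, 2])
  expect_equal(sac$amplitude_deg, sqrt(17), tolerance = 0.15)
})

test_that("detector equals the brute-force per-sample scan on noisy multi-saccade traces", {
  set.seed(21)
  for (rep in 1:20) {
    pos <- cbind(runif(5, -4, 4), runif(5, -4, 4))
    tr <- make_ramp_trace(pos, dwell_ms = 150, sacc_ms = 24, noise_sd = 0.02)
    sac <- detect_saccades(tr)
    oracle <- oracle_saccade_scan(tr)
    expect_equal(nrow(sac), if (is.null(oracle)) 0L else nrow(oracle))
    if (!is.null(oracle)) {
      expect_equal(sac$onset_ms, oracle[, 1])
      expect_equal(sac$offset_ms, oracle[, 2])
    }
  }
})

test_that("non-uniform or too-short traces are rejected", {
  bad <- data.frame(time_ms = c(0, 2, 5, 8), x_deg = 0, y_deg = 0)
  expect_error(detect_saccades(bad), "uniform")
  tiny <- data.frame(time_ms = c(0, 2), x_deg = 0, y_deg = 0)
  expect_error(detect_saccades(tiny), "short")
})

test_that("fixations are the complement of the saccade set", {
  n <- 500
  tr <- data.frame(time_ms = (0:(n - 1)) * 2, x_deg = 0, y_deg = 0)
  # no saccades: one fixation spanning the trace
  f0 <- segment_fixations(tr, detect_saccades(tr))
  expect_equal(nrow(f0), 1L)
  expect_equal(f0$duration_ms, n * 2)
  # k synthetic saccade intervals strictly inside -> k + 1 fixations
  sac <- data.frame(onset_ms = c(100, 400, 700), offset_ms = c(130, 430, 730),
                    amplitude_deg = 1, peak_velocity_dps = 100,
                    direction_rad = 0)
  fx <- segment_fixations(tr, sac)
  expect_equal(nrow(fx), 4L)
  # partition conservation: fixations + saccades tile the trace
  expect_equal(sum(fx$duration_ms) + sum(sac$offset_ms - sac$onset_ms), n * 2)
  # interval-complement oracle
  expect_equal(fx$onset_ms, c(0, 130, 430, 730))
  expect_equal(fx$offset_ms, c(100, 400, 700, 1000))
  # overlapping saccades rejected
  bad <- sac; bad$onset_ms[2] <- 120
  expect_error(segment_fixations(tr, bad), "overlap")
})

test_that("parsed saccades and fixations partition simulator traces", {
  d <- generate_display("1T_0RD", 3)
  g <- simulate_gaze(d, rng_seed = 3)
  sac <- detect_saccades(g$trace)
  fx <- segment_fixations(g$trace, sac)
  expect_equal(sum(fx$duration_ms) + sum(sac$offset_ms - sac$onset_ms),
               nrow(g$trace) * 2)
  ints <- rbind(cbind(fx$onset_ms, fx$offset_ms),
                cbind(sac$onset_ms, sac$offset_ms))
  ints <- ints[order(ints[, 1]), ]
  expect_true(all(ints[-1, 1] == ints[-nrow(ints), 2]))  # no gaps, no overlap
})

test_that("assign_item matches brute-force nearest-item search and its tie rule", {
  set.seed(33)
  d <- generate_display("1T_1RD", 8)
  for (i in 1:200) {
    p <- runif(2, -5.2, 5.2)
    id <- assign_item(p[1], p[2], d)
    dists <- sqrt((d$items$x - p[1])^2 + (d$items$y - p[2])^2)
    expect_equal(id, which(dists == min(dists))[1])
  }
  # documented tie rule: equidistant -> lowest id
  toy <- structure(list(items = data.frame(id = 1:2, x = c(-1, 1), y = c(0, 0),
                                           type = c("CD", "CD")),
                        condition = "0T_0RD"), class = "fixfmri_display")
  expect_equal(assign_item(0, 5, toy), 1L)
  # rigid translation invariance
  sh <- c(2.3, -1.1)
  toy2 <- toy; toy2$items$x <- toy$items$x + sh[1]; toy2$items$y <- toy$items$y + sh[2]
  for (i in 1:20) {
    p <- runif(2, -4, 4)
    expect_equal(assign_item(p[1], p[2], toy),
                 assign_item(p[1] + sh[1], p[2] + sh[2], toy2))
  }
})

test_that("collapse_refixations merges exactly the immediate refixation runs", {
  f <- data.frame(onset_ms = c(0, 210, 370), duration_ms = c(200, 150, 300),
                  x_deg = c(1, 1.1, 3), y_deg = 0,
                  item_id = c(5L, 5L, 9L), item_type = c("T", "T", "CD"),
                  prec_sacc_amp = c(NA, 0.3, 2), foll_sacc_amp = c(0.3, 2, NA))
  out <- collapse_refixations(f)
  expect_equal(nrow(out), 2L)
  expect_equal(out$duration_ms, c(350, 300))
  expect_equal(out$onset_ms, c(0, 370))
  expect_equal(out$n_collapsed, c(2L, 1L))
  # preceding saccade of the first member, following saccade of the last
  expect_true(is.na(out$prec_sacc_amp[1]))
  expect_equal(out$foll_sacc_amp[1], 2)

  # A, B, A: no collapsing
  f2 <- f; f2$item_id <- c(5L, 9L, 5L)
  expect_equal(nrow(collapse_refixations(f2)), 3L)

  # empty input and idempotence
  expect_equal(nrow(collapse_refixations(f[0, ])), 0L)
  expect_equal(collapse_refixations(out)$duration_ms, out$duration_ms)
  expect_equal(collapse_refixations(out)$n_collapsed, c(1L, 1L))

  # unsorted input rejected
  expect_error(collapse_refixations(f[c(2, 1, 3), ]), "sorted")
})

test_that("ranks are contiguous in onset order and first-visit flags are correct", {
  f <- data.frame(onset_ms = c(0, 300, 700), duration_ms = c(200, 300, 250),
                  x_deg = 0, y_deg = 0, item_id = c(5L, 9L, 5L),
                  item_type = "CD", prec_sacc_amp = NA, foll_sacc_amp = NA,
                  n_collapsed = 1L)
  out <- compute_ranks(f)
  expect_equal(out$rank, 1:3)
  expect_equal(out$is_first_fixation_on_item, c(TRUE, TRUE, FALSE))
  single <- compute_ranks(f[1, ])
  expect_equal(single$rank, 1L)
})

test_that("the parse pipeline recovers ground-truth item visits", {
  hits <- 0; total <- 0
  for (seed in 1:8) {
    d <- generate_display(search_conditions()[(seed %% 6) + 1], seed)
    g <- simulate_gaze(d, rng_seed = 400 + seed)
    fx <- parse_trial(g$trace, d)
    expect_equal(fx$rank, seq_len(nrow(fx)))
    truth <- g$fixations
    total <- total + nrow(truth)
    for (j in seq_len(nrow(truth))) {
      hits <- hits + any(fx$item_id == truth$item_id[j] &
                           abs(fx$onset_ms - truth$onset_ms[j]) <= 10)
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("behavioral summaries match independent recounts", {
  ses <- fixation_session(5)
  s <- summarize_behavior(ses$trials, ses$fixations)
  expect_true(all(s$by_condition$error_rate_pct >= 0 &
                    s$by_condition$error_rate_pct <= 100))
  # recount oracle for one condition: mean fixation count over correct trials
  cc <- "1T_0RD"
  ok <- ses$trials[ses$trials$condition == cc & ses$trials$correct, ]
  counts <- vapply(seq_len(nrow(ok)), function(i) {
    sum(ses$fixations$run == ok$run[i] & ses$fixations$trial == ok$trial[i])
  }, numeric(1))
  expect_equal(s$by_condition$mean_n_fixations[s$by_condition$condition == cc],
               mean(counts))
  # all-correct session: error rate 0 everywhere
  tr0 <- ses$trials; tr0$correct <- TRUE
  s0 <- summarize_behavior(tr0, ses$fixations)
  expect_true(all(s0$by_condition$error_rate_pct == 0))
  # item-type table has the three classes with plausible durations
  expect_equal(s$by_item_type$item_type, c("T", "RD", "CD"))
  expect_true(all(s$by_item_type$mean_fixdur_ms > 200, na.rm = TRUE))
})
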