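# Shared across the blocks below: one small bank run (shorter sessions than
# the defaults to keep the unit suite fast; the full-length study runs in the
# acceptance suite).
small_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) {
      subjects <- make_subject_bank(4, seed = 2, segment_bins = 300)
      bank <<- run_bank(subjects, duration_s = 300, seed = 40)
    }
    bank
  }
})

test_that("open-loop runs are deterministic with zero control effort", {
  subj <- make_subject_bank(1, seed = 3, segment_bins = 300)[[1]]
  r1 <- run_scenario(subj, "open", "lvhv", seed = 9, duration_s = 300)
  r2 <- run_scenario(subj, "open", "lvhv", seed = 9, duration_s = 300)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_true(all(r1$trajectory$u == 0))
  # matches the generative model driven by s alone
  K <- nrow(r1$trajectory)
  draws <- withr::with_seed(9, list(eps = rnorm(K, 0, sqrt(subj$params$sigma_eps2))))
  x_manual <- cumsum(c(subj$params$x0,
                       (draws$eps + r1$trajectory$s)[-K])) +
    c(0, cumsum(rep(0, K - 1))) # control contributes nothing
  expect_equal(r1$trajectory$x_true, x_manual, tolerance = 1e-12)
})

test_that("closed modes require a matching calibrated controller", {
  subj <- make_subject_bank(1, seed = 3, segment_bins = 300)[[1]]
  expect_error(run_scenario(subj, "inhibitory", "lvhv", seed = 1,
                            duration_s = 300),
               class = "valenceloop_calibration_error")
  open <- run_scenario(subj, "open", "lvhv", seed = 1, duration_s = 300)
  ctrl <- calibrate_controller(fuzzy_controller("excitatory"), open)
  expect_error(run_scenario(subj, "inhibitory", "lvhv", seed = 1,
                            duration_s = 300, controller = ctrl),
               "does not match")
})

test_that("same-seed open and closed runs differ only after the first control action", {
  subj <- make_subject_bank(1, seed = 4, segment_bins = 300)[[1]]
  open <- run_scenario(subj, "open", "lvhv", seed = 11, duration_s = 300)
  ctrl <- calibrate_controller(fuzzy_controller("inhibitory"), open)
  inhib <- run_scenario(subj, "inhibitory", "lvhv", seed = 11,
                        duration_s = 300, controller = ctrl)
  first_u <- which(inhib$trajectory$u != 0)[1]
  if (is.na(first_u)) first_u <- nrow(inhib$trajectory)
  expect_identical(open$trajectory$x_true[seq_len(first_u)],
                   inhib$trajectory$x_true[seq_len(first_u)])
  expect_identical(open$trajectory$n[seq_len(first_u)],
                   inhib$trajectory$n[seq_len(first_u)])
  # warm-up suspension
  expect_true(all(inhib$trajectory$u[inhib$trajectory$t_s < 60] == 0))
  # inhibitory control never excites
  expect_true(all(inhib$trajectory$u <= 0))
})

test_that("inhibitory control stays silent in the first LV half and acts in HV", {
  subj <- make_subject_bank(1, seed = 6, segment_bins = 600)[[1]]
  open <- run_scenario(subj, "open", "lvhv", seed = 12, duration_s = 600)
  ctrl <- calibrate_controller(fuzzy_controller("inhibitory"), open)
  inhib <- run_scenario(subj, "inhibitory", "lvhv", seed = 12,
                        duration_s = 600, controller = ctrl)
  tr <- inhib$trajectory
  lv_half <- tr$label == "LV" & tr$t_s >= 60
  hv_half <- tr$label == "HV"
  expect_lt(mean(tr$u[lv_half] != 0), 0.05)
  expect_lt(mean(tr$u[hv_half]), 0) # sustained negative effort in HV
})

test_that("per-period summaries recompute from the trajectory and partition spikes", {
  bank <- small_bank()
  subj <- make_subject_bank(1, seed = 3, segment_bins = 300)[[1]]
  res <- run_scenario(subj, "open", "hvlv", seed = 5, duration_s = 300)
  tr <- res$trajectory[res$trajectory$t_s >= res$warmup_s, ]
  manual <- tapply(tr$n, tr$label, sum)
  expect_equal(res$summaries$spike_count[res$summaries$period == "HV"],
               unname(manual[["HV"]]))
  expect_equal(sum(res$summaries$spike_count), sum(tr$n))
  # round trip through CSV export
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(res$trajectory, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  back <- back[back$t_s >= res$warmup_s, ]
  expect_equal(as.vector(tapply(back$n, back$label, sum)[c("HV", "LV")]),
               res$summaries$spike_count)
})

test_that("paired evaluation computes exact t statistics and degenerate cases", {
  # identical open/closed -> zero mean difference, degenerate p = 1
  base <- tibble::tibble(
    subject = rep(1:4, each = 2), order = "lvhv",
    period = rep(c("LV", "HV"), 4),
    spike_count = rep(c(10, 20), 4), mean_valence = rep(c(-1, 0), 4)
  )
  same <- dplyr::bind_rows(
    dplyr::mutate(base, mode = "open"),
    dplyr::mutate(base, mode = "inhibitory")
  )
  w <- testthat::capture_warnings(ev <- evaluate_bank(same))
  expect_true(all(grepl("zero-variance", w)))
  expect_true(all(ev$mean_diff == 0))
  expect_true(all(ev$p_value == 1))

  # constructed shift + tiny noise: strongly significant
  shifted <- dplyr::bind_rows(
    dplyr::mutate(base, mode = "open"),
    dplyr::mutate(base, mode = "inhibitory",
                  spike_count = spike_count + c(1, 1.01, 0.99, 1, 1.02, 0.98, 1, 1),
                  mean_valence = mean_valence + 1)
  )
  suppressWarnings(ev2 <- evaluate_bank(shifted))
  expect_lt(max(ev2$p_value[ev2$metric == "spike_count"]), 0.01)

  # t statistic equals the hand-rolled paired formula on a printed fixture
  d5 <- c(0.8, 1.1, 0.7, 1.3, 0.9)
  t_manual <- mean(d5) / (sd(d5) / sqrt(5))
  p_manual <- 2 * pt(-abs(t_manual), df = 4)
  expect_equal(t.test(d5)$p.value, p_manual, tolerance = 1e-12)
  fix <- dplyr::bind_rows(
    tibble::tibble(subject = 1:5, order = "lvhv", period = "HV", mode = "open",
                   spike_count = c(10, 12, 9, 14, 11), mean_valence = 0),
    tibble::tibble(subject = 1:5, order = "lvhv", period = "HV",
                   mode = "inhibitory",
                   spike_count = c(10, 12, 9, 14, 11) + d5, mean_valence = 0)
  )
  suppressWarnings(ev3 <- evaluate_bank(fix))
  expect_equal(ev3$p_value[ev3$metric == "spike_count"], p_manual,
               tolerance = 1e-12)
})

test_that("directional efficacy emerges on a small bank", {
  bank <- small_bank()
  ev <- suppressWarnings(evaluate_bank(bank))
  inh_hv <- ev[ev$mode == "inhibitory" & ev$period == "HV", ]
  exc_lv <- ev[ev$mode == "excitatory" & ev$period == "LV", ]
  expect_true(all(inh_hv$mean_diff < 0))
  expect_true(all(exc_lv$mean_diff > 0))
  # non-interference: first-half LV under inhibition is (near-)untouched
  ni <- ev[ev$mode == "inhibitory" & ev$period == "LV" & ev$order == "lvhv", ]
  expect_true(all(ni$p_value > 0.05))
  expect_s3_class(autoplot(run_scenario(
    make_subject_bank(1, seed = 3, segment_bins = 300)[[1]],
    "open", "lvhv", seed = 9, duration_s = 300
  )), "ggplot")
})
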