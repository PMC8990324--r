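test_that("membership functions evaluate their piecewise-linear shapes", {
  tr <- membership_fn("trapezoid", c(0, 1, 2, 4))
  expect_equal(mf_eval(tr, c(-1, 0, 0.5, 1, 1.5, 2, 3, 4, 5)),
               c(0, 0, 0.5, 1, 1, 1, 0.5, 0, 0))
  tri <- membership_fn("triangle", c(-1, 0, 1))
  expect_equal(mf_eval(tri, c(-1, -0.5, 0, 0.25, 1)), c(0, 0.5, 1, 0.75, 0))

  # dense-grid agreement with the independent interpolation oracle
  v <- seq(-2, 6, length.out = 2001)
  expect_equal(mf_eval(tr, v), mf_oracle(tr, v), tolerance = 1e-12)
  expect_equal(mf_eval(tri, v), mf_oracle(tri, v), tolerance = 1e-12)

  expect_error(membership_fn("trapezoid", c(1, 0, 2, 3)), "non-decreasing")
})

test_that("fuzzification clamps to the universe and honours symmetry", {
  ctrl <- test_controller()
  # plateau -> degree 1
  expect_equal(fuzzify(-1.5, ctrl)[["LowValence"]], 1)
  # crossover of the two symmetric functions -> both 0.5
  d <- fuzzify(0, ctrl)
  expect_equal(unname(d["LowValence"]), 0.5)
  expect_equal(unname(d["HighValence"]), 0.5)
  # clamping: values beyond the universe behave like the edge
  expect_equal(fuzzify(-100, ctrl), fuzzify(-2, ctrl))

  unc <- fuzzy_controller("inhibitory")
  expect_error(fuzzify(0, unc), class = "valenceloop_calibration_error")
})

test_that("Mamdani inference equals brute-force max-min on the grid", {
  ctrl <- test_controller("inhibitory")
  # single active rule: aggregate is that output MF clipped at the degree
  agg1 <- fuzzy_infer(c(LowValence = 0, HighValence = 0.6), ctrl)
  clip <- pmin(0.6, mf_eval(ctrl$output_mfs$Inhibition, agg1$u))
  expect_equal(agg1$mu, clip)

  # all degrees zero -> identically zero aggregate, defuzzifies to 0
  agg0 <- fuzzy_infer(c(LowValence = 0, HighValence = 0), ctrl)
  expect_equal(agg0$mu, rep(0, nrow(agg0)))
  expect_equal(defuzzify_centroid(agg0), 0)

  # two active rules vs the independent max-min oracle on the same grid
  set.seed(91)
  for (i in 1:20) {
    degs <- c(LowValence = runif(1), HighValence = runif(1))
    agg <- fuzzy_infer(degs, ctrl)
    oracle <- mamdani_oracle_fn(ctrl, degs)(agg$u)
    expect_equal(agg$mu, oracle, tolerance = 1e-12)
  }
})

test_that("centroid defuzzification is exact on symmetric shapes", {
  u_max <- 0.1
  grid <- u_max * seq(-1, 1, length.out = 2001)

  # symmetric triangle centred at c
  cc <- 0.03
  tri <- membership_fn("triangle", c(cc - 0.02, cc, cc + 0.02))
  expect_equal(defuzzify_centroid(tibble::tibble(u = grid, mu = mf_eval(tri, grid))),
               cc, tolerance = 1e-6)

  # symmetric trapezoid clipped at any height keeps its centroid
  trap <- membership_fn("trapezoid", c(-0.06, -0.02, 0.02, 0.06))
  for (h in c(0.25, 0.6, 1)) {
    mu <- pmin(h, mf_eval(trap, grid))
    expect_equal(defuzzify_centroid(tibble::tibble(u = grid, mu = mu)), 0,
                 tolerance = 1e-9)
  }
})

test_that("centroid matches a fine Riemann quadrature on random aggregates", {
  set.seed(101)
  for (mode in c("inhibitory", "excitatory")) {
    ctrl <- test_controller(mode)
    for (i in 1:10) {
      degs <- c(LowValence = runif(1), HighValence = runif(1))
      u_pkg <- defuzzify_centroid(fuzzy_infer(degs, ctrl))
      u_ref <- riemann_centroid(mamdani_oracle_fn(ctrl, degs), ctrl$u_max,
                                n_points = 1e6)
      expect_lt(abs(u_pkg - u_ref), 1e-6 * ctrl$u_max)
    }
  }
})

test_that("input smoothing is a trailing moving average", {
  expect_equal(smooth_input(rep(2.5, 100)), 2.5)
  expect_equal(smooth_input(c(1, 2, 3), window_bins = 20), 2) # shorter history
  step <- c(rep(0, 30), rep(1, 40))
  sm <- sapply(seq_along(step), function(k) smooth_input(step[1:k], 20))
  expect_equal(sm[50], 1) # exactly 20 bins after the step
  expect_lt(sm[49], 1)
})

test_that("control steps respect warm-up, sign, bound and monotonicity", {
  for (mode in c("inhibitory", "excitatory")) {
    ctrl <- test_controller(mode)
    # suspended during the first minute
    expect_identical(control_step(ctrl, c(5, 5, 5), t_s = 30), 0)

    vs <- seq(-2, 2, length.out = 401)
    us <- sapply(vs, function(v) control_step(ctrl, rep(v, 30), t_s = 120))
    expect_true(all(abs(us) <= ctrl$u_max))
    if (mode == "inhibitory") {
      expect_true(all(us <= 0))
      expect_true(all(diff(us) <= 1e-9)) # non-increasing in valence
      expect_identical(us[vs <= -0.5][1], 0) # LowValence plateau -> Neutral
      expect_lt(us[length(us)], 0) # deep HighValence -> inhibition
    } else {
      expect_true(all(us >= 0))
      # corrective magnitude shrinks as v leaves the low-valence region
      expect_true(all(diff(us) <= 1e-9))
      expect_gt(us[1], 0) # deep LowValence -> excitation
      expect_identical(us[length(us)], 0)
    }
    # continuity: no jump exceeding what the grid resolution supports
    expect_lt(max(abs(diff(us))), 0.05 * ctrl$u_max)
  }
})

test_that("calibration places breakpoints on the open-loop medians", {
  set.seed(111)
  d <- tibble::tibble(
    x_filt = c(rnorm(300, -1, 0.1), rnorm(300, 1, 0.1)),
    label = rep(c("LV", "HV"), each = 300)
  )
  ctrl <- calibrate_controller(fuzzy_controller("inhibitory"), d)
  m_lv <- median(d$x_filt[d$label == "LV"])
  m_hv <- median(d$x_filt[d$label == "HV"])
  mid <- (m_lv + m_hv) / 2
  degs <- fuzzify(mid, ctrl)
  expect_equal(unname(degs["LowValence"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(degs["HighValence"]), 0.5, tolerance = 1e-9)
  # dead band: at the LV median the controller sees no HighValence at all
  expect_equal(unname(fuzzify(m_lv, ctrl)["HighValence"]), 0)

  # shift equivariance: +c moves every breakpoint by +c
  d2 <- dplyr::mutate(d, x_filt = x_filt + 0.7)
  ctrl2 <- calibrate_controller(fuzzy_controller("inhibitory"), d2)
  expect_equal(ctrl2$input_mfs$LowValence$bp,
               ctrl$input_mfs$LowValence$bp + 0.7, tolerance = 1e-9)

  # degenerate contrast -> calibration error advising exclusion
  flat <- tibble::tibble(x_filt = rep(0.3, 100),
                         label = rep(c("LV", "HV"), 50))
  expect_error(calibrate_controller(fuzzy_controller("inhibitory"), flat),
               class = "valenceloop_calibration_error")

  expect_s3_class(plot_memberships(ctrl), "ggplot")
})
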