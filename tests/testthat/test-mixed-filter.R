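test_that("prediction step adds process variance and keeps the mean", {
  pr <- valence_params(sigma_eps2 = 0.1)
  st <- list(x_filt = 1.0, v_filt = 0.5)
  nxt <- mixed_filter_step(st, n = 0, z = pr$alpha + pr$beta * 1.0, pr)
  expect_equal(nxt$x_pred, 1.0)
  expect_equal(nxt$v_pred, 0.6)

  # repeated prediction grows variance linearly: T steps add T * sigma_eps2
  pr2 <- valence_params(sigma_eps2 = 0.02, beta = 1e-9, sigma_omega2 = 1e9)
  st <- NULL
  for (k in 1:10) st <- mixed_filter_step(st, 0, 0, pr2, v0 = 1, use_binary = FALSE)
  expect_equal(st$v_pred, 1 + 9 * 0.02, tolerance = 1e-6)
})

test_that("continuous-only update reproduces the textbook Kalman update", {
  pr <- valence_params(alpha = 0, beta = 1, sigma_eps2 = 1, sigma_omega2 = 1,
                       gamma = 0, x0 = 0)
  st <- mixed_filter_step(NULL, n = 0, z = 1, pr, v0 = 1, use_binary = FALSE)
  expect_equal(st$x_filt, 0.5, tolerance = 1e-12)
  expect_equal(st$v_filt, 0.5, tolerance = 1e-12)
})

test_that("binary-only update matches the grid-search posterior mode", {
  pr <- valence_params(alpha = 0, beta = 1e-9, sigma_eps2 = 1,
                       sigma_omega2 = 1, gamma = 0, x0 = 0)
  st <- mixed_filter_step(NULL, n = 1, z = 0, pr, v0 = 1, use_continuous = FALSE)
  # oracle: maximize N(x; 0, 1) * plogis(x)^1 on a fine grid
  g <- seq(-8, 8, length.out = 400001)
  lp <- -g^2 / 2 + log(plogis(g))
  expect_lt(abs(st$x_filt - g[which.max(lp)]), 1e-4)
})

test_that("no innovation when both correction terms vanish", {
  pr <- valence_params(alpha = 0.3, beta = 0.5, sigma_omega2 = 0.01,
                       gamma = -1, x0 = 0.7, sigma_eps2 = 0.05)
  x_pred <- 0.7
  n_star <- spike_prob(x_pred, pr$gamma) # continuous-valued "observation"
  st <- mixed_filter_step(NULL, n = n_star, z = pr$alpha + pr$beta * x_pred,
                          pr, v0 = 0.2)
  expect_equal(st$x_filt, x_pred, tolerance = 1e-9)
})

test_that("Newton solution equals the posterior mode on randomized cases", {
  set.seed(77)
  for (i in 1:25) {
    x_pred <- rnorm(1, 0, 2)
    v_pred <- runif(1, 0.05, 2)
    alpha <- rnorm(1); beta <- rnorm(1, 0.5, 0.5); gamma <- rnorm(1)
    sw2 <- runif(1, 0.05, 2)
    n <- rbinom(1, 1, 0.5)
    z <- alpha + beta * x_pred + rnorm(1, 0, sqrt(sw2))
    pr <- valence_params(alpha = alpha, beta = beta, sigma_eps2 = 1,
                         sigma_omega2 = sw2, gamma = gamma, x0 = x_pred)
    st <- mixed_filter_step(NULL, n, z, pr, v0 = v_pred)
    oracle <- grid_posterior_mode(x_pred, v_pred, n, z, alpha, beta, gamma, sw2)
    expect_lt(abs(st$x_filt - oracle), 1e-4)
  }
})

test_that("batch filtering equals streaming and handles empty input", {
  pr <- valence_params()
  sim <- simulate_valence(pr, K = 120, seed = 21)
  post <- mixed_filter(sim, pr)
  st <- NULL
  for (k in seq_len(120)) {
    st <- mixed_filter_step(st, sim$n[k], sim$z[k], pr)
    expect_identical(st$x_filt, post$x_filt[k])
    expect_identical(st$v_filt, post$v_filt[k])
  }
  empty <- mixed_filter(tibble::tibble(n = integer(), z = numeric()), pr)
  expect_equal(nrow(empty), 0)
})

test_that("filtered variance converges to a fixed point on long constant runs", {
  pr <- valence_params()
  K <- 2000
  const <- tibble::tibble(n = rep(0L, K), z = rep(pr$alpha, K))
  post <- mixed_filter(const, pr)
  expect_lt(max(abs(diff(tail(post$v_filt, 100)))), 1e-10)
  expect_true(all(post$v_filt <= post$v_pred))
})

test_that("smoother matches the static-state conjugate posterior when noise-free", {
  # sigma_eps2 ~ 0: the state is static, so the smoothed mean at every bin
  # equals the full-information Gaussian posterior mean of a single unknown
  pr <- valence_params(alpha = 0, beta = 1, sigma_eps2 = 1e-14,
                       sigma_omega2 = 0.5, gamma = 0, x0 = 0)
  set.seed(31)
  K <- 40
  z <- rnorm(K, 0.8, sqrt(0.5))
  post <- mixed_filter(tibble::tibble(n = rep(0L, K), z = z), pr,
                       v0 = 1, use_binary = FALSE)
  sm <- mixed_smoother(post)
  # conjugate posterior: prior N(0, 1), K observations with variance 0.5
  post_var <- 1 / (1 / 1 + K / 0.5)
  post_mean <- post_var * sum(z) / 0.5
  expect_equal(sm$x_sm, rep(post_mean, K), tolerance = 1e-6)
  expect_equal(sm$v_sm, rep(post_var, K), tolerance = 1e-6)
})

test_that("smoother initialization, variance ordering and moments hold", {
  pr <- valence_params()
  sim <- simulate_valence(pr, K = 300, seed = 41)
  post <- mixed_filter(sim, pr)
  sm <- mixed_smoother(post)
  K <- nrow(post)
  expect_equal(sm$x_sm[K], post$x_filt[K])
  expect_equal(sm$v_sm[K], post$v_filt[K])
  expect_true(all(sm$v_sm <= post$v_filt + 1e-12))
  expect_true(all(sm$W >= sm$x_sm^2))
  expect_equal(sm$A[-K], post$v_filt[-K] / post$v_pred[-1])
  expect_equal(sm$cov_cross[-1], sm$A[-K] * sm$v_sm[-1])
})

test_that("with the binary channel off, filter and smoother match Kalman/RTS", {
  set.seed(51)
  for (i in 1:5) {
    pr <- valence_params(alpha = rnorm(1), beta = rnorm(1, 1, 0.3),
                         sigma_eps2 = runif(1, 0.001, 0.1),
                         sigma_omega2 = runif(1, 0.01, 1),
                         gamma = rnorm(1), x0 = rnorm(1))
    z <- rnorm(200)
    feats <- tibble::tibble(n = rbinom(200, 1, 0.3), z = z)
    post <- mixed_filter(feats, pr, use_binary = FALSE)
    sm <- mixed_smoother(post)
    ref <- kalman_rts_ref(z, pr$alpha, pr$beta, pr$sigma_eps2,
                          pr$sigma_omega2, pr$x0, pr$sigma_eps2)
    expect_lt(max(abs(post$x_filt - ref$x_filt)), 1e-10)
    expect_lt(max(abs(post$v_filt - ref$v_filt)), 1e-10)
    expect_lt(max(abs(sm$x_sm - ref$x_sm)), 1e-10)
    expect_lt(max(abs(sm$v_sm - ref$v_sm)), 1e-10)
  }
})

test_that("95% smoother band covers the true state at its nominal rate", {
  pr <- valence_params()
  cover <- sapply(1:4, function(s) {
    ss <- simulate_session(pr, n_trials = 10, seed = 60 + s)
    post <- mixed_filter(ss, pr)
    sm <- mixed_smoother(post)
    mean(abs(ss$x - sm$x_sm) <= 1.96 * sqrt(sm$v_sm))
  })
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})
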