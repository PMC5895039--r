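test_that("stimulus regression through the origin matches its closed form", {
  set.seed(5)
  x <- rnorm(60); y <- 3 * x + rnorm(60)
  beta <- sum(x * y) / sum(x^2)
  expect_equal(regress_out_stimulus(y, x), y - beta * x)
  # exactly proportional counts leave zero residuals
  expect_equal(regress_out_stimulus(3 * x, x), rep(0, 60), tolerance = 1e-12)
  # zero signal: residuals are the counts themselves
  expect_equal(regress_out_stimulus(y, rep(0, 60)), y)
})

test_that("the Poisson GLM recovers the closed-form intercept and the GP limits hold", {
  tr <- toy_session(n = 60, spikes = rep(7L, 60))
  d <- build_design(filter_trials(tr), character(0), target = "spikes")
  f <- fit_poisson_glm(d)
  expect_equal(unname(f$coef[1]), log(7), tolerance = 1e-8)
  # amplitude -> 0 collapses onto the plain GLM
  trials <- small_pop()$trials
  flt <- filter_trials(trials)
  one <- flt[flt$unit_id == flt$unit_id[1], ]
  attr(one, "cp_filtered") <- TRUE
  d2 <- build_design(one, c("choice_prev", "win_prev", "spikes_prev"), "spikes")
  f0 <- fit_poisson_glm(d2)
  f1 <- fit_poisson_glm(d2, gp = list(tau = 35, amplitude = 1e-4))
  expect_lt(max(abs(f0$coef - f1$coef)), 1e-6)
  expect_null(f0$g)
})

test_that("the GP latent is identifiable (near-zero mean) and degenerates to iid ridge", {
  trials <- small_pop()$trials
  flt <- filter_trials(trials)
  one <- flt[flt$unit_id == flt$unit_id[2], ]
  attr(one, "cp_filtered") <- TRUE
  d <- build_design(one, c("win_prev", "spikes_prev"), "spikes")
  f <- fit_poisson_glm(d, gp = list(tau = 35, amplitude = 1))
  expect_lt(abs(mean(f$g)), 0.05 * sd(f$g) + 0.01)
  # tau -> 0: the kernel is diagonal, so each latent solves an independent
  # one-dimensional ridge-penalized Poisson problem
  amp <- 0.5
  f3 <- fit_poisson_glm(d, gp = list(tau = 0.01, amplitude = amp))
  eta <- drop(cbind(1, d$x[d$train, ]) %*% f3$coef)
  y <- d$y[d$train]
  g_oracle <- vapply(seq_along(y), function(i) {
    gi <- 0
    for (it in 1:100) {
      mu <- exp(eta[i] + gi)
      step <- ((y[i] - mu) - gi / amp^2) / (mu + 1 / amp^2)
      gi <- gi + step
      if (abs(step) < 1e-12) break
    }
    gi
  }, numeric(1))
  expect_lt(max(abs(f3$g - g_oracle)), 1e-3)
})

test_that("prediction cc is exact for oracle predictions, zero for constants and shuffles", {
  set.seed(9)
  y <- rpois(100, 20)
  expect_equal(serialcp:::safe_cc(y, y), 1)
  expect_equal(serialcp:::safe_cc(rep(3, 100), y), 0)
  shuffles <- replicate(200, serialcp:::safe_cc(sample(y), y))
  expect_lt(abs(mean(shuffles)), 0.03)
})

test_that("serial structure in spiking is detected and ranked as generated", {
  trials <- small_pop()$trials
  flt <- filter_trials(trials)
  cc_prev <- spike_prediction_cc(flt, "spikes_prev")
  cc_sf <- spike_prediction_cc(flt, c("spikes_prev", "sf"))
  expect_gt(mean(cc_prev$cc), 0.15)
  # adding the slow-fluctuation latent helps on top of the previous count
  expect_gt(mean(cc_sf$cc - cc_prev$cc), 0)
})

test_that("cumulative spike increments isolate the generative pathways", {
  # reward-modulated generator without choice-history pathways into spiking
  cfg <- sim_config(n_units = 10, n_nosignal = 90, signal_counts = rep(15L, 6),
                    w_choice = 0, w_target = 0, w_win = 0, rho = 0,
                    reward_gain = 0.2, ar = 0.05, gp_amp = 0, seed = 83)
  pop <- generate_population(cfg)
  cum <- cumulative_cc(pop$trials,
                       c("choice_prev", "target_prev", "win_prev", "spikes_prev"))
  inc <- setNames(cum$mean_increment, cum$covariate)
  expect_gt(inc[["win_prev"]], 0.05)
  expect_lt(abs(inc[["target_prev"]]), 0.05)
  expect_lt(cum$p_value[cum$covariate == "win_prev"], 0.05)
  # a duplicated covariate contributes exactly nothing
  cum2 <- cumulative_cc(pop$trials, c("win_prev", "win_prev"))
  expect_equal(cum2$mean_increment[2], 0, tolerance = 1e-8)
})

test_that("PSTH basis spans exact template mixtures and survives 1% noise", {
  pp0 <- generate_psth_population(20, 5, noise = 0, max_shift = 0, seed = 2)
  b0 <- psth_basis(pp0$psth, pp0$unit)
  expect_gt(b0$var_explained, 1 - 1e-9)
  pp1 <- generate_psth_population(30, 5, noise = 0.01, max_shift = 2, seed = 3)
  b1 <- psth_basis(pp1$psth, pp1$unit)
  expect_gte(b1$var_explained, 0.99)
  # orthonormal basis
  expect_equal(crossprod(b1$basis), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  # latency recovery up to a common offset
  rel_true <- pp1$latency - pp1$latency[1]
  rel_est <- b1$latency - b1$latency[1]
  expect_gt(mean(rel_true == rel_est), 0.9)
})

test_that("time-resolved fits aggregate to whole-trial predictions", {
  pop <- small_pop()
  trials <- pop$trials
  flt <- filter_trials(trials)
  pm <- psth_matrix_from_trials(trials)
  basis <- psth_basis(pm$psth, pm$unit)
  one <- flt[flt$unit_id == flt$unit_id[1], ]
  attr(one, "cp_filtered") <- TRUE
  tf <- fit_time_resolved(one, basis)
  d <- build_design(one, c("choice", "choice_prev", "target_prev", "win_prev",
                           "spikes_prev", "signal"), "spikes")
  wf <- fit_poisson_glm(d)
  whole <- predict(wf, d, rows = "test")
  expect_lt(abs(sum(tf$pred_test) / sum(whole) - 1), 0.05)
  expect_equal(nrow(tf$quartiles), 4)
})

test_that("early-trial history modulation concentrates prediction in the first quartile", {
  # construct binned counts whose win_prev modulation acts on bins 1-5 only;
  # no-signal trials are rewarded by a fair coin, as in the task
  set.seed(64)
  base <- toy_session(n = 240, signal = rep(c(0.25, -0.25, 0, 0.125, -0.125, 0),
                                            40),
                      choice = rbinom(240, 1, 0.5))
  ns <- base$signal == 0
  base$target[ns] <- rbinom(sum(ns), 1, 0.5)
  base$win <- as.integer(base$choice == base$target)
  profile <- rep(1, 20)
  binned <- lapply(seq_len(240), function(i) {
    wp <- if (i > 1) base$win[i - 1] else 0
    lam <- profile * 2
    lam[1:5] <- lam[1:5] * exp(0.8 * (2 * wp - 1))
    as.integer(rpois(20, lam))
  })
  base$binned <- binned
  base$spikes <- vapply(binned, sum, integer(1))
  flt <- filter_trials(base)
  basis <- psth_basis(matrix(rep(profile * 2, 4), nrow = 4, byrow = TRUE) +
                        matrix(rnorm(80, 0, 0.01), nrow = 4),
                      unit = rep("toy", 4))
  tf <- fit_time_resolved(flt, basis)
  expect_equal(which.max(tf$quartiles$cc), 1)
  expect_gt(tf$quartiles$cc[1], max(tf$quartiles$cc[-1]))
})

test_that("flat templates and constant rates leave nothing to predict", {
  set.seed(65)
  base <- toy_session(n = 160, signal = rep(c(0.25, -0.25, 0, 0), 40),
                      choice = rbinom(160, 1, 0.5))
  ns <- base$signal == 0
  base$target[ns] <- rbinom(sum(ns), 1, 0.5)
  base$win <- as.integer(base$choice == base$target)
  base$binned <- lapply(seq_len(160), function(i) as.integer(rpois(20, 2)))
  base$spikes <- vapply(base$binned, sum, integer(1))
  flt <- filter_trials(base)
  basis <- psth_basis(matrix(2 + rnorm(80, 0, 0.01), nrow = 4),
                      unit = rep("toy", 4))
  tf <- fit_time_resolved(flt, basis)
  expect_true(all(abs(tf$quartiles$cc) < 0.2))
})
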