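test_that("stimulus sequences permute the level multiset; histograms hold 192 frames", {
  cfg <- sim_config(n_nosignal = 30, signal_counts = rep(5L, 6), seed = 1)
  stim <- generate_stimulus_sequence(cfg, seed = 7)
  expect_equal(sort(stim$signal),
               sort(c(rep(0, 30), rep(cfg$signal_levels, cfg$signal_counts))))
  expect_true(all(vapply(stim$frame_hist, sum, numeric(1)) == 192))
  # signal trials elevate the signal disparity on average
  pref <- vapply(stim$frame_hist[stim$signal == 0.25], function(h) h[7], numeric(1))
  ns <- vapply(stim$frame_hist[stim$signal == 0], function(h) h[7], numeric(1))
  expect_gt(mean(pref), mean(ns))
  # one level only -> constant sequence
  cfg1 <- sim_config(n_nosignal = 10, signal_levels = numeric(0),
                     signal_counts = integer(0))
  expect_true(all(generate_stimulus_sequence(cfg1, seed = 1)$signal == 0))
})

test_that("sign alternation in balanced sequences matches the permutation closed form", {
  # uniform permutation of m pluses and m minuses: P(alternation) = m/(2m-1)
  m <- 25L
  cfg <- sim_config(n_nosignal = 1, signal_levels = c(-0.25, 0.25),
                    signal_counts = c(m, m), seed = 1)
  alt <- replicate(1500, {
    s <- generate_stimulus_sequence(cfg)$signal
    s <- s[s != 0]  # the sign subsequence is itself a uniform permutation
    mean(diff(sign(s)) != 0)
  })
  closed <- m / (2 * m - 1)
  se <- sd(alt) / sqrt(length(alt))
  expect_lt(abs(mean(alt) - closed), 3 * se + 1e-3)
  expect_gt(closed, 0.5)
})

test_that("behavior generator reduces to a fair coin and saturates with strong stimulus", {
  w0 <- list(w0 = 0, w_choice = 0, w_target = 0, w_win = 0, w_signal = 0)
  b <- generate_behavior(rep(0, 4000), w0, seed = 2)
  expect_lt(abs(mean(b$choice) - 0.5), 3 * 0.5 / sqrt(4000))
  wS <- list(w0 = 0, w_choice = 0, w_target = 0, w_win = 0, w_signal = 100)
  sig <- rep(c(-0.25, 0.25), 300)
  b2 <- generate_behavior(sig, wS, seed = 3)
  expect_gt(mean(b2$choice == b2$target), 0.999)
})

test_that("switching-weight choice autocorrelation matches an independent recursion oracle", {
  w <- list(w0 = 0, w_choice = -0.275, w_target = 0, w_win = 0, w_signal = 0)
  n <- 2e5
  b <- generate_behavior(rep(0, n), w, seed = 5)
  cb <- 2 * b$choice - 1
  ac_pkg <- cor(cb[-n], cb[-1])
  # independent oracle: plain-R rewrite of the same recursion
  set.seed(99)
  ch <- integer(n); prev <- 0
  for (i in seq_len(n)) {
    ch[i] <- rbinom(1, 1, pnorm(-0.275 * prev))
    prev <- 2 * ch[i] - 1
  }
  cb2 <- 2 * ch - 1
  ac_oracle <- cor(cb2[-n], cb2[-1])
  se <- sqrt(2 / n)
  expect_lt(abs(ac_pkg - ac_oracle), 3 * se)
  expect_lt(ac_pkg, -0.1)  # switching means negative lag-1 autocorrelation
})

test_that("spike generator is Poisson in the no-structure limit and binned counts are consistent", {
  cfg <- sim_config(ar = 0, gp_amp = 0, reward_gain = 0, choice_gain = 0,
                    tuning = 0, baseline_sd = 0, seed = 1)
  tr <- tibble::tibble(signal = rep(0, 5000), choice = rbinom(5000, 1, 0.5),
                       win = rbinom(5000, 1, 0.5), frame_hist = vector("list", 5000))
  sp <- generate_spikes(tr, cfg, seed = 11)
  fano <- var(sp$spikes) / mean(sp$spikes)
  expect_lt(abs(fano - 1), 0.08)
  expect_equal(vapply(sp$binned, sum, numeric(1)), as.numeric(sp$spikes))
  expect_true(all(sp$gp == 0))
})

test_that("slow-fluctuation autocovariance of counts follows the kernel closed form", {
  # with only the GP in the log rate, counts are Poisson-lognormal:
  # cov(s_t, s_{t+k}) = m^2 (exp(K(k)) - 1),  var = m + m^2 (exp(K(0)) - 1)
  cfg <- sim_config(ar = 0, gp_amp = 0.3, gp_tau = 35, reward_gain = 0,
                    choice_gain = 0, tuning = 0, baseline_sd = 0, seed = 1)
  n <- 1500
  acv <- matrix(0, 4, 10)
  for (r in 1:4) {
    tr <- tibble::tibble(signal = rep(0, n), choice = rbinom(n, 1, 0.5),
                         win = rbinom(n, 1, 0.5), frame_hist = vector("list", n))
    sp <- generate_spikes(tr, cfg, seed = 200 + r)
    s <- sp$spikes
    acv[r, ] <- vapply(1:10, function(k) cov(s[1:(n - k)], s[(k + 1):n]), numeric(1))
  }
  emp <- colMeans(acv)
  m <- exp(cfg$log_baseline + cfg$gp_amp^2 / 2)
  theo <- m^2 * (exp(cfg$gp_amp^2 * exp(-((1:10) / cfg$gp_tau)^2)) - 1)
  expect_gt(cor(emp, theo), 0.9)
  expect_lt(abs(emp[1] / theo[1] - 1), 0.35)
  # autocovariance decays with lag as the kernel predicts
  expect_gt(emp[1], emp[10])
})

test_that("populations are bit-reproducible from the seed and pass validation", {
  cfg <- sim_config(n_units = 3, n_nosignal = 40, signal_counts = rep(7L, 6),
                    seed = 77)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$trials, p2$trials)
  expect_silent(validate_sessions(p1$trials))
  expect_equal(p1$truth$units[[1]]$seed, p1$truth$seeds[1])
})

test_that("uncoupled populations sit at chance CP; coupled ones do not", {
  cfg0 <- sim_config(n_units = 10, n_nosignal = 80, signal_counts = rep(14L, 6),
                     rho = 0, seed = 31)
  cp0 <- semipartial_cp(generate_population(cfg0)$trials, "none")
  expect_lt(abs(mean(cp0$cp) - 0.5), 0.05)
  cp1 <- semipartial_cp(small_pop()$trials, "none")
  expect_gt(mean(cp1$cp), 0.53)
})

test_that("YAML configurations round-trip into sim_config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "n_units: 3", "gp_tau: 20", "w_choice: -0.1"), path)
  cfg <- sim_config_from_yaml(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 5)
  expect_equal(cfg$gp_tau, 20)
  expect_equal(cfg$w_choice, -0.1)
  writeLines("not_a_field: 1", path)
  expect_error(sim_config_from_yaml(path), "unknown configuration")
  unlink(path)
})
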