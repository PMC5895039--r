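test_that("area under the ROC matches hand-counted examples", {
  expect_equal(area_under_roc(c(2, 4, 1, 3), c(1, 1, 0, 0)), 0.75)
  expect_equal(area_under_roc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
})

test_that("aROC handles ties as one half and flips under score negation", {
  expect_equal(area_under_roc(rep(3, 8), c(1, 1, 1, 1, 0, 0, 0, 0)), 0.5)
  set.seed(4)
  s <- rnorm(50); l <- rbinom(50, 1, 0.5)
  expect_equal(area_under_roc(-s, l), 1 - area_under_roc(s, l))
  expect_error(area_under_roc(s, rep(1, 50)), "both label classes")
})

test_that("large penalties zero every weight; separation triggers the bounded fallback", {
  flt <- filter_trials(small_pop()$trials)
  one <- flt[flt$unit_id == flt$unit_id[1], ]
  attr(one, "cp_filtered") <- TRUE
  d <- build_design(one, c("choice_prev", "target_prev", "win_prev", "signal"),
                    "choice")
  f <- fit_probit_lasso(d, lambda = 10)
  expect_true(all(f$coef[-1] == 0))
  expect_true(f$converged)
  # perfectly separable toy design at lambda = 0
  tr <- toy_session(n = 30, signal = rep(c(0.25, -0.25, 0), 10),
                    choice = rep(c(1, 0, 1), 10))
  dsep <- build_design(filter_trials(tr), "signal", "choice")
  expect_warning(fsep <- fit_probit_lasso(dsep, lambda = 0), "separation")
  expect_lte(max(abs(fsep$coef)), 12)
})

test_that("independent targets give near-zero weights", {
  set.seed(8)
  n <- 20000
  tr <- toy_session(n = n, signal = rep(c(0.1, -0.1, 0), length.out = n),
                    choice = rbinom(n, 1, 0.5),
                    spikes = rpois(n, 20))
  d <- build_design(filter_trials(tr), c("choice_prev", "spikes"), "choice")
  f <- fit_probit_lasso(d, lambda = 0)
  se <- sqrt(diag(solve(crossprod(cbind(1, d$x[d$train, ])))) * (2 * pi / 4))
  expect_true(all(abs(f$coef[-1]) < 3 * se[-1] + 0.02))
})

test_that("training likelihood never decreases when covariates are added at lambda 0", {
  flt <- filter_trials(small_pop()$trials)
  one <- flt[flt$unit_id == flt$unit_id[2], ]
  attr(one, "cp_filtered") <- TRUE
  sets <- list("choice_prev",
               c("choice_prev", "target_prev"),
               c("choice_prev", "target_prev", "win_prev", "spikes"))
  nlls <- vapply(sets, function(cv) {
    fit_probit_lasso(build_design(one, cv, "choice"), lambda = 0)$nll
  }, numeric(1))
  expect_true(all(diff(nlls) <= 1e-8))
})

test_that("choice prediction performance detects history and respects the null", {
  cfg_hist <- sim_config(n_units = 8, n_nosignal = 80, signal_counts = rep(14L, 6),
                         w_choice = -0.5, w_target = 0, w_win = 0, rho = 0,
                         seed = 61)
  cpp_hist <- choice_prediction_performance(
    generate_population(cfg_hist)$trials, "choice_prev", lambda = 0.025)
  expect_gt(mean(cpp_hist$cpp, na.rm = TRUE), 0.54)
  cfg_null <- sim_config(n_units = 8, n_nosignal = 80, signal_counts = rep(14L, 6),
                         w_choice = 0, w_target = 0, w_win = 0, rho = 0,
                         seed = 62)
  cpp_null <- choice_prediction_performance(
    generate_population(cfg_null)$trials, "choice_prev", lambda = 0.025)
  expect_lt(abs(mean(cpp_null$cpp, na.rm = TRUE) - 0.5), 0.04)
})

test_that("cumulative increments: first equals solo performance, duplicates add zero", {
  trials <- small_pop()$trials
  cum <- cumulative_cpp(trials, c("choice_prev", "choice_prev"), lambda = 0.025)
  per_unit <- attr(cum, "per_unit")
  solo <- cp_to_choice_correlation(
    choice_prediction_performance(trials, "choice_prev", lambda = 0.025)$cpp)
  expect_equal(unname(per_unit[, 1]), solo, tolerance = 1e-6)
  expect_equal(cum$mean_increment[1], cum$mean_metric[1])
  # duplicated columns give the same optimum up to solver tolerance; the
  # rank-based metric can flip ties, so the increment is only near zero
  expect_lt(abs(cum$mean_increment[2]), 0.005)
})

test_that("the CP / choice-correlation conversion is odd, increasing, and exact at chance", {
  expect_equal(cp_to_choice_correlation(0.5), 0)
  expect_equal(cp_to_choice_correlation(0.4), -cp_to_choice_correlation(0.6),
               tolerance = 1e-8)
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(cp_to_choice_correlation(grid)) > 0))
  expect_error(cp_to_choice_correlation(1.2), "strictly in")
  # round trip
  expect_equal(cp_from_choice_correlation(cp_to_choice_correlation(0.62)), 0.62,
               tolerance = 1e-8)
})

test_that("history-induced performance loss follows (pi/16) sigma^2 and tracks simulation", {
  expect_equal(history_performance_loss(0), 0)
  expect_equal(history_performance_loss(0.16), pi / 16 * 0.16)
  # simulated observer with a history-induced bias b of variance sigma2 on the
  # decision variable: accuracy at signed stimulus x is (Phi(x+b)+Phi(x-b))/2
  set.seed(12)
  x <- rep(c(0.06, 0.125, 0.25) * 4, each = 40000)
  sim_drop <- vapply(c(0.05, 0.1, 0.2), function(s2) {
    b <- rnorm(length(x), 0, sqrt(s2))
    mean(pnorm(x)) - mean((pnorm(x + b) + pnorm(x - b)) / 2)
  }, numeric(1))
  pred <- history_performance_loss(c(0.05, 0.1, 0.2))
  expect_true(all(sim_drop > 0))
  expect_true(all(diff(sim_drop) > 0))
  expect_true(all(sim_drop / pred > 0.25 & sim_drop / pred < 3))
})

test_that("psychometric fits recover the generating bias and slope, split shifts oppositely", {
  set.seed(3)
  n <- 6000
  signal <- sample(c(-0.25, -0.125, -0.06, 0, 0.06, 0.125, 0.25), n, replace = TRUE)
  mu <- 0.03; sigma <- 0.18
  tr <- toy_session(n = n, signal = signal,
                    choice = rbinom(n, 1, pnorm((signal - mu) / sigma)))
  fit <- fit_psychometric(tr)
  expect_lt(abs(fit$mu - mu), 0.02)
  expect_lt(abs(fit$sigma - sigma), 0.02)
  # switching generator: bias after a preferred choice moves away from preferred
  cfg <- sim_config(n_units = 6, w_choice = -0.5, w_target = 0, w_win = 0,
                    rho = 0, seed = 41)
  pop <- generate_population(cfg)
  split <- fit_psychometric(pop$trials, split_by_prev_choice = TRUE)
  wide <- tidyr::pivot_wider(split[, c("unit_id", "group", "mu")],
                             names_from = "group", values_from = "mu")
  expect_gt(mean(wide$prev_pref - wide$prev_null), 0)
  # degenerate one-sided data errors
  expect_error(fit_psychometric(toy_session(n = 10, choice = rep(1, 10))),
               "degenerate")
})

test_that("the independent observer erases history structure", {
  cfg <- sim_config(n_units = 16, seed = 71)
  pop <- generate_population(cfg)
  io <- independent_observer(pop$trials, seed = 72)
  wc <- io$weights$estimate[io$weights$term == "choice_prev"]
  wt <- io$weights$estimate[io$weights$term == "target_prev"]
  expect_lt(abs(mean(wc)), 0.06)
  expect_lt(abs(mean(wt)), 0.06)
  cpp <- choice_prediction_performance(io$trials,
                                       c("choice_prev", "target_prev", "win_prev"),
                                       lambda = 0.025)
  expect_lt(abs(mean(cpp$cpp, na.rm = TRUE) - 0.5), 0.05)
  # the original (history-driven) population does carry history signal
  flt <- filter_trials(pop$trials)
  wc_orig <- strategy_summary(
    purrr::map_dfr(split(flt, flt$unit_id), function(u) {
      attr(u, "cp_filtered") <- TRUE
      d <- build_design(u, c("choice_prev", "target_prev", "win_prev", "signal"),
                        "choice")
      f <- fit_probit_lasso(d, 0.025)
      tibble::tibble(unit_id = u$unit_id[1], term = names(f$coef),
                     estimate = unname(f$coef))
    }))
  expect_lt(attr(wc_orig, "mean_w_choice"), -0.1)
})

test_that("strategy quadrants follow the weight signs", {
  w <- tibble::tibble(
    unit_id = c("a", "a", "b", "b", "c", "c", "d", "d"),
    term = rep(c("choice_prev", "target_prev"), 4),
    estimate = c(0.2, 0.1, -0.2, 0.1, -0.2, -0.1, 0.2, -0.1)
  )
  s <- strategy_summary(w)
  expect_equal(s$quadrant, c("win-stay", "lose-switch", "win-switch", "lose-stay"))
})

test_that("the penalty selector picks the grid maximizer of population CPP", {
  trials <- small_pop()$trials
  lam <- select_lambda(trials, c("choice_prev", "spikes"),
                       grid = c(0, 0.025, 0.5))
  means <- attr(lam, "cpp")
  expect_length(means, 3)
  expect_equal(unname(means[as.character(lam)]), max(means))
  # an absurdly strong penalty (constant scores) cannot win
  expect_lt(lam, 0.5)
})
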