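# Autoregressive choice-spike models: four single-neuron simulators in which
# choice probabilities arise from instantaneous coupling (compatible models
# CM1 feedforward, CM2 feedback) or purely serial pathways (incompatible
# models ICM1 previous-choice->spikes, ICM2 previous-spikes->choice),
# moment-matching fits, and the semipartial-CP power analysis.

ar_model_ids <- c(CM1 = 1L, CM2 = 2L, ICM1 = 3L, ICM2 = 4L)

#' Autoregressive model parameters
#'
#' CM1:  `s_t = mu + alpha (s_{t-1} - mu) + sigma2 e_t`;
#'       `c_t = 1[omega (s_t - mu) + beta cb_{t-1} + sigma1 n_t > 0]`.
#' CM2:  `c_t = 1[beta cb_{t-1} + sigma1 n_t > 0]`;
#'       `s_t = mu + alpha (s_{t-1} - mu) + gamma cb_t + sigma2 e_t`.
#' ICM1: as CM2 but with `gamma cb_{t-1}`.
#' ICM2: `s_t` a plain AR(1); `c_t = 1[omega (s_{t-1} - mu) + beta cb_{t-1}
#'       + sigma1 n_t > 0]`.
#' `cb` is the +/-1 coded choice; counts are emitted as `max(0, round(s_t))`.
#' The threshold rule is invariant to rescaling the decision equation, so
#' `sigma1` is conventionally fixed at 1 when fitting.
#'
#' @param model `"CM1"`, `"CM2"`, `"ICM1"` or `"ICM2"`.
#' @param alpha Spike lag-1 coefficient, `|alpha| < 1`.
#' @param beta Choice lag-1 coefficient, `|beta| < 1` by convention.
#' @param gamma Choice-to-spike gain (CM2, ICM1 only).
#' @param omega Spike-to-choice gain (CM1, ICM2 only).
#' @param sigma1,sigma2 Decision and spike noise SDs (> 0).
#' @param mu Spike baseline.
#' @return An `ar_params` list.
#' @export
ar_params <- function(model, alpha, beta, gamma = NULL, omega = NULL,
                      sigma1 = 1, sigma2, mu) {
  model <- match.arg(model, names(ar_model_ids))
  uses_omega <- model %in% c("CM1", "ICM2")
  if (uses_omega && (is.null(omega) || !is.null(gamma))) {
    stop(model, " uses omega (spike->choice gain), not gamma", call. = FALSE)
  }
  if (!uses_omega && (is.null(gamma) || !is.null(omega))) {
    stop(model, " uses gamma (choice->spike gain), not omega", call. = FALSE)
  }
  stopifnot(abs(alpha) < 1, abs(beta) < 1, sigma1 > 0, sigma2 > 0)
  structure(
    list(model = model, alpha = alpha, beta = beta,
         gamma = gamma, omega = omega,
         coupling = if (uses_omega) omega else gamma,
         sigma1 = sigma1, sigma2 = sigma2, mu = mu),
    class = "ar_params"
  )
}

#' @export
print.ar_params <- function(x, ...) {
  g <- if (x$model %in% c("CM1", "ICM2")) sprintf("omega = %.4g", x$coupling)
       else sprintf("gamma = %.4g", x$coupling)
  cat(sprintf("<ar_params> %s: alpha = %.4g, beta = %.4g, %s, sigma1 = %.4g, sigma2 = %.4g, mu = %.4g\n",
              x$model, x$alpha, x$beta, g, x$sigma1, x$sigma2, x$mu))
  invisible(x)
}

#' Simulate an autoregressive choice-spike model
#'
#' @param params An [ar_params()] object.
#' @param n_trials Number of trials.
#' @param seed Optional seed.
#' @return A tibble with `choice` (0/1) and `count`.
#' @export
simulate_ar <- function(params, n_trials, seed = NULL) {
  stopifnot(inherits(params, "ar_params"))
  with_seed(seed, {
    sim <- ar_simulate_cpp(ar_model_ids[[params$model]], params$alpha,
                           params$beta, params$coupling, params$sigma1,
                           params$sigma2, params$mu, as.integer(n_trials))
    tibble(choice = sim$choice, count = sim$count)
  })
}

#' Observed statistics an AR model is fit to
#'
#' @param choices Binary choices.
#' @param counts Spike counts.
#' @return A one-row tibble with `cp`, `choice_autocov` (lag-1
#'   autocovariance of the +/-1 coded choices), `spike_autocov` (lag-1
#'   autocovariance of the counts), `spike_mean`, `spike_var`.  `cp` is `NA`
#'   when only one choice class is present.
#' @export
ar_moments <- function(choices, counts) {
  as_tibble(as.list(ar_moments_vec(choices, counts)))
}

# Lean vector version used inside fitting loops.  The simulators emit small
# nonnegative integer counts, so the Mann-Whitney statistic is computed from
# per-class histograms in O(max count) rather than by ranking.
ar_moments_vec <- function(choices, counts) {
  n <- length(choices)
  cb <- 2 * choices - 1
  n1 <- as.numeric(sum(choices))
  cp <- if (n1 < 1 || n1 >= n) NA_real_ else {
    nb <- max(counts) + 1L
    h1 <- tabulate(counts[choices == 1] + 1L, nbins = nb)
    h0 <- tabulate(counts[choices == 0] + 1L, nbins = nb)
    below0 <- cumsum(h0) - h0
    sum(h1 * (below0 + 0.5 * h0)) / (n1 * (n - n1))
  }
  c(cp = cp,
    choice_autocov = cov(cb[-n], cb[-1]),
    spike_autocov = cov(counts[-n], counts[-1]),
    spike_mean = mean(counts),
    spike_var = var(counts))
}

ar_free_names <- function(model) {
  c("alpha", "beta", "coupling", "log_sigma2", "mu")
}

ar_theta_to_params <- function(model, theta) {
  ar_params(model,
            alpha = tanh(theta[["alpha"]]),
            beta = tanh(theta[["beta"]]),
            gamma = if (model %in% c("CM2", "ICM1")) theta[["coupling"]] else NULL,
            omega = if (model %in% c("CM1", "ICM2")) theta[["coupling"]] else NULL,
            sigma1 = 1,
            sigma2 = exp(theta[["log_sigma2"]]),
            mu = theta[["mu"]])
}

# Moment-implied starting point: the spike AR chain gives alpha, sigma2 and
# mu in closed form; the choice chain gives beta; the coupling start comes
# from the CP converted to a choice correlation through each model's
# (approximate) covariance pathway.
ar_start_theta <- function(model, stats) {
  alpha0 <- max(min(stats$spike_autocov / max(stats$spike_var, 1e-6), 0.9), -0.9)
  beta0 <- qnorm(min(max((1 + stats$choice_autocov) / 2, 0.01), 0.99))
  sd_s <- sqrt(max(stats$spike_var, 1e-6))
  r <- cp_to_choice_correlation(min(max(stats$cp, 0.01), 0.99))
  rho_c <- max(min(stats$choice_autocov, 0.95), -0.95)
  coup0 <- switch(model,
    CM1 = r / max(sd_s * sqrt(max(1 - r^2, 0.1)), 1e-3),
    ICM2 = r / max(sd_s * max(abs(alpha0), 0.15), 1e-3),
    CM2 = r * sd_s,
    ICM1 = if (abs(rho_c) < 0.02) 0 else r * sd_s * (1 - alpha0 * rho_c) / rho_c
  )
  c(alpha = atanh(alpha0), beta = atanh(max(min(beta0, 0.95), -0.95)),
    coupling = coup0,
    log_sigma2 = 0.5 * log(max(stats$spike_var * (1 - alpha0^2), 1e-3)),
    mu = stats$spike_mean)
}

ar_relative_mismatch <- function(moments, stats) {
  scale <- c(cp = max(abs(stats$cp), 0.5),
             choice_autocov = max(abs(stats$choice_autocov), 0.05),
             spike_autocov = max(abs(stats$spike_autocov), 0.05 * stats$spike_var),
             spike_mean = max(abs(stats$spike_mean), 1),
             spike_var = max(abs(stats$spike_var), 1))
  m <- if (is.data.frame(moments)) unlist(moments[1, names(scale)]) else moments[names(scale)]
  t <- unlist(stats[1, names(scale)])
  if (anyNA(m)) return(rep(10, length(scale)))
  (m - t) / scale
}

#' Fit an AR model to observed statistics by moment matching
#'
#' Minimizes the summed squared relative mismatch between the model's
#' simulated moments (common random numbers across evaluations) and the
#' targets, over the free parameters (`alpha`, `beta`, the coupling gain,
#' `sigma2`, `mu`; `sigma1` fixed at 1 by the threshold-rule scale
#' invariance), using multi-start Nelder-Mead.
#'
#' @param model Model id.
#' @param stats A one-row tibble as from [ar_moments()] (targets: CP, lag-1
#'   choice and spike autocovariance, spike mean and variance).
#' @param n_sim Trials per objective evaluation.
#' @param seed Seed; also fixes the common random numbers.
#' @param restarts Number of jittered restarts.
#' @param reltol Relative mismatch below which every moment must fall for the
#'   fit to be flagged converged.
#' @return An `ar_fit` list: `params`, achieved `moments`, target `stats`,
#'   `objective`, `converged`.
#' @export
fit_ar <- function(model, stats, n_sim = 20000, seed = 1, restarts = 3,
                   reltol = 0.02) {
  model <- match.arg(model, names(ar_model_ids))
  stopifnot(!is.na(stats$cp), stats$cp > 0, stats$cp < 1,
            stats$spike_var >= 0)
  seeds <- substream_seeds(seed, restarts + 1)
  sim_seed <- seeds[1]
  mid <- ar_model_ids[[model]]
  objective <- function(theta) {
    a <- tanh(theta[1]); b <- tanh(theta[2])
    s2 <- exp(theta[4])
    if (!is.finite(s2) || s2 <= 0) return(1e6)
    sim <- with_seed(sim_seed,
                     ar_simulate_cpp(mid, a, b, theta[3], 1, s2, theta[5], n_sim))
    r <- ar_relative_mismatch(ar_moments_vec(sim$choice, sim$count), stats)
    sum(r^2)
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    theta0 <- ar_start_theta(model, stats)
    if (r > 1) {
      theta0 <- theta0 + with_seed(seeds[r + 1],
                                   rnorm(length(theta0), 0, c(0.3, 0.3, abs(theta0[["coupling"]]) + 0.2, 0.2, 1)))
    }
    # stage 1: couplings only (beta, coupling), spike chain held at its
    # moment-implied values -- a well-conditioned 2-D problem
    fixed <- theta0
    opt2d <- optim(theta0[c("beta", "coupling")], function(th2) {
      th <- fixed; th[c("beta", "coupling")] <- th2
      objective(th)
    }, method = "Nelder-Mead", control = list(maxit = 200, reltol = 1e-9))
    theta1 <- fixed
    theta1[c("beta", "coupling")] <- opt2d$par
    # stage 2: full joint refinement
    opt <- optim(theta1, objective, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-9))
    if (opt$value > 1e-5) {
      opt <- optim(opt$par, objective, method = "Nelder-Mead",
                   control = list(maxit = 250, reltol = 1e-9))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
    # every relative mismatch is below reltol/2 at this objective value
    if (best$value < (reltol / 2)^2) break
  }
  theta <- setNames(best$par, ar_free_names(model))
  params <- ar_theta_to_params(model, theta)
  sim <- simulate_ar(params, n_sim, seed = sim_seed)
  moments <- ar_moments(sim$choice, sim$count)
  rel <- ar_relative_mismatch(moments, stats)
  structure(
    list(model = model, params = params, moments = moments, stats = stats,
         objective = best$value, relative_mismatch = rel,
         converged = all(abs(rel) < reltol), n_sim = n_sim),
    class = "ar_fit"
  )
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("<ar_fit> %s, objective %.3g%s\n", x$model, x$objective,
              if (x$converged) "" else " (NOT converged)"))
  print(x$params)
  invisible(x)
}

#' Synthetic per-unit target statistics
#'
#' A synthetic stand-in for the per-unit empirical statistics of a recorded
#' population (the source dataset is not deposited): choice probabilities in
#' 0.55-0.60, negative lag-1 choice autocovariance (a switching strategy),
#' positive lag-1 spike autocovariance, and overdispersed count variance.
#'
#' @param n_units Number of units.
#' @param seed Optional seed.
#' @return A tibble with one row per unit (columns as [ar_moments()]).
#' @export
synthetic_unit_stats <- function(n_units = 75, seed = NULL) {
  with_seed(seed, {
    spike_mean <- runif(n_units, 25, 55)
    spike_var <- spike_mean * runif(n_units, 1.3, 2)
    tibble(
      unit_id = sprintf("unit%03d", seq_len(n_units)),
      cp = runif(n_units, 0.55, 0.60),
      choice_autocov = runif(n_units, -0.35, -0.18),
      spike_autocov = spike_var * runif(n_units, 0.25, 0.45),
      spike_mean = spike_mean,
      spike_var = spike_var
    )
  })
}

#' Per-unit no-signal trial counts for the power analysis
#'
#' Near-equal counts summing to `total` (default 9522 over 75 units).
#'
#' @param n_units Number of units.
#' @param total Total trials over all units.
#' @return Integer vector.
#' @export
power_trial_counts <- function(n_units = 75, total = 9522) {
  base <- total %/% n_units
  extra <- total - base * n_units
  counts <- rep(base, n_units)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  as.integer(counts)
}

# Semipartial CP of one simulated unit: regress the count on the previous
# choice (+/-1) and previous count, take the residual CP.  NA when fewer
# than four choices of either sign.
ar_semipartial_cp <- function(sim) {
  n <- nrow(sim)
  if (sum(sim$choice == 1) < 4 || sum(sim$choice == 0) < 4) {
    return(c(raw = NA_real_, semi = NA_real_))
  }
  cb <- 2 * sim$choice - 1
  keep <- 2:n
  reg <- cbind(choice_prev = cb[keep - 1], count_prev = sim$count[keep - 1])
  res <- residualize(sim$count[keep], reg)
  ch <- sim$choice[keep]
  if (sum(ch == 1) < 4 || sum(ch == 0) < 4) {
    return(c(raw = NA_real_, semi = NA_real_))
  }
  c(raw = choice_probability(sim$count[keep], ch),
    semi = choice_probability(res, ch))
}

#' Semipartial-CP power analysis
#'
#' Repeatedly simulates the fitted model of every unit with its own no-signal
#' trial count; per repetition computes each unit's raw CP and its
#' semipartial CP (previous choice and previous spike count regressed out of
#' the counts), the one-sample t test of the population-mean semipartial CP
#' against 0.5, and the across-unit correlation between raw and semipartial
#' CPs.
#'
#' @param fits A list of `ar_fit` objects (or `ar_params`), one per unit.
#' @param n_trials Integer vector of per-unit trial counts (recycled).
#' @param reps Number of repetitions (default 500).
#' @param seed Seed.
#' @param target_cp Optional per-unit reference CPs (defaults to the CPs the
#'   models were fit to, when `fits` are `ar_fit` objects); used for
#'   `cor_target_semi`, the correlation between the reference CPs and the
#'   repetition's semipartial CPs — the statistic that compares simulated
#'   semipartial CPs against the empirical CPs.
#' @return A `cp_power` tibble with one row per repetition: `rep`,
#'   `mean_semi_cp`, `mean_raw_cp`, `p_value`, `cor_raw_semi` (within-run raw
#'   vs semipartial), `cor_target_semi`, and the summary attribute
#'   `reject_fraction` (share of repetitions with p < 0.05).
#' @export
power_analysis <- function(fits, n_trials, reps = 500, seed = 1,
                           target_cp = NULL) {
  params <- lapply(fits, function(f) if (inherits(f, "ar_fit")) f$params else f)
  if (is.null(target_cp)) {
    target_cp <- vapply(fits, function(f) {
      if (inherits(f, "ar_fit")) f$stats$cp else NA_real_
    }, numeric(1))
  }
  n_units <- length(params)
  n_trials <- rep_len(as.integer(n_trials), n_units)
  rep_seeds <- substream_seeds(seed, reps)
  out <- purrr::map_dfr(seq_len(reps), function(r) {
    cps <- with_seed(rep_seeds[r], {
      vapply(seq_len(n_units), function(u) {
        ar_semipartial_cp(simulate_ar(params[[u]], n_trials[u], seed = NULL))
      }, numeric(2))
    })
    raw <- cps["raw", ]; semi <- cps["semi", ]
    ok <- !is.na(semi)
    tibble(
      rep = r,
      mean_semi_cp = mean(semi[ok]),
      mean_raw_cp = mean(raw[ok]),
      p_value = t.test(semi[ok], mu = 0.5)$p.value,
      cor_raw_semi = if (sum(ok) > 2) cor(raw[ok], semi[ok]) else NA_real_,
      cor_target_semi = if (sum(ok) > 2 && !anyNA(target_cp))
        cor(target_cp[ok], semi[ok]) else NA_real_,
      n_units_used = sum(ok)
    )
  })
  structure(out,
            reject_fraction = mean(out$p_value < 0.05),
            class = c("cp_power", class(out)))
}
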