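# Synthetic session generator.
#
# Emulates the statistical structure of pseudorandomized disparity
# discrimination sessions: balanced, shuffled stimulus sequences with
# interleaved no-signal trials; choices from a probit decision rule with
# history terms (previous choice / target / win) and an instantaneous coupling
# to the neuron's spike count; spike counts from a log-rate with stimulus
# tuning, lag-1 autoregression, reward modulation and a slow Gaussian-process
# drift; within-trial profiles spanned by two smooth PSTH templates.

#' Default within-trial PSTH templates
#'
#' Two smooth nonnegative 20-bin shapes (100-ms bins over a 2-s trial): a
#' transient onset response and a sustained ramp.  Unit PSTHs are generated as
#' positive mixtures of the two.
#'
#' @return A 20 x 2 matrix.
#' @export
default_psth_templates <- function() {
  b <- seq_len(N_TIME_BINS)
  transient <- dgamma(b, shape = 2.5, rate = 0.9)
  sustained <- 1 / (1 + exp(-(b - 6) / 2.5)) * (1 - 0.015 * b)
  cbind(transient = transient / sum(transient),
        sustained = sustained / sum(sustained))
}

#' Configuration for the synthetic session generator
#'
#' Defaults reproduce the study conditions the analyses assume: 75 units with
#' ~252 trials each, half of them no-signal (9450 no-signal trials in total),
#' signal strengths of 6, 12.5 and 25% of extra frames at each of the two
#' signal disparities, a switching choice strategy (mean previous-choice
#' weight -0.275, previous-target weight 0.054), and an instantaneous
#' choice-spike coupling calibrated so that the population spike-count CP is
#' 0.56.
#'
#' @param n_units Number of units/sessions.
#' @param n_nosignal No-signal trials per session.
#' @param signal_levels Signed signal strengths (fraction of extra frames at
#'   the signal disparity; positive = the unit's preferred disparity).
#' @param signal_counts Trials per signal level (balanced, shuffled without
#'   replacement together with the no-signal trials).
#' @param n_disparity Number of disparity levels in the frame histogram grid.
#' @param w0,w_choice,w_target,w_win,w_signal Probit decision weights: bias,
#'   previous choice, previous target, previous win (all on +/-1 coded
#'   regressors) and current signal.
#' @param rho Instantaneous choice-spike coupling, expressed as the target
#'   choice correlation (Pearson scale) between the standardized spike count
#'   and the decision variable on no-signal trials.  `NULL` calibrates it from
#'   `target_cp` via the CP/correlation conversion.
#' @param target_cp Population spike-count choice probability the coupling is
#'   calibrated to when `rho` is `NULL`.
#' @param coupling `"feedforward"` (the spike count enters the decision
#'   variable on the same trial) or `"feedback"` (the choice enters the spike
#'   log-rate through `choice_gain`).
#' @param log_baseline Baseline log spike count per trial.
#' @param baseline_sd SD of per-unit jitter on `log_baseline`.
#' @param tuning Log-rate gain per unit of signed signal strength.
#' @param ar Lag-1 autoregressive coefficient on the standardized previous
#'   spike count (log-rate scale).
#' @param gp_tau Length scale (trials) of the squared-exponential kernel of
#'   the slow-fluctuation Gaussian process.
#' @param gp_amp Marginal SD (log-rate scale) of the slow fluctuation; 0
#'   disables it.
#' @param reward_gain Log-rate gain of the previous reward (+/-1 coded).
#' @param choice_gain Log-rate gain of the current choice (+/-1 coded); only
#'   used with `coupling = "feedback"`.
#' @param frame_gain Log-rate gain of the frame-content regressor (mean of a
#'   linear disparity tuning ramp over the trial's frames); 0 disables
#'   stimulus leakage into no-signal counts.
#' @param psth_templates 20 x 2 matrix of nonnegative within-trial templates.
#' @param seed Master seed; every unit gets its own substream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_units = 75, n_nosignal = 126,
                       signal_levels = c(-0.25, -0.125, -0.06, 0.06, 0.125, 0.25),
                       signal_counts = rep(21L, 6), n_disparity = 7,
                       w0 = 0, w_choice = -0.275, w_target = 0.054,
                       w_win = 0.05, w_signal = 4,
                       rho = NULL, target_cp = 0.56,
                       coupling = c("feedforward", "feedback"),
                       log_baseline = log(40), baseline_sd = 0.15,
                       tuning = 2, ar = 0.04, gp_tau = 35, gp_amp = 0.1,
                       reward_gain = 0.1, choice_gain = 0, frame_gain = 0,
                       psth_templates = default_psth_templates(),
                       seed = 1) {
  coupling <- match.arg(coupling)
  stopifnot(length(signal_levels) == length(signal_counts),
            all(signal_counts >= 1) || length(signal_counts) == 0,
            n_nosignal >= 1, gp_tau > 0, gp_amp >= 0,
            all(psth_templates >= 0), ncol(psth_templates) == 2,
            nrow(psth_templates) == N_TIME_BINS)
  if (is.null(rho)) rho <- cp_to_choice_correlation(target_cp)
  stopifnot(abs(rho) < 1)
  structure(
    list(n_units = n_units, n_nosignal = as.integer(n_nosignal),
         signal_levels = signal_levels, signal_counts = as.integer(signal_counts),
         n_disparity = as.integer(n_disparity),
         w0 = w0, w_choice = w_choice, w_target = w_target, w_win = w_win,
         w_signal = w_signal, rho = rho, coupling = coupling,
         log_baseline = log_baseline, baseline_sd = baseline_sd,
         tuning = tuning, ar = ar, gp_tau = gp_tau, gp_amp = gp_amp,
         reward_gain = reward_gain, choice_gain = choice_gain,
         frame_gain = frame_gain, psth_templates = psth_templates,
         seed = seed),
    class = "sim_config"
  )
}

# Disparity grid bookkeeping: level values, the indices of the two signal
# disparities (preferred = largest, null = smallest), and a linear tuning
# ramp used by the optional frame-content regressor.
disparity_grid <- function(config) {
  k <- config$n_disparity
  values <- seq(-0.3, 0.3, length.out = k)
  list(values = values, i_pref = k, i_null = 1L,
       ramp = seq(-1, 1, length.out = k))
}

#' Generate one pseudorandomized stimulus sequence
#'
#' The per-trial signal levels are a uniform random permutation of the level
#' multiset (no-signal trials interleaved).  Frame histograms hold 192 frames:
#' uniform-multinomial over the disparity grid on no-signal trials; on signal
#' trials the signal disparity receives an extra probability mass equal to
#' `|signal|`, the remainder staying uniform.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (`NULL` uses the current RNG stream).
#' @return A tibble with `signal`, `target` (sign of the signal; fair coin on
#'   no-signal trials) and the `frame_hist` list-column.
#' @export
generate_stimulus_sequence <- function(config, seed = NULL) {
  with_seed(seed, {
    grid <- disparity_grid(config)
    k <- config$n_disparity
    levels_multiset <- c(rep(0, config$n_nosignal),
                         rep(config$signal_levels, config$signal_counts))
    n <- length(levels_multiset)
    signal <- sample(levels_multiset, n, replace = FALSE)
    frame_hist <- lapply(signal, function(s) {
      p <- rep(1 / k, k)
      if (s != 0) {
        i <- if (s > 0) grid$i_pref else grid$i_null
        p <- (1 - abs(s)) * p
        p[i] <- p[i] + abs(s)
      }
      as.integer(rmultinom(1, FRAMES_PER_TRIAL, p))
    })
    target <- ifelse(signal > 0, 1L,
                     ifelse(signal < 0, 0L, NA_integer_))
    target[is.na(target)] <- rbinom(sum(is.na(target)), 1, 0.5)
    tibble(signal = signal, target = as.integer(target), frame_hist = frame_hist)
  })
}

# Sample a zero-mean GP with kernel amp^2 * exp(-((i-j)/tau)^2) at trial
# indices idx, by Cholesky with escalating jitter.
gp_sample <- function(idx, tau, amp, jitter = 1e-6) {
  n <- length(idx)
  if (amp <= 0) return(rep(0, n))
  K <- amp^2 * exp(-(outer(idx, idx, "-") / tau)^2)
  for (j in jitter * 10^(0:3)) {
    L <- tryCatch(chol(K + diag(j, n)), error = function(e) NULL)
    if (!is.null(L)) return(drop(crossprod(L, rnorm(n))))
  }
  stop("GP kernel not positive definite even after jitter", call. = FALSE)
}

# Analytic per-trial count moments given the signal, used to standardize the
# instantaneous spike signal: extra log-rate variance v from the AR term,
# the GP and the reward term makes the count Poisson-lognormal.
count_moments <- function(config, eta0, v) {
  m <- exp(eta0 + v / 2)
  list(mean = m, var = m + m^2 * (exp(v) - 1))
}

#' Simulate the behavior of a probit observer with history terms
#'
#' The decision variable on trial n is
#' `w0 + w_choice*c(n-1) + w_target*t(n-1) + w_win*r(n-1) + w_signal*signal(n)
#'  + rho_w*spike_stream(n)` with +/-1 coding of the history regressors, and
#' the choice is Bernoulli of its probit.  Targets follow the signal sign
#' (fair coin on no-signal trials); wins are `choice == target`.
#'
#' @param signals Signed signal strengths per trial.
#' @param weights Named list/vector with `w0`, `w_choice`, `w_target`,
#'   `w_win`, `w_signal` and `rho_w` (the raw decision-variable weight of the
#'   spike stream; 0 if absent).
#' @param spike_stream Standardized instantaneous spike signal per trial, or
#'   `NULL` for none.
#' @param seed Optional seed.
#' @return A tibble with `choice`, `target`, `win`.
#' @export
generate_behavior <- function(signals, weights, spike_stream = NULL, seed = NULL) {
  with_seed(seed, {
    n <- length(signals)
    if (is.null(spike_stream)) spike_stream <- rep(0, n)
    stopifnot(length(spike_stream) == n)
    w <- as.list(weights)
    rho_w <- w$rho_w %||% 0
    choice <- integer(n); target <- integer(n); win <- integer(n)
    cb <- 0; tb <- 0; rb <- 0  # +/-1 history terms, 0 before the first trial
    for (i in seq_len(n)) {
      m <- w$w0 + w$w_choice * cb + w$w_target * tb + w$w_win * rb +
        w$w_signal * signals[i] + rho_w * spike_stream[i]
      choice[i] <- rbinom(1, 1, pnorm(m))
      target[i] <- if (signals[i] > 0) 1L else if (signals[i] < 0) 0L else
        rbinom(1, 1, 0.5)
      win[i] <- as.integer(choice[i] == target[i])
      cb <- 2 * choice[i] - 1; tb <- 2 * target[i] - 1; rb <- 2 * win[i] - 1
    }
    tibble(choice = choice, target = as.integer(target), win = win)
  })
}

#' Simulate spike counts for a fixed behavioral sequence
#'
#' Log-rate on trial n: baseline + tuning * signal(n) + ar * z(n-1) +
#' reward_gain * r(n-1) + choice_gain * c(n) + g(n), where z is the
#' standardized previous count, r and c are +/-1 coded, and g is a
#' squared-exponential Gaussian process over trials.  Counts are Poisson;
#' binned counts are multinomial over the within-trial profile.
#'
#' @param trials Tibble with `signal`, `choice`, `win` (and optionally
#'   `frame_hist` when `frame_gain != 0`).
#' @param config A [sim_config()] supplying the spike parameters.
#' @param profile Optional 20-vector within-trial profile; default is an even
#'   mixture of the configured templates.
#' @param log_baseline Per-unit baseline log-rate (defaults to the config's).
#' @param seed Optional seed.
#' @return A tibble with `spikes`, the `binned` list-column and the latent
#'   `gp` trajectory.
#' @export
generate_spikes <- function(trials, config, profile = NULL,
                            log_baseline = NULL, seed = NULL) {
  with_seed(seed, {
    n <- nrow(trials)
    b0 <- log_baseline %||% config$log_baseline
    if (is.null(profile)) profile <- rowMeans(config$psth_templates)
    profile <- profile / sum(profile)
    g <- gp_sample(seq_len(n), config$gp_tau, config$gp_amp)
    grid <- disparity_grid(config)
    v <- spike_nuisance_var(config)
    spikes <- integer(n); z_prev <- 0; rb_prev <- 0
    for (i in seq_len(n)) {
      ft <- frame_term(config, grid, trials$frame_hist[[i]] %||% NULL)
      cb <- 2 * trials$choice[i] - 1
      eta <- b0 + config$tuning * trials$signal[i] + ft +
        config$ar * z_prev + config$reward_gain * rb_prev +
        config$choice_gain * cb + g[i]
      spikes[i] <- rpois(1, exp(eta))
      mo <- count_moments(config, b0 + config$tuning * trials$signal[i], v)
      z_prev <- clip_z((spikes[i] - mo$mean) / sqrt(mo$var))
      rb_prev <- 2 * trials$win[i] - 1
    }
    binned <- lapply(spikes, function(s) as.integer(rmultinom(1, s, profile)))
    tibble(spikes = spikes, binned = binned, gp = g)
  })
}

# Log-rate variance of the nuisance terms (AR + GP + reward), used for the
# analytic count standardization.
spike_nuisance_var <- function(config) {
  config$ar^2 + config$gp_amp^2 + config$reward_gain^2
}

# The AR feedback acts on the standardized previous count; clipping it keeps
# the exponential-link recursion contracting (unbounded positive feedback
# would otherwise be explosive for rare large counts).
AR_CLIP <- 3
clip_z <- function(z) pmax(pmin(z, AR_CLIP), -AR_CLIP)

frame_term <- function(config, grid, frame_hist) {
  if (config$frame_gain == 0 || is.null(frame_hist)) return(0)
  config$frame_gain * sum(frame_hist * grid$ramp) / FRAMES_PER_TRIAL
}

# Joint per-session simulation: spikes and choices are coupled within the
# trial.  Feedforward: the count is drawn first and its standardized value
# enters the decision variable with weight rho_w, chosen so that the choice
# correlation of the coupling equals config$rho after accounting for the
# decision-variable variance contributed by the history weights.  Feedback:
# the choice is drawn from history alone and enters the spike log-rate.
simulate_session <- function(config, unit_id, seed) {
  with_seed(seed, {
    stim <- generate_stimulus_sequence(config, seed = NULL)
    n <- nrow(stim)
    b0 <- config$log_baseline + rnorm(1, 0, config$baseline_sd)
    mix <- runif(2, 0.2, 1)
    profile <- drop(config$psth_templates %*% mix)
    profile <- profile / sum(profile)
    g <- gp_sample(seq_len(n), config$gp_tau, config$gp_amp)
    grid <- disparity_grid(config)
    v <- spike_nuisance_var(config)
    v_hist <- config$w_choice^2 + config$w_target^2 + config$w_win^2
    rho_w <- config$rho * sqrt((1 + v_hist) / (1 - config$rho^2))
    choice <- integer(n); target <- integer(n); win <- integer(n)
    spikes <- integer(n)
    cb <- 0; tb <- 0; rb <- 0; z_prev <- 0
    for (i in seq_len(n)) {
      ft <- frame_term(config, grid, stim$frame_hist[[i]])
      eta_base <- b0 + config$tuning * stim$signal[i] + ft +
        config$ar * z_prev + config$reward_gain * rb + g[i]
      mo <- count_moments(config, b0 + config$tuning * stim$signal[i], v)
      m_hist <- config$w0 + config$w_choice * cb + config$w_target * tb +
        config$w_win * rb + config$w_signal * stim$signal[i]
      if (config$coupling == "feedforward") {
        spikes[i] <- rpois(1, exp(eta_base))
        zsig <- (spikes[i] - mo$mean) / sqrt(mo$var)
        choice[i] <- rbinom(1, 1, pnorm(m_hist + rho_w * zsig))
      } else {
        choice[i] <- rbinom(1, 1, pnorm(m_hist))
        spikes[i] <- rpois(1, exp(eta_base + config$choice_gain * (2 * choice[i] - 1)))
      }
      target[i] <- stim$target[i]
      win[i] <- as.integer(choice[i] == target[i])
      z_prev <- clip_z((spikes[i] - mo$mean) / sqrt(mo$var))
      cb <- 2 * choice[i] - 1; tb <- 2 * target[i] - 1; rb <- 2 * win[i] - 1
    }
    binned <- lapply(spikes, function(s) as.integer(rmultinom(1, s, profile)))
    trials <- tibble(
      unit_id = unit_id, index = seq_len(n) - 1L,
      signal = stim$signal, choice = choice, target = as.integer(target),
      win = win, spikes = spikes, complete = 1L,
      frame_hist = stim$frame_hist, binned = binned
    )
    list(trials = trials,
         truth = list(unit_id = unit_id, seed = seed, log_baseline = b0,
                      psth_mixture = mix, gp = g, rho_w = rho_w))
  })
}

#' Generate a synthetic population of sessions
#'
#' Couples the stimulus, behavior and spike generators per unit, with the
#' instantaneous choice-spike coupling realized by sharing the standardized
#' spike count with the decision variable (feedforward) or the choice with
#' the spike log-rate (feedback).  Each unit draws from its own RNG
#' substream, so the dataset is bit-reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `cp_population` with the `trials` tibble (all
#'   units) and `truth`, the ground-truth generative record (config, per-unit
#'   baselines, PSTH mixtures, GP trajectories, realized coupling weight).
#' @export
generate_population <- function(config) {
  seeds <- substream_seeds(config$seed, config$n_units)
  sims <- purrr::map(seq_len(config$n_units), function(i) {
    simulate_session(config, sprintf("unit%03d", i), seeds[i])
  })
  trials <- dplyr::bind_rows(purrr::map(sims, "trials"))
  structure(
    list(trials = trials,
         truth = list(config = config, seeds = seeds,
                      units = purrr::map(sims, "truth"))),
    class = "cp_population"
  )
}

#' @export
print.cp_population <- function(x, ...) {
  cat(sprintf("<cp_population> %d units, %d trials (%d no-signal)\n",
              length(unique(x$trials$unit_id)), nrow(x$trials),
              sum(x$trials$signal == 0)))
  invisible(x)
}

#' Generate a synthetic population of PSTHs
#'
#' Rows are unit x stimulus-condition PSTHs (20 bins) built as random positive
#' mixtures of the two configured templates, scaled per condition, circularly
#' shifted by a per-unit integer latency, with additive Gaussian noise scaled
#' to the signal SD.  Used to exercise the latency-correction + PCA pipeline.
#'
#' @param n_units,n_conditions Grid size.
#' @param noise Noise SD as a fraction of the signal SD (default 1%).
#' @param max_shift Maximum per-unit latency shift in bins.
#' @param templates 20 x 2 template matrix.
#' @param seed Optional seed.
#' @return A list with the PSTH matrix `psth` (rows = unit x condition),
#'   `unit` row labels, and the true `latency` per unit.
#' @export
generate_psth_population <- function(n_units = 75, n_conditions = 7,
                                     noise = 0.01, max_shift = 2,
                                     templates = default_psth_templates(),
                                     seed = NULL) {
  with_seed(seed, {
    rows <- n_units * n_conditions
    unit <- rep(seq_len(n_units), each = n_conditions)
    mix <- matrix(runif(2 * n_units, 0.2, 1), ncol = 2)
    gain <- runif(rows, 0.5, 1.5)
    latency <- sample(0:max_shift, n_units, replace = TRUE)
    psth <- t(vapply(seq_len(rows), function(r) {
      u <- unit[r]
      shape <- drop(templates %*% mix[u, ]) * gain[r] * 40
      circ_shift(shape, latency[u])
    }, numeric(N_TIME_BINS)))
    sig_sd <- sd(as.vector(psth))
    psth <- psth + rnorm(length(psth), 0, noise * sig_sd)
    list(psth = psth, unit = unit, latency = latency)
  })
}

#' Read a generator configuration from YAML
#'
#' The file holds any subset of [sim_config()]'s arguments by name
#' (e.g. `seed`, `n_units`, `gp_tau`, `w_choice`); unnamed parameters keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$signal_counts)) cfg$signal_counts <- as.integer(cfg$signal_counts)
  do.call(sim_config, cfg)
}
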