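# Poisson spike-count models with an optional Gaussian-process latent for
# slow firing-rate fluctuations, plus the time-resolved (100-ms bin) variant.

#' Regress the stimulus-induced component out of previous spike counts
#'
#' Least squares of the counts on the signed signal strength through the
#' origin; the residuals are orthogonal to the signal.
#'
#' @param counts Spike counts (typically the lagged counts).
#' @param signals The corresponding signed signal strengths.
#' @return Residual counts.
#' @export
regress_out_stimulus <- function(counts, signals) {
  stopifnot(length(counts) == length(signals))
  resid_through_origin(as.numeric(counts), as.numeric(signals))
}

se_kernel <- function(idx1, idx2, tau, amplitude) {
  amplitude^2 * exp(-(outer(idx1, idx2, "-") / tau)^2)
}

# MAP for the latent g of a Poisson GLM with GP prior, given the fixed-effect
# linear predictor eta: maximize y'(eta+g) - sum exp(eta+g) - g'K^{-1}g/2
# by Newton steps.
gp_map_latent <- function(eta, y, K, g0 = NULL, jitter = 1e-6, max_newton = 50) {
  n <- length(y)
  Kj <- K + diag(jitter, n)
  Kinv <- chol2inv(chol(Kj))
  g <- g0 %||% rep(0, n)
  for (it in seq_len(max_newton)) {
    mu <- exp(eta + g)
    grad <- (y - mu) - drop(Kinv %*% g)
    H <- diag(mu) + Kinv
    delta <- solve(H, grad)
    # step halving on the MAP objective
    obj <- function(gg) sum(y * (eta + gg)) - sum(exp(eta + gg)) -
      0.5 * drop(gg %*% Kinv %*% gg)
    o0 <- obj(g)
    s <- 1
    repeat {
      gnew <- g + s * delta
      if (obj(gnew) >= o0 - 1e-12) break
      s <- s / 2
      if (s < 1e-8) { gnew <- g; break }
    }
    moved <- max(abs(gnew - g))
    g <- gnew
    if (moved < 1e-9) break
  }
  list(g = g, Kinv = Kinv)
}

#' Fit a Poisson spike-count GLM, optionally with a GP latent
#'
#' Exponential-nonlinearity (log link) Poisson regression of the spike counts
#' on the standardized covariates of the training (signal) rows.  With
#' `gp = list(tau, amplitude)`, a zero-mean Gaussian-process latent with
#' squared-exponential kernel `amplitude^2 * exp(-((i - j) / tau)^2)` over the
#' trial index is added to the log-rate and the model is fit by alternating
#' maximization: Newton steps for the latent given the weights, IRLS for the
#' weights given the latent (MAP estimate).  `amplitude = 0` or `gp = NULL`
#' reduces exactly to the plain GLM.
#'
#' @param design A [build_design()] object with `target = "spikes"`.
#' @param gp `NULL`, or a list with `tau` (trials, default 35) and
#'   `amplitude` (log-rate SD, default 1).
#' @param max_alt Maximum alternating iterations.
#' @param tol Convergence tolerance on the coefficient change.
#' @return An object of class `spike_fit`: `coef` (intercept first), the
#'   latent `g` at the training trials (NULL when disabled), the kernel
#'   hyperparameters, and convergence diagnostics.
#' @export
fit_poisson_glm <- function(design, gp = NULL, max_alt = 50, tol = 1e-8) {
  stopifnot(inherits(design, "cp_design"))
  y <- design$y[design$train]
  if (any(y < 0) || any(y != round(y))) {
    stop("spike counts must be nonnegative integers", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, design$x)[design$train, , drop = FALSE]
  idx <- as.numeric(design$index[design$train])
  use_gp <- !is.null(gp) && (gp$amplitude %||% 1) > 0
  fit0 <- suppressWarnings(glm.fit(X, y, family = poisson()))
  beta <- coef(fit0)
  g <- NULL
  converged <- TRUE
  if (use_gp) {
    tau <- gp$tau %||% 35
    amplitude <- gp$amplitude %||% 1
    K <- se_kernel(idx, idx, tau, amplitude)
    g <- rep(0, length(y))
    converged <- FALSE
    for (it in seq_len(max_alt)) {
      eta <- drop(X %*% beta)
      g <- gp_map_latent(eta, y, K, g0 = g)$g
      fit <- suppressWarnings(glm.fit(X, y, family = poisson(), offset = g,
                                      start = beta))
      bnew <- coef(fit)
      moved <- max(abs(bnew - beta))
      beta <- bnew
      if (moved < tol) { converged <- TRUE; break }
    }
  }
  structure(
    list(coef = setNames(beta, colnames(X)), g = g,
         gp = if (use_gp) list(tau = gp$tau %||% 35,
                               amplitude = gp$amplitude %||% 1) else NULL,
         train_index = idx, converged = converged,
         covariates = design$covariates, unit_id = design$unit_id,
         n_train = length(y)),
    class = "spike_fit"
  )
}

#' @export
print.spike_fit <- function(x, ...) {
  cat(sprintf("<spike_fit> unit %s, %d train trials%s%s\n",
              x$unit_id %||% "?", x$n_train,
              if (is.null(x$gp)) "" else
                sprintf(", GP(tau = %g, amp = %g)", x$gp$tau, x$gp$amplitude),
              if (x$converged) "" else " (not converged)"))
  print(round(x$coef, 4))
  invisible(x)
}

#' Predict spike counts from a fitted Poisson GLM
#'
#' Held-out trials receive the GP posterior-mean latent interpolated from the
#' training-trial latents through the kernel.
#'
#' @param object A `spike_fit`.
#' @param design The design to score.
#' @param rows `"test"`, `"train"` or `"all"`.
#' @param ... Unused.
#' @return Predicted counts (rate scale).
#' @export
predict.spike_fit <- function(object, design, rows = c("test", "train", "all"), ...) {
  rows <- match.arg(rows)
  keep <- switch(rows, test = design$test, train = design$train,
                 all = rep(TRUE, length(design$y)))
  X <- cbind(1, design$x)[keep, , drop = FALSE]
  eta <- drop(X %*% object$coef)
  if (!is.null(object$g)) {
    idx_new <- as.numeric(design$index[keep])
    Ktt <- se_kernel(object$train_index, object$train_index,
                     object$gp$tau, object$gp$amplitude)
    Kst <- se_kernel(idx_new, object$train_index,
                     object$gp$tau, object$gp$amplitude)
    g_new <- drop(Kst %*% solve(Ktt + diag(1e-6, nrow(Ktt)), object$g))
    eta <- eta + g_new
  }
  exp(eta)
}

# Pearson correlation that returns 0 for degenerate (constant) predictions.
safe_cc <- function(pred, obs) {
  if (length(pred) < 3 || sd(pred) < 1e-12 || sd(obs) < 1e-12) return(0)
  cor(pred, obs)
}

spike_cc_one_unit <- function(tr, covariates, gp) {
  covs <- setdiff(covariates, "sf")
  gp_on <- "sf" %in% covariates
  d <- build_design(tr, covs, target = "spikes")
  fit <- fit_poisson_glm(d, gp = if (gp_on) gp else NULL)
  safe_cc(predict(fit, d, rows = "test"), d$y[d$test])
}

#' Spike-count prediction performance
#'
#' Per session: fit the Poisson GLM (always including the current stimulus)
#' on signal trials, predict the no-signal trials, and report the Pearson
#' correlation between predicted and measured counts.  The pseudo-covariate
#' `"sf"` turns on the slow-fluctuation GP latent.
#'
#' @param trials A trial tibble.
#' @param covariates Covariate names (plus optionally `"sf"`).  The stimulus
#'   `"signal"` is always added.
#' @param gp_tau,gp_amplitude GP hyperparameters used when `"sf"` is present.
#' @return A tibble with `unit_id`, `cc`, `n_test`.
#' @export
spike_prediction_cc <- function(trials, covariates, gp_tau = 35,
                                gp_amplitude = 1) {
  trials <- filter_trials(trials)
  gp <- list(tau = gp_tau, amplitude = gp_amplitude)
  trials %>%
    dplyr::group_by(.data$unit_id) %>%
    dplyr::group_modify(function(tr, key) {
      tr$unit_id <- key$unit_id
      attr(tr, "cp_filtered") <- TRUE
      covs <- union(setdiff(covariates, "sf"), "signal")
      if ("sf" %in% covariates) covs <- c(covs, "sf")
      tibble(cc = spike_cc_one_unit(tr, covs, gp),
             n_test = sum(tr$signal == 0))
    }) %>%
    dplyr::ungroup()
}

#' Cumulative spike-prediction increments
#'
#' As [cumulative_cpp()] but for the Poisson spike-count model and the
#' Pearson-correlation metric; the stimulus is always in the model, and the
#' entry `"sf"` in the order switches on the GP latent from that step on.
#'
#' @inheritParams spike_prediction_cc
#' @param covariates Ordered covariate names (may include `"sf"` and
#'   `"choice"`).
#' @return A `cp_cumulative` tibble (metric = Pearson cc), with the per-unit
#'   metric matrix as attribute `per_unit`.
#' @export
cumulative_cc <- function(trials, covariates = c("choice_prev", "target_prev",
                                                 "win_prev", "spikes_prev",
                                                 "sf", "choice"),
                          gp_tau = 35, gp_amplitude = 1) {
  if (length(covariates) == 0) stop("empty covariate list", call. = FALSE)
  trials <- filter_trials(trials)
  steps <- lapply(seq_along(covariates), function(k) {
    spike_prediction_cc(trials, covariates[seq_len(k)], gp_tau, gp_amplitude)
  })
  units <- steps[[1]]$unit_id
  cc <- vapply(steps, function(s) s$cc, numeric(length(units)))
  cc <- matrix(cc, nrow = length(units), dimnames = list(units, covariates))
  inc <- cc - cbind(0, cc[, -ncol(cc), drop = FALSE])
  out <- purrr::map_dfr(seq_along(covariates), function(k) {
    x <- inc[, k][!is.na(inc[, k])]
    tibble(covariate = covariates[k],
           mean_metric = mean(cc[, k], na.rm = TRUE),
           mean_increment = mean(x),
           p_value = wilcoxon_p(x),
           n_units = length(x))
  })
  structure(out, per_unit = cc, class = c("cp_cumulative", class(out)))
}

# ---- PSTH basis ----------------------------------------------------------

#' Extract per-unit, per-condition PSTHs from binned trials
#'
#' @param trials A trial tibble with the `binned` list-column.
#' @return A list with the PSTH matrix `psth` (rows = unit x signal level,
#'   mean 100-ms counts) and the `unit` label of each row.
#' @export
psth_matrix_from_trials <- function(trials) {
  stopifnot("binned" %in% names(trials))
  grp <- trials %>%
    dplyr::filter(!vapply(.data$binned, is.null, logical(1))) %>%
    dplyr::group_by(.data$unit_id, .data$signal) %>%
    dplyr::summarise(
      psth = list(colMeans(do.call(rbind, .data$binned))),
      .groups = "drop"
    )
  list(psth = do.call(rbind, grp$psth), unit = grp$unit_id)
}

#' PSTH basis by latency-corrected PCA
#'
#' Estimates a per-unit response latency (integer-bin circular shift
#' maximizing the cross-correlation of the unit's mean PSTH with the
#' population mean), removes it, runs PCA across all unit-x-condition PSTHs
#' and keeps the leading two components.
#'
#' @param psth Matrix of PSTHs (rows = unit x condition, 20 columns), e.g.
#'   from [psth_matrix_from_trials()] or [generate_psth_population()].
#' @param unit Row labels mapping rows to units (one latency per unit).
#' @param max_shift Maximum latency magnitude searched, in bins.
#' @param latency Optional known per-unit latencies (named or in unit order);
#'   skips estimation.
#' @return An object of class `psth_basis`: orthonormal `basis` (20 x 2),
#'   cumulative `var_explained` of the two components, per-unit `latency`,
#'   per-unit `mean_psth`, and the shifted matrix.
#' @export
psth_basis <- function(psth, unit = rep(1, nrow(psth)), max_shift = 3,
                       latency = NULL) {
  stopifnot(ncol(psth) == N_TIME_BINS)
  units <- unique(unit)
  pop_mean <- colMeans(psth)
  if (is.null(latency)) {
    latency <- vapply(units, function(u) {
      m <- colMeans(psth[unit == u, , drop = FALSE])
      scores <- vapply(-max_shift:max_shift, function(k) {
        sum(circ_shift(m, -k) * pop_mean)
      }, numeric(1))
      (-max_shift:max_shift)[which.max(scores)]
    }, numeric(1))
    names(latency) <- as.character(units)
  } else {
    latency <- setNames(rep_len(latency, length(units)), as.character(units))
  }
  shifted <- psth
  for (r in seq_len(nrow(psth))) {
    shifted[r, ] <- circ_shift(psth[r, ], -latency[[as.character(unit[r])]])
  }
  pc <- prcomp(shifted, center = TRUE, scale. = FALSE)
  ve <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  mean_psth <- t(vapply(units, function(u) {
    colMeans(shifted[unit == u, , drop = FALSE])
  }, numeric(N_TIME_BINS)))
  rownames(mean_psth) <- as.character(units)
  structure(
    list(basis = pc$rotation[, 1:2, drop = FALSE],
         var_explained = ve[2], var_by_component = pc$sdev^2 / sum(pc$sdev^2),
         latency = latency, mean_psth = mean_psth, shifted = shifted),
    class = "psth_basis"
  )
}

#' @export
print.psth_basis <- function(x, ...) {
  cat(sprintf("<psth_basis> 2 components, %.2f%% of PSTH variance, %d units\n",
              100 * x$var_explained, length(x$latency)))
  invisible(x)
}

# ---- Time-resolved model -------------------------------------------------

epoch_of_bin <- function(bin) (bin - 1L) %/% 5L + 1L

# Long-format design for the 20-bin model of one session.
time_resolved_frame <- function(tr, basis) {
  stopifnot("binned" %in% names(tr))
  u <- as.character(tr$unit_id[1])
  mean_psth <- if (u %in% rownames(basis$mean_psth)) basis$mean_psth[u, ]
               else colMeans(basis$mean_psth)
  sp_resid <- regress_out_stimulus(tr$spikes_prev, tr$signal_prev)
  rows <- purrr::map_dfr(seq_len(nrow(tr)), function(i) {
    tibble(trial = i, bin = seq_len(N_TIME_BINS),
           y = as.numeric(tr$binned[[i]]),
           train = tr$signal[i] != 0,
           choice = tr$choice[i], choice_prev = tr$choice_prev[i],
           target_prev = tr$target_prev[i], win_prev = tr$win_prev[i],
           signal = tr$signal[i], spikes_prev_resid = sp_resid[i])
  })
  rows$epoch <- epoch_of_bin(rows$bin)
  rows$basis1 <- basis$basis[rows$bin, 1] - mean_psth[rows$bin]
  rows$basis2 <- basis$basis[rows$bin, 2] - mean_psth[rows$bin]
  rows
}

time_resolved_design <- function(rows) {
  epo <- function(v, e) v * (rows$epoch == e)
  cols <- list()
  for (v in c("choice", "choice_prev", "target_prev", "win_prev")) {
    for (e in 1:4) cols[[paste0(v, "_q", e)]] <- epo(rows[[v]], e)
  }
  cols$spikes_prev <- rows$spikes_prev_resid
  cols$signal <- rows$signal
  cols$basis1 <- rows$basis1
  cols$basis2 <- rows$basis2
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Time-resolved spike prediction
#'
#' Splits each trial into 20 bins of 100 ms, fits a Poisson GLM on the signal
#' trials with per-epoch (four nonoverlapping 500-ms blocks) predictors for
#' the current choice and each choice-history covariate, the residualized
#' previous spike count, the current stimulus, and the two PSTH basis
#' regressors (each minus the unit's mean PSTH), and evaluates the prediction
#' on no-signal trials as a Pearson correlation per 500-ms quartile
#' (quartile counts summed within trial).
#'
#' @param trials Trials of one session with the `binned` list-column.
#' @param basis A [psth_basis()] object.
#' @return A list of class `time_resolved_fit`: `coef`, a `quartiles` tibble
#'   (`quartile`, `cc`), the overall per-bin `cc`, and the per-trial predicted
#'   bin means for the no-signal trials.
#' @export
fit_time_resolved <- function(trials, basis) {
  tr <- filter_trials(trials)
  if (length(unique(tr$unit_id)) != 1) {
    stop("fit_time_resolved expects a single session", call. = FALSE)
  }
  rows <- time_resolved_frame(tr, basis)
  X <- time_resolved_design(rows)
  std <- standardize_columns(X, rows$train)
  Xs <- cbind(`(Intercept)` = 1, std$x)
  fit <- suppressWarnings(glm.fit(Xs[rows$train, , drop = FALSE],
                                  rows$y[rows$train], family = poisson()))
  beta <- coef(fit)
  beta[is.na(beta)] <- 0  # aliased (collinear) columns drop out
  eta <- drop(Xs %*% beta)
  pred <- exp(eta)
  test <- !rows$train
  qtab <- purrr::map_dfr(1:4, function(q) {
    sel <- test & rows$epoch == q
    by_trial <- rowsum(cbind(pred[sel], rows$y[sel]), rows$trial[sel])
    tibble(quartile = q, cc = safe_cc(by_trial[, 1], by_trial[, 2]))
  })
  structure(
    list(coef = setNames(beta, colnames(Xs)),
         quartiles = qtab,
         cc_bins = safe_cc(pred[test], rows$y[test]),
         pred_test = pred[test], y_test = rows$y[test],
         trial_test = rows$trial[test],
         unit_id = tr$unit_id[1]),
    class = "time_resolved_fit"
  )
}

#' @export
print.time_resolved_fit <- function(x, ...) {
  cat(sprintf("<time_resolved_fit> unit %s; per-quartile cc: %s\n",
              x$unit_id, paste(sprintf("%.3f", x$quartiles$cc), collapse = ", ")))
  invisible(x)
}
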