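# History-aware probit choice model and choice-prediction performance.

# Stable probit log-likelihood pieces.  eta is the linear predictor.
probit_nll <- function(eta, y) {
  -mean(ifelse(y == 1, pnorm(eta, log.p = TRUE), pnorm(-eta, log.p = TRUE)))
}

# d loglik / d eta per observation (inverse Mills ratios).
probit_dldeta <- function(eta, y) {
  logphi <- dnorm(eta, log = TRUE)
  ifelse(y == 1,
         exp(logphi - pnorm(eta, log.p = TRUE)),
         -exp(logphi - pnorm(-eta, log.p = TRUE)))
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Fit a lasso-regularized probit choice model
#'
#' Minimizes the mean probit negative log-likelihood plus `lambda * sum(|beta|)`
#' (intercept unpenalized) over the training (signal) rows of the design, by
#' proximal gradient descent with backtracking.  Convergence is declared when
#' the KKT residual falls below `tol`.  With `lambda = 0` and separable data
#' the weights are box-constrained at +/-12 with a warning.
#'
#' @param design A [build_design()] object with a binary target.
#' @param lambda Nonnegative lasso penalty on the mean log-likelihood scale.
#' @param tol KKT/gradient tolerance.
#' @param max_iter Iteration cap.
#' @return An object of class `probit_fit` with named `coef` (intercept
#'   first), `lambda`, iteration count, convergence flag and the design
#'   standardization metadata.
#' @export
fit_probit_lasso <- function(design, lambda = 0.025, tol = 1e-7,
                             max_iter = 50000) {
  stopifnot(inherits(design, "cp_design"), lambda >= 0)
  X <- cbind(`(Intercept)` = 1, design$x)[design$train, , drop = FALSE]
  y <- design$y[design$train]
  if (!is_binary01(y) || anyNA(y)) stop("probit target must be binary", call. = FALSE)
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1))
  bound <- 12
  beta <- rep(0, p)
  f <- function(b) probit_nll(drop(X %*% b), y)
  grad <- function(b) -drop(crossprod(X, probit_dldeta(drop(X %*% b), y))) / nrow(X)
  step <- 1
  fb <- f(beta)
  clamped <- FALSE
  iter <- 0L
  converged <- FALSE
  kkt <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- grad(beta)
    # KKT residual of the penalized problem
    kkt <- max(abs(g[1]),
               if (p > 1) max(ifelse(beta[-1] != 0,
                                     abs(g[-1] + lambda * sign(beta[-1])),
                                     pmax(abs(g[-1]) - lambda, 0))) else 0)
    if (kkt < tol) { converged <- TRUE; break }
    repeat {
      bnew <- soft_threshold(beta - step * g, step * pen)
      if (lambda == 0 && max(abs(bnew)) > bound) {
        if (!clamped) {
          warning("probit fit hit the weight bound (possible separation); ",
                  "weights box-constrained at +/-", bound, call. = FALSE)
          clamped <- TRUE
        }
        bnew <- pmin(pmax(bnew, -bound), bound)
      }
      d <- bnew - beta
      fnew <- f(bnew)
      if (fnew <= fb + sum(g * d) + sum(d^2) / (2 * step) + 1e-14) break
      step <- step / 2
      if (step < 1e-12) break
    }
    if (sqrt(sum((bnew - beta)^2)) < 1e-14 && clamped) { converged <- TRUE; beta <- bnew; break }
    beta <- bnew
    fb <- fnew
    step <- min(step * 1.25, 1e3)
  }
  if (lambda == 0 && !clamped) {
    eta <- drop(X %*% beta)
    phat <- ifelse(y == 1, pnorm(eta), pnorm(-eta))
    if (all(phat > 1 - 1e-6)) {
      warning("perfect separation at lambda = 0; weights are only bounded ",
              "by the optimizer tolerance", call. = FALSE)
      clamped <- TRUE
    }
  }
  structure(
    list(coef = setNames(beta, colnames(X)), lambda = lambda,
         iterations = iter, converged = converged, kkt = kkt,
         clamped = clamped, nll = fb,
         covariates = design$covariates, center = design$center,
         scale = design$scale, unit_id = design$unit_id,
         n_train = nrow(X)),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("<probit_fit> unit %s, lambda = %g, %d train trials%s\n",
              x$unit_id %||% "?", x$lambda, x$n_train,
              if (x$converged) "" else " (not converged)"))
  print(round(x$coef, 4))
  invisible(x)
}

#' Predict choice probabilities from a fitted probit model
#'
#' @param object A `probit_fit`.
#' @param design The [build_design()] object to score (its standardization
#'   must match the fit).
#' @param rows `"test"`, `"train"` or `"all"`.
#' @param type `"response"` (probit of the linear predictor) or `"link"`.
#' @param ... Unused.
#' @return A numeric vector of scores for the selected rows.
#' @export
predict.probit_fit <- function(object, design, rows = c("test", "train", "all"),
                               type = c("response", "link"), ...) {
  rows <- match.arg(rows)
  type <- match.arg(type)
  keep <- switch(rows, test = design$test, train = design$train,
                 all = rep(TRUE, length(design$y)))
  X <- cbind(1, design$x)[keep, , drop = FALSE]
  eta <- drop(X %*% object$coef)
  if (type == "response") pnorm(eta) else eta
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) implementation: the probability that a
#' positive-class score exceeds a negative-class score, ties counted 1/2.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes must be present).
#' @return A value in `[0, 1]`.
#' @export
area_under_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!is_binary01(labels)) stop("labels must be binary 0/1", call. = FALSE)
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) stop("both label classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

cpp_one_unit <- function(tr, covariates, lambda) {
  d <- build_design(tr, covariates, target = "choice")
  if (length(unique(d$y[d$test])) < 2) return(NA_real_)
  fit <- fit_probit_lasso(d, lambda)
  area_under_roc(predict(fit, d, rows = "test"), d$y[d$test])
}

#' Choice prediction performance (CPP)
#'
#' Per session: fit the probit-lasso choice model with exactly the given
#' covariates on the signal trials, score the no-signal trials, and return the
#' area under the ROC of the scores against the realized choices.  Sessions
#' failing the inclusion rule (fewer than four no-signal choices of either
#' sign) get `NA`.
#'
#' @param trials A trial tibble (any number of sessions).
#' @param covariates Covariate names, see [build_design()].
#' @param lambda Lasso penalty (default the cross-validated population value
#'   0.025).
#' @return A tibble with `unit_id`, `cpp`, `n_train`, `n_test`.
#' @export
choice_prediction_performance <- function(trials, covariates, lambda = 0.025) {
  trials <- filter_trials(trials)
  trials %>%
    dplyr::group_by(.data$unit_id) %>%
    dplyr::group_modify(function(tr, key) {
      tr$unit_id <- key$unit_id
      attr(tr, "cp_filtered") <- TRUE
      cpp <- if (!tr$passes_inclusion[1]) NA_real_ else
        cpp_one_unit(tr, covariates, lambda)
      tibble(cpp = cpp, n_train = sum(tr$signal != 0), n_test = sum(tr$signal == 0))
    }) %>%
    dplyr::ungroup()
}

#' Cumulative choice-prediction increments
#'
#' Adds the covariates one at a time in the given order, computes each
#' session's CPP, converts it to a choice correlation, and reports the
#' per-covariate increment (model with covariates 1..k minus 1..k-1; the
#' first increment is the covariate's solo performance) together with a
#' two-sided Wilcoxon signed-rank test of the increments across sessions.
#'
#' @inheritParams choice_prediction_performance
#' @param covariates Ordered covariate names.
#' @return A `cp_cumulative` tibble with `covariate`, `mean_metric` (mean
#'   choice correlation of the cumulative model), `mean_increment`,
#'   `p_value`, `n_units`.  The per-unit metric matrix is attached as
#'   attribute `per_unit`.
#' @export
cumulative_cpp <- function(trials, covariates = c("choice_prev", "target_prev",
                                                  "win_prev", "spikes_prev",
                                                  "spikes"),
                           lambda = 0.025) {
  if (length(covariates) == 0) stop("empty covariate list", call. = FALSE)
  trials <- filter_trials(trials)
  steps <- lapply(seq_along(covariates), function(k) {
    choice_prediction_performance(trials, covariates[seq_len(k)], lambda)
  })
  units <- steps[[1]]$unit_id
  cc <- vapply(steps, function(s) cp_to_choice_correlation(s$cpp), numeric(length(units)))
  cc <- matrix(cc, nrow = length(units),
               dimnames = list(units, covariates))
  inc <- cc - cbind(0, cc[, -ncol(cc), drop = FALSE])
  out <- purrr::map_dfr(seq_along(covariates), function(k) {
    x <- inc[, k]
    x <- x[!is.na(x)]
    tibble(
      covariate = covariates[k],
      mean_metric = mean(cc[, k], na.rm = TRUE),
      mean_increment = mean(x),
      p_value = wilcoxon_p(x),
      n_units = length(x)
    )
  })
  structure(out, per_unit = cc, class = c("cp_cumulative", class(out)))
}

# Two-sided Wilcoxon signed-rank p value vs 0: exact for n <= 25 (no ties),
# normal approximation with continuity correction otherwise.
wilcoxon_p <- function(x, mu = 0) {
  x <- x[!is.na(x)]
  if (length(x) < 1) return(NA_real_)
  if (all(x == mu)) return(1)  # signed-rank discards zeros; nothing to test
  exact <- length(x) <= 25 && !any(duplicated(abs(x - mu))) && !any(x == mu)
  suppressWarnings(
    wilcox.test(x, mu = mu, exact = exact, correct = TRUE)$p.value
  )
}

# ---- CP <-> choice correlation conversion -------------------------------

# Density of the sum of two independent half-normal variables.
halfnormal_sum_density <- function(s) {
  (2 / sqrt(pi)) * exp(-s^2 / 4) * (2 * pnorm(s / sqrt(2)) - 1)
}

#' Convert a choice correlation to a choice probability
#'
#' Exact relation under the bivariate-Gaussian threshold model: a spike
#' variable and a decision variable are standard bivariate normal with
#' correlation `rho`, the choice is the sign of the decision variable, and
#' CP is the probability that a preferred-choice spike draw exceeds a
#' null-choice draw, `E[pnorm(rho (|u|+|v|) / sqrt(2 (1 - rho^2)))]` with
#' `u, v` standard normal.  Evaluated by adaptive quadrature over the
#' closed-form density of `|u| + |v|`.
#'
#' @param rho Choice correlation(s) in (-1, 1).
#' @return Choice probabilities in (0, 1).
#' @export
cp_from_choice_correlation <- function(rho) {
  vapply(rho, function(r) {
    stopifnot(abs(r) < 1)
    a <- r / sqrt(2 * (1 - r^2))
    0.5 + stats::integrate(function(s) halfnormal_sum_density(s) * (pnorm(a * s) - 0.5),
                           0, Inf, rel.tol = 1e-12)$value
  }, numeric(1))
}

#' Convert a choice probability to a choice correlation
#'
#' Numerical inversion of [cp_from_choice_correlation()]; odd-symmetric about
#' CP = 0.5 and strictly increasing on (0, 1).
#'
#' @param cp Choice probabilities in (0, 1); `NA`s pass through.
#' @return Choice correlations in (-1, 1).
#' @export
cp_to_choice_correlation <- function(cp) {
  vapply(cp, function(p) {
    if (is.na(p)) return(NA_real_)
    if (p <= 0 || p >= 1) stop("cp must lie strictly in (0, 1)", call. = FALSE)
    if (p == 0.5) return(0)
    uniroot(function(r) cp_from_choice_correlation(r) - p,
            interval = c(-0.999999, 0.999999), tol = 1e-10)$root
  }, numeric(1))
}

#' Expected performance loss from choice history
#'
#' The drop in proportion correct attributable to history-induced variance
#' of the decision variable, `(pi / 16) * sigma2`.
#'
#' @param sigma2 History-induced variance of the linear predictor.
#' @return Expected drop in proportion correct.
#' @export
history_performance_loss <- function(sigma2) {
  stopifnot(all(sigma2 >= 0))
  (pi / 16) * sigma2
}

# ---- Psychometrics and the independent observer --------------------------

fit_psychometric_one <- function(signal, choice) {
  if (length(unique(choice)) < 2) {
    stop("degenerate (one-sided) choice data for psychometric fit", call. = FALSE)
  }
  fit <- suppressWarnings(glm(choice ~ signal, family = binomial("probit")))
  a <- coef(fit)[[1]]; b <- coef(fit)[[2]]
  if (!is.finite(b) || b <= 0) {
    stop("psychometric slope not positive; cannot express as cumulative Gaussian",
         call. = FALSE)
  }
  c(mu = -a / b, sigma = 1 / b)
}

#' Fit cumulative-Gaussian psychometric functions
#'
#' Maximum-likelihood fit of `P(preferred choice) = pnorm((signal - mu) / sigma)`
#' per session; optionally split by the sign of the previous choice, reporting
#' the bias (`mu`) of each branch.
#'
#' @param trials A trial tibble.
#' @param split_by_prev_choice Fit separately for trials preceded by a
#'   preferred vs a null choice (requires [filter_trials()] lag columns;
#'   applied automatically).
#' @return A tibble with `unit_id`, `group` (`"all"`, `"prev_pref"`,
#'   `"prev_null"`), `mu`, `sigma`, `n`.
#' @export
fit_psychometric <- function(trials, split_by_prev_choice = FALSE) {
  if (split_by_prev_choice) trials <- filter_trials(trials)
  trials %>%
    dplyr::group_by(.data$unit_id) %>%
    dplyr::group_modify(function(tr, key) {
      fit_one <- function(rows, label) {
        ms <- fit_psychometric_one(tr$signal[rows], tr$choice[rows])
        tibble(group = label, mu = ms[["mu"]], sigma = ms[["sigma"]],
               n = sum(rows))
      }
      if (!split_by_prev_choice) {
        fit_one(rep(TRUE, nrow(tr)), "all")
      } else {
        dplyr::bind_rows(
          fit_one(tr$choice_prev == 1, "prev_pref"),
          fit_one(tr$choice_prev == 0, "prev_null")
        )
      }
    }) %>%
    dplyr::ungroup()
}

#' Independent observer control
#'
#' Re-simulates every session with a stimulus-only observer: a cumulative
#' Gaussian psychometric function is fit to the session's behavior, choices
#' are regenerated as `Bernoulli(pnorm((signal - mu) / sigma))` on the
#' identical stimulus sequence (targets unchanged, wins recomputed), the
#' history probit-lasso GLM is re-run, and the >= 4-choices-per-sign inclusion
#' rule is re-applied (sessions may drop by random sampling).
#'
#' @param trials A trial tibble.
#' @param covariates Covariates of the re-run history GLM; the default is the
#'   history terms plus the current stimulus.
#' @param lambda Lasso penalty for the re-run GLM.
#' @param seed Optional seed for the regenerated choices.
#' @return A list of class `observer_control`: `trials` (the regenerated
#'   dataset), `weights` (per-session fitted weights, long format),
#'   `strategy` (see [strategy_summary()]), and `n_excluded`.
#' @export
independent_observer <- function(trials,
                                 covariates = c("choice_prev", "target_prev",
                                                "win_prev", "signal"),
                                 lambda = 0.025, seed = NULL) {
  base <- trials[, intersect(c(trial_columns, "frame_hist", "binned"), names(trials))]
  attr(base, "cp_filtered") <- NULL
  psy <- fit_psychometric(base)
  sim <- with_seed(seed, {
    base %>%
      dplyr::left_join(psy[, c("unit_id", "mu", "sigma")], by = "unit_id") %>%
      dplyr::mutate(
        choice = as.integer(rbinom(dplyr::n(), 1,
                                   pnorm((.data$signal - .data$mu) / .data$sigma))),
        win = as.integer(.data$choice == .data$target)
      ) %>%
      dplyr::select(-"mu", -"sigma")
  })
  filt <- filter_trials(sim)
  kept <- filt %>%
    dplyr::filter(.data$passes_inclusion)
  n_excluded <- length(unique(filt$unit_id)) - length(unique(kept$unit_id))
  weights <- kept %>%
    dplyr::group_by(.data$unit_id) %>%
    dplyr::group_modify(function(tr, key) {
      tr$unit_id <- key$unit_id
      attr(tr, "cp_filtered") <- TRUE
      d <- build_design(tr, covariates, target = "choice")
      fit <- fit_probit_lasso(d, lambda)
      tibble(term = names(fit$coef), estimate = unname(fit$coef))
    }) %>%
    dplyr::ungroup()
  structure(
    list(trials = sim, weights = weights,
         strategy = strategy_summary(weights), n_excluded = n_excluded),
    class = "observer_control"
  )
}

#' Summarize behavioral strategies from history-GLM weights
#'
#' Reads each session's previous-choice weight (positive = stay, negative =
#' switch) and previous-target weight (positive = reward-following) off the
#' fitted model and labels the strategy quadrant.
#'
#' @param weights Long tibble with `unit_id`, `term`, `estimate` containing
#'   terms `choice_prev` and `target_prev` (e.g. from
#'   [independent_observer()] or your own fits).
#' @return A `strategy_summary` tibble with per-session `(w_choice, w_target)`
#'   pairs, `quadrant` labels, plus population means as attributes.
#' @export
strategy_summary <- function(weights) {
  wide <- weights %>%
    dplyr::filter(.data$term %in% c("choice_prev", "target_prev")) %>%
    tidyr::pivot_wider(names_from = "term", values_from = "estimate") %>%
    dplyr::rename(w_choice = "choice_prev", w_target = "target_prev") %>%
    dplyr::mutate(
      quadrant = dplyr::case_when(
        .data$w_choice >= 0 & .data$w_target >= 0 ~ "win-stay",
        .data$w_choice < 0 & .data$w_target >= 0 ~ "lose-switch",
        .data$w_choice < 0 & .data$w_target < 0 ~ "win-switch",
        TRUE ~ "lose-stay"
      )
    )
  structure(wide,
            mean_w_choice = mean(wide$w_choice),
            mean_w_target = mean(wide$w_target),
            class = c("strategy_summary", class(wide)))
}

#' Select the lasso penalty by population cross-validation
#'
#' Evaluates each candidate penalty by the mean cross-validated choice
#' prediction performance across the population (fit on signal trials,
#' scored on no-signal trials) and returns the maximizer.
#'
#' @inheritParams choice_prediction_performance
#' @param grid Candidate penalties.
#' @return The selected penalty, with the per-candidate mean CPPs attached
#'   as attribute `cpp`.
#' @export
select_lambda <- function(trials, covariates,
                          grid = c(0, 0.005, 0.01, 0.025, 0.05, 0.1)) {
  trials <- filter_trials(trials)
  means <- vapply(grid, function(l) {
    mean(choice_prediction_performance(trials, covariates, l)$cpp, na.rm = TRUE)
  }, numeric(1))
  structure(grid[which.max(means)], cpp = setNames(means, grid))
}
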