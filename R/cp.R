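# Choice probability, the stimulus-variability correction, semipartial CPs
# and the statistical-interaction ladder.

#' Correct no-signal spike counts for stimulus-induced variability
#'
#' Even on no-signal trials the frame-by-frame disparity content varies, so
#' choice-dependent stimulus differences can leak into the spike counts.  The
#' correction regresses the counts on the per-trial frame histogram (one
#' regressor per disparity level, intercept included), subtracts the fitted
#' stimulus component and adds back the grand mean; the corrected counts have
#' no linear dependence on frame content.  With more disparity levels than
#' trials a small ridge is used instead, with a warning.
#'
#' @param counts Spike counts on no-signal trials.
#' @param frame_hist Matrix of frame counts (trials x disparity levels), or a
#'   list of per-trial histogram vectors.
#' @return Corrected counts (same mean as the input).
#' @export
correct_stimulus_variability <- function(counts, frame_hist) {
  if (is.list(frame_hist)) frame_hist <- do.call(rbind, frame_hist)
  stopifnot(nrow(frame_hist) == length(counts))
  n <- length(counts)
  X <- cbind(1, frame_hist)
  if (ncol(X) >= n) {
    warning("more disparity levels than trials; using ridge correction",
            call. = FALSE)
    lam <- 1e-3
    beta <- solve(crossprod(X) + diag(lam, ncol(X)), crossprod(X, counts))
    fitted <- drop(X %*% beta)
  } else {
    # frame counts sum to a constant per trial, so the system is rank
    # deficient with the intercept; qr.fitted handles the aliasing
    fitted <- drop(qr.fitted(qr(X), counts))
  }
  counts - fitted + mean(counts)
}

#' Choice probability
#'
#' Area under the ROC comparing the spike-count distributions conditioned on
#' the two choices, with the preferred-choice distribution as the positive
#' class; ties counted 1/2.
#'
#' @param counts Spike counts (or residuals).
#' @param choices Binary choices (1 = preferred).
#' @return CP in `[0, 1]`.
#' @export
choice_probability <- function(counts, choices) {
  area_under_roc(counts, choices)
}

#' Residualize values on a set of regressors
#'
#' Ordinary least squares with an intercept (no cross-validation); the
#' residuals are orthogonal to the regressors and to the constant.
#'
#' @param values Numeric vector.
#' @param regressors Matrix or data frame of regressors (may be `NULL` or
#'   zero-column, in which case the values are returned unchanged).
#' @return Residuals.
#' @export
residualize <- function(values, regressors = NULL) {
  if (is.null(regressors) || NCOL(regressors) == 0) return(values)
  X <- cbind(1, as.matrix(regressors))
  drop(qr.resid(qr(X), values))
}

regressor_sets <- list(
  none = character(0),
  choice = "choice",
  history = c("choice_prev", "target_prev", "win_prev"),
  full = c("choice_prev", "target_prev", "win_prev", "spikes_prev")
)

# Build the (unstandardized, intercept handled by residualize) regressor
# matrix for the no-signal trials of one session.  spikes_prev is
# residualized on the previous signal through the origin first.
semipartial_regressors <- function(ns, regress_out) {
  if (is.character(regress_out) && length(regress_out) == 1 &&
      regress_out %in% names(regressor_sets)) {
    regress_out <- regressor_sets[[regress_out]]
  }
  if (length(regress_out) == 0) return(NULL)
  unknown <- setdiff(regress_out, names(covariate_columns))
  if (length(unknown) > 0) {
    stop("unknown regressor(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(regress_out, function(cv) {
    v <- as.numeric(ns[[covariate_columns[[cv]]]])
    if (cv %in% c("spikes_prev", "spikes_prev2")) {
      v <- regress_out_stimulus(v, ns[[sub("spikes", "signal", cv)]])
    }
    v
  })
  X <- do.call(cbind, cols)
  colnames(X) <- regress_out
  X
}

#' Semipartial choice probability
#'
#' Per session: take the no-signal trials, correct the counts for
#' stimulus-induced variability (when frame histograms are available),
#' regress the requested covariates out of the counts only (choices are left
#' untouched), and compute the CP of the residuals.  With an empty regressor
#' set this reproduces the raw CP exactly.  The CP is also converted to a
#' choice correlation.
#'
#' @param trials A trial tibble.
#' @param regress_out One of the named sets `"none"`, `"choice"` (current
#'   choice), `"history"` (previous choice/target/win), `"full"` (history +
#'   residualized previous spike count), or a character vector of covariate
#'   names.
#' @param correct_stimulus Apply [correct_stimulus_variability()] first
#'   (default `TRUE` when frame histograms are present).
#' @return A tibble with `unit_id`, `cp`, `choice_correlation`, `n`.
#' @export
semipartial_cp <- function(trials, regress_out = "none",
                           correct_stimulus = NULL) {
  trials <- filter_trials(trials)
  trials %>%
    dplyr::filter(.data$passes_inclusion) %>%
    dplyr::group_by(.data$unit_id) %>%
    dplyr::group_modify(function(tr, key) {
      ns <- tr[tr$signal == 0, ]
      counts <- as.numeric(ns$spikes)
      do_corr <- correct_stimulus %||%
        ("frame_hist" %in% names(ns) && !vapply(ns$frame_hist, is.null, logical(1))[1])
      if (isTRUE(do_corr)) {
        counts <- correct_stimulus_variability(counts, ns$frame_hist)
      }
      res <- residualize(counts, semipartial_regressors(ns, regress_out))
      cp <- choice_probability(res, ns$choice)
      tibble(cp = cp, choice_correlation = cp_to_choice_correlation(cp),
             n = nrow(ns))
    }) %>%
    dplyr::ungroup()
}

#' Full CP decomposition per unit
#'
#' Raw CP plus the three semipartial variants (current choice regressed out;
#' choice history regressed out; history + spike history regressed out), all
#' on stimulus-corrected no-signal counts.
#'
#' @inheritParams semipartial_cp
#' @return A `cp_results` tibble with `unit_id`, `raw_cp`,
#'   `semipartial_cp_choice`, `semipartial_cp_history`, `semipartial_cp_full`,
#'   `choice_correlation`, `n`.
#' @export
cp_summary <- function(trials, correct_stimulus = NULL) {
  raw <- semipartial_cp(trials, "none", correct_stimulus)
  ch <- semipartial_cp(trials, "choice", correct_stimulus)
  hi <- semipartial_cp(trials, "history", correct_stimulus)
  fu <- semipartial_cp(trials, "full", correct_stimulus)
  out <- tibble(
    unit_id = raw$unit_id,
    raw_cp = raw$cp,
    semipartial_cp_choice = ch$cp,
    semipartial_cp_history = hi$cp,
    semipartial_cp_full = fu$cp,
    choice_correlation = raw$choice_correlation,
    n = raw$n
  )
  structure(out, class = c("cp_results", class(out)))
}

#' Statistical-interaction ladder
#'
#' For each queried edge (covariate block -> target, given a conditioning
#' set), computes the population increment in prediction performance from
#' adding the block to the conditioning model — choice-prediction performance
#' in choice-correlation units for choice targets, Pearson cc for spike
#' targets — and a two-sided Wilcoxon signed-rank test across sessions.  An
#' edge is retained when p < 0.05.
#'
#' @param trials A trial tibble.
#' @param edges A list of edges, each a list with `target` (`"choice"` or
#'   `"spikes"`), `add` (covariates forming the edge) and `given`
#'   (conditioning covariates; may include `"sf"` for spike targets).
#'   Defaults to the four-panel ladder: history->choice given spike counts;
#'   previous spikes->choice given history + current spikes; history->spikes
#'   given previous spikes + current choice; the same with slow fluctuations.
#' @param lambda Probit-lasso penalty for choice targets.
#' @param gp_tau,gp_amplitude GP hyperparameters for `"sf"`.
#' @return A tibble with `edge`, `target`, `mean_increment`, `p_value`,
#'   `retained`.
#' @export
interaction_ladder <- function(trials, edges = default_ladder(),
                               lambda = 0.025, gp_tau = 35, gp_amplitude = 1) {
  trials <- filter_trials(trials)
  purrr::map_dfr(edges, function(e) {
    order <- c(e$given, e$add)
    k0 <- length(e$given)
    if (e$target == "choice") {
      cum <- cumulative_cpp(trials, order, lambda)
    } else {
      cum <- cumulative_cc(trials, order, gp_tau, gp_amplitude)
    }
    per_unit <- attr(cum, "per_unit")
    base <- if (k0 == 0) rep(0, nrow(per_unit)) else per_unit[, k0]
    inc <- per_unit[, length(order)] - base
    inc <- inc[!is.na(inc)]
    tibble(
      edge = paste0(paste(e$add, collapse = "+"), " -> ", e$target,
                    if (k0 > 0) paste0(" | ", paste(e$given, collapse = "+")) else ""),
      target = e$target,
      mean_increment = mean(inc),
      p_value = wilcoxon_p(inc),
      retained = wilcoxon_p(inc) < 0.05
    )
  })
}

#' @rdname interaction_ladder
#' @export
default_ladder <- function() {
  history <- c("choice_prev", "target_prev", "win_prev")
  list(
    list(target = "choice", add = history, given = c("spikes_prev", "spikes")),
    list(target = "choice", add = "spikes_prev", given = c(history, "spikes")),
    list(target = "spikes", add = history, given = c("spikes_prev", "choice")),
    list(target = "spikes", add = history, given = c("spikes_prev", "choice", "sf"))
  )
}
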