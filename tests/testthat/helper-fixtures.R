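# Shared fixtures: all synthetic, built in code at test time.

# Hand-assembled minimal session (no frame histograms / binned counts).
toy_session <- function(n = 8,
                        signal = rep(c(0.25, 0, -0.125, 0), length.out = n),
                        choice = rep(c(1, 0), length.out = n),
                        complete = rep(1L, n),
                        spikes = seq_len(n) + 10L,
                        unit_id = "toy") {
  target <- ifelse(signal > 0, 1L, ifelse(signal < 0, 0L, choice))
  tibble::tibble(
    unit_id = unit_id, index = seq_len(n) - 1L,
    signal = signal, choice = as.integer(choice), target = as.integer(target),
    win = as.integer(choice == target), spikes = as.integer(spikes),
    complete = as.integer(complete)
  )
}

# Small cached populations shared across test files (built once per run).
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

small_pop <- function() cached("small_pop", function() {
  generate_population(sim_config(n_units = 8, n_nosignal = 80,
                                 signal_counts = rep(14L, 6), seed = 101))
})

# Plain-R reference for the AR simulators, mirroring the C++ draw order
# (one uniform for the initial choice, then per trial: spike innovation,
# decision noise).  Used as the dual-route oracle.
ar_reference_sim <- function(params, n, seed) {
  set.seed(seed)
  al <- params$alpha; be <- params$beta; cp <- params$coupling
  s1 <- params$sigma1; s2 <- params$sigma2; mu <- params$mu
  model <- params$model
  cbar_prev <- if (runif(1) < 0.5) 1 else -1
  s_prev <- mu
  choice <- integer(n); count <- numeric(n)
  for (t in seq_len(n)) {
    e2 <- rnorm(1); e1 <- rnorm(1)
    if (model == "CM1") {
      s_t <- mu + al * (s_prev - mu) + s2 * e2
      m <- cp * (s_t - mu) + be * cbar_prev + s1 * e1
      cb <- if (m > 0) 1 else -1
    } else if (model == "CM2") {
      m <- be * cbar_prev + s1 * e1
      cb <- if (m > 0) 1 else -1
      s_t <- mu + al * (s_prev - mu) + cp * cb + s2 * e2
    } else if (model == "ICM1") {
      m <- be * cbar_prev + s1 * e1
      cb <- if (m > 0) 1 else -1
      s_t <- mu + al * (s_prev - mu) + cp * cbar_prev + s2 * e2
    } else {
      m <- cp * (s_prev - mu) + be * cbar_prev + s1 * e1
      cb <- if (m > 0) 1 else -1
      s_t <- mu + al * (s_prev - mu) + s2 * e2
    }
    choice[t] <- if (cb > 0) 1L else 0L
    count[t] <- max(0, round(s_t))
    s_prev <- s_t; cbar_prev <- cb
  }
  list(choice = choice, count = count)
}
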