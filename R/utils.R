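# Internal helpers shared across modules.

# Draw n reproducible substream seeds from a master seed (kept < 2^31).
substream_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr_seed <- as.integer(seed %% .Machine$integer.max)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(withr_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run an expression under a local RNG state seeded with `seed`
# (NULL seed = use the current stream, do not restore).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Column-wise z-scoring with statistics taken from `rows` only.
# Constant columns get scale 1 so they pass through unchanged (minus center).
standardize_columns <- function(x, rows) {
  center <- apply(x[rows, , drop = FALSE], 2, mean)
  scale <- apply(x[rows, , drop = FALSE], 2, sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  xs <- sweep(x, 2, center, "-")
  xs <- sweep(xs, 2, scale, "/")
  list(x = xs, center = center, scale = scale)
}

# Least squares through the origin of y on x; returns residuals.
resid_through_origin <- function(y, x) {
  sxx <- sum(x^2)
  if (sxx < 1e-12) return(y)
  y - x * (sum(x * y) / sxx)
}

# Circularly shift a vector by k positions (positive k delays).
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

is_binary01 <- function(x) all(x %in% c(0, 1) | is.na(x))
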