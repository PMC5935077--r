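# Internal helpers shared across modules. No science here beyond small,
# self-contained numerics (vectorised OLS, permutations, silhouette).

# Run `code` under a fixed RNG state when `seed` is given, without touching
# the caller's .Random.seed; otherwise use the current RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

# Ordinary least squares of y on x with the two-sided t test of slope = 0.
# Vectorised over the columns of `y` (a matrix); x is a single predictor.
# Returns a tibble with one row per column of y.
ols_slope_test <- function(x, y) {
  y <- as.matrix(y)
  n <- length(x)
  if (nrow(y) != n) abort("`x` and `y` have incompatible lengths.")
  if (n < 3L) abort("At least 3 points are required for the slope test.")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) abort("Predictor `x` has zero variance.")
  xc <- x - mean(x)
  sxy <- as.vector(crossprod(xc, y))          # sum xc * y
  slope <- sxy / sxx
  intercept <- colMeans(y) - slope * mean(x)
  fitted <- outer(x, slope) + rep(intercept, each = n)
  rss <- colSums((y - fitted)^2)
  tss <- colSums((y - rep(colMeans(y), each = n))^2)
  r_squared <- ifelse(tss > 0, pmax(0, pmin(1, 1 - rss / tss)), 0)
  df <- n - 2L
  se <- sqrt(pmax(rss, 0) / df / sxx)
  degenerate <- se == 0
  tval <- ifelse(degenerate, Inf, slope / se)
  p_value <- ifelse(degenerate & slope != 0, 0, 2 * pt(abs(tval), df, lower.tail = FALSE))
  p_value[degenerate & slope == 0] <- 1
  tibble(
    slope = slope, intercept = intercept, r_squared = r_squared,
    p_value = p_value, n = n, degenerate = degenerate
  )
}

# All permutations of 1..n as an n! x n integer matrix (n <= 8 in practice).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# Mean silhouette width for a labelled distance matrix (plain matrix) and a
# grouping vector; small and self-contained.
mean_silhouette <- function(d, groups) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  s <- vapply(seq_len(n), function(i) {
    own <- groups == groups[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(
      setdiff(unique(groups), groups[i]),
      function(g) mean(d[i, groups == g]),
      numeric(1)
    ))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
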