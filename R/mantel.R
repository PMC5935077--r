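# Matrix-correlation statistics: Mantel tests, matrix regressions and the
# all-pairs panel.

# Accept a dist_matrix, a transformed matrix, or any labelled square matrix.
as_square_matrix <- function(x, name = "matrix") {
  m <- unclass(as.matrix(x))
  if (nrow(m) != ncol(m) || is.null(rownames(m))) {
    abort(sprintf("`%s` must be a labelled square matrix.", name))
  }
  m
}

#' Mantel test between two distance matrices
#'
#' The Mantel statistic M is the Pearson correlation of the strictly-upper-
#' triangle entries of `a` and `b`. Significance comes from jointly
#' permuting the row/column labels of `b`:
#' `p = (1 + #\{r* >= r_obs\}) / (1 + n_permutations)` for the default
#' one-sided (greater) alternative. With `exhaustive = TRUE` (n <= 7
#' labels) all `n!` label permutations are enumerated and the p-value is
#' exact.
#'
#' @param a,b Labelled square symmetric matrices (e.g. [dist_matrix()])
#'   sharing labels in the same order.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @param alternative `"greater"` (the classical Mantel convention, default)
#'   or `"two_sided"`.
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return An object of class `mantel_test` with fields `r` (the statistic
#'   M), `p_value`, `n_permutations`, `alternative`, `n`, `seed`. `tidy()`
#'   returns it as a one-row tibble.
#' @examples
#' sites <- marsh_sites()
#' mantel(env_difference_matrix(sites, "air_temp"),
#'        geographic_distance_matrix(sites), exhaustive = TRUE)
#' @export
mantel <- function(a, b, n_permutations = 999, seed = NULL,
                   alternative = c("greater", "two_sided"), exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  check_same_labels(a, b)
  ma <- as_square_matrix(a, "a")
  mb <- as_square_matrix(b, "b")
  n <- nrow(ma)
  if (n < 3L) abort("At least 3 labels are required.")
  va <- ma[upper.tri(ma)]
  vb <- mb[upper.tri(mb)]
  if (sd(va) == 0 || sd(vb) == 0) abort("A matrix has zero variance off the diagonal.")
  r_obs <- cor(va, vb)
  score <- function(r) if (alternative == "greater") r else abs(r)
  if (exhaustive) {
    if (n > 7L) abort("Exhaustive enumeration is limited to 7 labels.")
    perms <- all_permutations(n)
    stats <- apply(perms, 1L, function(p) cor(va, mb[p, p][upper.tri(mb)]))
    p_value <- mean(score(stats) >= score(r_obs) - 1e-12)
    n_permutations <- nrow(perms)
  } else {
    assert_scalar_number(n_permutations, "n_permutations", lower = 1)
    stats <- with_seed_if(seed, {
      vapply(seq_len(n_permutations), function(i) {
        p <- sample.int(n)
        cor(va, mb[p, p][upper.tri(mb)])
      }, numeric(1))
    })
    p_value <- (1 + sum(score(stats) >= score(r_obs) - 1e-12)) / (1 + n_permutations)
  }
  structure(
    list(
      r = r_obs, p_value = p_value, n_permutations = n_permutations,
      alternative = alternative, exhaustive = exhaustive, n = n,
      seed = seed
    ),
    class = "mantel_test"
  )
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf(
    "Mantel test (%s, %s): M = %.4f, p = %.4g (n = %d labels, %d permutations)\n",
    x$alternative, if (x$exhaustive) "exhaustive" else "sampled",
    x$r, x$p_value, x$n, x$n_permutations
  ))
  invisible(x)
}

#' @rdname mantel
#' @param x A `mantel_test` object.
#' @param ... Unused.
#' @export
tidy.mantel_test <- function(x, ...) {
  tibble(
    statistic = x$r, p_value = x$p_value,
    n_permutations = x$n_permutations, alternative = x$alternative, n = x$n
  )
}

#' Matrix regression on upper-triangle pairs
#'
#' Ordinary least squares of the strictly-upper-triangle entries of `a`
#' (response) on those of `b` (predictor). The reported `r_squared` equals
#' the squared Mantel statistic of the same pair.
#'
#' @inheritParams mantel
#' @return A one-row tibble with `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided t test of slope = 0), `n_pairs`.
#' @export
matrix_regression <- function(a, b) {
  check_same_labels(a, b)
  ma <- as_square_matrix(a, "a")
  mb <- as_square_matrix(b, "b")
  y <- ma[upper.tri(ma)]
  x <- mb[upper.tri(mb)]
  if (sd(x) == 0) abort("Predictor matrix has zero variance off the diagonal.")
  fit <- ols_slope_test(x, matrix(y, ncol = 1))
  tibble(
    slope = fit$slope, intercept = fit$intercept, r_squared = fit$r_squared,
    p_value = fit$p_value, n_pairs = length(x)
  )
}

#' All-pairs Mantel and regression panel
#'
#' Runs [mantel()] and [matrix_regression()] for every unordered pair of a
#' named list of distance matrices — the matrix-comparison panel used to
#' screen environmental variables and control communities against
#' geographic distance.
#'
#' @param matrices A named list of labelled square matrices sharing labels.
#' @inheritParams mantel
#' @return A tibble with one row per unordered pair: `name_a`, `name_b`,
#'   `m` (Mantel statistic), `r_squared`, `p_value`, `slope`, `intercept`.
#' @export
pairwise_panel <- function(matrices, n_permutations = 999, seed = NULL, exhaustive = FALSE) {
  if (length(matrices) < 2L || is.null(names(matrices))) {
    abort("`matrices` must be a named list with at least two entries.")
  }
  pairs <- utils::combn(names(matrices), 2L)
  seeds <- with_seed_if(seed, sample.int(.Machine$integer.max, ncol(pairs)))
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    na <- pairs[1, k]; nb <- pairs[2, k]
    mt <- mantel(matrices[[na]], matrices[[nb]], n_permutations = n_permutations,
                 seed = seeds[k], exhaustive = exhaustive)
    reg <- matrix_regression(matrices[[na]], matrices[[nb]])
    tibble(
      name_a = na, name_b = nb, m = mt$r, r_squared = reg$r_squared,
      p_value = mt$p_value, slope = reg$slope, intercept = reg$intercept
    )
  })
}
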