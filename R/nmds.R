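#' Pool-adjacent-violators isotonic regression
#'
#' Least-squares monotone non-decreasing fit to `y` with optional weights:
#' adjacent blocks that violate monotonicity are pooled into their weighted
#' mean until the fitted sequence is non-decreasing. Already-monotone input
#' is returned unchanged.
#'
#' @param y Numeric vector.
#' @param w Positive weights (default all 1).
#' @return The fitted non-decreasing vector, same length as `y`.
#' @examples
#' pava(c(3, 1, 2)) # c(2, 2, 2)
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  if (length(w) != n || any(w <= 0)) abort("`w` must be positive and match `y` in length.")
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; wt[nb] <- w[i]; len[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      tot <- wt[nb - 1L] + wt[nb]
      val[nb - 1L] <- (val[nb - 1L] * wt[nb - 1L] + val[nb] * wt[nb]) / tot
      wt[nb - 1L] <- tot
      len[nb - 1L] <- len[nb - 1L] + len[nb]
      nb <- nb - 1L
    }
  }
  rep(val[seq_len(nb)], len[seq_len(nb)])
}

#' Kruskal stress-1 of a configuration against a dissimilarity matrix
#'
#' Given target dissimilarities D and a k-dimensional configuration, the
#' configuration distances d are ordered by D (primary tie handling: tied D
#' entries carry no monotonicity constraint between them), fitted by
#' monotone regression ([pava()]), and scored as
#' `stress = sqrt(sum((d - dhat)^2) / sum(d^2))`.
#'
#' @param d A [dist_matrix()] of target dissimilarities.
#' @param coordinates Numeric matrix, rows in the order of `d`'s labels.
#' @return Stress-1, a non-negative scalar (0 for a perfect configuration).
#' @export
kruskal_stress <- function(d, coordinates) {
  m <- as_square_matrix(d, "d")
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != nrow(m)) abort("`coordinates` rows must match the matrix labels.")
  delta <- as.matrix(dist(coordinates))
  dv <- m[upper.tri(m)]
  cv <- delta[upper.tri(delta)]
  if (all(cv == cv[1])) abort("Degenerate configuration: all inter-point distances are equal.")
  # primary ties: sorting tied blocks by the configuration distance lets
  # PAVA leave them unconstrained relative to one another
  ord <- order(dv, cv)
  fitted <- pava(cv[ord])
  sqrt(sum((cv[ord] - fitted)^2) / sum(cv^2))
}

#' Non-metric multidimensional scaling
#'
#' Embeds the samples in `k` dimensions so that the rank order of
#' configuration distances matches the rank order of the input
#' dissimilarities, minimising Kruskal stress-1. The optimisation is
#' vegan's monotone-regression nMDS engine, restarted from `n_starts`
#' random configurations plus one classical-scaling (metric MDS) start;
#' the lowest-stress solution is returned. Reproducible given `seed`.
#'
#' @param d A [dist_matrix()] of dissimilarities.
#' @param k Embedding dimension (default 2).
#' @param n_starts Number of random restarts (default 10).
#' @param max_iterations Iteration cap per start (default 999).
#' @param tol Convergence tolerance on stress (default 1e-6).
#' @param seed Optional integer seed.
#' @return An object of class `nmds_ord` with centred `coordinates`
#'   (n x k, rownames = labels), `stress`, `n_starts`, `k`, `seed`.
#'   `tidy()` returns the coordinates as a tibble; `glance()` the fit
#'   summary; `autoplot()` draws the ordination.
#' @export
ordinate_nmds <- function(d, k = 2, n_starts = 10, max_iterations = 999,
                          tol = 1e-6, seed = NULL) {
  stopifnot(is_dist_matrix(d))
  assert_scalar_number(k, "k", lower = 1)
  assert_scalar_number(n_starts, "n_starts", lower = 0)
  n <- nrow(d)
  if (n < k + 1) abort("Need at least k + 1 samples.")
  if (any(!is.finite(d))) abort("Non-finite dissimilarities.")
  dd <- stats::as.dist(unclass(d))
  best <- NULL
  with_seed_if(seed, {
    starts <- vector("list", n_starts + 1L)
    starts[[1L]] <- cmdscale(dd, k = k)            # metric-MDS start
    if (ncol(starts[[1L]]) < k) {
      starts[[1L]] <- cbind(starts[[1L]], matrix(0, n, k - ncol(starts[[1L]])))
    }
    for (s in seq_len(n_starts)) {
      starts[[s + 1L]] <- matrix(runif(n * k, -1, 1), n, k)
    }
    for (init in starts) {
      fit <- vegan::monoMDS(dd, y = init, k = k, model = "global",
                            maxit = max_iterations, sratmax = 1 - tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  dimnames(coords) <- list(dm_labels(d), paste0("nmds", seq_len(k)))
  structure(
    list(
      coordinates = coords, stress = best$stress, k = k,
      n_starts = n_starts, n_iterations = max_iterations, seed = seed
    ),
    class = "nmds_ord"
  )
}

#' @export
print.nmds_ord <- function(x, ...) {
  cat(sprintf(
    "nMDS ordination: %d samples in %d dimensions, stress-1 = %.4f (%d random starts)\n",
    nrow(x$coordinates), x$k, x$stress, x$n_starts
  ))
  invisible(x)
}

#' @rdname ordinate_nmds
#' @param x An `nmds_ord` object.
#' @param ... Unused.
#' @export
tidy.nmds_ord <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = rownames(x$coordinates)), as_tibble(x$coordinates))
}

#' @rdname ordinate_nmds
#' @export
glance.nmds_ord <- function(x, ...) {
  tibble(stress = x$stress, k = x$k, n_samples = nrow(x$coordinates), n_starts = x$n_starts)
}
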