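#' Bray-Curtis dissimilarity between samples
#'
#' For samples x and y over shared OTUs,
#' `BC(x, y) = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, a compositional
#' distance in \[0, 1\]. Computed on counts after rarefaction to equal
#' depths (where it reduces to `1 - sum(min) / depth`), or on relative
#' abundances via `input = "relative"`.
#'
#' @param tbl An OTU table or relative-abundance tibble.
#' @param input `"counts"` (default) or `"relative"`.
#' @return A [dist_matrix()] over the samples.
#' @examples
#' tbl <- otu_table(tibble::tibble(
#'   otu_id = c("a", "b", "c"),
#'   S1 = c(4, 2, 0), S2 = c(1, 2, 3)
#' ))
#' bray_curtis(tbl) # 0.5 between S1 and S2
#' @export
bray_curtis <- function(tbl, input = c("counts", "relative")) {
  input <- match.arg(input)
  tbl <- if (input == "counts") otu_table(tbl) else as_tibble(tbl)
  m <- as.matrix(tbl[, otu_sample_ids(tbl), drop = FALSE])
  n <- ncol(m)
  if (n < 2L) abort("At least 2 samples are required.")
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf("Sample '%s' is all-zero; Bray-Curtis is undefined.", colnames(m)[totals == 0][1]))
  }
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      shared <- sum(pmin(m[, i], m[, j]))
      d[i, j] <- d[j, i] <- 1 - 2 * shared / (totals[i] + totals[j])
    }
  }
  dist_matrix(d)
}

#' Great-circle distance matrix between sites
#'
#' Haversine distance on a sphere of radius 6371 km, from the signed decimal
#' coordinates of a [site_environment()] table.
#'
#' @param sites A [site_environment()] tibble.
#' @return A [dist_matrix()] in kilometres, labelled by site code.
#' @export
geographic_distance_matrix <- function(sites) {
  sites <- site_environment(sites)
  p <- cbind(sites$longitude, sites$latitude)
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(sites$site, sites$site))
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(p[i, ], p, r = 6371) # r in km
  }
  diag(d) <- 0
  dist_matrix(d)
}

#' Pairwise environmental difference matrix
#'
#' Entry (i, j) is the absolute difference `|v_i - v_j|` of one
#' environmental variable between two sites, in the variable's own units.
#'
#' @param sites A [site_environment()] tibble.
#' @param variable One of `"air_temp"`, `"pct_nitrogen"`, `"pct_carbon"`,
#'   `"salinity"`.
#' @return A [dist_matrix()] labelled by site code.
#' @export
env_difference_matrix <- function(sites, variable) {
  sites <- site_environment(sites)
  variable <- match.arg(variable, env_variables)
  v <- sites[[variable]]
  if (any(!is.finite(v))) abort(sprintf("Missing %s value in the site table.", variable))
  d <- abs(outer(v, v, "-"))
  dimnames(d) <- list(sites$site, sites$site)
  dist_matrix(d)
}

#' Natural-log transform of a distance matrix
#'
#' Replaces every off-diagonal entry by `ln(x + pseudocount)`, leaving the
#' diagonal at zero (it is excluded from all downstream statistics). Used to
#' reduce skew before regressing community dissimilarity on geographic
#' distance.
#'
#' @param x A [dist_matrix()].
#' @param transform `"natural_log"` or `"none"`.
#' @param pseudocount Non-negative value added before the log; with
#'   `pseudocount = 0` every off-diagonal entry must be strictly positive.
#' @return A matrix of the same shape and labels (class `dist_matrix` is
#'   dropped, since log values may be negative and asymmetric metrics no
#'   longer apply).
#' @export
transform_matrix <- function(x, transform = c("natural_log", "none"), pseudocount = 0) {
  stopifnot(is_dist_matrix(x))
  transform <- match.arg(transform)
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  if (transform == "none") return(x)
  m <- unclass(as.matrix(x))
  off <- !diag(nrow(m)) > 0
  bad <- which(off & upper.tri(m) & (m + pseudocount <= 0), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Cannot ln-transform cell ('%s', '%s') = %g with pseudocount %g.",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, 1], bad[1, 2]], pseudocount
    ))
  }
  m[off] <- log(m[off] + pseudocount)
  structure(m, class = c("transformed_matrix", "matrix", "array"))
}
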