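# The directional indicator-OTU regression scan: for each OTU surviving a
# prevalence filter, regress its per-sample share of grand total against the
# environmental change each sample experienced from origin to destination.

scan_variables <- c("air_temp", "pct_nitrogen", "salinity", "geographic_distance")

#' Directional environmental change from origin to destination
#'
#' For the ln-scale variables (`air_temp`, `pct_nitrogen`, `salinity`) the
#' delta is `ln(v_destination) - ln(v_origin)`: antisymmetric in direction
#' and zero when origin equals destination. For `geographic_distance` the
#' default convention is `ln(1 + d_km)` with d the great-circle distance —
#' symmetric and zero at d = 0 (so control samples sit at x = 0);
#' `"raw_symmetric"` uses d itself.
#'
#' @param origin,destination Site codes (vectorised).
#' @param variable One of `air_temp`, `pct_nitrogen`, `salinity`,
#'   `geographic_distance`.
#' @param sites A [site_environment()] tibble containing both sites.
#' @param geodist_convention `"ln1p_symmetric"` (default) or
#'   `"raw_symmetric"`.
#' @return Numeric vector of deltas.
#' @examples
#' env_delta("WB", "AB", "air_temp", marsh_sites()) # ln(24.2) - ln(17.1)
#' @export
env_delta <- function(origin, destination, variable, sites,
                      geodist_convention = c("ln1p_symmetric", "raw_symmetric")) {
  variable <- match.arg(variable, scan_variables)
  geodist_convention <- match.arg(geodist_convention)
  sites <- site_environment(sites)
  io <- match(origin, sites$site)
  id <- match(destination, sites$site)
  if (anyNA(io)) abort(sprintf("Unknown origin site '%s'.", origin[is.na(io)][1]))
  if (anyNA(id)) abort(sprintf("Unknown destination site '%s'.", destination[is.na(id)][1]))
  if (variable == "geographic_distance") {
    g <- unclass(geographic_distance_matrix(sites))
    dkm <- g[cbind(io, id)]
    if (geodist_convention == "ln1p_symmetric") log1p(dkm) else dkm
  } else {
    v <- sites[[variable]]
    log(v[id]) - log(v[io])
  }
}

#' Assemble one OTU-by-variable regression dataset
#'
#' One (x, y) point per included sample, with x the [env_delta()] of the
#' sample's origin-to-destination move (controls sit at x = 0) and y the
#' sample's share of the OTU's grand total ([otu_percent_of_total()]).
#'
#' @param tbl An OTU-table tibble.
#' @param metadata A [sample_metadata()] tibble covering the table's
#'   samples.
#' @param sites A [site_environment()] tibble.
#' @param otu_id The OTU to scan.
#' @param variable The environmental variable (see [env_delta()]).
#' @param include_classes Sample classes to include (default all three).
#' @inheritParams env_delta
#' @return A tibble with columns `sample_id`, `x`, `y`.
#' @export
assemble_regression_dataset <- function(tbl, metadata, sites, otu_id, variable,
                                        include_classes = sample_classes,
                                        geodist_convention = "ln1p_symmetric") {
  metadata <- sample_metadata(metadata)
  shares <- otu_percent_of_total(tbl, otu_id)
  meta <- metadata[metadata$sample_class %in% include_classes, ]
  missing <- setdiff(meta$sample_id, shares$sample_id)
  if (length(missing)) {
    abort(sprintf("Sample '%s' is in the metadata but not in the OTU table.", missing[1]))
  }
  meta <- dplyr::left_join(meta, shares, by = "sample_id")
  tibble(
    sample_id = meta$sample_id,
    x = env_delta(meta$origin_site, meta$destination_site, variable, sites,
                  geodist_convention = geodist_convention),
    y = meta$share
  )
}

#' Least-squares regression with the two-sided slope test
#'
#' Ordinary least squares of y on x. The p-value is the two-sided Student-t
#' test of slope = 0 with n - 2 degrees of freedom. A perfect fit (zero
#' residual variance) reports p = 0 with `degenerate = TRUE`.
#'
#' @param points A data frame with columns `x` and `y` (>= 3 rows, x not
#'   constant).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`, `degenerate`.
#' @examples
#' linear_regression_test(data.frame(x = 1:5, y = 2 * (1:5) + 1))
#' @export
linear_regression_test <- function(points) {
  if (!all(c("x", "y") %in% names(points))) abort("`points` needs columns `x` and `y`.")
  ols_slope_test(points$x, matrix(points$y, ncol = 1))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param n_tests Number of hypotheses tested.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.001, 63337 * 4) # 3.9e-9 at two significant figures
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly between 0 and 1.")
  assert_scalar_number(n_tests, "n_tests", lower = 1)
  alpha / n_tests
}

#' Run the indicator-OTU regression scan
#'
#' Applies the prevalence curation, assembles the per-sample (x, y) dataset
#' for every surviving OTU and every scan variable, fits each least-squares
#' regression, and marks passes at the Bonferroni-corrected threshold
#' `alpha / (n_surviving_OTUs * n_variables)`.
#'
#' @param tbl An OTU-table tibble (typically rarefied and singleton-free).
#' @param metadata A [sample_metadata()] tibble.
#' @param sites A [site_environment()] tibble.
#' @param variables Scan variables (default `air_temp`, `pct_nitrogen`,
#'   `salinity`, `geographic_distance`; percent carbon is excluded by
#'   default because it is collinear with nitrogen).
#' @param alpha Family-wise significance level before correction (default
#'   0.001).
#' @param prevalence_min_fraction Prevalence curation fraction (default
#'   0.95: an OTU must occur in strictly more than 95% of samples).
#' @param include_classes Sample classes entering each regression (default
#'   all; controls contribute points at x = 0).
#' @inheritParams env_delta
#' @return An object of class `indicator_scan`: `results` (tibble sorted by
#'   p-value: `otu_id`, `variable`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, `passes`), and a `summary` list with `n_otus_tested`,
#'   `n_variables`, `n_tests`, `corrected_alpha`, `n_pass`,
#'   `passing_otus`, and `prevalence_threshold`. `tidy()` returns the
#'   results tibble; `glance()` the summary as one row.
#' @export
run_scan <- function(tbl, metadata, sites,
                     variables = scan_variables, alpha = 0.001,
                     prevalence_min_fraction = 0.95,
                     include_classes = sample_classes,
                     geodist_convention = "ln1p_symmetric") {
  tbl <- otu_table(tbl)
  metadata <- sample_metadata(metadata)
  variables <- match.arg(variables, scan_variables, several.ok = TRUE)
  meta <- metadata[metadata$sample_class %in% include_classes, ]
  keep_samples <- intersect(otu_sample_ids(tbl), meta$sample_id)
  if (length(keep_samples) < 3L) abort("Fewer than 3 usable samples.")
  sub <- tbl[, c("otu_id", intersect("taxonomy", names(tbl)), keep_samples)]
  surv <- suppressMessages(prevalence_filter(sub, prevalence_min_fraction))
  k_threshold <- attr(surv, "prevalence_threshold")
  if (nrow(surv) == 0L) {
    warn("No OTU survives the prevalence curation; the scan result is empty.")
    return(new_indicator_scan(
      tibble(otu_id = character(), variable = character(), slope = numeric(),
             intercept = numeric(), r_squared = numeric(), p_value = numeric(),
             n = integer(), passes = logical()),
      list(n_otus_tested = 0L, n_variables = length(variables), n_tests = 0L,
           corrected_alpha = NA_real_, n_pass = 0L, passing_otus = character(),
           prevalence_threshold = k_threshold, alpha = alpha)
    ))
  }
  counts <- otu_counts(surv)
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  grand <- rowSums(counts)
  if (any(grand == 0)) abort("An OTU surviving prevalence has grand total 0.")
  y <- t(counts / grand)                               # samples x OTUs shares
  n_tests <- nrow(surv) * length(variables)
  corrected_alpha <- bonferroni_threshold(alpha, n_tests)
  results <- purrr::map_dfr(variables, function(v) {
    x <- env_delta(meta$origin_site, meta$destination_site, v, sites,
                   geodist_convention = geodist_convention)
    fit <- ols_slope_test(x, y)
    dplyr::bind_cols(tibble(otu_id = colnames(y), variable = v), fit)
  })
  results$passes <- results$p_value < corrected_alpha
  results <- dplyr::arrange(results, .data$p_value, .data$otu_id)
  results <- dplyr::select(results, "otu_id", "variable", "slope", "intercept",
                           "r_squared", "p_value", "n", "passes", "degenerate")
  new_indicator_scan(results, list(
    n_otus_tested = nrow(surv), n_variables = length(variables),
    n_tests = n_tests, corrected_alpha = corrected_alpha,
    n_pass = sum(results$passes),
    passing_otus = unique(results$otu_id[results$passes]),
    prevalence_threshold = k_threshold, alpha = alpha
  ))
}

new_indicator_scan <- function(results, summary) {
  structure(list(results = results, summary = summary), class = "indicator_scan")
}

#' @export
print.indicator_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Indicator-OTU scan: %d OTUs x %d variables = %d regressions\n",
    s$n_otus_tested, s$n_variables, s$n_tests
  ))
  cat(sprintf(
    "Bonferroni-corrected alpha = %.3g (family alpha %.3g); %d passing result(s) among %d OTU(s)\n",
    s$corrected_alpha, s$alpha, s$n_pass, length(s$passing_otus)
  ))
  if (s$n_pass > 0) print(head(x$results[x$results$passes, ], 10))
  invisible(x)
}

#' @rdname run_scan
#' @param x An `indicator_scan` object.
#' @param ... Unused.
#' @export
tidy.indicator_scan <- function(x, ...) x$results

#' @rdname run_scan
#' @export
glance.indicator_scan <- function(x, ...) {
  s <- x$summary
  tibble(
    n_otus_tested = s$n_otus_tested, n_variables = s$n_variables,
    n_tests = s$n_tests, corrected_alpha = s$corrected_alpha,
    n_pass = s$n_pass, n_passing_otus = length(s$passing_otus),
    prevalence_threshold = s$prevalence_threshold
  )
}
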