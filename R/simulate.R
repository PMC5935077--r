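# Ground-truth simulator for the fully factorial reciprocal-transplant
# design: region/site-structured baseline communities, an origin/destination
# mixing (invasion) fraction, planted indicator OTUs responding
# log-linearly to environmental deltas, and Dirichlet-multinomial
# sequencing noise.

#' Build a fully factorial transplant design
#'
#' One record per (origin, destination, replicate) over all ordered site
#' pairs — the origin == destination cells are the replanted controls —
#' plus `n_pristine_per_site` never-moved pristine controls per site.
#' Specific records can be dropped to model unrecovered cores.
#'
#' @param sites A [site_environment()] tibble or a character vector of site
#'   codes (>= 2 sites).
#' @param replicates_per_cell Cores per design cell (default 3).
#' @param n_pristine_per_site Pristine controls per site (default 3).
#' @param dropped_cells Optional character vector of sample ids to omit
#'   (e.g. `"PI_to_JR_2"`); ids not in the design are an error.
#' @return A [sample_metadata()] tibble. With 5 sites, 3 replicates, 3
#'   pristine controls and 2 drops this is the study's 88-sample layout.
#' @examples
#' nrow(build_design(marsh_sites(), dropped_cells = c("PI_to_JR_2", "WB_to_AB_3")))
#' @export
build_design <- function(sites, replicates_per_cell = 3, n_pristine_per_site = 3,
                         dropped_cells = NULL) {
  codes <- if (is.data.frame(sites)) site_environment(sites)$site else as.character(sites)
  if (length(codes) < 2L) abort("At least 2 sites are required.")
  assert_scalar_number(replicates_per_cell, "replicates_per_cell", lower = 1)
  assert_scalar_number(n_pristine_per_site, "n_pristine_per_site", lower = 0)
  grid <- tidyr::expand_grid(
    origin_site = codes, destination_site = codes,
    replicate = seq_len(replicates_per_cell)
  )
  grid$sample_class <- ifelse(grid$origin_site == grid$destination_site,
                              "replant_control", "transplant")
  grid$sample_id <- sprintf("%s_to_%s_%d", grid$origin_site, grid$destination_site, grid$replicate)
  pristine <- tidyr::expand_grid(origin_site = codes, replicate = seq_len(n_pristine_per_site))
  if (nrow(pristine)) {
    pristine$destination_site <- pristine$origin_site
    pristine$sample_class <- "pristine_control"
    pristine$sample_id <- sprintf("%s_pristine_%d", pristine$origin_site, pristine$replicate)
  }
  design <- dplyr::bind_rows(grid, pristine)
  if (!is.null(dropped_cells)) {
    unknown <- setdiff(dropped_cells, design$sample_id)
    if (length(unknown)) {
      abort(sprintf("Dropped cell '%s' is not in the design.", unknown[1]))
    }
    design <- design[!design$sample_id %in% dropped_cells, ]
  }
  sample_metadata(design[, c("sample_id", "origin_site", "destination_site",
                             "sample_class", "replicate")])
}

#' Planted indicator specifications
#'
#' Each indicator plants a known log-linear response: before
#' renormalisation the OTU's expected relative abundance is multiplied by
#' `exp(beta * delta_v)` where `delta_v` is the [env_delta()] of the
#' sample's origin-to-destination move. A negative `beta` on `air_temp`
#' reproduces the canonical pattern of a warm-adapted OTU declining as its
#' community is moved to warmer-relative-to-origin conditions.
#'
#' @param otu_index Integer index of the planted OTU (1-based, <= `n_otus`).
#' @param variable One of the scan variables (see [env_delta()]).
#' @param beta Log-linear response slope.
#' @return A one-row tibble; rows from several calls can be bound together.
#' @export
indicator_spec <- function(otu_index, variable, beta) {
  variable <- match.arg(variable, scan_variables)
  assert_scalar_number(otu_index, "otu_index", lower = 1)
  assert_scalar_number(beta, "beta")
  tibble(otu_index = as.integer(otu_index), variable = variable, beta = beta)
}

default_indicators <- function() {
  dplyr::bind_rows(
    indicator_spec(1L, "air_temp", -1.15),  # less abundant when moved to warmer sites
    indicator_spec(2L, "air_temp", 1.15),
    indicator_spec(3L, "pct_nitrogen", -0.42),
    indicator_spec(4L, "salinity", 0.42),
    indicator_spec(5L, "geographic_distance", 0.075)
  )
}

#' Simulation configuration for the transplant-design generator
#'
#' Defaults emulate the study conditions: the five marshes of
#' [marsh_sites()] with their north/south regional split, a fully factorial
#' 3-replicate design plus 3 pristine controls per site with the two
#' unrecovered cores dropped (88 samples), log-normal baseline abundances
#' with region- and site-level multiplicative perturbations, a small
#' invasion fraction (the study found communities resistant to invasion),
#' five planted indicator OTUs calibrated so their realised regression
#' R-squared falls in the 0.4-0.6 range, and Dirichlet-multinomial
#' sequencing noise at the study's even rarefaction depth.
#'
#' @param sites A [site_environment()] tibble.
#' @param region_of_site Named character vector mapping site to region.
#' @param n_otus Number of OTUs K (default 300).
#' @param base_lognormal_mu,base_lognormal_sigma Parameters of the
#'   per-OTU baseline relative-abundance draw (default 0 and 0.7).
#' @param region_effect_sigma Log-scale sd of the region-specific
#'   multiplicative perturbation shared by all sites of a region (bounded:
#'   uniform on the log scale with this sd for an average-abundance OTU,
#'   scaled per OTU in proportion to its replicate-level noise; default
#'   0.095).
#' @param site_effect_sigma Log-scale sd of the per-site perturbation that
#'   distinguishes sites within a region (bounded, noise-proportional,
#'   centred to zero within each region and orthogonal to the within-region
#'   salinity pattern on the log scale; default 0.36).
#' @param invasion_fraction Mixing fraction pi in \[0, 1\]: the expected
#'   transplant profile is `(1 - pi) * theta_origin + pi *
#'   theta_destination` (default 0.05).
#' @param indicators A tibble of [indicator_spec()] rows (default five
#'   planted indicators across the four scan variables).
#' @param indicator_base_abundance Baseline expected relative abundance
#'   assigned to each planted indicator OTU (default 0.03), keeping them
#'   prevalent enough to survive the scan's curation, as the study's
#'   indicators were.
#' @param depth Reads per sample D (default 14376, the study's even
#'   rarefaction depth).
#' @param overdispersion Dirichlet concentration c > 0; counts are
#'   Dirichlet-multinomial(D, c * theta). Larger is closer to plain
#'   multinomial; the default 1500 gives clear extra-multinomial
#'   replicate-to-replicate scatter.
#' @param replicates_per_cell,n_pristine_per_site,dropped_cells Passed to
#'   [build_design()] by [simulate_dataset()] when no design is supplied.
#' @param geodist_convention Delta convention for geographic-distance
#'   indicators (see [env_delta()]).
#' @param seed Optional integer seed making the whole simulation
#'   deterministic.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(sites = marsh_sites(),
                              region_of_site = marsh_regions(),
                              n_otus = 300,
                              base_lognormal_mu = 0,
                              base_lognormal_sigma = 0.7,
                              region_effect_sigma = 0.095,
                              site_effect_sigma = 0.36,
                              invasion_fraction = 0.05,
                              indicators = default_indicators(),
                              indicator_base_abundance = 0.03,
                              depth = 14376,
                              overdispersion = 1500,
                              replicates_per_cell = 3,
                              n_pristine_per_site = 3,
                              dropped_cells = c("PI_to_JR_2", "WB_to_AB_3"),
                              geodist_convention = "ln1p_symmetric",
                              seed = NULL) {
  sites <- site_environment(sites)
  missing_region <- setdiff(sites$site, names(region_of_site))
  if (length(missing_region)) {
    abort(sprintf("No region label for site '%s'.", missing_region[1]))
  }
  assert_scalar_number(n_otus, "n_otus", lower = 2)
  assert_scalar_number(invasion_fraction, "invasion_fraction", lower = 0, upper = 1)
  assert_scalar_number(depth, "depth", lower = 1)
  assert_scalar_number(overdispersion, "overdispersion")
  if (overdispersion <= 0) abort("`overdispersion` must be positive.")
  assert_scalar_number(region_effect_sigma, "region_effect_sigma", lower = 0)
  assert_scalar_number(site_effect_sigma, "site_effect_sigma", lower = 0)
  indicators <- as_tibble(indicators)
  if (nrow(indicators) && any(indicators$otu_index > n_otus)) {
    abort("An indicator otu_index exceeds `n_otus`.")
  }
  structure(
    list(
      sites = sites, region_of_site = region_of_site,
      n_otus = as.integer(n_otus),
      base_lognormal_mu = base_lognormal_mu,
      base_lognormal_sigma = base_lognormal_sigma,
      region_effect_sigma = region_effect_sigma,
      site_effect_sigma = site_effect_sigma,
      invasion_fraction = invasion_fraction,
      indicators = indicators,
      indicator_base_abundance = indicator_base_abundance,
      depth = as.integer(depth), overdispersion = overdispersion,
      replicates_per_cell = replicates_per_cell,
      n_pristine_per_site = n_pristine_per_site,
      dropped_cells = dropped_cells,
      geodist_convention = geodist_convention,
      seed = seed
    ),
    class = "sim_config"
  )
}

otu_id_for <- function(i, k) sprintf("otu_%0*d", nchar(k), i)

#' Expected community profile per site
#'
#' Draws a per-OTU baseline relative abundance from the configured
#' log-normal (planted indicator OTUs get a fixed baseline share instead),
#' multiplies it by a region-specific log-normal perturbation shared by all
#' sites of a region and by an independent per-site perturbation, and
#' normalises per site. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `site`, `otu_id`, `theta`; `theta` sums to
#'   1 within each site.
#' @export
simulate_site_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_otus
  sites <- config$sites$site
  regions <- config$region_of_site[sites]
  with_seed_if(config$seed, {
    base <- exp(rnorm(k, config$base_lognormal_mu, config$base_lognormal_sigma))
    if (nrow(config$indicators)) {
      # pin indicators near a target share of the expected community
      target <- config$indicator_base_abundance
      expected_total <- k * exp(config$base_lognormal_mu + config$base_lognormal_sigma^2 / 2)
      base[unique(config$indicators$otu_index)] <- target * expected_total
    }
    # Nested decomposition on the log scale: a region-level effect shared by
    # all sites of a region, plus site-within-region deviations centred to
    # zero within each region. Effects are bounded (uniform, sd = sigma for
    # an average-abundance OTU) and scaled per OTU to a constant multiple of
    # its replicate-level noise (sd proportional to 1 / sqrt(c * theta),
    # capped), so that spatial structure is an aggregate of many modest
    # shifts and no single taxon is individually resolvable as an
    # environmental responder unless planted.
    share <- base / sum(base)
    noise_scale <- pmin(sqrt((1 / k) / share), 3)
    half_r <- sqrt(3) * config$region_effect_sigma * noise_scale
    half_s <- sqrt(3) * config$site_effect_sigma * noise_scale
    region_fx <- sapply(unique(regions), function(r) exp(runif(k, -half_r, half_r)))
    site_log <- sapply(sites, function(s) runif(k, -half_s, half_s))
    for (r in unique(regions)) {
      cols <- which(regions == r)
      site_log[, cols] <- site_log[, cols, drop = FALSE] -
        rowMeans(site_log[, cols, drop = FALSE])
    }
    # The generator's contract is that only planted indicators respond to the
    # measured environment. Temperature and nitrogen follow the regional
    # gradient (handled by the region term), but salinity varies site-to-site
    # within region, so random site idiosyncrasy could mimic a salinity
    # response; project the within-region salinity pattern out of the site
    # deviations to keep the unplanted community a true null for the scan.
    sal <- log(config$sites$salinity)
    sal_centred <- sal
    for (r in unique(regions)) {
      cols <- which(regions == r)
      sal_centred[cols] <- sal[cols] - mean(sal[cols])
    }
    if (sum(sal_centred^2) > 0) {
      p_hat <- sal_centred / sqrt(sum(sal_centred^2))
      site_log <- site_log - (site_log %*% p_hat) %*% t(p_hat)
    }
    site_fx <- exp(site_log)
    profiles <- purrr::map_dfr(seq_along(sites), function(si) {
      theta <- base * region_fx[, regions[si]] * site_fx[, si]
      tibble(site = sites[si], otu_id = otu_id_for(seq_len(k), k), theta = theta / sum(theta))
    })
  })
  profiles
}

profiles_to_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(profiles, names_from = "site", values_from = "theta")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$otu_id
  m
}

#' Simulate a full transplant-design OTU dataset
#'
#' For each sample the expected profile is the invasion mixture
#' `(1 - pi) * theta_origin + pi * theta_destination` (controls have origin
#' equal to destination, so they sit at their site profile for any pi). Each
#' planted indicator OTU's entry is then multiplied by
#' `exp(beta * delta_v)` for the sample's origin-to-destination
#' [env_delta()], the profile is renormalised, and counts are drawn as
#' Dirichlet-multinomial(depth, overdispersion * theta). Every sample's
#' counts sum exactly to `depth`.
#'
#' @param config A [simulation_config()].
#' @param design Optional [sample_metadata()] tibble; by default the fully
#'   factorial design implied by the config (including its dropped cells).
#' @return A list of class `transplant_sim` with elements `otu_table`
#'   (tibble), `metadata`, `sites`, `profiles` (the expected site
#'   profiles) and `ground_truth` (tibble of planted `otu_id`, `variable`,
#'   `beta`, plus the invasion fraction as an attribute).
#' @examples
#' sim <- simulate_dataset(simulation_config(n_otus = 50, depth = 500, seed = 1))
#' dplyr::count(sim$metadata, sample_class)
#' @export
simulate_dataset <- function(config, design = NULL) {
  stopifnot(inherits(config, "sim_config"))
  design <- design %||% build_design(
    config$sites, config$replicates_per_cell,
    config$n_pristine_per_site, config$dropped_cells
  )
  design <- sample_metadata(design)
  unknown <- setdiff(unique(c(design$origin_site, design$destination_site)), config$sites$site)
  if (length(unknown)) abort(sprintf("Design references unknown site '%s'.", unknown[1]))
  profiles <- simulate_site_profiles(config)
  theta_site <- profiles_to_matrix(profiles)       # OTUs x sites
  k <- config$n_otus
  pi <- config$invasion_fraction
  ind <- config$indicators
  deltas <- if (nrow(ind)) {
    vapply(seq_len(nrow(ind)), function(r) {
      env_delta(design$origin_site, design$destination_site, ind$variable[r],
                config$sites, geodist_convention = config$geodist_convention)
    }, numeric(nrow(design)))
  }
  counts_seed <- if (is.null(config$seed)) NULL else config$seed + 1L
  counts <- with_seed_if(counts_seed, {
    vapply(seq_len(nrow(design)), function(s) {
      theta <- (1 - pi) * theta_site[, design$origin_site[s]] +
        pi * theta_site[, design$destination_site[s]]
      if (nrow(ind)) {
        mult <- exp(ind$beta * deltas[s, ])
        theta[ind$otu_index] <- theta[ind$otu_index] * mult
      }
      theta <- theta / sum(theta)
      p <- rgamma(k, shape = config$overdispersion * theta)
      if (all(p == 0)) p <- theta                  # extreme underflow guard
      rmultinom(1, config$depth, p / sum(p))[, 1]
    }, numeric(k))
  })
  dimnames(counts) <- list(otu_id_for(seq_len(k), k), design$sample_id)
  ground_truth <- if (nrow(ind)) {
    tibble(otu_id = otu_id_for(ind$otu_index, k), variable = ind$variable, beta = ind$beta)
  } else {
    tibble(otu_id = character(), variable = character(), beta = numeric())
  }
  attr(ground_truth, "invasion_fraction") <- pi
  structure(
    list(
      otu_table = otu_table(dplyr::bind_cols(tibble(otu_id = rownames(counts)),
                                             as_tibble(counts))),
      metadata = design, sites = config$sites, profiles = profiles,
      ground_truth = ground_truth, config = config
    ),
    class = "transplant_sim"
  )
}

#' @export
print.transplant_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated transplant dataset: %d OTUs x %d samples at depth %d (pi = %g, %d planted indicators)\n",
    nrow(x$otu_table), nrow(x$metadata), x$config$depth,
    x$config$invasion_fraction, nrow(x$ground_truth)
  ))
  invisible(x)
}
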