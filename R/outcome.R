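# Formalisation of the four transplant-outcome hypotheses (no change, total
# adoption, host shift, random shift) as a deterministic classifier over
# Bray-Curtis dissimilarities to the origin and destination control clouds.

outcome_levels <- c("no_change", "total_adoption", "host_shift", "random_shift")

#' Control-cloud statistics per site
#'
#' For each site, `baseline` is the mean pairwise Bray-Curtis dissimilarity
#' among that site's control samples (the natural within-site dispersion);
#' `separation(s, t)` is the mean dissimilarity between the controls of two
#' sites.
#'
#' @param bc A [dist_matrix()] of community dissimilarities over all
#'   samples.
#' @param metadata A [sample_metadata()] tibble.
#' @param controls `"pristine"` (default: pristine controls define the
#'   undisturbed reference state) or `"both"` (pool pristine and replanted
#'   controls).
#' @return A list with `baselines` (tibble: `site`, `baseline`,
#'   `n_controls`), `separations` (labelled site-by-site matrix) and
#'   `control_ids` (named list of control sample ids per site).
#' @export
control_statistics <- function(bc, metadata, controls = c("pristine", "both")) {
  controls <- match.arg(controls)
  metadata <- sample_metadata(metadata)
  classes <- if (controls == "pristine") "pristine_control" else
    c("pristine_control", "replant_control")
  ctrl <- metadata[metadata$sample_class %in% classes, ]
  ctrl <- ctrl[ctrl$sample_id %in% dm_labels(bc), ]
  used_sites <- unique(c(
    metadata$origin_site[metadata$sample_class == "transplant"],
    metadata$destination_site[metadata$sample_class == "transplant"]
  ))
  ids <- split(ctrl$sample_id, ctrl$origin_site)
  short <- used_sites[vapply(used_sites, function(s) length(ids[[s]] %||% character()) < 2L, logical(1))]
  if (length(short)) {
    abort(sprintf(
      "Site '%s' has fewer than 2 %s controls in the dissimilarity matrix.",
      short[1], controls
    ))
  }
  m <- unclass(as.matrix(bc))
  baselines <- purrr::map_dfr(names(ids), function(s) {
    sub <- m[ids[[s]], ids[[s]], drop = FALSE]
    tibble(site = s, baseline = mean(sub[upper.tri(sub)]), n_controls = length(ids[[s]]))
  })
  sites <- names(ids)
  sep <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
  for (i in seq_along(sites)) {
    for (j in seq_along(sites)) {
      if (i != j) sep[i, j] <- mean(m[ids[[sites[i]]], ids[[sites[j]]]])
    }
  }
  list(baselines = baselines, separations = sep, control_ids = ids)
}

#' Classify transplant outcomes
#'
#' For each transplant sample let `d_o` and `d_d` be its mean Bray-Curtis
#' dissimilarity to the origin-site and destination-site control clouds, and
#' `eps_o = tau * baseline_origin`, `eps_d = tau * baseline_destination` the
#' tolerance bands scaled from the within-cloud dispersions. The call is:
#'
#' * `no_change` if `d_o <= eps_o` and `d_o <= d_d` — the community still
#'   looks like its origin site;
#' * `total_adoption` if `d_d <= eps_d` and `d_d < d_o` — it now looks like
#'   its destination site;
#' * `host_shift` if neither holds but `max(d_o, d_d) <= separation(origin,
#'   destination)` — it lies between the two control clouds;
#' * `random_shift` otherwise — distinct from both.
#'
#' @param tbl_or_bc An OTU-table tibble (Bray-Curtis is computed for you)
#'   or a precomputed [dist_matrix()] over all samples.
#' @param metadata A [sample_metadata()] tibble.
#' @param tau Tolerance multiplier on the baseline dispersion (>= 1,
#'   default 1.5).
#' @param controls Which control classes define the reference clouds (see
#'   [control_statistics()]).
#' @return A tibble with one row per transplant sample: `sample_id`,
#'   `origin_site`, `destination_site`, `call`, `d_origin`,
#'   `d_destination`, `baseline_origin`, `baseline_destination`,
#'   `separation`. The call is fully re-derivable from the stored distances
#'   and `tau`.
#' @export
classify_outcomes <- function(tbl_or_bc, metadata, tau = 1.5,
                              controls = c("pristine", "both")) {
  controls <- match.arg(controls)
  assert_scalar_number(tau, "tau", lower = 1)
  bc <- if (is_dist_matrix(tbl_or_bc)) tbl_or_bc else bray_curtis(tbl_or_bc)
  metadata <- sample_metadata(metadata)
  stats <- control_statistics(bc, metadata, controls = controls)
  trans <- metadata[metadata$sample_class == "transplant", ]
  trans <- trans[trans$sample_id %in% dm_labels(bc), ]
  if (nrow(trans) == 0L) abort("No transplant samples to classify.")
  m <- unclass(as.matrix(bc))
  base <- setNames(stats$baselines$baseline, stats$baselines$site)
  out <- purrr::map_dfr(seq_len(nrow(trans)), function(i) {
    s <- trans$sample_id[i]
    o <- trans$origin_site[i]
    d <- trans$destination_site[i]
    d_o <- mean(m[s, stats$control_ids[[o]]])
    d_d <- mean(m[s, stats$control_ids[[d]]])
    eps_o <- tau * base[[o]]
    eps_d <- tau * base[[d]]
    sep <- stats$separations[o, d]
    call <- if (d_o <= eps_o && d_o <= d_d) {
      "no_change"
    } else if (d_d <= eps_d && d_d < d_o) {
      "total_adoption"
    } else if (max(d_o, d_d) <= sep) {
      "host_shift"
    } else {
      "random_shift"
    }
    tibble(
      sample_id = s, origin_site = o, destination_site = d,
      call = call, d_origin = d_o, d_destination = d_d,
      baseline_origin = base[[o]], baseline_destination = base[[d]],
      separation = sep
    )
  })
  attr(out, "tau") <- tau
  attr(out, "controls") <- controls
  out
}

#' Summarise outcome calls per design cell
#'
#' Tabulates [classify_outcomes()] calls within each (origin, destination)
#' cell and reports the modal call; ties are reported as ties.
#'
#' @param calls The tibble returned by [classify_outcomes()].
#' @return A tibble with one row per design cell: `origin_site`,
#'   `destination_site`, `modal_call` (`"tie"` when tied), `n`, and one
#'   count column per outcome (`n_no_change`, `n_total_adoption`,
#'   `n_host_shift`, `n_random_shift`).
#' @export
outcome_summary <- function(calls) {
  if (!all(c("origin_site", "destination_site", "call") %in% names(calls))) {
    abort("`calls` must come from classify_outcomes().")
  }
  calls |>
    group_by(.data$origin_site, .data$destination_site) |>
    summarise(
      n = dplyr::n(),
      n_no_change = sum(.data$call == "no_change"),
      n_total_adoption = sum(.data$call == "total_adoption"),
      n_host_shift = sum(.data$call == "host_shift"),
      n_random_shift = sum(.data$call == "random_shift"),
      .groups = "drop"
    ) |>
    mutate(modal_call = purrr::pmap_chr(
      list(.data$n_no_change, .data$n_total_adoption, .data$n_host_shift, .data$n_random_shift),
      function(a, b, c, d) {
        counts <- c(no_change = a, total_adoption = b, host_shift = c, random_shift = d)
        top <- names(counts)[counts == max(counts)]
        if (length(top) > 1L) "tie" else top
      }
    )) |>
    dplyr::relocate("modal_call", .after = "destination_site")
}
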