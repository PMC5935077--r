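#' OTU tables as wide tibbles
#'
#' Throughout the package an OTU table is a tibble with an `otu_id` column,
#' an optional `taxonomy` column (semicolon-delimited lineage strings), and
#' one non-negative integer count column per sample. These helpers validate
#' that shape and convert to/from the underlying counts matrix.
#'
#' @param tbl An OTU-table tibble.
#' @return `otu_table()` returns the validated tibble; `otu_counts()` the
#'   counts matrix (rows = OTUs, columns = samples); `otu_sample_ids()` the
#'   sample column names.
#' @examples
#' tbl <- otu_table(tibble::tibble(otu_id = c("a", "b"), S1 = c(1, 0), S2 = c(2, 3)))
#' otu_counts(tbl)
#' @export
otu_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  if (!"otu_id" %in% names(tbl)) abort("An OTU table needs an `otu_id` column.")
  tbl$otu_id <- as.character(tbl$otu_id)
  samples <- otu_sample_ids(tbl)
  if (length(samples) == 0L || nrow(tbl) == 0L) abort("OTU table is empty.")
  if (anyDuplicated(tbl$otu_id)) {
    abort(sprintf("Duplicated OTU id: '%s'.", tbl$otu_id[duplicated(tbl$otu_id)][1]))
  }
  if (anyDuplicated(samples)) {
    abort(sprintf("Duplicated sample id: '%s'.", samples[duplicated(samples)][1]))
  }
  for (s in samples) {
    v <- tbl[[s]]
    if (!is.numeric(v)) abort(sprintf("Counts in sample '%s' are not numeric.", s))
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf(
        "Count at (%s, %s) is '%s'; counts must be non-negative integers.",
        tbl$otu_id[bad[1]], s, format(v[bad[1]])
      ))
    }
  }
  tbl
}

#' @rdname otu_table
#' @export
otu_sample_ids <- function(tbl) setdiff(names(tbl), c("otu_id", "taxonomy"))

#' @rdname otu_table
#' @export
otu_counts <- function(tbl) {
  samples <- otu_sample_ids(tbl)
  m <- as.matrix(tbl[, samples, drop = FALSE])
  rownames(m) <- tbl$otu_id
  m
}

# Rebuild a table like `tbl` around a new counts matrix (same OTU order).
set_otu_counts <- function(tbl, counts) {
  out <- tibble(otu_id = rownames(counts))
  if ("taxonomy" %in% names(tbl)) {
    out$taxonomy <- tbl$taxonomy[match(out$otu_id, tbl$otu_id)]
  }
  dplyr::bind_cols(out, as_tibble(counts))
}

#' Read and write OTU count tables
#'
#' Tab-separated with one header row and one label column. A trailing
#' `taxonomy` column, if present, is captured as lineage strings. Both
#' orientations are accepted; the table is normalised to OTUs-as-rows.
#'
#' @param path File path.
#' @param orientation `"otus_as_rows"` (default) or `"samples_as_rows"`.
#' @return A validated OTU-table tibble (see [otu_table()]).
#' @export
read_otu_table <- function(path, orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(),
                        name_repair = "minimal")
  if (nrow(df) == 0L || ncol(df) < 2L) abort("OTU table file is empty.")
  if (anyDuplicated(names(df))) {
    abort(sprintf("Duplicated column label: '%s'.", names(df)[duplicated(names(df))][1]))
  }
  label_col <- names(df)[1]
  has_tax <- tolower(names(df)[ncol(df)]) == "taxonomy"
  tax <- if (has_tax) as.character(df[[ncol(df)]]) else NULL
  if (has_tax) df <- df[, -ncol(df), drop = FALSE]
  labels <- as.character(df[[1]])
  num <- df[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf(
        "Cell (%s, %s) is '%s'; counts must be non-negative integers.",
        labels[bad[1]], names(num)[j], as.character(df[[j + 1]][bad[1]])
      ))
    }
    num[[j]] <- v
  }
  if (orientation == "otus_as_rows") {
    out <- tibble(otu_id = labels)
    if (has_tax) out$taxonomy <- tax
    out <- dplyr::bind_cols(out, num)
  } else {
    m <- t(as.matrix(num))
    colnames(m) <- labels
    out <- tibble(otu_id = rownames(m))
    out <- dplyr::bind_cols(out, as_tibble(m))
  }
  otu_table(out)
}

#' @param tbl A validated OTU-table tibble.
#' @rdname read_otu_table
#' @export
write_otu_table <- function(tbl, path) {
  tbl <- otu_table(tbl)
  cols <- c("otu_id", otu_sample_ids(tbl), intersect("taxonomy", names(tbl)))
  readr::write_tsv(tbl[, cols], path)
  invisible(path)
}

sample_classes <- c("transplant", "replant_control", "pristine_control")

#' Validate sample metadata for a transplant design
#'
#' Metadata holds one row per sample: `sample_id`, `origin_site`,
#' `destination_site`, `sample_class` (one of `transplant`,
#' `replant_control`, `pristine_control`) and `replicate`. Control classes
#' must have origin equal to destination.
#'
#' @param tbl A data frame with the columns above.
#' @return The validated tibble with normalised class strings.
#' @export
sample_metadata <- function(tbl) {
  tbl <- as_tibble(tbl)
  need <- c("sample_id", "origin_site", "destination_site", "sample_class", "replicate")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) abort(sprintf("Metadata is missing column(s): %s.", paste(miss, collapse = ", ")))
  tbl$sample_id <- as.character(tbl$sample_id)
  tbl$origin_site <- as.character(tbl$origin_site)
  tbl$destination_site <- as.character(tbl$destination_site)
  tbl$sample_class <- tolower(trimws(as.character(tbl$sample_class)))
  unknown <- setdiff(unique(tbl$sample_class), sample_classes)
  if (length(unknown)) {
    abort(sprintf(
      "Unknown sample class '%s'; allowed values are: %s.",
      unknown[1], paste(sample_classes, collapse = ", ")
    ))
  }
  if (anyDuplicated(tbl$sample_id)) {
    abort(sprintf("Duplicated sample id: '%s'.", tbl$sample_id[duplicated(tbl$sample_id)][1]))
  }
  ctrl <- tbl$sample_class != "transplant" & tbl$origin_site != tbl$destination_site
  if (any(ctrl)) {
    abort(sprintf(
      "Sample '%s' is a %s but origin ('%s') != destination ('%s').",
      tbl$sample_id[ctrl][1], tbl$sample_class[ctrl][1],
      tbl$origin_site[ctrl][1], tbl$destination_site[ctrl][1]
    ))
  }
  tbl$replicate <- as.integer(tbl$replicate)
  tbl
}

#' Read and write sample metadata
#'
#' Tab-separated with columns `sample_id`, `origin_site`,
#' `destination_site`, `sample_class`, `replicate`. Class strings are
#' normalised case-insensitively. If the factorial (origin x destination)
#' grid of transplant/replant cells is incomplete relative to the modal
#' replicate count, a design-completeness warning lists the missing cells.
#'
#' @param path File path.
#' @return A validated metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  tbl <- sample_metadata(readr::read_tsv(path, show_col_types = FALSE))
  check_design_completeness(tbl)
  tbl
}

check_design_completeness <- function(tbl) {
  core <- tbl[tbl$sample_class %in% c("transplant", "replant_control"), ]
  if (nrow(core) == 0L) return(invisible(tbl))
  sites <- sort(unique(c(core$origin_site, core$destination_site)))
  counts <- table(factor(core$origin_site, sites), factor(core$destination_site, sites))
  reps <- as.integer(names(which.max(table(counts[counts > 0]))))
  short <- which(counts < reps, arr.ind = TRUE)
  if (nrow(short)) {
    cells <- apply(short, 1L, function(i) sprintf("%s->%s", sites[i[1]], sites[i[2]]))
    warn(sprintf(
      "Design incomplete: %d factorial cell(s) below the modal %d replicates: %s.",
      nrow(short), reps, paste(cells, collapse = ", ")
    ))
  }
  invisible(tbl)
}

#' @param tbl A metadata tibble.
#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(tbl, path) {
  readr::write_tsv(sample_metadata(tbl), path)
  invisible(path)
}

env_variables <- c("pct_nitrogen", "pct_carbon", "salinity", "air_temp")

#' Validate a site environment table
#'
#' One row per site: `site`, `latitude` (degrees N), `longitude` (stored as
#' signed decimal degrees, west negative), `pct_nitrogen` and `pct_carbon`
#' (percent by weight), `salinity` (ppt) and `air_temp` (degrees C). All
#' environmental values must be strictly positive because downstream
#' comparisons are on natural-log scale.
#'
#' @param tbl A data frame with the columns above (`longitude` already
#'   signed).
#' @return The validated tibble.
#' @export
site_environment <- function(tbl) {
  tbl <- as_tibble(tbl)
  need <- c("site", "latitude", "longitude", env_variables)
  miss <- setdiff(need, names(tbl))
  if (length(miss)) abort(sprintf("Site table is missing column(s): %s.", paste(miss, collapse = ", ")))
  tbl$site <- as.character(tbl$site)
  if (any(is.na(tbl$site) | tbl$site == "")) abort("Missing site code in site table.")
  if (anyDuplicated(tbl$site)) {
    abort(sprintf("Duplicated site code: '%s'.", tbl$site[duplicated(tbl$site)][1]))
  }
  if (any(abs(tbl$latitude) > 90)) abort("Latitude must lie in [-90, 90].")
  if (any(abs(tbl$longitude) > 180)) abort("Longitude must lie in [-180, 180].")
  for (v in env_variables) {
    bad <- which(!is.finite(tbl[[v]]) | tbl[[v]] <= 0)
    if (length(bad)) {
      abort(sprintf(
        "Site '%s' has non-positive %s (%s); strictly positive values are required for the ln transform.",
        tbl$site[bad[1]], v, format(tbl[[v]][bad[1]])
      ))
    }
  }
  tbl
}

#' Read a site environment table
#'
#' Tab-separated with columns `site`, `latitude`, `longitude`,
#' `pct_nitrogen`, `pct_carbon`, `salinity`, `air_temp`. Longitude is
#' accepted either as degrees-west-positive (the printed-table convention;
#' converted to signed negative) or as signed decimal degrees, and is always
#' stored signed, west negative.
#'
#' @param path File path.
#' @param lon_convention `"auto"` (default: all-positive longitudes are
#'   treated as degrees west), `"west_positive"`, or `"signed"`.
#' @return A validated [site_environment()] tibble.
#' @export
read_site_table <- function(path, lon_convention = c("auto", "west_positive", "signed")) {
  lon_convention <- match.arg(lon_convention)
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  flip <- switch(lon_convention,
    west_positive = TRUE,
    signed = FALSE,
    auto = all(tbl$longitude > 0)
  )
  if (flip) tbl$longitude <- -tbl$longitude
  site_environment(tbl)
}

#' @param tbl A site environment tibble (signed longitude).
#' @rdname read_site_table
#' @export
write_site_table <- function(tbl, path) {
  readr::write_tsv(site_environment(tbl), path)
  invisible(path)
}

#' The five study marshes and their environment
#'
#' The packaged fixture describing the five US East Coast salt marsh sites
#' (WB, PI, JR, RC, AB, listed north to south) with coordinates, percent
#' nitrogen and carbon by weight, salinity and mean air temperature over the
#' transplant season.
#'
#' @return A [site_environment()] tibble with 5 rows.
#' @examples
#' marsh_sites()
#' @export
marsh_sites <- function() {
  read_site_table(
    system.file("extdata", "table1_sites.tsv", package = "marshtransplant", mustWork = TRUE),
    lon_convention = "west_positive"
  )
}

#' North/south region labels for the study sites
#'
#' The two northern marshes (WB, PI) versus the three southern marshes
#' (JR, RC, AB) — the regional split the bacterial communities follow.
#'
#' @return A named character vector mapping site code to region.
#' @export
marsh_regions <- function() {
  c(WB = "north", PI = "north", JR = "south", RC = "south", AB = "south")
}
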