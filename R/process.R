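#' Rarefy an OTU table to an even depth
#'
#' Each sample's counts are replaced by a uniform random subsample of
#' exactly `depth` reads drawn without replacement (multivariate
#' hypergeometric), so that richness and dissimilarity are comparable across
#' samples. OTUs reduced to zero everywhere are kept; drop them with a
#' subsequent filter if desired.
#'
#' @param tbl An OTU-table tibble (see [otu_table()]).
#' @param depth Target reads per sample (>= 1).
#' @param seed Optional integer seed; the subsample is bit-identical for a
#'   given seed.
#' @param drop_shallow If `FALSE` (default) a sample with fewer than `depth`
#'   reads is an error naming the sample; if `TRUE` such samples are removed
#'   with a warning.
#' @return A rarefied OTU-table tibble; every remaining sample sums to
#'   exactly `depth`.
#' @examples
#' tbl <- otu_table(tibble::tibble(otu_id = c("a", "b"), S1 = c(60, 40)))
#' colSums(otu_counts(rarefy(tbl, 50, seed = 1)))
#' @export
rarefy <- function(tbl, depth, seed = NULL, drop_shallow = FALSE) {
  tbl <- otu_table(tbl)
  assert_scalar_number(depth, "depth", lower = 1)
  depth <- as.integer(depth)
  m <- otu_counts(tbl)
  totals <- colSums(m)
  shallow <- names(totals)[totals < depth]
  if (length(shallow)) {
    if (!drop_shallow) {
      abort(sprintf(
        "Sample '%s' has %d reads, fewer than the rarefaction depth %d.",
        shallow[1], totals[shallow[1]], depth
      ))
    }
    warn(sprintf(
      "Dropping %d sample(s) below depth %d: %s.",
      length(shallow), depth, paste(shallow, collapse = ", ")
    ))
    m <- m[, !colnames(m) %in% shallow, drop = FALSE]
    if (ncol(m) == 0L) abort("No sample reaches the rarefaction depth.")
  }
  with_seed_if(seed, {
    for (j in seq_len(ncol(m))) {
      x <- m[, j]
      total <- sum(x)
      if (total == depth) next
      reads <- sample.int(total, depth)            # positions among the reads
      cum <- cumsum(x)
      keep <- tabulate(findInterval(reads, cum + 0.5) + 1L, nbins = length(x))
      m[, j] <- keep
    }
  })
  set_otu_counts(tbl, m)
}

#' Remove singleton OTUs
#'
#' A singleton is an OTU represented by exactly one read across the whole
#' table. Removal is idempotent; the number removed is reported via a
#' message and stored in the `n_removed` attribute.
#'
#' @param tbl An OTU-table tibble.
#' @return The filtered tibble with attribute `n_removed`.
#' @export
remove_singletons <- function(tbl) {
  tbl <- otu_table(tbl)
  totals <- rowSums(otu_counts(tbl))
  keep <- totals != 1
  out <- tbl[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  inform(sprintf(
    "remove_singletons: %d OTUs in, %d singletons removed, %d kept.",
    nrow(tbl), n_removed, nrow(out)
  ))
  attr(out, "n_removed") <- n_removed
  out
}

#' Convert counts to within-sample relative abundances
#'
#' @param tbl An OTU-table tibble; every sample total must be positive.
#' @return A tibble of the same shape whose sample columns are fractions
#'   summing to 1.
#' @export
relative_abundance <- function(tbl) {
  tbl <- otu_table(tbl)
  m <- otu_counts(tbl)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf("Sample '%s' has zero total count.", colnames(m)[totals == 0][1]))
  }
  set_otu_counts_raw(tbl, sweep(m, 2L, totals, "/"))
}

# like set_otu_counts but without integer validation (fractions)
set_otu_counts_raw <- function(tbl, m) {
  out <- tibble(otu_id = rownames(m))
  if ("taxonomy" %in% names(tbl)) {
    out$taxonomy <- tbl$taxonomy[match(out$otu_id, tbl$otu_id)]
  }
  dplyr::bind_cols(out, as_tibble(m))
}

#' Keep the n most abundant OTUs
#'
#' Abundance is the total count across all samples; ties at the boundary are
#' broken lexicographically on OTU id (and reported via a message).
#'
#' @param tbl An OTU-table tibble.
#' @param n Number of OTUs to keep (>= 1).
#' @return The subset table, in decreasing-abundance order.
#' @export
top_n_otus <- function(tbl, n) {
  tbl <- otu_table(tbl)
  assert_scalar_number(n, "n", lower = 1)
  n <- as.integer(n)
  if (n > nrow(tbl)) {
    warn(sprintf("n = %d exceeds the %d OTUs present; returning the full table.", n, nrow(tbl)))
    return(tbl)
  }
  totals <- rowSums(otu_counts(tbl))
  ord <- order(-totals, tbl$otu_id)
  boundary <- totals[ord][n]
  if (sum(totals == boundary) > 1 && n < nrow(tbl) && totals[ord][n + 1L] == boundary) {
    inform(sprintf(
      "top_n_otus: tie at the boundary (total %s) broken lexicographically on OTU id.",
      format(boundary)
    ))
  }
  tbl[ord[seq_len(n)], , drop = FALSE]
}

#' Filter OTUs by prevalence across samples
#'
#' Keeps OTUs with a nonzero count in strictly more than `min_fraction` of
#' the samples. The integer occupancy threshold is the smallest `k` with
#' `k / n_samples > min_fraction` (e.g. 84 of 88 samples at
#' `min_fraction = 0.95`).
#'
#' @param tbl An OTU-table tibble.
#' @param min_fraction Prevalence fraction in (0, 1).
#' @return The filtered tibble, with the integer threshold in attribute
#'   `prevalence_threshold`.
#' @export
prevalence_filter <- function(tbl, min_fraction) {
  tbl <- otu_table(tbl)
  assert_scalar_number(min_fraction, "min_fraction")
  if (min_fraction <= 0 || min_fraction >= 1) abort("`min_fraction` must lie strictly between 0 and 1.")
  m <- otu_counts(tbl)
  k <- prevalence_threshold(min_fraction, ncol(m))
  occupancy <- rowSums(m > 0)
  out <- tbl[occupancy >= k, , drop = FALSE]
  inform(sprintf(
    "prevalence_filter: threshold %d of %d samples; %d OTUs in, %d kept.",
    k, ncol(m), nrow(tbl), nrow(out)
  ))
  attr(out, "prevalence_threshold") <- k
  out
}

#' @param n_samples Number of samples the fraction refers to.
#' @rdname prevalence_filter
#' @export
prevalence_threshold <- function(min_fraction, n_samples) {
  as.integer(floor(min_fraction * n_samples) + 1L)
}

#' Aggregate a relative-abundance table to display taxa
#'
#' OTUs are summed by their lineage at `rank` (1-based position in the
#' semicolon-delimited taxonomy string; missing ranks map to
#' `"unclassified"`). Taxa whose maximum per-sample fraction is below
#' `min_any_sample` are pooled into `"other"`, so column sums remain 1.
#'
#' @param rel A relative-abundance tibble with a `taxonomy` column (from
#'   [relative_abundance()]).
#' @param rank Integer rank position to aggregate at.
#' @param min_any_sample Display threshold on the maximum per-sample
#'   fraction (default 0.05).
#' @return A tibble with columns `taxon` plus one column per sample.
#' @export
aggregate_display_taxa <- function(rel, rank, min_any_sample = 0.05) {
  rel <- as_tibble(rel)
  if (!"taxonomy" %in% names(rel)) abort("`rel` must carry a `taxonomy` column.")
  assert_scalar_number(rank, "rank", lower = 1)
  samples <- otu_sample_ids(rel)
  taxon <- vapply(strsplit(ifelse(is.na(rel$taxonomy), "", rel$taxonomy), ";"), function(parts) {
    parts <- trimws(parts)
    if (length(parts) >= rank && nzchar(parts[rank])) parts[rank] else "unclassified"
  }, character(1))
  m <- as.matrix(rel[, samples, drop = FALSE])
  agg <- rowsum(m, taxon)
  show <- apply(agg, 1L, max) >= min_any_sample
  if (!all(show)) {
    other <- colSums(agg[!show, , drop = FALSE])
    agg <- agg[show, , drop = FALSE]
    agg <- rbind(agg, other = other)
  }
  out <- tibble(taxon = rownames(agg))
  dplyr::bind_cols(out, as_tibble(agg))
}

#' Per-sample share of one OTU's grand total
#'
#' For a chosen OTU, divides its count in each sample by its total count
#' across all samples, giving each sample's share of that OTU (the shares
#' sum to 1 across samples). This is the dependent variable of the
#' indicator-OTU regression scan.
#'
#' @param tbl An OTU-table tibble.
#' @param otu_id The OTU identifier.
#' @return A tibble with columns `sample_id` and `share`.
#' @examples
#' tbl <- otu_table(tibble::tibble(otu_id = "v", S1 = 100, S2 = 900))
#' otu_percent_of_total(tbl, "v")
#' @export
otu_percent_of_total <- function(tbl, otu_id) {
  tbl <- otu_table(tbl)
  if (!otu_id %in% tbl$otu_id) abort(sprintf("OTU '%s' is not in the table.", otu_id))
  x <- otu_counts(tbl)[otu_id, ]
  total <- sum(x)
  if (total == 0) abort(sprintf("OTU '%s' has grand total 0; shares are undefined.", otu_id))
  tibble(sample_id = names(x), share = unname(x) / total)
}
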