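# Small fixtures built in code, shared across test files.

tiny_table <- function() {
  otu_table(tibble::tibble(
    otu_id = c("otu1", "otu2", "otu3"),
    S1 = c(4, 2, 0), S2 = c(1, 2, 3), S3 = c(5, 0, 5), S4 = c(2, 2, 6)
  ))
}

random_table <- function(n_otu, n_sample, max_count = 20) {
  m <- matrix(sample.int(max_count + 1L, n_otu * n_sample, replace = TRUE) - 1L,
              n_otu, n_sample)
  tbl <- tibble::tibble(otu_id = sprintf("otu%03d", seq_len(n_otu)))
  samples <- tibble::as_tibble(m, .name_repair = ~ sprintf("S%02d", seq_len(n_sample)))
  otu_table(dplyr::bind_cols(tbl, samples))
}

random_dist_matrix <- function(n, labels = paste0("s", seq_len(n))) {
  m <- as.matrix(stats::dist(matrix(stats::runif(n * 3), n, 3)))
  dimnames(m) <- list(labels, labels)
  dist_matrix(m)
}

# a symmetric labelled matrix whose upper triangle holds the given values
symmetric_from_upper <- function(values, n, labels = paste0("s", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- values
  m <- m + t(m)
  m
}

# quiet (no message) variants used where the chatter is irrelevant
quiet_scan <- function(...) suppressMessages(run_scan(...))
quiet_prevalence <- function(...) suppressMessages(prevalence_filter(...))
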