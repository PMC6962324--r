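#' Relative abundance of a taxon from classified read counts
#'
#' @param classified_reads Reads classified to the taxon.
#' @param total_reads Total (post-preprocessing) reads in the sample; must
#'   be positive.
#' @return Percent, `100 * classified_reads / total_reads`. Vectorised.
#' @examples
#' relative_abundance(1000, 8.7e6) # ~0.011 %
#' @export
relative_abundance <- function(classified_reads, total_reads) {
  if (any(total_reads <= 0)) abort("`total_reads` must be > 0")
  if (any(classified_reads > total_reads)) {
    abort("`classified_reads` cannot exceed `total_reads`")
  }
  if (any(classified_reads < 0)) abort("`classified_reads` must be >= 0")
  100 * classified_reads / total_reads
}

#' Estimated fold coverage from classified read counts
#'
#' Naive coverage estimate used to anchor presence thresholds: 1,000 reads
#' of 100 bp on a ~100 kb genome is roughly 1x.
#'
#' @param classified_reads Reads classified to the taxon.
#' @param read_length Read length in bp.
#' @param genome_length Genome length in bp.
#' @return Fold coverage, vectorised.
#' @examples
#' estimate_coverage(1000, 100, 1e5) # 1x
#' @export
estimate_coverage <- function(classified_reads, read_length = 100,
                              genome_length = 97000) {
  if (any(genome_length <= 0)) abort("`genome_length` must be > 0")
  if (any(read_length <= 0)) abort("`read_length` must be > 0")
  classified_reads * read_length / genome_length
}

#' Call presence of a taxon per sample
#'
#' Applies the classified-read presence rule: a sample is positive for the
#' taxon when at least `threshold` reads are classified to it (default
#' 1,000, roughly 1x coverage for 100 bp reads on a ~100 kb genome; use
#' 10,000 for virome-enriched sequencing). Samples with fewer than
#' `min_total_reads` total reads are flagged `excluded` and receive no call.
#'
#' @param counts A data frame of per-sample classified read counts with
#'   columns `sample_id`, `total_reads`, `taxon`, `classified_reads` and any
#'   metadata columns (`subject`, `family`, `role`, `day`), e.g. from
#'   [simulate_cohort()] or [read_read_counts()].
#' @param taxon Taxon to call. Samples with no row for the taxon count 0.
#' @param threshold Minimum classified reads for presence (>= 1).
#' @param min_total_reads Sample-level depth filter applied before calling.
#' @param read_length,genome_length Passed to [estimate_coverage()].
#' @return A tibble, one row per sample: metadata plus `classified_reads`,
#'   `threshold`, `excluded`, `present`, `relative_abundance` (percent),
#'   `est_coverage` (fold).
#' @export
call_presence <- function(counts, taxon, threshold = 1000,
                          min_total_reads = 10000, read_length = 100,
                          genome_length = 97000) {
  threshold <- assert_count(threshold, "threshold", min = 1)
  need <- c("sample_id", "total_reads", "taxon", "classified_reads")
  if (!all(need %in% names(counts))) {
    abort(paste("`counts` must have columns", paste(need, collapse = ", ")))
  }
  meta_cols <- intersect(c("subject", "family", "role", "day"), names(counts))
  base <- counts |>
    select(dplyr::all_of(c("sample_id", "total_reads", meta_cols))) |>
    dplyr::distinct(.data$sample_id, .keep_all = TRUE)
  hits <- counts |>
    filter(.data$taxon == !!taxon) |>
    select("sample_id", "classified_reads")
  base |>
    left_join(hits, by = "sample_id") |>
    mutate(
      taxon = !!taxon,
      classified_reads = dplyr::coalesce(.data$classified_reads, 0L),
      threshold = threshold,
      excluded = .data$total_reads < min_total_reads,
      present = !.data$excluded & .data$classified_reads >= threshold,
      relative_abundance = ifelse(
        .data$total_reads > 0,
        100 * .data$classified_reads / .data$total_reads, NA_real_),
      est_coverage = estimate_coverage(.data$classified_reads, read_length,
                                       genome_length)
    ) |>
    as_tibble()
}

#' Per-group prevalence from presence calls
#'
#' A subject counts as positive when at least one of its non-excluded
#' samples is positive; prevalence is the fraction of such subjects per
#' group (role by default).
#'
#' @param calls Output of [call_presence()] with `subject` and `role`.
#' @param group Column to group subjects by (default `role`).
#' @return A tibble with `group`, `n_subjects`, `n_positive`, `prevalence`.
#' @export
prevalence_table <- function(calls, group = "role") {
  if (!nrow(calls)) {
    return(tibble(group = character(), n_subjects = integer(),
                  n_positive = integer(), prevalence = double()))
  }
  if (length(unique(calls$taxon)) > 1) {
    abort("presence calls must share one taxon")
  }
  calls |>
    filter(!.data$excluded) |>
    group_by(group = .data[[group]], .data$subject) |>
    summarise(pos = any(.data$present), .groups = "drop") |>
    group_by(.data$group) |>
    summarise(n_subjects = n(), n_positive = sum(.data$pos),
              prevalence = mean(.data$pos), .groups = "drop")
}

#' Per-subject presence timeline
#'
#' Orders each subject's presence calls by collection day, the layout used
#' for longitudinal detection plots (e.g. FMT recipients pre/post
#' transplant).
#'
#' @param calls Output of [call_presence()] with `subject` and `day`.
#' @return A tibble ordered by subject then day with a `timepoint` index.
#' @export
presence_timeline <- function(calls) {
  calls |>
    filter(!.data$excluded) |>
    arrange(.data$subject, .data$day) |>
    group_by(.data$subject) |>
    mutate(timepoint = row_number()) |>
    ungroup() |>
    select(dplyr::any_of(c("subject", "family", "role", "day", "timepoint",
                           "sample_id", "present", "classified_reads",
                           "relative_abundance", "est_coverage")))
}
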