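#' F_multi: coverage-normalised multiallelic site fraction
#'
#' At a minor allele fraction threshold `x`, `F_multi` is the proportion of
#' multiallelic sites with minor AF > `x` among genome positions covered
#' well enough that a minor allele at fraction `x` would be detectable
#' (depth >= `ceiling(min_allele_reads / x)`, see [detectable_sites()]).
#' The normalisation makes samples with highly variable coverage
#' comparable.
#'
#' @param variants A `variant_set` from [call_variants()].
#' @param x Minor AF thresholds; the default grid is
#'   `c(0.40, 0.30, 0.20, 0.10)`.
#' @param min_allele_reads Allele support threshold used by the
#'   detectability rule (defaults to the one the variant set was called
#'   with).
#' @return A tibble with one row per threshold: `sample_id`, `x`,
#'   `numerator`, `denominator`, `value` and `undefined` (TRUE when no
#'   position is detectable at `x`, in which case `value` is `NA`).
#' @examples
#' g <- generate_genome(500, seed = 1)
#' pop <- simulate_population(g, 2, divergence = 0.01, seed = 2)
#' vs <- call_variants(simulate_pileup(pop, 200, seed = 3), g)
#' f_multi(vs)
#' @export
f_multi <- function(variants, x = c(0.40, 0.30, 0.20, 0.10),
                    min_allele_reads = NULL) {
  stopifnot(inherits(variants, "variant_set"))
  m <- min_allele_reads %||% variants$min_allele_reads
  multi <- filter(variants$calls, .data$status == "multiallelic")
  purrr::map_dfr(x, function(xi) {
    mask <- detectable_sites(variants, xi, m)
    denom <- sum(mask)
    numer <- sum(multi$minor_af > xi & mask[multi$pos + 1L])
    tibble(sample_id = variants$sample_id, x = xi,
           numerator = numer, denominator = denom,
           value = if (denom > 0) numer / denom else NA_real_,
           undefined = denom == 0)
  })
}

#' Multiallelic site density per kb and percent of genome
#'
#' Re-expresses [f_multi()] as sites per kilobase of detectable genome and
#' as a percentage of detectable positions
#' (`density = 1000 * numerator / denominator`,
#' `percent = 100 * numerator / denominator = density / 10`).
#'
#' @inheritParams f_multi
#' @param x Minor AF threshold (default 0.1, the genome-wide summary value).
#' @return A tibble: `sample_id`, `x`, `numerator`, `denominator`,
#'   `density` (sites/kb), `percent`.
#' @export
sites_per_kb <- function(variants, x = 0.10, min_allele_reads = NULL) {
  fm <- f_multi(variants, x = x, min_allele_reads = min_allele_reads)
  if (any(fm$undefined)) abort("no detectable positions at this threshold")
  fm |>
    mutate(density = 1000 * .data$value, percent = 100 * .data$value) |>
    select("sample_id", "x", "numerator", "denominator", "density", "percent")
}

#' Compare a diversity statistic between two groups
#'
#' Two-sided Wilcoxon rank-sum test, the comparison used for mother-vs-
#' infant F_multi at each AF threshold. Exact p-values are used for small
#' groups without ties (both n <= 20); otherwise the normal approximation
#' with tie correction. No multiple-testing correction is applied.
#'
#' @param data A data frame with one value per sample.
#' @param value Name of the value column.
#' @param group Name of the grouping column (exactly two groups).
#' @return A one-row tibble: `group1`, `group2`, `n1`, `n2`, `statistic`
#'   (rank-sum W), `p.value`, `method`.
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 3), v = c(1, 2, 3, 10, 11, 12))
#' group_compare(d, "v", "g") # exact two-sided p = 0.1
#' @export
group_compare <- function(data, value, group) {
  v <- data[[value]]
  g <- data[[group]]
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- as.character(g[keep])
  lev <- sort(unique(g))
  if (length(lev) != 2) abort("`group` must have exactly two levels")
  x <- v[g == lev[1]]
  y <- v[g == lev[2]]
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  exact <- length(x) <= 20 && length(y) <= 20 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  tibble(group1 = lev[1], group2 = lev[2], n1 = length(x), n2 = length(y),
         statistic = unname(wt$statistic), p.value = min(1, wt$p.value),
         method = if (exact) "wilcoxon_exact" else "wilcoxon_normal_ties")
}

# Infant's fixed base at given 0-based positions, or NA when the infant is
# not fixed/covered there.
fixed_base_at <- function(variants, pos) {
  ref_fixed <- variants$depth[pos + 1L] >= variants$min_depth
  out <- rep(NA_character_, length(pos))
  calls <- variants$calls
  hit <- match(pos, calls$pos)
  # positions with any non-ref call: fixed_alt -> its allele; multiallelic
  # or flagged -> not fixed.
  is_alt <- !is.na(hit) & calls$status[hit] == "fixed_alt"
  is_multi <- !is.na(hit) & calls$status[hit] == "multiallelic"
  is_uncalled <- pos %in% variants$uncalled
  plain_ref <- ref_fixed & is.na(hit) & !is_uncalled
  out[plain_ref] <- "ref"
  out[is_alt & ref_fixed] <- calls$allele1[hit[is_alt & ref_fixed]]
  out[is_multi] <- NA_character_
  out
}

#' Mother-to-infant allele sharing at maternal multiallelic sites
#'
#' For every maternal multiallelic site at which the infant is fixed and
#' covered >= 10x, classifies which maternal allele the infant carries:
#' `major_detected`, `minor_detected`, or `neither` (an allele absent in
#' the mother, e.g. a post-acquisition mutation). The accompanying test
#' compares the maternal allele fractions of infant-detected vs
#' non-detected alleles by a two-sided rank-sum test; disproportionate
#' detection of maternal major alleles indicates that the dominant maternal
#' strain founded the infant population. The analysis is only attempted
#' when the mother has at least `min_mother_sites` multiallelic sites.
#'
#' @param mother,infant `variant_set` objects called against the same
#'   reference.
#' @param min_mother_sites Minimum maternal multiallelic sites (default 10).
#' @return An `allele_sharing` object: list with `records` (one row per
#'   informative site: `pos`, maternal alleles/AFs, `infant_allele`,
#'   `transmitted_class`), `test` (rank-sum comparison of maternal AFs of
#'   detected vs non-detected alleles, `NULL` when degenerate), `skipped`
#'   and `reason`. `tidy()` returns the records.
#' @export
allele_sharing <- function(mother, infant, min_mother_sites = 10) {
  stopifnot(inherits(mother, "variant_set"), inherits(infant, "variant_set"))
  if (mother$reference_id != infant$reference_id ||
      mother$L != infant$L) {
    abort("mother and infant must be called against the same reference")
  }
  msites <- filter(mother$calls, .data$status == "multiallelic")
  if (nrow(msites) < min_mother_sites) {
    return(structure(list(records = empty_sharing_records(), test = NULL,
                          skipped = TRUE,
                          reason = sprintf(
                            "mother has %d multiallelic site(s); need >= %d",
                            nrow(msites), min_mother_sites)),
                     class = "allele_sharing"))
  }
  inf_base <- fixed_base_at(infant, msites$pos)
  idx_ref <- which(!is.na(inf_base) & inf_base == "ref")
  inf_base[idx_ref] <- msites$ref[idx_ref]
  keep <- !is.na(inf_base)
  msites <- msites[keep, ]
  inf_base <- inf_base[keep]
  major_af <- 1 - msites$minor_af
  records <- tibble(
    pos = msites$pos,
    mother_major = msites$allele1, mother_major_af = major_af,
    mother_minor = msites$allele2, mother_minor_af = msites$minor_af,
    infant_allele = inf_base,
    transmitted_class = dplyr::case_when(
      inf_base == msites$allele1 ~ "major_detected",
      inf_base == msites$allele2 ~ "minor_detected",
      TRUE ~ "neither"
    )
  )
  # AFs of detected vs non-detected maternal alleles (two per site).
  af_long <- bind_rows(
    tibble(af = records$mother_major_af,
           detected = records$infant_allele == records$mother_major),
    tibble(af = records$mother_minor_af,
           detected = records$infant_allele == records$mother_minor)
  )
  test <- if (nrow(records) && length(unique(af_long$detected)) == 2) {
    group_compare(mutate(af_long, grp = ifelse(.data$detected, "detected",
                                               "not_detected")),
                  "af", "grp")
  } else NULL
  structure(list(records = records, test = test, skipped = FALSE,
                 reason = NA_character_),
            class = "allele_sharing")
}

empty_sharing_records <- function() {
  tibble(pos = integer(), mother_major = character(),
         mother_major_af = double(), mother_minor = character(),
         mother_minor_af = double(), infant_allele = character(),
         transmitted_class = character())
}

#' @export
print.allele_sharing <- function(x, ...) {
  if (x$skipped) {
    cat("<allele_sharing> skipped:", x$reason, "\n")
  } else {
    tab <- table(x$records$transmitted_class)
    cat(sprintf("<allele_sharing> %d informative site(s): %s\n",
                nrow(x$records),
                paste(names(tab), tab, sep = "=", collapse = ", ")))
    if (!is.null(x$test)) {
      cat(sprintf("  rank-sum p (detected vs not) = %.3g\n", x$test$p.value))
    }
  }
  invisible(x)
}

#' @export
tidy.allele_sharing <- function(x, ...) x$records

#' @export
glance.allele_sharing <- function(x, ...) {
  tibble(
    n_sites = nrow(x$records),
    n_major = sum(x$records$transmitted_class == "major_detected"),
    n_minor = sum(x$records$transmitted_class == "minor_detected"),
    n_neither = sum(x$records$transmitted_class == "neither"),
    p.value = if (is.null(x$test)) NA_real_ else x$test$p.value,
    skipped = x$skipped
  )
}

#' Longitudinal F_multi trajectory for one subject
#'
#' Orders a subject's samples by collection day and reports F_multi and
#' multiallelic site counts at each AF threshold per timepoint, flagging
#' timepoints whose detectability denominator differs materially (by more
#' than a factor of 2) from the subject's median, where F_multi values are
#' not directly comparable. A per-threshold least-squares slope of F_multi
#' on day summarises the trend.
#'
#' @param variant_sets List of `variant_set` objects for one subject.
#' @param days Numeric collection days, parallel to `variant_sets`.
#' @param x AF thresholds (default grid).
#' @return A tibble: `day`, `timepoint`, `x`, `numerator`, `denominator`,
#'   `value`, `denominator_flagged`, `slope` (per threshold, repeated).
#' @export
longitudinal_summary <- function(variant_sets, days,
                                 x = c(0.40, 0.30, 0.20, 0.10)) {
  if (length(variant_sets) != length(days)) {
    abort("`variant_sets` and `days` must have the same length")
  }
  if (!length(variant_sets)) abort("need at least one sample")
  ord <- order(days)
  fm <- purrr::map_dfr(seq_along(ord), function(k) {
    i <- ord[k]
    f_multi(variant_sets[[i]], x = x) |>
      mutate(day = days[i], timepoint = k)
  })
  fm |>
    group_by(.data$x) |>
    mutate(
      denominator_flagged = .data$denominator <
        median(.data$denominator) / 2 |
        .data$denominator > median(.data$denominator) * 2,
      slope = if (dplyr::n_distinct(.data$day) > 1 && !all(is.na(.data$value)))
        unname(coef(lm(value ~ day))[2]) else NA_real_
    ) |>
    ungroup() |>
    select("sample_id", "day", "timepoint", "x", "numerator", "denominator",
           "value", "undefined", "denominator_flagged", "slope")
}

#' Pick the analysis sample for a subject with repeat samples
#'
#' When a mother has multiple samples, diversity analyses use the one with
#' the highest estimated phage coverage.
#'
#' @param variant_sets List of `variant_set` objects.
#' @return The index of the sample with the highest mean depth.
#' @export
select_best_sample <- function(variant_sets) {
  if (!length(variant_sets)) abort("no samples supplied")
  which.max(vapply(variant_sets, function(v) mean(v$depth), numeric(1)))
}
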