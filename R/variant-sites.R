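#' Call the allele status of a single site
#'
#' Implements the pileup site-calling rule used throughout the package:
#' a site is `uncovered` below `min_depth` total depth (default 10x);
#' alleles require at least `min_allele_reads` supporting reads (default 5)
#' to be called; one qualifying allele gives a fixed call (`fixed_ref` or
#' `fixed_alt`); two qualifying alleles give a `multiallelic` call with
#' `minor_af` computed from the two called alleles' counts only. Sites with
#' three or more qualifying alleles are recorded as multiallelic using the
#' top two alleles by count (ties break by base order A<C<G<T) and flagged
#' in `extra_alleles`. A covered site where no allele reaches
#' `min_allele_reads` has no callable allele and is reported `uncovered`.
#'
#' @param counts Named or ordered numeric vector of A, C, G, T read counts.
#' @param ref_base Reference base at the site.
#' @param min_depth Minimum total depth for any call.
#' @param min_allele_reads Minimum reads supporting a called allele.
#' @return A one-row tibble: `ref`, `depth`, `status`, `allele1`, `allele2`,
#'   `count1`, `count2`, `minor_af`, `extra_alleles`.
#' @examples
#' call_site(c(A = 6, C = 0, G = 5, T = 0), "A") # multiallelic, AF 5/11
#' call_site(c(A = 9, C = 0, G = 4, T = 0), "A") # fixed_ref
#' @export
call_site <- function(counts, ref_base, min_depth = 10, min_allele_reads = 5) {
  if (length(counts) != 4 || any(counts < 0)) {
    abort("`counts` must be 4 non-negative values (A, C, G, T)")
  }
  if (!is.null(names(counts)) && setequal(names(counts), BASES)) {
    counts <- counts[BASES]
  }
  counts <- as.integer(counts)
  pu <- new_site_pileup("site", matrix(counts, nrow = 1), "ref")
  vs <- call_variants_matrix(pu$counts, ref_base, min_depth, min_allele_reads)
  tibble(ref = ref_base, depth = sum(counts), status = vs$status,
         allele1 = vs$allele1, allele2 = vs$allele2,
         count1 = vs$count1, count2 = vs$count2,
         minor_af = vs$minor_af, extra_alleles = vs$extra_alleles)
}

# Vectorised core caller over an L x 4 counts matrix. Returns parallel
# vectors (length L) of status and called-allele details.
call_variants_matrix <- function(counts, ref_chars, min_depth,
                                 min_allele_reads) {
  L <- nrow(counts)
  depth <- rowSums(counts)
  qual <- counts >= min_allele_reads
  n_qual <- rowSums(qual)

  # Top two alleles by count; ties break by base order A<C<G<T, which is
  # the column order, and max.col(ties.method = "first") respects it.
  first <- max.col(counts, ties.method = "first")
  c1 <- counts[cbind(seq_len(L), first)]
  masked <- counts
  masked[cbind(seq_len(L), first)] <- -1L
  second <- max.col(masked, ties.method = "first")
  c2 <- counts[cbind(seq_len(L), second)]

  status <- rep("uncovered", L)
  covered <- depth >= min_depth
  is_multi <- covered & n_qual >= 2
  is_fixed <- covered & n_qual == 1
  # The single qualifying allele of a fixed site.
  fix_idx <- max.col(qual, ties.method = "first")
  fixed_base <- BASES[fix_idx]
  status[is_fixed & fixed_base == ref_chars] <- "fixed_ref"
  status[is_fixed & fixed_base != ref_chars] <- "fixed_alt"
  status[is_multi] <- "multiallelic"

  allele1 <- rep(NA_character_, L)
  allele2 <- rep(NA_character_, L)
  count1 <- rep(NA_integer_, L)
  count2 <- rep(NA_integer_, L)
  minor_af <- rep(0, L)

  allele1[is_fixed] <- fixed_base[is_fixed]
  count1[is_fixed] <- counts[cbind(which(is_fixed), fix_idx[is_fixed])]

  if (any(is_multi)) {
    i <- which(is_multi)
    allele1[i] <- BASES[first[i]]
    allele2[i] <- BASES[second[i]]
    count1[i] <- c1[i]
    count2[i] <- c2[i]
    minor_af[i] <- c2[i] / (c1[i] + c2[i])
  }

  list(depth = as.integer(depth), status = status, allele1 = allele1,
       allele2 = allele2, count1 = count1, count2 = count2,
       minor_af = minor_af, extra_alleles = n_qual >= 3,
       uncalled = covered & n_qual == 0)
}

#' Call fixed SNPs and multiallelic sites across a pileup
#'
#' Applies [call_site()] at every genome position against the reference and
#' collects the non-reference calls, the depth profile (for detectability
#' masks and co-coverage), and covered-but-uncallable positions.
#'
#' @param pileup A `site_pileup` (see [simulate_pileup()], [read_pileup()]).
#' @param reference The `phage_genome` the pileup was built against; its
#'   length must equal the pileup length.
#' @param min_depth,min_allele_reads Site-calling thresholds (10x depth,
#'   5 reads per allele by default).
#' @return A `variant_set`: list with `sample_id`, `calls` (tibble of
#'   fixed_alt and multiallelic sites with 0-based `pos`), `depth` (integer
#'   vector length L), `uncalled` (positions covered but with no qualifying
#'   allele), `L`, `reference_id`, and the thresholds used.
#' @examples
#' g <- generate_genome(500, seed = 1)
#' pop <- simulate_population(g, 2, divergence = 0.01, seed = 2)
#' pu <- simulate_pileup(pop, 100, error_rate = 0, seed = 3)
#' vs <- call_variants(pu, g)
#' head(tidy(vs))
#' @export
call_variants <- function(pileup, reference, min_depth = 10,
                          min_allele_reads = 5) {
  stopifnot(inherits(pileup, "site_pileup"),
            inherits(reference, "phage_genome"))
  if (nrow(pileup$counts) != reference$length) {
    abort(sprintf("pileup has %d positions but reference %s has %d",
                  nrow(pileup$counts), reference$id, reference$length))
  }
  ref_chars <- seq_chars(reference$sequence)
  v <- call_variants_matrix(pileup$counts, ref_chars, min_depth,
                            min_allele_reads)
  keep <- which(v$status %in% c("fixed_alt", "multiallelic"))
  calls <- tibble(
    pos = keep - 1L,
    ref = ref_chars[keep],
    status = v$status[keep],
    allele1 = v$allele1[keep],
    allele2 = v$allele2[keep],
    count1 = v$count1[keep],
    count2 = v$count2[keep],
    depth = v$depth[keep],
    minor_af = v$minor_af[keep],
    extra_alleles = v$extra_alleles[keep]
  )
  structure(
    list(sample_id = pileup$sample_id, calls = calls, depth = v$depth,
         uncalled = which(v$uncalled) - 1L, L = reference$length,
         reference_id = reference$id, min_depth = min_depth,
         min_allele_reads = min_allele_reads),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf(
    "<variant_set> %s vs %s: %d fixed SNP(s), %d multiallelic site(s), %0.1f%% of %d bp covered >=%dx\n",
    x$sample_id, x$reference_id, sum(x$calls$status == "fixed_alt"),
    sum(x$calls$status == "multiallelic"),
    100 * mean(x$depth >= x$min_depth), x$L, x$min_depth))
  invisible(x)
}

#' @export
tidy.variant_set <- function(x, ...) {
  mutate(x$calls, sample_id = x$sample_id, .before = 1)
}

#' @export
glance.variant_set <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    n_fixed = sum(x$calls$status == "fixed_alt"),
    n_multiallelic = sum(x$calls$status == "multiallelic"),
    frac_covered = mean(x$depth >= x$min_depth),
    mean_depth = mean(x$depth),
    L = x$L
  )
}

#' Detectability mask for a minor allele fraction
#'
#' A site can reveal a minor allele at fraction `x` only when its depth is
#' high enough that the expected minor-allele reads reach the allele support
#' threshold: `depth >= ceiling(min_allele_reads / x)`. This is the
#' denominator rule behind [f_multi()].
#'
#' @param variants A `variant_set`.
#' @param x Minor allele fraction in (0, 0.5).
#' @param min_allele_reads Allele support threshold (default taken from the
#'   variant set).
#' @return Logical vector of length L.
#' @export
detectable_sites <- function(variants, x, min_allele_reads = NULL) {
  assert_fraction(x, "x")
  if (x >= 0.5) abort("`x` must be < 0.5")
  m <- min_allele_reads %||% variants$min_allele_reads
  variants$depth >= ceiling(m / x)
}

# Expand a variant_set's calls into one row per non-reference allele
# (multiallelic sites can contribute one or two alt alleles).
variant_alleles <- function(variants, scope = c("all", "fixed",
                                                "multiallelic"),
                            min_af = 0) {
  scope <- match.arg(scope)
  calls <- variants$calls
  if (scope == "fixed") calls <- filter(calls, .data$status == "fixed_alt")
  if (scope == "multiallelic") {
    calls <- filter(calls, .data$status == "multiallelic",
                    .data$minor_af > min_af)
  } else if (min_af > 0) {
    calls <- filter(calls, .data$status == "fixed_alt" |
                      .data$minor_af > min_af)
  }
  if (!nrow(calls)) {
    return(tibble(pos = integer(), ref = character(), alt = character(),
                  status = character(), minor_af = double()))
  }
  long <- tidyr::pivot_longer(calls, c("allele1", "allele2"),
                              values_to = "alt", names_to = NULL)
  long |>
    filter(!is.na(.data$alt), .data$alt != .data$ref) |>
    select("pos", "ref", "alt", "status", "minor_af")
}

#' Transition/transversion ratio of a variant set
#'
#' Counts each non-reference called allele (fixed alternate alleles and the
#' non-reference alleles of multiallelic sites) as one substitution and
#' returns transitions (A<->G, C<->T) over transversions. With no
#' transversions the ratio is undefined and returned as `NA` with
#' `undefined = TRUE` rather than infinity.
#'
#' @param variants A `variant_set`, or a list of them to pool.
#' @param scope Which variants to count: `"all"`, `"fixed"` or
#'   `"multiallelic"`.
#' @param min_af For multiallelic alleles, count only sites with
#'   `minor_af > min_af` (default 0; the genome-wide summaries use 0.1).
#' @return A one-row tibble: `transitions`, `transversions`, `ts_tv`,
#'   `undefined`.
#' @export
ts_tv <- function(variants, scope = c("all", "fixed", "multiallelic"),
                  min_af = 0) {
  scope <- match.arg(scope)
  sets <- if (inherits(variants, "variant_set")) list(variants) else variants
  alle <- bind_rows(lapply(sets, variant_alleles, scope = scope,
                           min_af = min_af))
  if (!nrow(alle)) abort("no variants in scope; Ts/Tv needs >= 1 variant")
  ts <- sum(is_transition(alle$ref, alle$alt))
  tv <- nrow(alle) - ts
  tibble(transitions = ts, transversions = tv,
         ts_tv = if (tv == 0) NA_real_ else ts / tv,
         undefined = tv == 0)
}
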