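EFFECT_LEVELS <- c("synonymous", "nonsynonymous", "nonsense", "noncoding")
# severity order for sites falling in overlapping genes
EFFECT_SEVERITY <- c(noncoding = 0, synonymous = 1, nonsynonymous = 2,
                     nonsense = 3)

#' Predict the coding effect of single-base substitutions
#'
#' Classifies each substitution as `synonymous`, `nonsynonymous`,
#' `nonsense` (alternate codon is a stop, reference codon is not) or
#' `noncoding` (outside every gene), translating codons with the standard
#' genetic code and handling minus-strand genes by reverse complement.
#' Stop-loss and start-codon changes that alter the amino acid classify as
#' nonsynonymous. A substitution inside overlapping genes takes the most
#' severe category (nonsense > nonsynonymous > synonymous).
#'
#' @param sites A data frame with 0-based `pos` and `alt` columns (`ref` is
#'   optional and checked against the genome when present).
#' @param annotation Gene annotation tibble (see [generate_annotation()]).
#' @param genome A `phage_genome`.
#' @return A tibble, one row per input substitution: `pos`, `ref`, `alt`,
#'   `gene_id`, `strand`, `category`, `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`. Substitutions in overlapping genes report the gene giving
#'   the most severe category.
#' @examples
#' g <- new_phage_genome("toy", "ATGAAATAA")
#' ann <- tibble::tibble(gene_id = "g1", start = 0L, end = 9L,
#'                       strand = "+", product = "toy")
#' predict_effect(tibble::tibble(pos = 5L, alt = "G"), ann, g)
#' @export
predict_effect <- function(sites, annotation, genome) {
  stopifnot(inherits(genome, "phage_genome"))
  validate_annotation(annotation, genome)
  chars <- seq_chars(genome$sequence)
  L <- genome$length
  if (any(sites$pos < 0 | sites$pos >= L)) abort("site position out of range")
  ref <- chars[sites$pos + 1L]
  if ("ref" %in% names(sites) && any(!is.na(sites$ref) & sites$ref != ref)) {
    abort("`ref` column disagrees with the genome sequence")
  }
  if (any(sites$alt == ref)) abort("`alt` must differ from the reference base")

  out <- tibble(
    idx = seq_len(nrow(sites)), pos = as.integer(sites$pos), ref = ref,
    alt = sites$alt, gene_id = NA_character_, strand = NA_character_,
    category = "noncoding", ref_codon = NA_character_,
    alt_codon = NA_character_, ref_aa = NA_character_,
    alt_aa = NA_character_
  )
  code <- Biostrings::GENETIC_CODE
  for (gi in seq_len(nrow(annotation))) {
    gstart <- annotation$start[gi]
    gend <- annotation$end[gi]
    hit <- which(out$pos >= gstart & out$pos < gend)
    if (!length(hit)) next
    p <- out$pos[hit]
    if (annotation$strand[gi] == "+") {
      off <- (p - gstart) %% 3L
      cs <- p - off  # codon start (0-based)
      rc <- paste0(chars[cs + 1L], chars[cs + 2L], chars[cs + 3L])
      ac <- rc
      substr(ac, off + 1L, off + 1L) <- out$alt[hit]
    } else {
      off <- (gend - 1L - p) %% 3L
      hi <- p + off  # highest genome position of the codon
      rc <- paste0(COMPLEMENT[chars[hi + 1L]], COMPLEMENT[chars[hi]],
                   COMPLEMENT[chars[hi - 1L]])
      ac <- rc
      substr(ac, off + 1L, off + 1L) <- COMPLEMENT[out$alt[hit]]
    }
    raa <- unname(code[rc])
    aaa <- unname(code[ac])
    cat_g <- ifelse(raa == aaa, "synonymous",
                    ifelse(aaa == "*" & raa != "*", "nonsense",
                           "nonsynonymous"))
    better <- EFFECT_SEVERITY[cat_g] > EFFECT_SEVERITY[out$category[hit]]
    upd <- hit[better]
    if (length(upd)) {
      sel <- which(better)
      out$gene_id[upd] <- annotation$gene_id[gi]
      out$strand[upd] <- annotation$strand[gi]
      out$category[upd] <- cat_g[sel]
      out$ref_codon[upd] <- rc[sel]
      out$alt_codon[upd] <- ac[sel]
      out$ref_aa[upd] <- raa[sel]
      out$alt_aa[upd] <- aaa[sel]
    }
  }
  select(out, -"idx")
}

#' Null distribution of effects under equal-probability mutation
#'
#' Enumerates all `3L` single-base substitutions of the genome (each DNA
#' change at each position equally likely), classifies each with
#' [predict_effect()], and returns category counts and proportions. This is
#' the background against which observed multiallelic-site effect
#' distributions are tested.
#'
#' @inheritParams predict_effect
#' @return An `effect_distribution` tibble: `category`, `count`,
#'   `proportion` (summing to 1), with the total number of changes in
#'   attribute `n`.
#' @export
null_effect_distribution <- function(genome, annotation) {
  chars <- seq_chars(genome$sequence)
  L <- genome$length
  alt_lookup <- vapply(BASES, function(b) setdiff(BASES, b), character(3))
  alts <- alt_lookup[, match(chars, BASES), drop = FALSE]
  sites <- tibble(pos = rep(seq_len(L) - 1L, each = 3), alt = as.vector(alts))
  eff <- predict_effect(sites, annotation, genome)
  effect_distribution(eff$category)
}

#' Tabulate an effect-category distribution
#'
#' @param categories Character vector of effect categories (or a tibble
#'   with a `category` column).
#' @return An `effect_distribution` tibble: `category`, `count`,
#'   `proportion`.
#' @export
effect_distribution <- function(categories) {
  if (is.data.frame(categories)) categories <- categories$category
  counts <- table(factor(categories, levels = EFFECT_LEVELS))
  out <- tibble(category = EFFECT_LEVELS, count = as.integer(counts),
                proportion = as.numeric(counts) / max(1, sum(counts)))
  class(out) <- c("effect_distribution", class(out))
  attr(out, "n") <- sum(out$count)
  out
}

# log-likelihood helper with the 0*log(0) = 0 convention
xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

g_binomial <- function(o, n, p0) {
  2 * (xlogy(o, o / (n * p0)) + xlogy(n - o, (n - o) / (n * (1 - p0))))
}

#' Likelihood-ratio enrichment test of effect categories against a null
#'
#' Per category, a binomial likelihood-ratio (G) test of the observed count
#' against the null proportion:
#' `G = 2 * (O * log(O / (n * p0)) + (n - O) * log((n - O) / (n * (1 - p0))))`,
#' with p from a chi-square distribution with 1 df and the `0 * log(0) = 0`
#' convention. The overall test is the multinomial G-test with `k - 1` df.
#' Used to ask whether multiallelic sites are depleted of nonsynonymous and
#' nonsense changes relative to equal-probability mutation.
#'
#' @param observed Observed categories: a character vector, a tibble with a
#'   `category` column, or an `effect_distribution`.
#' @param null The null `effect_distribution` (see
#'   [null_effect_distribution()]).
#' @return An `effect_lrt` object; `tidy()` gives the per-category table
#'   (`category`, `observed`, `expected`, `proportion`, `null_proportion`,
#'   `statistic`, `p.value`, `direction`), `glance()` the overall
#'   multinomial test.
#' @export
effect_enrichment_lrt <- function(observed, null) {
  obs <- as_effect_distribution(observed)
  n <- attr(obs, "n")
  if (n < 1) abort("observed effect set is empty")
  tab <- left_join(obs, select(null, "category", null_proportion = "proportion"),
                   by = "category")
  per <- tab |>
    mutate(
      expected = n * .data$null_proportion,
      statistic = ifelse(.data$null_proportion %in% c(0, 1), NA_real_,
                         g_binomial(.data$count, n, .data$null_proportion)),
      p.value = pchisq(.data$statistic, df = 1, lower.tail = FALSE),
      direction = dplyr::case_when(
        .data$count > .data$expected ~ "enriched",
        .data$count < .data$expected ~ "depleted",
        TRUE ~ "none")
    ) |>
    select("category", observed = "count", "expected",
           proportion = "proportion", "null_proportion", "statistic",
           "p.value", "direction")
  keep <- tab$null_proportion > 0
  g_all <- 2 * sum(xlogy(tab$count[keep],
                         tab$count[keep] / (n * tab$null_proportion[keep])))
  df_all <- sum(keep) - 1
  structure(list(per_category = per, n = n,
                 overall = tibble(statistic = g_all, df = df_all,
                                  p.value = pchisq(g_all, df_all,
                                                   lower.tail = FALSE),
                                  n = n, method = "multinomial_g_test")),
            class = "effect_lrt")
}

as_effect_distribution <- function(x) {
  if (inherits(x, "effect_distribution")) x else effect_distribution(x)
}

#' @export
print.effect_lrt <- function(x, ...) {
  cat(sprintf("<effect_lrt> n = %d; overall G = %.3f (df %d), p = %.3g\n",
              x$n, x$overall$statistic, x$overall$df, x$overall$p.value))
  print(x$per_category)
  invisible(x)
}

#' @export
tidy.effect_lrt <- function(x, ...) x$per_category

#' @export
glance.effect_lrt <- function(x, ...) x$overall

#' Compare two observed effect distributions category by category
#'
#' Two-sample binomial likelihood-ratio test per category (e.g. mother vs
#' infant multiallelic sites): the saturated model fits each group's
#' proportion, the null pools them; `G` is twice the log-likelihood
#' difference, 1 df.
#'
#' @param a,b Observed categories in either group (any form accepted by
#'   [effect_distribution()]).
#' @return A tibble per category: counts, proportions, `statistic`,
#'   `p.value`.
#' @export
compare_effect_distributions <- function(a, b) {
  da <- as_effect_distribution(a)
  db <- as_effect_distribution(b)
  na <- attr(da, "n")
  nb <- attr(db, "n")
  if (na < 1 || nb < 1) abort("both observed effect sets must be non-empty")
  ll <- function(o, n, p) xlogy(o, p) + xlogy(n - o, 1 - p)
  purrr::map_dfr(seq_len(nrow(da)), function(i) {
    oa <- da$count[i]
    ob <- db$count[i]
    p_pool <- (oa + ob) / (na + nb)
    g <- 2 * (ll(oa, na, oa / na) + ll(ob, nb, ob / nb) -
                ll(oa, na, p_pool) - ll(ob, nb, p_pool))
    tibble(category = da$category[i], count_a = oa, count_b = ob,
           proportion_a = oa / na, proportion_b = ob / nb,
           statistic = g, p.value = pchisq(g, 1, lower.tail = FALSE))
  })
}

#' Rank genes by length-normalised nonsynonymous variation
#'
#' Counts nonsynonymous multiallelic-site effects per gene, normalises by
#' gene length, and ranks descending (ties break by gene start
#' coordinate). Genes with no sites are included with density 0. Tail
#' genes ranking high by this measure suggest diversifying variation in
#' host-tropism functions.
#'
#' @param effects Effect calls from [predict_effect()] (one row per
#'   multiallelic site).
#' @param annotation Gene annotation tibble.
#' @return A tibble per gene: `gene_id`, `start`, `length_bp`, `n_sites`
#'   (any-category sites in the gene), `n_nonsynonymous`, `ns_per_kb`,
#'   `rank`; attribute `genes_with_sites` counts genes with >= 1 site.
#' @export
gene_ns_ranking <- function(effects, annotation) {
  validate_annotation(annotation)
  per_gene <- effects |>
    filter(!is.na(.data$gene_id)) |>
    group_by(gene_id = .data$gene_id) |>
    summarise(n_sites = n(),
              n_nonsynonymous = sum(.data$category == "nonsynonymous"),
              .groups = "drop")
  out <- annotation |>
    select("gene_id", "start", "end") |>
    left_join(per_gene, by = "gene_id") |>
    mutate(
      length_bp = .data$end - .data$start,
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      n_nonsynonymous = dplyr::coalesce(.data$n_nonsynonymous, 0L),
      ns_per_kb = 1000 * .data$n_nonsynonymous / .data$length_bp
    ) |>
    arrange(desc(.data$ns_per_kb), .data$start) |>
    mutate(rank = row_number()) |>
    select("gene_id", "start", "length_bp", "n_sites", "n_nonsynonymous",
           "ns_per_kb", "rank")
  attr(out, "genes_with_sites") <- sum(out$n_sites > 0)
  out
}
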