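#' Simulate a multi-strain phage population
#'
#' Creates `n_strains` strain haplotypes around a reference genome. Each
#' strain carries `Binomial(L, divergence)` substitutions at uniformly drawn
#' positions; alternate bases are drawn with a transition bias
#' `kappa` (a transition with probability `kappa / (kappa + 1)`, otherwise one
#' of the two transversions uniformly, so the generative Ts/Tv ratio of
#' emitted variants is `kappa`). Relative abundances come from a
#' symmetric Dirichlet with the given concentration. This is the latent
#' object whose diversity the pileup-based statistics estimate: many closely
#' related strains (small `divergence`) and few divergent strains (large
#' `divergence`) are both reachable.
#'
#' @param reference A `phage_genome`.
#' @param n_strains Number of strains (>= 1).
#' @param divergence Per-site substitution probability per strain (>= 0).
#' @param abundance_concentration Symmetric Dirichlet concentration for
#'   strain abundances (> 0). Small values give skewed populations.
#' @param kappa Transition:transversion draw bias; the generative Ts/Tv of
#'   emitted variants equals `kappa`. Default 3.
#' @param seed Integer seed.
#' @param founder Optional tibble of shared variants (`pos`, `ref`, `alt`)
#'   carried by every strain, used to place a whole population at a set
#'   divergence from the reference (between-host structure).
#' @return A `strain_population`: list with `reference`, `strains` (list of
#'   variant tibbles `pos`/`ref`/`alt`, 0-based positions), `abundance`,
#'   `strain_id`.
#' @examples
#' g <- generate_genome(2000, seed = 1)
#' pop <- simulate_population(g, n_strains = 2, divergence = 1e-3, seed = 1)
#' pop$abundance
#' @export
simulate_population <- function(reference, n_strains = 2, divergence = 5e-4,
                                abundance_concentration = 1, kappa = 3,
                                seed = NULL, founder = NULL) {
  stopifnot(inherits(reference, "phage_genome"))
  n_strains <- assert_count(n_strains, "n_strains", min = 1)
  if (divergence < 0) abort("`divergence` must be >= 0")
  if (abundance_concentration <= 0) abort("`abundance_concentration` must be > 0")
  chars <- seq_chars(reference$sequence)
  with_seed(seed, {
    strains <- lapply(seq_len(n_strains), function(i) {
      v <- draw_variants(chars, divergence, kappa)
      if (!is.null(founder)) {
        v <- bind_rows(v, founder[!founder$pos %in% v$pos, ])
        v <- arrange(v, .data$pos)
      }
      v
    })
    ab <- if (n_strains == 1) 1 else rdirichlet1(n_strains, abundance_concentration)
    new_strain_population(reference, strains, ab,
                          sprintf("strain_%02d", seq_len(n_strains)))
  })
}

# Draw Binomial(L, rate) substitutions with transition bias kappa.
draw_variants <- function(chars, rate, kappa = 3) {
  L <- length(chars)
  n <- rbinom(1, L, min(rate, 1))
  if (n == 0) {
    return(tibble(pos = integer(), ref = character(), alt = character()))
  }
  pos <- sort(sample.int(L, n)) - 1L
  ref <- chars[pos + 1L]
  ts <- runif(n) < kappa / (kappa + 1)
  alt <- ifelse(ts, TRANSITION[ref], NA_character_)
  needs_tv <- which(!ts)
  if (length(needs_tv)) {
    alt[needs_tv] <- vapply(ref[needs_tv], function(b) {
      sample(setdiff(BASES, c(b, TRANSITION[[b]])), 1)
    }, character(1))
  }
  tibble(pos = pos, ref = unname(ref), alt = unname(alt))
}

new_strain_population <- function(reference, strains, abundance, strain_id,
                                  source_strains = NULL) {
  if (any(abundance <= 0)) abort("strain abundances must be > 0")
  if (abs(sum(abundance) - 1) > 1e-9) abort("strain abundances must sum to 1")
  structure(
    list(reference = reference, strains = strains,
         abundance = abundance / sum(abundance), strain_id = strain_id,
         source_strains = source_strains),
    class = "strain_population"
  )
}

#' @export
print.strain_population <- function(x, ...) {
  cat(sprintf("<strain_population> %d strain(s) on %s (%d bp)\n",
              length(x$strains), x$reference$id, x$reference$length))
  for (i in seq_along(x$strains)) {
    cat(sprintf("  %s: abundance %.3f, %d variant(s)\n", x$strain_id[i],
                x$abundance[i], nrow(x$strains[[i]])))
  }
  invisible(x)
}

#' Full sequence of one strain
#'
#' Applies a strain's variant set to the reference sequence.
#'
#' @param population A `strain_population`.
#' @param strain Strain index.
#' @return Character string of the strain genome.
#' @export
strain_sequence <- function(population, strain = 1) {
  chars <- seq_chars(population$reference$sequence)
  v <- population$strains[[strain]]
  if (nrow(v)) chars[v$pos + 1L] <- v$alt
  chars_to_seq(chars)
}

#' Abundance-weighted consensus sequence of a population
#'
#' The base at each position is the one carried by the largest total strain
#' abundance; ties break toward the reference, then base order A<C<G<T. This
#' is the package's stand-in for a metagenome-assembled genome, which
#' represents the dominant allele at each position.
#'
#' @param population A `strain_population`.
#' @return Character string.
#' @export
consensus_sequence <- function(population) {
  chars <- seq_chars(population$reference$sequence)
  ab <- population$abundance
  allv <- bind_rows(lapply(seq_along(population$strains), function(i) {
    v <- population$strains[[i]]
    if (!nrow(v)) return(NULL)
    mutate(v, w = ab[i])
  }))
  if (is.null(allv) || !nrow(allv)) return(chars_to_seq(chars))
  byallele <- allv |>
    group_by(.data$pos, .data$alt) |>
    summarise(w = sum(.data$w), .groups = "drop") |>
    group_by(.data$pos) |>
    mutate(ref_w = 1 - sum(.data$w)) |>
    arrange(desc(.data$w), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    filter(.data$w > .data$ref_w)
  if (nrow(byallele)) chars[byallele$pos + 1L] <- byallele$alt
  chars_to_seq(chars)
}

#' Simulate a pileup from a strain population
#'
#' Per-site sequencing depth is negative-binomial with the given mean and
#' dispersion (size); each read is assigned to a strain with probability
#' equal to its abundance, reports that strain's base, and is perturbed to a
#' uniformly chosen different base with probability `error_rate`.
#'
#' @param population A `strain_population`.
#' @param coverage_mean Mean fold coverage (> 0).
#' @param dispersion Negative-binomial size parameter (> 0); smaller values
#'   give more variable coverage.
#' @param error_rate Per-base sequencing error probability in \[0, 0.25).
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return A `site_pileup`: list with `sample_id`, `counts` (integer matrix
#'   L x 4, columns A/C/G/T), `reference_id`.
#' @examples
#' g <- generate_genome(500, seed = 1)
#' pop <- simulate_population(g, 2, divergence = 5e-3, seed = 2)
#' pu <- simulate_pileup(pop, coverage_mean = 50, seed = 3)
#' head(tidy(pu))
#' @export
simulate_pileup <- function(population, coverage_mean = 100, dispersion = 5,
                            error_rate = 0.002, seed = NULL,
                            sample_id = "sample_1") {
  stopifnot(inherits(population, "strain_population"))
  if (coverage_mean <= 0) abort("`coverage_mean` must be > 0")
  if (dispersion <= 0) abort("`dispersion` must be > 0")
  if (error_rate < 0 || error_rate >= 0.25) {
    abort("`error_rate` must be in [0, 0.25)")
  }
  ref_chars <- seq_chars(population$reference$sequence)
  L <- length(ref_chars)
  ref_idx <- match(ref_chars, BASES)
  n_strains <- length(population$strains)
  ab <- population$abundance

  with_seed(seed, {
    depth <- rnbinom(L, size = dispersion, mu = coverage_mean)
    counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
    # Positions where any strain differs from the reference need per-strain
    # read assignment; everywhere else all strains agree on the ref base.
    var_pos <- sort(unique(unlist(lapply(population$strains, `[[`, "pos"))))
    plain <- if (length(var_pos)) setdiff(seq_len(L), var_pos + 1L) else seq_len(L)
    counts[cbind(plain, ref_idx[plain])] <- depth[plain]

    if (length(var_pos)) {
      vi <- var_pos + 1L
      # strain base at each variant position (n_var x n_strains index matrix)
      base_idx <- matrix(rep(ref_idx[vi], n_strains), ncol = n_strains)
      for (s in seq_len(n_strains)) {
        v <- population$strains[[s]]
        if (nrow(v)) {
          hit <- match(v$pos, var_pos)
          base_idx[hit, s] <- match(v$alt, BASES)
        }
      }
      for (k in seq_along(vi)) {
        d <- depth[vi[k]]
        if (d == 0) next
        per_strain <- if (n_strains == 1) d else
          as.integer(rmultinom(1, d, ab))
        for (s in seq_len(n_strains)) {
          b <- base_idx[k, s]
          counts[vi[k], b] <- counts[vi[k], b] + per_strain[s]
        }
      }
    }

    if (error_rate > 0) {
      # Move a Binomial(e) share of each base's reads to the other three
      # bases, uniformly.
      for (b in 1:4) {
        src <- counts[, b]
        nerr <- rbinom(L, src, error_rate)
        if (!any(nerr > 0)) next
        others <- setdiff(1:4, b)
        e1 <- rbinom(L, nerr, 1 / 3)
        e2 <- rbinom(L, nerr - e1, 1 / 2)
        e3 <- nerr - e1 - e2
        counts[, b] <- src - nerr
        counts[, others[1]] <- counts[, others[1]] + e1
        counts[, others[2]] <- counts[, others[2]] + e2
        counts[, others[3]] <- counts[, others[3]] + e3
      }
    }
    new_site_pileup(sample_id, counts, population$reference$id)
  })
}

new_site_pileup <- function(sample_id, counts, reference_id) {
  stopifnot(is.matrix(counts), ncol(counts) == 4)
  if (any(counts < 0)) abort("pileup counts must be >= 0")
  storage.mode(counts) <- "integer"
  colnames(counts) <- BASES
  structure(list(sample_id = sample_id, counts = counts,
                 reference_id = reference_id),
            class = "site_pileup")
}

#' @export
print.site_pileup <- function(x, ...) {
  cat(sprintf("<site_pileup> %s vs %s: %d positions, mean depth %.1f\n",
              x$sample_id, x$reference_id, nrow(x$counts),
              mean(rowSums(x$counts))))
  invisible(x)
}

#' @export
tidy.site_pileup <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    pos = seq_len(nrow(x$counts)) - 1L,
    depth = as.integer(rowSums(x$counts)),
    A = x$counts[, "A"], C = x$counts[, "C"],
    G = x$counts[, "G"], T = x$counts[, "T"]
  )
}

#' Simulate vertical transmission with a bottleneck
#'
#' Samples `bottleneck_k` strains from a donor population without
#' replacement, with probability proportional to abundance, renormalises the
#' sampled abundances, and then mutates each transmitted strain at
#' `post_mutation_rate` substitutions per site. If `bottleneck_k` is at
#' least the number of available strains, the whole population is
#' transmitted (renormalisation is then a no-op). Ground-truth identities of
#' the transmitted strains are recorded in `source_strains`.
#'
#' @param mother Donor `strain_population`.
#' @param bottleneck_k Number of strains surviving the bottleneck (>= 1).
#' @param post_mutation_rate Per-site substitution rate applied to each
#'   transmitted strain after acquisition.
#' @param kappa Transition bias for post-acquisition mutations.
#' @param seed Integer seed.
#' @return A `strain_population` whose `source_strains` field names the
#'   donor strains each recipient strain descends from.
#' @export
simulate_transmission <- function(mother, bottleneck_k = 1,
                                  post_mutation_rate = 0, kappa = 3,
                                  seed = NULL) {
  stopifnot(inherits(mother, "strain_population"))
  bottleneck_k <- assert_count(bottleneck_k, "bottleneck_k", min = 1)
  n <- length(mother$strains)
  with_seed(seed, {
    take <- if (bottleneck_k >= n) seq_len(n) else
      sample.int(n, bottleneck_k, prob = mother$abundance)
    ab <- mother$abundance[take] / sum(mother$abundance[take])
    chars <- seq_chars(mother$reference$sequence)
    strains <- lapply(take, function(i) {
      v <- mother$strains[[i]]
      if (post_mutation_rate > 0) {
        extra <- draw_variants(chars, post_mutation_rate, kappa)
        v <- arrange(bind_rows(v, extra[!extra$pos %in% v$pos, ]), .data$pos)
      }
      v
    })
    new_strain_population(mother$reference, strains, ab,
                          sprintf("strain_%02d", seq_along(take)),
                          source_strains = mother$strain_id[take])
  })
}
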