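#' Define a synthetic cohort scenario
#'
#' Bundles the generative parameters for [simulate_cohort()]. Defaults
#' describe a mother-infant shotgun-metagenome study of a prevalent gut
#' phage: a ~97 kb reference with 88 genes, mothers carrying a few closely
#' related strains (within-host divergence 5e-4 substitutions/site) founded
#' from host-specific lineages about 2% diverged from the reference (so
#' unrelated hosts' genomes share roughly 96% identity), negative-binomial
#' coverage (mean 100x, dispersion 5), sequencing error 0.002, a
#' single-strain transmission bottleneck, and per-timepoint infant mutation
#' that seeds new low-frequency sub-strains.
#'
#' @param n_families Number of mother-infant families (mother-infant mode)
#'   or recipients (FMT mode).
#' @param mode `"mother_infant"` or `"fmt"`.
#' @param transmission_probability Probability an infant acquires the
#'   phage from its mother (or a recipient engrafts from the donor).
#' @param independent_acquisition_probability Probability a non-transmitting
#'   infant instead acquires an unrelated lineage from the environment.
#' @param bottleneck_k Strains surviving transmission (>= 1).
#' @param post_mutation_rate Per-site substitution rate applied to the
#'   infant population at each timepoint after acquisition; each bout
#'   splits off a mutated sub-strain so multiallelic sites accrue.
#' @param n_strains Strains per carrier population.
#' @param within_divergence Per-site strain divergence within a host.
#' @param between_divergence Per-site divergence of each host's founding
#'   lineage from the reference.
#' @param coverage_mean,coverage_dispersion Negative-binomial depth model.
#' @param error_rate Per-base sequencing error (in \[0, 0.25)).
#' @param genome_length,n_genes,gc Reference genome properties.
#' @param mother_carrier_probability Probability a mother carries the
#'   phage at all.
#' @param infant_days Infant sampling days (mother-infant mode); FMT mode
#'   samples recipients on `fmt_days` relative to transplant at day 0.
#' @param mean_total_reads Mean per-sample sequencing depth (reads) after
#'   preprocessing.
#' @param kappa Transition bias of simulated substitutions.
#' @param emit_pileups Generate per-sample pileups (turn off when only
#'   assembled-genome comparisons are needed).
#' @param taxon Taxon label used in read-count tables.
#' @return A `cohort_scenario` list.
#' @export
cohort_scenario <- function(n_families = 20, mode = c("mother_infant", "fmt"),
                            transmission_probability = 0.5,
                            independent_acquisition_probability = 1,
                            bottleneck_k = 1, post_mutation_rate = 1e-4,
                            n_strains = 3, within_divergence = 5e-4,
                            between_divergence = 0.02,
                            coverage_mean = 100, coverage_dispersion = 5,
                            error_rate = 0.002, genome_length = 97000,
                            n_genes = 88, gc = 0.35,
                            mother_carrier_probability = 1,
                            infant_days = c(4, 120, 365),
                            mean_total_reads = 8.7e6, kappa = 3,
                            emit_pileups = TRUE, taxon = "p_crAssphage") {
  mode <- match.arg(mode)
  assert_fraction(transmission_probability, "transmission_probability",
                  open_left = FALSE, open_right = FALSE)
  assert_fraction(independent_acquisition_probability,
                  "independent_acquisition_probability",
                  open_left = FALSE, open_right = FALSE)
  bottleneck_k <- assert_count(bottleneck_k, "bottleneck_k", min = 1)
  if (error_rate < 0 || error_rate >= 0.25) {
    abort("`error_rate` must be in [0, 0.25)")
  }
  structure(
    list(n_families = assert_count(n_families, "n_families", min = 1),
         mode = mode,
         transmission_probability = transmission_probability,
         independent_acquisition_probability =
           independent_acquisition_probability,
         bottleneck_k = bottleneck_k,
         post_mutation_rate = post_mutation_rate, n_strains = n_strains,
         within_divergence = within_divergence,
         between_divergence = between_divergence,
         coverage_mean = coverage_mean,
         coverage_dispersion = coverage_dispersion,
         error_rate = error_rate, genome_length = genome_length,
         n_genes = n_genes, gc = gc,
         mother_carrier_probability = mother_carrier_probability,
         infant_days = infant_days, mean_total_reads = mean_total_reads,
         kappa = kappa, emit_pileups = emit_pileups, taxon = taxon),
    class = "cohort_scenario")
}

# One host population: a founding lineage `between_divergence` from the
# reference, with n_strains close relatives around it.
founder_population <- function(reference, sc) {
  chars <- seq_chars(reference$sequence)
  founder <- draw_variants(chars, sc$between_divergence, sc$kappa)
  simulate_population(reference, n_strains = sc$n_strains,
                      divergence = sc$within_divergence,
                      abundance_concentration = 1, kappa = sc$kappa,
                      founder = founder)
}

# Apply one bout of within-host evolution: each strain spawns a mutated
# sub-strain taking 30% of its abundance, creating new polymorphic sites.
drift_population <- function(pop, rate, kappa) {
  if (rate <= 0) return(pop)
  chars <- seq_chars(pop$reference$sequence)
  strains <- pop$strains
  ab <- pop$abundance
  new_strains <- list()
  new_ab <- numeric(0)
  for (i in seq_along(strains)) {
    extra <- draw_variants(chars, rate, kappa)
    if (nrow(extra)) {
      v <- arrange(bind_rows(strains[[i]],
                             extra[!extra$pos %in% strains[[i]]$pos, ]),
                   .data$pos)
      new_strains <- c(new_strains, list(v))
      new_ab <- c(new_ab, ab[i] * 0.3)
      ab[i] <- ab[i] * 0.7
    }
  }
  strains <- c(strains, new_strains)
  ab <- c(ab, new_ab)
  new_strain_population(pop$reference, strains, ab / sum(ab),
                        sprintf("strain_%02d", seq_along(strains)),
                        source_strains = pop$source_strains)
}

#' Simulate a longitudinal cohort with known ground truth
#'
#' Generates a full synthetic study: a reference genome and annotation,
#' per-host strain populations, per-sample classified read counts,
#' pileups, and consensus ("assembled") genomes, with ground-truth
#' carriage, strain composition and transmission labels attached. In
#' mother-infant mode each family has one maternal sample (day 0) and
#' infant samples at the scenario's timepoints; the infant acquires the
#' maternal phage through a `bottleneck_k`-strain bottleneck with the
#' scenario's probability, otherwise (with the independent-acquisition
#' probability) an unrelated lineage. In FMT mode one positive donor is
#' sampled at day 0 and each recipient pre- (day -7) and post-transplant;
#' engraftment follows the transmission probability and the virome-style
#' 10,000-read threshold applies downstream.
#'
#' @param scenario A [cohort_scenario()].
#' @param seed Integer seed; all randomness flows from it.
#' @return A `phage_cohort`: list with `reference`, `annotation`,
#'   `samples` (tibble: `sample_id`, `subject`, `family`, `role`, `day`,
#'   `total_reads`, `classified_reads`, `carrier`, `transmitted`,
#'   `taxon`), `pileups` (named list of `site_pileup`, carriers only, when
#'   `emit_pileups`), `genomes` (named list of consensus sequences,
#'   carriers only), `populations` (named list of `strain_population` per
#'   subject-timepoint), `scenario`, `seed`.
#' @export
simulate_cohort <- function(scenario = cohort_scenario(), seed = 1) {
  sc <- scenario
  stopifnot(inherits(sc, "cohort_scenario"))
  with_seed(seed, {
    reference <- generate_genome(sc$genome_length, gc = sc$gc,
                                 id = "synthetic_phage_ref")
    annotation <- generate_annotation(reference, n_genes = sc$n_genes,
                                      coding_fraction = 0.9)
    samples <- list()
    pileups <- list()
    genomes <- list()
    populations <- list()

    emit_sample <- function(sample_id, subject, family, role, day, pop,
                            coverage_mult = 1) {
      total <- round(rlnorm(1, log(sc$mean_total_reads), 0.3))
      carrier <- !is.null(pop)
      if (carrier) {
        cov <- rnbinom(1, size = sc$coverage_dispersion,
                       mu = sc$coverage_mean * coverage_mult)
        cov <- max(cov, 1)
        classified <- min(round(cov * reference$length / 100), total)
        if (sc$emit_pileups) {
          pileups[[sample_id]] <<- simulate_pileup(
            pop, coverage_mean = cov, dispersion = sc$coverage_dispersion,
            error_rate = sc$error_rate, sample_id = sample_id)
        }
        genomes[[sample_id]] <<- consensus_sequence(pop)
        populations[[sample_id]] <<- pop
      } else {
        classified <- 0L
      }
      samples[[length(samples) + 1]] <<- tibble(
        sample_id = sample_id, subject = subject, family = family,
        role = role, day = day, total_reads = as.integer(total),
        taxon = sc$taxon, classified_reads = as.integer(classified),
        carrier = carrier)
      invisible(NULL)
    }

    transmitted_flags <- list()
    if (sc$mode == "mother_infant") {
      for (f in seq_len(sc$n_families)) {
        fam <- sprintf("F%03d", f)
        mother_pop <- if (runif(1) < sc$mother_carrier_probability)
          founder_population(reference, sc) else NULL
        emit_sample(paste0(fam, "_M_d000"), paste0(fam, "_M"), fam,
                    "mother", 0, mother_pop)
        transmitted <- !is.null(mother_pop) &&
          runif(1) < sc$transmission_probability
        infant_pop <- if (transmitted) {
          simulate_transmission(mother_pop, bottleneck_k = sc$bottleneck_k,
                                post_mutation_rate = 0, kappa = sc$kappa)
        } else if (runif(1) < sc$independent_acquisition_probability) {
          founder_population(reference, sc) |>
            simulate_transmission(bottleneck_k = sc$bottleneck_k,
                                  post_mutation_rate = 0, kappa = sc$kappa)
        } else NULL
        transmitted_flags[[fam]] <- transmitted
        for (d in sc$infant_days) {
          if (!is.null(infant_pop) && d > sc$infant_days[1]) {
            infant_pop <- drift_population(infant_pop,
                                           sc$post_mutation_rate, sc$kappa)
          }
          emit_sample(sprintf("%s_I_d%03d", fam, d), paste0(fam, "_I"),
                      fam, "infant", d, infant_pop)
        }
      }
    } else {
      donor_pop <- founder_population(reference, sc)
      emit_sample("D1_d000", "D1", "FMT", "donor", 0, donor_pop)
      for (r in seq_len(sc$n_families)) {
        subj <- sprintf("P%02d", r)
        emit_sample(sprintf("%s_pre", subj), subj, "FMT", "recipient",
                    -7, NULL)
        engrafted <- runif(1) < sc$transmission_probability
        rec_pop <- if (engrafted) {
          simulate_transmission(donor_pop, bottleneck_k = sc$bottleneck_k,
                                post_mutation_rate = 0, kappa = sc$kappa)
        } else NULL
        transmitted_flags[[subj]] <- engrafted
        for (d in c(30, 365)) {
          emit_sample(sprintf("%s_d%03d", subj, d), subj, "FMT",
                      "recipient", d, rec_pop)
        }
      }
    }
    samples <- bind_rows(samples) |>
      mutate(transmitted = dplyr::coalesce(
        unlist(transmitted_flags)[.data$family], FALSE))
    if (sc$mode == "fmt") {
      samples$transmitted <- dplyr::coalesce(
        unlist(transmitted_flags)[samples$subject], FALSE)
      samples$transmitted[samples$role == "donor"] <- FALSE
    }
    structure(list(reference = reference, annotation = annotation,
                   samples = samples, pileups = pileups, genomes = genomes,
                   populations = populations, scenario = sc, seed = seed),
              class = "phage_cohort")
  })
}

#' @export
print.phage_cohort <- function(x, ...) {
  cat(sprintf(
    "<phage_cohort> %s: %d samples, %d carriers, reference %d bp, seed %d\n",
    x$scenario$mode, nrow(x$samples), sum(x$samples$carrier),
    x$reference$length, x$seed))
  invisible(x)
}

#' @export
tidy.phage_cohort <- function(x, ...) x$samples
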