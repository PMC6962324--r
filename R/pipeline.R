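#' Run the full analysis pipeline on a simulated cohort
#'
#' Chains the package end to end: simulate a cohort, write its inputs
#' (reference FASTA, GFF3 annotation, read-count TSV, pileup TSVs,
#' consensus-genome FASTA), then run detection, variant calling (VCF +
#' sites TSV), F_multi diversity, effect annotation (per-gene ranking and
#' window profiles), pairwise genome comparison with Ward clustering, and
#' transmission classification, writing one TSV per stage plus a JSON run
#' manifest with the seed, configuration echo and per-file checksums. All
#' randomness flows from `seed`; a rerun with the same seed writes
#' byte-identical outputs.
#'
#' @param scenario A [cohort_scenario()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param presence_threshold Classified-read presence threshold (1,000; use
#'   10,000 for virome-enriched sequencing).
#' @param min_total_reads Sample depth filter.
#' @param min_depth,min_allele_reads Variant-calling thresholds.
#' @param af_thresholds F_multi minor AF grid, each in (0, 0.5).
#' @param identity_cut,length_cut Transmission thresholds.
#' @param window,step Window profile geometry.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(scenario = cohort_scenario(n_families = 5),
                         out_dir, seed = 1,
                         presence_threshold = 1000,
                         min_total_reads = 10000,
                         min_depth = 10, min_allele_reads = 5,
                         af_thresholds = c(0.40, 0.30, 0.20, 0.10),
                         identity_cut = 99.7, length_cut = 20000,
                         window = 1500, step = 200) {
  if (any(af_thresholds <= 0 | af_thresholds >= 0.5)) {
    abort("validation: `af_thresholds` must lie in (0, 0.5)")
  }
  if (presence_threshold < 1 || min_depth < 1 || min_allele_reads < 1 ||
      length_cut < 1) {
    abort("validation: thresholds must be positive")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(...) file.path(out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  cohort <- stage("simulate", simulate_cohort(scenario, seed = seed))
  stage("write_inputs", {
    write_genome_fasta(cohort$reference, outfile("reference.fasta"))
    write_annotation_gff3(cohort$annotation, cohort$reference,
                          outfile("annotation.gff3"))
    write_read_counts(cohort$samples, outfile("read_counts.tsv"))
    if (length(cohort$genomes)) {
      write_genome_fasta(cohort$genomes, outfile("assemblies.fasta"))
    }
    if (length(cohort$pileups)) {
      dir.create(outfile("pileups"), showWarnings = FALSE)
      for (sid in names(cohort$pileups)) {
        write_pileup(cohort$pileups[[sid]],
                     outfile("pileups", paste0(sid, ".pileup.tsv")))
      }
    }
  })

  calls <- stage("detect", call_presence(
    cohort$samples, taxon = scenario$taxon,
    threshold = presence_threshold, min_total_reads = min_total_reads,
    genome_length = cohort$reference$length))
  readr::write_tsv(calls, outfile("presence_calls.tsv"), progress = FALSE)
  readr::write_tsv(presence_timeline(calls), outfile("presence_timeline.tsv"),
                   progress = FALSE)
  readr::write_tsv(prevalence_table(calls), outfile("prevalence.tsv"),
                   progress = FALSE)

  variant_sets <- stage("call", {
    vs <- lapply(cohort$pileups, call_variants, reference = cohort$reference,
                 min_depth = min_depth, min_allele_reads = min_allele_reads)
    if (length(vs)) {
      dir.create(outfile("vcf"), showWarnings = FALSE)
      for (sid in names(vs)) {
        write_vcf(vs[[sid]], outfile("vcf", paste0(sid, ".vcf")))
      }
      readr::write_tsv(bind_rows(lapply(vs, tidy)), outfile("sites.tsv"),
                       progress = FALSE)
    }
    vs
  })

  fm <- stage("diversity", {
    fm <- bind_rows(lapply(variant_sets, f_multi, x = af_thresholds))
    readr::write_tsv(fm, outfile("f_multi.tsv"), progress = FALSE)
    fm
  })

  stage("effects", {
    if (length(variant_sets)) {
      multi <- bind_rows(lapply(variant_sets, function(v) {
        alle <- variant_alleles(v, scope = "multiallelic")
        if (nrow(alle)) mutate(alle, sample_id = v$sample_id) else NULL
      }))
      eff <- if (!is.null(multi) && nrow(multi)) {
        cbind(predict_effect(multi, cohort$annotation, cohort$reference),
              sample_id = multi$sample_id)
      } else NULL
      if (!is.null(eff)) {
        readr::write_tsv(as_tibble(eff), outfile("effects.tsv"),
                         progress = FALSE)
        readr::write_tsv(gene_ns_ranking(eff, cohort$annotation),
                         outfile("gene_ranking.tsv"), progress = FALSE)
        sites <- as_tibble(eff) |>
          left_join(bind_rows(lapply(variant_sets, tidy)) |>
                      filter(.data$status == "multiallelic") |>
                      select("sample_id", "pos", "minor_af"),
                    by = c("sample_id", "pos"))
        wp <- window_profiles(cohort$reference, sites,
                              coverage = lapply(variant_sets, `[[`, "depth"),
                              window = window, step = step)
        readr::write_tsv(wp, outfile("window_profiles.tsv"), progress = FALSE)
      }
    }
  })

  trans <- stage("compare", {
    if (length(cohort$genomes) >= 2) {
      im <- identity_matrix(cohort$genomes)
      readr::write_tsv(im$pairs, outfile("comparisons.tsv"), progress = FALSE)
      readr::write_tsv(
        as_tibble(im$matrix, rownames = "sample_id"),
        outfile("identity_matrix.tsv"), progress = FALSE)
      write_newick(im, outfile("dendrogram.nwk"))
      tc <- classify_transmission(im$pairs, identity_cut = identity_cut,
                                  length_cut = length_cut)
      readr::write_tsv(tc, outfile("transmission_calls.tsv"),
                       progress = FALSE)
      tc
    } else NULL
  })

  manifest <- list(
    tool = "phagestrain",
    version = as.character(utils::packageVersion("phagestrain")),
    seed = seed,
    config = list(
      scenario = unclass(scenario),
      presence_threshold = presence_threshold,
      min_total_reads = min_total_reads, min_depth = min_depth,
      min_allele_reads = min_allele_reads, af_thresholds = af_thresholds,
      identity_cut = identity_cut, length_cut = length_cut,
      window = window, step = step),
    outputs = {
      fs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
      fs <- fs[basename(fs) != "manifest.json"]
      as.list(setNames(unname(tools::md5sum(fs)),
                       sub(paste0("^", out_dir, "/?"), "", fs)))
    })
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
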