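test_that("generate_genome hits the requested composition and is seeded", {
  g <- generate_genome(97000, gc = 0.35, seed = 1)
  expect_equal(g$length, 97000)
  expect_false(grepl("[^ACGT]", g$sequence))
  sd_gc <- sqrt(0.35 * 0.65 / 97000)
  expect_lt(abs(gc_content(g) - 0.35), 3 * sd_gc)

  expect_identical(generate_genome(300, gc = 0.5, seed = 7)$sequence,
                   generate_genome(300, gc = 0.5, seed = 7)$sequence)

  gcs <- vapply(1:50, function(s)
    gc_content(generate_genome(10000, gc = 0.35, seed = s)), numeric(1))
  expect_lt(abs(mean(gcs) - 0.35), 0.005)

  expect_error(generate_genome(0), "length")
  expect_error(generate_genome(1000, gc = 1.2), "gc")
})

test_that("generate_annotation places codon-length non-overlapping genes", {
  g <- generate_genome(97000, gc = 0.35, seed = 2)
  ann <- generate_annotation(g, n_genes = 88, coding_fraction = 0.9, seed = 3)
  expect_equal(nrow(ann), 88)
  total <- sum(ann$end - ann$start)
  expect_lt(abs(total - 87300) / 87300, 0.05)
  expect_true(all((ann$end - ann$start) %% 3 == 0))
  expect_true(all(ann$start >= 0 & ann$end <= g$length))
  # sorted and non-overlapping, none spans the origin
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))

  small <- generate_genome(300, gc = 0.5, seed = 1)
  one <- generate_annotation(small, n_genes = 1, coding_fraction = 1,
                             seed = 1, min_codons = 100)
  expect_equal(one$start, 0L)
  expect_equal(one$end, 300L)

  expect_error(generate_annotation(g, n_genes = 0), "n_genes")
})

test_that("simulate_population recovers binomial and Dirichlet moments", {
  g <- generate_genome(97000, gc = 0.35, seed = 4)
  one <- simulate_population(g, n_strains = 1, divergence = 1e-3, seed = 1)
  expect_equal(one$abundance, 1)

  pop <- simulate_population(g, n_strains = 2, divergence = 5e-4, seed = 3)
  expected <- 97000 * 5e-4
  sd3 <- 3 * sqrt(expected * (1 - 5e-4))
  for (v in pop$strains) {
    expect_lt(abs(nrow(v) - expected), sd3)
    expect_true(all(v$pos >= 0 & v$pos < 97000))
    expect_true(all(v$alt != v$ref))
  }

  small <- generate_genome(1000, gc = 0.35, seed = 5)
  ab <- vapply(1:200, function(s)
    simulate_population(small, 3, 1e-3, abundance_concentration = 1,
                        seed = s)$abundance, numeric(3))
  expect_true(all(abs(rowMeans(ab) - 1 / 3) < 0.03))
  expect_true(all(abs(colSums(ab) - 1) < 1e-9))
})

test_that("simulate_pileup is faithful to the population and depth model", {
  g <- generate_genome(2000, gc = 0.35, seed = 6)
  mono <- simulate_population(g, n_strains = 1, divergence = 0, seed = 1)
  pu <- simulate_pileup(mono, coverage_mean = 50, error_rate = 0, seed = 2)
  chars <- strsplit(g$sequence, "")[[1]]
  ref_col <- match(chars, c("A", "C", "G", "T"))
  ref_counts <- pu$counts[cbind(seq_len(2000), ref_col)]
  expect_equal(unname(rowSums(pu$counts)), unname(as.numeric(ref_counts)),
               tolerance = 0)

  # minor allele fraction converges to minor strain abundance
  pop <- simulate_population(g, 1, divergence = 0, seed = 1)
  v <- tibble::tibble(pos = c(100L, 500L, 900L), ref = chars[c(101, 501, 901)],
                      alt = ifelse(chars[c(101, 501, 901)] == "A", "C", "A"))
  pop2 <- pop
  pop2$strains <- list(tibble::tibble(pos = integer(), ref = character(),
                                      alt = character()), v)
  pop2$abundance <- c(0.7, 0.3)
  pop2$strain_id <- c("s1", "s2")
  afs <- vapply(1:100, function(s) {
    p <- simulate_pileup(pop2, coverage_mean = 200, error_rate = 0, seed = s)
    mean(p$counts[v$pos + 1L, ][cbind(1:3, match(v$alt, c("A","C","G","T")))] /
           rowSums(p$counts[v$pos + 1L, ]))
  }, numeric(1))
  expect_lt(abs(mean(afs) - 0.3), 0.02)

  # negative-binomial depth mean
  big <- generate_genome(20000, gc = 0.35, seed = 7)
  bigpop <- simulate_population(big, 1, 0, seed = 1)
  pu2 <- simulate_pileup(bigpop, coverage_mean = 100, dispersion = 5, seed = 3)
  expect_lt(abs(mean(rowSums(pu2$counts)) - 100) / 100, 0.02)
})

test_that("simulate_transmission bottlenecks proportionally to abundance", {
  g <- generate_genome(1000, gc = 0.35, seed = 8)
  pop <- simulate_population(g, 2, divergence = 5e-3, seed = 9)
  pop$abundance <- c(0.9, 0.1)
  major <- vapply(1:1000, function(s)
    simulate_transmission(pop, bottleneck_k = 1,
                          seed = s)$source_strains == "strain_01",
    logical(1))
  expect_lt(abs(mean(major) - 0.9), 3 * sqrt(0.9 * 0.1 / 1000))

  # zero post-acquisition mutation -> exact copies
  tr <- simulate_transmission(pop, 1, post_mutation_rate = 0, seed = 4)
  src <- match(tr$source_strains, pop$strain_id)
  expect_identical(tr$strains[[1]], pop$strains[[src]])

  # bottleneck wider than the population -> everything transmitted
  all_tr <- simulate_transmission(pop, bottleneck_k = 5, seed = 5)
  expect_equal(length(all_tr$strains), 2)
  expect_equal(sum(all_tr$abundance), 1, tolerance = 1e-9)
})

test_that("simulated populations stay normalised through the cohort", {
  sc <- cohort_scenario(n_families = 2, genome_length = 5000, n_genes = 4,
                        coverage_mean = 30)
  co <- simulate_cohort(sc, seed = 11)
  for (p in co$populations) {
    expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
  }
  # seeded determinism of the full cohort
  co2 <- simulate_cohort(sc, seed = 11)
  expect_identical(co$samples, co2$samples)
  expect_identical(co$genomes, co2$genomes)
  expect_identical(lapply(co$pileups, `[[`, "counts"),
                   lapply(co2$pileups, `[[`, "counts"))
})

test_that("zero transmission probability shares no maternal strains", {
  sc <- cohort_scenario(n_families = 3, genome_length = 4000, n_genes = 3,
                        transmission_probability = 0, emit_pileups = FALSE)
  co <- simulate_cohort(sc, seed = 12)
  expect_false(any(co$samples$transmitted))
  for (f in unique(co$samples$family)) {
    m <- co$samples$sample_id[co$samples$family == f &
                                co$samples$role == "mother"][1]
    i <- co$samples$sample_id[co$samples$family == f &
                                co$samples$role == "infant"][1]
    mv <- lapply(co$populations[[m]]$strains, function(s)
      paste(s$pos, s$alt))
    iv <- lapply(co$populations[[i]]$strains, function(s)
      paste(s$pos, s$alt))
    for (a in mv) for (b in iv) expect_false(identical(a, b))
  }
})

test_that("FMT mode engrafts recipients from the donor when forced", {
  sc <- cohort_scenario(n_families = 7, mode = "fmt",
                        transmission_probability = 1,
                        genome_length = 4000, n_genes = 3,
                        coverage_mean = 400, emit_pileups = FALSE)
  co <- simulate_cohort(sc, seed = 13)
  post <- dplyr::filter(co$samples, role == "recipient", day > 0)
  expect_true(all(post$carrier))
  pre <- dplyr::filter(co$samples, role == "recipient", day < 0)
  expect_false(any(pre$carrier))
  # the 10x virome threshold scaled to this 4 kb genome (10 * L / read_len)
  calls <- call_presence(co$samples, "p_crAssphage", threshold = 400,
                         genome_length = 4000)
  post_calls <- dplyr::semi_join(calls, post, by = "sample_id")
  expect_true(all(post_calls$present | post_calls$excluded))
  expect_false(any(post_calls$excluded))
})
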