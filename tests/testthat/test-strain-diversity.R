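test_that("f_multi matches its brute-force restatement on constructed pileups", {
  g <- generate_genome(1000, gc = 0.4, seed = 51)
  chars <- strsplit(g$sequence, "")[[1]]
  multi <- tibble::tibble(
    pos = c(10L, 200L, 500L),
    alt = sapply(chars[c(11, 201, 501)], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1]),
    minor_count = c(45L, 25L, 12L))  # minor AFs 0.45, 0.25, 0.12 at 100x
  pu <- make_pileup(g, depth = 100, multi = multi)
  vs <- call_variants(pu, g)
  fm <- f_multi(vs, x = 0.2)
  expect_equal(fm$denominator, 1000)
  expect_equal(fm$numerator, 2)
  expect_equal(fm$value, 0.002)

  # exact agreement with the oracle at every default threshold
  for (x in c(0.40, 0.30, 0.20, 0.10)) {
    o <- oracle_f_multi(pu$counts, chars, x)
    got <- f_multi(vs, x = x)
    expect_equal(got$numerator, o$numerator, info = paste("x =", x))
    expect_equal(got$denominator, o$denominator, info = paste("x =", x))
    expect_equal(got$value, o$value, info = paste("x =", x))
  }

  # and on a ragged-depth pileup
  set.seed(52)
  pu$counts <- pu$counts +
    matrix(rpois(4000, 2), ncol = 4) * rbinom(4000, 1, 0.1)
  storage.mode(pu$counts) <- "integer"
  vs2 <- call_variants(pu, g)
  for (x in c(0.40, 0.30, 0.20, 0.10)) {
    o <- oracle_f_multi(pu$counts, chars, x)
    got <- f_multi(vs2, x = x)
    expect_equal(got$value, o$value, info = paste("ragged x =", x))
  }
})

test_that("f_multi detectability denominator follows ceiling(5/x)", {
  g <- generate_genome(500, gc = 0.4, seed = 53)
  pu <- make_pileup(g, depth = 40)
  vs <- call_variants(pu, g)
  # x = 0.1 needs depth >= 50: nothing detectable
  fm <- f_multi(vs, x = 0.1)
  expect_true(fm$undefined)
  expect_true(is.na(fm$value))
  # x = 0.2 needs depth >= 25: everything detectable
  expect_equal(f_multi(vs, x = 0.2)$denominator, 500)
  # F_multi is non-increasing in x on a fixed mask
  pu2 <- make_pileup(g, depth = 100,
                     multi = tibble::tibble(pos = c(5L, 50L, 100L, 200L),
                                            alt = "A",
                                            minor_count = c(45L, 30L, 15L, 11L)))
  chars <- strsplit(g$sequence, "")[[1]]
  pu2$counts[c(6, 51, 101, 201), ] <- 0L
  pu2$counts[cbind(c(6, 51, 101, 201), match(chars[c(6, 51, 101, 201)],
                                             c("A", "C", "G", "T")))] <- 55L
  alt_col <- ifelse(chars[c(6, 51, 101, 201)] == "A", "C", "A")
  pu2$counts[cbind(c(6, 51, 101, 201), match(alt_col, c("A","C","G","T")))] <-
    c(45L, 30L, 15L, 11L)
  vs2 <- call_variants(pu2, g)
  vals <- f_multi(vs2, x = c(0.45, 0.35, 0.25, 0.15))$value
  expect_true(all(diff(vals) >= 0))  # ordered from high to low x
})

test_that("sites_per_kb density and percent conversions are exact", {
  g <- generate_genome(1000, gc = 0.4, seed = 54)
  chars <- strsplit(g$sequence, "")[[1]]
  multi <- tibble::tibble(pos = c(100L, 300L),
                          alt = sapply(chars[c(101, 301)], function(b)
                            setdiff(c("A", "C", "G", "T"), b)[1]),
                          minor_count = c(30L, 40L))
  vs <- call_variants(make_pileup(g, 100, multi), g)
  d <- sites_per_kb(vs, x = 0.1)
  expect_equal(d$density, 1000 * 2 / 1000)
  expect_equal(d$percent, d$density / 10)

  none <- call_variants(make_pileup(g, 100), g)
  expect_equal(sites_per_kb(none, 0.1)$density, 0)
})

test_that("group_compare reproduces exact rank-sum p-values", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                      v = c(1, 2, 3, 10, 11, 12))
  r <- group_compare(d, "v", "g")
  expect_equal(r$p.value, 0.1)
  expect_equal(r$method, "wilcoxon_exact")

  same <- tibble::tibble(g = rep(c("a", "b"), each = 4), v = rep(1:4, 2))
  r2 <- group_compare(same, "v", "g")
  expect_equal(r2$p.value, 1)

  expect_error(group_compare(tibble::tibble(g = "a", v = 1), "v", "g"),
               "two levels")
})

test_that("mothers with tenfold higher diversity separate with power", {
  set.seed(55)
  hits <- vapply(1:40, function(r) {
    mothers <- rgamma(15, shape = 4, rate = 4) * 0.02
    infants <- rgamma(15, shape = 4, rate = 4) * 0.002
    d <- tibble::tibble(
      g = rep(c("mother", "infant"), each = 15), v = c(mothers, infants))
    group_compare(d, "v", "g")$p.value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("allele sharing classifies maternal major/minor/neither alleles", {
  g <- generate_genome(2000, gc = 0.4, seed = 56)
  chars <- strsplit(g$sequence, "")[[1]]
  pos <- seq(50L, 950L, by = 75L)  # 13 maternal multiallelic sites
  alt <- sapply(chars[pos + 1], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1])
  mother <- call_variants(make_pileup(
    g, 100, tibble::tibble(pos = pos, alt = alt, minor_count = 30L),
    sample_id = "mom"), g)
  # infant fixed for the maternal MAJOR (= reference) allele everywhere
  infant_major <- call_variants(make_pileup(g, 80, sample_id = "kid"), g)
  sh <- allele_sharing(mother, infant_major)
  expect_false(sh$skipped)
  expect_equal(nrow(sh$records), 13)
  expect_true(all(sh$records$transmitted_class == "major_detected"))

  # infant fixed for the maternal MINOR allele at every shared site
  infant_minor <- call_variants(make_pileup(
    g, 80, tibble::tibble(pos = pos, alt = alt, minor_count = 80L),
    sample_id = "kid2"), g)
  sh2 <- allele_sharing(mother, infant_minor)
  expect_true(all(sh2$records$transmitted_class == "minor_detected"))

  # infant carrying a third allele -> neither
  third <- sapply(seq_along(pos), function(i)
    setdiff(c("A", "C", "G", "T"), c(chars[pos[i] + 1], alt[i]))[1])
  infant_third <- call_variants(make_pileup(
    g, 80, tibble::tibble(pos = pos, alt = third, minor_count = 80L),
    sample_id = "kid3"), g)
  sh3 <- allele_sharing(mother, infant_third)
  expect_true(all(sh3$records$transmitted_class == "neither"))

  # uncovered infant -> empty record set
  blank <- make_pileup(g, 0, sample_id = "kid4")
  sh4 <- allele_sharing(mother, call_variants(blank, g))
  expect_equal(nrow(sh4$records), 0)

  # too few maternal multiallelic sites -> skipped with reason
  few <- call_variants(make_pileup(
    g, 100, tibble::tibble(pos = pos[1:3], alt = alt[1:3],
                           minor_count = 30L)), g)
  sh5 <- allele_sharing(few, infant_major)
  expect_true(sh5$skipped)
  expect_match(sh5$reason, "need >= 10")
})

test_that("major alleles dominate sharing under a tight bottleneck", {
  g <- generate_genome(20000, gc = 0.35, seed = 57)
  major_frac <- vapply(1:5, function(s) {
    pop <- simulate_population(g, 3, divergence = 2e-3,
                               abundance_concentration = 0.8, seed = s)
    # force a clear major strain
    pop$abundance <- c(0.7, 0.2, 0.1)
    mother_pu <- simulate_pileup(pop, 200, error_rate = 0, seed = s + 10)
    kid <- simulate_transmission(pop, bottleneck_k = 1, seed = s + 20)
    kid_pu <- simulate_pileup(kid, 200, error_rate = 0, seed = s + 30)
    sh <- allele_sharing(call_variants(mother_pu, g),
                         call_variants(kid_pu, g))
    if (sh$skipped) return(NA_real_)
    mean(sh$records$transmitted_class == "major_detected")
  }, numeric(1))
  # the major strain is picked ~70% of draws; when it is, records are
  # overwhelmingly major_detected
  expect_gte(mean(major_frac >= 0.9, na.rm = TRUE), 0.5)
})

test_that("longitudinal summaries track accumulating infant diversity", {
  g <- generate_genome(10000, gc = 0.35, seed = 58)
  rising <- vapply(1:10, function(s) {
    pop <- simulate_population(g, 1, divergence = 1e-3, seed = s)
    counts <- numeric(3)
    vss <- list()
    for (tp in 1:3) {
      if (tp > 1) pop <- phagestrain:::drift_population(pop, 3e-4, 3)
      pu <- simulate_pileup(pop, 150, error_rate = 0, seed = s * 10 + tp)
      vss[[tp]] <- call_variants(pu, g)
      counts[tp] <- sum(vss[[tp]]$calls$status == "multiallelic")
    }
    ls <- longitudinal_summary(vss, days = c(4, 120, 365))
    stopifnot(nrow(ls) == 12)
    counts[3] > counts[1]
  }, logical(1))
  expect_gte(mean(rising), 0.9)

  # static maternal populations show no monotone trend
  slopes <- vapply(1:10, function(s) {
    pop <- simulate_population(g, 2, divergence = 1e-3, seed = s + 50)
    vss <- lapply(1:3, function(tp)
      call_variants(simulate_pileup(pop, 150, error_rate = 0,
                                    seed = s * 31 + tp), g))
    ls <- longitudinal_summary(vss, days = c(0, 90, 180), x = 0.1)
    ls$slope[1]
  }, numeric(1))
  expect_false(all(slopes > 0) || all(slopes < 0))

  # single sample -> trajectory of length 1 per threshold
  one <- call_variants(simulate_pileup(
    simulate_population(g, 1, 0, seed = 1), 50, seed = 2), g)
  expect_equal(nrow(longitudinal_summary(list(one), days = 5, x = 0.2)), 1)
})

test_that("the highest-coverage sample is selected for repeat sampling", {
  g <- generate_genome(1000, gc = 0.4, seed = 59)
  lo <- call_variants(make_pileup(g, 20, sample_id = "lo"), g)
  hi <- call_variants(make_pileup(g, 90, sample_id = "hi"), g)
  expect_equal(select_best_sample(list(lo, hi)), 2)
})
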