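toy_genome <- function() new_phage_genome("toy", "ATGAAATAA")
toy_ann <- function(strand = "+")
  tibble::tibble(gene_id = "g1", start = 0L, end = 9L, strand = strand,
                 product = "toy")

test_that("predict_effect applies the genetic code on both strands", {
  g <- toy_genome()
  ann <- toy_ann()
  # GAA->GAG style third-position change: AAA->AAG, both Lys
  r <- predict_effect(tibble::tibble(pos = 5L, alt = "G"), ann, g)
  expect_equal(r$category, "synonymous")
  # TGG->TGA nonsense
  g2 <- new_phage_genome("toy2", "ATGTGGTAA")
  r2 <- predict_effect(tibble::tibble(pos = 5L, alt = "A"), toy_ann(), g2)
  expect_equal(r2$ref_codon, "TGG")
  expect_equal(r2$alt_codon, "TGA")
  expect_equal(r2$category, "nonsense")
  # intergenic
  free <- new_phage_genome("toy3", "ATGAAATAACCC")
  r3 <- predict_effect(tibble::tibble(pos = 10L, alt = "A"), toy_ann(), free)
  expect_equal(r3$category, "noncoding")
  # minus strand: genome revcomp of ATGTGGTAA is TTACCACAT; gene on - strand
  g4 <- new_phage_genome("toy4", "TTACCACAT")
  r4 <- predict_effect(tibble::tibble(pos = 3L, alt = "T"), toy_ann("-"), g4)
  expect_equal(r4$ref_codon, "TGG")
  expect_equal(r4$category, "nonsense")
  # errors
  expect_error(predict_effect(tibble::tibble(pos = 99L, alt = "A"),
                              toy_ann(), g), "range")
  expect_error(predict_effect(tibble::tibble(pos = 0L, alt = "A"),
                              toy_ann(), g), "differ")
})

test_that("effects agree with the translate-and-compare oracle, both strands", {
  for (strand in c("+", "-")) {
    g <- generate_genome(600, gc = 0.4, seed = if (strand == "+") 61 else 62)
    ann <- tibble::tibble(
      gene_id = c("gA", "gB"), start = c(30L, 300L), end = c(240L, 540L),
      strand = c(strand, if (strand == "+") "-" else "+"),
      product = c("a", "b"))
    chars <- strsplit(g$sequence, "")[[1]]
    alt_of <- vapply(chars, function(b)
      setdiff(c("A", "C", "G", "T"), b), character(3))
    sites <- tibble::tibble(pos = rep(0:599, each = 3),
                            alt = as.vector(alt_of))
    eff <- predict_effect(sites, ann, g)
    # spot-exhaustive: every 7th substitution through the oracle
    idx <- seq(1, nrow(sites), by = 7)
    for (i in idx) {
      expect_equal(
        eff$category[i],
        oracle_effect(sites$pos[i], sites$alt[i], ann, g),
        info = sprintf("strand %s pos %d alt %s", strand, sites$pos[i],
                       sites$alt[i]))
    }
  }
})

test_that("null distribution matches hand enumeration on the toy gene", {
  g <- toy_genome()
  nd <- null_effect_distribution(g, toy_ann())
  expect_equal(attr(nd, "n"), 27)
  expect_equal(sum(nd$proportion), 1, tolerance = 1e-12)
  # independent full enumeration via the oracle
  chars <- strsplit(g$sequence, "")[[1]]
  cats <- character(0)
  for (p in 0:8) for (a in setdiff(c("A", "C", "G", "T"), chars[p + 1])) {
    cats <- c(cats, oracle_effect(p, a, toy_ann(), g))
  }
  expect_equal(nd$count,
               as.integer(table(factor(cats, levels = c(
                 "synonymous", "nonsynonymous", "nonsense", "noncoding")))))

  # no genes -> all noncoding
  nd0 <- null_effect_distribution(g, toy_ann()[0, ])
  expect_equal(nd0$proportion[nd0$category == "noncoding"], 1)

  # all-TGG gene: no third-position change can be synonymous
  gw <- new_phage_genome("trp", strrep("TGG", 20))
  ndw <- null_effect_distribution(gw, tibble::tibble(
    gene_id = "w", start = 0L, end = 60L, strand = "+", product = "w"))
  third <- predict_effect(
    tibble::tibble(pos = seq(2L, 59L, by = 3L), alt = "A"),
    tibble::tibble(gene_id = "w", start = 0L, end = 60L, strand = "+",
                   product = "w"), gw)
  expect_true(all(third$category %in% c("nonsense", "nonsynonymous")))
})

test_that("enrichment G statistics match an independent chi-square evaluation", {
  null <- effect_distribution(rep(c("synonymous", "nonsynonymous",
                                    "nonsense", "noncoding"),
                                  c(25, 45, 5, 25)))
  obs <- rep(c("synonymous", "nonsynonymous"), c(90, 10))
  lrt <- effect_enrichment_lrt(obs, null)
  td <- tidy(lrt)
  # hand-computed binomial G for the synonymous category
  o <- 90; n <- 100; p0 <- 0.25
  g_hand <- 2 * (o * log(o / (n * p0)) + (n - o) * log((n - o) / (n * (1 - p0))))
  row <- td[td$category == "synonymous", ]
  expect_equal(row$statistic, g_hand, tolerance = 1e-10)
  expect_equal(row$p.value, pchisq(g_hand, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(row$direction, "enriched")
  expect_equal(td$direction[td$category == "nonsense"], "depleted")

  # observed == null -> G = 0, p = 1 in every category
  flat <- effect_enrichment_lrt(
    rep(c("synonymous", "nonsynonymous", "nonsense", "noncoding"),
        c(25, 45, 5, 25)), null)
  expect_true(all(abs(tidy(flat)$statistic) < 1e-12))
  expect_true(all(tidy(flat)$p.value == 1))
  expect_equal(glance(flat)$statistic, 0, tolerance = 1e-12)

  expect_error(effect_enrichment_lrt(character(0), null), "empty")
})

test_that("two-sample category comparison detects a shifted proportion", {
  a <- rep(c("synonymous", "nonsynonymous"), c(60, 40))
  b <- rep(c("synonymous", "nonsynonymous"), c(30, 70))
  cmp <- compare_effect_distributions(a, b)
  syn <- cmp[cmp$category == "synonymous", ]
  expect_lt(syn$p.value, 0.01)
  same <- compare_effect_distributions(a, a)
  expect_true(all(abs(same$statistic) < 1e-12))
})

test_that("gene ranking normalises by length and breaks ties by start", {
  ann <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        start = c(0L, 2000L, 5000L),
                        end = c(1500L, 3500L, 5750L),
                        strand = "+", product = c("a", "b", "c"))
  eff <- tibble::tibble(
    pos = c(10L, 20L, 30L, 2100L, 2200L),
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    category = c("nonsynonymous", "nonsynonymous", "nonsynonymous",
                 "nonsynonymous", "synonymous"))
  rk <- gene_ns_ranking(eff, ann)
  expect_equal(rk$ns_per_kb[rk$gene_id == "g1"], 2.0)
  expect_equal(rk$rank[rk$gene_id == "g1"], 1)
  expect_equal(rk$n_nonsynonymous[rk$gene_id == "g3"], 0)
  expect_equal(attr(rk, "genes_with_sites"), 2)

  # tie on density -> earlier start wins
  tie <- tibble::tibble(pos = c(10L, 2010L), gene_id = c("g1", "g2"),
                        category = "nonsynonymous")
  rk2 <- gene_ns_ranking(tie, ann)
  first_two <- rk2$gene_id[rk2$rank <= 2]
  expect_equal(first_two, c("g1", "g2"))
})

test_that("a gene with planted nonsynonymous excess ranks first", {
  g <- generate_genome(6000, gc = 0.4, seed = 63)
  ann <- generate_annotation(g, n_genes = 5, coding_fraction = 0.8, seed = 64)
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    target <- ann[2, ]
    # 15 sites in the target gene, 3 elsewhere per other gene
    mk_sites <- function(a, n) {
      p <- sample(a$start:(a$end - 1), n)
      chars <- strsplit(g$sequence, "")[[1]]
      tibble::tibble(pos = as.integer(p),
                     alt = sapply(chars[p + 1], function(b)
                       setdiff(c("A", "C", "G", "T"), b)[1]))
    }
    sites <- dplyr::bind_rows(
      mk_sites(target, 15),
      dplyr::bind_rows(lapply(seq_len(nrow(ann))[-2], function(i)
        mk_sites(ann[i, ], 3))))
    eff <- predict_effect(sites, ann, g)
    rk <- gene_ns_ranking(eff, ann)
    rk$gene_id[rk$rank == 1] == target$gene_id
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("window profiles compute GC, skew and conserve counts", {
  g <- new_phage_genome("w", strrep("GGGCC", 100))  # 500 bp
  wp <- window_profiles(g, window = 5, step = 5)
  expect_true(all(abs(wp$gc_skew - 0.2) < 1e-12))
  expect_true(all(wp$gc == 1))

  # pseudocount log2 N/S
  g2 <- generate_genome(2000, gc = 0.4, seed = 65)
  sites <- tibble::tibble(pos = c(100L, 110L, 120L, 130L),
                          minor_af = 0.3,
                          category = c("nonsynonymous", "nonsynonymous",
                                       "nonsynonymous", "synonymous"))
  wp2 <- window_profiles(g2, sites, window = 2000, step = 2000)
  expect_equal(wp2$log2_ns, 1.0)

  # conservation: tiling windows sum to the total site count
  set.seed(66)
  many <- tibble::tibble(pos = sample(0:1999, 120), minor_af = 0.4,
                         category = "synonymous")
  wp3 <- window_profiles(g2, many, window = 250, step = 250)
  expect_equal(sum(wp3$n_multiallelic), 120)
  # truncated final window, never wrapped
  wp4 <- window_profiles(g2, many, window = 1500, step = 600)
  expect_equal(max(wp4$end), 2000)
  expect_true(all(wp4$width <= 1500))

  # coverage indicator needs half the window at >= 10x
  cov_half <- c(rep(20, 1000), rep(0, 1000))
  wp5 <- window_profiles(g2, coverage = list(cov_half),
                         window = 1000, step = 500)
  expect_equal(wp5$frac_samples_covered[wp5$start == 0], 1)
  expect_equal(wp5$frac_samples_covered[wp5$start == 500], 1)  # exactly half
  expect_equal(wp5$frac_samples_covered[wp5$start == 1000], 0)

  expect_error(window_profiles(g2, window = 3000), "exceeds")
})

test_that("uniform site placement stays within Poisson homogeneity bounds", {
  g <- generate_genome(20000, gc = 0.4, seed = 67)
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    sites <- tibble::tibble(pos = sample(0:19999, 100), minor_af = 0.4,
                            category = "synonymous")
    wp <- window_profiles(g, sites, window = 1500, step = 200)
    lambda <- 100 * 1500 / 20000
    all(wp$n_multiallelic <= qpois(0.999, lambda) + 3)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
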