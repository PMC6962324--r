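# Shared fixture builders. Everything is generated in code; no data files.

# A pileup with a given uniform depth where every site is reference-fixed,
# except planted multiallelic sites with specified minor counts.
make_pileup <- function(genome, depth = 100, multi = NULL,
                        sample_id = "fix") {
  chars <- strsplit(genome$sequence, "")[[1]]
  counts <- matrix(0L, nrow = genome$length, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_len(genome$length), match(chars, c("A", "C", "G", "T")))] <-
    as.integer(depth)
  if (!is.null(multi)) {
    for (i in seq_len(nrow(multi))) {
      p <- multi$pos[i] + 1L
      alt <- multi$alt[i]
      k <- as.integer(multi$minor_count[i])
      counts[p, match(alt, c("A", "C", "G", "T"))] <- k
      ref_col <- match(chars[p], c("A", "C", "G", "T"))
      counts[p, ref_col] <- counts[p, ref_col] - k
    }
  }
  structure(list(sample_id = sample_id, counts = counts,
                 reference_id = genome$id),
            class = "site_pileup")
}

# Independent brute-force site caller used as an oracle: literal
# re-statement of the calling rule, one site at a time, no shared code
# with call_variants().
oracle_call_site <- function(counts, ref, min_depth = 10, min_allele = 5) {
  bases <- c("A", "C", "G", "T")
  depth <- sum(counts)
  if (depth < min_depth) return(list(status = "uncovered", minor_af = 0))
  qual <- bases[counts >= min_allele]
  if (length(qual) == 0) return(list(status = "uncovered", minor_af = 0))
  if (length(qual) == 1) {
    return(list(status = if (qual == ref) "fixed_ref" else "fixed_alt",
                minor_af = 0, allele = qual))
  }
  ord <- order(-counts, seq_along(counts))
  top2 <- ord[1:2]
  list(status = "multiallelic",
       minor_af = unname(counts[top2[2]] / sum(counts[top2])),
       alleles = bases[top2])
}

# Brute-force F_multi: direct restatement of the definition over a raw
# counts matrix.
oracle_f_multi <- function(counts, ref_chars, x, min_depth = 10,
                           min_allele = 5) {
  depth <- rowSums(counts)
  denom <- sum(depth >= ceiling(min_allele / x))
  numer <- 0
  for (i in seq_len(nrow(counts))) {
    if (depth[i] < ceiling(min_allele / x)) next
    s <- oracle_call_site(counts[i, ], ref_chars[i], min_depth, min_allele)
    if (s$status == "multiallelic" && s$minor_af > x) numer <- numer + 1
  }
  list(numerator = numer, denominator = denom,
       value = if (denom > 0) numer / denom else NA_real_)
}

# Translate-and-compare effect oracle: mutate the full genome, re-extract
# and translate every gene with Biostrings, and diff the protein sequences.
oracle_effect <- function(pos, alt, annotation, genome) {
  chars <- strsplit(genome$sequence, "")[[1]]
  mut <- chars
  mut[pos + 1] <- alt
  best <- "noncoding"
  sev <- c(noncoding = 0, synonymous = 1, nonsynonymous = 2, nonsense = 3)
  for (i in seq_len(nrow(annotation))) {
    if (pos < annotation$start[i] || pos >= annotation$end[i]) next
    get_prot <- function(ch) {
      s <- paste0(ch[(annotation$start[i] + 1):annotation$end[i]],
                  collapse = "")
      d <- Biostrings::DNAString(s)
      if (annotation$strand[i] == "-") d <- Biostrings::reverseComplement(d)
      strsplit(as.character(
        Biostrings::translate(d, no.init.codon = TRUE,
                              if.fuzzy.codon = "solve")), "")[[1]]
    }
    p0 <- get_prot(chars)
    p1 <- get_prot(mut)
    diff <- which(p0 != p1)
    cat_i <- if (!length(diff)) "synonymous"
    else if (any(p1[diff] == "*" & p0[diff] != "*")) "nonsense"
    else "nonsynonymous"
    if (sev[cat_i] > sev[best]) best <- cat_i
  }
  best
}
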