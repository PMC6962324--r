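#' Generate a random phage genome
#'
#' Draws an i.i.d. nucleotide sequence with a target GC content, standing in
#' for a circular double-stranded DNA phage reference of the p-crAssphage
#' kind (~97 kb). Every base is independent with `P(G) + P(C) = gc`.
#'
#' @param length Genome length in bp (>= 300).
#' @param gc Target GC fraction, in (0, 1). crAss-like genomes sit near 0.35.
#' @param seed Integer seed; identical inputs and seed give identical genomes.
#' @param id Sequence identifier.
#' @param circular Logical flag carried on the object; genes never span the
#'   origin, so downstream code treats the sequence linearly.
#'
#' @return A `phage_genome` object: list with `id`, `sequence` (single
#'   character string over A/C/G/T), `length` and `circular`.
#' @examples
#' g <- generate_genome(1000, gc = 0.35, seed = 1)
#' g$length
#' @export
generate_genome <- function(length = 97000, gc = 0.35, seed = NULL,
                            id = "synthetic_phage", circular = TRUE) {
  length <- assert_count(length, "length", min = 300)
  assert_fraction(gc, "gc")
  bases <- with_seed(seed, {
    sample(BASES, length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  new_phage_genome(id, chars_to_seq(bases), circular)
}

#' Construct a phage genome from a sequence string
#'
#' @param id Sequence identifier.
#' @param sequence Nucleotide string over A/C/G/T.
#' @param circular Circularity flag.
#' @return A `phage_genome`.
#' @export
new_phage_genome <- function(id, sequence, circular = TRUE) {
  if (nchar(sequence) == 0) abort("genome sequence must be non-empty")
  if (grepl("[^ACGT]", sequence)) {
    abort("genome sequence may contain only A/C/G/T")
  }
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular)),
    class = "phage_genome"
  )
}

#' @export
print.phage_genome <- function(x, ...) {
  gc <- gc_content(x)
  cat(sprintf("<phage_genome> %s: %s bp, GC %.3f, %s\n", x$id,
              format(x$length, big.mark = ","), gc,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' GC content of a genome or sequence
#'
#' @param x A `phage_genome` or a character string.
#' @return GC fraction in \[0, 1\].
#' @export
gc_content <- function(x) {
  s <- if (inherits(x, "phage_genome")) x$sequence else x
  n <- nchar(s)
  gcn <- sum(seq_chars(s) %in% c("G", "C"))
  gcn / n
}

#' Generate a gene annotation for a genome
#'
#' Places `n_genes` non-overlapping protein-coding genes of codon-multiple
#' length on the genome, covering approximately `coding_fraction` of it and
#' never spanning the circular origin. Gene lengths are drawn from a gamma
#' distribution and rescaled so their sum hits the coding target; intergenic
#' space is spread randomly between genes. Defaults mirror the 88-gene,
#' ~90%-coding structure of the p-crAssphage reference.
#'
#' @param genome A `phage_genome`.
#' @param n_genes Number of genes (>= 1).
#' @param coding_fraction Target fraction of the genome covered by genes,
#'   in (0, 1\].
#' @param seed Integer seed.
#' @param min_codons Minimum gene length in codons.
#' @return A tibble with columns `gene_id`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `strand` (`+`/`-`), `product`.
#' @examples
#' g <- generate_genome(5000, seed = 1)
#' generate_annotation(g, n_genes = 4, seed = 1)
#' @export
generate_annotation <- function(genome, n_genes = 88, coding_fraction = 0.9,
                                seed = NULL, min_codons = 10) {
  stopifnot(inherits(genome, "phage_genome"))
  n_genes <- assert_count(n_genes, "n_genes", min = 1)
  assert_fraction(coding_fraction, "coding_fraction", open_right = FALSE)
  L <- genome$length
  target <- floor(coding_fraction * L / 3) * 3
  if (target < n_genes * min_codons * 3) {
    abort(sprintf(
      "coding_fraction %.3g cannot fit %d genes of >= %d codons on %d bp",
      coding_fraction, n_genes, min_codons, L))
  }
  with_seed(seed, {
    raw <- rgamma(n_genes, shape = 4, rate = 1)
    codons <- pmax(min_codons, round(raw / sum(raw) * target / 3))
    # Nudge lengths until total coding length is exactly on target.
    excess <- sum(codons) * 3 - target
    i <- 0L
    while (excess != 0) {
      j <- (i %% n_genes) + 1L
      step <- sign(excess)
      if (codons[j] - step >= min_codons) {
        codons[j] <- codons[j] - step
        excess <- excess - step * 3
      }
      i <- i + 1L
    }
    lens <- codons * 3
    spare <- L - sum(lens)
    gaps <- floor(rdirichlet1(n_genes + 1, 1) * spare)
    gaps[n_genes + 1] <- spare - sum(gaps[-(n_genes + 1)])
    starts <- cumsum(c(0L, lens[-n_genes])) + cumsum(gaps[seq_len(n_genes)])
    tibble(
      gene_id = sprintf("gene_%03d", seq_len(n_genes)),
      start = as.integer(starts),
      end = as.integer(starts + lens),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      product = sprintf("hypothetical protein %03d", seq_len(n_genes))
    )
  })
}

validate_annotation <- function(annotation, genome = NULL) {
  need <- c("gene_id", "start", "end", "strand")
  if (!all(need %in% names(annotation))) {
    abort(paste("annotation must have columns", paste(need, collapse = ", ")))
  }
  if (any(annotation$start >= annotation$end)) abort("gene start must be < end")
  if (any((annotation$end - annotation$start) %% 3 != 0)) {
    abort("coding gene lengths must be divisible by 3")
  }
  if (!is.null(genome) && any(annotation$end > genome$length)) {
    abort("gene interval extends past genome end")
  }
  invisible(annotation)
}
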