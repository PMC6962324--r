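# File formats. Internal coordinates are 0-based half-open everywhere;
# conversion to 1-based happens only at the GFF3/VCF boundary.

#' Read and write genome FASTA
#'
#' Thin wrappers over Biostrings. `write_genome_fasta()` accepts a
#' `phage_genome` or a named list/character vector of sequences;
#' `read_genome_fasta()` returns a `phage_genome` for the first (or named)
#' record.
#'
#' @param x A `phage_genome` or named character vector of sequences.
#' @param path File path.
#' @param id Record to extract (default first).
#' @return `read_genome_fasta()` returns a `phage_genome`;
#'   `read_fasta_sequences()` a named character vector.
#' @export
write_genome_fasta <- function(x, path) {
  seqs <- if (inherits(x, "phage_genome")) {
    setNames(x$sequence, x$id)
  } else {
    unlist(x)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 60)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname write_genome_fasta
#' @param circular Circularity flag for the returned genome.
#' @export
read_genome_fasta <- function(path, id = NULL, circular = TRUE) {
  seqs <- read_fasta_sequences(path)
  nm <- id %||% names(seqs)[1]
  # FASTA headers may carry a description after the identifier
  hit <- match(nm, sub("\\s.*", "", names(seqs)))
  if (is.na(hit)) abort(sprintf("no record '%s' in %s", nm, path))
  new_phage_genome(sub("\\s.*", "", names(seqs)[hit]), seqs[[hit]], circular)
}

#' Read and write gene annotations as GFF3
#'
#' GFF3 is 1-based inclusive on disk; the in-memory annotation tibble is
#' 0-based half-open. Serialisation goes through rtracklayer.
#'
#' @param annotation Annotation tibble (see [generate_annotation()]).
#' @param genome The `phage_genome` the annotation belongs to (for the
#'   sequence name).
#' @param path File path.
#' @return `read_annotation_gff3()` returns the annotation tibble.
#' @export
write_annotation_gff3 <- function(annotation, genome, path) {
  validate_annotation(annotation, genome)
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand)
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- annotation$gene_id
  gr$product <- annotation$product %||% annotation$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(
    gene_id = as.character(gr$ID),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = if (!is.null(gr$product)) as.character(gr$product)
              else as.character(gr$ID)
  )
}

#' Read and write pileups as 6-column TSV
#'
#' Columns: `pos` (0-based), `depth`, `A`, `C`, `G`, `T`.
#'
#' @param pileup A `site_pileup`.
#' @param path File path.
#' @param sample_id,reference_id Identifiers attached on read.
#' @return `read_pileup()` returns a `site_pileup`.
#' @export
write_pileup <- function(pileup, path) {
  readr::write_tsv(tidy.site_pileup(pileup)[, -1], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path, sample_id = NULL, reference_id = "reference") {
  d <- readr::read_tsv(path, col_types = "iiiiii", progress = FALSE)
  counts <- as.matrix(d[, BASES])
  if (!all(rowSums(counts) == d$depth)) {
    abort(sprintf("%s: depth column disagrees with base counts", path))
  }
  new_site_pileup(sample_id %||% sub("\\.[^.]*$", "", basename(path)),
                  counts, reference_id)
}

#' Read and write classified read-count tables
#'
#' Long TSV with header `sample_id`, `subject`, `family`, `role`, `day`,
#' `total_reads`, `taxon`, `classified_reads` — the stand-in for a
#' classifier report.
#'
#' @param counts The samples tibble (e.g. from [simulate_cohort()]).
#' @param path File path.
#' @export
write_read_counts <- function(counts, path) {
  cols <- c("sample_id", "subject", "family", "role", "day", "total_reads",
            "taxon", "classified_reads")
  readr::write_tsv(counts[, intersect(cols, names(counts))], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_read_counts
#' @export
read_read_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", subject = "c", family = "c", role = "c",
    day = "d", total_reads = "i", taxon = "c", classified_reads = "i"),
    progress = FALSE)
}

#' Write a variant set as minimal VCF 4.2
#'
#' One record per fixed or multiallelic call; positions are 1-based on
#' disk. FORMAT fields: `DP` (total site depth) and `AD` (depths of the
#' emitted alleles, REF-first style: the counts of the called alleles).
#' Multiallelic sites emit both called alleles' counts.
#'
#' @param variants A `variant_set`.
#' @param path File path.
#' @return `read_vcf_sites()` returns the calls tibble (0-based `pos`).
#' @export
write_vcf <- function(variants, path) {
  stopifnot(inherits(variants, "variant_set"))
  calls <- variants$calls
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", variants$reference_id,
            variants$L),
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Site status\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"Allele depths (called alleles)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           variants$sample_id))
  if (nrow(calls)) {
    alt <- ifelse(calls$status == "fixed_alt", calls$allele1,
                  ifelse(calls$allele1 == calls$ref, calls$allele2,
                         paste(calls$allele1, calls$allele2, sep = ",")))
    ad <- ifelse(calls$status == "fixed_alt", calls$count1,
                 paste(calls$count1, calls$count2, sep = ","))
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSTATUS=%s;MAF=%.6g\tDP:AD\t%d:%s",
                   variants$reference_id, calls$pos + 1L, calls$ref, alt,
                   calls$status, calls$minor_af, calls$depth, ad)
  } else rec <- character()
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf_sites <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(tibble(pos = integer(), ref = character(), alt = character(),
                  status = character(), depth = integer(),
                  minor_af = double(), ad = character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 10)
  if (length(bad)) {
    abort(sprintf("%s: malformed VCF record at data line %d", path, bad[1]))
  }
  info <- vapply(f, `[[`, character(1), 8)
  gt <- vapply(f, `[[`, character(1), 10)
  tibble(
    pos = as.integer(vapply(f, `[[`, character(1), 2)) - 1L,
    ref = vapply(f, `[[`, character(1), 4),
    alt = vapply(f, `[[`, character(1), 5),
    status = sub(".*STATUS=([^;]+).*", "\\1", info),
    depth = as.integer(sub(":.*", "", gt)),
    minor_af = as.numeric(sub(".*MAF=([^;]+).*", "\\1", info)),
    ad = sub(".*:", "", gt)
  )
}

#' Write a dendrogram as Newick
#'
#' @param x An `identity_matrix` (or an `hclust`).
#' @param path File path.
#' @export
write_newick <- function(x, path) {
  hc <- if (inherits(x, "identity_matrix")) x$hclust else x
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
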