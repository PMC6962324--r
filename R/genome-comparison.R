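#' Pairwise genome comparison by anchor chaining
#'
#' Aligns two assembled genome sequences and reports the length-weighted
#' average identity and total length of 1-1 aligned segments, the
#' quantities used to call putative transmission. The method: find maximal
#' exact matches of length >= `anchor_k` built from k-mers unique in both
#' sequences (MUM-style, so repeats are dropped); select the highest-weight
#' colinear chain by weighted longest-increasing-subsequence; close
#' inter-anchor gaps up to `max_gap` bp with global alignment (match +1,
#' mismatch -1, gap open -4, gap extend -1; equal-length gaps reduce to
#' direct base comparison); larger gaps split the alignment into separate
#' segments. Both orientations are tried and the one with the larger total
#' aligned length is reported.
#'
#' @param a,b Sequences to compare: character strings or `phage_genome`
#'   objects. Both must be at least `anchor_k` long.
#' @param anchor_k Anchor k-mer length (default 20; unique 20-mers are
#'   effectively specific at the 100 kb scale).
#' @param max_gap Largest inter-anchor gap closed by alignment (default
#'   2,000 bp); larger gaps are left unaligned so unrelated sequence is not
#'   forced into the identity average.
#' @return A `genome_comparison` object: `identity` (percent, length-
#'   weighted over segments), `aligned_length` (bp of aligned columns),
#'   `n_segments`, `orientation` (`"forward"`/`"reverse"`), `segments`
#'   tibble (`a_start`, `a_end`, `b_start`, `b_end`, `columns`, `matches`,
#'   `identity`; 0-based half-open, b-coordinates on the reported
#'   orientation). `glance()` gives the one-row summary; `tidy()` the
#'   segments.
#' @examples
#' g <- generate_genome(2000, seed = 1)
#' glance(align_pair(g, g))
#' @export
align_pair <- function(a, b, anchor_k = 20, max_gap = 2000) {
  a <- if (inherits(a, "phage_genome")) a$sequence else a
  b <- if (inherits(b, "phage_genome")) b$sequence else b
  anchor_k <- assert_count(anchor_k, "anchor_k", min = 8)
  if (nchar(a) < anchor_k || nchar(b) < anchor_k) {
    abort("both sequences must be at least `anchor_k` long")
  }
  fwd <- align_one_orientation(a, b, anchor_k, max_gap)
  rev <- align_one_orientation(a, revcomp(b), anchor_k, max_gap)
  res <- if (rev$aligned_length > fwd$aligned_length) rev else fwd
  res$orientation <- if (rev$aligned_length > fwd$aligned_length)
    "reverse" else "forward"
  structure(res, class = "genome_comparison")
}

align_one_orientation <- function(a, b, k, max_gap) {
  anchors <- find_anchors(a, b, k)
  if (!nrow(anchors)) {
    return(list(identity = NA_real_, aligned_length = 0L, n_segments = 0L,
                segments = empty_segments()))
  }
  chain <- chain_anchors(anchors)
  segs <- build_segments(a, b, chain, max_gap)
  total_cols <- sum(segs$columns)
  list(
    identity = if (total_cols > 0) 100 * sum(segs$matches) / total_cols
               else NA_real_,
    aligned_length = as.integer(total_cols),
    n_segments = nrow(segs),
    segments = segs
  )
}

empty_segments <- function() {
  tibble(a_start = integer(), a_end = integer(), b_start = integer(),
         b_end = integer(), columns = integer(), matches = integer(),
         identity = double())
}

# Maximal exact matches assembled from k-mers unique in both sequences.
# Returns a tibble of anchors (a_start, b_start 0-based, len).
find_anchors <- function(a, b, k) {
  na <- nchar(a) - k + 1L
  nb <- nchar(b) - k + 1L
  ka <- substring(a, 1:na, k:(na + k - 1L))
  kb <- substring(b, 1:nb, k:(nb + k - 1L))
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  ia <- which(ua)
  m <- match(ka[ia], kb)
  ok <- !is.na(m) & ub[pmax(m, 1L)]
  if (!any(ok)) {
    return(tibble(a_start = integer(), b_start = integer(), len = integer()))
  }
  ap <- ia[ok] - 1L   # 0-based
  bp <- m[ok] - 1L
  ord <- order(ap)
  ap <- ap[ord]
  bp <- bp[ord]
  # merge runs of consecutive seed matches on the same diagonal
  new_run <- c(TRUE, diff(ap) != 1L | diff(bp) != 1L)
  run_id <- cumsum(new_run)
  starts <- which(new_run)
  run_len <- tabulate(run_id)
  tibble(a_start = ap[starts], b_start = bp[starts],
         len = run_len + k - 1L)
}

# Highest-weight colinear chain (weight = anchor length) with strictly
# increasing starts in both sequences. O(n^2) DP with a vectorised inner
# scan; n is at most a few thousand for ~100 kb genomes.
chain_anchors <- function(anchors) {
  n <- nrow(anchors)
  if (n == 1) return(anchors)
  a0 <- anchors$a_start
  b0 <- anchors$b_start
  w <- as.numeric(anchors$len)
  score <- w
  prev <- rep(NA_integer_, n)
  for (i in 2:n) {
    j <- seq_len(i - 1L)
    feas <- a0[j] < a0[i] & b0[j] < b0[i]
    if (any(feas)) {
      cand <- score[j]
      cand[!feas] <- -Inf
      best <- which.max(cand)
      if (cand[best] > 0) {
        score[i] <- w[i] + cand[best]
        prev[i] <- best
      }
    }
  }
  path <- integer(0)
  i <- which.max(score)
  while (!is.na(i)) {
    path <- c(i, path)
    i <- prev[i]
  }
  anchors[path, ]
}

# Close inter-anchor gaps and accumulate 1-1 aligned segments.
build_segments <- function(a, b, chain, max_gap) {
  n <- nrow(chain)
  segs <- list()
  # trim anchors overlapping their predecessor (adjacent MUMs can share up
  # to k-1 bases)
  cur <- list(a_start = chain$a_start[1], b_start = chain$b_start[1],
              a_end = chain$a_start[1] + chain$len[1],
              b_end = chain$b_start[1] + chain$len[1],
              columns = chain$len[1], matches = chain$len[1])
  if (n >= 2) for (i in 2:n) {
    as0 <- chain$a_start[i]
    bs0 <- chain$b_start[i]
    len <- chain$len[i]
    trim <- max(cur$a_end - as0, cur$b_end - bs0, 0)
    as0 <- as0 + trim
    bs0 <- bs0 + trim
    len <- len - trim
    if (len <= 0) next
    ga <- as0 - cur$a_end
    gb <- bs0 - cur$b_end
    if (max(ga, gb) == 0) {
      cur$a_end <- as0 + len
      cur$b_end <- bs0 + len
      cur$columns <- cur$columns + len
      cur$matches <- cur$matches + len
    } else if (max(ga, gb) <= max_gap) {
      gap <- close_gap(substr(a, cur$a_end + 1, as0),
                       substr(b, cur$b_end + 1, bs0))
      cur$a_end <- as0 + len
      cur$b_end <- bs0 + len
      cur$columns <- cur$columns + gap$columns + len
      cur$matches <- cur$matches + gap$matches + len
    } else {
      segs[[length(segs) + 1]] <- cur
      cur <- list(a_start = as0, b_start = bs0, a_end = as0 + len,
                  b_end = bs0 + len, columns = len, matches = len)
    }
  }
  segs[[length(segs) + 1]] <- cur
  purrr::map_dfr(segs, function(s) {
    tibble(a_start = as.integer(s$a_start), a_end = as.integer(s$a_end),
           b_start = as.integer(s$b_start), b_end = as.integer(s$b_end),
           columns = as.integer(s$columns), matches = as.integer(s$matches),
           identity = 100 * s$matches / s$columns)
  })
}

# Align the sequence between two anchors. Equal-length gaps (pure
# substitution) reduce to direct comparison; a gap empty on one side is
# pure insertion (all gap columns, no matches); otherwise global alignment
# with nucmer-like scores.
close_gap <- function(ga, gb) {
  la <- nchar(ga)
  lb <- nchar(gb)
  if (la == lb) {
    m <- sum(seq_chars(ga) == seq_chars(gb))
    return(list(columns = la, matches = m))
  }
  if (la == 0 || lb == 0) {
    return(list(columns = max(la, lb), matches = 0L))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ga), Biostrings::DNAString(gb),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 4, gapExtension = 1)
  list(columns = Biostrings::nchar(al),
       matches = Biostrings::nmatch(al))
}

#' @export
print.genome_comparison <- function(x, ...) {
  cat(sprintf(
    "<genome_comparison> identity %.3f%%, aligned %s bp over %d segment(s) (%s)\n",
    x$identity, format(x$aligned_length, big.mark = ","), x$n_segments,
    x$orientation))
  invisible(x)
}

#' @export
tidy.genome_comparison <- function(x, ...) x$segments

#' @export
glance.genome_comparison <- function(x, ...) {
  tibble(identity = x$identity, aligned_length = x$aligned_length,
         n_segments = x$n_segments, orientation = x$orientation)
}

#' SNP identity between two samples
#'
#' Percent identity from fixed SNPs:
#' `100 * (1 - differing fixed SNPs / sites covered >= 10x in both)`.
#' A differing fixed SNP is a co-covered site where exactly one sample
#' carries a fixed alternate allele (the other being fixed reference) or
#' both carry different fixed alternates; multiallelic or uncallable sites
#' never count as differences.
#'
#' @param a,b `variant_set` objects called against the same reference.
#' @return A one-row tibble: `sample_a`, `sample_b`, `co_covered`,
#'   `n_differing`, `identity` (percent; `NA` with
#'   `insufficient_data = TRUE` when no site is co-covered).
#' @export
snp_identity <- function(a, b) {
  stopifnot(inherits(a, "variant_set"), inherits(b, "variant_set"))
  if (a$reference_id != b$reference_id || a$L != b$L) {
    abort("variant sets must share a reference")
  }
  co <- a$depth >= a$min_depth & b$depth >= b$min_depth
  n_co <- sum(co)
  if (n_co == 0) {
    return(tibble(sample_a = a$sample_id, sample_b = b$sample_id,
                  co_covered = 0L, n_differing = NA_integer_,
                  identity = NA_real_, insufficient_data = TRUE))
  }
  fa <- fixed_alt_map(a, co)
  fb <- fixed_alt_map(b, co)
  # positions where either has a non-fixed call (multiallelic/uncalled)
  # are uninformative
  bad <- union(non_fixed_positions(a, co), non_fixed_positions(b, co))
  fa <- fa[!names(fa) %in% bad]
  fb <- fb[!names(fb) %in% bad]
  shared <- intersect(names(fa), names(fb))
  only_a <- setdiff(names(fa), names(fb))
  only_b <- setdiff(names(fb), names(fa))
  n_diff <- sum(fa[shared] != fb[shared]) + length(only_a) + length(only_b)
  tibble(sample_a = a$sample_id, sample_b = b$sample_id,
         co_covered = as.integer(n_co), n_differing = as.integer(n_diff),
         identity = 100 * (1 - n_diff / n_co), insufficient_data = FALSE)
}

fixed_alt_map <- function(v, co_mask) {
  calls <- filter(v$calls, .data$status == "fixed_alt",
                  co_mask[.data$pos + 1L])
  setNames(calls$allele1, as.character(calls$pos))
}

non_fixed_positions <- function(v, co_mask) {
  multi <- filter(v$calls, .data$status == "multiallelic",
                  co_mask[.data$pos + 1L])$pos
  unc <- v$uncalled[co_mask[v$uncalled + 1L]]
  as.character(c(multi, unc))
}

#' All-vs-all identity matrix with Ward clustering
#'
#' Computes pairwise [align_pair()] identities between samples, clusters
#' the identity matrix with Ward's method (`ward.D2`) on Euclidean
#' distances between matrix rows, and serialises the dendrogram as Newick.
#' Pairs with no usable alignment (identity `NA`) are flagged and imputed
#' with the column minimum for clustering only.
#'
#' @param genomes Named list of sequences (character strings or
#'   `phage_genome` objects).
#' @param anchor_k,max_gap Passed to [align_pair()].
#' @return An `identity_matrix` object: `matrix` (percent identity,
#'   diagonal 100), `aligned_length` matrix, `flagged` logical matrix of
#'   imputed cells, `hclust`, `order` (leaf order), `newick` string, and
#'   `pairs` (tidy per-pair tibble).
#' @export
identity_matrix <- function(genomes, anchor_k = 20, max_gap = 2000) {
  n <- length(genomes)
  if (n < 2) abort("need at least two samples")
  ids <- names(genomes) %||% sprintf("sample_%d", seq_len(n))
  if (is.null(names(genomes))) names(genomes) <- ids
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  alen <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cmp <- align_pair(genomes[[i]], genomes[[j]], anchor_k = anchor_k,
                        max_gap = max_gap)
      m[i, j] <- m[j, i] <- cmp$identity
      alen[i, j] <- alen[j, i] <- cmp$aligned_length
      pairs[[length(pairs) + 1]] <- tibble(
        sample_a = ids[i], sample_b = ids[j], identity = cmp$identity,
        aligned_length = cmp$aligned_length, n_segments = cmp$n_segments,
        orientation = cmp$orientation)
    }
  }
  flagged <- is.na(m)
  mc <- m
  if (any(flagged)) {
    col_min <- apply(mc, 2, function(x) min(x, na.rm = TRUE))
    for (j in seq_len(n)) mc[is.na(mc[, j]), j] <- col_min[j]
  }
  hc <- hclust(dist(mc), method = "ward.D2")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  structure(list(matrix = m, aligned_length = alen, flagged = flagged,
                 hclust = hc, order = ids[hc$order], newick = nwk,
                 pairs = bind_rows(pairs)),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %d samples; leaf order: %s\n",
              nrow(x$matrix), paste(x$order, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.identity_matrix <- function(x, ...) x$pairs

#' Classify putative transmission from a genome comparison
#'
#' Applies the transmission rule: `putative_transmission` when identity
#' exceeds `identity_cut` (default 99.7%) over at least `length_cut`
#' aligned bp (default 20 kb); `related` for identities between 98% and
#' the cut with sufficient aligned length (the 99.2-99.7% span is included
#' here and flagged by the identity value itself); `unrelated` below 98%;
#' `insufficient_data` when less than `length_cut` aligned.
#'
#' @param comparisons A `genome_comparison`, or a data frame with
#'   `identity` and `aligned_length` columns (e.g. from
#'   [identity_matrix()]'s `pairs` or [glance()]).
#' @param identity_cut Percent identity threshold (default 99.7).
#' @param length_cut Minimum aligned length in bp (default 20,000).
#' @return The input rows as a tibble with a `label` column.
#' @examples
#' classify_transmission(
#'   tibble::tibble(identity = c(99.8, 99.8, 96),
#'                  aligned_length = c(85800, 12000, 80000)))
#' @export
classify_transmission <- function(comparisons, identity_cut = 99.7,
                                  length_cut = 20000) {
  if (inherits(comparisons, "genome_comparison")) {
    comparisons <- glance(comparisons)
  }
  comparisons |>
    as_tibble() |>
    mutate(label = dplyr::case_when(
      is.na(.data$identity) | .data$aligned_length < length_cut ~
        "insufficient_data",
      .data$identity > identity_cut ~ "putative_transmission",
      .data$identity >= 98 ~ "related",
      TRUE ~ "unrelated"
    ))
}
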