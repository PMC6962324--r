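#' Sliding-window genome profiles
#'
#' Computes the per-window tracks used to survey variation along a phage
#' genome: fraction of samples covering the window (a sample counts when at
#' least `min_window_frac` of window positions reach `min_depth`), GC
#' content, GC skew `(G - C) / (G + C)`, pooled multiallelic site count at
#' minor AF > `af_cut`, and `log2((N + 1) / (S + 1))` of nonsynonymous to
#' synonymous multiallelic sites (pseudocounts keep empty windows defined).
#' Windows start every `step` bp; the final partial window is truncated at
#' the genome end, never wrapped.
#'
#' @param genome A `phage_genome`.
#' @param sites Pooled effect-annotated multiallelic sites: a data frame
#'   with `pos`, `minor_af` and `category` columns (e.g.
#'   [predict_effect()] output joined to multiallelic calls). May be empty.
#' @param coverage A list of per-sample depth vectors (length L), e.g.
#'   `lapply(variant_sets, `[[`, "depth")`; may be empty, in which case the
#'   coverage track is `NA`.
#' @param window Window size in bp (default 1,500; must be <= L).
#' @param step Step size in bp (default 200).
#' @param af_cut Minor AF threshold for the site tracks (default 0.1).
#' @param min_depth Per-position coverage threshold (default 10).
#' @param min_window_frac Fraction of window positions that must reach
#'   `min_depth` for a sample to count as covering the window.
#' @return A `window_profile` tibble: `start`, `end`, `width`,
#'   `frac_samples_covered`, `gc`, `gc_skew`, `n_multiallelic`,
#'   `n_nonsynonymous`, `n_synonymous`, `log2_ns`.
#' @export
window_profiles <- function(genome, sites = NULL, coverage = list(),
                            window = 1500, step = 200, af_cut = 0.1,
                            min_depth = 10, min_window_frac = 0.5) {
  stopifnot(inherits(genome, "phage_genome"))
  L <- genome$length
  window <- assert_count(window, "window", min = 1)
  step <- assert_count(step, "step", min = 1)
  if (window > L) abort("`window` exceeds the genome length")
  chars <- seq_chars(genome$sequence)
  starts <- seq(0L, L - 1L, by = step)
  ends <- pmin(starts + window, L)

  # prefix sums: P[i+1] = count over positions [0, i)
  pre <- function(x) c(0, cumsum(x))
  win_sum <- function(P) P[ends + 1L] - P[starts + 1L]

  g_cum <- pre(chars == "G")
  c_cum <- pre(chars == "C")
  gn <- win_sum(g_cum)
  cn <- win_sum(c_cum)
  width <- ends - starts

  cover <- if (length(coverage)) {
    per_sample <- vapply(coverage, function(d) {
      if (length(d) != L) abort("coverage vector length must equal L")
      win_sum(pre(d >= min_depth)) / width >= min_window_frac
    }, logical(length(starts)))
    rowMeans(matrix(per_sample, nrow = length(starts)))
  } else NA_real_

  site_track <- function(mask_pos) {
    x <- integer(L)
    if (length(mask_pos)) {
      tab <- table(mask_pos)
      x[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    win_sum(pre(x))
  }
  if (is.null(sites) || !nrow(sites)) {
    n_multi <- n_ns <- n_s <- rep(0L, length(starts))
  } else {
    keep <- sites$minor_af > af_cut
    s <- sites[keep, ]
    n_multi <- site_track(s$pos)
    n_ns <- site_track(s$pos[s$category == "nonsynonymous"])
    n_s <- site_track(s$pos[s$category == "synonymous"])
  }

  out <- tibble(
    start = starts, end = ends, width = width,
    frac_samples_covered = cover,
    gc = (gn + cn) / width,
    gc_skew = ifelse(gn + cn > 0, (gn - cn) / (gn + cn), NA_real_),
    n_multiallelic = as.integer(n_multi),
    n_nonsynonymous = as.integer(n_ns),
    n_synonymous = as.integer(n_s),
    log2_ns = log2((n_ns + 1) / (n_s + 1))
  )
  class(out) <- c("window_profile", class(out))
  out
}

#' @rdname window_profiles
#' @param object A `window_profile`.
#' @param ... Unused.
#' @export
autoplot.window_profile <- function(object, ...) {
  long <- object |>
    select("start", "frac_samples_covered", "gc", "gc_skew",
           "n_multiallelic", "log2_ns") |>
    tidyr::pivot_longer(-"start", names_to = "track", values_to = "value") |>
    mutate(track = factor(.data$track, levels = c(
      "frac_samples_covered", "gc", "gc_skew", "n_multiallelic", "log2_ns")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track), scales = "free_y") +
    ggplot2::labs(x = "genome position (bp)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}
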