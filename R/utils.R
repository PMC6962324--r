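# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Complement / transition lookup tables, indexed by base character.
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")

# Evaluate `code` under a locally-set RNG seed; the caller's RNG state is
# untouched. A NULL seed leaves the global stream alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    withr::local_seed(as.integer(seed))
  }
  force(code)
}

# Split a genome string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste0(x, collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# TRUE when ref -> alt is a transition (A<->G, C<->T).
is_transition <- function(ref, alt) {
  unname(TRANSITION[ref] == alt)
}

assert_fraction <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || !lo_ok || !hi_ok) {
    abort(sprintf("`%s` must be a fraction in %s0, 1%s, got %s",
                  name, if (open_left) "(" else "[",
                  if (open_right) ")" else "]", format(x)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %s, got %s", name, min, format(x)))
  }
  invisible(as.integer(x))
}

# Draw one symmetric Dirichlet vector by gamma normalisation.
rdirichlet1 <- function(n, concentration) {
  g <- rgamma(n, shape = concentration, rate = 1)
  if (all(g == 0)) g <- rep(1, n)
  g / sum(g)
}

# Format numbers for TSV output without locale surprises.
num_chr <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}
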