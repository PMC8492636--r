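# Independent oracles and small fixture builders used across the suite.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Character-by-character reverse complement, independent of the package's
# chartr-based implementation.
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_is_primitive <- function(motif) {
  u <- nchar(motif)
  chars <- strsplit(motif, "")[[1]]
  for (d in seq_len(u - 1)) {
    if (u %% d != 0) next
    if (all(chars == rep(chars[seq_len(d)], u / d))) return(FALSE)
  }
  TRUE
}

# Shift-comparison run-length SSR scanner: for each unit length u, find
# maximal runs where s[j] == s[j + u] (N never matches), convert runs to
# tracts, keep complete repeats meeting the threshold and primitive motifs.
oracle_find_ssrs <- function(s, thresholds = ssr_thresholds()) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  out <- list()
  for (u in 2:6) {
    if (n < 2 * u) next
    lhs <- chars[1:(n - u)]
    rhs <- chars[(1 + u):n]
    eq <- lhs == rhs & lhs != "N" & rhs != "N"
    r <- rle(eq)
    starts <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      start <- starts[k]
      tract_len <- r$lengths[k] + u
      reps <- tract_len %/% u
      if (reps < thresholds[[as.character(u)]]) next
      motif <- paste(chars[start:(start + u - 1)], collapse = "")
      if (!oracle_is_primitive(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_length = u, repeats = reps,
        start = start, end = start + reps * u - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(), unit_length = integer(),
                      repeats = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random sequence with a few planted tandem repeats (possibly non-primitive
# motifs, possibly below threshold) to exercise the miner.
rand_seq_with_tracts <- function(len, n_tracts) {
  s <- rand_dna(len)
  for (k in seq_len(n_tracts)) {
    u <- sample(2:6, 1)
    motif <- rand_dna(u)
    reps <- sample(3:12, 1)
    tract <- strrep(motif, reps)
    pos <- sample(seq_len(max(1, len - nchar(tract))), 1)
    substr(s, pos, pos + nchar(tract) - 1) <- tract
  }
  s
}

# Direct band_matrix builder for statistics tests (values: bands x samples).
make_bm <- function(values, pair_names, sizes = NULL,
                    samples = paste0("s", seq_len(ncol(values)))) {
  if (is.null(sizes)) sizes <- 100 * seq_len(nrow(values))
  bands <- data.frame(pair_name = pair_names,
                      bin_id = as.integer(stats::ave(seq_along(pair_names),
                                                     pair_names,
                                                     FUN = seq_along)),
                      size = sizes, stringsAsFactors = FALSE)
  values <- as.matrix(values)
  dimnames(values) <- list(paste(bands$pair_name, bands$bin_id, bands$size,
                                 sep = ":"), samples)
  structure(list(values = values, bands = bands, samples = samples),
            class = "band_matrix")
}

# n_pairs single-band pairs of which n_poly are polymorphic across two
# samples; used for the percentage rounding checks.
poly_fraction_bm <- function(n_pairs, n_poly) {
  vals <- matrix(1L, n_pairs, 2)
  vals[seq_len(n_poly), 2] <- 0L
  make_bm(vals, pair_names = sprintf("p%02d", seq_len(n_pairs)))
}
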