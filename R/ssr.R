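#' MISA-style microsatellite search thresholds
#'
#' Minimum repeat counts per motif unit length (2-6 nt). The default is the
#' standard transcript-mining setting for di- to hexa-nucleotide motifs:
#' at least 6, 5, 5, 4 and 4 repeats respectively. Mononucleotide repeats
#' are not mined.
#'
#' @param min_repeats Named integer vector or list with names "2".."6".
#' @return Named integer vector of class `ssr_thresholds`.
#' @export
ssr_thresholds <- function(min_repeats = c(`2` = 6L, `3` = 5L, `4` = 5L,
                                           `5` = 4L, `6` = 4L)) {
  min_repeats <- unlist(min_repeats)
  if (!setequal(names(min_repeats), as.character(2:6))) {
    stop("thresholds must have keys exactly 2..6")
  }
  min_repeats <- min_repeats[as.character(2:6)]
  if (any(min_repeats < 2)) {
    stop("minimum repeat counts must be >= 2")
  }
  structure(as.integer(min_repeats), names = as.character(2:6),
            class = "ssr_thresholds")
}

# TRUE when the motif cannot be written as a tandem repetition of a shorter
# unit (e.g. ATAT = AT x 2 is non-primitive and is reported at unit AT).
is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && motif == strrep(substr(motif, 1L, d), u / d)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Find perfect microsatellites (SSR loci)
#'
#' Detects all maximal perfect tandem repeats of unit length 2-6 meeting the
#' per-unit minimum repeat counts, in MISA semantics: only complete repeat
#' units count towards the reported tract, motifs that are themselves
#' repetitions of a shorter unit are reported at the shorter unit, and the
#' motif is reported exactly as it occurs at the locus start. N never
#' matches, so an N interrupts a tract. Coordinates are 1-based inclusive.
#'
#' @param seqs data.frame with columns `id` and `seq` (as from
#'   [read_fasta()]), or a named character vector of DNA sequences.
#' @param thresholds An [ssr_thresholds()] object.
#' @param compound_max_gap Two loci of a sequence separated by at most this
#'   many nucleotides are annotated as members of the same compound SSR
#'   (column `compound`); they still count individually.
#' @return data.frame with columns `sequence_id`, `ssr_nr`, `motif`,
#'   `unit_length`, `repeats`, `size`, `start`, `end`, `compound`.
#' @export
find_ssrs <- function(seqs, thresholds = ssr_thresholds(),
                      compound_max_gap = 100L) {
  if (is.character(seqs)) {
    seqs <- data.frame(id = names(seqs), seq = unname(seqs),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  out <- list()
  for (i in seq_len(nrow(seqs))) {
    s <- check_dna(seqs$seq[i], paste0("sequence '", seqs$id[i], "'"))
    hits <- list()
    n_s <- nchar(s)
    for (u in 2:6) {
      min_r <- thresholds[[as.character(u)]]
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, min_r - 1L)
      # maximal same-unit tracts may overlap by up to u-1 bases (e.g.
      # ...CCGACCGA|ACGAACGA... sharing one A), so searching resumes u-1
      # bases before the previous match end rather than after it; the
      # periodic tail left behind is shorter than two units and can never
      # be re-reported.
      pos <- 1L
      while (pos + 2L * u - 1L <= n_s) {
        m <- regexpr(pat, substr(s, pos, n_s), perl = TRUE)
        if (m == -1L) break
        start <- pos + as.integer(m) - 1L
        len <- attr(m, "match.length")
        motif <- substr(s, start, start + u - 1L)
        if (is_primitive_motif(motif)) {
          reps <- len %/% u
          hits[[length(hits) + 1L]] <- data.frame(
            sequence_id = seqs$id[i], motif = motif, unit_length = u,
            repeats = reps, size = reps * u, start = start,
            end = start + reps * u - 1L, stringsAsFactors = FALSE)
        }
        pos <- start + len - u + 1L
      }
    }
    if (length(hits) == 0L) next
    loci <- do.call(rbind, hits)
    loci <- loci[order(loci$start, loci$unit_length), , drop = FALSE]
    loci$ssr_nr <- seq_len(nrow(loci))
    # compound annotation: chain loci whose gap is <= compound_max_gap
    comp <- integer(nrow(loci))
    if (nrow(loci) > 1L) {
      gap_join <- loci$start[-1L] - loci$end[-nrow(loci)] - 1L <= compound_max_gap
      grp <- cumsum(c(1L, !gap_join))
      sizes <- table(grp)
      comp <- ifelse(sizes[as.character(grp)] > 1L, grp, 0L)
    }
    loci$compound <- as.integer(comp)
    out[[length(out) + 1L]] <- loci
  }
  if (length(out) == 0L) {
    return(data.frame(sequence_id = character(), ssr_nr = integer(),
                      motif = character(), unit_length = integer(),
                      repeats = integer(), size = integer(),
                      start = integer(), end = integer(),
                      compound = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("sequence_id", "ssr_nr", "motif", "unit_length", "repeats",
          "size", "start", "end", "compound")]
}

canonical_rotation <- function(motif) {
  u <- nchar(motif)
  rots <- vapply(seq_len(u), function(k) {
    paste0(substr(motif, k, u), substr(motif, 1L, k - 1L))
  }, character(1))
  min(rots)
}

#' Motif frequency table from SSR loci
#'
#' Counts loci per motif and unit length, sorted by descending count within
#' unit length. With `canonicalize = TRUE` cyclic rotations of a motif are
#' merged to their lexicographically smallest representative; reverse
#' complements are never merged (TC and AG stay distinct selections).
#'
#' @param loci data.frame from [find_ssrs()].
#' @param canonicalize Merge cyclic rotations (default FALSE: motifs are
#'   reported exactly as they occur).
#' @return data.frame with columns `motif`, `unit_length`, `locus_count`,
#'   `sequence_ids` (semicolon-joined host sequence ids).
#' @export
motif_frequency <- function(loci, canonicalize = FALSE) {
  if (nrow(loci) == 0L) {
    return(data.frame(motif = character(), unit_length = integer(),
                      locus_count = integer(), sequence_ids = character(),
                      stringsAsFactors = FALSE))
  }
  key <- if (canonicalize) {
    vapply(loci$motif, canonical_rotation, character(1))
  } else {
    loci$motif
  }
  agg <- split(seq_len(nrow(loci)), key)
  tab <- data.frame(
    motif = names(agg),
    unit_length = vapply(agg, function(ix) loci$unit_length[ix[1]], integer(1)),
    locus_count = vapply(agg, length, integer(1)),
    sequence_ids = vapply(agg, function(ix) {
      paste(unique(loci$sequence_id[ix]), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$unit_length, -tab$locus_count, tab$motif), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

rank_norm <- function(x) {
  if (length(x) == 1L) return(1)
  r <- rank(x, ties.method = "average")
  (r - 1) / (length(x) - 1)
}

#' Select SSR motifs for ISSR primer design
#'
#' Ranks motifs within each unit length by a weighted combination of
#' abundance (locus count) and the activity of the genes hosting the motif
#' (e.g. |log2 fold-change| from a differential-expression table), then
#' returns the top `k_per_unit` motifs per unit length. By default di-,
#' tri- and penta-nucleotide motifs are considered. With no activity table
#' the score is abundance rank alone.
#'
#' @param freq Motif frequency table from [motif_frequency()].
#' @param gene_activity Optional named numeric vector (gene id -> activity
#'   score).
#' @param k_per_unit Motifs to keep per unit length (default 1).
#' @param units Unit lengths considered (default c(2, 3, 5)).
#' @param w_abund,w_act Score weights; `w_act` defaults to 1 when an
#'   activity table is supplied and 0 otherwise.
#' @return data.frame of chosen rows of `freq` plus a `score` column.
#' @export
select_motifs <- function(freq, gene_activity = NULL, k_per_unit = 1L,
                          units = c(2L, 3L, 5L), w_abund = 1,
                          w_act = if (is.null(gene_activity)) 0 else 1) {
  if (nrow(freq) == 0L) stop("empty motif frequency table")
  freq <- freq[freq$unit_length %in% units, , drop = FALSE]
  if (nrow(freq) == 0L) stop("no motifs with unit length in {",
                             paste(units, collapse = ","), "}")
  act_of <- function(ids_str) {
    if (is.null(gene_activity)) return(0)
    ids <- strsplit(ids_str, ";", fixed = TRUE)[[1]]
    v <- gene_activity[ids]
    if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
  }
  chosen <- list()
  for (u in sort(unique(freq$unit_length))) {
    sub <- freq[freq$unit_length == u, , drop = FALSE]
    act <- vapply(sub$sequence_ids, act_of, numeric(1))
    sub$score <- w_abund * rank_norm(sub$locus_count) + w_act * rank_norm(act)
    # ties broken by activity, then lexicographically for determinism
    ord <- order(-sub$score, -act, sub$motif)
    k <- k_per_unit
    if (k > nrow(sub)) {
      warning("only ", nrow(sub), " motif(s) of unit length ", u,
              " available (k_per_unit = ", k_per_unit, ")")
      k <- nrow(sub)
    }
    chosen[[as.character(u)]] <- sub[ord[seq_len(k)], , drop = FALSE]
  }
  res <- do.call(rbind, chosen)
  rownames(res) <- NULL
  res
}

#' Split two gene-id sets into exclusive and shared subsets
#'
#' Mirrors the Venn-diagram preparation of exclusive differentially
#' expressed gene sets before SSR mining.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return list with components `only_a`, `only_b`, `shared` (disjoint;
#'   union equals `set_a` ∪ `set_b`).
#' @export
exclusive_transcripts <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  list(only_a = setdiff(set_a, set_b),
       only_b = setdiff(set_b, set_a),
       shared = intersect(set_a, set_b))
}

#' Write SSR loci as a MISA-style TSV
#'
#' @param loci data.frame from [find_ssrs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ssr_tsv <- function(loci, path) {
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
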